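# Tie-aware rank comparison between the GC-derived chronology and published
# amino-acid chronologies, plus the abundance-vs-GC check. Tied
# (parenthesized) amino acids in the published lists share a rank; the
# GC-derived chronology uses column indices as ranks so its ties are
# preserved too.

#' Construct a chronology
#'
#' @param name identifier.
#' @param ranks named numeric vector amino acid -> rank; tied amino acids
#'   share a rank value.
#' @return a `chronology` object.
#' @export
chronology <- function(name, ranks) {
  stopifnot(is.numeric(ranks), !is.null(names(ranks)))
  names(ranks) <- aa_to_three(names(ranks))
  if (anyDuplicated(names(ranks))) stop("duplicated amino acid in chronology")
  structure(list(name = name, ranks = ranks, coverage = names(ranks)),
            class = "chronology")
}

#' @export
print.chronology <- function(x, ...) {
  cat("Chronology '", x$name, "' over ", length(x$ranks), " amino acids\n",
      sep = "")
  invisible(x)
}

#' The packaged chronologies
#'
#' Returns three chronologies: the Trifonov consensus order, the Trifonov
#' N6' (stability of complementary interactions) order — both transcribed
#' as printed, parenthesized ties as shared ranks — and the GC-derived
#' order of this package (column index as rank, amino acids only, stop
#' entries dropped).
#'
#' @param order optional `chrono_order` to derive the GC chronology from;
#'   defaults to [chrono_arrange()] on the standard code.
#' @param path TSV fixture with columns `name`, `aa`, `rank` for the
#'   published lists.
#' @return named list of `chronology` objects: `trifonov_consensus`,
#'   `trifonov_n6prime`, `gc_order`.
#' @examples
#' chr <- packaged_chronologies()
#' chr$trifonov_consensus$ranks[["Gly"]]  # 1
#' @export
packaged_chronologies <- function(order = NULL,
                                  path = system.file("extdata",
                                                     "chronologies.tsv",
                                                     package = "codonchron")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$name), function(d) {
    chronology(d$name[1L], stats::setNames(d$rank, d$aa))
  })
  for (nm in names(out)) {
    if (!setequal(out[[nm]]$coverage, AMINO_ACIDS)) {
      stop("chronology '", nm, "' must cover the 20 canonical amino acids")
    }
  }
  if (is.null(order)) order <- chrono_arrange(load_standard_code())
  ent <- chrono_flatten(order)
  aa <- ent[ent$type == "aa", ]
  out$gc_order <- chronology("gc_order",
                             stats::setNames(aa$column, aa$id))
  out[c("trifonov_consensus", "trifonov_n6prime", "gc_order")]
}

# concordant/discordant/tie counts over all pairs (n is small; O(n^2))
.pair_counts <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- txy <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) txy <- txy + 1L
      else if (dx == 0) tx <- tx + 1L
      else if (dy == 0) ty <- ty + 1L
      else if (dx == dy) C <- C + 1L
      else D <- D + 1L
    }
  }
  list(C = C, D = D, tx = tx, ty = ty, txy = txy, n0 = n * (n - 1L) / 2L)
}

#' Kendall tau-b between two chronologies
#'
#' Tie-corrected Kendall rank correlation over the intersection of the two
#' coverages, computed by explicit concordant/discordant pair counting:
#' tau_b = (C - D) / sqrt((n0 - t_x)(n0 - t_y)) with t_x, t_y the pairs
#' tied in each ranking (jointly tied pairs count in both). Spearman rho on
#' mid-ranks is reported alongside.
#'
#' @param a,b `chronology` objects (or named rank vectors).
#' @return A `rank_comparison`: list with `tau_b`, `rho`, `n`, and the pair
#'   counts (`concordant`, `discordant`).
#' @examples
#' chr <- packaged_chronologies()
#' kendall_tau_b(chr$gc_order, chr$trifonov_n6prime)
#' @export
kendall_tau_b <- function(a, b) {
  if (!inherits(a, "chronology")) a <- chronology("a", a)
  if (!inherits(b, "chronology")) b <- chronology("b", b)
  common <- intersect(a$coverage, b$coverage)
  if (length(common) < 3L) {
    stop("chronologies share fewer than 3 amino acids (", length(common), ")")
  }
  x <- unname(a$ranks[common])
  y <- unname(b$ranks[common])
  pc <- .pair_counts(x, y)
  denom <- sqrt((pc$n0 - pc$tx - pc$txy) * (pc$n0 - pc$ty - pc$txy))
  tau <- if (denom == 0) {
    warning("all pairs tied in at least one ranking; tau_b set to 0")
    0
  } else (pc$C - pc$D) / denom
  rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant ranks; rho set to 0")
    0
  } else stats::cor(rank(x), rank(y))
  structure(list(tau_b = tau, rho = rho, n = length(common),
                 concordant = pc$C, discordant = pc$D,
                 names = c(a$name, b$name)),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("Rank comparison %s vs %s (n = %d): tau_b = %.3f, rho = %.3f\n",
              x$names[1], x$names[2], x$n, x$tau_b, x$rho))
  invisible(x)
}

#' Reverse a chronology
#'
#' @param chron a `chronology`.
#' @return a `chronology` with ranks reflected (late becomes early).
#' @export
reverse_chronology <- function(chron) {
  stopifnot(inherits(chron, "chronology"))
  chronology(paste0(chron$name, "_reversed"),
             max(chron$ranks) + min(chron$ranks) - chron$ranks)
}

#' Rank correlation between prebiotic abundance and GC-order rank
#'
#' Exploratory check of whether amino-acid prebiotic abundance tracks the
#' GC-derived chronology. The comparison is reported descriptively only:
#' the underlying claim is that GC-richness is *not* linked to abundance,
#' so no pass/fail threshold applies. Higher abundance is converted to an
#' earlier (smaller) rank before comparison.
#'
#' @param abund an `abundance_table`.
#' @param order a `chrono_order`.
#' @param panel `"a"` or `"b"`.
#' @param summary abundance point summary, see [abundance_summary()];
#'   midpoints by default (derived, never stored).
#' @return a `rank_comparison` over the amino acids reported in the panel.
#' @export
abundance_vs_gc <- function(abund, order, panel = c("a", "b"),
                            summary = c("midpoint", "lo", "hi")) {
  panel <- match.arg(panel)
  summary <- match.arg(summary)
  val <- abundance_summary(abund, panel, summary)
  if (length(val) < 3L) stop("panel (", panel, ") reports fewer than 3 amino acids")
  abund_rank <- rank(-val)  # most abundant first
  chr <- packaged_chronologies(order = order)
  kendall_tau_b(chronology(paste0("abundance_", panel), abund_rank),
                chr$gc_order)
}
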