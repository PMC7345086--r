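# Overlay of aaRS class labels on the chronological order, detection of
# maximal same-class runs ("zones"), and a Monte-Carlo permutation statistic
# for zonal clustering (fewer runs than expected under random labeling).

#' Overlay aaRS classes on a chronological order
#'
#' Pure relabeling: each amino acid receives `"I"`, `"II"` or `"BOTH"` from
#' the class map; stop entries are labeled `"STOP"`. No reordering.
#'
#' @param order a `chrono_order` from [chrono_arrange()].
#' @param classes an `aars_class_map` from [load_aars_classes()].
#' @return A `class_sequence`: data.frame with columns `id`, `group`,
#'   `column`, `rank`, `label`, in flattened order.
#' @examples
#' seq <- overlay_classes(chrono_arrange(load_standard_code()),
#'                        load_aars_classes())
#' seq$label[seq$id == "Lys"]  # "BOTH"
#' @export
overlay_classes <- function(order, classes) {
  stopifnot(inherits(order, "chrono_order"),
            inherits(classes, "aars_class_map"))
  ent <- chrono_flatten(order)
  lab <- vapply(seq_len(nrow(ent)), function(i) {
    if (ent$type[i] == "stop") return("STOP")
    cl <- classes$class_of[[ent$id[i]]]
    if (is.null(cl)) stop("no aaRS class for amino acid: ", ent$id[i])
    if (length(cl) == 2L) "BOTH" else cl
  }, character(1))
  out <- data.frame(id = ent$id, group = ent$group, column = ent$column,
                    rank = ent$rank, label = lab, stringsAsFactors = FALSE)
  class(out) <- c("class_sequence", "data.frame")
  out
}

# effective label sequence under a dual/stop policy; STOP is always dropped
.effective_labels <- function(seq, dual_policy) {
  keep <- seq$label != "STOP"
  if (dual_policy == "exclude") keep <- keep & seq$label != "BOTH"
  lab <- seq$label[keep]
  if (dual_policy == "either" && length(lab)) {
    # BOTH never breaks a run: adopt the previous run's label (next, at start)
    for (i in seq_along(lab)) {
      if (lab[i] == "BOTH") {
        lab[i] <- if (i > 1L) lab[i - 1L] else {
          nxt <- lab[lab != "BOTH"]
          if (length(nxt)) nxt[1L] else "BOTH"
        }
      }
    }
  }
  list(labels = lab, id = seq$id[keep])
}

#' Detect maximal same-class runs (zones)
#'
#' Partitions the effective class sequence (after applying the dual/stop
#' policy) into maximal runs of identical labels.
#'
#' @param seq a `class_sequence` from [overlay_classes()].
#' @param dual_policy how dual-class (Lys) positions are handled:
#'   `"exclude"` (default, dropped together with stops), `"either"` (a BOTH
#'   position extends the adjacent run), or `"own"` (BOTH is its own label).
#' @return A `zone_partition`: list with `runs` (data.frame: label, length,
#'   members) and `n_runs`.
#' @examples
#' seq <- overlay_classes(chrono_arrange(load_standard_code()),
#'                        load_aars_classes())
#' detect_runs(seq)
#' @export
detect_runs <- function(seq, dual_policy = c("exclude", "either", "own")) {
  dual_policy <- match.arg(dual_policy)
  eff <- .effective_labels(seq, dual_policy)
  if (!length(eff$labels)) stop("effective class sequence is empty")
  r <- rle(eff$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(label = r$values, length = r$lengths,
                     members = vapply(seq_along(r$values), function(i) {
                       paste(eff$id[starts[i]:ends[i]], collapse = ",")
                     }, character(1)), stringsAsFactors = FALSE)
  structure(list(runs = runs, n_runs = nrow(runs), dual_policy = dual_policy),
            class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat("Zonal partition (", x$n_runs, " runs, dual policy ", x$dual_policy,
      "):\n", sep = "")
  for (i in seq_len(nrow(x$runs))) {
    cat(sprintf("  %-4s %s\n", x$runs$label[i], x$runs$members[i]))
  }
  invisible(x)
}

#' Permutation p-value for zonal clustering
#'
#' Monte-Carlo test of whether the observed number of same-class runs is
#' smaller than expected when class labels are shuffled over positions
#' (one-sided, clustering alternative). Uses the add-one correction
#' p = (1 + #\{permuted runs <= observed\}) / (n_permutations + 1).
#'
#' @param seq a `class_sequence`.
#' @param n_permutations number of label permutations (default 10000).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param dual_policy passed to [detect_runs()].
#' @return A `cluster_stat`: list with `observed_runs`, `n_permutations`,
#'   `seed`, `p_value`.
#' @examples
#' seq <- overlay_classes(chrono_arrange(load_standard_code()),
#'                        load_aars_classes())
#' clustering_pvalue(seq, n_permutations = 1000, seed = 1)
#' @export
clustering_pvalue <- function(seq, n_permutations = 10000, seed,
                              dual_policy = c("exclude", "either", "own")) {
  dual_policy <- match.arg(dual_policy)
  stopifnot(n_permutations >= 1)
  eff <- .effective_labels(seq, dual_policy)
  lab <- eff$labels
  if (length(lab) < 2L || length(unique(lab)) < 2L) {
    stop("clustering statistic undefined: need >= 2 positions with both labels")
  }
  observed <- length(rle(lab)$values)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample(lab)
    if (length(rle(perm)$values) <= observed) hits <- hits + 1L
  }
  structure(list(observed_runs = observed, n_positions = length(lab),
                 n_permutations = as.integer(n_permutations),
                 seed = seed,
                 p_value = (1 + hits) / (n_permutations + 1)),
            class = "cluster_stat")
}

#' @export
print.cluster_stat <- function(x, ...) {
  cat("Clustering permutation test: ", x$observed_runs, " runs over ",
      x$n_positions, " positions; p = ", signif(x$p_value, 4),
      " (", x$n_permutations, " permutations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Annotate the UGA stop codon relative to the class II / class I boundary
#'
#' The first stop codon UGA is proposed to mark the transition between the
#' early all-class-II period and the onset of class I synthetases. This
#' annotation reports UGA's position, its immediate flanking entries, the
#' nearest class II-only run before it and class I-only run at/after it,
#' and whether UGA sits in the boundary region (after the early class II
#' zone has ended and no later than the end of the first class I zone).
#'
#' @param seq a `class_sequence` containing a UGA entry.
#' @param dual_policy passed to [detect_runs()].
#' @return list with `uga_rank`, `flanking` (ids and labels of the entries
#'   directly before/after UGA), `last_II_run_before`, `first_I_run_after`,
#'   `at_boundary` (logical), and `note` for degenerate inputs.
#' @export
preluca_boundary <- function(seq, dual_policy = c("exclude", "either", "own")) {
  dual_policy <- match.arg(dual_policy)
  pos <- which(seq$id == "UGA")
  if (!length(pos)) stop("UGA not present in the ordered sequence")
  pos <- pos[1L]
  flank <- list(
    before = if (pos > 1L) seq[pos - 1L, c("id", "label")] else NULL,
    after = if (pos < nrow(seq)) seq[pos + 1L, c("id", "label")] else NULL)
  if (is.null(flank$before)) {
    return(list(uga_rank = seq$rank[pos], flanking = flank,
                last_II_run_before = NULL, first_I_run_after = NULL,
                at_boundary = FALSE, note = "degenerate: no preceding run"))
  }
  # runs over the effective sequence, with original ranks retained
  keep <- seq$label != "STOP"
  if (dual_policy == "exclude") keep <- keep & seq$label != "BOTH"
  eff <- seq[keep, ]
  r <- rle(.effective_labels(seq, dual_policy)$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_df <- data.frame(label = r$values,
                       start_rank = eff$rank[starts],
                       end_rank = eff$rank[ends],
                       members = vapply(seq_along(r$values), function(i) {
                         paste(eff$id[starts[i]:ends[i]], collapse = ",")
                       }, character(1)), stringsAsFactors = FALSE)
  uga_rank <- seq$rank[pos]
  ii_before <- run_df[run_df$label == "II" & run_df$end_rank < uga_rank, ]
  i_after <- run_df[run_df$label == "I" & run_df$end_rank > uga_rank, ]
  last_ii <- if (nrow(ii_before)) ii_before[nrow(ii_before), ] else NULL
  first_i <- if (nrow(i_after)) i_after[1L, ] else NULL
  at_boundary <- !is.null(last_ii) && !is.null(first_i) &&
    uga_rank > last_ii$end_rank && uga_rank < first_i$end_rank
  list(uga_rank = uga_rank, flanking = flank,
       last_II_run_before = last_ii, first_I_run_after = first_i,
       at_boundary = at_boundary, note = NULL)
}
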