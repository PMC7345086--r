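# Chronological arrangement of amino acids and stop codons by codon
# GC-richness. Two rules: (1) G/C at the middle base, then at the first
# base, place an entry earlier (middle has priority over first); (2) within
# the group set by rule 1, entries with more codons are earlier. Entries
# with the same score share a column (same inferred period).

#' GC key of a codon
#'
#' Positional G/C indicators used by the ordering rules: middle base first
#' (highest priority), then the first 5' base, then the third (wobble) base.
#'
#' @param codon a single codon (RNA or DNA alphabet).
#' @return named integer vector `middle_gc`, `first_gc`, `third_gc`,
#'   `gc_count` (their sum).
#' @examples
#' codon_key("GCG")  # all three positions G/C
#' @export
codon_key <- function(codon) {
  codon <- normalize_codon(codon)
  stopifnot(length(codon) == 1L)
  b <- strsplit(codon, "")[[1]]
  gc <- as.integer(b %in% c("G", "C"))
  c(middle_gc = gc[2L], first_gc = gc[1L], third_gc = gc[3L],
    gc_count = sum(gc))
}

.key_matrix <- function(codons) {
  t(vapply(codons, codon_key, c(middle_gc = 0L, first_gc = 0L,
                                third_gc = 0L, gc_count = 0L)))
}

# Highest-priority key among an entry's codons: lexicographic max on
# (middle_gc, first_gc, third_gc). Multi-block amino acids (Arg, Ser, Leu)
# are thereby classified by their best codon block.
.best_key <- function(codons) {
  k <- .key_matrix(codons)
  ord <- order(k[, "middle_gc"], k[, "first_gc"], k[, "third_gc"],
               decreasing = TRUE)
  k[ord[1L], ]
}

#' Chronological group labels
#' @export
CHRONO_GROUPS <- c("GC_RICH", "MIDDLE", "AU_RICH")

# codons for an entry id under a stop policy; ids are 3-letter amino acids,
# "UGA", or the merged "UAA/UAG" (or "UAA"/"UAG" when split)
.entry_codons <- function(id, table) {
  if (id %in% names(table$families)) return(table$families[[id]])
  cods <- normalize_codon(strsplit(id, "/", fixed = TRUE)[[1]])
  if (!all(cods %in% table$stops)) stop("unknown entry: ", id)
  cods
}

#' Assign the chronological group of an amino acid or stop entry
#'
#' GC-rich: some codon has G/C at both the middle and first positions.
#' Middle: the best codon has G/C at the middle position but A/U first.
#' AU-rich: every codon has A/U at the middle position.
#'
#' @param id amino-acid code, `"UGA"`, `"UAA"`, `"UAG"` or `"UAA/UAG"`.
#' @param table a `codon_table`.
#' @return one of `"GC_RICH"`, `"MIDDLE"`, `"AU_RICH"`.
#' @examples
#' code <- load_standard_code()
#' assign_group("Arg", code)  # GC_RICH via the CGN block
#' assign_group("Ser", code)  # MIDDLE
#' @export
assign_group <- function(id, table) {
  stopifnot(inherits(table, "codon_table"))
  if (!id %in% c("UGA", "UAA", "UAG", "UAA/UAG")) id <- aa_to_three(id)
  key <- .best_key(.entry_codons(id, table))
  if (key[["middle_gc"]] == 1L && key[["first_gc"]] == 1L) return("GC_RICH")
  if (key[["middle_gc"]] == 1L) return("MIDDLE")
  "AU_RICH"
}

# third-position-only degeneracy: max number of wobble variants within one
# (first, middle) codon box of the entry
.wobble_degeneracy <- function(codons) {
  max(table(substr(codons, 1L, 2L)))
}

#' Arrange the genetic code chronologically by GC-richness
#'
#' Produces the full arrangement: entries (20 amino acids plus stop
#' entries) are grouped GC-rich < middle < AU-rich and, within a group,
#' ranked by codon count descending (default `tie_rule = "total-codons"`;
#' `"wobble-only"` ranks by third-position degeneracy within the best codon
#' box instead, available for sensitivity analysis). Entries with equal
#' scores share a column, read as the same inferred period. The flattening
#' breaks in-column ties alphabetically by 3-letter code with stop entries
#' last; it is deterministic and purely rule-determined (independent of the
#' input row order of the code table).
#'
#' @param table a `codon_table`.
#' @param tie_rule within-group ranking rule, `"total-codons"` (default) or
#'   `"wobble-only"`.
#' @param stops `"merged"` (default): UAA and UAG form one 2-codon stop
#'   entry `"UAA/UAG"` (UGA is always its own entry); `"split"`: three
#'   separate 1-codon stop entries.
#' @return A `chrono_order` object: list with `entries` (data.frame: id,
#'   type, group, n_codons, column, rank and the GC-key columns; one row
#'   per entry in flattened order; `column` and `rank` are 1-based) and
#'   `provenance` (the rule parameters).
#' @examples
#' ord <- chrono_arrange(load_standard_code())
#' head(ord$entries)
#' @export
chrono_arrange <- function(table, tie_rule = c("total-codons", "wobble-only"),
                           stops = c("merged", "split")) {
  stopifnot(inherits(table, "codon_table"))
  tie_rule <- match.arg(tie_rule)
  stops <- match.arg(stops)
  stop_ids <- if (stops == "merged") c("UGA", "UAA/UAG") else
    c("UGA", "UAA", "UAG")
  ids <- c(sort(names(table$families)), stop_ids)
  rows <- lapply(ids, function(id) {
    cods <- .entry_codons(id, table)
    key <- .best_key(cods)
    data.frame(id = id,
               type = if (id %in% names(table$families)) "aa" else "stop",
               group = assign_group(id, table),
               n_codons = length(cods),
               score = if (tie_rule == "total-codons") length(cods) else
                 .wobble_degeneracy(cods),
               middle_gc = key[["middle_gc"]], first_gc = key[["first_gc"]],
               third_gc = key[["third_gc"]], stringsAsFactors = FALSE)
  })
  ent <- do.call(rbind, rows)
  grp <- match(ent$group, CHRONO_GROUPS)
  # flattened order: group, score desc, then alphabetical with stops last
  ord <- order(grp, -ent$score, ent$type == "stop", ent$id)
  ent <- ent[ord, ]
  # columns: consecutive (group, score) classes
  cls <- paste(ent$group, ent$score)
  ent$column <- cumsum(!duplicated(cls))
  ent$rank <- seq_len(nrow(ent))
  ent$score <- NULL
  rownames(ent) <- NULL
  structure(list(entries = ent,
                 provenance = list(tie_rule = tie_rule, stops = stops)),
            class = "chrono_order")
}

#' @export
print.chrono_order <- function(x, ...) {
  cat("Chronological order (", x$provenance$tie_rule, ", stops ",
      x$provenance$stops, "): ", nrow(x$entries), " entries in ",
      max(x$entries$column), " columns\n", sep = "")
  cols <- split(x$entries$id, x$entries$column)
  cat(paste(vapply(cols, paste, "", collapse = ","), collapse = " | "), "\n")
  invisible(x)
}

#' Flatten a chronological order
#'
#' Returns the deterministic total order over entries (in-column ties broken
#' alphabetically, stop entries after amino acids). Idempotent: the entries
#' of a `chrono_order` are already stored in flattened order.
#'
#' @param order a `chrono_order`.
#' @return data.frame of entries in rank order.
#' @export
chrono_flatten <- function(order) {
  stopifnot(inherits(order, "chrono_order"))
  order$entries[order(order$entries$rank), ]
}

#' Group membership lists of a chronological order
#'
#' @param order a `chrono_order`.
#' @return named list of entry-id vectors, one per chronological group.
#' @export
chrono_groups <- function(order) {
  stopifnot(inherits(order, "chrono_order"))
  split(order$entries$id, factor(order$entries$group, levels = CHRONO_GROUPS))
}
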