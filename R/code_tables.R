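# Packaged, validated data model of the standard genetic code, the aaRS
# class partition and the prebiotic abundance table. All downstream modules
# consume only the objects built here.

#' The 20 canonical amino acids (3-letter codes)
#'
#' Internal canonical identifier set; 1-letter codes are accepted at I/O
#' boundaries and converted with [aa_to_three()].
#'
#' @format Character vector of length 20.
#' @export
AMINO_ACIDS <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                 "Thr", "Trp", "Tyr", "Val")

.AA_ONE <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Convert amino-acid identifiers to 3-letter codes
#'
#' Accepts 3-letter codes (any case) or 1-letter codes; anything else errors.
#'
#' @param x character vector of amino-acid identifiers.
#' @return character vector of canonical 3-letter codes.
#' @export
aa_to_three <- function(x) {
  x <- as.character(x)
  out <- character(length(x))
  three <- paste0(toupper(substr(x, 1, 1)), tolower(substring(x, 2)))
  is3 <- three %in% AMINO_ACIDS
  out[is3] <- three[is3]
  one <- match(toupper(x), .AA_ONE)
  is1 <- !is3 & nchar(x) == 1 & !is.na(one)
  out[is1] <- names(.AA_ONE)[one[is1]]
  bad <- !(is3 | is1)
  if (any(bad)) {
    stop("unknown amino acid identifier(s): ", paste(x[bad], collapse = ", "))
  }
  out
}

#' Normalize codons to the RNA alphabet
#'
#' Uppercases, maps T to U (DNA input is accepted) and validates that every
#' codon is exactly three bases over A/C/G/U.
#'
#' @param x character vector of codons.
#' @return character vector of normalized codons.
#' @export
normalize_codon <- function(x) {
  x <- chartr("t", "u", chartr("T", "U", toupper(as.character(x))))
  bad <- nchar(x) != 3L | grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(x[bad], collapse = ", "),
         " (must be 3 bases over A/C/G/U; T accepted on input)")
  }
  x
}

#' Stop-codon token used in code tables
#' @export
STOP_LABEL <- "STOP"

.validate_code_table <- function(entries) {
  if (!all(c("codon", "label") %in% names(entries))) {
    stop("code table must have columns 'codon' and 'label'")
  }
  entries$codon <- normalize_codon(entries$codon)
  if (nrow(entries) != 64L) {
    stop("code table must have exactly 64 entries, got ", nrow(entries))
  }
  if (anyDuplicated(entries$codon)) {
    stop("duplicated codon(s): ",
         paste(unique(entries$codon[duplicated(entries$codon)]), collapse = ", "))
  }
  is_stop <- entries$label == STOP_LABEL
  entries$label[!is_stop] <- aa_to_three(entries$label[!is_stop])
  aas <- sort(unique(entries$label[!is_stop]))
  if (!identical(aas, sort(AMINO_ACIDS))) {
    stop("code table labels must cover exactly the 20 canonical amino acids")
  }
  stops <- sort(entries$codon[is_stop])
  if (!identical(stops, sort(c("UAA", "UAG", "UGA")))) {
    stop("stop codons must be exactly UAA, UAG, UGA; got ",
         paste(stops, collapse = ", "))
  }
  entries
}

#' Load the standard genetic code
#'
#' Reads the packaged 64-codon universal code (or a user table in the same
#' two-column TSV layout), normalizes DNA input to RNA and validates it:
#' 64 entries, the 20 canonical amino acids, stop set \{UAA, UAG, UGA\},
#' and codon families partitioning the 61 sense codons.
#'
#' @param path TSV file with columns `codon` and `label` (3- or 1-letter
#'   amino-acid code, or `STOP`). Defaults to the packaged fixture.
#' @return A `codon_table` object: list with `entries` (data.frame of codon,
#'   label), `stops` (character), and `families` (named list of codon sets
#'   per amino acid).
#' @examples
#' code <- load_standard_code()
#' code$entries$label[code$entries$codon == "UGG"]  # "Trp"
#' codon_family(code, "Arg")
#' @export
load_standard_code <- function(path = system.file("extdata", "genetic_code.tsv",
                                                  package = "codonchron")) {
  entries <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = "character")
  entries <- .validate_code_table(entries)
  sense <- entries[entries$label != STOP_LABEL, ]
  families <- split(sense$codon, sense$label)
  structure(
    list(entries = entries[, c("codon", "label")],
         stops = sort(entries$codon[entries$label == STOP_LABEL]),
         families = families),
    class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat("Standard genetic code: 64 codons, ",
      length(x$families), " amino acids, stops {",
      paste(x$stops, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Codon family of an amino acid
#'
#' @param table a `codon_table`.
#' @param aa amino-acid identifier (3- or 1-letter).
#' @return character vector of codons encoding `aa`.
#' @export
codon_family <- function(table, aa) {
  stopifnot(inherits(table, "codon_table"))
  aa <- aa_to_three(aa)
  fam <- table$families[[aa]]
  if (is.null(fam)) stop("amino acid not encoded by table: ", aa)
  fam
}

#' Degeneracy (codon count) of an amino acid
#'
#' Number of codons encoding the amino acid; the sum over the 20 amino acids
#' is 61 (the sense codons).
#'
#' @inheritParams codon_family
#' @return integer codon count.
#' @examples
#' degeneracy(load_standard_code(), "Trp")  # 1
#' @export
degeneracy <- function(table, aa) {
  length(codon_family(table, aa))
}

#' Write a code table to TSV
#'
#' Round-trip companion of [load_standard_code()]: re-reading the written
#' file reproduces an identical table.
#'
#' @param table a `codon_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_code_table <- function(table, path) {
  stopifnot(inherits(table, "codon_table"))
  utils::write.table(table$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load the aaRS class map
#'
#' Class I synthetases charge the 2'-OH of the terminal adenosine, class II
#' the 3'-OH. Eleven amino acids are class I (Met, Val, Ile, Leu, Cys, Glu,
#' Gln, Lys, Arg, Trp, Tyr), ten class II (Ala, His, Pro, Thr, Ser, Gly,
#' Phe, Asp, Asn, Lys); Lys alone is charged by both classes. The
#' noncanonical SepRS route for Cys is kept as an annotation only and never
#' enters the class counts.
#'
#' @param path TSV with columns `aa`, `classes` (comma-separated subset of
#'   I,II) and `noncanonical`. Defaults to the packaged fixture.
#' @return An `aars_class_map`: list with `class_of` (named list of class
#'   vectors) and `noncanonical` (named character annotations).
#' @examples
#' cls <- load_aars_classes()
#' cls$class_of[["Lys"]]  # c("I", "II")
#' @export
load_aars_classes <- function(path = system.file("extdata", "aars_classes.tsv",
                                                 package = "codonchron")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  tab$aa <- aa_to_three(tab$aa)
  if (anyDuplicated(tab$aa) || !setequal(tab$aa, AMINO_ACIDS)) {
    stop("aaRS class map must have exactly one row per canonical amino acid")
  }
  class_of <- lapply(strsplit(tab$classes, ","), function(cl) {
    cl <- trimws(cl)
    if (!length(cl) || !all(cl %in% c("I", "II"))) {
      stop("aaRS classes must be a non-empty subset of {I, II}")
    }
    sort(unique(cl))
  })
  names(class_of) <- tab$aa
  n1 <- sum(vapply(class_of, function(cl) "I" %in% cl, logical(1)))
  n2 <- sum(vapply(class_of, function(cl) "II" %in% cl, logical(1)))
  dual <- names(class_of)[vapply(class_of, length, integer(1)) == 2L]
  if (n1 != 11L || n2 != 10L || !identical(dual, "Lys")) {
    stop("aaRS class map does not match the published partition ",
         "(11 class I, 10 class II, Lys dual); got I=", n1, " II=", n2,
         " dual={", paste(dual, collapse = ","), "}")
  }
  noncanonical <- ifelse(tab$noncanonical %in% c("", "-"), NA_character_,
                         tab$noncanonical)
  names(noncanonical) <- tab$aa
  structure(list(class_of = class_of, noncanonical = noncanonical),
            class = "aars_class_map")
}

#' @export
print.aars_class_map <- function(x, ...) {
  n1 <- sum(vapply(x$class_of, function(cl) "I" %in% cl, logical(1)))
  n2 <- sum(vapply(x$class_of, function(cl) "II" %in% cl, logical(1)))
  cat("aaRS class map:", n1, "class I,", n2, "class II,",
      sum(vapply(x$class_of, length, integer(1)) == 2L), "dual\n")
  invisible(x)
}

#' Load the prebiotic amino-acid abundance table
#'
#' Relative abundances (ranges, glycine = 1) from prebiotic simulation
#' experiments: panel (a) atmospheric/hydrothermal simulations, panel (b)
#' interstellar-medium simulations and meteorite analyses. Ranges are stored
#' as printed; amino acids absent from a panel are carried with an explicit
#' not-reported marker (`reported = FALSE`, NA bounds), never an imputed
#' number. Point summaries (e.g. midpoints) are computed on demand with
#' [abundance_summary()].
#'
#' @param path TSV with columns `aa`, `panel` (a/b), `lo`, `hi`. Defaults to
#'   the packaged fixture.
#' @return An `abundance_table`: data.frame with columns `aa`, `panel`,
#'   `lo`, `hi`, `reported` covering all 20 amino acids in both panels.
#' @examples
#' ab <- load_abundance()
#' subset(ab, aa == "Ala" & panel == "a")
#' @export
load_abundance <- function(path = system.file("extdata", "abundance_table1.tsv",
                                              package = "codonchron")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$aa <- aa_to_three(tab$aa)
  stopifnot(all(tab$panel %in% c("a", "b")))
  if (any(tab$lo <= 0 | tab$hi < tab$lo)) {
    bad <- tab[tab$lo <= 0 | tab$hi < tab$lo, ]
    stop("malformed abundance range for: ",
         paste(bad$aa, bad$panel, collapse = "; "))
  }
  for (p in c("a", "b")) {
    g <- tab[tab$aa == "Gly" & tab$panel == p, ]
    if (nrow(g) != 1L || g$lo != 1 || g$hi != 1) {
      stop("panel (", p, ") must anchor Gly at 1.0")
    }
  }
  full <- expand.grid(aa = AMINO_ACIDS, panel = c("a", "b"),
                      stringsAsFactors = FALSE)
  out <- merge(full, tab, by = c("aa", "panel"), all.x = TRUE, sort = FALSE)
  out$reported <- !is.na(out$lo)
  out <- out[order(out$panel, match(out$aa, AMINO_ACIDS)), ]
  rownames(out) <- NULL
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Point summary of abundance ranges
#'
#' Derived on demand; the stored table keeps ranges only.
#'
#' @param abund an `abundance_table` from [load_abundance()].
#' @param panel `"a"` or `"b"`.
#' @param summary one of `"midpoint"`, `"lo"`, `"hi"`.
#' @return named numeric vector over the amino acids reported in the panel.
#' @export
abundance_summary <- function(abund, panel = c("a", "b"),
                              summary = c("midpoint", "lo", "hi")) {
  panel <- match.arg(panel)
  summary <- match.arg(summary)
  rows <- abund[abund$panel == panel & abund$reported, ]
  val <- switch(summary,
                midpoint = (rows$lo + rows$hi) / 2,
                lo = rows$lo,
                hi = rows$hi)
  stats::setNames(val, rows$aa)
}
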