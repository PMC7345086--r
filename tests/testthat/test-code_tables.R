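test_that("standard code loads validated with the expected families", {
  code <- load_standard_code()
  expect_equal(nrow(code$entries), 64L)
  expect_equal(code$entries$label[code$entries$codon == "UGG"], "Trp")
  expect_setequal(code$stops, c("UAA", "UAG", "UGA"))
  expect_setequal(codon_family(code, "Arg"),
                  c("CGU", "CGC", "CGA", "CGG", "AGA", "AGG"))
  expect_equal(degeneracy(code, "Trp"), 1L)
  expect_equal(degeneracy(code, "Met"), 1L)
  expect_equal(degeneracy(code, "Leu"), 6L)
  degs <- vapply(AMINO_ACIDS, degeneracy, integer(1), table = code)
  expect_equal(sum(degs), 61L)
  # families partition the sense codons
  expect_equal(anyDuplicated(unlist(code$families)), 0L)
  expect_error(degeneracy(code, "Xyz"), "unknown amino acid")
})

test_that("codon normalization maps DNA input to RNA and rejects junk", {
  expect_equal(normalize_codon(c("gct", "ATG")), c("GCU", "AUG"))
  expect_error(normalize_codon("GC"), "invalid codon")
  expect_error(normalize_codon("GXX"), "invalid codon")
  expect_equal(aa_to_three(c("R", "ala", "Trp")), c("Arg", "Ala", "Trp"))
})

test_that("corrupt code fixtures fail validation", {
  code <- load_standard_code()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_code_table(code, tmp)
  tab <- read.delim(tmp, colClasses = "character")
  write.table(tab[-1, ], tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_standard_code(tmp), "64 entries")
  tab2 <- tab
  tab2$label[tab2$codon == "GGG"] <- "Foo"
  write.table(tab2, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_standard_code(tmp), "Foo")
  tab3 <- tab
  tab3$label[tab3$codon == "UGA"] <- "Trp"   # loses a stop codon
  write.table(tab3, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_standard_code(tmp))
})

test_that("code table round-trips through TSV identically", {
  code <- load_standard_code()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_code_table(code, tmp)
  again <- load_standard_code(tmp)
  expect_identical(again$entries, code$entries)
  expect_identical(again$families, code$families)
  expect_identical(again$stops, code$stops)
})

test_that("aaRS class map matches the published partition", {
  cls <- load_aars_classes()
  n1 <- names(cls$class_of)[vapply(cls$class_of, function(x) "I" %in% x,
                                   logical(1))]
  n2 <- names(cls$class_of)[vapply(cls$class_of, function(x) "II" %in% x,
                                   logical(1))]
  expect_length(n1, 11L)
  expect_length(n2, 10L)
  expect_setequal(n1, c("Met", "Val", "Ile", "Leu", "Cys", "Glu", "Gln",
                        "Lys", "Arg", "Trp", "Tyr"))
  expect_setequal(n2, c("Ala", "His", "Pro", "Thr", "Ser", "Gly", "Phe",
                        "Asp", "Asn", "Lys"))
  expect_identical(intersect(n1, n2), "Lys")
  expect_equal(cls$class_of[["Lys"]], c("I", "II"))
  expect_equal(cls$class_of[["Arg"]], "I")
  expect_equal(cls$class_of[["Gly"]], "II")
  # SepRS route is annotation only, not a class
  expect_equal(unname(cls$noncanonical["Cys"]), "SepRS")
  expect_equal(cls$class_of[["Cys"]], "I")
})

test_that("class-map fixtures inconsistent with the published lists fail", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- read.delim(system.file("extdata", "aars_classes.tsv",
                                package = "codonchron"))
  tab$classes[tab$aa == "Arg"] <- "II"
  write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_aars_classes(tmp), "published partition")
})

test_that("abundance table stores printed ranges with Gly anchors", {
  ab <- load_abundance()
  ala_a <- ab[ab$aa == "Ala" & ab$panel == "a", ]
  expect_equal(c(ala_a$lo, ala_a$hi), c(0.30, 2.00))
  val_b <- ab[ab$aa == "Val" & ab$panel == "b", ]
  expect_equal(c(val_b$lo, val_b$hi), c(0.10, 0.30))
  for (p in c("a", "b")) {
    g <- ab[ab$aa == "Gly" & ab$panel == p, ]
    expect_equal(c(g$lo, g$hi), c(1, 1))
  }
  expect_equal(sum(ab$reported[ab$panel == "a"]), 16L)
  expect_equal(sum(ab$reported[ab$panel == "b"]), 6L)
  # unreported amino acids carry the explicit marker, never a number
  trp_a <- ab[ab$aa == "Trp" & ab$panel == "a", ]
  expect_false(trp_a$reported)
  expect_true(is.na(trp_a$lo) && is.na(trp_a$hi))
  # each panel covers all 20 amino acids once
  expect_equal(nrow(ab), 40L)
})

test_that("malformed abundance ranges fail validation", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- read.delim(system.file("extdata", "abundance_table1.tsv",
                                package = "codonchron"))
  tab$lo[tab$aa == "Ala" & tab$panel == "a"] <- 3.0  # lo > hi
  write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_abundance(tmp), "malformed abundance range")
})

test_that("abundance summaries are derived on demand", {
  ab <- load_abundance()
  mid <- abundance_summary(ab, "a", "midpoint")
  expect_length(mid, 16L)
  expect_equal(unname(mid["Ala"]), (0.30 + 2.00) / 2)
  expect_equal(unname(abundance_summary(ab, "b", "lo")["Asp"]), 0.20)
})
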