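# Antisense binding-sequence design and cassette assembly.

test_that("the default window yields the 24-nt antisense of the first
           eight codons", {
  cds <- "ATGGCTAAAGGTGAAGAACTGTTCACCGGG"
  b <- design_binding_sequence(cds, 1L)
  expect_equal(nchar(b), 24L)
  expect_equal(as.character(b), "GAACAGTTCTTCACCTTTAGCCAT")
  expect_equal(attr(b, "sense_window"), "ATGGCTAAAGGTGAAGAACTGTTC")
})

test_that("a -4..+48 window with 5' context yields 52 nt (no position
           zero)", {
  w <- target_window(-4, 48)
  expect_equal(w$length, 52L)
  set.seed(5)
  ctx <- paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")
  cds <- paste0(ctx, "ATG",
                paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                      collapse = ""))
  b <- design_binding_sequence(cds, 5L, w)
  expect_equal(nchar(b), 52L)
  expect_equal(as.character(b),
               reverse_complement(substr(cds, 1, 52)))
})

test_that("window and start-codon errors behave as documented", {
  expect_error(target_window(0, 10), "no position 0")
  expect_error(target_window(5, 2), ">=")
  expect_error(design_binding_sequence("ATGAAA", 1L,
                                       target_window(1, 50)),
               "outside")
  expect_error(design_binding_sequence("ATGNNN", 1L), "other than")
  expect_warning(design_binding_sequence("GTGAAACCCGGGTTTAAACCCGGGAAA",
                                         1L),
                 "GTG")
})

test_that("double reverse complement is the identity and GC content is
           preserved", {
  set.seed(99)
  gc <- function(s) {
    v <- strsplit(s, "")[[1]]
    mean(v %in% c("G", "C"))
  }
  for (i in 1:25) {
    n <- sample(10:80, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    rc <- reverse_complement(s)
    expect_equal(reverse_complement(rc), s)
    expect_equal(gc(rc), gc(s))
  }
  ## RNA input is normalised: U treated as T
  expect_equal(reverse_complement("AUGC"), "GCAT")
  ## a reverse-complement palindrome maps to itself
  expect_equal(reverse_complement("GAATTC"), "GAATTC")
})

test_that("assembly concatenates binding-scaffold-terminator with
           additive length", {
  b <- design_binding_sequence("ATGGCTAAAGGTGAAGAACTGTTCACC", 1L)
  for (sc in c("MicC", "DsrA", "MicF")) {
    d <- assemble_srna(b, sc, target_id = "gfp")
    expect_equal(d$full_sequence,
                 paste0(d$binding_sequence, d$scaffold_sequence,
                        d$terminator_sequence))
    expect_equal(nchar(d$full_sequence),
                 nchar(d$binding_sequence) + nchar(d$scaffold_sequence) +
                   nchar(d$terminator_sequence))
    expect_true(startsWith(d$full_sequence, as.character(b)))
  }
})

test_that("custom scaffolds come from user FASTA and empty bindings are
           rejected", {
  td <- withr::local_tempdir()
  p <- file.path(td, "scaffold.fasta")
  writeLines(c(">myscaffold custom hairpin", "ACGTACGTGGCC"), p)
  d <- assemble_srna("ATGCATGCATGC", "custom", scaffold_fasta = p)
  expect_equal(d$scaffold_name, "custom")
  expect_equal(d$scaffold_sequence, "ACGTACGTGGCC")
  expect_error(assemble_srna("", "MicC"), "non-empty")
  expect_error(assemble_srna("ATGC", "custom"), "requires")
  expect_error(assemble_srna("ATGC", "NotAScaffold"), "arg")
})

test_that("FASTA and TSV design reports round-trip the key fields", {
  td <- withr::local_tempdir()
  b <- design_binding_sequence("ATGGCTAAAGGTGAAGAACTGTTCACC", 1L)
  d <- assemble_srna(b, "MicC", target_id = "gltA")
  pf <- file.path(td, "srna.fasta")
  write_srna_fasta(d, pf)
  back <- Biostrings::readDNAStringSet(pf)
  expect_equal(as.character(back[[1]]), d$full_sequence)
  pt <- file.path(td, "srna.tsv")
  write_srna_report_tsv(d, pt)
  rep <- utils::read.delim(pt)
  expect_equal(rep$binding_length, 24L)
  expect_equal(rep$full_length, nchar(d$full_sequence))
})
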