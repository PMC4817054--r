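test_that("read_fasta handles single records, folding, case and empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT"), f)
  x <- read_fasta(f, "dna")
  expect_equal(names(x), "s1")
  expect_equal(as.character(x[["s1"]]), "ACGT")

  writeLines(c(">s1 descriptive text", "AC", "gt"), f)
  x <- read_fasta(f, "dna")
  expect_equal(names(x), "s1")  # id trimmed at whitespace
  expect_equal(as.character(x[["s1"]]), "ACGT")  # folded and uppercased

  file.create(f2 <- withr::local_tempfile(fileext = ".fasta"))
  expect_length(read_fasta(f2, "dna"), 0)
})

test_that("read_fasta refuses duplicate IDs, naming the offender", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">dup", "AAAA", ">dup", "CCCC"), f)
  expect_error(read_fasta(f, "dna"), "dup")
})

test_that("translate_cds follows the standard code and stop conventions", {
  expect_equal(translate_cds("ATGAAATAA")[c("protein", "internal_stop")],
               list(protein = "MK", internal_stop = FALSE))
  tr <- translate_cds("ATGTAAAAA")
  expect_equal(tr$protein, "M*K")
  expect_true(tr$internal_stop)
  expect_false(tr$has_terminal_stop)
  expect_equal(translate_cds("ATG")$protein, "M")
  expect_warning(tr <- translate_cds("ATGAAAT"), "multiple of 3")
  expect_equal(tr$protein, "MK")
  # N-containing codons give X and never call a stop
  tr <- translate_cds("ATGTANAAA")
  expect_equal(tr$protein, "MXK")
  expect_false(tr$internal_stop)
  expect_error(translate_cds("AT"), "shorter")
})

test_that("read_gff3 converts coordinates and splices minus-strand genes", {
  scaff <- Biostrings::DNAStringSet(c(toy = "ATGAAA", toy2 = "ATGCCCAAA"))
  f <- withr::local_tempfile(fileext = ".gff3")

  write_toy_gff3(f, "toy", "g1", cbind(1, 6))
  m <- read_gff3(f, scaff)[["g1"]]
  expect_equal(unname(m$exons[, "start"]), 0)   # 0-based half-open
  expect_equal(unname(m$exons[, "end"]), 6)
  expect_equal(m$cds, "ATGAAA")
  expect_true(m$intronless)

  # two-exon minus-strand gene: cds = revcomp("ATG" + "AAA")
  write_toy_gff3(f, "toy2", "g2", cbind(c(1, 7), c(3, 9)), strand = "-")
  m <- read_gff3(f, scaff)[["g2"]]
  expect_equal(m$cds, "TTTCAT")
  expect_equal(m$exon_count, 2)
  expect_false(m$intronless)
  expect_equal(nchar(m$cds), sum(m$exons[, "end"] - m$exons[, "start"]))
})

test_that("read_gff3 rejects malformed gene structures", {
  scaff <- Biostrings::DNAStringSet(c(toy = "ATGAAA"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff3(f, "toy", "g1", cbind(1, 12))
  expect_error(read_gff3(f, scaff), "bounds")
  write_toy_gff3(f, "toy", "g1", cbind(c(1, 2), c(4, 6)))
  expect_error(read_gff3(f, scaff), "[Oo]verlapping")
  write_toy_gff3(f, "missing", "g1", cbind(1, 6))
  expect_error(read_gff3(f, scaff), "scaffold")
})

test_that("CDS phase is honored and a missing phase warns", {
  scaff <- Biostrings::DNAStringSet(c(toy = "CCATGAAATAAG"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff3(f, "toy", "g1", cbind(1, 12), feature = "CDS", phase = "2")
  m <- suppressWarnings(read_gff3(f, scaff))[["g1"]]
  expect_equal(m$protein, "MK")
  write_toy_gff3(f, "toy", "g1", cbind(3, 11), feature = "CDS", phase = ".")
  expect_warning(read_gff3(f, scaff), "phase")
})

test_that("gene-model invariants hold on generated repertoires", {
  spec <- default_repertoire_spec()
  spec$counts <- c(co2 = 1, sugar = 1, gr43a_like = 1,
                   type1 = 3, type2 = 2, type3 = 5)
  spec$pseudogenes <- 1; spec$partials <- 1
  spec$arrays <- list()
  gen <- generate_repertoire_genome(spec, seed = 31)
  d <- withr::local_tempdir()
  write_repertoire_genome(gen, d)
  models <- suppressWarnings(
    read_gff3(file.path(d, "genes.gff3"),
              read_fasta(file.path(d, "genome.fasta"), "dna")))
  for (m in models) {
    expect_equal(nchar(m$cds),
                 sum(m$exons[, "end"] - m$exons[, "start"]))
    expect_equal(nchar(m$protein) + m$has_terminal_stop,
                 floor(nchar(m$cds) / 3))
    expect_equal(m$intronless, m$exon_count == 1)
  }
  # minus-strand property: stored protein equals translation of the
  # plus-strand reverse complement
  minus <- Filter(function(m) m$strand == "-", models)
  expect_gt(length(minus), 0)
  scaffs <- read_fasta(file.path(d, "genome.fasta"), "dna")
  for (m in minus) {
    pieces <- substring(as.character(scaffs[[m$scaffold_id]]),
                        m$exons[, "start"] + 1, m$exons[, "end"])
    plus_cds <- paste(pieces, collapse = "")
    tr <- suppressWarnings(
      translate_cds(grannot:::revcomp(plus_cds)))
    expect_equal(tr$protein, m$protein)
  }
})

test_that("repertoire tables round-trip bit-exactly, including header-only", {
  per_gene <- data.frame(
    gene_id = c("g1", "g2"), scaffold = c("s1", "s1"),
    start = c(10L, 500L), end = c(100L, 900L), strand = c("+", "-"),
    subfamily = c("bitter", "sugar"), bitter_type = c("type3", "not_bitter"),
    length_aa = c(250L, 420L), exon_count = c(1L, 4L),
    pseudogene = c(FALSE, FALSE), partial = c("none", "none"),
    stringsAsFactors = FALSE)
  summary <- summarize_repertoire(per_gene)
  d <- withr::local_tempdir()
  write_repertoire_tables(per_gene, summary, d)
  back <- read_repertoire_tables(d)
  expect_identical(back$per_gene, per_gene)
  expect_identical(back$summary, summary)

  empty <- per_gene[0, ]
  write_repertoire_tables(empty, summarize_repertoire(empty), d)
  back <- read_repertoire_tables(d)
  expect_identical(back$per_gene, empty)
  expect_equal(back$summary$n_genes, 0L)
})
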