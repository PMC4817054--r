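test_that("six-frame translation covers both strands at all offsets", {
  fr <- six_frame_translate("ATGAAA", "s1")
  peps <- setNames(vapply(fr, `[[`, character(1), "peptide"),
                   vapply(fr, `[[`, numeric(1), "frame"))
  expect_equal(peps[["1"]], "MK")
  expect_equal(peps[["-1"]], "FH")  # revcomp TTTCAT
  fr2 <- six_frame_translate("AATGAAA", "s2")
  expect_equal(fr2[[2]]$peptide, "MK")  # frame +2
  fr3 <- six_frame_translate("AC", "s3")
  expect_true(all(vapply(fr3, `[[`, character(1), "peptide") == ""))
  # peptide lengths follow the offset arithmetic
  L <- 100; s <- rand_dna(L)
  for (f in six_frame_translate(s, "s4"))
    expect_equal(nchar(f$peptide), floor((L - f$offset) / 3))
})

test_that("an identical window scores the BLOSUM62 diagonal sum exactly", {
  withr::local_seed(7)
  win <- rand_protein(10)
  scaff_pep <- paste0(rand_protein(20), win, rand_protein(20))
  cds <- grannot:::back_translate(scaff_pep)
  frames <- six_frame_translate(cds, "s1")
  hsps <- search_translated("q", win, frames, min_score = 30)
  expect_gt(nrow(hsps), 0)
  diag_sum <- sum(blosum62[cbind(strsplit(win, "")[[1]],
                                 strsplit(win, "")[[1]])])
  top <- hsps[1, ]
  expect_equal(top$score, diag_sum)
  expect_equal(top$identities, 10)
  expect_equal(top$s_start, 21)
  # genomic span maps back onto the implanted codons (frame +1)
  expect_equal(top$g_start, 3 * 20 + 1)
  expect_equal(top$g_end, 3 * 30)
})

test_that("a homopolymer query finds no seed against a mismatched frame", {
  # max BLOSUM62 score of an A-vs-W triple is 3 * (-3) < 11
  expect_lt(3 * blosum62["A", "W"], 11)
  frames <- six_frame_translate(grannot:::back_translate(
    strrep("W", 30)), "s1")
  hsps <- search_translated("q", strrep("A", 10), frames, min_score = 1)
  expect_equal(nrow(hsps), 0)
})

test_that("one substitution drops the score by diagonal minus substitution", {
  withr::local_seed(11)
  win <- rand_protein(20)
  frames <- six_frame_translate(grannot:::back_translate(win), "s1")
  base <- search_translated("q", win, frames, min_score = 30)[1, ]
  mut <- strsplit(win, "")[[1]]
  old <- mut[10]
  new <- if (old == "W") "A" else "W"
  mut[10] <- new
  hit <- search_translated("q", paste(mut, collapse = ""), frames,
                           min_score = 30)[1, ]
  expect_equal(base$score - hit$score,
               blosum62[old, old] - blosum62[new, old])
})

test_that("queries outside the amino-acid alphabet are rejected", {
  frames <- six_frame_translate("ATGAAAATGAAA", "s1")
  expect_error(search_translated("q", "MK1MK", frames), "alphabet")
})

test_that("reported HSPs cover the exhaustive ungapped oracle", {
  withr::local_seed(23)
  for (rep in 1:3) {
    # random scaffold with two implanted, diverged copies of the query
    query <- rand_protein(50)
    mutate <- function(p, k) {
      a <- strsplit(p, "")[[1]]
      idx <- sample(length(a), k)
      for (i in idx) a[i] <- sample(setdiff(AA20, a[i]), 1)
      paste(a, collapse = "")
    }
    scaff <- paste0(rand_dna(400),
                    grannot:::back_translate(mutate(query, 5)),
                    rand_dna(300),
                    grannot:::back_translate(mutate(query, 10)),
                    rand_dna(400))
    frames <- six_frame_translate(scaff, "s")
    hsps <- search_translated("q", query, frames, min_score = 50)
    oracle <- exhaustive_best_hsps(query, frames, min_score = 50)
    expect_gt(nrow(oracle), 1)
    for (k in seq_len(nrow(oracle))) {
      o <- oracle[k, ]
      fr <- Filter(function(f) f$frame == o$frame, frames)[[1]]
      if (!segment_has_seed(query, fr$peptide, o$q_start, o$q_end,
                            o$s_start)) next
      match_rows <- hsps$frame == o$frame &
        hsps$q_start <= o$q_end & hsps$q_end >= o$q_start &
        hsps$s_start - hsps$q_start == o$s_start - o$q_start
      expect_true(any(match_rows & hsps$score >= o$score),
                  label = paste("oracle segment covered, frame", o$frame))
    }
    # every reported score re-sums exactly from the matrix
    S <- grannot:::search_score_matrix()
    qidx <- grannot:::encode_protein(query)
    for (k in seq_len(nrow(hsps))) {
      h <- hsps[k, ]
      fr <- Filter(function(f) f$frame == h$frame, frames)[[1]]
      sidx <- match(strsplit(fr$peptide, "")[[1]], grannot:::aa_alphabet())
      expect_equal(h$score,
                   sum(S[cbind(qidx[h$q_start:h$q_end],
                               sidx[h$s_start:h$s_end])]))
    }
  }
})

test_that("searching the reverse complement mirrors strand and coordinates", {
  withr::local_seed(5)
  query <- rand_protein(40)
  scaff <- paste0(rand_dna(200), grannot:::back_translate(query),
                  rand_dna(150))
  fwd <- search_translated("q", query,
                           six_frame_translate(scaff, "s"))
  rev <- search_translated("q", query,
                           six_frame_translate(grannot:::revcomp(scaff), "s"))
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(fwd$score), sort(rev$score))
  expect_setequal(paste(fwd$strand, fwd$g_start, fwd$g_end),
                  paste(ifelse(rev$strand == "+", "-", "+"),
                        nchar(scaff) - rev$g_end + 1,
                        nchar(scaff) - rev$g_start + 1))
})

test_that("raising min_score never adds HSPs", {
  withr::local_seed(13)
  query <- rand_protein(40)
  scaff <- paste0(rand_dna(300), grannot:::back_translate(query),
                  rand_dna(300))
  frames <- six_frame_translate(scaff, "s")
  lo <- search_translated("q", query, frames, min_score = 40)
  hi <- search_translated("q", query, frames, min_score = 80)
  key <- function(h) paste(h$frame, h$q_start, h$q_end, h$s_start)
  expect_true(all(key(hi) %in% key(lo)))
  expect_true(all(hi$score >= 80))
})

test_that("HSPs merge into loci by strand and genomic gap", {
  hsp <- function(scaf, strand, g1, g2, q = "q", score = 100)
    data.frame(query_id = q, scaffold_id = scaf, frame = 1L,
               strand = strand, q_start = 1L, q_end = 10L,
               s_start = 1L, s_end = 10L, g_start = g1, g_end = g2,
               score = score, identities = 10L, length = 10L)
  close_pair <- rbind(hsp("s", "+", 1000, 1100),
                      hsp("s", "+", 1600, 1700))  # 500-base gap
  expect_equal(nrow(merge_hsps_to_loci(close_pair, max_gap = 2000)), 1)
  far_pair <- rbind(hsp("s", "+", 1000, 1100),
                    hsp("s", "+", 6100, 6200))    # 5000-base gap
  expect_equal(nrow(merge_hsps_to_loci(far_pair, max_gap = 2000)), 2)
  opposite <- rbind(hsp("s", "+", 1000, 1100),
                    hsp("s", "-", 1000, 1100))
  expect_equal(nrow(merge_hsps_to_loci(opposite, max_gap = 2000)), 2)
  expect_equal(nrow(merge_hsps_to_loci(close_pair[0, ])), 0)
  # locus covers all supporting HSPs; best query carried through
  loc <- merge_hsps_to_loci(close_pair, max_gap = 2000)
  expect_equal(c(loc$g_start, loc$g_end), c(1000, 1700))
  expect_equal(loc$n_hsps, 2)
})

test_that("raising max_gap never increases the locus count", {
  withr::local_seed(17)
  starts <- sort(sample(1:50000, 12))
  hsps <- data.frame(query_id = "q", scaffold_id = "s", frame = 1L,
                     strand = "+", q_start = 1L, q_end = 10L,
                     s_start = 1L, s_end = 10L,
                     g_start = starts, g_end = starts + 200L,
                     score = 100L, identities = 10L, length = 10L)
  counts <- vapply(c(500, 2000, 5000, 20000, 60000),
                   function(g) nrow(merge_hsps_to_loci(hsps, g)), integer(1))
  expect_true(all(diff(counts) <= 0))
})
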