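# tblastn-like translated homology screen: six-frame translation of genome
# scaffolds, BLOSUM62 word seeding, ungapped two-sided X-drop extension, and
# merging of HSPs into candidate gene loci. Ungapped only: candidates are
# refined downstream against curated gene models, so full BLAST statistics
# (gapped DP, E-values) are deliberately out of scope.

# Alphabet used for scoring: the 20 standard residues, X (ambiguity,
# score 0 vs everything) and '*' (frame stop, never aligned through).
aa_alphabet <- function() c("A","R","N","D","C","Q","E","G","H","I","L","K",
                            "M","F","P","S","T","W","Y","V","X","*")

# BLOSUM62 restricted to the working alphabet, with the X and '*'
# conventions above applied.
search_score_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  ab <- aa_alphabet()
  S <- e$BLOSUM62[ab, ab]
  S["X", ] <- 0L; S[, "X"] <- 0L
  S["*", ] <- -1000L; S[, "*"] <- -1000L
  S
}

# Map a protein string to indices into aa_alphabet(); ambiguity codes
# U/O/B/Z/J collapse to X; anything else is a hard error.
encode_protein <- function(seq, id = "query") {
  ch <- strsplit(toupper(seq), "")[[1]]
  ch[ch %in% c("U", "O", "B", "Z", "J")] <- "X"
  idx <- match(ch, aa_alphabet())
  if (anyNA(idx))
    stop("sequence ", id, " contains characters outside the amino-acid ",
         "alphabet: ", paste(unique(ch[is.na(idx)]), collapse = ", "))
  idx
}

#' Six-frame translation of a scaffold
#'
#' Frames +1..+3 translate the forward strand at offsets 0..2; -1..-3
#' translate the reverse complement at offsets 0..2. Stops are retained as
#' `*`; codons containing N translate to `X`.
#'
#' @param sequence Scaffold DNA string.
#' @param scaffold_id Scaffold label carried into the frames.
#' @return List of six frames, each a list with `scaffold_id`, `frame`
#'   (+1,+2,+3,-1,-2,-3), `offset`, `peptide` and `scaffold_length`.
#' @export
six_frame_translate <- function(sequence, scaffold_id = "scaffold") {
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  rc <- if (L) revcomp(sequence) else ""
  frames <- vector("list", 6)
  k <- 1
  for (sgn in c(1L, -1L)) {
    src <- if (sgn > 0) sequence else rc
    for (off in 0:2) {
      pep <- if (L - off >= 3)
        paste(translate_codons(substr(src, off + 1, L)), collapse = "") else ""
      frames[[k]] <- list(scaffold_id = scaffold_id, frame = sgn * (off + 1L),
                          offset = off, peptide = pep, scaffold_length = L)
      k <- k + 1
    }
  }
  frames
}

# Genomic (1-based inclusive) span of peptide positions [p1, p2] in a frame.
frame_genomic_span <- function(frame, p1, p2) {
  o <- frame$offset; L <- frame$scaffold_length
  if (frame$frame > 0) {
    c(o + 3 * (p1 - 1) + 1, o + 3 * p2)
  } else {
    c(L - o - 3 * p2 + 1, L - o - 3 * (p1 - 1))
  }
}

# Ungapped two-sided X-drop extension of a seed word at query position i,
# subject position p (word length w). Never extends across '*' in the
# subject. Returns the HSP span and its exactly re-summable score.
extend_seed <- function(qidx, sidx, i, p, w, S, x_drop) {
  star <- match("*", aa_alphabet())
  m <- length(qidx); n <- length(sidx)
  word_score <- sum(S[cbind(qidx[i:(i + w - 1)], sidx[p:(p + w - 1)])])
  ext_one <- function(qv, sv) {
    # best cumulative extension under X-drop; sv truncated at the first '*'
    if (!length(qv)) return(c(0L, 0))
    stop_at <- which(sv == star)
    if (length(stop_at)) {
      keep <- stop_at[1] - 1
      if (keep == 0) return(c(0L, 0))
      qv <- qv[seq_len(keep)]; sv <- sv[seq_len(keep)]
    }
    sc <- S[cbind(qv, sv)]
    cs <- cumsum(sc)
    cm <- cummax(c(0, cs[-length(cs)]))
    dropped <- which(pmax(cm, 0) - cs > x_drop)
    lim <- if (length(dropped)) dropped[1] - 1 else length(cs)
    if (lim == 0) return(c(0L, 0))
    best <- which.max(cs[seq_len(lim)])
    if (cs[best] <= 0) c(0L, 0) else c(best, cs[best])
  }
  kmax_r <- min(m - (i + w - 1), n - (p + w - 1))
  right <- if (kmax_r > 0)
    ext_one(qidx[(i + w):(i + w - 1 + kmax_r)],
            sidx[(p + w):(p + w - 1 + kmax_r)]) else c(0L, 0)
  kmax_l <- min(i - 1, p - 1)
  left <- if (kmax_l > 0)
    ext_one(qidx[(i - 1):(i - kmax_l)], sidx[(p - 1):(p - kmax_l)]) else c(0L, 0)
  q1 <- i - left[1]; q2 <- i + w - 1 + right[1]
  list(q_start = q1, q_end = q2, s_start = p - left[1],
       s_end = p + w - 1 + right[1],
       score = word_score + left[2] + right[2],
       identities = sum(qidx[q1:q2] == sidx[(p - left[1]):(p + w - 1 + right[1])]))
}

empty_hsp_table <- function() {
  data.frame(query_id = character(0), scaffold_id = character(0),
             frame = integer(0), strand = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             g_start = integer(0), g_end = integer(0),
             score = integer(0), identities = integer(0), length = integer(0),
             stringsAsFactors = FALSE)
}

#' Search a protein query against six translated frames
#'
#' Word seeding on BLOSUM62 (a seed is a query/subject word pair scoring at
#' least `seed_threshold`), ungapped two-sided extension with X-drop, HSPs
#' kept when their score reaches `min_score`. Deterministic for fixed input
#' and parameters; every reported score equals the sum of matrix entries
#' over the aligned pairs.
#'
#' @param query_id,query Protein query label and sequence.
#' @param frames Output of [six_frame_translate()] (one or more scaffolds
#'   concatenated into one list is fine).
#' @param word_size Seed word length.
#' @param seed_threshold Minimum BLOSUM62 word-pair score to seed.
#' @param x_drop Extension abandoned when the running score falls this far
#'   below the running maximum.
#' @param min_score Minimum HSP score to report.
#' @return data.frame of HSPs sorted by score (desc): peptide spans
#'   (`q_start`..`s_end`, 1-based) and genomic span (`g_start` <= `g_end`,
#'   1-based inclusive) with `strand`.
#' @export
search_translated <- function(query_id, query, frames, word_size = 3,
                              seed_threshold = 11, x_drop = 20,
                              min_score = 50) {
  stopifnot(word_size >= 1, x_drop > 0, min_score > 0)
  if (!nchar(query)) stop("empty query ", query_id)
  S <- search_score_matrix()
  star <- match("*", aa_alphabet())
  qidx <- encode_protein(query, query_id)
  m <- length(qidx)
  w <- word_size
  out <- list()
  for (fr in frames) {
    n <- nchar(fr$peptide)
    if (n < w || m < w) next
    sidx <- match(strsplit(fr$peptide, "")[[1]], aa_alphabet())
    # subject word validity: no '*' inside the word
    nw <- n - w + 1
    sub_cols <- lapply(seq_len(w), function(k) sidx[k:(k + nw - 1)])
    bad <- Reduce(`|`, lapply(sub_cols, function(v) v == star))
    seeds_i <- integer(0); seeds_p <- integer(0)
    for (i in seq_len(m - w + 1)) {
      sc <- 0
      for (k in seq_len(w)) sc <- sc + S[qidx[i + k - 1], ][sub_cols[[k]]]
      sc[bad] <- -Inf
      hit <- which(sc >= seed_threshold)
      if (length(hit)) {
        seeds_i <- c(seeds_i, rep.int(i, length(hit)))
        seeds_p <- c(seeds_p, hit)
      }
    }
    if (!length(seeds_i)) next
    dg <- seeds_p - seeds_i
    o <- order(dg, seeds_i)
    seeds_i <- seeds_i[o]; seeds_p <- seeds_p[o]; dg <- dg[o]
    hsps <- list(); covered_end <- -Inf; covered_diag <- NA
    for (s in seq_along(seeds_i)) {
      if (identical(covered_diag, dg[s]) && seeds_i[s] <= covered_end) next
      h <- extend_seed(qidx, sidx, seeds_i[s], seeds_p[s], w, S, x_drop)
      covered_diag <- dg[s]; covered_end <- h$q_end
      if (h$score >= min_score) hsps[[length(hsps) + 1]] <- h
    }
    if (!length(hsps)) next
    df <- do.call(rbind, lapply(hsps, as.data.frame))
    df <- unique(df)
    gs <- t(mapply(function(a, b) frame_genomic_span(fr, a, b),
                   df$s_start, df$s_end))
    df$g_start <- as.integer(gs[, 1]); df$g_end <- as.integer(gs[, 2])
    df$query_id <- query_id
    df$scaffold_id <- fr$scaffold_id
    df$frame <- fr$frame
    df$strand <- if (fr$frame > 0) "+" else "-"
    df$length <- df$q_end - df$q_start + 1L
    out[[length(out) + 1]] <- df
  }
  if (!length(out)) return(empty_hsp_table())
  res <- do.call(rbind, out)
  res <- res[order(-res$score, res$scaffold_id, res$frame, res$s_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, names(empty_hsp_table())]
}

#' Search several queries against an assembly
#' @param queries Named character vector or AAStringSet of protein queries.
#' @param scaffolds DNAStringSet of scaffolds.
#' @param ... Passed to [search_translated()].
#' @export
search_assembly <- function(queries, scaffolds, ...) {
  qnm <- names(queries)
  queries <- as.character(queries)
  if (is.null(names(queries))) names(queries) <- qnm
  frames <- unlist(lapply(names(scaffolds), function(id)
    six_frame_translate(as.character(scaffolds[[id]]), id)), recursive = FALSE)
  res <- lapply(names(queries), function(q)
    search_translated(q, queries[[q]], frames, ...))
  out <- do.call(rbind, res)
  if (is.null(out)) empty_hsp_table() else out
}

#' Merge HSPs into candidate gene loci
#'
#' HSPs on the same scaffold and strand whose genomic gaps are at most
#' `max_gap` bases merge into one locus (the gap accommodates introns);
#' loci are maximal and disjoint per strand.
#'
#' @param hsps HSP data.frame from [search_translated()].
#' @param max_gap Maximum genomic gap (bases) between consecutive HSPs.
#' @return data.frame of loci: scaffold, strand, genomic span, number of
#'   supporting HSPs, best-scoring query and scores.
#' @export
merge_hsps_to_loci <- function(hsps, max_gap = 10000) {
  stopifnot(max_gap > 0)
  empty <- data.frame(scaffold_id = character(0), strand = character(0),
                      g_start = integer(0), g_end = integer(0),
                      n_hsps = integer(0), best_query = character(0),
                      best_score = integer(0), total_score = integer(0),
                      stringsAsFactors = FALSE)
  if (!NROW(hsps)) return(empty)
  out <- list()
  for (key in unique(paste(hsps$scaffold_id, hsps$strand))) {
    sub <- hsps[paste(hsps$scaffold_id, hsps$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$g_start, sub$g_end), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      sub$g_start[-1] - cummax(sub$g_end)[-nrow(sub)] - 1L > max_gap)))
    for (g in unique(grp)) {
      blk <- sub[grp == g, , drop = FALSE]
      best <- blk[order(-blk$score, blk$query_id), , drop = FALSE][1, ]
      out[[length(out) + 1]] <- data.frame(
        scaffold_id = blk$scaffold_id[1], strand = blk$strand[1],
        g_start = min(blk$g_start), g_end = max(blk$g_end),
        n_hsps = nrow(blk), best_query = best$query_id,
        best_score = best$score, total_score = sum(blk$score),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold_id, res$strand, res$g_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
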