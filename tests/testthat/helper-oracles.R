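# Independent oracles and fixture builders used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Write a minimal GFF3 (gene/mRNA + segment features) for toy fixtures.
write_toy_gff3 <- function(path, scaffold, gene_id, exons, strand = "+",
                           feature = "exon", phase = ".") {
  tx <- paste0(gene_id, ".t1")
  span <- c(min(exons[, 1]), max(exons[, 2]))
  lines <- c("##gff-version 3",
    paste(scaffold, "toy", "gene", span[1], span[2], ".", strand, ".",
          paste0("ID=", gene_id), sep = "\t"),
    paste(scaffold, "toy", "mRNA", span[1], span[2], ".", strand, ".",
          paste0("ID=", tx, ";Parent=", gene_id), sep = "\t"))
  for (i in seq_len(nrow(exons))) {
    lines <- c(lines, paste(scaffold, "toy", feature, exons[i, 1],
                            exons[i, 2], ".", strand,
                            if (feature == "CDS") phase else ".",
                            paste0("ID=", tx, ".", feature, i, ";Parent=", tx),
                            sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# Best star-free ungapped segment per (frame, diagonal) with score >=
# min_score: the exhaustive oracle for the seed-and-extend search.
exhaustive_best_hsps <- function(query, frames, min_score = 50) {
  S <- grannot:::search_score_matrix()
  ab <- grannot:::aa_alphabet()
  star <- match("*", ab)
  qidx <- grannot:::encode_protein(query)
  m <- length(qidx)
  out <- list()
  for (fr in frames) {
    n <- nchar(fr$peptide)
    if (n == 0) next
    sidx <- match(strsplit(fr$peptide, "")[[1]], ab)
    for (d in (1 - m):(n - 1)) {
      i0 <- max(1, 1 - d); i1 <- min(m, n - d)
      if (i1 < i0) next
      qs <- i0:i1
      ss <- qs + d
      # split at subject stops
      chunks <- split(seq_along(qs), cumsum(sidx[ss] == star))
      for (ch in chunks) {
        ch <- ch[sidx[ss[ch]] != star]
        if (!length(ch)) next
        sc <- S[cbind(qidx[qs[ch]], sidx[ss[ch]])]
        # best-sum contiguous segment (Kadane with traceback)
        best <- -Inf; best_ij <- c(1, 1); cur <- 0; cur_start <- 1
        for (k in seq_along(sc)) {
          if (cur <= 0) { cur <- 0; cur_start <- k }
          cur <- cur + sc[k]
          if (cur > best) { best <- cur; best_ij <- c(cur_start, k) }
        }
        if (best >= min_score) {
          out[[length(out) + 1]] <- data.frame(
            frame = fr$frame, scaffold_id = fr$scaffold_id,
            q_start = qs[ch[best_ij[1]]], q_end = qs[ch[best_ij[2]]],
            s_start = ss[ch[best_ij[1]]], s_end = ss[ch[best_ij[2]]],
            score = best)
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# does the oracle segment contain at least one seed word pair scoring >=
# threshold?
segment_has_seed <- function(query, peptide, q_start, q_end, s_start,
                             word_size = 3, seed_threshold = 11) {
  S <- grannot:::search_score_matrix()
  ab <- grannot:::aa_alphabet()
  qidx <- grannot:::encode_protein(query)
  sidx <- match(strsplit(peptide, "")[[1]], ab)
  len <- q_end - q_start + 1
  if (len < word_size) return(FALSE)
  for (o in 0:(len - word_size)) {
    qi <- q_start + o; si <- s_start + o
    sc <- sum(S[cbind(qidx[qi:(qi + word_size - 1)],
                      sidx[si:(si + word_size - 1)])])
    if (sc >= seed_threshold) return(TRUE)
  }
  FALSE
}

# Random additive distance matrix: random unrooted topology with positive
# branch lengths; distances are path sums computed by ape (independent of
# the NJ implementation under test).
random_additive_matrix <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.5, 3)))
  tr$tip.label <- sort(tr$tip.label)
  D <- ape::cophenetic.phylo(tr)
  D[sort(rownames(D)), sort(rownames(D))]
}

# All 15 unrooted binary topologies on 5 taxa, as pairs of disjoint cherry
# pairs; least-squares fit of the 7 edge lengths gives an exact (residual
# zero) fit only for the generating topology.
brute_force_nj_check <- function(D) {
  taxa <- rownames(D)
  stopifnot(length(taxa) == 5)
  pairs <- utils::combn(5, 2, simplify = FALSE)
  fits <- list()
  for (p1 in pairs) {
    for (p2 in pairs) {
      if (length(intersect(p1, p2)) > 0 || p1[1] > p2[1]) next
      e <- setdiff(1:5, c(p1, p2))
      # edges: l1..l5 leaf edges, l6 = cherry1-center, l7 = cherry2-center
      rows <- list(); y <- c()
      for (ij in utils::combn(5, 2, simplify = FALSE)) {
        x <- numeric(7); x[ij[1]] <- 1; x[ij[2]] <- 1
        in1 <- ij %in% p1; in2 <- ij %in% p2
        if (xor(in1[1], in1[2])) x[6] <- x[6] + 0  # handled below
        # path crosses internal edge 6 iff exactly one endpoint in cherry1
        if (sum(ij %in% p1) == 1) x[6] <- 1
        if (sum(ij %in% p2) == 1) x[7] <- 1
        rows[[length(rows) + 1]] <- x
        y <- c(y, D[ij[1], ij[2]])
      }
      X <- do.call(rbind, rows)
      beta <- qr.solve(crossprod(X), crossprod(X, y))
      resid <- max(abs(X %*% beta - y))
      fits[[length(fits) + 1]] <- list(cherries = list(taxa[p1], taxa[p2]),
                                       resid = resid, lengths = beta)
    }
  }
  fits
}

# the unrooted 2|3 splits (as sorted 2-subsets of tip labels) of a 5-taxon
# binary tree
cherry_splits <- function(tree) {
  n <- ape::Ntip(tree)
  splits <- list()
  M <- grannot:::node_tip_matrix(tree)
  for (node in (n + 1):(n + tree$Nnode)) {
    tips_in <- tree$tip.label[M[node, ]]
    side <- if (length(tips_in) > n / 2) setdiff(tree$tip.label, tips_in)
    else tips_in
    if (length(side) == 2) splits[[length(splits) + 1]] <- sort(side)
  }
  unique(splits)
}
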