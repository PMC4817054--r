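# Reference-anchored subfamily assignment: protein distances (p-distance or
# Poisson-corrected, with pairwise deletion of gap columns), canonical
# neighbor joining with deterministic tie-breaking, column-bootstrap support,
# and clade-walk assignment of each gene to the subfamily of its nearest
# anchored clade. Distance-based NJ replaces a likelihood tree search on
# purpose: clade membership, not branch-length fidelity, drives the
# classification, and NJ admits an exact additive-matrix oracle.

#' Globally align two proteins
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps) via
#' Biostrings.
#'
#' @param a,b Protein strings.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Character vector of the two aligned strings (with `-`).
#' @export
align_pair <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

# Distance between two aligned residue vectors under pairwise deletion:
# columns with a gap (or ambiguity X) in either sequence are excluded.
aligned_distance <- function(ca, cb, model = c("poisson", "p_distance"),
                             max_distance = 10, ids = c("a", "b")) {
  model <- match.arg(model)
  keep <- ca != "-" & cb != "-" & ca != "X" & cb != "X"
  n <- sum(keep)
  if (n == 0)
    stop("no comparable columns between ", ids[1], " and ", ids[2])
  p <- sum(ca[keep] != cb[keep]) / n
  if (model == "p_distance") return(p)
  if (p >= 1 - 1e-12) max_distance else min(-log(1 - p), max_distance)
}

#' Pairwise protein distance
#'
#' Aligns the two sequences globally, excludes columns with a gap in either
#' sequence (pairwise deletion), then computes the proportion of differing
#' sites (`p_distance`) or its Poisson correction `-ln(1 - p)`, capped at
#' `max_distance` as p approaches saturation.
#'
#' @param a,b Protein strings (unaligned; aligned internally).
#' @param model `"poisson"` (default) or `"p_distance"`.
#' @param max_distance Cap applied to the Poisson distance.
#' @param ids Labels used in error messages.
#' @export
pairwise_distance <- function(a, b, model = c("poisson", "p_distance"),
                              max_distance = 10, ids = c("a", "b")) {
  al <- align_pair(a, b)
  aligned_distance(strsplit(al[1], "")[[1]], strsplit(al[2], "")[[1]],
                   model = model, max_distance = max_distance, ids = ids)
}

#' Multiple alignment via MAFFT
#'
#' Runs the MAFFT command-line aligner (single thread, fixed input order,
#' hence deterministic) and returns the alignment as a character matrix
#' (taxa x columns).
#'
#' @param seqs Named character vector or AAStringSet.
#' @return Character matrix with rownames = sequence IDs.
#' @export
align_msa <- function(seqs) {
  if (Sys.which("mafft") == "")
    stop("the 'mafft' executable is required for multiple alignment")
  nm <- names(seqs)
  seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- nm
  if (is.null(names(seqs)) || anyNA(names(seqs)))
    stop("sequences must be named")
  x <- Biostrings::AAStringSet(unname(seqs))
  names(x) <- names(seqs)
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  Biostrings::writeXStringSet(x, fin)
  status <- system2("mafft", c("--auto", "--anysymbol", "--thread", "1",
                               "--quiet", fin), stdout = fout)
  if (status != 0) stop("mafft failed with status ", status)
  aln <- Biostrings::readBStringSet(fout)
  m <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
  rownames(m) <- sub("\\s.*$", "", names(aln))
  m[names(x), , drop = FALSE]
}

#' Distance matrix from a multiple alignment
#'
#' All pairwise distances under pairwise deletion (see
#' [pairwise_distance()] for the models). A pair of fragments occupying
#' disjoint alignment regions (no comparable columns, possible for e.g. a
#' pseudogene's stop-free segment vs a partial model) is set to the
#' distance cap with a warning rather than failing the whole matrix.
#'
#' @param msa Character matrix from [align_msa()].
#' @inheritParams pairwise_distance
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
msa_distances <- function(msa, model = c("poisson", "p_distance"),
                          max_distance = 10) {
  model <- match.arg(model)
  n <- nrow(msa)
  ids <- rownames(msa)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  disjoint <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- tryCatch(
        aligned_distance(msa[i, ], msa[j, ], model = model,
                         max_distance = max_distance, ids = ids[c(i, j)]),
        error = function(e) {
          disjoint <<- c(disjoint, paste(ids[i], ids[j], sep = "/"))
          if (model == "p_distance") 1 else max_distance
        })
    }
  }
  if (length(disjoint))
    warning("no comparable columns (distance capped) for: ",
            paste(disjoint, collapse = ", "))
  D
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining with the Studier-Keppler Q
#' criterion. Ties in Q are broken deterministically by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest member taxon). Negative branch lengths are clamped to
#' zero with the deficit moved to the sister edge, preserving the pair
#' distance.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An [ape] `phylo` object (unrooted, stored with a basal
#'   trifurcation).
#' @export
build_nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(dm)
  if (is.null(labels)) stop("distance matrix must have taxon dimnames")
  n <- nrow(dm)
  D <- dm
  node_id <- seq_len(n)          # current node ids (tips 1..n)
  rep_lab <- labels              # representative label per cluster
  next_id <- n + 1L
  edges <- NULL                  # parent, child, length
  while (length(node_id) > 3) {
    k <- length(node_id)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12 & upper.tri(Q), arr.ind = TRUE)
    key <- apply(cand, 1, function(ij) {
      lab <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    vi <- dij / 2 + (r[i] - r[j]) / (2 * (k - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    u <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges,
                   c(u, node_id[i], vi),
                   c(u, node_id[j], vj))
    du <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    node_id <- c(node_id[keep], u)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
  }
  # final three clusters join at the basal trifurcation; closed-form lengths
  a <- 1; b <- 2; c3 <- 3
  va <- max((D[a, b] + D[a, c3] - D[b, c3]) / 2, 0)
  vb <- max((D[a, b] + D[b, c3] - D[a, c3]) / 2, 0)
  vc <- max((D[a, c3] + D[b, c3] - D[a, b]) / 2, 0)
  root <- next_id
  edges <- rbind(edges,
                 c(root, node_id[a], va),
                 c(root, node_id[b], vb),
                 c(root, node_id[c3], vc))
  # renumber internal nodes to ape convention (root = n + 1)
  internal <- c(root, setdiff(sort(unique(edges[, 1]), decreasing = TRUE),
                              root))
  map <- integer(max(internal))
  map[internal] <- n + seq_along(internal)
  e <- edges
  e[, 1] <- map[e[, 1]]
  e[, 2] <- ifelse(e[, 2] > n, map[e[, 2]], e[, 2])
  tr <- structure(list(edge = matrix(as.integer(e[, 1:2]), ncol = 2),
                       edge.length = as.numeric(e[, 3]),
                       tip.label = labels,
                       Nnode = length(internal)), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate and scores each internal edge of the original tree by the
#' percentage of replicates containing the same bipartition.
#'
#' @param msa Character matrix (taxa x columns) from [align_msa()].
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; results are reproducible given the seed.
#' @inheritParams msa_distances
#' @return List with `tree` (the original NJ tree, node labels set to the
#'   support values), `support` (numeric, one per internal node, root NA)
#'   and `degenerate` (TRUE when the alignment has a single column).
#' @export
bootstrap_support <- function(msa, replicates = 100, seed = 1,
                              model = c("poisson", "p_distance"),
                              max_distance = 10) {
  stopifnot(replicates >= 1)
  model <- match.arg(model)
  degenerate <- ncol(msa) == 1
  if (degenerate)
    warning("single-column alignment: bootstrap supports are degenerate")
  tree <- build_nj_tree(msa_distances(msa, model, max_distance))
  trees <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      cols <- sample.int(ncol(msa), replace = TRUE)
      build_nj_tree(msa_distances(msa[, cols, drop = FALSE],
                                  model, max_distance))
    })
  })
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / replicates
  support[1] <- NA  # basal trifurcation carries no split
  tree$node.label <- ifelse(is.na(support), "", format(support, trim = TRUE))
  list(tree = tree, support = support, degenerate = degenerate)
}

# Logical matrix (nodes x tips): tip membership of the subtree under each
# node in the stored rooting of `tree`.
node_tip_matrix <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- tree$Nnode
  M <- matrix(FALSE, n + nn, n)
  M[cbind(seq_len(n), seq_len(n))] <- TRUE
  desc <- phangorn::Descendants(tree, (n + 1):(n + nn), "tips")
  for (k in seq_len(nn)) M[n + k, desc[[k]]] <- TRUE
  M
}

#' Assign genes to subfamilies by anchored-clade walk
#'
#' The tree is given a deterministic rooted view (midpoint rooting, which
#' on anchor-separated repertoires places the root on the long branch
#' between subfamilies). Each non-anchor leaf then walks its parent chain
#' toward the root; the first enclosing clade holding at least one anchor
#' assigns its subfamily by majority over the anchors it contains, with
#' exact ties broken by lexicographic subfamily order and flagged as
#' ambiguous.
#'
#' @param tree A `phylo` tree containing genes and anchors as tips.
#' @param anchors Named character vector: names are anchor tip labels,
#'   values their subfamilies.
#' @param gene_ids Tips to assign; defaults to all non-anchor tips.
#' @return data.frame with `gene_id`, `subfamily`, `anchor_support`
#'   (comma-separated anchors of the deciding clade) and `ambiguous`.
#' @export
assign_subfamilies <- function(tree, anchors, gene_ids = NULL) {
  tips <- tree$tip.label
  anchors <- anchors[names(anchors) %in% tips]
  if (!length(anchors)) stop("tree contains no anchor tips")
  if (is.null(gene_ids)) gene_ids <- setdiff(tips, names(anchors))
  missing <- setdiff(gene_ids, tips)
  if (length(missing))
    stop("gene(s) not in tree: ", paste(missing, collapse = ", "))
  tr <- if (!is.null(tree$edge.length)) phangorn::midpoint(tree) else tree
  tips <- tr$tip.label
  n <- ape::Ntip(tr)
  M <- node_tip_matrix(tr)
  is_anchor <- tips %in% names(anchors)
  n_anchors <- as.integer(M[, is_anchor, drop = FALSE] %*%
                            rep(1L, sum(is_anchor)))
  parent <- integer(n + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  root <- n + 1L
  res <- lapply(gene_ids, function(g) {
    node <- parent[match(g, tips)]
    while (n_anchors[node] == 0 && node != root) node <- parent[node]
    if (n_anchors[node] == 0) stop("no anchored clade found for gene ", g)
    sup <- tips[M[node, ] & is_anchor]
    fams <- table(unname(anchors[sup]))
    top <- names(fams)[fams == max(fams)]
    data.frame(gene_id = g, subfamily = sort(top)[1],
               anchor_support = paste(sort(sup), collapse = ","),
               ambiguous = length(top) > 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @rdname assign_subfamilies
#' @param gene_id A single gene tip label.
#' @export
assign_subfamily <- function(tree, anchors, gene_id) {
  row <- assign_subfamilies(tree, anchors, gene_id)
  list(gene_id = row$gene_id, subfamily = row$subfamily,
       anchor_support = strsplit(row$anchor_support, ",")[[1]],
       ambiguous = row$ambiguous)
}

#' Tree-ready proteins for classification
#'
#' Complete proteins enter the tree as-is; pseudogene proteins (internal
#' stop) are represented by their longest stop-free segment.
#'
#' @param models Gene-model list from [read_gff3()].
#' @param min_segment Minimum stop-free segment length to keep a pseudogene.
#' @return Named character vector of tree-ready protein sequences.
#' @export
tree_proteins <- function(models, min_segment = 30) {
  seqs <- vapply(models, function(m) {
    p <- m$protein
    if (m$internal_stop) {
      seg <- strsplit(p, "*", fixed = TRUE)[[1]]
      p <- seg[order(-nchar(seg))[1]]
    }
    p
  }, character(1))
  seqs[nchar(seqs) >= min_segment]
}
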