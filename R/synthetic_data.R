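# Ground-truthed synthetic inputs for every pipeline stage: genome scaffolds
# carrying implanted GR genes of known subfamily, bitter type, pseudogene /
# partial status and tandem-array structure; read-count matrices with known
# presence truth; and membrane proteins with known TM segments. All outputs
# are pure functions of (spec, seed). Ancestor proteins are seeded random
# sequences, not real GR sequences, which keeps the repository data-free;
# real anchors can always be supplied instead.

amino_acids <- function() setdiff(aa_alphabet(), c("X", "*"))

random_protein <- function(n) {
  paste(sample(amino_acids(), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# point-substitute a fraction of residues (never to the same residue)
mutate_protein <- function(protein, divergence) {
  aa <- strsplit(protein, "")[[1]]
  hit <- which(stats::runif(length(aa)) < divergence)
  for (i in hit) {
    aa[i] <- sample(setdiff(amino_acids(), aa[i]), 1)
  }
  paste(aa, collapse = "")
}

# uniform synonymous back-translation (codon bias out of scope)
back_translate <- function(protein) {
  tab <- split(names(Biostrings::GENETIC_CODE),
               unname(Biostrings::GENETIC_CODE))
  aa <- strsplit(protein, "")[[1]]
  codons <- character(length(aa))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    codons[idx] <- sample(tab[[a]], length(idx), replace = TRUE)
  }
  paste(codons, collapse = "")
}

#' Default synthetic-repertoire specification
#'
#' The default composition is the characterised repertoire this package
#' emulates: 197 genes (3 CO2, 8 sugar, 2 GR43a-like, 184 bitter of which
#' 31 Type 1, 13 Type 2, 129 Type 3, 4 pseudogenes and 7 partial models),
#' one 38-gene Type 3 tandem array, one 9-gene Type 2 array and one
#' scaffold interleaving 5 Type 1 with 9 Type 3 genes. Length bands keep a
#' 10-residue guard margin away from the classification thresholds so type
#' truth is unambiguous.
#'
#' @export
default_repertoire_spec <- function() {
  list(
    counts = c(co2 = 3, sugar = 8, gr43a_like = 2,
               type1 = 31, type2 = 13, type3 = 129),
    pseudogenes = 4,
    partials = 7,
    divergence = 0.10,
    anchor_divergence = 0.02,
    arrays = list(
      list(name = "arr_type3", type = "type3", size = 38,
           gap_range = c(2500, 4000)),
      list(name = "arr_type2", type = "type2", size = 9,
           gap_range = c(2500, 4000)),
      list(name = "arr_mixed", interleave = c(type1 = 5, type3 = 9),
           gap_range = c(2500, 4000))),
    intergenic_mean = 3000,
    genes_per_scaffold = 10,
    flank = 1500,
    len_bands = list(type1 = c(370, 430), type2 = c(411, 470),
                     type3 = c(210, 345), nonbitter = c(390, 450),
                     pseudo = c(250, 330), partial = c(250, 345)),
    exon_bands = list(type1 = c(3, 4), nonbitter = c(3, 6)),
    intron_len = c(60, 400),
    ancestor_len = 520)
}

validate_repertoire_spec <- function(spec) {
  if (any(spec$counts < 0)) stop("spec counts must be >= 0")
  for (nm in names(spec$len_bands)) {
    b <- spec$len_bands[[nm]]
    if (b[1] > b[2]) stop("empty length band for ", nm)
  }
  if (spec$len_bands$type3[1] < 200 || spec$len_bands$type3[2] >= 360)
    stop("type3 length band must lie inside [200, 360)")
  if (spec$len_bands$type2[1] <= 400)
    stop("type2 length band must lie above 400")
  need <- c(type1 = unname(spec$counts["type1"]),
            type2 = unname(spec$counts["type2"]),
            type3 = unname(spec$counts["type3"]))
  for (ar in spec$arrays) {
    if (!is.null(ar$type)) {
      need[ar$type] <- need[ar$type] - ar$size
    } else {
      for (t in names(ar$interleave))
        need[t] <- need[t] - ar$interleave[[t]]
    }
  }
  if (any(need < 0)) stop("array specs request more genes than the counts provide")
  invisible(spec)
}

# Build one gene: protein from a mutated ancestor window, back-translated
# CDS, exon/intron structure, returned with block-relative exon coordinates.
build_gene <- function(id, category, subfamily, ancestor, spec,
                       pseudogene = FALSE, partial = "none") {
  band <- spec$len_bands[[switch(category,
    co2 = , sugar = , gr43a_like = "nonbitter",
    pseudo = "pseudo", partial = "partial", category)]]
  L <- sample(band[1]:band[2], 1)
  a_len <- nchar(ancestor)
  # genes share the ancestor's C-terminal region (the family's conserved
  # core); length variation trims the N-terminus, so any two family members
  # overlap over at least the shortest gene
  w0 <- a_len - L + 1
  prot <- mutate_protein(substr(ancestor, w0, w0 + L - 1), spec$divergence)
  aa <- strsplit(prot, "")[[1]]
  aa[1] <- if (partial %in% c("missing_n", "missing_both")) "L" else "M"
  prot <- paste(aa, collapse = "")
  cds <- back_translate(prot)
  if (pseudogene) {
    mid <- (floor(L / 2)) * 3 + 1
    substr(cds, mid, mid + 2) <- "TAA"
  }
  if (!partial %in% c("missing_c", "missing_both")) cds <- paste0(cds, "TAA")
  n_ex <- switch(category,
    type1 = sample(spec$exon_bands$type1[1]:spec$exon_bands$type1[2], 1),
    co2 = , sugar = , gr43a_like =
      sample(spec$exon_bands$nonbitter[1]:spec$exon_bands$nonbitter[2], 1),
    1L)
  nc <- nchar(cds)
  if (n_ex > 1) {
    base <- floor(nc / n_ex)
    cuts <- cumsum(rep(base, n_ex - 1)) + sample(-15:15, n_ex - 1, replace = TRUE)
    cuts <- pmin(pmax(cuts, seq_len(n_ex - 1) * 50), nc - 50)
    ex_len <- diff(c(0, sort(cuts), nc))
  } else {
    ex_len <- nc
  }
  introns <- if (n_ex > 1)
    vapply(seq_len(n_ex - 1), function(i) paste0(
      "GT", random_dna(sample(spec$intron_len[1]:spec$intron_len[2], 1) - 4),
      "AG"), character(1)) else character(0)
  # assemble plus-strand block and record exon coords within it
  pos <- 1L
  block <- character(0)
  ex_start <- integer(n_ex); ex_end <- integer(n_ex)
  cds_pos <- cumsum(c(0, ex_len))
  for (i in seq_len(n_ex)) {
    piece <- substr(cds, cds_pos[i] + 1, cds_pos[i + 1])
    ex_start[i] <- pos; ex_end[i] <- pos + nchar(piece) - 1L
    block <- c(block, piece)
    pos <- pos + nchar(piece)
    if (i < n_ex) {
      block <- c(block, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  block <- paste(block, collapse = "")
  strand <- sample(c("+", "-"), 1)
  if (strand == "-") {
    B <- nchar(block)
    block <- revcomp(block)
    new_start <- B - ex_end + 1L
    new_end <- B - ex_start + 1L
    o <- order(new_start)
    ex_start <- new_start[o]; ex_end <- new_end[o]
  }
  list(gene_id = id, category = category, subfamily = subfamily,
       bitter_type = if (category %in% c("type1", "type2", "type3"))
         category else if (subfamily == "bitter") "unknown" else "not_bitter",
       protein = prot, cds = cds, block = block, strand = strand,
       ex_start = ex_start, ex_end = ex_end, exon_count = n_ex,
       length_aa = L, pseudogene = pseudogene, partial = partial)
}

#' Generate a ground-truthed repertoire genome
#'
#' Builds scaffolds carrying implanted GR genes (each a mutated window of a
#' seeded subfamily ancestor, back-translated with uniform codon usage and
#' given the exon/intron structure its type prescribes), tandem arrays with
#' controlled gaps, pseudogenes (one internal stop), partial models, and
#' low-divergence anchor proteins per subfamily.
#'
#' @param spec Specification list, see [default_repertoire_spec()].
#' @param seed Integer seed; identical (spec, seed) reproduce every output
#'   byte-exactly.
#' @return List: `scaffolds` (DNAStringSet), `genes` (GRanges ready for GFF3
#'   export), `anchors` (AAStringSet), `anchor_table` (anchor_id,
#'   subfamily), `manifest` (per-gene truth data.frame), `proteins`
#'   (AAStringSet of the implanted proteins), `spec`, `seed`.
#' @export
generate_repertoire_genome <- function(spec = default_repertoire_spec(),
                                       seed = 1) {
  validate_repertoire_spec(spec)
  withr::with_seed(seed, {
    subfams <- c("co2", "sugar", "gr43a_like", "bitter")
    ancestors <- setNames(
      vapply(subfams, function(x) random_protein(spec$ancestor_len),
             character(1)), subfams)
    # gene plan, ids in category blocks
    plan <- data.frame(category = character(0), subfamily = character(0),
                       pseudogene = logical(0), partial = character(0),
                       stringsAsFactors = FALSE)
    add <- function(plan, category, n, subfamily, pseudo = FALSE,
                    partial = "none") {
      if (n <= 0) return(plan)
      rbind(plan, data.frame(category = category, subfamily = subfamily,
                             pseudogene = pseudo,
                             partial = partial, stringsAsFactors = FALSE)[
                               rep(1, n), , drop = FALSE])
    }
    plan <- add(plan, "co2", spec$counts["co2"], "co2")
    plan <- add(plan, "sugar", spec$counts["sugar"], "sugar")
    plan <- add(plan, "gr43a_like", spec$counts["gr43a_like"], "gr43a_like")
    plan <- add(plan, "type1", spec$counts["type1"], "bitter")
    plan <- add(plan, "type2", spec$counts["type2"], "bitter")
    plan <- add(plan, "type3", spec$counts["type3"], "bitter")
    plan <- add(plan, "pseudo", spec$pseudogenes, "bitter", pseudo = TRUE)
    if (spec$partials > 0) {
      kinds <- rep(c("missing_n", "missing_c"), length.out = spec$partials)
      for (kd in kinds) plan <- add(plan, "partial", 1, "bitter",
                                    partial = kd)
    }
    n_gene <- nrow(plan)
    plan$gene_id <- sprintf("SynGR%03d", seq_len(n_gene))
    genes <- lapply(seq_len(n_gene), function(i)
      build_gene(plan$gene_id[i], plan$category[i], plan$subfamily[i],
                 ancestors[[plan$subfamily[i]]], spec,
                 pseudogene = plan$pseudogene[i], partial = plan$partial[i]))
    names(genes) <- plan$gene_id
    # scaffold layout: arrays first, remainder in shuffled chunks
    pool <- split(plan$gene_id, plan$category)
    take <- function(cat, n) {
      ids <- pool[[cat]][seq_len(n)]
      pool[[cat]] <<- pool[[cat]][-seq_len(n)]
      ids
    }
    layouts <- list()
    for (ar in spec$arrays) {
      ids <- if (!is.null(ar$type)) take(ar$type, ar$size)
      else {  # interleave categories gene-by-gene
        picks <- lapply(names(ar$interleave), function(t)
          take(t, ar$interleave[[t]]))
        ord <- order(unlist(lapply(seq_along(picks), function(k)
          seq_along(picks[[k]]) + (k - 1) / length(picks))))
        unlist(picks)[ord]
      }
      layouts[[length(layouts) + 1]] <- list(ids = ids, array = ar$name,
                                             gap_range = ar$gap_range)
    }
    rest <- sample(unlist(pool, use.names = FALSE))
    while (length(rest)) {
      n_take <- min(spec$genes_per_scaffold, length(rest))
      layouts[[length(layouts) + 1]] <- list(ids = rest[seq_len(n_take)],
                                             array = "", gap_range = NULL)
      rest <- rest[-seq_len(n_take)]
    }
    # assemble scaffolds and genomic coordinates
    scaffold_seqs <- character(length(layouts))
    names(scaffold_seqs) <- sprintf("scaffold%03d", seq_along(layouts))
    rows <- list()
    for (s in seq_along(layouts)) {
      lay <- layouts[[s]]
      seq_parts <- random_dna(spec$flank)
      offset <- spec$flank
      for (gi in seq_along(lay$ids)) {
        g <- genes[[lay$ids[gi]]]
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = g$gene_id, scaffold = names(scaffold_seqs)[s],
          start = offset + min(g$ex_start), end = offset + max(g$ex_end),
          strand = g$strand, subfamily = g$subfamily,
          bitter_type = g$bitter_type, exon_count = g$exon_count,
          length_aa = g$length_aa, pseudogene = g$pseudogene,
          partial = g$partial, array_id = lay$array,
          g_offset = offset, stringsAsFactors = FALSE)
        seq_parts <- c(seq_parts, g$block)
        offset <- offset + nchar(g$block)
        gap <- if (!is.null(lay$gap_range))
          sample(lay$gap_range[1]:lay$gap_range[2], 1)
        else 200 + round(stats::rexp(1, 1 / spec$intergenic_mean))
        if (gi < length(lay$ids)) {
          seq_parts <- c(seq_parts, random_dna(gap))
          offset <- offset + gap
        }
      }
      seq_parts <- c(seq_parts, random_dna(spec$flank))
      scaffold_seqs[s] <- paste(seq_parts, collapse = "")
    }
    manifest <- do.call(rbind, rows)
    gr <- repertoire_granges(genes, manifest)
    manifest$g_offset <- NULL
    anchors <- make_anchors(ancestors, spec)
    proteins <- Biostrings::AAStringSet(
      vapply(genes, `[[`, character(1), "protein"))
    list(scaffolds = Biostrings::DNAStringSet(scaffold_seqs),
         genes = gr, anchors = anchors$seqs,
         anchor_table = anchors$table, manifest = manifest,
         proteins = proteins, spec = spec, seed = seed)
  })
}

# GRanges with gene/mRNA/exon/CDS rows ready for rtracklayer GFF3 export
repertoire_granges <- function(genes, manifest) {
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    g <- genes[[manifest$gene_id[i]]]
    off <- manifest$g_offset[i]
    st <- off + g$ex_start
    en <- off + g$ex_end
    id <- g$gene_id
    tx <- paste0(id, ".t1")
    # CDS phase in transcription order
    o_tx <- if (g$strand == "+") order(st) else order(-st)
    lens <- (en - st + 1)[o_tx]
    phase <- (3 - (cumsum(c(0, lens[-length(lens)])) %% 3)) %% 3
    phase_genomic <- integer(length(st))
    phase_genomic[o_tx] <- phase
    n_ex <- length(st)
    rows[[length(rows) + 1]] <- data.frame(
      seqnames = manifest$scaffold[i],
      start = c(min(st), min(st), st, st),
      end = c(max(en), max(en), en, en),
      strand = g$strand,
      type = c("gene", "mRNA", rep("exon", n_ex), rep("CDS", n_ex)),
      ID = c(id, tx, paste0(tx, ".exon", seq_len(n_ex)),
             paste0(tx, ".cds", seq_len(n_ex))),
      Parent = c(NA, id, rep(tx, 2 * n_ex)),
      phase = c(NA, NA, rep(NA, n_ex), phase_genomic),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr)$phase <- as.integer(df$phase)
  gr
}

make_anchors <- function(ancestors, spec) {
  defs <- list(
    c("co2", 3, 440), c("sugar", 4, 450), c("gr43a_like", 3, 430),
    c("bitter", 3, NA))
  bitter_lens <- c(400, 430, 300)  # the three bitter structural archetypes
  seqs <- character(0); fam <- character(0)
  for (d in defs) {
    sf <- d[[1]]; n <- as.integer(d[[2]])
    for (k in seq_len(n)) {
      L <- if (sf == "bitter") bitter_lens[k] else as.integer(d[[3]])
      anc <- ancestors[[sf]]
      w0 <- nchar(anc) - L + 1
      p <- mutate_protein(substr(anc, w0, w0 + L - 1),
                          spec$anchor_divergence)
      seqs <- c(seqs, p)
      fam <- c(fam, sf)
    }
  }
  ids <- paste0("ANC_", fam, "_", stats::ave(fam, fam, FUN = seq_along))
  list(seqs = Biostrings::AAStringSet(setNames(seqs, ids)),
       table = data.frame(anchor_id = ids, subfamily = fam,
                          stringsAsFactors = FALSE))
}

#' Write a generated repertoire to disk
#'
#' Emits `genome.fasta`, `genes.gff3`, `anchors.fasta`, `anchors.tsv`,
#' `manifest.tsv` and `params.yaml` under `dir`.
#'
#' @param gen Output of [generate_repertoire_genome()].
#' @param dir Output directory (created if missing).
#' @export
write_repertoire_genome <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(gen$scaffolds, file.path(dir, "genome.fasta"))
  gff <- file.path(dir, "genes.gff3")
  rtracklayer::export(gen$genes, gff, format = "gff3")
  # drop volatile comment headers so identical seeds give identical bytes
  lines <- readLines(gff)
  writeLines(lines[!grepl("^##(date|source-version)", lines)], gff)
  Biostrings::writeXStringSet(gen$anchors, file.path(dir, "anchors.fasta"))
  write_tsv(gen$anchor_table, file.path(dir, "anchors.tsv"))
  write_tsv(gen$manifest, file.path(dir, "manifest.tsv"))
  yaml::write_yaml(list(seed = gen$seed,
                        counts = as.list(gen$spec$counts),
                        pseudogenes = gen$spec$pseudogenes,
                        partials = gen$spec$partials,
                        divergence = gen$spec$divergence),
                   file.path(dir, "params.yaml"))
  invisible(dir)
}

# ---- expression ----------------------------------------------------------

#' Simulate read counts from abundance truth
#'
#' Counts are Poisson with mean `abundance x gene length (kb) x library
#' size (millions)`, the inverse of the RPKM normalisation, so
#' [relative_abundance()] recovers the truth in expectation.
#'
#' @param abundance Genes x libraries matrix of true abundances (RPKM).
#' @param gene_lengths,library_sizes Named vectors (bases / mapped reads).
#' @param seed Integer seed.
#' @param cutoff Detection cutoff recorded in the truth.
#' @return List with `counts` (integer matrix) and `truth_present`
#'   (logical matrix: abundance at or above the cutoff).
#' @export
simulate_expression_counts <- function(abundance, gene_lengths,
                                       library_sizes, seed = 1, cutoff = 1) {
  lambda <- sweep(sweep(abundance, 1, gene_lengths[rownames(abundance)] / 1e3,
                        "*"),
                  2, library_sizes[colnames(abundance)] / 1e6, "*")
  counts <- withr::with_seed(seed, {
    matrix(stats::rpois(length(lambda), lambda), nrow = nrow(lambda),
           dimnames = dimnames(abundance))
  })
  list(counts = counts, truth_present = abundance >= cutoff & abundance > 0)
}

#' Default expression design: 31 libraries with fixed per-group detection
#'
#' Emulates a transcriptome panel of 31 libraries — four developmental-stage
#' libraries (embryo, 3rd instar, 5th instar, pupa), 14 larval-tissue and
#' 13 adult-tissue libraries — with a detection truth whose per-group
#' detected-gene counts are the profile this package reproduces: 12 genes
#' detected in embryos, 4 in 3rd instar, 12 in 5th instar, 18 in pupae, 20
#' across larval tissues, 73 across adult tissues, 84 distinct genes in
#' total. Needs at least 84 genes.
#'
#' @param gene_ids Character vector of gene IDs (>= 84).
#' @param seed Integer seed (placement of genes within multi-library groups
#'   and abundance draws).
#' @param abundance_range Range of true abundances (RPKM) for expressed
#'   (gene, library) pairs; the default sits well above the 1.0 cutoff.
#' @return List: `abundance`, `library_sizes`, `groups`, `expected` (named
#'   per-group detected counts), `detected_truth` (gene IDs expressed
#'   anywhere).
#' @export
default_expression_design <- function(gene_ids, seed = 1,
                                      abundance_range = c(10, 100)) {
  n <- length(gene_ids)
  if (n < 84) stop("the default expression design needs at least 84 genes")
  libs <- c("stage_embryo", "stage_larva3", "stage_larva5", "stage_pupa",
            sprintf("larval_t%02d", 1:14), sprintf("adult_t%02d", 1:13))
  groups <- list(embryo = "stage_embryo", larva_3rd = "stage_larva3",
                 larva_5th = "stage_larva5", pupa = "stage_pupa",
                 larval_tissues = sprintf("larval_t%02d", 1:14),
                 adult_tissues = sprintf("adult_t%02d", 1:13))
  sets <- list(adult_tissues = 1:73, larval_tissues = 64:83,
               pupa = 66:83, embryo = 72:83, larva_5th = 70:81,
               larva_3rd = 81:84)
  withr::with_seed(seed, {
    ab <- matrix(0, n, length(libs), dimnames = list(gene_ids, libs))
    for (grp in names(sets)) {
      member_libs <- groups[[grp]]
      for (gi in sets[[grp]]) {
        in_libs <- if (length(member_libs) == 1) member_libs
        else sample(member_libs, sample(1:3, 1))
        ab[gi, in_libs] <- stats::runif(length(in_libs),
                                        abundance_range[1],
                                        abundance_range[2])
      }
    }
    library_sizes <- setNames(round(stats::runif(length(libs), 4e6, 8e6)),
                              libs)
    list(abundance = ab, library_sizes = library_sizes, groups = groups,
         expected = c(embryo = 12L, larva_3rd = 4L, larva_5th = 12L,
                      pupa = 18L, larval_tissues = 20L,
                      adult_tissues = 73L),
         detected_truth = gene_ids[1:84])
  })
}

# ---- membrane proteins ---------------------------------------------------

#' Generate a membrane protein with known topology
#'
#' `k` hydrophobic 21-mers (I/V cores) separated by hydrophilic loops.
#' Interior loops are at least 12 residues of D/E/N/Q (uniform KD -3.5), a
#' composition chosen so that, at the topology module defaults, the
#' detected segments are exactly the implanted ones by arithmetic rather
#' than by chance; the six loop residues flanking each helix are likewise
#' D/E/N/Q while the distal part of a terminal loop is K/R-enriched on the
#' intracellular side (positive-inside rule).
#'
#' @param k Number of TM segments (>= 0).
#' @param length Total protein length; defaults to `21k + 12(k-1) + 20`
#'   (80 for `k = 0`). An infeasible length is a hard error.
#' @param seed Integer seed.
#' @param n_inside Truth for the N-terminus side (ignored for `k = 0`).
#' @param id Protein identifier.
#' @return List: `id`, `sequence`, `tmd_count`, `n_terminus`, `c_terminus`,
#'   `segments` (matrix of implanted TM start/end positions).
#' @export
generate_membrane_protein <- function(k, length = NULL, seed = 1,
                                      n_inside = TRUE, id = "memprot") {
  stopifnot(k >= 0)
  tm_len <- 21L; interior <- 12L; term_min <- 5L
  if (is.null(length))
    length <- if (k == 0) 80L else 21L * k + interior * max(k - 1, 0) + 20L
  if (k > 0) {
    need <- tm_len * k + interior * max(k - 1, 0) + 2L * term_min
    if (length < need)
      stop("length ", length, " cannot accommodate ", k,
           " TM segments (need >= ", need, ")")
  }
  withr::with_seed(seed, {
    pad_set <- c("D", "E", "N", "Q")
    if (k == 0) {
      seqc <- sample(c(pad_set, "K", "R", "S", "T", "P"), length,
                     replace = TRUE)
      return(list(id = id, sequence = paste(seqc, collapse = ""),
                  tmd_count = 0L, n_terminus = NA_character_,
                  c_terminus = NA_character_,
                  segments = cbind(start = integer(0), end = integer(0))))
    }
    n_term <- if (n_inside) "inside" else "outside"
    c_term <- if (k %% 2 == 0) n_term
    else if (n_term == "inside") "outside" else "inside"
    rem <- length - tm_len * k - interior * max(k - 1, 0)
    ln <- max(term_min, floor(rem / 2)); lc <- rem - ln
    make_terminal <- function(l, side, n_end) {
      # `n_end`: TRUE when the terminus is at the start of this loop
      pad <- min(6L, l)
      distal <- l - pad
      distal_res <- if (distal > 0) {
        if (side == "inside") sample(c("K", "R"), distal, replace = TRUE)
        else sample(c("D", "E"), distal, replace = TRUE)
      } else character(0)
      pad_res <- sample(pad_set, pad, replace = TRUE)
      if (n_end) c(distal_res, pad_res) else c(pad_res, distal_res)
    }
    parts <- list(make_terminal(ln, n_term, TRUE))
    seg <- matrix(0L, k, 2, dimnames = list(NULL, c("start", "end")))
    pos <- ln
    for (i in seq_len(k)) {
      tm <- sample(c("I", "V"), tm_len, replace = TRUE, prob = c(.75, .25))
      seg[i, ] <- c(pos + 1L, pos + tm_len)
      parts[[length(parts) + 1]] <- tm
      pos <- pos + tm_len
      if (i < k) {
        parts[[length(parts) + 1]] <- sample(pad_set, interior,
                                             replace = TRUE)
        pos <- pos + interior
      }
    }
    parts[[length(parts) + 1]] <- make_terminal(lc, c_term, FALSE)
    list(id = id, sequence = paste(unlist(parts), collapse = ""),
         tmd_count = as.integer(k), n_terminus = n_term,
         c_terminus = c_term, segments = seg)
  })
}
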