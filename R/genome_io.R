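# Sequence and gene-model I/O.
#
# Internal coordinates are 0-based half-open throughout; GFF3 (1-based
# inclusive) is converted at the boundary on read and write.

#' Read a FASTA file
#'
#' Thin wrapper around Biostrings readers that uppercases sequences, trims
#' record IDs at the first whitespace and refuses duplicate IDs.
#'
#' @param path Path to a FASTA file. An empty file yields an empty set.
#' @param type `"dna"` or `"protein"`.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  empty <- if (type == "dna") Biostrings::DNAStringSet() else Biostrings::AAStringSet()
  if (file.size(path) == 0) return(empty)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA record ID: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(raw))
  names(seqs) <- ids
  if (type == "dna") Biostrings::DNAStringSet(seqs) else Biostrings::AAStringSet(seqs)
}

#' Write sequences to FASTA
#' @param x An XStringSet (or named character vector).
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Translate a coding sequence
#'
#' Standard genetic code. Codons containing non-ACGT characters (e.g. N)
#' translate to `X` and never count as stop codons. A trailing stop codon is
#' trimmed from the returned protein; internal stops are retained as `*`.
#'
#' @param cds A DNA string (length >= 3). A length that is not a multiple of
#'   three is flagged with a warning and the trailing bases are ignored.
#' @return A list with `protein`, `internal_stop` (TRUE iff `*` occurs before
#'   the final codon) and `has_terminal_stop` (final codon is a stop).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n < 3) stop("CDS shorter than one codon: ", n, " bases")
  if (n %% 3 != 0) {
    warning("CDS length ", n, " is not a multiple of 3; ignoring ",
            n %% 3, " trailing base(s)")
    n <- n - n %% 3
    cds <- substr(cds, 1, n)
  }
  aa <- translate_codons(cds)
  k <- length(aa)
  has_terminal_stop <- aa[k] == "*"
  internal_stop <- any(aa[-k] == "*")
  protein <- paste(if (has_terminal_stop) aa[-k] else aa, collapse = "")
  list(protein = protein, internal_stop = internal_stop,
       has_terminal_stop = has_terminal_stop)
}

# Raw codon-wise translation, '*' kept, N-containing codons -> 'X'.
# Trailing partial codon silently dropped (callers validate).
translate_codons <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return(character(0))
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon (and optionally CDS) features, resolves Parent
#' attributes and builds validated gene models against the supplied scaffold
#' assembly. GFF3 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention. Minus-strand CDS is reverse-complemented so
#' the stored CDS is in transcription order. CDS phase, when present on the
#' transcription-first segment, trims the 5' overhang; an absent phase is
#' assumed 0 with a warning.
#'
#' @param path GFF3 file.
#' @param scaffolds A [Biostrings::DNAStringSet] of scaffold sequences.
#' @return A list of gene models (class `gr_gene_model`), each with fields
#'   `gene_id`, `scaffold_id`, `strand`, `exons` (0-based half-open matrix),
#'   `exon_count`, `intronless`, `cds`, `protein`, `internal_stop`,
#'   `has_terminal_stop`, `start`, `end` (1-based inclusive gene span).
#' @export
read_gff3 <- function(path, scaffolds) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  mrna_idx <- which(typ %in% c("mRNA", "transcript"))
  models <- vector("list", length(mrna_idx))
  for (k in seq_along(mrna_idx)) {
    i <- mrna_idx[k]
    tx_id <- ids[i]
    gene_id <- if (!is.na(parents[i])) parents[i] else tx_id
    seg_idx <- which(typ == "CDS" & parents == tx_id)
    used_cds <- length(seg_idx) > 0
    if (!used_cds) seg_idx <- which(typ == "exon" & parents == tx_id)
    if (!length(seg_idx))
      stop("mRNA ", tx_id, " has no exon or CDS children")
    scaf <- as.character(GenomicRanges::seqnames(gr)[i])
    if (!scaf %in% names(scaffolds))
      stop("unknown scaffold '", scaf, "' for gene ", gene_id)
    sstrand <- as.character(GenomicRanges::strand(gr)[i])
    if (!sstrand %in% c("+", "-"))
      stop("gene ", gene_id, " lacks a strand")
    st <- GenomicRanges::start(gr)[seg_idx]
    en <- GenomicRanges::end(gr)[seg_idx]
    o <- order(st)
    st <- st[o]; en <- en[o]
    if (any(st < 1) || any(en > nchar(scaffolds[[scaf]])))
      stop("exon outside scaffold bounds for gene ", gene_id)
    if (length(st) > 1 && any(st[-1] <= en[-length(en)]))
      stop("overlapping exons within mRNA ", tx_id)
    phase <- gr$phase[seg_idx][o]
    models[[k]] <- build_gene_model(
      gene_id = gene_id, transcript_id = tx_id, scaffold_id = scaf,
      strand = sstrand, starts = st, ends = en,
      scaffold_seq = as.character(scaffolds[[scaf]]),
      phase = phase, phase_known = used_cds)
  }
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  models
}

# starts/ends are GFF 1-based inclusive, sorted by genomic position.
build_gene_model <- function(gene_id, transcript_id, scaffold_id, strand,
                             starts, ends, scaffold_seq,
                             phase = NULL, phase_known = TRUE) {
  pieces <- substring(scaffold_seq, starts, ends)
  cds <- paste(pieces, collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  # phase of the transcription-first segment trims the 5' overhang
  first_seg <- if (strand == "+") 1L else length(starts)
  ph <- if (!is.null(phase)) phase[first_seg] else NA
  if (is.na(ph)) {
    if (phase_known)
      warning("gene ", gene_id, ": CDS phase missing, assuming 0")
    ph <- 0L
  }
  if (ph > 0) cds <- substr(cds, ph + 1, nchar(cds))
  tr <- suppressWarnings(translate_cds(cds))
  structure(list(
    gene_id = gene_id, transcript_id = transcript_id,
    scaffold_id = scaffold_id, strand = strand,
    exons = cbind(start = starts - 1L, end = ends),  # 0-based half-open
    exon_count = length(starts),
    intronless = length(starts) == 1L,
    cds = cds,
    protein = tr$protein,
    internal_stop = tr$internal_stop,
    has_terminal_stop = tr$has_terminal_stop,
    start = min(starts), end = max(ends)), class = "gr_gene_model")
}

#' Tabulate gene models
#'
#' @param models List of gene models from [read_gff3()].
#' @return A data.frame with one row per gene: coordinates, exon count,
#'   protein length and the structural flags used downstream.
#' @export
gene_model_table <- function(models) {
  if (!length(models)) {
    return(data.frame(gene_id = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), exon_count = integer(0),
                      intronless = logical(0), cds_length = integer(0),
                      length_aa = integer(0), internal_stop = logical(0),
                      has_start_met = logical(0), has_terminal_stop = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(models, function(m) data.frame(
    gene_id = m$gene_id, scaffold = m$scaffold_id,
    start = m$start, end = m$end, strand = m$strand,
    exon_count = m$exon_count, intronless = m$intronless,
    cds_length = nchar(m$cds), length_aa = nchar(m$protein),
    internal_stop = m$internal_stop,
    has_start_met = substr(m$protein, 1, 1) == "M",
    has_terminal_stop = m$has_terminal_stop,
    stringsAsFactors = FALSE, row.names = NULL)))
}

#' Extract proteins from gene models
#' @param models List of gene models.
#' @return Named [Biostrings::AAStringSet].
#' @export
gene_model_proteins <- function(models) {
  Biostrings::AAStringSet(vapply(models, `[[`, character(1), "protein"))
}

# ---- TSV report I/O ------------------------------------------------------

#' Write a TSV table with fixed column order
#' @param df data.frame to write.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (missing directory): ", dir)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv()]
#' @param path Input file.
#' @param col_classes Optional named vector of column classes (used so that a
#'   header-only file round-trips with the original column types).
#' @export
read_tsv <- function(path, col_classes = NULL) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, comment.char = "")
  if (!is.null(col_classes)) {
    for (nm in intersect(names(col_classes), names(df))) {
      df[[nm]] <- as(df[[nm]], col_classes[[nm]])
    }
  }
  df
}

#' Write the repertoire report tables
#'
#' Emits `per_gene.tsv` (one row per gene: classification and coordinates)
#' and `summary.tsv` (one row per assembly). Re-reading with
#' [read_repertoire_tables()] reproduces the input exactly.
#'
#' @param per_gene Per-gene classification data.frame.
#' @param summary One-row repertoire summary data.frame.
#' @param dir Output directory (created if missing).
#' @export
write_repertoire_tables <- function(per_gene, summary, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("unwritable path: ", dir)
  write_tsv(per_gene, file.path(dir, "per_gene.tsv"))
  write_tsv(summary, file.path(dir, "summary.tsv"))
  invisible(dir)
}

#' @rdname write_repertoire_tables
#' @export
read_repertoire_tables <- function(dir) {
  pg_classes <- c(gene_id = "character", scaffold = "character",
                  start = "integer", end = "integer", strand = "character",
                  subfamily = "character", bitter_type = "character",
                  length_aa = "integer", exon_count = "integer",
                  pseudogene = "logical", partial = "character")
  list(per_gene = read_tsv(file.path(dir, "per_gene.tsv"), pg_classes),
       summary = read_tsv(file.path(dir, "summary.tsv")))
}
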