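# Presence/absence expression profiling from per-gene x per-library read
# counts. Counts are normalised to reads per kilobase of CDS per million
# mapped reads (RPKM) and compared against a conservative detection cutoff;
# single-library detection suffices because the libraries carry no
# biological replication, and no between-library differential testing is
# attempted.

#' Relative abundance (RPKM)
#'
#' `abundance = count / (gene length in kb x library size in millions)`.
#'
#' @param counts Non-negative integer matrix, genes x libraries, with
#'   dimnames.
#' @param gene_lengths Named vector of gene (CDS) lengths in bases; must be
#'   positive.
#' @param library_sizes Named vector of total mapped reads per library; must
#'   be positive and at least the column sums of `counts`.
#' @return Numeric abundance matrix with the same dimnames.
#' @export
relative_abundance <- function(counts, gene_lengths, library_sizes) {
  gene_lengths <- gene_lengths[rownames(counts)]
  library_sizes <- library_sizes[colnames(counts)]
  if (anyNA(gene_lengths)) stop("missing gene length(s)")
  if (anyNA(library_sizes)) stop("missing library size(s)")
  if (any(gene_lengths <= 0))
    stop("zero-length gene: ",
         paste(rownames(counts)[gene_lengths <= 0], collapse = ", "))
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (any(colSums(counts) > library_sizes))
    stop("library size smaller than its column sum of counts")
  sweep(sweep(counts, 1, gene_lengths / 1e3, "/"),
        2, library_sizes / 1e6, "/")
}

#' Presence calls from an abundance matrix
#'
#' @param abundance Matrix from [relative_abundance()].
#' @param cutoff Detection cutoff on the abundance scale (>= 0). A gene is
#'   present in a library iff its abundance reaches the cutoff.
#' @return Logical matrix with attribute `cutoff`.
#' @export
call_presence <- function(abundance, cutoff = 1) {
  stopifnot(cutoff >= 0)
  pres <- abundance >= cutoff & abundance > 0
  attr(pres, "cutoff") <- cutoff
  pres
}

#' Per-group detection summary and per-gene breadth
#'
#' A gene counts as detected in a group when it is present in at least one
#' member library; breadth is the number of libraries in which a gene is
#' present.
#'
#' @param presence Logical matrix from [call_presence()].
#' @param library_groups Named list mapping group name to a character vector
#'   of library IDs; the groups must cover every library.
#' @return List with `group_counts` (data.frame: group, n_libraries,
#'   detected), `gene_breadth` (data.frame: gene_id, breadth),
#'   `detected_total` (genes present anywhere) and `detected_by_group`
#'   (named list of detected gene IDs per group).
#' @export
presence_summary <- function(presence, library_groups) {
  libs <- colnames(presence)
  grouped <- unlist(library_groups, use.names = FALSE)
  orphan <- setdiff(libs, grouped)
  if (length(orphan))
    stop("library in no group: ", paste(orphan, collapse = ", "))
  missing <- setdiff(grouped, libs)
  if (length(missing))
    stop("group references unknown library: ",
         paste(missing, collapse = ", "))
  det <- lapply(library_groups, function(g)
    rownames(presence)[rowSums(presence[, g, drop = FALSE]) > 0])
  group_counts <- data.frame(
    group = names(library_groups),
    n_libraries = vapply(library_groups, length, integer(1)),
    detected = vapply(det, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  gene_breadth <- data.frame(gene_id = rownames(presence),
                             breadth = as.integer(rowSums(presence)),
                             stringsAsFactors = FALSE)
  list(group_counts = group_counts,
       gene_breadth = gene_breadth,
       detected_total = sum(rowSums(presence) > 0),
       detected_by_group = det)
}
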