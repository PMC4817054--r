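# Tandem-array detection: maximal runs of (optionally same-type) genes on a
# scaffold chained while the gap between consecutive genes stays within
# max_gap. When a type filter is applied, gaps are measured between
# consecutive genes of the filtered type, ignoring interleaved genes of
# other types (interleaved scaffolds still yield per-type arrays).

#' Detect tandem gene arrays on scaffolds
#'
#' @param genes data.frame with `gene_id`, `scaffold`, `start`, `end`
#'   (1-based inclusive) and, when `type_filter` is used, `bitter_type`.
#' @param max_gap Maximum gap (bases, `next_start - previous_end`) between
#'   consecutive members.
#' @param min_array_size Minimum genes per reported array.
#' @param type_filter Optional bitter type; only genes of that type are
#'   considered (membership and gap computation alike).
#' @return data.frame of arrays: scaffold, type filter, size, first/last
#'   coordinates, span (`last end - first start`) and the ordered member
#'   list.
#' @export
detect_tandem_arrays <- function(genes, max_gap = 1e5, min_array_size = 3,
                                 type_filter = NULL) {
  stopifnot(max_gap > 0, min_array_size >= 1)
  empty <- data.frame(scaffold = character(0), type = character(0),
                      size = integer(0), first_start = integer(0),
                      last_end = integer(0), span = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
  if (!NROW(genes)) return(empty)
  bad <- is.na(genes$start) | is.na(genes$end) | is.na(genes$scaffold)
  if (any(bad))
    stop("gene(s) lacking coordinates: ",
         paste(genes$gene_id[bad], collapse = ", "))
  if (!is.null(type_filter)) {
    genes <- genes[genes$bitter_type == type_filter, , drop = FALSE]
    if (!nrow(genes)) return(empty)
  }
  out <- list()
  for (scf in unique(genes$scaffold)) {
    sub <- genes[genes$scaffold == scf, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    gap_ok <- if (nrow(sub) > 1)
      sub$start[-1] - sub$end[-nrow(sub)] <= max_gap else logical(0)
    grp <- cumsum(c(1L, as.integer(!gap_ok)))
    for (g in unique(grp)) {
      blk <- sub[grp == g, , drop = FALSE]
      if (nrow(blk) < min_array_size) next
      out[[length(out) + 1]] <- data.frame(
        scaffold = scf,
        type = if (is.null(type_filter)) "any" else type_filter,
        size = nrow(blk),
        first_start = min(blk$start), last_end = max(blk$end),
        span = max(blk$end) - min(blk$start),
        members = paste(blk$gene_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$first_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
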