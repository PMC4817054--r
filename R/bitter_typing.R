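# Structural typing of bitter GRs. Three classes: Type 1 (intron-containing,
# ~400 aa), Type 2 (long intronless, > 400 aa), Type 3 (short intronless,
# 200-350 aa, sharp upper bound 360 aa). Intronless lengths in [360, 400] or
# below 200 aa fall in ranges the scheme leaves uncovered and map to
# "unknown" rather than being forced to a nearest type. Pseudogenes keep
# their measurements but are tallied in their own column, outside the typed
# counts; partial models are never length-typed.

#' Pseudogene call from a gene model
#'
#' A gene model is called a pseudogene when an in-frame stop occurs before
#' the final codon of its CDS. Codons containing N never call a stop.
#'
#' @param gm A gene model (from [read_gff3()]) or a CDS string.
#' @return logical
#' @export
detect_pseudogene <- function(gm) {
  if (is.character(gm)) gm <- suppressWarnings(translate_cds(gm))
  isTRUE(gm$internal_stop)
}

#' Partial-sequence call
#'
#' @param protein Translated protein (stop-trimmed).
#' @param has_terminal_stop Did the CDS end in a stop codon?
#' @param require_start_met Require the first residue to be methionine for a
#'   complete N-terminus.
#' @return One of `"none"`, `"missing_n"`, `"missing_c"`, `"missing_both"`.
#' @export
detect_partial <- function(protein, has_terminal_stop,
                           require_start_met = TRUE) {
  if (!nchar(protein)) stop("empty protein")
  miss_n <- require_start_met && substr(protein, 1, 1) != "M"
  miss_c <- !has_terminal_stop
  if (miss_n && miss_c) "missing_both"
  else if (miss_n) "missing_n"
  else if (miss_c) "missing_c"
  else "none"
}

#' Bitter-receptor type classification
#'
#' @param length_aa Protein length (residues).
#' @param exon_count Number of exons.
#' @param pseudogene Pseudogene flag; pseudogenes are reported in their own
#'   summary column and here return `"unknown"`.
#' @param partial Partial flag from [detect_partial()]; any partial model
#'   returns `"unknown"`.
#' @param subfamily Must be `"bitter"`; anything else is a hard error.
#' @param type2_min_len Intronless genes strictly longer than this are
#'   Type 2.
#' @param type3_min_len,type3_max_len Intronless genes with
#'   `type3_min_len <= length < type3_max_len` are Type 3.
#' @return One of `"type1"`, `"type2"`, `"type3"`, `"unknown"`.
#' @export
classify_bitter_type <- function(length_aa, exon_count, pseudogene = FALSE,
                                 partial = "none", subfamily = "bitter",
                                 type2_min_len = 400, type3_min_len = 200,
                                 type3_max_len = 360) {
  if (!identical(subfamily, "bitter"))
    stop("classify_bitter_type() applies to bitter genes only (got '",
         subfamily, "')")
  if (isTRUE(pseudogene)) return("unknown")
  if (!identical(partial, "none")) return("unknown")
  if (exon_count >= 2) return("type1")
  if (length_aa > type2_min_len) return("type2")
  if (length_aa >= type3_min_len && length_aa < type3_max_len) return("type3")
  "unknown"
}

#' Classify a repertoire table
#'
#' Vectorised driver over a per-gene data.frame carrying `subfamily`,
#' `length_aa`, `exon_count`, `pseudogene` and `partial` columns; adds a
#' `bitter_type` column (`"not_bitter"` for non-bitter genes).
#'
#' @param df Per-gene data.frame.
#' @param ... Threshold parameters passed to [classify_bitter_type()].
#' @export
classify_repertoire <- function(df, ...) {
  df$bitter_type <- vapply(seq_len(nrow(df)), function(i) {
    if (df$subfamily[i] != "bitter") return("not_bitter")
    classify_bitter_type(df$length_aa[i], df$exon_count[i],
                         df$pseudogene[i], df$partial[i],
                         subfamily = "bitter", ...)
  }, character(1))
  df
}

#' Repertoire summary
#'
#' One row per assembly: subfamily counts, the bitter pseudogene column,
#' the typed-bitter total and its Type 1/2/3/unknown split, plus the count
#' of partial-flagged genes. The typed columns exclude pseudogenes, so
#' `type1 + type2 + type3 + unknown == bitter_clade - pseudo`.
#'
#' @param df Classified per-gene data.frame (see [classify_repertoire()]).
#' @return One-row data.frame.
#' @export
summarize_repertoire <- function(df) {
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  bitter <- df$subfamily == "bitter"
  pseudo <- bitter & df$pseudogene
  typed <- bitter & !df$pseudogene
  cnt <- function(x) as.integer(sum(x))
  data.frame(
    n_genes = cnt(rep(TRUE, nrow(df))),
    co2 = cnt(df$subfamily == "co2"),
    sugar = cnt(df$subfamily == "sugar"),
    gr43a_like = cnt(df$subfamily == "gr43a_like"),
    pseudo = cnt(pseudo),
    bitter_clade = cnt(bitter),
    bitter_typed_total = cnt(typed),
    type1 = cnt(typed & df$bitter_type == "type1"),
    type2 = cnt(typed & df$bitter_type == "type2"),
    type3 = cnt(typed & df$bitter_type == "type3"),
    unknown = cnt(typed & df$bitter_type == "unknown"),
    partial_flagged = cnt(df$partial != "none"),
    stringsAsFactors = FALSE)
}

#' Classical summary row
#'
#' The nine-column layout used for cross-species repertoire tables:
#' CO2, sugar, GR43a-like, pseudo, bitter total (typed), Type 1, Type 2,
#' Type 3, unknown.
#'
#' @param summary Output of [summarize_repertoire()].
#' @export
table1_row <- function(summary) {
  summary[, c("co2", "sugar", "gr43a_like", "pseudo", "bitter_typed_total",
              "type1", "type2", "type3", "unknown")]
}
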