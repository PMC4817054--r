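# Transmembrane topology from sequence: a Kyte-Doolittle sliding-window
# hydropathy scanner with threshold segmentation, termini sidedness by the
# positive-inside rule, and a parameter-grid consensus that mirrors the
# common practice of comparing several predictors. A single transparent
# predictor (no external web tools) keeps the stage deterministic and
# testable.

#' Kyte-Doolittle hydropathy scale
#' @return Named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' Sliding-window hydropathy profile
#'
#' Mean Kyte-Doolittle hydropathy over a centered window; edge positions use
#' the truncated window. Residues outside the 20-letter alphabet (X etc.)
#' score 0.
#'
#' @param protein Protein string.
#' @param window Odd window size, 7..25; the protein must be at least this
#'   long.
#' @return Numeric track, one score per residue.
#' @export
hydropathy_profile <- function(protein, window = 19) {
  if (window %% 2 != 1 || window < 7 || window > 25)
    stop("window must be odd and within 7..25")
  n <- nchar(protein)
  if (n < window)
    stop("protein length ", n, " is shorter than the window (", window,
         "); use a smaller window")
  kd <- kyte_doolittle()
  v <- kd[strsplit(toupper(protein), "")[[1]]]
  v[is.na(v)] <- 0
  half <- (window - 1) / 2
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Predict transmembrane topology
#'
#' Maximal runs of hydropathy scores at or above `threshold`, merged when
#' separated by fewer than `merge_gap` sub-threshold positions and kept when
#' at least `min_tm_len` long, become the TM segments. The terminus-adjacent
#' loop with more K+R residues is taken as intracellular (positive-inside
#' rule; ties favour the N-terminus); the other terminus follows by parity
#' (odd segment count: opposite sides, even: same side).
#'
#' @param protein Protein string.
#' @param window Hydropathy window (see [hydropathy_profile()]).
#' @param threshold Kyte-Doolittle threshold for a TM-candidate position.
#' @param min_tm_len Minimum segment length (residues).
#' @param merge_gap Runs separated by fewer than this many positions merge.
#' @return List: `protein_id`-free prediction with `tm_segments` (matrix of
#'   start/end residue positions), `tmd_count`, `n_terminus`, `c_terminus`
#'   (`"inside"`/`"outside"`, `NA` when no segment is found) and
#'   `is_membrane_protein`.
#' @export
predict_topology <- function(protein, window = 19, threshold = 1.6,
                             min_tm_len = 15, merge_gap = 4) {
  stopifnot(min_tm_len > 0, merge_gap > 0)
  track <- hydropathy_profile(protein, window)
  above <- track >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- cbind(start = starts[r$values], end = ends[r$values])
  # merge runs separated by short sub-threshold gaps
  if (nrow(seg) > 1) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      gap <- seg[i, "start"] - merged[nrow(merged), "end"] - 1
      if (gap < merge_gap) {
        merged[nrow(merged), "end"] <- seg[i, "end"]
      } else {
        merged <- rbind(merged, seg[i, , drop = FALSE])
      }
    }
    seg <- merged
  }
  seg <- seg[seg[, "end"] - seg[, "start"] + 1 >= min_tm_len, , drop = FALSE]
  k <- nrow(seg)
  if (k == 0) {
    return(list(tm_segments = seg, tmd_count = 0L,
                n_terminus = NA_character_, c_terminus = NA_character_,
                is_membrane_protein = FALSE))
  }
  aa <- strsplit(toupper(protein), "")[[1]]
  kr <- aa %in% c("K", "R")
  n_loop <- seq_len(max(seg[1, "start"] - 1, 0))
  c_loop <- if (seg[k, "end"] < length(aa))
    (seg[k, "end"] + 1):length(aa) else integer(0)
  kr_n <- sum(kr[n_loop]); kr_c <- sum(kr[c_loop])
  even <- k %% 2 == 0
  if (kr_n >= kr_c) {
    n_term <- "inside"
    c_term <- if (even) "inside" else "outside"
  } else {
    c_term <- "inside"
    n_term <- if (even) "inside" else "outside"
  }
  list(tm_segments = seg, tmd_count = as.integer(k),
       n_terminus = n_term, c_terminus = c_term,
       is_membrane_protein = TRUE)
}

#' Consensus topology over a parameter grid
#'
#' The consensus TMD count is the median of the votes (an exact tie takes
#' the lower value); the segments come from the first parameterization that
#' achieved the median; termini are decided by majority vote with the
#' C-terminus repaired to respect parity with the consensus count.
#'
#' @param predictions Non-empty list of [predict_topology()] results.
#' @export
consensus_topology <- function(predictions) {
  if (!length(predictions)) stop("no predictions to form a consensus")
  votes <- vapply(predictions, `[[`, integer(1), "tmd_count")
  sv <- sort(votes)
  med <- sv[floor((length(sv) + 1) / 2)]
  rep_pred <- predictions[[which(votes == med)[1]]]
  n_votes <- vapply(predictions, `[[`, character(1), "n_terminus")
  n_votes <- n_votes[!is.na(n_votes)]
  n_term <- if (!length(n_votes)) NA_character_
  else if (sum(n_votes == "inside") >= sum(n_votes == "outside"))
    "inside" else "outside"
  c_term <- if (is.na(n_term) || med == 0) NA_character_
  else if (med %% 2 == 0) n_term
  else if (n_term == "inside") "outside" else "inside"
  list(tm_segments = rep_pred$tm_segments, tmd_count = med,
       n_terminus = if (med == 0) NA_character_ else n_term,
       c_terminus = c_term,
       is_membrane_protein = med > 0, votes = votes)
}

#' Topology table for a protein set
#'
#' @param proteins Named character vector or AAStringSet.
#' @param ... Parameters for [predict_topology()].
#' @return data.frame: protein_id, tmd_count, n/c terminus, segment list.
#' @export
topology_table <- function(proteins, ...) {
  pnm <- names(proteins)
  proteins <- as.character(proteins)
  if (is.null(names(proteins))) names(proteins) <- pnm
  rows <- lapply(names(proteins), function(id) {
    p <- predict_topology(proteins[[id]], ...)
    segs <- if (nrow(p$tm_segments))
      paste(p$tm_segments[, "start"], p$tm_segments[, "end"],
            sep = "-", collapse = ";") else ""
    data.frame(protein_id = id, length_aa = nchar(proteins[[id]]),
               tmd_count = p$tmd_count,
               n_terminus = ifelse(is.na(p$n_terminus), "na", p$n_terminus),
               c_terminus = ifelse(is.na(p$c_terminus), "na", p$c_terminus),
               segments = segs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(protein_id = character(0),
                                      length_aa = integer(0),
                                      tmd_count = integer(0),
                                      n_terminus = character(0),
                                      c_terminus = character(0),
                                      segments = character(0))
  rownames(out) <- NULL
  out
}
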