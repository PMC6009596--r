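#' Scoring parameters for restriction-map alignment
#'
#' @param tol_bp absolute sizing tolerance (bp). The tolerance of a matched
#'   interval is `max(tol_bp, tol_rel * reference interval)`.
#' @param tol_rel relative sizing tolerance.
#' @param match_bonus score awarded per matched interval.
#' @param miss_pen penalty per reference label skipped inside the alignment.
#' @param extra_pen penalty per query label skipped inside the alignment.
#' @param end_pen penalty per unmatched query end label beyond the first at
#'   each end (molecule ends are sizing artifacts).
#' @param max_skip maximum labels skipped in one transition.
#' @param min_score score floor below which no alignment is reported.
#' @return object of class `align_params`.
#' @export
align_params <- function(tol_bp = 500, tol_rel = 0.05, match_bonus = 3,
                         miss_pen = 3, extra_pen = 3, end_pen = 1.5,
                         max_skip = 6L, min_score = 6) {
  structure(list(tol_bp = tol_bp, tol_rel = tol_rel,
                 match_bonus = match_bonus, miss_pen = miss_pen,
                 extra_pen = extra_pen, end_pen = end_pen,
                 max_skip = as.integer(max_skip), min_score = min_score),
            class = "align_params")
}

## run the DP for one orientation; q, r numeric label vectors
run_dp <- function(q, r, p) {
  align_dp_cpp(q, r, p$tol_bp, p$tol_rel, p$match_bonus, p$miss_pen,
               p$extra_pen, p$end_pen, p$max_skip)
}

#' Align a query nick map to a reference nick map
#'
#' Dynamic-programming alignment over label intervals, both orientations
#' tried; returns the highest-scoring alignment above the score floor, or
#' `NULL`. Ties prefer the forward orientation, then the leftmost reference
#' start. `fully_aligned` is true when all query labels are matched except
#' at most one at each end.
#'
#' @param query,ref [nick_map()]s; the query needs >= 2 labels.
#' @param params an [align_params()].
#' @return object of class `map_alignment` or `NULL`.
#' @export
align_maps <- function(query, ref, params = align_params()) {
  stopifnot(inherits(query, "nick_map"), inherits(ref, "nick_map"))
  if (length(query$labels) < 2) stop("query must have >= 2 labels")
  if (any(diff(query$labels) <= 0) ||
      (length(ref$labels) > 1 && any(diff(ref$labels) <= 0)))
    stop("non-monotone label list")
  if (length(ref$labels) < 1) return(NULL)

  nq <- length(query$labels)
  fwd <- run_dp(query$labels, ref$labels, params)
  qrev <- query$length - 1 - rev(query$labels)
  bwd <- run_dp(qrev, ref$labels, params)
  if (fwd$score < -1e17 && bwd$score < -1e17) return(NULL)

  pick_fwd <-if (abs(fwd$score - bwd$score) <= 1e-9) {
    rf <- ref$labels[fwd$rj[1]]; rb <- ref$labels[bwd$rj[1]]
    if (abs(rf - rb) <= 1e-9) TRUE else rf <= rb
  } else fwd$score > bwd$score

  res <- if (pick_fwd) fwd else bwd
  if (res$score < params$min_score || length(res$qi) < 2) return(NULL)

  orientation <- if (pick_fwd) "+" else "-"
  qi_frame <- res$qi                      # indices in the oriented query
  qi_orig <- if (pick_fwd) qi_frame else nq + 1L - qi_frame
  k <- length(qi_frame)
  fully <- (res$extra == 0) && (qi_frame[1] <= 2) && (qi_frame[k] >= nq - 1)

  structure(list(
    query_id = query$map_id, ref_id = ref$map_id, orientation = orientation,
    pairs = data.frame(qi = qi_orig, rj = res$rj),
    residuals = res$residuals,
    missing_label_count = res$missing, extra_label_count = res$extra,
    score = res$score, fully_aligned = fully,
    n_matched = k,
    matched_query_pos = query$labels[qi_orig],
    matched_ref_pos = ref$labels[res$rj],
    ref_start_bp = ref$labels[res$rj[1]],
    ref_end_bp = ref$labels[res$rj[k]],
    query_frame_idx = qi_frame), class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat("<map_alignment>", x$query_id, "->", x$ref_id,
      sprintf("(%s) %d pairs, score %.2f%s\n", x$orientation, x$n_matched,
              x$score, if (x$fully_aligned) ", fully aligned" else ""))
  invisible(x)
}

#' Exhaustive monotone-matching alignment score (reference oracle)
#'
#' Enumerates every monotone matching between the two label lists (both
#' orientations) under the same scoring as [align_maps()] and returns the
#' best score. Exponential; intended for maps with few labels.
#'
#' @inheritParams align_maps
#' @return best score over all matchings (may be below the score floor).
#' @export
align_score_bruteforce <- function(query, ref, params = align_params()) {
  score_one_frame <- function(q, r) {
    nq <- length(q); nr <- length(r)
    best <- -Inf
    if (min(nq, nr) < 2) return(best)
    ## enumerate ordered index subsets of equal size k >= 2 on both sides
    ## (a single matched pair defines no interval, hence no alignment)
    for (k in 2:min(nq, nr)) {
      qs <- utils::combn(nq, k, simplify = FALSE)
      rs <- utils::combn(nr, k, simplify = FALSE)
      for (qi in qs) for (rj in rs) {
        s <- -params$end_pen * max(0, qi[1] - 2) -
          params$end_pen * max(0, nq - qi[k] - 1)
        if (k > 1) for (t in 2:k) {
          dq <- q[qi[t]] - q[qi[t - 1]]
          dr <- r[rj[t]] - r[rj[t - 1]]
          tol <- max(params$tol_bp, params$tol_rel * dr)
          s <- s + params$match_bonus - ((dq - dr) / tol)^2 -
            params$miss_pen * (rj[t] - rj[t - 1] - 1) -
            params$extra_pen * (qi[t] - qi[t - 1] - 1)
        }
        if (s > best) best <- s
      }
    }
    best
  }
  qrev <- query$length - 1 - rev(query$labels)
  max(score_one_frame(query$labels, ref$labels),
      score_one_frame(qrev, ref$labels))
}

#' Classify molecule support around a junction on an optical map
#'
#' Every molecule whose aligned span overlaps the window
#' `[junction - flank, junction + flank]` is classified by whether its
#' alignment is fully aligned and whether it has matched labels on both
#' sides of the junction coordinate.
#'
#' @param alignments list of [align_maps()] results for molecules (only
#'   those on the junction's map are considered).
#' @param map_id reference map carrying the junction.
#' @param junction junction coordinate (bp) on the reference map.
#' @param flank half-window in bp (default 50 kb).
#' @return data.frame: `query_id`, `fully_aligned`, `spans_junction`,
#'   `category` (`fully_aligned_in_window`, `spans_junction`, `other`).
#' @export
classify_flank_support <- function(alignments, map_id, junction,
                                   flank = 50000) {
  if (flank <= 0) stop("flank must be > 0")
  rows <- lapply(alignments, function(a) {
    if (is.null(a) || a$ref_id != map_id) return(NULL)
    lo <- min(a$matched_ref_pos); hi <- max(a$matched_ref_pos)
    if (hi < junction - flank || lo > junction + flank) return(NULL)
    spans <- any(a$matched_ref_pos < junction) &&
      any(a$matched_ref_pos > junction)
    data.frame(query_id = a$query_id, fully_aligned = a$fully_aligned,
               spans_junction = spans,
               category = if (a$fully_aligned) "fully_aligned_in_window"
                          else if (spans) "spans_junction" else "other",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(query_id = character(0), fully_aligned = logical(0),
                      spans_junction = logical(0), category = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best placement of each molecule across a set of reference maps
#'
#' @param molecules list of [nick_map()]s (>= 2 labels each; others are
#'   skipped).
#' @param refs list of reference [nick_map()]s.
#' @param params an [align_params()].
#' @return named list of `map_alignment` (best-scoring reference per
#'   molecule; molecules with no alignment above the floor are absent).
#' @export
align_molecules <- function(molecules, refs, params = align_params()) {
  out <- list()
  for (m in molecules) {
    if (length(m$labels) < 2) next
    best <- NULL
    for (r in refs) {
      a <- align_maps(m, r, params)
      if (!is.null(a) && (is.null(best) || a$score > best$score)) best <- a
    }
    if (!is.null(best)) out[[m$map_id]] <- best
  }
  out
}
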