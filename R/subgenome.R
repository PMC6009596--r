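#' Build a diagnostic k-mer index from two ancestral genomes
#'
#' Canonical (strand-collapsed) k-mers are collected for each ancestor; the
#' diagnostic set of an ancestor is its k-mers absent from the other.
#' k-mers touching non-ACGT characters are excluded.
#'
#' @param ancestor_a,ancestor_b named character vectors of sequences.
#' @param k odd k-mer length >= 11 (canonicalization needs odd k).
#' @return object of class `ancestor_index`: `k`, `diag_a`, `diag_b`
#'   (sorted numeric k-mer codes).
#' @export
build_ancestor_index <- function(ancestor_a, ancestor_b, k = 21) {
  if (k < 11 || k %% 2 == 0) stop("k must be odd and >= 11")
  if (!length(ancestor_a) || !length(ancestor_b))
    stop("both ancestor sets must be nonempty")
  kmers_of <- function(seqs) {
    v <- unlist(lapply(unname(seqs), canonical_kmers, k = k), use.names = FALSE)
    sort(unique(v[!is.na(v)]))
  }
  ka <- kmers_of(ancestor_a)
  kb <- kmers_of(ancestor_b)
  structure(list(k = k, diag_a = setdiff(ka, kb), diag_b = setdiff(kb, ka)),
            class = "ancestor_index")
}

#' @export
print.ancestor_index <- function(x, ...) {
  cat("<ancestor_index> k =", x$k, "-", length(x$diag_a), "A-diagnostic /",
      length(x$diag_b), "B-diagnostic k-mers\n")
  invisible(x)
}

#' Assign sequences to subgenomes by diagnostic k-mer voting
#'
#' Votes are the counts of a sequence's canonical k-mers found in each
#' diagnostic set. A sequence is labeled `A` iff `votes_a >= min_votes` and
#' `votes_a >= min_margin * votes_b` (symmetric for `B`); if both sides
#' reach `min_votes` but neither wins the margin, it is `ambiguous`;
#' otherwise `unassigned`. A per-window vote track (10-kb nonoverlapping)
#' is attached for chimera diagnostics.
#'
#' @param sequences named character vector.
#' @param index an [build_ancestor_index()] result.
#' @param min_votes vote floor (default 10).
#' @param min_margin required vote ratio (default 2.0).
#' @param window window size for the vote track (bp).
#' @return data.frame: `sequence_id`, `label`, `votes_a`, `votes_b`,
#'   `margin`; the window track is attribute `"windows"` (`sequence_id`,
#'   `win_start0`, `votes_a`, `votes_b`).
#' @export
assign_scaffolds <- function(sequences, index, min_votes = 10,
                             min_margin = 2.0, window = 10000) {
  stopifnot(inherits(index, "ancestor_index"))
  rows <- list()
  wins <- list()
  for (id in names(sequences)) {
    km <- canonical_kmers(sequences[[id]], index$k)
    pos <- which(!is.na(km))
    km <- km[pos]
    in_a <- km %in% index$diag_a
    in_b <- km %in% index$diag_b
    va <- sum(in_a); vb <- sum(in_b)
    label <- if (va >= min_votes && va >= min_margin * vb) "A"
      else if (vb >= min_votes && vb >= min_margin * va) "B"
      else if (va >= min_votes && vb >= min_votes) "ambiguous"
      else "unassigned"
    margin <- if (va == 0 && vb == 0) NA_real_ else
      max(va, vb) / max(1, min(va, vb))
    rows[[id]] <- data.frame(sequence_id = id, label = label,
                             votes_a = va, votes_b = vb, margin = margin,
                             stringsAsFactors = FALSE)
    if (length(pos)) {
      wbin <- (pos - 1L) %/% window
      wa <- tapply(in_a, wbin, sum)
      wb <- tapply(in_b, wbin, sum)
      wins[[id]] <- data.frame(sequence_id = id,
                               win_start0 = as.integer(names(wa)) * window,
                               votes_a = as.integer(wa),
                               votes_b = as.integer(wb),
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "windows") <- if (length(wins)) do.call(rbind, wins) else NULL
  out
}
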