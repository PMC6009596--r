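#' Simulate the allotetraploid truth set
#'
#' Generates two ancestor genomes (diverged from a common random sequence by
#' point substitutions at `ancestor_divergence`) and, from each ancestor, a
#' descendant subgenome carrying further substitutions and short (<= 5 bp)
#' indels at `subgenome_divergence`. The union of the two subgenomes is the
#' "true" tetraploid genome every simulator samples from.
#'
#' @param config a [sim_config()].
#' @return an object of class `truth_set`: a list with `ancestors` (named
#'   list `A`/`B` of named chromosome character vectors), `subgenomes`
#'   (likewise; chromosome names `A01`, `A02`, ..., `B01`, ...), and empty
#'   `fragments`/`chimeras` slots filled in by [make_draft_with_chimeras()].
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$chromosome_length <= 0L) stop("zero-length chromosome requested")
  op_seed(config$seed, "truth")
  nchr <- config$n_chromosomes_per_subgenome
  L <- config$chromosome_length

  base <- vapply(seq_len(nchr), function(i) random_dna(L), character(1))
  ## the two ancestors split from `base`: half the divergence on each branch
  half <- config$ancestor_divergence / 2
  anc_a <- vapply(base, function(s) mutate_dna(s, half), character(1), USE.NAMES = FALSE)
  anc_b <- vapply(base, function(s) mutate_dna(s, half), character(1), USE.NAMES = FALSE)
  names(anc_a) <- sprintf("ancA_chr%02d", seq_len(nchr))
  names(anc_b) <- sprintf("ancB_chr%02d", seq_len(nchr))

  indel_rate <- 0.05 * config$subgenome_divergence
  sub_a <- vapply(anc_a, function(s)
    mutate_dna(s, config$subgenome_divergence, indel_rate), character(1), USE.NAMES = FALSE)
  sub_b <- vapply(anc_b, function(s)
    mutate_dna(s, config$subgenome_divergence, indel_rate), character(1), USE.NAMES = FALSE)
  names(sub_a) <- sprintf("A%02d", seq_len(nchr))
  names(sub_b) <- sprintf("B%02d", seq_len(nchr))

  structure(list(ancestors = list(A = anc_a, B = anc_b),
                 subgenomes = list(A = sub_a, B = sub_b),
                 fragments = NULL,
                 chimeras = NULL,
                 config = config),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  chroms <- truth_chromosomes(x)
  cat("<truth_set>", length(chroms), "chromosomes,",
      sum(nchar(chroms)), "bp total")
  if (!is.null(x$fragments))
    cat(";", length(unique(x$fragments$draft_id)), "draft sequences,",
        if (is.null(x$chimeras)) 0L else nrow(x$chimeras), "planted chimeras")
  cat("\n")
  invisible(x)
}

## named character vector of all true chromosomes (both subgenomes)
truth_chromosomes <- function(truth) {
  c(truth$subgenomes$A, truth$subgenomes$B)
}

#' Fragment the truth into a draft assembly with planted chimeric joins
#'
#' Cuts every true chromosome into fragments (Normal around
#' `fragment_length_mean`, truncated at 25 kb), then joins `n_chimeras`
#' pairs of non-adjacent fragments into single chimeric draft sequences.
#' The junction coordinate and the two source intervals of every chimera are
#' recorded as truth.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the same [sim_config()].
#' @return the `truth_set` with `fragments` (data.frame: `draft_id`, `part`,
#'   `chrom`, `start0`, `end0`, `strand`, `draft_start0`, `subgenome`) and
#'   `chimeras` (data.frame: `draft_id`, `junction`, per-side source
#'   interval) filled, and a `draft` element: named character vector of
#'   draft sequences.
#' @export
make_draft_with_chimeras <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  op_seed(config$seed, "draft")
  chroms <- truth_chromosomes(truth)
  min_frag <- 25000L

  frags <- list()
  for (chrom in names(chroms)) {
    L <- nchar(chroms[[chrom]])
    cuts <- integer(0)
    pos <- 0L
    repeat {
      len <- as.integer(round(rnorm(1, config$fragment_length_mean,
                                    config$fragment_length_mean / 4)))
      len <- max(len, min_frag)
      if (pos + len + min_frag > L) break     # remainder becomes last fragment
      pos <- pos + len
      cuts <- c(cuts, pos)
    }
    starts <- c(0L, cuts)
    ends <- c(cuts, L)
    frags[[chrom]] <- data.frame(chrom = chrom, start0 = starts, end0 = ends,
                                 subgenome = substr(chrom, 1, 1),
                                 stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, frags)
  rownames(frags) <- NULL
  frags$order_index <- stats::ave(seq_len(nrow(frags)), frags$chrom,
                                  FUN = seq_along)
  nfrag <- nrow(frags)
  if (2L * config$n_chimeras > nfrag)
    stop("n_chimeras exceeds available fragment count")

  ## choose chimera partners: pairs of distinct, non-adjacent fragments
  chim_pairs <- matrix(integer(0), ncol = 2)
  if (config$n_chimeras > 0L) {
    avail <- seq_len(nfrag)
    for (i in seq_len(config$n_chimeras)) {
      repeat {
        if (config$prefer_cross_subgenome &&
            any(frags$subgenome[avail] == "A") &&
            any(frags$subgenome[avail] == "B")) {
          f1 <- sample(avail[frags$subgenome[avail] == "A"], 1)
          f2 <- sample(avail[frags$subgenome[avail] == "B"], 1)
        } else {
          pick <- sample(avail, 2)
          f1 <- pick[1]; f2 <- pick[2]
        }
        adjacent <- frags$chrom[f1] == frags$chrom[f2] &&
          abs(frags$order_index[f1] - frags$order_index[f2]) <= 1
        if (!adjacent) break
      }
      chim_pairs <- rbind(chim_pairs, c(f1, f2))
      avail <- setdiff(avail, c(f1, f2))
    }
  }

  in_chimera <- rep(FALSE, nfrag)
  in_chimera[as.vector(chim_pairs)] <- TRUE

  draft <- character(0)
  frag_rows <- list()
  chim_rows <- list()
  ctg <- 0L
  subseq_ <- function(chrom, s0, e0) substr(chroms[[chrom]], s0 + 1L, e0)

  for (i in which(!in_chimera)) {
    ctg <- ctg + 1L
    id <- sprintf("ctg%04d", ctg)
    draft[[id]] <- subseq_(frags$chrom[i], frags$start0[i], frags$end0[i])
    frag_rows[[length(frag_rows) + 1L]] <-
      data.frame(draft_id = id, part = 1L, chrom = frags$chrom[i],
                 start0 = frags$start0[i], end0 = frags$end0[i],
                 strand = "+", draft_start0 = 0L,
                 subgenome = frags$subgenome[i],
                 order_index = frags$order_index[i],
                 stringsAsFactors = FALSE)
  }
  if (nrow(chim_pairs)) for (r in seq_len(nrow(chim_pairs))) {
    ctg <- ctg + 1L
    id <- sprintf("ctg%04d", ctg)
    f1 <- chim_pairs[r, 1]; f2 <- chim_pairs[r, 2]
    s1 <- subseq_(frags$chrom[f1], frags$start0[f1], frags$end0[f1])
    s2 <- subseq_(frags$chrom[f2], frags$start0[f2], frags$end0[f2])
    draft[[id]] <- paste0(s1, s2)
    jct <- nchar(s1)
    frag_rows[[length(frag_rows) + 1L]] <-
      data.frame(draft_id = id, part = c(1L, 2L),
                 chrom = frags$chrom[c(f1, f2)],
                 start0 = frags$start0[c(f1, f2)],
                 end0 = frags$end0[c(f1, f2)],
                 strand = "+", draft_start0 = c(0L, jct),
                 subgenome = frags$subgenome[c(f1, f2)],
                 order_index = frags$order_index[c(f1, f2)],
                 stringsAsFactors = FALSE)
    chim_rows[[length(chim_rows) + 1L]] <-
      data.frame(draft_id = id, junction = jct,
                 chrom1 = frags$chrom[f1], start1 = frags$start0[f1], end1 = frags$end0[f1],
                 chrom2 = frags$chrom[f2], start2 = frags$start0[f2], end2 = frags$end0[f2],
                 stringsAsFactors = FALSE)
  }

  truth$fragments <- do.call(rbind, frag_rows)
  truth$chimeras <- if (length(chim_rows)) do.call(rbind, chim_rows) else
    data.frame(draft_id = character(0), junction = integer(0),
               chrom1 = character(0), start1 = integer(0), end1 = integer(0),
               chrom2 = character(0), start2 = integer(0), end2 = integer(0))
  truth$draft <- draft
  truth
}

## Lift truth-chromosome coordinates into draft coordinates.
## pos0 is 0-based on `chrom`; returns data.frame(draft_id, dpos0) with NA
## rows where the position falls in no fragment (cannot happen: fragments
## tile each chromosome).
lift_to_draft <- function(truth, chrom, pos0) {
  fr <- truth$fragments
  out_id <- rep(NA_character_, length(pos0))
  out_pos <- rep(NA_integer_, length(pos0))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    fsel <- fr[fr$chrom == ch, ]
    fsel <- fsel[order(fsel$start0), ]
    idx <- findInterval(pos0[sel], fsel$start0)
    ok <- idx >= 1 & pos0[sel] < fsel$end0[pmax(idx, 1)]
    out_id[sel[ok]] <- fsel$draft_id[idx[ok]]
    out_pos[sel[ok]] <- pos0[sel[ok]] - fsel$start0[idx[ok]] +
      fsel$draft_start0[idx[ok]]
  }
  data.frame(draft_id = out_id, dpos0 = out_pos, stringsAsFactors = FALSE)
}
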