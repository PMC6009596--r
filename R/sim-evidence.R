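#' Simulate optical molecules from the true chromosomes
#'
#' Samples single-molecule nick maps from the true chromosomes at
#' `molecule_coverage` fold coverage. Label positions are the true nick
#' positions of the sampled interval with multiplicative Gaussian sizing
#' noise on each inter-label interval; molecules are flipped with
#' probability 1/2. A `fraction_failing_filters` share of molecules is drawn
#' to violate one retention filter (short length, label SNR < 3, or average
#' intensity >= 0.6); the rest are drawn to pass all filters.
#'
#' @param truth a [simulate_truth()] result.
#' @param motif nickase recognition sequence (default Nt.BspQI, `GCTCTTC`).
#' @param config a [sim_config()].
#' @return list of [optical_molecule()] objects with a `"truth"` attribute
#'   (data.frame of molecule origin: chromosome, start, strand, planted
#'   filter failure).
#' @export
simulate_molecules <- function(truth, motif = "GCTCTTC", config) {
  stopifnot(inherits(truth, "truth_set"), nchar(motif) >= 4)
  if (config$molecule_coverage <= 0) stop("molecule coverage must be > 0")
  op_seed(config$seed, "molecules")
  chroms <- truth_chromosomes(truth)
  lens <- nchar(chroms)
  nicks <- lapply(chroms, function(s) digest_sequence(s, motif)$labels)
  target <- config$molecule_coverage * sum(lens)

  mols <- list()
  meta <- list()
  total <- 0
  i <- 0L
  while (total < target) {
    i <- i + 1L
    fails <- runif(1) < config$fraction_failing_filters
    mode <- if (fails) sample(c("short", "snr", "intensity"), 1) else "pass"
    len <- if (mode == "short") round(runif(1, 100000, 148000)) else
      max(155000, round(rnorm(1, config$molecule_length_mean,
                              config$molecule_length_sd)))
    snr <- if (mode == "snr") runif(1, 0.5, 2.9) else runif(1, 3, 15)
    intensity <- if (mode == "intensity") runif(1, 0.61, 0.9) else runif(1, 0.2, 0.55)
    chrom <- sample(names(chroms), 1, prob = lens)
    L <- lens[[chrom]]
    len <- min(len, L)
    start <- floor(runif(1, 0, L - len + 1))
    rel <- nicks[[chrom]]
    rel <- rel[rel >= start & rel < start + len] - start
    strand <- if (runif(1) < 0.5) "+" else "-"
    if (strand == "-") rel <- sort(len - rel)
    rel <- rel[rel >= 0 & rel < len]
    if (config$sizing_noise_sd > 0 && length(rel)) {
      d <- diff(c(0, rel))
      d <- d * (1 + rnorm(length(d), 0, config$sizing_noise_sd))
      rel <- round(cumsum(pmax(d, 1)))
      rel <- pmin(rel, len - 1)
      rel <- rel[!duplicated(rel)]
    }
    id <- sprintf("mol%05d", i)
    mols[[id]] <- optical_molecule(id, len, rel, snr, intensity)
    meta[[i]] <- data.frame(mol_id = id, chrom = chrom, start = start,
                            strand = strand, planted_fail = fails,
                            stringsAsFactors = FALSE)
    total <- total + len
  }
  attr(mols, "truth") <- do.call(rbind, meta)
  mols
}

#' Simulate mate-pair alignment records in draft coordinates
#'
#' Draws read pairs from the true chromosomes with per-library
#' Normal(insert_mean, insert_sd) inserts in innie (forward/reverse)
#' orientation, then projects each 100-bp mate onto the draft. Mates that
#' straddle a draft fragment boundary are dropped. A pair drawn across a
#' planted chimera junction therefore never yields a concordant pair inside
#' the chimeric draft sequence: the discordance is built in.
#'
#' @inheritParams simulate_molecules
#' @return data.frame with one row per mate: `read_id`, `mate`, `contig`,
#'   `pos0`, `strand`, `mapq`, `unique`, `library`.
#' @export
simulate_mate_pairs <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"), !is.null(truth$fragments))
  op_seed(config$seed, "matepairs")
  chroms <- truth_chromosomes(truth)
  lens <- nchar(chroms)
  rl <- 100L
  out <- list()
  for (lib in config$mp_libraries) {
    if (lib$insert_sd <= 0) stop("insert_sd must be > 0")
    n <- lib$n_pairs
    chrom <- sample(names(chroms), n, replace = TRUE, prob = lens)
    insert <- pmax(2L * rl, round(rnorm(n, lib$insert_mean, lib$insert_sd)))
    maxs <- lens[chrom] - insert
    keep <- maxs >= 0
    chrom <- chrom[keep]; insert <- insert[keep]; maxs <- maxs[keep]
    s <- floor(runif(length(chrom), 0, maxs + 1))
    ## mate 1 forward at [s, s+rl), mate 2 reverse at [s+insert-rl, s+insert)
    m1s <- lift_to_draft(truth, chrom, s)
    m1e <- lift_to_draft(truth, chrom, s + rl - 1L)
    m2s <- lift_to_draft(truth, chrom, s + insert - rl)
    m2e <- lift_to_draft(truth, chrom, s + insert - 1L)
    ok <- !is.na(m1s$draft_id) & !is.na(m2s$draft_id) &
      m1s$draft_id == m1e$draft_id & (m1e$dpos0 - m1s$dpos0) == rl - 1L &
      m2s$draft_id == m2e$draft_id & (m2e$dpos0 - m2s$dpos0) == rl - 1L
    nk <- sum(ok)
    if (!nk) next
    uniq <- runif(nk) >= 0.02
    read_id <- sprintf("%s_%07d", lib$name, seq_len(nk))
    out[[lib$name]] <- data.frame(
      read_id = rep(read_id, each = 2L),
      mate = rep(c(1L, 2L), nk),
      contig = as.vector(rbind(m1s$draft_id[ok], m2s$draft_id[ok])),
      pos0 = as.vector(rbind(m1s$dpos0[ok], m2s$dpos0[ok])),
      strand = rep(c("+", "-"), nk),
      mapq = rep(ifelse(uniq, 60L, 0L), each = 2L),
      unique = rep(uniq, each = 2L),
      library = lib$name,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(read_id = character(0), mate = integer(0),
                      contig = character(0), pos0 = integer(0),
                      strand = character(0), mapq = integer(0),
                      unique = logical(0), library = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate long-read alignment records with soft clips at chimera junctions
#'
#' Tiles every draft sequence with long-read alignments at
#' `longread_coverage`. Reads crossing a planted chimera junction are split
#' there: each side is emitted as an alignment ending within ~60 bp of the
#' junction with the unaligned remainder recorded as a soft clip, so no read
#' spans a chimeric junction while ordinary positions keep full spanning
#' coverage.
#'
#' @inheritParams simulate_molecules
#' @param draft named character vector of draft sequences
#'   (`truth$draft` from [make_draft_with_chimeras()]).
#' @return data.frame: `read_id`, `contig`, `start0`, `end0`, `clip_left`,
#'   `clip_right` (clip lengths in bp; 0 = no clip on that side).
#' @export
simulate_long_read_clips <- function(truth, draft, config) {
  stopifnot(inherits(truth, "truth_set"))
  op_seed(config$seed, "longreads")
  if (!length(draft))
    return(data.frame(read_id = character(0), contig = character(0),
                      start0 = integer(0), end0 = integer(0),
                      clip_left = integer(0), clip_right = integer(0)))
  junctions <- setNames(truth$chimeras$junction, truth$chimeras$draft_id)
  out <- list()
  rid <- 0L
  for (ctg in names(draft)) {
    L <- nchar(draft[[ctg]])
    mu <- config$longread_length_mean
    ## stratified (jittered evenly spaced) starts over the padded interval
    ## so interior coverage stays close to the nominal fold everywhere
    n <- ceiling(config$longread_coverage * (L + mu - 1000) / mu)
    len <- pmax(2000, round(rnorm(n, mu, mu / 4)))
    step <- (L + mu - 1000) / n
    s <- floor(-mu + 500 + (seq_len(n) - 0.5) * step +
                 runif(n, -step / 2, step / 2))
    a <- pmax(0L, as.integer(s))
    e <- pmin(L, as.integer(s + len))
    keep <- e - a >= 500
    a <- a[keep]; e <- e[keep]
    j <- junctions[ctg]
    rows <- list()
    if (!is.na(j)) {
      cross <- a < j & e > j
      for (i in which(cross)) {
        jit1 <- max(-60, min(60, round(rnorm(1, 0, 20))))
        jit2 <- max(-60, min(60, round(rnorm(1, 0, 20))))
        b1 <- j + jit1; b2 <- j + jit2
        if (b1 - a[i] >= 500) {
          rid <- rid + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = sprintf("lr%06d", rid), contig = ctg,
            start0 = a[i], end0 = b1, clip_left = 0L,
            clip_right = as.integer(e[i] - b1), stringsAsFactors = FALSE)
        }
        if (e[i] - b2 >= 500) {
          rid <- rid + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = sprintf("lr%06d", rid), contig = ctg,
            start0 = b2, end0 = e[i], clip_left = as.integer(b2 - a[i]),
            clip_right = 0L, stringsAsFactors = FALSE)
        }
      }
      a <- a[!cross]; e <- e[!cross]
    }
    if (length(a)) {
      ids <- sprintf("lr%06d", rid + seq_along(a))
      rid <- rid + length(a)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = ids, contig = ctg, start0 = a, end0 = e,
        clip_left = 0L, clip_right = 0L, stringsAsFactors = FALSE)
    }
    out[[ctg]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate Hi-C contact records in draft coordinates
#'
#' Intra-chromosomal pairs follow a power-law distance decay,
#' P(d) proportional to (1+d)^(-exponent); a `hic_inter_fraction` share is
#' uniform inter-chromosomal background. Both ends are projected from truth
#' onto the draft sequences. Ten percent of pairs get mapq <= 20 and 2% a
#' duplicate flag so downstream filtering has work to do.
#'
#' @inheritParams simulate_molecules
#' @return data.frame: `seq1`, `pos1`, `seq2`, `pos2`, `mapq`, `dup`.
#' @export
simulate_contacts <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"), !is.null(truth$fragments))
  if (config$hic_decay_exponent <= 0) stop("decay exponent must be > 0")
  op_seed(config$seed, "contacts")
  chroms <- truth_chromosomes(truth)
  lens <- nchar(chroms)
  n <- config$n_hic_pairs
  inter <- runif(n) < config$hic_inter_fraction
  alpha <- config$hic_decay_exponent

  ## intra: anchor uniform, separation by inverse-CDF of the truncated
  ## power law; pairs running off the chromosome end are redrawn so the
  ## joint density stays proportional to (1+d)^(-alpha) everywhere
  n_in <- sum(!inter)
  chrom1 <- sample(names(chroms), n_in, replace = TRUE, prob = lens)
  L <- lens[chrom1]
  draw_d <- function(m, L) {
    u <- runif(m)
    d <- if (abs(alpha - 1) < 1e-9) {
      (1 + L)^u - 1
    } else {
      (1 + u * ((1 + L)^(1 - alpha) - 1))^(1 / (1 - alpha)) - 1
    }
    pmin(round(d), L - 1L)
  }
  p1 <- floor(runif(n_in, 0, L))
  p2 <- p1 + draw_d(n_in, L)
  redo <- which(p2 >= L)
  while (length(redo)) {
    p1[redo] <- floor(runif(length(redo), 0, L[redo]))
    p2[redo] <- p1[redo] + draw_d(length(redo), L[redo])
    redo <- redo[p2[redo] >= L[redo]]
  }

  ## inter: uniform background across distinct chromosomes
  n_ie <- sum(inter)
  c1 <- sample(names(chroms), n_ie, replace = TRUE, prob = lens)
  c2 <- sample(names(chroms), n_ie, replace = TRUE, prob = lens)
  redo <- which(c1 == c2)
  while (length(redo)) {
    c2[redo] <- sample(names(chroms), length(redo), replace = TRUE, prob = lens)
    redo <- redo[c1[redo] == c2[redo]]
  }
  q1 <- floor(runif(n_ie, 0, lens[c1]))
  q2 <- floor(runif(n_ie, 0, lens[c2]))

  chrom <- c(chrom1, c1, chrom1, c2)
  pos <- c(p1, q1, p2, q2)
  lifted <- lift_to_draft(truth, chrom, pos)
  m <- n_in + n_ie
  res <- data.frame(seq1 = lifted$draft_id[seq_len(m)],
                    pos1 = lifted$dpos0[seq_len(m)],
                    seq2 = lifted$draft_id[m + seq_len(m)],
                    pos2 = lifted$dpos0[m + seq_len(m)],
                    mapq = ifelse(runif(m) < 0.1, sample(0:20, m, replace = TRUE), 60L),
                    dup = runif(m) < 0.02,
                    stringsAsFactors = FALSE)
  res[!is.na(res$seq1) & !is.na(res$seq2), , drop = FALSE]
}
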