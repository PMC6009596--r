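#' Hi-C processing parameters
#'
#' @param min_mapq records with mapq strictly greater are kept (default 20).
#' @param bin_size aggregation bin (bp, default 50 kb).
#' @param n_groups initial number of chromosome groups.
#' @param n_subgroups subgroups per group for hierarchical ordering.
#' @param heatmap_bin window for the log2 contact heatmap (bp).
#' @param pseudomolecule_gap N-gap between placed scaffolds (bp).
#' @return object of class `hic_params`.
#' @export
hic_params <- function(min_mapq = 20, bin_size = 50000, n_groups = 20,
                       n_subgroups = 5, heatmap_bin = 500000,
                       pseudomolecule_gap = 100) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (n_subgroups < 1) stop("n_subgroups must be >= 1")
  if (any(c(min_mapq, n_groups, heatmap_bin, pseudomolecule_gap) <= 0))
    stop("all parameters must be positive")
  structure(list(min_mapq = min_mapq, bin_size = bin_size,
                 n_groups = n_groups, n_subgroups = n_subgroups,
                 heatmap_bin = heatmap_bin,
                 pseudomolecule_gap = pseudomolecule_gap),
            class = "hic_params")
}

## keep uniquely-mapped, non-duplicate records
filter_contacts <- function(records, min_mapq = 20) {
  records[records$mapq > min_mapq & !records$dup, , drop = FALSE]
}

#' Bin Hi-C contacts and normalize intra-/inter-sequence submatrices
#'
#' Counts are aggregated per bin pair; each entry is then divided by the
#' product of its two bins' total coverage, computed separately over the
#' intra-sequence and inter-sequence submatrices, and each class is
#' rescaled so its nonzero entries have mean 1.
#'
#' @param records contact table (`seq1`, `pos1`, `seq2`, `pos2`, `mapq`,
#'   `dup`).
#' @param seq_lengths named vector of sequence lengths.
#' @param params a [hic_params()].
#' @return object of class `contact_matrix`: `bin_size`, `bins` (data.frame
#'   `seq`, `start0`), `mat` (normalized, symmetric), `raw` (counts),
#'   `raw_total` (links after filtering).
#' @export
bin_and_normalize <- function(records, seq_lengths, params = hic_params()) {
  if (params$bin_size <= 0) stop("bin_size must be > 0")
  rec <- filter_contacts(records, params$min_mapq)
  nb <- setNames(pmax(1L, as.integer(ceiling(seq_lengths / params$bin_size))),
                 names(seq_lengths))
  offs <- cumsum(c(0L, nb[-length(nb)]))
  names(offs) <- names(seq_lengths)
  bins <- data.frame(
    seq = rep(names(seq_lengths), nb),
    start0 = unlist(lapply(nb, function(n) (seq_len(n) - 1L)), use.names = FALSE) *
      params$bin_size)
  n <- nrow(bins)
  b1 <- offs[rec$seq1] + pmin(rec$pos1 %/% params$bin_size, nb[rec$seq1] - 1L) + 1L
  b2 <- offs[rec$seq2] + pmin(rec$pos2 %/% params$bin_size, nb[rec$seq2] - 1L) + 1L
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  U <- matrix(0, n, n)
  if (length(lo)) {
    tab <- table(factor(lo, levels = seq_len(n)), factor(hi, levels = seq_len(n)))
    U <- matrix(as.numeric(tab), n, n)
  }
  raw <- U + t(U)
  diag(raw) <- diag(U)                       # symmetric; diagonal kept once

  intra <- outer(bins$seq, bins$seq, "==")
  mat <- matrix(0, n, n)
  for (cls in c(TRUE, FALSE)) {
    mask <- intra == cls
    sub <- raw * mask
    cov <- rowSums(sub)
    denom <- outer(cov, cov)
    w <- ifelse(mask & raw > 0 & denom > 0, raw / denom, 0)
    nz <- w[mask & raw > 0]
    if (length(nz) && mean(nz) > 0) w <- w / mean(nz)
    mat <- mat + ifelse(mask, w, 0)
  }
  structure(list(bin_size = params$bin_size, bins = bins, mat = mat,
                 raw = raw, raw_total = length(lo)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix>", nrow(x$bins), "bins of", x$bin_size, "bp,",
      x$raw_total, "links\n")
  invisible(x)
}

#' Scaffold-level contact summary
#'
#' Length-normalized contact frequency between scaffold pairs:
#' `counts / (len_i * len_j)`, scaled by 1e9 for readability.
#'
#' @inheritParams bin_and_normalize
#' @param min_mapq mapq filter (strict).
#' @return list: `w` (symmetric frequency matrix), `counts` (raw link
#'   counts), `lengths`.
#' @export
scaffold_contact_summary <- function(records, seq_lengths, min_mapq = 20) {
  rec <- filter_contacts(records, min_mapq)
  ids <- names(seq_lengths)
  n <- length(ids)
  C <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(rec)) {
    i <- match(rec$seq1, ids); j <- match(rec$seq2, ids)
    lo <- pmin(i, j); hi <- pmax(i, j)
    tab <- table(factor(lo, levels = seq_len(n)), factor(hi, levels = seq_len(n)))
    U <- matrix(as.numeric(tab), n, n)
    C <- U + t(U); diag(C) <- diag(U)
    dimnames(C) <- list(ids, ids)
  }
  W <- 1e9 * C / outer(as.numeric(seq_lengths), as.numeric(seq_lengths))
  dimnames(W) <- list(ids, ids)
  list(w = W, counts = C, lengths = seq_lengths)
}

#' Cluster scaffolds into chromosome groups by contact frequency
#'
#' Average-linkage agglomerative clustering on inter-scaffold contact
#' frequency, cut at `n_groups`.
#'
#' @param summary result of [scaffold_contact_summary()].
#' @param n_groups number of groups.
#' @return named integer vector of group ids (1..n_groups, numbered by
#'   first appearance).
#' @export
cluster_groups <- function(summary, n_groups) {
  W <- summary$w
  n <- nrow(W)
  if (n_groups > n) stop("n_groups exceeds scaffold count")
  S <- W; diag(S) <- 0
  D <- max(S) - S
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = "average")
  grp <- cutree(hc, k = n_groups)
  ## renumber by first appearance for label stability
  first <- !duplicated(grp)
  relabel <- setNames(seq_len(n_groups), grp[first])
  out <- relabel[as.character(grp)]
  names(out) <- rownames(W)
  out
}

## greedy path chaining on a symmetric weight matrix; returns index order
greedy_chain <- function(W) {
  n <- nrow(W)
  if (n == 1) return(1L)
  diag(W) <- -Inf
  start <- which(W == max(W), arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  path <- c(start[1], start[2])
  used <- logical(n); used[path] <- TRUE
  while (!all(used)) {
    free <- which(!used)
    wl <- W[path[1], free]; wr <- W[path[length(path)], free]
    if (max(wl) >= max(wr)) {
      pick <- free[which.max(wl)]
      path <- c(pick, path)
    } else {
      pick <- free[which.max(wr)]
      path <- c(path, pick)
    }
    used[pick] <- TRUE
  }
  as.integer(path)
}

#' Order and orient the scaffolds of one chromosome group
#'
#' Hierarchical procedure: (1) the group is subclustered into
#' `min(n_subgroups, size)` subgroups; (2) each subgroup is ordered by
#' greedy chaining that maximizes adjacent contact frequency; (3) each
#' ordered subgroup is collapsed to a super-bin, the super-bin contact
#' matrix is rebuilt and the super-bins are chained the same way, flipping
#' each subgroup so its best-connected scaffold faces its neighbor;
#' (4) every scaffold is oriented by the contact-weighted position gradient
#' toward its neighbors. The result is defined up to global reversal; the
#' reported direction starts at the lexicographically smaller terminal
#' scaffold.
#'
#' @param summary result of [scaffold_contact_summary()] (whole assembly).
#' @param records contact table (for the orientation gradient).
#' @param members character vector: scaffolds of the group.
#' @param n_subgroups number of subgroups (default 5).
#' @param min_mapq mapq filter for the gradient.
#' @return data.frame: `contig`, `orientation`, in chromosome order.
#' @export
order_and_orient <- function(summary, records, members, n_subgroups = 5,
                             min_mapq = 20) {
  stopifnot(length(members) >= 1)
  if (length(members) == 1)
    return(data.frame(contig = members, orientation = "+",
                      stringsAsFactors = FALSE))
  W <- summary$w[members, members, drop = FALSE]
  C <- summary$counts[members, members, drop = FALSE]
  lens <- summary$lengths[members]
  k <- min(n_subgroups, length(members))

  sub_id <- if (k == length(members)) seq_along(members) else {
    S <- W; diag(S) <- 0
    D <- max(S) - S; diag(D) <- 0
    cutree(hclust(as.dist(D), method = "average"), k = k)
  }
  subgroups <- split(seq_along(members), sub_id)

  ## order scaffolds within each subgroup
  subgroups <- lapply(subgroups, function(idx) {
    if (length(idx) == 1) idx else idx[greedy_chain(W[idx, idx, drop = FALSE])]
  })

  ## super-bin matrix: length-normalized total contact between subgroups
  m <- length(subgroups)
  if (m > 1) {
    SW <- matrix(0, m, m)
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      ia <- subgroups[[a]]; ib <- subgroups[[b]]
      SW[a, b] <- SW[b, a] <- 1e9 * sum(C[ia, ib]) /
        (sum(as.numeric(lens[ia])) * sum(as.numeric(lens[ib])))
    }
    sorder <- greedy_chain(SW)
    subgroups <- subgroups[sorder]
    ## flip each subgroup so its best-connected scaffold faces the neighbor
    for (a in seq_len(m)) {
      idx <- subgroups[[a]]
      if (length(idx) == 1) next
      nb <- if (a < m) subgroups[[a + 1]] else subgroups[[a - 1]]
      w_first <- sum(W[idx[1], nb]); w_last <- sum(W[idx[length(idx)], nb])
      facing_last <- a < m     # neighbor sits after this subgroup
      if ((facing_last && w_first > w_last) ||
          (!facing_last && w_last > w_first))
        subgroups[[a]] <- rev(idx)
    }
  }
  order_idx <- unlist(subgroups, use.names = FALSE)
  ordered <- members[order_idx]

  ## orientation from the contact-weighted position gradient
  rec <- filter_contacts(records, min_mapq)
  rec <- rec[rec$seq1 %in% members & rec$seq2 %in% members, , drop = FALSE]
  ends <- data.frame(s = c(rec$seq1, rec$seq2), pos = c(rec$pos1, rec$pos2),
                     other = c(rec$seq2, rec$seq1), stringsAsFactors = FALSE)
  rank_of <- setNames(seq_along(ordered), ordered)
  orientation <- character(length(ordered))
  for (i in seq_along(ordered)) {
    s <- ordered[i]
    e <- ends[ends$s == s & ends$other != s, , drop = FALSE]
    side <- sign(rank_of[e$other] - i)
    mean_left <- if (any(side < 0)) mean(e$pos[side < 0]) else NA
    mean_right <- if (any(side > 0)) mean(e$pos[side > 0]) else NA
    L <- lens[[s]]
    orientation[i] <- if (!is.na(mean_left) && !is.na(mean_right)) {
      if (mean_left <= mean_right) "+" else "-"
    } else if (!is.na(mean_right)) {
      if (mean_right > L / 2) "+" else "-"
    } else if (!is.na(mean_left)) {
      if (mean_left < L / 2) "+" else "-"
    } else "+"
  }

  ## canonical global direction
  if (ordered[length(ordered)] < ordered[1]) {
    ordered <- rev(ordered)
    orientation <- rev(ifelse(orientation == "+", "-", "+"))
  }
  data.frame(contig = ordered, orientation = orientation,
             stringsAsFactors = FALSE)
}

#' Build pseudomolecule sequences from grouped, ordered scaffolds
#'
#' @param assembly named character vector of scaffold sequences.
#' @param grouping named list of data.frames (`contig`, `orientation`), one
#'   per pseudomolecule, in order; names become chromosome names.
#' @param params a [hic_params()] (for the inter-scaffold gap).
#' @return list: `chromosomes` (named character), `agp` (AGP v2.1 table,
#'   evidence `proximity_ligation`), `unplaced` (scaffold ids).
#' @export
build_pseudomolecules <- function(assembly, grouping, params = hic_params()) {
  placed <- unlist(lapply(grouping, `[[`, "contig"), use.names = FALSE)
  if (anyDuplicated(placed)) stop("duplicate scaffold placement")
  if (!all(placed %in% names(assembly))) stop("unknown scaffold in grouping")
  layout <- do.call(rbind, lapply(names(grouping), function(chr) {
    g <- grouping[[chr]]
    data.frame(object = chr, component = g$contig,
               orientation = g$orientation,
               gap_after = c(rep(params$pseudomolecule_gap, nrow(g) - 1), NA),
               stringsAsFactors = FALSE)
  }))
  lens <- nchar(assembly)
  agp <- agp_from_layout(layout, lens, gap_type = "scaffold",
                         evidence = "proximity_ligation")
  chroms <- reconstruct_from_agp(agp, assembly)
  list(chromosomes = chroms, agp = agp,
       unplaced = setdiff(names(assembly), placed))
}

#' Genome-wide log2 contact heatmap over pseudomolecule windows
#'
#' Records are lifted from scaffold to pseudomolecule coordinates via the
#' AGP, counted in nonoverlapping `heatmap_bin` windows, and reported as
#' log2(link count); empty bin pairs are NA.
#'
#' @param records contact table.
#' @param agp placement table from [build_pseudomolecules()].
#' @param heatmap_bin window size (bp).
#' @param min_mapq mapq filter (strict).
#' @return symmetric matrix of log2 link counts with a `bins` attribute.
#' @export
heatmap_matrix <- function(records, agp, heatmap_bin = 500000, min_mapq = 20) {
  rec <- filter_contacts(records, min_mapq)
  comp <- agp[agp$component_type == "W", , drop = FALSE]
  lift <- function(seqs, pos) {
    i <- match(seqs, comp$component_id)
    obj <- comp$object[i]
    len <- comp$component_end[i]
    gpos <- ifelse(comp$orientation[i] == "-",
                   comp$object_beg[i] - 1 + (len - 1 - pos),
                   comp$object_beg[i] - 1 + pos)
    data.frame(obj = obj, gpos = gpos, stringsAsFactors = FALSE)
  }
  e1 <- lift(rec$seq1, rec$pos1)
  e2 <- lift(rec$seq2, rec$pos2)
  ok <- !is.na(e1$obj) & !is.na(e2$obj)
  e1 <- e1[ok, ]; e2 <- e2[ok, ]

  obj_len <- tapply(agp$object_end, agp$object, max)
  objs <- sort(names(obj_len))
  nb <- setNames(as.integer(ceiling(obj_len[objs] / heatmap_bin)), objs)
  offs <- cumsum(c(0L, nb[-length(nb)]))
  names(offs) <- objs
  n <- sum(nb)
  b1 <- offs[e1$obj] + pmin(e1$gpos %/% heatmap_bin, nb[e1$obj] - 1L) + 1L
  b2 <- offs[e2$obj] + pmin(e2$gpos %/% heatmap_bin, nb[e2$obj] - 1L) + 1L
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  U <- matrix(0, n, n)
  if (length(lo)) {
    tab <- table(factor(lo, levels = seq_len(n)), factor(hi, levels = seq_len(n)))
    U <- matrix(as.numeric(tab), n, n)
  }
  counts <- U + t(U); diag(counts) <- diag(U)
  out <- ifelse(counts >= 1, log2(counts), NA)
  attr(out, "bins") <- data.frame(
    obj = rep(objs, nb),
    start0 = unlist(lapply(nb, function(k) (seq_len(k) - 1L)), use.names = FALSE) *
      heatmap_bin)
  out
}
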