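#' Decision thresholds for conflict curation
#'
#' Defaults follow the standard hybrid-scaffolding curation rules: a
#' conflict junction is a chimera candidate when its chimeric score is
#' >= 30% and more than two fully aligned molecules span it; a candidate is
#' broken when the mate-pair relationship of its 10-kb flanks is in
#' disagreement or fewer than 5 long reads fully span the region.
#'
#' @param flank half-window (bp) for the chimeric score (default 50 kb).
#' @param min_chimeric_score candidate threshold on the score (%).
#' @param min_spanning_molecules candidacy requires strictly more than this
#'   many fully aligned molecules spanning the junction.
#' @param mp_flank half-window (bp) for mate-pair and long-read evidence.
#' @param min_longread_span_coverage spanning long reads below this count
#'   confirm a break.
#' @param mp_min_concordant concordant bridging pairs needed to call the
#'   mate-pair relationship in agreement.
#' @param mp_k_sd insert-size tolerance in library SDs.
#' @param clip_cluster_tolerance soft-clip clustering tolerance (bp).
#' @param clip_min_reads minimum reads per clip cluster.
#' @param clip_search radius (bp) around the coarse junction searched for a
#'   clip cluster; the junction coordinate from map alignment is only
#'   label-interval accurate, so this exceeds `mp_flank`.
#' @return object of class `curation_thresholds`.
#' @export
curation_thresholds <- function(flank = 50000, min_chimeric_score = 30,
                                min_spanning_molecules = 2,
                                mp_flank = 10000,
                                min_longread_span_coverage = 5,
                                mp_min_concordant = 3, mp_k_sd = 5,
                                clip_cluster_tolerance = 100,
                                clip_min_reads = 3, clip_search = 25000) {
  vals <- c(flank, min_chimeric_score, min_spanning_molecules, mp_flank,
            min_longread_span_coverage, mp_min_concordant, mp_k_sd,
            clip_cluster_tolerance, clip_min_reads, clip_search)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  structure(list(flank = flank, min_chimeric_score = min_chimeric_score,
                 min_spanning_molecules = min_spanning_molecules,
                 mp_flank = mp_flank,
                 min_longread_span_coverage = min_longread_span_coverage,
                 mp_min_concordant = mp_min_concordant, mp_k_sd = mp_k_sd,
                 clip_cluster_tolerance = clip_cluster_tolerance,
                 clip_min_reads = clip_min_reads, clip_search = clip_search),
            class = "curation_thresholds")
}

#' Detect sequence-vs-optical-map conflicts
#'
#' A conflict is emitted where a sequence map's best explanation requires
#' two disjoint optical-map placements (split alignment), or where its best
#' alignment contains a run of >= 3 consecutive label intervals each
#' exceeding the sizing tolerance. The junction coordinate is the midpoint
#' between the two placements' inner matched labels (split) or the center
#' of the discordant run.
#'
#' @param seq_maps list of [nick_map()]s from [digest_sequence()] on the
#'   draft sequences.
#' @param optical_maps list of reference [nick_map()]s.
#' @param params an [align_params()].
#' @return data.frame of conflicts: `sequence_id`, `sequence_coordinate`,
#'   `map_id`, `map_coordinate`, `conflict_kind`; primary placements are
#'   attached as attribute `"placements"`.
#' @export
detect_conflicts <- function(seq_maps, optical_maps, params = align_params()) {
  conflicts <- list()
  placements <- list()
  for (q in seq_maps) {
    nq <- length(q$labels)
    if (nq < 2) next
    a <- NULL
    for (r in optical_maps) {
      cand <- align_maps(q, r, params)
      if (!is.null(cand) && (is.null(a) || cand$score > a$score)) a <- cand
    }
    if (!is.null(a)) placements[[q$map_id]] <- a
    single_score <- if (is.null(a)) -Inf else a$score

    ## split scan: does a two-placement explanation beat the single one?
    ## each side runs with a reduced floor (a short side still has to place
    ## its intervals within tolerance somewhere)
    sec_params <- params
    sec_params$min_score <- min(params$min_score, 2)
    best_align_of <- function(sub) {
      b <- NULL
      for (r in optical_maps) {
        cand <- align_maps(sub, r, sec_params)
        if (!is.null(cand) && (is.null(b) || cand$score > b$score)) b <- cand
      }
      b
    }
    best_split <- NULL
    if (nq >= 4) for (t in 2:(nq - 2)) {
      pa <- best_align_of(nick_map(paste0(q$map_id, ".L"), q$length,
                                   q$labels[seq_len(t)]))
      if (is.null(pa)) next
      pb <- best_align_of(nick_map(paste0(q$map_id, ".R"), q$length,
                                   q$labels[(t + 1):nq]))
      if (is.null(pb)) next
      tot <- pa$score + pb$score
      if (is.null(best_split) || tot > best_split$tot)
        best_split <- list(t = t, tot = tot, pa = pa, pb = pb)
    }
    if (!is.null(best_split) &&
        best_split$tot > single_score + params$match_bonus / 2) {
      pa <- best_split$pa; pb <- best_split$pb; t <- best_split$t
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        sequence_id = q$map_id,
        sequence_coordinate = (q$labels[t] + q$labels[t + 1]) / 2,
        map_id = pa$ref_id,
        map_coordinate = pa$matched_ref_pos[which.max(pa$matched_query_pos)],
        map_id2 = pb$ref_id,
        map_coordinate2 = pb$matched_ref_pos[which.min(pb$matched_query_pos)],
        conflict_kind = "split_alignment", stringsAsFactors = FALSE)
    }
    if (is.null(a)) next

    ## sizing discordance: >= 3 consecutive intervals beyond tolerance
    if (a$n_matched >= 4) {
      dr <- abs(diff(a$matched_ref_pos))
      tol <- pmax(params$tol_bp, params$tol_rel * dr)
      bad <- abs(a$residuals) > tol
      r <- rle(bad)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      hit <- which(r$values & r$lengths >= 3)
      for (h in hit) {
        qpos <- sort(a$matched_query_pos)
        lo <- qpos[starts[h]]; hi <- qpos[min(ends[h] + 1, a$n_matched)]
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          sequence_id = q$map_id, sequence_coordinate = (lo + hi) / 2,
          map_id = a$ref_id,
          map_coordinate = a$matched_ref_pos[starts[h]],
          map_id2 = NA_character_, map_coordinate2 = NA_real_,
          conflict_kind = "sizing_discordance", stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(sequence_id = character(0), sequence_coordinate = numeric(0),
               map_id = character(0), map_coordinate = numeric(0),
               map_id2 = character(0), map_coordinate2 = numeric(0),
               conflict_kind = character(0))
  rownames(out) <- NULL
  attr(out, "placements") <- placements
  out
}

#' Chimeric score of a conflict junction
#'
#' The percentage of molecules overlapping the junction window that fully
#' align across it. With zero overlapping molecules the score is 0 and the
#' no-evidence flag is set (absence of optical evidence never triggers a
#' break).
#'
#' @param support data.frame from [classify_flank_support()].
#' @return list: `score` (%), `n_overlapping`, `n_fully`,
#'   `n_spanning_fully` (fully aligned AND spanning), `no_evidence`.
#' @export
chimeric_score <- function(support) {
  n <- nrow(support)
  if (n == 0)
    return(list(score = 0, n_overlapping = 0L, n_fully = 0L,
                n_spanning_fully = 0L, no_evidence = TRUE))
  nf <- sum(support$fully_aligned)
  list(score = 100 * nf / n, n_overlapping = n, n_fully = nf,
       n_spanning_fully = sum(support$fully_aligned & support$spans_junction),
       no_evidence = FALSE)
}

## concordant innie bridging pairs across `junction` on `sequence_id`:
## one unique mate in each mp_flank window, forward mate leftmost, implied
## insert within mean +/- k_sd * sd of the pair's library
count_bridging_pairs <- function(mp_records, sequence_id, junction,
                                 libraries, mp_flank = 10000, k_sd = 5,
                                 read_len = 100) {
  mp <- mp_records[mp_records$contig == sequence_id & mp_records$unique, ,
                   drop = FALSE]
  if (!nrow(mp)) return(0L)
  mp <- mp[order(mp$read_id, mp$mate), ]
  cnt <- table(mp$read_id)
  keep <- names(cnt)[cnt == 2]            # both mates on this sequence
  mp <- mp[mp$read_id %in% keep, ]
  if (!nrow(mp)) return(0L)
  lib_by <- setNames(libraries, vapply(libraries, `[[`, "", "name"))
  m1 <- mp[mp$mate == 1L, ]; m2 <- mp[mp$mate == 2L, ]
  left_pos <- pmin(m1$pos0, m2$pos0)
  right_pos <- pmax(m1$pos0, m2$pos0)
  left_strand <- ifelse(m1$pos0 <= m2$pos0, m1$strand, m2$strand)
  right_strand <- ifelse(m1$pos0 <= m2$pos0, m2$strand, m1$strand)
  innie <- left_strand == "+" & right_strand == "-"
  insert <- right_pos + read_len - left_pos
  mu <- vapply(m1$library, function(l) lib_by[[l]]$insert_mean, numeric(1))
  sd <- vapply(m1$library, function(l) lib_by[[l]]$insert_sd, numeric(1))
  size_ok <- insert >= mu - k_sd * sd & insert <= mu + k_sd * sd
  bridges <- left_pos >= junction - mp_flank & left_pos < junction &
    right_pos >= junction & right_pos <= junction + mp_flank
  sum(innie & size_ok & bridges)
}

## long reads fully spanning `junction` with >= margin bp aligned both sides
count_spanning_reads <- function(longread_records, sequence_id, junction,
                                 margin = 1000) {
  lr <- longread_records[longread_records$contig == sequence_id, ,
                         drop = FALSE]
  sum(lr$start0 <= junction - margin & lr$end0 >= junction + margin)
}

#' Evaluate a conflict junction against all evidence
#'
#' A junction is a chimera candidate iff its chimeric score passes
#' `min_chimeric_score` and more than `min_spanning_molecules` fully
#' aligned molecules span it. A candidate is broken iff the mate-pair
#' relationship of the `mp_flank` windows is in disagreement (fewer than
#' `mp_min_concordant` concordant bridging pairs) or fewer than
#' `min_longread_span_coverage` long reads fully span the junction.
#'
#' @param junction one-row data.frame (or list) with `sequence_id`,
#'   `sequence_coordinate`, `map_id`, `map_coordinate`.
#' @param score_info result of [chimeric_score()].
#' @param mp_records mate-pair record table (see [simulate_mate_pairs()]).
#' @param longread_records long-read record table (see
#'   [simulate_long_read_clips()]).
#' @param libraries list of mate-pair library descriptions.
#' @param thresholds a [curation_thresholds()].
#' @return one-row data.frame of class `curation_decision`.
#' @export
evaluate_junction <- function(junction, score_info, mp_records,
                              longread_records, libraries,
                              thresholds = curation_thresholds()) {
  stopifnot(inherits(thresholds, "curation_thresholds"))
  j <- junction$sequence_coordinate
  candidate <- score_info$score >= thresholds$min_chimeric_score &&
    score_info$n_spanning_fully > thresholds$min_spanning_molecules
  n_bridge <- count_bridging_pairs(mp_records, junction$sequence_id, j,
                                   libraries, thresholds$mp_flank,
                                   thresholds$mp_k_sd)
  mp_concordant <- n_bridge >= thresholds$mp_min_concordant
  span_cov <- count_spanning_reads(longread_records, junction$sequence_id, j)

  if (!candidate) {
    action <- "keep"
    rationale <- if (score_info$score < thresholds$min_chimeric_score)
      "not_candidate_score" else "not_candidate_spanning"
  } else if (!mp_concordant && span_cov < thresholds$min_longread_span_coverage) {
    action <- "break"; rationale <- "mp_discordant+low_span_cov"
  } else if (!mp_concordant) {
    action <- "break"; rationale <- "mp_discordant"
  } else if (span_cov < thresholds$min_longread_span_coverage) {
    action <- "break"; rationale <- "low_span_cov"
  } else {
    action <- "keep"; rationale <- "confirmed_by_mp_and_longreads"
  }
  out <- data.frame(sequence_id = junction$sequence_id,
                    sequence_coordinate = j,
                    map_id = junction$map_id,
                    map_coordinate = junction$map_coordinate,
                    chimeric_score = score_info$score,
                    spanning_fully_aligned_molecules = score_info$n_spanning_fully,
                    mp_concordant = mp_concordant,
                    longread_span_coverage = span_cov,
                    action = action, breakpoint = NA_real_,
                    rationale_code = rationale, stringsAsFactors = FALSE)
  class(out) <- c("curation_decision", class(out))
  out
}

#' Locate a breakpoint from clustered soft-clip sites
#'
#' Clip boundaries on the junction's sequence are clustered by
#' single-linkage within `clip_cluster_tolerance`; if a cluster of at least
#' `clip_min_reads` boundaries lies within `clip_search` of the junction,
#' the breakpoint is the median boundary of the largest such cluster (ties
#' go to the cluster nearest the junction). Otherwise the junction
#' coordinate itself is the fallback.
#'
#' @inheritParams evaluate_junction
#' @return breakpoint coordinate (bp, integer).
#' @export
locate_breakpoint <- function(junction, longread_records,
                              thresholds = curation_thresholds()) {
  j <- junction$sequence_coordinate
  lr <- longread_records[longread_records$contig == junction$sequence_id, ,
                         drop = FALSE]
  bounds <- sort(c(lr$end0[lr$clip_right > 0], lr$start0[lr$clip_left > 0]))
  if (length(bounds)) {
    grp <- cumsum(c(1, diff(bounds) > thresholds$clip_cluster_tolerance))
    meds <- tapply(bounds, grp, median)
    sizes <- tapply(bounds, grp, length)
    ok <- sizes >= thresholds$clip_min_reads & abs(meds - j) <= thresholds$clip_search
    if (any(ok)) {
      meds <- meds[ok]; sizes <- sizes[ok]
      o <- order(-sizes, abs(meds - j))
      return(as.integer(round(meds[o[1]])))
    }
  }
  as.integer(round(j))
}

#' Break curated sequences at decided breakpoints
#'
#' @param draft named character vector of sequences.
#' @param decisions data.frame of curation decisions (rows with
#'   `action == "break"` and a `breakpoint` are applied; several breaks per
#'   sequence are allowed).
#' @return list with `assembly` (named character vector; broken sequences
#'   replaced by `{id}.1`, `{id}.2`, ... left to right) and `log`
#'   (data.frame: old id, new ids, coordinates, rationale).
#' @export
apply_breaks <- function(draft, decisions) {
  log <- data.frame(sequence_id = character(0), new_ids = character(0),
                    breakpoint = numeric(0), rationale_code = character(0),
                    stringsAsFactors = FALSE)
  if (is.null(decisions) || !nrow(decisions))
    return(list(assembly = draft, log = log))
  br <- decisions[decisions$action == "break", , drop = FALSE]
  if (!nrow(br)) return(list(assembly = draft, log = log))
  out <- draft
  for (id in unique(br$sequence_id)) {
    L <- nchar(draft[[id]])
    bps <- sort(unique(br$breakpoint[br$sequence_id == id]))
    if (any(bps <= 0 | bps >= L))
      stop("breakpoint at sequence boundary: ", id)
    starts <- c(0, bps); ends <- c(bps, L)
    pieces <- substring(draft[[id]], starts + 1, ends)
    new_ids <- sprintf("%s.%d", id, seq_along(pieces))
    out <- out[names(out) != id]
    out[new_ids] <- pieces
    log <- rbind(log, data.frame(
      sequence_id = id, new_ids = paste(new_ids, collapse = ","),
      breakpoint = bps,
      rationale_code = br$rationale_code[br$sequence_id == id][seq_along(bps)],
      stringsAsFactors = FALSE))
  }
  list(assembly = out, log = log)
}

#' Run the full conflict-curation pipeline
#'
#' Digests the draft, aligns draft maps and molecules to the optical maps,
#' detects conflicts, scores and evaluates each junction, locates
#' breakpoints at consistent soft-clip sites, and breaks the sequences.
#'
#' @param draft named character vector of draft sequences.
#' @param optical_maps list of reference [nick_map()]s.
#' @param molecules list of [optical_molecule()]s.
#' @param mp_records,longread_records evidence tables.
#' @param libraries mate-pair library list.
#' @param motif nickase recognition sequence.
#' @param params an [align_params()].
#' @param thresholds a [curation_thresholds()].
#' @param mol_filter a [molecule_filter()].
#' @return list: `assembly` (curated sequences), `decisions`, `conflicts`,
#'   `log`.
#' @export
curate_assembly <- function(draft, optical_maps, molecules, mp_records,
                            longread_records, libraries,
                            motif = "GCTCTTC",
                            params = align_params(),
                            thresholds = curation_thresholds(),
                            mol_filter = molecule_filter()) {
  mols <- filter_molecules(molecules, mol_filter)
  seq_maps <- lapply(names(draft), function(id)
    digest_sequence(draft[[id]], motif, map_id = id))
  mol_aligns <- align_molecules(mols, optical_maps, params)
  conflicts <- detect_conflicts(seq_maps, optical_maps, params)

  decisions <- list()
  if (nrow(conflicts)) for (i in seq_len(nrow(conflicts))) {
    jct <- conflicts[i, ]
    ## refine the junction at the consistent soft-clip site first, so the
    ## mate-pair and spanning-read evidence is read at the true breakpoint
    ## (with no clip cluster nearby the coarse coordinate is kept)
    jct$sequence_coordinate <- locate_breakpoint(jct, longread_records,
                                                 thresholds)
    ## a chimera abutting the optical map's edge cannot be spanned there;
    ## the secondary placement's boundary carries the same evidence
    support <- classify_flank_support(mol_aligns, jct$map_id,
                                      jct$map_coordinate, thresholds$flank)
    sc <- chimeric_score(support)
    if (!is.na(jct$map_id2)) {
      support2 <- classify_flank_support(mol_aligns, jct$map_id2,
                                         jct$map_coordinate2, thresholds$flank)
      sc2 <- chimeric_score(support2)
      if (sc2$n_spanning_fully > sc$n_spanning_fully) sc <- sc2
    }
    dec <- evaluate_junction(jct, sc, mp_records, longread_records,
                             libraries, thresholds)
    if (dec$action == "break")
      dec$breakpoint <- jct$sequence_coordinate
    decisions[[i]] <- dec
  }
  decisions <- if (length(decisions)) do.call(rbind, decisions) else
    data.frame()
  broken <- apply_breaks(draft, decisions)
  list(assembly = broken$assembly, decisions = decisions,
       conflicts = conflicts, log = broken$log)
}
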