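mk_score <- function(score, spanning, n = 10)
  list(score = score, n_overlapping = n, n_fully = round(score * n / 100),
       n_spanning_fully = spanning, no_evidence = n == 0)

mk_junction <- function(seq_id = "ctg1", coord = 50000)
  data.frame(sequence_id = seq_id, sequence_coordinate = coord,
             map_id = "map1", map_coordinate = coord,
             stringsAsFactors = FALSE)

lib1 <- list(list(name = "mp3k", insert_mean = 3000, insert_sd = 300,
                  n_pairs = 0L))

## n concordant innie bridging pairs across `coord` on `seq_id`
mk_bridging_mp <- function(n, coord = 50000, seq_id = "ctg1") {
  if (n == 0)
    return(data.frame(read_id = character(0), mate = integer(0),
                      contig = character(0), pos0 = integer(0),
                      strand = character(0), mapq = integer(0),
                      unique = logical(0), library = character(0)))
  data.frame(read_id = rep(sprintf("p%03d", seq_len(n)), each = 2),
             mate = rep(c(1L, 2L), n),
             contig = seq_id,
             pos0 = as.vector(rbind(coord - 1500, coord + 1400)),
             strand = rep(c("+", "-"), n),
             mapq = 60L, unique = TRUE, library = "mp3k",
             stringsAsFactors = FALSE)
}

## n long reads spanning coord with >= 1 kb on each side
mk_spanning_lr <- function(n, coord = 50000, seq_id = "ctg1") {
  if (n == 0)
    return(data.frame(read_id = character(0), contig = character(0),
                      start0 = integer(0), end0 = integer(0),
                      clip_left = integer(0), clip_right = integer(0)))
  data.frame(read_id = sprintf("r%03d", seq_len(n)), contig = seq_id,
             start0 = coord - 8000, end0 = coord + 8000,
             clip_left = 0L, clip_right = 0L, stringsAsFactors = FALSE)
}

test_that("chimeric score follows its percentage definition", {
  sup <- data.frame(query_id = sprintf("m%d", 1:10),
                    fully_aligned = c(rep(TRUE, 3), rep(FALSE, 7)),
                    spans_junction = TRUE,
                    category = "x", stringsAsFactors = FALSE)
  sc <- chimeric_score(sup)
  expect_equal(sc$score, 30.0)
  expect_false(sc$no_evidence)

  sup_all <- transform(sup, fully_aligned = TRUE)
  expect_equal(chimeric_score(sup_all)$score, 100.0)

  sc0 <- chimeric_score(sup[0, ])
  expect_equal(sc0$score, 0.0)
  expect_true(sc0$no_evidence)
})

test_that("junction evaluation follows the candidate and confirmation clauses", {
  jct <- mk_junction()
  ## score 30, 3 spanning molecules, discordant MP -> break
  d <- evaluate_junction(jct, mk_score(30, 3), mk_bridging_mp(0),
                         mk_spanning_lr(10), lib1)
  expect_equal(d$action, "break")
  expect_match(d$rationale_code, "mp_discordant")

  ## score below 30 -> never a candidate
  d2 <- evaluate_junction(jct, mk_score(29.9, 10), mk_bridging_mp(0),
                          mk_spanning_lr(0), lib1)
  expect_equal(d2$action, "keep")

  ## spanning molecules must exceed two
  d3 <- evaluate_junction(jct, mk_score(100, 2), mk_bridging_mp(0),
                          mk_spanning_lr(0), lib1)
  expect_equal(d3$action, "keep")

  ## concordant MP and span coverage exactly 5 -> keep ("<5" is strict)
  d4 <- evaluate_junction(jct, mk_score(100, 10), mk_bridging_mp(3),
                          mk_spanning_lr(5), lib1)
  expect_equal(d4$action, "keep")

  ## concordant MP but only 4 spanning reads -> break
  d5 <- evaluate_junction(jct, mk_score(100, 10), mk_bridging_mp(3),
                          mk_spanning_lr(4), lib1)
  expect_equal(d5$action, "break")
  expect_equal(d5$rationale_code, "low_span_cov")
})

test_that("evidence acts monotonically on the keep/break decision", {
  jct <- mk_junction()
  for (score in c(10, 30, 80)) for (span_mol in c(0, 3, 8)) {
    prev_break <- NULL
    for (cov in c(0, 3, 5, 12)) {
      d <- evaluate_junction(jct, mk_score(score, span_mol), mk_bridging_mp(3),
                             mk_spanning_lr(cov), lib1)
      is_break <- d$action == "break"
      ## increasing long-read coverage never flips keep -> break
      if (!is.null(prev_break) && !prev_break) expect_false(is_break)
      prev_break <- is_break
    }
  }
  ## decreasing chimeric score never flips keep -> break
  for (span_mol in c(0, 3, 8)) {
    high <- evaluate_junction(jct, mk_score(90, span_mol), mk_bridging_mp(0),
                              mk_spanning_lr(0), lib1)
    low <- evaluate_junction(jct, mk_score(20, span_mol), mk_bridging_mp(0),
                             mk_spanning_lr(0), lib1)
    if (high$action == "keep") expect_equal(low$action, "keep")
  }
})

test_that("breakpoints come from the dominant nearby clip cluster", {
  jct <- mk_junction("ctg1", 1251000)
  thr <- curation_thresholds(clip_cluster_tolerance = 200)
  ## 6 reads clipped at 1,250,000 +/- 50 -> median
  offs <- c(-50, -30, -10, 10, 30, 50)
  lr <- data.frame(read_id = sprintf("r%d", 1:6), contig = "ctg1",
                   start0 = 1200000, end0 = 1250000 + offs,
                   clip_left = 0L, clip_right = 500L, stringsAsFactors = FALSE)
  expect_equal(locate_breakpoint(jct, lr, thr), 1250000)

  ## two clusters (5 and 3 reads): the larger wins
  lr2 <- rbind(lr[1:5, ],
               data.frame(read_id = sprintf("s%d", 1:3), contig = "ctg1",
                          start0 = 1252000 + c(-20, 0, 20), end0 = 1290000,
                          clip_left = 400L, clip_right = 0L))
  expect_equal(locate_breakpoint(jct, lr2, thr), median(1250000 + offs[1:5]))

  ## no clips near the junction -> fallback to the junction coordinate
  far <- transform(lr, end0 = end0 + 500000)
  expect_equal(locate_breakpoint(jct, far, thr), 1251000)
})

test_that("apply_breaks conserves bases and names fragments left to right", {
  draft <- c(ctg1 = strrep("ACGT", 250))  # 1000 bp
  dec <- data.frame(sequence_id = "ctg1", action = "break", breakpoint = 400,
                    rationale_code = "test", stringsAsFactors = FALSE)
  out <- apply_breaks(draft, dec)
  expect_setequal(names(out$assembly), c("ctg1.1", "ctg1.2"))
  expect_equal(nchar(out$assembly[["ctg1.1"]]), 400)
  expect_equal(nchar(out$assembly[["ctg1.2"]]), 600)
  expect_equal(paste0(out$assembly[["ctg1.1"]], out$assembly[["ctg1.2"]]),
               draft[["ctg1"]])

  ## multiple breaks in one sequence
  dec2 <- rbind(dec, transform(dec, breakpoint = 700))
  out2 <- apply_breaks(draft, dec2)
  expect_equal(unname(nchar(out2$assembly[c("ctg1.1", "ctg1.2", "ctg1.3")])),
               c(400, 300, 300))

  ## no decisions: identity with empty log
  out3 <- apply_breaks(draft, dec[0, ])
  expect_identical(out3$assembly, draft)
  expect_equal(nrow(out3$log), 0)

  ## boundary breakpoints rejected
  expect_error(apply_breaks(draft, transform(dec, breakpoint = 0)), "boundary")
  expect_error(apply_breaks(draft, transform(dec, breakpoint = 1000)), "boundary")
})

test_that("a clean sequence raises no conflict; a planted split is found", {
  d <- sim_dataset(9)
  truth <- d$truth
  omaps <- truth_maps(truth)
  ## a chimera-free contig equal to one truth interval: no conflict
  normal <- setdiff(names(truth$draft), truth$chimeras$draft_id)
  seq_maps <- lapply(normal[1:5], function(id)
    digest_sequence(truth$draft[[id]], map_id = id))
  conf <- detect_conflicts(seq_maps, omaps)
  expect_equal(nrow(conf), 0)

  ## chimeric contigs: conflicts near the planted junctions
  chim_maps <- lapply(truth$chimeras$draft_id, function(id)
    digest_sequence(truth$draft[[id]], map_id = id))
  conf2 <- detect_conflicts(chim_maps, omaps)
  expect_gt(nrow(conf2), 0)
  for (i in seq_len(nrow(conf2))) {
    j <- truth$chimeras$junction[truth$chimeras$draft_id == conf2$sequence_id[i]]
    expect_lt(abs(conf2$sequence_coordinate[i] - j), 15000)
  }
})
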