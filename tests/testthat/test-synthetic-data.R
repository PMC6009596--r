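test_that("config validation rejects impossible settings", {
  expect_error(sim_config(chromosome_length = 0), "positive")
  expect_error(sim_config(ancestor_divergence = 1.5), "rates")
  expect_error(sim_config(mp_libraries = list(list(name = "x", insert_mean = 3000,
                                                   insert_sd = 0, n_pairs = 10))),
               "insert_sd")
  expect_error(simulate_contacts(structure(list(), class = "truth_set"),
                                 sim_config(hic_decay_exponent = -1)))
})

test_that("truth simulation is deterministic and hits the divergence rates", {
  cfg <- sim_config(seed = 7, n_chromosomes_per_subgenome = 1,
                    chromosome_length = 100000)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$subgenomes, t2$subgenomes)
  ## ancestors differ by substitutions only: direct positional comparison
  mism <- tetrascaf:::mismatch_fraction(t1$ancestors$A[[1]], t1$ancestors$B[[1]])
  expect_gt(mism, 0.03 * 0.8)
  expect_lt(mism, 0.03 * 1.2)
})

test_that("zero subgenome divergence reproduces the ancestors exactly", {
  cfg <- sim_config(seed = 3, n_chromosomes_per_subgenome = 1,
                    chromosome_length = 50000, subgenome_divergence = 0)
  truth <- simulate_truth(cfg)
  expect_identical(unname(truth$subgenomes$A), unname(truth$ancestors$A))
  expect_identical(unname(truth$subgenomes$B), unname(truth$ancestors$B))
})

test_that("draft fragmentation conserves bases and plants exact chimera counts", {
  d <- sim_dataset(2)
  truth <- d$truth
  expect_equal(nrow(truth$chimeras), 5)
  expect_equal(sum(nchar(truth$draft)),
               sum(nchar(c(truth$subgenomes$A, truth$subgenomes$B))))
  ## junctions strictly inside their sequences
  lens <- nchar(truth$draft)[truth$chimeras$draft_id]
  expect_true(all(truth$chimeras$junction > 0 & truth$chimeras$junction < lens))

  d0 <- sim_dataset(2, n_chimeras = 0)
  expect_equal(nrow(d0$truth$chimeras), 0)
  ## with no chimeras every draft contig is one contiguous truth interval,
  ## and concatenating the fragments of one chromosome in true order
  ## reconstructs it exactly
  fr <- d0$truth$fragments
  expect_true(all(table(fr$draft_id) == 1))
  ch <- fr$chrom[1]
  sel <- fr[fr$chrom == ch, ]
  sel <- sel[order(sel$start0), ]
  rebuilt <- paste(d0$truth$draft[sel$draft_id], collapse = "")
  expect_identical(rebuilt, c(d0$truth$subgenomes$A, d0$truth$subgenomes$B)[[ch]])
})

test_that("chimeras in excess of fragments are rejected", {
  cfg <- sim_config(seed = 1, n_chromosomes_per_subgenome = 1,
                    chromosome_length = 60000, n_chimeras = 50)
  truth <- simulate_truth(cfg)
  expect_error(make_draft_with_chimeras(truth, cfg), "exceeds")
})

test_that("molecule simulation respects coverage, noise and filter fractions", {
  cfg <- sim_config(seed = 5, n_chromosomes_per_subgenome = 1,
                    chromosome_length = 1000000, molecule_coverage = 30)
  truth <- simulate_truth(cfg)
  mols <- simulate_molecules(truth, config = cfg)
  total <- sum(vapply(mols, `[[`, numeric(1), "length"))
  target <- 30 * sum(nchar(c(truth$subgenomes$A, truth$subgenomes$B)))
  expect_lt(abs(total - target) / target, 0.15)

  ## planted filter failures behave binomially
  meta <- attr(mols, "truth")
  n <- nrow(meta)
  p <- cfg$fraction_failing_filters
  expect_lt(abs(sum(meta$planted_fail) - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  failed <- !names(mols) %in% names(filter_molecules(mols))
  expect_true(all(names(mols)[meta$planted_fail] %in% names(mols)[failed]))

  ## zero sizing noise: labels match the digested truth interval exactly
  cfg0 <- sim_config(seed = 5, n_chromosomes_per_subgenome = 1,
                     chromosome_length = 200000, molecule_coverage = 2,
                     sizing_noise_sd = 0, fraction_failing_filters = 0)
  truth0 <- simulate_truth(cfg0)
  mols0 <- simulate_molecules(truth0, config = cfg0)
  meta0 <- attr(mols0, "truth")
  i <- which(meta0$strand == "+")[1]
  expect_false(is.na(i))
  m <- mols0[[meta0$mol_id[i]]]
  nicks <- digest_sequence(c(truth0$subgenomes$A,
                             truth0$subgenomes$B)[[meta0$chrom[i]]])$labels
  expected <- nicks[nicks >= meta0$start[i] & nicks < meta0$start[i] + m$length] -
    meta0$start[i]
  expect_equal(m$labels, expected)

  expect_error(simulate_molecules(truth, config = sim_config(molecule_coverage = 0)),
               "coverage")
})

test_that("mate pairs are deterministic, innie, and respect insert geometry", {
  d <- sim_dataset(4)
  mp1 <- simulate_mate_pairs(d$truth, d$cfg)
  mp2 <- simulate_mate_pairs(d$truth, d$cfg)
  expect_identical(mp1, mp2)
  expect_setequal(unique(mp1$strand[mp1$mate == 1]), "+")
  expect_setequal(unique(mp1$strand[mp1$mate == 2]), "-")

  ## same-contig pairs: implied insert within the library's 5-SD window
  m1 <- mp1[mp1$mate == 1, ]; m2 <- mp1[mp1$mate == 2, ]
  same <- m1$contig == m2$contig
  insert <- m2$pos0[same] + 100 - m1$pos0[same]
  expect_true(all(insert >= 3000 - 5 * 300 & insert <= 3000 + 5 * 300))

  ## pairs spanning adjacent fragments produce links between those contigs
  lens <- nchar(d$truth$draft)
  links <- filter_links_by_insert(collect_links(mp1, lens), d$cfg$mp_libraries)
  fr <- d$truth$fragments
  fr1 <- fr[!fr$draft_id %in% d$truth$chimeras$draft_id, ]
  fr1 <- fr1[order(fr1$chrom, fr1$start0), ]
  ## truly adjacent fragment pairs (no chimera-consumed fragment between)
  adj <- which(fr1$chrom[-1] == fr1$chrom[-nrow(fr1)] &
               diff(fr1$order_index) == 1)
  found <- mapply(function(a, b) {
    any((links$contig_a == a & links$contig_b == b) |
        (links$contig_a == b & links$contig_b == a))
  }, fr1$draft_id[adj], fr1$draft_id[adj + 1])
  expect_gt(mean(found), 0.9)
})

test_that("long-read records cover normal regions and clip at chimeras", {
  d <- sim_dataset(6)
  lr <- simulate_long_read_clips(d$truth, d$truth$draft, d$cfg)
  ## every chimera junction has >= 3 clip boundaries within tolerance
  for (i in seq_len(nrow(d$truth$chimeras))) {
    id <- d$truth$chimeras$draft_id[i]; j <- d$truth$chimeras$junction[i]
    b <- c(lr$end0[lr$contig == id & lr$clip_right > 0],
           lr$start0[lr$contig == id & lr$clip_left > 0])
    expect_gte(sum(abs(b - j) <= 100), 3)
  }
  ## a chimera-free contig has spanning coverage >= 5 at interior points
  normal <- setdiff(names(d$truth$draft), d$truth$chimeras$draft_id)[1]
  L <- nchar(d$truth$draft[[normal]])
  for (x in seq(10000, L - 10000, length.out = 5)) {
    cov <- sum(lr$contig == normal & lr$start0 <= x - 1000 & lr$end0 >= x + 1000)
    expect_gte(cov, 5)
  }
  ## empty draft
  empty <- simulate_long_read_clips(d$truth, character(0), d$cfg)
  expect_equal(nrow(empty), 0)
})

test_that("contacts decay with distance and honor the inter fraction", {
  d <- sim_dataset(8, n_chimeras = 0)
  hic1 <- simulate_contacts(d$truth, d$cfg)
  hic2 <- simulate_contacts(d$truth, d$cfg)
  expect_identical(hic1, hic2)

  ## mean contact count at ~10 kb exceeds that at ~1 Mb equivalent distance:
  ## compare short- vs long-range counts on one chromosome via draft positions
  fr <- d$truth$fragments
  one_ctg <- fr$draft_id[which.max(fr$end0 - fr$start0)]
  same <- hic1[hic1$seq1 == one_ctg & hic1$seq2 == one_ctg, ]
  dist <- abs(same$pos2 - same$pos1)
  expect_gt(sum(dist < 10000), sum(dist > 40000))

  cfg0 <- sim_config(seed = 8, n_chimeras = 0, hic_inter_fraction = 0,
                     n_hic_pairs = 20000L)
  truth0 <- make_draft_with_chimeras(simulate_truth(cfg0), cfg0)
  hic0 <- simulate_contacts(truth0, cfg0)
  ctg2chrom <- setNames(truth0$fragments$chrom, truth0$fragments$draft_id)
  expect_true(all(ctg2chrom[hic0$seq1] == ctg2chrom[hic0$seq2]))
})
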