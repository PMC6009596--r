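libs <- list(list(name = "mp3k", insert_mean = 3000, insert_sd = 300,
                  n_pairs = 0L))

## one mate-pair record pair linking two contigs
mk_pair <- function(id, ctg_a, pos_a, strand_a, ctg_b, pos_b, strand_b,
                    unique = TRUE, library = "mp3k") {
  data.frame(read_id = id, mate = c(1L, 2L), contig = c(ctg_a, ctg_b),
             pos0 = c(pos_a, pos_b), strand = c(strand_a, strand_b),
             mapq = ifelse(unique, 60L, 0L), unique = unique,
             library = library, stringsAsFactors = FALSE)
}

lens2 <- c(A = 40000, B = 50000)

test_that("links keep only doubly-unique cross-contig pairs with innie ends", {
  rec <- rbind(
    mk_pair("p1", "A", 39000, "+", "B", 900, "-"),        # A tail -> B head
    mk_pair("p2", "A", 39100, "+", "B", 800, "-"),
    mk_pair("p3", "A", 100, "+", "A", 2900, "-"),         # same contig: not a link
    mk_pair("p4", "A", 39200, "+", "B", 700, "-", unique = FALSE))
  links <- collect_links(rec, lens2)
  expect_equal(nrow(links), 2)
  expect_true(all(links$contig_a == "A" & links$end_a == "tail"))
  expect_true(all(links$contig_b == "B" & links$end_b == "head"))
  ## d_a = len - pos, d_b = pos + read length
  expect_equal(links$d_a, c(1000, 900))
  expect_equal(links$d_b, c(1000, 900))
  expect_equal(nrow(collect_links(rec[0, ], lens2)), 0)
  expect_error(collect_links(mk_pair("x", "A", 1, "+", "Z", 1, "-"), lens2),
               "unknown contigs")
})

test_that("insert filter uses an inclusive 5-SD window", {
  mk_link <- function(d_a, d_b)
    data.frame(contig_a = "A", end_a = "tail", d_a = d_a,
               contig_b = "B", end_b = "head", d_b = d_b,
               library = "mp3k", read_id = "r", stringsAsFactors = FALSE)
  expect_equal(nrow(filter_links_by_insert(mk_link(2000, 2500), libs)), 1)  # 4500 = mean+5sd
  expect_equal(nrow(filter_links_by_insert(mk_link(2000, 2501), libs)), 0)  # 4501
  expect_equal(nrow(filter_links_by_insert(mk_link(1000, 500), libs)), 1)   # 1500 = mean-5sd
  expect_equal(nrow(filter_links_by_insert(mk_link(1000, 499), libs)), 0)
  ## degenerate k_sd = 0 keeps only exact-mean inserts
  expect_equal(nrow(filter_links_by_insert(mk_link(1500, 1500), libs, k_sd = 0)), 1)
  expect_equal(nrow(filter_links_by_insert(mk_link(1500, 1501), libs, k_sd = 0)), 0)
  expect_error(filter_links_by_insert(
    transform(mk_link(1, 1), library = "nope"), libs), "unknown library")
})

test_that("joins need three links in one library; ambiguity blocks joins", {
  three_links <- function(a, ea, b, eb, lib = "mp3k") {
    data.frame(contig_a = a, end_a = ea, d_a = c(900, 1000, 1100),
               contig_b = b, end_b = eb, d_b = c(1100, 1000, 900),
               library = lib, read_id = sprintf("%s%s%d", a, b, 1:3),
               stringsAsFactors = FALSE)
  }
  lens3 <- c(A = 40000, B = 50000, C = 30000)
  p <- join_contigs(lens3, three_links("A", "tail", "B", "head"), libs)
  ab <- p[p$scaffold_id == p$scaffold_id[p$contig == "A"], ]
  expect_equal(ab$contig, c("A", "B"))
  expect_equal(ab$orientation, c("+", "+"))

  ## only two links: no join
  p2 <- join_contigs(lens3, three_links("A", "tail", "B", "head")[1:2, ], libs)
  expect_equal(length(unique(p2$scaffold_id)), 3)

  ## three links split 2+1 across two libraries: below threshold in each
  libs2 <- c(libs, list(list(name = "mp8k", insert_mean = 3000,
                             insert_sd = 300, n_pairs = 0L)))
  mixed <- three_links("A", "tail", "B", "head")
  mixed$library[3] <- "mp8k"
  p3 <- join_contigs(lens3, mixed, libs2)
  expect_equal(length(unique(p3$scaffold_id)), 3)

  ## A.tail supported to both B.head and C.head: ambiguity -> no join
  amb <- rbind(three_links("A", "tail", "B", "head"),
               three_links("A", "tail", "C", "head"))
  p4 <- join_contigs(lens3, amb, libs)
  expect_equal(length(unique(p4$scaffold_id)), 3)
})

test_that("orientation flows through head/tail chains", {
  lens3 <- c(A = 40000, B = 50000, C = 30000)
  mk3 <- function(a, ea, b, eb)
    data.frame(contig_a = a, end_a = ea, d_a = 1000,
               contig_b = b, end_b = eb, d_b = 1000, library = "mp3k",
               read_id = sprintf("%s%s%d", a, b, 1:3), stringsAsFactors = FALSE)
  ## A tail -> B tail (B reversed), B head -> C head (C forward again)
  links <- rbind(mk3("A", "tail", "B", "tail"), mk3("B", "head", "C", "head"))
  p <- join_contigs(lens3, links, libs)
  expect_equal(length(unique(p$scaffold_id)), 1)
  expect_equal(p$contig, c("A", "B", "C"))
  expect_equal(p$orientation, c("+", "-", "+"))
})

test_that("gap estimates average link geometry and clamp at the floor", {
  mk_link <- function(d_a, d_b)
    data.frame(contig_a = "A", end_a = "tail", d_a = d_a, contig_b = "B",
               end_b = "head", d_b = d_b, library = "mp3k", read_id = "r",
               stringsAsFactors = FALSE)
  expect_equal(as.numeric(estimate_gap(mk_link(1000, 1500), libs)), 500)
  two <- rbind(mk_link(1300, 1300), mk_link(1200, 1200))  # gaps 400 and 600
  expect_equal(as.numeric(estimate_gap(two, libs)), 500)
  g <- estimate_gap(mk_link(1600, 1600), libs)            # implies -200
  expect_equal(as.numeric(g), 10)
  expect_true(attr(g, "clamped"))
})

test_that("scaffolding output is invariant to link order and conserves contigs", {
  d <- sim_dataset(10, n_chimeras = 0)
  mp <- simulate_mate_pairs(d$truth, d$cfg)
  lens <- nchar(d$truth$draft)
  links <- filter_links_by_insert(collect_links(mp, lens), d$cfg$mp_libraries)
  p1 <- join_contigs(lens, links, d$cfg$mp_libraries)
  set.seed(99)
  p2 <- join_contigs(lens, links[sample.int(nrow(links)), ], d$cfg$mp_libraries)
  expect_identical(p1, p2)
  expect_setequal(p1$contig, names(lens))
  expect_equal(anyDuplicated(p1$contig), 0)
})

test_that("error-free links reconstruct true adjacencies without misjoins", {
  d <- sim_dataset(10, n_chimeras = 0)
  mp <- simulate_mate_pairs(d$truth, d$cfg)
  lens <- nchar(d$truth$draft)
  links <- filter_links_by_insert(collect_links(mp, lens), d$cfg$mp_libraries)
  paths <- join_contigs(lens, links, d$cfg$mp_libraries)
  fr <- d$truth$fragments[order(d$truth$fragments$chrom,
                                d$truth$fragments$start0), ]
  true_adj <- unlist(lapply(split(fr$draft_id, fr$chrom), function(ids)
    paste(pmin(head(ids, -1), tail(ids, -1)),
          pmax(head(ids, -1), tail(ids, -1)))))
  pred_adj <- unlist(lapply(split(paths$contig, paths$scaffold_id), function(p)
    if (length(p) > 1) paste(pmin(head(p, -1), tail(p, -1)),
                             pmax(head(p, -1), tail(p, -1)))))
  expect_true(all(pred_adj %in% true_adj))        # zero misjoins
  expect_gte(mean(true_adj %in% pred_adj), 0.8)   # adjacency recall

  ## scaffold sequences carry N gaps between oriented components
  seqs <- scaffold_sequences(d$truth$draft, paths)
  expect_equal(sum(nchar(gsub("N", "", seqs))), sum(lens))
})
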