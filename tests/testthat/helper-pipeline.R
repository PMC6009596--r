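## shared fixtures: one simulated dataset per config, memoised across tests

local_sim_cache <- new.env(parent = emptyenv())

sim_dataset <- function(seed, n_chimeras = 5, ...) {
  key <- paste(seed, n_chimeras, paste(unlist(list(...)), collapse = "_"),
               sep = "_")
  if (!is.null(local_sim_cache[[key]])) return(local_sim_cache[[key]])
  cfg <- sim_config(seed = seed, n_chimeras = n_chimeras, ...)
  truth <- make_draft_with_chimeras(simulate_truth(cfg), cfg)
  out <- list(cfg = cfg, truth = truth)
  local_sim_cache[[key]] <- out
  out
}

truth_maps <- function(truth) {
  chroms <- c(truth$subgenomes$A, truth$subgenomes$B)
  maps <- lapply(names(chroms), function(ch)
    digest_sequence(chroms[[ch]], map_id = ch))
  names(maps) <- names(chroms)
  maps
}

## end-to-end curation of one simulated dataset; returns the curation result
## plus the truth
run_curation <- function(seed, n_chimeras = 5) {
  d <- sim_dataset(seed, n_chimeras)
  cfg <- d$cfg; truth <- d$truth
  omaps <- truth_maps(truth)
  mols <- simulate_molecules(truth, config = cfg)
  mp <- simulate_mate_pairs(truth, cfg)
  lr <- simulate_long_read_clips(truth, truth$draft, cfg)
  cur <- curate_assembly(truth$draft, omaps, mols, mp, lr, cfg$mp_libraries)
  list(cfg = cfg, truth = truth, cur = cur)
}

## random nick map for property tests
random_nick_map <- function(id, nlab, min_len = 50000, max_len = 100000) {
  L <- round(runif(1, min_len, max_len))
  labs <- sort(sample.int(L - 1, nlab))
  nick_map(id, L, labs)
}
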