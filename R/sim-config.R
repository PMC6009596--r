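#' Simulation configuration for the toy allotetraploid truth set
#'
#' Bundles every tunable of the synthetic-data generator. The defaults define
#' a desk-scale AABB genome: two subgenomes of two 500-kb chromosomes each,
#' derived from two simulated diploid ancestors, with five planted chimeric
#' joins in the fragmented draft.
#'
#' @param seed integer seed; every simulator draws from a stream derived from
#'   it, so equal seeds give byte-identical outputs.
#' @param n_chromosomes_per_subgenome chromosomes per subgenome.
#' @param chromosome_length chromosome length in bp.
#' @param ancestor_divergence substitution rate between the two ancestors
#'   (substitutions per bp; realized as point substitutions).
#' @param subgenome_divergence substitution rate from each ancestor to its
#'   descendant subgenome (plus short indels at 5% of events).
#' @param n_chimeras number of chimeric draft sequences to plant.
#' @param fragment_length_mean mean draft fragment length (bp); fragments are
#'   Normal(mean, mean/4) truncated at 25 kb so each carries several nick
#'   labels.
#' @param mp_libraries list of mate-pair libraries, each a list with fields
#'   `name`, `insert_mean`, `insert_sd`, `n_pairs`.
#' @param molecule_coverage fold coverage of optical molecules.
#' @param molecule_length_mean,molecule_length_sd molecule length model (bp).
#' @param sizing_noise_sd relative Gaussian sizing noise per label interval.
#' @param fraction_failing_filters fraction of molecules drawn to violate the
#'   retention filters (short, low SNR, or high intensity).
#' @param longread_coverage fold coverage of simulated long-read alignments.
#' @param longread_length_mean mean long-read length (bp).
#' @param n_hic_pairs number of Hi-C contact pairs.
#' @param hic_decay_exponent power-law exponent of intra-chromosomal contact
#'   decay: P(distance d) proportional to (1+d)^(-exponent).
#' @param hic_inter_fraction fraction of contacts that are uniform
#'   inter-chromosomal background.
#' @param prefer_cross_subgenome if `TRUE`, chimeras join fragments from
#'   different subgenomes (mimicking homoeologous misjoins); otherwise the
#'   two fragments are drawn uniformly.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_chimeras
sim_config <- function(seed = 1L,
                       n_chromosomes_per_subgenome = 2L,
                       chromosome_length = 500000L,
                       ancestor_divergence = 0.03,
                       subgenome_divergence = 0.01,
                       n_chimeras = 5L,
                       fragment_length_mean = 60000L,
                       mp_libraries = list(list(name = "mp3k",
                                                insert_mean = 3000,
                                                insert_sd = 300,
                                                n_pairs = 20000L)),
                       molecule_coverage = 40,
                       molecule_length_mean = 220000,
                       molecule_length_sd = 40000,
                       sizing_noise_sd = 0.02,
                       fraction_failing_filters = 0.1,
                       longread_coverage = 10,
                       longread_length_mean = 15000,
                       n_hic_pairs = 200000L,
                       hic_decay_exponent = 1.0,
                       hic_inter_fraction = 0.05,
                       prefer_cross_subgenome = FALSE) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes_per_subgenome = as.integer(n_chromosomes_per_subgenome),
              chromosome_length = as.integer(chromosome_length),
              ancestor_divergence = ancestor_divergence,
              subgenome_divergence = subgenome_divergence,
              n_chimeras = as.integer(n_chimeras),
              fragment_length_mean = as.integer(fragment_length_mean),
              mp_libraries = mp_libraries,
              molecule_coverage = molecule_coverage,
              molecule_length_mean = molecule_length_mean,
              molecule_length_sd = molecule_length_sd,
              sizing_noise_sd = sizing_noise_sd,
              fraction_failing_filters = fraction_failing_filters,
              longread_coverage = longread_coverage,
              longread_length_mean = longread_length_mean,
              n_hic_pairs = as.integer(n_hic_pairs),
              hic_decay_exponent = hic_decay_exponent,
              hic_inter_fraction = hic_inter_fraction,
              prefer_cross_subgenome = isTRUE(prefer_cross_subgenome))
  rates <- c(cfg$ancestor_divergence, cfg$subgenome_divergence,
             cfg$fraction_failing_filters, cfg$hic_inter_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$chromosome_length <= 0L) stop("chromosome_length must be positive")
  if (cfg$n_chromosomes_per_subgenome <= 0L) stop("need >= 1 chromosome per subgenome")
  if (cfg$fragment_length_mean <= 0L) stop("fragment_length_mean must be positive")
  if (cfg$n_chimeras < 0L) stop("n_chimeras must be >= 0")
  for (lib in cfg$mp_libraries) {
    if (lib$insert_sd <= 0) stop("insert_sd must be > 0")
    if (lib$insert_mean <= 0) stop("insert_mean must be > 0")
  }
  if (cfg$hic_decay_exponent <= 0) stop("hic_decay_exponent must be > 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "-",
      2L * x$n_chromosomes_per_subgenome, "chromosomes x",
      x$chromosome_length, "bp,", x$n_chimeras, "planted chimeras\n")
  invisible(x)
}
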