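## round half-up to `digits` decimals, matching printed assembly tables
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## maximal N runs of a sequence: data.frame(start0, length)
gap_runs <- function(seq) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1) return(data.frame(start0 = integer(0), length = integer(0)))
  data.frame(start0 = as.integer(m) - 1L,
             length = attr(m, "match.length"))
}

#' Contiguity statistics of a sequence set
#'
#' N50/N90 are the length of the smallest sequence in the minimal prefix of
#' the descending-sorted lengths whose sum reaches 50%/90% of the total;
#' L50/L90 are the sizes of those prefixes. GC% is computed over non-N
#' bases and gaps are maximal N runs when sequences are supplied.
#'
#' @param lengths numeric vector of sequence lengths (nonempty).
#' @param sequences optional named character vector (for GC and gaps).
#' @return list: `total`, `count`, `max`, `min`, `n50`, `l50`, `n90`,
#'   `l90`, and with sequences `gc_percent`, `gap_count`, `gap_length`.
#' @export
contiguity_stats <- function(lengths, sequences = NULL) {
  if (!length(lengths)) stop("empty length list")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cum <- cumsum(s)
  total <- cum[length(cum)]
  l50 <- which(cum >= 0.5 * total)[1]
  l90 <- which(cum >= 0.9 * total)[1]
  out <- list(total = total, count = length(s), max = s[1],
              min = s[length(s)], n50 = s[l50], l50 = l50,
              n90 = s[l90], l90 = l90)
  if (!is.null(sequences)) {
    allseq <- paste(toupper(sequences), collapse = "")
    counts <- table(strsplit(allseq, "", fixed = TRUE)[[1]])
    gc <- sum(counts[c("G", "C")], na.rm = TRUE)
    at <- sum(counts[c("A", "T")], na.rm = TRUE)
    gaps <- lapply(sequences, gap_runs)
    out$gc_percent <- round_half_up(100 * gc / (gc + at), 2)
    out$gap_count <- sum(vapply(gaps, nrow, 0L))
    out$gap_length <- sum(vapply(gaps, function(g) sum(g$length), 0))
  }
  out
}

#' Per-pseudochromosome statistics table
#'
#' For each chromosome: gap ratio = 100 * gap_length / length and anchored
#' percent = 100 * length / total assembly length, both half-up rounded to
#' two decimals; a totals row sums lengths and gaps and recomputes the
#' ratio from the totals.
#'
#' @param chromosomes data.frame with `subgenome`, `name`, `length`,
#'   `gap_count`, `gap_length` (one row per chromosome or unplaced bucket).
#' @param total_assembly_length grand total assembly length (bp).
#' @return data.frame with `gap_ratio` and `anchored_percent` columns and a
#'   final `Total` row.
#' @export
chromosome_table <- function(chromosomes, total_assembly_length) {
  if (total_assembly_length <= 0) stop("total_assembly_length must be > 0")
  tab <- chromosomes
  tab$gap_ratio <- round_half_up(100 * tab$gap_length / tab$length, 2)
  tab$anchored_percent <- round_half_up(100 * tab$length / total_assembly_length, 2)
  total <- data.frame(subgenome = "Total", name = "Total",
                      length = sum(tab$length), gap_count = sum(tab$gap_count),
                      gap_length = sum(tab$gap_length),
                      gap_ratio = round_half_up(
                        100 * sum(tab$gap_length) / sum(tab$length), 2),
                      anchored_percent = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(tab, total)
  rownames(out) <- NULL
  out
}

#' Per-subgenome assembly comparison
#'
#' Summarizes each subgenome label over sequences longer than `min_length`
#' (strict, so exactly `min_length` is excluded): size, count, max/min,
#' N50/N90, gap number, gap ratio and GC%.
#'
#' @param partition data.frame from [assign_scaffolds()] (or any table with
#'   `sequence_id` and `label`).
#' @param sequences named character vector.
#' @param min_length length floor in bp (default 10,000).
#' @return data.frame with one row per label present.
#' @export
subgenome_table <- function(partition, sequences, min_length = 10000) {
  rows <- list()
  for (lab in intersect(c("A", "B"), unique(partition$label))) {
    ids <- partition$sequence_id[partition$label == lab]
    seqs <- sequences[intersect(ids, names(sequences))]
    seqs <- seqs[nchar(seqs) > min_length]
    if (!length(seqs)) {
      rows[[lab]] <- data.frame(label = lab, genome_size = 0, contig_number = 0L,
                                max_length = NA_real_, min_length = NA_real_,
                                n50 = NA_real_, n90 = NA_real_,
                                gap_number = 0L, gap_ratio = NA_real_,
                                gc_percent = NA_real_, stringsAsFactors = FALSE)
      next
    }
    st <- contiguity_stats(nchar(seqs), seqs)
    rows[[lab]] <- data.frame(label = lab, genome_size = st$total,
                              contig_number = st$count, max_length = st$max,
                              min_length = st$min, n50 = st$n50, n90 = st$n90,
                              gap_number = st$gap_count,
                              gap_ratio = round_half_up(
                                100 * st$gap_length / st$total, 2),
                              gc_percent = st$gc_percent,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Anchoring and subgenome-separation summary
#'
#' Anchored percent is the summed length of named pseudochromosome rows
#' over the grand total; separated percent is the summed length of all A-
#' and B-labeled rows (including unplaced-but-labeled buckets) over the
#' grand total. Both half-up rounded to two decimals.
#'
#' @param chromosomes the input table of [chromosome_table()] (`subgenome`
#'   in `A`/`B`/`Unknown`, `name` with `Un-chr` marking unplaced buckets).
#' @return list: `anchored_percent`, `separated_percent`, `total_length`,
#'   `subgenome_lengths` (named A/B sums).
#' @export
anchoring_summary <- function(chromosomes) {
  total <- sum(chromosomes$length)
  named <- chromosomes$subgenome %in% c("A", "B") &
    chromosomes$name != "Un-chr"
  labeled <- chromosomes$subgenome %in% c("A", "B")
  list(anchored_percent = round_half_up(100 * sum(chromosomes$length[named]) / total, 2),
       separated_percent = round_half_up(100 * sum(chromosomes$length[labeled]) / total, 2),
       total_length = total,
       subgenome_lengths = c(
         A = sum(chromosomes$length[chromosomes$subgenome == "A"]),
         B = sum(chromosomes$length[chromosomes$subgenome == "B"])))
}

#' Published pseudochromosome statistics bundled with the package
#'
#' Loads the bundled per-pseudochromosome table (lengths, gap counts and
#' gap lengths of the 20 A/B pseudochromosomes, the two unplaced buckets
#' and the unknown fraction of the reference allotetraploid wild peanut
#' assembly) used by the reporting examples and tests.
#'
#' @return data.frame: `subgenome`, `name`, `length`, `gap_count`,
#'   `gap_length`.
#' @export
reference_chromosome_stats <- function() {
  path <- system.file("extdata", "pseudochromosome_stats.tsv",
                      package = "tetrascaf", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "numeric",
                            "numeric", "numeric"))
}
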