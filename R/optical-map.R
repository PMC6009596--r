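#' Nick map: ordered label positions along a molecule or sequence
#'
#' @param map_id identifier.
#' @param length map length in bp.
#' @param labels 0-based label positions, strictly increasing, `< length`.
#' @return object of class `nick_map`.
#' @export
nick_map <- function(map_id, length, labels) {
  labels <- as.numeric(labels)
  length <- as.numeric(length)
  if (length <= 0) stop("map length must be positive")
  if (length(labels)) {
    if (any(diff(labels) <= 0)) stop("labels must be strictly increasing")
    if (labels[1] < 0 || labels[length(labels)] >= length)
      stop("labels must lie in [0, length)")
  }
  structure(list(map_id = map_id, length = length, labels = labels),
            class = "nick_map")
}

#' @export
print.nick_map <- function(x, ...) {
  cat("<nick_map>", x$map_id, "-", format(x$length, big.mark = ","),
      "bp,", length(x$labels), "labels\n")
  invisible(x)
}

#' Optical molecule: a nick map with per-molecule quality attributes
#'
#' @inheritParams nick_map
#' @param label_snr label signal-to-noise ratio (>= 0).
#' @param avg_intensity average molecule intensity (>= 0).
#' @return object of class `optical_molecule` (inherits `nick_map`).
#' @export
optical_molecule <- function(map_id, length, labels, label_snr, avg_intensity) {
  if (label_snr < 0 || avg_intensity < 0)
    stop("label_snr and avg_intensity must be >= 0")
  m <- nick_map(map_id, length, labels)
  m$label_snr <- label_snr
  m$avg_intensity <- avg_intensity
  class(m) <- c("optical_molecule", "nick_map")
  m
}

#' In-silico nickase digestion of a sequence
#'
#' Emits one label per occurrence of the recognition motif on either strand,
#' at the occurrence's start position in forward-strand coordinates.
#' Occurrences overlapping N runs never match.
#'
#' @param sequence character scalar over A/C/G/T/N (case-insensitive).
#' @param motif recognition sequence over A/C/G/T, length >= 4.
#' @param map_id identifier for the resulting map.
#' @return a [nick_map()].
#' @export
#' @examples
#' digest_sequence("AAAAAGCTCTTCAAAAAAAA", "GCTCTTC")$labels  # 5
digest_sequence <- function(sequence, motif = "GCTCTTC", map_id = "map") {
  if (nchar(motif) < 4 || grepl("[^ACGT]", motif))
    stop("motif must be over A/C/G/T with length >= 4")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside A/C/G/T/N")
  subj <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::start(Biostrings::matchPattern(motif, subj))
  rev <- Biostrings::start(Biostrings::matchPattern(revcomp(motif), subj))
  labels <- sort(unique(c(fwd, rev))) - 1  # to 0-based
  nick_map(map_id, nchar(sequence), labels)
}

#' Molecule retention filter
#'
#' Default thresholds follow standard optical-map QC: molecules longer than
#' 150 kb carrying at least 8 labels, with label SNR >= 3.0 and average
#' intensity < 0.6.
#'
#' @param min_length minimum length in bp (strict: `length > min_length`).
#' @param min_labels minimum label count (inclusive).
#' @param min_snr minimum label SNR (inclusive).
#' @param max_intensity maximum average intensity (strict).
#' @return object of class `molecule_filter`.
#' @export
molecule_filter <- function(min_length = 150000, min_labels = 8,
                            min_snr = 3.0, max_intensity = 0.6) {
  if (any(c(min_length, min_labels, min_snr, max_intensity) < 0))
    stop("all thresholds must be >= 0")
  structure(list(min_length = min_length, min_labels = min_labels,
                 min_snr = min_snr, max_intensity = max_intensity),
            class = "molecule_filter")
}

#' Apply the molecule retention filter
#'
#' A molecule is retained iff `length > min_length` and
#' `label count >= min_labels` and `label_snr >= min_snr` and
#' `avg_intensity < max_intensity`. Input order is preserved.
#'
#' @param molecules list of [optical_molecule()]s.
#' @param filter a [molecule_filter()].
#' @return the retained sub-list.
#' @export
filter_molecules <- function(molecules, filter = molecule_filter()) {
  stopifnot(inherits(filter, "molecule_filter"))
  keep <- vapply(molecules, function(m) {
    m$length > filter$min_length &&
      length(m$labels) >= filter$min_labels &&
      m$label_snr >= filter$min_snr &&
      m$avg_intensity < filter$max_intensity
  }, logical(1))
  molecules[keep]
}

#' Write nick maps in the simplified CMAP dialect
#'
#' Headered TSV with columns `CMapId`, `ContigLength`, `NumSites`, `SiteID`,
#' `Position` (one row per label), plus `SNR` and `Intensity` columns when
#' any map is an [optical_molecule()]. Positions are integer bp (0-based).
#'
#' @param maps list of [nick_map()]s / [optical_molecule()]s.
#' @param path output file.
#' @export
write_cmap <- function(maps, path) {
  has_qual <- any(vapply(maps, inherits, logical(1), "optical_molecule"))
  rows <- lapply(maps, function(m) {
    n <- length(m$labels)
    if (n == 0)  # sentinel row so label-free maps survive the round trip
      d <- data.frame(CMapId = m$map_id, ContigLength = m$length,
                      NumSites = 0L, SiteID = 0L, Position = NA_real_)
    else
      d <- data.frame(CMapId = m$map_id, ContigLength = m$length,
                      NumSites = n, SiteID = seq_len(n), Position = m$labels)
    if (has_qual) {
      d$SNR <- if (!is.null(m$label_snr)) m$label_snr else NA_real_
      d$Intensity <- if (!is.null(m$avg_intensity)) m$avg_intensity else NA_real_
    }
    d
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the simplified CMAP dialect
#'
#' @param path file written by [write_cmap()].
#' @return list of [nick_map()]s (or [optical_molecule()]s when SNR and
#'   intensity columns are present), keyed by map id.
#' @export
read_cmap <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  has_qual <- all(c("SNR", "Intensity") %in% names(tab))
  ids <- unique(tab$CMapId)
  maps <- lapply(ids, function(id) {
    sub <- tab[tab$CMapId == id, , drop = FALSE]
    sub <- sub[order(sub$SiteID), , drop = FALSE]
    labels <- sub$Position[!is.na(sub$Position)]
    if (has_qual && !any(is.na(sub$SNR)))
      optical_molecule(id, sub$ContigLength[1], labels,
                       sub$SNR[1], sub$Intensity[1])
    else
      nick_map(id, sub$ContigLength[1], labels)
  })
  names(maps) <- ids
  maps
}
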