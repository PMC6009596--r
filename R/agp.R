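#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Build an AGP v2.1 table from an ordered component layout
#'
#' @param layout data.frame with one row per placed component in object
#'   order: `object`, `component`, `orientation` (`+`/`-`), `gap_after`
#'   (bp of N gap following the component; NA after the last).
#' @param component_lengths named vector of component lengths.
#' @param gap_type AGP gap type (default `"scaffold"`).
#' @param evidence AGP linkage evidence (e.g. `"paired-ends"`,
#'   `"proximity_ligation"`).
#' @return data.frame in AGP v2.1 column order (1-based inclusive
#'   coordinates).
#' @export
agp_from_layout <- function(layout, component_lengths,
                            gap_type = "scaffold", evidence = "paired-ends") {
  rows <- list()
  for (obj in unique(layout$object)) {
    p <- layout[layout$object == obj, , drop = FALSE]
    pos <- 0L
    part <- 0L
    for (i in seq_len(nrow(p))) {
      len <- as.integer(component_lengths[[p$component[i]]])
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = obj, object_beg = pos + 1L, object_end = pos + len,
        part_number = part, component_type = "W",
        component_id = p$component[i], component_beg = 1L,
        component_end = len, orientation = p$orientation[i],
        stringsAsFactors = FALSE)
      pos <- pos + len
      if (i < nrow(p) && !is.na(p$gap_after[i]) && p$gap_after[i] > 0) {
        g <- as.integer(p$gap_after[i])
        part <- part + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          object = obj, object_beg = pos + 1L, object_end = pos + g,
          part_number = part, component_type = "N",
          component_id = as.character(g), component_beg = NA_integer_,
          component_end = NA_integer_, orientation = NA_character_,
          stringsAsFactors = FALSE)
        rows[[length(rows)]]$gap_type <- gap_type
        pos <- pos + g
      }
    }
  }
  agp <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$gap_type)) r$gap_type <- NA_character_
    r
  }))
  agp$linkage <- ifelse(agp$component_type == "N", "yes", NA)
  agp$linkage_evidence <- ifelse(agp$component_type == "N", evidence, NA)
  rownames(agp) <- NULL
  agp
}

#' Write an AGP v2.1 file
#' @param agp data.frame from [agp_from_layout()].
#' @param path output file.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version 2.1", con)
  out <- agp
  for (i in seq_len(nrow(out))) {
    if (out$component_type[i] == "N") {
      fields <- c(out$object[i], out$object_beg[i], out$object_end[i],
                  out$part_number[i], "N", out$component_id[i],
                  out$gap_type[i], out$linkage[i], out$linkage_evidence[i])
    } else {
      fields <- c(out$object[i], out$object_beg[i], out$object_end[i],
                  out$part_number[i], "W", out$component_id[i],
                  out$component_beg[i], out$component_end[i],
                  out$orientation[i])
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an AGP v2.1 file
#' @param path AGP file.
#' @return data.frame in the same layout as [agp_from_layout()].
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(parts, function(f) {
    if (f[5] %in% c("N", "U"))
      data.frame(object = f[1], object_beg = as.integer(f[2]),
                 object_end = as.integer(f[3]), part_number = as.integer(f[4]),
                 component_type = f[5], component_id = f[6],
                 component_beg = NA_integer_, component_end = NA_integer_,
                 orientation = NA_character_, gap_type = f[7],
                 linkage = f[8], linkage_evidence = f[9],
                 stringsAsFactors = FALSE)
    else
      data.frame(object = f[1], object_beg = as.integer(f[2]),
                 object_end = as.integer(f[3]), part_number = as.integer(f[4]),
                 component_type = f[5], component_id = f[6],
                 component_beg = as.integer(f[7]), component_end = as.integer(f[8]),
                 orientation = f[9], gap_type = NA_character_,
                 linkage = NA_character_, linkage_evidence = NA_character_,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reconstruct object sequences from an AGP table and its components
#'
#' @param agp data.frame ([read_agp()] / [agp_from_layout()]).
#' @param components named character vector of component sequences.
#' @return named character vector of reconstructed objects.
#' @export
reconstruct_from_agp <- function(agp, components) {
  out <- character(0)
  for (obj in unique(agp$object)) {
    p <- agp[agp$object == obj, , drop = FALSE]
    p <- p[order(p$part_number), , drop = FALSE]
    parts <- vapply(seq_len(nrow(p)), function(i) {
      if (p$component_type[i] == "N")
        strrep("N", as.integer(p$component_id[i]))
      else {
        s <- substr(components[[p$component_id[i]]],
                    p$component_beg[i], p$component_end[i])
        if (identical(p$orientation[i], "-")) revcomp(s) else s
      }
    }, character(1))
    out[[obj]] <- paste(parts, collapse = "")
  }
  out
}
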