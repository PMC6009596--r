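#' Collect mate-pair links between contigs from alignment records
#'
#' Keeps only pairs with both mates uniquely mapped and on two different
#' contigs, and derives the joined end of each contig from the mate strand
#' under the innie (forward/reverse) convention: a forward mate points at
#' the contig tail, a reverse mate at the head.
#'
#' @param records mate alignment table (`read_id`, `mate`, `contig`, `pos0`,
#'   `strand`, `mapq`, `unique`, `library`).
#' @param contig_lengths named vector of contig lengths.
#' @param read_len read length in bp.
#' @return data.frame of links: `contig_a`, `end_a`, `d_a`, `contig_b`,
#'   `end_b`, `d_b`, `library`, `read_id` (`d_*` = distance from the mate's
#'   outer position to the joined contig end; a/b ordered so that
#'   `contig_a < contig_b`).
#' @export
collect_links <- function(records, contig_lengths, read_len = 100) {
  unknown <- setdiff(unique(records$contig), names(contig_lengths))
  if (length(unknown))
    stop(length(unknown), " records reference unknown contigs (e.g. ",
         unknown[1], ")")
  empty <- data.frame(contig_a = character(0), end_a = character(0),
                      d_a = numeric(0), contig_b = character(0),
                      end_b = character(0), d_b = numeric(0),
                      library = character(0), read_id = character(0))
  rec <- records[records$unique, , drop = FALSE]
  if (!nrow(rec)) return(empty)
  rec <- rec[order(rec$read_id, rec$mate), ]
  cnt <- table(rec$read_id)
  rec <- rec[rec$read_id %in% names(cnt)[cnt == 2], , drop = FALSE]
  if (!nrow(rec)) return(empty)
  m1 <- rec[rec$mate == 1L, ]; m2 <- rec[rec$mate == 2L, ]
  cross <- m1$contig != m2$contig
  m1 <- m1[cross, ]; m2 <- m2[cross, ]
  if (!nrow(m1)) return(empty)
  end_of <- function(strand) ifelse(strand == "+", "tail", "head")
  d_of <- function(contig, pos0, strand)
    ifelse(strand == "+", contig_lengths[contig] - pos0, pos0 + read_len)
  links <- data.frame(contig_a = m1$contig, end_a = end_of(m1$strand),
                      d_a = as.numeric(d_of(m1$contig, m1$pos0, m1$strand)),
                      contig_b = m2$contig, end_b = end_of(m2$strand),
                      d_b = as.numeric(d_of(m2$contig, m2$pos0, m2$strand)),
                      library = m1$library, read_id = m1$read_id,
                      stringsAsFactors = FALSE)
  flip <- links$contig_a > links$contig_b
  links[flip, c("contig_a", "end_a", "d_a", "contig_b", "end_b", "d_b")] <-
    links[flip, c("contig_b", "end_b", "d_b", "contig_a", "end_a", "d_a")]
  rownames(links) <- NULL
  links
}

#' Filter links by implied insert size
#'
#' A link is reasonable iff its implied insert (`d_a + d_b`, i.e. assuming
#' the contigs abut) lies within `insert_mean +/- k_sd * insert_sd` of its
#' library; the boundary is inclusive.
#'
#' @param links data.frame from [collect_links()].
#' @param libraries list of library descriptions (`name`, `insert_mean`,
#'   `insert_sd`).
#' @param k_sd tolerance in SDs (default 5).
#' @return the reasonable links.
#' @export
filter_links_by_insert <- function(links, libraries, k_sd = 5) {
  lib_by <- setNames(libraries, vapply(libraries, `[[`, "", "name"))
  unknown <- setdiff(unique(links$library), names(lib_by))
  if (length(unknown)) stop("unknown library: ", unknown[1])
  if (!nrow(links)) return(links)
  mu <- vapply(links$library, function(l) lib_by[[l]]$insert_mean, numeric(1))
  sd <- vapply(links$library, function(l) lib_by[[l]]$insert_sd, numeric(1))
  insert <- links$d_a + links$d_b
  links[insert >= mu - k_sd * sd & insert <= mu + k_sd * sd, , drop = FALSE]
}

## canonical edge key for a pair of contig ends
edge_key <- function(ca, ea, cb, eb) paste(ca, ea, cb, eb, sep = "|")

#' Join contigs into scaffold paths from filtered links
#'
#' An edge between two contig ends exists iff at least `min_links` links in
#' a single library support the same end pairing. Any contig end supported
#' to two or more different partners contributes no join (ambiguity rule).
#' The remaining edges form simple paths (cycles are opened at their
#' weakest edge); each maximal path becomes a scaffold. Gaps are estimated
#' from the supporting links ([estimate_gap()]).
#'
#' @param contig_lengths named vector of contig lengths.
#' @param links filtered links ([filter_links_by_insert()]).
#' @param libraries library list (for gap estimation).
#' @param min_links support threshold per library (default 3).
#' @param min_gap gap floor in bp (default 10).
#' @return data.frame of scaffold paths: `scaffold_id`, `contig`,
#'   `orientation`, `gap_after` (NA after the last contig).
#' @export
join_contigs <- function(contig_lengths, links, libraries, min_links = 3,
                         min_gap = 10) {
  contigs <- sort(names(contig_lengths))
  edges <- data.frame(key = character(0))
  if (nrow(links)) {
    key <- edge_key(links$contig_a, links$end_a, links$contig_b, links$end_b)
    tab <- table(key, links$library)
    supported <- rownames(tab)[apply(tab, 1, max) >= min_links]
    if (length(supported)) {
      parts <- do.call(rbind, strsplit(supported, "|", fixed = TRUE))
      edges <- data.frame(contig_a = parts[, 1], end_a = parts[, 2],
                          contig_b = parts[, 3], end_b = parts[, 4],
                          n_links = as.integer(apply(
                            tab[supported, , drop = FALSE], 1, sum)),
                          key = supported, stringsAsFactors = FALSE)
      ## ambiguity rule: an end with competing supported partners joins nothing
      end_ids <- c(paste(edges$contig_a, edges$end_a),
                   paste(edges$contig_b, edges$end_b))
      busy <- names(table(end_ids))[table(end_ids) >= 2]
      drop <- paste(edges$contig_a, edges$end_a) %in% busy |
        paste(edges$contig_b, edges$end_b) %in% busy
      edges <- edges[!drop, , drop = FALSE]
    }
  }

  ## adjacency over contig ends; each end now touches <= 1 edge
  nbr <- list()
  if (nrow(edges)) {
    edges <- edges[order(edges$key), ]
    ## open any cycle at its weakest edge so components are simple paths
    repeat {
      cyc_edge <- find_cycle_edge(edges)
      if (is.na(cyc_edge)) break
      edges <- edges[-cyc_edge, , drop = FALSE]
    }
    for (i in seq_len(nrow(edges))) {
      a <- paste(edges$contig_a[i], edges$end_a[i])
      b <- paste(edges$contig_b[i], edges$end_b[i])
      nbr[[a]] <- list(to_contig = edges$contig_b[i], to_end = edges$end_b[i],
                       key = edges$key[i])
      nbr[[b]] <- list(to_contig = edges$contig_a[i], to_end = edges$end_a[i],
                       key = edges$key[i])
    }
  }

  other_end <- function(e) if (e == "head") "tail" else "head"
  degree <- function(ctg) {
    sum(!is.null(nbr[[paste(ctg, "head")]]),
        !is.null(nbr[[paste(ctg, "tail")]]))
  }
  ## every component is a simple path, so it has two terminals (or is a
  ## singleton); iterating terminals in lexicographic order makes the
  ## output deterministic and starts each path at its smaller terminal
  terminals <- contigs[vapply(contigs, degree, 0L) <= 1L]
  visited <- character(0)
  paths <- list()
  for (start in terminals) {
    if (start %in% visited) next
    has_tail <- !is.null(nbr[[paste(start, "tail")]])
    exit_end <- if (has_tail || degree(start) == 0L) "tail" else "head"
    chain <- list()
    node <- start
    repeat {
      visited <- c(visited, node)
      orient <- if (exit_end == "tail") "+" else "-"
      el <- list(contig = node, orientation = orient, out_key = NA_character_)
      nxt <- nbr[[paste(node, exit_end)]]
      if (!is.null(nxt)) el$out_key <- nxt$key
      chain[[length(chain) + 1L]] <- el
      if (is.null(nxt)) break
      node <- nxt$to_contig
      exit_end <- other_end(nxt$to_end)
    }
    paths[[length(paths) + 1L]] <- chain
  }
  paths <- paths[order(vapply(paths, function(ch) ch[[1]]$contig, ""))]

  rows <- list()
  for (s in seq_along(paths)) {
    chain <- paths[[s]]
    sid <- sprintf("scaffold%04d", s)
    for (i in seq_along(chain)) {
      gap <- NA_real_
      if (i < length(chain)) {
        k <- chain[[i]]$out_key
        sup <- links[edge_key(links$contig_a, links$end_a,
                              links$contig_b, links$end_b) == k, , drop = FALSE]
        gap <- estimate_gap(sup, libraries, min_gap)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold_id = sid, contig = chain[[i]]$contig,
        orientation = chain[[i]]$orientation, gap_after = gap,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## detect an edge participating in a cycle; returns its row index or NA.
## with every end of degree <= 1 the components are paths or simple cycles;
## a component is a cycle iff #edges == #contigs in it.
find_cycle_edge <- function(edges) {
  if (!nrow(edges)) return(NA_integer_)
  verts <- unique(c(edges$contig_a, edges$contig_b))
  parent <- seq_along(verts)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ia <- match(edges$contig_a, verts); ib <- match(edges$contig_b, verts)
  for (i in seq_len(nrow(edges))) {
    ra <- find(ia[i]); rb <- find(ib[i])
    if (ra == rb) {
      ## cycle closed here: drop weakest edge of that component
      comp <- which(vapply(seq_len(nrow(edges)), function(j)
        find(ia[j]) == ra, logical(1)))
      return(comp[order(edges$n_links[comp], edges$key[comp])][1])
    }
    parent[ra] <- rb
  }
  NA_integer_
}

#' Estimate the gap between a joined contig pair
#'
#' `gap = round(mean(insert_mean - d_a - d_b))` over the supporting links;
#' estimates below `min_gap` are clamped and flagged with attribute
#' `"clamped"`.
#'
#' @param links supporting links for one joined pair.
#' @param libraries library list.
#' @param min_gap clamp floor (bp).
#' @return gap length in bp (numeric with attribute `clamped`).
#' @export
estimate_gap <- function(links, libraries, min_gap = 10) {
  stopifnot(nrow(links) >= 1)
  lib_by <- setNames(libraries, vapply(libraries, `[[`, "", "name"))
  mu <- vapply(links$library, function(l) lib_by[[l]]$insert_mean, numeric(1))
  g <- round(mean(mu - links$d_a - links$d_b))
  clamped <- g < min_gap
  g <- max(g, min_gap)
  attr(g, "clamped") <- clamped
  g
}

#' Build scaffold sequences from scaffold paths
#'
#' @param draft named character vector of contig sequences.
#' @param paths data.frame from [join_contigs()].
#' @return named character vector of scaffold sequences (gaps as N runs).
#' @export
scaffold_sequences <- function(draft, paths) {
  out <- character(0)
  for (sid in unique(paths$scaffold_id)) {
    p <- paths[paths$scaffold_id == sid, , drop = FALSE]
    parts <- character(0)
    for (i in seq_len(nrow(p))) {
      s <- draft[[p$contig[i]]]
      if (p$orientation[i] == "-") s <- revcomp(s)
      parts <- c(parts, s)
      if (i < nrow(p))
        parts <- c(parts, strrep("N", max(1, round(p$gap_after[i]))))
    }
    out[[sid]] <- paste(parts, collapse = "")
  }
  out
}
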