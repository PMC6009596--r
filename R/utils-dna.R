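## Low-level DNA helpers shared by the simulator and the subgenome module.
## Sequences are plain character strings internally; Biostrings is used at
## the I/O boundary (FASTA) and for pattern matching / reverse complement.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T/N
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

BASE_RAW <- charToRaw("ACGT")

## random sequence of length n (uniform base composition)
random_dna <- function(n) {
  rawToChar(BASE_RAW[sample.int(4L, n, replace = TRUE)])
}

## integer base codes A=0 C=1 G=2 T=3, NA otherwise
dna_codes <- function(x) {
  r <- as.integer(charToRaw(x))
  code <- rep(NA_integer_, 256L)
  code[as.integer(charToRaw("A")) + 1L] <- 0L
  code[as.integer(charToRaw("C")) + 1L] <- 1L
  code[as.integer(charToRaw("G")) + 1L] <- 2L
  code[as.integer(charToRaw("T")) + 1L] <- 3L
  code[as.integer(charToRaw("a")) + 1L] <- 0L
  code[as.integer(charToRaw("c")) + 1L] <- 1L
  code[as.integer(charToRaw("g")) + 1L] <- 2L
  code[as.integer(charToRaw("t")) + 1L] <- 3L
  code[r + 1L]
}

## Point-substitute a fraction `sub_rate` of positions (always to a different
## base) and, when `indel_rate` > 0, insert/delete short (<= max_indel bp)
## tracts. Returns the mutated string.
mutate_dna <- function(x, sub_rate, indel_rate = 0, max_indel = 5L) {
  r <- charToRaw(x)
  n <- length(r)
  if (sub_rate > 0) {
    idx <- which(runif(n) < sub_rate)
    if (length(idx)) {
      cur <- dna_codes(rawToChar(r[idx]))
      shift <- sample.int(3L, length(idx), replace = TRUE)
      r[idx] <- BASE_RAW[((cur + shift) %% 4L) + 1L]
    }
  }
  if (indel_rate > 0) {
    pos <- sort(which(runif(n) < indel_rate))
    if (length(pos)) {
      sizes <- sample.int(max_indel, length(pos), replace = TRUE)
      is_ins <- runif(length(pos)) < 0.5
      segs <- list()
      prev <- 1L
      for (i in seq_along(pos)) {
        p <- pos[i]
        if (p < prev) next
        if (is_ins[i]) {
          segs[[length(segs) + 1L]] <- r[prev:p]
          segs[[length(segs) + 1L]] <-
            BASE_RAW[sample.int(4L, sizes[i], replace = TRUE)]
          prev <- p + 1L
        } else {
          if (p > prev) segs[[length(segs) + 1L]] <- r[prev:(p - 1L)]
          prev <- min(n + 1L, p + sizes[i])
        }
      }
      if (prev <= n) segs[[length(segs) + 1L]] <- r[prev:n]
      r <- do.call(c, segs)
    }
  }
  rawToChar(r)
}

## fraction of mismatching positions between two equal-length strings
mismatch_fraction <- function(a, b) {
  ca <- charToRaw(a); cb <- charToRaw(b)
  stopifnot(length(ca) == length(cb))
  mean(ca != cb)
}

## Canonical k-mer codes (base-4 value packed into a double; exact for
## k <= 26). Returns numeric vector, NA where the window touches a non-ACGT
## character. Canonical = min(forward, reverse-complement) so the value is
## strand-invariant.
canonical_kmers <- function(x, k) {
  codes <- dna_codes(x)
  n <- length(codes)
  if (n < k) return(numeric(0))
  wf <- 4^(0:(k - 1))         # stats::filter weight m multiplies x[i - m + 1]
  wr <- 4^((k - 1):0)
  fwd <- as.numeric(stats::filter(codes, wf, sides = 1))
  rcv <- as.numeric(stats::filter(3 - codes, wr, sides = 1))
  fwd <- fwd[k:n]             # value at window *end* -> shift to window start
  rcv <- rcv[k:n]
  pmin(fwd, rcv)
}

## deterministic per-operation RNG seeding: one stream per (seed, op)
op_seed <- function(seed, op) {
  tags <- c(truth = 1L, draft = 2L, molecules = 3L, matepairs = 4L,
            longreads = 5L, contacts = 6L)
  tag <- tags[[op]]
  set.seed((as.integer(seed) %% 21000000L) * 100L + tag)
}
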