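# Internal helpers shared across modules. Coordinates are 0-based half-open.

# substring by 0-based half-open interval
subseq0 <- function(x, s, e) substr(x, s + 1L, e)

# vectorized reverse complement for plain character DNA
revcompChr <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rnaify <- function(x) chartr("Tt", "Uu", toupper(x))

revcompRna <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

#' Derived circRNA string id
#'
#' The identity of a circRNA is the tuple (contig, start, end, strand); the
#' string id is derived from it for reporting and never parsed back.
#'
#' @param contig,start,end character / integer vectors (0-based half-open).
#' @return character vector `circ_<contig>_<start>_<end>`.
#' @export
circId <- function(contig, start, end) {
  sprintf("circ_%s_%d_%d", contig, as.integer(start), as.integer(end))
}

# deterministic sub-seed derivation (kept below 2^31)
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483587)
}

# truncated normal on [lo, hi], integer-rounded, vectorized; simple
# rejection with a clamp fallback for infeasible tails
rtruncnormInt <- function(n, mean, sd, lo, hi = Inf) {
  x <- round(rnorm(n, mean, sd))
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 20L) {
    x[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lo), hi)
  as.integer(x)
}

# uniform random DNA
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
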