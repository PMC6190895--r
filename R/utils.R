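# shared internal helpers

BASES <- c("A", "C", "G", "T")

#' Build canonical variant keys
#'
#' A variant key is `chrom:pos:ref:alt` with a 1-based position; keys are the
#' unit of identity for caller intersection and database lookups, so both
#' sides must be normalized against the same genome first.
#'
#' @param chrom,pos,ref,alt parallel vectors describing variants.
#' @return Character vector of keys.
#' @export
variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

## reverse complement of a plain character string (ACGTN)
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## round half-up at `digits` decimals (table presentation convention;
## base round() is half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## phred-scaled, min-normalized genotype likelihoods from read counts under
## a binomial read-sampling model with per-read error `err`; capped at 255
phred_pl <- function(alt_reads, depth, err = 0.001, cap = 255) {
  ll <- c(
    dbinom(alt_reads, depth, err, log = TRUE),
    dbinom(alt_reads, depth, 0.5, log = TRUE),
    dbinom(alt_reads, depth, 1 - err, log = TRUE)
  )
  pl <- -10 / log(10) * ll
  pl <- pl - min(pl)
  pmin(round(pl), cap)
}

## classify allele pair into SNV / INDEL / invalid; indel size gate 2-100 bp
variant_class <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  cls <- rep(NA_character_, length(ref))
  cls[lr == 1L & la == 1L] <- "SNV"
  sz <- abs(lr - la)
  cls[(lr != la) & sz >= 2L & sz <= 100L] <- "INDEL"
  cls
}

iupac_expand <- function(code) {
  switch(code,
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
    stop("unknown IUPAC code: ", code)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
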