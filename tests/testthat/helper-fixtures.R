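# fixtures and independent oracles used across test files

## stack single-variant specs into a VariantSet; each spec is a list with
## chrom, pos, ref, alt, geno, depth, pl (list of triples), scf
stack_variants <- function(specs, samples = c("sire1", "dam1", "off1"),
                           caller = "A") {
  n <- length(specs)
  ns <- length(samples)
  geno <- matrix(NA_character_, n, ns)
  depth <- matrix(0L, n, ns)
  plarr <- array(NA_real_, c(n, ns, 3))
  scf <- matrix(NA_real_, n, ns)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    geno[i, ] <- sp$geno
    depth[i, ] <- sp$depth
    for (s in seq_len(ns)) plarr[i, s, ] <- sp$pl[[s]]
    scf[i, ] <- sp$scf
  }
  VariantSet(
    chrom = vapply(specs, function(s) s$chrom, ""),
    pos = vapply(specs, function(s) as.integer(s$pos), 1L),
    ref = vapply(specs, function(s) s$ref, ""),
    alt = vapply(specs, function(s) s$alt, ""),
    samples = samples, geno = geno, depth = depth, pl = plarr, scf = scf,
    caller = caller)
}

## a variant spec that passes every cascade criterion for trio
## (sire1, dam1, off1); override fields to engineer failures
passing_spec <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                         geno = c("AA", "AA", "AB"),
                         depth = c(30L, 30L, 28L),
                         pl = list(c(0, 60, 90), c(0, 45, 80),
                                   c(40, 0, 25)),
                         scf = c(0.01, 0.01, 0.01)) {
  list(chrom = chrom, pos = pos, ref = ref, alt = alt, geno = geno,
       depth = depth, pl = pl, scf = scf)
}

## independent brute-force evaluation of the de novo criteria, stage 1-6,
## written as one explicit per-variant predicate loop (no stage functions)
brute_denovo_keys <- function(a, b, trio, db,
                              min_pd = 12, den = 10, t = 20,
                              max_scf = 0.10) {
  ka <- variantKeys(a)
  g <- genotypes(a); d <- depths(a); p <- plArray(a); s <- softclip(a)
  cols <- sampleIds(a)
  oi <- match(trio@offspring, cols)
  si <- match(trio@sire, cols)
  di <- match(trio@dam, cols)
  others <- match(setdiff(trio@cohort, trio@offspring), cols)
  keep <- logical(length(ka))
  for (i in seq_along(ka)) {
    if (!(ka[i] %in% variantKeys(b))) next
    go <- g[i, oi]
    if (is.na(go) || !(go %in% c("AB", "BB"))) next
    other_carries <- FALSE
    for (j in others) {
      gj <- g[i, j]
      if (!is.na(gj) && gj %in% c("AB", "BB")) other_carries <- TRUE
    }
    if (other_carries) next
    if (ka[i] %in% dbKeys(db)) next
    if (is.na(d[i, si]) || is.na(d[i, di]) || is.na(d[i, oi])) next
    if (d[i, si] < min_pd || d[i, di] < min_pd) next
    if (den * d[i, oi] < d[i, si] + d[i, di]) next
    po <- p[i, oi, ]; ps <- p[i, si, ]; pd <- p[i, di, ]
    if (anyNA(c(po, ps, pd))) next
    if (!any(po == 0) || !any(ps == 0) || !any(pd == 0)) next
    if (!(po[1] > t && po[2] == 0 && po[3] > 0)) next
    if (!(ps[1] == 0 && ps[2] > t && ps[3] > t)) next
    if (!(pd[1] == 0 && pd[2] > t && pd[3] > t)) next
    if (!is.na(s[i, oi]) && s[i, oi] > max_scf) next
    keep[i] <- TRUE
  }
  ka[keep]
}

## independent off-target oracle: Biostrings Hamming distances per start
## position plus explicit PAM regex, on both strands
oracle_offtargets <- function(genome, gq) {
  iupac_re <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]",
                Y = "[CT]", N = "[ACGT]")
  pam_re <- paste0("^", paste(iupac_re[strsplit(gq@pam, "")[[1]]],
                              collapse = ""), "$")
  pat <- Biostrings::DNAString(gq@protospacer)
  seedpat <- Biostrings::DNAString(
    substr(gq@protospacer, 20L - gq@seed_length + 1L, 20L))
  out <- list()
  for (cn in names(genomeSeq(genome))) {
    s <- genomeSeq(genome)[[cn]]
    L <- length(s)
    if (L < 23L) next
    for (str in c("+", "-")) {
      subj <- if (str == "+") s else Biostrings::reverseComplement(s)
      n <- L - 22L
      mm <- Biostrings::neditStartingAt(pat, subj, starting.at = 1:n,
                                        with.indels = FALSE)
      mms <- Biostrings::neditStartingAt(
        seedpat, subj, starting.at = (1:n) + (20L - gq@seed_length),
        with.indels = FALSE)
      pams <- as.character(
        Biostrings::Views(subj, start = (1:n) + 20L, width = 3L))
      keep <- which(mm <= gq@max_mismatch_total &
                      mms <= gq@max_seed_mismatch & grepl(pam_re, pams))
      if (length(keep)) {
        st <- if (str == "+") keep else L - keep - 18L
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, start = st, strand = str, mm = mm[keep],
          mms = mms[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), mm = integer(0),
                      mms = integer(0)))
  tb <- do.call(rbind, out)
  tb <- tb[order(tb$chrom, tb$start, tb$strand), ]
  rownames(tb) <- NULL
  tb
}

## site GRanges -> comparable data.frame
sites_table <- function(sites) {
  tb <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites),
    strand = as.character(GenomicRanges::strand(sites)),
    mm = S4Vectors::mcols(sites)$mismatch_total,
    mms = S4Vectors::mcols(sites)$mismatch_seed,
    stringsAsFactors = FALSE)
  tb <- tb[order(tb$chrom, tb$start, tb$strand), ]
  rownames(tb) <- NULL
  tb
}

random_genome <- function(len, seed, name = "rg", chroms = 1L) {
  set.seed(seed)
  seqs <- vapply(seq_len(chroms), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- paste0("chr", seq_len(chroms))
  AnnotatedGenome(seqs, name = name)
}

random_guide <- function(seed, ...) {
  set.seed(seed)
  guideQuery(paste0("g", seed),
             paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
                   collapse = ""), ...)
}
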