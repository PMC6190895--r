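# PAM-aware mismatch-tolerant off-target search and the distance null model

## per-strand scan of one chromosome string; returns a data.frame of hits
## (start = 1-based position of the protospacer's 5' end on the scanned
## strand's coordinates)
scan_strand <- function(chrom_seq, guide) {
  L <- nchar(chrom_seq)
  W <- 23L  # 20-nt protospacer + 3-nt PAM
  if (L < W) return(NULL)
  n <- L - W + 1L
  chars <- strsplit(chrom_seq, "")[[1]]
  g <- strsplit(guide@protospacer, "")[[1]]
  mm <- integer(n)
  mm_seed <- integer(n)
  seed_from <- 20L - guide@seed_length + 1L
  for (k in 1:20) {
    diff <- chars[k:(n + k - 1L)] != g[k]   # N in genome never matches
    mm <- mm + diff
    if (k >= seed_from) mm_seed <- mm_seed + diff
  }
  pam_ok <- rep(TRUE, n)
  p <- strsplit(guide@pam, "")[[1]]
  for (j in 1:3) {
    allowed <- iupac_expand(p[j])  # never includes N: genome N never matches
    pam_ok <- pam_ok & chars[(20L + j):(n + 19L + j)] %in% allowed
  }
  keep <- which(pam_ok & mm <= guide@max_mismatch_total &
                  mm_seed <= guide@max_seed_mismatch)
  if (!length(keep)) return(NULL)
  data.frame(start = keep, mismatch_total = mm[keep],
             mismatch_seed = mm_seed[keep],
             matched = substr(rep(chrom_seq, length(keep)), keep,
                              keep + 19L))
}

#' Predict off-target sites of a guide in a genome
#'
#' Scans both strands of every chromosome for 20-nt windows with an adjacent
#' PAM matching the guide's IUPAC pattern and Hamming mismatch counts within
#' both the total and the PAM-proximal seed budget.  `N` bases never match
#' (neither in the protospacer nor under a PAM `N`).  Perfect on-target
#' matches are reported with `mismatch_total = 0`.
#'
#' @param genome An [AnnotatedGenome-class].
#' @param guide A [GuideQuery-class], or a list of them.
#' @return A [GenomicRanges::GRanges] of protospacer intervals (1-based,
#'   width 20; the PAM lies 3' of the interval in strand orientation) with
#'   metadata columns `guide`, `mismatch_total`, `mismatch_seed` and
#'   `matched` (the protospacer-oriented genomic sequence).
#' @examples
#' g <- AnnotatedGenome(c(chr1 = paste0("TTTT", strrep("ACGT", 5), "TGGAAA")))
#' predictOfftargets(g, guideQuery("sg1", strrep("ACGT", 5)))
#' @export
predictOfftargets <- function(genome, guide) {
  if (is.list(guide)) {
    hits <- lapply(guide, function(gq) predictOfftargets(genome, gq))
    return(do.call(c, unname(hits)))
  }
  out <- list()
  for (cn in names(genomeSeq(genome))) {
    cs <- chromString(genome, cn)
    L <- nchar(cs)
    fw <- scan_strand(cs, guide)
    if (!is.null(fw))
      out[[length(out) + 1L]] <- cbind(fw, chrom = cn, strand = "+",
                                       gstart = fw$start,
                                       gend = fw$start + 19L)
    rv <- scan_strand(revcomp_chr(cs), guide)
    if (!is.null(rv))
      out[[length(out) + 1L]] <- cbind(rv, chrom = cn, strand = "-",
                                       gstart = L - rv$start - 18L,
                                       gend = L - rv$start + 1L)
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      guide = character(0), mismatch_total = integer(0),
      mismatch_seed = integer(0), matched = character(0))
    return(gr)
  }
  tb <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(
    seqnames = tb$chrom,
    ranges = IRanges::IRanges(start = tb$gstart, end = tb$gend),
    strand = tb$strand,
    guide = guide@name,
    mismatch_total = tb$mismatch_total,
    mismatch_seed = tb$mismatch_seed,
    matched = tb$matched)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Consensus of two off-target site lists
#'
#' Keeps sites whose `(chrom, start, strand, guide)` agree in both lists —
#' the two-predictor overlap rule, emulated here by running the search under
#' two parameterizations (externally produced BED site lists can be matched
#' the same way after import).
#'
#' @param a,b `GRanges` from [predictOfftargets()] on the same genome.
#' @return The subset of `a` also present in `b`.
#' @export
consensusSites <- function(a, b) {
  key <- function(gr) paste(GenomicRanges::seqnames(gr),
                            GenomicRanges::start(gr),
                            GenomicRanges::strand(gr),
                            S4Vectors::mcols(gr)$guide)
  a[key(a) %in% key(b)]
}

#' Least distance from positions to off-target sites
#'
#' For each query position, the minimum distance in bp to any site interval,
#' measured as the gap size between position and interval (the IRanges
#' convention): 0 when the position falls inside or immediately abuts a
#' site; position 100 against a site spanning bases 221-240 is 120 bp away.
#' Positions on chromosomes without any site are excluded and counted in
#' the `n_excluded` attribute.
#'
#' @param positions `data.frame` with columns `chrom` and `pos` (1-based).
#' @param sites `GRanges` of sites.
#' @return Numeric vector of distances with attribute `n_excluded`.
#' @export
nearestDistances <- function(positions, sites) {
  if (!length(sites)) stop("empty site list")
  q <- GenomicRanges::GRanges(positions$chrom,
                              IRanges::IRanges(positions$pos,
                                               positions$pos))
  GenomeInfoDb::seqlevels(q) <-
    union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(sites))
  GenomeInfoDb::seqlevels(sites) <- GenomeInfoDb::seqlevels(q)
  hit <- GenomicRanges::distanceToNearest(q, sites, ignore.strand = TRUE)
  d <- rep(NA_real_, length(q))
  d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  out <- d[!is.na(d)]
  attr(out, "n_excluded") <- sum(is.na(d))
  out
}

#' Sample null positions
#'
#' Draws `n` positions uniformly (with replacement by default) from a pool
#' of candidate positions — by default the cohort's called-SNV positions.
#'
#' @param pool `data.frame` with columns `chrom` and `pos`.
#' @param n Number of draws (default 100,000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param replace Sample with replacement (default `TRUE`); without
#'   replacement `n` must not exceed the pool size.
#' @return A `data.frame` of sampled positions.
#' @export
sampleNullPositions <- function(pool, n = 100000L, seed, replace = TRUE) {
  if (!nrow(pool)) stop("empty position pool")
  if (missing(seed)) stop("a seed is required")
  if (!replace && n > nrow(pool))
    stop("cannot draw ", n, " positions without replacement from a pool of ",
         nrow(pool))
  set.seed(seed)
  idx <- sample.int(nrow(pool), n, replace = replace)
  pool[idx, c("chrom", "pos"), drop = FALSE]
}

#' Two-sample Kolmogorov-Smirnov comparison of distance distributions
#'
#' Two-sided two-sample KS test with the asymptotic p-value (distances are
#' integers, so exact small-sample p-values are unavailable under ties).
#'
#' @param observed,null Non-empty numeric distance vectors.
#' @return A list with `statistic` (sup-difference of the empirical CDFs)
#'   and `p_value`.
#' @export
ksCompare <- function(observed, null) {
  if (!length(observed) || !length(null)) stop("empty distance vector")
  kt <- suppressWarnings(ks.test(observed, null, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Bootstrap confidence band of the null distance CDF
#'
#' Percentile bootstrap band of the empirical CDF of the null distances,
#' evaluated on a fixed distance grid.  At `level = 1` the band spans the
#' min/max of the bootstrap CDFs.
#'
#' @param null Numeric null distances.
#' @param level Band level (default 0.95).
#' @param n_boot Bootstrap replicates (default 200).
#' @param grid Distance grid; defaults to the percentiles of `null`.
#' @param seed Integer seed.
#' @return `data.frame` with `grid`, `cdf`, `lower`, `upper`.
#' @export
distanceCIBand <- function(null, level = 0.95, n_boot = 200L, grid = NULL,
                           seed = 1L) {
  if (!length(null)) stop("empty null distances")
  if (is.null(grid))
    grid <- sort(unique(quantile(null, probs = seq(0.01, 0.99, 0.01),
                                 names = FALSE, type = 1)))
  set.seed(seed)
  n <- length(null)
  boot <- matrix(NA_real_, n_boot, length(grid))
  for (b in seq_len(n_boot)) {
    bs <- null[sample.int(n, n, replace = TRUE)]
    boot[b, ] <- vapply(grid, function(x) mean(bs <= x), numeric(1))
  }
  alpha <- (1 - level) / 2
  data.frame(grid = grid,
             cdf = vapply(grid, function(x) mean(null <= x), numeric(1)),
             lower = apply(boot, 2, quantile, probs = alpha, names = FALSE),
             upper = apply(boot, 2, quantile, probs = 1 - alpha,
                           names = FALSE))
}

#' Annotate variants overlapping off-target sites
#'
#' Marks each variant whose reference span intersects a predicted site
#' interval with the guide and mismatch information of the (first) hit, and
#' summarizes annotated counts per guide.
#'
#' @param x A [VariantSet-class].
#' @param sites `GRanges` from [predictOfftargets()].
#' @return A list with `annotated` (the per-variant `data.frame`: key,
#'   `in_site`, `guide`, `mismatch_total`, `mismatch_seed`) and `per_guide`
#'   (named count vector).
#' @export
annotateSiteOverlap <- function(x, sites) {
  tb <- variantTable(x)
  ann <- data.frame(key = variantKeys(x), in_site = FALSE,
                    guide = NA_character_, mismatch_total = NA_integer_,
                    mismatch_seed = NA_integer_)
  if (length(sites) && nrow(tb)) {
    q <- GenomicRanges::GRanges(
      tb$chrom, IRanges::IRanges(tb$pos, tb$pos + nchar(tb$ref) - 1L))
    GenomeInfoDb::seqlevels(q) <-
      union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(sites))
    GenomeInfoDb::seqlevels(sites) <- GenomeInfoDb::seqlevels(q)
    ov <- GenomicRanges::findOverlaps(q, sites, ignore.strand = TRUE)
    first <- !duplicated(S4Vectors::queryHits(ov))
    qi <- S4Vectors::queryHits(ov)[first]
    si <- S4Vectors::subjectHits(ov)[first]
    ann$in_site[qi] <- TRUE
    ann$guide[qi] <- S4Vectors::mcols(sites)$guide[si]
    ann$mismatch_total[qi] <- S4Vectors::mcols(sites)$mismatch_total[si]
    ann$mismatch_seed[qi] <- S4Vectors::mcols(sites)$mismatch_seed[si]
  }
  per_guide <- table(ann$guide[ann$in_site])
  list(annotated = ann, per_guide = per_guide)
}

#' Export off-target sites as BED6+1
#'
#' BED with 0-based half-open intervals: name = guide, score = total
#' mismatches, extra column = seed mismatches.
#'
#' @param sites `GRanges` from [predictOfftargets()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeSitesBed <- function(sites, path) {
  tb <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites) - 1L,
    end = GenomicRanges::end(sites),
    name = S4Vectors::mcols(sites)$guide,
    score = S4Vectors::mcols(sites)$mismatch_total,
    strand = as.character(GenomicRanges::strand(sites)),
    mismatch_seed = S4Vectors::mcols(sites)$mismatch_seed)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
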