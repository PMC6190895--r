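# PAM-aware off-target search and the distance null model

test_that("a planted exact protospacer+PAM is reported at zero mismatches", {
  set.seed(3)
  proto <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  left <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  g <- AnnotatedGenome(c(chr1 = paste0(left, proto, "TGG", right)))
  gq <- guideQuery("g1", proto, max_mismatch_total = 0L,
                   max_seed_mismatch = 0L)
  sites <- predictOfftargets(g, gq)
  hit <- sites[GenomicRanges::start(sites) == 51]
  expect_equal(length(hit), 1L)
  expect_equal(hit$mismatch_total, 0L)
  expect_equal(as.character(GenomicRanges::strand(hit)), "+")
  expect_equal(hit$matched, proto)
})

test_that("budget zero on a genome lacking the protospacer finds nothing", {
  g <- AnnotatedGenome(c(chr1 = strrep("AC", 200)))
  gq <- guideQuery("g1", strrep("GT", 10), max_mismatch_total = 0L,
                   max_seed_mismatch = 0L)
  expect_equal(length(predictOfftargets(g, gq)), 0L)
})

test_that("N bases never match, neither in the protospacer nor under a PAM N", {
  proto <- strrep("AC", 10)   # non-palindromic: no spurious minus-strand hit
  flank <- strrep("C", 30)
  exact <- AnnotatedGenome(c(chr1 = paste0(flank, proto, "TGG", flank)))
  n_in_proto <- AnnotatedGenome(c(chr1 = paste0(
    flank, sub("^A", "N", proto), "TGG", flank)))
  n_in_pam <- AnnotatedGenome(c(chr1 = paste0(flank, proto, "NGG", flank)))
  gq <- guideQuery("g1", proto, max_mismatch_total = 0L,
                   max_seed_mismatch = 0L)
  expect_equal(length(predictOfftargets(exact, gq)), 1L)
  expect_equal(length(predictOfftargets(n_in_proto, gq)), 0L)
  expect_equal(length(predictOfftargets(n_in_pam, gq)), 0L)
})

test_that("the scanner agrees with an independent sliding-window oracle", {
  for (seed in 1:6) {
    g <- random_genome(20000L, seed = 100 + seed)
    gq <- random_guide(seed, pam = sample(c("NGG", "NRG"), 1),
                       max_mismatch_total = sample(3:5, 1),
                       max_seed_mismatch = sample(0:2, 1))
    expect_equal(sites_table(predictOfftargets(g, gq)),
                 oracle_offtargets(g, gq))
  }
})

test_that("searching the reverse-complemented genome swaps strands only", {
  # use a genome with planted sites so the comparison is non-trivial
  cfg <- simulationConfig(rng_seed = 61L,
                          planted_offtarget_spec = list(c(2L, 0L),
                                                        c(4L, 1L)))
  sg <- simulateGenome(cfg)
  g <- sg$genome
  gq <- sg$guides[[1]]
  lens <- setNames(Biostrings::width(genomeSeq(g)), names(genomeSeq(g)))
  rc <- AnnotatedGenome(setNames(as.character(
    Biostrings::reverseComplement(genomeSeq(g))), names(genomeSeq(g))),
    autosome = g@autosome)
  fwd <- sites_table(predictOfftargets(g, gq))
  bwd <- sites_table(predictOfftargets(rc, gq))
  expect_gt(nrow(fwd), 0L)
  # map reverse-genome hits back: start' = L - (start + 19) + 1
  bwd$start <- lens[bwd$chrom] - bwd$start - 18L
  bwd$strand <- ifelse(bwd$strand == "+", "-", "+")
  bwd <- bwd[order(bwd$chrom, bwd$start, bwd$strand), ]
  rownames(bwd) <- NULL
  attr(bwd$start, "names") <- NULL
  expect_equal(bwd, fwd)
})

test_that("site lists are nested in the mismatch budget", {
  g <- random_genome(30000L, seed = 55)
  gq_m <- function(m) random_guide(9, max_mismatch_total = m,
                                   max_seed_mismatch = 2L)
  keys <- function(s) with(sites_table(s), paste(chrom, start, strand))
  prev <- character(0)
  for (m in 2:5) {
    cur <- keys(predictOfftargets(g, gq_m(m)))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("consensus of nested parameterizations equals the stricter list", {
  g <- random_genome(30000L, seed = 56)
  loose <- predictOfftargets(g, random_guide(9, max_mismatch_total = 5L,
                                             max_seed_mismatch = 2L))
  strict <- predictOfftargets(g, random_guide(9, max_mismatch_total = 3L,
                                              max_seed_mismatch = 2L))
  cons <- consensusSites(loose, strict)
  expect_equal(sites_table(cons)[, c("chrom", "start", "strand")],
               sites_table(strict)[, c("chrom", "start", "strand")])
  expect_equal(length(consensusSites(loose, loose)), length(loose))
  empty <- loose[0]
  expect_equal(length(consensusSites(loose, empty)), 0L)
})

test_that("nearest distances use the interval gap convention", {
  sites <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(221, 240),
                                  strand = "+", guide = "g",
                                  mismatch_total = 0L, mismatch_seed = 0L)
  pos <- data.frame(chrom = "chr1", pos = c(100L, 230L, 241L, 500L))
  d <- nearestDistances(pos, sites)
  expect_equal(as.numeric(d), c(120, 0, 0, 259))
  # invariant under site-list permutation
  sites2 <- c(sites, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1000, 1019), strand = "-", guide = "g",
    mismatch_total = 1L, mismatch_seed = 0L))
  expect_equal(as.numeric(nearestDistances(pos, sites2)),
               as.numeric(nearestDistances(pos, rev(sites2))))
  # positions on chromosomes without sites are excluded with a count
  pos2 <- rbind(pos, data.frame(chrom = "chr9", pos = 5L))
  d2 <- nearestDistances(pos2, sites)
  expect_equal(length(d2), 4L)
  expect_equal(attr(d2, "n_excluded"), 1L)
  expect_error(nearestDistances(pos, sites[0]), "empty site list")
})

test_that("null-position sampling is seeded and matches the pool composition", {
  pool <- data.frame(chrom = rep(c("chr1", "chr2"), c(7000, 3000)),
                     pos = seq_len(10000))
  s1 <- sampleNullPositions(pool, 5000, seed = 42)
  s2 <- sampleNullPositions(pool, 5000, seed = 42)
  expect_identical(s1, s2)
  expect_error(sampleNullPositions(pool[0, ], 10, seed = 1), "empty")
  # without replacement at n = pool size: the pool itself
  all_of_it <- sampleNullPositions(pool, nrow(pool), seed = 7,
                                   replace = FALSE)
  expect_setequal(paste(all_of_it$chrom, all_of_it$pos),
                  paste(pool$chrom, pool$pos))
  frac <- mean(s1$chrom == "chr1")
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 5000))
})

test_that("the KS comparison behaves on identical and disjoint samples", {
  x <- rnorm(200)
  same <- ksCompare(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  far <- ksCompare(x, x + 100)
  expect_equal(far$statistic, 1)
  expect_lt(far$p_value, 1e-6)
  expect_error(ksCompare(numeric(0), x), "empty")
})

test_that("the bootstrap CDF band is seeded, ordered and sample-size sensitive", {
  set.seed(2)
  null_big <- rexp(10000, 1 / 500)
  null_small <- sample(null_big, 100)
  b1 <- distanceCIBand(null_big, seed = 5)
  b2 <- distanceCIBand(null_big, seed = 5)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$cdf + 1e-12 & b1$cdf <= b1$upper + 1e-12))
  grid <- quantile(null_big, c(0.25, 0.5, 0.75), names = FALSE)
  wide <- distanceCIBand(null_small, grid = grid, seed = 5)
  narrow <- distanceCIBand(null_big, grid = grid, seed = 5)
  expect_true(all(wide$upper - wide$lower >
                    narrow$upper - narrow$lower))
  full <- distanceCIBand(null_small, level = 1, grid = grid, seed = 5)
  expect_true(all(full$lower <= wide$lower & full$upper >= wide$upper))
})

test_that("variant/off-target overlap annotation respects interval bounds", {
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(221, 240),
                                  strand = "+", guide = "sg1",
                                  mismatch_total = 2L, mismatch_seed = 0L)
  vs <- stack_variants(list(
    passing_spec(pos = 230L),    # inside
    passing_spec(pos = 220L),    # 1 bp before the interval
    passing_spec(pos = 241L)))   # 1 bp after
  ann <- annotateSiteOverlap(vs, sites)
  expect_equal(ann$annotated$in_site, c(TRUE, FALSE, FALSE))
  expect_equal(ann$annotated$guide[1], "sg1")
  expect_equal(unname(ann$per_guide["sg1"]), 1L)
  none <- annotateSiteOverlap(vs, sites[0])
  expect_false(any(none$annotated$in_site))
})
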