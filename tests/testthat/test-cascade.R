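# the de novo filter cascade: stage predicates and end-to-end behaviour

trio3 <- TrioContext("sire1", "dam1", "off1",
                     c("sire1", "dam1", "off1", "coh1"))

test_that("cohort uniqueness keeps offspring-private carriers only", {
  samples <- c("sire1", "dam1", "off1", "coh1")
  specs <- list(
    # private het in the focal offspring: kept
    passing_spec(pos = 10L, geno = c("AA", "AA", "AB", "AA"),
                 depth = rep(30L, 4),
                 pl = rep(list(c(0, 60, 90)), 4), scf = rep(0.01, 4)),
    # het shared with a parent: inherited, removed
    passing_spec(pos = 20L, geno = c("AB", "AA", "AB", "AA"),
                 depth = rep(30L, 4),
                 pl = rep(list(c(0, 60, 90)), 4), scf = rep(0.01, 4)),
    # het shared with another cohort member: removed
    passing_spec(pos = 30L, geno = c("AA", "AA", "AB", "AB"),
                 depth = rep(30L, 4),
                 pl = rep(list(c(0, 60, 90)), 4), scf = rep(0.01, 4)),
    # missing focal genotype: removed at this stage
    passing_spec(pos = 40L, geno = c("AA", "AA", NA, "AA"),
                 depth = rep(30L, 4),
                 pl = rep(list(c(0, 60, 90)), 4), scf = rep(0.01, 4)))
  vs <- stack_variants(specs, samples = samples)
  out <- stageCohortUnique(vs, trio3)
  expect_equal(variantKeys(out), "chr1:10:A:G")
})

test_that("known-database subtraction is a set difference on keys", {
  vs <- stack_variants(lapply(c(10L, 20L, 30L), function(p)
    passing_spec(pos = p)))
  expect_equal(length(stageKnownDb(vs, KnownVariants(character(0)))), 3L)
  expect_equal(length(stageKnownDb(vs, KnownVariants(variantKeys(vs)))), 0L)
  set.seed(1)
  pos <- sample(1000:9999, 100)
  vs100 <- stack_variants(lapply(pos, function(p) passing_spec(pos = p)))
  db <- KnownVariants(variantKey("chr1", pos[1:37], "A", "G"))
  expect_equal(length(stageKnownDb(vs100, db)), 63L)
})

test_that("depth stage applies the parental minimum and offspring fraction", {
  dp <- function(s, d, o) passing_spec(pos = 50L, depth = c(s, d, o))
  run1 <- function(sp) length(stageDepth(stack_variants(list(sp)), trio3))
  expect_equal(run1(dp(11L, 30L, 20L)), 0L)  # parent below 12: removed
  expect_equal(run1(dp(30L, 11L, 20L)), 0L)
  expect_equal(run1(dp(12L, 12L, 3L)), 1L)   # 10*3 >= 24: boundary passes
  expect_equal(run1(dp(12L, 12L, 2L)), 0L)   # 20 < 24: removed
  expect_equal(run1(dp(20L, 20L, 4L)), 1L)   # exactly 1/10: equality passes
  expect_equal(run1(dp(20L, 20L, 3L)), 0L)
  expect_equal(run1(passing_spec(pos = 50L,
                                 depth = c(NA, 30L, 20L))), 0L)
})

test_that("PL stage demands the de novo likelihood configuration", {
  pls <- function(off, sire = c(0, 60, 90), dam = c(0, 45, 80))
    passing_spec(pos = 60L, pl = list(sire, dam, off))
  run1 <- function(sp) length(stagePL(stack_variants(list(sp)), trio3))
  expect_equal(run1(pls(c(40, 0, 25))), 1L)
  expect_equal(run1(pls(c(15, 0, 25))), 0L)  # AA evidence too weak (<= 20)
  expect_equal(run1(pls(c(21, 0, 25))), 1L)  # strict > 20
  expect_equal(run1(pls(c(40, 0, 0))), 0L)   # BB must be > 0
  expect_equal(run1(pls(c(40, 0, 25), sire = c(0, 12, 80))), 0L)
  expect_equal(run1(pls(c(40, 0, 25), dam = c(0, 60, 12))), 0L)
  expect_equal(suppressWarnings(run1(pls(c(40, 0, 25),
                                         sire = c(5, 60, 90)))), 0L)
})

test_that("soft-clip stage removes only fractions strictly above the bound", {
  sc <- function(x) passing_spec(pos = 70L, scf = c(0.01, 0.01, x))
  run1 <- function(sp) length(stageSoftclip(stack_variants(list(sp)),
                                            trio3))
  expect_equal(run1(sc(0.05)), 1L)
  expect_equal(run1(sc(0.15)), 0L)
  expect_equal(run1(sc(0.10)), 1L)   # exactly 10% passes (strict >)
  expect_warning(n <- run1(sc(NA)), "without SCF")
  expect_equal(n, 1L)
  set.seed(9)
  pos <- sample(200:900, 20)
  scf_vals <- c(runif(14, 0, 0.10), runif(6, 0.11, 0.5))
  vs <- stack_variants(lapply(seq_along(pos), function(i)
    sc_sp <- passing_spec(pos = pos[i],
                          scf = c(0.01, 0.01, scf_vals[i]))))
  expect_equal(length(stageSoftclip(vs, trio3)), 14L)
})

test_that("review flags homopolymer context without removing candidates", {
  g <- AnnotatedGenome(
    c(chr1 = paste0("ACGTACGTAC", strrep("T", 12), "GACGTACGTACGATCGATCG",
                    "ACGATCGGCT")))
  # variant inside the 12-bp homopolymer (pos 15), and an isolated one far
  # from it (pos 40, non-repetitive context)
  vs <- stack_variants(list(passing_spec(pos = 15L, ref = "T", alt = "G"),
                            passing_spec(pos = 40L, ref = "T", alt = "C")))
  out <- stageReview(vs, g, filterCriteria(cluster_bp = 10L))
  expect_equal(length(out$set), 2L)           # default: flags only
  expect_true(out$annotations$homopolymer[1])
  expect_false(out$annotations$flagged[2])
  strict <- stageReview(vs, g, filterCriteria(cluster_bp = 10L,
                                              strict_review = TRUE))
  expect_equal(variantKeys(strict$set), "chr1:40:T:C")
  expect_lte(length(strict$set), length(vs))  # flags never add candidates
})

test_that("planted de novo events are fully recovered and artifacts removed at their designed stages", {
  cfg <- simulationConfig(
    rng_seed = 21L,
    artifact_counts = c(low_depth = 3, allelic_imbalance = 3,
                        pl_inconsistent = 3, high_softclip = 3,
                        in_database = 3, cohort_shared = 3))
  sg <- simulateGenome(cfg)
  sim <- simulateTrioCallsets(cfg, sg)
  res <- runCascade(sim$caller_a, sim$caller_b, sim$trio, sim$db,
                    sg$genome)
  tr <- traceTable(res$trace)
  cnt <- function(st) tr$count[tr$stage == st]
  # every planted de novo SNV survives to the candidate set
  expect_true(all(sim$truth$denovo_snv_keys %in%
                    variantKeys(res$candidates)))
  # each stage removes exactly its designed artifact class
  expect_equal(cnt("cohort_unique") - cnt("known_db"), 3)
  expect_equal(cnt("known_db") - cnt("depth_allelic"), 6)
  expect_equal(cnt("depth_allelic") - cnt("pl_pattern"), 3)
  expect_equal(cnt("pl_pattern") - cnt("softclip"), 3)
  expect_equal(cnt("softclip"), cfg$true_denovo_count)
  # no artifact key survives
  expect_length(intersect(unlist(sim$truth$artifact_keys),
                          variantKeys(res$candidates)), 0)
  # trace is non-increasing from the intersection stage on
  i0 <- which(tr$stage == "intersection")
  expect_true(all(diff(tr$count[i0:nrow(tr)]) <= 0))
})

test_that("the cascade matches an independent per-variant predicate", {
  for (seed in c(5L, 6L)) {
    cfg <- simulationConfig(
      rng_seed = seed, caller_discordance_rate = 0.1,
      artifact_counts = c(low_depth = 2, allelic_imbalance = 2,
                          pl_inconsistent = 2, high_softclip = 2,
                          in_database = 2, cohort_shared = 2))
    sg <- simulateGenome(cfg)
    sim <- simulateTrioCallsets(cfg, sg)
    res <- runCascade(sim$caller_a, sim$caller_b, sim$trio, sim$db,
                      sg$genome)
    a_snv <- sim$caller_a[sim$caller_a@vclass == "SNV"]
    b_snv <- sim$caller_b[sim$caller_b@vclass == "SNV"]
    expect_setequal(variantKeys(res$candidates),
                    brute_denovo_keys(a_snv, b_snv, sim$trio, sim$db))
  }
})

test_that("permuting the per-variant filter stages leaves the final set unchanged", {
  cfg <- simulationConfig(
    rng_seed = 31L,
    artifact_counts = c(low_depth = 2, allelic_imbalance = 2,
                        pl_inconsistent = 2, high_softclip = 2,
                        in_database = 2, cohort_shared = 2))
  sg <- simulateGenome(cfg)
  sim <- simulateTrioCallsets(cfg, sg)
  crit <- filterCriteria()
  base <- intersectCallsets(sim$caller_a[sim$caller_a@vclass == "SNV"],
                            sim$caller_b[sim$caller_b@vclass == "SNV"])
  stages <- list(
    unique = function(v) stageCohortUnique(v, sim$trio),
    db = function(v) stageKnownDb(v, sim$db),
    depth = function(v) stageDepth(v, sim$trio, crit),
    pl = function(v) stagePL(v, sim$trio, crit),
    scf = function(v) stageSoftclip(v, sim$trio, crit))
  apply_order <- function(ord) {
    out <- base
    for (s in ord) out <- stages[[s]](out)
    sort(variantKeys(out))
  }
  ref_keys <- apply_order(names(stages))
  set.seed(1)
  for (i in 1:5)
    expect_equal(apply_order(sample(names(stages))), ref_keys)
})

test_that("empty caller sets give an all-zero trace", {
  cfg <- simulationConfig(rng_seed = 2L)
  sg <- simulateGenome(cfg)
  sim <- simulateTrioCallsets(cfg, sg)
  e <- emptyVariantSet(sim$samples)
  res <- runCascade(e, e, sim$trio, sim$db, sg$genome)
  expect_true(all(traceTable(res$trace)$count == 0))
})

test_that("indels run through the identical cascade", {
  cfg <- simulationConfig(rng_seed = 13L, true_denovo_indel_count = 4L)
  sg <- simulateGenome(cfg)
  sim <- simulateTrioCallsets(cfg, sg)
  res <- runCascade(sim$caller_a, sim$caller_b, sim$trio, sim$db,
                    sg$genome, vclass = "INDEL")
  expect_setequal(variantKeys(res$candidates),
                  sim$truth$denovo_indel_keys)
  expect_equal(res$mu_alpha, 4L)
})
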