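# the seven-stage de novo filter cascade
#
# Stage order (the published filtering-summary order): caller intersection,
# cohort uniqueness, known-database subtraction, parental depth / allelic
# balance, PL patterns, soft-clip fraction, context review flags.  Stages
# 2-6 are pure per-variant predicates, so their order affects only the
# trace, never the final set.

#' Filter criteria of the de novo cascade
#'
#' Thresholds of the cascade stages.  Removal conditions are strict
#' inequalities as published (parent depth `< 12`, offspring depth `< 1/10`
#' of the summed parental depth, soft-clip fraction `> 10%`), so equality at
#' a boundary passes.  The depth fraction is compared in exact integer
#' arithmetic (`10 * offspring >= sire + dam`).
#'
#' @param min_parent_depth Minimum read depth in each parent (default 12).
#' @param offspring_depth_den Denominator of the offspring fraction rule:
#'   offspring depth must be at least `1/offspring_depth_den` of the summed
#'   parental depth (default 10).
#' @param pl_threshold PL threshold for the "confident" likelihood entries
#'   (default 20): offspring pattern (AA, AB, BB) = (> t, = 0, > 0), parent
#'   pattern = (= 0, > t, > t).
#' @param max_softclip Maximum offspring soft-clip fraction (default 0.10).
#' @param homopolymer_min Review flag: minimum homopolymer run length
#'   containing or abutting the variant (default 8).
#' @param cluster_bp Review flag: another surviving candidate within this
#'   many bp (default 100).
#' @param n_proximity_bp Review flag: an `N` reference base within this many
#'   bp (default 20).
#' @param strict_review If `TRUE`, flagged candidates are removed at the
#'   review stage; by default review only annotates.
#' @return A named list of class `filter_criteria`.
#' @export
filterCriteria <- function(min_parent_depth = 12L, offspring_depth_den = 10L,
                           pl_threshold = 20, max_softclip = 0.10,
                           homopolymer_min = 8L, cluster_bp = 100L,
                           n_proximity_bp = 20L, strict_review = FALSE) {
  stopifnot(min_parent_depth >= 0, offspring_depth_den >= 1,
            pl_threshold >= 0, max_softclip >= 0, max_softclip <= 1)
  structure(list(min_parent_depth = as.integer(min_parent_depth),
                 offspring_depth_den = as.integer(offspring_depth_den),
                 pl_threshold = pl_threshold, max_softclip = max_softclip,
                 homopolymer_min = as.integer(homopolymer_min),
                 cluster_bp = as.integer(cluster_bp),
                 n_proximity_bp = as.integer(n_proximity_bp),
                 strict_review = isTRUE(strict_review)),
            class = "filter_criteria")
}

role_col <- function(x, id) {
  i <- match(id, sampleIds(x))
  if (is.na(i)) stop("sample '", id, "' absent from call set")
  i
}

#' Cohort-uniqueness stage
#'
#' Keeps variants whose alternate allele is carried (het or hom) by the
#' focal offspring and by no other cohort member, parents included.  A
#' missing offspring genotype excludes the variant here (first stage that
#' inspects it); a missing genotype in a non-focal cohort member is treated
#' as non-carrying.
#'
#' @param x A [VariantSet-class] containing all cohort samples.
#' @param trio A [TrioContext-class].
#' @return The surviving subset of `x`.
#' @export
stageCohortUnique <- function(x, trio) {
  oi <- role_col(x, trio@offspring)
  others <- setdiff(intersect(trio@cohort, sampleIds(x)), trio@offspring)
  if (length(x) == 0L) return(x)
  g <- genotypes(x)
  carrier <- !is.na(g[, oi]) & g[, oi] %in% c("AB", "BB")
  og <- g[, others, drop = FALSE]
  none_other <- rowSums(!is.na(og) & (og == "AB" | og == "BB")) == 0L
  x[carrier & none_other]
}

#' Known-database stage
#'
#' Removes variants whose normalized key exists in the known-variant
#' database (set difference on keys).
#'
#' @param x A [VariantSet-class].
#' @param db A [KnownVariants-class].
#' @return The surviving subset of `x`.
#' @export
stageKnownDb <- function(x, db) {
  x[!(variantKeys(x) %in% dbKeys(db))]
}

#' Depth / allelic-balance stage
#'
#' Keeps variants where both parents have depth at least
#' `min_parent_depth` and the offspring depth is at least
#' `1/offspring_depth_den` of the summed parental depth (exact integer
#' comparison).  Missing depths are excluded here.
#'
#' @param x A [VariantSet-class].
#' @param trio A [TrioContext-class].
#' @param criteria A [filterCriteria()] list.
#' @return The surviving subset of `x`.
#' @export
stageDepth <- function(x, trio, criteria = filterCriteria()) {
  if (length(x) == 0L) return(x)
  d <- depths(x)
  ds <- d[, role_col(x, trio@sire)]
  dd <- d[, role_col(x, trio@dam)]
  do <- d[, role_col(x, trio@offspring)]
  keep <- !is.na(ds) & !is.na(dd) & !is.na(do) &
    ds >= criteria$min_parent_depth & dd >= criteria$min_parent_depth &
    criteria$offspring_depth_den * do >= (ds + dd)
  x[keep]
}

#' PL-pattern stage
#'
#' Keeps variants whose normalized PL triples match the de novo
#' configuration: offspring (AA, AB, BB) = (> t, = 0, > 0) — confident het
#' with the alternate allele — and each parent (= 0, > t, > t) — confident
#' hom-ref.  Triples without a zero entry (non-normalized) or with missing
#' values are excluded with a warning count.
#'
#' @inheritParams stageDepth
#' @return The surviving subset of `x`.
#' @export
stagePL <- function(x, trio, criteria = filterCriteria()) {
  if (length(x) == 0L) return(x)
  t <- criteria$pl_threshold
  p <- plArray(x)
  oi <- role_col(x, trio@offspring)
  si <- role_col(x, trio@sire)
  di <- role_col(x, trio@dam)
  norm_ok <- function(i) {
    m <- p[, i, , drop = FALSE]
    !apply(m, 1, anyNA) & apply(m, 1, function(v) any(v == 0))
  }
  nn <- norm_ok(oi) & norm_ok(si) & norm_ok(di)
  if (any(!nn))
    warning(sum(!nn), " variant(s) with missing or non-normalized PL ",
            "triples excluded at the PL stage")
  off_ok <- p[, oi, 1] > t & p[, oi, 2] == 0 & p[, oi, 3] > 0
  par_ok <- function(i) p[, i, 1] == 0 & p[, i, 2] > t & p[, i, 3] > t
  x[nn & off_ok & par_ok(si) & par_ok(di)]
}

#' Soft-clip stage
#'
#' Removes variants whose offspring mean soft-clip fraction exceeds
#' `max_softclip` (strict `>`, so SCF exactly at the bound passes).  Missing
#' SCF passes with a warning: the field is optional in the VCF contract.
#'
#' @inheritParams stageDepth
#' @return The surviving subset of `x`.
#' @export
stageSoftclip <- function(x, trio, criteria = filterCriteria()) {
  if (length(x) == 0L) return(x)
  scf <- softclip(x)[, role_col(x, trio@offspring)]
  if (anyNA(scf))
    warning(sum(is.na(scf)), " variant(s) without SCF pass the soft-clip ",
            "stage unfiltered")
  x[is.na(scf) | scf <= criteria$max_softclip]
}

## longest homopolymer run containing or immediately abutting position pos
homopolymer_run_at <- function(chrom_seq, pos) {
  L <- nchar(chrom_seq)
  run_len <- function(p) {
    if (p < 1L || p > L) return(0L)
    b <- substr(chrom_seq, p, p)
    lo <- p; hi <- p
    while (lo > 1L && substr(chrom_seq, lo - 1L, lo - 1L) == b) lo <- lo - 1L
    while (hi < L && substr(chrom_seq, hi + 1L, hi + 1L) == b) hi <- hi + 1L
    hi - lo + 1L
  }
  max(run_len(pos), run_len(pos - 1L), run_len(pos + 1L))
}

#' Context-review stage
#'
#' Automated proxy for manual review: flags candidates sitting inside long
#' homopolymer runs, close to another surviving candidate, or close to an
#' `N` reference base.  By default flags are reported but nothing is
#' removed; with `strict_review = TRUE` flagged candidates are dropped.
#'
#' @param x A [VariantSet-class] of surviving candidates.
#' @param genome An [AnnotatedGenome-class].
#' @param criteria A [filterCriteria()] list.
#' @return A list with `set` (the retained [VariantSet-class]) and
#'   `annotations` (a `data.frame` with per-candidate flags: `homopolymer`,
#'   `clustered`, `near_n`, `flagged`, plus the run length and nearest
#'   candidate distance).
#' @export
stageReview <- function(x, genome, criteria = filterCriteria()) {
  n <- length(x)
  ann <- data.frame(key = variantKeys(x),
                    homopolymer_run = integer(n),
                    nearest_candidate_bp = rep(NA_integer_, n),
                    homopolymer = logical(n), clustered = logical(n),
                    near_n = logical(n))
  for (i in seq_len(n)) {
    cs <- chromString(genome, x@chrom[i])
    ann$homopolymer_run[i] <- homopolymer_run_at(cs, x@pos[i])
    same <- which(x@chrom == x@chrom[i])
    same <- setdiff(same, i)
    if (length(same))
      ann$nearest_candidate_bp[i] <- min(abs(x@pos[same] - x@pos[i]))
    win_lo <- max(1L, x@pos[i] - criteria$n_proximity_bp)
    win_hi <- min(nchar(cs), x@pos[i] + criteria$n_proximity_bp)
    ann$near_n[i] <- grepl("N", substr(cs, win_lo, win_hi), fixed = TRUE)
  }
  ann$homopolymer <- ann$homopolymer_run >= criteria$homopolymer_min
  ann$clustered <- !is.na(ann$nearest_candidate_bp) &
    ann$nearest_candidate_bp <= criteria$cluster_bp
  ann$flagged <- ann$homopolymer | ann$clustered | ann$near_n
  set <- if (criteria$strict_review) x[!ann$flagged] else x
  list(set = set, annotations = ann)
}

#' Run the full de novo filter cascade for one trio
#'
#' Applies, in order: caller intersection, cohort uniqueness,
#' known-database subtraction, parental depth / allelic balance, PL
#' patterns, soft-clip fraction, and context-review flagging, recording the
#' surviving count after every stage.  The count after the soft-clip stage
#' is the candidate de novo count fed to the mutation-rate estimator
#' (`mu_alpha`); review flags are reported without removal unless
#' `strict_review` is set.
#'
#' @param caller_a,caller_b [VariantSet-class] objects from the two
#'   independent callers, normalized against `genome`; calls are taken from
#'   `caller_a`.
#' @param trio A [TrioContext-class].
#' @param db A [KnownVariants-class].
#' @param genome An [AnnotatedGenome-class].
#' @param criteria A [filterCriteria()] list.
#' @param vclass `"SNV"` or `"INDEL"`; the cascade runs on one class.
#' @return A list with elements `candidates` ([VariantSet-class]),
#'   `trace` ([FilterTrace-class]), `review` (annotation `data.frame`) and
#'   `mu_alpha` (candidate count after the soft-clip stage).
#' @examples
#' cfg <- simulationConfig(rng_seed = 7L)
#' sg <- simulateGenome(cfg)
#' sim <- simulateTrioCallsets(cfg, sg)
#' res <- runCascade(sim$caller_a, sim$caller_b, sim$trio, sim$db,
#'                   sg$genome)
#' res$trace
#' @export
runCascade <- function(caller_a, caller_b, trio, db, genome,
                       criteria = filterCriteria(), vclass = "SNV") {
  vclass <- match.arg(vclass, c("SNV", "INDEL"))
  a <- caller_a[caller_a@vclass == vclass]
  b <- caller_b[caller_b@vclass == vclass]
  counts <- c(caller_a = length(a), caller_b = length(b))
  s <- intersectCallsets(a, b)
  counts["intersection"] <- length(s)
  s <- stageCohortUnique(s, trio)
  counts["cohort_unique"] <- length(s)
  s <- stageKnownDb(s, db)
  counts["known_db"] <- length(s)
  s <- stageDepth(s, trio, criteria)
  counts["depth_allelic"] <- length(s)
  s <- stagePL(s, trio, criteria)
  counts["pl_pattern"] <- length(s)
  s <- stageSoftclip(s, trio, criteria)
  counts["softclip"] <- length(s)
  mu_alpha <- length(s)
  rev <- stageReview(s, genome, criteria)
  counts["review_pass"] <- sum(!rev$annotations$flagged)
  trace <- FilterTrace(
    data.frame(stage = names(counts), count = as.integer(counts),
               row.names = NULL),
    offspring = trio@offspring, caller_a = a@caller, caller_b = b@caller,
    vclass = vclass)
  list(candidates = rev$set, trace = trace, review = rev$annotations,
       mu_alpha = mu_alpha)
}
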