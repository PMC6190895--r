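# effective genome size, mutation-rate estimation, substitution spectrum

#' Effective genome size from coverage windows
#'
#' Counts fixed-size windows whose mean depth lies inside the callable range
#' (both bounds inclusive) and multiplies by the window size to obtain the
#' effective genome size `R`, the denominator of the mutation-rate
#' estimator.  Sex chromosomes are excluded by default.
#'
#' @param windows `data.frame` with columns `chrom`, `start` (0-based),
#'   `end`, `mean_depth`; all windows must have the same size.
#' @param autosome Named logical autosome flags, or an
#'   [AnnotatedGenome-class] from which they are taken; ignored when
#'   `autosomes_only = FALSE`.
#' @param window_size Window size in bp (default 10,000); checked against
#'   the table.
#' @param min_cov,max_cov Inclusive depth bounds (defaults 13 and 130).
#' @param autosomes_only Restrict to autosomal windows (default `TRUE`).
#' @return An [EffectiveGenome-class].
#' @examples
#' w <- data.frame(chrom = "chr1", start = 0:4 * 1e4, end = 1:5 * 1e4,
#'                 mean_depth = c(5, 40, 36, 131, 20))
#' effectiveGenome(w, autosome = c(chr1 = TRUE))
#' @export
effectiveGenome <- function(windows, autosome = NULL, window_size = 10000,
                            min_cov = 13, max_cov = 130,
                            autosomes_only = TRUE) {
  sizes <- unique(windows$end - windows$start)
  if (length(sizes) > 1L)
    stop("inconsistent window sizes in table: ",
         paste(sizes, collapse = ","))
  if (length(sizes) == 1L && sizes != window_size)
    stop("table windows are ", sizes, " bp, expected ", window_size)
  keep <- windows$mean_depth >= min_cov & windows$mean_depth <= max_cov
  if (autosomes_only) {
    if (is(autosome, "AnnotatedGenome")) autosome <- autosome@autosome
    if (is.null(autosome))
      stop("autosome flags are required when autosomes_only = TRUE")
    flag <- autosome[windows$chrom]
    if (anyNA(flag))
      stop("window chromosomes without autosome flag: ",
           paste(unique(windows$chrom[is.na(flag)]), collapse = ","))
    keep <- keep & flag
  }
  n <- sum(keep)
  new("EffectiveGenome", window_size = window_size, min_cov = min_cov,
      max_cov = max_cov, n_windows_pass = n, R = n * window_size,
      autosomes_only = autosomes_only)
}

#' Per-generation mutation rate from a candidate count
#'
#' The per-base-pair per-generation germline rate is the candidate de novo
#' count divided by twice the effective genome size (the factor 2 accounts
#' for diploidy): `mu_g = mu_alpha / (2 R)`.
#'
#' @param mu_alpha Candidate de novo count (the cascade's post-soft-clip
#'   count).
#' @param eg An [EffectiveGenome-class] (or the numeric `R` in bp).
#' @param offspring Optional offspring label.
#' @return A one-row `data.frame` with `offspring`, `mu_alpha`, `R`, `mu_g`
#'   (raw rate), `mu_g_1e8` (rate in 1e-8 units) and `mu_g_1e8_rounded`
#'   (half-up at two decimals, the table presentation convention).
#' @examples
#' mutationRate(53, 2457220000)
#' @export
mutationRate <- function(mu_alpha, eg, offspring = NA_character_) {
  R <- if (is(eg, "EffectiveGenome")) effectiveSize(eg) else as.numeric(eg)
  if (!is.finite(R) || R <= 0)
    stop("effective genome size R must be positive; got ", R)
  if (mu_alpha < 0) stop("mu_alpha must be non-negative")
  mu_g <- mu_alpha / (2 * R)
  data.frame(offspring = offspring, mu_alpha = mu_alpha, R = R,
             mu_g = mu_g, mu_g_1e8 = mu_g * 1e8,
             mu_g_1e8_rounded = round_half_up(mu_g * 1e8, 2))
}

#' Mean mutation rate across offspring
#'
#' @param estimates A `data.frame` of [mutationRate()] rows, or a numeric
#'   vector of `mu_g` values.
#' @return The arithmetic mean rate (per bp per generation).
#' @export
meanRate <- function(estimates) {
  x <- if (is.data.frame(estimates)) estimates$mu_g else as.numeric(estimates)
  if (!length(x)) stop("no rate estimates supplied")
  mean(x)
}

SPECTRUM_CLASSES <- c("T>G", "T>C", "T>A", "G>T", "G>A", "C>T",
                      "A>T", "A>G", "A>C")

#' Classify a substitution into the nine-class spectrum
#'
#' Maps each of the 12 ordered single-base substitutions onto the nine-class
#' scheme used for spectrum reporting (`T>G, T>C, T>A, G>T, G>A, C>T, A>T,
#' A>G, A>C`).  Of the three types not listed, `C>A` folds onto its reverse
#' complement `G>T`; the complementary pair `C>G`/`G>C` has no listed
#' representative and both fold onto a single configurable target (default
#' `G>A`, the listed class sharing the `G` reference base).  The `"full12"`
#' scheme returns the raw ordered type.
#'
#' @param ref,alt Single reference/alternate bases (vectors allowed).
#' @param scheme `"paper9"` (default) or `"full12"`.
#' @param cg_target Fold target for `C>G`/`G>C` under `"paper9"`.
#' @return Character vector of class labels.
#' @examples
#' classifySubstitution("C", "T")
#' classifySubstitution("C", "A")   # folds to G>T
#' @export
classifySubstitution <- function(ref, alt, scheme = c("paper9", "full12"),
                                 cg_target = "G>A") {
  scheme <- match.arg(scheme)
  if (!length(ref)) return(character(0))
  ref <- toupper(ref); alt <- toupper(alt)
  if (!all(ref %in% BASES) || !all(alt %in% BASES))
    stop("ref and alt must be single A/C/G/T bases")
  if (any(ref == alt)) stop("ref and alt must differ")
  type <- paste0(ref, ">", alt)
  if (scheme == "full12") return(type)
  if (!cg_target %in% SPECTRUM_CLASSES)
    stop("cg_target must be one of the nine listed classes")
  fold <- function(tt) {
    rc <- paste0(chartr("ACGT", "TGCA", substr(tt, 1, 1)), ">",
                 chartr("ACGT", "TGCA", substr(tt, 3, 3)))
    ifelse(tt %in% SPECTRUM_CLASSES, tt,
           ifelse(rc %in% SPECTRUM_CLASSES, rc, cg_target))
  }
  fold(type)
}

#' Substitution-spectrum counts and proportions
#'
#' Tabulates SNV substitution classes per group (animal, trio, or
#' parental-side pool) and converts to proportions.  Non-SNV records are
#' skipped with a count.
#'
#' @param ref,alt Allele vectors, or a [VariantSet-class] as `ref` (then
#'   `alt` is ignored).
#' @param group Optional grouping factor (one value per variant); `NULL`
#'   pools everything into one group.
#' @param scheme,cg_target Passed to [classifySubstitution()].
#' @return A list with `counts` (classes x groups matrix), `proportions`
#'   (same shape; columns sum to 1, `NaN` for empty groups) and `n_skipped`
#'   (non-SNV records).
#' @export
mutationSpectrum <- function(ref, alt = NULL, group = NULL,
                             scheme = "paper9", cg_target = "G>A") {
  if (is(ref, "VariantSet")) {
    vs <- ref
    keep <- vs@vclass == "SNV"
    n_skipped <- sum(!keep)
    ref <- vs@ref[keep]; alt <- vs@alt[keep]
    if (!is.null(group)) group <- group[keep]
  } else {
    snv <- nchar(ref) == 1L & nchar(alt) == 1L
    n_skipped <- sum(!snv)
    if (!is.null(group)) group <- group[snv]
    ref <- ref[snv]; alt <- alt[snv]
  }
  classes <- if (scheme == "full12") {
    as.vector(t(outer(BASES, BASES, paste, sep = ">")))[
      as.vector(t(outer(BASES, BASES, "!=")))]
  } else SPECTRUM_CLASSES
  if (is.null(group)) group <- rep("all", length(ref))
  group <- if (length(ref)) factor(group) else
    factor(character(0), levels = "all")
  cls <- factor(classifySubstitution(ref, alt, scheme, cg_target),
                levels = classes)
  counts <- table(class = cls, group = group)
  counts <- matrix(counts, nrow = length(classes),
                   dimnames = list(classes, levels(group)))
  props <- sweep(counts, 2, colSums(counts), "/")
  list(counts = counts, proportions = props, n_skipped = n_skipped)
}

#' Compare two spectrum profiles with a paired t-test
#'
#' Pairs the per-class proportions of two profiles (e.g. parents vs
#' offspring) and applies a two-sided paired Student's t-test across the
#' classes.  Note that when both profiles are complete compositions the
#' paired differences sum to zero by construction, so the mean difference is
#' identically zero and the test is extremely insensitive (statistic near 0,
#' p near 1); it can only flag gross bookkeeping mismatches, not spectrum
#' shape differences.  When every paired difference is zero the degenerate
#' result (statistic 0, p 1) is returned directly.
#'
#' @param parent,offspring Named numeric vectors of per-class proportions on
#'   identical class sets (order-insensitive), or one-column `proportions`
#'   matrices from [mutationSpectrum()].
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
compareSpectra <- function(parent, offspring) {
  as_vec <- function(p) if (is.matrix(p)) setNames(p[, 1], rownames(p)) else p
  p1 <- as_vec(parent); p2 <- as_vec(offspring)
  if (is.null(names(p1)) || is.null(names(p2)) ||
      !setequal(names(p1), names(p2)))
    stop("profiles must carry identical class-name sets")
  p2 <- p2[names(p1)]
  d <- p1 - p2
  if (all(abs(d) < .Machine$double.eps * 100))
    return(list(statistic = 0, df = length(d) - 1L, p_value = 1))
  tt <- t.test(p1, p2, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
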