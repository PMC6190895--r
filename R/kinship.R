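# kinship-based pedigree validation
#
# Pairwise kinship is estimated with the within-pair robust
# heterozygosity-concordance estimator (the KING-robust family):
#
#   phi_hat = (N_AaAa - 2 N_AA,aa) / (N_Aa(i) + N_Aa(j))
#
# over sites genotyped in both individuals, where N_AaAa counts shared
# heterozygotes, N_AA,aa opposite homozygotes, and N_Aa(.) per-individual
# heterozygotes.  The estimator needs no allele-frequency estimates and is
# invariant to allele-label flips.

#' Pairwise kinship matrix from cohort genotypes
#'
#' @param genotypes Integer matrix, sites x samples, coded as alternate
#'   allele counts (0/1/2, `NA` for missing); or a [VariantSet-class],
#'   whose genotypes are recoded.
#' @param min_sites Warn when a pair shares fewer informative sites
#'   (default 100).
#' @return A [KinshipMatrix-class].  Self-kinship is reported as 0.5 by
#'   convention; pairs without shared non-missing sites get `NA` with a
#'   warning.
#' @examples
#' G <- simulateGenotypes(
#'   data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
#'              dam = c(NA, NA, "d")), n_sites = 2000, seed = 1)
#' kinshipCoefficients(kinshipMatrix(G))
#' @export
kinshipMatrix <- function(genotypes, min_sites = 100L) {
  if (is(genotypes, "VariantSet")) {
    g <- genotypes(genotypes)
    G <- matrix(match(g, c("AA", "AB", "BB")) - 1L, nrow = nrow(g),
                dimnames = dimnames(g))
  } else {
    G <- genotypes
  }
  samples <- colnames(G) %||% paste0("S", seq_len(ncol(G)))
  ns <- length(samples)
  phi <- matrix(NA_real_, ns, ns, dimnames = list(samples, samples))
  nmat <- matrix(0L, ns, ns, dimnames = list(samples, samples))
  diag(phi) <- 0.5
  diag(nmat) <- colSums(!is.na(G))
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      ok <- !is.na(G[, i]) & !is.na(G[, j])
      gi <- G[ok, i]; gj <- G[ok, j]
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      het_i <- sum(gi == 1L); het_j <- sum(gj == 1L)
      if (sum(ok) == 0L || het_i + het_j == 0L) {
        warning("no informative shared sites for pair ", samples[i], "/",
                samples[j])
        next
      }
      if (sum(ok) < min_sites)
        warning("only ", sum(ok), " shared sites for pair ", samples[i],
                "/", samples[j])
      n_hethet <- sum(gi == 1L & gj == 1L)
      n_opp <- sum(abs(gi - gj) == 2L)
      phi[i, j] <- phi[j, i] <- (n_hethet - 2 * n_opp) / (het_i + het_j)
    }
  }
  new("KinshipMatrix", phi = phi, n_sites = nmat, samples = samples)
}

#' Validate a declared trio against estimated kinship
#'
#' Passes when both parent-offspring kinship coefficients fall inside the
#' first-degree window (default `[0.177, 0.354]`, the standard powers-of-two
#' inference bins).  The sire-dam kinship is checked against
#' `max_parental_kinship` but only warns by default, since breeding designs
#' may legitimately mate related animals.
#'
#' @param km A [KinshipMatrix-class].
#' @param trio A [TrioContext-class].
#' @param parent_bounds First-degree kinship window.
#' @param max_parental_kinship Sire-dam kinship warn threshold
#'   (default 0.177, the lower first-degree bound).
#' @param fail_on_parental If `TRUE`, a related sire-dam pair fails the trio
#'   instead of warning.
#' @return A list with `status` (`"pass"`, `"warn"`, `"fail"` or
#'   `"inconclusive"`), the three pairwise coefficients, and `messages`.
#' @export
validateTrio <- function(km, trio, parent_bounds = c(0.177, 0.354),
                         max_parental_kinship = 0.177,
                         fail_on_parental = FALSE) {
  need <- c(trio@sire, trio@dam, trio@offspring)
  if (!all(need %in% km@samples))
    stop("kinship matrix does not cover all trio roles")
  phi <- km@phi
  so <- phi[trio@sire, trio@offspring]
  do <- phi[trio@dam, trio@offspring]
  sd <- phi[trio@sire, trio@dam]
  msgs <- character(0)
  if (anyNA(c(so, do, sd)))
    return(list(status = "inconclusive", sire_offspring = so,
                dam_offspring = do, sire_dam = sd,
                messages = "missing kinship entries"))
  status <- "pass"
  in_win <- function(v) v >= parent_bounds[1] & v <= parent_bounds[2]
  if (!in_win(so)) {
    status <- "fail"
    msgs <- c(msgs, sprintf("sire-offspring kinship %.3f outside [%g, %g]",
                            so, parent_bounds[1], parent_bounds[2]))
  }
  if (!in_win(do)) {
    status <- "fail"
    msgs <- c(msgs, sprintf("dam-offspring kinship %.3f outside [%g, %g]",
                            do, parent_bounds[1], parent_bounds[2]))
  }
  if (sd > max_parental_kinship) {
    msgs <- c(msgs, sprintf("sire-dam kinship %.3f above %g", sd,
                            max_parental_kinship))
    if (fail_on_parental) status <- "fail"
    else if (status == "pass") status <- "warn"
  }
  list(status = status, sire_offspring = so, dam_offspring = do,
       sire_dam = sd, messages = msgs)
}
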