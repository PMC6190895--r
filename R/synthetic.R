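# synthetic trio cohorts with full ground truth
#
# The generator emulates the statistical structure the cascade assumes:
# Mendelian transmission of population polymorphisms shared with a known
# database, heterozygous de novo events private to the offspring, caller
# discordance, and artifact variants each violating exactly one cascade
# criterion (orthogonal design, so every removal is attributable to its
# designed stage).  De novo events are planted at well-covered sites — the
# planted set emulates the *callable* de novo set.

ARTIFACT_TYPES <- c("low_depth", "allelic_imbalance", "pl_inconsistent",
                    "high_softclip", "in_database", "cohort_shared")

#' Simulation configuration
#'
#' Study-condition defaults: ~37x mean depth, 10-kb coverage windows with a
#' 13x-130x callable range, two guides with a handful of planted mismatched
#' off-target copies, a small multi-chromosome genome with one
#' non-autosomal chromosome, and ten true de novo SNVs per offspring.
#'
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param population_snp_rate Per-bp probability of a population SNP.
#' @param db_fraction Fraction of population SNPs present in the known
#'   database.
#' @param true_denovo_count,true_denovo_indel_count De novo SNVs / indels
#'   planted in the offspring.
#' @param mean_depth,depth_dispersion Negative-binomial read-depth model:
#'   mean and dispersion (variance = mu + dispersion * mu^2).
#' @param caller_discordance_rate Probability that caller B misses a
#'   variant reported by caller A.
#' @param artifact_counts Named integer vector over
#'   `low_depth, allelic_imbalance, pl_inconsistent, high_softclip,
#'   in_database, cohort_shared`: how many artifact variants of each class
#'   to inject.
#' @param n_extra_cohort Unrelated cohort samples beyond the trio.
#' @param guide_count Number of guides planted in the genome.
#' @param planted_offtarget_spec List of `c(mismatch_total,
#'   seed_mismatches)` pairs planted per guide (beyond the exact
#'   on-target).
#' @param window_size Coverage window size in bp.
#' @param coverage_outlier_fraction Fraction of windows forced outside the
#'   callable depth range.
#' @param rng_seed Integer seed; all simulation draws derive from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulationConfig <- function(
    chrom_lengths = c(chr1 = 120000L, chr2 = 120000L, chrX = 60000L),
    population_snp_rate = 2e-3,
    db_fraction = 0.95,
    true_denovo_count = 10L,
    true_denovo_indel_count = 3L,
    mean_depth = 36.8,
    depth_dispersion = 0.15,
    caller_discordance_rate = 0,
    artifact_counts = setNames(integer(length(ARTIFACT_TYPES)),
                               ARTIFACT_TYPES),
    n_extra_cohort = 2L,
    guide_count = 2L,
    planted_offtarget_spec = list(c(2L, 0L), c(4L, 1L)),
    window_size = 10000L,
    coverage_outlier_fraction = 0.05,
    rng_seed = 1L) {
  probs <- c(population_snp_rate, db_fraction, caller_discordance_rate,
             coverage_outlier_fraction)
  if (any(probs < 0 | probs > 1))
    stop("all rates/fractions must lie in [0, 1]")
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named")
  if (sum(chrom_lengths) < 10 * window_size)
    stop("total genome length must be at least 10 x window_size")
  full <- setNames(integer(length(ARTIFACT_TYPES)), ARTIFACT_TYPES)
  full[names(artifact_counts)] <- as.integer(artifact_counts)
  if (any(!names(artifact_counts) %in% ARTIFACT_TYPES))
    stop("unknown artifact class: ",
         paste(setdiff(names(artifact_counts), ARTIFACT_TYPES),
               collapse = ","))
  structure(list(
    chrom_lengths = chrom_lengths,
    population_snp_rate = population_snp_rate, db_fraction = db_fraction,
    true_denovo_count = as.integer(true_denovo_count),
    true_denovo_indel_count = as.integer(true_denovo_indel_count),
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    caller_discordance_rate = caller_discordance_rate,
    artifact_counts = full, n_extra_cohort = as.integer(n_extra_cohort),
    guide_count = as.integer(guide_count),
    planted_offtarget_spec = planted_offtarget_spec,
    window_size = as.integer(window_size),
    coverage_outlier_fraction = coverage_outlier_fraction,
    rng_seed = as.integer(rng_seed)), class = "simulation_config")
}

## draw a concrete PAM instance from an IUPAC pattern
realize_pam <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]],
               function(cd) sample(iupac_expand(cd), 1L), character(1)),
        collapse = "")
}

## mutate a protospacer with exactly (total, seed) mismatches;
## seed = PAM-proximal `seed_len` positions
mutate_protospacer <- function(proto, total, seed, seed_len = 12L) {
  ch <- strsplit(proto, "")[[1]]
  seed_pos <- (20L - seed_len + 1L):20L
  nonseed_pos <- setdiff(1:20, seed_pos)
  pick <- c(if (seed > 0) sample(seed_pos, seed),
            if (total - seed > 0) sample(nonseed_pos, total - seed))
  for (p in pick) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Simulate a genome with planted guide targets
#'
#' Draws a uniform-composition random genome and plants, for each guide, an
#' exact protospacer+PAM on-target match plus the configured mismatched
#' off-target copies, on random strands of autosomal chromosomes without
#' overlap.  Fully reproducible from `rng_seed`.
#'
#' @param cfg A [simulationConfig()].
#' @return A list with `genome` ([AnnotatedGenome-class]), `guides` (list
#'   of [GuideQuery-class]) and `planted` (`GRanges` of planted protospacer
#'   intervals with `guide`, `mismatch_total`, `mismatch_seed`,
#'   `on_target`).
#' @export
simulateGenome <- function(cfg) {
  if (length(cfg$chrom_lengths) == 0L) stop("zero chromosomes configured")
  set.seed(cfg$rng_seed)
  chroms <- lapply(cfg$chrom_lengths, function(L)
    sample(BASES, L, replace = TRUE))
  autos <- !grepl("^(chr)?(X|Y|MT?)$", names(chroms), ignore.case = TRUE)
  if (!any(autos)) stop("at least one autosome is required")
  occupied <- lapply(chroms, function(x) integer(0))

  n_per_guide <- 1L + length(cfg$planted_offtarget_spec)
  need <- cfg$guide_count * n_per_guide * 30L
  if (sum(cfg$chrom_lengths[autos]) < need)
    stop("genome too short to host the requested planted sites")

  guides <- list()
  planted <- list()
  place <- function(seq23) {
    # find a free slot on an autosome; returns c(chrom_index, start)
    for (try in 1:200) {
      ci <- sample(which(autos), 1L)
      L <- length(chroms[[ci]])
      s <- sample.int(L - 25L, 1L)
      if (!any((s:(s + 22L)) %in% occupied[[ci]])) {
        chroms[[ci]][s:(s + 22L)] <<- strsplit(seq23, "")[[1]]
        occupied[[ci]] <<- c(occupied[[ci]], (s - 5L):(s + 27L))
        return(c(ci, s))
      }
    }
    stop("could not place a site without overlap; genome too crowded")
  }
  for (gi in seq_len(cfg$guide_count)) {
    proto <- paste(sample(BASES, 20L, replace = TRUE), collapse = "")
    gq <- guideQuery(paste0("guide", gi), proto)
    guides[[gq@name]] <- gq
    specs <- c(list(c(0L, 0L)), cfg$planted_offtarget_spec)
    for (si in seq_along(specs)) {
      tot <- specs[[si]][1]; sd_mm <- specs[[si]][2]
      variant <- if (tot == 0L) proto else
        mutate_protospacer(proto, tot, sd_mm, gq@seed_length)
      pam <- realize_pam(if (tot == 0L) "NGG" else gq@pam)
      strand <- sample(c("+", "-"), 1L)
      seq23 <- paste0(variant, pam)
      if (strand == "-") seq23 <- revcomp_chr(seq23)
      loc <- place(seq23)
      L <- length(chroms[[loc[1]]])
      start <- if (strand == "+") loc[2] else loc[2] + 3L
      planted[[length(planted) + 1L]] <- data.frame(
        chrom = names(chroms)[loc[1]], start = start, end = start + 19L,
        strand = strand, guide = gq@name, mismatch_total = tot,
        mismatch_seed = sd_mm, on_target = tot == 0L)
    }
  }
  pl <- do.call(rbind, planted)
  genome <- AnnotatedGenome(
    vapply(chroms, paste, character(1), collapse = ""),
    autosome = setNames(autos, names(chroms)),
    name = sprintf("sim-genome-seed%d", cfg$rng_seed))
  list(genome = genome, guides = guides,
       planted = GenomicRanges::GRanges(
         pl$chrom, IRanges::IRanges(pl$start, pl$end), strand = pl$strand,
         guide = pl$guide, mismatch_total = pl$mismatch_total,
         mismatch_seed = pl$mismatch_seed, on_target = pl$on_target))
}

## depth draw under the NB model
draw_depth <- function(n, cfg) {
  if (cfg$depth_dispersion <= 0) return(rep(round(cfg$mean_depth), n))
  rnbinom(n, mu = cfg$mean_depth, size = 1 / cfg$depth_dispersion)
}

## alt-read draw given genotype count (0/1/2) and depth
draw_alt_reads <- function(gcount, depth, err = 0.001) {
  if (gcount == 0L) rbinom(1L, depth, err)
  else if (gcount == 2L) depth - rbinom(1L, depth, err)
  else rbinom(1L, depth, 0.5)
}

#' Simulate two-caller trio call sets with ground truth
#'
#' Generates, for one trio plus unrelated cohort samples: Mendelian-
#' transmitted population SNPs (mostly shared with the known database),
#' heterozygous de novo SNVs and indels private to the offspring, and
#' artifact variants each engineered to violate exactly one cascade
#' criterion.  Depths follow a negative-binomial model; PL triples are
#' phred-scaled binomial genotype likelihoods from simulated ref/alt read
#' counts, min-normalized.  Caller B misses variants at the configured
#' discordance rate.  De novo and artifact sites (except the designed
#' violation) are planted at callable depths so that, with artifact counts
#' 0 and discordance 0, every planted de novo survives the cascade.
#'
#' @param cfg A [simulationConfig()].
#' @param sg Output of [simulateGenome()] (or an [AnnotatedGenome-class]).
#' @return A list: `caller_a`, `caller_b` ([VariantSet-class]), `trio`
#'   ([TrioContext-class]), `db` ([KnownVariants-class]), `truth` (lists of
#'   keys per category plus `planted_offtarget`), and `samples`.
#' @export
simulateTrioCallsets <- function(cfg, sg) {
  genome <- if (is(sg, "AnnotatedGenome")) sg else sg$genome
  set.seed(cfg$rng_seed + 1L)
  samples <- c("sire1", "dam1", "off1",
               if (cfg$n_extra_cohort > 0)
                 paste0("coh", seq_len(cfg$n_extra_cohort)))
  trio <- TrioContext("sire1", "dam1", "off1", samples)
  ns <- length(samples)
  chrom_names <- names(genomeSeq(genome))
  seqs <- lapply(setNames(nm = chrom_names),
                 function(cn) chromString(genome, cn))
  autos <- genome@autosome

  rows <- list()   # each: chrom,pos,ref,alt,category,gcount (per sample)
  used_pos <- lapply(seqs, function(x) integer(0))

  ## --- population SNPs, Mendelian transmission -------------------------
  for (cn in chrom_names) {
    L <- nchar(seqs[[cn]])
    pos <- which(runif(L) < cfg$population_snp_rate)
    pos <- pos[pos > 2L & pos < L - 105L]
    for (p in pos) {
      ref <- substr(seqs[[cn]], p, p)
      alt <- sample(setdiff(BASES, ref), 1L)
      freq <- runif(1, 0.05, 0.95)
      gc <- integer(ns)
      names(gc) <- samples
      gc[trio@sire] <- rbinom(1L, 2L, freq)
      gc[trio@dam] <- rbinom(1L, 2L, freq)
      extra <- setdiff(samples, c(trio@sire, trio@dam, trio@offspring))
      gc[extra] <- rbinom(length(extra), 2L, freq)
      transmit <- function(g) if (g == 1L) rbinom(1L, 1L, 0.5) else g / 2L
      gc[trio@offspring] <- transmit(gc[trio@sire]) + transmit(gc[trio@dam])
      if (all(gc == 0L)) next   # callers emit only sites with an alt allele
      rows[[length(rows) + 1L]] <- list(chrom = cn, pos = p, ref = ref,
                                        alt = alt, category = "inherited",
                                        gcount = gc)
      used_pos[[cn]] <- c(used_pos[[cn]], p)
    }
  }

  ## --- private offspring events ---------------------------------------
  free_pos <- function(cn, span = 1L) {
    L <- nchar(seqs[[cn]])
    repeat {
      p <- sample(3:(L - 110L), 1L)
      if (!any((p - 1L):(p + span) %in% used_pos[[cn]])) {
        used_pos[[cn]] <<- c(used_pos[[cn]], p:(p + span - 1L))
        return(p)
      }
    }
  }
  private_row <- function(category, indel = FALSE, carrier_extra = NULL) {
    cn <- sample(names(autos)[autos], 1L)
    if (indel) {
      sz <- sample(2:6, 1L)
      if (runif(1) < 0.5) {   # deletion
        p <- free_pos(cn, sz + 1L)
        ref <- substr(seqs[[cn]], p, p + sz)
        alt <- substr(seqs[[cn]], p, p)
      } else {                # insertion
        p <- free_pos(cn)
        ref <- substr(seqs[[cn]], p, p)
        alt <- paste0(ref, paste(sample(BASES, sz, replace = TRUE),
                                 collapse = ""))
      }
    } else {
      p <- free_pos(cn)
      ref <- substr(seqs[[cn]], p, p)
      alt <- sample(setdiff(BASES, ref), 1L)
    }
    gc <- setNames(integer(ns), samples)
    gc[trio@offspring] <- 1L
    if (!is.null(carrier_extra)) gc[carrier_extra] <- 1L
    list(chrom = cn, pos = p, ref = ref, alt = alt, category = category,
         gcount = gc)
  }
  for (i in seq_len(cfg$true_denovo_count))
    rows[[length(rows) + 1L]] <- private_row("denovo_snv")
  for (i in seq_len(cfg$true_denovo_indel_count))
    rows[[length(rows) + 1L]] <- private_row("denovo_indel", indel = TRUE)
  extra_cohort <- setdiff(samples, c(trio@sire, trio@dam, trio@offspring))
  for (at in ARTIFACT_TYPES) {
    for (i in seq_len(cfg$artifact_counts[[at]])) {
      carrier <- if (at == "cohort_shared") {
        if (!length(extra_cohort))
          stop("cohort_shared artifacts need extra cohort samples")
        sample(extra_cohort, 1L)
      } else NULL
      rows[[length(rows) + 1L]] <-
        private_row(paste0("artifact_", at), carrier_extra = carrier)
    }
  }

  ## normalize allele representations row-wise up front so ground-truth
  ## keys and emitted records share one canonical spelling
  for (i in seq_along(rows)) {
    nv <- normalize_one(seqs[[rows[[i]]$chrom]], rows[[i]]$pos,
                        rows[[i]]$ref, rows[[i]]$alt)
    rows[[i]]$pos <- nv$pos; rows[[i]]$ref <- nv$ref; rows[[i]]$alt <- nv$alt
  }
  row_keys <- vapply(rows, function(r)
    variantKey(r$chrom, r$pos, r$ref, r$alt), character(1))
  rows <- rows[!duplicated(row_keys)]

  ## --- call-level synthesis -------------------------------------------
  n <- length(rows)
  geno <- matrix(NA_character_, n, ns, dimnames = list(NULL, samples))
  depth <- matrix(0L, n, ns, dimnames = list(NULL, samples))
  plarr <- array(NA_real_, c(n, ns, 3L))
  scf <- matrix(NA_real_, n, ns, dimnames = list(NULL, samples))
  category <- vapply(rows, `[[`, "", "category")
  engineered <- category != "inherited"
  roles <- c(trio@sire, trio@dam, trio@offspring)
  for (i in seq_len(n)) {
    gc <- rows[[i]]$gcount
    d <- draw_depth(ns, cfg)
    names(d) <- samples
    if (engineered[i]) {
      # plant at callable depths: parents in [13,80], offspring in [17,80]
      d[trio@sire] <- min(max(d[trio@sire], 13L), 80L)
      d[trio@dam] <- min(max(d[trio@dam], 13L), 80L)
      d[trio@offspring] <- min(max(d[trio@offspring], 17L), 80L)
    }
    for (s in samples) {
      a <- draw_alt_reads(gc[[s]], d[[s]])
      if (engineered[i] && gc[[s]] == 1L && s %in% roles)
        a <- min(max(a, 2L), d[[s]] - 2L)   # confident het evidence
      if (engineered[i] && gc[[s]] == 0L)
        a <- 0L   # callable site: non-carriers read error-free
      plarr[i, match(s, samples), ] <- phred_pl(a, d[[s]])
      geno[i, match(s, samples)] <- c("AA", "AB", "BB")[gc[[s]] + 1L]
      depth[i, match(s, samples)] <- d[[s]]
      scf[i, match(s, samples)] <- round(runif(1, 0, 0.05), 4)
    }
    # engineered single-criterion violations; depth changes re-synthesize
    # the affected sample's reads and PL so DP and PL stay consistent
    oi <- match(trio@offspring, samples)
    si <- match(trio@sire, samples)
    resynth <- function(col, new_depth, gcount) {
      depth[i, col] <<- new_depth
      a <- draw_alt_reads(gcount, new_depth)
      plarr[i, col, ] <<- phred_pl(a, new_depth)
    }
    if (category[i] == "artifact_low_depth") {
      resynth(si, sample(5:11, 1L), 0L)
    } else if (category[i] == "artifact_allelic_imbalance") {
      dsum <- depth[i, si] + depth[i, match(trio@dam, samples)]
      resynth(oi, max(0L, as.integer(floor(dsum / 10)) - 1L), 1L)
    } else if (category[i] == "artifact_pl_inconsistent") {
      plarr[i, si, ] <- c(0, 12, 80)
    } else if (category[i] == "artifact_high_softclip") {
      scf[i, oi] <- round(runif(1, 0.12, 0.40), 4)
    }
  }

  vs <- VariantSet(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, function(r) r$pos, 1L),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    samples = samples, geno = geno, depth = depth, pl = plarr, scf = scf,
    caller = "callerA")
  keys <- variantKeys(vs)   # canonical: rows were normalized up front

  ## --- known database ---------------------------------------------------
  inher <- keys[category == "inherited"]
  db_keys <- inher[runif(length(inher)) < cfg$db_fraction]
  db_keys <- c(db_keys, keys[category == "artifact_in_database"])
  db <- KnownVariants(db_keys, source_label = "sim-population-db",
                      n_individuals = 100)

  ## --- caller B: discordance --------------------------------------------
  keep_b <- runif(length(vs)) >= cfg$caller_discordance_rate
  caller_b <- vs[keep_b]
  caller_b@caller <- "callerB"

  truth <- list(
    denovo_snv_keys = keys[category == "denovo_snv"],
    denovo_indel_keys = keys[category == "denovo_indel"],
    inherited_keys = inher,
    artifact_keys = lapply(setNames(nm = ARTIFACT_TYPES), function(at)
      keys[category == paste0("artifact_", at)]),
    db_keys = dbKeys(db),
    planted_offtarget = if (!is(sg, "AnnotatedGenome")) sg$planted,
    rng_seed = cfg$rng_seed)

  list(caller_a = vs, caller_b = caller_b, trio = trio, db = db,
       truth = truth, samples = samples)
}

#' Simulate per-window mean coverage
#'
#' Tiles each chromosome with fixed-size windows (final partial window
#' dropped).  A configured fraction of windows is forced outside the
#' callable depth range (half below, half above); the rest draw around the
#' mean depth inside the range.
#'
#' @param cfg A [simulationConfig()].
#' @param genome An [AnnotatedGenome-class] (or [simulateGenome()] output).
#' @param min_cov,max_cov Callable range used to place outliers.
#' @return A `data.frame` with `chrom`, `start` (0-based), `end`,
#'   `mean_depth`, and a logical `forced_outlier` ground-truth column.
#' @export
simulateCoverageWindows <- function(cfg, genome, min_cov = 13,
                                    max_cov = 130) {
  if (!is(genome, "AnnotatedGenome")) genome <- genome$genome
  set.seed(cfg$rng_seed + 2L)
  ws <- cfg$window_size
  tb <- do.call(rbind, lapply(names(genomeSeq(genome)), function(cn) {
    nw <- nchar(chromString(genome, cn)) %/% ws
    if (nw == 0L) return(NULL)
    data.frame(chrom = cn, start = (seq_len(nw) - 1L) * ws,
               end = seq_len(nw) * ws)
  }))
  nw <- nrow(tb)
  depth <- rnorm(nw, cfg$mean_depth, 5)
  depth <- pmin(pmax(depth, min_cov + 0.5), max_cov - 0.5)
  n_out <- round(cfg$coverage_outlier_fraction * nw)
  out_idx <- sample.int(nw, n_out)
  lo <- out_idx[seq_len(n_out %/% 2)]
  hi <- setdiff(out_idx, lo)
  depth[lo] <- runif(length(lo), 0, min_cov - 0.5)
  depth[hi] <- runif(length(hi), max_cov + 0.5, max_cov + 60)
  tb$mean_depth <- round(depth, 2)
  tb$forced_outlier <- seq_len(nw) %in% out_idx
  tb
}

#' Simulate cohort genotypes from a pedigree
#'
#' Founders draw Hardy-Weinberg genotypes at independent biallelic sites
#' with per-site allele frequencies uniform in `maf_range`; non-founders
#' receive one Mendelian allele from each parent.  Intended for kinship
#' estimator validation.
#'
#' @param pedigree `data.frame` with columns `id`, `sire`, `dam` (`NA` for
#'   founders); every named parent must itself appear as a row.
#' @param n_sites Number of independent sites.
#' @param maf_range Allele-frequency range of the founder pool.
#' @param seed Integer seed.
#' @return Integer matrix, sites x samples, coded 0/1/2.
#' @export
simulateGenotypes <- function(pedigree, n_sites = 10000L,
                              maf_range = c(0.05, 0.5), seed = 1L) {
  set.seed(seed)
  freq <- runif(n_sites, maf_range[1], maf_range[2])
  ids <- pedigree$id
  G <- matrix(NA_integer_, n_sites, length(ids),
              dimnames = list(NULL, ids))
  haplos <- list()  # per sample: two gamete vectors
  resolved <- character(0)
  pending <- seq_len(nrow(pedigree))
  while (length(pending)) {
    progressed <- FALSE
    for (i in pending) {
      sire <- pedigree$sire[i]; dam <- pedigree$dam[i]
      parents_ok <- (is.na(sire) || sire %in% resolved) &&
        (is.na(dam) || dam %in% resolved)
      if (!parents_ok) next
      gamete <- function(pid) {
        if (is.na(pid)) return(rbinom(n_sites, 1L, freq))
        h <- haplos[[pid]]
        pick <- rbinom(n_sites, 1L, 0.5)
        ifelse(pick == 1L, h[[1]], h[[2]])
      }
      h1 <- gamete(sire); h2 <- gamete(dam)
      haplos[[ids[i]]] <- list(h1, h2)
      G[, ids[i]] <- h1 + h2
      resolved <- c(resolved, ids[i])
      pending <- setdiff(pending, i)
      progressed <- TRUE
    }
    if (!progressed)
      stop("pedigree contains unresolvable parent references or cycles")
  }
  G
}

#' Write a full simulation to disk in the pipeline's input formats
#'
#' Emits the genome FASTA, both caller VCFs, the known-database TSV, the
#' pedigree TSV, the coverage-window TSV, the guide TSV, a ground-truth key
#' table and a run-metadata TSV recording the configuration (including the
#' seed).
#'
#' @param cfg A [simulationConfig()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sg <- simulateGenome(cfg)
  sim <- simulateTrioCallsets(cfg, sg)
  wins <- simulateCoverageWindows(cfg, sg$genome)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    caller_a = file.path(dir, "caller_a.vcf"),
    caller_b = file.path(dir, "caller_b.vcf"),
    db = file.path(dir, "known_db.tsv"),
    pedigree = file.path(dir, "pedigree.tsv"),
    windows = file.path(dir, "coverage_windows.tsv"),
    guides = file.path(dir, "guides.tsv"),
    truth = file.path(dir, "ground_truth.tsv"),
    meta = file.path(dir, "run_metadata.tsv"))
  writeGenome(sg$genome, paths["genome"])
  writeVariants(sim$caller_a, paths["caller_a"], genome = sg$genome)
  writeVariants(sim$caller_b, paths["caller_b"], genome = sg$genome)
  writeKnownDb(sim$db, paths["db"])
  writePedigree(list(sim$trio), paths["pedigree"])
  write.table(wins[c("chrom", "start", "end", "mean_depth")],
              paths["windows"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(
    name = vapply(sg$guides, function(g) g@name, ""),
    protospacer = vapply(sg$guides, function(g) g@protospacer, ""),
    pam = vapply(sg$guides, function(g) g@pam, "")),
    paths["guides"], sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  tt <- rbind(
    data.frame(category = "denovo_snv", key = tr$denovo_snv_keys),
    data.frame(category = "denovo_indel", key = tr$denovo_indel_keys),
    data.frame(category = "inherited", key = tr$inherited_keys),
    do.call(rbind, lapply(names(tr$artifact_keys), function(at)
      if (length(tr$artifact_keys[[at]]))
        data.frame(category = paste0("artifact_", at),
                   key = tr$artifact_keys[[at]]))))
  write.table(tt, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  scalar <- vapply(cfg, function(x) length(x) == 1L && !is.list(x),
                   logical(1))
  write.table(data.frame(parameter = names(cfg)[scalar],
                         value = vapply(cfg[scalar], as.character, "")),
              paths["meta"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
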