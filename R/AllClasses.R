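# S4 containers shared across the pipeline

#' @importClassesFrom Biostrings DNAStringSet
NULL

# ---------------------------------------------------------------- genome ----

#' AnnotatedGenome: a reference genome with autosome flags
#'
#' Wraps a [Biostrings::DNAStringSet] of chromosome sequences together with a
#' per-chromosome autosome flag.  Autosome flags drive the effective-genome
#' computation (sex chromosomes are excluded from the callable size by
#' default) and restrict where the simulator plants events.
#'
#' @slot name Assembly label.
#' @slot seq Named `DNAStringSet`, uppercase A/C/G/T/N only.
#' @slot autosome Named logical, one flag per chromosome.
#'
#' @exportClass AnnotatedGenome
setClass("AnnotatedGenome",
  slots = c(name = "character", seq = "DNAStringSet", autosome = "logical")
)

setValidity("AnnotatedGenome", function(object) {
  nm <- names(object@seq)
  if (is.null(nm) || anyDuplicated(nm))
    return("chromosome names must be present and unique")
  if (!identical(sort(nm), sort(names(object@autosome))))
    return("every chromosome needs exactly one autosome flag")
  af <- Biostrings::alphabetFrequency(object@seq, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- setdiff(colnames(af)[colSums(af) > 0], allowed)
  if (length(bad))
    return(paste0("genome contains non-ACGTN letters: ",
                  paste(bad, collapse = ",")))
  TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param seq Named character vector or `DNAStringSet` of chromosome
#'   sequences (coerced to uppercase).
#' @param autosome Named logical vector of autosome flags; by default every
#'   chromosome whose name does not look like a sex/mitochondrial chromosome
#'   (`X`, `Y`, `MT`, optionally `chr`-prefixed) is flagged autosomal.
#' @param name Assembly label.
#' @return An [AnnotatedGenome-class] object.
#' @examples
#' g <- AnnotatedGenome(c(chr1 = "ACGTACGT", chrX = "GGGCCC"))
#' autosomes(g)
#' @export
AnnotatedGenome <- function(seq, autosome = NULL, name = "genome") {
  if (is.character(seq)) {
    seq <- Biostrings::DNAStringSet(toupper(seq))
  }
  if (is.null(autosome)) {
    autosome <- !grepl("^(chr)?(X|Y|MT?)$", names(seq), ignore.case = TRUE)
    names(autosome) <- names(seq)
  }
  new("AnnotatedGenome", name = name, seq = seq,
      autosome = autosome[names(seq)])
}

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome '", object@name, "': ", length(object@seq),
      " chromosome(s), ",
      format(sum(Biostrings::width(object@seq)), big.mark = ","),
      " bp (", sum(object@autosome), " autosomal)\n", sep = "")
})

#' @describeIn AnnotatedGenome names of autosomal chromosomes
#' @param x,object An `AnnotatedGenome`.
#' @export
autosomes <- function(x) names(x@autosome)[x@autosome]

#' @describeIn AnnotatedGenome chromosome sequences as a `DNAStringSet`
#' @export
genomeSeq <- function(x) x@seq

#' @describeIn AnnotatedGenome one chromosome as a plain character string
#' @param chrom Chromosome name.
#' @export
chromString <- function(x, chrom) {
  if (!chrom %in% names(x@seq)) stop("unknown chromosome: ", chrom)
  as.character(x@seq[[chrom]])
}

# -------------------------------------------------------------- variants ----

#' VariantSet: normalized biallelic variants with per-sample calls
#'
#' The central container of the pipeline: one row per biallelic site-allele
#' (multiallelic records are split on read), with per-sample genotype
#' (`"AA"`, `"AB"`, `"BB"` or `NA`; A = reference allele, B = alternate),
#' read depth, the normalized phred-scaled likelihood (PL) triple ordered
#' (AA, AB, BB), and the mean soft-clip fraction (SCF) of reads covering the
#' site.
#'
#' @slot chrom,pos,ref,alt,vclass Parallel per-variant vectors; `pos` is the
#'   1-based position of the first reference base, `vclass` is `"SNV"` or
#'   `"INDEL"` (indel size 2-100 bp).
#' @slot samples Sample identifiers (column order of the call matrices).
#' @slot geno Character matrix, variants x samples.
#' @slot depth Integer matrix, variants x samples.
#' @slot pl Numeric array, variants x samples x 3 (AA, AB, BB).
#' @slot scf Numeric matrix, variants x samples, values in \[0, 1\] or `NA`.
#' @slot caller Label of the producing caller.
#'
#' @exportClass VariantSet
setClass("VariantSet",
  slots = c(
    chrom = "character", pos = "integer", ref = "character",
    alt = "character", vclass = "character", samples = "character",
    geno = "matrix", depth = "matrix", pl = "array", scf = "matrix",
    caller = "character"
  )
)

setValidity("VariantSet", function(object) {
  n <- length(object@chrom)
  s <- length(object@samples)
  if (length(object@pos) != n || length(object@ref) != n ||
      length(object@alt) != n || length(object@vclass) != n)
    return("per-variant vectors must have equal length")
  if (!all(dim(object@geno) == c(n, s)) ||
      !all(dim(object@depth) == c(n, s)) ||
      !all(dim(object@scf) == c(n, s)) ||
      !all(dim(object@pl) == c(n, s, 3L)))
    return("call matrix dimensions do not match variants x samples")
  if (any(object@ref == object@alt))
    return("ref and alt alleles must differ")
  if (anyDuplicated(variantKey(object@chrom, object@pos,
                               object@ref, object@alt)))
    return("variant keys (chrom,pos,ref,alt) must be unique")
  if (!all(object@vclass %in% c("SNV", "INDEL")))
    return("vclass must be SNV or INDEL")
  ok_geno <- object@geno %in% c("AA", "AB", "BB") | is.na(object@geno)
  if (!all(ok_geno)) return("genotypes must be AA/AB/BB/NA")
  if (any(object@depth < 0, na.rm = TRUE)) return("depths must be >= 0")
  if (any(object@scf < 0 | object@scf > 1, na.rm = TRUE))
    return("soft-clip fractions must lie in [0, 1]")
  TRUE
})

#' Construct a VariantSet
#'
#' @param chrom,pos,ref,alt Parallel vectors describing variants; `pos` is
#'   1-based.  The variant class (SNV vs 2-100 bp indel) is derived from the
#'   alleles; records that are neither (MNPs, indels outside the size gate)
#'   are rejected.
#' @param samples Sample ids (column names of the matrices).
#' @param geno,depth,scf Matrices, variants x samples.
#' @param pl Array, variants x samples x 3, PL triples ordered (AA, AB, BB).
#' @param caller Label of the producing caller.
#' @return A [VariantSet-class].
#' @export
VariantSet <- function(chrom, pos, ref, alt, samples, geno, depth, pl, scf,
                       caller = "caller") {
  n <- length(chrom)
  vclass <- variant_class(ref, alt)
  if (anyNA(vclass))
    stop("records that are neither SNVs nor 2-100 bp indels at rows: ",
         paste(utils::head(which(is.na(vclass)), 5), collapse = ","))
  dimnames(geno) <- dimnames(depth) <- dimnames(scf) <-
    list(NULL, samples)
  new("VariantSet",
      chrom = as.character(chrom), pos = as.integer(pos),
      ref = toupper(ref), alt = toupper(alt), vclass = vclass,
      samples = samples,
      geno = geno, depth = depth, pl = pl, scf = scf, caller = caller)
}

setMethod("show", "VariantSet", function(object) {
  cat("VariantSet (", object@caller, "): ", length(object@chrom),
      " variant(s) [", sum(object@vclass == "SNV"), " SNV, ",
      sum(object@vclass == "INDEL"), " indel] x ",
      length(object@samples), " sample(s)\n", sep = "")
})

#' @describeIn VariantSet number of variants
#' @param x A `VariantSet`.
#' @export
setMethod("length", "VariantSet", function(x) length(x@chrom))

#' @describeIn VariantSet subset by variant index or logical mask
#' @param i Index vector.
#' @param j,...,drop Ignored (matrix-style signature).
#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x,
    chrom = x@chrom[i], pos = x@pos[i], ref = x@ref[i], alt = x@alt[i],
    vclass = x@vclass[i],
    geno = x@geno[i, , drop = FALSE], depth = x@depth[i, , drop = FALSE],
    pl = x@pl[i, , , drop = FALSE], scf = x@scf[i, , drop = FALSE])
})

#' Accessors for VariantSet call data
#'
#' @param x A [VariantSet-class].
#' @return `variantKeys()` the canonical `chrom:pos:ref:alt` keys;
#'   `sampleIds()` the sample identifiers; `genotypes()`, `depths()`,
#'   `softclip()` the call matrices; `plArray()` the PL triples;
#'   `variantTable()` a `data.frame` of the per-variant fields.
#' @name variantset-accessors
NULL

#' @rdname variantset-accessors
#' @export
variantKeys <- function(x) variantKey(x@chrom, x@pos, x@ref, x@alt)

#' @rdname variantset-accessors
#' @export
sampleIds <- function(x) x@samples

#' @rdname variantset-accessors
#' @export
genotypes <- function(x) x@geno

#' @rdname variantset-accessors
#' @export
depths <- function(x) x@depth

#' @rdname variantset-accessors
#' @export
plArray <- function(x) x@pl

#' @rdname variantset-accessors
#' @export
softclip <- function(x) x@scf

#' @rdname variantset-accessors
#' @export
variantTable <- function(x) {
  data.frame(chrom = x@chrom, pos = x@pos, ref = x@ref, alt = x@alt,
             vclass = x@vclass, stringsAsFactors = FALSE)
}

# ------------------------------------------------------------------ trio ----

#' TrioContext: pedigree roles bound to sample columns
#'
#' @slot sire,dam,offspring Sample ids of the three roles.
#' @slot cohort All sample ids in the study (used by the cohort-uniqueness
#'   filter stage); must contain the three roles.
#'
#' @exportClass TrioContext
setClass("TrioContext",
  slots = c(sire = "character", dam = "character", offspring = "character",
            cohort = "character")
)

setValidity("TrioContext", function(object) {
  roles <- c(object@sire, object@dam, object@offspring)
  if (anyDuplicated(roles)) return("sire, dam and offspring must be distinct")
  if (!all(roles %in% object@cohort))
    return("all trio roles must appear in the cohort")
  TRUE
})

#' Construct a TrioContext
#'
#' @param sire,dam,offspring Sample ids.
#' @param cohort All cohort sample ids (defaults to just the trio).
#' @return A [TrioContext-class].
#' @export
TrioContext <- function(sire, dam, offspring,
                        cohort = c(sire, dam, offspring)) {
  new("TrioContext", sire = sire, dam = dam, offspring = offspring,
      cohort = cohort)
}

setMethod("show", "TrioContext", function(object) {
  cat("TrioContext: ", object@offspring, " = ", object@sire, " x ",
      object@dam, " (cohort n = ", length(object@cohort), ")\n", sep = "")
})

# ------------------------------------------------------------- known db ----

#' KnownVariants: a known-variant (population SNP) database
#'
#' Holds the normalized `chrom:pos:ref:alt` keys of a population variant
#' database plus provenance metadata.  The database is treated as an opaque
#' key set: membership is the only query the cascade makes.
#'
#' @slot keys Character vector of normalized variant keys.
#' @slot source_label Free-text provenance label.
#' @slot n_individuals Number of individuals behind the database (metadata).
#'
#' @exportClass KnownVariants
setClass("KnownVariants",
  slots = c(keys = "character", source_label = "character",
            n_individuals = "numeric")
)

#' Construct a KnownVariants database
#'
#' @param keys Normalized variant keys (or a [VariantSet-class], whose keys
#'   are taken).
#' @param source_label Provenance label.
#' @param n_individuals Individuals behind the database.
#' @return A [KnownVariants-class].
#' @export
KnownVariants <- function(keys, source_label = "known-db",
                          n_individuals = NA_real_) {
  if (is(keys, "VariantSet")) keys <- variantKeys(keys)
  new("KnownVariants", keys = unique(keys), source_label = source_label,
      n_individuals = n_individuals)
}

setMethod("show", "KnownVariants", function(object) {
  cat("KnownVariants '", object@source_label, "': ",
      format(length(object@keys), big.mark = ","), " keys",
      if (!is.na(object@n_individuals))
        paste0(" (n = ", object@n_individuals, " individuals)"),
      "\n", sep = "")
})

#' @describeIn KnownVariants the key set
#' @param x A `KnownVariants` database.
#' @export
dbKeys <- function(x) x@keys

# --------------------------------------------------------------- trace ----

#' FilterTrace: per-stage surviving counts of the filter cascade
#'
#' The machine twin of a published filtering-summary table: an ordered list
#' of stage labels with the number of variants surviving each stage.  From
#' the caller-intersection stage onward counts are non-increasing (enforced
#' by the validity method).
#'
#' @slot trace `data.frame` with columns `stage` and `count`.
#' @slot offspring,caller_a,caller_b,vclass Run labels.
#'
#' @exportClass FilterTrace
setClass("FilterTrace",
  slots = c(trace = "data.frame", offspring = "character",
            caller_a = "character", caller_b = "character",
            vclass = "character")
)

setValidity("FilterTrace", function(object) {
  tr <- object@trace
  if (!all(c("stage", "count") %in% names(tr)))
    return("trace needs 'stage' and 'count' columns")
  i0 <- match("intersection", tr$stage)
  if (!is.na(i0)) {
    cc <- tr$count[seq(i0, nrow(tr))]
    if (any(diff(cc) > 0))
      return("surviving counts must be non-increasing from intersection on")
  }
  TRUE
})

FilterTrace <- function(trace, offspring, caller_a, caller_b, vclass) {
  new("FilterTrace", trace = trace, offspring = offspring,
      caller_a = caller_a, caller_b = caller_b, vclass = vclass)
}

setMethod("show", "FilterTrace", function(object) {
  cat("FilterTrace [", object@vclass, "] for ", object@offspring, " (",
      object@caller_a, " + ", object@caller_b, "):\n", sep = "")
  print(object@trace, row.names = FALSE)
})

#' @describeIn FilterTrace the stage/count table
#' @param x A `FilterTrace`.
#' @export
traceTable <- function(x) x@trace

#' @describeIn FilterTrace surviving count at a named stage
#' @param stage Stage label.
#' @export
traceCount <- function(x, stage) {
  i <- match(stage, x@trace$stage)
  if (is.na(i)) stop("no such stage: ", stage)
  x@trace$count[i]
}

# ----------------------------------------------------- effective genome ----

#' EffectiveGenome: callable genome size from coverage windows
#'
#' The denominator of the mutation-rate estimator: the number of fixed-size
#' coverage windows whose mean depth lies inside the callable range, times
#' the window size.
#'
#' @slot window_size Window size in bp.
#' @slot min_cov,max_cov Inclusive callable-depth bounds.
#' @slot n_windows_pass Number of windows inside the bounds.
#' @slot R Effective size in bp, exactly `n_windows_pass * window_size`.
#' @slot autosomes_only Whether sex chromosomes were excluded.
#'
#' @exportClass EffectiveGenome
setClass("EffectiveGenome",
  slots = c(window_size = "numeric", min_cov = "numeric", max_cov = "numeric",
            n_windows_pass = "numeric", R = "numeric",
            autosomes_only = "logical")
)

setValidity("EffectiveGenome", function(object) {
  if (object@min_cov >= object@max_cov) return("min_cov must be < max_cov")
  if (object@R != object@n_windows_pass * object@window_size)
    return("R must equal n_windows_pass * window_size exactly")
  TRUE
})

setMethod("show", "EffectiveGenome", function(object) {
  cat("EffectiveGenome: ", format(object@n_windows_pass, big.mark = ","),
      " windows x ", format(object@window_size, big.mark = ","), " bp in [",
      object@min_cov, "x, ", object@max_cov, "x] -> R = ",
      format(object@R, big.mark = ","), " bp\n", sep = "")
})

#' @describeIn EffectiveGenome effective size R in bp
#' @param x An `EffectiveGenome`.
#' @export
effectiveSize <- function(x) x@R

# --------------------------------------------------------------- guides ----

#' GuideQuery: a guide RNA with search budgets
#'
#' A 20-nt protospacer with its PAM pattern and the mismatch budgets used by
#' the off-target scanner: a total Hamming budget over the protospacer and a
#' tighter budget inside the PAM-proximal seed region.
#'
#' @slot name Guide label.
#' @slot protospacer 20-nt DNA string (5'->3', PAM-distal to PAM-proximal).
#' @slot pam 3-letter IUPAC PAM pattern (e.g. `"NGG"`, `"NRG"`).
#' @slot max_mismatch_total Total mismatch budget (default 5).
#' @slot seed_length Seed length in bp, measured PAM-proximal (default 12).
#' @slot max_seed_mismatch Seed mismatch budget (default 1).
#'
#' @exportClass GuideQuery
setClass("GuideQuery",
  slots = c(name = "character", protospacer = "character", pam = "character",
            max_mismatch_total = "integer", seed_length = "integer",
            max_seed_mismatch = "integer")
)

setValidity("GuideQuery", function(object) {
  if (nchar(object@protospacer) != 20L)
    return("protospacer must be 20 nt")
  if (!grepl("^[ACGT]{20}$", object@protospacer))
    return("protospacer must be plain ACGT")
  if (nchar(object@pam) != 3L) return("PAM pattern must be 3 letters")
  if (object@max_mismatch_total < 0L || object@max_seed_mismatch < 0L)
    return("mismatch budgets must be non-negative")
  if (object@max_seed_mismatch > object@max_mismatch_total)
    return("seed budget cannot exceed the total budget")
  if (object@seed_length < 0L || object@seed_length > 20L)
    return("seed length must lie in [0, 20]")
  TRUE
})

#' Construct a GuideQuery
#'
#' @param name Guide label.
#' @param protospacer 20-nt DNA string, PAM-proximal end last.
#' @param pam IUPAC PAM pattern, default `"NGG"`.
#' @param max_mismatch_total Total mismatch budget.
#' @param seed_length PAM-proximal seed length in bp.
#' @param max_seed_mismatch Seed mismatch budget.
#' @return A [GuideQuery-class].
#' @examples
#' guideQuery("sg1", strrep("ACGT", 5))
#' @export
guideQuery <- function(name, protospacer, pam = "NGG",
                       max_mismatch_total = 5L, seed_length = 12L,
                       max_seed_mismatch = 1L) {
  new("GuideQuery", name = name, protospacer = toupper(protospacer),
      pam = toupper(pam),
      max_mismatch_total = as.integer(max_mismatch_total),
      seed_length = as.integer(seed_length),
      max_seed_mismatch = as.integer(max_seed_mismatch))
}

setMethod("show", "GuideQuery", function(object) {
  cat("GuideQuery '", object@name, "': ", object@protospacer, "-",
      object@pam, ", budget ", object@max_mismatch_total, " total / ",
      object@max_seed_mismatch, " in ", object@seed_length, "-bp seed\n",
      sep = "")
})

# -------------------------------------------------------------- kinship ----

#' KinshipMatrix: pairwise kinship coefficients
#'
#' Symmetric matrix of robust pairwise kinship coefficients with, per pair,
#' the number of informative (both-genotyped) sites.  Self-kinship is
#' reported as 0.5 by convention.
#'
#' @slot phi Symmetric numeric matrix of kinship coefficients.
#' @slot n_sites Matrix of informative-site counts per pair.
#' @slot samples Sample ids (dimnames of both matrices).
#'
#' @exportClass KinshipMatrix
setClass("KinshipMatrix",
  slots = c(phi = "matrix", n_sites = "matrix", samples = "character")
)

setValidity("KinshipMatrix", function(object) {
  p <- object@phi
  if (!isTRUE(all.equal(p, t(p), tolerance = 1e-12,
                        check.attributes = FALSE)))
    return("kinship matrix must be symmetric")
  off <- p[row(p) != col(p)]
  if (any(off < -0.5 - 1e-9 | off > 0.5 + 1e-9, na.rm = TRUE))
    return("off-diagonal kinship must lie in [-0.5, 0.5]")
  TRUE
})

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix over", length(object@samples), "samples\n")
  print(round(object@phi, 4))
})

#' @describeIn KinshipMatrix the coefficient matrix
#' @param x A `KinshipMatrix`.
#' @export
kinshipCoefficients <- function(x) x@phi
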