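# readers/writers for the pipeline's standard formats, plus variant
# normalization and caller intersection

# ----------------------------------------------------------------- VCF -----

## PL index for the diploid genotype (a,b) with a<=b in the standard VCF
## ordering: idx = b(b+1)/2 + a  (0-based)
pl_index <- function(a, b) b * (b + 1L) / 2L + a + 1L

#' Read a VCF into a VariantSet
#'
#' Reads a VCF 4.x file with `GT`, `DP`, `PL` FORMAT fields and an optional
#' custom `SCF` field (mean soft-clip fraction per covering read).
#' Multiallelic rows are split into one biallelic record per alternate
#' allele: genotypes are reduced to the \{ref, alt_j\} diploid subset and the
#' PL triple is taken from the corresponding genotype indices of the full PL
#' vector.  Records that are neither SNVs nor 2-100 bp indels are dropped
#' with a message.
#'
#' @param path VCF file (plain text or gzip).
#' @param caller_label Label recorded on the returned set.
#' @return A [VariantSet-class]; sample order follows the VCF header.
#' @export
readVariants <- function(path, caller_label = "caller") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  as_row_matrix <- function(x) {
    if (is.matrix(x)) x else matrix(x, nrow = 1L,
                                    dimnames = list(NULL, names(x)))
  }
  fix <- as_row_matrix(vcfR::getFIX(v))
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns: ", path)
  samples <- colnames(v@gt)[-1L]

  gt <- as_row_matrix(vcfR::extract.gt(v, element = "GT"))
  dp <- as_row_matrix(vcfR::extract.gt(v, element = "DP",
                                       as.numeric = TRUE))
  pl <- as_row_matrix(vcfR::extract.gt(v, element = "PL"))
  scf <- tryCatch(
    as_row_matrix(vcfR::extract.gt(v, element = "SCF", as.numeric = TRUE)),
    error = function(e) NULL)

  out <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    ref <- fix[r, "REF"]
    for (j in seq_along(alts)) {
      cls <- variant_class(ref, alts[j])
      if (is.na(cls)) next
      geno_r <- character(length(samples))
      dp_r <- as.integer(round(dp[r, ]))
      pl_r <- matrix(NA_real_, length(samples), 3L)
      for (s in seq_along(samples)) {
        g <- gt[r, s]
        if (is.na(g) || g %in% c(".", "./.", ".|.")) {
          geno_r[s] <- NA_character_
        } else {
          al <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
          if (length(al) != 2L || anyNA(al))
            stop("non-diploid or malformed GT '", g, "' at VCF row ", r)
          nb <- sum(al == j)
          geno_r[s] <- c("AA", "AB", "BB")[nb + 1L]
        }
        p <- pl[r, s]
        if (!is.na(p) && p != ".") {
          pv <- suppressWarnings(as.numeric(strsplit(p, ",")[[1]]))
          m <- length(alts)
          if (length(pv) != (m + 1) * (m + 2) / 2 || anyNA(pv))
            stop("PL arity does not match ", m, " alt allele(s) at VCF row ",
                 r, " sample ", samples[s])
          pl_r[s, ] <- pv[c(pl_index(0L, 0L), pl_index(0L, j),
                            pl_index(j, j))]
        }
      }
      out[[length(out) + 1L]] <- list(
        chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
        ref = ref, alt = alts[j], geno = geno_r, dp = dp_r, pl = pl_r,
        scf = if (is.null(scf)) rep(NA_real_, length(samples)) else scf[r, ])
    }
    if (all(is.na(variant_class(ref, alts))))
      message("dropped record outside SNV/2-100bp-indel classes at row ", r)
  }
  n <- length(out)
  if (n == 0L)
    return(emptyVariantSet(samples, caller_label))
  pl_arr <- array(NA_real_, c(n, length(samples), 3L))
  for (i in seq_len(n)) pl_arr[i, , ] <- out[[i]]$pl
  VariantSet(
    chrom = vapply(out, `[[`, "", "chrom"),
    pos = vapply(out, `[[`, 1L, "pos"),
    ref = vapply(out, `[[`, "", "ref"),
    alt = vapply(out, `[[`, "", "alt"),
    samples = samples,
    geno = do.call(rbind, lapply(out, `[[`, "geno")),
    depth = do.call(rbind, lapply(out, `[[`, "dp")),
    pl = pl_arr,
    scf = do.call(rbind, lapply(out, function(x) as.numeric(x$scf))),
    caller = caller_label)
}

#' An empty VariantSet over given samples
#' @param samples Sample ids.
#' @param caller_label Caller label.
#' @return A zero-variant [VariantSet-class].
#' @export
emptyVariantSet <- function(samples, caller_label = "caller") {
  new("VariantSet",
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), vclass = character(0), samples = samples,
      geno = matrix(character(0), 0, length(samples),
                    dimnames = list(NULL, samples)),
      depth = matrix(integer(0), 0, length(samples),
                     dimnames = list(NULL, samples)),
      pl = array(numeric(0), c(0, length(samples), 3)),
      scf = matrix(numeric(0), 0, length(samples),
                   dimnames = list(NULL, samples)),
      caller = caller_label)
}

#' Write a VariantSet as VCF 4.2
#'
#' Emits a plain-text VCF with `GT:DP:PL:SCF` FORMAT fields (SCF written at
#' four decimals, `.` when missing).  Records are written sorted by
#' chromosome and position.
#'
#' @param x A [VariantSet-class].
#' @param path Output file.
#' @param genome Optional [AnnotatedGenome-class] used to emit contig header
#'   lines.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(x, path, genome = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=trioDNV",
    if (!is.null(genome))
      sprintf("##contig=<ID=%s,length=%d>", names(genomeSeq(genome)),
              Biostrings::width(genomeSeq(genome))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=PL,Number=G,Type=Integer,Description=",
           "\"Normalized phred-scaled genotype likelihoods\">"),
    paste0("##FORMAT=<ID=SCF,Number=1,Type=Float,Description=",
           "\"Mean soft-clipped fraction per covering read\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(x)), collapse = "\t")
  )
  o <- order(x@chrom, x@pos, x@ref, x@alt)
  gt_map <- c(AA = "0/0", AB = "0/1", BB = "1/1")
  lines <- vapply(o, function(i) {
    cells <- vapply(seq_along(x@samples), function(s) {
      g <- x@geno[i, s]
      gt <- if (is.na(g)) "./." else gt_map[[g]]
      dp <- x@depth[i, s]
      pl <- x@pl[i, s, ]
      scf <- x@scf[i, s]
      paste(gt,
            if (is.na(dp)) "." else dp,
            if (anyNA(pl)) "." else paste(round(pl), collapse = ","),
            if (is.na(scf)) "." else sprintf("%.4f", scf),
            sep = ":")
    }, character(1))
    paste(c(x@chrom[i], x@pos[i], ".", x@ref[i], x@alt[i], ".", ".", ".",
            "GT:DP:PL:SCF", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# -------------------------------------------------------- normalization ----

## left-align + parsimony-trim one allele pair against the reference;
## returns list(pos, ref, alt)
normalize_one <- function(chrom_seq, pos, ref, alt) {
  # verify the claimed reference allele
  obs <- substr(chrom_seq, pos, pos + nchar(ref) - 1L)
  if (!identical(obs, ref))
    stop("reference mismatch at ", pos, ": VCF says '", ref,
         "', genome has '", obs, "'")
  if (nchar(ref) == 1L && nchar(alt) == 1L)
    return(list(pos = pos, ref = ref, alt = alt))
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    # trim shared trailing base, extending left when an allele would empty
    if (lr > 0 && la > 0 &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      if (lr == 1L || la == 1L) {
        if (pos == 1L) break  # cannot extend further left
        pos <- pos - 1L
        b <- substr(chrom_seq, pos, pos)
        ref <- paste0(b, substr(ref, 1, lr - 1L))
        alt <- paste0(b, substr(alt, 1, la - 1L))
      } else {
        ref <- substr(ref, 1, lr - 1L)
        alt <- substr(alt, 1, la - 1L)
      }
    } else break
  }
  # trim shared leading bases while both alleles keep >= 1 base
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variants against a reference genome
#'
#' Left-aligns and parsimony-trims indel representations so that caller
#' intersection and database lookups compare like with like; SNVs are
#' returned unchanged.  The operation is idempotent.  Distinct input
#' spellings that normalize to the same key are deduplicated (first record
#' kept) with a message.
#'
#' @param x A [VariantSet-class].
#' @param genome An [AnnotatedGenome-class]; every record's reference allele
#'   is checked against it.
#' @return A normalized [VariantSet-class].
#' @export
normalizeVariants <- function(x, genome) {
  if (length(x) == 0L) return(x)
  missing_chrom <- setdiff(unique(x@chrom), names(genomeSeq(genome)))
  if (length(missing_chrom))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ","))
  seqs <- lapply(setNames(nm = unique(x@chrom)),
                 function(cn) chromString(genome, cn))
  for (i in seq_len(length(x))) {
    nv <- normalize_one(seqs[[x@chrom[i]]], x@pos[i], x@ref[i], x@alt[i])
    x@pos[i] <- nv$pos; x@ref[i] <- nv$ref; x@alt[i] <- nv$alt
  }
  keys <- variantKeys(x)
  if (anyDuplicated(keys)) {
    message("deduplicated ", sum(duplicated(keys)),
            " record(s) that normalized to the same key")
    x <- x[!duplicated(keys)]
  }
  x
}

# ---------------------------------------------------------- intersection ----

#' Intersect two caller call sets on variant keys
#'
#' Keeps variants whose normalized `(chrom, pos, ref, alt)` key is reported
#' by both callers; per-sample calls are taken from `a` (the primary
#' caller).
#'
#' @param a,b [VariantSet-class] objects normalized against the same genome.
#' @return The subset of `a` whose keys also occur in `b`.
#' @export
intersectCallsets <- function(a, b) {
  chroms_a <- unique(a@chrom); chroms_b <- unique(b@chrom)
  if (length(chroms_a) && length(chroms_b) &&
      !length(intersect(chroms_a, chroms_b)) &&
      (length(a) > 0L && length(b) > 0L))
    stop("call sets share no contig names; were they normalized against ",
         "the same genome?")
  a[variantKeys(a) %in% variantKeys(b)]
}

# ------------------------------------------------------------- tables -----

#' Read a known-variant database
#'
#' Accepts either a VCF (keys taken after the same biallelic splitting as
#' [readVariants()]) or a tab-separated table with columns
#' `chrom, pos, ref, alt` (header required).
#'
#' @param path VCF or TSV file.
#' @param source_label,n_individuals Provenance metadata.
#' @return A [KnownVariants-class].
#' @export
readKnownDb <- function(path, source_label = basename(path),
                        n_individuals = NA_real_) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    keys <- unlist(lapply(seq_len(nrow(fix)), function(r) {
      alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
      variantKey(fix[r, "CHROM"], as.integer(fix[r, "POS"]),
                 fix[r, "REF"], alts)
    }))
  } else {
    tb <- read.table(path, header = TRUE, sep = "\t",
                     colClasses = c("character", "integer", "character",
                                    "character"))
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tb)))
      stop("known-db table needs columns: ", paste(need, collapse = ", "))
    keys <- variantKey(tb$chrom, tb$pos, tb$ref, tb$alt)
  }
  KnownVariants(keys, source_label = source_label,
                n_individuals = n_individuals)
}

#' Write a known-variant database as a 4-column TSV
#' @param db A [KnownVariants-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeKnownDb <- function(db, path) {
  parts <- strsplit(dbKeys(db), ":", fixed = TRUE)
  tb <- data.frame(chrom = vapply(parts, `[`, "", 1),
                   pos = as.integer(vapply(parts, `[`, "", 2)),
                   ref = vapply(parts, `[`, "", 3),
                   alt = vapply(parts, `[`, "", 4))
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree table
#'
#' Tab-separated with header and at least the columns `offspring`, `sire`,
#' `dam`.  Each row is validated (three distinct ids; an offspring may not
#' be its own parent).
#'
#' @param path Pedigree file.
#' @param cohort Optional full cohort ids; defaults to all ids in the file.
#' @return A list of [TrioContext-class] objects, one per row, named by
#'   offspring id.
#' @export
readPedigree <- function(path, cohort = NULL) {
  tb <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("offspring", "sire", "dam")
  if (!all(need %in% names(tb)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  if (is.null(cohort))
    cohort <- unique(c(tb$offspring, tb$sire, tb$dam))
  trios <- lapply(seq_len(nrow(tb)), function(i) {
    if (tb$offspring[i] %in% c(tb$sire[i], tb$dam[i]))
      stop("pedigree row ", i, ": offspring listed as its own parent")
    TrioContext(tb$sire[i], tb$dam[i], tb$offspring[i], cohort)
  })
  names(trios) <- tb$offspring
  trios
}

#' Write a pedigree table
#' @param trios List of [TrioContext-class] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(trios, path) {
  tb <- data.frame(
    offspring = vapply(trios, function(t) t@offspring, ""),
    sire = vapply(trios, function(t) t@sire, ""),
    dam = vapply(trios, function(t) t@dam, ""))
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a reference genome as FASTA
#'
#' @param path FASTA file.
#' @param autosome Optional named logical autosome flags (default heuristic:
#'   names not matching X/Y/MT are autosomal).
#' @param name Assembly label.
#' @return `readGenome()` an [AnnotatedGenome-class]; `writeGenome()` the
#'   path, invisibly.
#' @export
readGenome <- function(path, autosome = NULL, name = basename(path)) {
  seq <- Biostrings::readDNAStringSet(path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  AnnotatedGenome(seq, autosome = autosome, name = name)
}

#' @rdname readGenome
#' @param genome An [AnnotatedGenome-class].
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genomeSeq(genome), path, width = 70L)
  invisible(path)
}

#' Read coverage windows
#'
#' Tab-separated with header columns `chrom`, `start` (0-based), `end`,
#' `mean_depth`.
#'
#' @param path Window table file.
#' @return A `data.frame`.
#' @export
readCoverageWindows <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "mean_depth")
  if (!all(need %in% names(tb)))
    stop("coverage table needs columns: ", paste(need, collapse = ", "))
  tb
}

#' Read guides from a TSV (name, protospacer, pam) or FASTA
#'
#' @param path Guide file.  FASTA records may carry the PAM pattern after a
#'   space in the header (default `NGG`).
#' @param ... Budget arguments passed to [guideQuery()].
#' @return List of [GuideQuery-class] objects.
#' @export
readGuides <- function(path, ...) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    nm <- names(seqs)
    pam <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "NGG")
    nm <- sub("\\s.*$", "", nm)
    mapply(function(n, s, p) guideQuery(n, s, pam = p, ...),
           nm, as.character(seqs), pam, SIMPLIFY = FALSE)
  } else {
    tb <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    out <- lapply(seq_len(nrow(tb)), function(i)
      guideQuery(tb$name[i], tb$protospacer[i], pam = tb$pam[i], ...))
    names(out) <- tb$name
    out
  }
}
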