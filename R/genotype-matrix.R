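#' Construct a genotype matrix
#'
#' The central genotype container: unphased biallelic (optionally triallelic)
#' calls for a fixed panel of variants, one row per sample. Calls are stored
#' as unordered allele pairs (`"A/G"`); missing calls are `NA`. A per-sample
#' CYP2D6 copy number (default 2) travels with the matrix because the CYP2D6
#' activity score is copy-number aware.
#'
#' @param calls character matrix (samples x variants) of `"allele1/allele2"`
#'   strings, or `NA` for missing calls. Row and column names are used as
#'   sample and variant identifiers when `samples`/`variants` are not given.
#' @param variants data.frame with columns `variant_id`, `major_allele`,
#'   `minor_allele` and optionally `chrom`, `position`, `extra_allele`.
#' @param samples character vector of sample identifiers.
#' @param cyp2d6_cn integer vector of per-sample CYP2D6 copy numbers
#'   (recycled; default 2).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, samples = rownames(calls),
                            cyp2d6_cn = 2L) {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "major_allele", "minor_allele") %in%
                  names(variants)))
  variants$variant_id <- as.character(variants$variant_id)
  if (ncol(calls) != nrow(variants))
    stop("calls has ", ncol(calls), " columns but ", nrow(variants),
         " variants are declared")
  if (length(samples) != nrow(calls))
    stop("sample labels do not match the number of rows")
  if (any(variants$major_allele == variants$minor_allele))
    stop("major and minor allele must differ")
  if (!"chrom" %in% names(variants)) variants$chrom <- NA_character_
  if (!"position" %in% names(variants)) variants$position <- NA_real_
  if (!"extra_allele" %in% names(variants))
    variants$extra_allele <- NA_character_
  rownames(calls) <- samples
  colnames(calls) <- variants$variant_id
  ## canonicalize each call to a sorted allele pair and validate alleles
  for (j in seq_len(ncol(calls))) {
    ok <- !is.na(calls[, j])
    if (!any(ok)) next
    parts <- strsplit(calls[ok, j], "/", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad))
      stop("malformed call(s) at ", variants$variant_id[j], ": ",
           paste(unique(calls[ok, j][bad]), collapse = ", "))
    declared <- c(variants$major_allele[j], variants$minor_allele[j],
                  variants$extra_allele[j])
    declared <- declared[!is.na(declared)]
    alle <- unlist(parts)
    if (!all(alle %in% declared))
      stop("undeclared allele(s) at ", variants$variant_id[j], ": ",
           paste(setdiff(unique(alle), declared), collapse = ", "))
    calls[ok, j] <- vapply(parts, function(a)
      paste(sort(a), collapse = "/"), character(1))
  }
  structure(list(calls = calls, variants = variants,
                 samples = as.character(samples),
                 cyp2d6_cn = rep_len(as.integer(cyp2d6_cn), length(samples))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$calls))
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants;", n_missing, "missing call(s)\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Minor-allele dosage of one variant
#'
#' Counts copies of the (orientation-normalized) minor allele in each
#' sample's call: the additive 0/1/2 encoding used throughout association
#' testing. For triallelic variants the analysis is restricted to the
#' primary allele pair: calls carrying the extra allele are returned as `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param variant_id variant to extract.
#' @param count_allele allele to count; defaults to the declared minor allele.
#' @return integer vector (one per sample) with `NA` for missing calls.
#' @export
genotype_dosage <- function(gm, variant_id, count_allele = NULL) {
  j <- match(variant_id, gm$variants$variant_id)
  if (is.na(j)) stop("variant not in panel: ", variant_id)
  target <- count_allele %||% gm$variants$minor_allele[j]
  extra <- gm$variants$extra_allele[j]
  calls <- gm$calls[, j]
  out <- rep(NA_integer_, length(calls))
  ok <- !is.na(calls)
  if (any(ok)) {
    parts <- strsplit(calls[ok], "/", fixed = TRUE)
    d <- vapply(parts, function(a) sum(a == target), integer(1))
    if (!is.na(extra)) {
      has_extra <- vapply(parts, function(a) any(a == extra), logical(1))
      d[has_extra] <- NA_integer_
    }
    out[ok] <- d
  }
  out
}

#' Normalize allele orientation so the minor allele is the rarer one
#'
#' Swaps the declared major/minor labels of any variant whose declared minor
#' allele has empirical frequency above 0.5 in the data, so that reported
#' MAFs are always at most 0.5. Ties (frequency exactly 0.5) keep the
#' declared orientation. Idempotent; calls are untouched (orientation is
#' metadata).
#'
#' @param gm a [genotype_matrix()].
#' @return the matrix with possibly swapped major/minor labels.
#' @export
normalize_orientation <- function(gm) {
  for (j in seq_len(nrow(gm$variants))) {
    d <- genotype_dosage(gm, gm$variants$variant_id[j])
    if (all(is.na(d))) next
    f <- mean(d, na.rm = TRUE) / 2
    if (f > 0.5) {
      tmp <- gm$variants$major_allele[j]
      gm$variants$major_allele[j] <- gm$variants$minor_allele[j]
      gm$variants$minor_allele[j] <- tmp
    }
  }
  gm
}

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param samples,variants character vectors (or logical/integer indices)
#'   selecting samples and/or variants; `NULL` keeps all.
#' @return the subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(gm$samples) else {
    if (is.character(samples)) match(samples, gm$samples) else samples
  }
  vi <- if (is.null(variants)) seq_len(nrow(gm$variants)) else {
    if (is.character(variants)) match(variants, gm$variants$variant_id)
    else variants
  }
  if (anyNA(si)) stop("unknown sample(s)")
  if (anyNA(vi)) stop("unknown variant(s)")
  genotype_matrix(gm$calls[si, vi, drop = FALSE],
                  gm$variants[vi, , drop = FALSE],
                  samples = gm$samples[si],
                  cyp2d6_cn = gm$cyp2d6_cn[si])
}
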