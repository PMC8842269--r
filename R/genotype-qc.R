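#' Hardy-Weinberg equilibrium test
#'
#' Tests genotype counts `(n_AA, n_Aa, n_aa)` against Hardy-Weinberg
#' proportions, either by the 1-df Pearson chi-square test or by the exact
#' conditional test on the heterozygote count (all heterozygote counts
#' compatible with the observed minor-allele count are enumerated and the
#' probabilities of those no more likely than the observed configuration are
#' summed). `method = "auto"` (the package default throughout QC) uses the
#' exact test when fewer than 100 minor alleles are observed and the
#' chi-square test otherwise, the usual small-sample practice.
#'
#' @param counts integer vector `c(n_AA, n_Aa, n_aa)` of genotype counts,
#'   major homozygote first.
#' @param method `"auto"`, `"chi2"` or `"exact"`.
#' @return the p-value in (0, 1]. Monomorphic input returns 1 with a warning.
#' @examples
#' hwe_test(c(25, 50, 25))          # exact HWE proportions -> p = 1
#' hwe_test(c(10, 0, 10), "exact")  # extreme heterozygote deficit
#' @export
hwe_test <- function(counts, method = c("auto", "chi2", "exact")) {
  method <- match.arg(method)
  stopifnot(length(counts) == 3, all(counts >= 0), sum(counts) >= 1)
  counts <- as.integer(counts)
  n <- sum(counts)
  n_minor <- counts[2] + 2L * counts[3]
  if (n_minor == 0L || n_minor == 2L * n) {
    warning("monomorphic genotype counts: HWE p-value set to 1")
    return(1)
  }
  if (method == "auto")
    method <- if (min(n_minor, 2L * n - n_minor) < 100L) "exact" else "chi2"
  if (method == "chi2") hwe_chi2(counts) else hwe_exact(counts)
}

hwe_chi2 <- function(counts) {
  n <- sum(counts)
  p <- (counts[1] + counts[2] / 2) / n
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

## exact test conditional on the minor-allele count: probabilities of all
## compatible heterozygote counts via a log-scale recurrence
hwe_exact <- function(counts) {
  n <- sum(counts)
  nm <- min(counts[2] + 2L * counts[3], 2L * n - counts[2] - 2L * counts[3])
  obs_het <- counts[2]
  hets <- seq(nm %% 2L, nm, by = 2L)
  ## P(het = h | n, nm) proportional to n! 2^h / (h! n_aa! n_AA!)
  logp <- vapply(hets, function(h) {
    naa <- (nm - h) / 2
    nAA <- n - h - naa
    h * log(2) - lgamma(h + 1) - lgamma(naa + 1) - lgamma(nAA + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(obs_het, hets)]
  min(1, sum(pr[pr <= p_obs + 1e-12]))
}

#' Genotype quality-control summary
#'
#' Per-sample and per-variant call rates, minor-allele frequencies, and
#' Hardy-Weinberg p-values (chi-square, exact, and the auto-selected
#' default). Triallelic variants are summarized on their primary
#' major/minor pair, with the extra-allele frequency reported separately.
#' When a case/control `status` is supplied, HWE is additionally evaluated
#' within each stratum, since deviations confined to cases can flag
#' genotyping or association artefacts.
#'
#' @param gm a [genotype_matrix()].
#' @param status optional 0/1 vector (one per sample) splitting the cohort
#'   into controls (0) and cases (1) for stratified HWE.
#' @return a `qc_summary` object: list with `sample` (data.frame
#'   `sample_id`, `call_rate`) and `variant` (data.frame with `call_rate`,
#'   `maf`, `extra_allele_freq`, `hwe_chi2_p`, `hwe_exact_p`, `hwe_p`, and
#'   stratified columns when `status` is given; variants with zero
#'   non-missing calls have `maf = NA` and `flagged = TRUE`).
#' @export
compute_qc <- function(gm, status = NULL) {
  stopifnot(length(gm$samples) >= 1, nrow(gm$variants) >= 1)
  calls <- gm$calls
  sample_cr <- rowMeans(!is.na(calls))
  vt <- gm$variants
  res <- lapply(seq_len(nrow(vt)), function(j) {
    d <- genotype_dosage(gm, vt$variant_id[j])
    nonmiss_calls <- sum(!is.na(calls[, j]))
    cr <- nonmiss_calls / length(gm$samples)
    extra_freq <- NA_real_
    if (!is.na(vt$extra_allele[j])) {
      alle <- unlist(strsplit(calls[!is.na(calls[, j]), j], "/", fixed = TRUE))
      extra_freq <- if (length(alle)) mean(alle == vt$extra_allele[j]) else NA
    }
    nd <- sum(!is.na(d))
    if (nd == 0L) {
      return(data.frame(variant_id = vt$variant_id[j], call_rate = cr,
                        maf = NA_real_, extra_allele_freq = extra_freq,
                        n_AA = 0L, n_Aa = 0L, n_aa = 0L,
                        hwe_chi2_p = NA_real_, hwe_exact_p = NA_real_,
                        hwe_p = NA_real_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    cnt <- c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
             sum(d == 2, na.rm = TRUE))
    maf <- (cnt[2] + 2 * cnt[3]) / (2 * nd)
    mono <- maf == 0 || maf == 1
    hp <- function(m) if (mono) 1 else suppressWarnings(hwe_test(cnt, m))
    data.frame(variant_id = vt$variant_id[j], call_rate = cr, maf = maf,
               extra_allele_freq = extra_freq,
               n_AA = cnt[1], n_Aa = cnt[2], n_aa = cnt[3],
               hwe_chi2_p = hp("chi2"), hwe_exact_p = hp("exact"),
               hwe_p = hp("auto"), flagged = mono,
               stringsAsFactors = FALSE)
  })
  variant <- do.call(rbind, res)
  if (!is.null(status)) {
    stopifnot(length(status) == length(gm$samples))
    for (s in c(0, 1)) {
      lab <- if (s == 1) "cases" else "controls"
      sub <- subset_genotypes(gm, samples = which(status == s))
      pv <- vapply(vt$variant_id, function(v) {
        d <- genotype_dosage(sub, v)
        d <- d[!is.na(d)]
        if (!length(d)) return(NA_real_)
        cnt <- c(sum(d == 0), sum(d == 1), sum(d == 2))
        if (cnt[1] == length(d) || cnt[3] == length(d)) return(1)
        suppressWarnings(hwe_test(cnt, "auto"))
      }, numeric(1))
      variant[[paste0("hwe_p_", lab)]] <- pv
    }
  }
  structure(list(sample = data.frame(sample_id = gm$samples,
                                     call_rate = sample_cr,
                                     stringsAsFactors = FALSE),
                 variant = variant),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("QC summary:", nrow(x$sample), "samples,", nrow(x$variant),
      "variants\n")
  cat(sprintf("  mean sample call rate %.2f%%; mean variant call rate %.2f%%\n",
              100 * mean(x$sample$call_rate),
              100 * mean(x$variant$call_rate, na.rm = TRUE)))
  nfail <- sum(x$variant$hwe_p < 0.001, na.rm = TRUE)
  cat("  variants with HWE p < 0.001:", nfail, "\n")
  invisible(x)
}

#' Write a QC report as TSV and JSON
#'
#' @param qc a [compute_qc()] result.
#' @param prefix output path prefix; writes `<prefix>_variants.tsv`,
#'   `<prefix>_samples.tsv` and `<prefix>.json`.
#' @return the JSON path, invisibly.
#' @export
write_qc_report <- function(qc, prefix) {
  utils::write.table(qc$variant, paste0(prefix, "_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qc$sample, paste0(prefix, "_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(sample = qc$sample, variant = qc$variant),
                       paste0(prefix, ".json"), digits = NA, na = "null")
  invisible(paste0(prefix, ".json"))
}

#' Filter variants (and optionally samples) on call rate
#'
#' Reproduces the usual genotyping QC gate: variants below the call-rate
#' threshold are dropped (each drop is reported via `message()`), and
#' samples below `min_sample_call_rate` are dropped when that threshold is
#' given.
#'
#' @param gm a [genotype_matrix()].
#' @param qc matching [compute_qc()] result (recomputed when `NULL`).
#' @param min_call_rate minimum per-variant call rate in \[0,1\].
#' @param min_sample_call_rate optional minimum per-sample call rate.
#' @return the filtered `genotype_matrix`; dropped variant/sample ids are
#'   attached as attributes `dropped_variants` / `dropped_samples`.
#' @export
filter_variants <- function(gm, qc = NULL, min_call_rate = 0.9,
                            min_sample_call_rate = NULL) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1)
  if (is.null(qc)) qc <- compute_qc(gm)
  keep <- qc$variant$call_rate >= min_call_rate
  dropped <- qc$variant$variant_id[!keep]
  for (v in dropped)
    message("dropping variant ", v, ": call rate ",
            sprintf("%.3f", qc$variant$call_rate[qc$variant$variant_id == v]),
            " < ", min_call_rate)
  if (!any(keep))
    stop("all ", nrow(qc$variant), " variants fall below call rate ",
         min_call_rate)
  out <- subset_genotypes(gm, variants = which(keep))
  dropped_samples <- character(0)
  if (!is.null(min_sample_call_rate)) {
    scr <- rowMeans(!is.na(out$calls))
    keep_s <- scr >= min_sample_call_rate
    dropped_samples <- out$samples[!keep_s]
    for (s in dropped_samples)
      message("dropping sample ", s, ": call rate below ",
              min_sample_call_rate)
    if (!any(keep_s)) stop("all samples fall below the sample call rate gate")
    out <- subset_genotypes(out, samples = which(keep_s))
  }
  attr(out, "dropped_variants") <- dropped
  attr(out, "dropped_samples") <- dropped_samples
  out
}
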