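#' Estimate multi-locus haplotype frequencies by EM
#'
#' Expectation-maximization over unphased multilocus genotypes: the E-step
#' distributes each sample's probability over all phase assignments
#' compatible with its genotype, proportional to the product of the current
#' haplotype frequencies; the M-step re-estimates the frequencies from the
#' expected haplotype counts. The log-likelihood is non-decreasing across
#' iterations and convergence is declared when the largest frequency change
#' falls below `tol`. Frequencies are initialized from phase-ignorant
#' allele-frequency products with a small seeded jitter, which avoids the
#' flat-likelihood stall of all-heterozygote inputs while keeping runs
#' deterministic.
#'
#' Samples with a missing call at any block locus are excluded from the
#' estimation; both the complete-call coverage and the fraction of samples
#' with unambiguous phase (at most one heterozygous locus) are reported.
#'
#' @param gm a [genotype_matrix()].
#' @param loci 2-8 variant ids defining the block.
#' @param tol convergence tolerance on frequency changes (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @param seed seed for the initialization jitter.
#' @param block_id optional label.
#' @return a `haplotype_block`: list with `loci`, `haplotypes` (data.frame
#'   with one 0/1 column per locus, `label` built from allele symbols, and
#'   `freq`), `loglik` (per-iteration trace), `converged`, `n_used`,
#'   `coverage_complete`, `coverage_phased`, and `dosage` (samples x
#'   haplotypes matrix of posterior-expected haplotype counts, `NA` rows
#'   for excluded samples).
#' @export
em_haplotype_frequencies <- function(gm, loci, tol = 1e-8, max_iter = 1000,
                                     seed = 1, block_id = NULL) {
  L <- length(loci)
  stopifnot(L >= 2, L <= 8)
  D <- vapply(loci, function(v) genotype_dosage(gm, v),
              integer(length(gm$samples)))
  D <- matrix(D, ncol = L, dimnames = list(gm$samples, loci))
  complete <- stats::complete.cases(D)
  n_used <- sum(complete)
  if (n_used == 0) stop("no sample has complete calls at the block loci")
  Dc <- D[complete, , drop = FALSE]
  haps <- as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE))
  colnames(haps) <- loci
  H <- nrow(haps)
  ## per-sample compatible ordered phase assignments (h1, h2): the het loci
  ## are split between the two haplotypes in every possible way
  pairs <- lapply(seq_len(n_used), function(i) {
    g <- Dc[i, ]
    het <- which(g == 1L)
    base <- ifelse(g == 2L, 1L, 0L)
    if (!length(het)) {
      h <- hap_index(base)
      return(cbind(h, h))
    }
    combos <- as.matrix(expand.grid(rep(list(0:1), length(het)),
                                    KEEP.OUT.ATTRS = FALSE))
    t(apply(combos, 1, function(cc) {
      h1 <- base; h1[het] <- cc
      h2 <- base; h2[het] <- 1L - cc
      c(hap_index(h1), hap_index(h2))
    }))
  })
  ## initialization: allele-frequency products with multiplicative jitter
  p <- colMeans(Dc) / 2
  f <- apply(haps, 1, function(h) prod(ifelse(h == 1, p, 1 - p)))
  set.seed(seed)
  f <- f * exp(stats::runif(H, -1e-3, 1e-3))
  f <- pmax(f, 1e-12)
  f <- f / sum(f)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    counts <- numeric(H)
    ll <- 0
    for (i in seq_len(n_used)) {
      pr <- pairs[[i]]
      w <- f[pr[, 1]] * f[pr[, 2]]
      tot <- sum(w)
      ll <- ll + log(tot)
      w <- w / tot
      for (k in seq_len(nrow(pr))) {
        counts[pr[k, 1]] <- counts[pr[k, 1]] + w[k]
        counts[pr[k, 2]] <- counts[pr[k, 2]] + w[k]
      }
    }
    loglik <- c(loglik, ll)
    f_new <- counts / (2 * n_used)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  ## posterior-expected haplotype dosage per sample under the final f
  dosage <- matrix(NA_real_, length(gm$samples), H,
                   dimnames = list(gm$samples, NULL))
  for (i in seq_len(n_used)) {
    pr <- pairs[[i]]
    w <- f[pr[, 1]] * f[pr[, 2]]
    w <- w / sum(w)
    row <- numeric(H)
    for (k in seq_len(nrow(pr))) {
      row[pr[k, 1]] <- row[pr[k, 1]] + w[k]
      row[pr[k, 2]] <- row[pr[k, 2]] + w[k]
    }
    dosage[which(complete)[i], ] <- row
  }
  vt <- gm$variants[match(loci, gm$variants$variant_id), ]
  labels <- apply(haps, 1, function(h)
    paste(ifelse(h == 1, vt$minor_allele, vt$major_allele), collapse = ""))
  hap_df <- data.frame(haps, label = labels, freq = f,
                       stringsAsFactors = FALSE, check.names = FALSE)
  n_het <- rowSums(Dc == 1L)
  structure(list(block_id = block_id %||% paste(loci, collapse = "+"),
                 loci = loci, haplotypes = hap_df, loglik = loglik,
                 converged = converged, n_used = n_used,
                 coverage_complete = n_used / length(gm$samples),
                 coverage_phased = sum(n_het <= 1) / length(gm$samples),
                 dosage = dosage),
            class = "haplotype_block")
}

hap_index <- function(h) sum(h * 2L^(seq_along(h) - 1L)) + 1L

#' @export
print.haplotype_block <- function(x, min_freq = 0.01, ...) {
  cat("haplotype_block", x$block_id, ":", length(x$loci), "loci,",
      x$n_used, "samples used;",
      if (x$converged) "EM converged" else "EM NOT converged", "\n")
  hd <- x$haplotypes[x$haplotypes$freq >= min_freq, c("label", "freq")]
  hd <- hd[order(-hd$freq), ]
  print(hd, row.names = FALSE)
  invisible(x)
}

#' Pairwise linkage disequilibrium from two-locus haplotype frequencies
#'
#' For two biallelic loci with estimated haplotype frequencies:
#' `D = p_AB - p_A p_B` (A, B the minor alleles),
#' `D' = |D| / D_max` with `D_max = min(p_A q_B, q_A p_B)` for `D > 0` and
#' `min(p_A p_B, q_A q_B)` otherwise, and
#' `r^2 = D^2 / (p_A q_A p_B q_B)`.
#'
#' @param block a two-locus `haplotype_block` from
#'   [em_haplotype_frequencies()].
#' @return list with `D`, `D_prime`, `r2`, and the marginal minor-allele
#'   frequencies `p_A`, `p_B`.
#' @export
ld_pairwise <- function(block) {
  stopifnot(inherits(block, "haplotype_block"), length(block$loci) == 2)
  h <- block$haplotypes
  p_a <- sum(h$freq[h[[block$loci[1]]] == 1])
  p_b <- sum(h$freq[h[[block$loci[2]]] == 1])
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1))
    stop("monomorphic locus: LD undefined")
  p_ab <- sum(h$freq[h[[block$loci[1]]] == 1 & h[[block$loci[2]]] == 1])
  D <- p_ab - p_a * p_b
  d_max <- if (D > 0) min(p_a * (1 - p_b), (1 - p_a) * p_b) else
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  list(D = D,
       D_prime = if (d_max == 0) 0 else abs(D) / d_max,
       r2 = D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)),
       p_A = p_a, p_B = p_b)
}

#' Pairwise D'/r2 matrix over a set of loci
#'
#' Runs the two-locus EM on every pair and collects D' and r^2, the usual
#' input of an LD heatmap.
#'
#' @param gm a [genotype_matrix()].
#' @param loci variant ids (default: all panel variants).
#' @param seed EM initialization seed.
#' @return list of matrices `D_prime` and `r2` (loci x loci).
#' @export
ld_matrix <- function(gm, loci = gm$variants$variant_id, seed = 1) {
  k <- length(loci)
  dp <- matrix(NA_real_, k, k, dimnames = list(loci, loci))
  r2 <- dp
  diag(dp) <- 1
  diag(r2) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ld <- ld_pairwise(em_haplotype_frequencies(gm, c(loci[i], loci[j]),
                                               seed = seed))
    dp[i, j] <- dp[j, i] <- ld$D_prime
    r2[i, j] <- r2[j, i] <- ld$r2
  }
  list(D_prime = dp, r2 = r2)
}

#' Detect LD blocks by greedy adjacent-D' merging
#'
#' Orders the loci by position, computes D' between each adjacent pair
#' (two-locus EM), and greedily merges adjacent loci whose D' meets the
#' threshold; runs the multi-locus EM on every merged block of two or more
#' loci. Loci on different chromosomes are never merged.
#'
#' @param gm a [genotype_matrix()].
#' @param loci variant ids to scan (default: all panel variants, ordered
#'   by chromosome and position).
#' @param dprime_threshold merge threshold on D' (default 0.8).
#' @param seed EM initialization seed.
#' @return list of `haplotype_block` objects (blocks of >= 2 loci).
#' @export
find_blocks <- function(gm, loci = NULL, dprime_threshold = 0.8, seed = 1) {
  vt <- gm$variants
  if (is.null(loci)) {
    vt <- vt[order(vt$chrom, vt$position), ]
    loci <- vt$variant_id
  } else {
    vt <- vt[match(loci, vt$variant_id), ]
  }
  k <- length(loci)
  if (k < 2) return(list())
  same_chrom <- function(i) {
    c1 <- vt$chrom[i]; c2 <- vt$chrom[i + 1]
    is.na(c1) || is.na(c2) || c1 == c2
  }
  dp_adj <- vapply(seq_len(k - 1), function(i) {
    if (!same_chrom(i)) return(-Inf)
    ld_pairwise(em_haplotype_frequencies(gm, loci[c(i, i + 1)],
                                         seed = seed))$D_prime
  }, numeric(1))
  merge <- dp_adj >= dprime_threshold
  blocks <- list()
  i <- 1
  bi <- 0
  while (i <= k) {
    j <- i
    while (j < k && merge[j]) j <- j + 1
    if (j > i) {
      bi <- bi + 1
      blocks[[bi]] <- em_haplotype_frequencies(
        gm, loci[i:j], seed = seed, block_id = paste0("block", bi))
    }
    i <- j + 1
  }
  blocks
}

#' Haplotype-outcome association
#'
#' For each haplotype above the frequency floor, the per-sample expected
#' haplotype dosage (posterior-weighted count from the EM phase
#' posteriors) is tested against the binary outcome. The default,
#' unadjusted mode reports the 1-df chi-square score statistic
#' `STAT = U^2 / V` with `U = sum d_i (y_i - ybar)` and
#' `V = ybar (1 - ybar) sum (d_i - dbar)^2`, plus the OR from a logistic
#' fit of the outcome on the dosage; the covariate-adjusted mode includes
#' the eight risk covariates and reports the Wald chi-square of the
#' dosage term.
#'
#' @param block a `haplotype_block`.
#' @param outcome name of the binary outcome column in `data`.
#' @param data cohort data.frame aligned with the block's samples (matched
#'   on `sample_id` when present).
#' @param covariate_adjust include the eight risk covariates (default
#'   FALSE).
#' @param min_freq haplotypes below this frequency are skipped (default
#'   0.01).
#' @return data.frame with `haplotype`, `frequency`, `or`, `stat`, `p`
#'   per tested haplotype.
#' @export
haplotype_association <- function(block, outcome, data,
                                  covariate_adjust = FALSE,
                                  min_freq = 0.01) {
  idx <- if (!is.null(data$sample_id))
    match(data$sample_id, rownames(block$dosage)) else
      seq_len(nrow(block$dosage))
  keep_h <- which(block$haplotypes$freq >= min_freq)
  rows <- list()
  for (h in keep_h) {
    d <- block$dosage[idx, h]
    y <- data[[outcome]]
    ok <- !is.na(d) & !is.na(y)
    dd <- d[ok]; yy <- y[ok]
    if (covariate_adjust) {
      dat <- data[ok, , drop = FALSE]
      dat$.hap <- dd
      dat$.y <- yy
      fit <- fit_logistic(logistic_model_spec(".y", eq1_covariates(),
                                              marker = ".hap",
                                              encoding = "continuous_score"),
                          dat)
      stat <- (fit$beta[".hap"] / fit$se[".hap"])^2
      or_ <- fit$or_[".hap"]
      p <- fit$p[".hap"]
    } else {
      ybar <- mean(yy)
      u <- sum(dd * (yy - ybar))
      v <- ybar * (1 - ybar) * sum((dd - mean(dd))^2)
      stat <- if (v == 0) 0 else u^2 / v
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
      X <- cbind(`(Intercept)` = 1, hap = dd)
      or_ <- exp(irls_logistic(X, yy)$beta["hap"])
    }
    rows[[length(rows) + 1]] <- data.frame(
      haplotype = block$haplotypes$label[h],
      frequency = block$haplotypes$freq[h],
      or = unname(or_), stat = unname(stat), p = unname(p),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write haplotype block and association tables
#'
#' @param block a `haplotype_block`.
#' @param assoc optional [haplotype_association()] result.
#' @param prefix output path prefix.
#' @return the TSV path, invisibly.
#' @export
write_haplotype_report <- function(block, assoc = NULL, prefix) {
  hd <- block$haplotypes[order(-block$haplotypes$freq), ]
  hd$coverage_complete <- block$coverage_complete
  hd$coverage_phased <- block$coverage_phased
  utils::write.table(hd, paste0(prefix, "_haplotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(assoc))
    utils::write.table(assoc, paste0(prefix, "_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paste0(prefix, "_haplotypes.tsv"))
}
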