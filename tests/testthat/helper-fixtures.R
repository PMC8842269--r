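# shared fixture builders: everything is generated in code at test time

# tiny genotype matrix from dosage vectors (one column per variant)
gm_from_dosages <- function(..., alleles = list()) {
  dos <- list(...)
  vids <- names(dos)
  n <- length(dos[[1]])
  calls <- matrix(NA_character_, n, length(vids),
                  dimnames = list(paste0("S", seq_len(n)), vids))
  defs <- lapply(vids, function(v) {
    al <- alleles[[v]] %||% c("A", "G")
    data.frame(variant_id = v, major_allele = al[1], minor_allele = al[2],
               stringsAsFactors = FALSE)
  })
  defs <- do.call(rbind, defs)
  for (j in seq_along(vids)) {
    al <- alleles[[vids[j]]] %||% c("A", "G")
    g <- dos[[j]]
    calls[, j] <- ifelse(is.na(g), NA,
                         c(paste(al[1], al[1], sep = "/"),
                           paste(sort(al), collapse = "/"),
                           paste(al[2], al[2], sep = "/"))[g + 1])
  }
  genotype_matrix(calls, defs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force oracle for the exact HWE test: direct multinomial
# probabilities of every heterozygote count compatible with the observed
# minor-allele count
hwe_exact_oracle <- function(counts) {
  n <- sum(counts)
  nm <- min(counts[2] + 2 * counts[3], 2 * n - counts[2] - 2 * counts[3])
  hets <- seq(nm %% 2, nm, by = 2)
  pr <- vapply(hets, function(h) {
    naa <- (nm - h) / 2
    nAA <- n - h - naa
    exp(lfactorial(n) - lfactorial(h) - lfactorial(naa) - lfactorial(nAA) +
          h * log(2) + lfactorial(nm) + lfactorial(2 * n - nm) -
          lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)  # guard rounding
  p_obs <- pr[match(counts[2], hets)]
  sum(pr[pr <= p_obs + 1e-12])
}

# brute-force AUC: count concordant pairs, ties as 1/2
auc_pairs_oracle <- function(scores, outcomes) {
  cases <- scores[outcomes == 1]
  controls <- scores[outcomes == 0]
  tot <- 0
  for (x in cases) for (y in controls)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cases) * length(controls))
}

# exhaustive two-locus haplotype likelihood oracle: allele margins of the
# MLE equal the observed allele frequencies, so the likelihood is maximized
# over the single free haplotype frequency p11 on a fine grid
em_grid_oracle <- function(dosage1, dosage2, step = 1e-5) {
  p1 <- mean(dosage1) / 2
  p2 <- mean(dosage2) / 2
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(p11) {
    f <- c(`11` = p11, `10` = p1 - p11, `01` = p2 - p11,
           `00` = 1 - p1 - p2 + p11)
    if (any(f < -1e-12)) return(-Inf)
    f <- pmax(f, 1e-300)
    sum(mapply(function(g1, g2) {
      # sum of f[h1]*f[h2] over ordered compatible phase assignments
      tot <- 0
      for (a1 in 0:1) for (b1 in 0:1) {
        a2 <- g1 - a1
        b2 <- g2 - b1
        if (a2 %in% 0:1 && b2 %in% 0:1) {
          h1 <- paste0(a1, b1)
          h2 <- paste0(a2, b2)
          tot <- tot + f[h1] * f[h2]
        }
      }
      log(tot)
    }, dosage1, dosage2))
  }, numeric(1))
  best <- grid[which.max(ll)]
  c(`11` = best, `10` = p1 - best, `01` = p2 - best,
    `00` = 1 - p1 - p2 + best)
}
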