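test_that("unambiguous phase collapses to a single haplotype", {
  gm <- gm_from_dosages(v1 = c(0, 0, 0), v2 = c(0, 0, 0))
  em <- em_haplotype_frequencies(gm, c("v1", "v2"), seed = 1)
  hap <- em$haplotypes
  expect_equal(hap$freq[hap$v1 == 0 & hap$v2 == 0], 1, tolerance = 1e-8)
  expect_true(em$converged)
  expect_equal(em$coverage_phased, 1)
})

test_that("EM equals the exhaustive likelihood grid on tiny fixtures", {
  fixtures <- list(
    list(v1 = c(1, 0, 2), v2 = c(1, 0, 2)),   # one double het
    list(v1 = c(1, 1, 0, 2), v2 = c(1, 0, 1, 2)),
    list(v1 = c(1, 1, 1, 0), v2 = c(1, 1, 0, 1)),
    list(v1 = c(2, 1, 1, 0, 0, 1), v2 = c(1, 1, 0, 0, 1, 1)))
  for (fx in fixtures) {
    gm <- gm_from_dosages(v1 = fx$v1, v2 = fx$v2)
    em <- em_haplotype_frequencies(gm, c("v1", "v2"), seed = 3)
    oracle <- em_grid_oracle(fx$v1, fx$v2)
    hap <- em$haplotypes
    got <- c(hap$freq[hap$v1 == 1 & hap$v2 == 1],
             hap$freq[hap$v1 == 1 & hap$v2 == 0],
             hap$freq[hap$v1 == 0 & hap$v2 == 1],
             hap$freq[hap$v1 == 0 & hap$v2 == 0])
    expect_equal(got, unname(oracle), tolerance = 1e-3)
  }
})

test_that("EM log-likelihood is monotone and frequencies sum to one", {
  set.seed(5)
  b <- block_spec("b", list(locus_spec("v1", 0.3, "A", "G"),
                            locus_spec("v2", 0.4, "A", "G"),
                            locus_spec("v3", 0.2, "A", "G")),
                  data.frame(v1 = c(0, 1, 0, 1), v2 = c(0, 1, 1, 0),
                             v3 = c(0, 1, 0, 0),
                             freq = c(0.5, 0.2, 0.2, 0.1)))
  gm <- generate_genotypes(list(b), 400, seed = 5)
  em <- em_haplotype_frequencies(gm, c("v1", "v2", "v3"), seed = 2)
  expect_true(all(diff(em$loglik) >= -1e-9))
  expect_equal(sum(em$haplotypes$freq), 1, tolerance = 1e-6)
})

test_that("pairwise LD statistics match direct arithmetic", {
  mk_block <- function(freqs) {
    # freqs in order (0,0), (1,0), (0,1), (1,1)
    structure(list(loci = c("v1", "v2"),
                   haplotypes = data.frame(
                     v1 = c(0, 1, 0, 1), v2 = c(0, 0, 1, 1),
                     label = c("aa", "Aa", "aB", "AB"), freq = freqs)),
              class = "haplotype_block")
  }
  # hand-computed: p_AB=0.4, p_A=0.5, p_B=0.6 -> D=0.1,
  # D_max=min(0.5*0.4, 0.5*0.6)=0.2 -> D'=0.5; r2=0.01/0.06
  ld <- ld_pairwise(mk_block(c(0.3, 0.1, 0.2, 0.4)))
  expect_equal(ld$D, 0.1, tolerance = 1e-12)
  expect_equal(ld$D_prime, 0.5, tolerance = 1e-12)
  expect_equal(ld$r2, 0.01 / (0.5 * 0.5 * 0.6 * 0.4), tolerance = 1e-12)

  # perfect LD: only AB and ab
  ld <- ld_pairwise(mk_block(c(0.5, 0, 0, 0.5)))
  expect_equal(ld$D_prime, 1)
  expect_equal(ld$r2, 1)

  # independence
  ld <- ld_pairwise(mk_block(c(0.42, 0.28, 0.18, 0.12)))
  expect_equal(ld$D, 0, tolerance = 1e-12)
  expect_equal(ld$r2, 0, tolerance = 1e-12)

  # D' = 1 whenever one haplotype class has zero frequency
  ld <- ld_pairwise(mk_block(c(0.5, 0.3, 0, 0.2)))
  expect_equal(ld$D_prime, 1, tolerance = 1e-12)

  # r2 is invariant to swapping allele labels at one locus
  ld1 <- ld_pairwise(mk_block(c(0.35, 0.15, 0.1, 0.4)))
  ld2 <- ld_pairwise(mk_block(c(0.15, 0.35, 0.4, 0.1)))
  expect_equal(ld1$r2, ld2$r2, tolerance = 1e-12)

  expect_error(ld_pairwise(mk_block(c(0.6, 0.4, 0, 0))), "monomorphic")
})

test_that("block detection follows the adjacent-D' rule", {
  set.seed(19)
  # two blocked pairs separated by an independent locus
  b1 <- block_spec("b1", list(locus_spec("v1", 0.3, "A", "G"),
                              locus_spec("v2", 0.3, "A", "G")),
                   data.frame(v1 = c(0, 1), v2 = c(0, 1),
                              freq = c(0.7, 0.3)))
  mid <- locus_spec("v3", 0.4, "A", "G")
  b2 <- block_spec("b2", list(locus_spec("v4", 0.2, "A", "G"),
                              locus_spec("v5", 0.2, "A", "G")),
                   data.frame(v4 = c(0, 1), v5 = c(0, 1),
                              freq = c(0.8, 0.2)))
  gm <- generate_genotypes(list(b1, mid, b2), 600, seed = 19)
  blocks <- find_blocks(gm, loci = c("v1", "v2", "v3", "v4", "v5"))
  expect_length(blocks, 2)
  expect_equal(blocks[[1]]$loci, c("v1", "v2"))
  expect_equal(blocks[[2]]$loci, c("v4", "v5"))

  # threshold 0 merges everything; independent loci yield no blocks
  all_in_one <- find_blocks(gm, loci = c("v1", "v2", "v3", "v4", "v5"),
                            dprime_threshold = 0)
  expect_length(all_in_one, 1)
  expect_length(all_in_one[[1]]$loci, 5)
  ind <- generate_genotypes(list(locus_spec("w1", 0.3, "A", "G"),
                                 locus_spec("w2", 0.3, "A", "G"),
                                 locus_spec("w3", 0.3, "A", "G")),
                            800, seed = 23)
  expect_length(find_blocks(ind, loci = c("w1", "w2", "w3")), 0)
})

test_that("the default profile yields the three serotonin-receptor blocks", {
  sc <- generate_cohort(n = 2000, seed = 29, missing_rate = 0)
  chr11 <- sc$genotypes$variants$variant_id[
    sc$genotypes$variants$chrom == "11"]
  blocks <- find_blocks(subset_genotypes(sc$genotypes, variants = chr11))
  expect_length(blocks, 3)
  pairs <- lapply(blocks, `[[`, "loci")
  expect_true(list(c("rs3758987", "rs45460698")) %in% pairs ||
                any(vapply(pairs, identical, logical(1),
                           c("rs3758987", "rs45460698"))))
  expect_true(any(vapply(pairs, identical, logical(1),
                         c("rs76124337", "rs3782025"))))
  expect_true(any(vapply(pairs, identical, logical(1),
                         c("rs10160548", "rs1176713"))))
})

test_that("haplotype association has a chi-square(1) null and matches counts when phase is unambiguous", {
  # null distribution: mean STAT over replicates near 1
  set.seed(37)
  stats <- vapply(1:100, function(i) {
    b <- block_spec("b", list(locus_spec("v1", 0.3, "A", "G"),
                              locus_spec("v2", 0.3, "A", "G")),
                    data.frame(v1 = c(0, 1), v2 = c(0, 1),
                               freq = c(0.7, 0.3)))
    gm <- generate_genotypes(list(b), 300, seed = 5000 + i)
    em <- em_haplotype_frequencies(gm, c("v1", "v2"), seed = 1)
    y <- rbinom(300, 1, 0.45)
    res <- haplotype_association(em, "y", data.frame(y = y))
    res$stat[res$haplotype == "GG"]
  }, numeric(1))
  expect_gt(mean(stats), 0.6)
  expect_lt(mean(stats), 1.5)

  # perfect-LD block: expected haplotype dosage equals the allele dosage,
  # so STAT must equal the score statistic computed directly from counts
  b <- block_spec("b", list(locus_spec("v1", 0.4, "A", "G"),
                            locus_spec("v2", 0.4, "A", "G")),
                  data.frame(v1 = c(0, 1), v2 = c(0, 1),
                             freq = c(0.6, 0.4)))
  gm <- generate_genotypes(list(b), 500, seed = 43)
  em <- em_haplotype_frequencies(gm, c("v1", "v2"), seed = 1)
  d <- genotype_dosage(gm, "v1")
  set.seed(44)
  y <- rbinom(500, 1, plogis(-0.5 + 0.4 * d))
  res <- haplotype_association(em, "y", data.frame(y = y))
  u <- sum(d * (y - mean(y)))
  v <- mean(y) * (1 - mean(y)) * sum((d - mean(d))^2)
  expect_equal(res$stat[res$haplotype == "GG"], u^2 / v,
               tolerance = 1e-6)

  # rare haplotypes are skipped
  expect_false(any(res$frequency < 0.01))
})

test_that("covariate-adjusted haplotype association runs on cohort data", {
  sc <- generate_cohort(n = 600, seed = 47, missing_rate = 0)
  em <- em_haplotype_frequencies(sc$genotypes,
                                 c("rs76124337", "rs3782025"), seed = 1)
  res <- haplotype_association(em, "ponv_occurrence", sc$cohort,
                               covariate_adjust = TRUE)
  expect_true(all(res$stat >= 0))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true("-G" %in% res$haplotype)
})
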