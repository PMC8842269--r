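tab <- load_allele_table()

cyp2c19_gm <- function(rs4244285 = 0, rs4986893 = 0, rs12248560 = 0) {
  gm_from_dosages(rs4244285 = rs4244285, rs4986893 = rs4986893,
                  rs12248560 = rs12248560,
                  alleles = list(rs4244285 = c("G", "A"),
                                 rs4986893 = c("G", "A"),
                                 rs12248560 = c("C", "T")))
}

test_that("single-variant diplotypes are assigned deterministically", {
  gm <- cyp2c19_gm(rs4244285 = 1)
  expect_equal(assign_diplotype(gm, "S1", "CYP2C19", tab), c("*1", "*2"))
  gm <- cyp2c19_gm()  # all reference
  expect_equal(assign_diplotype(gm, "S1", "CYP2C19", tab), c("*1", "*1"))
  gm <- cyp2c19_gm(rs4244285 = 2)
  expect_equal(assign_diplotype(gm, "S1", "CYP2C19", tab), c("*2", "*2"))
  gm <- cyp2c19_gm(rs4244285 = 1, rs12248560 = 1)
  expect_equal(assign_diplotype(gm, "S1", "CYP2C19", tab), c("*17", "*2"))
})

test_that("mutually exclusive homozygous definitions yield a no-call", {
  # homozygous for both *2 and *17 defining variants: no allele pair can
  # jointly explain dosage 2 at both sites (oracle = the exhaustive pair
  # enumeration the assigner performs, checked by hand: 10 pairs, none fit)
  gm <- cyp2c19_gm(rs4244285 = 2, rs12248560 = 2)
  d <- assign_diplotype(gm, "S1", "CYP2C19", tab)
  expect_true(all(is.na(d)))
  expect_true(attr(d, "no_call"))
})

test_that("all-missing defining variants fall back to the reference with a warning", {
  gm <- cyp2c19_gm()
  gm$calls[1, ] <- NA
  expect_warning(d <- assign_diplotype(gm, "S1", "CYP2C19", tab),
                 "defaulting")
  expect_equal(d, c("*1", "*1"))
})

test_that("additive gene scores match the published per-allele values", {
  expect_equal(score_additive_gene(c("*1", "*1"), "CYP2C19", tab), 2)
  expect_equal(score_additive_gene(c("*2", "*3"), "CYP2C19", tab), 0)
  expect_equal(score_additive_gene(c("*1", "*17"), "CYP2C19", tab), 3)
  expect_equal(score_additive_gene(c("*1F", "*1C"), "CYP1A2", tab), 2)
  expect_equal(score_additive_gene(c("*1A", "*1L"), "CYP1A2", tab), 2)
  expect_equal(score_additive_gene(c("*4", "*22"), "CYP2B6", tab), 4)
  expect_equal(score_additive_gene(c("*5", "*6"), "CYP2B6", tab), 0)
  expect_error(score_additive_gene(c("*1", "*99"), "CYP2C19", tab),
               "\\*99")
})

test_that("additive scores equal brute-force lookup over the full allele cross-product", {
  for (gene in c("CYP1A2", "CYP2B6", "CYP2C19")) {
    alleles <- names(tab[[gene]])
    for (a in alleles) for (b in alleles) {
      expected <- tab[[gene]][[a]]$score + tab[[gene]][[b]]$score
      expect_equal(score_additive_gene(c(a, b), gene, tab), expected,
                   info = paste(gene, a, b))
      # permutation invariance
      expect_equal(score_additive_gene(c(b, a), gene, tab), expected)
    }
  }
})

test_that("replacing an allele with a lower-scored one never raises the score", {
  gene <- "CYP2C19"
  alleles <- names(tab[[gene]])
  scores <- vapply(alleles, function(a) tab[[gene]][[a]]$score, numeric(1))
  for (a in alleles) for (b in alleles) for (b2 in alleles) {
    if (scores[b2] <= scores[b])
      expect_lte(score_additive_gene(c(a, b2), gene, tab),
                 score_additive_gene(c(a, b), gene, tab))
  }
})

test_that("CYP2D6 scoring is copy-number aware", {
  expect_equal(score_cyp2d6(c("*1", "*1"), 2, tab), 2)
  expect_equal(score_cyp2d6(c("*4", "*4"), 2, tab), 0)   # poor metabolizer
  expect_equal(score_cyp2d6(c("*1", "*41"), 2, tab), 1.5)
  # duplication assigned to the higher-activity allele: oracle enumerates
  # both assignments (dup *1 -> 2 + 0 + 1 = 3? no: *1 doubled = 2, *4 = 0)
  # and the rule takes the higher branch
  both <- c(sum(c(1, 1, 0)), sum(c(1, 0, 0)))  # dup *1 vs dup *4
  expect_equal(score_cyp2d6(c("*1", "*4"), 3, tab), max(both))
  expect_equal(score_cyp2d6(c("*1", "*4"), 3, tab), 2)
  # hemizygous drops the lower-activity allele
  expect_equal(score_cyp2d6(c("*1", "*1"), 1, tab), 1)
  # copy number 0 with functional alleles is flagged
  s <- score_cyp2d6(c("*1", "*1"), 0, tab)
  expect_equal(as.numeric(s), 0)
  expect_match(attr(s, "flag"), "copy number 0")
})

test_that("CYP3A grouping applies the CYP3A7*1C category increment with an EM cap", {
  # base PM (non-expressor + *22 carrier) promoted to IM by *1C
  r <- score_cyp3a(c("*1", "*22"), c("*3", "*3"), c("*1", "*1C"))
  expect_equal(r$group, "IM")
  expect_equal(r$score, 1)
  # base EM stays EM (cap)
  r <- score_cyp3a(c("*1", "*1"), c("*1", "*3"), c("*1", "*1C"))
  expect_equal(r$group, "EM")
  expect_equal(r$score, 2)
  # base IM without *1C stays IM
  r <- score_cyp3a(c("*1", "*1"), c("*3", "*3"))
  expect_equal(r$group, "IM")
  expect_equal(r$score, 1)
  # no-call propagation
  r <- score_cyp3a(c(NA, NA), c("*3", "*3"))
  expect_true(is.na(r$score))
})

test_that("CYP2C9 activity is the reduced-allele count", {
  expect_equal(score_cyp2c9(c("*1", "*1")), 0)
  expect_equal(score_cyp2c9(c("*2", "*3")), 2)
  expect_equal(score_cyp2c9(c("*1", "*3")), 1)
})

test_that("the CYP1A2 smoking adjustment multiplies by 1.5 exactly once", {
  expect_equal(as.numeric(adjust_cyp1a2_smoking(4, TRUE)), 6)
  expect_equal(as.numeric(adjust_cyp1a2_smoking(2, FALSE)), 2)
  expect_equal(as.numeric(adjust_cyp1a2_smoking(0, TRUE)), 0)
  s <- adjust_cyp1a2_smoking(2, TRUE)
  expect_error(adjust_cyp1a2_smoking(s, TRUE), "already applied")
})

test_that("per-sample activity profiles cover all genes", {
  gm <- gm_from_dosages(
    rs4244285 = c(0, 1), rs762551 = c(2, 0), rs2069514 = c(0, 0),
    rs776746 = c(2, 2), rs35599367 = c(0, 1), rs45446698 = c(0, 0),
    alleles = list(rs4244285 = c("G", "A"), rs762551 = c("C", "A"),
                   rs2069514 = c("G", "A"), rs776746 = c("A", "G"),
                   rs35599367 = c("C", "T"), rs45446698 = c("T", "G")))
  prof <- suppressWarnings(
    cyp_activity_profiles(gm, tab, smoker = c(TRUE, FALSE)))
  p1 <- prof[prof$sample_id == "S1", ]
  # CYP1A2 *1F/*1F = 4, smoker -> 6
  expect_equal(p1$activity_score[p1$gene == "CYP1A2"], 6)
  expect_true(all(p1$smoking_adjusted[p1$gene == "CYP1A2"]))
  p2 <- prof[prof$sample_id == "S2", ]
  expect_equal(p2$activity_score[p2$gene == "CYP1A2"], 2)
  expect_equal(p2$activity_score[p2$gene == "CYP2C19"], 1)  # *1/*2
  # CYP3A: S1 non-expressor (*3/*3), CYP3A4 *1/*1 -> IM
  expect_equal(p1$activity_group[p1$gene == "CYP3A"], "IM")
  # S2 non-expressor + *22 carrier -> PM
  expect_equal(p2$activity_group[p2$gene == "CYP3A"], "PM")
})
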