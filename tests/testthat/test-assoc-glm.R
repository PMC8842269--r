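test_that("dichotomization applies the risk coding and its boundaries", {
  raw <- data.frame(
    sex = c("female", "male", "female"),
    age_years = c(49, 50, 62),
    smoking = c("yes", "no", "no"),
    cannabis = c("no", "no", "yes"),
    ponv_history = c("no", "yes", "no"),
    surgery_type = c("orthopedic", "visceral", "gynecologic"),
    volatile = c("yes", "no", "yes"),
    opioid_mg = c(25, 19, 18.9))
  d <- dichotomize(raw)
  expect_equal(d$Gender, c(1L, 0L, 1L))
  expect_equal(d$Age, c(1L, 0L, 0L))         # exactly 50 codes 0
  expect_equal(d$Smoking, c(0L, 1L, 1L))     # smoker codes 0
  expect_equal(d$Cannabis, c(1L, 1L, 0L))
  expect_equal(d$PONVhistory, c(0L, 1L, 0L))
  expect_equal(d$SurgeryType, c(0L, 1L, 1L))
  expect_equal(d$VolatileAnesthetics, c(1L, 0L, 1L))
  expect_equal(d$HighOpioid, c(1L, 0L, 0L))  # exactly 19 mg codes 0
  expect_true(all(d$complete_case))

  raw$age_years[2] <- NA
  d <- dichotomize(raw)
  expect_true(is.na(d$Age[2]))
  expect_false(d$complete_case[2])
  expect_error(dichotomize(raw[, -1]), "sex")
})

test_that("genetic encodings map dosages as defined", {
  d <- c(0, 1, 2, NA)
  expect_equal(encode_genotype(d, "additive"), c(0, 1, 2, NA))
  expect_equal(encode_genotype(d, "dominant"), c(0, 1, 1, NA))
  expect_equal(encode_genotype(d, "recessive"), c(0, 0, 1, NA))
})

test_that("IRLS matches the closed-form 2x2 logistic solution to 1e-6", {
  for (cell in list(c(40, 25, 30, 55), c(10, 5, 7, 20),
                    c(120, 80, 60, 140))) {
    a <- cell[1]; b <- cell[2]; c_ <- cell[3]; d <- cell[4]
    x <- rep(c(1, 1, 0, 0), times = c(a, b, c_, d))
    y <- rep(c(1, 0, 1, 0), times = c(a, b, c_, d))
    fit <- fit_logistic(logistic_model_spec("y", covariates = "x"),
                        data.frame(y = y, x = x))
    expect_equal(unname(fit$or_["x"]), (a * d) / (b * c_),
                 tolerance = 1e-6)
    expect_equal(unname(fit$se["x"]),
                 sqrt(1 / a + 1 / b + 1 / c_ + 1 / d), tolerance = 1e-6)
    expect_true(fit$converged)
  }
})

test_that("the IRLS log-likelihood is non-decreasing", {
  set.seed(31)
  n <- 400
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 0.9 * x1 - 0.5 * x2))
  fit <- fit_logistic(logistic_model_spec("y", covariates = c("x1", "x2")),
                      data.frame(y = y, x1 = x1, x2 = x2))
  expect_true(all(diff(fit$loglik) >= -1e-8))
  expect_true(all(fit$ci95[, 1] <= fit$or_ & fit$or_ <= fit$ci95[, 2]))
})

test_that("a null model estimates near-zero effects", {
  set.seed(17)
  n <- 1e4
  d <- data.frame(y = rbinom(n, 1, 0.5), x1 = rbinom(n, 1, 0.5),
                  x2 = rbinom(n, 1, 0.3))
  fit <- fit_logistic(logistic_model_spec("y", covariates = c("x1", "x2")),
                      d)
  expect_true(all(abs(fit$beta[-1]) < 0.1))
})

test_that("separation is flagged instead of silently reported", {
  d <- data.frame(y = c(rep(0, 20), rep(1, 20)),
                  x = c(rep(0, 20), rep(1, 20)))
  fit <- fit_logistic(logistic_model_spec("y", covariates = "x"), d)
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("rank-deficient designs name the aliased column", {
  d <- data.frame(y = rbinom(50, 1, 0.5), x1 = rbinom(50, 1, 0.5))
  d$x2 <- d$x1
  expect_error(
    fit_logistic(logistic_model_spec("y", covariates = c("x1", "x2")), d),
    "x2")
})

test_that("additive fits are symmetric under allele-label swap", {
  set.seed(23)
  n <- 800
  g <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.35 * g))
  f1 <- fit_logistic(logistic_model_spec("y", covariates = "g"),
                     data.frame(y = y, g = g))
  f2 <- fit_logistic(logistic_model_spec("y", covariates = "g"),
                     data.frame(y = y, g = 2 - g))
  expect_equal(unname(f1$beta["g"]), -unname(f2$beta["g"]),
               tolerance = 1e-8)
})

test_that("marker association recovers the generating model ordering", {
  # recessive truth: the recessive encoding attains the highest likelihood
  set.seed(41)
  n <- 6000
  g <- rbinom(n, 2, 0.45)
  y <- rbinom(n, 1, plogis(-0.6 + 1.2 * (g == 2)))
  ll <- vapply(c("additive", "dominant", "recessive"), function(enc) {
    x <- encode_genotype(g, enc)
    fit <- fit_logistic(logistic_model_spec("y", covariates = "x"),
                        data.frame(y = y, x = x))
    max(fit$loglik)
  }, numeric(1))
  expect_equal(names(which.max(ll)), "recessive")
})

test_that("associate_marker rejects monomorphic markers and restricts recurrence", {
  sc <- generate_cohort(n = 400, seed = 51, missing_rate = 0)
  gm <- sc$genotypes
  gm$calls[, "rs1799971"] <- "A/A"
  expect_error(associate_marker("rs1799971", "occurrence", sc$cohort, gm),
               "monomorphic")
  res <- associate_marker("rs3782025", "recurrence", sc$cohort,
                          sc$genotypes)
  expect_equal(res$n, sum(sc$cohort$followed_flag == 1 &
                            !is.na(sc$cohort$ponv_recurrence)))
})

test_that("activity association is invariant to score translation", {
  sc <- generate_cohort(n = 500, seed = 61, missing_rate = 0)
  score <- rbinom(500, 4, 0.4)
  r1 <- associate_activity(score, "occurrence", sc$cohort, "toy")
  r2 <- associate_activity(score + 1, "occurrence", sc$cohort, "toy")
  expect_equal(r1$beta, r2$beta, tolerance = 1e-7)
  # constant activity is aliased with the intercept
  expect_error(associate_activity(rep(2, 500), "occurrence", sc$cohort),
               "aliased|rank")
})

test_that("Bonferroni thresholds and flags follow alpha/m", {
  b <- bonferroni(c(0.005, 0.001, 0.05), m = 27)
  expect_equal(b$threshold, 0.05 / 27)
  expect_equal(round(b$threshold, 3), 0.002)
  expect_equal(b$significant, c(FALSE, TRUE, FALSE))
  expect_equal(bonferroni(0.04, m = 1)$threshold, 0.05)
})

test_that("VIF is 1 for orthogonal designs and Inf for duplicated columns", {
  d <- data.frame(a = rep(c(0, 1), each = 4), b = rep(c(0, 1), 4))
  expect_equal(unname(vif(d, c("a", "b"))), c(1, 1))
  d$c <- d$a
  expect_true(is.infinite(vif(d, c("a", "b", "c"))[["c"]]))
})

test_that("default-coupling cohorts keep all VIFs below 1.2", {
  sc <- generate_cohort(n = 5000, seed = 71)
  v <- vif(sc$cohort, eq1_covariates())
  expect_true(all(v < 1.2))
  expect_true(all(v >= 1))
})

test_that("confounding scan flags a planted collinear marker", {
  set.seed(81)
  sc <- generate_cohort(n = 800, seed = 81, missing_rate = 0)
  gm <- sc$genotypes
  # plant a marker tracking Gender (with slight noise to avoid aliasing)
  g <- sc$cohort$Gender
  flip <- sample(800, 40)
  g[flip] <- 1 - g[flip]
  gm$calls[, "rs324420"] <- ifelse(g == 1, "A/C", "C/C")
  scan <- confounding_scan(sc$cohort, gm, "rs324420")
  gender_row <- scan[scan$covariate == "Gender", ]
  expect_true(abs(gender_row$rel_change) > 0.10)
  expect_true(gender_row$flagged)

  # an independent marker barely moves the covariate estimates, and the
  # flag threshold is a strict inequality around the measured change
  scan2 <- confounding_scan(sc$cohort, gm, "rs1128503")
  expect_true(all(abs(scan2$rel_change) < 0.10))
  expect_false(any(scan2$flagged))
  r <- abs(scan2$rel_change[1])
  above <- confounding_scan(sc$cohort, gm, "rs1128503",
                            threshold = r + 1e-6)
  below <- confounding_scan(sc$cohort, gm, "rs1128503",
                            threshold = r - 1e-6)
  expect_false(above$flagged[1])
  expect_true(below$flagged[1])
})
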