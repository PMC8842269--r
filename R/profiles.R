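#' Canonical covariate set of the association model
#'
#' The eight dichotomized risk covariates adjusted for in every genetic
#' association fit: female sex, age below 50, non-smoking, no cannabis use,
#' previous PONV history, visceral/gynecological surgery, volatile
#' anesthetics, and above-median opioid consumption.
#'
#' @return character vector of column names.
#' @export
eq1_covariates <- function() {
  c("Gender", "Age", "Smoking", "Cannabis", "PONVhistory",
    "SurgeryType", "VolatileAnesthetics", "HighOpioid")
}

## odds ratio of a 2x2 table specified by P(B=1|A=1), P(A=1), P(B=1)
or_from_conditional <- function(p_b_given_a, p_a, p_b) {
  p11 <- p_a * p_b_given_a
  p10 <- p_a - p11
  p01 <- p_b - p11
  p00 <- 1 - p11 - p10 - p01
  (p11 * p00) / (p10 * p01)
}

default_snp_table <- function() {
  tab <- rbind(
    c("rs4680",     "COMT",  "22", 19963748, "G",   "A", 0.47),
    c("rs4633",     "COMT",  "22", 19962712, "C",   "T", 0.47),
    c("rs165722",   "COMT",  "22", 19962905, "C",   "T", 0.48),
    c("rs6269",     "COMT",  "22", 19962429, "A",   "G", 0.43),
    c("rs4818",     "COMT",  "22", 19963684, "C",   "G", 0.41),
    c("rs2165870",  "CHRM3",  "1", 239752183, "G",  "A", 0.34),
    c("rs10802789", "CHRM3",  "1", 239801234, "C",  "T", 0.43),
    c("rs685550",   "CHRM3",  "1", 239850456, "A",  "G", 0.26),
    c("rs6295",     "HTR1A",  "5", 63962738, "C",   "G", 0.49),
    c("rs6313",     "HTR2A", "13", 46897343, "G",   "A", 0.45),
    c("rs1800497",  "DRD2",  "11", 113400106, "G",  "A", 0.18),
    c("rs3758987",  "HTR3B", "11", 113915201, "T",  "C", 0.26),
    c("rs45460698", "HTR3B", "11", 113916301, "AAG", "-", 0.14),
    c("rs1176744",  "HTR3B", "11", 113920201, "A",  "C", 0.30),
    c("rs76124337", "HTR3B", "11", 113925101, "CA", "-", 0.33),
    c("rs3782025",  "HTR3B", "11", 113926201, "A",  "G", 0.44),
    c("rs1672717",  "HTR3B", "11", 113931401, "A",  "G", 0.35),
    c("rs1985242",  "HTR3A", "11", 113975101, "T",  "A", 0.34),
    c("rs10160548", "HTR3A", "11", 113980201, "T",  "G", 0.39),
    c("rs1176713",  "HTR3A", "11", 113985301, "A",  "G", 0.25),
    c("rs6443930",  "HTR3D",  "3", 184043210, "G",  "C", 0.49),
    c("rs1799971",  "OPRM1",  "6", 154039662, "A",  "G", 0.15),
    c("rs3755468",  "TACR1",  "2", 75046789, "C",   "T", 0.44),
    c("rs324420",   "FAAH",   "1", 46405089, "C",   "A", 0.20),
    c("rs1128503",  "ABCB1",  "7", 87550285, "G",   "A", 0.40),
    c("rs1045642",  "ABCB1",  "7", 87509329, "G",   "A", 0.47),
    c("rs2032582",  "ABCB1",  "7", 87531302, "C",   "A", 0.38))
  tab <- data.frame(variant_id = tab[, 1], gene = tab[, 2], chrom = tab[, 3],
                    position = as.numeric(tab[, 4]), major_allele = tab[, 5],
                    minor_allele = tab[, 6], maf = as.numeric(tab[, 7]),
                    stringsAsFactors = FALSE)
  tab$extra_allele <- ifelse(tab$variant_id == "rs2032582", "T", NA)
  tab$extra_freq <- ifelse(tab$variant_id == "rs2032582", 0.016, 0)
  tab
}

#' Default calibration profile of the synthetic cohort generator
#'
#' The shipped profile emulates the statistical structure of a 601-patient
#' surgical cohort genotyped for PONV susceptibility:
#'
#' * covariate prevalences: female 0.526, age < 50 0.577, non-smoking
#'   0.681, no cannabis 0.937, PONV history 0.238, visceral/gynecological
#'   surgery 0.408, volatile anesthetics 0.875, high opioid 0.484, with two
#'   couplings (PONV history with female sex; non-smoking with younger
#'   age) matching the observed covariate overlap;
#' * a 27-SNP panel at the cohort minor-allele frequencies, with three
#'   two-locus LD blocks in the *HTR3B*/*HTR3A* region simulated from
#'   their haplotype frequencies (including the risk haplotype `-G` of
#'   rs76124337/rs3782025 at frequency 0.33) and the triallelic ABCB1
#'   rs2032582 as nested biallelic draws;
#' * a logistic occurrence model with the reported covariate odds ratios
#'   (female 4.11, age 1.52, non-smoking 1.35, cannabis 1.08, history 2.38,
#'   surgery 0.72, volatile 2.88, high opioid 0.85), a per-allele odds
#'   ratio of 1.40 for rs3782025, and the intercept solved numerically so
#'   the implied PONV prevalence equals `target_prevalence`;
#' * a recurrence model among followed cases with the reported recurrence
#'   odds ratios and an intercept solved so the implied recurrence rate
#'   equals `target_recurrence`.
#'
#' @param target_prevalence implied PONV occurrence prevalence (default
#'   0.439).
#' @param target_recurrence implied recurrence rate among followed cases
#'   (default 0.686).
#' @return a `cohort_profile` object with elements `covariates`, `loci`,
#'   and `model`.
#' @export
default_profile <- function(target_prevalence = 0.439,
                            target_recurrence = 0.686) {
  or_hist_fem <- or_from_conditional(0.71, 0.238, 0.526)
  or_smoke_young <- or_from_conditional(0.67, 1 - 0.681, 0.577)
  covariates <- list(
    covariate_spec("Gender", 0.526),
    covariate_spec("Age", 0.577),
    ## non-smoking is the risk-coded level, so the smoker/young coupling
    ## enters inverted
    covariate_spec("Smoking", 0.681, couple_to = "Age",
                   couple_or = 1 / or_smoke_young),
    covariate_spec("Cannabis", 0.937),
    covariate_spec("PONVhistory", 0.238, couple_to = "Gender",
                   couple_or = or_hist_fem),
    covariate_spec("SurgeryType", 0.408),
    covariate_spec("VolatileAnesthetics", 0.875),
    covariate_spec("HighOpioid", 0.484))

  tab <- default_snp_table()
  tab <- tab[order(tab$chrom, tab$position), ]
  mk_locus <- function(v) {
    r <- tab[tab$variant_id == v, ]
    locus_spec(r$variant_id, r$maf, r$major_allele, r$minor_allele,
               chrom = r$chrom, position = r$position,
               extra_allele = if (!is.na(r$extra_allele)) r$extra_allele,
               extra_freq = r$extra_freq)
  }
  blocked <- list(
    b1 = c("rs3758987", "rs45460698"),
    b2 = c("rs76124337", "rs3782025"),
    b3 = c("rs10160548", "rs1176713"))
  hap_tabs <- list(
    b1 = data.frame(rs3758987 = c(0, 1, 0), rs45460698 = c(0, 0, 1),
                    freq = c(0.60, 0.26, 0.14)),
    b2 = data.frame(rs76124337 = c(0, 0, 1), rs3782025 = c(0, 1, 1),
                    freq = c(0.56, 0.11, 0.33)),
    b3 = data.frame(rs10160548 = c(0, 1, 1), rs1176713 = c(0, 0, 1),
                    freq = c(0.61, 0.14, 0.25)))
  loci <- list()
  done <- character(0)
  for (v in tab$variant_id) {
    if (v %in% done) next
    in_block <- vapply(blocked, function(b) v %in% b, logical(1))
    if (any(in_block)) {
      bid <- names(blocked)[in_block][1]
      loci[[length(loci) + 1]] <-
        block_spec(bid, lapply(blocked[[bid]], mk_locus), hap_tabs[[bid]])
      done <- c(done, blocked[[bid]])
    } else {
      loci[[length(loci) + 1]] <- mk_locus(v)
      done <- c(done, v)
    }
  }

  occ_or <- c(Gender = 4.11, Age = 1.52, Smoking = 1.35, Cannabis = 1.08,
              PONVhistory = 2.38, SurgeryType = 0.72,
              VolatileAnesthetics = 2.88, HighOpioid = 0.85)
  rec_or <- c(Gender = 0.92, Age = 1.35, Smoking = 1.56, Cannabis = 1.27,
              PONVhistory = 1.86, SurgeryType = 0.70,
              VolatileAnesthetics = 0.92, HighOpioid = 0.35)
  marker_or <- c(rs3782025 = 1.40)
  rec_marker_or <- c(rs3782025 = 0.66)

  model <- outcome_model_spec(
    intercept = 0, covariate_betas = log(occ_or),
    marker_betas = log(marker_or),
    recurrence = list(intercept = 0, covariate_betas = log(rec_or),
                      marker_betas = log(rec_marker_or)),
    followed_prob = 0.867)
  profile <- structure(list(covariates = covariates, loci = loci,
                            model = model),
                       class = "cohort_profile")
  profile$model$intercept <-
    calibrate_intercept(profile, target_prevalence, which = "occurrence")
  profile$model$recurrence$intercept <-
    calibrate_intercept(profile, target_recurrence, which = "recurrence")
  profile
}

#' @export
print.cohort_profile <- function(x, ...) {
  nloc <- nrow(loci_to_variant_defs(x$loci))
  cat("cohort_profile:", length(x$covariates), "covariates,", nloc,
      "loci (", sum(vapply(x$loci, inherits, logical(1), "block_spec")),
      "LD blocks )\n")
  cat(sprintf("  implied PONV prevalence %.3f; implied recurrence %.3f\n",
              implied_prevalence(x), implied_prevalence(x, "recurrence")))
  invisible(x)
}

## exact enumeration of the covariate joint distribution: the sequential-
## conditional scheme couples each covariate to at most one earlier one, so
## the joint factorizes into a product of conditionals over 2^k cells
covariate_cells <- function(specs) {
  nm <- vapply(specs, `[[`, character(1), "name")
  grid <- as.matrix(expand.grid(rep(list(0:1), length(specs)),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- nm
  prob <- rep(1, nrow(grid))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    if (is.null(sp$couple_to)) {
      p1 <- rep(sp$prevalence, nrow(grid))
    } else {
      p_par <- specs[[match(sp$couple_to, nm)]]$prevalence
      p11 <- solve_2x2_or(p_par, sp$prevalence, sp$couple_or)
      p1 <- ifelse(grid[, sp$couple_to] == 1, p11 / p_par,
                   (sp$prevalence - p11) / (1 - p_par))
    }
    prob <- prob * ifelse(grid[, j] == 1, p1, 1 - p1)
  }
  list(grid = grid, prob = prob)
}

marker_maf <- function(loci, variant_id) {
  for (l in loci) {
    if (inherits(l, "block_spec")) {
      for (s in l$loci) if (s$variant_id == variant_id) return(s$maf)
    } else if (l$variant_id == variant_id) return(l$maf)
  }
  stop("marker ", variant_id, " not among the profile loci")
}

#' Implied outcome prevalence of a cohort profile
#'
#' Computes, by exact enumeration over the covariate cells and marker
#' genotype classes (HWE at the locus MAF), the population prevalence the
#' outcome model implies: for `"occurrence"` the marginal probability of
#' PONV, for `"recurrence"` the conditional probability of a second episode
#' given occurrence.
#'
#' @param profile a `cohort_profile`.
#' @param which `"occurrence"` or `"recurrence"`.
#' @param intercept optional intercept overriding the profile's (used by
#'   the calibration solver).
#' @return the implied prevalence.
#' @export
implied_prevalence <- function(profile, which = c("occurrence", "recurrence"),
                               intercept = NULL) {
  which <- match.arg(which)
  cells <- covariate_cells(profile$covariates)
  model <- profile$model
  markers <- union(names(model$marker_betas),
                   names(model$recurrence$marker_betas %||% numeric(0)))
  ## expand cells over the genotype classes of each modelled marker
  gprob <- list(numeric(0))
  if (length(markers)) {
    gg <- expand.grid(rep(list(0:2), length(markers)),
                      KEEP.OUT.ATTRS = FALSE)
    colnames(gg) <- markers
    gp <- rep(1, nrow(gg))
    for (m in markers) {
      q <- marker_maf(profile$loci, m)
      hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
      gp <- gp * hwe[gg[[m]] + 1]
    }
  } else {
    gg <- data.frame(row.names = 1)
    gp <- 1
  }
  eta_occ <- as.vector(cells$grid[, names(model$covariate_betas),
                                  drop = FALSE] %*% model$covariate_betas)
  g_occ <- if (length(model$marker_betas))
    as.vector(as.matrix(gg[, names(model$marker_betas), drop = FALSE]) %*%
                model$marker_betas) else rep(0, nrow(gg))
  b0_occ <- if (which == "occurrence" && !is.null(intercept)) intercept else
    model$intercept
  p_occ <- outer(eta_occ, g_occ, function(a, b) inv_logit(b0_occ + a + b))
  w <- outer(cells$prob, gp)
  if (which == "occurrence") return(sum(w * p_occ))
  rec <- model$recurrence
  if (is.null(rec)) stop("profile has no recurrence model")
  eta_rec <- as.vector(cells$grid[, names(rec$covariate_betas),
                                  drop = FALSE] %*% rec$covariate_betas)
  g_rec <- if (length(rec$marker_betas))
    as.vector(as.matrix(gg[, names(rec$marker_betas), drop = FALSE]) %*%
                rec$marker_betas) else rep(0, nrow(gg))
  b0_rec <- intercept %||% rec$intercept
  p_rec <- outer(eta_rec, g_rec, function(a, b) inv_logit(b0_rec + a + b))
  sum(w * p_occ * p_rec) / sum(w * p_occ)
}

## solve the intercept so the implied prevalence hits the target
calibrate_intercept <- function(profile, target, which = "occurrence") {
  stats::uniroot(function(b0)
    implied_prevalence(profile, which, intercept = b0) - target,
    c(-20, 20), tol = 1e-10)$root
}

#' Inject missing calls into a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param rate per-call missingness probability.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return the matrix with calls masked at the given rate.
#' @export
inject_missingness <- function(gm, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (rate > 0) {
    mask <- matrix(stats::runif(length(gm$calls)) < rate, nrow(gm$calls))
    gm$calls[mask] <- NA_character_
  }
  gm
}

#' Generate a complete synthetic PONV cohort
#'
#' Draws covariates, genotypes, and outcomes under a calibration profile,
#' synthesizes the corresponding raw clinical columns (age in years, sex,
#' smoking status, surgery type, opioid morphine equivalents, ...) so that
#' [dichotomize()] reproduces the generating risk flags, adds a
#' postoperative-opioid flag (used by the Apfel score) and a tramadol flag,
#' and finally injects genotype missingness to exercise the QC gate.
#' Outcomes are always drawn from the complete (pre-missingness) genotypes.
#'
#' @param profile a `cohort_profile` (default [default_profile()]).
#' @param n cohort size.
#' @param seed RNG seed for the whole generation.
#' @param missing_rate per-call genotype missingness (default 0.006,
#'   matching >99% call rates).
#' @param postop_opioid_prev prevalence of postoperative opioid use.
#' @param tramadol_prev prevalence of tramadol analgesia.
#' @return a `synthetic_cohort`: list with `cohort` (data.frame),
#'   `genotypes` (a [genotype_matrix()]), and `truth` (profile and seed).
#' @export
generate_cohort <- function(profile = default_profile(), n, seed = 1,
                            missing_rate = 0.006, postop_opioid_prev = 0.70,
                            tramadol_prev = 0.083) {
  set.seed(seed)
  cov <- generate_covariates(profile$covariates, n)
  gm <- generate_genotypes(profile$loci, n)
  cohort <- generate_outcomes(cov, gm, profile$model)
  cohort <- cbind(sample_id = gm$samples, cohort,
                  stringsAsFactors = FALSE)
  ## raw clinical columns consistent with the dichotomized flags
  cohort$sex <- ifelse(cohort$Gender == 1, "female", "male")
  cohort$age_years <- ifelse(cohort$Age == 1,
                             sample(18:49, n, replace = TRUE),
                             sample(50:90, n, replace = TRUE))
  cohort$smoking <- ifelse(cohort$Smoking == 1, "no", "yes")
  cohort$cannabis <- ifelse(cohort$Cannabis == 1, "no", "yes")
  cohort$ponv_history <- ifelse(cohort$PONVhistory == 1, "yes", "no")
  cohort$surgery_type <- ifelse(
    cohort$SurgeryType == 1,
    sample(c("visceral", "gynecologic"), n, replace = TRUE),
    sample(c("orthopedic", "ENT", "neurologic", "plastic"), n,
           replace = TRUE))
  cohort$volatile <- ifelse(cohort$VolatileAnesthetics == 1, "yes", "no")
  cohort$opioid_mg <- round(ifelse(cohort$HighOpioid == 1,
                                   19.1 + stats::rexp(n, 1 / 27),
                                   stats::runif(n, 0, 19)), 1)
  cohort$postop_opioid <- stats::rbinom(n, 1, postop_opioid_prev)
  cohort$tramadol_flag <- stats::rbinom(n, 1, tramadol_prev)
  gm <- inject_missingness(gm, missing_rate)
  structure(list(cohort = cohort, genotypes = gm,
                 truth = list(profile = profile, seed = seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$cohort), "patients;",
      sprintf("PONV prevalence %.1f%%\n",
              100 * mean(x$cohort$ponv_occurrence)))
  print(x$genotypes)
  invisible(x)
}

#' Write a cohort table as TSV
#'
#' @param cohort the `cohort` data.frame of a [generate_cohort()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
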