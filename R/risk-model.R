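#' Simplified Apfel risk score
#'
#' Counts one point each for female sex, non-smoking status, a history of
#' PONV (or motion sickness), and postoperative opioid use. Note the
#' opioid factor is the postoperative-use flag of the published score, not
#' the median split on morphine equivalents used as a covariate in the
#' association model.
#'
#' @param data data.frame with columns `Gender`, `Smoking` (risk-coded
#'   non-smoking flag), `PONVhistory`, and `postop_opioid`.
#' @return integer vector 0-4; `NA` when any factor is missing.
#' @export
apfel_score <- function(data) {
  need <- c("Gender", "Smoking", "PONVhistory", "postop_opioid")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing Apfel factor column(s): ",
                         paste(miss, collapse = ", "))
  as.integer(data$Gender + data$Smoking + data$PONVhistory +
               data$postop_opioid)
}

#' rs3782025 genetic risk flag
#'
#' Deterministic risk rule for the rs3782025 genotype: `A/A` codes 0 and
#' `G/G` codes 1 at any age, while heterozygotes code 0 for patients older
#' than 50 years and 1 otherwise.
#'
#' @param dosage minor-allele (G) dosage 0/1/2, e.g. from
#'   [genotype_dosage()].
#' @param age_years patient age in years.
#' @return integer flag 0/1; `NA` for missing genotype.
#' @export
genetic_risk_flag <- function(dosage, age_years) {
  ifelse(is.na(dosage), NA_integer_,
         ifelse(dosage == 2, 1L,
                ifelse(dosage == 0, 0L,
                       ifelse(age_years > 50, 0L, 1L))))
}

#' Select the subpopulation to genotype
#'
#' Model 1 genotypes only Apfel category 2 women younger than 50; Model 2
#' genotypes all Apfel category 2 women.
#'
#' @param data data.frame with columns `Gender`, `age_years`, and `apfel`.
#' @param model 1 or 2.
#' @return logical vector selecting the genotyped subpopulation.
#' @export
select_genotyping_population <- function(data, model = c(1, 2)) {
  model <- match.arg(as.character(model), c("1", "2"))
  sel <- data$Gender == 1 & data$apfel == 2
  if (model == "1") sel <- sel & data$age_years < 50
  sel & !is.na(sel)
}

#' Genotype-adjusted Apfel category
#'
#' Within the genotyped subset, the category moves up one unit for a
#' positive genetic risk flag and down one unit for a negative flag;
#' everyone else keeps the unadjusted category.
#'
#' @param apfel integer Apfel categories.
#' @param selected logical genotyped-subset indicator.
#' @param flag 0/1 genetic risk flags (`NA` outside the subset is fine).
#' @return integer adjusted categories.
#' @export
adjusted_category <- function(apfel, selected, flag) {
  out <- as.integer(apfel)
  idx <- which(selected & !is.na(flag))
  out[idx] <- out[idx] + ifelse(flag[idx] == 1, 1L, -1L)
  out
}

#' Classification metrics and NNT/NNG from group sizes and risks
#'
#' Exact closed-form evaluation of a binary risk stratification given the
#' genotyped group sizes and the PONV proportions in the flagged and
#' unflagged groups: sensitivity, specificity, accuracy, overall PONV
#' percentage, the number needed to treat
#' `NNT = 1 / (p_risk - p_norisk)`, and the numbers needed to genotype,
#' `NNG = NNT / group frequency` for the flagged (increased-risk) and
#' unflagged (decreased-risk) directions, rounded to the nearest integer.
#'
#' @param n_risk,n_norisk genotyped patients with and without the genetic
#'   risk flag.
#' @param p_risk,p_norisk PONV proportion in each group.
#' @return a `classification_metrics` list: `n_genotyped`,
#'   `n_risk_flagged`, `pct_ponv_overall`, `pct_ponv_risk`,
#'   `pct_ponv_norisk` (percentages), `sensitivity`, `specificity`,
#'   `accuracy`, `nnt`, `nng_increased`, `nng_decreased`.
#' @examples
#' metrics_from_groups(51, 29, 0.75, 0.44)  # NNG 5 / 9
#' @export
metrics_from_groups <- function(n_risk, n_norisk, p_risk, p_norisk) {
  stopifnot(n_risk >= 1, n_norisk >= 1,
            p_risk >= 0, p_risk <= 1, p_norisk >= 0, p_norisk <= 1)
  total <- n_risk + n_norisk
  cases <- n_risk * p_risk + n_norisk * p_norisk
  noncases <- total - cases
  sens <- if (cases > 0) n_risk * p_risk / cases else NA_real_
  spec <- if (noncases > 0) n_norisk * (1 - p_norisk) / noncases else
    NA_real_
  acc <- (n_risk * p_risk + n_norisk * (1 - p_norisk)) / total
  if (p_risk == p_norisk) {
    warning("equal group risks: NNT/NNG undefined")
    nnt <- NA_real_
    nng_inc <- nng_dec <- NA_real_
  } else {
    nnt <- 1 / (p_risk - p_norisk)
    nng_inc <- round_half_up(nnt / (n_risk / total))
    nng_dec <- round_half_up(nnt / (n_norisk / total))
  }
  structure(list(n_genotyped = total, n_risk_flagged = n_risk,
                 pct_ponv_overall = 100 * cases / total,
                 pct_ponv_risk = 100 * p_risk,
                 pct_ponv_norisk = 100 * p_norisk,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 nnt = nnt, nng_increased = nng_inc,
                 nng_decreased = nng_dec),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("genotyped %d (flagged %d); PONV overall %.0f%% (risk %.0f%% / no-risk %.0f%%)\n",
              x$n_genotyped, x$n_risk_flagged, x$pct_ponv_overall,
              x$pct_ponv_risk, x$pct_ponv_norisk))
  cat(sprintf("sensitivity %.2f  specificity %.2f  accuracy %.2f\n",
              x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("NNT %.2f  NNG increased-risk %d  decreased-risk %d\n",
              x$nnt, x$nng_increased, x$nng_decreased))
  invisible(x)
}

#' ROC curve and AUC by the Mann-Whitney pair statistic
#'
#' AUC is computed as the probability that a random case scores above a
#' random control, with ties counted 1/2 (the Mann-Whitney U statistic).
#' The 95% CI comes from the DeLong placement-variance estimator or from a
#' seeded bootstrap (2000 stratified resamples).
#'
#' @param scores numeric risk scores.
#' @param outcomes binary outcomes (1 = case).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param seed bootstrap seed.
#' @param n_boot bootstrap resamples (default 2000).
#' @return a `roc_curve`: list with `auc`, `ci95`, and `curve`
#'   (data.frame `threshold`, `sensitivity`, `one_minus_specificity`).
#' @export
roc_auc <- function(scores, outcomes, ci_method = c("delong", "bootstrap"),
                    seed = 1, n_boot = 2000) {
  ci_method <- match.arg(ci_method)
  ok <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[ok]
  outcomes <- outcomes[ok]
  cases <- scores[outcomes == 1]
  controls <- scores[outcomes == 0]
  if (!length(cases) || !length(controls))
    stop("need at least one case and one control")
  auc <- auc_mw(cases, controls)
  if (ci_method == "delong") {
    ## DeLong: variance from case and control placement values
    v10 <- vapply(cases, function(x) auc_mw(x, controls), numeric(1))
    v01 <- vapply(controls, function(y) auc_mw(cases, y), numeric(1))
    var_auc <- stats::var(v10) / length(cases) +
      stats::var(v01) / length(controls)
    ci <- auc + c(-1, 1) * Z95 * sqrt(var_auc)
  } else {
    set.seed(seed)
    boots <- replicate(n_boot, {
      auc_mw(sample(cases, replace = TRUE),
             sample(controls, replace = TRUE))
    })
    ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(cases >= t), numeric(1)),
    one_minus_specificity = vapply(thr, function(t)
      mean(controls >= t), numeric(1)))
  structure(list(auc = auc, ci95 = pmin(pmax(ci, 0), 1), curve = curve,
                 n_cases = length(cases), n_controls = length(controls)),
            class = "roc_curve")
}

## Mann-Whitney AUC with ties counted 1/2
auc_mw <- function(cases, controls) {
  r <- rank(c(cases, controls), ties.method = "average")
  n1 <- length(cases)
  n0 <- length(controls)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("AUC %.3f [95%% CI %.3f-%.3f] (%d cases / %d controls)\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_cases, x$n_controls))
  invisible(x)
}

#' End-to-end genotype-adjusted risk assessment of a cohort
#'
#' Computes the Apfel score, selects the genotyping subpopulation of the
#' chosen model, derives the rs3782025 genetic risk flag, builds the
#' adjusted categories, and evaluates the stratification: observed group
#' risks, [metrics_from_groups()] on them, the ROC/AUC of the genotyped
#' subset (genetic flag as score) and of the whole cohort (adjusted
#' category as ordinal score, with the unadjusted Apfel AUC alongside).
#'
#' @param cohort cohort data.frame (risk flags, `age_years`,
#'   `postop_opioid`, `ponv_occurrence`).
#' @param gm matching [genotype_matrix()] containing rs3782025.
#' @param model 1 or 2.
#' @param marker risk variant (default `"rs3782025"`).
#' @return a `risk_assessment`: list with the per-patient table
#'   (`apfel`, `genotyped_flag`, `genetic_risk`, `adjusted_category`,
#'   `predicted_ponv`), `metrics`, `roc_subset`, `roc_cohort`,
#'   `roc_cohort_unadjusted`.
#' @export
risk_assessment <- function(cohort, gm, model = 1, marker = "rs3782025") {
  data <- cohort
  data$apfel <- apfel_score(data)
  sel <- select_genotyping_population(data, model)
  dosage <- genotype_dosage(gm, marker)
  dosage <- dosage[match(data$sample_id %||% gm$samples, gm$samples)]
  flag <- rep(NA_integer_, nrow(data))
  flag[sel] <- genetic_risk_flag(dosage[sel], data$age_years[sel])
  adj <- adjusted_category(data$apfel, sel, flag)
  usable <- sel & !is.na(flag)
  n_risk <- sum(flag[usable] == 1)
  n_norisk <- sum(flag[usable] == 0)
  y <- data$ponv_occurrence
  metrics <- if (n_risk >= 1 && n_norisk >= 1)
    metrics_from_groups(n_risk, n_norisk,
                        mean(y[usable][flag[usable] == 1]),
                        mean(y[usable][flag[usable] == 0])) else NULL
  roc_subset <- if (n_risk >= 1 && n_norisk >= 1 &&
                    length(unique(y[usable])) == 2)
    roc_auc(flag[usable], y[usable]) else NULL
  table <- data.frame(sample_id = data$sample_id %||% gm$samples,
                      apfel = data$apfel, genotyped_flag = sel,
                      genetic_risk = flag, adjusted_category = adj,
                      predicted_ponv = as.integer(
                        ifelse(sel & !is.na(flag), flag, data$apfel >= 3)),
                      stringsAsFactors = FALSE)
  structure(list(table = table, model = model, metrics = metrics,
                 roc_subset = roc_subset,
                 roc_cohort = roc_auc(adj, y),
                 roc_cohort_unadjusted = roc_auc(data$apfel, y)),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("risk_assessment, Model", x$model, "\n")
  if (!is.null(x$metrics)) print(x$metrics)
  if (!is.null(x$roc_subset)) {
    cat("genotyped subset: ")
    print(x$roc_subset)
  }
  cat("whole cohort (adjusted): ")
  print(x$roc_cohort)
  cat("whole cohort (Apfel only): ")
  print(x$roc_cohort_unadjusted)
  invisible(x)
}

#' Write a per-patient risk report and metrics JSON
#'
#' @param ra a [risk_assessment()] result.
#' @param prefix output path prefix.
#' @return the JSON path, invisibly.
#' @export
write_risk_report <- function(ra, prefix) {
  utils::write.table(ra$table, paste0(prefix, "_patients.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ra$metrics))
    jsonlite::write_json(unclass(ra$metrics), paste0(prefix, ".json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(ra$roc_cohort))
    utils::write.table(ra$roc_cohort$curve, paste0(prefix, "_roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paste0(prefix, ".json"))
}
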