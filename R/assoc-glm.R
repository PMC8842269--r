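#' Dichotomize raw clinical covariates into risk flags
#'
#' Applies the study's risk coding (1 = increased risk): `Gender` = 1 for
#' female; `Age` = 1 for age < 50 years; `Smoking` = 1 for non-smokers and
#' `Cannabis` = 1 for non-users (smoking is protective); `PONVhistory` = 1
#' for previous PONV; `SurgeryType` = 1 for visceral or gynecological
#' surgery; `VolatileAnesthetics` = 1 when volatile agents were used;
#' `HighOpioid` = 1 for perioperative consumption strictly above the
#' 19 mg morphine-equivalent median (values of exactly 19 mg code 0).
#'
#' @param raw data.frame with columns `sex` (`"female"`/`"male"`),
#'   `age_years`, `smoking`, `cannabis`, `ponv_history`, `volatile`
#'   (each `"yes"`/`"no"`), `surgery_type`, and `opioid_mg`.
#' @param opioid_cutoff morphine-equivalent cutoff in mg (default 19).
#' @return `raw` with the eight risk columns appended plus a logical
#'   `complete_case` column; rows with missing raw fields have `NA` flags
#'   and `complete_case = FALSE` (they are dropped listwise by the model
#'   fits).
#' @export
dichotomize <- function(raw, opioid_cutoff = 19) {
  need <- c("sex", "age_years", "smoking", "cannabis", "ponv_history",
            "surgery_type", "volatile", "opioid_mg")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing raw field(s): ", paste(miss, collapse = ", "))
  yes <- function(x) ifelse(is.na(x), NA_integer_,
                            as.integer(tolower(as.character(x)) == "yes"))
  raw$Gender <- ifelse(is.na(raw$sex), NA_integer_,
                       as.integer(tolower(raw$sex) == "female"))
  raw$Age <- ifelse(is.na(raw$age_years), NA_integer_,
                    as.integer(raw$age_years < 50))
  raw$Smoking <- 1L - yes(raw$smoking)
  raw$Cannabis <- 1L - yes(raw$cannabis)
  raw$PONVhistory <- yes(raw$ponv_history)
  raw$SurgeryType <- ifelse(is.na(raw$surgery_type), NA_integer_,
                            as.integer(tolower(raw$surgery_type) %in%
                                         c("visceral", "gynecologic",
                                           "gynecological")))
  raw$VolatileAnesthetics <- yes(raw$volatile)
  raw$HighOpioid <- ifelse(is.na(raw$opioid_mg), NA_integer_,
                           as.integer(raw$opioid_mg > opioid_cutoff))
  raw$complete_case <-
    stats::complete.cases(raw[, eq1_covariates(), drop = FALSE])
  raw
}

#' Encode genotype dosages under a genetic model
#'
#' @param dosage additive minor-allele dosage vector (0/1/2, `NA` missing),
#'   e.g. from [genotype_dosage()].
#' @param encoding `"additive"` (0/1/2), `"dominant"` (0/1/1),
#'   `"recessive"` (0/0/1), or `"continuous_score"` (values passed
#'   through, for activity scores).
#' @return numeric vector; missing stays `NA` (excluded listwise by fits).
#' @export
encode_genotype <- function(dosage, encoding = c("additive", "dominant",
                                                 "recessive",
                                                 "continuous_score")) {
  encoding <- match.arg(encoding)
  switch(encoding,
         additive = as.numeric(dosage),
         dominant = as.numeric(dosage >= 1),
         recessive = as.numeric(dosage == 2),
         continuous_score = as.numeric(dosage))
}

#' Specify a covariate-adjusted logistic model
#'
#' @param outcome name of the binary outcome column.
#' @param covariates ordered covariate columns (default the eight risk
#'   flags of [eq1_covariates()]).
#' @param marker optional name of the genetic term column.
#' @param encoding genetic encoding of the marker (see
#'   [encode_genotype()]).
#' @return a `logistic_model_spec`.
#' @export
logistic_model_spec <- function(outcome, covariates = eq1_covariates(),
                                marker = NULL, encoding = "additive") {
  if (anyDuplicated(covariates)) stop("covariates must be distinct")
  structure(list(outcome = outcome, covariates = covariates,
                 marker = marker, encoding = encoding),
            class = "logistic_model_spec")
}

## core IRLS solver: Newton-Raphson on the logistic log-likelihood with
## Fisher scoring weights. Convergence when the maximum absolute score
## drops below `tol_score` or the relative deviance change below
## `tol_dev`; coefficients beyond `sep_limit` in magnitude flag separation.
irls_logistic <- function(X, y, max_iter = 50, tol_score = 1e-8,
                          tol_dev = 1e-10, sep_limit = 15) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  beta <- rep(0, ncol(X))
  dev_old <- Inf
  converged <- FALSE
  separation <- FALSE
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- inv_logit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    score <- as.vector(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    beta <- beta + solve(info, score)
    eta <- as.vector(X %*% beta)
    mu <- inv_logit(eta)
    ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
    loglik <- c(loglik, ll)
    dev <- -2 * ll
    if (any(abs(beta) > sep_limit)) {
      separation <- TRUE
      break
    }
    score_new <- as.vector(crossprod(X, y - mu))
    if (max(abs(score_new)) < tol_score ||
        abs(dev_old - dev) < tol_dev * (abs(dev_old) + 1e-8)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  mu <- inv_logit(as.vector(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  vcov <- solve(crossprod(X * w, X))
  list(beta = stats::setNames(as.vector(beta), colnames(X)),
       vcov = vcov, loglik = loglik, converged = converged && !separation,
       separation = separation, n = length(y))
}

#' Fit a covariate-adjusted logistic model by IRLS
#'
#' Maximum-likelihood logistic regression implemented as iteratively
#' reweighted least squares, with Wald standard errors from the inverse
#' observed information, odds ratios `exp(beta)`, and 95% Wald intervals
#' `exp(beta +- 1.959964 se)`. Rows with missing outcome, covariate, or
#' marker values are dropped listwise. Quasi-separation (a coefficient
#' exceeding 15 in magnitude) is flagged as non-converged rather than
#' reported silently.
#'
#' @param spec a [logistic_model_spec()].
#' @param data data.frame holding outcome, covariates, and (optionally)
#'   the already-encoded marker column.
#' @return a `ponv_fit`: data.frame-like list with `beta`, `se`, `or_`,
#'   `ci95` (matrix), `p` (Wald), `converged`, `separation`, `n_used`,
#'   `loglik`.
#' @export
fit_logistic <- function(spec, data) {
  cols <- c(spec$outcome, spec$covariates, spec$marker)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("column(s) not in data: ",
                         paste(miss, collapse = ", "))
  d <- data[, cols, drop = FALSE]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  y <- d[[spec$outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(d[, c(spec$covariates, spec$marker), drop = FALSE]))
  fit <- irls_logistic(X, y)
  se <- sqrt(diag(fit$vcov))
  ci <- cbind(lower = exp(fit$beta - Z95 * se),
              upper = exp(fit$beta + Z95 * se))
  p <- 2 * stats::pnorm(-abs(fit$beta / se))
  structure(list(beta = fit$beta, se = stats::setNames(se, names(fit$beta)),
                 or_ = exp(fit$beta), ci95 = ci, p = p,
                 converged = fit$converged, separation = fit$separation,
                 n_used = fit$n, loglik = fit$loglik, spec = spec),
            class = "ponv_fit")
}

#' @export
print.ponv_fit <- function(x, digits = 3, ...) {
  cat("Logistic fit (IRLS):", x$spec$outcome, "~",
      paste(c(x$spec$covariates, x$spec$marker), collapse = " + "), "\n")
  cat("n =", x$n_used,
      if (!x$converged) "[NOT CONVERGED]",
      if (x$separation) "[SEPARATION]", "\n")
  tab <- data.frame(beta = round(x$beta, digits),
                    OR = round(x$or_, digits),
                    `CI low` = round(x$ci95[, 1], digits),
                    `CI high` = round(x$ci95[, 2], digits),
                    p = signif(x$p, digits), check.names = FALSE)
  print(tab)
  invisible(x)
}

#' Marker association under the covariate-adjusted model
#'
#' Fits the full eight-covariate logistic model plus one genetic marker
#' term and reports the marker's OR, 95% CI, and Wald p-value. Recurrence
#' analyses are automatically restricted to followed PONV cases.
#'
#' @param marker_id variant to test.
#' @param outcome `"occurrence"` or `"recurrence"`.
#' @param cohort cohort data.frame with the risk flags and outcome
#'   columns.
#' @param gm matching [genotype_matrix()].
#' @param encoding genetic encoding (default additive).
#' @return one-row data.frame (`marker`, `encoding`, `outcome`, `n`,
#'   `maf`, `beta`, `or`, `ci_low`, `ci_high`, `p`, `converged`) with the
#'   full `ponv_fit` attached as attribute `fit`.
#' @export
associate_marker <- function(marker_id, outcome = c("occurrence",
                                                    "recurrence"),
                             cohort, gm, encoding = "additive") {
  outcome <- match.arg(outcome)
  d <- genotype_dosage(gm, marker_id)
  if (length(unique(stats::na.omit(d))) < 2)
    stop("marker ", marker_id, " is monomorphic; association undefined")
  data <- cohort
  data$.marker <- encode_genotype(d[match(cohort$sample_id %||%
                                            gm$samples, gm$samples)],
                                  encoding)
  ycol <- if (outcome == "occurrence") "ponv_occurrence" else
    "ponv_recurrence"
  if (outcome == "recurrence")
    data <- data[!is.na(data$ponv_recurrence) & data$followed_flag == 1, ]
  spec <- logistic_model_spec(ycol, eq1_covariates(), marker = ".marker",
                              encoding = encoding)
  fit <- fit_logistic(spec, data)
  res <- data.frame(marker = marker_id, encoding = encoding,
                    outcome = outcome, n = fit$n_used,
                    maf = mean(d, na.rm = TRUE) / 2,
                    beta = fit$beta[".marker"], or = fit$or_[".marker"],
                    ci_low = fit$ci95[".marker", 1],
                    ci_high = fit$ci95[".marker", 2],
                    p = fit$p[".marker"], converged = fit$converged,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "fit") <- fit
  res
}

#' Activity-score association under the covariate-adjusted model
#'
#' Fits the eight-covariate model with a predicted enzyme activity score
#' entered as a continuous term.
#'
#' @param scores numeric activity scores, one per cohort row.
#' @param outcome `"occurrence"` or `"recurrence"`.
#' @param cohort cohort data.frame.
#' @param gene label for the reported row.
#' @return one-row data.frame as in [associate_marker()].
#' @export
associate_activity <- function(scores, outcome = c("occurrence",
                                                   "recurrence"),
                               cohort, gene = "activity") {
  outcome <- match.arg(outcome)
  data <- cohort
  data$.score <- as.numeric(scores)
  ycol <- if (outcome == "occurrence") "ponv_occurrence" else
    "ponv_recurrence"
  if (outcome == "recurrence")
    data <- data[!is.na(data$ponv_recurrence) & data$followed_flag == 1, ]
  spec <- logistic_model_spec(ycol, eq1_covariates(), marker = ".score",
                              encoding = "continuous_score")
  fit <- fit_logistic(spec, data)
  res <- data.frame(marker = gene, encoding = "continuous_score",
                    outcome = outcome, n = fit$n_used, maf = NA_real_,
                    beta = fit$beta[".score"], or = fit$or_[".score"],
                    ci_low = fit$ci95[".score", 1],
                    ci_high = fit$ci95[".score", 2], p = fit$p[".score"],
                    converged = fit$converged, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "fit") <- fit
  res
}

#' Bonferroni multiple-testing correction
#'
#' @param p_values vector of raw p-values.
#' @param m number of tests (default `length(p_values)`).
#' @param alpha family-wise error rate (default 0.05).
#' @return list with the corrected `threshold` (`alpha/m`) and a logical
#'   `significant` vector (`p < alpha/m`).
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  stopifnot(m >= 1)
  list(threshold = alpha / m, significant = p_values < alpha / m)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the least-squares regression of
#' covariate `j` on the remaining covariates; a covariate perfectly
#' explained by the others (aliased) is reported as `Inf`.
#'
#' @param data data.frame holding the covariates.
#' @param covariates character vector of two or more column names.
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(data, covariates = eq1_covariates()) {
  stopifnot(length(covariates) >= 2)
  X <- as.matrix(data[, covariates, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  vapply(seq_along(covariates), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else max(1, 1 / (1 - r2))
  }, numeric(1)) |> stats::setNames(covariates)
}

#' Scan markers for confounding of covariate effects
#'
#' Refits the base covariate model with each marker added and reports the
#' relative change of every significant covariate coefficient; changes
#' above `threshold` (default 10%) are flagged as potential confounding.
#'
#' @param cohort cohort data.frame.
#' @param gm matching [genotype_matrix()].
#' @param markers variant ids to scan.
#' @param outcome `"occurrence"` or `"recurrence"`.
#' @param threshold relative-change flag threshold (default 0.10).
#' @param alpha significance level selecting the covariates to monitor.
#' @return data.frame with one row per (marker, covariate):
#'   `beta_without`, `beta_with`, `rel_change`, `flagged`.
#' @export
confounding_scan <- function(cohort, gm, markers,
                             outcome = "occurrence", threshold = 0.10,
                             alpha = 0.05) {
  ycol <- if (outcome == "occurrence") "ponv_occurrence" else
    "ponv_recurrence"
  data <- cohort
  if (outcome == "recurrence")
    data <- data[!is.na(data$ponv_recurrence) & data$followed_flag == 1, ]
  base <- fit_logistic(logistic_model_spec(ycol), data)
  if (!base$converged) stop("base model did not converge")
  sig <- names(base$p)[base$p < alpha & names(base$p) != "(Intercept)"]
  rows <- list()
  for (m in markers) {
    res <- associate_marker(m, outcome, cohort, gm)
    fit <- attr(res, "fit")
    for (cv in sig) {
      b0 <- base$beta[cv]
      b1 <- fit$beta[cv]
      rel <- if (abs(b0) < 1e-12) NA_real_ else (b1 - b0) / b0
      rows[[length(rows) + 1]] <- data.frame(
        marker = m, covariate = cv, beta_without = b0, beta_with = b1,
        rel_change = rel,
        flagged = !is.na(rel) && abs(rel) > threshold,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write association results in the tabular report layout
#'
#' @param results data.frame of rows from [associate_marker()] /
#'   [associate_activity()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return the TSV path, invisibly.
#' @export
write_association_results <- function(results, prefix) {
  utils::write.table(results, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(results, paste0(prefix, ".json"), digits = NA,
                       na = "null")
  invisible(paste0(prefix, ".tsv"))
}
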