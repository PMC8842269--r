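#' Declare a dichotomized covariate for cohort simulation
#'
#' Each covariate is a Bernoulli risk flag (1 = risk-coded level) with a
#' target marginal prevalence. A covariate may be coupled to one covariate
#' declared *earlier* in the list through a pairwise odds ratio; couplings
#' are realized by sequential conditional draws that preserve both marginals
#' exactly (see [generate_covariates()]).
#'
#' @param name column name of the covariate (e.g. `"Gender"`).
#' @param prevalence marginal probability of the risk-coded level, in \[0,1\].
#' @param couple_to optional name of an earlier covariate to couple with.
#' @param couple_or odds ratio of the coupling (required with `couple_to`).
#' @return a `covariate_spec` object.
#' @export
covariate_spec <- function(name, prevalence, couple_to = NULL,
                           couple_or = NULL) {
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1)
    stop("invalid prevalence for covariate '", name, "': must be in [0,1]")
  if (!is.null(couple_to) && is.null(couple_or))
    stop("covariate '", name, "': couple_to given without couple_or")
  structure(list(name = name, prevalence = prevalence,
                 couple_to = couple_to, couple_or = couple_or),
            class = "covariate_spec")
}

#' Generate dichotomized covariates with coupled margins
#'
#' Draws each covariate in declaration order. An uncoupled covariate is
#' Bernoulli at its marginal prevalence. A covariate coupled to an earlier
#' one is drawn from the conditional distribution implied by the unique 2x2
#' table with the two marginals and the requested odds ratio
#' ([solve_2x2_or()]), so both marginals are preserved exactly and the
#' pairwise odds ratio is realized in expectation.
#'
#' @param specs list of [covariate_spec()] objects.
#' @param n number of patients (>= 1).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return data.frame of 0/1 columns, one per covariate.
#' @export
generate_covariates <- function(specs, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate covariate names")
  out <- matrix(0L, n, length(specs), dimnames = list(NULL, nm))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    if (is.null(sp$couple_to)) {
      out[, j] <- stats::rbinom(n, 1, sp$prevalence)
    } else {
      k <- match(sp$couple_to, nm[seq_len(j - 1)])
      if (is.na(k))
        stop("covariate '", sp$name, "' is coupled to '", sp$couple_to,
             "', which is not declared earlier")
      p_par <- specs[[k]]$prevalence
      p11 <- solve_2x2_or(p_par, sp$prevalence, sp$couple_or)
      p_given1 <- if (p_par > 0) p11 / p_par else 0
      p_given0 <- if (p_par < 1) (sp$prevalence - p11) / (1 - p_par) else 0
      pr <- ifelse(out[, k] == 1L, p_given1, p_given0)
      out[, j] <- stats::rbinom(n, 1, pr)
    }
  }
  as.data.frame(out)
}

#' Declare a single locus for genotype simulation
#'
#' @param variant_id dbSNP-style identifier.
#' @param maf minor-allele frequency in (0, 0.5\].
#' @param major_allele,minor_allele allele symbols (SNV or indel symbols,
#'   e.g. `"CA"` / `"-"`).
#' @param chrom,position optional coordinates (used to order loci for LD
#'   block detection).
#' @param extra_allele,extra_freq optional third allele and its frequency:
#'   the locus is simulated as two nested biallelic draws (major vs.
#'   non-major, then the extra allele among non-major at the rate giving the
#'   requested overall frequency).
#' @return a `locus_spec` object.
#' @export
locus_spec <- function(variant_id, maf, major_allele = "A",
                       minor_allele = "G", chrom = NA, position = NA,
                       extra_allele = NULL, extra_freq = 0) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop("invalid maf for ", variant_id, ": must be in (0, 0.5]")
  structure(list(variant_id = variant_id, maf = maf,
                 major_allele = major_allele, minor_allele = minor_allele,
                 chrom = chrom, position = position,
                 extra_allele = extra_allele, extra_freq = extra_freq),
            class = "locus_spec")
}

#' Declare an LD block of loci with joint haplotype frequencies
#'
#' Blocked loci are simulated as two independent haplotype draws per sample
#' from the supplied multi-locus haplotype distribution, then collapsed to
#' unphased genotypes. Single-locus margins of the haplotype distribution
#' must reproduce each locus' `maf`.
#'
#' @param block_id block label.
#' @param loci list of [locus_spec()] objects (2-8 loci).
#' @param haplotypes data.frame with one 0/1 column per locus (1 = minor
#'   allele) named by `variant_id`, plus a `freq` column summing to 1.
#' @return a `block_spec` object.
#' @export
block_spec <- function(block_id, loci, haplotypes) {
  vids <- vapply(loci, `[[`, character(1), "variant_id")
  stopifnot(length(vids) >= 2, length(vids) <= 8,
            all(vids %in% names(haplotypes)), "freq" %in% names(haplotypes))
  if (abs(sum(haplotypes$freq) - 1) > 1e-6)
    stop("block ", block_id, ": haplotype frequencies sum to ",
         sum(haplotypes$freq), ", not 1")
  for (i in seq_along(loci)) {
    margin <- sum(haplotypes$freq * haplotypes[[vids[i]]])
    if (abs(margin - loci[[i]]$maf) > 1e-6)
      stop("block ", block_id, ": haplotype margin ", round(margin, 4),
           " at ", vids[i], " does not reproduce maf ", loci[[i]]$maf)
  }
  structure(list(block_id = block_id, loci = loci, haplotypes = haplotypes),
            class = "block_spec")
}

loci_to_variant_defs <- function(loci) {
  rows <- lapply(loci, function(l) {
    if (inherits(l, "block_spec")) return(loci_to_variant_defs(l$loci))
    data.frame(variant_id = l$variant_id, chrom = l$chrom,
               position = l$position, major_allele = l$major_allele,
               minor_allele = l$minor_allele,
               extra_allele = l$extra_allele %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate unphased genotypes under HWE and block LD structure
#'
#' Unblocked loci are drawn as two independent allele draws at the locus
#' MAF (Hardy-Weinberg). Blocked loci are drawn as two independent
#' haplotypes from the block's haplotype frequencies and collapsed to
#' unphased genotypes; the phased draws are retained in the
#' `phased_truth` attribute so estimators can be validated against the
#' generating phase.
#'
#' @param loci list of [locus_spec()] and/or [block_spec()] objects.
#' @param n number of samples.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param missing_rate per-call missingness probability (default 0).
#' @return a [genotype_matrix()]; attribute `phased_truth` holds, per
#'   block, an `n x 2` matrix of haplotype row indices into the block's
#'   haplotype table.
#' @export
generate_genotypes <- function(loci, n, seed = NULL, missing_rate = 0) {
  stopifnot(n >= 1, missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  defs <- loci_to_variant_defs(loci)
  calls <- matrix(NA_character_, n, nrow(defs),
                  dimnames = list(paste0("S", seq_len(n)), defs$variant_id))
  phased <- list()
  for (l in loci) {
    if (inherits(l, "block_spec")) {
      vids <- vapply(l$loci, `[[`, character(1), "variant_id")
      h1 <- sample.int(nrow(l$haplotypes), n, replace = TRUE,
                       prob = l$haplotypes$freq)
      h2 <- sample.int(nrow(l$haplotypes), n, replace = TRUE,
                       prob = l$haplotypes$freq)
      phased[[l$block_id]] <- cbind(h1, h2)
      for (i in seq_along(vids)) {
        a1 <- ifelse(l$haplotypes[[vids[i]]][h1] == 1,
                     l$loci[[i]]$minor_allele, l$loci[[i]]$major_allele)
        a2 <- ifelse(l$haplotypes[[vids[i]]][h2] == 1,
                     l$loci[[i]]$minor_allele, l$loci[[i]]$major_allele)
        calls[, vids[i]] <- paste_sorted(a1, a2)
      }
    } else {
      p_alt <- l$maf + (l$extra_freq %||% 0)
      draw_allele <- function() {
        alt <- stats::runif(n) < p_alt
        a <- ifelse(alt, l$minor_allele, l$major_allele)
        if (!is.null(l$extra_allele) && l$extra_freq > 0) {
          is_extra <- alt & stats::runif(n) < l$extra_freq / p_alt
          a[is_extra] <- l$extra_allele
        }
        a
      }
      calls[, l$variant_id] <- paste_sorted(draw_allele(), draw_allele())
    }
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(calls)) < missing_rate, n)
    calls[mask] <- NA_character_
  }
  gm <- genotype_matrix(calls, defs)
  attr(gm, "phased_truth") <- phased
  gm
}

paste_sorted <- function(a1, a2) {
  ifelse(a1 <= a2, paste(a1, a2, sep = "/"), paste(a2, a1, sep = "/"))
}

#' Specify the logistic outcome model of the simulator
#'
#' Occurrence of PONV is drawn Bernoulli with
#' `logit(p) = intercept + x'covariate_betas + g'marker_betas`, where `x`
#' are the dichotomized risk covariates and `g` the additive minor-allele
#' dosages of the named markers. Among patients with an occurrence, a
#' `followed_prob` fraction is followed up and recurrence is drawn from the
#' analogous `recurrence` coefficient set.
#'
#' @param intercept occurrence log-odds intercept.
#' @param covariate_betas named numeric vector of per-covariate log-odds.
#' @param marker_betas named (by variant_id) numeric vector of per-minor-
#'   allele log-odds.
#' @param recurrence optional list with elements `intercept`,
#'   `covariate_betas`, `marker_betas` for the recurrence model.
#' @param followed_prob probability that a PONV case is followed up.
#' @return an `outcome_model_spec` object.
#' @export
outcome_model_spec <- function(intercept, covariate_betas,
                               marker_betas = numeric(0),
                               recurrence = NULL, followed_prob = 0.867) {
  stopifnot(is.finite(intercept), all(is.finite(covariate_betas)),
            all(is.finite(marker_betas)))
  structure(list(intercept = intercept, covariate_betas = covariate_betas,
                 marker_betas = marker_betas, recurrence = recurrence,
                 followed_prob = followed_prob),
            class = "outcome_model_spec")
}

linear_predictor <- function(cohort, gm, intercept, covariate_betas,
                             marker_betas) {
  miss <- setdiff(names(covariate_betas), names(cohort))
  if (length(miss))
    stop("covariate(s) referenced by the outcome model are missing: ",
         paste(miss, collapse = ", "))
  eta <- rep(intercept, nrow(cohort))
  for (v in names(covariate_betas))
    eta <- eta + covariate_betas[[v]] * cohort[[v]]
  for (m in names(marker_betas)) {
    d <- genotype_dosage(gm, m)
    if (anyNA(d)) stop("marker ", m, " has missing dosages; generate ",
                       "outcomes before injecting missingness")
    eta <- eta + marker_betas[[m]] * d
  }
  eta
}

#' Draw PONV occurrence and recurrence outcomes
#'
#' @param cohort covariate table from [generate_covariates()].
#' @param gm matching [genotype_matrix()] (complete calls).
#' @param model an [outcome_model_spec()].
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return `cohort` with columns `ponv_occurrence`, `followed_flag`, and
#'   `ponv_recurrence` (`NA` for patients without occurrence or follow-up).
#' @export
generate_outcomes <- function(cohort, gm, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  eta <- linear_predictor(cohort, gm, model$intercept,
                          model$covariate_betas, model$marker_betas)
  occ <- stats::rbinom(n, 1, inv_logit(eta))
  followed <- integer(n)
  followed[occ == 1] <- stats::rbinom(sum(occ == 1), 1, model$followed_prob)
  rec <- rep(NA_integer_, n)
  if (!is.null(model$recurrence)) {
    eta_r <- linear_predictor(cohort, gm, model$recurrence$intercept,
                              model$recurrence$covariate_betas,
                              model$recurrence$marker_betas %||% numeric(0))
    idx <- which(occ == 1 & followed == 1)
    rec[idx] <- stats::rbinom(length(idx), 1, inv_logit(eta_r[idx]))
  }
  cohort$ponv_occurrence <- occ
  cohort$followed_flag <- followed
  cohort$ponv_recurrence <- rec
  cohort
}
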