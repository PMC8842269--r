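#' Load a star-allele definition table
#'
#' An allele definition table maps star alleles of each pharmacogene to
#' their defining variant calls and carries the per-allele activity score
#' and a deterministic matching priority (lower = preferred, used to
#' resolve ambiguous diplotypes; the reference allele carries priority 99).
#' The package ships a default table covering the alleles used by the
#' activity scores (CYP1A2 *1A/*1L/*1F/*1C, CYP2B6 *1/*4/*5/*6/*9/*22,
#' CYP2C19 *1/*2/*3/*17, CYP2C9 *1/*2/*3, common CYP2D6 alleles,
#' CYP3A4*22, CYP3A5*3, CYP3A7*1C) keyed by rsID; it is an editable,
#' user-overridable file, not an authoritative nomenclature export.
#'
#' @param path TSV with columns `gene`, `star_allele`, `variant_id`,
#'   `required_allele`, `score`, `priority` (`"."` marks the reference
#'   allele row); `NULL` loads the shipped default.
#' @return an `allele_table`: named list (per gene) of allele definitions.
#' @export
load_allele_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "star_allele_definitions.tsv",
                                package = "ponvrisk", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(score = "numeric",
                                          priority = "numeric"))
  need <- c("gene", "star_allele", "variant_id", "required_allele",
            "score", "priority")
  if (!all(need %in% names(tab)))
    stop("allele table needs columns ", paste(need, collapse = ", "))
  if (any(tab$score < 0, na.rm = TRUE))
    stop("negative per-allele scores are not allowed")
  out <- lapply(split(tab, tab$gene), function(g) {
    alleles <- lapply(split(g, g$star_allele), function(a) {
      req <- a$required_allele[a$variant_id != "."]
      names(req) <- a$variant_id[a$variant_id != "."]
      list(score = a$score[1], priority = a$priority[1], req = req)
    })
    if (!any(vapply(alleles, function(a) length(a$req) == 0, logical(1))))
      stop("gene ", g$gene[1], " has no reference (default) allele")
    alleles
  })
  structure(out, class = "allele_table")
}

default_allele_for <- function(alleles) {
  ref <- names(alleles)[vapply(alleles, function(a) length(a$req) == 0,
                               logical(1))]
  ref[1]
}

## observed dosage of `allele` at `variant_id` for one sample; NA when the
## call is missing or the variant is absent from the panel
observed_dosage <- function(gm, sample, variant_id, allele) {
  if (!variant_id %in% gm$variants$variant_id) return(NA_integer_)
  i <- match(sample, gm$samples)
  cl <- gm$calls[i, variant_id]
  if (is.na(cl)) return(NA_integer_)
  sum(strsplit(cl, "/", fixed = TRUE)[[1]] == allele)
}

#' Assign a star-allele diplotype from panel calls
#'
#' Enumerates all unordered pairs of the gene's defined alleles and keeps
#' those whose joint expected dosages (each allele copy contributing one
#' copy of each of its defining variant alleles) exactly explain every
#' observed defining-variant dosage; variants with missing calls act as
#' wildcards. Ties are resolved deterministically by the allele priority
#' order (then lexicographically). When every defining variant is missing
#' the reference diplotype is returned with a warning; when no allele pair
#' can explain the calls, a no-call is returned.
#'
#' @param gm a [genotype_matrix()].
#' @param sample sample identifier.
#' @param gene gene name present in `table`.
#' @param table an [load_allele_table()] result.
#' @return character vector of two star alleles (sorted), or `c(NA, NA)`
#'   with attribute `no_call = TRUE` when inconsistent.
#' @export
assign_diplotype <- function(gm, sample, gene, table = load_allele_table()) {
  alleles <- table[[gene]]
  if (is.null(alleles)) stop("gene not in allele table: ", gene)
  vids <- unique(unlist(lapply(alleles, function(a) names(a$req))))
  obs <- vapply(vids, function(v) {
    a <- unique(unlist(lapply(alleles, function(al) al$req[v])))
    a <- a[!is.na(a)]
    observed_dosage(gm, sample, v, a[1])
  }, integer(1))
  if (length(obs) && all(is.na(obs))) {
    warning("sample ", sample, ", gene ", gene,
            ": all defining variants missing; defaulting to reference")
    ref <- default_allele_for(alleles)
    return(c(ref, ref))
  }
  nm <- names(alleles)
  cand <- list()
  for (i in seq_along(nm)) for (j in i:length(nm)) {
    exp_d <- vapply(vids, function(v) {
      sum(!is.na(alleles[[nm[i]]]$req[v]), !is.na(alleles[[nm[j]]]$req[v]))
    }, numeric(1))
    ok <- is.na(obs) | exp_d == obs
    if (all(ok))
      cand[[length(cand) + 1]] <- list(
        pair = sort(c(nm[i], nm[j])),
        ## variant copies the pair requires at positions without an
        ## observed call: never assert an allele on missing evidence when
        ## a pair needing less does
        assumed = sum(exp_d[is.na(obs)]),
        prio = alleles[[nm[i]]]$priority + alleles[[nm[j]]]$priority)
  }
  if (!length(cand)) {
    out <- c(NA_character_, NA_character_)
    attr(out, "no_call") <- TRUE
    return(out)
  }
  ord <- order(vapply(cand, `[[`, numeric(1), "assumed"),
               vapply(cand, `[[`, numeric(1), "prio"),
               vapply(cand, function(c) paste(c$pair, collapse = "/"),
                      character(1)))
  cand[[ord[1]]]$pair
}

#' Additive activity score of a diplotype
#'
#' The gene activity score is the sum of the two per-allele scores from the
#' allele definition table (e.g. CYP2C19 `*1/*1` scores 2, `*2/*3` scores
#' 0, CYP1A2 `*1F/*1C` scores 2).
#'
#' @param diplotype character vector of two star alleles.
#' @param gene gene name.
#' @param table an [load_allele_table()] result.
#' @return numeric activity score (`NA` for a no-call diplotype).
#' @export
score_additive_gene <- function(diplotype, gene,
                                table = load_allele_table()) {
  if (anyNA(diplotype)) return(NA_real_)
  alleles <- table[[gene]]
  if (is.null(alleles)) stop("gene not in allele table: ", gene)
  s <- vapply(diplotype, function(a) {
    if (is.null(alleles[[a]])) stop("unscored allele for ", gene, ": ", a)
    alleles[[a]]$score
  }, numeric(1))
  sum(s)
}

#' Copy-number-aware CYP2D6 activity score
#'
#' Sums the two per-allele activity values; gene duplications
#' (`copy_number > 2`) add the extra copies to the higher-activity allele
#' of the pair (the conventional resolution when the duplicated allele is
#' not assayed directly), and a single-copy genotype (`copy_number = 1`,
#' i.e. one allele deleted) drops the lower-activity allele. A copy number
#' of 0 scores 0 and is flagged inconsistent when the assigned alleles are
#' not null alleles.
#'
#' @param diplotype character vector of two CYP2D6 star alleles.
#' @param copy_number non-negative gene copy number (default 2).
#' @param table an [load_allele_table()] result.
#' @return numeric activity score; attribute `flag` carries inconsistency
#'   notes.
#' @export
score_cyp2d6 <- function(diplotype, copy_number = 2L,
                         table = load_allele_table()) {
  stopifnot(copy_number >= 0)
  if (anyNA(diplotype)) return(NA_real_)
  alleles <- table[["CYP2D6"]]
  s <- vapply(diplotype, function(a) {
    if (is.null(alleles[[a]])) stop("unscored allele for CYP2D6: ", a)
    alleles[[a]]$score
  }, numeric(1))
  if (copy_number == 0) {
    out <- 0
    if (any(s > 0)) attr(out, "flag") <-
        "copy number 0 with non-deleted alleles"
    return(out)
  }
  if (copy_number == 1) return(max(s))
  sum(s) + (copy_number - 2) * max(s)
}

#' Default CYP3A base-group rule table
#'
#' Mirrors the combined CYP3A4/CYP3A5 classification used for tacrolimus
#' dose adjustment: CYP3A5 expressors (carrying *1) are extensive
#' metabolizers, CYP3A5 non-expressors with fully functional CYP3A4 are
#' intermediate, and CYP3A4*22 carriers among non-expressors are poor
#' metabolizers.
#'
#' @return data.frame with columns `a5_expressor`, `a4_22_carrier`,
#'   `group`.
#' @export
default_cyp3a_rule <- function() {
  data.frame(a5_expressor = c(TRUE, TRUE, FALSE, FALSE),
             a4_22_carrier = c(FALSE, TRUE, FALSE, TRUE),
             group = c("EM", "EM", "IM", "PM"),
             stringsAsFactors = FALSE)
}

cyp3a_group_levels <- c("PM", "IM", "EM")

#' Combined CYP3A activity group and score
#'
#' Derives the base metabolizer group from the CYP3A4 and CYP3A5
#' diplotypes through a configurable rule table, applies one category
#' increment (capped at EM) for CYP3A7*1C carriers, and maps the group to
#' the score scale PM = 0, IM = 1, EM = 2.
#'
#' @param cyp3a4_diplotype,cyp3a5_diplotype,cyp3a7_diplotype star-allele
#'   pairs for the three genes (any `NA` propagates a no-call).
#' @param rule base-group rule table (see [default_cyp3a_rule()]).
#' @return list with `group` (`"PM"`, `"IM"`, `"EM"`) and `score`.
#' @export
score_cyp3a <- function(cyp3a4_diplotype, cyp3a5_diplotype,
                        cyp3a7_diplotype = c("*1", "*1"),
                        rule = default_cyp3a_rule()) {
  if (anyNA(c(cyp3a4_diplotype, cyp3a5_diplotype, cyp3a7_diplotype)))
    return(list(group = NA_character_, score = NA_real_))
  a5_exp <- any(cyp3a5_diplotype == "*1")
  a4_22 <- any(cyp3a4_diplotype == "*22")
  hit <- rule$group[rule$a5_expressor == a5_exp &
                      rule$a4_22_carrier == a4_22]
  if (!length(hit)) stop("CYP3A rule table does not cover this combination")
  g <- match(hit[1], cyp3a_group_levels)
  if (any(cyp3a7_diplotype == "*1C"))
    g <- min(g + 1L, length(cyp3a_group_levels))
  list(group = cyp3a_group_levels[g], score = g - 1)
}

#' CYP2C9 reduced-allele count
#'
#' CYP2C9 activity is expressed as the number of alleles with reduced
#' activity in the diplotype (by default *2 and *3).
#'
#' @param diplotype character vector of two CYP2C9 star alleles.
#' @param reduced_alleles set of reduced-activity alleles.
#' @return integer count in 0..2 (`NA` for a no-call).
#' @export
score_cyp2c9 <- function(diplotype, reduced_alleles = c("*2", "*3")) {
  if (anyNA(diplotype)) return(NA_integer_)
  sum(diplotype %in% reduced_alleles)
}

#' Apply the CYP1A2 smoking-induction adjustment
#'
#' Smoking induces CYP1A2; the genetic activity score of smokers is
#' multiplied by 1.5 (non-smokers are unchanged). The adjustment is marked
#' on the result and applying it twice is an error.
#'
#' @param score numeric CYP1A2 activity score(s), >= 0.
#' @param smoker logical flag(s), recycled against `score`.
#' @return adjusted score(s) with attribute `smoking_adjusted = TRUE`.
#' @export
adjust_cyp1a2_smoking <- function(score, smoker) {
  if (isTRUE(attr(score, "smoking_adjusted")))
    stop("smoking adjustment already applied")
  stopifnot(all(score >= 0, na.rm = TRUE))
  out <- ifelse(rep_len(smoker, length(score)), score * 1.5, score)
  attr(out, "smoking_adjusted") <- TRUE
  out
}

#' Per-sample activity profiles for all genes of an allele table
#'
#' Runs diplotype assignment and the gene-appropriate scoring rule
#' (additive score; copy-number-aware CYP2D6; reduced-allele count for
#' CYP2C9; combined CYP3A group from CYP3A4/CYP3A5/CYP3A7) over every
#' sample. CYP1A2 smoking induction is applied when `smoker` is supplied.
#'
#' @param gm a [genotype_matrix()] containing the defining variants.
#' @param table an [load_allele_table()] result.
#' @param smoker optional logical vector (per sample) of active smoking.
#' @return data.frame with one row per sample and gene: `sample_id`,
#'   `gene`, `allele1`, `allele2`, `copy_number`, `activity_score`,
#'   `activity_group`, `smoking_adjusted`, `no_call`.
#' @export
cyp_activity_profiles <- function(gm, table = load_allele_table(),
                                  smoker = NULL) {
  genes <- names(table)
  cyp3a_parts <- intersect(c("CYP3A4", "CYP3A5", "CYP3A7"), genes)
  single_genes <- setdiff(genes, cyp3a_parts)
  rows <- list()
  for (s in gm$samples) {
    dip <- lapply(stats::setNames(genes, genes), function(g)
      suppressWarnings(assign_diplotype(gm, s, g, table)))
    for (g in single_genes) {
      d <- dip[[g]]
      score <- if (anyNA(d)) NA_real_
      else if (g == "CYP2D6")
        score_cyp2d6(d, gm$cyp2d6_cn[match(s, gm$samples)], table)
      else if (g == "CYP2C9") score_cyp2c9(d)
      else score_additive_gene(d, g, table)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, gene = g, allele1 = d[1], allele2 = d[2],
        copy_number = if (g == "CYP2D6")
          gm$cyp2d6_cn[match(s, gm$samples)] else NA_integer_,
        activity_score = as.numeric(score),
        activity_group = cyp_group(g, score),
        smoking_adjusted = FALSE, no_call = anyNA(d),
        stringsAsFactors = FALSE)
    }
    if (length(cyp3a_parts) == 3) {
      g3 <- score_cyp3a(dip[["CYP3A4"]], dip[["CYP3A5"]], dip[["CYP3A7"]])
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, gene = "CYP3A",
        allele1 = dip[["CYP3A4"]][1], allele2 = dip[["CYP3A4"]][2],
        copy_number = NA_integer_, activity_score = g3$score,
        activity_group = g3$group %||% NA_character_,
        smoking_adjusted = FALSE, no_call = is.na(g3$score),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(smoker)) {
    idx <- out$gene == "CYP1A2"
    sm <- smoker[match(out$sample_id[idx], gm$samples)]
    out$activity_score[idx] <-
      as.numeric(adjust_cyp1a2_smoking(out$activity_score[idx], sm))
    out$smoking_adjusted[idx] <- TRUE
  }
  out
}

cyp_group <- function(gene, score) {
  if (is.na(score) || gene != "CYP2D6") return(NA_character_)
  if (score == 0) "PM" else if (score < 1) "IM" else "EM"
}

#' Write activity profiles as TSV and JSON
#'
#' @param profiles a [cyp_activity_profiles()] result.
#' @param prefix output path prefix.
#' @return the JSON path, invisibly.
#' @export
write_activity_profiles <- function(profiles, prefix) {
  utils::write.table(profiles, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(profiles, paste0(prefix, ".json"), digits = NA,
                       na = "null")
  invisible(paste0(prefix, ".json"))
}
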