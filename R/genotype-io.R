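#' Read genotype calls from TSV or VCF
#'
#' The TSV dialect is a long table with header
#' `sample_id  variant_id  allele1  allele2`; missing alleles are coded
#' `"."` (both alleles missing makes the call missing). The VCF dialect is a
#' minimal VCF v4.2 reader that uses only the GT field (via the `vcfR`
#' parser); REF is taken as the major and the first ALT as the minor allele
#' before orientation normalization.
#'
#' After reading, allele orientation is normalized so that the minor allele
#' is the rarer allele in the data; ties are broken by the declared
#' `variants` table when supplied, otherwise the declared orientation from
#' the file is kept.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param variants optional `VariantDef` data.frame (columns `variant_id`,
#'   `major_allele`, `minor_allele`, optional `chrom`, `position`,
#'   `extra_allele`) declaring the panel; when `NULL` the panel is inferred
#'   from the data (alleles ordered by decreasing frequency).
#' @param cyp2d6_cn optional per-sample copy-number table
#'   (`sample_id`, `copy_number`).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "vcf"), variants = NULL,
                           cyp2d6_cn = NULL) {
  dialect <- match.arg(dialect)
  gm <- switch(dialect,
               tsv = read_genotypes_tsv(path, variants),
               vcf = read_genotypes_vcf(path, variants))
  if (!is.null(cyp2d6_cn)) {
    idx <- match(gm$samples, cyp2d6_cn$sample_id)
    cn <- cyp2d6_cn$copy_number[idx]
    cn[is.na(cn)] <- 2L
    gm$cyp2d6_cn <- as.integer(cn)
  }
  normalize_orientation(gm)
}

read_genotypes_tsv <- function(path, variants = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "variant_id", "allele1", "allele2")
  if (!all(need %in% names(tab)))
    stop("malformed genotype TSV header: need columns ",
         paste(need, collapse = ", "))
  tab$allele1[tab$allele1 %in% c(".", "")] <- NA
  tab$allele2[tab$allele2 %in% c(".", "")] <- NA
  samples <- unique(tab$sample_id)
  vids <- if (!is.null(variants)) variants$variant_id else
    unique(tab$variant_id)
  calls <- matrix(NA_character_, length(samples), length(vids),
                  dimnames = list(samples, vids))
  known <- tab$variant_id %in% vids
  if (!all(known))
    stop("undeclared variant(s) in TSV: ",
         paste(unique(tab$variant_id[!known]), collapse = ", "))
  ok <- !is.na(tab$allele1) & !is.na(tab$allele2)
  calls[cbind(match(tab$sample_id[ok], samples),
              match(tab$variant_id[ok], vids))] <-
    paste(tab$allele1[ok], tab$allele2[ok], sep = "/")
  if (is.null(variants)) variants <- infer_variant_defs(calls, vids)
  genotype_matrix(calls, variants, samples = samples)
}

## build a VariantDef table from observed alleles: most frequent allele is
## major, next is minor, a third (if any) becomes the extra allele
infer_variant_defs <- function(calls, vids) {
  defs <- lapply(seq_along(vids), function(j) {
    alle <- unlist(strsplit(calls[!is.na(calls[, j]), j], "/", fixed = TRUE))
    tab <- sort(table(alle), decreasing = TRUE)
    a <- names(tab)
    if (length(a) < 1) stop("variant with no calls and no declared alleles: ",
                            vids[j])
    if (length(a) == 1) a <- c(a, "?")
    if (length(a) > 3)
      stop("more than three alleles observed at ", vids[j])
    data.frame(variant_id = vids[j], major_allele = a[1], minor_allele = a[2],
               extra_allele = if (length(a) == 3) a[3] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, defs)
}

read_genotypes_vcf <- function(path, variants = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")
  vids <- fix[, "ID"]
  alt_split <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  samples <- colnames(gt)
  calls <- matrix(NA_character_, length(samples), length(vids),
                  dimnames = list(samples, vids))
  for (j in seq_along(vids)) {
    alleles <- c(fix[j, "REF"], alt_split[[j]])
    g <- gt[j, ]
    ok <- !is.na(g) & !grepl("\\.", g)
    idx <- strsplit(gsub("|", "/", g[ok], fixed = TRUE), "/", fixed = TRUE)
    calls[which(ok), j] <- vapply(idx, function(k)
      paste(alleles[as.integer(k) + 1L], collapse = "/"), character(1))
  }
  if (is.null(variants)) {
    variants <- data.frame(
      variant_id = vids, chrom = fix[, "CHROM"],
      position = as.numeric(fix[, "POS"]),
      major_allele = fix[, "REF"],
      minor_allele = vapply(alt_split, `[`, character(1), 1L),
      extra_allele = vapply(alt_split, function(a)
        if (length(a) > 1) a[2] else NA_character_, character(1)),
      stringsAsFactors = FALSE)
  }
  genotype_matrix(calls, variants, samples = samples)
}

#' Write genotype calls to the long TSV dialect
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  long <- expand.grid(sample_id = gm$samples,
                      variant_id = gm$variants$variant_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  calls <- gm$calls[cbind(match(long$sample_id, gm$samples),
                          match(long$variant_id, gm$variants$variant_id))]
  parts <- strsplit(ifelse(is.na(calls), "./.", calls), "/", fixed = TRUE)
  long$allele1 <- vapply(parts, `[`, character(1), 1L)
  long$allele2 <- vapply(parts, `[`, character(1), 2L)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a minimal VCF v4.2 with GT fields
#'
#' Indel-style alleles coded as `"-"` in the panel are written verbatim;
#' the writer targets round-tripping within this package rather than strict
#' allele normalization against a reference genome.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  for (j in seq_len(nrow(gm$variants))) {
    v <- gm$variants[j, ]
    alleles <- c(v$major_allele, v$minor_allele,
                 if (!is.na(v$extra_allele)) v$extra_allele)
    gts <- vapply(gm$calls[, j], function(cl) {
      if (is.na(cl)) return("./.")
      a <- strsplit(cl, "/", fixed = TRUE)[[1]]
      paste(match(a, alleles) - 1L, collapse = "/")
    }, character(1))
    writeLines(paste(c(ifelse(is.na(v$chrom), ".", v$chrom),
                       ifelse(is.na(v$position), 0, v$position),
                       v$variant_id, v$major_allele,
                       paste(alleles[-1], collapse = ","),
                       ".", "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}
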