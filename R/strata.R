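# APOE x diagnosis x age stratification and per-stratum allele-frequency
# tabulation.

#' APOE e4 allele dosage
#'
#' Counts e4 alleles in APOE genotype strings (`"e3/e4"` style). An e2/e4
#' genotype counts as dosage 1: stratification is by e4 carriage only.
#'
#' @param apoe character vector of genotype strings.
#' @return integer vector in 0..2.
#' @export
e4_dosage <- function(apoe) {
  ok <- grepl("^e[234]/e[234]$", apoe)
  if (any(!ok)) {
    stop("invalid APOE genotype string: '", apoe[which(!ok)[1]], "'",
         call. = FALSE)
  }
  a <- strsplit(apoe, "/", fixed = TRUE)
  vapply(a, function(x) sum(x == "e4"), integer(1))
}

#' Default discovery strata
#'
#' The six frequency-table strata (elderly healthy e4/4, all healthy e4/4,
#' e4/4 AD, elderly healthy e4 het, all healthy e4 het, e4 het AD) plus the
#' e4 non-carrier stratum (dosage 0, any diagnosis). "Elderly" means age at
#' last examination of at least `age_hom` (70) years for homozygotes and
#' `age_het` (80) years for heterozygotes, inclusive. AD strata carry no age
#' floor: case ages are onset ages.
#'
#' @param age_hom,age_het inclusive elderly age thresholds in years.
#' @return data.frame with columns `name`, `e4_dosage`, `diagnosis`, `min_age`.
#' @export
default_strata <- function(age_hom = 70, age_het = 80) {
  data.frame(
    name = c("elderly_healthy_hom", "all_healthy_hom", "hom_AD",
             "elderly_healthy_het", "all_healthy_het", "het_AD",
             "noncarrier"),
    e4_dosage = c(2L, 2L, 2L, 1L, 1L, 1L, 0L),
    diagnosis = c("control", "control", "AD", "control", "control", "AD",
                  NA),
    min_age = c(age_hom, NA, NA, age_het, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Assign samples to strata
#'
#' Maps every sample to every stratum whose predicate it satisfies. Age
#' thresholds are inclusive and applied after flooring ages to whole years
#' ("over the age of 70" counts a 70.4-year-old as 70). Samples with unknown
#' diagnosis are excluded from diagnosis-conditioned strata.
#'
#' @param samples phenotype data.frame (see [read_phenotypes()]).
#' @param defs stratum definitions, as from [default_strata()].
#' @return named list of character vectors of `sample_id`s, one per stratum.
#' @export
assign_strata <- function(samples, defs = default_strata()) {
  if (any(duplicated(defs$name))) {
    stop("stratum names must be distinct", call. = FALSE)
  }
  d4 <- e4_dosage(samples$apoe)
  age <- floor(samples$age)
  out <- vector("list", nrow(defs))
  names(out) <- defs$name
  for (i in seq_len(nrow(defs))) {
    keep <- d4 == defs$e4_dosage[i]
    if (!is.na(defs$diagnosis[i])) {
      keep <- keep & !is.na(samples$diagnosis) &
        samples$diagnosis == defs$diagnosis[i]
    }
    if (!is.na(defs$min_age[i])) {
      keep <- keep & !is.na(age) & age >= defs$min_age[i]
    }
    out[[i]] <- samples$sample_id[keep]
  }
  out
}

#' Allele counts and MAF within one stratum
#'
#' Counts are taken over non-missing genotypes only: `n_genotyped` is the
#' number of stratum members with a called dosage, `n_carriers` the number with
#' dosage >= 1, `alt_alleles` the dosage sum, and
#' `maf = alt_alleles / (2 * n_genotyped)`. With no genotyped members the MAF
#' is undefined and reported as `NA`, not 0.
#'
#' @param variant_id row name into `calls`.
#' @param calls post-QC [genotype_calls()].
#' @param members character vector of sample ids in the stratum.
#' @param stratum optional stratum label carried into the output.
#' @return one-row data.frame (`variant_id`, `stratum`, `n_genotyped`,
#'   `n_carriers`, `alt_alleles`, `maf`).
#' @export
stratum_allele_counts <- function(variant_id, calls, members,
                                  stratum = NA_character_) {
  dos <- calls$dosage[variant_id, intersect(members, colnames(calls$dosage))]
  dos <- dos[!is.na(dos)]
  n <- length(dos)
  alt <- sum(dos)
  data.frame(
    variant_id = variant_id,
    stratum = stratum,
    n_genotyped = n,
    n_carriers = sum(dos >= 1L),
    alt_alleles = alt,
    maf = if (n > 0L) alt / (2 * n) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Per-variant stratum frequency table
#'
#' One row per variant per cohort carrying the six stratum MAFs (as percents,
#' rounded to 2 decimals) of the discovery frequency table, ordered by
#' (cohort, chrom, pos).
#'
#' @param variants variant/annotation data.frame with `variant_id`, `chrom`,
#'   `pos` (and optionally `gene`).
#' @param samples phenotype data.frame.
#' @param calls post-QC [genotype_calls()].
#' @param defs stratum definitions ([default_strata()]).
#' @return data.frame with `cohort`, `variant_id`, `gene`, and one `maf_*`
#'   percent column per non-noncarrier stratum.
#' @export
frequency_table <- function(variants, samples, calls,
                            defs = default_strata()) {
  freq_strata <- defs$name[defs$name != "noncarrier"]
  cohorts <- sort(unique(samples$cohort))
  rows <- list()
  for (co in cohorts) {
    sm <- samples[samples$cohort == co, , drop = FALSE]
    members <- assign_strata(sm, defs)
    for (i in seq_len(nrow(variants))) {
      vid <- variants$variant_id[i]
      mafs <- vapply(freq_strata, function(s) {
        stratum_allele_counts(vid, calls, members[[s]])$maf
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = co,
        variant_id = vid,
        gene = if ("gene" %in% names(variants)) variants$gene[i] else NA,
        chrom = variants$chrom[i],
        pos = variants$pos[i],
        t(round(100 * mafs, 2)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:5)] <- paste0("maf_", freq_strata)
  out <- out[order(out$cohort, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
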