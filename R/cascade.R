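# The segregation cascade: ordered filters selecting rare coding variants that
# are carried by cognitively unaffected elderly e4 carriers, absent in e4
# non-carriers, and (preferentially) absent in e4-carrier AD cases.

#' Cascade configuration
#'
#' @param min_elderly_hom_carrier_fraction minimum fraction of genotyped
#'   elderly healthy e4/4 individuals that must carry the variant (default 1%).
#' @param require_het_support if `TRUE` (default), require at least one carrier
#'   among elderly healthy e4 heterozygotes.
#' @param case_absence_mode how presence in e4-carrier AD cases is used:
#'   `"rank_only"` (default) keeps all candidates and uses case absence for
#'   tier ranking (tier 1 = absent in all e4 AD, tier 2 = absent in e4/4 AD
#'   only, tier 3 = otherwise); `"hard_hom_AD_only"` drops candidates seen in
#'   any e4/4 AD case; `"hard_all_e4_AD"` drops candidates seen in any
#'   e4-carrier AD case. Case absence is a prioritization signal in the
#'   screen's design: with a strongly protective but non-deterministic effect,
#'   carriers can still develop AD, so ranking is the default.
#' @param per_cohort run the cascade independently per cohort and also report
#'   the intersection (default `TRUE`); `FALSE` pools all samples.
#' @return list of class `cascade_config`.
#' @export
cascade_config <- function(min_elderly_hom_carrier_fraction = 0.01,
                           require_het_support = TRUE,
                           case_absence_mode = c("rank_only",
                                                 "hard_hom_AD_only",
                                                 "hard_all_e4_AD"),
                           per_cohort = TRUE) {
  stopifnot(min_elderly_hom_carrier_fraction >= 0,
            min_elderly_hom_carrier_fraction <= 1)
  structure(list(
    min_elderly_hom_carrier_fraction = min_elderly_hom_carrier_fraction,
    require_het_support = isTRUE(require_het_support),
    case_absence_mode = match.arg(case_absence_mode),
    per_cohort = isTRUE(per_cohort)
  ), class = "cascade_config")
}

count_carriers <- function(variant_id, calls, members) {
  dos <- calls$dosage[variant_id, intersect(members, colnames(calls$dosage))]
  dos <- dos[!is.na(dos)]
  c(n_genotyped = length(dos), n_carriers = sum(dos >= 1L),
    alt_alleles = sum(dos))
}

#' Is a variant absent from all e4 non-carriers?
#'
#' `TRUE` iff the alt allele count is zero among all genotyped samples with e4
#' dosage 0, regardless of diagnosis or age.
#'
#' @param variant_id row name into `calls`.
#' @param calls post-QC [genotype_calls()].
#' @param noncarriers sample ids of the e4 non-carrier stratum.
#' @return logical.
#' @export
noncarrier_absence <- function(variant_id, calls, noncarriers) {
  unname(count_carriers(variant_id, calls, noncarriers)["alt_alleles"] == 0L)
}

#' Carrier fraction among elderly healthy e4/4 individuals
#'
#' Fraction of genotyped stratum members carrying at least one copy
#' (individual-level, not allele-level). Undefined (`NA`) for an empty
#' stratum, which fails the gate.
#'
#' @inheritParams noncarrier_absence
#' @param members sample ids of the elderly healthy e4/4 stratum.
#' @return numeric fraction in \[0, 1\] or `NA`.
#' @export
elderly_hom_carrier_fraction <- function(variant_id, calls, members) {
  cc <- count_carriers(variant_id, calls, members)
  if (cc["n_genotyped"] == 0L) return(NA_real_)
  unname(cc["n_carriers"] / cc["n_genotyped"])
}

#' Case-absence flags
#'
#' @inheritParams noncarrier_absence
#' @param strata membership map from [assign_strata()] over definitions that
#'   include `hom_AD` and `het_AD`.
#' @return named logical vector `(absent_in_hom_AD, absent_in_all_e4_AD)`.
#' @export
case_absence_flags <- function(variant_id, calls, strata) {
  hom_ad <- count_carriers(variant_id, calls, strata$hom_AD)["alt_alleles"] == 0L
  het_ad <- count_carriers(variant_id, calls, strata$het_AD)["alt_alleles"] == 0L
  c(absent_in_hom_AD = unname(hom_ad),
    absent_in_all_e4_AD = unname(hom_ad && het_ad))
}

run_cascade_one <- function(variants, samples, calls, config, defs) {
  strata <- assign_strata(samples, defs)
  required <- c("elderly_healthy_hom", "noncarrier",
                if (config$require_het_support) "elderly_healthy_het")
  for (s in required) {
    if (length(strata[[s]]) == 0L) {
      stop("cascade aborted: no samples in required stratum '", s, "'",
           call. = FALSE)
    }
  }
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    vid <- variants$variant_id[i]
    if (!vid %in% rownames(calls$dosage)) next
    if (!noncarrier_absence(vid, calls, strata$noncarrier)) next
    frac <- elderly_hom_carrier_fraction(vid, calls,
                                         strata$elderly_healthy_hom)
    if (is.na(frac) || frac < config$min_elderly_hom_carrier_fraction) next
    het_cc <- count_carriers(vid, calls, strata$elderly_healthy_het)
    het_support <- unname(het_cc["n_carriers"] >= 1L)
    if (config$require_het_support && !het_support) next
    flags <- case_absence_flags(vid, calls, strata)
    if (config$case_absence_mode == "hard_hom_AD_only" &&
        !flags["absent_in_hom_AD"]) next
    if (config$case_absence_mode == "hard_all_e4_AD" &&
        !flags["absent_in_all_e4_AD"]) next
    tier <- if (flags["absent_in_all_e4_AD"]) 1L
            else if (flags["absent_in_hom_AD"]) 2L else 3L
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = vid,
      gene = if ("gene" %in% names(variants)) variants$gene[i] else NA,
      chrom = variants$chrom[i],
      pos = variants$pos[i],
      elderly_hom_fraction = frac,
      absent_in_noncarriers = TRUE,
      het_support = het_support,
      absent_in_hom_AD = unname(flags["absent_in_hom_AD"]),
      absent_in_all_e4_AD = unname(flags["absent_in_all_e4_AD"]),
      tier = tier,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(variant_id = character(0), gene = character(0),
                      chrom = character(0), pos = integer(0),
                      elderly_hom_fraction = numeric(0),
                      absent_in_noncarriers = logical(0),
                      het_support = logical(0),
                      absent_in_hom_AD = logical(0),
                      absent_in_all_e4_AD = logical(0),
                      tier = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$tier, -out$elderly_hom_fraction, out$chrom, out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the segregation cascade
#'
#' Pipeline order: (1) absence in e4 non-carriers; (2) carrier fraction among
#' elderly healthy e4/4 at or above the threshold; (3) at least one carrier
#' among elderly healthy e4 heterozygotes, if required; (4) case absence,
#' applied as a hard filter or as tier ranking per
#' `config$case_absence_mode`. Candidates are sorted by (tier, descending
#' elderly-hom carrier fraction, chrom, pos).
#'
#' Inputs are expected to be QC'd ([apply_genotype_qc()]) and pre-filtered for
#' rarity and consequence ([filter_by_reference_af()],
#' [filter_by_consequence()]).
#'
#' @param variants annotation data.frame of the variants to screen.
#' @param samples phenotype data.frame.
#' @param calls post-QC [genotype_calls()].
#' @param config a [cascade_config()].
#' @param defs stratum definitions ([default_strata()]).
#' @return In pooled mode, the candidate data.frame. In per-cohort mode
#'   (default), a list of class `cascade_result` with `per_cohort` (named list
#'   of candidate data.frames), `intersection` (variant ids present in every
#'   cohort's candidates) and `candidates` (union table with a `cohort`
#'   column).
#' @export
run_cascade <- function(variants, samples, calls,
                        config = cascade_config(),
                        defs = default_strata()) {
  if (!config$per_cohort || length(unique(samples$cohort)) == 1L) {
    res <- run_cascade_one(variants, samples, calls, config, defs)
    if (!config$per_cohort) return(res)
    co <- unique(samples$cohort)[1]
    out <- list(per_cohort = stats::setNames(list(res), co),
                intersection = res$variant_id,
                candidates = if (nrow(res)) cbind(cohort = co, res)
                             else cbind(cohort = character(0), res))
    class(out) <- "cascade_result"
    return(out)
  }
  cohorts <- sort(unique(samples$cohort))
  per <- lapply(cohorts, function(co) {
    sm <- samples[samples$cohort == co, , drop = FALSE]
    run_cascade_one(variants, sm, calls, config, defs)
  })
  names(per) <- cohorts
  out <- list(
    per_cohort = per,
    intersection = Reduce(intersect, lapply(per, `[[`, "variant_id")),
    candidates = do.call(rbind, lapply(cohorts, function(co) {
      if (nrow(per[[co]])) cbind(cohort = co, per[[co]])
      else cbind(cohort = character(0), per[[co]])
    }))
  )
  class(out) <- "cascade_result"
  out
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  for (co in names(x$per_cohort)) {
    cat(sprintf("  %s: %d candidate(s)\n", co, nrow(x$per_cohort[[co]])))
  }
  cat(sprintf("  intersection: %d variant(s)\n", length(x$intersection)))
  invisible(x)
}
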