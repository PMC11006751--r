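#' Configuration for the synthetic family-cohort generator
#'
#' Builds and validates the parameter set that [simulate_cohort()] uses to
#' generate a family-based case-control cohort with Mendelian APOE and
#' rare-variant transmission, an e4-dosage-dependent AD liability model, a
#' planted protective effect among e4 carriers, and sequencing-quality
#' artifacts.
#'
#' The disease model is
#' \deqn{P(AD) = \mathrm{logit}^{-1}\{\mathrm{logit}(b_d) + k \ln(\mathrm{OR}) \cdot 1[d \ge 1]\}}
#' where \eqn{d} is the e4 allele dosage, \eqn{b_d} the baseline risk for that
#' dosage, and \eqn{k} the protective-allele dosage. Cases receive an age at
#' onset \eqn{N(\mu_d + k\delta, \sigma^2)}; controls receive a censoring age
#' (age at last examination) drawn uniformly from `censor_age_range`.
#'
#' By default the planted protective variant is seeded only in e4/4 founders at
#' a conditional allele frequency `protective_af / P(e4/4)`, so that its
#' population-scale founder frequency equals `protective_af` while every
#' descendant carrier is an e4 carrier (an e4/4 parent always transmits an e4
#' allele). This emulates the co-segregation with e4 that the discovery screen
#' exploits; transmission itself is unlinked. Set `plant_in_e4_hom = FALSE` for
#' unrestricted Hardy-Weinberg seeding across all founders.
#'
#' @param seed integer root seed; per-family substreams are derived from it so
#'   results do not depend on the order families are generated in.
#' @param n_families number of two-generation families (founder couple plus
#'   offspring).
#' @param offspring_range integer min/max of the uniform offspring count per
#'   family.
#' @param apoe_allele_freqs named probabilities over `c(e2, e3, e4)`; must sum
#'   to 1. The default is enriched for e4, as in multiplex AD family studies.
#' @param protective_af founder allele frequency of the planted protective
#'   variant, on the population scale (must be < 0.01 by default to stay in the
#'   rare regime the screen targets).
#' @param protective_or multiplicative odds effect per protective allele among
#'   e4 carriers; the planted default is 0.29.
#' @param plant_protective logical; plant the protective variant at all?
#' @param plant_in_e4_hom logical; seed the planted variant only in e4/4
#'   founders (default) or across all founders.
#' @param baseline_risk_by_dosage AD probability at reference age for e4 dosage
#'   0/1/2.
#' @param aao_mean_by_dosage mean age at onset (years) for e4 dosage 0/1/2.
#' @param aao_delay_per_allele years of onset delay per protective allele; the
#'   planted default is 3.37.
#' @param aao_sd standard deviation (years) of age at onset.
#' @param censor_age_range uniform range (years) for control censoring ages.
#' @param n_background number of neutral background rare sites (negatives for
#'   the cascade to reject).
#' @param background_af_range founder allele-frequency range for background
#'   sites; a fraction of sites are given reference AF >= 1% so the rarity
#'   filter has something to remove.
#' @param mean_depth mean sequencing depth (reads); DP is Poisson with this
#'   mean, truncated so that non-degraded calls pass DP >= 10.
#' @param gq_mean,gq_sd normal parameters for the genotype-quality (GQ)
#'   distribution, truncated to \[20, 99\] for non-degraded calls.
#' @param qc_fail_fraction fraction of genotype calls degraded below the
#'   GQ >= 20 / DP >= 10 thresholds (by lowering GQ and/or DP, never by
#'   deleting the call, so the QC filter itself is exercised).
#' @param ascertainment_min_affected optional family ascertainment: if > 0,
#'   families are resampled until at least this many members have AD
#'   (default 0 = no ascertainment filter).
#' @param cohort_name,ancestry labels written to the phenotype table.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 350L,
                       offspring_range = c(2L, 5L),
                       apoe_allele_freqs = c(e2 = 0.05, e3 = 0.65, e4 = 0.30),
                       protective_af = 0.008,
                       protective_or = 0.29,
                       plant_protective = TRUE,
                       plant_in_e4_hom = TRUE,
                       baseline_risk_by_dosage = c(0.15, 0.45, 0.60),
                       aao_mean_by_dosage = c(78, 74, 70),
                       aao_delay_per_allele = 3.37,
                       aao_sd = 6,
                       censor_age_range = c(65, 95),
                       n_background = 200L,
                       background_af_range = c(5e-4, 9e-3),
                       mean_depth = 30,
                       gq_mean = 65,
                       gq_sd = 15,
                       qc_fail_fraction = 0.05,
                       ascertainment_min_affected = 0L,
                       cohort_name = "SIM",
                       ancestry = "synthetic") {
  cfg <- list(
    seed = as.integer(seed),
    n_families = as.integer(n_families),
    offspring_range = as.integer(offspring_range),
    apoe_allele_freqs = apoe_allele_freqs,
    protective_af = protective_af,
    protective_or = protective_or,
    plant_protective = isTRUE(plant_protective),
    plant_in_e4_hom = isTRUE(plant_in_e4_hom),
    baseline_risk_by_dosage = baseline_risk_by_dosage,
    aao_mean_by_dosage = aao_mean_by_dosage,
    aao_delay_per_allele = aao_delay_per_allele,
    aao_sd = aao_sd,
    censor_age_range = censor_age_range,
    n_background = as.integer(n_background),
    background_af_range = background_af_range,
    mean_depth = mean_depth,
    gq_mean = gq_mean,
    gq_sd = gq_sd,
    qc_fail_fraction = qc_fail_fraction,
    ascertainment_min_affected = as.integer(ascertainment_min_affected),
    cohort_name = cohort_name,
    ancestry = ancestry
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  f <- cfg$apoe_allele_freqs
  if (length(f) != 3L || is.null(names(f)) ||
      !setequal(names(f), c("e2", "e3", "e4"))) {
    stop("apoe_allele_freqs must be named probabilities over e2, e3, e4",
         call. = FALSE)
  }
  if (any(f < 0) || any(f > 1) || abs(sum(f) - 1) > 1e-8) {
    stop("apoe_allele_freqs must be in [0,1] and sum to 1", call. = FALSE)
  }
  cfg$apoe_allele_freqs <- f[c("e2", "e3", "e4")]
  if (cfg$protective_af < 0 || cfg$protective_af > 1) {
    stop("protective_af must be in [0,1]", call. = FALSE)
  }
  if (cfg$protective_or <= 0) stop("protective_or must be > 0", call. = FALSE)
  if (cfg$aao_sd <= 0) stop("aao_sd must be > 0", call. = FALSE)
  stopifnot(
    length(cfg$offspring_range) == 2L,
    cfg$offspring_range[1] >= 0L,
    cfg$offspring_range[1] <= cfg$offspring_range[2],
    length(cfg$baseline_risk_by_dosage) == 3L,
    all(cfg$baseline_risk_by_dosage > 0 & cfg$baseline_risk_by_dosage < 1),
    length(cfg$aao_mean_by_dosage) == 3L,
    length(cfg$censor_age_range) == 2L,
    cfg$censor_age_range[1] > 0,
    cfg$censor_age_range[1] <= cfg$censor_age_range[2],
    cfg$qc_fail_fraction >= 0, cfg$qc_fail_fraction <= 1,
    cfg$mean_depth > 0, cfg$n_families >= 1L, cfg$n_background >= 0L
  )
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d families, %d-%d offspring, seed %d\n",
              x$n_families, x$offspring_range[1], x$offspring_range[2], x$seed))
  cat(sprintf("  APOE allele freqs: e2=%.2f e3=%.2f e4=%.2f\n",
              x$apoe_allele_freqs["e2"], x$apoe_allele_freqs["e3"],
              x$apoe_allele_freqs["e4"]))
  cat(sprintf("  planted protective variant: %s (AF %.4f, OR %.2f, AAO delay %.2f y)\n",
              if (x$plant_protective) "yes" else "no",
              x$protective_af, x$protective_or, x$aao_delay_per_allele))
  cat(sprintf("  %d background sites; depth %g x; QC-fail fraction %.2f\n",
              x$n_background, x$mean_depth, x$qc_fail_fraction))
  invisible(x)
}
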