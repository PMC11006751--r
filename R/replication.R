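# Replication-layer statistics: carrier-based effect-allele frequencies, 2x2
# and logistic association, SE recovery from printed confidence intervals,
# fixed-effects inverse-variance-weighted meta-analysis with Cochran's Q, and
# age-at-onset regression.

Z95 <- 1.959964  # fixed 97.5% normal quantile for bit-stable 95% CI round-trips

#' Effect-allele frequency from carrier counts
#'
#' In the rare-variant regime carriers are assumed single-copy unless stated,
#' so `EAF% = 100 * n_carriers * copies_per_carrier / (2 * n_total)`.
#'
#' @param n_carriers,n_total carrier and sample counts.
#' @param copies_per_carrier allele copies per carrier (default 1).
#' @return percent.
#' @export
eaf_from_carrier_counts <- function(n_carriers, n_total,
                                    copies_per_carrier = 1) {
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  stopifnot(all(n_carriers >= 0), all(n_carriers <= n_total))
  100 * (n_carriers * copies_per_carrier) / (2 * n_total)
}

#' Odds ratio from a 2x2 carrier table
#'
#' Cross-product odds ratio for AD given carrier status, with a Wald CI on the
#' log scale and a two-sided Wald p-value. If any cell is zero the
#' Haldane-Anscombe correction (0.5 added to every cell) is applied.
#'
#' @param cn_carriers,cn_noncarriers control counts.
#' @param ad_carriers,ad_noncarriers case counts.
#' @param level CI level (default 0.95).
#' @return list `(or, log_or, se, ci_low, ci_high, p, corrected)`.
#' @export
odds_ratio_2x2 <- function(cn_carriers, cn_noncarriers,
                           ad_carriers, ad_noncarriers, level = 0.95) {
  cells <- c(cn_carriers, cn_noncarriers, ad_carriers, ad_noncarriers)
  stopifnot(all(cells >= 0))
  if ((cn_carriers + ad_carriers) == 0 && (cn_noncarriers + ad_noncarriers) == 0 ||
      (cn_carriers + cn_noncarriers) == 0 || (ad_carriers + ad_noncarriers) == 0) {
    stop("degenerate 2x2 table: an empty margin", call. = FALSE)
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  log_or <- log((c * b) / (a * d))   # odds of AD in carriers vs non-carriers
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- if (level == 0.95) Z95 else stats::qnorm((1 + level) / 2)
  list(or = exp(log_or), log_or = log_or, se = se,
       ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
       p = 2 * stats::pnorm(-abs(log_or / se)), corrected = corrected)
}

#' Standard error of a log odds ratio from its printed CI
#'
#' `se = (ln(ci_high) - ln(ci_low)) / (2 * z)` with `z = 1.959964` at the 95%
#' level; used to meta-analyze published estimates when only OR and CI are
#' printed.
#'
#' @param ci_low,ci_high positive CI bounds on the OR scale.
#' @param level CI level (default 0.95).
#' @return standard error on the log-OR scale.
#' @export
se_from_ci <- function(ci_low, ci_high, level = 0.95) {
  if (any(ci_low <= 0) || any(ci_high <= 0)) {
    stop("CI bounds must be positive", call. = FALSE)
  }
  if (any(ci_high < ci_low)) stop("ci_high must exceed ci_low", call. = FALSE)
  z <- if (level == 0.95) Z95 else stats::qnorm((1 + level) / 2)
  (log(ci_high) - log(ci_low)) / (2 * z)
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Pools log odds ratios with weights `w_i = se_i^-2`:
#' `pooled = sum(w * theta) / sum(w)`, `pooled_se = sum(w)^-1/2`, two-sided
#' normal p-value, and Cochran's heterogeneity statistic
#' `Q = sum(w * (theta - pooled)^2)` referred to a chi-square with k-1 df.
#'
#' @param log_or numeric vector of per-study log odds ratios.
#' @param se per-study standard errors (> 0).
#' @param labels optional study labels.
#' @return list of class `meta_result`: `pooled_log_or`, `pooled_se`, `or`,
#'   `ci_low`, `ci_high`, `z`, `p`, `cochran_q`, `q_df`, `q_p`, `studies`.
#' @export
ivw_meta <- function(log_or, se, labels = NULL) {
  if (length(log_or) == 0L) stop("no estimates to pool", call. = FALSE)
  stopifnot(length(log_or) == length(se), all(se > 0))
  w <- se^-2
  pooled <- sum(w * log_or) / sum(w)
  pooled_se <- sum(w)^-0.5
  z <- pooled / pooled_se
  q <- sum(w * (log_or - pooled)^2)
  q_df <- length(log_or) - 1L
  out <- list(
    pooled_log_or = pooled, pooled_se = pooled_se,
    or = exp(pooled),
    ci_low = exp(pooled - Z95 * pooled_se),
    ci_high = exp(pooled + Z95 * pooled_se),
    z = z, p = 2 * stats::pnorm(-abs(z)),
    cochran_q = q, q_df = q_df,
    q_p = if (q_df > 0L) stats::pchisq(q, q_df, lower.tail = FALSE) else NA_real_,
    studies = data.frame(
      label = if (is.null(labels)) paste0("study", seq_along(log_or)) else labels,
      log_or = log_or, se = se, weight = w / sum(w))
  )
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> OR = %.3f [%.3f, %.3f], p = %.3g (k = %d)\n",
              x$or, x$ci_low, x$ci_high, x$p, nrow(x$studies)))
  cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n",
              x$cochran_q, x$q_df, x$q_p))
  invisible(x)
}

#' Logistic case-control association
#'
#' Maximum-likelihood logistic regression of disease status on allele dosage
#' (plus optional covariates); reports the per-allele odds ratio with a Wald
#' CI. With no covariates the slope equals the log of the 2x2 allele-dosage
#' odds ratio. Complete separation is flagged and the CI reported as
#' unbounded.
#'
#' @param status 0/1 (or logical, or "AD"/"control") disease indicator.
#' @param allele_dosage numeric dosage vector.
#' @param covariates optional data.frame of covariates.
#' @param level CI level.
#' @return list `(or, log_or, se, ci_low, ci_high, p, separation, fit)`.
#' @export
logistic_assoc <- function(status, allele_dosage, covariates = NULL,
                           level = 0.95) {
  if (is.character(status)) status <- as.integer(status == "AD")
  status <- as.integer(status)
  stopifnot(all(status %in% 0:1))
  if (length(unique(status)) < 2L) {
    stop("need at least one case and one control", call. = FALSE)
  }
  if (length(unique(allele_dosage)) < 2L) {
    stop("allele dosage is constant; slope undefined", call. = FALSE)
  }
  dat <- data.frame(.status = status, .dosage = allele_dosage)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.status ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (any(is.na(stats::coef(fit)))) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  est <- summary(fit)$coefficients[".dosage", ]
  beta <- est["Estimate"]; se <- est["Std. Error"]
  if (!sep && abs(beta) > 15) sep <- TRUE   # quasi-separation guard
  z <- if (level == 0.95) Z95 else stats::qnorm((1 + level) / 2)
  list(
    or = exp(unname(beta)), log_or = unname(beta), se = unname(se),
    ci_low = if (sep) 0 else exp(unname(beta - z * se)),
    ci_high = if (sep) Inf else exp(unname(beta + z * se)),
    p = unname(est["Pr(>|z|)"]),
    separation = sep, fit = fit
  )
}

#' Age-at-onset regression
#'
#' Ordinary least squares of age at onset on protective-allele dosage (plus
#' optional covariates), among cases only. The per-allele coefficient is the
#' onset delay in years per copy.
#'
#' @param ages_at_onset numeric vector (cases only).
#' @param allele_dosage numeric dosage vector.
#' @param covariates optional data.frame of covariates.
#' @param level CI level.
#' @return list of class `aao_fit`: `beta_per_allele`, `se`, `ci_low`,
#'   `ci_high`, `p`, `covariate_estimates`, `fit`.
#' @export
aao_regression <- function(ages_at_onset, allele_dosage, covariates = NULL,
                           level = 0.95) {
  if (length(unique(allele_dosage)) < 2L) {
    stop("need at least two distinct dosage values", call. = FALSE)
  }
  dat <- data.frame(.aao = ages_at_onset, .dosage = allele_dosage)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- stats::lm(.aao ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design", call. = FALSE)
  }
  est <- summary(fit)$coefficients
  beta <- est[".dosage", "Estimate"]; se <- est[".dosage", "Std. Error"]
  tq <- stats::qt((1 + level) / 2, df = fit$df.residual)
  out <- list(
    beta_per_allele = beta, se = se,
    ci_low = beta - tq * se, ci_high = beta + tq * se,
    p = est[".dosage", "Pr(>|t|)"],
    covariate_estimates = est[setdiff(rownames(est), ".dosage"), , drop = FALSE],
    fit = fit
  )
  class(out) <- "aao_fit"
  out
}

#' @export
print.aao_fit <- function(x, ...) {
  cat(sprintf("<aao_fit> %.2f years/allele [%.2f, %.2f], p = %.3g\n",
              x$beta_per_allele, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Published replication carrier counts
#'
#' The per-cohort carrier counts and printed per-cohort odds ratios and
#' confidence intervals from the published replication of the protective FN1
#' variant (rs140926439) in APOE e4/4 carriers aged 60+: controls (CN) and AD
#' cases per cohort (ADGC, ADSP, UKB), plus the combined row. The printed ORs
#' are covariate-adjusted, so they are carried as data for meta-analysis, not
#' recomputed here.
#'
#' @return data.frame with columns `cohort`, `cn_carriers`, `cn_total`,
#'   `ad_carriers`, `ad_total`, `or`, `ci_low`, `ci_high`.
#' @export
fn1_replication_counts <- function() {
  data.frame(
    cohort = c("ADGC", "ADSP", "UKB", "Combined"),
    cn_carriers = c(4L, 1L, 54L, 59L),
    cn_total = c(129L, 81L, 4804L, 5014L),
    ad_carriers = c(9L, 2L, 3L, 14L),
    ad_total = c(1381L, 275L, 515L, 2171L),
    or = c(0.12, 0.42, 0.54, 0.29),
    ci_low = c(0.03, 0.02, 0.14, 0.11),
    ci_high = c(0.58, 10.2, 2.08, 0.78),
    stringsAsFactors = FALSE
  )
}
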