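# Group-comparison and regression statistics for per-vessel immunofluorescence
# quantification: heteroscedastic ANOVAs, two-stage BKY FDR, Kruskal-Wallis
# with Dunn's pairwise test, Kolmogorov-Smirnov, percent change, and
# intensity-versus-diameter regression.

check_groups <- function(groups, min_n = 2L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- vapply(groups, length, integer(1))
  if (any(n < min_n)) {
    stop("every group needs at least ", min_n, " observations", call. = FALSE)
  }
  invisible(n)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F with Satterthwaite-type denominator degrees of freedom
#' (equal variances not assumed). With two groups, F equals the squared Welch
#' t statistic.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list `(statistic, df1, df2, p)`.
#' @export
welch_anova <- function(groups) {
  check_groups(groups)
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("all groups have zero variance; Welch ANOVA undefined", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- stats::oneway.test(x ~ g, var.equal = FALSE)
  list(statistic = unname(ft$statistic),
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
       p = unname(ft$p.value))
}

#' Brown-Forsythe one-way ANOVA
#'
#' The Brown-Forsythe modified F statistic
#' \deqn{F^* = \sum_i n_i(\bar x_i - \bar x)^2 / \sum_i (1 - n_i/N) s_i^2,}
#' with numerator df k-1 and Satterthwaite denominator df
#' \eqn{1/f = \sum_i c_i^2/(n_i - 1)} where
#' \eqn{c_i = (1 - n_i/N)s_i^2 / \sum_j (1 - n_j/N)s_j^2}. Under equal
#' variances and large samples it approaches the classical one-way F.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list `(statistic, df1, df2, p)`.
#' @export
brown_forsythe_anova <- function(groups) {
  n <- check_groups(groups)
  s2 <- vapply(groups, stats::var, numeric(1))
  if (all(s2 == 0)) {
    stop("all groups have zero variance; Brown-Forsythe ANOVA undefined",
         call. = FALSE)
  }
  k <- length(groups)
  N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  grand <- sum(n * m) / N
  denom_terms <- (1 - n / N) * s2
  fstar <- sum(n * (m - grand)^2) / sum(denom_terms)
  ci <- denom_terms / sum(denom_terms)
  df2 <- 1 / sum(ci^2 / (n - 1))
  df1 <- k - 1
  list(statistic = fstar, df1 = df1, df2 = df2,
       p = stats::pf(fstar, df1, df2, lower.tail = FALSE))
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' Adaptive linear step-up FDR control. Stage 1 runs Benjamini-Hochberg at
#' `q' = q / (1 + q)`, yielding `r1` rejections; if `r1` is 0 or m the answer
#' is final. Otherwise the null count is estimated as `m0 = m - r1` and stage 2
#' runs BH at `q' * m / m0`; stage 2's rejections are returned. Adjusted
#' values are `(m0/m) * p_BH` (compared to `q'` for rejection), monotone by
#' construction of BH.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param q target FDR level (default 0.05).
#' @return list `(rejected, adjusted, r1, m0, q_threshold)`; `rejected` is a
#'   logical vector aligned with `pvalues`.
#' @export
bky_two_stage <- function(pvalues, q = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1), q > 0, q < 1)
  m <- length(pvalues)
  qp <- q / (1 + q)
  bh <- stats::p.adjust(pvalues, method = "BH")
  r1 <- sum(bh <= qp)
  if (r1 == 0L) {
    return(list(rejected = rep(FALSE, m), adjusted = pmin(1, bh),
                r1 = r1, m0 = m, q_threshold = qp))
  }
  if (r1 == m) {
    return(list(rejected = rep(TRUE, m), adjusted = numeric(m),
                r1 = r1, m0 = 0L, q_threshold = qp))
  }
  m0 <- m - r1
  adjusted <- pmin(1, (m0 / m) * bh)
  list(rejected = adjusted <= qp, adjusted = adjusted,
       r1 = r1, m0 = m0, q_threshold = qp)
}

#' Kruskal-Wallis test with Dunn's pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H, followed by Dunn's z statistics on mean
#' ranks for every pair of groups, with Bonferroni-adjusted two-sided
#' p-values.
#'
#' @param groups named (or unnamed) list of numeric vectors.
#' @return list `(H, df, p, pairwise)` where `pairwise` is a data.frame with
#'   `group1`, `group2`, `z`, `p`, `p_adjusted`.
#' @export
kruskal_dunn <- function(groups) {
  check_groups(groups, min_n = 1L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1L) {
    kw <- list(statistic = 0, parameter = length(groups) - 1L, p.value = 1)
  } else {
    kt <- stats::kruskal.test(x, g)
    kw <- list(statistic = unname(kt$statistic),
               parameter = unname(kt$parameter), p.value = kt$p.value)
  }
  # Dunn's z on mean ranks with tie correction
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2L)
  pw <- apply(pairs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    sd_ij <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z <- if (sd_ij > 0) (rbar[[i]] - rbar[[j]]) / sd_ij else 0
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  pairwise <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = pw["z", ], p = pw["p", ],
    p_adjusted = pmin(1, pw["p", ] * ncol(pairs)),
    stringsAsFactors = FALSE
  )
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pairwise)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test (exact where sample sizes permit, asymptotic otherwise).
#'
#' @param a,b numeric samples.
#' @return list `(D, p)`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Percent change relative to a reference mean
#'
#' @param mean_test,mean_ref group means; `mean_ref` must be nonzero.
#' @return `100 * (mean_test - mean_ref) / mean_ref`.
#' @export
percent_change <- function(mean_test, mean_ref) {
  if (any(mean_ref == 0)) stop("reference mean is zero", call. = FALSE)
  100 * (mean_test - mean_ref) / mean_ref
}

#' Validate per-vessel measurement records
#'
#' Drops vessels wider than `max_diameter` (default 50 um, the acquisition
#' rule) and checks fields.
#'
#' @param records data.frame with at least `diameter` and `intensity`
#'   (optionally `subject_id`, `group`, `marker`).
#' @param max_diameter exclusion threshold in um.
#' @return the filtered data.frame.
#' @export
vessel_records <- function(records, max_diameter = 50) {
  stopifnot(all(c("diameter", "intensity") %in% names(records)))
  if (any(records$diameter <= 0)) {
    stop("vessel diameters must be positive", call. = FALSE)
  }
  if (any(records$intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  records[records$diameter <= max_diameter, , drop = FALSE]
}

#' Intensity-versus-diameter regression
#'
#' Ordinary least squares of marker intensity on vessel diameter, either a
#' simple line or an unweighted second-order polynomial. Reports the slope,
#' R-squared, adjusted R-squared (`1 - (1 - R2)(n - 1)/(n - k - 1)`), and the
#' t-test p-value for a nonzero (linear) slope.
#'
#' @param records data.frame with `diameter` and `intensity`.
#' @param model `"linear"` or `"quadratic"`.
#' @return list of class `regression_fit`: `slope`, `intercept`, `quadratic`
#'   (NA for linear), `r_squared`, `adj_r_squared`, `slope_p`, `n`, `fit`.
#' @export
fit_intensity_vs_diameter <- function(records, model = c("linear", "quadratic")) {
  model <- match.arg(model)
  x <- records$diameter
  y <- records$intensity
  min_n <- if (model == "linear") 3L else 4L
  if (length(x) < min_n) {
    stop("need at least ", min_n, " points for a ", model, " fit",
         call. = FALSE)
  }
  if (stats::var(x) == 0) stop("diameter is constant", call. = FALSE)
  fit <- if (model == "linear") {
    stats::lm(y ~ x)
  } else {
    stats::lm(y ~ x + I(x^2))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  list(
    slope = co["x", "Estimate"],
    intercept = co["(Intercept)", "Estimate"],
    quadratic = if (model == "quadratic") co["I(x^2)", "Estimate"] else NA_real_,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    slope_p = co["x", "Pr(>|t|)"],
    n = length(x),
    fit = fit
  )
}

#' Group comparisons with FDR-adjusted contrasts
#'
#' The per-marker analysis used for vessel intensity tables: an omnibus test
#' across groups (Welch ANOVA for roughly Gaussian data or Kruskal-Wallis for
#' non-Gaussian data), followed by contrasts of every group against the
#' reference group (Welch t or Dunn's z), two-stage BKY adjustment across the
#' contrasts, and the percent change of each group mean versus the reference
#' mean.
#'
#' @param records data.frame with columns `group` and `intensity`.
#' @param reference_group the comparison baseline (e.g. "e3/3").
#' @param test `"welch"` or `"kruskal"`.
#' @param q FDR level for the BKY adjustment.
#' @return list `(omnibus, contrasts)`; `contrasts` is a data.frame with
#'   `group`, `statistic`, `p`, `q_value`, `rejected`, `percent_change`.
#' @export
compare_groups <- function(records, reference_group,
                           test = c("welch", "kruskal"), q = 0.05) {
  test <- match.arg(test)
  stopifnot(all(c("group", "intensity") %in% names(records)),
            reference_group %in% records$group)
  groups <- split(records$intensity, records$group)
  others <- setdiff(names(groups), reference_group)
  omnibus <- if (test == "welch") welch_anova(groups) else kruskal_dunn(groups)
  ref <- groups[[reference_group]]
  stat_p <- vapply(others, function(gname) {
    gx <- groups[[gname]]
    if (test == "welch") {
      tt <- stats::t.test(gx, ref)
      c(statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      dn <- kruskal_dunn(list(a = gx, ref = ref))
      c(statistic = dn$pairwise$z[1], p = dn$pairwise$p[1])
    }
  }, numeric(2))
  adj <- bky_two_stage(stat_p["p", ], q = q)
  contrasts <- data.frame(
    group = others,
    statistic = stat_p["statistic", ],
    p = stat_p["p", ],
    q_value = adj$adjusted,
    rejected = adj$rejected,
    percent_change = vapply(others, function(gname) {
      percent_change(mean(groups[[gname]]), mean(ref))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(contrasts) <- NULL
  list(omnibus = omnibus, contrasts = contrasts)
}
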