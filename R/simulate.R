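# Family-cohort simulator: Mendelian APOE + rare-variant transmission, an
# e4-dosage-dependent AD liability model with a planted protective effect, and
# sequencing-quality artifacts.

APOE_ALLELES <- c("e2", "e3", "e4")

# Locus table for one simulated cohort: the planted protective site plus
# n_background neutral sites. Annotation ref_af is the gnomAD-style reference
# frequency used by the rarity filter; founder_af is the frequency alleles are
# actually seeded at. A fraction of background sites get ref_af >= 1% so the
# rarity filter has true negatives, and a fraction are synonymous so the
# consequence filter does too.
make_loci <- function(config) {
  n <- config$n_background
  loci <- data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), gene = character(0), consequence = character(0),
    ref_af = numeric(0), founder_af = numeric(0), planted = logical(0),
    stringsAsFactors = FALSE
  )
  if (config$plant_protective) {
    loci <- rbind(loci, data.frame(
      chrom = "2", pos = 216083000L, ref = "G", alt = "A",
      gene = "PROT1", consequence = "missense",
      ref_af = 0.0046, founder_af = config$protective_af, planted = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  if (n > 0L) {
    founder_af <- stats::runif(n, config$background_af_range[1],
                               config$background_af_range[2])
    ref_af <- founder_af
    common <- stats::runif(n) < 0.10         # annotated too common -> rarity filter fodder
    ref_af[common] <- stats::runif(sum(common), 0.01, 0.05)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    loci <- rbind(loci, data.frame(
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      pos = sample.int(2.4e8, n),
      ref = ref, alt = alt,
      gene = sprintf("BG%03d", seq_len(n)),
      consequence = sample(c("missense", "LOF", "synonymous"), n,
                           replace = TRUE, prob = c(0.55, 0.15, 0.30)),
      ref_af = ref_af, founder_af = founder_af, planted = FALSE,
      stringsAsFactors = FALSE
    ))
  }
  loci$variant_id <- paste(loci$chrom, loci$pos, loci$ref, loci$alt, sep = ":")
  loci
}

#' Draw founder genotypes
#'
#' Each founder receives two APOE alleles drawn independently from the
#' configured allele frequencies and a rare-variant dosage drawn from
#' Hardy-Weinberg proportions at each locus's founder allele frequency. The
#' planted protective site is, by default, seeded only in e4/4 founders at the
#' conditional frequency `protective_af / P(e4/4)` (see [sim_config()]).
#'
#' @param n number of founders.
#' @param config a [sim_config()].
#' @param loci locus table; defaults to the cohort's standard locus set.
#' @return list with `apoe` (n x 2 character matrix) and `dosage`
#'   (n x n_loci integer matrix, columns named by `variant_id`).
#' @export
sample_founders <- function(n, config, loci = make_loci(config)) {
  freqs <- config$apoe_allele_freqs
  apoe <- matrix(sample(APOE_ALLELES, 2L * n, replace = TRUE, prob = freqs),
                 ncol = 2L)
  L <- nrow(loci)
  dosage <- matrix(0L, nrow = n, ncol = L,
                   dimnames = list(NULL, loci$variant_id))
  if (L > 0L && n > 0L) {
    e4hom <- apoe[, 1] == "e4" & apoe[, 2] == "e4"
    for (l in seq_len(L)) {
      af <- loci$founder_af[l]
      if (af <= 0) next
      if (loci$planted[l] && config$plant_in_e4_hom) {
        p_hom <- unname(freqs["e4"])^2
        cond_af <- if (p_hom > 0) min(af / p_hom, 0.5) else 0
        k <- integer(n)
        if (any(e4hom)) {
          k[e4hom] <- stats::rbinom(sum(e4hom), 2L, cond_af)
        }
        dosage[, l] <- k
      } else {
        dosage[, l] <- stats::rbinom(n, 2L, af)
      }
    }
  }
  list(apoe = apoe, dosage = dosage)
}

#' Mendelian transmission from a parent pair
#'
#' Each offspring receives one uniformly chosen allele per parent per locus,
#' independently across loci. APOE is treated as a single locus; no
#' recombination is modelled.
#'
#' @param father,mother lists with `apoe` (length-2 character vector) and
#'   `dosage` (integer vector over loci).
#' @param n_offspring number of children to draw.
#' @return list with `apoe` (n x 2 matrix; column 1 paternal) and `dosage`
#'   (n x n_loci integer matrix).
#' @export
transmit_alleles <- function(father, mother, n_offspring) {
  stopifnot(length(father$apoe) == 2L, length(mother$apoe) == 2L,
            length(father$dosage) == length(mother$dosage))
  n <- as.integer(n_offspring)
  pat <- father$apoe[sample.int(2L, n, replace = TRUE)]
  mat <- mother$apoe[sample.int(2L, n, replace = TRUE)]
  transmit_one <- function(dos) {
    L <- length(dos)
    out <- matrix(rep(as.integer(dos == 2L), each = n), nrow = n, ncol = L)
    het <- which(dos == 1L)
    if (length(het)) {
      out[, het] <- stats::rbinom(n * length(het), 1L, 0.5)
    }
    out
  }
  dosage <- transmit_one(father$dosage) + transmit_one(mother$dosage)
  colnames(dosage) <- names(father$dosage)
  list(apoe = cbind(pat, mat, deparse.level = 0), dosage = dosage)
}

#' Assign diagnosis and age under the liability / age-at-onset model
#'
#' Disease probability is
#' `plogis(qlogis(baseline_risk_by_dosage[d]) + k * log(protective_or) * (d >= 1))`:
#' the protective allele multiplies the AD odds by `protective_or` per copy,
#' but only in e4 carriers. Cases get an age at onset
#' `Normal(aao_mean_by_dosage[d] + k * aao_delay_per_allele, aao_sd)`; controls
#' get a censoring age uniform on `censor_age_range`. Ages are reals > 0.
#'
#' @param e4_dosage integer vector in 0..2.
#' @param protective_dosage integer vector in 0..2.
#' @param config a [sim_config()].
#' @return data.frame with columns `diagnosis` ("AD"/"control") and `age`.
#' @export
assign_phenotype <- function(e4_dosage, protective_dosage, config) {
  d <- as.integer(e4_dosage)
  k <- as.integer(protective_dosage)
  stopifnot(all(d %in% 0:2), all(k %in% 0:2), length(d) == length(k))
  n <- length(d)
  base <- config$baseline_risk_by_dosage[d + 1L]
  lin <- stats::qlogis(base) + k * log(config$protective_or) * (d >= 1L)
  p_ad <- stats::plogis(lin)
  ad <- stats::runif(n) < p_ad
  age <- numeric(n)
  if (any(ad)) {
    mu <- config$aao_mean_by_dosage[d[ad] + 1L] +
      k[ad] * config$aao_delay_per_allele
    age[ad] <- stats::rnorm(sum(ad), mu, config$aao_sd)
  }
  if (any(!ad)) {
    age[!ad] <- stats::runif(sum(!ad), config$censor_age_range[1],
                             config$censor_age_range[2])
  }
  data.frame(diagnosis = ifelse(ad, "AD", "control"),
             age = pmax(age, 1), stringsAsFactors = FALSE)
}

apoe_string <- function(apoe_mat) {
  # canonical unordered encoding, e.g. "e3/e4"
  apply(apoe_mat, 1L, function(a) paste(sort(a), collapse = "/"))
}

sim_one_family <- function(fam_idx, config, loci) {
  n_off <- if (config$offspring_range[1] == config$offspring_range[2]) {
    config$offspring_range[1]
  } else {
    sample(seq(config$offspring_range[1], config$offspring_range[2]), 1L)
  }
  founders <- sample_founders(2L, config, loci)
  father <- list(apoe = founders$apoe[1, ], dosage = founders$dosage[1, ])
  mother <- list(apoe = founders$apoe[2, ], dosage = founders$dosage[2, ])
  kids <- transmit_alleles(father, mother, n_off)
  apoe <- rbind(founders$apoe, kids$apoe)
  dosage <- rbind(founders$dosage, kids$dosage)
  d4 <- rowSums(apoe == "e4")
  k <- if (config$plant_protective) dosage[, 1L] else integer(nrow(dosage))
  phen <- assign_phenotype(d4, k, config)
  n <- nrow(apoe)
  fam_id <- sprintf("F%04d", fam_idx)
  ids <- sprintf("%s_S%02d", fam_id, seq_len(n))
  samples <- data.frame(
    sample_id = ids,
    family_id = fam_id,
    cohort = config$cohort_name,
    apoe = apoe_string(apoe),
    diagnosis = phen$diagnosis,
    age = phen$age,
    sex = c("M", "F", sample(c("F", "M"), n_off, replace = TRUE)),
    ancestry = config$ancestry,
    stringsAsFactors = FALSE
  )
  pedigree <- data.frame(
    sample_id = ids,
    father_id = c(NA, NA, rep(ids[1], n_off)),
    mother_id = c(NA, NA, rep(ids[2], n_off)),
    stringsAsFactors = FALSE
  )
  rownames(dosage) <- ids
  list(samples = samples, pedigree = pedigree, dosage = dosage)
}

#' Simulate a complete family cohort
#'
#' Generates `n_families` two-generation families, assigns diagnoses and ages
#' under the liability model, and overlays sequencing-quality artifacts:
#' per-call depth `Poisson(mean_depth)` and truncated-normal GQ, with a
#' `qc_fail_fraction` of calls degraded below the GQ >= 20 / DP >= 10
#' thresholds (the underlying dosage is kept, so the QC filter is what removes
#' them). Deterministic given the config (including the seed); per-family
#' random substreams are derived from the root seed up front, so results do not
#' depend on generation order.
#'
#' @param config a [sim_config()].
#' @return An object of class `e4_cohort`: list with `samples` (phenotype
#'   table), `variants` (annotation table), `calls` ([genotype_calls()]), and
#'   `truth` (planted variant id, true per-sample dosages, realized effect
#'   parameters, pedigree).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  loci <- make_loci(config)
  fam_seeds <- sample.int(.Machine$integer.max, config$n_families)
  artifact_seed <- sample.int(.Machine$integer.max, 1L)

  fams <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    set.seed(fam_seeds[f])
    fam <- sim_one_family(f, config, loci)
    if (config$ascertainment_min_affected > 0L) {
      tries <- 0L
      while (sum(fam$samples$diagnosis == "AD") <
             config$ascertainment_min_affected) {
        tries <- tries + 1L
        if (tries > 1000L) {
          stop("ascertainment filter not satisfiable; lower ",
               "ascertainment_min_affected or raise disease risk", call. = FALSE)
        }
        fam <- sim_one_family(f, config, loci)
      }
    }
    fams[[f]] <- fam
  }
  samples <- do.call(rbind, lapply(fams, `[[`, "samples"))
  pedigree <- do.call(rbind, lapply(fams, `[[`, "pedigree"))
  dosage_sm <- do.call(rbind, lapply(fams, `[[`, "dosage"))
  dosage <- t(dosage_sm)   # variants x samples

  # sequencing artifacts
  set.seed(artifact_seed)
  n_calls <- length(dosage)
  lambda <- config$mean_depth
  dp <- as.integer(
    stats::qpois(stats::runif(n_calls, stats::ppois(9, lambda), 1), lambda))
  gq <- pmax(20L, pmin(99L, as.integer(round(
    stats::rnorm(n_calls, config$gq_mean, config$gq_sd)))))
  fail <- stats::runif(n_calls) < config$qc_fail_fraction
  if (any(fail)) {
    mode <- sample.int(3L, sum(fail), replace = TRUE)  # 1 GQ, 2 DP, 3 both
    idx <- which(fail)
    low_gq <- idx[mode != 2L]
    low_dp <- idx[mode != 1L]
    gq[low_gq] <- sample(0:19, length(low_gq), replace = TRUE)
    dp[low_dp] <- sample(0:9, length(low_dp), replace = TRUE)
  }
  dim(dp) <- dim(dosage)
  dim(gq) <- dim(dosage)
  dimnames(dp) <- dimnames(gq) <- dimnames(dosage)

  variants <- loci[, c("variant_id", "chrom", "pos", "ref", "alt",
                       "gene", "consequence", "ref_af")]
  rownames(variants) <- NULL
  truth <- list(
    planted_variant = if (config$plant_protective) loci$variant_id[1] else NULL,
    true_dosage = if (config$plant_protective) dosage[1, ] else NULL,
    protective_or = config$protective_or,
    aao_delay_per_allele = config$aao_delay_per_allele,
    pedigree = pedigree
  )
  structure(
    list(samples = samples,
         variants = variants,
         calls = genotype_calls(dosage, gq, dp),
         truth = truth,
         config = config),
    class = "e4_cohort"
  )
}

#' @export
print.e4_cohort <- function(x, ...) {
  d4 <- e4_dosage(x$samples$apoe)
  cat(sprintf(
    "<e4_cohort> %d samples in %d families; %d variants\n",
    nrow(x$samples), length(unique(x$samples$family_id)), nrow(x$variants)))
  cat(sprintf("  AD %d / control %d; e4 het %d, e4 hom %d\n",
              sum(x$samples$diagnosis == "AD"),
              sum(x$samples$diagnosis == "control"),
              sum(d4 == 1L), sum(d4 == 2L)))
  invisible(x)
}
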