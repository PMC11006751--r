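# Family-cohort generator: founder sampling, Mendelian transmission, the
# liability / age-at-onset model, determinism, and file round-trips.

test_that("founder sampling respects degenerate and Hardy-Weinberg frequencies", {
  cfg0 <- small_config(protective_af = 0, plant_in_e4_hom = FALSE,
                       n_background = 0L)
  set.seed(1)
  f0 <- sample_founders(500, cfg0)
  expect_true(all(f0$dosage == 0L))

  cfg_e4 <- small_config(apoe_allele_freqs = c(e2 = 0, e3 = 0, e4 = 1))
  set.seed(1)
  f4 <- sample_founders(300, cfg_e4)
  expect_true(all(f4$apoe == "e4"))

  # binomial sampling oracle: observed AF within 3 binomial SDs of 0.005
  af <- 0.005
  n <- 10000
  cfg <- small_config(protective_af = af, plant_in_e4_hom = FALSE,
                      n_background = 0L)
  set.seed(11)
  fd <- sample_founders(n, cfg)
  obs <- sum(fd$dosage[, 1]) / (2 * n)
  expect_lt(abs(obs - af), 3 * sqrt(af * (1 - af) / (2 * n)))

  # e4/4-restricted planting keeps the population-scale frequency
  cfg_r <- small_config(protective_af = af, plant_in_e4_hom = TRUE,
                        n_background = 0L)
  set.seed(12)
  fr <- sample_founders(20000, cfg_r)
  hom <- fr$apoe[, 1] == "e4" & fr$apoe[, 2] == "e4"
  expect_true(all(fr$dosage[!hom, 1] == 0L))
  obs_r <- sum(fr$dosage[, 1]) / (2 * 20000)
  expect_lt(abs(obs_r - af), 3 * sqrt(af * (1 - af) / (2 * 20000)))
})

test_that("transmission is Mendelian with the right segregation ratios", {
  hom_ref <- list(apoe = c("e3", "e3"), dosage = c(v = 0L))
  hom_alt <- list(apoe = c("e4", "e4"), dosage = c(v = 2L))
  het <- list(apoe = c("e3", "e4"), dosage = c(v = 1L))

  set.seed(2)
  kids0 <- transmit_alleles(hom_ref, hom_ref, 50)
  expect_true(all(kids0$dosage == 0L))

  kids44 <- transmit_alleles(hom_alt, hom_alt, 50)
  expect_true(all(kids44$apoe == "e4"))
  expect_true(all(kids44$dosage == 2L))

  # het x ref: carrier fraction ~ 0.5 within 3 binomial SDs
  n <- 10000
  set.seed(3)
  kids <- transmit_alleles(het, hom_ref, n)
  frac <- mean(kids$dosage >= 1L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("offspring genotypes are always consistent with their parents", {
  coh <- simulate_cohort(small_config(seed = 5))
  ped <- coh$truth$pedigree
  dos <- coh$calls$dosage
  kids <- ped[!is.na(ped$father_id), ]
  df <- dos[, kids$father_id, drop = FALSE]
  dm <- dos[, kids$mother_id, drop = FALSE]
  dc <- dos[, kids$sample_id, drop = FALSE]
  lower <- (df == 2L) + (dm == 2L)
  upper <- (df >= 1L) + (dm >= 1L)
  expect_true(all(dc >= lower & dc <= upper))

  # APOE: every child allele pair is attainable from one allele per parent
  ap <- strsplit(coh$samples$apoe, "/")
  names(ap) <- coh$samples$sample_id
  ok <- vapply(seq_len(nrow(kids)), function(i) {
    f <- ap[[kids$father_id[i]]]; m <- ap[[kids$mother_id[i]]]
    ch <- ap[[kids$sample_id[i]]]
    any(vapply(f, function(a) {
      any(vapply(m, function(b) setequal_multiset(c(a, b), ch), logical(1)))
    }, logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("the liability model applies the protective odds only in e4 carriers", {
  cfg <- sim_config(baseline_risk_by_dosage = c(0.2, 0.45, 0.6),
                    protective_or = 0.29)
  n <- 300000

  # null effect: protective_or = 1 leaves the baseline untouched
  cfg1 <- sim_config(protective_or = 1, baseline_risk_by_dosage = c(0.2, 0.45, 0.6))
  set.seed(21)
  ph <- assign_phenotype(rep(2L, n), rep(1L, n), cfg1)
  rate <- mean(ph$diagnosis == "AD")
  expect_lt(abs(rate - 0.6), 3 * sqrt(0.6 * 0.4 / n))

  # one protective copy in an e4/4 carrier multiplies the odds by exactly 0.29
  expected <- plogis(qlogis(0.6) + log(0.29))
  set.seed(22)
  ph2 <- assign_phenotype(rep(2L, n), rep(1L, n), cfg)
  rate2 <- mean(ph2$diagnosis == "AD")
  expect_lt(abs(rate2 - expected), 3 * sqrt(expected * (1 - expected) / n))

  # no effect in e4 non-carriers
  expected0 <- 0.2
  set.seed(23)
  ph0 <- assign_phenotype(rep(0L, n), rep(1L, n), cfg)
  expect_lt(abs(mean(ph0$diagnosis == "AD") - expected0),
            3 * sqrt(expected0 * 0.8 / n))

  expect_true(all(ph$age > 0))
})

test_that("a logistic fit recovers the planted log odds ratio", {
  cfg <- sim_config(protective_or = 0.29)
  n <- 50000
  set.seed(31)
  k <- rbinom(n, 2L, 0.03)
  ph <- assign_phenotype(rep(2L, n), k, cfg)
  fit <- logistic_assoc(ph$diagnosis, k)
  expect_lt(abs(fit$log_or - log(0.29)), 2 * fit$se)
})

test_that("simulation is deterministic and QC-clean when asked", {
  cfg <- small_config(seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$calls$dosage, b$calls$dosage)
  expect_identical(a$calls$gq, b$calls$gq)
  expect_identical(a$calls$dp, b$calls$dp)

  clean <- simulate_cohort(small_config(seed = 9, qc_fail_fraction = 0))
  qc <- apply_genotype_qc(clean$calls, 20, 10)
  expect_identical(qc$dosage, clean$calls$dosage)

  dirty <- simulate_cohort(small_config(seed = 9, qc_fail_fraction = 0.3))
  qc2 <- apply_genotype_qc(dirty$calls)
  frac_missing <- mean(is.na(qc2$dosage))
  expect_lt(abs(frac_missing - 0.3), 0.02)
})

test_that("written cohorts round-trip losslessly through the readers", {
  coh <- simulate_cohort(small_config(seed = 13, n_background = 10L))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)

  rt <- read_vcf(paths$vcf)
  expect_identical(rt$calls$dosage, coh$calls$dosage)
  expect_identical(rt$calls$gq, coh$calls$gq)
  expect_identical(rt$calls$dp, coh$calls$dp)
  expect_identical(rt$variants$variant_id, coh$variants$variant_id)
  expect_identical(rt$variants$pos, coh$variants$pos)

  ph <- read_phenotypes(paths$phenotypes)
  expect_identical(ph$sample_id, coh$samples$sample_id)
  expect_identical(ph$apoe, coh$samples$apoe)
  expect_equal(ph$age, coh$samples$age, tolerance = 1e-8)
  expect_identical(nrow(ph), nrow(coh$samples))

  an <- read_annotations(paths$annotations)
  expect_identical(an$variant_id, coh$variants$variant_id)
  expect_equal(an$ref_af, coh$variants$ref_af, tolerance = 1e-8)

  # VCF sample columns match the phenotype rows
  expect_identical(colnames(rt$calls$dosage), ph$sample_id)
})

test_that("family ascertainment keeps only multiply-affected families when asked", {
  coh <- simulate_cohort(small_config(seed = 17, ascertainment_min_affected = 2L))
  affected <- tapply(coh$samples$diagnosis == "AD", coh$samples$family_id, sum)
  expect_true(all(affected >= 2L))
})

test_that("configuration validation rejects malformed inputs", {
  expect_error(sim_config(apoe_allele_freqs = c(e2 = 0.5, e3 = 0.6, e4 = 0.2)),
               "sum to 1")
  expect_error(sim_config(protective_or = 0), "protective_or")
  expect_error(sim_config(aao_sd = -1), "aao_sd")
  expect_error(sim_config(protective_af = 2), "protective_af")
})
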