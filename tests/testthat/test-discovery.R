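# The segregation cascade: individual gates, the full pipeline, soundness
# against a brute-force scan, and the per-cohort intersection.

toy_gate_cohort <- function() {
  sm <- make_samples(
    apoe = c(rep("e4/e4", 5), rep("e3/e4", 4), rep("e3/e3", 3)),
    diagnosis = c("control", "control", "control", "AD", "AD",
                  "control", "control", "AD", "AD",
                  "control", "control", "AD"),
    age = c(75, 72, 68, 70, 74, 85, 81, 77, 70, 70, 75, 72)
  )
  dos <- matrix(0L, 3, 12, dimnames = list(c("vA", "vB", "vC"), sm$sample_id))
  dos["vA", c(1, 6)] <- 1L        # elderly hom ctrl + elderly het ctrl
  dos["vB", c(1, 6, 10)] <- 1L    # also in an e3/3 sample
  dos["vC", c(1, 6, 8)] <- 1L     # also in a het AD case
  list(samples = sm, calls = calls_from_dosage(dos),
       variants = data.frame(variant_id = c("vA", "vB", "vC"),
                             chrom = "1", pos = c(10L, 20L, 30L),
                             gene = c("A", "B", "C")))
}

test_that("the non-carrier absence gate sees any non-carrier copy", {
  toy <- toy_gate_cohort()
  st <- assign_strata(toy$samples)
  expect_true(noncarrier_absence("vA", toy$calls, st$noncarrier))
  expect_false(noncarrier_absence("vB", toy$calls, st$noncarrier))
})

test_that("the elderly-hom carrier fraction is individual-level", {
  toy <- toy_gate_cohort()
  st <- assign_strata(toy$samples)
  # elderly healthy e4/4: samples 1 and 2 -> 1 carrier of 2
  expect_equal(elderly_hom_carrier_fraction("vA", toy$calls,
                                            st$elderly_healthy_hom), 0.5)
  expect_equal(elderly_hom_carrier_fraction("vB", toy$calls, character(0)),
               NA_real_)
  # 1 of 27 (the published discovery configuration) -> 0.0370
  dos <- matrix(c(1L, rep(0L, 26)), 1, 27,
                dimnames = list("v", sprintf("S%03d", 1:27)))
  expect_equal(
    round(elderly_hom_carrier_fraction("v", calls_from_dosage(dos),
                                       colnames(dos)), 4), 0.037)
})

test_that("case-absence flags distinguish hom-AD from any-e4-AD presence", {
  toy <- toy_gate_cohort()
  st <- assign_strata(toy$samples)
  expect_identical(case_absence_flags("vA", toy$calls, st),
                   c(absent_in_hom_AD = TRUE, absent_in_all_e4_AD = TRUE))
  # allele in one het AD patient: absent in hom AD, not in all e4 AD
  expect_identical(case_absence_flags("vC", toy$calls, st),
                   c(absent_in_hom_AD = TRUE, absent_in_all_e4_AD = FALSE))
  dos <- toy$calls$dosage
  dos["vA", 4] <- 1L  # hom AD carrier
  cl <- calls_from_dosage(dos)
  expect_identical(case_absence_flags("vA", cl, st),
                   c(absent_in_hom_AD = FALSE, absent_in_all_e4_AD = FALSE))
})

test_that("the cascade gates, tiers and hard modes behave as specified", {
  toy <- toy_gate_cohort()
  res <- run_cascade(toy$variants, toy$samples, toy$calls,
                     cascade_config(per_cohort = FALSE))
  # vA passes with full case absence (tier 1); vB is excluded at gate 1;
  # vC is kept but ranked tier 2 (het AD carrier)
  expect_identical(res$variant_id, c("vA", "vC"))
  expect_identical(res$tier, c(1L, 2L))
  expect_true(all(res$absent_in_noncarriers))

  hard <- run_cascade(toy$variants, toy$samples, toy$calls,
                      cascade_config(case_absence_mode = "hard_all_e4_AD",
                                     per_cohort = FALSE))
  expect_identical(hard$variant_id, "vA")

  # a hom-AD carrier falls to tier 3 and is dropped by hard_hom_AD_only
  dos <- toy$calls$dosage
  dos["vC", 4] <- 1L
  cl <- calls_from_dosage(dos)
  soft <- run_cascade(toy$variants, toy$samples, cl,
                      cascade_config(per_cohort = FALSE))
  expect_identical(soft$tier[soft$variant_id == "vC"], 3L)
  hard2 <- run_cascade(toy$variants, toy$samples, cl,
                       cascade_config(case_absence_mode = "hard_hom_AD_only",
                                      per_cohort = FALSE))
  expect_false("vC" %in% hard2$variant_id)
})

test_that("the cascade aborts with a diagnostic when a stratum is empty", {
  toy <- toy_gate_cohort()
  sm <- toy$samples[toy$samples$apoe != "e4/e4" | toy$samples$age < 70, ]
  expect_error(run_cascade(toy$variants, sm, toy$calls,
                           cascade_config(per_cohort = FALSE)),
               "elderly_healthy_hom")
})

test_that("raising the carrier-fraction threshold never adds candidates", {
  coh <- simulate_cohort(small_config(seed = 31))
  calls <- apply_genotype_qc(coh$calls)
  v <- filter_by_consequence(filter_by_reference_af(coh$variants))
  prev <- NULL
  for (thr in c(0.005, 0.01, 0.05, 0.2)) {
    cand <- run_cascade(v, coh$samples, calls,
                        cascade_config(min_elderly_hom_carrier_fraction = thr,
                                       per_cohort = FALSE))$variant_id
    if (!is.null(prev)) expect_true(all(cand %in% prev))
    prev <- cand
  }
})

test_that("cascade output matches an independent brute-force scan", {
  # includes null cohorts (protective_or = 1): every emitted candidate, and
  # only those, passes the gates when re-derived from the raw matrices
  for (seed in 1:8) {
    cfg <- small_config(seed = 100 + seed,
                        protective_or = if (seed %% 2) 1 else 0.29)
    coh <- simulate_cohort(cfg)
    calls <- apply_genotype_qc(coh$calls)
    v <- filter_by_consequence(filter_by_reference_af(coh$variants))
    got <- run_cascade(v, coh$samples, calls,
                       cascade_config(per_cohort = FALSE))$variant_id
    want <- brute_force_cascade(v, coh$samples, calls)
    expect_setequal(got, want)
  }
})

test_that("per-cohort mode reports each cohort and their intersection", {
  toy <- toy_gate_cohort()
  b <- toy
  b$samples$sample_id <- paste0("B_", b$samples$sample_id)
  b$samples$cohort <- "T2"
  # cohort B lacks the het-AD carrier of vC, so vC is tier 1 there but the
  # candidate sets still agree
  dosB <- toy$calls$dosage
  dosB["vC", 8] <- 0L
  colnames(dosB) <- b$samples$sample_id
  dos <- cbind(toy$calls$dosage, dosB)
  samples <- rbind(toy$samples, b$samples)
  res <- run_cascade(toy$variants, samples, calls_from_dosage(dos),
                     cascade_config())
  expect_s3_class(res, "cascade_result")
  expect_identical(sort(names(res$per_cohort)), c("T", "T2"))
  expect_identical(res$per_cohort$T$variant_id, c("vA", "vC"))
  expect_identical(res$per_cohort$T2$tier, c(1L, 1L))
  expect_setequal(res$intersection, c("vA", "vC"))
  for (co in names(res$per_cohort)) {
    expect_lte(length(res$intersection), nrow(res$per_cohort[[co]]))
    expect_true(all(res$intersection %in% res$per_cohort[[co]]$variant_id))
  }

  # a variant failing in one cohort drops out of the intersection
  dos2 <- dos
  dos2["vA", "B_S010"] <- 1L   # vA now seen in a T2 non-carrier
  res2 <- run_cascade(toy$variants, samples, calls_from_dosage(dos2),
                      cascade_config())
  expect_false("vA" %in% res2$intersection)
  expect_true("vA" %in% res2$per_cohort$T$variant_id)
})
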