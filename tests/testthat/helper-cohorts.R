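# Shared fixtures: small configurations and hand-built genotype sets.

small_config <- function(seed = 7L, ...) {
  args <- list(seed = seed, n_families = 40L, n_background = 30L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# a genotype_calls object from a plain dosage matrix, all calls passing QC
calls_from_dosage <- function(dosage, gq = 99L, dp = 30L) {
  genotype_calls(dosage,
                 matrix(gq, nrow(dosage), ncol(dosage),
                        dimnames = dimnames(dosage)),
                 matrix(dp, nrow(dosage), ncol(dosage),
                        dimnames = dimnames(dosage)))
}

# a minimal phenotype table
make_samples <- function(apoe, diagnosis, age, cohort = "T") {
  n <- length(apoe)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    family_id = sprintf("F%03d", seq_len(n)),
    cohort = cohort, apoe = apoe, diagnosis = diagnosis, age = age,
    sex = "F", ancestry = "x", stringsAsFactors = FALSE
  )
}

setequal_multiset <- function(a, b) {
  identical(sort(a), sort(b))
}

# brute-force re-derivation of the cascade from raw matrices, written without
# the package's gate functions; used as an independent oracle.
brute_force_cascade <- function(variants, samples, calls, threshold = 0.01,
                                require_het = TRUE) {
  d4 <- sapply(strsplit(samples$apoe, "/"), function(a) sum(a == "e4"))
  age <- floor(samples$age)
  dos <- calls$dosage[, samples$sample_id, drop = FALSE]
  hits <- character(0)
  for (vid in variants$variant_id) {
    g <- dos[vid, ]
    nc <- g[d4 == 0]
    if (sum(nc, na.rm = TRUE) > 0) next
    eh <- g[d4 == 2 & samples$diagnosis == "control" & age >= 70]
    eh <- eh[!is.na(eh)]
    if (length(eh) == 0 || sum(eh >= 1) / length(eh) < threshold) next
    if (require_het) {
      ht <- g[d4 == 1 & samples$diagnosis == "control" & age >= 80]
      if (sum(ht >= 1, na.rm = TRUE) < 1) next
    }
    hits <- c(hits, vid)
  }
  hits
}
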