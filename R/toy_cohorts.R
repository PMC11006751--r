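# Toy cohorts built from published stratum counts, so the stratification and
# cascade machinery can be run against the printed frequency tables.

#' Build a cohort from per-stratum counts
#'
#' Expands a compact per-stratum design into a phenotype table and genotype
#' calls for a single variant, so printed stratum MAFs can be reconstructed by
#' running the actual tabulation machinery. Each design row describes one
#' disjoint block of samples: e4 dosage, diagnosis, a representative age, the
#' number of samples, how many of them are genotyped (the rest get a failing
#' GQ, so QC sets them missing — this models published denominators smaller
#' than the demographic totals), and how many genotyped samples carry one or
#' two copies of the variant.
#'
#' @param design data.frame with columns `e4_dosage`, `diagnosis`, `age`, `n`,
#'   and optionally `genotyped` (default `n`), `carriers_het`, `carriers_hom`
#'   (default 0).
#' @param cohort cohort label.
#' @param variant list with `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `ref_af` describing the single variant.
#' @return an `e4_cohort`-shaped list (`samples`, `variants`, `calls`).
#' @export
cohort_from_stratum_counts <- function(design, cohort = "TOY",
                                       variant = list(chrom = "2",
                                                      pos = 1000L,
                                                      ref = "G", alt = "A",
                                                      gene = "GENE",
                                                      consequence = "missense",
                                                      ref_af = 0.005)) {
  if (is.null(design$genotyped)) design$genotyped <- design$n
  if (is.null(design$carriers_het)) design$carriers_het <- 0L
  if (is.null(design$carriers_hom)) design$carriers_hom <- 0L
  stopifnot(all(design$genotyped <= design$n),
            all(design$carriers_het + design$carriers_hom <= design$genotyped))
  apoe_by_dosage <- c("e3/e3", "e3/e4", "e4/e4")
  samples <- list(); dosage <- list(); gq <- list()
  for (i in seq_len(nrow(design))) {
    n <- design$n[i]
    if (n == 0L) next
    ids <- sprintf("%s_B%02d_S%04d", cohort, i, seq_len(n))
    samples[[i]] <- data.frame(
      sample_id = ids,
      family_id = sprintf("%s_B%02d", cohort, i),
      cohort = cohort,
      apoe = apoe_by_dosage[design$e4_dosage[i] + 1L],
      diagnosis = design$diagnosis[i],
      age = design$age[i],
      sex = "F",
      ancestry = "published",
      stringsAsFactors = FALSE
    )
    dos <- rep(0L, n)
    nh <- design$carriers_hom[i]; nt <- design$carriers_het[i]
    if (nh > 0L) dos[seq_len(nh)] <- 2L
    if (nt > 0L) dos[nh + seq_len(nt)] <- 1L
    dosage[[i]] <- dos
    g <- rep(99L, n)
    if (design$genotyped[i] < n) {
      g[(design$genotyped[i] + 1L):n] <- 0L   # fails GQ >= 20 -> missing post-QC
    }
    gq[[i]] <- g
  }
  samples <- do.call(rbind, samples)
  dos <- matrix(unlist(dosage), nrow = 1L,
                dimnames = list(
                  paste(variant$chrom, variant$pos, variant$ref, variant$alt,
                        sep = ":"),
                  samples$sample_id))
  gq <- matrix(unlist(gq), nrow = 1L, dimnames = dimnames(dos))
  dp <- matrix(30L, nrow = 1L, ncol = ncol(dos), dimnames = dimnames(dos))
  variants <- data.frame(
    variant_id = rownames(dos),
    chrom = variant$chrom, pos = variant$pos, ref = variant$ref,
    alt = variant$alt, gene = variant$gene,
    consequence = variant$consequence, ref_af = variant$ref_af,
    stringsAsFactors = FALSE
  )
  list(samples = samples, variants = variants,
       calls = genotype_calls(dos, gq, dp))
}

#' Published discovery stratum designs for the two FN1 variants
#'
#' Per-stratum blocks reproducing the published demographic totals and the
#' printed stratum MAFs for rs116558455 (Caribbean Hispanic EFIGA/WHICAP
#' families) and rs140926439 (non-Hispanic White NIA-AD FBS families). Where a
#' printed MAF implies a genotyped denominator smaller than the demographic
#' total (the all-healthy-homozygote and het-AD cells of the NIA-AD FBS row),
#' the design carries the implied denominator via its `genotyped` column.
#'
#' @return named list of two design data.frames (`EFIGA_WHICAP`, `NIA_AD_FBS`)
#'   suitable for [cohort_from_stratum_counts()].
#' @export
fn1_discovery_designs <- function() {
  list(
    EFIGA_WHICAP = data.frame(
      block = c("hom_ctrl_elderly", "hom_ctrl_young", "hom_AD",
                "het_ctrl_elderly", "het_ctrl_young", "het_AD",
                "noncarrier_ctrl"),
      e4_dosage = c(2L, 2L, 2L, 1L, 1L, 1L, 0L),
      diagnosis = c("control", "control", "AD", "control", "control", "AD",
                    "control"),
      age = c(75, 65, 72, 85, 70, 74, 70),
      n = c(27L, 48L, 114L, 75L, 207L, 442L, 200L),
      genotyped = c(27L, 48L, 114L, 75L, 207L, 442L, 200L),
      carriers_het = c(1L, 0L, 0L, 1L, 0L, 0L, 0L),
      carriers_hom = 0L,
      stringsAsFactors = FALSE
    ),
    NIA_AD_FBS = data.frame(
      block = c("hom_ctrl_elderly", "hom_ctrl_young", "hom_AD",
                "het_ctrl_elderly", "het_ctrl_young", "het_AD",
                "noncarrier_ctrl"),
      e4_dosage = c(2L, 2L, 2L, 1L, 1L, 1L, 0L),
      diagnosis = c("control", "control", "AD", "control", "control", "AD",
                    "control"),
      age = c(75, 65, 70, 85, 70, 73, 70),
      n = c(15L, 15L, 155L, 45L, 116L, 265L, 200L),
      genotyped = c(15L, 14L, 155L, 45L, 116L, 261L, 200L),
      carriers_het = c(1L, 2L, 0L, 2L, 3L, 5L, 0L),
      carriers_hom = 0L,
      stringsAsFactors = FALSE
    )
  )
}
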