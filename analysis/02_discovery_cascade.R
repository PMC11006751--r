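#!/usr/bin/env Rscript
# Step 2: the discovery screen. Read the simulated cohort back from disk,
# apply genotype QC (GQ >= 20, DP >= 10), keep rare (reference AF < 1%)
# potentially damaging coding variants, and run the segregation cascade:
# absent in e4 non-carriers, carried by >= 1% of elderly (>= 70 y) healthy
# e4/4 individuals, supported by >= 1 elderly (>= 80 y) healthy heterozygote,
# then ranked by absence in e4-carrier AD cases.

library(e4screen)

cohort_dir <- "results/cohort"
if (!dir.exists(cohort_dir)) stop("run analysis/01_simulate_cohort.R first")

vcf <- read_vcf(file.path(cohort_dir, "genotypes.vcf"))
samples <- read_phenotypes(file.path(cohort_dir, "phenotypes.tsv"))
annot <- read_annotations(file.path(cohort_dir, "annotations.tsv"))
message("Read ", nrow(vcf$variants), " variants x ", nrow(samples), " samples")

calls <- apply_genotype_qc(vcf$calls, gq_min = 20, dp_min = 10)
message(sprintf("QC set %.1f%% of calls missing",
                100 * mean(is.na(calls$dosage))))

v <- filter_by_reference_af(annot, max_af = 0.01)
message(nrow(annot) - nrow(v), " variants removed by the rarity filter")
v2 <- filter_by_consequence(v, c("missense", "LOF"))
message(nrow(v) - nrow(v2), " removed by the consequence filter; ",
        nrow(v2), " screened")

res <- run_cascade(v2, samples, calls, cascade_config())
print(res)
cand <- res$candidates
write.table(cand, "results/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ft <- frequency_table(v2[v2$variant_id %in% cand$variant_id, , drop = FALSE],
                      samples, calls)
write.table(ft, "results/frequency_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("Candidates (stratum MAFs in %):")
print(ft)
message("Top candidate: ", cand$variant_id[1], " (", cand$gene[1],
        "), elderly-hom carrier fraction ",
        sprintf("%.1f%%", 100 * cand$elderly_hom_fraction[1]),
        ", tier ", cand$tier[1])
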