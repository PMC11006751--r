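# Reading/writing the pipeline's formats (VCF v4.2 with GT:GQ:DP, phenotype and
# annotation TSVs) and the genotype-/variant-level QC filters.

PHENO_COLS <- c("sample_id", "family_id", "cohort", "apoe", "diagnosis",
                "age", "sex", "ancestry")
ANNOT_COLS <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "ref_af")

#' Write a cohort's VCF, phenotype and annotation files
#'
#' Emits a VCF v4.2 (FORMAT `GT:GQ:DP`, 1-based positions), a tab-separated
#' phenotype table and a tab-separated annotation table. The files round-trip
#' losslessly through [read_vcf()], [read_phenotypes()] and
#' [read_annotations()].
#'
#' @param cohort an `e4_cohort` from [simulate_cohort()], or any list with
#'   `samples`, `variants` and `calls` components.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                phenotypes = file.path(dir, "phenotypes.tsv"),
                annotations = file.path(dir, "annotations.tsv"))
  write_vcf(cohort$variants, cohort$calls, paths$vcf)
  utils::write.table(cohort$samples[, PHENO_COLS], paths$phenotypes,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$variants[, ANNOT_COLS], paths$annotations,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write genotype calls as VCF v4.2
#'
#' @param variants variant table (`chrom`, `pos`, `ref`, `alt`, plus optional
#'   `variant_id` used for the ID column).
#' @param calls a [genotype_calls()] object aligned with `variants`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(variants, calls, path) {
  n_var <- nrow(variants)
  samples <- colnames(calls$dosage)
  stopifnot(nrow(calls$dosage) == n_var)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=e4screen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  if (n_var > 0L && length(samples) > 0L) {
    gt <- matrix("./.", n_var, length(samples))
    gt[calls$dosage == 0L] <- "0/0"
    gt[calls$dosage == 1L] <- "0/1"
    gt[calls$dosage == 2L] <- "1/1"
    field <- matrix(paste(gt,
                          ifelse(is.na(calls$gq), ".", calls$gq),
                          ifelse(is.na(calls$dp), ".", calls$dp),
                          sep = ":"),
                    n_var, length(samples))
    ids <- if ("variant_id" %in% names(variants)) variants$variant_id else "."
    recs <- paste(variants$chrom, variants$pos, ids, variants$ref,
                  variants$alt, ".", "PASS", ".", "GT:GQ:DP", sep = "\t")
    body <- paste(recs, apply(field, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  } else if (n_var > 0L) {
    writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, ".", "PASS", ".", "GT:GQ:DP", sep = "\t"),
               con)
  }
  invisible(path)
}

# dosage of one alt allele index within GT strings like "0/1", "2|1", "./.",
# "0/."; any missing haploid call makes the genotype missing (half-calls are
# conservative).
gt_to_dosage <- function(gt, alt_index) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(a) {
    if (length(a) == 0L || any(a == "." | a == "" | is.na(a))) return(NA_integer_)
    sum(a == as.character(alt_index))
  }, integer(1))
}

#' Read a VCF into variants and genotype calls
#'
#' Parses a VCF v4.2 with per-genotype `GT`, `GQ` and `DP` fields.
#' Multi-allelic records are split into biallelic records at read time, one per
#' alt allele, with per-sample dosages recomputed against that alt; positions
#' stay 1-based and untouched. Half-calls (e.g. `0/.`) are treated as missing.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return list with `variants` (data.frame: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`) and `calls` ([genotype_calls()]).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gq_raw <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  dp_raw <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))

  out_var <- list(); out_dos <- list(); out_gq <- list(); out_dp <- list()
  k <- 0L
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (a in seq_along(alts)) {
      k <- k + 1L
      out_var[[k]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a], stringsAsFactors = FALSE)
      out_dos[[k]] <- gt_to_dosage(gt_raw[i, ], a)
      out_gq[[k]] <- gq_raw[i, ]
      out_dp[[k]] <- dp_raw[i, ]
    }
  }
  variants <- do.call(rbind, out_var)
  variants$variant_id <- paste(variants$chrom, variants$pos, variants$ref,
                               variants$alt, sep = ":")
  variants <- variants[, c("variant_id", "chrom", "pos", "ref", "alt")]
  dn <- list(variants$variant_id, samples)
  calls <- genotype_calls(
    matrix(as.integer(unlist(out_dos)), nrow = k, byrow = TRUE, dimnames = dn),
    matrix(as.integer(unlist(out_gq)), nrow = k, byrow = TRUE, dimnames = dn),
    matrix(as.integer(unlist(out_dp)), nrow = k, byrow = TRUE, dimnames = dn))
  list(variants = variants, calls = calls)
}

#' Read a phenotype table
#'
#' Expects a tab-separated file with header
#' `sample_id family_id cohort apoe diagnosis age sex ancestry`. APOE genotype
#' strings (`"e3/e4"` style) are validated; duplicate sample ids, unknown APOE
#' strings and non-positive ages are rejected with the offending row named.
#'
#' @param path path to the TSV.
#' @return data.frame of samples.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(PHENO_COLS, names(ph))
  if (length(missing_cols)) {
    stop("phenotype file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ph$age <- as.numeric(ph$age)
  dup <- which(duplicated(ph$sample_id))
  if (length(dup)) {
    stop("duplicate sample_id at row ", dup[1], ": ", ph$sample_id[dup[1]],
         call. = FALSE)
  }
  ok_apoe <- grepl("^e[234]/e[234]$", ph$apoe)
  if (any(!ok_apoe)) {
    bad <- which(!ok_apoe)[1]
    stop("unknown APOE genotype at row ", bad, ": '", ph$apoe[bad], "'",
         call. = FALSE)
  }
  bad_age <- which(!is.na(ph$age) & ph$age <= 0)
  if (length(bad_age)) {
    stop("non-positive age at row ", bad_age[1], call. = FALSE)
  }
  ok_dx <- ph$diagnosis %in% c("AD", "control", "unknown")
  if (any(!ok_dx)) {
    stop("unknown diagnosis at row ", which(!ok_dx)[1], ": '",
         ph$diagnosis[which(!ok_dx)[1]], "'", call. = FALSE)
  }
  ph[, PHENO_COLS]
}

#' Read a variant annotation table
#'
#' Tab-separated with header `chrom pos ref alt gene consequence ref_af`.
#'
#' @param path path to the TSV.
#' @return data.frame of annotations with a `variant_id` key column.
#' @export
read_annotations <- function(path) {
  an <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(ANNOT_COLS, names(an))
  if (length(missing_cols)) {
    stop("annotation file lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  an$variant_id <- paste(an$chrom, an$pos, an$ref, an$alt, sep = ":")
  an[, c("variant_id", ANNOT_COLS)]
}

#' Apply per-genotype QC (GQ / DP thresholds)
#'
#' Calls with GQ below `gq_min` or DP below `dp_min` are set to missing;
#' everything else is untouched. Thresholds are inclusive (GQ >= 20 and
#' DP >= 10 pass at the defaults). Calls with missing GQ or DP are treated as
#' failing. Idempotent.
#'
#' @param calls a [genotype_calls()].
#' @param gq_min,dp_min inclusive thresholds (defaults 20 and 10).
#' @return a [genotype_calls()] with failing dosages set to `NA`.
#' @export
apply_genotype_qc <- function(calls, gq_min = 20, dp_min = 10) {
  stopifnot(gq_min >= 0, dp_min >= 0)
  fail <- is.na(calls$gq) | is.na(calls$dp) |
    calls$gq < gq_min | calls$dp < dp_min
  dosage <- calls$dosage
  dosage[fail] <- NA_integer_
  genotype_calls(dosage, calls$gq, calls$dp)
}

#' Keep rare variants (reference-population allele frequency filter)
#'
#' Keeps variants with `ref_af` strictly below `max_af` (the screen targets
#' rare variants, reference MAF < 1%). Variants with missing `ref_af` are kept
#' with a warning: absence from the reference panel must not disqualify a rare
#' variant.
#'
#' @param variants annotation data.frame with a `ref_af` column.
#' @param max_af exclusive upper bound (default 0.01).
#' @return the filtered data.frame.
#' @export
filter_by_reference_af <- function(variants, max_af = 0.01) {
  miss <- is.na(variants$ref_af)
  if (any(miss)) {
    warning(sum(miss), " variant(s) lack ref_af; kept as rare", call. = FALSE)
  }
  variants[miss | variants$ref_af < max_af, , drop = FALSE]
}

#' Keep variants by consequence class
#'
#' Retains variants whose `consequence` is in `allowed_classes` (default:
#' potentially damaging coding classes, missense and LOF). Variants with a
#' class outside the known vocabulary are dropped with a warning.
#'
#' @param variants annotation data.frame with a `consequence` column.
#' @param allowed_classes character vector of classes to keep, or `"all"` to
#'   keep every variant.
#' @return the filtered data.frame.
#' @export
filter_by_consequence <- function(variants,
                                  allowed_classes = c("missense", "LOF")) {
  if (identical(allowed_classes, "all")) return(variants)
  known <- c("missense", "LOF", "synonymous")
  unknown <- !(variants$consequence %in% union(known, allowed_classes))
  if (any(unknown)) {
    warning("dropping ", sum(unknown), " variant(s) with unknown consequence: ",
            paste(unique(variants$consequence[unknown]), collapse = ", "),
            call. = FALSE)
  }
  variants[variants$consequence %in% allowed_classes & !unknown, ,
           drop = FALSE]
}
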