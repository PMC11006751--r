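#' Per-sample genotype calls with quality fields
#'
#' A light container for a biallelic genotype matrix and its per-call quality
#' fields, mirroring the VCF `GT:GQ:DP` FORMAT. Rows are variants (named by
#' `variant_id`), columns are samples.
#'
#' @param dosage integer matrix of alt-allele dosages (0/1/2), `NA` = missing.
#' @param gq integer matrix of phred-scaled genotype qualities (>= 0).
#' @param dp integer matrix of read depths (>= 0).
#' @return An object of class `genotype_calls`.
#' @export
genotype_calls <- function(dosage, gq, dp) {
  dosage <- as.matrix(dosage)
  gq <- as.matrix(gq)
  dp <- as.matrix(dp)
  if (!identical(dim(dosage), dim(gq)) || !identical(dim(dosage), dim(dp))) {
    stop("dosage, gq and dp must have identical dimensions", call. = FALSE)
  }
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("dosage must carry variant rownames and sample colnames", call. = FALSE)
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0) || any(bad > 2))) {
    stop("dosages must be in 0..2 or NA", call. = FALSE)
  }
  structure(list(dosage = dosage, gq = gq, dp = dp),
            class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf("<genotype_calls> %d variants x %d samples (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_calls <- function(x) dim(x$dosage)

# Subset calls to a sample and/or variant set (internal).
subset_calls <- function(calls, variants = NULL, samples = NULL) {
  i <- if (is.null(variants)) seq_len(nrow(calls$dosage)) else variants
  j <- if (is.null(samples)) seq_len(ncol(calls$dosage)) else samples
  genotype_calls(calls$dosage[i, j, drop = FALSE],
                 calls$gq[i, j, drop = FALSE],
                 calls$dp[i, j, drop = FALSE])
}
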