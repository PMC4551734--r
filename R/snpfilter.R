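# SNP retention filtering on multi-sample variant tables: calling quality,
# call rate, mean depth and minor allele frequency, all strict (>) by
# default.

#' SNP retention criteria
#'
#' The four retention thresholds applied to each candidate site. All are
#' strict (`>`) by default, matching the protocol's "greater than" rules:
#' a sample counts as genotyped only when its genotype quality exceeds
#' `min_quality`; the genotyped fraction of samples must exceed
#' `min_called_fraction` (25%, i.e. more than 63 of 252 samples); the mean
#' depth over genotyped samples must exceed `min_mean_depth` (5x); and the
#' minor allele frequency over genotyped samples must exceed `min_maf`
#' (0.05).
#'
#' @param min_quality genotype-quality threshold (default 20).
#' @param min_called_fraction called-fraction threshold (default 0.25).
#' @param min_mean_depth mean-depth threshold (default 5).
#' @param min_maf minor-allele-frequency threshold (default 0.05).
#' @param min_called_count optional absolute called-sample count used
#'   instead of the fraction when set (e.g. 63).
#' @param inclusive use `>=` instead of `>` for all four thresholds.
#' @param depth_over_all average depth over all samples rather than over
#'   genotyped samples only.
#' @return list of class `ggrs_criteria`.
#' @export
filter_criteria <- function(min_quality = 20, min_called_fraction = 0.25,
                            min_mean_depth = 5, min_maf = 0.05,
                            min_called_count = NULL, inclusive = FALSE,
                            depth_over_all = FALSE) {
  for (v in c(min_quality, min_called_fraction, min_mean_depth, min_maf))
    if (!is.numeric(v) || v < 0) stop("criteria must be non-negative")
  if (min_called_fraction > 1) stop("min_called_fraction must be <= 1")
  structure(list(min_quality = min_quality,
                 min_called_fraction = min_called_fraction,
                 min_mean_depth = min_mean_depth, min_maf = min_maf,
                 min_called_count = min_called_count,
                 inclusive = inclusive, depth_over_all = depth_over_all),
            class = "ggrs_criteria")
}

GT_DOSE <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)

#' Minor allele frequency of one site
#'
#' Alternate-allele count over called genotypes only (missing genotypes are
#' excluded from the denominator), folded: `min(p, 1 - p)`.
#'
#' @param gt character vector of genotypes (`0/0`, `0/1`, `1/1`, `./.`).
#' @return MAF as a fraction; `NA` when no genotype is called.
#' @examples
#' minor_allele_frequency(c("0/0", "0/0", "0/1", "1/1"))  # 3/8 = 0.375
#' @export
minor_allele_frequency <- function(gt) {
  dose <- GT_DOSE[gt]
  called <- !is.na(dose)
  if (!any(called)) return(NA_real_)
  p <- sum(dose[called]) / (2 * sum(called))
  min(p, 1 - p)
}

gt_exceeds <- function(x, thr, inclusive) {
  ok <- if (inclusive) x >= thr else x > thr
  ok & !is.na(x)
}

#' Evaluate the retention criteria for every site
#'
#' A sample's call counts as genotyped only when its genotype is present
#' and its genotype quality exceeds the quality threshold. Per-site
#' statistics and per-criterion flags are returned; multiallelic records
#' never pass.
#'
#' @param sites a `ggrs_sites` object (see [read_variant_sites()]).
#' @param criteria a [filter_criteria()] object.
#' @param n_samples cohort size used for the called fraction (defaults to
#'   the number of sample columns).
#' @return data.frame, one row per site: `n_called`, `call_fraction`,
#'   `mean_depth`, `maf`, flags `ok_called`, `ok_depth`, `ok_maf`,
#'   `multiallelic`, and the overall `pass`.
#' @export
site_passes <- function(sites, criteria = filter_criteria(), n_samples = NULL) {
  stopifnot(inherits(sites, "ggrs_sites"), inherits(criteria, "ggrs_criteria"))
  n_sites <- length(sites$chrom)
  if (is.null(n_samples)) n_samples <- length(sites$samples)
  if (n_sites == 0L)
    return(data.frame(n_called = integer(0), call_fraction = numeric(0),
                      mean_depth = numeric(0), maf = numeric(0),
                      ok_called = logical(0), ok_depth = logical(0),
                      ok_maf = logical(0), multiallelic = logical(0),
                      pass = logical(0)))
  gq_ok <- !is.na(sites$gq) & gt_exceeds(sites$gq, criteria$min_quality,
                                         criteria$inclusive)
  dose <- matrix(GT_DOSE[sites$gt], nrow = n_sites)
  genotyped <- gq_ok & !is.na(dose)
  n_called <- rowSums(genotyped)
  call_fraction <- n_called / n_samples
  dp <- sites$dp
  dp[is.na(dp)] <- 0
  mean_depth <- if (criteria$depth_over_all) rowMeans(dp)
                else rowSums(dp * genotyped) / pmax(1L, n_called)
  mean_depth[n_called == 0L & !criteria$depth_over_all] <- NA_real_
  dose_called <- dose
  dose_called[!genotyped] <- NA
  p <- rowSums(dose_called, na.rm = TRUE) / (2 * pmax(1L, n_called))
  maf <- pmin(p, 1 - p)
  maf[n_called == 0L] <- NA_real_
  ok_called <- if (!is.null(criteria$min_called_count))
    gt_exceeds(n_called, criteria$min_called_count, criteria$inclusive)
  else gt_exceeds(call_fraction, criteria$min_called_fraction, criteria$inclusive)
  ok_depth <- gt_exceeds(mean_depth, criteria$min_mean_depth, criteria$inclusive)
  ok_maf <- gt_exceeds(maf, criteria$min_maf, criteria$inclusive)
  data.frame(n_called = n_called, call_fraction = call_fraction,
             mean_depth = mean_depth, maf = maf,
             ok_called = ok_called, ok_depth = ok_depth, ok_maf = ok_maf,
             multiallelic = sites$multiallelic,
             pass = ok_called & ok_depth & ok_maf & !sites$multiallelic)
}

# subset a ggrs_sites object by site index
sites_subset <- function(sites, idx) {
  structure(list(chrom = sites$chrom[idx], pos = sites$pos[idx],
                 id = sites$id[idx], ref = sites$ref[idx],
                 alt = sites$alt[idx], samples = sites$samples,
                 gt = sites$gt[idx, , drop = FALSE],
                 dp = sites$dp[idx, , drop = FALSE],
                 gq = sites$gq[idx, , drop = FALSE],
                 multiallelic = sites$multiallelic[idx]),
            class = "ggrs_sites")
}

#' Filter a multi-sample VCF with the SNP retention criteria
#'
#' Applies [site_passes()] to every record, preserving input order among
#' retained sites, and reports per-criterion rejection counts (a site may
#' fail several criteria; the counts are non-exclusive) together with the
#' retained/rejected totals.
#'
#' @param input VCF path or a `ggrs_sites` object.
#' @param criteria a [filter_criteria()] object.
#' @param n_samples cohort size (defaults to the sample columns present).
#' @param vcf_out optional path for the retained sites (`.vcf.gz`).
#' @param summary_out optional path for the summary TSV.
#' @return list with `sites` (retained `ggrs_sites`), `verdicts`
#'   (the [site_passes()] data.frame for all input sites), and `summary`
#'   (data.frame `metric`, `count`: input/retained/rejected and the
#'   per-criterion failure counts).
#' @export
filter_vcf <- function(input, criteria = filter_criteria(), n_samples = NULL,
                       vcf_out = NULL, summary_out = NULL) {
  sites <- if (is.character(input)) read_variant_sites(input) else input
  stopifnot(inherits(sites, "ggrs_sites"))
  verdicts <- site_passes(sites, criteria, n_samples)
  keep <- verdicts$pass
  out <- sites_subset(sites, which(keep))
  smry <- data.frame(
    metric = c("input", "retained", "rejected", "fail_call_rate",
               "fail_depth", "fail_maf", "fail_multiallelic"),
    count = c(length(keep), sum(keep), sum(!keep), sum(!verdicts$ok_called),
              sum(!verdicts$ok_depth), sum(!verdicts$ok_maf),
              sum(verdicts$multiallelic)))
  if (!is.null(vcf_out) && length(out$chrom)) write_variant_sites(out, vcf_out)
  if (!is.null(summary_out))
    utils::write.table(smry, summary_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(sites = out, verdicts = verdicts, summary = smry)
}
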