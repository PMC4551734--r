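# SNP retention criteria: MAF, call rate, depth, quality; strictness and
# oracle equivalence.

test_that("minor allele frequency counts alleles over called genotypes only", {
  expect_equal(minor_allele_frequency(c("0/0", "0/0", "0/1", "1/1")), 0.375)
  expect_equal(minor_allele_frequency(rep("0/0", 5)), 0)
  expect_equal(minor_allele_frequency(c("1/1", "1/1")), 0)  # folded
  expect_equal(minor_allele_frequency(c("0/1", "./.")), 0.5)
  expect_true(is.na(minor_allele_frequency(rep("./.", 3))))
  # brute-force allele tally oracle on random sites
  set.seed(91)
  for (i in 1:20) {
    gt <- sample(c("0/0", "0/1", "1/1", "./."), 40, TRUE)
    called <- gt[gt != "./."]
    alt <- sum(called == "0/1") + 2 * sum(called == "1/1")
    p <- alt / (2 * length(called))
    expect_equal(minor_allele_frequency(gt), min(p, 1 - p))
  }
})

test_that("retention thresholds are strict, as in 'greater than'", {
  n <- 252
  mk <- function(n_called, depth, maf_dose_het) {
    gt <- c(rep("0/1", maf_dose_het), rep("0/0", n_called - maf_dose_het))
    gt <- c(gt, rep("./.", n - n_called))
    make_sites(matrix(gt, 1), matrix(rep(depth, n), 1),
               matrix(c(rep(30, n_called), rep(0, n - n_called)), 1))
  }
  crit <- filter_criteria()
  # exactly 63 of 252 called = 25%: fails (strictly more required)
  expect_false(site_passes(mk(63, 10, 30), crit)$pass)
  expect_true(site_passes(mk(64, 10, 30), crit)$pass)
  # mean depth exactly 5: fails (strict)
  expect_false(site_passes(mk(64, 5, 30), crit)$pass)
  v <- site_passes(mk(64, 5, 30), filter_criteria(inclusive = TRUE))
  expect_true(v$pass)
  # MAF exactly 0.05 fails, just above passes
  gt64 <- function(het) mk(64, 10, het)
  maf_of <- function(het) het / (2 * 64)
  expect_false(site_passes(gt64(6), crit)$ok_maf)   # 6/128 = 0.047
  expect_true(site_passes(gt64(7), crit)$ok_maf)    # 7/128 = 0.055
  # quality gate: calls at GQ <= 20 do not count as genotyped
  s <- mk(64, 10, 30)
  s$gq[1, 1:64] <- 20
  expect_equal(site_passes(s, crit)$n_called, 0)
})

test_that("filter_vcf equals the brute-force oracle and preserves site order", {
  set.seed(95)
  n_sites <- 60; n_samp <- 30
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), n_sites * n_samp, TRUE,
                      prob = c(0.5, 0.2, 0.1, 0.2)), n_sites, n_samp)
  dp <- matrix(rpois(n_sites * n_samp, 7), n_sites, n_samp)
  gq <- matrix(sample(0:60, n_sites * n_samp, TRUE), n_sites, n_samp)
  multi <- rep(FALSE, n_sites); multi[c(3, 40)] <- TRUE
  sites <- make_sites(gt, dp, gq, pos = seq_len(n_sites) * 10L,
                      multiallelic = multi)
  res <- filter_vcf(sites, filter_criteria())
  expect_equal(res$verdicts$pass, oracle_site_pass(sites))
  # order preserved, conservation holds
  keep_pos <- sites$pos[res$verdicts$pass]
  expect_equal(res$sites$pos, keep_pos)
  smry <- setNames(res$summary$count, res$summary$metric)
  expect_equal(unname(smry["retained"] + smry["rejected"]), n_sites)
  expect_true(all(res$summary$count >= 0))
  # multiallelic records never pass
  expect_false(any(res$verdicts$pass[multi]))
})

test_that("tightening any single criterion never increases the retained count", {
  set.seed(96)
  n_sites <- 80; n_samp <- 40
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), n_sites * n_samp, TRUE,
                      prob = c(0.45, 0.25, 0.1, 0.2)), n_sites, n_samp)
  dp <- matrix(rpois(n_sites * n_samp, 6), n_sites, n_samp)
  gq <- matrix(sample(0:60, n_sites * n_samp, TRUE), n_sites, n_samp)
  sites <- make_sites(gt, dp, gq)
  n_ret <- function(crit) sum(filter_vcf(sites, crit)$verdicts$pass)
  base <- n_ret(filter_criteria())
  expect_lte(n_ret(filter_criteria(min_quality = 30)), base)
  expect_lte(n_ret(filter_criteria(min_called_fraction = 0.5)), base)
  expect_lte(n_ret(filter_criteria(min_mean_depth = 8)), base)
  expect_lte(n_ret(filter_criteria(min_maf = 0.2)), base)
  # and loosening never decreases
  expect_gte(n_ret(filter_criteria(min_maf = 0.01)), base)
})

test_that("filter recovers the planted common/rare split on simulated data", {
  g <- random_genome(c(chr1 = 1.2e5), seed = 201)
  sheet <- data.frame(sample_id = sprintf("S%02d", 1:40),
                      barcode = generate_barcodes(40, seed = 202))
  cfg <- sim_config(g, sheet, depth = 25, n_snps = 60,
                    maf_range = c(0, 0.5), error_rate = 0, n_read_rate = 0,
                    dimer_fraction = 0, seed = 203)
  sim <- simulate_reads(cfg)
  calls <- genotype_calls(sim)
  res <- filter_vcf(calls, filter_criteria())
  # oracle agreement on the synthetic calls
  expect_equal(res$verdicts$pass, oracle_site_pass(calls))
  # retained sites are dominated by truly common loci (realized MAF > 0.05)
  realized_maf <- apply(sim$truth$gt, 1, function(d) {
    p <- sum(d) / (2 * length(d)); min(p, 1 - p)
  })
  expect_true(all(realized_maf[res$verdicts$pass] > 0.04))
})

test_that("empty and file-based inputs work end to end", {
  empty <- make_sites(matrix(character(0), 0, 3), matrix(numeric(0), 0, 3),
                      matrix(numeric(0), 0, 3))
  res <- filter_vcf(empty, filter_criteria())
  expect_equal(length(res$sites$chrom), 0)
  # through a VCF file
  gt <- matrix(rep(c("0/1", "0/0"), each = 4), 2, 4, byrow = TRUE)
  dp <- matrix(10, 2, 4); gq <- matrix(50, 2, 4)
  sites <- make_sites(gt, dp, gq, pos = c(10L, 20L))
  f <- file.path(withr::local_tempdir(), "in.vcf.gz")
  write_variant_sites(sites, f)
  res2 <- filter_vcf(f, filter_criteria(), summary_out = tempfile(fileext = ".tsv"))
  expect_equal(res2$verdicts$pass, c(TRUE, FALSE))  # second site MAF 0
})
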