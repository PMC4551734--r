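# Synthetic library generator: truth tables, read structure, noise models.

sim_fixture <- function(n_samples = 4, seed = 101, ...) {
  g <- random_genome(c(chr1 = 8e4, chr2 = 6e4), seed = 1)
  sheet <- data.frame(sample_id = paste0("S", seq_len(n_samples)),
                      barcode = generate_barcodes(n_samples, seed = 2))
  cfg <- sim_config(g, sheet, seed = seed, ...)
  list(genome = g, sheet = sheet, cfg = cfg)
}

test_that("plant_variants follows Hardy-Weinberg at the drawn frequency", {
  g <- random_genome(c(chr1 = 5e4), seed = 4)
  frags <- digest_genome(g)$fragments
  ids <- paste0("S", 1:500)
  tv <- plant_variants(frags, g, 30, ids, maf_range = c(0.5, 0.5), seed = 6)
  # at freq 0.5 expected heterozygosity is 0.5; binomial 3-sigma over 500x30 draws
  het <- mean(tv$gt == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / length(tv$gt)))
  # loci live inside their fragments and REF matches the genome
  expect_true(all(tv$loci$pos >= frags$start[tv$loci$frag] &
                    tv$loci$pos < frags$end[tv$loci$frag]))
  seqs <- as.character(g)
  expect_equal(tv$loci$ref,
               substring(seqs[tv$loci$chrom], tv$loci$pos + 1, tv$loci$pos + 1),
               ignore_attr = TRUE)
  expect_false(any(tv$loci$ref == tv$loci$alt))
  # degenerate settings
  expect_equal(nrow(plant_variants(frags, g, 0, ids, seed = 1)$loci), 0)
  all_ref <- plant_variants(frags, g, 10, ids, maf_range = c(0, 0), seed = 1)
  expect_true(all(all_ref$gt == 0L))
})

test_that("truth-table allele frequency converges to the drawn frequency", {
  g <- random_genome(c(chr1 = 5e4), seed = 4)
  frags <- digest_genome(g)$fragments
  tv <- plant_variants(frags, g, 20, paste0("S", 1:2000), seed = 8)
  realized <- rowMeans(tv$gt) / 2
  expect_lt(max(abs(realized - tv$loci$freq)), 0.05)
})

test_that("simulated reads carry barcode + genomic remnant and honor the clean channel", {
  fx <- sim_fixture(error_rate = 0, n_read_rate = 0, dimer_fraction = 0, n_snps = 0)
  sim <- simulate_reads(fx$cfg)
  bl <- nchar(fx$sheet$barcode[match(sim$truth_reads$sample_id, fx$sheet$sample_id)])
  # every R1 starts with its sample's barcode followed by the GWCC remnant
  expect_true(all(substr(sim$r1$seq, 1, bl) ==
                    fx$sheet$barcode[match(sim$truth_reads$sample_id, fx$sheet$sample_id)]))
  expect_true(all(substr(sim$r1$seq, bl + 1, bl + 4) %in% c("GACC", "GTCC")))
  # R2 begins with the remnant of the opposite end
  expect_true(all(substr(sim$r2$seq, 1, 4) %in% c("GACC", "GTCC")))
  expect_true(all(nchar(sim$r1$seq) == 100 & nchar(sim$r2$seq) == 100))
  # clean channel: every read passes all four filters and maps to its sample
  dm <- demux_fastq(sim$r1, sim$r2, fx$sheet)
  expect_equal(sum(dm$rejections), 0)
  expect_equal(dm$per_read$sample_id, sim$truth_reads$sample_id)
})

test_that("same seed gives byte-identical FASTQ, different seed differs", {
  fx <- sim_fixture()
  td <- withr::local_tempdir()
  p1 <- simulate_reads(fx$cfg, out_prefix = file.path(td, "a"))$paths
  p2 <- simulate_reads(fx$cfg, out_prefix = file.path(td, "b"))$paths
  expect_identical(readLines(p1$r1), readLines(p2$r1))
  expect_identical(readLines(p1$r2), readLines(p2$r2))
  cfg2 <- sim_config(fx$genome, fx$sheet, seed = 999)
  p3 <- simulate_reads(cfg2, out_prefix = file.path(td, "c"))$paths
  expect_false(identical(readLines(p1$r1), readLines(p3$r1)))
})

test_that("dimer read count is binomial around the configured fraction", {
  fx <- sim_fixture(n_samples = 6, dimer_fraction = 0.1, error_rate = 0,
                    n_read_rate = 0, depth = 8)
  sim <- simulate_reads(fx$cfg)
  n <- nrow(sim$r1)
  expect_gt(n, 1500)
  k <- sum(sim$truth_reads$dimer)
  expect_lt(abs(k - 0.1 * n), 3 * sqrt(n * 0.1 * 0.9))
})

test_that("per-sample read counts reproduce the configured dispersion", {
  g <- random_genome(c(chr1 = 6e4), seed = 31)
  sheet <- data.frame(sample_id = sprintf("S%03d", 1:252),
                      barcode = generate_barcodes(252, seed = 32))
  cfg <- sim_config(g, sheet, depth = 2, cv = 0.69, n_snps = 0, seed = 33)
  sim <- simulate_reads(cfg)
  cv <- cv_of_counts(sim$counts, exclude_top = 5, exclude_bottom = 2)
  expect_lt(abs(cv - 0.69), 0.15)
})

test_that("per-locus depth tracks the configured per-fragment depth", {
  fx <- sim_fixture(n_samples = 8, depth = 6, n_snps = 40, dimer_fraction = 0,
                    error_rate = 0, n_read_rate = 0)
  sim <- simulate_reads(fx$cfg)
  # each fragment receives ~depth reads per sample; a locus is covered by a
  # mate with probability ~ (read window)/(insert length), so mean coverage
  # is bounded by depth and well above depth/4 for 200-400 bp inserts
  mean_cov <- mean(sim$coverage)
  expect_lt(mean_cov, 6)
  expect_gt(mean_cov, 6 / 4)
  # read counts of truth table and FASTQ agree
  expect_equal(nrow(sim$truth_reads), nrow(sim$r1))
  expect_equal(unname(sim$counts), unname(table(sim$truth_reads$sample_id)[fx$sheet$sample_id]),
               ignore_attr = TRUE)
})

test_that("synthetic genotype calls reflect truth where covered", {
  fx <- sim_fixture(n_samples = 6, depth = 10, n_snps = 25, error_rate = 0,
                    n_read_rate = 0, dimer_fraction = 0)
  sim <- simulate_reads(fx$cfg)
  calls <- genotype_calls(sim)
  covered <- sim$coverage > 0
  dose <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[calls$gt[covered]]
  expect_equal(unname(dose), unname(sim$truth$gt[covered]))
  expect_true(all(calls$gt[!covered] == "./."))
  expect_true(all(calls$gq[covered] > 0))
})
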