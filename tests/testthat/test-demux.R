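# The four read filters, demultiplexing, unique reads and CV statistics.

test_that("classify_reads applies the four filters in order", {
  bc <- "ACGT"
  insert96 <- strrep("ACGT", 24)
  clean <- paste0(bc, "GACC", substr(insert96, 1, 92))
  res <- classify_reads(c(clean,
                          paste0(bc, "GGCC", substr(insert96, 1, 92)),  # W must be A/T
                          paste0(bc, "GACC", "N", substr(insert96, 1, 91)),
                          paste0("TTTT", "GACC", substr(insert96, 1, 92)),
                          paste0(bc, "GTCC", substr(ggrs_common_adapter(), 1, 92))),
                        barcodes = bc)
  expect_equal(res$reason, c("assigned", "bad_remnant", "contains_N",
                             "no_barcode", "adapter_dimer"))
  expect_equal(res$barcode[1], "ACGT")
  # read shorter than barcode + remnant
  expect_equal(classify_reads("ACGTGA", bc)$reason, "no_barcode")
  # variable-length codes resolve by longest prefix
  res2 <- classify_reads(paste0("ACGTT", "GACC", strrep("T", 91)),
                         barcodes = c("ACGT", "ACGTT"))
  expect_equal(res2$barcode, "ACGTT")
})

test_that("demultiplexing conserves reads and rejections match injected noise", {
  g <- random_genome(c(chr1 = 8e4), seed = 51)
  sheet <- data.frame(sample_id = paste0("S", 1:5),
                      barcode = generate_barcodes(5, seed = 52))
  cfg <- sim_config(g, sheet, depth = 8, n_snps = 0, error_rate = 0,
                    n_read_rate = 0.05, dimer_fraction = 0.08, seed = 53)
  sim <- simulate_reads(cfg)
  dm <- demux_fastq(sim$r1, sim$r2, sheet)
  n <- dm$n_total
  # conservation: assigned + rejected = input
  expect_equal(sum(dm$good_reads) + sum(dm$rejections), n)
  expect_equal(nrow(dm$per_read), n)
  # every dimer read is rejected, and the dimer count sits within 3 sigma
  expect_true(all(dm$per_read$reason[sim$truth_reads$dimer] != "assigned"))
  expect_lt(abs(sum(dm$per_read$reason == "adapter_dimer") - 0.08 * n),
            3 * sqrt(n * 0.08 * 0.92) + sum(sim$truth_reads$has_n))
  # every N-contaminated read is rejected (reason may be an earlier filter
  # when the N falls in the barcode or remnant)
  expect_true(all(dm$per_read$reason[sim$truth_reads$has_n] != "assigned"))
  n_rej <- sum(sim$truth_reads$has_n & !sim$truth_reads$dimer)
  expect_lt(abs(n_rej - 0.05 * (1 - 0.08) * n), 3 * sqrt(n * 0.05 * 0.95))
  # all clean reads are assigned to their true samples
  clean <- !sim$truth_reads$dimer & !sim$truth_reads$has_n
  assigned_clean <- dm$per_read$reason == "assigned" & clean
  expect_equal(dm$per_read$sample_id[assigned_clean],
               sim$truth_reads$sample_id[assigned_clean])
})

test_that("per-sample FASTQ output trims barcode + remnant and pairs stay together", {
  g <- random_genome(c(chr1 = 4e4), seed = 61)
  sheet <- data.frame(sample_id = c("S1", "S2"),
                      barcode = generate_barcodes(2, seed = 62))
  cfg <- sim_config(g, sheet, depth = 3, n_snps = 0, error_rate = 0,
                    n_read_rate = 0, dimer_fraction = 0, seed = 63)
  sim <- simulate_reads(cfg)
  td <- withr::local_tempdir()
  dm <- demux_fastq(sim$r1, sim$r2, sheet, out_dir = td)
  for (s in sheet$sample_id) {
    r1 <- read_fastq(file.path(td, paste0(s, "_R1.fastq")))
    r2 <- read_fastq(file.path(td, paste0(s, "_R2.fastq")))
    expect_equal(nrow(r1), unname(dm$good_reads[s]))
    expect_equal(r1$id, r2$id)                       # pairs kept together
    bl <- nchar(sheet$barcode[sheet$sample_id == s])
    expect_true(all(nchar(r1$seq) == 100 - bl - 4))  # barcode+remnant trimmed
    expect_true(all(nchar(r2$seq) == 100))
  }
  # empty input -> empty outputs, zero counts
  empty <- data.frame(id = character(0), seq = character(0), qual = character(0))
  dm0 <- demux_fastq(empty, empty, sheet)
  expect_equal(dm0$n_total, 0)
  expect_equal(sum(dm0$good_reads), 0)
})

test_that("unique reads count distinct (chrom, position, strand) keys", {
  pt <- data.frame(sample_id = "S1",
                   chrom = c("c1", "c1", "c1"),
                   pos = c(100, 100, 200),
                   strand = "+")
  expect_equal(unname(unique_read_count(pt)), 2L)
  expect_length(unique_read_count(pt[0, ]), 0)
  # strand-aware by default, collapsible on request
  pt2 <- data.frame(sample_id = "S1", chrom = "c1", pos = 100, strand = c("+", "-"))
  expect_equal(unname(unique_read_count(pt2)), 2L)
  expect_equal(unname(unique_read_count(pt2, ignore_strand = TRUE)), 1L)
  # random table equals an independent set-based oracle
  set.seed(71)
  big <- data.frame(sample_id = sample(c("A", "B"), 500, TRUE),
                    chrom = sample(c("c1", "c2"), 500, TRUE),
                    pos = sample(1:40, 500, TRUE),
                    strand = sample(c("+", "-"), 500, TRUE))
  got <- unique_read_count(big)
  for (s in c("A", "B")) {
    sub <- big[big$sample_id == s, ]
    expect_equal(unname(got[s]),
                 nrow(unique(sub[, c("chrom", "pos", "strand")])))
  }
})

test_that("cv_of_counts matches its definition and exclusion rule", {
  expect_equal(cv_of_counts(c(100, 200, 300), 0, 0), 0.5)  # sd 100 / mean 200
  expect_equal(cv_of_counts(rep(42, 10), 0, 0), 0)
  expect_error(cv_of_counts(c(1, 2, 3), exclude_top = 5, exclude_bottom = 2),
               "fewer than 2")
  # exclusion removes exactly the extremes
  x <- c(1000, 1, 2, 50, 60, 70, 500, 400, 300, 200)
  kept <- sort(x)[3:(length(x) - 5)]
  expect_equal(cv_of_counts(x, 5, 2), sd(kept) / mean(kept))
  # 252 lognormal draws tuned for CV 0.69 recover it within 0.15
  set.seed(81)
  mu <- 1.36e6; s <- sqrt(log(1 + 0.69^2))
  draws <- rpois(252, rlnorm(252, log(mu) - s^2 / 2, s))
  expect_lt(abs(cv_of_counts(draws, 5, 2) - 0.69), 0.15)
})
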