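# Capacity/cost arithmetic and constrained barcode/adapter design.

test_that("target_marker_count floors genome_size / spacing", {
  expect_equal(target_marker_count(1.0e9, 1e4), 100000L)
  expect_equal(target_marker_count(1e4, 1e4), 1L)
  expect_equal(target_marker_count(9999, 1e4), 0L)
})

test_that("samples_per_lane follows the lane-yield formula", {
  expect_equal(samples_per_lane(library_design()), 333L)  # 35e9/(1.05e9*0.02*5)
  expect_equal(samples_per_lane(library_design(1e6, 1e6, 1.0, 1)), 1L)
  # at the realized 2.2% coverage the same lane holds 303 samples
  expect_equal(samples_per_lane(library_design(coverage_fraction = 0.022)), 303L)
  expect_error(library_design(coverage_fraction = 0), "positive")
})

test_that("samples_per_lane is monotone in its inputs", {
  base <- samples_per_lane(library_design())
  expect_lte(samples_per_lane(library_design(coverage_fraction = 0.03)), base)
  expect_lte(samples_per_lane(library_design(target_depth = 8)), base)
  expect_gte(samples_per_lane(library_design(lane_yield_bp = 50e9)), base)
})

test_that("run capacity and per-sample cost reproduce the protocol arithmetic", {
  expect_equal(run_capacity(252, 7, 2), 3528L)
  expect_equal(run_capacity(504, 7, 2), 7056L)
  expect_equal(run_capacity(1, 1, 1), 1L)
  cost <- cost_per_sample(4500, 252)
  expect_equal(cost$per_sample, 4500 / 252, tolerance = 1e-12)
  expect_equal(cost$rounded, 18)
  expect_equal(cost_per_sample(100, 100)$per_sample, 1)
  expect_equal(cost_per_sample(4500, 450)$per_sample, 10)
})

test_that("generated barcodes satisfy every design invariant at 252-plex", {
  bc <- generate_barcodes(252, seed = 11)
  expect_length(bc, 252)
  expect_false(any(duplicated(bc)))
  expect_true(all(nchar(bc) >= 4 & nchar(bc) <= 8))
  expect_gt(length(unique(nchar(bc))), 2)              # lengths spread
  expect_false(any(grepl("GGACC|GGTCC", bc)))          # no motif inside
  expect_false(any(endsWith(bc, "G")))                 # junction rule
  # barcode + remnant never recreates the motif across the junction
  for (rem in c("GACC", "GTCC"))
    expect_false(any(grepl("GGACC|GGTCC", paste0(bc, rem))))
  # prefix-freeness on barcode + first remnant base
  bG <- paste0(sort(bc), "G")
  expect_false(any(startsWith(bG[-1], bG[-length(bG)])))
  # pairwise shared-prefix Hamming distance >= 3 (exhaustive check)
  spd <- function(a, b) {
    L <- min(nchar(a), nchar(b))
    sum(strsplit(substr(a, 1, L), "")[[1]] != strsplit(substr(b, 1, L), "")[[1]])
  }
  dmin <- min(vapply(seq_along(bc)[-1], function(i)
    min(vapply(seq_len(i - 1), function(j) spd(bc[i], bc[j]), 0L)), 0L))
  expect_gte(dmin, 3)
})

test_that("barcode generation is seed-deterministic and errors on impossible requests", {
  expect_identical(generate_barcodes(20, seed = 3), generate_barcodes(20, seed = 3))
  expect_false(identical(generate_barcodes(20, seed = 3),
                         generate_barcodes(20, seed = 4)))
  expect_length(generate_barcodes(1, seed = 1), 1)
  # the 4-mer code space cannot hold 100 codes at distance >= 3
  expect_error(generate_barcodes(100, len_min = 4, len_max = 4, seed = 1),
               "unsatisfiable")
})

test_that("adapter dimer check finds the longest reverse-complementary run", {
  a <- "ACGTACGTACGTACGTACGT"
  res <- adapter_dimer_check(a, revcomp(a), min_complement_run = 10)
  expect_equal(res$max_run, nchar(a))  # full-length complementarity
  expect_true(res$risk)
  expect_error(adapter_dimer_check("", "ACGT"), "non-empty")

  # brute-force oracle over all offset alignments on random 30-mers
  oracle_run <- function(x, y) {
    yc <- revcomp(y)
    best <- 0
    for (i in seq_len(nchar(x))) for (j in seq_len(nchar(yc))) {
      k <- 0
      while (i + k <= nchar(x) && j + k <= nchar(yc) &&
             substr(x, i + k, i + k) == substr(yc, j + k, j + k)) k <- k + 1
      best <- max(best, k)
    }
    best
  }
  set.seed(21)
  for (rep in 1:5) {
    x <- rand_seq(30); y <- rand_seq(30)
    expect_equal(adapter_dimer_check(x, y)$max_run, oracle_run(x, y))
  }

  # a 64 + 64 nt adapter pair sits in the ~128 bp dimer band
  long <- adapter_dimer_check(rand_seq(64), rand_seq(64))
  expect_equal(long$dimer_length_bp, 128)
  expect_true(long$near_dimer_band)
})
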