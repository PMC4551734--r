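# Shared fixtures, all built in code.

# Deterministic random sequence over ACGT.
rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A tiny genome whose AvaII fragment structure is easy to reason about:
# cut-site motifs separated by fixed-length spacers.
spaced_genome <- function(spacers, motifs = NULL, flank = 50L, seed = 1L) {
  set.seed(seed)
  n <- length(spacers) + 1L
  if (is.null(motifs)) motifs <- sample(c("GGACC", "GGTCC"), n, replace = TRUE)
  stopifnot(length(motifs) == n)
  parts <- character(0)
  # spacers must not create motifs at junctions: use T-only filler
  parts <- c(strrep("T", flank), motifs[1])
  for (i in seq_along(spacers)) parts <- c(parts, strrep("T", spacers[i]), motifs[i + 1L])
  parts <- c(parts, strrep("T", flank))
  paste(parts, collapse = "")
}

# Minimal sample sheet with hand-picked valid barcodes (no G at the end,
# no motif, prefix-free with remnant base G).
tiny_sheet <- function(n = 3L) {
  bc <- c("ACGT", "TGCAT", "CATTAC", "GTACA", "TTGGA", "ACCTT")[seq_len(n)]
  data.frame(sample_id = paste0("S", seq_len(n)), barcode = bc)
}

# Construct a ggrs_sites object from matrices (loci x samples).
make_sites <- function(gt, dp, gq, chrom = NULL, pos = NULL,
                       ref = NULL, alt = NULL, multiallelic = NULL) {
  n <- nrow(gt)
  samples <- colnames(gt)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  dimnames(gt) <- dimnames(dp) <- dimnames(gq) <- list(NULL, samples)
  structure(list(
    chrom = chrom %||% rep("chr1", n),
    pos = pos %||% (seq_len(n) * 100L),
    id = rep(".", n),
    ref = ref %||% rep("A", n),
    alt = alt %||% rep("C", n),
    samples = samples, gt = gt, dp = dp, gq = gq,
    multiallelic = multiallelic %||% rep(FALSE, n)),
    class = "ggrs_sites")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force site verdict, independent of site_passes(): explicit loops.
oracle_site_pass <- function(sites, min_q = 20, min_frac = 0.25,
                             min_depth = 5, min_maf = 0.05,
                             n_samples = length(sites$samples)) {
  n <- length(sites$chrom)
  out <- logical(n)
  for (i in seq_len(n)) {
    called <- character(0); depths <- numeric(0); doses <- integer(0)
    for (j in seq_along(sites$samples)) {
      g <- sites$gt[i, j]; q <- sites$gq[i, j]
      if (g %in% c("0/0", "0/1", "1/0", "1/1") && !is.na(q) && q > min_q) {
        called <- c(called, g)
        depths <- c(depths, ifelse(is.na(sites$dp[i, j]), 0, sites$dp[i, j]))
        doses <- c(doses, switch(g, "0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L))
      }
    }
    if (!length(called)) { out[i] <- FALSE; next }
    p <- sum(doses) / (2 * length(doses))
    maf <- min(p, 1 - p)
    out[i] <- !sites$multiallelic[i] &&
      (length(called) / n_samples) > min_frac &&
      mean(depths) > min_depth && maf > min_maf
  }
  out
}
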