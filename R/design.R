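# Multiplex capacity/cost planning and constrained barcode/adapter design.

#' Library design parameters
#'
#' Holds the sequencing arithmetic inputs: lane yield, genome size, the
#' fraction of the genome captured by the reduced representation, target
#' per-site depth, read length and the marker spacing implied by the extent
#' of linkage disequilibrium (LD). Defaults follow a HiSeq 2500 paired-end
#' 2 x 100 bp lane (~35 Gbp), a 2% genome fraction at 5x depth, and a 10 kb
#' LD extent.
#'
#' @param lane_yield_bp bases sequenced per lane.
#' @param genome_size_bp genome size in bp.
#' @param coverage_fraction fraction of the genome captured, in (0, 1].
#' @param target_depth desired per-site sequencing depth.
#' @param read_length read length in bp.
#' @param marker_spacing_bp desired marker spacing (LD extent) in bp.
#' @return list of class `ggrs_design`.
#' @export
library_design <- function(lane_yield_bp = 35e9, genome_size_bp = 1.05e9,
                           coverage_fraction = 0.02, target_depth = 5,
                           read_length = 100, marker_spacing_bp = 1e4) {
  stopifnot_scalar_num(lane_yield_bp, "lane_yield_bp")
  stopifnot_scalar_num(genome_size_bp, "genome_size_bp")
  stopifnot_scalar_num(coverage_fraction, "coverage_fraction")
  if (coverage_fraction > 1) stop("coverage_fraction must be in (0, 1]")
  stopifnot_scalar_num(target_depth, "target_depth")
  stopifnot_scalar_num(read_length, "read_length")
  stopifnot_scalar_num(marker_spacing_bp, "marker_spacing_bp")
  structure(list(lane_yield_bp = lane_yield_bp, genome_size_bp = genome_size_bp,
                 coverage_fraction = coverage_fraction, target_depth = target_depth,
                 read_length = read_length, marker_spacing_bp = marker_spacing_bp),
            class = "ggrs_design")
}

#' Number of genomic locations at a given marker spacing
#'
#' `floor(genome_size / spacing)`: dividing the genome size by the LD extent
#' gives the number of independently informative marker locations.
#'
#' @param genome_size_bp genome size in bp.
#' @param marker_spacing_bp marker spacing (LD extent) in bp.
#' @return integer count.
#' @examples
#' target_marker_count(1e9, 1e4)  # 100000
#' @export
target_marker_count <- function(genome_size_bp, marker_spacing_bp = 1e4) {
  stopifnot_scalar_num(genome_size_bp, "genome_size_bp")
  stopifnot_scalar_num(marker_spacing_bp, "marker_spacing_bp")
  as.integer(floor(genome_size_bp / marker_spacing_bp))
}

#' Samples that fit in one lane
#'
#' `floor(lane_yield / (genome_size x coverage_fraction x target_depth))`:
#' each sample consumes `genome x fraction x depth` bases of the lane.
#'
#' @param design a [library_design()] object.
#' @return integer sample count.
#' @export
samples_per_lane <- function(design = library_design()) {
  stopifnot(inherits(design, "ggrs_design"))
  denom <- design$genome_size_bp * design$coverage_fraction * design$target_depth
  if (denom == 0) stop("zero per-sample base requirement")
  as.integer(floor(design$lane_yield_bp / denom))
}

#' Run-level multiplex capacity
#'
#' Product of samples per channel, channels per flow cell and flow cells per
#' run. With the 252-plex library, 7 channels and 2 flow cells, 3528 samples
#' are sequenced per run.
#'
#' @param samples_per_channel samples pooled per channel (lane).
#' @param channels_per_flowcell channels per flow cell.
#' @param flowcells_per_run flow cells per run.
#' @return integer capacity.
#' @examples
#' run_capacity()            # 3528
#' run_capacity(504, 7, 2)   # 7056
#' @export
run_capacity <- function(samples_per_channel = 252L, channels_per_flowcell = 7L,
                         flowcells_per_run = 2L) {
  for (v in list(samples_per_channel, channels_per_flowcell, flowcells_per_run))
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("capacity inputs must be positive integers")
  as.integer(samples_per_channel * channels_per_flowcell * flowcells_per_run)
}

#' Per-sample sequencing cost
#'
#' @param total_cost_usd total run cost in USD.
#' @param n_samples number of samples sharing the cost.
#' @return list with `per_sample` (raw) and `rounded` (nearest dollar).
#' @examples
#' cost_per_sample(4500, 252)  # $17.86, rounds to $18
#' @export
cost_per_sample <- function(total_cost_usd, n_samples) {
  stopifnot_scalar_num(total_cost_usd, "total_cost_usd")
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1)
    stop("n_samples must be a positive integer")
  raw <- total_cost_usd / n_samples
  list(per_sample = raw, rounded = round(raw))
}

# --- barcode design -------------------------------------------------------

# Does `b` satisfy the per-barcode constraints for `enz`?
# - alphabet {A,C,G,T}
# - contains no literal expansion of the recognition motif
# - barcode + remnant must not recreate the motif across the junction:
#   sufficient to forbid any suffix of the barcode that, extended by the
#   remnant, matches the motif. For AvaII (G^GWCC) this reduces to
#   "must not end in G".
barcode_ok <- function(b, enz, lits = expand_motif(enz$motif),
                       head_lits = expand_motif(substr(enz$motif, 1L, enz$cut_offset))) {
  if (grepl("[^ACGT]", b)) return(FALSE)
  for (m in lits) if (grepl(m, b, fixed = TRUE)) return(FALSE)
  for (h in head_lits) if (endsWith(b, h)) return(FALSE)
  TRUE
}

# Hamming distance over the shared prefix length.
shared_prefix_dist <- function(a, b) {
  L <- min(nchar(a), nchar(b))
  sum(strsplit(substr(a, 1L, L), "")[[1L]] != strsplit(substr(b, 1L, L), "")[[1L]])
}

#' Generate a set of demultiplexing barcodes
#'
#' Randomized greedy construction of `n` variable-length barcodes subject to:
#' no occurrence of the enzyme's recognition motif inside the barcode; the
#' barcode must not recreate the motif when followed by the cut-site remnant
#' (for AvaII: must not end in `G`, since `G` + `GWCC` = `GGWCC`);
#' prefix-freeness of the `barcode + first remnant base` strings, so
#' longest-prefix demultiplexing of variable-length codes is unambiguous; and
#' pairwise Hamming distance over the shared prefix length of at least
#' `min_dist`. The construction is deterministic given `seed`.
#'
#' With the distance constraint computed over shared prefixes, short codes
#' are strongly constrained against every other code, so realized lengths
#' concentrate toward `len_max`; an explicit capacity error is raised when
#' the constraints cannot be satisfied for the requested `n`.
#'
#' @param n number of barcodes (e.g. 252 for the 252-plex library).
#' @param len_min,len_max inclusive barcode length range (default 4-8).
#' @param min_dist minimum pairwise shared-prefix Hamming distance
#'   (default 3: detects single errors and avoids most collisions).
#' @param enz a [enzyme()] object.
#' @param seed RNG seed (mandatory; same seed gives identical output).
#' @param max_tries candidate budget before declaring the constraints
#'   unsatisfiable.
#' @return character vector of `n` barcodes.
#' @export
generate_barcodes <- function(n, len_min = 4L, len_max = 8L, min_dist = 3L,
                              enz = enzyme(), seed, max_tries = 2000L * n) {
  if (missing(seed)) stop("seed is mandatory for generate_barcodes()")
  if (!is.numeric(n) || n < 1L) stop("n must be >= 1")
  if (len_min > len_max || len_min < 1L) stop("invalid length range")
  n <- as.integer(n)
  lits <- expand_motif(enz$motif)
  head_lits <- expand_motif(substr(enz$motif, 1L, enz$cut_offset))
  with_seed(seed, {
    # Small fully-enumerable spaces: exhaustively screen candidates so the
    # capacity error is exact rather than budget-dependent.
    n_space <- sum(4^(len_min:len_max))
    exhaustive <- n_space <= 70000
    if (exhaustive) {
      cand <- unlist(lapply(len_min:len_max, function(L) {
        g <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), L),
                                    stringsAsFactors = FALSE))
        apply(g, 1L, paste, collapse = "")
      }))
      cand <- cand[vapply(cand, barcode_ok, TRUE, enz = enz,
                          lits = lits, head_lits = head_lits)]
      cand <- sample(cand)  # random order, seed-deterministic
    }
    acc <- character(0)
    # accepted set as a padded character matrix for vectorized distance checks
    accm <- matrix(NA_character_, 0L, len_max)
    acclen <- integer(0)
    compatible <- function(b) {
      if (!length(acc)) return(TRUE)
      bl <- nchar(b)
      bch <- strsplit(b, "")[[1L]]
      L <- pmin(acclen, bl)
      cmp <- accm[, seq_len(bl), drop = FALSE]
      neq <- sweep(cmp, 2L, bch, FUN = "!=")
      neq[is.na(neq)] <- FALSE
      d <- rowSums(neq)
      # distance beyond each shared prefix is ignored: recompute for rows
      # where the shared prefix is shorter than bl
      short <- which(acclen < bl)
      for (i in short) d[i] <- sum(neq[i, seq_len(acclen[i])])
      if (any(d < min_dist)) return(FALSE)
      # prefix-freeness on barcode + first remnant base
      bG <- paste0(b, substr(enz$remnant, 1L, 1L))
      aG <- paste0(acc, substr(enz$remnant, 1L, 1L))
      if (any(startsWith(bG, aG) | startsWith(aG, bG))) return(FALSE)
      TRUE
    }
    add <- function(b) {
      acc <<- c(acc, b)
      row <- rep(NA_character_, len_max)
      row[seq_len(nchar(b))] <- strsplit(b, "")[[1L]]
      accm <<- rbind(accm, row)
      acclen <<- c(acclen, nchar(b))
    }
    if (exhaustive) {
      for (b in cand) {
        if (length(acc) >= n) break
        if (compatible(b)) add(b)
      }
      if (length(acc) < n)
        stop("barcode constraints unsatisfiable: only ", length(acc),
             " of ", n, " codes exist for lengths ", len_min, "-", len_max,
             " at min_dist ", min_dist)
    } else {
      tries <- 0L
      while (length(acc) < n && tries < max_tries) {
        tries <- tries + 1L
        L <- if (len_min == len_max) len_min else sample(len_min:len_max, 1L)
        b <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
        if (!barcode_ok(b, enz, lits, head_lits)) next
        if (compatible(b)) add(b)
      }
      if (length(acc) < n)
        stop("barcode constraints unsatisfiable within the candidate budget: ",
             length(acc), " of ", n, " found")
    }
    unname(acc)
  })
}

#' Check two adapter strands for dimer-forming complementarity
#'
#' Reports the longest reverse-complementary run between the two single
#' strands over all offset alignments (brute-force diagonal scan of the
#' complementarity matrix) and flags dimer risk when the run reaches
#' `min_complement_run`. Also reports the expected dimer product length
#' (sum of the adapter lengths) and flags it when it falls near the
#' adapter-dimer band seen on electropherograms (~128 bp).
#'
#' @param adapter_a,adapter_b adapter strand sequences (5'->3').
#' @param min_complement_run run length at or above which risk is flagged.
#' @param dimer_band_bp,dimer_band_tol expected dimer band and +/- tolerance.
#' @return list with `max_run`, `risk`, `dimer_length_bp`, `near_dimer_band`.
#' @export
adapter_dimer_check <- function(adapter_a, adapter_b, min_complement_run = 10L,
                                dimer_band_bp = 128L, dimer_band_tol = 20L) {
  for (a in c(adapter_a, adapter_b))
    if (!is.character(a) || length(a) != 1L || !nzchar(a))
      stop("adapters must be non-empty strings")
  a <- strsplit(toupper(adapter_a), "")[[1L]]
  b <- strsplit(revcomp(toupper(adapter_b)), "")[[1L]]
  na <- length(a); nb <- length(b)
  eq <- outer(a, b, "==")
  max_run <- 0L
  for (off in seq(-(na - 1L), nb - 1L)) {
    i <- max(1L, 1L - off); j <- i + off
    run <- 0L
    while (i <= na && j <= nb) {
      run <- if (eq[i, j]) run + 1L else 0L
      if (run > max_run) max_run <- run
      i <- i + 1L; j <- j + 1L
    }
  }
  dl <- nchar(adapter_a) + nchar(adapter_b)
  list(max_run = max_run,
       risk = max_run >= min_complement_run,
       dimer_length_bp = dl,
       near_dimer_band = abs(dl - dimer_band_bp) <= dimer_band_tol)
}

#' Capacity and cost plan
#'
#' Combines [samples_per_lane()], [target_marker_count()], [run_capacity()]
#' and [cost_per_sample()] into one report.
#'
#' @param design a [library_design()] object.
#' @param samples_per_channel realized plexity per channel (default 252).
#' @param channels_per_flowcell,flowcells_per_run run geometry.
#' @param total_cost_usd total cost per channel in USD.
#' @return named list of the plan quantities.
#' @export
plan_run <- function(design = library_design(), samples_per_channel = 252L,
                     channels_per_flowcell = 7L, flowcells_per_run = 2L,
                     total_cost_usd = 4500) {
  cost <- cost_per_sample(total_cost_usd, samples_per_channel)
  list(target_markers = target_marker_count(design$genome_size_bp,
                                            design$marker_spacing_bp),
       samples_per_lane = samples_per_lane(design),
       samples_per_channel = as.integer(samples_per_channel),
       run_capacity = run_capacity(samples_per_channel, channels_per_flowcell,
                                   flowcells_per_run),
       cost_per_sample_usd = cost$per_sample,
       cost_per_sample_usd_rounded = cost$rounded)
}
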