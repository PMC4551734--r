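# Synthetic GGRS library generator: a toy genome, planted variant truth
# sets, and paired-end reads with the library structure produced by the
# protocol (barcode + cut-site remnant + insert), plus configurable
# sequencing noise and adapter-dimer contamination.

#' Read-through sequence of the common adapter
#'
#' The sequence that appears in R1 when the insert is shorter than the read:
#' the reverse complement of the common-adapter amplification primer.
#' @return character scalar.
#' @export
ggrs_common_adapter <- function() {
  revcomp("CAAGCAGAAGACGGCATACGAGATCGGTCTCGGCATTCCTGCTGAACCGCTCTTCCGATCT")
}

# Read-through sequence on the R2 side (barcode-adapter primer, revcomp).
ggrs_barcode_adapter <- function() {
  revcomp("AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT")
}

#' Generate a random toy genome
#'
#' Uniform i.i.d. bases at a given GC content; used as the reference for the
#' end-to-end demonstration and for property tests. Contains no N bases.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param gc GC content in (0, 1).
#' @param seed RNG seed (mandatory).
#' @return `DNAStringSet`.
#' @export
random_genome <- function(chrom_lengths = c(chr1 = 5e5, chr2 = 5e5),
                          gc = 0.45, seed) {
  if (missing(seed)) stop("seed is mandatory for random_genome()")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(chrom_lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, "")
    Biostrings::DNAStringSet(seqs)
  })
}

#' Simulation configuration
#'
#' Bundles and validates all inputs of [simulate_reads()]. Defaults mirror
#' the 252-plex chicken library: AvaII digestion with a 200-400 bp size
#' window, 2 x 100 bp reads, per-sample read counts drawn lognormal with a
#' coefficient of variation of 0.69, a small substitution-error rate
#' consistent with >Q30 average base quality, sparse per-read N
#' contamination, and a small adapter-dimer read fraction (dimers are rare
#' in a well-built library but not absent).
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param sample_sheet data.frame `sample_id`, `barcode`.
#' @param enz a [enzyme()] object.
#' @param min_len,max_len fragment size-selection window (bp).
#' @param depth target reads per fragment per sample; the expected
#'   per-sample read count is `depth x number of selected fragments` unless
#'   `reads_per_sample` is given.
#' @param reads_per_sample expected good-read count per sample (overrides
#'   `depth`).
#' @param cv lognormal dispersion of per-sample expected read counts
#'   (CV = sd/mean).
#' @param read_length read length (bp) for both mates.
#' @param error_rate per-base substitution error rate.
#' @param n_read_rate per-read probability of N contamination (1-3 N bases
#'   at uniform positions in R1).
#' @param dimer_fraction fraction of reads that are adapter-dimer products
#'   (barcode + remnant + common adapter, no insert).
#' @param n_snps number of variant loci to plant in the selected fragments.
#' @param maf_range uniform range for the planted alternate-allele
#'   frequency.
#' @param common_adapter common-adapter read-through sequence.
#' @param seed RNG seed (mandatory).
#' @return list of class `ggrs_simconfig`.
#' @export
sim_config <- function(genome, sample_sheet, enz = enzyme(),
                       min_len = 200L, max_len = 400L,
                       depth = 5, reads_per_sample = NULL, cv = 0.69,
                       read_length = 100L, error_rate = 0.001,
                       n_read_rate = 0.005, dimer_fraction = 0.01,
                       n_snps = 100L, maf_range = c(0.05, 0.5),
                       common_adapter = ggrs_common_adapter(), seed) {
  if (missing(seed)) stop("seed is mandatory for sim_config()")
  sample_sheet <- validate_sample_sheet(sample_sheet)
  for (r in c(error_rate, n_read_rate, dimer_fraction))
    if (!is.numeric(r) || r < 0 || r > 1) stop("rates must be in [0, 1]")
  if (cv < 0) stop("cv must be >= 0")
  stopifnot(length(maf_range) == 2L, maf_range[1] >= 0, maf_range[2] <= 1,
            maf_range[1] <= maf_range[2])
  structure(list(genome = genome, sample_sheet = sample_sheet, enz = enz,
                 min_len = min_len, max_len = max_len, depth = depth,
                 reads_per_sample = reads_per_sample, cv = cv,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, n_read_rate = n_read_rate,
                 dimer_fraction = dimer_fraction, n_snps = as.integer(n_snps),
                 maf_range = maf_range, common_adapter = toupper(common_adapter),
                 seed = as.integer(seed)),
            class = "ggrs_simconfig")
}

#' Plant variant loci in selected fragments
#'
#' Places `n_snps` biallelic loci uniformly within the fragment set (distinct
#' positions), draws the alternate-allele frequency uniformly from
#' `maf_range`, and samples per-sample genotypes under Hardy-Weinberg
#' (alternate-allele dosage ~ Binomial(2, freq)). The in-fragment bases of
#' the flanking recognition motifs are excluded via `exclude_ends`: a
#' variant inside the recognition site would abolish the cut site (allele
#' dropout), which this generator does not model.
#'
#' @param fragments data.frame `chrom,start,end,length` (selected fragments).
#' @param genome `DNAStringSet` or named character vector (for REF bases).
#' @param n_snps number of loci.
#' @param sample_ids character vector of samples to genotype.
#' @param maf_range uniform frequency range.
#' @param seed RNG seed (mandatory).
#' @param exclude_ends bases excluded at the fragment 5' and 3' ends
#'   (defaults: the AvaII remnant length 4 and the pre-cut base 1).
#' @return list with `loci` (data.frame `chrom,pos,ref,alt,freq,frag`;
#'   `pos` 0-based) and `gt` (integer dosage matrix, loci x samples).
#' @export
plant_variants <- function(fragments, genome, n_snps, sample_ids,
                           maf_range = c(0.05, 0.5), seed,
                           exclude_ends = c(4L, 1L)) {
  if (missing(seed)) stop("seed is mandatory for plant_variants()")
  seqs <- as_genome_chr(genome)
  n_snps <- as.integer(n_snps)
  empty <- list(loci = data.frame(chrom = character(0), pos = integer(0),
                                  ref = character(0), alt = character(0),
                                  freq = numeric(0), frag = integer(0)),
                gt = matrix(0L, 0L, length(sample_ids),
                            dimnames = list(NULL, sample_ids)))
  if (n_snps == 0L || !nrow(fragments)) return(empty)
  lo <- as.integer(exclude_ends[1]); hi <- as.integer(exclude_ends[2])
  interior <- fragments$length - lo - hi
  if (all(interior <= 0L)) stop("no fragment interior to place variants in")
  with_seed(seed, {
    # uniform over the pooled interior bp, distinct positions
    frag_idx <- integer(0); pos <- integer(0)
    for (i in 1:50) {
      need <- n_snps - length(pos)
      if (need <= 0L) break
      f <- sample.int(nrow(fragments), need, replace = TRUE,
                      prob = pmax(0L, interior))
      o <- floor(stats::runif(need) * interior[f])
      p <- fragments$start[f] + lo + as.integer(o)
      key <- paste(fragments$chrom[f], p)
      keep <- !duplicated(key) & !(key %in% paste(fragments$chrom[frag_idx], pos))
      frag_idx <- c(frag_idx, f[keep]); pos <- c(pos, p[keep])
    }
    if (length(pos) < n_snps)
      stop("could not place ", n_snps, " distinct loci in the fragment set")
    ord <- order(fragments$chrom[frag_idx], pos)
    frag_idx <- frag_idx[ord]; pos <- pos[ord]
    chrom <- fragments$chrom[frag_idx]
    ref <- substring(seqs[chrom], pos + 1L, pos + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  "", USE.NAMES = FALSE)
    freq <- stats::runif(n_snps, maf_range[1], maf_range[2])
    gt <- matrix(stats::rbinom(n_snps * length(sample_ids), 2L, rep(freq, length(sample_ids))),
                 nrow = n_snps, ncol = length(sample_ids),
                 dimnames = list(NULL, sample_ids))
    list(loci = data.frame(chrom = chrom, pos = pos, ref = unname(ref),
                           alt = alt, freq = freq, frag = frag_idx),
         gt = gt)
  })
}

# append read-through filler so every read has length read_len
pad_reads <- function(x, read_len, filler) {
  deficit <- read_len - nchar(x)
  short <- which(deficit > 0L)
  if (length(short)) {
    fill <- paste0(filler, strrep("A", read_len))
    x[short] <- paste0(x[short], substring(fill, 1L, deficit[short]))
  }
  substring(x, 1L, read_len)
}

#' Simulate a paired-end GGRS library
#'
#' Digests the genome, plants variant loci, draws per-sample read counts
#' from a lognormal with the configured CV, and assembles reads with the
#' library structure: R1 = barcode + cut-site remnant + fragment 5' sequence
#' (the remnant `GWCC` is the first four bases of every fragment, with W
#' taken from the actual genomic site), R2 = the remnant plus reverse
#' complement of the fragment's other end. Each molecule's barcode end is
#' chosen at random, alternate alleles are substituted according to the true
#' genotype (heterozygotes transmit either allele with probability 1/2 per
#' read), reads shorter than the read length continue into the adapter,
#' substitution errors and per-read N contamination are injected, and a
#' configured fraction of reads are adapter-dimer products with no insert.
#' Base qualities are constant Q35.
#'
#' @param config a [sim_config()] object.
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>_R1.fastq`, `<prefix>_R2.fastq`, `<prefix>_truth_reads.tsv`
#'   and `<prefix>_truth_loci.vcf.gz`.
#' @return list with `r1`, `r2` (data.frames `id,seq,qual`), `truth_reads`
#'   (per-read truth: `read_id,sample_id,frag,chrom,pos,strand,dimer,has_n`),
#'   `truth` (the [plant_variants()] result), `coverage` (loci x samples
#'   matrix of covering mates), `fragments`, `counts` (per-sample read
#'   counts) and `paths` (when written).
#' @export
simulate_reads <- function(config, out_prefix = NULL) {
  stopifnot(inherits(config, "ggrs_simconfig"))
  cfg <- config
  with_seed(cfg$seed, {
    dg <- digest_genome(cfg$genome, cfg$enz, cfg$min_len, cfg$max_len)
    frags <- dg$fragments
    rem_len <- nchar(cfg$enz$remnant)
    too_short <- frags$length < rem_len
    if (any(too_short)) {
      warning(sum(too_short), " fragment(s) shorter than the remnant skipped")
      frags <- frags[!too_short, , drop = FALSE]
    }
    if (!nrow(frags)) stop("no selected fragments to sequence")
    seqs <- as_genome_chr(cfg$genome)
    # ligated insert: fragment plus the first motif bases of the downstream
    # site, so both ends start with the remnant after (reverse) reading
    ext <- nchar(cfg$enz$motif) - cfg$enz$cut_offset - 1L
    ins <- substring(seqs[frags$chrom], frags$start + 1L, frags$end + ext)
    truth <- plant_variants(frags, cfg$genome, cfg$n_snps,
                            cfg$sample_sheet$sample_id, cfg$maf_range,
                            seed = sample.int(.Machine$integer.max, 1L),
                            exclude_ends = c(rem_len, cfg$enz$cut_offset))
    n_samples <- nrow(cfg$sample_sheet)
    mu <- if (!is.null(cfg$reads_per_sample)) cfg$reads_per_sample
          else cfg$depth * nrow(frags)
    sigma <- sqrt(log(1 + cfg$cv^2))
    lam <- stats::rlnorm(n_samples, log(mu) - sigma^2 / 2, sigma)
    counts <- stats::rpois(n_samples, lam)
    total <- sum(counts)
    if (total == 0L) stop("no reads to simulate; increase depth")
    samp <- rep.int(seq_len(n_samples), counts)
    barcode <- cfg$sample_sheet$barcode[samp]
    bl <- nchar(barcode)
    dimer <- stats::runif(total) < cfg$dimer_fraction
    frag_of <- sample.int(nrow(frags), total, replace = TRUE)
    fwd <- stats::runif(total) < 0.5
    template <- ifelse(fwd, ins[frag_of], NA_character_)
    rc_ins <- revcomp(ins)
    template[!fwd] <- rc_ins[frag_of[!fwd]]
    ins_len <- nchar(ins)[frag_of]

    # substitute alternate alleles per true genotype
    loci <- truth$loci
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (nrow(loci)) {
      for (l in seq_len(nrow(loci))) {
        rs <- which(frag_of == loci$frag[l] & !dimer)
        if (!length(rs)) next
        dose <- truth$gt[l, samp[rs]]
        carry <- stats::runif(length(rs)) < dose / 2
        rs <- rs[carry]
        if (!length(rs)) next
        o_fwd <- loci$pos[l] - frags$start[loci$frag[l]]
        for (dir in c(TRUE, FALSE)) {
          sel <- rs[fwd[rs] == dir]
          if (!length(sel)) next
          off <- if (dir) o_fwd else ins_len[sel][1L] - 1L - o_fwd
          base <- if (dir) loci$alt[l] else comp[[loci$alt[l]]]
          substr(template[sel], off + 1L, off + 1L) <- base
        }
      }
    }

    rl <- cfg$read_length
    r1 <- paste0(barcode, substring(template, 1L, rl - bl))
    rc_template <- revcomp(template)
    r2 <- substring(rc_template, 1L, rl)
    # adapter-dimer reads: barcode + remnant (random W etc.) + common adapter
    if (any(dimer)) {
      nd <- sum(dimer)
      rem <- expand_motif(cfg$enz$remnant)
      rrem <- rem[sample.int(length(rem), nd, replace = TRUE)]
      r1[dimer] <- paste0(barcode[dimer], rrem, cfg$common_adapter)
      r2[dimer] <- paste0(rrem, ggrs_barcode_adapter())
    }
    r1 <- pad_reads(r1, rl, cfg$common_adapter)
    r2 <- pad_reads(r2, rl, ggrs_barcode_adapter())

    # substitution errors, independent per mate
    inject_errors <- function(x) {
      n_err <- stats::rbinom(1L, length(x) * rl, cfg$error_rate)
      if (n_err == 0L) return(x)
      i <- sample.int(length(x), n_err, replace = TRUE)
      p <- sample.int(rl, n_err, replace = TRUE)
      for (k in seq_len(n_err)) {
        old <- substr(x[i[k]], p[k], p[k])
        substr(x[i[k]], p[k], p[k]) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
      x
    }
    r1 <- inject_errors(r1)
    r2 <- inject_errors(r2)
    # per-read N contamination (R1, the filtered mate)
    has_n <- stats::runif(total) < cfg$n_read_rate
    for (i in which(has_n)) {
      k <- sample.int(3L, 1L)
      p <- sample.int(rl, k)
      for (pp in p) substr(r1[i], pp, pp) <- "N"
    }

    # per-locus covering mates for synthetic genotype calls
    coverage <- matrix(0L, nrow(loci), n_samples,
                       dimnames = list(NULL, cfg$sample_sheet$sample_id))
    if (nrow(loci)) {
      for (l in seq_len(nrow(loci))) {
        rs <- which(frag_of == loci$frag[l] & !dimer)
        if (!length(rs)) next
        o_fwd <- loci$pos[l] - frags$start[loci$frag[l]]
        t_off <- ifelse(fwd[rs], o_fwd, ins_len[rs] - 1L - o_fwd)
        cov <- (t_off <= rl - bl[rs] - 1L) + (ins_len[rs] - 1L - t_off <= rl - 1L)
        agg <- rowsum(cov, samp[rs])
        coverage[l, as.integer(rownames(agg))] <- as.integer(agg)
      }
    }

    id <- paste0(cfg$sample_sheet$sample_id[samp], ":",
                 ifelse(dimer, "dimer", frag_of), ":", seq_len(total))
    qual <- strrep(rawToChar(as.raw(35L + 33L)), rl)
    r1df <- data.frame(id = id, seq = r1, qual = qual)
    r2df <- data.frame(id = id, seq = r2, qual = qual)
    truth_reads <- data.frame(
      read_id = id,
      sample_id = cfg$sample_sheet$sample_id[samp],
      frag = ifelse(dimer, NA_integer_, frag_of),
      chrom = ifelse(dimer, NA_character_, frags$chrom[frag_of]),
      pos = ifelse(dimer, NA_integer_,
                   ifelse(fwd, frags$start[frag_of], frags$end[frag_of] + ext - 1L)),
      strand = ifelse(dimer, NA_character_, ifelse(fwd, "+", "-")),
      dimer = dimer, has_n = has_n)
    out <- list(r1 = r1df, r2 = r2df, truth_reads = truth_reads, truth = truth,
                coverage = coverage, fragments = frags,
                counts = stats::setNames(counts, cfg$sample_sheet$sample_id))
    if (!is.null(out_prefix)) {
      paths <- list(r1 = paste0(out_prefix, "_R1.fastq"),
                    r2 = paste0(out_prefix, "_R2.fastq"),
                    truth_reads = paste0(out_prefix, "_truth_reads.tsv"),
                    truth_loci = paste0(out_prefix, "_truth_loci.vcf.gz"))
      write_fastq(r1df, paths$r1)
      write_fastq(r2df, paths$r2)
      utils::write.table(truth_reads, paths$truth_reads, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      if (nrow(loci)) write_variant_sites(genotype_calls(out, min_gq_dp = 0L),
                                          paths$truth_loci)
      out$paths <- paths
    }
    out
  })
}

#' Synthetic genotype calls from simulation truth
#'
#' Converts a [simulate_reads()] result into a multi-sample variant-site
#' table that stands where an external aligner + caller would sit in the
#' real pipeline: per-sample depth is the number of simulated mates covering
#' the locus, the genotype is the true genotype when depth is positive and
#' missing otherwise, and the genotype quality is a saturating function of
#' depth (`GQ = min(99, gq_per_read x DP)`), so shallow samples fail a
#' GQ > 20 screen just as real low-coverage calls do.
#'
#' @param sim a [simulate_reads()] result.
#' @param gq_per_read GQ contributed per covering mate (default 12).
#' @param min_gq_dp depth below which the genotype is set missing (default 1).
#' @return a `ggrs_sites` object (see [read_variant_sites()]).
#' @export
genotype_calls <- function(sim, gq_per_read = 12, min_gq_dp = 1L) {
  loci <- sim$truth$loci
  gtm <- sim$truth$gt
  dp <- sim$coverage
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gtm + 1L], nrow(gtm), ncol(gtm),
                   dimnames = dimnames(gtm))
  miss <- dp < max(1L, min_gq_dp)
  if (min_gq_dp > 0L) gt_str[miss] <- "./."
  gq <- gq_per_read * dp
  gq[gq > 99] <- 99
  structure(list(chrom = loci$chrom, pos = loci$pos,
                 id = rep(".", nrow(loci)),
                 ref = loci$ref, alt = loci$alt,
                 samples = colnames(gtm),
                 gt = gt_str, dp = dp, gq = gq,
                 multiallelic = rep(FALSE, nrow(loci))),
            class = "ggrs_sites")
}
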