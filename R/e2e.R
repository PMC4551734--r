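# End-to-end demonstration: digest -> plan -> barcodes -> simulate ->
# demux -> filter -> report on a synthetic toy genome, with a run manifest.

#' Write a run manifest
#'
#' Records tool version, subcommand, parameter map, seed, md5 digests of the
#' input/output files and timestamps as JSON. Reruns with identical inputs
#' and seed produce identical manifests up to the timestamps.
#'
#' @param path output JSON path.
#' @param subcommand name of the stage being recorded.
#' @param params named list of parameters.
#' @param seed the RNG seed used (or `NA` for deterministic stages).
#' @param files character vector of input/output paths to digest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, subcommand, params, seed = NA, files = character(0)) {
  files <- files[file.exists(files)]
  manifest <- list(
    tool = "ggrs",
    version = as.character(utils::packageVersion("ggrs")),
    subcommand = subcommand,
    seed = seed,
    params = params,
    file_md5 = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Run the whole pipeline on a synthetic toy genome
#'
#' Generates a random genome, digests it with AvaII and size-selects
#' 200-400 bp fragments, designs barcodes, simulates a multiplexed
#' paired-end library with planted variants, demultiplexes it with the four
#' read filters, builds synthetic genotype calls, applies the SNP retention
#' criteria, and produces the density/occupancy reports. Accuracy metrics
#' are computed against the simulation truth. All outputs plus a manifest
#' are written under `out_dir`.
#'
#' @param out_dir output directory (created).
#' @param seed RNG seed driving every stochastic stage.
#' @param n_samples number of multiplexed samples.
#' @param chrom_lengths named lengths of the toy chromosomes.
#' @param depth reads per fragment per sample.
#' @param n_snps planted variant loci.
#' @param error_rate,n_read_rate,dimer_fraction noise settings (see
#'   [sim_config()]).
#' @param quiet suppress the progress messages.
#' @return list with `metrics` (demux accuracy, good-read fraction,
#'   CV of good reads, SNP filter recovery), the stage results and the
#'   manifest.
#' @export
run_ggrs_e2e <- function(out_dir = tempfile("ggrs_e2e_"), seed = 1L,
                         n_samples = 48L,
                         chrom_lengths = c(chr1 = 6e5, chr2 = 4e5),
                         depth = 5, n_snps = 150L, error_rate = 0.001,
                         n_read_rate = 0.005, dimer_fraction = 0.01,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  enz <- enzyme()
  say("1/7 toy genome + in silico digestion")
  genome <- random_genome(chrom_lengths, seed = seed)
  write_fasta(genome, file.path(out_dir, "toy_genome.fa"))
  dg <- digest_genome(genome, enz,
                      bed = file.path(out_dir, "fragments.bed"),
                      summary = file.path(out_dir, "digest_summary.tsv"))
  say("   ", dg$totals[["n_selected"]], " fragments selected (200-400 bp)")

  say("2/7 capacity plan")
  plan <- plan_run(library_design(genome_size_bp = genome_length(genome)))
  jsonlite::write_json(plan, file.path(out_dir, "plan.json"),
                       auto_unbox = TRUE, digits = NA)

  say("3/7 barcode design")
  barcodes <- generate_barcodes(n_samples, seed = seed + 1L)
  sheet <- data.frame(sample_id = sprintf("S%03d", seq_len(n_samples)),
                      barcode = barcodes)
  write_sample_sheet(sheet, file.path(out_dir, "barcodes.tsv"))

  say("4/7 library simulation")
  cfg <- sim_config(genome, sheet, enz, depth = depth, n_snps = n_snps,
                    error_rate = error_rate, n_read_rate = n_read_rate,
                    dimer_fraction = dimer_fraction, seed = seed + 2L)
  sim <- simulate_reads(cfg, out_prefix = file.path(out_dir, "sim"))
  say("   ", nrow(sim$r1), " read pairs simulated")

  say("5/7 demultiplexing")
  dm <- demux_fastq(sim$r1, sim$r2, sheet, enz)
  assigned <- dm$per_read$reason == "assigned"
  accuracy <- if (any(assigned))
    mean(dm$per_read$sample_id[assigned] ==
           sim$truth_reads$sample_id[assigned]) else NA_real_
  cv_good <- cv_of_counts(dm$good_reads,
                          exclude_top = min(5L, n_samples %/% 10L),
                          exclude_bottom = min(2L, n_samples %/% 20L))

  say("6/7 SNP retention filtering")
  calls <- genotype_calls(sim)
  flt <- filter_vcf(calls, filter_criteria(),
                    vcf_out = file.path(out_dir, "retained.vcf.gz"),
                    summary_out = file.path(out_dir, "filter_summary.tsv"))
  retained <- flt$sites

  say("7/7 reports")
  sizes_mbp <- stats::setNames(as.numeric(chrom_lengths) / 1e6, names(chrom_lengths))
  rep_tab <- NULL
  occ <- NULL
  dist <- NULL
  if (length(retained$chrom)) {
    pos <- data.frame(chrom = retained$chrom, pos = retained$pos)
    counts <- as.data.frame(table(factor(pos$chrom, levels = names(chrom_lengths))))
    per_chrom <- data.frame(chrom = names(chrom_lengths), size_mbp = sizes_mbp,
                            snps = counts$Freq)
    rep_tab <- density_table(per_chrom)
    utils::write.table(rep_tab$table, file.path(out_dir, "density_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    occ <- block_occupancy(pos, chrom_lengths)
    dist <- adjacent_distances(pos)
  }

  truth_maf <- pmin(sim$truth$loci$freq, 1 - sim$truth$loci$freq)
  metrics <- list(
    n_fragments = unname(dg$totals[["n_selected"]]),
    n_reads = nrow(sim$r1),
    good_read_fraction = sum(dm$good_reads) / dm$n_total,
    demux_accuracy = accuracy,
    cv_good_reads = cv_good,
    n_truth_loci = nrow(sim$truth$loci),
    n_truth_common = sum(truth_maf > 0.05),
    n_retained = length(retained$chrom),
    occupancy_overall = if (!is.null(occ)) occ$overall else NA_real_,
    fraction_within_10kb = if (!is.null(dist)) dist$fraction_within else NA_real_)
  manifest <- write_manifest(
    file.path(out_dir, "manifest.json"), "e2e",
    params = list(n_samples = n_samples, chrom_lengths = as.list(chrom_lengths),
                  depth = depth, n_snps = n_snps, error_rate = error_rate,
                  n_read_rate = n_read_rate, dimer_fraction = dimer_fraction),
    seed = seed,
    files = list.files(out_dir, full.names = TRUE))
  say("demux accuracy ", round(100 * metrics$demux_accuracy, 2),
      "%, good reads ", round(100 * metrics$good_read_fraction, 1),
      "%, CV ", round(metrics$cv_good_reads, 2),
      ", retained SNPs ", metrics$n_retained, "/", metrics$n_truth_loci)
  list(metrics = metrics, plan = plan, digest = dg, demux = dm, filter = flt,
       report = rep_tab, occupancy = occ, distances = dist, sim = sim,
       manifest = manifest, out_dir = out_dir)
}
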