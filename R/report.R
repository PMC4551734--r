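# Evaluation reports: per-chromosome marker density tables, adjacent-marker
# distance distributions, 10-kb block occupancy, and platform comparisons.

#' Published chicken marker counts (Gallus_gallus-4.0)
#'
#' Per-chromosome sizes, gene counts and marker counts for the 252-plex
#' GGRS chicken experiment and the commercial Illumina 60K and Affymetrix
#' 600K chicken SNP chips (autosomes 1-28 and heterosome Z; GGA32, W,
#' linkage groups and unplaced contigs excluded). Printed per-Mbp densities
#' are included so recomputation can be checked against the published
#' presentation. Platform totals — including markers on unplaced
#' contigs/linkage groups, hence larger than the per-chromosome sums — are
#' attached for whole-platform arithmetic.
#'
#' @return list with `per_chrom` (data.frame: `chrom, size_mbp, genes,
#'   ggrs, chip60k, chip600k` and printed densities `d_*`) and
#'   `platform_totals` (named vector: ggrs 91767, chip60k 57636,
#'   chip600k 580954).
#' @export
chicken_marker_table <- function() {
  path <- system.file("extdata", "chicken_markers_gg4.tsv", package = "ggrs",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, colClasses = c(chrom = "character"))
  list(per_chrom = tab,
       platform_totals = c(ggrs = 91767, chip60k = 57636, chip600k = 580954))
}

#' Per-chromosome marker density table
#'
#' For each count column, the per-row density is `count / size_mbp`
#' (markers per Mbp, rounded to 2 decimals in the output). The summary row
#' carries column totals and, for densities, the arithmetic MEAN of the
#' per-chromosome densities — the convention used in the published
#' per-chromosome tables. The overall density `total count / total Mbp` is
#' a different quantity and is reported separately, also expressed per
#' 10 kb.
#'
#' @param per_chrom data.frame with columns `chrom`, `size_mbp` and one
#'   column per platform of marker (or gene) counts.
#' @param platforms count columns to use (default: every numeric column
#'   except `size_mbp` and printed `d_*` columns).
#' @return list with
#'   \describe{
#'     \item{table}{`per_chrom` plus `density_<platform>` columns (2 dp)}
#'     \item{mean_density}{named vector: mean of per-chromosome densities}
#'     \item{overall_per_mbp}{named vector: total count / total Mbp}
#'     \item{overall_per_10kb}{named vector: overall density per 10 kb (2 dp)}
#'     \item{totals}{named vector of count totals; `size_mbp` total included}
#'   }
#' @export
density_table <- function(per_chrom, platforms = NULL) {
  stopifnot(is.data.frame(per_chrom),
            all(c("chrom", "size_mbp") %in% names(per_chrom)))
  if (any(per_chrom$size_mbp <= 0)) stop("chromosome sizes must be positive")
  if (is.null(platforms))
    platforms <- setdiff(names(per_chrom)[vapply(per_chrom, is.numeric, TRUE)],
                         c("size_mbp", grep("^d_", names(per_chrom), value = TRUE)))
  dens <- sapply(platforms, function(p) per_chrom[[p]] / per_chrom$size_mbp)
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = nrow(per_chrom))
  colnames(dens) <- platforms
  out <- per_chrom
  for (p in platforms) out[[paste0("density_", p)]] <- round(dens[, p], 2)
  totals <- vapply(platforms, function(p) sum(per_chrom[[p]]), 0)
  size_total <- sum(per_chrom$size_mbp)
  overall <- totals / size_total
  list(table = out,
       mean_density = round(colMeans(dens), 1),
       overall_per_mbp = overall,
       overall_per_10kb = round(overall / 100, 2),
       totals = c(totals, size_mbp = size_total))
}

#' Distances between adjacent markers
#'
#' Sorts positions within each chromosome and takes successive differences;
#' distances never cross chromosome boundaries. Reports the distance
#' vector, bin fractions over `breaks`, and the fraction of distances at or
#' below `threshold` (default 10 kb, the LD extent).
#'
#' @param positions data.frame with columns `chrom` and `pos`.
#' @param threshold distance (bp) for the "tightly linked" fraction.
#' @param breaks histogram breaks in bp (right-closed).
#' @return list with `distances` (data.frame `chrom, distance`),
#'   `fraction_within` (fraction <= threshold) and `bins` (data.frame
#'   `bin, fraction`, fractions summing to 1).
#' @export
adjacent_distances <- function(positions, threshold = 1e4,
                               breaks = c(0, 1, 2, 5, 10, 20, 50, 100, Inf) * 1e3) {
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  d <- unlist(lapply(split(positions$pos, positions$chrom), function(p) {
    if (length(p) < 2L) return(numeric(0))
    diff(sort(p))
  }), use.names = FALSE)
  chroms <- rep(names(split(positions$pos, positions$chrom)),
                vapply(split(positions$pos, positions$chrom),
                       function(p) max(0L, length(p) - 1L), 0L))
  if (any(d <= 0)) stop("duplicate positions on one chromosome")
  bins <- if (length(d)) {
    ct <- table(cut(d, breaks, include.lowest = TRUE))
    data.frame(bin = names(ct), fraction = as.numeric(ct) / length(d))
  } else data.frame(bin = character(0), fraction = numeric(0))
  list(distances = data.frame(chrom = chroms, distance = d),
       fraction_within = if (length(d)) mean(d <= threshold) else NA_real_,
       bins = bins)
}

#' Block occupancy of marker positions
#'
#' Tiles each chromosome into half-open blocks of `block` bp from position
#' 0 and marks a block present when at least one marker falls in it; the
#' occupancy fraction is occupied / total blocks.
#'
#' @param positions data.frame with columns `chrom` and `pos` (0-based).
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param block block size in bp (default 10 kb).
#' @return list with `per_chrom` (data.frame `chrom, n_blocks, occupied,
#'   fraction`), `overall` (pooled fraction) and `occupied` (data.frame
#'   `chrom, block_start` of present blocks).
#' @export
block_occupancy <- function(positions, chrom_sizes, block = 1e4) {
  stopifnot(all(c("chrom", "pos") %in% names(positions)),
            !is.null(names(chrom_sizes)))
  if (!all(positions$chrom %in% names(chrom_sizes)))
    stop("positions on chromosomes absent from chrom_sizes")
  if (any(positions$pos < 0 |
          positions$pos >= chrom_sizes[positions$chrom]))
    stop("positions outside chromosome bounds")
  per <- lapply(names(chrom_sizes), function(cn) {
    nb <- as.integer(ceiling(chrom_sizes[[cn]] / block))
    p <- positions$pos[positions$chrom == cn]
    occ <- sort(unique(p %/% block))
    list(row = data.frame(chrom = cn, n_blocks = nb, occupied = length(occ),
                          fraction = length(occ) / nb),
         occ = if (length(occ)) data.frame(chrom = cn, block_start = occ * block)
               else NULL)
  })
  per_chrom <- do.call(rbind, lapply(per, `[[`, "row"))
  occupied <- do.call(rbind, Filter(Negate(is.null), lapply(per, `[[`, "occ")))
  if (is.null(occupied))
    occupied <- data.frame(chrom = character(0), block_start = numeric(0))
  list(per_chrom = per_chrom,
       overall = sum(per_chrom$occupied) / sum(per_chrom$n_blocks),
       occupied = occupied)
}

#' Compare two genotyping platforms
#'
#' Reports the whole-platform marker-count difference, each platform's
#' macrochromosome percentage — markers on GGA1-5 as a percentage of the
#' platform's TOTAL marker count including unplaced markers, rounded to the
#' nearest integer — and density summaries (mean per-chromosome density and
#' its ratio to the gene density when a `genes` column is present).
#'
#' @param per_chrom per-chromosome count table (see [chicken_marker_table()]).
#' @param platform_totals named vector of whole-platform marker totals.
#' @param a,b the two platforms to difference (columns of `per_chrom`).
#' @param macro_chroms chromosome names forming the macrochromosome set.
#' @return list with `difference` (`total_a - total_b`), `totals`,
#'   `macro_pct` (named, all platforms in `platform_totals`),
#'   `mean_density`, and `density_vs_genes` (mean-density and count ratios,
#'   `NA` without gene counts).
#' @export
platform_compare <- function(per_chrom, platform_totals, a = "ggrs",
                             b = "chip60k", macro_chroms = as.character(1:5)) {
  stopifnot(a %in% names(per_chrom), b %in% names(per_chrom),
            a %in% names(platform_totals), b %in% names(platform_totals))
  platforms <- intersect(names(platform_totals), names(per_chrom))
  macro <- per_chrom$chrom %in% macro_chroms
  macro_pct <- vapply(platforms, function(p) {
    round(100 * sum(per_chrom[[p]][macro]) / platform_totals[[p]])
  }, 0)
  dens <- density_table(per_chrom, platforms = unique(c(platforms,
    if ("genes" %in% names(per_chrom)) "genes")))
  has_genes <- "genes" %in% names(per_chrom)
  ratio <- if (has_genes) {
    md <- dens$mean_density
    list(mean_density_ratio = md[platforms] / md[["genes"]],
         count_ratio = vapply(platforms, function(p) sum(per_chrom[[p]]), 0) /
           sum(per_chrom$genes))
  } else NULL
  list(difference = unname(platform_totals[[a]] - platform_totals[[b]]),
       totals = platform_totals[platforms],
       macro_pct = macro_pct,
       mean_density = dens$mean_density,
       overall_per_10kb = dens$overall_per_10kb,
       density_vs_genes = ratio)
}
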