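# Read classification (the four GGRS quality filters), per-sample
# demultiplexing, and read statistics (good reads, unique reads, CV).

REJECT_REASONS <- c("no_barcode", "bad_remnant", "adapter_dimer", "contains_N")

#' Classify R1 reads with the four GGRS filters
#'
#' Applies, in order: (1) the read must start with an exact barcode match
#' (longest-prefix match over the prefix-free barcode set); (2) the
#' cut-site remnant (`GWCC` for AvaII, W in {A,T}) must follow the barcode;
#' (3) the read must not be an adapter dimer, detected as an exact
#' `dimer_k`-base common-adapter prefix immediately after barcode + remnant
#' (the empty-insert signature); (4) no non-calling `N` base anywhere in the
#' read. The first failing rule is the reported reason. Reads shorter than
#' barcode + remnant are `no_barcode`.
#'
#' @param r1 character vector of R1 sequences.
#' @param barcodes character vector of barcodes (prefix-free by design).
#' @param enz a [enzyme()] object.
#' @param common_adapter common-adapter read-through sequence (filter 3).
#' @param dimer_k adapter prefix length declaring a dimer (default 8).
#' @return data.frame with `barcode` (NA when rejected) and `reason`
#'   (`"assigned"` or one of `no_barcode`, `bad_remnant`, `adapter_dimer`,
#'   `contains_N`).
#' @export
classify_reads <- function(r1, barcodes, enz = enzyme(),
                           common_adapter = ggrs_common_adapter(),
                           dimer_k = 8L) {
  barcodes <- toupper(barcodes)
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  n <- length(r1)
  bc_hit <- rep(NA_character_, n)
  # longest-prefix match: try lengths in decreasing order
  for (L in sort(unique(nchar(barcodes)), decreasing = TRUE)) {
    bset <- barcodes[nchar(barcodes) == L]
    todo <- is.na(bc_hit)
    if (!any(todo)) break
    pref <- substr(r1[todo], 1L, L)
    hit <- pref %in% bset
    bc_hit[todo][hit] <- pref[hit]
  }
  bl <- nchar(bc_hit)
  rem_len <- nchar(enz$remnant)
  too_short <- !is.na(bc_hit) & nchar(r1) < bl + rem_len
  bc_hit[too_short] <- NA_character_
  bl <- nchar(bc_hit)
  rem_ok <- !is.na(bc_hit) &
    substr(r1, bl + 1L, bl + rem_len) %in% expand_motif(enz$remnant)
  ad_pref <- substr(toupper(common_adapter), 1L, dimer_k)
  is_dimer <- rem_ok &
    substr(r1, bl + rem_len + 1L, bl + rem_len + dimer_k) == ad_pref
  has_n <- grepl("N", r1, fixed = TRUE)
  reason <- rep("assigned", n)
  reason[has_n] <- "contains_N"
  reason[is_dimer] <- "adapter_dimer"
  reason[!rem_ok] <- "bad_remnant"
  reason[is.na(bc_hit)] <- "no_barcode"
  bc_hit[reason != "assigned"] <- NA_character_
  data.frame(barcode = bc_hit, reason = reason)
}

#' Demultiplex a paired-end FASTQ into per-sample good reads
#'
#' Classifies every R1 with [classify_reads()]; R2 inherits R1's verdict
#' (pairs are kept or rejected together). When `out_dir` is given, one
#' FASTQ pair per sample is written with the barcode and remnant trimmed
#' from R1.
#'
#' @param r1,r2 FASTQ paths or data.frames (`id,seq,qual`).
#' @param sample_sheet data.frame `sample_id`, `barcode`.
#' @param enz a [enzyme()] object.
#' @param common_adapter,dimer_k see [classify_reads()].
#' @param out_dir optional directory for per-sample FASTQ pairs.
#' @return list of class `ggrs_demux`:
#'   \describe{
#'     \item{per_read}{data.frame `id, sample_id, reason`}
#'     \item{good_reads}{named integer vector of good-read counts per sample
#'       (zero-filled for absent samples)}
#'     \item{rejections}{named integer vector of rejection counts by reason}
#'     \item{n_total}{input read count}
#'   }
#' @export
demux_fastq <- function(r1, r2 = NULL, sample_sheet, enz = enzyme(),
                        common_adapter = ggrs_common_adapter(), dimer_k = 8L,
                        out_dir = NULL) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  sample_sheet <- validate_sample_sheet(sample_sheet)
  cls <- classify_reads(r1$seq, sample_sheet$barcode, enz, common_adapter, dimer_k)
  sample_id <- sample_sheet$sample_id[match(cls$barcode, sample_sheet$barcode)]
  per_read <- data.frame(id = r1$id, sample_id = sample_id, reason = cls$reason)
  good <- table(factor(sample_id[cls$reason == "assigned"],
                       levels = sample_sheet$sample_id))
  rej <- table(factor(cls$reason[cls$reason != "assigned"], levels = REJECT_REASONS))
  res <- structure(list(per_read = per_read,
                        good_reads = stats::setNames(as.integer(good), names(good)),
                        rejections = stats::setNames(as.integer(rej), names(rej)),
                        n_total = nrow(r1)),
                   class = "ggrs_demux")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    keep <- cls$reason == "assigned"
    trim <- nchar(cls$barcode) + nchar(enz$remnant)
    for (s in sample_sheet$sample_id) {
      i <- which(keep & sample_id == s)
      out1 <- data.frame(id = r1$id[i],
                         seq = substring(r1$seq[i], trim[i] + 1L),
                         qual = substring(r1$qual[i], trim[i] + 1L))
      write_fastq(out1, file.path(out_dir, paste0(s, "_R1.fastq")))
      if (!is.null(r2))
        write_fastq(r2[i, , drop = FALSE],
                    file.path(out_dir, paste0(s, "_R2.fastq")))
    }
  }
  res
}

#' @export
print.ggrs_demux <- function(x, ...) {
  cat("GGRS demultiplexing: ", x$n_total, " reads, ",
      sum(x$good_reads), " good (",
      round(100 * sum(x$good_reads) / max(1L, x$n_total), 1), "%)\n", sep = "")
  print(x$rejections)
  invisible(x)
}

#' Unique reads per sample
#'
#' A unique read is a distinct genome position — (chrom, 5' position,
#' strand) — covered by at least one good read. Set `ignore_strand = TRUE`
#' to collapse the two strands.
#'
#' @param positions data.frame as returned by [read_positions()] (columns
#'   `sample_id, chrom, pos, strand`).
#' @param ignore_strand drop strand from the position key.
#' @return named integer vector of unique-read counts per sample.
#' @export
unique_read_count <- function(positions, ignore_strand = FALSE) {
  stopifnot(all(c("sample_id", "chrom", "pos") %in% names(positions)))
  if (!nrow(positions)) return(stats::setNames(integer(0), character(0)))
  key <- if (ignore_strand) paste(positions$chrom, positions$pos)
         else paste(positions$chrom, positions$pos, positions$strand)
  tab <- tapply(key, positions$sample_id, function(k) length(unique(k)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Coefficient of variation with extreme-sample exclusion
#'
#' CV = sample standard deviation / mean, computed after removing the
#' `exclude_top` largest and `exclude_bottom` smallest values — the
#' convention used to report read-count evenness for the 252-plex library
#' (5 maximal and 2 minimal samples excluded).
#'
#' @param counts numeric vector of per-sample counts.
#' @param exclude_top,exclude_bottom number of extreme values to drop.
#' @return CV as a fraction.
#' @export
cv_of_counts <- function(counts, exclude_top = 5L, exclude_bottom = 2L) {
  stopifnot(is.numeric(counts), exclude_top >= 0L, exclude_bottom >= 0L)
  if (length(counts) - exclude_top - exclude_bottom < 2L)
    stop("fewer than 2 values remain after exclusion")
  x <- sort(counts)
  if (exclude_top > 0L) x <- utils::head(x, length(x) - exclude_top)
  if (exclude_bottom > 0L) x <- utils::tail(x, length(x) - exclude_bottom)
  if (length(x) < 2L) stop("fewer than 2 values remain after exclusion")
  stats::sd(x) / mean(x)
}
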