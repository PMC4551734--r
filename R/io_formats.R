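# Readers/writers for the standard formats the pipeline touches (FASTA,
# FASTQ, minimal SAM / position tables, sample sheets, VCF) plus config.
# All internal coordinates are 0-based half-open; SAM/VCF adapters convert
# at the boundary.

#' Read a reference genome from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()]: lowercase is folded to uppercase,
#' the description after the first whitespace is dropped from each name, and
#' duplicate names are an error.
#'
#' @param path FASTA file.
#' @return a `DNAStringSet`, one element per sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (!length(x)) stop("empty FASTA: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA header(s): ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(x))
}

#' Write sequences to FASTA
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  seqs <- as_genome_chr(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Total genome length in bp
#' @param genome `DNAStringSet` or named character vector.
#' @return total number of bases.
#' @export
genome_length <- function(genome) sum(nchar(as_genome_chr(genome)))

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(id = character(0), seq = character(0), qual = character(0)))
  # the reader attaches mcols that later conversions drop with a warning;
  # neither carries information for plain (id, seq, qual) records
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  suppressWarnings(
    data.frame(id = names(x),
               seq = as.character(x),
               qual = as.character(Biostrings::quality(x)),
               row.names = NULL))
}

#' Write a FASTQ file (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (!nrow(reads)) { file.create(path); return(invisible(path)) }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a sample sheet (sample_id, barcode)
#'
#' @param path tab-separated file with columns `sample_id` and `barcode`.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "barcode") %in% names(df)))
    stop("sample sheet must have columns sample_id and barcode")
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  df$barcode <- toupper(df$barcode)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  if (anyDuplicated(df$barcode)) stop("duplicate barcode in sample sheet")
  if (any(grepl("[^ACGT]", df$barcode))) stop("barcodes must be over {A,C,G,T}")
  df
}

#' Write a sample sheet
#' @param df data.frame with `sample_id`, `barcode`.
#' @param path output TSV.
#' @export
write_sample_sheet <- function(df, path) {
  validate_sample_sheet(df)
  utils::write.table(df[, c("sample_id", "barcode")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned read positions from minimal SAM or a position TSV
#'
#' Accepts either a SAM text file (only QNAME/FLAG/RNAME/POS/MAPQ are used;
#' unmapped reads are dropped; strand taken from FLAG bit 0x10; the SAM
#' 1-based POS is converted to the internal 0-based convention; a
#' `sample_id` is taken from the QNAME prefix before the first `:` when
#' present) or a tab-separated table with columns
#' `read_id, sample_id, chrom, pos, strand, mapq` where `pos` is already
#' 0-based.
#'
#' Rows are retained when `mapq > min_mapq` (strictly greater than, the
#' alignment-quality rule used before variant calling); set `strict = FALSE`
#' for `>=`.
#'
#' @param path SAM or TSV file.
#' @param min_mapq mapping-quality threshold (default 20).
#' @param strict if `TRUE` (default) keep `mapq > min_mapq`, else `>=`.
#' @return data.frame `read_id, sample_id, chrom, pos, strand, mapq`.
#' @export
read_positions <- function(path, min_mapq = 20, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  empty <- data.frame(read_id = character(0), sample_id = character(0),
                      chrom = character(0), pos = integer(0),
                      strand = character(0), mapq = numeric(0))
  if (!length(body)) return(empty)
  nf <- length(strsplit(body[1L], "\t", fixed = TRUE)[[1L]])
  if (nf >= 11L) {
    f <- strsplit(body, "\t", fixed = TRUE)
    qname <- vapply(f, `[[`, "", 1L)
    flag <- as.integer(vapply(f, `[[`, "", 2L))
    rname <- vapply(f, `[[`, "", 3L)
    pos1 <- as.integer(vapply(f, `[[`, "", 4L))
    mapq <- as.numeric(vapply(f, `[[`, "", 5L))
    mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
    df <- data.frame(
      read_id = qname,
      sample_id = ifelse(grepl(":", qname, fixed = TRUE),
                         sub(":.*$", "", qname), NA_character_),
      chrom = rname,
      pos = pos1 - 1L,
      strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
      mapq = mapq)[mapped, , drop = FALSE]
  } else {
    first <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
    has_header <- identical(first,
                            c("read_id", "sample_id", "chrom", "pos", "strand", "mapq"))
    df <- utils::read.delim(text = body, header = has_header,
                            stringsAsFactors = FALSE,
                            col.names = c("read_id", "sample_id", "chrom",
                                          "pos", "strand", "mapq"))
    if (any(df$pos < 0)) stop("positions must be >= 0 (0-based)")
  }
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  keep <- if (strict) df$mapq > min_mapq else df$mapq >= min_mapq
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a multi-sample VCF into a variant-site table
#'
#' Wraps [vcfR::read.vcfR()]. Per-sample `GT`, `DP` and `GQ` fields are
#' extracted into matrices (sites x samples); records whose ALT contains a
#' comma are flagged `multiallelic`. Positions are converted to the internal
#' 0-based convention.
#'
#' @param path VCF (optionally gzipped).
#' @return object of class `ggrs_sites`: list with `chrom`, `pos` (0-based),
#'   `id`, `ref`, `alt`, `samples`, `gt` (character matrix, `"./."` for
#'   missing), `dp`, `gq` (numeric matrices, `NA` when absent) and
#'   `multiallelic` (logical vector).
#' @export
read_variant_sites <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(structure(list(chrom = character(0), pos = integer(0), id = character(0),
                          ref = character(0), alt = character(0),
                          samples = character(0),
                          gt = matrix(character(0), 0, 0),
                          dp = matrix(numeric(0), 0, 0),
                          gq = matrix(numeric(0), 0, 0),
                          multiallelic = logical(0)),
                     class = "ggrs_sites"))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  gt[is.na(gt)] <- "./."
  gt <- gsub("|", "/", gt, fixed = TRUE)
  structure(list(chrom = unname(fix[, "CHROM"]),
                 pos = as.integer(fix[, "POS"]) - 1L,
                 id = unname(fix[, "ID"]),
                 ref = unname(fix[, "REF"]),
                 alt = unname(fix[, "ALT"]),
                 samples = colnames(gt),
                 gt = gt, dp = dp, gq = gq,
                 multiallelic = grepl(",", fix[, "ALT"], fixed = TRUE)),
            class = "ggrs_sites")
}

#' Write a variant-site table as VCF (GT:DP:GQ)
#'
#' Builds a `vcfR` object and writes it with [vcfR::write.vcf()] (always
#' bgzip/gzip compressed; a `.gz` suffix is appended when missing).
#'
#' @param sites a `ggrs_sites` object (see [read_variant_sites()]).
#' @param path output file, `.vcf.gz`.
#' @return the path written.
#' @importClassesFrom vcfR vcfR
#' @export
write_variant_sites <- function(sites, path) {
  stopifnot(inherits(sites, "ggrs_sites"))
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  n <- length(sites$chrom)
  meta <- c("##fileformat=VCFv4.2",
            "##source=ggrs",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  fix <- cbind(CHROM = sites$chrom,
               POS = as.character(sites$pos + 1L),
               ID = if (length(sites$id)) sites$id else rep(".", n),
               REF = sites$ref, ALT = sites$alt,
               QUAL = rep(".", n), FILTER = rep("PASS", n), INFO = rep(".", n))
  fmt <- function(g, d, q) {
    d <- ifelse(is.na(d), ".", as.character(as.integer(round(d))))
    q <- ifelse(is.na(q), ".", as.character(as.integer(round(q))))
    paste(g, d, q, sep = ":")
  }
  body <- matrix("", n, length(sites$samples) + 1L,
                 dimnames = list(NULL, c("FORMAT", sites$samples)))
  body[, "FORMAT"] <- "GT:DP:GQ"
  for (j in seq_along(sites$samples))
    body[, j + 1L] <- fmt(sites$gt[, j], sites$dp[, j], sites$gq[, j])
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = body)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a flat YAML config file
#'
#' One flat mapping of parameter names to values, as used by the command-line
#' wrapper; flags override config values.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a flat mapping")
  cfg
}
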