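# In silico restriction digestion: IUPAC motif scanning, fragment extraction
# between successive cut sites, and size selection.

#' Define a restriction enzyme
#'
#' An enzyme is described by its (possibly IUPAC-degenerate) recognition motif
#' and the offset of the top-strand cut within the motif. The remnant — the
#' motif suffix downstream of the cut — is the sequence expected at the start
#' of every ligated read in a GGRS/GBS library. The default is AvaII
#' (`G^GWCC`, W = A or T), which leaves the four-base remnant `GWCC`.
#'
#' @param name enzyme name (informational).
#' @param motif recognition motif, IUPAC alphabet.
#' @param cut_offset bases from motif start to the top-strand cut;
#'   must satisfy `0 <= cut_offset < nchar(motif)`.
#' @return an object of class `ggrs_enzyme` with fields `name`, `motif`,
#'   `cut_offset` and `remnant` (= `substring(motif, cut_offset + 1)`).
#' @examples
#' enzyme()          # AvaII
#' enzyme("EcoRI", "GAATTC", 1L)
#' @export
enzyme <- function(name = "AvaII", motif = "GGWCC", cut_offset = 1L) {
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl(paste0("[^", paste(names(IUPAC_CODES), collapse = ""), "]"), motif))
    stop("motif contains non-IUPAC characters: ", motif)
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset >= nchar(motif))
    stop("cut_offset must satisfy 0 <= cut_offset < motif length")
  structure(
    list(name = name, motif = motif, cut_offset = cut_offset,
         remnant = substring(motif, cut_offset + 1L)),
    class = "ggrs_enzyme"
  )
}

#' @export
print.ggrs_enzyme <- function(x, ...) {
  cut_mark <- paste0(substr(x$motif, 1L, x$cut_offset), "^", x$remnant)
  cat("Restriction enzyme ", x$name, ": ", cut_mark,
      " (remnant ", x$remnant, ")\n", sep = "")
  invisible(x)
}

# Expand an IUPAC motif into the set of literal sequences it denotes.
expand_motif <- function(motif) {
  sets <- IUPAC_CODES[strsplit(motif, "")[[1]]]
  out <- do.call(expand.grid, c(lapply(rev(sets), function(s) strsplit(s, "")[[1]]),
                                stringsAsFactors = FALSE))
  sort(apply(out[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = ""))
}

#' Find restriction-site positions on the forward strand
#'
#' Scans an uppercase sequence for all (possibly overlapping) matches of the
#' enzyme's degenerate motif. `N` in the sequence never matches a degenerate
#' motif position. For palindromic motifs such as AvaII's `GGWCC`
#' (reverse complement equals itself as a degenerate set) a single-strand
#' scan finds every site on both strands.
#'
#' @param sequence a single uppercase nucleotide string (or `DNAString`).
#' @param enz a [enzyme()] object.
#' @return integer vector of 0-based motif start positions, sorted ascending.
#' @examples
#' find_sites("TTTTGGACCTTTTTTTTGGTCCTTTT", enzyme())  # 4, 17
#' @export
find_sites <- function(sequence, enz = enzyme()) {
  stopifnot(inherits(enz, "ggrs_enzyme"))
  if (methods::is(sequence, "DNAString")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single character string")
  if (nchar(sequence) < nchar(enz$motif)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(enz$motif),
                                Biostrings::DNAString(sequence),
                                fixed = "subject")
  sort(BiocGenerics::start(m) - 1L)
}

#' Digest one chromosome into internal fragments
#'
#' Cut positions are `site + cut_offset`. Fragments are the intervals between
#' consecutive cuts; the two terminal intervals (upstream of the first cut,
#' downstream of the last) carry only one ligatable end and are excluded by
#' default, because only fragments cut at both ends receive both adapters in
#' the library chemistry.
#'
#' @param sequence a single uppercase nucleotide string.
#' @param enz a [enzyme()] object.
#' @param include_terminal if `TRUE`, also return the two terminal intervals
#'   (bounded by the sequence ends).
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `length`; empty when fewer than two sites are found (unless
#'   `include_terminal`).
#' @export
digest_chromosome <- function(sequence, enz = enzyme(), include_terminal = FALSE) {
  sites <- find_sites(sequence, enz)
  cuts <- sites + enz$cut_offset
  if (include_terminal) cuts <- unique(c(0L, cuts, nchar(sequence)))
  if (length(cuts) < 2L)
    return(data.frame(start = integer(0), end = integer(0), length = integer(0)))
  start <- cuts[-length(cuts)]
  end <- cuts[-1L]
  data.frame(start = start, end = end, length = end - start)
}

#' Size-select fragments
#'
#' Retains fragments with `min_len <= length <= max_len` (inclusive at both
#' bounds).
#'
#' @param fragments data.frame with a `length` column (as returned by
#'   [digest_chromosome()] or [digest_genome()]).
#' @param min_len,max_len inclusive size window in bp (protocol default
#'   200–400 bp).
#' @return the retained subset, row order preserved.
#' @export
select_fragments <- function(fragments, min_len = 200L, max_len = 400L) {
  stopifnot(is.data.frame(fragments), "length" %in% names(fragments))
  if (min_len > max_len) stop("min_len must not exceed max_len")
  fragments[fragments$length >= min_len & fragments$length <= max_len, , drop = FALSE]
}

#' Digest a whole genome and summarize
#'
#' Runs [digest_chromosome()] on every sequence, applies the size window, and
#' tabulates per-chromosome site/fragment/selected counts. The selected
#' fragments can be written as BED3 (0-based half-open) and the summary as TSV.
#'
#' @param genome `DNAStringSet` or named character vector of chromosome
#'   sequences.
#' @param enz a [enzyme()] object.
#' @param min_len,max_len inclusive fragment size window (bp).
#' @param include_terminal passed to [digest_chromosome()].
#' @param bed,summary optional output file paths (BED3 of selected fragments;
#'   TSV summary).
#' @return list with elements
#'   \describe{
#'     \item{fragments}{data.frame `chrom,start,end,length` of selected fragments}
#'     \item{all_fragments}{same, before size selection}
#'     \item{summary}{per-chromosome data.frame `chrom,n_sites,n_fragments,n_selected`}
#'     \item{totals}{named vector with `n_sites`, `n_fragments`, `n_selected`,
#'       `min_len`, `max_len`}
#'   }
#' @export
digest_genome <- function(genome, enz = enzyme(), min_len = 200L, max_len = 400L,
                          include_terminal = FALSE, bed = NULL, summary = NULL) {
  seqs <- as_genome_chr(genome)
  per <- lapply(names(seqs), function(nm) {
    frags <- digest_chromosome(seqs[[nm]], enz, include_terminal = include_terminal)
    sel <- select_fragments(frags, min_len, max_len)
    list(nm = nm,
         frags = if (nrow(frags)) cbind(chrom = nm, frags) else NULL,
         sel   = if (nrow(sel))   cbind(chrom = nm, sel)   else NULL,
         n_sites = length(find_sites(seqs[[nm]], enz)),
         n_fragments = nrow(frags), n_selected = nrow(sel))
  })
  all_frags <- do.call(rbind, c(list(data.frame(chrom = character(0), start = integer(0),
                                                end = integer(0), length = integer(0))),
                                Filter(Negate(is.null), lapply(per, `[[`, "frags"))))
  sel_frags <- do.call(rbind, c(list(all_frags[0, ]),
                                Filter(Negate(is.null), lapply(per, `[[`, "sel"))))
  rownames(all_frags) <- rownames(sel_frags) <- NULL
  smry <- data.frame(chrom = vapply(per, `[[`, "", "nm"),
                     n_sites = vapply(per, `[[`, 0L, "n_sites"),
                     n_fragments = vapply(per, `[[`, 0L, "n_fragments"),
                     n_selected = vapply(per, `[[`, 0L, "n_selected"))
  totals <- c(n_sites = sum(smry$n_sites), n_fragments = sum(smry$n_fragments),
              n_selected = sum(smry$n_selected), min_len = min_len, max_len = max_len)
  if (!is.null(bed)) write_bed(sel_frags, bed)
  if (!is.null(summary))
    utils::write.table(smry, summary, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fragments = sel_frags, all_fragments = all_frags, summary = smry, totals = totals)
}

#' Write fragments as BED3
#'
#' @param fragments data.frame with `chrom,start,end` (0-based half-open).
#' @param path output file.
#' @export
write_bed <- function(fragments, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  utils::write.table(fragments[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
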