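# Internal helpers shared across modules.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Reverse complement of plain character sequences
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on character
#' vectors (IUPAC alphabet).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Coerce a genome argument (DNAStringSet or named character vector) to an
# uppercase named character vector; validates names and alphabet.
as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- toupper(as.character(genome))
  } else if (is.character(genome)) {
    seqs <- toupper(genome)
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("genome sequences must be named")
  if (anyDuplicated(nm))
    stop("duplicate sequence name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence(s) contain characters outside {A,C,G,T,N}: ", paste(nm[bad], collapse = ", "))
  seqs
}

stopifnot_scalar_num <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (positive && x <= 0))
    stop("`", name, "` must be a single ", if (positive) "positive " else "", "number")
  invisible(x)
}
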