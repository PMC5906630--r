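#' Genome object
#'
#' A lightweight container for a genome: ordered chromosome names, lengths in
#' base pairs, and (optionally) the nucleotide sequence of each chromosome.
#' All coordinates in this package are 0-based, half-open.
#'
#' @param lengths Named numeric vector of chromosome lengths (bp); names are
#'   the chromosome identifiers.
#' @param sequence Optional named character vector of chromosome sequences
#'   (A/C/G/T/N, upper case). Names and lengths must match `lengths`.
#' @return An object of class `Genome` with fields `chrom_names`,
#'   `chrom_lengths` and `sequence`.
#' @export
genome <- function(lengths, sequence = NULL) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("chromosome lengths must be uniquely named")
  nm <- names(lengths)
  lengths <- as.numeric(lengths)
  names(lengths) <- nm
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  if (!is.null(sequence)) {
    if (!all(names(lengths) %in% names(sequence)))
      stop("sequence missing for some chromosomes")
    sequence <- sequence[names(lengths)]
    got <- nchar(sequence)
    if (any(got != lengths))
      stop(sprintf("sequence length mismatch for %s",
                   paste(names(lengths)[got != lengths], collapse = ", ")))
  }
  structure(list(chrom_names = names(lengths),
                 chrom_lengths = lengths,
                 sequence = sequence),
            class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome: %d chromosome(s), %.0f bp total, sequence %s\n",
              length(x$chrom_names), sum(x$chrom_lengths),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  unname(genome$chrom_lengths[chrom])
}

stopifnot_genome <- function(genome) {
  if (!inherits(genome, "Genome")) stop("expected a Genome object")
}

#' Read a genome from a FASTA file
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @param keep_sequence Keep the nucleotide sequence (default TRUE). With
#'   FALSE only names and lengths are retained.
#' @return A [genome()] object.
#' @export
read_genome_fasta <- function(path, keep_sequence = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  lens <- Biostrings::width(seqs)
  names(lens) <- nm
  seq <- NULL
  if (keep_sequence) {
    seq <- toupper(as.character(seqs))
    names(seq) <- nm
  }
  genome(lens, seq)
}

#' Write a genome to a FASTA file
#'
#' @param genome A [genome()] with sequence present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot_genome(genome)
  if (is.null(genome$sequence)) stop("genome has no sequence to write")
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$chrom_names
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Cumulative G+C and N indicator sums per chromosome; index i holds the count
# in bases [0, i). Used for O(1) GC content of arbitrary windows.
gc_cumsums <- function(genome) {
  stopifnot_genome(genome)
  if (is.null(genome$sequence)) stop("genome sequence required for GC analysis")
  lapply(genome$sequence, function(s) {
    r <- charToRaw(s)
    isgc <- (r == as.raw(71L)) | (r == as.raw(67L))   # G, C
    isn <- r == as.raw(78L)                           # N
    list(gc = c(0, cumsum(as.integer(isgc))),
         n = c(0, cumsum(as.integer(isn))))
  })
}

# GC fraction of windows [start, end) on one chromosome given its cumsums;
# N bases are excluded from numerator and denominator. Returns NA where the
# window is entirely N.
gc_fraction <- function(cums, start, end) {
  gc <- cums$gc[end + 1L] - cums$gc[start + 1L]
  nn <- cums$n[end + 1L] - cums$n[start + 1L]
  den <- (end - start) - nn
  ifelse(den > 0, gc / den, NA_real_)
}
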