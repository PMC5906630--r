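#' Fragment set
#'
#' Genomic intervals from one sequencing sample (immunoprecipitate, input, or
#' MNase digest). Coordinates are 0-based, half-open. A `FragmentSet` is a
#' data frame with columns `chrom`, `start`, `end` plus attributes
#' `sample_label` and `size_filter` (the applied length range, if any).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like vectors; `0 <= start < end <= chrom length`.
#' @param genome A [genome()] used for validation.
#' @param sample_label Free-text label for the sample.
#' @return A `FragmentSet`.
#' @export
fragment_set <- function(chrom, start, end, genome, sample_label = "sample") {
  stopifnot_genome(genome)
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  bad_chrom <- !(chrom %in% genome$chrom_names)
  if (any(bad_chrom))
    stop(sprintf("unknown chromosome(s): %s (first at record %d)",
                 paste(unique(chrom[bad_chrom]), collapse = ", "),
                 which(bad_chrom)[1]))
  if (any(start >= end))
    stop(sprintf("start >= end at record %d", which(start >= end)[1]))
  lens <- genome$chrom_lengths[chrom]
  oob <- start < 0 | end > lens
  if (any(oob))
    stop(sprintf("fragment out of chromosome bounds at record %d",
                 which(oob)[1]))
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  attr(out, "sample_label") <- sample_label
  attr(out, "size_filter") <- NULL
  class(out) <- c("FragmentSet", "data.frame")
  out
}

#' Read fragments from a BED3 file
#'
#' Reads a 3+-column tab-separated BED file (0-based, half-open). Records are
#' validated against the genome; malformed lines are reported by line number.
#'
#' @param path Path to a BED file.
#' @param genome A [genome()].
#' @param sample_label Label stored on the returned set (defaults to the file
#'   base name).
#' @return A [fragment_set()].
#' @export
read_fragments <- function(path, genome,
                           sample_label = tools::file_path_sans_ext(basename(path))) {
  stopifnot_genome(genome)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(fragment_set(character(), numeric(), numeric(), genome,
                        sample_label))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop(sprintf("line %d: fewer than 3 tab-separated fields",
                 which(nf < 3)[1]))
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("line %d: non-numeric coordinates",
                 which(is.na(start) | is.na(end))[1]))
  bad_chrom <- !(chrom %in% genome$chrom_names)
  if (any(bad_chrom))
    stop(sprintf("line %d: unknown chromosome '%s'",
                 which(bad_chrom)[1], chrom[which(bad_chrom)[1]]))
  if (any(start >= end))
    stop(sprintf("line %d: start >= end", which(start >= end)[1]))
  lens <- genome$chrom_lengths[chrom]
  oob <- start < 0 | end > lens
  if (any(oob))
    stop(sprintf("line %d: interval outside chromosome", which(oob)[1]))
  fragment_set(chrom, start, end, genome, sample_label)
}

#' Write fragments to a BED3 file
#'
#' @param frags A [fragment_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  out <- sprintf("%s\t%d\t%d", frags$chrom, as.integer(frags$start),
                 as.integer(frags$end))
  writeLines(out, path)
  invisible(path)
}

fragment_lengths <- function(frags) frags$end - frags$start
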