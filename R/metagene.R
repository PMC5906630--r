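#' TSS-anchored metagene (average gene) profile
#'
#' Averages a normalized coverage track across genes aligned at their TSS in
#' transcription orientation: offset 0 is the TSS, positive offsets run
#' downstream (so minus-strand genes are read right-to-left). Each gene
#' contributes from `TSS - upstream` to
#' `min(TSS + downstream, polyA - end_buffer)`: genes stop contributing once
#' their (buffered) polyadenylation site is reached, and the per-offset mean
#' is taken over the genes still contributing there (ragged averaging; no
#' zero-filling beyond short genes). Offsets that would fall outside the
#' chromosome are likewise skipped for that gene.
#'
#' @param track A genome-mean or spike-in normalized [coverage_track()].
#' @param genes A [gene_annotation()].
#' @param upstream,downstream Profile extent around the TSS (bp).
#' @param end_buffer Stop this many bp before the polyA site (300 for RNAP II
#'   profiles, where 3' peaks skew quantification; 0 otherwise).
#' @return A `MetageneProfile`: data frame with columns `offset`,
#'   `mean_signal`, `n_genes`, plus attributes `end_buffer` and
#'   `excluded_genes` (ids whose truncated extent was < 1 bp downstream).
#' @export
metagene_profile <- function(track, genes, upstream = 500, downstream = 2500,
                             end_buffer = 0) {
  if (upstream < 0 || downstream < 0 || end_buffer < 0)
    stop("upstream, downstream and end_buffer must be >= 0")
  offsets <- seq(-upstream, downstream - 1L)
  width <- length(offsets)
  sums <- numeric(width)
  counts <- numeric(width)
  excluded <- character()
  dir <- gene_direction(genes)
  glen <- gene_length(genes)
  for (i in seq_len(nrow(genes))) {
    # downstream extent in gene coordinates, truncated at polyA - buffer
    max_down <- min(downstream - 1L, glen[i] - end_buffer - 1L)
    if (max_down < 0) {
      excluded <- c(excluded, genes$id[i])
      next
    }
    x <- track$values[[genes$chrom[i]]]
    L <- length(x)
    offs <- seq(-upstream, max_down)
    pos <- genes$tss[i] + dir[i] * offs      # 0-based genomic positions
    ok <- pos >= 0 & pos < L
    if (!any(ok)) next
    idx <- offs[ok] + upstream + 1L          # 1-based index into profile
    sums[idx] <- sums[idx] + x[pos[ok] + 1L]
    counts[idx] <- counts[idx] + 1
  }
  if (all(counts == 0)) stop("no eligible genes for metagene profile")
  out <- data.frame(offset = offsets,
                    mean_signal = ifelse(counts > 0, sums / counts, NA_real_),
                    n_genes = as.integer(counts))
  attr(out, "end_buffer") <- end_buffer
  attr(out, "excluded_genes") <- excluded
  class(out) <- c("MetageneProfile", "data.frame")
  out
}

#' Write a metagene profile as TSV
#'
#' @param profile A [metagene_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metagene <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Locate a peak in a metagene profile
#'
#' Returns the offset of the maximum mean signal within `range` (a length-2
#' vector of offsets). Used to verify -1/+1 nucleosome peak positions.
#'
#' @param profile A [metagene_profile()].
#' @param range Offset interval (inclusive) to search.
#' @return A list with `offset` and `height`.
#' @export
profile_peak <- function(profile, range) {
  sel <- profile$offset >= range[1] & profile$offset <= range[2] &
    !is.na(profile$mean_signal)
  if (!any(sel)) stop("no profile positions in range")
  sub <- profile[sel, ]
  i <- which.max(sub$mean_signal)
  list(offset = sub$offset[i], height = sub$mean_signal[i])
}

#' Locate a trough in a metagene profile
#'
#' @param profile A [metagene_profile()].
#' @param range Offset interval (inclusive) to search.
#' @return A list with `offset` and `depth` (the minimum mean signal).
#' @export
profile_trough <- function(profile, range) {
  sel <- profile$offset >= range[1] & profile$offset <= range[2] &
    !is.na(profile$mean_signal)
  if (!any(sel)) stop("no profile positions in range")
  sub <- profile[sel, ]
  i <- which.min(sub$mean_signal)
  list(offset = sub$offset[i], depth = sub$mean_signal[i])
}
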