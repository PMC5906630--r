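#' Coverage track
#'
#' Per-base signal across the genome with a recorded normalization state.
#' Internally a named list of numeric vectors (one per chromosome, one value
#' per base) plus bookkeeping: `normalization` is one of `"raw"`,
#' `"genome_mean"` or `"spikein"`; `source_mode` records whether fragments
#' contributed over their full span or only at their midpoint;
#' `sigma_applied` is the Gaussian smoothing SD, if any.
#'
#' @param values Named list of per-chromosome numeric vectors.
#' @param genome The [genome()] the track is defined on.
#' @param normalization,source_mode,sigma_applied Bookkeeping fields.
#' @return A `CoverageTrack`.
#' @export
coverage_track <- function(values, genome, normalization = "raw",
                           source_mode = "full_span", sigma_applied = NULL) {
  stopifnot_genome(genome)
  if (!all(genome$chrom_names %in% names(values)))
    stop("values must cover every chromosome")
  values <- values[genome$chrom_names]
  got <- vapply(values, length, 0L)
  if (any(got != genome$chrom_lengths))
    stop("per-chromosome value length must equal chromosome length")
  if (any(!vapply(values, function(v) all(is.finite(v)), TRUE)))
    stop("coverage values must be finite")
  structure(list(values = values,
                 chrom_lengths = genome$chrom_lengths,
                 normalization = normalization,
                 source_mode = source_mode,
                 sigma_applied = sigma_applied),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf(
    "CoverageTrack: %d chromosome(s), %.0f bp, normalization=%s, mode=%s%s\n",
    length(x$values), sum(x$chrom_lengths), x$normalization, x$source_mode,
    if (is.null(x$sigma_applied)) "" else sprintf(", sigma=%g", x$sigma_applied)))
  invisible(x)
}

track_total <- function(track) sum(vapply(track$values, sum, 0))
track_mean <- function(track) track_total(track) / sum(track$chrom_lengths)

#' Filter fragments by length
#'
#' Retains fragments whose length satisfies `min_bp <= end - start <= max_bp`
#' and records the applied range on the returned set. MNase and ChIP
#' libraries are filtered to exclude sizes outside the expected protected or
#' sonicated fragment range.
#'
#' @param frags A [fragment_set()].
#' @param min_bp,max_bp Inclusive length bounds (bp).
#' @return A filtered `FragmentSet`.
#' @export
filter_fragments_by_size <- function(frags, min_bp, max_bp) {
  if (min_bp > max_bp) stop("min_bp must be <= max_bp")
  len <- frags$end - frags$start
  keep <- len >= min_bp & len <= max_bp
  out <- frags[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_label") <- attr(frags, "sample_label")
  attr(out, "size_filter") <- c(min_bp, max_bp)
  class(out) <- c("FragmentSet", "data.frame")
  if (nrow(out) == 0) warning("size filter removed all fragments")
  out
}

#' Deduplicate fragments
#'
#' Removes exact duplicate (chrom, start, end) records, a proxy for PCR
#' duplicate removal. Off by default throughout the pipeline.
#'
#' @param frags A [fragment_set()].
#' @return A `FragmentSet` without duplicate records.
#' @export
dedup_fragments <- function(frags) {
  keep <- !duplicated(frags[, c("chrom", "start", "end")])
  out <- frags[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_label") <- attr(frags, "sample_label")
  attr(out, "size_filter") <- attr(frags, "size_filter")
  class(out) <- c("FragmentSet", "data.frame")
  out
}

#' Per-base coverage from fragments
#'
#' `full_span` adds 1 to every base a fragment covers; `midpoint` adds 1 at
#' `floor((start + end) / 2)` only (the convention used for nucleosome dyad
#' profiling, where the fragment midpoint estimates the dyad).
#'
#' @param frags A [fragment_set()].
#' @param genome The [genome()].
#' @param mode `"full_span"` or `"midpoint"`.
#' @return A raw [coverage_track()].
#' @export
coverage_from_fragments <- function(frags, genome,
                                    mode = c("full_span", "midpoint")) {
  stopifnot_genome(genome)
  mode <- match.arg(mode)
  values <- lapply(genome$chrom_names, function(cn) {
    L <- as.integer(genome$chrom_lengths[cn])
    sel <- frags$chrom == cn
    if (!any(sel)) return(numeric(L))
    s <- as.integer(frags$start[sel])
    e <- as.integer(frags$end[sel])
    if (mode == "midpoint") {
      mid <- (s + e) %/% 2L
      as.numeric(tabulate(mid + 1L, nbins = L))
    } else {
      # difference-array trick: +1 at start, -1 past end, then cumsum
      d <- numeric(L + 1L)
      add <- tabulate(s + 1L, nbins = L + 1L)
      subtr <- tabulate(e + 1L, nbins = L + 1L)
      cumsum(add - subtr)[seq_len(L)]
    }
  })
  names(values) <- genome$chrom_names
  coverage_track(values, genome, normalization = "raw", source_mode = mode)
}

gaussian_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  d <- seq(-r, r)
  w <- exp(-d^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian smoothing of a coverage track
#'
#' Discrete convolution with a Gaussian kernel truncated at 4 sigma and
#' renormalized to unit sum. At chromosome ends the kernel is renormalized
#' over the in-bounds support (no padding is fabricated), so total signal is
#' conserved in the interior and only redistributed near ends. `sigma = 0`
#' returns the track unchanged.
#'
#' @param track A [coverage_track()].
#' @param sigma Kernel standard deviation (bp).
#' @param circular Treat each chromosome as circular (wrap-around
#'   convolution; conserves total mass exactly). Mainly for validation.
#' @return A smoothed `CoverageTrack` with `sigma_applied` set.
#' @export
smooth_gaussian <- function(track, sigma = 4, circular = FALSE) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(track)
  w <- gaussian_kernel(sigma)
  r <- (length(w) - 1L) %/% 2L
  vals <- lapply(track$values, function(x) {
    n <- length(x)
    if (circular) {
      as.numeric(stats::filter(x, w, method = "convolution", sides = 2,
                               circular = TRUE))
    } else {
      xp <- c(numeric(r), x, numeric(r))
      num <- stats::filter(xp, w, method = "convolution", sides = 2)
      norm <- stats::filter(c(numeric(r), rep(1, n), numeric(r)), w,
                            method = "convolution", sides = 2)
      as.numeric(num[(r + 1L):(r + n)]) / as.numeric(norm[(r + 1L):(r + n)])
    }
  })
  structure(list(values = vals,
                 chrom_lengths = track$chrom_lengths,
                 normalization = track$normalization,
                 source_mode = track$source_mode,
                 sigma_applied = sigma),
            class = "CoverageTrack")
}

#' Normalize a track to its genome-wide mean
#'
#' Divides every base by the genome-wide mean coverage so the resulting
#' track has mean 1. This is the within-sample normalization applied before
#' all enrichment and occupancy-change computation; it removes sequencing
#' depth but, by construction, also any genuine global shift (which is why
#' global RNAP II changes need spike-in scaling instead).
#'
#' @param track A [coverage_track()].
#' @return A `CoverageTrack` with `normalization = "genome_mean"`.
#' @export
normalize_genome_mean <- function(track) {
  m <- track_mean(track)
  if (m <= 0) stop("cannot normalize a track with zero genome-wide mean")
  vals <- lapply(track$values, function(x) x / m)
  structure(list(values = vals,
                 chrom_lengths = track$chrom_lengths,
                 normalization = "genome_mean",
                 source_mode = track$source_mode,
                 sigma_applied = track$sigma_applied),
            class = "CoverageTrack")
}

#' Scale a track by a constant factor
#'
#' Used to apply spike-in scale factors; marks the track `spikein`.
#'
#' @param track A [coverage_track()].
#' @param factor Positive scalar multiplier.
#' @return A scaled `CoverageTrack` with `normalization = "spikein"`.
#' @export
scale_track <- function(track, factor) {
  if (!is.finite(factor) || factor <= 0) stop("factor must be positive")
  vals <- lapply(track$values, function(x) x * factor)
  structure(list(values = vals,
                 chrom_lengths = track$chrom_lengths,
                 normalization = "spikein",
                 source_mode = track$source_mode,
                 sigma_applied = track$sigma_applied),
            class = "CoverageTrack")
}

#' Write a coverage track as bedGraph
#'
#' 0-based half-open intervals; runs of equal values are merged into one
#' interval, and zero runs are written explicitly so the genome-wide mean is
#' reconstructible from the file alone. A JSON sidecar (`<path>.json`)
#' records the normalization state.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @param sidecar Also write the JSON sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, sidecar = TRUE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cn in names(track$values)) {
    x <- track$values[[cn]]
    r <- rle(x)
    ends <- cumsum(r$lengths)
    starts <- c(0, ends[-length(ends)])
    writeLines(sprintf("%s\t%d\t%d\t%s", cn, as.integer(starts),
                       as.integer(ends),
                       sprintf("%.15g", r$values)), con)
  }
  if (sidecar)
    write_manifest(list(normalization = track$normalization,
                        source_mode = track$source_mode,
                        sigma_applied = track$sigma_applied),
                   paste0(path, ".json"))
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Inverse of [write_bedgraph()]. Bases not covered by any interval are 0.
#' If the JSON sidecar is present its normalization state is restored.
#'
#' @param path Path to a bedGraph file.
#' @param genome A [genome()].
#' @return A `CoverageTrack`.
#' @export
read_bedgraph <- function(path, genome) {
  stopifnot_genome(genome)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           stringsAsFactors = FALSE)
  bad <- !(tab$chrom %in% genome$chrom_names)
  if (any(bad)) stop(sprintf("bedGraph line %d: unknown chromosome",
                             which(bad)[1]))
  values <- lapply(genome$chrom_names, function(cn) {
    L <- as.integer(genome$chrom_lengths[cn])
    x <- numeric(L)
    sel <- which(tab$chrom == cn)
    for (i in sel) {
      if (tab$end[i] > L || tab$start[i] < 0)
        stop(sprintf("bedGraph interval outside chromosome %s", cn))
      x[(tab$start[i] + 1L):tab$end[i]] <- tab$value[i]
    }
    x
  })
  names(values) <- genome$chrom_names
  meta <- list(normalization = "raw", source_mode = "full_span",
               sigma_applied = NULL)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    got <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta[names(got)] <- got
  }
  coverage_track(values, genome, normalization = meta$normalization,
                 source_mode = meta$source_mode,
                 sigma_applied = meta$sigma_applied)
}
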