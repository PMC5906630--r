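#' Tile the genome into sliding windows
#'
#' Per chromosome, windows start at 0 and advance by `step`; windows that
#' would extend past the chromosome end are dropped, giving
#' `floor((L - size) / step) + 1` windows on a chromosome of length
#' `L >= size` and none otherwise.
#'
#' @param genome A [genome()].
#' @param size,step Window size and step (bp), `step <= size`.
#' @return A `WindowTable`: data frame with `chrom`, `start`, `end`.
#' @export
tile_windows <- function(genome, size = 500, step = 250) {
  stopifnot_genome(genome)
  if (step > size) stop("step must be <= size")
  if (step <= 0 || size <= 0) stop("size and step must be positive")
  parts <- lapply(genome$chrom_names, function(cn) {
    L <- genome$chrom_lengths[cn]
    if (L < size) return(NULL)
    n <- floor((L - size) / step) + 1
    starts <- (seq_len(n) - 1) * step
    data.frame(chrom = cn, start = starts, end = starts + size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("WindowTable", "data.frame")
  out
}

#' Mean signal per window
#'
#' Arithmetic mean of per-base track values over each `[start, end)`
#' interval, computed with per-chromosome cumulative sums.
#'
#' @param track A [coverage_track()].
#' @param windows A window table (or any data frame with `chrom`, `start`,
#'   `end`).
#' @return Numeric vector, one mean per window.
#' @export
window_signal <- function(track, windows) {
  cums <- lapply(track$values, function(x) c(0, cumsum(x)))
  out <- numeric(nrow(windows))
  for (cn in unique(windows$chrom)) {
    sel <- windows$chrom == cn
    cs <- cums[[cn]]
    if (is.null(cs)) stop(sprintf("track has no chromosome '%s'", cn))
    s <- windows$start[sel]
    e <- windows$end[sel]
    out[sel] <- (cs[e + 1] - cs[s + 1]) / (e - s)
  }
  out
}

#' Nucleosome occupancy change
#'
#' Difference of genome-mean-normalized MNase occupancies,
#' `control - treatment`, so positive values mean nucleosome loss. A
#' log2-ratio mode is available but undefined at zero-coverage windows.
#'
#' @param occ_control,occ_treatment Per-window (or per-site) occupancy from
#'   mean-normalized tracks.
#' @param method `"difference"` (default) or `"log2_ratio"`.
#' @param pseudocount Added to both terms in log2-ratio mode.
#' @return Numeric vector of occupancy changes (positive = loss).
#' @export
occupancy_change <- function(occ_control, occ_treatment,
                             method = c("difference", "log2_ratio"),
                             pseudocount = 0) {
  method <- match.arg(method)
  if (length(occ_control) != length(occ_treatment))
    stop("occupancy vectors must have equal length")
  if (method == "difference") {
    occ_control - occ_treatment
  } else {
    log2((occ_control + pseudocount) / (occ_treatment + pseudocount))
  }
}

#' Quantile bin labels
#'
#' Partitions values into `n_bins` near-equal groups by rank: rank
#' boundaries at `ceiling(k * n / n_bins)`, with q1 the lowest fifth (for
#' the default quintiles). Ties are broken by stable input order, so bin
#' sizes differ by at most 1; a warning notes heavy ties.
#'
#' @param values Numeric vector, `length(values) >= n_bins`.
#' @param n_bins Number of bins (default 5).
#' @param labels Label prefix (default `"q"`, giving `q1..q5`).
#' @return Factor of bin labels aligned with `values`.
#' @export
quantile_bins <- function(values, n_bins = 5, labels = "q") {
  n <- length(values)
  if (n < n_bins) stop("need at least n_bins values")
  ord <- order(values)                      # stable for ties
  bounds <- ceiling(seq_len(n_bins) * n / n_bins)
  bin_of_rank <- findInterval(seq_len(n) - 1L, c(0L, bounds[-n_bins])) # 1..n_bins
  bins <- integer(n)
  bins[ord] <- bin_of_rank
  if (any(duplicated(values)) &&
      length(unique(values)) < n_bins)
    warning("heavy ties: bins determined by stable input order")
  factor(paste0(labels, bins), levels = paste0(labels, seq_len(n_bins)))
}

#' Welch's two-sample t-test
#'
#' Two-sided location test without the equal-variance assumption:
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric samples, each of length >= 2 with nonzero variance in
#'   at least one.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    # degenerate limit: identical constants -> no evidence; distinct
    # constants -> infinitely strong evidence
    if (mean(a) == mean(b)) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2, p = 0))
  }
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Box-plot summary statistics
#'
#' Quartiles by the midpoint (Tukey hinge) rule: the data are split at the
#' median (included in both halves when n is odd) and each hinge is the
#' median of its half. Whiskers extend to the most extreme data within
#' 1.5 * IQR of the box; notches are
#' `median +/- notch_constant * IQR / sqrt(n)`, an approximate 95%
#' confidence interval for the median.
#'
#' @param values Numeric vector, n >= 1.
#' @param notch_constant Notch multiplier (default 1.58).
#' @return A `BoxplotSummary` list: `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `notch_lo`, `notch_hi`, `n`.
#' @export
boxplot_stats <- function(values, notch_constant = 1.58) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("need at least one value")
  s <- sort(values)
  med <- stats::median(s)
  if (n == 1) {
    q1 <- q3 <- med
  } else {
    half <- if (n %% 2 == 0) n / 2 else (n + 1) / 2
    q1 <- stats::median(s[seq_len(half)])
    q3 <- stats::median(s[seq.int(n - half + 1, n)])
  }
  iqr <- q3 - q1
  lo_fence <- q1 - 1.5 * iqr
  hi_fence <- q3 + 1.5 * iqr
  wlo <- min(s[s >= lo_fence])
  whi <- max(s[s <= hi_fence])
  notch <- notch_constant * iqr / sqrt(n)
  structure(list(median = med, q1 = q1, q3 = q3,
                 whisker_lo = wlo, whisker_hi = whi,
                 notch_lo = med - notch, notch_hi = med + notch,
                 n = n),
            class = "BoxplotSummary")
}

#' Per-bin association of occupancy change with a binned covariate
#'
#' The quintile-association engine: given per-unit occupancy changes and bin
#' labels (e.g. DVNP-enrichment quintiles), returns per-bin box-plot
#' summaries, per-bin medians/means, and the two-sided Welch test of the top
#' versus bottom bin.
#'
#' @param occ_change Per-unit occupancy change (positive = loss).
#' @param bins Factor of bin labels covering all units (see
#'   [quantile_bins()]).
#' @param notch_constant Passed to [boxplot_stats()].
#' @return A list with `summaries` (per-bin `BoxplotSummary`), `medians`,
#'   `means`, `n`, and `test` (Welch top-vs-bottom: `t`, `df`, `p`).
#' @export
bin_association <- function(occ_change, bins, notch_constant = 1.58) {
  if (length(occ_change) != length(bins))
    stop("occ_change and bins must align")
  bins <- droplevels(as.factor(bins))
  groups <- split(occ_change, bins)
  if (any(lengths(groups) == 0)) stop("empty bin")
  summaries <- lapply(groups, boxplot_stats, notch_constant = notch_constant)
  lev <- levels(bins)
  test <- welch_t(groups[[lev[length(lev)]]], groups[[lev[1]]])
  list(summaries = summaries,
       medians = vapply(groups, stats::median, 0),
       means = vapply(groups, mean, 0),
       n = lengths(groups),
       test = test)
}

#' Input-signal strata
#'
#' Quantile strata of the ChIP input signal, used to control for DNA
#' accessibility bias: the binned association is re-examined within each
#' input stratum, so a trend driven purely by accessibility disappears
#' under stratification.
#'
#' @param input_signal Per-window input signal.
#' @param n_strata Number of strata (default 5).
#' @return Factor of stratum labels `s1..s5`.
#' @export
input_strata <- function(input_signal, n_strata = 5) {
  quantile_bins(input_signal, n_bins = n_strata, labels = "s")
}

#' Binned association within input strata
#'
#' Runs [bin_association()] separately inside each input stratum. Bin labels
#' are recomputed within each stratum from the supplied binning variable so
#' that every stratum contributes all bins.
#'
#' @param occ_change Per-window occupancy change.
#' @param bin_variable Variable to quantile-bin within each stratum (e.g.
#'   DVNP enrichment).
#' @param strata Stratum labels from [input_strata()].
#' @param n_bins Bins per stratum (default 5).
#' @return Named list (one element per stratum) of [bin_association()]
#'   results.
#' @export
stratified_association <- function(occ_change, bin_variable, strata,
                                   n_bins = 5) {
  strata <- droplevels(as.factor(strata))
  out <- lapply(levels(strata), function(sl) {
    sel <- strata == sl
    bins <- quantile_bins(bin_variable[sel], n_bins = n_bins)
    bin_association(occ_change[sel], bins)
  })
  names(out) <- levels(strata)
  out
}

#' Sequence-predicted nucleosome occupancy (GC proxy)
#'
#' GC content of the 147 bp window centered on each dyad, used as a proxy
#' for sequence-encoded nucleosome stability: GC-rich sequence is predicted
#' to form more stable, higher-occupancy nucleosomes. N bases are excluded
#' from both numerator and denominator; sites whose window runs off the
#' chromosome are dropped with a warning.
#'
#' @param genome A [genome()] with sequence.
#' @param sites Data frame with `chrom` and `dyad` columns (e.g. a
#'   nucleosome map).
#' @param window Window width centered on the dyad (default 147).
#' @return `sites` with a `predicted_occupancy` column appended (dropped
#'   sites removed).
#' @export
predicted_occupancy_gc <- function(genome, sites, window = 147) {
  stopifnot_genome(genome)
  cums <- gc_cumsums(genome)
  half <- window %/% 2
  start <- sites$dyad - half
  end <- start + window
  lens <- genome$chrom_lengths[sites$chrom]
  ok <- start >= 0 & end <= lens
  if (any(!ok)) {
    warning(sprintf("%d site(s) dropped: %d bp window off chromosome",
                    sum(!ok), window))
    sites <- sites[ok, , drop = FALSE]
    start <- start[ok]; end <- end[ok]
  }
  gc <- numeric(nrow(sites))
  for (cn in unique(sites$chrom)) {
    sel <- sites$chrom == cn
    gc[sel] <- gc_fraction(cums[[cn]], start[sel], end[sel])
  }
  sites$predicted_occupancy <- gc
  rownames(sites) <- NULL
  sites
}

#' Occupancy over nucleosomal sites
#'
#' Mean normalized coverage over the 147 bp window `[dyad - 73, dyad + 74)`
#' of each nucleosome site.
#'
#' @param track A normalized [coverage_track()].
#' @param sites Data frame with `chrom` and `dyad`.
#' @return Numeric vector of per-site occupancies.
#' @export
nucleosome_site_signal <- function(track, sites) {
  win <- data.frame(chrom = sites$chrom,
                    start = sites$dyad - 73,
                    end = sites$dyad + 74)
  lens <- track$chrom_lengths[win$chrom]
  if (any(win$start < 0 | win$end > lens))
    stop("nucleosome site window outside chromosome")
  window_signal(track, win)
}

#' Build the genome-wide window association table
#'
#' Convenience wrapper producing the sliding-window table underlying the
#' DVNP-vs-nucleosome-loss association: windows are tiled, per-window DVNP
#' enrichment (IP/input of mean-normalized tracks, or IP alone), input
#' signal, and MNase occupancy change are computed, and quintile/stratum
#' labels are attached.
#'
#' @param genome A [genome()].
#' @param chip_ip,chip_input Mean-normalized ChIP coverage tracks.
#' @param mnase_control,mnase_treatment Mean-normalized MNase tracks.
#' @param size,step Window tiling parameters.
#' @param n_bins Quantile bins (default 5).
#' @param enrichment Per-window enrichment mode: `"ratio"` (IP/input) or
#'   `"ip_only"`.
#' @param min_input Windows with input signal below this are dropped in
#'   ratio mode (guards against division by ~0; default 0.05).
#' @param min_occupancy Windows whose control MNase occupancy falls below
#'   this (in genome-mean units; default 1.2, i.e. above-average occupancy)
#'   are dropped. Occupancy change is undefined where there are no
#'   nucleosomes, and because the change statistic scales with the
#'   occupancy level itself, restricting to solidly nucleosomal windows
#'   keeps the per-quintile comparison from mixing coverage regimes. The
#'   number dropped is reported via the `n_dropped` attribute.
#' @return A `WindowTable` with columns `dvnp_enrichment`, `input_signal`,
#'   `occ_control`, `occ_treatment`, `occ_change`, `dvnp_bin`,
#'   `input_stratum`.
#' @export
window_association_table <- function(genome, chip_ip, chip_input,
                                     mnase_control, mnase_treatment,
                                     size = 500, step = 250, n_bins = 5,
                                     enrichment = c("ratio", "ip_only"),
                                     min_input = 0.05,
                                     min_occupancy = 1.2) {
  enrichment <- match.arg(enrichment)
  win <- tile_windows(genome, size = size, step = step)
  n_raw <- nrow(win)
  ip <- window_signal(chip_ip, win)
  input <- window_signal(chip_input, win)
  if (enrichment == "ratio") {
    keep <- input >= min_input
    win <- win[keep, , drop = FALSE]
    ip <- ip[keep]; input <- input[keep]
    win$dvnp_enrichment <- ip / input
  } else {
    win$dvnp_enrichment <- ip
  }
  win$input_signal <- input
  win$occ_control <- window_signal(mnase_control, win)
  win$occ_treatment <- window_signal(mnase_treatment, win)
  keep <- win$occ_control >= min_occupancy
  win <- win[keep, , drop = FALSE]
  attr(win, "n_dropped") <- n_raw - nrow(win)
  win$occ_change <- occupancy_change(win$occ_control, win$occ_treatment)
  win$dvnp_bin <- quantile_bins(win$dvnp_enrichment, n_bins = n_bins)
  win$input_stratum <- input_strata(win$input_signal, n_strata = n_bins)
  rownames(win) <- NULL
  class(win) <- c("WindowTable", "data.frame")
  win
}
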