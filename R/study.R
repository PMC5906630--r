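#' dvnpchrom: nucleosome displacement analysis for a viral nucleoprotein
#'
#' Pipeline stages for quantifying chromatin disruption by the
#' dinoflagellate-viral nucleoprotein DVNP expressed in budding yeast:
#' fragment I/O and normalized coverage, TSS-anchored metagene profiles,
#' sliding-window quintile association of DVNP enrichment with nucleosome
#' loss, GC-based predicted nucleosome stability, spike-in normalized RNAP
#' II occupancy change, and synthetic genetic array screen statistics --
#' together with a synthetic-data generator planting known ground truth.
#'
#' @keywords internal
"_PACKAGE"

#' Mean-normalized MNase/ChIP coverage from fragments
#'
#' Standard preprocessing for one library: size filtering, optional
#' deduplication, coverage (full span or midpoints), optional Gaussian
#' smoothing, and genome-mean normalization.
#'
#' @param frags A [fragment_set()].
#' @param genome A [genome()].
#' @param size_range Length filter (bp).
#' @param mode `"full_span"` or `"midpoint"`.
#' @param sigma Gaussian smoothing SD (0 = none).
#' @param dedup Remove duplicate fragments first.
#' @return A genome-mean normalized [coverage_track()].
#' @export
prepare_track <- function(frags, genome, size_range = c(0, Inf),
                          mode = "full_span", sigma = 0, dedup = FALSE) {
  f <- filter_fragments_by_size(frags, size_range[1], size_range[2])
  if (dedup) f <- dedup_fragments(f)
  tr <- coverage_from_fragments(f, genome, mode)
  if (sigma > 0) tr <- smooth_gaussian(tr, sigma)
  normalize_genome_mean(tr)
}

#' Genome-wide DVNP / nucleosome-loss association stage
#'
#' Runs the sliding-window association on a simulated (or real) study:
#' builds mean-normalized tracks for ChIP IP, ChIP input, and the two MNase
#' conditions, assembles the window table with DVNP quintiles and input
#' strata, and returns the per-quintile association plus its
#' input-stratified version.
#'
#' @param study A [simulate_study()] result (or a list with the same
#'   `genome`, `chip`, `mnase_control`, `mnase_dvnp`, `config` fields).
#' @param enrichment `"ratio"` (IP/input) or `"ip_only"`.
#' @return List with `windows` (the table), `association`
#'   ([bin_association()] on DVNP quintiles), and `stratified`
#'   ([stratified_association()] across input strata).
#' @export
occupancy_association_stage <- function(study,
                                        enrichment = c("ratio", "ip_only")) {
  enrichment <- match.arg(enrichment)
  cfg <- study$config
  gen <- study$genome
  ip <- prepare_track(study$chip$ip, gen, cfg$chip_size_range)
  input <- prepare_track(study$chip$input, gen, cfg$chip_size_range)
  # midpoint counting assigns each MNase fragment to exactly one window,
  # so occupancy noise in disjoint windows is independent
  mn_c <- prepare_track(study$mnase_control, gen, cfg$mnase_size_range,
                        mode = "midpoint")
  mn_d <- prepare_track(study$mnase_dvnp, gen, cfg$mnase_size_range,
                        mode = "midpoint")
  win <- window_association_table(gen, ip, input, mn_c, mn_d,
                                  size = cfg$window_size,
                                  step = cfg$window_step,
                                  n_bins = cfg$n_bins,
                                  enrichment = enrichment)
  assoc <- bin_association(win$occ_change, win$dvnp_bin,
                           notch_constant = cfg$notch_constant)
  strat <- stratified_association(win$occ_change, win$dvnp_enrichment,
                                  win$input_stratum, n_bins = cfg$n_bins)
  list(windows = win, association = assoc, stratified = strat)
}

#' Nucleosome-stability protection stage
#'
#' The predicted-occupancy analysis: per nucleosome site, GC-predicted
#' occupancy (147 bp window on the dyad) and observed occupancy change
#' between MNase conditions; sites are binned into predicted-occupancy
#' quintiles and the per-quintile loss compared (weak q1 vs stable q5).
#'
#' @param study A [simulate_study()] result.
#' @param sites Optional dyad table (`chrom`, `dyad`); defaults to the
#'   simulation's planted nucleosome map.
#' @return List with `sites` (the annotated table) and `association`
#'   (per-quintile [bin_association()]; note `test` compares q5 vs q1).
#' @export
stability_stage <- function(study, sites = NULL) {
  cfg <- study$config
  gen <- study$genome
  if (is.null(sites)) sites <- study$map$sites[, c("chrom", "dyad")]
  sites <- predicted_occupancy_gc(gen, sites, window = 147)
  mn_c <- prepare_track(study$mnase_control, gen, cfg$mnase_size_range,
                        mode = "midpoint")
  mn_d <- prepare_track(study$mnase_dvnp, gen, cfg$mnase_size_range,
                        mode = "midpoint")
  occ_c <- nucleosome_site_signal(mn_c, sites)
  occ_t <- nucleosome_site_signal(mn_d, sites)
  sites$occ_change <- occupancy_change(occ_c, occ_t)
  sites$occupancy_bin <- quantile_bins(sites$predicted_occupancy,
                                       n_bins = cfg$n_bins)
  assoc <- bin_association(sites$occ_change, sites$occupancy_bin,
                           notch_constant = cfg$notch_constant)
  list(sites = sites, association = assoc)
}

#' Metagene stage for the MNase conditions
#'
#' Midpoint coverage, Gaussian smoothing (sigma from the config),
#' genome-mean normalization, and TSS-anchored metagene profiles for the
#' control and DVNP-condition MNase libraries.
#'
#' @param study A [simulate_study()] result.
#' @return List with `control` and `dvnp` [metagene_profile()]s.
#' @export
mnase_metagene_stage <- function(study) {
  cfg <- study$config
  gen <- study$genome
  mk <- function(frags) {
    tr <- prepare_track(frags, gen, cfg$mnase_size_range,
                        mode = "midpoint", sigma = cfg$smoothing_sigma)
    metagene_profile(tr, study$genes, upstream = cfg$upstream,
                     downstream = cfg$downstream)
  }
  list(control = mk(study$mnase_control), dvnp = mk(study$mnase_dvnp))
}
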