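#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the study design this package implements: metagene windows 500 bp upstream
#' to 2500 bp downstream of the TSS, Gaussian midpoint smoothing with a 4 bp
#' standard deviation, genome tiling into 500 bp windows with 250 bp steps,
#' quintile (5-bin) association, a 300 bp 3'-end buffer for RNAP II gene-body
#' quantification, and 1.58 * IQR / sqrt(n) box-plot notches.
#'
#' @param smoothing_sigma Gaussian smoothing standard deviation (bp).
#' @param window_size,window_step Genome tiling window size and step (bp);
#'   `window_step <= window_size`.
#' @param n_bins Number of quantile bins (default 5, i.e. quintiles).
#' @param upstream,downstream Metagene extent around the TSS (bp).
#' @param rpb3_end_buffer Gene-body 3' buffer for RNAP II occupancy (bp).
#' @param mnase_size_range,chip_size_range Fragment length filters (bp).
#' @param notch_constant Box-plot notch multiplier.
#' @param sga_pos_threshold,sga_neg_threshold Relative-growth thresholds for
#'   rescuer / sensitizer calls; `NULL` means derive from the data
#'   (1 +/- 2 robust SD, see [classify_hits()]).
#' @param dedup Remove duplicate fragments before coverage (default FALSE).
#' @param random_seed Integer seed recorded in run manifests.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(smoothing_sigma = 4,
                            window_size = 500,
                            window_step = 250,
                            n_bins = 5,
                            upstream = 500,
                            downstream = 2500,
                            rpb3_end_buffer = 300,
                            mnase_size_range = c(120, 200),
                            chip_size_range = c(50, 500),
                            notch_constant = 1.58,
                            sga_pos_threshold = NULL,
                            sga_neg_threshold = NULL,
                            dedup = FALSE,
                            random_seed = 1L) {
  cfg <- list(smoothing_sigma = smoothing_sigma,
              window_size = window_size,
              window_step = window_step,
              n_bins = n_bins,
              upstream = upstream,
              downstream = downstream,
              rpb3_end_buffer = rpb3_end_buffer,
              mnase_size_range = mnase_size_range,
              chip_size_range = chip_size_range,
              notch_constant = notch_constant,
              sga_pos_threshold = sga_pos_threshold,
              sga_neg_threshold = sga_neg_threshold,
              dedup = isTRUE(dedup),
              random_seed = as.integer(random_seed))
  if (cfg$window_step > cfg$window_size)
    stop("window_step must be <= window_size")
  if (cfg$n_bins < 2) stop("n_bins must be >= 2")
  bp <- c(cfg$smoothing_sigma, cfg$window_size, cfg$window_step,
          cfg$upstream, cfg$downstream, cfg$rpb3_end_buffer,
          cfg$mnase_size_range, cfg$chip_size_range)
  if (any(bp < 0)) stop("all bp parameters must be >= 0")
  if (cfg$mnase_size_range[1] > cfg$mnase_size_range[2] ||
      cfg$chip_size_range[1] > cfg$chip_size_range[2])
    stop("size ranges must be (min, max) with min <= max")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Vector values are
#' comma-separated. Unknown keys are an error; missing keys take the
#' [pipeline_config()] default.
#'
#' @param path Path to the config file.
#' @return A `PipelineConfig`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop(sprintf("malformed config line: '%s'",
                             lines[which(bad)[1]]))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  defaults <- pipeline_config()
  known <- setdiff(names(unclass(defaults)), character())
  unk <- setdiff(keys, known)
  if (length(unk) > 0)
    stop(sprintf("unknown config key(s): %s", paste(unk, collapse = ", ")))
  parsed <- lapply(seq_along(keys), function(i) {
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    if (keys[i] == "dedup") return(tolower(v) %in% c("true", "1", "yes"))
    suppressWarnings(num <- as.numeric(v))
    if (anyNA(num)) stop(sprintf("non-numeric value for key '%s'", keys[i]))
    num
  })
  names(parsed) <- keys
  do.call(pipeline_config, parsed)
}

#' Write a configuration file
#'
#' @param config A `PipelineConfig`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  lines <- vapply(names(cfg), function(k) {
    sprintf("%s = %s", k, paste(format(cfg[[k]], scientific = FALSE),
                                collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records effective parameters (and, for simulations, the planted ground
#' truth) alongside pipeline outputs so every run is reconstructible.
#'
#' @param x A named list (e.g. a config and/or simulation truth).
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
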