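#' Simulate a genome with smoothly varying GC content
#'
#' Nucleotides are drawn blockwise: each `gc_block` bp block gets a GC level
#' from a stationary AR(1) process around `gc_mean` (so GC varies smoothly
#' on the block scale, giving the sequence-encoded stability structure the
#' downstream GC-proxy analysis exploits), then bases are drawn i.i.d.
#' within the block with P(G) = P(C) = gc/2.
#'
#' @param n_chroms Number of chromosomes.
#' @param lengths Chromosome lengths (bp), recycled to `n_chroms`.
#' @param gc_mean Mean GC fraction in (0, 1).
#' @param gc_block Block size (bp) of GC variation.
#' @param gc_sd Stationary SD of the block GC process.
#' @param gc_rho AR(1) correlation between adjacent blocks.
#' @param seed Integer seed (deterministic output).
#' @return A [genome()] with sequence.
#' @export
simulate_genome <- function(n_chroms = 1, lengths = 1e5, gc_mean = 0.39,
                            gc_block = 500, gc_sd = 0.1, gc_rho = 0.5,
                            seed = 1) {
  if (gc_mean <= 0 || gc_mean >= 1) stop("gc_mean must be in (0, 1)")
  if (gc_block < 1) stop("gc_block must be >= 1")
  set.seed(seed)
  lengths <- rep_len(as.integer(lengths), n_chroms)
  nm <- paste0("chr", utils::as.roman(seq_len(n_chroms)))
  seqs <- vapply(seq_len(n_chroms), function(i) {
    L <- lengths[i]
    nb <- ceiling(L / gc_block)
    e <- numeric(nb)
    e[1] <- stats::rnorm(1, 0, gc_sd)
    if (nb > 1)
      for (b in 2:nb)
        e[b] <- gc_rho * e[b - 1] +
          stats::rnorm(1, 0, gc_sd * sqrt(1 - gc_rho^2))
    g <- pmin(0.95, pmax(0.05, gc_mean + e))
    blen <- c(rep(gc_block, nb - 1), L - gc_block * (nb - 1))
    p_gc <- rep(g, times = blen)
    is_gc <- stats::runif(L) < p_gc
    u <- stats::runif(L) < 0.5
    base <- ifelse(is_gc, ifelse(u, "G", "C"), ifelse(u, "A", "T"))
    paste(base, collapse = "")
  }, "")
  names(lengths) <- nm
  names(seqs) <- nm
  genome(lengths, seqs)
}

#' Simulate non-overlapping genes
#'
#' Places genes sequentially along each chromosome with random lengths,
#' strands, and inter-gene gaps, reserving a `flank` bp margin on both sides
#' of every gene so promoter windows of adjacent genes never overlap. The
#' target count is split across chromosomes in proportion to length.
#'
#' @param genome A [genome()].
#' @param n_genes Number of genes to place.
#' @param len_range Gene length range (bp).
#' @param flank Reserved flank per gene side (bp, default 500).
#' @param gap_range Extra random gap between reserved regions (bp).
#' @param seed Integer seed.
#' @return A [gene_annotation()].
#' @export
simulate_genes <- function(genome, n_genes, len_range = c(1000, 2500),
                           flank = 500, gap_range = c(0, 600), seed = 1) {
  stopifnot_genome(genome)
  set.seed(seed)
  if (n_genes == 0)
    return(gene_annotation(character(), character(), character(),
                           numeric(), numeric(), genome))
  total <- sum(genome$chrom_lengths)
  quota <- round(n_genes * genome$chrom_lengths / total)
  # fix rounding so quotas sum to n_genes
  excess <- sum(quota) - n_genes
  if (excess != 0) quota[1] <- quota[1] - excess
  rows <- list()
  placed <- 0
  for (cn in genome$chrom_names) {
    L <- genome$chrom_lengths[cn]
    cursor <- flank
    k <- 0
    while (k < quota[cn]) {
      len <- round(stats::runif(1, len_range[1], len_range[2]))
      if (cursor + len + flank > L) break
      strand <- sample(c("+", "-"), 1)
      tss <- if (strand == "+") cursor else cursor + len
      polya <- if (strand == "+") cursor + len else cursor
      placed <- placed + 1
      k <- k + 1
      rows[[length(rows) + 1]] <-
        data.frame(id = sprintf("g%04d", placed), chrom = cn,
                   strand = strand, tss = tss, polya = polya,
                   stringsAsFactors = FALSE)
      gap <- round(stats::runif(1, gap_range[1], gap_range[2]))
      cursor <- cursor + len + 2 * flank + gap
    }
  }
  if (placed < n_genes)
    stop(sprintf("could only place %d of %d genes without overlap",
                 placed, n_genes))
  tab <- do.call(rbind, rows)
  gene_annotation(tab$id, tab$chrom, tab$strand, tab$tss, tab$polya, genome)
}

#' Build a phased nucleosome map around gene promoters
#'
#' Emulates the canonical yeast promoter architecture: a nucleosome-depleted
#' region (NDR) immediately upstream of each TSS, a -1 nucleosome upstream of
#' the NDR, a +1 nucleosome just downstream of the TSS, and phased genic
#' nucleosomes every `spacing` bp until the polyadenylation site. Each
#' site's occupancy weight encodes sequence-dependent stability:
#' `weight = base_occupancy * (1 + stability_coupling * (GC147 - mean GC147))`
#' clipped to (0, 1], where GC147 is the GC fraction of the 147 bp window
#' centered on the dyad. With `stability_coupling = 0` all weights are equal.
#'
#' @param genes A [gene_annotation()].
#' @param genome A [genome()] (sequence required when
#'   `stability_coupling > 0`).
#' @param spacing Nucleosome repeat length (bp, default 165).
#' @param ndr_width NDR width upstream of the TSS (bp, default 140).
#' @param stability_coupling Coupling of weight to GC stability (gamma >= 0).
#' @param base_occupancy Baseline occupancy weight in (0, 1].
#' @return A `NucleosomeMap`: list with `sites` (chrom, dyad, weight,
#'   gene_id, nuc_index; nuc_index -1 is the -1 nucleosome, 1 the +1, ...)
#'   and `ndr` (gene_id, chrom, center, width), plus `spacing`.
#' @export
build_nucleosome_map <- function(genes, genome, spacing = 165,
                                 ndr_width = 140, stability_coupling = 0,
                                 base_occupancy = 0.8) {
  stopifnot_genome(genome)
  if (stability_coupling < 0) stop("stability_coupling must be >= 0")
  dir <- gene_direction(genes)
  glen <- gene_length(genes)
  site_rows <- vector("list", nrow(genes))
  ndr_rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    n_genic <- max(0, floor((glen[i] - 73) / spacing) + 1)
    genic_off <- 73 + spacing * seq_len(n_genic) - spacing
    offs <- c(-(ndr_width + 73), genic_off)
    idx <- c(-1L, seq_len(n_genic))
    dyads <- genes$tss[i] + dir[i] * offs
    L <- genome$chrom_lengths[genes$chrom[i]]
    ok <- dyads >= 73 & dyads <= L - 74
    site_rows[[i]] <- data.frame(chrom = genes$chrom[i],
                                 dyad = dyads[ok],
                                 gene_id = genes$id[i],
                                 nuc_index = idx[ok],
                                 stringsAsFactors = FALSE)
    ndr_rows[[i]] <- data.frame(gene_id = genes$id[i],
                                chrom = genes$chrom[i],
                                center = genes$tss[i] - dir[i] * ndr_width / 2,
                                width = ndr_width,
                                stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  if (stability_coupling > 0) {
    sites <- predicted_occupancy_gc(genome, sites, window = 147)
    gc <- sites$predicted_occupancy
    w <- base_occupancy * (1 + stability_coupling * (gc - mean(gc)))
    sites$weight <- pmin(1, pmax(1e-3, w))
  } else {
    sites$weight <- rep(base_occupancy, nrow(sites))
  }
  structure(list(sites = sites,
                 ndr = do.call(rbind, ndr_rows),
                 spacing = spacing,
                 ndr_width = ndr_width),
            class = "NucleosomeMap")
}

#' Per-base DVNP affinity track
#'
#' Models where DVNP binds. In `"nucleosome"` mode affinity follows
#' nucleosome-bound DNA: each site contributes a unit 147 bp footprint
#' `[dyad - 73, dyad + 74)`, with the promoter-proximal -1/+1 nucleosomes
#' boosted by `promoter_boost` (DVNP enrichment peaks there), and NDRs /
#' linkers receive only the small `floor` baseline. `"free_dna"` mode
#' returns the complement (a naive model in which the protein prefers
#' accessible DNA), included so the pipeline can be shown to distinguish
#' the two hypotheses. On top of the footprint profile, a smooth lognormal
#' concentration field (block scale `field_scale`, log-SD `field_sd`)
#' modulates local DVNP abundance, giving genuine region-to-region
#' variation in binding -- the variation the quintile association detects.
#' The track is scaled to a maximum of 1.
#'
#' @param map A [build_nucleosome_map()].
#' @param genome A [genome()].
#' @param mode `"nucleosome"` or `"free_dna"`.
#' @param floor Small baseline added everywhere (keeps sampling defined in
#'   gene deserts; default 0.02).
#' @param promoter_boost Multiplier on the -1/+1 nucleosome footprints.
#' @param field_sd Log-scale SD of the concentration field (0 = none).
#' @param field_scale Block scale of the field (bp).
#' @param seed Seed for the field (required when `field_sd > 0`).
#' @return A raw [coverage_track()].
#' @export
build_affinity_track <- function(map, genome,
                                 mode = c("nucleosome", "free_dna"),
                                 floor = 0.02, promoter_boost = 1.6,
                                 field_sd = 0, field_scale = 2000,
                                 seed = 1) {
  stopifnot_genome(genome)
  mode <- match.arg(mode)
  sites <- map$sites
  h <- ifelse(abs(sites$nuc_index) == 1, promoter_boost, 1)
  values <- lapply(genome$chrom_names, function(cn) {
    L <- as.integer(genome$chrom_lengths[cn])
    x <- numeric(L + 1L)
    sel <- which(sites$chrom == cn)
    if (length(sel) > 0) {
      s <- pmax(0L, as.integer(sites$dyad[sel]) - 73L)
      e <- pmin(L, as.integer(sites$dyad[sel]) + 74L)
      for (j in seq_along(sel)) {
        x[s[j] + 1L] <- x[s[j] + 1L] + h[sel[j]]
        x[e[j] + 1L] <- x[e[j] + 1L] - h[sel[j]]
      }
    }
    cumsum(x)[seq_len(L)]
  })
  names(values) <- genome$chrom_names
  mx <- max(vapply(values, max, 0))
  if (mx <= 0) stop("empty nucleosome map")
  values <- lapply(values, function(x) {
    a <- x / mx
    if (mode == "free_dna") a <- 1 - a
    a + floor
  })
  if (field_sd > 0) {
    set.seed(seed)
    values <- lapply(values, function(a) {
      L <- length(a)
      nb <- ceiling(L / field_scale)
      z <- numeric(nb)
      z[1] <- stats::rnorm(1, 0, field_sd)
      if (nb > 1)
        for (b in 2:nb)
          z[b] <- 0.5 * z[b - 1] + stats::rnorm(1, 0, field_sd * sqrt(0.75))
      blen <- c(rep(field_scale, nb - 1), L - field_scale * (nb - 1))
      a * exp(rep(z, times = blen))
    })
  }
  mx <- max(vapply(values, max, 0))
  values <- lapply(values, function(a) a / mx)
  coverage_track(values, genome, normalization = "raw",
                 source_mode = "full_span")
}

#' Planted simulation truth
#'
#' Records the ground-truth parameters a simulation plants so downstream
#' recovery can be checked: the per-base DVNP affinity track, the coupling
#' `loss_coupling` (beta) of DVNP affinity to nucleosome loss, the coupling
#' `stability_coupling` (gamma) making weak (low-weight) nucleosomes more
#' susceptible (loss proportional to `1/weight^gamma`), and the global RNAP
#' II occupancy ratio `rpb3_global_ratio` (r; treatment/control).
#'
#' @param affinity A [build_affinity_track()] coverage track.
#' @param loss_coupling beta >= 0.
#' @param stability_coupling gamma >= 0.
#' @param rpb3_global_ratio r in (0, 1].
#' @param seed Integer seed recorded verbatim.
#' @return A `SimulationTruth` list.
#' @export
simulation_truth <- function(affinity, loss_coupling = 0,
                             stability_coupling = 0,
                             rpb3_global_ratio = 1, seed = 1) {
  if (loss_coupling < 0) stop("loss_coupling must be >= 0")
  if (stability_coupling < 0) stop("stability_coupling must be >= 0")
  if (rpb3_global_ratio <= 0 || rpb3_global_ratio > 1)
    stop("rpb3_global_ratio must be in (0, 1]")
  structure(list(affinity = affinity,
                 loss_coupling = loss_coupling,
                 stability_coupling = stability_coupling,
                 rpb3_global_ratio = rpb3_global_ratio,
                 seed = as.integer(seed)),
            class = "SimulationTruth")
}

truth_manifest <- function(truth) {
  list(loss_coupling = truth$loss_coupling,
       stability_coupling = truth$stability_coupling,
       rpb3_global_ratio = truth$rpb3_global_ratio,
       seed = truth$seed)
}

# value of a coverage track at single (chrom, pos) coordinates
track_value_at <- function(track, chrom, pos) {
  out <- numeric(length(chrom))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    out[sel] <- track$values[[cn]][pos[sel] + 1]
  }
  out
}

# truncated-normal lengths via inverse-CDF; returned rounded to integer bp
rtrunc_lengths <- function(n, mean, sd, range) {
  lo <- stats::pnorm(range[1], mean, sd)
  hi <- stats::pnorm(range[2], mean, sd)
  u <- stats::runif(n, lo, hi)
  round(stats::qnorm(u, mean, sd))
}

# assemble a FragmentSet from midpoints and lengths, clipped to chromosome
fragments_from_midpoints <- function(mid, len, chrom, genome, label) {
  start <- mid - len %/% 2
  end <- start + len
  L <- genome$chrom_lengths[chrom]
  start <- pmax(0, start)
  end <- pmin(L, end)
  keep <- end > start
  fragment_set(chrom[keep], start[keep], end[keep], genome, label)
}

#' Simulate MNase-seq fragments from a nucleosome map
#'
#' Fragments are drawn per nucleosome site with probability proportional to
#' its occupancy weight (`condition = "control"`) or to
#' `weight * max(0, 1 - beta * affinity(dyad) * (mean(weight)/weight)^gamma)`
#' (`condition = "dvnp"`): DVNP-bound nucleosomes are displaced in
#' proportion to local DVNP affinity, and weak (low-weight) nucleosomes are
#' more susceptible when gamma > 0. Fragment midpoints jitter around the
#' dyad (Normal, SD `jitter_sd`); lengths are Normal(`frag_mean`,
#' `frag_sd`) truncated to `size_range`.
#'
#' @param map A [build_nucleosome_map()].
#' @param genome A [genome()].
#' @param truth A [simulation_truth()] (required for `condition = "dvnp"`).
#' @param n_fragments Number of fragments to draw.
#' @param condition `"control"` or `"dvnp"`.
#' @param frag_mean,frag_sd Fragment length distribution (bp).
#' @param size_range Truncation range (bp), the MNase-protected size band.
#' @param jitter_sd Midpoint jitter around the dyad (bp).
#' @param seed Integer seed.
#' @return A [fragment_set()] labelled `mnase_<condition>`.
#' @export
simulate_mnase <- function(map, genome, truth = NULL, n_fragments = 1e5,
                           condition = c("control", "dvnp"),
                           frag_mean = 147, frag_sd = 12,
                           size_range = c(120, 200), jitter_sd = 10,
                           seed = 1) {
  condition <- match.arg(condition)
  sites <- map$sites
  if (nrow(sites) == 0) stop("empty nucleosome map")
  set.seed(seed)
  w <- sites$weight
  if (condition == "dvnp") {
    if (is.null(truth)) stop("truth required for the dvnp condition")
    aff <- track_value_at(truth$affinity, sites$chrom, sites$dyad)
    susc <- (mean(w) / w)^truth$stability_coupling
    w <- w * pmax(0, 1 - truth$loss_coupling * aff * susc)
  }
  if (all(w <= 0)) stop("all effective site weights are zero")
  site <- sample.int(nrow(sites), n_fragments, replace = TRUE, prob = w)
  mid <- sites$dyad[site] + round(stats::rnorm(n_fragments, 0, jitter_sd))
  len <- rtrunc_lengths(n_fragments, frag_mean, frag_sd, size_range)
  fragments_from_midpoints(mid, len, sites$chrom[site], genome,
                           paste0("mnase_", condition))
}

# sample n midpoints genome-wide with per-base probability ∝ track
sample_midpoints <- function(track, n, uniform = FALSE) {
  lens <- track$chrom_lengths
  if (uniform) {
    chrom_w <- lens
  } else {
    chrom_w <- vapply(track$values, sum, 0)
  }
  n_per <- stats::rmultinom(1, n, chrom_w)[, 1]
  chrom <- rep(names(lens), n_per)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    k <- n_per[i]
    if (k == 0) return(integer())
    if (uniform) {
      sample.int(as.integer(lens[i]), k, replace = TRUE) - 1L
    } else {
      sample.int(as.integer(lens[i]), k, replace = TRUE,
                 prob = track$values[[i]]) - 1L
    }
  }), use.names = FALSE)
  list(chrom = chrom, pos = pos)
}

#' Simulate a DVNP ChIP-seq experiment
#'
#' IP fragment midpoints are sampled with per-base probability proportional
#' to the planted DVNP affinity track; input midpoints are sampled uniformly
#' (or proportional to a supplied accessibility track, to exercise the
#' input-stratification logic).
#'
#' @param truth A [simulation_truth()] carrying the affinity track.
#' @param genome A [genome()].
#' @param n_ip,n_input Fragment counts.
#' @param frag_mean,frag_sd,size_range Fragment length model (sonicated
#'   ChIP fragments).
#' @param input_track Optional accessibility [coverage_track()] for the
#'   input sample; `NULL` means uniform.
#' @param seed Integer seed.
#' @return List with `ip` and `input` [fragment_set()]s.
#' @export
simulate_dvnp_chip <- function(truth, genome, n_ip = 1e5, n_input = 1e5,
                               frag_mean = 150, frag_sd = 40,
                               size_range = c(50, 500),
                               input_track = NULL, seed = 1) {
  set.seed(seed)
  mk <- function(n, track, uniform, label) {
    if (n == 0)
      return(fragment_set(character(), numeric(), numeric(), genome, label))
    m <- sample_midpoints(track, n, uniform = uniform)
    len <- rtrunc_lengths(n, frag_mean, frag_sd, size_range)
    fragments_from_midpoints(m$pos, len, m$chrom, genome, label)
  }
  ip <- mk(n_ip, truth$affinity, FALSE, "dvnp_ip")
  input <- if (is.null(input_track)) {
    mk(n_input, truth$affinity, TRUE, "dvnp_input")
  } else {
    mk(n_input, input_track, FALSE, "dvnp_input")
  }
  list(ip = ip, input = input)
}

#' Simulate an Rpb3 (RNAP II) ChIP with spike-in controls
#'
#' Control-condition fragment midpoints fall in gene bodies with per-gene
#' probability proportional to `expression`; in the treatment condition
#' every gene's sampling rate is multiplied by the planted global ratio
#' `r = rpb3_global_ratio`. Both libraries are then resampled to exactly
#' `n_per_sample` genomic fragments, so the global reduction is invisible
#' from genomic reads alone. Spike-in read counts are drawn Poisson with
#' expectation `n_per_sample * spike_rate / (r_condition)`: the spike-in
#' mass is fixed while cellular material scales with r, so the treatment
#' spike fraction exceeds control by 1/r in expectation -- the signal the
#' spike-in normalization decodes.
#'
#' @param genes A [gene_annotation()].
#' @param genome A [genome()].
#' @param truth A [simulation_truth()] (uses `rpb3_global_ratio`).
#' @param expression Per-gene relative expression; default log-normal.
#' @param n_per_sample Genomic fragments per library.
#' @param spike_rate Expected spike reads per genomic read in the control.
#' @param spike_mass Named spike-in masses (ng) added to each sample.
#' @param frag_mean,frag_sd,size_range Fragment length model.
#' @param seed Integer seed.
#' @return List with `control`, `treatment` (fragment sets), `spikein`
#'   (a `SpikeInCounts` data frame), and `expression`.
#' @export
simulate_rpb3 <- function(genes, genome, truth, expression = NULL,
                          n_per_sample = 1e5, spike_rate = 0.2,
                          spike_mass = c(control = 1, treatment = 1),
                          frag_mean = 150, frag_sd = 40,
                          size_range = c(50, 500), seed = 1) {
  set.seed(seed)
  r <- truth$rpb3_global_ratio
  ng <- nrow(genes)
  if (is.null(expression))
    expression <- stats::rlnorm(ng, meanlog = 0, sdlog = 0.6)
  dir <- gene_direction(genes)
  glen <- gene_length(genes)
  body_start <- pmin(genes$tss, genes$polya)
  # per-gene sampling weight ∝ expression x length (uniform within body);
  # the global factor r cancels after depth resampling, by design
  wgene <- expression * glen
  mk <- function(label) {
    gi <- sample.int(ng, n_per_sample, replace = TRUE, prob = wgene)
    pos <- body_start[gi] + floor(stats::runif(n_per_sample) * glen[gi])
    len <- rtrunc_lengths(n_per_sample, frag_mean, frag_sd, size_range)
    fragments_from_midpoints(pos, len, genes$chrom[gi], genome, label)
  }
  ctrl <- mk("rpb3_control")
  treat <- mk("rpb3_treatment")
  spike_ctrl <- stats::rpois(1, n_per_sample * spike_rate *
                               unname(spike_mass["control"]))
  spike_treat <- stats::rpois(1, n_per_sample * spike_rate *
                                unname(spike_mass["treatment"]) / r)
  spikein <- spikein_counts(
    sample = c("control", "treatment"),
    genomic_reads = c(n_per_sample, n_per_sample),
    spike_reads = c(spike_ctrl, spike_treat),
    spike_mass_added = unname(spike_mass[c("control", "treatment")]),
    dilution = c(1 / 400, 1 / 400))
  list(control = ctrl, treatment = treat, spikein = spikein,
       expression = expression)
}

#' Simulate a synthetic genetic array screen
#'
#' Per strain, the latent relative growth is `1 + effect + Normal(0,
#' noise_sd)`, with effects planted on named hit sets. Colony sizes are then
#' emitted for experimental and control plates (replicate colonies, per-plate
#' multiplicative scale factors, small per-colony noise) so the plate-median
#' normalization in [relative_growth()] has real work to do.
#'
#' @param n_strains Number of deletion strains.
#' @param hit_sets Named list; each element is `list(genes = <ids>,
#'   effect = <scalar>)`. Gene ids must be disjoint across sets.
#' @param noise_sd SD of strain-level growth noise.
#' @param n_reps Colony replicates per condition.
#' @param plate_size Strains per plate.
#' @param colony_cv Per-colony multiplicative noise CV.
#' @param base_size Mean colony area (arbitrary units).
#' @param seed Integer seed.
#' @return An `SGATable` data frame: `gene`, `plate`, `position`,
#'   `set_label`, `true_growth`, and `exp_<i>` / `ctrl_<i>` colony sizes.
#' @export
simulate_sga <- function(n_strains = 5426, hit_sets = NULL, noise_sd = 0.05,
                         n_reps = 2, plate_size = 384, colony_cv = 0.01,
                         base_size = 400, seed = 1) {
  set.seed(seed)
  gene <- sprintf("yor%04d", seq_len(n_strains))
  effect <- numeric(n_strains)
  set_label <- rep("none", n_strains)
  if (!is.null(hit_sets)) {
    all_genes <- unlist(lapply(hit_sets, `[[`, "genes"))
    if (anyDuplicated(all_genes)) stop("hit sets must be disjoint")
    for (nm in names(hit_sets)) {
      idx <- match(hit_sets[[nm]]$genes, gene)
      if (anyNA(idx)) stop(sprintf("hit set '%s' has unknown genes", nm))
      effect[idx] <- hit_sets[[nm]]$effect
      set_label[idx] <- nm
    }
  }
  growth <- 1 + effect + stats::rnorm(n_strains, 0, noise_sd)
  growth <- pmax(0, growth)
  plate <- ceiling(seq_len(n_strains) / plate_size)
  n_plates <- max(plate)
  position <- seq_len(n_strains) - (plate - 1) * plate_size
  out <- data.frame(gene = gene, plate = plate, position = position,
                    set_label = set_label, true_growth = growth,
                    stringsAsFactors = FALSE)
  for (rep_i in seq_len(n_reps)) {
    pf_exp <- stats::rlnorm(n_plates, 0, 0.15)
    pf_ctrl <- stats::rlnorm(n_plates, 0, 0.15)
    noise <- function(n) exp(stats::rnorm(n, 0, colony_cv))
    out[[sprintf("exp_%d", rep_i)]] <-
      base_size * growth * pf_exp[plate] * noise(n_strains)
    out[[sprintf("ctrl_%d", rep_i)]] <-
      base_size * pf_ctrl[plate] * noise(n_strains)
  }
  class(out) <- c("SGATable", "data.frame")
  out
}

#' Simulate a complete study
#'
#' One-call front end generating every input the pipeline consumes, under
#' the default study conditions: a two-chromosome 1.3 Mb genome, 300 genes,
#' phased nucleosomes with GC-coupled stability, DVNP ChIP (IP + input),
#' MNase control and DVNP-condition libraries, a spike-in-controlled Rpb3
#' experiment with a planted 0.65 global ratio (a 35% reduction), and an
#' SGA screen with 21-gene histone-up/-down sets at effects -0.3/+0.3.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param chrom_lengths Chromosome lengths (bp).
#' @param n_genes Gene count.
#' @param loss_coupling,stability_coupling,rpb3_global_ratio Planted effects
#'   (beta, gamma, r).
#' @param n_mnase,n_chip,n_rpb3 Fragments per library.
#' @param n_strains SGA strain count.
#' @param sga_effect Absolute planted SGA effect for the histone sets.
#' @param config A [pipeline_config()].
#' @return A list with `genome`, `genes`, `map`, `truth`, `mnase_control`,
#'   `mnase_dvnp`, `chip` (ip/input), `rpb3` (control/treatment/spikein),
#'   `sga`, `hit_sets`, and `config`.
#' @export
simulate_study <- function(seed = 1,
                           chrom_lengths = c(650000, 650000),
                           n_genes = 300,
                           loss_coupling = 0.8,
                           stability_coupling = 2,
                           rpb3_global_ratio = 0.65,
                           n_mnase = 4e5, n_chip = 2e5, n_rpb3 = 1e5,
                           n_strains = 5426, sga_effect = 0.3,
                           config = pipeline_config(random_seed = seed)) {
  seed <- as.integer(seed)
  gen <- simulate_genome(n_chroms = length(chrom_lengths),
                         lengths = chrom_lengths, seed = seed)
  genes <- simulate_genes(gen, n_genes, seed = seed + 1L)
  map <- build_nucleosome_map(genes, gen,
                              stability_coupling = stability_coupling)
  aff <- build_affinity_track(map, gen, mode = "nucleosome",
                              field_sd = 0.6, seed = seed + 7L)
  truth <- simulation_truth(aff, loss_coupling = loss_coupling,
                            stability_coupling = stability_coupling,
                            rpb3_global_ratio = rpb3_global_ratio,
                            seed = seed)
  mnase_control <- simulate_mnase(map, gen, truth, n_fragments = n_mnase,
                                  condition = "control",
                                  size_range = config$mnase_size_range,
                                  seed = seed + 2L)
  mnase_dvnp <- simulate_mnase(map, gen, truth, n_fragments = n_mnase,
                               condition = "dvnp",
                               size_range = config$mnase_size_range,
                               seed = seed + 3L)
  chip <- simulate_dvnp_chip(truth, gen, n_ip = n_chip, n_input = n_chip,
                             size_range = config$chip_size_range,
                             seed = seed + 4L)
  rpb3 <- simulate_rpb3(genes, gen, truth, n_per_sample = n_rpb3,
                        size_range = config$chip_size_range,
                        seed = seed + 5L)
  genes_pool <- sprintf("yor%04d", seq_len(n_strains))
  histone_down <- genes_pool[seq_len(21)]
  histone_up <- genes_pool[22:42]
  hit_sets <- list(
    histone_down = list(genes = histone_down, effect = sga_effect),
    histone_up = list(genes = histone_up, effect = -sga_effect))
  sga <- simulate_sga(n_strains = n_strains, hit_sets = hit_sets,
                      seed = seed + 6L)
  list(genome = gen, genes = genes, map = map, truth = truth,
       mnase_control = mnase_control, mnase_dvnp = mnase_dvnp,
       chip = chip, rpb3 = rpb3, sga = sga, hit_sets = hit_sets,
       config = config)
}
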