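test_that("simulated genomes are deterministic with controlled GC", {
  g1 <- simulate_genome(2, c(20000, 10000), seed = 5)
  g2 <- simulate_genome(2, c(20000, 10000), seed = 5)
  expect_identical(g1$sequence, g2$sequence)
  expect_false(identical(g1$sequence,
                         simulate_genome(2, c(20000, 10000), seed = 6)$sequence))

  g <- simulate_genome(1, 1e5, gc_mean = 0.5, gc_block = 500, seed = 3)
  bases <- strsplit(g$sequence[[1]], "")[[1]]
  gc_obs <- mean(bases %in% c("G", "C"))
  # block-mean sampling: ~200 blocks, tolerance 3 * sqrt(0.25 / n_blocks)
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / 200))

  expect_error(simulate_genome(1, 1e4, gc_mean = 0), "gc_mean")
  expect_error(simulate_genome(1, 1e4, gc_mean = 1), "gc_mean")
})

test_that("simulated genes are disjoint with flanks and strand-consistent", {
  gen <- simulate_genome(2, c(60000, 40000), seed = 2)
  expect_equal(nrow(simulate_genes(gen, 0)), 0)

  genes <- simulate_genes(gen, 30, seed = 3)
  expect_equal(nrow(genes), 30)
  minus <- genes$strand == "-"
  expect_true(all(genes$tss[minus] > genes$polya[minus]))
  expect_true(all(genes$tss[!minus] < genes$polya[!minus]))
  for (cn in unique(genes$chrom)) {
    g <- genes[genes$chrom == cn, ]
    lo <- pmin(g$tss, g$polya) - 500
    hi <- pmax(g$tss, g$polya) + 500
    ord <- order(lo)
    expect_true(all(lo[ord][-1] >= hi[ord][-length(ord)]))
  }
  expect_error(simulate_genes(gen, 5000, seed = 1), "could only place")
})

test_that("nucleosome map places phased dyads and GC-coupled weights", {
  gen <- simulate_genome(1, 50000, seed = 9)
  genes <- gene_annotation("a", "chrI", "+", 10000, 11650, gen)
  map <- build_nucleosome_map(genes, gen, spacing = 165,
                              stability_coupling = 0)
  # floor((1650 - 73)/165) + 1 = 10 genic dyads plus the -1 nucleosome
  expect_equal(nrow(map$sites), 11)
  expect_equal(sum(map$sites$nuc_index == -1), 1)
  expect_equal(length(unique(map$sites$weight)), 1)
  genic <- sort(map$sites$dyad[map$sites$nuc_index > 0])
  expect_equal(unique(diff(genic)), 165)
  expect_equal(genic[1], 10073)

  gen2 <- simulate_genome(1, 2e5, seed = 11)
  genes2 <- simulate_genes(gen2, 40, seed = 12)
  map2 <- build_nucleosome_map(genes2, gen2, stability_coupling = 2)
  expect_gt(cor(map2$sites$weight, map2$sites$predicted_occupancy), 0)
  expect_true(all(map2$sites$weight > 0 & map2$sites$weight <= 1))
})

test_that("MNase simulation: null condition matches control site counts", {
  gen <- simulate_genome(1, 2e5, seed = 21)
  genes <- simulate_genes(gen, 40, seed = 22)
  map <- build_nucleosome_map(genes, gen)
  aff <- build_affinity_track(map, gen)
  truth0 <- simulation_truth(aff, loss_coupling = 0)
  fr <- simulate_mnase(map, gen, truth0, 1e5, "dvnp", seed = 23)

  # assign fragments to nearest dyad; jitter (sd 10) << spacing (165)
  mids <- (fr$start + fr$end) %/% 2
  counts <- integer(nrow(map$sites))
  for (cn in unique(map$sites$chrom)) {
    d <- sort(map$sites$dyad[map$sites$chrom == cn])
    idx <- findInterval(mids[fr$chrom == cn],
                        c(-Inf, head(d, -1) + diff(d) / 2))
    tb <- tabulate(idx, nbins = length(d))
    counts[map$sites$chrom == cn][order(map$sites$dyad[map$sites$chrom == cn])] <- tb
  }
  p_exp <- map$sites$weight / sum(map$sites$weight)
  gof <- suppressWarnings(chisq.test(counts, p = p_exp))
  expect_gt(gof$p.value, 0.01)

  # fragment lengths: truncated-normal mean within 1 bp of 147 at n = 1e5
  expect_lt(abs(mean(fr$end - fr$start) - 147), 1)

  # determinism
  fr2 <- simulate_mnase(map, gen, truth0, 1e5, "dvnp", seed = 23)
  expect_identical(as.data.frame(fr), as.data.frame(fr2))

  truth_kill <- simulation_truth(constant_track(gen, 1, "raw"),
                                 loss_coupling = 1)
  expect_error(simulate_mnase(map, gen, truth_kill, 100, "dvnp", seed = 1),
               "zero")
})

test_that("DVNP ChIP enrichment is higher over dyads than NDR centers", {
  gen <- simulate_genome(1, 3e5, seed = 31)
  genes <- simulate_genes(gen, 60, seed = 32)
  map <- build_nucleosome_map(genes, gen)
  aff <- build_affinity_track(map, gen, mode = "nucleosome")
  truth <- simulation_truth(aff)
  sim <- simulate_dvnp_chip(truth, gen, 1e5, 1e5, seed = 33)

  ip <- prepare_track(sim$ip, gen)
  input <- prepare_track(sim$input, gen)
  dyad_enr <- mean(nucleosome_site_signal(ip, map$sites)) /
    mean(nucleosome_site_signal(input, map$sites))
  ndr_sites <- data.frame(chrom = map$ndr$chrom,
                          dyad = round(map$ndr$center))
  ndr_enr <- mean(nucleosome_site_signal(ip, ndr_sites)) /
    mean(nucleosome_site_signal(input, ndr_sites))
  expect_gt(dyad_enr, 1.5 * ndr_enr)

  empty <- simulate_dvnp_chip(truth, gen, 0, 10, seed = 1)
  expect_equal(nrow(empty$ip), 0)
})

test_that("spike-in simulation encodes the global ratio in spike fractions", {
  gen <- simulate_genome(1, 3e5, seed = 41)
  genes <- simulate_genes(gen, 60, seed = 42)
  aff <- constant_track(gen, 1, "raw")

  t1 <- simulation_truth(aff, rpb3_global_ratio = 1)
  s1 <- simulate_rpb3(genes, gen, t1, n_per_sample = 1e5, seed = 43)
  frac <- s1$spikein$spike_reads / s1$spikein$genomic_reads
  expect_lt(abs(frac[1] / frac[2] - 1), 0.05)

  t2 <- simulation_truth(aff, rpb3_global_ratio = 0.65)
  s2 <- simulate_rpb3(genes, gen, t2, n_per_sample = 1e5, seed = 44)
  frac2 <- s2$spikein$spike_reads / s2$spikein$genomic_reads
  expect_lt(abs(frac2[2] / frac2[1] - 1 / 0.65), 0.05 / 0.65)

  # depth matching is exact by construction
  expect_equal(diff(s2$spikein$genomic_reads), 0)
  expect_equal(nrow(s2$control), nrow(s2$treatment))

  expect_error(simulation_truth(aff, rpb3_global_ratio = 0), "rpb3")
})

test_that("SGA simulation plants effects with Gaussian growth noise", {
  sga0 <- simulate_sga(n_strains = 5000, noise_sd = 0.05, seed = 51)
  rg <- relative_growth(sga0)
  # true relative growth beyond 1 +/- 2 sd under the null: ~4.6%; the
  # colony pipeline adds a little measurement noise on top
  frac_out <- mean(rg > 1.1 | rg < 0.9)
  expect_lt(abs(frac_out - 0.046), 0.02)

  hit <- list(res = list(genes = sprintf("yor%04d", 1:42), effect = 0.3))
  sga1 <- simulate_sga(n_strains = 1000, hit_sets = hit, noise_sd = 0.05,
                       seed = 52)
  rg1 <- relative_growth(sga1)
  expect_true(all(rg1[sga1$set_label == "res"] > 1.15))

  expect_identical(simulate_sga(n_strains = 200, seed = 7),
                   simulate_sga(n_strains = 200, seed = 7))
  overlap <- list(a = list(genes = c("yor0001"), effect = 1),
                  b = list(genes = c("yor0001"), effect = 2))
  expect_error(simulate_sga(n_strains = 10, hit_sets = overlap), "disjoint")
})

test_that("control metagene recovers planted phasing and NDR", {
  gen <- simulate_genome(2, c(2e5, 2e5), seed = 61)
  genes <- simulate_genes(gen, 80, seed = 62)
  map <- build_nucleosome_map(genes, gen)
  aff <- build_affinity_track(map, gen)
  truth <- simulation_truth(aff)
  fr <- simulate_mnase(map, gen, truth, 2e5, "control", seed = 63)
  tr <- prepare_track(fr, gen, c(120, 200), mode = "midpoint", sigma = 4)
  prof <- metagene_profile(tr, genes, 500, 1500)

  p1 <- profile_peak(prof, c(20, 140))
  m1 <- profile_peak(prof, c(-300, -150))
  p2 <- profile_peak(prof, c(150, 320))
  expect_lt(abs(p1$offset - 73), 5)
  expect_lt(abs(m1$offset - (-213)), 5)
  # detected peak-to-peak distance equals the planted spacing within 5 bp
  expect_lt(abs((p2$offset - p1$offset) - map$spacing), 5)
  ndr <- profile_trough(prof, c(-150, -20))
  expect_lt(ndr$depth, 0.25 * p1$height)
})
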