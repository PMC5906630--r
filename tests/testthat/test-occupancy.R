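test_that("window tiling follows the closed-form count", {
  gen <- bare_genome(c(a = 1500, b = 499, c = 500))
  win <- tile_windows(gen, 500, 250)
  wa <- win[win$chrom == "a", ]
  expect_equal(wa$start, c(0, 250, 500, 750, 1000))
  expect_equal(nrow(win[win$chrom == "b", ]), 0)
  expect_equal(nrow(win[win$chrom == "c", ]), 1)

  for (L in c(500, 777, 1000, 12345)) {
    for (step in c(100, 250, 500)) {
      g <- bare_genome(c(x = L))
      expect_equal(nrow(tile_windows(g, 500, step)),
                   floor((L - 500) / step) + 1)
    }
  }
  expect_error(tile_windows(gen, 100, 200), "step")
})

test_that("window means match brute force and conserve totals at step=size", {
  gen <- bare_genome(c(chr = 2000))
  expect_equal(window_signal(constant_track(gen, 2.2),
                             tile_windows(gen, 500, 250)),
               rep(2.2, 7))

  set.seed(4)
  x <- rexp(2000)
  tr <- track_from_values(gen, list(chr = x))
  win <- tile_windows(gen, 500, 250)
  got <- window_signal(tr, win)
  brute <- vapply(seq_len(nrow(win)),
                  function(i) mean(x[(win$start[i] + 1):win$end[i]]), 0)
  expect_equal(got, brute, tolerance = 1e-12)

  # disjoint windows partition the chromosome: sums recover the total
  win2 <- tile_windows(gen, 500, 500)
  expect_equal(sum(window_signal(tr, win2) * 500), sum(x),
               tolerance = 1e-9)
})

test_that("occupancy change is control minus treatment (positive = loss)", {
  expect_equal(occupancy_change(c(1, 1), c(1, 1)), c(0, 0))
  expect_equal(occupancy_change(1.2, 0.9), 0.3)
  expect_error(occupancy_change(1:3, 1:2), "length")

  # with mean-normalized tracks and a step=size tiling that covers the
  # genome, the mean change is 0 by linearity
  gen <- bare_genome(c(chr = 5000))
  set.seed(10)
  t1 <- normalize_genome_mean(track_from_values(gen, list(chr = rexp(5000))))
  t2 <- normalize_genome_mean(track_from_values(gen, list(chr = rexp(5000))))
  win <- tile_windows(gen, 500, 500)
  ch <- occupancy_change(window_signal(t1, win), window_signal(t2, win))
  expect_equal(mean(ch), 0, tolerance = 1e-12)
})

test_that("quantile bins split ranks into near-equal fifths", {
  b <- quantile_bins(1:10)
  expect_equal(as.character(b[1:2]), c("q1", "q1"))
  expect_equal(as.character(b[9:10]), c("q5", "q5"))

  expect_warning(b2 <- quantile_bins(rep(1, 10)), "ties")
  expect_equal(as.integer(table(b2)), rep(2L, 5))

  # brute-force sort-and-slice oracle on random vectors
  for (s in 1:5) {
    set.seed(s)
    n <- sample(23:400, 1)
    v <- rnorm(n)
    got <- quantile_bins(v)
    ord <- order(v)
    brute <- integer(n)
    bounds <- ceiling((1:5) * n / 5)
    brute[ord] <- findInterval(seq_len(n) - 1, c(0, bounds[-5]))
    expect_equal(as.integer(got), brute)
    expect_lte(diff(range(table(got))), 1)
  }
  expect_error(quantile_bins(1:3, 5), "n_bins")
})

test_that("binning is invariant under monotone transforms", {
  set.seed(12)
  v <- rexp(101)
  expect_equal(quantile_bins(v), quantile_bins(log(v)))
  expect_equal(quantile_bins(v), quantile_bins(rank(v, ties.method = "first")))
})

test_that("welch_t matches its definition and the reference implementation", {
  r <- welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(r$t, -1 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(r$df, 6, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  for (s in 1:25) {
    set.seed(s)
    a <- rnorm(sample(5:50, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:50, 1), mean = runif(1, -1, 1))
    got <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    swapped <- welch_t(b, a)
    expect_equal(swapped$t, -got$t)
    expect_equal(swapped$p, got$p)
  }
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("boxplot stats use midpoint quartiles, clamped whiskers, notches", {
  s <- boxplot_stats(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$q3 - s$q1, 50)
  expect_equal(s$notch_hi - s$median, 1.58 * 50 / 10)

  s3 <- boxplot_stats(c(1, 2, 3))
  expect_equal(s3$median, 2)
  expect_equal(s3$q1, 1.5)
  expect_equal(s3$q3, 2.5)

  s1 <- boxplot_stats(42)
  expect_equal(s1$q1, 42)
  expect_equal(s1$notch_lo, 42)

  for (seed in 1:5) {
    set.seed(seed)
    v <- rcauchy(200)   # heavy tails exercise the whisker clamp
    bs <- boxplot_stats(v)
    expect_gte(bs$whisker_lo, min(v))
    expect_lte(bs$whisker_hi, max(v))
    expect_gte(bs$whisker_lo, bs$q1 - 1.5 * (bs$q3 - bs$q1))
    expect_lte(bs$whisker_hi, bs$q3 + 1.5 * (bs$q3 - bs$q1))
    expect_true(bs$q1 <= bs$median && bs$median <= bs$q3)
  }
})

test_that("bin association reports per-bin summaries and top-vs-bottom test", {
  occ <- c(1, 2, 3, 10, 11, 12)
  bins <- factor(c("q1", "q1", "q1", "q5", "q5", "q5"),
                 levels = c("q1", "q5"))
  a <- bin_association(occ, bins)
  expect_equal(a$summaries$q1$median, 2)
  expect_equal(a$summaries$q1$q1, 1.5)
  expect_equal(a$summaries$q1$q3, 2.5)
  expect_equal(unname(a$medians), c(2, 11))
  expect_equal(a$test$t, welch_t(c(10, 11, 12), c(1, 2, 3))$t)

  expect_error(bin_association(occ[1:5], bins), "align")
})

test_that("input stratification separates a confounded association", {
  # accessibility drives both apparent enrichment and occupancy change;
  # there is no direct effect, so within-stratum trends must be null
  set.seed(77)
  n <- 5000
  acc <- runif(n)
  enrich <- acc + rnorm(n, 0, 0.08)
  occ_ch <- acc + rnorm(n, 0, 0.08)
  un <- bin_association(occ_ch, quantile_bins(enrich))
  expect_lt(un$test$p, 1e-10)        # spurious unstratified trend

  strata <- input_strata(acc, 20)
  strat <- stratified_association(occ_ch, enrich, strata)
  ps <- vapply(strat, function(s) s$test$p, 0)
  expect_gt(min(ps), 1e-4)           # no stratum shows the strong effect
  expect_gt(mean(ps > 0.05), 0.5)

  # uniform input: strata are arbitrary, results match the unstratified run
  flat <- rep(1, n)
  expect_warning(s_flat <- input_strata(flat), "ties")
  expect_equal(as.integer(table(s_flat)), rep(1000L, 5))
})

test_that("GC predicted occupancy counts G+C, excludes N, drops edge sites", {
  gen <- genome_from_seqs(chr = paste0(strrep("G", 200), strrep("A", 200),
                                       "GCGCAT", strrep("T", 94)))
  sites <- data.frame(chrom = "chr",
                      dyad = c(100, 300))
  got <- predicted_occupancy_gc(gen, sites, window = 147)
  expect_equal(got$predicted_occupancy, c(1, 0))

  # hand-counted mixed window: dyad at the GCGCAT block (0-based 400..405)
  sites2 <- data.frame(chrom = "chr", dyad = 402)
  got2 <- predicted_occupancy_gc(gen, sites2, window = 11)
  # window [397, 408): AAAGCGCATTT -> 4 of 11 are G/C
  expect_equal(got2$predicted_occupancy, 4 / 11)

  # N excluded from numerator and denominator
  genN <- genome_from_seqs(chr = paste0("GCNNA", strrep("T", 95)))
  gotN <- predicted_occupancy_gc(genN, data.frame(chrom = "chr", dyad = 2),
                                 window = 5)
  expect_equal(gotN$predicted_occupancy, 2 / 3)

  expect_warning(
    edge <- predicted_occupancy_gc(gen, data.frame(chrom = "chr",
                                                   dyad = c(10, 300)),
                                   window = 147),
    "dropped")
  expect_equal(nrow(edge), 1)
})
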