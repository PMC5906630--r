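test_that("relative growth uses plate-median normalization", {
  tab <- data.frame(gene = c("a", "b", "c"), plate = 1,
                    set_label = "none",
                    exp_1 = c(200, 400, 800),
                    ctrl_1 = c(400, 400, 400))
  # plate medians: exp 400, ctrl 400 -> a: (200/400)/(400/400) = 0.5
  rg <- relative_growth(tab)
  expect_equal(unname(rg), c(0.5, 1, 2))

  # exp == ctrl everywhere -> 1
  tab2 <- data.frame(gene = c("a", "b"), plate = 1,
                     exp_1 = c(300, 500), ctrl_1 = c(300, 500))
  expect_equal(unname(relative_growth(tab2)), c(1, 1))

  # per-plate multiplicative scaling cancels
  tab3 <- tab
  tab3$exp_1 <- tab3$exp_1 * 7
  expect_equal(relative_growth(tab3), rg)

  # zero control median -> NA flag
  tab4 <- data.frame(gene = c("a", "b"), plate = c(1, 2),
                     exp_1 = c(300, 300), ctrl_1 = c(300, 0))
  expect_true(is.na(relative_growth(tab4)["b"]))
})

test_that("hit classification applies the growth thresholds", {
  rg <- c(a = 1.0, b = 1.4, c = 0.6, d = NA)
  cls <- classify_hits(rg, pos_threshold = 1.2, neg_threshold = 0.8)
  expect_equal(as.character(cls[1:3]), c("neutral", "rescuer", "sensitizer"))
  expect_true(is.na(cls[4]))

  set.seed(19)
  rg2 <- rnorm(2000, 1, 0.05)
  cls2 <- classify_hits(rg2)
  th <- attr(cls2, "thresholds")
  brute <- ifelse(rg2 > th["pos"], "rescuer",
                  ifelse(rg2 < th["neg"], "sensitizer", "neutral"))
  expect_equal(as.character(cls2), brute)
  expect_error(classify_hits(rg, pos_threshold = 0.8, neg_threshold = 1.2),
               "neg_threshold")
})

test_that("2x2 chi-squared matches the closed form without correction", {
  # [[10,0],[0,10]] -> chi2 = n(ad-bc)^2/((a+b)(c+d)(a+c)(b+d)) = 20, df 1
  classes <- factor(c(rep("sensitizer", 10), rep("rescuer", 10)),
                    levels = c("sensitizer", "neutral", "rescuer"))
  set_label <- c(rep("histone_up", 10), rep("histone_down", 10))
  res <- suppressWarnings(chi2_geneset_tests(classes, set_label))
  expect_equal(res$stat_H02, 20)
  expect_equal(res$df_H02, 1)
  expect_equal(res$p_H02, pchisq(20, 1, lower.tail = FALSE))

  # cross-check against the reference implementation on random tables
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(sample(5:60, 4), 2)
    expd <- outer(rowSums(m), colSums(m)) / sum(m)
    stat <- sum((m - expd)^2 / expd)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(stat, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("H02 is invariant under simultaneous polarity/threshold swap", {
  set.seed(23)
  n <- 400
  classes <- factor(sample(c("sensitizer", "neutral", "rescuer"), n, TRUE,
                           prob = c(0.2, 0.6, 0.2)),
                    levels = c("sensitizer", "neutral", "rescuer"))
  set_label <- sample(c("histone_up", "histone_down", "none"), n, TRUE,
                      prob = c(0.2, 0.2, 0.6))
  res <- suppressWarnings(chi2_geneset_tests(classes, set_label))
  flipped <- factor(c(sensitizer = "rescuer", neutral = "neutral",
                      rescuer = "sensitizer")[as.character(classes)],
                    levels = c("sensitizer", "neutral", "rescuer"))
  swapped_sets <- c(histone_up = "histone_down",
                    histone_down = "histone_up",
                    none = "none")[set_label]
  res2 <- suppressWarnings(chi2_geneset_tests(flipped, swapped_sets))
  expect_equal(res2$stat_H02, res$stat_H02, tolerance = 1e-12)
  expect_equal(res2$p_H02, res$p_H02, tolerance = 1e-12)
})

test_that("chi-squared null p-values are uniform under random classes", {
  set.seed(29)
  n <- 3000
  ps <- replicate(200, {
    classes <- factor(sample(c("sensitizer", "neutral", "rescuer"), n, TRUE,
                             prob = c(0.1, 0.8, 0.1)),
                      levels = c("sensitizer", "neutral", "rescuer"))
    set_label <- c(rep("histone_up", 150), rep("histone_down", 150),
                   rep("none", n - 300))
    chi2_geneset_tests(classes, set_label)$p_H01
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("planted rescue/sensitizer sets reject both null hypotheses", {
  hit_sets <- list(
    histone_down = list(genes = sprintf("yor%04d", 1:21), effect = 0.3),
    histone_up = list(genes = sprintf("yor%04d", 22:42), effect = -0.3))
  sga <- simulate_sga(n_strains = 3000, hit_sets = hit_sets, seed = 31)
  res <- suppressWarnings(sga_stage(sga))
  expect_lt(res$tests$p_H01, 1e-6)
  expect_lt(res$tests$p_H02, 1e-6)
  down <- res$classes[sga$set_label == "histone_down"]
  expect_true(all(down == "rescuer"))
})

test_that("hypergeometric enrichment equals the brute-force tail sum", {
  universe <- sprintf("g%04d", 1:5000)
  rescuers <- universe[1:50]
  categories <- list(hit_cat = c(universe[1:5], universe[100:104]),
                     other = universe[200:299])
  enr <- category_enrichment(rescuers, categories, universe)
  # P(X >= 5), X ~ Hypergeom(N=5000, K=10, n=50), by direct summation
  brute <- sum(vapply(5:10, function(k) {
    choose(10, k) * choose(4990, 50 - k) / choose(5000, 50)
  }, 0))
  expect_equal(enr$p[enr$category == "hit_cat"], brute, tolerance = 1e-12)
  expect_equal(enr$p_bonferroni, pmin(1, enr$p * 2))

  # category identical to the rescuer set: the minimal attainable p
  cat_exact <- list(exact = rescuers)
  enr2 <- category_enrichment(rescuers, cat_exact, universe)
  expect_equal(enr2$hits, 50)
  expect_equal(enr2$p, stats::phyper(49, 50, 4950, 50, lower.tail = FALSE),
               tolerance = 1e-12)

  # random categories give uniform p
  set.seed(37)
  ps <- replicate(300, {
    category_enrichment(rescuers,
                        list(r = sample(universe, 40)), universe)$p
  })
  expect_gt(mean(ps > 0.05), 0.85)

  expect_warning(
    category_enrichment(rescuers, list(bad = c("zz1"), ok = universe[1:10]),
                        universe),
    "disjoint")
  expect_error(suppressWarnings(
    category_enrichment(rescuers, list(bad = "zz1"), universe)),
    "no usable")
})
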