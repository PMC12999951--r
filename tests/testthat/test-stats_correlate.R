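test_that("pearson obeys the basic identities and error contract", {
  set.seed(1)
  x <- rnorm(20)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, 3 * x + 2), 1)
  expect_error(pearson(x, rep(1, 20)), "zero variance")
  expect_error(pearson(x, x[1:10]), "equal length")
  expect_error(pearson(1:2, 2:1), "at least 3")
})

test_that("correlation set recovers the selection-driven sign pattern", {
  sim <- small_sim(seed = 13, length = 524288L, p_lead = 0.9)
  cs <- replicon_correlation_set(sim$replicon, sim$features,
                                 class_label = "archaeal_chromosome")
  expect_gt(cs$pcc_codon1, 0.5)
  expect_lt(cs$pcc_codon2, -0.5)
  expect_true(all(abs(unlist(cs[paste0("pcc_", c("total", "codon1", "codon2",
                                                 "codon3", "noncoding"))]))
                  <= 1))
})

test_that("PCC is unaffected by display normalization of either curve", {
  set.seed(7)
  a <- cumsum(runif(40, -1, 1))
  b <- cumsum(runif(40, -1, 1))
  expect_equal(pearson(normalize_curve(a, 3), b), pearson(a, b))
  expect_equal(pearson(a, normalize_curve(b, -1)), pearson(a, b))
})

test_that("a strand-less or unvarying class yields NA, not zero", {
  sim <- small_sim(seed = 14)
  # truncate to a codon multiple and cover every position: the non-coding
  # class then has an all-zero (constant) cumulative curve
  n3 <- (sim$replicon$length %/% (3L * 4096L)) * 3L * 4096L
  r <- replicon(sim$replicon$id, substr(sim$replicon$sequence, 1, n3))
  ft <- feature_table(r$id, 0L, n3, "+", 0L)
  cs <- replicon_correlation_set(r, ft)
  expect_true(is.na(cs$pcc_noncoding))
  expect_false(is.na(cs$pcc_codon1))
})

test_that("aggregate_class reproduces the summary arithmetic", {
  mk <- function(v, cls = "archaeal_chromosome")
    structure(list(replicon_id = "x", class_label = cls, pcc_total = v,
                   pcc_codon1 = NA_real_, pcc_codon2 = NA_real_,
                   pcc_codon3 = NA_real_, pcc_noncoding = NA_real_),
              class = "correlation_set")
  s <- aggregate_class(lapply(c(0.6, 0.8, 1.0), mk))
  expect_equal(s$mean, 0.8)
  expect_equal(s$frac_above_half, 1)
  expect_equal(s$cv_percent, 100 * s$sd / abs(s$mean))
  s2 <- aggregate_class(lapply(c(0.4, 0.6), mk))
  expect_equal(s2$frac_above_half, 0.5)
  s3 <- aggregate_class(list(mk(0.3)))
  expect_true(is.na(s3$sd) && is.na(s3$cv_percent))
  expect_error(aggregate_class(list(mk(0.1), mk(0.2, "other"))),
               "single class")
})

test_that("aggregation agrees with an independent streaming (Welford) pass", {
  set.seed(15)
  v <- runif(1000, -1, 1)
  sets <- lapply(v, function(x)
    structure(list(replicon_id = "x", class_label = "other", pcc_total = x,
                   pcc_codon1 = NA_real_, pcc_codon2 = NA_real_,
                   pcc_codon3 = NA_real_, pcc_noncoding = NA_real_),
              class = "correlation_set"))
  s <- aggregate_class(sets)
  m <- 0; m2 <- 0; k <- 0
  for (x in v) {
    k <- k + 1; d <- x - m; m <- m + d / k; m2 <- m2 + d * (x - m)
  }
  expect_equal(s$mean, m, tolerance = 1e-12)
  expect_equal(s$sd, sqrt(m2 / (k - 1)), tolerance = 1e-12)
  expect_equal(s$frac_above_half, mean(v > 0.5))
})

test_that("parity regression recovers slope 1 under exact and noisy parity", {
  set.seed(16)
  exact <- lapply(1:10, function(i) {
    half <- paste(sample(c("G", "C", "A", "T"), 200 * i,
                         replace = TRUE), collapse = "")
    # append the complement of the same draw so G == C exactly
    replicon(paste0("r", i), paste0(half, chartr("GCAT", "CGTA", half)))
  })
  fit <- chargaff_parity(exact)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 10), tolerance = 1e-9)

  noisy <- lapply(1:100, function(i) {
    n <- sample(2000:20000, 1)
    gc <- 0.5 * runif(1, 0.99, 1.01)   # 1% multiplicative parity noise
    s <- sample(c("G", "C", "A", "T"), n, replace = TRUE,
                prob = c(gc / 2, (1 - gc) / 2, 0.25, 0.25) /
                  sum(c(gc / 2, (1 - gc) / 2, 0.25, 0.25)))
    replicon(paste0("n", i), paste(s, collapse = ""))
  })
  nf <- chargaff_parity(noisy)
  expect_gt(nf$slope, 0.98)
  expect_lt(nf$slope, 1.02)
  expect_gt(nf$r_squared, 0.98)
  expect_error(chargaff_parity(exact[1]), "at least 2")
})

test_that("group comparisons behave under null and large effects", {
  set.seed(17)
  a <- rnorm(30)
  same <- compare_groups(list(g1 = a, g2 = a), "mann_whitney_two_tailed")
  expect_gt(same$p_value, 0.9)
  big <- compare_groups(list(g1 = rnorm(50), g2 = rnorm(50, 3)),
                        "mann_whitney_two_tailed")
  expect_lt(big$p_value, 1e-4)

  kw <- compare_groups(list(g1 = a, g2 = a, g3 = a), "kruskal_wallis")
  expect_gt(kw$p_value, 0.9)
  expect_true(all(kw$pairwise == 1, na.rm = TRUE))

  an <- compare_groups(list(g1 = rnorm(20), g2 = rnorm(20, 2),
                            g3 = rnorm(20, 4)), "anova_oneway")
  expect_lt(an$p_value, 1e-6)
  expect_true(all(an$pairwise < 0.05, na.rm = TRUE))
  expect_equal(an$groups$n, c(20L, 20L, 20L))
  expect_error(compare_groups(list(g1 = 1:5)), "at least 2 groups")
  expect_error(compare_groups(list(g1 = 1:5, g2 = numeric(0))),
               "empty or singleton")
})
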