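test_that("Spearman reproduces the published rank correlations exactly", {
  tab <- published_rsi_table()
  # d^2 = 96 -> 1 - 576/336; d^2 = 58 -> 1 - 348/336 (exact rationals)
  expect_equal(spearman_cor(tab$md, tab$resim)$estimate, 1 - 6 * 96 / (7 * 48))
  expect_equal(round(spearman_cor(tab$md, tab$resim)$estimate, 3), -0.714)
  expect_equal(round(spearman_cor(tab$kpca, tab$resim)$estimate, 5), -0.03571)
  x <- c(1, 2, 5, 9); y <- x^3 + 2
  expect_equal(spearman_cor(x, y)$estimate, 1)
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "rsi_constant_series")
})

test_that("Pearson reproduces the published product-moment correlations", {
  tab <- published_rsi_table()
  expect_equal(round(pearson_cor(tab$edpca, tab$resim)$estimate, 4), -0.1149)
  expect_equal(round(pearson_cor(tab$cvid, tab$resim)$estimate, 2), -0.04)
  x <- rnorm(20)
  expect_equal(pearson_cor(x, 2 * x + 3)$estimate, 1)
  expect_error(pearson_cor(1:2, 2:3), class = "rsi_too_few_rows")
})

test_that("Anderson-Darling matches the published statistics on the fixture", {
  tab <- published_rsi_table()
  # the reported statistic is the unadjusted A^2; p from the adjusted one
  expect_equal(round(anderson_darling(tab$resim)$statistic, 3), 0.455)
  expect_equal(round(anderson_darling(tab$resim)$p.value, 3), 0.182)
  expect_equal(round(anderson_darling(tab$edpca)$statistic, 3), 0.155)
  expect_equal(round(anderson_darling(tab$edpca)$p.value, 3), 0.919)
  expect_equal(round(anderson_darling(tab$md)$statistic, 3), 1.057)
  expect_equal(round(anderson_darling(tab$cvid)$statistic, 3), 0.658)
  expect_error(anderson_darling(rep(2, 10)), class = "rsi_constant_series")
  expect_error(anderson_darling(1:4), class = "rsi_too_few_rows")
})

test_that("Anderson-Darling holds its size and has power against exponential data", {
  set.seed(100)
  size <- mean(vapply(1:40, function(i) anderson_darling(rnorm(500))$normal, logical(1)))
  expect_gte(size, 0.85)  # nominal 95%, Monte-Carlo at 40 replicates
  power <- mean(vapply(1:40, function(i) !anderson_darling(rexp(200))$normal, logical(1)))
  expect_equal(power, 1)  # exponential n=200 is rejected essentially always
})

test_that("Friedman test matches brute-force rank arithmetic", {
  m <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  f <- friedman_rank_test(m)
  expect_equal(unname(f$mean_ranks), c(1, 2, 3))
  expect_equal(f$statistic, 8)
  expect_equal(f$p.value, pchisq(8, 2, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(round(f$p.value, 4), 0.0183)

  all_same <- matrix(5, 4, 3)
  f0 <- friedman_rank_test(all_same)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p.value, 1)

  set.seed(30)
  v <- matrix(rnorm(24), 8, 3)
  f1 <- friedman_rank_test(v)
  perm <- v[, c(3, 1, 2)]
  f2 <- friedman_rank_test(perm)
  expect_equal(f2$statistic, f1$statistic)
  expect_equal(unname(f2$mean_ranks), unname(f1$mean_ranks[c(3, 1, 2)]))
  # invariance under monotone within-subject transforms
  f3 <- friedman_rank_test(exp(v))
  expect_equal(f3$statistic, f1$statistic)
  # agreement with the reference implementation on tie-free data
  expect_equal(f1$statistic, unname(friedman.test(v)$statistic))
  expect_equal(f1$summary$MD, apply(v, 2, median))
})

test_that("phase 1 vs phase 5 correlations behave on constructed recordings", {
  prot <- tiny_protocol(8)
  set.seed(41)
  base <- matrix(rnorm(8 * 4 * 5 * 5), ncol = 5,
                 dimnames = list(NULL, c("EMG", "BVP", "BR", "SC", "PT")))
  rec <- recording(base, fs = 4)
  # make phase 5 identical to phase 1 -> every rho = 1
  lab <- segment_phases(rec$n_samples, prot, rec$fs)
  rec$channels[lab == 5, ] <- rec$channels[lab == 1, ]
  r <- phase15_feature_correlations(rec, prot)
  expect_equal(unname(r$per_channel), rep(1, 5))
  expect_equal(r$mean, 1)

  # unequal aggregated lengths are truncated with a warning
  rec2 <- recording(base[-(1:8), ], fs = 4, t0_offset = 2)
  expect_warning(phase15_feature_correlations(rec2, prot),
                 class = "rsi_truncated_pairing")
})

test_that("published phase-1/5 table row means and their rank correlation check out", {
  tab <- published_phase15_table()
  means <- rowMeans(tab[, c("EMG", "HR", "BR", "SC", "PT")])
  expect_equal(round(means, 2), tab$mean, tolerance = 0.005)
  r <- spearman_cor(tab$mean, tab$resim)
  expect_equal(r$estimate, -0.5)  # exact rational: d^2 = 84, n = 7
})

test_that("questionnaire validation gates coefficients and honours overrides", {
  tab <- published_rsi_table()
  m <- as.matrix(tab[, c("edpca", "md", "cvid", "kpca")])
  rep_auto <- resim_validation(m, tab$resim)
  expect_true(all(rep_auto$estimate >= -1 & rep_auto$estimate <= 1))
  # gate consistency: pearson only when both vectors passed
  for (k in seq_len(nrow(rep_auto))) {
    if (rep_auto$coefficient[k] == "pearson")
      expect_true(rep_auto$rsi_normal[k] && rep_auto$resim_normal[k])
  }
  # forcing the published assignment reproduces all four coefficients
  rep_pub <- resim_validation(m, tab$resim,
                              coefficient = c(edpca = "pearson", md = "spearman",
                                              cvid = "pearson", kpca = "spearman"))
  expect_equal(round(rep_pub$estimate, 4), c(-0.1149, -0.7143, -0.0404, -0.0357))

  # a method agreeing with the questionnaire ranks exactly correlates at 1
  perfect <- cbind(exact = rank(tab$resim))
  rp <- resim_validation(perfect, tab$resim, coefficient = c(exact = "spearman"))
  expect_equal(rp$estimate, 1)

  # too few subjects for the gate -> spearman fallback with warning
  expect_warning(r3 <- resim_validation(m[1:3, ], tab$resim[1:3]),
                 class = "rsi_small_sample")
  expect_true(all(r3$coefficient == "spearman"))
  expect_error(resim_validation(m, tab$resim[1:5]), class = "rsi_bad_input")
})
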