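test_that("one-way ANOVA matches textbook hand computations", {
  a <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(3, 4, 5)))
  expect_equal(a$between_ss, 6)
  expect_equal(a$within_ss, 6)
  expect_equal(a$total_ss, 12)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 6L)
  expect_equal(a$f_ratio, 3)
  expect_equal(a$p_value, 1 - pf(3, 2, 6))

  # equal means with nonzero spread: F is exactly 0
  a0 <- one_way_anova(list(c(1, 2, 3), c(3, 2, 1), c(2, 1, 3)))
  expect_equal(a0$f_ratio, 0)

  expect_error(one_way_anova(list(c(1, 2))), class = "bm_config_error")
  expect_error(one_way_anova(list(c(1), c(2, 3))), class = "bm_data_error")
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), class = "bm_data_error")
})

test_that("sums of squares decompose exactly on random inputs", {
  set.seed(20)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:12, 1), j, 2))
    a <- one_way_anova(groups)
    expect_equal(a$between_ss + a$within_ss, a$total_ss, tolerance = 1e-10)
    values <- unlist(groups)
    expect_equal(a$total_ss, sum((values - mean(values))^2),
                 tolerance = 1e-10)
    expect_equal(a$df_total, length(values) - 1L)
    expect_equal(a$ms_between, a$between_ss / a$df_between)
    expect_equal(a$f_ratio, a$ms_between / a$ms_within)
  }
})

test_that("pooled t matches hand computation and squares to the 2-group F", {
  r <- t_test_pooled(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  # identical samples: t = 0
  expect_equal(t_test_pooled(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  # degenerate
  expect_error(t_test_pooled(c(2, 2), c(2, 2)), class = "bm_data_error")
  expect_error(t_test_pooled(1, c(1, 2)), class = "bm_data_error")

  # two-group consistency: F = t^2, identical p
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(sample(4:15, 1), 0, 1)
    y <- rnorm(sample(4:15, 1), 0.8, 1.3)
    tt <- t_test_pooled(x, y)
    av <- one_way_anova(list(x, y))
    expect_equal(av$f_ratio, tt$statistic^2, tolerance = 1e-10)
    expect_equal(av$p_value, tt$p_value, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney matches closed forms and the exact null distribution", {
  # complete separation at n1 = 10, n2 = 30: U = 0, |Z| = 150 / sqrt(1025)
  r <- mann_whitney(1:10, 101:130)
  expect_equal(r$statistic, 0)
  expect_equal(abs(r$z), 150 / sqrt(1025), tolerance = 1e-12)
  expect_equal(abs(r$z), 4.6852, tolerance = 1e-4)

  # {1,2,3} vs {4,5}: U = 0, |Z| = sqrt(3)
  r2 <- mann_whitney(c(1, 2, 3), c(4, 5))
  expect_equal(r2$statistic, 0)
  expect_equal(abs(r2$z), sqrt(3), tolerance = 1e-12)

  # a sample against itself (distinct values): U = n^2 / 2, Z = 0
  a <- c(2, 5, 11)
  r3 <- mann_whitney(a, a)
  expect_equal(r3$statistic, 9 / 2)
  expect_equal(r3$z, 0)

  # tie-corrected variance equals the hand formula on tied data
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 5)
  r4 <- mann_whitney(x, y)
  all_v <- c(x, y); tt <- table(all_v); N <- 8; n1 <- 4; n2 <- 4
  s2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
  u <- sum(rank(all_v)[1:4]) - n1 * (n1 + 1) / 2
  expect_equal(r4$z, (u - n1 * n2 / 2) / sqrt(s2), tolerance = 1e-12)

  # degenerate: everything tied across both samples
  expect_error(mann_whitney(c(3, 3), c(3, 3)), class = "bm_data_error")

  # the normal approximation uses the exact enumeration's mean and
  # variance for every design with total n <= 12 (no ties)
  for (nn in list(c(3, 4), c(5, 5), c(4, 8), c(2, 10))) {
    us <- exact_u_distribution(nn[1], nn[2])
    mu <- mean(us)
    sigma <- sqrt(mean((us - mu)^2))   # population variance of the exact law
    expect_equal(mu, nn[1] * nn[2] / 2)
    set.seed(sum(nn))
    x <- rnorm(nn[1]); y <- rnorm(nn[2])
    r5 <- mann_whitney(x, y)
    expect_equal(r5$z, (r5$statistic - mu) / sigma, tolerance = 1e-12)
  }

  # agreement with the standard implementation's p-value (no continuity)
  set.seed(8)
  x <- rnorm(12); y <- rnorm(15, 0.7)
  expect_equal(mann_whitney(x, y)$p_value,
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
  expect_equal(mann_whitney(x, y, continuity = TRUE)$p_value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("Kruskal-Wallis matches hand computation and corrects for ties", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(r$df, 2L)
  expect_equal(r$p_value, 1 - pchisq(32 / 7, 2), tolerance = 1e-12)

  # tie correction: hand formula H / (1 - sum(t^3 - t) / (N^3 - N))
  g <- list(c(1, 2, 2), c(2, 3, 4), c(4, 4, 5))
  values <- unlist(g); N <- length(values)
  rk <- rank(values)
  Rj <- tapply(rk, rep(1:3, each = 3), sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / 3) - 3 * (N + 1)
  tt <- table(values)
  H_corr <- H / (1 - sum(tt^3 - tt) / (N^3 - N))
  expect_equal(kruskal_wallis(g)$statistic, H_corr, tolerance = 1e-12)

  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), class = "bm_data_error")
  expect_error(kruskal_wallis(list(c(1, 2))), class = "bm_config_error")
})

test_that("rank tests hold their nominal type-I error under the null", {
  set.seed(99)
  n_sim <- 2000
  rej_kw <- 0L; rej_mw <- 0L
  for (i in seq_len(n_sim)) {
    g <- list(rnorm(8), rnorm(8), rnorm(8))
    if (kruskal_wallis(g)$p_value <= 0.05) rej_kw <- rej_kw + 1L
    if (mann_whitney(g[[1]], g[[2]])$p_value <= 0.05) rej_mw <- rej_mw + 1L
  }
  # binomial 3-sigma band around 0.05 at 2000 simulations: (0.035, 0.065)
  expect_gt(rej_kw / n_sim, 0.035)
  expect_lt(rej_kw / n_sim, 0.065)
  expect_gt(rej_mw / n_sim, 0.035)
  expect_lt(rej_mw / n_sim, 0.065)
})

test_that("rank statistics are invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rlnorm(14); y <- rlnorm(18, 0.4); z <- rlnorm(10, 0.8)
  for (f in list(log, sqrt, function(v) 3 * v + 1, function(v) -1 / v)) {
    expect_equal(abs(mann_whitney(f(x), f(y))$z), abs(mann_whitney(x, y)$z),
                 tolerance = 1e-12)
    expect_equal(kruskal_wallis(lapply(list(x, y, z), f))$statistic,
                 kruskal_wallis(list(x, y, z))$statistic, tolerance = 1e-12)
  }
})

test_that("the full comparison bundles every variable and test family", {
  rep <- suppressWarnings(run_full_comparison(table2_fixture()))
  expect_s3_class(rep, "morph_report")
  expect_equal(nrow(rep$anova), 7L)
  expect_equal(nrow(rep$t_tests), 21L)
  expect_equal(nrow(rep$mann_whitney), 21L)
  expect_equal(nrow(rep$kruskal_wallis), 7L)
  expect_equal(nrow(rep$summaries), 21L)
  expect_equal(unique(rep$anova$df_between), 2L)
  expect_equal(unique(rep$anova$df_within), 67L)
  # printed dfs of the pairwise design: 38 for 30-vs-10, 58 for 30-vs-30
  t_na <- rep$t_tests[rep$t_tests$variable == "nuclear_area", ]
  expect_equal(t_na$df, c(38, 38, 58))
  # form PE and CI are monotonically related, so every pairwise rank test
  # agrees exactly between the two descriptors per compartment
  for (comp in c("nuclear", "cellular")) {
    mw_pe <- rep$mann_whitney[rep$mann_whitney$variable ==
                                paste0(comp, "_form_pe"), ]
    mw_ci <- rep$mann_whitney[rep$mann_whitney$variable ==
                                paste0(comp, "_ci"), ]
    expect_equal(mw_pe$z, mw_ci$z, tolerance = 1e-12)
    kw <- rep$kruskal_wallis
    expect_equal(kw$chisq[kw$variable == paste0(comp, "_form_pe")],
                 kw$chisq[kw$variable == paste0(comp, "_ci")],
                 tolerance = 1e-12)
  }
  # a missing group is a configuration error listing what is present
  two <- table2_fixture()
  two <- two[two$group != "normal", ]
  expect_error(run_full_comparison(two), "missing group",
               class = "bm_config_error")
})
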