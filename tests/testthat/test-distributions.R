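test_that("an all-zero series is a delta at the origin bin", {
  d <- akv_histogram(rep(0, 100))
  expect_equal(d$p[1], 1)
  expect_equal(region_masses(d)$R1, 1)
})

test_that("histogram counting matches hand counts on unit-width bins", {
  d <- akv_histogram(c(0.5, 1.5, 2.5), n_bins = 10, v_max = 10,
                     zero_bin_edge = 1)
  expect_equal(d$bin_edges, as.numeric(0:10))
  expect_equal(d$p, c(1, 1, 1, rep(0, 7)) / 3)
})

test_that("values above v_max are clipped into the last bin", {
  d <- akv_histogram(c(0.5, 30, 100), n_bins = 10, v_max = 10,
                     zero_bin_edge = 1)
  expect_equal(d$p[10], 2 / 3)
})

test_that("empirical bin masses match the Rayleigh closed form", {
  sigma <- 2
  n <- 1e5
  set.seed(5)
  v <- sqrt(rnorm(n, 0, sigma)^2 + rnorm(n, 0, sigma)^2)
  d <- akv_histogram(v, n_bins = 50, v_max = 25)
  edges <- d$bin_edges
  p_true <- diff(1 - exp(-edges^2 / (2 * sigma^2)))
  p_true[length(p_true)] <- p_true[length(p_true)] + exp(-25^2 / (2 * sigma^2))
  se <- sqrt(p_true * (1 - p_true) / n)
  z <- abs(d$p - p_true) / (se + 1e-5)
  # per-bin binomial fluctuation: all bins within 4 SE, at most a couple
  # of the 50 bins beyond 3 SE (multiple comparisons)
  expect_true(all(z < 4))
  expect_lte(sum(z > 3), 2)
})

test_that("histogram error shrinks roughly as n^(-1/2)", {
  sigma <- 2
  err_at <- function(n, seed) {
    set.seed(seed)
    v <- sqrt(rnorm(n, 0, sigma)^2 + rnorm(n, 0, sigma)^2)
    d <- akv_histogram(v)
    p_true <- diff(1 - exp(-d$bin_edges^2 / (2 * sigma^2)))
    sqrt(mean((d$p - p_true)^2))
  }
  e3 <- mean(vapply(1:5, function(s) err_at(1e3, s), 0))
  e5 <- mean(vapply(1:5, function(s) err_at(1e5, s), 0))
  expect_gt(e3 / e5, 5)   # expected factor 10, allow wide slack
})

test_that("region masses split boundary bins proportionally", {
  # uniform density over [0, 20]: mass proportional to bin width
  edges <- akv_bin_edges_test <- akvdetect:::akv_bin_edges(41, 20, 0.05)
  p <- diff(edges) / 20
  d <- structure(list(bin_edges = edges, p = p, n_samples = 1000L),
                 class = "akv_distribution")
  r <- region_masses(d)
  expect_equal(r$R4, 0.5, tolerance = 1e-12)
  expect_equal(r$R1 + r$R2 + r$R3 + r$R4, 1, tolerance = 1e-12)
  expect_equal(r$R3, 7 / 20, tolerance = 1e-12)
})

test_that("R4 is undefined below 10 cm/s support", {
  d <- akv_histogram(runif(100, 0, 5), n_bins = 10, v_max = 8)
  expect_error(region_masses(d), "R4 undefined")
})

test_that("pathological cohorts carry more fast-velocity mass", {
  co <- fix_cohort
  r4 <- apply(co$features, 1, function(p) {
    region_masses(structure(list(bin_edges = co$bin_edges, p = p,
                                 n_samples = 1L),
                            class = "akv_distribution"))$R4
  })
  expect_gt(mean(r4[co$labels == "pathological"]),
            mean(r4[co$labels == "normative"]))
})

test_that("KLD is zero on identity, positive and asymmetric otherwise", {
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  expect_equal(kld(p, p, eps = 0), 0)
  expect_equal(kld(p, q, eps = 0), 0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1))
  expect_equal(kld(p, q, eps = 0), 0.5108256, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(kld(p, q), kld(q, p))))
  # non-negativity across cohort pairs (shared smoothing)
  co <- fix_cohort
  for (i in 1:5) {
    expect_gte(kld(co$features[i, ], co$features[i + 5, ]), 0)
  }
})

test_that("KLD refuses mismatched bin geometry", {
  d1 <- akv_histogram(runif(100, 0, 10), n_bins = 20, v_max = 20)
  d2 <- akv_histogram(runif(100, 0, 10), n_bins = 30, v_max = 20)
  expect_error(kld(d1, d2), "geometry")
})

test_that("two-sample KS behaves on degenerate and disjoint samples", {
  a <- c(1, 2, 3, 4, 5)
  r_same <- ks_two_sample(a, a)
  expect_equal(r_same$statistic, 0)
  expect_equal(r_same$p_value, 1)
  r_disj <- ks_two_sample(c(1, 2, 3, 3.5, 3.8), c(4, 5, 6, 7, 8))
  expect_equal(r_disj$statistic, 1)
  expect_warning(ks_two_sample(1:3, 4:9), "n < 5")
})

test_that("KS type-I error rate sits near the nominal level", {
  set.seed(11)
  rej <- mean(vapply(1:1000, function(i) {
    suppressWarnings(ks.test(rnorm(100), rnorm(100))$p.value) < 0.05
  }, logical(1)))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("Lilliefors rejects chi-squared data and accepts normal data", {
  set.seed(13)
  expect_lt(lilliefors_normality(rchisq(1e4, df = 2)), 0.001)
  ps <- vapply(1:10, function(s) {
    set.seed(s)
    lilliefors_normality(rnorm(1e4))
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
  expect_lt(lilliefors_normality(rep(3, 20)), 0.001)
})

test_that("Wilcoxon rank-sum matches exhaustive enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5)), 1)
  set.seed(17)
  power <- mean(vapply(1:20, function(i) {
    wilcoxon_rank_sum(rnorm(50), rnorm(50, 2)) < 0.001
  }, logical(1)))
  expect_gte(power, 0.95)
})

test_that("pairwise KS executes one test per cohort pair", {
  co <- synth_akv_cohort(n_norm = 26, n_path = 53, n_draws = 500, seed = 19)
  res <- pairwise_ks_failure_rate(co$draws[co$labels == "pathological"],
                                  co$draws[co$labels == "normative"])
  expect_equal(res$n_tests, 1378L)
})

test_that("pairwise KS failure rate tracks separability", {
  null_co <- synth_akv_cohort(n_norm = 8, n_path = 8, sigma_norm = 2,
                              sigma_path = 2, n_draws = 800, seed = 23,
                              subject_sd_jitter = 0)
  r_null <- pairwise_ks_failure_rate(
    null_co$draws[null_co$labels == "pathological"],
    null_co$draws[null_co$labels == "normative"])
  expect_gt(r_null$failure_pct, 85)

  sep_co <- synth_akv_cohort(n_norm = 10, n_path = 20, sigma_norm = 1,
                             sigma_path = 3, n_draws = 10000, seed = 23,
                             subject_sd_jitter = 0.05)
  r_sep <- pairwise_ks_failure_rate(
    sep_co$draws[sep_co$labels == "pathological"],
    sep_co$draws[sep_co$labels == "normative"])
  expect_lt(r_sep$failure_pct, 5)
})
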