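test_that("hidden layer initialisation is standard-normal and reproducible", {
  W <- init_hidden(50, 200, seed = 3)
  expect_equal(dim(W), c(50, 200))
  n <- length(W)
  expect_lt(abs(mean(W)), 3 / sqrt(n))
  expect_lt(abs(sd(W) - 1), 3 / sqrt(2 * n))
  expect_identical(W, init_hidden(50, 200, seed = 3))
  expect_false(identical(W, init_hidden(50, 200, seed = 4)))
})

test_that("hidden map is a sigmoid of random projections", {
  X <- matrix(runif(20), 4, 5)
  expect_true(all(hidden_map(X, matrix(0, 5, 3)) == 0.5))
  Y <- hidden_map(X, init_hidden(5, 8, 1))
  expect_true(all(Y > 0 & Y < 1))
  # scalar case: single feature, single hyperplane, weight 1
  y <- hidden_map(matrix(c(0, 1, -1), 3, 1), matrix(1, 1, 1))
  expect_equal(as.numeric(y), c(0.5, 1 / (1 + exp(-1)), 1 / (1 + exp(1))))
  expect_equal(y[2], 0.7310586, tolerance = 1e-6)
  expect_error(hidden_map(X, matrix(0, 4, 3)), "does not match")
})

test_that("output fit solves the identity system exactly", {
  W2 <- fit_output(diag(2), rbind(c(1, 0), c(0, 1)))
  expect_equal(W2, diag(2), tolerance = 1e-12)
})

test_that("least-squares residual matches the normal-equation oracle", {
  set.seed(31)
  for (rep in 1:100) {
    n_s <- sample(5:12, 1)
    n_h <- sample(2:5, 1)
    Y <- matrix(rnorm(n_s * n_h), n_s, n_h)
    T_mat <- matrix(rbinom(n_s * 2, 1, 0.5), n_s, 2)
    W2 <- fit_output(Y, T_mat)
    W2_ne <- solve(crossprod(Y), crossprod(Y, T_mat))
    r1 <- norm(T_mat - Y %*% W2, "F")
    r2 <- norm(T_mat - Y %*% W2_ne, "F")
    expect_lt(abs(r1 - r2), 1e-8)
  }
})

test_that("interpolation regime drives training error to zero", {
  set.seed(37)
  n_s <- 10; n_h <- 16
  Y <- 1 / (1 + exp(-matrix(rnorm(n_s * n_h), n_s, n_h)))
  T_mat <- target_coding(rep(c("pathological", "normative"), 5))
  W2 <- fit_output(Y, T_mat)
  expect_lt(norm(T_mat - Y %*% W2, "F"), 1e-6)
})

test_that("the returned solution has minimum norm among equal-residual solutions", {
  skip_if_not_installed("MASS")
  set.seed(41)
  Y <- matrix(rnorm(12), 6, 2) %*% matrix(rnorm(8), 2, 4)  # rank 2 of 4
  T_mat <- matrix(rnorm(12), 6, 2)
  W2 <- fit_output(Y, T_mat)
  W2_g <- MASS::ginv(Y) %*% T_mat
  expect_equal(W2, W2_g, tolerance = 1e-9)
  # any null-space perturbation with equal residual has larger norm
  ns <- svd(Y)$v[, 3:4]
  for (k in 1:20) {
    pert <- W2 + ns %*% matrix(rnorm(4, 0, 0.1), 2, 2)
    expect_equal(norm(T_mat - Y %*% pert, "F"), norm(T_mat - Y %*% W2, "F"),
                 tolerance = 1e-9)
    expect_gt(norm(pert, "F"), norm(W2, "F"))
  }
})

test_that("the fitted output is the argmin against random perturbations", {
  set.seed(43)
  for (rep in 1:100) {
    n_s <- sample(4:12, 1)
    n_h <- sample(2:8, 1)
    Y <- matrix(rnorm(n_s * n_h), n_s, n_h)
    T_mat <- target_coding(sample(c("pathological", "normative"), n_s,
                                  replace = TRUE))
    W2 <- fit_output(Y, T_mat)
    r0 <- norm(T_mat - Y %*% W2, "F")
    r_pert <- vapply(1:1000, function(i) {
      norm(T_mat - Y %*% (W2 + matrix(rnorm(n_h * 2, 0, 0.05), n_h, 2)), "F")
    }, numeric(1))
    expect_true(all(r_pert >= r0 - 1e-10))
  }
})

test_that("training labels are reproduced in the interpolation regime", {
  co <- fix_cohort
  model <- rlsfn_train(co$features, co$labels, n_h = 60, seed = 5)
  Z <- predict(model, co$features)
  expect_true(all(Z > 0 & Z < 1))
  calls <- ifelse(Z[, 1] > Z[, 2], "pathological", "normative")
  expect_equal(unname(calls), co$labels)
})

test_that("prediction is a row-wise map", {
  co <- fix_cohort
  model <- rlsfn_train(co$features, co$labels, n_h = 30, seed = 5)
  Z <- predict(model, co$features)
  perm <- sample(nrow(co$features))
  Zp <- predict(model, co$features[perm, ])
  expect_equal(Zp, Z[perm, ])
})

test_that("LLR scores follow the log-ratio identities", {
  expect_equal(llr_scores(cbind(0.4, 0.4)), 0)
  expect_equal(llr_scores(cbind(0.9, 0.1), eps = 0), log(9))
  expect_equal(llr_scores(cbind(0.9, 0.1), eps = 0), 2.197225, tolerance = 1e-6)
  Z <- cbind(runif(10, 0.01, 0.99), runif(10, 0.01, 0.99))
  expect_equal(llr_scores(Z[, 2:1]), -llr_scores(Z))
})

test_that("models survive a JSON round trip", {
  co <- fix_cohort
  model <- rlsfn_train(co$features, co$labels, n_h = 12, seed = 8)
  p <- withr::local_tempfile(fileext = ".json")
  save_rlsfn(model, p)
  back <- load_rlsfn(p)
  expect_equal(back$W1, model$W1)
  expect_equal(back$W2, model$W2)
  expect_equal(llr_scores(predict(back, co$features)),
               llr_scores(predict(model, co$features)))
})

test_that("well-separated 2-D clusters are classified perfectly in LOO", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 10
    X <- rbind(matrix(rnorm(2 * n, 0, 0.5), n, 2),
               matrix(rnorm(2 * n, 3, 0.5), n, 2))
    labels <- rep(c("normative", "pathological"), each = n)
    s <- loo_run(X, labels, n_h = 50, seed = seed)
    correct <- (s$lambda > 0) == (s$labels == "pathological")
    expect_equal(mean(correct), 1)
  }
})

test_that("label shuffling destroys classification skill", {
  co <- fix_cohort
  set.seed(47)
  aucs <- vapply(1:50, function(i) {
    roc_auc(loo_run(co$features, sample(co$labels), n_h = 50, seed = i))$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})
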