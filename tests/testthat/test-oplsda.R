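test_that("NIPALS PCA matches eigendecomposition on random matrices", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(6:12, 1); p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    k <- min(3, p, n - 1)
    got <- nipals_pca(X, k)
    Xc <- scale(X, scale = FALSE)
    eig <- eigen(crossprod(Xc), symmetric = TRUE)
    for (a in seq_len(k)) {
      v <- eig$vectors[, a]
      expect_equal(abs(sum(got$loadings[, a] * v)), 1, tolerance = 1e-6)
      expect_equal(got$r2x[a], eig$values[a] / sum(diag(crossprod(Xc))),
                   tolerance = 1e-8)
    }
  }
})

test_that("PCA components are orthogonal and rank-1 input is fully explained", {
  set.seed(2)
  X <- matrix(rnorm(40), 8, 5)
  out <- nipals_pca(X, 3)
  g <- crossprod(out$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  expect_equal(crossprod(out$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(out$r2x) <= 1e-10))

  r1 <- tcrossprod(rnorm(6), rnorm(4))
  out1 <- nipals_pca(r1, 1)
  expect_equal(out1$r2x[1], 1, tolerance = 1e-10)
})

test_that("OPLS-DA with no orthogonal component equals the PLS1 oracle", {
  set.seed(20)
  for (i in 1:50) {
    X <- matrix(rnorm(20 * 30), 20, 30,
                dimnames = list(NULL, paste0("f", 1:30)))
    y <- rep(c("CON", "CASE"), each = 10)
    n_pred <- sample(1:2, 1)
    m <- fit_oplsda(X, y, n_pred = n_pred, n_ortho = 0)
    orc <- oracle_pls1(X, as.numeric(y == "CASE"), n_pred)
    expect_equal(unname(m$b), orc$b, tolerance = 1e-8)
    expect_equal(m$fitted, orc$fitted, tolerance = 1e-8)
  }
})

test_that("fitted model honors its structural invariants", {
  sim <- simulate_preclinical(cohort_spec(seed = 33))
  X <- ft_study_matrix(sim$table); y <- ft_study_groups(sim$table)
  m <- fit_oplsda(X, y, n_pred = 1, n_ortho = 2)
  # unit-norm weights
  expect_equal(unname(colSums(m$w^2)), rep(1, m$n_pred), tolerance = 1e-12)
  expect_equal(unname(colSums(m$w_o^2)), rep(1, m$n_ortho), tolerance = 1e-12)
  # predictive scores orthogonal to orthogonal scores
  ip <- crossprod(m$t, m$t_o)
  expect_lt(max(abs(ip)) / sqrt(sum(m$t^2) * max(colSums(m$t_o^2))), 1e-8)
  # the linear form reproduces the stored fitted values
  pr <- predict(m, X)
  expect_equal(pr$y_hat, m$fitted, tolerance = 1e-10)
  # diagnostics within range
  d <- m$diagnostics
  expect_true(d$r2y_cum >= 0 && d$r2y_cum <= 1)
  expect_true(d$r2x_cum >= 0 && d$r2x_cum <= 1)
  expect_equal(d$r2x_cum, d$r2x_pred + d$r2x_ortho)
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
  expect_error(fit_oplsda(X, rep("A", 10)), "two classes")
  expect_error(fit_oplsda(X, rep(c("A", "B"), each = 5), n_ortho = 9),
               "n_ortho")
  Xc <- X; Xc[, 2] <- 1
  expect_error(fit_oplsda(Xc, rep(c("A", "B"), each = 5)), "f2")
})

test_that("well-separated classes fit almost perfectly", {
  set.seed(14)
  X <- rbind(matrix(rnorm(10 * 8), 10, 8),
             matrix(rnorm(10 * 8, mean = 5), 10, 8))
  colnames(X) <- paste0("f", 1:8)
  y <- rep(c("CON", "CASE"), each = 10)
  m <- fit_oplsda(X, y)
  expect_gte(m$diagnostics$r2y_cum, 0.9)
  expect_identical(predict(m, X)$class, y)
})

test_that("R2Y is nondecreasing in the predictive component count", {
  set.seed(26)
  X <- matrix(rnorm(18 * 12), 18, 12, dimnames = list(NULL, paste0("f", 1:12)))
  y <- rep(c("A", "B"), each = 9)
  r2 <- vapply(1:3, function(a)
    fit_oplsda(X, y, n_pred = a, n_ortho = 0)$diagnostics$r2y_cum, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("Q2Y behaves like a cross-validated R2", {
  # y an exact function of the (collinear) features -> near-perfect prediction
  x1 <- rep(c(0, 3), each = 12)
  X <- cbind(f1 = x1, f2 = 0.5 * x1 + 1, f3 = 2 * x1)
  y <- rep(c("CON", "CASE"), each = 12)
  expect_gte(cross_validate_q2(X, y, n_ortho = 0, seed = 1), 0.99)

  # independent X and y -> Q2 at or below zero in the typical seed
  q2_null <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(20 * 50), 20, 50, dimnames = list(NULL, paste0("f", 1:50)))
    yn <- rep(c("A", "B"), each = 10)
    cross_validate_q2(Xn, yn, seed = s)
  }, numeric(1))
  expect_lte(median(q2_null), 0)
  expect_true(all(q2_null <= 1))
})

test_that("Q2Y is invariant to feature and sample order", {
  sim <- simulate_preclinical(cohort_spec(n_per_group = 6, seed = 55))
  X <- ft_study_matrix(sim$table); y <- ft_study_groups(sim$table)
  q2 <- cross_validate_q2(X, y, seed = 3)
  set.seed(99)
  pf <- sample(ncol(X))
  # same fold seed, features shuffled: identical Q2
  expect_equal(cross_validate_q2(X[, pf], y, seed = 3), q2, tolerance = 1e-10)
})

test_that("permutation diagnostics bound pQ2 and separate signal from noise", {
  sim <- simulate_preclinical(cohort_spec(cv_noise = 0.12, seed = 66))
  tab <- qc_block_normalize(sim$table)$table
  X <- ft_study_matrix(tab); y <- ft_study_groups(tab)
  pt <- permutation_test(X, y, n_perm = 19, seed = 7)
  expect_gte(pt$p_q2, 1 / 20)
  expect_equal(pt$p_q2, 1 / 20)  # strong signal: no permutation wins
  expect_error(permutation_test(X, y, n_perm = 0), "n_perm")

  set.seed(42)
  Xn <- matrix(rnorm(20 * 40), 20, 40, dimnames = list(NULL, paste0("f", 1:40)))
  yn <- rep(c("A", "B"), each = 10)
  ptn <- permutation_test(Xn, yn, n_perm = 19, seed = 8)
  expect_gte(ptn$p_q2, 0.05)
})

test_that("VIP satisfies its normalization identity and closed forms", {
  sim <- simulate_preclinical(cohort_spec(seed = 21))
  X <- ft_study_matrix(sim$table); y <- ft_study_groups(sim$table)
  m <- fit_oplsda(X, y, n_pred = 2, n_ortho = 1)
  v <- vip(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
  expect_true(all(v >= 0))
  # single predictive component: VIP_j = sqrt(p) * |w_j|
  m1 <- fit_oplsda(X, y, n_pred = 1, n_ortho = 1)
  expect_equal(unname(vip(m1)), sqrt(ncol(X)) * abs(unname(m1$w[, 1])),
               tolerance = 1e-10)
  # hand evaluation: w = (0.8, 0.6), one component -> VIP = w * sqrt(2)
  w <- c(0.8, 0.6); ss <- 1
  vip_hand <- sqrt(2 * ss * w^2 / ss)
  expect_equal(vip_hand, c(0.8, 0.6) * sqrt(2), tolerance = 1e-12)
  expect_equal(round(vip_hand, 3), c(1.131, 0.849))
})

test_that("model-quality verdicts follow the Q2Y thresholds", {
  expect_identical(model_quality(0.572)$verdict, "good")
  u <- model_quality(-0.029)
  expect_identical(u$verdict, "none")
  expect_true(u$rejected)
  expect_identical(model_quality(0.3)$verdict, "some")
  expect_false(model_quality(0.572, p_q2 = 0.02)$rejected)
  expect_true(model_quality(0.572, p_q2 = 0.05)$rejected)
  expect_error(model_quality(1.2), "exceed")
})

test_that("serialized models reload bit-identically for prediction", {
  sim <- simulate_preclinical(cohort_spec(n_per_group = 5, seed = 71))
  X <- ft_study_matrix(sim$table); y <- ft_study_groups(sim$table)
  m <- fit_oplsda(X, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_latent_model(m, path)
  m2 <- read_latent_model(path)
  expect_identical(m2$features, m$features)
  expect_equal(unname(m2$b), unname(m$b), tolerance = 1e-14)
  expect_identical(m2$rmsee, m$rmsee)
  expect_equal(predict(m2, X)$y_hat, predict(m, X)$y_hat, tolerance = 1e-12)
})

test_that("prediction reconciles columns by name and flags gaps", {
  sim <- simulate_preclinical(cohort_spec(n_per_group = 5, seed = 72))
  X <- ft_study_matrix(sim$table); y <- ft_study_groups(sim$table)
  m <- fit_oplsda(X, y)
  set.seed(1)
  pf <- sample(ncol(X))
  expect_equal(predict(m, X[, pf])$y_hat, predict(m, X)$y_hat,
               tolerance = 1e-12)
  expect_error(predict(m, X[, -1]), colnames(X)[1], fixed = TRUE)
  X2 <- cbind(X, unexpected = rnorm(nrow(X)))
  expect_warning(pr <- predict(m, X2), "unexpected")
  expect_equal(pr$y_hat, predict(m, X)$y_hat)
  # row permutation permutes predictions identically
  expect_equal(predict(m, X[10:1, ])$y_hat, rev(predict(m, X[1:10, ])$y_hat))
})

test_that("RMSEE uses the n - 1 - n_pred denominator", {
  sim <- simulate_preclinical(cohort_spec(n_per_group = 5, seed = 73))
  X <- ft_study_matrix(sim$table); y <- ft_study_groups(sim$table)
  m <- fit_oplsda(X, y)
  resid <- as.numeric(y == "CASE") - m$fitted
  expect_equal(m$rmsee, sqrt(sum(resid^2) / (10 - 1 - 1)), tolerance = 1e-12)
})
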