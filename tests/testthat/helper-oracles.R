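# Independent oracles used across the suite. Each is a deliberately
# straightforward (often brute-force) implementation kept separate from the
# package's code paths.

# U statistic by explicit pair counting.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) u <- u + 1
    else if (xi == yj) u <- u + 0.5
  }
  u
}

# Exact two-sided Mann-Whitney p by enumerating every group assignment.
oracle_mw_exact_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  u_obs <- oracle_u(x, y)
  mu <- n1 * length(y) / 2
  us <- apply(idx, 2, function(ii) oracle_u(pool[ii], pool[-ii]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Benjamini-Hochberg step-up by the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(c(p[o][i:m] * m / (i:m), 1))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# PLS1 regression via its Krylov-subspace characterisation: the a-component
# PLS1 coefficient vector is the least-squares solution restricted to
# span{s, As, A^2 s, ...} with A = X'X and s = X'y. Completely independent
# of the NIPALS deflation route used by the package.
oracle_pls1 <- function(X, y01, n_comp) {
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, sd)
  Xs <- scale(X, center = x_mean, scale = x_sd)
  yc <- y01 - mean(y01)
  A <- crossprod(Xs)
  s <- crossprod(Xs, yc)
  K <- matrix(0, ncol(Xs), n_comp)
  v <- s
  for (a in seq_len(n_comp)) {
    K[, a] <- v / sqrt(sum(v^2))
    v <- A %*% K[, a]
  }
  M <- crossprod(K, A %*% K)
  b <- K %*% solve(M, crossprod(K, s))
  fitted <- mean(y01) + as.numeric(Xs %*% b)
  list(b = as.numeric(b), fitted = fitted)
}

# Balanced accuracy of model calls against latent truth labels.
balanced_accuracy <- function(model_class, truth_class) {
  mean(c(mean(model_class[truth_class == "at-risk"] == "at-risk"),
         mean(model_class[truth_class == "healthy"] == "healthy")))
}

# Small dense feature table built by hand (no generator) for toy tests.
toy_table <- function(ab, group, block = 1L, is_qc = FALSE,
                      cohort = "preclinical") {
  n <- nrow(ab)
  if (is.null(rownames(ab))) rownames(ab) <- sprintf("s%02d", seq_len(n))
  feature_table(ab, data.frame(
    sample_id = rownames(ab), cohort = cohort,
    group = rep_len(group, n), block = rep_len(block, n),
    is_qc = rep_len(is_qc, n), stringsAsFactors = FALSE
  ))
}
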