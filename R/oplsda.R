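#' NIPALS principal component analysis
#'
#' Computes principal components one at a time by the NIPALS iteration with
#' successive deflation. Initialization is deterministic (score started from
#' the column of maximal variance); each loading is signed so its
#' largest-magnitude entry is positive.
#'
#' @param X numeric matrix, samples x features.
#' @param n_comp number of components, at most `min(nrow - 1, ncol)`.
#' @param center,scale. column centering / unit-variance scaling applied
#'   before decomposition (defaults: center, no scaling).
#' @param tol relative score-change convergence tolerance (default 1e-10).
#' @param max_iter iteration cap per component (default 10000; the power
#'   iteration underlying NIPALS converges slowly when leading eigenvalues
#'   are close, so a generous cap buys accuracy at negligible cost on the
#'   matrix sizes this package handles).
#' @return list with `scores` (n x n_comp), `loadings` (p x n_comp,
#'   orthonormal), `r2x` (fraction of total variance per component).
#' @export
nipals_pca <- function(X, n_comp, center = TRUE, scale. = FALSE,
                       tol = 1e-10, max_iter = 10000L) {
  X <- as.matrix(X)
  if (n_comp > min(nrow(X) - 1, ncol(X)))
    stop("n_comp exceeds min(n_samples - 1, n_features)")
  X <- scale(X, center = center, scale = scale.)
  ss_tot <- sum(X^2)
  n <- nrow(X); p <- ncol(X)
  scores <- matrix(0, n, n_comp)
  loadings <- matrix(0, p, n_comp,
                     dimnames = list(colnames(X), NULL))
  r2x <- numeric(n_comp)
  for (a in seq_len(n_comp)) {
    t_vec <- X[, which.max(apply(X, 2, stats::var))]
    for (it in seq_len(max_iter)) {
      p_vec <- crossprod(X, t_vec) / sum(t_vec^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- X %*% p_vec
      if (sqrt(sum((t_new - t_vec)^2)) < tol * max(sqrt(sum(t_new^2)), 1e-300)) {
        t_vec <- t_new
        break
      }
      t_vec <- t_new
      if (it == max_iter)
        stop("NIPALS failed to converge after ", max_iter, " iterations")
    }
    s <- sign(p_vec[which.max(abs(p_vec))])
    p_vec <- p_vec * s; t_vec <- t_vec * s
    scores[, a] <- t_vec
    loadings[, a] <- p_vec
    r2x[a] <- sum(t_vec^2) / ss_tot
    X <- X - tcrossprod(t_vec, p_vec)
  }
  list(scores = scores, loadings = loadings, r2x = r2x)
}

# Code a two-class label vector as 0/1. The positive class is coded 1.
code_classes <- function(y_labels, positive = NULL) {
  y_labels <- as.character(y_labels)
  lv <- unique(y_labels)
  if (length(lv) != 2)
    stop("exactly two classes required, got ", length(lv), ": ",
         paste(lv, collapse = ", "))
  if (min(table(y_labels)) < 3) stop("each class needs at least 3 samples")
  if (is.null(positive)) positive <- if ("CON" %in% lv) setdiff(lv, "CON") else lv[2]
  if (!positive %in% lv) stop("positive class '", positive, "' not among labels")
  list(y = as.numeric(y_labels == positive),
       positive = positive, negative = setdiff(lv, positive))
}

#' Fit an OPLS-DA model
#'
#' Orthogonal partial least-squares discriminant analysis for a two-class
#' problem. Predictors are unit-variance scaled and centered from the
#' training data; the class is coded 0/1 (positive class = 1) and centered.
#' `n_ortho` class-orthogonal components are removed from X by the
#' orthogonal-projection construction (w_ortho proportional to
#' p - (w'p) w), then `n_pred` predictive PLS1 components are fitted on the
#' filtered matrix. The model collapses to a single linear form: coefficient
#' vector `b` on the scaled scale (and `b_raw`/`intercept_raw` on the raw
#' scale) so prediction on new data is one inner product.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y_labels two-class label vector.
#' @param n_pred predictive components (default 1).
#' @param n_ortho orthogonal components (default 1; must be <
#'   `nrow(X) - 2`).
#' @param positive label coded 1; default the non-`"CON"` label if `"CON"`
#'   is present, otherwise the second unique label.
#' @return An object of class `opls_model`; see Details for fields.
#' @details Fields include `scaling` (x_mean, x_sd, y_mean, class coding),
#'   per-component weights/scores/loadings (`w`, `t`, `p`, `q` predictive;
#'   `w_o`, `t_o`, `p_o` orthogonal), `b`, `b_raw`, `intercept_raw`,
#'   `fitted` (coded scale), `rmsee` (denominator n - 1 - n_pred), and
#'   `diagnostics` (`r2x_pred`, `r2x_ortho`, `r2x_cum`, `r2y_cum`).
#' @export
fit_oplsda <- function(X, y_labels, n_pred = 1, n_ortho = 1, positive = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  coding <- code_classes(y_labels, positive)
  n <- nrow(X)
  if (length(coding$y) != n) stop("labels and X disagree in length")
  if (n_ortho >= n - 2) stop("n_ortho must be below n_samples - 2")
  if (n_pred < 1) stop("need at least one predictive component")

  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  if (any(x_sd == 0))
    stop("constant feature(s) after scaling: ",
         paste(colnames(X)[x_sd == 0], collapse = ", "))
  Xs <- scale(X, center = x_mean, scale = x_sd)
  y_mean <- mean(coding$y)
  yc <- coding$y - y_mean

  p_feat <- ncol(Xs)
  ss_x_tot <- sum(Xs^2)
  ss_y_tot <- sum(yc^2)
  Xf <- Xs

  W_o <- matrix(0, p_feat, 0); T_o <- matrix(0, n, 0); P_o <- matrix(0, p_feat, 0)
  for (o in seq_len(n_ortho)) {
    w <- crossprod(Xf, yc); w <- w / sqrt(sum(w^2))
    t_vec <- Xf %*% w
    p_vec <- crossprod(Xf, t_vec) / sum(t_vec^2)
    w_o <- p_vec - as.numeric(crossprod(w, p_vec)) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12)
      stop("no orthogonal variation left for component ", o)
    w_o <- w_o / nrm
    t_o <- Xf %*% w_o
    p_o <- crossprod(Xf, t_o) / sum(t_o^2)
    s <- sign(w_o[which.max(abs(w_o))])
    w_o <- s * w_o; t_o <- s * t_o; p_o <- s * p_o
    Xf <- Xf - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o)
  }

  W <- matrix(0, p_feat, 0); Tm <- matrix(0, n, 0)
  P <- matrix(0, p_feat, 0); q <- numeric(0)
  Xp <- Xf; yr <- yc
  for (a in seq_len(n_pred)) {
    w <- crossprod(Xp, yr)
    nrm <- sqrt(sum(w^2))
    if (nrm < 1e-12) stop("response orthogonal to predictors at component ", a)
    w <- w / nrm
    t_vec <- Xp %*% w
    p_vec <- crossprod(Xp, t_vec) / sum(t_vec^2)
    q_a <- as.numeric(crossprod(yr, t_vec) / sum(t_vec^2))
    s <- sign(w[which.max(abs(w))])
    w <- s * w; t_vec <- s * t_vec; p_vec <- s * p_vec; q_a <- s * q_a
    Xp <- Xp - tcrossprod(t_vec, p_vec)
    yr <- yr - q_a * t_vec
    W <- cbind(W, w); Tm <- cbind(Tm, t_vec); P <- cbind(P, p_vec)
    q <- c(q, q_a)
  }

  # single linear form on the scaled scale: filtered-space coefficients
  # mapped back through the orthogonal filter
  b_f <- W %*% solve(crossprod(P, W), q)
  Fm <- diag(p_feat)
  for (o in seq_len(ncol(W_o)))
    Fm <- Fm %*% (diag(p_feat) - tcrossprod(W_o[, o], P_o[, o]))
  b <- as.numeric(Fm %*% b_f)
  names(b) <- colnames(X)

  fitted_coded <- y_mean + as.numeric(Xs %*% b)
  resid <- coding$y - fitted_coded
  dof <- n - 1 - n_pred
  rmsee <- sqrt(sum(resid^2) / dof)
  r2y <- 1 - sum(resid^2) / ss_y_tot
  r2x_pred <- sum(vapply(seq_len(n_pred), function(a)
    sum(tcrossprod(Tm[, a], P[, a])^2), numeric(1))) / ss_x_tot
  r2x_ortho <- if (ncol(T_o)) sum(vapply(seq_len(ncol(T_o)), function(o)
    sum(tcrossprod(T_o[, o], P_o[, o])^2), numeric(1))) / ss_x_tot else 0

  b_raw <- b / x_sd
  intercept_raw <- y_mean - sum(b_raw * x_mean)

  structure(list(
    features = colnames(X),
    scaling = list(x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
                   positive = coding$positive, negative = coding$negative),
    n_pred = n_pred, n_ortho = n_ortho,
    w = W, t = Tm, p = P, q = q,
    w_o = W_o, t_o = T_o, p_o = P_o,
    b = b, b_raw = b_raw, intercept_raw = intercept_raw,
    fitted = fitted_coded, rmsee = rmsee,
    diagnostics = list(r2x_pred = r2x_pred, r2x_ortho = r2x_ortho,
                       r2x_cum = r2x_pred + r2x_ortho, r2y_cum = r2y)
  ), class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<opls_model> %d features, %d predictive + %d orthogonal component(s)\n",
    length(x$features), x$n_pred, x$n_ortho))
  cat(sprintf("  R2X(pred) %.3f, R2X(ortho) %.3f, R2Y %.3f, RMSEE %.3f\n",
              d$r2x_pred, d$r2x_ortho, d$r2y_cum, x$rmsee))
  cat(sprintf("  positive class: %s (coded 1)\n", x$scaling$positive))
  invisible(x)
}

#' Predict from an OPLS-DA model
#'
#' Applies the model's single linear form. Columns of `X_new` are matched to
#' model features by name; missing features are an error, extras are dropped
#' with a warning. Class labels use the midpoint of the 0/1 coding: positive
#' iff the continuous score is >= 0.5.
#'
#' @param object an `opls_model`.
#' @param X_new numeric matrix with named columns.
#' @param scaling `"training"` (default: standardize with the stored
#'   training means/SDs) or `"none"` (treat `X_new` as already standardized
#'   and apply `b` directly around the coded-class mean).
#' @param ... unused.
#' @return list with `y_hat` (continuous, coded scale) and `class`
#'   (character labels).
#' @export
predict.opls_model <- function(object, X_new, scaling = c("training", "none"),
                               ...) {
  scaling <- match.arg(scaling)
  X_new <- as.matrix(X_new)
  miss <- setdiff(object$features, colnames(X_new))
  if (length(miss))
    stop("missing model features: ", paste(miss, collapse = ", "))
  extra <- setdiff(colnames(X_new), object$features)
  if (length(extra))
    warning("ignoring features absent from the model: ",
            paste(extra, collapse = ", "))
  X_new <- X_new[, object$features, drop = FALSE]
  y_hat <- if (scaling == "training") {
    object$intercept_raw + as.numeric(X_new %*% object$b_raw)
  } else {
    object$scaling$y_mean + as.numeric(X_new %*% object$b)
  }
  cls <- ifelse(y_hat >= 0.5, object$scaling$positive, object$scaling$negative)
  list(y_hat = y_hat, class = cls)
}

#' Cross-validated predictive ability Q2Y
#'
#' Stratified K-fold cross-validation of the coded class response:
#' Q2Y = 1 - PRESS / SS, with PRESS the out-of-fold squared prediction error
#' and SS the total sum of squares of the centered coded response. Scaling
#' and the whole model are refit inside every training split.
#'
#' @param X,y_labels as in [fit_oplsda()].
#' @param n_pred,n_ortho component structure (defaults 1 and 1).
#' @param folds number of folds (default 7, capped at the smaller class
#'   size).
#' @param seed integer seed for fold assignment.
#' @param positive positive class label passed through to the fits.
#' @return Q2Y (numeric scalar, at most 1, possibly negative).
#' @export
cross_validate_q2 <- function(X, y_labels, n_pred = 1, n_ortho = 1,
                              folds = 7, seed = 1L, positive = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  coding <- code_classes(y_labels, positive)
  y0 <- coding$y
  n <- length(y0)
  if (folds < 2) stop("folds must be at least 2")
  folds <- min(folds, min(table(y0)))

  set.seed(as.integer(seed))
  fold_id <- integer(n)
  for (cls in unique(y0)) {
    idx <- sample(which(y0 == cls))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  press <- 0
  for (k in seq_len(folds)) {
    train <- fold_id != k
    if (length(unique(y0[train])) < 2)
      stop("fold ", k, " lost a class in its training split")
    fit <- fit_oplsda(X[train, , drop = FALSE], y_labels[train],
                      n_pred = n_pred, n_ortho = n_ortho,
                      positive = coding$positive)
    pr <- predict(fit, X[!train, , drop = FALSE])
    press <- press + sum((y0[!train] - pr$y_hat)^2)
  }
  ss <- sum((y0 - mean(y0))^2)
  1 - press / ss
}

#' Permutation diagnostics for an OPLS-DA model
#'
#' Permutes the class labels `n_perm` times, refits the full model and its
#' cross-validated Q2Y per permutation, and reports add-one permutation
#' p-values: pQ2 = (1 + #\{Q2_perm >= Q2_obs\}) / (n_perm + 1), analogously
#' pR2Y.
#'
#' @param X,y_labels as in [fit_oplsda()].
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed (drives both fold assignment and permutations).
#' @param n_pred,n_ortho,folds,positive as in [cross_validate_q2()].
#' @return list with `q2_obs`, `r2y_obs`, `q2_perm`, `r2y_perm`, `p_q2`,
#'   `p_r2y`, `n_perm`.
#' @export
permutation_test <- function(X, y_labels, n_perm = 999, seed = 1L,
                             n_pred = 1, n_ortho = 1, folds = 7,
                             positive = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  obs_fit <- fit_oplsda(X, y_labels, n_pred, n_ortho, positive)
  q2_obs <- cross_validate_q2(X, y_labels, n_pred, n_ortho, folds,
                              seed = child_seed(seed, "cv_obs"),
                              positive = positive)
  q2_perm <- numeric(n_perm)
  r2y_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(child_seed(seed, paste0("perm", i)))
    yp <- sample(as.character(y_labels))
    fit_p <- try(fit_oplsda(X, yp, n_pred, n_ortho, positive), silent = TRUE)
    r2y_perm[i] <- if (inherits(fit_p, "try-error")) NA_real_
                   else fit_p$diagnostics$r2y_cum
    q2_perm[i] <- tryCatch(
      cross_validate_q2(X, yp, n_pred, n_ortho, folds,
                        seed = child_seed(seed, paste0("cvperm", i)),
                        positive = positive),
      error = function(e) NA_real_
    )
  }
  list(
    q2_obs = q2_obs, r2y_obs = obs_fit$diagnostics$r2y_cum,
    q2_perm = q2_perm, r2y_perm = r2y_perm,
    p_q2 = (1 + sum(q2_perm >= q2_obs, na.rm = TRUE)) / (n_perm + 1),
    p_r2y = (1 + sum(r2y_perm >= obs_fit$diagnostics$r2y_cum, na.rm = TRUE)) /
      (n_perm + 1),
    n_perm = n_perm
  )
}

#' Variable importance in the projection
#'
#' VIP_j = sqrt( p * sum_a SS_a w_aj^2 / sum_a SS_a ) over the predictive
#' components, with SS_a = q_a^2 t_a't_a. Orthogonal components do not enter:
#' they are class-orthogonal by construction. Mean squared VIP equals 1.
#'
#' @param model an `opls_model`.
#' @return named numeric vector of VIP scores, one per feature.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  ss <- model$q^2 * colSums(model$t^2)
  if (sum(ss) <= 0) stop("zero explained response sum of squares")
  p <- length(model$features)
  v <- sqrt(p * as.numeric(model$w^2 %*% ss) / sum(ss))
  stats::setNames(v, model$features)
}

#' Model-quality verdict from Q2Y
#'
#' Q2Y below 0 indicates no predictive ability, between 0 and 0.5 some, and
#' above 0.5 good. A model is additionally flagged rejected when Q2Y < 0 or
#' its permutation pQ2 >= 0.05 — the rule that discards an overfitted
#' discriminant branch.
#'
#' @param q2y cross-validated Q2Y (must be <= 1).
#' @param p_q2 optional permutation p-value for Q2Y.
#' @return list with `verdict` in `c("none", "some", "good")` and `rejected`
#'   logical.
#' @export
model_quality <- function(q2y, p_q2 = NULL) {
  if (q2y > 1 + 1e-12) stop("Q2Y cannot exceed 1")
  verdict <- if (q2y < 0) "none" else if (q2y <= 0.5) "some" else "good"
  rejected <- q2y < 0 || (!is.null(p_q2) && p_q2 >= 0.05)
  list(verdict = verdict, rejected = rejected)
}

#' Serialize an OPLS-DA model to JSON
#'
#' Writes every field needed to reproduce predictions bit-identically on
#' another machine (scaling, weights, loadings, coefficients, diagnostics,
#' feature names) with full numeric precision.
#'
#' @param model an `opls_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_latent_model <- function(model, path) {
  stopifnot(inherits(model, "opls_model"))
  doc <- list(
    format = "metabotrans-opls", version = 1L,
    features = model$features,
    scaling = model$scaling,
    n_pred = model$n_pred, n_ortho = model$n_ortho,
    w = model$w, t = model$t, p = model$p, q = model$q,
    w_o = model$w_o, t_o = model$t_o, p_o = model$p_o,
    b = unname(model$b), b_raw = unname(model$b_raw),
    intercept_raw = model$intercept_raw,
    fitted = model$fitted, rmsee = model$rmsee,
    diagnostics = model$diagnostics
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}

#' Read an OPLS-DA model serialized by [write_latent_model()]
#'
#' @param path JSON file path.
#' @return An `opls_model`.
#' @export
read_latent_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "metabotrans-opls"))
    stop("not a serialized OPLS-DA model: ", path)
  as_mat <- function(m, nr) {
    m <- as.matrix(m)
    if (length(m) == 0) matrix(0, nr, 0) else m
  }
  p <- length(doc$features)
  n <- length(doc$fitted)
  model <- list(
    features = doc$features,
    scaling = list(
      x_mean = stats::setNames(as.numeric(doc$scaling$x_mean), doc$features),
      x_sd = stats::setNames(as.numeric(doc$scaling$x_sd), doc$features),
      y_mean = doc$scaling$y_mean,
      positive = doc$scaling$positive, negative = doc$scaling$negative
    ),
    n_pred = doc$n_pred, n_ortho = doc$n_ortho,
    w = as_mat(doc$w, p), t = as_mat(doc$t, n), p = as_mat(doc$p, p),
    q = as.numeric(doc$q),
    w_o = as_mat(doc$w_o, p), t_o = as_mat(doc$t_o, n),
    p_o = as_mat(doc$p_o, p),
    b = stats::setNames(as.numeric(doc$b), doc$features),
    b_raw = stats::setNames(as.numeric(doc$b_raw), doc$features),
    intercept_raw = doc$intercept_raw,
    fitted = as.numeric(doc$fitted), rmsee = doc$rmsee,
    diagnostics = doc$diagnostics
  )
  class(model) <- "opls_model"
  model
}
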