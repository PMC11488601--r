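# Ridge fitting, fold assignment, lambda selection, and cross-validated RSS.
# All CV machinery funnels through one vectorized engine (cv_rss_engine) that
# treats an arbitrary number of outcome columns at once: one SVD per training
# fold serves every voxel, every candidate lambda, and every permutation
# surrogate, which is what makes permutation inference tractable.

#' Default ridge penalty grid
#'
#' 20 points log-spaced in [1e-3, 1e3], on the standardized-design scale.
#'
#' @param n_points number of grid points.
#' @param range lower and upper penalty.
#' @export
lambda_grid <- function(n_points = 20, range = c(1e-3, 1e3)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n_points))
}

#' Assign subjects to cross-validation folds
#'
#' Deterministic given the seed; fold sizes differ by at most one.
#'
#' @param n number of subjects.
#' @param K number of folds (default 10).
#' @param seed master seed (fold labels derive from it via
#'   [derive_seed()]).
#' @return object of class \code{vb_folds}: integer labels in 1..K.
#' @export
make_folds <- function(n, K = 10, seed = 1L) {
  vb_check(n >= 2 * K, sprintf("need at least %d subjects for %d-fold CV", 2 * K, K),
           "fold")
  set.seed(derive_seed(seed, "folds"))
  labels <- sample(rep_len(seq_len(K), n))
  structure(list(labels = labels, K = as.integer(K), seed = as.integer(seed)),
            class = "vb_folds")
}

#' @export
print.vb_folds <- function(x, ...) {
  cat(sprintf("%d-fold assignment of %d subjects (seed %d)\n",
              x$K, length(x$labels), x$seed))
  invisible(x)
}

#' Fit a ridge regression with an unpenalized intercept
#'
#' Minimizes \eqn{\|y - \alpha - X\beta\|^2 + \lambda \|\beta\|^2} in closed
#' form via the SVD of the centred design. Ridge tolerates multicollinear
#' regressors -- the motivating case for compositional microbiome predictors
#' -- by trading a downward bias in the coefficients for estimation
#' efficiency. At \eqn{\lambda = 0} with a rank-deficient design the
#' minimum-norm least-squares solution is returned with a warning.
#'
#' @param X numeric matrix of regressors (not standardized internally;
#'   standardize beforehand if a common penalty scale is wanted).
#' @param y numeric outcome vector.
#' @param lambda nonnegative penalty.
#' @return list of class \code{vb_ridge}: \code{intercept}, \code{coef},
#'   \code{lambda}, \code{fitted}.
#' @export
fit_ridge <- function(X, y, lambda) {
  X <- as.matrix(X)
  vb_check(is.numeric(lambda) && length(lambda) == 1 && lambda >= 0,
           "lambda must be a single nonnegative number", "parameter")
  vb_check(nrow(X) >= 2 && nrow(X) == length(y),
           "X must have >= 2 rows matching length(y)", "data")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  yc <- y - mean(y)
  sv <- svd(Xc)
  tol <- max(sv$d) * 1e-10
  keep <- sv$d > tol
  if (lambda == 0 && sum(keep) < ncol(X)) {
    warning("singular design at lambda = 0; returning the minimum-norm solution")
  }
  d <- sv$d[keep]
  shrink <- d / (d^2 + lambda)
  beta <- sv$v[, keep, drop = FALSE] %*%
    (shrink * crossprod(sv$u[, keep, drop = FALSE], yc))
  beta <- as.numeric(beta)
  names(beta) <- colnames(X)
  intercept <- mean(y) - sum(ctr * beta)
  structure(list(intercept = intercept, coef = beta, lambda = lambda,
                 fitted = as.numeric(intercept + X %*% beta)),
            class = "vb_ridge")
}

# Standardize columns using training statistics; constant columns get scale 1
# (their standardized values are 0, so they drop out of the fit).
train_standardizer <- function(Xtr) {
  m <- colMeans(Xtr)
  s <- apply(Xtr, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(center = m, scale = s,
       apply = function(X) sweep(sweep(X, 2, m), 2, s, "/"))
}

# GCV score for every lambda on one training block, vectorized over outcome
# columns. d: singular values; W = U'Yc (r x C); ss_y = colSums(Yc^2).
# One crossprod covers all lambdas at once: RSS(lambda) = ss_y - (2a - a^2)'W^2
# with a = d^2/(d^2 + lambda).
gcv_scores <- function(d, W, ss_y, grid, ntr, df0 = 1) {
  A <- outer(d^2, grid, function(d2, l) d2 / (d2 + l))   # r x nl shrinkages
  rss <- rep(ss_y, each = length(grid)) - crossprod(2 * A - A * A, W * W)
  rss[rss < 0] <- 0  # guard against cancellation
  df <- colSums(A) + df0   # df0: unpenalized nuisance dimensions (incl. intercept)
  denom <- (ntr - df)^2
  gcv <- ntr * rss / denom
  gcv[df >= ntr - 1e-8, ] <- Inf
  gcv
}

# Index of the per-column minimizing lambda, ties broken toward the LARGER
# lambda (more shrinkage when indifferent).
pick_lambda <- function(score) {
  max.col(-t(score), ties.method = "last")
}

# Fold-level preparation for the vectorized CV engine: per fold, the
# nuisance projection, the penalized block's residualization/scaling, and its
# SVD are computed once and reused for every outcome column (voxels, and in
# permutation inference every surrogate). Everything -- nuisance fit,
# scaling, penalty selection -- stays strictly inside the training part of
# each fold.
#
# The model per fold is y = Z1 gamma + P beta + e with Z1 = [1, nuisance]
# unpenalized (fitted by least squares) and only the block P carrying the
# ridge penalty. With nuisance = NULL this reduces to the classic centred
# all-penalized ridge; with ncol(P) = 0 it reduces to OLS on the nuisance.
cv_prepare <- function(X, folds, grid = lambda_grid(), nuisance = NULL) {
  X <- as.matrix(X)
  labels <- folds$labels
  vb_check(length(labels) == nrow(X), "folds and design must agree in length",
           "alignment")
  vb_check(length(grid) >= 1 && all(grid >= 0), "lambda grid must be nonnegative",
           "parameter")
  Z1 <- cbind(intercept = rep(1, nrow(X)), nuisance)
  prep <- vector("list", folds$K)
  for (k in seq_len(folds$K)) {
    te <- which(labels == k)
    tr <- which(labels != k)
    if (length(te) == 0) next
    if (length(tr) < 2) vb_stop(sprintf("fold %d leaves < 2 training subjects", k),
                                "fold")
    qz <- qr(Z1[tr, , drop = FALSE])
    fp <- list(tr = tr, te = te, ntr = length(tr), qz = qz,
               Z1_tr = Z1[tr, , drop = FALSE],
               Z1_te = Z1[te, , drop = FALSE], q = ncol(Z1))
    if (ncol(X) > 0) {
      # residualize the penalized block on the training nuisance fit
      cx <- qr.coef(qz, X[tr, , drop = FALSE])
      cx[is.na(cx)] <- 0
      Xtr_r <- X[tr, , drop = FALSE] - Z1[tr, , drop = FALSE] %*% cx
      Xte_r <- X[te, , drop = FALSE] - fp$Z1_te %*% cx
      s <- apply(Xtr_r, 2, sd)
      s[s == 0 | !is.finite(s)] <- 1
      Xtr_r <- sweep(Xtr_r, 2, s, "/")
      Xte_r <- sweep(Xte_r, 2, s, "/")
      sv <- svd(Xtr_r)
      keep <- sv$d > max(sv$d[1], 0) * 1e-12 & sv$d > 0
      fp$d <- sv$d[keep]
      fp$U <- sv$u[, keep, drop = FALSE]
      fp$G <- Xte_r %*% sv$v[, keep, drop = FALSE]
    } else {
      fp$d <- numeric(0)
    }
    prep[[k]] <- fp
  }
  list(folds = prep, K = folds$K, grid = grid, n = nrow(X))
}

# Apply a prepared CV engine to a matrix of outcome columns. Returns
# list(rss = per-column CV RSS, lambda_index = K x C chosen grid ids).
cv_apply <- function(prep, Y) {
  Y <- as.matrix(Y)
  vb_check(nrow(Y) == prep$n, "outcomes must match the prepared design rows",
           "alignment")
  grid <- prep$grid
  C <- ncol(Y)
  total <- numeric(C)
  lam_idx <- matrix(NA_integer_, prep$K, C)
  for (k in seq_len(prep$K)) {
    fp <- prep$folds[[k]]
    if (is.null(fp)) next
    gam <- qr.coef(fp$qz, Y[fp$tr, , drop = FALSE])
    gam[is.na(gam)] <- 0
    gam <- matrix(gam, ncol = C)
    Ytr_r <- Y[fp$tr, , drop = FALSE] - fp$Z1_tr %*% gam
    Yte_res <- Y[fp$te, , drop = FALSE] - fp$Z1_te %*% gam
    if (length(fp$d) == 0) {  # no penalized block: nuisance-only prediction
      total <- total + colSums(Yte_res^2)
      lam_idx[k, ] <- length(grid)
      next
    }
    W <- crossprod(fp$U, Ytr_r)
    gcv <- gcv_scores(fp$d, W, colSums(Ytr_r^2), grid, fp$ntr, df0 = fp$q)
    idx <- pick_lambda(gcv)
    sse <- matrix(NA_real_, length(grid), C)
    for (li in sort(unique(idx))) {
      shrink <- fp$d / (fp$d^2 + grid[li])
      cols <- which(idx == li)
      pred <- fp$G %*% (W[, cols, drop = FALSE] * shrink)
      sse[li, cols] <- colSums((Yte_res[, cols, drop = FALSE] - pred)^2)
    }
    total <- total + sse[cbind(idx, seq_len(C))]
    lam_idx[k, ] <- idx
  }
  list(rss = total, lambda_index = lam_idx)
}

# One-shot convenience wrapper around cv_prepare + cv_apply.
cv_rss_engine <- function(X, Y, folds, grid = lambda_grid(), nuisance = NULL) {
  cv_apply(cv_prepare(X, folds, grid, nuisance), Y)
}

#' Cross-validated residual sum of squares
#'
#' Computes the K-fold cross-validated RSS of a ridge regression of \code{y}
#' on \code{X}: within each fold, column standardization and penalty selection
#' use only the training nine-tenths, and squared prediction errors are
#' accumulated on the held-out tenth until every subject has been predicted
#' once. Cross-validation is what protects the downstream RSS-ratio statistic
#' from overfitting when pure-noise predictors are added.
#'
#' @param X design matrix (raw scale; standardized per training fold).
#' @param y outcome vector.
#' @param folds a [make_folds()] assignment covering all subjects.
#' @param lambda_rule \code{"gcv"} (default: generalized cross-validation on
#'   each training fold) or \code{"fixed"}.
#' @param grid candidate penalties for \code{"gcv"}.
#' @param lambda fixed penalty for \code{"fixed"}.
#' @return The cross-validated RSS (a single nonnegative number).
#' @export
cv_rss <- function(X, y, folds, lambda_rule = c("gcv", "fixed"),
                   grid = lambda_grid(), lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  if (lambda_rule == "fixed") {
    vb_check(!is.null(lambda), "lambda_rule = 'fixed' needs lambda", "parameter")
    grid <- lambda
  }
  cv_rss_engine(X, cbind(y), folds, grid)$rss[1]
}

#' Select a ridge penalty by K-fold cross-validation
#'
#' Returns the grid value minimizing the K-fold CV RSS, with ties broken
#' toward the larger (more conservative) penalty. For a constant outcome all
#' penalties tie and the largest is returned.
#'
#' @param X design matrix.
#' @param y outcome vector.
#' @param folds a [make_folds()] assignment.
#' @param grid nonempty vector of nonnegative candidate penalties.
#' @return The selected penalty (an element of \code{grid}).
#' @export
select_lambda <- function(X, y, folds, grid = lambda_grid()) {
  vb_check(length(grid) >= 1 && all(grid >= 0), "grid must be nonempty, all >= 0",
           "parameter")
  X <- as.matrix(X)
  grid <- sort(grid)
  sse <- numeric(length(grid))
  labels <- folds$labels
  for (k in seq_len(folds$K)) {
    te <- which(labels == k)
    tr <- which(labels != k)
    if (length(te) == 0) next
    std <- train_standardizer(X[tr, , drop = FALSE])
    Xtr <- std$apply(X[tr, , drop = FALSE])
    Xte <- std$apply(X[te, , drop = FALSE])
    sv <- svd(Xtr)
    keep <- sv$d > max(sv$d[1], 0) * 1e-12 & sv$d > 0
    d <- sv$d[keep]
    U <- sv$u[, keep, drop = FALSE]
    G <- Xte %*% sv$v[, keep, drop = FALSE]
    muY <- mean(y[tr])
    w <- as.numeric(crossprod(U, y[tr] - muY))
    for (li in seq_along(grid)) {
      pred <- if (length(d)) as.numeric(G %*% (w * d / (d^2 + grid[li]))) else 0
      sse[li] <- sse[li] + sum((y[te] - muY - pred)^2)
    }
  }
  # largest lambda among (near-)minimizers: exact ties only
  best <- min(sse)
  grid[max(which(sse == best))]
}
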