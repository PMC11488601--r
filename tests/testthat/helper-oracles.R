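# Independent brute-force oracles, deliberately coded with different
# algorithms (flood-fill queues, normal-equation solves) than the package.

# Flood-fill component labeling over a logical 3-D array.
oracle_label <- function(in_set, connectivity = 26) {
  dims <- dim(in_set)
  labels <- array(0L, dims)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(offsets != 0) > 0, , drop = FALSE]
  manh <- rowSums(abs(offsets))
  offsets <- switch(as.character(connectivity),
                    "6" = offsets[manh == 1, , drop = FALSE],
                    "18" = offsets[manh <= 2, , drop = FALSE],
                    "26" = offsets)
  lab <- 0L
  for (idx in which(in_set)) {
    if (labels[idx] != 0L) next
    lab <- lab + 1L
    queue <- list(arrayInd(idx, dims)[1, ])
    labels[idx] <- lab
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (r in seq_len(nrow(offsets))) {
        nb <- cur + offsets[r, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (in_set[nb[1], nb[2], nb[3]] && labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- lab
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  labels
}

# Triple-loop TFCE: for every voxel, walk the thresholds and add
# extent^E * h^H * dh using oracle_label at each threshold.
oracle_tfce <- function(stat, E, H, dh, connectivity) {
  dims <- dim(stat)
  s <- stat
  s[!is.finite(s)] <- 0
  out <- array(0, dims)
  mx <- max(s)
  if (mx <= 0) return(out)
  nsteps <- floor(mx / dh + 1e-12)
  for (step in seq_len(nsteps)) {
    h <- step * dh
    labels <- oracle_label(s >= h, connectivity)
    if (max(labels) == 0) next
    sizes <- tabulate(labels[labels > 0])
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
      l <- labels[i, j, k]
      if (l > 0) out[i, j, k] <- out[i, j, k] + sizes[l]^E * h^H * dh
    }
  }
  out
}

# Naive cross-validated RSS: explicit per-fold loops, normal-equation ridge
# solves, and hat-matrix-trace GCV. Mirrors the CV contract (standardization
# and penalty selection strictly inside the training part) with none of the
# SVD machinery.
oracle_cv_rss <- function(X, y, fold_labels, grid) {
  X <- as.matrix(X)
  total <- 0
  for (k in sort(unique(fold_labels))) {
    te <- which(fold_labels == k)
    tr <- which(fold_labels != k)
    m <- colMeans(X[tr, , drop = FALSE])
    s <- apply(X[tr, , drop = FALSE], 2, sd)
    s[s == 0] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], center = m, scale = s)
    Xte <- scale(X[te, , drop = FALSE], center = m, scale = s)
    mu <- mean(y[tr])
    ytr <- y[tr] - mu
    ntr <- length(tr)
    best <- NULL
    best_gcv <- Inf
    for (lam in grid) {
      A <- crossprod(Xtr) + diag(lam, ncol(Xtr))
      beta <- tryCatch(solve(A, crossprod(Xtr, ytr)), error = function(e) NULL)
      if (is.null(beta)) next
      Hmat <- Xtr %*% solve(A, t(Xtr))
      df <- sum(diag(Hmat)) + 1
      rss <- sum((ytr - Xtr %*% beta)^2)
      gcv <- if (df < ntr - 1e-8) ntr * rss / (ntr - df)^2 else Inf
      if (gcv <= best_gcv) {  # <=: ties go to the larger lambda (grid ascending)
        best_gcv <- gcv
        best <- beta
      }
    }
    pred <- mu + Xte %*% best
    total <- total + sum((y[te] - pred)^2)
  }
  total
}

# Benjamini-Hochberg step-up done by hand: largest k with p_(k) <= alpha*k/m.
oracle_bh_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0, which(ps <= alpha * seq_len(m) / m)))
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}
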