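## Independent oracles used by the tests. These deliberately share no code
## with the package's own estimators.

## LAD as a linear program, solved by a dense tableau simplex with Bland's
## rule. minimize sum(u + v) s.t. X(b+ - b-) + u - v = y, u, v, b+, b- >= 0.
## The initial basis {u_i if y_i >= 0 else v_i} is feasible, so no phase I.
lad_lp_oracle <- function(X, y, offset = NULL, tol = 1e-9, max_iter = 50000) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  yy <- y - (if (is.null(offset)) 0 else offset)
  A <- cbind(X, -X, diag(n), -diag(n))
  cost <- c(rep(0, 2 * p), rep(1, 2 * n))
  s <- ifelse(yy >= 0, 1, -1)
  Tb <- A * s
  xb <- abs(yy)
  basis <- ifelse(yy >= 0, 2 * p + seq_len(n), 2 * p + n + seq_len(n))
  for (it in seq_len(max_iter)) {
    z <- cost - drop(cost[basis] %*% Tb)
    enter <- which(z < -tol)
    if (!length(enter)) break
    j <- enter[1]                                  # Bland entering
    col <- Tb[, j]
    pos <- which(col > tol)
    if (!length(pos)) stop("LP unbounded; impossible for LAD")
    ratio <- xb[pos] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + 1e-12]
    i <- cand[which.min(basis[cand])]              # Bland leaving
    piv <- Tb[i, j]
    Tb[i, ] <- Tb[i, ] / piv
    xb[i] <- xb[i] / piv
    for (r in seq_len(n)) {
      if (r != i && Tb[r, j] != 0) {
        f <- Tb[r, j]
        Tb[r, ] <- Tb[r, ] - f * Tb[i, ]
        xb[r] <- xb[r] - f * xb[i]
        if (xb[r] < 0 && xb[r] > -1e-9) xb[r] <- 0
      }
    }
    basis[i] <- j
  }
  list(objective = sum(cost[basis] * xb))
}

## Exhaustive vertex enumeration: an LAD optimum interpolates p data points.
lad_enum_oracle <- function(X, y, offset = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  yy <- y - (if (is.null(offset)) 0 else offset)
  best <- Inf
  subsets <- utils::combn(n, p)
  for (j in seq_len(ncol(subsets))) {
    S <- subsets[, j]
    b <- tryCatch(solve(X[S, , drop = FALSE], yy[S]), error = function(e) NULL)
    if (is.null(b) || any(!is.finite(b))) next
    best <- min(best, sum(abs(yy - drop(X %*% b))))
  }
  best
}

## O(n^2) concordance by direct pair enumeration in plain R.
c_index_oracle <- function(y, yhat, tie_policy = "as_printed") {
  n <- length(y)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (yhat[i] == yhat[j]) next
      den <- den + 1
      pr <- (yhat[i] - yhat[j]) * (y[i] - y[j])
      if (pr > 0) num <- num + 1
      else if (y[i] == y[j] && tie_policy == "half_credit") num <- num + 0.5
    }
  }
  num / den
}

## Grid search for the intercept-only LAD minimizer (CL oracle).
cl_grid_oracle <- function(res, grid = NULL) {
  if (is.null(grid)) grid <- sort(unique(res))   # optimum sits at a data point
  obj <- vapply(grid, function(a) sum(abs(res - a)), numeric(1))
  list(minimum = grid[which.min(obj)], objective = min(obj))
}
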