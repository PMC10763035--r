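#' Configure chained-equation multiple imputation
#'
#' Defaults mirror a full registry analysis — 100 imputed datasets with 100
#' chained-equation sweeps each; smaller `m`/`iterations` are appropriate
#' at test scale. Continuous columns are imputed by predictive mean
#' matching (PMM), categorical columns by bootstrap polytomous regression.
#' Outcome (EPIC-26 score) columns belong on the `never_impute` list: they
#' are left bit-identical and excluded from the conditional models.
#'
#' @param m Number of imputed datasets (default 100).
#' @param iterations Chained-equation sweeps per dataset (default 100).
#' @param pmm_donors Donor-pool size k for PMM (default 5).
#' @param seed Integer seed; dataset d uses the stream seeded `seed + d`.
#' @param imputable Allow-list of columns that may be imputed.
#' @param never_impute Columns that must pass through untouched.
#' @param predictors Columns used in the conditional models; default: all
#'   columns except ids, `never_impute` and non-allow-listed incomplete
#'   columns.
#' @param id_cols Identifier columns ignored by the models.
#' @return Object of class `promval_imputation_config`.
#' @export
imputation_config <- function(m = 100, iterations = 100, pmm_donors = 5,
                              seed = 1L,
                              imputable = c("psa", "general_health", "age_dx"),
                              never_impute = character(),
                              predictors = NULL,
                              id_cols = "subject_id") {
  if (m < 1) stop_config("m", "must be >= 1")
  if (iterations < 1) stop_config("iterations", "must be >= 1")
  if (pmm_donors < 1) stop_config("pmm_donors", "must be >= 1")
  overlap <- intersect(imputable, never_impute)
  if (length(overlap)) {
    stop_config("never_impute", sprintf("'%s' is both imputable and never-impute",
                                        overlap[1]))
  }
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 pmm_donors = as.integer(pmm_donors), seed = as.integer(seed),
                 imputable = imputable, never_impute = never_impute,
                 predictors = predictors, id_cols = id_cols),
            class = "promval_imputation_config")
}

## Design matrix from predictor columns, characters as factors; returns a
## full-rank numeric matrix (aliased columns dropped via pivoted QR).
impute_design <- function(tab, cols) {
  if (!length(cols)) return(matrix(1, nrow(tab), 1, dimnames = list(NULL, "(Intercept)")))
  df <- tab[cols]
  for (cn in names(df)) if (is.character(df[[cn]])) df[[cn]] <- factor(df[[cn]])
  ## constant factors (e.g. a single-treatment cohort) carry no information
  ## and break the contrast machinery
  keep <- vapply(df, function(x) !is.factor(x) || nlevels(droplevels(x)) >= 2L,
                 logical(1))
  df <- df[keep]
  if (!ncol(df)) return(matrix(1, nrow(tab), 1, dimnames = list(NULL, "(Intercept)")))
  df[] <- lapply(df, function(x) if (is.factor(x)) droplevels(x) else x)
  X <- stats::model.matrix(~ ., data = df)
  q <- qr(X)
  X[, q$pivot[seq_len(q$rank)], drop = FALSE]
}

#' Predictive-mean-matching imputation for one column
#'
#' Fits a Bayesian-perturbed linear regression of the observed values on
#' the observed design, draws coefficients from their posterior, and for
#' each missing row returns the *observed* value of a donor sampled
#' uniformly from the `k` observed cases with closest predicted values
#' (type-1 matching: drawn-coefficient predictions for missing rows against
#' least-squares predictions for observed rows). Equal match distances
#' break toward the lowest observed-row index when forming the donor pool.
#' Imputed values are always members of the observed-value set.
#'
#' @param y_obs Observed values.
#' @param X_obs,X_mis Design matrices of observed and missing rows.
#' @param k Donor-pool size; must not exceed `length(y_obs)`.
#' @return Vector of `nrow(X_mis)` imputed values. Uses the current RNG
#'   stream.
#' @export
pmm_impute <- function(y_obs, X_obs, X_mis, k = 5) {
  X_obs <- as.matrix(X_obs); X_mis <- as.matrix(X_mis)
  n_obs <- length(y_obs)
  if (k > n_obs) stop(sprintf("k = %d donors exceed %d observed cases", k, n_obs),
                      call. = FALSE)
  q <- qr(X_obs)
  keep <- q$pivot[seq_len(q$rank)]
  X_o <- X_obs[, keep, drop = FALSE]
  X_m <- X_mis[, keep, drop = FALSE]
  fit <- stats::lm.fit(X_o, y_obs)
  beta_hat <- fit$coefficients
  res <- fit$residuals
  df <- max(n_obs - q$rank, 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  XtX <- crossprod(X_o)
  R <- tryCatch(chol(XtX), error = function(e) chol(XtX + diag(1e-8, ncol(XtX))))
  beta_star <- beta_hat + backsolve(R, stats::rnorm(ncol(X_o))) * sqrt(sigma2)
  pred_o <- drop(X_o %*% beta_hat)
  pred_m <- drop(X_m %*% beta_star)
  vapply(pred_m, function(pm) {
    d <- abs(pred_o - pm)
    pool <- order(d, seq_along(d))[seq_len(k)]
    y_obs[pool[sample.int(k, 1L)]]
  }, numeric(1))
}

## Bootstrap polytomous regression imputation for a categorical column.
polyreg_impute <- function(y_obs, X_obs, X_mis) {
  y_obs <- factor(y_obs)
  n_obs <- length(y_obs)
  idx <- sample.int(n_obs, n_obs, replace = TRUE)
  yb <- droplevels(y_obs[idx])
  if (nlevels(yb) < 2L) {
    return(rep(as.character(yb[1]), nrow(X_mis)))
  }
  Xb <- X_obs[idx, -1, drop = FALSE]
  Xm <- X_mis[, -1, drop = FALSE]
  vn <- paste0("x", seq_len(ncol(Xb)))  # syntactic names for the formula interface
  colnames(Xb) <- vn
  dfb <- data.frame(.y = yb, Xb, check.names = FALSE)
  fit <- nnet::multinom(.y ~ ., data = dfb, trace = FALSE,
                        maxit = 200, MaxNWts = 5000)
  colnames(Xm) <- vn
  newd <- as.data.frame(Xm)
  pr <- stats::predict(fit, newdata = newd, type = "probs")
  if (is.null(dim(pr))) {
    ## predict() drops to a vector for 2 classes or a single missing row
    pr <- if (nlevels(yb) == 2L) cbind(1 - pr, pr) else matrix(pr, nrow = 1L)
  }
  levs <- levels(yb)
  apply(pr, 1L, function(p) {
    p <- pmax(p, 0); p <- p / sum(p)
    levs[sample.int(length(levs), 1L, prob = p)]
  })
}

#' Multiple imputation by chained equations
#'
#' Produces `config$m` completed copies of `table`. Each dataset starts
#' from random hot-deck fills and runs `config$iterations` sweeps; each
#' sweep re-imputes every allow-listed incomplete column from a conditional
#' model on the other predictors (PMM for numeric columns, bootstrap
#' polytomous regression for categorical ones), fitted on the originally
#' observed rows. Observed cells are never altered, `never_impute` columns
#' pass through bit-identical, and a missing column outside the allow-list
#' is left untouched with a warning. Deterministic given `config$seed`,
#' with an independent stream per dataset.
#'
#' @param table Data frame to complete.
#' @param config An [imputation_config()].
#' @return List of `m` completed data frames (attribute `"config"` keeps
#'   the configuration).
#' @export
impute_chained <- function(table, config = imputation_config()) {
  stopifnot(inherits(config, "promval_imputation_config"))
  has_na <- names(table)[vapply(table, anyNA, logical(1))]
  stray <- setdiff(has_na, c(config$imputable, config$never_impute))
  if (length(stray)) {
    warning(sprintf("column(s) %s have missing values but are not allow-listed; left unimputed",
                    paste(sQuote(stray), collapse = ", ")), call. = FALSE)
  }
  targets <- intersect(config$imputable, has_na)
  for (col in targets) {
    if (all(is.na(table[[col]]))) {
      stop(sprintf("column '%s' has no observed values (empty donor pool)", col),
           call. = FALSE)
    }
  }
  predictors <- config$predictors %||%
    setdiff(names(table), c(config$id_cols, config$never_impute, stray))
  complete_predictors <- setdiff(predictors, targets)
  if (length(targets) && !length(complete_predictors)) {
    stop("no fully observed column available to seed the conditional models",
         call. = FALSE)
  }

  mis_idx <- lapply(table[targets], function(x) which(is.na(x)))
  names(mis_idx) <- targets

  out <- vector("list", config$m)
  for (d in seq_len(config$m)) {
    set.seed(config$seed + d)
    tab <- table
    if (length(targets)) {
      for (col in targets) {
        obs <- table[[col]][!is.na(table[[col]])]
        mi <- mis_idx[[col]]
        tab[[col]][mi] <- sample(obs, length(mi), replace = TRUE)
      }
      for (it in seq_len(config$iterations)) {
        for (col in targets) {
          mi <- mis_idx[[col]]
          obs_rows <- setdiff(seq_len(nrow(tab)), mi)
          X <- impute_design(tab, setdiff(predictors, col))
          y_obs <- table[[col]][obs_rows]
          if (is.numeric(table[[col]])) {
            k <- min(config$pmm_donors, length(obs_rows))
            tab[[col]][mi] <- pmm_impute(y_obs, X[obs_rows, , drop = FALSE],
                                         X[mi, , drop = FALSE], k = k)
          } else {
            tab[[col]][mi] <- polyreg_impute(y_obs, X[obs_rows, , drop = FALSE],
                                             X[mi, , drop = FALSE])
          }
        }
      }
    }
    out[[d]] <- tab
  }
  attr(out, "config") <- config
  out
}
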