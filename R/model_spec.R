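## Known predictor terms and how they bind to analysis-table columns.
## "months" is the continuous time-post-treatment term; "timepoint" is the
## per-timepoint indicator alternative -- a model may use either basis.
.numeric_terms <- c(baseline = "baseline", age_dx = "age_dx", psa = "psa",
                    months = "months_post_surgery")
.categorical_terms <- c(treatment = "treatment", race = "race",
                        gleason = "gleason", general_health = "general_health",
                        timepoint = "timepoint")
.term_order <- c("months", "timepoint", "treatment", "age_dx", "race",
                 "baseline", "general_health", "psa", "gleason")

#' Construct a linear prediction-model specification
#'
#' A model is an intercept plus a linear combination of numeric terms
#' (`baseline`, `age_dx`, `psa`, `months`) and categorical terms
#' (`treatment`, `race`, `gleason`, `general_health`, `timepoint`), each
#' categorical with a reference level (contributing 0) and per-level offsets
#' in score units. Predictions are in EPIC-26 score units and are *not*
#' clipped to \[0, 100\] unless `clip_predictions` is set: validation
#' statistics should see the model as published.
#'
#' @param domain Domain label (free text; the five EPIC-26 domains in practice).
#' @param intercept Intercept, score units.
#' @param terms Named list. Numeric terms map to a single coefficient;
#'   categorical terms to `list(ref = <level>, levels = c(level = coef, ...))`.
#' @param clip_predictions Clamp predictions to \[0, 100\]? Default `FALSE`.
#' @return Object of class `promval_model`.
#' @export
model_spec <- function(domain, intercept, terms = list(), clip_predictions = FALSE) {
  known <- c(names(.numeric_terms), names(.categorical_terms))
  bad <- setdiff(names(terms), known)
  if (length(bad)) {
    stop(sprintf("unknown predictor '%s' (known: %s)", bad[1],
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  if (is.null(names(terms)) && length(terms)) {
    stop("terms must be a named list", call. = FALSE)
  }
  for (tn in names(terms)) {
    t <- terms[[tn]]
    if (tn %in% names(.numeric_terms)) {
      if (!is.numeric(t) || length(t) != 1L || !is.finite(t)) {
        stop(sprintf("coefficient for numeric term '%s' must be a single finite number", tn),
             call. = FALSE)
      }
      terms[[tn]] <- as.numeric(t)
    } else {
      if (is.null(t$ref)) {
        stop(sprintf("categorical term '%s' is missing its reference level", tn),
             call. = FALSE)
      }
      lev <- unlist(t$levels)
      if (length(lev) && (is.null(names(lev)) || any(!nzchar(names(lev))))) {
        stop(sprintf("categorical term '%s' has unnamed levels", tn), call. = FALSE)
      }
      if (length(lev) && !is.numeric(lev)) {
        stop(sprintf("non-numeric coefficient in categorical term '%s'", tn), call. = FALSE)
      }
      if (t$ref %in% names(lev)) {
        stop(sprintf("reference level '%s' of term '%s' must not carry a coefficient",
                     t$ref, tn), call. = FALSE)
      }
      terms[[tn]] <- list(ref = as.character(t$ref),
                          levels = if (length(lev)) {
                            lev <- stats::setNames(as.numeric(lev), names(lev))
                            lev[order(names(lev))]
                          } else stats::setNames(numeric(0), character(0)))
    }
  }
  terms <- terms[intersect(.term_order, names(terms))]
  structure(list(domain = as.character(domain),
                 intercept = as.numeric(intercept),
                 terms = terms,
                 clip_predictions = isTRUE(clip_predictions)),
            class = "promval_model")
}

#' @export
print.promval_model <- function(x, ...) {
  cat(sprintf("<promval_model> domain=%s intercept=%g terms=%s clip=%s\n",
              x$domain, x$intercept, paste(names(x$terms), collapse = ","),
              x$clip_predictions))
  invisible(x)
}

model_to_list <- function(m) {
  terms <- lapply(m$terms, function(t) {
    if (is.list(t)) list(ref = t$ref, levels = as.list(t$levels)) else t
  })
  list(domain = m$domain, intercept = m$intercept,
       clip_predictions = m$clip_predictions, terms = terms)
}

#' Read / write model specifications (YAML)
#'
#' A file holds either a single model or a `models:` list. Writing is
#' canonical (terms in a fixed order, categorical levels sorted), so
#' write-load-write round-trips byte-identically.
#'
#' @param path YAML file path.
#' @return `read_model_spec()`: one `promval_model`; `read_model_specs()`:
#'   a named list of them (by domain).
#' @export
read_model_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$models)) {
    stop(sprintf("'%s' holds multiple models; use read_model_specs()", path),
         call. = FALSE)
  }
  list_to_model(raw, path)
}

#' @rdname read_model_spec
#' @export
read_model_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- if (!is.null(raw$models)) raw$models else list(raw)
  models <- lapply(entries, list_to_model, path = path)
  stats::setNames(models, vapply(models, function(m) m$domain, character(1)))
}

list_to_model <- function(raw, path = "<model spec>") {
  for (f in c("domain", "intercept")) {
    if (is.null(raw[[f]])) {
      stop(sprintf("%s: missing field '%s'", path, f), call. = FALSE)
    }
  }
  if (!is.numeric(raw$intercept)) {
    stop(sprintf("%s: non-numeric intercept", path), call. = FALSE)
  }
  tryCatch(
    model_spec(raw$domain, raw$intercept, raw$terms %||% list(),
               isTRUE(raw$clip_predictions)),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
  )
}

#' @rdname read_model_spec
#' @param x A `promval_model` or a list of them.
#' @export
write_model_spec <- function(x, path) {
  if (inherits(x, "promval_model")) {
    yaml::write_yaml(model_to_list(x), path, precision = 15)
  } else {
    yaml::write_yaml(list(models = lapply(x, model_to_list)), path, precision = 15)
  }
  invisible(path)
}

#' Apply a prediction model to analysis-table rows
#'
#' Computes the linear predictor for each row of `table`. Rows must supply
#' every model term (run imputation first); a missing covariate raises an
#' error naming it. A missing `race` column or value defaults to the
#' reference-style `"White"` level, matching registries that do not record
#' race. Extra columns and column order are ignored.
#'
#' @param model A `promval_model`.
#' @param table Data frame with the columns the model's terms bind to
#'   (`baseline`, `age_dx`, `psa`, `months_post_surgery`, `treatment`,
#'   `race`, `gleason`, `general_health`, `timepoint` as needed).
#' @return Numeric vector of predicted scores, clipped iff the model says so.
#' @export
predict_score <- function(model, table) {
  stopifnot(inherits(model, "promval_model"))
  n <- nrow(table)
  yhat <- rep(model$intercept, n)
  for (tn in names(model$terms)) {
    t <- model$terms[[tn]]
    if (tn %in% names(.numeric_terms)) {
      col <- .numeric_terms[[tn]]
      v <- table[[col]]
      if (is.null(v) || anyNA(v)) {
        stop(sprintf("missing covariate '%s' (column '%s'); was imputation skipped?",
                     tn, col), call. = FALSE)
      }
      yhat <- yhat + t * as.numeric(v)
    } else {
      col <- .categorical_terms[[tn]]
      v <- table[[col]]
      if (tn == "race") {
        if (is.null(v)) v <- rep("White", n)
        v[is.na(v)] <- "White"
      }
      if (is.null(v) || anyNA(v)) {
        stop(sprintf("missing covariate '%s' (column '%s'); was imputation skipped?",
                     tn, col), call. = FALSE)
      }
      v <- as.character(v)
      unknown <- setdiff(unique(v), c(t$ref, names(t$levels)))
      if (length(unknown)) {
        stop(sprintf("unknown level '%s' for categorical term '%s'", unknown[1], tn),
             call. = FALSE)
      }
      contrib <- stats::setNames(c(0, t$levels), c(t$ref, names(t$levels)))
      yhat <- yhat + as.numeric(contrib[v])
    }
  }
  if (model$clip_predictions) yhat <- pmin(100, pmax(0, yhat))
  yhat
}
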