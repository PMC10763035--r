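#' EPIC-26 domains
#'
#' The five scored domains of the EPIC-26 instrument. Each domain score lies
#' in \[0, 100\] with higher values indicating better function.
#'
#' @export
epic26_domains <- function() {
  c("sexual", "urinary_incontinence", "urinary_irritation", "bowel", "hormonal")
}

## Item ids per domain for the reference scoring map: 4 + 4 + 6 + 6 + 5 scored
## items plus one overall urinary-function item that belongs to no domain = 26.
.epic26_items <- function() {
  list(
    ov_1 = list(domain = "overall",              n_levels = 5L, reversed = FALSE),
    ui_1 = list(domain = "urinary_incontinence", n_levels = 5L, reversed = TRUE),
    ui_2 = list(domain = "urinary_incontinence", n_levels = 4L, reversed = TRUE),
    ui_3 = list(domain = "urinary_incontinence", n_levels = 5L, reversed = FALSE),
    ui_4 = list(domain = "urinary_incontinence", n_levels = 5L, reversed = TRUE),
    uo_1 = list(domain = "urinary_irritation",   n_levels = 5L, reversed = TRUE),
    uo_2 = list(domain = "urinary_irritation",   n_levels = 5L, reversed = TRUE),
    uo_3 = list(domain = "urinary_irritation",   n_levels = 5L, reversed = TRUE),
    uo_4 = list(domain = "urinary_irritation",   n_levels = 4L, reversed = TRUE),
    bw_1 = list(domain = "bowel",                n_levels = 5L, reversed = TRUE),
    bw_2 = list(domain = "bowel",                n_levels = 5L, reversed = TRUE),
    bw_3 = list(domain = "bowel",                n_levels = 5L, reversed = TRUE),
    bw_4 = list(domain = "bowel",                n_levels = 4L, reversed = TRUE),
    bw_5 = list(domain = "bowel",                n_levels = 5L, reversed = TRUE),
    bw_6 = list(domain = "bowel",                n_levels = 5L, reversed = TRUE),
    sx_1 = list(domain = "sexual",               n_levels = 5L, reversed = FALSE),
    sx_2 = list(domain = "sexual",               n_levels = 5L, reversed = FALSE),
    sx_3 = list(domain = "sexual",               n_levels = 4L, reversed = FALSE),
    sx_4 = list(domain = "sexual",               n_levels = 5L, reversed = FALSE),
    sx_5 = list(domain = "sexual",               n_levels = 5L, reversed = FALSE),
    sx_6 = list(domain = "sexual",               n_levels = 5L, reversed = TRUE,
                six_q_only = TRUE),
    hm_1 = list(domain = "hormonal",             n_levels = 5L, reversed = TRUE),
    hm_2 = list(domain = "hormonal",             n_levels = 5L, reversed = TRUE),
    hm_3 = list(domain = "hormonal",             n_levels = 5L, reversed = TRUE),
    hm_4 = list(domain = "hormonal",             n_levels = 4L, reversed = TRUE),
    hm_5 = list(domain = "hormonal",             n_levels = 5L, reversed = TRUE)
  )
}

#' Reference EPIC-26 scoring map
#'
#' Builds the package's reference scoring map: 26 items, each with a domain
#' membership, an ordinal level count and a per-level linear transform onto
#' \[0, 100\]. "Reversed" items are those where a *lower* raw response level
#' denotes better function. One sexual item is flagged `six_q_only` and is
#' dropped under the 5-question sexual-domain variant. The map is a
#' stand-in reference (the licensed instrument is not redistributed); the
#' same structure can be loaded from an edited YAML file with
#' [load_scoring_map()].
#'
#' @return A list of class `promval_scoring_map`: one entry per item with
#'   fields `domain`, `values` (numeric, the 0-100 value of each response
#'   level `1..L`) and `six_q_only` (logical).
#' @export
epic26_default_map <- function() {
  items <- .epic26_items()
  map <- lapply(items, function(it) {
    v <- seq(0, 100, length.out = it$n_levels)
    if (it$reversed) v <- rev(v)
    list(domain = it$domain, values = v,
         six_q_only = isTRUE(it$six_q_only))
  })
  class(map) <- "promval_scoring_map"
  map
}

#' Load / write an EPIC-26 scoring map
#'
#' @param path Path to a YAML file with one entry per item:
#'   `domain`, `values` (per-level 0-100 values) and optional `six_q_only`.
#' @return A `promval_scoring_map`.
#' @export
load_scoring_map <- function(path) {
  raw <- yaml::read_yaml(path)
  map <- lapply(raw, function(it) {
    if (is.null(it$domain) || is.null(it$values)) {
      stop_config("scoring_map", "each item needs 'domain' and 'values'")
    }
    list(domain = it$domain, values = as.numeric(it$values),
         six_q_only = isTRUE(it$six_q_only))
  })
  names(map) <- names(raw)
  validate_scoring_map(map)
  class(map) <- "promval_scoring_map"
  map
}

#' @rdname load_scoring_map
#' @param map A `promval_scoring_map`.
#' @export
write_scoring_map <- function(map, path) {
  out <- lapply(unclass(map), function(it) {
    e <- list(domain = it$domain, values = as.numeric(it$values))
    if (isTRUE(it$six_q_only)) e$six_q_only <- TRUE
    e
  })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

validate_scoring_map <- function(map) {
  for (id in names(map)) {
    v <- map[[id]]$values
    if (any(!is.finite(v)) || any(v < 0 | v > 100)) {
      stop_config("scoring_map", sprintf("item '%s' has level values outside [0,100]", id))
    }
    if (length(v) < 2) {
      stop_config("scoring_map", sprintf("item '%s' needs at least 2 levels", id))
    }
  }
  invisible(map)
}

domain_items <- function(map, domain, sexual_variant = "5q") {
  ids <- names(map)[vapply(map, function(it) it$domain == domain, logical(1))]
  if (domain == "sexual" && sexual_variant == "5q") {
    ids <- ids[!vapply(map[ids], function(it) isTRUE(it$six_q_only), logical(1))]
  }
  ids
}

#' Score one EPIC-26 domain from item responses
#'
#' Each answered item is linearly rescaled to \[0, 100\] via the scoring map;
#' the domain score is the mean of the rescaled answered items. If fewer than
#' `min_complete` of the domain's items are answered the score is missing
#' (`NA`), the usual half/80-percent completeness convention for
#' multi-item PRO scales.
#'
#' @param responses Named vector/list of ordinal response levels (integers,
#'   `1..L` per item); unanswered items may be `NA` or absent.
#' @param domain One of [epic26_domains()].
#' @param map Scoring map, default [epic26_default_map()].
#' @param sexual_variant `"5q"` (default, drops the `six_q_only` item) or
#'   `"6q"` for the full sexual domain.
#' @param min_complete Minimum answered fraction of the domain's items
#'   (default 0.8) below which the score is `NA`.
#' @return Score in \[0, 100\], or `NA` if insufficiently complete.
#' @export
score_domain <- function(responses, domain, map = epic26_default_map(),
                         sexual_variant = c("5q", "6q"), min_complete = 0.8) {
  sexual_variant <- match.arg(sexual_variant)
  if (!domain %in% epic26_domains()) {
    stop_config("domain", sprintf("'%s' is not a scored EPIC-26 domain", domain))
  }
  ids <- domain_items(map, domain, sexual_variant)
  if (!length(ids)) stop_config("scoring_map", sprintf("no items for domain '%s'", domain))
  responses <- unlist(responses)
  vals <- rep(NA_real_, length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    if (!id %in% names(responses) || is.na(responses[[id]])) next
    lev <- responses[[id]]
    L <- length(map[[id]]$values)
    if (!is.finite(lev) || lev != round(lev) || lev < 1 || lev > L) {
      stop(sprintf("response for item '%s' out of range 1..%d: %s", id, L, format(lev)),
           call. = FALSE)
    }
    vals[j] <- map[[id]]$values[lev]
  }
  answered <- sum(!is.na(vals))
  if (answered / length(ids) < min_complete) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Score an EPIC-26 item-response table into per-domain scores
#'
#' @param items Data frame with columns `subject_id`, `item_id`, `response`.
#' @inheritParams score_domain
#' @return Data frame: `subject_id` plus one column per domain.
#' @export
score_epic26 <- function(items, map = epic26_default_map(),
                         sexual_variant = c("5q", "6q"), min_complete = 0.8) {
  sexual_variant <- match.arg(sexual_variant)
  stopifnot(all(c("subject_id", "item_id", "response") %in% names(items)))
  subjects <- unique(items$subject_id)
  doms <- epic26_domains()
  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (d in doms) out[[d]] <- NA_real_
  for (i in seq_along(subjects)) {
    rows <- items[items$subject_id == subjects[i], ]
    resp <- stats::setNames(rows$response, rows$item_id)
    for (d in doms) {
      out[i, d] <- score_domain(resp, d, map, sexual_variant, min_complete)
    }
  }
  out
}

## Inverse-scoring helper for tests: pick, per item of a domain, the response
## level whose rescaled value is closest to the target score. Recovers the
## target exactly only when it matches an attainable item-mean.
epic26_responses_for_score <- function(score, domain, map = epic26_default_map(),
                                       sexual_variant = "5q") {
  ids <- domain_items(map, domain, sexual_variant)
  resp <- vapply(ids, function(id) which.min(abs(map[[id]]$values - score)), integer(1))
  stats::setNames(as.integer(resp), ids)
}
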