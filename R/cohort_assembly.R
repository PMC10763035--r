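#' Configure cohort assembly
#'
#' Inclusion windows and exclusion thresholds for building per-timepoint
#' validation cohorts: post-surgery questionnaires within 8-16 months define
#' the 1-year cohort and 20-28 months the 2-year cohort (both ends
#' inclusive), with exclusions for adjunct therapy (ADT, brachytherapy,
#' cryoablation), age > 80, PSA >= 50 and non-localized disease.
#'
#' @param target_months Target months of the validation timepoints.
#' @param windows Named list mapping each target month to `c(low, high)`.
#' @param max_age Exclude subjects with age at diagnosis strictly above this.
#' @param max_psa Exclude subjects with PSA at or above this (missing PSA
#'   does not exclude; it is imputed later).
#' @param treatments Treatments retained (default `"RP"`).
#' @return Object of class `promval_assembly_config`.
#' @export
assembly_config <- function(target_months = c(12, 24),
                            windows = list("12" = c(8, 16), "24" = c(20, 28)),
                            max_age = 80, max_psa = 50, treatments = "RP") {
  for (m in target_months) {
    w <- windows[[as.character(m)]]
    if (is.null(w)) stop_config("windows", sprintf("no window for target month %s", m))
    if (!(w[1] < m && m < w[2])) {
      stop_config("windows", sprintf("window [%s, %s] must bracket target %s", w[1], w[2], m))
    }
  }
  structure(list(target_months = target_months, windows = windows,
                 max_age = max_age, max_psa = max_psa, treatments = treatments),
            class = "promval_assembly_config")
}

#' Apply the study exclusion criteria
#'
#' A subject is excluded iff any criterion holds: androgen deprivation
#' therapy, brachytherapy, cryoablation, age > `max_age`, PSA >=
#' `max_psa`, non-localized disease, or a treatment outside
#' `treatments`. Missing fields never trigger their criterion (missing PSA
#' in particular passes through for later imputation). All triggered
#' reasons are logged per subject.
#'
#' @param subjects Subjects table (see [generate_cohort()]).
#' @param config An [assembly_config()].
#' @return List: `subjects` (retained rows) and `log` (data frame
#'   `subject_id`, `reason`, one row per triggered reason).
#' @export
apply_exclusions <- function(subjects, config = assembly_config()) {
  stopifnot(inherits(config, "promval_assembly_config"))
  flag <- function(x) !is.na(x) & x
  reasons <- list(
    adt = flag(subjects$adt),
    brachytherapy = flag(subjects$brachytherapy),
    cryoablation = flag(subjects$cryoablation),
    age = !is.na(subjects$age_dx) & subjects$age_dx > config$max_age,
    psa = !is.na(subjects$psa) & subjects$psa >= config$max_psa,
    non_localized = !is.na(subjects$stage_localized) & !subjects$stage_localized,
    treatment = !is.na(subjects$treatment) & !(subjects$treatment %in% config$treatments)
  )
  log_rows <- list()
  for (r in names(reasons)) {
    hit <- which(reasons[[r]])
    if (length(hit)) {
      log_rows[[r]] <- data.frame(subject_id = subjects$subject_id[hit],
                                  reason = r, stringsAsFactors = FALSE)
    }
  }
  excluded <- Reduce(`|`, reasons)
  log <- if (length(log_rows)) do.call(rbind, log_rows) else {
    data.frame(subject_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(log) <- NULL
  list(subjects = subjects[!excluded, , drop = FALSE], log = log)
}

#' Select the questionnaire closest to a target time
#'
#' Among a subject's visits with `months_post_surgery` inside
#' `[window[1], window[2]]` (inclusive), returns the row minimizing
#' `|months - target|`; ties break toward the earlier visit.
#'
#' @param visits Visit rows of one subject.
#' @param target Target month.
#' @param window `c(low, high)` inclusive bounds.
#' @return A single visit row, or `NULL` if no visit falls in the window.
#' @export
select_visit <- function(visits, target, window) {
  m <- visits$months_post_surgery
  in_win <- which(m >= window[1] & m <= window[2])
  if (!length(in_win)) return(NULL)
  d <- abs(m[in_win] - target)
  ## order() is stable; sorting on (distance, month) breaks exact-distance
  ## ties toward the earlier visit.
  pick <- in_win[order(d, m[in_win])][1]
  visits[pick, , drop = FALSE]
}

#' Build per-domain, per-timepoint analysis tables
#'
#' For each subject the baseline score per domain is the latest pre-surgery
#' questionnaire (months <= 0) on which the domain is non-missing; the
#' post-surgery score comes from the in-window visit selected by
#' [select_visit()]. A subject contributes one row per (domain, timepoint)
#' and is dropped from a domain only (never globally) when that domain's
#' baseline or outcome score is missing — missing domain scores are never
#' imputed. Every dropped subject is logged with a single reason
#' (`no_window_visit`, then `missing_baseline`, then `missing_outcome`), so
#' subjects partition exactly into included + dropped per (domain,
#' timepoint) — a flow-diagram invariant checked by [assembly_flow()].
#'
#' @param subjects Retained subjects (after [apply_exclusions()]).
#' @param visits Visits table.
#' @param config An [assembly_config()].
#' @param domains Domains to assemble.
#' @return Object of class `promval_assembly`: `tables` (nested list
#'   `tables[[domain]][[timepoint]]` of analysis rows), `drop_log`,
#'   `n_input`, `config`, `domains`.
#' @export
build_analysis_table <- function(subjects, visits, config = assembly_config(),
                                 domains = epic26_domains()) {
  stopifnot(inherits(config, "promval_assembly_config"))
  key <- paste(visits$subject_id, round(visits$months_post_surgery, 6))
  if (anyDuplicated(key)) {
    dup <- unique(visits$subject_id[duplicated(key)])
    stop(sprintf("duplicate (subject, month) visit rows for: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }

  vis_by_subj <- split(visits, visits$subject_id)
  tables <- stats::setNames(vector("list", length(domains)), domains)
  drop_rows <- list()
  for (d in domains) tables[[d]] <- list()

  for (target in config$target_months) {
    tp <- paste0(target, "m")
    window <- config$windows[[as.character(target)]]
    sel <- lapply(subjects$subject_id, function(sid) {
      v <- vis_by_subj[[sid]]
      if (is.null(v)) NULL else select_visit(v[v$months_post_surgery > 0, , drop = FALSE],
                                             target, window)
    })
    for (d in domains) {
      rows <- list()
      for (i in seq_len(nrow(subjects))) {
        sid <- subjects$subject_id[i]
        post <- sel[[i]]
        if (is.null(post)) {
          drop_rows[[length(drop_rows) + 1L]] <- data.frame(
            subject_id = sid, domain = d, timepoint = tp,
            reason = "no_window_visit", stringsAsFactors = FALSE)
          next
        }
        v <- vis_by_subj[[sid]]
        pre <- v[v$months_post_surgery <= 0 & !is.na(v[[d]]), , drop = FALSE]
        if (!nrow(pre)) {
          drop_rows[[length(drop_rows) + 1L]] <- data.frame(
            subject_id = sid, domain = d, timepoint = tp,
            reason = "missing_baseline", stringsAsFactors = FALSE)
          next
        }
        pre <- pre[which.max(pre$months_post_surgery), , drop = FALSE]
        if (is.na(post[[d]])) {
          drop_rows[[length(drop_rows) + 1L]] <- data.frame(
            subject_id = sid, domain = d, timepoint = tp,
            reason = "missing_outcome", stringsAsFactors = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, domain = d, timepoint = tp,
          baseline = pre[[d]], observed = post[[d]],
          age_dx = subjects$age_dx[i], psa = subjects$psa[i],
          gleason = subjects$gleason[i],
          general_health = subjects$general_health[i],
          race = subjects$race[i], treatment = subjects$treatment[i],
          months_post_surgery = post$months_post_surgery,
          stringsAsFactors = FALSE)
      }
      tab <- if (length(rows)) do.call(rbind, rows) else NULL
      if (!is.null(tab)) rownames(tab) <- NULL
      tables[[d]][[tp]] <- tab
    }
  }
  drop_log <- if (length(drop_rows)) do.call(rbind, drop_rows) else {
    data.frame(subject_id = character(0), domain = character(0),
               timepoint = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(drop_log) <- NULL
  structure(list(tables = tables, drop_log = drop_log,
                 n_input = nrow(subjects), config = config, domains = domains),
            class = "promval_assembly")
}

#' Flow-diagram summary of an assembly
#'
#' Counts per (domain, timepoint): included rows and each drop reason.
#' `included + no_window_visit + missing_baseline + missing_outcome` equals
#' the number of input subjects for every cell.
#'
#' @param assembly A `promval_assembly`.
#' @return Data frame with columns `domain`, `timepoint`, `included`,
#'   `no_window_visit`, `missing_baseline`, `missing_outcome`, `n_input`.
#' @export
assembly_flow <- function(assembly) {
  stopifnot(inherits(assembly, "promval_assembly"))
  out <- list()
  for (d in assembly$domains) {
    for (tp in names(assembly$tables[[d]])) {
      tab <- assembly$tables[[d]][[tp]]
      dl <- assembly$drop_log
      dl <- dl[dl$domain == d & dl$timepoint == tp, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        domain = d, timepoint = tp,
        included = if (is.null(tab)) 0L else nrow(tab),
        no_window_visit = sum(dl$reason == "no_window_visit"),
        missing_baseline = sum(dl$reason == "missing_baseline"),
        missing_outcome = sum(dl$reason == "missing_outcome"),
        n_input = assembly$n_input, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
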