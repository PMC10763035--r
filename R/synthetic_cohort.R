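#' Default "true" generating models for the synthetic registry
#'
#' One linear model per EPIC-26 domain, used both as the generating truth of
#' the simulator and as the model under validation in the package's
#' null-case (parameter recovery) checks. Coefficients were fixed once so
#' that, under the default covariate distributions, mean post-surgery scores
#' sit near the registry-typical values (sexual ~34, urinary incontinence
#' ~75, urinary irritation ~92, bowel ~93, hormonal ~92 at one year), with a
#' continuous months-post-surgery time basis.
#'
#' @return Named list of [model_spec()] objects, one per domain.
#' @export
default_true_models <- function() {
  race <- function(black, hisp, asian, other) {
    list(ref = "White", levels = c(Black = black, Hispanic = hisp,
                                   Asian = asian, Other = other))
  }
  gh <- function(poor, fair, vg, exc) {
    list(ref = "Good", levels = c(Poor = poor, Fair = fair,
                                  "Very good" = vg, Excellent = exc))
  }
  gl <- function(a, b, c) {
    list(ref = "<=6", levels = c("3+4" = a, "4+3" = b, ">=8" = c))
  }
  list(
    sexual = model_spec("sexual", 36.2, list(
      months = -0.35, age_dx = -0.45, baseline = 0.55, psa = -0.15,
      gleason = gl(-2, -4, -7), general_health = gh(-8, -4, 3, 6),
      race = race(3, -1, -3.5, 1))),
    urinary_incontinence = model_spec("urinary_incontinence", 65.0, list(
      months = 0.1, age_dx = -0.5, baseline = 0.45, psa = -0.1,
      gleason = gl(-1, -2, -3), general_health = gh(-6, -3, 2, 4),
      race = race(-2, 1, 2, 8.5))),
    urinary_irritation = model_spec("urinary_irritation", 58.4, list(
      months = 0.05, age_dx = -0.15, baseline = 0.5, psa = -0.05,
      gleason = gl(-0.5, -1, -1.5), general_health = gh(-5, -2.5, 1.5, 3),
      race = race(1, -0.5, -1, 0.5))),
    bowel = model_spec("bowel", 57.1, list(
      months = 0.02, age_dx = -0.1, baseline = 0.45, psa = -0.05,
      gleason = gl(-0.5, -1, -2), general_health = gh(-7, -3.5, 2, 4),
      race = race(-1, 0.5, 1, -0.5))),
    hormonal = model_spec("hormonal", 51.8, list(
      months = 0.03, age_dx = -0.1, baseline = 0.5, psa = -0.1,
      gleason = gl(-1, -1.5, -2.5), general_health = gh(-9, -5, 2.5, 5),
      race = race(0.5, -1, -1.5, 1)))
  )
}

default_baseline_distribution <- function() {
  ## Two-part ceiling mixture per domain: point mass at 100 plus a normal
  ## truncated to [0, 100), matched to registry-typical pre-surgery
  ## means/medians (median 100 for incontinence/bowel/hormonal).
  list(
    sexual               = list(ceiling_weight = 0.08, mean = 58, sd = 28),
    urinary_incontinence = list(ceiling_weight = 0.55, mean = 85, sd = 11),
    urinary_irritation   = list(ceiling_weight = 0.30, mean = 81, sd = 13),
    bowel                = list(ceiling_weight = 0.55, mean = 87, sd = 9),
    hormonal             = list(ceiling_weight = 0.50, mean = 89, sd = 7)
  )
}

default_missingness <- function() {
  ## MAR rules: covariate missingness concentrated in PSA (~20%) and general
  ## health (~55%), both more likely at older ages; outcome scores go
  ## missing at registry-typical per-domain rates and are never imputed
  ## downstream.
  list(
    list(field = "age_dx", target = 0.02),
    list(field = "psa", target = 0.20, slopes = c(age_dx = 0.4)),
    list(field = "general_health", target = 0.55, slopes = c(age_dx = 0.4)),
    list(field = "sexual", target = 0.07, scope = "baseline"),
    list(field = "sexual", target = 0.15, scope = "post", slopes = c(age_dx = 0.3)),
    list(field = "urinary_incontinence", target = 0.03, scope = "baseline"),
    list(field = "urinary_incontinence", target = 0.10, scope = "post"),
    list(field = "urinary_irritation", target = 0.03, scope = "baseline"),
    list(field = "urinary_irritation", target = 0.03, scope = "post"),
    list(field = "bowel", target = 0.02, scope = "baseline"),
    list(field = "bowel", target = 0.02, scope = "post"),
    list(field = "hormonal", target = 0.05, scope = "baseline"),
    list(field = "hormonal", target = 0.08, scope = "post")
  )
}

#' Configure the synthetic registry-cohort generator
#'
#' Defaults emulate a prostatectomy PRO registry: age truncated-normal
#' 65.4 (6.3) on \[40, 80\]; PSA log-normal (meanlog 1.88, sdlog 0.5)
#' truncated below 50 ng/mL; Gleason categories 12/50/22/16 percent over
#' \{<=6, 3+4, 4+3, >=8\}; general health 1/2/40/45/12 percent over
#' \{Poor, ..., Excellent\}; ceiling-heavy baseline domain scores; scheduled
#' follow-up questionnaires at 3, 12 and 24 months with jittered timing and
#' imperfect response; and MAR missingness concentrated in PSA (~20%) and
#' general health (~55%). Outcome (domain score) missingness is applied
#' after outcome generation and such scores are never imputed downstream.
#'
#' @param n_subjects Number of subjects (default 750).
#' @param seed Integer RNG seed.
#' @param domains Subset of [epic26_domains()].
#' @param true_models Named list of [model_spec()]s, one per domain.
#' @param residual_sd Named non-negative residual SD per domain (score units).
#' @param baseline_distribution Per-domain `list(ceiling_weight, mean, sd)`.
#' @param covariates List with `age` (mean, sd, min, max), `psa` (meanlog,
#'   sdlog, max), `gleason` and `general_health` category probability
#'   vectors, and adjunct-therapy / stage probabilities `p_adt`,
#'   `p_brachytherapy`, `p_cryoablation`, `p_localized`.
#' @param missingness List of MAR rules (see [apply_missingness()]), or
#'   `NULL` for fully observed data.
#' @param visit_months Scheduled post-surgery questionnaire months.
#' @param visit_jitter_sd SD (months) of timing jitter around each schedule.
#' @param response_prob Response probability per post-surgery questionnaire.
#' @param baseline_response_prob Response probability for the pre-surgery
#'   questionnaire.
#' @return Object of class `promval_sim_config`.
#' @export
simulation_config <- function(n_subjects = 750,
                              seed = 1L,
                              domains = epic26_domains(),
                              true_models = default_true_models(),
                              residual_sd = c(sexual = 22,
                                              urinary_incontinence = 20,
                                              urinary_irritation = 10,
                                              bowel = 9, hormonal = 9),
                              baseline_distribution = default_baseline_distribution(),
                              covariates = list(
                                age = list(mean = 65.4, sd = 6.3, min = 40, max = 80),
                                psa = list(meanlog = 1.88, sdlog = 0.5, max = 50),
                                gleason = c("<=6" = 0.12, "3+4" = 0.50,
                                            "4+3" = 0.22, ">=8" = 0.16),
                                general_health = c(Poor = 0.01, Fair = 0.02,
                                                   Good = 0.40, "Very good" = 0.45,
                                                   Excellent = 0.12),
                                p_adt = 0.03, p_brachytherapy = 0.01,
                                p_cryoablation = 0.005, p_localized = 0.97),
                              missingness = default_missingness(),
                              visit_months = c(3, 12, 24),
                              visit_jitter_sd = 1.5,
                              response_prob = 0.85,
                              baseline_response_prob = 0.92) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop_config("n_subjects", "must be a positive integer")
  }
  bad <- setdiff(domains, epic26_domains())
  if (length(bad)) stop_config("domains", sprintf("unknown domain '%s'", bad[1]))
  for (d in domains) {
    if (is.null(true_models[[d]])) stop_config("true_models", sprintf("no model for domain '%s'", d))
    if (is.na(residual_sd[d]) || residual_sd[d] < 0) {
      stop_config("residual_sd", sprintf("domain '%s' needs a non-negative SD", d))
    }
    bd <- baseline_distribution[[d]]
    if (is.null(bd)) stop_config("baseline_distribution", sprintf("missing domain '%s'", d))
    if (bd$ceiling_weight < 0 || bd$ceiling_weight > 1) {
      stop_config("baseline_distribution", sprintf("'%s' ceiling_weight outside [0,1]", d))
    }
  }
  for (nm in c("gleason", "general_health")) {
    pr <- covariates[[nm]]
    if (any(pr < 0 | pr > 1) || abs(sum(pr) - 1) > 1e-8) {
      stop_config(nm, "category probabilities must lie in [0,1] and sum to 1")
    }
  }
  if (any(visit_months <= 0)) stop_config("visit_months", "must be positive")
  for (p in c(response_prob, baseline_response_prob)) {
    if (p < 0 || p > 1) stop_config("response_prob", "must lie in [0,1]")
  }
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 domains = domains, true_models = true_models[domains],
                 residual_sd = residual_sd,
                 baseline_distribution = baseline_distribution,
                 covariates = covariates, missingness = missingness,
                 visit_months = visit_months, visit_jitter_sd = visit_jitter_sd,
                 response_prob = response_prob,
                 baseline_response_prob = baseline_response_prob),
            class = "promval_sim_config")
}

draw_baseline <- function(n, bd) {
  at_ceiling <- stats::runif(n) < bd$ceiling_weight
  x <- numeric(n)
  x[at_ceiling] <- 100
  k <- sum(!at_ceiling)
  if (k) x[!at_ceiling] <- rtruncnorm(k, bd$mean, bd$sd, 0, 100 - 1e-9)
  x
}

#' Generate a synthetic registry cohort
#'
#' Draws subjects (demographics, disease covariates, adjunct-therapy flags),
#' latent baseline domain scores from the ceiling mixture, and longitudinal
#' questionnaire visits. Each observed post-surgery score is the generating
#' model's linear predictor plus Gaussian noise, clipped to \[0, 100\];
#' covariate and outcome missingness is applied *after* outcome generation
#' via [apply_missingness()]. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `subjects` and `visits` data frames, `truth` (the
#'   generating models), and `log` (clipped-outcome fractions per domain and
#'   the realized-missingness log).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "promval_sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  cv <- config$covariates

  subjects <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age_dx = rtruncnorm(n, cv$age$mean, cv$age$sd, cv$age$min, cv$age$max),
    psa = rlnorm_trunc(n, cv$psa$meanlog, cv$psa$sdlog, cv$psa$max),
    gleason = sample(names(cv$gleason), n, replace = TRUE, prob = cv$gleason),
    general_health = sample(names(cv$general_health), n, replace = TRUE,
                            prob = cv$general_health),
    race = "White",
    treatment = "RP",
    stage_localized = stats::runif(n) < cv$p_localized,
    adt = stats::runif(n) < cv$p_adt,
    brachytherapy = stats::runif(n) < cv$p_brachytherapy,
    cryoablation = stats::runif(n) < cv$p_cryoablation,
    stringsAsFactors = FALSE
  )

  ## Latent baseline scores exist for everyone; they are only *observed*
  ## through a returned pre-surgery questionnaire.
  baselines <- sapply(config$domains, function(d) {
    draw_baseline(n, config$baseline_distribution[[d]])
  })
  baselines <- matrix(baselines, nrow = n,
                      dimnames = list(NULL, config$domains))

  responded_baseline <- stats::runif(n) < config$baseline_response_prob
  visit_rows <- list()
  if (any(responded_baseline)) {
    b <- data.frame(subject_id = subjects$subject_id[responded_baseline],
                    scheduled_month = 0, months_post_surgery = 0,
                    stringsAsFactors = FALSE)
    for (d in config$domains) b[[d]] <- baselines[responded_baseline, d]
    visit_rows[[length(visit_rows) + 1L]] <- b
  }

  clipped <- stats::setNames(numeric(length(config$domains)), config$domains)
  n_post <- stats::setNames(numeric(length(config$domains)), config$domains)
  for (m in config$visit_months) {
    responded <- stats::runif(n) < config$response_prob
    k <- sum(responded)
    if (!k) next
    months <- pmax(0.5, m + stats::rnorm(k, 0, config$visit_jitter_sd))
    v <- data.frame(subject_id = subjects$subject_id[responded],
                    scheduled_month = m, months_post_surgery = months,
                    stringsAsFactors = FALSE)
    pred_tab <- subjects[responded, , drop = FALSE]
    pred_tab$months_post_surgery <- months
    pred_tab$timepoint <- paste0(m, "m")
    for (d in config$domains) {
      pred_tab$baseline <- baselines[responded, d]
      lp <- predict_score(config$true_models[[d]], pred_tab)
      y <- lp + stats::rnorm(k, 0, config$residual_sd[[d]])
      yc <- pmin(100, pmax(0, y))
      clipped[d] <- clipped[d] + sum(y != yc)
      n_post[d] <- n_post[d] + k
      v[[d]] <- yc
    }
    visit_rows[[length(visit_rows) + 1L]] <- v
  }
  visits <- do.call(rbind, visit_rows)
  rownames(visits) <- NULL

  miss_log <- NULL
  if (length(config$missingness)) {
    masked <- apply_missingness(subjects, visits, config$missingness,
                                seed = config$seed + 1L)
    subjects <- masked$subjects
    visits <- masked$visits
    miss_log <- masked$log
  }

  list(subjects = subjects, visits = visits, truth = config$true_models,
       log = list(clipped_fraction = ifelse(n_post > 0, clipped / n_post, 0),
                  missingness = miss_log))
}

rule_scope_rows <- function(visits, scope) {
  if (is.null(scope)) rep(TRUE, nrow(visits))
  else if (identical(scope, "baseline")) visits$scheduled_month == 0
  else if (identical(scope, "post")) visits$scheduled_month > 0
  else visits$scheduled_month %in% scope
}

#' Apply a missing-at-random mechanism to cohort tables
#'
#' Each rule blanks one field: a subject covariate (e.g. `psa`,
#' `general_health`, `age_dx`) or a visit-level domain score, optionally
#' restricted by `scope` (`"baseline"`, `"post"`, or scheduled months).
#' Missingness probabilities follow a logistic model on *fully observed*
#' conditioning covariates of the input tables (standardized, with the given
#' `slopes`); the intercept is either given directly or solved so the
#' marginal probability matches `target`. Probabilities are evaluated
#' against the input (pre-blanking) tables, so the mechanism stays MAR even
#' when several rules touch related fields. A rule conditioning on a
#' covariate that itself has missing values is rejected: the realized
#' mechanism would be non-ignorable (MNAR).
#'
#' @param subjects,visits Cohort tables as from [generate_cohort()].
#' @param mechanism List of rules: `list(field =, target = | intercept =,
#'   slopes = c(cov = beta, ...), scope =)`.
#' @param seed Integer seed; results are deterministic given it.
#' @return List with masked `subjects`, `visits`, and `log` (a data frame of
#'   realized missingness fractions per rule).
#' @export
apply_missingness <- function(subjects, visits, mechanism, seed = 1L) {
  set.seed(seed)
  sub0 <- subjects; vis0 <- visits
  log_rows <- list()
  for (rule in mechanism) {
    field <- rule$field
    in_subjects <- field %in% names(sub0)
    if (!in_subjects && !field %in% names(vis0)) {
      stop_config("mechanism", sprintf("unknown field '%s'", field))
    }
    rows <- if (in_subjects) rep(TRUE, nrow(sub0)) else rule_scope_rows(vis0, rule$scope)
    n_rows <- sum(rows)
    if (!n_rows) next

    lin <- rep(0, n_rows)
    for (cov in names(rule$slopes)) {
      x <- if (cov %in% names(sub0)) {
        xx <- sub0[[cov]]
        if (in_subjects) xx[rows] else xx[match(vis0$subject_id[rows], sub0$subject_id)]
      } else stop_config("mechanism", sprintf("unknown conditioning covariate '%s'", cov))
      if (anyNA(x)) {
        stop(sprintf(
          "mechanism for '%s' conditions on '%s', which has missing values; the mechanism would not be MAR",
          field, cov), call. = FALSE)
      }
      s <- stats::sd(x)
      z <- if (is.finite(s) && s > 0) (x - mean(x)) / s else rep(0, length(x))
      lin <- lin + rule$slopes[[cov]] * z
    }
    a <- rule$intercept
    if (is.null(a)) {
      target <- rule$target
      if (is.null(target)) stop_config("mechanism", sprintf("rule for '%s' needs target or intercept", field))
      a <- if (target <= 0) -Inf else if (target >= 1) Inf else if (all(lin == 0)) {
        stats::qlogis(target)
      } else {
        stats::uniroot(function(aa) mean(stats::plogis(aa + lin)) - target,
                       c(-40, 40), tol = 1e-10)$root
      }
    }
    p <- stats::plogis(a + lin)
    blank <- stats::runif(n_rows) < p
    if (in_subjects) {
      sub <- which(rows)[blank]
      subjects[[field]][sub] <- NA
    } else {
      sub <- which(rows)[blank]
      visits[[field]][sub] <- NA
    }
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      field = field,
      scope = if (in_subjects) "subjects" else paste(rule$scope %||% "all", collapse = ","),
      target = rule$target %||% NA_real_,
      realized = mean(blank), n = n_rows, stringsAsFactors = FALSE)
  }
  list(subjects = subjects, visits = visits,
       log = if (length(log_rows)) do.call(rbind, log_rows) else NULL)
}

#' Write / read cohort tables as CSV
#'
#' Headered UTF-8 CSV; missing values are empty fields. The generating truth
#' is written alongside in the model-spec YAML schema.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cohort$truth)) {
    write_model_spec(cohort$truth, file.path(dir, "truth_models.yaml"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              na.strings = "", stringsAsFactors = FALSE)
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            na.strings = "", stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth_models.yaml")
  truth <- if (file.exists(truth_path)) read_model_specs(truth_path) else NULL
  list(subjects = subjects, visits = visits, truth = truth)
}
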