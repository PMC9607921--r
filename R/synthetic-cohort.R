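# Cohort simulator: emulates a pilot study's app usage — an allocated
# cohort with dropouts and never-users, daily activity tracking and
# intermittent side-effect reporting — so the full pipeline can be exercised
# end to end with no external data. Record counts are allocated
# constructively (totals partitioned across users, then assigned to dates),
# not sampled in expectation, so a feasible configuration reproduces its
# target counts exactly.

#' Cohort generator configuration
#'
#' @param n_allocated Patients allocated to the app.
#' @param dropouts Named integer vector breaking down dropouts by reason
#'   (e.g. `c(lack_of_response = 7, medical = 2, lost_to_follow_up = 2,
#'   personal = 1)`).
#' @param n_never_used Patients who never used the app.
#' @param se_total Total side-effect records to generate.
#' @param se_users Number of distinct users with at least one side-effect
#'   record.
#' @param activity_total Total daily-activity records (at most one per user
#'   per day).
#' @param activity_users Number of distinct users with at least one activity
#'   record.
#' @param start_date,end_date Study window (inclusive), `YYYY-MM-DD`.
#' @param seed Default RNG seed for [generate_cohort()].
#' @return Validated object of class `ehr_cohort_config`. Infeasible targets
#'   (more reporting users than users, fewer records than reporting users,
#'   more activity records than user-days, or side-effect targets exceeding
#'   the distinct date-finding combinations available) error here, before
#'   any generation.
#' @export
cohort_config <- function(n_allocated, dropouts, n_never_used,
                          se_total, se_users, activity_total, activity_users,
                          start_date, end_date, seed = 1L) {
  stopifnot(is.numeric(n_allocated), n_allocated >= 0)
  stopifnot(is.numeric(dropouts), all(dropouts >= 0))
  stopifnot(is.numeric(n_never_used), n_never_used >= 0)
  n_dropouts <- sum(dropouts)
  if (n_allocated < n_dropouts + n_never_used) {
    stop("infeasible cohort: allocated (", n_allocated, ") < dropouts (",
         n_dropouts, ") + never-users (", n_never_used, ")", call. = FALSE)
  }
  n_users <- n_allocated - n_dropouts - n_never_used
  for (nm in c("se_total", "se_users", "activity_total", "activity_users")) {
    v <- get(nm)
    stopifnot(is.numeric(v), length(v) == 1L, v >= 0)
  }
  if (se_users > n_users || activity_users > n_users) {
    stop("infeasible targets: users with >=1 record (", se_users, "/",
         activity_users, ") exceed total users (", n_users, ")", call. = FALSE)
  }
  if (se_total < se_users || activity_total < activity_users) {
    stop("infeasible targets: totals must be >= number of reporting users",
         call. = FALSE)
  }
  start <- parse_iso_date(start_date)
  end <- parse_iso_date(end_date)
  if (end < start) stop("end_date before start_date", call. = FALSE)
  n_days <- as.integer(end - start) + 1L
  if (activity_users > 0 && activity_total > activity_users * n_days) {
    stop("infeasible targets: ", activity_total,
         " activity records cannot fit in ", activity_users, " users x ",
         n_days, " days at <=1/user/day", call. = FALSE)
  }
  structure(list(
    n_allocated = as.integer(n_allocated),
    dropouts = stats::setNames(as.integer(dropouts), names(dropouts)),
    n_never_used = as.integer(n_never_used),
    n_users = as.integer(n_users),
    se_total = as.integer(se_total), se_users = as.integer(se_users),
    activity_total = as.integer(activity_total),
    activity_users = as.integer(activity_users),
    start_date = start, end_date = end, n_days = n_days,
    seed = as.integer(seed)
  ), class = "ehr_cohort_config")
}

#' Study-scale default configuration
#'
#' The pilot-scale constants: 62 allocated patients; 12 dropouts
#' (7 lack of response to questionnaires, 2 medical, 2 lost to follow-up,
#' 1 personal); 3 never-users; hence 47 users. 234 side-effect records over
#' exactly 34 users and 866 daily-activity records over exactly 38 users,
#' across the study window 2020-12-22 to 2022-04-04.
#'
#' @param seed RNG seed stored in the config (overridable in
#'   [generate_cohort()]).
#' @return An `ehr_cohort_config`.
#' @export
study_defaults <- function(seed = 1L) {
  cohort_config(
    n_allocated = 62,
    dropouts = c(lack_of_response = 7, medical = 2, lost_to_follow_up = 2,
                 personal = 1),
    n_never_used = 3,
    se_total = 234, se_users = 34,
    activity_total = 866, activity_users = 38,
    start_date = "2020-12-22", end_date = "2022-04-04",
    seed = seed
  )
}

# Random composition of `total` into `k` parts, each >= 1. Constructive:
# exact totals by design.
rand_composition <- function(total, k) {
  if (k == 0L) return(integer(0))
  counts <- rep(1L, k)
  extra <- total - k
  if (extra > 0L) {
    counts <- counts + tabulate(sample.int(k, extra, replace = TRUE), nbins = k)
  }
  counts
}

#' Generate a synthetic app-usage cohort
#'
#' Deterministic given the seed (Mersenne-Twister via `set.seed()`).
#' Dropouts and never-users generate no records; side-effect and activity
#' totals are partitioned over exactly the configured numbers of reporting
#' users. Activity is at most one record per user per day; side-effect
#' reports are unique per (user, date, finding) with labels drawn uniformly
#' from the mapping config.
#'
#' @param config An [cohort_config()].
#' @param seed RNG seed; defaults to the one in the config.
#' @param mapping Mapping config supplying finding/severity labels.
#' @return List with `side_effects` and `activity` record data frames,
#'   `links` (the app-to-study link table covering the users), and
#'   `summary` (class `ehr_cohort_summary`).
#' @export
generate_cohort <- function(config, seed = config$seed,
                            mapping = load_builtin_mapping()) {
  stopifnot(inherits(config, "ehr_cohort_config"))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n_users <- config$n_users
  width <- max(3L, nchar(as.character(max(1L, config$n_allocated))))
  app_ids <- sprintf(paste0("XR-%0", width, "d"), seq_len(config$n_allocated))
  roles <- rep("user", config$n_allocated)
  non_user_idx <- if (config$n_allocated > 0)
    sample.int(config$n_allocated, config$n_never_used + sum(config$dropouts))
  else integer(0)
  if (length(non_user_idx)) {
    roles[non_user_idx[seq_len(config$n_never_used)]] <- "never_used"
    roles[non_user_idx[-seq_len(config$n_never_used)]] <- "dropout"
  }
  users <- app_ids[roles == "user"]
  links <- patient_links(data.frame(
    app_patient_id = users,
    study_id = sprintf("ASC-%04d", 1000L + seq_along(users)),
    stringsAsFactors = FALSE
  ))
  all_days <- seq(config$start_date, config$end_date, by = "day")

  # Reporting sets: overlap between side-effect and activity reporters falls
  # out of taking the first se_users and last activity_users of one shuffle.
  shuffled <- if (n_users > 0) sample(users) else character(0)
  se_set <- shuffled[seq_len(config$se_users)]
  act_set <- if (config$activity_users > 0)
    shuffled[seq.int(n_users - config$activity_users + 1L, n_users)]
  else character(0)

  finding_labels <- vapply(mapping$findings, `[[`, character(1), "local_label")
  severity_labels <- vapply(mapping$severities, `[[`, character(1), "local_label")
  if (config$se_total > 0 &&
      config$se_total > config$se_users * config$n_days * length(finding_labels)) {
    stop("infeasible: side-effect target exceeds distinct (date, finding) ",
         "combinations available", call. = FALSE)
  }

  se_counts <- rand_composition(config$se_total, config$se_users)
  se_rows <- list()
  phrases <- c("malestar leve", "me despierto por la noche",
               "dificultad para dormir", "molestias tras la medicación", NA, NA)
  for (i in seq_along(se_set)) {
    k <- se_counts[[i]]
    grid_n <- config$n_days * length(finding_labels)
    pick <- sample.int(grid_n, k)
    day_i <- (pick - 1L) %% config$n_days + 1L
    find_i <- (pick - 1L) %/% config$n_days + 1L
    ord <- order(day_i, find_i)
    se_rows[[i]] <- data.frame(
      app_patient_id = se_set[[i]],
      date = format(all_days[day_i[ord]], "%Y-%m-%d"),
      finding_label = finding_labels[find_i[ord]],
      severity_label = sample(severity_labels, k, replace = TRUE),
      value_text = sample(phrases, k, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  side_effects <- if (length(se_rows)) do.call(rbind, se_rows) else
    data.frame(app_patient_id = character(0), date = character(0),
               finding_label = character(0), severity_label = character(0),
               value_text = character(0), stringsAsFactors = FALSE)

  act_counts <- rand_composition(config$activity_total, config$activity_users)
  act_rows <- list()
  for (i in seq_along(act_set)) {
    k <- act_counts[[i]]
    days <- sort(sample.int(config$n_days, k))
    steps <- sample(300:16000, k, replace = TRUE)
    act_rows[[i]] <- data.frame(
      app_patient_id = act_set[[i]],
      date = format(all_days[days], "%Y-%m-%d"),
      steps = steps,
      calories = pmax(0, round(steps * 0.04 + stats::rnorm(k, 0, 12))),
      duration = pmax(0, round(steps / 110 + stats::rnorm(k, 0, 6))),
      stringsAsFactors = FALSE
    )
  }
  activity <- if (length(act_rows)) do.call(rbind, act_rows) else
    data.frame(app_patient_id = character(0), date = character(0),
               steps = numeric(0), calories = numeric(0), duration = numeric(0),
               stringsAsFactors = FALSE)
  rownames(side_effects) <- NULL
  rownames(activity) <- NULL

  summary <- structure(list(
    n_allocated = config$n_allocated,
    dropouts = config$dropouts,
    n_never_used = config$n_never_used,
    n_users = n_users,
    n_side_effect_records = nrow(side_effects),
    n_side_effect_users = length(unique(side_effects$app_patient_id)),
    n_activity_records = nrow(activity),
    n_activity_users = length(unique(activity$app_patient_id)),
    start_date = config$start_date, end_date = config$end_date,
    seed = as.integer(seed)
  ), class = "ehr_cohort_summary")

  list(side_effects = side_effects, activity = activity, links = links,
       summary = summary)
}

#' Enrollment accounting report
#'
#' Dropouts, never-users and users as counts and percentages of the
#' allocated cohort (one-decimal half-up, via [pct()]), plus the dropout
#' breakdown as whole-number percentages of all dropouts.
#'
#' @param summary An `ehr_cohort_summary` from [generate_cohort()], or any
#'   list with `n_allocated`, `dropouts`, `n_never_used`, `n_users`.
#' @return Object of class `ehr_cohort_accounting` with `$table`
#'   (category, n, pct_of_allocated) and `$dropout_breakdown`.
#' @export
#' @examples
#' cohort_accounting(generate_cohort(study_defaults())$summary)
cohort_accounting <- function(summary) {
  n_drop <- sum(summary$dropouts)
  tab <- data.frame(
    category = c("allocated", "dropouts", "never_used", "users"),
    n = c(summary$n_allocated, n_drop, summary$n_never_used, summary$n_users),
    pct_of_allocated = pct(
      c(summary$n_allocated, n_drop, summary$n_never_used, summary$n_users),
      summary$n_allocated),
    stringsAsFactors = FALSE
  )
  breakdown <- data.frame(
    reason = names(summary$dropouts),
    n = unname(summary$dropouts),
    pct_of_dropouts = if (n_drop > 0)
      floor(100 * unname(summary$dropouts) / n_drop + 0.5) else
      rep(0, length(summary$dropouts)),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, dropout_breakdown = breakdown),
            class = "ehr_cohort_accounting")
}

#' @export
print.ehr_cohort_accounting <- function(x, ...) {
  cat("Cohort accounting\n")
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  %-11s %3d (%.1f%%)\n", r$category, r$n, r$pct_of_allocated))
  }
  if (nrow(x$dropout_breakdown)) {
    cat("  dropout reasons:\n")
    for (i in seq_len(nrow(x$dropout_breakdown))) {
      r <- x$dropout_breakdown[i, ]
      cat(sprintf("    %-19s %2d (%d%%)\n", r$reason, r$n, r$pct_of_dropouts))
    }
  }
  invisible(x)
}
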