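# End-to-end convenience wrapper: simulate -> convert -> validate -> ingest
# -> report, the same composition the CLI exposes stage by stage.

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the cohort, converts all records to coded extracts, validates
#' every extract, ingests them into a fresh repository, and builds the
#' count report with the cohort's user total as the patient denominator.
#'
#' @param config Cohort configuration; defaults to the study-scale
#'   [study_defaults()].
#' @param seed RNG seed; defaults to the config's.
#' @param mapping Terminology mapping.
#' @param registry Archetype registry.
#' @return List with `cohort` (generator output), `extracts`,
#'   `conversion_failures`, `n_validation_errors`, `repo`, `ingest`
#'   (batch ingestion result) and `report` ([count_report()]).
#' @export
#' @examples
#' \donttest{
#' run <- run_study_pipeline(study_defaults(), seed = 1)
#' run$report
#' }
run_study_pipeline <- function(config = study_defaults(), seed = config$seed,
                               mapping = load_builtin_mapping(),
                               registry = builtin_registry()) {
  cohort <- generate_cohort(config, seed = seed, mapping = mapping)
  batch <- batch_daily(cohort$side_effects, cohort$activity,
                       mapping = mapping, registry = registry)
  n_val_err <- 0L
  for (x in batch$extracts) {
    rep_x <- validate_extract(x, registry, mapping)
    n_val_err <- n_val_err + length(report_errors(rep_x))
  }
  repo <- new_repository(registry, mapping)
  ingest <- ingest_batch(repo, batch$extracts, cohort$links)
  report <- count_report(repo, total_users = cohort$summary$n_users)
  list(cohort = cohort, extracts = batch$extracts,
       conversion_failures = batch$failures,
       n_validation_errors = n_val_err,
       repo = repo, ingest = ingest, report = report)
}
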