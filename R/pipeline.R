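#' Build and validate a pipeline configuration
#'
#' @param seed Integer seed (required; all stage seeds are derived from
#'   it, so each stage is independently reproducible).
#' @param n_selection,n_rejection Participants per condition.
#' @param n_ballots Ballots per participant (even).
#' @param noise_sd Candidate stance noise SD.
#' @param design Trial design, `"two_stage"` or `"trinary"`.
#' @param deadline_prob Per-trial censoring probability.
#' @param params_by_condition Named list of [agent_params()]; defaults to
#'   the package defaults per condition.
#' @param out_dir Output directory (created if absent).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed, n_selection = 4, n_rejection = 4,
                       n_ballots = 100, noise_sd = 0.3,
                       design = c("two_stage", "trinary"),
                       deadline_prob = 0.001,
                       params_by_condition = NULL, out_dir = tempfile("run")) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("`seed` is required for any stochastic pipeline run")
  }
  design <- match.arg(design)
  if (n_ballots %% 2 != 0 || n_ballots < 2) {
    stop("`n_ballots` must be a positive even number")
  }
  if (n_selection < 1 && n_rejection < 1) stop("no participants requested")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (is.null(params_by_condition)) {
    params_by_condition <- list(selection = agent_params("selection"),
                                rejection = agent_params("rejection"))
  }
  structure(
    list(seed = as.integer(seed), n_selection = n_selection,
         n_rejection = n_rejection, n_ballots = n_ballots,
         noise_sd = noise_sd, design = design,
         deadline_prob = deadline_prob,
         params_by_condition = params_by_condition, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes profiles -> ballots -> trials -> exclusions -> standardization
#' -> fits -> quartile summaries -> election scenarios for a validated
#' [run_config()], writing every artifact as CSV into the configured
#' output directory together with a manifest of file checksums. The run is
#' deterministic for a fixed config: repeating it produces byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return The manifest data frame (`file`, `md5`, `rows`), invisibly
#'   also written to `manifest.csv`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  profiles <- stage("profiles", c(
    with_seed(child_seed(config$seed, 1),
              random_profiles(config$n_selection, "selection", "s")),
    with_seed(child_seed(config$seed, 2),
              random_profiles(config$n_rejection, "rejection", "r"))
  ))
  write_profiles(profiles, path("profiles.csv"))

  ballot_sets <- stage("ballots", lapply(seq_along(profiles), function(i) {
    tab <- build_candidate_table(profiles[[i]], noise_sd = config$noise_sd,
                                 seed = child_seed(config$seed, 100 + i))
    generate_ballot_set(profiles[[i]], tab,
                        seed = child_seed(config$seed, 500 + i),
                        n_iterations = config$n_ballots / 2)
  }))
  write_ballots(ballot_sets, path("ballots.csv"))

  trials <- stage("trials", simulate_dataset(
    profiles, ballot_sets, config$params_by_condition,
    design = config$design, seed = child_seed(config$seed, 900),
    deadline_prob = config$deadline_prob
  ))
  write_trials(trials, path("trials.csv"))

  excl <- stage("exclusions", apply_exclusions(trials))
  write.csv(excl$log, path("exclusions.csv"), row.names = FALSE)
  kept <- stage("standardize", standardize_within_participant(excl$trials))

  for (cond in c("selection", "rejection")) {
    dc <- kept[kept$condition == cond, , drop = FALSE]
    if (!length(unique(dc$participant_id))) next
    stage(paste0("fit_", cond), {
      write_fit_result(fit_optout(dc), path(sprintf("fit_optout_%s.csv", cond)))
      write_fit_result(fit_choice(dc), path(sprintf("fit_choice_%s.csv", cond)))
      write.csv(quartile_optout_summary(dc),
                path(sprintf("quartiles_%s.csv", cond)), row.names = FALSE)
    })
  }
  if (length(unique(kept$condition)) == 2) {
    stage("fit_interaction",
          write_fit_result(fit_condition_interaction(kept, "optout"),
                           path("fit_optout_interaction.csv")))
  }

  stage("elections", {
    moments <- reference_moments(n_participants = 8,
                                 seed = child_seed(config$seed, 4000),
                                 noise_sd = config$noise_sd)
    write_scenarios(run_scenarios(config$params_by_condition,
                                  moments = moments),
                    path("election_scenarios.csv"))
  })

  files <- sort(list.files(config$out_dir, pattern = "\\.csv$"))
  files <- setdiff(files, "manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    rows = vapply(files, function(f) {
      nrow(read.csv(file.path(config$out_dir, f)))
    }, integer(1))
  )
  rownames(manifest) <- NULL
  write.csv(manifest, path("manifest.csv"), row.names = FALSE)
  manifest
}
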