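# End-to-end orchestration and file I/O: trial tables as CSV, cohort
# round-trips, and the full analysis pipeline (exclusions, priors, model
# selection, psychometrics, complexity, group summaries).

TRIAL_COLUMNS <- c("subject_id", "block", "trial_index", "jar", "n",
                   "sample", "rare_count", "response")

#' Read a trial table from CSV
#'
#' Comma-separated with a header row; one row per trial. The \code{sample}
#' column stores the ball sequence as a string of "R" (rare) and "C"
#' (common) characters; \code{trial_index} is 0-based. A missing
#' \code{response} column is tolerated for stimulus-only files. Rows whose
#' sample string disagrees with the \code{n} or \code{rare_count} columns are
#' rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return Trial data frame.
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample = "character"))
  need <- setdiff(TRIAL_COLUMNS, c("response", "subject_id"))
  missing_cols <- setdiff(need, names(tr))
  if (length(missing_cols) > 0L)
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(tr$response)) tr$response <- NA_character_
  if (is.null(tr$subject_id)) tr$subject_id <- NA_character_
  tr$sample[is.na(tr$sample)] <- ""
  bad_len <- which(nchar(tr$sample) != tr$n)
  if (length(bad_len) > 0L)
    stop("sample length disagrees with n at data row(s): ",
         paste(utils::head(bad_len, 5L), collapse = ", "), call. = FALSE)
  counts <- vapply(tr$sample, function(s)
    sum(strsplit(s, "")[[1]] == "R"), integer(1), USE.NAMES = FALSE)
  bad_k <- which(counts != tr$rare_count)
  if (length(bad_k) > 0L)
    stop("rare_count disagrees with sample at data row(s): ",
         paste(utils::head(bad_k, 5L), collapse = ", "), call. = FALSE)
  tr$response[!is.na(tr$response) & tr$response == ""] <- NA_character_
  tr
}

#' Write a trial table to CSV
#'
#' @param trials Trial data frame.
#' @param path Output path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write or read a cohort as plain-text tables
#'
#' A cohort round-trips as three CSVs in a directory: \code{trials.csv},
#' \code{subjects.csv} (truth labels and exclusion flags, kept apart from
#' the trials so fitting code cannot see them) and \code{params.csv}
#' (true parameters per subject-block), plus \code{config.csv} with the
#' scalar design settings.
#'
#' @param cohort A \code{cohort}.
#' @param dir Directory (created if needed).
#' @return \code{write_cohort}: the directory, invisibly.
#'   \code{read_cohort}: a \code{cohort} (without the generating functions
#'   of the original config).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(cohort$trials, file.path(dir, "trials.csv"))
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$params, file.path(dir, "params.csv"),
                   row.names = FALSE, na = "")
  cfg <- cohort$config
  utils::write.csv(data.frame(key = c("n_subjects", "seed", "pretest_trials",
                                      "interlude_trials", "n_interludes"),
                              value = c(cfg$n_subjects, cfg$seed,
                                        cfg$pretest_trials,
                                        cfg$interlude_trials,
                                        cfg$n_interludes)),
                   file.path(dir, "config.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  trials <- read_trials(file.path(dir, "trials.csv"))
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  subjects$reason[subjects$reason == ""] <- NA_character_
  params <- utils::read.csv(file.path(dir, "params.csv"),
                            stringsAsFactors = FALSE)
  structure(list(subjects = subjects, params = params, trials = trials,
                 config = NULL), class = "cohort")
}

#' Run the full analysis pipeline
#'
#' Executes the analysis flow on a cohort: exclusions, informative-prior
#' construction from a pilot cohort, per subject-block model fitting and
#' Bayes-factor selection, optional cross-validation, psychometric fits with
#' the bias/noise/variance decomposition, mutual-information and complexity
#' measures, and group summaries. A failing subject-block is isolated
#' (recorded in \code{failures}) and the pipeline continues.
#'
#' @param cohort A \code{cohort} (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @param blocks Named list of [block_config()]s matching the cohort's block
#'   labels.
#' @param prior_source \code{"pilot"} builds informative priors from a fresh
#'   pilot cohort; \code{"flat"} uses flat priors; or pass a named list of
#'   [informative_prior]s directly.
#' @param cross_validation Also run 10-fold cross-validation of each selected
#'   model (slower).
#' @param n_boot Bootstrap resamples for group summaries.
#' @param seed Master seed; stage seeds derive from it and are recorded in
#'   the manifest.
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSVs.
#' @return List of class \code{pipeline_result} with \code{selection},
#'   \code{psychometrics}, \code{complexity}, \code{groups},
#'   \code{exclusions}, \code{failures} and \code{manifest}.
#' @export
run_pipeline <- function(cohort, blocks = study_blocks(),
                         prior_source = c("pilot", "flat"),
                         cross_validation = FALSE, n_boot = 1000L, seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.list(prior_source) || inherits(prior_source, "informative_prior")) {
    informative <- prior_source
    prior_label <- "supplied"
  } else {
    prior_source <- match.arg(prior_source)
    prior_label <- prior_source
    informative <- if (prior_source == "pilot")
      informative_priors_from_pilot(generate_pilot(blocks = blocks,
                                                   seed = seed + 1000L),
                                    blocks = blocks)
    else NULL
  }
  cohort <- apply_exclusions(cohort)
  keep <- cohort$subjects$subject_id[!cohort$subjects$excluded]
  block_names <- vapply(blocks, `[[`, "", "name")
  sel_rows <- list(); psy_rows <- list(); cx_rows <- list(); fails <- list()
  for (b in seq_along(blocks)) {
    block <- blocks[[b]]
    tables <- block_fit_tables(block)
    inf_b <- if (is.null(informative)) NULL else informative[[block_names[b]]]
    for (sid in keep) {
      tr <- cohort$trials[cohort$trials$subject_id == sid &
                            cohort$trials$block == block$name, ]
      if (nrow(tr) == 0L) next
      res <- tryCatch({
        sel <- select_model(tr, block, informative = inf_b, tables = tables)
        cv <- if (cross_validation)
          cross_validate(tr, block, sel$selected, informative = inf_b,
                         seed = seed + 2000L)
        else NA_real_
        psy <- fit_psychometric(tr, block)
        cx <- complexity_result(tr, block, sel$selected)
        list(sel = data.frame(subject_id = sid, block = block$name,
                              selected_model = sel$selected,
                              strong_evidence = sel$strong_evidence,
                              cv_accuracy = cv,
                              t(sel$log_bf)),
             psy = data.frame(subject_id = sid, block = block$name,
                              alpha = psy$alpha, beta = psy$beta,
                              phi = psy$phi, bias = psy$bias,
                              noise = psy$noise, variance = psy$variance,
                              degenerate = psy$degenerate),
             cx = cbind(subject_id = sid, cx))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(
          subject_id = sid, block = block$name,
          message = conditionMessage(res))
      } else {
        sel_rows[[length(sel_rows) + 1L]] <- res$sel
        psy_rows[[length(psy_rows) + 1L]] <- res$psy
        cx_rows[[length(cx_rows) + 1L]] <- res$cx
      }
    }
  }
  selection <- do.call(rbind, sel_rows)
  psychometrics <- do.call(rbind, psy_rows)
  complexity <- do.call(rbind, cx_rows)
  gdf <- merge(psychometrics[, c("subject_id", "block", "bias", "variance")],
               selection[, c("subject_id", "block", "selected_model")],
               by = c("subject_id", "block"))
  groups <- suppressWarnings(group_summaries(gdf, n_boot = n_boot,
                                             seed = seed + 3000L))
  manifest <- list(package_version = as.character(utils::packageVersion("jarinfer")),
                   seed = seed,
                   stage_seeds = c(pilot = seed + 1000L, cv = seed + 2000L,
                                   bootstrap = seed + 3000L),
                   prior_source = prior_label,
                   n_subjects = length(keep),
                   n_excluded = sum(cohort$subjects$excluded),
                   timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  out <- structure(list(selection = selection, psychometrics = psychometrics,
                        complexity = complexity, groups = groups,
                        exclusions = cohort$subjects,
                        failures = if (length(fails)) do.call(rbind, fails)
                        else NULL,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline result> %d subjects, %d subject-block fits, %d failures\n",
              x$manifest$n_subjects, nrow(x$selection),
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  print(table(x$selection$block, x$selection$selected_model))
  invisible(x)
}

#' Write pipeline result tables
#'
#' @param result A \code{pipeline_result}.
#' @param dir Output directory (created if needed).
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$selection, file.path(dir, "model_selection.csv"),
                   row.names = FALSE)
  utils::write.csv(result$psychometrics, file.path(dir, "psychometrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$complexity, file.path(dir, "complexity.csv"),
                   row.names = FALSE)
  utils::write.csv(result$groups$summary, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  if (!is.null(result$groups$tests))
    utils::write.csv(result$groups$tests, file.path(dir, "group_tests.csv"),
                     row.names = FALSE)
  utils::write.csv(result$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE, na = "")
  man <- result$manifest
  utils::write.csv(data.frame(key = names(unlist(man)),
                              value = unname(unlist(man))),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
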