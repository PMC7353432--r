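participant_cohorts <- c("4-10", "11-18", "19-64", "65plus")

participant_cols <- readr::cols(
  id = readr::col_integer(),
  cohort = readr::col_character(),
  gender = readr::col_character(),
  intake_diet = readr::col_double(),
  intake_supp = readr::col_double(),
  rtec_g = readr::col_double(),
  month = readr::col_integer(),
  serum = readr::col_double(),
  psu = readr::col_character(),
  stratum = readr::col_character()
)

#' Read a participant CSV
#'
#' Reads and validates the package's participant schema (`id, cohort,
#' gender, intake_diet, intake_supp, rtec_g, month, serum, psu, stratum`;
#' missing serum encoded as an empty field). Rows violating the record
#' invariants (negative intakes or RTEC grams, month outside 1..12,
#' nonpositive serum, unknown cohort or gender token) are rejected with an
#' error naming the row and field.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A participant tibble (see [generate_cohort()]).
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) abort_bad_arg("file not found: %s", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(names(participant_cols$cols), header)
  if (length(missing_cols)) {
    abort_bad_arg("participant file is missing columns: %s",
                  paste(missing_cols, collapse = ", "))
  }
  d <- readr::read_csv(path, col_types = participant_cols, na = c("", "NA"))
  probs <- readr::problems(d)
  if (nrow(probs) > 0) {
    abort_bad_arg("malformed numeric values at row(s) %s",
                  paste(unique(probs$row), collapse = ", "))
  }
  if (nrow(d) == 0L) return(d)
  check_rows <- function(bad, field, why) {
    if (any(bad, na.rm = TRUE)) {
      abort_bad_arg("invalid %s (%s) in row(s) %s", field, why,
                    paste(utils::head(which(bad), 5), collapse = ", "))
    }
  }
  check_rows(!(d$cohort %in% participant_cohorts), "cohort",
             paste("expected one of", paste(participant_cohorts, collapse = "/")))
  check_rows(!(d$gender %in% c("male", "female")), "gender", "expected male/female")
  check_rows(d$intake_diet < 0, "intake_diet", "must be >= 0")
  check_rows(d$intake_supp < 0, "intake_supp", "must be >= 0")
  check_rows(d$rtec_g < 0, "rtec_g", "must be >= 0")
  check_rows(!(d$month %in% 1:12), "month", "must be an integer in 1..12")
  check_rows(!is.na(d$serum) & d$serum <= 0, "serum", "must be > 0 when present")
  d
}

#' Write a participant table to CSV
#'
#' Numeric fields are stored at full precision; missing serum becomes an
#' empty field. [read_participants()] round-trips the result.
#'
#' @param records Participant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Read a generator configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file holding the fields of
#'   [generator_config()] (`cells`, `dose_response_params`,
#'   `seasonal_params`, `serum_noise_sd`, `n_psu`, `n_strata`, `seed`).
#' @return A validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) abort_bad_arg("file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw$seed)) abort_bad_arg("config file must carry a seed")
  generator_config(
    cells = dplyr::bind_rows(raw$cells),
    dose_response_params = dplyr::bind_rows(raw$dose_response_params),
    seasonal_params = dplyr::bind_rows(raw$seasonal_params),
    serum_noise_sd = unlist(raw$serum_noise_sd),
    n_psu = raw$n_psu %||% 36L,
    n_strata = raw$n_strata %||% 9L,
    seed = raw$seed
  )
}

#' Write a generator configuration to YAML or JSON
#'
#' @param config A `generator_config`.
#' @param path Destination (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  payload <- list(
    cells = config$cells,
    dose_response_params = config$dose_response_params,
    seasonal_params = config$seasonal_params,
    serum_noise_sd = as.list(config$serum_noise_sd),
    n_psu = config$n_psu, n_strata = config$n_strata, seed = config$seed
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lapply(payload, function(x) {
      if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ])) else x
    }), path, precision = 15L)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a participant table, summarizes it, fits the
#' dose-response and both seasonal models per cohort, runs the
#' fortification counterfactual, and returns the report bundle. Every
#' report is deterministic given the generator seed; the bundle carries the
#' seed and a configuration hash for provenance.
#'
#' @param config A `generator_config` (ignored when `participants` is
#'   given, except as an error to omit both).
#' @param scenario A `fortification_scenario` (default 4.2 \eqn{\mu}g/100 g,
#'   consumers only).
#' @param participants Optional pre-existing participant tibble or CSV
#'   path; bypasses generation.
#' @param cohorts Cohorts to process (default: all present).
#' @param out_dir Optional directory; when given, the participant CSV and
#'   all reports are written there (JSON, plus the participant CSV).
#' @return A list of class `pipeline_report`: `participants`, `summary`
#'   (cohort summary), `dose_response` (tibble of per-cohort coefficients
#'   and plateaus), `seasonal` (tibble of per cohort x gender fits, both
#'   model types, with the model comparison), `fortification`
#'   (`fortification_result`), `provenance` (seed, config hash, timestamp).
#' @export
run_pipeline <- function(config = NULL, scenario = fortification_scenario(),
                         participants = NULL, cohorts = NULL, out_dir = NULL) {
  if (is.null(participants)) {
    if (is.null(config)) abort_bad_arg("either a generator config or a participant table is required")
    participants <- generate_cohort(config)
  } else if (is.character(participants)) {
    participants <- read_participants(participants)
  }
  if (!is.null(cohorts)) {
    participants <- dplyr::filter(participants, .data$cohort %in% cohorts)
  }
  if (nrow(participants) == 0L) abort_bad_arg("pipeline stage 'input': no participants to process")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
                   class = "vitdfort_pipeline_error")
    })
  }
  summary_tbl <- stage("summarize", summarize_cohort(participants))

  with_serum <- dplyr::filter(participants, !is.na(.data$serum))
  dr_fits <- stage("dose-response", {
    fits <- list()
    for (co in unique(with_serum$cohort)) {
      sub <- dplyr::filter(with_serum, .data$cohort == co) |>
        dplyr::mutate(intake = .data$intake_diet + .data$intake_supp)
      fits[[co]] <- fit_dose_response(sub)
    }
    fits
  })
  dr_tbl <- purrr::imap(dr_fits, function(f, co) {
    dplyr::bind_cols(tibble::tibble(cohort = co, a = f$a, b = f$b, c = f$c),
                     glance(f))
  }) |> dplyr::bind_rows()

  seasonal <- stage("seasonal", {
    with_serum |>
      dplyr::group_by(.data$cohort, .data$gender) |>
      dplyr::group_modify(function(d, key) {
        pol <- fit_polynomial_season(d)
        tri <- fit_trig_season(d)
        cmp <- compare_seasonal_models(pol, tri)
        tibble::tibble(alpha = pol$alpha, beta = pol$beta, gamma = pol$gamma,
                       peak_month = pol$peak_month,
                       r_squared_poly = cmp$r_squared_poly,
                       r_squared_trig = cmp$r_squared_trig,
                       rss_ratio = cmp$rss_ratio, n = pol$n)
      }) |>
      dplyr::ungroup()
  })
  seasonal_fits <- stage("seasonal", {
    out <- list()
    for (i in seq_len(nrow(seasonal))) {
      if (!is.finite(seasonal$alpha[i]) || seasonal$alpha[i] >= 0) next
      out[[paste(seasonal$cohort[i], seasonal$gender[i], sep = ".")]] <-
        seasonal_fit(seasonal$alpha[i], seasonal$beta[i], seasonal$gamma[i])
    }
    out
  })

  fort <- stage("fortification",
                apply_scenario(participants, scenario, dr_fits, seasonal_fits))

  provenance <- list(
    seed = if (!is.null(config)) config$seed else NA_integer_,
    config_hash = if (!is.null(config)) rlang::hash(config) else rlang::hash(participants),
    scenario_level = scenario$level,
    n_participants = nrow(participants)
  )
  report <- structure(
    list(participants = participants, summary = summary_tbl,
         dose_response = dr_tbl, seasonal = seasonal,
         fortification = fort, provenance = provenance),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_participants(participants, file.path(out_dir, "participants.csv"))
    payload <- list(
      provenance = provenance,
      intake_summary = summary_tbl$intake,
      serum_summary = summary_tbl$serum,
      dose_response = dr_tbl,
      seasonal = seasonal,
      fortification_summary = fort$summary,
      fortification_prevalence = fort$prevalence
    )
    jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d participants (seed %s, config %s)\n\n",
              x$provenance$n_participants, x$provenance$seed, x$provenance$config_hash))
  print(x$summary)
  cat("\nDose-response fits per cohort:\n"); print(x$dose_response, n = Inf)
  cat("\nSeasonal fits per cohort x gender:\n"); print(x$seasonal, n = Inf)
  cat("\n"); print(x$fortification)
  invisible(x)
}
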