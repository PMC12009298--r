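SCHEMA_VERSION <- "1.0"

check_schema_version <- function(version, what) {
  major <- suppressWarnings(as.integer(strsplit(as.character(version),
                                                ".", fixed = TRUE)[[1]][1]))
  ours <- as.integer(strsplit(SCHEMA_VERSION, ".", fixed = TRUE)[[1]][1])
  if (is.na(major) || major != ours)
    stop_introchoice(sprintf("%s has schema version '%s'; this reader handles major version %d",
                             what, version, ours),
                     "introchoice_schema_error")
  invisible(TRUE)
}

#' Write / read choice datasets as long-format CSV
#'
#' One row per (participant, trial, attribute) with columns
#' `participant_id, trial, attribute, value_A, value_B, choice`. The long
#' format keeps the file layout independent of the attribute count.
#'
#' @param datasets List of `choice_dataset` objects (or a single one).
#' @param path File path.
#' @return `write_choices` returns `path` invisibly; `read_choices` returns
#'   a named list of `choice_dataset` objects.
#' @export
write_choices <- function(datasets, path) {
  if (inherits(datasets, "choice_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    n <- n_trials(d); K <- n_attributes(d)
    data.frame(participant_id = d$participant_id,
               trial = rep(seq_len(n), each = K),
               attribute = rep(seq_len(K), times = n),
               value_A = as.vector(t(d$trials$x_A)),
               value_B = as.vector(t(d$trials$x_B)),
               choice = rep(d$choices, each = K),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "trial", "attribute", "value_A", "value_B",
              "choice")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_introchoice(paste("choices file is missing columns:",
                           paste(missing, collapse = ", ")),
                     "introchoice_schema_error")
  bad <- which(df$value_A < 0 | df$value_A > 1 | df$value_B < 0 |
                 df$value_B > 1)
  if (length(bad))
    stop_introchoice(sprintf(
      "attribute values outside [0, 1] at data row %d (and %d more)",
      bad[1], length(bad) - 1L), "introchoice_range_error")
  if (!all(df$choice %in% c("A", "B")))
    stop_introchoice("choice column must contain only 'A' or 'B'",
                     "introchoice_schema_error")
  out <- lapply(split(df, df$participant_id), function(sub) {
    counts <- table(sub$trial)
    if (length(unique(counts)) != 1)
      stop_introchoice(sprintf(
        "participant '%s' has inconsistent attribute counts across trials",
        sub$participant_id[1]), "introchoice_schema_error")
    K <- unname(counts[1])
    sub <- sub[order(sub$trial, sub$attribute), ]
    n <- length(counts)
    if (!all(sub$attribute == rep(seq_len(K), times = n)))
      stop_introchoice(sprintf(
        "participant '%s' has irregular attribute indices",
        sub$participant_id[1]), "introchoice_schema_error")
    trials <- choice_trials(matrix(sub$value_A, n, K, byrow = TRUE),
                            matrix(sub$value_B, n, K, byrow = TRUE))
    choice_dataset(sub$participant_id[1], trials,
                   sub$choice[sub$attribute == 1])
  })
  out[order(names(out))]
}

#' Write / read self-reports as CSV
#'
#' One row per participant: `participant_id`, signed graded weights
#' `graded_1..K`, signed binary weights `binary_1..K`, `single_index` and
#' `single_sign` (the one-hot single-attribute report), and the three
#' heuristic-use extents `extent_single_attribute`, `extent_binary_weights`,
#' `extent_binary_values`.
#'
#' @param reports List of `self_report` objects (or a single one).
#' @param path File path.
#' @return `write_reports` returns `path` invisibly; `read_reports` a named
#'   list of `self_report` objects.
#' @export
write_reports <- function(reports, path) {
  if (inherits(reports, "self_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    K <- length(r$graded)
    row <- data.frame(participant_id = r$participant_id,
                      stringsAsFactors = FALSE)
    row[paste0("graded_", seq_len(K))] <- as.list(r$graded)
    row[paste0("binary_", seq_len(K))] <- as.list(r$binary)
    nz <- which(r$single != 0)
    row$single_index <- nz
    row$single_sign <- r$single[nz]
    row$extent_single_attribute <- r$heuristic_extents[[1]]
    row$extent_binary_weights <- r$heuristic_extents[[2]]
    row$extent_binary_values <- r$heuristic_extents[[3]]
    row
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reports
#' @export
read_reports <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  graded_cols <- grep("^graded_[0-9]+$", names(df), value = TRUE)
  K <- length(graded_cols)
  needed <- c("participant_id", paste0("graded_", seq_len(K)),
              paste0("binary_", seq_len(K)), "single_index", "single_sign",
              "extent_single_attribute", "extent_binary_weights",
              "extent_binary_values")
  missing <- setdiff(needed, names(df))
  if (K == 0 || length(missing))
    stop_introchoice(paste("reports file is missing columns:",
                           paste(if (K == 0) "graded_*" else missing,
                                 collapse = ", ")),
                     "introchoice_schema_error")
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    single <- numeric(K)
    if (!row$single_index %in% seq_len(K))
      stop_introchoice(sprintf("row %d: single_index out of range", i),
                       "introchoice_schema_error")
    single[row$single_index] <- row$single_sign
    self_report(row$participant_id,
                as.numeric(row[paste0("graded_", seq_len(K))]),
                as.numeric(row[paste0("binary_", seq_len(K))]),
                single,
                c(row$extent_single_attribute, row$extent_binary_weights,
                  row$extent_binary_values))
  })
  names(out) <- df$participant_id
  out[order(names(out))]
}

#' Serialize a participant fit to JSON
#'
#' Floats are written at full precision so reruns can be diffed; the file
#' embeds the schema version and the seed that produced the fit.
#'
#' @param fit A `participant_fit`.
#' @param path File path.
#' @return `write_participant_fit` returns `path` invisibly;
#'   `read_participant_fit` the deserialized `participant_fit`.
#' @export
write_participant_fit <- function(fit, path) {
  stopifnot(inherits(fit, "participant_fit"))
  payload <- list(
    schema_version = SCHEMA_VERSION,
    participant_id = fit$participant_id,
    seed = fit$seed,
    log_marginals = fit$log_marginals,
    model_probs = fit$model_probs,
    family_probs = as.list(fit$family_probs),
    averaged_w = fit$averaged_w,
    averaged_reported_w = fit$averaged_reported_w,
    fits = lapply(fit$fits, function(f) {
      list(model_id = f$spec$model_id, map_w = f$map_w,
           map_beta = f$map_beta, log_post = f$log_post,
           log_marginal = f$log_marginal, se = f$se,
           diagnostics = f$diagnostics)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_participant_fit
#' @export
read_participant_fit <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema_version(payload$schema_version %||% "0", "participant fit")
  fits <- lapply(seq_len(6), function(i) {
    f <- if (is.data.frame(payload$fits)) as.list(payload$fits[i, ])
         else payload$fits[[i]]
    list(spec = model_spec_from_id(f$model_id),
         map_w = unlist(f$map_w), map_beta = f$map_beta,
         log_post = f$log_post, log_marginal = f$log_marginal,
         se = f$se, diagnostics = f$diagnostics)
  })
  out <- list(participant_id = payload$participant_id,
              fits = fits,
              log_marginals = payload$log_marginals,
              model_probs = payload$model_probs,
              family_probs = unlist(payload$family_probs),
              averaged_w = payload$averaged_w,
              averaged_reported_w = payload$averaged_reported_w,
              seed = payload$seed)
  class(out) <- "participant_fit"
  out
}

#' Run configuration: every knob of a pipeline run in one object
#'
#' Round-trips losslessly through YAML or JSON; the hash of the effective
#' configuration can be embedded in outputs to tie artifacts to the run
#' that produced them.
#'
#' @param task A `task_config`.
#' @param prior A `prior_config`.
#' @param fit A `fit_config`.
#' @param n_per_model Deciders per model for simulation/recovery runs.
#' @param n_boot Bootstrap count for chance levels.
#' @param seed Master seed.
#' @param report_noise Report-noise level for simulated cohorts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(task = task_config(), prior = prior_config(),
                       fit = fit_config(), n_per_model = 10, n_boot = 1000,
                       seed = 1L, report_noise = 0) {
  structure(list(task = task, prior = prior, fit = fit,
                 n_per_model = as.integer(n_per_model),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 report_noise = report_noise),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config` to write.
#' @param path File path ending in `.yaml`, `.yml`, or `.json`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- list(schema_version = SCHEMA_VERSION,
                  task = unclass(config$task),
                  prior = unclass(config$prior),
                  fit = unclass(config$fit),
                  n_per_model = config$n_per_model,
                  n_boot = config$n_boot, seed = config$seed,
                  report_noise = config$report_noise)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(payload, path)
  else jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                            null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  payload <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
             else jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema_version(payload$schema_version %||% "0", "run config")
  run_config(task = do.call(task_config, payload$task[
                !vapply(payload$task, is.null, logical(1))]),
             prior = do.call(prior_config, payload$prior),
             fit = do.call(fit_config, payload$fit),
             n_per_model = payload$n_per_model,
             n_boot = payload$n_boot, seed = payload$seed,
             report_noise = payload$report_noise)
}

#' Deterministic hash of a run configuration
#'
#' @param config A `run_config`.
#' @return Character MD5 hash of the canonical JSON form.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}
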