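#' Configuration of a synthetic multi-attribute choice task
#'
#' Emulates the study design measured by this package: two options described
#' by K attributes, values scaled to `[0, 1]`, and the two options required
#' to differ substantially on every attribute so that each trial is
#' informative about every weight (and binary-values ties cannot occur).
#'
#' @param K Attribute count (default 9).
#' @param n_trials Trials per participant (default 100).
#' @param min_separation Minimum per-attribute difference between the two
#'   options, in (0, 1) (default 0.25).
#' @param value_grid Optional vector of discrete levels in `[0, 1]` to draw
#'   attribute values from (e.g. a 5-point scale); `NULL` means continuous
#'   uniform values.
#' @return An object of class `task_config`.
#' @export
task_config <- function(K = 9, n_trials = 100, min_separation = 0.25,
                        value_grid = NULL) {
  stopifnot(K >= 1, n_trials >= 1)
  if (!(min_separation > 0 && min_separation < 1))
    stop_introchoice("min_separation must lie strictly within (0, 1)",
                     "introchoice_infeasible_task")
  if (!is.null(value_grid)) {
    stopifnot(all(value_grid >= 0 & value_grid <= 1), length(value_grid) >= 2)
    value_grid <- sort(unique(value_grid))
    if (max(value_grid) - min(value_grid) < min_separation)
      stop_introchoice(
        "value_grid cannot satisfy min_separation: no two levels far enough apart",
        "introchoice_infeasible_task")
  }
  structure(list(K = as.integer(K), n_trials = as.integer(n_trials),
                 min_separation = min_separation, value_grid = value_grid),
            class = "task_config")
}

#' Generate choice trials with guaranteed per-attribute separation
#'
#' Attribute values are drawn uniformly (from `[0, 1]` or from the
#' configured grid) and rejection-sampled per attribute until
#' `|x_A - x_B| >= min_separation` holds everywhere.
#'
#' @param config A `task_config`.
#' @param seed Integer seed; the same seed reproduces the same trials.
#' @return A `choice_trials` object (choices unobserved).
#' @export
generate_trials <- function(config = task_config(), seed) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_trials * config$K
  draw <- if (is.null(config$value_grid)) {
    function(m) runif(m)
  } else {
    function(m) sample(config$value_grid, m, replace = TRUE)
  }
  local_seed(seed, {
    a <- draw(n); b <- draw(n)
    bad <- which(abs(a - b) < config$min_separation)
    guard <- 0L
    while (length(bad) > 0) {
      a[bad] <- draw(length(bad)); b[bad] <- draw(length(bad))
      bad <- bad[abs(a[bad] - b[bad]) < config$min_separation]
      guard <- guard + 1L
      if (guard > 10000L)
        stop_introchoice("separation constraint appears infeasible",
                         "introchoice_infeasible_task")
    }
    choice_trials(matrix(a, config$n_trials, config$K),
                  matrix(b, config$n_trials, config$K))
  })
}

#' A simulated decision-maker with a known choice process
#'
#' @param spec A `choice_model_spec` (the generating strategy).
#' @param w Attribute weights satisfying the spec.
#' @param beta Nonnegative inverse temperature.
#' @param report_noise Nonnegative noise level for simulated self-reports
#'   (0 = perfectly truthful).
#' @return An object of class `simulated_decider`.
#' @export
simulated_decider <- function(spec, w, beta, report_noise = 0) {
  validate_weights(spec, w)
  stopifnot(beta >= 0, report_noise >= 0)
  structure(list(spec = spec, w = as.numeric(w), beta = beta,
                 report_noise = report_noise),
            class = "simulated_decider")
}

#' Simulate a decider's choices on a set of trials
#'
#' Each choice is drawn independently with the decider's model choice
#' probability.
#'
#' @param decider A `simulated_decider`.
#' @param trials A `choice_trials` object.
#' @param seed Integer seed.
#' @param participant_id Identifier for the resulting dataset.
#' @return A `choice_dataset`.
#' @export
simulate_choices <- function(decider, trials, seed, participant_id = "sim") {
  stopifnot(inherits(decider, "simulated_decider"),
            inherits(trials, "choice_trials"))
  d <- value_diff_matrix(trials, decider$spec$binary_values)
  p_A <- plogis(decider$beta * drop(d %*% decider$w))
  choices <- local_seed(seed,
    ifelse(runif(length(p_A)) < p_A, "A", "B"))
  choice_dataset(participant_id, trials, choices)
}

# Truthful report formats implied by a weight vector: the binary-format
# answer includes an attribute when it carried at least half the maximal
# weight; the single-format answer names the largest-magnitude attribute
# (ties to the lowest index; an all-zero w defaults to attribute 1, +1).
truthful_report_formats <- function(w) {
  binary <- sign(w) * (abs(w) >= 0.5)
  single <- numeric(length(w))
  if (all(w == 0)) single[1] <- 1
  else {
    k <- which.max(abs(w))
    single[k] <- sign(w[k])
  }
  list(binary = binary, single = single)
}

#' Simulate a decider's self-report
#'
#' With `report_noise = 0` the report is perfectly truthful: the graded
#' weights equal the generating weights, the binary and single formats are
#' the binarized truth, and each heuristic-use extent is 1 if the generating
#' model uses that heuristic and 0 otherwise. With noise > 0, graded
#' magnitudes and extents receive additive Gaussian noise (sd =
#' `report_noise`) clipped back into range, signs flip independently with
#' probability `min(report_noise / 2, 0.5)`, and the binary/single formats
#' are re-derived from the noisy graded weights (so one coherent noisy
#' belief underlies all formats).
#'
#' @param decider A `simulated_decider`.
#' @param seed Integer seed.
#' @param participant_id Identifier.
#' @return A `self_report`.
#' @export
simulate_self_report <- function(decider, seed, participant_id = "sim") {
  stopifnot(inherits(decider, "simulated_decider"))
  spec <- decider$spec
  truth_extents <- c(single_attribute = as.numeric(spec$single_attribute),
                     binary_weights = as.numeric(spec$binary_weights),
                     binary_values = as.numeric(spec$binary_values))
  noise <- decider$report_noise
  if (noise == 0) {
    graded <- decider$w
    fmts <- if (is_discrete_spec(spec))
      list(binary = decider$w,
           single = truthful_report_formats(decider$w)$single)
    else truthful_report_formats(decider$w)
    return(self_report(participant_id, graded, fmts$binary, fmts$single,
                       truth_extents))
  }
  local_seed(seed, {
    K <- length(decider$w)
    mag <- pmin(pmax(abs(decider$w) + rnorm(K, 0, noise), 0), 1)
    sgn <- sign(decider$w)
    sgn[sgn == 0] <- sample(c(-1, 1), sum(sgn == 0), replace = TRUE)
    flip <- runif(K) < min(noise / 2, 0.5)
    graded <- sgn * ifelse(flip, -1, 1) * mag
    extents <- pmin(pmax(truth_extents + rnorm(3, 0, noise), 0), 1)
    fmts <- truthful_report_formats(graded)
    self_report(participant_id, graded, fmts$binary, fmts$single, extents)
  })
}

#' Generate a cohort of simulated deciders with ground truth
#'
#' Draws `n_per_model` deciders from each of the six models: continuous
#' weights uniform on `[-1, 1]` per attribute, discrete weights uniform over
#' the model's admissible configurations, and inverse temperatures from the
#' Gamma prior. Each decider then produces a trial set, choices, and a
#' self-report, all independently seeded from the master seed.
#'
#' @param n_per_model Deciders per model id (cohort size = 6 x n_per_model).
#' @param task A `task_config`.
#' @param prior A `prior_config` (source of the beta distribution).
#' @param seed Master integer seed.
#' @param report_noise Report noise passed to every decider.
#' @return List with `datasets` (list of `choice_dataset`), `reports` (list
#'   of `self_report`) and `truth` (data frame: participant_id, model_id,
#'   beta, plus the generating weights as a `w` matrix column).
#' @export
generate_cohort <- function(n_per_model, task = task_config(),
                            prior = prior_config(), seed, report_noise = 0) {
  stopifnot(n_per_model >= 1)
  n_total <- 6L * n_per_model
  seeds <- derive_seeds(seed, 4L * n_total + 1L)
  beta_seed <- seeds[1]
  # per decider: weights, trials, choices, report
  seeds <- matrix(seeds[-1], ncol = 4)
  betas <- local_seed(beta_seed,
                      rgamma(n_total, shape = prior$beta_shape,
                             rate = prior$beta_rate))
  datasets <- vector("list", n_total)
  reports <- vector("list", n_total)
  W <- matrix(NA_real_, n_total, task$K)
  model_ids <- rep(1:6, each = n_per_model)
  for (i in seq_len(n_total)) {
    spec <- model_spec_from_id(model_ids[i])
    w <- local_seed(seeds[i, 1], draw_weights(spec, task$K))
    pid <- sprintf("sim%03d", i)
    decider <- simulated_decider(spec, w, betas[i], report_noise)
    trials <- generate_trials(task, seed = seeds[i, 2])
    datasets[[i]] <- simulate_choices(decider, trials, seed = seeds[i, 3],
                                      participant_id = pid)
    reports[[i]] <- simulate_self_report(decider, seed = seeds[i, 4],
                                         participant_id = pid)
    W[i, ] <- w
  }
  truth <- data.frame(participant_id = sprintf("sim%03d", seq_len(n_total)),
                      model_id = model_ids, beta = betas)
  truth$w <- W
  list(datasets = datasets, reports = reports, truth = truth)
}

# Draw a weight vector uniformly from a model's prior (assumes RNG state set).
draw_weights <- function(spec, K) {
  if (!is_discrete_spec(spec)) return(runif(K, -1, 1))
  if (spec$single_attribute) {
    w <- numeric(K)
    w[sample.int(K, 1)] <- sample(c(-1, 1), 1)
    w
  } else {
    sample(c(-1, 0, 1), K, replace = TRUE)
  }
}
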