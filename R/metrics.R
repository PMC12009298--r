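#' Pearson correlation between fitted and reported attribute weights
#'
#' The primary weight-accuracy measure: the per-participant Pearson
#' correlation across attributes between the model-averaged best-fit weights
#' and the model-averaged self-reported weights. Both are continuous in
#' `[-1, 1]` and neither is constrained to sum to a constant, so they are
#' directly comparable; the correlation is also invariant to the overall
#' scale of either vector. When either vector is constant the correlation is
#' undefined and `NA` is returned (callers exclude such participants from
#' cohort averages).
#'
#' @param fitted,reported Numeric K-vectors (K >= 3).
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
weight_correlation <- function(fitted, reported) {
  if (length(fitted) != length(reported))
    stop_introchoice("weight vectors must have equal length",
                     "introchoice_length_mismatch")
  stopifnot(length(fitted) >= 3)
  if (sd(fitted) == 0 || sd(reported) == 0) return(NA_real_)
  cor(fitted, reported)
}

#' Mean absolute difference between fitted and reported weights
#'
#' @param fitted,reported Numeric K-vectors.
#' @return Mean element-wise absolute difference, in `[0, 2]`.
#' @export
absolute_weight_error <- function(fitted, reported) {
  if (length(fitted) != length(reported))
    stop_introchoice("weight vectors must have equal length",
                     "introchoice_length_mismatch")
  mean(abs(fitted - reported))
}

#' Heuristic error: reported extents vs. model-estimated probabilities
#'
#' The absolute difference between the reported extent of using each
#' heuristic and the model-estimated (family posterior) probability of using
#' it, averaged across the three heuristics.
#'
#' @param family_probs Numeric 3-vector of heuristic-family probabilities.
#' @param extents Numeric 3-vector of reported heuristic-use extents.
#' @return Mean absolute difference, in `[0, 1]`.
#' @export
heuristic_error <- function(family_probs, extents) {
  stopifnot(length(family_probs) == 3, length(extents) == 3)
  if (any(family_probs < 0 | family_probs > 1 | extents < 0 | extents > 1))
    stop_introchoice("family probabilities and extents must lie in [0, 1]",
                     "introchoice_range_error")
  mean(abs(family_probs - extents))
}

#' The overall choice model implied by a participant's heuristic reports
#'
#' Dichotomizes each reported heuristic-use extent at 50%: an extent above
#' 0.5 counts as "used the heuristic", at or below 0.5 as "did not". When
#' both single_attribute and binary_weights exceed 0.5 (a combination no
#' model allows), single_attribute takes precedence, since it is the special
#' case subsumed by binary weights; the conflict is signalled as a warning.
#'
#' @param report A `self_report` (or a bare length-3 extents vector).
#' @return The reported `choice_model_spec`.
#' @export
reported_model <- function(report) {
  extents <- if (inherits(report, "self_report")) report$heuristic_extents
             else report
  stopifnot(length(extents) == 3, all(extents >= 0 & extents <= 1))
  sa <- extents[1] > 0.5
  bw <- extents[2] > 0.5
  bv <- extents[3] > 0.5
  if (sa && bw) {
    warning("single_attribute and binary_weights both reported > 0.5; ",
            "single_attribute takes precedence", call. = FALSE)
    bw <- FALSE
  }
  model_spec(single_attribute = sa, binary_weights = bw, binary_values = bv)
}

#' Bayes factor of the reported model relative to the best-fitting model
#'
#' The model-estimated posterior probability of the participant's reported
#' choice method divided by that of the most likely method; 1 means the
#' participant reported the best-fitting method.
#'
#' @param model_probs Numeric 6-simplex.
#' @param reported A `choice_model_spec` (the reported model).
#' @return Value in `[0, 1]`.
#' @export
reported_model_bayes_factor <- function(model_probs, reported) {
  stopifnot(length(model_probs) == 6,
            inherits(reported, "choice_model_spec"))
  model_probs[reported$model_id] / max(model_probs)
}

#' Did the participant report the overall best-fitting choice method?
#'
#' @param model_probs Numeric 6-simplex.
#' @param reported A `choice_model_spec`.
#' @return Logical; ties in the argmax are broken towards the lowest model
#'   id. Under uniform random reporting over the six methods, this is true
#'   with probability 1/6 (the analytic chance level).
#' @export
correct_method <- function(model_probs, reported) {
  stopifnot(length(model_probs) == 6,
            inherits(reported, "choice_model_spec"))
  which.max(model_probs) == reported$model_id
}

#' All accuracy metrics for one participant
#'
#' @param fit A `participant_fit`.
#' @param report The participant's `self_report`.
#' @return One-row data frame: weight_correlation, absolute_weight_error,
#'   heuristic_error, reported_model_id, reported_model_bayes_factor,
#'   correct_method.
#' @export
accuracy_metrics <- function(fit, report) {
  stopifnot(inherits(fit, "participant_fit"), inherits(report, "self_report"))
  rep_w <- model_averaged_reported_weights(report, fit$model_probs)
  rm <- suppressWarnings(reported_model(report))
  data.frame(
    participant_id = fit$participant_id,
    weight_correlation = weight_correlation(fit$averaged_w, rep_w),
    absolute_weight_error = absolute_weight_error(fit$averaged_w, rep_w),
    heuristic_error = heuristic_error(fit$family_probs,
                                      report$heuristic_extents),
    reported_model_id = rm$model_id,
    reported_model_bayes_factor =
      reported_model_bayes_factor(fit$model_probs, rm),
    correct_method = correct_method(fit$model_probs, rm),
    stringsAsFactors = FALSE)
}

#' Metrics table for a cohort
#'
#' @param fits List of `participant_fit` objects.
#' @param reports List of matching `self_report` objects (same order).
#' @return Data frame with one row per participant.
#' @export
cohort_metrics <- function(fits, reports) {
  stopifnot(length(fits) == length(reports))
  do.call(rbind, Map(accuracy_metrics, fits, reports))
}

#' Chance levels of the accuracy metrics by report re-pairing
#'
#' Estimates what each metric would be if reports carried no information
#' about the reporter's own fitted process: reports are randomly re-paired
#' with other participants' fits `n_boot` times and each metric is averaged
#' over re-pairings and participants. The chance level of `correct_method`
#' is additionally reported analytically as 1/6 (six possible methods under
#' uniform guessing).
#'
#' @param fits List of at least two `participant_fit` objects.
#' @param reports Matching list of `self_report` objects.
#' @param n_boot Number of random re-pairings (default 1000).
#' @param seed Integer seed.
#' @return List with `chance` (named means over re-pairings),
#'   `correct_method_analytic` (= 1/6), `n_boot`, and `seed`.
#' @export
chance_levels <- function(fits, reports, n_boot = 1000, seed = 1L) {
  n <- length(fits)
  if (n < 2)
    stop_introchoice("chance levels require at least two participants",
                     "introchoice_too_few_participants")
  stopifnot(length(reports) == n)
  perms <- local_seed(seed,
                      replicate(n_boot, sample.int(n), simplify = FALSE))
  acc <- vapply(perms, function(idx) {
    m <- cohort_metrics(fits, reports[idx])
    c(weight_correlation = mean(m$weight_correlation, na.rm = TRUE),
      absolute_weight_error = mean(m$absolute_weight_error),
      heuristic_error = mean(m$heuristic_error),
      reported_model_bayes_factor = mean(m$reported_model_bayes_factor),
      correct_method = mean(m$correct_method))
  }, numeric(5))
  list(chance = rowMeans(acc), correct_method_analytic = 1 / 6,
       n_boot = n_boot, seed = seed)
}
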