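#' Construct a set of two-alternative choice trials
#'
#' @param x_A,x_B Numeric matrices (n_trials x K) of attribute values in
#'   `[0, 1]` for options A and B.
#' @return An object of class `choice_trials`.
#' @export
choice_trials <- function(x_A, x_B) {
  x_A <- as.matrix(x_A); x_B <- as.matrix(x_B)
  stopifnot(identical(dim(x_A), dim(x_B)))
  if (any(x_A < 0 | x_A > 1 | x_B < 0 | x_B > 1))
    stop_introchoice("attribute values must lie in [0, 1]",
                     "introchoice_range_error")
  structure(list(x_A = x_A, x_B = x_B), class = "choice_trials")
}

#' @export
print.choice_trials <- function(x, ...) {
  cat(sprintf("<choice_trials: %d trials x %d attributes>\n",
              nrow(x$x_A), ncol(x$x_A)))
  invisible(x)
}

#' A participant's choice dataset: trials plus observed choices
#'
#' @param participant_id Identifier (coerced to character).
#' @param trials A `choice_trials` object.
#' @param choices Character vector of "A"/"B", one per trial.
#' @return An object of class `choice_dataset` with a precomputed
#'   `choice_sign` (+1 where A was chosen, -1 where B was).
#' @export
choice_dataset <- function(participant_id, trials, choices) {
  stopifnot(inherits(trials, "choice_trials"))
  choices <- as.character(choices)
  if (length(choices) != nrow(trials$x_A))
    stop_introchoice("one observed choice is required per trial",
                     "introchoice_schema_error")
  if (!all(choices %in% c("A", "B")))
    stop_introchoice("choices must be 'A' or 'B'", "introchoice_schema_error")
  structure(list(participant_id = as.character(participant_id),
                 trials = trials,
                 choices = choices,
                 choice_sign = ifelse(choices == "A", 1, -1)),
            class = "choice_dataset")
}

#' @export
print.choice_dataset <- function(x, ...) {
  cat(sprintf("<choice_dataset '%s': %d trials x %d attributes, %d%% A>\n",
              x$participant_id, n_trials(x), n_attributes(x),
              round(100 * mean(x$choices == "A"))))
  invisible(x)
}

#' Number of trials / attributes in a choice dataset
#' @param data A `choice_dataset`.
#' @export
n_trials <- function(data) {
  if (inherits(data, "choice_trials")) nrow(data$x_A) else nrow(data$trials$x_A)
}

#' @rdname n_trials
#' @export
n_attributes <- function(data) {
  if (inherits(data, "choice_trials")) ncol(data$x_A) else ncol(data$trials$x_A)
}

#' A participant's self-report of their choice process
#'
#' Participants (or observers) report their attribute weights in three
#' formats — graded (signed, in `[-1, 1]`, magnitude from a 0-100 scale
#' rescaled to 0-1 with sign from separate direction questions), binary
#' (signed, in \{-1, 0, 1\}: which attributes were in play at all), and
#' single-attribute (a signed one-hot vector: the one most-used attribute) —
#' plus the extent, in `[0, 1]`, to which they believe they used each of the
#' three heuristics (single_attribute, binary_weights, binary_values).
#'
#' @param participant_id Identifier.
#' @param graded Signed numeric K-vector in `[-1, 1]`.
#' @param binary Signed numeric K-vector with entries in \{-1, 0, 1\}.
#' @param single Signed one-hot K-vector (exactly one entry is ±1).
#' @param heuristic_extents Named or unnamed length-3 numeric in `[0, 1]`,
#'   ordered (single_attribute, binary_weights, binary_values).
#' @return An object of class `self_report`.
#' @export
self_report <- function(participant_id, graded, binary, single,
                        heuristic_extents) {
  K <- length(graded)
  stopifnot(length(binary) == K, length(single) == K,
            length(heuristic_extents) == 3)
  if (any(abs(graded) > 1))
    stop_introchoice("graded weights must lie in [-1, 1]",
                     "introchoice_range_error")
  if (!all(binary %in% c(-1, 0, 1)))
    stop_introchoice("binary weights must be in {-1, 0, 1}",
                     "introchoice_range_error")
  nz <- which(single != 0)
  if (length(nz) != 1 || !single[nz] %in% c(-1, 1))
    stop_introchoice("single-attribute report must be one-hot with value +-1",
                     "introchoice_invariant_error")
  if (any(heuristic_extents < 0 | heuristic_extents > 1))
    stop_introchoice("heuristic extents must lie in [0, 1]",
                     "introchoice_range_error")
  structure(list(participant_id = as.character(participant_id),
                 graded = as.numeric(graded),
                 binary = as.numeric(binary),
                 single = as.numeric(single),
                 heuristic_extents = setNames(as.numeric(heuristic_extents),
                                              c("single_attribute",
                                                "binary_weights",
                                                "binary_values"))),
            class = "self_report")
}

#' @export
print.self_report <- function(x, ...) {
  cat(sprintf("<self_report '%s': K=%d, extents (%.2f, %.2f, %.2f)>\n",
              x$participant_id, length(x$graded),
              x$heuristic_extents[1], x$heuristic_extents[2],
              x$heuristic_extents[3]))
  invisible(x)
}

#' Priors used by every model fit
#'
#' Weights get a uniform prior: a continuous box on `[-1, 1]^K` for models
#' 1-2, a discrete uniform over the enumerated configurations for models
#' 3-6. The inverse temperature gets a Gamma prior, shape-rate
#' parameterized (the default Gamma(4, 1) has mean 4).
#'
#' @param beta_shape,beta_rate Gamma shape and rate for the inverse
#'   temperature prior.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(beta_shape = 4, beta_rate = 1) {
  stopifnot(beta_shape > 0, beta_rate > 0)
  structure(list(beta_shape = beta_shape, beta_rate = beta_rate),
            class = "prior_config")
}
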