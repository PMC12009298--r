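#' The six-model family of multi-attribute choice strategies
#'
#' All models share a weighted-additive softmax core: each option's value is a
#' linear combination of its (possibly transformed) attribute values with
#' signed attribute weights, and the probability of choosing option A is a
#' logistic function of an inverse temperature times the value difference.
#' Three composable heuristics simplify the core process:
#'
#' * **single_attribute** ("take the best" / lexicographic): exactly one
#'   weight is ±1 and all others are 0.
#' * **binary_weights** ("equal weights"): every weight is in \{-1, 0, 1\} —
#'   attributes are either in (equally weighted, with a direction) or out.
#' * **binary_values** ("weighted pros"): per attribute, only which option is
#'   greater is represented — the greater option's value becomes 1, the
#'   other's 0.
#'
#' `single_attribute` and `binary_weights` cannot be combined because the
#' former is a special case of the latter. The six valid combinations are
#' numbered: 1 = none ("classically rational" weighted-additive rule),
#' 2 = binary_values, 3 = binary_weights, 4 = binary_weights + binary_values,
#' 5 = single_attribute, 6 = single_attribute + binary_values.
#'
#' @param single_attribute,binary_weights,binary_values Logical flags naming
#'   the heuristics the strategy uses.
#' @return An object of class `choice_model_spec`: a list with the three
#'   flags and `model_id` (1..6).
#' @examples
#' model_spec(single_attribute = TRUE, binary_values = TRUE)$model_id # 6
#' @export
model_spec <- function(single_attribute = FALSE, binary_weights = FALSE,
                       binary_values = FALSE) {
  stopifnot(is.logical(single_attribute), is.logical(binary_weights),
            is.logical(binary_values))
  if (single_attribute && binary_weights)
    stop_introchoice(paste0(
      "invalid heuristic combination: single_attribute cannot be combined ",
      "with binary_weights (the former is a special case of the latter)"),
      "introchoice_invalid_combination")
  id <- if (single_attribute) 5L + as.integer(binary_values)
        else if (binary_weights) 3L + as.integer(binary_values)
        else 1L + as.integer(binary_values)
  structure(list(single_attribute = single_attribute,
                 binary_weights = binary_weights,
                 binary_values = binary_values,
                 model_id = id),
            class = "choice_model_spec")
}

#' @export
print.choice_model_spec <- function(x, ...) {
  used <- c("single_attribute", "binary_weights", "binary_values")[
    c(x$single_attribute, x$binary_weights, x$binary_values)]
  cat(sprintf("<choice model %d: %s>\n", x$model_id,
              if (length(used)) paste(used, collapse = " + ")
              else "classically rational (no heuristics)"))
  invisible(x)
}

#' Look up a model specification by its id
#'
#' @param model_id Integer 1..6.
#' @return A `choice_model_spec`.
#' @export
model_spec_from_id <- function(model_id) {
  stopifnot(length(model_id) == 1, model_id %in% 1:6)
  all_model_specs()[[as.integer(model_id)]]
}

#' All six valid model specifications, in id order
#' @return List of six `choice_model_spec` objects.
#' @export
all_model_specs <- function() {
  list(model_spec(FALSE, FALSE, FALSE),
       model_spec(FALSE, FALSE, TRUE),
       model_spec(FALSE, TRUE, FALSE),
       model_spec(FALSE, TRUE, TRUE),
       model_spec(TRUE, FALSE, FALSE),
       model_spec(TRUE, FALSE, TRUE))
}

# Continuous-weight models (1-2) have free weights in [-1,1]^K; the discrete
# models (3-6) restrict weights to finitely many configurations.
is_discrete_spec <- function(spec) spec$binary_weights || spec$single_attribute

#' Check a weight vector against a model's constraints
#'
#' @param spec A `choice_model_spec`.
#' @param w Numeric weight vector.
#' @param tol Tolerance for the discrete-value checks.
#' @return `TRUE` invisibly; errors if `w` violates the spec.
#' @export
validate_weights <- function(spec, w, tol = 1e-8) {
  stopifnot(inherits(spec, "choice_model_spec"), is.numeric(w), length(w) >= 1)
  if (any(!is.finite(w)))
    stop_introchoice("weights must be finite", "introchoice_constraint_violation")
  if (any(abs(w) > 1 + tol))
    stop_introchoice("weights must lie in [-1, 1]",
                     "introchoice_constraint_violation")
  if (spec$single_attribute) {
    nz <- which(abs(w) > tol)
    ok <- length(nz) == 1 && abs(abs(w[nz]) - 1) <= tol
    if (!ok)
      stop_introchoice(
        "single-attribute models require exactly one weight of +1 or -1",
        "introchoice_constraint_violation")
  } else if (spec$binary_weights) {
    if (any(pmin(abs(w), abs(abs(w) - 1)) > tol))
      stop_introchoice("binary-weights models require weights in {-1, 0, 1}",
                       "introchoice_constraint_violation")
  }
  invisible(TRUE)
}

#' Transform a trial's attribute values under the binary-values heuristic
#'
#' With `binary_values` unset the raw values pass through unchanged. With it
#' set, each attribute is reduced to which option is greater: the greater
#' option's value becomes 1 and the other's 0. An exact tie maps both to 0.5
#' so the attribute contributes nothing to the value difference.
#'
#' @param x_A,x_B Numeric vectors of K attribute values in `[0, 1]`.
#' @param binary_values Logical flag.
#' @return List with transformed `x_A` and `x_B`.
#' @export
transform_attribute_values <- function(x_A, x_B, binary_values = FALSE) {
  stopifnot(length(x_A) == length(x_B))
  if (!binary_values) return(list(x_A = x_A, x_B = x_B))
  a <- ifelse(x_A > x_B, 1, ifelse(x_A < x_B, 0, 0.5))
  list(x_A = a, x_B = 1 - a)
}

# Per-trial signed value differences w-ready: rows = trials, cols = attributes.
# Returns the matrix of (transformed) x_A - x_B.
value_diff_matrix <- function(trials, binary_values = FALSE) {
  d <- trials$x_A - trials$x_B
  if (binary_values) d <- sign(d)  # 1/0 coding differences are exactly sign()
  d
}

#' Probability of choosing option A
#'
#' `P(A) = logistic(beta * (w . x~_A - w . x~_B))` where `x~` are the
#' attribute values after the model's `binary_values` transform. The softmax
#' over two options reduces to this logistic of the value difference.
#'
#' @param spec A `choice_model_spec`.
#' @param w Attribute weights satisfying the spec's constraints.
#' @param beta Nonnegative inverse temperature.
#' @param x_A,x_B Attribute-value vectors in `[0, 1]`.
#' @return Probability in (0, 1).
#' @examples
#' s5 <- model_spec(single_attribute = TRUE)
#' choice_probability(s5, c(1, 0), 3, x_A = c(0.8, 0.1), x_B = c(0.2, 0.9))
#' @export
choice_probability <- function(spec, w, beta, x_A, x_B) {
  validate_weights(spec, w)
  stopifnot(beta >= 0, length(x_A) == length(w), length(x_B) == length(w))
  tv <- transform_attribute_values(x_A, x_B, spec$binary_values)
  plogis(beta * sum(w * (tv$x_A - tv$x_B)))
}

#' Log-likelihood of a choice dataset under one model
#'
#' Sums, over trials, the log probability of the observed choice. Trials are
#' conditionally independent given the parameters. An empty dataset has
#' log-likelihood 0.
#'
#' @param spec A `choice_model_spec`.
#' @param w Attribute weights satisfying the spec's constraints.
#' @param beta Nonnegative inverse temperature.
#' @param data A `choice_dataset` (see [choice_dataset()]).
#' @return Scalar log-probability.
#' @export
log_likelihood <- function(spec, w, beta, data) {
  validate_weights(spec, w)
  stopifnot(inherits(data, "choice_dataset"), beta >= 0)
  if (n_trials(data) == 0) return(0)
  d <- value_diff_matrix(data$trials, spec$binary_values)
  v <- drop(d %*% w) * data$choice_sign  # + favours the observed choice
  sum(log_logistic(beta * v))
}

#' Enumerate all admissible weight configurations of a discrete model
#'
#' For binary-weights models every weight independently takes a value in
#' \{-1, 0, 1\} (3^K configurations, the all-zero one included); for
#' single-attribute models exactly one weight is ±1 (2K configurations).
#' Continuous models are not enumerable.
#'
#' @param spec A `choice_model_spec` with `model_id` in 3..6.
#' @param K Number of attributes.
#' @return Matrix with one row per configuration and K columns, in a fixed
#'   deterministic order (row index is the configuration index used for
#'   tie-breaking).
#' @export
enumerate_weight_configs <- function(spec, K) {
  stopifnot(inherits(spec, "choice_model_spec"), K >= 1)
  if (!is_discrete_spec(spec))
    stop_introchoice(
      "continuous-weight models (ids 1-2) have no enumerable configurations",
      "introchoice_not_enumerable")
  if (spec$single_attribute) {
    cfg <- matrix(0, nrow = 2L * K, ncol = K)
    for (k in seq_len(K)) {
      cfg[2L * k - 1L, k] <- 1
      cfg[2L * k, k] <- -1
    }
    cfg
  } else {
    grid <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), K),
                                  KEEP.OUT.ATTRS = FALSE))
    dimnames(grid) <- NULL
    grid
  }
}
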