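test_that("the heuristic flags map to the six model ids in canonical order", {
  cases <- list(
    list(FALSE, FALSE, FALSE, 1L),
    list(FALSE, FALSE, TRUE, 2L),
    list(FALSE, TRUE, FALSE, 3L),
    list(FALSE, TRUE, TRUE, 4L),
    list(TRUE, FALSE, FALSE, 5L),
    list(TRUE, FALSE, TRUE, 6L))
  for (cs in cases) {
    spec <- model_spec(single_attribute = cs[[1]], binary_weights = cs[[2]],
                       binary_values = cs[[3]])
    expect_identical(spec$model_id, cs[[4]])
    expect_identical(model_spec_from_id(cs[[4]]), spec)
  }
  ids <- vapply(all_model_specs(), `[[`, integer(1), "model_id")
  expect_identical(ids, 1:6)
})

test_that("single_attribute + binary_weights is rejected", {
  expect_error(model_spec(single_attribute = TRUE, binary_weights = TRUE),
               class = "introchoice_invalid_combination")
  expect_error(model_spec(TRUE, TRUE, TRUE),
               class = "introchoice_invalid_combination")
})

test_that("weight constraints are enforced per model class", {
  expect_silent(validate_weights(model_spec_from_id(1), c(0.3, -0.7, 1)))
  expect_error(validate_weights(model_spec_from_id(1), c(0.3, 1.4)),
               class = "introchoice_constraint_violation")
  expect_silent(validate_weights(model_spec_from_id(3), c(-1, 0, 1)))
  expect_error(validate_weights(model_spec_from_id(3), c(0.5, 0, 1)),
               class = "introchoice_constraint_violation")
  expect_silent(validate_weights(model_spec_from_id(5), c(0, -1, 0)))
  expect_error(validate_weights(model_spec_from_id(5), c(1, -1, 0)),
               class = "introchoice_constraint_violation")
  expect_error(validate_weights(model_spec_from_id(5), c(0, 0, 0)),
               class = "introchoice_constraint_violation")
})

test_that("binary-values transform keeps winners, losers, and ties", {
  tv <- transform_attribute_values(c(0.8, 0.3), c(0.2, 0.9),
                                   binary_values = TRUE)
  expect_equal(tv$x_A, c(1, 0))
  expect_equal(tv$x_B, c(0, 1))
  tie <- transform_attribute_values(c(0.5, 0.5), c(0.5, 0.5),
                                    binary_values = TRUE)
  expect_equal(tie$x_A, c(0.5, 0.5))
  expect_equal(tie$x_B, c(0.5, 0.5))
  ident <- transform_attribute_values(c(0.8, 0.3), c(0.2, 0.9),
                                      binary_values = FALSE)
  expect_identical(ident$x_A, c(0.8, 0.3))
  expect_identical(ident$x_B, c(0.2, 0.9))
})

test_that("choice probability follows the logistic closed form", {
  s5 <- model_spec_from_id(5)
  w <- c(1, rep(0, 8))
  x_A <- c(0.8, rep(0.5, 8)); x_B <- c(0.2, rep(0.5, 8))
  expect_equal(choice_probability(s5, w, 3, x_A, x_B),
               1 / (1 + exp(-1.8)), tolerance = 1e-12)
  # all-zero weights are indifferent under every model that admits them
  for (id in 1:4) {
    spec <- model_spec_from_id(id)
    expect_equal(choice_probability(spec, rep(0, 9), 2.5, x_A, x_B), 0.5)
  }
  # inconsistent weights are rejected
  expect_error(choice_probability(s5, c(0.5, rep(0, 8)), 1, x_A, x_B),
               class = "introchoice_constraint_violation")
})

test_that("choice probabilities of the two options always sum to one", {
  set.seed(101)
  for (rep_i in 1:50) {
    id <- sample(1:6, 1)
    spec <- model_spec_from_id(id)
    K <- sample(2:6, 1)
    w <- if (id %in% 1:2) runif(K, -1, 1)
         else if (id %in% 3:4) sample(c(-1, 0, 1), K, replace = TRUE)
         else { w0 <- numeric(K); w0[sample.int(K, 1)] <- sample(c(-1, 1), 1); w0 }
    beta <- rgamma(1, 4, 1)
    x_A <- runif(K); x_B <- runif(K)
    p_A <- choice_probability(spec, w, beta, x_A, x_B)
    p_B <- choice_probability(spec, w, beta, x_B, x_A)
    expect_equal(p_A + p_B, 1, tolerance = 1e-12)
  }
})

test_that("with a single positive weight, P(A) is monotone in that attribute", {
  spec <- model_spec_from_id(5)
  w <- c(0, 1, 0)
  xs <- seq(0, 1, by = 0.05)
  p <- vapply(xs, function(x)
    choice_probability(spec, w, 2, c(0.5, x, 0.5), c(0.5, 0.4, 0.5)),
    numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("log-likelihood matches a trial-by-trial oracle and its identities", {
  for (id in 1:6) {
    fix <- make_small_dataset(seed = 40 + id, K = 3, n_trials = 15,
                              model_id = id, beta = 2)
    ll <- log_likelihood(fix$spec, fix$w, 2, fix$data)
    expect_equal(ll, oracle_loglik(fix$w, 2, fix$data,
                                   fix$spec$binary_values),
                 tolerance = 1e-10)
  }
  # indifference: beta = 0 gives n * log(1/2)
  fix <- make_small_dataset(seed = 7, K = 3, n_trials = 20)
  expect_equal(log_likelihood(fix$spec, fix$w, 0, fix$data), 20 * log(0.5))
  # empty dataset has log-likelihood 0
  empty <- choice_dataset("p0",
                          choice_trials(matrix(numeric(0), 0, 3),
                                        matrix(numeric(0), 0, 3)),
                          character(0))
  expect_identical(log_likelihood(fix$spec, fix$w, 1, empty), 0)
})

test_that("continuous models are invariant to the beta*w rescaling", {
  fix <- make_small_dataset(seed = 9, K = 4, n_trials = 25, model_id = 1,
                            beta = 3)
  spec <- model_spec_from_id(1)
  set.seed(2); w <- runif(4, -0.5, 0.5)
  expect_equal(log_likelihood(spec, w, 4, fix$data),
               log_likelihood(spec, w / 2, 8, fix$data), tolerance = 1e-10)
})

test_that("a one-hot binary-weights likelihood equals the single-attribute one", {
  fix <- make_small_dataset(seed = 13, K = 4, n_trials = 25, model_id = 5,
                            beta = 3)
  w <- c(0, 0, -1, 0)
  expect_equal(log_likelihood(model_spec_from_id(5), w, 2.5, fix$data),
               log_likelihood(model_spec_from_id(3), w, 2.5, fix$data))
})

test_that("binary-values likelihood depends only on attribute order", {
  fix <- make_small_dataset(seed = 17, K = 3, n_trials = 20, model_id = 2,
                            beta = 2)
  spec <- model_spec_from_id(2)
  set.seed(3); w <- runif(3, -1, 1)
  base <- log_likelihood(spec, w, 2, fix$data)
  # strictly monotone per-attribute rescaling: x -> x^3 (order-preserving)
  warped <- choice_dataset(
    "warp",
    choice_trials(fix$data$trials$x_A^3, fix$data$trials$x_B^3),
    fix$data$choices)
  expect_equal(log_likelihood(spec, w, 2, warped), base, tolerance = 1e-10)
})

test_that("weight-configuration enumeration is exhaustive and duplicate-free", {
  expect_equal(nrow(enumerate_weight_configs(model_spec_from_id(5), 9)), 18)
  expect_equal(nrow(enumerate_weight_configs(model_spec_from_id(3), 9)),
               3^9)
  cfg2 <- enumerate_weight_configs(model_spec_from_id(3), 2)
  expect_equal(nrow(cfg2), 9)
  expect_equal(nrow(unique(cfg2)), 9)
  cfg5 <- enumerate_weight_configs(model_spec_from_id(5), 4)
  expect_equal(nrow(unique(cfg5)), 8)
  expect_true(all(rowSums(cfg5 != 0) == 1))
  # the same sets as the constructive oracle, regardless of ordering
  ref <- oracle_enumerate(FALSE, 3)
  got <- enumerate_weight_configs(model_spec_from_id(4), 3)
  key <- function(m) sort(apply(m, 1, paste, collapse = ","))
  expect_identical(key(got), key(ref))
  expect_error(enumerate_weight_configs(model_spec_from_id(1), 3),
               class = "introchoice_not_enumerable")
})
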