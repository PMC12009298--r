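test_that("posterior model probabilities normalize log marginals", {
  expect_equal(posterior_model_probabilities(rep(-3.7, 6)), rep(1 / 6, 6))
  expect_equal(posterior_model_probabilities(c(log(2), 0, 0, 0, 0, 0)),
               c(2, 1, 1, 1, 1, 1) / 7, tolerance = 1e-12)
  # large offsets do not overflow
  p <- posterior_model_probabilities(c(-1000, -1001, -1002, -1000, -1005,
                                       -1000))
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("heuristic-family probabilities sum the right models", {
  one_hot <- function(i) { p <- rep(0, 6); p[i] <- 1; p }
  expect_equal(unname(heuristic_family_probabilities(one_hot(1))),
               c(0, 0, 0))
  expect_equal(unname(heuristic_family_probabilities(one_hot(6))),
               c(1, 0, 1))
  expect_equal(unname(heuristic_family_probabilities(rep(1 / 6, 6))),
               c(1 / 3, 1 / 3, 1 / 2), tolerance = 1e-12)
  # each family probability equals the summed probability of its users
  set.seed(21)
  p <- posterior_model_probabilities(rnorm(6))
  fam <- heuristic_family_probabilities(p)
  expect_equal(unname(fam),
               c(p[5] + p[6], p[3] + p[4], p[2] + p[4] + p[6]))
})

test_that("model-averaged weights are the probability-weighted mean", {
  W <- rbind(c(0.5, -0.5), c(1, 0), c(-1, 1), c(0, 0), c(1, 0), c(0, -1))
  one_hot <- function(i) { p <- rep(0, 6); p[i] <- 1; p }
  expect_equal(model_averaged_weights(W, one_hot(3)), c(-1, 1))
  expect_equal(model_averaged_weights(W, c(0.5, 0.5, 0, 0, 0, 0)),
               c(0.75, -0.25))
  set.seed(4)
  p <- posterior_model_probabilities(rnorm(6))
  expect_true(all(abs(model_averaged_weights(W, p)) <= 1))
})

test_that("model-averaged reported weights blend the three report formats", {
  rep1 <- self_report("p1", graded = c(0.8, 0.2), binary = c(1, 0),
                      single = c(1, 0), heuristic_extents = c(0, 0, 0))
  expect_equal(model_averaged_reported_weights(rep1,
                                               c(0.5, 0, 0.5, 0, 0, 0)),
               c(0.9, 0.1))
  expect_equal(model_averaged_reported_weights(rep1,
                                               c(0, 0, 0, 0, 0.3, 0.7)),
               c(1, 0))
  set.seed(5)
  p <- posterior_model_probabilities(rnorm(6))
  expect_true(all(abs(model_averaged_reported_weights(rep1, p)) <= 1))
})

test_that("discrete MAP matches an exhaustive config-by-config oracle", {
  prior <- prior_config()
  for (fix_seed in c(3, 11, 19)) {
    fix <- make_small_dataset(seed = fix_seed, K = 3, n_trials = 20,
                              model_id = 4, beta = 4)
    for (id in 3:6) {
      spec <- model_spec_from_id(id)
      got <- fit_map(spec, fix$data, prior, fast_fit_config())
      cfgs <- enumerate_weight_configs(spec, 3)
      # oracle: optimize beta separately for every configuration
      best_lp <- -Inf; best_w <- NULL
      for (ci in seq_len(nrow(cfgs))) {
        obj <- function(b) {
          v <- oracle_loglik(cfgs[ci, ], b, fix$data, spec$binary_values) +
            dgamma(b, 4, 1, log = TRUE)
          if (is.finite(v)) v else -1e10  # naive log(0) underflow
        }
        opt <- optimize(obj, c(1e-6, 50), maximum = TRUE, tol = 1e-9)
        if (opt$objective > best_lp + 1e-10) {
          best_lp <- opt$objective; best_w <- cfgs[ci, ]
        }
      }
      expect_equal(got$log_post, best_lp - log(nrow(cfgs)), tolerance = 1e-6)
      expect_equal(unname(got$map_w), unname(best_w))
    }
  }
})

test_that("MAP recovers a planted single-attribute strategy", {
  task <- task_config()
  trials <- generate_trials(task, seed = 23)
  w <- c(0, 0, 1, rep(0, 6))
  dec <- simulated_decider(model_spec_from_id(5), w, beta = 5)
  ds <- simulate_choices(dec, trials, seed = 9)
  got <- fit_map(model_spec_from_id(5), ds, prior_config(), fit_config())
  expect_equal(unname(got$map_w), w)
  expect_gt(got$map_beta, 1)
})

test_that("continuous MAP beats a dense parameter grid", {
  fix <- make_small_dataset(seed = 29, K = 2, n_trials = 20, model_id = 1,
                            beta = 3)
  spec <- model_spec_from_id(1)
  prior <- prior_config()
  got <- fit_map(spec, fix$data, prior, fit_config(), seed = 5)
  # dense box grid over (w1, w2, beta)
  ws <- seq(-1, 1, length.out = 101)
  bs <- seq(0.05, 15, length.out = 120)
  delta <- fix$data$trials$x_A - fix$data$trials$x_B
  sgn <- ifelse(fix$data$choices == "A", 1, -1)
  WW <- as.matrix(expand.grid(w1 = ws, w2 = ws))
  V <- (WW %*% t(delta * sgn))
  grid_best <- -Inf
  for (b in bs) {
    Z <- b * V
    lp <- rowSums(-log1p(exp(-abs(Z))) + pmin(Z, 0)) + dgamma(b, 4, 1,
                                                              log = TRUE)
    grid_best <- max(grid_best, max(lp))
  }
  lp_map <- log_likelihood(spec, got$map_w, got$map_beta, fix$data) +
    dgamma(got$map_beta, 4, 1, log = TRUE)
  expect_gte(lp_map, grid_best - 1e-3)
})

test_that("marginal likelihood of an empty dataset is zero", {
  empty <- choice_dataset("p0",
                          choice_trials(matrix(numeric(0), 0, 2),
                                        matrix(numeric(0), 0, 2)),
                          character(0))
  out <- log_marginal_likelihood(model_spec_from_id(3), empty)
  expect_identical(out$log_marginal, 0)
})

test_that("discrete marginal likelihoods match brute-force Monte Carlo", {
  cfg <- fast_fit_config()
  for (fix_seed in c(2, 8)) {
    for (id in 3:6) {
      fix <- make_small_dataset(seed = fix_seed, K = 3, n_trials = 20,
                                model_id = id, beta = 3)
      got <- log_marginal_likelihood(model_spec_from_id(id), fix$data,
                                     prior_config(), cfg)
      ref <- oracle_mc_marginal_discrete(model_spec_from_id(id), fix$data,
                                         n_draws = 1e5,
                                         seed = fix_seed + 100)
      expect_lt(abs(got$log_marginal - ref$log_marginal), 3 * ref$se)
    }
  }
})

test_that("continuous marginal likelihood matches prior Monte Carlo", {
  fix <- make_small_dataset(seed = 37, K = 2, n_trials = 10, model_id = 1,
                            beta = 2)
  for (id in 1:2) {
    got <- log_marginal_likelihood(model_spec_from_id(id), fix$data,
                                   prior_config(), fit_config(), seed = 3)
    ref <- oracle_mc_marginal_continuous(model_spec_from_id(id), fix$data,
                                         n_draws = 1e6, seed = 41)
    tol <- 3 * sqrt(ref$se^2 + got$se^2)
    expect_lt(abs(got$log_marginal - ref$log_marginal), tol)
    expect_equal(got$diagnostics$method, "laplace-importance")
  }
})

test_that("discrete marginals are quadrature-converged", {
  fix <- make_small_dataset(seed = 53, K = 3, n_trials = 30, model_id = 3,
                            beta = 4)
  for (id in c(3, 6)) {
    lm64 <- log_marginal_likelihood(model_spec_from_id(id), fix$data,
                                    prior_config(),
                                    fit_config(n_quad_nodes = 64))
    lm128 <- log_marginal_likelihood(model_spec_from_id(id), fix$data,
                                     prior_config(),
                                     fit_config(n_quad_nodes = 128))
    expect_lt(abs(lm64$log_marginal - lm128$log_marginal), 1e-6)
  }
})

test_that("fit_participant assembles a coherent, reproducible fit", {
  fix <- make_small_dataset(seed = 61, K = 3, n_trials = 30, model_id = 5,
                            beta = 5)
  report <- simulate_self_report(
    simulated_decider(fix$spec, fix$w, fix$beta), seed = 1)
  fit <- fit_participant(fix$data, report, config = fast_fit_config(),
                         seed = 17)
  expect_s3_class(fit, "participant_fit")
  expect_equal(sum(fit$model_probs), 1, tolerance = 1e-12)
  expect_true(all(fit$model_probs >= 0))
  expect_equal(unname(fit$family_probs[1]),
               fit$model_probs[5] + fit$model_probs[6])
  expect_true(which.max(fit$model_probs) %in% 5:6)
  expect_true(all(abs(fit$averaged_w) <= 1))
  expect_length(fit$averaged_reported_w, 3)
  # discrete-model marginals are exact: a re-run reproduces them bit-for-bit
  fit2 <- fit_participant(fix$data, report, config = fast_fit_config(),
                          seed = 17)
  expect_identical(fit$log_marginals[3:6], fit2$log_marginals[3:6])
  expect_identical(fit$log_marginals, fit2$log_marginals)
})

test_that("Occam's razor: the generating simple model beats the rational one", {
  # single-attribute data should favour model 5 over the flexible model 1
  wins <- 0
  for (s in 1:5) {
    fix <- make_small_dataset(seed = 70 + s, K = 3, n_trials = 40,
                              model_id = 5, beta = 5)
    fit <- fit_participant(fix$data, config = fast_fit_config(), seed = s)
    wins <- wins + (fit$model_probs[5] > fit$model_probs[1])
  }
  expect_gte(wins, 4)
})
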