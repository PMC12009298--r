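#' Estimator settings for per-participant fitting
#'
#' @param n_quad_nodes Gauss-Legendre node count for the inverse-temperature
#'   quadrature in the discrete-model marginal likelihoods (default 64).
#' @param n_is_draws Importance-sampling draw count for the continuous-model
#'   marginal likelihoods (default 4000).
#' @param n_restarts Multi-start count for continuous MAP optimization
#'   (default 10).
#' @param refine_top For discrete MAP: how many of the best grid
#'   configurations to refine with an exact 1-D beta optimization
#'   (default 20).
#' @param beta_max Upper box constraint on the inverse temperature during
#'   optimization (default 50; the Gamma prior makes larger values
#'   irrelevant).
#' @param t_df Degrees of freedom of the multivariate-t importance proposal
#'   (default 5).
#' @param scale_inflate Multiplicative inflation of the Laplace proposal
#'   covariance (default 1.5; guards against an over-tight proposal along
#'   the beta*w scale ridge).
#' @param quantile_eps The beta quadrature covers the Gamma prior between
#'   its `quantile_eps` and `1 - quantile_eps` quantiles (default 1e-8).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_quad_nodes = 64, n_is_draws = 4000, n_restarts = 10,
                       refine_top = 20, beta_max = 50, t_df = 5,
                       scale_inflate = 1.5, quantile_eps = 1e-8) {
  stopifnot(n_quad_nodes >= 2, n_is_draws >= 10, n_restarts >= 1,
            refine_top >= 1, beta_max > 0, t_df > 2, scale_inflate > 0)
  structure(list(n_quad_nodes = as.integer(n_quad_nodes),
                 n_is_draws = as.integer(n_is_draws),
                 n_restarts = as.integer(n_restarts),
                 refine_top = as.integer(refine_top),
                 beta_max = beta_max, t_df = t_df,
                 scale_inflate = scale_inflate,
                 quantile_eps = quantile_eps),
            class = "fit_config")
}

# Quadrature rule for integrating a likelihood against the Gamma prior on
# beta: Gauss-Legendre on the beta scale over the prior's central quantile
# range [Q(eps), Q(1 - eps)], with the prior density folded into the
# (log) weights, so sum(exp(log_w) * L(beta)) ~= int L dGamma.  The
# integrand L * dgamma is smooth and compactly concentrated, so this
# converges to machine precision well before 64 nodes.
beta_quadrature <- function(prior, n_nodes = 64, eps = 1e-8) {
  lo <- qgamma(eps, shape = prior$beta_shape, rate = prior$beta_rate)
  hi <- qgamma(1 - eps, shape = prior$beta_shape, rate = prior$beta_rate)
  gl <- pracma::gaussLegendre(n_nodes, lo, hi)
  list(beta = gl$x,
       log_w = log(gl$w) + dgamma(gl$x, shape = prior$beta_shape,
                                  rate = prior$beta_rate, log = TRUE))
}

# Signed value-difference matrix for a dataset under a spec: entry [t] is
# w-free per attribute; rows are trials, columns attributes, and every row is
# sign-flipped so that positive weighted sums favour the observed choice.
signed_diffs <- function(spec, data) {
  value_diff_matrix(data$trials, spec$binary_values) * data$choice_sign
}

# Log-likelihood at every (configuration, beta node): configs is ncfg x K,
# A is the signed trial x K difference matrix.
config_loglik_grid <- function(configs, A, betas) {
  V <- configs %*% t(A)  # ncfg x ntrial
  .loglik_grid_cpp(V, betas)
}

log_posterior_beta <- function(beta, v, prior) {
  # v: per-trial signed value differences for a fixed weight configuration
  sum(log_logistic(beta * v)) +
    dgamma(beta, prior$beta_shape, prior$beta_rate, log = TRUE)
}

#' Maximum a posteriori parameters of one model for one participant
#'
#' Discrete models (ids 3-6): the posterior is maximized exactly over the
#' enumerated weight configurations; a dense inverse-temperature grid (the
#' quadrature nodes) ranks the configurations and the best `refine_top` are
#' refined with a 1-D optimization of beta, so the returned pair is the
#' exact argmax up to the 1-D optimizer tolerance. Ties are broken towards
#' the lowest configuration index. Continuous models (ids 1-2): multi-start
#' L-BFGS-B with analytic gradients on the box `[-1,1]^K x (0, beta_max]`.
#'
#' @param spec A `choice_model_spec`.
#' @param data A nonempty `choice_dataset`.
#' @param prior A `prior_config`.
#' @param config A `fit_config`.
#' @param seed Integer seed for the multi-start initial points (continuous
#'   models only).
#' @return List with `map_w`, `map_beta`, and `log_post` (unnormalized log
#'   joint density at the optimum, weight prior included).
#' @export
fit_map <- function(spec, data, prior = prior_config(), config = fit_config(),
                    seed = 1L) {
  stopifnot(n_trials(data) > 0)
  if (is_discrete_spec(spec)) fit_map_discrete(spec, data, prior, config)
  else fit_map_continuous(spec, data, prior, config, seed)
}

fit_map_discrete <- function(spec, data, prior, config, grid = NULL,
                             configs = NULL, A = NULL) {
  K <- n_attributes(data)
  if (is.null(A)) A <- signed_diffs(spec, data)
  if (is.null(configs)) configs <- enumerate_weight_configs(spec, K)
  quad <- beta_quadrature(prior, config$n_quad_nodes, config$quantile_eps)
  if (is.null(grid)) grid <- config_loglik_grid(configs, A, quad$beta)
  lp_grid <- grid + rep(dgamma(quad$beta, prior$beta_shape, prior$beta_rate,
                               log = TRUE), each = nrow(grid))
  best_per_cfg <- apply(lp_grid, 1, max)
  top <- order(-best_per_cfg, seq_along(best_per_cfg))[
    seq_len(min(config$refine_top, nrow(configs)))]
  best <- list(lp = -Inf, idx = NA_integer_, beta = NA_real_)
  for (idx in sort(top)) {  # ascending index => deterministic tie-break
    v <- drop(A %*% configs[idx, ])
    opt <- optimize(function(b) log_posterior_beta(b, v, prior),
                    interval = c(1e-6, config$beta_max), maximum = TRUE,
                    tol = 1e-9)
    if (opt$objective > best$lp + 1e-12) {
      best <- list(lp = opt$objective, idx = idx, beta = opt$maximum)
    }
  }
  list(map_w = configs[best$idx, ], map_beta = best$beta,
       log_post = best$lp - log(nrow(configs)), config_index = best$idx)
}

# Negative log joint and gradient for continuous models; theta = c(w, beta).
neg_log_post_continuous <- function(theta, A, prior) {
  K <- ncol(A)
  w <- theta[seq_len(K)]; beta <- theta[K + 1L]
  u <- drop(A %*% w)
  z <- beta * u
  ll <- sum(log_logistic(z)) +
    dgamma(beta, prior$beta_shape, prior$beta_rate, log = TRUE) - K * log(2)
  -ll
}

neg_log_post_grad_continuous <- function(theta, A, prior) {
  K <- ncol(A)
  w <- theta[seq_len(K)]; beta <- theta[K + 1L]
  u <- drop(A %*% w)
  r <- plogis(-beta * u)  # d log plogis(z) / dz
  gw <- beta * drop(crossprod(A, r))
  gb <- sum(r * u) + (prior$beta_shape - 1) / beta - prior$beta_rate
  -c(gw, gb)
}

fit_map_continuous <- function(spec, data, prior, config, seed) {
  K <- n_attributes(data)
  A <- signed_diffs(spec, data)
  lower <- c(rep(-1, K), 1e-6)
  upper <- c(rep(1, K), config$beta_max)
  starts <- local_seed(seed, {
    s <- replicate(config$n_restarts,
                   c(runif(K, -1, 1),
                     rgamma(1, prior$beta_shape, prior$beta_rate)),
                   simplify = FALSE)
    s[[1]][seq_len(K)] <- 0  # one neutral start at indifference
    s[[1]][K + 1L] <- prior$beta_shape / prior$beta_rate
    s
  })
  best <- NULL
  for (st in starts) {
    st[K + 1L] <- min(max(st[K + 1L], 1e-4), config$beta_max)
    opt <- tryCatch(
      optim(st, neg_log_post_continuous, neg_log_post_grad_continuous,
            A = A, prior = prior, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500, factr = 10)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best))
    stop_introchoice("all optimizer restarts failed",
                     "introchoice_optimizer_failure")
  list(map_w = best$par[seq_len(K)], map_beta = best$par[K + 1L],
       log_post = -best$value)
}

#' Log marginal likelihood of one model for one participant
#'
#' Discrete models: the weight configurations are enumerated and, for each,
#' the inverse temperature is integrated against its Gamma prior by
#' Gauss-Legendre quadrature on the quantile scale; the results are averaged
#' over the discrete-uniform weight prior. This estimator is deterministic
#' and quadrature-converged. Continuous models: importance sampling with a
#' multivariate-t proposal built from a Laplace approximation at the MAP
#' (falling back to sampling from the prior when the Hessian is unusable);
#' the Monte-Carlo standard error of the log estimate is reported.
#'
#' An empty dataset has log marginal likelihood 0 (the marginal of no data
#' is 1).
#'
#' @inheritParams fit_map
#' @param seed Integer seed (continuous models only).
#' @param map Optional precomputed [fit_map()] result to reuse.
#' @return List with `log_marginal`, `se` (0 for quadrature), and
#'   `diagnostics` (method, node/draw counts, effective sample size).
#' @export
log_marginal_likelihood <- function(spec, data, prior = prior_config(),
                                    config = fit_config(), seed = 1L,
                                    map = NULL) {
  if (n_trials(data) == 0)
    return(list(log_marginal = 0, se = 0,
                diagnostics = list(method = "empty")))
  if (is_discrete_spec(spec)) {
    log_marginal_discrete(spec, data, prior, config)
  } else {
    log_marginal_continuous(spec, data, prior, config, seed, map)
  }
}

log_marginal_discrete <- function(spec, data, prior, config, grid = NULL,
                                  configs = NULL) {
  K <- n_attributes(data)
  if (is.null(configs)) configs <- enumerate_weight_configs(spec, K)
  quad <- beta_quadrature(prior, config$n_quad_nodes, config$quantile_eps)
  if (is.null(grid)) {
    A <- signed_diffs(spec, data)
    grid <- config_loglik_grid(configs, A, quad$beta)
  }
  # int L dGamma per configuration, then average over configurations
  per_cfg <- apply(grid + rep(quad$log_w, each = nrow(grid)), 1, logsumexp)
  lm <- logsumexp(per_cfg) - log(nrow(configs))
  list(log_marginal = lm, se = 0,
       diagnostics = list(method = "enumeration+quadrature",
                          n_configs = nrow(configs),
                          n_nodes = config$n_quad_nodes))
}

# Multivariate-t log density with location mu and scale matrix S (chol R).
dmvt_log <- function(X, mu, chol_S, df) {
  p <- length(mu)
  Z <- forwardsolve(t(chol_S), t(X) - mu)
  q <- colSums(Z^2)
  lgamma((df + p) / 2) - lgamma(df / 2) - (p / 2) * log(df * pi) -
    sum(log(diag(chol_S))) - ((df + p) / 2) * log1p(q / df)
}

log_marginal_continuous <- function(spec, data, prior, config, seed,
                                    map = NULL) {
  K <- n_attributes(data)
  A <- signed_diffs(spec, data)
  if (is.null(map)) map <- fit_map_continuous(spec, data, prior, config, seed)
  theta_hat <- c(map$map_w, map$map_beta)
  p <- K + 1L
  # Laplace covariance from a finite-difference Hessian of the analytic
  # gradient; eigenvalue-floored so boundary/ridge directions stay proper.
  H <- tryCatch(fd_hessian(function(th) neg_log_post_grad_continuous(th, A, prior),
                           theta_hat),
                error = function(e) NULL)
  proposal <- NULL
  if (!is.null(H) && all(is.finite(H))) {
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    floor_ev <- pmax(ev$values, max(abs(ev$values)) * 1e-6, 1e-4)
    S <- config$scale_inflate^2 *
      ev$vectors %*% diag(1 / floor_ev, p) %*% t(ev$vectors)
    chol_S <- tryCatch(chol((S + t(S)) / 2), error = function(e) NULL)
    if (!is.null(chol_S)) proposal <- list(chol_S = chol_S)
  }
  n <- config$n_is_draws
  if (!is.null(proposal)) {
    draws <- local_seed(seed, {
      Z <- matrix(rnorm(n * p), n, p) %*% proposal$chol_S
      scale <- sqrt(config$t_df / rchisq(n, config$t_df))
      sweep(Z * scale, 2, theta_hat, "+")
    })
    lq <- dmvt_log(draws, theta_hat, proposal$chol_S, config$t_df)
    method <- "laplace-importance"
  } else {
    # degenerate Hessian: fall back to sampling the prior itself
    draws <- local_seed(seed, cbind(matrix(runif(n * K, -1, 1), n, K),
                                    rgamma(n, prior$beta_shape,
                                           prior$beta_rate)))
    lq <- dgamma(draws[, p], prior$beta_shape, prior$beta_rate, log = TRUE) -
      K * log(2)
    method <- "prior-sampling"
  }
  in_support <- draws[, p] > 0 &
    rowSums(abs(draws[, seq_len(K), drop = FALSE]) > 1) == 0
  log_target <- rep(-Inf, n)
  if (any(in_support)) {
    sub <- draws[in_support, , drop = FALSE]
    V <- (sub[, seq_len(K), drop = FALSE]) %*% t(A)
    ll <- .loglik_draws_cpp(V, sub[, p])
    log_target[in_support] <- ll +
      dgamma(sub[, p], prior$beta_shape, prior$beta_rate, log = TRUE) -
      K * log(2)
  }
  lw <- log_target - lq
  m <- max(lw)
  wt <- exp(lw - m)
  est <- m + log(mean(wt))
  se <- sd(wt) / (sqrt(n) * mean(wt))  # delta-method SE on the log scale
  ess <- sum(wt)^2 / sum(wt^2)
  list(log_marginal = est, se = se,
       diagnostics = list(method = method, n_draws = n, ess = ess,
                          frac_in_support = mean(in_support)))
}

# Symmetric finite-difference Hessian from a gradient function.
fd_hessian <- function(grad_fn, theta, h = 1e-5) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    hj <- h * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + hj
    tm <- theta; tm[j] <- tm[j] - hj
    H[, j] <- (grad_fn(tp) - grad_fn(tm)) / (2 * hj)
  }
  (H + t(H)) / 2
}

#' Posterior model probabilities from log marginal likelihoods
#'
#' Normalizes the marginal likelihoods across the six models under a uniform
#' model prior (log-sum-exp stabilized).
#'
#' @param log_marginals Numeric vector of 6 finite log marginal likelihoods,
#'   in model-id order.
#' @return Numeric 6-vector summing to 1.
#' @export
posterior_model_probabilities <- function(log_marginals) {
  stopifnot(length(log_marginals) == 6, all(is.finite(log_marginals)))
  p <- exp(log_marginals - logsumexp(log_marginals))
  p / sum(p)
}

#' Posterior probability that each heuristic was used
#'
#' Partitions the six models into families that do or do not use each
#' heuristic and sums the posterior model probabilities of the users:
#' single_attribute = models 5 + 6; binary_weights = models 3 + 4;
#' binary_values = models 2 + 4 + 6.
#'
#' @param model_probs Numeric 6-simplex of posterior model probabilities.
#' @return Named numeric 3-vector (single_attribute, binary_weights,
#'   binary_values), each in `[0, 1]`.
#' @export
heuristic_family_probabilities <- function(model_probs) {
  stopifnot(length(model_probs) == 6, all(model_probs >= 0),
            abs(sum(model_probs) - 1) < 1e-6)
  c(single_attribute = model_probs[5] + model_probs[6],
    binary_weights = model_probs[3] + model_probs[4],
    binary_values = model_probs[2] + model_probs[4] + model_probs[6])
}

#' Model-averaged attribute weights
#'
#' Element-wise average of the six per-model MAP weight vectors, weighted by
#' the posterior model probabilities. Averaging across methods decouples
#' the weight estimate from any single assumed choice method.
#'
#' @param map_weights 6 x K matrix (or list of 6 K-vectors) of MAP weights.
#' @param model_probs Numeric 6-simplex.
#' @return K-vector with entries in `[-1, 1]`.
#' @export
model_averaged_weights <- function(map_weights, model_probs) {
  if (is.list(map_weights)) map_weights <- do.call(rbind, map_weights)
  stopifnot(nrow(map_weights) == 6, length(model_probs) == 6)
  drop(crossprod(map_weights, model_probs))
}

#' Model-averaged self-reported attribute weights
#'
#' The self-report formats map onto the weight formats the models assume:
#' graded for models 1-2, binary for models 3-4, single-attribute for models
#' 5-6. The reported vectors are averaged with the corresponding posterior
#' model probabilities, making the reported weights directly comparable to
#' the model-averaged fitted weights.
#'
#' @param report A `self_report`.
#' @param model_probs Numeric 6-simplex.
#' @return K-vector with entries in `[-1, 1]`.
#' @export
model_averaged_reported_weights <- function(report, model_probs) {
  stopifnot(inherits(report, "self_report"), length(model_probs) == 6)
  (model_probs[1] + model_probs[2]) * report$graded +
    (model_probs[3] + model_probs[4]) * report$binary +
    (model_probs[5] + model_probs[6]) * report$single
}

#' Fit all six choice models to one participant
#'
#' Runs [fit_map()] and [log_marginal_likelihood()] for every model, then
#' derives posterior model probabilities, heuristic-family probabilities,
#' model-averaged fitted weights, and (when a report is supplied)
#' model-averaged reported weights.
#'
#' @param data A nonempty `choice_dataset`.
#' @param report Optional `self_report` for the same participant.
#' @param prior A `prior_config`.
#' @param config A `fit_config`.
#' @param seed Integer seed (stochastic estimators only; discrete-model
#'   results are deterministic).
#' @return An object of class `participant_fit`.
#' @export
fit_participant <- function(data, report = NULL, prior = prior_config(),
                            config = fit_config(), seed = 1L) {
  stopifnot(inherits(data, "choice_dataset"), n_trials(data) > 0)
  seeds <- derive_seeds(seed, 6L)
  fits <- vector("list", 6L)
  for (id in 1:6) {
    spec <- model_spec_from_id(id)
    res <- tryCatch({
      if (is_discrete_spec(spec)) {
        K <- n_attributes(data)
        A <- signed_diffs(spec, data)
        configs <- enumerate_weight_configs(spec, K)
        quad <- beta_quadrature(prior, config$n_quad_nodes,
                                config$quantile_eps)
        grid <- config_loglik_grid(configs, A, quad$beta)
        map <- fit_map_discrete(spec, data, prior, config, grid = grid,
                                configs = configs, A = A)
        ml <- log_marginal_discrete(spec, data, prior, config, grid = grid,
                                    configs = configs)
        list(map = map, ml = ml)
      } else {
        map <- fit_map_continuous(spec, data, prior, config, seeds[id])
        ml <- log_marginal_continuous(spec, data, prior, config, seeds[id],
                                      map = map)
        list(map = map, ml = ml)
      }
    }, error = function(e) {
      stop_introchoice(sprintf("model %d fit failed for '%s': %s", id,
                               data$participant_id, conditionMessage(e)),
                       "introchoice_fit_failure")
    })
    fits[[id]] <- list(spec = spec, map_w = res$map$map_w,
                       map_beta = res$map$map_beta,
                       log_post = res$map$log_post,
                       log_marginal = res$ml$log_marginal,
                       se = res$ml$se, diagnostics = res$ml$diagnostics)
  }
  lms <- vapply(fits, `[[`, numeric(1), "log_marginal")
  probs <- posterior_model_probabilities(lms)
  W <- do.call(rbind, lapply(fits, `[[`, "map_w"))
  out <- list(participant_id = data$participant_id,
              fits = fits,
              log_marginals = lms,
              model_probs = probs,
              family_probs = heuristic_family_probabilities(probs),
              averaged_w = model_averaged_weights(W, probs),
              averaged_reported_w =
                if (!is.null(report))
                  model_averaged_reported_weights(report, probs)
                else NULL,
              seed = seed)
  class(out) <- "participant_fit"
  out
}

#' @export
print.participant_fit <- function(x, ...) {
  cat(sprintf("<participant_fit '%s'>\n", x$participant_id))
  cat("  model probs:",
      paste(sprintf("%d: %.3f", 1:6, x$model_probs), collapse = "  "), "\n")
  cat(sprintf(
    "  family probs: single_attribute %.3f, binary_weights %.3f, binary_values %.3f\n",
    x$family_probs[1], x$family_probs[2], x$family_probs[3]))
  invisible(x)
}
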