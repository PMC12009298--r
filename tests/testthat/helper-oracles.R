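# Independent reference implementations used to validate the package's
# estimators.  Everything here is deliberately written from the definitions
# (explicit loops, naive formulas) and shares no code with the package
# internals beyond base R.

# Choice probability from the definitions: transform values, weighted sums,
# logistic of the scaled difference.
oracle_choice_prob <- function(w, beta, x_A, x_B, binary_values) {
  if (binary_values) {
    ta <- numeric(length(x_A)); tb <- numeric(length(x_B))
    for (k in seq_along(x_A)) {
      if (x_A[k] > x_B[k]) { ta[k] <- 1; tb[k] <- 0 }
      else if (x_A[k] < x_B[k]) { ta[k] <- 0; tb[k] <- 1 }
      else { ta[k] <- 0.5; tb[k] <- 0.5 }
    }
  } else { ta <- x_A; tb <- x_B }
  1 / (1 + exp(-beta * (sum(w * ta) - sum(w * tb))))
}

# Trial-by-trial log-likelihood loop.
oracle_loglik <- function(w, beta, data, binary_values) {
  total <- 0
  for (t in seq_len(nrow(data$trials$x_A))) {
    p_A <- oracle_choice_prob(w, beta, data$trials$x_A[t, ],
                              data$trials$x_B[t, ], binary_values)
    total <- total + log(if (data$choices[t] == "A") p_A else 1 - p_A)
  }
  total
}

# All admissible weight vectors of a discrete model, by direct construction.
oracle_enumerate <- function(single_attribute, K) {
  if (single_attribute) {
    out <- list()
    for (k in seq_len(K)) for (s in c(1, -1)) {
      w <- numeric(K); w[k] <- s
      out[[length(out) + 1L]] <- w
    }
    do.call(rbind, out)
  } else {
    as.matrix(expand.grid(rep(list(c(-1, 0, 1)), K)))
  }
}

# Brute-force Monte-Carlo estimate of a discrete model's log marginal
# likelihood: configurations from their discrete-uniform prior, beta from
# the Gamma prior.  Returns the log estimate and the MC standard error of
# the log.
oracle_mc_marginal_discrete <- function(spec, data, n_draws = 1e5,
                                        shape = 4, rate = 1, seed = 1) {
  set.seed(seed)
  cfgs <- oracle_enumerate(spec$single_attribute, ncol(data$trials$x_A))
  idx <- sample.int(nrow(cfgs), n_draws, replace = TRUE)
  betas <- rgamma(n_draws, shape, rate)
  delta <- if (spec$binary_values) sign(data$trials$x_A - data$trials$x_B)
           else data$trials$x_A - data$trials$x_B
  sgn <- ifelse(data$choices == "A", 1, -1)
  V <- (cfgs %*% t(delta * sgn))[idx, , drop = FALSE] * betas
  ll <- rowSums(-log1p(exp(-abs(V))) + pmin(V, 0))
  mc_log_mean(ll)
}

# Same for continuous models: weights uniform on [-1, 1]^K.
oracle_mc_marginal_continuous <- function(spec, data, n_draws = 1e6,
                                          shape = 4, rate = 1, seed = 1) {
  set.seed(seed)
  K <- ncol(data$trials$x_A)
  W <- matrix(runif(n_draws * K, -1, 1), n_draws, K)
  betas <- rgamma(n_draws, shape, rate)
  delta <- if (spec$binary_values) sign(data$trials$x_A - data$trials$x_B)
           else data$trials$x_A - data$trials$x_B
  sgn <- ifelse(data$choices == "A", 1, -1)
  V <- (W %*% t(delta * sgn)) * betas
  ll <- rowSums(-log1p(exp(-abs(V))) + pmin(V, 0))
  mc_log_mean(ll)
}

# log(mean(exp(ll))) with a delta-method standard error on the log scale.
mc_log_mean <- function(ll) {
  m <- max(ll)
  w <- exp(ll - m)
  list(log_marginal = m + log(mean(w)),
       se = sd(w) / (sqrt(length(w)) * mean(w)))
}

# Small simulated dataset for estimator tests.
make_small_dataset <- function(seed, K = 3, n_trials = 20, model_id = 3,
                               beta = 3) {
  task <- task_config(K = K, n_trials = n_trials)
  trials <- generate_trials(task, seed = seed)
  spec <- model_spec_from_id(model_id)
  w <- local({
    set.seed(seed + 1)
    if (model_id %in% 1:2) runif(K, -1, 1)
    else if (model_id %in% 3:4) sample(c(-1, 0, 1), K, replace = TRUE)
    else { w <- numeric(K); w[sample.int(K, 1)] <- sample(c(-1, 1), 1); w }
  })
  dec <- simulated_decider(spec, w, beta)
  list(data = simulate_choices(dec, trials, seed = seed + 2),
       spec = spec, w = w, beta = beta)
}

# Reduced-cost estimator settings for unit tests.
fast_fit_config <- function() {
  fit_config(n_quad_nodes = 32, n_is_draws = 1500, n_restarts = 4,
             refine_top = 10)
}
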