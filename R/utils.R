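#' @useDynLib introchoice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dgamma qgamma rgamma optim optimize plogis rnorm runif
#'   rbinom cor sd rchisq setNames
#' @importFrom utils read.csv write.csv
NULL

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Stable log(1 / (1 + exp(-x))); accepts vectors/matrices.
log_logistic <- function(x) {
  ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))
}

# Evaluate an expression under a temporary RNG state, restoring the caller's.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive reproducible sub-seeds from one master seed
#'
#' One global seed fans out into independent per-component seeds so that any
#' single stage of a pipeline (trial generation, choice simulation, report
#' simulation, fitting) can be re-run on its own.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_introchoice <- function(msg, class) {
  stop(structure(class = c(class, "introchoice_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
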