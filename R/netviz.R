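#' Jittered-grid layout for the perception experiment
#'
#' 49 nodes on a 7-by-7 grid spanning the unit square, each coordinate
#' displaced by `jitter * U(0, 1)` with an independent random sign per axis
#' (the magnitude is what the experiment specifies; the sign convention is
#' a layout choice recorded in the result). `jitter = 0` gives the exact
#' regular grid — a degenerate control with many collinear triples that the
#' crossing counter will reject.
#'
#' @param seed integer seed.
#' @param jitter displacement magnitude factor.
#' @return 49 x 2 coordinate matrix with attributes `jitter` and
#'   `jitter_sign_convention`.
#' @export
netviz_layout <- function(seed = NULL, jitter = 0.08) {
  if (!is.null(seed)) set.seed(seed)
  base <- as.matrix(expand.grid(x = (0:6) / 6, y = (0:6) / 6))
  disp <- jitter * matrix(runif(98), 49, 2) *
    matrix(sample(c(-1, 1), 98, replace = TRUE), 49, 2)
  out <- base + disp
  attr(out, "jitter") <- jitter
  attr(out, "jitter_sign_convention") <- "independent random sign per axis"
  out
}

#' Exclusion filters for trial records
#'
#' Keeps trials whose retained edge count lies in `[2, 1175]` and whose
#' elapsed time lies in `[1, 3600]` seconds (inclusive bounds: only strict
#' outsiders are excluded). Malformed records (missing or non-finite
#' fields) are dropped and counted. Idempotent.
#'
#' @param records data frame with columns `condition`, `L` (retained edge
#'   count) and `elapsed_s` (seconds).
#' @param L_range,time_range inclusive retention ranges.
#' @return the retained records, with attributes `n_excluded` and
#'   `n_malformed`.
#' @export
apply_exclusion_filters <- function(records, L_range = c(2, 1175),
                                    time_range = c(1, 3600)) {
  if (!all(c("condition", "L", "elapsed_s") %in% names(records)))
    stop("records need columns condition, L, elapsed_s")
  ok_form <- is.finite(records$L) & is.finite(records$elapsed_s)
  if (any(!ok_form))
    message(sum(!ok_form), " malformed record(s) skipped")
  r <- records[ok_form, , drop = FALSE]
  keep <- r$L >= L_range[1] & r$L <= L_range[2] &
    r$elapsed_s >= time_range[1] & r$elapsed_s <= time_range[2]
  out <- r[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "n_malformed") <- sum(!ok_form)
  out
}

#' Gamma-Poisson (negative binomial) fit of overdispersed counts
#'
#' Maximum-likelihood fit of Poisson counts whose rates are Gamma mixed,
#' parameterized by the mean `lambda` and a scale `gamma` so that the
#' variance is `lambda * (1 + gamma)`; `gamma -> 0` recovers the Poisson.
#' The fit is the standard negative binomial MLE (`MASS::fitdistr`)
#' reparameterized as `gamma = lambda / size`. For underdispersed data
#' (sample variance at or below the mean) the mixture degenerates; the
#' Poisson MLE is returned with `gamma = 0` and a warning.
#'
#' @param counts non-negative integer vector, length `>= 10`.
#' @return list with `lambda`, `gamma`, `loglik` and `overdispersed`.
#' @export
fit_gamma_poisson <- function(counts) {
  if (length(counts) < 10) stop("need at least 10 counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (var(counts) <= mean(counts)) {
    warning("counts are not overdispersed; returning the Poisson limit gamma = 0")
    lam <- mean(counts)
    return(list(lambda = lam, gamma = 0,
                loglik = sum(dpois(counts, lam, log = TRUE)),
                overdispersed = FALSE))
  }
  fit <- MASS::fitdistr(counts, "negative binomial")
  mu <- unname(fit$estimate["mu"])
  size <- unname(fit$estimate["size"])
  list(lambda = mu, gamma = mu / size, loglik = as.numeric(logLik(fit)),
       overdispersed = TRUE)
}

#' Gamma-Poisson log-likelihood at given parameters
#'
#' @param counts non-negative integer vector.
#' @param lambda mean parameter, `> 0`.
#' @param gamma scale parameter, `>= 0` (0 = Poisson).
#' @return log-likelihood.
#' @export
gamma_poisson_loglik <- function(counts, lambda, gamma) {
  if (gamma <= 0) return(sum(dpois(counts, lambda, log = TRUE)))
  sum(dnbinom(counts, size = lambda / gamma, mu = lambda, log = TRUE))
}

#' Cohen's d standardized mean difference
#'
#' `(mean(x) - mean(y))` divided by the pooled standard deviation (variances
#' weighted by their degrees of freedom). Antisymmetric in its arguments.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return standardized effect size.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("both samples need at least 2 observations")
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("pooled variance is zero; effect size undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Simulate perception-experiment trial records
#'
#' Synthetic stand-in for the deposited trial data: per condition, retained
#' edge counts are Gamma-Poisson with the condition's mean and common scale
#' `gamma`, and elapsed times are log-normal. Default condition means are
#' the observed ones of the 49-node experiment (short 281.87, random
#' 150.27, long 131.83 retained edges out of 1,176 possible).
#'
#' @param n_per_condition trials per condition.
#' @param means named vector of per-condition mean retained edge counts.
#' @param gamma Gamma-Poisson scale (variance `mean * (1 + gamma)`).
#' @param elapsed_meanlog,elapsed_sdlog log-normal elapsed-time parameters
#'   (seconds).
#' @param seed integer seed.
#' @return data frame with columns `condition`, `L`, `elapsed_s`.
#' @export
simulate_trials <- function(n_per_condition = 3000,
                            means = c(short = 281.87, random = 150.27,
                                      long = 131.83),
                            gamma = 2,
                            elapsed_meanlog = log(120), elapsed_sdlog = 1,
                            seed = NULL) {
  if (gamma < 0 || any(means <= 0)) stop("parameters must be positive")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(means), function(cond) {
    mu <- means[[cond]]
    L <- if (gamma > 0)
      rnbinom(n_per_condition, size = mu / gamma, mu = mu)
    else stats::rpois(n_per_condition, mu)
    data.frame(condition = cond, L = L,
               elapsed_s = rlnorm(n_per_condition, elapsed_meanlog,
                                  elapsed_sdlog))
  })
  do.call(rbind, out)
}

#' Mean selected density per condition
#'
#' @param records trial records (see [simulate_trials()]).
#' @param n_possible number of selectable edges (1176 for the 49-node
#'   layout).
#' @return named numeric vector of mean densities per condition.
#' @export
condition_densities <- function(records, n_possible = 1176) {
  means <- tapply(records$L, records$condition, mean)
  setNames(as.numeric(means) / n_possible, names(means))
}
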