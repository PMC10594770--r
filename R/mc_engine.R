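#' @title Monte Carlo perturbation engine
#'
#' @description
#' Structural uncertainty in the observed service rates is represented by
#' triangular distributions centred on the observed value: the observed
#' rate is the mode and the support is obtained by decreasing/increasing
#' it by expert-defined percentages (30% both sides by default). Runs are
#' generated with per-service RNG substreams, so adding a service leaves
#' the other services' draws untouched. Convergence of any simulated
#' quantity is monitored with an error statistic — the 95% confidence
#' half-width of the mean, expressed as a percentage of the mean — with a
#' 2.5% stopping limit.
#'
#' @name mc_engine
NULL

#' Build a triangular perturbation distribution around an observed rate
#'
#' @param mode Observed (modal) value, >= 0.
#' @param down_pct,up_pct Fractions in `[0, 1)` / `>= 0`: the support is
#'   `[mode * (1 - down_pct), mode * (1 + up_pct)]`.
#' @return List of class `triangular_spec` with `left`, `mode`, `right`.
#' @export
make_triangular <- function(mode, down_pct = 0.30, up_pct = 0.30) {
  if (down_pct < 0 || down_pct >= 1 || up_pct < 0) {
    stop("perturbation percentages must satisfy 0 <= down < 1, up >= 0",
         call. = FALSE)
  }
  if (mode < 0) stop("mode must be >= 0", call. = FALSE)
  structure(list(left = mode * (1 - down_pct), mode = mode,
                 right = mode * (1 + up_pct)),
            class = "triangular_spec")
}

#' Sample from a triangular distribution (inverse CDF)
#'
#' A degenerate spec (`left == right`) returns the mode: zero-valued rates
#' stay at zero through the simulation.
#'
#' @param spec A `triangular_spec`.
#' @param n Number of draws.
#' @return Numeric vector of draws, all within `[left, right]`.
#' @export
sample_triangular <- function(spec, n = 1L) {
  l <- spec$left; m <- spec$mode; r <- spec$right
  if (r <= l) return(rep(m, n))
  u <- stats::runif(n)
  fc <- (m - l) / (r - l)
  ifelse(u < fc,
         l + sqrt(u * (r - l) * (m - l)),
         r - sqrt((1 - u) * (r - l) * (r - m)))
}

#' Analytic mean of a triangular distribution
#' @param spec A `triangular_spec`.
#' @return `(left + mode + right) / 3`.
#' @export
triangular_mean <- function(spec) (spec$left + spec$mode + spec$right) / 3

# deterministic 32-bit substream seed for service i under root seed
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Generate a batch of perturbed rate matrices
#'
#' @param rates Numeric service x variable matrix of observed rates (with
#'   dimnames).
#' @param percentages Either a single `c(down, up)` pair applied to every
#'   variable, or a named list mapping variable names to such pairs;
#'   variables not named fall back to `default_pct`.
#' @param n_runs Number of Monte Carlo runs (>= 1).
#' @param seed Root RNG seed; each service draws from its own substream.
#' @param default_pct Fallback `c(down, up)` pair.
#' @return A 3-d array `[service, variable, run]` of class
#'   `simulation_batch`, with the triangular specs in
#'   `attr(, "specs")` (list indexed `[[service]][[variable]]`).
#' @export
run_simulation <- function(rates, percentages = NULL, n_runs = 1000L,
                           seed = 1L, default_pct = c(0.30, 0.30)) {
  stopifnot(is.matrix(rates), n_runs >= 1L)
  ns <- nrow(rates); nv <- ncol(rates)
  vars <- colnames(rates)
  if (is.null(vars)) vars <- paste0("v", seq_len(nv))
  pct_for <- function(v) {
    if (is.null(percentages)) return(default_pct)
    if (is.numeric(percentages) && length(percentages) == 2L) {
      return(percentages)
    }
    p <- percentages[[v]]
    if (is.null(p)) {
      if (is.null(default_pct)) {
        stop("no perturbation percentage for variable '", v, "'",
             call. = FALSE)
      }
      return(default_pct)
    }
    p
  }
  out <- array(NA_real_, dim = c(ns, nv, n_runs),
               dimnames = list(rownames(rates), vars, NULL))
  specs <- vector("list", ns)
  for (i in seq_len(ns)) {
    set.seed(substream_seed(seed, i))
    specs[[i]] <- vector("list", nv)
    names(specs[[i]]) <- vars
    for (j in seq_len(nv)) {
      p <- pct_for(vars[j])
      sp <- make_triangular(rates[i, j], p[1L], p[2L])
      specs[[i]][[j]] <- sp
      out[i, j, ] <- sample_triangular(sp, n_runs)
    }
  }
  structure(out, specs = specs, seed = seed, class = "simulation_batch")
}

#' Monte Carlo convergence error of a sample mean
#'
#' Absolute error is the 95% confidence half-width `1.96 * s / sqrt(n)`;
#' the percentage error is taken relative to the sample mean, and the run
#' is converged when it does not exceed `threshold_pct`. A zero mean makes
#' the percentage undefined; the quantity is then reported as
#' not-converged with a flagged reason.
#'
#' @param samples Numeric vector (length >= 2).
#' @param threshold_pct Convergence limit, percent of the mean.
#' @return List with `n`, `mean`, `absolute`, `percentage`, `converged`,
#'   `reason`.
#' @export
error_statistic <- function(samples, threshold_pct = 2.5) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  m <- mean(samples)
  abs_err <- 1.96 * stats::sd(samples) / sqrt(n)
  if (m == 0) {
    return(list(n = n, mean = m, absolute = abs_err,
                percentage = NA_real_, converged = FALSE,
                reason = "mean is zero; percentage error undefined"))
  }
  pct <- 100 * abs_err / abs(m)
  list(n = n, mean = m, absolute = abs_err, percentage = pct,
       converged = pct <= threshold_pct, reason = NA_character_)
}
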