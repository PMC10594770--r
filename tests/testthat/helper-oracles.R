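# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: closed forms, normal equations and exhaustive
# enumeration, never the code paths they check.

# OLS via normal equations, with slope F-test computed from sums of squares
ols_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxx <- sum((x - mx)^2); sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  pred <- intercept + slope * x
  sse <- sum((y - pred)^2)
  sst <- sum((y - my)^2)
  ssr <- sst - sse
  df2 <- n - 2
  fstat <- if (sse <= 0) Inf else (ssr / 1) / (sse / df2)
  list(slope = slope, intercept = intercept,
       F_statistic = fstat,
       p_value = stats::pf(fstat, 1, df2, lower.tail = FALSE),
       R_squared = if (sst > 0) ssr / sst else NA_real_,
       residual_sd = sqrt(sse / df2))
}

# brute-force LP oracle: enumerate all basic solutions of
#   min c'x  s.t. A_ub x <= b_ub, A_eq x = b_eq, x >= 0
# by adding slacks and solving every square subsystem
lp_enum_oracle <- function(obj, A_ub = NULL, b_ub = NULL,
                           A_eq = NULL, b_eq = NULL, tol = 1e-8) {
  nv <- length(obj)
  A <- NULL; b <- NULL; n_ub <- 0L
  if (!is.null(A_ub)) {
    A_ub <- matrix(A_ub, ncol = nv)
    A <- A_ub; b <- b_ub; n_ub <- nrow(A_ub)
  }
  if (!is.null(A_eq)) {
    A_eq <- matrix(A_eq, ncol = nv)
    A <- rbind(A, A_eq); b <- c(b, b_eq)
  }
  m <- nrow(A)
  S <- matrix(0, m, n_ub)
  if (n_ub > 0L) S[cbind(seq_len(n_ub), seq_len(n_ub))] <- 1
  Afull <- cbind(A, S)
  ntot <- ncol(Afull)
  cfull <- c(obj, rep(0, n_ub))
  best <- Inf; best_x <- NULL
  for (cols in utils::combn(ntot, m, simplify = FALSE)) {
    B <- Afull[, cols, drop = FALSE]
    if (abs(det(B)) < 1e-12) next
    xb <- tryCatch(solve(B, b), error = function(e) NULL)
    if (is.null(xb) || any(xb < -tol)) next
    x <- numeric(ntot); x[cols] <- xb
    val <- sum(cfull * x)
    if (val < best - 1e-12) { best <- val; best_x <- x[seq_len(nv)] }
  }
  list(x = best_x, value = best,
       status = if (is.finite(best)) "optimal" else "infeasible")
}

# closed-form input-oriented VRS score for 1 input / 1 output: the minimal
# input attainable at output >= y_k over singletons and pairs of DMUs
dea_1in1out_oracle <- function(x, y, k) {
  n <- length(x)
  best <- x[k]  # self
  for (i in seq_len(n)) {
    if (y[i] >= y[k] && x[i] < best) best <- x[i]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (y[i] == y[j]) next
      lam <- (y[k] - y[j]) / (y[i] - y[j])
      if (lam < 0 || lam > 1) next
      xin <- lam * x[i] + (1 - lam) * x[j]
      if (xin < best) best <- xin
    }
  }
  best / x[k]
}

# exhaustive two-sided permutation p-value for the Mann-Whitney U test
mw_perm_oracle <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1); n <- length(pooled)
  ustat <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- ustat(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  us <- vapply(utils::combn(n, n1, simplify = FALSE), ustat, numeric(1))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# small canonical service table used across tests
tiny_services <- function() {
  wf <- matrix(1, 3, 9,
               dimnames = list(NULL, workforce_categories()))
  data.frame(service_id = c("s1", "s2", "s3"),
             desde_code = c("R1", "R9", "O8"),
             beds = c(10, 20, 0), users = c(100, 25, 400),
             days_of_stay = c(2924, 8000, 0),
             contacts = c(120, 30, 4000), wf,
             stringsAsFactors = FALSE)
}
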