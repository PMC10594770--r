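#' @title Input-oriented VRS data envelopment analysis
#'
#' @description
#' Two-phase input-oriented DEA under variable returns to scale (the BCC
#' model). For each decision-making unit (DMU) `k`, phase 1 solves
#'
#' \deqn{\min \theta \ \ s.t.\ X'\lambda \le \theta x_k,\ Y'\lambda \ge
#'   y_k,\ \sum\lambda = 1,\ \lambda \ge 0}
#'
#' and phase 2, with \eqn{\theta} fixed at its optimum, maximises the sum
#' of input and output slacks over the same feasible set. No weights are
#' placed on the variables. A DMU is *efficient* when \eqn{\theta = 1}
#' (within tolerance) with all slacks at zero, *weakly efficient* when
#' \eqn{\theta = 1} but some slack remains, and *inefficient* when
#' \eqn{\theta < 1}.
#'
#' @name dea_core
NULL

#' Construct and validate a DEA problem
#'
#' Negative inputs are clipped to zero with a warning. Zero inputs are
#' retained: the envelopment LP stays feasible through self-inclusion
#' (a zero entry simply restricts the reference set to peers that also
#' use none of that resource). Clipping zeros to a shared small epsilon
#' instead would make those columns identical across DMUs and force
#' every score to 1, besides being numerically near-singular. A DMU with
#' *all* inputs zero has no defined input-oriented score and is
#' rejected.
#'
#' @param inputs DMU x m numeric matrix (non-negative).
#' @param outputs DMU x s numeric matrix (non-negative).
#' @param ids DMU identifiers (defaults to rownames or indices).
#' @return List of class `dea_problem`.
#' @export
dea_problem <- function(inputs, outputs, ids = NULL) {
  inputs <- as.matrix(inputs); outputs <- as.matrix(outputs)
  stopifnot(nrow(inputs) == nrow(outputs))
  if (anyNA(inputs) || anyNA(outputs)) {
    stop("DEA matrices must not contain missing values", call. = FALSE)
  }
  if (any(outputs < 0)) stop("outputs must be >= 0", call. = FALSE)
  if (any(inputs < 0)) {
    warning("clipping ", sum(inputs < 0),
            " negative input value(s) to 0")
    inputs[inputs < 0] <- 0
  }
  if (any(rowSums(inputs) == 0)) {
    stop("DMU(s) with all inputs zero: ",
         paste(which(rowSums(inputs) == 0), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(ids)) ids <- rownames(inputs) %||% as.character(
    seq_len(nrow(inputs)))
  structure(list(inputs = inputs, outputs = outputs,
                 ids = as.character(ids)),
            class = "dea_problem")
}

#' Solve the two-phase input-oriented VRS model for one DMU
#'
#' @param problem A [dea_problem()].
#' @param k DMU index (1-based).
#' @param tol Tolerance for the theta = 1 and zero-slack decisions.
#' @return List with `theta`, `lambda` (intensity weights over DMUs),
#'   `input_slacks`, `output_slacks`, `classification`.
#' @export
solve_dmu <- function(problem, k, tol = 1e-6) {
  X <- problem$inputs; Y <- problem$outputs
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  xk <- X[k, ]; yk <- Y[k, ]
  # phase 1: variables (lambda_1..n, theta)
  obj <- c(rep(0, n), 1)
  A_ub <- rbind(cbind(t(X), -xk),          # X'lambda - theta xk <= 0
                cbind(-t(Y), rep(0, s)))   # -Y'lambda <= -yk
  b_ub <- c(rep(0, m), -yk)
  A_eq <- matrix(c(rep(1, n), 0), nrow = 1)
  sol1 <- simplex_lp(obj, A_ub, b_ub, A_eq, 1)
  if (sol1$status != "optimal") {
    stop("DEA phase-1 LP ", sol1$status, " for DMU ", problem$ids[k],
         " (solver or data defect: self-inclusion guarantees a solution)",
         call. = FALSE)
  }
  theta <- min(sol1$value, 1)
  # phase 2: fix theta, maximise total slack
  # variables (lambda_1..n, sminus_1..m, splus_1..s)
  nv <- n + m + s
  obj2 <- c(rep(0, n), rep(-1, m + s))  # maximise slack sum
  A_eq2 <- rbind(
    cbind(t(X), diag(m), matrix(0, m, s)),   # X'l + s- = theta xk
    cbind(t(Y), matrix(0, s, m), -diag(s)),  # Y'l - s+ = yk
    c(rep(1, n), rep(0, m + s)))
  b_eq2 <- c(theta * xk, yk, 1)
  sol2 <- simplex_lp(obj2, A_eq = A_eq2, b_eq = b_eq2)
  if (sol2$status != "optimal") {
    stop("DEA phase-2 LP ", sol2$status, " for DMU ", problem$ids[k],
         call. = FALSE)
  }
  lambda <- sol2$x[seq_len(n)]
  s_in <- sol2$x[n + seq_len(m)]
  s_out <- sol2$x[n + m + seq_len(s)]
  names(lambda) <- problem$ids
  names(s_in) <- colnames(X)
  names(s_out) <- colnames(Y)
  slack_tot <- max(c(s_in, s_out))
  classification <- if (theta >= 1 - tol) {
    if (slack_tot <= tol) "efficient" else "weakly_efficient"
  } else "inefficient"
  list(theta = theta, lambda = lambda, input_slacks = s_in,
       output_slacks = s_out, classification = classification)
}

#' Solve a DEA problem for every DMU
#'
#' @param problem A [dea_problem()] (or a list with `inputs`, `outputs`,
#'   `ids`, e.g. from [plant_frontier()]).
#' @param tol Shared tolerance for theta = 1 and zero-slack decisions.
#' @return A `dea_result` list: `summary` (data.frame of dmu_id, theta,
#'   classification), `lambdas` (n x n matrix), `input_slacks`,
#'   `output_slacks` (matrices).
#' @export
solve_all <- function(problem, tol = 1e-6) {
  if (!inherits(problem, "dea_problem")) {
    problem <- dea_problem(problem$inputs, problem$outputs, problem$ids)
  }
  n <- nrow(problem$inputs)
  res <- lapply(seq_len(n), function(k) {
    tryCatch(solve_dmu(problem, k, tol), error = function(e) {
      stop("DMU ", problem$ids[k], ": ", conditionMessage(e),
           call. = FALSE)
    })
  })
  summary <- data.frame(
    dmu_id = problem$ids,
    theta = vapply(res, `[[`, numeric(1), "theta"),
    classification = vapply(res, `[[`, character(1), "classification"),
    stringsAsFactors = FALSE)
  structure(list(
    summary = summary,
    lambdas = do.call(rbind, lapply(res, `[[`, "lambda")),
    input_slacks = do.call(rbind, lapply(res, `[[`, "input_slacks")),
    output_slacks = do.call(rbind, lapply(res, `[[`, "output_slacks")),
    tol = tol), class = "dea_result")
}
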