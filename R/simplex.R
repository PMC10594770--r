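#' @title Dense two-phase primal simplex
#'
#' @description
#' Small self-contained LP solver used by the DEA engine. Problems are of
#' the form: minimise `c'x` subject to `A_ub x <= b_ub`, `A_eq x = b_eq`,
#' `x >= 0`. Rows are equilibrated to unit max magnitude before solving
#' (DEA rate matrices mix scales from 1e-9 clipped staff rates to
#' several-hundred-day lengths of stay). The entering variable takes the
#' most negative reduced cost, falling back to Bland's rule after a long
#' stall so cycling is impossible; the leaving row breaks ratio-test ties
#' on the largest pivot element, which keeps the tableau numerically
#' stable. DEA problems are tiny (tens of variables, a handful of
#' constraints), so a dense full-tableau implementation is adequate and
#' easy to verify.
#'
#' @name simplex
NULL

#' Solve a linear program with the two-phase simplex method
#'
#' @param obj Objective coefficients (minimised).
#' @param A_ub,b_ub Inequality constraints `A_ub x <= b_ub` (may be NULL).
#' @param A_eq,b_eq Equality constraints (may be NULL).
#' @param tol Numerical tolerance.
#' @param max_iter Iteration cap per phase.
#' @param bland_after Iterations of the default pricing rule before
#'   switching to Bland's anti-cycling rule.
#' @return List with `x` (solution), `value` (objective), `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`).
#' @export
simplex_lp <- function(obj, A_ub = NULL, b_ub = NULL,
                       A_eq = NULL, b_eq = NULL,
                       tol = 1e-9, max_iter = 10000L,
                       bland_after = 1000L) {
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
  # row equilibration: unit max magnitude per row
  scale <- pmax(apply(abs(A), 1L, max), abs(b), .Machine$double.xmin)
  A <- A / scale; b <- b / scale
  # slack columns for the inequality rows
  S <- matrix(0, m, n_ub)
  if (n_ub > 0L) S[cbind(seq_len(n_ub), seq_len(n_ub))] <- 1
  A2 <- cbind(A, S)
  neg <- b < 0
  A2[neg, ] <- -A2[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  n2 <- ncol(A2)
  Tb <- cbind(A2, diag(m), b)
  basis <- n2 + seq_len(m)

  run_phase <- function(Tb, basis, cost, active_cols) {
    m <- nrow(Tb); ncols <- ncol(Tb) - 1L
    rhs_col <- ncols + 1L
    for (it in seq_len(max_iter)) {
      cB <- cost[basis]
      red <- cost - as.vector(crossprod(cB, Tb[, seq_len(ncols),
                                              drop = FALSE]))
      red[!active_cols] <- Inf
      red[basis] <- Inf
      neg_red <- which(red < -tol)
      if (length(neg_red) == 0L) {
        return(list(Tb = Tb, basis = basis, status = "optimal"))
      }
      j <- if (it > bland_after) neg_red[1L]            # Bland
           else neg_red[which.min(red[neg_red])]        # Dantzig
      col <- Tb[, j]
      pos <- which(col > 1e-8)  # rows equilibrated: smaller is roundoff
      if (length(pos) == 0L) {
        return(list(Tb = Tb, basis = basis, status = "unbounded"))
      }
      ratios <- Tb[pos, rhs_col] / col[pos]
      ratios[ratios < 0] <- 0  # degenerate negatives from roundoff
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol * (1 + abs(rmin))]
      i <- if (it > bland_after) cand[which.min(basis[cand])]
           else cand[which.max(col[cand])]  # largest pivot: stability
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      upd <- which(abs(Tb[, j]) > 0 & seq_len(m) != i)
      if (length(upd) > 0L) {
        Tb[upd, ] <- Tb[upd, ] - outer(Tb[upd, j], Tb[i, ])
      }
      basis[i] <- j
    }
    stop("simplex iteration limit reached", call. = FALSE)
  }

  ncols <- n2 + m
  active <- rep(TRUE, ncols)
  cost1 <- c(rep(0, n2), rep(1, m))
  ph1 <- run_phase(Tb, basis, cost1, active)
  if (ph1$status != "optimal") {
    return(list(x = NULL, value = NA_real_, status = ph1$status))
  }
  Tb <- ph1$Tb; basis <- ph1$basis
  if (sum(abs(Tb[basis > n2, ncol(Tb)])) > 1e-7) {
    return(list(x = NULL, value = NA_real_, status = "infeasible"))
  }
  # drive residual (zero-valued) artificials out of the basis
  drop_rows <- integer(0)
  for (i in which(basis > n2)) {
    row_part <- Tb[i, seq_len(n2)]
    piv_cand <- which(abs(row_part) > 1e-7)
    if (length(piv_cand) == 0L) { drop_rows <- c(drop_rows, i); next }
    j <- piv_cand[which.max(abs(row_part[piv_cand]))]
    Tb[i, ] <- Tb[i, ] / Tb[i, j]
    for (r in seq_len(nrow(Tb))) {
      if (r != i && abs(Tb[r, j]) > 0) {
        Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
      }
    }
    basis[i] <- j
  }
  if (length(drop_rows) > 0L) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  active[n2 + seq_len(m)] <- FALSE
  cost2 <- c(obj, rep(0, ncols - nv))
  ph2 <- run_phase(Tb, basis, cost2, active)
  if (ph2$status != "optimal") {
    return(list(x = NULL, value = NA_real_, status = ph2$status))
  }
  Tb <- ph2$Tb; basis <- ph2$basis
  x <- numeric(ncols)
  x[basis] <- Tb[, ncol(Tb)]
  x[x < 0 & x > -1e-9] <- 0
  xs <- x[seq_len(nv)]
  list(x = xs, value = sum(obj * xs), status = "optimal")
}
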