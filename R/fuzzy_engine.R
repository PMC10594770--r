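#' @title Knowledge-based appropriateness transformation
#'
#' @description
#' Before DEA, simulated rates are interpreted against expert
#' appropriateness ranges derived from the balanced-care model: each
#' variable carries a range `[x_left, x_right]` within which its value is
#' considered appropriate for quality care, together with an orientation
#' (whether appropriateness increases or decreases with the raw value
#' inside the range) and linear penalty slopes outside it.
#'
#' Inside the range, when the raw monotonicity disagrees with
#' DEA-favourability (e.g. a staff input whose higher values are more
#' appropriate, yet DEA prefers smaller inputs) the value is reflected:
#' `x_transformed = (x_right + x_left) - x_original`, so that more
#' appropriate raw values become more favourable to the DMU. When raw
#' monotonicity already agrees, the value passes through unchanged.
#' Outside the range the value is penalised linearly with distance, always
#' away from favourability: above `x_right` for inputs, below `x_left`
#' (floored at zero) for outputs.
#'
#' @name fuzzy_engine
NULL

#' Construct a per-variable appropriateness rule
#'
#' @param variable Variable name.
#' @param role `"input"` or `"output"` (DEA role of the variable).
#' @param range Numeric pair `c(x_left, x_right)`, `x_left <= x_right`.
#' @param orientation `"increasing"` (appropriateness grows with the raw
#'   value inside the range) or `"decreasing"`.
#' @param penalty_slope_left,penalty_slope_right Non-negative multipliers
#'   on the distance outside the range.
#' @return List of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(variable, role = c("input", "output"),
                       range, orientation = c("increasing", "decreasing"),
                       penalty_slope_left = 1, penalty_slope_right = 1) {
  role <- match.arg(role)
  orientation <- match.arg(orientation)
  stopifnot(length(range) == 2L, is.finite(range))
  if (range[1L] > range[2L]) stop("x_left must be <= x_right",
                                  call. = FALSE)
  if (penalty_slope_left < 0 || penalty_slope_right < 0) {
    stop("penalty slopes must be >= 0", call. = FALSE)
  }
  structure(list(variable = variable, role = role,
                 x_left = range[1L], x_right = range[2L],
                 orientation = orientation,
                 penalty_slope_left = penalty_slope_left,
                 penalty_slope_right = penalty_slope_right),
            class = "fuzzy_rule")
}

#' Transform raw values onto the DEA-favourable scale
#'
#' Vectorised over `x`. Within `[x_left, x_right]` the reflection
#' `(x_right + x_left) - x` is applied when the rule's orientation
#' disagrees with DEA-favourability (input/increasing and
#' output/decreasing); otherwise the identity. Outside the range, inputs
#' are pushed above `x_right` and outputs below `x_left` (never below 0)
#' in proportion to the distance from the range, so any out-of-range value
#' is strictly less favourable than every within-range value whenever its
#' penalty slope is positive.
#'
#' @param rule A [fuzzy_rule()].
#' @param x Numeric vector of raw (non-negative, finite) values.
#' @return Numeric vector of transformed values.
#' @export
transform_value <- function(rule, x) {
  stopifnot(inherits(rule, "fuzzy_rule"))
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  L <- rule$x_left; R <- rule$x_right
  reflect <- (rule$role == "input" && rule$orientation == "increasing") ||
    (rule$role == "output" && rule$orientation == "decreasing")
  inside <- if (reflect) (L + R) - x else x
  if (rule$role == "input") {
    below <- R + rule$penalty_slope_left * (L - x)
    above <- R + rule$penalty_slope_right * (x - R)
  } else {
    below <- pmax(0, L - rule$penalty_slope_left * (L - x))
    above <- pmax(0, L - rule$penalty_slope_right * (x - R))
  }
  out <- inside
  out[x < L] <- below[x < L]
  out[x > R] <- above[x > R]
  out
}

#' Assemble a rule base
#'
#' @param rules List of [fuzzy_rule()] objects.
#' @param provenance `"expert"` or `"data_quantile"` — whether ranges come
#'   from an expert elicitation file or from empirical quantiles.
#' @return List of class `rule_base` with one rule per variable.
#' @export
rule_base <- function(rules, provenance = "expert") {
  names(rules) <- vapply(rules, `[[`, character(1), "variable")
  if (anyDuplicated(names(rules))) {
    stop("duplicate rule for a variable", call. = FALSE)
  }
  structure(list(rules = rules, provenance = provenance),
            class = "rule_base")
}

#' Column-wise fuzzy transformation of a rate matrix
#'
#' @param rb A [rule_base()] holding a rule for every column of `rates`.
#' @param rates Numeric service x variable matrix with column names.
#' @return Matrix of the same shape, transformed elementwise.
#' @export
transform_matrix <- function(rb, rates) {
  stopifnot(inherits(rb, "rule_base"), is.matrix(rates))
  vars <- colnames(rates)
  missing <- setdiff(vars, names(rb$rules))
  if (length(missing) > 0L) {
    stop("no fuzzy rule for variable(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- rates
  for (v in vars) out[, v] <- transform_value(rb$rules[[v]], rates[, v])
  out
}

#' Data-derived default rule base
#'
#' When the expert-elicited appropriateness ranges are unavailable, each
#' variable's range is taken as the empirical inter-quantile interval
#' (linear-interpolation quantiles, defaults 0.40-0.60), with
#' increasing-appropriateness orientation and unit penalty slopes. The
#' provenance is recorded as `"data_quantile"` so downstream reports can
#' flag the substitution. A constant column yields the degenerate range
#' `[v, v]`: the transform is the identity at `v` with penalties on both
#' sides.
#'
#' @param rates Numeric service x variable matrix (>= 5 services).
#' @param roles Character vector, recycled over columns: `"input"` or
#'   `"output"`.
#' @param lower_q,upper_q Quantile bounds, `0 <= lower_q < upper_q <= 1`.
#' @return A [rule_base()].
#' @export
default_rule_base <- function(rates, roles = "input",
                              lower_q = 0.40, upper_q = 0.60) {
  stopifnot(is.matrix(rates))
  if (nrow(rates) < 5L) stop("need at least 5 services", call. = FALSE)
  if (!(lower_q >= 0 && lower_q < upper_q && upper_q <= 1)) {
    stop("quantiles must satisfy 0 <= lower_q < upper_q <= 1",
         call. = FALSE)
  }
  vars <- colnames(rates)
  roles <- rep_len(roles, length(vars))
  rules <- lapply(seq_along(vars), function(j) {
    qs <- unname(stats::quantile(rates[, j], c(lower_q, upper_q),
                                 type = 7))
    fuzzy_rule(vars[j], role = roles[j], range = qs,
               orientation = "increasing")
  })
  rule_base(rules, provenance = "data_quantile")
}

#' Read a rule base from a JSON file
#'
#' The file holds an array of objects with fields `variable`, `role`,
#' `x_left`, `x_right`, `orientation`, `penalty_slope_left`,
#' `penalty_slope_right`, plus an optional top-level `provenance`.
#'
#' @param path JSON file path.
#' @param variables Optional character vector; when given, the rule base
#'   must cover exactly these variables.
#' @return A [rule_base()].
#' @export
read_rule_base <- function(path, variables = NULL) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  prov <- spec$provenance %||% "expert"
  entries <- spec$rules %||% spec
  rules <- lapply(entries, function(e) {
    fuzzy_rule(e$variable, role = e$role,
               range = c(e$x_left, e$x_right),
               orientation = e$orientation %||% "increasing",
               penalty_slope_left = e$penalty_slope_left %||% 1,
               penalty_slope_right = e$penalty_slope_right %||% 1)
  })
  rb <- rule_base(rules, provenance = prov)
  if (!is.null(variables)) {
    extra <- setdiff(names(rb$rules), variables)
    missing <- setdiff(variables, names(rb$rules))
    if (length(missing) > 0L || length(extra) > 0L) {
      stop("rule base does not match variable list; missing: [",
           paste(missing, collapse = ", "), "], extra: [",
           paste(extra, collapse = ", "), "]", call. = FALSE)
    }
  }
  rb
}

#' Write a rule base to JSON
#' @param rb A [rule_base()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rule_base <- function(rb, path) {
  entries <- lapply(rb$rules, function(r) {
    list(variable = r$variable, role = r$role, x_left = r$x_left,
         x_right = r$x_right, orientation = r$orientation,
         penalty_slope_left = r$penalty_slope_left,
         penalty_slope_right = r$penalty_slope_right)
  })
  jsonlite::write_json(list(provenance = rb$provenance,
                            rules = unname(entries)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
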