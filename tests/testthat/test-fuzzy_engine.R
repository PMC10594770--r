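nurse_rule <- function(sl = 1, sr = 1) {
  fuzzy_rule("NurseR9", "input", c(0.1618, 0.1708), "increasing",
             penalty_slope_left = sl, penalty_slope_right = sr)
}

test_that("the reflection transform reproduces the published worked case", {
  r <- nurse_rule()
  # the range's lower bound reflects onto its upper bound
  expect_equal(transform_value(r, 0.1618), 0.1708)
  expect_equal(transform_value(r, 0.1708), 0.1618)
  # the midpoint is a fixed point
  expect_equal(transform_value(r, 0.1663), 0.1663)
  # below-range penalty: worse (larger input) than any within-range value
  expect_equal(transform_value(r, 0.15), 0.1708 + (0.1618 - 0.15))
  expect_gt(transform_value(r, 0.15), 0.1708)
})

test_that("reflection is an involution inside the range", {
  set.seed(3)
  for (i in 1:20) {
    lo <- runif(1, 0, 5); hi <- lo + runif(1, 0.1, 3)
    role <- sample(c("input", "output"), 1)
    orient <- if (role == "input") "increasing" else "decreasing"
    r <- fuzzy_rule("v", role, c(lo, hi), orient)
    x <- runif(10, lo, hi)
    expect_equal(transform_value(r, transform_value(r, x)), x,
                 tolerance = 1e-12)
  }
})

test_that("boundary behaviour: continuous at x_left, penalty meets x_right", {
  r <- nurse_rule()
  eps <- 1e-10
  # pointwise continuity at the left edge
  expect_equal(transform_value(r, 0.1618 - eps),
               transform_value(r, 0.1618), tolerance = 1e-8)
  # the right penalty branch starts at the reflection branch's extreme
  # value x_right (the reflection itself maps x_right to x_left)
  expect_equal(transform_value(r, 0.1708 + eps), 0.1708,
               tolerance = 1e-8)
})

test_that("penalties grow with distance and preserve favourability", {
  r <- nurse_rule(sl = 2, sr = 0.5)
  below <- transform_value(r, c(0.16, 0.15, 0.10))
  expect_true(all(diff(below) > 0))        # further below -> worse
  above <- transform_value(r, c(0.18, 0.25, 0.40))
  expect_true(all(diff(above) > 0))        # further above -> worse
  expect_true(all(c(below, above) > 0.1708))

  # inside the range, more appropriate (higher) raw values give smaller
  # (more favourable) transformed inputs
  xs <- seq(0.1618, 0.1708, length.out = 9)
  expect_true(all(diff(transform_value(r, xs)) < 0))

  # output with decreasing appropriateness: low raw values (appropriate)
  # map to large outputs; out-of-range values drop below x_left, never
  # below zero
  ro <- fuzzy_rule("los", "output", c(10, 20), "decreasing",
                   penalty_slope_left = 1, penalty_slope_right = 1)
  expect_equal(transform_value(ro, 10), 20)
  expect_equal(transform_value(ro, c(25, 40)), c(5, 0))
  expect_equal(transform_value(ro, 5), 5)
  expect_equal(transform_value(ro, 2), 2)

  # agreeing orientations pass through unchanged inside the range
  ri <- fuzzy_rule("staff", "input", c(1, 2), "decreasing")
  expect_equal(transform_value(ri, 1.4), 1.4)
  expect_gt(transform_value(ri, 0.5), 2)
  ru <- fuzzy_rule("contacts", "output", c(1, 2), "increasing")
  expect_equal(transform_value(ru, 1.7), 1.7)
  expect_lt(transform_value(ru, 2.5), 1)
})

test_that("transform_matrix works column-wise with context in errors", {
  set.seed(8)
  mat <- cbind(a = runif(6, 1, 2), b = runif(6, 5, 6))
  rb <- rule_base(list(
    fuzzy_rule("a", "input", c(1, 2), "increasing"),
    fuzzy_rule("b", "input", c(5, 6), "increasing")))
  tm <- transform_matrix(rb, mat)
  expect_equal(dim(tm), dim(mat))
  expect_equal(transform_matrix(rb, tm), mat, tolerance = 1e-12)

  mid <- cbind(a = rep(1.5, 3), b = rep(5.5, 3))
  expect_equal(transform_matrix(rb, mid), mid)

  low <- mat; low[, "b"] <- low[, "b"] - 2  # entirely below b's range
  expect_true(all(transform_matrix(rb, low)[, "b"] > 6))

  expect_error(transform_matrix(rb, cbind(mat, c = 1:6)), "c")
})

test_that("default_rule_base derives quantile ranges and flags provenance", {
  mat <- cbind(v = c(1, 2, 3, 4, 5), w = rep(7, 5))
  rb <- default_rule_base(mat, roles = "input")
  expect_equal(rb$provenance, "data_quantile")
  expect_equal(c(rb$rules$v$x_left, rb$rules$v$x_right), c(2.6, 3.4))
  # constant column: degenerate range, identity at the value, penalties
  # on both sides
  expect_equal(c(rb$rules$w$x_left, rb$rules$w$x_right), c(7, 7))
  expect_equal(transform_value(rb$rules$w, 7), 7)
  expect_gt(transform_value(rb$rules$w, 8), 7)
  expect_gt(transform_value(rb$rules$w, 6), 7)

  expect_error(default_rule_base(mat[1:4, , drop = FALSE]), "at least 5")
  expect_error(default_rule_base(mat, lower_q = 0.7, upper_q = 0.6),
               "quantiles")

  # every generated rule passes the FuzzyRule invariants on a fixture
  eco <- generate_ecosystem(generator_config(seed = 19))
  rm <- rates_matrix(eco$services, "T2")
  rbx <- default_rule_base(cbind(rm$inputs, rm$outputs),
                           c(rep("input", 5), rep("output", 2)))
  for (r in rbx$rules) {
    expect_lte(r$x_left, r$x_right)
    expect_gte(r$penalty_slope_left, 0)
  }
})

test_that("rule bases round-trip through JSON and validate coverage", {
  rb <- rule_base(list(nurse_rule(), fuzzy_rule("los", "output", c(10, 20),
                                                "decreasing")),
                  provenance = "expert")
  path <- withr::local_tempfile(fileext = ".json")
  write_rule_base(rb, path)
  back <- read_rule_base(path, variables = c("NurseR9", "los"))
  expect_equal(back$provenance, "expert")
  expect_equal(back$rules$NurseR9$x_right, 0.1708)
  expect_error(read_rule_base(path, variables = c("NurseR9", "other")),
               "missing: \\[other\\]")
})
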