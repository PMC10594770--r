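test_that("summarize_rte counts classes and threshold exceedances", {
  st <- summarize_rte(c(1, 1, 0.9, 0.8),
                      c("efficient", "efficient", "inefficient",
                        "inefficient"))
  expect_equal(st$mean, 0.925)
  expect_equal(st$p_efficient, 0.5)
  expect_equal(st$p_inefficient, 0.5)
  expect_equal(st$p_weakly_efficient, 0)
  expect_equal(st$p_gt_075, 1)

  allg <- summarize_rte(rep(1, 10), rep("efficient", 10))
  expect_equal(allg$p_efficient, 1)
  expect_equal(allg$sd, 0)
  expect_true(allg$converged)

  expect_error(summarize_rte(1, "efficient"), "at least 2")
  expect_error(summarize_rte(c(1, 1), c("efficient", "best")),
               "unknown classification")
})

test_that("class probabilities are exhaustive and ordered per service", {
  set.seed(31)
  n_svc <- 6; n_runs <- 40
  theta <- matrix(runif(n_svc * n_runs, 0.5, 1), n_svc,
                  dimnames = list(paste0("s", 1:n_svc), NULL))
  classes <- ifelse(theta > 1 - 1e-12, "efficient",
                    ifelse(theta > 0.97, "weakly_efficient",
                           "inefficient"))
  theta[classes != "inefficient"] <- 1
  dists <- rte_distributions(theta, classes)
  for (d in dists) {
    st <- d$statistics
    expect_equal(st$p_efficient + st$p_weakly_efficient +
                   st$p_inefficient, 1)
    expect_gte(st$p_gt_075, st$p_efficient)
  }
})

test_that("aggregate_by_code pools run-level samples per group", {
  sv <- tiny_services()
  sv2 <- sv; sv2$service_id <- c("s4", "s5", "s6")
  sv2$desde_code <- c("R2", "R11", "O9")
  services <- validate_services(rbind(sv, sv2))
  theta <- rbind(s1 = c(1, 1, 0.8, 0.9), s4 = c(1, 0.7, 0.7, 0.7))
  classes <- rbind(s1 = c("efficient", "efficient", "inefficient",
                          "inefficient"),
                   s4 = c("efficient", rep("inefficient", 3)))
  dists <- rte_distributions(theta, classes)
  tab <- aggregate_by_code(dists, services)
  r1 <- tab[tab$group == "R1", ]
  # singleton group equals the service's own statistics
  expect_equal(r1$rte_mean, mean(theta["s1", ]))
  expect_equal(r1$p_efficient, 0.5)
  # two services with P(efficient) 0.5 and 0.25, equal runs -> 0.375
  pooled <- tab[tab$group == "R1-R2", ]
  expect_equal(pooled$p_efficient, 0.375)
  expect_equal(pooled$n_services, 2L)
  expect_equal(pooled$rte_mean, mean(theta))
  # service-level averaging mode
  tab2 <- aggregate_by_code(dists, services, pool_runs = FALSE)
  expect_equal(tab2[tab2$group == "R1-R2", "rte_mean"],
               mean(rowMeans(theta)))
})

test_that("quartile classification follows the quantile-cut convention", {
  mk <- function(means) {
    theta <- matrix(rep(means, each = 2), ncol = 2, byrow = TRUE,
                    dimnames = list(paste0("s", seq_along(means)), NULL))
    classes <- matrix("inefficient", length(means), 2,
                      dimnames = dimnames(theta))
    rte_distributions(theta, classes)
  }
  q8 <- classify_quartiles(mk(seq(0.1, 0.8, by = 0.1)))
  expect_equal(as.integer(table(q8)), rep(2L, 4))
  expect_equal(unname(q8[c("s1", "s8")]), c(1L, 4L))

  # five services: (2, 1, 1, 1) under the 25/50/75% type-7 cuts
  q5 <- classify_quartiles(mk(c(0.5, 0.6, 0.7, 0.8, 0.9)))
  expect_equal(as.integer(table(q5)), c(2L, 1L, 1L, 1L))

  # permutation invariance
  d <- mk(c(0.3, 0.9, 0.5, 0.7, 0.4, 0.6))
  q <- classify_quartiles(d)
  qp <- classify_quartiles(d[sample(length(d))])
  expect_equal(qp[names(q)], q)

  expect_error(classify_quartiles(mk(c(0.1, 0.2, 0.3))), "at least 4")
})

test_that("mann_whitney matches exhaustive permutation on small samples", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(mw$exact)

  same <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p_value, 1)

  set.seed(77)
  for (i in 1:15) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    g1 <- round(runif(n1, 0, 20), 1); g2 <- round(runif(n2, 0, 20), 1)
    if (any(duplicated(c(g1, g2)))) next  # oracle ties handled separately
    mw <- mann_whitney(g1, g2)
    expect_equal(mw$p_value, mw_perm_oracle(g1, g2), tolerance = 1e-9)
    expect_true(mw$U >= 0 && mw$U <= n1 * n2)
  }
})

test_that("a planted +5 nurse median shift is detected with power >= 0.8", {
  set.seed(123)
  hits <- replicate(20, {
    q1 <- draw_workforce_counts(10, 5)
    q4 <- draw_workforce_counts(10, 10)  # +5 median shift
    mann_whitney(q1, q4)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("compare_workforce reports gross and rate comparisons", {
  set.seed(11)
  eco <- generate_ecosystem(generator_config(seed = 11))
  sv <- eco$services
  t1_ids <- sv$service_id[sv$typology == "T1"]
  q1 <- t1_ids[1:5]; q4 <- t1_ids[6:10]
  denom <- stats::setNames(sv$beds, sv$service_id)
  cmp <- compare_workforce(sv, q1, q4, denominators = denom)
  expect_setequal(unique(cmp$variable),
                  c(workforce_categories(), "overall"))
  expect_setequal(unique(cmp$basis), c("gross", "rate"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_equal(cmp$significant, cmp$p_value < 0.05)
  expect_error(compare_workforce(sv, character(0), q4), "non-empty")
})
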