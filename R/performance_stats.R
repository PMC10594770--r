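#' @title RTE distributions, quartiles and workforce comparison
#'
#' @description
#' Each Monte Carlo run yields one DEA score per service; over the runs
#' this gives the service's relative technical efficiency (RTE)
#' distribution. The summary follows the study convention: RTE average,
#' standard deviation, error (95% CI half-width) and error percentage,
#' together with the per-run class frequencies P(efficient),
#' P(weakly efficient), P(inefficient) and P(RTE > 0.75). Services are
#' then ranked into quartiles by RTE average within typology and the
#' workforce of the least (Q1) and most (Q4) efficient services is
#' compared with the Mann-Whitney U test.
#'
#' @name performance_stats
NULL

#' Summarise one service's RTE distribution
#'
#' @param theta_samples Numeric vector of per-run DEA scores (>= 2).
#' @param classification_samples Character vector of per-run classes
#'   (`"efficient"`, `"weakly_efficient"`, `"inefficient"`), same length.
#' @param threshold_pct Convergence limit for the error percentage.
#' @return List with `n_runs`, `mean`, `sd`, `error`, `error_pct`,
#'   `converged`, `p_efficient`, `p_weakly_efficient`, `p_inefficient`,
#'   `p_gt_075`.
#' @export
summarize_rte <- function(theta_samples, classification_samples,
                          threshold_pct = 2.5) {
  n <- length(theta_samples)
  if (n < 2L) stop("need at least 2 runs", call. = FALSE)
  stopifnot(length(classification_samples) == n)
  bad <- setdiff(unique(classification_samples),
                 c("efficient", "weakly_efficient", "inefficient"))
  if (length(bad) > 0L) {
    stop("unknown classification value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  err <- error_statistic(theta_samples, threshold_pct)
  list(n_runs = n,
       mean = mean(theta_samples),
       sd = stats::sd(theta_samples),
       error = err$absolute,
       error_pct = err$percentage,
       converged = err$converged,
       p_efficient = mean(classification_samples == "efficient"),
       p_weakly_efficient = mean(classification_samples ==
                                   "weakly_efficient"),
       p_inefficient = mean(classification_samples == "inefficient"),
       p_gt_075 = mean(theta_samples > 0.75))
}

#' Build per-service RTE distributions from run-level DEA results
#'
#' @param theta_matrix Service x run matrix of DEA scores (rownames are
#'   service ids).
#' @param class_matrix Service x run character matrix of classes.
#' @param threshold_pct Convergence limit.
#' @return List of class `rte_distributions`: per-service list with
#'   `theta_samples`, `classification_samples`, `statistics`.
#' @export
rte_distributions <- function(theta_matrix, class_matrix,
                              threshold_pct = 2.5) {
  stopifnot(all(dim(theta_matrix) == dim(class_matrix)))
  ids <- rownames(theta_matrix)
  out <- lapply(seq_len(nrow(theta_matrix)), function(i) {
    list(service_id = ids[i],
         theta_samples = theta_matrix[i, ],
         classification_samples = class_matrix[i, ],
         statistics = summarize_rte(theta_matrix[i, ], class_matrix[i, ],
                                    threshold_pct))
  })
  names(out) <- ids
  structure(out, class = "rte_distributions")
}

rte_stats_row <- function(theta, classes, label, threshold_pct = 2.5) {
  st <- summarize_rte(theta, classes, threshold_pct)
  data.frame(group = label, n_services = NA_integer_,
             rte_mean = st$mean, rte_sd = st$sd, rte_error = st$error,
             rte_error_pct = st$error_pct,
             p_efficient = st$p_efficient,
             p_weakly_efficient = st$p_weakly_efficient,
             p_inefficient = st$p_inefficient, p_gt_075 = st$p_gt_075,
             stringsAsFactors = FALSE)
}

#' Aggregate RTE statistics per DESDE code and per typology
#'
#' Group rows pool the run-level samples of the group's services (the
#' per-run score distribution is the primary source); set
#' `pool_runs = FALSE` to average service-level statistics instead.
#'
#' @param dists An [rte_distributions()] object.
#' @param services Validated service table (supplies the code of each
#'   service).
#' @param pool_runs Pool run-level samples (default) or average
#'   service-level statistics.
#' @param threshold_pct Convergence limit.
#' @return data.frame, one row per DESDE code present plus one per
#'   typology grouping.
#' @export
aggregate_by_code <- function(dists, services, pool_runs = TRUE,
                              threshold_pct = 2.5) {
  services <- validate_services(services)
  code_of <- stats::setNames(services$desde_code, services$service_id)
  ids <- names(dists)
  groups <- c(as.list(stats::setNames(nm = sort(unique(code_of[ids])))),
              list("R1-R2" = c("R1", "R2"),
                   "R9-R13" = c("R9", "R11", "R12", "R13"),
                   "O8-O10" = c("O8", "O9", "O10")))
  rows <- list()
  for (g in names(groups)) {
    members <- ids[code_of[ids] %in% groups[[g]]]
    if (length(members) == 0L) {
      # typology groupings outside the analysed set are omitted silently;
      # an empty single-code group is a data problem worth a notice
      if (!grepl("-", g)) message("empty group omitted from RTE table: ", g)
      next
    }
    if (pool_runs) {
      theta <- unlist(lapply(dists[members], `[[`, "theta_samples"),
                      use.names = FALSE)
      classes <- unlist(lapply(dists[members], `[[`,
                               "classification_samples"),
                        use.names = FALSE)
      row <- rte_stats_row(theta, classes, g, threshold_pct)
    } else {
      stats_list <- lapply(dists[members], `[[`, "statistics")
      avg <- function(f) mean(vapply(stats_list, `[[`, numeric(1), f))
      row <- data.frame(group = g, n_services = NA_integer_,
                        rte_mean = avg("mean"), rte_sd = avg("sd"),
                        rte_error = avg("error"),
                        rte_error_pct = avg("error_pct"),
                        p_efficient = avg("p_efficient"),
                        p_weakly_efficient = avg("p_weakly_efficient"),
                        p_inefficient = avg("p_inefficient"),
                        p_gt_075 = avg("p_gt_075"),
                        stringsAsFactors = FALSE)
    }
    row$n_services <- length(members)
    rows[[g]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify services into RTE quartiles within a typology
#'
#' Cuts are the type-7 25/50/75% quantiles of the service RTE means; a
#' service falls in the lowest quartile whose cut its mean does not
#' exceed. Ties in the means are broken by service id, making the
#' assignment deterministic and order-invariant.
#'
#' @param dists An [rte_distributions()] object (services of one
#'   typology; >= 4 services).
#' @return Named integer vector: service id -> quartile (1 = least
#'   efficient, 4 = most efficient).
#' @export
classify_quartiles <- function(dists) {
  ids <- names(dists)
  if (length(ids) < 4L) stop("need at least 4 services", call. = FALSE)
  means <- vapply(dists, function(d) d$statistics$mean, numeric(1))
  ord <- order(means, ids)  # deterministic tie-break
  means <- means[ord]; ids <- ids[ord]
  cuts <- stats::quantile(means, c(0.25, 0.50, 0.75), type = 7)
  q <- findInterval(means, cuts, left.open = TRUE) + 1L
  stats::setNames(q, ids)[names(dists)]
}

#' Mann-Whitney U comparison of two groups
#'
#' Exact two-sided p-value when the combined sample size is at most 20
#' and there are no ties; otherwise the normal approximation with tie
#' correction. The U statistic counts pairs where a group-1 value exceeds
#' a group-2 value (plus half-ties).
#'
#' @param g1,g2 Numeric vectors (both non-empty).
#' @return List with `U`, `p_value`, `n1`, `n2`, `exact`.
#' @export
mann_whitney <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty",
                                 call. = FALSE)
  ties <- any(duplicated(c(g1, g2)))
  exact <- (n1 + n2 <= 20L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(g1, g2, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n1 = n1, n2 = n2, exact = exact)
}

#' Compare workforce between least and most efficient services
#'
#' For each workforce category and the overall total, gross headcounts
#' (and, when `denominators` are supplied, rates per bed or per user) of
#' the first- and fourth-quartile services are compared with the
#' Mann-Whitney U test at the 0.05 level.
#'
#' @param services Validated service table.
#' @param q1_ids,q4_ids Service ids of the first and fourth quartiles.
#' @param denominators Optional named numeric vector (service id ->
#'   denominator) to additionally compare rates.
#' @return data.frame with one row per variable: medians (and means for
#'   rates), U, p-value and significance flag.
#' @export
compare_workforce <- function(services, q1_ids, q4_ids,
                              denominators = NULL) {
  services <- validate_services(services)
  if (length(q1_ids) == 0L || length(q4_ids) == 0L) {
    stop("both quartile groups must be non-empty", call. = FALSE)
  }
  rownames(services) <- services$service_id
  cats <- c(workforce_categories(), "overall")
  grab <- function(ids, cat) {
    if (cat == "overall") {
      rowSums(services[ids, workforce_categories(), drop = FALSE])
    } else services[ids, cat]
  }
  rows <- lapply(cats, function(cat) {
    v1 <- grab(q1_ids, cat); v4 <- grab(q4_ids, cat)
    mw <- mann_whitney(v1, v4)
    row <- data.frame(variable = cat, basis = "gross",
                      q1_median = stats::median(v1),
                      q4_median = stats::median(v4),
                      q1_mean = mean(v1), q4_mean = mean(v4),
                      U = mw$U, p_value = mw$p_value,
                      significant = mw$p_value < 0.05,
                      stringsAsFactors = FALSE)
    if (!is.null(denominators)) {
      r1 <- v1 / denominators[q1_ids]; r4 <- v4 / denominators[q4_ids]
      mwr <- mann_whitney(r1, r4)
      row <- rbind(row, data.frame(
        variable = cat, basis = "rate",
        q1_median = stats::median(r1), q4_median = stats::median(r4),
        q1_mean = mean(r1), q4_mean = mean(r4),
        U = mwr$U, p_value = mwr$p_value,
        significant = mwr$p_value < 0.05, stringsAsFactors = FALSE))
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
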