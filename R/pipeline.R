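#' @title End-to-end stochastic fuzzy-DEA pipeline
#'
#' @description
#' Orchestrates the full analysis: load and validate the service table,
#' compute typology rate matrices, run the pattern-of-use regressions,
#' build (or load) the appropriateness rule base, perturb the rates with
#' the Monte Carlo engine, transform every run with the fuzzy engine,
#' solve input-oriented VRS DEA per run, aggregate RTE distributions and
#' statistics, classify quartiles and compare the workforce of the least
#' and most efficient services.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param input Path to a service CSV, a service data.frame, or an
#'   `mh_ecosystem`.
#' @param typologies Typologies to analyse.
#' @param n_runs Monte Carlo runs per service (study setting: 1000).
#' @param seed Root RNG seed.
#' @param percentages Perturbation percentages: `c(down, up)` or a named
#'   per-variable list; default 30% both sides.
#' @param error_threshold_pct Convergence limit on the RTE error
#'   percentage (study setting: 2.5).
#' @param rule_base_path Optional JSON rule-base file; when `NULL` a
#'   data-quantile default rule base is derived per typology.
#' @param rule_quantiles Quantile pair for the default rule base.
#' @param dea_tol DEA classification tolerance.
#' @param subset_policy `"typology"` (default) or `"pattern"`: whether T2
#'   DEA is run on the whole typology or separately per pattern of use.
#' @param pool_runs Pooling mode for group RTE statistics.
#' @param out_dir Optional output directory; when given, tabular and JSON
#'   reports plus a run manifest are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, typologies = c("T1", "T2", "T3"),
                            n_runs = 1000L, seed = 1L,
                            percentages = c(0.30, 0.30),
                            error_threshold_pct = 2.5,
                            rule_base_path = NULL,
                            rule_quantiles = c(0.40, 0.60),
                            dea_tol = 1e-6,
                            subset_policy = c("typology", "pattern"),
                            pool_runs = TRUE,
                            out_dir = NULL) {
  subset_policy <- match.arg(subset_policy)
  if (n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)
  if (error_threshold_pct <= 0) stop("error threshold must be > 0",
                                     call. = FALSE)
  if (is.character(input) && !file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  if (!is.null(rule_base_path) && !file.exists(rule_base_path)) {
    stop("rule base file not found: ", rule_base_path, call. = FALSE)
  }
  structure(list(input = input, typologies = typologies,
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 percentages = percentages,
                 error_threshold_pct = error_threshold_pct,
                 rule_base_path = rule_base_path,
                 rule_quantiles = rule_quantiles, dea_tol = dea_tol,
                 subset_policy = subset_policy, pool_runs = pool_runs,
                 out_dir = out_dir),
            class = "pipeline_config")
}

load_pipeline_input <- function(input) {
  if (inherits(input, "mh_ecosystem")) return(input$services)
  if (is.data.frame(input)) return(validate_services(input))
  read_services(input)
}

# DEA over every run of a simulation batch, after fuzzy transformation
run_dea_over_batch <- function(batch, rb, input_vars, output_vars,
                               dea_tol) {
  ns <- dim(batch)[1L]; n_runs <- dim(batch)[3L]
  ids <- dimnames(batch)[[1L]]
  theta <- matrix(NA_real_, ns, n_runs, dimnames = list(ids, NULL))
  classes <- matrix(NA_character_, ns, n_runs,
                    dimnames = list(ids, NULL))
  for (r in seq_len(n_runs)) {
    mat <- transform_matrix(rb, batch[, , r, drop = TRUE])
    if (ns == 1L) mat <- matrix(mat, nrow = 1,
                                dimnames = list(ids, names(mat)))
    inp <- pmax(mat[, input_vars, drop = FALSE], 0)
    outp <- pmax(mat[, output_vars, drop = FALSE], 0)
    prob <- suppressWarnings(dea_problem(inp, outp, ids))
    res <- solve_all(prob, dea_tol)
    theta[, r] <- res$summary$theta
    classes[, r] <- res$summary$classification
  }
  list(theta = theta, classes = classes)
}

analyse_typology <- function(services, typology, cfg) {
  rm <- rates_matrix(services, typology)
  if (length(rm$ids) < 2L) {
    return(list(typology = typology, skipped = TRUE,
                reason = "fewer than 2 rate-computable services"))
  }
  def <- typology_definition(typology)
  raw <- cbind(rm$inputs, rm$outputs)
  roles <- c(rep("input", ncol(rm$inputs)),
             rep("output", ncol(rm$outputs)))
  rb <- if (!is.null(cfg$rule_base_path)) {
    read_rule_base(cfg$rule_base_path, variables = colnames(raw))
  } else {
    default_rule_base(raw, roles, cfg$rule_quantiles[1L],
                      cfg$rule_quantiles[2L])
  }
  subsets <- list(all = rm$ids)
  pattern_split <- NULL
  if (typology == "T2" && length(rm$ids) >= 4L) {
    rows <- services[match(rm$ids, services$service_id), ]
    pattern_split <- split_patterns(rows$users, rows$beds,
                                    rows$service_id)
    if (cfg$subset_policy == "pattern" &&
        !is.null(pattern_split$turnover)) {
      asn <- pattern_split$assignment
      subsets <- split(names(asn), asn)
    }
  }
  theta <- NULL; classes <- NULL
  for (ids_sub in subsets) {
    keep <- match(ids_sub, rm$ids)
    batch <- run_simulation(raw[keep, , drop = FALSE], cfg$percentages,
                            cfg$n_runs, cfg$seed)
    dea <- run_dea_over_batch(batch, rb,
                              colnames(rm$inputs), colnames(rm$outputs),
                              cfg$dea_tol)
    theta <- rbind(theta, dea$theta)
    classes <- rbind(classes, dea$classes)
  }
  theta <- theta[rm$ids, , drop = FALSE]
  classes <- classes[rm$ids, , drop = FALSE]
  dists <- rte_distributions(theta, classes, cfg$error_threshold_pct)
  not_conv <- names(dists)[!vapply(dists, function(d)
    isTRUE(d$statistics$converged), logical(1))]
  if (cfg$n_runs >= 2L && length(not_conv) > 0L) {
    warning(typology, ": RTE error percentage above ",
            cfg$error_threshold_pct, "% for ", length(not_conv),
            " service(s); consider more runs", call. = FALSE)
  }
  table3 <- aggregate_by_code(dists, services, cfg$pool_runs,
                              cfg$error_threshold_pct)
  quartiles <- if (length(dists) >= 4L) classify_quartiles(dists)
               else NULL
  comparison <- NULL
  if (!is.null(quartiles)) {
    q1 <- names(quartiles)[quartiles == 1L]
    q4 <- names(quartiles)[quartiles == 4L]
    if (length(q1) > 0L && length(q4) > 0L) {
      denom_col <- def$rate_basis
      denom <- stats::setNames(services[[denom_col]],
                               services$service_id)[rm$ids]
      comparison <- compare_workforce(services, q1, q4,
                                      denominators = denom)
    }
  }
  list(typology = typology, skipped = FALSE, ids = rm$ids,
       excluded = rm$excluded, rule_base = rb,
       pattern_split = pattern_split, usage = summarize_usage(services,
                                                              typology),
       distributions = dists, rte_table = table3,
       quartiles = quartiles, workforce_comparison = comparison,
       not_converged = not_conv)
}

#' Run the full analysis pipeline
#'
#' Convergence failures (RTE error percentage above the threshold) warn
#' and recommend more runs rather than aborting: the threshold is a
#' quality limit, and desk-scale runs legitimately use fewer runs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: one entry per typology plus a
#'   `manifest` (config snapshot, seed, convergence report, output file
#'   inventory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  services <- load_pipeline_input(config$input)
  results <- lapply(config$typologies, function(typ)
    analyse_typology(services, typ, config))
  names(results) <- config$typologies
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (typ in names(results)) {
      r <- results[[typ]]
      if (isTRUE(r$skipped)) next
      f1 <- file.path(config$out_dir, paste0("rte_", typ, ".csv"))
      utils::write.csv(r$rte_table, f1, row.names = FALSE)
      files <- c(files, f1)
      if (!is.null(r$workforce_comparison)) {
        f2 <- file.path(config$out_dir,
                        paste0("workforce_", typ, ".csv"))
        utils::write.csv(r$workforce_comparison, f2, row.names = FALSE)
        files <- c(files, f2)
      }
      if (!is.null(r$quartiles)) {
        f3 <- file.path(config$out_dir, paste0("quartiles_", typ,
                                               ".csv"))
        utils::write.csv(data.frame(service_id = names(r$quartiles),
                                    quartile = unname(r$quartiles)),
                         f3, row.names = FALSE)
        files <- c(files, f3)
      }
    }
  }
  manifest <- list(
    config = unclass(config[setdiff(names(config), "input")]),
    seed = config$seed, n_runs = config$n_runs,
    convergence = lapply(results, function(r)
      if (isTRUE(r$skipped)) character(0) else r$not_converged),
    outputs = files)
  if (!is.null(config$out_dir)) {
    fm <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, fm, auto_unbox = TRUE, digits = NA,
                         null = "null")
    manifest$outputs <- c(files, fm)
  }
  structure(c(results, list(manifest = manifest)),
            class = "pipeline_result")
}
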