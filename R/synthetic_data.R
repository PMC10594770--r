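#' @title Seeded synthetic service ecosystems
#'
#' @description
#' Generates service tables with the statistical structure the analysis
#' assumes — two T2 patterns of use (beds tracking users with slope 1 versus
#' a high-turnover slope of 0.14), length-of-stay regimes, outpatient
#' contact intensities, and workforce profiles — together with ground-truth
#' labels, so every downstream stage can be tested without the confidential
#' study data.
#'
#' @name synthetic_data
NULL

# gamma draw moment-matched to (mean, sd); degenerate sd -> constant
rgamma_ms <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# lognormal workforce draw with the given median; zero-median categories are
# mostly absent with occasional small counts (FTE, 2 decimals). sdlog 0.5
# keeps within-quartile spread low enough that median shifts of the
# magnitude reported between efficiency quartiles are detectable at the
# study's group sizes, as the published U tests were.
draw_workforce_counts <- function(n, median, sdlog = 0.5) {
  if (median <= 0) {
    present <- stats::rbinom(n, 1L, 0.2)
    return(round(present * stats::runif(n, 0.2, 2), 2))
  }
  round(stats::rlnorm(n, meanlog = log(median), sdlog = sdlog), 2)
}

#' Default generator configuration
#'
#' Defaults encode the regional structure the generator emulates: per-code
#' service counts matching the analysed sample (88 services), a T2
#' high-turnover subset confined to R11, mean lengths of stay of 29.24
#' (T1), 335.2 (T2 standard) and 79.51 (T2 turnover) days/user, outpatient
#' contact intensities of 84.81 (O8) and 14.1 (O9-O10) contacts/user, T1
#' users-per-bed mean 16.26 (SD 9.46), and beds~users noise calibrated so
#' the population R-squared equals the observed 0.897 / 0.970.
#'
#' @param seed Integer RNG seed.
#' @param n_services Named integer vector, services per DESDE code.
#' @param t2_turnover_fraction Proportion of T2 services in the
#'   high-turnover pattern (assigned among R11 services).
#' @param slope_standard,slope_turnover users-to-beds slopes of the two T2
#'   patterns.
#' @param los_means,los_sds Named lists: length-of-stay regimes (days/user)
#'   for `T1`, `T2_standard`, `T2_turnover`. The T1 SD is the observed
#'   descriptive spread; the T2 SDs are calibrated so the total-days on
#'   users regression attains the observed within-pattern R-squared
#'   (0.91 standard, 0.987 turnover) under the default user-count
#'   distributions.
#' @param contact_means,contact_sds Contacts/user regimes for `O8` and
#'   `O9_O10`.
#' @param t1_users_per_bed_mean,t1_users_per_bed_sd T1 annual users per bed.
#' @param noise_cv_standard,noise_cv_turnover Coefficient of variation of
#'   the Gaussian beds~users residual in each T2 pattern: the residual SD
#'   of a service is `cv * slope * users`, so pattern separability does not
#'   depend on service size. Defaults are calibrated so the population
#'   R-squared of each within-pattern fit equals the observed values
#'   (0.897 standard, 0.970 turnover) under the default user-count
#'   distributions.
#' @param workforce_medians Named list (per typology) of named numeric
#'   vectors: median headcount per workforce category.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_services = c(R1 = 2L, R2 = 18L, R9 = 1L,
                                            R11 = 18L, R12 = 8L, R13 = 2L,
                                            O8 = 3L, O9 = 33L, O10 = 3L),
                             t2_turnover_fraction = 4 / 29,
                             slope_standard = 1.0,
                             slope_turnover = 0.14,
                             los_means = list(T1 = 29.24, T2_standard = 335.2,
                                              T2_turnover = 79.51),
                             los_sds = list(T1 = 29.03, T2_standard = 72.5,
                                            T2_turnover = 4.3),
                             contact_means = list(O8 = 84.81, O9_O10 = 14.1),
                             contact_sds = list(O8 = 69.08, O9_O10 = 12.27),
                             t1_users_per_bed_mean = 16.26,
                             t1_users_per_bed_sd = 9.46,
                             noise_cv_standard = 0.233,
                             noise_cv_turnover = 0.083,
                             workforce_medians = NULL) {
  if (is.null(workforce_medians)) {
    workforce_medians <- list(
      T1 = c(psychiatrists = 1.5, psychiatrists_in_training = 0, gps = 0,
             other_doctors = 0, nurses = 10, psychologists = 0.75,
             social_workers = 1, occupational_therapists = 0.5, other = 7),
      T2 = c(psychiatrists = 0, psychiatrists_in_training = 0, gps = 0,
             other_doctors = 0, nurses = 2, psychologists = 0,
             social_workers = 0, occupational_therapists = 0, other = 6),
      T3 = c(psychiatrists = 2.5, psychiatrists_in_training = 0, gps = 0,
             other_doctors = 0, nurses = 6, psychologists = 1.2,
             social_workers = 0.75, occupational_therapists = 0.9,
             other = 2))
  }
  cfg <- list(seed = as.integer(seed), n_services = n_services,
              t2_turnover_fraction = t2_turnover_fraction,
              slope_standard = slope_standard,
              slope_turnover = slope_turnover,
              los_means = los_means, los_sds = los_sds,
              contact_means = contact_means, contact_sds = contact_sds,
              t1_users_per_bed_mean = t1_users_per_bed_mean,
              t1_users_per_bed_sd = t1_users_per_bed_sd,
              noise_cv_standard = noise_cv_standard,
              noise_cv_turnover = noise_cv_turnover,
              workforce_medians = workforce_medians)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (any(cfg$n_services < 0)) stop("n_services must be >= 0", call. = FALSE)
  if (!all(names(cfg$n_services) %in% analysis_codes())) {
    stop("n_services names must be analysis DESDE codes", call. = FALSE)
  }
  if (cfg$t2_turnover_fraction < 0 || cfg$t2_turnover_fraction > 1) {
    stop("t2_turnover_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$slope_standard <= 0 || cfg$slope_turnover <= 0) {
    stop("pattern slopes must be > 0", call. = FALSE)
  }
  if (any(unlist(cfg$los_means) <= 0) || any(unlist(cfg$contact_means) <= 0)) {
    stop("regime means must be > 0", call. = FALSE)
  }
  if (cfg$noise_cv_standard < 0 || cfg$noise_cv_turnover < 0) {
    stop("noise CVs must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a synthetic service ecosystem
#'
#' T2 beds follow `slope * users * (1 + N(0, cv))` per pattern (floored at
#' 1 bed); T1 users-per-bed, lengths of stay and contact intensities are
#' gamma draws moment-matched to the configured mean/SD (non-negative by
#' construction); workforce counts are lognormal around the configured
#' medians. The same seed yields an identical ecosystem.
#'
#' @param config A [generator_config()].
#' @return List of class `mh_ecosystem` with `services` (validated service
#'   table) and `truth` (per-service pattern membership and generating
#'   parameters).
#' @export
generate_ecosystem <- function(config = generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  rows <- list()
  truth <- list()
  counter <- 0L
  n_t2 <- sum(config$n_services[c("R9", "R11", "R12", "R13")], na.rm = TRUE)
  n_r11 <- if ("R11" %in% names(config$n_services))
    config$n_services[["R11"]] else 0L
  n_turn <- min(round(config$t2_turnover_fraction * n_t2), n_r11)
  r11_turn_idx <- seq_len(n_turn)  # first n_turn R11 services are turnover

  for (code in names(config$n_services)) {
    n <- config$n_services[[code]]
    if (n == 0L) next
    typ <- assign_typology(code)
    wf_med <- config$workforce_medians[[typ]]
    wf <- vapply(workforce_categories(),
                 function(cat) draw_workforce_counts(n, wf_med[[cat]]),
                 numeric(n))
    wf <- matrix(wf, nrow = n,
                 dimnames = list(NULL, workforce_categories()))

    if (typ == "T1") {
      # narrow bed-count spread: acute wards are similar in size, and the
      # users~beds relationship must stay uncoupled (the variation in
      # annual users is carried by the users-per-bed rate)
      beds <- pmax(1, round(stats::rlnorm(n, log(30), 0.2)))
      upb <- rgamma_ms(n, config$t1_users_per_bed_mean,
                       config$t1_users_per_bed_sd)
      users <- pmax(1, round(upb * beds))
      los <- rgamma_ms(n, config$los_means$T1, config$los_sds$T1)
      days <- round(los * users)
      apu <- rgamma_ms(n, 1.1, 0.2)  # admissions per user, acute wards
      contacts <- round(apu * users)
      pattern <- rep(NA_character_, n)
    } else if (typ == "T2") {
      is_turn <- if (code == "R11") seq_len(n) %in% r11_turn_idx
                 else rep(FALSE, n)
      users <- ifelse(is_turn,
                      pmax(5, round(stats::rlnorm(n, log(150), 0.5))),
                      pmax(3, round(stats::rlnorm(n, log(30), 0.8))))
      slope <- ifelse(is_turn, config$slope_turnover, config$slope_standard)
      cv <- ifelse(is_turn, config$noise_cv_turnover,
                   config$noise_cv_standard)
      beds <- pmax(1, round(slope * users *
                              (1 + stats::rnorm(n, 0, cv))))
      los <- ifelse(is_turn,
                    rgamma_ms(n, config$los_means$T2_turnover,
                              config$los_sds$T2_turnover),
                    rgamma_ms(n, config$los_means$T2_standard,
                              config$los_sds$T2_standard))
      days <- round(los * users)
      contacts <- round(rgamma_ms(n, 1.0, 0.3) * users)
      pattern <- ifelse(is_turn, "turnover", "standard")
    } else {
      users <- pmax(5, round(stats::rlnorm(n, log(200), 0.9)))
      beds <- rep(0, n)
      days <- rep(0, n)
      cm <- if (code == "O8") config$contact_means$O8
            else config$contact_means$O9_O10
      cs <- if (code == "O8") config$contact_sds$O8
            else config$contact_sds$O9_O10
      cpu <- rgamma_ms(n, cm, cs)
      contacts <- pmax(1, round(cpu * users))
      pattern <- rep(NA_character_, n)
    }

    ids <- sprintf("%s_%03d", code, seq_len(n))
    counter <- counter + n
    rows[[code]] <- data.frame(
      service_id = ids, desde_code = code, beds = beds, users = users,
      days_of_stay = days, contacts = contacts, wf,
      stringsAsFactors = FALSE)
    truth[[code]] <- data.frame(
      service_id = ids, typology = typ, pattern = pattern,
      stringsAsFactors = FALSE)
  }
  services <- do.call(rbind, rows)
  rownames(services) <- NULL
  services <- validate_services(services)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(services = services, truth = truth, config = config),
            class = "mh_ecosystem")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant a DEA problem with a known efficient frontier
#'
#' Frontier DMUs lie on a strictly concave, strictly monotone input-output
#' surface (inputs proportional to `t`, outputs proportional to `sqrt(t)`),
#' so every frontier DMU is strongly efficient under input-oriented VRS
#' DEA. Dominated DMUs are frontier points with all inputs inflated by a
#' recorded factor `gamma > 1`; their expected efficiency score is exactly
#' `1/gamma` (radial contraction back onto the frontier point).
#'
#' @param n_frontier Number of frontier DMUs (>= 1).
#' @param n_dominated Number of dominated DMUs.
#' @param dims Integer pair `c(m, s)`: number of inputs and outputs.
#' @param seed RNG seed.
#' @return List with `inputs`, `outputs` (matrices), `ids`, and `truth`
#'   (data.frame: id, role, inflation, theta_expected).
#' @export
plant_frontier <- function(n_frontier, n_dominated = 0L, dims = c(1L, 1L),
                           seed = 1L) {
  stopifnot(n_frontier >= 1L, n_dominated >= 0L, length(dims) == 2L,
            all(dims >= 1L))
  set.seed(seed)
  m <- dims[1L]; s <- dims[2L]
  a <- stats::runif(m, 0.5, 2)   # input ray direction
  b <- stats::runif(s, 0.5, 2)   # output scale
  t <- sort(stats::runif(n_frontier, 0.2, 4))
  fx <- outer(t, a)              # n_frontier x m
  fy <- outer(sqrt(t), b)
  gamma <- if (n_dominated > 0L) stats::runif(n_dominated, 1.2, 3) else
    numeric(0)
  pick <- if (n_dominated > 0L)
    sample.int(n_frontier, n_dominated, replace = TRUE) else integer(0)
  dx <- fx[pick, , drop = FALSE] * gamma
  dy <- fy[pick, , drop = FALSE]
  inputs <- rbind(fx, dx)
  outputs <- rbind(fy, dy)
  ids <- c(sprintf("F%02d", seq_len(n_frontier)),
           if (n_dominated > 0L) sprintf("D%02d", seq_len(n_dominated)))
  rownames(inputs) <- rownames(outputs) <- ids
  truth <- data.frame(
    service_id = ids,
    role = c(rep("frontier", n_frontier), rep("dominated", n_dominated)),
    inflation = c(rep(1, n_frontier), gamma),
    theta_expected = c(rep(1, n_frontier),
                       if (n_dominated > 0L) 1 / gamma),
    stringsAsFactors = FALSE)
  list(inputs = inputs, outputs = outputs, ids = ids, truth = truth)
}

#' Write an ecosystem to disk (service table CSV + JSON truth side-file)
#'
#' @param ecosystem An `mh_ecosystem`.
#' @param path CSV path for the service table; the truth file is written
#'   next to it with a `.truth.json` suffix.
#' @return `path`, invisibly.
#' @export
write_ecosystem <- function(ecosystem, path) {
  write_services(ecosystem$services, path)
  jsonlite::write_json(ecosystem$truth,
                       paste0(sub("\\.csv$", "", path), ".truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
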