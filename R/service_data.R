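#' @title Service-level data model for DESDE-LTC classified mental-health care
#'
#' @description
#' A service table is a plain `data.frame` with one row per service-year and
#' a fixed column schema: `service_id`, `desde_code`, the annual activity
#' counts `beds`, `users`, `days_of_stay`, `contacts` (admissions for
#' residential services, outpatient contacts otherwise), and one column per
#' workforce category (see [workforce_categories()]).
#'
#' Three analysis typologies group the nine DESDE-LTC codes:
#' * T1 — acute hospital residential care (R1, R2)
#' * T2 — non-acute non-hospital residential care (R9, R11, R12, R13)
#' * T3 — non-acute outpatient care (O8, O9, O10)
#'
#' @name service_data
NULL

#' Workforce headcount categories carried by a service record
#'
#' GPs and other (non-psychiatrist) doctors are part of the data model and of
#' the workforce comparison tables, but are never DEA inputs.
#'
#' @return Character vector of the nine category names, in canonical order.
#' @export
workforce_categories <- function() {
  c("psychiatrists", "psychiatrists_in_training", "gps", "other_doctors",
    "nurses", "psychologists", "social_workers", "occupational_therapists",
    "other")
}

#' DESDE-LTC codes retained for analysis
#' @return Character vector of the nine analysed codes.
#' @export
analysis_codes <- function() {
  c("R1", "R2", "R9", "R11", "R12", "R13", "O8", "O9", "O10")
}

#' Canonical column names of a service table
#' @return Character vector of required columns.
#' @export
service_columns <- function() {
  c("service_id", "desde_code", "beds", "users", "days_of_stay", "contacts",
    workforce_categories())
}

#' Typology definition: member codes, DEA variable lists and rate basis
#'
#' @param label One of `"T1"`, `"T2"`, `"T3"`.
#' @return A list with elements `label`, `member_codes`, `input_categories`
#'   (workforce categories used as DEA inputs), `outputs` (output variable
#'   names) and `rate_basis` (`"beds"` or `"users"`).
#' @export
typology_definition <- function(label) {
  label <- match.arg(label, c("T1", "T2", "T3"))
  staff7 <- c("psychiatrists", "psychiatrists_in_training", "nurses",
              "psychologists", "social_workers", "occupational_therapists",
              "other")
  switch(label,
    T1 = list(label = "T1", member_codes = c("R1", "R2"),
              input_categories = staff7,
              outputs = c("length_of_stay_per_user", "users_per_bed",
                          "admissions_per_bed"),
              rate_basis = "beds"),
    T2 = list(label = "T2", member_codes = c("R9", "R11", "R12", "R13"),
              input_categories = c("psychiatrists", "nurses",
                                   "social_workers",
                                   "occupational_therapists", "other"),
              outputs = c("length_of_stay_per_user", "users_per_bed"),
              rate_basis = "beds"),
    T3 = list(label = "T3", member_codes = c("O8", "O9", "O10"),
              input_categories = staff7,
              outputs = "contacts_per_user",
              rate_basis = "users"))
}

#' Map DESDE-LTC codes to analysis typologies
#'
#' Codes outside the nine analysed ones map to `NA` (out-of-analysis), never
#' to an error, so directory files containing day-care or mobile codes can be
#' read and flagged rather than rejected.
#'
#' @param desde_code Character vector of DESDE-LTC codes.
#' @return Character vector with values `"T1"`, `"T2"`, `"T3"` or `NA`.
#' @export
assign_typology <- function(desde_code) {
  out <- rep(NA_character_, length(desde_code))
  out[desde_code %in% c("R1", "R2")] <- "T1"
  out[desde_code %in% c("R9", "R11", "R12", "R13")] <- "T2"
  out[desde_code %in% c("O8", "O9", "O10")] <- "T3"
  out
}

#' Validate a service table against the data-model invariants
#'
#' @param services A data.frame in the canonical schema.
#' @return The validated data.frame (invisibly unchanged), with a
#'   `typology` column added if absent.
#' @export
validate_services <- function(services) {
  stopifnot(is.data.frame(services))
  missing <- setdiff(service_columns(), names(services))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  count_cols <- setdiff(service_columns(), c("service_id", "desde_code"))
  for (cc in count_cols) {
    v <- services[[cc]]
    if (!is.numeric(v)) {
      stop("column '", cc, "' must be numeric", call. = FALSE)
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0L) {
      stop("negative or non-finite count in column '", cc, "', row ",
           bad[1L], " (service ", services$service_id[bad[1L]], ")",
           call. = FALSE)
    }
  }
  if (anyDuplicated(services$service_id)) {
    stop("duplicated service_id values", call. = FALSE)
  }
  services$typology <- assign_typology(services$desde_code)
  invisible(services)
}

#' Read a service table from a comma-separated file
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(beds = "Beds_total")`.
#' @return A validated data.frame with an added `typology` column; rows with
#'   unknown DESDE codes are retained with `typology = NA`.
#' @export
read_services <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      file_col <- schema[[canon]]
      if (!file_col %in% names(df)) {
        stop("schema maps '", canon, "' to absent column '", file_col, "'",
             call. = FALSE)
      }
      names(df)[names(df) == file_col] <- canon
    }
  }
  df <- df[, intersect(c(service_columns(), setdiff(names(df),
                                                    service_columns())),
                       names(df)), drop = FALSE]
  services <- validate_services(df)
  services$service_id <- as.character(services$service_id)
  services
}

#' Write a service table as CSV
#'
#' Round-trips losslessly through [read_services()].
#'
#' @param services Validated service table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_services <- function(services, path) {
  keep <- intersect(c(service_columns(), "typology"), names(services))
  utils::write.csv(services[, keep, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Compute the DEA rate profile of one service record
#'
#' Staff rates are headcount per bed for residential typologies (T1, T2) and
#' per user for outpatient care (T3); `length_of_stay_per_user` is annual
#' days over annual users; `users_per_bed` and `admissions_per_bed` are per
#' bed; `contacts_per_user` per user. Rate bases follow the typology
#' definition; a zero denominator raises an undefined-rate error naming the
#' service and variable.
#'
#' @param record A one-row service data.frame (canonical schema).
#' @return List with `service_id`, `typology`, `inputs` (named numeric) and
#'   `outputs` (named numeric).
#' @export
compute_rates <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  typ <- assign_typology(record$desde_code)
  if (is.na(typ)) {
    stop("service ", record$service_id, ": code ", record$desde_code,
         " is outside the analysed typologies", call. = FALSE)
  }
  def <- typology_definition(typ)
  denom <- record[[def$rate_basis]]
  if (denom <= 0) {
    stop("undefined rate for service ", record$service_id,
         ": zero ", def$rate_basis, " (staff rates)", call. = FALSE)
  }
  inputs <- vapply(def$input_categories,
                   function(cat) record[[cat]] / denom, numeric(1))
  outputs <- numeric(0)
  for (ov in def$outputs) {
    outputs[[ov]] <- switch(ov,
      length_of_stay_per_user = {
        if (record$users <= 0) {
          stop("undefined rate for service ", record$service_id,
               ": zero users (length_of_stay_per_user)", call. = FALSE)
        }
        record$days_of_stay / record$users
      },
      users_per_bed = record$users / record$beds,
      admissions_per_bed = record$contacts / record$beds,
      contacts_per_user = record$contacts / record$users)
  }
  list(service_id = as.character(record$service_id), typology = typ,
       inputs = inputs, outputs = outputs)
}

#' Assemble the DEA rate matrices of one typology
#'
#' Services whose rates are undefined (zero denominator) are excluded from
#' the matrices, reported in the `excluded` element, and noted via
#' `message()`; the paper-style analysis never imputes.
#'
#' @param services Validated service table.
#' @param typology `"T1"`, `"T2"` or `"T3"`.
#' @return List with `ids`, `inputs` (service x category matrix), `outputs`
#'   (service x variable matrix) and `excluded` (data.frame of id + reason).
#' @export
rates_matrix <- function(services, typology) {
  services <- validate_services(services)
  def <- typology_definition(typology)
  rows <- services[services$typology %in% def$label, , drop = FALSE]
  profiles <- list()
  excluded <- data.frame(service_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rows))) {
    p <- tryCatch(compute_rates(rows[i, , drop = FALSE]), error = identity)
    if (inherits(p, "error")) {
      excluded <- rbind(excluded, data.frame(
        service_id = as.character(rows$service_id[i]),
        reason = conditionMessage(p), stringsAsFactors = FALSE))
    } else {
      profiles[[length(profiles) + 1L]] <- p
    }
  }
  if (nrow(excluded) > 0L) {
    message(nrow(excluded), " service(s) excluded from ", typology,
            " DEA: ", paste(excluded$service_id, collapse = ", "))
  }
  ids <- vapply(profiles, `[[`, character(1), "service_id")
  inp <- do.call(rbind, lapply(profiles, `[[`, "inputs"))
  out <- do.call(rbind, lapply(profiles, `[[`, "outputs"))
  if (length(profiles) > 0L) {
    rownames(inp) <- rownames(out) <- ids
    colnames(inp) <- def$input_categories
    colnames(out) <- def$outputs
  }
  list(ids = ids, inputs = inp, outputs = out, excluded = excluded)
}
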