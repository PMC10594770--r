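test_that("typology assignment maps the nine analysis codes and nothing else", {
  expect_equal(assign_typology("R2"), "T1")
  expect_equal(assign_typology("O10"), "T3")
  expect_true(is.na(assign_typology("R10")))
  # the three typologies partition exactly the nine analysis codes
  typ <- assign_typology(analysis_codes())
  expect_false(anyNA(typ))
  expect_equal(sort(unique(typ)), c("T1", "T2", "T3"))
  for (lab in c("T1", "T2", "T3")) {
    def <- typology_definition(lab)
    expect_setequal(def$member_codes,
                    analysis_codes()[typ == lab])
  }
  # idempotent / total on arbitrary strings
  expect_true(all(is.na(assign_typology(c("", "X1", "R99")))))
})

test_that("typology definitions carry the declared DEA variable sets", {
  t1 <- typology_definition("T1")
  t2 <- typology_definition("T2")
  t3 <- typology_definition("T3")
  expect_length(t1$input_categories, 7)
  expect_length(t2$input_categories, 5)
  expect_identical(t3$input_categories, t1$input_categories)
  expect_equal(t1$outputs, c("length_of_stay_per_user", "users_per_bed",
                             "admissions_per_bed"))
  expect_equal(t2$outputs, c("length_of_stay_per_user", "users_per_bed"))
  expect_equal(t3$outputs, "contacts_per_user")
  expect_equal(t3$rate_basis, "users")
})

test_that("read_services round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_services(tiny_services(), path)
  got <- read_services(path)
  expect_equal(nrow(got), 3L)
  expect_equal(got$typology, c("T1", "T2", "T3"))
  expect_equal(got$beds, c(10, 20, 0))

  bad <- tiny_services(); bad$beds[1] <- -1
  expect_error(validate_services(bad), "negative.*beds")
  missing_col <- tiny_services(); missing_col$nurses <- NULL
  expect_error(validate_services(missing_col), "nurses")
  # schema remapping
  renamed <- tiny_services()
  names(renamed)[names(renamed) == "beds"] <- "Beds_total"
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(renamed, p2, row.names = FALSE)
  got2 <- read_services(p2, schema = c(beds = "Beds_total"))
  expect_equal(got2$beds, c(10, 20, 0))
  expect_error(read_services(p2, schema = c(beds = "nope")), "nope")
})

test_that("a generated 229-service ecosystem round-trips losslessly", {
  ns <- c(R1 = 5L, R2 = 47L, R9 = 3L, R11 = 47L, R12 = 21L, R13 = 5L,
          O8 = 8L, O9 = 86L, O10 = 7L)  # sums to 229
  eco <- generate_ecosystem(generator_config(seed = 9, n_services = ns))
  expect_equal(nrow(eco$services), 229L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_services(eco$services, path)
  got <- read_services(path)
  expect_equal(got[service_columns()], eco$services[service_columns()])
})

test_that("compute_rates uses the typology's rate basis", {
  sv <- tiny_services()
  r2 <- compute_rates(sv[2, ])  # T2: nurses 1 over 20 beds
  expect_equal(unname(r2$inputs[["nurses"]]), 1 / 20)
  expect_equal(unname(r2$outputs[["users_per_bed"]]), 25 / 20)
  r1 <- compute_rates(sv[1, ])  # T1: 2924 days over 100 users
  expect_equal(unname(r1$outputs[["length_of_stay_per_user"]]), 29.24)
  r3 <- compute_rates(sv[3, ])  # T3: per-user basis
  expect_equal(unname(r3$inputs[["nurses"]]), 1 / 400)
  expect_equal(unname(r3$outputs[["contacts_per_user"]]), 10)

  zero_users <- sv[3, ]; zero_users$users <- 0
  expect_error(compute_rates(zero_users), "undefined rate.*s3")
})

test_that("rates round-trip and matrices share the typology key set", {
  eco <- generate_ecosystem(generator_config(seed = 3))
  sv <- eco$services
  for (i in sample(nrow(sv), 10)) {
    rec <- sv[i, ]
    p <- compute_rates(rec)
    def <- typology_definition(p$typology)
    expect_identical(names(p$inputs), def$input_categories)
    expect_identical(names(p$outputs), def$outputs)
    denom <- rec[[def$rate_basis]]
    # multiplying back by the denominator recovers raw headcounts
    expect_equal(unname(p$inputs * denom),
                 unname(unlist(rec[def$input_categories])),
                 tolerance = 1e-12)
  }
  rm <- rates_matrix(sv, "T2")
  expect_equal(colnames(rm$inputs),
               typology_definition("T2")$input_categories)
  expect_true(all(is.finite(rm$inputs)), all(rm$inputs >= 0))
  expect_equal(rownames(rm$inputs), rm$ids)
})

test_that("zero-denominator services are excluded with a notice, not imputed", {
  sv <- tiny_services()
  sv$beds[2] <- 0  # T2 service without beds
  expect_message(rm <- rates_matrix(sv, "T2"), "excluded")
  expect_equal(nrow(rm$excluded), 1L)
  expect_equal(rm$excluded$service_id, "s2")
  expect_length(rm$ids, 0L)
})
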