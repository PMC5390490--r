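test_that("leaf records survive a write-read round trip losslessly", {
  df <- make_leaf_df(3)
  df$AN <- df$AN + pi * 1e-8  # exercise full float precision
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(df, path)
  back <- read_leaf_records(path)
  for (cl in setdiff(names(df), "treatment"))
    expect_equal(back[[cl]], df[[cl]], tolerance = 0)
  expect_equal(back$treatment, rep("control", 3))
})

test_that("well-formed files load and row-level violations are located", {
  df <- make_leaf_df(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(df, path)
  expect_equal(nrow(read_leaf_records(path)), 3)

  bad <- df
  bad$Fs[2] <- 0.9  # exceeds Fm_prime = 0.7
  write_records(bad, path)
  expect_error(read_leaf_records(path), "Fm_prime < Fs.*2")
})

test_that("missing mandatory columns give a schema error", {
  df <- make_leaf_df(2)
  df$gs <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(df, path)
  expect_error(read_leaf_records(path), "missing mandatory column.*gs")
})

test_that("column maps rename instrument headers to canonical names", {
  df <- make_leaf_df(2)
  names(df)[names(df) == "AN"] <- "Photo"
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(df, path)
  got <- read_leaf_records(path, col_map = list(AN = "Photo"))
  expect_equal(got$AN, c(15, 16))
})

test_that("treatment labels map the 2x2 factorial to the four conditions", {
  expect_equal(
    treatment_label(c("WW", "WD", "WW", "WD"),
                    c("control25", "control25", "HT38", "HT38")),
    c("control", "WD", "HT", "HT-WD"))
  expect_error(treatment_label("dry", "control25"))
})

test_that("constants carry paper kcat values and provenance flags", {
  for (sp in c("rice", "wheat", "maize")) {
    k <- kinetic_constants(sp)
    prov <- attr(k, "provenance")
    expect_equal(prov[["kcat"]], "paper")
    expect_true(all(prov[setdiff(names(prov), "kcat")] ==
                      "literature-default"))
    expect_setequal(names(prov), names(k))
  }
  expect_equal(kinetic_constants("maize")$kcat, 4.1)
  expect_equal(kinetic_constants("rice")$kcat, 2.1)
  expect_equal(kinetic_constants("wheat")$kcat, 2.2)
})

test_that("constant overrides are applied last and flagged as user", {
  k <- kinetic_constants("rice", list(gamma_star = 40))
  expect_equal(k$gamma_star, 40)
  expect_equal(attr(k, "provenance")[["gamma_star"]], "user")
  expect_error(kinetic_constants("rice", list(kcat = 0)), "positive")
  expect_error(kinetic_constants("rice", list(bogus = 1)), "unknown")
})

test_that("load_constants merges a YAML file before programmatic overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("constants:\n  gamma_star: 38.6\n  Kp: 95", path)
  k <- load_constants("maize", path)
  expect_equal(k$gamma_star, 38.6)
  expect_equal(k$Kp, 95)
  k2 <- load_constants("maize", path, overrides = list(gamma_star = 41))
  expect_equal(k2$gamma_star, 41)
})

test_that("biochem validation tolerates small initial>total noise only", {
  bio <- data.frame(
    species = "rice", irrigation = "WW", temperature = "control25",
    replicate_id = "r1", initial_activity = 0.37, total_activity = 0.36,
    rubisco_amount = 0.49, rca_total = 1, rca_large = 1, rca_small = 1)
  expect_silent(validate_biochem_records(bio))   # within 5% slack
  bio$initial_activity <- 0.40
  expect_error(validate_biochem_records(bio), "exceeds total")
})

test_that("A-Ci curves need 4+ points with strictly increasing Ci", {
  aci <- data.frame(
    species = "maize", irrigation = "WW", temperature = "control25",
    replicate_id = "m1", Ci = c(50, 100, 200, 400),
    AN = c(10, 20, 30, 35))
  expect_silent(validate_aci_curves(aci))
  expect_error(validate_aci_curves(aci[1:3, ]), "fewer than 4")
  aci$Ci[3] <- 100
  expect_error(validate_aci_curves(aci), "strictly increasing")
})
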