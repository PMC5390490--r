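ref_leaf <- function() {
  k <- kinetic_constants("rice")
  gs <- 0.35; gm <- 0.30; vc <- 77; rd <- 0.75
  st <- solve_c3_state(gs, gm, vc, rd, 400, k)
  list(k = k, gs = gs, gm = gm, vc = vc, rd = rd,
       state = reference_state(AG = st$AN + rd, gs_co2 = gs / 1.6,
                               gm = gm, Vcmax = vc, C = st$Cc))
}

test_that("limitation weights sum to one and match hand substitution", {
  k <- kinetic_constants("rice")
  # symmetric conductances with dAdC chosen equal to them
  km <- k$Kc * (1 + k$O / k$Ko)
  # choose C and Vcmax so dAdC = 0.25 exactly
  C <- 250
  vc <- 0.25 * (C + km)^2 / (k$gamma_star + km)
  ref <- reference_state(AG = 20, gs_co2 = 0.25, gm = 0.25, Vcmax = vc,
                         C = C)
  w <- limitation_weights(ref, k)
  expect_equal(w$g_tot, 0.125)
  expect_equal(w$dAdC, 0.25)
  expect_equal(w$l_b, 1 / 3)
  expect_equal(w$l_s, 1 / 3)
  expect_equal(w$l_mc, 1 / 3)
  expect_equal(w$l_s + w$l_mc + w$l_b, 1, tolerance = 1e-9)
})

test_that("weights sum to one over random reference states", {
  k <- kinetic_constants("wheat")
  set.seed(17)
  for (i in 1:30) {
    ref <- reference_state(AG = runif(1, 5, 30),
                           gs_co2 = runif(1, 0.05, 0.4),
                           gm = runif(1, 0.05, 0.5),
                           Vcmax = runif(1, 20, 120),
                           C = runif(1, 100, 400))
    w <- limitation_weights(ref, k)
    expect_equal(w$l_s + w$l_mc + w$l_b, 1, tolerance = 1e-9)
    expect_true(all(c(w$l_s, w$l_mc, w$l_b) >= 0 &
                      c(w$l_s, w$l_mc, w$l_b) <= 1))
  }
})

test_that("equal conductances give equal stomatal and mesophyll weights", {
  k <- kinetic_constants("rice")
  ref <- reference_state(AG = 20, gs_co2 = 0.2, gm = 0.2, Vcmax = 80,
                         C = 250)
  w <- limitation_weights(ref, k)
  expect_equal(w$l_s, w$l_mc)
})

test_that("vanishing assimilation slope makes the limitation all diffusive-free", {
  k <- kinetic_constants("rice")
  ref <- reference_state(AG = 20, gs_co2 = 0.2, gm = 0.2, Vcmax = 1e-9,
                         C = 250)
  w <- limitation_weights(ref, k)
  expect_equal(w$l_b, 1, tolerance = 1e-6)
})

test_that("identical states give a zero partition; DL = SL + MCL always", {
  rl <- ref_leaf()
  w <- limitation_weights(rl$state, rl$k)
  p <- partition_limitations(rl$state, rl$state, w)
  expect_equal(p$SL, 0)
  expect_equal(p$MCL, 0)
  expect_equal(p$BL, 0)
  set.seed(23)
  for (i in 1:20) {
    s <- rl$state
    s$gs_co2 <- s$gs_co2 * runif(1, 0.4, 1)
    s$gm <- s$gm * runif(1, 0.4, 1)
    s$Vcmax <- s$Vcmax * runif(1, 0.4, 1)
    s$AG <- s$AG * 0.9
    p <- partition_limitations(rl$state, s, w)
    expect_identical(p$DL, p$SL + p$MCL)
  }
})

test_that("a single halved factor puts the whole limitation on its term", {
  rl <- ref_leaf()
  w <- limitation_weights(rl$state, rl$k)
  s <- rl$state
  s$gs_co2 <- s$gs_co2 / 2
  p <- suppressWarnings(partition_limitations(rl$state, s, w))
  expect_equal(p$SL, w$l_s * log(2))
  expect_equal(p$MCL, 0)
  expect_equal(p$BL, 0)
  s2 <- rl$state
  s2$Vcmax <- s2$Vcmax / 2
  p2 <- suppressWarnings(partition_limitations(rl$state, s2, w))
  expect_equal(p2$DL, 0)
  expect_equal(p2$BL, w$l_b * log(2))
})

test_that("improved factors are clipped at zero with a warning", {
  rl <- ref_leaf()
  w <- limitation_weights(rl$state, rl$k)
  s <- rl$state
  s$gs_co2 <- s$gs_co2 * 1.2   # stress opened stomata
  s$Vcmax <- s$Vcmax * 0.7
  expect_warning(p <- partition_limitations(rl$state, s, w), "clipped")
  expect_equal(p$SL, 0)
  expect_gt(p$BL, 0)
})

test_that("partition predicts the forward model's decline to first order", {
  rl <- ref_leaf()
  w <- limitation_weights(rl$state, rl$k)
  # single-factor perturbations up to 10% of one driver at a time
  perts <- list(c(0.9, 1, 1), c(1, 0.9, 1), c(1, 1, 0.9),
                c(0.95, 1, 1), c(1, 0.95, 1), c(1, 1, 0.95))
  for (pp in perts) {
    st <- solve_c3_state(rl$gs * pp[1], rl$gm * pp[2], rl$vc * pp[3],
                         rl$rd, 400, rl$k)
    s <- reference_state(AG = st$AN + rl$rd, gs_co2 = rl$gs * pp[1] / 1.6,
                         gm = rl$gm * pp[2], Vcmax = rl$vc * pp[3],
                         C = st$Cc)
    p <- partition_limitations(rl$state, s, w)
    actual <- (rl$state$AG - s$AG) / rl$state$AG
    expect_equal(p$total, actual, tolerance = 0.03)
  }
})

test_that("larger combined stress declines agree within 10 percent", {
  rl <- ref_leaf()
  w <- limitation_weights(rl$state, rl$k)
  st <- solve_c3_state(rl$gs * 0.7, rl$gm * 0.8, rl$vc * 0.6,
                       rl$rd, 400, rl$k)
  s <- reference_state(AG = st$AN + rl$rd, gs_co2 = rl$gs * 0.7 / 1.6,
                       gm = rl$gm * 0.8, Vcmax = rl$vc * 0.6, C = st$Cc)
  p <- partition_limitations(rl$state, s, w)
  # the log-form total approximates the log decline of AG; on the
  # relative-decline scale that is 1 - exp(-total)
  actual <- (rl$state$AG - s$AG) / rl$state$AG
  expect_equal(1 - exp(-p$total), actual, tolerance = 0.10)
  # the raw-fraction variant tracks the relative decline directly
  p2 <- partition_limitations(rl$state, s, w, method = "fraction")
  expect_equal(p2$total, actual, tolerance = 0.10)
})

test_that("maize partition holds mesophyll constant and loads Vcmax on BL", {
  k <- kinetic_constants("maize")
  ref_st <- solve_c4_state(0.20, 34, 0.75, 1.5, 400, k)
  ref <- reference_state(AG = ref_st$AN + 0.75, gs_co2 = 0.20 / 1.6,
                         gm = k$gm_c4, Vcmax = 34, C = ref_st$Cs)
  w <- limitation_weights(ref, k)
  p0 <- partition_limitations_c4(ref, ref, w, constants = k)
  expect_equal(p0$SL + p0$MCL + p0$BL, 0)
  # only Vcmax reduced: all decline is biochemical
  st <- solve_c4_state(0.20, 34 * 0.6, 0.75, 1.5, 400, k)
  s <- reference_state(AG = st$AN + 0.75, gs_co2 = 0.20 / 1.6,
                       gm = k$gm_c4, Vcmax = 34 * 0.6, C = st$Cs)
  p <- partition_limitations_c4(ref, s, w, constants = k)
  expect_equal(p$DL, 0)
  expect_equal(p$BL, w$l_b * log(1 / 0.6))
  # simulated WD maize: amount -25%, activation +10%, gs -45%; the amount
  # loss outweighs the activation gain, so Vcmax falls and BL dominates
  vc_wd <- 34 * 0.75 * 1.10
  st_wd <- solve_c4_state(0.20 * 0.55, vc_wd, 0.75, 1.5, 400, k)
  s_wd <- reference_state(AG = st_wd$AN + 0.75,
                          gs_co2 = 0.20 * 0.55 / 1.6,
                          gm = k$gm_c4, Vcmax = vc_wd, C = st_wd$Cs)
  p_wd <- suppressWarnings(
    partition_limitations_c4(ref, s_wd, w, constants = k))
  expect_gt(p_wd$BL, 0)
  expect_equal(p_wd$MCL, 0)
  expect_gt(p_wd$BL, p_wd$SL)
})

test_that("treatment-level analysis is reproducible and well-formed", {
  exp <- generate_experiment(seed = 4)
  lf <- derive_c4(derive_c3(add_fluorescence(exp$leaf_records)))
  bio <- derive_biochem(exp$biochem)
  lim1 <- analyze_limitations(lf, bio, n_boot = 200, seed = 99)
  lim2 <- analyze_limitations(lf, bio, n_boot = 200, seed = 99)
  expect_identical(lim1, lim2)
  expect_equal(nrow(lim1), 9)  # 3 species x 3 stressed treatments
  expect_identical(lim1$DL, lim1$SL + lim1$MCL)
  expect_true(all(lim1$SL >= 0 & lim1$MCL >= 0 & lim1$BL >= 0))
  expect_true(all(is.finite(lim1$SL_se)))
  # the qualitative pattern: biochemical limitation dominates HT
  ht <- lim1[lim1$treatment == "HT", ]
  expect_true(all(ht$BL > ht$DL))
})
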