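# Synthetic-experiment generator: complete factorial datasets (leaf
# records, A-Ci curves, biochemistry) drawn around treatment means, built
# self-consistently through the forward models so the inverse pipeline has
# a recoverable ground truth.

#' Build a scenario configuration for the synthetic generator
#'
#' Describes one factorial experiment: 3 species x 4 treatments
#' (control / WD / HT / HT-WD) x `n_reps` replicates. `species` holds the
#' control-treatment means per species; `effects` holds multiplicative
#' treatment effects (scalar, or a named per-species vector); `cv` holds
#' the coefficients of variation of the multiplicative log-normal
#' replicate noise (truncated at 3 sigma). A water-deficit scenario must
#' reduce stomatal conductance to at most 60% of the well-watered mean —
#' the operational definition of the WD treatment.
#'
#' @param n_reps Replicates per species x treatment (default 5).
#' @param Ca Ambient CO2 (umol mol-1).
#' @param PPFD Light (umol m-2 s-1).
#' @param Tleaf Leaf temperature (degC).
#' @param alpha Leaf absorbance.
#' @param tsp_area Total soluble protein per leaf area (g m-2) used to put
#'   per-TSP Rubisco amounts on a leaf-area basis.
#' @param aci_sigma Gaussian measurement noise (umol m-2 s-1) added to
#'   A-Ci curve points.
#' @param aci_ca_grid Ambient CO2 grid for the maize A-Ci curves.
#' @param species Named list (rice/wheat/maize) of control means: `gs`
#'   (mol H2O m-2 s-1), `gm` (mol m-2 s-1, C3 only), `Rdark`
#'   (umol m-2 s-1), `amount` (mg Rubisco mg-1 TSP), `total_activity`
#'   (umol mg-1 min-1), `activation` (0-1), `rca_total`, `rca_large`,
#'   `rca_small` (relative, control = 1).
#' @param effects Named list per treatment (`WD`, `HT`, `HT-WD`) of
#'   multipliers for the fields above.
#' @param cv Named list of CVs for the replicate noise.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_reps = 5, Ca = 400, PPFD = 1500, Tleaf = 25,
                            alpha = 0.87, tsp_area = 6, aci_sigma = 0.3,
                            aci_ca_grid = c(50, 100, 150, 200, 250, 300,
                                            400, 600),
                            species = NULL, effects = NULL, cv = NULL) {
  cfg <- list(n_reps = n_reps, Ca = Ca, PPFD = PPFD, Tleaf = Tleaf,
              alpha = alpha, tsp_area = tsp_area, aci_sigma = aci_sigma,
              aci_ca_grid = aci_ca_grid,
              species = species %||% default_species_means(),
              effects = effects %||% default_effects(),
              cv = cv %||% default_cvs())
  validate_scenario_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Control-treatment means. Rubisco amount and initial/total activities are
# the published control values for these three cultivars; the conductances
# and respiration are typical well-watered values for chamber-grown
# cereals at saturating light (see the methods vignette).
default_species_means <- function() {
  list(
    rice = list(gs = 0.35, gm = 0.30, Rdark = 1.5, amount = 0.49,
                total_activity = 0.36, activation = 0.31 / 0.36,
                rca_total = 1, rca_large = 1, rca_small = 1),
    wheat = list(gs = 0.30, gm = 0.25, Rdark = 1.5, amount = 0.34,
                 total_activity = 0.44, activation = 0.19 / 0.44,
                 rca_total = 1, rca_large = 1, rca_small = 1),
    maize = list(gs = 0.20, gm = NA_real_, Rdark = 1.5, amount = 0.15,
                 total_activity = 0.13, activation = 0.08 / 0.13,
                 rca_total = 1, rca_large = 1, rca_small = 1)
  )
}

# Qualitative treatment effects: WD halves gs everywhere (the >= 40%
# reduction that operationally defines the treatment) and reduces gm in
# the C3 species (strongly in rice) and Rubisco amount in rice and maize,
# with a higher activation state in WD maize; HT halves the activation
# state in all species and reduces gm only in rice; HT-WD combines both.
default_effects <- function() {
  wd <- list(gs = 0.5,
             gm = c(rice = 0.6, wheat = 0.85, maize = 1),
             amount = c(rice = 0.8, wheat = 1, maize = 0.75),
             activation = c(rice = 0.95, wheat = 1, maize = 1.15),
             total_activity = 1,
             rca_total = c(rice = 1.1, wheat = 1, maize = 1.4),
             rca_large = c(rice = 1.1, wheat = 1, maize = 1),
             rca_small = c(rice = 1.1, wheat = 1, maize = 1.4))
  ht <- list(gs = 1,
             gm = c(rice = 0.8, wheat = 1, maize = 1),
             amount = c(rice = 0.8, wheat = 1, maize = 1),
             activation = 0.5,
             total_activity = 1,
             rca_total = 1,
             rca_large = c(rice = 1.15, wheat = 0.85, maize = 1),
             rca_small = 1)
  htwd <- Map(function(a, b) {
    m <- expand_mult(a) * expand_mult(b)
    if (length(unique(m)) == 1) unname(m[1]) else m
  }, wd, ht)
  list(WD = wd, HT = ht, `HT-WD` = htwd)
}

expand_mult <- function(x) {
  if (length(x) == 1 && is.null(names(x)))
    setNames(rep(x, 3), PHOTOLIM_SPECIES)
  else x[PHOTOLIM_SPECIES]
}

default_cvs <- function() {
  list(gs = 0.08, gm = 0.08, Rdark = 0.10, amount = 0.05,
       total_activity = 0.05, activation = 0.05, rca = 0.10)
}

#' The default scenario configuration
#'
#' Control means seeded from the published control values (Rubisco amount
#' 0.49/0.34/0.15 mg mg-1 TSP and initial/total activities for rice,
#' wheat, maize) and treatment multipliers reproducing the qualitative
#' stress pattern: HT halves the Rubisco activation state in all species;
#' WD halves gs everywhere and depresses gm in the C3 species and Rubisco
#' amount in rice and maize; HT-WD combines both.
#'
#' @return A [scenario_config()].
#' @export
default_paper_like_config <- function() scenario_config()

#' Validate a scenario configuration
#' @param cfg A scenario configuration list.
#' @return The config, classed `scenario_config`.
#' @export
validate_scenario_config <- function(cfg) {
  stopifnot(cfg$n_reps >= 2, cfg$Ca > 0, cfg$PPFD > 0,
            cfg$alpha > 0, cfg$alpha <= 1, cfg$tsp_area > 0,
            cfg$aci_sigma >= 0)
  if (!all(PHOTOLIM_SPECIES %in% names(cfg$species)))
    stop("species means must cover rice, wheat and maize")
  if (!all(c("WD", "HT", "HT-WD") %in% names(cfg$effects)))
    stop("effects must cover WD, HT and HT-WD")
  if (any(unlist(cfg$cv) < 0)) stop("CVs must be >= 0")
  for (tr in c("WD", "HT-WD")) {
    gsm <- expand_mult(cfg$effects[[tr]]$gs)
    if (any(gsm > 0.6))
      stop(tr, " scenario violates the water-deficit definition: ",
           "gs multiplier must be <= 0.6")
  }
  structure(cfg, class = "scenario_config")
}

# truncated log-normal multiplicative noise: median-preserving, positive
rlnorm_trunc <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  z <- pmin(pmax(rnorm(n), -3), 3)
  mean * exp(z * sdlog)
}

scenario_mean <- function(cfg, sp, tr, param) {
  base <- cfg$species[[sp]][[param]]
  if (tr == "control") return(base)
  base * unname(expand_mult(cfg$effects[[tr]][[param]] %||% 1)[sp])
}

#' Generate a complete synthetic factorial experiment
#'
#' Draws replicate-level physiological states around the scenario's
#' treatment means (log-normal noise truncated at 3 sigma) and builds the
#' observable records through the forward models so every derived quantity
#' has a known ground truth:
#' * C3 leaves: the sampled gs, gm and biochemical Vcmax are pushed
#'   through the Rubisco-limited steady state ([solve_c3_state()]); the
#'   electron transport consistent with that operating point
#'   ([j_from_operating_point()]) is converted back into a fluorescence
#'   pair (Fm' uniform in 0.5-0.8, Fs solved) so the fluorescence stage
#'   has nontrivial inputs with known truth.
#' * Maize leaves: the C4 steady state ([solve_c4_state()]) under the
#'   constant-conductance mass balance, plus an A-Ci curve per replicate
#'   obtained by re-solving the state over an ambient-CO2 grid (with
#'   optional Gaussian observation noise on AN).
#' * Biochemistry: initial activity = activation x total activity;
#'   amounts and activase signals as sampled.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return List with data.frames `leaf_records`, `aci_curves`, `biochem`,
#'   `ground_truth`.
#' @export
generate_experiment <- function(cfg = default_paper_like_config(),
                                seed = 1) {
  cfg <- validate_scenario_config(unclass(cfg))
  set.seed(seed)
  leaf <- list(); aci <- list(); bio <- list(); truth <- list()
  for (sp in PHOTOLIM_SPECIES) {
    k <- kinetic_constants(sp)
    beta <- default_beta(sp)
    maize <- is_c4(sp)
    for (tr in TREATMENT_LEVELS) {
      irr <- if (tr %in% c("WD", "HT-WD")) "WD" else "WW"
      tmp <- if (tr %in% c("HT", "HT-WD")) "HT38" else "control25"
      n <- cfg$n_reps
      gs <- rlnorm_trunc(n, scenario_mean(cfg, sp, tr, "gs"), cfg$cv$gs)
      gm <- if (!maize)
        rlnorm_trunc(n, scenario_mean(cfg, sp, tr, "gm"), cfg$cv$gm)
      else rep(k$gm_c4, n)
      rdark <- rlnorm_trunc(n, scenario_mean(cfg, sp, tr, "Rdark"),
                            cfg$cv$Rdark)
      amount <- rlnorm_trunc(n, scenario_mean(cfg, sp, tr, "amount"),
                             cfg$cv$amount)
      act <- pmin(rlnorm_trunc(n, scenario_mean(cfg, sp, tr, "activation"),
                               cfg$cv$activation), 1)
      tot <- rlnorm_trunc(n, scenario_mean(cfg, sp, tr, "total_activity"),
                          cfg$cv$total_activity)
      rca_t <- rlnorm_trunc(n, scenario_mean(cfg, sp, tr, "rca_total"),
                            cfg$cv$rca)
      rca_l <- rlnorm_trunc(n, scenario_mean(cfg, sp, tr, "rca_large"),
                            cfg$cv$rca)
      rca_s <- rlnorm_trunc(n, scenario_mean(cfg, sp, tr, "rca_small"),
                            cfg$cv$rca)
      vcmax <- vcmax_biochemical(amount * cfg$tsp_area, act, k$kcat,
                                 molar_mass = k$rubisco_molar_mass,
                                 sites = k$sites_per_holoenzyme)
      fm <- runif(n, 0.5, 0.8)
      for (i in seq_len(n)) {
        rd <- rdark[i] / 2
        if (!maize) {
          st <- solve_c3_state(gs[i], gm[i], vcmax[i], rd, cfg$Ca, k)
          cref <- st$Cc
        } else {
          st <- solve_c4_state(gs[i], vcmax[i], rd, rdark[i], cfg$Ca, k)
          cref <- st$Cs
        }
        if (st$AN <= 0)
          stop("infeasible scenario: non-positive assimilation for ",
               sp, "/", tr)
        jtrue <- j_from_operating_point(st$AN, rd, cref, k$gamma_star)
        phi <- jtrue / (cfg$PPFD * cfg$alpha * beta)
        if (phi >= 1)
          stop("infeasible scenario: PSII efficiency >= 1 for ",
               sp, "/", tr, " (J = ", round(jtrue, 1), ")")
        rep_id <- sprintf("%s_%s_r%d", sp, tr, i)
        leaf[[length(leaf) + 1]] <- data.frame(
          species = sp, irrigation = irr, temperature = tmp,
          replicate_id = rep_id, AN = st$AN, gs = gs[i], Ci = st$Ci,
          Ca = cfg$Ca, PPFD = cfg$PPFD, Tleaf = cfg$Tleaf,
          Rdark = rdark[i], Fs = fm[i] * (1 - phi), Fm_prime = fm[i],
          alpha = cfg$alpha, beta = beta, stringsAsFactors = FALSE)
        bio[[length(bio) + 1]] <- data.frame(
          species = sp, irrigation = irr, temperature = tmp,
          replicate_id = rep_id,
          initial_activity = act[i] * tot[i], total_activity = tot[i],
          rubisco_amount = amount[i], rca_total = rca_t[i],
          rca_large = rca_l[i], rca_small = rca_s[i],
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          species = sp, irrigation = irr, temperature = tmp,
          treatment = tr, replicate_id = rep_id,
          gs = gs[i], gm = gm[i], Vcmax = vcmax[i], AN = st$AN,
          Ci = st$Ci, C_chl = cref, J = jtrue,
          activation = act[i], amount = amount[i],
          stringsAsFactors = FALSE)
        if (maize) {
          pts <- lapply(cfg$aci_ca_grid, function(ca) {
            s <- solve_c4_state(gs[i], vcmax[i], rd, rdark[i], ca, k)
            c(s$Ci, s$AN)
          })
          ci <- vapply(pts, `[`, numeric(1), 1)
          an <- vapply(pts, `[`, numeric(1), 2) +
            rnorm(length(pts), 0, cfg$aci_sigma)
          o <- order(ci)
          aci[[length(aci) + 1]] <- data.frame(
            species = sp, irrigation = irr, temperature = tmp,
            replicate_id = rep_id, Ci = ci[o], AN = an[o],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(leaf_records = do.call(rbind, leaf),
       aci_curves = do.call(rbind, aci),
       biochem = do.call(rbind, bio),
       ground_truth = do.call(rbind, truth))
}

#' Write a generated experiment to a directory as CSV inputs
#'
#' Writes `leaf_records.csv`, `aci_curves.csv`, `biochem.csv` and
#' `ground_truth.csv` in the formats the readers expect.
#'
#' @param exp Output of [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_records(exp$leaf_records, file.path(dir, "leaf_records.csv"))
  write_records(exp$aci_curves, file.path(dir, "aci_curves.csv"))
  write_records(exp$biochem, file.path(dir, "biochem.csv"))
  write_records(exp$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
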