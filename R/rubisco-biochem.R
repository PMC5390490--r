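# Rubisco biochemistry: 14C assay arithmetic, activation state,
# densitometry and immunoblot quantification, and biochemical Vcmax.

#' Construct a validated 14C assay record
#'
#' Protocol defaults match the assay as run: 500 uL reaction quenched after
#' 60 s, 10 uL crude-extract aliquot, extract from 1.5 cm2 of leaf in
#' 500 uL buffer, bicarbonate specific radioactivity 15.54 kBq umol-1.
#'
#' @param acid_stable_kBq Acid-stable 14C counts (kBq).
#' @param tsp_conc Total soluble protein in the extract (mg mL-1).
#' @param reaction_time Reaction time (s).
#' @param aliquot_volume Extract aliquot added to the reaction (mL).
#' @param extract_volume Total extract volume (mL).
#' @param leaf_area Leaf area extracted (cm2).
#' @param specific_radioactivity kBq per umol bicarbonate.
#' @return List of class `assay_raw`.
#' @export
assay_raw <- function(acid_stable_kBq, tsp_conc, reaction_time = 60,
                      aliquot_volume = 0.010, extract_volume = 0.500,
                      leaf_area = 1.5, specific_radioactivity = 15.54) {
  x <- list(acid_stable_kBq = acid_stable_kBq, tsp_conc = tsp_conc,
            reaction_time = reaction_time, aliquot_volume = aliquot_volume,
            extract_volume = extract_volume, leaf_area = leaf_area,
            specific_radioactivity = specific_radioactivity)
  num <- vapply(x, function(v) is.numeric(v) && length(v) == 1, logical(1))
  if (!all(num)) stop("assay fields must be numeric scalars")
  if (x$acid_stable_kBq < 0) stop("acid_stable_kBq must be >= 0")
  pos <- c("tsp_conc", "reaction_time", "aliquot_volume", "extract_volume",
           "leaf_area", "specific_radioactivity")
  for (nm in pos) if (x[[nm]] <= 0) stop(nm, " must be > 0")
  structure(x, class = "assay_raw")
}

#' Carboxylase activity from acid-stable 14C counts
#'
#' Converts counts to a per-TSP rate: umol CO2 fixed =
#' `acid_stable_kBq / specific_radioactivity`; scaled to a per-minute rate
#' by `60 / reaction_time` and normalised by the TSP in the aliquot
#' (`aliquot_volume * tsp_conc`, mg).
#'
#' @param raw An [assay_raw()] record.
#' @return Activity in umol CO2 mg-1 TSP min-1.
#' @export
#' @examples
#' activity_from_counts(assay_raw(0.4662, tsp_conc = 10))  # 0.30
activity_from_counts <- function(raw) {
  if (!inherits(raw, "assay_raw")) stop("raw must be an assay_raw record")
  umol_fixed <- raw$acid_stable_kBq / raw$specific_radioactivity
  rate_per_min <- umol_fixed * (60 / raw$reaction_time)
  mg_tsp <- raw$aliquot_volume * raw$tsp_conc
  rate_per_min / mg_tsp
}

#' Rubisco activation state from initial and total activities
#'
#' The activation (carbamylation) state is the ratio of the activity of the
#' extract as sampled (initial) to the activity after full carbamylation of
#' the catalytic sites (total). Ratios marginally above 1 are measurement
#' noise and are clipped to 1 with a warning up to `slack`; larger excesses
#' are an error.
#'
#' @param initial Initial activity (umol mg-1 min-1), vectorised.
#' @param total Total activity, same units.
#' @param slack Tolerated excess over 1 before erroring (default 0.05).
#' @return Activation state in (0, 1].
#' @export
#' @examples
#' activation_state(0.31, 0.36)  # 0.8611
activation_state <- function(initial, total, slack = 0.05) {
  stopifnot(is.numeric(initial), is.numeric(total))
  if (any(total <= 0)) stop("total activity must be > 0")
  if (any(initial < 0)) stop("initial activity must be >= 0")
  s <- initial / total
  over <- s > 1 + slack
  if (any(over))
    stop("activation state above ", 1 + slack, " at index ",
         paste(utils::head(which(over), 5), collapse = ", "))
  clip <- s > 1
  if (any(clip)) {
    warning(sum(clip), " activation state(s) in (1, ", 1 + slack,
            "] clipped to 1")
    s[clip] <- 1
  }
  s
}

#' Rubisco amount per TSP from gel densitometry against purified standards
#'
#' Fits a straight line to the calibration points (load of purified Rubisco
#' in ug vs optical density), rejects poorly linear calibrations
#' (R2 below `min_r2`), and inverts it for the sample band. The recovered
#' ug of Rubisco is divided by the TSP loaded in the lane (15 ug by
#' protocol) to give mg Rubisco per mg TSP.
#'
#' @param band_od Sample band optical density.
#' @param calibration Data frame or 2-column matrix with columns `load`
#'   (ug Rubisco) and `od`.
#' @param tsp_loaded ug TSP loaded in the sample lane (default 15).
#' @param min_r2 Minimum calibration R2 (default 0.95).
#' @return mg Rubisco mg-1 TSP. Values outside the calibrated OD range
#'   warn; negative inversions are clipped to 0 with a warning.
#' @export
densitometry_amount <- function(band_od, calibration, tsp_loaded = 15,
                                min_r2 = 0.95) {
  calibration <- as.data.frame(calibration)
  if (!all(c("load", "od") %in% names(calibration)))
    stop("calibration needs columns 'load' and 'od'")
  if (nrow(calibration) < 2) stop("need at least 2 calibration points")
  fit <- lm(od ~ load, data = calibration)
  r2 <- if (nrow(calibration) == 2) 1 else
    suppressWarnings(summary(fit)$r.squared)  # perfect fits warn
  if (r2 < min_r2)
    stop("calibration not linear enough (R2 = ", signif(r2, 3), ")")
  sl <- coef(fit)[["load"]]
  if (sl <= 0) stop("calibration line must have positive slope")
  if (any(band_od < min(calibration$od) | band_od > max(calibration$od)))
    warning("band OD outside calibrated range; extrapolating")
  ug <- (band_od - coef(fit)[[1]]) / sl
  neg <- ug < 0
  if (any(neg)) {
    warning("negative inverted load clipped to 0")
    ug[neg] <- 0
  }
  ug / tsp_loaded  # ug Rubisco / ug TSP == mg mg-1
}

#' Rubisco activase amount relative to the control standard line
#'
#' Immunoblot signals are normalised per ug of TSP loaded and expressed
#' relative to the per-ug signal of serial dilutions (5, 10, 15 ug TSP) of
#' a control extract run on the same blot. The control line is fitted
#' through the origin (signal proportional to load); non-monotone standards
#' indicate a failed blot and are an error. Apply separately to the large
#' and small isoform signals and their sum.
#'
#' @param sample_signal Whole-band signal of the sample lane, vectorised.
#' @param standards Data frame with columns `load` (ug TSP) and `signal`
#'   for the control serial dilution.
#' @param sample_load ug TSP loaded in the sample lane (default 6).
#' @return Relative amount (control = 1).
#' @export
rca_relative <- function(sample_signal, standards, sample_load = 6) {
  standards <- as.data.frame(standards)
  if (!all(c("load", "signal") %in% names(standards)))
    stop("standards need columns 'load' and 'signal'")
  if (nrow(standards) < 2) stop("need at least 2 standard dilutions")
  o <- order(standards$load)
  if (any(diff(standards$signal[o]) <= 0))
    stop("standards not monotone increasing in load; calibration failed")
  if (any(sample_signal < 0)) stop("signals must be >= 0")
  if (sample_load <= 0) stop("sample_load must be > 0")
  per_ug_control <- coef(lm(signal ~ 0 + load, data = standards))[[1]]
  (sample_signal / sample_load) / per_ug_control
}

#' Biochemical maximum carboxylation rate
#'
#' Vcmax is the product of the catalytic-site density and the per-site
#' turnover actually available:
#' \deqn{V_{cmax} = [\mathrm{Rubisco}] \cdot \frac{sites}{M} \cdot
#'   \mathrm{activation} \cdot k_{cat}}
#' with `rubisco_area_density` in g m-2, the holoenzyme molar mass `M`
#' (550 kg mol-1) and 8 catalytic sites per holoenzyme. The result is
#' returned in umol CO2 m-2 s-1.
#'
#' @param rubisco_area_density Rubisco per leaf area (g m-2).
#' @param activation Activation state (0, 1]; values in (1, 1.05] are
#'   tolerated with a warning.
#' @param kcat Carboxylase turnover per site (s-1): 2.1 (rice), 2.2
#'   (wheat), 4.1 (maize) at 25 degC.
#' @param molar_mass Holoenzyme molar mass (g mol-1).
#' @param sites Catalytic sites per holoenzyme.
#' @return Vcmax (umol m-2 s-1).
#' @export
#' @examples
#' vcmax_biochemical(2.0, 0.861, 2.1)  # ~52.6
vcmax_biochemical <- function(rubisco_area_density, activation, kcat,
                              molar_mass = 550000, sites = 8) {
  stopifnot(is.numeric(rubisco_area_density), is.numeric(activation),
            is.numeric(kcat))
  if (any(rubisco_area_density < 0)) stop("density must be >= 0")
  if (any(activation < 0)) stop("activation must be >= 0")
  if (any(activation > 1.05)) stop("activation state above 1.05")
  if (any(activation > 1))
    warning("activation state above 1 used as-is (soft bound)")
  if (any(kcat <= 0)) stop("kcat must be > 0")
  sites_mol <- rubisco_area_density * sites / molar_mass  # mol sites m-2
  sites_mol * activation * kcat * 1e6                     # umol m-2 s-1
}

#' Per-replicate biochemistry table: activation state and Vcmax
#'
#' Computes the activation state from initial/total activities and the
#' biochemical Vcmax from the Rubisco amount. Amounts are per mg TSP; the
#' conversion to leaf-area basis multiplies by the TSP area density
#' (g TSP m-2), taken from a measured `tsp_area` column when present or
#' from the `tsp_area` argument otherwise (recorded in the result's
#' `tsp_area_source` attribute).
#'
#' @param biochem Validated biochemistry data.frame
#'   (see [read_biochem_records()]).
#' @param tsp_area TSP per leaf area (g m-2) used when the table has no
#'   `tsp_area` column.
#' @param constants_by_species Named list of constant sets per species.
#' @return The data frame with `activation_state`, `rubisco_area_density`
#'   and `Vcmax` columns appended.
#' @export
derive_biochem <- function(biochem, tsp_area = 6,
                           constants_by_species = NULL) {
  if (is.null(constants_by_species))
    constants_by_species <- lapply(
      setNames(nm = PHOTOLIM_SPECIES), kinetic_constants)
  biochem$activation_state <-
    activation_state(biochem$initial_activity, biochem$total_activity)
  src <- if (!is.null(biochem$tsp_area)) "measured-column" else "config-constant"
  tsp <- if (!is.null(biochem$tsp_area)) biochem$tsp_area else tsp_area
  biochem$rubisco_area_density <- biochem$rubisco_amount * tsp
  kcat <- vapply(biochem$species,
                 function(s) constants_by_species[[s]]$kcat, numeric(1))
  mm <- vapply(biochem$species,
               function(s) constants_by_species[[s]]$rubisco_molar_mass,
               numeric(1))
  st <- vapply(biochem$species,
               function(s) constants_by_species[[s]]$sites_per_holoenzyme,
               numeric(1))
  biochem$Vcmax <- vcmax_biochemical(biochem$rubisco_area_density,
                                     biochem$activation_state, kcat,
                                     molar_mass = mm, sites = st)
  attr(biochem, "tsp_area_source") <- src
  biochem
}
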