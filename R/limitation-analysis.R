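# Partition the decline in photosynthesis relative to the control
# treatment into stomatal, mesophyll and biochemical components
# (Grassi-Magnani decomposition).

#' Reference-state limitation weights
#'
#' At the reference (control) operating point the relative sensitivity of
#' gross assimilation to each conductance and to the carboxylation
#' capacity is
#' \deqn{l_s = \frac{g_{tot}/g_s \cdot \partial A/\partial C}
#'              {g_{tot} + \partial A/\partial C}, \quad
#'       l_{mc} = \frac{g_{tot}/g_m \cdot \partial A/\partial C}
#'              {g_{tot} + \partial A/\partial C}, \quad
#'       l_b = \frac{g_{tot}}{g_{tot} + \partial A/\partial C}}
#' with the total diffusive conductance
#' \eqn{g_{tot} = (1/g_s + 1/g_m)^{-1}} (gs on a CO2 basis, i.e. the
#' H2O-basis conductance divided by 1.6) and the Rubisco-limited slope
#' \deqn{\partial A/\partial C =
#'   V_{cmax} (\Gamma^* + K_m) / (C + K_m)^2, \qquad
#'   K_m = K_c (1 + O/K_o)} evaluated at the reference chloroplast
#' (C3: Cc) or bundle-sheath (maize: Cs) CO2. The three weights sum to 1
#' by construction.
#'
#' @param ref List with reference-state fields `gs_co2`, `gm`, `Vcmax` and
#'   `C` (the reference Cc or Cs, umol mol-1); see [reference_state()].
#' @param constants Constant set from [kinetic_constants()].
#' @return List with `l_s`, `l_mc`, `l_b`, `g_tot`, `dAdC`.
#' @export
limitation_weights <- function(ref, constants) {
  for (nm in c("gs_co2", "gm", "Vcmax", "C"))
    if (is.null(ref[[nm]]) || !is.finite(ref[[nm]]) || ref[[nm]] <= 0)
      stop("reference state needs positive ", nm)
  km <- constants$Kc * (1 + constants$O / constants$Ko)
  dAdC <- ref$Vcmax * (constants$gamma_star + km) / (ref$C + km)^2
  g_tot <- 1 / (1 / ref$gs_co2 + 1 / ref$gm)
  den <- g_tot + dAdC
  list(l_s = (g_tot / ref$gs_co2) * dAdC / den,
       l_mc = (g_tot / ref$gm) * dAdC / den,
       l_b = g_tot / den,
       g_tot = g_tot, dAdC = dAdC)
}

#' Bundle a reference or stressed operating state
#'
#' @param AG Gross assimilation (umol m-2 s-1).
#' @param gs_co2 Stomatal conductance on a CO2 basis (mol m-2 s-1); divide
#'   an H2O-basis conductance by 1.6.
#' @param gm Mesophyll conductance (mol m-2 s-1); for maize use the
#'   constant `gm_c4`.
#' @param Vcmax Maximum carboxylation rate (umol m-2 s-1).
#' @param C Operating chloroplast CO2 (C3: Cc; maize: Cs; umol mol-1).
#'   Only the reference state needs it.
#' @return List of class `reference_state`.
#' @export
reference_state <- function(AG, gs_co2, gm, Vcmax, C = NA_real_) {
  x <- list(AG = AG, gs_co2 = gs_co2, gm = gm, Vcmax = Vcmax, C = C)
  bad <- names(x)[vapply(
    x[c("AG", "gs_co2", "gm", "Vcmax")],
    function(v) !is.numeric(v) || !is.finite(v) || v <= 0, logical(1))]
  if (length(bad)) stop("state fields must be positive: ",
                        paste(bad, collapse = ", "))
  structure(x, class = "reference_state")
}

#' Partition the photosynthetic decline of a stressed state
#'
#' Decomposes the decline of gross assimilation in a stressed treatment
#' relative to the reference into stomatal (`SL`), mesophyll (`MCL`) and
#' biochemical (`BL`) components using the reference weights:
#' \deqn{S_L = l_s \Delta\ln g_s, \quad MC_L = l_{mc} \Delta\ln g_m,
#'   \quad B_L = l_b \Delta\ln V_{cmax}}
#' with \eqn{\Delta\ln x = \ln x_{ref} - \ln x_{stress}} (the
#' log-difference form; `method = "fraction"` uses the raw fractional
#' differences \eqn{(x_{ref} - x_{stress})/x_{ref}} instead). Components
#' that come out negative (a factor improved under stress) are clipped to
#' 0 with a warning. The total diffusive limitation is `DL = SL + MCL`
#' exactly, `total = SL + MCL + BL` approximates the relative decline of
#' AG, and `SL_frac`/`MCL_frac`/`BL_frac` express each component as a
#' fraction of the total.
#'
#' @param ref Reference (control) state from [reference_state()].
#' @param stressed Stressed-treatment state from [reference_state()].
#' @param weights Weights from [limitation_weights()] at `ref`.
#' @param method `"log"` (default) or `"fraction"`.
#' @param clip_negative Clip negative components at 0 (default TRUE).
#' @return List with `SL`, `MCL`, `BL`, `DL`, `total` and the `_frac`
#'   shares.
#' @export
partition_limitations <- function(ref, stressed, weights,
                                  method = c("log", "fraction"),
                                  clip_negative = TRUE) {
  method <- match.arg(method)
  if (stressed$AG > ref$AG)
    warning("stressed AG exceeds reference AG; limitations may be <= 0")
  delta <- function(r, s) {
    if (method == "log") log(r) - log(s) else (r - s) / r
  }
  comps <- c(SL = weights$l_s * delta(ref$gs_co2, stressed$gs_co2),
             MCL = weights$l_mc * delta(ref$gm, stressed$gm),
             BL = weights$l_b * delta(ref$Vcmax, stressed$Vcmax))
  if (clip_negative && any(comps < 0)) {
    warning("negative limitation component(s) clipped to 0: ",
            paste(names(comps)[comps < 0], collapse = ", "))
    comps[comps < 0] <- 0
  }
  total <- sum(comps)
  frac <- if (total > 0) comps / total else comps * NA_real_
  list(SL = unname(comps["SL"]), MCL = unname(comps["MCL"]),
       BL = unname(comps["BL"]),
       DL = unname(comps["SL"] + comps["MCL"]),
       total = total,
       SL_frac = unname(frac["SL"]), MCL_frac = unname(frac["MCL"]),
       BL_frac = unname(frac["BL"]))
}

#' C4 (maize) variant of the limitation partition
#'
#' Identical decomposition with the Rubisco-limited slope evaluated at the
#' reference bundle-sheath CO2 (`Cs`) and the mesophyll term using the
#' constant `gm_c4`; since that conductance does not vary between
#' treatments, its log-difference — and hence `MCL` — is zero, and the
#' diffusive limitation is carried by the stomatal term. The biochemical
#' analysis is restricted to the C3-cycle (Rubisco) activity.
#'
#' @inheritParams partition_limitations
#' @param constants Maize constant set (supplies `gm_c4` when states omit
#'   `gm`).
#' @return As [partition_limitations()].
#' @export
partition_limitations_c4 <- function(ref, stressed, weights,
                                     constants = NULL,
                                     method = "log",
                                     clip_negative = TRUE) {
  if (is.null(constants)) constants <- kinetic_constants("maize")
  if (is.null(ref$gm) || is.na(ref$gm)) ref$gm <- constants$gm_c4
  if (is.null(stressed$gm) || is.na(stressed$gm))
    stressed$gm <- constants$gm_c4
  partition_limitations(ref, stressed, weights, method = method,
                        clip_negative = clip_negative)
}

# -- treatment-level analysis --------------------------------------------

state_from_rows <- function(rows, is_maize, constants, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(rows))
  r <- rows[idx, , drop = FALSE]
  gm <- if (is_maize) constants$gm_c4 else mean(r$gm)
  cref <- if (is_maize) mean(r$Cs) else mean(r$Cc)
  list(AG = mean(r$AG), gs_co2 = mean(r$gs) / 1.6, gm = gm,
       Vcmax = mean(r$Vcmax), C = cref)
}

#' Treatment-level limitation analysis with bootstrap uncertainty
#'
#' For each species, averages the per-replicate derived quantities by
#' treatment (control as reference) and partitions each stressed
#' treatment's decline into SL, MCL and BL. Per-replicate Vcmax values
#' come from the biochemistry table; replicates are matched by treatment
#' (not paired), so treatment means feed the decomposition. Uncertainty is
#' propagated by a nonparametric bootstrap over replicates within each
#' treatment and the control.
#'
#' Records flagged infeasible by the diffusion stages are excluded from
#' the means.
#'
#' @param derived Leaf table after [add_fluorescence()], [derive_c3()] and
#'   [derive_c4()].
#' @param biochem Biochemistry table after [derive_biochem()].
#' @param constants_by_species Named list of constant sets per species.
#' @param method Decomposition form, `"log"` (default) or `"fraction"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @return Data frame: one row per species x stressed treatment with the
#'   limitation components, their shares and bootstrap SEs.
#' @export
analyze_limitations <- function(derived, biochem,
                                constants_by_species = NULL,
                                method = "log", n_boot = 2000, seed = 1) {
  if (is.null(constants_by_species))
    constants_by_species <- lapply(
      setNames(nm = PHOTOLIM_SPECIES), kinetic_constants)
  if (is.null(derived$treatment))
    derived$treatment <- treatment_label(derived$irrigation,
                                         derived$temperature)
  if (is.null(biochem$treatment))
    biochem$treatment <- treatment_label(biochem$irrigation,
                                         biochem$temperature)
  ok <- derived$feasibility_flag == "ok"
  out <- list()
  set.seed(seed)
  for (sp in intersect(PHOTOLIM_SPECIES, unique(derived$species))) {
    k <- constants_by_species[[sp]]
    maize <- is_c4(sp)
    gx <- derived[derived$species == sp & ok, , drop = FALSE]
    bx <- biochem[biochem$species == sp, , drop = FALSE]
    # merge per-replicate Vcmax into the gas-exchange rows by treatment mean
    # (leaves and biochem disks are different samples of the same plants)
    vc_by_tr <- tapply(bx$Vcmax, bx$treatment, mean)
    gx$Vcmax <- as.numeric(vc_by_tr[gx$treatment])
    ref_rows <- gx[gx$treatment == "control", , drop = FALSE]
    if (!nrow(ref_rows)) stop("no control records for ", sp)
    ref <- state_from_rows(ref_rows, maize, k)
    w <- limitation_weights(ref, k)
    for (tr in setdiff(TREATMENT_LEVELS, "control")) {
      str_rows <- gx[gx$treatment == tr, , drop = FALSE]
      if (!nrow(str_rows)) next
      str <- state_from_rows(str_rows, maize, k)
      part <- suppressWarnings(
        partition_limitations(ref, str, w, method = method))
      # bootstrap over replicates in both the control and stressed cells,
      # re-deriving Vcmax means from the resampled biochemistry
      bref <- bx[bx$treatment == "control", , drop = FALSE]
      bstr <- bx[bx$treatment == tr, , drop = FALSE]
      bs <- replicate(n_boot, {
        i_r <- sample.int(nrow(ref_rows), replace = TRUE)
        i_s <- sample.int(nrow(str_rows), replace = TRUE)
        j_r <- sample.int(nrow(bref), replace = TRUE)
        j_s <- sample.int(nrow(bstr), replace = TRUE)
        r2 <- state_from_rows(ref_rows, maize, k, i_r)
        s2 <- state_from_rows(str_rows, maize, k, i_s)
        r2$Vcmax <- mean(bref$Vcmax[j_r])
        s2$Vcmax <- mean(bstr$Vcmax[j_s])
        w2 <- limitation_weights(r2, k)
        p <- suppressWarnings(
          partition_limitations(r2, s2, w2, method = method))
        c(p$SL, p$MCL, p$BL, p$DL)
      })
      se <- apply(bs, 1, sd)
      out[[length(out) + 1]] <- data.frame(
        species = sp, treatment = tr, reference = "control",
        SL = part$SL, MCL = part$MCL, BL = part$BL, DL = part$DL,
        total = part$total,
        SL_frac = part$SL_frac, MCL_frac = part$MCL_frac,
        BL_frac = part$BL_frac,
        SL_se = se[1], MCL_se = se[2], BL_se = se[3], DL_se = se[4],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
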