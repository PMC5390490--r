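# Maize (C4) stages: hyperbolic A-Ci description and inversion of a
# von Caemmerer-type model for bundle-sheath CO2, with gm and gbs held
# constant.

#' Fit a rectangular hyperbola to an A-Ci response curve
#'
#' Least-squares fit of \eqn{A_N = A_{max} C_i / (K + C_i)} to a curve's
#' points. A near-flat curve (all AN equal at large Ci) drives K to its
#' lower boundary; the fit is then flagged rather than trusted.
#'
#' @param Ci Substomatal CO2 values (umol mol-1), strictly increasing,
#'   length >= 4.
#' @param AN Net assimilation at each Ci (umol m-2 s-1).
#' @return List with `Amax`, `K`, `rmse`, `boundary` (logical flag for a
#'   degenerate plateau fit) and `fitted` values.
#' @export
#' @examples
#' ci <- c(50, 100, 200, 400)
#' fit_aci_hyperbola(ci, 50 * ci / (100 + ci))
fit_aci_hyperbola <- function(Ci, AN) {
  stopifnot(is.numeric(Ci), is.numeric(AN), length(Ci) == length(AN))
  if (length(Ci) < 4)
    stop("A-Ci hyperbola needs at least 4 points")
  if (any(diff(Ci) <= 0))
    stop("Ci must be strictly increasing")
  # Amax has a closed form given K, so profile the 1-D RSS over K; this
  # cannot fail to converge, and a Levenberg-Marquardt polish refines the
  # well-conditioned cases
  amax_given_k <- function(K) {
    f <- Ci / (K + Ci)
    sum(f * AN) / sum(f * f)
  }
  rss_k <- function(K) {
    f <- Ci / (K + Ci)
    am <- sum(f * AN) / sum(f * f)
    sum((AN - am * f)^2)
  }
  k_lo <- 1e-6
  opt <- stats::optimize(rss_k, c(k_lo, 20 * max(Ci)), tol = 1e-10)
  k_hat <- opt$minimum
  amax_hat <- amax_given_k(k_hat)
  fit <- try(suppressWarnings(
    minpack.lm::nlsLM(AN ~ Amax * Ci / (K + Ci),
                      start = list(Amax = amax_hat, K = k_hat),
                      lower = c(Amax = 1e-6, K = k_lo),
                      control = minpack.lm::nls.lm.control(maxiter = 200))),
    silent = TRUE)
  if (!inherits(fit, "try-error")) {
    p <- coef(fit)
    if (sum((AN - p[["Amax"]] * Ci / (p[["K"]] + Ci))^2) <= opt$objective) {
      amax_hat <- p[["Amax"]]
      k_hat <- p[["K"]]
    }
  }
  if (amax_hat <= 0)
    stop("A-Ci hyperbola fit degenerate: non-positive Amax")
  fitted <- amax_hat * Ci / (k_hat + Ci)
  boundary <- k_hat <= max(1e-3, 2 * k_lo)
  if (boundary)
    warning("hyperbola K at lower boundary: curve is a flat plateau")
  list(Amax = amax_hat, K = k_hat,
       rmse = sqrt(mean((AN - fitted)^2)),
       boundary = boundary, fitted = fitted)
}

#' Bundle-sheath CO2 from the C4 mass balance
#'
#' With mesophyll conductance `gm_c4` and bundle-sheath conductance `gbs`
#' held constant, the mesophyll CO2, PEP carboxylation flux, and
#' bundle-sheath CO2 follow from the record's gas exchange:
#' \deqn{C_m = C_i - A_N / g_{m}}
#' \deqn{V_p = V_{pmax} C_m / (C_m + K_p)} (or the fitted hyperbola's
#'   initial-slope supply, see `vp_source`)
#' \deqn{C_s = C_m + (V_p - A_N - R_m) / g_{bs}}
#' with mesophyll respiration \eqn{R_m = f_m R_{dark}}. The bundle-sheath
#' leak rate is \eqn{g_{bs} (C_s - C_m) = V_p - A_N - R_m}.
#'
#' @param AN Net assimilation (umol m-2 s-1), vectorised.
#' @param Ci Substomatal CO2 (umol mol-1).
#' @param Rdark Dark respiration (umol m-2 s-1).
#' @param constants Constant set from [kinetic_constants()] (uses `gm_c4`,
#'   `gbs`, `Vpmax`, `Kp`, `Rm_fraction`).
#' @param vp_source `"michaelis"` (default) computes Vp from the PEPC
#'   Michaelis form; `"hyperbola"` takes Vp as the fitted A-Ci curve's
#'   initial-slope supply `(Amax/K) * Cm`, requiring `hyperbola`.
#' @param hyperbola Fit from [fit_aci_hyperbola()] when
#'   `vp_source = "hyperbola"`.
#' @param on_infeasible `"error"` or `"na"` for records with `Cm <= 0` or
#'   `Cs <= 0`.
#' @return List of vectors `Cm`, `Vp`, `Cs`, `leak` (umol mol-1 /
#'   umol m-2 s-1).
#' @export
#' @examples
#' k <- kinetic_constants("maize")
#' estimate_cs(AN = 40, Ci = 140, Rdark = 2, constants = k)
estimate_cs <- function(AN, Ci, Rdark, constants,
                        vp_source = c("michaelis", "hyperbola"),
                        hyperbola = NULL,
                        on_infeasible = c("error", "na")) {
  vp_source <- match.arg(vp_source)
  on_infeasible <- match.arg(on_infeasible)
  stopifnot(is.numeric(AN), is.numeric(Ci), is.numeric(Rdark))
  cm <- Ci - AN / constants$gm_c4
  bad <- cm <= 0
  vp <- if (vp_source == "michaelis") {
    constants$Vpmax * cm / (cm + constants$Kp)
  } else {
    if (is.null(hyperbola))
      stop("vp_source = 'hyperbola' requires a fitted hyperbola")
    (hyperbola$Amax / hyperbola$K) * cm
  }
  rm_ <- constants$Rm_fraction * Rdark
  cs <- cm + (vp - AN - rm_) / constants$gbs
  bad <- bad | cs <= 0
  if (any(bad)) {
    if (on_infeasible == "error")
      stop("infeasible C4 record(s) (Cm <= 0 or Cs <= 0) at index ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    cm[bad] <- NA_real_
    vp[bad] <- NA_real_
    cs[bad] <- NA_real_
  }
  list(Cm = cm, Vp = vp, Cs = cs, leak = constants$gbs * (cs - cm))
}

#' Rubisco-limited C3-cycle rate at the bundle-sheath CO2 (C4 forward)
#'
#' The maize biochemical analysis is restricted to the C3 cycle: net
#' assimilation is the Rubisco-limited rate evaluated at the bundle-sheath
#' CO2 concentration,
#' \deqn{A_N = V_{cmax} (C_s - \Gamma^*)/(C_s + K_c(1 + O/K_o)) - R_d.}
#'
#' @param Cs Bundle-sheath CO2 (umol mol-1, > 0), vectorised.
#' @param Vcmax Maximum carboxylation rate (umol m-2 s-1).
#' @param Rd Respiration (umol m-2 s-1).
#' @param constants Constant set from [kinetic_constants()].
#' @return Net assimilation (umol m-2 s-1).
#' @export
c4_forward <- function(Cs, Vcmax, Rd, constants) {
  if (any(Cs <= 0)) stop("Cs must be > 0")
  km <- constants$Kc * (1 + constants$O / constants$Ko)
  Vcmax * (Cs - constants$gamma_star) / (Cs + km) - Rd
}

#' Solve the C4 steady state for a maize leaf with known gs and Vcmax
#'
#' Finds AN such that the Rubisco-limited demand at the bundle-sheath CO2
#' equals the net flux, with `Ci = Ca - 1.6 AN / gs` (gs in H2O units) and
#' the mass balance of [estimate_cs()] closing the loop.
#'
#' @param gs Stomatal conductance to H2O (mol m-2 s-1).
#' @param Vcmax Maximum carboxylation rate (umol m-2 s-1).
#' @param Rd Bundle-sheath-side respiration entering the demand function
#'   (umol m-2 s-1).
#' @param Rdark Dark respiration feeding the mesophyll respiration term.
#' @param Ca Ambient CO2 (umol mol-1).
#' @param constants Constant set from [kinetic_constants()].
#' @return List with `AN`, `Ci`, `Cm`, `Vp`, `Cs`.
#' @export
solve_c4_state <- function(gs, Vcmax, Rd, Rdark, Ca, constants) {
  f <- function(an) {
    ci <- Ca - 1.6 * an / gs
    st <- estimate_cs(an, ci, Rdark, constants, on_infeasible = "na")
    if (is.na(st$Cs)) return(NA_real_)
    c4_forward(st$Cs, Vcmax, Rd, constants) - an
  }
  # assimilation cannot exceed Vcmax - Rd nor exhaust the supply (Ci > 0);
  # the balance turns infeasible (Cs <= 0) just beyond the root, so the
  # upper bracket is found by bisecting toward the feasibility edge
  lower <- -Rd + 1e-9
  upper <- min(Vcmax - Rd, 0.999 * Ca * gs / 1.6)
  if (!is.finite(f(lower)) || f(lower) < 0)
    stop("infeasible C4 leaf: no positive supply at compensation")
  fu <- f(upper)
  for (it in 1:60) {
    if (!is.na(fu) && fu < 0) break
    if (is.na(fu)) {
      upper <- (lower + upper) / 2        # stepped past the Cs > 0 edge
    } else {
      lower <- upper                      # still feasible and demand-rich
      upper <- upper + (min(Vcmax - Rd, Ca * gs / 1.6) - upper) / 2
    }
    fu <- f(upper)
  }
  if (is.na(fu) || fu >= 0)
    stop("could not bracket the C4 steady state")
  sol <- uniroot(f, lower = lower, upper = upper, tol = 1e-12)
  an <- sol$root
  ci <- Ca - 1.6 * an / gs
  st <- estimate_cs(an, ci, Rdark, constants)
  list(AN = an, Ci = ci, Cm = st$Cm, Vp = st$Vp, Cs = st$Cs)
}

#' Derive bundle-sheath CO2 for the maize rows of a leaf-record table
#'
#' Applies [estimate_cs()] per maize record; infeasible records are
#' flagged. C3 rows pass through unchanged.
#'
#' @param leaf Leaf-record data.frame (after [derive_c3()], so `AG` and
#'   `feasibility_flag` exist).
#' @param constants Maize constant set; defaults to
#'   `kinetic_constants("maize")`.
#' @param vp_source Passed to [estimate_cs()].
#' @param hyperbola_by_rep Optional named list of hyperbola fits keyed by
#'   `replicate_id` for `vp_source = "hyperbola"`.
#' @return The data frame with `Cm`, `Vp`, `Cs`, `leak` columns appended.
#' @export
derive_c4 <- function(leaf, constants = NULL,
                      vp_source = "michaelis", hyperbola_by_rep = NULL) {
  if (is.null(constants)) constants <- kinetic_constants("maize")
  leaf$Cm <- NA_real_
  leaf$Vp <- NA_real_
  leaf$Cs <- NA_real_
  leaf$leak <- NA_real_
  c4 <- which(is_c4(leaf$species))
  if (!length(c4)) return(leaf)
  for (i in c4) {
    hyp <- if (!is.null(hyperbola_by_rep))
      hyperbola_by_rep[[leaf$replicate_id[i]]] else NULL
    st <- estimate_cs(leaf$AN[i], leaf$Ci[i], leaf$Rdark[i], constants,
                      vp_source = vp_source, hyperbola = hyp,
                      on_infeasible = "na")
    leaf$Cm[i] <- st$Cm
    leaf$Vp[i] <- st$Vp
    leaf$Cs[i] <- st$Cs
    leaf$leak[i] <- st$leak
  }
  bad <- c4[is.na(leaf$Cs[c4])]
  if (length(bad)) {
    leaf$feasibility_flag[bad] <- "infeasible"
    warning(length(bad), " C4 record(s) infeasible; flagged")
  }
  leaf
}
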