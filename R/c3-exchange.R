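# C3 stages: gross assimilation, variable-J chloroplast CO2 and mesophyll
# conductance, and the FvCB forward model used as recovery-test oracle.

#' Gross CO2 assimilation from net assimilation and dark respiration
#'
#' \eqn{A_G = A_N + R_{dark}/2}: half the pre-dawn dark respiration is taken
#' to continue in the light. Negative net assimilation is a sign of a
#' non-steady-state or fault record; such rows return `AG = 0` with a
#' warning rather than a negative gross rate.
#'
#' @param AN Net CO2 assimilation (umol m-2 s-1), vectorised.
#' @param Rdark Dark respiration (umol m-2 s-1, >= 0).
#' @return Gross assimilation AG (umol m-2 s-1).
#' @export
#' @examples
#' gross_assimilation(20, 2)  # 21
gross_assimilation <- function(AN, Rdark) {
  stopifnot(is.numeric(AN), is.numeric(Rdark))
  if (any(Rdark < 0)) stop("Rdark must be >= 0")
  ag <- AN + Rdark / 2
  neg <- AN < 0
  if (any(neg)) {
    warning(sum(neg), " record(s) with negative AN: AG set to 0")
    ag[neg] <- 0
  }
  ag
}

#' Chloroplast CO2 concentration by the variable-J method
#'
#' Inverts the RuBP-regeneration-limited assimilation equation using the
#' fluorescence-derived electron transport rate J:
#' \deqn{C_c = \Gamma^* \frac{J + 8(A_N + R_d)}{J - 4(A_N + R_d)}}
#' A point is feasible only when `J > 4 (AN + Rd)`; infeasible points are
#' either an error (`on_infeasible = "error"`, default) or returned as `NA`
#' so the caller can flag and exclude them (`"na"`).
#'
#' @param AN Net assimilation (umol m-2 s-1), vectorised.
#' @param J Electron transport rate (umol e- m-2 s-1).
#' @param Rd Daytime mitochondrial respiration (umol m-2 s-1); the pipeline
#'   convention is `Rdark / 2`.
#' @param gamma_star CO2 compensation point without Rd (umol mol-1).
#' @param on_infeasible `"error"` or `"na"`.
#' @return Cc (umol mol-1).
#' @export
#' @examples
#' cc_variable_j(25, 200, 1, 42.75)  # 181.6875
cc_variable_j <- function(AN, J, Rd, gamma_star,
                          on_infeasible = c("error", "na")) {
  on_infeasible <- match.arg(on_infeasible)
  stopifnot(is.numeric(AN), is.numeric(J), is.numeric(Rd),
            is.numeric(gamma_star))
  if (any(gamma_star <= 0)) stop("gamma_star must be > 0")
  a <- AN + Rd
  den <- J - 4 * a
  bad <- den <= 0
  if (any(bad)) {
    if (on_infeasible == "error")
      stop("infeasible variable-J point(s): J <= 4 (AN + Rd) at index ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    den[bad] <- NA_real_
  }
  gamma_star * (J + 8 * a) / den
}

#' Mesophyll conductance from the CO2 drawdown Ci - Cc
#'
#' Rearranges \eqn{C_c = C_i - A_N / g_m} to
#' \eqn{g_m = A_N / (C_i - C_c)}. Requires `Ci > Cc` and `AN > 0`.
#'
#' @param AN Net assimilation (umol m-2 s-1), vectorised.
#' @param Ci Substomatal CO2 (umol mol-1).
#' @param Cc Chloroplast CO2 (umol mol-1).
#' @param on_infeasible `"error"` or `"na"` for points with `Ci <= Cc`.
#' @return gm (mol CO2 m-2 s-1).
#' @export
gm_from_cc <- function(AN, Ci, Cc, on_infeasible = c("error", "na")) {
  on_infeasible <- match.arg(on_infeasible)
  stopifnot(is.numeric(AN), is.numeric(Ci), is.numeric(Cc))
  dd <- Ci - Cc
  bad <- !is.na(dd) & (dd <= 0 | AN <= 0)
  if (any(bad)) {
    if (on_infeasible == "error")
      stop("infeasible drawdown (Ci <= Cc or AN <= 0) at index ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    dd[bad] <- NA_real_
  }
  AN / dd
}

#' FvCB forward model of C3 net assimilation at the chloroplast
#'
#' Minimum of the Rubisco-limited and RuBP-regeneration-limited rates:
#' \deqn{A_c = V_{cmax} (C_c - \Gamma^*) / (C_c + K_c (1 + O/K_o))}
#' \deqn{A_j = J (C_c - \Gamma^*) / (4 C_c + 8 \Gamma^*)}
#' \deqn{A_N = \min(A_c, A_j) - R_d}
#' Used as the self-consistent generator/oracle for recovery tests of the
#' variable-J inversion.
#'
#' @param Cc Chloroplast CO2 (umol mol-1, > 0), vectorised.
#' @param Vcmax Maximum carboxylation rate (umol m-2 s-1).
#' @param J Electron transport rate (umol e- m-2 s-1).
#' @param Rd Daytime respiration (umol m-2 s-1).
#' @param constants Constant set from [kinetic_constants()].
#' @return Net assimilation AN (umol m-2 s-1).
#' @export
fvcb_forward <- function(Cc, Vcmax, J, Rd, constants) {
  stopifnot(is.numeric(Cc), is.numeric(Vcmax), is.numeric(J),
            is.numeric(Rd))
  if (any(Cc <= 0)) stop("Cc must be > 0")
  km <- constants$Kc * (1 + constants$O / constants$Ko)
  ac <- Vcmax * (Cc - constants$gamma_star) / (Cc + km)
  aj <- J * (Cc - constants$gamma_star) / (4 * Cc + 8 * constants$gamma_star)
  pmin(ac, aj) - Rd
}

#' Electron transport consistent with an operating point
#'
#' Solves the RuBP-regeneration-limited equation for the J that reproduces
#' a given gross flux at a given Cc:
#' \deqn{J = 4 (A_N + R_d) (C_c + 2\Gamma^*) / (C_c - \Gamma^*)}
#' This is the fluorescence-side ground truth the synthetic generator
#' assigns so the variable-J inversion can recover the generating state
#' exactly.
#'
#' @inheritParams cc_variable_j
#' @param Cc Chloroplast CO2 (umol mol-1, > gamma_star).
#' @return J (umol e- m-2 s-1).
#' @export
j_from_operating_point <- function(AN, Rd, Cc, gamma_star) {
  if (any(Cc <= gamma_star))
    stop("Cc must exceed gamma_star for a positive gross flux")
  4 * (AN + Rd) * (Cc + 2 * gamma_star) / (Cc - gamma_star)
}

#' Solve the C3 steady state for a leaf with known conductances
#'
#' Finds the Rubisco-limited operating point where supply through stomata
#' and mesophyll equals biochemical demand:
#' `AN = Vcmax (Cc - gamma_star)/(Cc + Km) - Rd` with
#' `Cc = Ca - AN (1.6/gs + 1/gm)` (gs given in H2O units; the factor 1.6 is
#' the H2O:CO2 diffusivity ratio).
#'
#' @param gs Stomatal conductance to H2O (mol m-2 s-1).
#' @param gm Mesophyll conductance to CO2 (mol m-2 s-1).
#' @param Vcmax Maximum carboxylation rate (umol m-2 s-1).
#' @param Rd Daytime respiration (umol m-2 s-1).
#' @param Ca Ambient CO2 (umol mol-1).
#' @param constants Constant set from [kinetic_constants()].
#' @return List with `AN`, `Ci`, `Cc`.
#' @export
solve_c3_state <- function(gs, gm, Vcmax, Rd, Ca, constants) {
  km <- constants$Kc * (1 + constants$O / constants$Ko)
  gstar <- constants$gamma_star
  rtot <- 1.6 / gs + 1 / gm  # total resistance, CO2 basis
  f <- function(an) {
    cc <- Ca - an * rtot
    Vcmax * (cc - gstar) / (cc + km) - Rd - an
  }
  upper <- min(Vcmax, (Ca - gstar) / rtot) - 1e-9
  sol <- uniroot(f, lower = -Rd, upper = upper, tol = 1e-12)
  an <- sol$root
  cc <- Ca - an * rtot
  list(AN = an, Ci = Ca - an * 1.6 / gs, Cc = cc)
}

#' Derive AG, Cc and gm for the C3 rows of a leaf-record table
#'
#' Runs the variable-J chain per record: gross assimilation
#' (`AG = AN + Rdark/2`), daytime respiration `Rd = rd_fraction * Rdark`,
#' chloroplast CO2 by [cc_variable_j()] and mesophyll conductance by
#' [gm_from_cc()]. Records failing the `J > 4 (AN + Rd)` feasibility test
#' (or with `Ci <= Cc`) keep `NA` estimates and are flagged in
#' `feasibility_flag` so treatment means exclude rather than clip them.
#' Maize rows pass through with `NA` (the C4 chain handles them).
#'
#' @param leaf Leaf-record data.frame with `phi_psii`/`J` columns (see
#'   [add_fluorescence()]).
#' @param constants_by_species Named list of constant sets; defaults to
#'   [kinetic_constants()] per species.
#' @param rd_fraction Fraction of Rdark active in the light (default 0.5,
#'   mirroring the AG convention).
#' @return The data frame with `AG`, `Rd`, `Cc`, `gm`, `feasibility_flag`
#'   columns appended.
#' @export
derive_c3 <- function(leaf, constants_by_species = NULL, rd_fraction = 0.5) {
  if (is.null(leaf$J))
    stop("leaf table lacks J; call add_fluorescence() first")
  if (is.null(constants_by_species))
    constants_by_species <- lapply(
      setNames(nm = PHOTOLIM_SPECIES), kinetic_constants)
  leaf$AG <- gross_assimilation(leaf$AN, leaf$Rdark)
  leaf$Rd <- rd_fraction * leaf$Rdark
  leaf$Cc <- NA_real_
  leaf$gm <- NA_real_
  leaf$feasibility_flag <- "ok"
  c3 <- which(!is_c4(leaf$species))
  if (!length(c3)) return(leaf)
  gstar <- vapply(leaf$species[c3],
                  function(s) constants_by_species[[s]]$gamma_star,
                  numeric(1))
  cc <- cc_variable_j(leaf$AN[c3], leaf$J[c3], leaf$Rd[c3], gstar,
                      on_infeasible = "na")
  gm <- gm_from_cc(leaf$AN[c3], leaf$Ci[c3], cc, on_infeasible = "na")
  leaf$Cc[c3] <- cc
  leaf$gm[c3] <- gm
  bad <- c3[is.na(cc) | is.na(gm)]
  if (length(bad)) {
    leaf$feasibility_flag[bad] <- "infeasible"
    warning(length(bad),
            " C3 record(s) failed the variable-J feasibility test; ",
            "flagged and excluded downstream")
  }
  leaf
}
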