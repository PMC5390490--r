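# PSII operating efficiency and linear electron transport.

#' PSII operating efficiency from steady-state fluorescence
#'
#' Computes the operating quantum efficiency of photosystem II from the
#' steady-state fluorescence yield `Fs` and the maximum yield `Fm_prime`
#' under a light-saturating pulse:
#' \deqn{\Phi_{PSII} = (F_m' - F_s) / F_m'}
#'
#' @param Fs Steady-state fluorescence yield (>= 0), vectorised.
#' @param Fm_prime Light-saturated maximum fluorescence yield (> 0).
#' @return Operating efficiency in \[0, 1\].
#' @export
#' @examples
#' phi_psii(0.3, 0.6)  # 0.5
phi_psii <- function(Fs, Fm_prime) {
  stopifnot(is.numeric(Fs), is.numeric(Fm_prime))
  if (any(Fm_prime <= 0)) stop("Fm_prime must be > 0")
  if (any(Fs < 0)) stop("Fs must be >= 0")
  if (any(Fs > Fm_prime)) stop("Fs exceeds Fm_prime")
  (Fm_prime - Fs) / Fm_prime
}

#' Linear electron transport rate from PSII efficiency and light
#'
#' \deqn{J = \Phi_{PSII} \cdot PPFD \cdot \alpha \cdot \beta}
#' where `alpha` is the leaf absorbance (measured 0.86-0.87 for these
#' species) and `beta` the fraction of absorbed quanta reaching PSII
#' (assumed 0.5 for the C3 species and 0.4 for maize).
#'
#' @param phi PSII operating efficiency in \[0, 1\].
#' @param PPFD Incident photon flux density (umol m-2 s-1, >= 0).
#' @param alpha Leaf absorbance, (0, 1].
#' @param beta PSII partitioning fraction, (0, 1).
#' @return Electron transport rate J (umol e- m-2 s-1).
#' @export
#' @examples
#' electron_transport(0.5, 1500, 0.87, 0.5)  # 326.25
electron_transport <- function(phi, PPFD, alpha, beta) {
  stopifnot(is.numeric(phi), is.numeric(PPFD), is.numeric(alpha),
            is.numeric(beta))
  if (any(phi < 0 | phi > 1)) stop("phi outside [0, 1]")
  if (any(PPFD < 0)) stop("PPFD must be >= 0")
  if (any(alpha <= 0 | alpha > 1)) stop("alpha outside (0, 1]")
  if (any(beta <= 0 | beta >= 1)) stop("beta outside (0, 1)")
  phi * PPFD * alpha * beta
}

#' Default PSII partitioning fraction by species
#'
#' 0.5 for the C3 cereals (rice, wheat) and 0.4 for maize.
#'
#' @param species Character vector of species names.
#' @return Numeric vector of beta values.
#' @export
default_beta <- function(species) {
  ifelse(is_c4(species), 0.4, 0.5)
}

#' Append PSII efficiency and electron transport columns to leaf records
#'
#' Adds `phi_psii` and `J` computed from each record's fluorescence, light
#' and absorbance fields. Records carry their own `beta`; see
#' [default_beta()] for the species convention the generator uses.
#'
#' @param leaf Validated leaf-record data.frame (see [read_leaf_records()]).
#' @return The data frame with `phi_psii` and `J` columns appended.
#' @export
add_fluorescence <- function(leaf) {
  leaf$phi_psii <- phi_psii(leaf$Fs, leaf$Fm_prime)
  leaf$J <- electron_transport(leaf$phi_psii, leaf$PPFD, leaf$alpha,
                               leaf$beta)
  leaf
}
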