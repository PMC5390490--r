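#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm anova coef nls qtukey resid rnorm runif
#'   setNames uniroot var sd median
#' @importFrom utils read.csv write.csv modifyList
NULL

# Species and treatment labels -------------------------------------------

#' Species handled by the pipeline
#' @export
PHOTOLIM_SPECIES <- c("rice", "wheat", "maize")

#' Is a species C4?
#'
#' Of the three cereals covered, only maize runs a C4 carbon-concentrating
#' mechanism; rice and wheat are C3.
#'
#' @param species Character vector of species names.
#' @return Logical vector.
#' @export
is_c4 <- function(species) {
  species <- match.arg(species, PHOTOLIM_SPECIES, several.ok = TRUE)
  species == "maize"
}

#' Compose the treatment label from irrigation and growth temperature
#'
#' The factorial design crosses irrigation (well-watered `WW` vs water
#' deficit `WD`) with growth temperature (25 degC control vs 38 degC `HT38`),
#' giving the four conventional labels `control`, `WD`, `HT` and `HT-WD`.
#'
#' @param irrigation Character vector, `"WW"` or `"WD"`.
#' @param temperature Character vector, `"control25"` or `"HT38"`.
#' @return Character vector of treatment labels.
#' @export
treatment_label <- function(irrigation, temperature) {
  stopifnot(all(irrigation %in% c("WW", "WD")),
            all(temperature %in% c("control25", "HT38")))
  ifelse(temperature == "control25",
         ifelse(irrigation == "WW", "control", "WD"),
         ifelse(irrigation == "WW", "HT", "HT-WD"))
}

TREATMENT_LEVELS <- c("control", "WD", "HT", "HT-WD")

# Kinetic and protocol constants -----------------------------------------

# Catalytic turnover rates (s-1 per site) measured in vitro at 25 degC.
KCAT_DEFAULTS <- c(rice = 2.1, wheat = 2.2, maize = 4.1)

CONSTANT_DEFAULTS <- list(
  gamma_star = 42.75,          # umol mol-1, CO2 compensation point sans Rd
  Kc = 404.9,                  # umol mol-1
  Ko = 278.4,                  # mmol mol-1
  O = 210,                     # mmol mol-1
  gbs = 0.01,                  # mol m-2 s-1, bundle-sheath conductance
  gm_c4 = 1.0,                 # mol m-2 s-1, maize mesophyll conductance
  Vpmax = 120,                 # umol m-2 s-1, PEP carboxylation capacity
  Kp = 80,                     # umol mol-1, PEPC Michaelis constant for CO2
  Rm_fraction = 0.5,           # mesophyll share of dark respiration
  rubisco_molar_mass = 550000, # g mol-1, holoenzyme
  sites_per_holoenzyme = 8
)

#' Assemble the kinetic-constant set for one species
#'
#' Returns the constants used throughout the model stages: Rubisco kinetics
#' (`gamma_star`, `Kc`, `Ko`, oxygen `O`), the species catalytic turnover
#' rate `kcat`, the C4 transport parameters (`gbs`, `gm_c4`, `Vpmax`, `Kp`,
#' `Rm_fraction`) and the holoenzyme stoichiometry used to convert Rubisco
#' mass to catalytic sites. Each constant carries a provenance flag
#' (`"paper"` for the measured kcat values, `"literature-default"` for
#' kinetics the source experiment did not report, `"user"` for overrides)
#' stored in the `"provenance"` attribute.
#'
#' All analyses are at 25 degC; no temperature corrections are applied.
#'
#' @param species One of `"rice"`, `"wheat"`, `"maize"`.
#' @param overrides Named list of user-supplied constant values.
#' @return Named list of constants with a `"provenance"` attribute.
#' @export
#' @examples
#' kinetic_constants("maize")$kcat  # 4.1
kinetic_constants <- function(species, overrides = list()) {
  species <- match.arg(species, PHOTOLIM_SPECIES)
  k <- CONSTANT_DEFAULTS
  k$kcat <- unname(KCAT_DEFAULTS[species])
  prov <- setNames(rep("literature-default", length(k)), names(k))
  prov["kcat"] <- "paper"
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("constant overrides must be a named list")
    unknown <- setdiff(names(overrides), names(k))
    if (length(unknown))
      stop("unknown constant(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) {
      k[[nm]] <- overrides[[nm]]
      prov[nm] <- "user"
    }
  }
  bad <- names(k)[!vapply(k, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("constants must be strictly positive finite scalars: ",
         paste(bad, collapse = ", "))
  attr(k, "provenance") <- prov
  attr(k, "species") <- species
  k
}

#' Load constants for a species, optionally merging a YAML override file
#'
#' The file may contain a top-level `constants:` mapping or be a flat
#' mapping of constant names to values; values found there are applied as
#' user overrides on top of the defaults, and `overrides` (given
#' programmatically) are applied last.
#'
#' @param species One of `"rice"`, `"wheat"`, `"maize"`.
#' @param path Optional path to a YAML configuration file.
#' @param overrides Named list applied after the file.
#' @return As [kinetic_constants()].
#' @export
load_constants <- function(species, path = NULL, overrides = list()) {
  file_over <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("constants file not found: ", path)
    cfg <- yaml::read_yaml(path)
    file_over <- if (!is.null(cfg$constants)) cfg$constants else cfg
    file_over <- file_over[names(file_over) %in% names(CONSTANT_DEFAULTS) |
                             names(file_over) == "kcat"]
  }
  kinetic_constants(species, modifyList(file_over, overrides))
}

# Delimited-text readers -------------------------------------------------

LEAF_COLUMNS <- c("species", "irrigation", "temperature", "replicate_id",
                  "AN", "gs", "Ci", "Ca", "PPFD", "Tleaf", "Rdark",
                  "Fs", "Fm_prime", "alpha", "beta")
ACI_COLUMNS <- c("species", "irrigation", "temperature", "replicate_id",
                 "Ci", "AN")
BIOCHEM_COLUMNS <- c("species", "irrigation", "temperature", "replicate_id",
                     "initial_activity", "total_activity", "rubisco_amount",
                     "rca_total", "rca_large", "rca_small")

read_table_mapped <- function(path, required, col_map = NULL, sep = ",",
                              optional = character()) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  if (length(col_map)) {
    # col_map: names are canonical, values are the file's header names
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(df))
        stop("column map refers to missing column '", src, "' in ", path)
      names(df)[names(df) == src] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing mandatory column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  df[, c(required, intersect(optional, names(df))), drop = FALSE]
}

check_treatment_cols <- function(df, where) {
  bad <- which(!df$species %in% PHOTOLIM_SPECIES)
  if (length(bad))
    stop(where, ": unknown species in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!df$irrigation %in% c("WW", "WD"))
  if (length(bad))
    stop(where, ": irrigation must be WW or WD, row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!df$temperature %in% c("control25", "HT38"))
  if (length(bad))
    stop(where, ": temperature must be control25 or HT38, row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(df)
}

#' Read and validate steady-state leaf gas-exchange/fluorescence records
#'
#' Each row is one leaf's steady-state observation: net assimilation `AN`
#' (umol CO2 m-2 s-1), stomatal conductance to water `gs` (mol H2O m-2 s-1),
#' substomatal and ambient CO2 (`Ci`, `Ca`, umol mol-1), light `PPFD`
#' (umol m-2 s-1), leaf temperature `Tleaf` (degC), pre-dawn dark
#' respiration `Rdark` (umol m-2 s-1, >= 0), steady-state and
#' light-saturated-pulse fluorescence (`Fs`, `Fm_prime`), leaf absorbance
#' `alpha` (0-1] and PSII partitioning fraction `beta` (0-1).
#'
#' Validation enforces `Fm_prime >= Fs > 0`, `0 < alpha <= 1`,
#' `0 < beta < 1`, `Rdark >= 0` and `Ci <= Ca` whenever `AN > 0`; a
#' violation is reported with its row number.
#'
#' @param path Path to a delimited text file.
#' @param col_map Optional named list mapping canonical column names to the
#'   file's header names (instrument exports vary).
#' @param sep Field separator (default comma).
#' @return A validated data.frame with a `treatment` label column appended.
#' @export
read_leaf_records <- function(path, col_map = NULL, sep = ",") {
  df <- read_table_mapped(path, LEAF_COLUMNS, col_map, sep)
  validate_leaf_records(df)
}

#' Validate a leaf-record data.frame (see [read_leaf_records()])
#' @param df Data frame with the leaf-record columns.
#' @return The data frame with a `treatment` column, invisibly checked.
#' @export
validate_leaf_records <- function(df) {
  missing <- setdiff(LEAF_COLUMNS, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  check_treatment_cols(df, "leaf records")
  num <- setdiff(LEAF_COLUMNS, c("species", "irrigation", "temperature",
                                 "replicate_id"))
  for (cl in num) {
    if (!is.numeric(df[[cl]]))
      stop("leaf records: column ", cl, " is not numeric")
    if (anyNA(df[[cl]]))
      stop("leaf records: NA in column ", cl, ", row(s) ",
           paste(utils::head(which(is.na(df[[cl]])), 5), collapse = ", "))
  }
  fail <- function(cond, msg) {
    bad <- which(cond)
    if (length(bad))
      stop("leaf records: ", msg, " in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  fail(df$Fs <= 0, "Fs must be > 0")
  fail(df$Fm_prime < df$Fs, "Fm_prime < Fs")
  fail(df$alpha <= 0 | df$alpha > 1, "alpha outside (0, 1]")
  fail(df$beta <= 0 | df$beta >= 1, "beta outside (0, 1)")
  fail(df$Rdark < 0, "Rdark must be >= 0")
  fail(df$AN > 0 & df$Ci > df$Ca, "Ci > Ca while AN > 0")
  fail(df$PPFD < 0, "PPFD must be >= 0")
  fail(df$gs <= 0, "gs must be > 0")
  df$treatment <- treatment_label(df$irrigation, df$temperature)
  df
}

#' Read A-Ci response curves (maize) as a long table
#'
#' One row per (curve, point); a curve is identified by species, irrigation,
#' temperature and `replicate_id`. Each curve must have at least 4 points
#' with strictly increasing `Ci` (the two-parameter hyperbola is otherwise
#' under-determined).
#'
#' @inheritParams read_leaf_records
#' @return A validated long data.frame with a `treatment` column.
#' @export
read_aci_curves <- function(path, col_map = NULL, sep = ",") {
  df <- read_table_mapped(path, ACI_COLUMNS, col_map, sep)
  validate_aci_curves(df)
}

#' Validate an A-Ci curve table (see [read_aci_curves()])
#' @param df Long data frame of curve points.
#' @return The validated data frame with a `treatment` column.
#' @export
validate_aci_curves <- function(df) {
  missing <- setdiff(ACI_COLUMNS, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  check_treatment_cols(df, "A-Ci curves")
  if (!is.numeric(df$Ci) || !is.numeric(df$AN))
    stop("A-Ci curves: Ci and AN must be numeric")
  key <- interaction(df$species, df$irrigation, df$temperature,
                     df$replicate_id, drop = TRUE)
  for (k in levels(key)) {
    ci <- df$Ci[key == k]
    if (length(ci) < 4)
      stop("A-Ci curve ", k, ": fewer than 4 points")
    if (any(diff(ci) <= 0))
      stop("A-Ci curve ", k, ": Ci not strictly increasing")
  }
  df$treatment <- treatment_label(df$irrigation, df$temperature)
  df
}

#' Read per-replicate Rubisco biochemistry records
#'
#' Columns: initial and total carboxylase activity (umol CO2 mg-1 TSP
#' min-1), Rubisco amount (mg Rubisco mg-1 TSP), Rubisco activase signals
#' (`rca_total`, `rca_large`, `rca_small`; relative units, control = 1) and
#' optionally `tsp_conc` (mg mL-1) for raw-count workflows. Total activity
#' may fall below initial activity only within `activity_slack`
#' (measurement noise); larger violations are rejected.
#'
#' @inheritParams read_leaf_records
#' @param activity_slack Tolerated relative excess of initial over total
#'   activity before a row is rejected (default 0.05).
#' @return A validated data.frame with a `treatment` column.
#' @export
read_biochem_records <- function(path, col_map = NULL, sep = ",",
                                 activity_slack = 0.05) {
  df <- read_table_mapped(path, BIOCHEM_COLUMNS, col_map, sep,
                          optional = "tsp_conc")
  validate_biochem_records(df, activity_slack = activity_slack)
}

#' Validate a biochemistry table (see [read_biochem_records()])
#' @param df Data frame of biochemistry records.
#' @param activity_slack Tolerated relative excess of initial over total.
#' @return The validated data frame with a `treatment` column.
#' @export
validate_biochem_records <- function(df, activity_slack = 0.05) {
  missing <- setdiff(BIOCHEM_COLUMNS, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  check_treatment_cols(df, "biochem records")
  num <- setdiff(BIOCHEM_COLUMNS, c("species", "irrigation", "temperature",
                                    "replicate_id"))
  for (cl in num) {
    if (!is.numeric(df[[cl]]))
      stop("biochem records: column ", cl, " is not numeric")
    bad <- which(df[[cl]] < 0)
    if (length(bad))
      stop("biochem records: negative ", cl, " in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(df$initial_activity > df$total_activity * (1 + activity_slack))
  if (length(bad))
    stop("biochem records: initial activity exceeds total beyond slack ",
         "in row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  df$treatment <- treatment_label(df$irrigation, df$temperature)
  df
}

#' Write a records table as CSV (full double precision)
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(df, path) {
  df <- df[, setdiff(names(df), "treatment"), drop = FALSE]
  write.csv(format_numeric_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# format numerics at 17 significant digits so read-write round trips are
# lossless for doubles
format_numeric_full <- function(df) {
  for (cl in names(df)) {
    if (is.numeric(df[[cl]]))
      df[[cl]] <- formatC(df[[cl]], digits = 17, format = "g")
  }
  df
}
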