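# End-to-end orchestration: simulate -> fluorescence -> diffusion/C4 ->
# biochemistry -> limitations -> statistics, with a reproducible manifest.

# FNV-1a hash of a string; used to fingerprint the run configuration
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256  # XOR with a byte touches only the low 8 bits
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit multiply by 16777619 = 2^24 + 403 in double-safe pieces
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Run the full analysis pipeline on a directory of input CSVs
#'
#' Reads `leaf_records.csv`, `aci_curves.csv` and `biochem.csv` from
#' `input_dir`, then runs every stage: fluorescence (PSII efficiency,
#' electron transport), C3 variable-J diffusion (AG, Cc, gm), C4
#' bundle-sheath inversion (Cm, Vp, Cs), per-curve hyperbola fits,
#' biochemistry (activation state, biochemical Vcmax), the treatment-level
#' limitation partition, factorial ANOVA, Duncan letters per species and
#' the trait-trait regressions. Writes `derived_records.csv`,
#' `aci_fits.csv`, `biochem_derived.csv`, `limitations.csv`, `anova.csv`,
#' `duncan_letters.csv`, `regressions.csv` and `manifest.json` into
#' `out_dir`.
#'
#' All stochastic steps (the bootstrap) are governed by `seed`; two runs
#' with the same inputs, config and seed produce byte-identical CSVs.
#'
#' @param input_dir Directory holding the three input CSVs.
#' @param out_dir Output directory (created if needed).
#' @param config Optional named list: `tsp_area` (g m-2, default 6),
#'   `rd_fraction` (default 0.5), `vp_source`, `method`
#'   (`"log"`/`"fraction"`), `n_boot`, `alpha`, `constants` (named list of
#'   per-species override lists).
#' @param seed Integer seed for the bootstrap.
#' @return Invisibly, a list with all result tables and the manifest.
#' @export
run_pipeline <- function(input_dir, out_dir, config = list(), seed = 1) {
  cfg <- modifyList(list(tsp_area = 6, rd_fraction = 0.5,
                         vp_source = "michaelis", method = "log",
                         n_boot = 2000, alpha = 0.05,
                         constants = list()), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warn_log <- character()
  wh <- function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  constants <- lapply(setNames(nm = PHOTOLIM_SPECIES), function(sp)
    kinetic_constants(sp, cfg$constants[[sp]] %||% list()))

  leaf <- read_leaf_records(file.path(input_dir, "leaf_records.csv"))
  aci <- read_aci_curves(file.path(input_dir, "aci_curves.csv"))
  biochem <- read_biochem_records(file.path(input_dir, "biochem.csv"))

  withCallingHandlers({
    leaf <- add_fluorescence(leaf)
    leaf <- derive_c3(leaf, constants, rd_fraction = cfg$rd_fraction)

    key <- unique(aci$replicate_id)
    fits <- lapply(setNames(nm = key), function(kk) {
      d <- aci[aci$replicate_id == kk, ]
      fit_aci_hyperbola(d$Ci, d$AN)
    })
    aci_fits <- data.frame(
      replicate_id = key,
      Amax = vapply(fits, `[[`, numeric(1), "Amax"),
      K = vapply(fits, `[[`, numeric(1), "K"),
      rmse = vapply(fits, `[[`, numeric(1), "rmse"),
      boundary = vapply(fits, `[[`, logical(1), "boundary"),
      stringsAsFactors = FALSE)
    rownames(aci_fits) <- NULL

    leaf <- derive_c4(leaf, constants$maize, vp_source = cfg$vp_source,
                      hyperbola_by_rep = fits)
    biochem <- derive_biochem(biochem, tsp_area = cfg$tsp_area,
                              constants_by_species = constants)
    limitations <- analyze_limitations(leaf, biochem, constants,
                                       method = cfg$method,
                                       n_boot = cfg$n_boot, seed = seed)

    # factorial statistics on the key traits
    leaf_bio <- merge(
      leaf[, c("species", "irrigation", "temperature", "treatment",
               "replicate_id", "AN", "gs", "J", "AG", "Cc", "gm", "Cs")],
      biochem[, c("replicate_id", "activation_state", "rubisco_amount",
                  "Vcmax")],
      by = "replicate_id")
    leaf_bio <- leaf_bio[order(leaf_bio$replicate_id), ]
    anova_rows <- list()
    for (resp in c("AN", "gs", "J", "activation_state", "rubisco_amount",
                   "Vcmax")) {
      at <- factorial_anova(leaf_bio, resp,
                            c("species", "irrigation", "temperature"))
      at$response <- resp
      anova_rows[[resp]] <- at
    }
    anova_tab <- do.call(rbind, anova_rows)
    rownames(anova_tab) <- NULL

    duncan_rows <- list()
    for (sp in unique(leaf_bio$species)) {
      d <- leaf_bio[leaf_bio$species == sp, ]
      for (resp in c("AN", "activation_state")) {
        g <- duncan_test(d[[resp]], d$treatment, alpha = cfg$alpha)
        g$species <- sp
        g$response <- resp
        duncan_rows[[paste(sp, resp)]] <- as.data.frame(g)
      }
    }
    duncan_tab <- do.call(rbind, duncan_rows)
    rownames(duncan_tab) <- NULL

    reg_rows <- list()
    for (sp in unique(leaf_bio$species)) {
      d <- leaf_bio[leaf_bio$species == sp, ]
      for (pair in list(c("activation_state", "AN"),
                        c("J", "activation_state"))) {
        r <- simple_regression(d[[pair[1]]], d[[pair[2]]])
        reg_rows[[paste(sp, pair[1], pair[2])]] <- data.frame(
          species = sp, x = pair[1], y = pair[2],
          slope = r$slope, intercept = r$intercept, r2 = r$r2, p = r$p,
          n = r$n, stringsAsFactors = FALSE)
      }
    }
    reg_tab <- do.call(rbind, reg_rows)
    rownames(reg_tab) <- NULL
  }, warning = wh)

  write_records(leaf, file.path(out_dir, "derived_records.csv"))
  write_records(aci_fits, file.path(out_dir, "aci_fits.csv"))
  write_records(biochem, file.path(out_dir, "biochem_derived.csv"))
  write_records(limitations, file.path(out_dir, "limitations.csv"))
  write_records(anova_tab, file.path(out_dir, "anova.csv"))
  write_records(duncan_tab, file.path(out_dir, "duncan_letters.csv"))
  write_records(reg_tab, file.path(out_dir, "regressions.csv"))

  manifest <- list(
    config = cfg[setdiff(names(cfg), "constants")],
    config_hash = fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                         digits = NA)),
    seed = seed,
    constants = lapply(constants, function(k)
      list(values = k[], provenance = as.list(attr(k, "provenance")))),
    tsp_area_source = attr(biochem, "tsp_area_source"),
    rd_convention = paste0("Rd = ", cfg$rd_fraction, " * Rdark inside the ",
                           "variable-J formula, mirroring AG"),
    n_records = list(leaf = nrow(leaf), aci_points = nrow(aci),
                     biochem = nrow(biochem)),
    n_infeasible = sum(leaf$feasibility_flag != "ok"),
    warnings = as.list(warn_log),
    package_version = as.character(utils::packageVersion("photolim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(derived = leaf, aci_fits = aci_fits, biochem = biochem,
                 limitations = limitations, anova = anova_tab,
                 duncan = duncan_tab, regressions = reg_tab,
                 manifest = manifest))
}

#' Simulate an experiment and run the pipeline on it
#'
#' Convenience wrapper: [generate_experiment()] -> [write_experiment()] ->
#' [run_pipeline()]. The generator uses `seed` and the pipeline bootstrap
#' `seed + 1`.
#'
#' @param out_dir Output directory; inputs land in `out_dir/inputs`.
#' @param cfg Scenario configuration (default
#'   [default_paper_like_config()]).
#' @param config Pipeline configuration, as in [run_pipeline()].
#' @param seed Integer seed.
#' @return Invisibly, the [run_pipeline()] result list.
#' @export
simulate_and_run <- function(out_dir, cfg = default_paper_like_config(),
                             config = list(), seed = 1) {
  exp <- generate_experiment(cfg, seed = seed)
  write_experiment(exp, file.path(out_dir, "inputs"))
  config$tsp_area <- config$tsp_area %||% cfg$tsp_area
  run_pipeline(file.path(out_dir, "inputs"), out_dir, config = config,
               seed = seed + 1)
}
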