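# Pipeline orchestration: one entry point dispatching the analysis stages,
# usable programmatically (a config list) or from the thin command-line
# wrapper shipped in inst/scripts/ctdbind.R.

#' Run an analysis pipeline stage
#'
#' Dispatches on `config$stage`:
#' \describe{
#'   \item{`peptide`}{parse `config$spec` and report residue count, repeat
#'     count, motifs, motif spacing and extinction coefficient.}
#'   \item{`simulate`}{generate a synthetic dataset: `config$what` one of
#'     `"sw_isotherm"`, `"hsqc"`, `"competition"`, `"guinier"`, with the
#'     generator arguments in `config$args` and `config$seed`.}
#'   \item{`fit-auc`}{read `config$input` (isotherm CSV,
#'     `titrant_uM, sw_S[, sw_err_S]`) and fit the two-site sw model;
#'     `config$peptide_total_uM` required, `config$float_b` optional.}
#'   \item{`fit-nmr`}{read `config$manifest` (peak-table manifest) and run
#'     CSP -> per-residue Kd -> aggregate; `config$P_total_uM` required,
#'     `config$threshold_ppm` optional (default 0.03).}
#'   \item{`fit-fa`}{read `config$input` (`competitor_uM, anisotropy`) and
#'     fit the 4PL competition model.}
#'   \item{`guinier`}{read `config$inputs` (CSV files `q_invA, I[, I_err]`
#'     with `config$concentrations_mg_ml`), Guinier-fit each and
#'     extrapolate Rg to infinite dilution.}
#'   \item{`recover`}{seeded end-to-end parameter-recovery experiment:
#'     `config$scenario` one of `"auc-5R"`, `"auc-1R"`, `"auc-4R-floatb"`,
#'     `"nmr-5R"`, `"nmr-1R"`, `"fa-2R"`, `"saxs"`, using the reference
#'     affinities as generative truth.}
#' }
#' When `config$out_dir` is set, results and the resolved config are written
#' there as JSON (and generated datasets as CSV).
#'
#' @param config Named list (or path to a JSON config file).
#' @return The stage's result, invisibly when written to disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config) || is.null(config$stage)) {
    stop("config must be a list with at least a `stage` field", call. = FALSE)
  }
  stage <- match.arg(config$stage,
                     c("peptide", "simulate", "fit-auc", "fit-nmr",
                       "fit-fa", "guinier", "recover"))
  result <- switch(stage,
    "peptide" = .stage_peptide(config),
    "simulate" = .stage_simulate(config),
    "fit-auc" = .stage_fit_auc(config),
    "fit-nmr" = .stage_fit_nmr(config),
    "fit-fa" = .stage_fit_fa(config),
    "guinier" = .stage_guinier(config),
    "recover" = .stage_recover(config))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(.jsonable(result),
                         file.path(config$out_dir, paste0(stage, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(config,
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(result))
  }
  result
}

# Strip classes/attributes so jsonlite serialises fit objects cleanly.
.jsonable <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .jsonable)
    attributes(x) <- list(names = names(x))
  }
  x
}

.stage_peptide <- function(config) {
  if (is.null(config$spec)) stop("peptide stage needs `spec`", call. = FALSE)
  p <- parse_peptide_spec(config$spec, name = config$name)
  motifs <- suppressWarnings(locate_psp_motifs(p))
  list(name = p$name, spec = format_peptide_spec(p),
       n_residues = length(p$sequence), n_repeats = p$n_repeats,
       phospho_positions = p$phospho_positions,
       motifs = motifs, motif_spacing = motif_spacing(p),
       extinction_280 = extinction_coefficient(p))
}

.stage_simulate <- function(config) {
  what <- match.arg(config$what,
                    c("sw_isotherm", "hsqc", "competition", "guinier"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  a <- config$args
  out <- switch(what,
    "sw_isotherm" = {
      iso <- gen_sw_isotherm(
        a = a$a %||% SW_A_DEFAULT, b = a$b %||% SW_B_DEFAULT,
        k = two_site_params(a$Kd1, a$Kd2),
        peptide_total = a$peptide_total %||% 50,
        noise = noise_spec(a$sd %||% 0.01, seed))
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        write_sw_isotherm(iso, file.path(config$out_dir, "isotherm.csv"))
      }
      iso
    },
    "hsqc" = gen_hsqc_titration(
      n_residues = a$n_residues %||% 20L, Kd = a$Kd,
      P_total = a$P_total %||% 100,
      ratios = if (is.null(a$max_ratio)) default_ratio_grid(3)
               else default_ratio_grid(a$max_ratio),
      noise = noise_spec(a$sd %||% 0.002, seed)),
    "competition" = gen_competition_curve(
      fourpl_params(a$min %||% 0.05, a$max %||% 0.20, a$ic50,
                    a$hillslope %||% -1),
      noise = noise_spec(a$sd %||% 0.0015, seed)),
    "guinier" = gen_guinier_profiles(
      intercept = a$intercept %||% 19.8, slope = a$slope %||% 0.31,
      noise = noise_spec(a$sd %||% 0.005, seed)))
  out
}

.stage_fit_auc <- function(config) {
  if (is.null(config$input) || !file.exists(config$input)) {
    stop("fit-auc: input CSV not found: ", config$input, call. = FALSE)
  }
  iso <- read_sw_isotherm(config$input, config$peptide_total_uM)
  fit_sw_isotherm(iso, float_b = isTRUE(config$float_b))
}

.stage_fit_nmr <- function(config) {
  if (is.null(config$manifest) || !file.exists(config$manifest)) {
    stop("fit-nmr: manifest not found: ", config$manifest, call. = FALSE)
  }
  series <- read_titration_set(config$manifest, config$P_total_uM)
  csps <- lapply(series, compute_csp)
  fits <- lapply(series, fit_residue_kd)
  aggregate_kd(fits, csps,
               threshold = config$threshold_ppm %||% CSP_THRESHOLD_PPM)
}

.stage_fit_fa <- function(config) {
  if (is.null(config$input) || !file.exists(config$input)) {
    stop("fit-fa: input CSV not found: ", config$input, call. = FALSE)
  }
  fit_fourpl(read_competition_curve(config$input))
}

.stage_guinier <- function(config) {
  if (is.null(config$inputs) || !all(file.exists(config$inputs))) {
    stop("guinier: input CSV file(s) missing", call. = FALSE)
  }
  conc <- config$concentrations_mg_ml
  stopifnot(length(conc) == length(config$inputs))
  fits <- lapply(seq_along(config$inputs), function(i) {
    df <- utils::read.csv(config$inputs[[i]])
    guinier_fit(scatter_profile(df$q_invA, df$I,
                                I_err = df$I_err, concentration = conc[i]))
  })
  line <- extrapolate_rg_infinite_dilution(
    conc, vapply(fits, `[[`, numeric(1), "Rg"))
  list(fits = fits, extrapolation = line)
}

.stage_recover <- function(config) {
  scenario <- match.arg(config$scenario,
                        c("auc-5R", "auc-1R", "auc-4R-floatb",
                          "nmr-5R", "nmr-1R", "fa-2R", "saxs"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  ref <- ctd_reference_affinities
  switch(scenario,
    "auc-5R" = recover_sw_isotherm(ref$auc$kd1_uM[3], ref$auc$kd2_uM[3],
                                   seed = seed),
    "auc-1R" = recover_sw_isotherm(ref$auc$kd1_uM[1], ref$auc$kd2_uM[1],
                                   seed = seed),
    "auc-4R-floatb" = recover_sw_isotherm(ref$auc$kd1_uM[2],
                                          ref$auc$kd2_uM[2],
                                          b = ref$sw_b_4R_S,
                                          float_b = TRUE, seed = seed),
    "nmr-5R" = recover_nmr_aggregate(ref$nmr$kd_uM[3], max_ratio = 3,
                                     seed = seed),
    "nmr-1R" = recover_nmr_aggregate(ref$nmr$kd_uM[1], max_ratio = 6,
                                     seed = seed),
    "fa-2R" = recover_ic50(ref$anisotropy$ic50_uM[2], seed = seed),
    "saxs" = recover_rg(ref$saxs_rg_A, ref$saxs_slope, seed = seed))
}

# Seeded generate-then-fit round trips used by the recover stage, the
# test-suite and the acceptance script.

#' Two-site isotherm parameter-recovery round trip
#'
#' Generates an isotherm with [gen_sw_isotherm()] at the given truth and
#' refits it with [fit_sw_isotherm()].
#'
#' @param Kd1,Kd2 Generative dissociation constants (uM).
#' @param a,b Observable parameters (S); defaults are the shared fixed
#'   values.
#' @param float_b Float `b` in the refit (the fit then starts `b` at the
#'   shared default, not at the generative value).
#' @param sd Noise sd (S).
#' @param seed Integer seed.
#' @return List with `truth`, `fit` (the `sw_isotherm_fit`), and recovered
#'   `Kd1`, `Kd2`, `b`.
#' @export
recover_sw_isotherm <- function(Kd1, Kd2, a = SW_A_DEFAULT, b = SW_B_DEFAULT,
                                float_b = FALSE, sd = 0.01, seed = 1L) {
  iso <- gen_sw_isotherm(a, b, two_site_params(Kd1, Kd2),
                         noise = noise_spec(sd, seed))
  fit <- fit_sw_isotherm(iso, a = a, b = SW_B_DEFAULT, float_b = float_b)
  list(truth = list(Kd1 = Kd1, Kd2 = Kd2, a = a, b = b),
       fit = fit,
       Kd1 = fit$params$k$Kd1, Kd2 = fit$params$k$Kd2, b = fit$params$b)
}

#' NMR aggregate-Kd parameter-recovery round trip
#'
#' Generates `n_residues` HSQC titration series at a common true Kd and
#' runs the CSP -> per-residue fit -> aggregate pipeline.
#'
#' @param Kd True dissociation constant (uM).
#' @param n_residues Number of simulated residues (default 20).
#' @param P_total Protein concentration (uM, default 100).
#' @param max_ratio Endpoint ligand:protein ratio (3 or 6).
#' @param sd Shift noise sd (ppm, 1H).
#' @param seed Integer seed.
#' @return List with `truth`, `aggregate` (the `aggregate_kd`), `mean_Kd`.
#' @export
recover_nmr_aggregate <- function(Kd, n_residues = 20L, P_total = 100,
                                  max_ratio = 3, sd = 0.002, seed = 1L) {
  series <- gen_hsqc_titration(n_residues, Kd, P_total = P_total,
                               ratios = default_ratio_grid(max_ratio),
                               noise = noise_spec(sd, seed))
  csps <- lapply(series, compute_csp)
  fits <- lapply(series, fit_residue_kd)
  agg <- aggregate_kd(fits, csps)
  list(truth = list(Kd = Kd), aggregate = agg, mean_Kd = agg$mean_Kd)
}

#' Competition IC50 parameter-recovery round trip
#'
#' @param ic50 Generative IC50 (uM).
#' @param min,max Anisotropy baseline and plateau.
#' @param hillslope Generative slope (negative = descending).
#' @param sd Noise sd in anisotropy units; default 1% of the range.
#' @param seed Integer seed.
#' @return List with `truth`, `fit` (the `fourpl_fit`), `ic50`.
#' @export
recover_ic50 <- function(ic50, min = 0.05, max = 0.20, hillslope = -1,
                         sd = 0.01 * (max - min), seed = 1L) {
  curve <- gen_competition_curve(fourpl_params(min, max, ic50, hillslope),
                                 noise = noise_spec(sd, seed))
  fit <- fit_fourpl(curve)
  list(truth = list(ic50 = ic50),
       fit = fit,
       ic50 = if (fit$degenerate) NA_real_ else fit$params$ic50)
}

#' Guinier infinite-dilution Rg recovery round trip
#'
#' @param intercept,slope Generative Rg(c) line (Angstrom, Angstrom per
#'   mg/mL).
#' @param sd Relative multiplicative noise.
#' @param seed Integer seed.
#' @return List with `truth`, per-profile `fits`, `extrapolation`, and the
#'   recovered `Rg0`.
#' @export
recover_rg <- function(intercept = 19.8, slope = 0.31, sd = 0.005,
                       seed = 1L) {
  profiles <- gen_guinier_profiles(intercept, slope,
                                   noise = noise_spec(sd, seed))
  fits <- lapply(profiles, guinier_fit)
  line <- extrapolate_rg_infinite_dilution(
    vapply(fits, `[[`, numeric(1), "concentration"),
    vapply(fits, `[[`, numeric(1), "Rg"))
  list(truth = list(intercept = intercept, slope = slope),
       fits = fits, extrapolation = line, Rg0 = line$intercept)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
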