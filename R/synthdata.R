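# Seeded synthetic-data generators.
#
# Every generator is a deterministic function of (parameters, seed) and its
# sd = 0 output is exactly the corresponding forward model, so each fitter
# can be exercised by parameter-recovery round trips.  A global seed expands
# into per-stream substreams (e.g. one per residue) so enlarging one stream
# never perturbs another.

#' Gaussian noise specification
#'
#' @param sd Standard deviation in the observable's units (>= 0).
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @return A `noise_spec`.
#' @export
noise_spec <- function(sd, seed = 1L) {
  stopifnot_nonneg(sd, "sd")
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_spec")
}

#' Default Ess1 titration design for sw isotherms
#'
#' Twelve log-spaced titrant concentrations from 0.5 to 1000 uM, the design
#' of the Ess1 titrations into 50 uM peptide.
#'
#' @param n Number of points.
#' @param lo,hi Concentration range (uM).
#' @return Numeric vector of concentrations (uM).
#' @export
default_titrant_grid <- function(n = 12L, lo = 0.5, hi = 1000) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Generate a synthetic sw isotherm
#'
#' `sw = predict_sw(...) + N(0, sd)` over the titration design.
#'
#' @param a,b,k Observable parameters as in [predict_sw()].
#' @param titrant Titrant concentrations (uM); default
#'   [default_titrant_grid()].
#' @param peptide_total Fixed peptide concentration (uM, default 50).
#' @param noise A [noise_spec()].
#' @return An [sw_isotherm()].
#' @export
gen_sw_isotherm <- function(a, b, k, titrant = default_titrant_grid(),
                            peptide_total = 50, noise = noise_spec(0.01)) {
  stopifnot(inherits(noise, "noise_spec"))
  mu <- predict_sw(a, b, k, peptide_total, titrant)
  eps <- with_seed(noise$seed, stats::rnorm(length(mu), 0, noise$sd))
  sw_isotherm(titrant, mu + eps, peptide_total)
}

#' Generate a synthetic c(s) distribution as a sum of Gaussian peaks
#'
#' @param peaks data.frame with columns `s` (peak centre, S), `area`
#'   (integrated signal), `width` (Gaussian sd, S, > 0).
#' @param grid Sedimentation-coefficient grid (S).
#' @return List with `s_grid` and `c` (signal density per S).
#' @export
gen_cs_distribution <- function(peaks, grid = seq(0, 5, by = 0.0025)) {
  stopifnot(is.data.frame(peaks),
            all(c("s", "area", "width") %in% names(peaks)))
  stopifnot_pos(peaks$width, "peaks$width")
  cc <- rep(0, length(grid))
  for (i in seq_len(nrow(peaks))) {
    cc <- cc + peaks$area[i] * stats::dnorm(grid, peaks$s[i], peaks$width[i])
  }
  list(s_grid = grid, c = cc)
}

#' Default ligand:protein ratio grid for HSQC titrations
#'
#' Ten points from the apo reference to `max_ratio`, denser below 1.5 where
#' the bound fraction turns over under ligand depletion.
#'
#' @param max_ratio Endpoint peptide:protein ratio (3 for the long-peptide
#'   design, 6 for the single-repeat design).
#' @return Numeric vector of ratios starting at 0.
#' @export
default_ratio_grid <- function(max_ratio = 3) {
  base <- c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 2.5, 3)
  if (max_ratio == 3) base else base * (max_ratio / 3)
}

#' Generate synthetic HSQC titration series
#'
#' Per-residue saturation CSPs (`delta_bound`) are drawn uniformly in
#' `delta_bound_range` and split between the 1H and 15N dimensions by a
#' random direction; shifts follow the fast-exchange weighted-average model
#' `CSP(L) = delta_bound * [PL]/P_total` with `[PL]` from
#' [solve_single_site()].  Gaussian noise of sd `noise$sd` is added to the
#' 1H shifts and `5 * noise$sd` to the 15N shifts, so the CSP-level noise is
#' isotropic.  Each residue uses its own RNG substream.
#'
#' @param n_residues Number of residues to simulate.
#' @param Kd True dissociation constant (uM).
#' @param P_total Protein concentration (uM, default 100).
#' @param ratios Ligand:protein ratio grid starting at 0; default
#'   [default_ratio_grid()].
#' @param delta_bound_range Range for the uniform `delta_bound` draw (ppm).
#' @param noise A [noise_spec()]; `sd` in ppm on the 1H dimension.
#' @return List of [titration_series()], with the drawn `delta_bound`
#'   values in the `"delta_bound"` attribute.
#' @export
gen_hsqc_titration <- function(n_residues, Kd, P_total = 100,
                               ratios = default_ratio_grid(3),
                               delta_bound_range = c(0.05, 0.4),
                               noise = noise_spec(0.002)) {
  stopifnot(inherits(noise, "noise_spec"))
  stopifnot_pos(Kd, "Kd")
  if (ratios[1] != 0) stop("`ratios` must start at 0", call. = FALSE)
  L <- ratios * P_total
  fb <- solve_single_site(P_total, L, Kd) / P_total

  series <- vector("list", n_residues)
  dbounds <- numeric(n_residues)
  for (i in seq_len(n_residues)) {
    draws <- with_seed(substream(noise$seed, i), {
      list(dbound = stats::runif(1, delta_bound_range[1],
                                 delta_bound_range[2]),
           phi = stats::runif(1, 0, 2 * pi),
           epsH = stats::rnorm(length(L), 0, noise$sd),
           epsN = stats::rnorm(length(L), 0, CSP_NITROGEN_SCALE * noise$sd))
    })
    dbounds[i] <- draws$dbound
    # Split the saturation CSP into H and N components; the 15N component
    # is scaled by 5 so the CSP equation recovers |dbound| at saturation.
    dH_sat <- draws$dbound * cos(draws$phi)
    dN_sat <- CSP_NITROGEN_SCALE * draws$dbound * sin(draws$phi)
    series[[i]] <- titration_series(
      residue_id = i,
      L_total = L,
      dH = 8.0 + dH_sat * fb + draws$epsH,
      dN = 118.0 + dN_sat * fb + draws$epsN,
      P_total = P_total
    )
    # Apo reference must be exactly the first recorded point.
    series[[i]]$dH[1] <- 8.0 + draws$epsH[1]
    series[[i]]$dN[1] <- 118.0 + draws$epsN[1]
  }
  attr(series, "delta_bound") <- dbounds
  series
}

#' Default competitor grid for competition anisotropy
#'
#' Zero plus nine log-spaced concentrations from 1 to 350 uM.
#'
#' @return Numeric vector of concentrations (uM).
#' @export
default_competitor_grid <- function() {
  c(0, exp(seq(log(1), log(350), length.out = 9)))
}

#' Generate a synthetic competition anisotropy curve
#'
#' Default mode evaluates [fourpl_response()] plus Gaussian noise.  The
#' exact-equilibrium mode instead computes the bound-probe fraction from
#' [solve_competitive()] and maps it to anisotropy linearly,
#' `r = min + (max - min) * fb / fb0`, where `fb0` is the bound fraction
#' with no competitor (so the curve spans `[~min, max]`).
#'
#' @param p A [fourpl_params()]; in equilibrium mode `min`/`max` set the
#'   anisotropy scale and `ic50`/`hillslope` are ignored.
#' @param grid Competitor concentrations (uM); default
#'   [default_competitor_grid()].
#' @param noise A [noise_spec()]; `sd` in anisotropy units.
#' @param mode `"fourpl"` (default) or `"equilibrium"`.
#' @param P_total,probe_total,Kd_probe,Kd_comp Equilibrium-mode assay
#'   parameters (uM).
#' @return A [competition_curve()].
#' @export
gen_competition_curve <- function(p, grid = default_competitor_grid(),
                                  noise = noise_spec(0.0015),
                                  mode = c("fourpl", "equilibrium"),
                                  P_total = 50, probe_total = 1,
                                  Kd_probe = 60, Kd_comp = 60) {
  stopifnot(inherits(p, "fourpl_params"), inherits(noise, "noise_spec"))
  mode <- match.arg(mode)
  mu <- if (mode == "fourpl") {
    fourpl_response(p, grid)
  } else {
    fb <- vapply(grid, function(ct) {
      solve_competitive(P_total, probe_total, ct,
                        Kd_probe, Kd_comp)$bound_probe / probe_total
    }, numeric(1))
    p$min + (p$max - p$min) * fb / fb[1]
  }
  eps <- with_seed(noise$seed, stats::rnorm(length(mu), 0, noise$sd))
  competition_curve(grid, mu + eps,
                    probe_total = if (mode == "equilibrium") probe_total
                                  else NA_real_,
                    protein_total = if (mode == "equilibrium") P_total
                                    else NA_real_)
}

#' Generate synthetic Guinier-region scattering profiles
#'
#' `I(q) = I0 exp(-q^2 Rg(c)^2 / 3)` with `Rg(c) = intercept + slope * c`
#' and multiplicative Gaussian noise `I * (1 + N(0, sd))`; one profile per
#' concentration, each on its own RNG substream.
#'
#' @param intercept Infinite-dilution Rg (Angstrom, > 0).
#' @param slope Concentration slope of Rg (Angstrom per mg/mL).
#' @param concentrations Protein concentrations (mg/mL); defaults to the
#'   measured series 1.57, 3.19, 4.78.
#' @param q Momentum-transfer grid (1/Angstrom); default 60 points over
#'   0.01-0.12.
#' @param I0 Zero-angle intensity.
#' @param noise A [noise_spec()]; `sd` is the relative (multiplicative)
#'   noise level, default 0.005.
#' @return List of [scatter_profile()], one per concentration.
#' @export
gen_guinier_profiles <- function(intercept = 19.8, slope = 0.31,
                                 concentrations = c(1.57, 3.19, 4.78),
                                 q = seq(0.01, 0.12, length.out = 60L),
                                 I0 = 1, noise = noise_spec(0.005)) {
  stopifnot_pos(intercept, "intercept")
  stopifnot(inherits(noise, "noise_spec"))
  lapply(seq_along(concentrations), function(i) {
    conc <- concentrations[i]
    rg <- intercept + slope * conc
    mu <- I0 * exp(-q^2 * rg^2 / 3)
    eps <- with_seed(substream(noise$seed, i),
                     stats::rnorm(length(q), 0, noise$sd))
    scatter_profile(q, mu * (1 + eps), concentration = conc)
  })
}
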