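# Guinier analysis of small-angle X-ray scattering profiles.
#
# In the Guinier region ln I(q) = ln I0 - q^2 Rg^2 / 3, valid for
# q Rg < ~1.3.  Rg is determined from a linear fit of ln I vs q^2 over a
# window shrunk iteratively until q_max * Rg <= 1.3, and extrapolated to
# infinite dilution over a concentration series.

GUINIER_QRG_MAX <- 1.3

#' Construct a scattering profile
#'
#' @param q Strictly increasing momentum-transfer grid (1/Angstrom, > 0).
#' @param I Scattered intensity (arbitrary units).
#' @param I_err Optional per-point intensity uncertainties.
#' @param concentration Protein concentration (mg/mL), optional metadata.
#' @return A `scatter_profile`.
#' @export
scatter_profile <- function(q, I, I_err = NULL, concentration = NA_real_) {
  stopifnot_pos(q, "q")
  if (is.unsorted(q, strictly = TRUE)) {
    stop("`q` must be strictly increasing", call. = FALSE)
  }
  if (length(I) != length(q) || any(!is.finite(I))) {
    stop("`I` must be finite and match `q` in length", call. = FALSE)
  }
  if (!is.null(I_err)) stopifnot_pos(I_err, "I_err")
  structure(list(q = as.numeric(q), I = as.numeric(I),
                 I_err = if (is.null(I_err)) NULL else as.numeric(I_err),
                 concentration = concentration),
            class = "scatter_profile")
}

#' Guinier fit of a scattering profile
#'
#' Iterative linear fit of `ln I` vs `q^2`.  The starting window is the
#' first `init_points` points; each iteration keeps the points with
#' `q <= q_rg_max / Rg` and refits, converging when Rg changes by less than
#' 0.1%.  The fit is error-weighted when the profile carries `I_err`
#' (weights `(I/I_err)^2`, the delta-method variance of `ln I`).  Positive
#' slope (non-decaying intensity) raises an invalid-Guinier error; a window
#' below `min_points` points raises an insufficient-data error.
#'
#' @param p A [scatter_profile()] with intensities positive in the fitted
#'   window.
#' @param q_rg_max Window rule threshold on `q * Rg` (default 1.3).
#' @param min_points Minimum points in the fitted window (default 5).
#' @param init_points Points used for the initial Rg estimate (default 10).
#' @return A `guinier_fit`: `Rg` (Angstrom), `I0`, `q_window` (range used),
#'   `n_points`, `se_Rg`, `iterations`, `concentration`.
#' @export
guinier_fit <- function(p, q_rg_max = GUINIER_QRG_MAX, min_points = 5L,
                        init_points = 10L) {
  stopifnot(inherits(p, "scatter_profile"))
  if (length(p$q) < min_points) {
    stop("insufficient data: fewer than ", min_points, " points",
         call. = FALSE)
  }

  fit_window <- function(idx) {
    q <- p$q[idx]; I <- p$I[idx]
    if (any(I <= 0)) {
      stop("non-positive intensity inside the Guinier window", call. = FALSE)
    }
    w <- if (is.null(p$I_err)) NULL else (I / p$I_err[idx])^2
    fit <- stats::lm(log(I) ~ I(q^2), weights = w)
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0) {
      stop("invalid Guinier region: ln(I) does not decay with q^2",
           call. = FALSE)
    }
    list(Rg = sqrt(-3 * slope), fit = fit)
  }

  idx <- seq_len(min(init_points, length(p$q)))
  cur <- fit_window(idx)
  for (iter in seq_len(100L)) {
    keep <- which(p$q <= q_rg_max / cur$Rg)
    if (length(keep) < min_points) {
      stop("insufficient data: Guinier window collapsed below ",
           min_points, " points", call. = FALSE)
    }
    nxt <- fit_window(keep)
    done <- abs(nxt$Rg - cur$Rg) < 1e-3 * cur$Rg
    idx <- keep
    cur <- nxt
    if (done) break
  }

  cf <- stats::coef(cur$fit)
  se_slope <- tryCatch(
    suppressWarnings(sqrt(diag(stats::vcov(cur$fit)))[[2]]),
    error = function(e) NA_real_)
  structure(
    list(Rg = cur$Rg, I0 = exp(cf[[1]]),
         q_window = range(p$q[idx]), n_points = length(idx),
         se_Rg = if (is.finite(se_slope)) 3 * se_slope / (2 * cur$Rg)
                 else NA_real_,
         iterations = iter, concentration = p$concentration),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat("<guinier_fit>\n")
  cat(sprintf("  Rg = %.3f A (se %.3g), I0 = %.4g\n", x$Rg, x$se_Rg, x$I0))
  cat(sprintf("  window q = [%.4g, %.4g] (%d points, qmax*Rg = %.3f)\n",
              x$q_window[1], x$q_window[2], x$n_points,
              x$q_window[2] * x$Rg))
  invisible(x)
}

#' Extrapolate Rg to infinite dilution
#'
#' Ordinary least-squares line of Rg against concentration; the intercept
#' is the infinite-dilution radius of gyration.
#'
#' @param concentration Protein concentrations (mg/mL, >= 2 distinct).
#' @param Rg Fitted radii of gyration (Angstrom), same length.
#' @return List with `intercept` (Rg at c = 0, Angstrom), `slope`
#'   (Angstrom per mg/mL), `se_intercept`, `se_slope`.
#' @export
extrapolate_rg_infinite_dilution <- function(concentration, Rg) {
  stopifnot(length(concentration) == length(Rg))
  if (length(unique(concentration)) < 2L) {
    stop("need Rg at >= 2 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(Rg ~ concentration)
  cf <- stats::coef(fit)
  se <- if (length(Rg) > 2L) {
    tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
             error = function(e) rep(NA_real_, 2))
  } else rep(NA_real_, 2)
  list(intercept = cf[[1]], slope = cf[[2]],
       se_intercept = se[[1]], se_slope = se[[2]])
}
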