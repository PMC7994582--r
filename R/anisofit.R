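# Competition fluorescence anisotropy: four-parameter-logistic IC50 fits.
#
# The competition response is modelled by the 4PL curve
#   f1 = min + (max - min) / (1 + (x / IC50)^(-Hillslope))
# with the exponent written exactly in that sign convention, so a
# descending displacement curve (anisotropy falls as unlabelled competitor
# displaces the FITC probe) has Hillslope < 0.

#' Four-parameter-logistic parameter container
#'
#' @param min Baseline response (anisotropy units).
#' @param max Saturating response (`max >= min`).
#' @param ic50 Competitor concentration at half effect (uM, > 0).
#' @param hillslope Dimensionless slope; the response is
#'   `min + (max - min)/(1 + (x/ic50)^(-hillslope))`, so negative values
#'   give descending competition curves.
#' @return A `fourpl_params` list.
#' @export
fourpl_params <- function(min, max, ic50, hillslope) {
  stopifnot_pos(ic50, "ic50")
  if (max < min) stop("`max` must be >= `min`", call. = FALSE)
  structure(list(min = min, max = max, ic50 = ic50, hillslope = hillslope),
            class = "fourpl_params")
}

#' Evaluate the four-parameter-logistic competition model
#'
#' `f1 = min + (max - min) / (1 + (x/IC50)^(-Hillslope))`.  At `x = 0` the
#' appropriate asymptote is returned by taking the limit (`max` for
#' negative Hillslope, `min` for positive).
#'
#' @param p A [fourpl_params()].
#' @param x Competitor concentration(s) (uM, >= 0).
#' @return Response value(s).
#' @export
fourpl_response <- function(p, x) {
  stopifnot(inherits(p, "fourpl_params"))
  stopifnot_nonneg(x, "x")
  .fourpl(x, p$min, p$max, p$ic50, p$hillslope)
}

.fourpl <- function(x, min, max, ic50, hill) {
  r <- (x / ic50)^(-hill)           # 0^pos = 0, 0^neg = Inf: limits fall out
  out <- min + (max - min) / (1 + r)
  out[is.nan(out)] <- min + (max - min) / 2  # hill == 0 at x == 0
  out
}

#' Construct a competition curve
#'
#' @param competitor_total Non-decreasing competitor concentrations (uM,
#'   may include 0).
#' @param response Anisotropy per point (finite).
#' @param probe_total,protein_total Optional assay metadata (uM).
#' @return A `competition_curve`.
#' @export
competition_curve <- function(competitor_total, response,
                              probe_total = NA_real_,
                              protein_total = NA_real_) {
  stopifnot_nonneg(competitor_total, "competitor_total")
  if (is.unsorted(competitor_total)) {
    stop("`competitor_total` must be non-decreasing", call. = FALSE)
  }
  if (length(response) != length(competitor_total) ||
      any(!is.finite(response))) {
    stop("`response` must be finite and match `competitor_total`",
         call. = FALSE)
  }
  structure(
    list(competitor_total = as.numeric(competitor_total),
         response = as.numeric(response),
         probe_total = probe_total, protein_total = protein_total),
    class = "competition_curve"
  )
}

#' Fit the four-parameter-logistic competition model
#'
#' Bounded Levenberg-Marquardt least squares over a small deterministic set
#' of Hillslope starts (best RSS wins).  Flat curves (no transition) are
#' flagged degenerate rather than returning a meaningless IC50.
#'
#' @param curve A [competition_curve()] with >= 5 points spanning the
#'   transition.
#' @param ic50_bounds Search bounds on IC50 (uM).
#' @return A `fourpl_fit`: `params` ([fourpl_params()]), `se` (per-parameter
#'   standard errors), `rss`, `n`, `degenerate` flag (with `reason`).
#' @export
fit_fourpl <- function(curve, ic50_bounds = c(1e-3, 1e6)) {
  stopifnot(inherits(curve, "competition_curve"))
  x <- curve$competitor_total
  y <- curve$response
  if (length(x) < 5L) {
    stop("competition fit needs >= 5 points", call. = FALSE)
  }
  degen <- function(reason) {
    structure(list(params = NULL, se = NULL, rss = NA_real_, n = length(x),
                   degenerate = TRUE, reason = reason),
              class = "fourpl_fit")
  }
  rng <- diff(range(y))
  if (rng == 0) return(degen("flat response (zero range)"))

  # IC50 start: concentration whose response is nearest the midpoint.
  mid <- (stats::median(utils::head(y, 2)) + stats::median(utils::tail(y, 2))) / 2
  x_pos <- x[x > 0]
  ic50_0 <- if (length(x_pos)) x_pos[which.min(abs(y[x > 0] - mid))] else 1
  descending <- stats::cor(x, y) < 0
  hill_starts <- if (descending) c(-1, -2, -0.5) else c(1, 2, 0.5)

  df <- data.frame(x = x, y = y)
  fits <- lapply(hill_starts, function(h0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ .fourpl(x, mn, mx, ic50, hill),
        data = df,
        start = list(mn = min(y), mx = max(y), ic50 = ic50_0, hill = h0),
        lower = c(mn = -Inf, mx = -Inf, ic50 = ic50_bounds[1], hill = -20),
        upper = c(mn = Inf, mx = Inf, ic50 = ic50_bounds[2], hill = 20),
        control = minpack.lm::nls.lm.control(maxiter = 300L)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) return(degen("fit did not converge from any start"))
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  fit <- fits[[which.min(rss)]]
  cf <- stats::coef(fit)

  # Degenerate when the fitted transition is indistinguishable from noise.
  resid_sd <- sqrt(min(rss) / max(1, length(x) - 4))
  if (abs(cf["mx"] - cf["mn"]) < 3 * resid_sd) {
    return(degen("no resolvable transition (amplitude < 3x residual sd)"))
  }

  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    stats::setNames(rep(NA_real_, 4), c("mn", "mx", "ic50", "hill"))
  })
  structure(
    list(params = fourpl_params(min(cf["mn"], cf["mx"]),
                                max(cf["mn"], cf["mx"]),
                                unname(cf["ic50"]), unname(cf["hill"])),
         se = list(min = unname(se["mn"]), max = unname(se["mx"]),
                   ic50 = unname(se["ic50"]), hillslope = unname(se["hill"])),
         rss = min(rss), n = length(x), degenerate = FALSE,
         reason = NA_character_),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("<fourpl_fit>\n")
  if (x$degenerate) {
    cat("  degenerate fit:", x$reason, "\n")
  } else {
    cat(sprintf("  IC50 = %.4g uM (se %.3g), Hillslope = %.3g\n",
                x$params$ic50, x$se$ic50, x$params$hillslope))
    cat(sprintf("  min = %.4g, max = %.4g, RSS = %.4g over %d points\n",
                x$params$min, x$params$max, x$rss, x$n))
  }
  invisible(x)
}

#' Read a competition curve from CSV (`competitor_uM, anisotropy`)
#'
#' @param path CSV file path.
#' @param ... Passed to [competition_curve()] (metadata).
#' @return A [competition_curve()].
#' @export
read_competition_curve <- function(path, ...) {
  df <- utils::read.csv(path)
  if (!all(c("competitor_uM", "anisotropy") %in% names(df))) {
    stop("curve CSV must have columns competitor_uM, anisotropy",
         call. = FALSE)
  }
  competition_curve(df$competitor_uM, df$anisotropy, ...)
}
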