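# NMR chemical-shift-perturbation (CSP) titration analysis.
#
# Amide shifts in the fast-exchange regime are population-weighted averages
# of the free and bound states, so each residue's CSP along the titration is
#   CSP(L) = delta_bound * [PL] / P_total
# with [PL] from the single-site ligand-depletion quadratic.  Per-residue
# Kds are fitted and then averaged over residues whose endpoint CSP clears
# a threshold (0.03 ppm); residues broadened beyond detection (intermediate
# exchange) are excluded from fitting.

CSP_NITROGEN_SCALE <- 5     # fixed 15N scaling in the CSP equation
CSP_THRESHOLD_PPM <- 0.03   # endpoint threshold for aggregation
CSP_STRONG_PPM <- 0.1       # strong-CSP class boundary for structure maps

#' Construct a per-residue titration series
#'
#' @param residue_id Integer residue number.
#' @param residue_name Residue name (e.g. `"K21"`); optional.
#' @param L_total Non-decreasing total ligand concentrations (uM); the first
#'   point must be the apo reference (`L_total[1] == 0`).
#' @param dH,dN Amide 1H and 15N chemical shifts (ppm) per point.
#' @param P_total Protein concentration (uM).
#' @param broadened Logical per point: resonance broadened beyond detection.
#' @return A `titration_series`.
#' @export
titration_series <- function(residue_id, L_total, dH, dN, P_total,
                             residue_name = NA_character_,
                             broadened = rep(FALSE, length(L_total))) {
  np <- length(L_total)
  stopifnot(length(dH) == np, length(dN) == np, length(broadened) == np)
  if (np < 1L || L_total[1] != 0) {
    stop("first titration point must be the apo reference (L_total = 0)",
         call. = FALSE)
  }
  if (is.unsorted(L_total)) {
    stop("`L_total` must be non-decreasing", call. = FALSE)
  }
  stopifnot_pos(P_total, "P_total")
  structure(
    list(residue_id = as.integer(residue_id), residue_name = residue_name,
         L_total = as.numeric(L_total), dH = as.numeric(dH),
         dN = as.numeric(dN), P_total = P_total,
         broadened = as.logical(broadened)),
    class = "titration_series"
  )
}

#' Compute chemical shift perturbations along a titration
#'
#' \deqn{CSP = \sqrt{(\Delta\delta_H)^2 + (\Delta\delta_N / 5)^2}}
#' against the apo reference point.  Broadened points carry `NA`.  The CSP
#' is invariant to uniform referencing offsets applied to all spectra.
#'
#' @param series A [titration_series()].
#' @return A `csp_record`: list with `residue_id`, `L_total`, `csp` (ppm per
#'   point), `endpoint_csp` (ppm, last non-broadened point), `broadened`.
#' @export
compute_csp <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  csp <- sqrt((series$dH - series$dH[1])^2 +
                ((series$dN - series$dN[1]) / CSP_NITROGEN_SCALE)^2)
  csp[series$broadened] <- NA_real_
  ok <- which(!is.na(csp))
  endpoint <- if (length(ok)) csp[max(ok)] else NA_real_
  structure(
    list(residue_id = series$residue_id, residue_name = series$residue_name,
         L_total = series$L_total, csp = csp, endpoint_csp = endpoint,
         broadened = series$broadened),
    class = "csp_record"
  )
}

#' Fit a per-residue dissociation constant from a CSP titration
#'
#' Least-squares fit of `CSP(L) = delta_bound * [PL] / P_total` with `[PL]`
#' from [solve_single_site()], by bounded Levenberg-Marquardt.  Starts:
#' Kd at the titration midpoint, delta_bound at the endpoint CSP; bounds
#' Kd in [1e-2, 1e5] uM, delta_bound >= 0.  Broadened points are dropped.
#' Failures return a structured failure record so a multi-residue pipeline
#' can continue.
#'
#' @param series A [titration_series()] with >= 4 usable points.
#' @return A `residue_fit`: `residue_id`, `ok`, `Kd` (uM), `delta_bound`
#'   (ppm), `se_Kd`, `se_delta_bound`, `rss`, `n`, and `reason` on failure.
#' @export
fit_residue_kd <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  rec <- compute_csp(series)
  use <- !series$broadened & !is.na(rec$csp)
  fail <- function(reason) {
    structure(list(residue_id = series$residue_id,
                   residue_name = series$residue_name,
                   ok = FALSE, Kd = NA_real_, delta_bound = NA_real_,
                   se_Kd = NA_real_, se_delta_bound = NA_real_,
                   rss = NA_real_, n = sum(use), reason = reason),
              class = "residue_fit")
  }
  if (sum(use) < 4L) return(fail("fewer than 4 usable points"))
  L <- series$L_total[use]
  y <- rec$csp[use]
  if (!is.finite(rec$endpoint_csp) || rec$endpoint_csp <= 0 ||
      max(y) <= 0) {
    return(fail("no perturbation (endpoint CSP <= 0)"))
  }
  P <- series$P_total
  df <- data.frame(L = L, y = y)
  start <- list(Kd = max(stats::median(L[L > 0]), 1e-2),
                dbound = rec$endpoint_csp)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ dbound * solve_single_site(P, L, Kd) / P,
      data = df, start = start,
      lower = c(Kd = 1e-2, dbound = 0),
      upper = c(Kd = 1e5, dbound = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200L)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear fit did not converge"))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    c(Kd = NA_real_, dbound = NA_real_)
  })
  structure(
    list(residue_id = series$residue_id, residue_name = series$residue_name,
         ok = TRUE, Kd = unname(cf["Kd"]), delta_bound = unname(cf["dbound"]),
         se_Kd = unname(se["Kd"]), se_delta_bound = unname(se["dbound"]),
         rss = sum(stats::residuals(fit)^2), n = sum(use), reason = NA_character_),
    class = "residue_fit"
  )
}

#' Aggregate per-residue Kds over threshold-passing residues
#'
#' Unweighted mean and population standard deviation of the fitted Kds of
#' residues whose endpoint CSP exceeds `threshold` (default 0.03 ppm) and
#' whose fit succeeded; every excluded residue is itemized with its reason.
#'
#' @param fits List of `residue_fit` objects (from [fit_residue_kd()]).
#' @param csps List of `csp_record` objects (from [compute_csp()]), keyed to
#'   `fits` by residue id.
#' @param threshold Endpoint-CSP inclusion threshold (ppm).
#' @return An `aggregate_kd`: `mean_Kd` (uM), `sd_Kd` (uM, population SD),
#'   `n`, `contributing` (residue ids), `exclusions` (data.frame residue_id,
#'   reason).  When nothing contributes, `mean_Kd`/`sd_Kd` are `NA` and `n`
#'   is 0 (an explicit empty aggregate).
#' @export
aggregate_kd <- function(fits, csps, threshold = CSP_THRESHOLD_PPM) {
  ids_f <- vapply(fits, `[[`, integer(1), "residue_id")
  ids_c <- vapply(csps, `[[`, integer(1), "residue_id")
  kds <- numeric(0); contributing <- integer(0)
  excl_id <- integer(0); excl_why <- character(0)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    j <- match(f$residue_id, ids_c)
    if (is.na(j)) {
      excl_id <- c(excl_id, f$residue_id)
      excl_why <- c(excl_why, "no CSP record")
      next
    }
    ep <- csps[[j]]$endpoint_csp
    if (!isTRUE(f$ok)) {
      excl_id <- c(excl_id, f$residue_id)
      excl_why <- c(excl_why, paste0("fit failed: ", f$reason))
    } else if (!is.finite(ep) || ep <= threshold) {
      excl_id <- c(excl_id, f$residue_id)
      excl_why <- c(excl_why,
                    sprintf("endpoint CSP %.4g <= threshold %.3g ppm",
                            ep, threshold))
    } else {
      kds <- c(kds, f$Kd)
      contributing <- c(contributing, f$residue_id)
    }
  }
  structure(
    list(mean_Kd = if (length(kds)) mean(kds) else NA_real_,
         sd_Kd = if (length(kds)) pop_sd(kds) else NA_real_,
         n = length(kds), contributing = contributing,
         exclusions = data.frame(residue_id = excl_id, reason = excl_why),
         threshold = threshold),
    class = "aggregate_kd"
  )
}

#' @export
print.aggregate_kd <- function(x, ...) {
  cat("<aggregate_kd>\n")
  if (x$n == 0) {
    cat("  empty aggregate: no contributing residues\n")
  } else {
    cat(sprintf("  mean Kd = %.4g uM, SD = %.4g uM over %d residues\n",
                x$mean_Kd, x$sd_Kd, x$n))
  }
  cat(sprintf("  threshold: endpoint CSP > %.3g ppm; %d excluded\n",
              x$threshold, nrow(x$exclusions)))
  invisible(x)
}

#' Classify an endpoint CSP for structure mapping
#'
#' Classes used when colouring binding-interface maps: `strong`
#' (> 0.1 ppm), `moderate` (> 0.03 ppm), `none` otherwise; `broadened`
#' (resonance lost to intermediate exchange) dominates all three.
#'
#' @param endpoint_csp Endpoint CSP(s) in ppm (may be `NA` when broadened).
#' @param broadened Logical, same length: broadened beyond detection.
#' @return Character vector in `{"none","moderate","strong","broadened"}`.
#' @export
classify_csp <- function(endpoint_csp, broadened = FALSE) {
  n <- max(length(endpoint_csp), length(broadened))
  endpoint_csp <- rep_len(endpoint_csp, n)
  broadened <- rep_len(broadened, n)
  out <- ifelse(broadened, "broadened",
                ifelse(endpoint_csp > CSP_STRONG_PPM, "strong",
                       ifelse(endpoint_csp > CSP_THRESHOLD_PPM, "moderate",
                              "none")))
  out[!broadened & !is.finite(rep_len(endpoint_csp, n))] <- NA_character_
  out
}

#' Resonance-assignment completeness
#'
#' @param assigned Number of assigned resonances (0 <= assigned <= total).
#' @param total Number of assignable resonances (> 0).
#' @return List with `percent` (exact, 100*assigned/total) and `rounded`
#'   (nearest integer percentage).
#' @examples
#' assignment_completeness(154, 162)$rounded  # 95
#' @export
assignment_completeness <- function(assigned, total) {
  if (any(total <= 0)) stop("`total` must be positive", call. = FALSE)
  if (any(assigned < 0) || any(assigned > total)) {
    stop("need 0 <= assigned <= total", call. = FALSE)
  }
  pct <- 100 * assigned / total
  list(percent = pct, rounded = round(pct))
}

#' Read a titration peak-table set from CSV
#'
#' Each titration point is one peak-table CSV with columns
#' `residue_id, residue_name, dH_ppm, dN_ppm, broadened`; a manifest maps
#' point files to ligand concentrations (`file, L_total_uM`), ordered with
#' the apo reference first.
#'
#' @param manifest_path Manifest CSV path (`file, L_total_uM`); `file` paths
#'   are resolved relative to the manifest's directory.
#' @param P_total Protein concentration (uM).
#' @return List of [titration_series()], one per residue.
#' @export
read_titration_set <- function(manifest_path, P_total) {
  man <- utils::read.csv(manifest_path)
  if (!all(c("file", "L_total_uM") %in% names(man))) {
    stop("manifest must have columns file, L_total_uM", call. = FALSE)
  }
  man <- man[order(man$L_total_uM), , drop = FALSE]
  dir <- dirname(manifest_path)
  tabs <- lapply(file.path(dir, man$file), utils::read.csv)
  ids <- sort(unique(unlist(lapply(tabs, `[[`, "residue_id"))))
  lapply(ids, function(id) {
    rows <- lapply(tabs, function(t) t[t$residue_id == id, , drop = FALSE])
    keep <- vapply(rows, nrow, integer(1)) == 1L
    titration_series(
      residue_id = id,
      residue_name = rows[[which(keep)[1]]]$residue_name,
      L_total = man$L_total_uM[keep],
      dH = vapply(rows[keep], `[[`, numeric(1), "dH_ppm"),
      dN = vapply(rows[keep], `[[`, numeric(1), "dN_ppm"),
      P_total = P_total,
      broadened = as.logical(vapply(rows[keep], `[[`, numeric(1),
                                    "broadened"))
    )
  })
}
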