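# Binding-equilibrium solvers shared by all fitters.
#
# Three systems, all at thermodynamic equilibrium in units of uM:
#   * single site with ligand depletion (closed-form quadratic),
#   * a two-site receptor E binding titrant S at independent sites with
#     microscopic constants Kd1, Kd2 (species E, SE, ES, SES), the
#     thermodynamic cycle closed by site independence,
#   * two ligands competing for one shared site.
# The two-site and competition systems reduce to a monotone 1-D conservation
# root and are solved by a bracketed method.

#' Single-site bound complex with ligand depletion
#'
#' Closed-form solution of P + L <-> PL:
#' \deqn{[PL] = \frac{(P_t + L_t + K_d) - \sqrt{(P_t + L_t + K_d)^2 - 4 P_t L_t}}{2}}
#' Valid at any depletion level; 0 <= PL <= min(P_t, L_t).
#'
#' @param P_total Total protein concentration (uM, scalar).
#' @param L_total Total ligand concentration (uM, vectorised).
#' @param Kd Dissociation constant (uM, > 0).
#' @return Bound complex concentration(s) `[PL]` (uM).
#' @examples
#' solve_single_site(100, 100, 100)  # 100 * (3 - sqrt(5)) / 2
#' @export
solve_single_site <- function(P_total, L_total, Kd) {
  stopifnot_nonneg(P_total, "P_total")
  stopifnot_nonneg(L_total, "L_total")
  stopifnot_pos(Kd, "Kd")
  b <- P_total + L_total + Kd
  disc <- b^2 - 4 * P_total * L_total
  disc[disc < 0] <- 0  # guard tiny negative round-off
  pl <- (b - sqrt(disc)) / 2
  pmin(pmax(pl, 0), pmin(P_total, L_total))
}

#' Two-site parameter container
#'
#' Microscopic (per-site) dissociation constants of the two-site receptor;
#' no statistical factors are applied and the thermodynamic cycle is closed
#' by site independence (the cycle product is 1, no cooperativity term).
#'
#' @param Kd1 Site-1 dissociation constant (uM, > 0).
#' @param Kd2 Site-2 dissociation constant (uM, > 0).
#' @return A `two_site_params` list.
#' @export
two_site_params <- function(Kd1, Kd2) {
  stopifnot_pos(Kd1, "Kd1")
  stopifnot_pos(Kd2, "Kd2")
  structure(list(Kd1 = Kd1, Kd2 = Kd2), class = "two_site_params")
}

# Species concentrations implied by free titrant S at receptor total E_total.
.two_site_species <- function(S_free, E_total, Kd1, Kd2) {
  denom <- 1 + S_free / Kd1 + S_free / Kd2 + S_free^2 / (Kd1 * Kd2)
  E <- E_total / denom
  list(E = E,
       S_free = S_free,
       SE = E * S_free / Kd1,
       ES = E * S_free / Kd2,
       SES = E * S_free^2 / (Kd1 * Kd2))
}

#' Solve the two-site binding equilibrium
#'
#' Species of receptor E with independent sites 1 and 2 binding titrant S:
#' free receptor E, singly occupied SE (site 1) and ES (site 2), doubly
#' occupied SES, with mass-action relations SE = E.S/Kd1, ES = E.S/Kd2,
#' SES = E.S^2/(Kd1.Kd2).  Solved as a 1-D root problem in free titrant on
#' the bracket [0, S_total]; the conservation function is strictly
#' increasing, so the root is unique.
#'
#' @param E_total Total two-site receptor (uM, scalar >= 0).
#' @param S_total Total titrant (uM, scalar >= 0).
#' @param k A [two_site_params()].
#' @param tol Absolute tolerance on the titrant-conservation residual (uM).
#' @return A `species_state` list: `E`, `S_free`, `SE`, `ES`, `SES` (uM).
#' @export
solve_two_site <- function(E_total, S_total, k, tol = 1e-12) {
  stopifnot(inherits(k, "two_site_params"))
  stopifnot_nonneg(E_total, "E_total")
  stopifnot_nonneg(S_total, "S_total")
  Kd1 <- k$Kd1; Kd2 <- k$Kd2

  if (S_total == 0 || E_total == 0) {
    sp <- .two_site_species(S_total, E_total, Kd1, Kd2)
    return(structure(sp, class = "species_state"))
  }

  resid <- function(S) {
    sp <- .two_site_species(S, E_total, Kd1, Kd2)
    S + sp$SE + sp$ES + 2 * sp$SES - S_total
  }
  root <- tryCatch(
    stats::uniroot(resid, lower = 0, upper = S_total,
                   tol = min(tol, 1e-12 * max(1, S_total)), maxiter = 2000L),
    error = function(e) {
      stop(sprintf(paste0("two-site equilibrium root-solve failed ",
                          "(E_total=%g, S_total=%g, Kd1=%g, Kd2=%g): %s"),
                   E_total, S_total, Kd1, Kd2, conditionMessage(e)),
           call. = FALSE)
    })
  sp <- .two_site_species(root$root, E_total, Kd1, Kd2)
  structure(sp, class = "species_state")
}

#' Competitive binding of two ligands for one shared site
#'
#' Exact equilibrium of P + A <-> PA, P + B <-> PB (A = labelled probe,
#' B = unlabelled competitor).  The generator behind four-parameter-logistic
#' competition fits.  Solved as a bracketed root in free protein.
#'
#' @param P_total Total protein (uM).
#' @param probe_total Total probe (uM).
#' @param competitor_total Total competitor (uM).
#' @param Kd_probe,Kd_comp Dissociation constants (uM, > 0).
#' @return List with `bound_probe`, `bound_competitor`, `P_free` (uM).
#' @export
solve_competitive <- function(P_total, probe_total, competitor_total,
                              Kd_probe, Kd_comp) {
  stopifnot_nonneg(P_total, "P_total")
  stopifnot_nonneg(probe_total, "probe_total")
  stopifnot_nonneg(competitor_total, "competitor_total")
  stopifnot_pos(Kd_probe, "Kd_probe")
  stopifnot_pos(Kd_comp, "Kd_comp")

  bound <- function(Pf) {
    list(a = probe_total * Pf / (Kd_probe + Pf),
         b = competitor_total * Pf / (Kd_comp + Pf))
  }
  if (P_total == 0) {
    return(list(bound_probe = 0, bound_competitor = 0, P_free = 0))
  }
  resid <- function(Pf) {
    bb <- bound(Pf)
    Pf + bb$a + bb$b - P_total
  }
  root <- tryCatch(
    stats::uniroot(resid, lower = 0, upper = P_total,
                   tol = 1e-13 * max(1, P_total), maxiter = 2000L),
    error = function(e) {
      stop("competitive equilibrium root-solve failed: ",
           conditionMessage(e), call. = FALSE)
    })
  bb <- bound(root$root)
  list(bound_probe = bb$a, bound_competitor = bb$b, P_free = root$root)
}

#' @export
print.species_state <- function(x, ...) {
  cat("<species_state> (uM)\n")
  for (nm in c("E", "S_free", "SE", "ES", "SES")) {
    cat(sprintf("  %-7s %.6g\n", nm, x[[nm]]))
  }
  invisible(x)
}
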