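# Solution chemistry ground truth: acid-base speciation by charge balance,
# strong-base titrant addition, and first-order FFA release kinetics.

#' Molar mass of sodium dihydrogen phosphate monohydrate (g/mol)
#'
#' Used by [make_phosphate_buffer()] to convert a weighed mass of
#' NaH2PO4.H2O into moles of total phosphate.
#' @export
MW_NAH2PO4_H2O <- 137.99

#' Define a (poly)protic acid present in the vessel
#'
#' An acid is described by its *fully protonated* form: `total_moles` is the
#' analytical total over all protonation states, and `pKa` lists the stepwise
#' acid dissociation constants in strictly ascending order. A phosphate salt
#' such as NaH2PO4 is therefore entered as total H3PO4 plus one mole of Na+
#' per formula unit in the solution state's `fixed_ion_charge`.
#'
#' @param name Species label (e.g. `"phosphate"`, `"FFA"`).
#' @param total_moles Analytical moles of the acid, all protonation states
#'   combined. Must be >= 0.
#' @param pKa Numeric vector of stepwise pKa values, strictly ascending.
#' @return An object of class `acid_species`.
#' @examples
#' acid_species("phosphate", 2.8e-4, c(2.15, 7.21, 12.35))
#' @export
acid_species <- function(name, total_moles, pKa) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(total_moles) || length(total_moles) != 1L ||
      !is.finite(total_moles) || total_moles < 0) {
    stop("'total_moles' must be a single finite number >= 0", call. = FALSE)
  }
  pKa <- as.numeric(pKa)
  if (length(pKa) < 1L || any(!is.finite(pKa))) {
    stop("'pKa' must be a non-empty vector of finite values", call. = FALSE)
  }
  if (length(pKa) > 1L && any(diff(pKa) <= 0)) {
    stop("'pKa' values must be strictly ascending", call. = FALSE)
  }
  structure(list(name = name, total_moles = total_moles, pKa = pKa),
            class = "acid_species")
}

#' Create a vessel solution state
#'
#' The chemistry ground truth for the simulator: the vessel volume plus the
#' conserved mole totals of every species. Concentrations are derived, never
#' stored, so dilution on titrant addition is handled exactly.
#'
#' @param volume_L Vessel volume in litres (> 0).
#' @param acids List of [acid_species()] objects.
#' @param strong_base_moles Moles of Na+ delivered as NaOH titrant.
#' @param strong_acid_moles Moles of fully dissociated strong-acid
#'   counter-charge (e.g. HCl used to pre-acidify).
#' @param fixed_ion_charge Net moles of spectator charge: cations positive,
#'   anions negative. Na+ bound in NaH2PO4 contributes +1 per formula unit;
#'   balanced salts such as NaCl or CaCl2 contribute zero net charge.
#' @return An object of class `solution_state`.
#' @seealso [solve_ph()], [add_titrant()]
#' @export
solution_state <- function(volume_L, acids = list(), strong_base_moles = 0,
                           strong_acid_moles = 0, fixed_ion_charge = 0) {
  if (!is.numeric(volume_L) || length(volume_L) != 1L ||
      !is.finite(volume_L) || volume_L <= 0) {
    stop("'volume_L' must be a single number > 0", call. = FALSE)
  }
  if (inherits(acids, "acid_species")) acids <- list(acids)
  if (!all(vapply(acids, inherits, logical(1), "acid_species"))) {
    stop("'acids' must be a list of acid_species objects", call. = FALSE)
  }
  for (v in c(strong_base_moles, strong_acid_moles)) {
    if (!is.finite(v) || v < 0) {
      stop("mole totals must be finite and >= 0", call. = FALSE)
    }
  }
  if (!is.finite(fixed_ion_charge)) {
    stop("'fixed_ion_charge' must be finite", call. = FALSE)
  }
  names(acids) <- vapply(acids, `[[`, character(1), "name")
  structure(list(volume_L = volume_L, acids = acids,
                 strong_base_moles = strong_base_moles,
                 strong_acid_moles = strong_acid_moles,
                 fixed_ion_charge = fixed_ion_charge),
            class = "solution_state")
}

# Mean number of protons dissociated per mole of an n-protic acid at a given
# [H+]; computed in log10 space to avoid overflow for extreme pH.
mean_dissociation <- function(pKa, h) {
  n <- length(pKa)
  j <- 0:n
  log_terms <- c(0, cumsum(-pKa)) + (n - j) * log10(h)
  log_terms <- log_terms - max(log_terms)
  terms <- 10^log_terms
  sum(j * terms) / sum(terms)
}

#' Charge-balance residual of a solution at a trial pH
#'
#' Electroneutrality residual in mol/L (positive charge excess):
#' `[H+] - [OH-] + (base - acid + fixed)/V - sum_i C_i * nbar_i(pH)` where
#' `nbar_i` is the mean number of dissociated protons of acid i. The pH of
#' the state is the root of this function.
#'
#' @param pH Trial pH.
#' @param state A [solution_state()].
#' @param pKw Water autoprotolysis constant, -log10(Kw). Default 14.00 (25 C).
#' @return Residual in mol/L.
#' @export
charge_residual <- function(pH, state, pKw = 14) {
  h <- 10^(-pH)
  oh <- 10^(pH - pKw)
  fixed <- (state$strong_base_moles - state$strong_acid_moles +
              state$fixed_ion_charge) / state$volume_L
  acid_anions <- 0
  for (a in state$acids) {
    if (a$total_moles > 0) {
      acid_anions <- acid_anions +
        (a$total_moles / state$volume_L) * mean_dissociation(a$pKa, h)
    }
  }
  h - oh + fixed - acid_anions
}

#' Solve for the equilibrium pH of a solution
#'
#' Finds the unique root of the charge-balance residual on a fixed bracket
#' (default `[0, 14]`) by Brent's method ([stats::uniroot()]); the returned
#' root satisfies `|charge_residual| < 1e-12` mol/L. Bracketed root-finding is
#' used for robustness: the residual is strictly decreasing in pH so the root
#' is unique whenever a sign change exists.
#'
#' @inheritParams charge_residual
#' @param interval Search bracket in pH units.
#' @return The equilibrium pH (scalar).
#' @examples
#' solve_ph(solution_state(1))  # pure water -> 7
#' @export
solve_ph <- function(state, pKw = 14, interval = c(0, 14)) {
  stopifnot(inherits(state, "solution_state"))
  f <- function(p) charge_residual(p, state, pKw)
  f_lo <- f(interval[1])
  f_hi <- f(interval[2])
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0) {
    stop("charge-balance residual has no sign change on [",
         interval[1], ", ", interval[2],
         "]: inconsistent solution state (check signed charge totals)",
         call. = FALSE)
  }
  r <- stats::uniroot(f, interval, f.lower = f_lo, f.upper = f_hi,
                      tol = 1e-15, maxiter = 2000L)
  root <- r$root
  if (abs(f(root)) >= 1e-12) {
    # polish by bisection; the residual slope is at least ~2.3*[H+], so a few
    # extra halvings always push |f| under the contract tolerance
    lo <- max(interval[1], root - 1e-6)
    hi <- min(interval[2], root + 1e-6)
    if (f(lo) < 0) lo <- interval[1]
    if (f(hi) > 0) hi <- interval[2]
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) < 1e-12 || hi - lo < 1e-16) break
      if (fm > 0) lo <- mid else hi <- mid
    }
    root <- mid
  }
  root
}

#' Build the monobasic phosphate buffer from a weighed mass
#'
#' Dissolves `mass_g` grams of NaH2PO4.H2O in `volume_L` litres of water:
#' the resulting state carries the total phosphate as a triprotic acid plus
#' one Na+ per formula unit as fixed spectator charge.
#'
#' @param mass_g Mass of NaH2PO4.H2O in grams (> 0).
#' @param volume_L Final volume in litres (> 0).
#' @param pKa Phosphate stepwise pKa values (thermodynamic, 25 C).
#' @param molar_mass Formula mass of NaH2PO4.H2O in g/mol.
#' @return A list with components `state` (a [solution_state()]) and
#'   `molarity` (total phosphate, mol/L).
#' @examples
#' b <- make_phosphate_buffer(0.03898, 0.25)
#' signif(b$molarity, 3)  # 1.13e-3
#' @export
make_phosphate_buffer <- function(mass_g, volume_L,
                                  pKa = c(2.15, 7.21, 12.35),
                                  molar_mass = MW_NAH2PO4_H2O) {
  if (!is.finite(mass_g) || mass_g <= 0) {
    stop("'mass_g' must be > 0", call. = FALSE)
  }
  if (!is.finite(volume_L) || volume_L <= 0) {
    stop("'volume_L' must be > 0", call. = FALSE)
  }
  moles <- mass_g / molar_mass
  state <- solution_state(
    volume_L = volume_L,
    acids = list(acid_species("phosphate", moles, pKa)),
    fixed_ion_charge = moles  # one Na+ per NaH2PO4 formula unit
  )
  list(state = state, molarity = moles / volume_L)
}

#' Add a volume of strong titrant to the vessel
#'
#' Adds `volume_L * normality` equivalents of NaOH (or, with
#' `kind = "acid"`, of a strong monoprotic acid) and increases the vessel
#' volume accordingly. Acid totals are conserved; only their concentrations
#' change through dilution.
#'
#' @param state A [solution_state()].
#' @param volume_L Titrant volume in litres (>= 0).
#' @param normality Titrant normality in eq/L.
#' @param kind `"base"` (NaOH, the validated path) or `"acid"` (sign mirror).
#' @return The updated `solution_state`.
#' @export
add_titrant <- function(state, volume_L, normality, kind = c("base", "acid")) {
  stopifnot(inherits(state, "solution_state"))
  kind <- match.arg(kind)
  if (!is.finite(volume_L) || volume_L < 0) {
    stop("'volume_L' must be >= 0", call. = FALSE)
  }
  eq <- volume_L * normality
  if (kind == "base") {
    state$strong_base_moles <- state$strong_base_moles + eq
  } else {
    state$strong_acid_moles <- state$strong_acid_moles + eq
  }
  state$volume_L <- state$volume_L + volume_L
  state
}

#' Adjust strong base/acid so a state sits exactly at a target pH
#'
#' The charge-balance residual is linear in the strong-base concentration, so
#' the titrant moles needed to pin the state at `target_pH` have a closed
#' form. The vessel volume is left unchanged (an idealised adjustment used by
#' scenario builders, not a simulated dosing).
#'
#' @inheritParams solve_ph
#' @param target_pH The pH the state should equilibrate to.
#' @return The adjusted `solution_state`.
#' @export
equilibrate_to_ph <- function(state, target_pH, pKw = 14) {
  stopifnot(inherits(state, "solution_state"))
  r <- charge_residual(target_pH, state, pKw)
  if (r < 0) {
    state$strong_base_moles <- state$strong_base_moles - r * state$volume_L
  } else {
    state$strong_acid_moles <- state$strong_acid_moles + r * state$volume_L
  }
  state
}

#' Define first-order lipolysis kinetics
#'
#' Free fatty acids (FFA) are released from a finite hydrolyzable pool by
#' first-order decay of the remaining pool: over an interval `dt` (past an
#' optional lag), `remaining * (1 - exp(-k dt))` moles of FFA move from the
#' pool into the solution as a single effective monoprotic acid with
#' interfacial pKa `ffa_pKa_eff`. The pool for `W` grams of oil of mean
#' triglyceride molar mass `M` is `2 W / M` (up to two FFAs per
#' triglyceride under intestinal lipolysis).
#'
#' @param releasable_ffa_moles0 Initial hydrolyzable FFA pool in moles.
#' @param rate_constant First-order rate constant in 1/s.
#' @param ffa_pKa_eff Effective pKa of released FFAs. Long-chain fatty acids
#'   at an emulsion interface titrate well above the aqueous monomer value;
#'   default 7.5.
#' @param lag_s Delay in seconds before enzyme addition takes effect.
#' @return An object of class `lipolysis_kinetics`; carries the remaining
#'   pool (`remaining_moles`) and internal elapsed time, updated by
#'   [release_ffa()].
#' @seealso [oil_ffa_pool()]
#' @export
lipolysis_kinetics <- function(releasable_ffa_moles0, rate_constant,
                               ffa_pKa_eff = 7.5, lag_s = 0) {
  for (v in c(releasable_ffa_moles0, rate_constant, ffa_pKa_eff, lag_s)) {
    if (!is.finite(v) || v < 0) {
      stop("all kinetics parameters must be finite and >= 0", call. = FALSE)
    }
  }
  structure(list(releasable_ffa_moles0 = releasable_ffa_moles0,
                 rate_constant = rate_constant,
                 ffa_pKa_eff = ffa_pKa_eff,
                 lag_s = lag_s,
                 remaining_moles = releasable_ffa_moles0,
                 elapsed_s = 0),
            class = "lipolysis_kinetics")
}

#' Hydrolyzable FFA pool of a weighed oil sample
#'
#' @param W_lipid_g Oil mass in grams.
#' @param M_lipid Mean triglyceride molar mass in g/mol (default 885,
#'   triolein, representative of olive oil).
#' @return Moles of releasable FFA, `2 * W / M`.
#' @export
oil_ffa_pool <- function(W_lipid_g, M_lipid = 885) {
  stopifnot(W_lipid_g >= 0, M_lipid > 0)
  2 * W_lipid_g / M_lipid
}

#' Advance lipolysis by a time step
#'
#' Moves FFA moles from the remaining hydrolyzable pool into the solution
#' (species `"FFA"`, monoprotic at `ffa_pKa_eff`). `dt = 0` or a zero rate
#' constant are identities; released moles never exceed the initial pool.
#'
#' @param state A [solution_state()].
#' @param kinetics A [lipolysis_kinetics()] (tracks remaining pool and
#'   elapsed time).
#' @param dt Time step in seconds (>= 0).
#' @return A list with updated `state` and `kinetics`.
#' @export
release_ffa <- function(state, kinetics, dt) {
  stopifnot(inherits(state, "solution_state"),
            inherits(kinetics, "lipolysis_kinetics"))
  if (!is.finite(dt) || dt < 0) stop("'dt' must be >= 0", call. = FALSE)
  t0 <- kinetics$elapsed_s
  t1 <- t0 + dt
  dt_eff <- max(0, t1 - max(t0, kinetics$lag_s))
  released <- kinetics$remaining_moles *
    (1 - exp(-kinetics$rate_constant * dt_eff))
  kinetics$remaining_moles <- kinetics$remaining_moles - released
  kinetics$elapsed_s <- t1
  if (released > 0) {
    ffa <- state$acids[["FFA"]]
    if (is.null(ffa)) {
      ffa <- acid_species("FFA", released, kinetics$ffa_pKa_eff)
    } else {
      ffa$total_moles <- ffa$total_moles + released
    }
    state$acids[["FFA"]] <- ffa
  }
  list(state = state, kinetics = kinetics)
}

#' @export
print.solution_state <- function(x, ...) {
  cat(sprintf("<solution_state> %.4g L, pH %.3f\n", x$volume_L, solve_ph(x)))
  for (a in x$acids) {
    cat(sprintf("  acid %-10s %.4g mol (pKa %s)\n", a$name, a$total_moles,
                paste(a$pKa, collapse = "/")))
  }
  cat(sprintf("  strong base %.4g mol, strong acid %.4g mol, fixed charge %+.4g mol\n",
              x$strong_base_moles, x$strong_acid_moles, x$fixed_ion_charge))
  invisible(x)
}
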