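# Post-experiment computation: %FFA from the dosed NaOH volume, release
# curves, endpoint detection, and first-order rate-constant recovery.

#' Lipolysis assay constants
#'
#' Constants of the free-fatty-acid calculation: the titrant normality, the
#' mean triglyceride molar mass of the oil, and the oil mass in the
#' reaction. Units at this boundary are litres (NaOH volume), grams (oil)
#' and g/mol, regardless of the uL/mL mixture used elsewhere.
#'
#' @param W_lipid Total oil mass in the reaction, grams.
#' @param N_NaOH Titrant normality, eq/L (default 0.1).
#' @param M_lipid Mean triglyceride molar mass, g/mol (default 885,
#'   triolein).
#' @return An object of class `lipolysis_assay`.
#' @export
lipolysis_assay <- function(W_lipid, N_NaOH = 0.1, M_lipid = 885) {
  for (v in c(W_lipid, N_NaOH, M_lipid)) {
    if (!is.finite(v) || v <= 0) {
      stop("assay constants must be finite and > 0", call. = FALSE)
    }
  }
  structure(list(N_NaOH = N_NaOH, M_lipid = M_lipid, W_lipid = W_lipid),
            class = "lipolysis_assay")
}

#' Percent free fatty acids released
#'
#' `%FFA = 100 * V_NaOH * N_NaOH * M_lipid / (W_lipid * 2)`: the dosed base
#' equivalents counted against the two FFAs that intestinal lipolysis can
#' release per triglyceride.
#'
#' @param V_NaOH_L Total NaOH volume dosed, litres (vectorised, >= 0).
#' @param assay A [lipolysis_assay()].
#' @return Percent FFA released (same length as `V_NaOH_L`).
#' @examples
#' percent_ffa(2e-3, lipolysis_assay(W_lipid = 0.35))  # 25.29 %
#' @export
percent_ffa <- function(V_NaOH_L, assay) {
  stopifnot(inherits(assay, "lipolysis_assay"))
  if (any(!is.finite(V_NaOH_L)) || any(V_NaOH_L < 0)) {
    stop("'V_NaOH_L' must be >= 0", call. = FALSE)
  }
  100 * V_NaOH_L * assay$N_NaOH * assay$M_lipid / (assay$W_lipid * 2)
}

#' FFA release curve from a titration log
#'
#' Applies [percent_ffa()] pointwise to the cumulative dispensed volume, so
#' the curve is non-decreasing by construction. Values above 100% are
#' permitted but flagged with a warning (they indicate inconsistent assay
#' constants, e.g. an underestimated oil mass).
#'
#' @param log A [titration_log()] with the cumulative volume column.
#' @param assay A [lipolysis_assay()].
#' @return A data.frame of class `ffa_curve` with columns `t_s` and
#'   `percent_ffa`.
#' @export
ffa_curve <- function(log, assay) {
  stopifnot(inherits(log, "titration_log"))
  if (is.null(log$records$cum_volume_uL)) {
    stop("log has no cumulative volume column", call. = FALSE)
  }
  pct <- percent_ffa(log$records$cum_volume_uL * 1e-6, assay)
  if (any(pct > 100)) {
    warning("%FFA exceeds 100%: check the assay constants (W_lipid, M_lipid)",
            call. = FALSE)
  }
  structure(data.frame(t_s = log$records$t_s, percent_ffa = pct),
            class = c("ffa_curve", "data.frame"))
}

#' Locate the titration endpoint in a log
#'
#' The endpoint can only be found after the fact, from the stored data: it
#' is the earliest time `t` such that over `(t, t + window_s]` no aliquot is
#' dosed and the recorded pH stays within `band_pH` (constant pH without
#' further NaOH addition; a dose exactly at `t` marks the quiet window's
#' start, matching the controller's own stability rule). The log must extend
#' at least `window_s` beyond `t`; otherwise `NA` is returned.
#'
#' @param log A [titration_log()].
#' @param window_s Quiet-window length, seconds (default 600, i.e. pH stable
#'   over 10 min).
#' @param band_pH Maximum pH spread inside the window (default 0.02).
#' @return The endpoint time in seconds, or `NA` if no qualifying window
#'   exists.
#' @export
detect_endpoint <- function(log, window_s = 600, band_pH = 0.02) {
  stopifnot(inherits(log, "titration_log"))
  r <- log$records
  n <- nrow(r)
  if (!n) return(NA_real_)
  dose_t <- r$t_s[c(FALSE, diff(r$aliquots) > 0)]
  if (n > 0 && r$aliquots[1] > 0) dose_t <- c(r$t_s[1], dose_t)
  t_end <- r$t_s[n]
  jr <- 1L
  for (il in seq_len(n)) {
    t0 <- r$t_s[il]
    if (t0 + window_s > t_end) return(NA_real_)  # window would overrun the log
    if (any(dose_t > t0 & dose_t <= t0 + window_s)) next
    if (jr < il) jr <- il
    while (jr < n && r$t_s[jr + 1L] <= t0 + window_s) jr <- jr + 1L
    win <- r$pH[il:jr]
    if (max(win) - min(win) <= band_pH) return(t0)
  }
  NA_real_
}

#' Recover the first-order release rate constant from an FFA curve
#'
#' Least-squares fit of the saturating exponential `A (1 - exp(-k t))` to
#' the curve (Levenberg-Marquardt via [minpack.lm::nlsLM()]), quantifying
#' the rate and extent of FFA release. Starting values come from the curve
#' itself: the plateau from the final values, the rate from the time of
#' half-plateau crossing.
#'
#' @param curve An [ffa_curve()], or any data.frame with `t_s` and
#'   `percent_ffa` columns, with at least 5 distinct time points.
#' @return A list with `rate_constant` (1/s), `plateau` (%FFA) and the
#'   underlying `fit` object.
#' @section Degenerate input: a flat curve carries no rate information; an
#'   error of class `phstatsim_no_fit` is signalled.
#' @export
recover_rate_constant <- function(curve) {
  t <- curve$t_s
  y <- curve$percent_ffa
  if (is.null(t) || is.null(y) || length(unique(t)) < 5L) {
    stop("need at least 5 distinct curve points", call. = FALSE)
  }
  A0 <- max(y)
  if (!is.finite(A0) || A0 <= 0 || (max(y) - min(y)) < 1e-12) {
    stop(structure(class = c("phstatsim_no_fit", "error", "condition"),
                   list(message = "flat curve: no rate information",
                        call = sys.call())))
  }
  t_half <- suppressWarnings(min(t[y >= A0 / 2 & t > 0]))
  k0 <- if (is.finite(t_half) && t_half > 0) log(2) / t_half else 1 / max(t)
  fit <- minpack.lm::nlsLM(
    y ~ A * (1 - exp(-k * t)),
    start = list(A = A0, k = k0),
    lower = c(A = 0, k = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  list(rate_constant = unname(co["k"]), plateau = unname(co["A"]), fit = fit)
}
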