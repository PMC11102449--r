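#' Create the humoral state
#'
#' Holds the spatially global (well-mixed) quantities of the model: the
#' adenosine level `Ad`, the hypoxia-inhibitor concentration `px`, the raw
#' adenosine-inhibitor concentration `s_raw`, the length-`M` history buffer of
#' `s_raw`, and the moving-average output `S_t` (the adhesion-filtered drug
#' level that acts in the tumor area). All start at zero; the buffer is
#' zero-padded, so `S_t` is the mean of the last `M` samples with zeros before
#' the history fills.
#'
#' @param M Moving-average window length (steps).
#' @return A list of class `"tme_humoral"`.
#' @export
new_humoral_state <- function(M) {
  M <- as.integer(M)
  if (M < 1) stop("'M' must be >= 1")
  structure(
    list(Ad = 0, px = 0, s_raw = 0, s_buf = numeric(M), s_pos = 1L, S_t = 0),
    class = "tme_humoral"
  )
}

#' Advance the hypoxia-inhibitor concentration by one step
#'
#' Bolus-decay pharmacokinetics integrated by forward Euler with the time
#' unit equal to one simulation step: on a dose step the bolus is added
#' first, then one decay step `px <- px * (1 - eta)` is applied.
#'
#' @param state A `"tme_humoral"` state.
#' @param is_dose_step Logical; whether a bolus is injected this step.
#' @param params Model parameters (`eta`, `dose_px`).
#' @param dose Bolus magnitude; defaults to `params$dose_px` (40).
#' @return The updated state.
#' @export
step_px <- function(state, is_dose_step = FALSE, params, dose = params$dose_px) {
  if (is_dose_step) state$px <- state$px + dose
  state$px <- state$px * (1 - params$eta)
  state
}

#' Advance the adenosine-inhibitor concentration by one step
#'
#' As [step_px()] but with elimination rate `lambda_s` and bolus `dose_s`
#' (4200). The raw concentration is then appended to the length-`M` history
#' buffer and the moving-average output `S_t` is recomputed as the buffer
#' mean; `S_t` models the adhesive accumulation of the drug in the tumor
#' area.
#'
#' @inheritParams step_px
#' @param dose Bolus magnitude; defaults to `params$dose_s`.
#' @return The updated state (fields `s_raw`, `s_buf`, `s_pos`, `S_t`).
#' @export
step_s <- function(state, is_dose_step = FALSE, params, dose = params$dose_s) {
  if (is_dose_step) state$s_raw <- state$s_raw + dose
  state$s_raw <- state$s_raw * (1 - params$lambda_s)
  M <- length(state$s_buf)
  state$s_buf[state$s_pos] <- state$s_raw
  state$s_pos <- state$s_pos %% M + 1L
  state$S_t <- sum(state$s_buf) / M
  state
}

#' Advance the adenosine level by one step
#'
#' Forward-Euler step of the global adenosine balance: basal production
#' `beta`, hypoxia-driven production `a / (U_eff + c)`, first-order
#' elimination at rate `r`, and inhibition `gamma * S_t * Ad` by the
#' adhesion-filtered adenosine-inhibitor drug. The result is clamped at zero.
#' `U_eff` is the effective oxygen seen by the (global) adenosine pool; the
#' engine uses the mean oxygen over tumor sites and their Moore neighbors.
#'
#' The fixed point for constant `U_eff` and `S_t` is
#' `Ad* = (beta + a / (U_eff + c)) / (r + gamma * S_t)`, to which iteration
#' converges monotonically from zero at the default rates; the fixed point
#' does not depend on the Euler step `dt`.
#'
#' The adenosine balance evolves on the daily timescale (its rates are per
#' day) while the lattice advances in `dt_minutes` steps, so the engine
#' integrates it with `dt = dt_minutes / 1440` (1/720 day per step at the
#' default 2-minute step); see [adenosine_dt()]. The default `dt = 1` gives
#' one full Euler step in the ODE's own time unit.
#'
#' @param state A `"tme_humoral"` state.
#' @param U_eff Effective oxygen concentration (>= 0).
#' @param params Model parameters (`beta`, `a`, `c`, `r`, `gamma`).
#' @param dt Euler step in the ODE's time unit (default 1).
#' @return The updated state.
#' @export
step_adenosine <- function(state, U_eff, params, dt = 1) {
  if (U_eff < 0) stop("'U_eff' must be non-negative")
  if (dt <= 0) stop("'dt' must be positive")
  Ad <- state$Ad
  Ad <- Ad + (params$beta + params$a / (U_eff + params$c) -
                params$r * Ad - params$gamma * state$S_t * Ad) * dt
  state$Ad <- max(Ad, 0)
  state
}

#' Adenosine Euler step per lattice step
#'
#' The conversion between the lattice clock (`dt_minutes` per step) and the
#' adenosine ODE's daily time unit: `dt_minutes / 1440` days per step (1/720
#' at the default 2-minute step). The engine advances the adenosine balance
#' by this fraction of a day every lattice step, so adenosine accumulates
#' over days rather than equilibrating within the first simulated hour.
#'
#' @param params Model parameters.
#' @return Days of adenosine time per lattice step.
#' @export
adenosine_dt <- function(params) {
  params$dt_minutes / 1440
}

#' Closed-form adenosine steady state
#'
#' `Ad* = (beta + a / (U_eff + c)) / (r + gamma * S_t)`, the fixed point of
#' [step_adenosine()] for constant effective oxygen and filtered inhibitor
#' level.
#'
#' @inheritParams step_adenosine
#' @param S_t Filtered inhibitor level.
#' @return Steady-state adenosine level.
#' @export
adenosine_steady_state <- function(U_eff, S_t = 0, params) {
  (params$beta + params$a / (U_eff + params$c)) / (params$r + params$gamma * S_t)
}
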