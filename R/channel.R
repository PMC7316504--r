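# Frequency-sensing Markov channel: a two-state (open/closed) pore gated by
# voltage, deactivated by a slow catalytic agent a that accumulates while the
# membrane sits in a plateau-voltage window. The channel conducts only when
# all n identical subunits are open, so the current scales as O^n.

#' Parameters of the frequency-sensing (BioICD) channel
#'
#' Defaults reproduce the published Model I design: maximal conductance
#' 150 nS/pF, non-selective pore (reversal 0 mV), n = 8 subunits, opening
#' above -60 mV, characteristic times of 1400 ms for both the open fraction
#' and the catalytic deactivation agent, and a catalysed closing rate
#' `k_oc + 2e4 * a1^5` representing non-cooperative binding of five catalyst
#' molecules. The catalyst accumulates while the membrane potential lies in
#' the plateau window (-55, 0) mV and otherwise decays fast (rate 200,
#' e-fold time 7 ms).
#'
#' @param g_max maximal conductance density (nS/pF).
#' @param e_rev reversal potential (mV).
#' @param n_subunits number of identical subunits; the current scales as
#'   `O^n_subunits`.
#' @param tau_o,tau_a characteristic times (ms) of the open fraction and the
#'   catalytic agent.
#' @param k_oc_catalysis_scale scale of the catalysed closing rate.
#' @param catalyst_power exponent on `a1` in the catalysed closing rate.
#' @param v_gate opening/closing threshold voltage (mV).
#' @param v_cat_low,v_cat_high bounds (mV) of the catalyst accumulation
#'   window.
#' @param k_co_on,k_oc_base,k01_on,k10_off dimensionless rate values of the
#'   piecewise-constant voltage dependence.
#' @return An object of class `bioicd_params` (a named list).
#' @export
bioicd_params <- function(g_max = 150, e_rev = 0, n_subunits = 8L,
                          tau_o = 1400, tau_a = 1400,
                          k_oc_catalysis_scale = 2e4, catalyst_power = 5L,
                          v_gate = -60, v_cat_low = -55, v_cat_high = 0,
                          k_co_on = 1, k_oc_base = 7, k01_on = 1,
                          k10_off = 200) {
  p <- list(g_max = g_max, e_rev = e_rev, n_subunits = as.integer(n_subunits),
            tau_o = tau_o, tau_a = tau_a,
            k_oc_catalysis_scale = k_oc_catalysis_scale,
            catalyst_power = as.integer(catalyst_power), v_gate = v_gate,
            v_cat_low = v_cat_low, v_cat_high = v_cat_high,
            k_co_on = k_co_on, k_oc_base = k_oc_base, k01_on = k01_on,
            k10_off = k10_off)
  validate_bioicd_params(p)
  structure(p, class = "bioicd_params")
}

validate_bioicd_params <- function(p) {
  stopifnot(p$g_max >= 0, p$tau_o > 0, p$tau_a > 0, p$n_subunits >= 1L,
            p$catalyst_power >= 1L, p$v_cat_low < p$v_cat_high,
            p$k_co_on >= 0, p$k_oc_base >= 0, p$k01_on >= 0, p$k10_off >= 0)
  invisible(p)
}

#' Initial channel state
#'
#' Both the open fraction and the active-catalyst fraction start at zero: at
#' the resting potential the voltage-dependent rates drive `O` and `a1` to 0,
#' so this is the channel's rest state.
#'
#' @param o open fraction in \[0, 1\].
#' @param a1 active-catalyst fraction in \[0, 1\].
#' @return An object of class `bioicd_state`.
#' @export
bioicd_init <- function(o = 0, a1 = 0) {
  stopifnot(is.finite(o), is.finite(a1), o >= 0, o <= 1, a1 >= 0, a1 <= 1)
  structure(list(o = o, a1 = a1), class = "bioicd_state")
}

#' Piecewise-constant gating rates
#'
#' Opening (`k_co`) switches on above `v_gate`; the base closing rate
#' (`k_oc`) switches off there. Catalyst activation (`k01`) is confined to
#' the open window `(v_cat_low, v_cat_high)`; outside it the catalyst decays
#' at `k10`. Inequalities are strict as specified; at exact threshold
#' equality the "otherwise" branch applies.
#'
#' @param v membrane potential (mV), vectorized.
#' @param params a [bioicd_params()] object.
#' @return A list with numeric components `k_co`, `k_oc`, `k01`, `k10`.
#' @export
bioicd_rates <- function(v, params = bioicd_params()) {
  if (any(!is.finite(v))) stop("invalid input: non-finite membrane potential")
  below <- v < params$v_gate
  win <- v > params$v_cat_low & v < params$v_cat_high
  list(k_co = ifelse(below, 0, params$k_co_on),
       k_oc = ifelse(below, params$k_oc_base, 0),
       k01 = ifelse(win, params$k01_on, 0),
       k10 = ifelse(win, 0, params$k10_off))
}

#' Effective closing rate with catalysis
#'
#' Adds the catalysed flow `k_oc_catalysis_scale * a1^catalyst_power` to the
#' base closing rate, the reduced form of the catalyst-binding Markov chain.
#'
#' @param k_oc base closing rate.
#' @param a1 active-catalyst fraction in \[0, 1\], vectorized.
#' @param params a [bioicd_params()] object.
#' @return Effective closing rate (dimensionless).
#' @export
bioicd_koc_eff <- function(k_oc, a1, params = bioicd_params()) {
  if (any(!is.finite(a1)) || any(a1 < 0) || any(a1 > 1))
    stop("invalid state: a1 must lie in [0, 1]")
  k_oc + params$k_oc_catalysis_scale * a1^params$catalyst_power
}

#' Advance the channel state one time step
#'
#' For a voltage held over the step, both state ODEs are linear in their own
#' variable (with `a1` frozen while updating `O`, and `V` frozen while
#' updating `a1`), so the default update applies the exact exponential
#' relaxation towards each variable's momentary steady state. This keeps `O`
#' and `a1` in \[0, 1\] for any step size. A plain forward-Euler update is
#' available for cross-checking.
#'
#' @param state a [bioicd_init()] state.
#' @param v membrane potential (mV) held over the step.
#' @param dt step size (ms), > 0.
#' @param params a [bioicd_params()] object.
#' @param method `"exponential"` (default, unconditionally bounded) or
#'   `"euler"`.
#' @return The advanced `bioicd_state`.
#' @export
bioicd_step <- function(state, v, dt, params = bioicd_params(),
                        method = c("exponential", "euler")) {
  method <- match.arg(method)
  if (!is.finite(dt) || dt <= 0) stop("invalid input: dt must be positive")
  r <- bioicd_rates(v, params)
  koc_eff <- bioicd_koc_eff(r$k_oc, state$a1, params)
  ko <- r$k_co + koc_eff
  ka <- r$k01 + r$k10
  if (method == "exponential") {
    o_inf <- if (ko > 0) r$k_co / ko else state$o
    a_inf <- if (ka > 0) r$k01 / ka else state$a1
    o <- o_inf + (state$o - o_inf) * exp(-ko * dt / params$tau_o)
    a1 <- a_inf + (state$a1 - a_inf) * exp(-ka * dt / params$tau_a)
  } else {
    o <- state$o + dt * (r$k_co * (1 - state$o) - koc_eff * state$o) / params$tau_o
    a1 <- state$a1 + dt * (r$k01 * (1 - state$a1) - r$k10 * state$a1) / params$tau_a
  }
  bioicd_init(o = o, a1 = a1)
}

#' Channel current density
#'
#' `g_max * O^n * (V - E_rev)` in pA/pF. Under the monodomain sign
#' convention (ionic current subtracted from dV/dt) the current is
#' depolarizing (negative) whenever `V < e_rev` and the channel is open.
#'
#' @param state a [bioicd_init()] state (or any list with an `o` field).
#' @param v membrane potential (mV).
#' @param params a [bioicd_params()] object.
#' @return Current density (pA/pF).
#' @export
bioicd_current <- function(state, v, params = bioicd_params()) {
  stopifnot(state$o >= 0, state$o <= 1)
  params$g_max * state$o^params$n_subunits * (v - params$e_rev)
}

#' @export
print.bioicd_params <- function(x, ...) {
  cat("Frequency-sensing channel parameters:\n")
  cat(sprintf("  g_max %.4g nS/pF, e_rev %.4g mV, n = %d subunits\n",
              x$g_max, x$e_rev, x$n_subunits))
  cat(sprintf("  tau_o = tau_a = %.4g ms, catalysed closing %.3g * a1^%d\n",
              x$tau_o, x$k_oc_catalysis_scale, x$catalyst_power))
  cat(sprintf("  gate threshold %.4g mV, catalyst window (%.4g, %.4g) mV\n",
              x$v_gate, x$v_cat_low, x$v_cat_high))
  invisible(x)
}
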