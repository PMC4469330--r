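#' Full mass-action state of the carrier cycle
#'
#' Builds the explicit six-state (2 + 2 per substrate) mass-action system
#' corresponding to an \code{\link{assay_state}} and
#' \code{\link{carrier_params}}: free carrier at each face, one
#' carrier-substrate complex per substrate per face, and the free substrate
#' pools. Binding is explicit (\code{k_on}, \code{k_off = k_on * K}), loaded
#' complexes translocate at rate \code{d}, the empty carrier at \code{h * d}.
#' The total carrier amount is chosen as \code{T = V * v_in / d} so that the
#' system reduces to the quasi-steady-state flux law with the same effective
#' \code{V} in the fast-binding limit.
#'
#' Used as the validation oracle for the quasi-steady-state reduction:
#' agreement is expected (and asserted) only in the fast-binding regime,
#' operationalized as \code{k_off >= 1000 * d} for every substrate.
#'
#' @param state an \code{\link{assay_state}}.
#' @param params a \code{\link{carrier_params}}; substrates with infinite K
#'   are not representable here and are rejected.
#' @param d loaded-carrier translocation rate, 1/min.
#' @param k_on association rate constant, 1/(uM min), shared by all
#'   substrates (\code{k_off} then differs through K).
#' @return An object of class \code{"full_kinetic_state"}.
#' @export
full_kinetic_state <- function(state, params, d = 1000, k_on = NULL) {
  subs <- rownames(state$conc)
  K <- params$K[subs]
  if (any(!is.finite(K)))
    stop("infinite K has no finite mass-action representation")
  if (!is.finite(d) || d <= 0) stop("'d' must be > 0")
  if (is.null(k_on)) k_on <- 1e4 * d / min(K)   # comfortably fast binding
  if (!is.finite(k_on) || k_on <= 0) stop("'k_on' must be > 0")
  T_amt <- params$V * state$v_in / d
  structure(list(state = state, subs = subs, K = K,
                 k_on = rep_len(k_on, length(subs)),
                 k_off = rep_len(k_on, length(subs)) * K,
                 d = d, h = params$h, T_amt = T_amt,
                 X_I = T_amt / 2, X_II = T_amt / 2,
                 SX_I = stats::setNames(rep(0, length(subs)), subs),
                 SX_II = stats::setNames(rep(0, length(subs)), subs)),
            class = "full_kinetic_state")
}

## Mass-action RHS. Carrier species in amounts (uM*ul); pools in uM.
.mass_action_rhs <- function(t, y, p) {
  ns <- p$ns
  X_I <- y[1L]; X_II <- y[2L]
  SX_I <- y[2L + seq_len(ns)]
  SX_II <- y[2L + ns + seq_len(ns)]
  C_I <- pmax(y[2L + 2L * ns + seq_len(ns)], 0)
  C_II <- pmax(y[2L + 3L * ns + seq_len(ns)], 0)
  bind_I <- p$k_on * C_I * X_I - p$k_off * SX_I      # amount/min
  bind_II <- p$k_on * C_II * X_II - p$k_off * SX_II
  trans <- p$d * (SX_I - SX_II)                      # loaded, net I -> II
  empty <- p$h * p$d * (X_I - X_II)                  # empty, net I -> II
  dX_I <- -sum(bind_I) - empty
  dX_II <- -sum(bind_II) + empty
  dSX_I <- bind_I - trans
  dSX_II <- bind_II + trans
  dC_I <- -bind_I / p$v_out
  dC_II <- -bind_II / p$v_in
  list(c(dX_I, dX_II, dSX_I, dSX_II, dC_I, dC_II))
}

#' Integrate the full mass-action carrier cycle
#'
#' Exact reference integration of the explicit binding + translocation
#' system. Conserves total carrier and, per chemical species, free pool +
#' complexed amounts. Serves as the independent oracle against which the
#' quasi-steady-state \code{\link{simulate_uptake}} is validated.
#'
#' @param full a \code{\link{full_kinetic_state}}.
#' @param times output times, minutes, starting at 0, strictly increasing.
#' @param rtol,atol integrator tolerances (the binding reactions make the
#'   system stiff; lsoda switches automatically).
#' @return A \code{"carrier_timecourse"} whose \code{conc} array holds the
#'   free pools, with an extra \code{carrier} element (matrix of carrier
#'   amounts per time: \code{X_I}, \code{X_II} and the complexes).
#' @export
full_ode_oracle <- function(full, times, rtol = 1e-10, atol = 1e-12) {
  times <- .check_times(times)
  ns <- length(full$subs)
  y0 <- c(full$X_I, full$X_II, full$SX_I, full$SX_II,
          full$state$conc[, "I"], full$state$conc[, "II"])
  p <- list(ns = ns, k_on = full$k_on, k_off = full$k_off, d = full$d,
            h = full$h, v_in = full$state$v_in, v_out = full$state$v_out)
  sol <- deSolve::lsoda(y0, times, .mass_action_rhs, p,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1L] < 0)
    stop("mass-action integration failed (lsoda istate = ", diagn[1L], ")")
  if (nrow(sol) < length(times))
    stop("mass-action integration stopped early at t = ", sol[nrow(sol), 1L])
  conc <- array(NA_real_, dim = c(length(times), ns, 2L),
                dimnames = list(NULL, full$subs, c("I", "II")))
  conc[, , 1L] <- pmax(sol[, 2L + 2L * ns + seq_len(ns) + 1L, drop = FALSE], 0)
  conc[, , 2L] <- pmax(sol[, 2L + 3L * ns + seq_len(ns) + 1L, drop = FALSE], 0)
  carrier <- sol[, 1L + seq_len(2L + 2L * ns), drop = FALSE]
  colnames(carrier) <- c("X_I", "X_II",
                         paste0(full$subs, "X_I"), paste0(full$subs, "X_II"))
  structure(list(times = times, conc = conc,
                 v_in = full$state$v_in, v_out = full$state$v_out,
                 params = carrier_params(full$d * full$T_amt /
                                           full$state$v_in,
                                         full$h, full$K),
                 carrier = carrier),
            class = "carrier_timecourse")
}
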