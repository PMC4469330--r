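#' Kinetic parameters of a symmetric amino acid carrier
#'
#' Bundles the three quantities that determine carrier-cycle transport: the
#' effective maximal transport rate \code{V}, the relative mobility of the
#' unbound carrier \code{h}, and one dissociation constant per substrate.
#'
#' \code{V} is expressed on the intravesicular-concentration scale
#' (\eqn{V \equiv D T / V_{in}}, in uM/min), so that the intravesicular
#' concentration of substrate \eqn{s} obeys
#' \deqn{dc_{s,II}/dt = V (\theta_I p_{s,I} - \theta_{II} p_{s,II}).}
#' \code{h} is the ratio of the empty-carrier to the loaded-carrier
#' translocation rate: \code{h = 0} is an obligate (1:1) exchanger, \code{h >
#' 0} adds a facilitated (uniporter) component. Labeled and unlabeled pools
#' of the same chemical species share one \code{K}; carrier saturation
#' depends on their sum.
#'
#' @param V effective maximal transport rate, uM/min (> 0).
#' @param h relative mobility of the unbound carrier, dimensionless (>= 0).
#' @param K named numeric vector of dissociation constants, uM (> 0, may be
#'   \code{Inf} for a non-substrate). Names are substrate ids.
#' @return An object of class \code{"carrier_params"}.
#' @examples
#' carrier_params(V = 92, h = 0.04, K = c(tracer = 1129, serine = 1129))
#' @export
carrier_params <- function(V, h, K) {
  stopifnot(is.numeric(V), length(V) == 1L, is.numeric(h), length(h) == 1L,
            is.numeric(K), length(K) >= 1L)
  if (is.null(names(K)) || any(!nzchar(names(K))))
    stop("'K' must be a named vector of per-substrate dissociation constants")
  if (!is.finite(V) || V <= 0) stop("'V' must be a positive finite rate")
  if (is.na(h) || h < 0) stop("'h' must be >= 0")
  if (any(is.na(K)) || any(K <= 0)) stop("all 'K' must be > 0")
  structure(list(V = as.numeric(V), h = as.numeric(h),
                 K = stats::setNames(as.numeric(K), names(K))),
            class = "carrier_params")
}

#' @export
print.carrier_params <- function(x, ...) {
  cat("Carrier parameters\n")
  cat(sprintf("  V = %g uM/min, h = %g%s\n", x$V, x$h,
              if (x$h == 0) " (obligate exchange)" else ""))
  cat("  K (uM):", paste(sprintf("%s = %g", names(x$K), x$K), collapse = ", "),
      "\n")
  invisible(x)
}

#' Two-compartment assay state
#'
#' Concentrations of every substrate pool at the two membrane faces:
#' face I is extravesicular, face II intravesicular. The tracer is an
#' ordinary substrate row; it is distinguished from the unlabeled pool of the
#' same species only by its id.
#'
#' @param conc numeric matrix, one row per substrate (rownames are substrate
#'   ids), columns \code{"I"} (extravesicular) and \code{"II"}
#'   (intravesicular), in uM.
#' @param v_in intravesicular volume, ul (> 0).
#' @param v_out extravesicular volume, ul (> 0).
#' @return An object of class \code{"assay_state"}.
#' @examples
#' assay_state(rbind(tracer = c(7.5, 0), serine = c(250, 1000)),
#'             v_in = 0.26, v_out = 69.74)
#' @export
assay_state <- function(conc, v_in, v_out) {
  conc <- as.matrix(conc)
  if (ncol(conc) != 2L) stop("'conc' needs two columns: faces I and II")
  colnames(conc) <- c("I", "II")
  if (is.null(rownames(conc))) stop("'conc' rows must be named by substrate")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (!is.finite(v_in) || v_in <= 0) stop("'v_in' must be > 0")
  if (!is.finite(v_out) || v_out <= 0) stop("'v_out' must be > 0")
  structure(list(conc = conc, v_in = as.numeric(v_in),
                 v_out = as.numeric(v_out)),
            class = "assay_state")
}

#' Swap the two faces of an assay state
#'
#' Utility for symmetry checks: exchanges extravesicular and intravesicular
#' concentrations and volumes.
#'
#' @param state an \code{\link{assay_state}}.
#' @return The mirrored \code{assay_state}.
#' @export
swap_faces <- function(state) {
  assay_state(state$conc[, c(2L, 1L), drop = FALSE],
              v_in = state$v_out, v_out = state$v_in)
}

#' Rapid-equilibrium carrier occupancy at one membrane face
#'
#' Under the rapid-binding assumption the fraction of carrier at a face that
#' is bound to substrate \eqn{s} is
#' \deqn{p_s = (c_s/K_s) / (1 + \sum_j c_j/K_j),}
#' with free fraction \eqn{p_0 = 1/(1 + \sum_j c_j/K_j)}. The fractions sum
#' to one exactly.
#'
#' @param conc named numeric vector of concentrations at the face, uM.
#' @param K named numeric vector of dissociation constants, uM; must cover
#'   every substrate in \code{conc}. \code{Inf} marks a non-substrate.
#' @return A list of class \code{"face_occupancy"} with elements \code{p}
#'   (named bound fractions), \code{p0} (free fraction) and \code{L} (total
#'   loaded fraction).
#' @examples
#' face_occupancy(c(serine = 1129), K = c(serine = 1129)) # half saturation
#' @export
face_occupancy <- function(conc, K) {
  if (length(conc) && (is.null(names(conc)) || any(!nzchar(names(conc)))))
    stop("'conc' must be named by substrate")
  if (any(is.na(conc)) || any(conc < 0)) stop("concentrations must be >= 0")
  if (any(is.na(K)) || any(K <= 0)) stop("all 'K' must be > 0")
  if (!all(names(conc) %in% names(K)))
    stop("missing dissociation constant for: ",
         paste(setdiff(names(conc), names(K)), collapse = ", "))
  r <- conc / K[names(conc)]            # c/K; Inf K -> 0 occupancy
  den <- 1 + sum(r)
  p <- r / den
  structure(list(p = p, p0 = 1 / den, L = sum(p)), class = "face_occupancy")
}

#' Quasi-steady-state carrier distribution between the two faces
#'
#' The carrier cycles between the faces; at quasi-steady state the fraction
#' \eqn{\theta_I} facing out and \eqn{\theta_{II}} facing in balance the exit
#' rates \eqn{\theta_I (L_I + h p_{0,I}) = \theta_{II} (L_{II} + h
#' p_{0,II})}, with \eqn{\theta_I + \theta_{II} = 1}. Loaded carrier
#' translocates at the full rate, empty carrier at the fraction \code{h} of
#' it. When both exit rates vanish (\code{h = 0} and no substrate on either
#' face) the split is set to (0.5, 0.5); the flux is zero regardless.
#'
#' @param occ_I,occ_II \code{\link{face_occupancy}} of faces I and II.
#' @param h relative mobility of the unbound carrier (>= 0).
#' @return Numeric vector \code{c(I = theta_I, II = theta_II)} summing to 1.
#' @export
carrier_distribution <- function(occ_I, occ_II, h) {
  if (is.na(h) || h < 0) stop("'h' must be >= 0")
  e_I <- occ_I$L + h * occ_I$p0
  e_II <- occ_II$L + h * occ_II$p0
  den <- e_I + e_II
  if (den == 0) return(c(I = 0.5, II = 0.5))
  c(I = e_II / den, II = e_I / den)
}

#' Net carrier-mediated flux for every substrate
#'
#' Evaluates the quasi-steady-state flux law: the intravesicular
#' concentration of substrate \eqn{s} changes at
#' \deqn{dc_{s,II}/dt = V (\theta_I p_{s,I} - \theta_{II} p_{s,II})}
#' (uM/min), and the extravesicular pool at \eqn{-(v_{in}/v_{out})} times
#' that rate (the same number of molecules spread over the other volume).
#' The law is antisymmetric under swapping the two faces.
#'
#' @param state an \code{\link{assay_state}}.
#' @param params a \code{\link{carrier_params}}.
#' @return A list of class \code{"carrier_flux"}: \code{d_int} (named
#'   uM/min, rate of change at face II), \code{d_ext} (face I), and
#'   \code{theta} (the carrier distribution used).
#' @export
net_flux <- function(state, params) {
  occ_I <- face_occupancy(state$conc[, "I"], params$K)
  occ_II <- face_occupancy(state$conc[, "II"], params$K)
  theta <- carrier_distribution(occ_I, occ_II, params$h)
  d_int <- params$V * (theta[["I"]] * occ_I$p - theta[["II"]] * occ_II$p)
  structure(list(d_int = d_int,
                 d_ext = -(state$v_in / state$v_out) * d_int,
                 theta = theta),
            class = "carrier_flux")
}

## Vectorized pool ODE shared by one or many conditions with a common
## substrate set. y is c(as.vector(C_I), as.vector(C_II)) where C_* are
## (n_cond x n_sub) matrices. Volumes enter only through v_in/v_out per
## condition; recycling of length-n_cond vectors down matrix columns is the
## intended column-major broadcast.
.pool_rhs <- function(t, y, parms) {
  nc <- parms$n_cond
  ns <- parms$n_sub
  half <- nc * ns
  C_I <- matrix(pmax(y[seq_len(half)], 0), nc, ns)
  C_II <- matrix(pmax(y[half + seq_len(half)], 0), nc, ns)
  r_I <- sweep(C_I, 2L, parms$K, "/")
  r_II <- sweep(C_II, 2L, parms$K, "/")
  den_I <- 1 + rowSums(r_I)
  den_II <- 1 + rowSums(r_II)
  p_I <- r_I / den_I
  p_II <- r_II / den_II
  e_I <- (den_I - 1 + parms$h) / den_I    # L + h*p0
  e_II <- (den_II - 1 + parms$h) / den_II
  den_e <- e_I + e_II
  theta_I <- ifelse(den_e > 0, e_II / den_e, 0.5)
  d_II <- parms$V * (theta_I * p_I - (1 - theta_I) * p_II)
  d_I <- -parms$v_ratio * d_II
  list(c(as.vector(d_I), as.vector(d_II)))
}

.check_times <- function(times) {
  if (length(times) < 1L || times[1L] != 0)
    stop("'times' must start at 0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  as.numeric(times)
}

## Integrate many conditions sharing one substrate set as a single stacked
## system (one lsoda call). states: list of assay_state with identical
## substrate rownames. Returns a list of carrier_timecourse.
simulate_states <- function(states, params, times,
                            rtol = 1e-8, atol = 1e-10) {
  times <- .check_times(times)
  subs <- rownames(states[[1L]]$conc)
  for (s in states)
    if (!identical(rownames(s$conc), subs))
      stop("all states must share one substrate set")
  if (!all(subs %in% names(params$K)))
    stop("missing dissociation constant for: ",
         paste(setdiff(subs, names(params$K)), collapse = ", "))
  nc <- length(states)
  ns <- length(subs)
  if (length(times) == 1L)   # degenerate request: the initial state itself
    return(lapply(states, function(s) {
      conc <- array(s$conc, dim = c(1L, ns, 2L),
                    dimnames = list(NULL, subs, c("I", "II")))
      structure(list(times = times, conc = conc, v_in = s$v_in,
                     v_out = s$v_out, params = params),
                class = "carrier_timecourse")
    }))
  y0 <- c(vapply(states, function(s) s$conc[, "I"], numeric(ns)),
          vapply(states, function(s) s$conc[, "II"], numeric(ns)))
  ## vapply gives (ns x nc); transpose to condition-major matrices
  C_I0 <- t(matrix(y0[seq_len(nc * ns)], ns, nc))
  C_II0 <- t(matrix(y0[nc * ns + seq_len(nc * ns)], ns, nc))
  parms <- list(n_cond = nc, n_sub = ns, K = params$K[subs],
                V = params$V, h = params$h,
                v_ratio = vapply(states, function(s) s$v_in / s$v_out,
                                 numeric(1L)))
  sol <- deSolve::lsoda(c(as.vector(C_I0), as.vector(C_II0)), times,
                        .pool_rhs, parms, rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1L] < 0)
    stop("ODE integration failed (lsoda istate = ", diagn[1L],
         ") at V = ", params$V, ", h = ", params$h)
  if (nrow(sol) < length(times))
    stop("ODE integration stopped early at t = ", sol[nrow(sol), 1L],
         " of ", times[length(times)], " min")
  lapply(seq_len(nc), function(i) {
    conc <- array(NA_real_, dim = c(length(times), ns, 2L),
                  dimnames = list(NULL, subs, c("I", "II")))
    for (j in seq_len(ns)) {
      conc[, j, 1L] <- pmax(sol[, 1L + (j - 1L) * nc + i], 0)
      conc[, j, 2L] <- pmax(sol[, 1L + nc * ns + (j - 1L) * nc + i], 0)
    }
    structure(list(times = times, conc = conc,
                   v_in = states[[i]]$v_in, v_out = states[[i]]$v_out,
                   params = params),
              class = "carrier_timecourse")
  })
}

#' Simulate tracer and substrate uptake time courses
#'
#' Integrates the coupled pool equations of the quasi-steady-state carrier
#' model for every substrate in both compartments, from a given initial
#' state. Total amount of each chemical species (uM x ul summed over the two
#' compartments) is conserved to integrator tolerance.
#'
#' @param initial an \code{\link{assay_state}} at t = 0.
#' @param params a \code{\link{carrier_params}}.
#' @param times output times in minutes, starting at 0, strictly increasing.
#' @param rtol,atol relative / absolute integrator tolerances. The defaults
#'   (1e-8, 1e-10 uM) are deliberately tight: the overshoot peak height is
#'   tolerance-sensitive.
#' @return An object of class \code{"carrier_timecourse"}: list with
#'   \code{times}, a \code{conc} array (time x substrate x face, uM),
#'   volumes and the parameters used. Coerce with
#'   \code{\link{as.data.frame.carrier_timecourse}}; extract the
#'   intravesicular trace with \code{\link{intravesicular}}.
#' @examples
#' st <- assay_state(rbind(tracer = c(7.5, 0), serine = c(50, 1000)),
#'                   v_in = 0.26, v_out = 399.74)
#' pp <- carrier_params(92, 0.04, c(tracer = 1129, serine = 1129))
#' tc <- simulate_uptake(st, pp, times = c(0, 0.5, 1, 2, 5, 10))
#' intravesicular(tc, "tracer")
#' @export
simulate_uptake <- function(initial, params, times,
                            rtol = 1e-8, atol = 1e-10) {
  simulate_states(list(initial), params, times, rtol = rtol, atol = atol)[[1L]]
}

#' Intravesicular concentration trace of one substrate
#'
#' @param tc a \code{"carrier_timecourse"}.
#' @param substrate substrate id (default \code{"tracer"}).
#' @return Numeric vector of face-II concentrations (uM) at \code{tc$times}.
#' @export
intravesicular <- function(tc, substrate = "tracer") {
  if (!substrate %in% dimnames(tc$conc)[[2L]])
    stop("no substrate '", substrate, "' in this time course")
  tc$conc[, substrate, "II"]
}

#' Tidy data frame form of a time course
#'
#' Long format matching the on-disk CSV schema: one row per (time,
#' substrate, face), with concentrations in uM and — for the intravesicular
#' face — the equivalent uptake in pmol per mg protein.
#'
#' @param x a \code{"carrier_timecourse"}.
#' @param row.names,optional unused, for the generic.
#' @param condition_id optional condition label column.
#' @param vol_per_mg intravesicular volume per mg protein, ul/mg, used for
#'   the pmol/mg column (default 1.3).
#' @param ... unused.
#' @export
as.data.frame.carrier_timecourse <- function(x, row.names = NULL,
                                             optional = FALSE,
                                             condition_id = NA_character_,
                                             vol_per_mg = 1.3, ...) {
  subs <- dimnames(x$conc)[[2L]]
  out <- expand.grid(time_min = x$times, substrate_id = subs,
                     face = c("I", "II"), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$conc_uM <- as.vector(x$conc)
  out$uptake_pmol_per_mg <- ifelse(out$face == "II",
                                   out$conc_uM * vol_per_mg, NA_real_)
  cbind(condition_id = condition_id, out)
}

#' @export
print.carrier_timecourse <- function(x, ...) {
  cat(sprintf("Carrier time course: %d times (0..%g min), substrates %s\n",
              length(x$times), max(x$times),
              paste(dimnames(x$conc)[[2L]], collapse = ", ")))
  cat(sprintf("  v_in = %g ul, v_out = %g ul\n", x$v_in, x$v_out))
  invisible(x)
}

#' Overshoot summary of an uptake trace
#'
#' An overshoot is a transient accumulation of intravesicular tracer above
#' its final (equilibrium) level: fast exchange against an outward substrate
#' gradient loads the vesicle beyond where the slower facilitated leg
#' eventually relaxes it.
#'
#' @param tc a \code{"carrier_timecourse"} or a plain numeric trace.
#' @param substrate substrate id to summarize (ignored for numeric input).
#' @param threshold relative excess of peak over final value required to
#'   flag an overshoot (default 0.05, i.e. 5 percent).
#' @return List: \code{peak} (uM), \code{peak_time} (min; NA for numeric
#'   input without times), \code{final}, \code{ratio} (peak/final, 1 for an
#'   all-zero trace), \code{is_overshoot}.
#' @examples
#' overshoot_metrics(c(0, 10, 6, 5))
#' @export
overshoot_metrics <- function(tc, substrate = "tracer", threshold = 0.05) {
  if (inherits(tc, "carrier_timecourse")) {
    trace <- intravesicular(tc, substrate)
    times <- tc$times
  } else {
    trace <- as.numeric(tc)
    times <- seq_along(trace)
  }
  if (length(trace) < 3L) stop("need at least 3 points to assess overshoot")
  peak_i <- which.max(trace)
  peak <- trace[peak_i]
  final <- trace[length(trace)]
  ratio <- if (peak == final) 1 else peak / final
  list(peak = peak, peak_time = times[peak_i], final = final,
       ratio = ratio,
       is_overshoot = peak > final * (1 + threshold))
}
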