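#' Specification of a model fit
#'
#' Declares which carrier-model variant is fitted and how. The mixed variant
#' fits (h, V, K); the obligate variant pins h = 0 and instead fits an
#' initial intravesicular unlabeled concentration \code{endo_int} that is
#' added to every condition's nominal preload (endogenous substrate would be
#' present in every preparation). Multistart uses a fixed, deterministic
#' grid of starting points — reproducibility over random exploration.
#'
#' @param variant \code{"mixed"} or \code{"obligate"}.
#' @param multistart number of starting points (default 8).
#' @param weighting \code{"none"} (unweighted least squares, the default) or
#'   \code{"sem"} (inverse-sem-squared weights).
#' @param bounds named list overriding the default box bounds
#'   \code{h} in [0, 10], \code{V} in [0.1, 1e4] uM/min, \code{K} in
#'   [1, 1e5] uM, \code{endo_int} in [0, 1e3] uM.
#' @return A list of class \code{"fit_spec"}.
#' @export
fit_spec <- function(variant = c("mixed", "obligate"), multistart = 8,
                     weighting = c("none", "sem"), bounds = list()) {
  variant <- match.arg(variant)
  weighting <- match.arg(weighting)
  stopifnot(multistart >= 1)
  b <- list(h = c(0, 10), V = c(0.1, 1e4), K = c(1, 1e5),
            endo_int = c(0, 1e3))
  b[names(bounds)] <- bounds
  for (nm in names(b))
    if (length(b[[nm]]) != 2L || b[[nm]][1L] >= b[[nm]][2L])
      stop("invalid bounds for '", nm, "'")
  structure(list(variant = variant, multistart = as.integer(multistart),
                 weighting = weighting, bounds = b),
            class = "fit_spec")
}

## Deterministic multistart grid on the natural scale.
.start_grid <- function(spec) {
  b <- spec$bounds
  base <- if (spec$variant == "mixed")
    expand.grid(h = c(0.02, 0.3), V = c(10, 300), K = c(100, 5000),
                KEEP.OUT.ATTRS = FALSE)
  else
    expand.grid(V = c(10, 300), K = c(100, 5000), endo_int = c(3, 100),
                KEEP.OUT.ATTRS = FALSE)
  m <- spec$multistart
  if (m <= nrow(base)) {
    base[round(seq(1L, nrow(base), length.out = m)), , drop = FALSE]
  } else {
    extra <- m - nrow(base)
    lg <- function(rng, n) exp(seq(log(max(rng[1L], 1e-3)), log(rng[2L]),
                                   length.out = n + 2L))[seq_len(n) + 1L]
    add <- if (spec$variant == "mixed")
      data.frame(h = lg(c(0.005, b$h[2L]), extra), V = lg(b$V, extra),
                 K = lg(b$K, extra))
    else
      data.frame(V = lg(b$V, extra), K = lg(b$K, extra),
                 endo_int = lg(c(0.5, b$endo_int[2L]), extra))
    rbind(base, add)
  }
}

## par: named list with h, V, K (scalar, shared by tracer and unlabeled
## pools) and endo_int. Returns model intravesicular tracer (uM) for each
## dataset row.
.model_at <- function(par, matrix, index) {
  params <- carrier_params(par$V, par$h,
                           c(tracer = par$K, serine = par$K))
  states <- condition_states(matrix, endo_int = par$endo_int)
  tcs <- simulate_states(states, params, c(0, index$times))
  pred <- vapply(tcs, function(tc) intravesicular(tc)[-1L],
                 numeric(length(index$times)))
  pred[cbind(index$time_i, index$cond_i)]
}

## Precompute the (condition, time) lookup joining dataset rows to the
## stacked simulation grid.
.loss_index <- function(dataset, matrix) {
  if (!all(dataset$condition_id %in% matrix$condition_id))
    stop("dataset conditions not in matrix: ",
         paste(setdiff(dataset$condition_id, matrix$condition_id),
               collapse = ", "))
  times <- sort(unique(dataset$time_min))
  if (any(times <= 0)) stop("dataset times must be > 0")
  list(times = times,
       time_i = match(dataset$time_min, times),
       cond_i = match(dataset$condition_id, matrix$condition_id))
}

.loss_weights <- function(dataset, weighting) {
  if (weighting == "none") return(rep(1, nrow(dataset)))
  if (any(!is.finite(dataset$sem)) || any(dataset$sem <= 0))
    stop("inverse-sem weighting needs strictly positive sem values")
  uptake_to_conc(dataset$sem)^-2
}

#' Sum-of-squares loss of a parameter set against an uptake dataset
#'
#' All conditions are fitted simultaneously with a single parameter set:
#' the loss is the (optionally weighted) sum of squared differences between
#' observed mean uptake, converted to intravesicular concentration, and the
#' model's simulated intravesicular tracer, over every (condition, time)
#' pair in the dataset.
#'
#' @param par named list with elements \code{h}, \code{V}, \code{K} and
#'   optionally \code{endo_int} (default 0).
#' @param dataset an \code{"uptake_dataset"}.
#' @param matrix the \code{\link{build_matrix}} condition matrix.
#' @param weighting \code{"none"} or \code{"sem"}.
#' @return SSR in uM^2 (weighted if requested).
#' @export
carrier_loss <- function(par, dataset, matrix, weighting = "none") {
  par$endo_int <- par$endo_int %||% 0
  index <- .loss_index(dataset, matrix)
  obs <- uptake_to_conc(dataset$mean_uptake_pmol_per_mg,
                        matrix$vol_per_mg[1L])
  w <- .loss_weights(dataset, weighting)
  sum(w * (.model_at(par, matrix, index) - obs)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Natural <-> optimizer scale. V, K on log scale (conditioning); h and
## endo_int linear because 0 is on their boundary and meaningful.
.to_opt <- function(par, variant) {
  if (variant == "mixed") c(h = par$h, logV = log(par$V), logK = log(par$K))
  else c(logV = log(par$V), logK = log(par$K), endo_int = par$endo_int)
}

.from_opt <- function(t, variant) {
  if (variant == "mixed")
    list(h = unname(t[1L]), V = exp(unname(t[2L])), K = exp(unname(t[3L])),
         endo_int = 0)
  else
    list(h = 0, V = exp(unname(t[1L])), K = exp(unname(t[2L])),
         endo_int = unname(t[3L]))
}

.opt_bounds <- function(spec) {
  b <- spec$bounds
  if (spec$variant == "mixed")
    list(lower = c(b$h[1L], log(b$V[1L]), log(b$K[1L])),
         upper = c(b$h[2L], log(b$V[2L]), log(b$K[2L])))
  else
    list(lower = c(log(b$V[1L]), log(b$K[1L]), b$endo_int[1L]),
         upper = c(log(b$V[2L]), log(b$K[2L]), b$endo_int[2L]))
}

#' Fit a carrier-model variant to an uptake dataset
#'
#' Bounded Levenberg-Marquardt least squares
#' (\code{\link[minpack.lm]{nls.lm}}) from every point of a fixed multistart
#' grid; the best optimum is returned. Deterministic for a given dataset and
#' spec. A simulation failure at a parameter point yields a large penalty
#' residual (with a warning) so the optimizer stays in bounds rather than
#' aborting.
#'
#' @param dataset an \code{"uptake_dataset"} (means in pmol/mg; fitting is
#'   done on the concentration scale after \code{\link{uptake_to_conc}}).
#' @param matrix the condition matrix the data refer to.
#' @param spec a \code{\link{fit_spec}}.
#' @return An object of class \code{"carrier_fit"}: fitted \code{par}
#'   (h, V, K, endo_int on the natural scale), \code{ssr} (uM^2),
#'   \code{r_squared}, approximate standard errors \code{se}, per-start
#'   diagnostics \code{starts}, \code{best_start}, plus the spec, matrix and
#'   number of observations.
#' @examples
#' \donttest{
#' pp <- carrier_params(92, 0.04, c(tracer = 1129, serine = 1129))
#' m <- build_matrix()
#' ds <- generate_dataset(pp, m, noise = noise_model(cv = 0, floor = 0,
#'                                                   n_replicates = 5))
#' fit_carrier(ds, m, fit_spec("mixed", multistart = 2))
#' }
#' @export
fit_carrier <- function(dataset, matrix, spec = fit_spec()) {
  stopifnot(inherits(spec, "fit_spec"), inherits(matrix, "condition_matrix"))
  if (length(unique(dataset$condition_id)) < 2L ||
      length(unique(dataset$time_min)) < 3L)
    warning("fewer than 2 conditions x 3 time points; ",
            "parameters may be poorly identified")
  index <- .loss_index(dataset, matrix)
  obs <- uptake_to_conc(dataset$mean_uptake_pmol_per_mg,
                        matrix$vol_per_mg[1L])
  sw <- sqrt(.loss_weights(dataset, spec$weighting))
  n_obs <- length(obs)
  failed_once <- FALSE
  resid_fn <- function(t) {
    par <- .from_opt(t, spec$variant)
    tryCatch(sw * (.model_at(par, matrix, index) - obs),
             error = function(e) {
               if (!failed_once) {
                 warning("simulation failed during fitting (",
                         conditionMessage(e), "); penalty applied",
                         call. = FALSE)
                 failed_once <<- TRUE
               }
               rep(1e3, n_obs)
             })
  }
  bnd <- .opt_bounds(spec)
  starts <- .start_grid(spec)
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    t0 <- .to_opt(as.list(starts[i, , drop = FALSE]), spec$variant)
    t0 <- pmin(pmax(t0, bnd$lower), bnd$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(t0, lower = bnd$lower, upper = bnd$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(ok = FALSE, ssr = Inf, fit = NULL,
                                  info = NA_integer_))
    list(ok = TRUE, ssr = sum(fit$fvec^2), fit = fit, info = fit$info)
  })
  ssrs <- vapply(runs, `[[`, numeric(1L), "ssr")
  if (all(!is.finite(ssrs)))
    stop("all ", nrow(starts), " starts failed; per-start info: ",
         paste(vapply(runs, function(r) as.character(r$info),
                      character(1L)), collapse = ", "))
  best_i <- which.min(ssrs)
  best <- runs[[best_i]]$fit
  par <- .from_opt(best$par, spec$variant)
  ## unweighted residuals for R^2, consistent with a grand-mean null model
  pred <- .model_at(par, matrix, index)
  sst <- sum((obs - mean(obs))^2)
  r2 <- if (sst > 0) 1 - sum((pred - obs)^2) / sst else NA_real_
  ## approximate SEs from the local curvature, delta-method to natural scale
  se <- rep(NA_real_, length(best$par))
  p <- length(best$par)
  if (n_obs > p) {
    sigma2 <- sum(best$fvec^2) / (n_obs - p)
    cv <- tryCatch(solve(best$hessian) * sigma2, error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  se_nat <- if (spec$variant == "mixed")
    c(h = se[1L], V = par$V * se[2L], K = par$K * se[3L])
  else
    c(V = par$V * se[1L], K = par$K * se[2L], endo_int = se[3L])
  structure(list(variant = spec$variant, par = par,
                 ssr = sum(best$fvec^2), r_squared = r2, se = se_nat,
                 starts = data.frame(starts, ssr = ssrs,
                                     info = vapply(runs, function(r)
                                       as.numeric(r$info), numeric(1L))),
                 best_start = best_i, convergence = best$info,
                 message = best$message, n_obs = n_obs,
                 spec = spec, matrix = matrix),
            class = "carrier_fit")
}

#' @export
print.carrier_fit <- function(x, ...) {
  cat(sprintf("Carrier model fit (%s variant)\n", x$variant))
  pars <- if (x$variant == "mixed")
    sprintf("h = %.4g, V = %.4g uM/min, K = %.4g uM",
            x$par$h, x$par$V, x$par$K)
  else
    sprintf("V = %.4g uM/min, K = %.4g uM, endo_int = %.4g uM (h = 0)",
            x$par$V, x$par$K, x$par$endo_int)
  cat(" ", pars, "\n")
  cat(sprintf("  SSR = %.4g uM^2, R^2 = %.4g (n = %d, best start %d/%d)\n",
              x$ssr, x$r_squared, x$n_obs, x$best_start, nrow(x$starts)))
  invisible(x)
}

#' Model predictions of a fit on a dataset's grid
#'
#' @param object a \code{"carrier_fit"}.
#' @param dataset dataset whose (condition, time) grid to predict on;
#'   defaults to nothing — supply one.
#' @param ... unused.
#' @return Numeric vector of intravesicular tracer concentrations (uM), one
#'   per dataset row.
#' @export
predict.carrier_fit <- function(object, dataset, ...) {
  .model_at(object$par, object$matrix, .loss_index(dataset, object$matrix))
}

#' Coefficient of determination of a fit against a dataset
#'
#' \eqn{R^2 = 1 - SSR/SST} with SST taken about the grand mean of all
#' fitted observations across all conditions; a model no better than that
#' flat line scores 0, and a worse one scores negative.
#'
#' @param fit a \code{"carrier_fit"}.
#' @param dataset the dataset to score against (concentration scale is used
#'   internally).
#' @return R-squared (dimensionless, may be negative).
#' @export
r_squared <- function(fit, dataset) {
  stopifnot(inherits(fit, "carrier_fit"))
  obs <- uptake_to_conc(dataset$mean_uptake_pmol_per_mg,
                        fit$matrix$vol_per_mg[1L])
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("constant data: R^2 undefined (SST = 0)")
  1 - sum((predict(fit, dataset) - obs)^2) / sst
}

#' Discriminate obligate exchange from mixed transport
#'
#' Fits both model variants to the same dataset and compares them by
#' R-squared: the mixed variant is preferred iff its R-squared exceeds the
#' obligate one's. Because the mixed family contains h = 0, its best SSR can
#' only be higher than the obligate one's through the obligate variant's
#' extra endogenous-substrate degree of freedom.
#'
#' @param dataset an \code{"uptake_dataset"}.
#' @param matrix the condition matrix.
#' @param multistart starting points per variant (default 8).
#' @param weighting \code{"none"} or \code{"sem"}.
#' @return List of class \code{"carrier_discrimination"}: both fits,
#'   \code{delta_r2} (mixed - obligate), \code{delta_ssr}, and
#'   \code{verdict} ("mixed-preferred" or "obligate-preferred").
#' @export
discriminate <- function(dataset, matrix, multistart = 8,
                         weighting = "none") {
  mixed <- fit_carrier(dataset, matrix,
                       fit_spec("mixed", multistart, weighting))
  obligate <- fit_carrier(dataset, matrix,
                          fit_spec("obligate", multistart, weighting))
  structure(list(mixed = mixed, obligate = obligate,
                 delta_r2 = mixed$r_squared - obligate$r_squared,
                 delta_ssr = mixed$ssr - obligate$ssr,
                 verdict = if (mixed$r_squared > obligate$r_squared)
                   "mixed-preferred" else "obligate-preferred"),
            class = "carrier_discrimination")
}

#' @export
print.carrier_discrimination <- function(x, ...) {
  cat("Model discrimination: obligate exchange vs mixed transport\n")
  cat(sprintf("  mixed:    R^2 = %.4g (h = %.4g, V = %.4g, K = %.4g)\n",
              x$mixed$r_squared, x$mixed$par$h, x$mixed$par$V,
              x$mixed$par$K))
  cat(sprintf("  obligate: R^2 = %.4g (V = %.4g, K = %.4g, endo = %.4g)\n",
              x$obligate$r_squared, x$obligate$par$V, x$obligate$par$K,
              x$obligate$par$endo_int))
  cat(sprintf("  delta R^2 = %.4g -> %s\n", x$delta_r2, x$verdict))
  invisible(x)
}
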