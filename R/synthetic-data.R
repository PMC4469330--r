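#' Replicate-noise model for synthetic uptake data
#'
#' Emulates the statistical structure of vesicle uptake measurements:
#' per-replicate Gaussian noise on the pmol/mg scale (the scale of
#' scintillation counting), truncated at zero, with standard deviation
#' \code{max(floor, cv * value)}, summarized as mean and standard error over
#' replicates ("placentas").
#'
#' @param cv relative noise fraction (default 0.10).
#' @param floor absolute noise floor, pmol/mg (default 0.3).
#' @param n_replicates replicates per condition: a single count, or a range
#'   \code{c(min, max)} sampled per condition (default \code{c(5, 9)}).
#' @param seed integer seed making generation reproducible; NULL uses the
#'   current RNG state.
#' @return A list of class \code{"noise_model"}.
#' @export
noise_model <- function(cv = 0.10, floor = 0.3, n_replicates = c(5, 9),
                        seed = NULL) {
  stopifnot(cv >= 0, floor >= 0, all(n_replicates >= 1),
            length(n_replicates) %in% 1:2)
  structure(list(cv = cv, floor = floor,
                 n_replicates = as.integer(round(n_replicates)),
                 seed = seed),
            class = "noise_model")
}

## Exact noise-free generation (no RNG touched)
.noiseless <- function(noise) noise$cv == 0 && noise$floor == 0

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.summarize_reps <- function(value, n, noise) {
  if (.noiseless(noise)) return(c(mean = value, sem = 0))
  reps <- pmax(0, stats::rnorm(n, mean = value,
                               sd = max(noise$floor, noise$cv * value)))
  c(mean = mean(reps), sem = stats::sd(reps) / sqrt(n))
}

#' Generate a synthetic uptake dataset over a condition matrix
#'
#' Simulates every condition with the quasi-steady-state carrier model,
#' converts intravesicular tracer to pmol per mg protein, and adds
#' replicate noise per the noise model. With \code{cv = 0, floor = 0} the
#' returned means equal the noise-free model curve exactly and no random
#' numbers are drawn. Output schema matches the real-data reader, so
#' synthetic and experimental tables are interchangeable.
#'
#' @param true_params \code{\link{carrier_params}} generating the data.
#' @param matrix a \code{\link{build_matrix}} condition matrix.
#' @param times sampling times in minutes (default
#'   \code{c(0.25, 0.5, 1, 2, 5, 10)}); t = 0 is simulated but not reported.
#' @param noise a \code{\link{noise_model}}.
#' @param endo_int unlabeled substrate added to every vesicle interior, uM
#'   (default 0; used to generate obligate-variant data).
#' @return Data frame of class \code{"uptake_dataset"} with columns
#'   condition_id, time_min, mean_uptake_pmol_per_mg, sem, n, and a
#'   \code{"provenance"} attribute recording the generating inputs.
#' @examples
#' pp <- carrier_params(92, 0.04, c(tracer = 1129, serine = 1129))
#' ds <- generate_dataset(pp, build_matrix(), noise = noise_model(seed = 1))
#' head(ds)
#' @export
generate_dataset <- function(true_params, matrix,
                             times = c(0.25, 0.5, 1, 2, 5, 10),
                             noise = noise_model(), endo_int = 0) {
  stopifnot(inherits(true_params, "carrier_params"),
            inherits(matrix, "condition_matrix"),
            inherits(noise, "noise_model"))
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("'times' must be positive and strictly increasing")
  states <- condition_states(matrix, endo_int = endo_int)
  tcs <- simulate_states(states, true_params, c(0, times))
  .with_seed(noise$seed, {
    rows <- lapply(seq_along(tcs), function(i) {
      n <- if (length(noise$n_replicates) == 2L)
        sample(noise$n_replicates[1L]:noise$n_replicates[2L], 1L)
      else noise$n_replicates
      uptake <- conc_to_uptake(intravesicular(tcs[[i]])[-1L],
                               matrix$vol_per_mg[i])
      stats_m <- vapply(uptake, .summarize_reps, numeric(2L),
                        n = n, noise = noise)
      data.frame(condition_id = matrix$condition_id[i], time_min = times,
                 mean_uptake_pmol_per_mg = stats_m["mean", ],
                 sem = stats_m["sem", ], n = n, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out,
              class = c("uptake_dataset", "data.frame"),
              provenance = list(params = true_params, noise = noise,
                                endo_int = endo_int, times = times))
  })
}

#' Trans-stimulation panel for preloaded substrates
#'
#' Simulates tracer uptake into vesicles preloaded with different
#' intravesicular substrates, each described only by its dissociation
#' constant. Substrates with finite K trans-stimulate tracer influx; an
#' infinite K marks a non-substrate (osmotic control) and reproduces the
#' non-loaded baseline, which is always included as condition "none".
#'
#' @param substrate_Ks named numeric vector: dissociation constant (uM, may
#'   be \code{Inf}) of each preloaded substrate.
#' @param true_params \code{\link{carrier_params}} of the carrier; its K map
#'   must contain the tracer.
#' @param noise a \code{\link{noise_model}}.
#' @param preload_uM intravesicular preload concentration (default 1000).
#' @param tracer_uM external tracer concentration (default 7.5).
#' @param times sampling times, minutes.
#' @param mix \code{\link{mixing_scheme}} for volumes.
#' @return An \code{"uptake_dataset"} whose condition_id is the preloaded
#'   substrate name.
#' @export
generate_preload_panel <- function(substrate_Ks, true_params,
                                   noise = noise_model(),
                                   preload_uM = 1000, tracer_uM = 7.5,
                                   times = c(0.25, 0.5, 1, 2, 5, 10),
                                   mix = mixing_scheme()) {
  stopifnot(inherits(true_params, "carrier_params"),
            is.numeric(substrate_Ks), length(substrate_Ks) >= 1L,
            !is.null(names(substrate_Ks)))
  if (!"tracer" %in% names(true_params$K))
    stop("'true_params$K' must contain the tracer")
  v_in <- mix$protein_mg * mix$vol_per_mg
  v_out <- mix$vol_susp + mix$vol_buffer - v_in
  panel <- c(stats::setNames(Inf, "none"), substrate_Ks)
  .with_seed(noise$seed, {
    rows <- lapply(names(panel), function(nm) {
      K <- c(true_params$K["tracer"], preload = unname(panel[[nm]]))
      pp <- carrier_params(true_params$V, true_params$h, K)
      st <- assay_state(rbind(tracer = c(tracer_uM, 0),
                              preload = c(0, preload_uM)),
                        v_in = v_in, v_out = v_out)
      tc <- simulate_uptake(st, pp, c(0, times))
      n <- if (length(noise$n_replicates) == 2L)
        sample(noise$n_replicates[1L]:noise$n_replicates[2L], 1L)
      else noise$n_replicates
      uptake <- conc_to_uptake(intravesicular(tc)[-1L], mix$vol_per_mg)
      stats_m <- vapply(uptake, .summarize_reps, numeric(2L),
                        n = n, noise = noise)
      data.frame(condition_id = nm, time_min = times,
                 mean_uptake_pmol_per_mg = stats_m["mean", ],
                 sem = stats_m["sem", ], n = n, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out,
              class = c("uptake_dataset", "data.frame"),
              provenance = list(params = true_params, noise = noise,
                                substrate_Ks = substrate_Ks,
                                preload_uM = preload_uM, times = times))
  })
}

#' Read / write uptake datasets as CSV
#'
#' The on-disk schema is the five-column tidy table
#' (condition_id, time_min, mean_uptake_pmol_per_mg, sem, n).
#'
#' @param dataset an \code{"uptake_dataset"} (or compatible data frame).
#' @param path file path.
#' @return \code{read_uptake} returns an \code{"uptake_dataset"};
#'   \code{write_uptake} returns \code{path} invisibly.
#' @export
write_uptake <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset)[, c(
    "condition_id", "time_min", "mean_uptake_pmol_per_mg", "sem", "n")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_uptake
#' @export
read_uptake <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition_id", "time_min", "mean_uptake_pmol_per_mg", "sem", "n")
  if (!all(need %in% names(out)))
    stop("uptake CSV must have columns: ", paste(need, collapse = ", "))
  out$condition_id <- as.character(out$condition_id)
  if (any(out$sem < 0)) stop("negative sem in uptake data")
  structure(out[, need], class = c("uptake_dataset", "data.frame"))
}
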