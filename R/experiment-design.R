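#' Mixing scheme of one uptake assay
#'
#' Volumes and protein content that turn stock and preload concentrations
#' into post-mix initial conditions. The assay mixes a vesicle suspension
#' (vesicles plus suspension medium) into extravesicular buffer; the vesicle
#' interior is not diluted, the suspension medium is.
#'
#' @param vol_susp vesicle-suspension volume added, ul (default 20).
#' @param vol_buffer extravesicular buffer volume, ul (default 20; the
#'   steep-gradient dilution conditions use 50 or 380).
#' @param protein_mg vesicle protein in the assay, mg (default 0.2).
#' @param vol_per_mg intravesicular volume per mg protein, ul/mg
#'   (default 1.3).
#' @param nominal if TRUE (default), stated matrix concentrations are taken
#'   as post-mix initial values; if FALSE they are computed mechanistically
#'   from the volumes.
#' @return A list of class \code{"mixing_scheme"}.
#' @export
mixing_scheme <- function(vol_susp = 20, vol_buffer = 20, protein_mg = 0.2,
                          vol_per_mg = 1.3, nominal = TRUE) {
  stopifnot(vol_susp > 0, vol_buffer > 0, protein_mg > 0, vol_per_mg > 0)
  v_in <- protein_mg * vol_per_mg
  if (v_in >= vol_susp + vol_buffer)
    stop("intravesicular volume exceeds total assay volume")
  structure(list(vol_susp = vol_susp, vol_buffer = vol_buffer,
                 protein_mg = protein_mg, vol_per_mg = vol_per_mg,
                 nominal = isTRUE(nominal)),
            class = "mixing_scheme")
}

#' Post-mix initial concentrations from a preload
#'
#' Dilution arithmetic for one condition: substrate dissolved in the
#' suspension medium spreads over the whole assay volume, substrate inside
#' the vesicles stays at its preload concentration, and any substrate in the
#' extravesicular buffer is diluted by its own volume fraction. Moles are
#' conserved by construction.
#'
#' @param preload_conc unlabeled substrate concentration in the vesicle
#'   suspension (interior and medium alike), uM.
#' @param mix a \code{\link{mixing_scheme}}.
#' @param buffer_conc unlabeled substrate concentration in the added
#'   extravesicular buffer, uM (default 0).
#' @return List with \code{ext} and \code{int} initial concentrations (uM)
#'   and the compartment volumes \code{v_in}, \code{v_out} (ul).
#' @examples
#' # 1000 uM suspension into 380 ul buffer -> 50 uM outside
#' apply_mixing(1000, mixing_scheme(vol_buffer = 380))$ext
#' @export
apply_mixing <- function(preload_conc, mix, buffer_conc = 0) {
  stopifnot(inherits(mix, "mixing_scheme"),
            preload_conc >= 0, buffer_conc >= 0)
  total <- mix$vol_susp + mix$vol_buffer
  v_in <- mix$protein_mg * mix$vol_per_mg
  list(ext = preload_conc * mix$vol_susp / total +
         buffer_conc * mix$vol_buffer / total,
       int = preload_conc,
       v_in = v_in, v_out = total - v_in)
}

.matrix_template <- function() {
  data.frame(
    condition_id = c("1", "2", "3", "4", "4b", "5", "6", "7"),
    ext_uM = c(0, 250, 250, 250, 50, 1000, 1000, 1000),
    int_uM = c(0, 0, 250, 1000, 1000, 0, 250, 1000),
    vol_buffer_ul = c(20, 20, 20, 50, 380, 20, 20, 20),
    stringsAsFactors = FALSE)
}

#' The eight-condition cis/trans substrate matrix
#'
#' Builds the experimental design used to separate obligate exchange from
#' facilitated transport: tracer uptake measured under all combinations of
#' extravesicular (cis) and intravesicular (trans) unlabeled substrate.
#' Nominal (ext:int) unlabeled concentrations are 1:(0:0), 2:(250:0),
#' 3:(250:250), 4:(250:1000), 4b:(50:1000), 5:(1000:0), 6:(1000:250),
#' 7:(1000:1000) uM, with tracer added externally at t = 0. Conditions 1, 2
#' and 5 are the zero-trans series (cis-inhibition), 2-3-4/4b the
#' trans-stimulation series, and 4/4b impose the outward gradients that
#' elicit the uptake overshoot.
#'
#' @param tracer_uM initial external tracer concentration, uM (default 7.5;
#'   treated as post-mix in nominal mode, as the buffer concentration in
#'   mechanistic mode).
#' @param mix a \code{\link{mixing_scheme}} giving volumes shared by all
#'   conditions except the per-condition buffer volume (50 ul for condition
#'   4, 380 ul for 4b).
#' @return A data frame of class \code{"condition_matrix"} with columns
#'   condition_id, ext_uM, int_uM, tracer_uM, vol_susp_ul, vol_buffer_ul,
#'   protein_mg, vol_per_mg.
#' @examples
#' build_matrix()
#' @export
build_matrix <- function(tracer_uM = 7.5, mix = mixing_scheme()) {
  stopifnot(inherits(mix, "mixing_scheme"), tracer_uM >= 0)
  m <- .matrix_template()
  m$tracer_uM <- tracer_uM
  m$vol_susp_ul <- mix$vol_susp
  m$protein_mg <- mix$protein_mg
  m$vol_per_mg <- mix$vol_per_mg
  if (!mix$nominal) {
    ## mechanistic mode: interiors hold the preload; the stated external
    ## additions live in the buffer; condition 4/4b externals arise purely
    ## from diluting the 1000 uM suspension medium
    buffer_uM <- c(0, 250, 250, 0, 0, 1000, 1000, 1000)
    total <- m$vol_susp_ul + m$vol_buffer_ul
    m$ext_uM <- m$int_uM * m$vol_susp_ul / total +
      buffer_uM * m$vol_buffer_ul / total
    m$tracer_uM <- tracer_uM * m$vol_buffer_ul / total
  }
  m <- m[, c("condition_id", "ext_uM", "int_uM", "tracer_uM",
             "vol_susp_ul", "vol_buffer_ul", "protein_mg", "vol_per_mg")]
  class(m) <- c("condition_matrix", "data.frame")
  m
}

#' Add endogenous substrate to every condition of a matrix
#'
#' Scenario modifier for endogenous amino acids present in the vesicle
#' isolate: the stated concentration is added to the vesicle interior and to
#' the suspension medium of every condition, the medium fraction diluting
#' into the external pool according to each condition's volumes.
#'
#' @param matrix a \code{\link{build_matrix}} result.
#' @param endo_conc endogenous substrate concentration in the vesicle
#'   suspension, uM (>= 0).
#' @return The modified \code{condition_matrix}.
#' @examples
#' add_endogenous(build_matrix(), 300)
#' @export
add_endogenous <- function(matrix, endo_conc) {
  stopifnot(inherits(matrix, "condition_matrix"), endo_conc >= 0)
  matrix$int_uM <- matrix$int_uM + endo_conc
  matrix$ext_uM <- matrix$ext_uM + endo_conc * matrix$vol_susp_ul /
    (matrix$vol_susp_ul + matrix$vol_buffer_ul)
  matrix
}

#' Initial assay states for every matrix condition
#'
#' Expands a condition matrix into per-condition \code{\link{assay_state}}
#' objects with two substrate pools, the tracer and the unlabeled substrate
#' (same chemical species, shared K).
#'
#' @param matrix a \code{\link{build_matrix}} result.
#' @param endo_int additional unlabeled substrate added to the vesicle
#'   interior only, uM (the obligate-variant fitting degree of freedom;
#'   default 0).
#' @param tracer_id,substrate_id pool names (defaults "tracer", "serine").
#' @return Named list of \code{assay_state}, one per condition.
#' @export
condition_states <- function(matrix, endo_int = 0,
                             tracer_id = "tracer", substrate_id = "serine") {
  stopifnot(inherits(matrix, "condition_matrix"), endo_int >= 0)
  v_in <- matrix$protein_mg * matrix$vol_per_mg
  v_out <- matrix$vol_susp_ul + matrix$vol_buffer_ul - v_in
  out <- lapply(seq_len(nrow(matrix)), function(i) {
    conc <- rbind(c(matrix$tracer_uM[i], 0),
                  c(matrix$ext_uM[i], matrix$int_uM[i] + endo_int))
    rownames(conc) <- c(tracer_id, substrate_id)
    assay_state(conc, v_in = v_in[i], v_out = v_out[i])
  })
  stats::setNames(out, matrix$condition_id)
}

#' Convert uptake per mg protein to intravesicular concentration
#'
#' @param uptake uptake in pmol per mg protein.
#' @param vol_per_mg intravesicular volume per mg protein, ul/mg (> 0,
#'   default 1.3).
#' @return Concentration in uM. \code{conc_to_uptake} is the exact inverse.
#' @examples
#' uptake_to_conc(13)       # 10 uM
#' conc_to_uptake(10)       # 13 pmol/mg
#' @export
uptake_to_conc <- function(uptake, vol_per_mg = 1.3) {
  if (!is.finite(vol_per_mg) || vol_per_mg <= 0)
    stop("'vol_per_mg' must be > 0")
  uptake / vol_per_mg
}

#' @rdname uptake_to_conc
#' @param conc concentration in uM.
#' @export
conc_to_uptake <- function(conc, vol_per_mg = 1.3) {
  if (!is.finite(vol_per_mg) || vol_per_mg <= 0)
    stop("'vol_per_mg' must be > 0")
  conc * vol_per_mg
}
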