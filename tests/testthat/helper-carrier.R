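# Shared fixtures: everything is built in code, nothing read from disk.

# Reference serine carrier set (V = 92 uM/min, K = 1129 uM); h varies by test.
ref_params <- function(h = 0.04) serine_params(h = h)

# Exact, RNG-free generation
noise_free <- function() noise_model(cv = 0, floor = 0, n_replicates = 5)

# A two-substrate state with an outward unlabeled gradient (the
# steep-dilution condition: 20 ul suspension into 380 ul buffer)
outward_state <- function() {
  assay_state(rbind(tracer = c(7.5, 0), serine = c(50, 1000)),
              v_in = 0.26, v_out = 399.74)
}

# Random parameter/state draw in the physiological envelope used by the
# oracle-equivalence property
random_draw <- function() {
  K <- runif(1, 10, 1e4)
  pp <- carrier_params(V = runif(1, 10, 500), h = runif(1, 0, 1),
                       K = c(tracer = K, serine = K))
  st <- assay_state(rbind(tracer = c(runif(1, 1, 20), 0),
                          serine = c(runif(1, 0, 1000),
                                     runif(1, 0, 1000))),
                    v_in = 0.26, v_out = runif(1, 30, 400))
  list(params = pp, state = st)
}
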