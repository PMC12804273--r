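# Shared fixtures: a coarse mesh for fast unit tests (the acceptance tests
# use the full default mesh) and a few convenience constructors.

coarse_grids <- function() sim_grids(X = 10, N = 41, M = 21)

coarse_model <- function(params = model_params(), protocol = oxygen_protocol(),
                         ...) {
  invasion_model(params, protocol, grids = coarse_grids(), ...)
}

# tumor_state with prescribed fields on a given mesh
make_state <- function(grids, n = NULL, h = NULL, e = NULL, t = 0) {
  if (is.null(n)) n <- numeric(grids$N)
  if (is.null(e)) e <- numeric(grids$N)
  if (is.null(h)) h <- matrix(0, grids$N, grids$M)
  structure(list(t = t, n = n, h = h, e = e, grids = grids),
            class = "tumor_state")
}

# manual forward-Euler loop over the exported reference step
run_reference <- function(model, t_final, dt) {
  st <- initialize_state(model$grids, model$init$n0, model$init$e0,
                         model$init$a, model$init$b)
  for (k in seq_len(round(t_final / dt)))
    st <- step_state(st, model$protocol, model$params, model$grids, dt)
  st
}
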