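# Shared fixtures, built in code and memoised per test session.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

# default 27-frame protocol with its 0.05-min fine grid
fx_protocol <- function() fx("protocol", function() {
  sch <- default_frame_schedule()
  t_fine <- fine_time_grid(sch, 0.05)
  list(schedule = sch, t_fine = t_fine,
       Fmat = frame_integration_matrix(sch, t_fine))
})

# tracer specs and canonical AIFs on the default fine grid
fx_tracers <- function() fx("tracers", function() {
  pr <- fx_protocol()
  tr <- list(FDG = tracer_spec("FDG"), MET = tracer_spec("MET"))
  aifs <- lapply(tr, function(x) feng_aif(feng_params(x), pr$t_fine))
  list(specs = tr, aifs = aifs)
})

# 25-function bases for both tracers on the default fine grid
fx_bases <- function() fx("bases", function() {
  pr <- fx_protocol()
  trs <- fx_tracers()$specs
  lapply(trs, function(x) build_basis(x, pr$t_fine))
})

# small desk-scale simulated example (32x32, 10-frame schedule)
fx_desk_example <- function() fx("desk_example", function() {
  cfg <- experiment_config("desk", n_phantoms = 1L, n_realisations = 2L,
                           seed = 42L)
  simulate_example(cfg, 1L)
})

# toy spectral system on a 2-sample grid where frames == fine samples:
# identity frame matrix, dt = 1, one basis function per tracer
fx_toy_system <- function() {
  list(Fmat = diag(2), dt = 1,
       B_step = matrix(c(1, 1), 2, 1),     # constant basis function
       B_impulse = matrix(c(1, 0), 2, 1),  # unit-impulse basis function
       h_identity = c(1, 0),               # identity kernel at dt = 1
       h_ones = c(1, 1))
}

# deterministic desk-scale training dataset for the network tests
fx_train_data <- function(n_examples, seed = 5L, n_realisations = 1L) {
  cfg <- experiment_config("desk", n_phantoms = n_examples,
                           n_realisations = n_realisations, seed = seed,
                           n_iter_mlem = 20L)
  lapply(seq_len(n_examples), function(i) {
    ex <- simulate_example(cfg, i)
    list(m = ex$noisy[[1]]$dual$values,
         labels = list(FDG = ex$noisy[[1]]$FDG$values,
                       MET = ex$noisy[[1]]$MET$values),
         ref = list(FDG = ex$ref$FDG$values, MET = ex$ref$MET$values),
         slice = ex$slice, example = ex)
  })
}
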