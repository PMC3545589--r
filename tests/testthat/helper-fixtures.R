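# shared fixture shortcuts for the test suite

k_pmf <- make_fixture("k_pmf")
cl_pmf <- make_fixture("cl_pmf")
c60f36 <- make_fixture("c60f36_pmf")
c60f60 <- make_fixture("c60f60_pmf")
flat_pmf <- make_fixture("flat_pmf")

# short-duration simulation config for unit tests (not the study conditions)
quick_config <- function(pmf = k_pmf, sp = potassium_ion(), ...) {
  defaults <- list(pmfs = stats::setNames(list(pmf), sp$name),
                   species = list(sp), timestep_ps = 0.1,
                   duration_ns = 200, equilibration_ns = 20,
                   n_replicates = 1, seed = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
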