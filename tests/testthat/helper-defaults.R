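# Shared builders for the default parameter set and cheaper meshes used by
# most tests.  All stochastic tests fix their seeds through sim_config().

default_neuron <- function(...) neuron_params(...)
default_input <- function(...) uncorrelated_input(...)

# coarser working mesh for tests where 1e-2 mV resolution is overkill
test_mesh <- function(p, dv = 0.05) build_mesh(p, dv = dv)

# independent trapezoid (used to cross-check solver output)
trapz_ref <- function(x, y) sum(0.5 * diff(x) * (y[-1] + y[-length(y)]))
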