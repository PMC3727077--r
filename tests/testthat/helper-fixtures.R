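# Shared fixtures, built once per test run and cached across files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, build(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

xeno_config <- function() cached("cfg", function() default_config())
xeno_model <- function() cached("model", function() vegf_model(xeno_config()))
xeno_ss <- function() cached("ss", function() steady_state(xeno_model()))

normal_config <- function() cached("cfg2", function() default_config(tumor = FALSE))
normal_model <- function() cached("model2", function() vegf_model(normal_config()))

# Minimal closed single-compartment configuration: one isoform pair,
# one surface carrying only VEGFR1, no soluble factors, no transport
# (no blood compartment), no turnover.  Used for analytic equilibrium
# oracles.
closed_config <- function(kon = 3e7, koff = 1e-3, k_int = 0) {
  cfg <- default_config(tumor = FALSE)
  cfg$name <- "closed_toy"
  cfg$network$compartments <- list(
    t1 = list(
      type = "tissue",
      fluid = list(trap = FALSE, svegfr1 = FALSE, a2m = FALSE),
      matrix_regions = character(0),
      surfaces = list(
        cell = surface_spec("VEGFR1",
                            densities = c(VEGFR1 = 10000),
                            cells_per_cm3 = 1e7))))
  cfg$network$isoforms <- list(mouse = c("mV120", "mV164"),
                               human = character(0))
  cfg$network$heparin_binding <- "mV164"
  cfg$geometry <- list(t1 = list(volume = 1, K_av = 1, S_EC = 0,
                                 region_avail = list()))
  cfg$kinetics$kon[cfg$kinetics$class == "V-R1"] <- kon
  cfg$kinetics$koff[cfg$kinetics$class == "V-R1"] <- koff
  cfg$trafficking$k_int <- k_int
  cfg$transport$k_deg <- 0
  cfg$secretion$q_muscle <- 0
  cfg$secretion$q_EC <- 0
  cfg$secretion$q_sR1_EC <- 0
  cfg
}

# A673 baseline mean secretion rates (molecules/cell/s), the
# ground-truth parameter set of the recovery experiments.
a673_theta <- function() c(q_muscle = 0.011, q_EC = 0.009, q_tumor = 0.009)
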