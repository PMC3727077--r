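#' Plasma drug observables of a simulation
#'
#' Free VEGF Trap and the mouse-VEGF and human-VEGF Trap complexes in
#' plasma, the observables reported by the fitted pseudo-experimental
#' time courses.
#'
#' @param sim a `vegf_sim`.
#' @return data.frame with columns `time_days`, `trap_free`,
#'   `trap_mVEGF`, `trap_hVEGF` (pM).
#' @export
plasma_observables <- function(sim) {
  stopifnot(inherits(sim, "vegf_sim"))
  sp <- sim$model$species
  iso_m <- sim$model$config$network$isoforms$mouse
  iso_h <- sim$model$config$network$isoforms$human
  col <- function(ids) {
    ids <- ids[ids %in% colnames(sim$state)]
    if (!length(ids)) return(rep(0, length(sim$time)))
    rowSums(sim$state[, ids, drop = FALSE])
  }
  data.frame(
    time_days = sim$time / 86400,
    trap_free = 1e15 * col("blood.fluid.Trap"),
    trap_mVEGF = 1e15 * col(paste0("blood.fluid.", iso_m, ".Trap")),
    trap_hVEGF = 1e15 * col(paste0("blood.fluid.", iso_h, ".Trap")))
}

#' Free VEGF concentration per compartment
#'
#' @param sim a `vegf_sim`.
#' @param compartment compartment name.
#' @param origin `"mouse"`, `"human"` or `"all"`.
#' @return numeric vector (pM in the compartment's available fluid /
#'   plasma) along `sim$time`.
#' @export
free_vegf <- function(sim, compartment = "blood", origin = "all") {
  iso <- sim$model$config$network$isoforms
  set <- switch(origin, mouse = iso$mouse, human = iso$human,
                all = c(iso$mouse, iso$human),
                stop("origin must be mouse/human/all"))
  ids <- paste0(compartment, ".fluid.", set)
  ids <- ids[ids %in% colnames(sim$state)]
  kav <- if (compartment == "blood") 1 else
    sim$model$config$geometry[[compartment]]$K_av
  1e15 * rowSums(sim$state[, ids, drop = FALSE]) / kav
}

#' Fraction of free VEGF in the heparin-binding isoform
#'
#' @param sim a `vegf_sim`.
#' @param compartment compartment name.
#' @param origin `"mouse"` (VEGF164 share) or `"human"` (VEGF165 share).
#' @return numeric vector of fractions along `sim$time`.
#' @export
isoform_fraction <- function(sim, compartment = "blood", origin = "mouse") {
  iso <- sim$model$config$network$isoforms[[origin]]
  hb <- intersect(iso, sim$model$config$network$heparin_binding)
  tot <- rowSums(sim$state[, paste0(compartment, ".fluid.", iso),
                           drop = FALSE])
  hbv <- rowSums(sim$state[, paste0(compartment, ".fluid.", hb),
                           drop = FALSE])
  ifelse(tot > 0, hbv / tot, NA_real_)
}

#' Composition of circulating VEGF
#'
#' Splits total plasma VEGF into free, sVEGFR1-bound,
#' alpha-2-macroglobulin-bound (native plus activated) and
#' Trap-bound pools.
#'
#' @param sim a `vegf_sim`.
#' @return data.frame with `time_days` and the four pool fractions.
#' @export
circulating_composition <- function(sim) {
  iso <- with(sim$model$config$network$isoforms, c(mouse, human))
  col <- function(suffix) {
    ids <- paste0("blood.fluid.", iso, suffix)
    ids <- ids[ids %in% colnames(sim$state)]
    if (!length(ids)) return(rep(0, length(sim$time)))
    rowSums(sim$state[, ids, drop = FALSE])
  }
  free <- col(""); sr1 <- col(".sR1")
  a2m <- col(".a2Mn") + col(".a2Mf"); trap <- col(".Trap")
  tot <- free + sr1 + a2m + trap
  data.frame(time_days = sim$time / 86400,
             free = free / tot, sVEGFR1_bound = sr1 / tot,
             a2M_bound = a2m / tot, trap_bound = trap / tot)
}

#' Total drug amount in the system plus cleared integral
#'
#' Sums VEGF Trap (free and complexed) over all compartments, weighted
#' by compartment volume (the tumor volume at each time point), and
#' adds the cumulative moles removed by plasma clearance; under pure
#' transport/binding/clearance this total equals the infused amount.
#'
#' @param sim a `vegf_sim`.
#' @return numeric vector of moles along `sim$time`.
#' @export
drug_mass_audit <- function(sim) {
  sp <- sim$model$species
  cfg <- sim$model$config
  trap_ids <- sp$id[grepl("Trap", sp$name)]
  vol <- function(cn, t_i) {
    if (cn == "tumor") sim$tumor_volume[t_i]
    else cfg$geometry[[cn]]$volume
  }
  tot <- numeric(length(sim$time))
  for (cn in unique(sp$compartment[match(trap_ids, sp$id)])) {
    ids <- trap_ids[sp$compartment[match(trap_ids, sp$id)] == cn]
    conc <- rowSums(sim$state[, ids, drop = FALSE])
    v <- if (cn == "tumor") sim$tumor_volume
         else rep(cfg$geometry[[cn]]$volume, length(sim$time))
    tot <- tot + conc * v
  }
  tot + sim$state[, "audit.cleared_trap"]
}

#' Long-format trajectory table
#'
#' @param x a `vegf_sim`.
#' @param row.names,optional,... ignored.
#' @return data.frame with columns `time_days`, `compartment`,
#'   `species`, `concentration_pM` (per cm^3 of the owning
#'   compartment's reference volume).
#' @export
as.data.frame.vegf_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  sp <- x$model$species
  long <- expand.grid(time_days = x$time / 86400, id = sp$id,
                      stringsAsFactors = FALSE)
  long$compartment <- sp$compartment[match(long$id, sp$id)]
  long$species <- sp$name[match(long$id, sp$id)]
  long$concentration_pM <- as.vector(x$state[, sp$id]) * 1e15
  long[, c("time_days", "compartment", "species", "concentration_pM")]
}

#' Plot plasma drug observables
#'
#' @param x a `vegf_sim`.
#' @param log logical; logarithmic concentration axis.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.vegf_sim <- function(x, log = TRUE, ...) {
  obs <- plasma_observables(x)
  m <- as.matrix(obs[, -1])
  m[m <= 0] <- NA
  graphics::matplot(obs$time_days, m, type = "l", lty = 1,
                    col = c("black", "blue", "red"),
                    xlab = "time (days)", ylab = "plasma concentration (pM)",
                    log = if (log) "y" else "", ...)
  graphics::legend("topright", legend = c("free Trap", "mVEGF-Trap",
                                          "hVEGF-Trap"),
                   col = c("black", "blue", "red"), lty = 1, bty = "n")
  invisible(x)
}
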