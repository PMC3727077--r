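#' Assemble the compartment model
#'
#' Builds the complete ODE model from a configuration: enumerates the
#' species, generates the reaction network, and compiles mass-action,
#' transport, lymphatic, clearance, degradation, secretion and
#' growth-dilution terms into the index arrays evaluated by the
#' compiled right-hand side.  Association rates are converted to the
#' internal mol/cm^3 basis, with interstitial reactions corrected for
#' the available fluid volume fraction of the compartment.
#'
#' @param config a `vegf_config`, see [default_config()].
#' @return an object of class `vegf_model`.
#' @examples
#' m <- vegf_model(default_config())
#' m$manifest$counts
#' @export
vegf_model <- function(config) {
  net <- enumerate_species(config)
  rx <- build_reactions(net, config)
  sp <- net$species
  n <- nrow(sp)
  idx <- stats::setNames(seq_len(n), sp$id)

  comp_type <- vapply(config$network$compartments, function(x) x$type, "")
  kav_of <- function(cn) {
    if (identical(comp_type[[cn]], "blood")) 1 else config$geometry[[cn]]$K_av
  }
  is_fluid <- sp$locale == "fluid"
  sp_kav <- ifelse(is_fluid,
                   vapply(sp$compartment, kav_of, numeric(1)), 1)

  V_b <- config$geometry$blood$volume
  has_tumor <- "tumor" %in% names(config$network$compartments)

  bi_a <- bi_b <- bi_p <- integer(0); bi_k <- numeric(0)
  l_src <- l_tgt <- l_vs <- integer(0); l_coef <- numeric(0)
  s_tgt <- s_vs <- integer(0); s_rate <- numeric(0)

  lin <- function(src, tgt, coef, vs = 0L) {
    l_src <<- c(l_src, src); l_tgt <<- c(l_tgt, tgt)
    l_coef <<- c(l_coef, coef); l_vs <<- c(l_vs, vs)
  }
  src <- function(tgt, rate, vs = 0L) {
    s_tgt <<- c(s_tgt, tgt); s_rate <<- c(s_rate, rate)
    s_vs <<- c(s_vs, vs)
  }

  ## audit state: cumulative moles of drug (Trap and complexes) removed
  ## by plasma clearance; appended after the network species
  i_audit <- n + 1L

  rx_cols <- as.list(rx)
  for (i in seq_len(nrow(rx))) {
    r <- lapply(rx_cols, `[`, i)
    if (r$kind %in% c("binding", "coupling")) {
      a <- idx[[r$r1]]; b <- idx[[r$r2]]; p <- idx[[r$p1]]
      kav <- if (sp$locale[a] == "fluid" || sp$locale[b] == "fluid")
        kav_of(r$compartment) else 1
      bi_a <- c(bi_a, a); bi_b <- c(bi_b, b); bi_p <- c(bi_p, p)
      bi_k <- c(bi_k, r$kon * 1000 / kav)
      lin(p, p, -r$koff); lin(p, a, r$koff); lin(p, b, r$koff)
    } else if (r$kind %in% c("internalization", "trafficking", "insertion",
                             "degradation", "clearance") && !is.na(r$r1)) {
      a <- idx[[r$r1]]
      lin(a, a, -r$rate)
      if (!is.na(r$p1)) lin(a, idx[[r$p1]], r$rate)
      if (r$kind == "clearance" && grepl("Trap", r$r1))
        lin(a, i_audit, r$rate * V_b)
    } else if (r$kind %in% c("secretion", "insertion") && is.na(r$r1)) {
      src(idx[[r$p1]], r$rate, r$vscale)
    } else if (r$kind == "transport" || r$kind == "lymph") {
      cn <- r$compartment
      it <- idx[[r$r1]]; ib <- idx[[r$p1]]
      kav <- kav_of(cn)
      V_t <- config$geometry[[cn]]$volume   # NULL for tumor (dynamic)
      if (r$kind == "transport") {
        kpS <- r$rate * config$geometry[[cn]]$S_EC
        lin(ib, it, kpS)
        lin(it, it, -kpS / kav)
        if (identical(cn, "tumor")) {
          lin(ib, ib, -kpS / V_b, 1L)
          lin(it, ib, kpS / (kav * V_b), 1L)
        } else {
          lin(ib, ib, -kpS * V_t / V_b)
          lin(it, ib, kpS * V_t / (kav * V_b))
        }
      } else {
        kL <- r$rate
        lin(it, it, -kL / kav)
        if (identical(cn, "tumor")) {
          lin(it, ib, kL / (kav * V_b), 1L)
        } else {
          lin(it, ib, kL * V_t / (kav * V_b))
        }
      }
    }
  }

  dil_idx <- which(sp$compartment == "tumor")

  ## initial condition: receptors/sites at configured density, soluble
  ## factors at their synthesis/clearance balance, everything else zero
  y0 <- stats::setNames(numeric(n + 1L), c(sp$id, "audit.cleared_trap"))
  for (cn in names(config$network$compartments)) {
    comp <- config$network$compartments[[cn]]
    for (sn in names(comp$surfaces)) {
      surf <- comp$surfaces[[sn]]
      scale <- if (identical(surf$ref_volume, "tumor"))
        config$growth$V0 / V_b else 1
      dens <- surf$densities * surf$cells_per_cm3 / AVOGADRO * scale
      for (r in surf$receptors)
        y0[paste(cn, sn, r, sep = ".")] <- dens[[r]]
    }
    for (reg in comp$matrix_regions) {
      avail <- .region_avail(config, cn, reg)
      y0[paste(cn, reg, "GAG", sep = ".")] <-
        config$sites$gag_uM[[reg]] * 1e-9 * avail
    }
    if (identical(comp$type, "blood") && isTRUE(comp$fluid$a2m)) {
      y0[paste(cn, "fluid", "a2Mn", sep = ".")] <-
        config$soluble$a2m_native_M * 1e-3
      y0[paste(cn, "fluid", "a2Mf", sep = ".")] <-
        config$soluble$a2m_fast_M * 1e-3
    }
  }

  structure(list(
    config = config,
    species = sp,
    manifest = net$manifest,
    network = net,
    reactions = rx,
    n_state = n + 1L,
    idx = idx,
    sp_kav = sp_kav,
    has_tumor = has_tumor,
    y0 = y0,
    compiled = list(
      bi_a = bi_a - 1L, bi_b = bi_b - 1L, bi_p = bi_p - 1L, bi_k = bi_k,
      l_src = l_src - 1L, l_tgt = l_tgt - 1L, l_coef = l_coef, l_vs = l_vs,
      s_tgt = s_tgt - 1L, s_rate = s_rate, s_vs = s_vs,
      dil_idx = dil_idx - 1L)),
    class = "vegf_model")
}

.region_avail <- function(config, cn, reg) {
  g <- config$geometry[[cn]]
  if (!is.null(g$derived)) {
    t <- g$derived$interstitium$regions
    t$available_fluid_volume[match(reg, t$region)]
  } else {
    g$region_avail[[reg]]
  }
}

#' @export
print.vegf_model <- function(x, ...) {
  cat(sprintf("VEGF compartment model '%s'\n", x$config$name))
  print(x$manifest)
  cat(sprintf("  %d reactions, %d compiled mass-action fluxes\n",
              nrow(x$reactions), length(x$compiled$bi_k)))
  invisible(x)
}

#' @export
summary.vegf_model <- function(object, ...) {
  print(object)
  network_audit(object$network)
  invisible(object)
}

# Raw derivative at a state (R-side convenience wrapper).
.rhs <- function(model, y, t = 0, g = 0, vt0 = 0, t0 = 0, extra = NULL) {
  cc <- model$compiled
  s_tgt <- cc$s_tgt; s_rate <- cc$s_rate; s_vs <- cc$s_vs
  if (!is.null(extra)) {
    s_tgt <- c(s_tgt, extra$tgt - 1L)
    s_rate <- c(s_rate, extra$rate)
    s_vs <- c(s_vs, integer(length(extra$rate)))
  }
  rhs_core(t, y, cc$bi_a, cc$bi_b, cc$bi_p, cc$bi_k,
           cc$l_src, cc$l_tgt, cc$l_coef, cc$l_vs,
           s_tgt, s_rate, s_vs, cc$dil_idx, g, vt0, t0)
}

# Integrate one segment with fixed growth setting and optional
# constant infusion sources.
.integrate_segment <- function(model, y, times, g = 0, vt0 = 0, t0 = times[1],
                               extra = NULL, rtol = NULL, atol = NULL) {
  cc <- model$compiled
  solver <- model$config$solver
  if (is.null(rtol)) rtol <- solver$rtol
  if (is.null(atol)) atol <- solver$atol
  s_tgt <- cc$s_tgt; s_rate <- cc$s_rate; s_vs <- cc$s_vs
  if (!is.null(extra)) {
    s_tgt <- c(s_tgt, extra$tgt - 1L)
    s_rate <- c(s_rate, extra$rate)
    s_vs <- c(s_vs, integer(length(extra$rate)))
  }
  func <- function(t, y, p) {
    list(rhs_core(t, y, cc$bi_a, cc$bi_b, cc$bi_p, cc$bi_k,
                  cc$l_src, cc$l_tgt, cc$l_coef, cc$l_vs,
                  s_tgt, s_rate, s_vs, cc$dil_idx, g, vt0, t0))
  }
  out <- deSolve::lsodes(y = y, times = times, func = func, parms = NULL,
                         rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed (istate ", attr(out, "istate")[1],
         ") at t = ", utils::tail(out[, 1], 1), call. = FALSE)
  out
}

#' Drug-free steady state of the model
#'
#' Integrates the system with tumor growth disabled (volume held at its
#' current value) until the largest relative rate of change falls below
#' `tol` (per second), and returns the settled state.  Used to
#' initialize the pre-inoculation condition.
#'
#' @param model a `vegf_model`.
#' @param y optional starting state (defaults to the model's nominal
#'   initial condition).
#' @param tol convergence tolerance on max |dC/dt| / (|C| + floor), 1/s.
#' @param t_max maximum integration horizon (s).
#' @param v_tumor tumor volume at which the state is held.
#' @return named state vector with attribute `converged`.
#' @export
steady_state <- function(model, y = NULL, tol = 1e-12, t_max = 1e9,
                         v_tumor = model$config$growth$V0) {
  stopifnot(inherits(model, "vegf_model"))
  if (is.null(y)) y <- model$y0
  t_now <- 0; horizon <- 1e5
  repeat {
    out <- .integrate_segment(model, y, c(0, horizon), g = 0,
                              vt0 = v_tumor, rtol = 1e-10, atol = 1e-24)
    y <- out[nrow(out), -1]
    t_now <- t_now + horizon
    dy <- .rhs(model, y, g = 0, vt0 = v_tumor)
    rel <- max(abs(dy) / (abs(y) + 1e-22))
    if (rel < tol || t_now >= t_max) {
      if (rel >= tol)
        warning(sprintf(
          "steady state not converged: max relative rate %.3g /s after %.3g s",
          rel, t_now))
      attr(y, "converged") <- rel < tol
      y["audit.cleared_trap"] <- 0
      return(y)
    }
    horizon <- horizon * 10
  }
}

#' Dosing schedule constructor
#'
#' @param dose dose in mg/kg (recycled over `times_days`).
#' @param times_days injection times in days (default twice weekly for
#'   two weeks: days 0, 3.5, 7, 10.5).
#' @return data.frame of class `dose_schedule` with columns `time_days`
#'   and `dose_mg_kg`.
#' @export
dose_schedule <- function(dose, times_days = c(0, 3.5, 7, 10.5)) {
  structure(data.frame(time_days = times_days,
                       dose_mg_kg = rep_len(dose, length(times_days))),
            class = c("dose_schedule", "data.frame"))
}

#' Convert a dose to a molar infusion input
#'
#' A dose in mg/kg with the configured body weight and drug molecular
#' weight is delivered as a constant molar inflow into the plasma over
#' the infusion duration; the zero-duration limit is a bolus increment
#' of `moles / plasma_volume`.
#'
#' @param dose_mg_kg dose (mg drug per kg body weight).
#' @param body_weight_g body weight (g).
#' @param mw_kda drug molecular weight (kDa).
#' @param plasma_volume plasma volume (cm^3).
#' @param duration_s infusion duration (s).
#' @return list with `moles` delivered (mol), `rate` (mol/cm^3 plasma
#'   per s; `Inf` for zero duration) and `bolus_conc` (mol/cm^3), the
#'   concentration increment of an instantaneous bolus.
#' @examples
#' dose_to_input(2.5)$moles * 1e9   # ~0.543 nmol
#' @export
dose_to_input <- function(dose_mg_kg, body_weight_g = 25, mw_kda = 115,
                          plasma_volume = 1, duration_s = 60) {
  stopifnot(dose_mg_kg >= 0, body_weight_g > 0, plasma_volume > 0,
            duration_s >= 0)
  if (mw_kda <= 0) stop("molecular weight must be positive", call. = FALSE)
  # (mg/kg) * kg = mg of drug; /1000 -> g; / (g/mol) -> mol
  moles <- dose_mg_kg * (body_weight_g / 1000) * 1e-3 / (mw_kda * 1000)
  list(moles = moles,
       rate = if (duration_s > 0) moles / (duration_s * plasma_volume) else Inf,
       bolus_conc = moles / plasma_volume)
}

#' Simulate the model under a dosing protocol
#'
#' Runs the full study protocol: (1) settle the drug-free steady state;
#' (2) grow the tumor exponentially from the inoculation volume to the
#' trigger volume (skipped for the two-compartment model); (3) apply
#' the dosing schedule, restarting the integration exactly at every
#' infusion start and stop.  Time zero of the returned trajectories is
#' the first injection.
#'
#' @param object a `vegf_model`.
#' @param nsim,seed unused (present for compatibility with
#'   [stats::simulate()]).
#' @param schedule a [dose_schedule()]; `NULL` simulates drug-free.
#' @param days duration of the observation window after the first dose.
#' @param dt_out output resolution in seconds (default 1 h).
#' @param t_out optional explicit output times (s, relative to first
#'   dose); overrides `dt_out`.
#' @param init optional pre-computed steady state to start from.
#' @param rtol,atol optional solver tolerance overrides.
#' @param ... unused.
#' @return object of class `vegf_sim`: list with `time` (s), `state`
#'   (matrix time x species), `tumor_volume` (cm^3), `model`,
#'   `schedule`.
#' @export
simulate.vegf_model <- function(object, nsim = 1, seed = NULL,
                                schedule = NULL, days = 14, dt_out = 3600,
                                t_out = NULL, init = NULL,
                                rtol = NULL, atol = NULL, ...) {
  model <- object
  cfg <- model$config
  gr <- cfg$growth
  g_s <- if (model$has_tumor) gr$rate[[gr$profile]] / 86400 else 0

  y <- if (is.null(init)) steady_state(model) else init
  v_trig <- if (model$has_tumor) gr$trigger_volume else 0

  ## growth to trigger volume
  if (model$has_tumor && g_s > 0) {
    t_grow <- log(v_trig / gr$V0) / g_s
    out <- .integrate_segment(model, y, c(0, t_grow), g = g_s,
                              vt0 = gr$V0, t0 = 0, rtol = rtol, atol = atol)
    y <- out[nrow(out), -1]
    vt_start <- v_trig
  } else {
    vt_start <- if (model$has_tumor) gr$V0 else 0
  }

  t_end <- days * 86400
  if (is.null(t_out)) t_out <- seq(0, t_end, by = dt_out)
  t_out <- sort(unique(c(0, t_out[t_out <= t_end], t_end)))

  ## segment boundaries: infusion starts and stops
  events <- numeric(0)
  if (!is.null(schedule) && nrow(schedule) > 0) {
    st <- schedule$time_days * 86400
    events <- sort(unique(c(st, st + cfg$dosing$infusion_s)))
    events <- events[events > 0 & events < t_end]
  }
  bounds <- sort(unique(c(0, events, t_end)))

  inf_rate_at <- function(t) {
    if (is.null(schedule) || nrow(schedule) == 0) return(0)
    r <- 0
    for (j in seq_len(nrow(schedule))) {
      t0j <- schedule$time_days[j] * 86400
      if (t >= t0j - 1e-9 && t < t0j + cfg$dosing$infusion_s - 1e-9)
        r <- r + dose_to_input(schedule$dose_mg_kg[j],
                               cfg$dosing$body_weight_g, cfg$dosing$mw_kda,
                               cfg$geometry$blood$volume,
                               cfg$dosing$infusion_s)$rate
    }
    r
  }
  i_trap <- model$idx[["blood.fluid.Trap"]]

  rec_t <- numeric(0); rec_y <- NULL
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    rate <- inf_rate_at((t0 + t1) / 2)
    extra <- if (rate > 0) list(tgt = i_trap, rate = rate) else NULL
    tt <- sort(unique(c(t0, t_out[t_out > t0 & t_out < t1], t1)))
    vt0 <- if (model$has_tumor) vt_start * exp(g_s * t0) else 0
    out <- .integrate_segment(model, y, tt, g = g_s, vt0 = vt0, t0 = t0,
                              extra = extra, rtol = rtol, atol = atol)
    y <- out[nrow(out), -1]
    keep <- if (k == 1) seq_len(nrow(out)) else -1
    rec_t <- c(rec_t, out[keep, 1])
    rec_y <- rbind(rec_y, out[keep, -1, drop = FALSE])
  }
  sel <- rec_t %in% t_out
  structure(list(
    time = rec_t[sel],
    state = rec_y[sel, , drop = FALSE],
    tumor_volume = if (model$has_tumor) vt_start * exp(g_s * rec_t[sel])
                   else rep(0, sum(sel)),
    model = model,
    schedule = schedule),
    class = "vegf_sim")
}

#' @export
print.vegf_sim <- function(x, ...) {
  cat(sprintf("vegf_sim: %d time points over %.2f days, %d states\n",
              length(x$time), max(x$time) / 86400, ncol(x$state)))
  if (!is.null(x$schedule)) {
    cat("  doses (mg/kg at days): ",
        paste(sprintf("%g@%g", x$schedule$dose_mg_kg, x$schedule$time_days),
              collapse = ", "), "\n")
  }
  invisible(x)
}
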