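test_that("zero secretion with zero initial VEGF stays identically zero", {
  cfg <- default_config()
  cfg$secretion$q_muscle <- 0
  cfg$secretion$q_EC <- 0
  cfg$secretion$q_tumor <- 0
  m <- vegf_model(cfg)
  ss <- suppressWarnings(steady_state(m, t_max = 1e7))
  iso_ids <- m$species$id[m$species$name %in%
                            c("mV120", "mV164", "hV121", "hV165")]
  expect_true(all(abs(ss[iso_ids]) < 1e-30))
})

test_that("closed ligand-receptor pair settles to the Kd equilibrium", {
  kon <- 3e7; koff <- 1e-3
  cfg <- closed_config(kon, koff)
  m <- vegf_model(cfg)
  y <- m$y0
  v0 <- 5e-15   # 5 pM free ligand, mol/cm^3
  y["t1.fluid.mV120"] <- v0
  r0 <- y[["t1.cell.VEGFR1"]]
  out <- vegftrap:::.integrate_segment(m, y, c(0, 1e6))
  yf <- out[nrow(out), -1]
  # analytic oracle: C solves kon'(V0-C)(R0-C) = koff C
  konp <- kon * 1000
  kd <- koff / konp
  disc <- (v0 + r0 + kd)^2 - 4 * v0 * r0
  c_an <- ((v0 + r0 + kd) - sqrt(disc)) / 2
  expect_equal(yf[["t1.cell.mV120.VEGFR1"]], c_an, tolerance = 1e-6)
  # mass conserved in the closed pair
  expect_equal(yf[["t1.fluid.mV120"]] + yf[["t1.cell.mV120.VEGFR1"]], v0,
               tolerance = 1e-9)
})

test_that("growth-only dynamics conserve amounts while diluting", {
  cfg <- default_config()
  cfg$kinetics$kon[] <- 0; cfg$kinetics$koff[] <- 0
  cfg$secretion[c("q_muscle", "q_EC", "q_tumor", "q_sR1_EC")] <- 0
  cfg$transport$k_p$normal[] <- 0; cfg$transport$k_p$tumor[] <- 0
  cfg$transport$k_L[] <- 0; cfg$transport$k_deg <- 0
  cfg$transport$clearance[] <- 0
  cfg$trafficking[c("k_int", "k_rec", "k_ins", "k_deg_endo")] <- 0
  cfg$soluble$a2m_native_M <- 0; cfg$soluble$a2m_fast_M <- 0
  m <- vegf_model(cfg)
  y <- m$y0
  y["tumor.fluid.mV164"] <- 1e-15
  g <- 1e-5; v0 <- 1e-3
  out <- vegftrap:::.integrate_segment(m, y, seq(0, 2e5, by = 5e4),
                                       g = g, vt0 = v0, t0 = 0)
  vt <- v0 * exp(g * out[, 1])
  conc <- out[, "tumor.fluid.mV164"]
  # concentration falls as V0/V(t); amount C*V stays constant
  expect_equal(conc, 1e-15 * v0 / vt, tolerance = 1e-8)
  expect_equal(conc * vt, rep(1e-15 * v0, length(vt)), tolerance = 1e-8)
  # surface-bound tumor species dilute identically
  rec <- out[, "tumor.tumor_cell.VEGFR1"]
  expect_equal(rec * vt, rep(y[["tumor.tumor_cell.VEGFR1"]] * v0,
                             length(vt)), tolerance = 1e-8)
})

test_that("dose-to-input arithmetic and limits are exact", {
  # 2.5 mg/kg in a 25 g mouse at 115 kDa delivers 0.543 nmol
  expect_equal(dose_to_input(2.5, 25, 115, 1, 60)$moles, 0.543e-9,
               tolerance = 1e-3)
  # dose linearity: 25 vs 0.5 mg/kg is exactly 50x
  expect_equal(dose_to_input(25)$moles / dose_to_input(0.5)$moles, 50)
  # zero-duration limit is the bolus increment dose*BW/(MW*V_plasma)
  b <- dose_to_input(2.5, duration_s = 0)
  expect_identical(b$rate, Inf)
  expect_equal(b$bolus_conc, dose_to_input(2.5)$moles / 1)
  expect_error(dose_to_input(2.5, mw_kda = 0), "positive")
})

test_that("drug mass is audited to solver tolerance after one bolus", {
  m <- xeno_model()
  sim <- simulate(m, schedule = dose_schedule(2.5, 0), days = 7,
                  init = xeno_ss())
  aud <- drug_mass_audit(sim)
  delivered <- dose_to_input(2.5)$moles
  post <- aud[sim$time > m$config$dosing$infusion_s]
  expect_equal(max(post), delivered, tolerance = 1e-6)
  expect_lt((max(post) - min(post)) / delivered, 1e-6)
})

test_that("trajectories stay non-negative", {
  m <- xeno_model()
  sim <- simulate(m, schedule = dose_schedule(10), days = 14,
                  init = xeno_ss())
  expect_gt(min(sim$state), -1e-27)  # -1e-12 pM
})

test_that("the alpha-2-macroglobulin balance holds at steady state", {
  ss <- xeno_ss()
  # synthesis = clearance x target by construction
  expect_equal(ss[["blood.fluid.a2Mn"]] * 1e9, 1.4, tolerance = 1e-3)
  expect_equal(ss[["blood.fluid.a2Mf"]] * 1e12, 14, tolerance = 1e-3)
})

test_that("steady state is invariant under further integration", {
  m <- xeno_model()
  ss <- xeno_ss()
  out <- vegftrap:::.integrate_segment(m, ss, c(0, 1e6),
                                       vt0 = m$config$growth$V0)
  yf <- out[nrow(out), -1]
  keep <- names(ss) != "audit.cleared_trap"
  rel <- abs(yf[keep] - ss[keep]) / (abs(ss[keep]) + 1e-22)
  expect_lt(max(rel), 1e-6)
})

test_that("free VEGF responds near-linearly to secretion at low occupancy", {
  cfg <- default_config()
  m1 <- xeno_model()
  ss1 <- xeno_ss()
  cfg$secretion$q_muscle <- cfg$secretion$q_muscle * 2
  cfg$secretion$q_EC <- cfg$secretion$q_EC * 2
  cfg$secretion$q_tumor <- cfg$secretion$q_tumor * 2
  m2 <- vegf_model(cfg)
  ss2 <- steady_state(m2)
  for (id in c("blood.fluid.mV164", "normal.fluid.mV164",
               "tumor.fluid.hV165"))
    expect_equal(ss2[[id]] / ss1[[id]], 2, tolerance = 0.1)
})

test_that("receptor totals are conserved under binding-only dynamics", {
  cfg <- default_config()
  cfg$trafficking[c("k_int", "k_rec", "k_ins", "k_deg_endo")] <- 0
  m <- vegf_model(cfg)
  y <- m$y0
  y["normal.fluid.mV164"] <- 1e-15
  y["blood.fluid.mV120"] <- 1e-15
  out <- vegftrap:::.integrate_segment(m, y, c(0, 1e5, 1e6),
                                       vt0 = cfg$growth$V0)
  total_r1 <- function(yy, surf) {
    ids <- m$species$id[m$species$locale == surf &
                          grepl("VEGFR1", m$species$name) &
                          !grepl("sR1\\.", m$species$name)]
    sum(yy[ids])
  }
  for (surf in c("myocyte", "ec_abluminal", "ec_luminal_normal")) {
    t0 <- total_r1(y, surf)
    tf <- total_r1(out[nrow(out), -1], surf)
    expect_equal(tf, t0, tolerance = 1e-8)
  }
})

test_that("three-compartment model with tumor disabled matches a native
           two-compartment build", {
  cfg3 <- default_config()
  cfg3$growth$V0 <- 0
  cfg3$growth$trigger_volume <- 0
  cfg3$growth$rate[] <- 0
  m3 <- vegf_model(cfg3)
  m2 <- normal_model()
  ss3 <- suppressWarnings(steady_state(m3, v_tumor = 0, t_max = 1e9))
  ss2 <- suppressWarnings(steady_state(m2, t_max = 1e9))
  shared <- intersect(m2$species$id, m3$species$id)
  expect_gte(length(shared), m2$n_state - 1L)
  sched <- dose_schedule(2.5, c(0, 3.5))
  s3 <- simulate(m3, schedule = sched, days = 7, init = ss3, atol = 1e-24)
  s2 <- simulate(m2, schedule = sched, days = 7, init = ss2, atol = 1e-24)
  err <- vapply(shared, function(id) {
    a <- s3$state[, id]; b <- s2$state[, id]
    max(abs(a - b)) / (max(abs(b)) + 1e-22)
  }, numeric(1))
  expect_lt(max(err), 1e-4)
})
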