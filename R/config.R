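#' Surface specification helper
#'
#' @param receptors receptor ids among `VEGFR1`, `VEGFR2`, `NRP1`, `NRP2`.
#' @param r1_nrp_coupling generate VEGFR1-NRP coupling species/reactions.
#' @param ligated_r1_nrp also allow VEGF on the coupled VEGFR1-NRP.
#' @param sr1_nrp soluble VEGFR1 binds NRP on this surface.
#' @param v_sr1_nrp VEGF/sVEGFR1 complex anchors to NRP: `FALSE`, `TRUE`
#'   (all isoforms) or `"hb"` (heparin-binding isoforms, attachment via
#'   the VEGF heparin domain).
#' @param trafficking track endosomal and recycling pools as explicit
#'   species (endothelial beds).
#' @param densities named numeric, receptors per cell.
#' @param cells_per_cm3 cell density (per cm^3 of the reference volume
#'   of the compartment the surface faces).
#' @param cell_type one of `"myocyte"`, `"ec"`, `"tumor_cell"`; selects
#'   the secretion rule applied to the surface.
#' @param ref_volume `"local"` when `cells_per_cm3` refers to the host
#'   compartment volume, `"tumor"` for luminal tumor endothelium whose
#'   abundance per cm^3 plasma scales with the growing tumor volume.
#' @return a list suitable for the `surfaces` block of a network config.
#' @export
surface_spec <- function(receptors,
                         r1_nrp_coupling = FALSE,
                         ligated_r1_nrp = FALSE,
                         sr1_nrp = FALSE,
                         v_sr1_nrp = FALSE,
                         trafficking = FALSE,
                         densities = NULL,
                         cells_per_cm3 = NULL,
                         cell_type = "ec",
                         ref_volume = "local") {
  list(receptors = receptors,
       r1_nrp_coupling = r1_nrp_coupling,
       ligated_r1_nrp = ligated_r1_nrp,
       sr1_nrp = sr1_nrp,
       v_sr1_nrp = v_sr1_nrp,
       trafficking = trafficking,
       densities = densities,
       cells_per_cm3 = cells_per_cm3,
       cell_type = match.arg(cell_type, c("ec", "myocyte", "tumor_cell")),
       ref_volume = match.arg(ref_volume, c("local", "tumor")))
}

#' Default kinetic rate table
#'
#' Association/dissociation rates per interaction class.  These are
#' prior-model defaults: the structural network and the printed
#' geometric values are the package's correctness surface, while every
#' rate here is overridable through the configuration.  Rates are keyed
#' by interaction class, not by species origin: mouse/human
#' cross-species pairings use the same class rates.  The two
#' association routes of the VEGFR2-NRP coupled complex are chosen so
#' the thermodynamic cycle is exactly balanced
#' (Kd(V-R2) Kd(R2N) = Kd(V-N) Kd(R2Nb)).
#'
#' @return data.frame with columns `class`, `kon` (1/M/s), `koff` (1/s).
#' @export
default_kinetics <- function() {
  data.frame(
    class = c("V-R1", "V-R2", "V-N", "R2N", "R2Nb", "R1N",
              "V-GAG", "V-sR1", "sR1-N", "VsR1-N",
              "V-Trap", "V-a2Mn", "V-a2Mf"),
    kon = c(3e7, 1e7, 3.2e6, 3.2e6, 1e7, 3.1e6,
            4.2e5, 3e7, 3.2e6, 3.2e6,
            1e7, 1e3, 1e5),
    koff = c(1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 1e-2,
             1e-2, 3e-4, 1e-3, 1e-3,
             6e-6, 1e-2, 1e-2),
    stringsAsFactors = FALSE)
}

#' Canonical model configuration of the tumor-bearing mouse
#'
#' Returns the full configuration of the three-compartment xenograft
#' model: network structure (species/reaction rules per compartment),
#' kinetic rate table, geometry, receptor and site densities, secretion,
#' transport, clearance, tumor growth, dosing and solver settings.
#' Units are declared in the comments of the shipped YAML mirror
#' (`system.file("extdata", "xenograft_mouse.yaml", package =
#' "vegftrap")`); internally lengths are cm, times s, concentrations
#' mol/cm^3.
#'
#' @param tumor logical; `FALSE` builds the two-compartment
#'   (non-tumor-bearing) configuration: the tumor compartment and the
#'   tumor endothelial bed are removed.
#' @return a list of class `vegf_config`.
#' @export
default_config <- function(tumor = TRUE) {
  ec_receptors <- c(VEGFR1 = 3750, VEGFR2 = 300, NRP1 = 20000)
  ec_tumor_receptors <- c(VEGFR1 = 3750, VEGFR2 = 5000, NRP1 = 35000)
  geom_tumor <- derive_tumor_geometry()
  tumor_cells_cm3 <- geom_tumor$composition$f_parenchymal /
    (geom_tumor$cell$volume * 1e-12)
  ec_area_cm2 <- 1e-5   # ~1000 um^2 apparent surface per EC
  tumor_ec_cm3 <- geom_tumor$composition$S_EC / ec_area_cm2
  V_normal <- 20     # cm^3
  V_plasma <- 1      # cm^3
  S_EC_normal <- 70  # cm^2 vessel surface per cm^3 normal tissue
  normal_ec_cm3 <- S_EC_normal / ec_area_cm2
  normal_bed_luminal_cm3 <- normal_ec_cm3 * V_normal / V_plasma

  comps <- list(
    normal = list(
      type = "tissue",
      fluid = list(trap = TRUE, svegfr1 = TRUE, a2m = FALSE),
      matrix_regions = c("ECM", "EBM", "PBM"),
      surfaces = list(
        myocyte = surface_spec(
          c("VEGFR1", "VEGFR2", "NRP1"),
          densities = c(VEGFR1 = 10000, VEGFR2 = 4500, NRP1 = 40000),
          cells_per_cm3 = 6.3e4, cell_type = "myocyte"),
        ec_abluminal = surface_spec(
          c("VEGFR1", "VEGFR2", "NRP1"),
          densities = ec_receptors,
          cells_per_cm3 = normal_ec_cm3))),
    blood = list(
      type = "blood",
      fluid = list(trap = TRUE, svegfr1 = TRUE, a2m = TRUE),
      matrix_regions = character(0),
      surfaces = list(
        ec_luminal_normal = surface_spec(
          c("VEGFR1", "VEGFR2", "NRP1"),
          r1_nrp_coupling = TRUE, sr1_nrp = TRUE, trafficking = TRUE,
          densities = ec_receptors,
          cells_per_cm3 = normal_bed_luminal_cm3),
        ec_luminal_tumor = surface_spec(
          c("VEGFR1", "VEGFR2", "NRP1"),
          r1_nrp_coupling = TRUE, sr1_nrp = TRUE, trafficking = TRUE,
          densities = ec_tumor_receptors,
          # per cm^3 tumor; scaled by V_tumor/V_plasma at assembly
          cells_per_cm3 = tumor_ec_cm3, ref_volume = "tumor"))),
    tumor = list(
      type = "tissue",
      fluid = list(trap = TRUE, svegfr1 = TRUE, a2m = FALSE),
      matrix_regions = c("ECM", "EBM", "PBM"),
      surfaces = list(
        tumor_cell = surface_spec(
          c("VEGFR1", "VEGFR2", "NRP1", "NRP2"),
          r1_nrp_coupling = TRUE, ligated_r1_nrp = TRUE,
          sr1_nrp = TRUE, v_sr1_nrp = "hb",
          densities = c(VEGFR1 = 1100, VEGFR2 = 550,
                        NRP1 = 35000, NRP2 = 35000),
          cells_per_cm3 = tumor_cells_cm3, cell_type = "tumor_cell"),
        ec_abluminal = surface_spec(
          c("VEGFR1", "VEGFR2", "NRP1"),
          r1_nrp_coupling = TRUE, ligated_r1_nrp = TRUE,
          densities = ec_tumor_receptors,
          cells_per_cm3 = tumor_ec_cm3))))
  if (!tumor) {
    comps$tumor <- NULL
    comps$blood$surfaces$ec_luminal_tumor <- NULL
  }

  cfg <- list(
    name = if (tumor) "xenograft_mouse" else "normal_mouse",
    network = list(
      isoforms = list(mouse = c("mV120", "mV164"),
                      human = if (tumor) c("hV121", "hV165") else character(0)),
      heparin_binding = if (tumor) c("mV164", "hV165") else "mV164",
      compartments = comps),
    kinetics = default_kinetics(),
    geometry = list(
      normal = list(volume = V_normal, K_av = 0.10, S_EC = S_EC_normal,
                    region_avail = list(ECM = 0.065, EBM = 0.005,
                                        PBM = 0.030)),
      blood = list(volume = V_plasma),
      tumor = if (tumor) list(
        primitives = list(),   # overrides for derive_tumor_geometry()
        derived = geom_tumor,
        K_av = geom_tumor$interstitium$K_av,
        S_EC = geom_tumor$composition$S_EC) else NULL),
    sites = list(
      # GAG binding-site concentration, uM in region fluid
      gag_uM = c(ECM = 0.75, EBM = 13, PBM = 13)),
    secretion = list(
      q_muscle = 0.011,     # molecules/cell/s, A673 baseline estimates
      q_EC = 0.009,
      q_tumor = 0.009,
      q_sR1_EC = 6e-3,
      split_muscle = c(0.08, 0.92),   # VEGF120:VEGF164
      split_EC = c(0.10, 0.90),
      split_tumor = c(0.50, 0.50)),   # VEGF121:VEGF165
    transport = list(
      # microvascular permeability, cm/s, per species class and interface
      k_p = list(
        normal = c(V = 4e-8, Trap = 3e-8, TrapV = 3e-8,
                   sR1 = 1.5e-8, VsR1 = 1.5e-8),
        tumor = c(V = 4e-7, Trap = 3e-7, TrapV = 3e-7,
                  sR1 = 1.5e-7, VsR1 = 1.5e-7)),
      k_L = c(normal = 7.1e-7, tumor = 0),  # lymph, cm^3/s per cm^3 tissue
      clearance = c(V = 2.3e-4, Trap = 1.3e-5, TrapV = 2.5e-6,
                    sR1 = 6.6e-4, a2m = 4.37e-5),  # 1/s
      k_deg = 1e-4),          # proteolysis of free tissue VEGF, 1/s
    trafficking = list(
      k_int = 2.8e-4,   # surface internalization, 1/s
      k_rec = 5e-4,     # endosome -> recycling, 1/s
      k_ins = 1e-3,     # recycling -> surface, 1/s
      k_deg_endo = 5e-4 # endosomal degradation, 1/s
    ),
    soluble = list(
      a2m_native_M = 1.4e-6,  # plasma concentration, mol/L
      a2m_fast_M = 1.4e-8),
    growth = list(
      V0 = 1e-6,              # cm^3 at inoculation
      trigger_volume = 0.1,   # cm^3 (~100 mm^3) before first dose
      profile = "average",
      # exponential rate constants, 1/day: average reaches 100 mm^3 in
      # 14 days from 1e-6 cm^3, fast in 10 days
      rate = c(average = log(1e5) / 14, fast = log(1e5) / 10)),
    dosing = list(
      body_weight_g = 25,
      mw_kda = 115,
      infusion_s = 60),
    solver = list(rtol = 1e-8, atol = 1e-21, method = "lsoda"))
  class(cfg) <- "vegf_config"
  cfg
}

#' @export
print.vegf_config <- function(x, ...) {
  cat(sprintf("VEGF compartment model configuration '%s'\n", x$name))
  cat(sprintf("  compartments: %s\n",
              paste(names(x$network$compartments), collapse = ", ")))
  cat(sprintf("  isoforms: %s\n",
              paste(c(x$network$isoforms$mouse, x$network$isoforms$human),
                    collapse = ", ")))
  invisible(x)
}
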