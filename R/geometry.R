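#' Geometry of a spherical cell
#'
#' Volume and surface area of a sphere of the given diameter.  Tumor
#' cells are taken to have the volume of a 12 um diameter sphere
#' (roughly 905 um^3, surface 452 um^2), matching MCF-7 breast tumor
#' cell measurements.
#'
#' @param diameter cell diameter in micrometres (> 0).
#' @return an object of class `cell_geometry` with fields `diameter`,
#'   `volume` (um^3), `surface_area` (um^2) and `shape = "sphere"`.
#' @examples
#' sphere_geometry(12)
#' @export
sphere_geometry <- function(diameter) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L)
  if (!is.finite(diameter) || diameter <= 0)
    stop("'diameter' must be a positive finite number", call. = FALSE)
  structure(
    list(diameter = diameter,
         volume = pi * diameter^3 / 6,
         surface_area = pi * diameter^2,
         shape = "sphere"),
    class = "cell_geometry")
}

#' Surface area of a regular dodecahedron of given volume
#'
#' Since tumor cells are not spherical, the cell surface is modelled as
#' a regular dodecahedron with the same volume as the measured sphere.
#' For edge length a, V = (15 + 7 sqrt(5)) / 4 * a^3 and
#' A = 3 sqrt(25 + 10 sqrt(5)) * a^2; the area follows from inverting
#' the volume relation.  A 905 um^3 cell has a dodecahedral surface of
#' about 497 um^2.
#'
#' @param volume cell volume in um^3 (> 0).
#' @return surface area in um^2.
#' @examples
#' dodecahedron_surface_from_volume(905)
#' @export
dodecahedron_surface_from_volume <- function(volume) {
  stopifnot(is.numeric(volume), length(volume) == 1L)
  if (!is.finite(volume) || volume <= 0)
    stop("'volume' must be a positive finite number", call. = FALSE)
  a <- (4 * volume / (15 + 7 * sqrt(5)))^(1 / 3)
  3 * sqrt(25 + 10 * sqrt(5)) * a^2
}

#' Dodecahedral cell of a given volume
#'
#' @param volume cell volume in um^3.
#' @return a `cell_geometry` with `shape = "dodecahedron"`; the
#'   `diameter` field is the diameter of the equal-volume sphere.
#' @export
dodecahedron_geometry <- function(volume) {
  structure(
    list(diameter = (6 * volume / pi)^(1 / 3),
         volume = volume,
         surface_area = dodecahedron_surface_from_volume(volume),
         shape = "dodecahedron"),
    class = "cell_geometry")
}

#' Capillary cross-section and perimeter geometry
#'
#' Microvessels are modelled as cylinders of the given luminal diameter
#' and endothelial wall thickness; because tumor capillaries are not
#' circular in cross-section, the outer perimeter is increased by an
#' empirical correction (23% in breast cancer capillaries).
#'
#' @param lumen_diameter luminal diameter in um.
#' @param wall_thickness endothelial cell thickness in um.
#' @param perimeter_correction fractional increase of true perimeter
#'   over the circular perimeter (default 0.23).
#' @return an object of class `capillary_geometry` with cross-sections
#'   (um^2) and perimeters (um).
#' @examples
#' capillary_geometry(13.94, 0.5)
#' @export
capillary_geometry <- function(lumen_diameter, wall_thickness,
                               perimeter_correction = 0.23) {
  stopifnot(lumen_diameter > 0, wall_thickness >= 0,
            perimeter_correction >= 0)
  outer_d <- lumen_diameter + 2 * wall_thickness
  lumen_cs <- pi * lumen_diameter^2 / 4
  outer_cs <- pi * outer_d^2 / 4
  perim_circ <- pi * outer_d
  structure(
    list(lumen_diameter = lumen_diameter,
         wall_thickness = wall_thickness,
         lumen_cross_section = lumen_cs,
         outer_cross_section = outer_cs,
         wall_cross_section = outer_cs - lumen_cs,
         outer_perimeter_circular = perim_circ,
         perimeter_correction = perimeter_correction,
         true_perimeter = perim_circ * (1 + perimeter_correction)),
    class = "capillary_geometry")
}

#' Capillary density from intravascular volume fraction
#'
#' With well-mixed vasculature the number of capillaries crossing a
#' unit tissue area equals the intravascular volume fraction divided by
#' the luminal cross-sectional area of one vessel.
#'
#' @param lumen_cross_section luminal cross-section of one capillary (um^2).
#' @param f_intravascular intravascular volume fraction, in `[0, 1)`.
#' @return capillary density in capillaries per mm^2.
#' @examples
#' capillary_density(pi * 13.94^2 / 4, 0.10)  # ~655 / mm^2
#' @export
capillary_density <- function(lumen_cross_section, f_intravascular) {
  stopifnot(is.numeric(lumen_cross_section), is.numeric(f_intravascular))
  if (any(lumen_cross_section <= 0))
    stop("'lumen_cross_section' must be positive", call. = FALSE)
  if (any(f_intravascular < 0 | f_intravascular >= 1))
    stop("'f_intravascular' must be in [0, 1)", call. = FALSE)
  f_intravascular / lumen_cross_section * 1e6  # um^-2 -> mm^-2
}

#' Vessel and parenchymal-cell surface densities
#'
#' Total endothelial (abluminal vessel) and parenchymal-cell surface
#' area per unit tissue volume.  S_EC is the true vessel perimeter
#' times the capillary density; S_PC is the parenchymal volume fraction
#' divided by the cell volume, times the cell surface area.
#'
#' @param capillary a [capillary_geometry()] object.
#' @param density capillary density (per mm^2).
#' @param cell a `cell_geometry` object for the parenchymal cell.
#' @param f_parenchymal parenchymal (cell) volume fraction of tissue.
#' @return list with `S_EC` and `S_PC` in cm^2 per cm^3 tissue, and
#'   `f_EC_wall`, the tissue volume fraction occupied by the
#'   endothelial wall.
#' @export
surface_densities <- function(capillary, density, cell, f_parenchymal) {
  stopifnot(inherits(capillary, "capillary_geometry"),
            inherits(cell, "cell_geometry"),
            density >= 0, f_parenchymal >= 0, f_parenchymal <= 1)
  dens_cm2 <- density * 100          # mm^-2 -> cm^-2
  perim_cm <- um_to_cm(capillary$true_perimeter)
  wall_cm2 <- capillary$wall_cross_section * 1e-8   # um^2 -> cm^2
  list(S_EC = perim_cm * dens_cm2,
       S_PC = f_parenchymal / (cell$volume * 1e-12) * (cell$surface_area * 1e-8),
       f_EC_wall = wall_cm2 * dens_cm2)
}

#' Available fluid volumes of the interstitial sub-regions
#'
#' The interstitium is split into extracellular matrix (ECM) and the
#' endothelial and parenchymal basement membranes (EBM, PBM).  Each
#' region is a porous medium; the volume available to VEGF is the
#' product of the region volume fraction, its fluid (non-collagen)
#' fraction, and a steric partition coefficient.
#'
#' @param regions a data.frame with columns `region`, `volume_fraction`,
#'   `fluid_fraction`, `partition_coefficient` (one row per region, all
#'   fractions in `[0, 1]`, volume fractions in cm^3/cm^3 tissue).
#' @param f_interstitial total interstitial volume fraction; the region
#'   volume fractions must not exceed it (a tolerance of 1e-6 is allowed).
#' @return the input data.frame with an `available_fluid_volume` column
#'   (cm^3/cm^3 tissue) appended.
#' @examples
#' interstitial_partition(data.frame(
#'   region = c("ECM", "EBM", "PBM"),
#'   volume_fraction = c(0.3404, 0.0081, 0.0015),
#'   fluid_fraction = c(0.9318, 0.7, 0.7),
#'   partition_coefficient = c(0.9, 0.9, 0.9)), f_interstitial = 0.35)
#' @export
interstitial_partition <- function(regions, f_interstitial = sum(regions$volume_fraction)) {
  need <- c("region", "volume_fraction", "fluid_fraction", "partition_coefficient")
  if (!all(need %in% names(regions)))
    stop("'regions' must have columns ", paste(need, collapse = ", "), call. = FALSE)
  frac <- regions[, c("volume_fraction", "fluid_fraction", "partition_coefficient")]
  if (any(frac < 0 | frac > 1))
    stop("fractions and partition coefficients must lie in [0, 1]", call. = FALSE)
  if (sum(regions$volume_fraction) > f_interstitial + 1e-6)
    stop("region volume fractions sum above 'f_interstitial'", call. = FALSE)
  regions$available_fluid_volume <-
    regions$volume_fraction * regions$fluid_fraction * regions$partition_coefficient
  regions
}

#' Derive tumor-compartment geometry from primitive measurements
#'
#' Carries the full chain of geometric derivations for the tumor
#' compartment: cell volume and dodecahedral surface from the measured
#' cell diameter, capillary cross-sections and corrected perimeter,
#' capillary density from the intravascular volume fraction,
#' endothelial wall volume fraction, parenchymal fraction as the
#' remainder, vessel and tumor-cell surface densities, and the
#' available fluid volumes of the interstitial sub-regions.
#' Intermediates are kept unrounded; printed values such as 57.7 um or
#' 655 per mm^2 emerge as roundings.
#'
#' @param cell_diameter tumor cell diameter (um), default 12.
#' @param lumen_diameter capillary luminal diameter (um), default 13.94.
#' @param wall_thickness endothelial thickness (um), default 0.5.
#' @param perimeter_correction perimeter correction fraction, default 0.23.
#' @param f_extracellular_fluid extracellular fluid volume fraction,
#'   default 0.45 (split into interstitial and intravascular space).
#' @param f_intravascular intravascular volume fraction, default 0.10.
#' @param ebm_thickness_nm,pbm_thickness_nm basement membrane
#'   thicknesses (nm), defaults 50 and 30; used only for reporting.
#' @param ebm_fraction,pbm_fraction basement membrane volume fractions
#'   (cm^3/cm^3 tissue), defaults 0.0081 and 0.0015.
#' @param fluid_fraction_bm,fluid_fraction_ecm fluid (non-collagen)
#'   fractions of basement membranes and ECM, defaults 0.7 and 0.9318.
#' @param partition_coefficient steric partition coefficient, default 0.9.
#' @return an object of class `tumor_geometry`: a list with elements
#'   `cell`, `capillary`, `composition` (volume fractions, capillary
#'   density, `S_EC`, `S_PC`), and `interstitium` (the region table with
#'   available fluid volumes and their total `K_av`).
#' @examples
#' g <- derive_tumor_geometry()
#' g$composition$capillary_density_mm2   # ~655
#' @export
derive_tumor_geometry <- function(cell_diameter = 12,
                                  lumen_diameter = 13.94,
                                  wall_thickness = 0.5,
                                  perimeter_correction = 0.23,
                                  f_extracellular_fluid = 0.45,
                                  f_intravascular = 0.10,
                                  ebm_thickness_nm = 50,
                                  pbm_thickness_nm = 30,
                                  ebm_fraction = 0.0081,
                                  pbm_fraction = 0.0015,
                                  fluid_fraction_bm = 0.7,
                                  fluid_fraction_ecm = 0.9318,
                                  partition_coefficient = 0.9) {
  sphere <- sphere_geometry(cell_diameter)
  cell <- dodecahedron_geometry(sphere$volume)
  cap <- capillary_geometry(lumen_diameter, wall_thickness, perimeter_correction)
  dens <- capillary_density(cap$lumen_cross_section, f_intravascular)
  f_interstitial <- f_extracellular_fluid - f_intravascular
  # wall fraction needs the density; parenchyma is the remainder
  wall <- cap$wall_cross_section * 1e-8 * dens * 100
  f_parenchymal <- 1 - f_intravascular - wall - f_interstitial
  sd <- surface_densities(cap, dens, cell, f_parenchymal)
  ecm_fraction <- f_interstitial - ebm_fraction - pbm_fraction
  regions <- interstitial_partition(
    data.frame(region = c("ECM", "EBM", "PBM"),
               volume_fraction = c(ecm_fraction, ebm_fraction, pbm_fraction),
               fluid_fraction = c(fluid_fraction_ecm, fluid_fraction_bm,
                                  fluid_fraction_bm),
               partition_coefficient = rep(partition_coefficient, 3)),
    f_interstitial = f_interstitial)
  structure(
    list(cell = cell,
         sphere = sphere,
         capillary = cap,
         composition = list(
           f_extracellular_fluid = f_extracellular_fluid,
           f_intravascular = f_intravascular,
           f_EC_wall = wall,
           f_parenchymal = f_parenchymal,
           f_interstitial = f_interstitial,
           capillary_density_mm2 = dens,
           S_EC = sd$S_EC,
           S_PC = sd$S_PC),
         interstitium = list(
           regions = regions,
           K_av = sum(regions$available_fluid_volume),
           ebm_thickness_nm = ebm_thickness_nm,
           pbm_thickness_nm = pbm_thickness_nm)),
    class = "tumor_geometry")
}

#' @export
print.tumor_geometry <- function(x, digits = 4, ...) {
  comp <- x$composition
  cat("Tumor compartment geometry\n")
  cat(sprintf("  cell: sphere d = %.4g um, V = %.4g um^3, A(sphere) = %.4g um^2, A(dodecahedron) = %.4g um^2\n",
              x$sphere$diameter, x$cell$volume, x$sphere$surface_area,
              x$cell$surface_area))
  cat(sprintf("  capillary: lumen %.4g um, wall %.4g um, true perimeter %.4g um\n",
              x$capillary$lumen_diameter, x$capillary$wall_thickness,
              x$capillary$true_perimeter))
  cat(sprintf("  capillary density: %.4g / mm^2\n", comp$capillary_density_mm2))
  cat(sprintf("  volume fractions: vascular %.3g, EC wall %.3g, parenchymal %.3g, interstitial %.3g (sum %.4g)\n",
              comp$f_intravascular, comp$f_EC_wall, comp$f_parenchymal,
              comp$f_interstitial,
              comp$f_intravascular + comp$f_EC_wall + comp$f_parenchymal +
                comp$f_interstitial))
  cat(sprintf("  surface densities: S_EC %.4g, S_PC %.4g cm^2/cm^3\n",
              comp$S_EC, comp$S_PC))
  cat("  interstitial regions:\n")
  print(x$interstitium$regions, digits = digits, row.names = FALSE)
  cat(sprintf("  total available fluid volume K_av = %.4g cm^3/cm^3\n",
              x$interstitium$K_av))
  invisible(x)
}

#' Export derived geometry to a flat table
#'
#' @param x a `tumor_geometry` object.
#' @param path optional path; when given, the table is written as CSV.
#' @return a data.frame of (quantity, value, unit) rows, invisibly when
#'   writing to `path`.
#' @export
geometry_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "tumor_geometry"))
  comp <- x$composition
  reg <- x$interstitium$regions
  df <- data.frame(
    quantity = c("cell_volume", "cell_surface_sphere", "cell_surface_dodecahedron",
                 "lumen_cross_section", "wall_cross_section", "true_perimeter",
                 "capillary_density", "f_intravascular", "f_EC_wall",
                 "f_parenchymal", "f_interstitial", "S_EC", "S_PC",
                 paste0("available_fluid_", reg$region), "K_av"),
    value = c(x$cell$volume, x$sphere$surface_area, x$cell$surface_area,
              x$capillary$lumen_cross_section, x$capillary$wall_cross_section,
              x$capillary$true_perimeter, comp$capillary_density_mm2,
              comp$f_intravascular, comp$f_EC_wall, comp$f_parenchymal,
              comp$f_interstitial, comp$S_EC, comp$S_PC,
              reg$available_fluid_volume, x$interstitium$K_av),
    unit = c("um^3", "um^2", "um^2", "um^2", "um^2", "um", "mm^-2",
             "", "", "", "", "cm^2/cm^3", "cm^2/cm^3",
             rep("cm^3/cm^3", nrow(reg)), "cm^3/cm^3"))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
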