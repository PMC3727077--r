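#' Species naming conventions
#'
#' Species identifiers are `<compartment>.<locale>[.<pool>].<name>`,
#' e.g. `normal.fluid.mV120`, `tumor.ECM.mV164.GAG`,
#' `blood.ec_luminal_normal.endosome.VEGFR1`.  Complex names join the
#' component names with `.` in ligand-receptor-coreceptor order.
#' Enumeration order is: compartment (configuration order), locale
#' (fluid, matrix regions, surfaces, each in configuration order),
#' pool (surface, endosome, recycling), then alphabetical name.
#' @name network-conventions
#' @keywords internal
NULL

.receptor_names <- c("VEGFR1", "VEGFR2", "NRP1", "NRP2")

.is_nrp <- function(r) r %in% c("NRP1", "NRP2")

#' Species of one cell-surface locale
#'
#' @param surface a surface configuration: list with `receptors` and the
#'   logical/character flags `r1_nrp_coupling`, `ligated_r1_nrp`,
#'   `sr1_nrp`, `v_sr1_nrp` (FALSE, TRUE, or "hb"), `trafficking`.
#' @param iso character vector of isoform names.
#' @param hb heparin-binding subset of `iso`.
#' @return character vector of species names (no compartment prefix).
#' @keywords internal
.surface_species <- function(surface, iso, hb) {
  rec <- surface$receptors
  bad <- setdiff(rec, .receptor_names)
  if (length(bad))
    stop("unknown receptor id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  nrps <- rec[.is_nrp(rec)]
  out <- rec
  if ("VEGFR1" %in% rec) out <- c(out, paste0(iso, ".VEGFR1"))
  if ("VEGFR2" %in% rec) out <- c(out, paste0(iso, ".VEGFR2"))
  for (np in nrps) {
    out <- c(out, paste0(hb, ".", np))
    if ("VEGFR2" %in% rec)
      out <- c(out, paste0(hb, ".VEGFR2.", np))
    if ("VEGFR1" %in% rec && isTRUE(surface$r1_nrp_coupling)) {
      out <- c(out, paste0("VEGFR1.", np))
      if (isTRUE(surface$ligated_r1_nrp))
        out <- c(out, paste0(iso, ".VEGFR1.", np))
    }
    if (isTRUE(surface$sr1_nrp)) {
      out <- c(out, paste0("sR1.", np))
      vs <- surface$v_sr1_nrp
      if (identical(vs, "hb")) out <- c(out, paste0(hb, ".sR1.", np))
      else if (isTRUE(vs)) out <- c(out, paste0(iso, ".sR1.", np))
    }
  }
  sort(out)
}

.fluid_species <- function(fluid, iso) {
  out <- iso
  if (isTRUE(fluid$trap)) out <- c(out, "Trap", paste0(iso, ".Trap"))
  if (isTRUE(fluid$svegfr1)) out <- c(out, "sR1", paste0(iso, ".sR1"))
  if (isTRUE(fluid$a2m))
    out <- c(out, "a2Mn", "a2Mf", paste0(iso, ".a2Mn"), paste0(iso, ".a2Mf"))
  sort(out)
}

.matrix_species <- function(hb) sort(c("GAG", paste0(hb, ".GAG")))

#' Enumerate all molecular species of a configured network
#'
#' Walks the compartment/locale structure of a model configuration and
#' produces the deterministic, ordered species list together with a
#' manifest of per-compartment counts.  The enumeration is a pure
#' function of the configuration: repeated calls give identical output.
#'
#' @param config a model configuration (see [default_config()]); only
#'   the `network` block is used.
#' @return an object of class `vegf_network_species`: a list with
#'   `species` (data.frame with columns `id`, `compartment`, `locale`,
#'   `pool`, `name`) and `manifest` (class `vegf_manifest`).
#' @examples
#' sp <- enumerate_species(default_config())
#' sp$manifest$counts   # c(normal = 53, blood = 126, tumor = 79)
#' @export
enumerate_species <- function(config) {
  net <- config$network
  iso <- c(net$isoforms$mouse, net$isoforms$human)
  hb <- net$heparin_binding
  if (!all(hb %in% iso))
    stop("heparin_binding must be a subset of the active isoforms", call. = FALSE)
  rows <- list()
  add <- function(compartment, locale, pool, names) {
    if (!length(names)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      compartment = compartment, locale = locale, pool = pool,
      name = names, stringsAsFactors = FALSE)
  }
  for (cname in names(net$compartments)) {
    comp <- net$compartments[[cname]]
    add(cname, "fluid", "main", .fluid_species(comp$fluid, iso))
    for (reg in comp$matrix_regions)
      add(cname, reg, "main", .matrix_species(hb))
    for (sname in names(comp$surfaces)) {
      surf <- comp$surfaces[[sname]]
      sp <- .surface_species(surf, iso, hb)
      add(cname, sname, "surface", sp)
      if (isTRUE(surf$trafficking)) {
        add(cname, sname, "endosome", sp)
        add(cname, sname, "recycling", sp)
      }
    }
  }
  species <- do.call(rbind, rows)
  species$id <- ifelse(
    species$pool %in% c("main", "surface"),
    paste(species$compartment, species$locale, species$name, sep = "."),
    paste(species$compartment, species$locale, species$pool, species$name,
          sep = "."))
  species <- species[, c("id", "compartment", "locale", "pool", "name")]
  if (anyDuplicated(species$id))
    stop("internal error: duplicated species ids", call. = FALSE)
  counts <- vapply(names(net$compartments),
                   function(cn) sum(species$compartment == cn), integer(1))
  manifest <- structure(
    list(counts = counts, total = nrow(species),
         locale_counts = stats::aggregate(
           list(n = seq_len(nrow(species))),
           by = list(compartment = species$compartment,
                     locale = species$locale, pool = species$pool),
           FUN = length),
         hash = .manifest_hash(species$id)),
    class = "vegf_manifest")
  structure(list(species = species, manifest = manifest),
            class = "vegf_network_species")
}

# Polynomial rolling hash over the concatenated species ids (mod
# 2^31 - 1); stable across platforms, used only as an audit fingerprint.
.manifest_hash <- function(ids) {
  bytes <- utf8ToInt(paste(ids, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.vegf_manifest <- function(x, ...) {
  cat("Network manifest\n")
  for (cn in names(x$counts))
    cat(sprintf("  %-8s %4d species\n", cn, x$counts[[cn]]))
  cat(sprintf("  total    %4d state equations (hash %s)\n", x$total, x$hash))
  invisible(x)
}

#' Print the full enumeration audit
#'
#' Lists every locale with its species count and members, so that any
#' discrepancy against published structural counts can be localized to
#' a specific compartment and locale.
#'
#' @param x a `vegf_network_species` object.
#' @param species logical; list individual species ids per locale.
#' @return `x`, invisibly.
#' @export
network_audit <- function(x, species = FALSE) {
  stopifnot(inherits(x, "vegf_network_species"))
  sp <- x$species
  print(x$manifest)
  key <- paste(sp$compartment, sp$locale, sp$pool)
  for (k in unique(key)) {
    sub <- sp[key == k, ]
    cat(sprintf("  %-10s %-22s %-10s %3d species\n",
                sub$compartment[1], sub$locale[1], sub$pool[1], nrow(sub)))
    if (species)
      cat(paste0("      ", sub$name, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
print.vegf_network_species <- function(x, ...) {
  network_audit(x, species = FALSE)
}
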