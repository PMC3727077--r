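#' Build the mass-action reaction list of a configured network
#'
#' Generates, per compartment and locale, every reaction implied by the
#' configuration: VEGF binding to VEGFR1/VEGFR2 on all surfaces for all
#' isoforms; neuropilin binding and VEGFR2-NRP coupling for the
#' heparin-binding isoforms only; VEGFR1-NRP coupling where enabled;
#' glycosaminoglycan-site binding in the matrix regions (heparin
#' binders only); soluble VEGFR1 and VEGF Trap binding in the fluid
#' phases; alpha-2-macroglobulin binding in blood; receptor
#' internalization, trafficking and insertion; secretion sources;
#' proteolytic degradation; plasma clearance; and transmembrane
#' transport/lymph descriptors used by the simulation assembly.
#'
#' Kinetic rates are looked up by interaction class in
#' `config$kinetics`; the same class is used for mouse and human
#' pairings.  Reversible binding rows carry `kon` (1/M/s) and `koff`
#' (1/s); unary rows carry a first-order `rate` (1/s); source rows a
#' zero-order `rate` (mol/cm^3/s, already divided by Avogadro's
#' number).
#'
#' @param net a `vegf_network_species` object from [enumerate_species()].
#' @param config the model configuration the species were built from.
#' @return data.frame of class `vegf_reactions` with columns `id`,
#'   `kind`, `class`, `compartment`, `r1`, `r2`, `p1`, `kon`, `koff`,
#'   `rate`, `vscale` (1 for source terms that scale with the growing
#'   tumor volume).
#' @export
build_reactions <- function(net, config) {
  stopifnot(inherits(net, "vegf_network_species"))
  sp_ids <- net$species$id
  kin <- config$kinetics
  krow <- function(class) {
    i <- match(class, kin$class)
    if (is.na(i)) stop("kinetic class '", class, "' missing from table",
                       call. = FALSE)
    kin[i, ]
  }
  netc <- config$network
  iso <- c(netc$isoforms$mouse, netc$isoforms$human)
  hb <- netc$heparin_binding
  cap <- 4096L; n_rx <- 0L
  F_kind <- F_class <- F_comp <- F_r1 <- F_r2 <- F_p1 <- character(cap)
  F_kon <- F_koff <- F_rate <- F_vs <- numeric(cap)
  emit <- function(kind, class, compartment, r1 = NA, r2 = NA, p1 = NA,
                   kon = NA, koff = NA, rate = NA, vscale = 0) {
    for (s in c(r1, r2, p1))
      if (!is.na(s) && !(s %in% sp_ids))
        stop("reaction references unknown species '", s, "'", call. = FALSE)
    n_rx <<- n_rx + 1L
    F_kind[n_rx] <<- kind; F_class[n_rx] <<- class
    F_comp[n_rx] <<- compartment
    F_r1[n_rx] <<- r1; F_r2[n_rx] <<- r2; F_p1[n_rx] <<- p1
    F_kon[n_rx] <<- kon; F_koff[n_rx] <<- koff; F_rate[n_rx] <<- rate
    F_vs[n_rx] <<- vscale
  }
  bind <- function(class, compartment, a, b, ab) {
    k <- krow(class)
    emit("binding", class, compartment, r1 = a, r2 = b, p1 = ab,
         kon = k$kon, koff = k$koff)
  }
  tr <- config$transport
  traf <- config$trafficking

  for (cn in names(netc$compartments)) {
    comp <- netc$compartments[[cn]]
    fl <- function(name) paste(cn, "fluid", name, sep = ".")

    ## fluid-phase binding
    for (v in iso) {
      if (isTRUE(comp$fluid$trap))
        bind("V-Trap", cn, fl(v), fl("Trap"), fl(paste0(v, ".Trap")))
      if (isTRUE(comp$fluid$svegfr1))
        bind("V-sR1", cn, fl(v), fl("sR1"), fl(paste0(v, ".sR1")))
      if (isTRUE(comp$fluid$a2m)) {
        bind("V-a2Mn", cn, fl(v), fl("a2Mn"), fl(paste0(v, ".a2Mn")))
        bind("V-a2Mf", cn, fl(v), fl("a2Mf"), fl(paste0(v, ".a2Mf")))
      }
    }

    ## matrix GAG binding (heparin binders only)
    for (reg in comp$matrix_regions)
      for (v in hb)
        bind("V-GAG", cn, fl(v), paste(cn, reg, "GAG", sep = "."),
             paste(cn, reg, paste0(v, ".GAG"), sep = "."))

    ## surfaces
    for (sn in names(comp$surfaces)) {
      surf <- comp$surfaces[[sn]]
      rec <- surf$receptors
      nrps <- rec[.is_nrp(rec)]
      pid <- function(name) paste(cn, sn, name, sep = ".")
      for (v in iso) {
        if ("VEGFR1" %in% rec)
          bind("V-R1", cn, fl(v), pid("VEGFR1"), pid(paste0(v, ".VEGFR1")))
        if ("VEGFR2" %in% rec)
          bind("V-R2", cn, fl(v), pid("VEGFR2"), pid(paste0(v, ".VEGFR2")))
      }
      for (np in nrps) {
        for (v in hb) {
          bind("V-N", cn, fl(v), pid(np), pid(paste0(v, ".", np)))
          if ("VEGFR2" %in% rec) {
            ab <- pid(paste0(v, ".VEGFR2.", np))
            k <- krow("R2N")
            emit("coupling", "R2N", cn, r1 = pid(paste0(v, ".VEGFR2")),
                 r2 = pid(np), p1 = ab, kon = k$kon, koff = k$koff)
            k <- krow("R2Nb")
            emit("coupling", "R2Nb", cn, r1 = pid(paste0(v, ".", np)),
                 r2 = pid("VEGFR2"), p1 = ab, kon = k$kon, koff = k$koff)
          }
        }
        if ("VEGFR1" %in% rec && isTRUE(surf$r1_nrp_coupling)) {
          k <- krow("R1N")
          emit("coupling", "R1N", cn, r1 = pid("VEGFR1"), r2 = pid(np),
               p1 = pid(paste0("VEGFR1.", np)), kon = k$kon, koff = k$koff)
          if (isTRUE(surf$ligated_r1_nrp))
            for (v in iso) {
              # both routes share the class rates of the unligated pair,
              # so the thermodynamic cycle closes exactly
              bind("V-R1", cn, fl(v), pid(paste0("VEGFR1.", np)),
                   pid(paste0(v, ".VEGFR1.", np)))
              emit("coupling", "R1N", cn, r1 = pid(paste0(v, ".VEGFR1")),
                   r2 = pid(np), p1 = pid(paste0(v, ".VEGFR1.", np)),
                   kon = krow("R1N")$kon, koff = krow("R1N")$koff)
            }
        }
        if (isTRUE(surf$sr1_nrp)) {
          bind("sR1-N", cn, fl("sR1"), pid(np), pid(paste0("sR1.", np)))
          vs <- surf$v_sr1_nrp
          vset <- if (identical(vs, "hb")) hb else if (isTRUE(vs)) iso
                  else character(0)
          for (v in vset)
            bind("VsR1-N", cn, fl(paste0(v, ".sR1")), pid(np),
                 pid(paste0(v, ".sR1.", np)))
        }
      }

      ## internalization / trafficking / insertion
      ssp <- net$species[net$species$compartment == cn &
                         net$species$locale == sn, ]
      surf_sp <- ssp$name[ssp$pool == "surface"]
      dens_conc <- surf$densities * surf$cells_per_cm3 / AVOGADRO
      vsc <- if (identical(surf$ref_volume, "tumor")) 1 else 0
      if (isTRUE(surf$trafficking)) {
        for (s in surf_sp) {
          emit("internalization", "k_int", cn, r1 = pid(s),
               p1 = paste(cn, sn, "endosome", s, sep = "."),
               rate = traf$k_int)
          emit("trafficking", "k_rec", cn,
               r1 = paste(cn, sn, "endosome", s, sep = "."),
               p1 = paste(cn, sn, "recycling", s, sep = "."),
               rate = traf$k_rec)
          emit("degradation", "k_deg_endo", cn,
               r1 = paste(cn, sn, "endosome", s, sep = "."),
               rate = traf$k_deg_endo)
          emit("insertion", "k_ins", cn,
               r1 = paste(cn, sn, "recycling", s, sep = "."),
               p1 = pid(s), rate = traf$k_ins)
        }
        # basal synthesis balancing endosomal loss at the drug-free
        # steady state of the linear trafficking chain
        syn <- if (traf$k_rec + traf$k_deg_endo > 0)
          traf$k_int * traf$k_deg_endo / (traf$k_rec + traf$k_deg_endo)
        else 0
        for (r in rec)
          emit("insertion", "synthesis", cn, p1 = pid(r),
               rate = syn * dens_conc[[r]], vscale = vsc)
      } else {
        for (s in surf_sp)
          emit("internalization", "k_int", cn, r1 = pid(s),
               rate = traf$k_int)
        for (r in rec)
          emit("insertion", "synthesis", cn, p1 = pid(r),
               rate = traf$k_int * dens_conc[[r]], vscale = vsc)
      }

      ## secretion sources
      sec <- config$secretion
      cells <- surf$cells_per_cm3
      if (identical(surf$cell_type, "myocyte")) {
        q <- sec$q_muscle; split <- sec$split_muscle
        targets <- netc$isoforms$mouse
      } else if (identical(surf$cell_type, "tumor_cell")) {
        q <- sec$q_tumor; split <- sec$split_tumor
        targets <- netc$isoforms$human
      } else {
        q <- sec$q_EC; split <- sec$split_EC
        targets <- netc$isoforms$mouse
      }
      if (length(targets) == 2 && q > 0)
        for (j in seq_along(targets))
          emit("secretion", paste0("q_", surf$cell_type), cn,
               p1 = fl(targets[j]),
               rate = q * split[j] * cells / AVOGADRO, vscale = vsc)
      if (identical(surf$cell_type, "ec") && isTRUE(comp$fluid$svegfr1) &&
          sec$q_sR1_EC > 0)
        emit("secretion", "q_sR1", cn, p1 = fl("sR1"),
             rate = sec$q_sR1_EC * cells / AVOGADRO, vscale = vsc)
    }

    ## degradation of free VEGF in tissue interstitium
    if (identical(comp$type, "tissue"))
      for (v in iso)
        emit("degradation", "k_deg", cn, r1 = fl(v), rate = tr$k_deg)

    ## plasma clearance and soluble-factor synthesis
    if (identical(comp$type, "blood")) {
      cl <- tr$clearance
      rate_for <- function(name) {
        if (name %in% iso) cl[["V"]]
        else if (name == "Trap") cl[["Trap"]]
        else if (name == "sR1") cl[["sR1"]]
        else if (name %in% c("a2Mn", "a2Mf")) cl[["a2m"]]
        else if (grepl("\\.Trap$", name)) cl[["TrapV"]]
        # complexes are cleared at the slower partner's rate
        else if (grepl("\\.sR1$", name)) min(cl[["V"]], cl[["sR1"]])
        else if (grepl("\\.a2M[nf]$", name)) min(cl[["V"]], cl[["a2m"]])
        else NA_real_
      }
      fsp <- net$species[net$species$compartment == cn &
                         net$species$locale == "fluid", "name"]
      for (name in fsp) {
        r <- rate_for(name)
        if (!is.na(r) && r > 0)
          emit("clearance", "clearance", cn, r1 = fl(name), rate = r)
      }
      if (isTRUE(comp$fluid$a2m)) {
        emit("secretion", "a2m_synthesis", cn, p1 = fl("a2Mn"),
             rate = cl[["a2m"]] * config$soluble$a2m_native_M * 1e-3)
        emit("secretion", "a2m_synthesis", cn, p1 = fl("a2Mf"),
             rate = cl[["a2m"]] * config$soluble$a2m_fast_M * 1e-3)
      }
    }
  }

  ## transport descriptors: tissue fluid <-> blood fluid, and lymph
  blood <- names(netc$compartments)[vapply(netc$compartments,
                                           function(x) x$type == "blood",
                                           logical(1))]
  if (length(blood) == 1) {
    kp_class <- function(name) {
      if (name %in% iso) "V"
      else if (name == "Trap") "Trap"
      else if (grepl("\\.Trap$", name)) "TrapV"
      else if (name == "sR1") "sR1"
      else if (grepl("\\.sR1$", name)) "VsR1"
      else NA_character_
    }
    for (cn in names(netc$compartments)) {
      comp <- netc$compartments[[cn]]
      if (!identical(comp$type, "tissue")) next
      iface <- if (!is.null(comp$interface)) comp$interface else cn
      fsp <- net$species[net$species$compartment == cn &
                         net$species$locale == "fluid", "name"]
      for (name in fsp) {
        kcl <- kp_class(name)
        if (is.na(kcl)) next
        bl <- paste(blood, "fluid", name, sep = ".")
        if (!(bl %in% sp_ids)) next
        emit("transport", kcl, cn, r1 = paste(cn, "fluid", name, sep = "."),
             p1 = bl, rate = tr$k_p[[iface]][[kcl]])
        if (tr$k_L[[iface]] > 0)
          emit("lymph", "k_L", cn, r1 = paste(cn, "fluid", name, sep = "."),
               p1 = bl, rate = tr$k_L[[iface]])
      }
    }
  }

  keep <- seq_len(n_rx)
  out <- data.frame(kind = F_kind[keep], class = F_class[keep],
                    compartment = F_comp[keep], r1 = F_r1[keep],
                    r2 = F_r2[keep], p1 = F_p1[keep], kon = F_kon[keep],
                    koff = F_koff[keep], rate = F_rate[keep],
                    vscale = F_vs[keep], stringsAsFactors = FALSE)
  out$id <- sprintf("r%04d", seq_len(nrow(out)))
  out <- out[, c("id", "kind", "class", "compartment", "r1", "r2", "p1",
                 "kon", "koff", "rate", "vscale")]
  class(out) <- c("vegf_reactions", "data.frame")
  out
}

# Token decomposition of a species name into molecular components.
.species_tokens <- function(name) {
  toks <- strsplit(name, ".", fixed = TRUE)[[1]]
  toks[toks != ""]
}

#' Validate a generated reaction network
#'
#' Checks (i) molecular-component mass balance across every binary
#' binding/coupling reaction, (ii) that no enumerated species is an
#' orphan (absent from all reactions), and (iii) that koff/kon of every
#' reversible reaction reproduces the dissociation constant implied by
#' the kinetic table to a relative tolerance.
#'
#' @param net a `vegf_network_species` object.
#' @param reactions a `vegf_reactions` data.frame.
#' @param config the configuration used to build both.
#' @param tol relative tolerance for the Kd consistency check.
#' @return list with `ok` (logical) and a data.frame `violations`.
#' @export
validate_network <- function(net, reactions, config, tol = 1e-6) {
  viol <- list()
  note <- function(what, where)
    viol[[length(viol) + 1L]] <<- data.frame(check = what, where = where,
                                             stringsAsFactors = FALSE)
  strip <- function(id) {
    # species name = id minus compartment/locale/pool prefix
    i <- match(id, net$species$id)
    net$species$name[i]
  }
  bin <- reactions[reactions$kind %in% c("binding", "coupling"), ]
  for (i in seq_len(nrow(bin))) {
    lhs <- sort(c(.species_tokens(strip(bin$r1[i])),
                  .species_tokens(strip(bin$r2[i]))))
    rhs <- sort(.species_tokens(strip(bin$p1[i])))
    if (!identical(lhs, rhs))
      note("mass_balance", bin$id[i])
  }
  kin <- config$kinetics
  for (i in seq_len(nrow(bin))) {
    k <- kin[match(bin$class[i], kin$class), ]
    if (nrow(k) == 0 || is.na(k$kon)) { note("unknown_class", bin$id[i]); next }
    kd_cfg <- k$koff / k$kon
    kd_rxn <- bin$koff[i] / bin$kon[i]
    if (abs(kd_rxn - kd_cfg) > tol * kd_cfg)
      note("kd_mismatch", bin$id[i])
  }
  used <- unique(stats::na.omit(c(reactions$r1, reactions$r2, reactions$p1)))
  orphan <- setdiff(net$species$id, used)
  for (o in orphan) note("orphan_species", o)
  viol <- if (length(viol)) do.call(rbind, viol)
          else data.frame(check = character(0), where = character(0))
  list(ok = nrow(viol) == 0L, violations = viol)
}
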