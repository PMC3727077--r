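test_that("full xenograft enumeration reproduces the structural counts", {
  net <- enumerate_species(xeno_config())
  expect_equal(unname(net$manifest$counts),
               c(53L, 126L, 79L))
  expect_equal(net$manifest$total, 258L)
})

test_that("enumeration is a pure, hash-stable function of the config", {
  n1 <- enumerate_species(xeno_config())
  n2 <- enumerate_species(default_config())
  expect_identical(n1$species$id, n2$species$id)
  expect_identical(n1$manifest$hash, n2$manifest$hash)
})

test_that("disabling factors or compartments never adds species", {
  full <- enumerate_species(xeno_config())$manifest
  cfg <- default_config()
  cfg$network$compartments$blood$fluid$a2m <- FALSE
  no_a2m <- enumerate_species(cfg)$manifest
  expect_lt(no_a2m$counts[["blood"]], full$counts[["blood"]])
  expect_identical(no_a2m$counts[["normal"]], full$counts[["normal"]])

  cfg2 <- default_config()
  for (cn in names(cfg2$network$compartments))
    cfg2$network$compartments[[cn]]$fluid$svegfr1 <- FALSE
  # sVEGFR1 species exist on surfaces too; strip the surface flags
  cfg2$network$compartments$blood$surfaces$ec_luminal_normal$sr1_nrp <- FALSE
  cfg2$network$compartments$blood$surfaces$ec_luminal_tumor$sr1_nrp <- FALSE
  cfg2$network$compartments$tumor$surfaces$tumor_cell$sr1_nrp <- FALSE
  no_sr1 <- enumerate_species(cfg2)$manifest
  expect_true(all(no_sr1$counts < full$counts))

  two <- enumerate_species(default_config(tumor = FALSE))$manifest
  expect_lt(two$total, full$counts[["normal"]] + full$counts[["blood"]])
})

test_that("a toy configuration matches its hand enumeration", {
  cfg <- closed_config()
  net <- enumerate_species(cfg)
  # by hand: fluid mV120, mV164; surface VEGFR1, mV120.VEGFR1,
  # mV164.VEGFR1
  expect_identical(net$species$id,
                   c("t1.fluid.mV120", "t1.fluid.mV164",
                     "t1.cell.VEGFR1",
                     "t1.cell.mV120.VEGFR1", "t1.cell.mV164.VEGFR1"))
  # two isoforms, one surface with R1/R2/N1: hand-enumerated 15 species
  cfg$network$compartments$t1$surfaces$cell <- surface_spec(
    c("VEGFR1", "VEGFR2", "NRP1"),
    densities = c(VEGFR1 = 1, VEGFR2 = 1, NRP1 = 1), cells_per_cm3 = 1)
  sp <- enumerate_species(cfg)$species
  hand <- c("mV120", "mV164",                     # fluid
            "VEGFR1", "VEGFR2", "NRP1",           # free receptors
            "mV120.VEGFR1", "mV164.VEGFR1",
            "mV120.VEGFR2", "mV164.VEGFR2",
            "mV164.NRP1", "mV164.VEGFR2.NRP1")
  expect_setequal(sp$name, hand)
})

test_that("reaction generation honors the exon-splicing distinction", {
  m <- xeno_model()
  rx <- m$reactions
  gag <- rx[rx$class == "V-GAG", ]
  # short isoforms never bind matrix sites
  expect_false(any(grepl("mV120|hV121", gag$r1)))
  # both heparin binders do, in all three regions of both tissues
  expect_equal(nrow(gag), 2 * 3 * 2)
  # NRP binding restricted to heparin binders
  vn <- rx[rx$class == "V-N", ]
  expect_false(any(grepl("mV120|hV121", vn$r1)))
})

test_that("the Trap forms exactly four 1:1 complexes per compartment", {
  rx <- xeno_model()$reactions
  trap <- rx[rx$class == "V-Trap", ]
  expect_equal(as.vector(table(trap$compartment)[c("normal", "blood",
                                                   "tumor")]),
               c(4L, 4L, 4L))
  # identical stoichiometry: one ligand + Trap -> one complex
  expect_true(all(!is.na(trap$r1) & !is.na(trap$r2) & !is.na(trap$p1)))
  expect_true(all(grepl("\\.Trap$", trap$p1)))
})

test_that("network validation passes and flags injected defects", {
  m <- xeno_model()
  v <- validate_network(m$network, m$reactions, m$config)
  expect_true(v$ok)
  expect_equal(nrow(v$violations), 0L)

  # mismatched product
  bad <- m$reactions
  i <- which(bad$kind == "binding")[1]
  bad$p1[i] <- "blood.fluid.sR1"
  vb <- validate_network(m$network, bad, m$config)
  expect_false(vb$ok)
  expect_true("mass_balance" %in% vb$violations$check)

  # tampered dissociation rate
  bad2 <- m$reactions
  j <- which(bad2$class == "V-Trap")[1]
  bad2$koff[j] <- bad2$koff[j] * 2
  vb2 <- validate_network(m$network, bad2, m$config)
  expect_true("kd_mismatch" %in% vb2$violations$check)
})

test_that("reaction Kds reproduce the configured table", {
  m <- xeno_model()
  rx <- m$reactions
  kin <- m$config$kinetics
  bin <- rx[rx$kind %in% c("binding", "coupling"), ]
  kd_cfg <- (kin$koff / kin$kon)[match(bin$class, kin$class)]
  expect_equal(bin$koff / bin$kon, kd_cfg, tolerance = 1e-10)
  # Trap affinity is sub-picomolar as configured
  kd_trap <- with(kin, koff[class == "V-Trap"] / kon[class == "V-Trap"])
  expect_equal(kd_trap / 1e-12, 0.6, tolerance = 1e-6)
})

test_that("SBML round trip reproduces the manifest", {
  m <- xeno_model()
  path <- tempfile(fileext = ".xml")
  export_sbml(m, path)
  imp <- import_sbml(path)
  expect_equal(imp$counts,
               stats::setNames(as.integer(m$manifest$counts),
                               names(m$manifest$counts)))
  expect_equal(imp$total, m$manifest$total)
  expect_equal(imp$n_reactions, nrow(m$reactions))
  # document is namespaced, well-formed SBML level 3
  doc <- xml2::read_xml(path)
  expect_match(xml2::xml_ns(doc)[[1]], "sbml/level3")
  expect_equal(xml2::xml_attr(doc, "level"), "3")
})
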