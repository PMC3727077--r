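#' Save a configuration to YAML
#'
#' Writes the configuration as a YAML document.  The derived tumor
#' geometry is not serialized: only the primitive measurements are
#' stored and the derivation chain is re-run on load.  The kinetic
#' table is stored as a list of `{class, kon, koff}` records.
#'
#' @param config a `vegf_config`.
#' @param path output file path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "vegf_config"))
  x <- unclass(config)
  x$tumor <- "tumor" %in% names(x$network$compartments)
  if (!is.null(x$geometry$tumor)) {
    x$geometry$tumor$derived <- NULL
    x$geometry$tumor$K_av <- NULL
    x$geometry$tumor$S_EC <- NULL
  }
  x$kinetics <- lapply(seq_len(nrow(config$kinetics)), function(i)
    as.list(config$kinetics[i, ]))
  # YAML drops the names of atomic vectors; serialize them as maps
  yamlify <- function(v) {
    if (is.list(v)) lapply(v, yamlify)
    else if (is.atomic(v) && !is.null(names(v))) as.list(v)
    else v
  }
  x <- yamlify(x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

# Recursive override with unknown-key rejection; leaves of the default
# tree define the schema.
.merge_config <- function(base, override, path = character(0)) {
  for (nm in names(override)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!(nm %in% names(base)))
      stop("unknown configuration key '", here, "'", call. = FALSE)
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.data.frame(base[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]],
                                  c(path, nm))
    } else {
      v <- override[[nm]]
      if (is.list(v) && !is.list(base[[nm]])) v <- unlist(v)
      if (!is.null(names(base[[nm]])) && !is.null(names(v)))
        base[[nm]][names(v)] <- v
      else base[[nm]] <- v
    }
  }
  base
}

.validate_config <- function(config) {
  chk_nonneg <- function(x, where) {
    bad <- which(unlist(x) < 0)
    if (length(bad))
      stop("negative value at configuration key '", where, ".",
           names(unlist(x))[bad[1]], "' (expected a non-negative rate)",
           call. = FALSE)
  }
  chk_nonneg(config$transport$k_p, "transport.k_p")
  chk_nonneg(config$transport$k_L, "transport.k_L")
  chk_nonneg(config$transport$clearance, "transport.clearance")
  chk_nonneg(config$secretion[c("q_muscle", "q_EC", "q_tumor", "q_sR1_EC")],
             "secretion")
  for (sp in c("split_muscle", "split_EC", "split_tumor"))
    if (abs(sum(config$secretion[[sp]]) - 1) > 1e-9)
      stop("secretion.", sp, " must sum to 1", call. = FALSE)
  for (cn in names(config$network$compartments))
    for (sn in names(config$network$compartments[[cn]]$surfaces)) {
      s <- config$network$compartments[[cn]]$surfaces[[sn]]
      if (any(s$densities < 0))
        stop("negative receptor density at network.compartments.", cn,
             ".surfaces.", sn, call. = FALSE)
    }
  invisible(config)
}

#' Load a configuration from YAML or JSON
#'
#' Reads a configuration file, validates it against the schema of the
#' default configuration (unknown keys are rejected with their full
#' path; negative rates and malformed secretion splits are rejected),
#' re-derives the tumor geometry from the primitive measurements, and
#' returns the normalized internal representation (cm, s, mol/cm^3).
#' A file containing only overrides is merged onto [default_config()].
#'
#' @param path YAML (or JSON) file path.
#' @return a `vegf_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
       else yaml::read_yaml(path)
  tumor <- !isFALSE(y$tumor)
  y$tumor <- NULL
  base <- default_config(tumor = tumor)
  kin_over <- y$kinetics; y$kinetics <- NULL
  prim <- y$geometry$tumor$primitives
  if (!is.null(y$geometry$tumor)) y$geometry$tumor$primitives <- NULL
  cfg <- .merge_config(unclass(base), y)
  class(cfg) <- "vegf_config"
  if (!is.null(kin_over)) {
    for (rec in kin_over) {
      i <- match(rec$class, cfg$kinetics$class)
      if (is.na(i))
        stop("unknown kinetic class '", rec$class, "' in ", path,
             call. = FALSE)
      if (!is.null(rec$kon)) cfg$kinetics$kon[i] <- rec$kon
      if (!is.null(rec$koff)) cfg$kinetics$koff[i] <- rec$koff
    }
  }
  if (tumor && length(prim)) {
    g <- do.call(derive_tumor_geometry, prim)
    cfg$geometry$tumor$primitives <- prim
    cfg$geometry$tumor$derived <- g
    cfg$geometry$tumor$K_av <- g$interstitium$K_av
    cfg$geometry$tumor$S_EC <- g$composition$S_EC
  }
  .validate_config(cfg)
  cfg
}
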