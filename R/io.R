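SCHEMA_VERSION <- "1.0"

#' Write a surface as a tidy CSV table
#'
#' One row per grid cell, row-major with temperature varying slowest,
#' columns `temperature_c, pco2_uatm, value` (plus `state` for a phase
#' map), numerics at 9 significant digits. Coordinates are cell-center
#' driver levels.
#'
#' @param x A `perf_surface`, `net_surface`, or `phase_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface_table <- function(x, path) {
  if (!inherits(x, "phasetip_surface")) {
    stop("`x` must be a performance, net, or phase surface", call. = FALSE)
  }
  cols <- intersect(c("temperature_c", "pco2_uatm", "value", "state"),
                    names(x))
  out <- tibble::as_tibble(as.data.frame(x)[cols])
  for (nm in c("temperature_c", "pco2_uatm", "value")) {
    out[[nm]] <- signif(out[[nm]], 9)
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a tidy surface CSV
#'
#' @param path A file written by [write_surface_table()].
#' @return A tibble with the file's columns.
#' @export
read_surface_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write isocline polylines as CSV
#'
#' Columns `polyline_id, vertex_index, temperature_c, pco2_uatm`; an empty
#' isocline list produces a header-only file.
#'
#' @param iso A list of polyline tibbles from [extract_isocline()] or
#'   [isoclines()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isoclines <- function(iso, path) {
  if (length(iso) == 0L) {
    out <- tibble::tibble(polyline_id = integer(0),
                          vertex_index = integer(0),
                          temperature_c = numeric(0),
                          pco2_uatm = numeric(0))
  } else {
    out <- dplyr::bind_rows(lapply(seq_along(iso), function(i) {
      tibble::tibble(polyline_id = i,
                     vertex_index = seq_len(nrow(iso[[i]])),
                     temperature_c = signif(iso[[i]]$temperature_c, 9),
                     pco2_uatm = signif(iso[[i]]$pco2_uatm, 9))
    }))
  }
  readr::write_csv(out, path)
  invisible(path)
}

## scenario config (JSON / YAML) --------------------------------------------

species_to_list <- function(sp) {
  out <- list(role = sp$role, thermal = unclass(sp$thermal))
  if (!is.null(sp$co2)) {
    fam <- if (inherits(sp$co2, "co2_saturating")) "saturating" else
      "threshold"
    out$co2 <- c(list(family = fam), unclass(sp$co2))
  }
  if (!is.null(sp$interaction)) {
    out$interaction <- unclass(sp$interaction)
  }
  out
}

scenario_to_config <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  list(
    schema_version = SCHEMA_VERSION,
    scenario = list(
      name = spec$name,
      rho = spec$rho,
      efficiency = spec$efficiency,
      grid = list(t_axis = spec$grid$t_axis, c_axis = spec$grid$c_axis),
      producer = species_to_list(spec$producer),
      consumer = species_to_list(spec$consumer)
    )
  )
}

#' Write a scenario configuration file
#'
#' Serializes a [scenario_spec()] to JSON (`.json`) or YAML
#' (`.yaml`/`.yml`), chosen by the file extension. The round trip through
#' [read_scenario_config()] is lossless.
#'
#' @param spec A [scenario_spec()].
#' @param path Output path ending in `.json`, `.yaml`, or `.yml`.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(spec, path) {
  doc <- scenario_to_config(spec)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path, precision = 17L)
  } else {
    stop("unsupported config extension ", deparse(ext),
         "; use .json, .yaml, or .yml", call. = FALSE)
  }
  invisible(path)
}

check_keys <- function(x, required, optional, path) {
  if (!is.list(x)) {
    stop("config field `", path, "` must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(x), c(required, optional))
  if (length(unknown) > 0L) {
    stop("unknown config field `", path, ".", unknown[1L], "`",
         call. = FALSE)
  }
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("missing required config field `", path, ".", missing[1L], "`",
         call. = FALSE)
  }
  invisible(TRUE)
}

with_field_context <- function(path, expr) {
  tryCatch(expr, error = function(e) {
    stop("invalid config at `", path, "`: ", conditionMessage(e),
         call. = FALSE)
  })
}

species_from_list <- function(x, path) {
  check_keys(x, required = c("role", "thermal"),
             optional = c("co2", "interaction"), path = path)
  th <- x$thermal
  check_keys(th, required = c("t_opt", "ct_min", "ct_max", "sigma_rise"),
             optional = "p_max", path = paste0(path, ".thermal"))
  thermal <- with_field_context(paste0(path, ".thermal"), {
    tpc(th$t_opt, th$ct_min, th$ct_max, th$sigma_rise,
        p_max = th$p_max %||% 1)
  })
  co2 <- NULL
  if (!is.null(x$co2)) {
    co2_path <- paste0(path, ".co2")
    fam <- x$co2$family
    if (is.null(fam) || !fam %in% c("saturating", "threshold")) {
      stop("config field `", co2_path,
           ".family` must be \"saturating\" or \"threshold\"",
           call. = FALSE)
    }
    if (fam == "saturating") {
      check_keys(x$co2, required = c("family", "k_half"),
                 optional = "baseline", path = co2_path)
      co2 <- with_field_context(co2_path, {
        saturating_response(x$co2$k_half, baseline = x$co2$baseline %||% 0)
      })
    } else {
      check_keys(x$co2, required = c("family", "c_mid", "steepness"),
                 optional = "floor", path = co2_path)
      co2 <- with_field_context(co2_path, {
        threshold_response(x$co2$c_mid, x$co2$steepness,
                           floor = x$co2$floor %||% 0)
      })
    }
  }
  interaction <- NULL
  if (!is.null(x$interaction)) {
    ip <- paste0(path, ".interaction")
    check_keys(x$interaction, required = c("d_topt", "d_ctmax"),
               optional = character(0), path = ip)
    interaction <- with_field_context(ip, {
      interaction_modulator(x$interaction$d_topt, x$interaction$d_ctmax)
    })
  }
  with_field_context(path, {
    species_response(x$role, thermal, co2 = co2, interaction = interaction)
  })
}

#' Read and validate a scenario configuration file
#'
#' Parses a JSON or YAML scenario document (schema version "1.0"),
#' validates every field against the component
#' invariants, and rejects unknown keys; errors name the first offending
#' field by its dotted path.
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` config file.
#' @return A validated [scenario_spec()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension ", deparse(ext),
         "; use .json, .yaml, or .yml", call. = FALSE)
  }
  check_keys(doc, required = c("schema_version", "scenario"),
             optional = character(0), path = "$")
  if (!identical(as.character(doc$schema_version), SCHEMA_VERSION)) {
    stop("unsupported config schema_version ",
         deparse(as.character(doc$schema_version)), "; this build reads ",
         SCHEMA_VERSION, call. = FALSE)
  }
  sc <- doc$scenario
  check_keys(sc, required = c("grid", "producer", "consumer"),
             optional = c("name", "rho", "efficiency"), path = "scenario")
  check_keys(sc$grid, required = c("t_axis", "c_axis"),
             optional = character(0), path = "scenario.grid")
  grid <- with_field_context("scenario.grid", {
    driver_grid(unlist(sc$grid$t_axis), unlist(sc$grid$c_axis))
  })
  producer <- species_from_list(sc$producer, "scenario.producer")
  consumer <- species_from_list(sc$consumer, "scenario.consumer")
  with_field_context("scenario", {
    scenario_spec(producer, consumer, grid = grid,
                  rho = sc$rho %||% 1,
                  efficiency = sc$efficiency %||% 1,
                  name = sc$name %||% "custom")
  })
}

#' Write a provenance manifest for a scenario run
#'
#' JSON document recording the full scenario parameterization (identical to
#' the scenario config schema), the package version, and a `metadata` block
#' with the creation timestamp. Everything outside `metadata` is
#' reproducible bit-for-bit across runs.
#'
#' @param spec A [scenario_spec()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(spec, path) {
  doc <- scenario_to_config(spec)
  doc$package <- list(name = "phasetip",
                      version = as.character(utils::packageVersion("phasetip")))
  doc$metadata <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
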