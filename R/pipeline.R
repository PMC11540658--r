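#' Run the full trait-extraction pipeline from a config
#'
#' Orchestrates crop -> per-organ trait stage over a declarative YAML
#' (or list) configuration and returns a trait report, one row per
#' measurement. Per-organ failures are recorded in the report and the
#' run continues — in a survey context partial results beat none. A
#' missing input file, by contrast, aborts the run before any
#' processing.
#'
#' Config schema (YAML):
#' ```yaml
#' seed: 1                   # recorded in provenance
#' calibration: cal.json     # optional; applied to non-metric clouds
#' organs:
#'   - plant: p1
#'     organ: stem1
#'     kind: stem            # stem | leaf | fruit
#'     file: stem1.ply
#'     region:               # optional crop
#'       kind: box
#'       min: [-1, -1, 0]
#'       max: [1, 1, 2]
#'     params:               # optional per-stage overrides
#'       sample_spacing: 0.005
#' ```
#' Polygon regions use `kind: polygon` with `vertices` (list of
#' \[u, v\] pairs) and `view` (length-3).
#'
#' @param config path to a YAML config file, or an equivalent list.
#' @param output_dir directory for artifacts (skeleton/mesh/ellipsoid
#'   PLY files); `NULL` disables artifact export.
#' @param verbose emit per-stage log lines with timings.
#' @return A `trait_report` tibble with columns `plant`, `organ`,
#'   `trait`, `value`, `unit`, `diagnostics` (list column), `error`;
#'   provenance (input files, config hash, seed) in attributes.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = FALSE) {
  config_hash <- NA_character_
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config_hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$organs)) {
    stop("config must contain an `organs` list")
  }
  log_line <- function(...) {
    if (verbose) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  }

  files <- vapply(config$organs, function(o) o$file %||% NA_character_,
                  character(1))
  missing <- files[!is.na(files) & !file.exists(files)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  cal <- NULL
  if (!is.null(config$calibration)) {
    cal <- if (is.character(config$calibration)) {
      read_calibration(config$calibration)
    } else {
      config$calibration
    }
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  }

  rows <- list()
  for (o in config$organs) {
    plant <- o$plant %||% "plant"
    organ <- o$organ %||% "organ"
    kind <- match.arg(o$kind, c("stem", "leaf", "fruit"))
    t0 <- Sys.time()
    res <- tryCatch({
      cloud <- if (!is.null(o$cloud)) o$cloud else read_point_cloud(o$file)
      if (!is_metric(cloud)) {
        if (is.null(cal)) {
          stop("cloud is not metric and no calibration was supplied")
        }
        cloud <- apply_scale(cloud, cal)
      }
      if (!is.null(o$region)) {
        cloud <- crop_cloud(cloud, parse_region(o$region))
      }
      p <- o$params %||% list()
      switch(kind,
        stem = pipeline_stem(cloud, p, output_dir, plant, organ),
        leaf = pipeline_leaf(cloud, p, output_dir, plant, organ),
        fruit = pipeline_fruit(cloud, p, output_dir, plant, organ)
      )
    }, error = function(e) e)
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      log_line("%s/%s (%s) FAILED after %.2fs: %s", plant, organ, kind, dt,
               conditionMessage(res))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        plant = plant, organ = organ, trait = paste0(kind, "_failed"),
        value = NA_real_, unit = NA_character_,
        diagnostics = list(NULL), error = conditionMessage(res))
    } else {
      log_line("%s/%s (%s): %d row(s) in %.2fs", plant, organ, kind,
               nrow(res), dt)
      rows[[length(rows) + 1L]] <- res
    }
  }
  report <- dplyr::bind_rows(rows)
  class(report) <- c("trait_report", class(report))
  attr(report, "provenance") <- list(
    inputs = files[!is.na(files)],
    config_hash = config_hash,
    seed = config$seed %||% NA_integer_)
  report
}

parse_region <- function(r) {
  kind <- r$kind %||% "box"
  if (kind == "box") {
    crop_region_box(unlist(r$min), unlist(r$max))
  } else if (kind == "polygon") {
    crop_region_polygon(do.call(rbind, lapply(r$vertices, unlist)),
                        view = unlist(r$view %||% c(0, 0, 1)))
  } else {
    stop("unknown region kind: ", kind)
  }
}

pipeline_stem <- function(cloud, p, output_dir, plant, organ) {
  params <- contraction_params(
    k_neighbors = p$k_neighbors %||% 12,
    max_iterations = p$max_iterations %||% 20)
  spacing <- p$sample_spacing %||% 0.005
  res <- stem_internodes(cloud, params, sample_spacing = spacing)
  if (!is.null(output_dir)) {
    write_skeleton(res$graph,
                   file.path(output_dir, paste0(plant, "_", organ,
                                                "_skeleton.ply")),
                   file.path(output_dir, paste0(plant, "_", organ,
                                                "_nodes.csv")))
  }
  if (length(res$lengths) == 0) {
    return(tibble::tibble(
      plant = plant, organ = organ, trait = "inter_node_length_m",
      value = NA_real_, unit = "m", diagnostics = list(res$nodes),
      error = "fewer than 2 branch nodes detected"))
  }
  tibble::tibble(
    plant = plant, organ = organ, trait = "inter_node_length_m",
    value = res$lengths, unit = "m",
    diagnostics = lapply(seq_along(res$lengths), function(i) {
      list(path_length_m = res$path_lengths[i], segment = i)
    }),
    error = NA_character_)
}

pipeline_leaf <- function(cloud, p, output_dir, plant, organ) {
  res <- leaf_area_pipeline(
    cloud,
    mls = mls_params(search_radius = p$mls_search_radius %||% NULL),
    bpa = bpa_params(radii = p$bpa_radii %||% NULL))
  if (!is.null(output_dir)) {
    write_mesh(res$mesh, file.path(output_dir,
                                   paste0(plant, "_", organ, "_mesh.ply")))
  }
  tibble::tibble(
    plant = plant, organ = organ, trait = "leaf_area_m2",
    value = res$area_m2, unit = "m2",
    diagnostics = list(as.list(res$diagnostics)),
    error = NA_character_)
}

pipeline_fruit <- function(cloud, p, output_dir, plant, organ) {
  res <- fruit_volume_pipeline(cloud)
  if (!is.null(output_dir)) {
    write_mesh(ellipsoid_mesh(res$fit),
               file.path(output_dir, paste0(plant, "_", organ,
                                            "_ellipsoid.ply")))
  }
  tibble::tibble(
    plant = plant, organ = organ, trait = "fruit_volume_m3",
    value = res$fit$volume, unit = "m3",
    diagnostics = list(list(
      semi_axes_mm = res$fit$semi_axes * 1e3,
      residual = res$fit$residual, coverage = res$coverage,
      n_points = res$fit$n_points)),
    error = NA_character_)
}

#' Write a trait report as CSV (SI and cm-based units side by side)
#'
#' @param report a `trait_report` from [run_pipeline()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_report <- function(report, path) {
  df <- as.data.frame(report[, c("plant", "organ", "trait", "value", "unit")])
  conv <- c(m = 1e2, m2 = 1e4, m3 = 1e6)
  alt <- c(m = "cm", m2 = "cm2", m3 = "cm3")
  df$value_cm_units <- ifelse(df$unit %in% names(conv),
                              df$value * conv[df$unit], NA_real_)
  df$cm_unit <- ifelse(df$unit %in% names(alt), alt[df$unit], NA_character_)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
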