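CASE_FORMAT_VERSION <- 1L

#' Write a case to a directory
#'
#' Serializes a case as plain-text files: `manifest.yaml` (format version,
#' grid, prescription, structures as index lists), `layers.csv`, `spots.csv`,
#' and one Matrix Market coordinate file `layer_###.mtx` per energy layer.
#' Uncertainty scenarios, when supplied, go to `scenarios/s##/` subdirectories
#' with their weights recorded in the manifest. Matrix data round-trips
#' bit-exactly through [read_case()].
#'
#' @param case an `elo_case`.
#' @param dir output directory (created if missing).
#' @param scenarios optional `elo_scenarios` to store alongside.
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir, scenarios = NULL) {
  stopifnot(inherits(case, "elo_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = CASE_FORMAT_VERSION,
    grid = list(
      shape = as.integer(case$grid$shape),
      spacing_mm = as.numeric(case$grid$spacing_mm),
      origin_mm = as.numeric(case$grid$origin_mm)
    ),
    prescription_pct = case$prescription_pct,
    n_layers = nrow(case$layers),
    structures = lapply(case$structures, function(st) {
      list(name = st$name, role = st$role, voxel_indices = as.integer(st$voxel_indices))
    })
  )
  if (!is.null(scenarios)) {
    manifest$scenarios <- list(
      n = length(scenarios$scenarios),
      weights = as.numeric(scenarios$weights),
      nominal_index = scenarios$nominal_index,
      descriptions = scenarios$descriptions
    )
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"), precision = 17L)
  readr::write_csv(case$layers, file.path(dir, "layers.csv"))
  readr::write_csv(case$spots, file.path(dir, "spots.csv"))
  write_influence(case$influence, dir)
  if (!is.null(scenarios)) {
    for (si in seq_along(scenarios$scenarios)) {
      sdir <- file.path(dir, "scenarios", sprintf("s%02d", si))
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      write_influence(scenarios$scenarios[[si]], sdir)
    }
  }
  invisible(dir)
}

write_influence <- function(influence, dir) {
  for (i in seq_along(influence$blocks)) {
    write_mm_coordinate(
      influence$blocks[[i]],
      file.path(dir, sprintf("layer_%03d.mtx", i))
    )
  }
}

# Matrix Market coordinate writer with %.17g entries so that doubles
# round-trip bit-exactly through the text file (readMM parses with strtod).
write_mm_coordinate <- function(m, path) {
  m <- methods::as(m, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "%%MatrixMarket matrix coordinate real general",
    sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))
  ), con)
  if (length(m@x) > 0) {
    writeLines(sprintf("%d %d %.17g", m@i + 1L, m@j + 1L, m@x), con)
  }
  invisible(path)
}

read_influence <- function(dir, n_layers, n_spots_per_layer, n_vox) {
  blocks <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    f <- file.path(dir, sprintf("layer_%03d.mtx", i))
    if (!file.exists(f)) {
      stop(sprintf("missing dose-influence file for layer %d: %s", i, f), call. = FALSE)
    }
    m <- methods::as(Matrix::readMM(f), "CsparseMatrix")
    if (nrow(m) != n_vox || ncol(m) != n_spots_per_layer[i]) {
      stop(sprintf(
        "layer %d matrix is %d x %d but the manifest implies %d x %d",
        i, nrow(m), ncol(m), n_vox, n_spots_per_layer[i]
      ), call. = FALSE)
    }
    blocks[[i]] <- m
  }
  list(
    blocks = blocks, layer_ids = seq_len(n_layers),
    n_spots_per_layer = as.integer(n_spots_per_layer)
  )
}

#' Read a case written by [write_case()]
#'
#' Validates the manifest version, file presence, and matrix dimensions, and
#' rebuilds the in-memory case (plus the scenario set when one was stored).
#'
#' @param dir case directory.
#' @return An `elo_case`; if scenarios were stored, they are attached as
#'   attribute `"scenarios"` (an `elo_scenarios`).
#' @export
read_case <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop(sprintf("no manifest.yaml in %s", dir), call. = FALSE)
  manifest <- yaml::read_yaml(mf)
  if (is.null(manifest$format_version) ||
    manifest$format_version != CASE_FORMAT_VERSION) {
    stop(sprintf(
      "unsupported case format version '%s' (reader supports %d)",
      manifest$format_version %||% "missing", CASE_FORMAT_VERSION
    ), call. = FALSE)
  }
  grid <- voxel_grid(
    unlist(manifest$grid$shape), unlist(manifest$grid$spacing_mm),
    unlist(manifest$grid$origin_mm)
  )
  structures <- lapply(manifest$structures, function(st) {
    make_structure(st$name, unlist(st$voxel_indices) %||% integer(0), st$role, grid)
  })
  names(structures) <- vapply(structures, `[[`, "", "name")
  layers <- readr::read_csv(file.path(dir, "layers.csv"), show_col_types = FALSE)
  spots <- readr::read_csv(file.path(dir, "spots.csv"), show_col_types = FALSE)
  if (nrow(layers) != manifest$n_layers) {
    stop(sprintf(
      "manifest lists %d layers but layers.csv has %d",
      manifest$n_layers, nrow(layers)
    ), call. = FALSE)
  }
  influence <- read_influence(dir, nrow(layers), layers$n_spots, n_voxels(grid))
  case <- structure(
    list(
      grid = grid, structures = structures, spots = spots, layers = layers,
      influence = influence,
      prescription_pct = manifest$prescription_pct,
      config = NULL, jitter = NULL
    ),
    class = "elo_case"
  )
  if (!is.null(manifest$scenarios)) {
    scen <- vector("list", manifest$scenarios$n)
    for (si in seq_len(manifest$scenarios$n)) {
      scen[[si]] <- read_influence(
        file.path(dir, "scenarios", sprintf("s%02d", si)),
        nrow(layers), layers$n_spots, n_voxels(grid)
      )
    }
    attr(case, "scenarios") <- structure(
      list(
        scenarios = scen,
        weights = unlist(manifest$scenarios$weights),
        nominal_index = manifest$scenarios$nominal_index,
        descriptions = unlist(manifest$scenarios$descriptions)
      ),
      class = "elo_scenarios"
    )
  }
  case
}

#' Plan-quality and delivery metrics of a finished plan
#'
#' Reports the standard plan-comparison row: number of delivered energies,
#' objective value, conformity index, maximum target dose, mean dose per
#' structure, and the delivery-time breakdown. Dosimetric quantities are
#' computed on the D95-normalized dose (the objective value is reported for
#' the optimized plan as-is).
#'
#' @param plan an `elo_plan`.
#' @param delivery a [delivery_config()].
#' @param normalize rescale to CTV D95 = 100 percent before reporting
#'   dosimetric quantities (default TRUE).
#' @return One-row tibble.
#' @export
plan_metrics <- function(plan, delivery = delivery_config(), normalize = TRUE) {
  case <- plan$case
  x_rep <- if (normalize) normalize_plan(plan$x, case) else plan$x
  dose <- compute_dose(case$influence, as.numeric(x_rep))
  ctv <- case$structures$ctv
  tt <- total_delivery_time(plan, config = delivery)
  lids <- rep(seq_along(case$influence$n_spots_per_layer),
    times = case$influence$n_spots_per_layer
  )
  n_energy <- length(unique(lids[plan$x > 0]))
  means <- lapply(case$structures, function(st) mean(dose[st$voxel_indices]))
  names(means) <- paste0("dmean_", names(case$structures), "_pct")
  dplyr::bind_cols(
    tibble::tibble(
      mode = plan$mode,
      energy = n_energy,
      f = plan$f,
      ci = conformity_index(dose, ctv, case$structures$body, case$prescription_pct),
      dmax_target_pct = max(dose[ctv$voxel_indices]),
      d95_target_pct = coverage_dose(dose, ctv, 0.95)
    ),
    tibble::as_tibble(means),
    tibble::tibble(
      elst_s = tt$elst_s, sspt_s = tt$sspt_s, sswt_s = tt$sswt_s,
      total_s = tt$total_s
    )
  )
}

#' Write a plan report
#'
#' Emits a machine-readable JSON report, the metrics row as CSV, the spot
#' intensity table, and per-structure DVH curves as CSV.
#'
#' @param plan an `elo_plan`.
#' @param dir output directory.
#' @param delivery a [delivery_config()].
#' @param seed seed to record in the report metadata.
#' @return The metrics tibble, invisibly.
#' @export
write_report <- function(plan, dir, delivery = delivery_config(), seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- plan_metrics(plan, delivery)
  readr::write_csv(metrics, file.path(dir, "metrics.csv"))
  spots_tbl <- tibble::tibble(
    spot_id = plan$case$spots$spot_id,
    layer_id = plan$case$spots$layer_id,
    intensity = plan$x
  )
  readr::write_csv(spots_tbl, file.path(dir, "plan_spots.csv"))
  x_rep <- normalize_plan(plan$x, plan$case)
  dose <- compute_dose(plan$case$influence, as.numeric(x_rep))
  dvh <- dplyr::bind_rows(lapply(plan$case$structures, function(st) {
    dvh_curve(dose, st)
  }))
  readr::write_csv(dvh, file.path(dir, "dvh.csv"))
  report <- list(
    mode = plan$mode,
    ne = plan$ne,
    selected_layers = which(plan$s == 1),
    metrics = as.list(metrics),
    objective_history = plan$objective_history,
    primal_residuals = plan$primal_residuals,
    seed = seed %||% plan$config$seed,
    robust = plan$robust,
    n_scenarios = plan$n_scenarios
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(metrics)
}
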