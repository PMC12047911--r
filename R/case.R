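#' Configuration for a synthetic pencil-beam-scanning case
#'
#' Defines the digital phantom (voxel grid, spherical clinical target volume,
#' cuboid organ at risk), the beam arrangement, and the analytic beam model
#' used by [generate_case()]. Defaults follow common PBS planning
#' conventions: a 3 mm isotropic dose grid, 3 mm lateral and 5 mm
#' longitudinal spot spacing.
#'
#' The depth-dose curve for each spot is an analytic Bragg-like profile: a
#' slowly rising entrance plateau, a Gaussian peak at the layer's nominal
#' range (`bragg_sigma_mm`), and a sharper Gaussian distal falloff
#' (`distal_sigma_mm`). Lateral spread is Gaussian with `lateral_sigma_mm`.
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param spacing_mm voxel spacing, mm (isotropic scalar or length-3).
#' @param beam_angles_deg gantry angles in the x-y plane, degrees.
#' @param ctv_radius_mm radius of the spherical target, mm.
#' @param ctv_center_mm target center, mm; default grid center.
#' @param oar_offset_mm offset of the cuboid OAR center from the CTV center.
#' @param oar_half_size_mm half-size of the OAR cuboid per axis, mm.
#' @param lateral_spacing_mm spot grid spacing within a layer, mm.
#' @param longitudinal_spacing_mm spacing between layer nominal ranges, mm.
#' @param lateral_sigma_mm Gaussian lateral spread of a spot, mm.
#' @param bragg_sigma_mm width of the Bragg peak (proximal side), mm.
#' @param distal_sigma_mm width of the distal falloff, mm.
#' @param entrance_plateau entrance dose relative to the peak.
#' @param layer_margin_mm extension of layer ranges beyond the target depth
#'   extent, mm.
#' @param layer_repeat number of coincident-range copies of every layer
#'   (> 1 builds deliberately redundant layer sets).
#' @param amplitude_jitter lognormal sd of the per-spot amplitude jitter
#'   (0 disables).
#' @param prescription_pct prescription dose; all doses are carried as
#'   percent of prescription, so the default is 100.
#' @param seed integer seed used by [generate_case()].
#' @return A list of class `elo_case_config`.
#' @export
case_config <- function(grid_shape = c(20L, 20L, 20L),
                        spacing_mm = 3,
                        beam_angles_deg = c(0, 90),
                        ctv_radius_mm = 12,
                        ctv_center_mm = NULL,
                        oar_offset_mm = c(0, 18, 0),
                        oar_half_size_mm = c(9, 6, 9),
                        lateral_spacing_mm = 3,
                        longitudinal_spacing_mm = 5,
                        lateral_sigma_mm = 3,
                        bragg_sigma_mm = 2.5,
                        distal_sigma_mm = 1.2,
                        entrance_plateau = 0.3,
                        layer_margin_mm = 0,
                        layer_repeat = 1L,
                        amplitude_jitter = 0.05,
                        prescription_pct = 100,
                        seed = 1L) {
  spacing_mm <- rep_len(spacing_mm, 3L)
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape < 1L)) stop("grid_shape entries must be >= 1", call. = FALSE)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive", call. = FALSE)
  if (is.null(ctv_center_mm)) ctv_center_mm <- grid_shape * spacing_mm / 2
  structure(
    list(
      grid_shape = grid_shape, spacing_mm = spacing_mm,
      beam_angles_deg = beam_angles_deg,
      ctv_radius_mm = ctv_radius_mm, ctv_center_mm = ctv_center_mm,
      oar_offset_mm = oar_offset_mm, oar_half_size_mm = oar_half_size_mm,
      lateral_spacing_mm = lateral_spacing_mm,
      longitudinal_spacing_mm = longitudinal_spacing_mm,
      lateral_sigma_mm = lateral_sigma_mm,
      bragg_sigma_mm = bragg_sigma_mm, distal_sigma_mm = distal_sigma_mm,
      entrance_plateau = entrance_plateau,
      layer_margin_mm = layer_margin_mm,
      layer_repeat = as.integer(layer_repeat),
      amplitude_jitter = amplitude_jitter,
      prescription_pct = prescription_pct,
      seed = as.integer(seed)
    ),
    class = "elo_case_config"
  )
}

voxel_grid <- function(shape, spacing_mm, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing_mm <- rep_len(spacing_mm, 3L)
  if (any(shape < 1L)) stop("voxel counts must be >= 1", call. = FALSE)
  if (any(spacing_mm <= 0)) stop("voxel spacing must be > 0", call. = FALSE)
  list(shape = shape, spacing_mm = spacing_mm, origin_mm = rep_len(origin_mm, 3L))
}

n_voxels <- function(grid) prod(grid$shape)

# Voxel-center coordinates (mm), rows in flat-index order (x fastest).
voxel_centers <- function(grid) {
  sh <- grid$shape
  sp <- grid$spacing_mm
  o <- grid$origin_mm
  ix <- rep.int(seq_len(sh[1]), times = sh[2] * sh[3])
  iy <- rep.int(rep(seq_len(sh[2]), each = sh[1]), times = sh[3])
  iz <- rep(seq_len(sh[3]), each = sh[1] * sh[2])
  cbind(
    o[1] + (ix - 0.5) * sp[1],
    o[2] + (iy - 0.5) * sp[2],
    o[3] + (iz - 0.5) * sp[3]
  )
}

make_structure <- function(name, voxel_indices, role, grid) {
  voxel_indices <- sort(unique(as.integer(voxel_indices)))
  if (length(voxel_indices) > 0 &&
    (min(voxel_indices) < 1L || max(voxel_indices) > n_voxels(grid))) {
    stop(sprintf("structure '%s' has voxel indices outside the grid", name), call. = FALSE)
  }
  role <- match.arg(role, c("target", "oar", "body"))
  if (role == "target" && length(voxel_indices) == 0) {
    stop(sprintf("target structure '%s' is empty", name), call. = FALSE)
  }
  list(name = name, voxel_indices = voxel_indices, role = role)
}

# Bragg-like depth-dose: entrance plateau (smoothly gated off past the peak)
# plus an asymmetric Gaussian peak, as a function of depth t and range R.
bragg_curve <- function(t, range_mm, config) {
  sig_p <- config$bragg_sigma_mm
  sig_d <- config$distal_sigma_mm
  plateau <- config$entrance_plateau * (1 + 0.3 * pmax(t, 0) / max(range_mm, 1e-6))
  gate <- stats::plogis((range_mm - t) / max(sig_d / 2, 0.3))
  sig <- ifelse(t <= range_mm, sig_p, sig_d)
  peak <- exp(-(t - range_mm)^2 / (2 * sig^2))
  out <- plateau * gate + peak
  out[t < 0] <- 0
  out
}

# Beam frame for a gantry angle: direction u in the x-y plane, lateral axes
# e1 (in-plane) and e2 (z).
beam_frame <- function(angle_deg) {
  th <- angle_deg * pi / 180
  list(
    u = c(cos(th), sin(th), 0),
    e1 = c(-sin(th), cos(th), 0),
    e2 = c(0, 0, 1)
  )
}

#' Generate a synthetic pencil-beam-scanning case
#'
#' Builds a digital phantom and its per-energy-layer sparse dose-influence
#' matrices. The phantom holds a spherical CTV, a cuboid OAR, and a body
#' structure covering the grid. Per beam, spots are laid out on a lateral
#' grid covering the target footprint and energy layers are placed at the
#' configured longitudinal spacing across the target's depth extent; a
#' deeper energy index always means a deeper Bragg peak. Deterministic for a
#' fixed seed.
#'
#' @param config an [case_config()] object.
#' @return An object of class `elo_case`: fields `grid`, `structures` (named
#'   list with `ctv`, `oar`, `body`), `spots` (tibble: `spot_id`, `layer_id`,
#'   `beam_id`, `energy_index`, `x_mm`, `y_mm`), `layers` (tibble),
#'   `influence` (list with `blocks`, `layer_ids`, `n_spots_per_layer`),
#'   `prescription_pct`, `config`.
#' @examples
#' case <- generate_case(case_config(grid_shape = c(12, 12, 12), seed = 7))
#' length(case$influence$blocks)
#' @export
generate_case <- function(config = case_config()) {
  stopifnot(inherits(config, "elo_case_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  grid <- voxel_grid(config$grid_shape, config$spacing_mm)
  centers <- voxel_centers(grid)
  extent <- grid$shape * grid$spacing_mm

  ctv_idx <- which(rowSums(sweep(centers, 2, config$ctv_center_mm)^2) <=
    config$ctv_radius_mm^2)
  if (length(ctv_idx) == 0) {
    stop("CTV lies outside the grid: no voxel within ctv_radius_mm of its center",
      call. = FALSE
    )
  }
  oar_center <- config$ctv_center_mm + config$oar_offset_mm
  oar_dev <- abs(sweep(centers, 2, oar_center))
  oar_idx <- which(oar_dev[, 1] <= config$oar_half_size_mm[1] &
    oar_dev[, 2] <= config$oar_half_size_mm[2] &
    oar_dev[, 3] <= config$oar_half_size_mm[3])
  structures <- list(
    ctv = make_structure("ctv", ctv_idx, "target", grid),
    oar = make_structure("oar", oar_idx, "oar", grid),
    body = make_structure("body", seq_len(n_voxels(grid)), "body", grid)
  )

  spots <- list()
  layers <- list()
  layer_id <- 0L
  for (b in seq_along(config$beam_angles_deg)) {
    fr <- beam_frame(config$beam_angles_deg[b])
    t_all <- drop(centers %*% fr$u)
    a_all <- drop(centers %*% fr$e1)
    b_all <- drop(centers %*% fr$e2)
    t0 <- min(t_all) # entry plane of the body along this beam
    t_ctv <- t_all[ctv_idx] - t0
    a_ctv <- a_all[ctv_idx]
    b_ctv <- b_all[ctv_idx]

    ranges <- seq(
      min(t_ctv) - config$layer_margin_mm,
      max(t_ctv) + config$layer_margin_mm,
      by = config$longitudinal_spacing_mm
    )
    ranges <- rep(ranges, each = config$layer_repeat)

    off <- stats::runif(2, -0.5, 0.5) * config$lateral_spacing_mm
    ax <- seq(min(a_ctv) - config$lateral_sigma_mm,
      max(a_ctv) + config$lateral_sigma_mm,
      by = config$lateral_spacing_mm
    ) + off[1]
    bx <- seq(min(b_ctv) - config$lateral_sigma_mm,
      max(b_ctv) + config$lateral_sigma_mm,
      by = config$lateral_spacing_mm
    ) + off[2]
    lat <- expand.grid(x_mm = ax, y_mm = bx)
    # keep lateral positions near the projected target footprint
    keep <- vapply(seq_len(nrow(lat)), function(i) {
      any((a_ctv - lat$x_mm[i])^2 + (b_ctv - lat$y_mm[i])^2 <=
        (1.5 * config$lateral_sigma_mm + config$lateral_spacing_mm)^2)
    }, logical(1))
    lat <- lat[keep, , drop = FALSE]
    if (nrow(lat) == 0) {
      stop(sprintf("beam %d: no spot positions cover the target footprint", b),
        call. = FALSE
      )
    }

    for (e in seq_along(ranges)) {
      layer_id <- layer_id + 1L
      layers[[layer_id]] <- tibble::tibble(
        layer_id = layer_id, beam_id = b, energy_index = e,
        range_mm = ranges[e], n_spots = nrow(lat)
      )
      spots[[layer_id]] <- tibble::tibble(
        layer_id = layer_id, beam_id = b, energy_index = e,
        x_mm = lat$x_mm, y_mm = lat$y_mm
      )
    }
  }
  layers <- dplyr::bind_rows(layers)
  spots <- dplyr::bind_rows(spots)
  spots$spot_id <- seq_len(nrow(spots))
  spots <- spots[, c("spot_id", "layer_id", "beam_id", "energy_index", "x_mm", "y_mm")]

  jitter <- if (config$amplitude_jitter > 0) {
    exp(stats::rnorm(nrow(spots), 0, config$amplitude_jitter))
  } else {
    rep(1, nrow(spots))
  }

  influence <- compute_influence(grid, centers, spots, layers, config, jitter)
  check <- Matrix::rowSums(do.call(cbind, influence$blocks))[ctv_idx]
  if (any(check <= 0)) {
    stop("generated case leaves CTV voxels without dose influence; enlarge the spot layout",
      call. = FALSE
    )
  }

  structure(
    list(
      grid = grid, structures = structures, spots = spots, layers = layers,
      influence = influence, prescription_pct = config$prescription_pct,
      config = config, jitter = jitter
    ),
    class = "elo_case"
  )
}

# Dose-influence blocks for the given geometry; `shift_mm` displaces the
# phantom (setup error) and `range_scale` scales every layer's nominal range
# (range error). Used for both the nominal case and uncertainty scenarios.
compute_influence <- function(grid, centers, spots, layers, config, jitter,
                              shift_mm = c(0, 0, 0), range_scale = 1) {
  nv <- nrow(centers)
  shifted <- sweep(centers, 2, shift_mm, `+`)
  blocks <- vector("list", nrow(layers))
  cutoff <- 3 * config$lateral_sigma_mm
  for (b in unique(layers$beam_id)) {
    fr <- beam_frame(config$beam_angles_deg[b])
    t_all <- drop(shifted %*% fr$u)
    a_all <- drop(shifted %*% fr$e1)
    b_all <- drop(shifted %*% fr$e2)
    # entry plane fixed in the machine frame (unshifted phantom), so setup
    # errors along the beam axis change the depth as they should
    t0 <- min(drop(centers %*% fr$u))
    depth <- t_all - t0
    for (li in which(layers$beam_id == b)) {
      lay <- layers[li, ]
      rng <- lay$range_mm * range_scale
      sp <- spots[spots$layer_id == lay$layer_id, , drop = FALSE]
      depth_ok <- which(depth <= rng + 4 * config$distal_sigma_mm)
      dd <- bragg_curve(depth[depth_ok], rng, config)
      ii <- integer(0)
      jj <- integer(0)
      xx <- numeric(0)
      for (k in seq_len(nrow(sp))) {
        r2 <- (a_all[depth_ok] - sp$x_mm[k])^2 + (b_all[depth_ok] - sp$y_mm[k])^2
        near <- which(r2 <= cutoff^2)
        if (length(near) == 0) next
        val <- jitter[sp$spot_id[k]] * dd[near] *
          exp(-r2[near] / (2 * config$lateral_sigma_mm^2))
        keep <- val > 1e-4
        ii <- c(ii, depth_ok[near][keep])
        jj <- c(jj, rep.int(k, sum(keep)))
        xx <- c(xx, val[keep])
      }
      blocks[[li]] <- Matrix::sparseMatrix(
        i = ii, j = jj, x = xx,
        dims = c(nv, nrow(sp))
      )
    }
  }
  list(
    blocks = blocks,
    layer_ids = layers$layer_id,
    n_spots_per_layer = layers$n_spots
  )
}

#' @export
print.elo_case <- function(x, ...) {
  cat(sprintf(
    "<elo_case: %s grid, %d layers, %d spots, %d beams>\n",
    paste(x$grid$shape, collapse = "x"),
    nrow(x$layers), nrow(x$spots), length(unique(x$layers$beam_id))
  ))
  invisible(x)
}

#' Generate setup and range uncertainty scenarios for a case
#'
#' Produces the standard robust-planning scenario set: the nominal geometry,
#' six cardinal setup shifts of `setup_shift_mm` along +/- x, y, z, and two
#' range scalings of +/- `range_uncertainty_fraction` — nine scenarios when
#' both uncertainties are positive. Setup shifts displace the phantom
#' relative to the spot positions; range errors scale the depth of every
#' layer's Bragg peak. Scenario weights default to uniform.
#'
#' @param case an [generate_case()] result.
#' @param setup_shift_mm setup uncertainty magnitude, mm (>= 0).
#' @param range_uncertainty_fraction relative range uncertainty (>= 0),
#'   e.g. 0.035 for 3.5 percent.
#' @param weights optional scenario weights; recycled/normalized to sum 1.
#' @return An object of class `elo_scenarios`: `scenarios` (list of influence
#'   lists), `weights`, `nominal_index`, `descriptions`.
#' @export
generate_scenarios <- function(case, setup_shift_mm = 5,
                               range_uncertainty_fraction = 0.035,
                               weights = NULL) {
  stopifnot(inherits(case, "elo_case"))
  if (setup_shift_mm < 0 || range_uncertainty_fraction < 0) {
    stop("uncertainty magnitudes must be >= 0", call. = FALSE)
  }
  shifts <- list(c(0, 0, 0))
  scales <- 1
  desc <- "nominal"
  if (setup_shift_mm > 0) {
    for (ax in 1:3) {
      for (sgn in c(1, -1)) {
        v <- c(0, 0, 0)
        v[ax] <- sgn * setup_shift_mm
        shifts <- c(shifts, list(v))
        scales <- c(scales, 1)
        desc <- c(desc, sprintf("setup %+g mm along %s", sgn * setup_shift_mm, c("x", "y", "z")[ax]))
      }
    }
  }
  if (range_uncertainty_fraction > 0) {
    for (sgn in c(1, -1)) {
      shifts <- c(shifts, list(c(0, 0, 0)))
      scales <- c(scales, 1 + sgn * range_uncertainty_fraction)
      desc <- c(desc, sprintf("range %+.1f%%", sgn * 100 * range_uncertainty_fraction))
    }
  }
  centers <- voxel_centers(case$grid)
  scenarios <- vector("list", length(shifts))
  scenarios[[1]] <- case$influence
  if (length(shifts) > 1) {
    for (s in 2:length(shifts)) {
      scenarios[[s]] <- compute_influence(
        case$grid, centers, case$spots, case$layers, case$config, case$jitter,
        shift_mm = shifts[[s]], range_scale = scales[s]
      )
    }
  }
  if (is.null(weights)) weights <- rep(1, length(scenarios))
  weights <- rep_len(weights, length(scenarios))
  if (any(weights < 0)) stop("scenario weights must be nonnegative", call. = FALSE)
  weights <- weights / sum(weights)
  structure(
    list(
      scenarios = scenarios, weights = weights, nominal_index = 1L,
      descriptions = desc
    ),
    class = "elo_scenarios"
  )
}

#' @export
print.elo_scenarios <- function(x, ...) {
  cat(sprintf(
    "<elo_scenarios: %d scenarios (%s)>\n",
    length(x$scenarios), paste(x$descriptions, collapse = "; ")
  ))
  invisible(x)
}
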