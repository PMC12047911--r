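#' Delivery-time machine parameters
#'
#' Constants of the per-fraction delivery-time model. Energy switching to a
#' lower energy takes `t_switch_down_s` (default 0.7 s) and to a higher
#' energy `t_switch_up_s` (default 5.5 s). Spot spill time is the total
#' delivered charge over the beam current `gamma_protons_per_min`
#' (default 2.6e11 protons/min). Spot switching combines speed-limited
#' lateral travel with a magnetic preparation time of
#' `t_magnet_prep_s` (default 1 ms).
#'
#' @param t_switch_down_s,t_switch_up_s energy switching times, seconds.
#' @param gamma_protons_per_min beam current, protons per minute.
#' @param t_magnet_prep_s magnet preparation time per spot transition, s.
#' @param scan_speed_x_mm_per_s,scan_speed_y_mm_per_s lateral scanning
#'   speeds, mm/s.
#' @param protons_per_intensity_unit conversion from spot intensity units to
#'   protons for the spill-time term (set to 1 when intensities already are
#'   proton counts).
#' @return A list of class `elo_delivery_config`.
#' @export
delivery_config <- function(t_switch_down_s = 0.7, t_switch_up_s = 5.5,
                            gamma_protons_per_min = 2.6e11,
                            t_magnet_prep_s = 0.001,
                            scan_speed_x_mm_per_s = 10000,
                            scan_speed_y_mm_per_s = 10000,
                            protons_per_intensity_unit = 1e8) {
  stopifnot(
    t_switch_down_s > 0, t_switch_up_s > 0, gamma_protons_per_min > 0,
    t_magnet_prep_s > 0, scan_speed_x_mm_per_s > 0, scan_speed_y_mm_per_s > 0,
    protons_per_intensity_unit > 0
  )
  structure(
    list(
      t_switch_down_s = t_switch_down_s, t_switch_up_s = t_switch_up_s,
      gamma_protons_per_min = gamma_protons_per_min,
      t_magnet_prep_s = t_magnet_prep_s,
      scan_speed_x_mm_per_s = scan_speed_x_mm_per_s,
      scan_speed_y_mm_per_s = scan_speed_y_mm_per_s,
      protons_per_intensity_unit = protons_per_intensity_unit
    ),
    class = "elo_delivery_config"
  )
}

#' Order the delivered spots of a plan
#'
#' Delivery convention: beams in index order; within a beam, active layers
#' (selected and carrying nonzero intensity) in descending energy order,
#' which minimizes time-expensive upward energy switches; within a layer,
#' spots in serpentine row order — rows by increasing y, direction along x
#' alternating row by row. Spots with zero intensity are skipped.
#'
#' @param x spot intensity vector.
#' @param s binary layer selection (default all ones).
#' @param spots spot table (`spot_id`, `layer_id`, `beam_id`, `energy_index`,
#'   `x_mm`, `y_mm`), as in `case$spots`.
#' @return Tibble of delivery steps in order: `step`, `spot_id`, `layer_id`,
#'   `beam_id`, `energy_index`, `x_mm`, `y_mm`, `intensity`.
#' @export
delivery_sequence <- function(x, spots, s = NULL) {
  lids <- sort(unique(spots$layer_id))
  if (is.null(s)) s <- rep(1L, length(lids))
  sel <- stats::setNames(s, lids)
  df <- spots
  df$intensity <- x[spots$spot_id]
  df <- df[df$intensity > 0 & sel[as.character(df$layer_id)] == 1, , drop = FALSE]
  if (nrow(df) == 0) stop("plan has no active spots to deliver", call. = FALSE)

  out <- list()
  for (b in sort(unique(df$beam_id))) {
    dfb <- df[df$beam_id == b, , drop = FALSE]
    for (e in sort(unique(dfb$energy_index), decreasing = TRUE)) {
      dfl <- dfb[dfb$energy_index == e, , drop = FALSE]
      ys <- sort(unique(dfl$y_mm))
      rows <- lapply(seq_along(ys), function(r) {
        dr <- dfl[dfl$y_mm == ys[r], , drop = FALSE]
        dr[order(dr$x_mm, decreasing = (r %% 2 == 0)), , drop = FALSE]
      })
      out[[length(out) + 1L]] <- dplyr::bind_rows(rows)
    }
  }
  seqd <- dplyr::bind_rows(out)
  seqd$step <- seq_len(nrow(seqd))
  tibble::as_tibble(seqd[, c(
    "step", "spot_id", "layer_id", "beam_id",
    "energy_index", "x_mm", "y_mm", "intensity"
  )])
}

#' Energy-layer switching time
#'
#' Sum over consecutive layer transitions in the delivery sequence
#' (including transitions across beams): the down-switch time when the
#' energy decreases, the up-switch time when it increases, zero when the
#' energy index is unchanged.
#'
#' @param sequence a [delivery_sequence()] tibble.
#' @param config a [delivery_config()].
#' @return Seconds.
#' @export
elst <- function(sequence, config = delivery_config()) {
  keys <- paste(sequence$beam_id, sequence$layer_id)
  first <- !duplicated(keys)
  en <- sequence$energy_index[first]
  if (length(en) <= 1) {
    return(0)
  }
  d <- diff(en)
  sum(ifelse(d < 0, config$t_switch_down_s, ifelse(d > 0, config$t_switch_up_s, 0)))
}

#' Spot spill time
#'
#' Total delivered charge over the beam current: `||x||_1 / gamma`, in
#' seconds (`gamma` is per minute).
#'
#' @param x spot intensity vector (nonnegative).
#' @param config a [delivery_config()].
#' @return Seconds.
#' @export
sspt <- function(x, config = delivery_config()) {
  protons <- sum(abs(x)) * config$protons_per_intensity_unit
  protons / config$gamma_protons_per_min * 60
}

#' Spot switching time
#'
#' Sum over consecutive same-layer spot transitions of the speed-limited
#' lateral travel time `max(|dx| / v_x, |dy| / v_y)` plus the magnetic
#' preparation time. Transitions between layers are excluded (their cost is
#' the energy switch, see [elst()]).
#'
#' @param sequence a [delivery_sequence()] tibble.
#' @param config a [delivery_config()].
#' @return Seconds.
#' @export
sswt <- function(sequence, config = delivery_config()) {
  if (nrow(sequence) <= 1) {
    return(0)
  }
  same_layer <- sequence$layer_id[-1] == sequence$layer_id[-nrow(sequence)] &
    sequence$beam_id[-1] == sequence$beam_id[-nrow(sequence)]
  dx <- abs(diff(sequence$x_mm))
  dy <- abs(diff(sequence$y_mm))
  travel <- pmax(dx / config$scan_speed_x_mm_per_s, dy / config$scan_speed_y_mm_per_s)
  sum((travel + config$t_magnet_prep_s)[same_layer])
}

#' Per-fraction delivery-time breakdown of a plan
#'
#' Composes energy-layer switching time (ELST), spot spill time (SSPT), and
#' spot switching time (SSWT); the total is their exact sum.
#'
#' @param plan an `elo_plan`, or a list with fields `x` and `s`.
#' @param spots spot table, as in `case$spots`; defaults to the plan's case.
#' @param config a [delivery_config()].
#' @return A list of class `elo_delivery_time` with fields `elst_s`,
#'   `sspt_s`, `sswt_s`, `total_s`, and the `sequence`.
#' @export
total_delivery_time <- function(plan, spots = NULL, config = delivery_config()) {
  if (is.null(spots)) spots <- plan$case$spots
  seqd <- delivery_sequence(plan$x, spots, plan$s)
  e <- elst(seqd, config)
  sp <- sspt(plan$x, config)
  sw <- sswt(seqd, config)
  structure(
    list(
      elst_s = e, sspt_s = sp, sswt_s = sw, total_s = e + sp + sw,
      sequence = seqd
    ),
    class = "elo_delivery_time"
  )
}

#' @export
print.elo_delivery_time <- function(x, ...) {
  cat(sprintf(
    "<elo_delivery_time: ELST %.2f s + SSPT %.2f s + SSWT %.2f s = %.2f s>\n",
    x$elst_s, x$sspt_s, x$sswt_s, x$total_s
  ))
  invisible(x)
}
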