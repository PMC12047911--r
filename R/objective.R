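#' Define a plan objective term
#'
#' A plan objective is a weighted sum of per-structure quadratic terms
#' \deqn{f(d, \Omega) = \sum_i \frac{\omega_i}{|\Omega_i|}
#'   \sum_{j \in \Omega_i} (d_j - t_i)^2,}
#' where the active voxel set \eqn{\Omega_i} depends on the term kind:
#' * `"L2"` — the whole structure is always active (mean-squared deviation
#'   from the prescribed level).
#' * `"DVH_max"` — at most a fraction `volume_fraction` of the structure may
#'   exceed `dose_level`; only violating voxels beyond that allowance are
#'   active.
#' * `"DVH_min"` — at least a fraction `volume_fraction` must reach
#'   `dose_level`; only underdosed voxels beyond the complementary allowance
#'   are active.
#'
#' Doses are in percent of prescription throughout.
#'
#' @param kind `"L2"`, `"DVH_max"`, or `"DVH_min"`.
#' @param structure structure name (must exist in the case).
#' @param weight nonnegative weight `omega`.
#' @param dose_level prescribed or limit dose (percent of prescription).
#' @param volume_fraction allowed/required volume fraction in `[0, 1]`
#'   (DVH terms only).
#' @return A list of class `elo_objective_term`.
#' @export
objective_term <- function(kind = c("L2", "DVH_max", "DVH_min"), structure,
                           weight, dose_level, volume_fraction = NULL) {
  kind <- match.arg(kind)
  if (weight < 0) stop("weight must be >= 0", call. = FALSE)
  if (dose_level < 0) stop("dose_level must be >= 0", call. = FALSE)
  if (kind != "L2") {
    if (is.null(volume_fraction) || volume_fraction < 0 || volume_fraction > 1) {
      stop("DVH terms need volume_fraction in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(
      kind = kind, structure = structure, weight = weight,
      dose_level = dose_level, volume_fraction = volume_fraction
    ),
    class = "elo_objective_term"
  )
}

#' Default objective terms for the synthetic phantom
#'
#' Target coverage (L2 at 100 percent), a target hot-spot DVH-max, an OAR
#' DVH-max, and a small L2 falloff term on the body that rewards conformity.
#'
#' @param case an `elo_case`.
#' @return List of [objective_term()]s.
#' @export
default_objective_terms <- function(case) {
  list(
    objective_term("L2", "ctv", weight = 100, dose_level = 100),
    objective_term("DVH_max", "ctv", weight = 10, dose_level = 110, volume_fraction = 0.05),
    objective_term("DVH_max", "oar", weight = 1, dose_level = 60, volume_fraction = 0.1),
    objective_term("L2", "body", weight = 0.02, dose_level = 0)
  )
}

check_terms <- function(terms, structures) {
  for (tm in terms) {
    if (!inherits(tm, "elo_objective_term")) {
      stop("objective terms must be built with objective_term()", call. = FALSE)
    }
    if (!tm$structure %in% names(structures)) {
      stop(sprintf("objective term references unknown structure '%s'", tm$structure),
        call. = FALSE
      )
    }
  }
  invisible(terms)
}

#' Update the active voxel sets of DVH objective terms
#'
#' One sweep of the iterative convex relaxation (ICR) rule that decouples the
#' nonconvex DVH objective: given the current dose, each DVH term's active
#' set is the voxels currently violating its dose level, minus the allowed
#' number of most-violating voxels (floor of the allowed fraction of the
#' structure size), which are excused. L2 terms are always active on the full
#' structure. Ties in dose are broken by voxel index, so the map is
#' deterministic and idempotent at fixed dose.
#'
#' @param dose numeric voxelwise dose (percent of prescription).
#' @param terms list of [objective_term()]s.
#' @param structures named list of structures (each with `voxel_indices`).
#' @return A list of class `elo_active_sets`: one sorted integer vector of
#'   active voxel indices per term.
#' @export
update_active_sets <- function(dose, terms, structures) {
  check_terms(terms, structures)
  active <- lapply(terms, function(tm) {
    vox <- structures[[tm$structure]]$voxel_indices
    if (tm$kind == "L2") {
      return(vox)
    }
    d <- dose[vox]
    n_struct <- length(vox)
    if (tm$kind == "DVH_max") {
      viol <- vox[d > tm$dose_level]
      allowed <- floor(tm$volume_fraction * n_struct + 1e-9)
      if (allowed > 0 && length(viol) > 0) {
        # excuse the `allowed` highest-dose voxels (ties by voxel index)
        ord <- order(-dose[viol], viol)
        viol <- viol[-ord[seq_len(min(allowed, length(viol)))]]
      }
      sort(viol)
    } else { # DVH_min
      viol <- vox[d < tm$dose_level]
      allowed <- floor((1 - tm$volume_fraction) * n_struct + 1e-9)
      if (allowed > 0 && length(viol) > 0) {
        ord <- order(dose[viol], viol)
        viol <- viol[-ord[seq_len(min(allowed, length(viol)))]]
      }
      sort(viol)
    }
  })
  structure(active, class = "elo_active_sets")
}

#' Evaluate the plan objective at a dose distribution
#'
#' Computes the weighted mean-squared-deviation objective over the supplied
#' active sets. Empty active sets contribute zero.
#'
#' @param dose numeric voxelwise dose (percent of prescription).
#' @param terms list of [objective_term()]s.
#' @param active an `elo_active_sets` from [update_active_sets()].
#' @return Nonnegative scalar objective value.
#' @export
evaluate_objective <- function(dose, terms, active) {
  if (length(terms) != length(active)) {
    stop("terms and active sets must align", call. = FALSE)
  }
  f <- 0
  for (i in seq_along(terms)) {
    om <- active[[i]]
    if (length(om) == 0 || terms[[i]]$weight == 0) next
    if (max(om) > length(dose) || min(om) < 1) {
      stop("active set index out of dose range", call. = FALSE)
    }
    dev <- dose[om] - terms[[i]]$dose_level
    f <- f + terms[[i]]$weight / length(om) * sum(dev^2)
  }
  f
}

# Objective at a dose with active sets refreshed from that dose; the value
# reported for finished plans.
objective_at_dose <- function(dose, terms, structures) {
  evaluate_objective(dose, terms, update_active_sets(dose, terms, structures))
}

#' Conformity index of a dose distribution
#'
#' CI = V100,CTV^2 / (V_CTV x V100): the squared target volume receiving at
#' least the prescription, over the product of target volume and total body
#' volume receiving at least the prescription. Ideal conformity gives 1;
#' returns 0 when no voxel reaches the prescription.
#'
#' @param dose voxelwise dose (percent of prescription).
#' @param ctv,body structures (lists with `voxel_indices`).
#' @param prescription_pct prescription dose on the same scale as `dose`.
#' @return CI in `[0, 1]`.
#' @export
conformity_index <- function(dose, ctv, body, prescription_pct = 100) {
  if (prescription_pct <= 0) stop("prescription must be > 0", call. = FALSE)
  if (length(ctv$voxel_indices) == 0) stop("CTV is empty", call. = FALSE)
  v100_ctv <- sum(dose[ctv$voxel_indices] >= prescription_pct)
  v100 <- sum(dose[body$voxel_indices] >= prescription_pct)
  if (v100 == 0) {
    return(0)
  }
  v100_ctv^2 / (length(ctv$voxel_indices) * v100)
}

# Dx%: the dose received by at least x% of the structure (here x = coverage).
coverage_dose <- function(dose, structure, coverage = 0.95) {
  d <- dose[structure$voxel_indices]
  as.numeric(stats::quantile(d, probs = 1 - coverage, type = 1))
}

#' Normalize a plan so that CTV D95 equals the prescription
#'
#' Rescales the spot intensities by a single positive factor so that 95
#' percent of the CTV receives at least the prescription dose — the standard
#' D95 = 100 percent normalization used when reporting plans.
#'
#' @param x spot intensity vector.
#' @param case an `elo_case` (supplies the dose-influence matrix and CTV).
#' @param ctv optional structure to normalize on; default the case CTV.
#' @return `x` scaled; the factor is attached as attribute `"scale"`.
#' @export
normalize_plan <- function(x, case, ctv = NULL) {
  if (is.null(ctv)) ctv <- case$structures$ctv
  dose <- compute_dose(case$influence, x)
  d95 <- coverage_dose(dose, ctv, 0.95)
  if (d95 <= 0) stop("CTV receives no dose; cannot normalize", call. = FALSE)
  fac <- case$prescription_pct / d95
  out <- x * fac
  attr(out, "scale") <- fac
  out
}

#' Cumulative dose-volume histogram of a structure
#'
#' @param dose voxelwise dose.
#' @param structure structure (list with `voxel_indices`, optionally `name`).
#' @param dose_bins increasing vector of dose levels; default 0 to just above
#'   the structure maximum in 200 steps.
#' @return A tibble of class `elo_dvh` with columns `dose`, `volume_fraction`
#'   (fraction of the structure receiving at least `dose`), and `structure`.
#' @export
dvh_curve <- function(dose, structure, dose_bins = NULL) {
  vox <- structure$voxel_indices
  if (length(vox) == 0) stop("cannot compute a DVH for an empty structure", call. = FALSE)
  d <- dose[vox]
  if (is.null(dose_bins)) {
    dose_bins <- seq(0, max(d) * 1.02 + 1e-9, length.out = 200)
  }
  if (is.unsorted(dose_bins, strictly = FALSE)) {
    stop("dose_bins must be increasing", call. = FALSE)
  }
  vf <- vapply(dose_bins, function(b) mean(d >= b), numeric(1))
  out <- tibble::tibble(
    dose = as.numeric(dose_bins),
    volume_fraction = vf,
    structure = if (!is.null(structure$name)) structure$name else NA_character_
  )
  class(out) <- c("elo_dvh", class(out))
  out
}

#' Voxelwise dose of an intensity vector
#'
#' Total dose through the per-layer dose-influence blocks:
#' `d = sum_i D_i x_i`.
#'
#' @param influence an influence list (`case$influence` or one scenario).
#' @param x spot intensity vector (length = total spot count).
#' @return Numeric dose vector, one entry per voxel.
#' @export
compute_dose <- function(influence, x) {
  cols <- influence$n_spots_per_layer
  stopifnot(length(x) == sum(cols))
  dose <- numeric(nrow(influence$blocks[[1]]))
  ofs <- 0L
  for (i in seq_along(influence$blocks)) {
    if (cols[i] > 0) {
      xi <- x[(ofs + 1L):(ofs + cols[i])]
      if (any(xi != 0)) {
        dose <- dose + as.numeric(influence$blocks[[i]] %*% xi)
      }
    }
    ofs <- ofs + cols[i]
  }
  dose
}

# Column offsets of each layer block in the full spot vector.
layer_offsets <- function(influence) {
  c(0L, cumsum(influence$n_spots_per_layer))
}
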