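#' Solvent constants for the binary NAF gradient
#'
#' Heptane (7H) at 0.68 g cm^-3 and tetrachlorethylene (TCE) at
#' 1.60 g cm^-3. The TCE constant is the unique value consistent with both
#' the heptane density and the 7H:TCE = 0.484:1 ratio quoted for a
#' 1.3 g cm^-3 working mixture; it is configurable wherever it is used.
#'
#' @param name `"heptane"` or `"tetrachlorethylene"`.
#' @param density Override the default density (g cm^-3).
#' @return A `naf_solvent` list with `name` and `density`.
#' @export
solvent <- function(name = c("heptane", "tetrachlorethylene"),
                    density = NULL) {
  name <- match.arg(name)
  defaults <- c(heptane = 0.68, tetrachlorethylene = 1.60)
  density <- density %||% unname(defaults[name])
  if (density <= 0) stop("solvent density must be positive")
  structure(list(name = name, density = density), class = "naf_solvent")
}

#' Density of a solvent mixture
#'
#' The density of an ideal mixture is the total mass over the total volume:
#' `sum(rho_i * V_i) / sum(V_i)`. Volume additivity of the solvents is
#' assumed; no excess-volume correction is applied.
#'
#' @param volumes Component volumes (mL), all positive.
#' @param densities Component densities (g cm^-3), same length.
#' @return Mixture density in g cm^-3.
#' @examples
#' mixture_density(c(1.05, 0.137), c(1.55, 0.68))  # ~1.45
#' @export
mixture_density <- function(volumes, densities) {
  volumes <- as.numeric(volumes)
  densities <- as.numeric(densities)
  if (!length(volumes)) stop("empty component list")
  if (length(volumes) != length(densities)) {
    stop("volumes and densities differ in length")
  }
  if (any(volumes <= 0)) stop("all volumes must be positive")
  sum(densities * volumes) / sum(volumes)
}

#' Diluent volume needed to reach a target density
#'
#' Solves the mixture-density formula for the volume `x` of diluent (density
#' `diluent_density`) that brings `current_volume` at `current_density` to
#' `target_density`:
#' `x = current_volume * (current_density - target) / (target - diluent_density)`.
#'
#' @param current_volume Current volume (mL).
#' @param current_density Current density (g cm^-3).
#' @param diluent_density Diluent density (g cm^-3).
#' @param target_density Desired mixture density; must lie in the open
#'   interval between `diluent_density` and `current_density` (equal to
#'   `current_density` returns 0).
#' @return Diluent volume to add, in mL.
#' @examples
#' diluent_volume_for_target(1.05, 1.55, 0.68, 1.45)  # ~0.136 mL of heptane
#' @export
diluent_volume_for_target <- function(current_volume, current_density,
                                      diluent_density, target_density) {
  if (current_volume <= 0) stop("current_volume must be positive")
  if (target_density == current_density) return(0)
  lo <- min(current_density, diluent_density)
  hi <- max(current_density, diluent_density)
  if (target_density <= lo || target_density >= hi) {
    stop(sprintf(
      "unreachable density: target %.4g not strictly between %.4g and %.4g",
      target_density, diluent_density, current_density))
  }
  current_volume * (current_density - target_density) /
    (target_density - diluent_density)
}

#' Light:heavy volume ratio for a target density
#'
#' Returns the ratio `r` such that mixing `r` volumes of the light solvent
#' with 1 volume of the heavy solvent yields the target density.
#'
#' @param target_density Desired density (g cm^-3).
#' @param heavy,light [solvent()] objects (or anything with a `density`
#'   field).
#' @return The ratio light:heavy as a single number (`r` in `r:1`).
#' @examples
#' solvent_ratio_for_density(1.3, solvent("tetrachlorethylene"),
#'                           solvent("heptane"))  # ~0.484
#' @export
solvent_ratio_for_density <- function(target_density, heavy, light) {
  dh <- heavy$density
  dl <- light$density
  if (dh <= dl) stop("heavy solvent must be denser than the light one")
  if (target_density == dh) return(0)
  if (target_density <= dl || target_density > dh) {
    stop(sprintf(
      "unreachable density: target %.4g not within (%.4g, %.4g]",
      target_density, dl, dh))
  }
  (dh - target_density) / (target_density - dl)
}

#' Plan the stepwise dilution of a gradient
#'
#' Produces the per-step pipetting plan for the iterative supernatant loop:
#' starting from the densest supernatant, each step adds just enough diluent
#' (heptane by default) to reach the next target density. Cumulative volumes
#' are tracked across steps and every step is verified by a
#' [mixture_density()] round-trip.
#'
#' @param start_volume Starting supernatant volume (mL).
#' @param start_density Starting density (g cm^-3).
#' @param targets Target densities, strictly decreasing.
#' @param diluent A [solvent()]; defaults to heptane.
#' @param residual_supernatant_volume Supernatant volume (mL) assumed to
#'   remain in each pellet, recorded as plan metadata (default 0.05 mL).
#' @return A `naf_gradient_plan`: a data frame with one row per step
#'   (`step`, `target_density`, `addition_ml`, `total_volume_ml`,
#'   `achieved_density`).
#' @export
plan_gradient <- function(start_volume, start_density, targets,
                          diluent = solvent("heptane"),
                          residual_supernatant_volume = 0.05) {
  targets <- as.numeric(targets)
  if (length(targets) && is.unsorted(rev(targets), strictly = TRUE)) {
    stop("targets must be strictly decreasing")
  }
  vol <- start_volume
  dens <- start_density
  rows <- vector("list", length(targets))
  for (k in seq_along(targets)) {
    x <- tryCatch(
      diluent_volume_for_target(vol, dens, diluent$density, targets[k]),
      error = function(e) {
        stop(sprintf("step %d (target %.4g g cm-3): %s",
                     k, targets[k], conditionMessage(e)))
      })
    achieved <- mixture_density(c(vol, x)[c(vol, x) > 0],
                                c(dens, diluent$density)[c(vol, x) > 0])
    vol <- vol + x
    dens <- targets[k]
    rows[[k]] <- data.frame(step = k, target_density = targets[k],
                            addition_ml = x, total_volume_ml = vol,
                            achieved_density = achieved)
  }
  plan <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(), target_density = numeric(),
               addition_ml = numeric(), total_volume_ml = numeric(),
               achieved_density = numeric())
  attr(plan, "start_volume") <- start_volume
  attr(plan, "start_density") <- start_density
  attr(plan, "diluent") <- diluent
  attr(plan, "residual_supernatant_volume") <- residual_supernatant_volume
  class(plan) <- c("naf_gradient_plan", "data.frame")
  plan
}
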