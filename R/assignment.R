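#' Pairwise slopes of a percent profile
#'
#' For every unordered pair of detected fractions (i < j) the slope is the
#' percentage-point difference `percent(j) - percent(i)`. With k detected
#' fractions this yields choose(k, 2) slopes. Division by the density
#' spacing is unnecessary in the default mode: the psi distance subtracts
#' slopes of identically indexed pairs, so any common denominator cancels.
#'
#' @param profile A `naf_percent_profile` (or numeric vector, normalized
#'   first).
#' @param fraction_densities Densities, required for
#'   `slope_mode = "density-normalized"`.
#' @param slope_mode `"difference"` or `"density-normalized"`.
#' @return A `naf_slope_set`: data frame with columns `i`, `j`, `delta`.
#'   With fewer than 2 detected fractions a zero-row slope set is returned
#'   with attribute `single_fraction` set to the detected index (the
#'   single-fraction special case, routed to [single_fraction_hits()]).
#' @export
pairwise_slopes <- function(profile, fraction_densities = NULL,
                            slope_mode = c("difference", "density-normalized")) {
  slope_mode <- match.arg(slope_mode)
  profile <- normalize_profile(profile)
  idx <- which(profile$detected)
  if (length(idx) < 2L) {
    out <- data.frame(i = integer(), j = integer(), delta = numeric())
    attr(out, "analyte_id") <- profile$analyte_id
    attr(out, "single_fraction") <- if (length(idx) == 1L) idx else NA_integer_
    class(out) <- c("naf_slope_set", "data.frame")
    return(out)
  }
  pairs <- utils::combn(idx, 2L)
  i <- pairs[1L, ]
  j <- pairs[2L, ]
  delta <- profile$percents[j] - profile$percents[i]
  if (slope_mode == "density-normalized") {
    if (is.null(fraction_densities)) {
      stop("density-normalized slopes need fraction_densities")
    }
    delta <- delta / (fraction_densities[j] - fraction_densities[i])
  }
  out <- data.frame(i = i, j = j, delta = delta)
  attr(out, "analyte_id") <- profile$analyte_id
  class(out) <- c("naf_slope_set", "data.frame")
  out
}

#' Psi distances between a metabolite and the marker compartments
#'
#' On each fraction pair, the distance of the metabolite to a compartment is
#' the absolute difference between their slopes:
#' `psi(pair, comp) = |delta_met(pair) - delta_comp(pair)|`.
#'
#' @param met_slopes Metabolite `naf_slope_set`.
#' @param marker_slopes Named list of marker `naf_slope_set`s, one per
#'   compartment; each must cover every pair present in `met_slopes`.
#' @return A `naf_distance_set`: data frame with columns `i`, `j` and one
#'   psi column per compartment.
#' @export
psi_distances <- function(met_slopes, marker_slopes) {
  comps <- names(marker_slopes)
  if (is.null(comps) || !length(comps)) {
    stop("marker_slopes must be a named list")
  }
  out <- met_slopes[c("i", "j")]
  met_key <- paste(met_slopes$i, met_slopes$j)
  for (comp in comps) {
    ms <- marker_slopes[[comp]]
    m <- match(met_key, paste(ms$i, ms$j))
    if (anyNA(m)) {
      stop(sprintf(
        "marker slope set '%s' is missing fraction pair (%d, %d)",
        comp, met_slopes$i[which(is.na(m))[1]], met_slopes$j[which(is.na(m))[1]]))
    }
    out[[comp]] <- abs(met_slopes$delta - ms$delta[m])
  }
  attr(out, "metabolite_id") <- attr(met_slopes, "analyte_id")
  attr(out, "compartments") <- comps
  class(out) <- c("naf_distance_set", "data.frame")
  out
}

#' Hit increments for one fraction pair
#'
#' Implements the minimum + multi-bound counting on one pair. The minimum of
#' the psi distances identifies the closest compartment; then, for every
#' uncertainty bound b, each compartment with `psi - min < b` (strict by
#' default) earns one hit. Under the default bound-loop scheme the arg-min
#' compartment therefore earns exactly `length(bounds)` hits, and
#' compartments tied at the minimum earn the same; a full three-way tie
#' gives every compartment the maximum count. The `"min-plus-bounds"`
#' variant adds one separate hit for the first arg-min compartment.
#'
#' @param psi Named non-negative numeric vector, one psi per compartment.
#' @param config An [algorithm_config()].
#' @return Named numeric vector of hit increments per compartment.
#' @export
assign_pair_hits <- function(psi, config = algorithm_config()) {
  if (any(psi < 0)) stop("psi distances must be non-negative")
  m <- min(psi)
  excess <- psi - m
  cmp <- if (config$strict_inequality) `<` else `<=`
  hits <- vapply(excess, function(e) sum(cmp(e, config$bounds)), numeric(1))
  if (config$scheme == "min-plus-bounds") {
    hits[which.min(psi)] <- hits[which.min(psi)] + 1
  }
  hits
}

#' Single-fraction special case
#'
#' When a metabolite is detected in exactly one fraction no pair can be
#' built; the compartment with the highest marker enzyme percent in that
#' fraction receives the full single-fraction hit weight. Ties at the
#' maximum follow the configured tie policy.
#'
#' @param fraction_index The single detected fraction.
#' @param markers A [marker_profiles()] object.
#' @param config An [algorithm_config()].
#' @return Named numeric vector of hits per compartment.
#' @export
single_fraction_hits <- function(fraction_index, markers,
                                 config = algorithm_config()) {
  at <- vapply(markers, function(p) p$percents[fraction_index], numeric(1))
  if (anyNA(at)) stop("marker profiles undefined at that fraction")
  hits <- stats::setNames(numeric(length(at)), names(at))
  top <- which(at == max(at))
  w <- config$single_fraction_hit_weight
  hits[top] <- if (config$tie_policy == "split") w / length(top) else w
  hits
}

#' Relative subcellular distribution of one metabolite (one replicate)
#'
#' Runs the full per-replicate algorithm: slopes over detected fractions,
#' psi distances against the marker slopes on the matching pairs, per-pair
#' minimum + multi-bound hit counting (or the single-fraction special case),
#' then normalization of summed hits to percents.
#'
#' @param met A metabolite percent profile (or raw numeric profile).
#' @param markers A [marker_profiles()] object on the same fraction axis.
#' @param config An [algorithm_config()].
#' @param fraction_densities Densities, only needed for density-normalized
#'   slopes.
#' @return A `naf_distribution` list: `metabolite_id`, `hits` (named),
#'   `pair_count`, `percents` (named, summing to 100),
#'   `single_fraction` (logical).
#' @export
metabolite_distribution <- function(met, markers,
                                    config = algorithm_config(),
                                    fraction_densities = NULL) {
  met <- normalize_profile(met)
  f_markers <- length(markers[[1]]$percents)
  if (length(met$percents) != f_markers) {
    stop(sprintf("metabolite '%s': fraction axis differs from markers",
                 met$analyte_id))
  }
  comps <- names(markers)
  k <- sum(met$detected)
  if (k == 0L) stop(sprintf("metabolite '%s' undetected in all fractions",
                            met$analyte_id))
  if (k == 1L) {
    hits <- single_fraction_hits(which(met$detected), markers, config)
    pair_count <- 0L
    single <- TRUE
  } else {
    met_slopes <- pairwise_slopes(met, fraction_densities, config$slope_mode)
    marker_slopes <- lapply(markers, pairwise_slopes,
                            fraction_densities = fraction_densities,
                            slope_mode = config$slope_mode)
    psi <- psi_distances(met_slopes, marker_slopes)
    hits <- stats::setNames(numeric(length(comps)), comps)
    for (r in seq_len(nrow(psi))) {
      p <- vapply(comps, function(cc) psi[[cc]][r], numeric(1))
      hits <- hits + assign_pair_hits(p, config)
    }
    pair_count <- nrow(psi)
    single <- FALSE
  }
  structure(
    list(metabolite_id = met$analyte_id, hits = hits,
         pair_count = pair_count, percents = 100 * hits / sum(hits),
         single_fraction = single),
    class = "naf_distribution"
  )
}

#' @export
print.naf_distribution <- function(x, ...) {
  cat(sprintf("<distribution '%s' (%s)>\n", x$metabolite_id,
              if (x$single_fraction) "single-fraction case"
              else sprintf("%d pairs", x$pair_count)))
  print(round(x$percents, 1))
  invisible(x)
}

#' Aggregate per-replicate distributions
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' per-compartment percents across replicates of the same metabolite.
#'
#' @param distributions List of `naf_distribution` objects (or of named
#'   percent vectors) for the same metabolite.
#' @return A `naf_relative_distribution` list: `metabolite_id`, `mean`,
#'   `sd`, `n`, `single_replicate` (flag; SD is reported as 0 when n = 1).
#' @export
aggregate_replicates <- function(distributions) {
  if (!length(distributions)) stop("need at least one replicate")
  percs <- lapply(distributions, function(d) {
    if (inherits(d, "naf_distribution")) d$percents else d
  })
  ids <- unique(vapply(distributions, function(d) {
    if (inherits(d, "naf_distribution")) d$metabolite_id else NA_character_
  }, character(1)))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1L) {
    stop(sprintf("replicates mix metabolites: %s", paste(ids, collapse = ", ")))
  }
  mat <- do.call(rbind, percs)
  n <- nrow(mat)
  means <- colMeans(mat)
  sds <- if (n > 1L) apply(mat, 2L, stats::sd) else
    stats::setNames(numeric(ncol(mat)), colnames(mat))
  structure(
    list(metabolite_id = if (length(ids)) ids else "metabolite",
         mean = means, sd = sds, n = n, single_replicate = n == 1L),
    class = "naf_relative_distribution"
  )
}

#' Absolute subcellular metabolite levels
#'
#' Multiplies the relative distribution (product of means) with the
#' whole-tissue absolute level, propagating the relative errors in
#' quadrature: `SD(comp) = level(comp) * sqrt((rel_sd/rel_mean)^2 +
#' (whole_sd/whole_mean)^2)`, and 0 where the relative mean is 0.
#'
#' @param rel A `naf_relative_distribution` (from
#'   [aggregate_replicates()]).
#' @param whole_mean,whole_sd Whole-tissue level (mean and SD) of the
#'   metabolite from non-fractionated extracts.
#' @param unit Unit string carried through (e.g. `"nmol g-1 DW"`).
#' @return A `naf_absolute_distribution` list: `metabolite_id`, `level`,
#'   `sd`, `unit`. Levels sum to `whole_mean`.
#' @export
absolute_subcellular_levels <- function(rel, whole_mean, whole_sd = 0,
                                        unit = "nmol g-1 DW") {
  if (is.na(whole_mean) || whole_mean <= 0) {
    stop(sprintf("metabolite '%s': whole-tissue mean must be positive",
                 rel$metabolite_id))
  }
  level <- rel$mean / 100 * whole_mean
  sd_out <- stats::setNames(numeric(length(level)), names(level))
  pos <- rel$mean > 0
  sd_out[pos] <- level[pos] *
    sqrt((rel$sd[pos] / rel$mean[pos])^2 + (whole_sd / whole_mean)^2)
  structure(
    list(metabolite_id = rel$metabolite_id, level = level, sd = sd_out,
         unit = unit),
    class = "naf_absolute_distribution"
  )
}

# ---- experiment-level driver ------------------------------------------------

marker_map_for <- function(marker_ids, compartments) {
  map <- stats::setNames(rep(NA_character_, length(marker_ids)), marker_ids)
  for (id in marker_ids) {
    hit <- compartments[vapply(compartments, function(cc)
      grepl(cc, id, fixed = TRUE), logical(1))]
    if (length(hit) == 1L) map[id] <- hit
  }
  if (anyNA(map) || anyDuplicated(map)) {
    stop(sprintf(
      "cannot infer compartments from marker ids (%s); pass marker_map",
      paste(marker_ids, collapse = ", ")))
  }
  map
}

sample_markers <- function(experiment, sample, marker_map,
                           compartments = naf_compartments()) {
  sub <- experiment[experiment$sample_id == sample &
                      experiment$kind == "marker_enzyme", ]
  profs <- lapply(compartments, function(cc) {
    id <- names(marker_map)[marker_map == cc]
    rows <- sub[sub$analyte_id == id, ]
    rows <- rows[order(rows$fraction_index), ]
    rows$value
  })
  names(profs) <- compartments
  marker_profiles(profs, compartments = compartments)
}

#' Assign subcellular distributions for a whole experiment
#'
#' Runs [metabolite_distribution()] for every metabolite and replicate of an
#' experiment table against that replicate's marker profiles, then
#' aggregates replicates per condition.
#'
#' @param experiment A `naf_experiment` (see [experiment_table()],
#'   [read_experiment()], [generate_experiment()]).
#' @param config An [algorithm_config()].
#' @param marker_map Named character vector mapping marker `analyte_id`s to
#'   compartment labels; inferred from the ids when they contain a
#'   compartment name (e.g. `marker_plastid`).
#' @param whole_tissue Optional data frame with columns `condition`,
#'   `analyte_id`, `mean`, `sd` (whole-tissue absolute levels); when given,
#'   absolute per-compartment levels are added to the summary.
#' @return A `naf_assignment` list with data frames `per_replicate`
#'   (condition, replicate, metabolite, compartment, hits, percent) and
#'   `summary` (condition, metabolite, compartment, mean, sd, n, and
#'   `abs_level`/`abs_sd` when `whole_tissue` is given). Metabolites
#'   undetected in every fraction of a replicate are dropped from that
#'   replicate with a warning.
#' @export
assign_experiment <- function(experiment, config = algorithm_config(),
                              marker_map = NULL, whole_tissue = NULL) {
  compartments <- naf_compartments()
  marker_ids <- unique(experiment$analyte_id[experiment$kind == "marker_enzyme"])
  if (length(marker_ids) != length(compartments)) {
    stop(sprintf("expected %d marker enzymes, found %d",
                 length(compartments), length(marker_ids)))
  }
  marker_map <- marker_map %||% marker_map_for(marker_ids, compartments)
  densities <- attr(experiment, "densities")
  samples <- unique(as.data.frame(experiment)[c("sample_id", "condition",
                                                "replicate")])
  per_rep <- list()
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    markers <- sample_markers(experiment, sid, marker_map, compartments)
    sub <- experiment[experiment$sample_id == sid &
                        experiment$kind == "metabolite", ]
    for (met in unique(sub$analyte_id)) {
      rows <- sub[sub$analyte_id == met, ]
      rows <- rows[order(rows$fraction_index), ]
      prof <- rows$value
      if (all(is.na(prof)) || sum(prof, na.rm = TRUE) <= 0) {
        warning(sprintf(
          "metabolite '%s' undetected in sample '%s'; excluded", met, sid))
        next
      }
      dist <- metabolite_distribution(
        normalize_profile(prof, analyte_id = met), markers, config,
        fraction_densities = densities)
      per_rep[[length(per_rep) + 1L]] <- data.frame(
        condition = samples$condition[s], replicate = samples$replicate[s],
        metabolite = met, compartment = compartments,
        hits = unname(dist$hits[compartments]),
        percent = unname(dist$percents[compartments]))
    }
  }
  per_rep <- do.call(rbind, per_rep)
  summ <- list()
  for (cond in unique(per_rep$condition)) {
    for (met in unique(per_rep$metabolite[per_rep$condition == cond])) {
      sub <- per_rep[per_rep$condition == cond & per_rep$metabolite == met, ]
      dists <- lapply(split(sub, sub$replicate), function(d)
        stats::setNames(d$percent, d$compartment)[compartments])
      agg <- aggregate_replicates(dists)
      row <- data.frame(condition = cond, metabolite = met,
                        compartment = compartments,
                        mean = unname(agg$mean), sd = unname(agg$sd),
                        n = agg$n)
      if (!is.null(whole_tissue)) {
        wt <- whole_tissue[whole_tissue$condition == cond &
                             whole_tissue$analyte_id == met, ]
        if (nrow(wt) == 1L && !is.na(wt$mean)) {
          agg$metabolite_id <- met
          abs_lv <- absolute_subcellular_levels(
            list(metabolite_id = met,
                 mean = stats::setNames(agg$mean, compartments),
                 sd = stats::setNames(agg$sd, compartments)),
            wt$mean, wt$sd %||% 0)
          row$abs_level <- unname(abs_lv$level[compartments])
          row$abs_sd <- unname(abs_lv$sd[compartments])
        } else {
          warning(sprintf(
            "no whole-tissue level for '%s' (%s); absolute levels skipped",
            met, cond))
          row$abs_level <- NA_real_
          row$abs_sd <- NA_real_
        }
      }
      summ[[length(summ) + 1L]] <- row
    }
  }
  structure(
    list(per_replicate = per_rep, summary = do.call(rbind, summ),
         config = config),
    class = "naf_assignment"
  )
}

#' @export
print.naf_assignment <- function(x, ...) {
  cat(sprintf("<NAF assignment: %d metabolites, %d condition(s)>\n",
              length(unique(x$summary$metabolite)),
              length(unique(x$summary$condition))))
  utils::head(x$summary)
  invisible(x)
}

#' Table-1-shaped summary of an assignment
#'
#' Reshapes an assignment summary to one row per metabolite with
#' `mean +/- sd` strings per compartment (and condition), the layout used
#' to report relative subcellular distributions.
#'
#' @param assignment A `naf_assignment`.
#' @param digits Decimals for presentation rounding (default 1).
#' @return A data frame, one row per metabolite.
#' @export
format_distribution_table <- function(assignment, digits = 1) {
  s <- assignment$summary
  out <- data.frame(metabolite = sort(unique(s$metabolite)))
  for (cond in unique(s$condition)) {
    for (comp in unique(s$compartment)) {
      sub <- s[s$condition == cond & s$compartment == comp, ]
      m <- match(out$metabolite, sub$metabolite)
      lab <- if (length(unique(s$condition)) > 1L)
        sprintf("%s.%s", comp, cond) else comp
      out[[lab]] <- ifelse(is.na(m), NA_character_,
                           sprintf("%s ± %s",
                                   formatC(round(sub$mean[m], digits),
                                           format = "fg"),
                                   formatC(round(sub$sd[m], digits),
                                           format = "fg")))
    }
  }
  out
}
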