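#' Configuration of a synthetic NAF experiment
#'
#' Defines the study conditions a simulated experiment emulates: the number
#' of gradient fractions, the shapes of the three marker-enzyme percent
#' profiles over the density axis, the multiplicative technical noise of the
#' measurements, and the replicate/condition layout.
#'
#' Marker shapes are discretized overlapping unimodal (Gaussian) curves over
#' the fraction axis, emulating the characteristic ordered enrichment seen
#' in real gradients: the plastid markers band at low density, the vacuole
#' at high density, the cytosol in between. Positions and widths are given
#' as fractions of the axis range so the shapes scale with `f`.
#'
#' @param f Number of gradient fractions (default 6).
#' @param n_metabolites Number of simulated metabolites (default 10).
#' @param n_replicates Replicates per condition (default 3).
#' @param n_conditions 1 or 2 experimental conditions (default 1).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   technical noise on raw abundances (default 0.05, a typical photometry /
#'   GC-MS technical error).
#' @param marker_positions Peak positions of the three marker shapes on the
#'   `[0, 1]` fraction axis (0 = lightest fraction).
#' @param marker_widths Gaussian widths on the same scale.
#' @param density_range Fraction densities (g cm^-3), lightest to densest,
#'   interpolated over `f` fractions.
#' @param seed Master seed; all randomness is derived from it.
#' @return A `naf_synthetic_config` list.
#' @export
synthetic_config <- function(f = 6L, n_metabolites = 10L, n_replicates = 3L,
                             n_conditions = 1L, noise_cv = 0.05,
                             marker_positions = c(plastid = 0.15,
                                                  cytosol = 0.5,
                                                  vacuole = 0.9),
                             marker_widths = c(plastid = 0.2,
                                               cytosol = 0.22,
                                               vacuole = 0.18),
                             density_range = c(1.30, 1.55),
                             seed = 1L) {
  if (f < 2L) stop("need at least 2 fractions")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (!n_conditions %in% 1:2) stop("n_conditions must be 1 or 2")
  comps <- naf_compartments()
  if (!setequal(names(marker_positions), comps) ||
      !setequal(names(marker_widths), comps)) {
    stop("marker shape parameters must be named by compartment")
  }
  structure(
    list(f = as.integer(f), n_metabolites = as.integer(n_metabolites),
         n_replicates = as.integer(n_replicates),
         n_conditions = as.integer(n_conditions),
         noise_cv = noise_cv,
         marker_positions = marker_positions[comps],
         marker_widths = marker_widths[comps],
         density_range = density_range, seed = as.integer(seed)),
    class = "naf_synthetic_config"
  )
}

# Derive reproducible sub-seeds from the master seed, one per named stream.
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max, n)
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate idealized marker percent profiles
#'
#' Evaluates the configured unimodal marker shapes on the fraction grid and
#' normalizes each to 100%. The output is deterministic (technical noise is
#' applied per replicate by [generate_experiment()], not here). Setting all
#' three positions/widths identical is allowed and produces the degenerate
#' full-tie regime; a flag attribute marks it.
#'
#' @param config A [synthetic_config()].
#' @return A [marker_profiles()] object; attribute `degenerate` is `TRUE`
#'   when all shapes coincide.
#' @export
generate_marker_profiles <- function(config = synthetic_config()) {
  x <- seq(0, 1, length.out = config$f)
  shapes <- lapply(naf_compartments(), function(cc) {
    exp(-0.5 * ((x - config$marker_positions[cc]) /
                  config$marker_widths[cc])^2)
  })
  names(shapes) <- naf_compartments()
  degenerate <- length(unique(lapply(shapes, round, 12))) == 1L
  if (degenerate) {
    warning("all marker shapes identical: full-tie regime")
  }
  mp <- marker_profiles(shapes)
  attr(mp, "degenerate") <- degenerate
  mp
}

#' Generate one metabolite's raw fraction profile
#'
#' The raw profile is a convex mixture of the marker percent profiles,
#' `sum_c w_c * marker_c(fraction)`, scaled to a peak-area-like magnitude
#' and perturbed by i.i.d. multiplicative lognormal noise with the given
#' coefficient of variation (mean 1, so noise does not bias the expected
#' profile).
#'
#' @param true_weights Named weights on the compartment simplex (sum 1,
#'   non-negative).
#' @param markers A [marker_profiles()] object.
#' @param noise_cv Noise coefficient of variation.
#' @param seed Optional seed applied before drawing the noise.
#' @param amplitude Scale of the raw values (default 1e5).
#' @return A [fraction_profile()] of kind `"metabolite"`.
#' @export
generate_metabolite_profile <- function(true_weights, markers,
                                        noise_cv = 0.05, seed = NULL,
                                        amplitude = 1e5) {
  comps <- names(markers)
  w <- true_weights[comps]
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("true_weights must be non-negative and sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  mix <- Reduce(`+`, lapply(comps, function(cc) w[cc] * markers[[cc]]$percents))
  raw <- amplitude * (mix / 100) * lognormal_noise(length(mix), noise_cv)
  fraction_profile("synthetic_metabolite", raw, kind = "metabolite")
}

#' Generate a full synthetic experiment with known ground truth
#'
#' Emulates a complete NAF study: per-replicate marker profiles (ideal
#' shapes with multiplicative technical noise applied to raw activities),
#' metabolites as convex mixtures of the compartment profiles with weights
#' drawn uniformly on the simplex, replicates, and optionally two
#' conditions with independently drawn weights. Whole-tissue absolute
#' levels are generated alongside so the absolute-level stage can be
#' exercised.
#'
#' @param config A [synthetic_config()].
#' @return A list: `experiment` (a `naf_experiment` with fraction densities
#'   attached), `truth` (data frame `condition`, `metabolite`, one weight
#'   column per compartment), `whole_tissue` (data frame `condition`,
#'   `analyte_id`, `mean`, `sd`), `markers` (the ideal
#'   [marker_profiles()]), `config`.
#' @export
generate_experiment <- function(config = synthetic_config()) {
  comps <- naf_compartments()
  markers <- generate_marker_profiles(config)
  densities <- seq(config$density_range[1], config$density_range[2],
                   length.out = config$f)
  seeds <- derive_seeds(config$seed, 4L)
  conditions <- paste0("condition_", seq_len(config$n_conditions))

  set.seed(seeds[1])  # ground-truth weights, uniform on the simplex
  truth <- do.call(rbind, lapply(conditions, function(cond) {
    w <- matrix(stats::rexp(config$n_metabolites * length(comps)),
                ncol = length(comps))
    w <- w / rowSums(w)
    colnames(w) <- comps
    data.frame(condition = cond,
               metabolite = sprintf("met_%02d", seq_len(config$n_metabolites)),
               w)
  }))

  set.seed(seeds[2])  # whole-tissue absolute levels
  whole <- do.call(rbind, lapply(conditions, function(cond) {
    data.frame(condition = cond,
               analyte_id = sprintf("met_%02d", seq_len(config$n_metabolites)),
               mean = stats::rlnorm(config$n_metabolites, log(100), 0.5),
               sd = NA_real_)
  }))
  whole$sd <- whole$mean * config$noise_cv

  set.seed(seeds[3])  # measurement noise
  rows <- list()
  for (cond in conditions) {
    for (rep_k in seq_len(config$n_replicates)) {
      sid <- sprintf("%s_rep%d", cond, rep_k)
      for (cc in comps) {
        raw <- markers[[cc]]$percents *
          lognormal_noise(config$f, config$noise_cv)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, condition = cond, replicate = rep_k,
          fraction_index = seq_len(config$f),
          analyte_id = paste0("marker_", cc), kind = "marker_enzyme",
          value = raw)
      }
      tw <- truth[truth$condition == cond, ]
      for (m in seq_len(config$n_metabolites)) {
        w <- stats::setNames(as.numeric(tw[m, comps]), comps)
        mix <- Reduce(`+`, lapply(comps, function(cc)
          w[cc] * markers[[cc]]$percents))
        raw <- 1e5 * (mix / 100) * lognormal_noise(config$f, config$noise_cv)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, condition = cond, replicate = rep_k,
          fraction_index = seq_len(config$f),
          analyte_id = tw$metabolite[m], kind = "metabolite", value = raw)
      }
    }
  }
  experiment <- experiment_table(do.call(rbind, rows), densities = densities)
  list(experiment = experiment, truth = truth, whole_tissue = whole,
       markers = markers, config = config)
}

#' Write / read ground-truth weights
#'
#' JSON round-trip for the truth table emitted by [generate_experiment()].
#'
#' @param truth Truth data frame.
#' @param path JSON path.
#' @return `read_truth` returns the truth data frame.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
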