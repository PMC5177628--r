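#' Default compartment labels
#'
#' The three subcellular compartments resolved by the marker-enzyme triple:
#' plastid (alkaline pyrophosphatase), cytosol (UGPase) and vacuole (acid
#' phosphatase). The set is fixed per run; configurations may substitute a
#' different marker set but the default is these three.
#'
#' @return Character vector of compartment labels.
#' @export
naf_compartments <- function() c("plastid", "cytosol", "vacuole")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction profile of one analyte
#'
#' One analyte's raw values (enzyme activity or GC-MS peak area) over the
#' ordered gradient fractions. Fraction index 1 is the lightest fraction
#' (the last supernatant); index `f` is the densest. Missing values (`NA`)
#' are allowed for metabolites and mean "not detected"; marker profiles must
#' be complete.
#'
#' @param analyte_id Analyte identifier.
#' @param values Numeric vector of length `f`; non-missing values must be
#'   non-negative.
#' @param kind `"marker_enzyme"` or `"metabolite"`.
#' @param fraction_densities Optional numeric vector of fraction densities
#'   (g cm^-3), strictly monotone, same length as `values`.
#' @return A `naf_fraction_profile` object.
#' @export
fraction_profile <- function(analyte_id, values,
                             kind = c("metabolite", "marker_enzyme"),
                             fraction_densities = NULL) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("profile needs at least one fraction")
  if (any(!is.na(values) & values < 0)) {
    stop(sprintf("negative value in profile '%s'", analyte_id))
  }
  if (kind == "marker_enzyme" && anyNA(values)) {
    stop(sprintf("marker profile '%s' has missing values", analyte_id))
  }
  if (!is.null(fraction_densities)) {
    fraction_densities <- as.numeric(fraction_densities)
    if (length(fraction_densities) != length(values)) {
      stop("fraction_densities and values differ in length")
    }
    d <- diff(fraction_densities)
    if (!(all(d > 0) || all(d < 0))) {
      stop("fraction_densities must be strictly monotone")
    }
  }
  structure(
    list(analyte_id = as.character(analyte_id), kind = kind,
         values = values, fraction_densities = fraction_densities),
    class = "naf_fraction_profile"
  )
}

#' Percent-normalize a fraction profile
#'
#' Scales the detected (non-missing) values of a profile so that they sum to
#' 100, giving the analyte's relative distribution over the gradient.
#' Undetected fractions carry no percent (`NA`) and are excluded from
#' downstream pair building.
#'
#' @param profile A [fraction_profile()] or a plain numeric vector.
#' @param analyte_id Identifier used when `profile` is a bare vector.
#' @return A `naf_percent_profile` with fields `analyte_id`, `percents`
#'   (`NA` where undetected) and `detected` (logical mask).
#' @examples
#' normalize_profile(c(2, 2, 4, 2))$percents  # 20 20 40 20
#' @export
normalize_profile <- function(profile, analyte_id = "analyte") {
  if (inherits(profile, "naf_percent_profile")) return(profile)
  if (inherits(profile, "naf_fraction_profile")) {
    values <- profile$values
    analyte_id <- profile$analyte_id
  } else {
    values <- as.numeric(profile)
  }
  detected <- !is.na(values)
  total <- sum(values[detected])
  if (!any(detected) || total <= 0) {
    stop(sprintf("undetectable analyte '%s': no positive detected values",
                 analyte_id))
  }
  percents <- rep(NA_real_, length(values))
  percents[detected] <- 100 * values[detected] / total
  structure(
    list(analyte_id = as.character(analyte_id), percents = percents,
         detected = detected),
    class = "naf_percent_profile"
  )
}

#' @export
print.naf_percent_profile <- function(x, ...) {
  cat(sprintf("<percent profile '%s', %d fractions, %d detected>\n",
              x$analyte_id, length(x$percents), sum(x$detected)))
  print(round(x$percents, 2))
  invisible(x)
}

#' Marker profiles for one replicate
#'
#' Bundles the per-compartment percent profiles of the marker enzymes for a
#' single replicate. All profiles must share the fraction axis, be fully
#' detected and each sum to 100.
#'
#' @param ... Named arguments, one percent profile (or raw numeric profile,
#'   normalized on the fly) per compartment; names are the compartment
#'   labels.
#' @param compartments Expected compartment set (defaults to the
#'   plastid/cytosol/vacuole triple).
#' @return A `naf_marker_profiles` object: a named list of percent profiles.
#' @export
marker_profiles <- function(..., compartments = naf_compartments()) {
  profs <- list(...)
  if (length(profs) == 1L && is.list(profs[[1]]) &&
      !inherits(profs[[1]], "naf_percent_profile")) {
    profs <- profs[[1]]
  }
  if (is.null(names(profs)) || !setequal(names(profs), compartments)) {
    stop(sprintf("marker profiles must be named exactly: %s",
                 paste(compartments, collapse = ", ")))
  }
  profs <- profs[compartments]
  profs <- lapply(seq_along(profs), function(k) {
    p <- normalize_profile(profs[[k]], analyte_id = compartments[k])
    if (!all(p$detected)) {
      stop(sprintf("marker profile '%s' has undetected fractions",
                   compartments[k]))
    }
    p
  })
  names(profs) <- compartments
  f <- unique(vapply(profs, function(p) length(p$percents), integer(1)))
  if (length(f) != 1L) stop("marker profiles differ in fraction count")
  structure(profs, class = "naf_marker_profiles")
}

#' @export
print.naf_marker_profiles <- function(x, ...) {
  f <- length(x[[1]]$percents)
  cat(sprintf("<marker profiles: %s; %d fractions>\n",
              paste(names(x), collapse = "/"), f))
  m <- do.call(rbind, lapply(x, function(p) round(p$percents, 2)))
  print(m)
  invisible(x)
}

# ---- experiment table -------------------------------------------------------

experiment_columns <- c("sample_id", "condition", "replicate",
                        "fraction_index", "analyte_id", "kind", "value")

#' Assemble a validated experiment table
#'
#' Long-format container for a NAF experiment: one row per (sample, fraction,
#' analyte) with the raw measured value. Fractions per sample must form a
#' contiguous 1..f range and the (sample, fraction, analyte) key must be
#' unique.
#'
#' @param df Data frame with columns `sample_id`, `condition`, `replicate`,
#'   `fraction_index`, `analyte_id`, `kind` (`marker_enzyme`/`metabolite`)
#'   and `value`.
#' @param densities Optional numeric vector of fraction densities
#'   (g cm^-3), one per fraction index, attached as metadata.
#' @return A `naf_experiment` data frame.
#' @export
experiment_table <- function(df, densities = NULL) {
  missing_cols <- setdiff(experiment_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(df)[experiment_columns]
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$replicate <- as.integer(df$replicate)
  df$fraction_index <- as.integer(df$fraction_index)
  df$analyte_id <- as.character(df$analyte_id)
  df$kind <- as.character(df$kind)
  df$value <- as.numeric(df$value)
  bad_kind <- !df$kind %in% c("marker_enzyme", "metabolite")
  if (any(bad_kind)) {
    stop(sprintf("unknown kind at row %d: '%s'",
                 which(bad_kind)[1], df$kind[which(bad_kind)[1]]))
  }
  neg <- which(!is.na(df$value) & df$value < 0)
  if (length(neg)) {
    stop(sprintf("negative value at row %d (analyte '%s')",
                 neg[1], df$analyte_id[neg[1]]))
  }
  key <- paste(df$sample_id, df$fraction_index, df$analyte_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (sample, fraction, analyte) at row %d",
                 which(duplicated(key))[1]))
  }
  for (s in unique(df$sample_id)) {
    fr <- sort(unique(df$fraction_index[df$sample_id == s]))
    if (!identical(fr, seq_len(max(fr)))) {
      stop(sprintf("sample '%s': fractions are not a contiguous 1..f range", s))
    }
  }
  if (!is.null(densities)) {
    f <- max(df$fraction_index)
    if (length(densities) != f) {
      stop("densities length must equal the fraction count")
    }
    attr(df, "densities") <- as.numeric(densities)
  }
  class(df) <- c("naf_experiment", "data.frame")
  df
}

#' Read an experiment table from CSV/TSV
#'
#' Reads either the long dialect (columns `sample_id`, `condition`,
#' `replicate`, `fraction_index`, `analyte_id`, `kind`, `value`) or the wide
#' dialect (one row per analyte and sample, fraction values in columns
#' `fraction_1` .. `fraction_f`). Field separator is inferred from the file
#' extension (`.tsv`/`.txt` = tab, otherwise comma). Empty cells are treated
#' as "not detected".
#'
#' @param path File path.
#' @param format `"auto"` (detect from the header), `"long"` or `"wide"`.
#' @param densities Optional fraction densities passed to
#'   [experiment_table()].
#' @return A `naf_experiment` data frame.
#' @export
read_experiment <- function(path, format = c("auto", "long", "wide"),
                            densities = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (format == "auto") {
    format <- if ("fraction_index" %in% names(raw)) "long" else "wide"
  }
  if (format == "long") {
    return(experiment_table(raw, densities = densities))
  }
  frac_cols <- grep("^fraction_\\d+$", names(raw), value = TRUE)
  if (!length(frac_cols)) {
    stop("missing column(s): fraction_1..fraction_f (wide dialect)")
  }
  id_cols <- c("sample_id", "condition", "replicate", "analyte_id", "kind")
  missing_cols <- setdiff(id_cols, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  frac_idx <- as.integer(sub("^fraction_", "", frac_cols))
  long <- do.call(rbind, lapply(seq_along(frac_cols), function(k) {
    out <- raw[id_cols]
    out$fraction_index <- frac_idx[k]
    out$value <- as.numeric(raw[[frac_cols[k]]])
    out
  }))
  experiment_table(long, densities = densities)
}

#' Write an experiment table to CSV/TSV
#'
#' Inverse of [read_experiment()]; round-trips all records. Separator is
#' inferred from the extension as in [read_experiment()].
#'
#' @param x A `naf_experiment`.
#' @param path Output path.
#' @param format `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(x, path, format = c("long", "wide")) {
  format <- match.arg(format)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  if (format == "long") {
    out <- as.data.frame(x)[experiment_columns]
  } else {
    f <- max(x$fraction_index)
    ids <- unique(as.data.frame(x)[c("sample_id", "condition", "replicate",
                                     "analyte_id", "kind")])
    out <- ids
    for (k in seq_len(f)) {
      col <- rep(NA_real_, nrow(ids))
      sub <- x[x$fraction_index == k, ]
      m <- match(paste(ids$sample_id, ids$analyte_id),
                 paste(sub$sample_id, sub$analyte_id))
      col[!is.na(m)] <- sub$value[m[!is.na(m)]]
      out[[sprintf("fraction_%d", k)]] <- col
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

# ---- algorithm configuration ------------------------------------------------

#' Configure the hit-counting algorithm
#'
#' @param bounds Uncertainty bounds in percentage points, strictly increasing
#'   and positive. The defaults 5, 7.5 and 10 represent the average technical
#'   error of photometric enzyme assays and GC-MS quantification; using three
#'   graded bounds instead of a single one lets slight slope differences be
#'   distinguished from strong ones.
#' @param single_fraction_hit_weight Hits awarded in the single-fraction
#'   special case; defaults to `length(bounds)` so the special case carries
#'   the same weight as a unanimous fraction pair.
#' @param tie_policy `"all-pass"` (every compartment tied at the maximum gets
#'   the full weight) or `"split"` (the weight is divided among them). Only
#'   relevant in the single-fraction special case; relative distributions are
#'   identical under both.
#' @param strict_inequality Use strict `<` when comparing `psi - min` to a
#'   bound (the printed form); boundary-equal differences then do not hit.
#' @param scheme `"bound-loop"` (default): per pair and per bound, every
#'   compartment within the bound of the minimum earns a hit, so the arg-min
#'   compartment always earns `length(bounds)` hits and a full three-way tie
#'   yields 33.3/33.3/33.3. `"min-plus-bounds"`: one additional separate hit
#'   for the (first) arg-min compartment, for sensitivity analysis.
#' @param slope_mode `"difference"` (default): a slope is the plain
#'   percentage-point difference between two fractions. Because the psi
#'   distance subtracts slopes of identically indexed pairs, any common
#'   denominator cancels; `"density-normalized"` divides by the density
#'   spacing and is provided as a variant (requires fraction densities).
#' @return An `naf_algorithm_config` list.
#' @export
algorithm_config <- function(bounds = c(5, 7.5, 10),
                             single_fraction_hit_weight = length(bounds),
                             tie_policy = c("all-pass", "split"),
                             strict_inequality = TRUE,
                             scheme = c("bound-loop", "min-plus-bounds"),
                             slope_mode = c("difference", "density-normalized")) {
  bounds <- as.numeric(bounds)
  if (!length(bounds) || any(bounds <= 0) || is.unsorted(bounds, strictly = TRUE)) {
    stop("bounds must be positive and strictly increasing")
  }
  if (single_fraction_hit_weight <= 0) {
    stop("single_fraction_hit_weight must be positive")
  }
  structure(
    list(bounds = bounds,
         single_fraction_hit_weight = single_fraction_hit_weight,
         tie_policy = match.arg(tie_policy),
         strict_inequality = isTRUE(strict_inequality),
         scheme = match.arg(scheme),
         slope_mode = match.arg(slope_mode)),
    class = "naf_algorithm_config"
  )
}
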