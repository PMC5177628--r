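#' Significance stars for a p-value
#'
#' Pure threshold mapping: `p < 0.05` = `*`, `p < 0.01` = `**`,
#' `p < 0.001` = `***`, otherwise empty.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @return Character vector of star marks.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

#' Compare one variable across conditions
#'
#' One-way ANOVA across the condition groups. With two conditions the ANOVA
#' p-value is reported (equivalent to the two-sample pooled F test); with
#' more than two, Tukey HSD pairwise comparisons are appended. The direction
#' arrow is the sign of the later group's mean minus the earlier group's
#' (e.g. acclimated minus non-acclimated).
#'
#' @param groups Named list of numeric replicate vectors, one per
#'   condition, each with at least 2 replicates.
#' @return A `naf_condition_comparison` list: `p_value`, `direction`
#'   (`"up"`, `"down"`, `"none"`), `stars`, and for more than two groups a
#'   `tukey` data frame (`contrast`, `diff`, `p_adj`, `stars`).
#' @export
compare_conditions <- function(groups) {
  if (length(groups) < 2L) stop("need at least two condition groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("need at least 2 replicates per group")
  }
  values <- unlist(groups, use.names = FALSE)
  cond <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                 levels = names(groups))
  means <- vapply(groups, mean, numeric(1))
  ss_within <- sum((values - means[as.integer(cond)])^2)
  ss_between <- sum(vapply(groups, length, integer(1)) *
                      (means - mean(values))^2)
  if (ss_within < 1e-24) {
    # degenerate: no within-group variance; aov would return NaN
    p <- if (ss_between < 1e-24) 1 else 0
    fit <- NULL
  } else {
    fit <- stats::aov(values ~ cond)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
  }
  dmean <- means[length(means)] - means[1L]
  direction <- if (p < 0.05 && dmean > 0) "up"
               else if (p < 0.05 && dmean < 0) "down" else "none"
  out <- list(p_value = p, direction = direction,
              stars = significance_stars(p))
  if (length(groups) > 2L && !is.null(fit)) {
    tk <- stats::TukeyHSD(fit)$cond
    out$tukey <- data.frame(contrast = rownames(tk),
                            diff = tk[, "diff"],
                            p_adj = tk[, "p adj"],
                            stars = significance_stars(tk[, "p adj"]),
                            row.names = NULL)
  }
  class(out) <- "naf_condition_comparison"
  out
}

#' Condition comparison table for an assignment
#'
#' Applies [compare_conditions()] to the per-replicate percents of every
#' metabolite and compartment of an assignment with two or more conditions,
#' producing the annotated layout used for relative-distribution tables
#' (mean difference direction arrows and significance stars). No
#' family-wise correction is applied across metabolites.
#'
#' @param assignment A `naf_assignment` covering >= 2 conditions.
#' @return Data frame: `metabolite`, `compartment`, `p_value`, `direction`,
#'   `arrow`, `stars`.
#' @export
condition_comparison <- function(assignment) {
  pr <- assignment$per_replicate
  conds <- unique(pr$condition)
  if (length(conds) < 2L) stop("assignment has a single condition")
  rows <- list()
  for (met in unique(pr$metabolite)) {
    for (comp in unique(pr$compartment)) {
      sub <- pr[pr$metabolite == met & pr$compartment == comp, ]
      groups <- lapply(conds, function(cc) sub$percent[sub$condition == cc])
      names(groups) <- conds
      if (any(vapply(groups, length, integer(1)) < 2L)) next
      cmp <- compare_conditions(groups)
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = met, compartment = comp, p_value = cmp$p_value,
        direction = cmp$direction,
        arrow = switch(cmp$direction, up = "↑", down = "↓", ""),
        stars = cmp$stars)
    }
  }
  do.call(rbind, rows)
}

#' Z-score scale the rows of a matrix
#'
#' Centers each row to mean 0 and scales to unit variance (sample SD,
#' n-1 denominator, matching the replicate-SD convention; the population
#' denominator is available). Constant rows cannot be scaled and are
#' dropped with a warning.
#'
#' @param mat Numeric matrix; rows are the variables (e.g. metabolite x
#'   compartment), columns the condition means.
#' @param denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return The scaled matrix (possibly with fewer rows).
#' @export
zscore_scale <- function(mat, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  mat <- as.matrix(mat)
  sds <- apply(mat, 1L, stats::sd)
  if (denominator == "population") {
    sds <- sds * sqrt((ncol(mat) - 1) / ncol(mat))
  }
  keep <- sds > 0
  if (any(!keep)) {
    warning(sprintf("dropped %d constant row(s): %s", sum(!keep),
                    paste(rownames(mat)[!keep], collapse = ", ")))
  }
  mat <- mat[keep, , drop = FALSE]
  (mat - rowMeans(mat)) / sds[keep]
}

#' Hierarchical clustering on Euclidean distances
#'
#' Agglomerative clustering of the rows or columns of a (typically
#' z-scored) matrix on Euclidean distances; linkage defaults to average.
#'
#' @param mat Numeric matrix.
#' @param axis `"rows"` or `"columns"`.
#' @param method Linkage: `"average"` (default), `"single"`, `"complete"`
#'   or `"ward"` (Ward D2).
#' @return A `naf_cluster` list: `hclust` (the [stats::hclust] tree),
#'   `merge`, `heights`, `order` (leaf order), `labels`.
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "columns"),
                                 method = c("average", "single",
                                            "complete", "ward")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  m <- if (axis == "columns") t(mat) else as.matrix(mat)
  if (nrow(m) < 2L) stop("need at least 2 items to cluster")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = if (method == "ward") "ward.D2" else method)
  structure(
    list(hclust = hc, merge = hc$merge, heights = hc$height,
         order = hc$order, labels = hc$labels),
    class = "naf_cluster"
  )
}
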