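# Independent brute-force oracles. These deliberately avoid every package
# code path for the quantity they check: explicit loops, no shared helpers.

# Hit table by exhaustive loops over detected pairs, compartments and bounds.
# met_raw: raw metabolite values (NA = not detected);
# marker_percents: named list of percent vectors (each sums to 100).
oracle_hit_table <- function(met_raw, marker_percents,
                             bounds = c(5, 7.5, 10), strict = TRUE) {
  comps <- names(marker_percents)
  hits <- setNames(numeric(length(comps)), comps)
  detected <- which(!is.na(met_raw))
  met_pct <- rep(NA_real_, length(met_raw))
  met_pct[detected] <- 100 * met_raw[detected] / sum(met_raw[detected])
  if (length(detected) < 2L) {
    at <- sapply(comps, function(cc) marker_percents[[cc]][detected])
    top <- which(at == max(at))
    hits[top] <- length(bounds)
    return(hits)
  }
  for (a in seq_along(detected)) {
    for (b in seq_along(detected)) {
      if (b <= a) next
      i <- detected[a]; j <- detected[b]
      met_delta <- met_pct[j] - met_pct[i]
      psi <- numeric(0)
      for (cc in comps) {
        comp_delta <- marker_percents[[cc]][j] - marker_percents[[cc]][i]
        psi[cc] <- abs(met_delta - comp_delta)
      }
      m <- min(psi)
      for (cc in comps) {
        for (bnd in bounds) {
          diff <- psi[cc] - m
          if ((strict && diff < bnd) || (!strict && diff <= bnd)) {
            hits[cc] <- hits[cc] + 1
          }
        }
      }
    }
  }
  hits
}

# Textbook one-way fixed-effects ANOVA p-value.
oracle_anova_p <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(sapply(groups, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

# Naive O(n^3) average-linkage agglomeration; returns the cophenetic
# distance matrix (merge height at which each pair first joins).
oracle_average_linkage_cophenetic <- function(mat) {
  n <- nrow(mat)
  d <- as.matrix(stats::dist(mat))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        h <- mean(d[clusters[[a]], clusters[[b]]])
        if (h < best_h) { best_h <- h; best <- c(a, b) }
      }
    }
    ca <- clusters[[best[1]]]; cb <- clusters[[best[2]]]
    for (x in ca) for (y in cb) coph[x, y] <- coph[y, x] <- best_h
    clusters[[best[1]]] <- c(ca, cb)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Random percent-profile generator for property tests: f fractions, optional
# missingness (always leaving >= min_detected detected fractions).
random_raw_profile <- function(f, allow_na = TRUE, min_detected = 2L) {
  raw <- stats::runif(f, 0.1, 10)
  if (allow_na && f > min_detected && stats::runif(1) < 0.4) {
    drop <- sample(f, sample.int(f - min_detected, 1))
    raw[drop] <- NA
  }
  raw
}

random_marker_percents <- function(f) {
  lapply(setNames(nm = nafkit::naf_compartments()), function(cc) {
    raw <- stats::runif(f, 0.1, 10)
    100 * raw / sum(raw)
  })
}
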