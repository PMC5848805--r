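# Soft clustering of chromatin-accessibility trajectories: row-standardized
# log2 profiles, fuzzifier estimation, fuzzy c-means with a fixed seed,
# cluster-number selection from the minimum-centroid-distance curve, and
# biological labeling of the resulting trajectory shapes.

#' Standardize per-window activity profiles
#'
#' Averages representative scores over replicates within each (species,
#' time) cell, takes log2(x + offset), and z-scores each window's profile
#' across time. Zero-variance rows are dropped (count recorded in the
#' `n_dropped` attribute).
#'
#' @param scores Windows x samples score matrix (from
#'   [score_and_classify()]).
#' @param replicate_map Design data frame covering the score columns.
#' @param species Which species' samples to profile.
#' @param offset Added inside the log2 so zero activity is admissible.
#' @return Matrix (windows x time points, ordered Pre..T24) with rows of
#'   mean 0 and sd 1; class `profile_matrix`.
#' @export
standardize_profiles <- function(scores, replicate_map, species, offset = 1) {
  map <- replicate_map[replicate_map$species == species, , drop = FALSE]
  if (!nrow(map)) stop("no samples for species '", species, "'")
  tps <- intersect(time_levels(), unique(as.character(map$time)))
  if (length(tps) < 2) stop("need at least 2 time points")
  prof <- vapply(tps, function(tp) {
    cols <- map$sample[as.character(map$time) == tp]
    rowMeans(scores[, cols, drop = FALSE])
  }, numeric(nrow(scores)))
  dimnames(prof) <- list(rownames(scores), tps)
  prof <- log2(prof + offset)
  mu <- rowMeans(prof)
  sdv <- apply(prof, 1, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all profiles are constant; nothing to standardize")
  z <- (prof[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  attr(z, "n_dropped") <- sum(!keep)
  class(z) <- c("profile_matrix", class(z))
  z
}

#' Estimate the fuzzifier from data dimensions
#'
#' The published minimum-fuzzifier estimator for soft c-means on
#' standardized expression-like profiles, a function of the number of rows
#' N and columns D only:
#' m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134).
#'
#' @param pm Profile matrix (or anything with >= 2 rows and columns).
#' @return Fuzzifier m > 1.
#' @export
estimate_fuzzifier <- function(pm) {
  N <- nrow(pm)
  D <- ncol(pm)
  if (is.null(N) || N < 2 || is.null(D) || D < 2) {
    stop("fuzzifier estimation needs at least 2 rows and 2 columns")
  }
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means with Euclidean distance: alternates membership
#' and centroid updates until the largest centroid shift falls below `tol`.
#' Centroids are ordered canonically by their value at the final time point
#' (decreasing) so cluster identities are reproducible.
#'
#' @param pm Profile matrix (rows are windows, columns time points).
#' @param c Number of clusters, `2 <= c < nrow(pm)`.
#' @param m Fuzzifier (> 1), e.g. from [estimate_fuzzifier()].
#' @param seed Seed for the random centroid initialization.
#' @param tol Convergence tolerance on the centroid shift.
#' @param max_iter Iteration cap.
#' @return Object of class `fuzzy_clustering`: `centroids` (c x T),
#'   `membership` (N x c, rows summing to 1), `m`, `c`, `objective`
#'   (per-iteration values), `converged`, `iterations`.
#' @export
fuzzy_cmeans <- function(pm, c, m, seed = 1, tol = 1e-6, max_iter = 500) {
  X <- unclass(pm)
  N <- nrow(X)
  if (c < 2 || c >= N) stop("cluster count must satisfy 2 <= c < N")
  if (m <= 1) stop("fuzzifier must exceed 1")
  set.seed(seed)
  centroids <- X[sample.int(N, c), , drop = FALSE]
  expo <- 2 / (m - 1)
  obj <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(c), function(k) {
      rowSums((X - matrix(centroids[k, ], N, ncol(X), byrow = TRUE))^2)
    }, numeric(N))
    zero <- d2 < 1e-12
    d2 <- pmax(d2, 1e-12)
    inv <- (1 / d2)^(expo / 2)
    u <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0   # coincides with a centroid: crisp membership
    if (any(hit)) {
      u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    obj <- c(obj, sum(u^m * d2))
    um <- u^m
    new_cent <- t(um) %*% X / colSums(um)
    shift <- max(abs(new_cent - centroids))
    centroids <- new_cent
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  ord <- order(-centroids[, ncol(X)])
  centroids <- centroids[ord, , drop = FALSE]
  u <- u[, ord, drop = FALSE]
  rownames(centroids) <- colnames(u) <- paste0("c", seq_len(c))
  structure(list(centroids = centroids, membership = u, m = m, c = c,
                 objective = obj, converged = converged, iterations = it),
            class = "fuzzy_clustering")
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat("fuzzy_clustering:", x$c, "clusters, m =", round(x$m, 3),
      ",", nrow(x$membership), "profiles,",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Choose the cluster number from the Dmin curve
#'
#' Clusters the profiles at every candidate c and records Dmin(c), the
#' minimum pairwise centroid distance. Adding clusters beyond the number of
#' genuine trajectory shapes splits a real cluster and collapses Dmin, so
#' the chosen c is the largest candidate whose drop Dmin(c) - Dmin(c+1)
#' still amounts to at least `drop_frac` of Dmin at the smallest candidate;
#' when no drop is that large the smallest candidate is returned.
#'
#' @param pm Profile matrix.
#' @param c_range Increasing integer vector of candidate cluster numbers.
#' @param m Fuzzifier.
#' @param seed Seed passed to every [fuzzy_cmeans()] run.
#' @param drop_frac Fraction of Dmin at the first candidate that a drop
#'   must reach to count as substantial.
#' @return List with `c` (chosen), `dmin` (named curve), `drops`.
#' @export
choose_cluster_number <- function(pm, c_range = 2:8, m, seed = 1,
                                  drop_frac = 0.1) {
  if (!length(c_range)) stop("empty cluster-number range")
  c_range <- sort(unique(as.integer(c_range)))
  dmin <- vapply(c_range, function(cc) {
    fc <- fuzzy_cmeans(pm, cc, m, seed = seed)
    min(stats::dist(fc$centroids))
  }, numeric(1))
  names(dmin) <- c_range
  if (length(c_range) == 1) {
    return(list(c = c_range, dmin = dmin, drops = numeric(0)))
  }
  drops <- -diff(dmin)
  names(drops) <- utils::head(c_range, -1)
  big <- which(drops >= drop_frac * dmin[1])
  chosen <- if (length(big)) c_range[max(big)] else c_range[1]
  list(c = chosen, dmin = dmin, drops = drops)
}

#' Label clusters and windows by trajectory shape
#'
#' Clusters are labeled from their centroid profile: `opening` when the
#' final-time value exceeds the first by at least `delta` (in SD units)
#' with a monotone trend, `closing` symmetrically, `transient_up`/`_down`
#' when the extreme value is interior, otherwise `other`. Windows inherit
#' their best cluster's label when their maximum membership reaches
#' `membership_min`, and are `other` below it.
#'
#' @param fc A [fuzzy_cmeans()] result.
#' @param membership_min Minimum membership for a window to be labeled.
#' @param delta Minimum first-to-last centroid change, SD units.
#' @param mono_tol Tolerated counter-movement per step for "monotone".
#' @return List with `window_labels` (named character vector) and
#'   `cluster_labels`.
#' @export
trajectory_classes <- function(fc, membership_min = 0.6, delta = 0.5,
                               mono_tol = 0.1) {
  stopifnot(inherits(fc, "fuzzy_clustering"))
  label_one <- function(v) {
    Tn <- length(v)
    i_max <- which.max(v)
    i_min <- which.min(v)
    if (i_max > 1 && i_max < Tn &&
        v[i_max] >= v[1] + delta && v[i_max] >= v[Tn] + delta) {
      return("transient_up")
    }
    if (i_min > 1 && i_min < Tn &&
        v[i_min] <= v[1] - delta && v[i_min] <= v[Tn] - delta) {
      return("transient_down")
    }
    if (v[Tn] - v[1] >= delta && all(diff(v) >= -mono_tol)) return("opening")
    if (v[1] - v[Tn] >= delta && all(diff(v) <= mono_tol)) return("closing")
    "other"
  }
  cl_labels <- apply(fc$centroids, 1, label_one)
  best <- max.col(fc$membership, ties.method = "first")
  best_u <- fc$membership[cbind(seq_len(nrow(fc$membership)), best)]
  wl <- ifelse(best_u >= membership_min, cl_labels[best], "other")
  names(wl) <- rownames(fc$membership)
  list(window_labels = wl, cluster_labels = cl_labels)
}
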