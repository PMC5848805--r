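# Differential expression for two-species ortholog count matrices:
# trimmed-mean (TMM) normalization factors, per-gene negative binomial GLM
# fits with method-of-moments dispersion shrunk toward a mean-dispersion
# trend, and likelihood-ratio tests with Benjamini-Hochberg FDR control.

#' Construct a count matrix with its sample design
#'
#' @param counts Non-negative integer matrix, genes x samples, with unique
#'   gene rownames and sample colnames.
#' @param design Data frame with columns `sample`, `species`, `time`,
#'   `replicate`, one row per column of `counts` (matched by `sample`).
#' @param lib_sizes Optional per-sample library sizes; defaults to the
#'   column sums.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, design, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique gene rownames")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  stopifnot(all(c("sample", "species", "time", "replicate") %in% names(design)))
  if (is.null(colnames(counts))) colnames(counts) <- design$sample
  if (!setequal(colnames(counts), design$sample) ||
      nrow(design) != ncol(counts)) {
    stop("design samples must match count matrix columns")
  }
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) {
    stop("library size is zero for sample ",
         colnames(counts)[which(lib_sizes <= 0)[1]])
  }
  structure(list(counts = counts, design = design,
                 lib_sizes = stats::setNames(as.numeric(lib_sizes),
                                             colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      paste(tapply(x$design$sample, x$design$species, length), collapse = "+"),
      "by species )\n")
  invisible(x)
}

#' @export
`[.count_matrix` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE],
               x$design[match(colnames(x$counts)[j], x$design$sample), ,
                        drop = FALSE],
               x$lib_sizes[j])
}

#' Remove blacklisted genes from a count matrix
#'
#' Used to drop genes whose expression tracks the cell cycle rather than
#' the serum response before testing. Identifiers absent from the matrix
#' raise a warning, not an error.
#'
#' @param cm A [count_matrix()].
#' @param blacklist Character vector of gene identifiers to remove.
#' @return The count matrix without the blacklisted genes, original gene
#'   order preserved.
#' @export
exclude_genes <- function(cm, blacklist) {
  stopifnot(inherits(cm, "count_matrix"))
  blacklist <- unique(blacklist)
  absent <- setdiff(blacklist, rownames(cm$counts))
  if (length(absent)) {
    warning(length(absent), " blacklisted gene(s) not in matrix: ",
            paste(utils::head(absent, 5), collapse = ", "),
            if (length(absent) > 5) ", ..." else "")
  }
  keep <- !(rownames(cm$counts) %in% blacklist)
  count_matrix(cm$counts[keep, , drop = FALSE], cm$design, cm$lib_sizes)
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Compositional normalization for count libraries: for each sample, the
#' per-gene log ratios (M) against a reference sample are trimmed 30% on
#' each tail, the log intensities (A) 5% on each tail, and the factor is
#' 2^mean of the doubly-trimmed M values. The reference is the sample whose
#' upper-quartile count fraction is closest to the mean upper quartile.
#' Factors are rescaled to geometric mean 1.
#'
#' @param cm A [count_matrix()].
#' @param trim_m,trim_a Tail trim fractions for M and A.
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(cm, trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  y <- cm$counts
  if (ncol(y) < 2) stop("TMM needs at least 2 samples")
  zero_col <- colSums(y) == 0
  if (any(zero_col)) {
    stop("cannot normalize all-zero sample ", colnames(y)[which(zero_col)[1]])
  }
  lib <- cm$lib_sizes
  uq <- vapply(seq_len(ncol(y)), function(k) {
    stats::quantile(y[, k], 0.75) / lib[k]
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(y)), function(k) {
    if (k == ref) return(1)
    ok <- y[, k] > 0 & y[, ref] > 0
    pk <- y[ok, k] / lib[k]
    pr <- y[ok, ref] / lib[ref]
    M <- log2(pk / pr)
    A <- 0.5 * log2(pk * pr)
    n <- length(M)
    if (n == 0) return(1)
    loM <- floor(n * trim_m) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1
    hiA <- n + 1 - loA
    rM <- rank(M)
    rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    2^mean(M[keep])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(y))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_i = min over j >= i of p_(j) * n / j.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# ---- NB GLM machinery -----------------------------------------------------

# Single-gene negative binomial GLM (log link, fixed dispersion phi, offset)
# fitted by iteratively reweighted least squares.
fit_nb_glm <- function(y, X, offset, phi, tol = 1e-8, max_iter = 100) {
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  dev_old <- Inf
  converged <- FALSE
  beta <- rep(NA_real_, ncol(X))
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- pmax(exp(eta), 1e-10)
    dev <- -2 * sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  list(beta = beta, deviance = dev_old, converged = converged)
}

# Per-gene dispersion: a Pearson moment estimator under the full-model cell
# means, a lowess mean-dispersion trend, and empirical-Bayes shrinkage
# toward the trend with a weight estimated from the excess variance of the
# per-gene estimates over their sampling variance. On data whose genes
# share one dispersion the weight collapses to the trend (keeping the
# likelihood-ratio test calibrated); genuine gene-to-gene heterogeneity
# keeps the per-gene component.
estimate_dispersions <- function(y, offset_mat, groups, floor = 1e-4) {
  o <- exp(offset_mat)
  z <- y / o
  h <- 1 / o
  grp <- factor(groups)
  n_s <- ncol(y)
  df <- n_s - nlevels(grp)
  if (df < 1) stop("no residual degrees of freedom to estimate dispersion")
  raw <- vapply(seq_len(nrow(y)), function(g) {
    mu <- stats::ave(z[g, ], grp)
    ok <- mu > 0
    if (sum(ok) < nlevels(grp) + 1) return(NA_real_)
    r2 <- (z[g, ok] - mu[ok])^2
    pearson <- function(phi) {
      sum(r2 / (mu[ok] * h[g, ok] + phi * mu[ok]^2)) - df
    }
    if (pearson(0) <= 0) return(0)
    if (pearson(100) > 0) return(100)
    stats::uniroot(pearson, c(0, 100), tol = 1e-6)$root
  }, numeric(1))
  ave_z <- rowMeans(z)
  ok <- is.finite(raw) & ave_z > 0
  if (sum(ok) >= 10) {
    # iter = 0: the raw estimates are right-skewed and the trend must track
    # their conditional mean, not a robustified centre
    lo <- stats::lowess(log(ave_z[ok]), raw[ok], f = 0.5, iter = 0)
    ux <- !duplicated(lo$x)
    trend <- stats::approx(lo$x[ux], lo$y[ux],
                           xout = log(pmax(ave_z, min(ave_z[ok]))),
                           rule = 2)$y
    trend <- pmax(trend, floor)
  } else {
    trend <- rep(max(mean(raw[ok]), floor), nrow(y))
  }
  # delta-method sampling variance of the per-gene estimate at the trend
  hbar <- rowMeans(h)
  svar <- 2 * (trend + hbar / pmax(ave_z, 1e-8))^2 / df
  excess <- max(0, mean((raw[ok] - trend[ok])^2) - mean(svar[ok]))
  w <- excess / (excess + svar)
  shrunk <- w * ifelse(is.finite(raw), raw, trend) + (1 - w) * trend
  pmax(shrunk, floor)
}

#' Negative binomial GLM likelihood-ratio differential test
#'
#' Fits, for every gene, a negative binomial GLM with log link and offset
#' log(library size x TMM factor) under a full and a reduced model formula,
#' and tests the dropped coefficients with a likelihood-ratio chi-squared
#' test. Dispersions are per-gene Pearson moment estimates shrunk toward a
#' lowess mean-dispersion trend, with the shrinkage weight estimated from
#' the excess gene-to-gene variance of the raw estimates (so homogeneous
#' data collapse to the trend). Genes with zero counts in all samples are
#' excluded before fitting and listed in the `excluded` attribute.
#'
#' @param cm A [count_matrix()].
#' @param full,reduced Model formulas over the design columns (e.g.
#'   `~ species` vs `~ 1`).
#' @param samples Optional character vector restricting the fit to a subset
#'   of samples (e.g. one time point).
#' @param factors Normalization factors; default [tmm_factors()] of the
#'   subsetted matrix.
#' @param fdr Significance threshold on BH-adjusted p-values.
#' @return Data frame (one row per fitted gene) with `gene`, `log2fc`
#'   (for single-coefficient contrasts), `lrt_stat`, `p`, `q`,
#'   `significant`, `converged`. Attributes: `excluded` (all-zero genes),
#'   `df` (contrast rank).
#' @export
de_test <- function(cm, full = ~species, reduced = ~1, samples = NULL,
                    factors = NULL, fdr = 0.10) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is.null(samples)) {
    cm <- cm[, match(samples, colnames(cm$counts))]
  }
  des <- cm$design
  des$time <- droplevels(factor(des$time, levels = time_levels()))
  des$species <- factor(des$species, levels = unique(des$species))
  X1 <- stats::model.matrix(full, des)
  X0 <- stats::model.matrix(reduced, des)
  if (qr(X1)$rank < ncol(X1)) stop("full design is not of full rank")
  if (qr(X0)$rank < ncol(X0)) stop("reduced design is not of full rank")
  df_test <- ncol(X1) - ncol(X0)
  if (df_test < 1) stop("full model must contain the reduced model")
  dropped <- setdiff(colnames(X1), colnames(X0))

  if (is.null(factors)) factors <- tmm_factors(cm)
  y <- cm$counts
  nonzero <- rowSums(y) > 0
  excluded <- rownames(y)[!nonzero]
  y <- y[nonzero, , drop = FALSE]
  off <- log(cm$lib_sizes * factors)
  off <- off - mean(off)            # centre so coefficients stay interpretable
  offset_mat <- matrix(off, nrow(y), ncol(y), byrow = TRUE)

  groups <- apply(X1, 1, paste, collapse = "/")
  phi <- estimate_dispersions(y, offset_mat, groups)

  n <- nrow(y)
  lrt <- lfc <- numeric(n)
  conv <- logical(n)
  for (g in seq_len(n)) {
    f1 <- fit_nb_glm(y[g, ], X1, off, phi[g])
    f0 <- fit_nb_glm(y[g, ], X0, off, phi[g])
    lrt[g] <- max(0, f0$deviance - f1$deviance)
    conv[g] <- f1$converged && f0$converged
    lfc[g] <- if (df_test == 1) f1$beta[dropped] / log(2) else NA_real_
  }
  p <- stats::pchisq(lrt, df = df_test, lower.tail = FALSE)
  q <- bh_adjust(p)
  out <- data.frame(
    gene = rownames(y), log2fc = lfc, lrt_stat = lrt, p = p, q = q,
    significant = q <= fdr, converged = conv
  )
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "df") <- df_test
  attr(out, "contrast") <- dropped
  out
}

#' Summaries of significant between-species calls per time point
#'
#' Reproduces the layout of a per-time-point differential expression table:
#' counts of genes significantly higher in each species, their total, and
#' the B:A ratio rounded to two decimals.
#'
#' @param results Named list (per time point) of [de_test()] result frames
#'   whose `log2fc` is positive when expression is higher in species B.
#' @param fdr FDR threshold applied to the `q` column.
#' @return Data frame with one row per time point: `higher_in_A`,
#'   `higher_in_B`, `total`, `ratio_B_A`.
#' @export
summarize_de_counts <- function(results, fdr = 0.10) {
  stopifnot(is.list(results), !is.null(names(results)))
  rows <- lapply(names(results), function(tp) {
    r <- results[[tp]]
    sig <- r$q <= fdr
    de_count_summary(sum(sig & r$log2fc < 0), sum(sig & r$log2fc > 0),
                     time = tp)
  })
  do.call(rbind, rows)
}

#' Arithmetic summary of directional DE counts
#'
#' @param higher_in_A,higher_in_B Counts of significant genes with higher
#'   expression in species A / species B.
#' @param time Optional time point label.
#' @return One-row data frame with `total` and `ratio_B_A` (2 decimals;
#'   `NA` when `higher_in_A` is zero).
#' @export
de_count_summary <- function(higher_in_A, higher_in_B, time = NA_character_) {
  stopifnot(higher_in_A >= 0, higher_in_B >= 0)
  data.frame(
    time = time,
    higher_in_A = higher_in_A,
    higher_in_B = higher_in_B,
    total = higher_in_A + higher_in_B,
    ratio_B_A = if (higher_in_A > 0) {
      round(higher_in_B / higher_in_A, 2)
    } else {
      NA_real_
    }
  )
}
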