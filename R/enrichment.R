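# Gene set enrichment: the weighted running-sum (GSEA) statistic with
# gene-label permutation significance, hypergeometric category enrichment
# against a user-supplied background, and the set algebra used to isolate
# serum-response-specific and species-common category lists.

#' Build a ranked gene list
#'
#' Orders genes by a signed ranking statistic (descending), breaking ties
#' by gene identifier so the ordering is deterministic.
#'
#' @param genes Character vector of unique gene identifiers.
#' @param stat Signed ranking statistic (e.g. sign(log2fc) * -log10(p)).
#' @return Data frame of class `ranked_list` with columns `gene`, `stat`,
#'   ordered by decreasing statistic.
#' @export
ranked_list <- function(genes, stat) {
  if (anyDuplicated(genes)) stop("ranked list genes must be unique")
  if (length(genes) != length(stat)) stop("genes and stat lengths differ")
  ord <- order(-stat, genes)
  out <- data.frame(gene = genes[ord], stat = stat[ord])
  class(out) <- c("ranked_list", "data.frame")
  out
}

# Core running-sum statistic. Hits increment by |stat|^weight (normalized),
# misses decrement by 1/(N - Nh); the enrichment score is the running sum's
# maximum deviation from zero, signed.
gsea_running_sum <- function(stat, hit, weight = 1) {
  N <- length(stat)
  nh <- sum(hit)
  w <- abs(stat)^weight
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  if (N > nh) inc[!hit] <- -1 / (N - nh)
  rs <- cumsum(inc)
  # at ties the peak furthest into the list is kept, so the leading edge
  # includes every hit contributing to the extreme
  i_max <- max(which(rs >= max(rs) - 1e-12))
  i_min <- min(which(rs <= min(rs) + 1e-12))
  es <- if (rs[i_max] >= -rs[i_min]) rs[i_max] else rs[i_min]
  list(es = es, running = rs, peak = if (es >= 0) i_max else i_min)
}

#' Running-sum gene set enrichment with permutation significance
#'
#' Computes the weighted running-sum enrichment score of a gene set in a
#' ranked list and assesses it against gene-label permutations (random
#' sets of the same size drawn from the ranked genes). The normalized
#' enrichment score divides the observed score by the mean magnitude of
#' same-sign permutation scores.
#'
#' @param rl A [ranked_list()].
#' @param gene_set Character vector of member genes; must intersect the
#'   ranked list.
#' @param weight Exponent on the ranking statistic for hit increments.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutations.
#' @param set_name Label carried into the result.
#' @return List of class `enrichment_result`: `set`, `es`, `nes`, `p`,
#'   `fdr`, `leading_edge`, `size`, `running` (the running-sum vector),
#'   `perm_es`.
#' @export
gsea_enrichment <- function(rl, gene_set, weight = 1, n_perm = 1000,
                            seed = 1, set_name = "set") {
  stopifnot(inherits(rl, "ranked_list"))
  if (n_perm < 100) stop("n_perm must be at least 100")
  hit <- rl$gene %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set '", set_name, "' has no genes in the ranked list")
  obs <- gsea_running_sum(rl$stat, hit, weight)

  set.seed(seed)
  N <- nrow(rl)
  perm_es <- vapply(seq_len(n_perm), function(b) {
    h <- logical(N)
    h[sample.int(N, nh)] <- TRUE
    gsea_running_sum(rl$stat, h, weight)$es
  }, numeric(1))

  same <- if (obs$es >= 0) perm_es >= 0 else perm_es < 0
  n_same <- sum(same)
  p <- (1 + sum(same & abs(perm_es) >= abs(obs$es))) / (1 + n_same)
  nes <- if (n_same > 0) obs$es / mean(abs(perm_es[same])) else NA_real_

  le <- if (obs$es >= 0) {
    rl$gene[seq_len(obs$peak)][hit[seq_len(obs$peak)]]
  } else {
    idx <- obs$peak:N
    rl$gene[idx][hit[idx]]
  }
  structure(list(set = set_name, es = obs$es, nes = nes, p = p, fdr = p,
                 leading_edge = le, size = nh, running = obs$running,
                 perm_es = perm_es),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: ES %.3f, NES %.3f, p %.4g, FDR %.4g (%d genes)\n",
              x$set, x$es, x$nes, x$p, x$fdr, x$size))
  invisible(x)
}

#' Enrichment of a whole gene-set collection
#'
#' Runs [gsea_enrichment()] for every set and computes the canonical
#' sign-stratified permutation FDR: for each set, the fraction of pooled
#' same-sign permutation NES values at least as extreme as its NES, divided
#' by the fraction of observed same-sign NES values at least as extreme.
#'
#' @inheritParams gsea_enrichment
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param min_size Sets with a smaller intersection are skipped.
#' @return Data frame with one row per tested set: `set`, `size`, `es`,
#'   `nes`, `p`, `fdr`.
#' @export
gsea_collection <- function(rl, collection, weight = 1, n_perm = 1000,
                            seed = 1, min_size = 3) {
  keep <- vapply(collection, function(s) sum(rl$gene %in% s) >= min_size,
                 logical(1))
  collection <- collection[keep]
  if (!length(collection)) stop("no gene set overlaps the ranked list")
  res <- lapply(names(collection), function(nm) {
    gsea_enrichment(rl, collection[[nm]], weight = weight, n_perm = n_perm,
                    seed = seed, set_name = nm)
  })
  nes_obs <- vapply(res, `[[`, numeric(1), "nes")
  # permutation NES pool: each permutation score normalized by the same-sign
  # mean within its own set's null
  nes_perm <- unlist(lapply(res, function(r) {
    pos <- r$perm_es[r$perm_es >= 0]
    neg <- r$perm_es[r$perm_es < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) -neg / mean(-neg) * -1)
  }))
  fdr <- vapply(nes_obs, function(s) {
    if (!is.finite(s)) return(NA_real_)
    if (s >= 0) {
      num_pool <- mean(nes_perm[nes_perm >= 0] >= s)
      den_obs <- mean(nes_obs[nes_obs >= 0] >= s)
    } else {
      num_pool <- mean(nes_perm[nes_perm < 0] <= s)
      den_obs <- mean(nes_obs[nes_obs < 0] <= s)
    }
    min(1, num_pool / max(den_obs, 1e-12))
  }, numeric(1))
  data.frame(
    set = names(collection),
    size = vapply(res, `[[`, numeric(1), "size"),
    es = vapply(res, `[[`, numeric(1), "es"),
    nes = nes_obs,
    p = vapply(res, `[[`, numeric(1), "p"),
    fdr = fdr
  )
}

#' Hypergeometric category enrichment against a custom background
#'
#' For each category, tests whether the foreground (e.g. genes upregulated
#' in one species) overlaps the category more than expected given a
#' background universe (e.g. all genes active in fibroblasts of either
#' species). Upper-tail hypergeometric p-values.
#'
#' @param foreground Character vector of genes; must be a subset of
#'   `background`.
#' @param background Character vector defining the universe.
#' @param collection Named list of category gene sets.
#' @return Data frame sorted by p: `set`, `overlap`, `set_in_background`,
#'   `fold`, `p`.
#' @export
hypergeom_enrichment <- function(foreground, background, collection) {
  foreground <- unique(foreground)
  background <- unique(background)
  stray <- setdiff(foreground, background)
  if (length(stray)) {
    stop("foreground genes missing from background: ",
         paste(utils::head(stray, 5), collapse = ", "),
         if (length(stray) > 5) ", ..." else "")
  }
  N <- length(background)
  n <- length(foreground)
  rows <- lapply(names(collection), function(nm) {
    set_bg <- intersect(collection[[nm]], background)
    K <- length(set_bg)
    k <- length(intersect(set_bg, foreground))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K == 0) NA_real_ else (k / n) / (K / N)
    data.frame(set = nm, overlap = k, set_in_background = K, fold = fold, p = p)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Species-common and serum-response-specific category sets
#'
#' Given enriched-category name lists for the four time points, returns
#' either the categories common to all four time points, or the categories
#' enriched during the serum response (T12, T24) but absent from the union
#' of the early time points (Pre, T0). Names are compared
#' case-insensitively after whitespace normalization.
#'
#' @param lists Named list with elements `Pre`, `T0`, `T12`, `T24`, each a
#'   character vector of category names.
#' @param mode `"common"` or `"serum_specific"`.
#' @return For `"common"`, a character vector; for `"serum_specific"`, a
#'   list with elements `T12` and `T24`.
#' @export
category_timepoint_sets <- function(lists, mode = c("common", "serum_specific")) {
  mode <- match.arg(mode)
  need <- c("Pre", "T0", "T12", "T24")
  if (!all(need %in% names(lists))) {
    stop("missing time point list(s): ",
         paste(setdiff(need, names(lists)), collapse = ", "))
  }
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  nl <- lapply(lists[need], norm)
  if (mode == "common") {
    Reduce(intersect, nl)
  } else {
    early <- union(nl$Pre, nl$T0)
    list(T12 = setdiff(nl$T12, early), T24 = setdiff(nl$T24, early))
  }
}
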