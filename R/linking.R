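# Linking accessibility windows to genes: nearest-TSS assignment,
# per-cluster window/gene ratios, correlation of accessibility with
# expression, and exact-score motif scanning.

#' Assign each window to its nearest TSS
#'
#' Distance is measured from the window midpoint to the TSS on the same
#' chromosome (strand ignored); ties go to the lexicographically smaller
#' gene identifier. Windows on chromosomes without annotated genes stay
#' unassigned (NA).
#'
#' @param windows Interval data frame with `chrom`, `start`, `end` and a
#'   `window` id column.
#' @param annotation Data frame with `gene`, `chrom`, `tss`, `strand`.
#' @return Data frame `window`, `gene`, `distance` (bp, >= 0),
#'   `signed_distance` (midpoint - TSS).
#' @export
nearest_tss <- function(windows, annotation) {
  stopifnot(all(c("gene", "chrom", "tss") %in% names(annotation)))
  if (anyDuplicated(annotation$gene)) stop("gene identifiers must be unique")
  mid <- floor((windows$start + windows$end) / 2)
  gene <- rep(NA_character_, nrow(windows))
  sdist <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    wi <- which(windows$chrom == ch)
    if (!nrow(ann)) next
    ord <- order(ann$tss, ann$gene)
    pos <- ann$tss[ord]
    ids <- ann$gene[ord]
    # one entry per distinct TSS position, keeping the smallest gene id
    first <- !duplicated(pos)
    upos <- pos[first]
    uid <- ids[first]
    i <- findInterval(mid[wi], upos)
    left <- pmax(i, 1L)
    right <- pmin(i + 1L, length(upos))
    d_left <- ifelse(i >= 1, mid[wi] - upos[left], Inf)
    d_right <- ifelse(i < length(upos), upos[right] - mid[wi], Inf)
    use_left <- d_left < d_right |
      (d_left == d_right & uid[left] <= uid[right])
    pick <- ifelse(use_left, left, right)
    gene[wi] <- uid[pick]
    sdist[wi] <- mid[wi] - upos[pick]
  }
  data.frame(window = windows$window, gene = gene,
             distance = abs(sdist), signed_distance = sdist)
}

#' Windows and genes per trajectory class
#'
#' Summarizes, per species and trajectory class, how many windows fall in
#' the class and how many distinct genes they are linked to, with the
#' windows-per-gene ratio rounded to two decimals.
#'
#' @param assignments Data frame with columns `species`, `label` (trajectory
#'   class) and `gene` (nearest gene, NA allowed).
#' @param classes Which labels to tabulate.
#' @return Data frame `species`, `label`, `n_windows`, `n_genes`, `ratio`
#'   (NA when no gene is linked).
#' @export
cluster_gene_summary <- function(assignments,
                                 classes = c("opening", "closing")) {
  stopifnot(all(c("species", "label", "gene") %in% names(assignments)))
  combos <- expand.grid(species = unique(assignments$species),
                        label = classes, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- assignments[assignments$species == combos$species[i] &
                         assignments$label == combos$label[i], , drop = FALSE]
    n_w <- nrow(sub)
    n_g <- length(unique(stats::na.omit(sub$gene)))
    data.frame(species = combos$species[i], label = combos$label[i],
               n_windows = n_w, n_genes = n_g,
               ratio = if (n_g > 0) round(n_w / n_g, 2) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Correlate total DHS signal with gene expression
#'
#' For each gene, sums the representative scores (averaged over replicates
#' of the given species at the given time point) of all windows linked to
#' it, and computes Spearman's correlation against the gene's normalized
#' expression in the same (species, time) cell.
#'
#' @param scores Windows x samples score matrix.
#' @param links Output of [nearest_tss()].
#' @param cm Expression [count_matrix()].
#' @param species,time The (species, time) cell to correlate.
#' @param factors Optional normalization factors for the expression matrix.
#' @return List with `rho`, `p`, `n` (genes used).
#' @export
dhs_expression_correlation <- function(scores, links, cm, species, time,
                                       factors = NULL) {
  map <- cm$design
  cols_expr <- map$sample[map$species == species &
                            as.character(map$time) == time]
  if (!length(cols_expr)) stop("no expression samples for that cell")
  if (is.null(factors)) factors <- tmm_factors(cm)
  cpm <- t(t(cm$counts) / (cm$lib_sizes * factors)) * 1e6
  expr <- rowMeans(cpm[, cols_expr, drop = FALSE])

  score_cols <- intersect(cols_expr, colnames(scores))
  if (!length(score_cols)) score_cols <- colnames(scores)
  wmean <- rowMeans(scores[, score_cols, drop = FALSE])
  ok <- !is.na(links$gene)
  total <- tapply(wmean[links$window][ok], links$gene[ok], sum)

  genes <- intersect(names(total), names(expr))
  if (length(genes) < 3) stop("need at least 3 genes with both measures")
  x <- as.numeric(total[genes])
  y <- as.numeric(expr[genes])
  spearman_cor(x, y)
}

#' Correlate between-species expression change with DHS activity balance
#'
#' Per gene, the activity ratio is (active windows in species A + 1) /
#' (active windows in species B + 1); Spearman correlation against the
#' between-species log2 fold-change.
#'
#' @param log2fc Named numeric vector (per gene), positive = higher in A.
#' @param active_a,active_b Named integer vectors: number of active linked
#'   windows per gene in species A / B.
#' @return List with `rho`, `p`, `n`.
#' @export
fc_activity_correlation <- function(log2fc, active_a, active_b) {
  genes <- intersect(names(log2fc),
                     union(names(active_a), names(active_b)))
  if (length(genes) < 3) stop("need at least 3 genes with both measures")
  a <- ifelse(is.na(active_a[genes]), 0, active_a[genes])
  b <- ifelse(is.na(active_b[genes]), 0, active_b[genes])
  ratio <- (a + 1) / (b + 1)
  spearman_cor(as.numeric(ratio), as.numeric(log2fc[genes]))
}

# Spearman correlation with a constant-vector guard; exact p for small n
# (no ties), t approximation otherwise.
spearman_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant vector")
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = length(x) < 10)
  )
  list(rho = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Scan a sequence for position-weight-matrix matches
#'
#' Scores every placement of the motif on the forward (and optionally
#' reverse-complement) strand and reports those whose relative score
#' (score - min) / (max - min) reaches `min_rel_score`. At the default 1.0
#' only words achieving the maximum possible score match, and positions
#' containing N never match.
#'
#' @param sequence Character scalar over A, C, G, T, N.
#' @param pwm 4 x L numeric matrix with rownames A, C, G, T.
#' @param min_rel_score Minimum relative score in [0, 1].
#' @param both_strands Also scan the reverse complement.
#' @return Data frame `position` (0-based start on the forward strand),
#'   `strand`, `score`, `rel_score`; empty when the sequence is shorter
#'   than the motif.
#' @export
pwm_scan <- function(sequence, pwm, min_rel_score = 1.0, both_strands = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  pwm <- as.matrix(pwm)
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  L <- ncol(pwm)
  empty <- data.frame(position = integer(), strand = character(),
                      score = numeric(), rel_score = numeric())
  n <- nchar(sequence)
  if (n < L || n == 0) return(empty)
  smin <- sum(apply(pwm, 2, min))
  smax <- sum(apply(pwm, 2, max))
  denom <- smax - smin
  thr <- if (denom > 0) smin + min_rel_score * denom else smax

  scan_strand <- function(seq_chars, strand) {
    idx <- match(seq_chars, c("A", "C", "G", "T"))
    np <- length(idx) - L + 1
    sc <- vapply(seq_len(np), function(i) {
      cols <- idx[i:(i + L - 1)]
      if (anyNA(cols)) return(-Inf)
      sum(pwm[cbind(cols, seq_len(L))])
    }, numeric(1))
    hit <- which(sc >= thr - 1e-9)
    if (!length(hit)) return(empty)
    pos0 <- hit - 1L
    if (strand == "-") pos0 <- (length(idx) - (hit - 1L) - L)
    data.frame(position = pos0, strand = strand, score = sc[hit],
               rel_score = if (denom > 0) (sc[hit] - smin) / denom else 1)
  }

  chars <- strsplit(toupper(sequence), "")[[1]]
  out <- scan_strand(chars, "+")
  if (both_strands) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    rc <- rev(unname(comp[chars]))
    rc[is.na(rc)] <- "N"
    out <- rbind(out, scan_strand(rc, "-"))
  }
  out[order(out$position, out$strand), , drop = FALSE]
}
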