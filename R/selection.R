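# Molecular-evolution tests: gene-level dN/dS summaries with a Fisher test
# for positive-selection enrichment in a focal gene set, and a
# promoter-versus-intron human-branch substitution-rate likelihood-ratio
# test using a macaque outgroup and parsimony-assigned substitutions.

#' Collapse isoform-level dN/dS records to one per gene
#'
#' Keeps, per gene, the isoform with the highest dN; ties broken by higher
#' dS, then by lexicographically smaller isoform identifier.
#'
#' @param records Data frame with columns `gene`, `isoform`, `dN`, `dS`.
#' @return One row per gene, same columns.
#' @export
collapse_isoforms <- function(records) {
  stopifnot(all(c("gene", "isoform", "dN", "dS") %in% names(records)))
  if (any(records$dN < 0 | records$dS < 0)) stop("dN and dS must be >= 0")
  ord <- order(records$gene, -records$dN, -records$dS, records$isoform)
  r <- records[ord, , drop = FALSE]
  out <- r[!duplicated(r$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of positively selected genes in a focal set
#'
#' A gene counts as positive when dS > 0 and dN/dS > 1; genes with dS = 0
#' cannot enter the ratio-defined class and are reported separately.
#' Fractions are percentages (2 decimals) of the focal set and of all
#' genes. Enrichment is a two-sided Fisher's exact test; with
#' `construction = "complement"` the 2x2 compares the focal set against
#' the non-focal remainder, with `"all"` against the full gene set.
#'
#' @param records Per-gene records (see [collapse_isoforms()]).
#' @param focal_set Character vector of focal gene identifiers (subset of
#'   `records$gene`).
#' @param construction Which 2x2 table to test.
#' @return List with `frac_focal`, `frac_all` (percent), `fisher_p`,
#'   `k_focal`, `n_focal`, `k_all`, `n_all`, `n_ds_zero_focal`,
#'   `n_ds_zero_all`, `table`.
#' @export
positive_fraction_test <- function(records, focal_set,
                                   construction = c("complement", "all")) {
  construction <- match.arg(construction)
  if (!length(focal_set)) stop("focal set is empty")
  if (anyDuplicated(records$gene)) {
    stop("records must hold one row per gene; run collapse_isoforms() first")
  }
  missing_g <- setdiff(focal_set, records$gene)
  if (length(missing_g)) {
    stop("focal genes without records: ",
         paste(utils::head(missing_g, 5), collapse = ", "))
  }
  pos <- records$dS > 0 & records$dN / records$dS > 1
  focal <- records$gene %in% focal_set
  k_focal <- sum(pos & focal)
  n_focal <- sum(focal)
  k_all <- sum(pos)
  n_all <- nrow(records)
  tab <- if (construction == "complement") {
    matrix(c(k_focal, n_focal - k_focal,
             k_all - k_focal, (n_all - n_focal) - (k_all - k_focal)),
           nrow = 2, byrow = TRUE)
  } else {
    matrix(c(k_focal, n_focal - k_focal,
             k_all, n_all - k_all), nrow = 2, byrow = TRUE)
  }
  p <- stats::fisher.test(tab)$p.value
  list(
    frac_focal = round(100 * k_focal / n_focal, 2),
    frac_all = round(100 * k_all / n_all, 2),
    fisher_p = p,
    k_focal = k_focal, n_focal = n_focal, k_all = k_all, n_all = n_all,
    n_ds_zero_focal = sum(records$dS == 0 & focal),
    n_ds_zero_all = sum(records$dS == 0),
    table = tab
  )
}

#' Percentile of a gene's dN among all genes
#'
#' @param gene Gene identifier.
#' @param records Per-gene records with `gene` and `dN`.
#' @return Percentile in (0, 100]: 100 * (number of genes with dN <= this
#'   gene's dN) / (number of genes).
#' @export
dn_percentile <- function(gene, records) {
  if (nrow(records) < 2) stop("need at least 2 genes")
  i <- match(gene, records$gene)
  if (is.na(i)) stop("gene '", gene, "' has no record")
  100 * sum(records$dN <= records$dN[i]) / nrow(records)
}

#' Count human-branch substitutions by outgroup parsimony
#'
#' Walks an equal-length human/chimpanzee/macaque alignment and counts a
#' column as a human-branch substitution when human differs from
#' chimpanzee while macaque agrees with chimpanzee. Columns containing
#' gaps or N in any taxon are skipped and do not contribute to the aligned
#' length L.
#'
#' @param alignment Named character vector with elements `human`, `chimp`,
#'   `macaque` (equal-length sequences).
#' @param region Region label, e.g. `"promoter"` or `"intron"`.
#' @param gene Optional gene identifier carried into the result.
#' @return One-row data frame: `gene`, `region`, `k` (human-branch
#'   substitutions), `L` (valid columns).
#' @export
lineage_substitution_counts <- function(alignment, region,
                                        gene = NA_character_) {
  need <- c("human", "chimp", "macaque")
  if (!all(need %in% names(alignment))) {
    stop("alignment must have sequences named human, chimp, macaque")
  }
  lens <- nchar(alignment[need])
  if (length(unique(lens)) != 1) {
    stop("alignment length mismatch: ", paste(lens, collapse = ", "))
  }
  h <- strsplit(toupper(alignment[["human"]]), "")[[1]]
  c_ <- strsplit(toupper(alignment[["chimp"]]), "")[[1]]
  m <- strsplit(toupper(alignment[["macaque"]]), "")[[1]]
  bases <- c("A", "C", "G", "T")
  valid <- h %in% bases & c_ %in% bases & m %in% bases
  k <- sum(valid & h != c_ & m == c_)
  data.frame(gene = gene, region = region, k = k, L = sum(valid))
}

#' Promoter-versus-intron substitution-rate likelihood-ratio test
#'
#' Compares the human-branch substitution rate in a gene's promoter with
#' the neutral rate in its introns using binomial likelihoods: under the
#' null both regions share one pooled rate; under the alternative each has
#' its own. The chi-squared (df 1) tail probability is halved and assigned
#' to the upper tail only when the promoter rate exceeds the intron rate
#' (one-sided test for acceleration); otherwise p = 1. A gene is flagged
#' selected when p <= alpha.
#'
#' @param promoter,intron One-row results of
#'   [lineage_substitution_counts()] (or any list with `k` and `L`).
#' @param alpha Significance threshold.
#' @return List with `lrt_stat`, `p`, `selected`, `rate_promoter`,
#'   `rate_intron`.
#' @export
promoter_rate_lrt <- function(promoter, intron, alpha = 0.01) {
  k_p <- promoter$k; L_p <- promoter$L
  k_i <- intron$k; L_i <- intron$L
  if (L_p <= 0 || L_i <= 0) stop("aligned length must be positive")
  if (k_p > L_p || k_i > L_i) stop("substitution count exceeds length")
  ll <- function(k, L, p) stats::dbinom(k, L, p, log = TRUE)
  p0 <- (k_p + k_i) / (L_p + L_i)
  l0 <- ll(k_p, L_p, p0) + ll(k_i, L_i, p0)
  l1 <- ll(k_p, L_p, k_p / L_p) + ll(k_i, L_i, k_i / L_i)
  lrt <- max(0, 2 * (l1 - l0))
  rate_p <- k_p / L_p
  rate_i <- k_i / L_i
  p <- if (rate_p > rate_i) {
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  } else {
    1
  }
  list(lrt_stat = lrt, p = p, selected = p <= alpha,
       rate_promoter = rate_p, rate_intron = rate_i)
}

#' Promoter selection scan over an alignment bundle
#'
#' Convenience wrapper: counts substitutions and runs the promoter LRT for
#' every gene of a [simulate_alignments()]-style bundle.
#'
#' @param alignments List with `promoter` and `intron` per-gene alignment
#'   lists.
#' @param alpha Significance threshold.
#' @return Data frame per gene: counts, rates, `lrt_stat`, `p`, `selected`.
#' @export
promoter_selection_scan <- function(alignments, alpha = 0.01) {
  genes <- names(alignments$promoter)
  rows <- lapply(genes, function(g) {
    bp <- lineage_substitution_counts(alignments$promoter[[g]], "promoter", g)
    bi <- lineage_substitution_counts(alignments$intron[[g]], "intron", g)
    lrt <- promoter_rate_lrt(bp, bi, alpha = alpha)
    data.frame(gene = g, k_promoter = bp$k, L_promoter = bp$L,
               k_intron = bi$k, L_intron = bi$L,
               rate_promoter = lrt$rate_promoter,
               rate_intron = lrt$rate_intron,
               lrt_stat = lrt$lrt_stat, p = lrt$p, selected = lrt$selected)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
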