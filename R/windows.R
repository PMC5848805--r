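# Cross-species harmonization of DNase-hypersensitive-site peak calls:
# partition the pooled peaks into comparable windows, attach per-sample
# representative scores and activity flags, classify windows as shared or
# species-specific, test them for differential accessibility, and overlap
# them with external interval sets.

#' Partition pooled peaks into harmonized windows
#'
#' The union of all peaks (across samples and species) is cut at every
#' distinct peak boundary, yielding disjoint segments over which every
#' sample can be scored (multi-intersect semantics). Segments shorter than
#' `min_len` or longer than `max_len` bp are discarded.
#'
#' @param peaks Data frame of peaks with `chrom`, `start`, `end` (0-based
#'   half-open); typically pooled over all samples.
#' @param min_len,max_len Retained window length bounds in bp.
#' @return Data frame `chrom`, `start`, `end`, `window` (ids in coordinate
#'   order), sorted and non-overlapping.
#' @export
build_windows <- function(peaks, min_len = 50, max_len = 2000) {
  bad <- which(peaks$end <= peaks$start)
  if (length(bad)) {
    stop("malformed interval at row ", bad[1], ": end <= start")
  }
  gr <- intervals_to_granges(peaks)
  seg <- GenomicRanges::disjoin(gr)
  w <- GenomicRanges::width(seg)
  seg <- seg[w >= min_len & w <= max_len]
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(seg)),
    start = GenomicRanges::start(seg) - 1L,
    end = GenomicRanges::end(seg)
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$window <- sprintf("w%06d", seq_len(nrow(out)))
  out
}

#' Score windows per sample and classify species sharing
#'
#' Each window's representative score in a sample is the maximum
#' -10*log10(p) of any overlapping peak from that sample (the lowest peak
#' p-value), or 0 when no peak overlaps. A (species, time) cell is active
#' when at least one replicate has a positive score. Windows active in both
#' species (at any time) are `shared`; active in exactly one species,
#' species-specific; in neither, `inactive`.
#'
#' @param windows Output of [build_windows()] (or any interval frame with a
#'   `window` id column).
#' @param peaks Peak data frame with `chrom`, `start`, `end`, `score` and a
#'   `sample` column.
#' @param replicate_map Design data frame (`sample`, `species`, `time`,
#'   `replicate`) covering every sample present in `peaks`. The first
#'   species in the map is species A.
#' @return List with `windows` (the input plus a `class` column), `scores`
#'   (windows x samples matrix), `activity` (windows x species_time logical
#'   matrix) and `species` (the A/B labels).
#' @export
score_and_classify <- function(windows, peaks, replicate_map) {
  stopifnot(all(c("chrom", "start", "end", "score", "sample") %in% names(peaks)))
  missing_s <- setdiff(unique(peaks$sample), replicate_map$sample)
  if (length(missing_s)) {
    stop("sample(s) absent from replicate map: ",
         paste(missing_s, collapse = ", "))
  }
  wgr <- intervals_to_granges(windows)
  pgr <- intervals_to_granges(peaks)
  hits <- GenomicRanges::findOverlaps(wgr, pgr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  samples <- replicate_map$sample
  scores <- matrix(0, nrow(windows), length(samples),
                   dimnames = list(windows$window, samples))
  if (length(qh)) {
    key <- paste(qh, peaks$sample[sh], sep = "\r")
    mx <- tapply(peaks$score[sh], key, max)
    parts <- strsplit(names(mx), "\r", fixed = TRUE)
    wi <- as.integer(vapply(parts, `[`, character(1), 1))
    si <- match(vapply(parts, `[`, character(1), 2), samples)
    scores[cbind(wi, si)] <- as.numeric(mx)
  }

  st <- paste(replicate_map$species, replicate_map$time, sep = ".")
  st_levels <- unique(st)
  activity <- matrix(FALSE, nrow(windows), length(st_levels),
                     dimnames = list(windows$window, st_levels))
  for (cell in st_levels) {
    cols <- which(st == cell)
    activity[, cell] <- rowSums(scores[, cols, drop = FALSE] > 0) > 0
  }

  species_a <- replicate_map$species[1]
  species_b <- setdiff(unique(replicate_map$species), species_a)[1]
  act_a <- rowSums(scores[, samples[replicate_map$species == species_a],
                          drop = FALSE] > 0) > 0
  act_b <- rowSums(scores[, samples[replicate_map$species == species_b],
                          drop = FALSE] > 0) > 0
  cls <- ifelse(act_a & act_b, "shared",
         ifelse(act_a, "speciesA_specific",
         ifelse(act_b, "speciesB_specific", "inactive")))
  windows$class <- cls
  list(windows = windows, scores = scores, activity = activity,
       species = c(A = species_a, B = species_b))
}

#' Tabulate window sharing classes
#'
#' @param classes Character vector of sharing classes (from
#'   [score_and_classify()]).
#' @return Data frame of per-class counts plus a `total` row; the class
#'   counts always sum to the total window count.
#' @export
classification_summary <- function(classes) {
  lev <- c("shared", "speciesA_specific", "speciesB_specific", "inactive")
  counts <- table(factor(classes, levels = lev))
  data.frame(class = c(lev, "total"),
             n = c(as.integer(counts), length(classes)))
}

#' Differential accessibility of windows
#'
#' Applies the negative binomial GLM likelihood-ratio machinery of
#' [de_test()] to window-level read counts, with the 5% FDR default used
#' for chromatin comparisons.
#'
#' @inheritParams de_test
#' @return As [de_test()].
#' @export
differential_windows <- function(cm, full = ~species, reduced = ~1,
                                 samples = NULL, factors = NULL, fdr = 0.05) {
  de_test(cm, full = full, reduced = reduced, samples = samples,
          factors = factors, fdr = fdr)
}

#' Directional balance of differential windows
#'
#' Tests whether significantly more windows are more accessible in species
#' A than expected, via a two-sided exact binomial test of the species-A
#' count against `Binomial(n_A + n_B, reference_ratio)`.
#'
#' @param n_higher_A,n_higher_B Counts of windows with significantly higher
#'   accessibility in species A / B.
#' @param reference_ratio Null proportion for species A (default 0.5).
#' @return List with `p`, `estimate` (observed proportion A) and the counts.
#' @export
directional_balance_test <- function(n_higher_A, n_higher_B,
                                     reference_ratio = 0.5) {
  if (n_higher_A < 0 || n_higher_B < 0) stop("counts must be non-negative")
  n <- n_higher_A + n_higher_B
  if (n == 0) stop("directional balance undefined: both counts are zero")
  ht <- stats::binom.test(n_higher_A, n, p = reference_ratio)
  list(p = ht$p.value, estimate = n_higher_A / n,
       n_higher_A = n_higher_A, n_higher_B = n_higher_B)
}

#' Overlap of windows with an external interval set
#'
#' A window counts once if it overlaps at least one external interval by at
#' least 1 bp (half-open semantics), mirroring `bedtools intersect -u`.
#'
#' @param windows,external Interval data frames (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return List with `n_overlapping` and `fraction` of windows overlapped.
#' @export
overlap_external <- function(windows, external) {
  if (nrow(windows) == 0) return(list(n_overlapping = 0L, fraction = NaN))
  n_ov <- if (nrow(external) == 0) 0L else {
    sum(GenomicRanges::countOverlaps(intervals_to_granges(windows),
                                     intervals_to_granges(external)) > 0)
  }
  list(n_overlapping = as.integer(n_ov),
       fraction = n_ov / nrow(windows))
}
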