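# Independent brute-force oracles used across test files. These work
# per-base on small coordinate ranges and never share code with the
# package implementations they check.

# Partition the union of peaks at every distinct boundary, per base.
brute_force_partition <- function(peaks, min_len = 50, max_len = 2000) {
  out <- list()
  for (ch in sort(unique(peaks$chrom))) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    hi <- max(p$end)
    covered <- logical(hi)
    boundary <- logical(hi + 1)
    for (i in seq_len(nrow(p))) {
      covered[(p$start[i] + 1):p$end[i]] <- TRUE
      boundary[p$start[i] + 1] <- TRUE
      boundary[p$end[i] + 1] <- TRUE
    }
    # walk the bases, cutting at every boundary
    run_start <- NA
    for (b in seq_len(hi + 1)) {
      base_cov <- b <= hi && covered[b]
      if (!is.na(run_start) && (!base_cov || boundary[b])) {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = run_start - 1,
                                             end = b - 1)
        run_start <- NA
      }
      if (base_cov && is.na(run_start)) run_start <- b
    }
  }
  res <- do.call(rbind, out)
  res <- res[res$end - res$start >= min_len & res$end - res$start <= max_len, ,
             drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Per-base overlap check between two interval sets (half-open).
brute_force_overlap_count <- function(windows, external) {
  hits <- 0
  for (i in seq_len(nrow(windows))) {
    w_bases <- seq(windows$start[i], windows$end[i] - 1)
    ov <- FALSE
    for (j in seq_len(nrow(external))) {
      if (external$chrom[j] != windows$chrom[i]) next
      if (any(w_bases >= external$start[j] & w_bases < external$end[j])) {
        ov <- TRUE
        break
      }
    }
    hits <- hits + ov
  }
  hits
}

# Random peak set on a small coordinate range.
random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 3000,
                         sample_ids = c("a", "b")) {
  start <- sample.int(max_pos - 400, n, replace = TRUE)
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample(30:400, n, replace = TRUE),
    score = round(stats::runif(n, 50, 300), 2),
    sample = sample(sample_ids, n, replace = TRUE)
  )
}

# Small two-species design for unit tests.
tiny_design <- function(n_human = 2, n_chimp = 2,
                        times = c("T0", "T12")) {
  sp <- c(rep("human", n_human), rep("chimp", n_chimp))
  rep_id <- c(seq_len(n_human), seq_len(n_chimp))
  d <- expand.grid(idx = seq_along(sp), time = times,
                   stringsAsFactors = FALSE)
  out <- data.frame(
    species = sp[d$idx],
    time = factor(d$time, levels = c("Pre", "T0", "T12", "T24")),
    replicate = rep_id[d$idx]
  )
  out$sample <- paste(out$species, out$time, out$replicate, sep = "_")
  out[, c("sample", "species", "time", "replicate")]
}
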