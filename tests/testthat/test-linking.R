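test_that("nearest TSS assignment handles the worked example and ties", {
  ann <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                    tss = c(1000, 2000), strand = "+")
  win <- data.frame(chrom = "chr1", start = 900, end = 950, window = "w1")
  r <- nearest_tss(win, ann)
  expect_equal(r$gene, "gA")
  expect_equal(r$distance, 75)       # midpoint 925 -> 1000
  expect_equal(r$signed_distance, -75)

  # equidistant midpoint: lexicographically smaller id wins
  win2 <- data.frame(chrom = "chr1", start = 1400, end = 1600, window = "w2")
  expect_equal(nearest_tss(win2, ann)$gene, "gA")
  ann2 <- data.frame(gene = c("gZ", "gY"), chrom = "chr1",
                     tss = c(1000, 2000), strand = "+")
  expect_equal(nearest_tss(win2, ann2)$gene, "gY")

  # chromosome without genes stays unassigned
  win3 <- data.frame(chrom = "chrX", start = 0, end = 100, window = "w3")
  expect_true(is.na(nearest_tss(win3, ann)$gene))
})

test_that("nearest TSS equals an exhaustive scan on random instances", {
  withr::local_seed(1)
  for (i in 1:10) {
    n_g <- sample(5:40, 1)
    ann <- data.frame(gene = sprintf("g%03d", sample(999, n_g)),
                      chrom = sample(c("chr1", "chr2"), n_g, replace = TRUE),
                      tss = sample.int(5000, n_g), strand = "+")
    n_w <- sample(5:20, 1)
    st <- sample.int(4900, n_w)
    win <- data.frame(chrom = sample(c("chr1", "chr2"), n_w, replace = TRUE),
                      start = st, end = st + sample(50:100, n_w, TRUE),
                      window = paste0("w", seq_len(n_w)))
    got <- nearest_tss(win, ann)
    for (j in seq_len(n_w)) {
      cand <- ann[ann$chrom == win$chrom[j], ]
      if (!nrow(cand)) {
        expect_true(is.na(got$gene[j]))
        next
      }
      mid <- floor((win$start[j] + win$end[j]) / 2)
      d <- abs(mid - cand$tss)
      best <- cand$gene[d == min(d)]
      expect_equal(got$gene[j], min(best))
      expect_equal(got$distance[j], min(d))
    }
  }
})

test_that("cluster-gene summaries reproduce the published ratios", {
  # windows-per-gene ratios as printed for opening/closing chromatin
  mk <- function(n_windows, n_genes, species, label) {
    data.frame(species = species, label = label,
               window = paste(species, label, seq_len(n_windows)),
               gene = paste0(species, label,
                             rep_len(seq_len(n_genes), n_windows)))
  }
  asg <- rbind(mk(19974, 7286, "human", "opening"),
               mk(4462, 3163, "human", "closing"),
               mk(13282, 5910, "chimp", "opening"),
               mk(13350, 6501, "chimp", "closing"))
  s <- cluster_gene_summary(asg)
  get <- function(sp, lb, col) s[s$species == sp & s$label == lb, col]
  expect_equal(get("human", "opening", "ratio"), 2.74)
  expect_equal(get("human", "closing", "ratio"), 1.41)
  expect_equal(get("chimp", "opening", "ratio"), 2.25)
  expect_equal(get("chimp", "closing", "ratio"), 2.05)
  expect_equal(get("human", "opening", "n_windows") /
                 get("human", "closing", "n_windows"), 4.48, tolerance = 0.01)
  # single window, single gene
  s1 <- cluster_gene_summary(data.frame(species = "human", label = "opening",
                                        gene = "g1"))
  expect_equal(s1$ratio[s1$label == "opening"], 1.00)
  expect_true(all(s$n_genes <= s$n_windows))
})

test_that("DHS/expression correlation is 1 under monotone coupling", {
  withr::local_seed(2)
  map <- tiny_design(n_human = 2, n_chimp = 2, times = c("T0", "T12"))
  n_w <- 30
  scores <- matrix(runif(n_w * nrow(map), 1, 100), n_w,
                   dimnames = list(paste0("w", 1:n_w), map$sample))
  links <- data.frame(window = paste0("w", 1:n_w),
                      gene = paste0("g", 1:n_w))
  h12 <- map$sample[map$species == "human" & map$time == "T12"]
  total <- rowMeans(scores[, h12])
  counts <- matrix(50L, n_w, nrow(map),
                   dimnames = list(paste0("g", 1:n_w), map$sample))
  counts[, h12] <- as.integer(round(10 * total))   # monotone transform
  cm <- count_matrix(counts, map)
  ones <- stats::setNames(rep(1, nrow(map)), map$sample)
  r <- dhs_expression_correlation(scores, links, cm, "human", "T12",
                                  factors = ones)
  expect_equal(r$rho, 1, tolerance = 1e-9)
  # constant expression is an error
  counts[, h12] <- 50L
  expect_error(
    dhs_expression_correlation(scores, links, count_matrix(counts, map),
                               "human", "T12", factors = ones),
    "constant")
})

test_that("independent measures give near-zero correlation", {
  withr::local_seed(3)
  hits <- replicate(100, {
    x <- rnorm(200)
    y <- rnorm(200)
    abs(suppressWarnings(cor(x, y, method = "spearman"))) < 0.14
  })
  expect_gte(mean(hits), 0.90)
})

test_that("fold-change/activity-ratio correlation recovers planted coupling", {
  withr::local_seed(4)
  genes <- sprintf("g%03d", 1:300)
  a <- rpois(300, 4)
  b <- rpois(300, 4)
  ratio <- (a + 1) / (b + 1)
  lfc <- scale(log2(ratio))[, 1] * 0.5 + rnorm(300, 0, 0.87)
  r <- fc_activity_correlation(stats::setNames(lfc, genes),
                               stats::setNames(a, genes),
                               stats::setNames(b, genes))
  expect_gt(r$rho, 0.2)
  expect_lt(r$rho, 0.7)
  # perfect monotone association
  r2 <- fc_activity_correlation(stats::setNames(log2(ratio), genes),
                                stats::setNames(a, genes),
                                stats::setNames(b, genes))
  expect_equal(r2$rho, 1, tolerance = 1e-9)
  # identical ratios are degenerate
  expect_error(fc_activity_correlation(stats::setNames(lfc, genes),
                                       stats::setNames(rep(2, 300), genes),
                                       stats::setNames(rep(1, 300), genes)),
               "constant")
})

test_that("PWM scanning finds exact-score hits on both strands", {
  pwm <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm["A", 1] <- 2; pwm["A", 2] <- 2; pwm["C", 3] <- 2  # consensus AAC
  hits <- pwm_scan("TTAACTT", pwm)
  expect_equal(hits$position, 2)
  expect_equal(hits$strand, "+")
  # reverse complement of AAC is GTT
  hits2 <- pwm_scan("CCGTTCC", pwm)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$position, 2)
  expect_equal(substr("CCGTTCC", hits2$position + 1, hits2$position + 3),
               "GTT")
  # one mismatch misses at 100% threshold; N never matches
  expect_equal(nrow(pwm_scan("TTAAGTT", pwm, both_strands = FALSE)), 0)
  expect_equal(nrow(pwm_scan("TTANCTT", pwm, both_strands = FALSE)), 0)
  # motif longer than the sequence is empty, not an error
  expect_equal(nrow(pwm_scan("AC", pwm)), 0)
})

test_that("100% PWM hits equal naive consensus-word search", {
  withr::local_seed(5)
  for (i in 1:10) {
    L <- sample(3:6, 1)
    pwm <- matrix(runif(4 * L), 4, L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    consensus <- paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    seq <- paste0(seq, consensus, "TT")   # guarantee one hit
    hits <- pwm_scan(seq, pwm, both_strands = FALSE)
    # naive scan over every placement (catches overlapping occurrences)
    naive <- which(vapply(seq_len(nchar(seq) - L + 1), function(i) {
      substr(seq, i, i + L - 1) == consensus
    }, logical(1))) - 1L
    expect_setequal(hits$position, naive)
  }
})
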