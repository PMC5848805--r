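make_cm <- function(counts, des = NULL) {
  if (is.null(des)) {
    des <- data.frame(sample = colnames(counts),
                      species = rep(c("human", "chimp"),
                                    each = ncol(counts) / 2),
                      time = "T0",
                      replicate = rep(seq_len(ncol(counts) / 2), 2))
  }
  count_matrix(counts, des)
}

test_that("exclude_genes drops exactly the blacklisted genes, in order", {
  withr::local_seed(1)
  counts <- matrix(rpois(40, 30), 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  cm <- make_cm(counts)
  expect_identical(exclude_genes(cm, character(0))$counts, cm$counts)
  out <- exclude_genes(cm, c("g2", "g5", "g9"))
  expect_equal(rownames(out$counts), paste0("g", c(1, 3, 4, 6, 7, 8, 10)))
  # absent ids warn but leave present genes untouched (set-difference oracle)
  expect_warning(out2 <- exclude_genes(cm, c("g3", "nope")), "not in matrix")
  expect_equal(rownames(out2$counts), setdiff(paste0("g", 1:10), "g3"))
})

test_that("TMM factors are 1 for identical and depth-scaled columns", {
  withr::local_seed(2)
  base <- rpois(200, 100)
  counts <- cbind(s1 = base, s2 = base, s3 = base, s4 = base)
  rownames(counts) <- paste0("g", 1:200)
  f <- tmm_factors(make_cm(counts))
  expect_equal(unname(f), rep(1, 4), tolerance = 1e-12)
  # doubling a column is pure depth: library-size offset absorbs it
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 2L
  f2 <- tmm_factors(make_cm(counts2))
  expect_equal(unname(f2), rep(1, 4), tolerance = 1e-12)
})

test_that("TMM matches a hand-worked double trim on 50 genes", {
  withr::local_seed(3)
  counts <- matrix(rnbinom(100, mu = exp(runif(100, 3, 7)), size = 5), 50,
                   dimnames = list(paste0("g", 1:50), c("s1", "s2")))
  counts[counts == 0] <- 1
  cm <- make_cm(counts, data.frame(sample = c("s1", "s2"), species = "human",
                                   time = "T0", replicate = 1:2))
  f <- tmm_factors(cm)
  # hand computation against the non-reference column
  lib <- colSums(counts)
  uq <- apply(counts, 2, quantile, 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  k <- setdiff(1:2, ref)
  M <- log2((counts[, k] / lib[k]) / (counts[, ref] / lib[ref]))
  A <- 0.5 * log2((counts[, k] / lib[k]) * (counts[, ref] / lib[ref]))
  n <- length(M)
  keepM <- rank(M) >= floor(n * 0.3) + 1 & rank(M) <= n - floor(n * 0.3)
  keepA <- rank(A) >= floor(n * 0.05) + 1 & rank(A) <= n - floor(n * 0.05)
  raw <- c(1, 1)
  raw[k] <- 2^mean(M[keepM & keepA])
  expected <- raw / exp(mean(log(raw)))
  expect_equal(unname(f), unname(expected), tolerance = 1e-12)
})

test_that("TMM factors agree with edgeR's unweighted TMM", {
  skip_if_not_installed("edgeR")
  withr::local_seed(4)
  counts <- matrix(rnbinom(600 * 6, mu = exp(runif(600 * 6, 2, 8)), size = 5),
                   600, dimnames = list(paste0("g", 1:600), paste0("s", 1:6)))
  f <- tmm_factors(make_cm(counts,
                           data.frame(sample = paste0("s", 1:6),
                                      species = "human", time = "T0",
                                      replicate = 1:6)))
  fe <- edgeR::calcNormFactors(counts, method = "TMM", doWeighting = FALSE)
  expect_equal(unname(f), unname(fe), tolerance = 1e-10)
})

test_that("factor geometric mean is imposed at 1", {
  withr::local_seed(5)
  for (i in 1:5) {
    counts <- matrix(rnbinom(400, mu = 50, size = 2), 100,
                     dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
    counts[1, ] <- pmax(counts[1, ], 1)   # guard against all-zero columns
    f <- tmm_factors(make_cm(counts))
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  }
})

test_that("all-zero samples are rejected by name", {
  counts <- matrix(c(5, 3, 0, 0), 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(count_matrix(counts,
                            data.frame(sample = c("s1", "s2"),
                                       species = "human", time = "T0",
                                       replicate = 1:2)),
               "s2")
})

test_that("BH adjustment matches the hand-worked step-up", {
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::local_seed(6)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("symmetric genes get log2fc of zero and sign flips with contrast", {
  withr::local_seed(7)
  counts <- matrix(rnbinom(50 * 8, mu = 80, size = 8), 50,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  counts[1, ] <- rep(c(40L, 60L, 80L, 100L), 2)  # identical in both groups
  des <- data.frame(sample = paste0("s", 1:8),
                    species = rep(c("human", "chimp"), each = 4),
                    time = "T0", replicate = rep(1:4, 2))
  cm <- count_matrix(counts, des, lib_sizes = rep(1e4, 8))
  ones <- stats::setNames(rep(1, 8), paste0("s", 1:8))
  r <- de_test(cm, ~species, ~1, factors = ones)
  expect_lt(abs(r$log2fc[r$gene == "g1"]), 1e-6)

  # reversing which species leads the design flips the contrast sign and
  # leaves p unchanged
  ord <- c(5:8, 1:4)
  r2 <- de_test(count_matrix(counts[, ord], des[ord, ],
                             lib_sizes = rep(1e4, 8)),
                ~species, ~1, factors = ones)
  expect_equal(r$log2fc, -r2$log2fc, tolerance = 1e-6)
  expect_equal(r$p, r2$p, tolerance = 1e-8)
})

test_that("de_test is invariant to gene order", {
  withr::local_seed(8)
  counts <- matrix(rnbinom(60 * 8, mu = 100, size = 10), 60,
                   dimnames = list(paste0("g", 1:60), paste0("s", 1:8)))
  cm <- make_cm(counts)
  r1 <- de_test(cm, ~species, ~1)
  perm <- sample(60)
  r2 <- de_test(make_cm(counts[perm, ]), ~species, ~1)
  r2 <- r2[match(r1$gene, r2$gene), ]
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("planted fold-changes are recovered and all-zero genes reported", {
  cfg <- sim_config(n_genes = 600, seed = 9)
  e <- simulate_expression(cfg)
  cm <- e$counts
  cm$counts["g00001", ] <- 0L
  r <- de_test(cm, ~species, ~1,
               samples = cm$design$sample[cm$design$time == "T0"])
  expect_true("g00001" %in% attr(r, "excluded"))
  up <- e$truth$gene[e$truth$true_log2fc > 0]
  expect_lt(abs(median(r$log2fc[r$gene %in% up]) - 2), 0.2)
  dn <- e$truth$gene[e$truth$true_log2fc < 0]
  expect_lt(abs(median(r$log2fc[r$gene %in% dn]) + 2), 0.2)
})

test_that("DE count summaries reproduce the published table arithmetic", {
  # per-time-point totals and ratios as printed for the serum-challenge data
  s <- de_count_summary(910, 1460)
  expect_equal(s$total, 2370)
  expect_equal(s$ratio_B_A, 1.60)
  s <- de_count_summary(925, 2203)
  expect_equal(s$total, 3128)
  expect_equal(s$ratio_B_A, 2.38)
  s <- de_count_summary(0, 0)
  expect_equal(s$total, 0)
  expect_true(is.na(s$ratio_B_A))
})

test_that("summarize_de_counts tabulates signed significant calls", {
  res <- list(
    T0 = data.frame(gene = paste0("g", 1:6),
                    log2fc = c(2, -1, 3, -2, 0.5, -0.1),
                    q = c(0.01, 0.05, 0.2, 0.01, 0.01, 0.5))
  )
  s <- summarize_de_counts(res, fdr = 0.1)
  expect_equal(s$higher_in_B, 2)   # positive log2fc, q <= 0.1
  expect_equal(s$higher_in_A, 2)
  expect_equal(s$total, 4)
  expect_equal(s$ratio_B_A, 1)
})
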