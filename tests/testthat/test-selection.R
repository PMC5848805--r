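test_that("isoform collapse keeps the max-dN isoform with tie rules", {
  one <- data.frame(gene = "gA", isoform = "iso1", dN = 0.01, dS = 0.02)
  expect_equal(collapse_isoforms(one)$isoform, "iso1")
  two <- data.frame(gene = "gA", isoform = c("iso1", "iso2"),
                    dN = c(0.01, 0.02), dS = c(0.5, 0.1))
  expect_equal(collapse_isoforms(two)$isoform, "iso2")
  # dN tie -> larger dS; full tie -> smaller isoform id
  ties <- data.frame(gene = "gA", isoform = c("isoB", "isoA", "isoC"),
                     dN = c(0.02, 0.02, 0.02), dS = c(0.1, 0.3, 0.3))
  expect_equal(collapse_isoforms(ties)$isoform, "isoA")

  # randomized group-by-max oracle
  withr::local_seed(1)
  rec <- data.frame(gene = sample(sprintf("g%03d", 1:200), 600, replace = TRUE),
                    isoform = paste0("iso", 1:600),
                    dN = round(runif(600), 3), dS = round(runif(600), 3))
  got <- collapse_isoforms(rec)
  want <- do.call(rbind, lapply(split(rec, rec$gene), function(d) {
    d <- d[order(-d$dN, -d$dS, d$isoform), ]
    d[1, ]
  }))
  expect_equal(got$isoform, want$isoform)
  expect_equal(got$dN, want$dN)
})

test_that("positive fractions reproduce the published percentages", {
  # build a gene table realizing the printed counts: 50/973 positive in the
  # focal set, 971/12865 positive overall
  n_all <- 12865; n_focal <- 973; k_focal <- 50; k_all <- 971
  genes <- sprintf("g%05d", seq_len(n_all))
  pos <- c(rep(TRUE, k_focal), rep(FALSE, n_focal - k_focal),
           rep(TRUE, k_all - k_focal),
           rep(FALSE, n_all - n_focal - (k_all - k_focal)))
  rec <- data.frame(gene = genes, isoform = "iso1",
                    dN = ifelse(pos, 0.02, 0.01), dS = 0.01)
  r <- positive_fraction_test(rec, genes[seq_len(n_focal)])
  expect_equal(r$frac_focal, 5.14)
  expect_equal(r$frac_all, 7.55)
  expect_equal(r$table, matrix(c(50, 923, 921, 10971), 2, byrow = TRUE))
  expect_lt(r$fisher_p, 0.05)
  # the alternative 2x2 construction is selectable
  r2 <- positive_fraction_test(rec, genes[seq_len(n_focal)],
                               construction = "all")
  expect_false(isTRUE(all.equal(r$fisher_p, r2$fisher_p)))
})

test_that("dS = 0 genes are excluded from the ratio class but reported", {
  rec <- data.frame(gene = c("g1", "g2", "g3", "g4"), isoform = "i",
                    dN = c(0.02, 0.02, 0.001, 0.001),
                    dS = c(0.01, 0, 0.01, 0.02))
  r <- positive_fraction_test(rec, c("g1", "g2"))
  expect_equal(r$k_focal, 1)          # g2 has dS = 0, not counted positive
  expect_equal(r$n_ds_zero_focal, 1)
  expect_equal(r$frac_focal, 50)
  expect_error(positive_fraction_test(rec, character(0)), "empty")
})

test_that("a focal set equal to all genes gives Fisher p = 1", {
  withr::local_seed(2)
  rec <- data.frame(gene = sprintf("g%03d", 1:50), isoform = "i",
                    dN = runif(50), dS = runif(50))
  r <- positive_fraction_test(rec, rec$gene)
  expect_equal(r$fisher_p, 1)
})

test_that("dN percentiles match their definition", {
  rec <- data.frame(gene = sprintf("g%03d", 1:10), isoform = "i",
                    dN = 1:10 / 100, dS = 0.01)
  expect_equal(dn_percentile("g010", rec), 100)
  rec2 <- data.frame(gene = sprintf("g%03d", 1:100), isoform = "i",
                     dN = (1:100) / 100, dS = 0.01)
  expect_equal(dn_percentile("g090", rec2), 90)
  expect_error(dn_percentile("nope", rec), "no record")
  # brute-force rank oracle
  withr::local_seed(3)
  rec3 <- data.frame(gene = sprintf("g%03d", 1:60), isoform = "i",
                     dN = round(runif(60), 2), dS = 0.01)
  g <- sample(rec3$gene, 1)
  expect_equal(dn_percentile(g, rec3),
               100 * sum(rec3$dN <= rec3$dN[rec3$gene == g]) / 60)
})

test_that("parsimony assigns substitutions to the correct branch", {
  aln <- c(human = "AAAA", chimp = "GAAA", macaque = "GAAA")
  expect_equal(lineage_substitution_counts(aln, "promoter")$k, 1)
  # chimp differs, macaque sides with human: chimp-branch event
  aln2 <- c(human = "AAAA", chimp = "GAAA", macaque = "AAAA")
  expect_equal(lineage_substitution_counts(aln2, "promoter")$k, 0)
  # human/chimp agree: no human-branch event
  aln3 <- c(human = "AAAA", chimp = "AAAA", macaque = "GAAA")
  expect_equal(lineage_substitution_counts(aln3, "promoter")$k, 0)
  # gap and N columns drop out of L
  aln4 <- c(human = "A-AN", chimp = "G-AN", macaque = "G-AA")
  bc <- lineage_substitution_counts(aln4, "promoter")
  expect_equal(bc$L, 2)
  expect_equal(bc$k, 1)
  expect_error(
    lineage_substitution_counts(c(human = "AA", chimp = "A", macaque = "AA"),
                                "promoter"),
    "length mismatch")
})

test_that("promoter LRT matches the closed-form binomial log-likelihoods", {
  # equal rates: no evidence
  r0 <- promoter_rate_lrt(list(k = 10, L = 1000), list(k = 10, L = 1000))
  expect_equal(r0$lrt_stat, 0)
  expect_equal(r0$p, 1)
  expect_false(r0$selected)

  # closed-form oracle at k_p=30/1000 vs k_i=10/1000
  ll <- function(k, L, p) k * log(p) + (L - k) * log(1 - p)
  p_hat <- 40 / 2000
  lrt_direct <- 2 * (ll(30, 1000, 0.03) + ll(10, 1000, 0.01) -
                       ll(30, 1000, p_hat) - ll(10, 1000, p_hat))
  r <- promoter_rate_lrt(list(k = 30, L = 1000), list(k = 10, L = 1000))
  expect_equal(r$lrt_stat, lrt_direct, tolerance = 1e-9)
  expect_equal(r$p, 0.5 * pchisq(lrt_direct, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$selected, r$p <= 0.01)

  # promoter slower than intron is never selected
  r2 <- promoter_rate_lrt(list(k = 5, L = 1000), list(k = 50, L = 1000))
  expect_equal(r2$p, 1)
  expect_false(r2$selected)
  expect_error(promoter_rate_lrt(list(k = 1, L = 0), list(k = 1, L = 10)),
               "positive")
})

test_that("LRT depends only on the encoded substitution counts", {
  # two alignments with identical (k, L) give identical tests
  a1 <- c(human = "GGAA", chimp = "AGAA", macaque = "AGAA")
  a2 <- c(human = "TTTC", chimp = "TTTA", macaque = "TTTA")
  b <- c(human = "CCCC", chimp = "CCCC", macaque = "ACCC")
  r1 <- promoter_rate_lrt(lineage_substitution_counts(a1, "promoter"),
                          lineage_substitution_counts(b, "intron"))
  r2 <- promoter_rate_lrt(lineage_substitution_counts(a2, "promoter"),
                          lineage_substitution_counts(b, "intron"))
  expect_identical(r1, r2)
})

test_that("planted accelerated promoters are flagged with high power", {
  cfg <- sim_config(promoter_rate_multiplier = 5, frac_selected = 0.5,
                    neutral_sub_rate = 0.01, seed = 18)
  a <- simulate_alignments(cfg, n_genes = 120)
  scan <- promoter_selection_scan(a$alignments)
  expect_gte(mean(scan$selected[a$truth$selected]), 0.9)
})
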