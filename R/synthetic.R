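# Synthetic-data generator. Every downstream stage of the package can be
# exercised on data produced here, with truth tables recording the planted
# structure (differentially expressed genes, serum-responsive gene sets,
# shared/species-specific accessibility windows, opening/closing
# trajectories, promoters under accelerated human-branch substitution).

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' study design the package targets: four time points (Pre-challenge, then
#' 0 h, 12 h and 24 h after serum replacement) in fibroblasts from four
#' human and three chimpanzee donors.
#'
#' @param n_genes Number of ortholog gene pairs to simulate.
#' @param n_windows Number of accessibility windows to plant.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param design Data frame with columns `sample`, `species`, `time`,
#'   `replicate`; defaults to [default_design()].
#' @param nb_dispersion Global negative binomial dispersion phi in the
#'   parameterization variance = mu + phi * mu^2.
#' @param baseline_mean Median per-gene expected count at library scale 1.
#' @param frac_de Fraction of genes given a between-species expression shift.
#' @param planted_log2fc Magnitude (log2) of planted expression and
#'   accessibility effects.
#' @param frac_shared,frac_speciesA_only,frac_speciesB_only Sharing-class
#'   mixture for windows; must sum to 1. Species A is the first species of
#'   the design (human by default).
#' @param frac_opening,frac_closing Fractions of windows given monotone
#'   rising / falling accessibility trajectories after serum replacement.
#' @param promoter_len,intron_len Alignment lengths (bp) for the selection
#'   simulator.
#' @param neutral_sub_rate Neutral substitutions/site on the human and
#'   chimpanzee branches (macaque outgroup branch uses 4x this rate).
#' @param promoter_rate_multiplier Human-branch promoter rate multiplier for
#'   genes planted as positively selected.
#' @param frac_selected Fraction of genes planted with accelerated promoters.
#' @param jitter_bp Uniform jitter (+/- bp) applied to peak boundaries per
#'   sample, so that window harmonization is exercised.
#' @param frac_csr_up,frac_csr_down Fractions of genes planted as
#'   serum-response up-/downregulated (the synthetic analogue of the core
#'   serum response sets).
#' @param gene_mean_sdlog Log-normal sd of per-gene baseline means.
#' @param lib_sdlog Log-normal sd of library size factors.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_windows = 800,
                       chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                       design = default_design(),
                       nb_dispersion = 0.1,
                       baseline_mean = 100,
                       frac_de = 0.1,
                       planted_log2fc = 2,
                       frac_shared = 0.475,
                       frac_speciesA_only = 0.363,
                       frac_speciesB_only = 0.162,
                       frac_opening = 0.3,
                       frac_closing = 0.1,
                       promoter_len = 5000,
                       intron_len = 5000,
                       neutral_sub_rate = 0.01,
                       promoter_rate_multiplier = 5,
                       frac_selected = 0.1,
                       jitter_bp = 20,
                       frac_csr_up = 0.1,
                       frac_csr_down = 0.1,
                       gene_mean_sdlog = 1,
                       lib_sdlog = 0.2,
                       seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_windows = as.integer(n_windows),
    chrom_sizes = chrom_sizes, design = design,
    nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
    frac_de = frac_de, planted_log2fc = planted_log2fc,
    frac_shared = frac_shared, frac_speciesA_only = frac_speciesA_only,
    frac_speciesB_only = frac_speciesB_only,
    frac_opening = frac_opening, frac_closing = frac_closing,
    promoter_len = as.integer(promoter_len), intron_len = as.integer(intron_len),
    neutral_sub_rate = neutral_sub_rate,
    promoter_rate_multiplier = promoter_rate_multiplier,
    frac_selected = frac_selected,
    jitter_bp = as.integer(jitter_bp),
    frac_csr_up = frac_csr_up, frac_csr_down = frac_csr_down,
    gene_mean_sdlog = gene_mean_sdlog, lib_sdlog = lib_sdlog,
    seed = as.integer(seed)
  )
  fracs <- c(cfg$frac_de, cfg$frac_opening, cfg$frac_closing,
             cfg$frac_csr_up, cfg$frac_csr_down, cfg$frac_selected,
             cfg$frac_shared, cfg$frac_speciesA_only, cfg$frac_speciesB_only)
  if (any(fracs < 0 | fracs > 1)) stop("invalid config: fractions must lie in [0, 1]")
  share_sum <- cfg$frac_shared + cfg$frac_speciesA_only + cfg$frac_speciesB_only
  if (abs(share_sum - 1) > 1e-12) {
    stop("invalid config: sharing fractions must sum to 1 (got ", share_sum, ")")
  }
  if (cfg$frac_opening + cfg$frac_closing > 1) {
    stop("invalid config: frac_opening + frac_closing must not exceed 1")
  }
  if (cfg$nb_dispersion <= 0 || cfg$baseline_mean <= 0) {
    stop("invalid config: nb_dispersion and baseline_mean must be positive")
  }
  if (any(c(cfg$n_genes, cfg$n_windows, cfg$chrom_sizes,
            cfg$promoter_len, cfg$intron_len) <= 0)) {
    stop("invalid config: counts and lengths must be positive")
  }
  if (cfg$neutral_sub_rate < 0 || cfg$neutral_sub_rate > 0.25) {
    stop("invalid config: neutral_sub_rate must lie in [0, 0.25]")
  }
  stopifnot(all(c("sample", "species", "time", "replicate") %in% names(design)))
  class(cfg) <- "sim_config"
  cfg
}

#' Default two-species serum-challenge design
#'
#' Four human and three chimpanzee biological replicates, each sampled at
#' Pre, T0, T12 and T24.
#'
#' @param n_human,n_chimp Replicates per species.
#' @return Design data frame (`sample`, `species`, `time`, `replicate`).
#' @export
default_design <- function(n_human = 4, n_chimp = 3) {
  sp <- c(rep("human", n_human), rep("chimp", n_chimp))
  rep_id <- c(seq_len(n_human), seq_len(n_chimp))
  d <- expand.grid(idx = seq_along(sp), time = time_levels(),
                   stringsAsFactors = FALSE)
  out <- data.frame(
    species = sp[d$idx],
    time = factor(d$time, levels = time_levels()),
    replicate = rep_id[d$idx]
  )
  out$sample <- paste(out$species, out$time, paste0("r", out$replicate), sep = "_")
  out[, c("sample", "species", "time", "replicate")]
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_windows, "windows,",
      nrow(x$design), "samples, seed", x$seed, "\n")
  invisible(x)
}

#' Simulate an ortholog expression count matrix with planted effects
#'
#' Counts are negative binomial with per-gene log-normal baseline means and
#' per-sample log-normal library scale. A fraction `frac_de` of genes gets a
#' between-species shift of `planted_log2fc` log2 units (random sign), and
#' disjoint "serum-response" gene sets rise or fall after serum replacement
#' (no effect at Pre/T0, 75% of the full effect at T12, full at T24).
#'
#' @param config A [sim_config()].
#' @return List with `counts` (a [count_matrix()]), `truth` (per-gene data
#'   frame: `de`, `true_log2fc`, `csr`), `gene_sets` (list `CSR_UP`,
#'   `CSR_DOWN`) and `expected_mean` (the exact expectation of every count).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  des <- config$design
  genes <- sprintf("g%05d", seq_len(n))

  base_mean <- config$baseline_mean *
    exp(stats::rnorm(n, 0, config$gene_mean_sdlog))
  phi <- config$nb_dispersion * exp(stats::rnorm(n, 0, 0.2))
  size_fac <- exp(stats::rnorm(nrow(des), 0, config$lib_sdlog))

  n_de <- round(config$frac_de * n)
  de_genes <- sample(n, n_de)
  de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
  true_lfc <- numeric(n)
  true_lfc[de_genes] <- de_sign * config$planted_log2fc

  n_up <- round(config$frac_csr_up * n)
  n_dn <- round(config$frac_csr_down * n)
  csr_pool <- sample(n, n_up + n_dn)
  csr_up <- csr_pool[seq_len(n_up)]
  csr_dn <- csr_pool[n_up + seq_len(n_dn)]
  csr <- rep("none", n)
  csr[csr_up] <- "up"
  csr[csr_dn] <- "down"

  # time effect in log2 units, shared by both species
  time_scale <- c(Pre = 0, T0 = 0, T12 = 0.75, T24 = 1)[as.character(des$time)]
  time_eff <- outer(ifelse(csr == "up", 1, ifelse(csr == "down", -1, 0)) *
                      config$planted_log2fc, time_scale)
  # species effect applies on the second species (B)
  species_b <- des$species != des$species[1]
  sp_eff <- outer(true_lfc, as.numeric(species_b))

  mu <- (base_mean * 2^(sp_eff + time_eff)) %*% diag(size_fac)
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = rep(1 / phi, nrow(des))),
    nrow = n, dimnames = list(genes, des$sample)
  )
  storage.mode(counts) <- "integer"
  dimnames(mu) <- dimnames(counts)

  truth <- data.frame(
    gene = genes,
    de = seq_len(n) %in% de_genes,
    true_log2fc = true_lfc,
    csr = csr,
    base_mean = base_mean,
    dispersion = phi
  )
  list(
    counts = count_matrix(counts, des),
    truth = truth,
    gene_sets = list(CSR_UP = genes[csr_up], CSR_DOWN = genes[csr_dn]),
    expected_mean = mu
  )
}

#' Simulate per-sample DNase peak calls over planted windows
#'
#' Plants non-overlapping windows on the configured chromosomes, assigns
#' each a sharing class (shared / species-A-only / species-B-only) and a
#' trajectory (opening / closing / flat), then emits one peak per active
#' sample with boundaries jittered by +/- `jitter_bp` and a score of at
#' least 50 (the -10*log10 p scale of a 1e-5 peak-calling threshold).
#' Opening windows have monotone rising scores from T0 to T24, closing
#' windows the reverse. Window-level read counts correlated with the scores
#' and a synthetic TSS annotation are returned alongside.
#'
#' @param config A [sim_config()].
#' @return List with `peaks` (per-sample BED-like data frame), `counts`
#'   (window-level [count_matrix()]), `truth` (per-window class and
#'   trajectory), `windows` (planted intervals) and `annotation`
#'   (synthetic gene TSS table for linking).
#' @export
simulate_dhs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_windows
  des <- config$design
  species_a <- des$species[1]
  species_b <- setdiff(unique(des$species), species_a)[1]

  # --- placement: round-robin over chromosomes, sequential with gaps
  chrom_names <- names(config$chrom_sizes)
  chrom_of <- rep(chrom_names, length.out = n)
  len <- round(stats::runif(n, 150, 800))
  gap <- round(stats::runif(n, 60, 200))
  start <- integer(n)
  for (ch in chrom_names) {
    idx <- which(chrom_of == ch)
    pos <- cumsum(gap[idx] + len[idx]) - len[idx]
    if (length(idx) && (pos[length(idx)] + len[idx[length(idx)]] >
                        config$chrom_sizes[[ch]])) {
      stop("placement error: chromosome ", ch,
           " too small for requested windows")
    }
    start[idx] <- pos
  }
  end <- start + len
  window_id <- sprintf("w%05d", seq_len(n))

  class_lab <- sample(
    c("shared", "speciesA_specific", "speciesB_specific"), n, replace = TRUE,
    prob = c(config$frac_shared, config$frac_speciesA_only,
             config$frac_speciesB_only)
  )
  traj <- sample(
    c("opening", "closing", "flat"), n, replace = TRUE,
    prob = c(config$frac_opening, config$frac_closing,
             1 - config$frac_opening - config$frac_closing)
  )

  base <- stats::runif(n, 30, 250)
  traj_mult <- rbind(
    opening = c(Pre = 0.1, T0 = 0.1, T12 = 0.5, T24 = 1),
    closing = c(Pre = 1, T0 = 1, T12 = 0.5, T24 = 0.1),
    flat    = c(Pre = 1, T0 = 1, T12 = 1, T24 = 1)
  )

  active_in <- function(cls, sp) {
    (cls == "shared") |
      (cls == "speciesA_specific" & sp == species_a) |
      (cls == "speciesB_specific" & sp == species_b)
  }

  peak_list <- vector("list", nrow(des))
  score_mat <- matrix(0, n, nrow(des), dimnames = list(window_id, des$sample))
  for (s in seq_len(nrow(des))) {
    act <- active_in(class_lab, des$species[s])
    idx <- which(act)
    if (!length(idx)) next
    mult <- traj_mult[traj[idx], as.character(des$time[s])]
    score <- 50 + base[idx] * mult * exp(stats::rnorm(length(idx), 0, 0.15))
    j <- config$jitter_bp
    js <- if (j > 0) sample(seq(-j, j), length(idx), replace = TRUE) else 0L
    je <- if (j > 0) sample(seq(-j, j), length(idx), replace = TRUE) else 0L
    peak_list[[s]] <- data.frame(
      chrom = chrom_of[idx],
      start = pmax(0L, start[idx] + js),
      end = end[idx] + je,
      name = paste0(des$sample[s], "_p", seq_along(idx)),
      score = round(score, 4),
      strand = ".",
      sample = des$sample[s]
    )
    score_mat[idx, s] <- score
  }
  peaks <- do.call(rbind, peak_list)
  rownames(peaks) <- NULL

  # window-level read counts: NB, mean tied to the per-sample score
  depth <- exp(stats::rnorm(nrow(des), 0, config$lib_sdlog))
  mu <- (5 + 0.5 * score_mat) %*% diag(depth)
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
    nrow = n, dimnames = list(window_id, des$sample)
  )
  storage.mode(counts) <- "integer"

  # synthetic annotation: TSSs spread over the same chromosomes so windows
  # can be linked to genes
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  ann_chrom <- rep(chrom_names, length.out = config$n_genes)
  ann <- data.frame(
    gene = genes,
    chrom = ann_chrom,
    tss = unlist(lapply(chrom_names, function(ch) {
      k <- sum(ann_chrom == ch)
      sort(sample(config$chrom_sizes[[ch]] - 1L, k))
    })),
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
  )

  truth <- data.frame(
    window = window_id, chrom = chrom_of, start = start, end = end,
    class = class_lab, trajectory = traj
  )
  list(
    peaks = peaks,
    counts = count_matrix(counts, des),
    truth = truth,
    windows = truth[, c("chrom", "start", "end", "window")],
    annotation = ann
  )
}

#' Simulate three-taxon promoter and intron alignments
#'
#' For each gene an ancestral promoter and intron sequence is evolved along
#' the fixed topology ((human, chimpanzee), macaque): the human and
#' chimpanzee branches receive `neutral_sub_rate` substitutions/site, the
#' macaque outgroup branch four times that. Genes planted as selected get
#' their human-branch *promoter* rate multiplied by
#' `promoter_rate_multiplier`; intron rates stay neutral.
#'
#' @param config A [sim_config()].
#' @param n_genes Number of genes to simulate (defaults to
#'   `min(config$n_genes, 500)` to keep alignment bundles small).
#' @return List with `alignments` (per region, per gene, named character
#'   vectors human/chimp/macaque) and `truth` (per-gene `selected` flag).
#' @export
simulate_alignments <- function(config, n_genes = min(config$n_genes, 500L)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$frac_selected > 0 && config$promoter_rate_multiplier < 1) {
    stop("invalid config: promoter_rate_multiplier must be >= 1 when ",
         "selected genes are planted")
  }
  set.seed(config$seed + 2L)
  genes <- sprintf("g%05d", seq_len(n_genes))
  n_sel <- round(config$frac_selected * n_genes)
  selected <- logical(n_genes)
  selected[sample(n_genes, n_sel)] <- TRUE

  bases <- c("A", "C", "G", "T")
  mutate <- function(seq_chars, rate) {
    if (rate <= 0) return(seq_chars)
    hit <- which(stats::runif(length(seq_chars)) < rate)
    if (length(hit)) {
      shift <- sample(3L, length(hit), replace = TRUE)
      cur <- match(seq_chars[hit], bases)
      seq_chars[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
    seq_chars
  }
  evolve <- function(len, human_rate, other_rate) {
    root <- sample(bases, len, replace = TRUE)
    anc_hc <- mutate(root, other_rate)           # root -> human/chimp ancestor
    list(
      human = paste(mutate(anc_hc, human_rate), collapse = ""),
      chimp = paste(mutate(anc_hc, other_rate), collapse = ""),
      macaque = paste(mutate(root, 4 * other_rate), collapse = "")
    )
  }

  r <- config$neutral_sub_rate
  promoter <- vector("list", n_genes)
  intron <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    h_rate <- if (selected[i]) r * config$promoter_rate_multiplier else r
    promoter[[i]] <- unlist(evolve(config$promoter_len, h_rate, r))
    intron[[i]] <- unlist(evolve(config$intron_len, r, r))
  }
  names(promoter) <- names(intron) <- genes
  list(
    alignments = list(promoter = promoter, intron = intron),
    truth = data.frame(gene = genes, selected = selected)
  )
}

#' Simulate a per-isoform dN/dS table
#'
#' Gamma-distributed synonymous and nonsynonymous rates with 1-3 isoforms
#' per gene; a small fraction of genes is given dN above dS (dN/dS > 1) and
#' a further small fraction dS = 0, mirroring the pathologies a real
#' Ensembl-derived table contains.
#'
#' @param config A [sim_config()].
#' @param n_genes Number of genes (defaults to `config$n_genes`).
#' @param frac_positive Fraction of genes with dN/dS > 1.
#' @param frac_ds_zero Fraction of genes with dS reported as 0.
#' @return Data frame with columns `gene`, `isoform`, `dN`, `dS`.
#' @export
simulate_dnds <- function(config, n_genes = config$n_genes,
                          frac_positive = 0.075, frac_ds_zero = 0.01) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  genes <- sprintf("g%05d", seq_len(n_genes))
  n_iso <- sample(1:3, n_genes, replace = TRUE)
  gene_col <- rep(genes, n_iso)
  iso <- unlist(lapply(n_iso, function(k) paste0("iso", seq_len(k))))
  m <- length(gene_col)
  dS <- stats::rgamma(m, shape = 2, scale = 0.005)
  dN <- dS * stats::rgamma(m, shape = 2, scale = 0.15)
  pos <- genes %in% sample(genes, round(frac_positive * n_genes))
  pos_rows <- pos[match(gene_col, genes)]
  dN[pos_rows] <- dS[pos_rows] * stats::runif(sum(pos_rows), 1.1, 3)
  zero <- genes %in% sample(genes[!pos], round(frac_ds_zero * n_genes))
  dS[zero[match(gene_col, genes)]] <- 0
  data.frame(gene = gene_col, isoform = iso, dN = dN, dS = dS)
}

#' Write a fixture bundle to disk
#'
#' Serializes generator outputs as plain-text files (TSV counts/design/
#' truth, BED peaks, GMT gene sets, FASTA alignments) plus a JSON manifest
#' with an md5 checksum per file. Everything round-trips through the
#' package readers.
#'
#' @param dir Output directory (created if missing).
#' @param expression Output of [simulate_expression()], or NULL.
#' @param dhs Output of [simulate_dhs()], or NULL.
#' @param alignments Output of [simulate_alignments()], or NULL.
#' @param dnds Output of [simulate_dnds()], or NULL.
#' @return Data frame manifest (file, md5, bytes), invisibly written to
#'   `manifest.json` in `dir`.
#' @export
write_fixture_bundle <- function(dir, expression = NULL, dhs = NULL,
                                 alignments = NULL, dnds = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory '", dir, "'")
  }
  files <- character(0)
  put <- function(fname) file.path(dir, fname)
  if (!is.null(expression)) {
    write_counts(expression$counts$counts, put("counts.tsv"))
    write_design(expression$counts$design, put("design.tsv"))
    utils::write.table(expression$truth, put("truth_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(expression$gene_sets, put("gene_sets.gmt"))
    files <- c(files, "counts.tsv", "design.tsv", "truth_genes.tsv",
               "gene_sets.gmt")
  }
  if (!is.null(dhs)) {
    write_bed(dhs$peaks, put("peaks.bed"))
    write_counts(dhs$counts$counts, put("window_counts.tsv"))
    utils::write.table(dhs$truth, put("truth_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dhs$annotation, put("annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, "peaks.bed", "window_counts.tsv", "truth_windows.tsv",
               "annotation.tsv")
  }
  if (!is.null(alignments)) {
    for (region in names(alignments$alignments)) {
      aln <- alignments$alignments[[region]]
      seqs <- unlist(aln)
      names(seqs) <- unlist(lapply(names(aln), function(g) {
        paste(g, names(aln[[g]]), sep = "|")
      }))
      write_fasta(seqs, put(paste0(region, ".fa")))
      files <- c(files, paste0(region, ".fa"))
    }
    utils::write.table(alignments$truth, put("truth_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, "truth_selection.tsv")
  }
  if (!is.null(dnds)) {
    utils::write.table(dnds, put("dnds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, "dnds.tsv")
  }
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    bytes = unname(file.size(file.path(dir, files)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
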