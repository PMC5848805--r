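# End-to-end orchestration: simulate (or load) inputs, then run the
# expression, enrichment, window, clustering, linking and selection stages
# in order, collecting every summary table into one report.

#' Pipeline configuration
#'
#' Thresholds default to the conventions used throughout the package:
#' 10% FDR for expression, 5% FDR for accessibility windows, minimum
#' cluster membership 0.6, window lengths within [50, 2000] bp, and a 1%
#' promoter-selection alpha.
#'
#' @param stages Named logical vector toggling `simulate`, `expression`,
#'   `enrichment`, `windows`, `clustering`, `linking`, `selection`.
#' @param sim A [sim_config()] used when the simulate stage is enabled.
#' @param input_dir Directory holding a fixture bundle (see
#'   [write_fixture_bundle()]) when `simulate` is disabled.
#' @param fdr_expression,fdr_windows,membership_min,window_min,window_max,alpha_selection
#'   Stage thresholds.
#' @param gsea_perms Permutations for the enrichment stage.
#' @param cluster_range Candidate cluster numbers.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c(simulate = TRUE, expression = TRUE,
                                       enrichment = TRUE, windows = TRUE,
                                       clustering = TRUE, linking = TRUE,
                                       selection = TRUE),
                            sim = sim_config(seed = seed),
                            input_dir = NULL,
                            fdr_expression = 0.10,
                            fdr_windows = 0.05,
                            membership_min = 0.6,
                            window_min = 50,
                            window_max = 2000,
                            alpha_selection = 0.01,
                            gsea_perms = 200,
                            cluster_range = 2:6,
                            seed = 1) {
  stopifnot(fdr_expression > 0, fdr_expression < 1,
            fdr_windows > 0, fdr_windows < 1,
            membership_min >= 0, membership_min <= 1,
            window_min > 0, window_max > window_min,
            alpha_selection > 0, alpha_selection < 1,
            gsea_perms >= 100)
  cfg <- list(stages = stages, sim = sim, input_dir = input_dir,
              fdr_expression = fdr_expression, fdr_windows = fdr_windows,
              membership_min = membership_min, window_min = window_min,
              window_max = window_max, alpha_selection = alpha_selection,
              gsea_perms = gsea_perms, cluster_range = cluster_range,
              seed = as.integer(seed))
  if (!isTRUE(stages[["simulate"]]) && is.null(input_dir)) {
    needs_input <- any(unlist(stages[setdiff(names(stages), "simulate")]))
    if (needs_input) {
      stop("configuration error: simulate disabled and no input_dir given")
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; keys under
#' `sim:` are passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configuration requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  seed <- if (!is.null(raw$seed)) raw$seed else 1
  sim_args <- if (!is.null(raw$sim)) raw$sim else list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  raw$sim <- do.call(sim_config, sim_args)
  if (!is.null(raw$stages)) raw$stages <- unlist(raw$stages)
  if (!is.null(raw$cluster_range) && length(raw$cluster_range) == 2) {
    raw$cluster_range <- seq(raw$cluster_range[1], raw$cluster_range[2])
  }
  do.call(pipeline_config, raw)
}

#' Run the full comparative serum-challenge pipeline
#'
#' Executes the enabled stages in order on simulated (or loaded) data and
#' returns a nested report: per-time-point between-species DE summaries,
#' gene set enrichment of the serum-response ranking, window sharing
#' classification and directional balance, trajectory clustering with
#' per-class gene linking, accessibility/expression correlations, and
#' dN/dS plus promoter-selection results. Fully deterministic given the
#' configured seed.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, the report is written as
#'   `report.json` plus TSV tables.
#' @return The report, a nested list; `report$config` echoes thresholds.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  on <- function(stage) isTRUE(cfg$stages[[stage]])
  report <- list(config = cfg[setdiff(names(cfg), c("stages", "sim"))])
  report$config$stages <- as.list(cfg$stages)

  expr <- dhs <- aln <- dnds <- NULL
  if (on("simulate")) {
    expr <- simulate_expression(cfg$sim)
    dhs <- simulate_dhs(cfg$sim)
    aln <- simulate_alignments(cfg$sim)
    dnds <- simulate_dnds(cfg$sim)
  } else if (!is.null(cfg$input_dir)) {
    expr <- load_expression_bundle(cfg$input_dir)
    dhs <- load_dhs_bundle(cfg$input_dir)
  }

  species <- unique(expr$counts$design$species)
  sp_a <- species[1]
  sp_b <- species[2]

  de_results <- NULL
  if (on("expression")) {
    cm <- expr$counts
    factors <- tmm_factors(cm)
    tps <- levels(droplevels(cm$design$time))
    de_results <- lapply(stats::setNames(tps, tps), function(tp) {
      de_test(cm, full = ~species, reduced = ~1,
              samples = cm$design$sample[as.character(cm$design$time) == tp],
              fdr = cfg$fdr_expression)
    })
    report$expression <- list(
      table1 = summarize_de_counts(de_results, fdr = cfg$fdr_expression),
      n_genes_tested = nrow(de_results[[1]]),
      n_excluded_all_zero = length(attr(de_results[[1]], "excluded"))
    )
  }

  if (on("enrichment")) {
    # serum-response ranking within species A: T0 vs T12
    cm <- expr$counts
    sel <- cm$design$species == sp_a &
      as.character(cm$design$time) %in% c("T0", "T12")
    rt <- de_test(cm, full = ~time, reduced = ~1,
                  samples = cm$design$sample[sel], fdr = cfg$fdr_expression)
    rl <- ranked_list(rt$gene, sign(rt$log2fc) * -log10(pmax(rt$p, 1e-300)))
    sets <- expr$gene_sets
    gsea <- gsea_collection(rl, sets, n_perm = cfg$gsea_perms,
                            seed = cfg$seed + 10L)
    report$enrichment <- list(gsea = gsea)
    if (!is.null(de_results)) {
      up_b <- lapply(de_results, function(r) {
        r$gene[r$significant & r$log2fc > 0]
      })
      background <- de_results[[1]]$gene
      hyp <- hypergeom_enrichment(up_b[["T12"]], background, sets)
      report$enrichment$hypergeom_T12 <- hyp
    }
  }

  sc <- NULL
  links <- NULL
  if (on("windows")) {
    win <- build_windows(dhs$peaks, cfg$window_min, cfg$window_max)
    sc <- score_and_classify(win, dhs$peaks, expr$counts$design)
    report$windows <- list(
      n_windows = nrow(win),
      classification = classification_summary(sc$windows$class)
    )
    dw <- differential_windows(dhs$counts, full = ~species, reduced = ~1,
                               samples = dhs$counts$design$sample[
                                 as.character(dhs$counts$design$time) == "T0"],
                               fdr = cfg$fdr_windows)
    n_a <- sum(dw$significant & dw$log2fc < 0)
    n_b <- sum(dw$significant & dw$log2fc > 0)
    report$windows$differential_T0 <- list(
      higher_in_A = n_a, higher_in_B = n_b,
      balance_p = if (n_a + n_b > 0) {
        directional_balance_test(n_a, n_b)$p
      } else {
        NA_real_
      }
    )
  }

  clusterings <- NULL
  if (on("clustering")) {
    if (is.null(sc)) stop("clustering stage requires the windows stage")
    clusterings <- lapply(stats::setNames(species, species), function(sp) {
      pm <- standardize_profiles(sc$scores, expr$counts$design, sp)
      m <- estimate_fuzzifier(pm)
      pick <- choose_cluster_number(pm, cfg$cluster_range, m,
                                    seed = cfg$seed + 20L)
      fc <- fuzzy_cmeans(pm, pick$c, m, seed = cfg$seed + 20L)
      labs <- trajectory_classes(fc, membership_min = cfg$membership_min)
      list(m = m, c = pick$c, dmin = pick$dmin, clustering = fc,
           labels = labs)
    })
    report$clustering <- lapply(clusterings, function(x) {
      list(fuzzifier = x$m, c = x$c,
           label_counts = as.list(table(x$labels$window_labels)))
    })
  }

  if (on("linking")) {
    if (is.null(sc)) stop("linking stage requires the windows stage")
    links <- nearest_tss(sc$windows, dhs$annotation)
    if (!is.null(clusterings)) {
      assignments <- do.call(rbind, lapply(species, function(sp) {
        wl <- clusterings[[sp]]$labels$window_labels
        data.frame(species = sp, window = names(wl), label = unname(wl),
                   gene = links$gene[match(names(wl), links$window)])
      }))
      report$linking <- list(
        table2 = cluster_gene_summary(assignments)
      )
    }
    corr <- dhs_expression_correlation(sc$scores, links, expr$counts,
                                       species = sp_a, time = "T12")
    report$linking$dhs_expression_T12 <- corr
    if (!is.null(de_results)) {
      act_cols <- function(sp) {
        expr$counts$design$sample[expr$counts$design$species == sp]
      }
      count_active <- function(sp) {
        act <- rowSums(sc$scores[, act_cols(sp), drop = FALSE] > 0) > 0
        ok <- !is.na(links$gene)
        tapply(act[links$window][ok], links$gene[ok], sum)
      }
      lfc <- stats::setNames(-de_results[["T12"]]$log2fc,
                             de_results[["T12"]]$gene)  # positive = higher in A
      report$linking$fc_activity_T12 <- fc_activity_correlation(
        lfc, count_active(sp_a), count_active(sp_b))
    }
  }

  if (on("selection")) {
    per_gene <- collapse_isoforms(dnds)
    focal <- per_gene$gene[seq_len(max(20, round(nrow(per_gene) * 0.075)))]
    pft <- positive_fraction_test(per_gene, focal)
    scan <- promoter_selection_scan(aln$alignments,
                                    alpha = cfg$alpha_selection)
    report$selection <- list(
      frac_focal = pft$frac_focal, frac_all = pft$frac_all,
      fisher_p = pft$fisher_p,
      promoter_selected_fraction = mean(scan$selected),
      n_promoters = nrow(scan)
    )
  }

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Internal: bundle loaders for running the pipeline on files.
load_expression_bundle <- function(dir) {
  counts <- read_counts(file.path(dir, "counts.tsv"))
  design <- read_design(file.path(dir, "design.tsv"))
  list(counts = count_matrix(counts, design),
       gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
       truth = utils::read.delim(file.path(dir, "truth_genes.tsv")))
}

load_dhs_bundle <- function(dir) {
  peaks <- read_bed(file.path(dir, "peaks.bed"))
  peaks$sample <- sub("_p[0-9]+$", "", peaks$name)
  counts <- read_counts(file.path(dir, "window_counts.tsv"))
  design <- read_design(file.path(dir, "design.tsv"))
  list(peaks = peaks,
       counts = count_matrix(counts, design),
       truth = utils::read.delim(file.path(dir, "truth_windows.tsv")),
       annotation = utils::read.delim(file.path(dir, "annotation.tsv")))
}

# Internal: serialize a report as JSON plus TSV side tables.
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  if (!is.null(report$expression$table1)) {
    utils::write.table(report$expression$table1,
                       file.path(out_dir, "table1_de_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$linking$table2)) {
    utils::write.table(report$linking$table2,
                       file.path(out_dir, "table2_cluster_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
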