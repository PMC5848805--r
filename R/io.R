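# Readers and writers for the plain-text formats used throughout the
# package: BED6 interval files, TSV count/design/result tables, GMT gene-set
# collections and FASTA alignments. All genomic coordinates in data frames
# are 0-based half-open (BED convention); conversion to the 1-based closed
# convention of GenomicRanges happens only inside internal helpers.

#' Read a BED file of scored intervals
#'
#' Parses a 3-6 column tab-separated BED file. Coordinates are kept 0-based
#' half-open. The score column (column 5) is interpreted as -10*log10(p) of
#' the peak call when the file holds DNase peaks.
#'
#' @param path Path to a BED file.
#' @return A data frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", lineno[which(nf < 3)[1]], " in '", path,
         "': fewer than 3 fields")
  }
  ncol_use <- min(nf)
  m <- do.call(rbind, lapply(fields, function(f) f[seq_len(ncol_use)]))
  out <- data.frame(
    chrom = m[, 1],
    start = suppressWarnings(as.integer(m[, 2])),
    end   = suppressWarnings(as.integer(m[, 3]))
  )
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad)) {
    stop("malformed BED line ", lineno[bad[1]], " in '", path,
         "': non-integer coordinates")
  }
  bad <- which(out$end <= out$start)
  if (length(bad)) {
    stop("malformed BED line ", lineno[bad[1]], " in '", path,
         "': end <= start")
  }
  if (ncol_use >= 4) out$name <- m[, 4]
  if (ncol_use >= 5) out$score <- as.numeric(m[, 5])
  if (ncol_use >= 6) out$strand <- m[, 6]
  out
}

#' Write intervals as BED
#'
#' @param x Data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand` (0-based half-open coordinates).
#' @param path Output path.
#' @param digits Number of decimals kept for the score column.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path, digits = 4) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(x$name) || !is.null(x$score) || !is.null(x$strand)) {
    cols <- c(cols, list(if (is.null(x$name)) "." else x$name))
  }
  if (!is.null(x$score) || !is.null(x$strand)) {
    sc <- if (is.null(x$score)) 0 else round(x$score, digits)
    cols <- c(cols, list(format(sc, trim = TRUE, scientific = FALSE)))
  }
  if (!is.null(x$strand)) cols <- c(cols, list(x$strand))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a genes-by-samples count table
#'
#' Expects a TSV whose first column holds gene (ortholog pair) identifiers
#' and whose header row holds sample identifiers.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count table '", path, "' has no sample columns")
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in '", path, "'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a genes-by-samples count table
#' @param counts Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample`, `species`, `time`, `replicate`.
#' @return Data frame with `time` as a factor ordered Pre, T0, T12, T24.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "species", "time", "replicate")
  if (!all(need %in% names(d))) {
    stop("design table '", path, "' must have columns ",
         paste(need, collapse = ", "))
  }
  d$time <- factor(d$time, levels = intersect(time_levels(), unique(d$time)))
  d
}

#' Write a sample design table
#' @param design Data frame with columns `sample`, `species`, `time`, `replicate`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Canonical ordering of the serum-challenge time points.
time_levels <- function() c("Pre", "T0", "T12", "T24")

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   then member genes, tab-separated).
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set name in '", path, "': ",
         names(sets)[duplicated(names(sets))][1])
  }
  if (any(lengths(sets) == 0)) {
    stop("empty gene set in '", path, "': ",
         names(sets)[lengths(sets) == 0][1])
  }
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read FASTA sequences
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write FASTA sequences
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a three-taxon alignment bundle
#'
#' Reads a FASTA written by [write_fixture_bundle()] whose record names are
#' `gene|taxon` and regroups sequences per gene.
#'
#' @param path FASTA path.
#' @return Named list (per gene) of named character vectors (per taxon).
#' @export
read_alignment_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  gene <- vapply(parts, `[`, character(1), 1)
  taxon <- vapply(parts, `[`, character(1), 2)
  out <- split(stats::setNames(unname(seqs), taxon), gene)
  lapply(out, function(s) s)
}

# Internal: BED-style 0-based half-open intervals -> GRanges (1-based closed).
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}
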