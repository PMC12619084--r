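#' Configuration for the synthetic TRAP expression tables
#'
#' Emulates the structure of a TRAP/RiboTag experiment: FPKM tables for an
#' immunoprecipitated (IP, astrocyte ribosome-bound) fraction and a total
#' tissue (input) fraction, each with control and kainate (KA) samples,
#' plus a per-gene differential-statistics table.
#'
#' The generative model: each gene g has a baseline mean FPKM drawn
#' log-normally. Planted astrocyte-enriched genes have their IP-fraction
#' mean multiplied by `enrich_ratio`; planted DEGs have both fractions'
#' KA means multiplied by `2^log2fc` (a tissue-level change of an
#' astrocyte-expressed transcript), so every gene's expected IP/input
#' ratio equals its planted enrichment ratio. Observed values are the
#' means under multiplicative log-normal noise with coefficient of
#' variation `noise_cv`. Baselines of planted DEGs are floored at FPKM 10
#' so that planted truth always survives the expressed-gene filter.
#'
#' Because differential-model fitting is out of scope (log2FC and
#' adjusted p are treated as inputs throughout), the statistics table is
#' truth-driven: planted DEGs carry their exact planted log2FC with
#' adjusted p below 0.05; all other genes get near-zero log2FC and
#' adjusted p of at least 0.05.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per condition within each fraction
#'   (3 triplicates by default).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline mean FPKM.
#' @param deg_log2fc Named numeric vector: planted log2 fold changes
#'   (KA vs control), names are gene ids from `gene_ids(config)`.
#' @param enrich_ratio Named numeric vector: planted IP/input enrichment
#'   ratios.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return A `sim_expression_config` list.
#' @export
sim_expression_config <- function(n_genes = 5000, n_per_group = 3,
                                  baseline_meanlog = log(10),
                                  baseline_sdlog = 1.2,
                                  deg_log2fc = numeric(0),
                                  enrich_ratio = numeric(0),
                                  noise_cv = 0.1, seed = NULL) {
  stopifnot(n_genes >= 1, n_per_group >= 2, noise_cv >= 0,
            all(enrich_ratio > 0))
  ids <- sprintf("g%05d", seq_len(n_genes))
  chk <- function(v, what) {
    if (length(v)) {
      if (is.null(names(v)) || anyDuplicated(names(v)))
        stop_srseize(what, " must be uniquely named by gene id")
      if (!all(names(v) %in% ids))
        stop_srseize(what, " names outside the gene universe")
    }
    v
  }
  structure(list(n_genes = n_genes, n_per_group = n_per_group,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 deg_log2fc = chk(deg_log2fc, "deg_log2fc"),
                 enrich_ratio = chk(enrich_ratio, "enrich_ratio"),
                 noise_cv = noise_cv, seed = seed, gene_ids = ids),
            class = "sim_expression_config")
}

#' Gene identifiers of a simulated expression universe
#' @param config A [sim_expression_config].
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(config) config$gene_ids

#' Construct an FPKM expression table
#'
#' @param fpkm Numeric matrix of FPKM values, genes in rows (unique
#'   rownames = gene ids), samples in columns.
#' @param samples Data frame with one row per column of `fpkm`, columns
#'   `sample_id`, `condition` (e.g. control/KA/PBS) and `fraction`
#'   (IP/input).
#' @return An `fpkm_table`.
#' @export
fpkm_table <- function(fpkm, samples) {
  fpkm <- as.matrix(fpkm)
  if (is.null(rownames(fpkm)) || anyDuplicated(rownames(fpkm)))
    stop_srseize("fpkm must have unique gene-id rownames")
  if (any(!is.finite(fpkm)) || any(fpkm < 0))
    stop_srseize("FPKM values must be finite and non-negative")
  need <- c("sample_id", "condition", "fraction")
  if (!is.data.frame(samples) || !all(need %in% names(samples)))
    stop_srseize("samples must be a data frame with columns ",
                 paste(need, collapse = ", "))
  if (nrow(samples) != ncol(fpkm))
    stop_srseize("one samples row per fpkm column required")
  colnames(fpkm) <- samples$sample_id
  structure(list(fpkm = fpkm, samples = samples), class = "fpkm_table")
}

#' @export
print.fpkm_table <- function(x, ...) {
  cat(sprintf("FPKM table: %d genes x %d samples (%s)\n",
              nrow(x$fpkm), ncol(x$fpkm),
              paste(unique(paste(x$samples$condition, x$samples$fraction,
                                 sep = "/")), collapse = ", ")))
  invisible(x)
}

#' Simulate TRAP IP/input FPKM tables with planted truth
#'
#' @param config A [sim_expression_config].
#' @return A list with `ip` and `input` ([fpkm_table]s over control and KA
#'   samples), `de_stats` (data frame `gene_id`, `log2fc`, `adj_p`) and
#'   `truth` (data frame `gene_id`, `is_deg`, `log2fc`, `is_enriched`,
#'   `enrich_ratio`).
#' @examples
#' cfg <- sim_expression_config(n_genes = 200,
#'   deg_log2fc = c(g00001 = 2, g00002 = -2),
#'   enrich_ratio = c(g00001 = 4), seed = 1)
#' sim <- simulate_trap_tables(cfg)
#' sim$de_stats[1:3, ]
#' @export
simulate_trap_tables <- function(config) {
  stopifnot(inherits(config, "sim_expression_config"))
  with_seed(config$seed, {
    ids <- config$gene_ids
    n <- config$n_genes
    m <- config$n_per_group
    base <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
    names(base) <- ids
    is_deg <- ids %in% names(config$deg_log2fc)
    base[is_deg] <- pmax(base[is_deg], 10)
    lfc <- setNames(numeric(n), ids)
    lfc[names(config$deg_log2fc)] <- config$deg_log2fc
    ratio <- setNames(rep(1, n), ids)
    ratio[names(config$enrich_ratio)] <- config$enrich_ratio

    mean_mat <- function(fraction, condition) {
      mu <- base
      if (fraction == "IP") mu <- mu * ratio
      if (condition == "KA") mu <- mu * 2^lfc
      mu
    }
    noise <- function(k) {
      if (config$noise_cv == 0) return(matrix(1, n, k))
      sl <- sqrt(log(1 + config$noise_cv^2))
      matrix(rlnorm(n * k, -sl^2 / 2, sl), n, k)  # multiplicative, mean 1
    }
    build <- function(fraction) {
      conds <- rep(c("control", "KA"), each = m)
      mus <- cbind(matrix(mean_mat(fraction, "control"), n, m),
                   matrix(mean_mat(fraction, "KA"), n, m))
      fpkm <- mus * noise(2 * m)
      rownames(fpkm) <- ids
      samples <- data.frame(
        sample_id = sprintf("%s_%s_%d", tolower(fraction), conds,
                            c(seq_len(m), seq_len(m))),
        condition = conds, fraction = fraction,
        stringsAsFactors = FALSE)
      fpkm_table(fpkm, samples)
    }
    ip <- build("IP")
    input <- build("input")
    de_stats <- data.frame(
      gene_id = ids,
      log2fc = ifelse(is_deg, lfc, rnorm(n, 0, 0.25)),
      adj_p = ifelse(is_deg, runif(n, 1e-6, 0.04), runif(n, 0.05, 1)),
      stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = ids, is_deg = is_deg, log2fc = lfc,
                        is_enriched = ids %in% names(config$enrich_ratio),
                        enrich_ratio = ratio, stringsAsFactors = FALSE)
    list(ip = ip, input = input, de_stats = de_stats, truth = truth)
  })
}

#' Write an FPKM table as TSV
#'
#' First column `gene_id`, one column per sample; a companion metadata TSV
#' (`sample_id`, `condition`, `fraction`) is written next to it.
#'
#' @param tbl An [fpkm_table].
#' @param path Output TSV path; metadata goes to
#'   `<path minus extension>_samples.tsv`.
#' @return `path`, invisibly.
#' @export
write_fpkm_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "fpkm_table"))
  df <- data.frame(gene_id = rownames(tbl$fpkm), tbl$fpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta_path <- paste0(tools::file_path_sans_ext(path), "_samples.tsv")
  utils::write.table(tbl$samples, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an FPKM table from TSV
#' @param path TSV with `gene_id` first column, samples after.
#' @param meta_path Sample metadata TSV; defaults to the companion file
#'   written by [write_fpkm_table()].
#' @return An [fpkm_table].
#' @export
read_fpkm_table <- function(path,
                            meta_path = paste0(tools::file_path_sans_ext(path),
                                               "_samples.tsv")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop_srseize("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  samples <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  fpkm_table(m, samples)
}
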