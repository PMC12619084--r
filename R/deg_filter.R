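#' Expressed-gene filter
#'
#' Keeps genes whose FPKM is strictly greater than `fpkm_min` in every
#' sample of the supplied table(s). The canonical usage screens on the IP
#' (immunoprecipitated) samples only; pass both fractions to screen on all
#' comparison samples.
#'
#' @param tbl An [fpkm_table], or a list of them (a gene must pass in
#'   every sample of every table).
#' @param fpkm_min Threshold; strict (FPKM exactly equal to `fpkm_min` is
#'   excluded).
#' @return Character vector of surviving gene ids (in table order).
#' @export
expressed_genes <- function(tbl, fpkm_min = 1) {
  tables <- if (inherits(tbl, "fpkm_table")) list(tbl) else tbl
  if (!length(tables) || !all(vapply(tables, inherits, TRUE, "fpkm_table")))
    stop_srseize("'tbl' must be an fpkm_table or a list of them")
  ids <- rownames(tables[[1]]$fpkm)
  keep <- rep(TRUE, length(ids))
  for (tb in tables) {
    if (!identical(rownames(tb$fpkm), ids))
      stop_srseize("tables must share the same gene universe")
    keep <- keep & apply(tb$fpkm > fpkm_min, 1L, all)
  }
  ids[keep]
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when it is expressed, its |log2 fold change| is at
#' least `lfc_min` (boundary inclusive) and its adjusted p-value is
#' strictly below `alpha`.
#'
#' @param de_stats Data frame with columns `gene_id`, `log2fc`, `adj_p`
#'   (one row per gene; log2FC is KA vs control in the IP fraction).
#' @param expressed Character vector of expressed gene ids (from
#'   [expressed_genes()]); every id must appear in `de_stats`.
#' @param lfc_min Minimum |log2FC| (inclusive).
#' @param alpha Adjusted-p threshold (strict).
#' @return Data frame `gene_id`, `log2fc`, `adj_p`, `direction`
#'   (`"up"`/`"down"`), one row per DEG.
#' @export
call_degs <- function(de_stats, expressed, lfc_min = 1, alpha = 0.05) {
  need <- c("gene_id", "log2fc", "adj_p")
  if (!all(need %in% names(de_stats)))
    stop_srseize("de_stats needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(de_stats$gene_id))
    stop_srseize("duplicate gene_id in de_stats")
  if (any(de_stats$adj_p < 0 | de_stats$adj_p > 1, na.rm = TRUE))
    stop_srseize("adj_p outside [0, 1]")
  missing <- setdiff(expressed, de_stats$gene_id)
  if (length(missing))
    stop_srseize(length(missing), " expressed gene(s) missing from ",
                 "de_stats, e.g. ", missing[1L])
  st <- de_stats[de_stats$gene_id %in% expressed, , drop = FALSE]
  hit <- abs(st$log2fc) >= lfc_min & st$adj_p < alpha
  out <- st[hit, c("gene_id", "log2fc", "adj_p"), drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Astrocyte-enrichment filter (IP vs input)
#'
#' For each gene, the ratio of its mean FPKM across IP samples to its mean
#' FPKM across input samples; a gene is astrocyte-enriched when that ratio
#' exceeds `ratio_threshold` (strictly, by default). Means are taken
#' across samples within each fraction because IP and input libraries are
#' not pairable at the read level.
#'
#' A zero input mean with a non-zero IP mean yields an infinite ratio
#' (enriched) with a warning; set `pseudocount` to damp this. Upstream
#' FPKM filtering normally removes such genes.
#'
#' @param deg_ids Character vector of DEG ids to assess.
#' @param ip,input [fpkm_table]s for the two fractions.
#' @param ratio_threshold Enrichment threshold (default 2).
#' @param comparator `">"` (strict, default) or `">="`.
#' @param pseudocount Added to both means before the ratio (default 0).
#' @return Data frame `gene_id`, `ip_mean`, `input_mean`, `ratio`,
#'   `enriched`.
#' @export
astrocyte_enrichment <- function(deg_ids, ip, input, ratio_threshold = 2,
                                 comparator = c(">", ">="),
                                 pseudocount = 0) {
  comparator <- match.arg(comparator)
  stopifnot(inherits(ip, "fpkm_table"), inherits(input, "fpkm_table"))
  for (tb in list(IP = ip, input = input)) {
    miss <- setdiff(deg_ids, rownames(tb$fpkm))
    if (length(miss))
      stop_srseize("gene(s) absent from a fraction table, e.g. ", miss[1L])
  }
  ip_mean <- rowMeans(ip$fpkm[deg_ids, , drop = FALSE])
  input_mean <- rowMeans(input$fpkm[deg_ids, , drop = FALSE])
  ratio <- (ip_mean + pseudocount) / (input_mean + pseudocount)
  if (any(input_mean + pseudocount == 0 & ip_mean > 0))
    warning("zero input mean with non-zero IP mean: infinite ratio; ",
            "consider a pseudocount", call. = FALSE)
  enriched <- if (comparator == ">") ratio > ratio_threshold
              else ratio >= ratio_threshold
  data.frame(gene_id = deg_ids, ip_mean = unname(ip_mean),
             input_mean = unname(input_mean), ratio = unname(ratio),
             enriched = unname(enriched), stringsAsFactors = FALSE)
}

#' Top-k DEGs by fold-change magnitude
#'
#' Ranks DEGs of one direction by |log2FC| (descending), breaking ties by
#' ascending adjusted p then lexicographic gene id, and returns the first
#' `k`.
#'
#' @param degs DEG data frame (from [call_degs()], optionally restricted
#'   to enriched genes).
#' @param k Number of genes to return (> 0).
#' @param direction `"up"` or `"down"`.
#' @return The ordered head of the table (at most `k` rows).
#' @export
rank_top_degs <- function(degs, k = 10, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (k <= 0) stop_srseize("k must be positive")
  if (!nrow(degs)) stop_srseize("empty DEG table")
  d <- degs[degs$direction == direction, , drop = FALSE]
  o <- order(-abs(d$log2fc), d$adj_p, d$gene_id)
  out <- head(d[o, , drop = FALSE], k)
  rownames(out) <- NULL
  out
}

#' Cell-type marker enrichment ratios
#'
#' For each marker panel (a character vector of gene ids per cell type),
#' the mean over panel genes of (mean IP FPKM / mean input FPKM) — the
#' Fig-style readout that astrocyte markers are enriched and other
#' lineages depleted in the immunoprecipitated fraction.
#'
#' @param ip,input [fpkm_table]s.
#' @param panels Named list of character vectors (cell type -> gene ids).
#' @return Named numeric vector of per-panel mean ratios.
#' @export
marker_enrichment_ratios <- function(ip, input, panels) {
  if (!length(panels) || is.null(names(panels)))
    stop_srseize("panels must be a named list of gene-id vectors")
  vapply(panels, function(genes) {
    if (!length(genes)) stop_srseize("empty marker panel")
    res <- astrocyte_enrichment(genes, ip, input)
    mean(res$ratio)
  }, numeric(1))
}

#' Estimate released extracellular concentration
#'
#' Scales a total tissue concentration range by the assumed fraction of
#' the protein's content that astrocytes release (by analogy with the
#' ~5% steady-state release of BDNF), giving the expected extracellular
#' concentration range.
#'
#' @param total_low,total_high Total concentration bounds in ng/mL
#'   (`total_low <= total_high`, both non-negative).
#' @param release_fraction Released fraction in `[0, 1]`.
#' @return Named numeric vector `c(low, high)` in ng/mL.
#' @examples
#' estimate_release_concentration(370, 560, 0.05)  # 18.5 to 28 ng/mL
#' @export
estimate_release_concentration <- function(total_low, total_high,
                                           release_fraction) {
  if (total_low < 0 || total_high < 0)
    stop_srseize("concentrations must be non-negative")
  if (total_low > total_high)
    stop_srseize("total_low must not exceed total_high")
  if (release_fraction < 0 || release_fraction > 1)
    stop_srseize("release_fraction must lie in [0, 1]")
  c(low = total_low * release_fraction,
    high = total_high * release_fraction)
}
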