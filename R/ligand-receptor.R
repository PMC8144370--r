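#' Build a population expression summary for ligand-receptor analysis
#'
#' Per gene and population (cell type x zone cluster, e.g. crypt goblet,
#' villus-tip enterocyte, telocyte) the mean normalized expression and the
#' fraction of expressing cells.
#'
#' @param values genes x cells matrix of normalized expression
#' @param populations population label per cell (>= 2 distinct values)
#' @return a `type_expression_summary`: list of `mean_expr`, `frac_expr`
#'   (genes x populations) and population sizes
#' @export
build_type_summary <- function(values, populations) {
  pops <- sort(unique(populations))
  if (length(pops) < 2L) stop("need at least 2 populations")
  mean_expr <- vapply(pops, function(p)
    rowMeans(values[, populations == p, drop = FALSE]),
    numeric(nrow(values)))
  frac_expr <- vapply(pops, function(p)
    rowMeans(values[, populations == p, drop = FALSE] > 0),
    numeric(nrow(values)))
  dn <- list(rownames(values), pops)
  structure(list(
    mean_expr = matrix(mean_expr, ncol = length(pops), dimnames = dn),
    frac_expr = matrix(frac_expr, ncol = length(pops), dimnames = dn),
    n_cells = table(populations)[pops]
  ), class = "type_expression_summary")
}

#' Per-population enrichment Z-scores
#'
#' For gene g and population c,
#' \deqn{Z_g^c = (\bar{x}_g^c - mean_c(\bar{x}_g^c)) / sd_c(\bar{x}_g^c)}
#' with mean and sd taken across populations. The sd convention is the
#' sample standard deviation (n - 1) by default (`lr.sd_type`;
#' `"population"` switches to the n denominator). Genes with zero sd get
#' Z = 0 in every population.
#'
#' @param summary a [build_type_summary()]-style object, or any list with a
#'   `mean_expr` genes x populations matrix
#' @param config a [clumpseq_config()]
#' @return Z matrix, genes x populations
#' @export
compute_type_zscores <- function(summary, config = clumpseq_config()) {
  x <- summary$mean_expr
  if (ncol(x) < 2L) stop("Z-scores need at least 2 populations")
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  if (identical(config$lr$sd_type, "population"))
    sdv <- sdv * sqrt((ncol(x) - 1) / ncol(x))
  z <- (x - mu) / sdv
  z[sdv == 0, ] <- 0
  z
}

#' Score ligand-receptor interactions between populations
#'
#' For every ligand-receptor pair and every ordered pair of populations
#' (C1 expressing the ligand, C2 the receptor) the interaction score is
#' \deqn{Z_{interaction} = \sqrt{(Z_L^{C1})^2 + (Z_R^{C2})^2}}
#' By default only combinations where both the ligand and the receptor are
#' enriched (Z > 0) are reported — the raw quadrature would otherwise
#' reward strong depletion equally (`lr.require_positive = FALSE` gives the
#' literal formula). Pairs whose genes are absent from the Z matrix are
#' skipped.
#'
#' @param z Z matrix from [compute_type_zscores()]
#' @param lr_pairs data.frame with columns `ligand`, `receptor`
#' @param config a [clumpseq_config()]
#' @return data.frame: ligand, receptor, C1, C2, Z_L, Z_R, z_interaction
#' @export
compute_interaction_scores <- function(z, lr_pairs,
                                       config = clumpseq_config()) {
  if (nrow(lr_pairs) == 0L) stop("empty ligand-receptor pair list")
  present <- lr_pairs$ligand %in% rownames(z) &
    lr_pairs$receptor %in% rownames(z)
  if (any(!present))
    log_msg(sum(!present), " LR pairs skipped (genes absent)")
  lr_pairs <- lr_pairs[present, , drop = FALSE]
  pops <- colnames(z)
  grid <- expand.grid(pair = seq_len(nrow(lr_pairs)), C1 = pops, C2 = pops,
                      stringsAsFactors = FALSE)
  zl <- z[cbind(lr_pairs$ligand[grid$pair], grid$C1)]
  zr <- z[cbind(lr_pairs$receptor[grid$pair], grid$C2)]
  out <- data.frame(
    ligand = lr_pairs$ligand[grid$pair],
    receptor = lr_pairs$receptor[grid$pair],
    C1 = grid$C1, C2 = grid$C2, Z_L = zl, Z_R = zr,
    z_interaction = sqrt(zl^2 + zr^2)
  )
  if (isTRUE(config$lr$require_positive))
    out <- out[out$Z_L > 0 & out$Z_R > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter interaction scores for analysis or export
#'
#' Analysis mode keeps edges where the fraction of cells expressing either
#' the ligand (in C1) or the receptor (in C2) exceeds `lr.min_frac` (0.05)
#' and `z_interaction > 2`. Export mode additionally requires the mean
#' expression of ligand or receptor above `lr.export_min_expr` (2e-5) and
#' `z_interaction > 5`; it is the edge table handed to graph tools.
#'
#' @param scores data.frame from [compute_interaction_scores()]
#' @param summary the [build_type_summary()] the scores came from
#' @param mode `"analysis"` or `"export"`
#' @param config a [clumpseq_config()]
#' @return filtered edge data.frame
#' @export
filter_interactions <- function(scores, summary,
                                mode = c("analysis", "export"),
                                config = clumpseq_config()) {
  mode <- match.arg(mode)
  lr <- config$lr
  frac_l <- summary$frac_expr[cbind(scores$ligand, scores$C1)]
  frac_r <- summary$frac_expr[cbind(scores$receptor, scores$C2)]
  keep <- pmax(frac_l, frac_r) > lr$min_frac &
    scores$z_interaction > lr$z_analysis
  if (mode == "export") {
    mean_l <- summary$mean_expr[cbind(scores$ligand, scores$C1)]
    mean_r <- summary$mean_expr[cbind(scores$receptor, scores$C2)]
    keep <- keep & pmax(mean_l, mean_r) > lr$export_min_expr &
      scores$z_interaction > lr$z_export
  }
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an interaction edge table to TSV
#' @param edges data.frame from [filter_interactions()]
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
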