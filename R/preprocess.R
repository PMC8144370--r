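#' Subtract plate-wise ambient background estimated from empty wells
#'
#' For every plate the per-gene background is the mean expression of that
#' plate's empty wells; it is subtracted from every non-empty well of the
#' plate and negative values are clamped to zero. Empty wells are dropped
#' from the output (they have served their purpose).
#'
#' @param cm a [count_matrix()] in which every occupied plate has at least
#'   one empty well
#' @return a [count_matrix()]-like object of background-subtracted values
#'   (values may be fractional after subtracting a mean), empty wells removed
#' @export
subtract_background <- function(cm) {
  meta <- cm$well_meta
  counts <- cm$counts
  out <- counts
  for (plate in unique(meta$plate_id)) {
    on_plate <- meta$plate_id == plate
    empty <- on_plate & meta$well_kind == "empty"
    samp <- on_plate & meta$well_kind != "empty"
    if (!any(samp)) next
    if (!any(empty)) stop("plate without empty wells: ", plate)
    bg <- rowMeans(counts[, empty, drop = FALSE])
    out[, samp] <- pmax(counts[, samp, drop = FALSE] - bg, 0)
  }
  keep <- meta$well_kind != "empty"
  structure(list(counts = out[, keep, drop = FALSE],
                 well_meta = meta[keep, , drop = FALSE]),
            class = "count_matrix")
}

#' QC-filter clumps or single cells
#'
#' Clump mode retains wells with more than `clump_min_umi` total UMIs, at
#' least `clump_min_genes` detected genes and mitochondrial fraction at most
#' `clump_max_mito`. Single-cell mode retains wells with total UMIs strictly
#' inside (`cell_min_umi`, `cell_max_umi`), detected genes strictly inside
#' (`cell_min_genes`, `cell_max_genes`) and mitochondrial fraction at most
#' `cell_max_mito`. All bounds come from `config$qc`. Retained counts are
#' never altered.
#'
#' @param cm a [count_matrix()] (post background subtraction)
#' @param mode `"clump"` or `"single_cell"`
#' @param config a [clumpseq_config()]
#' @param mito_genes character vector of mitochondrial gene symbols
#' @return list with `counts` (filtered [count_matrix()]) and `report`
#'   (data.frame with one row per input well: totals, detected genes, mito
#'   fraction, pass flag and failure reasons)
#' @export
qc_filter <- function(cm, mode = c("clump", "single_cell"), config,
                      mito_genes) {
  mode <- match.arg(mode)
  if (length(mito_genes) == 0L)
    stop("mitochondrial gene set is empty")
  qc <- config$qc
  totals <- colSums(cm$counts)
  genes_detected <- colSums(cm$counts > 0)
  mito <- colSums(cm$counts[rownames(cm$counts) %in% mito_genes, ,
                            drop = FALSE])
  mito_frac <- ifelse(totals > 0, mito / totals, 0)
  reasons <- vector("list", ncol(cm$counts))
  add <- function(flag, why) {
    for (i in which(flag)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  if (mode == "clump") {
    add(totals <= qc$clump_min_umi, "low_umi")
    add(genes_detected < qc$clump_min_genes, "few_genes")
    add(mito_frac > qc$clump_max_mito, "high_mito")
  } else {
    add(totals <= qc$cell_min_umi, "low_umi")
    add(totals >= qc$cell_max_umi, "high_umi")
    add(genes_detected <= qc$cell_min_genes, "few_genes")
    add(genes_detected >= qc$cell_max_genes, "many_genes")
    add(mito_frac > qc$cell_max_mito, "high_mito")
  }
  pass <- lengths(reasons) == 0L
  report <- data.frame(
    well_id = colnames(cm$counts),
    total_umi = totals, genes_detected = genes_detected,
    mito_fraction = mito_frac, pass = pass,
    reasons = vapply(reasons, function(r) paste(r, collapse = ";"),
                     character(1)),
    row.names = NULL
  )
  filtered <- structure(
    list(counts = cm$counts[, pass, drop = FALSE],
         well_meta = cm$well_meta[pass, , drop = FALSE]),
    class = "count_matrix"
  )
  list(counts = filtered, report = report)
}

#' Normalize each well by its total UMIs
#'
#' @param cm a [count_matrix()] or plain genes x wells matrix
#' @return a [norm_matrix()] with scope `"total"` (every column sums to 1)
#' @export
normalize_total <- function(cm) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else cm
  meta <- if (inherits(cm, "count_matrix")) cm$well_meta else NULL
  sums <- colSums(m)
  if (any(sums == 0))
    stop("all-zero wells cannot be normalized: ",
         paste(utils::head(colnames(m)[sums == 0], 5), collapse = ", "))
  norm_matrix(sweep(m, 2L, sums, "/"), "total", well_meta = meta)
}

#' Internally normalize expression over a gene subset
#'
#' Restricts the matrix to `gene_subset` and divides each column by its sum
#' over the subset, making samples with different cell numbers comparable on
#' that subset. Columns with zero subset expression are dropped with a
#' warning.
#'
#' @param m a [norm_matrix()], [count_matrix()] or plain matrix
#' @param gene_subset non-empty character vector of gene symbols
#' @return a [norm_matrix()] with scope `"gene_subset"`
#' @export
internal_normalize <- function(m, gene_subset) {
  if (length(gene_subset) == 0L) stop("gene subset is empty")
  vals <- if (inherits(m, c("norm_matrix"))) m$values
          else if (inherits(m, "count_matrix")) m$counts else m
  meta <- if (inherits(m, c("norm_matrix", "count_matrix")))
    m$well_meta else NULL
  sub <- vals[rownames(vals) %in% gene_subset, , drop = FALSE]
  sums <- colSums(sub)
  drop <- sums == 0
  if (any(drop)) {
    warning(sum(drop), " wells with zero subset expression dropped")
    sub <- sub[, !drop, drop = FALSE]
    sums <- sums[!drop]
    if (!is.null(meta)) meta <- meta[!drop, , drop = FALSE]
  }
  norm_matrix(sweep(sub, 2L, sums, "/"), "gene_subset",
              subset_ids = rownames(sub), well_meta = meta)
}

#' Label single cells by marker-sum Z-scores
#'
#' For each cell type the normalized expression of its markers is summed per
#' cell and converted to a Z-score across cells; each cell is labeled by the
#' type with the highest positive Z-score, and cells with no positive score
#' are labeled `"enterocyte"` (the default, dominant type).
#'
#' @param cells a [norm_matrix()] of total-normalized single cells
#' @param marker_sets named list of disjoint marker gene vectors, one per
#'   secretory type
#' @return named character vector of cell type labels (names = well ids)
#' @export
classify_cells_by_markers <- function(cells, marker_sets) {
  if (anyDuplicated(unlist(marker_sets)))
    stop("marker sets must be disjoint")
  vals <- cells$values
  z <- vapply(marker_sets, function(genes) {
    s <- colSums(vals[rownames(vals) %in% genes, , drop = FALSE])
    sdv <- stats::sd(s)
    if (is.na(sdv) || sdv == 0) rep(0, length(s)) else (s - mean(s)) / sdv
  }, numeric(ncol(vals)))
  z <- matrix(z, ncol = length(marker_sets),
              dimnames = list(colnames(vals), names(marker_sets)))
  best <- max.col(z, ties.method = "first")
  labels <- ifelse(z[cbind(seq_len(nrow(z)), best)] > 0,
                   colnames(z)[best], "enterocyte")
  stats::setNames(labels, colnames(vals))
}
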