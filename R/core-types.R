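#' UMI count matrix with well metadata
#'
#' Container for raw genes x wells UMI counts plus per-well metadata. Wells
#' are clumps, single cells or empty wells; every well belongs to a plate and
#' every plate carrying clump/cell wells must contain at least one empty well,
#' since background subtraction is per plate.
#'
#' @param counts non-negative integer matrix, genes as rows (rownames = gene
#'   symbols), wells as columns (colnames = well ids)
#' @param well_meta data.frame with columns `well_id`, `plate_id`,
#'   `well_kind` (one of clump / single_cell / empty) and optionally
#'   `n_cells_estimate`, `time_stamp`
#' @return an object of class `count_matrix`
#' @export
count_matrix <- function(counts, well_meta) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in count matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integer")
  required <- c("well_id", "plate_id", "well_kind")
  if (!all(required %in% names(well_meta)))
    stop("well_meta must have columns: ", paste(required, collapse = ", "))
  if (!setequal(well_meta$well_id, colnames(counts)))
    stop("well_meta wells do not match count matrix columns")
  well_meta <- well_meta[match(colnames(counts), well_meta$well_id), ,
                         drop = FALSE]
  rownames(well_meta) <- NULL
  bad <- setdiff(unique(well_meta$well_kind),
                 c("clump", "single_cell", "empty"))
  if (length(bad)) stop("unknown well_kind: ", paste(bad, collapse = ", "))
  if (anyNA(well_meta$plate_id)) stop("every well needs a plate_id")
  occupied <- unique(well_meta$plate_id[well_meta$well_kind != "empty"])
  empties <- unique(well_meta$plate_id[well_meta$well_kind == "empty"])
  missing_bg <- setdiff(occupied, empties)
  if (length(missing_bg))
    stop("plates without empty wells (background unavailable): ",
         paste(missing_bg, collapse = ", "))
  structure(list(counts = counts, well_meta = well_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  kinds <- table(x$well_meta$well_kind)
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " wells (", paste(names(kinds), kinds, sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Normalized expression matrix
#'
#' Genes x wells matrix of expression fractions. `scope = "total"` means each
#' column was divided by its total (columns sum to 1); `scope = "gene_subset"`
#' means values are restricted to `subset_ids` and each column was divided by
#' its sum over that subset.
#'
#' @param values non-negative numeric matrix with dimnames
#' @param scope `"total"` or `"gene_subset"`
#' @param subset_ids gene ids defining the subset (required for
#'   `gene_subset` scope)
#' @param well_meta optional per-well metadata carried along
#' @return an object of class `norm_matrix`
#' @export
norm_matrix <- function(values, scope = c("total", "gene_subset"),
                        subset_ids = NULL, well_meta = NULL) {
  scope <- match.arg(scope)
  stopifnot(is.matrix(values), all(values >= 0))
  if (scope == "gene_subset") {
    if (is.null(subset_ids)) stop("gene_subset scope requires subset_ids")
    sums <- colSums(values[rownames(values) %in% subset_ids, , drop = FALSE])
  } else {
    sums <- colSums(values)
  }
  if (any(abs(sums - 1) > 1e-9))
    stop("normalized columns must sum to 1 over the ", scope, " scope")
  structure(list(values = values, scope = scope, subset_ids = subset_ids,
                 well_meta = well_meta),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("norm_matrix (", x$scope, "): ", nrow(x$values), " genes x ",
      ncol(x$values), " wells\n", sep = "")
  invisible(x)
}

#' Spatial reference zonation table
#'
#' Genes x ordered zones mean normalized expression; zone 1 is the crypt and
#' zone indices increase toward the villus tip. This is the coordinate system
#' clumps are mapped onto.
#'
#' @param values non-negative matrix, genes x zones, with dimnames
#' @return an object of class `spatial_reference`
#' @export
spatial_reference <- function(values) {
  stopifnot(is.matrix(values), all(values >= 0), ncol(values) >= 2,
            !is.null(rownames(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("zone", seq_len(ncol(values)))
  structure(list(values = values, zone_labels = colnames(values),
                 n_zones = ncol(values)),
            class = "spatial_reference")
}

#' Zonation table
#'
#' The pipeline's central output: per gene and zone the mean and SEM of
#' normalized expression across samples, the number of expressing samples,
#' and per-gene Kruskal-Wallis p with Benjamini-Hochberg q over the tested
#' gene set (genes below the testing floor have NA p/q).
#'
#' @param mean,sem non-negative genes x zones matrices
#' @param n_expressing integer genes x zones matrix
#' @param p,q per-gene p- and q-values (NA when untested)
#' @param group_sizes samples per zone
#' @return an object of class `zonation_table`
#' @export
zonation_table <- function(mean, sem, n_expressing, p, q, group_sizes) {
  stopifnot(identical(dim(mean), dim(sem)),
            identical(dim(mean), dim(n_expressing)),
            all(mean >= 0), all(sem >= 0),
            length(p) == nrow(mean), length(q) == nrow(mean))
  if (any(sweep(n_expressing, 2L, group_sizes) > 0))
    stop("n_expressing exceeds zone group size")
  structure(list(gene_ids = rownames(mean), zone_labels = colnames(mean),
                 mean = mean, sem = sem, n_expressing = n_expressing,
                 p = p, q = q, group_sizes = group_sizes),
            class = "zonation_table")
}

#' @export
print.zonation_table <- function(x, ...) {
  cat("zonation_table: ", nrow(x$mean), " genes x ", ncol(x$mean),
      " zones; ", sum(!is.na(x$p)), " genes tested\n", sep = "")
  invisible(x)
}

#' Landmark gene set
#'
#' Disjoint lists of crypt, (optionally) mid-villus and tip landmark genes
#' for one cell type.
#'
#' @param cell_type cell type name
#' @param crypt,tip character vectors of gene symbols
#' @param mid optional mid-villus list (enterocytes only)
#' @return an object of class `landmark_set`
#' @export
landmark_set <- function(cell_type, crypt, tip, mid = character()) {
  all_genes <- c(crypt, mid, tip)
  if (anyDuplicated(all_genes))
    stop("landmark lists must be pairwise disjoint")
  structure(list(cell_type = cell_type, crypt = crypt, mid = mid, tip = tip),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set (", x$cell_type, "): ", length(x$crypt), " crypt, ",
      length(x$mid), " mid, ", length(x$tip), " tip\n", sep = "")
  invisible(x)
}
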