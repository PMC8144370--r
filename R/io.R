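#' Read a UMI count matrix with well metadata
#'
#' Accepts either a MatrixMarket `.mtx` file with `genes.tsv` /
#' `barcodes.tsv` sidecars in the same directory (one id per line), or a
#' dense TSV/CSV with gene symbols in the first column and wells as the
#' remaining columns. The metadata file is a TSV with one row per well and
#' columns `well_id`, `plate_id`, `well_kind`, optionally
#' `n_cells_estimate` and `time_stamp`.
#'
#' @param path matrix file (`.mtx`, `.tsv` or `.csv`)
#' @param metadata_path well metadata TSV
#' @return a [count_matrix()]
#' @export
read_count_matrix <- function(path, metadata_path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes <- readLines(file.path(dir, "genes.tsv"))
    wells <- readLines(file.path(dir, "barcodes.tsv"))
    if (nrow(m) != length(genes) || ncol(m) != length(wells))
      stop("MTX dimensions do not match sidecar files")
    dimnames(m) <- list(genes, wells)
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  storage.mode(m) <- "double"
  if (any(m != round(m))) stop("non-integer counts in ", path)
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  absent <- setdiff(meta$well_id, colnames(m))
  if (length(absent))
    stop("metadata lists wells absent from the matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  absent_meta <- setdiff(colnames(m), meta$well_id)
  if (length(absent_meta))
    stop("matrix wells missing from metadata: ",
         paste(utils::head(absent_meta, 5), collapse = ", "))
  count_matrix(m, meta)
}

#' Write a count matrix to MatrixMarket or dense TSV
#'
#' @param cm a [count_matrix()]
#' @param dir output directory (created if needed)
#' @param format `"mtx"` (matrix.mtx + genes.tsv + barcodes.tsv) or
#'   `"tsv"` (counts.tsv)
#' @return paths of the matrix file and metadata file, invisibly
#' @export
write_count_matrix <- function(cm, dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "mtx") {
    mpath <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), mpath)
    writeLines(rownames(cm$counts), file.path(dir, "genes.tsv"))
    writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  } else {
    mpath <- file.path(dir, "counts.tsv")
    df <- data.frame(gene = rownames(cm$counts), cm$counts,
                     check.names = FALSE)
    utils::write.table(df, mpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  meta_path <- file.path(dir, "well_metadata.tsv")
  utils::write.table(cm$well_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mpath, metadata = meta_path))
}

#' Write a zonation table to TSV
#'
#' One row per gene; per-zone `mean_*`, `sem_*` and `n_*` columns followed by
#' `p` and `q` (empty for genes below the testing floor). Values are written
#' at full double precision so a read-back reproduces them to 1e-12.
#'
#' @param table a [zonation_table()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_zonation_table <- function(table, path) {
  z <- table$zone_labels
  df <- data.frame(gene = table$gene_ids, check.names = FALSE)
  for (j in seq_along(z)) df[[paste0("mean_", z[j])]] <- table$mean[, j]
  for (j in seq_along(z)) df[[paste0("sem_", z[j])]] <- table$sem[, j]
  for (j in seq_along(z)) df[[paste0("n_", z[j])]] <- table$n_expressing[, j]
  df$p <- table$p
  df$q <- table$q
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "gene" &
    !grepl("^n_", names(df))
  for (nm in names(df)[num])
    df[[nm]] <- ifelse(is.na(df[[nm]]), "", sprintf("%.17g", df[[nm]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a zonation table written by [write_zonation_table()]
#' @param path TSV path
#' @param group_sizes optional samples-per-zone vector; defaults to the
#'   per-zone maximum of `n_expressing` (sufficient for downstream use)
#' @return a [zonation_table()]
#' @export
read_zonation_table <- function(path, group_sizes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  zcols <- grep("^mean_", names(df), value = TRUE)
  zones <- sub("^mean_", "", zcols)
  pick <- function(prefix) {
    m <- as.matrix(df[paste0(prefix, zones)])
    dimnames(m) <- list(df$gene, zones)
    m
  }
  mean_m <- pick("mean_"); sem_m <- pick("sem_"); n_m <- pick("n_")
  if (is.null(group_sizes)) group_sizes <- apply(n_m, 2L, max)
  zonation_table(mean_m, sem_m, n_m, as.numeric(df$p), as.numeric(df$q),
                 group_sizes)
}

#' Read a two-column ligand-receptor pair list
#' @param path TSV with columns `ligand`, `receptor` (header required)
#' @return data.frame with columns ligand, receptor
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df)))
    stop("LR pair list needs 'ligand' and 'receptor' columns")
  df[c("ligand", "receptor")]
}

#' Write a landmark set to TSV
#' @param set a [landmark_set()]
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_landmark_set <- function(set, path) {
  df <- data.frame(
    gene = c(set$crypt, set$mid, set$tip),
    list = rep(c("crypt", "mid", "tip"),
               c(length(set$crypt), length(set$mid), length(set$tip))),
    cell_type = set$cell_type
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
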