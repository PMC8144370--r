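#' Assign clumps to crypt-villus zones by landmark correlation
#'
#' Input clumps must be internally normalized over the enterocyte-specific
#' gene set (the landmarks are a subset of that set). The bottom
#' `clump.discard_fraction` of clumps by total landmark expression are
#' discarded as unassignable. Landmark expression is then max-normalized per
#' gene across reference zones and across clumps, and each clump is assigned
#' the zone whose normalized landmark vector it correlates best with
#' (Pearson by default; ties go to the lowest zone index).
#'
#' @param clumps a [norm_matrix()] with `gene_subset` scope over the
#'   enterocyte-specific genes
#' @param reference a [spatial_reference()]
#' @param landmarks an enterocyte [landmark_set()]
#' @param config a [clumpseq_config()]
#' @return data.frame: `clump_id`, `zone` (NA when discarded),
#'   `correlation`, `discarded`, `reason`
#' @export
assign_clump_zones <- function(clumps, reference, landmarks, config) {
  lm_genes <- c(landmarks$crypt, landmarks$mid, landmarks$tip)
  lm_genes <- intersect(lm_genes, rownames(clumps$values))
  lm_genes <- intersect(lm_genes, rownames(reference$values))
  if (length(lm_genes) < 2L)
    stop("fewer than 2 landmark genes present in the clump matrix")
  vals <- clumps$values[lm_genes, , drop = FALSE]

  lm_sum <- colSums(vals)
  n_discard <- floor(config$clump$discard_fraction * ncol(vals))
  cutoff_idx <- order(lm_sum)[seq_len(n_discard)]
  discarded <- seq_len(ncol(vals)) %in% cutoff_idx

  ref_norm <- max_normalize_rows(reference$values[lm_genes, , drop = FALSE])
  clump_norm <- max_normalize_rows(vals[, !discarded, drop = FALSE])

  method <- config$clump$correlation_method
  cors <- suppressWarnings(
    stats::cor(clump_norm, ref_norm, method = method))
  cors[is.na(cors)] <- -Inf  # zero-variance clump vectors match nothing
  zone <- apply(cors, 1L, which.max)  # which.max takes the lowest on ties
  best_cor <- cors[cbind(seq_len(nrow(cors)), zone)]

  out <- data.frame(clump_id = colnames(vals), zone = NA_integer_,
                    correlation = NA_real_, discarded = discarded,
                    reason = ifelse(discarded, "low_landmark_sum", ""),
                    row.names = NULL)
  out$zone[!discarded] <- as.integer(zone)
  out$correlation[!discarded] <- ifelse(is.finite(best_cor), best_cor, NA)
  out
}

#' Compute a zonation table from zoned samples
#'
#' Per gene: mean and SEM of expression per zone across samples, the number
#' of samples expressing the gene (value > `expr_threshold`), a
#' Kruskal-Wallis p-value across zone groups for genes whose maximal zone
#' mean exceeds `test_floor`, and Benjamini-Hochberg q-values over the
#' tested genes.
#'
#' @param m a [norm_matrix()] or plain genes x samples matrix
#' @param zones integer zone per sample (named by sample id or aligned with
#'   columns); every zone in `1..max(zones)` must have at least one sample
#' @param test_floor maximal-zone-mean threshold under which no p is
#'   computed (default `clump.zonation_test_floor` = 5e-6)
#' @param expr_threshold value a sample must exceed to count as expressing
#'   (default 0)
#' @param n_zones number of zones (defaults to `max(zones)`)
#' @return a [zonation_table()]
#' @export
compute_zonation_table <- function(m, zones, test_floor = 5e-6,
                                   expr_threshold = 0, n_zones = NULL) {
  vals <- if (inherits(m, "norm_matrix")) m$values else m
  if (!is.null(names(zones))) zones <- zones[colnames(vals)]
  stopifnot(length(zones) == ncol(vals))
  n_zones <- n_zones %||% max(zones)
  sizes <- tabulate(zones, n_zones)
  if (any(sizes == 0L))
    stop("zones with zero samples: ",
         paste(which(sizes == 0L), collapse = ", "))

  zf <- factor(zones, levels = seq_len(n_zones))
  group <- function(fun) {
    out <- vapply(levels(zf), function(l) {
      sub <- vals[, zf == l, drop = FALSE]
      apply(sub, 1L, fun)
    }, numeric(nrow(vals)))
    matrix(out, ncol = n_zones,
           dimnames = list(rownames(vals), paste0("zone", seq_len(n_zones))))
  }
  mean_m <- group(mean)
  sem_m <- group(sem)
  nexp <- group(function(x) sum(x > expr_threshold))

  tested <- apply(mean_m, 1L, max) > test_floor
  p <- rep(NA_real_, nrow(vals))
  p[tested] <- apply(vals[tested, , drop = FALSE], 1L, kw_pvalue,
                     groups = zf)
  q <- rep(NA_real_, nrow(vals))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  names(p) <- names(q) <- rownames(vals)
  zonation_table(mean_m, sem_m, nexp, p, q, sizes)
}

#' Extract secretory landmark genes from a per-type clump zonation table
#'
#' Among the secretory-specific genes whose maximal zone-mean expression in
#' the clump table reaches `clump.secretory_landmark_min_expr`, crypt
#' landmarks have COM at most `crypt_cutoff` and at least
#' `clump.min_clumps_expressing` expressing clumps in the crypt (zone 1);
#' tip landmarks have COM at least `tip_cutoff` and the same support in the
#' tip-most zone.
#'
#' @param type_table a [zonation_table()] built from this secretory type's
#'   clumps (internally normalized over its specific genes)
#' @param secretory_genes the type's specific gene set
#' @param crypt_cutoff,tip_cutoff COM thresholds (e.g. goblet 3 / 4.7,
#'   enteroendocrine and tuft 1.8 / 4.2, on a 7-zone table)
#' @param config a [clumpseq_config()]
#' @param cell_type label stored in the result
#' @return a [landmark_set()] with crypt and tip lists
#' @export
select_secretory_landmarks <- function(type_table, secretory_genes,
                                       crypt_cutoff, tip_cutoff, config,
                                       cell_type = "secretory") {
  cl <- config$clump
  genes <- intersect(secretory_genes, type_table$gene_ids)
  mean_m <- type_table$mean[genes, , drop = FALSE]
  nexp <- type_table$n_expressing[genes, , drop = FALSE]
  nz <- ncol(mean_m)
  expressed <- apply(mean_m, 1L, max) >= cl$secretory_landmark_min_expr
  com <- center_of_mass(mean_m)
  crypt <- genes[expressed & !is.na(com) & com <= crypt_cutoff &
                   nexp[, 1L] >= cl$min_clumps_expressing]
  tip <- genes[expressed & !is.na(com) & com >= tip_cutoff &
                 nexp[, nz] >= cl$min_clumps_expressing]
  if (length(crypt) == 0L || length(tip) == 0L)
    stop("no ", if (length(crypt) == 0L) "crypt" else "tip",
         " landmarks pass the filters for ", cell_type)
  landmark_set(cell_type, crypt = crypt, tip = tip)
}
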