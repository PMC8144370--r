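#' Embed clumps in marker-sum principal-component space
#'
#' For each secretory type the total-normalized expression of its
#' classification markers is summed per clump; the four sums are converted
#' to Z-scores across clumps (projecting clumps into a 4-dimensional
#' marker space), reduced to three principal components, and each component
#' is median-centered so the origin sits at the enterocyte-only bulk.
#' Pairs and larger clumps must be embedded separately (their relative
#' marker content differs systematically with clump size), so `clumps`
#' should contain one stratum.
#'
#' @param clumps a [norm_matrix()] of total-normalized clumps (one stratum)
#' @param marker_sets named list of marker gene vectors (goblet,
#'   enteroendocrine, tuft, paneth)
#' @return a `clump_embedding`: list with `marker_sum_z` (clumps x types),
#'   `pc_position` (clumps x 3), `origin_distance`, and the `pca` rotation
#' @export
embed_clumps <- function(clumps, marker_sets) {
  vals <- clumps$values
  if (ncol(vals) < 5L) stop("fewer than 5 clumps in stratum")
  sums <- vapply(marker_sets, function(genes)
    colSums(vals[rownames(vals) %in% genes, , drop = FALSE]),
    numeric(ncol(vals)))
  z <- scale(sums)
  z[, attr(z, "scaled:scale") == 0] <- 0
  pca <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(pca$x))
  pcs <- pca$x[, seq_len(k), drop = FALSE]
  pcs <- sweep(pcs, 2L, apply(pcs, 2L, stats::median))
  structure(list(
    clump_ids = colnames(vals),
    marker_sum_z = matrix(as.numeric(z), ncol = ncol(z),
                          dimnames = list(colnames(vals),
                                          names(marker_sets))),
    pc_position = pcs,
    origin_distance = sqrt(rowSums(pcs^2)),
    rotation = pca$rotation[, seq_len(k), drop = FALSE]
  ), class = "clump_embedding")
}

#' Fit secretory-type rays through the origin
#'
#' Clumps beyond the `ray_percentile` (default 99th) of origin distance are
#' grouped by the secretory type whose marker-sum Z-score peaks in them;
#' each group's ray direction is the leading principal axis of its PC
#' positions constrained through the origin (origin-constrained total least
#' squares), oriented toward the far clumps.
#'
#' @param embedding a [embed_clumps()] result
#' @param config a [clumpseq_config()]
#' @return named list of unit direction 3-vectors, one per secretory type
#' @export
fit_rays <- function(embedding, config) {
  pct <- config$classification$ray_percentile / 100
  cutoff <- stats::quantile(embedding$origin_distance, pct)
  far <- embedding$origin_distance > cutoff
  if (sum(far) < length(colnames(embedding$marker_sum_z)))
    stop("fewer far clumps than secretory types")
  peak <- colnames(embedding$marker_sum_z)[
    max.col(embedding$marker_sum_z[far, , drop = FALSE],
            ties.method = "first")]
  rays <- lapply(colnames(embedding$marker_sum_z), function(ty) {
    pts <- embedding$pc_position[far, , drop = FALSE][peak == ty, ,
                                                      drop = FALSE]
    if (nrow(pts) == 0L)
      stop("no far clumps for secretory type: ", ty)
    # leading eigenvector of the (uncentered) scatter: the line through the
    # origin minimizing total squared orthogonal distance
    ev <- eigen(crossprod(pts), symmetric = TRUE)$vectors[, 1L]
    if (sum(pts %*% ev) < 0) ev <- -ev  # point toward the far clumps
    ev / sqrt(sum(ev^2))
  })
  stats::setNames(rays, colnames(embedding$marker_sum_z))
}

ray_distances <- function(positions, rays) {
  d2 <- rowSums(positions^2)
  vapply(rays, function(dir) {
    proj <- as.vector(positions %*% dir)
    sqrt(pmax(d2 - proj^2, 0))
  }, numeric(nrow(positions)))
}

#' Classify clump secretory content with ray geometry and abundance quotas
#'
#' Each clump's Euclidean distances to the four rays are converted to
#' Z-scores within the clump (across its own four distances); candidates
#' are clumps whose closest-ray distance Z lies below
#' `ray_distance_z_cutoff` (-1), i.e. clumps distinctly closer to one ray
#' than to the other three. Per ray and region (crypt = zone 1,
#' villus = zones 2..N) candidates are sorted by origin distance
#' (descending) and the top fraction equal to the measured regional
#' proportion of the type times the stratum's quota multiplier (2 for pairs,
#' 3 for larger clumps, capped at 1) is accepted; every other clump is
#' enterocyte-only.
#'
#' @param embedding a [embed_clumps()] result for one stratum
#' @param rays a [fit_rays()] result
#' @param zones integer zone per clump (named by clump id); clumps with NA
#'   zone are left unclassified (enterocyte-only)
#' @param stratum `"pairs"` or `"larger"`
#' @param config a [clumpseq_config()]
#' @return data.frame: `clump_id`, `call` (secretory type or
#'   `"enterocyte"`), `closest_ray`, `ray_distance_z`, `origin_distance`
#' @export
classify_clump_types <- function(embedding, rays, zones, stratum, config) {
  cls <- config$classification
  mult <- if (stratum == "pairs") cls$quota_multiplier_pairs
          else cls$quota_multiplier_larger
  d <- ray_distances(embedding$pc_position, rays)
  mu <- rowMeans(d)
  sdv <- apply(d, 1L, stats::sd)
  dz <- (d - mu) / ifelse(sdv > 0, sdv, 1)
  closest <- max.col(-d, ties.method = "first")
  closest_z <- dz[cbind(seq_len(nrow(d)), closest)]
  zone <- zones[embedding$clump_ids]
  region <- ifelse(zone == 1L, "crypt", "villus")
  candidate <- closest_z < cls$ray_distance_z_cutoff & !is.na(region)

  call <- rep("enterocyte", length(embedding$clump_ids))
  for (ty in names(rays)) {
    for (reg in c("crypt", "villus")) {
      idx <- which(candidate & names(rays)[closest] == ty &
                     region == reg)
      if (!length(idx)) next
      frac <- min(1, cls$proportions[[reg]][[ty]] * mult)
      n_accept <- round(frac * length(idx))
      if (n_accept == 0L) next
      ord <- idx[order(embedding$origin_distance[idx],
                       embedding$clump_ids[idx], decreasing = TRUE)]
      call[ord[seq_len(n_accept)]] <- ty
    }
  }
  data.frame(clump_id = embedding$clump_ids, call = call,
             closest_ray = names(rays)[closest],
             ray_distance_z = closest_z,
             origin_distance = embedding$origin_distance,
             row.names = NULL)
}

#' Classify all clumps, handling pair/larger strata
#'
#' Splits clumps into pairs (`n_cells_estimate == 2`) and larger clumps,
#' embeds each stratum separately, fits rays and applies the quota
#' classifier, then combines the per-stratum calls.
#'
#' @param clumps a [norm_matrix()] of total-normalized clumps whose
#'   `well_meta` carries `n_cells_estimate`
#' @param marker_sets named list of classification marker vectors per type
#' @param zones integer zone per clump (named)
#' @param config a [clumpseq_config()]
#' @return data.frame as in [classify_clump_types()], plus a `stratum`
#'   column
#' @export
classify_clumps <- function(clumps, marker_sets, zones, config) {
  meta <- clumps$well_meta
  if (is.null(meta$n_cells_estimate))
    stop("well metadata must carry n_cells_estimate to stratify clumps")
  est <- stats::setNames(meta$n_cells_estimate, meta$well_id)
  res <- lapply(c("pairs", "larger"), function(stratum) {
    sel <- if (stratum == "pairs") est[colnames(clumps$values)] == 2
           else est[colnames(clumps$values)] > 2
    if (!any(sel)) return(NULL)
    sub <- norm_matrix(clumps$values[, sel, drop = FALSE], clumps$scope,
                       clumps$subset_ids,
                       meta[meta$well_id %in% colnames(clumps$values)[sel], ,
                            drop = FALSE])
    emb <- embed_clumps(sub, marker_sets)
    rays <- fit_rays(emb, config)
    out <- classify_clump_types(emb, rays, zones, stratum, config)
    out$stratum <- stratum
    out
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}
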