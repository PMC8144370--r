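#' Compute the eta spatial coordinate per sample
#'
#' For each sample, X is the summed normalized expression of the crypt
#' landmark genes and Y of the tip landmark genes; the unit-less crypt-villus
#' coordinate is eta = Y / (X + Y), 0 at a pure-crypt signal and 1 at a
#' pure-tip signal. eta is a ratio, so it is invariant to rescaling a
#' sample's expression vector. Samples with X + Y = 0 have no defined
#' coordinate and are excluded with a warning.
#'
#' @param samples a [norm_matrix()]: internally normalized clumps (over the
#'   secretory-specific genes) or total-normalized single cells
#' @param landmarks a [landmark_set()] with non-empty crypt and tip lists
#' @return data.frame: `sample_id`, `X`, `Y`, `eta`
#' @export
compute_eta <- function(samples, landmarks) {
  if (length(landmarks$crypt) == 0L || length(landmarks$tip) == 0L)
    stop("crypt and tip landmark lists must be non-empty")
  vals <- samples$values
  X <- colSums(vals[rownames(vals) %in% landmarks$crypt, , drop = FALSE])
  Y <- colSums(vals[rownames(vals) %in% landmarks$tip, , drop = FALSE])
  ok <- X + Y > 0
  if (any(!ok))
    warning(sum(!ok), " samples with zero landmark expression excluded")
  data.frame(sample_id = colnames(vals)[ok], X = X[ok], Y = Y[ok],
             eta = (Y / (X + Y))[ok], row.names = NULL)
}

#' Enumerate candidate eta zone-limit sets
#'
#' The lowest considered crypt upper bound, eta_min, is the median eta of
#' crypt clumps. The candidate grid eta_vec runs from eta_min to 1 in steps
#' of `d_eta` (1 is always included). Every strictly increasing
#' (`n_zones` - 1)-combination of eta_vec, wrapped with 0 and 1, is a
#' candidate limit set; candidates leaving any zone with fewer than
#' `min_cells` single cells are discarded. Zone bins are half-open
#' [b_i, b_{i+1}), with the last bin closed at 1.
#'
#' @param crypt_clump_etas eta values of clumps assigned to the crypt
#' @param cell_etas eta values of the single cells to be binned
#' @param n_zones desired zones in the reconstruction (>= 2)
#' @param d_eta grid step (goblet 0.05, enteroendocrine/tuft 0.02)
#' @param min_cells minimum single cells per zone (default 10)
#' @return list: `eta_min`, `eta_vec`, `boundaries` (candidates x
#'   (`n_zones` + 1) matrix, rows `(0, b_1, ..., 1)`)
#' @export
enumerate_eta_limits <- function(crypt_clump_etas, cell_etas, n_zones,
                                 d_eta, min_cells = 10L) {
  if (length(crypt_clump_etas) < 1L) stop("no crypt clumps")
  stopifnot(n_zones >= 2)
  eta_min <- stats::median(crypt_clump_etas)
  eta_vec <- seq(eta_min, 1, by = d_eta)
  if (utils::tail(eta_vec, 1L) < 1 - 1e-12) eta_vec <- c(eta_vec, 1)

  inner <- utils::combn(eta_vec, n_zones - 1L)
  cand <- t(rbind(0, inner, 1))
  # wrapping with 1 makes combinations whose top element is already 1
  # degenerate (zero-width last zone); drop non-strictly-increasing rows
  cand <- cand[apply(cand, 1L, function(b) all(diff(b) > 0)), ,
               drop = FALSE]
  counts <- apply(cand, 1L, function(b) {
    zone <- zone_of_eta(cell_etas, b)
    min(tabulate(zone, length(b) - 1L))
  })
  keep <- counts >= min_cells
  if (!any(keep)) stop("no candidate eta limits leave every zone with >= ",
                       min_cells, " cells")
  boundaries <- cand[keep, , drop = FALSE]
  attr(boundaries, "n_total") <- choose(length(eta_vec), n_zones - 1L)
  list(eta_min = eta_min, eta_vec = eta_vec, boundaries = boundaries)
}

#' Zone index of eta values given zone boundaries
#'
#' Bins are half-open `[b_i, b_{i+1})`; the last bin is closed at 1, and an
#' eta below the first inner boundary falls in zone 1.
#' @param eta numeric vector in \[0, 1\]
#' @param boundaries increasing vector `(0, b_1, ..., 1)`
#' @return integer zone per eta
#' @export
zone_of_eta <- function(eta, boundaries) {
  n_zones <- length(boundaries) - 1L
  pmin(findInterval(eta, boundaries), n_zones)
}

#' Select optimal eta limits by matching clump zonation profiles
#'
#' For each candidate limit set the single cells are binned and averaged per
#' zone; for every comparison gene the Euclidean distance between the
#' max-normalized single-cell profile and the max-normalized clump profile
#' (coarse-grained to the same zone count) is computed, and the median over
#' genes, Med_Euc, scores the candidate. The candidate with the smallest
#' Med_Euc wins; ties go to the first candidate in enumeration order.
#'
#' @param candidates the `boundaries` matrix from [enumerate_eta_limits()]
#' @param cells a [norm_matrix()] of the secretory single cells
#' @param cell_etas named eta per cell (from [compute_eta()])
#' @param clump_profile genes x zones matrix of the type's clump zonation
#'   means at the target zone count
#' @param genes comparison genes (secretory-specific, above the expression
#'   floor)
#' @return list: `boundaries` (optimal set), `med_euc`, `per_candidate`
#' @export
optimize_eta_limits <- function(candidates, cells, cell_etas,
                                clump_profile, genes) {
  genes <- intersect(genes, rownames(cells$values))
  genes <- intersect(genes, rownames(clump_profile))
  if (length(genes) == 0L) stop("no genes available for profile comparison")
  vals <- cells$values[genes, names(cell_etas), drop = FALSE]
  ref <- max_normalize_rows(clump_profile[genes, , drop = FALSE])
  n_zones <- ncol(candidates) - 1L
  # cells sorted by eta occupy each zone contiguously, so per-zone means
  # are differences of cumulative sums: O(genes x zones) per candidate
  ord <- order(cell_etas)
  eta_s <- cell_etas[ord]
  cs <- cbind(0, t(apply(vals[, ord, drop = FALSE], 1L, cumsum)))
  scores <- apply(candidates, 1L, function(b) {
    nz <- tabulate(zone_of_eta(eta_s, b), n_zones)
    idx <- cumsum(c(0L, nz)) + 1L
    zmeans <- cs[, idx[-1L], drop = FALSE] - cs[, idx[-length(idx)],
                                                drop = FALSE]
    zmeans <- sweep(zmeans, 2L, pmax(nz, 1L), "/")
    zmeans <- max_normalize_rows(zmeans)
    stats::median(sqrt(rowSums((zmeans - ref)^2)))
  })
  best <- which.min(scores)
  list(boundaries = candidates[best, ], med_euc = scores[best],
       per_candidate = scores)
}

#' Reconstruct a zonation table from single cells and eta limits
#'
#' Cells are binned into zones by eta and genome-wide means, SEMs,
#' expressing-cell counts, Kruskal-Wallis p and BH q are computed as in
#' [compute_zonation_table()], with the 5e-6 expression threshold both as
#' testing floor and expressing-cell definition.
#'
#' @param cells a [norm_matrix()] of the secretory single cells
#'   (total-normalized)
#' @param cell_etas named eta per cell
#' @param boundaries optimal limit set `(0, b_1, ..., 1)`
#' @param config a [clumpseq_config()]
#' @return a [zonation_table()]
#' @export
reconstruct_zonation <- function(cells, cell_etas, boundaries, config) {
  thr <- config$reconstruction$expression_threshold
  vals <- cells$values[, names(cell_etas), drop = FALSE]
  zone <- zone_of_eta(cell_etas, boundaries)
  compute_zonation_table(vals, zone, test_floor = thr,
                         expr_threshold = thr,
                         n_zones = length(boundaries) - 1L)
}

#' Merge two zonation tables reconstructed from independent datasets
#'
#' Genes expressed in only one dataset keep that dataset's profile. Genes
#' expressed in both need a mutual zone: a zone where both datasets have at
#' least `mutual_zone_min_cells` expressing cells; without one the gene is
#' excluded. With several mutual zones, the zone with the most similar
#' expressing-cell counts is used (ties to the lowest zone). Both profiles
#' are scaled by their mutual-zone value, averaged per zone with
#' expressing-cell-count weights, re-normalized to maximum 1 and rescaled by
#' the larger of the two tables' maxima. The merged p-value per gene is the
#' smaller of the two; q is BH over the merged gene set.
#'
#' @param table_a,table_b [zonation_table()]s with identical zone counts
#' @param config a [clumpseq_config()]
#' @return a [zonation_table()] over the union of retained genes
#' @export
merge_zonation_tables <- function(table_a, table_b, config) {
  if (ncol(table_a$mean) != ncol(table_b$mean))
    stop("zone counts differ between tables")
  min_cells <- config$reconstruction$mutual_zone_min_cells
  genes <- union(table_a$gene_ids, table_b$gene_ids)
  nz <- ncol(table_a$mean)

  get_row <- function(tab, g, what)
    if (g %in% tab$gene_ids) tab[[what]][g, ] else NULL

  rows <- lapply(genes, function(g) {
    na <- get_row(table_a, g, "n_expressing")
    nb <- get_row(table_b, g, "n_expressing")
    in_a <- !is.null(na) && any(na > 0)
    in_b <- !is.null(nb) && any(nb > 0)
    if (!in_a && !in_b) return(NULL)
    if (in_a && !in_b)
      return(list(mean = table_a$mean[g, ], sem = table_a$sem[g, ],
                  n = na, p = table_a$p[[g]]))
    if (in_b && !in_a)
      return(list(mean = table_b$mean[g, ], sem = table_b$sem[g, ],
                  n = nb, p = table_b$p[[g]]))
    mutual <- which(na >= min_cells & nb >= min_cells)
    if (length(mutual) == 0L) return(NULL)  # expressed in both, no overlap
    mz <- mutual[which.min(abs(na[mutual] - nb[mutual]))]
    ma <- table_a$mean[g, ]; mb <- table_b$mean[g, ]
    if (ma[mz] == 0 || mb[mz] == 0) return(NULL)
    sa <- ma / ma[mz]; sb <- mb / mb[mz]
    w <- na + nb
    avg <- ifelse(w > 0, (sa * na + sb * nb) / pmax(w, 1), 0)
    scale_back <- max(ma, mb)
    prof <- if (max(avg) > 0) avg / max(avg) * scale_back else avg
    sem_scaled <- ifelse(w > 0,
                         (table_a$sem[g, ] / ma[mz] * na +
                            table_b$sem[g, ] / mb[mz] * nb) / pmax(w, 1), 0)
    sem_out <- if (max(avg) > 0) sem_scaled / max(avg) * scale_back
               else sem_scaled
    pab <- c(table_a$p[[g]], table_b$p[[g]])
    list(mean = prof, sem = sem_out, n = na + nb,
         p = if (all(is.na(pab))) NA_real_ else min(pab, na.rm = TRUE))
  })
  keep <- !vapply(rows, is.null, logical(1))
  rows <- rows[keep]; genes <- genes[keep]
  pull <- function(what) {
    m <- t(vapply(rows, function(r) as.numeric(r[[what]]), numeric(nz)))
    dimnames(m) <- list(genes, table_a$zone_labels)
    m
  }
  p <- vapply(rows, function(r) {
    v <- r$p
    if (is.null(v) || is.infinite(v)) NA_real_ else v
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  names(p) <- names(q) <- genes
  sizes <- pmax(table_a$group_sizes, 0) + pmax(table_b$group_sizes, 0)
  zonation_table(pull("mean"), pull("sem"), pull("n"), p, q, sizes)
}

#' Temporal expression profile over equal-count bins
#'
#' Cells are sorted by time stamp (ties broken by sample id) and split into
#' `n_bins` bins of equal count, any remainder going to the earliest bins;
#' per-gene bin means, Kruskal-Wallis p across bins and BH q are computed.
#'
#' @param cells a [norm_matrix()] of single cells
#' @param time_stamps named numeric vector (arbitrary real units)
#' @param n_bins number of temporal bins (default 7)
#' @return a [zonation_table()] whose "zones" are temporal bins
#' @export
temporal_profile <- function(cells, time_stamps, n_bins = 7L) {
  vals <- cells$values
  ts <- time_stamps[colnames(vals)]
  if (anyNA(ts)) stop("every cell needs a time stamp")
  n <- ncol(vals)
  if (n < n_bins) stop("fewer cells than temporal bins")
  ord <- order(ts, colnames(vals))
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin <- rep(seq_len(n_bins), sizes)
  zones <- integer(n)
  zones[ord] <- bin
  compute_zonation_table(vals, zones, test_floor = 0, expr_threshold = 0,
                         n_zones = n_bins)
}
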