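#' Build the population mean-expression / fraction-expressing table
#'
#' Per gene and population the mean normalized expression across that
#' population's cells and the fraction of its cells expressing the gene
#' (value > 0). Enterocytes form one population per villus zone
#' (`enterocyte_zone<z>`), because their expression is strongly zonated;
#' each secretory type is a single population.
#'
#' @param cells a [norm_matrix()] of total-normalized single cells
#' @param labels named character vector: cell type per well id
#' @param enterocyte_zones named integer vector: zone per enterocyte well id
#' @return a `specificity_table`: list with `mean_expr` and `frac_expr`
#'   (genes x populations matrices) and `populations` metadata
#' @export
build_specificity_table <- function(cells, labels, enterocyte_zones) {
  vals <- cells$values
  labels <- labels[colnames(vals)]
  if (anyNA(labels)) stop("every cell must be labeled")
  pop <- labels
  ent <- labels == "enterocyte"
  if (any(ent)) {
    z <- enterocyte_zones[colnames(vals)[ent]]
    if (anyNA(z)) stop("every enterocyte must be zone-labeled")
    pop[ent] <- paste0("enterocyte_zone", z)
  }
  pops <- sort(unique(pop))
  mean_expr <- vapply(pops, function(p)
    rowMeans(vals[, pop == p, drop = FALSE]), numeric(nrow(vals)))
  frac_expr <- vapply(pops, function(p)
    rowMeans(vals[, pop == p, drop = FALSE] > 0), numeric(nrow(vals)))
  dn <- list(rownames(vals), pops)
  structure(list(
    mean_expr = matrix(mean_expr, ncol = length(pops), dimnames = dn),
    frac_expr = matrix(frac_expr, ncol = length(pops), dimnames = dn),
    populations = data.frame(
      population = pops,
      cell_type = ifelse(grepl("^enterocyte_zone", pops), "enterocyte", pops),
      n_cells = as.integer(table(pop)[pops])
    )
  ), class = "specificity_table")
}

enterocyte_cols <- function(table)
  grep("^enterocyte_zone", colnames(table$mean_expr), value = TRUE)

#' Select genes specific to one cell type
#'
#' A gene is target-specific when its maximal mean expression over the
#' target's population(s) strictly exceeds `fold` times the maximal mean
#' over all complementary populations, and it is expressed in at least
#' `min_frac` of the cells of the population achieving that maximum.
#' For `target = "enterocyte"` the target populations are the per-zone
#' enterocyte columns and the complement is every secretory type; for a
#' secretory target the complement is the enterocyte zone columns.
#'
#' @param table a [build_specificity_table()] result
#' @param target `"enterocyte"` or a secretory type name
#' @param fold strict fold-change requirement (> 1)
#' @param min_frac minimum fraction expressing in the maximal population
#' @return character vector of gene symbols
#' @export
select_type_specific_genes <- function(table, target, fold, min_frac) {
  stopifnot(fold > 1, min_frac > 0, min_frac < 1)
  ent <- enterocyte_cols(table)
  sec <- setdiff(colnames(table$mean_expr), ent)
  if (target == "enterocyte") {
    tgt <- ent; cmp <- sec
  } else {
    if (!target %in% sec) stop("unknown target: ", target)
    tgt <- target; cmp <- ent
  }
  tm <- table$mean_expr[, tgt, drop = FALSE]
  best <- max.col(tm, ties.method = "first")
  tmax <- tm[cbind(seq_len(nrow(tm)), best)]
  cmax <- apply(table$mean_expr[, cmp, drop = FALSE], 1L, max)
  frac_at_best <- table$frac_expr[, tgt, drop = FALSE][
    cbind(seq_len(nrow(tm)), best)]
  keep <- tmax > fold * cmax & frac_at_best >= min_frac
  rownames(table$mean_expr)[keep]
}

#' Select cell-type classification markers for a secretory type
#'
#' Markers must have mean normalized expression above
#' `specificity.marker_min_mean` in the type, be expressed in more than
#' `specificity.marker_min_frac` of its cells, and exceed
#' `specificity.marker_fold` times the maximal mean expression in every
#' other epithelial population (the specificity ratio). Genes are ordered by
#' specificity ratio (descending) and up to
#' `specificity.marker_max_genes` are returned.
#'
#' @param table a [build_specificity_table()] result covering all epithelial
#'   types
#' @param type secretory type name (a column of the table)
#' @param config a [clumpseq_config()]
#' @return character vector of marker gene symbols (<= 50 by default)
#' @export
select_classification_markers <- function(table, type, config) {
  sp <- config$specificity
  if (!type %in% colnames(table$mean_expr)) stop("unknown type: ", type)
  others <- setdiff(colnames(table$mean_expr), type)
  m <- table$mean_expr[, type]
  f <- table$frac_expr[, type]
  omax <- apply(table$mean_expr[, others, drop = FALSE], 1L, max)
  ratio <- ifelse(omax > 0, m / omax, ifelse(m > 0, Inf, 0))
  keep <- m > sp$marker_min_mean & f > sp$marker_min_frac &
    ratio > sp$marker_fold
  if (!any(keep))
    stop("no classification markers pass the filters for type: ", type)
  genes <- names(m)[keep][order(ratio[keep], decreasing = TRUE)]
  utils::head(genes, sp$marker_max_genes)
}

#' Select enterocyte landmark genes from the spatial reference
#'
#' Candidate landmarks must be (1) abundant: mean normalized expression
#' across reference zones of at least `landmark_min_abundance`; (2)
#' enterocyte-specific: mean expression in some enterocyte zone population
#' strictly above `landmark_fold` times the maximal secretory mean, expressed
#' in at least `enterocyte_min_frac` of that population; (3) zonated:
#' (max - min) / max across zones of at least `landmark_min_dynamic_range`.
#' Candidates are max-normalized and ranked by Euclidean distance to three
#' scale-free ideal profiles (1 at the crypt / at mid-villus / at the tip and
#' 0 elsewhere); each list takes the `landmarks_per_profile` nearest genes,
#' and a gene ranked in several lists is kept only in the list whose ideal
#' profile is nearest.
#'
#' @param reference a [spatial_reference()] (zone 1 = crypt)
#' @param table a [build_specificity_table()] result
#' @param config a [clumpseq_config()]
#' @param mid_zone zone index of the ideal mid-villus peak; defaults to the
#'   middle zone, which for a 7-zone crypt/V1-V6 reference is V3
#' @return a [landmark_set()] with crypt, mid and tip lists
#' @export
select_enterocyte_landmarks <- function(reference, table, config,
                                        mid_zone = NULL) {
  sp <- config$specificity
  vals <- reference$values
  n <- ncol(vals)
  mid_zone <- mid_zone %||% ((n + 1) %/% 2)

  abundant <- rowMeans(vals) >= sp$landmark_min_abundance
  ent <- enterocyte_cols(table)
  sec <- setdiff(colnames(table$mean_expr), ent)
  common <- intersect(rownames(vals), rownames(table$mean_expr))
  em <- table$mean_expr[common, ent, drop = FALSE]
  best <- max.col(em, ties.method = "first")
  emax <- em[cbind(seq_along(common), best)]
  smax <- apply(table$mean_expr[common, sec, drop = FALSE], 1L, max)
  fbest <- table$frac_expr[common, ent, drop = FALSE][
    cbind(seq_along(common), best)]
  specific <- stats::setNames(
    emax > sp$landmark_fold * smax & fbest >= sp$enterocyte_min_frac, common)

  mx <- apply(vals, 1L, max)
  mn <- apply(vals, 1L, min)
  zonated <- mx > 0 & (mx - mn) / pmax(mx, .Machine$double.xmin) >=
    sp$landmark_min_dynamic_range

  cand <- rownames(vals)[abundant & zonated &
                           rownames(vals) %in% common[specific[common]]]
  if (length(cand) < 1L) stop("no candidate landmark genes")

  prof <- max_normalize_rows(vals[cand, , drop = FALSE])
  ideal <- function(peak) { v <- numeric(n); v[peak] <- 1; v }
  ideals <- rbind(crypt = ideal(1L), mid = ideal(mid_zone), tip = ideal(n))
  dist_to <- apply(ideals, 1L, function(id)
    sqrt(rowSums(sweep(prof, 2L, id)^2)))
  if (length(cand) == 1L)
    dist_to <- matrix(dist_to, nrow = 1,
                      dimnames = list(cand, rownames(ideals)))

  k <- sp$landmarks_per_profile
  lists <- lapply(colnames(dist_to), function(nm)
    cand[order(dist_to[, nm])][seq_len(min(k, length(cand)))])
  names(lists) <- colnames(dist_to)
  # overlapping genes stay only in the list whose ideal profile is nearest
  all_genes <- unique(unlist(lists))
  nearest <- colnames(dist_to)[max.col(-dist_to[all_genes, , drop = FALSE],
                                       ties.method = "first")]
  names(nearest) <- all_genes
  for (nm in names(lists))
    lists[[nm]] <- lists[[nm]][nearest[lists[[nm]]] == nm]
  landmark_set("enterocyte", crypt = lists$crypt, tip = lists$tip,
               mid = lists$mid)
}
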