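#' Benchmark clump zone assignment against simulated ground truth
#'
#' Simulates a tissue, runs preprocessing and landmark-based zone
#' assignment, and scores the fraction of non-discarded clumps assigned
#' within one zone of their generating zone.
#'
#' @param seed integer seed
#' @param config a [clumpseq_config()]
#' @param n_clumps,n_cells dataset sizes
#' @return list: `rate` (fraction within +/- 1 zone), `exact`, `n`
#' @export
benchmark_zone_recovery <- function(seed, config = clumpseq_config(),
                                    n_clumps = 500L, n_cells = 500L) {
  sim <- simulate_clumpseq(config, seed = seed, n_cells = n_cells,
                           n_clumps = n_clumps, n_secretory_cells = 0L)
  prep <- prepare_pipeline(sim, config)
  zonation <- run_clump_zonation(prep)
  asg <- zonation$assignment
  truth <- stats::setNames(sim$clump_truth$zone, sim$clump_truth$well_id)
  ok <- !asg$discarded
  err <- abs(asg$zone[ok] - truth[asg$clump_id[ok]])
  list(rate = mean(err <= 1), exact = mean(err == 0), n = sum(ok))
}

#' Benchmark the geometric secretory classifier
#'
#' Simulates clumps, classifies their secretory content and scores
#' precision of secretory calls (the called type is truly contained) and
#' specificity for enterocyte-only clumps (truly secretory-free clumps
#' called enterocyte).
#'
#' @inheritParams benchmark_zone_recovery
#' @return list: `precision`, `specificity`, `n_secretory_calls`, `n`
#' @export
benchmark_classification <- function(seed, config = clumpseq_config(),
                                     n_clumps = 6000L, n_cells = 600L) {
  sim <- simulate_clumpseq(config, seed = seed, n_cells = n_cells,
                           n_clumps = n_clumps, n_secretory_cells = 0L)
  prep <- prepare_pipeline(sim, config)
  zonation <- run_clump_zonation(prep)
  zones <- stats::setNames(zonation$assignment$zone,
                           zonation$assignment$clump_id)
  calls <- run_clump_classification(prep, zones)
  ct <- sim$clump_truth
  rownames(ct) <- ct$well_id
  sec <- calls$call != "enterocyte"
  precision <- mean(mapply(function(id, ty)
    ct[id, paste0("contains_", ty)],
    calls$clump_id[sec], calls$call[sec]))
  ent_only <- rowSums(ct[, paste0("contains_",
                                  c("goblet", "enteroendocrine", "tuft",
                                    "paneth"))]) == 0
  specificity <- mean(calls$call[ent_only[calls$clump_id]] == "enterocyte")
  list(precision = precision, specificity = specificity,
       n_secretory_calls = sum(sec), n = nrow(calls))
}

#' Benchmark eta-limit recovery on a 5-zone goblet world
#'
#' Derives goblet landmarks from a 7-zone clump experiment, then builds a
#' matched 5-zone world (clump reference and a marker-typed goblet sort),
#' runs the eta-limit grid optimization and measures each selected
#' boundary's distance to the generating separation interval (the eta gap
#' between adjacent true zones; over an empty gap every split is
#' equivalent).
#'
#' @inheritParams benchmark_zone_recovery
#' @return list: `max_offset` (largest boundary distance), `d_eta`,
#'   `recovered` (max_offset within one grid step), `misassigned`
#'   (fraction of cells binned outside their generating zone), `n_cells`
#' @export
benchmark_boundary_recovery <- function(seed, config = clumpseq_config()) {
  sim <- simulate_clumpseq(config, seed = seed, n_cells = 600L,
                           n_clumps = 500L, n_secretory_cells = 0L)
  prep <- prepare_pipeline(sim, config)
  sp <- config$specificity
  zonation <- run_clump_zonation(prep)
  zones <- stats::setNames(zonation$assignment$zone,
                           zonation$assignment$clump_id)
  sec_genes <- select_type_specific_genes(prep$spec_table, "goblet",
                                          sp$secretory_fold,
                                          sp$secretory_min_frac)
  ct <- sim$clump_truth
  gob_ids <- intersect(
    ct$well_id[ct$contains_goblet],
    zonation$assignment$clump_id[!zonation$assignment$discarded])
  gi <- suppressWarnings(internal_normalize(
    prep$clumps$norm$values[, gob_ids, drop = FALSE], sec_genes))
  tab7 <- compute_zonation_table(gi, zones[colnames(gi$values)],
                                 test_floor =
                                   config$clump$zonation_test_floor,
                                 n_zones = sim$reference$n_zones)
  cutoffs <- config$clump$com_cutoffs$goblet
  lm <- select_secretory_landmarks(tab7, sec_genes, cutoffs[["crypt"]],
                                   cutoffs[["tip"]], config, "goblet")

  truth5 <- coarse_truth(sim$truth, 5L)
  cl5 <- generate_clumps(truth5, 3000L, config, seed = seed + 20L)
  cells5 <- generate_cells(truth5, 500L, config, seed = seed + 10L,
                           proportions = c(enterocyte = 0.05,
                                           goblet = 0.60,
                                           enteroendocrine = 0.15,
                                           tuft = 0.15, paneth = 0.05),
                           label = "gob5")
  ppc <- preprocess_counts(cl5$counts, "clump", config,
                           sim$truth$mito_genes)
  ref5 <- coarse_grain_reference(sim$reference, 5L)
  lms5 <- select_enterocyte_landmarks(ref5, prep$spec_table, config)
  ent_specific <- select_type_specific_genes(prep$spec_table, "enterocyte",
                                             sp$enterocyte_fold,
                                             sp$enterocyte_min_frac)
  ci5 <- suppressWarnings(internal_normalize(ppc$norm, ent_specific))
  asg5 <- assign_clump_zones(ci5, ref5, lms5, config)
  z5 <- stats::setNames(asg5$zone, asg5$clump_id)
  gob5 <- intersect(
    cl5$clump_truth$well_id[cl5$clump_truth$contains_goblet],
    asg5$clump_id[!asg5$discarded])
  gi5 <- suppressWarnings(internal_normalize(
    ppc$norm$values[, gob5, drop = FALSE], sec_genes))
  gz5 <- z5[colnames(gi5$values)]
  tab5 <- compute_zonation_table(gi5, gz5, test_floor = Inf, n_zones = 5L)
  clump_eta <- compute_eta(gi5, lm)
  crypt_etas <- clump_eta$eta[gz5[clump_eta$sample_id] == 1L]

  pp <- preprocess_counts(cells5$counts, "single_cell", config,
                          sim$truth$mito_genes)
  lab5 <- classify_cells_by_markers(pp$norm, sim$truth$markers)
  gcells <- names(lab5)[lab5 == "goblet"]
  cells_gob <- norm_matrix(pp$norm$values[, gcells, drop = FALSE], "total")
  eta_df <- compute_eta(cells_gob, lm)
  etas <- stats::setNames(eta_df$eta, eta_df$sample_id)
  tz <- stats::setNames(cells5$cell_truth$zone,
                        cells5$cell_truth$well_id)[names(etas)]

  true_b <- vapply(1:4, function(z) {
    a <- sort(etas[tz == z]); b <- sort(etas[tz == z + 1])
    cand <- sort(unique(c(a, b)))
    miss <- vapply(cand, function(th) sum(a >= th) + sum(b < th),
                   numeric(1))
    cand[which.min(miss)]
  }, numeric(1))
  iv <- t(vapply(1:4, function(z) {
    a <- etas[tz <= z]; b <- etas[tz >= z + 1]
    th <- true_b[z]
    c(suppressWarnings(max(a[a < th], -Inf)),
      suppressWarnings(min(b[b >= th], Inf)))
  }, numeric(2)))

  d_eta <- config$reconstruction$d_eta$goblet
  grid <- enumerate_eta_limits(crypt_etas, etas, 5L, d_eta,
                               config$reconstruction$min_cells_per_zone)
  cmp <- rownames(tab5$mean)[apply(tab5$mean, 1L, max) >
                               config$reconstruction$expression_threshold]
  ci <- suppressWarnings(internal_normalize(cells_gob$values, sec_genes))
  etas_i <- etas[intersect(names(etas), colnames(ci$values))]
  opt <- optimize_eta_limits(grid$boundaries, ci, etas_i, tab5$mean, cmp)
  off <- vapply(1:4, function(z) {
    b <- opt$boundaries[z + 1]
    if (b >= iv[z, 1] && b <= iv[z, 2]) 0 else min(abs(b - iv[z, ]))
  }, numeric(1))
  mis <- mean(zone_of_eta(etas, opt$boundaries) != tz)
  list(max_offset = max(off), d_eta = d_eta,
       recovered = max(off) <= d_eta + 1e-9, misassigned = mis,
       n_cells = length(etas))
}

#' Benchmark genome-wide goblet zonation recovery
#'
#' Runs the full goblet reconstruction (clump zonation, secretory
#' landmarks, eta optimization, reconstruction) and correlates the
#' reconstructed per-gene centers of mass with the generating profiles'
#' COMs over genes with at least `min_dynamic_range`-fold true spatial
#' dynamic range.
#'
#' @inheritParams benchmark_zone_recovery
#' @param min_dynamic_range true max/min fold defining the scored gene set
#' @return list: `spearman`, `n_genes`
#' @export
benchmark_reconstruction <- function(seed, config = clumpseq_config(),
                                     n_clumps = 500L,
                                     min_dynamic_range = 2) {
  sim <- simulate_clumpseq(config, seed = seed, n_cells = 600L,
                           n_clumps = n_clumps, n_secretory_cells = 500L)
  prep <- prepare_pipeline(sim, config)
  ct <- sim$clump_truth
  runner <- make_goblet_runner(prep, ct$well_id[ct$contains_goblet])
  tab <- runner(config)
  tru5 <- coarse_grain_reference(
    spatial_reference(sim$truth$profiles$goblet), 5L)
  dynr <- apply(tru5$values, 1L, max) /
    pmax(apply(tru5$values, 1L, min), 1e-12)
  genes <- intersect(rownames(tru5$values)[dynr >= min_dynamic_range],
                     tab$gene_ids)
  com_t <- center_of_mass(tru5$values[genes, , drop = FALSE])
  com_r <- center_of_mass(tab$mean[genes, , drop = FALSE])
  ok <- !is.na(com_t) & !is.na(com_r)
  list(spearman = stats::cor(com_t[ok], com_r[ok], method = "spearman"),
       n_genes = sum(ok))
}
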