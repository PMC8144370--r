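#' Coarse-grain a spatial reference to fewer zones
#'
#' Per gene, the zone profile is linearly interpolated at `n_zones` equally
#' spaced positions spanning the original zone range; monotone profiles
#' stay monotone.
#'
#' @param reference a [spatial_reference()]
#' @param n_zones target zone count (2..N)
#' @return a [spatial_reference()] with `n_zones` zones
#' @export
coarse_grain_reference <- function(reference, n_zones) {
  n <- reference$n_zones
  if (n_zones < 2) stop("n_zones must be at least 2")
  if (n_zones > n) stop("cannot refine a reference (n_zones > N)")
  if (n_zones == n) return(reference)
  xout <- seq(1, n, length.out = n_zones)
  vals <- t(apply(reference$values, 1L, function(y)
    stats::approx(seq_len(n), y, xout = xout)$y))
  colnames(vals) <- paste0("zone", seq_len(n_zones))
  spatial_reference(vals)
}

#' Select held-out genes for validating a single-cell reconstruction
#'
#' Validation genes are secretory-specific genes that were not used as
#' landmarks, are highly expressed (maximal zone mean above
#' `validation.min_expression` in both tables) and have a max-normalized
#' SEM (largest per-zone SEM divided by the profile maximum) below the
#' type's cutoff in both the single-cell and the coarse-grained clump
#' table.
#'
#' @param sc_table,clump_table [zonation_table()]s with the same zone count
#' @param landmarks the [landmark_set()] used for the reconstruction
#' @param secretory_genes the type's specific gene set
#' @param sem_cutoff max-normalized SEM cutoff (goblet 0.4, tuft 0.5)
#' @param config a [clumpseq_config()]
#' @return character vector of validation genes
#' @export
select_validation_genes <- function(sc_table, clump_table, landmarks,
                                    secretory_genes, sem_cutoff, config) {
  if (ncol(sc_table$mean) != ncol(clump_table$mean))
    stop("tables must share a zone count (coarse-grain the clump table)")
  min_expr <- config$validation$min_expression
  genes <- intersect(secretory_genes,
                     intersect(sc_table$gene_ids, clump_table$gene_ids))
  genes <- setdiff(genes, c(landmarks$crypt, landmarks$mid, landmarks$tip))
  ok <- vapply(genes, function(g) {
    for (tab in list(sc_table, clump_table)) {
      mx <- max(tab$mean[g, ])
      if (mx <= min_expr) return(FALSE)
      if (max(tab$sem[g, ]) / mx >= sem_cutoff) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- genes[ok]
  if (length(out) == 0L)
    stop("no validation genes pass; consider relaxing the expression or ",
         "SEM thresholds")
  out
}

#' Validate a reconstruction by COM rank correlation against clumps
#'
#' Spearman rank correlation between the per-gene centers of mass of the
#' single-cell and clump-based zonation tables over the validation genes.
#'
#' @param sc_table,clump_table [zonation_table()]s with the same zone count
#' @param genes validation genes (>= 3)
#' @return list: `R` (Spearman rho), `p`, `n_genes`, `com_sc`, `com_clump`
#' @export
validate_reconstruction <- function(sc_table, clump_table, genes) {
  if (length(genes) < 3L) stop("need at least 3 validation genes")
  com_sc <- center_of_mass(sc_table$mean[genes, , drop = FALSE])
  com_cl <- center_of_mass(clump_table$mean[genes, , drop = FALSE])
  if (length(unique(com_sc)) < 2L || length(unique(com_cl)) < 2L)
    stop("constant COM vector; correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(com_sc, com_cl, method = "spearman", exact = FALSE))
  list(R = unname(ct$estimate), p = ct$p.value, n_genes = length(genes),
       com_sc = com_sc, com_clump = com_cl)
}

#' Parameter-perturbation robustness sweep
#'
#' Reruns a reconstruction at linearly spaced perturbations of one
#' registered config parameter over `robustness.fold_range` (default
#' 0.5-1.5 times the default value, ~75 values; integer parameters are
#' rounded and deduplicated). Each perturbed zonation table is compared to
#' the unperturbed one by the Spearman correlation P of per-gene COMs over
#' genes expressed above 5e-6 in the baseline. The P curve (ordered by
#' fold value) is smoothed with a window-10 moving median, after which the
#' exact point P = 1 at zero perturbation is reinserted. Perturbed values
#' whose reconstruction fails (e.g. no landmark genes pass) are recorded as
#' NA, not zero.
#'
#' @param run_fn function(config) returning a [zonation_table()]
#' @param config baseline [clumpseq_config()]
#' @param parameter a name from [clumpseq_param_registry()]
#' @param n_values grid size override (default `robustness.n_values`)
#' @return data.frame: `fold`, `value`, `P`, `P_smooth`
#' @export
robustness_sweep <- function(run_fn, config, parameter, n_values = NULL) {
  registry <- clumpseq_param_registry()
  if (!parameter %in% names(registry))
    stop("unregistered parameter: ", parameter)
  key <- registry[[parameter]]
  default <- cfg_get(config, key)
  n_values <- n_values %||% config$robustness$n_values
  folds <- seq(config$robustness$fold_range[1],
               config$robustness$fold_range[2], length.out = n_values)
  values <- folds * default
  if (is_integer_param(parameter)) {
    values <- unique(round(values))
    folds <- values / default
  }

  baseline <- run_fn(config)
  base_com <- center_of_mass(baseline$mean)
  expressed <- apply(baseline$mean, 1L, max) > 5e-6 & !is.na(base_com)

  P <- vapply(values, function(v) {
    tab <- tryCatch(run_fn(cfg_set(config, key, v)),
                    error = function(e) NULL)
    if (is.null(tab)) return(NA_real_)
    common <- intersect(names(base_com)[expressed], tab$gene_ids)
    if (length(common) < 3L) return(NA_real_)
    pert_com <- center_of_mass(tab$mean[common, , drop = FALSE])
    suppressWarnings(stats::cor(base_com[common], pert_com,
                                method = "spearman",
                                use = "complete.obs"))
  }, numeric(1))

  ord <- order(folds)
  sm <- rep(NA_real_, length(P))
  ok <- !is.na(P[ord])
  sm[ord][ok] <- moving_median(P[ord][ok],
                               k = config$robustness$median_window)
  smooth <- sm
  smooth[ord] <- sm[ord]
  # reinsert the exact zero-perturbation point
  at_zero <- which(abs(folds - 1) < 1e-12)
  if (length(at_zero)) smooth[at_zero] <- 1
  data.frame(fold = folds, value = values, P = P, P_smooth = smooth)
}
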