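#' Default pipeline configuration
#'
#' Every numeric parameter of the pipeline with its default, grouped by stage.
#' All values are overridable, either programmatically with [cfg_set()] or by
#' loading a YAML file with [read_config()]. Units: expression values are
#' fractions of a sample's total (or subset) UMIs; zones are 1-based with zone
#' 1 the crypt.
#'
#' Groups:
#' \describe{
#'   \item{qc}{UMI/gene/mitochondrial retention bounds for clumps and single
#'     cells (clumps: >500 UMIs, >=200 genes, <=30\% mito; cells: UMIs in
#'     (200, 7000), genes in (150, 1500), <=40\% mito).}
#'   \item{specificity}{fold-change and fraction-expressing thresholds for
#'     type-specific genes (3x / 10\% enterocyte, 3x / 1\% secretory),
#'     classification markers (4x, 15\%, mean > 1e-4, up to 50 genes) and
#'     enterocyte landmarks (10x, abundance 5e-4, dynamic range 0.7, 30 genes
#'     per ideal profile).}
#'   \item{clump}{zone-assignment parameters: 2\% low-landmark discard,
#'     Pearson correlation, 5e-6 zonation-testing floor, secretory landmark
#'     extraction (max expression >= 5e-5, per-type COM cutoffs, >=2
#'     supporting clumps).}
#'   \item{classification}{ray geometry: 99th-percentile origin distance for
#'     ray fitting, ray-distance Z cutoff -1, quota multipliers 2 (pairs) / 3
#'     (larger clumps), measured secretory proportions per region.}
#'   \item{reconstruction}{per-type zone counts (goblet 5, EEC 4, tuft 4) and
#'     eta grid steps (0.05 / 0.02), >=10 cells per zone, 5e-6 expression
#'     threshold, >=5 mutually expressing cells for merging, 7 temporal bins.}
#'   \item{validation}{validation-gene expression floor 1e-5 and per-type
#'     max-normalized SEM cutoffs (goblet 0.4, tuft 0.5).}
#'   \item{robustness}{75 linearly spaced perturbations over the 0.5-1.5 fold
#'     range, moving-median window 10.}
#'   \item{lr}{ligand-receptor filters: fraction expressing > 0.05,
#'     Z_interaction > 2 (analysis) / > 5 with mean > 2e-5 (export).}
#'   \item{synthetic}{the tissue simulator's study conditions (see the
#'     methods vignette).}
#' }
#'
#' @return a nested named list of class `clumpseq_config`
#' @export
clumpseq_config <- function() {
  cfg <- list(
    qc = list(
      clump_min_umi = 500, clump_min_genes = 200, clump_max_mito = 0.30,
      cell_min_umi = 200, cell_max_umi = 7000,
      cell_min_genes = 150, cell_max_genes = 1500, cell_max_mito = 0.40
    ),
    specificity = list(
      enterocyte_fold = 3, secretory_fold = 3, landmark_fold = 10,
      marker_fold = 4,
      enterocyte_min_frac = 0.10, marker_min_frac = 0.15,
      secretory_min_frac = 0.01,
      landmark_min_abundance = 5e-4, landmark_min_dynamic_range = 0.7,
      landmarks_per_profile = 30, marker_max_genes = 50,
      marker_min_mean = 1e-4
    ),
    clump = list(
      discard_fraction = 0.02,
      correlation_method = "pearson",
      zonation_test_floor = 5e-6,
      secretory_landmark_min_expr = 5e-5,
      min_clumps_expressing = 2,
      com_cutoffs = list(
        goblet = c(crypt = 3, tip = 4.7),
        enteroendocrine = c(crypt = 1.8, tip = 4.2),
        tuft = c(crypt = 1.8, tip = 4.2)
      )
    ),
    classification = list(
      ray_percentile = 99,
      ray_distance_z_cutoff = -1,
      quota_multiplier_pairs = 2,
      quota_multiplier_larger = 3,
      proportions = list(
        crypt  = c(goblet = 0.08, enteroendocrine = 0.01,
                   tuft = 0.01, paneth = 0.04),
        villus = c(goblet = 0.08, enteroendocrine = 0.01,
                   tuft = 0.01, paneth = 0.04)
      )
    ),
    reconstruction = list(
      n_zones = list(goblet = 5, enteroendocrine = 4, tuft = 4),
      d_eta = list(goblet = 0.05, enteroendocrine = 0.02, tuft = 0.02),
      min_cells_per_zone = 10,
      expression_threshold = 5e-6,
      mutual_zone_min_cells = 5,
      temporal_bins = 7
    ),
    validation = list(
      min_expression = 1e-5,
      sem_cutoffs = list(goblet = 0.4, tuft = 0.5)
    ),
    robustness = list(
      n_values = 75, fold_range = c(0.5, 1.5), median_window = 10
    ),
    lr = list(
      min_frac = 0.05, z_analysis = 2, z_export = 5,
      export_min_expr = 2e-5,
      require_positive = TRUE,
      sd_type = "sample"
    ),
    synthetic = list(
      n_genes = 450, n_zones = 7,
      shape_mix = c(flat = 0.4, crypt = 0.25, tip = 0.25, mid = 0.1),
      effect_size_enterocyte = 4, effect_size_secretory = 20,
      markers_per_type = 40, marker_specificity_fold = 10,
      n_mito_genes = 10, mito_fraction = 0.10,
      cell_library_median = 2000, library_sdlog = 0.3,
      secretory_program_sdlog = c(goblet = 1.0, enteroendocrine = 0.5,
                                  tuft = 0.5, paneth = 0.5),
      clump_size_range = c(2, 10), clump_size_decay = 0.6,
      ambient_rate = 5, empty_wells_per_plate = 4, plate_capacity = 384,
      proportions = c(enterocyte = 0.86, goblet = 0.08,
                      enteroendocrine = 0.01, tuft = 0.01, paneth = 0.04)
    )
  )
  class(cfg) <- c("clumpseq_config", "list")
  cfg
}

#' Get a configuration value by dotted path
#' @param config a `clumpseq_config`
#' @param key dotted path, e.g. `"qc.clump_min_umi"`
#' @return the stored value
#' @export
cfg_get <- function(config, key) {
  node <- config
  for (part in strsplit(key, ".", fixed = TRUE)[[1]]) {
    if (!part %in% names(node)) stop("unknown config key: ", key)
    node <- node[[part]]
  }
  node
}

#' Set a configuration value by dotted path
#' @inheritParams cfg_get
#' @param value replacement value
#' @return the modified config
#' @export
cfg_set <- function(config, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, p) call("[[", acc, p), parts, quote(config))
  eval(call("<-", expr, value))
  config
}

#' Read a configuration overlay from YAML
#'
#' Starts from [clumpseq_config()] and overrides any keys present in the file.
#' @param path YAML file
#' @return a `clumpseq_config`
#' @export
read_config <- function(path) {
  overlay <- yaml::read_yaml(path)
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      o <- over[[nm]]
      if (is.list(base[[nm]]) && is.list(o)) {
        base[[nm]] <- merge_into(base[[nm]], o)
      } else if (is.atomic(base[[nm]]) && is.list(o) &&
                 all(lengths(o) == 1L)) {
        # a named numeric vector was serialized as a YAML map
        base[[nm]] <- unlist(o)
      } else {
        base[[nm]] <- o
      }
    }
    base
  }
  cfg <- merge_into(clumpseq_config(), overlay)
  class(cfg) <- c("clumpseq_config", "list")
  cfg
}

#' Write a configuration to YAML
#' @param config a `clumpseq_config`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  # serialize named vectors as maps so their names survive the round trip
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(listify(unclass(config)), path)
  invisible(path)
}

#' Registered robustness-sweep parameters
#'
#' Named character vector mapping sweepable parameter names to config paths.
#' Only registered scalars can be perturbed by [robustness_sweep()].
#' @param integer_only if TRUE, return only the names of integer-valued
#'   parameters
#' @return named character vector of config paths
#' @export
clumpseq_param_registry <- function(integer_only = FALSE) {
  reg <- c(
    secretory_landmark_min_expr = "clump.secretory_landmark_min_expr",
    zonation_test_floor         = "clump.zonation_test_floor",
    discard_fraction            = "clump.discard_fraction",
    landmark_min_abundance      = "specificity.landmark_min_abundance",
    landmark_min_dynamic_range  = "specificity.landmark_min_dynamic_range",
    landmarks_per_profile       = "specificity.landmarks_per_profile",
    min_cells_per_zone          = "reconstruction.min_cells_per_zone",
    min_clumps_expressing       = "clump.min_clumps_expressing"
  )
  ints <- c("landmarks_per_profile", "min_cells_per_zone",
            "min_clumps_expressing")
  if (integer_only) reg[names(reg) %in% ints] else reg
}

#' Is a registered sweep parameter integer-valued?
#' @param parameter registered parameter name
#' @return logical
#' @export
is_integer_param <- function(parameter) {
  parameter %in% names(clumpseq_param_registry(integer_only = TRUE))
}
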