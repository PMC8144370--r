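#' Generate a synthetic crypt-villus expression reference with ground truth
#'
#' Builds expected expression-fraction profiles (genes x zones) for five
#' epithelial cell types (enterocyte, goblet, enteroendocrine, tuft,
#' paneth) over `n_zones` crypt-villus zones (zone 1 = crypt). The gene
#' panel contains enterocyte-specific genes (zonated per the shape mix, used
#' as landmark candidates), designed type-exclusive secretory markers at a
#' configured specificity fold, flat housekeeping genes shared by all types,
#' and a named mitochondrial subset so QC filters are exercisable. Spatial
#' shapes (flat, crypt-decreasing, tip-increasing, mid-peaked) are shared
#' across types for a given gene; amplitudes are type-specific. Profiles are
#' normalized so each (type, zone) expression vector sums to 1.
#'
#' @param config a [clumpseq_config()]; the `synthetic` group holds gene
#'   counts, the shape mix, per-class effect sizes (max/min fold change;
#'   effect size 1 means no zonation) and type proportions
#' @param seed integer RNG seed
#' @return list with `reference` (the enterocyte [spatial_reference()], the
#'   coordinate system clumps are mapped onto) and `truth` (profiles per
#'   type, designed marker/mito gene registry, per-zone type proportions)
#' @export
generate_reference <- function(config = clumpseq_config(), seed = 1L) {
  sy <- config$synthetic
  set.seed(seed)
  if (abs(sum(sy$shape_mix) - 1) > 1e-9)
    stop("shape mix must sum to 1")
  n_zones <- sy$n_zones
  stopifnot(n_zones >= 2, sy$effect_size_enterocyte >= 1,
            sy$effect_size_secretory >= 1)

  types <- c("enterocyte", "goblet", "enteroendocrine", "tuft", "paneth")
  sec_types <- types[-1]
  n_mk <- sy$markers_per_type
  n_mito <- sy$n_mito_genes
  n_ent <- max(30L, round((sy$n_genes - 4L * n_mk - n_mito) * 0.63))
  n_hkg <- sy$n_genes - 4L * n_mk - n_mito - n_ent
  if (n_hkg < 1L) stop("n_genes too small for the configured panel")

  genes <- c(
    sprintf("Ent-%03d", seq_len(n_ent)),
    sprintf("Gob-%03d", seq_len(n_mk)),
    sprintf("Eec-%03d", seq_len(n_mk)),
    sprintf("Tuf-%03d", seq_len(n_mk)),
    sprintf("Pan-%03d", seq_len(n_mk)),
    sprintf("Hkg-%03d", seq_len(n_hkg)),
    sprintf("mt-Mito%02d", seq_len(n_mito))
  )
  markers <- list(
    goblet = grep("^Gob-", genes, value = TRUE),
    enteroendocrine = grep("^Eec-", genes, value = TRUE),
    tuft = grep("^Tuf-", genes, value = TRUE),
    paneth = grep("^Pan-", genes, value = TRUE)
  )
  mito_genes <- grep("^mt-", genes, value = TRUE)
  ent_genes <- grep("^Ent-", genes, value = TRUE)
  hkg_genes <- grep("^Hkg-", genes, value = TRUE)

  # one spatial shape per gene, shared across cell types
  shape_of <- stats::setNames(rep("flat", length(genes)), genes)
  shape_of[ent_genes] <- sample(names(sy$shape_mix), n_ent, replace = TRUE,
                                prob = sy$shape_mix)
  for (ty in sec_types)
    shape_of[markers[[ty]]] <- sample(c("crypt", "tip", "peak", "flat"),
                                      n_mk, replace = TRUE,
                                      prob = c(0.33, 0.33, 0.22, 0.12))
  gamma <- stats::setNames(stats::runif(length(genes), 0.5, 1.5), genes)
  # secretory marker shapes: mild curvature spread, so summed landmark
  # signals decay smoothly along the axis
  gamma[unlist(markers)] <- stats::runif(length(unlist(markers)), 0.8, 1.2)
  # intermediately zonated genes peak at variable positions along the
  # villus; they fail the landmark COM cutoffs and serve validation
  center_of <- stats::setNames(rep((n_zones + 1) / 2, length(genes)),
                               genes)
  is_peak <- shape_of == "peak"
  center_of[is_peak] <- stats::runif(sum(is_peak), 2, n_zones - 1)

  effect_of <- stats::setNames(rep(1, length(genes)), genes)
  effect_of[ent_genes] <- sy$effect_size_enterocyte
  effect_of[unlist(markers)] <- sy$effect_size_secretory

  t_pos <- (seq_len(n_zones) - 1) / (n_zones - 1)
  mid <- (n_zones + 1) / 2
  d_mid <- abs(seq_len(n_zones) - mid) / max(abs(seq_len(n_zones) - mid))
  shape_profile <- function(g) {
    e <- log(effect_of[[g]])
    d_g <- abs(seq_len(n_zones) - center_of[[g]])
    d_g <- d_g / max(d_g)
    switch(shape_of[[g]],
      flat = rep(1, n_zones),
      crypt = exp(-e * t_pos^gamma[[g]]),
      tip = exp(-e * (1 - t_pos)^gamma[[g]]),
      mid = exp(-e * d_mid^gamma[[g]]),
      peak = exp(-e * d_g^gamma[[g]])
    )
  }
  shapes <- t(vapply(genes, shape_profile, numeric(n_zones)))
  rownames(shapes) <- genes

  # per-type amplitude budgets (fractions of the transcriptome); designed
  # markers are absent from enterocytes, and the designed specificity fold
  # is realized against the other secretory types (the closest background)
  fold <- sy$marker_specificity_fold
  own_marker <- 0.25 / n_mk
  foreign_marker <- own_marker / fold
  weights <- function(type) {
    w <- stats::setNames(numeric(length(genes)), genes)
    w[mito_genes] <- sy$mito_fraction / n_mito
    if (type != "enterocyte")
      for (ty in sec_types)
        w[markers[[ty]]] <- if (ty == type) own_marker else foreign_marker
    w[ent_genes] <- if (type == "enterocyte") 0.35 / n_ent
                    else 0.01 / n_ent
    w[hkg_genes] <- (1 - sum(w)) / n_hkg
    w
  }
  profiles <- lapply(stats::setNames(types, types), function(ty) {
    p <- shapes * weights(ty)
    p <- sweep(p, 2L, colSums(p), "/")
    if (ty != "enterocyte") {
      # a secretory cell's marker program occupies a constant share of its
      # transcriptome along the axis (composition within the program is
      # what zonation changes); iterate share-flattening to convergence
      own <- markers[[ty]]
      for (it in 1:4) {
        share <- colSums(p[own, , drop = FALSE])
        p[own, ] <- sweep(p[own, , drop = FALSE], 2L,
                          mean(share) / share, "*")
        p <- sweep(p, 2L, colSums(p), "/")
      }
    }
    p
  })

  prop <- sy$proportions[c("enterocyte", sec_types)]
  type_proportions <- matrix(rep(prop, each = n_zones), nrow = n_zones,
                             dimnames = list(paste0("zone",
                                                    seq_len(n_zones)),
                                             names(prop)))

  list(
    reference = spatial_reference(profiles$enterocyte),
    truth = list(
      profiles = profiles,
      markers = markers,
      mito_genes = mito_genes,
      enterocyte_genes = ent_genes,
      shape_of = shape_of,
      type_proportions = type_proportions,
      n_zones = n_zones
    )
  )
}

# expected expression fractions of one cell, with its secretory program
# intensity scaled by s (bursty marker-program expression; s = 1 for
# enterocytes); the whole lineage marker program scales together, so a
# weak-program cell keeps its own-to-foreign marker ratio; renormalized
# to sum 1
cell_fractions <- function(truth, type, zone, s = 1) {
  p <- truth$profiles[[type]][, zone]
  if (type != "enterocyte" && s != 1) {
    prog <- unlist(truth$markers, use.names = FALSE)
    p[prog] <- p[prog] * s
    p <- p / sum(p)
  }
  p
}

# per-type burstiness of the secretory marker program: goblet cells vary
# widely in mucin program intensity, tuft/enteroendocrine programs are tight
program_intensity <- function(n, type, config) {
  sdlog <- config$synthetic$secretory_program_sdlog
  out <- rep(1, n)
  sec <- type != "enterocyte"
  out[sec] <- stats::rlnorm(sum(sec), 0, sdlog[type[sec]])
  out
}

plate_layout <- function(n_wells, prefix, config) {
  sy <- config$synthetic
  per_plate <- sy$plate_capacity - sy$empty_wells_per_plate
  plate <- rep(seq_len(ceiling(n_wells / per_plate)),
               each = per_plate)[seq_len(n_wells)]
  paste0(prefix, plate)
}

ambient_profile <- function(truth) {
  # ambient RNA mirrors the average tissue transcriptome
  all_prof <- Reduce(`+`, truth$profiles) / length(truth$profiles)
  rowMeans(all_prof)
}

add_empty_wells <- function(counts, meta, truth, config, prefix) {
  sy <- config$synthetic
  if (sy$ambient_rate < 0) stop("ambient_rate must be non-negative")
  plates <- unique(meta$plate_id)
  amb <- ambient_profile(truth) * sy$ambient_rate
  empties <- lapply(plates, function(pl) {
    m <- matrix(stats::rpois(length(amb) * sy$empty_wells_per_plate,
                             rep(amb, sy$empty_wells_per_plate)),
                nrow = length(amb))
    colnames(m) <- paste0(prefix, "_", pl, "_empty",
                          seq_len(sy$empty_wells_per_plate))
    m
  })
  em <- do.call(cbind, empties)
  rownames(em) <- rownames(counts)
  emeta <- data.frame(
    well_id = colnames(em),
    plate_id = rep(plates, each = sy$empty_wells_per_plate),
    well_kind = "empty", n_cells_estimate = NA_integer_,
    time_stamp = NA_real_
  )
  list(counts = cbind(counts, em), meta = rbind(meta, emeta))
}

#' Simulate single epithelial cells
#'
#' Each cell draws a zone (uniform), a cell type (from the per-zone
#' proportions), a log-normal library size (median
#' `synthetic.cell_library_median` UMIs) and UMI counts from a multinomial
#' over its (type, zone) expected expression fractions. Cells carry a
#' migration-time stamp increasing with zone. Four empty wells per
#' 384-well plate draw Poisson ambient counts at `synthetic.ambient_rate`
#' expected total UMIs.
#'
#' @param truth ground truth from [generate_reference()]
#' @param n_cells number of cells
#' @param config a [clumpseq_config()]
#' @param seed integer RNG seed
#' @param proportions optional named cell-type proportion override (uniform
#'   across zones), e.g. a secretory-enriched sort; defaults to the tissue
#'   proportions in `truth`
#' @param label well-id prefix, so several cell datasets can coexist
#' @return list with `counts` (a [count_matrix()] including empty wells)
#'   and `cell_truth` (well id, true zone, true type, library size)
#' @export
generate_cells <- function(truth, n_cells, config = clumpseq_config(),
                           seed = 1L, proportions = NULL, label = "cell") {
  sy <- config$synthetic
  set.seed(seed)
  if (!is.null(proportions)) {
    stopifnot(setequal(names(proportions),
                       colnames(truth$type_proportions)))
    truth$type_proportions[] <- rep(
      proportions[colnames(truth$type_proportions)],
      each = nrow(truth$type_proportions))
  }
  genes <- rownames(truth$profiles[[1]])
  if (n_cells == 0L) {
    counts <- matrix(integer(), nrow = length(genes), ncol = 0,
                     dimnames = list(genes, character()))
    return(list(counts = structure(list(counts = counts,
                                        well_meta = data.frame(
                                          well_id = character(),
                                          plate_id = character(),
                                          well_kind = character())),
                                   class = "count_matrix"),
                cell_truth = data.frame()))
  }
  zones <- sample.int(truth$n_zones, n_cells, replace = TRUE)
  types <- vapply(zones, function(z)
    sample(colnames(truth$type_proportions), 1L,
           prob = truth$type_proportions[z, ]), character(1))
  libs <- pmax(1L, round(stats::rlnorm(n_cells,
                                       log(sy$cell_library_median),
                                       sy$library_sdlog)))
  counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes,
                                   sprintf("%s_%05d", label, seq_len(n_cells))))
  intensity <- program_intensity(n_cells, types, config)
  for (i in seq_len(n_cells)) {
    p <- cell_fractions(truth, types[i], zones[i], intensity[i])
    counts[, i] <- stats::rmultinom(1L, libs[i], p)
  }
  meta <- data.frame(
    well_id = colnames(counts),
    plate_id = plate_layout(n_cells, paste0("plate_", label), config),
    well_kind = "single_cell", n_cells_estimate = 1L,
    time_stamp = zones + stats::runif(n_cells, -0.5, 0.5)
  )
  full <- add_empty_wells(counts, meta, truth, config, label)
  list(
    counts = count_matrix(full$counts, full$meta),
    cell_truth = data.frame(well_id = colnames(counts), zone = zones,
                            type = types, library_size = libs)
  )
}

#' Simulate multi-cell clumps
#'
#' Each clump draws a zone, a size in `synthetic.clump_size_range`
#' (geometrically decaying probabilities: dissociation yields mostly small
#' clumps), member types from the zone's proportions with at least one
#' enterocyte, and per-member library sizes; expected fractions are the
#' library-size-weighted mean of the member type profiles at the shared
#' zone, and one multinomial draw of the summed library produces the
#' counts. Empty wells are added per plate as in [generate_cells()].
#'
#' @param truth ground truth from [generate_reference()]
#' @param n_clumps number of clumps
#' @param config a [clumpseq_config()]
#' @param seed integer RNG seed
#' @return list with `counts` (a [count_matrix()]) and `clump_truth`
#'   (well id, zone, size, member count per type, contains_* flags)
#' @export
generate_clumps <- function(truth, n_clumps, config = clumpseq_config(),
                            seed = 1L) {
  sy <- config$synthetic
  set.seed(seed)
  genes <- rownames(truth$profiles[[1]])
  sizes_range <- seq(sy$clump_size_range[1], sy$clump_size_range[2])
  stopifnot(min(sizes_range) >= 2, max(sizes_range) <= 10)
  size_prob <- sy$clump_size_decay^(sizes_range - min(sizes_range))
  zones <- sample.int(truth$n_zones, n_clumps, replace = TRUE)
  sizes <- sample(sizes_range, n_clumps, replace = TRUE, prob = size_prob)
  type_names <- colnames(truth$type_proportions)
  counts <- matrix(0L, nrow = length(genes), ncol = n_clumps,
                   dimnames = list(genes,
                                   sprintf("clump_%05d", seq_len(n_clumps))))
  member_tab <- matrix(0L, nrow = n_clumps, ncol = length(type_names),
                       dimnames = list(NULL, type_names))
  for (i in seq_len(n_clumps)) {
    members <- c("enterocyte",
                 sample(type_names, sizes[i] - 1L, replace = TRUE,
                        prob = truth$type_proportions[zones[i], ]))
    libs <- pmax(1L, round(stats::rlnorm(sizes[i],
                                         log(sy$cell_library_median),
                                         sy$library_sdlog)))
    intensity <- program_intensity(sizes[i], members, config)
    frac <- Reduce(`+`, Map(function(ty, l, s)
      l * cell_fractions(truth, ty, zones[i], s), members, libs,
      intensity))
    frac <- frac / sum(frac)
    counts[, i] <- stats::rmultinom(1L, sum(libs), frac)
    member_tab[i, ] <- tabulate(match(members, type_names),
                                length(type_names))
  }
  meta <- data.frame(
    well_id = colnames(counts),
    plate_id = plate_layout(n_clumps, "plateK", config),
    well_kind = "clump", n_cells_estimate = sizes,
    time_stamp = NA_real_
  )
  full <- add_empty_wells(counts, meta, truth, config, "cl")
  ct <- data.frame(well_id = colnames(counts), zone = zones, size = sizes,
                   member_tab, check.names = FALSE)
  for (ty in setdiff(type_names, "enterocyte"))
    ct[[paste0("contains_", ty)]] <- member_tab[, ty] > 0
  list(counts = count_matrix(full$counts, full$meta), clump_truth = ct)
}

#' Coarse-grain a ground truth to fewer zones
#'
#' Linearly interpolates every cell type's expected expression profiles at
#' `n_zones` equally spaced positions (re-normalized per zone) and reduces
#' the per-zone type proportions accordingly. Used to draw single cells on
#' the coarser zone grid a reconstruction targets.
#'
#' @param truth ground truth from [generate_reference()]
#' @param n_zones target zone count
#' @return a truth list on the coarser grid
#' @export
coarse_truth <- function(truth, n_zones) {
  truth$profiles <- lapply(truth$profiles, function(p) {
    cg <- coarse_grain_reference(spatial_reference(p), n_zones)$values
    sweep(cg, 2L, colSums(cg), "/")
  })
  xout <- seq(1, truth$n_zones, length.out = n_zones)
  truth$type_proportions <- apply(truth$type_proportions, 2L, function(y)
    stats::approx(seq_len(truth$n_zones), y, xout = xout)$y)
  rownames(truth$type_proportions) <- paste0("zone", seq_len(n_zones))
  truth$n_zones <- n_zones
  truth
}

#' Write a simulated dataset with its ground truth to disk
#'
#' Emits the MTX/TSV formats [read_count_matrix()] reads, plus ground-truth
#' TSVs so all labels are recoverable by id.
#'
#' @param sim a list from [generate_cells()] or [generate_clumps()]
#' @param dir output directory
#' @param format passed to [write_count_matrix()]
#' @return `dir`, invisibly
#' @export
write_simulated_dataset <- function(sim, dir, format = "mtx") {
  write_count_matrix(sim$counts, dir, format = format)
  truth <- sim$cell_truth %||% sim$clump_truth
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
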