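test_that("background subtraction uses the plate empty-well mean and clamps", {
  counts <- matrix(c(5L, 1L,
                     2L, 2L,
                     2L, 2L,
                     2L, 2L,
                     2L, 2L),
                   nrow = 2,
                   dimnames = list(c("gA", "gB"),
                                   c("s1", "e1", "e2", "e3", "e4")))
  meta <- data.frame(well_id = colnames(counts), plate_id = "p1",
                     well_kind = c("clump", rep("empty", 4)))
  cm <- count_matrix(counts, meta)
  out <- subtract_background(cm)
  # sample 5 minus mean 2 -> 3; sample 1 minus mean 2 clamps to 0
  expect_equal(unname(out$counts[, "s1"]), c(3, 0))
  expect_false("e1" %in% colnames(out$counts))
})

test_that("all-zero empty wells leave sample counts unchanged", {
  cm <- tiny_counts()
  cm$counts[, "empty1"] <- 0L
  out <- subtract_background(cm)
  expect_equal(out$counts, cm$counts[, 1:3] + 0)
})

test_that("background subtraction is per plate and fails without empties", {
  counts <- matrix(c(4L, 8L, 0L, 2L), nrow = 1,
                   dimnames = list("g", c("a1", "b1", "ae", "be")))
  meta <- data.frame(well_id = colnames(counts),
                     plate_id = c("A", "B", "A", "B"),
                     well_kind = c("clump", "clump", "empty", "empty"))
  out <- subtract_background(count_matrix(counts, meta))
  expect_equal(unname(out$counts[1, ]), c(4, 6))

  broken <- count_matrix(counts, meta)
  broken$well_meta$well_kind[3] <- "clump"  # plate A loses its empty well
  expect_error(subtract_background(broken), "plate without empty wells")
})

test_that("clump QC applies the retention bounds as printed", {
  cfg <- clumpseq_config()
  set.seed(1)
  n_genes <- 300
  mk_well <- function(total, genes, mito_frac) {
    v <- numeric(n_genes)
    mito <- round(total * mito_frac)
    v[1] <- mito
    rest <- total - mito
    picked <- sample(2:n_genes, genes - 1)
    v[picked] <- rmultinom(1, rest, rep(1, genes - 1))
    v
  }
  counts <- cbind(mk_well(450, 250, 0.1),    # low UMI -> removed
                  mk_well(2000, 250, 0.35),  # 35% mito -> removed
                  mk_well(2000, 250, 0.1),   # retained
                  mk_well(2000, 150, 0.1))   # too few genes -> removed
  counts <- cbind(counts, 0)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(c("mt-1", paste0("g", 2:n_genes)),
                           c("w1", "w2", "w3", "w4", "e"))
  meta <- data.frame(well_id = colnames(counts), plate_id = "p",
                     well_kind = c(rep("clump", 4), "empty"))
  cm <- subtract_background(count_matrix(counts, meta))
  res <- qc_filter(cm, "clump", cfg, mito_genes = "mt-1")
  expect_equal(res$report$pass, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(colnames(res$counts$counts), "w3")
  # retained counts are untouched
  expect_equal(res$counts$counts[, "w3"], cm$counts[, "w3"])
  expect_equal(nrow(res$report), 4)  # one row per input well
  expect_error(qc_filter(cm, "clump", cfg, mito_genes = character()),
               "empty")
})

test_that("single-cell QC uses strict bounds and the 40% mito cutoff", {
  cfg <- clumpseq_config()
  mk <- function(total, genes, mito_frac) {
    v <- integer(500)
    v[1] <- as.integer(round(total * mito_frac))
    per <- (total - v[1]) %/% (genes - 1)
    v[2:genes] <- as.integer(per)
    v[2] <- v[2] + as.integer(total - sum(v))
    v
  }
  counts <- cbind(mk(1000, 400, 0.10),   # retained
                  mk(1000, 400, 0.41),   # 41% mito -> removed
                  mk(200, 180, 0.05),    # UMI exactly 200 -> removed
                  mk(1000, 150, 0.05))   # genes exactly 150 -> removed
  counts <- cbind(counts, 0L)
  dimnames(counts) <- list(c("mt-1", paste0("g", 2:500)),
                           c("c1", "c2", "c3", "c4", "e"))
  meta <- data.frame(well_id = colnames(counts), plate_id = "p",
                     well_kind = c(rep("single_cell", 4), "empty"))
  cm <- subtract_background(count_matrix(counts, meta))
  res <- qc_filter(cm, "single_cell", cfg, mito_genes = "mt-1")
  expect_equal(res$report$pass, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("total normalization divides by column sums", {
  m <- matrix(c(2, 3, 5, 1, 0, 1), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("w1", "w2")))
  nm <- normalize_total(m)
  expect_equal(unname(nm$values[, "w1"]), c(0.2, 0.3, 0.5))
  expect_equal(unname(colSums(nm$values)), c(1, 1))
  m0 <- cbind(m, w3 = c(0, 0, 0))
  expect_error(normalize_total(m0), "w3")
})

test_that("internal normalization restricts to the subset and drops zeros", {
  m <- matrix(c(1, 3, 6, 2, 0, 5), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("w1", "w2")))
  expect_silent(nm <- internal_normalize(m, c("a", "b")))
  expect_equal(unname(nm$values[, "w1"]), c(0.25, 0.75))
  expect_equal(nm$scope, "gene_subset")
  # ratios within the subset are unchanged by the op
  expect_equal(nm$values["b", "w1"] / nm$values["a", "w1"], 3)
  # a column with zero subset expression is dropped with a warning
  expect_warning(nm2 <- internal_normalize(m, "b"), "dropped")
  expect_equal(colnames(nm2$values), "w1")
  expect_error(internal_normalize(m, character()), "empty")
})

test_that("marker-score typing labels synthetic cells at >= 99% accuracy", {
  sim <- shared_sim()
  cfg <- clumpseq_config()
  # tissue-proportion survey only: the enriched sort intentionally contains
  # low-intensity secretory cells that typing conservatively defaults
  survey <- grepl("^cell_", sim$cell_truth$well_id)
  ids <- sim$cell_truth$well_id[survey]
  pp <- preprocess_counts(sim$cells, "single_cell", cfg,
                          sim$truth$mito_genes)
  keep <- intersect(ids, colnames(pp$norm$values))
  nm <- norm_matrix(pp$norm$values[, keep, drop = FALSE], "total")
  labels <- classify_cells_by_markers(nm, sim$truth$markers)
  truth <- setNames(sim$cell_truth$type, sim$cell_truth$well_id)
  expect_gte(mean(labels == truth[names(labels)]), 0.99)
})

test_that("cells with zero marker expression default to enterocyte", {
  m <- matrix(c(0, 0, 1, 5, 0, 1), nrow = 3,
              dimnames = list(c("gobA", "tufA", "hk"), c("c1", "c2")))
  nm <- normalize_total(m)
  lab <- classify_cells_by_markers(nm, list(goblet = "gobA",
                                            tuft = "tufA"))
  expect_equal(unname(lab["c1"]), "enterocyte")
  expect_equal(unname(lab["c2"]), "goblet")
  expect_error(classify_cells_by_markers(nm, list(a = "gobA", b = "gobA")),
               "disjoint")
})
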