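toy_cells <- function(vals) norm_matrix(vals, "total")

test_that("eta is Y/(X+Y) with boundary and degenerate cases handled", {
  lm <- landmark_set("goblet", crypt = "cg", tip = "tg")
  vals <- cbind(s1 = c(0.25, 0.25, 0.5),
                s2 = c(0, 0.5, 0.5),
                s3 = c(0, 0, 1))
  rownames(vals) <- c("cg", "tg", "other")
  expect_warning(eta <- compute_eta(toy_cells(vals), lm), "excluded")
  expect_equal(eta$sample_id, c("s1", "s2"))
  expect_equal(eta$eta, c(0.5, 1))  # X=Y -> 0.5; X=0 -> 1
  expect_error(compute_eta(toy_cells(vals),
                           landmark_set("goblet", crypt = character(),
                                        tip = "tg")),
               "non-empty")
})

test_that("eta is exactly invariant to per-sample rescaling", {
  set.seed(3)
  n <- 200
  vals <- matrix(runif(20 * n), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("s%03d", 1:n)))
  lm <- landmark_set("goblet", crypt = sprintf("g%02d", 1:5),
                     tip = sprintf("g%02d", 6:10))
  nm1 <- norm_matrix(sweep(vals, 2, colSums(vals), "/"), "total")
  eta1 <- compute_eta(nm1, lm)
  # rescaling a sample's expression cancels in the ratio; compare the raw
  # (unnormalized) values against the normalized ones
  scaled <- sweep(vals, 2, runif(n, 0.1, 10), "*")
  X <- colSums(scaled[lm$crypt, ]); Y <- colSums(scaled[lm$tip, ])
  expect_equal(eta1$eta, unname(Y / (X + Y)), tolerance = 1e-12)
})

test_that("the eta grid and candidate combinatorics follow the recipe", {
  set.seed(13)
  cell_etas <- runif(300)
  grid <- enumerate_eta_limits(crypt_clump_etas = rep(0.3, 5),
                               cell_etas = cell_etas, n_zones = 4,
                               d_eta = 0.05, min_cells = 10)
  expect_equal(grid$eta_min, 0.3)
  expect_length(grid$eta_vec, 15)  # 0.30, 0.35, ..., 1.00
  expect_equal(attr(grid$boundaries, "n_total"), choose(15, 3))
  expect_true(all(apply(grid$boundaries, 1, function(b) all(diff(b) > 0))))
  # every surviving candidate leaves >= 10 cells in every zone
  counts <- apply(grid$boundaries, 1, function(b)
    min(tabulate(zone_of_eta(cell_etas, b), 4)))
  expect_true(all(counts >= 10))
  # a grid whose span is not a multiple of the step still ends at 1
  g2 <- enumerate_eta_limits(rep(0.33, 3), cell_etas, 3, 0.05, 5)
  expect_equal(tail(g2$eta_vec, 1), 1)
  expect_error(enumerate_eta_limits(numeric(), cell_etas, 4, 0.05),
               "no crypt clumps")
})

test_that("eta bins are half-open with the last bin closed", {
  b <- c(0, 0.3, 0.6, 1)
  expect_equal(zone_of_eta(c(0, 0.29, 0.3, 0.59, 0.6, 0.99, 1), b),
               c(1, 1, 2, 2, 3, 3, 3))
})

test_that("optimization selects the boundaries that reproduce the table", {
  set.seed(23)
  genes <- sprintf("g%02d", 1:20)
  profile <- matrix(runif(20 * 3, 0.1, 1), nrow = 20,
                    dimnames = list(genes, paste0("zone", 1:3)))
  profile <- sweep(profile, 2, colSums(profile), "/")  # zones comparable
  # cells drawn exactly from the profile's zones at eta 0.1 / 0.5 / 0.9
  zones_true <- rep(1:3, each = 30)
  etas <- c(runif(30, 0.05, 0.15), runif(30, 0.45, 0.55),
            runif(30, 0.85, 0.95))
  names(etas) <- sprintf("s%02d", seq_along(etas))
  vals <- sapply(zones_true, function(z) {
    v <- profile[, z]
    v / sum(v)
  })
  colnames(vals) <- names(etas)
  cells <- norm_matrix(vals, "total")
  cand <- rbind(c(0, 0.3, 0.7, 1),     # reproduces the generating zones
                c(0, 0.2, 0.5, 1),
                c(0, 0.5, 0.8, 1))
  opt <- optimize_eta_limits(cand, cells, etas, profile, genes)
  expect_equal(opt$boundaries, cand[1, ])
  expect_equal(opt$med_euc, 0, tolerance = 1e-9)
  # max-normalization makes the distance scale-free per gene
  profile2 <- profile
  profile2["g01", ] <- profile2["g01", ] * 2
  vals2 <- vals
  vals2["g01", ] <- vals2["g01", ] * 2
  cells2 <- list(values = vals2)  # same data, one gene rescaled end to end
  opt2 <- optimize_eta_limits(cand, cells2, etas, profile2, genes)
  expect_equal(opt2$per_candidate, opt$per_candidate, tolerance = 1e-6)
  expect_error(optimize_eta_limits(cand, cells, etas, profile,
                                   "absent_gene"), "no genes")
})

test_that("reconstruction bins cells and applies the testing floor", {
  cfg <- clumpseq_config()
  genes <- c("hi", "lo")
  vals <- rbind(hi = c(0.5, 0.5, 0.4, 0.6), lo = rep(4e-6, 4))
  vals <- rbind(vals, filler = 1 - colSums(vals))
  colnames(vals) <- paste0("s", 1:4)
  etas <- setNames(c(0.1, 0.2, 0.8, 0.9), colnames(vals))
  tab <- reconstruct_zonation(norm_matrix(vals, "total"), etas,
                              c(0, 0.5, 1), cfg)
  expect_equal(unname(tab$mean["hi", ]), c(0.5, 0.5))
  expect_equal(unname(tab$sem["hi", "zone1"]), 0)  # equal values -> SEM 0
  # a gene with maximal expression 4e-6 is below the 5e-6 floor: untested
  expect_true(is.na(tab$p[["lo"]]))
  expect_false(is.na(tab$p[["hi"]]))
})

test_that("merging keeps single-dataset genes and drops non-overlapping ones", {
  cfg <- clumpseq_config()
  zones <- paste0("zone", 1:3)
  mk <- function(means, nexp, p) {
    g <- rownames(means)
    q <- rep(NA_real_, length(p)); q[!is.na(p)] <- p.adjust(p[!is.na(p)], "BH")
    zonation_table(means, means * 0.1, nexp, setNames(p, g),
                   setNames(q, g), group_sizes = c(20, 20, 20))
  }
  means_a <- rbind(shared = c(2, 4, 8), only_a = c(1, 2, 3),
                   no_overlap = c(5, 5, 5)) * 1e-5
  colnames(means_a) <- zones
  nexp_a <- rbind(shared = c(6L, 8L, 10L), only_a = c(5L, 5L, 5L),
                  no_overlap = c(5L, 4L, 4L))
  colnames(nexp_a) <- zones
  means_b <- rbind(shared = c(1, 2, 4), only_b = c(3, 2, 1),
                   no_overlap = c(6, 6, 6)) * 1e-5
  colnames(means_b) <- zones
  nexp_b <- rbind(shared = c(6L, 9L, 10L), only_b = c(5L, 5L, 5L),
                  no_overlap = c(4L, 4L, 4L))
  colnames(nexp_b) <- zones
  ta <- mk(means_a, nexp_a, c(0.01, 0.2, 0.5))
  tb <- mk(means_b, nexp_b, c(0.05, 0.3, 0.4))
  m <- merge_zonation_tables(ta, tb, cfg)
  # gene only in A keeps A's profile unchanged
  expect_equal(m$mean["only_a", ], ta$mean["only_a", ])
  expect_equal(m$mean["only_b", ], tb$mean["only_b", ])
  # expressed in both but never 5+ cells in the same zone -> excluded
  expect_false("no_overlap" %in% m$gene_ids)
  # shared gene: profiles are proportional (2,4,8) ~ (1,2,4), so the
  # merged profile keeps that shape and the larger table's scale
  expect_equal(unname(m$mean["shared", ] / max(m$mean["shared", ])),
               c(0.25, 0.5, 1))
  expect_equal(max(m$mean["shared", ]), max(ta$mean["shared", ]))
  # p is the smaller of the two
  expect_equal(m$p[["shared"]], 0.01)
  expect_error(merge_zonation_tables(ta, toy_zonation_table(
    means_b[, 1:2]), cfg), "zone counts")
})

test_that("merging identical tables reproduces them", {
  cfg <- clumpseq_config()
  set.seed(33)
  means <- matrix(runif(30, 1e-6, 1e-4), 10, 3,
                  dimnames = list(sprintf("g%02d", 1:10),
                                  paste0("zone", 1:3)))
  nexp <- matrix(7L, 10, 3, dimnames = dimnames(means))
  p <- runif(10)
  q <- p.adjust(p, "BH")
  ta <- zonation_table(means, means * 0.1, nexp,
                       setNames(p, rownames(means)),
                       setNames(q, rownames(means)), c(20, 20, 20))
  m <- merge_zonation_tables(ta, ta, cfg)
  expect_equal(m$mean[rownames(means), ], means, tolerance = 1e-9)
  # 5 vs 4 expressing cells in every zone -> no mutual zone -> excluded
  tb <- ta
  tb$n_expressing[] <- 4L
  m2 <- merge_zonation_tables(ta, tb, cfg)
  expect_equal(nrow(m2$mean), 0L)
})

test_that("temporal binning splits cells into equal-count bins", {
  cfg <- clumpseq_config()
  set.seed(43)
  mk_cells <- function(n) {
    vals <- matrix(runif(3 * n), nrow = 3,
                   dimnames = list(c("a", "b", "c"), sprintf("t%03d", 1:n)))
    norm_matrix(sweep(vals, 2, colSums(vals), "/"), "total")
  }
  ts70 <- setNames(runif(70), sprintf("t%03d", 1:70))
  tab <- temporal_profile(mk_cells(70), ts70, n_bins = 7)
  expect_equal(unname(tab$group_sizes), rep(10L, 7))
  ts72 <- setNames(runif(72), sprintf("t%03d", 1:72))
  tab72 <- temporal_profile(mk_cells(72), ts72, n_bins = 7)
  expect_equal(unname(tab72$group_sizes), c(11L, 11L, 10L, 10L, 10L,
                                            10L, 10L))
  # constant gene -> flat profile with p = 1
  cells <- mk_cells(70)
  cells$values["a", ] <- 0.5
  cells$values["b", ] <- 0.3
  cells$values["c", ] <- 0.2
  tabc <- temporal_profile(cells, ts70, n_bins = 7)
  expect_equal(unname(tabc$mean["a", ]), rep(0.5, 7))
  expect_equal(unname(tabc$p["a"]), 1)
  expect_error(temporal_profile(mk_cells(5), setNames(runif(5),
                                                      sprintf("t%03d", 1:5))),
               "fewer cells")
})
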