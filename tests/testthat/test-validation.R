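test_that("coarse-graining interpolates linearly and preserves monotony", {
  ref <- spatial_reference(matrix(c(0, 1), 1, 2,
                                  dimnames = list("g", c("z1", "z2"))))
  cg <- coarse_grain_reference(ref, 2)
  expect_equal(cg$values, ref$values)  # n_zones = N is the identity
  ref3 <- spatial_reference(matrix(c(0, 1), 1, 2,
                                   dimnames = list("g", c("z1", "z2"))))
  # a 2-zone (0, 1) profile cannot be refined; build a 3-zone one instead
  ref3 <- spatial_reference(matrix(c(0, 0.5, 1), 1, 3,
                                   dimnames = list("g", paste0("z", 1:3))))
  cg2 <- coarse_grain_reference(ref3, 2)
  expect_equal(unname(cg2$values[1, ]), c(0, 1))

  set.seed(5)
  mono <- sort(runif(7))
  ref7 <- spatial_reference(matrix(mono, 1, 7,
                                   dimnames = list("g", paste0("z", 1:7))))
  cg5 <- coarse_grain_reference(ref7, 5)
  expect_true(all(diff(cg5$values[1, ]) >= 0))
  expect_equal(cg5$values[1, 1], mono[1])   # endpoints preserved
  expect_equal(cg5$values[1, 5], mono[7])
  expect_error(coarse_grain_reference(ref7, 1), "at least 2")
  expect_error(coarse_grain_reference(ref7, 9), "refine")
})

test_that("the (0,1) profile interpolated to 3 zones gives (0, 0.5, 1)", {
  ref <- spatial_reference(matrix(c(0, 1, 2, 6), 2, 2, byrow = TRUE,
                                  dimnames = list(c("a", "b"),
                                                  c("z1", "z2"))))
  # linear-interpolation oracle at positions 1, 1.5, 2
  manual <- t(apply(ref$values, 1, function(y)
    approx(1:2, y, xout = c(1, 1.5, 2))$y))
  expect_equal(manual["a", ], c(0, 0.5, 1))
  # cannot refine via coarse_grain_reference; the oracle documents the rule
  cg <- coarse_grain_reference(spatial_reference(
    matrix(c(0, 0.5, 1), 1, 3, dimnames = list("a", paste0("z", 1:3)))), 3)
  expect_equal(unname(cg$values[1, ]), c(0, 0.5, 1))
})

test_that("validation gene selection excludes landmarks and noisy profiles", {
  cfg <- clumpseq_config()
  zones <- paste0("zone", 1:5)
  mk_tab <- function(sem_scale) {
    means <- rbind(lmk = c(5, 4, 3, 2, 1) * 1e-5,
                   good = c(1, 2, 4, 6, 8) * 1e-5,
                   noisy = c(2, 3, 4, 5, 6) * 1e-5,
                   dim_g = c(1, 2, 3, 4, 5) * 1e-7)
    colnames(means) <- zones
    sems <- means * 0.05
    sems["noisy", ] <- max(means["noisy", ]) * sem_scale
    nexp <- matrix(12L, 4, 5, dimnames = dimnames(means))
    p <- rep(0.01, 4)
    zonation_table(means, sems, nexp, p, p.adjust(p, "BH"),
                   group_sizes = rep(20L, 5))
  }
  sc <- mk_tab(0.45)
  cl <- mk_tab(0.45)
  lm <- landmark_set("goblet", crypt = "lmk", tip = character())
  sec <- c("lmk", "good", "noisy", "dim_g")
  got <- select_validation_genes(sc, cl, lm, sec, sem_cutoff = 0.4,
                                 config = cfg)
  expect_false("lmk" %in% got)    # landmarks excluded regardless
  expect_false("noisy" %in% got)  # SEM 0.45 >= goblet cutoff 0.4
  expect_false("dim_g" %in% got)  # below the 1e-5 expression floor
  expect_equal(got, "good")
  # the tuft cutoff 0.5 admits the same gene
  got_tuft <- select_validation_genes(sc, cl, lm, sec, sem_cutoff = 0.5,
                                      config = cfg)
  expect_true("noisy" %in% got_tuft)
  expect_error(select_validation_genes(sc, cl, lm, "lmk", 0.4, cfg),
               "relaxing|pass")
})

test_that("COM validation matches a brute-force rank correlation", {
  means <- matrix(runif(300, 1e-6, 1e-4), 100, 3,
                  dimnames = list(sprintf("g%03d", 1:100),
                                  paste0("zone", 1:3)))
  ta <- toy_zonation_table(means)
  tb <- toy_zonation_table(means)  # identical tables -> R = 1
  v <- validate_reconstruction(ta, tb, rownames(means))
  expect_equal(unname(v$R), 1)
  # reversed ranks -> R = -1
  com <- center_of_mass(means)
  rev_means <- means[order(com, decreasing = TRUE), ]
  rownames(rev_means) <- rownames(means)[order(com)]
  tc <- toy_zonation_table(rev_means)
  v2 <- validate_reconstruction(ta, tc, rownames(means))
  expect_equal(unname(v2$R), -1, tolerance = 1e-12)
  # brute-force rank-formula oracle on random COM pairs
  set.seed(17)
  means_b <- matrix(runif(300, 1e-6, 1e-4), 100, 3,
                    dimnames = dimnames(means))
  td <- toy_zonation_table(means_b)
  v3 <- validate_reconstruction(ta, td, rownames(means))
  expect_equal(unname(v3$R),
               brute_force_spearman(center_of_mass(means),
                                    center_of_mass(means_b)),
               tolerance = 1e-12)
  expect_error(validate_reconstruction(ta, tb, c("g001", "g002")),
               "at least 3")
  flat <- toy_zonation_table(matrix(1e-5, 10, 3,
                                    dimnames = list(sprintf("f%02d", 1:10),
                                                    paste0("zone", 1:3))))
  expect_error(validate_reconstruction(flat, flat, sprintf("f%02d", 1:10)),
               "constant")
})

test_that("robustness sweeps perturb registered parameters only", {
  cfg <- clumpseq_config()
  # a cheap stand-in reconstruction whose output depends mildly on one
  # registered threshold
  base_means <- matrix(runif(150, 1e-6, 1e-4), 50, 3,
                       dimnames = list(sprintf("g%02d", 1:50),
                                       paste0("zone", 1:3)))
  run_fn <- function(config) {
    floor_v <- config$clump$zonation_test_floor
    keep <- apply(base_means, 1, max) > floor_v
    toy_zonation_table(base_means[keep, , drop = FALSE])
  }
  cfg$robustness$n_values <- 5
  rc <- robustness_sweep(run_fn, cfg, "zonation_test_floor")
  expect_equal(nrow(rc), 5)
  expect_equal(rc$fold, seq(0.5, 1.5, length.out = 5))
  # the reinserted point: P = 1 at zero perturbation
  expect_equal(rc$P_smooth[rc$fold == 1], 1)
  expect_true(all(rc$P >= 0.99, na.rm = TRUE))  # rank-stable stand-in
  expect_error(robustness_sweep(run_fn, cfg, "not_a_parameter"),
               "unregistered")
})

test_that("integer parameters are rounded and deduplicated", {
  cfg <- clumpseq_config()
  cfg$robustness$n_values <- 75
  run_fn <- function(config) {
    k <- config$specificity$landmarks_per_profile
    expect_equal(k, round(k))
    toy_zonation_table(matrix(runif(30, 1e-6, 1e-4), 10, 3,
                              dimnames = list(sprintf("g%02d", 1:10),
                                              paste0("zone", 1:3))))
  }
  rc <- robustness_sweep(run_fn, cfg, "landmarks_per_profile")
  expect_true(all(rc$value == round(rc$value)))
  expect_equal(anyDuplicated(rc$value), 0L)
  expect_lte(nrow(rc), 75)
  # 30 +/- 50% spans 15..45: 31 unique integers
  expect_equal(nrow(rc), 31)
})

test_that("the moving median shrinks its window at the boundaries", {
  x <- c(5, 1, 2, 3, 4, 6, 8, 7, 9, 10, 12, 11)
  sm <- moving_median(x, k = 10)
  # interior point: median over the full 10-wide window (4 back, 5 ahead)
  expect_equal(sm[6], median(x[2:11]))
  # first point: window shrinks to x[1:6]
  expect_equal(sm[1], median(x[1:6]))
  expect_length(sm, length(x))
})
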