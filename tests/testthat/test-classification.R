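make_marker_matrix <- function(sums, marker_names) {
  # build a normalized matrix in which each clump's per-type marker sums
  # equal the requested values (one marker gene per type + filler)
  n <- nrow(sums)
  vals <- t(cbind(sums, filler = pmax(1 - rowSums(sums), 0)))
  rownames(vals) <- c(marker_names, "filler")
  colnames(vals) <- sprintf("cl%03d", seq_len(n))
  norm_matrix(vals, "total")
}

test_that("marker-sum Z-scores are standardized and reduced to 3 PCs", {
  set.seed(21)
  types <- c("goblet", "enteroendocrine", "tuft", "paneth")
  sums <- matrix(runif(400 * 4, 0, 0.2), ncol = 4,
                 dimnames = list(NULL, types))
  nm <- make_marker_matrix(sums, paste0("mk_", types))
  emb <- embed_clumps(nm, as.list(setNames(paste0("mk_", types), types)))
  expect_equal(unname(colMeans(emb$marker_sum_z)), rep(0, 4),
               tolerance = 1e-12)
  expect_equal(unname(apply(emb$marker_sum_z, 2, sd)), rep(1, 4),
               tolerance = 1e-12)
  expect_equal(ncol(emb$pc_position), 3L)  # 4 input dims -> 3 PCs kept
  expect_equal(unname(apply(emb$pc_position, 2, median)), rep(0, 3),
               tolerance = 1e-12)
  # a clump whose sums all sit at the across-clump means has Z = 0
  sums2 <- rbind(sums, colMeans(sums))
  nm2 <- make_marker_matrix(sums2, paste0("mk_", types))
  emb2 <- embed_clumps(nm2, as.list(setNames(paste0("mk_", types), types)))
  expect_equal(unname(emb2$marker_sum_z[nrow(sums2), ]), rep(0, 4),
               tolerance = 1e-10)
  expect_error(embed_clumps(make_marker_matrix(sums[1:3, ],
                                               paste0("mk_", types)),
                            as.list(setNames(paste0("mk_", types), types))),
               "fewer than 5")
})

test_that("rays constructed in PC space are recovered within one degree", {
  cfg <- clumpseq_config()
  set.seed(31)
  types <- c("goblet", "enteroendocrine", "tuft", "paneth")
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 1) / sqrt(3))
  names(dirs) <- types
  lengths <- c(seq(0.1, 3, length.out = 99), 10)  # one far point per type
  pts <- do.call(rbind, lapply(seq_along(dirs), function(i)
    outer(lengths, dirs[[i]])))
  z <- matrix(0, 400, 4, dimnames = list(NULL, types))
  for (i in seq_along(dirs)) z[(i - 1) * 100 + 1:100, i] <- lengths
  emb <- structure(list(
    clump_ids = sprintf("c%03d", 1:400), marker_sum_z = z,
    pc_position = pts,
    origin_distance = sqrt(rowSums(pts^2))
  ), class = "clump_embedding")
  rays <- fit_rays(emb, cfg)
  for (ty in types) {
    ang <- acos(min(1, abs(sum(rays[[ty]] * dirs[[ty]])))) * 180 / pi
    expect_lt(ang, 1)
    # orientation points toward the far clumps (positive projection)
    expect_gt(sum(rays[[ty]] * dirs[[ty]]), 0)
  }
  # only clumps above the 99th percentile are used: 4 of 400 here
  far_n <- sum(emb$origin_distance >
                 quantile(emb$origin_distance, 0.99))
  expect_equal(far_n, 4L)
})

test_that("quota classification keeps origin clumps enterocyte-only", {
  cfg <- clumpseq_config()
  set.seed(41)
  types <- c("goblet", "enteroendocrine", "tuft", "paneth")
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 1, 0) / sqrt(2))
  names(dirs) <- types
  # 100 clumps per type on rays + 200 at the origin
  on_ray <- do.call(rbind, lapply(dirs, function(d)
    outer(seq(0.5, 5, length.out = 100), d)))
  origin <- matrix(rnorm(600, 0, 0.05), ncol = 3)
  pts <- rbind(on_ray, origin)
  z <- matrix(0, nrow(pts), 4, dimnames = list(NULL, types))
  for (i in 1:4) z[(i - 1) * 100 + 1:100, i] <- seq(0.5, 5,
                                                    length.out = 100)
  emb <- structure(list(
    clump_ids = sprintf("c%04d", seq_len(nrow(pts))),
    marker_sum_z = z, pc_position = pts,
    origin_distance = sqrt(rowSums(pts^2))
  ), class = "clump_embedding")
  rays <- fit_rays(emb, cfg)
  zones <- setNames(rep(c(1L, 5L), length.out = nrow(pts)),
                    emb$clump_ids)
  calls <- classify_clump_types(emb, rays, zones, "pairs", cfg)
  origin_ids <- emb$clump_ids[401:600]
  # clumps at the origin are never called secretory
  expect_true(all(calls$call[calls$clump_id %in% origin_ids] ==
                    "enterocyte"))
  # a clump with closest-ray distance Z >= -1 is never called secretory
  weak <- calls$ray_distance_z >= -1
  expect_true(all(calls$call[weak] == "enterocyte"))
  # quota arithmetic: accepted goblet calls per region are the rounded
  # proportion x multiplier share of that region's candidates
  for (reg in c(1L, 5L)) {
    cand <- calls$ray_distance_z < -1 & calls$closest_ray == "goblet" &
      zones[calls$clump_id] == reg
    n_acc <- sum(calls$call == "goblet" & zones[calls$clump_id] == reg)
    expect_equal(n_acc, round(0.08 * 2 * sum(cand)))
  }
})

test_that("classification output is invariant to clump order", {
  cfg <- clumpseq_config()
  sim <- shared_sim()
  prep <- shared_prep()
  est <- setNames(prep$clumps$norm$well_meta$n_cells_estimate,
                  prep$clumps$norm$well_meta$well_id)
  sel <- which(est[colnames(prep$clumps$norm$values)] > 2)
  vals <- prep$clumps$norm$values[, sel]
  nm <- norm_matrix(vals, "total")
  emb <- embed_clumps(nm, sim$truth$markers)
  rays <- fit_rays(emb, cfg)
  zones <- setNames(rep(c(1L, 4L), length.out = ncol(vals)),
                    colnames(vals))
  calls1 <- classify_clump_types(emb, rays, zones, "larger", cfg)

  perm <- sample(ncol(vals))
  nm2 <- norm_matrix(vals[, perm], "total")
  emb2 <- embed_clumps(nm2, sim$truth$markers)
  rays2 <- fit_rays(emb2, cfg)
  calls2 <- classify_clump_types(emb2, rays2, zones, "larger", cfg)
  m <- match(calls1$clump_id, calls2$clump_id)
  expect_equal(calls1$call, calls2$call[m])
})

test_that("secretory calls are precise and enterocyte clumps specific", {
  cfg <- clumpseq_config()
  stats <- sapply(1:2, function(seed) {
    sim <- simulate_clumpseq(cfg, seed = seed, n_cells = 600,
                             n_clumps = 6000, n_secretory_cells = 0)
    prep <- prepare_pipeline(sim, cfg)
    zonation <- run_clump_zonation(prep)
    zones <- setNames(zonation$assignment$zone,
                      zonation$assignment$clump_id)
    calls <- run_clump_classification(prep, zones)
    ct <- sim$clump_truth
    rownames(ct) <- ct$well_id
    sec <- calls$call != "enterocyte"
    prec <- mean(mapply(function(id, ty) ct[id, paste0("contains_", ty)],
                        calls$clump_id[sec], calls$call[sec]))
    ent_only <- rowSums(ct[, paste0("contains_",
                                    c("goblet", "enteroendocrine",
                                      "tuft", "paneth"))]) == 0
    spec <- mean(calls$call[ent_only[calls$clump_id]] == "enterocyte")
    c(prec, spec)
  })
  expect_gte(mean(stats[1, ]), 0.8)
  expect_gte(mean(stats[2, ]), 0.95)
})
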