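# Shared fixtures, generated in code. The moderately sized simulation and
# its prepared pipeline products are cached per test run because several
# files exercise downstream stages of the same dataset.

.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_clumpseq(clumpseq_config(), seed = 3L,
                                          n_cells = 600, n_clumps = 1500)
  .fixture_env$sim
}

shared_prep <- function() {
  if (is.null(.fixture_env$prep))
    .fixture_env$prep <- prepare_pipeline(shared_sim(), clumpseq_config())
  .fixture_env$prep
}

# tiny deterministic count matrix: 3 genes x (3 sample + 1 empty) wells
tiny_counts <- function() {
  counts <- matrix(c(5L, 0L, 2L,
                     1L, 3L, 0L,
                     4L, 4L, 4L,
                     2L, 2L, 2L),
                   nrow = 3,
                   dimnames = list(c("g1", "g2", "mt-g3"),
                                   c("w1", "w2", "w3", "empty1")))
  meta <- data.frame(
    well_id = colnames(counts), plate_id = "p1",
    well_kind = c("clump", "clump", "clump", "empty")
  )
  count_matrix(counts, meta)
}

# small zonation-table builder from explicit mean profiles
toy_zonation_table <- function(means, n_expressing = NULL, p = NULL,
                               group_sizes = NULL) {
  nz <- ncol(means)
  if (is.null(n_expressing))
    n_expressing <- matrix(10L, nrow(means), nz, dimnames = dimnames(means))
  if (is.null(p)) p <- rep(NA_real_, nrow(means))
  q <- rep(NA_real_, nrow(means))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], "BH")
  if (is.null(group_sizes)) group_sizes <- rep(max(n_expressing), nz)
  zonation_table(means, means * 0, n_expressing, p, q, group_sizes)
}

# independent step-up Benjamini-Hochberg, written from the definition
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# brute-force center of mass from the definition
brute_force_com <- function(profile) {
  profile <- unname(profile)
  num <- 0
  den <- 0
  for (i in seq_along(profile)) {
    num <- num + profile[i] * i
    den <- den + profile[i]
  }
  if (den == 0) NA_real_ else num / den
}

# Spearman rank correlation from the rank formula (mean-rank ties)
brute_force_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  stats::cov(rx, ry) / (stats::sd(rx) * stats::sd(ry))
}
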