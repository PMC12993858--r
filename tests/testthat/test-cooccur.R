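# a tiny deterministic observation world: 4 taxa x 10 sites
tiny_obs <- function(seed = 31) {
  set.seed(seed)
  counts <- matrix(0L, 12, 4,
                   dimnames = list(sprintf("s%02d", 1:12), paste0("t", 1:4)))
  for (i in 1:12) {
    k <- sample(2:4, 1)
    taxa <- sample(4, k)
    counts[i, taxa] <- stats::rpois(k, 20) + 1L
  }
  reg <- regional_stats(counts)
  list(counts = counts, reg = reg,
       obs = build_matrix(counts[1:10, ], reg))
}

test_that("build_matrix drops absent taxa, keeps order, validates input", {
  w <- small_world()
  reg <- regional_stats(w$counts)
  ten <- w$counts[1:10, ]
  obs <- build_matrix(ten, reg)
  expect_equal(nrow(obs$mat), sum(colSums(ten > 0) > 0))
  expect_identical(colnames(obs$mat), rownames(ten))
  present <- colnames(ten)[colSums(ten > 0) > 0]
  expect_identical(rownames(obs$mat), present)
  dup <- ten; rownames(dup)[2] <- rownames(dup)[1]
  expect_error(build_matrix(dup, reg), "duplicate")
  expect_error(build_matrix(ten[1:9, ], reg), "exactly 10")
})

test_that("null_matrix preserves per-site richness and frequency weighting", {
  tw <- tiny_obs()
  obs <- tw$obs
  set.seed(1)
  for (i in 1:10) {
    nm <- null_matrix(obs)
    expect_identical(colSums(nm > 0), colSums(obs$mat > 0))
    # abundances come from the observed pools
    for (t in rownames(nm)) {
      vals <- nm[t, nm[t, ] > 0]
      expect_true(all(vals %in% tw$counts[, t]))
    }
  }
})

test_that("null draw frequencies track regional frequencies (1-taxon sites)", {
  # sites of richness 1 make the marginal draw probability exactly
  # proportional to regional frequency, so a binomial check is exact
  counts <- matrix(0L, 10, 4,
                   dimnames = list(sprintf("s%02d", 1:10), paste0("t", 1:4)))
  counts[cbind(1:10, rep(1:4, length.out = 10))] <- 5L
  reg <- regional_stats(counts)
  # unequal regional frequencies
  reg$frequency <- stats::setNames(c(0.4, 0.3, 0.2, 0.1), paste0("t", 1:4))
  obs <- build_matrix(counts, reg)
  set.seed(99)
  draws <- integer(4); names(draws) <- paste0("t", 1:4)
  n_draw <- 2000L
  for (b in seq_len(n_draw)) {
    nm <- null_matrix(obs)
    hits <- rowSums(nm > 0)
    draws <- draws + hits
  }
  tot <- 10 * n_draw
  p <- obs$regional$frequency / sum(obs$regional$frequency)
  for (t in names(draws)) {
    se <- sqrt(p[t] * (1 - p[t]) / tot)
    expect_lt(abs(draws[t] / tot - p[t]), 3.5 * se + 1e-9)
  }
})

test_that("pair_statistic closed forms", {
  x <- c(1, 5, 2, 9, 4, 7, 3, 8, 6, 2)
  expect_equal(pair_statistic(x, x), 1.0)
  a <- rep(c(1, 0), 5); b <- rep(c(0, 1), 5)
  expect_equal(pair_statistic(a, b), -1.0)
  expect_true(is.na(pair_statistic(rep(3, 10), x)))
})

test_that("ses formula: (r_obs - null mean) / sample sd", {
  # the documented example: null {0.1, 0.2, 0.3}, observed 0.4 -> ses 2
  nulls <- c(0.1, 0.2, 0.3)
  expect_equal((0.4 - mean(nulls)) / stats::sd(nulls), 2.0)
})

test_that("ses_edges matches the brute-force oracle exactly", {
  tw <- tiny_obs()
  obs <- tw$obs
  set.seed(4242)
  got <- ses_edges(obs, n_perm = 50)
  pool <- lapply(rownames(obs$mat), function(t) {
    v <- tw$counts[, t]; as.integer(v[v > 0])
  })
  set.seed(4242)
  want <- oracle_ses_edges(obs$mat, obs$regional$frequency, pool, 50)
  expect_equal(nrow(got), nrow(want))
  got <- got[order(got$taxon_a, got$taxon_b), ]
  want <- want[order(want$taxon_a, want$taxon_b), ]
  expect_equal(got$ses, want$ses, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
})

test_that("ses_edges output is invariant to consistent site relabeling", {
  tw <- tiny_obs()
  perm <- c(3, 1, 4, 2, 10, 6, 5, 9, 7, 8)
  mat_p <- tw$obs$mat[, perm]
  # observed pair statistics are permutation invariant
  for (a in 1:3) for (b in (a + 1):4) {
    expect_equal(pair_statistic(tw$obs$mat[a, ], tw$obs$mat[b, ]),
                 pair_statistic(mat_p[a, ], mat_p[b, ]))
  }
})

test_that("fdr_filter implements BH step-up", {
  e <- empty <- data.frame(taxon_a = c("a", "a", "b"),
                           taxon_b = c("b", "c", "c"),
                           r_obs = 0, null_mean = 0, null_sd = 1,
                           ses = 0, p = c(1e-6, 0.5, 0.9))
  f <- fdr_filter(e, 1e-4)
  # BH by hand: 1e-6 <= (1/3) * 1e-4 -> retained; others not
  expect_equal(sum(f$retained), 1)
  expect_true(f$retained[f$p == 1e-6])
  expect_true(all(f$q >= f$p))
  all1 <- transform(e, p = 1)
  expect_equal(sum(fdr_filter(all1, 1e-4)$retained), 0)
  single <- e[1, ]; single$p <- 5e-5
  expect_true(fdr_filter(single, 1e-4)$retained)
})

test_that("topology metrics: connectance, strength, composition", {
  w <- small_world()
  reg <- regional_stats(w$counts)
  obs <- build_matrix(w$counts[1:10, ], reg)
  n <- nrow(obs$mat)
  taxa <- rownames(obs$mat)
  edges <- data.frame(
    taxon_a = taxa[c(1, 1, 2, 3)], taxon_b = taxa[c(2, 3, 3, 4)],
    ses = c(2, -3, 4, 1.5), q = 0, retained = TRUE)
  topo <- network_topology(obs, edges, w$taxa)
  expect_equal(topo$size, n)
  expect_equal(topo$connectance, 4 / (n * (n - 1) / 2))
  expect_equal(topo$mean_strength, mean(c(2, 3, 4, 1.5)))
  tr <- w$taxa[match(taxa, w$taxa$taxon_id), ]
  expect_equal(topo$mean_tolerance, mean(tr$tolerance))
  # empty edge set: zeros, not NA
  topo0 <- network_topology(obs, transform(edges, retained = FALSE), w$taxa)
  expect_equal(topo0$connectance, 0)
  expect_equal(topo0$modularity, 0)
  expect_equal(topo0$mean_strength, 0)
  # adding a retained edge never decreases connectance
  edges5 <- rbind(edges, data.frame(taxon_a = taxa[2], taxon_b = taxa[4],
                                    ses = 1, q = 0, retained = TRUE))
  expect_gt(network_topology(obs, edges5, w$taxa)$connectance,
            topo$connectance)
})

test_that("graphml export round-trips node and edge attributes", {
  w <- small_world()
  reg <- regional_stats(w$counts)
  obs <- build_matrix(w$counts[1:10, ], reg)
  taxa <- rownames(obs$mat)
  edges <- data.frame(taxon_a = taxa[1], taxon_b = taxa[2], ses = 2.5,
                      q = 0, retained = TRUE)
  g <- network_to_igraph(obs, edges, w$taxa)
  expect_equal(igraph::vcount(g), nrow(obs$mat))
  expect_equal(igraph::ecount(g), 1)
  path <- tempfile(fileext = ".graphml")
  export_graphml(g, path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::E(g2)$ses, 2.5)
  unlink(path)
})
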