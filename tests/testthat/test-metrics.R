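test_that("richness counts positive taxa", {
  expect_equal(richness(c(5, 0, 2, 1)), 3)
  expect_equal(richness(c(0, 0)), 0)
  expect_equal(richness(c(x = 200)), 1)
})

test_that("shannon matches closed forms and the direct-evaluation oracle", {
  expect_equal(shannon(rep(50, 4)), log(4))
  expect_equal(shannon(c(200)), 0)
  # frozen from -sum(p log p) evaluated by hand for p = (.6, .3, .1)
  expect_equal(shannon(c(60, 30, 10)), 0.8979457, tolerance = 1e-6)
  expect_error(shannon(c(0, 0)), "empty")
})

test_that("shannon is bounded by log richness with equality at uniformity", {
  set.seed(5)
  for (i in 1:25) {
    ct <- stats::rmultinom(1, 200, stats::runif(12))[, 1]
    expect_lte(shannon(ct), log(richness(ct)) + 1e-12)
  }
  expect_equal(shannon(rep(10, 7)), log(7))
})

test_that("ept_richness requires both order and tolerance <= 4", {
  tr <- toy_traits()
  ct <- named_counts(x1 = 5, x2 = 3, x3 = 2)  # E tol2, P tol5, other tol2
  expect_equal(ept_richness(ct, tr), 1)
  expect_equal(ept_richness(named_counts(x3 = 9, x5 = 1), tr), 0)
  # tolerance exactly 4 is inclusive
  expect_equal(ept_richness(named_counts(x4 = 7), tr), 1)
  expect_error(ept_richness(named_counts(zz = 1), tr), "trait")
})

test_that("ffg_proportions exclude unknown and piercer individuals", {
  tr <- toy_traits()
  ct <- named_counts(x1 = 50, x2 = 30, x3 = 20)  # CG, SC, PR
  p <- ffg_proportions(ct, tr)
  expect_equal(unname(p[c("collector-gatherer", "scraper", "predator")]),
               c(0.5, 0.3, 0.2))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # adding unknown/piercer individuals changes nothing
  ct2 <- c(ct, named_counts(x6 = 10, x7 = 5))
  expect_equal(ffg_proportions(ct2, tr), p)
  # single-group sample
  p3 <- ffg_proportions(named_counts(x4 = 100), tr)
  expect_equal(unname(p3["shredder"]), 1)
  expect_warning(ffg_proportions(named_counts(x6 = 3), tr), "undefined")
})

test_that("mean_tolerance unweighted and abundance-weighted", {
  tr <- toy_traits()
  expect_equal(mean_tolerance(named_counts(x1 = 1, x4 = 1, x5 = 1), tr), 4)
  expect_equal(mean_tolerance(named_counts(x7 = 2), tr), 8)
  # counts 90 at tol 2, 10 at tol 8 -> weighted mean 2.6
  expect_equal(
    mean_tolerance(named_counts(x1 = 90, x7 = 10), tr, "abundance"), 2.6)
  expect_error(mean_tolerance(named_counts(x1 = 0), tr), "empty")
})

test_that("surrogate_ibi hits its bounds and is monotone", {
  cal <- default_ibi_calibration()
  at_ceiling <- list(richness = 30, ept_richness = 15, shannon = 3,
                     mean_tolerance = 0)
  at_floor <- list(richness = 0, ept_richness = 0, shannon = 0,
                   mean_tolerance = 10)
  expect_equal(surrogate_ibi(at_ceiling, cal), 100)
  expect_equal(surrogate_ibi(at_floor, cal), 0)
  # components scoring (100, 50, 50, 0) average to 50
  mid <- list(richness = 30, ept_richness = 7.5, shannon = 1.5,
              mean_tolerance = 10)
  expect_equal(surrogate_ibi(mid, cal), 50)
  # monotone in each component
  set.seed(9)
  for (i in 1:20) {
    m <- list(richness = stats::runif(1, 0, 30),
              ept_richness = stats::runif(1, 0, 15),
              shannon = stats::runif(1, 0, 3),
              mean_tolerance = stats::runif(1, 0, 10))
    up <- m; up$richness <- up$richness + 1
    expect_gte(surrogate_ibi(up, cal), surrogate_ibi(m, cal))
    worse <- m; worse$mean_tolerance <- min(10, worse$mean_tolerance + 1)
    expect_lte(surrogate_ibi(worse, cal), surrogate_ibi(m, cal))
  }
  expect_error(surrogate_ibi(mid, list(richness = c(1, 1),
                                       ept_richness = c(0, 15),
                                       shannon = c(0, 3),
                                       tolerance_score = c(0, 10))),
               "floor equals ceiling")
})

test_that("sample_metrics table is coherent on the synthetic world", {
  w <- small_world()
  met <- sample_metrics(w$counts, w$taxa)
  expect_equal(nrow(met), nrow(w$samples))
  expect_true(all(met$ept_richness <= met$richness))
  expect_true(all(met$shannon <= log(met$richness) + 1e-12))
  expect_true(all(met$ibi >= 0 & met$ibi <= 100))
  ffg_cols <- grep("^ffg_", names(met))
  sums <- rowSums(met[, ffg_cols])
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("planted stress lowers mean surrogate IBI across stress quartiles", {
  cfg <- sim_config(n_huc8 = 2,
                    samples_per_stratum = stats::setNames(
                      rep(125L, 4),
                      as.vector(outer(sprintf("HUC%05d", 1:2),
                                      c("cogd_only", "both"),
                                      paste, sep = "|"))),
                    n_taxa = 60,
                    effect_sizes = list(cogd = -0.5, uogd = 0, dlc = 0),
                    seed = 23)
  taxa <- generate_taxa(cfg)
  gs <- generate_samples(cfg, taxa)
  met <- sample_metrics(gs$counts, taxa)
  d <- gs$samples$cogd_density_true
  top <- d >= stats::quantile(d, 0.75)
  bottom <- d <= stats::quantile(d, 0.25)
  expect_lt(mean(met$ibi[top]), mean(met$ibi[bottom]))
})
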