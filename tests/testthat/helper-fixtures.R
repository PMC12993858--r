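# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small seeded world with no planted effects
small_world <- function() {
  fixture("small_world", function() {
    cfg <- sim_config(n_huc8 = 2, samples_per_stratum = 8, n_taxa = 40,
                      seed = 101)
    taxa <- generate_taxa(cfg)
    gs <- generate_samples(cfg, taxa)
    gw <- generate_wells(gs$samples, cfg)
    list(cfg = cfg, taxa = taxa, samples = gs$samples, counts = gs$counts,
         truth = gs$truth, wells = gw$wells, catchments = gw$catchments,
         membership = gw$membership)
  })
}

# a trait table with hand-picked values for metric tests
toy_traits <- function() {
  data.frame(
    taxon_id = paste0("x", 1:8),
    order = c("Ephemeroptera", "Plecoptera", "other", "Trichoptera",
              "other", "other", "other", "Ephemeroptera"),
    ffg = c("collector-gatherer", "scraper", "predator", "shredder",
            "filter-collector", "unknown", "piercer", "predator"),
    tolerance = c(2, 5, 2, 4, 6, 3, 8, 4.5),
    stringsAsFactors = FALSE
  )
}

named_counts <- function(...) {
  v <- c(...)
  stopifnot(!is.null(names(v)))
  v
}
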