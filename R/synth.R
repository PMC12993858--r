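#' Simulation configuration for the synthetic BMI world
#'
#' Bundles and validates every knob of the synthetic-data generator: the
#' stratification design (HUC8 watersheds crossed with oil-and-gas development
#' groups), the taxon pool, the fixed-count subsampling protocol
#' (`target_total` +/- `tolerance_halfwidth` individuals per sample, emulating
#' the 200 +/- 20 field protocol), the planted per-unit-stress effect sizes,
#' and the latent co-occurrence block structure.
#'
#' @param n_huc8 number of watersheds (HUC8 codes) to simulate.
#' @param samples_per_stratum named integer vector keyed
#'   `"<huc8>|<ogd_group>"` giving the number of samples per stratum, or a
#'   single unnamed integer applied to every (huc8, group) combination with
#'   groups `none`, `cogd_only`, `uogd_only`, `both`.
#' @param n_taxa size of the regional taxon pool (>= 10).
#' @param target_total target number of individuals per sample (default 200).
#' @param tolerance_halfwidth half-width of the allowed total (default 20);
#'   totals are drawn uniformly in `target_total +/- tolerance_halfwidth`.
#' @param effect_sizes named list/vector with elements `cogd`, `uogd`, `dlc`:
#'   planted per-unit-stress log-abundance slopes. Negative values harm
#'   pollution-sensitive taxa (tolerance < 5) and favour tolerant taxa.
#' @param n_blocks number of latent co-occurrence blocks taxa are assigned to.
#' @param block_strength standard-deviation scale (>= 0) of the shared
#'   Gaussian site factor each block experiences; 0 disables co-occurrence
#'   structure.
#' @param seed global integer seed; every operation derives its own keyed
#'   substream via [substream_seed()].
#' @param covariates list of covariate-distribution knobs: `p_fall` (fall
#'   season probability), `p_semiwadeable`, `p_amd` (acid-mine-drainage
#'   rate), `dlc_shape` (two Beta shape parameters for developed land
#'   cover), `dlc_cap` (DLC is `dlc_cap * Beta(...)`, so a cap of 0.2 makes
#'   every sample pass the 20% network filter). Defaults emulate a
#'   statewide monitoring mix: mostly spring, mostly wadeable, AMD in a
#'   minority of catchments, low-developed catchments.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_huc8 = 2, samples_per_stratum = 5, n_taxa = 30)
sim_config <- function(n_huc8 = 3,
                       samples_per_stratum = 20,
                       n_taxa = 120,
                       target_total = 200,
                       tolerance_halfwidth = 20,
                       effect_sizes = list(cogd = 0, uogd = 0, dlc = 0),
                       n_blocks = 4,
                       block_strength = 0,
                       seed = 1L,
                       covariates = list()) {
  stopifnot(
    n_huc8 >= 1, n_taxa >= 10,
    target_total > 0, tolerance_halfwidth >= 0,
    tolerance_halfwidth < target_total,
    n_blocks >= 1, is.finite(block_strength), block_strength >= 0
  )
  es <- as.list(effect_sizes)
  if (!all(c("cogd", "uogd", "dlc") %in% names(es))) {
    stop("effect_sizes must name cogd, uogd and dlc", call. = FALSE)
  }
  huc8 <- sprintf("HUC%05d", seq_len(n_huc8))
  if (is.null(names(samples_per_stratum))) {
    stopifnot(length(samples_per_stratum) == 1L)
    keys <- as.vector(outer(huc8, ogd_groups(), paste, sep = "|"))
    samples_per_stratum <- stats::setNames(
      rep(as.integer(samples_per_stratum), length(keys)), keys)
  }
  stopifnot(all(samples_per_stratum >= 1))
  cov_defaults <- list(p_fall = 0.15, p_semiwadeable = 0.10, p_amd = 0.15,
                       dlc_shape = c(1.2, 10), dlc_cap = 1)
  covariates <- utils::modifyList(cov_defaults, as.list(covariates))
  stopifnot(covariates$dlc_cap > 0, covariates$dlc_cap <= 1)
  structure(
    list(
      huc8 = huc8,
      samples_per_stratum = samples_per_stratum,
      n_taxa = as.integer(n_taxa),
      target_total = as.integer(target_total),
      tolerance_halfwidth = as.integer(tolerance_halfwidth),
      effect_sizes = lapply(es[c("cogd", "uogd", "dlc")], as.numeric),
      n_blocks = as.integer(n_blocks),
      block_strength = as.numeric(block_strength),
      seed = as.integer(seed),
      covariates = covariates
    ),
    class = "sim_config"
  )
}

#' The four joint oil-and-gas development groups
#' @return character vector of the group labels.
#' @export
ogd_groups <- function() c("none", "cogd_only", "uogd_only", "both")

#' Functional feeding groups retained in analyses
#' @return the five analyzed FFG labels.
#' @export
analyzed_ffgs <- function() {
  c("collector-gatherer", "filter-collector", "predator", "scraper",
    "shredder")
}

#' Generate the synthetic taxon trait table
#'
#' Draws `n_taxa` taxa with order (Ephemeroptera / Plecoptera / Trichoptera /
#' other), functional feeding group, a pollution tolerance value in \[0, 10\],
#' a baseline log-abundance, and a latent co-occurrence block. EPT taxa are
#' drawn toward the sensitive end of the tolerance scale and non-EPT taxa
#' toward the tolerant end, so the sensitive-taxa metrics have signal to work
#' with. Each of the five analyzed FFGs is guaranteed at least one taxon.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `taxon_id`, `order`, `ffg`, `tolerance`,
#'   `base_log_abund`, `block`.
#' @export
generate_taxa <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_taxa
  ffg_levels <- c(analyzed_ffgs(), "unknown", "piercer")
  with_seed(substream_seed(config$seed, "taxa"), {
    ord <- sample(c("Ephemeroptera", "Plecoptera", "Trichoptera", "other"),
                  n, replace = TRUE, prob = c(0.15, 0.12, 0.13, 0.60))
    ffg <- sample(ffg_levels, n, replace = TRUE,
                  prob = c(0.28, 0.14, 0.20, 0.14, 0.14, 0.06, 0.04))
    # ensure all five analyzed FFGs are represented
    for (g in analyzed_ffgs()) {
      if (!any(ffg == g)) ffg[sample.int(n, 1L)] <- g
    }
    is_ept <- ord != "other"
    tol <- ifelse(is_ept, stats::runif(n, 0, 6), stats::runif(n, 2, 10))
    data.frame(
      taxon_id = sprintf("t%04d", seq_len(n)),
      order = ord,
      ffg = ffg,
      tolerance = round(tol, 3),
      base_log_abund = round(stats::rnorm(n, 0, 1), 6),
      block = sample.int(config$n_blocks, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

# per-taxon stress-response multiplier: sensitive taxa (tol < 5) carry
# positive weight so a negative planted slope depresses them under stress.
# tolerant taxa carry no direct term: because totals are fixed by the
# subsampling protocol, the multinomial reallocation raises their relative
# abundance mechanically ("tolerant persist"), without letting an absolute
# tolerant bloom reverse the richness response in unlucky taxon draws
tolerance_response <- function(tolerance) pmax((5 - tolerance) / 5, 0)

#' Generate synthetic BMI samples with planted stress effects
#'
#' For each stratum (HUC8 x OGD group) draws per-sample covariates, then
#' counts. The expected log-abundance of taxon t at sample i is
#' `base_t + s_i * m(tol_t) + block_strength * u[block(t), i]`, where
#' `s_i = b_cogd z(cogd_i) + b_uogd z(uogd_i) + b_dlc z(dlc_i)` is the
#' composite planted stress (z-scored planted well densities and developed
#' land cover weighted by the configured effect sizes), `m(tol) = (5-tol)/5`
#' grades the response by pollution tolerance (sensitive decline, tolerant
#' increase, for negative slopes under rising stress), and `u` is a shared
#' standard-normal site factor per latent block. Counts are a multinomial
#' allocation of a total drawn uniformly in `target_total +/-
#' tolerance_halfwidth`, mirroring the fixed-count subsampling protocol.
#'
#' @param config a [sim_config()].
#' @param taxa trait table from [generate_taxa()].
#' @return list with `samples` (covariate data.frame, one row per sample),
#'   `counts` (samples x taxa integer matrix, rownames = sample ids), and
#'   `truth` (planted slopes, per-sample stress and densities, block map).
#' @export
generate_samples <- function(config, taxa) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(taxa) || nrow(taxa) == 0L) stop("empty taxa table", call. = FALSE)
  strata <- names(config$samples_per_stratum)
  if (length(strata) == 0L) stop("empty stratum map", call. = FALSE)

  with_seed(substream_seed(config$seed, "samples"), {
    rows <- list()
    for (key in strata) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      h <- parts[1]; grp <- parts[2]
      n_s <- config$samples_per_stratum[[key]]
      area <- round(exp(stats::rnorm(n_s, log(8), 0.8)), 3)
      # development-present strata are guaranteed a density that rounds to
      # >= 1 well so attribution-based classification recovers the stratum
      cogd_d <- if (grp %in% c("cogd_only", "both")) {
        pmax(stats::rgamma(n_s, shape = 2, rate = 2), 0.6 / area)
      } else rep(0, n_s)
      uogd_d <- if (grp %in% c("uogd_only", "both")) {
        pmax(stats::rgamma(n_s, shape = 2, rate = 5), 0.6 / area)
      } else rep(0, n_s)
      cv <- config$covariates
      rows[[key]] <- data.frame(
        huc8 = h, ogd_group = grp,
        ecoregion = sample(paste0("ER", 1:5), n_s, replace = TRUE),
        amd_present = stats::runif(n_s) < cv$p_amd,
        dlc = round(cv$dlc_cap *
                      stats::rbeta(n_s, cv$dlc_shape[1], cv$dlc_shape[2]), 4),
        season = sample(c("spring", "fall"), n_s, replace = TRUE,
                        prob = c(1 - cv$p_fall, cv$p_fall)),
        stream_type = sample(c("wadeable", "semiwadeable"), n_s,
                             replace = TRUE, prob = c(1 - cv$p_semiwadeable,
                                                      cv$p_semiwadeable)),
        sample_date = as.Date("2005-01-01") +
          sample.int(6500L, n_s, replace = TRUE),
        catchment_area_km2 = area,
        cogd_density_true = round(cogd_d, 4),
        uogd_density_true = round(uogd_d, 4),
        stringsAsFactors = FALSE
      )
    }
    samples <- do.call(rbind, rows)
    rownames(samples) <- NULL
    n <- nrow(samples)
    samples$sample_id <- sprintf("s%05d", seq_len(n))
    samples <- samples[, c("sample_id", setdiff(names(samples), "sample_id"))]

    # composite planted stress
    zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    es <- config$effect_sizes
    stress <- es$cogd * zs(samples$cogd_density_true) +
      es$uogd * zs(samples$uogd_density_true) +
      es$dlc * zs(samples$dlc)

    resp <- tolerance_response(taxa$tolerance)           # length T
    u <- matrix(stats::rnorm(config$n_blocks * n), config$n_blocks, n)
    # log-lambda: n x T
    loglam <- outer(stress, resp) +
      matrix(taxa$base_log_abund, n, nrow(taxa), byrow = TRUE) +
      config$block_strength * t(u[taxa$block, , drop = FALSE])
    totals <- config$target_total +
      sample.int(2L * config$tolerance_halfwidth + 1L, n, replace = TRUE) -
      config$tolerance_halfwidth - 1L
    counts <- matrix(0L, n, nrow(taxa),
                     dimnames = list(samples$sample_id, taxa$taxon_id))
    for (i in seq_len(n)) {
      p <- exp(loglam[i, ] - max(loglam[i, ]))
      counts[i, ] <- as.integer(stats::rmultinom(1, totals[i], p))
    }
    truth <- list(
      effect_sizes = es,
      stress = stats::setNames(stress, samples$sample_id),
      block = stats::setNames(taxa$block, taxa$taxon_id),
      totals = stats::setNames(totals, samples$sample_id)
    )
    list(samples = samples, counts = counts, truth = truth)
  })
}

#' Generate synthetic well records consistent with planted densities
#'
#' Each sample owns a square planar catchment (side `sqrt(area)`) on a
#' non-overlapping grid. For each sample, `round(density * area)` active
#' wells of each development type are placed uniformly inside its catchment
#' with spud dates strictly before the sample date; additional decoy wells
#' (spudded after sampling, or inactive) are emitted to exercise the
#' attribution filters.
#'
#' @param samples sample covariate table from [generate_samples()].
#' @param config a [sim_config()].
#' @param decoy_rate expected number of decoy wells per sample (default 0.5).
#' @return list with `wells` (well record table), `catchments` (square
#'   polygon table: sample_id, vertex, x, y), and `membership`
#'   (well_id, sample_id).
#' @export
generate_wells <- function(samples, config, decoy_rate = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(samples) || nrow(samples) == 0L) {
    stop("empty samples table", call. = FALSE)
  }
  with_seed(substream_seed(config$seed, "wells"), {
    n <- nrow(samples)
    grid_step <- 2 * sqrt(max(samples$catchment_area_km2)) + 1
    ncol_grid <- ceiling(sqrt(n))
    cx <- ((seq_len(n) - 1L) %% ncol_grid) * grid_step
    cy <- ((seq_len(n) - 1L) %/% ncol_grid) * grid_step
    side <- sqrt(samples$catchment_area_km2)

    catchments <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(
        sample_id = samples$sample_id[i], vertex = 1:4,
        x = cx[i] + c(0, side[i], side[i], 0),
        y = cy[i] + c(0, 0, side[i], side[i])
      )
    }))

    wells <- list()
    wid <- 0L
    emit <- function(k, i, dev, status, pre_date) {
      if (k <= 0L) return(NULL)
      dt <- samples$sample_date[i]
      spud <- if (pre_date) dt - sample.int(3650L, k, replace = TRUE) else
        dt + sample.int(365L, k, replace = TRUE)
      data.frame(
        well_id = sprintf("w%06d", wid + seq_len(k)),
        x = cx[i] + stats::runif(k) * side[i],
        y = cy[i] + stats::runif(k) * side[i],
        dev_type = dev, status = status, spud_date = spud,
        sample_id = samples$sample_id[i],
        stringsAsFactors = FALSE
      )
    }
    for (i in seq_len(n)) {
      k_c <- as.integer(round(samples$cogd_density_true[i] *
                                samples$catchment_area_km2[i]))
      k_u <- as.integer(round(samples$uogd_density_true[i] *
                                samples$catchment_area_km2[i]))
      for (spec in list(list(k_c, "conventional"), list(k_u, "unconventional"))) {
        w <- emit(spec[[1]], i, spec[[2]], "active", TRUE)
        if (!is.null(w)) { wells[[length(wells) + 1L]] <- w; wid <- wid + nrow(w) }
      }
      # decoys: post-date actives and pre-date inactives, both excluded later
      n_dec <- stats::rpois(1, decoy_rate)
      if (n_dec > 0L) {
        post <- stats::runif(n_dec) < 0.5
        dev <- sample(c("conventional", "unconventional"), n_dec, replace = TRUE)
        for (j in seq_len(n_dec)) {
          w <- if (post[j]) emit(1L, i, dev[j], "active", FALSE) else
            emit(1L, i, dev[j], "inactive", TRUE)
          wells[[length(wells) + 1L]] <- w; wid <- wid + 1L
        }
      }
    }
    wells <- if (length(wells)) do.call(rbind, wells) else
      data.frame(well_id = character(), x = double(), y = double(),
                 dev_type = character(), status = character(),
                 spud_date = as.Date(character()), sample_id = character())
    rownames(wells) <- NULL
    membership <- wells[, c("well_id", "sample_id")]
    wells$sample_id <- NULL
    list(wells = wells, catchments = catchments, membership = membership)
  })
}
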