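#' Filter the network-eligible sample subset
#'
#' Retains samples that (i) were collected in spring, (ii) came from
#' wadeable streams, (iii) lack acid mine drainage in the catchment, and
#' (iv) have developed land cover at or below `dlc_max` (inclusive).
#'
#' @param samples sample covariate table.
#' @param dlc_max developed-land-cover ceiling (default 0.20).
#' @return the filtered sample table.
#' @export
filter_subset <- function(samples, dlc_max = 0.20) {
  keep <- samples$season == "spring" &
    samples$stream_type == "wadeable" &
    !samples$amd_present &
    samples$dlc <= dlc_max
  samples[keep, , drop = FALSE]
}

#' Joint oil-and-gas development classification
#'
#' Maps the two presence flags to the four-way label used for
#' stratification.
#'
#' @param cogd_present,uogd_present logical vectors.
#' @return character vector in `none`, `cogd_only`, `uogd_only`, `both`.
#' @export
classify_ogd <- function(cogd_present, uogd_present) {
  ifelse(cogd_present & uogd_present, "both",
         ifelse(cogd_present, "cogd_only",
                ifelse(uogd_present, "uogd_only", "none")))
}

#' Enumerate eligible strata
#'
#' One stratum per (HUC8, OGD group) combination with at least `min_n`
#' classified samples, ordered by HUC8 then group for determinism.
#'
#' @param subset filtered sample table with columns `huc8`, `ogd_group`,
#'   `sample_id`.
#' @param min_n minimum stratum size (default 15, boundary inclusive).
#' @return data.frame `huc8`, `ogd_group`, `n`, plus a list-column
#'   `members` of sample-id vectors.
#' @export
enumerate_strata <- function(subset, min_n = 15L) {
  key <- interaction(subset$huc8, factor(subset$ogd_group,
                                         levels = ogd_groups()),
                     sep = "|", drop = TRUE)
  members <- split(subset$sample_id, key)
  n <- lengths(members)
  keep <- n >= min_n
  keys <- names(members)[keep]
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    huc8 = vapply(parts, `[`, "", 1),
    ogd_group = vapply(parts, `[`, "", 2),
    n = as.integer(n[keep]),
    stringsAsFactors = FALSE
  )
  ord <- order(out$huc8, match(out$ogd_group, ogd_groups()))
  out <- out[ord, , drop = FALSE]
  out$members <- unname(members[keep])[ord]
  rownames(out) <- NULL
  out
}

#' Run the stratified network ensemble
#'
#' For each eligible stratum and each of `reps` replicates, draws `k`
#' samples without replacement (per-rep draws are independent, so a sample
#' may recur across replicates), builds the co-occurrence network (null
#' permutations, standardized effect sizes, Benjamini-Hochberg filter), and
#' records its topology and composition metrics together with the mean
#' surrogate IBI of the `k` subsampled samples. Each (stratum, rep) uses an
#' RNG substream keyed by `huc8|group|rep` derived from `seed`, so results
#' do not depend on processing order.
#'
#' @param counts samples x taxa count matrix for the filtered subset.
#' @param strata stratum table from [enumerate_strata()].
#' @param traits taxon trait table.
#' @param metrics per-sample metric table (for the network IBI); must cover
#'   all subset samples.
#' @param reps replicates per stratum (default 100).
#' @param k samples per network (default 10).
#' @param n_perm null permutations per network (default 100).
#' @param q_threshold FDR threshold for edge retention (default `1e-4`).
#' @param seed global integer seed.
#' @return data.frame with one row per (stratum, rep): `huc8`, `ogd_group`,
#'   `rep`, the [network_topology()] columns, and `ibi`.
#' @export
run_ensemble <- function(counts, strata, traits, metrics,
                         reps = 100L, k = 10L, n_perm = 100L,
                         q_threshold = 1e-4, seed = 1L) {
  stopifnot(reps >= 1L, k >= 2L)
  if (nrow(strata) == 0L) {
    stop("no eligible strata", call. = FALSE)
  }
  if (any(strata$n < k)) {
    stop("subsample size k exceeds a stratum size", call. = FALSE)
  }
  regional <- regional_stats(counts)
  ibi <- stats::setNames(metrics$ibi, metrics$sample_id)
  rows <- vector("list", nrow(strata) * reps)
  idx <- 0L
  for (s in seq_len(nrow(strata))) {
    memb <- strata$members[[s]]
    for (r in seq_len(reps)) {
      key <- paste(strata$huc8[s], strata$ogd_group[s], r, sep = "|")
      row <- with_seed(substream_seed(seed, key), {
        ids <- sample(memb, k)
        obs <- build_matrix(counts[ids, , drop = FALSE], regional,
                            expected_n = k)
        edges <- fdr_filter(ses_edges(obs, n_perm), q_threshold)
        topo <- network_topology(obs, edges, traits)
        cbind(data.frame(huc8 = strata$huc8[s],
                         ogd_group = strata$ogd_group[s], rep = r,
                         stringsAsFactors = FALSE),
              topo, data.frame(ibi = mean(ibi[ids])))
      })
      idx <- idx + 1L
      rows[[idx]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
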