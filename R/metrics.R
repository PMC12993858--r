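#' Taxon richness of a sample
#'
#' @param counts named (by taxon) nonnegative count vector.
#' @return number of taxa with count > 0.
#' @export
richness <- function(counts) {
  stopifnot(all(counts >= 0))
  sum(counts > 0)
}

#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i log p_i)` over taxa with positive counts. Dimensionless,
#' natural-log units; bounded by `log(richness)`.
#'
#' @param counts nonnegative count vector.
#' @return Shannon index, or an error for an empty sample.
#' @export
shannon <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("Shannon diversity undefined for empty sample",
                       call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Richness of sensitive EPT taxa
#'
#' Counts the present taxa that are both in one of the orders Ephemeroptera,
#' Plecoptera or Trichoptera *and* have pollution tolerance at most 4
#' (the tolerance 0-4 band is inclusive at 4).
#'
#' @param counts named nonnegative count vector (names = taxon ids).
#' @param traits trait table with `taxon_id`, `order`, `tolerance`.
#' @return integer EPT richness.
#' @export
ept_richness <- function(counts, traits) {
  present <- names(counts)[counts > 0]
  missing <- setdiff(present, traits$taxon_id)
  if (length(missing)) {
    stop("no trait row for taxa: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tr <- traits[match(present, traits$taxon_id), ]
  sum(tr$order %in% c("Ephemeroptera", "Plecoptera", "Trichoptera") &
        tr$tolerance <= 4)
}

#' Functional feeding group proportions of a sample
#'
#' Individual-based proportions over the five analyzed FFGs
#' (collector-gatherer, filter-collector, predator, scraper, shredder).
#' Individuals of taxa labelled `unknown` or `piercer` are removed from both
#' numerator and denominator before the proportions are formed.
#'
#' @param counts named nonnegative count vector.
#' @param traits trait table with `taxon_id`, `ffg`.
#' @return named numeric vector of length 5 summing to 1, or NAs (with a
#'   warning) when no classified individuals exist.
#' @export
ffg_proportions <- function(counts, traits) {
  ffg <- traits$ffg[match(names(counts), traits$taxon_id)]
  groups <- analyzed_ffgs()
  keep <- ffg %in% groups
  tot <- sum(counts[keep])
  out <- stats::setNames(rep(NA_real_, 5), groups)
  if (tot == 0) {
    warning("no individuals in analyzed FFGs; proportions undefined")
    return(out)
  }
  for (g in groups) out[g] <- sum(counts[keep & ffg == g]) / tot
  out
}

#' Mean pollution tolerance
#'
#' Unweighted mean over the present taxa (default), or abundance-weighted.
#'
#' @param counts named nonnegative count vector.
#' @param traits trait table with `taxon_id`, `tolerance`.
#' @param weighting `"unweighted"` (per-taxon) or `"abundance"`.
#' @return mean tolerance in \[0, 10\].
#' @export
mean_tolerance <- function(counts, traits,
                           weighting = c("unweighted", "abundance")) {
  weighting <- match.arg(weighting)
  present <- counts > 0
  if (!any(present)) stop("mean tolerance undefined for empty sample",
                          call. = FALSE)
  tol <- traits$tolerance[match(names(counts)[present], traits$taxon_id)]
  if (weighting == "unweighted") mean(tol) else
    sum(tol * counts[present]) / sum(counts[present])
}

#' Default calibration for the surrogate IBI
#'
#' Floor/ceiling pairs used to rescale each component metric to \[0, 100\].
#' Values reflect typical ranges of fixed-count (about 200-individual)
#' riffle samples; they are configuration, not estimates.
#'
#' @return named list of `c(floor, ceiling)` pairs for `richness`,
#'   `ept_richness`, `shannon` and `tolerance_score` (10 - mean tolerance).
#' @export
default_ibi_calibration <- function() {
  list(
    richness = c(0, 30),
    ept_richness = c(0, 15),
    shannon = c(0, 3),
    tolerance_score = c(0, 10)
  )
}

#' Surrogate index of biotic integrity
#'
#' A documented stand-in for agency composite indices: each component
#' (richness, EPT richness, Shannon diversity, and `10 - mean tolerance`) is
#' rescaled to \[0, 100\] by clamped linear interpolation between its
#' calibration floor and ceiling, and the IBI is the arithmetic mean of the
#' four component scores. Monotone nondecreasing in every component.
#'
#' @param metrics list or one-row data.frame with `richness`, `ept_richness`,
#'   `shannon`, `mean_tolerance`.
#' @param calibration named list of `c(floor, ceiling)` pairs; see
#'   [default_ibi_calibration()].
#' @return IBI score in \[0, 100\].
#' @export
surrogate_ibi <- function(metrics, calibration = default_ibi_calibration()) {
  need <- c("richness", "ept_richness", "shannon", "tolerance_score")
  if (!all(need %in% names(calibration))) {
    stop("calibration must cover: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vals <- c(
    richness = as.numeric(metrics$richness),
    ept_richness = as.numeric(metrics$ept_richness),
    shannon = as.numeric(metrics$shannon),
    tolerance_score = 10 - as.numeric(metrics$mean_tolerance)
  )
  scores <- vapply(need, function(k) {
    fc <- calibration[[k]]
    if (fc[1] == fc[2]) stop("calibration floor equals ceiling for ", k,
                             call. = FALSE)
    100 * min(1, max(0, (vals[k] - fc[1]) / (fc[2] - fc[1])))
  }, numeric(1))
  mean(scores)
}

#' Per-sample metric table
#'
#' Computes all sample-level bioassessment metrics for a counts matrix.
#'
#' @param counts samples x taxa integer matrix (rownames = sample ids).
#' @param traits taxon trait table.
#' @param calibration IBI calibration map.
#' @return data.frame with one row per sample: richness, shannon,
#'   ept_richness, mean_tolerance, ibi, and the five FFG proportions
#'   (columns prefixed `ffg_`).
#' @export
sample_metrics <- function(counts, traits,
                           calibration = default_ibi_calibration()) {
  rows <- lapply(rownames(counts), function(sid) {
    ct <- counts[sid, ]
    r <- richness(ct)
    h <- shannon(ct)
    e <- ept_richness(ct, traits)
    mt <- mean_tolerance(ct, traits)
    ffg <- suppressWarnings(ffg_proportions(ct, traits))
    ibi <- surrogate_ibi(
      list(richness = r, ept_richness = e, shannon = h, mean_tolerance = mt),
      calibration)
    cbind(data.frame(sample_id = sid, richness = r, shannon = h,
                     ept_richness = e, mean_tolerance = mt, ibi = ibi,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(
            ffg, paste0("ffg_", gsub("-", "_", names(ffg)))))))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
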