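#' Regional occurrence statistics for the null-community sampler
#'
#' From the full network-eligible sample subset, computes each taxon's
#' occurrence frequency (fraction of subset samples in which it is present)
#' and its pool of observed nonzero abundances. Null communities draw taxa
#' with probability proportional to these frequencies and abundances with
#' replacement from these pools, so null matrices are regionally realistic.
#'
#' @param counts samples x taxa integer matrix for the full filtered subset.
#' @return list with `frequency` (named numeric) and `pool` (named list of
#'   integer vectors), plus flattened-pool indices used internally.
#' @export
regional_stats <- function(counts) {
  freq <- colMeans(counts > 0)
  pool <- lapply(seq_len(ncol(counts)), function(j) {
    v <- counts[, j]
    as.integer(v[v > 0])
  })
  names(pool) <- colnames(counts)
  flat <- unlist(pool, use.names = FALSE)
  len <- lengths(pool)
  start <- cumsum(c(0L, len[-length(len)]))
  structure(list(frequency = freq, pool = pool,
                 flat = flat, pool_start = start, pool_len = len),
            class = "regional_stats")
}

#' Build the 10-sample observation matrix
#'
#' Restricts the taxon rows to taxa present in at least one of the 10
#' subsampled samples and attaches the regional statistics. Column order is
#' the input sample order.
#'
#' @param counts 10 x taxa integer matrix (rownames = the 10 sample ids).
#' @param regional a [regional_stats()] object for the full subset.
#' @param expected_n required number of samples (default 10, the field
#'   protocol; the ensemble's `k` when changed there).
#' @return object of class `obs_matrix`: list with `mat` (taxa x 10),
#'   `regional` (statistics restricted to the retained taxa).
#' @export
build_matrix <- function(counts, regional, expected_n = 10L) {
  stopifnot(inherits(regional, "regional_stats"), expected_n >= 2L)
  if (nrow(counts) != expected_n) {
    stop("exactly ", expected_n, " samples required", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  keep <- colSums(counts > 0) > 0
  mat <- t(counts[, keep, drop = FALSE])
  idx <- match(rownames(mat), names(regional$frequency))
  if (anyNA(idx)) stop("taxa missing from regional statistics", call. = FALSE)
  structure(list(
    mat = mat,
    regional = list(
      frequency = regional$frequency[idx],
      flat = regional$flat,
      pool_start = regional$pool_start[idx],
      pool_len = regional$pool_len[idx]
    )
  ), class = "obs_matrix")
}

#' Draw one richness-preserving null community matrix
#'
#' For each site (column), the null community has exactly the observed
#' site richness: that many taxa are drawn without replacement with
#' probability proportional to regional occurrence frequency, and each drawn
#' taxon's abundance is sampled with replacement from its regional pool of
#' observed nonzero abundances. Uses the current RNG stream.
#'
#' @param obs an `obs_matrix`.
#' @return taxa x 10 integer matrix with the same dimnames as `obs$mat`.
#' @export
null_matrix <- function(obs) {
  mat <- obs$mat
  nt <- nrow(mat)
  freq <- obs$regional$frequency
  if (any(freq <= 0)) {
    stop("regional frequency must be positive for all taxa in the matrix",
         call. = FALSE)
  }
  rich <- colSums(mat > 0)
  if (any(rich > nt)) stop("site richness exceeds taxon pool", call. = FALSE)
  out <- matrix(0L, nt, ncol(mat), dimnames = dimnames(mat))
  reg <- obs$regional
  for (j in seq_len(ncol(mat))) {
    r <- rich[j]
    if (r == 0L) next
    drawn <- sample.int(nt, r, prob = freq)
    # vectorized with-replacement draw from each taxon's abundance pool
    pick <- reg$pool_start[drawn] +
      floor(stats::runif(r) * reg$pool_len[drawn]) + 1
    out[drawn, j] <- reg$flat[pick]
  }
  out
}

#' Pairwise co-occurrence statistic
#'
#' Pearson correlation of `log(x + 1)`-transformed abundance vectors across
#' the 10 sites; `NA` when either vector has zero variance.
#'
#' @param x,y site abundance vectors of equal length.
#' @return correlation in \[-1, 1\] or `NA`.
#' @export
pair_statistic <- function(x, y) {
  lx <- log1p(x); ly <- log1p(y)
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) return(NA_real_)
  stats::cor(lx, ly)
}

# full pairwise statistic matrix; NA rows/cols for zero-variance taxa.
# hand-rolled centered crossprod: called ~100x per network, so this is the
# pipeline's hot path and avoids cor()'s per-call overhead
pair_statistic_matrix <- function(mat) {
  x <- log1p(t(mat))                       # sites x taxa
  n <- nrow(x)
  x <- x - rep(colMeans(x), each = n)
  cv <- crossprod(x) / (n - 1)
  v <- diag(cv)
  r <- cv / tcrossprod(sqrt(v))
  bad <- v < 1e-20                         # constant vector up to rounding
  if (any(bad)) {
    r[bad, ] <- NA_real_
    r[, bad] <- NA_real_
  }
  r
}

#' Standardized effect sizes of all taxon pairs
#'
#' Compares each pair's observed statistic to its distribution over `n_perm`
#' richness-preserving null matrices:
#' `ses = (r_obs - mean(r_null)) / sd(r_null)` (sample sd, n-1 denominator),
#' with a two-sided p-value from the standard normal approximation,
#' `p = 2 (1 - Phi(|ses|))`. Pairs whose observed statistic is undefined,
#' with fewer than 2 defined null values, or with zero null spread are
#' excluded.
#'
#' @param obs an `obs_matrix`.
#' @param n_perm number of null permutations (default 100).
#' @return data.frame (class `edge_table`) with columns `taxon_a`, `taxon_b`,
#'   `r_obs`, `null_mean`, `null_sd`, `ses`, `p`.
#' @export
ses_edges <- function(obs, n_perm = 100L) {
  stopifnot(n_perm >= 2L)
  mat <- obs$mat
  nt <- nrow(mat)
  taxa <- rownames(mat)
  r_obs <- pair_statistic_matrix(mat)
  s1 <- matrix(0, nt, nt); s2 <- matrix(0, nt, nt)
  n_ok <- matrix(0L, nt, nt)
  for (b in seq_len(n_perm)) {
    rn <- pair_statistic_matrix(null_matrix(obs))
    ok <- !is.na(rn)
    rn[!ok] <- 0
    s1 <- s1 + rn
    s2 <- s2 + rn * rn
    n_ok <- n_ok + ok
  }
  if (nt < 2L) {
    return(empty_edge_table())
  }
  ut <- upper.tri(r_obs)
  ia <- row(r_obs)[ut]; ib <- col(r_obs)[ut]
  m <- n_ok[ut]
  mu <- ifelse(m > 0, s1[ut] / m, NA_real_)
  varn <- ifelse(m > 1, (s2[ut] - m * mu^2) / (m - 1), NA_real_)
  varn[varn < 0] <- 0  # guard tiny negative from rounding
  sdn <- sqrt(varn)
  ro <- r_obs[ut]
  keep <- !is.na(ro) & m >= 2L & !is.na(sdn) & sdn > 0
  ses <- (ro[keep] - mu[keep]) / sdn[keep]
  out <- data.frame(
    taxon_a = taxa[ia[keep]], taxon_b = taxa[ib[keep]],
    r_obs = ro[keep], null_mean = mu[keep], null_sd = sdn[keep],
    ses = ses, p = 2 * stats::pnorm(-abs(ses)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("edge_table", "data.frame")
  out
}

empty_edge_table <- function() {
  out <- data.frame(taxon_a = character(), taxon_b = character(),
                    r_obs = double(), null_mean = double(),
                    null_sd = double(), ses = double(), p = double(),
                    stringsAsFactors = FALSE)
  class(out) <- c("edge_table", "data.frame")
  out
}

#' Benjamini-Hochberg edge filter
#'
#' Adjusts the pair p-values by the Benjamini-Hochberg step-up procedure
#' over all tested pairs of the network and flags edges with adjusted
#' `q < q_threshold` as retained.
#'
#' @param edges edge table from [ses_edges()].
#' @param q_threshold FDR threshold (default `1e-4`).
#' @return the edge table with added columns `q` and `retained`.
#' @export
fdr_filter <- function(edges, q_threshold = 1e-4) {
  stopifnot(all(edges$p >= 0 & edges$p <= 1))
  edges$q <- stats::p.adjust(edges$p, method = "BH")
  edges$retained <- edges$q < q_threshold
  edges
}

#' Topology and composition metrics of a filtered network
#'
#' Size counts every taxon row of the observation matrix (isolated taxa
#' included); connectance is retained edges over `size (size - 1) / 2`;
#' mean strength is the mean `|ses|` over retained edges (0 for an empty
#' edge set); modularity is Newman's Q of the partition found by
#' deterministic greedy agglomeration on the `|ses|`-weighted retained
#' edges (0 for an empty edge set). Composition metrics are unweighted over
#' the node taxa: mean pollution tolerance and FFG proportions over the
#' five analyzed groups.
#'
#' @param obs an `obs_matrix`.
#' @param edges FDR-filtered edge table (with `retained`).
#' @param traits taxon trait table.
#' @return one-row data.frame: `size`, `n_edges`, `connectance`,
#'   `modularity`, `mean_strength`, `mean_tolerance`, and `ffg_*` node
#'   proportions.
#' @export
network_topology <- function(obs, edges, traits) {
  taxa <- rownames(obs$mat)
  size <- length(taxa)
  if (size < 2L) stop("connectance undefined for networks of size < 2",
                      call. = FALSE)
  ret <- edges[edges$retained, , drop = FALSE]
  n_edges <- nrow(ret)
  connectance <- n_edges / (size * (size - 1) / 2)
  if (n_edges > 0L) {
    mean_strength <- mean(abs(ret$ses))
    part <- greedy_modularity(ret$taxon_a, ret$taxon_b, abs(ret$ses))
    modularity <- part$q
  } else {
    mean_strength <- 0
    modularity <- 0
  }
  tr <- traits[match(taxa, traits$taxon_id), ]
  ffg_ok <- tr$ffg %in% analyzed_ffgs()
  ffg_prop <- if (any(ffg_ok)) {
    tab <- table(factor(tr$ffg[ffg_ok], levels = analyzed_ffgs()))
    as.numeric(tab) / sum(tab)
  } else rep(NA_real_, 5)
  out <- data.frame(
    size = size, n_edges = n_edges, connectance = connectance,
    modularity = modularity, mean_strength = mean_strength,
    mean_tolerance = mean(tr$tolerance)
  )
  out[paste0("ffg_", gsub("-", "_", analyzed_ffgs()))] <- as.list(ffg_prop)
  out
}

#' Convert a filtered network to an igraph object
#'
#' Nodes are the observation-matrix taxa (with `ffg` and `tolerance`
#' attributes); edges are the retained pairs with their `ses` weight.
#'
#' @param obs an `obs_matrix`.
#' @param edges FDR-filtered edge table.
#' @param traits taxon trait table.
#' @return an igraph graph.
#' @export
network_to_igraph <- function(obs, edges, traits) {
  taxa <- rownames(obs$mat)
  tr <- traits[match(taxa, traits$taxon_id), ]
  vert <- data.frame(name = taxa, ffg = tr$ffg, tolerance = tr$tolerance,
                     stringsAsFactors = FALSE)
  ret <- edges[edges$retained, c("taxon_a", "taxon_b", "ses"), drop = FALSE]
  igraph::graph_from_data_frame(ret, directed = FALSE, vertices = vert)
}

#' Export a network as GraphML
#'
#' @param graph an igraph graph (see [network_to_igraph()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
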