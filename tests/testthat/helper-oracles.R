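# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: per-pair loops, stats::cor / mean / sd, and an
# explicit reimplementation of the null-community sampler. RNG consumption
# order matches the documented sampler (per site: one weighted
# without-replacement draw, then one uniform per drawn taxon) so seeded runs
# are comparable draw-for-draw.

oracle_null_matrix <- function(mat, freq, pool) {
  nt <- nrow(mat)
  out <- matrix(0L, nt, ncol(mat), dimnames = dimnames(mat))
  for (j in seq_len(ncol(mat))) {
    r <- sum(mat[, j] > 0)
    if (r == 0) next
    drawn <- sample.int(nt, r, prob = freq)
    u <- stats::runif(r)
    for (k in seq_along(drawn)) {
      pl <- pool[[drawn[k]]]
      out[drawn[k], j] <- pl[floor(u[k] * length(pl)) + 1]
    }
  }
  out
}

oracle_pair_r <- function(x, y) {
  lx <- log1p(x); ly <- log1p(y)
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) return(NA_real_)
  stats::cor(lx, ly)
}

oracle_ses_edges <- function(mat, freq, pool, n_perm) {
  nt <- nrow(mat)
  taxa <- rownames(mat)
  nulls <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    nulls[[b]] <- oracle_null_matrix(mat, freq, pool)
  }
  rows <- list()
  for (a in seq_len(nt - 1)) {
    for (b2 in seq((a + 1), nt)) {
      ro <- oracle_pair_r(mat[a, ], mat[b2, ])
      rn <- vapply(nulls, function(nm) oracle_pair_r(nm[a, ], nm[b2, ]),
                   numeric(1))
      rn <- rn[!is.na(rn)]
      if (is.na(ro) || length(rn) < 2) next
      s <- stats::sd(rn)
      if (s == 0) next
      ses <- (ro - mean(rn)) / s
      rows[[length(rows) + 1]] <- data.frame(
        taxon_a = taxa[a], taxon_b = taxa[b2], ses = ses,
        p = 2 * stats::pnorm(-abs(ses)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# brute-force rectangle containment for the well-assignment oracle
oracle_assign_rect <- function(wells, rects) {
  out <- list()
  for (i in seq_len(nrow(rects))) {
    hit <- wells$x >= rects$x0[i] & wells$x <= rects$x1[i] &
      wells$y >= rects$y0[i] & wells$y <= rects$y1[i]
    if (any(hit)) {
      out[[i]] <- data.frame(well_id = wells$well_id[hit],
                             sample_id = rects$sample_id[i],
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
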