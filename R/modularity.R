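#' Newman modularity of a weighted partition
#'
#' `Q = sum_c (e_cc - a_c^2)` where `e_cd` is the fraction of total edge
#' weight (each edge counted in both directions) between communities `c` and
#' `d`, and `a_c = sum_d e_cd`. For a complete unit-weight graph under the
#' single-community partition Q is exactly 0.
#'
#' @param from,to character vectors of edge endpoints.
#' @param weight positive edge weights.
#' @param membership named vector mapping every node to a community label.
#' @return modularity Q in \[-0.5, 1\].
#' @export
modularity_q <- function(from, to, weight, membership) {
  stopifnot(length(from) == length(to), length(from) == length(weight),
            all(weight > 0))
  m2 <- 2 * sum(weight)
  cf <- as.character(membership[from])
  ct <- as.character(membership[to])
  comms <- unique(as.character(membership))
  e_cc <- vapply(comms, function(c) 2 * sum(weight[cf == c & ct == c]) / m2,
                 numeric(1))
  deg <- tapply(c(weight, weight), c(cf, ct), sum)
  a_c <- vapply(comms, function(c) {
    d <- deg[c]; if (is.na(d)) 0 else d / m2
  }, numeric(1))
  sum(e_cc - a_c^2)
}

#' Deterministic greedy modularity maximization
#'
#' Agglomerative community detection on a weighted undirected graph: start
#' from singleton communities and repeatedly merge the pair of connected
#' communities with the largest modularity gain, stopping when no merge
#' increases Q. Ties (within 1e-12) are broken lexicographically by the
#' sorted pair of community labels, so the result is fully deterministic.
#' Communities are labelled by their lexicographically smallest member node.
#'
#' @param from,to character vectors of edge endpoints.
#' @param weight positive edge weights.
#' @return list with `membership` (named by node), `q` (modularity of the
#'   final partition).
#' @export
greedy_modularity <- function(from, to, weight) {
  nodes <- sort(unique(c(from, to)))
  if (!length(nodes)) return(list(membership = character(0), q = 0))
  m2 <- 2 * sum(weight)
  # community adjacency e (both directions / 2m) over current communities
  comm <- stats::setNames(nodes, nodes)   # node -> community label
  labels <- nodes
  e <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (k in seq_along(from)) {
    w <- weight[k] / m2
    e[from[k], to[k]] <- e[from[k], to[k]] + w
    e[to[k], from[k]] <- e[to[k], from[k]] + w
  }
  a <- rowSums(e)
  repeat {
    # labels stay sorted, so index order (ci < cj) is lexicographic order
    best <- NULL; best_gain <- 0
    for (ci in seq_along(labels)) {
      for (cj in seq_along(labels)) {
        if (cj <= ci) next
        la <- labels[ci]; lb <- labels[cj]
        if (e[la, lb] == 0) next
        gain <- 2 * (e[la, lb] - a[la] * a[lb])
        if (gain <= 1e-12) next
        if (gain > best_gain + 1e-12) {
          best <- c(la, lb); best_gain <- gain
        }
        # within-tolerance ties keep the earlier (lexicographically
        # smaller) pair, i.e. do nothing
      }
    }
    if (is.null(best)) break
    keep <- best[1]; drop <- best[2]
    e[keep, ] <- e[keep, ] + e[drop, ]
    e[, keep] <- e[, keep] + e[, drop]
    a[keep] <- a[keep] + a[drop]
    labels <- setdiff(labels, drop)
    e <- e[labels, labels, drop = FALSE]
    a <- a[labels]
    comm[comm == drop] <- keep
  }
  q <- modularity_q(from, to, weight, comm)
  list(membership = comm, q = q)
}
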