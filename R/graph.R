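# Weighted network metrics on coherence graphs: clustering coefficient
# (CLU), local efficiency (LE), global efficiency (GE) and characteristic
# path length (L), in the standard weighted (BCT) forms. Edge length is
# 1/weight by default: strongly coherent pairs are topologically close.

#' Weighted graph from raw weights
#'
#' @param weights N x N symmetric numeric matrix, entries in `[0, 1]`,
#'   zero diagonal (a unit diagonal is zeroed with a note that self-loops
#'   are excluded).
#' @param labels Optional node names.
#' @return Object of class `"weighted_graph"`.
#' @export
weighted_graph <- function(weights, labels = NULL) {
  w <- as.matrix(weights)
  if (nrow(w) != ncol(w)) stop("`weights` must be square")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-8)))
    stop("`weights` must be symmetric")
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  diag(w) <- 0
  if (is.null(labels)) labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(w)))
  dimnames(w) <- list(labels, labels)
  structure(list(weights = w, labels = labels, n = nrow(w)),
            class = "weighted_graph")
}

#' Weighted graph from a coherence matrix
#'
#' Copies the coherence values as edge weights, zeroes the diagonal
#' (self-loops excluded) and preserves labels. No thresholding or
#' binarization is applied: the network stays fully weighted.
#'
#' @param cm A `"coherence_matrix"`.
#' @return A `"weighted_graph"`.
#' @export
from_coherence <- function(cm) {
  validate_coherence_matrix(cm)
  weighted_graph(cm$values, cm$labels)
}

as_weighted_graph <- function(g) {
  if (inherits(g, "coherence_matrix")) from_coherence(g)
  else if (inherits(g, "weighted_graph")) g
  else weighted_graph(g)
}

#' All-pairs shortest path lengths
#'
#' Edge length is `1/w` for `w > 0` (the usual coherence-network
#' convention: strong edges are short), or `1 - w` if
#' `lengths = "one_minus"`. Distances are summed minimal path lengths
#' (Dijkstra from every source); unreachable pairs are `Inf`.
#'
#' @param g A `"weighted_graph"` (or coercible).
#' @param lengths Edge-length convention, `"inverse"` (default) or
#'   `"one_minus"`.
#' @return N x N symmetric matrix with zero diagonal.
#' @export
shortest_paths <- function(g, lengths = c("inverse", "one_minus")) {
  g <- as_weighted_graph(g)
  lengths <- match.arg(lengths)
  w <- g$weights
  len <- matrix(Inf, g$n, g$n)
  pos <- w > 0
  len[pos] <- if (lengths == "inverse") 1 / w[pos] else 1 - w[pos]
  d <- matrix(Inf, g$n, g$n, dimnames = dimnames(w))
  for (src in seq_len(g$n)) {
    dist <- rep(Inf, g$n)
    dist[src] <- 0
    done <- rep(FALSE, g$n)
    for (step in seq_len(g$n)) {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      relax <- !done & is.finite(len[u, ])
      dist[relax] <- pmin(dist[relax], dist[u] + len[u, relax])
    }
    d[src, ] <- dist
  }
  diag(d) <- 0
  d
}

#' Global efficiency
#'
#' Mean inverse shortest path length:
#' `GE = (1/N) * sum_i [ sum_{j != i} 1/d_ij / (N - 1) ]`.
#' Unreachable pairs contribute 0.
#'
#' @inheritParams shortest_paths
#' @return Scalar in `[0, 1]` when all weights lie in `[0, 1]`.
#' @export
global_efficiency <- function(g, lengths = "inverse") {
  g <- as_weighted_graph(g)
  if (g$n < 2) stop("global efficiency requires >= 2 nodes")
  d <- shortest_paths(g, lengths)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  mean(rowSums(inv) / (g$n - 1))
}

#' Characteristic path length
#'
#' Mean shortest path length:
#' `L = (1/N) * sum_i [ sum_{j != i} d_ij / (N - 1) ]`.
#' Unreachable pairs are excluded from the mean with a warning; a node with
#' no finite path to any other node is an error.
#'
#' @inheritParams shortest_paths
#' @return Positive scalar (>= 1 when all weights are <= 1 and the edge
#'   length convention is `1/w`).
#' @export
characteristic_path_length <- function(g, lengths = "inverse") {
  g <- as_weighted_graph(g)
  if (g$n < 2) stop("path length requires >= 2 nodes")
  d <- shortest_paths(g, lengths)
  diag(d) <- NA
  if (any(apply(d, 1, function(r) all(!is.finite(r) | is.na(r)))))
    stop("graph contains a fully disconnected node; L is undefined")
  if (any(!is.finite(d) & !is.na(d))) {
    warning("disconnected node pairs excluded from the path-length mean")
    d[!is.finite(d)] <- NA
  }
  mean(apply(d, 1, mean, na.rm = TRUE))
}

#' Weighted clustering coefficient
#'
#' Onnela-form weighted clustering, averaged over nodes:
#' `C_i = sum_{j,l} (w_hat_ij * w_hat_il * w_hat_jl)^(1/3) / (k_i (k_i - 1))`
#' where `k_i` counts nonzero edges at `i`. Nodes with fewer than two
#' neighbours contribute 0.
#'
#' With `normalize = "graph_max"` (the generic recipe for weights of
#' arbitrary units) `w_hat = w / max(w)`. With `normalize = "none"`,
#' `w_hat = w`: appropriate for coherence, which already lives on an
#' absolute `[0, 1]` scale -- per-graph max normalization would make CLU
#' blind to overall coupling strength and is not comparable across
#' networks (see [network_properties()], which therefore defaults to raw
#' weights).
#'
#' @inheritParams shortest_paths
#' @param normalize `"graph_max"` (default) or `"none"`.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(g, normalize = c("graph_max", "none")) {
  g <- as_weighted_graph(g)
  normalize <- match.arg(normalize)
  if (g$n < 3) stop("clustering requires >= 3 nodes")
  w <- g$weights
  mx <- if (normalize == "graph_max") max(w) else 1
  if (max(w) == 0) return(0)
  wh <- (w / mx)^(1 / 3)
  cyc <- diag(wh %*% wh %*% wh)          # 2 * triangle intensity per node
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  mean(ci)
}

#' Weighted local efficiency
#'
#' For each node `i`, efficiency of its neighbourhood subgraph (excluding
#' `i` itself): `LE_i = sum_{j != l in N(i)} (w_ij * w_il / d_jl(N_i))^(1/3)
#' / (k_i (k_i - 1))`, where `d_jl(N_i)` is the shortest path length between
#' neighbours `j` and `l` restricted to the subgraph on `N(i)`, with edge
#' length `1/w`. Nodes with fewer than two neighbours contribute 0;
#' unreachable neighbour pairs contribute 0.
#'
#' @inheritParams shortest_paths
#' @return Scalar in `[0, 1]` when weights lie in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  g <- as_weighted_graph(g)
  if (g$n < 3) stop("local efficiency requires >= 3 nodes")
  w <- g$weights
  le <- numeric(g$n)
  for (i in seq_len(g$n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- weighted_graph(w[nb, nb, drop = FALSE])
    dsub <- shortest_paths(sub)
    winv <- 1 / dsub
    diag(winv) <- 0
    winv[!is.finite(winv)] <- 0
    terms <- (outer(w[i, nb], w[i, nb]) * winv)^(1 / 3)
    diag(terms) <- 0
    le[i] <- sum(terms) / (k * (k - 1))
  }
  mean(le)
}

#' All four weighted network properties of a coherence network
#'
#' Bundles the clustering coefficient (CLU), local efficiency (LE), global
#' efficiency (GE) and characteristic path length (L) of a coherence
#' network, together with the shortest-path matrix and the edge-length
#' convention used.
#'
#' Because coherence weights are on an absolute `[0, 1]` scale, the
#' clustering coefficient is computed on raw weights by default
#' (`clu_normalize = "none"`): per-graph max normalization would cancel
#' genuine between-network differences in coupling strength.
#'
#' @param cm A `"coherence_matrix"` or `"weighted_graph"`.
#' @param lengths Edge-length convention passed to [shortest_paths()].
#' @param clu_normalize Normalization passed to [clustering_coefficient()].
#' @return Object of class `"network_metrics"`: `clu`, `le`, `ge`,
#'   `path_length`, `d`, `lengths`.
#' @export
network_properties <- function(cm, lengths = "inverse",
                               clu_normalize = "none") {
  g <- as_weighted_graph(cm)
  structure(list(clu = clustering_coefficient(g, clu_normalize),
                 le = local_efficiency(g),
                 ge = global_efficiency(g, lengths),
                 path_length = characteristic_path_length(g, lengths),
                 d = shortest_paths(g, lengths),
                 lengths = lengths),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> CLU=%.4f LE=%.4f GE=%.4f L=%.4f (%s lengths)\n",
              x$clu, x$le, x$ge, x$path_length, x$lengths))
  invisible(x)
}
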