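#' Classical Weisfeiler-Lehman vertex relabeling
#'
#' The classical 1-dimensional WL procedure: every vertex repeatedly forms a
#' signature from its own label and the sorted labels of its immediate
#' neighbours; signatures are sorted lexicographically and vertices are
#' relabelled by signature rank (equal signatures share a label). Iteration
#' stops when the labelling stabilises or after `max_iters` rounds. Used in
#' this package as a reference ordering oracle; the production ordering is
#' [palette_wl()].
#'
#' @param adjacency square 0/1 adjacency matrix of a simple graph.
#' @param init_labels optional integer start labels (default: all 1).
#' @param max_iters iteration cap.
#' @return Integer vector of final labels (dense, starting at 1); empty
#'   input gives an empty vector.
#' @export
wl_classical <- function(adjacency, init_labels = NULL, max_iters = 50L) {
  adjacency <- as.matrix(adjacency)
  nv <- nrow(adjacency)
  if (nv == 0L) return(integer(0))
  labels <- if (is.null(init_labels)) rep(1L, nv) else as.integer(init_labels)
  stopifnot(length(labels) == nv)
  for (iter in seq_len(max_iters)) {
    sig <- vapply(seq_len(nv), function(v) {
      nb <- sort(labels[adjacency[v, ] != 0])
      paste(sprintf("%06d", c(labels[v], nb)), collapse = "|")
    }, character(1))
    new_labels <- match(sig, sort(unique(sig)))
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  labels
}

# Hop distances from both anchors over interaction edges (anchor edge
# already removed). Unreachable vertices are capped at 2K.
anchor_distances <- function(sub) {
  nv <- nrow(sub$vertices)
  g <- igraph::graph_from_adjacency_matrix(sub$dti_adj, mode = "undirected")
  d <- igraph::distances(g, v = c(1, 2))
  d[is.infinite(d)] <- 2 * sub$K
  pmin(d, 2 * sub$K)
}

#' Geometric mean distance to the anchor pair
#'
#' For each subgraph vertex, the geometric mean of its hop distances (over
#' interaction edges, the anchor edge having been removed) to the anchor
#' drug and the anchor target: `sqrt(dist(v, d_i) * dist(v, t_j))`.
#' `dist(v, v) = 0`, and unreachable vertices are capped at `2K`. Both
#' anchors therefore always score 0.
#'
#' @param sub a `dti_subgraph`.
#' @param v position(s) within `sub$vertices` (default: all vertices).
#' @return Numeric vector of geometric mean distances.
#' @export
geometric_mean_distance <- function(sub, v = seq_len(nrow(sub$vertices))) {
  stopifnot(inherits(sub, "dti_subgraph"))
  if (any(v < 1 | v > nrow(sub$vertices))) stop("vertex not in subgraph")
  d <- anchor_distances(sub)
  sqrt(d[1, v] * d[2, v])
}

#' Initial colours from geometric mean distances
#'
#' Dense ranking of the geometric mean distances: the smallest distance
#' maps to colour 1, the next distinct distance to colour 2, and so on;
#' equal distances share a colour. Both anchors always receive colour 1.
#'
#' @param sub a `dti_subgraph`.
#' @return Integer vector of colours, one per subgraph vertex.
#' @export
initial_colors <- function(sub) {
  gmd <- geometric_mean_distance(sub)
  match(gmd, sort(unique(gmd)))
}

# Dense-rank real values with a small tolerance so that sums of identical
# multisets accumulated in different orders still collapse to one colour.
dense_rank_tol <- function(x, tol = 1e-9) {
  ord <- order(x)
  r <- integer(length(x))
  col <- 1L
  r[ord[1]] <- col
  if (length(x) > 1L) {
    for (k in 2:length(x)) {
      if (x[ord[k]] - x[ord[k - 1]] > tol) col <- col + 1L
      r[ord[k]] <- col
    }
  }
  r
}

#' Palette-WL vertex ordering of an enclosing subgraph
#'
#' Orders the vertices of an enclosing subgraph so that vertices closer to
#' the anchor pair come first and structurally equivalent vertices from
#' different subgraphs land on similar ranks. Vertices start from the
#' colours of [initial_colors()] (geometric mean distance to the anchors)
#' and are iteratively refined by an order-preserving hash:
#' `h(v) = c(v) + g(v)` with
#' `g(v) = sum(log p(c(u)), u in N(v)) / (1 + sum(log p(c(u)), u in V))`,
#' where `p(c)` is the c-th prime (p(1) = 2) and neighbourhoods follow
#' interaction edges. Because `g < 1` the integer colour always dominates,
#' so the initial colour order is preserved at every iteration; refinement
#' stops when the colouring stabilises. Residual ties are broken
#' deterministically by (initial colour, drug before target, identifier),
#' yielding a bijective ranking: the anchors always occupy ranks 1 and 2.
#'
#' @param sub a `dti_subgraph`.
#' @param max_iters iteration cap (default `2 * nv`); if refinement has not
#'   stabilised by then, the deterministic tie-break is applied and a
#'   warning is issued.
#' @return An object of class `dti_ordering`: list with `ranks` (bijection
#'   onto `1..nv`), `initial_colors`, `colors` (final refined colours),
#'   `iterations`, `converged`.
#' @export
palette_wl <- function(sub, max_iters = NULL) {
  stopifnot(inherits(sub, "dti_subgraph"))
  nv <- nrow(sub$vertices)
  if (nv == 0L) stop("empty subgraph")
  if (is.null(max_iters)) max_iters <- 2L * nv
  init <- initial_colors(sub)
  cols <- init
  primes <- prime_table(nv)
  adj <- sub$dti_adj
  converged <- FALSE
  iterations <- 0L
  repeat {
    if (iterations >= max_iters) break
    iterations <- iterations + 1L
    logp <- log(primes[cols])
    g <- as.vector(adj %*% logp) / (1 + sum(logp))
    new_cols <- dense_rank_tol(cols + g)
    if (identical(new_cols, cols)) {
      converged <- TRUE
      break
    }
    cols <- new_cols
  }
  if (!converged && iterations >= max_iters && max_iters > 0L) {
    # colouring still moving: fall back on the deterministic tie-break
    warning("palette_wl did not stabilise after ", max_iters,
            " iterations; deterministic tie-break applied")
  }
  ord <- order(cols, init, sub$vertices$role != "drug", sub$vertices$id)
  ranks <- integer(nv)
  ranks[ord] <- seq_len(nv)
  structure(
    list(ranks = ranks, initial_colors = init, colors = cols,
         iterations = iterations, converged = converged),
    class = "dti_ordering"
  )
}

#' @export
print.dti_ordering <- function(x, ...) {
  cat("<dti_ordering> ", length(x$ranks), " vertices, ",
      x$iterations, " refinement iterations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Tabulate a vertex ordering
#'
#' @param x a `dti_ordering`.
#' @param sub the `dti_subgraph` it was computed from.
#' @param ... unused.
#' @return A tibble with columns `id`, `role`, `initial_color`, `color`,
#'   `rank`, sorted by rank.
#' @export
ordering_table <- function(x, sub, ...) {
  stopifnot(inherits(x, "dti_ordering"), inherits(sub, "dti_subgraph"))
  out <- tibble::tibble(
    id = sub$vertices$id, role = sub$vertices$role,
    initial_color = x$initial_colors, color = x$colors, rank = x$ranks
  )
  out[order(out$rank), ]
}

# First nv primes (2, 3, 5, ...), cached.
prime_table <- local({
  cache <- c(2L, 3L, 5L, 7L, 11L, 13L)
  function(k) {
    while (length(cache) < k) {
      upper <- max(100, ceiling(k * (log(k) + log(log(k + 2)) + 2)))
      cache <<- as.integer(pracma::primes(upper))
    }
    cache[seq_len(max(k, 1L))]
  }
})
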