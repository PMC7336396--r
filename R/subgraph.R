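#' Extract the K-vertex enclosing subgraph of a drug-target pair
#'
#' The enclosing subgraph captures the local interaction environment of an
#' anchor pair (d_i, t_j). Starting from the two anchors, all first-hop
#' interaction neighbours (targets of d_i, drugs of t_j) are added. While
#' fewer than `K` vertices are present, a pool of the current frontier's
#' unexplored interaction neighbours is built and admitted in decreasing
#' similarity to the anchors (drugs scored by `S_D[i, .]`, targets by
#' `S_T[j, .]`, on the shared \[0, 1\] scale; ties broken drugs-first, then
#' by identifier). If the first hop alone exceeds `K`, the vertices are
#' ordered with [palette_wl()] and the lowest-ranked non-anchor vertices are
#' discarded. Subgraphs smaller than `K` are padded (recorded in
#' `padded_count`) so that every pair maps to exactly `K` encoding slots.
#'
#' The anchor pair's own interaction edge, when present, is removed from the
#' induced subgraph, so positive and negative training pairs are
#' distinguished only through their neighbourhoods, never through the label
#' itself.
#'
#' @param net a [dti_network].
#' @param i drug index (1-based).
#' @param j target index (1-based).
#' @param K subgraph size, at least 2.
#' @return An object of class `dti_subgraph`: a list with `vertices` (tibble
#'   `role`, `index`, `id`; anchors in rows 1-2), `dti_adj` (binary
#'   interaction adjacency among subgraph vertices, anchor edge removed),
#'   `sim` (within-side similarity values, 0 across sides), `K`,
#'   `padded_count`, `anchor_edge_present`.
#' @export
extract_subgraph <- function(net, i, j, K) {
  stopifnot(inherits(net, "dti_network"))
  if (K < 2) stop("K must be at least 2")
  if (i < 1 || i > net$m || j < 1 || j > net$n) stop("index out of range")

  in_d <- logical(net$m); in_t <- logical(net$n)
  in_d[i] <- TRUE; in_t[j] <- TRUE
  # first hop: all interaction neighbours of both anchors
  fh_t <- setdiff(drug_targets(net, i), j)
  fh_d <- setdiff(target_drugs(net, j), i)
  in_d[fh_d] <- TRUE; in_t[fh_t] <- TRUE
  ord_d <- c(i, sort(fh_d)); ord_t <- c(j, sort(fh_t))
  frontier_d <- sort(fh_d); frontier_t <- sort(fh_t)

  n_verts <- function() length(ord_d) + length(ord_t)
  while (n_verts() < K && (length(frontier_d) || length(frontier_t))) {
    pool_t <- setdiff(unique(unlist(lapply(frontier_d, function(d) drug_targets(net, d)))),
                      which(in_t))
    pool_d <- setdiff(unique(unlist(lapply(frontier_t, function(t) target_drugs(net, t)))),
                      which(in_d))
    if (!length(pool_t) && !length(pool_d)) break
    pool <- tibble::tibble(
      role = c(rep("drug", length(pool_d)), rep("target", length(pool_t))),
      index = c(pool_d, pool_t),
      score = c(net$S_D[i, pool_d], net$S_T[j, pool_t]),
      id = c(net$drug_ids[pool_d], net$target_ids[pool_t])
    )
    pool <- pool[order(-pool$score, pool$role != "drug", pool$id), ]
    take <- min(K - n_verts(), nrow(pool))
    added <- pool[seq_len(take), ]
    add_d <- added$index[added$role == "drug"]
    add_t <- added$index[added$role == "target"]
    in_d[add_d] <- TRUE; in_t[add_t] <- TRUE
    ord_d <- c(ord_d, add_d); ord_t <- c(ord_t, add_t)
    # breadth-first: next round expands only what was just admitted
    frontier_d <- add_d; frontier_t <- add_t
  }

  sub <- build_subgraph(net, i, j, ord_d, ord_t, K)
  if (nrow(sub$vertices) > K) {
    ordering <- palette_wl(sub)
    keep <- which(ordering$ranks <= K)  # anchors hold ranks 1-2, never cut
    kv <- sub$vertices[keep, ]
    sub <- build_subgraph(net, i, j,
                          kv$index[kv$role == "drug"],
                          kv$index[kv$role == "target"], K)
  }
  sub
}

# Induce the subgraph on the given drug/target index sets (anchors first in
# each), removing the anchor pair's own interaction edge.
build_subgraph <- function(net, i, j, d_idx, t_idx, K) {
  stopifnot(d_idx[1] == i, t_idx[1] == j)
  nd <- length(d_idx); nt <- length(t_idx)
  vertices <- tibble::tibble(
    role = c("drug", "target", rep("drug", nd - 1), rep("target", nt - 1)),
    index = as.integer(c(i, j, d_idx[-1], t_idx[-1])),
    id = c(net$drug_ids[i], net$target_ids[j],
           net$drug_ids[d_idx[-1]], net$target_ids[t_idx[-1]])
  )
  nv <- nd + nt
  is_drug <- vertices$role == "drug"
  dti_adj <- matrix(0, nv, nv)
  dti_adj[is_drug, !is_drug] <- net$Y[vertices$index[is_drug],
                                      vertices$index[!is_drug], drop = FALSE]
  dti_adj[!is_drug, is_drug] <- t(dti_adj[is_drug, !is_drug, drop = FALSE])
  anchor_edge_present <- dti_adj[1, 2] == 1
  dti_adj[1, 2] <- 0; dti_adj[2, 1] <- 0

  sim <- matrix(0, nv, nv)
  sim[is_drug, is_drug] <- net$S_D[vertices$index[is_drug],
                                   vertices$index[is_drug], drop = FALSE]
  sim[!is_drug, !is_drug] <- net$S_T[vertices$index[!is_drug],
                                     vertices$index[!is_drug], drop = FALSE]
  structure(
    list(vertices = vertices, dti_adj = dti_adj, sim = sim,
         K = as.integer(K), padded_count = max(0L, as.integer(K) - nv),
         anchor_edge_present = anchor_edge_present),
    class = "dti_subgraph"
  )
}

#' @export
print.dti_subgraph <- function(x, ...) {
  cat("<dti_subgraph> anchor (", x$vertices$id[1], ", ", x$vertices$id[2],
      "), ", nrow(x$vertices), " vertices (K = ", x$K, ", padded ",
      x$padded_count, "), ", sum(x$dti_adj) / 2, " interaction edges\n",
      sep = "")
  invisible(x)
}

#' Export a subgraph's interaction edges as a tibble
#'
#' One row per interaction edge of the enclosing subgraph (the anchor edge,
#' having been removed on extraction, never appears). Useful for inspecting
#' what a given pair's topological environment looks like.
#'
#' @param sub a `dti_subgraph`.
#' @return A tibble with columns `drug_id`, `target_id`.
#' @export
subgraph_edges <- function(sub) {
  stopifnot(inherits(sub, "dti_subgraph"))
  is_drug <- sub$vertices$role == "drug"
  e <- which(sub$dti_adj == 1 & outer(is_drug, !is_drug), arr.ind = TRUE)
  tibble::tibble(drug_id = sub$vertices$id[e[, 1]],
                 target_id = sub$vertices$id[e[, 2]])
}
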