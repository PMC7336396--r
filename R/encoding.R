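#' Encode an ordered enclosing subgraph as a fixed-length vector
#'
#' Builds the `K x K` symmetric adjacency matrix of the subgraph with rows
#' and columns in Palette-WL rank order: drug-target cells are 1 when the
#' interaction edge is present (0 otherwise), drug-drug and target-target
#' cells carry the similarity values `S_D` / `S_T`, and any cell touching a
#' padding slot is 0. The anchor cell (ranks 1, 2) is always 0: the anchor
#' pair's own edge is masked so training vectors never contain their label.
#' The strict upper triangle is flattened column by column into a vector of
#' length `K(K-1)/2`.
#'
#' @param sub a `dti_subgraph`.
#' @param ordering a `dti_ordering` for `sub` (default: computed with
#'   [palette_wl()]).
#' @return Numeric vector of length `K(K-1)/2`, entries in `[0, 1]`, with
#'   attribute `K`.
#' @export
encode_subgraph <- function(sub, ordering = palette_wl(sub)) {
  stopifnot(inherits(sub, "dti_subgraph"), inherits(ordering, "dti_ordering"))
  nv <- nrow(sub$vertices)
  ranks <- ordering$ranks
  if (length(ranks) != nv || !setequal(ranks, seq_len(nv))) {
    stop("ordering is not a bijection over the subgraph vertices")
  }
  K <- sub$K
  if (nv > K) stop("subgraph has more than K vertices; truncate first")
  A <- matrix(0, K, K)
  is_drug <- sub$vertices$role == "drug"
  cross <- outer(is_drug, is_drug, FUN = function(a, b) xor(a, b))
  vals <- ifelse(cross, sub$dti_adj, sub$sim)
  A[ranks, ranks] <- vals
  diag(A) <- 0
  A[1, 2] <- 0  # anchor mask
  A[2, 1] <- 0
  v <- A[upper.tri(A)]  # column-major strict upper triangle
  attr(v, "K") <- K
  v
}

#' Reconstruct the K x K matrix from an embedding vector
#'
#' Inverse of the flattening in [encode_subgraph()]: places the
#' `K(K-1)/2` values back into the strict upper triangle (column by
#' column) and mirrors them, giving back the symmetric encoded matrix with
#' a zero diagonal.
#'
#' @param v numeric vector of length `K(K-1)/2`.
#' @param K subgraph size.
#' @return A `K x K` symmetric numeric matrix.
#' @export
unflatten_embedding <- function(v, K = attr(v, "K")) {
  if (length(v) != K * (K - 1) / 2) {
    stop("length(v) must be K(K-1)/2")
  }
  A <- matrix(0, K, K)
  A[upper.tri(A)] <- v
  A + t(A)
}

#' Embed a table of drug-target pairs
#'
#' Runs the full extract / order / encode pipeline for each pair in a
#' sample table and returns one embedding row per pair.
#'
#' @param net a [dti_network].
#' @param pairs a tibble with integer columns `drug`, `target` (and
#'   optionally `drug_id`, `target_id`, `label`), e.g. from
#'   [assemble_samples()].
#' @param K subgraph size.
#' @return A tibble with the pair identifier columns, `label` if supplied,
#'   and feature columns `f1 ... f{K(K-1)/2}`.
#' @export
embed_pairs <- function(net, pairs, K) {
  stopifnot(inherits(net, "dti_network"))
  p <- K * (K - 1) / 2
  X <- matrix(0, nrow(pairs), p)
  for (r in seq_len(nrow(pairs))) {
    sub <- extract_subgraph(net, pairs$drug[r], pairs$target[r], K)
    X[r, ] <- encode_subgraph(sub)
  }
  colnames(X) <- paste0("f", seq_len(p))
  keep <- intersect(c("drug_id", "target_id", "drug", "target", "label"),
                    names(pairs))
  dplyr::bind_cols(pairs[, keep], tibble::as_tibble(X))
}

# Split an embedding tibble into a feature matrix and (optional) labels.
embedding_matrix <- function(embeddings) {
  feat <- grep("^f\\d+$", names(embeddings), value = TRUE)
  X <- as.matrix(embeddings[, feat])
  y <- if ("label" %in% names(embeddings)) embeddings$label else NULL
  list(x = X, y = y)
}

#' Write / read an embedding table
#'
#' @param embeddings tibble from [embed_pairs()].
#' @param path TSV file path.
#' @return `write_embeddings` returns `path` invisibly; `read_embeddings`
#'   the tibble.
#' @export
write_embeddings <- function(embeddings, path) {
  readr::write_tsv(embeddings, path)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
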