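#' Construct a semi-bipartite drug-target interaction network
#'
#' A DTI network couples three matrices: a binary drug-target interaction
#' matrix `Y` (1 = known interaction, 0 = unknown), a drug-drug similarity
#' matrix `S_D` and a target-target similarity matrix `S_T`, both real-valued
#' in \[0, 1\], symmetric, with unit diagonal. Interaction edges connect the
#' two sides; similarity values weight edges within a side, giving a
#' semi-bipartite graph.
#'
#' @param Y numeric matrix, `m x n`, entries in `{0, 1}`. Row names (drugs)
#'   and column names (targets) are used as identifiers when present.
#' @param S_D numeric `m x m` drug-drug similarity matrix in `[0, 1]`.
#' @param S_T numeric `n x n` target-target similarity matrix in `[0, 1]`.
#' @param drug_ids,target_ids character vectors of unique identifiers;
#'   default to the dimnames of `Y`.
#' @return An object of class `dti_network`: a list with elements `Y`, `S_D`,
#'   `S_T`, `drug_ids`, `target_ids`, `m`, `n`.
#' @examples
#' Y <- matrix(0, 3, 2, dimnames = list(c("d1", "d2", "d3"), c("t1", "t2")))
#' Y["d1", "t1"] <- 1
#' net <- dti_network(Y, diag(3), diag(2))
#' net
#' @export
dti_network <- function(Y, S_D, S_T,
                        drug_ids = rownames(Y), target_ids = colnames(Y)) {
  Y <- as.matrix(Y)
  S_D <- as.matrix(S_D)
  S_T <- as.matrix(S_T)
  if (is.null(drug_ids)) drug_ids <- paste0("d", seq_len(nrow(Y)))
  if (is.null(target_ids)) target_ids <- paste0("t", seq_len(ncol(Y)))
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)

  if (anyDuplicated(drug_ids)) stop("duplicate drug identifiers")
  if (anyDuplicated(target_ids)) stop("duplicate target identifiers")
  m <- length(drug_ids)
  n <- length(target_ids)
  if (!all(dim(Y) == c(m, n))) {
    stop("dimension mismatch: Y must be ", m, " x ", n)
  }
  if (!all(dim(S_D) == c(m, m))) {
    stop("dimension mismatch: S_D must be ", m, " x ", m)
  }
  if (!all(dim(S_T) == c(n, n))) {
    stop("dimension mismatch: S_T must be ", n, " x ", n)
  }
  if (!all(Y %in% c(0, 1))) stop("interaction matrix entries must be 0 or 1")
  storage.mode(Y) <- "double"

  S_D <- check_similarity(S_D, "S_D")
  S_T <- check_similarity(S_T, "S_T")

  dimnames(Y) <- list(drug_ids, target_ids)
  dimnames(S_D) <- list(drug_ids, drug_ids)
  dimnames(S_T) <- list(target_ids, target_ids)

  structure(
    list(Y = Y, S_D = S_D, S_T = S_T,
         drug_ids = drug_ids, target_ids = target_ids, m = m, n = n),
    class = "dti_network"
  )
}

# Validate one similarity matrix: range, symmetry (exact to 1e-9;
# symmetrized with a warning up to 1e-6), unit diagonal (forced, warning).
check_similarity <- function(S, name) {
  if (anyNA(S)) stop(name, ": missing values not allowed")
  if (min(S) < 0 || max(S) > 1) stop(name, ": similarity out of range [0, 1]")
  asym <- max(abs(S - t(S)))
  if (asym > 1e-6) {
    stop(name, ": not symmetric (max deviation ", format(asym), ")")
  }
  if (asym > 1e-9) {
    warning(name, " symmetrized (max deviation ", format(asym), ")")
    S <- (S + t(S)) / 2
  }
  if (any(abs(diag(S) - 1) > 1e-9)) {
    warning(name, " diagonal forced to 1")
  }
  diag(S) <- 1
  S
}

#' @export
print.dti_network <- function(x, ...) {
  cat("<dti_network> ", x$m, " drugs x ", x$n, " targets, ",
      sum(x$Y), " known interactions\n", sep = "")
  invisible(x)
}

#' @export
format.dti_network <- function(x, ...) {
  paste0("<dti_network ", x$m, "x", x$n, ", ", sum(x$Y), " interactions>")
}

#' Vertex handle for either side of the network
#'
#' A uniform handle for a node of the semi-bipartite graph: a role
#' (`"drug"` or `"target"`) and a 1-based index into that role's
#' identifier list.
#'
#' @param role `"drug"` or `"target"`.
#' @param index 1-based integer index.
#' @return A list of class `dti_vertex` with elements `role` and `index`.
#' @export
dti_vertex <- function(role, index) {
  role <- match.arg(role, c("drug", "target"))
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 1L) {
    stop("index must be a single positive integer")
  }
  structure(list(role = role, index = index), class = "dti_vertex")
}

#' Interaction neighbours of a vertex
#'
#' Neighbourhoods are defined over interaction edges only: the neighbours of
#' a drug are the targets it is known to interact with, and vice versa.
#' Similarity edges are never traversed.
#'
#' @param net a [dti_network].
#' @param v a [dti_vertex].
#' @return A tibble with columns `role`, `index`, `id`, one row per
#'   neighbour.
#' @export
dti_neighbors <- function(net, v) {
  stopifnot(inherits(net, "dti_network"), inherits(v, "dti_vertex"))
  if (v$role == "drug") {
    if (v$index > net$m) stop("drug index out of range")
    idx <- which(net$Y[v$index, ] == 1)
    tibble::tibble(role = rep("target", length(idx)),
                   index = as.integer(idx),
                   id = net$target_ids[idx])
  } else {
    if (v$index > net$n) stop("target index out of range")
    idx <- which(net$Y[, v$index] == 1)
    tibble::tibble(role = rep("drug", length(idx)),
                   index = as.integer(idx),
                   id = net$drug_ids[idx])
  }
}

# Fast internal accessors (integer vectors, no tibble overhead).
drug_targets <- function(net, i) which(net$Y[i, ] == 1)
target_drugs <- function(net, j) which(net$Y[, j] == 1)

#' Read a DTI network from TSV files
#'
#' The similarity files are square matrix TSVs (first row = column
#' identifiers, first column = row identifiers); identifier order is taken
#' from their headers. The interaction file is either a full matrix TSV in
#' the same dialect or a headerless two-column edge list
#' (`drug_id <TAB> target_id`; a third weight column, if present, is
#' ignored — interactions are binary by presence). Interaction identifiers
#' absent from the similarity headers are an error.
#'
#' @param interaction_path,drug_sim_path,target_sim_path file paths.
#' @return A validated [dti_network].
#' @seealso [write_dti_network()]
#' @export
read_dti_network <- function(interaction_path, drug_sim_path, target_sim_path) {
  for (p in c(interaction_path, drug_sim_path, target_sim_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  S_D <- read_square_tsv(drug_sim_path)
  S_T <- read_square_tsv(target_sim_path)
  drug_ids <- rownames(S_D)
  target_ids <- rownames(S_T)

  first <- strsplit(readLines(interaction_path, n = 1L), "\t", fixed = TRUE)[[1]]
  # a matrix TSV starts with a full header row of target identifiers; a
  # two/three-column edge list cannot match that shape (its rows are short)
  looks_matrix <- length(first) > 3L ||
    (length(first) == length(target_ids) + 1L && all(first[-1] %in% target_ids))
  Y <- matrix(0, length(drug_ids), length(target_ids),
              dimnames = list(drug_ids, target_ids))
  if (looks_matrix) {
    M <- utils::read.delim(interaction_path, row.names = 1,
                           check.names = FALSE)
    M <- as.matrix(M)
    bad_d <- setdiff(rownames(M), drug_ids)
    bad_t <- setdiff(colnames(M), target_ids)
    if (length(bad_d) || length(bad_t)) {
      stop("interaction identifiers absent from similarity headers: ",
           paste(c(bad_d, bad_t), collapse = ", "))
    }
    Y[rownames(M), colnames(M)] <- M
  } else {
    el <- utils::read.delim(interaction_path, header = FALSE,
                            colClasses = "character")
    if (ncol(el) < 2) stop("edge list needs two identifier columns")
    bad_d <- setdiff(unique(el[[1]]), drug_ids)
    bad_t <- setdiff(unique(el[[2]]), target_ids)
    if (length(bad_d) || length(bad_t)) {
      stop("interaction identifiers absent from similarity headers: ",
           paste(c(bad_d, bad_t), collapse = ", "))
    }
    Y[cbind(el[[1]], el[[2]])] <- 1
  }
  dti_network(Y, S_D, S_T, drug_ids = drug_ids, target_ids = target_ids)
}

read_square_tsv <- function(path) {
  M <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop(path, ": similarity matrix is not square")
  if (anyDuplicated(rownames(M))) stop(path, ": duplicate identifiers")
  if (!identical(rownames(M), colnames(M))) {
    stop(path, ": row and column identifiers differ")
  }
  M
}

#' Write a DTI network to TSV files
#'
#' Writes `interactions.tsv` (full matrix), `drug_similarity.tsv` and
#' `target_similarity.tsv` in the matrix dialect read by
#' [read_dti_network()], so that a round trip reproduces the network
#' bit-exactly.
#'
#' @param net a [dti_network].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_dti_network <- function(net, dir) {
  stopifnot(inherits(net, "dti_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("interactions.tsv", "drug_similarity.tsv",
                            "target_similarity.tsv"))
  write_matrix_tsv(net$Y, paths[1])
  write_matrix_tsv(net$S_D, paths[2])
  write_matrix_tsv(net$S_T, paths[3])
  invisible(paths)
}

write_matrix_tsv <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  names(df)[1] <- ""
  # readr writes the shortest decimal that parses back to the same double,
  # so the round trip is bit-exact
  readr::write_tsv(df, path)
}
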