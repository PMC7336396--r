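#' Reliability score of an unknown drug-target pair
#'
#' A candidate negative pair (d_i, t_j) is scored by how dissimilar the two
#' nodes are to the known interactors of the other side:
#' `s_ij = exp(-(sDT_ij + sTD_ji))`, where `sDT_ij` sums the similarity of
#' t_j to every target known to interact with d_i, and `sTD_ji` sums the
#' similarity of d_i to every drug known to interact with t_j. The score
#' lies in (0, 1]; it equals 1 exactly when both sums are empty, and higher
#' scores mark more reliable negatives (a drug dissimilar to every known
#' drug of a target is unlikely to interact with it).
#'
#' @param net a [dti_network].
#' @param i drug index (1-based).
#' @param j target index (1-based).
#' @return A single number in (0, 1].
#' @examples
#' Y <- matrix(0, 2, 2); Y[1, 1] <- 1
#' net <- dti_network(Y, diag(2), matrix(c(1, .5, .5, 1), 2))
#' negative_score(net, 2, 2)  # exp(-(S_T[2,1] + 0)) = exp(-0.5)
#' @export
negative_score <- function(net, i, j) {
  stopifnot(inherits(net, "dti_network"))
  if (i < 1 || i > net$m || j < 1 || j > net$n) stop("index out of range")
  if (net$Y[i, j] == 1) stop("pair is a known interaction, not a candidate negative")
  s_dt <- sum(net$S_T[j, drug_targets(net, i)])
  s_td <- sum(net$S_D[i, target_drugs(net, j)])
  exp(-(s_dt + s_td))
}

# All-pairs reliability scores in one shot:
#   sDT[i, j] = sum_k Y[i, k] S_T[k, j],  sTD[i, j] = sum_k S_D[i, k] Y[k, j].
negative_score_matrix <- function(net) {
  exp(-(net$Y %*% net$S_T + net$S_D %*% net$Y))
}

#' Rank unknown pairs as reliable negatives
#'
#' Scores every unknown pair (known interactions are excluded from the
#' candidate pool) with [negative_score()] and returns the `top_k` pairs in
#' decreasing score order. Ties are broken by (drug identifier, target
#' identifier) lexicographic order so the ranking is deterministic.
#'
#' @param net a [dti_network].
#' @param top_k number of pairs to return; at most the pool size
#'   `m * n - sum(Y)`.
#' @return A tibble with columns `drug_id`, `target_id`, `drug`, `target`
#'   (indices), `label` (`"negative"`), `reliability`, sorted by
#'   `reliability` descending.
#' @export
rank_reliable_negatives <- function(net, top_k) {
  stopifnot(inherits(net, "dti_network"))
  pool <- which(net$Y == 0, arr.ind = TRUE)
  if (top_k > nrow(pool)) {
    stop("top_k (", top_k, ") exceeds candidate pool size (", nrow(pool), ")")
  }
  s <- negative_score_matrix(net)[pool]
  ord <- order(-s, net$drug_ids[pool[, 1]], net$target_ids[pool[, 2]],
               method = "radix")
  keep <- ord[seq_len(top_k)]
  tibble::tibble(
    drug_id = net$drug_ids[pool[keep, 1]],
    target_id = net$target_ids[pool[keep, 2]],
    drug = as.integer(pool[keep, 1]),
    target = as.integer(pool[keep, 2]),
    label = "negative",
    reliability = s[keep]
  )
}

#' Assemble a labelled training sample of pairs
#'
#' Draws `n_positives` known interactions uniformly at random (seeded) and
#' pairs them with `round(n_positives / ratio_alpha)` negatives: either the
#' top of the reliability ranking (`mode = "reliable"`) or a uniform draw of
#' unknown pairs (`mode = "random"`). The positive:negative ratio `alpha`
#' controls class imbalance: `alpha = 1` is balanced, `alpha = 0.1` gives
#' ten negatives per positive, and `ratio_alpha = "all_unknown"` uses every
#' unknown pair as a negative (the fully imbalanced regime). The combined
#' sample is shuffled under the same seed.
#'
#' @param net a [dti_network].
#' @param n_positives number of positives, or `"all"` for every known
#'   interaction.
#' @param ratio_alpha positive:negative ratio in (0, 1], or the sentinel
#'   `"all_unknown"`.
#' @param mode `"reliable"` or `"random"` negative selection.
#' @param seed integer seed; the draw is reproducible.
#' @return A tibble with columns `drug_id`, `target_id`, `drug`, `target`,
#'   `label` (`"positive"`/`"negative"`), `reliability` (`NA` for positives
#'   and for random-mode negatives).
#' @export
assemble_samples <- function(net, n_positives = "all", ratio_alpha = 1,
                             mode = c("reliable", "random"), seed = 1L) {
  stopifnot(inherits(net, "dti_network"))
  mode <- match.arg(mode)
  pos_all <- which(net$Y == 1, arr.ind = TRUE)
  n_pos_avail <- nrow(pos_all)
  if (identical(n_positives, "all")) n_positives <- n_pos_avail
  if (n_positives > n_pos_avail) {
    stop("n_positives exceeds the number of known interactions")
  }
  all_unknown <- identical(ratio_alpha, "all_unknown")
  if (!all_unknown && (!is.numeric(ratio_alpha) || ratio_alpha <= 0 || ratio_alpha > 1)) {
    stop("ratio_alpha must be in (0, 1] or \"all_unknown\"")
  }
  pool_size <- net$m * net$n - n_pos_avail
  n_negatives <- if (all_unknown) pool_size else round(n_positives / ratio_alpha)
  if (n_negatives > pool_size) {
    stop("requested ", n_negatives, " negatives but pool has ", pool_size)
  }

  withr::with_seed(seed, {
    keep <- sample.int(n_pos_avail, n_positives)
    positives <- tibble::tibble(
      drug_id = net$drug_ids[pos_all[keep, 1]],
      target_id = net$target_ids[pos_all[keep, 2]],
      drug = as.integer(pos_all[keep, 1]),
      target = as.integer(pos_all[keep, 2]),
      label = "positive",
      reliability = NA_real_
    )
    negatives <- if (mode == "reliable") {
      rank_reliable_negatives(net, n_negatives)
    } else {
      pool <- which(net$Y == 0, arr.ind = TRUE)
      keep_n <- sample.int(nrow(pool), n_negatives)
      tibble::tibble(
        drug_id = net$drug_ids[pool[keep_n, 1]],
        target_id = net$target_ids[pool[keep_n, 2]],
        drug = as.integer(pool[keep_n, 1]),
        target = as.integer(pool[keep_n, 2]),
        label = "negative",
        reliability = NA_real_
      )
    }
    out <- dplyr::bind_rows(positives, negatives)
    out[sample.int(nrow(out)), ]
  })
}

#' Write / read a pair-sample table
#'
#' Samples are serialized as TSV with columns `drug_id`, `target_id`,
#' `label`, `reliability`.
#'
#' @param samples a tibble as returned by [assemble_samples()].
#' @param path file path.
#' @param net a [dti_network] used to restore integer indices on read.
#' @return `write_samples` returns `path` invisibly; `read_samples` returns
#'   the sample tibble.
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(samples[, c("drug_id", "target_id", "label", "reliability")],
                   path)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path, net) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    drug_id = readr::col_character(), target_id = readr::col_character(),
    label = readr::col_character(), reliability = readr::col_double()
  ))
  tibble::tibble(
    drug_id = x$drug_id, target_id = x$target_id,
    drug = match(x$drug_id, net$drug_ids),
    target = match(x$target_id, net$target_ids),
    label = x$label, reliability = x$reliability
  )
}
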