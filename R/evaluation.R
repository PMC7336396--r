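#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, with tied scores counting 1/2
#' (average ranks).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (`"positive"`/`"negative"`, factor, or 0/1).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- normalize_labels(labels)
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) estimator: thresholds sweep the distinct
#' score values in decreasing order and each recall increment is weighted
#' by the precision reached at that threshold. Under heavy class imbalance
#' this metric is more informative than AUROC; a random ranker scores about
#' the positive prevalence.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(scores, labels) {
  y <- normalize_labels(labels)
  P <- sum(y == 1)
  if (P == 0) stop("at least one positive is required")
  ord <- order(-scores)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- which(diff(s) != 0)       # last index of each distinct threshold
  last <- c(last, length(s))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / P
  sum(diff(c(0, rec)) * prec)
}

#' Heuristic link-prediction scores
#'
#' Classical graph heuristics adapted to the semi-bipartite setting, used
#' as baselines for the learned classifier:
#' * `PA` (preferential attachment, first-order): degree product
#'   `|T_di| * |D_tj|` over interaction edges.
#' * `CN` (similarity-weighted common neighbours, second-order):
#'   `sum(S_D[i, D_tj]) + sum(S_T[j, T_di])` — how similar the drug is to
#'   the target's known drugs and vice versa.
#' * `Jaccard`: `CN / (|T_di| + |D_tj|)`, with `0/0 = 0`.
#' * `Katz` (higher-order): `sum_{l=1..l_max} beta^l (A^l)[d_i, t_j]` on
#'   the `(m+n) x (m+n)` weighted semi-bipartite adjacency (binary
#'   interaction blocks, similarity blocks with zero diagonal).
#'
#' @param net a [dti_network].
#' @param i drug index.
#' @param j target index.
#' @param method one of `"PA"`, `"CN"`, `"Jaccard"`, `"Katz"`.
#' @param beta Katz damping factor.
#' @param l_max Katz maximum path length.
#' @return A single numeric score (higher = more likely to interact).
#' @export
heuristic_score <- function(net, i, j, method = c("PA", "CN", "Jaccard", "Katz"),
                            beta = 0.01, l_max = 6L) {
  method <- match.arg(method)
  pairs <- tibble::tibble(drug = as.integer(i), target = as.integer(j))
  heuristic_scores(net, pairs, method, beta = beta, l_max = l_max)$score
}

#' @rdname heuristic_score
#' @param pairs tibble with integer columns `drug`, `target`.
#' @return `heuristic_scores` returns `pairs` with a `score` column added.
#' @export
heuristic_scores <- function(net, pairs, method = c("PA", "CN", "Jaccard", "Katz"),
                             beta = 0.01, l_max = 6L) {
  stopifnot(inherits(net, "dti_network"))
  method <- match.arg(method)
  ij <- cbind(pairs$drug, pairs$target)
  deg_d <- rowSums(net$Y); deg_t <- colSums(net$Y)
  score <- switch(method,
    PA = deg_d[pairs$drug] * deg_t[pairs$target],
    CN = (net$S_D %*% net$Y + net$Y %*% net$S_T)[ij],
    Jaccard = {
      cn <- (net$S_D %*% net$Y + net$Y %*% net$S_T)[ij]
      denom <- deg_d[pairs$drug] + deg_t[pairs$target]
      ifelse(denom == 0, 0, cn / denom)
    },
    Katz = {
      A <- semi_bipartite_adjacency(net)
      acc <- matrix(0, nrow(A), ncol(A))
      P <- diag(nrow(A))
      for (l in seq_len(l_max)) {
        P <- P %*% A
        acc <- acc + beta^l * P
      }
      acc[cbind(pairs$drug, net$m + pairs$target)]
    }
  )
  out <- pairs
  out$score <- as.numeric(score)
  out
}

# (m+n) x (m+n) weighted adjacency of the semi-bipartite graph:
# similarity blocks (zero diagonal) within sides, binary Y across.
semi_bipartite_adjacency <- function(net) {
  SD0 <- net$S_D; diag(SD0) <- 0
  ST0 <- net$S_T; diag(ST0) <- 0
  rbind(cbind(SD0, net$Y), cbind(t(net$Y), ST0))
}

#' Replace similarity information with identity matrices
#'
#' Ablation helper: switching off `S_D` and/or `S_T` (replacing them with
#' identity matrices) reduces the semi-bipartite graph towards the bare
#' bipartite interaction network, isolating the contribution of each
#' similarity source.
#'
#' @param net a [dti_network].
#' @param use_drug_sim,use_target_sim keep the corresponding similarity
#'   matrix?
#' @return A [dti_network].
#' @export
ablate_network <- function(net, use_drug_sim = TRUE, use_target_sim = TRUE) {
  stopifnot(inherits(net, "dti_network"))
  S_D <- if (use_drug_sim) net$S_D else diag(net$m)
  S_T <- if (use_target_sim) net$S_T else diag(net$n)
  dti_network(net$Y, S_D, S_T, net$drug_ids, net$target_ids)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Assembles a labelled pair sample, splits it into `folds` stratified
#' folds (class proportions preserved, so every test fold contains
#' positives even at small alpha), and for each fold runs the complete
#' pipeline: enclosing-subgraph extraction, Palette-WL ordering, encoding,
#' classifier training on the train folds, and scoring of the test fold.
#' Test-fold positive edges are removed from the network before the test
#' subgraphs are extracted, so no test label can leak through the topology
#' (each pair's own anchor edge is masked in any case). AUROC and AUPR are
#' reported per fold and as mean and SD.
#'
#' @param net a [dti_network].
#' @param K subgraph size.
#' @param n_positives,ratio_alpha,mode passed to [assemble_samples()].
#' @param folds number of folds.
#' @param classifier named list overriding [mlp_train()] defaults
#'   (`hidden`, `epochs`, `batch_size`, `learning_rate`, `patience`, ...).
#' @param seed root seed; sampling, fold assignment and per-fold training
#'   seeds are all derived from it.
#' @return An object of class `dti_cv`: list with `folds` (tibble `fold`,
#'   `auroc`, `aupr`, `n_train`, `n_test`), `mean_auroc`, `sd_auroc`,
#'   `mean_aupr`, `sd_aupr`, `samples`, `config`.
#' @export
cross_validate <- function(net, K = 10L, n_positives = "all", ratio_alpha = 1,
                           mode = c("reliable", "random"), folds = 10L,
                           classifier = list(), seed = 1L) {
  stopifnot(inherits(net, "dti_network"))
  mode <- match.arg(mode)
  if (folds < 2) stop("folds must be at least 2")
  samples <- assemble_samples(net, n_positives, ratio_alpha, mode, seed = seed)
  y <- samples$label
  if (min(table(y)) < folds) {
    stop("too few samples in a class for ", folds, " folds")
  }
  fold_id <- stratified_folds(y, folds, seed = seed + 1L)
  samples$fold <- fold_id

  # training subgraphs always see the full network (their own anchor edge
  # is masked per pair); test subgraphs see the network with the test
  # fold's positive edges removed
  train_emb <- embed_pairs(net, samples, K)

  fold_rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    net_f <- net
    tp <- samples[test & y == "positive", ]
    net_f$Y[cbind(tp$drug, tp$target)] <- 0
    test_emb <- embed_pairs(net_f, samples[test, ], K)
    cl <- classifier
    cl$seed <- NULL  # per-fold training seeds are fanned out from the root
    model <- do.call(mlp_train, c(
      list(x = train_emb[!test, ], seed = seed + 100L + f), cl
    ))
    prob <- predict(model, test_emb, type = "positive")
    fold_rows[[f]] <- tibble::tibble(
      fold = f,
      auroc = auroc(prob, y[test]),
      aupr = aupr(prob, y[test]),
      n_train = sum(!test), n_test = sum(test)
    )
  }
  per_fold <- dplyr::bind_rows(fold_rows)
  structure(
    list(folds = per_fold,
         mean_auroc = mean(per_fold$auroc), sd_auroc = stats::sd(per_fold$auroc),
         mean_aupr = mean(per_fold$aupr), sd_aupr = stats::sd(per_fold$aupr),
         samples = samples,
         config = list(K = K, n_positives = n_positives,
                       ratio_alpha = ratio_alpha, mode = mode, folds = folds,
                       classifier = classifier, seed = seed)),
    class = "dti_cv"
  )
}

#' Cross-validated evaluation of a heuristic baseline
#'
#' Scores a labelled pair sample with one of the [heuristic_score()]
#' baselines under the same protocol as [cross_validate()]: the sample is
#' split into the same stratified folds (the `fold` column of `cv$samples`
#' is reused when present; otherwise folds are re-derived from `seed` the
#' same way [cross_validate()] derives them), and before a test fold is
#' scored its positive edges are removed from the network, so the heuristic
#' cannot read a test label off the pair's own edge.
#'
#' @param net a [dti_network].
#' @param samples labelled pair tibble (e.g. `cv$samples`).
#' @param method heuristic name, see [heuristic_score()].
#' @param folds number of folds.
#' @param seed the root seed used by [cross_validate()].
#' @param beta,l_max Katz parameters.
#' @return A list with `folds` (tibble `fold`, `auroc`, `aupr`),
#'   `mean_auroc`, `mean_aupr`, and `scores` (per-sample, in sample order).
#' @export
heuristic_cv <- function(net, samples, method = c("PA", "CN", "Jaccard", "Katz"),
                         folds = 10L, seed = 1L, beta = 0.01, l_max = 6L) {
  stopifnot(inherits(net, "dti_network"))
  method <- match.arg(method)
  y <- samples$label
  fold_id <- if ("fold" %in% names(samples)) {
    samples$fold
  } else {
    stratified_folds(y, folds, seed = seed + 1L)
  }
  folds <- max(fold_id)
  scores <- numeric(nrow(samples))
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    net_f <- net
    tp <- samples[test & y == "positive", ]
    net_f$Y[cbind(tp$drug, tp$target)] <- 0
    sc <- heuristic_scores(net_f, samples[test, ], method,
                           beta = beta, l_max = l_max)$score
    scores[test] <- sc
    rows[[f]] <- tibble::tibble(fold = f, auroc = auroc(sc, y[test]),
                                aupr = aupr(sc, y[test]))
  }
  per_fold <- dplyr::bind_rows(rows)
  list(folds = per_fold,
       mean_auroc = mean(per_fold$auroc),
       mean_aupr = mean(per_fold$aupr),
       scores = scores)
}

# Stratified fold assignment: shuffle within each class, deal round-robin.
stratified_folds <- function(y, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' @export
print.dti_cv <- function(x, ...) {
  cat("<dti_cv> ", nrow(x$folds), "-fold cross-validation (K = ",
      x$config$K, ", mode = ", x$config$mode, ")\n",
      sprintf("  AUROC %.3f +/- %.3f   AUPR %.3f +/- %.3f\n",
              x$mean_auroc, x$sd_auroc, x$mean_aupr, x$sd_aupr), sep = "")
  invisible(x)
}

#' Per-fold metrics of a cross-validation run
#'
#' @param x a `dti_cv`.
#' @param ... unused.
#' @return Tibble with one row per fold.
#' @export
tidy.dti_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation run
#'
#' @param x a `dti_cv`.
#' @param ... unused.
#' @return Tibble with `folds`, `mean_auroc`, `sd_auroc`, `mean_aupr`,
#'   `sd_aupr`.
#' @export
glance.dti_cv <- function(x, ...) {
  tibble::tibble(
    folds = nrow(x$folds),
    mean_auroc = x$mean_auroc, sd_auroc = x$sd_auroc,
    mean_aupr = x$mean_aupr, sd_aupr = x$sd_aupr
  )
}

#' Plot per-fold cross-validation metrics
#'
#' @param object a `dti_cv`.
#' @param ... unused.
#' @return A ggplot: per-fold AUROC and AUPR with fold-mean bars.
#' @export
autoplot.dti_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds, c("auroc", "aupr"),
                            names_to = "metric", values_to = "value")
  df$metric <- toupper(df$metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          linewidth = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "area under curve",
                  title = sprintf("%d-fold cross-validation (K = %d)",
                                  nrow(object$folds), object$config$K))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
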