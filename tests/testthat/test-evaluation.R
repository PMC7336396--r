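test_that("auroc handles perfect, inverted and tied rankings", {
  y <- c(1, 1, 0, 0)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), y), 1)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), y), 0)
  expect_equal(auroc(rep(0.5, 4), y), 0.5)
  # 6-point tied case against the pair-counting oracle
  s <- c(0.7, 0.5, 0.5, 0.5, 0.3, 0.1)
  l <- c(1, 1, 0, 1, 0, 0)
  expect_equal(auroc(s, l), oracle_auroc(s, l))
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("aupr matches hand threshold enumeration and known baselines", {
  y <- c(1, 1, 0, 0)
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), y), 1)
  # 8-point example enumerated threshold by threshold
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  l <- c(1, 0, 1, 1, 0, 0, 1, 0)
  expect_equal(aupr(s, l), oracle_aupr(s, l))
  # random scores at prevalence p give AUPR near p
  set.seed(11)
  n <- 4000; lab <- rbinom(n, 1, 0.2)
  expect_lt(abs(aupr(runif(n), lab) - 0.2), 0.05)
  expect_error(aupr(1:3, c(0, 0, 0)), "positive")
})

test_that("both metrics agree with brute force on exhaustive small inputs", {
  set.seed(99)
  for (n in c(4, 6, 9, 12)) {
    for (rep in 1:6) {
      scores <- round(runif(n), 1)        # coarse grid forces ties
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
      expect_equal(aupr(scores, labels), oracle_aupr(scores, labels))
    }
  }
})

test_that("auroc agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- runif(40); l <- rbinom(40, 1, 0.5)
  want <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                         direction = "<", levels = c(0, 1))))
  expect_equal(auroc(s, l), want)
})

test_that("heuristics evaluate their closed forms on the toy network", {
  net <- toy_network()
  # d2 has degree 1 (t1); t2 has degree 1 (d1)
  expect_equal(heuristic_score(net, 2, 2, "PA"), 1)
  # degree-2 drug d1 with degree-1 target t3
  expect_equal(heuristic_score(net, 1, 3, "PA"), 2 * 1)
  # CN for (d2, t2): sum S_D[d2, drugs of t2 = {d1}] + S_T[t2, targets of d2 = {t1}]
  expect_equal(heuristic_score(net, 2, 2, "CN"), 0.9 + 0.2)
  expect_equal(heuristic_score(net, 2, 2, "Jaccard"), 1.1 / 2)
  # endpoints with empty neighbourhoods score 0; for Katz this additionally
  # requires them to carry no similarity weight (paths may run through
  # similarity edges otherwise)
  d <- c("d1", "d2", "d3"); t <- c("t1", "t2", "t3")
  Y <- matrix(0, 3, 3, dimnames = list(d, t)); Y["d1", "t1"] <- 1
  netI <- dti_network(Y, sym_mat(3, c(0.5, 0, 0), d), sym_mat(3, c(0.4, 0, 0), t))
  for (mth in c("PA", "CN", "Jaccard", "Katz")) {
    expect_equal(heuristic_score(netI, 3, 3, mth), 0)
  }
  expect_error(heuristic_score(net, 1, 1, "Adamic"), "arg")
})

matrixpow <- function(A, k) {
  P <- diag(nrow(A))
  for (i in seq_len(k)) P <- P %*% A
  P
}

test_that("Katz matches the explicit damped matrix-power sum", {
  net <- random_network(5, 6, density = 0.3, seed = 17)
  A <- rbind(cbind(net$S_D - diag(5), net$Y),
             cbind(t(net$Y), net$S_T - diag(6)))
  beta <- 0.01
  want <- matrix(0, 11, 11)
  for (l in 1:6) want <- want + beta^l * matrixpow(A, l)
  for (pair in list(c(1, 1), c(2, 5), c(4, 3))) {
    expect_equal(heuristic_score(net, pair[1], pair[2], "Katz"),
                 unname(want[pair[1], 5 + pair[2]]), tolerance = 1e-12)
  }
})

test_that("Jaccard returns 0 on empty neighbourhood unions", {
  d <- c("d1", "d2"); t <- c("t1", "t2")
  Y <- matrix(0, 2, 2, dimnames = list(d, t))
  Y["d1", "t1"] <- 1
  net <- dti_network(Y, sym_mat(2, 0.5, d), sym_mat(2, 0.5, t))
  expect_equal(heuristic_score(net, 2, 2, "Jaccard"), 0)
})

test_that("cross-validation partitions samples, stratifies and reproduces", {
  sim <- simulate_dti_network(m = 30, n = 36, density = 0.06,
                              assoc_strength = 4, seed = 5)
  cv <- cross_validate(sim$net, K = 6, folds = 5, seed = 5,
                       classifier = list(epochs = 30))
  s <- cv$samples
  expect_equal(sort(unique(s$fold)), 1:5)
  expect_equal(nrow(s), sum(table(s$fold)))
  # every fold holds positives (stratification)
  expect_true(all(tapply(s$label == "positive", s$fold, sum) > 0))
  # means and SDs consistent with the per-fold table
  expect_equal(cv$mean_auroc, mean(cv$folds$auroc), tolerance = 1e-12)
  expect_equal(cv$sd_aupr, sd(cv$folds$aupr), tolerance = 1e-12)
  expect_true(all(cv$folds$auroc >= 0 & cv$folds$auroc <= 1))
  # reproducibility
  cv2 <- cross_validate(sim$net, K = 6, folds = 5, seed = 5,
                        classifier = list(epochs = 30))
  expect_equal(cv$folds, cv2$folds)
  # tidy/glance accessors
  expect_equal(nrow(tidy(cv)), 5)
  expect_equal(glance(cv)$mean_auroc, cv$mean_auroc)
})

test_that("a label-revealing score gives every fold AUROC = AUPR = 1", {
  set.seed(3)
  lab <- rep(c("positive", "negative"), each = 25)
  truth <- as.numeric(lab == "positive")
  expect_equal(auroc(truth, lab), 1)
  expect_equal(aupr(truth, lab), 1)
})

test_that("heuristic_cv reuses the model folds and hides test edges", {
  sim <- simulate_dti_network(m = 30, n = 36, density = 0.06,
                              assoc_strength = 4, seed = 9)
  cv <- cross_validate(sim$net, K = 6, folds = 5, seed = 9,
                       classifier = list(epochs = 20))
  h <- heuristic_cv(sim$net, cv$samples, "PA", seed = 9)
  expect_equal(nrow(h$folds), 5)
  expect_length(h$scores, nrow(cv$samples))
  # PA on the fold-masked network cannot be the degenerate full-network
  # score that reads each positive's own edge
  full <- heuristic_scores(sim$net, cv$samples, "PA")$score
  expect_false(identical(h$scores, full))
})

test_that("ablation replaces similarities with identities", {
  net <- toy_network()
  ab <- ablate_network(net, use_drug_sim = FALSE, use_target_sim = FALSE)
  expect_equal(ab$S_D, diag(3), ignore_attr = TRUE)
  expect_equal(ab$S_T, diag(3), ignore_attr = TRUE)
  expect_identical(ab$Y, net$Y)
  ab2 <- ablate_network(net, use_drug_sim = TRUE, use_target_sim = FALSE)
  expect_identical(ab2$S_D, net$S_D)
})
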