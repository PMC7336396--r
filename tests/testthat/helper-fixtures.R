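# Small in-code fixtures and independent oracles shared across tests.

sym_mat <- function(n, vals, ids) {
  S <- diag(n)
  S[upper.tri(S)] <- vals
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  dimnames(S) <- list(ids, ids)
  S
}

# 3x3 toy: interactions {(d1,t1),(d2,t1),(d1,t2),(d3,t3)},
# S_D[d1,d2] = 0.9, S_T[t1,t2] = 0.2.
toy_network <- function() {
  d <- c("d1", "d2", "d3"); t <- c("t1", "t2", "t3")
  Y <- matrix(0, 3, 3, dimnames = list(d, t))
  Y["d1", "t1"] <- 1; Y["d2", "t1"] <- 1; Y["d1", "t2"] <- 1; Y["d3", "t3"] <- 1
  S_D <- sym_mat(3, c(0.9, 0.1, 0.15), d)
  S_T <- sym_mat(3, c(0.2, 0.05, 0.12), t)
  dti_network(Y, S_D, S_T)
}

# Random valid network: Bernoulli interactions, random symmetric similarities.
random_network <- function(m, n, density = 0.15, seed = 1) {
  withr::with_seed(seed, {
    Y <- matrix(rbinom(m * n, 1, density), m, n)
    S_D <- matrix(runif(m * m), m, m); S_D <- (S_D + t(S_D)) / 2; diag(S_D) <- 1
    S_T <- matrix(runif(n * n), n, n); S_T <- (S_T + t(S_T)) / 2; diag(S_T) <- 1
    dti_network(Y, S_D, S_T,
                drug_ids = sprintf("d%02d", 1:m),
                target_ids = sprintf("t%02d", 1:n))
  })
}

# Permute the storage order of a network's drugs and targets.
permute_network <- function(net, perm_d, perm_t) {
  dti_network(net$Y[perm_d, perm_t],
              net$S_D[perm_d, perm_d],
              net$S_T[perm_t, perm_t],
              drug_ids = net$drug_ids[perm_d],
              target_ids = net$target_ids[perm_t])
}

# --- independent oracles -------------------------------------------------

# Eq-by-hand reliability score: explicit double loop.
oracle_negative_score <- function(net, i, j) {
  s_dt <- 0
  for (k in seq_len(net$n)) if (net$Y[i, k] == 1) s_dt <- s_dt + net$S_T[j, k]
  s_td <- 0
  for (k in seq_len(net$m)) if (net$Y[k, j] == 1) s_td <- s_td + net$S_D[i, k]
  exp(-(s_dt + s_td))
}

# Score every unknown pair and sort (score desc, drug id, target id).
oracle_rank_negatives <- function(net) {
  rows <- list()
  for (i in seq_len(net$m)) for (j in seq_len(net$n)) {
    if (net$Y[i, j] == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        drug_id = net$drug_ids[i], target_id = net$target_ids[j],
        drug = i, target = j, score = oracle_negative_score(net, i, j)
      )
    }
  }
  df <- do.call(rbind, rows)
  df[order(-df$score, df$drug_id, df$target_id), ]
}

# Pair-counting AUROC: ties count 1/2.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Threshold-enumeration AUPR: counts recomputed from scratch per threshold.
oracle_aupr <- function(scores, labels) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Hop distances by repeated adjacency multiplication (reachability at
# growing path lengths), independent of the package's graph machinery.
oracle_distances_from <- function(adj, src) {
  nv <- nrow(adj)
  d <- rep(Inf, nv); d[src] <- 0
  reach <- diag(nv)
  for (l in seq_len(nv)) {
    reach <- reach %*% adj
    newly <- which(is.infinite(d) & reach[src, ] > 0)
    d[newly] <- l
  }
  d
}
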