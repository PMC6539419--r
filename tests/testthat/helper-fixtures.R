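# in-code fixtures shared across test files

toy_design <- function(reps = 3, stages = c("NEC", "PEC", "GE")) {
  sample_design(
    sample_id = paste0(rep(stages, each = reps), "_", seq_len(reps)),
    stage = rep(stages, each = reps),
    replicate = rep(seq_len(reps), length(stages)),
    stage_levels = stages)
}

# small deterministic abundance matrix; values strictly positive
toy_matrix <- function(n_features = 5, reps = 3, stages = c("NEC", "PEC"),
                       seed = 42) {
  set.seed(seed)
  d <- toy_design(reps, stages)
  v <- matrix(exp(rnorm(n_features * nrow(d), 10, 1)),
              n_features, nrow(d),
              dimnames = list(sprintf("m%02d", seq_len(n_features)),
                              d$sample_id))
  abundance_matrix(v, feature_annotation(rownames(v)), d)
}

# matrix where the two stages differ by exact multiplicative factors
planted_matrix <- function(fc_per_feature, reps = 3, base = 100) {
  stages <- c("NEC", "PEC")
  d <- toy_design(reps, stages)
  n <- length(fc_per_feature)
  ids <- sprintf("m%02d", seq_len(n))
  v <- cbind(matrix(base, n, reps), matrix(base * fc_per_feature, n, reps))
  dimnames(v) <- list(ids, d$sample_id)
  abundance_matrix(v, feature_annotation(ids), d)
}

# exhaustive hypergeometric upper tail by direct pmf enumeration (oracle,
# independent of stats::phyper / stats::dhyper)
enum_hyper_upper <- function(k, n, K, N) {
  if (k == 0) return(1)
  support <- max(0, n - (N - K)):min(n, K)
  pmf <- vapply(support, function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1))
  sum(pmf[support >= k])
}

# hand step-up BH oracle
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
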