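# Shared fixture builders.  Everything is generated in code; no data files.

# minimal valid atlas with hand-placed centroids
tiny_atlas <- function(K = 10, hemisphere = rep_len(c("L", "R"), K)) {
  as_atlas(data.frame(
    node_id = seq_len(K),
    hemisphere = hemisphere,
    network = rep_len(CANONICAL_NETWORKS, K),
    region = rep_len(c("prefrontal", "parietal", "cerebellum"), K),
    x = ifelse(hemisphere == "L", -1, 1) * seq_len(K),
    y = seq_len(K),
    z = rep(0, K)
  ))
}

# random symmetric zero-diagonal matrix
random_symmetric <- function(K, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(K * K), K, K)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    M
  })
}

# random logical edge mask for a K-node atlas
random_mask <- function(K, p = 0.2, seed = 1) {
  withr::with_seed(seed, runif(n_edges(K)) < p)
}

# brute-force per-edge Pearson selection: independent loop over edges using
# cor.test, the oracle for select_edges
brute_force_select <- function(edges, behavior, alpha,
                               covariates = NULL) {
  E <- ncol(edges)
  pos <- neg <- logical(E)
  for (e in seq_len(E)) {
    x <- edges[, e]
    if (sd(x) == 0) next
    if (is.null(covariates)) {
      ct <- cor.test(x, behavior, method = "pearson")
      r <- unname(ct$estimate)
      p <- ct$p.value
    } else {
      # residualization oracle: regress the covariates out of both sides,
      # correlate the residuals, p from t with reduced df
      rx <- resid(lm(x ~ ., data = as.data.frame(covariates)))
      ry <- resid(lm(behavior ~ ., data = as.data.frame(covariates)))
      r <- cor(rx, ry)
      df <- length(x) - ncol(as.matrix(covariates)) - 2
      tt <- r * sqrt(df / (1 - r^2))
      p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
    }
    if (p < alpha) {
      if (r > 0) pos[e] <- TRUE else if (r < 0) neg[e] <- TRUE
    }
  }
  list(pos_mask = pos, neg_mask = neg)
}

# independently coded Steiger (1980) pooled-estimate z, step by step
steiger_oracle <- function(r_jk, r_jh, r_kh, n) {
  fisher <- function(r) 0.5 * log((1 + r) / (1 - r))
  pooled <- 0.5 * (r_jk + r_jh)
  numerator <- r_kh * (1 - pooled^2 - pooled^2) -
    0.5 * (pooled * pooled) * (1 - pooled^2 - pooled^2 - r_kh^2)
  cov_term <- numerator / ((1 - pooled^2) * (1 - pooled^2))
  (fisher(r_jk) - fisher(r_jh)) * sqrt(n - 3) / sqrt(2 - 2 * cov_term)
}

# a small planted-signal dataset for pipeline-level tests
quick_dataset <- function(n = 60, K = 20, n_pos = 8, effect_r = 0.5,
                          seed = 11, ...) {
  generate_dataset(synthetic_spec(
    n_subjects = n, K = K, n_signal_pos = n_pos, effect_r = effect_r,
    seed = seed, ...))
}
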