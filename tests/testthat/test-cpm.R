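test_that("fold assignment is balanced and seed-deterministic", {
  f <- assign_folds(69, 10, seed = 3)
  expect_equal(sort(as.integer(table(f))), c(6L, rep(7L, 9)))
  expect_equal(as.integer(table(assign_folds(10, 10, seed = 1))), rep(1L, 10))
  expect_identical(f, assign_folds(69, 10, seed = 3))
  expect_false(identical(f, assign_folds(69, 10, seed = 4)))
  expect_error(assign_folds(5, 10, seed = 1), "exceeds")
})

test_that("edge selection finds planted signal and matches its p-value contract", {
  withr::with_seed(7, {
    y <- rnorm(50)
    signal <- y + rnorm(50, sd = 0.5)       # r ~ 0.9
    noise <- matrix(rnorm(50 * 20), 50, 20)
  })
  edges <- cbind(signal, noise)
  sel <- select_edges(edges, y, alpha = 0.01)
  expect_true(sel$pos_mask[1])
  expect_false(sel$neg_mask[1])
  expect_error(select_edges(edges, rep(1, 50)), "constant")
})

test_that("edge selection equals a brute-force per-edge cor.test loop", {
  for (s in 1:5) {
    withr::with_seed(s, {
      edges <- matrix(rnorm(30 * 120), 30, 120)
      y <- rnorm(30)
    })
    sel <- select_edges(edges, y, alpha = 0.05)
    oracle <- brute_force_select(edges, y, alpha = 0.05)
    expect_identical(sel$pos_mask, oracle$pos_mask)
    expect_identical(sel$neg_mask, oracle$neg_mask)
  }
})

test_that("partial-correlation selection removes a planted confound", {
  withr::with_seed(21, {
    confound <- rnorm(80)
    y <- confound + rnorm(80, sd = 0.4)
    edges <- cbind(confound + rnorm(80, sd = 0.05),
                   matrix(rnorm(80 * 10), 80, 10))
  })
  plain <- select_edges(edges, y, alpha = 0.01, statistic = "pearson")
  expect_true(plain$pos_mask[1])
  cov <- data.frame(motion = confound)
  adj <- select_edges(edges, y, alpha = 0.01,
                      statistic = "partial_pearson", covariates = cov)
  expect_false(adj$pos_mask[1])
  # and the partial route agrees with the residualization oracle
  oracle <- brute_force_select(edges, y, alpha = 0.05, covariates = cov)
  adj05 <- select_edges(edges, y, alpha = 0.05,
                        statistic = "partial_pearson", covariates = cov)
  expect_identical(adj05$pos_mask, oracle$pos_mask)
  expect_identical(adj05$neg_mask, oracle$neg_mask)
  expect_error(select_edges(edges, y, statistic = "partial_pearson"),
               "requires covariates")
})

test_that("zero-variance edges never enter a mask", {
  withr::with_seed(5, {
    edges <- cbind(rep(1, 40), matrix(rnorm(40 * 5), 40, 5))
    y <- rnorm(40)
  })
  sel <- select_edges(edges, y, alpha = 0.5)
  expect_false(sel$pos_mask[1] || sel$neg_mask[1])
})

test_that("lowering alpha never adds selected edges", {
  withr::with_seed(13, {
    edges <- matrix(rnorm(40 * 200), 40, 200)
    y <- rnorm(40)
  })
  loose <- select_edges(edges, y, alpha = 0.10)
  tight <- select_edges(edges, y, alpha = 0.01)
  expect_true(all(which(tight$pos_mask) %in% which(loose$pos_mask)))
  expect_true(all(which(tight$neg_mask) %in% which(loose$neg_mask)))
})

test_that("network strength sums masked edges (brute-force check)", {
  expect_equal(network_strength(c(0.1, 0.2, -0.05), rep(TRUE, 3)), 0.25)
  expect_equal(network_strength(rnorm(10), rep(FALSE, 10)), 0)
  withr::with_seed(3, {
    X <- matrix(rnorm(8 * 45), 8, 45)
    mask <- runif(45) < 0.3
  })
  loop <- vapply(seq_len(8), function(s) {
    total <- 0
    for (e in which(mask)) total <- total + X[s, e]
    total
  }, numeric(1))
  expect_equal(unname(network_strength(X, mask)), loop, tolerance = 1e-12)
  expect_error(network_strength(rnorm(5), rep(TRUE, 4)), "mask length")
})

test_that("fold model coefficients match the normal-equations oracle", {
  withr::with_seed(17, {
    pos <- rnorm(30); neg <- rnorm(30); y <- rnorm(30)
  })
  m <- fit_fold_model(pos, neg, y, "combined")
  X <- cbind(1, pos, neg)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(m$coefficients), as.vector(beta), tolerance = 1e-8)
  # single-predictor extrapolation: y = 2 s + 1 trained on s in {0,1,2}
  m2 <- fit_fold_model(c(0, 1, 2), rep(0, 3), c(1, 3, 5), "positive_only")
  expect_equal(predict_fold_model(m2, 3, 0), 7)
  # constant predictor is dropped with a warning, not an error
  expect_warning(m3 <- fit_fold_model(rep(1, 5), rnorm(5), rnorm(5), "combined"),
                 "constant predictor")
  expect_equal(unname(m3$coefficients["pos"]), 0)
})

test_that("noiseless linear behavior is recovered perfectly", {
  withr::with_seed(2, s <- rnorm(30))
  y <- 2 * s + 1
  edges <- cbind(s, s, matrix(0, 30, 5))  # planted edges + constants
  cfg <- cpm_config(n_folds = 5, n_iterations = 1, seed = 1,
                    model_form = "positive_only")
  run <- run_cv(edges, y, cfg, seed = 1)
  expect_equal(run$rho, 1)
  expect_equal(run$rmse, 0, tolerance = 1e-10)
})

test_that("held-out subjects never influence training (leakage contract)", {
  ds <- quick_dataset(n = 40, K = 12, n_pos = 5, seed = 31)
  y <- ds$phenotypes$child_ari
  cfg <- cpm_config(n_folds = 5, n_iterations = 1, seed = 9)
  run1 <- run_cv(ds$edges$frustration, y, cfg, seed = 9)
  target <- 7                                   # perturb one subject
  f <- run1$fold_assignment[target]
  y2 <- y
  y2[target] <- y2[target] + 50
  run2 <- run_cv(ds$edges$frustration, y2, cfg, seed = 9)
  expect_identical(run1$fold_models[[f]]$pos_mask,
                   run2$fold_models[[f]]$pos_mask)
  expect_identical(run1$fold_models[[f]]$neg_mask,
                   run2$fold_models[[f]]$neg_mask)
  expect_equal(run1$fold_models[[f]]$model$coefficients,
               run2$fold_models[[f]]$model$coefficients)
  others <- setdiff(which(run1$fold_assignment == f), target)
  expect_equal(run1$predictions[others], run2$predictions[others])
})

test_that("subjects with identical connectomes get identical predictions within a fold", {
  ds <- quick_dataset(n = 20, K = 12, n_pos = 4, seed = 8)
  edges <- rbind(ds$edges$frustration, ds$edges$frustration)
  y <- rep(ds$phenotypes$child_ari, 2)
  cfg <- cpm_config(n_folds = 4, n_iterations = 1, seed = 5)
  run <- run_cv(edges, y, cfg, seed = 5)
  for (f in 1:4) {
    idx <- which(run$fold_assignment == f)
    dup <- intersect(idx, idx[idx > 20] - 20)  # pairs (i, i+20) in same fold
    for (i in dup) {
      expect_equal(run$predictions[i], run$predictions[i + 20])
    }
  }
})

test_that("the median run is the lower-middle order statistic", {
  ds <- quick_dataset(n = 40, K = 12, n_pos = 5, seed = 4)
  cfg <- cpm_config(n_iterations = 6, seed = 2)  # even count: lower middle
  fit <- run_cpm(ds$edges$frustration, ds$phenotypes$child_ari, cfg)
  expect_equal(fit$rho_median, sort(fit$rhos)[3])
  expect_equal(fit$rho_median, fit$rhos[fit$median_run_index])
  cfg1 <- cpm_config(n_iterations = 1, seed = 2)
  fit1 <- run_cpm(ds$edges$frustration, ds$phenotypes$child_ari, cfg1)
  expect_equal(fit1$median_run_index, 1L)
  expect_equal(fit1$rho_median, fit1$runs[[1]]$rho)
})

test_that("consensus recovers the planted set exactly on noiseless data", {
  ds <- generate_dataset(synthetic_spec(
    n_subjects = 50, K = 15, n_signal_pos = 6, effect_r = 0.9,
    edge_noise_sd = 0, baseline_sd = 0.1, seed = 77))
  fit <- run_cpm(ds$edges$frustration, ds$phenotypes$child_ari,
                 cpm_config(n_iterations = 3, seed = 6))
  expect_setequal(which(fit$consensus_pos), ds$ground_truth$pos)
  expect_equal(sum(fit$consensus_neg), 0L)
})

test_that("identical config and seed give bit-identical results", {
  ds <- quick_dataset(n = 30, K = 12, n_pos = 4, seed = 19)
  cfg <- cpm_config(n_iterations = 3, seed = 44)
  a <- run_cpm(ds$edges$frustration, ds$phenotypes$child_ari, cfg)
  b <- run_cpm(ds$edges$frustration, ds$phenotypes$child_ari, cfg)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$rhos, b$rhos)
  expect_identical(a$consensus_pos, b$consensus_pos)
})

test_that("missing behavior is dropped listwise with a message", {
  ds <- quick_dataset(n = 30, K = 12, n_pos = 4, seed = 23)
  y <- ds$phenotypes$child_ari
  y[c(2, 9)] <- NA
  expect_message(
    fit <- run_cpm(ds$edges$frustration, y,
                   cpm_config(n_iterations = 2, seed = 3)),
    "dropping 2")
  expect_equal(fit$n_subjects, 28L)
  expect_equal(fit$n_dropped, 2L)
})

test_that("under the null the per-tail selection rate is at most alpha", {
  # aggregate calibration: pure-noise edges, many repeats
  alpha <- 0.05
  sel_frac <- vapply(1:40, function(s) {
    withr::with_seed(5000 + s, {
      edges <- matrix(rnorm(50 * 100), 50, 100)
      y <- rnorm(50)
    })
    sel <- select_edges(edges, y, alpha = alpha)
    c(mean(sel$pos_mask), mean(sel$neg_mask))
  }, numeric(2))
  # each tail should select ~alpha/2 of edges; bound with binomial slack
  expect_lt(mean(sel_frac), alpha / 2 + 3 * sqrt(alpha / 2 / (40 * 100)))
})
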