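# Connectome-based predictive modeling: per-fold edge selection, network
# strength, linear behavior model, repeated k-fold cross-validation, median
# model and consensus networks.

#' CPM configuration
#'
#' @param n_folds Cross-validation folds (default 10).
#' @param n_iterations Repeats of the full cross-validation (default 100);
#'   the run with the median prediction correlation is reported.
#' @param selection_alpha Edge-selection p-value threshold (default 0.01,
#'   the conventional CPM choice; always recorded in output).
#' @param selection_statistic `"pearson"` (default), `"spearman"` (Pearson on
#'   ranks), or `"partial_pearson"` (partial correlation given `covariates`).
#' @param model_form `"combined"` (behavior ~ positive strength + negative
#'   strength, default), `"positive_only"`, or `"negative_only"`.
#' @param consensus_fraction Fraction of the median run's folds an edge must
#'   be selected in to enter the consensus network (default 1, i.e. all folds).
#' @param covariates Character vector of covariate column names used when
#'   `selection_statistic = "partial_pearson"` (empty = none).
#' @param seed Integer seed; iteration `t` uses seed `seed + t`.
#' @return A list of class `cpm_config`.
#' @export
cpm_config <- function(n_folds = 10L, n_iterations = 100L,
                       selection_alpha = 0.01,
                       selection_statistic = c("pearson", "spearman",
                                               "partial_pearson"),
                       model_form = c("combined", "positive_only",
                                      "negative_only"),
                       consensus_fraction = 1,
                       covariates = character(),
                       seed = 1L) {
  selection_statistic <- match.arg(selection_statistic)
  model_form <- match.arg(model_form)
  stopifnot(n_folds >= 2L, n_iterations >= 1L,
            selection_alpha > 0, selection_alpha < 1,
            consensus_fraction > 0, consensus_fraction <= 1)
  structure(list(
    n_folds = as.integer(n_folds),
    n_iterations = as.integer(n_iterations),
    selection_alpha = selection_alpha,
    selection_statistic = selection_statistic,
    model_form = model_form,
    consensus_fraction = consensus_fraction,
    covariates = as.character(covariates),
    seed = as.integer(seed)
  ), class = "cpm_config")
}

#' Assign subjects to cross-validation folds
#'
#' Balanced random partition: fold sizes differ by at most one, and the
#' assignment is a deterministic function of the seed.
#'
#' @param n_subjects Number of subjects.
#' @param n_folds Number of folds (<= `n_subjects`).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in 1..n_folds.
#' @export
assign_folds <- function(n_subjects, n_folds, seed) {
  if (n_folds > n_subjects) {
    stop(sprintf("assign_folds: n_folds (%d) exceeds n_subjects (%d)",
                 n_folds, n_subjects))
  }
  withr::with_seed(seed,
    sample(rep_len(seq_len(n_folds), n_subjects)))
}

# Edge-wise correlation with behavior plus two-sided t p-values, vectorized
# over columns of `edges`.  With covariates, both sides are residualized on
# [1 | C] and df drops by the number of covariates.  Returns r, p, df.
edgewise_correlation <- function(edges, behavior, statistic = "pearson",
                                 covariates = NULL) {
  n <- nrow(edges)
  if (n < 3L) stop("edge selection: need at least 3 training subjects")
  if (stats::sd(behavior) == 0) {
    stop("edge selection: behavior is constant in the training set")
  }
  y <- behavior
  X <- edges
  n_cov <- 0L
  if (statistic == "spearman") {
    y <- rank(y)
    X <- apply(X, 2L, rank)
  } else if (statistic == "partial_pearson") {
    if (is.null(covariates) || !ncol(as.matrix(covariates))) {
      stop("edge selection: partial_pearson requires covariates")
    }
    C <- as.matrix(covariates)
    if (nrow(C) != n) stop("edge selection: covariate rows != subjects")
    qrC <- qr(cbind(1, C))
    if (qrC$rank < ncol(C) + 1L) {
      stop("edge selection: covariate matrix is rank deficient")
    }
    y <- qr.resid(qrC, y)
    X <- qr.resid(qrC, X)
    n_cov <- ncol(C)
  }
  sds <- matrixStats_colSds(X)
  ok <- sds > 0 & stats::sd(y) > 0
  r <- rep(NA_real_, ncol(edges))
  if (any(ok)) r[ok] <- as.vector(stats::cor(X[, ok, drop = FALSE], y))
  df <- n - n_cov - 2L
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  list(r = r, p = p, df = df)
}

# one-pass column SDs (values are O(1) z-scores, so no cancellation risk)
matrixStats_colSds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt(pmax(colSums(X * X) - n * mu^2, 0) / (n - 1L))
}

#' Select behavior-correlated edges in a training set
#'
#' The CPM feature-selection step: each edge is correlated with the behavior
#' across training subjects; edges with p below `alpha` enter the positive
#' network (r > 0) or the negative network (r < 0).  Zero-variance edges are
#' excluded from both.  With `statistic = "partial_pearson"` the correlations
#' and p-values are partial with respect to `covariates` (both edge and
#' behavior residualized on them; degrees of freedom reduced accordingly).
#'
#' @param train_edges Subjects x edges numeric matrix (training rows only).
#' @param train_behavior Numeric behavior vector (training rows only).
#' @param alpha Selection threshold on the p-value.
#' @param statistic `"pearson"`, `"spearman"`, or `"partial_pearson"`.
#' @param covariates Optional subjects x covariates matrix/data.frame
#'   (training rows only), required for `"partial_pearson"`.
#' @return List with logical `pos_mask` and `neg_mask` (length = edges) and
#'   the per-edge `r` and `p` vectors.
#' @export
select_edges <- function(train_edges, train_behavior, alpha = 0.01,
                         statistic = "pearson", covariates = NULL) {
  ec <- edgewise_correlation(train_edges, train_behavior, statistic, covariates)
  sel <- !is.na(ec$r) & !is.na(ec$p) & ec$p < alpha
  list(pos_mask = sel & ec$r > 0,
       neg_mask = sel & ec$r < 0,
       r = ec$r, p = ec$p)
}

#' Network strength: summed edge weights over a mask
#'
#' The scalar CPM predictor: the sum of a subject's edge values over a
#' selected edge set.  An empty mask gives 0.
#'
#' @param edges Edge vector (length E) or subjects x E matrix.
#' @param mask Logical vector of length E.
#' @return A scalar (vector input) or per-subject vector (matrix input).
#' @export
network_strength <- function(edges, mask) {
  E <- if (is.matrix(edges)) ncol(edges) else length(edges)
  if (length(mask) != E) {
    stop(sprintf("network_strength: mask length %d != edge count %d",
                 length(mask), E))
  }
  if (is.matrix(edges)) {
    drop(edges %*% as.numeric(mask))
  } else {
    sum(edges[mask])
  }
}

#' Fit the linear behavior model on training network strengths
#'
#' `combined` fits behavior ~ intercept + positive strength + negative
#' strength by least squares; `positive_only` / `negative_only` fit a
#' single-predictor line.  Constant or collinear predictors are dropped
#' (coefficient 0) with a warning and the model refit on what remains.
#'
#' @param pos_strength,neg_strength Training network-strength vectors.
#' @param behavior Training behavior vector.
#' @param model_form `"combined"`, `"positive_only"`, or `"negative_only"`.
#' @return List of class `cpm_fold_model` with named `coefficients`
#'   (intercept, pos, neg; dropped/unused terms 0) and `model_form`.
#' @export
fit_fold_model <- function(pos_strength, neg_strength, behavior,
                           model_form = "combined") {
  terms <- switch(model_form,
    combined      = list(pos = pos_strength, neg = neg_strength),
    positive_only = list(pos = pos_strength),
    negative_only = list(neg = neg_strength),
    stop("fit_fold_model: unknown model_form ", model_form)
  )
  keep <- vapply(terms, function(v) stats::sd(v) > 0, logical(1L))
  if (any(!keep)) {
    warning("fit_fold_model: dropping constant predictor(s): ",
            paste(names(terms)[!keep], collapse = ", "))
    terms <- terms[keep]
  }
  coefs <- c(intercept = mean(behavior), pos = 0, neg = 0)
  if (length(terms)) {
    X <- cbind(1, do.call(cbind, terms))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      # collinear strengths: keep the first predictor, drop the rest
      warning("fit_fold_model: collinear predictors, keeping '",
              names(terms)[1L], "' only")
      terms <- terms[1L]
      X <- cbind(1, terms[[1L]])
      qrX <- qr(X)
    }
    b <- qr.coef(qrX, behavior)
    coefs["intercept"] <- b[1L]
    coefs[names(terms)] <- b[-1L]
  }
  structure(list(coefficients = coefs, model_form = model_form),
            class = "cpm_fold_model")
}

#' Predict behavior from network strengths
#' @param model A `cpm_fold_model`.
#' @param pos_strength,neg_strength Held-out network-strength vectors.
#' @return Predicted behavior values.
#' @export
predict_fold_model <- function(model, pos_strength, neg_strength) {
  b <- model$coefficients
  b[["intercept"]] + b[["pos"]] * pos_strength + b[["neg"]] * neg_strength
}

#' One cross-validation run
#'
#' Subjects are partitioned into folds; within each training set edges are
#' selected and the strength model fitted, then the held-out subjects are
#' predicted.  Nothing computed on held-out subjects ever enters training.
#' A fold whose selection is empty in both tails predicts the training
#' behavior mean.  Performance is Spearman's rho and RMSE over the
#' assembled out-of-fold predictions.
#'
#' @param edges Subjects x edges matrix.
#' @param behavior Behavior vector (no missing values; drop upstream).
#' @param config A [cpm_config()].
#' @param seed Integer seed for the fold assignment.
#' @param covariates Optional subjects x covariates matrix/data.frame for
#'   partial-correlation selection.
#' @return List of class `cpm_cv_run`: `fold_assignment`, `fold_models`
#'   (per fold: masks + coefficients), `predictions`, `rho`, `rmse`,
#'   `n_empty_folds`, `degenerate`.
#' @export
run_cv <- function(edges, behavior, config, seed, covariates = NULL) {
  n <- nrow(edges)
  if (length(behavior) != n) stop("run_cv: behavior length != subjects")
  if (anyNA(behavior)) stop("run_cv: missing behavior values; drop upstream")
  folds <- assign_folds(n, config$n_folds, seed)
  preds <- numeric(n)
  fold_models <- vector("list", config$n_folds)
  n_empty <- 0L
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    te <- !tr
    sel <- select_edges(edges[tr, , drop = FALSE], behavior[tr],
                        alpha = config$selection_alpha,
                        statistic = config$selection_statistic,
                        covariates = if (!is.null(covariates))
                          covariates[tr, , drop = FALSE])
    if (!any(sel$pos_mask) && !any(sel$neg_mask)) {
      n_empty <- n_empty + 1L
      preds[te] <- mean(behavior[tr])
      fold_models[[f]] <- list(pos_mask = sel$pos_mask,
                               neg_mask = sel$neg_mask,
                               model = NULL, fold_id = f)
      next
    }
    pos_tr <- network_strength(edges[tr, , drop = FALSE], sel$pos_mask)
    neg_tr <- network_strength(edges[tr, , drop = FALSE], sel$neg_mask)
    model <- withCallingHandlers(
      fit_fold_model(pos_tr, neg_tr, behavior[tr], config$model_form),
      warning = function(w) invokeRestart("muffleWarning"))
    pos_te <- network_strength(edges[te, , drop = FALSE], sel$pos_mask)
    neg_te <- network_strength(edges[te, , drop = FALSE], sel$neg_mask)
    preds[te] <- predict_fold_model(model, pos_te, neg_te)
    fold_models[[f]] <- list(pos_mask = sel$pos_mask,
                             neg_mask = sel$neg_mask,
                             model = model, fold_id = f)
  }
  rho <- suppressWarnings(spearman_rho(preds, behavior))
  structure(list(
    fold_assignment = folds,
    fold_models = fold_models,
    predictions = preds,
    rho = rho,
    rmse = rmse(preds, behavior),
    n_empty_folds = n_empty,
    degenerate = n_empty == config$n_folds || is.na(rho)
  ), class = "cpm_cv_run")
}

#' Run CPM: repeated cross-validation, median model, consensus networks
#'
#' Runs `n_iterations` cross-validation repeats (iteration t seeded with
#' `config$seed + t`), reports the run whose prediction rho is the
#' lower-middle order statistic (the ceiling(m/2)-th smallest), and derives
#' consensus positive/negative networks as the edges selected in at least
#' `consensus_fraction` of that run's folds.
#'
#' Subjects with a missing behavior value are dropped listwise (with a
#' message); degenerate runs (undefined rho) are excluded from the median.
#'
#' @inheritParams run_cv
#' @param subject_ids Optional subject identifiers (default rownames).
#' @return List of class `cpm_result`: `runs`, `rhos`, `median_run_index`,
#'   `rho_median`, `rmse_median`, `predictions` (of the median run),
#'   `consensus_pos`, `consensus_neg`, `n_subjects`, `n_dropped`, `config`.
#' @export
run_cpm <- function(edges, behavior, config = cpm_config(),
                    covariates = NULL, subject_ids = rownames(edges)) {
  keep <- !is.na(behavior)
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(sprintf("run_cpm: dropping %d subject(s) with missing behavior; analyzing n = %d",
                    n_drop, sum(keep)))
    edges <- edges[keep, , drop = FALSE]
    behavior <- behavior[keep]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
    if (!is.null(subject_ids)) subject_ids <- subject_ids[keep]
  }
  runs <- lapply(seq_len(config$n_iterations), function(t) {
    run_cv(edges, behavior, config, seed = config$seed + t,
           covariates = covariates)
  })
  rhos <- vapply(runs, `[[`, numeric(1L), "rho")
  usable <- which(!is.na(rhos))
  if (!length(usable)) stop("run_cpm: all cross-validation runs degenerate")
  if (length(usable) < length(runs)) {
    message(sprintf("run_cpm: %d degenerate run(s) excluded from the median",
                    length(runs) - length(usable)))
  }
  ord <- usable[order(rhos[usable])]
  med_idx <- ord[ceiling(length(ord) / 2)]
  med <- runs[[med_idx]]
  nf <- config$n_folds
  pos_freq <- Reduce(`+`, lapply(med$fold_models, `[[`, "pos_mask"))
  neg_freq <- Reduce(`+`, lapply(med$fold_models, `[[`, "neg_mask"))
  thr <- config$consensus_fraction * nf - 1e-9
  structure(list(
    runs = runs,
    rhos = rhos,
    median_run_index = med_idx,
    rho_median = rhos[med_idx],
    rmse_median = med$rmse,
    predictions = med$predictions,
    behavior = behavior,
    subject_ids = subject_ids,
    consensus_pos = pos_freq >= thr,
    consensus_neg = neg_freq >= thr,
    n_subjects = nrow(edges),
    n_dropped = n_drop,
    config = config
  ), class = "cpm_result")
}

#' @export
print.cpm_result <- function(x, ...) {
  cat(sprintf("<cpm_result> n = %d subjects, %d x %d-fold CV\n",
              x$n_subjects, x$config$n_iterations, x$config$n_folds))
  cat(sprintf("  median run: rho = %.3f, RMSE = %.3f\n",
              x$rho_median, x$rmse_median))
  cat(sprintf("  consensus networks: %d positive, %d negative edges\n",
              sum(x$consensus_pos), sum(x$consensus_neg)))
  invisible(x)
}
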