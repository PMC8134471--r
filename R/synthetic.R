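# Synthetic study generator: atlases, ARI-like phenotypes, and
# condition-specific Fisher-z connectomes with planted brain-behavior
# signal, so every pipeline stage can be exercised and validated without
# clinical imaging data.

#' Specification of a synthetic CPM study
#'
#' Defaults emulate the target study design: 69 youths, a right-skewed
#' child irritability score (six-item ARI total; sample mean 1.79, SD 2.04,
#' observed range 0-9), frustration and nonfrustration connectomes per
#' subject, and a sparse positive edge set linearly tied to behavior that
#' is present only in the frustration condition.  The default node count is
#' 60 (full pipeline still exercised; the 268-node parcellation is
#' supported by setting `K = 268`).
#'
#' Signal is planted additively on the Fisher-z scale: a signal edge is
#' `baseline + beta * z(behavior) + noise` with `beta` chosen so the
#' population edge-behavior correlation equals `effect_r` given
#' `edge_noise_sd`.  A motion-like confound couples to `n_confound_edges`
#' edges at correlation `confound_strength`, and `behavior_motion_r` sets
#' the (Gaussian-copula) correlation between behavior and motion, so a
#' pure-confound dataset (`n_signal_pos = 0`, `behavior_motion_r > 0`,
#' `confound_strength > 0`) carries its entire edge-behavior association
#' through motion.
#'
#' @param n_subjects Number of subjects (default 69).
#' @param K Number of atlas nodes (default 60).
#' @param n_signal_pos,n_signal_neg Planted positively/negatively coupled
#'   edge counts (defaults 40 and 0).
#' @param n_confound_edges Edges coupled to motion instead of behavior.
#' @param effect_r Target population edge-behavior correlation of planted
#'   edges, in \[0, 1).
#' @param confound_strength Target edge-motion correlation of confound
#'   edges, in \[0, 1).
#' @param behavior_motion_r Latent correlation between behavior and motion.
#' @param edge_noise_sd Per-edge Fisher-z noise SD (default 0.2, a
#'   conventional scale for task connectomes).  Zero gives the noiseless
#'   limit: planted edges become exact linear functions of behavior.
#' @param baseline_mean,baseline_sd Distribution of per-edge baseline z
#'   values (drawn once, shared across subjects and conditions).
#' @param behavior_shape List `shape`, `scale`, `max`: the behavior score is
#'   a rounded gamma clipped to `[0, max]`.  Defaults (0.75, 2.47, 9) hit
#'   the target mean/SD after discretization.
#' @param condition_specific If `TRUE` (default) the planted signal appears
#'   only in frustration connectomes; nonfrustration shares the baselines.
#' @param n_missing_parent Parent-report values set missing (default 5).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the spec including this seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 69L, K = 60L,
                           n_signal_pos = 40L, n_signal_neg = 0L,
                           n_confound_edges = 0L,
                           effect_r = 0.4, confound_strength = 0,
                           behavior_motion_r = 0,
                           edge_noise_sd = 0.2,
                           baseline_mean = 0.3, baseline_sd = 0.15,
                           behavior_shape = list(shape = 0.75, scale = 2.47,
                                                 max = 9),
                           condition_specific = TRUE,
                           n_missing_parent = 5L,
                           seed = 1L) {
  E <- n_edges(K)
  if (K < 10L) stop("synthetic_spec: need K >= 10 (one node per network)")
  if (n_signal_pos + n_signal_neg + n_confound_edges > E) {
    stop(sprintf("synthetic_spec: %d planted edges exceed the %d available",
                 n_signal_pos + n_signal_neg + n_confound_edges, E))
  }
  if (effect_r < 0 || effect_r >= 1) {
    stop("synthetic_spec: effect_r must lie in [0, 1); the population ",
         "edge-behavior correlation cannot reach 1 with finite noise")
  }
  if (confound_strength < 0 || confound_strength >= 1) {
    stop("synthetic_spec: confound_strength must lie in [0, 1)")
  }
  stopifnot(n_subjects >= 10L, edge_noise_sd >= 0, baseline_sd >= 0)
  structure(list(
    n_subjects = as.integer(n_subjects), K = as.integer(K),
    n_signal_pos = as.integer(n_signal_pos),
    n_signal_neg = as.integer(n_signal_neg),
    n_confound_edges = as.integer(n_confound_edges),
    effect_r = effect_r, confound_strength = confound_strength,
    behavior_motion_r = behavior_motion_r,
    edge_noise_sd = edge_noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    behavior_shape = behavior_shape,
    condition_specific = isTRUE(condition_specific),
    n_missing_parent = as.integer(n_missing_parent),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

synthetic_regions <- c("prefrontal", "motor_strip", "parietal", "temporal",
                       "occipital", "insula", "subcortical", "cerebellum")

#' Generate a synthetic atlas
#'
#' Nodes alternate L/R hemispheres (near-even split), cycle through the ten
#' canonical networks, and cycle through a fixed set of macroscale region
#' labels; centroids are drawn uniformly in a head-sized box with the x
#' coordinate sign matching the hemisphere (L: x < 0, R: x > 0).
#'
#' @param K Node count (>= 10).
#' @param seed Integer seed.
#' @return A `cpm_atlas` with K nodes.
#' @export
generate_atlas <- function(K, seed = 1L) {
  if (K < 10L) stop("generate_atlas: need K >= 10")
  withr::with_seed(seed, {
    hemi <- rep_len(c("L", "R"), K)
    xmag <- stats::runif(K, 5, 70)
    as_atlas(data.frame(
      node_id = seq_len(K),
      hemisphere = hemi,
      network = rep_len(CANONICAL_NETWORKS, K),
      region = rep_len(synthetic_regions, K),
      x = ifelse(hemi == "L", -xmag, xmag),
      y = stats::runif(K, -100, 70),
      z = stats::runif(K, -50, 80)
    ))
  })
}

# Latent-Gaussian draw of the phenotype table.  `latent` (one N(0,1) per
# subject) drives the ARI score through the gamma quantile transform and,
# through the copula weight behavior_motion_r, the motion covariate.
generate_phenotypes_impl <- function(spec, latent) {
  n <- spec$n_subjects
  bs <- spec$behavior_shape
  degenerate <- bs$shape <= 0 || bs$scale <= 0
  child <- if (degenerate) rep(0L, n) else {
    as.integer(pmin(pmax(round(
      stats::qgamma(stats::pnorm(latent), shape = bs$shape, scale = bs$scale)
    ), 0), bs$max))
  }
  r <- spec$behavior_motion_r
  motion_z <- r * latent + sqrt(1 - r^2) * stats::rnorm(n)
  # lognormal with mean ~0.07 mm (meanlog chosen so E[motion] = 0.07)
  motion <- stats::qlnorm(stats::pnorm(motion_z),
                          meanlog = log(0.07) - 0.35^2 / 2, sdlog = 0.35)
  parent <- if (degenerate) rep(0L, n) else {
    as.integer(pmin(pmax(round(stats::rgamma(n, shape = 0.70, scale = 4.0)),
                         0), 10))
  }
  if (spec$n_missing_parent > 0L) {
    parent[sample.int(n, min(spec$n_missing_parent, n))] <- NA_integer_
  }
  ph <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    child_ari = child,
    parent_ari = parent,
    age = stats::runif(n, 8, 22),
    sex = stats::rbinom(n, 1L, 0.45),
    motion = motion,
    adhd = round(stats::rnorm(n, 55, 10)),
    anxiety = round(stats::rnorm(n, 52, 10)),
    med_stimulant = stats::rbinom(n, 1L, 0.2),
    med_antidepressant = stats::rbinom(n, 1L, 0.15),
    state_frustration = pmin(pmax(round(stats::rnorm(n, 5, 1.5) * 2) / 2, 1), 9)
  )
  attr(ph, "degenerate") <- degenerate
  validate_phenotypes(ph)
}

#' Generate synthetic behavior scores and covariates
#'
#' Draws the phenotype table alone (no connectomes): an integer ARI-like
#' score in \[0, 12\] from a rounded, clipped gamma (right-skewed), plus
#' age (uniform 8-22 years), sex (Bernoulli), motion (lognormal, mean
#' ~0.07 mm), symptom scores, medication flags and a state frustration
#' rating.  A zero-variance `behavior_shape` yields constant scores with
#' attribute `degenerate = TRUE`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed override (default `spec$seed`).
#' @return Phenotype data.frame (see [read_phenotypes()] for the columns).
#' @export
generate_behavior <- function(spec, seed = spec$seed) {
  withr::with_seed(seed, {
    generate_phenotypes_impl(spec, stats::rnorm(spec$n_subjects))
  })
}

#' Generate a full synthetic dataset
#'
#' Atlas, phenotypes, per-condition subjects x edges Fisher-z matrices, and
#' the planted ground truth.  Per-edge baselines are drawn once and shared
#' across subjects and both conditions; subject-level noise is independent
#' per condition.  Planted positive (negative) edges add
#' `+beta * z(score)` (`-beta * z(score)`), with
#' `beta = edge_noise_sd * effect_r / sqrt(1 - effect_r^2)` so the
#' population edge-behavior correlation is `effect_r`; confound edges add
#' the analogous multiple of standardized motion (in both conditions --
#' head motion is not condition-specific).  With `condition_specific`
#' (default), behavior signal appears only in frustration connectomes.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_dataset`: `atlas`, `edges` (list of
#'   subjects x edges matrices `frustration`, `nonfrustration`),
#'   `phenotypes`, `ground_truth` (edge index sets `pos`, `neg`,
#'   `confound`; coupling coefficients `beta`, `gamma`; the `spec`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  atlas <- generate_atlas(spec$K, seed = spec$seed + 1L)
  E <- n_edges(spec$K)
  n <- spec$n_subjects
  withr::with_seed(spec$seed, {
    phen <- generate_phenotypes_impl(spec, stats::rnorm(n))
    planted <- sample.int(E, spec$n_signal_pos + spec$n_signal_neg +
                             spec$n_confound_edges)
    pos <- planted[seq_len(spec$n_signal_pos)]
    neg <- planted[spec$n_signal_pos + seq_len(spec$n_signal_neg)]
    con <- planted[spec$n_signal_pos + spec$n_signal_neg +
                     seq_len(spec$n_confound_edges)]
    baseline <- stats::rnorm(E, spec$baseline_mean, spec$baseline_sd)

    z_std <- function(v) if (stats::sd(v) == 0) rep(0, length(v)) else
      (v - mean(v)) / stats::sd(v)
    z_beh <- z_std(phen$child_ari)
    z_mot <- z_std(phen$motion)
    coupling <- function(target_r) {
      if (spec$edge_noise_sd > 0) {
        spec$edge_noise_sd * target_r / sqrt(1 - target_r^2)
      } else if (target_r > 0) 0.1 else 0  # noiseless limit: exact linearity
    }
    beta <- coupling(spec$effect_r)
    gamma <- coupling(spec$confound_strength)

    draw_condition <- function(with_signal) {
      X <- matrix(baseline, n, E, byrow = TRUE) +
        matrix(stats::rnorm(n * E, 0, spec$edge_noise_sd), n, E)
      if (with_signal) {
        if (length(pos)) X[, pos] <- X[, pos] + beta * z_beh
        if (length(neg)) X[, neg] <- X[, neg] - beta * z_beh
      }
      if (length(con)) X[, con] <- X[, con] + gamma * z_mot
      rownames(X) <- phen$subject_id
      X
    }
    frus <- draw_condition(with_signal = TRUE)
    nonf <- draw_condition(with_signal = !spec$condition_specific)
  })
  structure(list(
    atlas = atlas,
    edges = list(frustration = frus, nonfrustration = nonf),
    phenotypes = phen,
    ground_truth = list(pos = pos, neg = neg, confound = con,
                        beta = beta, gamma = gamma, spec = spec)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  s <- x$ground_truth$spec
  cat(sprintf("<synthetic_dataset> n = %d subjects, K = %d nodes (%d edges)\n",
              s$n_subjects, s$K, n_edges(s$K)))
  cat(sprintf("  planted: %d pos / %d neg (effect_r = %g%s), %d confound edges\n",
              s$n_signal_pos, s$n_signal_neg, s$effect_r,
              if (s$condition_specific) ", frustration only" else "",
              s$n_confound_edges))
  invisible(x)
}

#' Reconstruct one subject's K x K connectivity matrix
#' @param dataset A `synthetic_dataset`.
#' @param subject_id Subject identifier.
#' @param condition `"frustration"` or `"nonfrustration"`.
#' @return Symmetric K x K Fisher-z matrix, diagonal 0.
#' @export
dataset_matrix <- function(dataset, subject_id,
                           condition = c("frustration", "nonfrustration")) {
  condition <- match.arg(condition)
  X <- dataset$edges[[condition]]
  if (!subject_id %in% rownames(X)) {
    stop("dataset_matrix: unknown subject ", subject_id)
  }
  devectorize_edges(X[subject_id, ], nrow(dataset$atlas))
}

#' Write a synthetic dataset to the standard file layouts
#'
#' Writes `atlas.tsv`, `phenotypes.csv`, one matrix file per subject and
#' condition under `matrices/` with a `manifest.tsv`, and
#' `ground_truth.json` -- exactly the formats the readers in this package
#' consume.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  write_atlas(dataset$atlas, file.path(dir, "atlas.tsv"))
  write_phenotypes(dataset$phenotypes, file.path(dir, "phenotypes.csv"))
  K <- nrow(dataset$atlas)
  man <- do.call(rbind, lapply(names(dataset$edges), function(cond) {
    X <- dataset$edges[[cond]]
    paths <- sprintf("matrices/%s_%s.txt", rownames(X), cond)
    for (s in seq_len(nrow(X))) {
      write_connectivity_matrix(devectorize_edges(X[s, ], K),
                                file.path(dir, paths[s]))
    }
    data.frame(subject_id = rownames(X), condition = cond, path = paths)
  }))
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- dataset$ground_truth
  jsonlite::write_json(
    list(pos = gt$pos, neg = gt$neg, confound = gt$confound,
         beta = gt$beta, gamma = gt$gamma,
         spec = unclass(gt$spec)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
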