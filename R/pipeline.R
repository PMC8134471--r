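# End-to-end orchestration: simulate or load data, run CPM, permutation
# inference and localization from one config, with a machine-readable run
# manifest.

pipeline_stages <- c("simulate", "load", "cpm", "permute", "localize")

validate_pipeline_config <- function(cfg) {
  problems <- character()
  need <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  need(is.list(cfg), "config must be a mapping")
  if (!is.list(cfg)) return(problems)
  need(!is.null(cfg$seed) && is.numeric(cfg$seed), "seed: integer required")
  need(!is.null(cfg$simulate) || !is.null(cfg$inputs),
       "either simulate: or inputs: must be given")
  if (!is.null(cfg$inputs)) {
    for (f in c("manifest", "atlas", "phenotypes")) {
      need(!is.null(cfg$inputs[[f]]), sprintf("inputs.%s: path required", f))
    }
  }
  if (!is.null(cfg$cpm)) {
    need(!is.null(cfg$cpm$target), "cpm.target: behavior column required")
    cond <- cfg$cpm$condition
    need(is.null(cond) ||
           cond %in% c("frustration", "nonfrustration", "difference"),
         "cpm.condition: must be frustration, nonfrustration or difference")
    a <- cfg$cpm$selection_alpha
    need(is.null(a) || (is.numeric(a) && a > 0 && a < 1),
         "cpm.selection_alpha: must lie in (0, 1)")
  }
  if (!is.null(cfg$permute)) {
    np <- cfg$permute$n_perm
    need(is.null(np) || (is.numeric(np) && np >= 1),
         "permute.n_perm: must be >= 1")
  }
  problems
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full CPM pipeline from a config
#'
#' Stages, in order and each optional except the data source: `simulate`
#' (generate a synthetic dataset) or `inputs` (read atlas / matrix manifest
#' / phenotypes from disk), `cpm` (repeated cross-validated prediction of
#' the target behavior from the chosen condition's connectomes), `permute`
#' (permutation significance for the median model), `localize` (summaries
#' of the consensus positive and negative networks).  Every numeric result
#' is written as JSON/TSV under `out_dir` together with `manifest.json`
#' recording the config, seeds, package version, input checksums, stage
#' timings and warnings; identical configs reproduce outputs bit-ically.
#'
#' With `condition: difference`, the per-subject elementwise difference
#' frustration minus nonfrustration is analyzed.
#'
#' @param config Path to a YAML config, or an equivalent named list.
#' @param out_dir Output directory (default `config$out_dir`, or a tempdir).
#' @return Invisibly, a list with the in-memory results (`dataset` or
#'   loaded inputs, `cpm`, `permutation`, `localization`) and the
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  problems <- validate_pipeline_config(cfg)
  if (length(problems)) {
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("cpm_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  manifest <- list(
    package = "cpmkit",
    version = as.character(utils::packageVersion("cpmkit")),
    config = cfg, seed = seed,
    inputs = list(), stages = list(), warnings = character()
  )
  res <- list()
  note <- function(...) {
    manifest$warnings <<- c(manifest$warnings, sprintf(...))
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(fun(), warning = function(w) {
      note("[%s] %s", name, conditionMessage(w))
      invokeRestart("muffleWarning")
    }, message = function(m) {
      note("[%s] %s", name, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
    manifest$stages[[name]] <<- list(
      completed = TRUE, seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  on.exit(write_manifest())

  # --- data source ---------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    res$dataset <- run_stage("simulate", function() {
      sim <- cfg$simulate
      sim$seed <- sim$seed %||% seed
      generate_dataset(do.call(synthetic_spec, sim))
    })
    atlas <- res$dataset$atlas
    phen <- res$dataset$phenotypes
    edges_by_cond <- res$dataset$edges
  } else {
    loaded <- run_stage("load", function() {
      manifest$inputs <<- lapply(cfg$inputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p))))
      atlas <- read_atlas(cfg$inputs$atlas)
      phen <- read_phenotypes(cfg$inputs$phenotypes)
      man <- utils::read.delim(cfg$inputs$manifest, stringsAsFactors = FALSE)
      edges_by_cond <- lapply(split(seq_len(nrow(man)), man$condition),
        function(rows) {
          mats <- lapply(man$path[rows], function(p) {
            read_connectivity_matrix(
              if (startsWith(p, "/")) p
              else file.path(dirname(cfg$inputs$manifest), p))
          })
          names(mats) <- man$subject_id[rows]
          edge_matrix(mats)
        })
      list(atlas = atlas, phen = phen, edges_by_cond = edges_by_cond)
    })
    atlas <- loaded$atlas
    phen <- loaded$phen
    edges_by_cond <- loaded$edges_by_cond
    res$inputs <- loaded
  }

  # --- cpm -----------------------------------------------------------------
  if (!is.null(cfg$cpm)) {
    cc <- cfg$cpm
    condition <- cc$condition %||% "frustration"
    res$cpm <- run_stage("cpm", function() {
      edges <- if (condition == "difference") {
        common <- intersect(rownames(edges_by_cond$frustration),
                            rownames(edges_by_cond$nonfrustration))
        edges_by_cond$frustration[common, , drop = FALSE] -
          edges_by_cond$nonfrustration[common, , drop = FALSE]
      } else {
        edges_by_cond[[condition]]
      }
      idx <- match(rownames(edges), phen$subject_id)
      if (anyNA(idx)) stop("cpm: subjects in matrices missing from phenotypes")
      behavior <- phen[[cc$target]][idx]
      if (is.null(behavior)) stop("cpm: unknown target column ", cc$target)
      covars <- cc$covariates %||% character()
      bad <- setdiff(covars, names(phen))
      if (length(bad)) stop("cpm: covariate(s) not in phenotypes: ",
                            paste(bad, collapse = ", "))
      config <- cpm_config(
        n_folds = cc$n_folds %||% 10L,
        n_iterations = cc$n_iterations %||% 100L,
        selection_alpha = cc$selection_alpha %||% 0.01,
        selection_statistic = cc$selection_statistic %||%
          (if (length(covars)) "partial_pearson" else "pearson"),
        model_form = cc$model_form %||% "combined",
        consensus_fraction = cc$consensus_fraction %||% 1,
        covariates = covars,
        seed = seed)
      fit <- run_cpm(edges, behavior, config,
                     covariates = if (length(covars))
                       phen[idx, covars, drop = FALSE],
                     subject_ids = rownames(edges))
      med <- fit$runs[[fit$median_run_index]]
      utils::write.csv(data.frame(
        subject_id = fit$subject_ids, actual = fit$behavior,
        predicted = fit$predictions, fold = med$fold_assignment,
        iteration = fit$median_run_index
      ), file.path(out_dir, "predictions.csv"), row.names = FALSE)
      for (side in c("pos", "neg")) {
        export_edge_list(fit[[paste0("consensus_", side)]], atlas,
                         file.path(out_dir,
                                   sprintf("consensus_%s_edges.tsv", side)))
      }
      jsonlite::write_json(list(
        target = cc$target, condition = condition,
        n_subjects = fit$n_subjects, n_dropped = fit$n_dropped,
        rho_median = fit$rho_median, rmse_median = fit$rmse_median,
        consensus_pos_edges = sum(fit$consensus_pos),
        consensus_neg_edges = sum(fit$consensus_neg),
        config = unclass(config)
      ), file.path(out_dir, "performance.json"),
      auto_unbox = TRUE, digits = NA)
      fit
    })
  }

  # --- permutation ---------------------------------------------------------
  if (!is.null(cfg$permute)) {
    if (is.null(res$cpm)) stop("permute stage requires the cpm stage")
    res$permutation <- run_stage("permute", function() {
      cc <- cfg$cpm
      condition <- cc$condition %||% "frustration"
      edges <- if (condition == "difference") {
        common <- intersect(rownames(edges_by_cond$frustration),
                            rownames(edges_by_cond$nonfrustration))
        edges_by_cond$frustration[common, , drop = FALSE] -
          edges_by_cond$nonfrustration[common, , drop = FALSE]
      } else edges_by_cond[[condition]]
      fit <- res$cpm
      keep <- match(fit$subject_ids, rownames(edges))
      covars <- fit$config$covariates
      idx <- match(fit$subject_ids, phen$subject_id)
      perm <- permutation_test(
        edges[keep, , drop = FALSE], fit$behavior, fit$config,
        rho_observed = fit,
        n_perm = cfg$permute$n_perm %||% 1000L,
        perm_seed = as.integer(cfg$permute$perm_seed %||% (seed + 10000L)),
        covariates = if (length(covars)) phen[idx, covars, drop = FALSE],
        n_iterations_per_perm =
          cfg$permute$n_iterations_per_perm %||% 1L)
      writeLines(format(perm$rho_null, digits = 17),
                 file.path(out_dir, "null_rho.txt"))
      jsonlite::write_json(
        list(rho_median = perm$rho_observed, p = perm$p,
             n_perm = perm$n_perm, tail = "one-tailed"),
        file.path(out_dir, "permutation.json"),
        auto_unbox = TRUE, digits = NA)
      perm
    })
  }

  # --- localization --------------------------------------------------------
  if (!is.null(cfg$localize)) {
    if (is.null(res$cpm)) stop("localize stage requires the cpm stage")
    res$localization <- run_stage("localize", function() {
      lc <- cfg$localize
      masks <- list(positive = res$cpm$consensus_pos,
                    negative = res$cpm$consensus_neg)
      summaries <- lapply(masks, function(m) {
        if (!sum(m)) return(list(total_edges = 0L))
        s <- summarize_network(m, atlas,
                               threshold_mm = lc$long_range_mm %||% 60)
        list(total_edges = s$total_edges,
             n_nodes_involved = s$n_nodes_involved,
             hemisphere_counts = as.list(s$hemisphere_counts),
             range = list(counts = as.list(s$range$counts),
                          threshold_mm = s$range$threshold_mm,
                          chi2 = s$range$chi2, p = s$range$p),
             network_matrix = s$network_matrix,
             degree = s$degree)
      })
      jsonlite::write_json(summaries, file.path(out_dir, "localization.json"),
                           auto_unbox = TRUE, digits = NA)
      summaries
    })
  }

  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}

#' Summarize a completed pipeline run
#'
#' Reads the JSON outputs under a run directory and prints the results in
#' the conventional reporting format (rho, RMSE, permutation p with its
#' iteration count and tail, consensus network sizes, localization
#' partitions).  Stages that were not run are noted, not invented; an
#' empty consensus network is reported as 0 edges with localization
#' skipped.
#'
#' @param result_dir Directory written by [run_pipeline()].
#' @return Invisibly, the collected result list.
#' @export
report_run <- function(result_dir) {
  perf_path <- file.path(result_dir, "performance.json")
  if (!file.exists(perf_path)) {
    stop("report_run: no performance.json in ", result_dir,
         " (cpm stage missing)")
  }
  perf <- jsonlite::read_json(perf_path, simplifyVector = TRUE)
  out <- list(performance = perf)
  cat(sprintf("CPM prediction of %s from %s connectivity (n = %d%s)\n",
              perf$target, perf$condition, perf$n_subjects,
              if (perf$n_dropped > 0)
                sprintf(", %d dropped for missing behavior", perf$n_dropped)
              else ""))
  perm_path <- file.path(result_dir, "permutation.json")
  if (file.exists(perm_path)) {
    perm <- jsonlite::read_json(perm_path, simplifyVector = TRUE)
    out$permutation <- perm
    cat(sprintf("  rho = %.2f, RMSE = %.2f, p = %.3g (permutation testing, %d iterations, %s)\n",
                perf$rho_median, perf$rmse_median, perm$p, perm$n_perm,
                perm$tail))
  } else {
    cat(sprintf("  rho = %.2f, RMSE = %.2f (no permutation stage run; p not available)\n",
                perf$rho_median, perf$rmse_median))
  }
  cat(sprintf("  consensus networks: %d positive, %d negative edges\n",
              perf$consensus_pos_edges, perf$consensus_neg_edges))
  loc_path <- file.path(result_dir, "localization.json")
  if (file.exists(loc_path)) {
    loc <- jsonlite::read_json(loc_path, simplifyVector = TRUE)
    out$localization <- loc
    for (side in names(loc)) {
      s <- loc[[side]]
      if (!s$total_edges) {
        cat(sprintf("  %s network: 0 edges, localization skipped\n", side))
      } else {
        h <- s$hemisphere_counts
        cat(sprintf("  %s network: %d edges over %d nodes (%d ipsi-R, %d ipsi-L, %d interhemispheric)\n",
                    side, s$total_edges, s$n_nodes_involved,
                    h$ipsi_R, h$ipsi_L, h$inter))
        r <- s$range
        cat(sprintf("    range >= %g mm: %d long, %d short (chi2 = %.2f, p = %.2g)\n",
                    r$threshold_mm, r$counts$long, r$counts$short,
                    r$chi2, r$p))
      }
    }
  }
  invisible(out)
}
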