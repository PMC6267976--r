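#' Pipeline configuration
#'
#' Bundles file paths, treatment definitions and settings for the full
#' calibrate -> predict -> evaluate workflow. Calibration may be skipped by
#' supplying a CWM constraints CSV directly (`constraints_csv`), in which
#' case the field data paths are not needed.
#'
#' @param trait_csv path to the species trait table (CSV) used for maxent
#'   prediction (typically the experimental species subset).
#' @param community_csv,env_csv field calibration data: sample x species
#'   cover matrix and sample environment table (CSV). Required unless
#'   `constraints_csv` is given.
#' @param calibration_trait_csv optional separate trait table covering the
#'   full field species pool (defaults to `trait_csv`).
#' @param constraints_csv optional CWM constraint table (unit_id + one
#'   column per trait); when given, calibration is skipped.
#' @param observed_csv optional observed experiment matrix (pots x species
#'   CSV with a `treatment` column) for evaluation.
#' @param observed_kind abundance type in `observed_csv` (default "count").
#' @param treatments data frame of prediction environments with columns
#'   `treatment`, `soil_ph`, `pine_ba`; default: the 2x2 sun/shade (basal
#'   area 0/59 m^2 ha^-1) x limestone/basalt (pH 6.8/5.9) design.
#' @param tol,max_iter,on_infeasible maxent solver settings.
#' @param n_perm,scheme evaluation permutation settings.
#' @param seed integer seed for all stochastic steps.
#' @param out_dir output directory for stage artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(trait_csv,
                            community_csv = NULL, env_csv = NULL,
                            calibration_trait_csv = NULL,
                            constraints_csv = NULL,
                            observed_csv = NULL, observed_kind = "count",
                            treatments = data.frame(
                              treatment = c("sun-limestone", "sun-basalt",
                                            "shade-limestone", "shade-basalt"),
                              soil_ph = c(6.8, 5.9, 6.8, 5.9),
                              pine_ba = c(0, 0, 59, 59)
                            ),
                            tol = 1e-8, max_iter = 10000,
                            on_infeasible = "error",
                            n_perm = 999, scheme = "within_row",
                            seed = 1, out_dir = tempfile("catspredict_run_")) {
  if (is.null(constraints_csv) && (is.null(community_csv) || is.null(env_csv))) {
    stop("either constraints_csv or both community_csv and env_csv are required",
         call. = FALSE)
  }
  if (nrow(treatments) < 1) stop("treatments must be non-empty", call. = FALSE)
  paths <- c(trait_csv, community_csv, env_csv, calibration_trait_csv,
             constraints_csv, observed_csv)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    trait_csv = trait_csv, community_csv = community_csv, env_csv = env_csv,
    calibration_trait_csv = calibration_trait_csv %||% trait_csv,
    constraints_csv = constraints_csv,
    observed_csv = observed_csv, observed_kind = observed_kind,
    treatments = treatments, tol = tol, max_iter = max_iter,
    on_infeasible = on_infeasible, n_perm = n_perm, scheme = scheme,
    seed = seed, out_dir = out_dir
  ), class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full CATS prediction pipeline
#'
#' Executes, in order: calibration (CWM trait-environment models fitted to
#' field data, unless constraints are supplied directly), CWM prediction at
#' the treatment environments, maxent prediction of species relative
#' abundances, evaluation against observed experimental communities
#' (fit statistics with permutation nulls, dominant-species accuracy, CWM
#' concordance) and a two-way PerMANOVA when treatment labels encode a
#' crossed design as "factorA-factorB". Every stage writes its artifact to
#' `cfg$out_dir`; the returned manifest lists files with MD5 checksums, so
#' re-runs under the same seed are verifiably identical.
#'
#' @param cfg a [pipeline_config()].
#' @return a `pipeline_run` list: `constraints`, `predicted`, `solutions`,
#'   `evaluation` (or `NULL`), `permanova` (or `NULL`), `fits` (or `NULL`),
#'   `manifest` (data frame of artifact paths and checksums), `log`
#'   (character vector of decided settings and diagnostics).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    paste0("seed: ", cfg$seed),
    paste0("maxent tol: ", format(cfg$tol), "; max_iter: ", cfg$max_iter,
           "; on_infeasible: ", cfg$on_infeasible),
    paste0("permutations: ", cfg$n_perm, "; scheme: ", cfg$scheme)
  )
  traits <- run_stage("read_traits", read_trait_table(cfg$trait_csv))

  fits <- NULL
  if (is.null(cfg$constraints_csv)) {
    calib <- run_stage("calibrate", {
      field_traits <- read_trait_table(cfg$calibration_trait_csv)
      community <- read_community_matrix(cfg$community_csv, kind = "cover")
      env <- read_environment_table(cfg$env_csv)
      cwm <- compute_cwm(relativize(community), field_traits)
      fits <- lapply(trait_names(field_traits), function(tr) {
        fit_cwm_model(cwm, env, tr)
      })
      names(fits) <- trait_names(field_traits)
      fits
    })
    fits <- calib
    for (nm in names(fits)) {
      write_cwm_fit(fits[[nm]], file.path(cfg$out_dir, paste0("fit_", nm, ".json")))
      log_lines <- c(log_lines, paste0(
        "calibrated ", nm, ": adj R2 = ",
        formatC(fits[[nm]]$adj_r2, digits = 3, format = "f")))
    }
    constraints <- run_stage("predict_cwm",
                             predict_cwm_table(fits, cfg$treatments))
  } else {
    constraints <- run_stage("read_constraints", read_cwm_table(cfg$constraints_csv))
    log_lines <- c(log_lines, "calibration skipped: constraints supplied directly")
  }
  write_cwm_table(constraints, file.path(cfg$out_dir, "predicted_cwm.csv"))
  for (i in seq_len(nrow(constraints))) {
    log_lines <- c(log_lines, paste0(
      "constraints[", constraints$unit_id[i], "]: ",
      paste(sprintf("%s=%.4g", setdiff(names(constraints), "unit_id"),
                    unlist(constraints[i, setdiff(names(constraints), "unit_id")])),
            collapse = ", ")))
  }

  pred <- run_stage("predict_abundances", predict_abundances(
    traits, constraints, tol = cfg$tol, max_iter = cfg$max_iter,
    on_infeasible = cfg$on_infeasible))
  write_community_matrix(pred$predicted,
                         file.path(cfg$out_dir, "predicted_abundances.csv"))
  diag_list <- lapply(pred$solutions, function(s) list(
    entropy = s$entropy, lambdas = as.list(s$lambdas),
    residuals = as.list(s$residuals), converged = s$converged,
    projected = s$projected, feasibility_distance = s$feasibility$distance))
  jsonlite::write_json(diag_list, file.path(cfg$out_dir, "maxent_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(pred$solutions)) {
    s <- pred$solutions[[nm]]
    log_lines <- c(log_lines, paste0(
      "maxent[", nm, "]: entropy = ", formatC(s$entropy, digits = 4, format = "f"),
      ", max residual = ", formatC(max(s$residuals_std), digits = 2, format = "e"),
      if (s$projected) paste0(" (constraints projected, distance ",
                              formatC(s$feasibility$distance, digits = 3,
                                      format = "g"), ")")))
  }

  evaluation <- NULL
  perm <- NULL
  if (!is.null(cfg$observed_csv)) {
    evaluation <- run_stage("evaluate", {
      obs <- read_community_matrix(cfg$observed_csv, kind = cfg$observed_kind)
      obs_rel <- relativize(obs)
      obs_means <- treatment_means(obs_rel)
      P <- unclass_matrix(pred$predicted)[rownames(obs_means), colnames(obs_means),
                                          drop = FALSE]
      fitres <- assess_fit(obs_means, P, n_perm = cfg$n_perm, seed = cfg$seed,
                           scheme = cfg$scheme)
      tops <- top_species_accuracy(obs_rel, unclass_matrix(pred$predicted))
      conc <- tryCatch({
        obs_cwm <- compute_cwm(obs_rel, traits)
        keep <- !attr(obs_rel, "zero_rows")
        obs_cwm_tr <- rowsum(
          as.matrix(obs_cwm[keep, trait_names(traits)]),
          attr(obs_rel, "treatment")[keep]
        ) / as.vector(table(attr(obs_rel, "treatment")[keep]))
        pred_cwm <- as.matrix(
          constraints[match(rownames(obs_cwm_tr), constraints$unit_id),
                      trait_names(traits)])
        rownames(pred_cwm) <- rownames(obs_cwm_tr)
        cwm_concordance(obs_cwm_tr, pred_cwm)
      }, error = function(e) NULL)
      list(fit = fitres, top_species = tops, cwm_concordance = conc,
           observed_means = obs_means)
    })
    jsonlite::write_json(list(
      r2 = evaluation$fit$r2, rmse_sqrt = evaluation$fit$rmse_sqrt,
      p_r2 = evaluation$fit$p_r2, p_rmse = evaluation$fit$p_rmse,
      n_perm = evaluation$fit$n_perm, scheme = evaluation$fit$scheme,
      pot_fraction = evaluation$top_species$pot_fraction,
      per_treatment = evaluation$top_species$per_treatment,
      cwm_concordance = evaluation$cwm_concordance
    ), file.path(cfg$out_dir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(
      data.frame(perm = seq_along(evaluation$fit$null_r2),
                 null_r2 = evaluation$fit$null_r2,
                 null_rmse = evaluation$fit$null_rmse),
      file.path(cfg$out_dir, "null_statistics.csv"), row.names = FALSE)
    log_lines <- c(log_lines, paste0(
      "evaluation: R2 = ", formatC(evaluation$fit$r2, digits = 3, format = "f"),
      " (P = ", formatC(evaluation$fit$p_r2, digits = 4, format = "f"),
      "), RMSE_sqrt = ", formatC(evaluation$fit$rmse_sqrt, digits = 3, format = "f"),
      " (P = ", formatC(evaluation$fit$p_rmse, digits = 4, format = "f"), ")"))

    # two-way PerMANOVA when treatment labels encode "factorA-factorB"
    obs <- read_community_matrix(cfg$observed_csv, kind = cfg$observed_kind)
    labels <- attr(obs, "treatment")
    if (!is.null(labels) && all(grepl("^[^-]+-[^-]+$", labels))) {
      perm <- run_stage("permanova", {
        obs_rel <- relativize(obs)
        keep <- !attr(obs_rel, "zero_rows")
        parts <- do.call(rbind, strsplit(labels[keep], "-", fixed = TRUE))
        m <- unclass_matrix(obs_rel)[keep, , drop = FALSE]
        permanova_2way(bray_curtis(m), parts[, 1], parts[, 2],
                       n_perm = cfg$n_perm, seed = cfg$seed,
                       names_ab = c("light", "soil"))
      })
      utils::write.csv(as.data.frame(perm),
                       file.path(cfg$out_dir, "permanova.csv"), row.names = FALSE)
    }
  }

  writeLines(log_lines, file.path(cfg$out_dir, "pipeline_log.txt"))
  files <- list.files(cfg$out_dir, full.names = TRUE)
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    row.names = NULL
  )
  structure(list(constraints = constraints, predicted = pred$predicted,
                 solutions = pred$solutions, evaluation = evaluation,
                 permanova = perm, fits = fits, manifest = manifest,
                 log = log_lines, out_dir = cfg$out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("catspredict pipeline run\n")
  cat("  artifacts in: ", x$out_dir, "\n", sep = "")
  cat("  ", nrow(x$manifest), " artifact(s)\n", sep = "")
  if (!is.null(x$evaluation)) {
    cat("  R2 = ", formatC(x$evaluation$fit$r2, digits = 3, format = "f"),
        ", RMSE_sqrt = ",
        formatC(x$evaluation$fit$rmse_sqrt, digits = 3, format = "f"), "\n",
        sep = "")
  }
  invisible(x)
}
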