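as_plain_matrix <- function(x) {
  if (inherits(x, "community_matrix")) unclass_matrix(x) else as.matrix(x)
}

check_fit_inputs <- function(observed, predicted) {
  o <- as_plain_matrix(observed); p <- as_plain_matrix(predicted)
  if (!all(dim(o) == dim(p))) {
    stop("observed and predicted matrices must have matching shapes", call. = FALSE)
  }
  if (!is.null(colnames(o)) && !is.null(colnames(p)) &&
      !identical(colnames(o), colnames(p))) {
    if (setequal(colnames(o), colnames(p))) {
      p <- p[, colnames(o), drop = FALSE]
    } else {
      stop("observed and predicted matrices have different species", call. = FALSE)
    }
  }
  if (any(o < 0) || any(p < 0)) {
    stop("abundances must be nonnegative", call. = FALSE)
  }
  list(o = o, p = p)
}

#' Squared correlation between observed and predicted abundances
#'
#' The squared Pearson correlation over all cells of the flattened
#' treatment x species matrices, computed on untransformed relative
#' abundances. This measures the degree of correlation between observed and
#' predicted community structure, not a regression-through-origin fit.
#'
#' @param observed,predicted matching T x S matrices of relative abundances
#'   (e.g. treatment means of observed pots vs. CATS predictions).
#' @return squared Pearson correlation in \[0, 1\].
#' @export
fit_r2 <- function(observed, predicted) {
  m <- check_fit_inputs(observed, predicted)
  if (stats::sd(m$o) == 0 || stats::sd(m$p) == 0) {
    stop("correlation undefined: zero variance in observed or predicted matrix",
         call. = FALSE)
  }
  stats::cor(as.vector(m$o), as.vector(m$p))^2
}

#' Root-mean-square error of square-root transformed abundances
#'
#' \deqn{RMSE_{sqrt} = \sqrt{\frac{1}{TS}\sum_{ts}(\sqrt{o_{ts}} - \sqrt{p_{ts}})^2}}
#' The square-root transform damps the influence of dominant species, so
#' this complements [fit_r2()] by weighting subordinate species more
#' evenly. For simplex-valued inputs it lies in \[0, 1\].
#'
#' @inheritParams fit_r2
#' @return RMSE of square-root transformed abundances (>= 0).
#' @export
rmse_sqrt <- function(observed, predicted) {
  m <- check_fit_inputs(observed, predicted)
  sqrt(mean((sqrt(m$o) - sqrt(m$p))^2))
}

#' Permutation test for prediction fit
#'
#' Compares an observed fit statistic ([fit_r2()] or [rmse_sqrt()]) to a
#' null distribution obtained by permuting the observed relative abundances
#' while holding predictions fixed. The default scheme permutes species
#' entries independently within each row (treatment), which preserves every
#' treatment's abundance profile but destroys species identity — the
#' hypothesis under test. `scheme = "rows"` instead permutes whole rows
#' across treatments. The p-value includes the observed statistic:
#' \eqn{p = (1 + b)/(1 + m)} with \eqn{b} the number of null statistics at
#' least as extreme as the observed one, so the attainable minimum at 999
#' permutations is 0.001.
#'
#' @inheritParams fit_r2
#' @param statistic `"r2"` (extreme = larger) or `"rmse_sqrt"` (extreme =
#'   smaller).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for reproducibility.
#' @param scheme `"within_row"` (default) or `"rows"`.
#' @return a `fit_assessment` list: observed `statistic` value, `p_value`,
#'   `null` (vector of permuted statistics), `n_perm`, `seed`, `scheme`.
#' @export
permutation_test <- function(observed, predicted,
                             statistic = c("r2", "rmse_sqrt"),
                             n_perm = 999, seed = 1,
                             scheme = c("within_row", "rows")) {
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  m <- check_fit_inputs(observed, predicted)
  stat_fun <- if (statistic == "r2") fit_r2 else rmse_sqrt
  obs_stat <- stat_fun(m$o, m$p)
  null <- numeric(n_perm)
  old_seed_state <- set_local_seed(seed)
  on.exit(restore_seed_state(old_seed_state), add = TRUE)
  S <- ncol(m$o)
  for (b in seq_len(n_perm)) {
    o_perm <- m$o
    if (scheme == "within_row") {
      for (r in seq_len(nrow(o_perm))) o_perm[r, ] <- o_perm[r, sample.int(S)]
    } else {
      o_perm <- o_perm[sample.int(nrow(o_perm)), , drop = FALSE]
    }
    null[b] <- stat_fun(o_perm, m$p)
  }
  extreme <- if (statistic == "r2") null >= obs_stat - 1e-12 else null <= obs_stat + 1e-12
  p <- (1 + sum(extreme)) / (1 + n_perm)
  structure(list(statistic = statistic, value = obs_stat, p_value = p,
                 null = null, n_perm = n_perm, seed = seed, scheme = scheme),
            class = "fit_assessment")
}

#' @export
print.fit_assessment <- function(x, ...) {
  cat("permutation test (", x$scheme, " scheme, ", x$n_perm, " permutations)\n",
      sep = "")
  cat("  ", x$statistic, " = ", formatC(x$value, digits = 3, format = "f"),
      ", P = ", formatC(x$p_value, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Assess fit with both statistics and their permutation nulls
#'
#' Convenience wrapper running [permutation_test()] for both [fit_r2()] and
#' [rmse_sqrt()] on the same pair of matrices with a shared seed.
#'
#' @inheritParams permutation_test
#' @return list with `r2`, `rmse_sqrt`, `p_r2`, `p_rmse`, `n_perm`, `seed`,
#'   `scheme`, and the two null vectors.
#' @export
assess_fit <- function(observed, predicted, n_perm = 999, seed = 1,
                       scheme = c("within_row", "rows")) {
  scheme <- match.arg(scheme)
  a <- permutation_test(observed, predicted, "r2", n_perm, seed, scheme)
  b <- permutation_test(observed, predicted, "rmse_sqrt", n_perm, seed, scheme)
  list(r2 = a$value, rmse_sqrt = b$value, p_r2 = a$p_value, p_rmse = b$p_value,
       n_perm = n_perm, seed = seed, scheme = scheme,
       null_r2 = a$null, null_rmse = b$null)
}

#' Treatment means of per-pot relative abundances
#'
#' Averages observed per-pot relative abundances within treatments,
#' excluding flagged all-zero pots (pots in which nothing emerged), to
#' produce the treatment x species matrix that predictions are evaluated
#' against.
#'
#' @param pots a relative `community_matrix` with a `treatment` attribute
#'   (or an explicit `treatment` argument).
#' @param treatment optional per-pot treatment labels overriding the
#'   attribute.
#' @return treatment x species matrix of mean relative abundances.
#' @export
treatment_means <- function(pots, treatment = NULL) {
  if (is.null(treatment)) treatment <- attr(pots, "treatment")
  if (is.null(treatment)) stop("no treatment labels supplied", call. = FALSE)
  m <- as_plain_matrix(pots)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  treatment <- treatment[keep]
  out <- rowsum(m, treatment) / as.vector(table(treatment)[sort(unique(treatment))])
  out[sort(unique(treatment)), , drop = FALSE]
}

#' Concordance between observed and predicted CWM traits
#'
#' Pearson correlation, per trait, between observed treatment-mean CWM
#' values and model-predicted CWM values across treatments, with the
#' classical t-distribution p-value.
#'
#' @param observed_cwm,predicted_cwm T x J matrices (or `cwm_table`s sharing
#'   `unit_id` order) of CWM values, T >= 3.
#' @return data frame with one row per trait: `trait`, `r`, `p_value`, `n`.
#' @export
cwm_concordance <- function(observed_cwm, predicted_cwm) {
  to_mat <- function(x) {
    if (inherits(x, "cwm_table") || is.data.frame(x)) {
      ids <- x$unit_id
      m <- as.matrix(x[setdiff(names(x), "unit_id")])
      rownames(m) <- ids
      m
    } else as.matrix(x)
  }
  o <- to_mat(observed_cwm); p <- to_mat(predicted_cwm)
  if (!all(dim(o) == dim(p))) stop("CWM matrices must match in shape", call. = FALSE)
  if (nrow(o) < 3) stop("need at least 3 units per trait", call. = FALSE)
  if (!is.null(rownames(o)) && !is.null(rownames(p)) &&
      setequal(rownames(o), rownames(p))) {
    p <- p[rownames(o), , drop = FALSE]
  }
  traits <- colnames(o)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(o)))
  res <- lapply(seq_along(traits), function(j) {
    if (stats::sd(o[, j]) == 0 || stats::sd(p[, j]) == 0) {
      stop("correlation undefined for trait '", traits[j],
           "': zero variance", call. = FALSE)
    }
    ct <- stats::cor.test(o[, j], p[, j])
    data.frame(trait = traits[j], r = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(o))
  })
  do.call(rbind, res)
}

#' Accuracy of predicted dominant species
#'
#' Checks whether the CATS model names the right dominant species: per
#' treatment, does the argmax of the predicted abundance vector match the
#' argmax of the observed treatment-mean vector; and across individual pots,
#' what fraction of (non-zero) pots are dominated by the species the model
#' predicts for their treatment. Ties in an observed maximum count as a hit
#' if the predicted dominant is among the tied species.
#'
#' @param observed_pots per-pot relative `community_matrix` with treatment
#'   labels (attribute or argument).
#' @param predicted treatment x species matrix of predicted relative
#'   abundances; row names must be treatment labels.
#' @param treatment optional per-pot treatment labels.
#' @return list with `per_treatment` (data frame: treatment, predicted and
#'   observed dominant species, hit flag) and `pot_fraction` (share of
#'   non-zero pots whose dominant species matches the prediction).
#' @export
top_species_accuracy <- function(observed_pots, predicted, treatment = NULL) {
  if (is.null(treatment)) treatment <- attr(observed_pots, "treatment")
  if (is.null(treatment)) stop("no treatment labels supplied", call. = FALSE)
  P <- as_plain_matrix(predicted)
  if (is.null(rownames(P))) stop("predicted matrix needs treatment row names",
                                 call. = FALSE)
  unknown <- setdiff(unique(treatment), rownames(P))
  if (length(unknown) > 0) {
    stop("treatment label(s) absent from predictions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  obs <- as_plain_matrix(observed_pots)
  if (!identical(colnames(obs), colnames(P))) {
    if (setequal(colnames(obs), colnames(P))) P <- P[, colnames(obs), drop = FALSE]
    else stop("species differ between observations and predictions", call. = FALSE)
  }
  means <- treatment_means(observed_pots, treatment)
  argmax_set <- function(v) colnames(P)[v >= max(v) - 1e-12]
  per_tr <- lapply(rownames(means), function(tr) {
    pred_top <- argmax_set(P[tr, ])[1]
    obs_top <- argmax_set(means[tr, ])
    data.frame(treatment = tr, predicted_top = pred_top,
               observed_top = paste(obs_top, collapse = "/"),
               hit = pred_top %in% obs_top)
  })
  per_tr <- do.call(rbind, per_tr)
  keep <- rowSums(obs) > 0
  obs_nz <- obs[keep, , drop = FALSE]
  tr_nz <- treatment[keep]
  hits <- vapply(seq_len(nrow(obs_nz)), function(i) {
    pred_top <- argmax_set(P[tr_nz[i], ])[1]
    pred_top %in% argmax_set(obs_nz[i, ])
  }, logical(1))
  list(per_treatment = per_tr, pot_fraction = mean(hits))
}
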