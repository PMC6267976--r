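#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarity
#' \deqn{d(x, y) = \sum_k |x_k - y_k| \, / \, \sum_k (x_k + y_k)}
#' between the rows of a community matrix, the standard distance for
#' multivariate composition data. All-zero rows are rejected because the
#' dissimilarity is undefined for them (exclude flagged empty pots first).
#'
#' @param m a `community_matrix` or nonnegative numeric matrix.
#' @return a `dist` object with sample labels.
#' @export
bray_curtis <- function(m) {
  x <- as_plain_matrix(m)
  if (any(x < 0)) stop("Bray-Curtis requires nonnegative values", call. = FALSE)
  zero <- rowSums(x) == 0
  if (any(zero)) {
    stop("Bray-Curtis undefined for all-zero row(s): ",
         paste(utils::head(rownames(x)[zero], 5), collapse = ", "), call. = FALSE)
  }
  vegan::vegdist(x, method = "bray")
}

check_two_way_design <- function(n, factor_a, factor_b) {
  if (length(factor_a) != n || length(factor_b) != n) {
    stop("factor labels must have one entry per sample", call. = FALSE)
  }
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    stop("empty design cell(s): every factor combination needs observations",
         call. = FALSE)
  }
  if (any(cells < 2)) {
    warning("some design cells have fewer than 2 replicates", call. = FALSE)
  }
  df_model <- (nlevels(fa) - 1) + (nlevels(fb) - 1) +
    (nlevels(fa) - 1) * (nlevels(fb) - 1)
  if (n <= df_model + 1) {
    stop("too few samples for the two-way model with interaction", call. = FALSE)
  }
  list(fa = fa, fb = fb)
}

#' Two-way PerMANOVA on a distance matrix
#'
#' Permutation-based multivariate analysis of variance for a crossed
#' two-way design with interaction, on any dissimilarity matrix. The
#' distance matrix is Gower-centered and partitioned by sequential (Type I)
#' projections for A, B and A x B; each term's pseudo-F is
#' (SS_term/df_term)/(SS_res/df_res), its R-squared is SS_term/SS_total,
#' and significance comes from free permutation of samples (rows and
#' columns of the distance matrix permuted together). Fitting is delegated
#' to [vegan::adonis2()], the standard implementation of this partition.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param factor_a,factor_b per-sample factor labels (>= 2 levels each).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param names_ab labels for the two factors in the output table.
#' @return a `permanova_result`: data frame with one row per term
#'   (A, B, A:B, Residual, Total) and columns `df`, `ss`, `pseudo_f`, `r2`,
#'   `p_value`; attributes `n_perm` and `seed`.
#' @export
permanova_2way <- function(d, factor_a, factor_b, n_perm = 999, seed = 1,
                           names_ab = c("A", "B")) {
  if (!inherits(d, "dist")) {
    dm <- as.matrix(d)
    if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-12 ||
        any(abs(diag(dm)) > 1e-12)) {
      stop("d must be a dist object or symmetric zero-diagonal matrix",
           call. = FALSE)
    }
    d <- stats::as.dist(dm)
  }
  n <- attr(d, "Size")
  des <- check_two_way_design(n, factor_a, factor_b)
  if (sum(d^2) == 0) {
    stop("degenerate design: all pairwise distances are zero (constant response)",
         call. = FALSE)
  }
  dat <- data.frame(.A = des$fa, .B = des$fb)
  old_seed_state <- set_local_seed(seed)
  on.exit(restore_seed_state(old_seed_state), add = TRUE)
  fit <- vegan::adonis2(d ~ .A * .B, data = dat, permutations = n_perm,
                        by = "terms")
  tab <- as.data.frame(fit)
  term_names <- c(names_ab[1], names_ab[2],
                  paste(names_ab[1], names_ab[2], sep = ":"),
                  "Residual", "Total")
  out <- data.frame(
    term = term_names,
    df = tab$Df,
    ss = tab$SumOfSqs,
    pseudo_f = tab$F,
    r2 = tab$R2,
    p_value = tab$`Pr(>F)`,
    row.names = NULL
  )
  structure(out, class = c("permanova_result", "data.frame"),
            n_perm = n_perm, seed = seed)
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("two-way PerMANOVA (", attr(x, "n_perm"), " permutations)\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Two-way PerMANOVA for a univariate response
#'
#' Runs [permanova_2way()] on the Euclidean distances of a single response
#' variable (an individual species' relative abundance, or a per-sample CWM
#' trait). With Euclidean distances each term's pseudo-F equals the
#' classical sequential two-way ANOVA F statistic on the raw values.
#'
#' @param y numeric response, one value per sample.
#' @inheritParams permanova_2way
#' @return a `permanova_result`.
#' @export
permanova_univariate <- function(y, factor_a, factor_b, n_perm = 999, seed = 1,
                                 names_ab = c("A", "B")) {
  if (anyNA(y) || any(!is.finite(y))) stop("response must be finite", call. = FALSE)
  if (stats::var(y) == 0) {
    stop("degenerate design: all pairwise distances are zero (constant response)",
         call. = FALSE)
  }
  permanova_2way(stats::dist(y), factor_a, factor_b, n_perm = n_perm,
                 seed = seed, names_ab = names_ab)
}
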