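#' Shannon entropy of a relative-abundance vector
#'
#' \deqn{H(p) = -\sum_i p_i \ln p_i} in nats, with the convention
#' \eqn{0 \ln 0 = 0}. This is the objective the CATS model maximizes:
#' among all abundance distributions consistent with the CWM constraints it
#' picks the most even one.
#'
#' @param p numeric vector on the unit simplex (nonnegative, sums to 1).
#' @return entropy in nats (scalar, >= 0).
#' @examples
#' entropy(c(0.5, 0.5))        # log(2)
#' entropy(rep(0.2, 5))        # log(5)
#' @export
entropy <- function(p) {
  if (any(p < 0)) stop("entropy() requires nonnegative entries", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6) {
    stop("entropy() requires a simplex vector (sum = 1)", call. = FALSE)
  }
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

#' Define a CATS maximum-entropy problem
#'
#' Packages the ingredients of the CATS prediction: the species trait matrix
#' \eqn{t_{ij}} (S species x J traits), the target community-weighted means
#' \eqn{\bar{T}_j} that act as equality constraints
#' \eqn{\sum_i p_i t_{ij} = \bar{T}_j}, and a prior distribution over the
#' species pool (uniform by default, i.e. the unweighted maxent model).
#'
#' Because the traits carry incommensurate units (mg, m g^-1, Julian day),
#' trait columns are z-standardized over the species pool before solving;
#' the solution is invariant to any affine rescaling of a trait column and
#' its constraint, so standardization changes nothing except making the
#' convergence tolerance meaningful across traits.
#'
#' @param traits a `trait_table` or numeric species x trait matrix with row
#'   and column names.
#' @param constraints named numeric vector of target CWM values; names must
#'   match trait columns.
#' @param prior optional prior relative abundances (defaults to uniform).
#' @param standardize z-standardize trait columns before solving (default
#'   `TRUE`; the reported solution is invariant to this choice).
#' @return a `maxent_problem` object.
#' @export
maxent_problem <- function(traits, constraints, prior = NULL, standardize = TRUE) {
  tm <- if (inherits(traits, "trait_table")) trait_matrix(traits) else as.matrix(traits)
  if (is.null(rownames(tm))) rownames(tm) <- paste0("sp", seq_len(nrow(tm)))
  if (is.null(colnames(tm))) colnames(tm) <- paste0("trait", seq_len(ncol(tm)))
  S <- nrow(tm); J <- ncol(tm)
  if (S < 2) stop("need at least 2 species", call. = FALSE)
  if (J < 1) stop("need at least 1 trait", call. = FALSE)
  if (anyNA(tm) || any(!is.finite(tm))) stop("trait values must be finite", call. = FALSE)
  constraints <- unlist(constraints)
  if (is.null(names(constraints))) {
    if (length(constraints) != J) {
      stop("unnamed constraints must have one value per trait column", call. = FALSE)
    }
    names(constraints) <- colnames(tm)
  }
  missing_tr <- setdiff(colnames(tm), names(constraints))
  if (length(missing_tr) > 0) {
    stop("no constraint supplied for trait(s): ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  constraints <- constraints[colnames(tm)]
  if (anyNA(constraints) || any(!is.finite(constraints))) {
    stop("constraint values must be finite", call. = FALSE)
  }
  if (is.null(prior)) {
    prior <- rep(1 / S, S)
  } else {
    if (length(prior) != S) stop("prior must have one entry per species", call. = FALSE)
    if (any(prior < 0)) stop("prior must be nonnegative", call. = FALSE)
    if (abs(sum(prior) - 1) > 1e-9) stop("prior must sum to 1", call. = FALSE)
  }
  structure(list(traits = tm, constraints = constraints,
                 prior = as.numeric(prior), standardize = isTRUE(standardize)),
            class = "maxent_problem")
}

#' @export
print.maxent_problem <- function(x, ...) {
  cat("CATS maxent problem: ", nrow(x$traits), " species, ",
      ncol(x$traits), " trait constraint(s)\n", sep = "")
  print(x$constraints)
  invisible(x)
}

# Standardized trait matrix and constraint vector. Zero-variance columns are
# centered and left unscaled; the hull there is a single point, so any
# mismatch shows up as infeasibility.
standardize_problem <- function(problem) {
  tm <- problem$traits
  if (problem$standardize) {
    ctr <- colMeans(tm)
    scl <- apply(tm, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(tm)); scl <- rep(1, ncol(tm))
  }
  list(
    traits = sweep(sweep(tm, 2, ctr), 2, scl, "/"),
    constraints = (problem$constraints - ctr) / scl,
    center = ctr, scale = scl
  )
}

# Euclidean projection of v onto the unit simplex (sort-based algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Projection of the constraint point onto the convex hull of the species'
# standardized trait vectors: minimize ||t(A) %*% w - b||^2 over the simplex
# by accelerated projected gradient, then polish the active set with an
# equality-constrained least-squares solve.
hull_projection <- function(A, b, max_iter = 20000) {
  S <- nrow(A)
  w <- rep(1 / S, S)
  G <- A %*% t(A)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, .Machine$double.eps)
  v <- w; tk <- 1
  for (it in seq_len(max_iter)) {
    grad <- as.numeric(A %*% (crossprod(A, v) - b))
    w_new <- project_simplex(v - grad / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    v <- w_new + ((tk - 1) / t_new) * (w_new - w)
    if (max(abs(w_new - w)) < 1e-15) { w <- w_new; break }
    w <- w_new; tk <- t_new
  }
  # active-set polish: exact solve on the support found by FISTA
  supp <- which(w > 1e-9)
  if (length(supp) >= 1) {
    m <- length(supp)
    As <- A[supp, , drop = FALSE]
    if (m == 1) {
      ws <- 1
    } else {
      # parameterize w = e1 + N u with N spanning the zero-sum subspace
      N <- rbind(-rep(1, m - 1), diag(m - 1))
      X <- crossprod(As, N)                 # J x (m-1)
      y <- b - as.numeric(crossprod(As, c(1, rep(0, m - 1))))
      cf <- stats::lm.fit(as.matrix(X), y)$coefficients
      cf[is.na(cf)] <- 0
      ws <- as.numeric(c(1, rep(0, m - 1)) + N %*% cf)
    }
    if (all(ws >= -1e-12)) {
      w_pol <- rep(0, S)
      w_pol[supp] <- pmax(ws, 0)
      w_pol <- w_pol / sum(w_pol)
      if (sum((crossprod(A, w_pol) - b)^2) <= sum((crossprod(A, w) - b)^2) + 1e-15) {
        w <- w_pol
      }
    }
  }
  proj <- as.numeric(crossprod(A, w))
  list(weights = w, projected = proj,
       distance = sqrt(sum((proj - b)^2)))
}

#' Check whether CWM constraints are attainable
#'
#' A CWM constraint vector is attainable by some abundance distribution
#' exactly when it lies in the convex hull of the species' trait vectors.
#' Predicted CWM constraints from a trait-environment model can fall outside
#' the hull of a small species pool (e.g. when the model extrapolates), in
#' which case no abundance distribution satisfies them; this reports the
#' Euclidean projection (in standardized trait units) of the target onto the
#' hull and the projection distance.
#'
#' @param problem a [maxent_problem()].
#' @param tol hull-membership tolerance on the projection distance in
#'   standardized trait units (default 1e-8).
#' @return list with `feasible` (logical), `projected_constraints` (length-J,
#'   original trait units), `distance` (standardized units) and
#'   `projection_weights` (a simplex vector attaining the projection).
#' @export
check_feasibility <- function(problem, tol = 1e-8) {
  stopifnot(inherits(problem, "maxent_problem"))
  std <- standardize_problem(problem)
  pr <- hull_projection(std$traits, std$constraints)
  list(
    feasible = pr$distance <= tol,
    projected_constraints = stats::setNames(
      pr$projected * std$scale + std$center, colnames(problem$traits)),
    distance = pr$distance,
    projection_weights = stats::setNames(pr$weights, rownames(problem$traits))
  )
}

#' Solve the CATS maximum-entropy model
#'
#' Finds the species relative-abundance distribution \eqn{p} that maximizes
#' the entropy \eqn{-\sum_i p_i \ln p_i} (relative to the prior, if one is
#' given) subject to the CWM equality constraints
#' \eqn{\sum_i p_i t_{ij} = \bar{T}_j} and \eqn{\sum_i p_i = 1}. The solution
#' has the exponential-family (Gibbs) form
#' \deqn{p_i \propto q_i \exp\left(\sum_j \lambda_j \tilde t_{ij}\right)}
#' with \eqn{q} the prior and \eqn{\tilde t} the standardized traits; the
#' dual coefficients \eqn{\lambda} are found by damped Newton iteration on
#' the convex dual objective \eqn{\log Z(\lambda) - \lambda^\top \tilde{T}},
#' with log-sum-exp stabilization. For the problem sizes that arise here
#' (a handful of species, up to three traits) convergence is quadratic and
#' takes a few iterations.
#'
#' @param problem a [maxent_problem()].
#' @param tol convergence tolerance on the maximum constraint residual in
#'   standardized trait units (default 1e-8).
#' @param max_iter maximum Newton iterations (default 10000).
#' @param on_infeasible what to do when the constraints lie outside the
#'   convex hull of the trait vectors: `"error"` (default) aborts with the
#'   projection report; `"project"` substitutes the hull projection as the
#'   target and records the projection distance.
#' @return a `maxent_solution`: `p` (named simplex vector), `lambdas` (dual
#'   coefficients per standardized trait), `log_partition`, `entropy` (nats),
#'   `residuals` (absolute constraint violations, original units),
#'   `residuals_std` (standardized units), `converged`, `iterations`,
#'   `feasibility` (the [check_feasibility()] report) and `projected`
#'   (whether the target was replaced by its hull projection).
#' @examples
#' pr <- maxent_problem(matrix(c(0, 1), 2, 1,
#'                             dimnames = list(c("a", "b"), "x")),
#'                      c(x = 0.7))
#' solve_maxent(pr)$p    # (0.3, 0.7)
#' @export
solve_maxent <- function(problem, tol = 1e-8, max_iter = 10000,
                         on_infeasible = c("error", "project")) {
  stopifnot(inherits(problem, "maxent_problem"))
  on_infeasible <- match.arg(on_infeasible)
  feas_tol <- max(1e-8, tol)
  feas <- check_feasibility(problem, tol = feas_tol)
  std <- standardize_problem(problem)
  target_raw <- problem$constraints
  projected <- FALSE
  b <- std$constraints
  if (!feas$feasible) {
    if (on_infeasible == "error") {
      stop("CWM constraints lie outside the convex hull of the species traits ",
           "(distance ", formatC(feas$distance, digits = 4, format = "g"),
           " in standardized units); rerun with on_infeasible = 'project' ",
           "to use the hull projection", call. = FALSE)
    }
    b <- (feas$projected_constraints - std$center) / std$scale
    target_raw <- feas$projected_constraints
    projected <- TRUE
  }
  A <- std$traits                       # S x J standardized traits
  S <- nrow(A); J <- ncol(A)
  q <- problem$prior
  logq <- ifelse(q > 0, log(q), -Inf)

  # dual objective phi(lambda) = logZ - lambda.b ; grad = E_p[t] - b
  eval_state <- function(lambda) {
    eta <- logq + as.numeric(A %*% lambda)
    m <- max(eta)
    w <- exp(eta - m)
    Z <- sum(w)
    p <- w / Z
    list(p = p, logZ = m + log(Z),
         phi = m + log(Z) - sum(lambda * b),
         grad = as.numeric(crossprod(A, p)) - b)
  }

  lambda <- rep(0, J)
  st <- eval_state(lambda)
  iters <- 0
  converged <- max(abs(st$grad)) <= tol
  while (!converged && iters < max_iter) {
    iters <- iters + 1
    p <- st$p
    Ap <- A * p
    H <- crossprod(A, Ap) - tcrossprod(crossprod(A, p))   # Cov_p[t]
    step <- tryCatch(
      solve(H + diag(1e-12, J), -st$grad),
      error = function(e) -st$grad                         # gradient fallback
    )
    # backtracking line search on the dual
    alpha <- 1
    repeat {
      cand <- eval_state(lambda + alpha * step)
      if (cand$phi <= st$phi + 1e-4 * alpha * sum(st$grad * step) ||
          alpha < 1e-12) break
      alpha <- alpha / 2
    }
    if (cand$phi >= st$phi && max(abs(st$grad)) <= 1e3 * tol) {
      # no further progress possible at this precision
      converged <- max(abs(st$grad)) <= tol
      break
    }
    lambda <- lambda + alpha * step
    st <- cand
    converged <- max(abs(st$grad)) <= tol
  }
  p <- stats::setNames(st$p, rownames(problem$traits))
  achieved_raw <- as.numeric(crossprod(problem$traits, p))
  structure(list(
    p = p,
    lambdas = stats::setNames(lambda, colnames(problem$traits)),
    log_partition = st$logZ,
    entropy = entropy(p),
    residuals = stats::setNames(abs(achieved_raw - target_raw),
                                colnames(problem$traits)),
    residuals_std = stats::setNames(abs(st$grad), colnames(problem$traits)),
    converged = converged,
    iterations = iters,
    feasibility = feas,
    projected = projected
  ), class = "maxent_solution")
}

#' @export
print.maxent_solution <- function(x, ...) {
  cat("CATS maxent solution (", if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iteration(s))\n", sep = "")
  cat("  entropy: ", formatC(x$entropy, digits = 4, format = "f"), " nats\n", sep = "")
  if (x$projected) {
    cat("  note: constraints were projected onto the trait hull (distance ",
        formatC(x$feasibility$distance, digits = 4, format = "g"), ")\n", sep = "")
  }
  cat("  predicted relative abundances:\n")
  print(round(x$p, 4))
  cat("  max constraint residual (standardized): ",
      formatC(max(x$residuals_std), digits = 3, format = "e"), "\n", sep = "")
  invisible(x)
}

#' Predict relative abundances for a table of CWM constraints
#'
#' Runs [solve_maxent()] once per row of a constraint table (one row per
#' treatment or site), returning the predicted treatment x species
#' relative-abundance matrix plus per-treatment solver diagnostics.
#'
#' @param traits a `trait_table` (or species x trait matrix) for the species
#'   pool to predict over.
#' @param constraints a `cwm_table` (`unit_id` plus one column per trait).
#' @param prior,tol,max_iter,on_infeasible passed to [solve_maxent()].
#' @return list with `predicted` (a relative `community_matrix`, rows =
#'   constraint units) and `solutions` (named list of `maxent_solution`s).
#' @export
predict_abundances <- function(traits, constraints, prior = NULL,
                               tol = 1e-8, max_iter = 10000,
                               on_infeasible = c("error", "project")) {
  on_infeasible <- match.arg(on_infeasible)
  tm <- if (inherits(traits, "trait_table")) trait_matrix(traits) else as.matrix(traits)
  tr_cols <- intersect(names(constraints), colnames(tm))
  if (length(tr_cols) == 0) {
    stop("constraint table shares no trait columns with the trait table", call. = FALSE)
  }
  sols <- list()
  P <- matrix(NA_real_, nrow(constraints), nrow(tm),
              dimnames = list(constraints$unit_id, rownames(tm)))
  for (i in seq_len(nrow(constraints))) {
    tgt <- unlist(constraints[i, tr_cols])
    pr <- maxent_problem(tm[, tr_cols, drop = FALSE], tgt, prior = prior)
    sol <- solve_maxent(pr, tol = tol, max_iter = max_iter,
                        on_infeasible = on_infeasible)
    sols[[as.character(constraints$unit_id[i])]] <- sol
    P[i, ] <- sol$p
  }
  list(predicted = community_matrix(P, kind = "relative"), solutions = sols)
}
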