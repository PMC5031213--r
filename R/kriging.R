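#' Gaussian correlation between feature vectors
#'
#' The simple-kriging basis function with all exponents fixed at 2:
#' `phi(x_i - x_j) = exp(-sum_h theta_h |x_ih - x_jh|^2)`. Symmetric, equal to
#' 1 exactly when the two vectors coincide, and strictly positive.
#'
#' @param x_i,x_j Numeric feature vectors of equal length.
#' @param theta Positive length-scale hyperparameters, one per feature.
#' @return A scalar in (0, 1].
#' @export
krig_correlation <- function(x_i, x_j, theta) {
  if (length(x_i) != length(x_j) || length(theta) != length(x_i)) {
    abort("x_i, x_j and theta must have equal lengths", class = "waterkrig_dimension_error")
  }
  if (any(theta <= 0)) abort("theta must be positive", class = "waterkrig_domain_error")
  exp(-sum(theta * (x_i - x_j)^2))
}

# weighted squared distances. Small problems use exact per-feature
# differences; large ones the centered Gram trick (centering columns first
# keeps the cancellation error far below the kernel's resolution).
.sq_dist_weighted <- function(X, theta, X2 = NULL) {
  n1 <- nrow(X); n2 <- if (is.null(X2)) n1 else nrow(X2)
  d <- ncol(X)
  if (as.double(n1) * n2 * d <= 4e6) {
    D <- matrix(0, n1, n2)
    for (h in seq_len(d)) {
      D <- D + theta[h] * (outer(X[, h], (if (is.null(X2)) X else X2)[, h], "-"))^2
    }
    return(D)
  }
  ctr <- colMeans(X)
  Xs <- (X - rep(ctr, each = n1)) * rep(sqrt(theta), each = n1)
  s1 <- rowSums(Xs^2)
  if (is.null(X2)) {
    D <- outer(s1, s1, "+") - 2 * tcrossprod(Xs)
  } else {
    X2s <- (X2 - rep(ctr, each = n2)) * rep(sqrt(theta), each = n2)
    D <- outer(s1, rowSums(X2s^2), "+") - 2 * tcrossprod(Xs, X2s)
  }
  D[D < 0] <- 0
  D
}

#' Build and factorize the training correlation matrix
#'
#' Computes `R_ij = phi(x_i - x_j)` for all training pairs, adds a nugget to
#' the diagonal, and Cholesky-factorizes. If factorization fails the nugget is
#' escalated tenfold up to `nugget_max`; persistent failure raises a
#' conditioning error reporting the last nugget tried.
#'
#' @param X Numeric matrix of training inputs (rows = points).
#' @param theta Positive length-scale hyperparameters.
#' @param nugget Initial diagonal regularization (default 1e-12).
#' @param nugget_max Largest nugget tried during escalation (default 1e-6).
#' @return A list: `R` (the regularized matrix), `chol` (upper-triangular
#'   factor), `log_det` (log-determinant), `nugget` (value actually used) and
#'   `escalated` (whether the initial nugget had to be raised).
#' @export
krig_correlation_matrix <- function(X, theta, nugget = 1e-12, nugget_max = 1e-6) {
  if (!all(is.finite(X))) abort("X must be finite", class = "waterkrig_domain_error")
  R0 <- exp(-.sq_dist_weighted(as.matrix(X), theta))
  ng <- nugget
  repeat {
    R <- R0
    diag(R) <- diag(R) + ng
    U <- tryCatch(chol(R), error = function(e) NULL)
    if (!is.null(U)) {
      return(list(R = R, chol = U, log_det = 2 * sum(log(diag(U))),
                  nugget = ng, escalated = ng > nugget))
    }
    if (ng >= nugget_max) {
      abort(sprintf("correlation matrix is not positive definite even with nugget %g", ng),
            class = "waterkrig_conditioning_error")
    }
    ng <- min(ng * 10, nugget_max)
    if (ng == 0) ng <- 1e-12
  }
}

# solve R^{-1} v given the upper Cholesky factor
.chol_solve <- function(U, v) backsolve(U, backsolve(U, v, transpose = TRUE))

#' Concentrated log-likelihood of a kriging model
#'
#' Profiles the mean and variance out of the Gaussian log-likelihood: the
#' generalized-least-squares mean `mu_hat = (1' R^-1 y) / (1' R^-1 1)` and
#' variance `sigma2_hat = (y - 1 mu)' R^-1 (y - 1 mu) / N_t` are plugged back
#' in, leaving a function of `theta` alone:
#' `L = -N_t/2 log(sigma2_hat) - 1/2 log|R| - N_t/2`.
#' `sigma2_hat` is floored at 1e-14 before the logarithm so a constant
#' response does not produce `-Inf`/`NaN`.
#'
#' @param X Training inputs (N_t x d matrix, or a data frame of features).
#' @param y Training responses (length N_t).
#' @inheritParams krig_correlation_matrix
#' @return A list: `L` (log-likelihood), `mu_hat`, `sigma2_hat`, `nugget`,
#'   `condition_flag` (nugget escalation happened).
#' @export
krig_likelihood <- function(X, y, theta, nugget = 1e-12, nugget_max = 1e-6) {
  X <- as.matrix(X)
  .check_training(X, y)
  fac <- krig_correlation_matrix(X, theta, nugget, nugget_max)
  .likelihood_given_factor(fac, y)
}

.likelihood_given_factor <- function(fac, y) {
  n <- length(y)
  ones <- rep(1, n)
  Ri1 <- .chol_solve(fac$chol, ones)
  Riy <- .chol_solve(fac$chol, y)
  mu <- sum(y * Ri1) / sum(Ri1)
  r <- y - mu
  quad <- sum(r * (Riy - mu * Ri1))    # r' R^-1 r
  sigma2 <- max(quad / n, 0)
  s2f <- max(sigma2, 1e-14)
  L <- -n / 2 * log(s2f) - fac$log_det / 2 - quad / (2 * s2f)
  list(L = L, mu_hat = mu, sigma2_hat = sigma2, nugget = fac$nugget,
       condition_flag = fac$escalated)
}

.check_training <- function(X, y) {
  if (nrow(X) != length(y)) abort("X and y sizes disagree", class = "waterkrig_dimension_error")
  if (nrow(X) < 2) abort("need at least 2 training points", class = "waterkrig_domain_error")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort("training data must be finite", class = "waterkrig_domain_error")
  }
}

#' Optimizer settings for kriging hyperparameter search
#'
#' The search runs in log10(theta) space within `log10_bounds`. Defaults are
#' the conventional particle-swarm constriction setup (inertia 0.729,
#' cognitive/social 1.494) and differential evolution rand/1/bin with F = 0.8,
#' CR = 0.9. One particle (or population member) is initialized at the
#' variance heuristic `theta_h = 1/(d var(x_h))`, which gives low-budget
#' searches a physically sensible anchor.
#'
#' @param method `"pso"` or `"de"`.
#' @param particles Swarm / population size.
#' @param iterations Maximum iterations (generations).
#' @param inertia,cognitive,social PSO coefficients.
#' @param f,cr DE differential weight and crossover rate.
#' @param log10_bounds Length-2 lower/upper bounds on log10(theta).
#' @param stagnation Stop after this many iterations without improvement.
#' @param nugget,nugget_max Diagonal regularization policy (see
#'   [krig_correlation_matrix()]).
#' @param seed Integer seed making the search deterministic.
#' @return A list of class `krig_control`.
#' @export
krig_control <- function(method = c("pso", "de"), particles = 40L, iterations = 500L,
                         inertia = 0.729, cognitive = 1.494, social = 1.494,
                         f = 0.8, cr = 0.9, log10_bounds = c(-6, 3),
                         stagnation = 50L, nugget = 1e-12, nugget_max = 1e-6,
                         seed = 42L) {
  method <- match.arg(method)
  if (particles < 2 || iterations < 1) {
    abort("need particles >= 2 and iterations >= 1", class = "waterkrig_domain_error")
  }
  if (length(log10_bounds) != 2 || diff(log10_bounds) <= 0) {
    abort("log10_bounds must be an increasing pair", class = "waterkrig_domain_error")
  }
  structure(list(method = method, particles = as.integer(particles),
                 iterations = as.integer(iterations), inertia = inertia,
                 cognitive = cognitive, social = social, f = f, cr = cr,
                 log10_bounds = log10_bounds, stagnation = as.integer(stagnation),
                 nugget = nugget, nugget_max = nugget_max, seed = as.integer(seed)),
            class = "krig_control")
}

#' Maximize the concentrated log-likelihood over theta
#'
#' Global search for the Gaussian-correlation length scales by particle swarm
#' or differential evolution, in log10(theta) space. Deterministic given
#' `control$seed`.
#'
#' @inheritParams krig_likelihood
#' @param control A [krig_control()].
#' @return A list: `theta` (best hyperparameters), `L` (its log-likelihood),
#'   `evaluations` (number of likelihood evaluations), `iterations` (performed),
#'   plus the `mu_hat`/`sigma2_hat`/`nugget`/`condition_flag` of the optimum.
#' @export
krig_optimize <- function(X, y, control = krig_control()) {
  X <- as.matrix(X)
  .check_training(X, y)
  d <- ncol(X)
  lb <- control$log10_bounds[1]; ub <- control$log10_bounds[2]
  n_eval <- 0L
  best_extra <- NULL
  objective <- function(log_theta) {
    n_eval <<- n_eval + 1L
    out <- tryCatch(krig_likelihood(X, y, 10^log_theta, control$nugget, control$nugget_max),
                    waterkrig_conditioning_error = function(e) NULL)
    if (is.null(out) || !is.finite(out$L)) return(list(L = -Inf, extra = NULL))
    list(L = out$L, extra = out)
  }
  v <- pmax(apply(X, 2, var), 1e-12)
  init_guess <- pmin(pmax(log10(1 / (d * v)), lb), ub)

  res <- withr::with_seed(control$seed, {
    if (control$method == "pso") {
      .pso_maximize(objective, d, lb, ub, control, init_guess)
    } else {
      .de_maximize(objective, d, lb, ub, control, init_guess)
    }
  })
  if (!is.finite(res$L)) {
    abort("all likelihood evaluations failed (conditioning)",
          class = "waterkrig_optimization_error")
  }
  c(list(theta = 10^res$x, L = res$L, evaluations = n_eval, iterations = res$iters),
    res$extra)
}

.pso_maximize <- function(objective, d, lb, ub, control, init_guess) {
  np <- control$particles
  pos <- matrix(runif(np * d, lb, ub), np, d)
  pos[1, ] <- init_guess
  vel <- matrix(0, np, d)
  pbest <- pos
  pbest_val <- rep(-Inf, np)
  gbest <- init_guess; gbest_val <- -Inf; gbest_extra <- NULL
  stagnant <- 0L; iters <- 0L
  vmax <- (ub - lb) / 2
  for (it in seq_len(control$iterations)) {
    iters <- it
    improved <- FALSE
    for (i in seq_len(np)) {
      o <- objective(pos[i, ])
      if (o$L > pbest_val[i]) { pbest_val[i] <- o$L; pbest[i, ] <- pos[i, ] }
      if (o$L > gbest_val) {
        gbest_val <- o$L; gbest <- pos[i, ]; gbest_extra <- o$extra; improved <- TRUE
      }
    }
    stagnant <- if (improved) 0L else stagnant + 1L
    if (stagnant >= control$stagnation) break
    r1 <- matrix(runif(np * d), np, d); r2 <- matrix(runif(np * d), np, d)
    vel <- control$inertia * vel +
      control$cognitive * r1 * (pbest - pos) +
      control$social * r2 * (sweep(matrix(0, np, d), 2, gbest, "+") - pos)
    vel <- pmin(pmax(vel, -vmax), vmax)
    pos <- pmin(pmax(pos + vel, lb), ub)
  }
  list(x = gbest, L = gbest_val, extra = gbest_extra, iters = iters)
}

.de_maximize <- function(objective, d, lb, ub, control, init_guess) {
  np <- max(control$particles, 4L)
  pop <- matrix(runif(np * d, lb, ub), np, d)
  pop[1, ] <- init_guess
  vals <- rep(-Inf, np); extras <- vector("list", np)
  for (i in seq_len(np)) {
    o <- objective(pop[i, ]); vals[i] <- o$L; extras[[i]] <- o$extra
  }
  stagnant <- 0L; iters <- 0L
  for (it in seq_len(control$iterations)) {
    iters <- it
    improved <- FALSE
    best_before <- max(vals)
    for (i in seq_len(np)) {
      r <- sample(setdiff(seq_len(np), i), 3)
      mutant <- pop[r[1], ] + control$f * (pop[r[2], ] - pop[r[3], ])
      mutant <- pmin(pmax(mutant, lb), ub)
      jrand <- sample.int(d, 1)
      cross <- runif(d) < control$cr
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      o <- objective(trial)
      if (o$L >= vals[i]) {
        pop[i, ] <- trial; vals[i] <- o$L; extras[[i]] <- o$extra
        if (o$L > best_before) improved <- TRUE
      }
    }
    stagnant <- if (improved) 0L else stagnant + 1L
    if (stagnant >= control$stagnation) break
  }
  b <- which.max(vals)
  list(x = pop[b, ], L = vals[b], extra = extras[[b]], iters = iters)
}

#' Fit a simple-kriging model
#'
#' Optimizes the Gaussian-correlation length scales by maximizing the
#' concentrated log-likelihood, then computes the kriging weights
#' `a = R^-1 (y - 1 mu_hat)`, which make the predictor
#' `y_hat(x*) = mu_hat + sum_i a_i phi(x* - x_i)` interpolate the training
#' responses exactly (up to the nugget).
#'
#' @param data A data frame containing the feature columns and the response.
#' @param response Name of the response column (default `"value"`).
#' @param features Character vector of feature column names; default all
#'   numeric columns except the response and any `cluster` id column.
#' @param control A [krig_control()].
#' @param theta Optional fixed hyperparameters; skips the optimizer.
#' @return An object of class `krig`, supporting [predict()][predict.krig],
#'   [tidy()], [glance()], [write_krig()].
#' @examples
#' d <- tibble::tibble(x1 = runif(20), x2 = runif(20))
#' d$value <- sin(3 * d$x1) + d$x2
#' m <- krig_fit(d, control = krig_control(particles = 8, iterations = 15, seed = 1))
#' predict(m, d[1:3, ])
#' @export
krig_fit <- function(data, response = "value", features = NULL,
                     control = krig_control(), theta = NULL) {
  if (!response %in% names(data)) {
    abort(sprintf("response column '%s' not found", response), class = "waterkrig_domain_error")
  }
  features <- features %||% setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                                    c(response, "cluster"))
  if (!length(features)) abort("no feature columns", class = "waterkrig_domain_error")
  X <- as.matrix(data[features])
  y <- data[[response]]
  .check_training(X, y)

  if (is.null(theta)) {
    opt <- krig_optimize(X, y, control)
  } else {
    if (length(theta) != ncol(X)) abort("theta length != feature count",
                                        class = "waterkrig_dimension_error")
    lk <- krig_likelihood(X, y, theta, control$nugget, control$nugget_max)
    opt <- c(list(theta = theta, evaluations = 1L, iterations = 0L), lk)
  }
  fac <- krig_correlation_matrix(X, opt$theta, opt$nugget, control$nugget_max)
  a <- .chol_solve(fac$chol, y - opt$mu_hat)
  structure(list(
    theta = opt$theta, p = rep(2, ncol(X)), mu_hat = opt$mu_hat,
    sigma2_hat = opt$sigma2_hat, weights = as.numeric(a), X = X,
    feature_names = features, response = response, nugget = fac$nugget,
    condition_flag = fac$escalated || isTRUE(opt$condition_flag),
    log_lik = opt$L, evaluations = opt$evaluations, method = control$method,
    seed = control$seed, version = "1.0"
  ), class = "krig")
}

#' @export
print.krig <- function(x, ...) {
  cat(sprintf("<krig> %d training points, %d features, response '%s'\n",
              nrow(x$X), length(x$theta), x$response))
  cat(sprintf("  log-likelihood %.4f | mu_hat %.6g | sigma2_hat %.6g | nugget %g\n",
              x$log_lik, x$mu_hat, x$sigma2_hat, x$nugget))
  invisible(x)
}

#' Predict with a fitted kriging model
#'
#' @param object A `krig` model.
#' @param newdata A data frame containing the model's feature columns, or a
#'   numeric matrix/vector in the training feature order.
#' @param ... Unused.
#' @return A numeric vector of predictions.
#' @export
predict.krig <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    miss <- setdiff(object$feature_names, names(newdata))
    if (length(miss)) {
      abort(paste0("newdata is missing feature(s): ", paste(head(miss, 3), collapse = ", ")),
            class = "waterkrig_dimension_error")
    }
    Xq <- as.matrix(newdata[object$feature_names])
  } else {
    Xq <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
    if (ncol(Xq) != length(object$theta)) {
      abort("newdata has the wrong number of features", class = "waterkrig_dimension_error")
    }
  }
  D <- .sq_dist_weighted(Xq, object$theta, object$X)
  phi <- exp(-D)
  # the nugget is interpolating jitter, not observation noise: a query that
  # coincides with a training input sees the regularized diagonal, which makes
  # the predictor reproduce the training value exactly
  phi[D == 0] <- phi[D == 0] + object$nugget
  as.numeric(object$mu_hat + phi %*% object$weights)
}

#' @export
tidy.krig <- function(x, ...) {
  tibble::tibble(term = x$feature_names, theta = x$theta, p = x$p)
}

#' @export
glance.krig <- function(x, ...) {
  tibble::tibble(n = nrow(x$X), d = length(x$theta), log_lik = x$log_lik,
                 mu_hat = x$mu_hat, sigma2_hat = x$sigma2_hat, nugget = x$nugget,
                 condition_flag = x$condition_flag, method = x$method, seed = x$seed)
}

#' Save / load a kriging model as a versioned JSON artifact
#'
#' The artifact stores hyperparameters, mean, variance, weights, nugget, the
#' training inputs and metadata (format version, response name, seed) at full
#' floating-point precision, so a save/load round trip reproduces predictions
#' bit-identically.
#'
#' @param model A `krig` model.
#' @param path File path (JSON).
#' @return `write_krig()` returns `path` invisibly; `read_krig()` the model.
#' @export
write_krig <- function(model, path) {
  stopifnot(inherits(model, "krig"))
  obj <- unclass(model)
  obj$X <- list(nrow = nrow(model$X), values = as.numeric(model$X))
  # 17 significant digits: doubles survive the round trip bit-identically
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_krig
#' @export
read_krig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$version)) {
    abort("artifact has no format version", class = "waterkrig_artifact_error")
  }
  if (!identical(obj$version, "1.0")) {
    abort(sprintf("artifact format version '%s' is not supported (expected 1.0)", obj$version),
          class = "waterkrig_artifact_error")
  }
  need <- c("theta", "mu_hat", "sigma2_hat", "weights", "X", "feature_names", "nugget")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    abort(paste0("artifact is missing field(s): ", paste(miss, collapse = ", ")),
          class = "waterkrig_artifact_error")
  }
  obj$X <- matrix(obj$X$values, nrow = obj$X$nrow)
  colnames(obj$X) <- obj$feature_names
  structure(obj, class = "krig")
}
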