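#' Solver configuration
#'
#' Levenberg-Marquardt settings. Convergence is declared on an absolute
#' change in total error of `abs_tol` or less between accepted iterations, a
#' relative change of `rel_tol` or less, or `max_iterations`, whichever
#' comes first. Damping starts at `lambda_init`, is multiplied by
#' `lambda_factor` on a rejected step and divided by it on an accepted step.
#'
#' @param abs_tol absolute error-change tolerance.
#' @param rel_tol relative error-change tolerance.
#' @param max_iterations iteration cap.
#' @param lambda_init,lambda_factor,lambda_max LM damping schedule.
#' @param seed unused by the (deterministic) solver; recorded for
#'   reproducibility bookkeeping.
#' @return list of class `"solver_config"`.
#' @export
solver_config <- function(abs_tol = 1e-6, rel_tol = 1e-4,
                          max_iterations = 10000L, lambda_init = 1e-5,
                          lambda_factor = 10, lambda_max = 1e12,
                          seed = NULL) {
  stopifnot(abs_tol > 0, rel_tol > 0, max_iterations >= 1,
            lambda_init > 0, lambda_factor > 1)
  structure(list(abs_tol = abs_tol, rel_tol = rel_tol,
                 max_iterations = as.integer(max_iterations),
                 lambda_init = lambda_init, lambda_factor = lambda_factor,
                 lambda_max = lambda_max, seed = seed),
            class = "solver_config")
}

#' On-manifold Levenberg-Marquardt over the factor graph
#'
#' Minimizes the total whitened squared error by damped Gauss-Newton on the
#' product manifold: the whitened Jacobian is assembled sparsely, the damped
#' normal equations are solved with a sparse Cholesky factorization (CHOLMOD
#' with fill-reducing ordering; only the diagonal shift is refactored when
#' the damping changes), and the step is applied through the retractions, so
#' rotations stay orthonormal and axes stay unit norm. The total error is
#' nonincreasing across accepted steps. Deterministic: identical inputs give
#' an identical iteration log.
#'
#' @param graph an [build_graph()] result (usually after
#'   [add_gauge_priors()]; without anchoring the normal matrix is singular).
#' @param init a complete value assignment, e.g. [initialize_values()].
#' @param config a [solver_config()].
#' @param verbose print per-iteration progress.
#' @return list of class `"imu_solution"`: final `values`, keyframe times
#'   `t`, total `error`, `group_err` breakdown, `iterations` log (iter,
#'   error, lambda, step_norm, accepted), and `termination`
#'   (`"abs_tol"`, `"rel_tol"`, `"max_iter"` or `"stalled"`).
#' @export
optimize_graph <- function(graph, init, config = solver_config(),
                           verbose = FALSE) {
  lin <- .lin_call(graph, init, TRUE)
  if (!is.finite(lin$err)) {
    bad <- names(which(!is.finite(lin$group_err) | lin$group_err > 1e300))
    stop("non-finite total error at initialization (factor group: ",
         paste(bad, collapse = ", "), ")")
  }
  vals <- init
  err <- lin$err
  J <- Matrix::sparseMatrix(i = lin$i, j = lin$j, x = lin$x,
                            dims = c(lin$nrow, graph$dim))
  lam <- config$lambda_init
  term <- "max_iter"
  log_it <- vector("list", 0)
  iter <- 0L

  while (iter < config$max_iterations) {
    iter <- iter + 1L
    A <- Matrix::forceSymmetric(Matrix::crossprod(J))
    gvec <- as.numeric(Matrix::crossprod(J, lin$r))
    Ch <- NULL
    accepted <- FALSE
    decrease <- NA_real_
    step_norm <- NA_real_
    stalled <- FALSE
    repeat {
      if (is.null(Ch))
        Ch <- tryCatch(Matrix::Cholesky(A, LDL = FALSE, perm = TRUE,
                                        Imult = lam),
                       error = function(e) NULL)
      if (is.null(Ch)) {
        lam <- lam * config$lambda_factor
        if (lam > config$lambda_max) { stalled <- TRUE; break }
        next
      }
      delta <- as.numeric(Matrix::solve(Ch, -gvec))
      step_norm <- sqrt(sum(delta^2))
      cand <- .retract_values(vals, delta)
      err_new <- .lin_call(graph, cand, FALSE)$err
      if (is.finite(err_new) &&
          (err_new < err || abs(err_new - err) < config$abs_tol)) {
        decrease <- err - err_new
        vals <- cand
        accepted <- TRUE
        lam <- max(lam / config$lambda_factor, 1e-12)
        break
      }
      lam <- lam * config$lambda_factor
      if (lam > config$lambda_max) { stalled <- TRUE; break }
      Ch <- tryCatch(stats::update(Ch, A, mult = lam),
                     error = function(e) NULL)
    }
    log_it[[iter]] <- data.frame(iter = iter, error = err, lambda = lam,
                                 step_norm = step_norm, accepted = accepted)
    if (verbose)
      message(sprintf("iter %4d  error %.6e  lambda %.1e  step %.3e  %s",
                      iter, err, lam, step_norm,
                      if (accepted) "accepted" else "rejected"))
    if (stalled) { term <- "stalled"; break }
    err_prev <- err
    err <- err - if (accepted) decrease else 0
    if (accepted) {
      if (decrease < config$abs_tol) { term <- "abs_tol"; break }
      if (err_prev > 0 && decrease / err_prev < config$rel_tol) {
        term <- "rel_tol"; break
      }
      lin <- .lin_call(graph, vals, TRUE)
      err <- lin$err
      J <- Matrix::sparseMatrix(i = lin$i, j = lin$j, x = lin$x,
                                dims = c(lin$nrow, graph$dim))
    }
  }

  final <- .lin_call(graph, vals, FALSE)
  structure(list(
    values = vals, M = graph$M, t = graph$t_kf,
    decimation = graph$decimation,
    error = final$err, group_err = final$group_err,
    iterations = do.call(rbind, log_it), termination = term,
    dim = graph$dim, counts = graph$counts
  ), class = "imu_solution")
}

#' @export
print.imu_solution <- function(x, ...) {
  cat("lower-body IMU solution:", x$M, "keyframes,",
      x$dim, "tangent dims\n")
  cat("  total error", format(x$error, digits = 6), "| termination",
      x$termination, "|", nrow(x$iterations), "iterations\n")
  invisible(x)
}
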