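# Average-information REML for linear covariance structures.
#
# The observed data model is y = X beta + u with Var(y) = V(theta) =
# sum_k theta_k V_k, each V_k a known symmetric matrix (or, in the
# "diagonal" representation, a vector holding the diagonal of V_k after an
# orthogonal rotation that diagonalises every structure simultaneously).
# Variance parameters are kept above a small floor; covariance parameters
# are kept inside the cone implied by their two parent variances.
#
# The update is the average-information (quasi-Newton) step with step
# halving; when no AI step improves the restricted likelihood an EM-flavoured
# damped gradient step is tried before declaring non-convergence. This is
# the scheme used by the large mixed-model packages (DMU, ASReml, AIREMLF90)
# expressed on the phenotype-covariance scale, which is convenient at the
# few-thousand-record sizes this package targets.

# Evaluate the restricted log-likelihood and the quantities shared by the
# score and AI computations. Returns NULL when V(theta) is not positive
# definite.
reml_eval <- function(theta, y, X, V, diag_mode) {
  n <- length(y)
  p <- ncol(X)
  if (diag_mode) {
    v <- rep(0, n)
    for (k in seq_along(V)) v <- v + theta[k] * V[[k]]
    if (any(v <= 0)) return(NULL)
    vi <- 1 / v
    W <- X * vi
    XtViX <- crossprod(X, W)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    Wty <- crossprod(W, y)
    alpha <- backsolve(chx, backsolve(chx, Wty, transpose = TRUE))
    Py <- y * vi - W %*% alpha
    logdetV <- sum(log(v))
    yPy <- sum(y * Py)
    logl <- -0.5 * (logdetV + 2 * sum(log(diag(chx))) + yPy)
    list(logl = logl, Py = as.vector(Py), vi = vi, W = W, chx = chx,
         alpha = alpha)
  } else {
    Vm <- matrix(0, n, n)
    for (k in seq_along(V)) Vm <- Vm + theta[k] * V[[k]]
    ch <- tryCatch(chol(Vm), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    W <- Vi %*% X
    XtViX <- crossprod(X, W)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    Wty <- crossprod(W, y)
    alpha <- backsolve(chx, backsolve(chx, Wty, transpose = TRUE))
    Py <- Vi %*% y - W %*% alpha
    yPy <- sum(y * Py)
    logl <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) + yPy)
    list(logl = logl, Py = as.vector(Py), Vi = Vi, W = W, chx = chx,
         alpha = alpha)
  }
}

# P z for the projection matrix P = Vi - W (X'ViX)^-1 W'.
reml_Pz <- function(ev, z, diag_mode) {
  Wtz <- crossprod(ev$W, z)
  a <- backsolve(ev$chx, backsolve(ev$chx, Wtz, transpose = TRUE))
  if (diag_mode) as.vector(z * ev$vi - ev$W %*% a)
  else as.vector(ev$Vi %*% z - ev$W %*% a)
}

# Score vector and average-information matrix at the current evaluation.
reml_derivs <- function(ev, theta, y, X, V, diag_mode) {
  k <- length(V)
  Py <- ev$Py
  Wk <- vector("list", k)   # V_k P y
  trPV <- numeric(k)
  for (j in seq_len(k)) {
    if (diag_mode) {
      d <- V[[j]]
      Wk[[j]] <- d * Py
      trViV <- sum(d * ev$vi)
      B <- crossprod(ev$W, d * ev$W)
    } else {
      Wk[[j]] <- as.vector(V[[j]] %*% Py)
      trViV <- sum(ev$Vi * V[[j]])
      B <- crossprod(ev$W, V[[j]] %*% ev$W)
    }
    corr <- backsolve(ev$chx, backsolve(ev$chx, B, transpose = TRUE))
    trPV[j] <- trViV - sum(diag(corr))
  }
  yPVPy <- vapply(Wk, function(w) sum(Py * w), numeric(1))
  score <- -0.5 * (trPV - yPVPy)
  PWk <- lapply(Wk, function(w) reml_Pz(ev, w, diag_mode))
  AI <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in a:k) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(Wk[[a]] * PWk[[b]])
    }
  }
  list(score = score, AI = AI, trPV = trPV, yPVPy = yPVPy)
}

# Moore-Penrose pseudoinverse via symmetric eigendecomposition; used when
# the AI matrix is singular (e.g. structurally confounded components).
sym_pinv <- function(A, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  lam <- e$values
  keep <- abs(lam) > tol * max(abs(lam), .Machine$double.eps)
  inv <- ifelse(keep, 1 / lam, 0)
  list(inv = e$vectors %*% (inv * t(e$vectors)),
       rank_deficient = any(!keep),
       null_vectors = e$vectors[, !keep, drop = FALSE])
}

#' Average-information REML for a linear covariance structure
#'
#' Maximises the restricted log-likelihood of `y = X beta + u`,
#' `Var(y) = sum_k theta_k V_k`, over the parameter vector theta. Structures
#' may be passed either as dense symmetric matrices or (all of them) as
#' vectors holding the diagonals of the simultaneously diagonalised
#' structures; the two representations give identical likelihoods, the
#' diagonal one in O(n p^2) per iteration.
#'
#' @param y Response vector.
#' @param X Full-column-rank fixed-effect design matrix.
#' @param V List of covariance structures (all dense matrices or all
#'   numeric vectors of diagonals).
#' @param init Initial parameter vector (variances positive).
#' @param cov_constraints Optional list of lists `(idx, v1, v2, scale)`:
#'   parameter `idx` is a covariance kept within
#'   `|theta_idx| <= sqrt(theta_v1 * theta_v2 / scale)`.
#' @param max_iter,tol_logl,tol_grad Convergence controls: iteration cap,
#'   relative restricted-log-likelihood change, squared score norm.
#' @param floor_frac Variance floor as a fraction of `var(y)`.
#' @return List with `theta`, `logl`, `score`, `AI`, `AI_inv` (pseudoinverse
#'   when singular), `iterations`, `converged`, `boundary` (logical per
#'   parameter), `non_identifiable`, and the iteration `trace`.
#' @export
reml_ai <- function(y, X, V, init, cov_constraints = list(),
                    max_iter = 200L, tol_logl = 1e-9, tol_grad = 1e-8,
                    floor_frac = 1e-8) {
  X <- as.matrix(X)
  k <- length(V)
  diag_mode <- all(vapply(V, function(v) is.numeric(v) && is.null(dim(v)), logical(1)))
  if (!diag_mode) V <- lapply(V, as.matrix)
  cov_idx <- vapply(cov_constraints, function(cc) cc$idx, integer(1))
  var_idx <- setdiff(seq_len(k), cov_idx)
  floor_val <- max(floor_frac * stats::var(y), 1e-12)

  project <- function(th) {
    th[var_idx] <- pmax(th[var_idx], floor_val)
    for (cc in cov_constraints) {
      bound <- sqrt(th[cc$v1] * th[cc$v2] / cc$scale) * (1 - 1e-6)
      th[cc$idx] <- max(-bound, min(bound, th[cc$idx]))
    }
    th
  }

  theta <- project(init)
  ev <- reml_eval(theta, y, X, V, diag_mode)
  if (is.null(ev)) {
    # retreat to an equal split of the phenotypic variance
    theta <- project(rep(stats::var(y) / max(1, length(var_idx)), k))
    theta[cov_idx] <- 0
    ev <- reml_eval(theta, y, X, V, diag_mode)
    if (is.null(ev)) stop("REML: initial covariance matrix not positive definite",
                          call. = FALSE)
  }

  trace <- data.frame(iter = 0L, logl = ev$logl, step = NA_real_)
  converged <- FALSE
  non_identifiable <- FALSE
  dv <- NULL
  iter <- 0L
  stall <- 0L
  for (iter in seq_len(max_iter)) {
    dv <- reml_derivs(ev, theta, y, X, V, diag_mode)
    # active set: variances pinned at the floor by a negative score, and
    # covariances pinned at their PSD bound by an outward-pointing score
    at_floor <- seq_len(k) %in% var_idx & theta <= floor_val * (1 + 1e-6)
    at_bound <- rep(FALSE, k)
    for (cc in cov_constraints) {
      bound <- sqrt(theta[cc$v1] * theta[cc$v2] / cc$scale) * (1 - 1e-6)
      at_bound[cc$idx] <- abs(theta[cc$idx]) >= bound * (1 - 1e-6) &&
        sign(dv$score[cc$idx]) == sign(theta[cc$idx])
    }
    free <- !((at_floor & dv$score < 0) | at_bound)
    delta <- rep(0, k)
    if (any(free)) {
      pin <- sym_pinv(dv$AI[free, free, drop = FALSE])
      if (pin$rank_deficient) non_identifiable <- TRUE
      delta[free] <- as.vector(pin$inv %*% dv$score[free])
    }

    grad_ok <- sum(dv$score[free]^2) < tol_grad
    step_used <- NA_real_
    improved <- FALSE
    step <- 1
    while (step > 1e-8) {
      cand <- project(theta + step * delta)
      evc <- reml_eval(cand, y, X, V, diag_mode)
      if (!is.null(evc) && evc$logl > ev$logl + 1e-13) {
        improved <- TRUE
        step_used <- step
        break
      }
      step <- step / 2
    }
    if (!improved) {
      # EM-flavoured damped gradient: variance updates use the classic
      # sigma^4-scaled score; covariances are scaled by their parent
      # variances so they move even when the AI direction fails
      d_em <- rep(0, k)
      d_em[var_idx] <- theta[var_idx]^2 *
        (dv$yPVPy[var_idx] - dv$trPV[var_idx]) / length(y)
      for (cc in cov_constraints) {
        d_em[cc$idx] <- theta[cc$v1] * theta[cc$v2] / length(y) *
          dv$score[cc$idx] * 2
      }
      d_em[!free] <- 0
      step <- 1
      while (step > 1e-8) {
        cand <- project(theta + step * d_em)
        evc <- reml_eval(cand, y, X, V, diag_mode)
        if (!is.null(evc) && evc$logl > ev$logl + 1e-13) {
          improved <- TRUE
          step_used <- -step  # negative marks a fallback step in the trace
          break
        }
        step <- step / 2
      }
    }
    if (!improved) {
      converged <- grad_ok
      break
    }
    dlogl <- evc$logl - ev$logl
    theta <- cand
    ev <- evc
    trace <- rbind(trace, data.frame(iter = iter, logl = ev$logl,
                                     step = step_used))
    if (abs(dlogl) < tol_logl * (1 + abs(ev$logl))) {
      if (grad_ok) {
        converged <- TRUE
        break
      }
      # flat likelihood without the gradient criterion (e.g. a parameter
      # pinned at a constraint): accept after three consecutive stalls
      stall <- stall + 1L
      if (stall >= 3L) {
        converged <- TRUE
        break
      }
    } else {
      stall <- 0L
    }
  }
  dv <- reml_derivs(ev, theta, y, X, V, diag_mode)
  pin <- sym_pinv(dv$AI)
  if (pin$rank_deficient) non_identifiable <- TRUE
  boundary <- seq_len(k) %in% var_idx & theta <= floor_val * (1 + 1e-6)
  if (!converged && iter >= max_iter) {
    warning("REML did not converge within ", max_iter,
            " iterations (final |score|^2 = ",
            format(sum(dv$score^2), digits = 3), ")", call. = FALSE)
  }
  list(theta = theta, logl = ev$logl, score = dv$score, AI = dv$AI,
       AI_inv = pin$inv, iterations = iter, converged = converged,
       boundary = boundary, non_identifiable = non_identifiable,
       trace = trace, floor = floor_val)
}
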