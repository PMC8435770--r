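# Animal-model wrappers around the AI-REML engine.
#
# Three model forms are supported, matching the standard proxy-validation
# workflow: (1) a univariate animal model for single-record traits,
# y = Xb + a + e with a ~ N(0, G sigma2_a); (2) a repeatability model for
# site-indexed repeated records, y = Xb + a + pe + e with a permanent-
# environment effect shared by an individual's records; and (3) a bivariate
# model linking a single-record reference trait to a (possibly repeated)
# proxy trait through a genetic covariance, with an optional residual
# covariance on the individuals carrying both traits.

get_trait_records <- function(phenotypes, trait) {
  d <- phenotypes[phenotypes$trait == trait & !is.na(phenotypes$value), ,
                  drop = FALSE]
  if (nrow(d) == 0) stop("no records for trait '", trait, "'", call. = FALSE)
  d
}

check_grm_cover <- function(ids, grm) {
  missing <- setdiff(unique(ids), grm$ids)
  if (length(missing)) {
    stop(length(missing), " phenotyped individuals absent from the GRM (e.g. ",
         missing[1], ")", call. = FALSE)
  }
}

# Treatment-coded design with intercept; single-level factors are dropped
# (e.g. cohort when analysing within cohort) and aliased columns removed.
build_fixed_design <- function(d, fixed) {
  keep <- fixed[vapply(fixed, function(f) {
    f %in% names(d) && length(unique(d[[f]])) > 1
  }, logical(1))]
  dd <- as.data.frame(d)
  for (f in keep) dd[[f]] <- factor(dd[[f]])
  form <- if (length(keep)) stats::reformulate(keep) else ~1
  X <- stats::model.matrix(form, data = dd)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  X
}

init_phen_var <- function(y, X) {
  r <- stats::lm.fit(X, y)$residuals
  max(stats::var(r), 1e-8)
}

new_varcomp_fit <- function(model, traits, components, engine, n_records,
                            n_individuals, blup) {
  se <- sqrt(pmax(diag(engine$AI_inv), 0))
  fit <- structure(list(
    model = model, traits = traits,
    components = tibble::tibble(
      component = names(components), estimate = unname(components),
      se = se, boundary = engine$boundary
    ),
    logl = engine$logl, AI = engine$AI, AI_inv = engine$AI_inv,
    convergence = list(converged = engine$converged,
                       iterations = engine$iterations,
                       score = engine$score,
                       non_identifiable = engine$non_identifiable,
                       trace = engine$trace),
    n_records = n_records, n_individuals = n_individuals,
    blup = blup
  ), class = "varcomp_fit")
  fit$derived <- derive_parameters(fit)
  fit
}

#' Univariate animal model by AI-REML
#'
#' Fits `y = Xb + a + e` with `a ~ N(0, G sigma2_a)` for a single-record
#' trait, estimating `(sigma2_a, sigma2_e)` by average-information REML. The
#' GRM is eigendecomposed once and the problem solved in the rotated basis
#' where both covariance structures are diagonal.
#'
#' @param phenotypes Long-format phenotype tibble (id, cohort, sex, site,
#'   trait, value).
#' @param grm A `grm` covering every phenotyped individual.
#' @param trait Trait name to fit.
#' @param fixed Candidate fixed factors; factors absent or single-level in
#'   the data are dropped automatically.
#' @param ... Passed to [reml_ai()].
#' @return A `varcomp_fit` with components, derived heritability and SEs.
#' @export
fit_univariate <- function(phenotypes, grm, trait = "lipid_ref",
                           fixed = c("cohort", "sex"), ...) {
  d <- get_trait_records(phenotypes, trait)
  if (anyDuplicated(d$id)) {
    stop("trait '", trait, "' has repeated records; use fit_repeatability()",
         call. = FALSE)
  }
  check_grm_cover(d$id, grm)
  n <- nrow(d)
  Gs <- grm$values[d$id, d$id]
  X <- build_fixed_design(d, fixed)
  eg <- eigen(Gs, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  yr <- drop(crossprod(U, d$value))
  Xr <- crossprod(U, X)
  v0 <- init_phen_var(d$value, X)
  eng <- reml_ai(yr, Xr, list(lam, rep(1, n)), init = c(0.5, 0.5) * v0, ...)
  Py_orig <- drop(U %*% reml_Py_vector(eng, yr, Xr, list(lam, rep(1, n))))
  new_varcomp_fit("univariate", trait,
                  c(sigma2_a = eng$theta[1], sigma2_e = eng$theta[2]),
                  eng, n, n,
                  blup = list(rec_ids = list(d$id), Py = list(Py_orig)))
}

# Recompute P y at the converged parameters (record space of the inputs).
reml_Py_vector <- function(engine, y, X, V) {
  diag_mode <- all(vapply(V, function(v) is.null(dim(v)), logical(1)))
  ev <- reml_eval(engine$theta, y, as.matrix(X), V, diag_mode)
  ev$Py
}

#' Repeatability animal model by AI-REML
#'
#' Fits `y = Xb + a + pe + e` for a trait with repeated (site-indexed)
#' records per individual: `a ~ N(0, G sigma2_a)`,
#' `pe ~ N(0, I sigma2_pe)` shared across an individual's records. With
#' balanced records the GRM eigendecomposition combines with an orthogonal
#' within-individual rotation that diagonalises all three structures
#' (means carry the genetic and permanent-environment signal, contrasts
#' carry pure residual); unbalanced data fall back to the dense
#' representation.
#'
#' @inheritParams fit_univariate
#' @param method `"auto"` (diagonalised when balanced) or `"dense"`.
#' @return A `varcomp_fit` with heritability and repeatability.
#' @export
fit_repeatability <- function(phenotypes, grm, trait = "lipid_ds",
                              fixed = c("cohort", "sex", "site"),
                              method = c("auto", "dense"), ...) {
  method <- match.arg(method)
  d <- get_trait_records(phenotypes, trait)
  d <- dplyr::arrange(d, .data$id, .data$site)
  counts <- table(d$id)
  if (max(counts) < 2) {
    stop("all individuals have a single record; permanent-environment ",
         "variance is inestimable (use fit_univariate)", call. = FALSE)
  }
  check_grm_cover(d$id, grm)
  uid <- unique(d$id)
  q <- length(uid)
  n <- nrow(d)
  X <- build_fixed_design(d, fixed)
  v0 <- init_phen_var(d$value, X)
  init <- c(0.5, 0.25, 0.25) * v0
  balanced <- length(unique(counts)) == 1L

  if (balanced && method == "auto") {
    m <- unname(counts[1])
    Gs <- grm$values[uid, uid]
    eg <- eigen(Gs, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    U <- eg$vectors
    Wm <- qr.Q(qr(cbind(rep(1, m), diag(m)[, -1, drop = FALSE])))
    if (Wm[1, 1] < 0) Wm <- -Wm
    rot <- function(v) as.vector(crossprod(U, matrix(v, nrow = q, byrow = TRUE)) %*% Wm)
    yr <- rot(d$value)
    Xr <- apply(X, 2L, rot)
    Vd <- list(c(m * lam, rep(0, q * (m - 1))),
               c(rep(m, q), rep(0, q * (m - 1))),
               rep(1, n))
    eng <- reml_ai(yr, Xr, Vd, init = init, ...)
    Py_rot <- reml_Py_vector(eng, yr, Xr, Vd)
    Py_orig <- as.vector(t(U %*% matrix(Py_rot, nrow = q) %*% t(Wm)))
  } else {
    idx <- match(d$id, uid)
    VG <- grm$values[d$id, d$id]
    Vpe <- 1 * outer(idx, idx, "==")
    Vlist <- list(VG, Vpe, diag(n))
    eng <- reml_ai(d$value, X, Vlist, init = init, ...)
    Py_orig <- reml_Py_vector(eng, d$value, X, Vlist)
  }
  new_varcomp_fit("repeatability", trait,
                  c(sigma2_a = eng$theta[1], sigma2_pe = eng$theta[2],
                    sigma2_e = eng$theta[3]),
                  eng, n, q,
                  blup = list(rec_ids = list(d$id), Py = list(Py_orig)))
}

#' Bivariate animal model by AI-REML
#'
#' Fits the joint model of a single-record reference trait (trait 1, no
#' permanent-environment term) and a proxy trait (trait 2, with a
#' permanent-environment term when it carries repeated records). Individuals
#' phenotyped for only one trait contribute through the genetic covariance.
#' The residual covariance `sigma_e12` links an individual's trait-1
#' residual equally to each of its trait-2 records and is estimated only on
#' individuals carrying both traits; set `res_cov = FALSE` to fix it at 0
#' (e.g. for non-simultaneous recording).
#'
#' @inheritParams fit_univariate
#' @param trait1,trait2 Trait names (trait 1 must be single-record).
#' @param fixed1,fixed2 Candidate fixed factors per trait; `"site"` is used
#'   for trait 2 only when it has repeated records.
#' @param res_cov Estimate the residual covariance between traits.
#' @return A `varcomp_fit` with genetic and phenotypic correlations.
#' @export
fit_bivariate <- function(phenotypes, grm, trait1 = "lipid_ref",
                          trait2 = "lipid_ds_mean",
                          fixed1 = c("cohort", "sex"),
                          fixed2 = c("cohort", "sex", "site"),
                          res_cov = TRUE, ...) {
  d1 <- get_trait_records(phenotypes, trait1)
  if (anyDuplicated(d1$id)) {
    stop("trait 1 ('", trait1, "') must be single-record", call. = FALSE)
  }
  d2 <- get_trait_records(phenotypes, trait2)
  d2 <- dplyr::arrange(d2, .data$id, .data$site)
  repeated2 <- anyDuplicated(d2$id) > 0
  if (!repeated2) fixed2 <- setdiff(fixed2, "site")
  check_grm_cover(c(d1$id, d2$id), grm)

  n1 <- nrow(d1); n2 <- nrow(d2); n <- n1 + n2
  b1 <- seq_len(n1); b2 <- n1 + seq_len(n2)
  zero <- function() matrix(0, n, n)
  blk <- function(M, rows, cols) {
    out <- zero()
    out[rows, cols] <- M
    if (!identical(rows, cols)) out[cols, rows] <- t(M)
    out
  }
  Va1 <- blk(grm$values[d1$id, d1$id], b1, b1)
  Va2 <- blk(grm$values[d2$id, d2$id], b2, b2)
  Va12 <- blk(grm$values[d1$id, d2$id], b1, b2)
  Ve1 <- blk(diag(n1), b1, b1)
  Ve2 <- blk(diag(n2), b2, b2)

  overlap <- intersect(d1$id, d2$id)
  use_rescov <- res_cov && length(overlap) > 0
  m2 <- max(table(d2$id))

  Vlist <- list(Va1, Va2, Va12, Ve1, Ve2)
  names(Vlist) <- c("sigma2_a1", "sigma2_a2", "sigma_a12", "sigma2_e1", "sigma2_e2")
  if (repeated2) {
    Vlist$sigma2_pe2 <- blk(1 * outer(d2$id, d2$id, "=="), b2, b2)
  }
  if (use_rescov) {
    Vlist$sigma_e12 <- blk(1 * outer(d1$id, d2$id, "=="), b1, b2)
  }

  X1 <- build_fixed_design(d1, fixed1)
  X2 <- build_fixed_design(d2, fixed2)
  X <- matrix(0, n, ncol(X1) + ncol(X2))
  X[b1, seq_len(ncol(X1))] <- X1
  X[b2, ncol(X1) + seq_len(ncol(X2))] <- X2

  v1 <- init_phen_var(d1$value, X1)
  v2 <- init_phen_var(d2$value, X2)
  init <- c(sigma2_a1 = 0.5 * v1, sigma2_a2 = 0.5 * v2,
            sigma_a12 = 0.25 * sqrt(0.25 * v1 * v2),
            sigma2_e1 = 0.5 * v1,
            sigma2_e2 = if (repeated2) 0.25 * v2 else 0.5 * v2)
  if (repeated2) init["sigma2_pe2"] <- 0.25 * v2
  if (use_rescov) init["sigma_e12"] <- 0
  init <- init[names(Vlist)]

  pos <- function(nm) which(names(Vlist) == nm)
  cons <- list(list(idx = pos("sigma_a12"), v1 = pos("sigma2_a1"),
                    v2 = pos("sigma2_a2"), scale = 1))
  if (use_rescov) {
    cons <- c(cons, list(list(idx = pos("sigma_e12"), v1 = pos("sigma2_e1"),
                              v2 = pos("sigma2_e2"), scale = m2)))
  }
  y <- c(d1$value, d2$value)
  eng <- reml_ai(y, X, Vlist, init = unname(init), cov_constraints = cons, ...)
  comps <- stats::setNames(eng$theta, names(Vlist))
  Py <- reml_Py_vector(eng, y, X, Vlist)
  new_varcomp_fit("bivariate", c(trait1, trait2), comps, eng, n,
                  length(unique(c(d1$id, d2$id))),
                  blup = list(rec_ids = list(d1$id, d2$id),
                              Py = list(Py[b1], Py[b2])))
}

#' Derived genetic parameters with delta-method standard errors
#'
#' Computes the ratio parameters appropriate to the model -- heritability
#' `h2 = sigma2_a / sigma2_p`, repeatability
#' `t2 = (sigma2_a + sigma2_pe) / sigma2_p`, genetic correlation
#' `r_g = sigma_a12 / sqrt(sigma2_a1 sigma2_a2)` and phenotypic correlation
#' `r_p = (sigma_a12 + sigma_e12) / sqrt(sigma2_p1 sigma2_p2)` -- with
#' first-order (Taylor-series) standard errors propagated from the inverse
#' average-information matrix. When the AI matrix is singular (confounded
#' components) its pseudoinverse is used and the affected SEs are
#' conservative placeholders.
#'
#' @param fit A `varcomp_fit`.
#' @return Tibble with columns parameter, estimate, se.
#' @export
derive_parameters <- function(fit) {
  stopifnot(inherits(fit, "varcomp_fit"))
  th <- stats::setNames(fit$components$estimate, fit$components$component)
  gv <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0
  funs <- switch(fit$model,
    univariate = list(
      h2 = function(v) v[["sigma2_a"]] / (v[["sigma2_a"]] + v[["sigma2_e"]])
    ),
    repeatability = list(
      h2 = function(v) v[["sigma2_a"]] /
        (v[["sigma2_a"]] + v[["sigma2_pe"]] + v[["sigma2_e"]]),
      t2 = function(v) (v[["sigma2_a"]] + v[["sigma2_pe"]]) /
        (v[["sigma2_a"]] + v[["sigma2_pe"]] + v[["sigma2_e"]])
    ),
    bivariate = list(
      r_g = function(v) v[["sigma_a12"]] /
        sqrt(v[["sigma2_a1"]] * v[["sigma2_a2"]]),
      r_p = function(v) (v[["sigma_a12"]] + gv(v, "sigma_e12")) /
        sqrt((v[["sigma2_a1"]] + v[["sigma2_e1"]]) *
               (v[["sigma2_a2"]] + gv(v, "sigma2_pe2") + v[["sigma2_e2"]])),
      h2_1 = function(v) v[["sigma2_a1"]] / (v[["sigma2_a1"]] + v[["sigma2_e1"]]),
      h2_2 = function(v) v[["sigma2_a2"]] /
        (v[["sigma2_a2"]] + gv(v, "sigma2_pe2") + v[["sigma2_e2"]])
    ),
    stop("unknown model type: ", fit$model)
  )
  Sigma <- fit$AI_inv
  rows <- lapply(names(funs), function(nm) {
    f <- funs[[nm]]
    est <- f(th)
    g <- vapply(seq_along(th), function(i) {
      h <- 1e-6 * (abs(th[i]) + 1e-8)
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      (f(tp) - f(tm)) / (2 * h)
    }, numeric(1))
    v <- drop(t(g) %*% Sigma %*% g)
    tibble::tibble(parameter = nm, estimate = est,
                   se = if (is.finite(v) && v >= 0) sqrt(v) else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Heritability from variance components
#'
#' `sigma2_a / (sigma2_a + sigma2_pe + sigma2_e)`; the `sigma2_pe` term is 0
#' for single-record traits.
#' @param sigma2_a,sigma2_e,sigma2_pe Variance components.
#' @return Scalar heritability.
#' @export
heritability <- function(sigma2_a, sigma2_e, sigma2_pe = 0) {
  sigma2_a / (sigma2_a + sigma2_pe + sigma2_e)
}

#' Repeatability from variance components
#'
#' `(sigma2_a + sigma2_pe) / (sigma2_a + sigma2_pe + sigma2_e)`: the
#' proportion of phenotypic variance due to permanent individual
#' differences; an upper bound on heritability.
#' @param sigma2_a,sigma2_pe,sigma2_e Variance components.
#' @return Scalar repeatability.
#' @export
repeatability <- function(sigma2_a, sigma2_pe, sigma2_e) {
  (sigma2_a + sigma2_pe) / (sigma2_a + sigma2_pe + sigma2_e)
}

#' Genomic estimated breeding values from a converged fit
#'
#' Computes BLUP breeding values `a_hat = Cov(a, y) P y` for every
#' individual in the GRM (phenotyped or not), for each trait in the fit.
#'
#' @param fit A `varcomp_fit`.
#' @param grm The GRM the model was fitted with.
#' @return Tibble with id and one GEBV column per trait.
#' @export
gebv <- function(fit, grm) {
  stopifnot(inherits(fit, "varcomp_fit"))
  th <- stats::setNames(fit$components$estimate, fit$components$component)
  ids <- grm$ids
  G <- grm$values
  cross <- function(rec_ids, Py) drop(G[, rec_ids, drop = FALSE] %*% Py)
  if (fit$model %in% c("univariate", "repeatability")) {
    a <- th[["sigma2_a"]] * cross(fit$blup$rec_ids[[1]], fit$blup$Py[[1]])
    out <- tibble::tibble(id = ids, gebv = a)
    names(out)[2] <- paste0("gebv_", fit$traits[1])
  } else {
    c1 <- cross(fit$blup$rec_ids[[1]], fit$blup$Py[[1]])
    c2 <- cross(fit$blup$rec_ids[[2]], fit$blup$Py[[2]])
    a1 <- th[["sigma2_a1"]] * c1 + th[["sigma_a12"]] * c2
    a2 <- th[["sigma_a12"]] * c1 + th[["sigma2_a2"]] * c2
    out <- tibble::tibble(id = ids, g1 = a1, g2 = a2)
    names(out)[2:3] <- paste0("gebv_", fit$traits)
  }
  out
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat(sprintf("%s animal model: %s (%d records, %d individuals)\n",
              x$model, paste(x$traits, collapse = " x "),
              x$n_records, x$n_individuals))
  comp <- x$components
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("  %-11s %8.4f +/- %.4f%s\n", comp$component[i],
                comp$estimate[i], comp$se[i],
                if (isTRUE(comp$boundary[i])) "  [at boundary]" else ""))
  }
  for (i in seq_len(nrow(x$derived))) {
    cat(sprintf("  %-11s %8.4f +/- %.4f\n", x$derived$parameter[i],
                x$derived$estimate[i], x$derived$se[i]))
  }
  cat(sprintf("  logL %.4f, %d iterations, %s%s\n", x$logl,
              x$convergence$iterations,
              if (x$convergence$converged) "converged" else "NOT converged",
              if (x$convergence$non_identifiable) " (singular AI: some components non-identifiable)" else ""))
  invisible(x)
}
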