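test_that("bivariate REML maximises the likelihood on covariance slices", {
  # moderate signals keep the tiny-instance optimum interior, which a
  # slice-through-the-optimum comparison requires
  cfg <- tiny_config(seed = 50, n_sires = 3, n_dams = 3, n_offspring = 12,
                     family_size_median = 4, n_snps = 200,
                     sigma2_a1 = 2, sigma2_e1 = 4, sigma2_a2 = 2,
                     sigma2_pe2 = 1, sigma2_e2 = 4, r_g = 0.5, r_e = 0.2,
                     prop_reference_phenotyped = 1)
  sim <- simulate_population(cfg)
  grm <- vanraden_grm(sim$genotypes)
  views <- suppressMessages(make_trait_views(sim$phenotypes))
  fit <- fit_bivariate(views, grm, "lipid_ref", "lipid_ds_mean",
                       fixed1 = character(0), fixed2 = character(0))
  est <- setNames(fit$components$estimate, fit$components$component)

  # independent dense likelihood over (sigma_a12, sigma_e12), other
  # components held at the REML solution
  d1 <- views[views$trait == "lipid_ref", ]
  d2 <- views[views$trait == "lipid_ds_mean", ]
  d2 <- d2[match(d1$id, d2$id), ]
  n1 <- nrow(d1)
  G <- grm$values[d1$id, d1$id]
  y <- c(d1$value, d2$value)
  X <- cbind(c(rep(1, n1), rep(0, n1)), c(rep(0, n1), rep(1, n1)))
  zero <- matrix(0, n1, n1)
  Vlist <- list(rbind(cbind(G, zero), cbind(zero, zero)),
                rbind(cbind(zero, zero), cbind(zero, G)),
                rbind(cbind(zero, G), cbind(G, zero)),
                rbind(cbind(diag(n1), zero), cbind(zero, zero)),
                rbind(cbind(zero, zero), cbind(zero, diag(n1))),
                rbind(cbind(zero, diag(n1)), cbind(diag(n1), zero)))
  th <- est[c("sigma2_a1", "sigma2_a2", "sigma_a12",
              "sigma2_e1", "sigma2_e2", "sigma_e12")]
  ll_at <- function(a12, e12) {
    t2 <- th; t2["sigma_a12"] <- a12; t2["sigma_e12"] <- e12
    oracle_reml_logl(unname(t2), y, X, Vlist)
  }
  bound_a <- sqrt(est["sigma2_a1"] * est["sigma2_a2"]) * 0.999
  bound_e <- sqrt(est["sigma2_e1"] * est["sigma2_e2"]) * 0.999
  a_grid <- seq(-bound_a, bound_a, length.out = 41)
  e_grid <- seq(-bound_e, bound_e, length.out = 41)
  lls <- outer(a_grid, e_grid, Vectorize(ll_at))
  best <- which(lls == max(lls), arr.ind = TRUE)[1, ]
  expect_lt(abs(a_grid[best[1]] - est["sigma_a12"]), diff(a_grid[1:2]))
  expect_lt(abs(e_grid[best[2]] - est["sigma_e12"]), diff(e_grid[1:2]))
  expect_gte(ll_at(est["sigma_a12"], est["sigma_e12"]), max(lls) - 1e-6)
})

test_that("null genetic covariance yields a genetic correlation near zero", {
  cfg <- tiny_config(seed = 51, n_offspring = 250, n_snps = 600,
                     n_sires = 10, n_dams = 10, r_g = 0, r_e = 0)
  sim <- simulate_population(cfg)
  grm <- vanraden_grm(sim$genotypes)
  views <- suppressMessages(make_trait_views(sim$phenotypes))
  fit <- fit_bivariate(views, grm, "lipid_ref", "lipid_ds_mean")
  rg <- fit$derived$estimate[fit$derived$parameter == "r_g"]
  expect_lt(abs(rg), 0.35)
})

test_that("missing-trait individuals are carried by the genetic covariance", {
  cfg <- tiny_config(seed = 52, n_offspring = 150, n_snps = 400,
                     prop_reference_phenotyped = 0.4)
  sim <- simulate_population(cfg)
  grm <- vanraden_grm(sim$genotypes)
  views <- suppressMessages(make_trait_views(sim$phenotypes))
  fit <- fit_bivariate(views, grm, "lipid_ref", "lipid_ds_mean")
  expect_equal(fit$n_records,
               sum(views$trait == "lipid_ref") + sum(views$trait == "lipid_ds_mean"))
  der <- setNames(fit$derived$estimate, fit$derived$parameter)
  expect_lte(abs(der["r_g"]), 1)
  expect_lte(abs(der["r_p"]), 1)
  expect_true(fit$convergence$converged)

  # residual covariance can be fixed at zero by design
  fit0 <- fit_bivariate(views, grm, "lipid_ref", "lipid_ds_mean",
                        res_cov = FALSE)
  expect_false("sigma_e12" %in% fit0$components$component)
})

test_that("repeated-record proxy enters the bivariate model with a pe term", {
  cfg <- tiny_config(seed = 53, n_offspring = 120, n_snps = 400)
  sim <- simulate_population(cfg)
  grm <- vanraden_grm(sim$genotypes)
  views <- suppressMessages(make_trait_views(sim$phenotypes))
  fit <- fit_bivariate(views, grm, "lipid_ref", "lipid_ds_rep")
  expect_true(all(c("sigma2_pe2", "sigma_e12") %in% fit$components$component))
  expect_equal(fit$n_records,
               sum(views$trait == "lipid_ref") + sum(views$trait == "lipid_ds_rep"))
})

test_that("derived ratios and their delta-method errors are coherent", {
  sim <- simulate_population(tiny_config(seed = 54, n_offspring = 150,
                                         n_snps = 400))
  grm <- vanraden_grm(sim$genotypes)
  fit <- fit_univariate(sim$phenotypes, grm, "lipid_ref")
  der <- derive_parameters(fit)
  est <- setNames(fit$components$estimate, fit$components$component)
  expect_equal(der$estimate[der$parameter == "h2"],
               heritability(est["sigma2_a"], est["sigma2_e"]),
               ignore_attr = TRUE)
  expect_true(all(der$se > 0))

  # scalar helpers agree with their definitions
  expect_equal(heritability(2, 2), 0.5)
  expect_equal(heritability(2, 1, sigma2_pe = 1), 0.5)
  expect_equal(repeatability(2, 1, 1), 0.75)
})

test_that("GEBVs from the fit track the simulated breeding values", {
  cfg <- tiny_config(seed = 55, n_offspring = 300, n_snps = 800,
                     n_sires = 10, n_dams = 10,
                     prop_reference_phenotyped = 1)
  sim <- simulate_population(cfg)
  grm <- vanraden_grm(sim$genotypes)
  fit <- fit_univariate(sim$phenotypes, grm, "lipid_ref")
  g <- gebv(fit, grm)
  acc <- cor(g$gebv_lipid_ref[match(rownames(sim$true_bv), g$id)],
             sim$true_bv[, 1])
  expect_gt(acc, 0.6)
})
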