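test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_sires = 1), "n_sires")
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(sigma2_a1 = -1), "variances")
  expect_error(sim_config(r_g = 1.5), "r_g")
  expect_error(sim_config(r_e = 0.9), "r_e")
  expect_error(sim_config(prop_reference_phenotyped = 0), "prop_reference")
  expect_error(sim_config(cohort_effects_ref = c(0, 0, 0)), "cohort effect")
})

test_that("gamete sampling obeys Mendelian segregation", {
  # homozygous parents transmit deterministically
  expect_true(all(proxyval:::sample_gametes(matrix(2L, 50, 4)) == 1L))
  expect_true(all(proxyval:::sample_gametes(matrix(0L, 50, 4)) == 0L))

  # cross of dosage-0 x dosage-2 parents always yields dosage 1
  set.seed(1)
  off <- proxyval:::sample_gametes(matrix(0L, 200, 1)) +
    proxyval:::sample_gametes(matrix(2L, 200, 1))
  expect_true(all(off == 1L))

  # het x het: dosage frequencies near (0.25, 0.5, 0.25)
  set.seed(2)
  off <- proxyval:::sample_gametes(matrix(1L, 10000, 1)) +
    proxyval:::sample_gametes(matrix(1L, 10000, 1))
  freqs <- tabulate(off + 1L, nbins = 3) / 10000
  expect_equal(freqs, c(0.25, 0.5, 0.25), tolerance = 0.1)
  expect_lt(max(abs(freqs - c(0.25, 0.5, 0.25))), 0.02)
})

test_that("pedigree and genotype structure is internally consistent", {
  cfg <- tiny_config(seed = 3)
  pg <- simulate_pedigree_genotypes(cfg)
  ped <- pg$pedigree
  offspring <- ped[!is.na(ped$sire), ]
  expect_equal(nrow(offspring), cfg$n_offspring)
  # every non-founder has exactly one sire and one dam present in the pedigree
  expect_true(all(offspring$sire %in% ped$id))
  expect_true(all(offspring$dam %in% ped$id))
  expect_true(all(pg$genotypes$dosages %in% 0:2))
  expect_equal(dim(pg$genotypes$dosages),
               c(cfg$n_offspring, cfg$n_snps))

  # optional genotyping error masks dosages at random
  cfg2 <- tiny_config(seed = 3, call_rate = 0.9)
  pg2 <- simulate_pedigree_genotypes(cfg2)
  expect_gt(mean(is.na(pg2$genotypes$dosages)), 0.05)
  expect_lt(mean(is.na(pg2$genotypes$dosages)), 0.15)
})

test_that("breeding values realize the configured genetic architecture", {
  cfg <- tiny_config(seed = 4, n_offspring = 300, n_snps = 800,
                     sigma2_a1 = 4, sigma2_a2 = 4, r_g = 1)
  pg <- simulate_pedigree_genotypes(cfg)
  bv <- simulate_breeding_values(pg$genotypes, cfg)
  # perfect genetic correlation with equal variances: identical pairs
  expect_equal(bv[, 1], bv[, 2], tolerance = 1e-8)

  cfg0 <- tiny_config(seed = 5, n_offspring = 500, n_snps = 800, r_g = 0)
  pg0 <- simulate_pedigree_genotypes(cfg0)
  bv0 <- simulate_breeding_values(pg0$genotypes, cfg0)
  expect_lt(abs(stats::cor(bv0[, 1], bv0[, 2])), 0.25)

  # realized sample variances track the target genetic variances; a single
  # family-structured replicate fluctuates by ~10-15%, so check the mean
  # over replicates with a broad founder base
  vv <- sapply(1:6, function(s) {
    cfgv <- tiny_config(seed = 600 + s, n_offspring = 400, n_snps = 1000,
                        n_sires = 25, n_dams = 25)
    pgv <- simulate_pedigree_genotypes(cfgv)
    diag(stats::var(simulate_breeding_values(pgv$genotypes, cfgv)))
  })
  expect_equal(mean(vv[1, ]), 4.15, tolerance = 0.15)
  expect_equal(mean(vv[2, ]), 5.44, tolerance = 0.15)
})

test_that("phenotypes follow the two-method record design", {
  # degenerate noise: every reference record equals the trait mean exactly
  cfg <- tiny_config(seed = 7, sigma2_a1 = 0, sigma2_e1 = 0, sigma2_a2 = 0,
                     sigma2_pe2 = 0, sigma2_e2 = 0, r_g = 0, r_e = 0,
                     mu1 = 5, cohort_effects_ref = c(0, 0),
                     cohort_effects_proxy = c(0, 0), sex_effects = c(0, 0),
                     site_effects = rep(0, 4), prop_reference_phenotyped = 1)
  sim <- simulate_population(cfg)
  ref <- sim$phenotypes[sim$phenotypes$trait == "lipid_ref", ]
  expect_true(all(ref$value == 5))

  # pe-only repeat structure: four records identical up to site effects
  cfg2 <- tiny_config(seed = 8, sigma2_pe2 = 2, sigma2_e2 = 0, r_e = 0)
  sim2 <- simulate_population(cfg2)
  ds <- sim2$phenotypes[sim2$phenotypes$trait == "lipid_ds", ]
  site_eff <- cfg2$site_effects[ds$site]
  adj <- tapply(ds$value - site_eff, ds$id, function(v) diff(range(v)))
  expect_lt(max(adj), 1e-10)

  # record counts: 4 proxy records per fish, reference on the subset
  cfg3 <- tiny_config(seed = 9)
  sim3 <- simulate_population(cfg3)
  ds3 <- sim3$phenotypes[sim3$phenotypes$trait == "lipid_ds", ]
  expect_true(all(table(ds3$id) == 4))
  n_ref <- sum(sim3$phenotypes$trait == "lipid_ref")
  expect_equal(n_ref, round(cfg3$prop_reference_phenotyped * cfg3$n_offspring))

  # determinism: identical seed, bit-identical result
  expect_identical(simulate_population(tiny_config(seed = 10)),
                   simulate_population(tiny_config(seed = 10)))
  expect_false(identical(simulate_population(tiny_config(seed = 10)),
                         simulate_population(tiny_config(seed = 11))))
})

test_that("default trait means and total variance are realized", {
  sim <- simulate_population(sim_config(seed = 12))
  ph <- sim$phenotypes
  expect_equal(mean(ph$value[ph$trait == "lipid_ref"]), 9.0, tolerance = 0.06)
  expect_equal(mean(ph$value[ph$trait == "lipid_ds"]), 7.1, tolerance = 0.06)

  # law of total variance for the reference trait across replicates
  vars <- vapply(1:5, function(r) {
    s <- simulate_population(tiny_config(seed = 100 + r, n_offspring = 400,
                                         prop_reference_phenotyped = 1))
    stats::var(s$phenotypes$value[s$phenotypes$trait == "lipid_ref"])
  }, numeric(1))
  expect_equal(mean(vars), 4.15 + 2.89, tolerance = 0.12)
})

test_that("averaging proxy records reduces variance per the repeatability formula", {
  cfg <- sim_config(seed = 13, site_effects = rep(0, 4),
                    cohort_effects_proxy = c(0, 0), sex_effects = c(0, 0))
  sim <- simulate_population(cfg)
  ds <- sim$phenotypes[sim$phenotypes$trait == "lipid_ds", ]
  v_single <- stats::var(ds$value)
  v_mean <- stats::var(tapply(ds$value, ds$id, mean))
  observed <- 100 * (1 - v_mean / v_single)
  t2 <- repeatability(cfg$sigma2_a2, cfg$sigma2_pe2, cfg$sigma2_e2)
  expect_equal(observed, averaging_variance_reduction(t2, 4), tolerance = 0.12)
})

test_that("simulated data round-trip through the on-disk formats", {
  sim <- simulate_population(tiny_config(seed = 14, call_rate = 0.95))
  dir <- withr::local_tempdir()
  paths <- write_sim_data(sim, dir)
  expect_true(all(file.exists(paths)))

  gv <- read_vcf_dosages(paths[["vcf"]])
  expect_equal(unname(gv$dosages[sim$genotypes$ids, sim$genotypes$snp_ids]),
               unname(sim$genotypes$dosages))

  gc <- read_dosage_csv(paths[["dosages"]])
  expect_equal(unname(gc$dosages), unname(sim$genotypes$dosages))
  expect_equal(gc$ids, sim$genotypes$ids)

  ph <- utils::read.csv(paths[["phenotypes"]])
  expect_equal(nrow(ph), nrow(sim$phenotypes))
  expect_equal(sum(ph$value), sum(sim$phenotypes$value), tolerance = 1e-8)
})
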