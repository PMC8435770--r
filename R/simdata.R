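#' Simulation configuration for a family-structured two-method lipid study
#'
#' Defines the population and trait architecture for the synthetic data
#' generator: a factorial-style mating of sires and dams producing full- and
#' half-sib families, SNP genotypes segregating through the pedigree, and two
#' lipid phenotypes per fish -- a destructive reference measurement (solvent
#' extraction, recorded once on a subset) and a non-destructive proxy
#' measurement (handheld dielectric spectroscopy, recorded at four body
#' sites on every fish).
#'
#' Trait-2 variances are parameterised *per single proxy record*; the
#' permanent-environment variance `sigma2_pe2` is shared by the four records
#' of one fish. Defaults reproduce the published combined-cohort component
#' estimates for the reference trait (4.15 / 2.89, heritability 0.59) and the
#' all-records proxy trait (5.44 / 2.16 / 6.00, heritability 0.40,
#' repeatability 0.56), a genetic correlation of 0.96 between methods, and
#' trait means of 9.0 and 7.1 lipid percent.
#'
#' The residual correlation `r_e` between the reference residual and each
#' single-site proxy residual is not identifiable from published tables; the
#' default 0.17 is back-solved so that the simulated phenotypic correlation
#' between the reference trait and the four-record proxy mean is about 0.66.
#' It must satisfy `4 * r_e^2 <= 1` for the joint residual covariance of the
#' five records of one fish to be positive semi-definite.
#'
#' @param n_sires,n_dams Number of founder sires and dams (>= 2 each).
#' @param n_offspring Target number of offspring (the study population; only
#'   offspring are genotyped and phenotyped, mirroring unsampled broodstock).
#' @param family_size_median Target median full-sib family size.
#' @param family_size_min,family_size_max Truncation bounds for family sizes.
#' @param n_snps Number of biallelic SNPs.
#' @param maf_range Founder allele frequencies are drawn uniformly from this
#'   interval (within (0, 0.5]).
#' @param n_cohorts Number of year-class cohorts (families are nested in
#'   cohorts).
#' @param mu1,mu2 Overall means of the reference and proxy traits (lipid %).
#' @param sigma2_a1,sigma2_e1 Additive-genetic and residual variance of the
#'   reference trait (lipid %^2).
#' @param sigma2_a2,sigma2_pe2,sigma2_e2 Additive-genetic,
#'   permanent-environment and residual variance of a single proxy record.
#' @param r_g Genetic correlation between the two traits, in \[-1, 1\].
#' @param r_e Residual correlation between the reference record and each
#'   single-site proxy record of the same fish.
#' @param cohort_effects_ref,cohort_effects_proxy Fixed cohort effects per
#'   trait (length `n_cohorts`, lipid %).
#' @param sex_effects Fixed sex effects, length 2 (applied to both traits).
#' @param site_effects Fixed body-site effects, length 4, named LA/LP/RA/RP.
#' @param prop_reference_phenotyped Fraction of offspring receiving the
#'   reference measurement, in (0, 1].
#' @param call_rate Per-entry genotype call rate; values below 1 mask dosages
#'   at random (missing completely at random).
#' @param bodyweight_mean,bodyweight_sd Per-cohort mean (length `n_cohorts`)
#'   and common SD of harvest body weight (g); body weight is simulated
#'   independently of the lipid traits.
#' @param seed Single integer seed; every stochastic sub-stream of the
#'   generator is derived deterministically from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 37,
                       n_dams = 33,
                       n_offspring = 749,
                       family_size_median = 5,
                       family_size_min = 2,
                       family_size_max = 150,
                       n_snps = 2000,
                       maf_range = c(0.05, 0.5),
                       n_cohorts = 2,
                       mu1 = 9.0,
                       mu2 = 7.1,
                       sigma2_a1 = 4.15,
                       sigma2_e1 = 2.89,
                       sigma2_a2 = 5.44,
                       sigma2_pe2 = 2.16,
                       sigma2_e2 = 6.00,
                       r_g = 0.96,
                       r_e = 0.17,
                       cohort_effects_ref = c(0.05, -0.05),
                       cohort_effects_proxy = c(-0.5, 0.5),
                       sex_effects = c(-0.1, 0.1),
                       site_effects = c(LA = -0.4, LP = 0.2, RA = -0.2, RP = 0.4),
                       prop_reference_phenotyped = 313 / 749,
                       call_rate = 1,
                       bodyweight_mean = c(376, 279),
                       bodyweight_sd = 60,
                       seed = 1L) {
  cfg <- list(
    n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
    n_offspring = as.integer(n_offspring),
    family_size_median = family_size_median,
    family_size_min = as.integer(family_size_min),
    family_size_max = as.integer(family_size_max),
    n_snps = as.integer(n_snps), maf_range = as.numeric(maf_range),
    n_cohorts = as.integer(n_cohorts),
    mu1 = mu1, mu2 = mu2,
    sigma2_a1 = sigma2_a1, sigma2_e1 = sigma2_e1,
    sigma2_a2 = sigma2_a2, sigma2_pe2 = sigma2_pe2, sigma2_e2 = sigma2_e2,
    r_g = r_g, r_e = r_e,
    cohort_effects_ref = cohort_effects_ref,
    cohort_effects_proxy = cohort_effects_proxy,
    sex_effects = sex_effects,
    site_effects = site_effects,
    prop_reference_phenotyped = prop_reference_phenotyped,
    call_rate = call_rate,
    bodyweight_mean = bodyweight_mean, bodyweight_sd = bodyweight_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (cfg$n_sires < 2 || cfg$n_dams < 2) stop_cfg("n_sires and n_dams must be >= 2")
  if (cfg$n_offspring < 1) stop_cfg("n_offspring must be positive")
  if (cfg$n_snps < 1) stop_cfg("n_snps must be >= 1")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop_cfg("maf_range must be an increasing interval within (0, 0.5]")
  }
  if (cfg$n_cohorts < 1) stop_cfg("n_cohorts must be >= 1")
  vars <- c(cfg$sigma2_a1, cfg$sigma2_e1, cfg$sigma2_a2, cfg$sigma2_pe2,
            cfg$sigma2_e2)
  if (any(vars < 0)) stop_cfg("all variances must be >= 0")
  if (abs(cfg$r_g) > 1) stop_cfg("r_g must lie in [-1, 1]")
  if (abs(cfg$r_e) > 1) stop_cfg("r_e must lie in [-1, 1]")
  # joint residual covariance of (reference, 4 proxy records) must be PSD
  if (4 * cfg$r_e^2 > 1 + 1e-12) {
    stop_cfg("|r_e| must be <= 0.5 for the 5-record residual covariance to be PSD")
  }
  # 2x2 genetic covariance PSD is implied by |r_g| <= 1 and nonneg variances
  if (length(cfg$cohort_effects_ref) != cfg$n_cohorts ||
      length(cfg$cohort_effects_proxy) != cfg$n_cohorts) {
    stop_cfg("cohort effect vectors must have length n_cohorts")
  }
  if (length(cfg$sex_effects) != 2) stop_cfg("sex_effects must have length 2")
  if (length(cfg$site_effects) != 4) stop_cfg("site_effects must have length 4")
  if (cfg$prop_reference_phenotyped <= 0 || cfg$prop_reference_phenotyped > 1) {
    stop_cfg("prop_reference_phenotyped must lie in (0, 1]")
  }
  if (cfg$call_rate <= 0 || cfg$call_rate > 1) stop_cfg("call_rate must lie in (0, 1]")
  if (cfg$family_size_min < 1 || cfg$family_size_max < cfg$family_size_min) {
    stop_cfg("family size bounds must satisfy 1 <= min <= max")
  }
  if (length(cfg$bodyweight_mean) != cfg$n_cohorts) {
    stop_cfg("bodyweight_mean must have length n_cohorts")
  }
  invisible(cfg)
}

# Deterministic sub-stream seeds derived from the single global seed.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7L + k * 1009) %% 2147483647)
}

# One meiosis per parent: dosage 0 transmits 0, dosage 2 transmits 1,
# heterozygotes transmit a fair coin. `parent_dosages` is offspring x SNPs
# (rows already expanded to one row per offspring).
sample_gametes <- function(parent_dosages) {
  het <- parent_dosages == 1L
  allele <- (parent_dosages == 2L) * 1L
  if (any(het)) {
    allele[het] <- stats::rbinom(sum(het), 1L, 0.5)
  }
  allele
}

# Family sizes: min + geometric, truncated above; the geometric success
# probability is chosen so the configured median is hit.
sample_family_size <- function(cfg) {
  m <- max(1, cfg$family_size_median - cfg$family_size_min)
  p <- 1 - 0.5^(1 / (m + 1))
  min(cfg$family_size_max, cfg$family_size_min + stats::rgeom(1, p))
}

#' Simulate a mated pedigree and SNP genotypes
#'
#' Founder genotypes are drawn per SNP from binomial(2, p) with p uniform in
#' `maf_range`; offspring genotypes follow Mendelian gamete sampling from
#' their assigned parents. Families are formed by repeatedly pairing a random
#' sire with a random dam (so parents recur across families, creating
#' half-sib links) with sizes drawn from a truncated geometric-like
#' distribution centred on the configured median. Each family is assigned to
#' one cohort; sexes are assigned per offspring. Only offspring genotypes are
#' returned (broodstock are treated as unsampled).
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]),
#'   `pedigree` (tibble id/sire/dam), and `samples` (tibble id/family/cohort/
#'   sex). The generator's true per-SNP allele frequencies are attached to
#'   the genotypes as attribute `p_true`.
#' @export
simulate_pedigree_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  m <- config$n_snps
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  sire_ids <- sprintf("S%03d", seq_len(config$n_sires))
  dam_ids <- sprintf("D%03d", seq_len(config$n_dams))
  sire_geno <- matrix(stats::rbinom(config$n_sires * m, 2L, rep(p, each = config$n_sires)),
                      nrow = config$n_sires)
  dam_geno <- matrix(stats::rbinom(config$n_dams * m, 2L, rep(p, each = config$n_dams)),
                     nrow = config$n_dams)

  fam_sire <- integer(0); fam_dam <- integer(0); fam_size <- integer(0)
  total <- 0L
  while (total < config$n_offspring) {
    fam_sire <- c(fam_sire, sample.int(config$n_sires, 1L))
    fam_dam <- c(fam_dam, sample.int(config$n_dams, 1L))
    sz <- sample_family_size(config)
    sz <- min(sz, config$n_offspring - total)
    fam_size <- c(fam_size, as.integer(sz))
    total <- total + sz
  }
  n_fam <- length(fam_size)
  fam_cohort <- sample.int(config$n_cohorts, n_fam, replace = TRUE)

  off_fam <- rep.int(seq_len(n_fam), fam_size)
  n <- length(off_fam)
  off_id <- sprintf("F%04d", seq_len(n))
  off_sire <- fam_sire[off_fam]
  off_dam <- fam_dam[off_fam]

  dos <- sample_gametes(sire_geno[off_sire, , drop = FALSE]) +
    sample_gametes(dam_geno[off_dam, , drop = FALSE])
  if (config$call_rate < 1) {
    miss <- stats::runif(length(dos)) > config$call_rate
    dos[miss] <- NA_integer_
  }
  dimnames(dos) <- list(off_id, sprintf("snp%05d", seq_len(m)))

  geno <- genotype_matrix(dos)
  attr(geno, "p_true") <- p

  pedigree <- tibble::tibble(
    id = c(sire_ids, dam_ids, off_id),
    sire = c(rep(NA_character_, config$n_sires + config$n_dams), sire_ids[off_sire]),
    dam = c(rep(NA_character_, config$n_sires + config$n_dams), dam_ids[off_dam])
  )
  samples <- tibble::tibble(
    id = off_id,
    family = sprintf("FAM%03d", off_fam),
    cohort = sprintf("C%d", fam_cohort[off_fam]),
    sex = sample(c("F", "M"), n, replace = TRUE)
  )
  list(genotypes = geno, pedigree = pedigree, samples = samples)
}

#' Simulate bivariate breeding values from explicit SNP effects
#'
#' Per-SNP effect pairs are drawn from a bivariate normal with correlation
#' `r_g` and then linearly recoloured so their sample covariance equals the
#' target genetic covariance divided by the VanRaden denominator
#' \eqn{2\sum_j p_j(1-p_j)}; each individual's breeding-value pair is the sum
#' of its centred dosages times these effects. Scaling the *effects* (rather
#' than the realized breeding-value sample) makes the genetic variance in
#' the relationship-matrix metric -- the quantity REML estimates -- equal the
#' configured `sigma2_a1`, `sigma2_a2` and the genetic correlation equal
#' `r_g`; the realized sample variance of the breeding values then
#' fluctuates around a value slightly below the target, as it does for any
#' set of related individuals. Breeding values stay a linear function of the
#' markers, so GRM-based REML is exercised against a genuinely marker-driven
#' architecture.
#'
#' @param genotypes A [genotype_matrix()] (offspring) as produced by
#'   [simulate_pedigree_genotypes()].
#' @param config A [sim_config()].
#' @return A numeric matrix with columns `bv1`, `bv2` and rownames equal to
#'   individual ids.
#' @export
simulate_breeding_values <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 2L))
  dos <- genotypes$dosages
  p <- attr(genotypes, "p_true")
  if (is.null(p)) p <- genotypes$freqs
  Zc <- sweep(dos, 2L, 2 * p)
  Zc[is.na(Zc)] <- 0

  m <- ncol(Zc)
  cov_a <- config$r_g * sqrt(config$sigma2_a1 * config$sigma2_a2)
  target <- matrix(c(config$sigma2_a1, cov_a, cov_a, config$sigma2_a2), 2L, 2L)
  denom <- 2 * sum(p * (1 - p))
  if (m < 2 || denom <= .Machine$double.eps) {
    # degenerate panel (single or monomorphic SNPs): no usable genetic signal
    u <- matrix(0, m, 2L)
  } else {
    u <- recolor_columns(cbind(stats::rnorm(m), stats::rnorm(m)),
                         target / denom)
  }
  bv <- Zc %*% u
  bv <- scale(bv, center = TRUE, scale = FALSE)
  dimnames(bv) <- list(genotypes$ids, c("bv1", "bv2"))
  bv
}

# Recolour an n x 2 centred matrix so its sample covariance equals `target`
# (symmetric PSD square roots on both sides; tolerant of rank deficiency).
recolor_columns <- function(x, target) {
  psd_sqrt <- function(S, inv = FALSE) {
    e <- eigen(S, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    d <- if (inv) ifelse(lam > 1e-12 * max(lam, 1e-300), 1 / sqrt(lam), 0) else sqrt(lam)
    e$vectors %*% (d * t(e$vectors))
  }
  S <- stats::cov(x)
  x %*% psd_sqrt(S, inv = TRUE) %*% psd_sqrt(target)
}

#' Simulate two-method lipid phenotypes
#'
#' Generates one reference record for a random fraction of the fish and four
#' site-indexed proxy records for every fish:
#' \deqn{y_1 = \mu_1 + C + S + a_1 + e_1}
#' \deqn{y_{2,site} = \mu_2 + C + S + B_{site} + a_2 + pe + e_{2,site}}
#' where the permanent-environment deviation `pe` is shared by the four
#' records of one fish and the residual of the reference record correlates
#' `r_e` with each of the fish's proxy residuals. Harvest body weight is
#' simulated per cohort, independent of the lipid architecture, so
#' method differences are size-independent by construction.
#'
#' @param true_bv Breeding-value matrix from [simulate_breeding_values()].
#' @param config A [sim_config()].
#' @param samples Tibble id/cohort/sex from [simulate_pedigree_genotypes()].
#' @return A long-format phenotype tibble with columns id, cohort, sex, site,
#'   trait (`lipid_ref`, `lipid_ds`, `body_weight`) and value.
#' @export
simulate_phenotypes <- function(true_bv, config, samples) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 3L))
  n <- nrow(samples)
  ids <- samples$id
  stopifnot(identical(rownames(true_bv), ids))
  cohort_i <- as.integer(sub("^C", "", samples$cohort))
  sex_i <- ifelse(samples$sex == "F", 1L, 2L)

  sites <- c("LA", "LP", "RA", "RP")
  e2 <- matrix(stats::rnorm(n * 4L, 0, sqrt(config$sigma2_e2)), n, 4L)
  pe <- stats::rnorm(n, 0, sqrt(config$sigma2_pe2))

  # Reference residual correlated with each proxy-site residual:
  # e1 = b * sum(e2) + independent remainder, b = c / sigma2_e2,
  # c = r_e * sqrt(sigma2_e1 * sigma2_e2).
  if (config$sigma2_e2 > 0 && config$sigma2_e1 > 0) {
    cc <- config$r_e * sqrt(config$sigma2_e1 * config$sigma2_e2)
    b <- cc / config$sigma2_e2
    v_rem <- config$sigma2_e1 - 4 * b^2 * config$sigma2_e2
    e1 <- b * rowSums(e2) + stats::rnorm(n, 0, sqrt(max(0, v_rem)))
  } else {
    e1 <- stats::rnorm(n, 0, sqrt(config$sigma2_e1))
  }

  n_ref <- round(config$prop_reference_phenotyped * n)
  ref_idx <- sort(sample.int(n, n_ref))

  y1 <- config$mu1 + config$cohort_effects_ref[cohort_i] +
    config$sex_effects[sex_i] + true_bv[, 1L] + e1
  base2 <- config$mu2 + config$cohort_effects_proxy[cohort_i] +
    config$sex_effects[sex_i] + true_bv[, 2L] + pe
  y2 <- base2 + sweep(e2, 2L, config$site_effects, "+")

  bw <- stats::rnorm(n, config$bodyweight_mean[cohort_i], config$bodyweight_sd)

  ref_tbl <- tibble::tibble(
    id = ids[ref_idx], cohort = samples$cohort[ref_idx],
    sex = samples$sex[ref_idx], site = NA_character_,
    trait = "lipid_ref", value = y1[ref_idx]
  )
  ds_tbl <- tibble::tibble(
    id = rep(ids, times = 4L),
    cohort = rep(samples$cohort, times = 4L),
    sex = rep(samples$sex, times = 4L),
    site = rep(sites, each = n),
    trait = "lipid_ds", value = as.vector(y2)
  )
  bw_tbl <- tibble::tibble(
    id = ids, cohort = samples$cohort, sex = samples$sex,
    site = NA_character_, trait = "body_weight", value = bw
  )
  phen <- dplyr::arrange(dplyr::bind_rows(ref_tbl, ds_tbl, bw_tbl),
                         .data$trait, .data$id, .data$site)
  phen
}

#' Simulate a complete study population
#'
#' Runs pedigree/genotype simulation, breeding-value simulation and phenotype
#' simulation under one global seed. With an identical configuration the
#' result is bit-identical across runs.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_result` with elements `genotypes`,
#'   `pedigree`, `samples`, `true_bv`, `phenotypes`, `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  pg <- simulate_pedigree_genotypes(config)
  bv <- simulate_breeding_values(pg$genotypes, config)
  phen <- simulate_phenotypes(bv, config, pg$samples)
  structure(list(genotypes = pg$genotypes, pedigree = pg$pedigree,
                 samples = pg$samples, true_bv = bv, phenotypes = phen,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated population:", length(x$genotypes$ids), "offspring,",
      length(x$genotypes$snp_ids), "SNPs\n")
  cat("  reference records:", sum(x$phenotypes$trait == "lipid_ref"),
      "| proxy records:", sum(x$phenotypes$trait == "lipid_ds"), "\n")
  invisible(x)
}

#' Write a simulated population to disk
#'
#' Writes genotypes as VCF and dosage CSV, phenotypes as long-format CSV and
#' the pedigree as a three-column CSV into `dir`.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim_data <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    dosages = file.path(dir, "genotypes.csv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    pedigree = file.path(dir, "pedigree.csv")
  )
  write_vcf_dosages(sim$genotypes, paths["vcf"])
  write_dosage_csv(sim$genotypes, paths["dosages"])
  utils::write.csv(sim$phenotypes, paths["phenotypes"], row.names = FALSE)
  utils::write.csv(sim$pedigree, paths["pedigree"], row.names = FALSE)
  invisible(paths)
}
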