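#' Derive the eight analysis views of the proxy records
#'
#' From the four site-indexed proxy records per fish, builds the trait views
#' the full analysis consumes, appended to the input table as new trait
#' names:
#' * `lipid_ds_la` / `_lp` / `_ra` / `_rp` -- each body site as a
#'   single-record trait;
#' * `lipid_ds_rep` -- all four records as a repeated-record trait
#'   (site retained);
#' * `lipid_ds_rep_lr` -- left-side and right-side means as a two-record
#'   repeated trait (site `L` / `R`);
#' * `lipid_ds_mean` -- the simple (unweighted) mean of the four records as
#'   a single-record trait.
#'
#' Fish missing any of the records entering a mean are excluded from that
#' mean view (side means need both records of the side; the grand mean needs
#' all four) but retained in the per-site views; exclusions are reported via
#' the `exclusions` attribute. `weighted = TRUE` weights the grand mean by
#' available records instead of excluding incomplete fish, for use with
#' unbalanced recording.
#'
#' @param phenotypes Long-format phenotype tibble.
#' @param proxy_trait Name of the repeated proxy trait (default `lipid_ds`).
#' @param weighted Use the mean of available records instead of excluding
#'   incomplete fish from the grand-mean view.
#' @return The phenotype tibble with the derived trait rows appended.
#' @export
make_trait_views <- function(phenotypes, proxy_trait = "lipid_ds",
                             weighted = FALSE) {
  ds <- phenotypes[phenotypes$trait == proxy_trait & !is.na(phenotypes$value), ,
                   drop = FALSE]
  if (nrow(ds) == 0) stop("no records for proxy trait '", proxy_trait, "'",
                          call. = FALSE)
  if (anyDuplicated(ds[, c("id", "site")])) {
    stop("duplicate site records for at least one fish", call. = FALSE)
  }
  sites <- c("LA", "LP", "RA", "RP")
  if (!all(ds$site %in% sites)) {
    stop("proxy sites must be LA/LP/RA/RP", call. = FALSE)
  }

  per_site <- lapply(sites, function(s) {
    d <- ds[ds$site == s, , drop = FALSE]
    d$trait <- paste0(proxy_trait, "_", tolower(s))
    d$site <- NA_character_
    d
  })

  rep_view <- ds
  rep_view$trait <- paste0(proxy_trait, "_rep")

  side_of <- substr(ds$site, 1, 1)
  lr <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(ds, side = side_of),
                    .data$id, .data$cohort, .data$sex, .data$side),
    value = mean(.data$value), n_rec = dplyr::n(), .groups = "drop"
  )
  lr_keep <- lr[lr$n_rec == 2, , drop = FALSE]
  lr_view <- tibble::tibble(
    id = lr_keep$id, cohort = lr_keep$cohort, sex = lr_keep$sex,
    site = lr_keep$side, trait = paste0(proxy_trait, "_rep_lr"),
    value = lr_keep$value
  )

  gm <- dplyr::summarise(
    dplyr::group_by(ds, .data$id, .data$cohort, .data$sex),
    value = mean(.data$value), n_rec = dplyr::n(), .groups = "drop"
  )
  gm_keep <- if (weighted) gm else gm[gm$n_rec == 4, , drop = FALSE]
  mean_view <- tibble::tibble(
    id = gm_keep$id, cohort = gm_keep$cohort, sex = gm_keep$sex,
    site = NA_character_, trait = paste0(proxy_trait, "_mean"),
    value = gm_keep$value
  )

  out <- dplyr::bind_rows(c(list(phenotypes), per_site,
                            list(rep_view, lr_view, mean_view)))
  excl <- list(grand_mean = setdiff(unique(ds$id), gm_keep$id),
               side_mean = setdiff(unique(ds$id), unique(lr_keep$id)))
  if (length(excl$grand_mean)) {
    message(length(excl$grand_mean),
            " fish with incomplete site records excluded from the grand-mean view")
  }
  attr(out, "exclusions") <- excl
  out
}

#' Configuration for the end-to-end analysis
#'
#' Either `sim` (a [sim_config()], synthetic mode) or `paths` (named list
#' with `genotypes` -- VCF or dosage CSV -- and `phenotypes` CSV) must be
#' given, not both.
#'
#' @param sim A [sim_config()] for synthetic mode.
#' @param paths Named list of input files for real-data mode.
#' @param qc List of QC thresholds (`maf_min`, `hwe_p_min`, `call_rate_min`).
#' @param bivariate_traits Proxy trait views to pair with the reference
#'   trait in bivariate fits.
#' @param res_cov Estimate residual covariances in the bivariate fits.
#' @param out_dir Optional output directory for CSV reports and the run
#'   manifest.
#' @param seed Seed echoed into outputs (synthetic mode draws everything
#'   from the `sim` config's own seed).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL, paths = NULL,
                       qc = list(maf_min = 0.01, hwe_p_min = 1e-7,
                                 call_rate_min = 0.93),
                       bivariate_traits = c("lipid_ds_la", "lipid_ds_lp",
                                            "lipid_ds_ra", "lipid_ds_rp",
                                            "lipid_ds_rep", "lipid_ds_rep_lr",
                                            "lipid_ds_mean"),
                       res_cov = TRUE,
                       out_dir = NULL, seed = NULL) {
  if (is.null(sim) == is.null(paths)) {
    stop("exactly one of `sim` (synthetic mode) or `paths` must be supplied",
         call. = FALSE)
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (!is.null(paths) && !all(c("genotypes", "phenotypes") %in% names(paths))) {
    stop("paths must name `genotypes` and `phenotypes` files", call. = FALSE)
  }
  structure(list(sim = sim, paths = paths, qc = qc,
                 bivariate_traits = bivariate_traits, res_cov = res_cov,
                 out_dir = out_dir,
                 seed = if (!is.null(seed)) seed else if (!is.null(sim)) sim$seed else NA),
            class = "run_config")
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full proxy-validation analysis
#'
#' Orchestrates simulate (or load) -> SNP QC -> GRM -> trait views ->
#' phenotypic agreement -> REML genetic parameters, producing (i) an
#' agreement table per cohort and pooled, (ii) a genetic-parameter table
#' with one row per trait view (univariate fits of the reference trait, the
#' four per-site traits and the four-record mean; repeatability fits of the
#' all-records and left/right-averaged views) including the genetic and
#' phenotypic correlation of each proxy view with the reference trait from
#' bivariate fits, and (iii) a machine-readable bundle echoing the
#' configuration and seed. With a fixed seed the bundle is reproducible
#' bit-for-bit.
#'
#' @param config A [run_config()].
#' @return A list of class `proxyval_run` with elements `agreement`,
#'   `genetic_parameters`, `fits`, `grm`, `phenotypes`, `qc`, `config`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$sim)) {
    sim <- run_stage("simulate", simulate_population(config$sim))
    geno <- sim$genotypes
    phen <- sim$phenotypes
  } else {
    sim <- NULL
    geno <- run_stage("load-genotypes", {
      f <- config$paths$genotypes
      if (grepl("\\.vcf(\\.gz)?$", f)) read_vcf_dosages(f) else read_dosage_csv(f)
    })
    phen <- run_stage("load-phenotypes", {
      tibble::as_tibble(utils::read.csv(config$paths$phenotypes,
                                        stringsAsFactors = FALSE))
    })
  }

  geno_qc <- run_stage("qc", qc_filter(geno,
                                       maf_min = config$qc$maf_min,
                                       hwe_p_min = config$qc$hwe_p_min,
                                       call_rate_min = config$qc$call_rate_min))
  grm <- run_stage("grm", vanraden_grm(geno_qc))
  views <- run_stage("trait-views", make_trait_views(phen))

  agreement <- run_stage("agreement", {
    tryCatch(agreement_report(views, reference = "lipid_ref",
                              proxy = "lipid_ds_mean", group = "cohort"),
             error = function(e) {
               message("agreement undefined: ", conditionMessage(e))
               NULL
             })
  })

  uni_traits <- c("lipid_ref", "lipid_ds_la", "lipid_ds_lp", "lipid_ds_ra",
                  "lipid_ds_rp", "lipid_ds_mean")
  rep_traits <- c("lipid_ds_rep", "lipid_ds_rep_lr")
  fits <- list()
  for (tr in uni_traits) {
    fits[[tr]] <- run_stage(paste0("reml-", tr),
                            fit_univariate(views, grm, trait = tr))
  }
  for (tr in rep_traits) {
    fits[[tr]] <- run_stage(paste0("reml-", tr),
                            fit_repeatability(views, grm, trait = tr))
  }
  bifits <- list()
  for (tr in intersect(config$bivariate_traits, c(uni_traits[-1], rep_traits))) {
    bifits[[tr]] <- run_stage(paste0("reml-bivar-", tr),
                              fit_bivariate(views, grm, trait1 = "lipid_ref",
                                            trait2 = tr,
                                            res_cov = config$res_cov))
  }

  genetic_parameters <- genetic_parameter_table(fits, bifits)

  out <- structure(list(agreement = agreement,
                        genetic_parameters = genetic_parameters,
                        fits = fits, bivariate_fits = bifits, grm = grm,
                        phenotypes = views,
                        qc = attr(geno_qc, "qc"), sim = sim, config = config),
                   class = "proxyval_run")
  if (!is.null(config$out_dir)) write_run_outputs(out, config$out_dir)
  out
}

# Assemble the genetic-parameter table (one row per trait view).
genetic_parameter_table <- function(fits, bifits) {
  row_of <- function(tr, fit) {
    comp <- stats::setNames(fit$components$estimate, fit$components$component)
    der <- fit$derived
    dget <- function(nm, col = "estimate") {
      i <- match(nm, der$parameter)
      if (is.na(i)) NA_real_ else der[[col]][i]
    }
    bi <- bifits[[tr]]
    rg <- rp <- rg_se <- rp_se <- NA_real_
    if (!is.null(bi)) {
      bd <- bi$derived
      rg <- bd$estimate[bd$parameter == "r_g"]
      rg_se <- bd$se[bd$parameter == "r_g"]
      rp <- bd$estimate[bd$parameter == "r_p"]
      rp_se <- bd$se[bd$parameter == "r_p"]
    }
    tibble::tibble(
      trait = tr, n_individuals = fit$n_individuals,
      n_records = fit$n_records,
      sigma2_a = unname(comp["sigma2_a"]),
      sigma2_pe = unname(ifelse("sigma2_pe" %in% names(comp),
                                comp["sigma2_pe"], NA_real_)),
      sigma2_e = unname(comp["sigma2_e"]),
      h2 = dget("h2"), h2_se = dget("h2", "se"),
      t2 = dget("t2"), t2_se = dget("t2", "se"),
      r_g = rg, r_g_se = rg_se, r_p = rp, r_p_se = rp_se
    )
  }
  dplyr::bind_rows(Map(row_of, names(fits), fits))
}

write_run_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(run$agreement)) {
    utils::write.csv(run$agreement, file.path(dir, "agreement.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(run$genetic_parameters,
                   file.path(dir, "genetic_parameters.csv"), row.names = FALSE)
  utils::write.csv(run$qc$report, file.path(dir, "snp_qc.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "proxyval",
    seed = run$config$seed,
    synthetic = !is.null(run$config$sim),
    qc = run$config$qc,
    n_snps_retained = run$qc$n_retained,
    traits = names(run$fits),
    bivariate_traits = names(run$bivariate_fits)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.proxyval_run <- function(x, ...) {
  cat("proxyval run\n")
  if (!is.null(x$agreement)) {
    print(x$agreement)
  } else {
    cat("  (agreement undefined on these data)\n")
  }
  cat("Genetic parameters:\n")
  print(as.data.frame(x$genetic_parameters), digits = 3)
  invisible(x)
}
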