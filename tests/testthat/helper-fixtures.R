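# Small populations for fast unit tests; study-scale defaults are exercised
# in the acceptance suite.
tiny_config <- function(seed = 1, ...) {
  args <- list(
    n_sires = 5, n_dams = 5, n_offspring = 60, family_size_median = 6,
    n_snps = 300, seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Long-format phenotype tibble for a single-record trait.
single_trait_phen <- function(ids, values, trait = "t", cohort = "C1",
                              sex = "F") {
  tibble::tibble(id = ids, cohort = cohort, sex = sex,
                 site = NA_character_, trait = trait, value = values)
}

# grm object wrapping an explicit relationship matrix (e.g. identity).
grm_from_matrix <- function(M, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("i%03d", seq_len(nrow(M)))
  dimnames(M) <- list(ids, ids)
  structure(list(values = M, ids = ids, bend = 0), class = "grm")
}
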