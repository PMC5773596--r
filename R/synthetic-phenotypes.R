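#' Configuration for the knockout phenotype simulator
#'
#' Describes a multi-center knockout screen: per-sex cohort sizes, the centers
#' contributing data, planted multiplicative knockout effects, and the noise
#' model. Defaults follow the screen design the pipeline targets: seven
#' mutant mice per sex per strain, one phenotyping center per gene, shared
#' wild-type control cohorts per center and sex.
#'
#' @param n_genes number of knockout strains to simulate
#' @param n_mut_per_sex mutant cohort size per sex (default 7)
#' @param n_wt_per_sex shared wild-type cohort size per center and sex
#' @param centers character vector of phenotyping center labels
#' @param effect_table `data.frame(gene, parameter, sex, effect)` of
#'   multiplicative knockout effects (effect 1 = null); `sex` in `c("f","m")`.
#'   `NULL` means all effects 1.
#' @param ratio_noise_cv coefficient of variation of the multiplicative
#'   (lognormal) between-animal noise; 0 gives fully deterministic data
#' @param mass_slope VO2-body-mass coupling, ml/h per g
#' @param seed integer RNG seed
#' @return an object of class `pheno_sim_config`
#' @export
pheno_sim_config <- function(n_genes,
                             n_mut_per_sex = 7,
                             n_wt_per_sex = 50,
                             centers = "HMGU",
                             effect_table = NULL,
                             ratio_noise_cv = 0.1,
                             mass_slope = 2.5,
                             seed = 1L) {
  stop_if_not(n_genes >= 1, "n_genes must be >= 1")
  stop_if_not(n_mut_per_sex >= 1 && n_wt_per_sex >= 1, "cohort sizes must be >= 1")
  stop_if_not(length(centers) >= 1, "at least one center required")
  stop_if_not(ratio_noise_cv >= 0, "ratio_noise_cv must be >= 0")
  if (!is.null(effect_table)) {
    need <- c("gene", "parameter", "sex", "effect")
    stop_if_not(all(need %in% names(effect_table)),
                "effect_table needs columns gene, parameter, sex, effect")
    stop_if_not(all(effect_table$effect > 0), "effects must be > 0")
    bad <- setdiff(effect_table$parameter, metabolic_parameters())
    if (length(bad)) stop("unknown parameter(s) in effect_table: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    stop_if_not(all(effect_table$sex %in% c("f", "m")),
                "effect_table$sex must be 'f' or 'm'")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_mut_per_sex = as.integer(n_mut_per_sex),
                 n_wt_per_sex = as.integer(n_wt_per_sex),
                 centers = as.character(centers),
                 effect_table = effect_table,
                 ratio_noise_cv = ratio_noise_cv,
                 mass_slope = mass_slope,
                 seed = as.integer(seed)),
            class = "pheno_sim_config")
}

# sex-specific physiological baselines (adult C57BL/6N-like scale):
# glucose mg/dl, AUC relative (mg/dl)*min, TG mg/dl, body mass g, RER
.pheno_baselines <- function(sex) {
  if (sex == "f") {
    list(T0 = 110, AUC = 240, TG = 90, BM = 22, RER = 0.85,
         vo2_intercept = 25, mr_intercept = 0.45, mr_slope = 0.016)
  } else {
    list(T0 = 120, AUC = 260, TG = 110, BM = 28, RER = 0.85,
         vo2_intercept = 25, mr_intercept = 0.45, mr_slope = 0.016)
  }
}

# deterministic per-center multiplicative offset (inter-center variation)
.center_factor <- function(center, centers) {
  i <- match(center, centers)
  1 + 0.03 * (i - (length(centers) + 1) / 2)
}

.simulate_cohort <- function(gene, genotype, zygosity, n, sex, center, config,
                             id_prefix) {
  b <- .pheno_baselines(sex)
  cf <- .center_factor(center, config$centers)
  cv <- config$ratio_noise_cv
  eff <- setNames(rep(1, length(metabolic_parameters())), metabolic_parameters())
  if (genotype == "mut" && !is.null(config$effect_table)) {
    et <- config$effect_table
    rows <- et$gene == gene & et$sex == sex
    if (any(rows)) eff[et$parameter[rows]] <- et$effect[rows]
  }
  bm <- b$BM * cf * eff[["BM"]] * rlnorm_cv(n, cv)
  mbm <- bm            # mean mass around the calorimetry trial
  # VO2/MR: linear in body mass so that mass explains most of the variance;
  # additive noise scaled to a fraction of the intercept
  vo2 <- (b$vo2_intercept * cf + config$mass_slope * mbm) * eff[["VO2"]] +
    rnorm(n, 0, cv * 0.3 * b$vo2_intercept)
  mr <- (b$mr_intercept * cf + b$mr_slope * mbm) * eff[["MR"]] +
    rnorm(n, 0, cv * 0.3 * b$mr_intercept)
  rer <- pmin(pmax(b$RER * eff[["RER"]] * rlnorm_cv(n, cv * 0.3), 0.65), 1.05)
  data.frame(
    mouse_id = sprintf("%s_%s_%s_%03d", id_prefix, center, sex, seq_len(n)),
    gene = gene, genotype = genotype, zygosity = zygosity, sex = sex,
    center = center,
    T0 = b$T0 * cf * eff[["T0"]] * rlnorm_cv(n, cv),
    AUC = b$AUC * cf * eff[["AUC"]] * rlnorm_cv(n, cv),
    TG = b$TG * cf * eff[["TG"]] * rlnorm_cv(n, cv),
    BM = bm, VO2 = vo2, MR = mr, RER = rer, mean_body_mass = mbm,
    stringsAsFactors = FALSE)
}

#' Simulate a multi-center knockout phenotyping table
#'
#' Wild-type control cohorts are shared per center and sex; each knockout
#' strain is phenotyped in one center (round-robin over `centers`) with
#' `n_mut_per_sex` animals per sex. Mutant values are the wild-type generative
#' baselines scaled by the configured multiplicative effects, with lognormal
#' between-animal noise. VO2 and MR are linear in body mass so the downstream
#' residual adjustment has signal to remove. With all effects at 1 and
#' `ratio_noise_cv = 0` every downstream mutant/wild-type ratio is exactly 1.
#'
#' @param config a [pheno_sim_config()]
#' @return `data.frame` with one row per mouse, columns `mouse_id, gene,
#'   genotype, zygosity, sex, center, T0, AUC, TG, BM, VO2, MR, RER,
#'   mean_body_mass`
#' @export
simulate_phenotypes <- function(config) {
  stop_if_not(inherits(config, "pheno_sim_config"), "need a pheno_sim_config")
  with_seed(config$seed, {
    out <- vector("list", 0)
    for (center in config$centers) {
      for (sex in c("f", "m")) {
        out[[length(out) + 1]] <- .simulate_cohort(
          "WT", "wt", "wt", config$n_wt_per_sex, sex, center, config, "wt")
      }
    }
    genes <- sprintf("Gene%05d", seq_len(config$n_genes))
    gene_center <- config$centers[((seq_len(config$n_genes) - 1) %%
                                     length(config$centers)) + 1]
    for (i in seq_len(config$n_genes)) {
      for (sex in c("f", "m")) {
        out[[length(out) + 1]] <- .simulate_cohort(
          genes[i], "mut", "hom", config$n_mut_per_sex, sex, gene_center[i],
          config, genes[i])
      }
    }
    as.data.frame(data.table::rbindlist(out))
  })
}
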