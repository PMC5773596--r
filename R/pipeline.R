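#' Default end-to-end run configuration
#'
#' A compact configuration that exercises every stage on synthetic data in
#' well under a minute. All stochastic stages derive their seeds from the
#' top-level `seed`.
#'
#' @param out_dir run directory
#' @param seed master seed
#' @return nested list accepted by [run_pipeline()]
#' @export
default_run_config <- function(out_dir = tempfile("phenomore_run_"),
                               seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = list(ratios = TRUE, outliers = TRUE, permutation = TRUE,
                  cpma = TRUE, more = TRUE, networks = TRUE,
                  prediction = TRUE),
    phenotypes = list(n_genes = 150, n_mut_per_sex = 7, n_wt_per_sex = 30,
                      centers = c("HMGU", "JAX"), ratio_noise_cv = 0.1,
                      n_effect_genes = 10, effect_size = 1.6),
    ratios = list(min_group_size = 7),
    outliers = list(lower = 0.05, upper = 0.95),
    permutation = list(n_permutations = 2000, band = c(0.05, 0.95)),
    cpma = list(n_snps = 2000, n_traits = 16, n_signal = 20,
                signal_lambda = 3, threshold = 3.1),
    more = list(n_promoters = 20, promoter_length = 601, n_carriers = 4,
                min_score = 0.9),
    prediction = list(n_genes = 120, p_carrier = 0.35, p_background = 0.15)
  )
}

#' Read a YAML run configuration
#' @param path YAML file
#' @return nested configuration list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  modifyList(base, cfg)
}

# small demo PWM library used by the pipeline's promoter stage
.demo_pwms <- function() {
  mk <- function(id, consensus) {
    bases <- strsplit(consensus, "")[[1]]
    m <- matrix(0.04, nrow = length(bases), ncol = 4)
    for (i in seq_along(bases)) m[i, .base_codes[[bases[i]]]] <- 0.88
    pwm(id, m)
  }
  list(TFA = mk("TFA", "TGACTTCA"), TFB = mk("TFB", "CACGTGAC"),
       TFC = mk("TFC", "GGGCGGGA"), TFD = mk("TFD", "TTTCCCGA"))
}

#' Run the discovery pipeline end to end
#'
#' Executes the stages in their natural order — phenotype simulation,
#' strain deduplication, mass-dependent adjustment, ratio table, outlier
#' gene lists, permutation enrichment, CPMA on a simulated SNP matrix, MORE
#' cassette mining and enrichment on promoters of a strong-phenotype set,
#' network construction, and prediction validation — writing every stage
#' output and a run manifest under `config$out_dir`. Re-running the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config nested list (see [default_run_config()]) or a YAML path
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  st <- config$stages
  res <- list()

  ## phenotypes + ratios
  stop_if_not(isTRUE(st$ratios), "the ratios stage is required downstream")
  ph <- config$phenotypes
  eff <- NULL
  if ((ph$n_effect_genes %||% 0) > 0) {
    genes <- sprintf("Gene%05d", seq_len(ph$n_effect_genes))
    eff <- data.frame(gene = rep(genes, each = 2),
                      parameter = rep(c("TG", "T0"), length.out = 2 * length(genes)),
                      sex = rep(c("f", "m"), length.out = 2 * length(genes)),
                      effect = ph$effect_size %||% 1.6)
  }
  pcfg <- pheno_sim_config(n_genes = ph$n_genes,
                           n_mut_per_sex = ph$n_mut_per_sex %||% 7,
                           n_wt_per_sex = ph$n_wt_per_sex %||% 30,
                           centers = ph$centers %||% "HMGU",
                           effect_table = eff,
                           ratio_noise_cv = ph$ratio_noise_cv %||% 0.1,
                           seed = seed)
  records <- simulate_phenotypes(pcfg)
  write_tsv(records, file.path(out_dir, "phenotypes.tsv"))
  records <- dedupe_strains(records)
  for (p in mass_dependent_parameters())
    records <- adjust_mass_dependent(records, p)
  ratio_table <- compute_ratio_table(records,
                                     min_group_size = config$ratios$min_group_size %||% 7)
  write_tsv(ratio_table, file.path(out_dir, "ratio_table.tsv"))
  res$ratio_table <- ratio_table

  ## outlier gene lists
  if (isTRUE(st$outliers)) {
    ol <- call_outliers(ratio_table, lower = config$outliers$lower %||% 0.05,
                        upper = config$outliers$upper %||% 0.95)
    write_tsv(ol$lists, file.path(out_dir, "gene_lists.tsv"))
    writeLines(ol$strong_genes, file.path(out_dir, "strong_genes.txt"))
    res$outliers <- ol
  }

  ## permutation enrichment of the planted-effect genes
  if (isTRUE(st$permutation)) {
    stop_if_not(!is.null(res$outliers), "permutation stage needs outliers")
    cand <- if (!is.null(eff)) unique(eff$gene) else
      head(unique(ratio_table$gene), 20)
    perm <- permutation_enrichment(cand, ratio_table,
                                   band = config$permutation$band %||% c(0.05, 0.95),
                                   n_permutations = config$permutation$n_permutations %||% 2000,
                                   seed = seed + 1L)
    write_tsv(data.frame(observed_fraction = perm$observed_fraction,
                         null_mean = perm$null_mean,
                         n_permutations = perm$n_permutations,
                         p_value = perm$p_value, seed = perm$seed),
              file.path(out_dir, "permutation.tsv"))
    res$permutation <- perm
  }

  ## CPMA
  if (isTRUE(st$cpma)) {
    cp <- config$cpma
    sig <- setNames(rep(cp$signal_lambda %||% 3, cp$n_signal %||% 0),
                    sprintf("snp%06d", seq_len(cp$n_signal %||% 0)))
    gcfg <- gwas_sim_config(n_snps = cp$n_snps, n_traits = cp$n_traits %||% 16,
                            signal_snps = if (length(sig)) sig else NULL,
                            seed = seed + 2L)
    pmat <- simulate_gwas_pvalues(gcfg)
    write_tsv(pmat, file.path(out_dir, "gwas_pvalues.tsv"))
    cpres <- cpma_matrix(pmat, threshold = cp$threshold %||% 3.1)
    write_tsv(cpres, file.path(out_dir, "cpma.tsv"))
    res$cpma <- cpres
  }

  ## MORE mining + enrichment on a strong-phenotype promoter set
  if (isTRUE(st$more)) {
    stop_if_not(!is.null(res$outliers), "more stage needs outliers")
    mo <- config$more
    pwms <- .demo_pwms()
    lists <- res$outliers$lists
    # largest sub-phenotype list defines the test set of the demo
    key <- paste(lists$parameter, lists$sex, lists$tail)
    top <- names(sort(table(key), decreasing = TRUE))[1]
    sel <- strsplit(top, " ")[[1]]
    set_genes <- unique(lists$gene[lists$parameter == sel[1] &
                                     lists$sex == sel[2] & lists$tail == sel[3]])
    n_prom <- max(mo$n_promoters %||% 20, length(set_genes))
    ids <- sprintf("gene%04d|promoter_1", seq_len(n_prom))
    carriers <- ids[seq_len(min(mo$n_carriers %||% 4, length(ids)))]
    cassette <- planted_cassette(
      "planted1",
      elements = data.frame(pwm_id = c("TFA", "TFB", "TFC"),
                            strand = c("+", "+", "-")),
      gaps = list(c(15, 25), c(20, 30)),
      carriers = carriers)
    scfg <- promoter_sim_config(n_promoters = n_prom,
                                promoter_length = mo$promoter_length %||% 601,
                                planted_cassettes = list(cassette),
                                seed = seed + 3L)
    prom <- simulate_promoters(scfg, pwms)
    write_fasta(prom$sequences, file.path(out_dir, "promoters.fasta"))
    write_tsv(prom$truth, file.path(out_dir, "promoter_truth.tsv"))
    scans <- scan_promoters(prom$sequences, pwms,
                            min_score = mo$min_score %||% 0.9)
    write_matches_bed(scans, file.path(out_dir, "tfbs_matches.bed"))
    # the planted carriers play the role of the sub-phenotype promoter set
    test_ids <- carriers
    mined <- mine_cassettes(scans[scans$promoter_id %in% test_ids, ],
                            test_ids, mining_params())
    write_cassettes(mined, file.path(out_dir, "cassettes.txt"))
    sets <- build_more_sets(mined, id_prefix = paste0(sel[1], "-",
                                                      substr(sel[2], 1, 1),
                                                      substr(sel[3], 1, 1)))
    lens <- setNames(nchar(prom$sequences), names(prom$sequences))
    enr <- lapply(sets, more_enrichment, test_ids = test_ids, all_ids = ids,
                  scans = scans, promoter_lengths = lens)
    if (length(enr))
      write_tsv(data.frame(more_set = vapply(sets, `[[`, character(1), "id"),
                           target_count = vapply(enr, `[[`, numeric(1), "target_count"),
                           background_count = vapply(enr, `[[`, numeric(1), "background_count"),
                           expected = vapply(enr, `[[`, numeric(1), "expected"),
                           ratio = vapply(enr, `[[`, numeric(1), "ratio"),
                           associated = vapply(enr, `[[`, logical(1), "associated")),
                file.path(out_dir, "more_enrichment.tsv"))
    res$more <- list(cassettes = mined, sets = sets, enrichment = enr,
                     set_genes = set_genes, test_ids = test_ids,
                     sub_phenotype = paste0(sel[1], "-", substr(sel[2], 1, 1),
                                            substr(sel[3], 1, 1)))
  }

  ## networks
  if (isTRUE(st$networks)) {
    stop_if_not(!is.null(res$more), "networks stage needs the more stage")
    sets <- res$more$sets
    if (length(sets)) {
      rows <- do.call(rbind, lapply(sets, function(s)
        data.frame(more_set = s$id, sub_phenotype = res$more$sub_phenotype,
                   gene = sub("\\|promoter_1$", "", s$support))))
      net <- build_more_network(rows)
      write_network(net, file.path(out_dir, "more_network.graphml"),
                    file.path(out_dir, "more_network_edges.tsv"))
      res$network <- net
    }
  }

  ## prediction validation on an independent synthetic cohort
  if (isTRUE(st$prediction)) {
    pr <- config$prediction
    n <- pr$n_genes %||% 120
    res$prediction <- with_seed(seed + 4L, {
      genes <- sprintf("val%04d", seq_len(n))
      carrier <- seq_len(n) <= round(n / 2)
      match_counts <- setNames(ifelse(carrier,
                                      1 + stats::rbinom(n, 5, 0.3), 0L), genes)
      prob <- ifelse(carrier, pr$p_carrier %||% 0.35,
                     pr$p_background %||% 0.15)
      flags <- setNames(runif(n) < prob, genes)
      validate_prediction(match_counts, flags)
    })
    write_tsv(data.frame(stratum = c("matched", "unmatched"),
                         phenotype = res$prediction$table[, 1],
                         no_phenotype = res$prediction$table[, 2],
                         p_value = res$prediction$p_value),
              file.path(out_dir, "prediction.tsv"))
  }

  ## manifest
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = seed,
                   package_version = as.character(packageVersion("phenomore")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   outputs = sort(setdiff(list.files(out_dir), "manifest.json")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  res$manifest <- manifest
  invisible(res)
}
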