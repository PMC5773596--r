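#' Reduce a phenotyping table to one strain per gene
#'
#' When a gene was measured with several zygosities, the homozygote cohort is
#' preferred over the heterozygote; among genotypes of equal zygosity rank,
#' a genotype measured in both sexes is preferred over a sex-discordant one.
#' Wild-type (reference) rows are retained unchanged and flagged.
#'
#' @param records phenotyping `data.frame` (see [simulate_phenotypes()])
#' @return the filtered records, with a logical `reference_strain` column
#' @export
dedupe_strains <- function(records) {
  stop_if_not(all(c("gene", "genotype", "zygosity", "sex") %in% names(records)),
              "records must have gene, genotype, zygosity and sex columns")
  records$reference_strain <- records$genotype == "wt"
  wt <- records[records$genotype == "wt", , drop = FALSE]
  mut <- records[records$genotype == "mut", , drop = FALSE]
  if (nrow(mut) == 0) return(records)
  keep <- logical(nrow(mut))
  zyg_rank <- c(hom = 1, het = 2)
  for (g in unique(mut$gene)) {
    idx <- which(mut$gene == g)
    zy <- mut$zygosity[idx]
    cand <- unique(zy)
    rank <- zyg_rank[cand]
    both_sex <- vapply(cand, function(z)
      length(unique(mut$sex[idx][zy == z])) == 2, logical(1))
    # homozygote first; among equal zygosity, both-sex genotypes win
    ord <- order(rank, !both_sex)
    keep[idx[zy == cand[ord[1]]]] <- TRUE
  }
  rbind(wt, mut[keep, , drop = FALSE])
}

#' Residual-adjust a body-mass-dependent parameter
#'
#' Body mass is the dominant source of variance in absolute VO2 and metabolic
#' rate. Within each (center, sex) stratum, a linear model
#' `value ~ mean_body_mass` is fitted over mutants and wild types jointly; the
#' adjusted value is the residual plus the model prediction at the stratum
#' mean body mass, so adjusted values keep the scale of the raw readout, have
#' the same stratum mean, and are uncorrelated with body mass.
#'
#' @param records phenotyping `data.frame`
#' @param parameter `"VO2"` or `"MR"`
#' @return records with the parameter column replaced by its adjusted value
#' @export
adjust_mass_dependent <- function(records, parameter = c("VO2", "MR")) {
  parameter <- match.arg(parameter)
  stop_if_not("mean_body_mass" %in% names(records),
              "records must have a mean_body_mass column")
  key <- interaction(records$center, records$sex, drop = TRUE)
  for (s in levels(key)) {
    idx <- which(key == s)
    ok <- idx[!is.na(records[[parameter]][idx]) &
                !is.na(records$mean_body_mass[idx])]
    if (length(ok) < 3) {
      warning("stratum ", s, " has fewer than 3 animals; not adjusted",
              call. = FALSE)
      next
    }
    fit <- lm(records[[parameter]][ok] ~ records$mean_body_mass[ok])
    const <- unname(coef(fit)[1] + coef(fit)[2] * mean(records$mean_body_mass[ok]))
    records[[parameter]][ok] <- unname(residuals(fit)) + const
  }
  records
}

#' Mutant/wild-type ratio table per gene, parameter, sex and center
#'
#' For every (gene, center, sex) cohort and every metabolic parameter, the
#' ratio of the mutant mean to the wild-type mean of the same center and sex.
#' Rows with fewer than `min_group_size` mutants are dropped; rows whose
#' wild-type mean is zero (or missing) are rejected and reported in the
#' `rejected` attribute.
#'
#' @param records deduped, mass-adjusted phenotyping `data.frame`
#' @param min_group_size minimum mutant cohort size per sex (default 7)
#' @param qc_bounds optional named list of `c(lower, upper)` validity bounds
#'   per parameter; values outside are treated as invalid (excluded from
#'   means). Default: no bounds.
#' @return long `data.frame` with columns `gene, parameter, sex, center,
#'   ratio, n_mut, n_wt`
#' @export
compute_ratio_table <- function(records, min_group_size = 7, qc_bounds = NULL) {
  params <- intersect(metabolic_parameters(), names(records))
  stop_if_not(length(params) > 0, "no metabolic parameter columns found")
  dt <- data.table::as.data.table(records)
  if (!is.null(qc_bounds)) {
    for (p in intersect(names(qc_bounds), params)) {
      b <- qc_bounds[[p]]
      bad <- !is.na(dt[[p]]) & (dt[[p]] < b[1] | dt[[p]] > b[2])
      if (any(bad)) data.table::set(dt, which(bad), p, NA_real_)
    }
  }
  long <- data.table::melt(dt[, c("gene", "genotype", "sex", "center", params),
                              with = FALSE],
                           id.vars = c("gene", "genotype", "sex", "center"),
                           variable.name = "parameter", value.name = "value",
                           variable.factor = FALSE)
  wt <- long[long$genotype == "wt",
             list(wt_mean = mean(value, na.rm = TRUE),
                  n_wt = sum(!is.na(value))),
             by = c("center", "sex", "parameter")]
  mut <- long[long$genotype == "mut",
              list(mut_mean = mean(value, na.rm = TRUE),
                   n_mut = sum(!is.na(value))),
              by = c("gene", "center", "sex", "parameter")]
  tab <- merge(mut, wt, by = c("center", "sex", "parameter"))
  tab <- tab[tab$n_mut >= min_group_size, ]
  rejected <- tab[is.na(tab$wt_mean) | tab$wt_mean == 0 | tab$n_wt == 0, ]
  if (nrow(rejected) > 0)
    warning(nrow(rejected), " row(s) rejected: wild-type mean zero or missing",
            call. = FALSE)
  tab <- tab[!(is.na(tab$wt_mean) | tab$wt_mean == 0 | tab$n_wt == 0), ]
  tab$ratio <- tab$mut_mean / tab$wt_mean
  out <- as.data.frame(tab[, c("gene", "parameter", "sex", "center",
                               "ratio", "n_mut", "n_wt"), with = FALSE])
  out <- out[order(out$gene, out$parameter, out$sex, out$center), ]
  rownames(out) <- NULL
  attr(out, "rejected") <- as.data.frame(rejected)
  out
}

#' Two-sided 5% tail thresholds from a mean and standard deviation
#'
#' `mean - 1.645 sd` and `mean + 1.645 sd`; 1.645 is the standard normal 0.95
#' quantile, so each tail approximates p < 0.05 (p < 0.1 combined).
#'
#' @param mean distribution mean
#' @param sd distribution standard deviation (> 0)
#' @return named numeric `c(lower, upper)`
#' @export
sd_thresholds <- function(mean, sd) {
  stop_if_not(is.finite(sd) && sd > 0, "sd must be > 0")
  k <- 1.645
  c(lower = mean - k * sd, upper = mean + k * sd)
}

#' Call percentile outliers into per-(parameter, sex, tail) gene lists
#'
#' Ratios are pooled per (parameter, sex) across centers; a gene enters the
#' low list when its ratio is strictly below the empirical `lower` quantile
#' and the high list when strictly above the `upper` quantile (linear
#' interpolation quantiles; strict inequalities keep the combined flag rate
#' at or below `lower + (1 - upper)` under ties). With 7 parameters and both
#' sexes this yields the 28 lists whose union is the strong-phenotype set.
#'
#' @param ratio_table output of [compute_ratio_table()]
#' @param lower,upper quantile bounds (defaults 0.05 and 0.95)
#' @param min_genes minimum number of ratios a (parameter, sex) distribution
#'   must have to be scored (default 20); smaller distributions are skipped
#'   with a warning
#' @return object of class `gene_list_set`: list with `lists` (data.frame
#'   `parameter, sex, tail, gene, center, ratio`), `strong_genes` (character
#'   union), and `thresholds` per (parameter, sex)
#' @export
call_outliers <- function(ratio_table, lower = 0.05, upper = 0.95,
                          min_genes = 20) {
  stop_if_not(lower > 0 && upper < 1 && lower < upper, "need 0 < lower < upper < 1")
  strata <- unique(ratio_table[, c("parameter", "sex")])
  lists <- vector("list", 0)
  thr <- vector("list", 0)
  for (i in seq_len(nrow(strata))) {
    p <- strata$parameter[i]; s <- strata$sex[i]
    rows <- ratio_table[ratio_table$parameter == p & ratio_table$sex == s, ]
    if (nrow(rows) < min_genes) {
      warning("distribution ", p, "/", s, " has fewer than ", min_genes,
              " ratios; skipped", call. = FALSE)
      next
    }
    q <- quantile(rows$ratio, c(lower, upper), type = 7, names = FALSE)
    thr[[paste(p, s, sep = "/")]] <- c(lower = q[1], upper = q[2])
    lo <- rows[rows$ratio < q[1], ]
    hi <- rows[rows$ratio > q[2], ]
    if (nrow(lo) > 0)
      lists[[length(lists) + 1]] <- data.frame(parameter = p, sex = s,
                                               tail = "low", gene = lo$gene,
                                               center = lo$center,
                                               ratio = lo$ratio)
    if (nrow(hi) > 0)
      lists[[length(lists) + 1]] <- data.frame(parameter = p, sex = s,
                                               tail = "high", gene = hi$gene,
                                               center = hi$center,
                                               ratio = hi$ratio)
  }
  lists <- if (length(lists)) do.call(rbind, lists) else
    data.frame(parameter = character(), sex = character(), tail = character(),
               gene = character(), center = character(), ratio = numeric())
  structure(list(lists = lists,
                 strong_genes = sort(unique(lists$gene)),
                 thresholds = thr,
                 bounds = c(lower = lower, upper = upper)),
            class = "gene_list_set")
}

#' @export
print.gene_list_set <- function(x, ...) {
  cat("gene_list_set:", nrow(x$lists), "list entries,",
      length(x$strong_genes), "strong-phenotype genes\n")
  invisible(x)
}
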