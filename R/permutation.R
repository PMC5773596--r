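#' Permutation enrichment of a candidate gene set in outlier tails
#'
#' The observed statistic is the fraction of candidate genes whose ratio falls
#' inside the outlier band (below the lower or above the upper pooled
#' percentile) in at least one (parameter, sex) distribution. The null is
#' built by permuting the gene-to-ratio assignment independently within each
#' (parameter, sex) stratum and recomputing the fraction; the one-sided
#' p-value uses the add-one estimator `(# null >= observed + 1) / (n + 1)`.
#'
#' @param candidate_genes character vector of genes to test (must all appear
#'   in `ratio_table`)
#' @param ratio_table output of [compute_ratio_table()]
#' @param band `c(lower, upper)` percentile band; `c(0.05, 0.95)` is the
#'   primary call, `c(0.20, 0.80)` the secondary check
#' @param n_permutations number of permutations (default 1e6)
#' @param seed integer RNG seed
#' @return list of class `permutation_result`: `observed_fraction`,
#'   `n_permutations`, `p_value`, `seed`, `null_mean`
#' @export
permutation_enrichment <- function(candidate_genes, ratio_table,
                                   band = c(0.05, 0.95),
                                   n_permutations = 1e6, seed = 1L) {
  stop_if_not(length(candidate_genes) > 0, "candidate set must not be empty")
  candidate_genes <- unique(candidate_genes)
  missing_g <- setdiff(candidate_genes, ratio_table$gene)
  if (length(missing_g))
    stop("candidate gene(s) absent from ratio table: ",
         paste(head(missing_g, 5), collapse = ", "), call. = FALSE)
  strata <- split(ratio_table,
                  interaction(ratio_table$parameter, ratio_table$sex, drop = TRUE))
  cand_idx_of <- function(genes) match(genes, candidate_genes)
  # per stratum: number of flagged rows (fixed under permutation) and the
  # candidate index of every row (NA for non-candidates)
  strata_info <- lapply(strata, function(rows) {
    q <- quantile(rows$ratio, band, type = 7, names = FALSE)
    flagged <- rows$ratio < q[1] | rows$ratio > q[2]
    list(n = nrow(rows), k = sum(flagged),
         cand = cand_idx_of(rows$gene),
         flagged_cand = unique(stats::na.omit(cand_idx_of(rows$gene[flagged]))))
  })
  n_cand <- length(candidate_genes)
  obs_hit <- logical(n_cand)
  for (si in strata_info) obs_hit[si$flagged_cand] <- TRUE
  observed <- mean(obs_hit)
  null_frac <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      hit <- logical(n_cand)
      for (si in strata_info) {
        if (si$k == 0) next
        g <- si$cand[sample.int(si$n, si$k)]
        hit[g[!is.na(g)]] <- TRUE
      }
      mean(hit)
    }, numeric(1))
  })
  p <- (sum(null_frac >= observed) + 1) / (n_permutations + 1)
  structure(list(observed_fraction = observed,
                 n_permutations = as.integer(n_permutations),
                 p_value = p, seed = as.integer(seed),
                 null_mean = mean(null_frac)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed fraction %.4f, null mean %.4f, p = %.3g (%d permutations)\n",
              x$observed_fraction, x$null_mean, x$p_value, x$n_permutations))
  invisible(x)
}

#' Stratify strong-phenotype genes by prior annotation
#'
#' Sequential novelty filter: a gene with a (non-screen-derived) metabolic
#' mammalian-phenotype annotation, or a metabolic GO biological-process or
#' KEGG Metabolism annotation, is `known-metabolic`; a gene with any other
#' annotation in any table is `known-nonmetabolic` (e.g., GO molecular
#' function only); a gene absent from all tables is `unannotated`.
#'
#' @param genes character vector of genes to classify
#' @param annotation_tables list with elements `mp` (`data.frame(gene,
#'   metabolic, impc_sourced)`), `go` (`data.frame(gene, domain, metabolic)`,
#'   domain in `biological_process`/`molecular_function`) and `kegg`
#'   (`data.frame(gene, class)`); any element may be an empty data.frame
#' @return named character vector: `known-metabolic`, `known-nonmetabolic`
#'   or `unannotated` per gene
#' @export
annotate_novelty <- function(genes, annotation_tables) {
  mp <- annotation_tables$mp %||% data.frame(gene = character(),
                                             metabolic = logical(),
                                             impc_sourced = logical())
  go <- annotation_tables$go %||% data.frame(gene = character(),
                                             domain = character(),
                                             metabolic = logical())
  kegg <- annotation_tables$kegg %||% data.frame(gene = character(),
                                                 class = character())
  # screen-derived phenotype rows are excluded to avoid circular discovery
  if (!"impc_sourced" %in% names(mp)) mp$impc_sourced <- FALSE
  mp <- mp[!mp$impc_sourced, , drop = FALSE]
  mp_metab <- unique(mp$gene[mp$metabolic])
  go_metab <- unique(go$gene[go$metabolic & go$domain == "biological_process"])
  kegg_metab <- unique(kegg$gene[kegg$class == "Metabolism"])
  any_annot <- unique(c(mp$gene, go$gene, kegg$gene))
  out <- ifelse(genes %in% mp_metab, "known-metabolic",
         ifelse(genes %in% go_metab | genes %in% kegg_metab, "known-metabolic",
         ifelse(genes %in% any_annot, "known-nonmetabolic", "unannotated")))
  setNames(out, genes)
}
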