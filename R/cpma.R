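#' SNP quality-control filter
#'
#' Retains common, bi-allelic, well-called, non-linked SNPs: minor allele
#' frequency at or above `maf_min`, call rate at or above `call_rate_min`
#' (both inclusive), bi-allelic, and pairwise linkage below `ld_r_max` to any
#' already-retained SNP (greedy pruning in input order).
#'
#' @param snps `data.frame` with columns `snp_id, maf, call_rate, biallelic`
#'   and optionally `ld_r_max` (precomputed max correlation to retained
#'   neighbours)
#' @param ld optional long `data.frame(snp_a, snp_b, r)` of pairwise
#'   correlations; used for greedy pruning when `ld_r_max` is absent
#' @param maf_min minimum minor allele frequency (default 0.05)
#' @param call_rate_min minimum call rate (default 0.75)
#' @param ld_r_max linkage threshold: retained SNPs must have r strictly
#'   below it (default 0.8)
#' @return the retained rows of `snps`
#' @export
snp_qc_filter <- function(snps, ld = NULL, maf_min = 0.05,
                          call_rate_min = 0.75, ld_r_max = 0.8) {
  stop_if_not(all(c("snp_id", "maf", "call_rate", "biallelic") %in% names(snps)),
              "snps needs columns snp_id, maf, call_rate, biallelic")
  keep <- snps$biallelic & snps$maf >= maf_min & snps$call_rate >= call_rate_min
  snps <- snps[keep, , drop = FALSE]
  if ("ld_r_max" %in% names(snps)) {
    snps <- snps[snps$ld_r_max < ld_r_max, , drop = FALSE]
  } else if (!is.null(ld) && nrow(snps) > 0) {
    retained <- character(0)
    sel <- logical(nrow(snps))
    for (i in seq_len(nrow(snps))) {
      id <- snps$snp_id[i]
      linked <- abs(ld$r[(ld$snp_a == id & ld$snp_b %in% retained) |
                           (ld$snp_b == id & ld$snp_a %in% retained)])
      if (length(linked) == 0 || max(linked) < ld_r_max) {
        retained <- c(retained, id)
        sel[i] <- TRUE
      }
    }
    snps <- snps[sel, , drop = FALSE]
  }
  rownames(snps) <- NULL
  snps
}

.clamp_p <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-16)

#' Cross-phenotype meta-analysis statistic for one SNP
#'
#' Tests whether a SNP's association p-values across traits decay faster (or
#' slower) than the uniform null. With x_i = -ln p_i, the x_i are unit
#' exponential under the null; the alternative is exponential with mean
#' 1/lambda. The decay-rate MLE is lambda_hat = n / sum(x); the
#' likelihood-ratio statistic 2 (n ln lambda_hat - n + sum x) is referred to
#' a chi-square with 1 df and reported as score = -log10 of its upper tail.
#' The statistic is two-sided: lambda_hat < 1 (anti-enrichment) also gives a
#' positive value.
#'
#' @param pvalues numeric vector of per-trait p-values (length >= 2); values
#'   are clamped to `[1e-300, 1 - 1e-16]`
#' @param threshold significance cut on the score (default 3.1)
#' @return list of class `cpma_result`: `lambda_hat`, `statistic`, `score`,
#'   `significant`, `n_traits`
#' @export
cpma <- function(pvalues, threshold = 3.1) {
  stop_if_not(length(pvalues) >= 2, "need p-values for at least 2 traits")
  stop_if_not(all(is.finite(pvalues)), "p-values must be finite")
  x <- -log(.clamp_p(pvalues))
  n <- length(x)
  s <- sum(x)
  lambda <- n / s
  statistic <- max(0, 2 * (n * log(lambda) - n + s))
  score <- -pchisq(statistic, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  structure(list(lambda_hat = lambda, statistic = statistic, score = score,
                 significant = score > threshold, n_traits = n),
            class = "cpma_result")
}

#' @export
print.cpma_result <- function(x, ...) {
  cat(sprintf("CPMA: lambda_hat %.3f, statistic %.3f, score %.3f (%s)\n",
              x$lambda_hat, x$statistic, x$score,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Row-wise CPMA over a SNP x trait p-value matrix
#'
#' @param pmat numeric matrix (rows = SNPs, columns = traits) or a
#'   `data.frame` whose first column is `snp_id`
#' @param threshold score significance cut (default 3.1)
#' @return `data.frame` with columns `snp_id, n_traits, lambda_hat,
#'   statistic, score, significant, min_p, p_class`
#' @export
cpma_matrix <- function(pmat, threshold = 3.1) {
  if (is.data.frame(pmat)) {
    ids <- as.character(pmat[[1]])
    pmat <- as.matrix(pmat[, -1, drop = FALSE])
  } else {
    ids <- rownames(pmat) %||% sprintf("snp%06d", seq_len(nrow(pmat)))
  }
  stop_if_not(ncol(pmat) >= 2, "need at least 2 trait columns")
  complete <- stats::complete.cases(pmat)
  if (any(!complete))
    warning(sum(!complete), " SNP(s) with missing trait p-values dropped",
            call. = FALSE)
  pmat <- pmat[complete, , drop = FALSE]
  ids <- ids[complete]
  x <- -log(.clamp_p(pmat))
  n <- ncol(x)
  s <- rowSums(x)
  lambda <- n / s
  statistic <- pmax(0, 2 * (n * log(lambda) - n + s))
  score <- -pchisq(statistic, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  minp <- apply(pmat, 1, min)
  data.frame(snp_id = ids, n_traits = n, lambda_hat = lambda,
             statistic = statistic, score = score,
             significant = score > threshold,
             min_p = minp,
             p_class = vapply(minp, classify_pvalue, character(1)),
             stringsAsFactors = FALSE)
}

#' Bin a p-value into the reporting significance classes
#'
#' Classes (inclusive upper bounds on the significant side): genome-wide
#' (p <= 5e-8), lookup-corrected (<= 2.59e-6), suggestive (<= 1e-3),
#' nominal (<= 0.05), weak otherwise.
#'
#' @param p a p-value in (0, 1]
#' @return one of `"genome-wide"`, `"lookup-corrected"`, `"suggestive"`,
#'   `"nominal"`, `"weak"`
#' @export
classify_pvalue <- function(p) {
  stop_if_not(length(p) == 1 && is.finite(p) && p > 0 && p <= 1,
              "p must be a single value in (0, 1]")
  if (p <= 5e-8) "genome-wide"
  else if (p <= 2.59e-6) "lookup-corrected"
  else if (p <= 1e-3) "suggestive"
  else if (p <= 0.05) "nominal"
  else "weak"
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05)
#' @param n_tests number of tests run in parallel (>= 1)
#' @return `alpha / n_tests`
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stop_if_not(is.finite(n_tests) && n_tests >= 1, "n_tests must be >= 1")
  alpha / n_tests
}

#' Configuration for the SNP x trait p-value simulator
#'
#' @param n_snps number of SNPs
#' @param n_traits number of traits (default 16)
#' @param signal_snps named numeric vector mapping SNP id (or index as
#'   `"snpNNNNNN"`) to a decay mean lambda > 1; unnamed SNPs are null
#' @param seed integer seed
#' @return object of class `gwas_sim_config`
#' @export
gwas_sim_config <- function(n_snps, n_traits = 16, signal_snps = NULL,
                            seed = 1L) {
  stop_if_not(n_traits >= 2, "need at least 2 traits")
  if (!is.null(signal_snps)) {
    stop_if_not(all(signal_snps > 0), "signal lambdas must be > 0")
    stop_if_not(!is.null(names(signal_snps)), "signal_snps must be named")
  }
  structure(list(n_snps = as.integer(n_snps), n_traits = as.integer(n_traits),
                 signal_snps = signal_snps, seed = as.integer(seed)),
            class = "gwas_sim_config")
}

#' Simulate a SNP x trait p-value matrix
#'
#' Null SNPs get i.i.d. uniform(0, 1) p-values per trait. Signal SNPs get
#' p-values whose -ln(p) is exponential with mean lambda (> 1 means stronger
#' multi-trait association than the null; lambda = 1 is the null itself).
#'
#' @param config a [gwas_sim_config()]
#' @return `data.frame` with `snp_id` and one column per trait
#' @export
simulate_gwas_pvalues <- function(config) {
  stop_if_not(inherits(config, "gwas_sim_config"), "need a gwas_sim_config")
  with_seed(config$seed, {
    ids <- sprintf("snp%06d", seq_len(config$n_snps))
    p <- matrix(runif(config$n_snps * config$n_traits),
                nrow = config$n_snps, ncol = config$n_traits)
    if (!is.null(config$signal_snps)) {
      idx <- match(names(config$signal_snps), ids)
      stop_if_not(!anyNA(idx), "signal SNP id not in simulated matrix")
      for (j in seq_along(idx)) {
        lam <- config$signal_snps[j]
        p[idx[j], ] <- exp(-rexp(config$n_traits, rate = 1 / lam))
      }
    }
    out <- data.frame(snp_id = ids, stringsAsFactors = FALSE)
    colnames(p) <- sprintf("trait%02d", seq_len(config$n_traits))
    cbind(out, as.data.frame(p))
  })
}
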