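#' @importFrom stats lm predict quantile rexp rnorm runif rlnorm pchisq qnorm
#'   dhyper phyper fisher.test coef residuals setNames optimize cor
#' @importFrom utils read.delim write.table head packageVersion
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so simulation helpers do not
#' perturb the global stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# lognormal multiplicative noise with unit median and coefficient of variation
# cv on the natural scale; cv = 0 degenerates to exactly 1
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

#' Metabolic parameters handled by the pipeline
#'
#' The seven readouts: fasting basal glucose (T0), glucose-tolerance AUC,
#' plasma triglycerides (TG), body mass (BM), oxygen consumption (VO2),
#' metabolic rate (MR) and respiratory exchange ratio (RER).
#' @return character vector of parameter names
#' @export
metabolic_parameters <- function() {
  c("T0", "AUC", "TG", "BM", "VO2", "MR", "RER")
}

#' Parameters that require body-mass residual adjustment
#'
#' Absolute oxygen consumption and metabolic rate are dominated by body
#' mass; they are residual-adjusted before ratios are taken.
#' @return character vector of parameter names
#' @export
mass_dependent_parameters <- function() c("VO2", "MR")
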