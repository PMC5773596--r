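#' Group mined cassettes into MORE cassette sets
#'
#' Cassettes identical in all elements and their order (and strands) fall
#' into one set regardless of their distance definitions. Cassettes of four
#' or more elements that differ in exactly one element at the same relative
#' position (e.g. A-B-C-D and A-B-F-D) are additionally merged when their
#' promoter-support overlap `|A ∩ B| / min(|A|, |B|)` exceeds 0.8. Grouping
#' is transitive; the result is order-invariant and idempotent under
#' re-grouping of singleton-set cassettes.
#'
#' @param cassettes list of `more_cassette` objects from one promoter set
#' @param id_prefix label prefix for set ids (e.g. the sub-phenotype tag)
#' @param overlap_min support-overlap threshold for one-mismatch merging
#' @return list of `more_set` objects: `id`, `cassettes`, `support` (union),
#'   `phenotype_tag` (the prefix)
#' @export
build_more_sets <- function(cassettes, id_prefix = "MORE",
                            overlap_min = 0.8) {
  n <- length(cassettes)
  if (n == 0) return(list())
  elkey <- vapply(cassettes, function(c)
    paste(.etype(c$elements$pwm_id, c$elements$strand), collapse = ","),
    character(1))
  ellist <- lapply(cassettes, function(c)
    .etype(c$elements$pwm_id, c$elements$strand))
  supp <- lapply(cassettes, `[[`, "support")
  # union-find over cassettes
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (elkey[i] == elkey[j]) { union2(i, j); next }
    a <- ellist[[i]]; b <- ellist[[j]]
    if (length(a) != length(b) || length(a) < 4) next
    if (sum(a != b) != 1) next
    ov <- length(intersect(supp[[i]], supp[[j]])) /
      min(length(supp[[i]]), length(supp[[j]]))
    if (ov > overlap_min) union2(i, j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  # canonical order: by the lexicographically smallest member signature
  keys <- vapply(groups, function(g) min(elkey[g]), character(1))
  groups <- groups[order(keys)]
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    out[[gi]] <- structure(
      list(id = sprintf("%s_%02d", id_prefix, gi),
           cassettes = cassettes[g],
           support = sort(unique(unlist(supp[g]))),
           phenotype_tag = id_prefix),
      class = "more_set")
  }
  out
}

#' @export
print.more_set <- function(x, ...) {
  cat("MORE set", x$id, "-", length(x$cassettes), "cassette(s),",
      length(x$support), "supporting promoters\n")
  invisible(x)
}

#' Over-representation of a cassette or MORE set in a test promoter set
#'
#' The expected hit count in the test set is its size times the genome-wide
#' (background) hit rate; the over-representation ratio observed/expected of
#' 2 or more declares an association. When an opposite-phenotype control set
#' is supplied its ratio is reported alongside.
#'
#' @param x a `more_cassette` or `more_set`
#' @param test_ids promoter ids of the test (sub-phenotype) set
#' @param all_ids promoter ids of the background (all promoters)
#' @param scans match table from [scan_promoters()] covering `all_ids`
#' @param promoter_lengths named lengths for opposite-strand matching
#' @param control_ids optional promoter ids of the opposite-phenotype set
#' @param ratio_min association threshold (default 2)
#' @return list of class `enrichment_result`: `target_count`,
#'   `background_count`, `expected`, `ratio`, `associated`, and
#'   `control_ratio` when a control set is given
#' @export
more_enrichment <- function(x, test_ids, all_ids, scans,
                            promoter_lengths = NULL, control_ids = NULL,
                            ratio_min = 2) {
  stop_if_not(all(test_ids %in% all_ids), "test set must be within background")
  hits_all <- match_cassette(x, scans, all_ids,
                             promoter_lengths = promoter_lengths,
                             both_orientations = !is.null(promoter_lengths))
  hit_ids <- hits_all$promoter_id[hits_all$hit]
  n_bg <- length(hit_ids)
  observed <- sum(test_ids %in% hit_ids)
  expected <- length(test_ids) * n_bg / length(all_ids)
  ratio <- if (n_bg == 0) NA_real_ else observed / expected
  res <- list(target_count = observed, background_count = n_bg,
              n_test = length(test_ids), n_all = length(all_ids),
              expected = expected, ratio = ratio,
              associated = !is.na(ratio) && ratio >= ratio_min)
  if (!is.null(control_ids)) {
    obs_c <- sum(control_ids %in% hit_ids)
    exp_c <- length(control_ids) * n_bg / length(all_ids)
    res$control_ratio <- if (n_bg == 0) NA_real_ else obs_c / exp_c
  }
  structure(res, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d/%d test hits, expected %.2f, ratio %.2f (%s)\n",
              x$target_count, x$n_test, x$expected,
              ifelse(is.na(x$ratio), NA, x$ratio),
              if (isTRUE(x$associated)) "associated" else "not associated"))
  invisible(x)
}
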