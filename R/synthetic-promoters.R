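#' Describe a cassette to plant in synthetic promoters
#'
#' @param id cassette label
#' @param elements `data.frame(pwm_id, strand)` in 5'-to-3' order
#' @param gaps list of `c(lo, hi)` start-to-start distance ranges, one per
#'   adjacent element pair (bp)
#' @param carriers character vector of carrier promoter ids
#' @return list describing the planted cassette
#' @export
planted_cassette <- function(id, elements, gaps, carriers) {
  stop_if_not(nrow(elements) >= 2, "a cassette needs at least 2 elements")
  stop_if_not(length(gaps) == nrow(elements) - 1,
              "need one gap range per adjacent element pair")
  stop_if_not(all(vapply(gaps, function(g) length(g) == 2 && g[1] <= g[2],
                         logical(1))), "each gap must be c(lo, hi), lo <= hi")
  list(id = id, elements = elements, gaps = gaps,
       carriers = as.character(carriers))
}

#' Configuration for the synthetic promoter generator
#'
#' @param n_promoters number of promoters
#' @param promoter_length length in bp (default 601)
#' @param gc_content background GC fraction, in (0, 1)
#' @param planted_cassettes list of [planted_cassette()] descriptions
#' @param seed integer seed
#' @return object of class `promoter_sim_config`
#' @export
promoter_sim_config <- function(n_promoters, promoter_length = 601,
                                gc_content = 0.5, planted_cassettes = list(),
                                seed = 1L) {
  stop_if_not(n_promoters >= 1, "n_promoters must be >= 1")
  stop_if_not(gc_content > 0 && gc_content < 1, "gc_content must be in (0, 1)")
  structure(list(n_promoters = as.integer(n_promoters),
                 promoter_length = as.integer(promoter_length),
                 gc_content = gc_content,
                 planted_cassettes = planted_cassettes,
                 seed = as.integer(seed)),
            class = "promoter_sim_config")
}

.consensus_for <- function(pwm, strand) {
  cons <- pwm_consensus(pwm)
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    cons <- paste(rev(comp[strsplit(cons, "")[[1]]]), collapse = "")
  }
  cons
}

#' Simulate promoter sequences with planted ordered cassettes
#'
#' Background promoters are i.i.d. bases at the configured GC content.
#' Carrier promoters additionally contain the planted cassette: the consensus
#' of each element's PWM (reverse-complemented for minus-strand elements)
#' written at start-to-start distances sampled uniformly inside the stated
#' gap ranges, at a uniformly sampled anchor. The returned truth table
#' records the exact coordinates (1-based inclusive) of every planted site.
#'
#' @param config a [promoter_sim_config()]
#' @param pwms named list of [pwm()] objects; every planted element must
#'   reference one of them
#' @return list with `sequences` (named character vector, ids
#'   `"geneNNNN|promoter_1"` unless carriers name others) and `truth`
#'   (`data.frame(promoter_id, cassette_id, element_index, pwm_id, strand,
#'   start, end)`)
#' @export
simulate_promoters <- function(config, pwms) {
  stop_if_not(inherits(config, "promoter_sim_config"),
              "need a promoter_sim_config")
  for (pc in config$planted_cassettes) {
    missing_p <- setdiff(pc$elements$pwm_id, names(pwms))
    if (length(missing_p))
      stop("planted element references unknown PWM: ",
           paste(missing_p, collapse = ", "), call. = FALSE)
  }
  with_seed(config$seed, {
    n <- config$n_promoters
    len <- config$promoter_length
    gc <- config$gc_content
    ids <- sprintf("gene%04d|promoter_1", seq_len(n))
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(names(probs), len, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    names(seqs) <- ids
    truth <- vector("list", 0)
    for (pc in config$planted_cassettes) {
      lens <- vapply(pc$elements$pwm_id, function(id) nrow(pwms[[id]]$matrix),
                     integer(1))
      for (j in seq_len(nrow(pc$elements) - 1)) {
        if (pc$gaps[[j]][1] < lens[j])
          stop("gap ", j, " of cassette ", pc$id,
               " can overlap the preceding element", call. = FALSE)
      }
      for (carrier in pc$carriers) {
        stop_if_not(carrier %in% ids,
                    paste("carrier", carrier, "not among promoter ids"))
        gaps <- vapply(pc$gaps, function(g)
          if (g[1] == g[2]) g[1] else sample(seq(g[1], g[2]), 1), numeric(1))
        starts <- cumsum(c(1, gaps))
        span <- starts[length(starts)] + lens[length(lens)] - 1
        if (span > len)
          stop("planted cassette ", pc$id, " span (", span,
               " bp) exceeds promoter length (", len, " bp)", call. = FALSE)
        anchor <- sample(seq(0, len - span), 1)
        starts <- starts + anchor
        s <- strsplit(seqs[[carrier]], "")[[1]]
        for (k in seq_len(nrow(pc$elements))) {
          cons <- .consensus_for(pwms[[pc$elements$pwm_id[k]]],
                                 pc$elements$strand[k])
          s[starts[k]:(starts[k] + lens[k] - 1)] <- strsplit(cons, "")[[1]]
          truth[[length(truth) + 1]] <- data.frame(
            promoter_id = carrier, cassette_id = pc$id, element_index = k,
            pwm_id = pc$elements$pwm_id[k], strand = pc$elements$strand[k],
            start = starts[k], end = starts[k] + lens[k] - 1L)
        }
        seqs[[carrier]] <- paste(s, collapse = "")
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(promoter_id = character(), cassette_id = character(),
                 element_index = integer(), pwm_id = character(),
                 strand = character(), start = integer(), end = integer())
    list(sequences = seqs, truth = truth)
  })
}
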