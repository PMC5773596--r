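#' Mining parameters for MORE cassette discovery
#'
#' @param min_elements minimum cassette size (default 3)
#' @param max_elements maximum cassette size (default 6)
#' @param quorum minimum number of supporting promoters (floor 3); the miner
#'   adapts the quorum top-down from the set size to this floor
#' @param dist_var maximum width of a distance range, bp (default 20;
#'   the miner falls back to 30 when nothing is found at 20)
#' @param min_dist minimum start-to-start distance between adjacent
#'   elements, bp (default 10)
#' @return object of class `mining_params`
#' @export
mining_params <- function(min_elements = 3, max_elements = 6, quorum = 3,
                          dist_var = 20, min_dist = 10) {
  stop_if_not(min_elements >= 2 && min_elements <= max_elements,
              "need 2 <= min_elements <= max_elements")
  stop_if_not(quorum >= 3, "quorum floor is 3")
  stop_if_not(dist_var > 0 && min_dist >= 0, "distances must be positive")
  structure(list(min_elements = as.integer(min_elements),
                 max_elements = as.integer(max_elements),
                 quorum = as.integer(quorum),
                 dist_var = as.integer(dist_var),
                 min_dist = as.integer(min_dist)),
            class = "mining_params")
}

# element type key: "pwm_id/strand"
.etype <- function(pwm_id, strand) paste(pwm_id, strand, sep = "/")

# per-promoter occurrence lists: named list promoter -> list(etype -> sorted starts)
.occurrences <- function(scans, promoter_ids) {
  occ <- setNames(vector("list", length(promoter_ids)), promoter_ids)
  for (p in promoter_ids) occ[[p]] <- list()
  if (nrow(scans) == 0) return(occ)
  scans$et <- .etype(scans$pwm_id, scans$strand)
  for (p in intersect(unique(scans$promoter_id), promoter_ids)) {
    sub <- scans[scans$promoter_id == p, ]
    occ[[p]] <- lapply(split(sub$start, sub$et), function(x) sort(unique(x)))
  }
  occ
}

# promoters (by name) containing an ordered chain of etypes with adjacent
# start-to-start gaps inside windows; windows is a (k-1) x 2 matrix
.chain_support <- function(occ, etypes, windows) {
  vapply(names(occ), function(p) {
    pos <- occ[[p]][[etypes[1]]]
    if (is.null(pos) || !length(pos)) return(FALSE)
    for (j in seq_len(length(etypes) - 1)) {
      nxt <- occ[[p]][[etypes[j + 1]]]
      if (is.null(nxt) || !length(nxt)) return(FALSE)
      reach <- unique(unlist(lapply(pos, function(s)
        nxt[nxt - s >= windows[j, 1] & nxt - s <= windows[j, 2]])))
      if (!length(reach)) return(FALSE)
      pos <- reach
    }
    TRUE
  }, logical(1))
}

# realised gap ranges over all valid chains in the supporting promoters:
# position p of element j is on a chain iff forward- and backward-reachable;
# realised gaps are all (q - p) with p on-chain at j, q on-chain at j+1 and
# q - p inside the window
.tighten_windows <- function(occ, etypes, windows, support) {
  k <- length(etypes)
  lo <- rep(Inf, k - 1); hi <- rep(-Inf, k - 1)
  for (p in support) {
    posl <- lapply(etypes, function(e) occ[[p]][[e]] %||% numeric(0))
    fwd <- vector("list", k)
    fwd[[1]] <- posl[[1]]
    for (j in 2:k) {
      fwd[[j]] <- posl[[j]][vapply(posl[[j]], function(q)
        any(q - fwd[[j - 1]] >= windows[j - 1, 1] &
              q - fwd[[j - 1]] <= windows[j - 1, 2]), logical(1))]
    }
    bwd <- vector("list", k)
    bwd[[k]] <- posl[[k]]
    for (j in (k - 1):1) {
      bwd[[j]] <- posl[[j]][vapply(posl[[j]], function(s)
        any(bwd[[j + 1]] - s >= windows[j, 1] &
              bwd[[j + 1]] - s <= windows[j, 2]), logical(1))]
    }
    onchain <- lapply(seq_len(k), function(j) intersect(fwd[[j]], bwd[[j]]))
    for (j in seq_len(k - 1)) {
      d <- outer(onchain[[j + 1]], onchain[[j]], "-")
      d <- d[d >= windows[j, 1] & d <= windows[j, 2]]
      if (length(d)) { lo[j] <- min(lo[j], min(d)); hi[j] <- max(hi[j], max(d)) }
    }
  }
  cbind(lo, hi)
}

# candidate adjacent pairs: for each ordered etype pair, maximal distance
# windows of width <= dist_var covering pair occurrences in >= quorum promoters
.pair_candidates <- function(occ, params, quorum) {
  etypes <- sort(unique(unlist(lapply(occ, names))))
  cands <- list()
  for (a in etypes) for (b in etypes) {
    dd <- list()
    for (p in names(occ)) {
      sa <- occ[[p]][[a]]; sb <- occ[[p]][[b]]
      if (is.null(sa) || is.null(sb) || !length(sa) || !length(sb)) next
      d <- as.vector(outer(sb, sa, "-"))
      d <- d[d >= params$min_dist]
      if (length(d)) dd[[p]] <- unique(d)
    }
    if (length(dd) < quorum) next
    alld <- sort(unique(unlist(dd)))
    seen <- character(0)
    for (d0 in alld) {
      inwin <- alld[alld >= d0 & alld <= d0 + params$dist_var]
      supp <- names(dd)[vapply(dd, function(x) any(x %in% inwin), logical(1))]
      if (length(supp) < quorum) next
      # tighten to the distances realised in supporting promoters
      dreal <- sort(unique(unlist(lapply(dd[supp], function(x)
        x[x %in% inwin]))))
      key <- paste(a, b, min(dreal), max(dreal))
      if (key %in% seen) next
      seen <- c(seen, key)
      cands[[length(cands) + 1]] <- list(a = a, b = b,
                                         window = c(min(dreal), max(dreal)))
    }
  }
  cands
}

.cassette_signature <- function(etypes, windows) {
  paste(paste(etypes, collapse = ","),
        paste(apply(windows, 1, paste, collapse = "-"), collapse = ","),
        sep = "|")
}

#' Mine MORE cassettes shared by a promoter set
#'
#' Level-wise (a-priori style) search for maximal ordered, strand-oriented
#' cassettes of `min_elements` to `max_elements` TFBS elements such that at
#' least `quorum` promoters contain matches in the stated order with adjacent
#' start-to-start distances inside the cassette's ranges. Ranges are the
#' tightest intervals covering the supporting occurrences, at most `dist_var`
#' wide, and at least `min_dist` at the lower end. The quorum is adapted
#' top-down from the set size to the floor of 3; if nothing is found at
#' `dist_var` 20, mining is retried at 30; a set that still yields nothing is
#' reported negative (empty result).
#'
#' @param scans match table from [scan_promoters()] restricted to the set
#' @param promoter_ids promoter ids of the set (>= 3), including promoters
#'   without matches
#' @param params a [mining_params()]
#' @param adapt_quorum adapt the quorum top-down from `length(promoter_ids)`
#'   (default `TRUE`); with `FALSE` the configured quorum is used as-is
#' @return list of `more_cassette` objects, each with `elements`
#'   (`data.frame(pwm_id, strand)`), `ranges` ((k-1) x 2 matrix of bp),
#'   `support` (character), `quorum_used` and `dist_var_used`; empty list if
#'   the set is negative
#' @export
mine_cassettes <- function(scans, promoter_ids, params = mining_params(),
                           adapt_quorum = TRUE) {
  stop_if_not(length(promoter_ids) >= 3, "a promoter set needs >= 3 members")
  occ <- .occurrences(scans, promoter_ids)
  for (dv in unique(c(params$dist_var, 30L))) {
    pars <- params; pars$dist_var <- dv
    quorums <- if (adapt_quorum)
      seq(length(promoter_ids), params$quorum) else params$quorum
    for (q in quorums) {
      res <- .mine_at(occ, pars, q)
      if (length(res)) {
        for (i in seq_along(res)) {
          res[[i]]$quorum_used <- as.integer(q)
          res[[i]]$dist_var_used <- as.integer(dv)
        }
        return(res)
      }
    }
  }
  list()
}

.mine_at <- function(occ, params, quorum) {
  pairs <- .pair_candidates(occ, params, quorum)
  if (!length(pairs)) return(list())
  # index pair candidates by first element for extension
  by_a <- split(pairs, vapply(pairs, `[[`, character(1), "a"))
  level <- lapply(pairs, function(pr) {
    w <- matrix(pr$window, nrow = 1)
    supp <- names(occ)[.chain_support(occ, c(pr$a, pr$b), w)]
    list(etypes = c(pr$a, pr$b), windows = w, support = supp)
  })
  level <- Filter(function(c) length(c$support) >= quorum, level)
  found <- if (params$min_elements <= 2) level else list()
  k <- 2
  while (k < params$max_elements && length(level)) {
    nxt <- list()
    seen <- character(0)
    for (cas in level) {
      lastel <- cas$etypes[length(cas$etypes)]
      for (pr in by_a[[lastel]] %||% list()) {
        etypes <- c(cas$etypes, pr$b)
        windows <- rbind(cas$windows, pr$window)
        sig <- .cassette_signature(etypes, windows)
        if (sig %in% seen) next
        seen <- c(seen, sig)
        suppmask <- .chain_support(occ[cas$support], etypes, windows)
        supp <- cas$support[suppmask]
        if (length(supp) < quorum) next
        nxt[[length(nxt) + 1]] <- list(etypes = etypes, windows = windows,
                                       support = supp)
      }
    }
    level <- nxt
    k <- k + 1
    if (k >= params$min_elements) found <- c(found, level)
  }
  if (!length(found)) return(list())
  # tighten windows to realised gaps, then deduplicate
  found <- lapply(found, function(cas) {
    w <- .tighten_windows(occ, cas$etypes, cas$windows, cas$support)
    cas$windows <- w
    cas
  })
  sigs <- vapply(found, function(c) .cassette_signature(c$etypes, c$windows),
                 character(1))
  found <- found[!duplicated(sigs)]
  # maximality: suppress a cassette whose element list is a contiguous
  # sub-list of another's with identical support
  is_contig_sublist <- function(a, b) {
    if (length(a) >= length(b)) return(FALSE)
    for (s in seq_len(length(b) - length(a) + 1))
      if (identical(a, b[s:(s + length(a) - 1)])) return(TRUE)
    FALSE
  }
  supstr <- vapply(found, function(c)
    paste(sort(c$support), collapse = ","), character(1))
  drop <- logical(length(found))
  for (i in seq_along(found)) {
    for (j in seq_along(found)) {
      if (i == j || drop[i]) next
      if (supstr[i] == supstr[j] &&
          is_contig_sublist(found[[i]]$etypes, found[[j]]$etypes))
        drop[i] <- TRUE
    }
  }
  found <- found[!drop]
  # canonical order: by size then signature, for input-order invariance
  ord <- order(-vapply(found, function(c) length(c$etypes), integer(1)),
               vapply(found, function(c) .cassette_signature(c$etypes, c$windows),
                      character(1)))
  lapply(found[ord], function(cas) {
    parts <- do.call(rbind, strsplit(cas$etypes, "/"))
    structure(list(elements = data.frame(pwm_id = parts[, 1],
                                         strand = parts[, 2],
                                         stringsAsFactors = FALSE),
                   ranges = unname(cas$windows),
                   support = sort(cas$support)),
              class = "more_cassette")
  })
}

#' @export
print.more_cassette <- function(x, ...) {
  cat("MORE cassette:",
      paste(paste0(x$elements$pwm_id, "(", x$elements$strand, ")"),
            collapse = " - "),
      "\n  ranges:",
      paste(apply(x$ranges, 1, function(r) paste0("[", r[1], ",", r[2], "]")),
            collapse = " "),
      "\n  support:", length(x$support), "promoters\n")
  invisible(x)
}

#' Match a cassette (or MORE set) against promoters
#'
#' A promoter hits a cassette when it contains matches of the cassette's
#' elements in order, on the stated strands, with adjacent start-to-start
#' distances inside the cassette's ranges. With `both_orientations = TRUE`
#' (the default) the mirrored reading — the cassette on the opposite strand
#' of the promoter — is also tested, which finds matches missed at mining
#' time. A MORE set hits when any member cassette hits.
#'
#' @param x a `more_cassette` or `more_set`
#' @param scans match table from [scan_promoters()] covering the promoters
#' @param promoter_ids promoters to test
#' @param promoter_lengths named integer vector of promoter lengths; required
#'   for `both_orientations`
#' @param both_orientations also test the opposite-strand reading
#' @return `data.frame(promoter_id, hit, orientation)`; orientation is
#'   `"forward"`, `"mirrored"` or `NA` for misses
#' @export
match_cassette <- function(x, scans, promoter_ids, promoter_lengths = NULL,
                           both_orientations = TRUE) {
  if (inherits(x, "more_set")) {
    hits <- lapply(x$cassettes, match_cassette, scans = scans,
                   promoter_ids = promoter_ids,
                   promoter_lengths = promoter_lengths,
                   both_orientations = both_orientations)
    hit <- Reduce(`|`, lapply(hits, `[[`, "hit"))
    ori <- rep(NA_character_, length(promoter_ids))
    for (h in hits) ori[is.na(ori) & h$hit] <- h$orientation[is.na(ori) & h$hit]
    return(data.frame(promoter_id = promoter_ids, hit = hit,
                      orientation = ori, stringsAsFactors = FALSE))
  }
  stop_if_not(inherits(x, "more_cassette"), "x must be a more_cassette or more_set")
  occ <- .occurrences(scans, promoter_ids)
  etypes <- .etype(x$elements$pwm_id, x$elements$strand)
  fwd <- .chain_support(occ, etypes, x$ranges)
  ori <- ifelse(fwd, "forward", NA_character_)
  hit <- fwd
  if (both_orientations) {
    stop_if_not(!is.null(promoter_lengths),
                "promoter_lengths required for both_orientations")
    # opposite-strand reading: flip coordinates and strands of the scans,
    # then run the same forward chain test
    flipped <- scans
    if (nrow(flipped)) {
      lens <- promoter_lengths[flipped$promoter_id]
      s2 <- lens - flipped$end + 1L
      e2 <- lens - flipped$start + 1L
      flipped$start <- s2; flipped$end <- e2
      flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
    }
    occ2 <- .occurrences(flipped, promoter_ids)
    mir <- .chain_support(occ2, etypes, x$ranges)
    ori[!hit & mir] <- "mirrored"
    hit <- hit | mir
  }
  data.frame(promoter_id = promoter_ids, hit = unname(hit),
             orientation = unname(ori), stringsAsFactors = FALSE)
}
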