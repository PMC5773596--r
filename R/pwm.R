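#' Construct a position weight matrix object
#'
#' @param id matrix identifier
#' @param matrix numeric matrix, one row per position, columns `A, C, G, T`,
#'   each row summing to 1 (counts are normalised automatically); at least 4
#'   positions
#' @param min_score default match threshold on the similarity scale `[0, 1]`
#' @return object of class `pwm`
#' @export
pwm <- function(id, matrix, min_score = 0.85) {
  m <- as.matrix(matrix)
  stop_if_not(ncol(m) == 4, "pwm matrix needs 4 columns (A, C, G, T)")
  stop_if_not(nrow(m) >= 4, "pwm must have at least 4 positions")
  stop_if_not(all(m >= 0), "pwm entries must be non-negative")
  rs <- rowSums(m)
  stop_if_not(all(rs > 0), "pwm rows must not be all zero")
  m <- m / rs
  colnames(m) <- c("A", "C", "G", "T")
  structure(list(id = id, matrix = m, min_score = min_score), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "-", nrow(x$matrix), "bp, consensus",
      pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param x a [pwm()] object
#' @return character string
#' @export
pwm_consensus <- function(x) {
  paste(colnames(x$matrix)[apply(x$matrix, 1, which.max)], collapse = "")
}

#' Read a JASPAR-format PWM file
#'
#' Parses the common JASPAR text layout: a `>ID name` header followed by four
#' lines `A [ 1 2 3 ... ]` (brackets optional). Counts are normalised to
#' per-position probabilities.
#'
#' @param path file path
#' @param min_score default threshold assigned to every matrix
#' @return named list of [pwm()] objects
#' @export
read_jaspar <- function(path, min_score = 0.85) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  stop_if_not(length(starts) > 0, "no JASPAR records found")
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    last <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    block <- lines[(starts[i] + 1):last]
    stop_if_not(length(block) >= 4, paste("incomplete JASPAR record", id))
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      list(base = toupper(parts[1]), counts = as.numeric(parts[-1]))
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    stop_if_not(setequal(bases, c("A", "C", "G", "T")),
                paste("JASPAR record", id, "must have A, C, G, T rows"))
    m <- do.call(cbind, lapply(c("A", "C", "G", "T"), function(b)
      rows[[match(b, bases)]]$counts))
    out[[id]] <- pwm(id, m, min_score = min_score)
  }
  out
}

#' Read PWMs from a simple tabular dialect
#'
#' TSV with columns `pwm_id, pos, A, C, G, T`, one row per matrix position.
#'
#' @param path file path
#' @param min_score default threshold assigned to every matrix
#' @return named list of [pwm()] objects
#' @export
read_pwm_table <- function(path, min_score = 0.85) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("pwm_id", "pos", "A", "C", "G", "T") %in% names(tab)),
              "pwm table needs columns pwm_id, pos, A, C, G, T")
  out <- list()
  for (id in unique(tab$pwm_id)) {
    rows <- tab[tab$pwm_id == id, ]
    rows <- rows[order(rows$pos), ]
    out[[id]] <- pwm(id, as.matrix(rows[, c("A", "C", "G", "T")]),
                     min_score = min_score)
  }
  out
}

#' Write PWMs to the tabular dialect
#' @param pwms named list of [pwm()] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pwm_table <- function(pwms, path) {
  rows <- do.call(rbind, lapply(pwms, function(p)
    data.frame(pwm_id = p$id, pos = seq_len(nrow(p$matrix)),
               A = p$matrix[, 1], C = p$matrix[, 2],
               G = p$matrix[, 3], T = p$matrix[, 4])))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.base_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)

.encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- .base_codes[chars]            # N and other ambiguity codes -> NA
  unname(codes)
}

# reverse-complemented matrix: scanning the forward strand with it is
# equivalent to scanning the reverse strand with the original matrix
.revcomp_matrix <- function(m) m[rev(seq_len(nrow(m))), 4:1, drop = FALSE]

.window_scores <- function(codes, m) {
  L <- nrow(m)
  n <- length(codes)
  if (n < L) return(numeric(0))
  nw <- n - L + 1
  sc <- numeric(nw)
  for (i in seq_len(L)) {
    b <- codes[i:(i + nw - 1)]
    v <- m[i, ][b]                       # NA base propagates NA
    sc <- sc + ifelse(is.na(v), NA_real_, v)
  }
  sc / sum(apply(m, 1, max))
}

#' Scan one promoter sequence with a PWM on both strands
#'
#' Every window is scored by probability-weighted matrix similarity
#' normalised to `[0, 1]` (score 1 = the per-position maximum base at every
#' position). Windows containing `N` are skipped; overlapping matches are
#' all reported. Coordinates are 1-based inclusive on the forward strand;
#' use [write_matches_bed()] for the 0-based half-open interchange format.
#'
#' @param sequence character string over `A, C, G, T, N`
#' @param pwm a [pwm()] object
#' @param min_score threshold override (default: the matrix's own)
#' @return `data.frame(pwm_id, start, end, strand, score)`; empty when the
#'   sequence is shorter than the matrix
#' @export
scan_pwm <- function(sequence, pwm, min_score = NULL) {
  min_score <- min_score %||% pwm$min_score
  codes <- .encode_seq(sequence)
  L <- nrow(pwm$matrix)
  empty <- data.frame(pwm_id = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric())
  if (length(codes) < L) return(empty)
  fw <- .window_scores(codes, pwm$matrix)
  rv <- .window_scores(codes, .revcomp_matrix(pwm$matrix))
  hit_f <- which(!is.na(fw) & fw >= min_score)
  hit_r <- which(!is.na(rv) & rv >= min_score)
  if (length(hit_f) + length(hit_r) == 0) return(empty)
  out <- data.frame(
    pwm_id = pwm$id,
    start = c(hit_f, hit_r),
    end = c(hit_f, hit_r) + L - 1L,
    strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
    score = c(fw[hit_f], rv[hit_r]),
    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a set of promoters with a PWM library
#'
#' @param sequences named character vector (or list) of promoter sequences
#' @param pwms named list of [pwm()] objects
#' @param min_score optional threshold override applied to every matrix
#' @return `data.frame(promoter_id, pwm_id, start, end, strand, score)`
#' @export
scan_promoters <- function(sequences, pwms, min_score = NULL) {
  stop_if_not(!is.null(names(sequences)) && all(nzchar(names(sequences))),
              "sequences must be named by promoter id")
  out <- vector("list", 0)
  for (pid in names(sequences)) {
    for (p in pwms) {
      m <- scan_pwm(sequences[[pid]], p, min_score = min_score)
      if (nrow(m) > 0) {
        m$promoter_id <- pid
        out[[length(out) + 1]] <- m
      }
    }
  }
  if (!length(out))
    return(data.frame(promoter_id = character(), pwm_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("promoter_id", "pwm_id", "start", "end", "strand", "score")]
}
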