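#' Read a FASTA file into a named character vector
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  stop_if_not(length(hdr) > 0, "no FASTA records found")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1)
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1):ends[i]], collapse = ""), character(1))
  setNames(toupper(gsub("\\s", "", seqs)), ids)
}

#' Write sequences to FASTA
#' @param sequences named character vector
#' @param path output path
#' @param width line-wrap width (default 70)
#' @return `path`, invisibly
#' @export
write_fasta <- function(sequences, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write TFBS matches as BED-like TSV (0-based half-open)
#'
#' Converts the package's 1-based inclusive coordinates to the BED
#' convention: `start0 = start - 1`, `end0 = end`.
#'
#' @param matches match table from [scan_promoters()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_matches_bed <- function(matches, path) {
  bed <- data.frame(chrom = matches$promoter_id,
                    chromStart = matches$start - 1L,
                    chromEnd = matches$end,
                    name = matches$pwm_id,
                    score = matches$score,
                    strand = matches$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like TSV of TFBS matches back to 1-based coordinates
#' @param path file path
#' @return match table as from [scan_promoters()]
#' @export
read_matches_bed <- function(path) {
  bed <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(promoter_id = bed$chrom, pwm_id = bed$name,
             start = bed$chromStart + 1L, end = bed$chromEnd,
             strand = bed$strand, score = bed$score,
             stringsAsFactors = FALSE)
}

#' Write phenotyping / ratio / gene-list tables as TSV
#' @param x data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path
#' @return data.frame
#' @export
read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write mined cassettes (or MORE sets) to a structured text file
#'
#' One block per cassette: elements with strands, distance ranges, and the
#' supporting promoters. The format round-trips bit-exactly through
#' [read_cassettes()].
#'
#' @param cassettes list of `more_cassette` objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cassettes <- function(cassettes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(cassettes)) {
    cas <- cassettes[[i]]
    writeLines(sprintf("cassette\t%d", i), con)
    writeLines(sprintf("elements\t%s",
                       paste(paste(cas$elements$pwm_id, cas$elements$strand,
                                   sep = "/"), collapse = ",")), con)
    writeLines(sprintf("ranges\t%s",
                       paste(apply(cas$ranges, 1, paste, collapse = ":"),
                             collapse = ",")), con)
    writeLines(sprintf("support\t%s", paste(cas$support, collapse = ",")), con)
    if (!is.null(cas$quorum_used))
      writeLines(sprintf("quorum\t%d", cas$quorum_used), con)
    if (!is.null(cas$dist_var_used))
      writeLines(sprintf("dist_var\t%d", cas$dist_var_used), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read cassettes written by [write_cassettes()]
#' @param path file path
#' @return list of `more_cassette` objects
#' @export
read_cassettes <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  flush_cur <- function() {
    if (is.null(cur)) return()
    parts <- do.call(rbind, strsplit(cur$elements, "/"))
    rng <- do.call(rbind, lapply(strsplit(cur$ranges, ":"), as.numeric))
    cas <- structure(list(elements = data.frame(pwm_id = parts[, 1],
                                                strand = parts[, 2],
                                                stringsAsFactors = FALSE),
                          ranges = unname(rng),
                          support = cur$support),
                     class = "more_cassette")
    if (!is.null(cur$quorum)) cas$quorum_used <- cur$quorum
    if (!is.null(cur$dist_var)) cas$dist_var_used <- cur$dist_var
    out[[length(out) + 1]] <<- cas
  }
  for (l in lines) {
    if (!nzchar(l)) next
    kv <- strsplit(l, "\t")[[1]]
    key <- kv[1]; val <- if (length(kv) > 1) kv[2] else ""
    if (key == "cassette") { flush_cur(); cur <- list() }
    else if (key == "elements") cur$elements <- strsplit(val, ",")[[1]]
    else if (key == "ranges") cur$ranges <- strsplit(val, ",")[[1]]
    else if (key == "support") cur$support <- strsplit(val, ",")[[1]]
    else if (key == "quorum") cur$quorum <- as.integer(val)
    else if (key == "dist_var") cur$dist_var <- as.integer(val)
  }
  flush_cur()
  out
}

#' Write a gene network as GraphML and as an edge-list TSV
#'
#' @param graph an `igraph` graph (from [build_more_network()] etc.)
#' @param graphml_path output GraphML path (skipped when `NULL`)
#' @param edges_path output edge-list TSV path (skipped when `NULL`)
#' @return invisibly, the edge-list data.frame
#' @export
write_network <- function(graph, graphml_path = NULL, edges_path = NULL) {
  el <- if (igraph::ecount(graph) > 0) {
    e <- as.data.frame(igraph::as_edgelist(graph), stringsAsFactors = FALSE)
    names(e) <- c("gene_a", "gene_b")
    for (a in igraph::edge_attr_names(graph))
      e[[a]] <- igraph::edge_attr(graph, a)
    e
  } else data.frame(gene_a = character(), gene_b = character())
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  if (!is.null(edges_path)) write_tsv(el, edges_path)
  invisible(el)
}
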