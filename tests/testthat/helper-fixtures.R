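# Shared fixtures: small PWM library, planted-cassette promoter sets, and the
# 14-gene regulatory network fixture transcribed from the published MORE-set
# table (gene-list spellings; alias map applied to the table's variants).

# near-deterministic PWMs with distinct, non-palindromic consensi
test_pwms <- function() {
  mk <- function(id, consensus, p_major = 0.9) {
    bases <- strsplit(consensus, "")[[1]]
    m <- matrix((1 - p_major) / 3, nrow = length(bases), ncol = 4)
    code <- c(A = 1, C = 2, G = 3, T = 4)
    for (i in seq_along(bases)) m[i, code[[bases[i]]]] <- p_major
    pwm(id, m)
  }
  list(M_A = mk("M_A", "TGACTCAG"),
       M_B = mk("M_B", "CCAATGGC"),
       M_C = mk("M_C", "GGGACTTC"),
       M_D = mk("M_D", "ATTGCACT"))
}

# promoter set with a three-element cassette planted in a subset of carriers
planted_fixture <- function(n_promoters = 12, carriers = 1:3,
                            gaps = list(c(15, 25), c(20, 30)),
                            strands = c("+", "+", "-"), seed = 101,
                            promoter_length = 400) {
  pwms <- test_pwms()
  ids <- sprintf("gene%04d|promoter_1", seq_len(n_promoters))
  cas <- planted_cassette("planted",
                          elements = data.frame(pwm_id = c("M_A", "M_B", "M_C"),
                                                strand = strands),
                          gaps = gaps, carriers = ids[carriers])
  cfg <- promoter_sim_config(n_promoters, promoter_length = promoter_length,
                             planted_cassettes = list(cas), seed = seed)
  prom <- simulate_promoters(cfg, pwms)
  list(pwms = pwms, ids = ids, carriers = ids[carriers], prom = prom,
       scans = scan_promoters(prom$sequences, pwms, min_score = 0.9))
}

# published MORE-set table: 17 printed set rows over 14 unique genes
table3_fixture <- function() {
  rows <- list(
    c("AUC-mh", "MHS",   "Dtnbp1", "Golga3"),
    c("AUC-mh", "PZE",   "Asf1a", "Atp2a2"),
    c("AUC-mh", "XSSh",  "Dtnbp1", "Bbs5"),
    c("AUC-ml", "PSH",   "Dtnbp1", "Dpm2"),
    c("BM-fh",  "CFS",   "Dtnbp1", "Ggnbp2", "Slc2a2", "Bbs5", "Mrap2"),
    c("BM-mh",  "GEgE",  "Ggnbp2", "Cir1"),
    c("MR-mh",  "PBLS",  "Dtnbp1", "Ggnbp2", "Zranb1"),
    c("MR-ml",  "ASF",   "Dtnbp1", "Epha5"),
    c("RER-mh", "XEE",   "Epha5", "Ggnbp2"),
    c("RER-mh", "GSO",   "Epha5", "Rabl2"),
    c("RER-ml", "MHS",   "Slc2a2", "Bbs5"),
    c("TG-fh",  "XEgEg", "Dtnbp1", "Ggnbp2"),
    c("TG-fl",  "NSF",   "Epha5", "Ggnbp2"),
    c("VO2-mh", "XXCS",  "Epha5", "Zranb1"),
    c("VO2-mh", "XXLSS", "Epha5", "Slc2a2"),
    c("VO2-fh", "XCHS",  "Epha5", "Zranb1"),
    c("VO2-fl", "XSSSf", "Slc2a2", "Rabl2", "Cpe"))
  do.call(rbind, lapply(rows, function(r)
    data.frame(more_set = paste(r[1], r[2]), sub_phenotype = r[1],
               gene = r[-(1:2)], stringsAsFactors = FALSE)))
}

# independent brute-force PWM scanner: enumerate every window on both strands
brute_force_scan <- function(sequence, pw, min_score) {
  code <- c(A = 1, C = 2, G = 3, T = 4)
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- nrow(pw$matrix)
  maxsum <- sum(apply(pw$matrix, 1, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- list()
  for (s in seq_len(max(0, length(chars) - L + 1))) {
    win <- chars[s:(s + L - 1)]
    if (any(!win %in% names(code))) next
    sc_f <- sum(vapply(seq_len(L), function(i)
      pw$matrix[i, code[[win[i]]]], numeric(1))) / maxsum
    rc <- rev(comp[win])
    sc_r <- sum(vapply(seq_len(L), function(i)
      pw$matrix[i, code[[rc[i]]]], numeric(1))) / maxsum
    if (sc_f >= min_score)
      out[[length(out) + 1]] <- data.frame(start = s, strand = "+", score = sc_f)
    if (sc_r >= min_score)
      out[[length(out) + 1]] <- data.frame(start = s, strand = "-", score = sc_r)
  }
  if (!length(out)) return(data.frame(start = integer(), strand = character(),
                                      score = numeric()))
  do.call(rbind, out)
}

# independent brute-force cassette matcher: recursive enumeration of ordered
# match chains with per-gap distance windows
brute_force_match <- function(cassette, scans, promoter_id) {
  sub <- scans[scans$promoter_id == promoter_id, ]
  k <- nrow(cassette$elements)
  pos <- lapply(seq_len(k), function(i)
    sort(sub$start[sub$pwm_id == cassette$elements$pwm_id[i] &
                     sub$strand == cassette$elements$strand[i]]))
  recurse <- function(level, prev) {
    if (level > k) return(TRUE)
    for (p in pos[[level]]) {
      if (level == 1) {
        if (recurse(2, p)) return(TRUE)
      } else {
        d <- p - prev
        if (d >= cassette$ranges[level - 1, 1] &&
            d <= cassette$ranges[level - 1, 2] && recurse(level + 1, p))
          return(TRUE)
      }
    }
    FALSE
  }
  recurse(1, NA)
}

# random DNA of given GC content
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
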