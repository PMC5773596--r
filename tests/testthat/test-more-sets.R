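mk_cassette <- function(pwm_ids, strands, ranges, support) {
  structure(list(elements = data.frame(pwm_id = pwm_ids, strand = strands,
                                       stringsAsFactors = FALSE),
                 ranges = ranges, support = sort(support)),
            class = "more_cassette")
}

test_that("cassettes identical in elements and order collapse into one set", {
  c1 <- mk_cassette(c("A", "B", "C"), "+", rbind(c(10, 20), c(15, 25)),
                    c("p1", "p2", "p3"))
  c2 <- mk_cassette(c("A", "B", "C"), "+", rbind(c(12, 22), c(14, 20)),
                    c("p2", "p3", "p4"))
  sets <- build_more_sets(list(c1, c2), "TG-fh")
  expect_length(sets, 1)
  expect_setequal(sets[[1]]$support, c("p1", "p2", "p3", "p4"))
  expect_identical(sets[[1]]$phenotype_tag, "TG-fh")
})

test_that("one-mismatch merging requires >= 4 elements and > 80% overlap", {
  base_sup <- sprintf("p%02d", 1:10)
  abcd <- mk_cassette(c("A", "B", "C", "D"), "+",
                      rbind(c(10, 20), c(15, 25), c(12, 18)), base_sup)
  abfd_hi <- mk_cassette(c("A", "B", "F", "D"), "+",
                         rbind(c(10, 20), c(15, 25), c(12, 18)),
                         c(base_sup[1:9], "q1"))          # overlap 0.9
  abfd_lo <- mk_cassette(c("A", "B", "F", "D"), "+",
                         rbind(c(10, 20), c(15, 25), c(12, 18)),
                         c(base_sup[1:5], sprintf("q%d", 1:5)))  # overlap 0.5
  expect_length(build_more_sets(list(abcd, abfd_hi)), 1)
  expect_length(build_more_sets(list(abcd, abfd_lo)), 2)
  # three-element cassettes never merge on a mismatch
  abc <- mk_cassette(c("A", "B", "C"), "+", rbind(c(10, 20), c(15, 25)),
                     base_sup)
  abf <- mk_cassette(c("A", "B", "F"), "+", rbind(c(10, 20), c(15, 25)),
                     base_sup)
  expect_length(build_more_sets(list(abc, abf)), 2)
  # a single cassette gives a singleton set
  expect_length(build_more_sets(list(abcd)), 1)
})

test_that("set building is idempotent and order-invariant", {
  c1 <- mk_cassette(c("A", "B", "C", "D"), "+",
                    rbind(c(10, 20), c(15, 25), c(12, 18)), sprintf("p%d", 1:5))
  c2 <- mk_cassette(c("A", "B", "F", "D"), "+",
                    rbind(c(10, 20), c(15, 25), c(12, 18)), sprintf("p%d", 1:5))
  c3 <- mk_cassette(c("X", "Y", "Z"), "-", rbind(c(30, 40), c(30, 40)),
                    sprintf("r%d", 1:4))
  s_fwd <- build_more_sets(list(c1, c2, c3))
  s_rev <- build_more_sets(list(c3, c2, c1))
  expect_equal(length(s_fwd), length(s_rev))
  expect_identical(lapply(s_fwd, `[[`, "support"),
                   lapply(s_rev, `[[`, "support"))
})

test_that("matching respects order and finds opposite-strand readings", {
  fx <- planted_fixture(n_promoters = 8, carriers = 1:3, seed = 202)
  mined <- mine_cassettes(fx$scans[fx$scans$promoter_id %in% fx$carriers, ],
                          fx$carriers, mining_params())
  cas <- mined[[1]]
  lens <- setNames(nchar(fx$prom$sequences), names(fx$prom$sequences))
  # supporting promoters rescan positive
  hits <- match_cassette(cas, fx$scans, fx$ids, lens)
  expect_true(all(hits$hit[hits$promoter_id %in% cas$support]))
  # a promoter with the elements in reversed order does not hit (forward)
  rev_cas <- structure(list(elements = cas$elements[rev(seq_len(nrow(cas$elements))), ],
                            ranges = cas$ranges[rev(seq_len(nrow(cas$ranges))), ,
                                                drop = FALSE],
                            support = cas$support), class = "more_cassette")
  fwd_only <- match_cassette(rev_cas, fx$scans, fx$carriers,
                             both_orientations = FALSE)
  expect_false(any(fwd_only$hit))
  # reverse-complementing a carrier turns a forward hit into a mirrored one
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  seqs2 <- fx$prom$sequences
  seqs2[[fx$carriers[1]]] <- rc(seqs2[[fx$carriers[1]]])
  scans2 <- scan_promoters(seqs2, fx$pwms, min_score = 0.9)
  hits2 <- match_cassette(cas, scans2, fx$ids, lens)
  h <- hits2[hits2$promoter_id == fx$carriers[1], ]
  expect_true(h$hit)
  expect_identical(h$orientation, "mirrored")
})

test_that("match frequency on background promoters equals the brute-force oracle", {
  pwms <- test_pwms()
  set.seed(404)
  seqs <- setNames(vapply(1:50, function(i) random_dna(300), character(1)),
                   sprintf("bg%02d", 1:50))
  scans <- scan_promoters(seqs, pwms, min_score = 0.8)
  cas <- mk_cassette(c("M_A", "M_B"), c("+", "+"),
                     matrix(c(10, 60), nrow = 1), character(0))
  got <- match_cassette(cas, scans, names(seqs), both_orientations = FALSE)
  want <- vapply(names(seqs), function(p) brute_force_match(cas, scans, p),
                 logical(1))
  expect_identical(unname(got$hit), unname(want))
})

test_that("enrichment arithmetic and association flag follow the definition", {
  # direct arithmetic check through the public interface: construct scans in
  # which the cassette hits 50 of 1000 background promoters and 10 of the
  # 100-promoter test set
  ids <- sprintf("p%04d", 1:1000)
  hit_ids <- c(ids[1:10], ids[101:140])   # 10 in test set, 40 outside
  scans <- do.call(rbind, lapply(hit_ids, function(p)
    data.frame(promoter_id = p, pwm_id = c("M_A", "M_B"),
               start = c(10, 40), end = c(17, 47), strand = "+", score = 1)))
  cas <- mk_cassette(c("M_A", "M_B"), c("+", "+"),
                     matrix(c(20, 40), nrow = 1), character(0))
  res <- more_enrichment(cas, test_ids = ids[1:100], all_ids = ids,
                         scans = scans)
  expect_equal(res$background_count, 50)
  expect_equal(res$target_count, 10)
  expect_equal(res$expected, 5)
  expect_equal(res$ratio, 2)
  expect_true(res$associated)
  # test set = all promoters gives ratio exactly 1, not associated
  res_all <- more_enrichment(cas, test_ids = ids, all_ids = ids, scans = scans)
  expect_equal(res_all$ratio, 1)
  expect_false(res_all$associated)
  # zero background hits: undefined ratio, reported not associated
  empty <- more_enrichment(cas, test_ids = ids[1:100], all_ids = ids,
                           scans = scans[0, ])
  expect_true(is.na(empty$ratio))
  expect_false(empty$associated)
  # opposite-phenotype control set is evaluated alongside
  ctrl <- more_enrichment(cas, test_ids = ids[1:100], all_ids = ids,
                          scans = scans, control_ids = ids[901:1000])
  expect_equal(ctrl$control_ratio, 0)
})

test_that("planted-carrier test sets are enriched on the synthetic fixture", {
  fx <- planted_fixture(n_promoters = 20, carriers = 1:4, seed = 303)
  mined <- mine_cassettes(fx$scans[fx$scans$promoter_id %in% fx$carriers, ],
                          fx$carriers, mining_params())
  lens <- setNames(nchar(fx$prom$sequences), names(fx$prom$sequences))
  res <- more_enrichment(mined[[1]], test_ids = fx$carriers,
                         all_ids = fx$ids, scans = fx$scans,
                         promoter_lengths = lens)
  expect_gte(res$ratio, 2)
  expect_true(res$associated)
})

test_that("cassette text format round-trips bit-exactly", {
  fx <- planted_fixture(n_promoters = 8, carriers = 1:3, seed = 55)
  mined <- mine_cassettes(fx$scans[fx$scans$promoter_id %in% fx$carriers, ],
                          fx$carriers, mining_params())
  path <- withr::local_tempfile(fileext = ".txt")
  write_cassettes(mined, path)
  back <- read_cassettes(path)
  expect_equal(length(back), length(mined))
  for (i in seq_along(mined)) {
    expect_identical(back[[i]]$elements, mined[[i]]$elements)
    expect_equal(back[[i]]$ranges, mined[[i]]$ranges)
    expect_identical(back[[i]]$support, mined[[i]]$support)
  }
  # writing the parsed cassettes again reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_cassettes(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
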