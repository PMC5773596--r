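make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    out <- data.frame(mouse_id = r$id, gene = r$gene,
                      genotype = r$genotype %||% "mut",
                      zygosity = r$zygosity %||% "hom",
                      sex = r$sex, center = r$center %||% "C1",
                      stringsAsFactors = FALSE)
    for (p in metabolic_parameters()) out[[p]] <- r[[p]] %||% 1
    out$mean_body_mass <- r$mass %||% 25
    out
  }))
}
`%||%` <- phenomore:::`%||%`

test_that("strain deduplication prefers homozygotes, then both-sex genotypes", {
  rec <- make_records(
    list(id = "a1", gene = "G1", zygosity = "hom", sex = "f"),
    list(id = "a2", gene = "G1", zygosity = "het", sex = "f"),
    list(id = "b1", gene = "G2", zygosity = "het", sex = "f"),
    list(id = "b2", gene = "G2", zygosity = "het", sex = "m"))
  out <- dedupe_strains(rec)
  expect_identical(out$zygosity[out$gene == "G1"], "hom")
  expect_identical(sort(out$sex[out$gene == "G2"]), c("f", "m"))

  # single cohort passes unchanged
  one <- make_records(list(id = "c1", gene = "G3", sex = "f"))
  expect_identical(dedupe_strains(one)$mouse_id, "c1")

  # wild types are retained and flagged as reference strains
  wt <- make_records(list(id = "w1", gene = "WT", genotype = "wt",
                          zygosity = "wt", sex = "f"))
  expect_true(dedupe_strains(rbind(rec, wt))$reference_strain[1])
})

test_that("mass adjustment removes the body-mass correlation exactly", {
  set.seed(10)
  n <- 60
  mass <- rnorm(n, 28, 3)
  rec <- data.frame(mouse_id = sprintf("m%02d", 1:n), gene = "WT",
                    genotype = "wt", zygosity = "wt", sex = "m",
                    center = "C1", VO2 = 20 + 1.5 * mass + rnorm(n, 0, 2),
                    mean_body_mass = mass)
  adj <- adjust_mass_dependent(rec, "VO2")
  expect_lt(abs(cor(adj$VO2, adj$mean_body_mass)), 1e-10)
  # mean preserved (least-squares residuals sum to zero)
  expect_equal(mean(adj$VO2), mean(rec$VO2), tolerance = 1e-12)
  # idempotent
  adj2 <- adjust_mass_dependent(adj, "VO2")
  expect_equal(adj2$VO2, adj$VO2, tolerance = 1e-9)
  # slope exactly zero leaves values unchanged (residual + mean identity)
  flat <- rec
  flat$VO2 <- rep(55, n)
  flat$mean_body_mass <- rep(c(20, 30), n / 2)
  expect_equal(adjust_mass_dependent(flat, "VO2")$VO2, flat$VO2,
               tolerance = 1e-9)
  # a tiny stratum is skipped with a warning
  small <- rec[1:2, ]
  expect_warning(adjust_mass_dependent(small, "VO2"), "fewer than 3")
})

test_that("ratio table is the ratio of group means, filtered by cohort size", {
  mk <- function(gene, sex, tg, n, genotype = "mut") {
    do.call(rbind, lapply(seq_len(n), function(i)
      make_records(list(id = paste0(gene, sex, i), gene = gene,
                        genotype = genotype,
                        zygosity = if (genotype == "wt") "wt" else "hom",
                        sex = sex, TG = tg[i]))))
  }
  rec <- rbind(mk("G1", "f", rep(2, 7), 7),
               mk("G2", "f", rep(3, 4), 4),          # below min_group_size
               mk("WT", "f", rep(1, 10), 10, "wt"))
  rt <- compute_ratio_table(rec)
  expect_equal(rt$ratio[rt$gene == "G1" & rt$parameter == "TG"], 2)
  expect_false("G2" %in% rt$gene)
  rt4 <- compute_ratio_table(rec, min_group_size = 4)
  expect_equal(rt4$ratio[rt4$gene == "G2" & rt4$parameter == "TG"], 3)
  # identical mutants and wild types give ratio exactly 1
  expect_equal(rt$ratio[rt$gene == "G1" & rt$parameter == "BM"], 1)
})

test_that("rows with a zero wild-type mean are rejected with a record", {
  rec <- make_records(
    list(id = "m1", gene = "G1", sex = "f", TG = 2),
    list(id = "m2", gene = "G1", sex = "f", TG = 2),
    list(id = "w1", gene = "WT", genotype = "wt", zygosity = "wt",
         sex = "f", TG = 0))
  # force all WT parameter values to zero for the test
  for (p in metabolic_parameters()) rec[[p]][3] <- 0
  expect_warning(rt <- compute_ratio_table(rec, min_group_size = 2),
                 "rejected")
  expect_equal(nrow(rt), 0)
  expect_gt(nrow(attr(rt, "rejected")), 0)
})

test_that("qc bounds blank invalid values before averaging", {
  rec <- make_records(
    list(id = "m1", gene = "G1", sex = "f", VO2 = 100),
    list(id = "m2", gene = "G1", sex = "f", VO2 = 100),
    list(id = "m3", gene = "G1", sex = "f", VO2 = 1e6),  # invalid
    list(id = "w1", gene = "WT", genotype = "wt", zygosity = "wt",
         sex = "f", VO2 = 50),
    list(id = "w2", gene = "WT", genotype = "wt", zygosity = "wt",
         sex = "f", VO2 = 50))
  rt <- compute_ratio_table(rec, min_group_size = 2,
                            qc_bounds = list(VO2 = c(0, 1000)))
  expect_equal(rt$ratio[rt$parameter == "VO2"], 2)
  expect_equal(rt$n_mut[rt$parameter == "VO2"], 2)
})

test_that("sd thresholds are mean +/- 1.645 sd", {
  thr <- sd_thresholds(1.0, 0.1)
  expect_equal(unname(thr), c(0.8355, 1.1645))
  expect_equal(sd_thresholds(0, 1)[["upper"]], round(qnorm(0.95), 3),
               tolerance = 5e-4)
  expect_error(sd_thresholds(1, 0), "sd")
  expect_error(sd_thresholds(1, -1), "sd")
})

test_that("outlier calling flags exactly the strict percentile tails", {
  rt <- data.frame(gene = sprintf("G%03d", 1:100), parameter = "TG",
                   sex = "f", center = "C1", ratio = seq(0.5, 1.5, length = 100),
                   n_mut = 7, n_wt = 20)
  ol <- call_outliers(rt)
  lows <- ol$lists[ol$lists$tail == "low", ]
  highs <- ol$lists[ol$lists$tail == "high", ]
  expect_equal(nrow(lows), 5)
  expect_equal(nrow(highs), 5)
  expect_setequal(lows$gene, sprintf("G%03d", 1:5))
  expect_setequal(highs$gene, sprintf("G%03d", 96:100))
  # low and high lists are disjoint
  expect_length(intersect(lows$gene, highs$gene), 0)
})

test_that("massive ties at the cutoff never push the flag rate above 10%", {
  rt <- data.frame(gene = sprintf("G%02d", 1:20), parameter = "TG",
                   sex = "f", center = "C1",
                   ratio = c(rep(0.9, 10), rep(1.1, 10)),
                   n_mut = 7, n_wt = 20)
  ol <- call_outliers(rt, min_genes = 20)
  expect_lte(nrow(ol$lists) / 20, 0.10)
})

test_that("small ratio distributions are skipped with a warning", {
  rt <- data.frame(gene = sprintf("G%02d", 1:10), parameter = "RER",
                   sex = "m", center = "C1", ratio = runif(10, 0.9, 1.1),
                   n_mut = 7, n_wt = 20)
  expect_warning(ol <- call_outliers(rt), "fewer than")
  expect_equal(nrow(ol$lists), 0)
})

test_that("novelty annotation applies the sequential filters", {
  tabs <- list(
    mp = data.frame(gene = c("G1", "G5"), metabolic = c(TRUE, TRUE),
                    impc_sourced = c(FALSE, TRUE)),
    go = data.frame(gene = c("G2", "G3"),
                    domain = c("biological_process", "molecular_function"),
                    metabolic = c(TRUE, FALSE)),
    kegg = data.frame(gene = "G2", class = "Metabolism"))
  out <- annotate_novelty(c("G1", "G2", "G3", "G4", "G5"), tabs)
  expect_identical(unname(out["G1"]), "known-metabolic")   # MP metabolic
  expect_identical(unname(out["G2"]), "known-metabolic")   # GO/KEGG metabolic
  # molecular function only, no biological process: annotated but not metabolic
  expect_identical(unname(out["G3"]), "known-nonmetabolic")
  expect_identical(unname(out["G4"]), "unannotated")
  # screen-derived MP rows are excluded entirely, so G5 has no prior annotation
  expect_identical(unname(out["G5"]), "unannotated")
  # empty tables leave everything unannotated
  empty <- annotate_novelty(c("A", "B"), list())
  expect_true(all(empty == "unannotated"))
})
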