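test_that("the published MORE-set table yields a 14-gene network", {
  tab <- table3_fixture()
  net <- build_more_network(tab)
  expect_equal(igraph::vcount(net), 14)
  # Dtnbp1 and Golga3 share the AUC-mh MHS set
  eid <- igraph::get_edge_ids(net, c("Dtnbp1", "Golga3"))
  expect_gt(eid, 0)
  expect_match(igraph::E(net)$sub_phenotypes[eid], "AUC-mh")
  # connected components are computable and cover all nodes
  comp <- igraph::components(net)
  expect_equal(sum(comp$csize), 14)
  expect_true(max(comp$csize) >= 12)
})

test_that("network construction is undirected, self-edge free and order-invariant", {
  tab <- table3_fixture()
  net1 <- build_more_network(tab)
  set.seed(8)
  net2 <- build_more_network(tab[sample(nrow(tab)), ])
  expect_false(igraph::is_directed(net1))
  expect_equal(sum(igraph::which_loop(net1)), 0)
  el <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(el(net1), el(net2))
  # genes sharing no set produce no edges
  lonely <- data.frame(more_set = c("S1", "S2"), sub_phenotype = "TG-fh",
                       gene = c("Ga", "Gb"))
  expect_equal(igraph::ecount(build_more_network(lonely)), 0)
  # sharing a set under different sub-phenotypes does not connect
  split_phen <- data.frame(more_set = "S1", sub_phenotype = c("TG-fh", "TG-fl"),
                           gene = c("Ga", "Gb"))
  expect_equal(igraph::ecount(build_more_network(split_phen)), 0)
})

test_that("pathway mapping and the pathway network follow the membership table", {
  tab <- data.frame(gene = c("Ga", "Ga", "Gb", "Gc"),
                    pathway_id = c("mmu00010", "mmu04151", "mmu00010", "mmu04151"),
                    pathway_name = c("Glycolysis", "PI3K-Akt", "Glycolysis",
                                     "PI3K-Akt"),
                    class = c("Metabolism", "Signaling", "Metabolism",
                              "Signaling"))
  pw <- map_to_pathways(c("Ga", "Gb", "Gc", "Gd"), tab)
  expect_identical(pw$Ga, c("mmu00010", "mmu04151"))
  expect_identical(pw$Gd, character(0))
  metab <- map_to_pathways(c("Ga", "Gb", "Gc"), tab, class = "Metabolism")
  expect_identical(metab$Ga, "mmu00010")
  expect_identical(metab$Gc, character(0))
  expect_true(all(lengths(map_to_pathways(c("Ga", "Gb"), tab[0, ])) == 0))
  net <- build_pathway_network(c("Ga", "Gb", "Gc", "Gd"), tab)
  ekeys <- apply(igraph::as_edgelist(net), 1, function(r)
    paste(sort(r), collapse = "-"))
  expect_setequal(ekeys, c("Ga-Gb", "Ga-Gc"))
})

test_that("network overlay labels provenance and counts doubly supported edges", {
  tab <- table3_fixture()
  more_net <- build_more_network(tab)
  genes <- igraph::V(more_net)$name
  # pathway network sharing two of the MORE edges plus one new edge
  ptab <- data.frame(gene = c("Dtnbp1", "Golga3", "Epha5", "Ggnbp2",
                              "Cpe", "Mrap2"),
                     pathway_id = c("P1", "P1", "P2", "P2", "P3", "P3"),
                     pathway_name = "x", class = "Metabolism")
  path_net <- build_pathway_network(genes, ptab)
  ov <- overlay_networks(more_net, path_net)
  expect_equal(igraph::ecount(ov),
               length(union(
                 apply(igraph::as_edgelist(more_net), 1, function(r)
                   paste(sort(r), collapse = "-")),
                 apply(igraph::as_edgelist(path_net), 1, function(r)
                   paste(sort(r), collapse = "-")))))
  prov <- igraph::E(ov)$provenance
  expect_equal(igraph::graph_attr(ov, "n_both"), sum(prov == "both"))
  expect_equal(sum(prov == "both"), 2)  # Dtnbp1-Golga3 and Epha5-Ggnbp2
  # identical networks: everything both; disjoint: nothing both
  same <- overlay_networks(more_net, more_net)
  expect_true(all(igraph::E(same)$provenance == "both"))
  empty_net <- build_more_network(data.frame(more_set = character(),
                                             sub_phenotype = character(),
                                             gene = character()))
  disj <- overlay_networks(more_net, empty_net)
  expect_false(any(igraph::E(disj)$provenance == "both"))
})

test_that("prediction validation reproduces the printed cohort table", {
  genes <- sprintf("g%03d", 1:757)
  match_counts <- setNames(c(rep(1, 460), rep(0, 297)), genes)
  flags <- setNames(c(rep(TRUE, 150), rep(FALSE, 310),
                      rep(TRUE, 68), rep(FALSE, 229)), genes)
  res <- validate_prediction(match_counts, flags)
  expect_equal(unname(res$table[1, ]), c(150, 310))
  expect_equal(unname(res$table[2, ]), c(68, 229))
  expect_equal(res$prop_matched, 150 / 460, tolerance = 1e-12)
  expect_equal(res$prop_unmatched, 68 / 297, tolerance = 1e-12)
  expect_lt(abs(res$p_value - 0.004), 0.001)
})

test_that("equal proportions give Fisher p of exactly 1", {
  genes <- sprintf("g%03d", 1:200)
  mc <- setNames(c(rep(1, 100), rep(0, 100)), genes)
  fl <- setNames(rep(c(rep(TRUE, 10), rep(FALSE, 90)), 2), genes)
  expect_equal(validate_prediction(mc, fl)$p_value, 1)
})

test_that("fisher p equals full enumeration for small-margin tables", {
  # independent oracle: enumerate all tables with the observed margins and
  # sum the hypergeometric probabilities not exceeding the observed one
  fisher_enum <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    n <- r1 + r2
    p_obs <- dhyper(tab[1, 1], r1, r2, c1)
    tot <- 0
    for (a in max(0, c1 - r2):min(r1, c1)) {
      pa <- dhyper(a, r1, r2, c1)
      if (pa <= p_obs * (1 + 1e-7)) tot <- tot + pa
    }
    tot
  }
  set.seed(12)
  for (i in 1:20) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    genes <- sprintf("g%03d", seq_len(sum(tab)))
    mc <- setNames(rep(c(1, 0), rowSums(tab)), genes)
    fl <- setNames(c(rep(c(TRUE, FALSE), tab[1, ]),
                     rep(c(TRUE, FALSE), tab[2, ])), genes)
    res <- validate_prediction(mc, fl)
    expect_equal(res$p_value, fisher_enum(tab), tolerance = 1e-7)
  }
})

test_that("fisher p is symmetric under simultaneous row and column swaps", {
  genes <- sprintf("g%03d", 1:60)
  mc <- setNames(c(rep(1, 25), rep(0, 35)), genes)
  fl <- setNames(c(rep(TRUE, 18), rep(FALSE, 7), rep(TRUE, 12),
                   rep(FALSE, 23)), genes)
  p1 <- validate_prediction(mc, fl)$p_value
  # swap rows (matched <-> unmatched) and columns (phenotype <-> none)
  mc2 <- setNames(ifelse(mc >= 1, 0, 1), genes)
  fl2 <- setNames(!fl, genes)
  p2 <- validate_prediction(mc2, fl2)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_gt(p1, 0)
  expect_lte(p1, 1)
  # an empty stratum is an error
  expect_error(validate_prediction(setNames(rep(1, 5), genes[1:5]),
                                   fl[1:5]), "strata")
})
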