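test_that("the canonical 27-pattern enumeration is a bijection with the
           stated ordering rules", {
  tab <- response_type_table()
  expect_equal(nrow(tab), 27)
  expect_equal(anyDuplicated(tab$pattern), 0)
  expect_equal(anyDuplicated(tab$type_id), 0)
  expect_equal(tab$pattern[27], "SSS")
  expect_false(tab$changing[27])
  expect_true(all(tab$changing[1:26]))

  first_change <- function(s) min(which(strsplit(s, "")[[1]] != "S"))
  # sorted by earliest transition of change
  fc <- vapply(tab$pattern[1:26], first_change, 1)
  expect_true(all(diff(fc) >= 0))
  # complementary pairs adjacent, upregulation first
  for (i in seq(1, 25, by = 2)) {
    expect_equal(tab$pattern[i + 1], chartr("UD", "DU", tab$pattern[i]))
    expect_equal(substr(tab$pattern[i], fc[i], fc[i]), "U")
  }
  # the specific adjacency called out for mirrored triples
  i_usd <- match("USD", tab$pattern)
  expect_equal(tab$pattern[i_usd + 1], "DSU")
})

test_that("classification maps fold-change/significance matrices to states", {
  lfc <- rbind(g1 = c(2, -2, 0), g2 = c(0, 0, 0), g3 = c(2, 2, 2),
               g4 = c(1.2, -0.5, 0.4))
  padj <- rbind(g1 = c(1e-5, 1e-5, 0.9), g2 = c(0.5, 0.6, 0.9),
                g3 = c(1e-5, 1e-5, 1e-5), g4 = c(1e-5, 1e-5, 1e-5))
  prof <- classify_response(lfc, padj)
  expect_equal(prof$pattern, c("UDS", "SSS", "UUU", "USS"))
  expect_equal(prof$changing, c(TRUE, FALSE, TRUE, TRUE))
  # a temporary-upregulation gene lands in the up-at-ND-then-down type
  tab <- response_type_table()
  expect_equal(prof$type_id[1], tab$type_id[tab$pattern == "UDS"])
  # deterministic and equivariant under gene reordering
  prof2 <- classify_response(lfc[c(3, 1, 4, 2), ], padj[c(3, 1, 4, 2), ])
  expect_equal(prof2$pattern, prof$pattern[c(3, 1, 4, 2)])
  expect_error(classify_response(lfc[, 1:2], padj[, 1:2]), "3 transitions")
})

test_that("count_types partitions the changing genes", {
  lfc <- matrix(rep(c(2, 0, 0), each = 10), 10, 3)
  padj <- matrix(1e-6, 10, 3)
  prof <- classify_response(lfc, padj)
  ct <- count_types(prof)
  expect_equal(ct$n_types, 1)
  expect_equal(sum(ct$counts$n), 10)
  expect_equal(ct$counts$n[ct$counts$pattern == "USS"], 10)
  expect_equal(ct$n_changing, sum(prof$changing))
})

test_that("annotation hierarchies are built from paths with a partition", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    category_path = c("A/B", "A/C", "SOM/CAZyme/GH28"))
  h <- build_hierarchy(ann)
  expect_true(all(c("", "A", "A/B", "A/C") %in% h$nodes$path))
  expect_equal(h$genes$partition[h$genes$gene_id == "g3"], "SOM-interaction")
  expect_equal(h$genes$partition[h$genes$gene_id == "g1"], "metabolism")

  empty <- build_hierarchy(data.frame(gene_id = character(),
                                      category_path = character()))
  expect_equal(nrow(empty$genes), 0)
  expect_equal(empty$nodes$path, "")

  conflicting <- data.frame(gene_id = c("g1", "g1"),
                            category_path = c("A/B", "A/C"))
  expect_error(build_hierarchy(conflicting), "conflicting.*g1")

  # "null" paths mean unannotated
  h2 <- build_hierarchy(data.frame(gene_id = c("g1", "g2"),
                                   category_path = c("A/B", "null")))
  expect_equal(h2$genes$gene_id, "g1")
})

test_that("annotation-guided clustering groups correlated profiles", {
  ann <- data.frame(gene_id = c("a", "b", "c"),
                    category_path = "SOM/CAZyme/GH28")
  h <- build_hierarchy(ann)
  prof <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  cl <- cluster_genes(prof, h)
  expect_equal(cl$cluster_id[1], cl$cluster_id[2])   # r = 1
  expect_false(cl$cluster_id[1] == cl$cluster_id[3]) # r = -1
  expect_error(cluster_genes(rbind(x = 1:4), h), "unannotated")
})

test_that("clustering recovers seeded profile groups within a node", {
  skip_if_not_installed("mclust")
  set.seed(41)
  # pairwise profile correlations all below 0.6, well clear of the 0.8
  # linkage threshold
  shapes <- rbind(c(0, 2, 4, 6), c(6, 4, 2, 0), c(0, 4, 0, 4),
                  c(4, 0, 4, 0), c(0, 6, 0, 0))
  genes <- sprintf("g%02d", 1:50)
  truth <- rep(1:5, each = 10)
  prof <- shapes[truth, ] + matrix(rnorm(200, 0, 0.15), 50, 4)
  rownames(prof) <- genes
  h <- build_hierarchy(data.frame(gene_id = genes,
                                  category_path = "SOM/peptidase/A01"))
  cl <- cluster_genes(prof, h, corr_threshold = 0.8)
  ari <- mclust::adjustedRandIndex(cl$cluster_id, truth)
  expect_gt(ari, 0.8)
})

test_that("permutation p values hit the formula endpoint on a strongly
           enriched cohort", {
  set.seed(42)
  meta <- make_meta()
  lib <- exp(runif(12, log(0.5), log(2)))
  # 40 SOM-interaction genes seeded with a strictly monotone pattern, in a
  # majority-null background (median-of-ratios normalisation assumes most
  # genes unchanged).  A monotone pattern is only reproduced by the
  # identity permutation of time labels, so the observed count exceeds
  # every null draw and the p value hits the formula endpoint.
  tpl <- rbind(
    data.frame(gene_id = sprintf("som%02d", 1:40), pattern = "UUU",
               lfc_magnitude = 2, base_mean = 500, dispersion = 0.02,
               category_path = "SOM/CAZyme/GH28"),
    data.frame(gene_id = sprintf("met%03d", 1:160), pattern = "SSS",
               lfc_magnitude = 0, base_mean = 500, dispersion = 0.02,
               category_path = "MET/energy/TCA"))
  sim <- simulate_counts(sim_design(seed = 42), tpl, seed = 42)
  h <- build_hierarchy(tpl[c("gene_id", "category_path")])
  res <- permutation_test(sim$counts, sim$metadata, h, B = 999, seed = 1)
  row <- res$table[res$table$pattern == "UUU", ]
  expect_equal(row$observed_som, 40)
  expect_equal(row$p, 1 / 1000)  # observed count exceeds every null draw
  expect_lte(row$p, 0.01)
  expect_error(permutation_test(sim$counts, sim$metadata, h, B = 10),
               "B must be >= 19")
})

test_that("the hypergeometric alternative gives a closed-form enrichment p", {
  set.seed(43)
  tpl <- rbind(
    data.frame(gene_id = sprintf("som%02d", 1:30), pattern = "USS",
               lfc_magnitude = 2, base_mean = 500, dispersion = 0.02,
               category_path = "SOM/CAZyme/GH28"),
    data.frame(gene_id = sprintf("met%03d", 1:120), pattern = "SSS",
               lfc_magnitude = 0, base_mean = 500, dispersion = 0.02,
               category_path = "MET/energy/TCA"))
  sim <- simulate_counts(sim_design(seed = 43), tpl, seed = 43)
  h <- build_hierarchy(tpl[c("gene_id", "category_path")])
  res <- permutation_test(sim$counts, sim$metadata, h,
                          statistic = "hypergeom")
  row <- res$table[res$table$pattern == "USS", ]
  expect_equal(row$p,
               phyper(row$observed_som - 1, 30, 120, row$n, lower.tail = FALSE))
  expect_lt(row$p, 0.01)
})

test_that("the full chain recovers seeded response types gene by gene", {
  d <- sim_design(seed = 12)
  tpl <- gene_templates(seed = 12)
  sim <- simulate_counts(d, tpl, seed = 12)
  prof <- response_profiles(sim$counts, sim$metadata)$profiles
  tg <- tpl$pattern != "SSS"
  expect_gte(mean(prof$pattern[tg] == tpl$pattern[tg]), 0.95)
  expect_equal(count_types(prof)$n_types, 15)
})
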