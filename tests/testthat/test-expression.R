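test_that("median-of-ratios size factors behave on worked examples", {
  m <- matrix(c(10, 20, 5, 10, 20, 5), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10, 20, 5), b = 2 * c(10, 20, 5))
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[2] / sf2[1]), 2)

  # worked 3 x 2 matrix: every per-gene ratio is 1/sqrt(2) or sqrt(2)
  m3 <- matrix(c(100, 10, 1000, 200, 20, 2000), 3, 2)
  expect_equal(unname(size_factors(m3)), c(1 / sqrt(2), sqrt(2)))

  mz <- matrix(c(0, 5, 3, 0), 2, 2)
  expect_error(size_factors(mz), "pseudo_reference")
  expect_silent(size_factors(mz, pseudo_reference = TRUE))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(10)
  p <- runif(200)
  q <- adjust_bh(p)
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_error(adjust_bh(c(0.1, 1.2)), "in \\[0, 1\\]")
})

test_that("time-course LRT keeps its type-I error near nominal", {
  set.seed(31)
  meta <- make_meta()
  cn <- make_null_counts(2000, meta, mu = 100, alpha = 0.1)
  tc <- test_time_course(cn, meta)
  rej <- mean(tc$p < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("time-course LRT detects an 8-fold step with high power", {
  set.seed(32)
  meta <- make_meta()
  lib <- exp(runif(12, log(0.5), log(2)))
  cn <- make_null_counts(1800, meta, mu = 100, alpha = 0.1, lib = lib)
  mu_alt <- ifelse(meta$time_point == "t1", 100, 800)
  ca <- sapply(seq_len(12), function(j) {
    rnbinom(200, mu = mu_alt[j] * lib[j], size = 1 / 0.1)
  })
  rownames(ca) <- paste0("alt", 1:200)
  cc <- rbind(cn, ca)
  colnames(cc) <- meta$sample_id
  tc <- test_time_course(cc, meta)
  expect_gt(mean(tc$p[1801:2000] < 0.01), 0.9)
  # empirical FDR among time-DEG calls stays near the nominal 1%
  called <- sum(tc$time_deg)
  false_called <- sum(tc$time_deg[1:1800])
  expect_lte(false_called / max(called, 1), 2 * 0.01 + 2 / called)
})

test_that("a constant noiseless gene is never called", {
  meta <- make_meta()
  cn <- matrix(50L, 3, 12, dimnames = list(paste0("g", 1:3), meta$sample_id))
  tc <- test_time_course(cn, meta)
  expect_true(all(tc$p > 0.99))
  z <- matrix(0L, 2, 12, dimnames = list(c("z1", "z2"), meta$sample_id))
  tcz <- test_time_course(rbind(cn, z), meta)
  expect_false(any(tcz$testable[4:5]))
  expect_equal(tcz$p[4:5], c(1, 1))
})

test_that("pairwise Wald estimates fold-changes with small bias", {
  set.seed(33)
  meta <- make_meta()
  lib <- exp(runif(12, log(0.5), log(2)))
  cn <- make_null_counts(1500, meta, mu = 300, alpha = 0.05, lib = lib)
  mu_alt <- ifelse(meta$time_point == "t2", 2000, 1000)
  ca <- sapply(seq_len(12), function(j) {
    rnbinom(300, mu = mu_alt[j] * lib[j], size = 1 / 0.05)
  })
  rownames(ca) <- paste0("alt", 1:300)
  cc <- rbind(cn, ca)
  colnames(cc) <- meta$sample_id
  pw <- test_pairwise(cc, meta, "t2", "t1")
  expect_lt(abs(mean(pw$lfc[1501:1800]) - 1), 0.2)
  # null genes: p approximately uniform
  expect_lt(abs(mean(pw$p[1:1500]) - 0.5), 0.05)
  rej <- mean(pw$p[1:1500] < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.08)
})

test_that("genes absent from one group get finite fold-changes", {
  meta <- make_meta()
  cn <- matrix(50L, 3, 12, dimnames = list(paste0("g", 1:3), meta$sample_id))
  only_t2 <- ifelse(meta$time_point == "t2", 80L, 0L)
  cc <- rbind(cn, matrix(only_t2, 1, dimnames = list("onset", NULL)))
  pw <- test_pairwise(cc, meta, "t2", "t1")
  expect_true(all(is.finite(pw$lfc)))
  expect_gt(pw$lfc[4], 1)
  both_zero <- rbind(cc, matrix(0L, 1, 12, dimnames = list("dead", NULL)))
  pw2 <- test_pairwise(both_zero, meta, "t2", "t1")
  expect_false(pw2$testable[5])
  expect_equal(pw2$p[5], 1)
})

test_that("DE calls are stable under a sample-level scaling absorbed by the
           size factors", {
  set.seed(34)
  meta <- make_meta()
  lib <- exp(runif(12, log(0.5), log(2)))
  cn <- make_null_counts(1500, meta, mu = 200, alpha = 0.05, lib = lib)
  mu_alt <- ifelse(meta$time_point == "t1", 100, 800)
  ca <- sapply(seq_len(12), function(j) {
    rnbinom(100, mu = mu_alt[j] * lib[j], size = 1 / 0.05)
  })
  rownames(ca) <- paste0("alt", 1:100)
  cc <- rbind(cn, ca)
  colnames(cc) <- meta$sample_id
  cc2 <- cc
  cc2[, 3] <- cc2[, 3] * 3L
  # the scale moves into the size factors: the tripled column's factor
  # grows by 3^(11/12) and the others shrink by 3^(-1/12) (the per-gene
  # geometric means absorb 3^(1/12)), leaving the normalised matrix
  # proportional to the original
  sf1 <- size_factors(cc)
  sf2 <- size_factors(cc2)
  expect_equal(unname(sf2[3] / sf1[3]), 3^(11 / 12), tolerance = 1e-10)
  x1 <- sweep(cc, 2, sf1, "/")
  x2 <- sweep(cc2, 2, sf2, "/")
  expect_equal(x2, 3^(1 / 12) * x1, tolerance = 1e-10)
  # DE calls agree (the raw-count NB likelihood is not exactly
  # scale-equivariant, so borderline genes may flip, but every seeded
  # signal gene and virtually all null genes are called identically)
  tc1 <- test_time_course(cc, meta)
  tc2 <- test_time_course(cc2, meta)
  sig <- grepl("^alt", tc1$gene_id)
  expect_identical(tc1$time_deg[sig], tc2$time_deg[sig])
  expect_gte(mean(tc1$time_deg == tc2$time_deg), 0.995)
})

test_that("onset-gene selection applies all three filters and recovers
           seeded onset genes", {
  set.seed(35)
  meta <- make_meta()
  lib <- exp(runif(12, log(0.5), log(2)))
  base <- exp(runif(4950, log(10), log(1000)))
  cn <- sapply(seq_len(12), function(j) {
    rnbinom(4950, mu = base * lib[j], size = 1 / 0.05)
  })
  rownames(cn) <- sprintf("null%04d", 1:4950)
  mu_on <- ifelse(meta$time_point == "t2", 4000, 1000)
  on <- sapply(seq_len(12), function(j) {
    rnbinom(50, mu = mu_on[j] * lib[j], size = 1 / 0.05)
  })
  rownames(on) <- sprintf("onset%02d", 1:50)
  cc <- rbind(cn, on)
  colnames(cc) <- meta$sample_id
  sf <- size_factors(cc, pseudo_reference = TRUE)
  de <- test_pairwise(cc, meta, "t2", "t1", sf = sf)
  expr_t2 <- de$mean_tx
  names(expr_t2) <- de$gene_id
  sel <- select_onset_genes(de, expr_t2, total_counts = rowSums(cc))
  expect_true(all(sprintf("onset%02d", 1:50) %in% sel))
  expect_lt(sum(!grepl("^onset", sel)), 5)

  # the three filters individually
  fake_de <- data.frame(gene_id = c("a", "b", "c"),
                        lfc = c(2, 0.5, 2), p_adj = c(1e-5, 1e-5, 0.5))
  expr <- c(a = 1000, b = 1000, c = 1000)
  universe <- c(expr, setNames(rep(1, 97), paste0("u", 1:97)))
  sel2 <- select_onset_genes(fake_de, universe[1:3],
                             total_counts = universe)
  expect_identical(sel2, "a")
  expect_error(select_onset_genes(fake_de, expr,
                                  total_counts = c(x = 0)), "empty gene universe")
})
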