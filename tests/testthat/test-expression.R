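nb_matrix <- function(n_genes, n_cells, seed, mu = 50, size = 5) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = size),
              nrow = n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_cells))))
  storage.mode(m) <- "integer"
  m
}

test_that("size factors obey the scaling identities", {
  base <- nb_matrix(200, 4, seed = 1)
  doubled <- base
  doubled[, 2] <- base[, 1] * 2L  # sample 2 is an exact doubling of sample 1
  sf <- size_factor_normalize(count_matrix(doubled))$size_factors
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  # all-equal samples -> unit size factors
  eqm <- matrix(rep(base[, 1], 4), ncol = 4,
                dimnames = list(rownames(base), sprintf("s%d", 1:4)))
  expect_equal(unname(size_factor_normalize(count_matrix(eqm))$size_factors),
               rep(1, 4), tolerance = 1e-12)
  # scale-equivariance: multiplying sample 3 by c multiplies its size factor
  # relative to every other sample by c, exactly
  sf0 <- size_factor_normalize(count_matrix(base))$size_factors
  scaled <- base; scaled[, 3] <- scaled[, 3] * 5L
  sf5 <- size_factor_normalize(count_matrix(scaled))$size_factors
  expect_equal(unname(sf5[3] / sf5[1]), unname(5 * sf0[3] / sf0[1]),
               tolerance = 1e-9)
  expect_equal(unname(sf5[3] / sf5[4]), unname(5 * sf0[3] / sf0[4]),
               tolerance = 1e-9)
})

test_that("size factors match the median-of-ratios formula recomputed directly", {
  counts <- nb_matrix(300, 6, seed = 2)
  sf <- size_factor_normalize(count_matrix(counts))$size_factors
  # independent recomputation from the definition
  keep <- apply(counts > 0, 1, all)
  geo <- exp(rowMeans(log(counts[keep, ])))
  raw <- apply(counts[keep, ], 2, function(col) median(col / geo))
  oracle <- raw / exp(mean(log(raw)))
  expect_equal(unname(sf), unname(oracle), tolerance = 1e-12)
})

test_that("size factors agree with DESeq2's estimator up to rescaling", {
  counts <- nb_matrix(500, 8, seed = 3)
  sf <- size_factor_normalize(count_matrix(counts))$size_factors
  ds <- DESeq2::estimateSizeFactorsForMatrix(counts)
  # DESeq2 medians in log space; with an even reference-set size the two
  # middle values are averaged on different scales, hence the loose tolerance
  expect_equal(unname(sf / sf[1]), unname(ds / ds[1]), tolerance = 1e-4)
})

test_that("sparse matrices fall back to the positive-count estimator", {
  counts <- nb_matrix(200, 10, seed = 4, mu = 3, size = 1)
  counts[counts < 1] <- 0L
  # force at least one zero in every gene
  counts[cbind(seq_len(nrow(counts)),
               rep_len(seq_len(ncol(counts)), nrow(counts)))] <- 0L
  expect_error(size_factor_normalize(count_matrix(counts), fallback = FALSE),
               "fallback")
  m <- size_factor_normalize(count_matrix(counts), min_prop = 0.5)
  expect_true(all(m$size_factors > 0))
})

test_that("BH adjustment equals the step-up oracle and caps type I error", {
  set.seed(11)
  p <- runif(500)^1.3
  expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  # identical groups (copied cells): nothing can be significant
  base <- nb_matrix(300, 6, seed = 5)
  copied <- cbind(base, base)
  colnames(copied) <- sprintf("s%02d", 1:12)
  m <- count_matrix(copied, groups = rep(c("a", "b"), each = 6))
  de <- de_test(m, c("b", "a"))
  expect_identical(sum(de$padj < 0.05, na.rm = TRUE), 0L)
})

test_that("a strong planted shift is the top-ranked gene", {
  set.seed(21)
  counts <- nb_matrix(400, 200, seed = 21)
  counts["g0001", 101:200] <- as.integer(
    rnbinom(100, mu = 50 * 2^5, size = 5))
  m <- count_matrix(counts, groups = rep(c("ctrl", "clone"), each = 100))
  de <- de_test(m, c("clone", "ctrl"))
  expect_identical(de$gene[1], "g0001")
  expect_lt(de$padj[1], 1e-6)
  expect_gt(de$log2fc[de$gene == "g0001"], 3)
  expect_error(de_test(m, c("clone", "nope")), "at least 3")
})

test_that("top-k pooling performs exact set arithmetic", {
  fake_de <- function(genes, lfc) {
    n <- length(genes)
    structure(data.frame(gene = genes, base_mean = 10, log2fc = lfc,
                         stat = 5, pvalue = seq(1e-10, 1e-3, length.out = n),
                         padj = seq(1e-8, 1e-2, length.out = n),
                         stringsAsFactors = FALSE),
              class = c("de_result", "data.frame"))
  }
  up <- function(tag) sprintf("%s_up%02d", tag, 1:30)
  dn <- function(tag) sprintf("%s_dn%02d", tag, 1:30)
  disjoint <- list(fake_de(c(up("a"), dn("a")), rep(c(1, -1), each = 30)),
                   fake_de(c(up("b"), dn("b")), rep(c(1, -1), each = 30)),
                   fake_de(c(up("c"), dn("c")), rep(c(1, -1), each = 30)))
  expect_identical(length(select_top_de(disjoint, k = 30)), 180L)
  identical3 <- disjoint[c(1, 1, 1)]
  expect_identical(length(select_top_de(identical3, k = 30)), 60L)
  # constructed overlap: contrasts share 10 up genes
  shared <- up("a")[1:10]
  partial <- list(disjoint[[1]],
                  fake_de(c(shared, up("d")[1:20], dn("d")),
                          rep(c(1, -1), c(30, 30))))
  expect_identical(length(select_top_de(partial, k = 30)),
                   length(unique(c(up("a"), dn("a"), shared, up("d")[1:20],
                                   dn("d")))))
  # p_cut filters before ranking
  weak <- fake_de(up("w"), rep(1, 30))
  weak$pvalue <- rep(0.5, 30)
  expect_identical(length(select_top_de(list(weak), k = 30)), 0L)
})

test_that("K-means recovers well-separated groups and is seed-stable", {
  set.seed(31)
  n <- 60
  counts <- nb_matrix(50, n, seed = 31)
  counts[1:10, 31:60] <- as.integer(rnbinom(300, mu = 50 * 2^4, size = 5))
  m <- count_matrix(counts)
  truth <- rep(c(1, 2), each = 30)
  fit <- kmeans_cluster(m, rownames(counts)[1:20], k = 2, seed = 1)
  expect_equal(ari(fit$assignment, truth), 1)
  fit2 <- kmeans_cluster(m, rownames(counts)[1:20], k = 2, seed = 1)
  expect_identical(fit$assignment, fit2$assignment)
  one <- kmeans_cluster(m, rownames(counts)[1:20], k = 1, seed = 1)
  expect_identical(unname(unique(one$assignment)), 1L)
  expect_error(kmeans_cluster(m, rownames(counts)[1:20], k = n + 1), "exceeds")
})

test_that("marker phenotype flags reflect planted shifts and recompute", {
  cfg <- simulation_config(n_cells = 120, clone_fraction = 0.5, n_genes = 60,
                           seed = 33, heavy_chain = FALSE)
  co <- simulate_repertoire(cfg, shared_ref)
  m <- simulate_expression(cfg, co)
  m$groups <- ifelse(co$cells$is_clone, "clone", "control")
  ph <- marker_phenotype(m)
  expect_true(ph$group_flags$clone[["cd19_negative"]])
  expect_true(ph$group_flags$clone[["hladr_low"]])
  expect_true(ph$group_flags$clone[["cd38_low"]])
  # flags recomputable from stored means and margin
  recomputed <- sweep(ph$means["clone", , drop = FALSE], 2,
                      ph$means["control", ] - ph$margin, "<")
  expect_identical(ph$flags["clone", ], recomputed["clone", ])
  # no effects -> no flags
  cfg0 <- simulation_config(n_cells = 120, clone_fraction = 0.5, n_genes = 60,
                            marker_effects = c(), seed = 34,
                            heavy_chain = FALSE)
  co0 <- simulate_repertoire(cfg0, shared_ref)
  m0 <- simulate_expression(cfg0, co0)
  m0$groups <- ifelse(co0$cells$is_clone, "clone", "control")
  ph0 <- marker_phenotype(m0)
  expect_false(any(ph0$flags))
  # absent markers are reported, not fatal
  small <- count_matrix(nb_matrix(5, 6, seed = 1),
                        groups = rep(c("control", "clone"), 3))
  expect_error(marker_phenotype(small), "none of the marker")
})

test_that("a fully open gate recovers everything at baseline purity", {
  cfg <- simulation_config(n_cells = 200, clone_fraction = 0.2, n_genes = 40,
                           seed = 35, heavy_chain = FALSE)
  co <- simulate_repertoire(cfg, shared_ref)
  m <- simulate_expression(cfg, co)
  g <- gate_clones_by_markers(m, truth = co$cells$is_clone,
                              thresholds = c(cd19 = Inf, hladr = Inf))
  expect_equal(g$recall, 1)
  expect_equal(g$purity, 0.2, tolerance = 1e-12)
  expect_identical(g$n_gated, 200L)
  # impossible gate warns and reports NA purity
  expect_warning(
    g0 <- gate_clones_by_markers(m, truth = co$cells$is_clone,
                                 thresholds = c(cd19 = -Inf, hladr = -Inf)),
    "zero cells")
  expect_identical(g0$n_gated, 0L)
  expect_true(is.na(g0$purity))
})
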