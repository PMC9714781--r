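test_that("a fixed seed fully determines every generator output", {
  cfg <- simulation_config(n_cells = 30, seed = 17, n_genes = 50,
                           bulk_read_depth = 1000)
  a <- simulate_cohort(cfg, shared_ref)
  b <- simulate_cohort(cfg, shared_ref)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$bulk$reads, b$bulk$reads)
  expect_identical(a$truth, b$truth)
})

test_that("planted clone size follows the rounding rule exactly", {
  for (case in list(c(100, 0.2, 20), c(60, 0.02, 1), c(59, 0.017, 1),
                    c(50, 0, 0), c(10, 1, 10))) {
    cfg <- simulation_config(n_cells = case[1], clone_fraction = case[2],
                             seed = 3, heavy_chain = FALSE)
    co <- simulate_repertoire(cfg, shared_ref)
    expect_identical(sum(co$cells$is_clone), as.integer(case[3]))
  }
})

test_that("no planted clone means no shared keys; full clone means identical cells", {
  cfg0 <- simulation_config(n_cells = 50, clone_fraction = 0,
                            per_base_error_rate = 0, heavy_chain = FALSE,
                            seed = 23)
  co0 <- simulate_repertoire(cfg0, shared_ref)
  keys <- paste(co0$cells$v_call, co0$cells$j_call, co0$cells$cdr3_nt)
  expect_identical(anyDuplicated(keys), 0L)
  cfg1 <- simulation_config(n_cells = 20, clone_fraction = 1,
                            per_base_error_rate = 0, seed = 23)
  co1 <- simulate_repertoire(cfg1, shared_ref)
  txs <- vapply(co1$transcripts, paste, "", collapse = "+")
  expect_identical(length(unique(txs)), 1L)
})

test_that("planted substitutions sit at the configured IMGT codons before error", {
  subs <- poems_substitutions("IGLV1-44*01")
  cfg <- simulation_config(n_cells = 4, clone_fraction = 1,
                           per_base_error_rate = 0, heavy_chain = FALSE,
                           seed = 31)
  co <- simulate_repertoire(cfg, shared_ref)
  vseg <- shared_ref[["IGLV1-44*01"]]
  tx <- co$transcripts[[1]][["tx1"]]
  imgt <- seg_imgt_positions(vseg)
  for (r in seq_len(nrow(subs))) {
    idx <- match(subs$position[r], imgt)
    codon <- substr(tx, 3 * idx - 2, 3 * idx)
    expect_identical(translate_dna(codon), subs$mutant[r])
  }
  # germline residues elsewhere are untouched
  aa_tx <- translate_dna(substr(tx, 1, nchar(seg_ungapped(vseg))))
  aa_germ <- translate_dna(seg_ungapped(vseg))
  expect_identical(sum(strsplit(aa_tx, "")[[1]] != strsplit(aa_germ, "")[[1]]),
                   2L)
})

test_that("marker effects shift clone means in the planted direction", {
  cfg <- simulation_config(n_cells = 500, clone_fraction = 0.5,
                           marker_effects = c(CD19 = -5), n_genes = 20,
                           seed = 41, heavy_chain = FALSE)
  co <- simulate_repertoire(cfg, shared_ref)
  m <- simulate_expression(cfg, co)
  clone <- co$cells$is_clone
  expect_lt(mean(m$counts["CD19", clone]), mean(m$counts["CD19", !clone]))
  # ratio of group means near 2^-5 (generous Monte-Carlo band)
  ratio <- mean(m$counts["CD19", clone]) / mean(m$counts["CD19", !clone])
  expect_lt(ratio, 2^-3)
  # null marker: groups exchangeable
  expect_equal(mean(m$counts["CD38", clone]), mean(m$counts["CD38", !clone]),
               tolerance = 0.15)
})

test_that("marker genes absent from the index are a configuration error", {
  cfg <- simulation_config(n_cells = 10, marker_effects = c(NOPE = -2),
                           n_genes = 20, seed = 1, heavy_chain = FALSE)
  co <- simulate_repertoire(cfg, shared_ref)
  expect_error(simulate_expression(cfg, co), "NOPE")
})

test_that("bulk clonal read counts follow binomial sampling around the truth", {
  cfg <- simulation_config(n_cells = 100, clone_fraction = 0.5,
                           bulk_read_depth = 10000, seed = 53,
                           heavy_chain = FALSE)
  co <- simulate_repertoire(cfg, shared_ref)
  bulk <- simulate_bulk_reads(cfg, co)
  n_clonal <- sum(bulk$is_clonal)
  sd3 <- 3 * sqrt(10000 * 0.5 * 0.5)
  expect_lt(abs(n_clonal - 5000), sd3)
  # no clone planted -> no reads carry the planted junction
  cfg0 <- simulation_config(n_cells = 50, clone_fraction = 0,
                            bulk_read_depth = 1000, seed = 54,
                            heavy_chain = FALSE)
  co0 <- simulate_repertoire(cfg0, shared_ref)
  bulk0 <- simulate_bulk_reads(cfg0, co0)
  expect_identical(sum(grepl(co0$truth$clonotype$junction, bulk0$reads,
                             fixed = TRUE)), 0L)
  expect_error(simulate_bulk_reads(
    simulation_config(bulk_read_depth = 10, seed = 1), co0), "1000")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(clone_fraction = 1.2), "clone_fraction")
  expect_error(simulation_config(per_base_error_rate = 0.2), "error_rate")
  expect_error(simulation_config(cdr3_length = 2), "cdr3_length")
  expect_error(simulation_config(seed = 2^33), "seed")
})

test_that("doublet merging plants a second light chain and is recorded", {
  cfg <- simulation_config(n_cells = 20, clone_fraction = 0.5,
                           doublet_rate = 0.2, per_base_error_rate = 0,
                           heavy_chain = FALSE, seed = 61)
  co <- simulate_repertoire(cfg, shared_ref)
  expect_identical(sum(co$cells$doublet), 4L)
  dbl <- co$cells$barcode[co$cells$doublet][1]
  expect_gte(length(co$transcripts[[dbl]]), 2L)
})

test_that("cohort files round-trip losslessly", {
  cfg <- simulation_config(n_cells = 12, seed = 71, n_genes = 30,
                           bulk_read_depth = 1000)
  co <- simulate_cohort(cfg, shared_ref)
  dir <- tempfile()
  write_cohort(co, dir)
  cells <- read_cell_fasta(file.path(dir, "cells.fasta"))
  expect_identical(lapply(cells, unname), lapply(co$transcripts, unname))
  expect_identical(names(cells[[1]]), names(co$transcripts[[1]]))
  counts <- read_counts_tsv(file.path(dir, "counts.tsv"))
  expect_identical(counts$counts, co$counts$counts)
  mm <- read_counts_mtx(file.path(dir, "counts"))
  expect_identical(mm$counts, co$counts$counts)
  reads <- read_bulk_fastq(file.path(dir, "bulk.fastq"))
  expect_identical(unname(reads), unname(co$bulk$reads))
  cfg2 <- read_config_yaml(file.path(dir, "config.yaml"))
  expect_identical(cfg2$seed, cfg$seed)
  expect_identical(cfg2$planted_substitutions, cfg$planted_substitutions)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_identical(truth$barcode, co$cells$barcode)
  expect_identical(truth$is_clone, co$cells$is_clone)
})
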