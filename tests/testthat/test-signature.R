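make_profile <- function(v_call = "IGLV1-44*01", j_call = "IGLJ3*02",
                         subs = data.frame(position = integer(),
                                           germline = character(),
                                           observed = character()),
                         covered = 1:104, cell_id = "c1") {
  structure(list(cell_id = cell_id, locus = "IGL", v_call = v_call,
                 j_call = j_call, substitutions = subs,
                 covered = as.integer(covered)),
            class = "substitution_profile")
}

sub_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(position = as.integer(m[, 1]), germline = m[, 2],
             observed = m[, 3], stringsAsFactors = FALSE)
}

test_that("the canonical family substitutions are called positive", {
  # IGLV1-44: T38P with Asn at 40
  p44 <- make_profile(subs = sub_df(38, "T", "P", 40, "H", "N"))
  expect_true(classify_poems_signature(p44)$verdict)
  # IGLV1-47: Y38P, Y40N
  p47 <- make_profile("IGLV1-47*01",
                      subs = sub_df(38, "Y", "P", 40, "Y", "N"))
  call47 <- classify_poems_signature(p47)
  expect_true(call47$verdict)
  expect_true(call47$pos38_nonpolar && call47$pos40_asn)
  # IGLV1-40: D38G, H40N
  p40 <- make_profile("IGLV1-40*01",
                      subs = sub_df(38, "D", "G", 40, "H", "N"))
  expect_true(classify_poems_signature(p40)$verdict)
})

test_that("position 40 must change to asparagine; 38 must go nonpolar", {
  not_asn <- make_profile("IGLV1-40*01",
                          subs = sub_df(38, "D", "G", 40, "H", "D"))
  expect_false(classify_poems_signature(not_asn)$verdict)
  polar38 <- make_profile(subs = sub_df(38, "T", "S", 40, "H", "N"))
  strict <- classify_poems_signature(polar38)
  expect_false(strict$verdict)
  expect_false(strict$pos38_nonpolar)
  # but either mode accepts the intact 40N evidence
  expect_true(classify_poems_signature(polar38, "either")$verdict)
})

test_that("wrong V family or J allele blocks the signature", {
  wrong_v <- make_profile(v_call = "IGLV5-01*01",
                          subs = sub_df(38, "T", "P", 40, "H", "N"))
  expect_false(classify_poems_signature(wrong_v)$verdict)
  wrong_j <- make_profile(j_call = "IGLJ2*01",
                          subs = sub_df(38, "T", "P", 40, "H", "N"))
  expect_false(classify_poems_signature(wrong_j)$verdict)
  # family matching is allele-agnostic
  allele2 <- make_profile(v_call = "IGLV1-44*02",
                          subs = sub_df(38, "T", "P", 40, "H", "N"))
  expect_true(classify_poems_signature(allele2)$verdict)
})

test_that("strict positivity implies either-mode positivity", {
  set.seed(13)
  aa <- strsplit("ARNDQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:50) {
    subs <- sub_df(38, "T", sample(aa, 1), 40, "H", sample(aa, 1))
    prof <- make_profile(v_call = sample(c("IGLV1-44*01", "IGLV9-9*01"), 1),
                         j_call = sample(c("IGLJ3*02", "IGLJ2*01"), 1),
                         subs = subs)
    s <- classify_poems_signature(prof, "strict")$verdict
    e <- classify_poems_signature(prof, "either")$verdict
    expect_true(!s || e)
  }
})

test_that("missing 38/40 coverage yields negative flags and a warning flag", {
  prof <- make_profile(subs = sub_df(38, "T", "P", 40, "H", "N")[0, ],
                       covered = 1:30)
  call <- classify_poems_signature(prof)
  expect_false(call$verdict)
  expect_true(call$coverage_warning)
})

test_that("substitution calling reports exactly the planted differences", {
  cfg <- simulation_config(n_cells = 6, clone_fraction = 0.5,
                           per_base_error_rate = 0, heavy_chain = FALSE,
                           seed = 401)
  co <- simulate_repertoire(cfg, shared_ref)
  ann <- annotate_cohort(co, shared_ref)
  ref44 <- shared_ref[["IGLV1-44*01"]]
  for (ch in ann$chains) {
    prof <- call_substitutions(ch, shared_ref[[ch$v_call]])
    if (co$cells$is_clone[match(ch$cell_id, co$cells$barcode)]) {
      expect_identical(prof$substitutions$position, c(38L, 40L))
      expect_identical(prof$substitutions$observed, c("P", "N"))
    } else {
      expect_identical(nrow(prof$substitutions), 0L)
    }
  }
  # v_call mismatch is an error
  ch1 <- ann$chains[[1]]
  wrong <- shared_ref[[setdiff(names(ref_subset(shared_ref, "V", "IGL")),
                               ch1$v_call)[1]]]
  expect_error(call_substitutions(ch1, wrong), "does not match")
})

test_that("signature-positive singletons are rescued without double counting", {
  # cohort sized to echo a single-cell clone among 59 plasma cells
  cfg <- simulation_config(n_cells = 59, clone_fraction = 1 / 59,
                           per_base_error_rate = 0, heavy_chain = FALSE,
                           clone_v_allele = "IGLV1-40*01",
                           planted_substitutions =
                             poems_substitutions("IGLV1-40*01"),
                           seed = 402)
  co <- simulate_repertoire(cfg, shared_ref)
  ann <- annotate_cohort(co, shared_ref)
  cc <- call_clones(group_clonotypes(ann), min_cells = 2)
  expect_identical(sum(cc$clonotypes$is_clone), 0L)
  scr <- signature_screen(ann, shared_ref)
  rescued <- rescue_singletons(cc, scr)
  idx <- which(rescued$clonotypes$is_clone)
  expect_identical(length(idx), 1L)
  expect_true(rescued$clonotypes$rescued[idx])
  expect_equal(rescued$clonotypes$fraction[idx], 1 / 59, tolerance = 1e-12)
  # applying the rescue twice changes nothing
  again <- rescue_singletons(rescued, scr)
  expect_identical(again$clonotypes, rescued$clonotypes)
  # no positives -> unchanged
  none <- scr; none$verdict <- FALSE
  expect_identical(rescue_singletons(cc, none)$clonotypes$is_clone,
                   cc$clonotypes$is_clone)
})
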