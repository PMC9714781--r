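# Synthetic cohorts with a planted clone: ground truth for every downstream
# stage. Clone fractions, signature substitutions at IMGT 38/40, sequencing
# error and clone-specific marker shifts are all configurable; a single seed
# fixes every output byte.

.MARKER_GENES <- c("CD19", "SDC1", "CD38", "HLA-DRA", "HLA-DRB1",
                   "MYC", "CCND1", "CCND2", "IRF4", "VEGFA", "IL6")

# default clone-specific marker shifts (log2): CD19 negative, MHC-II down,
# CD38 lowered, MYC/CCND1 low-to-normal — the phenotype of the small lambda
# clones this package is built to find
.DEFAULT_MARKER_EFFECTS <- c("CD19" = -5, "HLA-DRA" = -4, "HLA-DRB1" = -4,
                             "CD38" = -1.5, "MYC" = -1, "CCND1" = -1)

#' Signature substitutions for a lambda V family
#'
#' Returns the canonical position 38 / position 40 amino-acid changes planted
#' on clones of the given family: position 40 always mutates to asparagine,
#' position 38 to a nonpolar residue (the family-specific germline residues
#' are those of the package's scaffolds).
#'
#' @param v_allele V allele or gene name, e.g. `"IGLV1-44*01"`.
#' @return data.frame with columns `position`, `germline`, `mutant`.
#' @export
poems_substitutions <- function(v_allele = "IGLV1-44*01") {
  fam <- sub("\\*.*$", "", v_allele)
  g <- .FAMILY_3840[[fam]]
  if (is.null(g))
    stop("no signature defined for family ", fam,
         " (expected one of ", paste(names(.FAMILY_3840), collapse = ", "), ")")
  mut38 <- c("IGLV1-36" = "P", "IGLV1-40" = "G",
             "IGLV1-44" = "P", "IGLV1-47" = "P")[[fam]]
  data.frame(position = c(38L, 40L),
             germline = unname(g[c("38", "40")]),
             mutant = c(mut38, "N"))
}

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic cohort generator. The defaults describe
#' the regime the pipeline targets: a small monoclonal population (20% of
#' plasma cells) carrying an IGLV1-44 / IGLJ3*02 rearrangement with the
#' position 38/40 signature, modest sequencing error, and the clone phenotype
#' of lowered CD19, MHC class II and CD38 with low-to-normal MYC/CCND1.
#'
#' @param n_cells Number of cells.
#' @param clone_fraction Planted clone proportion in `[0, 1]`.
#' @param clone_v_allele,clone_j_allele Light-chain alleles of the clone.
#' @param planted_substitutions data.frame (`position`, `germline`, `mutant`)
#'   of amino-acid changes planted on the clone's V region, on IMGT
#'   coordinates. Default: [poems_substitutions()] for `clone_v_allele`.
#' @param cdr3_length CDR3 length in residues (IMGT 105-117 span).
#' @param per_base_error_rate Per-base substitution error in `[0, 0.05]`.
#' @param marker_effects Named numeric, log2 fold change applied to clone
#'   cells for each marker gene.
#' @param n_genes Genes in the count matrix (marker genes included).
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param lib_sdlog sdlog of the log-normal library-size multipliers.
#' @param bulk_read_depth Reads in the bulk repertoire library.
#' @param bulk_read_length Bulk read length (3'-anchored window).
#' @param heavy_chain Also simulate a paired heavy chain per cell.
#' @param doublet_rate Fraction of cells receiving a second, foreign light
#'   chain (merged-cell artifact).
#' @param seed Integer seed; fully determines all generator outputs.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_cells = 100L,
                              clone_fraction = 0.2,
                              clone_v_allele = "IGLV1-44*01",
                              clone_j_allele = "IGLJ3*02",
                              planted_substitutions =
                                poems_substitutions(clone_v_allele),
                              cdr3_length = 12L,
                              per_base_error_rate = 0.001,
                              marker_effects = .DEFAULT_MARKER_EFFECTS,
                              n_genes = 2000L,
                              nb_dispersion = 0.3,
                              lib_sdlog = 0.3,
                              bulk_read_depth = 10000L,
                              bulk_read_length = 200L,
                              heavy_chain = TRUE,
                              doublet_rate = 0,
                              seed = 1L) {
  if (clone_fraction < 0 || clone_fraction > 1)
    stop("clone_fraction must be in [0, 1]")
  if (per_base_error_rate < 0 || per_base_error_rate > 0.05)
    stop("per_base_error_rate must be in [0, 0.05]")
  if (cdr3_length < 5L) stop("cdr3_length must be at least 5 residues")
  if (n_cells < 1L) stop("n_cells must be positive")
  if (!is.numeric(seed) || is.na(seed) || abs(seed) > 2^30)
    stop("seed must be a 32-bit integer")
  seed <- as.integer(seed)
  if (length(marker_effects) && is.null(names(marker_effects)))
    stop("marker_effects must be a named numeric vector")
  structure(list(n_cells = as.integer(n_cells),
                 clone_fraction = clone_fraction,
                 clone_v_allele = clone_v_allele,
                 clone_j_allele = clone_j_allele,
                 planted_substitutions = planted_substitutions,
                 cdr3_length = as.integer(cdr3_length),
                 per_base_error_rate = per_base_error_rate,
                 marker_effects = marker_effects,
                 n_genes = as.integer(n_genes),
                 nb_dispersion = nb_dispersion,
                 lib_sdlog = lib_sdlog,
                 bulk_read_depth = as.integer(bulk_read_depth),
                 bulk_read_length = as.integer(bulk_read_length),
                 heavy_chain = isTRUE(heavy_chain),
                 doublet_rate = doublet_rate,
                 seed = seed),
            class = "simulation_config")
}

.random_cdr3_nt <- function(len) {
  aa <- sample(.AA_POOL, len, replace = TRUE)
  paste(vapply(aa, .random_codon, character(1)), collapse = "")
}

.inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in hit) {
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.apply_substitutions <- function(vseg, subs) {
  nt <- seg_ungapped(vseg)
  imgt <- seg_imgt_positions(vseg)
  germ_aa <- seg_aa(vseg)
  for (r in seq_len(nrow(subs))) {
    pos <- subs$position[r]
    idx <- match(pos, imgt)
    if (is.na(idx))
      stop("IMGT position ", pos, " is gapped in ", vseg$name)
    if (germ_aa[[as.character(pos)]] != subs$germline[r])
      stop("germline residue at IMGT ", pos, " of ", vseg$name, " is ",
           germ_aa[[as.character(pos)]], ", not ", subs$germline[r])
    codon <- .random_codon(subs$mutant[r])
    substr(nt, 3L * idx - 2L, 3L * idx) <- codon
  }
  nt
}

.recombine <- function(v_nt, cdr3_nt, jseg, c_stub) {
  paste0(v_nt, cdr3_nt, seg_ungapped(jseg), c_stub)
}

#' Simulate a per-cell immunoglobulin repertoire with a planted clone
#'
#' Clone cells share one V-J recombination with one fixed CDR3 and carry the
#' configured position-level substitutions; every other cell draws an
#' independent V, J and random CDR3. Per-base substitution errors are applied
#' last; the truth table (labels, clonotype key, substitution list) records
#' the pre-error state.
#'
#' @param cfg A [simulation_config()].
#' @param ref A [build_germline_reference()] result containing the clone
#'   alleles.
#' @return A `sim_cohort`: cell table, per-cell transcript lists (clean and
#'   error-bearing), truth, config and reference.
#' @export
simulate_repertoire <- function(cfg, ref) {
  if (!cfg$clone_v_allele %in% names(ref) ||
      !cfg$clone_j_allele %in% names(ref))
    stop("clone alleles not present in the germline reference")
  set.seed(cfg$seed)
  light_v <- ref_subset(ref, "V", "IGL")
  light_j <- ref_subset(ref, "J", "IGL")
  heavy_v <- ref_subset(ref, "V", "IGH")
  heavy_j <- ref_subset(ref, "J", "IGH")
  if (cfg$heavy_chain && (!length(heavy_v) || !length(heavy_j)))
    stop("heavy_chain = TRUE but the reference has no IGH segments")
  c_stub_l <- paste(sample(c("A", "C", "G", "T"), 45L, TRUE), collapse = "")
  c_stub_h <- paste(sample(c("A", "C", "G", "T"), 45L, TRUE), collapse = "")

  n <- cfg$n_cells
  n_clone <- round(n * cfg$clone_fraction)
  is_clone <- seq_len(n) <= n_clone
  barcodes <- sprintf("cell%04d", seq_len(n))

  vseg <- ref[[cfg$clone_v_allele]]
  jseg <- ref[[cfg$clone_j_allele]]
  clone_v_nt <- .apply_substitutions(vseg, cfg$planted_substitutions)
  clone_cdr3 <- .random_cdr3_nt(cfg$cdr3_length)
  clone_tx_l <- .recombine(clone_v_nt, clone_cdr3, jseg, c_stub_l)
  cys <- vseg$anchors[["CYS104"]]
  clone_junction <- paste0(substr(clone_v_nt, cys, cys + 2L), clone_cdr3,
                           substr(seg_ungapped(jseg), 1L, 3L))
  if (cfg$heavy_chain) {
    hv <- heavy_v[[1L]]; hj <- heavy_j[[1L]]
    clone_cdr3_h <- .random_cdr3_nt(cfg$cdr3_length)
    clone_tx_h <- .recombine(seg_ungapped(hv), clone_cdr3_h, hj, c_stub_h)
  }

  clean <- vector("list", n)
  names(clean) <- barcodes
  v_call <- j_call <- cdr3_nt <- character(n)
  jx_start <- jx_end <- integer(n)
  for (i in seq_len(n)) {
    if (is_clone[i]) {
      txs <- c(tx1 = clone_tx_l)
      if (cfg$heavy_chain) txs <- c(txs, tx2 = clone_tx_h)
      v_call[i] <- cfg$clone_v_allele; j_call[i] <- cfg$clone_j_allele
      cdr3_nt[i] <- clone_cdr3
      v_len <- nchar(clone_v_nt)
    } else {
      v <- light_v[[sample.int(length(light_v), 1L)]]
      j <- light_j[[sample.int(length(light_j), 1L)]]
      cdr3 <- .random_cdr3_nt(cfg$cdr3_length)
      txs <- c(tx1 = .recombine(seg_ungapped(v), cdr3, j, c_stub_l))
      if (cfg$heavy_chain) {
        hv <- heavy_v[[sample.int(length(heavy_v), 1L)]]
        hj <- heavy_j[[sample.int(length(heavy_j), 1L)]]
        txs <- c(txs, tx2 = .recombine(seg_ungapped(hv),
                                       .random_cdr3_nt(cfg$cdr3_length),
                                       hj, c_stub_h))
      }
      v_call[i] <- v$name; j_call[i] <- j$name
      cdr3_nt[i] <- cdr3
      v_len <- nchar(seg_ungapped(v))
    }
    # junction (Cys-104 codon .. Phe-118 codon) coordinates in the transcript
    jx_start[i] <- v_len - 2L
    jx_end[i] <- v_len + nchar(cdr3_nt[i]) + 3L
    clean[[i]] <- txs
  }

  doublet <- rep(FALSE, n)
  if (cfg$doublet_rate > 0 && n >= 2L) {
    n_dbl <- round(n * cfg$doublet_rate)
    if (n_dbl > 0L) {
      idx <- sample.int(n, n_dbl)
      for (i in idx) {
        donor <- sample(setdiff(seq_len(n), i), 1L)
        clean[[i]] <- c(clean[[i]],
                        setNames(clean[[donor]]["tx1"],
                                 paste0("tx", length(clean[[i]]) + 1L)))
        doublet[i] <- TRUE
      }
    }
  }

  transcripts <- lapply(clean, function(txs)
    setNames(.inject_errors(txs, cfg$per_base_error_rate), names(txs)))

  truth <- list(
    labels = data.frame(barcode = barcodes, is_clone = is_clone,
                        doublet = doublet, v_call = v_call, j_call = j_call,
                        cdr3_nt = cdr3_nt, jx_start = jx_start,
                        jx_end = jx_end, stringsAsFactors = FALSE),
    clonotype = list(v_call = cfg$clone_v_allele, j_call = cfg$clone_j_allele,
                     junction = clone_junction,
                     cdr3_nt = clone_cdr3,
                     cdr3_aa = translate_dna(clone_cdr3)),
    substitutions = cfg$planted_substitutions)

  structure(list(cells = truth$labels, transcripts = transcripts,
                 transcripts_clean = clean, truth = truth,
                 config = cfg, reference = ref),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d cells (%d clone), seed %d\n",
              nrow(x$cells), sum(x$cells$is_clone), x$config$seed))
  invisible(x)
}

#' Simulate a gene-by-cell count matrix with clone-specific marker shifts
#'
#' Counts are negative binomial with log-normal per-gene base means,
#' log-normal library-size multipliers and a common dispersion; in clone
#' cells the base mean of each configured marker gene is multiplied by
#' `2^effect`. The gene index always contains the canonical plasma-cell
#' marker panel (CD19, SDC1, CD38, HLA-DRA/B1, MYC, CCND1, CCND2, IRF4,
#' VEGFA, IL6).
#'
#' @param cfg A [simulation_config()].
#' @param cohort A `sim_cohort` from [simulate_repertoire()] (provides the
#'   truth labels).
#' @return A [count_matrix()] with groups `"clone"` / `"nonclone"`.
#' @export
simulate_expression <- function(cfg, cohort) {
  set.seed(cfg$seed + 1L)
  n_extra <- cfg$n_genes - length(.MARKER_GENES)
  if (n_extra < 0L) stop("n_genes must be at least ", length(.MARKER_GENES))
  genes <- c(.MARKER_GENES, sprintf("GENE%04d", seq_len(n_extra)))
  bad <- setdiff(names(cfg$marker_effects), genes)
  if (length(bad))
    stop("marker_effects for genes absent from the gene index: ",
         paste(bad, collapse = ", "))
  n <- nrow(cohort$cells)
  base_mu <- c(rep(128, length(.MARKER_GENES)),
               rlnorm(n_extra, meanlog = log(20), sdlog = 1.2))
  names(base_mu) <- genes
  lib <- rlnorm(n, 0, cfg$lib_sdlog)
  mu <- outer(base_mu, lib)
  if (length(cfg$marker_effects)) {
    eff <- names(cfg$marker_effects)
    mu[eff, cohort$cells$is_clone] <-
      mu[eff, cohort$cells$is_clone, drop = FALSE] *
      2^cfg$marker_effects
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = length(genes),
                   dimnames = list(genes, cohort$cells$barcode))
  storage.mode(counts) <- "integer"
  count_matrix(counts,
               groups = ifelse(cohort$cells$is_clone, "clone", "nonclone"))
}

#' Simulate bulk repertoire reads from a cohort
#'
#' Reads are drawn uniformly across cells (one read = a 3'-anchored window of
#' the cell's clean light-chain transcript, covering the junction and the V
#' 3' end) and then subjected to the configured per-base error rate. Under
#' uniform abundance the expected clonal read fraction equals the planted
#' clone fraction.
#'
#' @param cfg A [simulation_config()] with `bulk_read_depth >= 1000`.
#' @param cohort A `sim_cohort`.
#' @return A `bulk_reads` object: named read vector plus per-read truth.
#' @export
simulate_bulk_reads <- function(cfg, cohort) {
  if (cfg$bulk_read_depth < 1000L) stop("bulk_read_depth must be >= 1000")
  set.seed(cfg$seed + 2L)
  n <- nrow(cohort$cells)
  pick <- sample.int(n, cfg$bulk_read_depth, replace = TRUE)
  tx <- vapply(cohort$transcripts_clean, `[[`, "", "tx1")
  win <- function(s) substr(s, max(1L, nchar(s) - cfg$bulk_read_length + 1L),
                            nchar(s))
  reads <- .inject_errors(vapply(tx[pick], win, "", USE.NAMES = FALSE),
                          cfg$per_base_error_rate)
  names(reads) <- sprintf("read%06d", seq_along(reads))
  structure(list(reads = reads,
                 source_cell = cohort$cells$barcode[pick],
                 is_clonal = cohort$cells$is_clone[pick]),
            class = "bulk_reads")
}

#' Simulate a complete cohort (repertoire, counts, bulk reads)
#'
#' Convenience wrapper running [simulate_repertoire()],
#' [simulate_expression()] and [simulate_bulk_reads()] under one config.
#'
#' @param cfg A [simulation_config()].
#' @param ref Optional germline reference; built from `cfg$seed` when `NULL`.
#' @param expression,bulk Logical switches for the two optional layers.
#' @return A `sim_cohort` with `$counts` and `$bulk` filled in.
#' @export
simulate_cohort <- function(cfg, ref = NULL, expression = TRUE, bulk = TRUE) {
  if (is.null(ref)) ref <- build_germline_reference(seed = cfg$seed)
  cohort <- simulate_repertoire(cfg, ref)
  if (expression) cohort$counts <- simulate_expression(cfg, cohort)
  if (bulk) cohort$bulk <- simulate_bulk_reads(cfg, cohort)
  cohort
}
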