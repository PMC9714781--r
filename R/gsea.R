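# Pre-ranked GSEA: weighted Kolmogorov-Smirnov running-sum enrichment score
# with a gene-set permutation null.

# Running-sum enrichment score for one set on a ranked, signed score vector.
# Weight exponent p applies to |score| at hit positions; misses decrement
# uniformly by 1/(N - Nh). The maximal-deviation value (signed) is returned.
.es_running <- function(scores, hits, p = 1) {
  N <- length(scores)
  nh <- sum(hits)
  if (nh == 0L) stop("gene set does not intersect the ranking")
  if (nh == N) return(list(es = 0, running = rep(0, N)))  # degenerate set
  w <- abs(scores)^p
  inc <- numeric(N)
  sw <- sum(w[hits])
  inc[hits] <- if (sw > 0) w[hits] / sw else 1 / nh
  inc[!hits] <- -1 / (N - nh)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Pre-ranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment (weight exponent
#' `p = 1` on the absolute score), with significance from a gene-set
#' permutation null: random sets of equal size drawn from the ranked genes.
#' NES is the ES divided by the mean absolute permuted ES of matching sign;
#' the FDR q value compares each NES with the pooled sign-matched permuted
#' NES distribution relative to the observed NES distribution, in the manner
#' of the standard GSEA procedure. Genes expected to be excluded (e.g. those
#' with no reads in both samples of the underlying contrast) must be removed
#' upstream — [make_ranking()] applies that rule.
#'
#' @param ranking Named numeric vector of signed per-gene scores (any order;
#'   ranked internally, decreasing).
#' @param gene_sets Named list of character vectors (a single character
#'   vector is treated as one set).
#' @param n_perm Number of gene-set permutations (at least 100).
#' @param p Weight exponent on `|score|` (default 1).
#' @param seed RNG seed for the permutations.
#' @return An `enrichment_result` data.frame: `gene_set`, `size`, `es`,
#'   `nes`, `pvalue`, `fdr_q`, `leading_edge` (comma-separated genes).
#' @export
gsea_preranked <- function(ranking, gene_sets, n_perm = 1000L, p = 1,
                           seed = 1L) {
  if (!is.list(gene_sets)) gene_sets <- list(set1 = gene_sets)
  if (is.null(names(gene_sets)))
    names(gene_sets) <- sprintf("set%d", seq_along(gene_sets))
  if (n_perm < 100L) stop("n_perm must be at least 100")
  ord <- order(ranking, decreasing = TRUE)
  scores <- unname(ranking[ord])
  genes <- names(ranking)[ord]
  N <- length(scores)
  set.seed(seed)

  obs <- lapply(gene_sets, function(gs) {
    hits <- genes %in% gs
    if (!any(hits)) stop("gene set does not intersect the ranking")
    .es_running(scores, hits, p)
  })
  sizes <- vapply(gene_sets, function(gs) sum(genes %in% gs), 0L)

  # permutation null per set size (sets of equal size share a null)
  null_by_size <- list()
  for (s in unique(sizes)) {
    if (s == N) { null_by_size[[as.character(s)]] <- numeric(0); next }
    es_perm <- vapply(seq_len(n_perm), function(i) {
      hits <- logical(N)
      hits[sample.int(N, s)] <- TRUE
      .es_running(scores, hits, p)$es
    }, numeric(1))
    null_by_size[[as.character(s)]] <- es_perm
  }

  res <- lapply(seq_along(gene_sets), function(i) {
    es <- obs[[i]]$es
    perm <- null_by_size[[as.character(sizes[i])]]
    same <- if (es >= 0) perm[perm >= 0] else perm[perm < 0]
    pval <- if (length(same)) (1 + sum(abs(same) >= abs(es))) /
      (1 + length(same)) else NA_real_
    nes <- if (length(same) && mean(abs(same)) > 0) es / mean(abs(same))
           else NA_real_
    run <- obs[[i]]$running
    peak <- which.max(abs(run))
    hits <- genes %in% gene_sets[[i]]
    le <- if (es >= 0) genes[hits & seq_len(N) <= peak]
          else genes[hits & seq_len(N) >= peak]
    list(es = es, nes = nes, pvalue = pval, perm = perm,
         leading_edge = paste(le, collapse = ","))
  })

  nes_obs <- vapply(res, `[[`, 0, "nes")
  # normalized permutation pool for the FDR (each permuted ES scaled by the
  # sign-matched mean of its own size class)
  nes_pool <- unlist(lapply(unique(sizes), function(s) {
    perm <- null_by_size[[as.character(s)]]
    if (!length(perm)) return(numeric(0))
    mp <- mean(abs(perm[perm >= 0]))
    mn <- mean(abs(perm[perm < 0]))
    ifelse(perm >= 0, perm / mp, perm / mn)
  }))
  fdr <- vapply(seq_along(res), function(i) {
    nes <- nes_obs[i]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(nes_pool[nes_pool >= 0] >= nes)
      den <- mean(nes_obs[nes_obs >= 0] >= nes)
    } else {
      num <- mean(nes_pool[nes_pool < 0] <= nes)
      den <- mean(nes_obs[nes_obs < 0] <= nes)
    }
    if (is.nan(num) || is.nan(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  out <- data.frame(gene_set = names(gene_sets), size = sizes,
                    es = vapply(res, `[[`, 0, "es"),
                    nes = nes_obs,
                    pvalue = vapply(res, `[[`, 0, "pvalue"),
                    fdr_q = fdr,
                    leading_edge = vapply(res, `[[`, "", "leading_edge"),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Signed per-gene ranking for a two-group contrast
#'
#' Scores are the difference of group means of log2(normalized count + 1)
#' (`test` minus `reference`). Genes with zero counts in both groups are
#' excluded before ranking.
#'
#' @param m A `count_matrix`.
#' @param contrast Character pair `c(test, reference)`.
#' @param groups Group labels (default `m$groups`).
#' @return Named numeric vector of signed scores.
#' @export
make_ranking <- function(m, contrast, groups = m$groups) {
  stopifnot(length(contrast) == 2L, !is.null(groups))
  i1 <- which(groups == contrast[2]); i2 <- which(groups == contrast[1])
  keep <- rowSums(m$counts[, c(i1, i2), drop = FALSE]) > 0
  lx <- log2(normalized_counts(m)[keep, , drop = FALSE] + 1)
  score <- rowMeans(lx[, i2, drop = FALSE]) - rowMeans(lx[, i1, drop = FALSE])
  sort(score, decreasing = TRUE)
}

#' Read gene sets in GMT format
#' @param path Path to a GMT file (set name, description, genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  sets <- lapply(lines, function(x) x[-(1:2)])
  names(sets) <- vapply(lines, `[`, "", 1)
  sets
}
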