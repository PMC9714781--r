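# Expression profiling of clones vs nonclones vs controls: median-of-ratios
# normalization, a negative-binomial Wald test with method-of-moments
# dispersion, top-k pooling of DE genes, K-means on the pooled panel, marker
# phenotyping and in-silico gating.

#' Construct a count matrix container
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames are
#'   gene symbols), cells/samples in columns.
#' @param groups Optional character vector of group labels per cell (e.g.
#'   control / clone / nonclone / MGUS / MM).
#' @param size_factors Optional positive numeric vector per cell.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, groups = NULL, size_factors = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(counts))
    groups <- setNames(as.character(groups), colnames(counts))
  }
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
    size_factors <- setNames(as.numeric(size_factors), colnames(counts))
  }
  structure(list(counts = counts, groups = groups,
                 size_factors = size_factors),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells%s%s\n",
              nrow(x$counts), ncol(x$counts),
              if (!is.null(x$size_factors)) ", normalized" else "",
              if (!is.null(x$groups))
                paste0(" (groups: ",
                       paste(names(table(x$groups)), table(x$groups),
                             sep = ":", collapse = ", "), ")") else ""))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' The size factor of a sample is the median across reference genes of the
#' ratio of its count to the gene's geometric mean; genes with any zero count
#' are excluded from the reference set. When no gene is expressed everywhere
#' (common in sparse single-cell matrices) the estimator falls back to genes
#' nonzero in at least `min_prop` of cells, taking geometric means and
#' medians over the positive counts only. Size factors are rescaled to
#' geometric mean 1; the estimator is scale-equivariant in the ratio sense:
#' multiplying one sample's counts by `c` multiplies its size factor
#' relative to every other sample exactly by `c`.
#'
#' @param m A `count_matrix` with at least 2 samples.
#' @param fallback Allow the sparse-matrix fallback (default `TRUE`).
#' @param min_prop Minimum fraction of cells with a positive count for a gene
#'   to enter the fallback reference set.
#' @return `m` with `$size_factors` filled in.
#' @export
size_factor_normalize <- function(m, fallback = TRUE, min_prop = 0.9) {
  counts <- m$counts
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  all_nz <- rowSums(counts == 0) == 0L
  if (any(all_nz)) {
    ref <- counts[all_nz, , drop = FALSE]
    geo <- exp(rowMeans(log(ref)))
    sf <- apply(ref, 2L, function(col) median(col / geo))
  } else if (fallback) {
    usable <- rowMeans(counts > 0) >= min_prop
    if (!any(usable))
      stop("no usable reference genes for size-factor estimation")
    ref <- counts[usable, , drop = FALSE]
    lg <- log(ref)
    lg[ref == 0] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))
    sf <- apply(ref / geo, 2L, function(r) median(r[r > 0], na.rm = TRUE))
  } else {
    stop("no gene has nonzero counts in every sample and fallback is disabled")
  }
  sf <- sf / exp(mean(log(sf)))  # rescale to geometric mean 1
  m$size_factors <- setNames(sf, colnames(counts))
  m
}

#' Normalized counts (raw / size factor)
#' @param m A `count_matrix`; size factors are estimated on the fly when
#'   absent.
#' @return Numeric matrix of normalized counts.
#' @export
normalized_counts <- function(m) {
  if (is.null(m$size_factors)) m <- size_factor_normalize(m)
  sweep(m$counts, 2L, m$size_factors, "/")
}

.row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

#' Negative-binomial Wald test for differential expression
#'
#' Per gene, group means of normalized counts are compared on the log2 scale
#' with a Wald statistic whose standard error comes from a method-of-moments
#' negative-binomial variance (the sample variance floored at the mean, i.e.
#' dispersion `alpha = max(0, (var - mu) / mu^2)`). P values use a t
#' reference with `n1 + n2 - 2` degrees of freedom and are adjusted with
#' Benjamini-Hochberg across the tested genes. Genes with zero counts in
#' both groups are excluded. This is a deliberately simple, fully specified
#' NB test, not a reimplementation of shrinkage-based DE estimators.
#'
#' @param m A `count_matrix` with group labels.
#' @param contrast Character pair `c(test, reference)`; positive log2 fold
#'   change means higher in `test`.
#' @param groups Optional group vector overriding `m$groups`.
#' @return A `de_result` data.frame: `gene`, `base_mean`, `log2fc`, `stat`,
#'   `pvalue`, `padj`, ordered by p value; attribute `contrast`.
#' @export
de_test <- function(m, contrast, groups = m$groups) {
  stopifnot(length(contrast) == 2L, !is.null(groups))
  norm <- normalized_counts(m)
  i1 <- which(groups == contrast[2])  # reference
  i2 <- which(groups == contrast[1])  # test
  if (length(i1) < 3L || length(i2) < 3L)
    stop("each group needs at least 3 cells")
  x1 <- norm[, i1, drop = FALSE]; x2 <- norm[, i2, drop = FALSE]
  keep <- rowSums(m$counts[, c(i1, i2), drop = FALSE]) > 0
  x1 <- x1[keep, , drop = FALSE]; x2 <- x2[keep, , drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  mu1 <- rowMeans(x1) + 0.5 / n1  # continuity guard for all-zero groups
  mu2 <- rowMeans(x2) + 0.5 / n2
  v1 <- pmax(.row_vars(x1), mu1)  # NB variance is at least the mean
  v2 <- pmax(.row_vars(x2), mu2)
  lfc <- log2(mu2 / mu1)
  se <- sqrt(v1 / (n1 * mu1^2) + v2 / (n2 * mu2^2)) / log(2)
  stat <- lfc / se
  p <- 2 * pt(-abs(stat), df = n1 + n2 - 2L)
  out <- data.frame(gene = rownames(x1),
                    base_mean = (rowMeans(x1) * n1 + rowMeans(x2) * n2) /
                      (n1 + n2),
                    log2fc = lfc, stat = stat, pvalue = p,
                    padj = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$pvalue, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, contrast = contrast, class = c("de_result", "data.frame"))
}

#' Pool the top differentially expressed genes across contrasts
#'
#' For each contrast the `k` most significant upregulated and `k` most
#' significant downregulated genes among those passing the raw p-value cutoff
#' are taken; the pooled panel is the union across contrasts, so overlap
#' between contrasts shrinks it below `2 * k * n_contrasts`.
#'
#' @param results A `de_result` or list of them.
#' @param k Genes per direction per contrast (default 30).
#' @param p_cut Raw p-value cutoff (default 0.01).
#' @return Character vector of pooled gene symbols (sorted, unique).
#' @export
select_top_de <- function(results, k = 30L, p_cut = 0.01) {
  if (inherits(results, "de_result")) results <- list(results)
  pooled <- unlist(lapply(results, function(res) {
    res <- res[!is.na(res$pvalue) & res$pvalue < p_cut, , drop = FALSE]
    up <- res[res$log2fc > 0, , drop = FALSE]
    dn <- res[res$log2fc < 0, , drop = FALSE]
    c(head(up$gene[order(up$pvalue, up$gene)], k),
      head(dn$gene[order(dn$pvalue, dn$gene)], k))
  }))
  sort(unique(pooled))
}

#' K-means clustering on a pooled gene panel
#'
#' Cells are clustered on gene-standardized log2 normalized expression
#' (each gene centred and scaled across cells) restricted to the panel.
#'
#' @param m A `count_matrix`.
#' @param genes Gene panel (e.g. from [select_top_de()]).
#' @param k Number of clusters.
#' @param seed RNG seed for the restarts.
#' @param nstart Number of random restarts.
#' @return List with `assignment` (named integer per cell), `sse` (total
#'   within-cluster sum of squares) and the `kmeans` fit.
#' @export
kmeans_cluster <- function(m, genes, k, seed = 1L, nstart = 10L) {
  genes <- intersect(genes, rownames(m$counts))
  if (!length(genes)) stop("pooled gene list is empty")
  x <- log2(normalized_counts(m)[genes, , drop = FALSE] + 1)
  x <- x[apply(x, 1L, sd) > 0, , drop = FALSE]
  z <- t(scale(t(x)))
  items <- t(z)
  if (k > nrow(items)) stop("k exceeds the number of cells")
  set.seed(seed)
  fit <- kmeans(items, centers = k, nstart = nstart)
  list(assignment = setNames(fit$cluster, rownames(items)),
       sse = fit$tot.withinss, fit = fit)
}

#' Marker phenotype of each cell group
#'
#' Mean log2(normalized count + 1) per group for the plasma-cell marker
#' panel, with derived low/negative flags relative to the control group mean
#' minus a margin.
#'
#' @param m A `count_matrix`.
#' @param groups Group labels (default `m$groups`).
#' @param markers Marker genes (defaults to the canonical panel; absent
#'   genes are reported in `$absent`, not an error).
#' @param control Name of the reference group.
#' @param margin Log2 margin below the control mean for a "low" flag.
#' @return A `marker_phenotype`: `means` (group x marker matrix), `flags`
#'   (logical matrix for non-control groups), named convenience flags
#'   (`cd19_negative`, `hladr_low`, `cd38_low`, `myc_low`, `ccnd1_low`) per
#'   group, `absent`, and the margin used.
#' @export
marker_phenotype <- function(m, groups = m$groups, markers = .MARKER_GENES,
                             control = "control", margin = 1) {
  stopifnot(!is.null(groups))
  absent <- setdiff(markers, rownames(m$counts))
  markers <- intersect(markers, rownames(m$counts))
  if (!length(markers)) stop("none of the marker genes are present")
  lx <- log2(normalized_counts(m)[markers, , drop = FALSE] + 1)
  glev <- unique(groups)
  means <- matrix(NA_real_, length(glev), length(markers),
                  dimnames = list(glev, markers))
  for (g in glev) means[g, ] <- rowMeans(lx[, groups == g, drop = FALSE])
  flags <- NULL
  named <- NULL
  if (control %in% glev) {
    others <- setdiff(glev, control)
    flags <- sweep(means[others, , drop = FALSE], 2L,
                   means[control, ] - margin, "<")
    key <- c(cd19_negative = "CD19", hladr_low = "HLA-DRA",
             cd38_low = "CD38", myc_low = "MYC", ccnd1_low = "CCND1")
    key <- key[key %in% markers]
    named <- lapply(others, function(g) setNames(flags[g, key], names(key)))
    names(named) <- others
  }
  structure(list(means = means, flags = flags, group_flags = named,
                 absent = absent, margin = margin, control = control),
            class = "marker_phenotype")
}

#' @export
print.marker_phenotype <- function(x, ...) {
  cat("<marker_phenotype> mean log2(normalized count + 1):\n")
  print(round(x$means, 2))
  if (!is.null(x$flags)) {
    cat(sprintf("flags (mean < %s mean - %g):\n", x$control, x$margin))
    print(x$flags)
  }
  if (length(x$absent))
    cat("absent markers:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

#' In-silico gate for CD19-negative, HLA-DR-low cells
#'
#' Expression-space analog of the CD138+CD19-HLA-DR-/lo sorting gate: cells
#' whose log2 normalized CD19 and HLA-DR expression both fall below their
#' thresholds are gated. Thresholds default to the reference-group mean
#' minus `sd_mult` standard deviations in log2 space. When truth labels are
#' supplied the gate is scored by purity (fraction of gated cells that are
#' clone) and recall (fraction of clone cells gated).
#'
#' @param m A `count_matrix`.
#' @param truth Logical vector per cell: is the cell a clone? (Clonotype
#'   labels work equally.) Optional.
#' @param cd19_gene,hladr_gene Gene symbols used for the two gate axes.
#' @param thresholds Optional named numeric `c(cd19 =, hladr =)` in log2
#'   normalized space; computed from the reference when `NULL`.
#' @param reference Cells defining the threshold baseline: a group name in
#'   `m$groups` or a logical/integer index (default the `"control"` group,
#'   else all cells with a warning).
#' @param sd_mult Standard-deviation multiplier for the default thresholds.
#' @return List with `gated` (cell names), `purity`, `recall`, `thresholds`
#'   and `n_gated`. An empty gate warns and reports `purity = NA`.
#' @export
gate_clones_by_markers <- function(m, truth = NULL,
                                   cd19_gene = "CD19",
                                   hladr_gene = "HLA-DRA",
                                   thresholds = NULL,
                                   reference = "control",
                                   sd_mult = 2) {
  for (g in c(cd19_gene, hladr_gene))
    if (!g %in% rownames(m$counts)) stop("gate gene absent: ", g)
  lx <- log2(normalized_counts(m)[c(cd19_gene, hladr_gene), , drop = FALSE] + 1)
  if (is.null(thresholds)) {
    idx <- if (is.character(reference) && length(reference) == 1L) {
      if (!is.null(m$groups) && reference %in% m$groups)
        which(m$groups == reference)
      else {
        warning("reference group '", reference,
                "' not found; using all cells as baseline")
        seq_len(ncol(lx))
      }
    } else if (is.logical(reference)) which(reference)
    else as.integer(reference)
    thresholds <- c(
      cd19 = mean(lx[cd19_gene, idx]) - sd_mult * sd(lx[cd19_gene, idx]),
      hladr = mean(lx[hladr_gene, idx]) - sd_mult * sd(lx[hladr_gene, idx]))
  }
  gated <- lx[cd19_gene, ] < thresholds[["cd19"]] &
           lx[hladr_gene, ] < thresholds[["hladr"]]
  purity <- recall <- NA_real_
  if (!any(gated)) warning("gate selects zero cells")
  if (!is.null(truth)) {
    truth <- as.logical(truth)
    if (any(gated)) purity <- mean(truth[gated])
    if (any(truth)) recall <- mean(gated[truth])
  }
  list(gated = colnames(m$counts)[gated], n_gated = sum(gated),
       purity = purity, recall = recall, thresholds = thresholds)
}
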