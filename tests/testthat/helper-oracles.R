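# Shared fixtures and independent oracles used across the suite.

shared_ref <- build_germline_reference(seed = 42)

# random rearrangement table (no alignment involved) with forced key
# collisions, for partition tests
random_rearrangement_table <- function(n, seed, n_keys = max(2L, n %/% 3L)) {
  set.seed(seed)
  keys <- data.frame(
    v_call = sample(c("IGLV1-36*01", "IGLV1-44*01", "IGLV1-47*01"),
                    n_keys, replace = TRUE),
    j_call = sample(c("IGLJ3*02", "IGLJ2*01"), n_keys, replace = TRUE),
    junction = vapply(seq_len(n_keys), function(i)
      paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
            collapse = ""), ""),
    stringsAsFactors = FALSE)
  pick <- sample.int(n_keys, n, replace = TRUE)
  data.frame(cell_id = sprintf("c%03d", seq_len(n)),
             locus = "IGL",
             v_call = keys$v_call[pick], j_call = keys$j_call[pick],
             junction = keys$junction[pick],
             junction_aa = "X",
             productive = TRUE, doublet = FALSE,
             stringsAsFactors = FALSE)
}

# transitive closure of pairwise key equality: the brute-force grouping
# oracle; returns a canonical partition (list of sorted member vectors,
# sorted by first member)
partition_oracle <- function(tab) {
  n <- nrow(tab)
  eq <- outer(seq_len(n), seq_len(n), function(i, j)
    tab$v_call[i] == tab$v_call[j] & tab$j_call[i] == tab$j_call[j] &
    tab$junction[i] == tab$junction[j])
  repeat {
    nxt <- (eq %*% eq) > 0
    if (identical(nxt, eq)) break
    eq <- nxt
  }
  comp <- unique(apply(eq, 1, function(r) paste(which(r), collapse = ",")))
  parts <- lapply(strsplit(comp, ","), function(i)
    sort(tab$cell_id[as.integer(i)]))
  parts[order(vapply(parts, `[`, "", 1))]
}

canonical_partition <- function(clonotypes) {
  parts <- unname(lapply(clonotypes$members, sort))
  parts[order(vapply(parts, `[`, "", 1))]
}

# Benjamini-Hochberg step-up, written directly from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force weighted KS running-sum enrichment score (weight p = 1)
es_oracle <- function(scores, genes, set) {
  o <- order(scores, decreasing = TRUE)
  scores <- unname(scores[o]); genes <- genes[o]
  N <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  run <- 0; best <- 0
  sw <- sum(abs(scores[hit]))
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(scores[i]) / sw else -1 / (N - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ind <- si * sj / n
  (sij - exp_ind) / ((si + sj) / 2 - exp_ind)
}

# exact (Clopper-Pearson) binomial confidence interval for x successes of n
binom_ci <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

# clone fraction a cohort's pipeline estimates for its planted clonotype
estimate_clone_fraction <- function(cohort, ref) {
  ann <- annotate_cohort(cohort, ref)
  cc <- suppressWarnings(call_clones(group_clonotypes(ann), min_cells = 1L))
  est <- cc$clonotypes$fraction[
    match(cohort$truth$clonotype$junction, cc$clonotypes$junction)]
  if (is.na(est)) 0 else est
}
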