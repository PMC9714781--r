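# Clonotype grouping and clone-fraction estimation: cells sharing identical
# V and J calls and junction nucleotide sequence form a clonotype; clonotypes
# reaching the minimum cell count are called clones.

.light_table <- function(annotations) {
  tab <- if (inherits(annotations, "cell_annotations")) annotations$table
         else annotations
  tab[tab$locus %in% c("IGL", "IGK"), , drop = FALSE]
}

#' Group annotated cells into clonotypes
#'
#' Cells are partitioned by exact identity of the light-chain key
#' `(v_call, j_call, junction nucleotide sequence)`. With
#' `require_both_chains = TRUE` the heavy-chain triple must match as well and
#' cells lacking an IGH annotation are excluded; by default grouping is
#' light-chain-only (the heavy chain, when present, is reported per
#' clonotype). Doublet-flagged cells and non-productive light chains are
#' excluded.
#'
#' @param annotations A `cell_annotations` object (or its `$table`).
#' @param require_both_chains Require a matching IGH triple (strict mode).
#' @return A `clonotype_set`: data.frame with `clonotype_id`, `v_call`,
#'   `j_call`, `junction`, `junction_aa`, `n_cells` and a `members` list
#'   column; attribute `total_cells` counts the non-doublet cells that
#'   entered the partition.
#' @export
group_clonotypes <- function(annotations, require_both_chains = FALSE) {
  tab <- if (inherits(annotations, "cell_annotations")) annotations$table
         else annotations
  empty <- data.frame(clonotype_id = character(), v_call = character(),
                      j_call = character(), junction = character(),
                      junction_aa = character(), n_cells = integer(),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  attr(empty, "class") <- c("clonotype_set", "data.frame")
  if (!nrow(tab))
    return(structure(empty, total_cells = 0L,
                     class = c("clonotype_set", "data.frame")))
  light <- .light_table(tab)
  light <- light[!light$doublet & light$productive & !is.na(light$junction) &
                 !is.na(light$j_call), , drop = FALSE]
  if (require_both_chains) {
    heavy <- tab[tab$locus == "IGH" & !tab$doublet & !is.na(tab$junction) &
                 !is.na(tab$j_call), , drop = FALSE]
    light <- light[light$cell_id %in% heavy$cell_id, , drop = FALSE]
    hk <- paste(heavy$v_call, heavy$j_call, heavy$junction, sep = "|")
    key <- paste(light$v_call, light$j_call, light$junction,
                 hk[match(light$cell_id, heavy$cell_id)], sep = "|")
  } else {
    key <- paste(light$v_call, light$j_call, light$junction, sep = "|")
  }
  if (!nrow(light))
    return(structure(empty, total_cells = 0L,
                     class = c("clonotype_set", "data.frame")))
  groups <- split(seq_len(nrow(light)), key)
  # deterministic order: larger clonotypes first, then by key
  groups <- groups[order(-lengths(groups), names(groups))]
  out <- data.frame(
    clonotype_id = sprintf("CT%04d", seq_along(groups)),
    v_call = vapply(groups, function(i) light$v_call[i[1]], ""),
    j_call = vapply(groups, function(i) light$j_call[i[1]], ""),
    junction = vapply(groups, function(i) light$junction[i[1]], ""),
    junction_aa = vapply(groups, function(i) light$junction_aa[i[1]], ""),
    n_cells = lengths(groups),
    stringsAsFactors = FALSE, row.names = NULL)
  out$members <- lapply(groups, function(i) light$cell_id[i])
  structure(out, total_cells = nrow(light),
            class = c("clonotype_set", "data.frame"))
}

#' Call clones from grouped clonotypes
#'
#' A clonotype is a clone when it holds at least `min_cells` cells; fractions
#' are computed over all non-doublet cells that entered the partition.
#' Signature-positive singletons can later be promoted via
#' [rescue_singletons()].
#'
#' @param clonotypes A `clonotype_set` from [group_clonotypes()].
#' @param min_cells Minimum cell count for clone status (default 2; 1 is
#'   degenerate and warns).
#' @param total_cells Denominator override; defaults to the partition size.
#' @return A `clone_call_result`: the clonotype table with `fraction`,
#'   `is_clone` and `rescued` columns, plus `total_cells`.
#' @export
call_clones <- function(clonotypes, min_cells = 2L, total_cells = NULL) {
  if (min_cells < 1L) stop("min_cells must be at least 1")
  if (min_cells == 1L)
    warning("min_cells = 1 flags every clonotype as a clone")
  if (is.null(total_cells)) total_cells <- attr(clonotypes, "total_cells")
  tab <- as.data.frame(clonotypes)
  tab$fraction <- if (total_cells > 0) tab$n_cells / total_cells else numeric(nrow(tab))
  tab$is_clone <- tab$n_cells >= min_cells
  tab$rescued <- rep(FALSE, nrow(tab))
  structure(list(clonotypes = tab, total_cells = total_cells,
                 min_cells = as.integer(min_cells)),
            class = "clone_call_result")
}

#' @export
print.clone_call_result <- function(x, ...) {
  cl <- x$clonotypes[x$clonotypes$is_clone, , drop = FALSE]
  cat(sprintf("<clone_call_result> %d clonotypes over %d cells; %d clone(s)\n",
              nrow(x$clonotypes), x$total_cells, nrow(cl)))
  if (nrow(cl))
    print(cl[, c("clonotype_id", "v_call", "j_call", "junction_aa",
                 "n_cells", "fraction", "rescued")], row.names = FALSE)
  invisible(x)
}

#' Clonotype frequencies in a bulk repertoire library
#'
#' Every read is annotated like a cell transcript (best V, best J, junction
#' between the IMGT anchors); the frequency of a clonotype key is the number
#' of reads carrying it divided by all assignable reads. Identical reads are
#' annotated once and weighted by multiplicity.
#'
#' @param reads A `bulk_reads` object or named character vector of reads.
#' @param refs A `germline_reference`.
#' @param min_identity Identity floor for segment calls.
#' @return A data.frame `v_call`, `j_call`, `junction`, `n_reads`,
#'   `frequency`, sorted by frequency; attributes `total_reads` and
#'   `assignable_reads`.
#' @export
bulk_repertoire_frequencies <- function(reads, refs, min_identity = 0.8) {
  seqs <- if (inherits(reads, "bulk_reads")) reads$reads else reads
  if (!length(seqs)) stop("no reads supplied")
  uniq <- table(seqs)
  ann <- lapply(names(uniq), function(s) {
    ch <- .annotate_transcript(s, "read", refs, min_identity, .DEFAULT_SCORING)
    if (is.null(ch) || is.na(ch$junction) || is.na(ch$j_call)) return(NULL)
    data.frame(v_call = ch$v_call, j_call = ch$j_call,
               junction = ch$junction, n = as.integer(uniq[[s]]),
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, Filter(Negate(is.null), ann))
  if (is.null(ann) || !nrow(ann)) stop("no assignable reads in the library")
  key <- paste(ann$v_call, ann$j_call, ann$junction, sep = "|")
  agg <- rowsum(ann$n, key)
  total_assignable <- sum(agg)
  first <- !duplicated(key)
  out <- data.frame(v_call = ann$v_call[first], j_call = ann$j_call[first],
                    junction = ann$junction[first],
                    n_reads = as.integer(agg[match(key[first], rownames(agg)), 1]),
                    stringsAsFactors = FALSE)
  out$frequency <- out$n_reads / total_assignable
  out <- out[order(-out$n_reads, out$junction), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, total_reads = length(seqs),
            assignable_reads = total_assignable)
}

#' Concordance between single-cell clone fractions and bulk read frequencies
#'
#' Pairs clonotypes on their `(v_call, j_call, junction)` key and reports the
#' paired fractions with a Pearson correlation. With fewer than 3 pairs the
#' correlation is reported as absent. Tables from several cohorts/patients
#' can be concatenated (prefix the junctions or pass a `cohort` column to
#' keep keys distinct).
#'
#' @param sc A `clone_call_result`, or a data.frame with `v_call`, `j_call`,
#'   `junction`, `fraction`.
#' @param bulk Output of [bulk_repertoire_frequencies()], or a data.frame
#'   with the same key columns and a `frequency` column.
#' @return List with `pairs` (data.frame of paired fractions), `r` (Pearson
#'   correlation, `NA` when undefined) and `n_pairs`.
#' @export
compare_sc_bulk <- function(sc, bulk) {
  sc_tab <- if (inherits(sc, "clone_call_result")) sc$clonotypes else sc
  stopifnot(all(c("v_call", "j_call", "junction", "fraction") %in%
                colnames(sc_tab)),
            all(c("v_call", "j_call", "junction", "frequency") %in%
                colnames(bulk)))
  sk <- paste(sc_tab$v_call, sc_tab$j_call, sc_tab$junction, sep = "|")
  bk <- paste(bulk$v_call, bulk$j_call, bulk$junction, sep = "|")
  common <- intersect(sk, bk)
  pairs <- data.frame(
    v_call = sc_tab$v_call[match(common, sk)],
    junction = sc_tab$junction[match(common, sk)],
    sc_fraction = sc_tab$fraction[match(common, sk)],
    bulk_fraction = bulk$frequency[match(common, bk)],
    stringsAsFactors = FALSE)
  r <- if (nrow(pairs) >= 3L) cor(pairs$sc_fraction, pairs$bulk_fraction)
       else NA_real_
  list(pairs = pairs, r = r, n_pairs = nrow(pairs))
}
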