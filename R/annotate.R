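# Per-cell chain annotation: V/J assignment, IMGT numbering, CDR3/junction
# extraction. Replaces an external VDJ annotator with a transparent,
# oracle-testable implementation.

#' Project an aligned transcript onto IMGT unique numbering
#'
#' Each transcript codon inherits the IMGT position of the germline codon it
#' aligns to; positions are derived from the gapped germline template.
#' Insertions relative to germline are excluded; deleted or uncovered
#' germline codons leave their positions absent. Codons broken by an indel
#' are skipped.
#'
#' @param transcript Nucleotide string.
#' @param v_aln Top V alignment row (from [align_to_segments()] /
#'   [top_alignment()]).
#' @param ref The matching V `germline_segment`.
#' @param map Optional precomputed germline-to-query coordinate map (reused
#'   internally to avoid recomputation).
#' @return Named character vector: IMGT position -> amino acid.
#' @export
imgt_number <- function(transcript, v_aln, ref, map = NULL) {
  if (is.null(v_aln)) return(setNames(character(0), character(0)))
  stopifnot(v_aln$segment == ref$name)
  ung_len <- nchar(seg_ungapped(ref))
  if (is.null(map)) map <- .ref_to_query_map(v_aln, ung_len)
  imgt <- seg_imgt_positions(ref)
  ci <- seq_along(imgt)
  q1 <- map[3L * ci - 2L]; q2 <- map[3L * ci - 1L]; q3 <- map[3L * ci]
  ok <- !is.na(q1) & !is.na(q2) & !is.na(q3) & q2 == q1 + 1L & q3 == q2 + 1L
  if (!any(ok)) return(setNames(character(0), character(0)))
  codons <- substring(transcript, q1[ok], q3[ok])
  aa <- unname(.genetic_code()[codons])
  aa[is.na(aa)] <- "X"
  setNames(aa, as.character(imgt[ok]))
}

#' Extract the CDR3 and junction between the IMGT anchors
#'
#' The CDR3 is the codon run strictly between the conserved V Cys-104 and the
#' J Phe/Trp-118, located by mapping the germline anchor positions through
#' the V and J alignments. The junction (anchors included) is also returned;
#' clonotype identity downstream uses the junction nucleotide string.
#'
#' @param transcript Nucleotide string.
#' @param v_aln,j_aln Top alignment rows for the V and J segment.
#' @param v_ref,j_ref The matching `germline_segment`s.
#' @param vmap,jmap Optional precomputed coordinate maps.
#' @return List with `cdr3_nt`, `cdr3_aa`, `junction`, `junction_aa`,
#'   `productive`, `needs_review` and `reason`.
#' @export
extract_cdr3 <- function(transcript, v_aln, j_aln, v_ref, j_ref,
                         vmap = NULL, jmap = NULL) {
  fail <- function(reason) list(cdr3_nt = NA_character_, cdr3_aa = NA_character_,
                                junction = NA_character_,
                                junction_aa = NA_character_,
                                productive = FALSE, needs_review = FALSE,
                                reason = reason)
  if (is.null(v_aln) || is.null(j_aln)) return(fail("missing_alignment"))
  cys <- v_ref$anchors[["CYS104"]]
  if (is.null(vmap)) vmap <- .ref_to_query_map(v_aln, nchar(seg_ungapped(v_ref)))
  if (cys + 2L > length(vmap)) return(fail("cys104_not_covered"))
  q104 <- vmap[cys:(cys + 2L)]
  if (anyNA(q104) || q104[3] != q104[1] + 2L) return(fail("cys104_not_covered"))
  phe <- j_ref$anchors[["JPHE118"]]
  if (is.null(jmap)) jmap <- .ref_to_query_map(j_aln, nchar(seg_ungapped(j_ref)))
  if (phe + 2L > length(jmap)) return(fail("j_anchor_not_covered"))
  q118 <- jmap[phe:(phe + 2L)]
  if (anyNA(q118) || q118[3] != q118[1] + 2L) return(fail("j_anchor_not_covered"))
  if (q118[1] == q104[3] + 1L) {
    # anchors adjacent: degenerate empty CDR3, flagged for manual review
    junction <- substr(transcript, q104[1], q118[3])
    return(list(cdr3_nt = "", cdr3_aa = "", junction = junction,
                junction_aa = translate_dna(junction),
                productive = FALSE, needs_review = TRUE,
                reason = "empty_cdr3"))
  }
  if (q118[1] <= q104[3]) return(fail("anchors_out_of_order"))
  cdr3_nt <- substr(transcript, q104[3] + 1L, q118[1] - 1L)
  junction <- substr(transcript, q104[1], q118[3])
  in_frame <- nchar(cdr3_nt) %% 3L == 0L
  junction_aa <- if (in_frame) translate_dna(junction) else NA_character_
  cdr3_aa <- if (in_frame) translate_dna(cdr3_nt) else NA_character_
  aa104 <- unname(.genetic_code()[substr(transcript, q104[1], q104[3])])
  productive <- in_frame && !is.na(aa104) && aa104 == "C" &&
    !grepl("*", junction_aa, fixed = TRUE)
  list(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa, junction = junction,
       junction_aa = junction_aa, productive = productive,
       needs_review = FALSE,
       reason = if (in_frame) NA_character_ else "out_of_frame")
}

.annotate_transcript <- function(tx, tx_id, refs, min_identity, scoring) {
  v_alns <- align_to_segments(tx, refs, "V", scoring = scoring,
                              min_identity = min_identity)
  v_top <- top_alignment(v_alns)
  if (is.null(v_top)) return(NULL)
  v_ref <- refs[[v_top$segment]]
  locus <- v_ref$locus
  j_alns <- align_to_segments(tx, refs, "J", locus = locus, scoring = scoring,
                              min_identity = min_identity)
  j_top <- top_alignment(j_alns)
  j_ref <- if (is.null(j_top)) NULL else refs[[j_top$segment]]
  vmap <- .ref_to_query_map(v_top, nchar(seg_ungapped(v_ref)))
  jmap <- if (is.null(j_top)) NULL
          else .ref_to_query_map(j_top, nchar(seg_ungapped(j_ref)))
  cdr3 <- extract_cdr3(tx, v_top, j_top, v_ref, j_ref, vmap, jmap)
  imgt_aa <- imgt_number(tx, v_top, v_ref, vmap)
  structure(list(transcript_id = tx_id, transcript_length = nchar(tx),
                 locus = locus,
                 v_call = v_top$segment,
                 j_call = if (is.null(j_top)) NA_character_ else j_top$segment,
                 v_score = v_top$score, v_identity = v_top$identity,
                 cdr3_nt = cdr3$cdr3_nt, cdr3_aa = cdr3$cdr3_aa,
                 junction = cdr3$junction, junction_aa = cdr3$junction_aa,
                 imgt_aa = imgt_aa,
                 productive = cdr3$productive,
                 needs_review = cdr3$needs_review,
                 reason = cdr3$reason,
                 doublet = FALSE),
            class = "chain_annotation")
}

#' @export
print.chain_annotation <- function(x, ...) {
  cat(sprintf("<chain_annotation> %s %s: %s / %s, junction %s (%s)%s\n",
              if (is.null(x$cell_id)) "" else x$cell_id, x$locus, x$v_call,
              x$j_call, x$junction_aa,
              if (isTRUE(x$productive)) "productive" else "non-productive",
              if (isTRUE(x$doublet)) " [doublet]" else ""))
  invisible(x)
}

#' Annotate one cell's transcripts
#'
#' Each transcript is assigned to a locus via its best V hit; per locus the
#' transcript with the highest V alignment score wins (ties broken by longer
#' transcript, then transcript id). Cells presenting two distinct productive
#' light-chain junctions are flagged as suspected doublets; cells with no
#' assignable chain return an empty list (annotated `no_chain` at cohort
#' level and excluded downstream).
#'
#' @param transcripts Named character vector of the cell's transcript
#'   sequences.
#' @param refs A `germline_reference`.
#' @param cell_id Cell barcode attached to each annotation.
#' @param min_identity Identity floor for segment calls.
#' @param scoring Alignment scoring scheme (see [align_to_segments()]).
#' @return List of `chain_annotation` objects, at most one per locus.
#' @export
annotate_cell <- function(transcripts, refs, cell_id = "cell",
                          min_identity = 0.8, scoring = .DEFAULT_SCORING) {
  if (!length(transcripts)) stop("at least one transcript is required")
  if (is.null(names(transcripts)))
    names(transcripts) <- sprintf("tx%d", seq_along(transcripts))
  cands <- Filter(Negate(is.null),
                  lapply(names(transcripts), function(id)
                    .annotate_transcript(transcripts[[id]], id, refs,
                                         min_identity, scoring)))
  if (!length(cands)) return(list())
  loci <- vapply(cands, `[[`, "", "locus")
  out <- list()
  for (loc in unique(loci)) {
    sub <- cands[loci == loc]
    ord <- order(-vapply(sub, `[[`, 0, "v_score"),
                 -vapply(sub, `[[`, 0L, "transcript_length"),
                 vapply(sub, `[[`, "", "transcript_id"))
    best <- sub[[ord[1]]]
    if (loc %in% c("IGL", "IGK")) {
      junc <- vapply(sub, `[[`, "", "junction")
      prod <- vapply(sub, function(ch) isTRUE(ch$productive), TRUE)
      if (length(unique(junc[prod & !is.na(junc)])) >= 2L) best$doublet <- TRUE
    }
    best$cell_id <- cell_id
    out[[loc]] <- best
  }
  out
}

#' Annotate every cell of a cohort
#'
#' @param x A `sim_cohort`, or a named list of per-cell transcript vectors.
#' @param refs A `germline_reference`.
#' @param ... Passed to [annotate_cell()].
#' @return A `cell_annotations` object: `$chains` (list of
#'   `chain_annotation`), `$table` (AIRR-style rearrangement data.frame, one
#'   row per chain) and `$no_chain` (barcodes with no assignable chain).
#' @export
annotate_cohort <- function(x, refs, ...) {
  cells <- if (inherits(x, "sim_cohort")) x$transcripts else x
  stopifnot(is.list(cells), !is.null(names(cells)))
  chains <- list()
  no_chain <- character(0)
  for (bc in names(cells)) {
    ann <- annotate_cell(cells[[bc]], refs, cell_id = bc, ...)
    if (!length(ann)) no_chain <- c(no_chain, bc) else
      chains <- c(chains, unname(ann))
  }
  structure(list(chains = chains, table = .chains_to_table(chains),
                 no_chain = no_chain),
            class = "cell_annotations")
}

.chains_to_table <- function(chains) {
  if (!length(chains))
    return(data.frame(cell_id = character(), locus = character(),
                      v_call = character(), j_call = character(),
                      junction = character(), junction_aa = character(),
                      cdr3_aa = character(), v_identity = numeric(),
                      productive = logical(), doublet = logical(),
                      stringsAsFactors = FALSE))
  grab <- function(f, mode) vapply(chains, function(ch) {
    v <- ch[[f]]
    if (is.null(v) || !length(v)) v <- NA
    as.vector(v, mode)
  }, vector(mode, 1))
  df <- data.frame(cell_id = grab("cell_id", "character"),
                   locus = grab("locus", "character"),
                   v_call = grab("v_call", "character"),
                   j_call = grab("j_call", "character"),
                   junction = grab("junction", "character"),
                   junction_aa = grab("junction_aa", "character"),
                   cdr3_aa = grab("cdr3_aa", "character"),
                   v_identity = grab("v_identity", "numeric"),
                   productive = grab("productive", "logical"),
                   doublet = grab("doublet", "logical"),
                   stringsAsFactors = FALSE)
  # a doublet call on the light chain marks the whole cell
  dbl <- unique(df$cell_id[df$doublet])
  df$doublet <- df$cell_id %in% dbl
  df
}

#' @export
print.cell_annotations <- function(x, ...) {
  cat(sprintf("<cell_annotations> %d chains across %d cells (%d no_chain, %d doublet)\n",
              nrow(x$table), length(unique(x$table$cell_id)),
              length(x$no_chain), length(unique(x$table$cell_id[x$table$doublet]))))
  invisible(x)
}
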