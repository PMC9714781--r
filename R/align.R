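# Local alignment of transcripts against ungapped germline segments.
# The engine is a Smith-Waterman-Gotoh in C++ (src/align.cpp); this file
# ranks hits and turns CIGAR strings into coordinate maps.

.DEFAULT_SCORING <- list(match = 2L, mismatch = -2L,
                         gap_open = 6L, gap_ext = 1L)

#' Align a transcript to germline segments of one class
#'
#' Performs local alignment (affine gaps) of the transcript against the
#' ungapped sequence of every reference segment of the requested class, and
#' ranks hits by score (ties broken lexicographically by allele name). The
#' top hit is the segment call; if its identity falls below `min_identity`
#' the transcript is reported unassigned (an attribute, not an error).
#'
#' @param transcript Nucleotide string. Minimum length 50 nt for V search,
#'   15 nt for J search (shorter input is unassigned).
#' @param refs A `germline_reference`.
#' @param segment_class `"V"` or `"J"`.
#' @param locus Optional locus restriction.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_ext`.
#'   A gap of length L costs `gap_open + L * gap_ext`.
#' @param min_identity Identity floor for a call (fraction of alignment
#'   columns that match), default 0.8.
#' @return A data.frame of class `segment_alignments`, one row per reference,
#'   sorted best-first, with columns `segment`, `score`, `qstart`, `qend`,
#'   `sstart`, `send` (0-based, half-open), `identity`, `cigar`. Attribute
#'   `assigned` is `FALSE` when no hit clears the floor.
#' @export
align_to_segments <- function(transcript, refs,
                              segment_class = c("V", "J"),
                              locus = NULL,
                              scoring = .DEFAULT_SCORING,
                              min_identity = 0.8) {
  segment_class <- segment_class[1L]
  stopifnot(segment_class %in% c("V", "J"))
  refs <- ref_subset(refs, segment_class, locus)
  if (!length(refs)) stop("no reference segments of class ", segment_class)
  min_len <- if (segment_class == "V") 50L else 15L
  if (is.na(transcript) || nchar(transcript) < min_len) {
    empty <- .fast_df(list(segment = character(), score = integer(),
                           qstart = integer(), qend = integer(),
                           sstart = integer(), send = integer(),
                           identity = numeric(), cigar = character()))
    return(structure(empty, assigned = FALSE, class = c("segment_alignments",
                                                        "data.frame")))
  }
  a <- .sw_align_multi(transcript,
                       vapply(refs, seg_ungapped, ""),
                       scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_ext)
  nms <- unname(vapply(refs, `[[`, "", "name"))
  ord <- order(-a$score, nms)
  out <- .fast_df(list(segment = nms[ord],
                       score = a$score[ord],
                       qstart = a$qstart[ord], qend = a$qend[ord],
                       sstart = a$sstart[ord], send = a$send[ord],
                       identity = (a$matches / pmax(a$aln_length, 1L))[ord],
                       cigar = a$cigar[ord]))
  structure(out, assigned = nrow(out) > 0 && out$identity[1] >= min_identity,
            class = c("segment_alignments", "data.frame"))
}

#' Best alignment from a ranked hit table
#' @param alns A `segment_alignments` table.
#' @return The top row, or `NULL` when the transcript is unassigned.
#' @export
top_alignment <- function(alns) {
  if (!isTRUE(attr(alns, "assigned"))) return(NULL)
  alns[1L, , drop = FALSE]
}

# data.frame construction without the deparse/validation overhead of
# data.frame(); columns must already be equal-length atomic vectors
.fast_df <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1]])))
}

# Expand a CIGAR over {M,I,D} into per-column query/ref coordinates.
# Returns a list of 1-based qpos/spos vectors; NA where a side is gapped.
.alignment_columns <- function(aln) {
  ops <- regmatches(aln$cigar, gregexpr("\\d+[MID]", aln$cigar))[[1]]
  lens <- as.integer(sub("[MID]$", "", ops))
  kind <- substr(ops, nchar(ops), nchar(ops))
  total <- sum(lens)
  qpos <- integer(total); spos <- integer(total)
  q <- aln$qstart; s <- aln$sstart  # 0-based starts
  at <- 0L
  for (i in seq_along(ops)) {
    L <- lens[i]; idx <- at + seq_len(L)
    if (kind[i] == "M") {
      qpos[idx] <- q + seq_len(L); spos[idx] <- s + seq_len(L)
      q <- q + L; s <- s + L
    } else if (kind[i] == "I") {
      qpos[idx] <- q + seq_len(L); spos[idx] <- NA_integer_
      q <- q + L
    } else {
      qpos[idx] <- NA_integer_; spos[idx] <- s + seq_len(L)
      s <- s + L
    }
    at <- at + L
  }
  list(qpos = qpos, spos = spos)
}

# query position (1-based) aligned to each 1-based ref position; NA when the
# ref position is deleted or outside the aligned interval
.ref_to_query_map <- function(aln, ref_len) {
  cols <- .alignment_columns(aln)
  map <- rep(NA_integer_, ref_len)
  ok <- !is.na(cols$spos) & !is.na(cols$qpos)
  map[cols$spos[ok]] <- cols$qpos[ok]
  map
}

# Reference R implementation of the same scoring scheme, O(nm) over the three
# Gotoh matrices, score only. Used as an independent oracle in the tests;
# kept in the package namespace so the tests exercise the installed build.
.sw_score_r <- function(query, ref, match = 2, mismatch = -2,
                        gap_open = 6, gap_ext = 1) {
  q <- strsplit(query, "")[[1]]; s <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(s); oc <- gap_open + gap_ext
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i, j + 1] - oc, E[i, j + 1] - gap_ext)
      F_[i + 1, j + 1] <- max(H[i + 1, j] - oc, F_[i + 1, j] - gap_ext)
      sc <- H[i, j] + if (q[i] == s[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, sc, E[i + 1, j + 1], F_[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}
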