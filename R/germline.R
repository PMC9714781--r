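# Germline V/J scaffolds with IMGT-conforming anchor structure.
#
# Scaffolds are synthetic sequences, not database alleles: only the names,
# the gapped-alignment layout and the conserved anchor residues (1st-CYS 23,
# Trp 41, 2nd-CYS 104 on V; Phe 118 / F-G-X-G on J) follow the IMGT
# convention. That is all the downstream algorithms rely on.

# IMGT positions absent from every V scaffold (shared gap pattern, so all
# gapped V sequences have the same length, as in a real IMGT alignment)
.IMGT_V_GAPS <- c(10L, 32L, 33L, 34L, 60L, 61L, 81L, 82L)
.IMGT_V_LEN <- 104L

.CONSERVED_V <- c("23" = "C", "41" = "W", "104" = "C")

# germline residues at the signature positions 38 (CDR1) and 40 (FR2) for
# the four lambda families carrying the disease signature
.FAMILY_3840 <- list(
  "IGLV1-36" = c("38" = "S", "40" = "H"),
  "IGLV1-40" = c("38" = "D", "40" = "H"),
  "IGLV1-44" = c("38" = "T", "40" = "H"),
  "IGLV1-47" = c("38" = "Y", "40" = "Y"))

.AA_POOL <- setdiff(strsplit("ARNDQEGHILKMFPSTWYV", "")[[1]], "C")

.ct_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.ct_env$gc)) .ct_env$gc <- Biostrings::GENETIC_CODE
  .ct_env$gc
}

.codons_for_aa <- function() {
  if (is.null(.ct_env$by_aa)) {
    gc <- .genetic_code()
    .ct_env$by_aa <- split(names(gc), unname(gc))
  }
  .ct_env$by_aa
}

#' Translate a nucleotide string
#'
#' Frame 1 translation using the standard genetic code; trailing partial
#' codons are dropped. Stop codons are rendered as `*`.
#'
#' @param nt A nucleotide string over `A`, `C`, `G`, `T`.
#' @return An amino-acid string.
#' @export
translate_dna <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  aa <- .genetic_code()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.random_codon <- function(aa) {
  pool <- .codons_for_aa()[[aa]]
  pool[sample.int(length(pool), 1L)]
}

#' Construct a germline segment
#'
#' @param name Allele identifier, e.g. `"IGLV1-44*01"` or `"IGLJ3*02"`.
#' @param gapped_seq Nucleotide string over `{A,C,G,T,.}`; `.` marks an IMGT
#'   alignment gap (whole gapped codons only).
#' @param segment_class `"V"` or `"J"`.
#' @param anchors Named integer vector of anchor positions (1-based, in the
#'   ungapped sequence): `CYS104` for V segments; `JPHE118` and `FGXG` for J.
#' @param locus `"IGL"`, `"IGK"` or `"IGH"`.
#' @return An object of class `germline_segment`.
#' @export
germline_segment <- function(name, gapped_seq, segment_class = c("V", "J"),
                             anchors, locus = "IGL") {
  segment_class <- match.arg(segment_class)
  ung <- gsub(".", "", gapped_seq, fixed = TRUE)
  if (nchar(ung) %% 3L != 0L)
    stop("ungapped sequence of ", name, " is not codon-framed")
  if (!grepl("^[ACGT.]+$", gapped_seq))
    stop("gapped_seq must be over {A,C,G,T,.}")
  if (segment_class == "V") {
    stopifnot("CYS104" %in% names(anchors))
    cys <- substr(ung, anchors[["CYS104"]], anchors[["CYS104"]] + 2L)
    if (.genetic_code()[[cys]] != "C")
      stop("V segment ", name, ": codon at CYS104 anchor does not encode Cys")
  } else {
    stopifnot(all(c("JPHE118", "FGXG") %in% names(anchors)))
  }
  n_codon <- nchar(gapped_seq) %/% 3L
  codons <- substring(gapped_seq, seq(1L, by = 3L, length.out = n_codon),
                      seq(3L, by = 3L, length.out = n_codon))
  structure(list(name = name, gapped_seq = gapped_seq,
                 segment_class = segment_class,
                 anchors = anchors, locus = locus,
                 # cached derived views (hot paths)
                 ungapped = ung, imgt_positions = which(codons != "...")),
            class = "germline_segment")
}

#' @export
print.germline_segment <- function(x, ...) {
  cat(sprintf("<germline_segment> %s (%s, %s), %d nt ungapped\n",
              x$name, x$segment_class, x$locus, nchar(seg_ungapped(x))))
  invisible(x)
}

#' Ungapped sequence of a germline segment
#' @param seg A `germline_segment`.
#' @return Nucleotide string with IMGT gaps removed.
#' @export
seg_ungapped <- function(seg) {
  if (!is.null(seg$ungapped)) seg$ungapped
  else gsub(".", "", seg$gapped_seq, fixed = TRUE)
}

#' IMGT position of each ungapped codon of a V segment
#'
#' Positions are recovered by counting codons along the gapped sequence,
#' gaps included; codon `i` of the ungapped sequence inherits the IMGT number
#' of the gapped codon it came from.
#'
#' @param seg A `germline_segment` of class V.
#' @return Integer vector, one IMGT position per ungapped codon.
#' @export
seg_imgt_positions <- function(seg) {
  if (!is.null(seg$imgt_positions)) return(seg$imgt_positions)
  n <- nchar(seg$gapped_seq) %/% 3L
  codons <- substring(seg$gapped_seq, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  which(codons != "...")
}

#' Germline amino acids by IMGT position
#' @param seg A `germline_segment` of class V.
#' @return Named character vector (names are IMGT positions).
#' @export
seg_aa <- function(seg) {
  aa <- strsplit(translate_dna(seg_ungapped(seg)), "")[[1]]
  setNames(aa, as.character(seg_imgt_positions(seg)))
}

.make_v_scaffold <- function(name, locus, aa3840 = NULL) {
  pos <- setdiff(seq_len(.IMGT_V_LEN), .IMGT_V_GAPS)
  aa <- setNames(sample(.AA_POOL, length(pos), replace = TRUE),
                 as.character(pos))
  aa[names(.CONSERVED_V)] <- .CONSERVED_V
  if (!is.null(aa3840)) aa[names(aa3840)] <- aa3840
  codons <- vapply(aa, .random_codon, character(1))
  gapped <- character(.IMGT_V_LEN)
  gapped[.IMGT_V_GAPS] <- "..."
  gapped[pos] <- codons
  cys_codon_idx <- sum(pos <= 104L)  # ungapped codon index of IMGT 104
  germline_segment(name, paste(gapped, collapse = ""), "V",
                   anchors = c(CYS104 = 3L * cys_codon_idx - 2L),
                   locus = locus)
}

.make_j_scaffold <- function(name, locus) {
  # starts exactly at Phe 118, then the F-G-X-G motif and a short FR4 tail
  aa <- c("F", "G", sample(.AA_POOL, 1L), "G",
          sample(.AA_POOL, 6L, replace = TRUE))
  codons <- vapply(aa, .random_codon, character(1))
  codons[1] <- "TTC"  # fix Phe codon so the anchor is stable across alleles
  germline_segment(name, paste(codons, collapse = ""), "J",
                   anchors = c(JPHE118 = 1L, FGXG = 1L), locus = locus)
}

#' Build a synthetic germline reference
#'
#' Generates V and J scaffolds with valid IMGT anchor structure: every V
#' translates to Cys at IMGT position 104 and shares one gap pattern (so all
#' gapped V sequences have equal length); every J starts at the conserved
#' Phe 118 of an F-G-X-G motif. The reference always contains the four lambda
#' families `IGLV1-36/-40/-44/-47` that carry the light-chain signature;
#' additional V scaffolds get filler names. Sequences are random scaffolds —
#' only names and anchor layout follow the IMGT convention.
#'
#' @param v_count Number of lambda V scaffolds (at least 4).
#' @param j_alleles Character vector of lambda J allele names.
#' @param seed Integer seed; fixes every sequence byte.
#' @param include_heavy Also generate heavy-chain (IGH) V/J scaffolds so
#'   cohorts can carry paired chains.
#' @param heavy_v_count,heavy_j_alleles Heavy-chain reference size/names.
#' @return A `germline_reference`: list of [germline_segment] objects.
#' @export
build_germline_reference <- function(v_count = 4L,
                                     j_alleles = "IGLJ3*02",
                                     seed = 1L,
                                     include_heavy = TRUE,
                                     heavy_v_count = 2L,
                                     heavy_j_alleles = "IGHJ4*01") {
  if (v_count < 4L)
    stop("v_count must be >= 4: the signature families IGLV1-36/-40/-44/-47 ",
         "are always included")
  set.seed(as.integer(seed))
  fams <- names(.FAMILY_3840)
  v_names <- c(paste0(fams, "*01"),
               if (v_count > 4L) sprintf("IGLV5-%02d*01", seq_len(v_count - 4L)))
  segs <- vector("list", 0L)
  for (i in seq_along(v_names)) {
    fam <- sub("\\*.*$", "", v_names[i])
    segs[[v_names[i]]] <-
      .make_v_scaffold(v_names[i], "IGL", .FAMILY_3840[[fam]])
  }
  for (j in j_alleles) segs[[j]] <- .make_j_scaffold(j, "IGL")
  if (include_heavy) {
    hv <- sprintf("IGHV1-%02d*01", seq_len(heavy_v_count))
    for (h in hv) segs[[h]] <- .make_v_scaffold(h, "IGH")
    for (h in heavy_j_alleles) segs[[h]] <- .make_j_scaffold(h, "IGH")
  }
  structure(segs, class = "germline_reference")
}

#' @export
print.germline_reference <- function(x, ...) {
  cls <- vapply(x, `[[`, "", "segment_class")
  loc <- vapply(x, `[[`, "", "locus")
  cat(sprintf("<germline_reference> %d segments (%s)\n", length(x),
              paste(names(table(paste(loc, cls))), table(paste(loc, cls)),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Subset a germline reference by segment class and/or locus
#' @param ref A `germline_reference`.
#' @param segment_class Optional `"V"` or `"J"`.
#' @param locus Optional locus filter.
#' @return A `germline_reference` with the matching segments.
#' @export
ref_subset <- function(ref, segment_class = NULL, locus = NULL) {
  keep <- rep(TRUE, length(ref))
  if (!is.null(segment_class))
    keep <- keep & vapply(ref, `[[`, "", "segment_class") %in% segment_class
  if (!is.null(locus))
    keep <- keep & vapply(ref, `[[`, "", "locus") %in% locus
  structure(ref[keep], class = "germline_reference")
}

#' Write a germline reference as gapped FASTA
#'
#' IMGT gaps are kept as `.` characters; anchor positions are carried in the
#' header so the file round-trips through [read_germline_fasta()].
#'
#' @param ref A `germline_reference`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(ref, path) {
  lines <- unlist(lapply(ref, function(s) {
    anch <- paste(names(s$anchors), s$anchors, sep = ":", collapse = ",")
    c(sprintf(">%s class=%s locus=%s anchors=%s",
              s$name, s$segment_class, s$locus, anch),
      s$gapped_seq)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gapped germline FASTA written by [write_germline_fasta()]
#' @param path File path.
#' @return A `germline_reference`.
#' @export
read_germline_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  segs <- lapply(seq_along(hdr), function(i) {
    h <- sub("^>", "", lines[hdr[i]])
    parts <- strsplit(h, " ")[[1]]
    fields <- sub("^[a-z]+=", "", parts[-1])
    names(fields) <- sub("=.*$", "", parts[-1])
    anch_parts <- strsplit(strsplit(fields[["anchors"]], ",")[[1]], ":")
    anchors <- setNames(as.integer(vapply(anch_parts, `[`, "", 2)),
                        vapply(anch_parts, `[`, "", 1))
    to <- if (i < length(hdr)) hdr[i + 1] - 1L else length(lines)
    seq <- paste(lines[(hdr[i] + 1L):to], collapse = "")
    germline_segment(parts[1], seq, fields[["class"]], anchors,
                     fields[["locus"]])
  })
  names(segs) <- vapply(segs, `[[`, "", "name")
  structure(segs, class = "germline_reference")
}
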