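# Germline substitution calling on IMGT coordinates and the lambda
# light-chain signature: V family IGLV1-36/-40/-44/-47, J allele IGLJ3*02,
# position 40 mutated to asparagine and position 38 to a nonpolar residue.

.SIGNATURE_V_FAMILIES <- c("IGLV1-36", "IGLV1-40", "IGLV1-44", "IGLV1-47")
.SIGNATURE_J_ALLELE <- "IGLJ3*02"
.NONPOLAR_AA <- c("G", "A", "V", "L", "I", "P", "F", "M", "W")

#' Call amino-acid substitutions relative to germline
#'
#' Compares the chain's IMGT-numbered amino acids with the germline template
#' of its V call, over the covered positions only.
#'
#' @param chain A `chain_annotation` with an `imgt_aa` map.
#' @param ref The `germline_segment` matching the chain's `v_call`.
#' @return A `substitution_profile`: data.frame (`position`, `germline`,
#'   `observed`) plus `cell_id`, `locus`, `v_call`, `j_call` and the covered
#'   IMGT positions.
#' @export
call_substitutions <- function(chain, ref) {
  if (!identical(chain$v_call, ref$name))
    stop("chain v_call (", chain$v_call, ") does not match reference (",
         ref$name, ")")
  germ <- seg_aa(ref)
  obs <- chain$imgt_aa
  common <- intersect(names(germ), names(obs))
  diff <- common[germ[common] != obs[common]]
  diff <- diff[order(as.integer(diff))]
  structure(list(
    cell_id = chain$cell_id, locus = chain$locus,
    v_call = chain$v_call, j_call = chain$j_call,
    substitutions = data.frame(position = as.integer(diff),
                               germline = unname(germ[diff]),
                               observed = unname(obs[diff]),
                               stringsAsFactors = FALSE),
    covered = as.integer(names(obs))),
    class = "substitution_profile")
}

#' @export
print.substitution_profile <- function(x, ...) {
  cat(sprintf("<substitution_profile> %s %s (%s/%s): %d substitution(s)\n",
              x$cell_id, x$locus, x$v_call, x$j_call, nrow(x$substitutions)))
  if (nrow(x$substitutions)) print(x$substitutions, row.names = FALSE)
  invisible(x)
}

#' Classify the POEMS light-chain signature
#'
#' Evidence flags: `v_family_ok` (V gene in IGLV1-36/-40/-44/-47, allele
#' agnostic), `j_ok` (J allele exactly IGLJ3*02), `pos40_asn` (position 40
#' substituted to Asn — the change is invariably asparagine), and
#' `pos38_nonpolar` (position 38 substituted to one of G, A, V, L, I, P, F,
#' M, W). Strict mode requires all four; `either` mode accepts either
#' position change alongside the V/J requirements. Positions 38/40 not
#' covered by the chain leave the corresponding flag `FALSE` with a coverage
#' warning recorded in the call.
#'
#' @param profile A `substitution_profile`.
#' @param rule_mode `"strict"` (default) or `"either"`.
#' @return A `signature_call`: `verdict` (logical), the evidence flags,
#'   `rule_mode` and `coverage_warning`.
#' @export
classify_poems_signature <- function(profile,
                                     rule_mode = c("strict", "either")) {
  rule_mode <- match.arg(rule_mode)
  subs <- profile$substitutions
  v_family <- sub("\\*.*$", "", profile$v_call %||% "")
  v_family_ok <- v_family %in% .SIGNATURE_V_FAMILIES
  j_ok <- identical(profile$j_call, .SIGNATURE_J_ALLELE)
  at <- function(p) subs$observed[match(p, subs$position)]
  pos40_asn <- !is.na(at(40L)) && at(40L) == "N"
  pos38_nonpolar <- !is.na(at(38L)) && at(38L) %in% .NONPOLAR_AA
  coverage_warning <- !all(c(38L, 40L) %in% profile$covered)
  verdict <- if (rule_mode == "strict")
    v_family_ok && j_ok && pos40_asn && pos38_nonpolar
  else
    v_family_ok && j_ok && (pos40_asn || pos38_nonpolar)
  structure(list(cell_id = profile$cell_id, verdict = verdict,
                 v_family_ok = v_family_ok, j_ok = j_ok,
                 pos40_asn = pos40_asn, pos38_nonpolar = pos38_nonpolar,
                 rule_mode = rule_mode,
                 coverage_warning = coverage_warning),
            class = "signature_call")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.signature_call <- function(x, ...) {
  cat(sprintf(paste0("<signature_call> %s: %s (v_family=%s j=%s 40N=%s ",
                     "38nonpolar=%s, mode=%s)%s\n"),
              x$cell_id %||% "?",
              if (x$verdict) "POSITIVE" else "negative",
              x$v_family_ok, x$j_ok, x$pos40_asn, x$pos38_nonpolar,
              x$rule_mode,
              if (x$coverage_warning) " [incomplete 38/40 coverage]" else ""))
  invisible(x)
}

#' Signature-call every light chain of an annotated cohort
#'
#' @param annotations A `cell_annotations` object.
#' @param refs A `germline_reference`.
#' @param rule_mode Passed to [classify_poems_signature()].
#' @return data.frame, one row per light chain: cell id, calls, position
#'   38/40 observations, evidence flags and verdict.
#' @export
signature_screen <- function(annotations, refs,
                             rule_mode = c("strict", "either")) {
  rule_mode <- match.arg(rule_mode)
  light <- Filter(function(ch) ch$locus %in% c("IGL", "IGK"),
                  annotations$chains)
  rows <- lapply(light, function(ch) {
    ref <- refs[[ch$v_call]]
    prof <- call_substitutions(ch, ref)
    sig <- classify_poems_signature(prof, rule_mode)
    at <- function(p) {
      i <- match(p, prof$substitutions$position)
      if (is.na(i)) ch$imgt_aa[as.character(p)] %||% NA_character_
      else prof$substitutions$observed[i]
    }
    data.frame(cell_id = ch$cell_id, v_call = ch$v_call, j_call = ch$j_call,
               pos38 = unname(at(38L)) %||% NA_character_,
               pos40 = unname(at(40L)) %||% NA_character_,
               v_family_ok = sig$v_family_ok, j_ok = sig$j_ok,
               pos40_asn = sig$pos40_asn, pos38_nonpolar = sig$pos38_nonpolar,
               verdict = sig$verdict,
               coverage_warning = sig$coverage_warning,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = character(), v_call = character(),
                      j_call = character(), pos38 = character(),
                      pos40 = character(), v_family_ok = logical(),
                      j_ok = logical(), pos40_asn = logical(),
                      pos38_nonpolar = logical(), verdict = logical(),
                      coverage_warning = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Promote signature-positive singleton cells to putative clones
#'
#' A cell that forms a clonotype of its own but carries the full light-chain
#' signature is reported as a putative clone with fraction `1 / total cells`
#' — the single-cell-clone case that a pure count threshold would miss.
#' Cells already inside a called clone are left untouched (no double
#' counting).
#'
#' @param clone_result A `clone_call_result`.
#' @param signature_calls data.frame from [signature_screen()] (needs
#'   `cell_id` and `verdict`).
#' @return The updated `clone_call_result`; rescued clonotypes have
#'   `is_clone = TRUE` and `rescued = TRUE`.
#' @export
rescue_singletons <- function(clone_result, signature_calls) {
  stopifnot(inherits(clone_result, "clone_call_result"))
  pos_cells <- signature_calls$cell_id[signature_calls$verdict]
  tab <- clone_result$clonotypes
  for (i in seq_len(nrow(tab))) {
    if (tab$is_clone[i]) next
    if (tab$n_cells[i] == 1L && tab$members[[i]] %in% pos_cells) {
      tab$is_clone[i] <- TRUE
      tab$rescued[i] <- TRUE
    }
  }
  clone_result$clonotypes <- tab
  clone_result
}
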