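# Pseudogene diagnosis against an intact reference CDS.
#
# A candidate locus is aligned globally to the reference (free end-gaps on
# the candidate side, so fragments align within the reference), indels are
# projected to reference coordinates, and the candidate is translated
# linearly from the first in-frame aligned codon so that frameshifts
# propagate downstream exactly as they would for a ribosome. Diagnostic for
# pseudogenization: a non-zero net reading-frame offset, any premature stop
# codon, or loss of more than a configurable fraction of the reference 3'
# end. RNA editing (e.g. C-to-U rescue of apparent stops) is not modelled;
# the diagnosis is DNA-level.

STOP_CODONS <- c("TAA", "TAG", "TGA")

validate_cds <- function(reference_cds) {
  reference_cds <- clean_dna(reference_cds, "reference_cds")
  if (nchar(reference_cds) %% 3 != 0) {
    stop("reference_cds length is not a multiple of 3")
  }
  if (substr(reference_cds, 1, 3) != "ATG") {
    stop("reference_cds does not begin with a start codon (ATG)")
  }
  last <- substr(reference_cds, nchar(reference_cds) - 2, nchar(reference_cds))
  if (!last %in% STOP_CODONS) {
    stop("reference_cds does not end with a stop codon")
  }
  reference_cds
}

#' Scan a candidate locus for pseudogenization
#'
#' Aligns `candidate` to an intact reference CDS (global on the candidate,
#' local on the reference; affine gap penalties), then reports frameshift
#' indels (length not a multiple of 3) at reference coordinates, premature
#' stop codons in the frame implied by the alignment, and 3' truncation.
#'
#' Status semantics: `absent` when no alignable region of at least
#' `min_aln_len` bp at `min_identity` exists; `pseudogenized` when the net
#' frame offset over the aligned region is non-zero, a premature stop is
#' found, or more than `truncation_limit` of the reference 3' end is
#' missing; `intact` otherwise. The frame offset is cumulative, so a +1
#' insertion compensated by a downstream -1 deletion (with no stop codon in
#' the shifted segment) leaves the gene intact.
#'
#' @param candidate candidate locus sequence (may be a fragment; `""` or
#'   `NULL` reports `absent`).
#' @param reference_cds intact reference CDS: length divisible by 3,
#'   starts with ATG, ends with a stop codon.
#' @param min_identity minimum aligned identity for the locus to count as
#'   present (default 0.6).
#' @param truncation_limit fraction of the reference 3' end whose loss
#'   counts as pseudogenizing (default 0.2).
#' @param min_aln_len minimum alignable length in bp (default 30).
#' @return object of class `pseudogene_report`: `status`, `frameshifts`
#'   (data.frame `ref_pos` 0-based, `indel_len` signed), `premature_stops`
#'   (data.frame `codon_index` in the shifted reading, `ref_pos`),
#'   `truncation_3prime` (bp), `aligned_identity`, `net_frameshift`.
#' @export
scan_pseudogene <- function(candidate, reference_cds, min_identity = 0.6,
                            truncation_limit = 0.2, min_aln_len = 30) {
  reference_cds <- validate_cds(reference_cds)
  reflen <- nchar(reference_cds)
  report <- function(status, frameshifts = NULL, stops = NULL,
                     trunc = reflen, ident = NA_real_, net = NA_integer_) {
    structure(
      list(status = status,
           frameshifts = if (is.null(frameshifts))
             data.frame(ref_pos = integer(0), indel_len = integer(0))
           else frameshifts,
           premature_stops = if (is.null(stops))
             data.frame(codon_index = integer(0), ref_pos = integer(0))
           else stops,
           truncation_3prime = trunc,
           aligned_identity = ident, net_frameshift = net),
      class = "pseudogene_report"
    )
  }
  if (is.null(candidate) || !nzchar(candidate)) return(report("absent"))
  candidate <- clean_dna(candidate, "candidate")
  if (nchar(candidate) < min_aln_len) return(report("absent"))

  aln <- pairwiseAlignment(
    pattern = DNAString(candidate), subject = DNAString(reference_cds),
    type = "global-local",
    substitutionMatrix = nucleotideSubstitutionMatrix(match = 2, mismatch = -3),
    gapOpening = 10, gapExtension = 1
  )
  pa <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
  su <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
  ref_first <- BiocGenerics::start(Biostrings::subject(aln)) - 1L  # 0-based
  ref_last_excl <- BiocGenerics::end(Biostrings::subject(aln))
  ident <- nmatch(aln) / length(pa)
  aligned_ref <- ref_last_excl - ref_first
  if (aligned_ref < min_aln_len || ident < min_identity) {
    return(report("absent"))
  }

  # walk alignment columns: ref coordinate and candidate index per column
  is_ins <- su == "-"            # candidate base absent from reference
  is_del <- pa == "-"            # reference base absent from candidate
  # ref_at - 1 is the 0-based reference coordinate of each non-insertion
  # column; at insertion columns it is the coordinate of the preceding base
  ref_at <- ref_first + cumsum(!is_ins)
  cand_idx <- cumsum(!is_del)    # 1-based candidate index at each column

  # indel events projected to reference coordinates
  gap_run <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(col = starts[r$values], len = r$lengths[r$values])
  }
  ins <- gap_run(is_ins)
  del <- gap_run(is_del)
  events <- rbind(
    if (nrow(ins)) data.frame(ref_pos = ref_at[ins$col] - 1L, indel_len = ins$len),
    if (nrow(del)) data.frame(ref_pos = ref_at[del$col] - 1L, indel_len = -del$len)
  )
  if (is.null(events)) {
    events <- data.frame(ref_pos = integer(0), indel_len = integer(0))
  }
  events <- events[order(events$ref_pos), , drop = FALSE]
  rownames(events) <- NULL
  frameshifts <- events[events$indel_len %% 3 != 0, , drop = FALSE]
  net <- if (nrow(events)) sum(events$indel_len) %% 3 else 0L

  # translate the candidate linearly from the first aligned codon boundary
  first_codon_col <- which(!is_ins & !is_del & (ref_at - 1L) %% 3 == 0)
  stops <- data.frame(codon_index = integer(0), ref_pos = integer(0))
  if (length(first_codon_col)) {
    c0 <- cand_idx[first_codon_col[1]]          # 1-based candidate start
    col_of_cand <- match(seq_len(nchar(candidate)), cand_idx)
    k <- 0L
    for (p in seq(c0, nchar(candidate) - 2L, by = 3L)) {
      k <- k + 1L
      codon <- substr(candidate, p, p + 2L)
      if (codon %in% STOP_CODONS) {
        col <- col_of_cand[p]
        rp <- if (is.na(col)) NA_integer_ else ref_at[col] - 1L
        # the reference's own terminal stop is not premature
        if (is.na(rp) || rp < reflen - 3L) {
          stops <- rbind(stops, data.frame(codon_index = k, ref_pos = rp))
        }
      }
    }
  }

  trunc <- reflen - ref_last_excl
  status <- if (net != 0L || nrow(stops) > 0L ||
                trunc > truncation_limit * reflen) "pseudogenized" else "intact"
  report(status, frameshifts, stops, trunc, ident, net)
}

#' @export
print.pseudogene_report <- function(x, ...) {
  cat(sprintf(
    "<pseudogene_report> %s: %d frameshift event(s) (net %s), %d premature stop(s), 3' truncation %d bp, identity %.3f\n",
    x$status, nrow(x$frameshifts), x$net_frameshift,
    nrow(x$premature_stops), x$truncation_3prime, x$aligned_identity))
  invisible(x)
}

#' Diagnostic events shared by all pseudogenized reports
#'
#' Returns the frameshift events present (same indel sign, reference
#' position within `slop` bp) in every pseudogenized report -- the signature
#' of a single ancestral pseudogenizing mutation inherited by all copies.
#'
#' @param reports list of `pseudogene_report` objects against the same
#'   reference.
#' @param slop positional tolerance in bp (default 2).
#' @return data.frame `ref_pos`, `indel_len` of shared events (positions
#'   from the first pseudogenized report).
#' @export
shared_diagnostic_events <- function(reports, slop = 2) {
  if (is(reports, "pseudogene_report")) reports <- list(reports)
  ps <- Filter(function(r) r$status == "pseudogenized", reports)
  none <- data.frame(ref_pos = integer(0), indel_len = integer(0))
  if (length(ps) == 0L) return(none)
  base <- ps[[1]]$frameshifts
  if (length(ps) == 1L) return(base)
  keep <- vapply(seq_len(nrow(base)), function(i) {
    all(vapply(ps[-1], function(r) {
      fs <- r$frameshifts
      any(abs(fs$ref_pos - base$ref_pos[i]) <= slop &
            sign(fs$indel_len) == sign(base$indel_len[i]))
    }, logical(1)))
  }, logical(1))
  out <- base[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
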