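# Cis/trans configuration of a matR-containing group-II intron (nad1i728).
#
# In many angiosperms the nad1 intron that carries the matR ORF is spliced
# in cis: exon 4, matR and exon 5 sit in one contiguous locus. Genome
# rearrangement can split the locus so the intron must be spliced in trans;
# the two described configurations are the wheat type (breakpoint between
# exon 4 and matR) and the petunia type (breakpoint between matR and
# exon 5).

feature_row <- function(features, name) {
  i <- which(tolower(features$feature) == tolower(name))
  if (length(i) != 1L) return(NULL)
  features[i, , drop = FALSE]
}

# circular gap in bp from the 3' end of `a` to the 5' start of `b`,
# walking in the direction of transcription on `strand`
directional_gap <- function(a, b, strand, n) {
  if (strand == "+") (b$start - a$end) %% n else (a$start - b$end) %% n
}

#' Classify the splicing configuration of a matR-containing intron
#'
#' The configuration is `cis` when exon 4, matR and exon 5 lie on one
#' molecule, on one strand, in transcriptional order, within
#' `max_cis_span` bp; otherwise `trans`, subtyped `petunia` when exon 4 and
#' matR remain collinear at one locus with exon 5 elsewhere, and `wheat`
#' when exon 4 stands alone and matR travels with exon 5. For trans cases
#' the inter-locus distance is the circular distance from the 3' end of the
#' upstream locus to the 5' start of the downstream locus; both arcs are
#' reported since a circle has two.
#'
#' @param g a `CircularSequence` (supplies the circle length).
#' @param features data.frame with columns `feature` (must contain
#'   `exon4`, `matR`, `exon5`), `start`, `end` (0-based half-open) and
#'   `strand`.
#' @param max_cis_span maximum genomic span of a contiguous (cis) locus in
#'   bp (default 10000; plant mitochondrial cis introns are kilobase-scale).
#' @return object of class `intron_config_report`: `mode` (`cis`/`trans`),
#'   `breakpoint_type` (`none`/`wheat`/`petunia`), `locus_distance` (bp,
#'   shorter arc; 0 for cis), `distance_other_arc`, `features_found`.
#' @export
classify_intron_configuration <- function(g, features, max_cis_span = 10000) {
  g <- as_circ(g)
  n <- seq_length(g)
  found <- c(exon4 = !is.null(feature_row(features, "exon4")),
             matR = !is.null(feature_row(features, "matR")),
             exon5 = !is.null(feature_row(features, "exon5")))
  if (!all(found)) {
    stop("incomplete annotation; missing feature(s): ",
         paste(names(found)[!found], collapse = ", "))
  }
  e4 <- feature_row(features, "exon4")
  mr <- feature_row(features, "matR")
  e5 <- feature_row(features, "exon5")
  same_strand <- length(unique(c(e4$strand, mr$strand, e5$strand))) == 1L
  res <- function(mode, bp, dist, other) {
    structure(
      list(mode = mode, breakpoint_type = bp, locus_distance = dist,
           distance_other_arc = other, features_found = found),
      class = "intron_config_report"
    )
  }
  width <- function(f) f$end - f$start
  if (same_strand) {
    st <- e4$strand
    g1 <- directional_gap(e4, mr, st, n)
    g2 <- directional_gap(mr, e5, st, n)
    span <- width(e4) + g1 + width(mr) + g2 + width(e5)
    if (span <= max_cis_span) return(res("cis", "none", 0L, 0L))
    span_e4_matR <- width(e4) + g1 + width(mr)
    span_matR_e5 <- width(mr) + g2 + width(e5)
    if (span_e4_matR <= max_cis_span && span_matR_e5 > max_cis_span) {
      # breakpoint between matR and exon 5
      return(res("trans", "petunia", min(g2, n - g2), max(g2, n - g2)))
    }
    if (span_matR_e5 <= max_cis_span && span_e4_matR > max_cis_span) {
      # breakpoint between exon 4 and matR
      return(res("trans", "wheat", min(g1, n - g1), max(g1, n - g1)))
    }
    stop("unrecognized trans configuration: neither exon4+matR nor ",
         "matR+exon5 form a contiguous locus within max_cis_span")
  }
  # strands differ: the locus is split with one part inverted
  pair_ok <- function(a, b) {
    a$strand == b$strand && directional_gap(a, b, a$strand, n) +
      width(a) + width(b) <= max_cis_span
  }
  if (pair_ok(e4, mr)) {
    gp <- directional_gap(mr, e5, mr$strand, n)
    return(res("trans", "petunia", min(gp, n - gp), max(gp, n - gp)))
  }
  if (pair_ok(mr, e5)) {
    gp <- directional_gap(e4, mr, e4$strand, n)
    return(res("trans", "wheat", min(gp, n - gp), max(gp, n - gp)))
  }
  stop("unrecognized trans configuration: features lie on different ",
       "strands and no exon/matR pair is collinear")
}

#' @export
print.intron_config_report <- function(x, ...) {
  cat(sprintf("<intron_config_report> mode=%s breakpoint=%s locus_distance=%s bp\n",
              x$mode, x$breakpoint_type,
              format(x$locus_distance, big.mark = ",")))
  invisible(x)
}

#' Measure the sequence deleted at a trans-splitting breakpoint
#'
#' Aligns the two trans locus sequences (e.g. the two assembled contigs of
#' a split nad1 exon4--matR / exon5 region) to the contiguous reference
#' region of a cis-configured relative and reports the reference bp within
#' the intron that neither locus covers.
#'
#' @param report an `intron_config_report`; must be a trans configuration.
#' @param reference_region contiguous exon4--intron(matR)--exon5 sequence of
#'   a cis relative.
#' @param loci character vector of the two trans locus sequences.
#' @param intron_interval 0-based half-open `c(start, end)` of the intron
#'   within `reference_region`.
#' @return deleted bp within the intron span (integer).
#' @export
breakpoint_deletion <- function(report, reference_region, loci,
                                intron_interval) {
  stopifnot(is(report, "intron_config_report"))
  if (report$mode == "cis") {
    stop("not applicable: breakpoint deletion is defined only for a trans ",
         "configuration")
  }
  stopifnot(length(loci) == 2L, length(intron_interval) == 2L)
  reference_region <- clean_dna(reference_region, "reference_region")
  ref <- DNAString(reference_region)
  covered <- lapply(loci, function(s) {
    aln <- pairwiseAlignment(
      pattern = DNAString(clean_dna(s, "locus")), subject = ref,
      type = "local",
      substitutionMatrix = nucleotideSubstitutionMatrix(match = 2, mismatch = -3),
      gapOpening = 10, gapExtension = 1
    )
    IRanges(start = BiocGenerics::start(Biostrings::subject(aln)),
            end = BiocGenerics::end(Biostrings::subject(aln)))
  })
  cov <- reduce(do.call(c, covered))
  intron <- IRanges(start = intron_interval[1] + 1L, end = intron_interval[2])
  sum(IRanges::width(IRanges::setdiff(intron, cov)))
}
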