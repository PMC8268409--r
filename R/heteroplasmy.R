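# Quantification of structural heteroplasmy from junction-spanning reads.
#
# Recombination at a short direct repeat swaps the flanking sequences of its
# two copies, so the four windows "upstream flank + motif + downstream
# flank" (two per genome structure) are diagnostic: a read that fully spans
# motif plus both flanks matches the junction set of the structure it came
# from. Classifying spanning reads against the four junctions and counting
# yields the per-individual frequency of each structural type.

# circular occurrences (0-based starts) of `motif` in genome `g`, forward
# and reverse strand, with up to max_mismatch substitutions
locate_motif <- function(g, motif, max_mismatch = 0) {
  g <- as_circ(g)
  n <- seq_length(g)
  ml <- nchar(motif)
  dbl <- substr(paste0(g$seq, g$seq), 1L, n + ml - 1L)
  hit0 <- function(pat) {
    mp <- matchPattern(DNAString(pat), DNAString(dbl),
                       max.mismatch = max_mismatch, with.indels = FALSE)
    sort(unique((BiocGenerics::start(mp) - 1L) %% n))
  }
  fw <- hit0(motif)
  rv <- setdiff(hit0(revcomp(motif)), fw)
  data.frame(start = c(fw, rv),
             strand = rep(c("+", "-"), c(length(fw), length(rv))))
}

#' Build the four diagnostic junctional regions of a structure pair
#'
#' Extracts, for each of the two motif copies in each genome, the window
#' `flank_len` bp upstream + motif + `flank_len` bp downstream. `A1`/`B1`
#' label the copy nearest the origin of the respective genome record.
#' After a flank-swapping recombination, `{B1, B2}` carry the
#' cross-combinations of the `{A1, A2}` flank pairings.
#'
#' @param genome_a,genome_b `CircularSequence` objects (the two structural
#'   types).
#' @param motif the repeat motif sequence (e.g. the 61 bp short direct
#'   repeat).
#' @param flank_len flank length in bp (default 30).
#' @param max_mismatch substitutions tolerated when locating the motif
#'   (default 0).
#' @return object of class `junction_set`: list with `motif`, `flank_len`,
#'   `junctions` (named character: A1, A2, B1, B2) and `positions`.
#' @export
build_junctions <- function(genome_a, genome_b, motif, flank_len = 30,
                            max_mismatch = 0) {
  motif <- clean_dna(motif, "motif")
  one_genome <- function(g, label) {
    g <- as_circ(g)
    occ <- locate_motif(g, motif, max_mismatch)
    if (nrow(occ) != 2L) {
      stop("motif occurs ", nrow(occ), " times in genome '", g$id,
           "'; exactly 2 occurrences are required")
    }
    n <- seq_length(g)
    ml <- nchar(motif)
    js <- vapply(seq_len(2), function(i) {
      st <- (occ$start[i] - flank_len) %% n
      s <- cs_extract0(g$seq, st, ml + 2L * flank_len)
      if (occ$strand[i] == "-") revcomp(s) else s
    }, character(1))
    setNames(js, paste0(label, 1:2))
  }
  ja <- one_genome(genome_a, "A")
  jb <- one_genome(genome_b, "B")
  structure(
    list(motif = motif, flank_len = flank_len,
         junctions = c(ja, jb),
         positions = list(A = locate_motif(as_circ(genome_a), motif, max_mismatch),
                          B = locate_motif(as_circ(genome_b), motif, max_mismatch))),
    class = "junction_set"
  )
}

#' @export
print.junction_set <- function(x, ...) {
  cat(sprintf("<junction_set> motif %d bp, flanks %d bp, windows %d bp\n",
              nchar(x$motif), x$flank_len, nchar(x$junctions[[1]])))
  invisible(x)
}

as_readset <- function(reads) {
  if (is(reads, "sim_reads")) {
    return(DNAStringSet(setNames(reads$reads, reads$names)))
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    return(readDNAStringSet(reads, format = "fastq"))
  }
  if (is.character(reads)) return(DNAStringSet(reads))
  if (is(reads, "DNAStringSet")) return(reads)
  stop("reads must be a sim_reads object, DNAStringSet, character vector, ",
       "or FASTQ path")
}

#' Classify junction-spanning reads by structural type
#'
#' A read is informative only if some ungapped placement of it (forward or
#' reverse complement) fully covers motif plus both flanks of at least one
#' junction with at most `max_mismatches` substitutions. Covering reads are
#' labelled `A` if they match only A-junctions, `B` if only B-junctions,
#' and `ambiguous` if both (ties are not resolved); ambiguous and
#' uninformative reads are excluded from the analyzed count.
#'
#' @param reads a `sim_reads` object, `DNAStringSet`, character vector of
#'   sequences, or path to a FASTQ file.
#' @param junctions a `junction_set` from [build_junctions()].
#' @param max_mismatches substitution budget over the junction window
#'   (default 3).
#' @return object of class `read_classification`: per-read `labels`, counts
#'   `n_analyzed`, `n_A`, `n_B`, `n_ambiguous`, `n_uninformative`,
#'   percentages `pct_A`, `pct_B` (one decimal), and `minor_ci`, the Wilson
#'   95% interval for the minor-type fraction.
#' @export
classify_reads <- function(reads, junctions, max_mismatches = 3) {
  stopifnot(is(junctions, "junction_set"))
  rs <- as_readset(reads)
  if (length(rs) == 0L) stop("empty read set")
  jl <- nchar(junctions$junctions[[1]])
  w <- BiocGenerics::width(rs)
  if (max(w) < jl) {
    stop("no read is long enough to span motif + both flanks (window ", jl,
         " bp); reduce flank_len or use longer reads")
  }
  labels <- rep("uninformative", length(rs))

  # prefilter: a spanning read within the budget must contain the motif
  # within the same budget
  motif <- DNAString(junctions$motif)
  has_fw <- vcountPattern(motif, rs, max.mismatch = max_mismatches) > 0
  has_rv <- vcountPattern(reverseComplement(motif), rs,
                          max.mismatch = max_mismatches) > 0
  cand <- which((has_fw | has_rv) & w >= jl)

  jset <- lapply(junctions$junctions, DNAString)
  jnames <- names(jset)
  for (i in cand) {
    r_fw <- rs[[i]]
    r_rv <- reverseComplement(r_fw)
    nw <- w[i] - jl + 1L
    dmin <- vapply(jset, function(j) {
      min(neditStartingAt(j, r_fw, starting.at = seq_len(nw),
                          with.indels = FALSE),
          neditStartingAt(j, r_rv, starting.at = seq_len(nw),
                          with.indels = FALSE))
    }, numeric(1))
    hit <- dmin <= max_mismatches
    if (!any(hit)) next
    hitA <- any(hit[startsWith(jnames, "A")])
    hitB <- any(hit[startsWith(jnames, "B")])
    labels[i] <- if (hitA && hitB) "ambiguous" else if (hitA) "A" else "B"
  }

  n_A <- sum(labels == "A"); n_B <- sum(labels == "B")
  n_an <- n_A + n_B
  minor <- min(n_A, n_B)
  structure(
    list(labels = labels,
         n_analyzed = n_an, n_A = n_A, n_B = n_B,
         n_ambiguous = sum(labels == "ambiguous"),
         n_uninformative = sum(labels == "uninformative"),
         pct_A = if (n_an > 0) round_half_up(100 * n_A / n_an, 1) else NA_real_,
         pct_B = if (n_an > 0) round_half_up(100 * n_B / n_an, 1) else NA_real_,
         minor_ci = if (n_an > 0) wilson_ci(minor, n_an) else c(NA, NA)),
    class = "read_classification"
  )
}

#' @export
print.read_classification <- function(x, ...) {
  cat(sprintf(
    "<read_classification> analyzed %d (A %d [%.1f%%], B %d [%.1f%%]); %d ambiguous, %d uninformative\n",
    x$n_analyzed, x$n_A, x$pct_A, x$n_B, x$pct_B,
    x$n_ambiguous, x$n_uninformative))
  invisible(x)
}

#' Build a read classification from bare counts
#'
#' Convenience constructor when only the analyzed/A/B counts are known
#' (e.g. re-deriving percentages from a published count table).
#'
#' @param n_analyzed analyzed read count.
#' @param n_A reads supporting the A structure.
#' @param n_B reads supporting the B structure (default
#'   `n_analyzed - n_A`).
#' @return a `read_classification`.
#' @export
classification_from_counts <- function(n_analyzed, n_A, n_B = n_analyzed - n_A) {
  stopifnot(n_A + n_B == n_analyzed, n_A >= 0, n_B >= 0)
  minor <- min(n_A, n_B)
  structure(
    list(labels = NULL, n_analyzed = n_analyzed, n_A = n_A, n_B = n_B,
         n_ambiguous = 0L, n_uninformative = 0L,
         pct_A = if (n_analyzed > 0) round_half_up(100 * n_A / n_analyzed, 1) else NA_real_,
         pct_B = if (n_analyzed > 0) round_half_up(100 * n_B / n_analyzed, 1) else NA_real_,
         minor_ci = if (n_analyzed > 0) wilson_ci(minor, n_analyzed) else c(NA, NA)),
    class = "read_classification"
  )
}

#' Write a frequency table as TSV with one-decimal percentages
#'
#' @param tab a table from [frequency_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(tab, path) {
  tab$pct_A <- sprintf("%.1f", tab$pct_A)
  tab$pct_B <- sprintf("%.1f", tab$pct_B)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-individual structural-type frequency table
#'
#' One row per classification, with analyzed counts and A/B percentages at
#' one decimal (half-up rounding).
#'
#' @param classifications list of `read_classification` objects.
#' @param labels character vector of individual labels, one per
#'   classification.
#' @return data.frame with columns `label`, `analyzed`, `n_A`, `pct_A`,
#'   `n_B`, `pct_B`.
#' @export
frequency_table <- function(classifications, labels) {
  if (is(classifications, "read_classification")) {
    classifications <- list(classifications)
  }
  stopifnot(length(classifications) == length(labels))
  data.frame(
    label = as.character(labels),
    analyzed = vapply(classifications, `[[`, numeric(1), "n_analyzed"),
    n_A = vapply(classifications, `[[`, numeric(1), "n_A"),
    pct_A = vapply(classifications, `[[`, numeric(1), "pct_A"),
    n_B = vapply(classifications, `[[`, numeric(1), "n_B"),
    pct_B = vapply(classifications, `[[`, numeric(1), "pct_B"),
    stringsAsFactors = FALSE
  )
}
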