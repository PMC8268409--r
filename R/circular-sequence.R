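#' Circular (or linear) genome sequence
#'
#' Container for a genome sequence with explicit topology. Circular sequences
#' have rotation-equivalence semantics: two circular molecules represent the
#' same structure when one is a rotation of the other or of its reverse
#' complement (circular DNA has no intrinsic strand or origin).
#'
#' @param id character label for the molecule.
#' @param seq DNA sequence over `{A,C,G,T,N}`; case-insensitive input is
#'   stored uppercase.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return an object of class `CircularSequence` with fields `id`, `seq`,
#'   `topology` and `length`.
#' @examples
#' g <- circular_sequence("toy", "acgtACGT")
#' seq_length(g)
#' @export
circular_sequence <- function(id, seq, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  structure(
    list(id = as.character(id), seq = clean_dna(seq, "seq"),
         topology = topology),
    class = "CircularSequence"
  )
}

#' @export
print.CircularSequence <- function(x, ...) {
  cat(sprintf("<CircularSequence> %s: %s bp, %s\n", x$id,
              format(nchar(x$seq), big.mark = ","), x$topology))
  invisible(x)
}

#' Sequence length of a molecule
#' @param g a `CircularSequence`.
#' @return integer length in bp.
#' @export
seq_length <- function(g) nchar(g$seq)

as_circ <- function(g) {
  if (is(g, "CircularSequence")) return(g)
  if (is.character(g) && length(g) == 1L) {
    return(circular_sequence("seq", g))
  }
  stop("expected a CircularSequence or a single DNA string")
}

# ---- intervals -------------------------------------------------------------

#' Genome interval on a (possibly circular) molecule
#'
#' Coordinates are 0-based, half-open. On a circular molecule of length `n`,
#' `start` lies in `[0, n)` and `end` in `(start, start + n]`; an interval
#' with `end > n` wraps across the origin (the `wraps` flag is derived).
#' Extracting an interval and re-inserting it reconstructs the original
#' sequence.
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end, `end <= start + n`; `end > n` wraps.
#' @param strand `"+"` or `"-"`.
#' @param n molecule length (optional; enables validation).
#' @return a list of class `genome_interval` with fields `start`, `end`,
#'   `strand`, `wraps` and `width`.
#' @export
genome_interval <- function(start, end, strand = "+", n = NULL) {
  start <- as.integer(start); end <- as.numeric(end)
  stopifnot(strand %in% c("+", "-"))
  if (!is.null(n)) {
    if (start < 0 || start >= n) stop("start out of range [0, n)")
    if (end <= start || end > start + n) stop("end out of range (start, start+n]")
  } else if (end <= start || start < 0) {
    stop("need 0 <= start < end")
  }
  structure(
    list(start = start, end = as.integer(end), strand = strand,
         wraps = if (is.null(n)) NA else end > n,
         width = as.integer(end - start)),
    class = "genome_interval"
  )
}

# Circular substring: extract `len` bases starting at 0-based `start0`.
cs_extract0 <- function(seq, start0, len) {
  n <- nchar(seq)
  stopifnot(len >= 1, len <= n, start0 >= 0, start0 < n)
  substr(paste0(seq, seq), start0 + 1L, start0 + len)
}

#' Extract an interval's sequence from a molecule
#'
#' @param g a `CircularSequence` (or DNA string).
#' @param iv a `genome_interval` (0-based half-open; may wrap on circles).
#' @return the extracted sequence; reverse-complemented when
#'   `iv$strand == "-"`.
#' @export
extract_interval <- function(g, iv) {
  g <- as_circ(g)
  n <- seq_length(g)
  if (g$topology == "linear" && iv$end > n) {
    stop("interval wraps but molecule is linear")
  }
  s <- cs_extract0(g$seq, iv$start, iv$width)
  if (iv$strand == "-") revcomp(s) else s
}

# Rotate a circular sequence so 0-based position `r` becomes position 0.
rotate_seq <- function(seq, r) {
  n <- nchar(seq)
  r <- ((r %% n) + n) %% n
  if (r == 0) return(seq)
  cs_extract0(seq, r, n)
}

#' Rotate a circular molecule
#'
#' @param g a `CircularSequence`, topology circular.
#' @param r 0-based position that becomes the new origin.
#' @return the rotated `CircularSequence`.
#' @export
rotate_genome <- function(g, r) {
  g <- as_circ(g)
  if (g$topology != "circular") stop("cannot rotate a linear molecule")
  circular_sequence(g$id, rotate_seq(g$seq, r))
}

# ---- canonical rotation ----------------------------------------------------

# 0-based shift of the lexicographically smallest rotation of `s`.
# Iterative candidate elimination; linear expected time on non-repetitive DNA.
min_rotation_shift <- function(s) {
  x <- utf8ToInt(s)
  n <- length(x)
  cand <- which(x == min(x))
  k <- 0L
  while (length(cand) > 1L && k < n - 1L) {
    k <- k + 1L
    v <- x[((cand - 1L + k) %% n) + 1L]
    cand <- cand[v == min(v)]
  }
  cand[1L] - 1L
}

#' Canonical rotation of a circular sequence
#'
#' Returns the rotation, over both strand readings, with lexicographically
#' minimal sequence. This is an artifact convention that gives every circular
#' molecule a unique representative; it is idempotent and is the basis of
#' structure equality for sequences.
#'
#' @param g a `CircularSequence` with circular topology (or DNA string).
#' @return the canonical `CircularSequence`.
#' @export
canonical_rotation <- function(g) {
  g <- as_circ(g)
  if (g$topology != "circular") {
    stop("canonical_rotation requires circular topology")
  }
  fw <- rotate_seq(g$seq, min_rotation_shift(g$seq))
  rcs <- revcomp(g$seq)
  rv <- rotate_seq(rcs, min_rotation_shift(rcs))
  circular_sequence(g$id, if (fw <= rv) fw else rv)
}

#' Structure equality of two circular sequences
#'
#' TRUE when one molecule is a rotation of the other or of its reverse
#' complement, i.e. the two circles are the same strandless molecule.
#'
#' @param a,b `CircularSequence` objects (or DNA strings).
#' @return logical.
#' @export
seq_structure_equal <- function(a, b) {
  a <- as_circ(a); b <- as_circ(b)
  if (seq_length(a) != seq_length(b)) return(FALSE)
  identical(canonical_rotation(a)$seq, canonical_rotation(b)$seq)
}

# ---- FASTA / GFF3 ----------------------------------------------------------

#' Read genomes from a FASTA file
#'
#' Multi-record FASTA; a record is treated as circular when its description
#' line contains the token `topology=circular`, or unconditionally when
#' `topology` is forced.
#'
#' @param path FASTA file.
#' @param topology `NA` (honour description tokens; default linear) or one of
#'   `"circular"`, `"linear"` to force.
#' @return a list of `CircularSequence` objects.
#' @export
read_genome_fasta <- function(path, topology = NA) {
  ss <- readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    nm <- names(ss)[i]
    topo <- if (!is.na(topology)) topology
            else if (grepl("topology=circular", nm)) "circular" else "linear"
    circular_sequence(sub("\\s.*$", "", nm), as.character(ss[[i]]), topo)
  })
}

#' Write genomes to a FASTA file
#'
#' Circular molecules carry a `topology=circular` token in the description
#' so circularity round-trips through [read_genome_fasta()].
#'
#' @param genomes a `CircularSequence` or list of them.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (is(genomes, "CircularSequence")) genomes <- list(genomes)
  seqs <- DNAStringSet(vapply(genomes, function(g) g$seq, character(1)))
  names(seqs) <- vapply(genomes, function(g) {
    if (g$topology == "circular") paste0(g$id, " topology=circular") else g$id
  }, character(1))
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read feature intervals from a GFF3 file
#'
#' GFF3 1-based inclusive coordinates are converted to the package's 0-based
#' half-open convention. Requires the rtracklayer package.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `molecule`, `feature` (GFF3 ID or Name or
#'   type), `start`, `end` (0-based half-open), `strand`.
#' @export
read_features_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  label <- if (!is.null(md$ID) && !all(is.na(md$ID))) as.character(md$ID)
           else if (!is.null(md$Name)) as.character(md$Name)
           else as.character(md$type)
  data.frame(
    molecule = as.character(md$seqnames),
    feature = label,
    start = md$start - 1L,
    end = md$end,
    strand = ifelse(as.character(md$strand) == "-", "-", "+"),
    stringsAsFactors = FALSE
  )
}
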