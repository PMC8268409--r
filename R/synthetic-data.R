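# Synthetic fixtures with recorded ground truth.
#
# The generator emulates the study conditions under which structural
# heteroplasmy is measured: a circular mitogenome-like molecule carrying
# one long (~3.5 kb) and one short (~61 bp) direct repeat pair arranged so
# the short-repeat copies separate the long-repeat copies (the precondition
# of the two-step rearrangement), the alternative structure derived by that
# rearrangement, read sets drawn from a mixture of the two structures, and
# reference-CDS copies decayed by a shared single-"A" frameshift insertion
# plus private mutations. Background sequence is i.i.d. uniform over
# {A,C,G,T}, which makes planted repeats the only expected >= 30 bp repeats
# and the junction flanks diagnostic with overwhelming probability; every
# output is a pure function of its parameters and seed.

#' Generate an A-type/B-type circular genome pair with planted repeats
#'
#' Builds a random circular genome with a long and a short direct repeat
#' pair planted in alternating order (`short-1, long-1, short-2, long-2`
#' around the circle, separated by four random arcs of proportions
#' 28/22/31/19 percent of the non-repeat length), then derives the
#' alternative structure with [two_step_rearrangement()]. Repeat copies are
#' planted identical (0 mismatches).
#'
#' @param genome_len circle length in bp (>= 4 x (dr_long_len +
#'   dr_short_len)).
#' @param dr_long_len long direct repeat length (default 3500).
#' @param dr_short_len short direct repeat length (default 61).
#' @param seed integer seed; outputs are byte-identical for equal seeds.
#' @return object of class `mito_truth`: `genome_a`, `genome_b`
#'   (`CircularSequence`s), `dr_short`, `dr_long` (planted `RepeatPair`
#'   rows, A-type coordinates), `motif_short`, `motif_long`, `blocks`
#'   (boundary table of the A-type arrangement), `params`.
#' @export
make_toy_genome_pair <- function(genome_len = 30000, dr_long_len = 3500,
                                 dr_short_len = 61, seed = 1) {
  if (genome_len < 4 * (dr_long_len + dr_short_len)) {
    stop("genome_len must be >= 4 * (dr_long_len + dr_short_len)")
  }
  with_seed(seed, {
    arcs_total <- genome_len - 2L * (dr_long_len + dr_short_len)
    w <- floor(arcs_total * c(0.28, 0.22, 0.31, 0.19))
    w[4] <- arcs_total - sum(w[1:3])
    motif_s <- random_dna(dr_short_len)
    motif_l <- random_dna(dr_long_len)
    arcs <- lapply(w, random_dna)
    # layout: DRs X DRl Y DRs Z DRl W
    segs <- list(motif_s, arcs[[1]], motif_l, arcs[[2]],
                 motif_s, arcs[[3]], motif_l, arcs[[4]])
    seq_a <- paste(unlist(segs), collapse = "")
    starts <- cumsum(c(0L, vapply(segs, nchar, integer(1))))[1:8]
    genome_a <- circular_sequence("A-type", seq_a)
    dr_short <- pair_record(starts[1], starts[5], dr_short_len, 0L,
                            "direct", genome_len)
    dr_long <- pair_record(starts[3], starts[7], dr_long_len, 0L,
                           "direct", genome_len)
    genome_b <- two_step_rearrangement(genome_a, dr_short, dr_long,
                                       id = "B-type")
    blocks <- data.frame(
      label = c("s1", "x", "l1", "y", "s2", "z", "l2", "w"),
      start = starts,
      end = starts + vapply(segs, nchar, integer(1)),
      strand = "+"
    )
    structure(
      list(genome_a = genome_a, genome_b = genome_b,
           dr_short = dr_short, dr_long = dr_long,
           motif_short = motif_s, motif_long = motif_l,
           blocks = blocks,
           params = list(genome_len = genome_len, dr_long_len = dr_long_len,
                         dr_short_len = dr_short_len, seed = seed)),
      class = "mito_truth"
    )
  })
}

#' @export
print.mito_truth <- function(x, ...) {
  cat(sprintf(
    "<mito_truth> %s bp circle pair; DR long %d bp, DR short %d bp (seed %s)\n",
    format(x$params$genome_len, big.mark = ","), x$params$dr_long_len,
    x$params$dr_short_len, x$params$seed))
  invisible(x)
}

mutate_reads <- function(reads, error_rate) {
  rl <- nchar(reads)
  nerr <- rbinom(length(reads), rl, error_rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    r <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in sample.int(rl[i], nerr[i])) {
      r[p] <- sample(setdiff(DNA_BASES, r[p]), 1L)
    }
    reads[i] <- paste(r, collapse = "")
  }
  list(reads = reads, n_errors = nerr)
}

#' Simulate reads from a mixture of two genome structures
#'
#' Draws single-end (or paired-end) reads uniformly from circular positions
#' of the A-type or B-type genome, choosing the source per read (per
#' fragment when paired) as Bernoulli(`weight_b`), and applies i.i.d.
#' substitution errors at `error_rate` per base. Indel and quality-dependent
#' errors are not modelled. The true source is encoded in each read name.
#' The expected number of reads spanning one junction window of width `w`
#' is about `2 * coverage * (read_len - w + 1) / read_len` (two motif
#' copies per genome).
#'
#' @param truth a `mito_truth` from [make_toy_genome_pair()].
#' @param weight_b fraction of reads drawn from the B-type genome (0..1).
#' @param coverage mean fold coverage of the circle.
#' @param read_len read length in bp (default 150).
#' @param paired simulate read pairs from ~400 bp fragments (default
#'   FALSE).
#' @param error_rate per-base substitution error rate (default 0.002).
#' @param seed integer seed.
#' @return object of class `sim_reads`: `reads` (character), `names`,
#'   `source` (`"A"`/`"B"` per read), `params`.
#' @export
simulate_reads <- function(truth, weight_b, coverage, read_len = 150,
                           paired = FALSE, error_rate = 0.002, seed = 1) {
  stopifnot(is(truth, "mito_truth"))
  if (weight_b < 0 || weight_b > 1) stop("weight_b must be in [0, 1]")
  if (coverage <= 0) stop("coverage must be positive")
  n <- truth$params$genome_len
  if (read_len >= n) stop("read_len must be shorter than the genome")
  with_seed(seed, {
    n_units <- ceiling(coverage * n / (read_len * (if (paired) 2 else 1)))
    src <- ifelse(runif(n_units) < weight_b, "B", "A")
    pos <- sample.int(n, n_units, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n_units, replace = TRUE)
    dbl <- list(A = paste0(truth$genome_a$seq, truth$genome_a$seq),
                B = paste0(truth$genome_b$seq, truth$genome_b$seq))
    pull <- function(genome, p, len) substring(dbl[[genome]], p + 1L, p + len)
    if (!paired) {
      reads <- vapply(seq_len(n_units),
                      function(i) pull(src[i], pos[i], read_len), character(1))
      flip <- strand == "-"
      if (any(flip)) {
        reads[flip] <- as.character(reverseComplement(DNAStringSet(reads[flip])))
      }
      mut <- mutate_reads(reads, error_rate)
      nms <- sprintf("r%06d|src=%s|pos=%d|strand=%s", seq_len(n_units),
                     src, pos, strand)
      out <- list(reads = mut$reads, names = nms, source = src)
    } else {
      frag_len <- pmax(2L * read_len,
                       round(rnorm(n_units, mean = 400, sd = 40)))
      frag_len <- pmin(frag_len, n - 1L)
      frags <- vapply(seq_len(n_units),
                      function(i) pull(src[i], pos[i], frag_len[i]),
                      character(1))
      r1 <- substring(frags, 1L, read_len)
      r2 <- as.character(reverseComplement(DNAStringSet(
        substring(frags, frag_len - read_len + 1L, frag_len))))
      reads <- as.vector(rbind(r1, r2))
      mut <- mutate_reads(reads, error_rate)
      src2 <- rep(src, each = 2L)
      nms <- sprintf("r%06d/%d|src=%s|pos=%d", rep(seq_len(n_units), each = 2L),
                     rep(1:2, n_units), src2, rep(pos, each = 2L))
      out <- list(reads = mut$reads, names = nms, source = src2)
    }
    out$params <- list(weight_b = weight_b, coverage = coverage,
                       read_len = read_len, paired = paired,
                       error_rate = error_rate, seed = seed)
    structure(out, class = "sim_reads")
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("<sim_reads> %d reads x %d bp, weight_b=%.3f, error=%.4f\n",
              length(x$reads), x$params$read_len, x$params$weight_b,
              x$params$error_rate))
  invisible(x)
}

#' Write simulated reads to FASTQ
#' @param sim a `sim_reads` object.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  stopifnot(is(sim, "sim_reads"))
  rs <- DNAStringSet(setNames(sim$reads, sim$names))
  writeXStringSet(rs, path, format = "fastq",
                  qualities = Biostrings::BStringSet(
                    vapply(nchar(sim$reads),
                           function(w) paste(rep("I", w), collapse = ""),
                           character(1))))
  invisible(path)
}

#' Random intact CDS
#'
#' ATG start, internal codons drawn uniformly from the 60 non-stop sense
#' codons (excluding ATG for internal positions keeps planted events easy
#' to reason about), TAA stop.
#'
#' @param n_codons total codon count including start and stop (>= 3).
#' @param seed integer seed.
#' @return CDS string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons = 200, seed = 1) {
  stopifnot(n_codons >= 3)
  with_seed(seed, {
    all_codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES),
                        1, paste, collapse = "")
    sense <- setdiff(all_codons, c(STOP_CODONS, "ATG"))
    paste0("ATG",
           paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
           "TAA")
  })
}

#' Generate a set of pseudogenized CDS copies with a shared frameshift
#'
#' Every copy carries the same single-"A" insertion after
#' `shared_insert_pos` (within the first 60 bp: the early-5' frameshift
#' pattern), plus private decay: substitutions (Poisson, mean 4), with
#' probability 0.3 a private indel of 1-3 bp placed at least 80 bp
#' downstream of the shared insertion, and with probability 0.3 a 3'
#' truncation removing 10-40% of the reference.
#'
#' @param reference_cds an intact reference CDS (validated).
#' @param n_copies number of copies (default 7).
#' @param shared_insert_pos 0-based reference position after which the "A"
#'   is inserted; must be < 60.
#' @param seed integer seed.
#' @return list with `sequences` (character vector) and `truth` (per-copy
#'   list of planted events).
#' @export
make_pseudogene_set <- function(reference_cds, n_copies = 7,
                                shared_insert_pos = 30, seed = 1) {
  reference_cds <- validate_cds(reference_cds)
  if (shared_insert_pos >= 60) {
    stop("shared_insert_pos must lie within the first 60 bp (early 5' site)")
  }
  reflen <- nchar(reference_cds)
  with_seed(seed, {
    seqs <- character(n_copies)
    truth <- vector("list", n_copies)
    for (i in seq_len(n_copies)) {
      s <- paste0(substr(reference_cds, 1, shared_insert_pos + 1L), "A",
                  substr(reference_cds, shared_insert_pos + 2L, reflen))
      ev <- list(shared_insertion = shared_insert_pos)
      nsub <- rpois(1, 4)
      if (nsub > 0) {
        subpos <- sample.int(nchar(s), nsub)
        s <- mutate_string(s, subpos)
        ev$substitutions <- sort(subpos)
      }
      if (runif(1) < 0.3) {
        ilen <- sample(1:3, 1)
        ipos <- sample(seq(shared_insert_pos + 80L, nchar(s) - 10L), 1)
        if (runif(1) < 0.5) {
          s <- paste0(substr(s, 1, ipos), random_dna(ilen),
                      substr(s, ipos + 1L, nchar(s)))
          ev$private_indel <- c(pos = ipos, len = ilen)
        } else {
          s <- paste0(substr(s, 1, ipos), substr(s, ipos + ilen + 1L, nchar(s)))
          ev$private_indel <- c(pos = ipos, len = -ilen)
        }
      }
      if (runif(1) < 0.3) {
        cut <- round(nchar(s) * runif(1, 0.10, 0.40))
        s <- substr(s, 1, nchar(s) - cut)
        ev$truncation_3prime <- cut
      }
      seqs[i] <- s
      truth[[i]] <- ev
    }
    list(sequences = seqs, truth = truth,
         shared_insert_pos = shared_insert_pos, seed = seed)
  })
}
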