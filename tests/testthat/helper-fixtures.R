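# Shared fixture builders. Everything is generated in code under fixed
# seeds; no files are read.

bg_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# string helpers written independently of the package internals
str_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}
str_rotate <- function(s, r) {
  n <- nchar(s)
  r <- ((r %% n) + n) %% n
  if (r == 0) return(s)
  paste0(substr(s, r + 1, n), substr(s, 1, r))
}

# circle with a motif planted at two 0-based positions (same orientation
# when inverted = FALSE); returns list(seq, positions, motif)
plant_circle <- function(len, motif_len, pos1, pos2, inverted = FALSE,
                         n_subs = 0) {
  s <- strsplit(bg_dna(len), "")[[1]]
  motif <- bg_dna(motif_len)
  m2 <- if (inverted) str_revcomp(motif) else motif
  if (n_subs > 0) {
    mm <- strsplit(m2, "")[[1]]
    at <- sample.int(motif_len, n_subs)
    for (p in at) mm[p] <- sample(setdiff(c("A", "C", "G", "T"), mm[p]), 1)
    m2 <- paste(mm, collapse = "")
  }
  put <- function(chars, pos0, frag) {
    idx <- ((pos0 + seq_len(nchar(frag)) - 1L) %% len) + 1L
    chars[idx] <- strsplit(frag, "")[[1]]
    chars
  }
  s <- put(s, pos1, motif)
  s <- put(s, pos2, m2)
  list(seq = paste(s, collapse = ""), motif = motif,
       positions = c(pos1, pos2))
}

# contiguous exon4-intron(matR)-exon5 reference region plus a trans split
# of it with `deletion` bp removed at the cut (cut lies inside the intron)
make_intron_fixture <- function(deletion = 0, intron2_len = 1500, seed = 91) {
  set.seed(seed)
  widths <- c(exon4 = 400L, intron1 = 800L, matR = 1800L,
              intron2 = intron2_len, exon5 = 80L)
  parts <- lapply(widths, bg_dna)
  refreg <- paste(unlist(parts), collapse = "")
  cut <- sum(widths[1:3]) + 300L
  list(
    reference = refreg,
    intron_interval = c(widths[["exon4"]], sum(widths) - widths[["exon5"]]),
    loci = c(substr(refreg, 1, cut),
             substr(refreg, cut + deletion + 1, nchar(refreg))),
    cut = cut
  )
}
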