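#' Signed block arrangement of a circular molecule
#'
#' An ordered list of signed block labels describing a genome structure, as
#' in a locally-collinear-block (LCB) decomposition of a whole-genome
#' alignment. Concatenating the block sequences in listed order and
#' orientation reproduces the molecule (up to rotation, which is immaterial
#' on a circle).
#'
#' @param molecule molecule id.
#' @param blocks character vector of signed labels, e.g. `c("+b1","-b3")`.
#' @param block_seqs named list/character mapping label -> plus-orientation
#'   sequence (optional, needed for reconstruction).
#' @return object of class `BlockArrangement`.
#' @export
block_arrangement <- function(molecule, blocks, block_seqs = NULL) {
  stopifnot(length(blocks) >= 1L, all(grepl("^[+-].", blocks)))
  structure(
    list(molecule = as.character(molecule), blocks = as.character(blocks),
         block_seqs = block_seqs),
    class = "BlockArrangement"
  )
}

#' @export
print.BlockArrangement <- function(x, ...) {
  cat(sprintf("<BlockArrangement> %s: %s\n", x$molecule,
              paste(x$blocks, collapse = " ")))
  invisible(x)
}

block_label <- function(tok) substring(tok, 2L)
block_sign <- function(tok) substring(tok, 1L, 1L)
flip_token <- function(tok) {
  paste0(ifelse(block_sign(tok) == "+", "-", "+"), block_label(tok))
}

#' Decompose a circular genome into labeled blocks
#'
#' The boundary intervals must partition the circle without overlap. Blocks
#' are listed in genome order starting from the block that contains
#' position 0; a block annotated on the minus strand enters the arrangement
#' with a `-` sign and its stored sequence is its plus-orientation reading.
#'
#' @param g a `CircularSequence`, circular topology.
#' @param boundaries data.frame with columns `label`, `start`, `end`
#'   (0-based half-open, `end` may exceed the length for a wrapping block)
#'   and optionally `strand`.
#' @return a `BlockArrangement`; concatenating block sequences in listed
#'   order/orientation reproduces the molecule rotated to the first block's
#'   start.
#' @export
arrangement_of <- function(g, boundaries) {
  g <- as_circ(g)
  if (g$topology != "circular") stop("arrangement_of requires a circular molecule")
  n <- seq_length(g)
  b <- as.data.frame(boundaries)
  stopifnot(all(c("label", "start", "end") %in% names(b)))
  if (is.null(b$strand)) b$strand <- "+"
  b$start <- as.integer(b$start); b$end <- as.integer(b$end)
  if (any(b$start < 0 | b$start >= n | b$end <= b$start | b$end > b$start + n)) {
    stop("invalid boundary interval(s): need 0 <= start < n, start < end <= start + n")
  }
  b <- b[order(b$start), , drop = FALSE]
  if (sum(b$end - b$start) != n) {
    stop("boundaries do not partition the circle (total width != genome length)")
  }
  k <- nrow(b)
  if (k > 1L) {
    if (!all(b$end[-k] == b$start[-1]) || (b$end[k] %% n) != b$start[1]) {
      stop("boundaries overlap or leave gaps on the circle")
    }
  } else if ((b$end[1] - b$start[1]) != n) {
    stop("a single boundary must cover the whole circle")
  }
  # first block = the one containing position 0 (start 0, or the wrapping one)
  first <- which(b$start == 0L | b$end > n)
  if (length(first) == 0L) first <- 1L
  ord <- c(first[1]:k, if (first[1] > 1L) 1:(first[1] - 1L))
  b <- b[ord, , drop = FALSE]
  seqs <- lapply(seq_len(nrow(b)), function(i) {
    s <- cs_extract0(g$seq, b$start[i] %% n, b$end[i] - b$start[i])
    if (b$strand[i] == "-") revcomp(s) else s
  })
  block_arrangement(
    g$id,
    paste0(ifelse(b$strand == "-", "-", "+"), b$label),
    setNames(seqs, b$label)
  )
}

#' Reconstruct the molecule sequence from a block arrangement
#'
#' @param arr a `BlockArrangement` with `block_seqs`.
#' @return the concatenated sequence (a rotation of the original molecule).
#' @export
arrangement_sequence <- function(arr) {
  stopifnot(is(arr, "BlockArrangement"), !is.null(arr$block_seqs))
  paste(vapply(arr$blocks, function(tok) {
    s <- arr$block_seqs[[block_label(tok)]]
    if (block_sign(tok) == "-") revcomp(s) else s
  }, character(1)), collapse = "")
}

# Canonical form of a signed-label cycle: lexicographically minimal over all
# rotations of the cycle and of its reversed, sign-flipped reading.
canonical_cycle <- function(blocks) {
  k <- length(blocks)
  variants <- character(0)
  readings <- list(blocks, rev(vapply(blocks, flip_token, character(1))))
  for (r in readings) {
    for (i in seq_len(k)) {
      rot <- c(r[i:k], if (i > 1L) r[1:(i - 1L)])
      variants <- c(variants, paste(rot, collapse = "|"))
    }
  }
  min(variants)
}

#' Compare two block arrangements as circular structures
#'
#' TRUE when the signed-label cycles are equal up to rotation and to reading
#' the circle from the opposite strand (reversal with sign flip). Structure
#' equality is strandless, like the molecules it describes.
#'
#' @param a,b `BlockArrangement` objects over the same label universe.
#' @return logical.
#' @export
same_structure <- function(a, b) {
  stopifnot(is(a, "BlockArrangement"), is(b, "BlockArrangement"))
  la <- block_label(a$blocks); lb <- block_label(b$blocks)
  if (length(intersect(la, lb)) == 0L) {
    stop("arrangements share no block labels; structures are incomparable")
  }
  if (length(la) != length(lb) || !setequal(la, lb)) return(FALSE)
  identical(canonical_cycle(a$blocks), canonical_cycle(b$blocks))
}
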