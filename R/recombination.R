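# Repeat-mediated recombination on circular molecules.
#
# Homologous recombination between two copies of a direct repeat on one
# circle excises two subgenomic circles, each carrying one full copy of the
# repeat motif; recombination between copies on two different circles fuses
# them back into one. Composing the two events at a short and a long direct
# repeat pair interconverts two alternative genome arrangements (the
# two-step A-type <-> B-type scenario). The crossover is placed at the
# motif's 5' boundary, so outputs are deterministic; for copies identical up
# to the allowed mismatches all crossover placements are structure-equal.

as_pair <- function(pair) {
  if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1L)
    pair <- as.list(pair)
  }
  stopifnot(all(c("copy_a_start", "copy_a_end", "copy_b_start",
                  "copy_b_end", "orientation") %in% names(pair)))
  pair
}

#' Intramolecular recombination at a direct repeat pair
#'
#' Crossover between the two copies of a direct repeat on one circular
#' molecule excises it into exactly two subgenomic circles. Product 1 runs
#' from the start of `copy_a` to the start of `copy_b` (one full motif copy
#' plus the arc between the copies); product 2 is the complementary arc with
#' the other motif copy. Product lengths sum to the parent length.
#'
#' @param m a `CircularSequence`.
#' @param pair a direct `RepeatPair` (one row of a `repeat_set`, or a list
#'   with `copy_a_start`, `copy_a_end`, `copy_b_start`, `copy_b_end`,
#'   `orientation`), both copies on `m` and disjoint.
#' @return a `molecule_set`: list with `molecules` (two
#'   `CircularSequence`s) and `events` (provenance log).
#' @export
intramolecular_recombine <- function(m, pair) {
  m <- as_circ(m)
  pair <- as_pair(pair)
  n <- seq_length(m)
  if (pair$orientation != "direct") {
    stop("unsupported orientation: intramolecular excision requires a direct ",
         "repeat pair (inverted pairs invert the intervening segment instead)")
  }
  sa <- pair$copy_a_start %% n; sb <- pair$copy_b_start %% n
  La <- pair$copy_a_end - pair$copy_a_start
  Lb <- pair$copy_b_end - pair$copy_b_start
  if (!circ_disjoint(sa, sb, La, Lb, n)) {
    stop("repeat copies overlap; excision geometry undefined")
  }
  len1 <- (sb - sa) %% n
  len2 <- n - len1
  p1 <- circular_sequence(paste0(m$id, "_sub1"), cs_extract0(m$seq, sa, len1))
  p2 <- circular_sequence(paste0(m$id, "_sub2"), cs_extract0(m$seq, sb, len2))
  structure(
    list(molecules = list(p1, p2),
         events = list(list(type = "intramolecular", parent = m$id,
                            pair = pair))),
    class = "molecule_set"
  )
}

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("<molecule_set> %d molecule(s), %d event(s)\n",
              length(x$molecules), length(x$events)))
  for (m in x$molecules) print(m)
  invisible(x)
}

#' Intermolecular recombination at a direct repeat pair
#'
#' Crossover between a repeat copy on `m1` (`copy_a`) and one on `m2`
#' (`copy_b`) integrates the two circles into a single circular molecule of
#' summed length carrying both copies, with both parents' non-repeat arcs
#' intact.
#'
#' @param m1,m2 `CircularSequence` objects.
#' @param pair direct `RepeatPair`; `copy_a` coordinates refer to `m1`,
#'   `copy_b` to `m2`.
#' @param id id for the product (default derived from the parents).
#' @return the merged `CircularSequence`.
#' @export
intermolecular_recombine <- function(m1, m2, pair,
                                     id = paste0(m1$id, "+", m2$id)) {
  m1 <- as_circ(m1); m2 <- as_circ(m2)
  pair <- as_pair(pair)
  if (pair$orientation != "direct") {
    stop("unsupported orientation: integration requires a direct repeat pair")
  }
  if (identical(m1$id, m2$id) && identical(m1$seq, m2$seq)) {
    stop("both copies lie on the same molecule; use intramolecular_recombine")
  }
  s1 <- pair$copy_a_start %% seq_length(m1)
  s2 <- pair$copy_b_start %% seq_length(m2)
  circular_sequence(id, paste0(rotate_seq(m1$seq, s1), rotate_seq(m2$seq, s2)))
}

# map an interval of the parent circle onto an excision product that covers
# the parent arc [arc_start, arc_start + arc_len); NULL if not fully inside
map_to_product <- function(start, len, arc_start, arc_len, n) {
  off <- (start - arc_start) %% n
  if (off + len <= arc_len) list(start = off, len = len) else NULL
}

#' Two-step repeat-mediated rearrangement
#'
#' Composes an intramolecular excision at the short direct repeat pair with
#' an intermolecular re-integration of the two subgenomic products at the
#' long direct repeat pair. When the short-repeat copies separate the
#' long-repeat copies on the circle, the result has the same length and the
#' same segment content as the input but a different structure; applying the
#' same two-step operation to the output restores a structure equal to the
#' input.
#'
#' @param m a `CircularSequence`.
#' @param dr_short direct `RepeatPair` on `m` (excision step).
#' @param dr_long direct `RepeatPair` on `m` (re-integration step); one copy
#'   must land on each excision product.
#' @param id id for the product.
#' @return the rearranged `CircularSequence`.
#' @export
two_step_rearrangement <- function(m, dr_short, dr_long,
                                   id = paste0(m$id, "_rearranged")) {
  m <- as_circ(m)
  n <- seq_length(m)
  dr_short <- as_pair(dr_short); dr_long <- as_pair(dr_long)
  if (dr_long$orientation != "direct") stop("dr_long must be a direct pair")
  ms <- intramolecular_recombine(m, dr_short)
  p1 <- ms$molecules[[1]]; p2 <- ms$molecules[[2]]
  ss <- dr_short$copy_a_start %% n
  sb <- dr_short$copy_b_start %% n
  arc1 <- (sb - ss) %% n
  ll <- dr_long$copy_a_end - dr_long$copy_a_start
  la_on1 <- map_to_product(dr_long$copy_a_start %% n, ll, ss, arc1, n)
  la_on2 <- map_to_product(dr_long$copy_a_start %% n, ll, sb, n - arc1, n)
  lb_on1 <- map_to_product(dr_long$copy_b_start %% n, ll, ss, arc1, n)
  lb_on2 <- map_to_product(dr_long$copy_b_start %% n, ll, sb, n - arc1, n)
  if (!is.null(la_on1) && !is.null(lb_on2)) {
    c1 <- la_on1; c2 <- lb_on2
  } else if (!is.null(lb_on1) && !is.null(la_on2)) {
    c1 <- lb_on1; c2 <- la_on2
  } else {
    stop("scenario inapplicable: the long-repeat copies do not land on ",
         "different excision products (short-repeat copies must separate ",
         "the long-repeat copies on the circle)")
  }
  merged <- intermolecular_recombine(
    p1, p2,
    list(copy_a_start = c1$start, copy_a_end = c1$start + ll,
         copy_b_start = c2$start, copy_b_end = c2$start + ll,
         orientation = "direct"),
    id = id
  )
  merged
}
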