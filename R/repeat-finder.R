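# Repeat-pair detection on circular genomes.
#
# A repeat pair is two non-identical, non-overlapping intervals of equal
# length L >= min_len whose aligned reading (same strand for direct pairs,
# reverse complement for inverted pairs) differs at m substitutions with
# m/L <= max_mismatch_frac. Reported pairs are one-step maximal: extending
# the aligned window by one base on either side either breaks the mismatch
# bound or makes the two copies overlap. Pairs fully contained in a longer
# reported pair are suppressed.
#
# Every candidate pair lies on a "diagonal": for direct pairs the offset
# d = (b_start - a_start) mod n, for inverted pairs the anti-diagonal
# u = (a_start + b_start + L - 1) mod n. Any window with length >= min_len
# and mismatch density <= frac contains an aligned min_len sub-window whose
# density is also <= frac (averaging over all sub-window positions), so
# screening each diagonal for its best min_len window is a complete filter.
# On surviving diagonals, one-step-maximal windows are enumerated
# analytically: a window whose extensions are blocked by mismatches must
# start right after a mismatch and end right before one, with
# m <= frac*L and m + 1 > frac*(L + 1); windows blocked by copy-overlap
# geometry are enumerated separately from the diagonal arithmetic.
#
# Because the budget is a fraction, several staggered maximal windows
# usually surround one physical repeat (each absorbing a different set of
# flanking mismatches). Overlapping maximal windows on one diagonal are
# therefore one repeat locus: only the best window per locus is reported
# (longest, then fewest mismatches, then smallest start).

FEAS_EPS <- 1e-9

# integer codes with N forced to mismatch against everything incl. N
dna_codes <- function(seq, sentinel) {
  x <- utf8ToInt(seq)
  x[x == utf8ToInt("N")] <- sentinel
  x
}

# circular mismatch count helper built on a tripled prefix sum
make_counter <- function(mm_n) {
  n <- length(mm_n)
  cs <- c(0, cumsum(c(mm_n, mm_n, mm_n)))
  function(a0, L) {
    # a0 0-based circular, 0 <= L <= n
    s <- (a0 %% n) + n + 1L
    cs[s + L] - cs[s]
  }
}

circ_disjoint <- function(s1, s2, L1, L2, n) {
  (((s2 - s1) %% n) >= L1) && (((s1 - s2) %% n) >= L2)
}

# ---- per-diagonal machinery ------------------------------------------------

# mismatch vector of a diagonal: position p (0-based) vs its partner
direct_mismatch_vec <- function(xa, xb2, d, n) {
  xa != xb2[(d + 1L):(d + n)]
}

# Enumerate candidate (a0, L, m) windows whose one-step extensions are
# mismatch-blocked on both sides.
enumerate_mm_blocked <- function(mm_n, min_len, frac, Lcap) {
  n <- length(mm_n)
  mm3 <- c(mm_n, mm_n, mm_n)
  Q <- which(mm3)
  # starts following a mismatch in the middle copy
  sel <- which(Q >= n & Q <= 2L * n - 1L)
  if (length(sel) == 0L) {
    # diagonal with <= frac mismatch everywhere: only geometry-capped
    # windows exist; handled by the caller.
    return(NULL)
  }
  P <- Q[sel]
  out_a <- integer(0); out_L <- integer(0); out_m <- integer(0)
  mcap <- floor(frac * Lcap + FEAS_EPS) + 1L
  for (m in 0:mcap) {
    j <- sel + m + 1L
    ok <- j <= length(Q)
    if (!any(ok)) break
    L <- rep(NA_integer_, length(P))
    L[ok] <- Q[j[ok]] - P[ok] - 1L
    keep <- ok & L >= min_len & L <= Lcap &
      m <= frac * L + FEAS_EPS &
      (m + 1) > frac * (L + 1) + FEAS_EPS
    if (any(keep)) {
      out_a <- c(out_a, (P[keep]) %% n)      # a0 = index P (1-based) -> pos P %% n
      out_L <- c(out_L, L[keep])
      out_m <- c(out_m, rep.int(m, sum(keep)))
    }
  }
  if (length(out_a) == 0L) return(NULL)
  data.frame(a0 = out_a, L = out_L, m = out_m)
}

# Feasible fixed-length windows (geometry-capped candidates).
enumerate_fixed_L <- function(counter, n, L, frac) {
  if (L < 1L || L > n) return(NULL)
  m <- vapply(0:(n - 1L), counter, numeric(1), L = L)
  a0 <- which(m <= frac * L + FEAS_EPS) - 1L
  if (length(a0) == 0L) return(NULL)
  data.frame(a0 = a0, L = L, m = m[a0 + 1L])
}

# Diagonal passes iff some aligned min_len window has few enough mismatches.
diagonal_alive <- function(mm_n, min_len, frac) {
  n <- length(mm_n)
  ext <- c(mm_n, mm_n[seq_len(min_len - 1L)])
  cs <- c(0, cumsum(ext))
  wc <- cs[(min_len + 1L):(n + min_len)] - cs[1:n]
  min(wc) <= floor(frac * min_len + FEAS_EPS)
}

#' Find repeat pairs in a circular genome
#'
#' Detects direct and inverted repeat pairs of length at least `min_len`
#' whose two copies differ by at most `max_mismatch_frac` substitutions
#' (ungapped comparison; `N` never counts as a match). Reported pairs are
#' one-step maximal -- extending the aligned window by one base on either
#' side would break the mismatch bound or make the copies overlap.
#' Overlapping maximal windows on one alignment diagonal are one repeat
#' locus and only the best window per locus is reported (longest, then
#' fewest mismatches, then smallest start); pairs fully contained in a
#' longer reported pair are suppressed.
#' Coordinates are 0-based half-open on the circle; `*_end` exceeding the
#' genome length indicates a pair copy spanning the origin.
#'
#' @param g a `CircularSequence` (or DNA string, treated as circular).
#' @param min_len minimum repeat length in bp (default 30; must be >= 8).
#' @param max_mismatch_frac maximum mismatch fraction (default 0.10).
#' @return data.frame of class `repeat_set`, sorted by length descending
#'   then `copy_a_start`, with columns `copy_a_start`, `copy_a_end`,
#'   `copy_b_start`, `copy_b_end`, `orientation` (`"direct"`/`"inverted"`),
#'   `length`, `mismatches`, `identity`. The genome length is attached as
#'   attribute `genome_length`.
#' @examples
#' g <- make_toy_genome_pair(2000, dr_long_len = 200, dr_short_len = 61,
#'                           seed = 1)$genome_a
#' find_repeats(g)
#' @export
find_repeats <- function(g, min_len = 30, max_mismatch_frac = 0.10) {
  g <- as_circ(g)
  n <- seq_length(g)
  if (min_len < 8) stop("min_len must be >= 8")
  if (n < 2 * min_len) stop("genome shorter than 2 * min_len")
  frac <- max_mismatch_frac
  xa <- dna_codes(g$seq, -1L)
  xb <- dna_codes(g$seq, -2L)
  xb2 <- c(xb, xb)
  rc <- dna_codes(revcomp(g$seq), -2L)
  rc2 <- c(rc, rc)

  cand <- list()

  ## direct diagonals: offset d, partner of p is p + d (mod n)
  for (d in seq_len(n %/% 2)) {
    mm <- direct_mismatch_vec(xa, xb2, d, n)
    if (!diagonal_alive(mm, min_len, frac)) next
    Lmax <- min(d, n - d)
    if (Lmax < min_len) next
    counter <- make_counter(mm)
    cc <- enumerate_mm_blocked(mm, min_len, frac, Lmax)
    cc <- rbind(cc, enumerate_fixed_L(counter, n, Lmax, frac))
    if (is.null(cc) || nrow(cc) == 0L) next
    cc <- unique(cc[, c("a0", "L")])
    for (i in seq_len(nrow(cc))) {
      a0 <- cc$a0[i]; L <- cc$L[i]
      if (validate_direct(counter, n, a0, L, d, min_len, frac)) {
        b0 <- (a0 + d) %% n
        m <- counter(a0, L)
        rec <- pair_record(a0, b0, L, m, "direct", n)
        rec$diagonal <- paste0("d", d)
        rec$win_start <- a0
        cand[[length(cand) + 1L]] <- rec
      }
    }
  }

  ## inverted anti-diagonals: partner of p is u - p (mod n), read complemented
  for (u in 0:(n - 1L)) {
    # w[p] compares base p with complement(base (u-p) mod n):
    # complement(s[(u-p) mod n]) = revcomp(s)[(n-1-u+p) mod n]
    sh <- (n - 1L - u) %% n
    mm <- xa != rc2[(sh + 1L):(sh + n)]
    if (!diagonal_alive(mm, min_len, frac)) next
    counter <- make_counter(mm)
    Lcap <- n %/% 2L
    cc <- enumerate_mm_blocked(mm, min_len, frac, Lcap)
    cc <- rbind(cc, inverted_geometry_candidates(counter, n, u, min_len, frac))
    if (is.null(cc) || nrow(cc) == 0L) next
    cc <- unique(cc[, c("a0", "L")])
    for (i in seq_len(nrow(cc))) {
      a0 <- cc$a0[i]; L <- cc$L[i]
      b0 <- (u - a0 - L + 1L) %% n
      if (a0 >= b0) next  # each unordered pair kept once per anti-diagonal
      if (validate_inverted(counter, n, a0, L, u, min_len, frac)) {
        m <- counter(a0, L)
        rec <- pair_record(a0, b0, L, m, "inverted", n)
        rec$diagonal <- paste0("u", u)
        rec$win_start <- a0
        cand[[length(cand) + 1L]] <- rec
      }
    }
  }

  finalize_repeat_set(cand, n)
}

pair_record <- function(s1, s2, L, m, orientation, n) {
  if (s2 < s1) { tmp <- s1; s1 <- s2; s2 <- tmp }
  data.frame(
    copy_a_start = s1, copy_a_end = s1 + L,
    copy_b_start = s2, copy_b_end = s2 + L,
    orientation = orientation, length = L, mismatches = m,
    identity = (L - m) / L
  )
}

# Window extension feasibility shared by both orientations: an extension is
# possible iff the extended copies stay disjoint and the extended mismatch
# count respects the bound.
validate_direct <- function(counter, n, a0, L, d, min_len, frac) {
  if (L < min_len || L > n) return(FALSE)
  b0 <- (a0 + d) %% n
  m <- counter(a0, L)
  if (m > frac * L + FEAS_EPS) return(FALSE)
  if (!circ_disjoint(a0, b0, L, L, n)) return(FALSE)
  # right extension: both starts fixed, length L+1
  geo_ok <- (L + 1L) <= min(d, n - d)
  if (geo_ok && counter(a0, L + 1L) <= frac * (L + 1) + FEAS_EPS) return(FALSE)
  # left extension: both starts -1, length L+1
  if (geo_ok && counter((a0 - 1L) %% n, L + 1L) <= frac * (L + 1) + FEAS_EPS) {
    return(FALSE)
  }
  TRUE
}

validate_inverted <- function(counter, n, a0, L, u, min_len, frac) {
  if (L < min_len || L > n) return(FALSE)
  b0 <- (u - a0 - L + 1L) %% n
  if (((a0 - b0) %% n) == 0L) return(FALSE)  # identical interval
  m <- counter(a0, L)
  if (m > frac * L + FEAS_EPS) return(FALSE)
  if (!circ_disjoint(a0, b0, L, L, n)) return(FALSE)
  # right extension: copy_a end +1, copy_b start -1
  b_r <- (b0 - 1L) %% n
  if (circ_disjoint(a0, b_r, L + 1L, L + 1L, n) &&
      counter(a0, L + 1L) <= frac * (L + 1) + FEAS_EPS) {
    return(FALSE)
  }
  # left extension: copy_a start -1, copy_b end +1
  a_l <- (a0 - 1L) %% n
  if (circ_disjoint(a_l, b0, L + 1L, L + 1L, n) &&
      counter(a_l, L + 1L) <= frac * (L + 1) + FEAS_EPS) {
    return(FALSE)
  }
  TRUE
}

# Inverted windows whose extension is blocked by copy-overlap geometry:
# right-block requires (b0 - a0) mod n in {L, L+1}, i.e. 2*(a0+L) = u+1-delta
# (mod n); left-block requires 2*a0 = u+1+delta (mod n). Enumerate the few
# solutions and all lengths; definitional validation filters.
inverted_geometry_candidates <- function(counter, n, u, min_len, frac) {
  sols <- function(rhs) {
    rhs <- rhs %% n
    if (n %% 2L == 0L) {
      if (rhs %% 2L == 0L) c(rhs %/% 2L, rhs %/% 2L + n %/% 2L) else integer(0)
    } else {
      ((rhs * ((n + 1L) %/% 2L)) %% n)  # inverse of 2 mod odd n
    }
  }
  out <- NULL
  Ls <- min_len:(n %/% 2L)
  if (length(Ls) == 0L) return(NULL)
  for (delta in 0:1) {
    for (e in sols(u + 1L - delta)) {    # right-geometry: a0 = e - L
      a0 <- (e - Ls) %% n
      m <- vapply(seq_along(Ls), function(i) counter(a0[i], Ls[i]), numeric(1))
      keep <- m <= frac * Ls + FEAS_EPS
      if (any(keep)) {
        out <- rbind(out, data.frame(a0 = a0[keep], L = Ls[keep], m = m[keep]))
      }
    }
    for (a0 in sols(u + 1L + delta)) {   # left-geometry: a0 fixed
      m <- vapply(Ls, function(L) counter(a0, L), numeric(1))
      keep <- m <= frac * Ls + FEAS_EPS
      if (any(keep)) {
        out <- rbind(out, data.frame(a0 = a0, L = Ls[keep], m = m[keep]))
      }
    }
  }
  out
}

# Collapse overlapping maximal windows on one diagonal to the single best
# window (longest, then fewest mismatches, then smallest start) -- one
# reported pair per physical repeat locus.
merge_diagonal_loci <- function(df, n) {
  circ_overlap <- function(s1, L1, s2, L2) {
    (((s2 - s1) %% n) < L1) || (((s1 - s2) %% n) < L2)
  }
  out <- NULL
  for (dg in unique(df$diagonal)) {
    sub <- df[df$diagonal == dg, , drop = FALSE]
    k <- nrow(sub)
    if (k == 1L) { out <- rbind(out, sub); next }
    # union-find over window overlap on the diagonal
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (circ_overlap(sub$win_start[i], sub$length[i],
                       sub$win_start[j], sub$length[j])) {
        parent[find(j)] <- find(i)
      }
    }
    grp <- vapply(seq_len(k), find, integer(1))
    for (gid in unique(grp)) {
      rows <- sub[grp == gid, , drop = FALSE]
      rows <- rows[order(-rows$length, rows$mismatches, rows$win_start), ,
                   drop = FALSE]
      out <- rbind(out, rows[1, , drop = FALSE])
    }
  }
  out
}

# circular containment: is [s2, s2+L2) inside [s1, s1+L1)?
circ_contains <- function(s1, L1, s2, L2, n) {
  (((s2 - s1) %% n) + L2) <= L1
}

finalize_repeat_set <- function(cand, n) {
  empty <- data.frame(
    copy_a_start = integer(0), copy_a_end = integer(0),
    copy_b_start = integer(0), copy_b_end = integer(0),
    orientation = character(0), length = integer(0),
    mismatches = integer(0), identity = numeric(0)
  )
  df <- if (length(cand)) unique(do.call(rbind, cand)) else empty
  if (nrow(df) > 0L) {
    df <- merge_diagonal_loci(df, n)
    df$diagonal <- NULL
    df$win_start <- NULL
    df <- unique(df)  # d = n/2 yields the same pair from both window reps
  }
  df <- df[order(-df$length, df$copy_a_start, df$copy_b_start), , drop = FALSE]
  if (nrow(df) > 1L) {
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j] || df$length[j] <= df$length[i]) next
        if (df$orientation[i] != df$orientation[j]) next
        aa <- circ_contains(df$copy_a_start[j], df$length[j],
                            df$copy_a_start[i], df$length[i], n)
        bb <- circ_contains(df$copy_b_start[j], df$length[j],
                            df$copy_b_start[i], df$length[i], n)
        ab <- circ_contains(df$copy_b_start[j], df$length[j],
                            df$copy_a_start[i], df$length[i], n)
        ba <- circ_contains(df$copy_a_start[j], df$length[j],
                            df$copy_b_start[i], df$length[i], n)
        if ((aa && bb) || (ab && ba)) { keep[i] <- FALSE; break }
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "genome_length") <- n
  class(df) <- c("repeat_set", "data.frame")
  df
}

#' Total genomic bp covered by a set of repeat pairs
#'
#' Union of all copy intervals on the circle; overlapping copies are counted
#' once.
#'
#' @param pairs a `repeat_set` from [find_repeats()], or a data.frame with
#'   `copy_a_start`, `copy_a_end`, `copy_b_start`, `copy_b_end` columns.
#' @param genome_len circle length; defaults to the `genome_length`
#'   attribute of `pairs`.
#' @return total covered bp (integer).
#' @export
total_repeat_content <- function(pairs, genome_len = attr(pairs, "genome_length")) {
  if (is.null(genome_len)) stop("genome_len is required")
  if (nrow(pairs) == 0L) return(0L)
  s <- c(pairs$copy_a_start, pairs$copy_b_start) %% genome_len
  e <- s + c(pairs$copy_a_end - pairs$copy_a_start,
             pairs$copy_b_end - pairs$copy_b_start)
  # unroll wrapping intervals into two linear pieces
  st <- c(s + 1L, rep(1L, sum(e > genome_len)))
  en <- c(pmin(e, genome_len), e[e > genome_len] - genome_len)
  sum(IRanges::width(reduce(IRanges(start = st, end = en))))
}

#' Write a repeat set to TSV
#' @param pairs a `repeat_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_repeats_tsv <- function(pairs, path) {
  write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
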