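# Definitional brute-force oracle for repeat-pair detection, written
# independently of the package implementation. Semantics: all windows
# (a0, L) on every alignment diagonal with L >= min_len, mismatch count
# m <= frac * L, disjoint copies, whose one-base extensions on either side
# are each blocked (mismatch bound broken or copies would overlap);
# overlapping maximal windows on one diagonal collapse to the best
# (longest, fewest mismatches, smallest start); pairs fully contained in a
# longer reported pair are suppressed. Ordering: length desc, copy_a_start,
# copy_b_start.

oracle_repeats <- function(seq, min_len = 30, frac = 0.10) {
  eps <- 1e-9
  seq <- toupper(seq)
  n <- nchar(seq)
  cx <- strsplit(seq, "")[[1]]
  compc <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  half <- n %/% 2L
  Ls_all <- if (min_len <= half) min_len:half else integer(0)
  mcap_min <- floor(frac * min_len + eps)
  rows <- list()

  screen_ok <- function(mm) {
    cs <- c(0, cumsum(c(mm, mm[seq_len(min_len - 1L)])))
    any((cs[(min_len + 1L):(n + min_len)] - cs[1:n]) <= mcap_min)
  }

  scan_one <- function(mm, diag_key, orientation, partner_start) {
    # partner_start(a0, L): 0-based start of copy_b for window (a0, L),
    # vectorised over L
    cs <- c(0, cumsum(c(mm, mm)))
    cnt <- function(a0, L) cs[a0 + 1L + L] - cs[a0 + 1L]
    disj <- function(s1, s2, L) {
      (((s2 - s1) %% n) >= L) & (((s1 - s2) %% n) >= L)
    }
    for (a0 in 0:(n - 1L)) {
      if (length(Ls_all) == 0L) next
      m <- cnt(a0, Ls_all)
      b0 <- partner_start(a0, Ls_all)
      feas <- (m <= frac * Ls_all + eps) & disj(a0, b0, Ls_all)
      if (!any(feas)) next
      a_l <- (a0 - 1L) %% n
      # left extension keeps copy_b start (window grows 5'), right
      # extension shifts copy_b start for inverted pairs
      bl <- partner_start(a_l, Ls_all + 1L)
      br <- partner_start(a0, Ls_all + 1L)
      left_ok <- disj(a_l, bl, Ls_all + 1L) &
        (cnt(a_l, Ls_all + 1L) <= frac * (Ls_all + 1L) + eps)
      right_ok <- disj(a0, br, Ls_all + 1L) &
        (cnt(a0, Ls_all + 1L) <= frac * (Ls_all + 1L) + eps)
      rep_L <- Ls_all[feas & !left_ok & !right_ok]
      for (L in rep_L) {
        s2 <- partner_start(a0, L)
        s1 <- a0
        if (s2 < s1) { tmp <- s1; s1 <- s2; s2 <- tmp }
        if (orientation == "inverted" && a0 != s1) next  # one rep per pair
        rows[[length(rows) + 1L]] <<- data.frame(
          copy_a_start = s1, copy_a_end = s1 + L,
          copy_b_start = s2, copy_b_end = s2 + L,
          orientation = orientation, length = L,
          mismatches = cnt(a0, L), identity = (L - cnt(a0, L)) / L,
          diagonal = diag_key, win_start = a0
        )
      }
    }
  }

  for (d in seq_len(half)) {
    partner <- cx[((0:(n - 1L) + d) %% n) + 1L]
    mm <- (cx != partner) | cx == "N" | partner == "N"
    if (!screen_ok(mm)) next
    # copies overlap unless L <= min(d, n - d); disj() enforces this
    scan_one(mm, paste0("d", d), "direct",
             function(a0, L) rep((a0 + d) %% n, length(L)))
  }
  for (u in 0:(n - 1L)) {
    partner <- compc[cx[((u - 0:(n - 1L)) %% n) + 1L]]
    mm <- (cx != partner) | cx == "N" | partner == "N"
    if (!screen_ok(mm)) next
    scan_one(mm, paste0("u", u), "inverted",
             function(a0, L) (u - a0 - L + 1L) %% n)
  }

  empty <- data.frame(
    copy_a_start = integer(0), copy_a_end = integer(0),
    copy_b_start = integer(0), copy_b_end = integer(0),
    orientation = character(0), length = integer(0),
    mismatches = integer(0), identity = numeric(0)
  )
  if (length(rows) == 0L) return(empty)
  df <- unique(do.call(rbind, rows))

  # locus merge per diagonal: connected components of window overlap (BFS)
  circ_ov <- function(s1, L1, s2, L2) {
    (((s2 - s1) %% n) < L1) || (((s1 - s2) %% n) < L2)
  }
  merged <- NULL
  for (key in unique(df$diagonal)) {
    sub <- df[df$diagonal == key, , drop = FALSE]
    k <- nrow(sub)
    adj <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
      circ_ov(sub$win_start[i], sub$length[i], sub$win_start[j], sub$length[j])
    }))
    comp <- rep(NA_integer_, k)
    cid <- 0L
    for (i in seq_len(k)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, which(adj[v, ] & is.na(comp)))
      }
    }
    for (cc in unique(comp)) {
      grp <- sub[comp == cc, , drop = FALSE]
      grp <- grp[order(-grp$length, grp$mismatches, grp$win_start), ,
                 drop = FALSE]
      merged <- rbind(merged, grp[1, , drop = FALSE])
    }
  }
  df <- merged
  df$diagonal <- NULL; df$win_start <- NULL
  df <- unique(df)
  df <- df[order(-df$length, df$copy_a_start, df$copy_b_start), , drop = FALSE]

  # containment suppression against longer reported pairs
  inside <- function(As, AL, Bs, BL) (((Bs - As) %% n) + BL) <= AL
  keep <- rep(TRUE, nrow(df))
  if (nrow(df) > 1L) {
    for (i in seq_len(nrow(df))) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j] || df$length[j] <= df$length[i] ||
            df$orientation[i] != df$orientation[j]) next
        same <- inside(df$copy_a_start[j], df$length[j],
                       df$copy_a_start[i], df$length[i]) &&
                inside(df$copy_b_start[j], df$length[j],
                       df$copy_b_start[i], df$length[i])
        cross <- inside(df$copy_b_start[j], df$length[j],
                        df$copy_a_start[i], df$length[i]) &&
                 inside(df$copy_a_start[j], df$length[j],
                        df$copy_b_start[i], df$length[i])
        if (same || cross) { keep[i] <- FALSE; break }
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

strip_repeat_set <- function(r) {
  df <- as.data.frame(r)
  attr(df, "genome_length") <- NULL
  rownames(df) <- NULL
  df
}
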