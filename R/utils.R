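# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Fixed-digit rounding where ties go up (`0.05 -> 0.1`), matching the
#' conventional formatting of percentage tables, rather than R's
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)` on the proportion scale.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Reverse complement of a plain character string (N maps to N).
revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  as.character(reverseComplement(DNAString(s)))
}

# Uppercase and validate a DNA string over {A,C,G,T,N}.
clean_dna <- function(s, what = "sequence") {
  s <- toupper(s)
  if (nchar(s) == 0L) stop(what, " must be non-empty")
  if (grepl("[^ACGTN]", s)) {
    stop(what, " contains characters outside {A,C,G,T,N}")
  }
  s
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards. Generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Mutate `n_sub` positions of a string to a different random base.
mutate_string <- function(s, positions, rng_bases = NULL) {
  r <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in positions) {
    r[p] <- sample(setdiff(DNA_BASES, r[p]), 1L)
  }
  paste(r, collapse = "")
}
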