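test_that("junctions are motif plus flanks and B flanks are cross-combinations", {
  tr <- make_toy_genome_pair(6000, dr_long_len = 600, dr_short_len = 61,
                             seed = 401)
  js <- build_junctions(tr$genome_a, tr$genome_b, tr$motif_short,
                        flank_len = 30)
  expect_named(js$junctions, c("A1", "A2", "B1", "B2"))
  expect_true(all(nchar(js$junctions) == 61 + 2 * 30))
  # independent coordinate oracle: direct substring extraction around each
  # motif copy of the A genome
  dblA <- paste0(tr$genome_a$seq, tr$genome_a$seq)
  n <- seq_length(tr$genome_a)
  starts <- sort(mitostruct:::locate_motif(tr$genome_a, tr$motif_short)$start)
  for (i in 1:2) {
    from <- ((starts[i] - 30) %% n) + 1
    expect_equal(js$junctions[[paste0("A", i)]],
                 substr(dblA, from, from + 120))
  }
  # flank pairings of B are the cross-combinations of A's
  up <- function(j) substr(j, 1, 30); dn <- function(j) substr(j, 92, 121)
  crossed <-
    (up(js$junctions[["B1"]]) == up(js$junctions[["A1"]]) &&
       dn(js$junctions[["B1"]]) == dn(js$junctions[["A2"]])) ||
    (up(js$junctions[["B1"]]) == up(js$junctions[["A2"]]) &&
       dn(js$junctions[["B1"]]) == dn(js$junctions[["A1"]]))
  expect_true(crossed)
  # identical genomes give no diagnostic power
  js0 <- build_junctions(tr$genome_a, tr$genome_a, tr$motif_short)
  expect_setequal(unname(js0$junctions[c("B1", "B2")]),
                  unname(js0$junctions[c("A1", "A2")]))
  expect_error(build_junctions(tr$genome_a, tr$genome_b, "ACGTACGTACGT"),
               "occurs")
})

test_that("junction construction is rotation invariant", {
  tr <- make_toy_genome_pair(6000, dr_long_len = 600, dr_short_len = 61,
                             seed = 402)
  js1 <- build_junctions(tr$genome_a, tr$genome_b, tr$motif_short)
  js2 <- build_junctions(rotate_genome(tr$genome_a, 1234),
                         rotate_genome(tr$genome_b, 4321), tr$motif_short)
  expect_setequal(unname(js1$junctions[c("A1", "A2")]),
                  unname(js2$junctions[c("A1", "A2")]))
  expect_setequal(unname(js1$junctions[c("B1", "B2")]),
                  unname(js2$junctions[c("B1", "B2")]))
})

test_that("error-free reads from a pure source classify without error", {
  tr <- make_toy_genome_pair(6000, dr_long_len = 600, dr_short_len = 61,
                             seed = 403)
  js <- build_junctions(tr$genome_a, tr$genome_b, tr$motif_short)
  sim <- simulate_reads(tr, weight_b = 0, coverage = 300, read_len = 150,
                        error_rate = 0, seed = 404)
  cl <- classify_reads(sim, js, max_mismatches = 3)
  expect_gte(cl$n_analyzed, 50)
  expect_equal(cl$n_B, 0L)
  expect_equal(cl$pct_A, 100.0)
  expect_equal(cl$n_analyzed + cl$n_ambiguous + cl$n_uninformative,
               length(sim$reads))
})

test_that("reads not spanning motif plus both flanks are uninformative", {
  tr <- make_toy_genome_pair(6000, dr_long_len = 600, dr_short_len = 61,
                             seed = 405)
  js <- build_junctions(tr$genome_a, tr$genome_b, tr$motif_short)
  # a 100 bp read lying fully inside one junction window covers no
  # complete flank pair
  inside <- substr(js$junctions[["A1"]], 11, 110)
  cl <- classify_reads(c(inside, js$junctions[["A1"]]), js, max_mismatches = 0)
  expect_equal(cl$labels, c("uninformative", "A"))
  # reverse-complement spanning reads classify identically
  cl2 <- classify_reads(str_revcomp(js$junctions[["B2"]]), js, max_mismatches = 0)
  expect_equal(cl2$labels, "B")
  expect_error(classify_reads(character(0), js), "empty")
  expect_error(classify_reads("ACGT", js), "long enough")
})

test_that("a mixed read set recovers the planted minor fraction", {
  tr <- make_toy_genome_pair(20000, dr_long_len = 2000, dr_short_len = 61,
                             seed = 406)
  js <- build_junctions(tr$genome_a, tr$genome_b, tr$motif_short)
  sim <- simulate_reads(tr, weight_b = 0.95, coverage = 120, seed = 407)
  cl <- classify_reads(sim, js, max_mismatches = 3)
  ci <- wilson_ci(cl$n_B, cl$n_analyzed)
  expect_gte(0.95, ci["lower"])
  expect_lte(0.95, ci["upper"])
  # per-read labels agree with the simulator's source tags for analyzed reads
  ok <- cl$labels %in% c("A", "B")
  expect_true(all(cl$labels[ok] == sim$source[ok]))
})

test_that("frequency table reproduces printed counts at one decimal", {
  counts <- list(c(114, 113, 1), c(78, 77, 1), c(116, 116, 0),
                 c(70, 70, 0), c(101, 101, 0), c(121, 6, 115))
  cls <- lapply(counts, function(k) classification_from_counts(k[1], k[2], k[3]))
  tab <- frequency_table(cls, labels = paste0("ind", 1:6))
  expect_equal(tab$pct_A, c(99.1, 98.7, 100.0, 100.0, 100.0, 5.0))
  expect_equal(tab$pct_B, c(0.9, 1.3, 0.0, 0.0, 0.0, 95.0))
  expect_equal(tab$analyzed, vapply(counts, `[`, numeric(1), 1))
})

test_that("half-up rounding and the Wilson interval behave as documented", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(4.9587, 1), 5.0)
  expect_equal(round_half_up(99.122, 1), 99.1)
  ci <- wilson_ci(0, 30)
  expect_equal(unname(ci["lower"]), 0)
  expect_gt(ci["upper"], 0.05)
  ci2 <- wilson_ci(15, 30)
  expect_lt(ci2["lower"], 0.5); expect_gt(ci2["upper"], 0.5)
})

test_that("FASTQ written by the simulator classifies identically", {
  tr <- make_toy_genome_pair(6000, dr_long_len = 600, dr_short_len = 61,
                             seed = 408)
  js <- build_junctions(tr$genome_a, tr$genome_b, tr$motif_short)
  sim <- simulate_reads(tr, weight_b = 0.5, coverage = 150, seed = 409)
  tmp <- tempfile(fileext = ".fastq")
  write_fastq(sim, tmp)
  cl_mem <- classify_reads(sim, js)
  cl_file <- classify_reads(tmp, js)
  expect_equal(cl_file$labels, cl_mem$labels)
  unlink(tmp)
})
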