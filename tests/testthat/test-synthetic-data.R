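test_that("genome pair generation is deterministic and conserving", {
  tr1 <- make_toy_genome_pair(30000, seed = 701)
  tr2 <- make_toy_genome_pair(30000, seed = 701)
  expect_identical(tr1$genome_a$seq, tr2$genome_a$seq)
  expect_identical(tr1$genome_b$seq, tr2$genome_b$seq)
  expect_equal(seq_length(tr1$genome_a), 30000L)
  expect_equal(seq_length(tr1$genome_b), 30000L)
  expect_false(seq_structure_equal(tr1$genome_a, tr1$genome_b))
  tr3 <- make_toy_genome_pair(30000, seed = 702)
  expect_false(identical(tr1$genome_a$seq, tr3$genome_a$seq))
  expect_error(make_toy_genome_pair(10000), ">=")
})

test_that("planted repeats are the only repeats the finder reports", {
  tr <- make_toy_genome_pair(8000, dr_long_len = 800, dr_short_len = 61,
                             seed = 703)
  r <- find_repeats(tr$genome_a)
  expect_equal(nrow(r), 2L)
  expect_equal(sort(r$orientation), c("direct", "direct"))
  # recovered loci contain the planted coordinates (circular containment;
  # a reported window may wrap the origin and swap the copy labels)
  inside <- function(os, ol, is, il, n) (((is - os) %% n) + il) <= ol
  contains <- function(row, planted, n = 8000) {
    pl <- planted$copy_a_end - planted$copy_a_start
    rl <- row$length
    (inside(row$copy_a_start, rl, planted$copy_a_start, pl, n) &&
       inside(row$copy_b_start, rl, planted$copy_b_start, pl, n)) ||
      (inside(row$copy_a_start, rl, planted$copy_b_start, pl, n) &&
         inside(row$copy_b_start, rl, planted$copy_a_start, pl, n))
  }
  expect_true(contains(r[1, ], tr$dr_long))
  expect_true(contains(r[2, ], tr$dr_short))
  expect_lte(r$mismatches[1], r$length[1] - 800)  # planted copies are exact
  # flanks around the short-repeat copies are pairwise distinct
  js <- build_junctions(tr$genome_a, tr$genome_b, tr$motif_short)
  expect_equal(length(unique(unlist(js$junctions))), 4L)
})

test_that("the A-type block layout reconstructs the genome", {
  tr <- make_toy_genome_pair(5000, dr_long_len = 500, dr_short_len = 61,
                             seed = 704)
  arr <- arrangement_of(tr$genome_a, tr$blocks)
  expect_equal(arrangement_sequence(arr), tr$genome_a$seq)
  expect_equal(sum(tr$blocks$end - tr$blocks$start), 5000L)
})

test_that("read simulation is deterministic, labelled, and error-calibrated", {
  tr <- make_toy_genome_pair(8000, dr_long_len = 800, dr_short_len = 61,
                             seed = 705)
  s1 <- simulate_reads(tr, weight_b = 0.3, coverage = 10, seed = 706)
  s2 <- simulate_reads(tr, weight_b = 0.3, coverage = 10, seed = 706)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$names, s2$names)
  s0 <- simulate_reads(tr, weight_b = 0, coverage = 5, seed = 707)
  expect_true(all(s0$source == "A"))
  expect_true(all(grepl("src=A", s0$names)))
  expect_true(all(nchar(s1$reads) == 150))

  # mean per-base mismatch rate against the source is error_rate within 3 sd
  err <- 0.01
  sim <- simulate_reads(tr, weight_b = 0, coverage = 20, read_len = 100,
                        error_rate = err, seed = 708)
  dbl <- paste0(tr$genome_a$seq, tr$genome_a$seq)
  info <- regmatches(sim$names,
                     regexec("pos=(\\d+)\\|strand=([+-])", sim$names))
  mism <- vapply(seq_along(sim$reads), function(i) {
    pos <- as.integer(info[[i]][2]); strand <- info[[i]][3]
    src <- substr(dbl, pos + 1, pos + 100)
    if (strand == "-") src <- str_revcomp(src)
    sum(strsplit(src, "")[[1]] != strsplit(sim$reads[i], "")[[1]])
  }, numeric(1))
  total_bases <- length(sim$reads) * 100
  expect_lt(abs(sum(mism) - total_bases * err),
            3 * sqrt(total_bases * err * (1 - err)))
  expect_error(simulate_reads(tr, weight_b = 2, coverage = 1), "weight_b")
  expect_error(simulate_reads(tr, weight_b = 0, coverage = 0), "coverage")
})

test_that("paired-end mode emits mate pairs from one fragment source", {
  tr <- make_toy_genome_pair(8000, dr_long_len = 800, dr_short_len = 61,
                             seed = 709)
  sim <- simulate_reads(tr, weight_b = 0.5, coverage = 5, paired = TRUE,
                        seed = 710)
  expect_equal(length(sim$reads) %% 2, 0)
  expect_true(all(nchar(sim$reads) == 150))
  src_pairs <- matrix(sim$source, nrow = 2)
  expect_true(all(src_pairs[1, ] == src_pairs[2, ]))
})

test_that("pseudogene set generation is deterministic and records truth", {
  ref <- random_cds(150, seed = 711)
  p1 <- make_pseudogene_set(ref, n_copies = 3, shared_insert_pos = 20,
                            seed = 712)
  p2 <- make_pseudogene_set(ref, n_copies = 3, shared_insert_pos = 20,
                            seed = 712)
  expect_identical(p1$sequences, p2$sequences)
  expect_equal(length(p1$sequences), 3L)
  expect_true(all(vapply(p1$truth, function(t) t$shared_insertion == 20,
                         logical(1))))
  expect_error(make_pseudogene_set(ref, shared_insert_pos = 61), "60")
  # a single copy with no private events shows exactly one frameshift
  set.seed(713)
  bare <- paste0(substr(ref, 1, 21), "A", substr(ref, 22, nchar(ref)))
  r <- scan_pseudogene(bare, ref)
  expect_equal(nrow(r$frameshifts), 1L)
})

test_that("the full synthetic pipeline recovers planted mixture weights", {
  # compressed end-to-end check (the deep replicate study lives in the
  # acceptance suite): one replicate per weight must fall in the Wilson
  # interval
  for (w in c(0.05, 0.95)) {
    tr <- make_toy_genome_pair(20000, dr_long_len = 2000, dr_short_len = 61,
                               seed = 714 + round(100 * w))
    js <- build_junctions(tr$genome_a, tr$genome_b, tr$motif_short)
    sim <- simulate_reads(tr, weight_b = w, coverage = 150,
                          seed = 715 + round(100 * w))
    cl <- classify_reads(sim, js)
    ci <- wilson_ci(cl$n_B, cl$n_analyzed)
    expect_gte(w, ci["lower"])
    expect_lte(w, ci["upper"])
  }
})
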