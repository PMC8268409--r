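# End-to-end demo run binding all modules; also the engine behind the
# command-line wrapper in inst/cli/mitostruct.R.

#' Run an end-to-end synthetic demonstration
#'
#' Regenerates, from one seed, a toy genome-structure pair with planted
#' repeats, the repeat table, a simulated read mixture with its
#' structural-type frequency table, a pseudogene report set, and an intron
#' configuration report, writing every artifact plus the run configuration
#' to `out_dir`.
#'
#' @param seed integer master seed.
#' @param out_dir output directory (created if missing).
#' @param genome_len demo circle length (default 8000; scaled so the repeat
#'   scan completes in seconds).
#' @param dr_long_len,dr_short_len planted repeat lengths.
#' @param weight_b B-type mixture weight for the simulated individual.
#' @param coverage read coverage.
#' @return invisibly, a list with the in-memory results.
#' @export
run_demo <- function(seed = 1, out_dir = "mitostruct-demo",
                     genome_len = 8000, dr_long_len = 800,
                     dr_short_len = 61, weight_b = 0.95, coverage = 80) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  cfg <- list(seed = seed, genome_len = genome_len,
              dr_long_len = dr_long_len, dr_short_len = dr_short_len,
              weight_b = weight_b, coverage = coverage,
              read_len = 150, error_rate = 0.002, flank_len = 30,
              max_mismatches = 3)
  jsonlite::write_json(cfg, pth("config.json"), auto_unbox = TRUE)

  truth <- make_toy_genome_pair(genome_len, dr_long_len, dr_short_len,
                                seed = seed)
  write_genome_fasta(list(truth$genome_a, truth$genome_b), pth("genomes.fa"))

  reps <- find_repeats(truth$genome_a)
  write_repeats_tsv(reps, pth("repeats.tsv"))

  sim <- simulate_reads(truth, weight_b = weight_b, coverage = coverage,
                        read_len = cfg$read_len, error_rate = cfg$error_rate,
                        seed = seed + 1L)
  write_fastq(sim, pth("reads.fastq"))
  js <- build_junctions(truth$genome_a, truth$genome_b, truth$motif_short,
                        flank_len = cfg$flank_len)
  cl <- classify_reads(sim, js, max_mismatches = cfg$max_mismatches)
  tab <- frequency_table(list(cl), labels = sprintf("demo-seed%d", seed))
  write_frequency_table(tab, pth("structure_frequencies.tsv"))

  ref <- random_cds(200, seed = seed)
  pset <- make_pseudogene_set(ref, n_copies = 7, shared_insert_pos = 30,
                              seed = seed)
  reports <- lapply(pset$sequences, scan_pseudogene, reference_cds = ref)
  prep <- data.frame(
    copy = seq_along(reports),
    status = vapply(reports, `[[`, character(1), "status"),
    frameshifts = vapply(reports, function(r) nrow(r$frameshifts), numeric(1)),
    premature_stops = vapply(reports, function(r) nrow(r$premature_stops),
                             numeric(1)),
    truncation_3prime = vapply(reports, `[[`, numeric(1), "truncation_3prime")
  )
  write.table(prep, pth("pseudogene_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  shared <- shared_diagnostic_events(reports)

  # intron demo: exon4+matR locus with exon5 far away on the B circle
  n <- genome_len
  feats <- data.frame(
    feature = c("exon4", "matR", "exon5"),
    start = c(100L, 700L, (700L + 2000L + n %/% 3) %% n),
    end = c(500L, 2700L, (700L + 2000L + n %/% 3 + 300L) %% n),
    strand = "+"
  )
  feats$end <- feats$start + c(400L, 2000L, 300L)
  intron <- classify_intron_configuration(truth$genome_a, feats)
  jsonlite::write_json(
    list(mode = intron$mode, breakpoint_type = intron$breakpoint_type,
         locus_distance = intron$locus_distance,
         distance_other_arc = intron$distance_other_arc),
    pth("intron_report.json"), auto_unbox = TRUE)

  invisible(list(truth = truth, repeats = reps, classification = cl,
                 table = tab, pseudogene_reports = reports,
                 shared_events = shared, intron = intron))
}
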