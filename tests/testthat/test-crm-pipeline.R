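# End-to-end pipeline: input extraction, scanning, report writers.

make_genome_fixture <- function(dir) {
  set.seed(101)
  contig <- random_dna(1000, gc = 0.4)
  fa <- file.path(dir, "toy_genome.fasta")
  writeLines(c(">contig1 toy", contig), fa)
  bed <- file.path(dir, "regions.bed")
  writeLines("contig1\t100\t400\tcrmA\t0\t+", bed)
  list(fa = fa, bed = bed, contig = contig)
}

test_that("BED intervals extract the stated plus-strand subsequence", {
  dir <- withr::local_tempdir()
  fx <- make_genome_fixture(dir)
  expect_warning(regions <- read_bed(fx$bed), "strand")
  expect_equal(regions$start, 100L)
  expect_equal(regions$end, 400L)
  crms <- extract_crms(fx$fa, regions)
  expect_length(crms, 1L)
  expect_equal(crms[[1]]$name, "crmA")
  expect_equal(nchar(crms[[1]]$sequence), 300L)
  expect_equal(crms[[1]]$sequence, substr(fx$contig, 101, 400))
})

test_that("out-of-bounds and unknown-contig regions error naming the record", {
  dir <- withr::local_tempdir()
  fx <- make_genome_fixture(dir)
  genome <- read_fasta(fx$fa)
  bad_end <- data.frame(seq_id = "contig1", start = 900L, end = 1100L,
                        name = "crmOver", stringsAsFactors = FALSE)
  expect_error(extract_crms(genome, bad_end), "crmOver.*out of bounds")
  bad_contig <- data.frame(seq_id = "contigX", start = 0L, end = 10L,
                           name = "crmGhost", stringsAsFactors = FALSE)
  expect_error(extract_crms(genome, bad_contig), "crmGhost.*not found")
  expect_length(extract_crms(genome, bad_end[0, ]), 0L)
})

test_that("genome coordinates equal CRM offset plus within-CRM coordinates", {
  dir <- withr::local_tempdir()
  # plant an Ets word at a known genome position inside the region
  set.seed(7)
  contig <- random_dna(600, gc = 0.3)
  substr(contig, 251, 255) <- "AGGAT"
  fa <- file.path(dir, "g.fasta")
  writeLines(c(">c1", contig), fa)
  regions <- data.frame(seq_id = "c1", start = 200L, end = 500L,
                        name = "crm1", stringsAsFactors = FALSE)
  crms <- extract_crms(fa, regions)
  rep <- run_scan(crms, sfze_consensus_motifs())
  sites <- sfzescan:::report_sites(rep)
  ets <- sites[sites$tf_class == "E" & sites$strand == "+" &
                 sites$start == 250, ]
  expect_equal(nrow(ets), 1L)
  within <- rep$results$crm1$sites$sites
  hit <- within[within$tf_class == "E" & within$start == 50, ]
  expect_equal(200L + hit$start, ets$start)
})

test_that("run_scan classifies planted and background CRMs and is deterministic", {
  motifs <- synthetic_motif_set()
  cfg <- simulation_config(seed = 33, n_sequences = 2,
                           arrangement = c("FULL_DIRECT",
                                           "BACKGROUND_ONLY"))
  d <- generate_dataset(cfg, motifs = motifs)
  crms <- crms_from_fasta(d$sequences)
  rep1 <- run_scan(crms, motifs)
  expect_equal(rep1$results$synth_001$tier, "SFZE_FULL")
  expect_equal(rep1$results$synth_002$tier, "INCOMPLETE")
  expect_length(rep1$results$synth_002$instances, 0L)
  rep2 <- run_scan(crms, motifs)
  expect_identical(summary(rep1), summary(rep2))
  expect_identical(rep1$meta$config_fingerprint,
                   rep2$meta$config_fingerprint)
})

test_that("TSV and JSON outputs are byte-identical across repeated runs", {
  dir <- withr::local_tempdir()
  motifs <- synthetic_motif_set()
  d <- generate_dataset(simulation_config(seed = 12, n_sequences = 2,
                                          arrangement = "FULL_DIRECT"),
                        motifs = motifs)
  crms <- crms_from_fasta(d$sequences)
  for (run in 1:2) {
    rep <- run_scan(crms, motifs)
    write_summary_tsv(rep, file.path(dir, paste0("sum", run, ".tsv")))
    write_report_json(rep, file.path(dir, paste0("rep", run, ".json")))
  }
  expect_identical(readLines(file.path(dir, "sum1.tsv")),
                   readLines(file.path(dir, "sum2.tsv")))
  expect_identical(readLines(file.path(dir, "rep1.json")),
                   readLines(file.path(dir, "rep2.json")))
})

test_that("GFF3 output is 1-based inclusive and round-trips intervals", {
  dir <- withr::local_tempdir()
  motifs <- synthetic_motif_set()
  d <- generate_dataset(simulation_config(seed = 5, n_sequences = 1,
                                          arrangement = "FULL_DIRECT"),
                        motifs = motifs)
  rep <- run_scan(crms_from_fasta(d$sequences), motifs)
  gff <- file.path(dir, "sites.gff3")
  write_sites_gff3(rep, gff)
  back <- rtracklayer::import(gff)
  sites <- sfzescan:::report_sites(rep)
  got <- back[back$type == "TF_binding_site"]
  ord <- order(GenomicRanges::start(got))
  expect_equal(GenomicRanges::start(got)[ord], sites$start + 1L)
  expect_equal(GenomicRanges::end(got)[ord], sites$end)
  expect_equal(as.character(got$tf_class)[ord], sites$tf_class)
  region <- back[back$type == "region"]
  expect_equal(as.character(region$tier), "SFZE_FULL")
})

test_that("BED output scales scores to 0-1000 and empty reports give empty files", {
  dir <- withr::local_tempdir()
  motifs <- synthetic_motif_set()
  d <- generate_dataset(simulation_config(seed = 5, n_sequences = 1,
                                          arrangement = "FULL_DIRECT"),
                        motifs = motifs)
  rep <- run_scan(crms_from_fasta(d$sequences), motifs)
  bed <- file.path(dir, "sites.bed")
  write_sites_bed(rep, bed)
  back <- suppressWarnings(read_bed(bed))
  sites <- sfzescan:::report_sites(rep)
  expect_equal(nrow(back), nrow(sites))
  raw <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  cons_rows <- grepl("^(E|S|S_LIKE):", raw$V4) &
    raw$V4 %in% paste(sites$tf_class, sites$motif_id, sep = ":")
  expect_true(all(raw$V5[raw$V4 == "E:ETS_core"] == 1000L))
  # empty report: header-free, zero-length outputs that still parse
  empty <- run_scan(list(), motifs)
  write_sites_bed(empty, file.path(dir, "empty.bed"))
  expect_equal(length(readLines(file.path(dir, "empty.bed"))), 0L)
  write_summary_tsv(empty, file.path(dir, "empty.tsv"))
  expect_equal(length(readLines(file.path(dir, "empty.tsv"))), 1L)
})

test_that("JSON report round-trips its key fields", {
  dir <- withr::local_tempdir()
  motifs <- synthetic_motif_set()
  d <- generate_dataset(simulation_config(seed = 9, n_sequences = 1,
                                          arrangement = "PARTIAL_INVERTED"),
                        motifs = motifs)
  rep <- run_scan(crms_from_fasta(d$sequences), motifs)
  path <- file.path(dir, "report.json")
  write_report_json(rep, path)
  back <- read_report_json(path)
  expect_equal(back$crms[[1]]$tier, rep$results$synth_001$tier)
  expect_equal(back$crms[[1]]$arrangement,
               rep$results$synth_001$arrangement)
  got_sites <- back$crms[[1]]$sites
  want_sites <- rep$results$synth_001$sites$sites
  expect_equal(vapply(got_sites, function(s) s$start, numeric(1)),
               as.numeric(want_sites$start))
  expect_equal(vapply(got_sites, function(s) s$end, numeric(1)),
               as.numeric(want_sites$end))
  expect_equal(vapply(got_sites, function(s) s$tf_class, character(1)),
               want_sites$tf_class)
  expect_equal(back$meta$config_fingerprint, rep$meta$config_fingerprint)
  expect_equal(length(back$crms[[1]]$instances),
               length(rep$results$synth_001$instances))
})

test_that("errors inside a CRM propagate with the CRM name attached", {
  crm <- crm_record("tight_budget", "c", 0, 300, strrep("AGGAT", 60))
  tiny <- syntax_grammar(enumeration_budget = 1)
  expect_error(run_scan(list(crm), sfze_consensus_motifs(),
                        grammar = tiny),
               "tight_budget")
})
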