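# A small but structurally faithful configuration used throughout: two direct
# repeat pairs on a 30 kb circle.
small_cfg <- function(seed = 42, ...) {
  sim_config(genome_length = 30000, repeat_lengths = c(2000, 1200),
             read_mean_length = 5000, read_length_sd = 2000, n_reads = 60,
             error_rate = 0, flank_len = 400, seed = seed, ...)
}

test_that("the default configuration encodes the study conditions", {
  cfg <- sim_config()
  expect_identical(cfg$genome_length, 515187L)
  expect_identical(cfg$repeat_lengths, c(9026L, 7040L))
  expect_equal(cfg$gc_target, 0.4405)
  expect_equal(cfg$read_mean_length, 17520)
  expect_equal(cfg$depth, 75)
  expect_equal(sum(cfg$isomer_weights), 1)
})

test_that("config validation rejects infeasible settings", {
  expect_error(sim_config(genome_length = 1000, repeat_lengths = c(400, 10)),
               class = "mitorecomb_config_error")
  expect_error(sim_config(gc_target = 1.2), class = "mitorecomb_config_error")
  expect_error(sim_config(isomer_weights = c(-1, 1, 0, 0)),
               class = "mitorecomb_config_error")
})

test_that("generated master genome has the planted layout", {
  sim <- generate_master_genome(small_cfg())
  g <- sim$genome
  expect_identical(seq_len_bp(g), 30000L)
  expect_true(g$circular)
  expect_identical(sim$layout, c("S1", "R1", "S2", "R2", "S3", "R1", "S4", "R2"))
  expect_identical(nrow(sim$repeats), 4L)
  # planted copies are exact duplicates at the annotated coordinates
  for (rid in c("R1", "R2")) {
    cp <- sim$repeats[sim$repeats$repeat_id == rid, ]
    seqs <- vapply(seq_len(2), function(i) {
      circ_substr(g, cp$start[i], cp$end[i] - cp$start[i] + 1L)
    }, character(1))
    expect_identical(seqs[1], seqs[2])
    expect_identical(nchar(seqs[1]), cp$end[1] - cp$start[1] + 1L)
  }
})

test_that("realized GC tracks the target at scale", {
  cfg <- sim_config(genome_length = 100000, repeat_lengths = c(3000, 2000),
                    gc_target = 0.4405, seed = 5)
  sim <- generate_master_genome(cfg)
  expect_lt(abs(gc_content(sim$genome) - 44.05), 0.5)
})

test_that("degenerate configs drop repeats gracefully", {
  cfg0 <- sim_config(genome_length = 5000, repeat_lengths = c(0, 0), seed = 1)
  sim0 <- generate_master_genome(cfg0)
  expect_identical(nrow(sim0$repeats), 0L)
  expect_identical(length(derive_isomers(sim0)), 1L)

  cfg1 <- sim_config(genome_length = 10000, repeat_lengths = c(800, 0), seed = 2)
  sim1 <- generate_master_genome(cfg1)
  expect_identical(nrow(sim1$repeats), 2L)
  isos1 <- derive_isomers(sim1)
  expect_identical(length(isos1), 2L)
  expect_setequal(vapply(isos1, `[[`, character(1), "classification"),
                  c("master", "sub_circle_pair"))
})

test_that("derived isomers conserve the segment multiset and total length", {
  sim <- generate_master_genome(small_cfg())
  isos <- derive_isomers(sim)
  expect_named(isos, c("A", "B", "C", "D"))
  master_multiset <- sort(sim$layout)
  total <- seq_len_bp(sim$genome)
  tl <- tidy(isos)
  for (nm in names(isos)) {
    segs <- sort(unlist(isos[[nm]]$circles))
    expect_identical(segs, master_multiset)
    expect_equal(sum(tl$length[tl$isomer == nm]), total)
  }
  expect_identical(isos$A$classification, "master")
  expect_identical(isos$B$classification, "master")
  expect_identical(isos$C$classification, "sub_circle_pair")
  expect_identical(isos$D$classification, "sub_circle_pair")
  # isomer A reproduces the input master circle
  seqA <- isomer_to_fasta(isos$A, attr(isos, "graph"))$seq
  expect_identical(sort(strsplit(seqA, "")[[1]]), sort(strsplit(sim$genome$seq, "")[[1]]))
  expect_true(grepl(substr(sim$genome$seq, 1, 5000), strrep(seqA, 2), fixed = TRUE))
})

test_that("simulated read lengths follow the configured distribution", {
  cfg <- sim_config(genome_length = 100000, repeat_lengths = c(3000, 2000),
                    n_reads = 1000, read_mean_length = 17520,
                    read_length_sd = 3000, error_rate = 0, seed = 9)
  sim <- generate_master_genome(cfg)
  reads <- simulate_reads(sim, cfg)
  expect_identical(nrow(reads), 1000L)
  expect_lt(abs(mean(nchar(reads$seq)) - 17520) / 17520, 0.1)
})

test_that("error-free reads are exact circular substrings of their source", {
  cfg <- small_cfg(seed = 13)
  sim <- generate_master_genome(cfg)
  isos <- derive_isomers(sim)
  circles <- isomer_circles(isos)
  reads <- simulate_reads(sim, cfg, isos)
  for (i in sample.int(nrow(reads), 20)) {
    src <- circles[circles$circle_label == reads$source_circle[i], ]
    expected <- circ_substr(circ_seq(src$seq, circular = TRUE),
                            reads$start[i], reads$span[i])
    got <- reads$seq[i]
    if (reads$strand[i] == "-") got <- reverse_complement(got)
    expect_identical(got, expected)
  }
})

test_that("fixed seeds give byte-identical simulation output", {
  cfg <- small_cfg(seed = 77)
  a <- simulate_reads(generate_master_genome(cfg), cfg)
  b <- simulate_reads(generate_master_genome(cfg), cfg)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(a, f1); write_fastq(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reads simulated from isomer A alone never support recombinant paths", {
  cfg <- small_cfg(seed = 21, isomer_weights = c(1, 0, 0, 0))
  sim <- generate_master_genome(cfg)
  reads <- simulate_reads(sim, cfg)
  expect_setequal(unique(reads$source_isomer), "A")
  covered <- unlist(strsplit(reads$paths_covered, ","))
  expect_true(all(covered %in% c("p1", "p2", "p5", "p6", "")))
  refs <- build_path_references(sim$genome, sim$repeats, flank_len = cfg$flank_len)
  st <- count_spanning_reads(reads, refs, min_identity = 1)
  expect_true(all(st$n_spanning[st$kind == "recombinant"] == 0L))
  # and native counts match the truth-interval containment oracle
  truth <- vapply(refs$path, function(p) {
    sum(grepl(paste0("(^|,)", p, "($|,)"), reads$paths_covered))
  }, integer(1), USE.NAMES = FALSE)
  expect_identical(st$n_spanning, truth)
})

test_that("the dispersed-repeat finder recovers the planted repeat pairs", {
  sim <- generate_master_genome(small_cfg(seed = 31))
  hits <- find_dispersed_repeats(sim$genome, min_len = 30, max_mismatch = 0,
                                 kinds = "forward")
  for (rid in unique(sim$repeats$repeat_id)) {
    cp <- sim$repeats[sim$repeats$repeat_id == rid, ]
    found <- hits[hits$start_a <= cp$start[1] & hits$end_a >= cp$end[1] &
                    hits$start_b <= cp$start[2] & hits$end_b >= cp$end[2], ]
    expect_gte(nrow(found), 1L)
    expect_gte(max(found$length), cp$end[1] - cp$start[1] + 1L)
  }
})
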