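junction_fixture <- function(seed = 5) {
  cfg <- sim_config(genome_length = 20000, repeat_lengths = c(1200, 800),
                    read_mean_length = 4000, read_length_sd = 1200,
                    n_reads = 150, error_rate = 0, flank_len = 300, seed = seed)
  sim <- generate_master_genome(cfg)
  list(cfg = cfg, sim = sim,
       refs = build_path_references(sim$genome, sim$repeats, flank_len = 300))
}

test_that("path references have the expected structure and lengths", {
  fx <- junction_fixture()
  refs <- fx$refs
  expect_identical(nrow(refs), 8L)
  expect_identical(refs$path, paste0("p", 1:8))
  expect_identical(refs$kind, rep(c("native", "native", "recombinant",
                                    "recombinant"), 2))
  expect_true(all(refs$ref_length[refs$repeat_id == "R1"] == 1200 + 2 * 300))
  expect_true(all(refs$ref_length[refs$repeat_id == "R2"] == 800 + 2 * 300))
  # flank sources: native references use matching flanks, recombinant swap them
  expect_identical(refs$left_src, rep(c(1L, 2L, 1L, 2L), 2))
  expect_identical(refs$right_src, rep(c(1L, 2L, 2L, 1L), 2))
})

test_that("flank_len 0 collapses references to the repeat sequence", {
  fx <- junction_fixture()
  expect_warning(
    refs0 <- build_path_references(fx$sim$genome, fx$sim$repeats, flank_len = 0),
    "collapse")
  expect_identical(length(unique(refs0$seq[refs0$repeat_id == "R1"])), 1L)
  expect_identical(unique(nchar(refs0$seq[refs0$repeat_id == "R1"])), 1200L)
})

test_that("recombinant references are absent from the master but verbatim in isomer B", {
  fx <- junction_fixture(seed = 6)
  refs <- fx$refs
  isos <- derive_isomers(fx$sim)
  master2 <- strrep(fx$sim$genome$seq, 2)
  seqB <- isomer_to_fasta(isos$B, attr(isos, "graph"))$seq
  b2 <- strrep(seqB, 2)
  for (i in seq_len(nrow(refs))) {
    in_master <- grepl(refs$seq[i], master2, fixed = TRUE)
    in_b <- grepl(refs$seq[i], b2, fixed = TRUE)
    if (refs$kind[i] == "native") {
      expect_true(in_master)
      expect_false(in_b)
    } else {
      expect_false(in_master)
      expect_true(in_b)
    }
  }
})

test_that("spanning counts equal the exact-substring oracle for error-free reads", {
  fx <- junction_fixture(seed = 15)
  reads <- simulate_reads(fx$sim, fx$cfg)
  st <- count_spanning_reads(reads, fx$refs, min_identity = 1, max_end_slack = 0)
  expect_identical(st$n_spanning, oracle_spanning(fx$refs$seq, reads$seq))
  expect_gt(sum(st$n_spanning), 0L)
})

test_that("empty read sets give all-zero counts", {
  fx <- junction_fixture()
  st <- count_spanning_reads(tibble::tibble(read_id = character(),
                                            seq = character()), fx$refs)
  expect_identical(st$n_spanning, rep(0L, 8))
  summ <- summarize_recombination(st)
  expect_true(all(tidy(summ)$status == "no_coverage"))
})

test_that("raising min_identity never increases counts", {
  fx <- junction_fixture(seed = 23)
  cfg <- fx$cfg
  cfg$error_rate <- 0.05
  reads <- simulate_reads(fx$sim, cfg)
  prev <- NULL
  for (mi in c(0.7, 0.85, 0.95, 1)) {
    st <- count_spanning_reads(reads, fx$refs, min_identity = mi)
    if (!is.null(prev)) expect_true(all(st$n_spanning <= prev))
    prev <- st$n_spanning
  }
})

test_that("counts are invariant to rotation of the genome coordinates", {
  fx <- junction_fixture(seed = 33)
  reads <- simulate_reads(fx$sim, fx$cfg)
  st1 <- count_spanning_reads(reads, fx$refs, min_identity = 1)

  off <- 7317L
  n <- seq_len_bp(fx$sim$genome)
  rot <- rotate_seq(fx$sim$genome, off)
  shift <- function(p) (p - 1L - off) %% n + 1L
  reps <- fx$sim$repeats
  reps$start <- shift(reps$start)
  reps$end <- shift(reps$end)
  refs_rot <- build_path_references(rot, reps, flank_len = 300)
  st2 <- count_spanning_reads(reads, refs_rot, min_identity = 1)
  expect_identical(st1$n_spanning, st2$n_spanning)
})

test_that("slack parameter is validated and trims the evaluated core", {
  fx <- junction_fixture()
  expect_error(count_spanning_reads(tibble::tibble(read_id = "r", seq = "ACGT"),
                                    fx$refs, max_end_slack = 10000),
               class = "mitorecomb_parameter_error")
  reads <- simulate_reads(fx$sim, fx$cfg)
  st0 <- count_spanning_reads(reads, fx$refs, min_identity = 1, max_end_slack = 0)
  st50 <- count_spanning_reads(reads, fx$refs, min_identity = 1, max_end_slack = 50)
  expect_true(all(st50$n_spanning >= st0$n_spanning))
})

test_that("recombination summary applies the activity rule and the fraction formula", {
  tb <- tibble::tibble(
    repeat_id = "R1", path = paste0("p", 1:4),
    kind = c("native", "native", "recombinant", "recombinant"),
    n_spanning = c(27L, 23L, 23L, 14L))
  s <- tidy(summarize_recombination(tb))
  expect_true(s$active)
  expect_equal(s$recombinant_fraction, 37 / 87)
  expect_identical(s$majority, "native")

  tb$n_spanning <- c(10L, 10L, 0L, 0L)
  s2 <- tidy(summarize_recombination(tb))
  expect_false(s2$active)
  expect_equal(s2$recombinant_fraction, 0)

  g <- glance(summarize_recombination(tb))
  expect_identical(g$n_repeats, 1L)
  expect_equal(g$overall_recombinant_fraction, 0)
})

test_that("identity in the error-free limit matches the DP oracle", {
  set.seed(99)
  for (i in 1:25) {
    pat <- rnd_dna(sample(10:60, 1))
    txt <- rnd_dna(sample(20:120, 1))
    expect_identical(mitorecomb:::hw_distance_cpp(pat, txt), oracle_hw(pat, txt))
  }
  # embedded with known edits
  core <- rnd_dna(50)
  txt <- paste0(rnd_dna(30), core, rnd_dna(30))
  expect_identical(mitorecomb:::hw_distance_cpp(core, txt), 0L)
  mut <- paste0(substr(core, 1, 24), "A", substr(core, 26, 50))
  d <- mitorecomb:::hw_distance_cpp(mut, txt)
  expect_lte(d, 1L)
})
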