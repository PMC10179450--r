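test_that("SSR copy-number thresholds are applied at the boundary", {
  set.seed(1)
  pad1 <- rnd_dna(40); pad2 <- rnd_dna(40)
  below <- circ_seq(paste0(pad1, strrep("C", 9), pad2), circular = FALSE)
  at <- circ_seq(paste0(pad1, strrep("C", 10), pad2), circular = FALSE)
  expect_identical(nrow(find_ssrs(below)[find_ssrs(below)$motif == "C", ]), 0L)
  hit <- find_ssrs(at)
  hit <- hit[hit$motif == "C", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$copies, 10L)
  expect_identical(hit$length, 10L)
})

test_that("runs reducible to a shorter unit are reported at that unit only", {
  set.seed(2)
  s <- circ_seq(paste0(rnd_dna(30), strrep("AT", 5), rnd_dna(30)),
                circular = FALSE)
  res <- find_ssrs(s)
  res <- res[res$start > 25 & res$start < 45, ]
  expect_identical(nrow(res), 1L)
  expect_identical(res$motif, "AT")
  expect_identical(res$unit_size, 2L)
  expect_identical(res$copies, 5L)
})

test_that("SSRs wrap the origin on circular sequences", {
  set.seed(3)
  body <- paste0("C", rnd_dna(58), "G")
  s <- circ_seq(paste0("AAAAA", body, "AAAAAA"), circular = TRUE)
  res <- find_ssrs(s)
  run <- res[res$motif == "A", ]
  expect_identical(nrow(run), 1L)
  expect_identical(run$copies, 11L)
  expect_identical(run$start, 66L) # run begins in the tail and wraps
  expect_identical(run$end, 5L)
})

test_that("find_ssrs matches the exhaustive oracle on random sequences", {
  set.seed(1234)
  for (i in 1:30) {
    # salt with runs the thresholds can reach
    s <- paste0(rnd_dna(120), strrep("T", sample(8:12, 1)),
                rnd_dna(80), strrep(sample(c("AG", "CTT", "ACGT"), 1),
                                    sample(3:6, 1)),
                rnd_dna(120))
    got <- find_ssrs(circ_seq(s, circular = FALSE))
    exp <- oracle_ssrs(s)
    expect_identical(as.data.frame(got), as.data.frame(exp))
  }
})

test_that("planted forward and palindromic repeats are recovered", {
  set.seed(4)
  seg <- rnd_dna(40)
  s_f <- paste0(rnd_dna(300), seg, rnd_dna(400), seg, rnd_dna(300))
  hits_f <- find_dispersed_repeats(circ_seq(s_f, circular = FALSE),
                                   min_len = 30, max_evalue = 1e-3)
  cover <- hits_f[hits_f$kind == "forward" & hits_f$start_a <= 301 &
                    hits_f$end_a >= 340 & hits_f$start_b <= 741 &
                    hits_f$end_b >= 780, ]
  expect_gte(nrow(cover), 1L)
  expect_gte(max(cover$length), 40L)

  s_p <- paste0(rnd_dna(300), seg, rnd_dna(400), reverse_complement(seg),
                rnd_dna(300))
  hits_p <- find_dispersed_repeats(circ_seq(s_p, circular = FALSE),
                                   min_len = 30, max_evalue = 1e-3)
  expect_gte(nrow(hits_p[hits_p$kind == "palindromic", ]), 1L)
  expect_identical(nrow(hits_p[hits_p$kind == "forward" & hits_p$length >= 40, ]), 0L)
})

test_that("dispersed repeats match the exhaustive all-pairs oracle", {
  set.seed(555)
  for (i in 1:8) {
    seg <- rnd_dna(25)
    s <- paste0(rnd_dna(150), seg, rnd_dna(120),
                mutate_copy(seg, 1), rnd_dna(100),
                reverse_complement(seg), rnd_dna(110))
    got <- find_dispersed_repeats(circ_seq(s, circular = FALSE), min_len = 12,
                                  max_mismatch = 1, max_evalue = 1e-2)
    exp <- oracle_dispersed(s, min_len = 12, max_mm = 1, max_evalue = 1e-2)
    expect_identical(disp_key(got), disp_key(exp))
  }
})

test_that("tightening parameters never adds dispersed records", {
  set.seed(6)
  seg <- rnd_dna(60)
  s <- circ_seq(paste0(rnd_dna(250), seg, rnd_dna(200), seg, rnd_dna(200)),
                circular = FALSE)
  # E-value filtering is monotone in (length, mismatches) but not under
  # window re-maximalisation, so the containment property is checked unfiltered
  loose <- find_dispersed_repeats(s, min_len = 12, max_mismatch = 2,
                                  max_evalue = Inf)
  tight_mm <- find_dispersed_repeats(s, min_len = 12, max_mismatch = 1,
                                     max_evalue = Inf)
  tight_len <- find_dispersed_repeats(s, min_len = 20, max_mismatch = 2,
                                      max_evalue = Inf)
  # stricter mismatch bound: every record is contained in a looser record on
  # the same diagonal with at least as many mismatches allowed
  for (i in seq_len(nrow(tight_mm))) {
    r <- tight_mm[i, ]
    host <- loose[loose$kind == r$kind &
                    loose$start_a <= r$start_a & loose$end_a >= r$end_a &
                    loose$start_b <= r$start_b & loose$end_b >= r$end_b, ]
    expect_gte(nrow(host), 1L)
  }
  expect_lte(nrow(tight_mm), nrow(loose))
  # stricter length bound: records are an exact subset
  expect_true(all(disp_key(tight_len)$start_a %in% disp_key(loose)$start_a))
  expect_lte(nrow(tight_len), nrow(loose))
  expect_true(all(tight_len$length >= 20))
})

test_that("pairs are stored canonically with start_a <= start_b", {
  set.seed(7)
  seg <- rnd_dna(45)
  s <- circ_seq(paste0(rnd_dna(200), seg, rnd_dna(200), seg, rnd_dna(150)),
                circular = FALSE)
  hits <- find_dispersed_repeats(s, max_evalue = 1e-2)
  expect_true(all(hits$start_a <= hits$start_b))
  expect_identical(nrow(hits), nrow(dplyr::distinct(disp_key(hits))))
})

test_that("circular search finds repeats that wrap the origin", {
  set.seed(8)
  seg <- rnd_dna(50)
  # one copy crosses the origin: last 25 bp + first 25 bp
  s <- paste0(substr(seg, 26, 50), rnd_dna(300), seg, rnd_dna(300),
              substr(seg, 1, 25))
  hits <- find_dispersed_repeats(circ_seq(s, circular = TRUE), min_len = 30,
                                 max_mismatch = 0, kinds = "forward",
                                 max_evalue = 1e-3)
  wrapped <- hits[hits$end_b < hits$start_b, ]
  expect_gte(nrow(wrapped), 1L)
  expect_gte(max(wrapped$length), 50L)
  # linear mode must not see it
  lin <- find_dispersed_repeats(circ_seq(s, circular = FALSE), min_len = 30,
                                max_mismatch = 0, kinds = "forward",
                                max_evalue = 1e-3)
  expect_true(all(lin$length < 50))
})

test_that("repeat summaries count and cover correctly", {
  empty <- summarize_repeats(NULL, NULL, genome_length = 1000)
  expect_identical(empty$overview$n_ssr, 0L)
  expect_identical(empty$overview$n_dispersed, 0L)
  expect_identical(empty$overview$dispersed_union_bp, 0L)

  sim <- generate_master_genome(
    sim_config(genome_length = 30000, repeat_lengths = c(2000, 1200), seed = 42))
  disp <- find_dispersed_repeats(sim$genome, max_mismatch = 0, kinds = "forward")
  summ <- summarize_repeats(find_ssrs(sim$genome), disp, 30000)
  lower_bound <- 100 * (2000 + 1200) * 2 / 30000
  expect_gte(summ$overview$dispersed_union_pct, lower_bound)
  expect_lte(summ$overview$dispersed_union_bp, 30000L)
})
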