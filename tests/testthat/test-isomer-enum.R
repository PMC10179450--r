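fig_graph <- function(seed = 1) {
  set.seed(seed)
  seqs <- c(S1 = rnd_dna(400), R1 = rnd_dna(120), S2 = rnd_dna(300),
            R2 = rnd_dna(90), S3 = rnd_dna(250), S4 = rnd_dna(200))
  graph_from_layout(c("S1", "R1", "S2", "R2", "S3", "R1", "S4", "R2"), seqs = seqs)
}

test_that("a two-direct-repeat circular graph yields the four canonical isomers", {
  isos <- enumerate_isomers(fig_graph())
  expect_identical(length(isos), 4L)
  cls <- vapply(isos, `[[`, character(1), "classification")
  expect_identical(sum(cls == "master"), 2L)
  expect_identical(sum(cls == "sub_circle_pair"), 2L)
  for (iso in isos) {
    if (iso$classification == "sub_circle_pair") {
      expect_identical(length(iso$circles), 2L)
    }
  }
})

test_that("repeat-free and single-repeat graphs enumerate correctly", {
  g0 <- graph_from_layout("S1", lengths = c(S1 = 100))
  expect_identical(length(enumerate_isomers(g0)), 1L)

  g1 <- graph_from_layout(c("S1", "R1", "S2", "R1"),
                          lengths = c(S1 = 100, R1 = 30, S2 = 70))
  isos <- enumerate_isomers(g1)
  # brute force: the two entry/exit pairings of one two-copy repeat
  expect_identical(length(isos), 2L)
  expect_setequal(vapply(isos, `[[`, character(1), "classification"),
                  c("master", "sub_circle_pair"))
  pair <- isos[[which(vapply(isos, `[[`, character(1), "classification") ==
                        "sub_circle_pair")]]
  expect_setequal(vapply(pair$circles, function(cc) paste(sort(cc), collapse = "+"),
                         character(1)),
                  c("R1+S1", "R1+S2"))
})

test_that("every enumerated isomer conserves segment usage", {
  g <- fig_graph(seed = 2)
  isos <- enumerate_isomers(g)
  expected <- sort(g$links$from) # each traversal uses each link's source once
  for (iso in isos) {
    expect_identical(sort(unlist(iso$circles)), expected)
  }
  tl <- tidy(isos)
  total <- sum(g$segments$length) + sum(g$segments$length[g$segments$is_repeat])
  for (i in unique(tl$isomer)) {
    expect_equal(sum(tl$length[tl$isomer == i]), total)
  }
})

test_that("isomer_to_fasta linearises at the least rotation and conserves length", {
  g <- fig_graph(seed = 3)
  isos <- enumerate_isomers(g)
  master_len <- sum(g$segments$length) + sum(g$segments$length[g$segments$is_repeat])
  for (iso in isos) {
    fa <- isomer_to_fasta(iso, g)
    expect_equal(sum(fa$length), master_len)
    for (s in fa$seq) {
      # already at the minimal rotation: no other rotation sorts lower
      expect_identical(mitorecomb:::least_rotation_cpp(s), 0L)
    }
  }
})

test_that("emitted isomer sequences contain exactly the junction paths they support", {
  cfg <- sim_config(genome_length = 12000, repeat_lengths = c(600, 400),
                    flank_len = 150, seed = 8)
  sim <- generate_master_genome(cfg)
  isos <- derive_isomers(sim)
  refs <- build_path_references(sim$genome, sim$repeats, flank_len = 150)
  junc <- isomer_junctions(sim, isos, flank_len = 150)
  graph <- attr(isos, "graph")
  for (nm in names(isos)) {
    fa <- isomer_to_fasta(isos[[nm]], graph)
    doubled <- vapply(fa$seq, function(s) strrep(s, 2), character(1))
    present <- vapply(refs$seq, function(r) {
      any(vapply(doubled, function(dd) grepl(r, dd, fixed = TRUE), logical(1)))
    }, logical(1), USE.NAMES = FALSE)
    expect_setequal(refs$path[present], junc$path[junc$isomer == nm])
  }
})

test_that("malformed graphs are rejected", {
  expect_error(
    assembly_graph(tibble::tibble(id = c("a", "b"), length = c(5L, 5L)),
                   tibble::tibble(from = "a", to = "b")),
    class = "mitorecomb_structural_error")
  expect_error(
    assembly_graph(tibble::tibble(id = c("a", "b"), length = c(5L, 5L)),
                   tibble::tibble(from = c("a", "b"), to = c("b", "a"),
                                  from_orient = c("+", "-"),
                                  to_orient = c("+", "+"))),
    class = "mitorecomb_orientation_error")
})
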