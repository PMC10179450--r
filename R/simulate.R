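#' Simulation configuration for a repeat-bearing circular mitogenome
#'
#' The defaults describe the study system this package was built around: a
#' ~515 kb circular plant mitogenome at GC 44.05% carrying two pairs of large
#' direct repeats (9026 bp and 7040 bp, copies 100% identical), sequenced with
#' Nanopore-like long reads of mean length 17.52 kb at ~75-fold depth. The
#' four non-repeat segments split the non-repeat residue 40/25/20/15% (the
#' true unitig lengths of such assemblies are not published; the split is a
#' stand-in, not a reconstruction).
#'
#' @param genome_length Total master-circle length in bp.
#' @param repeat_lengths Lengths of the planted direct repeat pairs (0, 1 or 2
#'   entries; zeros drop a repeat).
#' @param gc_target Target GC fraction; bases are drawn i.i.d.
#' @param segment_fracs Fractions of the non-repeat residue assigned to the
#'   unique segments (renormalised to the number of segments needed).
#' @param read_mean_length,read_length_sd Truncated-normal read length model
#'   (bp); lengths are clamped to `[read_min_length, circle length]`.
#' @param read_min_length Minimum simulated read length (bp).
#' @param depth Target sequencing depth (used when `n_reads` is `NULL`).
#' @param n_reads Number of reads to simulate (overrides `depth`).
#' @param error_rate Total per-base error rate; split
#'   substitution:insertion:deletion = 2:1:1.
#' @param isomer_weights Non-negative sampling weights over the isomers
#'   (A, B, C, D for a two-repeat genome); renormalised to sum to 1. The
#'   default mixes the master circle with all three recombinant conformations
#'   at the relative levels long-read junction support typically shows for
#'   recombinationally active repeats.
#' @param flank_len Flank length (bp) used for junction truth labels.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 515187L,
                       repeat_lengths = c(9026L, 7040L),
                       gc_target = 0.4405,
                       segment_fracs = c(0.40, 0.25, 0.20, 0.15),
                       read_mean_length = 17520,
                       read_length_sd = 9000,
                       read_min_length = 200L,
                       depth = 75,
                       n_reads = NULL,
                       error_rate = 0.05,
                       isomer_weights = c(A = 0.37, B = 0.21, C = 0.21, D = 0.21),
                       flank_len = 500L,
                       seed = NULL) {
  repeat_lengths <- as.integer(repeat_lengths[repeat_lengths > 0])
  if (length(repeat_lengths) > 2L) {
    abort("at most two repeat pairs are supported", class = "mitorecomb_config_error")
  }
  if (any(repeat_lengths >= genome_length / 4)) {
    abort("repeat lengths must be < genome_length / 4", class = "mitorecomb_config_error")
  }
  n_segments <- max(1L, 2L * length(repeat_lengths))
  residue <- genome_length - 2L * sum(repeat_lengths)
  if (residue < n_segments) {
    abort("genome too short for the requested repeats", class = "mitorecomb_config_error")
  }
  if (gc_target <= 0 || gc_target >= 1) {
    abort("gc_target must be in (0, 1)", class = "mitorecomb_config_error")
  }
  if (error_rate < 0 || error_rate >= 1) {
    abort("error_rate must be in [0, 1)", class = "mitorecomb_config_error")
  }
  n_isomers <- if (length(repeat_lengths) == 2L) 4L else if (length(repeat_lengths) == 1L) 2L else 1L
  w <- rep_len(as.numeric(isomer_weights), n_isomers)
  if (any(w < 0) || sum(w) <= 0) {
    abort("isomer weights must be non-negative and not all zero",
          class = "mitorecomb_config_error")
  }
  w <- w / sum(w)
  names(w) <- c("A", "B", "C", "D")[seq_len(n_isomers)]
  if (n_isomers == 2L) names(w) <- c("A", "C")
  structure(list(
    genome_length = as.integer(genome_length),
    repeat_lengths = repeat_lengths,
    gc_target = gc_target,
    segment_fracs = segment_fracs,
    read_mean_length = read_mean_length,
    read_length_sd = read_length_sd,
    read_min_length = as.integer(read_min_length),
    depth = depth,
    n_reads = if (is.null(n_reads)) NULL else as.integer(n_reads),
    error_rate = error_rate,
    isomer_weights = w,
    flank_len = as.integer(flank_len),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s bp circle, repeats [%s] bp, GC %.2f%%\n",
              format(x$genome_length, big.mark = ","),
              paste(x$repeat_lengths, collapse = ", "), 100 * x$gc_target))
  cat(sprintf("  reads: mean %s bp (sd %s), error %.1f%%, weights [%s]\n",
              format(x$read_mean_length, big.mark = ","), x$read_length_sd,
              100 * x$error_rate,
              paste(sprintf("%s=%.2f", names(x$isomer_weights), x$isomer_weights),
                    collapse = ", ")))
  invisible(x)
}

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

with_seed_opt <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}

#' Generate a master circular genome with planted direct repeats
#'
#' Lays the genome out as alternating unique segments and repeat copies
#' (`S1 R1 S2 R2 S3 R1 S4 R2` for two repeats), so that every repeat copy has
#' distinct flanking segments — the six-contig unitig topology that large
#' direct repeats produce in organelle assemblies. Repeat copies are exact
#' (100% identity); all bases are drawn i.i.d. at the configured GC.
#'
#' @param config A [sim_config()].
#' @return A `mito_sim_genome`: list with elements `genome` (a [circ_seq()]),
#'   `repeats` (tibble: `repeat_id`, `copy`, `start`, `end` 1-based inclusive,
#'   `strand`, `length`, `identity`), `segments` (tibble of all layout pieces),
#'   `layout` (segment id order on the circle), `seg_seqs` (named character),
#'   and `config`.
#' @export
generate_master_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_opt(config$seed, {
    k <- length(config$repeat_lengths)
    n_seg <- max(1L, 2L * k)
    residue <- config$genome_length - 2L * sum(config$repeat_lengths)
    fr <- rep_len(config$segment_fracs, n_seg)
    fr <- fr / sum(fr)
    seg_len <- floor(residue * fr)
    seg_len[n_seg] <- residue - sum(seg_len[-n_seg])
    seg_ids <- paste0("S", seq_len(n_seg))
    rep_ids <- if (k) paste0("R", seq_len(k)) else character()

    layout <- if (k == 0L) "S1" else {
      as.vector(rbind(seg_ids, rep(rep_ids, length.out = n_seg)))
    }
    seqs <- c(
      setNames(lapply(seg_len, random_dna, gc = config$gc_target), seg_ids),
      setNames(lapply(config$repeat_lengths, random_dna, gc = config$gc_target), rep_ids)
    )
    seqs <- vapply(seqs, identity, character(1))

    lens <- setNames(nchar(seqs), names(seqs))
    offsets <- cumsum(c(0L, lens[layout][-length(layout)]))
    pieces <- tibble(
      id = layout,
      start = as.integer(offsets + 1L),
      end = as.integer(offsets + lens[layout]),
      length = as.integer(lens[layout]),
      is_repeat = layout %in% rep_ids
    )
    genome <- circ_seq(paste(seqs[layout], collapse = ""), id = "synthetic_mitogenome",
                       circular = TRUE)
    repeats <- pieces |>
      filter(.data$is_repeat) |>
      group_by(.data$id) |>
      mutate(copy = row_number()) |>
      ungroup() |>
      mutate(repeat_id = .data$id, strand = "+", identity = 1) |>
      select("repeat_id", "copy", "start", "end", "strand", "length", "identity")
    structure(list(
      genome = genome, repeats = repeats, segments = pieces,
      layout = layout, seg_seqs = seqs, config = config
    ), class = "mito_sim_genome")
  })
}

#' @export
print.mito_sim_genome <- function(x, ...) {
  cat(sprintf("<mito_sim_genome> %s bp, %d repeat pair(s), GC %.2f%%\n",
              format(seq_len_bp(x$genome), big.mark = ","),
              length(unique(x$repeats$repeat_id)), gc_content(x$genome)))
  invisible(x)
}

# Path label convention: for the j-th repeat, labels p(4j-3)..p(4j) are the
# four (left flank, right flank) pairings; p(4j-3)/p(4j-2) are the two native
# pairings on the master circle, p(4j-1)/p(4j) the recombinant ones.
path_flank_table <- function(layout) {
  rep_ids <- unique(layout[duplicated(layout)])
  n <- length(layout)
  prv <- function(i) layout[(i - 2L) %% n + 1L]
  nxt <- function(i) layout[i %% n + 1L]
  out <- list()
  for (j in seq_along(rep_ids)) {
    occ <- which(layout == rep_ids[j])
    la <- prv(occ[1]); ra <- nxt(occ[1])
    lb <- prv(occ[2]); rb <- nxt(occ[2])
    base <- 4L * (j - 1L)
    out[[j]] <- tibble(
      repeat_id = rep_ids[j],
      path = paste0("p", base + 1:4),
      left_seg = c(la, lb, la, lb),
      right_seg = c(ra, rb, rb, ra),
      kind = c("native", "native", "recombinant", "recombinant")
    )
  }
  list_rbind(out)
}

#' Derive the isomers of a simulated master genome
#'
#' Builds the assembly graph implied by the planted repeats and enumerates all
#' pairing combinations (see [enumerate_isomers()]). For two direct repeat
#' pairs the result is the canonical four-isomer set: master circles A
#' (input) and B (both repeats recombined), and sub-circle pairs C
#' (recombined at R1) and D (recombined at R2).
#'
#' @param sim A `mito_sim_genome` from [generate_master_genome()].
#' @return A named `isomer_set` (names `A`, `B`, `C`, `D` for two repeats;
#'   `A`, `C` for one; `A` for none).
#' @export
derive_isomers <- function(sim) {
  stopifnot(inherits(sim, "mito_sim_genome"))
  if (any(sim$repeats$strand != "+")) {
    abort("inverted repeat pairs are not supported (direct repeats only)",
          class = "mitorecomb_orientation_error")
  }
  graph <- graph_from_layout(sim$layout, seqs = sim$seg_seqs)
  isos <- enumerate_isomers(graph)
  k <- sum(graph$segments$is_repeat)
  label_map <- switch(as.character(k),
    "1" = c("0" = "A", "1" = "C"),
    "2" = c("00" = "A", "10" = "C", "01" = "D", "11" = "B"),
    NULL
  )
  nm <- if (k == 0L) "A" else vapply(isos, function(iso) {
    label_map[[paste(iso$pairing, collapse = "")]]
  }, character(1))
  ord <- order(match(nm, c("A", "B", "C", "D")))
  out <- structure(isos[ord], class = "isomer_set", graph = graph)
  names(out) <- nm[ord]
  out
}

#' Circle-level view of an isomer set
#'
#' Expands a (named) isomer set into one row per circle with its sequence,
#' used by the read simulator and by junction truth labelling. Circle labels
#' are the isomer name for single-circle isomers and `C1`, `C2`, ... for
#' multi-circle isomers.
#'
#' @param isomers A named `isomer_set` from [derive_isomers()].
#' @return A tibble: `isomer`, `circle_label`, `segments` (list column),
#'   `seq`, `length`.
#' @export
isomer_circles <- function(isomers) {
  graph <- attr(isomers, "graph")
  seqs <- setNames(graph$segments$seq, graph$segments$id)
  out <- purrr::imap(isomers, function(iso, nm) {
    labs <- if (length(iso$circles) == 1L) nm else paste0(nm, seq_along(iso$circles))
    tibble(
      isomer = nm,
      circle_label = labs,
      segments = iso$circles,
      seq = vapply(iso$circles, function(s) paste(seqs[s], collapse = ""), character(1))
    )
  })
  out <- list_rbind(out)
  out$length <- nchar(out$seq)
  out
}

#' Junction windows of every isomer circle
#'
#' For each repeat occurrence on each circle, the junction window is the
#' repeat plus `flank_len` bp of flanking sequence on both sides; the window's
#' path label follows the package's p1..p8 convention (native pairings first).
#' A read supports a path if and only if it fully contains the corresponding
#' window, which is what [count_spanning_reads()] measures from alignment.
#'
#' @param sim A `mito_sim_genome`.
#' @param isomers Optional pre-computed [derive_isomers()] result.
#' @param flank_len Flank length in bp.
#' @return A tibble: `isomer`, `circle_label`, `path`, `repeat_id`, `start`
#'   (1-based on the circle), `span`, `circle_length`.
#' @export
isomer_junctions <- function(sim, isomers = derive_isomers(sim),
                             flank_len = sim$config$flank_len) {
  circles <- isomer_circles(isomers)
  graph <- attr(isomers, "graph")
  lens <- setNames(graph$segments$length, graph$segments$id)
  ptab <- path_flank_table(sim$layout)
  out <- list()
  for (ci in seq_len(nrow(circles))) {
    segs <- circles$segments[[ci]]
    n <- length(segs)
    clen <- circles$length[ci]
    offs <- cumsum(c(0L, unname(lens[segs])[-n]))
    for (t in seq_len(n)) {
      sid <- segs[t]
      if (!sid %in% ptab$repeat_id) next
      left <- segs[(t - 2L) %% n + 1L]
      right <- segs[t %% n + 1L]
      hit <- ptab[ptab$repeat_id == sid & ptab$left_seg == left & ptab$right_seg == right, ]
      if (nrow(hit) != 1L) next
      start <- (offs[t] - flank_len) %% clen + 1L
      span <- lens[[sid]] + 2L * flank_len
      out[[length(out) + 1L]] <- tibble(
        isomer = circles$isomer[ci], circle_label = circles$circle_label[ci],
        path = hit$path, repeat_id = sid,
        start = as.integer(start), span = as.integer(span),
        circle_length = clen
      )
    }
  }
  arrange(list_rbind(out), .data$path, .data$circle_label)
}

apply_read_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hit <- runif(n) < rate
  if (!any(hit)) return(seq)
  idx <- which(hit)
  op <- sample(c("sub", "ins", "del"), length(idx), replace = TRUE,
               prob = c(0.5, 0.25, 0.25))
  bases <- c("A", "C", "G", "T")
  pieces <- chars
  for (i in seq_along(idx)) {
    p <- idx[i]
    if (op[i] == "sub") {
      pieces[p] <- sample(setdiff(bases, chars[p]), 1L)
    } else if (op[i] == "ins") {
      pieces[p] <- paste0(chars[p], sample(bases, 1L))
    } else {
      pieces[p] <- ""
    }
  }
  paste(pieces, collapse = "")
}

#' Simulate long reads from a weighted isomer mixture
#'
#' Each read's source circle is drawn from the configured isomer weights
#' (circles within a multi-circle isomer in proportion to length), its start
#' uniformly on the circle, its length from a truncated normal, and its strand
#' uniformly. Errors are applied per base at the configured rate
#' (substitution:insertion:deletion = 2:1:1). Truth labels record the source
#' interval and the junction paths the error-free read fully contains.
#'
#' @param sim A `mito_sim_genome`.
#' @param config A [sim_config()]; defaults to the one stored in `sim`.
#' @param isomers Optional pre-computed [derive_isomers()] result.
#' @return A tibble with one row per read: `read_id`, `seq`, and truth columns
#'   `source_isomer`, `source_circle`, `start`, `span`, `strand`,
#'   `paths_covered` (comma-separated path labels).
#' @export
simulate_reads <- function(sim, config = sim$config, isomers = derive_isomers(sim)) {
  stopifnot(inherits(sim, "mito_sim_genome"), inherits(config, "sim_config"))
  circles <- isomer_circles(isomers)
  junc <- isomer_junctions(sim, isomers, flank_len = config$flank_len)
  w <- config$isomer_weights
  n_reads <- config$n_reads %||%
    as.integer(round(config$depth * config$genome_length / config$read_mean_length))
  seed <- if (is.null(config$seed)) NULL else config$seed + 1L
  with_seed_opt(seed, {
    iso_draw <- sample(names(w), n_reads, replace = TRUE, prob = w)
    reads <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      cand <- circles[circles$isomer == iso_draw[i], ]
      ci <- if (nrow(cand) == 1L) 1L else
        sample.int(nrow(cand), 1L, prob = cand$length)
      clen <- cand$length[ci]
      len <- round(rnorm(1, config$read_mean_length, config$read_length_sd))
      len <- max(config$read_min_length, min(len, clen))
      start <- sample.int(clen, 1L)
      raw <- circ_substr(circ_seq(cand$seq[ci], circular = TRUE), start, len)
      strand <- sample(c("+", "-"), 1L)
      jw <- junc[junc$circle_label == cand$circle_label[ci], ]
      covered <- character()
      if (nrow(jw)) {
        rel <- (jw$start - start) %% clen # 0-based offset of window in read
        covered <- jw$path[rel + jw$span <= len & len <= clen]
      }
      seq_out <- apply_read_errors(raw, config$error_rate)
      if (strand == "-") seq_out <- reverse_complement(seq_out)
      reads[[i]] <- tibble(
        read_id = sprintf("read%06d", i),
        seq = seq_out,
        source_isomer = iso_draw[i],
        source_circle = cand$circle_label[ci],
        start = start, span = len, strand = strand,
        paths_covered = paste(sort(covered), collapse = ",")
      )
    }
    list_rbind(reads)
  })
}
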