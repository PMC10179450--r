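#' Build flank-swapped junction path references around a repeat pair
#'
#' For a two-copy direct repeat, extracts the repeat plus `flank_len` bp of
#' flanking sequence for each copy (the two native references) and the two
#' flank-swapped recombinant references (left flank of one copy, right flank
#' of the other). Reads spanning a reference end to end are evidence for the
#' corresponding genome conformation.
#'
#' Path labels follow the package convention: for the j-th repeat (sorted by
#' `repeat_id`), labels `p(4j-3)`/`p(4j-2)` are the native references of copy
#' 1 and copy 2, and `p(4j-1)`/`p(4j)` the two recombinant references. With
#' two repeats this yields p1..p8.
#'
#' @param genome A [circ_seq()] (the master-circle assembly).
#' @param repeats A tibble of repeat copies with columns `repeat_id`, `copy`,
#'   `start`, `end` (1-based inclusive) and optionally `strand` (must be `+`),
#'   e.g. the `repeats` element of [generate_master_genome()]. Each
#'   `repeat_id` must have exactly two copies.
#' @param flank_len Flank length in bp (default 500).
#' @return A `path_refs` tibble: `repeat_id`, `path`, `kind`, `left_src`,
#'   `right_src`, `seq`, `ref_length`, with attribute `flank_len`.
#' @export
build_path_references <- function(genome, repeats, flank_len = 500L) {
  stopifnot(inherits(genome, "circ_seq"))
  repeats <- as_tibble(repeats)
  stopifnot(all(c("repeat_id", "start", "end") %in% names(repeats)))
  if (!is.null(repeats[["strand"]]) && any(repeats[["strand"]] != "+")) {
    abort("inverted repeat copies are not supported (direct repeats only)",
          class = "mitorecomb_orientation_error")
  }
  flank_len <- as.integer(flank_len)
  if (flank_len < 0L) abort("flank_len must be >= 0")
  if (flank_len == 0L) {
    warn("flank_len = 0: all four references collapse to the repeat sequence")
  }
  n <- seq_len_bp(genome)
  rep_ids <- sort(unique(repeats$repeat_id))

  flank_left <- function(start) {
    if (flank_len == 0L) return("")
    s <- start - flank_len
    if (s < 1L) {
      if (!genome$circular) {
        warn("left flank truncated at the start of a linear sequence")
        return(substr(genome$seq, 1L, start - 1L))
      }
      s <- (s - 1L) %% n + 1L
    }
    circ_substr(genome, s, flank_len)
  }
  flank_right <- function(end) {
    if (flank_len == 0L) return("")
    if (!genome$circular && end + flank_len > n) {
      warn("right flank truncated at the end of a linear sequence")
      return(substr(genome$seq, end + 1L, n))
    }
    circ_substr(genome, end %% n + 1L, flank_len)
  }
  interval_overlaps <- function(a_start, a_end, b_start, b_end) {
    span <- a_end - a_start
    a_start <- ((a_start - 1L) %% n) + 1L
    pos <- (seq.int(a_start, a_start + span) - 1L) %% n + 1L
    any(pos >= b_start & pos <= b_end)
  }

  out <- list()
  for (j in seq_along(rep_ids)) {
    cp <- repeats[repeats$repeat_id == rep_ids[j], ]
    cp <- cp[order(cp[["copy"]] %||% seq_len(nrow(cp))), ]
    if (nrow(cp) != 2L) {
      abort(sprintf("repeat %s must have exactly 2 copies", rep_ids[j]))
    }
    rep_seq <- circ_substr(genome, cp$start[1], (cp$end[1] - cp$start[1]) %% n + 1L)
    fl <- lapply(cp$start, flank_left)
    fr <- lapply(cp$end, flank_right)
    # flanks running into the other copy blur the native/recombinant contrast
    for (x in 1:2) {
      other <- 3L - x
      if (flank_len > 0L &&
          (interval_overlaps(cp$start[x] - flank_len, cp$start[x] - 1L,
                             cp$start[other], cp$end[other]) ||
           interval_overlaps(cp$end[x] + 1L, cp$end[x] + flank_len,
                             cp$start[other], cp$end[other]))) {
        warn(sprintf("flank of %s copy %d overlaps the other copy", rep_ids[j], x))
      }
    }
    base <- 4L * (j - 1L)
    combos <- tibble(
      repeat_id = rep_ids[j],
      path = paste0("p", base + 1:4),
      kind = c("native", "native", "recombinant", "recombinant"),
      left_src = c(1L, 2L, 1L, 2L),
      right_src = c(1L, 2L, 2L, 1L)
    )
    combos$seq <- vapply(seq_len(4L), function(i) {
      paste0(fl[[combos$left_src[i]]], rep_seq, fr[[combos$right_src[i]]])
    }, character(1))
    out[[j]] <- combos
  }
  res <- list_rbind(out)
  res$ref_length <- nchar(res$seq)
  attr(res, "flank_len") <- flank_len
  class(res) <- c("path_refs", class(res))
  res
}

#' Count long reads that completely span each junction reference
#'
#' A read supports a path when it has an alignment to that path's reference
#' covering the reference end to end — allowing `max_end_slack` bp of slack at
#' each reference end — with edit identity at least `min_identity`, and with
#' both reference ends individually reaching `min_identity` at read positions
#' consistent with the full alignment (anchor windows of up to 250 bp). The
#' anchor condition is what makes the statistic discriminative: a read
#' covering a native junction still aligns to the flank-swapped reference
#' with only a modest identity loss (the swapped flank is a small fraction of
#' the reference), but the swapped flank's anchor cannot reach the identity
#' bar against unrelated sequence. Reads are tested on both strands and each
#' (read, path) pair is counted at most once. Alignment uses a bit-parallel
#' semi-global (infix) edit distance, so in the error-free limit
#' (`min_identity = 1`, `max_end_slack = 0`) a read counts if and only if it
#' contains the reference as an exact substring.
#'
#' @param reads A tibble with columns `read_id` and `seq` (e.g. from
#'   [simulate_reads()] or [read_fastq()]), or a character vector of read
#'   sequences.
#' @param refs A `path_refs` tibble from [build_path_references()].
#' @param min_identity Minimum alignment identity, `1 - dist / ref_length`
#'   (default 0.80).
#' @param max_end_slack Slack in bp tolerated at each reference end
#'   (default 0).
#' @return A `support_table` tibble: `repeat_id`, `path`, `kind`,
#'   `n_spanning`, `read_ids` (list column).
#' @export
count_spanning_reads <- function(reads, refs, min_identity = 0.8,
                                 max_end_slack = 0L) {
  if (is.character(reads)) {
    reads <- tibble(read_id = names(reads) %||% paste0("read", seq_along(reads)),
                    seq = unname(reads))
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)),
            all(c("path", "seq") %in% names(refs)))
  max_end_slack <- as.integer(max_end_slack)
  if (min_identity <= 0 || min_identity > 1) abort("min_identity must be in (0, 1]")
  if (any(nchar(refs$seq) <= 2L * max_end_slack)) {
    abort("reference shorter than twice max_end_slack",
          class = "mitorecomb_parameter_error")
  }
  cores <- substr(refs$seq, 1L + max_end_slack, nchar(refs$seq) - max_end_slack)
  if (nrow(reads) == 0L) {
    res_span <- matrix(0L, nrow = 0, ncol = length(cores))
  } else {
    res <- count_spanning_cpp(cores, reads$seq, min_identity)
    res_span <- res$span
  }
  out <- tibble(
    repeat_id = refs[["repeat_id"]] %||% NA_character_,
    path = refs$path,
    kind = refs[["kind"]] %||% NA_character_,
    n_spanning = as.integer(colSums(res_span)),
    read_ids = lapply(seq_along(cores), function(r) reads$read_id[res_span[, r] == 1L])
  )
  attr(out, "min_identity") <- min_identity
  attr(out, "max_end_slack") <- max_end_slack
  class(out) <- c("support_table", class(out))
  out
}

#' Summarise repeat-mediated recombination from junction support counts
#'
#' A repeat is called recombinationally active when all four of its junction
#' paths have at least `min_support` spanning reads. The recombinant fraction
#' is `(recombinant support) / (total support)` with an exact binomial
#' confidence interval.
#'
#' @param support A `support_table` from [count_spanning_reads()] (may cover
#'   one or several repeats).
#' @param min_support Minimum spanning-read count per path for the activity
#'   call (default 1).
#' @param conf_level Confidence level of the binomial interval.
#' @return A `recomb_summary` object; see [tidy.recomb_summary()] and
#'   [glance.recomb_summary()].
#' @export
summarize_recombination <- function(support, min_support = 1L, conf_level = 0.95) {
  stopifnot(all(c("repeat_id", "path", "kind", "n_spanning") %in% names(support)))
  rows <- support |>
    as_tibble() |>
    group_by(.data$repeat_id) |>
    summarise(
      n_native = sum(.data$n_spanning[.data$kind == "native"]),
      n_recombinant = sum(.data$n_spanning[.data$kind == "recombinant"]),
      n_total = sum(.data$n_spanning),
      active = all(.data$n_spanning >= min_support) && dplyr::n() == 4L,
      .groups = "drop"
    )
  rows <- rows |> mutate(
    status = ifelse(.data$n_total == 0L, "no_coverage", "ok"),
    recombinant_fraction = ifelse(.data$n_total > 0, .data$n_recombinant / .data$n_total, NA_real_),
    majority = dplyr::case_when(
      n_total == 0L ~ NA_character_,
      n_recombinant > n_native ~ "recombinant",
      TRUE ~ "native"
    )
  )
  ci <- purrr::map2(rows$n_recombinant, rows$n_total, function(x, nn) {
    if (nn == 0) return(c(NA_real_, NA_real_))
    stats::binom.test(x, nn, conf.level = conf_level)$conf.int
  })
  rows$ci_lower <- vapply(ci, `[`, numeric(1), 1)
  rows$ci_upper <- vapply(ci, `[`, numeric(1), 2)
  structure(list(
    by_repeat = rows,
    min_support = min_support,
    conf_level = conf_level
  ), class = "recomb_summary")
}

#' @export
print.recomb_summary <- function(x, ...) {
  cat("<recomb_summary>\n")
  for (i in seq_len(nrow(x$by_repeat))) {
    r <- x$by_repeat[i, ]
    if (r$status == "no_coverage") {
      cat(sprintf("  %s: no coverage\n", r$repeat_id))
    } else {
      cat(sprintf(
        "  %s: %s (native %d, recombinant %d; fraction %.3f [%.3f, %.3f], majority %s)\n",
        r$repeat_id,
        if (r$active) "recombinationally active" else "inactive",
        r$n_native, r$n_recombinant, r$recombinant_fraction,
        r$ci_lower, r$ci_upper, r$majority))
    }
  }
  invisible(x)
}

#' Tidy per-repeat recombination summary
#'
#' @param x A `recomb_summary`.
#' @param ... Unused.
#' @return A tibble with one row per repeat.
#' @export
tidy.recomb_summary <- function(x, ...) {
  x$by_repeat
}

#' One-row overview of a recombination summary
#'
#' @param x A `recomb_summary`.
#' @param ... Unused.
#' @return A one-row tibble: `n_repeats`, `n_active`, `total_spanning`,
#'   `overall_recombinant_fraction`.
#' @export
glance.recomb_summary <- function(x, ...) {
  tibble(
    n_repeats = nrow(x$by_repeat),
    n_active = sum(x$by_repeat$active),
    total_spanning = sum(x$by_repeat$n_total),
    overall_recombinant_fraction =
      sum(x$by_repeat$n_recombinant) / max(1L, sum(x$by_repeat$n_total))
  )
}
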