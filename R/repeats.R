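is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && strrep(substr(motif, 1L, d), u %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Find simple sequence repeats (microsatellites)
#'
#' Detects maximal perfect tandem runs of 1-6 bp motifs, MISA-style: a run is
#' reported when its number of complete copies reaches the threshold for its
#' unit size (defaults 10, 5, 4, 3, 3, 3 for mono- through hexanucleotides).
#' Runs whose motif is a repetition of a shorter motif are reported at the
#' shorter unit only; overlapping runs of different unit sizes are all
#' reported. Windows containing `N` never match. On circular sequences runs
#' may wrap the origin.
#'
#' @param g A [circ_seq()] (or character string, treated per `circular`).
#' @param thresholds Named integer vector mapping unit sizes `1..6` to minimum
#'   copy numbers.
#' @param circular Override the sequence's circularity flag.
#' @return An `ssr_table` tibble: `motif`, `unit_size`, `copies`, `start`,
#'   `end` (1-based inclusive; `end < start` when the run wraps the origin),
#'   `length`, sorted by `start`.
#' @export
find_ssrs <- function(g, thresholds = c(`1` = 10L, `2` = 5L, `3` = 4L,
                                        `4` = 3L, `5` = 3L, `6` = 3L),
                      circular = is_circular(g)) {
  s <- as_seq_string(g)
  n <- nchar(s)
  units <- as.integer(names(thresholds))
  stopifnot(!anyNA(units), all(units >= 1L), all(units <= 6L))
  scan <- if (circular) paste0(s, s) else s
  raw <- charToRaw(scan)
  n_raw <- utf8ToInt("N")
  recs <- list()
  for (u in units) {
    thr <- thresholds[[as.character(u)]]
    L <- length(raw)
    if (L <= u) next
    eq <- raw[seq_len(L - u)] == raw[(u + 1L):L]
    # N never matches anything, including N
    is_n <- as.integer(raw) == n_raw
    eq <- eq & !is_n[seq_len(L - u)] & !is_n[(u + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (ri in keep) {
      a <- starts[ri]
      span <- r$lengths[ri] + u
      copies <- span %/% u
      if (copies < thr) next
      if (circular) {
        if (a > n) next # image of a run already reported from the first copy
        # a run at position 1 that continues across the origin is the clipped
        # image of a wrapping run reported from its true start (unless the run
        # covers the whole circle, which has no canonical start)
        if (a == 1L && span < n + u &&
            raw[n] == raw[u] && !is_n[n] && !is_n[u]) next
        copies <- min(copies, n %/% u) # a run cannot exceed the circle
      }
      len <- u * copies
      motif <- substr(scan, a, a + u - 1L)
      if (!is_primitive_motif(motif)) next
      end1 <- if (circular) (a + len - 2L) %% n + 1L else a + len - 1L
      recs[[length(recs) + 1L]] <- tibble(
        motif = motif, unit_size = u, copies = as.integer(copies),
        start = as.integer(a), end = as.integer(end1), length = as.integer(len)
      )
    }
  }
  out <- if (length(recs)) arrange(list_rbind(recs), .data$start, .data$unit_size) else
    tibble(motif = character(), unit_size = integer(), copies = integer(),
           start = integer(), end = integer(), length = integer())
  class(out) <- c("ssr_table", class(out))
  out
}

#' E-value of a dispersed repeat pair
#'
#' Expected number of length-`len` pairs with `mm` mismatches in a genome of
#' length `n` under an i.i.d. uniform base model: a two-position Bonferroni
#' bound on the binomial match probability,
#' `E = n^2 * choose(len, mm) * (1/4)^(len - mm) * (3/4)^mm`.
#'
#' @param len Repeat length (bp).
#' @param mm Number of mismatches.
#' @param n Genome length (bp).
#' @return E-value(s), vectorised.
#' @export
dispersed_evalue <- function(len, mm, n) {
  exp(2 * log(n) + lchoose(len, mm) + (len - mm) * log(0.25) + mm * log(0.75))
}

#' Find dispersed (non-tandem) repeat pairs
#'
#' Reports maximal repeated pairs of four kinds: `forward` (second copy equals
#' the first), `reverse` (equals the reversed first), `palindromic` (equals
#' the reverse complement) and `complementary` (equals the complement), with
#' at most `max_mismatch` mismatches (Hamming distance; no gaps) and length at
#' least `min_len`. Maximality means no extension on either side keeps the
#' mismatch count within bound. Candidate pairs are found by exact k-mer
#' seeding with `k = ceiling((min_len - max_mismatch) / (max_mismatch + 1))`,
#' which the pigeonhole principle makes complete, and filtered at
#' `max_evalue` under the model of [dispersed_evalue()]. Pairs are stored
#' canonically with `start_a <= start_b`; identical-interval self matches are
#' excluded. On circular input the search wraps the origin (run with
#' `circular = FALSE` to reproduce linear tools).
#'
#' @param g A [circ_seq()] or character string.
#' @param min_len Minimum repeat length (bp, >= 8).
#' @param max_mismatch Maximum Hamming distance (0-12).
#' @param max_evalue E-value cutoff (records with E-value below this are
#'   kept).
#' @param kinds Subset of the four repeat kinds to search.
#' @param circular Override the sequence's circularity flag.
#' @return A `dispersed_table` tibble: `kind`, `start_a`, `end_a`, `start_b`,
#'   `end_b` (1-based inclusive), `length`, `mismatches`, `evalue`, sorted by
#'   decreasing length.
#' @export
find_dispersed_repeats <- function(g, min_len = 30L, max_mismatch = 3L,
                                   max_evalue = 1e-5,
                                   kinds = c("forward", "reverse",
                                             "palindromic", "complementary"),
                                   circular = is_circular(g)) {
  s <- as_seq_string(g)
  n <- nchar(s)
  min_len <- as.integer(min_len)
  max_mismatch <- as.integer(max_mismatch)
  if (min_len < 8L) abort("min_len must be >= 8")
  if (max_mismatch < 0L || max_mismatch > 12L) abort("max_mismatch must be in 0..12")
  kinds <- match.arg(kinds, several.ok = TRUE)
  # pigeonhole-complete seed length; capped so the 4^k seed buckets stay small
  k <- as.integer(ceiling((min_len - max_mismatch) / (max_mismatch + 1)))
  k <- max(2L, min(12L, k))

  S <- if (circular) paste0(s, s) else s
  Ns <- nchar(S)
  out <- list()
  for (kind in kinds) {
    T2 <- switch(kind,
      forward = S,
      reverse = rev_string(S),
      palindromic = reverse_complement(S),
      complementary = complement_dna(S)
    )
    win <- repeat_windows_cpp(
      S, T2, k, min_len, max_mismatch,
      skip_same_diag = (kind == "forward"),
      period = if (kind == "forward" && circular) n else 0L
    )
    if (!nrow(win)) next
    len <- win$len
    a0 <- win$start_s
    b0 <- switch(kind,
      forward = win$start_t,
      reverse = Ns - win$start_t - len,
      palindromic = Ns - win$start_t - len,
      complementary = win$start_t
    )
    if (circular) {
      # drop windows clipped at the ends of the unrolled (doubled) sequence:
      # every true circular window also appears unclipped in another image
      keep <- len <= n &
        win$start_s > 0L & win$start_t > 0L &
        (win$start_s + len) < Ns & (win$start_t + len) < Ns
      a0 <- a0[keep] %% n; b0 <- b0[keep] %% n
      len <- len[keep]; mm <- win$mm[keep]
    } else {
      mm <- win$mm
    }
    if (!length(len)) next
    sa <- pmin(a0, b0); sb <- pmax(a0, b0)
    tb <- tibble(kind = kind, start0_a = sa, start0_b = sb,
                 length = len, mismatches = mm)
    tb <- distinct(tb)
    tb <- tb[!(tb$start0_a == tb$start0_b), , drop = FALSE]
    out[[length(out) + 1L]] <- tb
  }
  res <- if (length(out)) list_rbind(out) else
    tibble(kind = character(), start0_a = integer(), start0_b = integer(),
           length = integer(), mismatches = integer())
  res$evalue <- dispersed_evalue(res$length, res$mismatches, n)
  res <- res[res$evalue < max_evalue, , drop = FALSE]
  end_of <- function(st0, len) {
    if (circular) (st0 + len - 1L) %% n + 1L else st0 + len
  }
  res <- tibble(
    kind = res$kind,
    start_a = as.integer(res$start0_a + 1L),
    end_a = as.integer(end_of(res$start0_a, res$length)),
    start_b = as.integer(res$start0_b + 1L),
    end_b = as.integer(end_of(res$start0_b, res$length)),
    length = as.integer(res$length),
    mismatches = as.integer(res$mismatches),
    evalue = res$evalue
  )
  res <- arrange(res, desc(.data$length), .data$start_a, .data$start_b, .data$kind)
  class(res) <- c("dispersed_table", class(res))
  res
}

unwrap_intervals <- function(start, end, n) {
  # split origin-wrapping 1-based inclusive intervals into linear pieces
  wraps <- end < start
  st <- c(start[!wraps], start[wraps], rep(1L, sum(wraps)))
  en <- c(end[!wraps], rep(n, sum(wraps)), end[wraps])
  list(start = st, end = en)
}

#' Summarise SSR and dispersed-repeat content
#'
#' @param ssrs An `ssr_table` from [find_ssrs()] (or `NULL`).
#' @param dispersed A `dispersed_table` from [find_dispersed_repeats()] (or
#'   `NULL`).
#' @param genome_length Genome length in bp (for coverage fractions).
#' @return A `repeat_summary` list: `ssr_by_unit`, `dispersed_by_kind`,
#'   `dispersed_by_length` (bins <50, 50-99, >=100 bp) and `overview` (one-row
#'   tibble with counts, the union length of dispersed-repeat-covered
#'   positions and its percentage of the genome).
#' @export
summarize_repeats <- function(ssrs = NULL, dispersed = NULL, genome_length) {
  ssr_by_unit <- if (!is.null(ssrs) && nrow(ssrs)) {
    count(as_tibble(ssrs), .data$unit_size, name = "n")
  } else tibble(unit_size = integer(), n = integer())
  disp <- if (is.null(dispersed)) tibble() else as_tibble(dispersed)
  dispersed_by_kind <- if (nrow(disp)) count(disp, .data$kind, name = "n") else
    tibble(kind = character(), n = integer())
  dispersed_by_length <- if (nrow(disp)) {
    disp |>
      mutate(length_bin = cut(.data$length, c(0, 49, 99, Inf),
                              labels = c("<50", "50-99", ">=100"))) |>
      count(.data$length_bin, name = "n", .drop = FALSE)
  } else tibble(length_bin = factor(), n = integer())
  union_len <- 0L
  if (nrow(disp)) {
    iv <- unwrap_intervals(c(disp$start_a, disp$start_b),
                           c(disp$end_a, disp$end_b), genome_length)
    rng <- IRanges::reduce(IRanges::IRanges(start = iv$start, end = iv$end))
    union_len <- sum(IRanges::width(rng))
  }
  overview <- tibble(
    n_ssr = if (is.null(ssrs)) 0L else nrow(ssrs),
    n_dispersed = nrow(disp),
    dispersed_union_bp = as.integer(union_len),
    dispersed_union_pct = 100 * union_len / genome_length,
    genome_length = as.integer(genome_length)
  )
  structure(list(ssr_by_unit = ssr_by_unit,
                 dispersed_by_kind = dispersed_by_kind,
                 dispersed_by_length = dispersed_by_length,
                 overview = overview),
            class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  o <- x$overview
  cat(sprintf("<repeat_summary> %d SSRs, %d dispersed pairs; dispersed union %s bp (%.2f%%)\n",
              o$n_ssr, o$n_dispersed, format(o$dispersed_union_bp, big.mark = ","),
              o$dispersed_union_pct))
  if (nrow(x$ssr_by_unit)) {
    cat("  SSRs by unit size: ",
        paste(sprintf("%d-mer: %d", x$ssr_by_unit$unit_size, x$ssr_by_unit$n),
              collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$dispersed_by_kind)) {
    cat("  dispersed by kind: ",
        paste(sprintf("%s: %d", x$dispersed_by_kind$kind, x$dispersed_by_kind$n),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
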