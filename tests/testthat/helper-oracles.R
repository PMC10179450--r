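# Independent brute-force oracles used to validate the optimised finders.
# These deliberately avoid the implementation's seeding/extension/bit-parallel
# machinery: plain scans and dynamic programming only.

# Introduce k random substitutions into a copy of s.
mutate_copy <- function(s, k) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

rnd_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Semi-global (infix) edit distance by textbook DP: pattern consumed fully,
# text ends free. N matches nothing, including N.
oracle_hw <- function(p, t) {
  m <- nchar(p); n <- nchar(t)
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  prev <- 0:m
  best <- m
  for (j in seq_len(n)) {
    cur <- integer(m + 1)
    for (i in seq_len(m)) {
      match <- pc[i] == tc[j] && pc[i] != "N"
      cur[i + 1] <- min(prev[i] + !match, prev[i + 1] + 1L, cur[i] + 1L)
    }
    best <- min(best, cur[m + 1])
    prev <- cur
  }
  best
}

# Exact substring containment spanning counts, both strands.
oracle_spanning <- function(ref_seqs, read_seqs) {
  rc <- reverse_complement(read_seqs)
  vapply(ref_seqs, function(ref) {
    sum(vapply(seq_along(read_seqs), function(i) {
      grepl(ref, read_seqs[i], fixed = TRUE) || grepl(ref, rc[i], fixed = TRUE)
    }, logical(1)))
  }, integer(1), USE.NAMES = FALSE)
}

# Exhaustive SSR scan: every (start, unit) with greedy complete-copy counting,
# keeping left-maximal runs of primitive motifs above threshold.
oracle_ssrs <- function(s, thresholds = c(`1` = 10L, `2` = 5L, `3` = 4L,
                                          `4` = 3L, `5` = 3L, `6` = 3L)) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  recs <- list()
  for (u in as.integer(names(thresholds))) {
    thr <- thresholds[[as.character(u)]]
    if (n < u * thr) next
    for (start in seq_len(n - u + 1L)) {
      motif <- paste(ch[start:(start + u - 1L)], collapse = "")
      if (grepl("N", motif, fixed = TRUE)) next
      if (!mitorecomb:::is_primitive_motif(motif)) next
      if (start > 1L && ch[start - 1L] != "N" &&
          ch[start - 1L] == ch[start + u - 1L]) next # not left-maximal
      copies <- 1L
      while (start + (copies + 1L) * u - 1L <= n) {
        nxt <- paste(ch[(start + copies * u):(start + (copies + 1L) * u - 1L)],
                     collapse = "")
        if (nxt != motif) break
        copies <- copies + 1L
      }
      if (copies >= thr) {
        recs[[length(recs) + 1L]] <- tibble::tibble(
          motif = motif, unit_size = u, copies = copies,
          start = start, end = start + u * copies - 1L, length = u * copies)
      }
    }
  }
  out <- if (length(recs)) dplyr::arrange(purrr::list_rbind(recs), start, unit_size)
  else tibble::tibble(motif = character(), unit_size = integer(),
                      copies = integer(), start = integer(), end = integer(),
                      length = integer())
  out
}

# Exhaustive maximal bounded-mismatch repeat pairs: full scan of every
# diagonal of S against the transformed sequence, no seeding. Linear mode.
oracle_dispersed <- function(s, min_len, max_mm, max_evalue = Inf,
                             kinds = c("forward", "reverse", "palindromic",
                                       "complementary")) {
  n <- nchar(s)
  Sx <- charToRaw(s)
  rawN <- charToRaw("N")
  recs <- list()
  for (kind in kinds) {
    Tstr <- switch(kind,
      forward = s,
      reverse = mitorecomb:::rev_string(s),
      palindromic = reverse_complement(s),
      complementary = mitorecomb:::complement_dna(s))
    Tx <- charToRaw(Tstr)
    nt <- length(Tx)
    for (d in seq(-(nt - min_len), n - min_len)) {
      lo <- max(0L, d); hi <- min(n, nt + d) # S positions (0-based) [lo, hi)
      if (hi - lo < min_len) next
      posS <- (lo + 1L):hi
      sv <- Sx[posS]; tv <- Tx[posS - d]
      ok <- sv != rawN & tv != rawN
      idx <- which(ok)
      if (!length(idx)) next
      for (r in split(idx, cumsum(c(1L, diff(idx) != 1L)))) {
        if (length(r) < min_len) next
        seg_lo <- posS[r[1]]; seg_hi <- posS[r[length(r)]]
        mmpos <- posS[r][sv[r] != tv[r]]
        M <- length(mmpos)
        if (M <= max_mm) {
          wins <- list(c(seg_lo, seg_hi, M))
        } else {
          q <- c(seg_lo - 1L, mmpos, seg_hi + 1L)
          wins <- lapply(seq_len(length(q) - max_mm - 1L), function(i) {
            c(q[i] + 1L, q[i + max_mm + 1L] - 1L, max_mm)
          })
        }
        for (w in wins) {
          len <- w[2] - w[1] + 1L
          if (len < min_len) next
          jt0 <- (w[1] - 1L) - d # 0-based start in T
          start_b <- switch(kind,
            forward = jt0 + 1L,
            reverse = n - jt0 - len + 1L,
            palindromic = n - jt0 - len + 1L,
            complementary = jt0 + 1L)
          if (kind == "forward" && d == 0L) next
          sa <- min(w[1], start_b); sb <- max(w[1], start_b)
          if (sa == sb) next
          recs[[length(recs) + 1L]] <- tibble::tibble(
            kind = kind, start_a = sa, end_a = sa + len - 1L,
            start_b = sb, end_b = sb + len - 1L,
            length = len, mismatches = w[3])
        }
      }
    }
  }
  out <- if (length(recs)) dplyr::distinct(purrr::list_rbind(recs)) else
    tibble::tibble(kind = character(), start_a = integer(), end_a = integer(),
                   start_b = integer(), end_b = integer(), length = integer(),
                   mismatches = integer())
  out$evalue <- mitorecomb::dispersed_evalue(out$length, out$mismatches, n)
  out <- out[out$evalue < max_evalue, , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(length), start_a, start_b, kind)
}

# Normalise a dispersed table for comparison with the oracle.
disp_key <- function(x) {
  dplyr::arrange(
    tibble::tibble(kind = as.character(x$kind), start_a = as.integer(x$start_a),
                   start_b = as.integer(x$start_b),
                   length = as.integer(x$length),
                   mismatches = as.integer(x$mismatches)),
    kind, start_a, start_b, length, mismatches)
}

# A small synthetic GenBank record with join/complement CDS locations.
toy_genbank <- function(path) {
  genome <- paste0(
    "ATGAAACCCGGGTTTTAA",            # 1..18  cds1 (+)
    "GCGCGCATATAT",                  # 19..30 spacer
    "TTACATGGGTCCCAT",               # 31..45 cds2 on minus strand
    "ACGTACGTACGT"                   # 46..57 spacer
  )
  n <- nchar(genome)
  lines <- c(
    sprintf("LOCUS       toyrecord %21d bp    DNA     circular PLN 01-JAN-2024", n),
    "DEFINITION  synthetic toy organelle record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    "     CDS             1..18",
    "                     /gene=\"geneA\"",
    "                     /product=\"toy protein A\"",
    "     CDS             complement(31..45)",
    "                     /gene=\"geneB\"",
    "     CDS             join(complement(31..45),1..6)",
    "                     /gene=\"geneC\"",
    "ORIGIN",
    paste0("        1 ", tolower(paste(
      substring(genome, seq(1, n, 10), pmin(seq(10, n + 9, 10), n)),
      collapse = " "))),
    "//"
  )
  writeLines(lines, path)
  genome
}
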