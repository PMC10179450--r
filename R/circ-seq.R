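#' Circular (or linear) DNA sequence
#'
#' Lightweight container for a single nucleotide sequence with a circularity
#' flag. Plant mitochondrial genomes are usually assembled as circles, and all
#' coordinate arithmetic in this package wraps through the origin when
#' `circular = TRUE`. The alphabet is restricted to `A`, `C`, `G`, `T`, `N`;
#' lower-case input is upper-cased.
#'
#' @param seq A single character string of DNA.
#' @param id Sequence identifier (first whitespace-delimited token is kept when
#'   reading FASTA headers).
#' @param circular Logical; does the sequence represent a circular molecule?
#' @return An object of class `circ_seq`: a list with elements `id`, `seq`,
#'   `circular`.
#' @examples
#' g <- circ_seq("ACGTACGT", id = "toy")
#' seq_len_bp(g)
#' gc_content(g)
#' @export
circ_seq <- function(seq, id = "seq", circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- str_to_upper(seq)
  if (nchar(seq) == 0L) abort("sequence must be non-empty", class = "mitorecomb_alphabet_error")
  check_dna(seq)
  structure(
    list(id = as.character(id), seq = seq, circular = isTRUE(circular)),
    class = "circ_seq"
  )
}

check_dna <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    abort(
      paste0("non-DNA character in sequence (alphabet is A,C,G,T,N)"),
      class = "mitorecomb_alphabet_error"
    )
  }
  invisible(TRUE)
}

#' @export
print.circ_seq <- function(x, ...) {
  topo <- if (x$circular) "circular" else "linear"
  cat(sprintf("<circ_seq> %s: %s bp (%s), GC %.2f%%\n",
              x$id, format(seq_len_bp(x), big.mark = ","), topo, gc_content(x)))
  invisible(x)
}

#' Sequence length in base pairs
#'
#' @param x A `circ_seq` or a character string.
#' @return Integer length.
#' @export
seq_len_bp <- function(x) {
  nchar(as_seq_string(x))
}

as_seq_string <- function(x) {
  if (inherits(x, "circ_seq")) x$seq else as.character(x)
}

is_circular <- function(x) {
  if (inherits(x, "circ_seq")) isTRUE(x$circular) else FALSE
}

#' Reverse complement of DNA strings
#'
#' Standard Watson-Crick reverse complement; `N` maps to `N`. Vectorised over
#' its input.
#'
#' @param seq Character vector of DNA strings (alphabet `A,C,G,T,N`), or a
#'   `circ_seq` (its sequence string is used).
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(seq) {
  if (inherits(seq, "circ_seq")) seq <- seq$seq
  seq <- str_to_upper(seq)
  for (s in seq) check_dna(s)
  vapply(seq, function(s) rev_string(chartr("ACGTN", "TGCAN", s)), character(1),
         USE.NAMES = FALSE)
}

complement_dna <- function(seq) {
  chartr("ACGTN", "TGCAN", str_to_upper(seq))
}

rev_string <- function(s) {
  intToUtf8(rev(utf8ToInt(s)))
}

#' Extract a (possibly origin-wrapping) substring
#'
#' On a circular sequence the extraction wraps through the origin, so any
#' window of up to the full genome length is defined from any start. On a
#' linear sequence a window running past the end is an error.
#'
#' @param x A `circ_seq` (or plain character string, treated as linear).
#' @param start 1-based start position, `1 <= start <= length`.
#' @param span Number of bases to extract, `1 <= span <= length`.
#' @return A character string of `span` bases.
#' @examples
#' g <- circ_seq("AACGTT")
#' circ_substr(g, 5, 4) # "TTAA"
#' @export
circ_substr <- function(x, start, span) {
  s <- as_seq_string(x)
  n <- nchar(s)
  start <- as.integer(start); span <- as.integer(span)
  if (is.na(start) || start < 1L || start > n) {
    abort(sprintf("start must be in [1, %d]", n), class = "mitorecomb_coord_error")
  }
  if (is.na(span) || span < 1L || span > n) {
    abort(sprintf("span must be in [1, %d]", n), class = "mitorecomb_coord_error")
  }
  if (start + span - 1L <= n) {
    return(substr(s, start, start + span - 1L))
  }
  if (!is_circular(x)) {
    abort("window runs past the end of a linear sequence",
          class = "mitorecomb_coord_error")
  }
  paste0(substr(s, start, n), substr(s, 1L, start + span - 1L - n))
}

#' GC content of a sequence, in percent
#'
#' Computed as `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from
#' the denominator.
#'
#' @param x A `circ_seq` or character string.
#' @return GC percentage (numeric scalar).
#' @export
gc_content <- function(x) {
  s <- as_seq_string(x)
  counts <- base_counts(s)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) {
    abort("GC content undefined: no unambiguous bases",
          class = "mitorecomb_empty_denominator")
  }
  100 * sum(counts[c("G", "C")]) / denom
}

base_counts <- function(s) {
  raw <- charToRaw(s)
  tab <- tabulate(as.integer(raw), nbins = 255L)
  c(A = tab[utf8ToInt("A")], C = tab[utf8ToInt("C")],
    G = tab[utf8ToInt("G")], T = tab[utf8ToInt("T")],
    N = tab[utf8ToInt("N")])
}

#' Rotate a circular sequence to a new origin
#'
#' @param x A circular `circ_seq`.
#' @param offset Number of bases to rotate by (the base at position
#'   `offset + 1` becomes the new first base).
#' @return A rotated `circ_seq`.
#' @export
rotate_seq <- function(x, offset) {
  stopifnot(inherits(x, "circ_seq"))
  if (!x$circular) abort("can only rotate a circular sequence")
  n <- seq_len_bp(x)
  offset <- ((as.integer(offset) %% n) + n) %% n
  if (offset == 0L) return(x)
  circ_seq(paste0(substr(x$seq, offset + 1L, n), substr(x$seq, 1L, offset)),
           id = x$id, circular = TRUE)
}
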