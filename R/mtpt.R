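blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

#' Find mitochondrial plastid DNA (MTPT) fragments
#'
#' Detects homologous segments between a mitogenome and a plastome with a
#' BLASTN search (the mitogenome as database, the plastome as query; word
#' size 7, E-value cutoff 1e-10, tabular output), then collapses hits to
#' unique mitogenome locations: hits whose mitogenome intervals overlap at
#' least `dedup_overlap` of the shorter interval — typically the plastome's
#' inverted repeat hitting the same insertion twice — are merged, keeping the
#' better E-value. Fragments are ranked by descending length as `MTPT1`,
#' `MTPT2`, ...
#'
#' @param mito A [circ_seq()]: the mitochondrial genome.
#' @param plastid A [circ_seq()]: the plastid genome.
#' @param word_size BLASTN word size (default 7).
#' @param max_evalue E-value cutoff (default 1e-10).
#' @param dedup_overlap Mitogenome-interval overlap fraction above which two
#'   hits are considered the same location (default 0.95).
#' @return An `mtpt_table` tibble: `rank_id`, `mito_start`, `mito_end`,
#'   `plastid_start`, `plastid_end`, `strand`, `length`, `identity` (percent),
#'   `mismatches`, `gap_opens`, `evalue`, `bitscore`, sorted by descending
#'   length.
#' @export
find_homologous_fragments <- function(mito, plastid, word_size = 7L,
                                      max_evalue = 1e-10,
                                      dedup_overlap = 0.95) {
  stopifnot(inherits(mito, "circ_seq"), inherits(plastid, "circ_seq"))
  if (!blast_available()) {
    abort("NCBI BLAST+ (blastn/makeblastdb) not found on PATH",
          class = "mitorecomb_missing_tool")
  }
  dir <- tempfile("mtpt")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  mito_fa <- file.path(dir, "mito.fasta")
  pt_fa <- file.path(dir, "plastid.fasta")
  out_tsv <- file.path(dir, "hits.tsv")
  write_fasta(mito, mito_fa)
  write_fasta(plastid, pt_fa)
  res <- system2("makeblastdb", c("-in", mito_fa, "-dbtype", "nucl"),
                 stdout = FALSE, stderr = FALSE)
  if (res != 0L) abort("makeblastdb failed")
  res <- system2("blastn", c(
    "-task", "blastn", "-word_size", word_size, "-evalue", format(max_evalue),
    "-query", pt_fa, "-db", mito_fa, "-outfmt", "6", "-out", out_tsv
  ), stdout = FALSE, stderr = FALSE)
  if (res != 0L) abort("blastn failed")

  cols <- c("qseqid", "sseqid", "pident", "length", "mismatches", "gap_opens",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  empty <- tibble(
    rank_id = character(), mito_start = integer(), mito_end = integer(),
    plastid_start = integer(), plastid_end = integer(), strand = character(),
    length = integer(), identity = numeric(), mismatches = integer(),
    gap_opens = integer(), evalue = numeric(), bitscore = numeric()
  )
  if (!file.size(out_tsv)) {
    class(empty) <- c("mtpt_table", class(empty))
    return(empty)
  }
  hits <- readr::read_tsv(out_tsv, col_names = cols, show_col_types = FALSE,
                          progress = FALSE)
  hits <- hits |>
    mutate(
      strand = ifelse(.data$send >= .data$sstart, "+", "-"),
      mito_start = pmin(.data$sstart, .data$send),
      mito_end = pmax(.data$sstart, .data$send)
    ) |>
    arrange(.data$evalue, desc(.data$bitscore), desc(.data$length))

  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- FALSE
    if (any(keep)) {
      kept <- hits[keep, ]
      inter <- pmin(kept$mito_end, hits$mito_end[i]) -
        pmax(kept$mito_start, hits$mito_start[i]) + 1L
      shorter <- pmin(kept$mito_end - kept$mito_start,
                      hits$mito_end[i] - hits$mito_start[i]) + 1L
      ov <- any(inter / shorter >= dedup_overlap)
    }
    keep[i] <- !ov
  }
  out <- hits[keep, ] |>
    arrange(desc(.data$length), .data$mito_start) |>
    mutate(rank_id = paste0("MTPT", row_number())) |>
    select("rank_id",
           mito_start = "mito_start", mito_end = "mito_end",
           plastid_start = "qstart", plastid_end = "qend",
           "strand", "length", identity = "pident",
           "mismatches", "gap_opens", "evalue", "bitscore") |>
    mutate(across(c("mito_start", "mito_end", "plastid_start", "plastid_end",
                    "length", "mismatches", "gap_opens"), as.integer))
  class(out) <- c("mtpt_table", class(out))
  out
}

#' Summarise MTPT fragments
#'
#' Total length is the sum of fragment lengths over unique mitogenome
#' locations (the accounting used when reporting MTPT content of plant
#' mitogenomes), not a positional union. Identity bins follow the
#' conventional >90%, 80-90%, <80% split.
#'
#' @param fragments An `mtpt_table` from [find_homologous_fragments()].
#' @param mito_length Mitogenome length in bp.
#' @return A one-row tibble: `n_fragments`, `total_length`, `pct_of_mito`,
#'   `longest`, `n_gt_1kb`, `n_identity_gt90`, `n_identity_80_90`,
#'   `n_identity_lt80`.
#' @export
summarize_mtpt <- function(fragments, mito_length) {
  tibble(
    n_fragments = nrow(fragments),
    total_length = sum(fragments$length),
    pct_of_mito = 100 * sum(fragments$length) / mito_length,
    longest = if (nrow(fragments)) max(fragments$length) else 0L,
    n_gt_1kb = sum(fragments$length > 1000L),
    n_identity_gt90 = sum(fragments$identity > 90),
    n_identity_80_90 = sum(fragments$identity >= 80 & fragments$identity <= 90),
    n_identity_lt80 = sum(fragments$identity < 80)
  )
}
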