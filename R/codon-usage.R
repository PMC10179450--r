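#' Extract CDS nucleotide sequences from a GenBank annotation
#'
#' Returns one spliced, strand-corrected sequence per `CDS` feature, including
#' duplicated gene copies. Trans-spliced genes are assembled only when the
#' annotation encodes them as a single joined feature; otherwise each feature
#' yields its own (flagged) part. Features whose location fails to parse are
#' skipped with a warning; sequences whose length is not a multiple of three
#' are flagged (`mod3 = FALSE`) and their trailing partial codon is dropped by
#' [compute_rscu()].
#'
#' @param annotation A path to a GenBank flat file, or a parsed record from
#'   [read_genbank()].
#' @param genome Optional [circ_seq()] overriding the record's ORIGIN
#'   sequence.
#' @return A tibble: `gene`, `product`, `location`, `n_parts`, `seq`,
#'   `length`, `mod3`, `partial`.
#' @export
extract_cds <- function(annotation, genome = NULL) {
  rec <- if (is.character(annotation)) read_genbank(annotation)[[1]] else annotation
  if (is.null(genome)) {
    if (is.na(rec$sequence) || !nchar(rec$sequence)) {
      abort("record has no ORIGIN sequence; supply `genome`")
    }
    genome <- circ_seq(rec$sequence, id = rec$locus, circular = isTRUE(rec$circular))
  }
  feats <- rec$features
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  qual_get <- function(q, nm) {
    if (!is.null(q) && nm %in% names(q)) q[[nm]] else NA_character_
  }
  rows <- list()
  for (i in seq_len(nrow(cds))) {
    q <- cds$qualifiers[[i]]
    loc <- cds$location[i]
    label <- qual_get(q, "gene")
    if (is.na(label)) label <- loc
    seq <- tryCatch(gb_location_seq(loc, genome), error = function(e) {
      warn(sprintf("skipping CDS '%s': %s", label, conditionMessage(e)))
      NULL
    })
    if (is.null(seq)) next
    mod3 <- nchar(seq) %% 3L == 0L
    if (!mod3) {
      warn(sprintf("CDS '%s' length %d is not a multiple of 3", label, nchar(seq)))
    }
    rows[[length(rows) + 1L]] <- tibble(
      gene = qual_get(q, "gene"),
      product = qual_get(q, "product"),
      location = loc,
      n_parts = count_loc_parts(loc),
      seq = seq,
      length = nchar(seq),
      mod3 = mod3,
      partial = grepl("[<>]", loc)
    )
  }
  if (!length(rows)) {
    return(tibble(gene = character(), product = character(), location = character(),
                  n_parts = integer(), seq = character(), length = integer(),
                  mod3 = logical(), partial = logical()))
  }
  list_rbind(rows)
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon `c` of an amino acid with `k` synonymous codons,
#' `RSCU(c) = count(c) * k / sum(counts over the family)`: the observed count
#' divided by the count expected if all synonymous codons were used equally.
#' Values above 1 mark preferred codons. Single-codon families (Met, Trp in
#' the standard code) have RSCU 1 whenever observed. Stop codons are excluded
#' by default; codons containing `N` are skipped; each sequence's trailing
#' partial codon (length not a multiple of 3) is dropped.
#'
#' @param cds A character vector of CDS sequences, or a tibble with a `seq`
#'   column (e.g. from [extract_cds()]).
#' @param include_stop Count stop codons as a (three-codon) family?
#' @param genetic_code A genetic code id understood by
#'   [Biostrings::getGeneticCode()] (default `"1"`, standard; plant
#'   mitochondria use the standard code).
#' @return An `rscu_table` tibble with one row per codon: `codon` (RNA
#'   alphabet), `dna_codon`, `amino_acid`, `count`, `rscu` (NA for families
#'   never observed), sorted by amino acid.
#' @examples
#' compute_rscu("ATGTTATTGTTATAA")["TTA" == compute_rscu("ATGTTATTGTTATAA")$dna_codon, ]
#' @export
compute_rscu <- function(cds, include_stop = FALSE, genetic_code = "1") {
  seqs <- if (is.data.frame(cds)) cds$seq else as.character(cds)
  seqs <- seqs[!is.na(seqs) & nchar(seqs) >= 3L]
  if (!length(seqs)) abort("no CDS sequences to count")
  code <- Biostrings::getGeneticCode(genetic_code)
  codons <- unlist(lapply(str_to_upper(seqs), function(s) {
    n <- nchar(s) - nchar(s) %% 3L
    substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  }), use.names = FALSE)
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  counts <- table(factor(codons, levels = names(code)))
  tab <- tibble(
    dna_codon = names(code),
    amino_acid = unname(code),
    count = as.integer(counts)
  )
  if (!include_stop) tab <- tab[tab$amino_acid != "*", , drop = FALSE]
  tab <- tab |>
    group_by(.data$amino_acid) |>
    mutate(
      family_size = dplyr::n(),
      family_count = sum(.data$count),
      rscu = ifelse(.data$family_count > 0,
                    .data$count * .data$family_size / .data$family_count,
                    NA_real_)
    ) |>
    ungroup() |>
    select(-"family_size", -"family_count")
  out <- tab |>
    mutate(codon = chartr("T", "U", .data$dna_codon)) |>
    select("codon", "dna_codon", "amino_acid", "count", "rscu") |>
    arrange(.data$amino_acid, .data$codon)
  class(out) <- c("rscu_table", class(out))
  out
}
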