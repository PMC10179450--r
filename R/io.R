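#' Read a FASTA file into a tibble
#'
#' Sequence ids are the first whitespace-delimited token of each header line.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param circular Logical, recorded on the returned records; organelle
#'   assemblies are conventionally circular.
#' @return A tibble with columns `id`, `seq`, `length`, `circular`.
#' @export
read_fasta <- function(path, circular = FALSE) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  tibble(
    id = ids,
    seq = unname(as.character(set)),
    length = Biostrings::width(set),
    circular = circular
  )
}

#' Write sequences to FASTA (wrapped at 70 columns)
#'
#' @param x A tibble with columns `id` and `seq`, a named character vector, or
#'   a single `circ_seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  x <- as_seq_tbl(x)
  set <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

as_seq_tbl <- function(x) {
  if (inherits(x, "circ_seq")) return(tibble(id = x$id, seq = x$seq))
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    return(tibble(id = ids, seq = unname(x)))
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  as_tibble(x[, c("id", "seq")])
}

#' Read a FASTQ file into a tibble
#'
#' Quality strings are passed through untouched; this package never interprets
#' them.
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("malformed FASTQ: %d lines is not a multiple of 4 (%s)",
                  length(lines), path))
  }
  idx <- seq(1L, length(lines), by = 4L)
  headers <- lines[idx]
  bad <- which(!startsWith(headers, "@"))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ record at line %d: header must start with '@'",
                  (bad[1] - 1L) * 4L + 1L))
  }
  tibble(
    read_id = vapply(strsplit(sub("^@", "", headers), "\\s+"), `[[`, character(1), 1L),
    seq = str_to_upper(lines[idx + 1L]),
    qual = lines[idx + 3L]
  )
}

#' Write reads to FASTQ
#'
#' @param reads A tibble with columns `read_id` and `seq`; an optional `qual`
#'   column is used verbatim, otherwise a constant dummy quality (`I`) is
#'   written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  qual <- reads[["qual"]] %||% vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  out <- rbind(paste0("@", reads$read_id), reads$seq, "+", qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read a BED file (0-based half-open) into a tibble
#'
#' @param path Path to a BED3+ file.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and, when present, `name` and `strand`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 3L) abort(sprintf("malformed BED (need >= 3 columns): %s", path))
  out <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  )
  if (ncol(raw) >= 4L) out$name <- as.character(raw[[4]])
  if (ncol(raw) >= 6L) out$strand <- as.character(raw[[6]])
  out
}

#' Write intervals to BED (0-based half-open)
#'
#' @param x A tibble with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`. `start`/`end` must already be 0-based
#'   half-open.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(x[["name"]])) {
    cols <- c(cols, list(x[["name"]], x[["score"]] %||% rep(0L, nrow(x)),
                         x[["strand"]] %||% rep("+", nrow(x))))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a tibble as TSV
#'
#' Thin wrapper standardising the package's report format: tab-separated,
#' UTF-8, header row. List-columns are collapsed with commas.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  x <- as_tibble(x)
  is_list <- vapply(x, is.list, logical(1))
  x[is_list] <- lapply(x[is_list], vapply, paste, character(1), collapse = ",")
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
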