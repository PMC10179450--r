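#' Read a GenBank flat file
#'
#' Minimal parser for the fields this package needs: LOCUS (name, length,
#' topology), the FEATURES table (feature keys, location strings, qualifiers)
#' and the ORIGIN sequence. Location strings are kept verbatim and interpreted
#' lazily by [extract_cds()], including nested `join(...)` /
#' `complement(...)`.
#'
#' @param path Path to a GenBank flat file (single or multi-record).
#' @return A list of records; each record is a list with elements `locus`,
#'   `length`, `circular`, `features` (tibble: `type`, `location`,
#'   `qualifiers` list column of named character vectors) and `sequence`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  breaks <- c(0L, which(trimws(lines) == "//"))
  if (length(breaks) == 1L) breaks <- c(0L, length(lines))
  records <- list()
  for (bi in seq_len(length(breaks) - 1L)) {
    chunk <- lines[(breaks[bi] + 1L):(breaks[bi + 1L])]
    if (!any(startsWith(chunk, "LOCUS"))) next
    records[[length(records) + 1L]] <- parse_genbank_record(chunk)
  }
  if (!length(records)) abort(sprintf("no GenBank records found in %s", path))
  records
}

parse_genbank_record <- function(lines) {
  locus_line <- lines[startsWith(lines, "LOCUS")][1]
  toks <- strsplit(trimws(locus_line), "\\s+")[[1]]
  locus <- toks[2] %||% NA_character_
  len <- suppressWarnings(as.integer(toks[toks != "bp"][3]))
  circular <- any(grepl("\\bcircular\\b", locus_line, ignore.case = TRUE))

  fstart <- grep("^FEATURES", lines)[1]
  oline <- grep("^ORIGIN", lines)[1]
  features <- tibble(type = character(), location = character(), qualifiers = list())
  if (!is.na(fstart)) {
    fend <- if (!is.na(oline)) oline - 1L else length(lines)
    flines <- lines[(fstart + 1L):fend]
    flines <- flines[grepl("^\\s{5}", flines) & nzchar(trimws(flines))]
    is_key <- grepl("^\\s{5}\\S", flines)
    if (any(is_key)) {
      grp <- cumsum(is_key)
      feats <- split(flines, grp)
      parsed <- lapply(feats, parse_gb_feature)
      features <- tibble(
        type = vapply(parsed, `[[`, character(1), "type"),
        location = vapply(parsed, `[[`, character(1), "location"),
        qualifiers = lapply(parsed, `[[`, "qualifiers")
      )
    }
  }

  sequence <- NA_character_
  if (!is.na(oline)) {
    send <- length(lines)
    seq_lines <- lines[(oline + 1L):send]
    seq_lines <- seq_lines[!trimws(seq_lines) %in% c("", "//")]
    sequence <- str_to_upper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  list(locus = locus, length = len, circular = circular,
       features = features, sequence = sequence)
}

parse_gb_feature <- function(flines) {
  key <- trimws(substr(flines[1], 6L, 20L))
  body <- trimws(substr(flines, 21L, nchar(flines)))
  body[1] <- trimws(substr(flines[1], 21L, nchar(flines[1])))
  qual_starts <- which(startsWith(body, "/"))
  loc_end <- if (length(qual_starts)) qual_starts[1] - 1L else length(body)
  location <- paste(body[seq_len(loc_end)], collapse = "")
  qualifiers <- character()
  if (length(qual_starts)) {
    bounds <- c(qual_starts, length(body) + 1L)
    for (qi in seq_along(qual_starts)) {
      qtext <- paste(body[bounds[qi]:(bounds[qi + 1L] - 1L)], collapse = " ")
      m <- regmatches(qtext, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", qtext))[[1]]
      if (length(m) < 2L) next
      qname <- m[2]
      qval <- if (nchar(m[4] %||% "")) gsub('^"|"$', "", m[4]) else "TRUE"
      qualifiers[qname] <- qval
    }
  }
  list(type = key, location = location, qualifiers = qualifiers)
}

# ---- location strings ------------------------------------------------------

split_top_commas <- function(txt) {
  depth <- 0L
  cuts <- integer()
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, nchar(txt))
  mapply(function(a, b) substr(txt, a, b), starts, ends, USE.NAMES = FALSE)
}

#' Evaluate a GenBank location string against a sequence
#'
#' Supports `a..b`, single-base `a`, and arbitrarily nested `join(...)`,
#' `order(...)` and `complement(...)`; partiality markers `<`/`>` are
#' stripped. `complement(join(a, b))` reverse-complements the spliced
#' concatenation, per the GenBank convention. On circular sequences a range
#' with `end < start` wraps the origin.
#'
#' @param location A GenBank location string.
#' @param g A [circ_seq()] (or character string).
#' @return The spliced, strand-corrected nucleotide sequence.
#' @export
gb_location_seq <- function(location, g) {
  loc <- gsub("\\s+", "", location)
  eval_loc(loc, g)
}

eval_loc <- function(loc, g) {
  if (startsWith(loc, "complement(") && endsWith(loc, ")")) {
    inner <- substr(loc, nchar("complement(") + 1L, nchar(loc) - 1L)
    return(reverse_complement(eval_loc(inner, g)))
  }
  for (op in c("join(", "order(")) {
    if (startsWith(loc, op) && endsWith(loc, ")")) {
      inner <- substr(loc, nchar(op) + 1L, nchar(loc) - 1L)
      parts <- split_top_commas(inner)
      return(paste(vapply(parts, eval_loc, character(1), g = g), collapse = ""))
    }
  }
  rng <- gsub("[<>]", "", loc)
  if (grepl("^[0-9]+$", rng)) {
    a <- as.integer(rng)
    return(circ_substr(g, a, 1L))
  }
  if (grepl("^[0-9]+\\.\\.[0-9]+$", rng)) {
    ab <- as.integer(strsplit(rng, "..", fixed = TRUE)[[1]])
    n <- seq_len_bp(g)
    span <- (ab[2] - ab[1]) %% n + 1L
    return(circ_substr(g, ab[1], span))
  }
  abort(sprintf("cannot parse location '%s'", loc),
        class = "mitorecomb_location_error")
}

count_loc_parts <- function(location) {
  length(gregexpr("[0-9]+(\\.\\.[0-9]+)?", gsub("\\s+", "", location))[[1]])
}
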