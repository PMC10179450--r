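#' Assembly graph with repeat nodes
#'
#' A minimal segment/link graph of the kind produced by unitig assemblers for
#' repeat-bearing circular genomes: unique segments traversed once and repeat
#' segments traversed according to their copy number (two, for the two-copy
#' direct repeats handled here). Links connect the right end of `from` to the
#' left end of `to`; only forward (`+/+`) links are supported, matching the
#' direct-repeat topology. Inverted links raise an unsupported-orientation
#' error.
#'
#' @param segments A tibble with columns `id` and at least one of `seq` /
#'   `length`; an optional logical `is_repeat` column (inferred from link
#'   degree when absent).
#' @param links A tibble with columns `from`, `to` (segment ids), each row an
#'   adjacency `from -> to`. Optional `from_orient` / `to_orient` columns must
#'   be `"+"`.
#' @return An `assembly_graph` object.
#' @export
assembly_graph <- function(segments, links) {
  segments <- as_tibble(segments)
  links <- as_tibble(links)
  stopifnot("id" %in% names(segments), all(c("from", "to") %in% names(links)))
  if (!"seq" %in% names(segments)) segments$seq <- NA_character_
  if (!"length" %in% names(segments)) {
    segments$length <- nchar(segments$seq)
  }
  segments$length <- as.integer(segments$length)
  orients <- c(links[["from_orient"]] %||% rep("+", nrow(links)),
               links[["to_orient"]] %||% rep("+", nrow(links)))
  if (any(orients != "+")) {
    abort("inverted (-) links are not supported: only direct-repeat graphs are handled",
          class = "mitorecomb_orientation_error")
  }
  unknown <- setdiff(c(links$from, links$to), segments$id)
  if (length(unknown)) {
    abort(paste0("links reference unknown segments: ", paste(unknown, collapse = ", ")))
  }
  outdeg <- table(factor(links$from, levels = segments$id))
  indeg <- table(factor(links$to, levels = segments$id))
  if (any(outdeg != indeg)) {
    abort("segment in-degree != out-degree: graph admits no circular decomposition",
          class = "mitorecomb_structural_error")
  }
  if (any(outdeg < 1L) || any(outdeg > 2L)) {
    abort("each segment must be traversed once (unique) or twice (two-copy repeat)",
          class = "mitorecomb_structural_error")
  }
  if (!"is_repeat" %in% names(segments)) {
    segments$is_repeat <- as.vector(outdeg[segments$id] == 2L)
  }
  if (any(segments$is_repeat != (outdeg[segments$id] == 2L))) {
    abort("is_repeat flags disagree with link degrees",
          class = "mitorecomb_structural_error")
  }
  structure(list(segments = segments, links = links), class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  nrep <- sum(x$segments$is_repeat)
  cat(sprintf("<assembly_graph> %d segments (%d repeat nodes), %d links\n",
              nrow(x$segments), nrep, nrow(x$links)))
  invisible(x)
}

#' Build an assembly graph from a circular segment layout
#'
#' Convenience constructor: the layout is the ordered traversal of the master
#' circle (e.g. `c("S1","R1","S2","R2","S3","R1","S4","R2")`); segments
#' appearing twice become repeat nodes.
#'
#' @param layout Character vector of segment ids in master-circle order.
#' @param seqs Named character vector of segment sequences (one entry per
#'   unique id), or `NULL` for a sequence-free graph (lengths must then be
#'   given via `lengths`).
#' @param lengths Named integer vector of segment lengths (ignored when `seqs`
#'   is given).
#' @return An `assembly_graph`.
#' @export
graph_from_layout <- function(layout, seqs = NULL, lengths = NULL) {
  ids <- unique(layout)
  counts <- table(factor(layout, levels = ids))
  segments <- tibble(
    id = ids,
    seq = if (is.null(seqs)) NA_character_ else unname(seqs[ids]),
    length = if (is.null(seqs)) unname(lengths[ids]) else nchar(unname(seqs[ids])),
    is_repeat = as.vector(counts > 1L)
  )
  nxt <- c(layout[-1], layout[1])
  links <- tibble(from = layout, to = nxt)
  assembly_graph(segments, links)
}

#' Enumerate circular isomers of a repeat-bearing assembly graph
#'
#' Each two-copy repeat node has two entering and two leaving links; a
#' conformation corresponds to a pairing of entries to exits (two pairings per
#' repeat). All `2^k` pairing combinations over the `k` repeat nodes are
#' expanded into circle decompositions, deduplicated up to rotation and
#' reverse complement of each circle, and classified as a single master circle
#' or a set of sub-genomic circles.
#'
#' @param graph An [assembly_graph()].
#' @return An `isomer_set`: a list of isomers, each a list with elements
#'   `circles` (list of character vectors of segment ids, in traversal order)
#'   and `classification` (`"master"` or `"sub_circle_pair"`).
#' @examples
#' g <- graph_from_layout(c("S1", "R1", "S2", "R2", "S3", "R1", "S4", "R2"),
#'                        lengths = c(S1 = 100, R1 = 50, S2 = 80, R2 = 40,
#'                                    S3 = 60, S4 = 30))
#' length(enumerate_isomers(g)) # 4
#' @export
enumerate_isomers <- function(graph) {
  stopifnot(inherits(graph, "assembly_graph"))
  links <- graph$links
  edges <- seq_len(nrow(links))
  seg_in <- split(edges, factor(links$to, levels = graph$segments$id))
  seg_out <- split(edges, factor(links$from, levels = graph$segments$id))
  rep_ids <- graph$segments$id[graph$segments$is_repeat]
  k <- length(rep_ids)

  combos <- if (k == 0) matrix(0L, nrow = 1, ncol = 0) else
    as.matrix(expand.grid(rep(list(0:1), k)))

  isomers <- list()
  keys <- character()
  for (ci in seq_len(nrow(combos))) {
    succ <- integer(length(edges)) # succ[e]: edge following e in the traversal
    for (sid in graph$segments$id) {
      ins <- seg_in[[sid]]
      outs <- seg_out[[sid]]
      if (length(ins) == 1L) {
        succ[ins] <- outs
      } else {
        swap <- sid %in% rep_ids && combos[ci, match(sid, rep_ids)] == 1L
        if (swap) {
          succ[ins[1]] <- outs[2]; succ[ins[2]] <- outs[1]
        } else {
          succ[ins[1]] <- outs[1]; succ[ins[2]] <- outs[2]
        }
      }
    }
    circles <- decompose_cycles(succ, links)
    key <- isomer_key(circles)
    if (!key %in% keys) {
      keys <- c(keys, key)
      isomers[[length(isomers) + 1L]] <- structure(
        list(circles = circles,
             classification = if (length(circles) == 1L) "master" else "sub_circle_pair",
             pairing = if (k) setNames(combos[ci, ], rep_ids) else integer()),
        class = "isomer"
      )
    }
  }
  structure(isomers, class = "isomer_set", graph = graph)
}

decompose_cycles <- function(succ, links) {
  visited <- rep(FALSE, length(succ))
  circles <- list()
  for (e0 in seq_along(succ)) {
    if (visited[e0]) next
    e <- e0
    segs <- character()
    repeat {
      visited[e] <- TRUE
      segs <- c(segs, links$to[e])
      e <- succ[e]
      if (e == e0) break
    }
    circles[[length(circles) + 1L]] <- segs
  }
  circles
}

canonical_circle <- function(ids) {
  n <- length(ids)
  rots <- function(v) {
    vapply(seq_len(n), function(i) paste(c(v[i:n], v[seq_len(i - 1L)]), collapse = ">"),
           character(1))
  }
  min(c(rots(ids), rots(rev(ids))))
}

isomer_key <- function(circles) {
  paste(sort(vapply(circles, canonical_circle, character(1))), collapse = " | ")
}

#' @export
print.isomer_set <- function(x, ...) {
  cat(sprintf("<isomer_set> %d isomer(s)\n", length(x)))
  for (i in seq_along(x)) {
    iso <- x[[i]]
    desc <- vapply(iso$circles, paste, character(1), collapse = "-")
    cat(sprintf("  [%d] %s: %s\n", i, iso$classification, paste(desc, collapse = " + ")))
  }
  invisible(x)
}

#' @export
tidy.isomer_set <- function(x, ...) {
  graph <- attr(x, "graph")
  len <- setNames(graph$segments$length, graph$segments$id)
  purrr::imap(x, function(iso, i) {
    tibble(
      isomer = i,
      classification = iso$classification,
      circle = seq_along(iso$circles),
      n_segments = lengths(iso$circles),
      segments = vapply(iso$circles, paste, character(1), collapse = ","),
      length = vapply(iso$circles, function(s) sum(len[s]), numeric(1))
    )
  }) |> list_rbind()
}

#' Emit the sequence of each circle of an isomer
#'
#' Circles are linearised starting at their lexicographically smallest
#' rotation so that equal circles always serialise identically.
#'
#' @param isomer An `isomer` (one element of an [enumerate_isomers()] result).
#' @param graph The [assembly_graph()] the isomer was enumerated from; every
#'   segment must carry a sequence.
#' @param prefix Record id prefix.
#' @return A tibble with columns `id`, `seq`, `length` (one row per circle).
#' @export
isomer_to_fasta <- function(isomer, graph, prefix = "isomer") {
  stopifnot(inherits(isomer, "isomer"), inherits(graph, "assembly_graph"))
  seqs <- setNames(graph$segments$seq, graph$segments$id)
  if (anyNA(seqs)) abort("all segments must carry a sequence")
  recs <- purrr::imap(isomer$circles, function(segs, i) {
    s <- paste(seqs[segs], collapse = "")
    rot <- least_rotation_cpp(s)
    if (rot > 0) s <- paste0(substr(s, rot + 1L, nchar(s)), substr(s, 1L, rot))
    tibble(id = paste0(prefix, "_circle", i), seq = s, length = nchar(s))
  })
  list_rbind(recs)
}

#' Read a GFA 1.0 graph (S/L lines)
#'
#' @param path Path to a GFA file. `S` lines may carry `*` sequences with an
#'   `LN:i:` tag; only `+/+` links are accepted downstream.
#' @return An [assembly_graph()].
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  segs <- list(); lnks <- list()
  for (li in seq_along(fields)) {
    f <- fields[[li]]
    if (!length(f)) next
    if (f[1] == "S") {
      if (length(f) < 3L) abort(sprintf("malformed GFA S line at line %d", li))
      sq <- if (f[3] == "*") NA_character_ else str_to_upper(f[3])
      ln <- NA_integer_
      tag <- grep("^LN:i:", f[-(1:3)], value = TRUE)
      if (length(tag)) ln <- as.integer(sub("^LN:i:", "", tag[1]))
      if (is.na(ln) && !is.na(sq)) ln <- nchar(sq)
      segs[[length(segs) + 1L]] <- tibble(id = f[2], seq = sq, length = ln)
    } else if (f[1] == "L") {
      if (length(f) < 5L) abort(sprintf("malformed GFA L line at line %d", li))
      lnks[[length(lnks) + 1L]] <- tibble(
        from = f[2], from_orient = f[3], to = f[4], to_orient = f[5]
      )
    }
  }
  if (!length(segs)) abort(sprintf("no S lines in GFA: %s", path))
  assembly_graph(list_rbind(segs), list_rbind(lnks))
}

#' Write an assembly graph as GFA 1.0
#'
#' @param graph An [assembly_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  s_lines <- with(graph$segments, sprintf(
    "S\t%s\t%s\tLN:i:%d", id, ifelse(is.na(seq), "*", seq), length))
  l_lines <- sprintf("L\t%s\t+\t%s\t+\t0M", graph$links$from, graph$links$to)
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}
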