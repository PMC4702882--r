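#' Parse an all-vs-all similarity hit table
#'
#' Reads tab-separated hits `(query, subject, bitscore)`. Protein ids carry a
#' species prefix delimited by the first `"."` (`"speciesid.proteinid"`).
#' Malformed lines (unparseable bit-score, missing species prefix, self-hits)
#' are dropped and reported with their line numbers via a warning; the
#' accepted hits are returned with the rejects attached as the `"errors"`
#' attribute.
#'
#' @param path Path to the hit table; may be gzip-compressed (`.gz`).
#' @return A data.frame with columns `query`, `subject`, `bitscore`.
#' @export
parse_hits <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, open = "rt") else file(path, open = "rt")
  on.exit(close(con))
  query <- character(0); subject <- character(0); bitscore <- numeric(0)
  errors <- character(0)
  lineno <- 0L
  repeat {
    chunk <- readLines(con, n = 50000L, warn = FALSE)
    if (!length(chunk)) break
    nums <- lineno + seq_along(chunk)
    lineno <- lineno + length(chunk)
    keep <- !grepl("^\\s*#", chunk) & nzchar(trimws(chunk))
    chunk <- chunk[keep]; nums <- nums[keep]
    if (!length(chunk)) next
    parts <- strsplit(chunk, "\t", fixed = TRUE)
    nf <- lengths(parts)
    q <- vapply(parts, function(p) if (length(p) >= 1L) p[1] else "", character(1))
    s <- vapply(parts, function(p) if (length(p) >= 2L) p[2] else "", character(1))
    b <- suppressWarnings(as.numeric(vapply(parts, function(p) {
      if (length(p) >= 3L) p[3] else NA_character_
    }, character(1))))
    has_prefix <- function(x) grepl("^[^.]+\\..+", x)
    bad <- nf < 3L | is.na(b) | b < 0 | !has_prefix(q) | !has_prefix(s)
    selfhit <- !bad & q == s
    reason <- ifelse(nf < 3L, "expected 3 fields",
              ifelse(is.na(b) | b < 0, "unparseable bitscore",
              ifelse(!has_prefix(q) | !has_prefix(s), "missing species prefix",
                     "self-hit")))
    drop <- bad | selfhit
    if (any(drop)) {
      errors <- c(errors, paste0("line ", nums[drop], ": ", reason[drop]))
    }
    query <- c(query, q[!drop])
    subject <- c(subject, s[!drop])
    bitscore <- c(bitscore, b[!drop])
  }
  if (length(errors)) {
    warning(length(errors), " malformed hit line(s) skipped: ",
            paste(utils::head(errors, 5L), collapse = "; "),
            if (length(errors) > 5L) " ..." else "")
  }
  out <- data.frame(query = query, subject = subject, bitscore = bitscore,
                    stringsAsFactors = FALSE)
  attr(out, "errors") <- errors
  out
}

#' Filter hits by bit-score threshold
#'
#' Retains exactly the hits whose bit-score is strictly greater than
#' `threshold`. The default of 50 bits is the conventional storage cut-off
#' for all-vs-all protein comparisons; hits at exactly the threshold are
#' dropped.
#'
#' @param hits Data.frame as returned by [parse_hits()].
#' @param threshold Bit-score cut-off (default 50).
#' @return The filtered data.frame.
#' @export
filter_hits <- function(hits, threshold = 50) {
  hits[hits$bitscore > threshold, , drop = FALSE]
}

#' Symmetrize directed hits into an undirected similarity graph
#'
#' All-vs-all comparisons report both directions of a pair, usually with
#' slightly different scores. One undirected edge is kept per unordered pair
#' with weight equal to the maximum of the observed directed scores; pairs
#' seen in only one direction keep that score.
#'
#' @param hits Data.frame of (filtered) hits.
#' @return A `hit_graph`: list with `edges` (data.frame `a`, `b`, `weight`
#'   with `a < b` lexicographically), `nodes` (protein ids) and `species`
#'   (named character vector, species per node).
#' @export
symmetrize <- function(hits) {
  if (!nrow(hits)) return(new_hit_graph(
    data.frame(a = character(0), b = character(0), weight = numeric(0),
               stringsAsFactors = FALSE), character(0)))
  a <- pmin(hits$query, hits$subject)
  b <- pmax(hits$query, hits$subject)
  key <- paste(a, b, sep = "\r")
  w <- tapply(hits$bitscore, key, max)
  ord <- sort(names(w))
  ab <- strsplit(ord, "\r", fixed = TRUE)
  edges <- data.frame(a = vapply(ab, `[`, character(1), 1L),
                      b = vapply(ab, `[`, character(1), 2L),
                      weight = as.numeric(w[ord]), stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$a, edges$b)))
  new_hit_graph(edges, nodes)
}

new_hit_graph <- function(edges, nodes) {
  structure(list(edges = edges, nodes = nodes,
                 species = stats::setNames(if (length(nodes)) species_of(nodes)
                                           else character(0), nodes)),
            class = "hit_graph")
}

#' @export
print.hit_graph <- function(x, ...) {
  cat("Similarity graph:", length(x$nodes), "proteins,",
      nrow(x$edges), "edges,", length(unique(x$species)), "species\n")
  invisible(x)
}

#' Restrict a similarity graph to the species of a taxonomic level
#'
#' Clustering runs independently per taxonomic level on the induced subgraph
#' of proteins whose species belong to the level.
#'
#' @param g A `hit_graph`.
#' @param level A level entry of a `level_hierarchy` (list with `species`),
#'   or a character vector of species ids.
#' @return The induced `hit_graph`.
#' @export
restrict_to_level <- function(g, level) {
  sp <- if (is.character(level)) level else level$species
  nodes <- g$nodes[g$species[g$nodes] %in% sp]
  keep <- g$edges$a %in% nodes & g$edges$b %in% nodes
  new_hit_graph(g$edges[keep, , drop = FALSE], nodes)
}
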