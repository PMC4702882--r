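#' Nested taxonomic levels
#'
#' Orthologous groups are computed independently at a set of manually chosen
#' taxonomic levels, each spanning a clade of the tree of life. A
#' `level_hierarchy` holds these levels as a rooted tree: each level owns a
#' species set and every non-root level's species are a subset of its
#' parent's, so OGs computed at nested levels can be reconciled against one
#' another.
#'
#' @section Level table format:
#' Tab-separated, three columns: `level_id`, `parent_id` (blank for the
#' root), `species_csv` (comma-separated species ids). Lines starting with
#' `#` are comments. Exactly one root is required and parent links must form
#' a tree.
#'
#' @param levels Named list of levels, each a list with fields `id`, `name`,
#'   `parent` (`NA` for root) and `species` (character vector).
#' @return A `level_hierarchy` object.
#' @export
level_hierarchy <- function(levels) {
  stopifnot(length(levels) >= 1L)
  ids <- vapply(levels, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate level id(s)")
  names(levels) <- ids
  parents <- vapply(levels, function(l) as.character(l$parent %||% NA_character_),
                    character(1))
  roots <- ids[is.na(parents)]
  if (length(roots) != 1L) {
    stop("hierarchy must have exactly one root level, found ", length(roots))
  }
  unknown <- parents[!is.na(parents) & !(parents %in% ids)]
  if (length(unknown)) stop("unknown parent level id(s): ",
                            paste(unique(unknown), collapse = ", "))
  # cycle check: walk each level to the root, bounded by the level count
  for (id in ids) {
    seen <- character(0)
    cur <- id
    while (!is.na(parents[[cur]])) {
      if (cur %in% seen) stop("cycle detected in level hierarchy at '", cur, "'")
      seen <- c(seen, cur)
      cur <- parents[[cur]]
      if (length(seen) > length(ids)) stop("cycle detected in level hierarchy")
    }
  }
  for (id in ids) {
    sp <- levels[[id]]$species
    if (!length(sp)) stop("level '", id, "' has an empty species set")
    if (anyDuplicated(sp)) stop("level '", id, "' lists duplicate species")
    p <- parents[[id]]
    if (!is.na(p)) {
      missing_sp <- setdiff(sp, levels[[p]]$species)
      if (length(missing_sp)) {
        stop("species-subset violation: level '", id, "' lists species not in ",
             "parent '", p, "': ", paste(missing_sp, collapse = ", "))
      }
    }
  }
  structure(list(levels = levels, root = roots), class = "level_hierarchy")
}

#' @export
print.level_hierarchy <- function(x, ...) {
  cat("Level hierarchy:", length(x$levels), "levels, root =", x$root, "\n")
  for (id in leafward_order(x)) {
    l <- x$levels[[id]]
    cat(sprintf("  %s (%d species)%s\n", id, length(l$species),
                if (is.na(l$parent %||% NA)) " [root]" else paste0(" < ", l$parent)))
  }
  invisible(x)
}

#' Load a taxonomic level hierarchy from a level table
#'
#' @param path Path to a tab-separated level table (see
#'   [level_hierarchy()] for the format).
#' @return A validated `level_hierarchy`.
#' @examples
#' tf <- tempfile()
#' writeLines(c("LUCA\t\tS1,S2,S3", "Bact\tLUCA\tS1,S2"), tf)
#' load_hierarchy(tf)
#' @export
load_hierarchy <- function(path) {
  tl <- read_tsv_lines(path)
  if (!length(tl$lines)) stop("empty level table: ", path)
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  levels <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 3L) {
      stop("line ", tl$numbers[i], ": expected 3 tab-separated fields")
    }
    list(id = p[1], name = p[1],
         parent = if (nzchar(trimws(p[2]))) trimws(p[2]) else NA_character_,
         species = trimws(strsplit(p[3], ",", fixed = TRUE)[[1]]))
  })
  level_hierarchy(levels)
}

#' Write a level hierarchy back to its table format
#'
#' @param h A `level_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  lines <- vapply(h$levels, function(l) {
    paste(l$id, ifelse(is.na(l$parent %||% NA_character_), "", l$parent),
          paste(l$species, collapse = ","), sep = "\t")
  }, character(1))
  write_tsv_lines(unname(lines), path)
}

#' Leaf-to-root processing order of taxonomic levels
#'
#' Returns level ids in the deterministic order used by the consistency scan:
#' every level appears before its parent (root-ward direction starting from
#' the leaves), with ties between available levels broken lexicographically
#' by level id.
#'
#' @param h A `level_hierarchy`.
#' @return Character vector of level ids, leaves first, root last.
#' @export
leafward_order <- function(h) {
  stopifnot(inherits(h, "level_hierarchy"))
  ids <- names(h$levels)
  parents <- vapply(h$levels, function(l) as.character(l$parent %||% NA_character_),
                    character(1))
  n_children <- table(factor(parents[!is.na(parents)], levels = ids))
  remaining <- stats::setNames(as.integer(n_children), ids)
  out <- character(0)
  avail <- sort(ids[remaining == 0L])
  while (length(avail)) {
    nxt <- avail[1L]
    out <- c(out, nxt)
    avail <- avail[-1L]
    p <- parents[[nxt]]
    if (!is.na(p)) {
      remaining[[p]] <- remaining[[p]] - 1L
      if (remaining[[p]] == 0L) avail <- sort(c(avail, p))
    }
  }
  if (length(out) != length(ids)) stop("cycle detected in level hierarchy")
  out
}

# children of a level, sorted; internal
level_children <- function(h, id) {
  kids <- names(h$levels)[vapply(h$levels, function(l) {
    identical(l$parent %||% NA_character_, id)
  }, logical(1))]
  sort(kids)
}

# all strict descendants of a level in leafward order; internal
level_descendants <- function(h, id) {
  out <- character(0)
  queue <- level_children(h, id)
  while (length(queue)) {
    out <- c(out, queue[1L])
    queue <- c(queue[-1L], level_children(h, queue[1L]))
  }
  ord <- leafward_order(h)
  ord[ord %in% out]
}
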