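#' OG hierarchy across taxonomic levels
#'
#' Bundles a `level_hierarchy` with one `og_set` per level. After
#' [enforce_consistency()] the sets are hierarchically consistent: every OG
#' at a non-root level has all of its members inside exactly one OG at the
#' parent level (members unclustered at the parent may be absent).
#'
#' @param hierarchy A `level_hierarchy`.
#' @param ogsets Named list of `og_set`, one per level id.
#' @return An `og_hierarchy`.
#' @export
og_hierarchy <- function(hierarchy, ogsets) {
  stopifnot(inherits(hierarchy, "level_hierarchy"))
  unknown <- setdiff(names(ogsets), names(hierarchy$levels))
  if (length(unknown)) stop("og sets for unknown level(s): ",
                            paste(unknown, collapse = ", "))
  structure(list(hierarchy = hierarchy, ogsets = ogsets),
            class = "og_hierarchy")
}

#' @export
print.og_hierarchy <- function(x, ...) {
  cat("OG hierarchy over", length(x$ogsets), "levels\n")
  for (id in leafward_order(x$hierarchy)) {
    if (!is.null(x$ogsets[[id]])) print(x$ogsets[[id]])
  }
  invisible(x)
}

#' Species overlap between two protein sets
#'
#' The species shared between the species sets of two groups of proteins;
#' a non-empty overlap between sibling partitions signals that their
#' separation reflects a duplication rather than an artefact.
#'
#' @param a,b Character vectors of protein ids (`"species.protein"`).
#' @return Character vector of shared species ids.
#' @export
species_overlap <- function(a, b) {
  intersect(unique(species_of(a)), unique(species_of(b)))
}

# order partitions "largest first": size desc, then species count desc,
# then lexicographically smallest member id asc
order_partitions <- function(parts) {
  sizes <- lengths(parts)
  nsp <- vapply(parts, function(m) length(unique(species_of(m))), integer(1))
  smallest <- vapply(parts, function(m) sort(m)[1L], character(1))
  parts[order(-sizes, -nsp, smallest)]
}

#' Find child OGs split across several parent OGs
#'
#' Scans a child level's OGs against the direct parent level: any child OG
#' whose members fall into two or more distinct parent OGs yields a split
#' record with the members partitioned by parent OG, ordered largest first.
#' Members unclustered at the parent are excluded from the partitions and
#' reported in the `"skipped"` attribute.
#'
#' @param child,parent `og_set`s at a child level and its direct parent.
#' @return List of split records: `child_og`, `partitions` (list of member
#'   vectors), `parent_ogs` (aligned parent OG ids).
#' @export
find_parental_splits <- function(child, parent) {
  parent_of <- stats::setNames(
    rep(names(parent$groups), lengths(parent$groups)),
    unlist(parent$groups, use.names = FALSE))
  records <- list()
  skipped <- character(0)
  for (og in sort(names(child$groups))) {
    members <- child$groups[[og]]
    pid <- parent_of[members]
    absent <- members[is.na(pid)]
    if (length(absent)) skipped <- c(skipped, absent)
    members <- members[!is.na(pid)]
    pid <- pid[!is.na(pid)]
    if (length(unique(pid)) < 2L) next
    parts <- split(members, pid)
    ord_parts <- order_partitions(parts)
    # realign parent ids with the ordered partitions
    pmap <- stats::setNames(names(parts),
                            vapply(parts, function(m) sort(m)[1L], character(1)))
    records[[length(records) + 1L]] <- list(
      child_og = og,
      partitions = unname(ord_parts),
      parent_ogs = unname(pmap[vapply(ord_parts, function(m) sort(m)[1L],
                                      character(1))]))
  }
  attr(records, "skipped") <- unique(skipped)
  records
}

# replace one OG's membership inside an og_set, keeping ids of others;
# new groups get temporary ids, canonical ids are reassigned at the end of
# enforcement
set_replace_group <- function(ogset, og_id, new_members_list) {
  groups <- ogset$groups
  so <- ogset$seed_origin
  origin <- so[[og_id]]
  groups[[og_id]] <- NULL
  k <- 0L
  for (m in new_members_list) {
    if (!length(m)) next
    k <- k + 1L
    nid <- paste0(og_id, ":", k)
    groups[[nid]] <- sort(m)
    if (!is.null(origin)) so[[nid]] <- origin
  }
  so[[og_id]] <- NULL
  og_set(ogset$level, groups, unclustered = ogset$unclustered, seed_origin = so)
}

# merge two OGs at a level into one (id = lexicographically smaller id)
set_merge_groups <- function(ogset, id_a, id_b) {
  groups <- ogset$groups
  so <- ogset$seed_origin
  keep <- min(id_a, id_b); drop <- max(id_a, id_b)
  groups[[keep]] <- sort(c(groups[[keep]], groups[[drop]]))
  groups[[drop]] <- NULL
  org <- unique(c(so[[id_a]], so[[id_b]]))
  so[[drop]] <- NULL
  if (length(org)) so[[keep]] <- org
  og_set(ogset$level, groups, unclustered = ogset$unclustered, seed_origin = so)
}

# separate members `sep` from any OG (at `level_id` and below) that holds
# them together with members of `against`; the separated members form their
# own OG at each affected level
separate_downstream <- function(oh, level_id, sep, against) {
  levels <- c(level_id, level_descendants(oh$hierarchy, level_id))
  for (lv in levels) {
    os <- oh$ogsets[[lv]]
    if (is.null(os)) next
    for (og in names(os$groups)) {
      m <- os$groups[[og]]
      s_in <- intersect(m, sep)
      l_in <- intersect(m, against)
      if (length(s_in) && length(l_in)) {
        os <- set_replace_group(os, og, list(setdiff(m, s_in), s_in))
      }
    }
    oh$ogsets[[lv]] <- os
  }
  oh
}

#' Resolve one parental split record
#'
#' Partitions are examined in sequence from largest to smallest (first
#' against second, then the winner against the third, and so on). For a pair
#' with empty species overlap, the two parent OGs are merged at the parental
#' level (the split is judged artefactual). For a pair with non-empty
#' overlap, the smaller partition's proteins are separated from the larger
#' partition's proteins at the child level and at every level below where
#' they still co-occur, forming their own OG at each affected level (the
#' split is judged a real duplication). "Smaller" ties are broken by species
#' count, then by lexicographically smallest member id.
#'
#' @param rec A split record from [find_parental_splits()].
#' @param oh An `og_hierarchy`.
#' @param child_level Level id the record was found at.
#' @return List with the updated `og_hierarchy` (`$oh`) and a data.frame of
#'   resolutions (`$report`).
#' @export
resolve_split <- function(rec, oh, child_level) {
  parent_level <- oh$hierarchy$levels[[child_level]]$parent
  stopifnot(!is.na(parent_level))
  cur <- rec$partitions[[1L]]
  cur_parent <- rec$parent_ogs[[1L]]
  rows <- list()
  for (k in seq_along(rec$partitions)[-1L]) {
    other <- rec$partitions[[k]]
    other_parent <- rec$parent_ogs[[k]]
    sz_pair <- paste(length(cur), length(other), sep = ",")
    ov <- species_overlap(cur, other)
    if (!length(ov)) {
      oh$ogsets[[parent_level]] <-
        set_merge_groups(oh$ogsets[[parent_level]], cur_parent, other_parent)
      cur_parent <- min(cur_parent, other_parent)
      cur <- sort(c(cur, other))
      resolution <- "merged"
    } else {
      ordered <- order_partitions(list(cur, other))
      larger <- ordered[[1L]]; smaller <- ordered[[2L]]
      oh <- separate_downstream(oh, child_level, smaller, larger)
      if (identical(larger, other)) cur_parent <- other_parent
      cur <- larger
      resolution <- "separated"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      child_level = child_level, child_og = rec$child_og,
      resolution = resolution,
      partition_sizes = sz_pair,
      species_overlap_size = length(ov), stringsAsFactors = FALSE)
  }
  list(oh = oh, report = do.call(rbind, rows))
}

#' Enforce hierarchical consistency of nested OGs
#'
#' Post-clustering reconciliation: levels are scanned in root-ward direction
#' starting from the leaves ([leafward_order()]); at each level, child OGs
#' split across several parent OGs are detected and resolved one at a time
#' (merging artefactual splits at the parent, separating real duplications
#' downstream), re-scanning until no records remain. Because resolutions can
#' touch levels already scanned, the full scan is repeated until a global
#' fixed point is reached. A termination guard bounds the iterations by the
#' total protein count.
#'
#' @param oh An `og_hierarchy` with independently computed per-level OG sets.
#' @return The consistent `og_hierarchy`, with canonical OG ids reassigned
#'   and the resolution report in the `"report"` attribute.
#' @export
enforce_consistency <- function(oh) {
  stopifnot(inherits(oh, "og_hierarchy"))
  ord <- leafward_order(oh$hierarchy)
  n_prot <- length(unique(unlist(lapply(oh$ogsets, function(s) {
    c(unlist(s$groups, use.names = FALSE), s$unclustered)
  }))))
  guard <- max(10L, 2L * n_prot)
  report <- list()
  pass <- 0L
  repeat {
    pass <- pass + 1L
    if (pass > guard) stop("consistency enforcement did not terminate (guard ",
                           guard, " passes exceeded)")
    changed <- FALSE
    for (lv in ord) {
      parent_level <- oh$hierarchy$levels[[lv]]$parent
      if (is.na(parent_level)) next
      if (is.null(oh$ogsets[[lv]]) || is.null(oh$ogsets[[parent_level]])) next
      iter <- 0L
      repeat {
        recs <- find_parental_splits(oh$ogsets[[lv]], oh$ogsets[[parent_level]])
        if (!length(recs)) break
        iter <- iter + 1L
        if (iter > guard) {
          stop("consistency enforcement did not terminate at level '", lv, "'")
        }
        res <- resolve_split(recs[[1L]], oh, lv)
        oh <- res$oh
        report[[length(report) + 1L]] <- res$report
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # canonical ids
  for (lv in names(oh$ogsets)) {
    os <- oh$ogsets[[lv]]
    ids <- assign_og_ids(lv, os$groups, os$seed_origin)
    oh$ogsets[[lv]] <- og_set(lv, ids$groups, unclustered = os$unclustered,
                              seed_origin = ids$seed_origin)
  }
  attr(oh, "report") <- if (length(report)) do.call(rbind, report) else
    data.frame(child_level = character(0), child_og = character(0),
               resolution = character(0), partition_sizes = character(0),
               species_overlap_size = integer(0), stringsAsFactors = FALSE)
  oh
}

#' List nesting violations in an OG hierarchy
#'
#' @param oh An `og_hierarchy`.
#' @return Data.frame of violations (`level`, `og`, `n_parent_ogs`); zero
#'   rows when the hierarchy is consistent.
#' @export
nesting_violations <- function(oh) {
  rows <- list()
  for (lv in leafward_order(oh$hierarchy)) {
    parent_level <- oh$hierarchy$levels[[lv]]$parent
    if (is.na(parent_level)) next
    child <- oh$ogsets[[lv]]; parent <- oh$ogsets[[parent_level]]
    if (is.null(child) || is.null(parent)) next
    parent_of <- stats::setNames(
      rep(names(parent$groups), lengths(parent$groups)),
      unlist(parent$groups, use.names = FALSE))
    for (og in names(child$groups)) {
      pid <- unique(stats::na.omit(parent_of[child$groups[[og]]]))
      if (length(pid) > 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          level = lv, og = og, n_parent_ogs = length(pid),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(level = character(0), og = character(0),
               n_parent_ogs = integer(0), stringsAsFactors = FALSE)
}

#' Is an OG hierarchy hierarchically consistent?
#'
#' @param oh An `og_hierarchy`.
#' @return `TRUE` when every OG at every non-root level maps into a single
#'   parent OG.
#' @export
is_consistent <- function(oh) {
  nrow(nesting_violations(oh)) == 0L
}
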