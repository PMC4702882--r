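#' Orthologous group sets
#'
#' An `og_set` is the clustering result at one taxonomic level: a set of
#' pairwise-disjoint orthologous groups (OGs), plus the proteins of the level
#' that remained unclustered. OG identifiers are deterministic: groups are
#' ordered by their lexicographically smallest member id and numbered with a
#' compact base-36 counter prefixed by the level id (e.g. `mam@0003`).
#'
#' @param level Level id.
#' @param groups List of character vectors (member protein ids).
#' @param unclustered Character vector of unclustered protein ids.
#' @param seed_origin Named list mapping og id -> character vector of seed
#'   cluster ids the group was conserved from.
#' @return An `og_set`.
#' @export
og_set <- function(level, groups, unclustered = character(0), seed_origin = list()) {
  groups <- lapply(groups, function(m) sort(unique(m)))
  groups <- groups[lengths(groups) > 0L]
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("OGs at level '", level, "' are not pairwise disjoint")
  }
  structure(list(level = level, groups = groups,
                 unclustered = sort(unique(unclustered)),
                 seed_origin = seed_origin),
            class = "og_set")
}

#' @export
print.og_set <- function(x, ...) {
  cat(sprintf("OG set at level %s: %d groups (%d proteins), %d unclustered\n",
              x$level, length(x$groups),
              length(unlist(x$groups, use.names = FALSE)),
              length(x$unclustered)))
  invisible(x)
}

# deterministic OG ids: order groups by smallest member id, base-36 counter
assign_og_ids <- function(level, groups, seed_origin = list()) {
  if (!length(groups)) return(list(groups = list(), seed_origin = list()))
  smallest <- vapply(groups, function(m) sort(m)[1L], character(1))
  ord <- order(smallest)
  groups <- groups[ord]
  ids <- paste0(level, "@", to_base36(seq_along(groups)))
  old_names <- names(groups)
  names(groups) <- ids
  so <- list()
  if (length(seed_origin) && !is.null(old_names)) {
    for (i in seq_along(groups)) {
      if (!is.null(old_names[i]) && !is.na(old_names[i]) &&
          old_names[i] %in% names(seed_origin)) {
        so[[ids[i]]] <- seed_origin[[old_names[i]]]
      }
    }
  }
  list(groups = groups, seed_origin = so)
}

#' Collapse same-species in-paralogs into units
#'
#' Two proteins of the same species are linked as in-paralogs when their
#' mutual score is at least as high as either protein's best score to any
#' protein of another species in the graph (`score(a,b) >=
#' max(bestout(a), bestout(b))`, with `bestout = 0` when a protein has no
#' cross-species hit). In-paralog units are the connected components of these
#' links; every protein of the level belongs to exactly one unit, possibly a
#' singleton.
#'
#' @param g A `hit_graph` restricted to the level.
#' @return Named list of units (character vectors of members, all of one
#'   species); names are deterministic unit ids.
#' @export
detect_inparalogs <- function(g) {
  nodes <- g$nodes
  if (!length(nodes)) return(stats::setNames(list(), character(0)))
  sp <- g$species
  e <- g$edges
  cross <- sp[e$a] != sp[e$b]
  # best out-of-species score per protein
  bestout <- stats::setNames(numeric(length(nodes)), nodes)
  if (any(cross)) {
    ce <- e[cross, , drop = FALSE]
    for (side in c("a", "b")) {
      agg <- tapply(ce$weight, ce[[side]], max)
      bestout[names(agg)] <- pmax(bestout[names(agg)], agg)
    }
  }
  same <- e[!cross, , drop = FALSE]
  linked <- same[same$weight >= pmax(bestout[same$a], bestout[same$b]), ,
                 drop = FALSE]
  gr <- igraph::graph_from_data_frame(linked[, c("a", "b")], directed = FALSE,
                                      vertices = data.frame(name = nodes))
  comp <- igraph::components(gr)$membership
  units <- split(names(comp), comp)
  units <- lapply(units, function(m) sort(m))
  smallest <- vapply(units, `[`, character(1), 1L)
  units <- units[order(smallest)]
  names(units) <- paste0("u", seq_along(units))
  units
}

#' Bidirectional best hits between in-paralog units
#'
#' The score between two units is the maximum member-pair score. A pair of
#' units of different species is emitted when each is the other's
#' best-scoring unit within the partner's species; units tied for best are
#' all kept.
#'
#' @param units Named list of in-paralog units (see [detect_inparalogs()]).
#' @param g The `hit_graph` the units were derived from.
#' @return Data.frame with columns `u`, `v` (unit ids, `u < v`) and `weight`.
#' @export
unit_best_hits <- function(units, g) {
  empty <- data.frame(u = character(0), v = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(units) < 2L) return(empty)
  unit_of <- stats::setNames(rep(names(units), lengths(units)),
                             unlist(units, use.names = FALSE))
  unit_sp <- vapply(units, function(m) species_of(m[1L]), character(1))
  e <- g$edges
  ua <- unit_of[e$a]; ub <- unit_of[e$b]
  keep <- !is.na(ua) & !is.na(ub) & ua != ub & unit_sp[ua] != unit_sp[ub]
  if (!any(keep)) return(empty)
  ua <- ua[keep]; ub <- ub[keep]; w <- e$weight[keep]
  p <- pmin(ua, ub); q <- pmax(ua, ub)
  key <- paste(p, q, sep = "\r")
  uw <- tapply(w, key, max)
  pq <- strsplit(names(uw), "\r", fixed = TRUE)
  pu <- vapply(pq, `[`, character(1), 1L)
  qu <- vapply(pq, `[`, character(1), 2L)
  uw <- as.numeric(uw)
  # best score per (unit, partner species); ties keep all best partners
  key2 <- paste(c(pu, qu), unit_sp[c(qu, pu)], sep = "\r")
  bb_t <- tapply(c(uw, uw), key2, max)
  bb <- stats::setNames(as.numeric(bb_t), names(bb_t))
  mutual <- uw == bb[paste(pu, unit_sp[qu], sep = "\r")] &
            uw == bb[paste(qu, unit_sp[pu], sep = "\r")]
  out <- data.frame(u = pu[mutual], v = qu[mutual], weight = uw[mutual],
                    stringsAsFactors = FALSE)
  out[order(out$u, out$v), , drop = FALSE]
}

#' Merge best-hit triangles into orthologous groups
#'
#' Triangles of bidirectional best-hit edges spanning three distinct species
#' are the seeds of orthologous groups; triangles sharing an edge are merged
#' iteratively. Best-hit edges that belong to no triangle still join units of
#' different species: a pair of otherwise unclustered units forms a two-unit
#' OG, and a unit hanging off an existing group joins that group (processed
#' in decreasing weight order). Units with no retained edge stay unclustered.
#'
#' @param bbh Data.frame of unit best-hit edges (see [unit_best_hits()]).
#' @param units Named list of units.
#' @param level Level id used for OG identifiers.
#' @return An `og_set`.
#' @export
triangle_merge <- function(bbh, units, level) {
  unit_sp <- vapply(units, function(m) species_of(m[1L]), character(1))
  cluster_of <- stats::setNames(rep(NA_integer_, length(units)), names(units))
  n_clusters <- 0L
  if (nrow(bbh)) {
    adj <- split(c(bbh$v, bbh$u), c(bbh$u, bbh$v))
    in_triangle <- logical(nrow(bbh))
    for (i in seq_len(nrow(bbh))) {
      u <- bbh$u[i]; v <- bbh$v[i]
      common <- intersect(adj[[u]], adj[[v]])
      in_triangle[i] <- any(!(unit_sp[common] %in% unit_sp[c(u, v)]))
    }
    tri <- bbh[in_triangle, , drop = FALSE]
    if (nrow(tri)) {
      gr <- igraph::graph_from_data_frame(tri[, c("u", "v")], directed = FALSE,
                                          vertices = data.frame(name = names(units)))
      comp <- igraph::components(gr)$membership
      clustered <- names(comp)[comp %in% comp[unique(c(tri$u, tri$v))]]
      for (cid in unique(comp[clustered])) {
        n_clusters <- n_clusters + 1L
        cluster_of[names(comp)[comp == cid & names(comp) %in% clustered]] <- n_clusters
      }
    }
    rest <- bbh[!in_triangle, , drop = FALSE]
    if (nrow(rest)) {
      rest <- rest[order(-rest$weight, rest$u, rest$v), , drop = FALSE]
      for (i in seq_len(nrow(rest))) {
        u <- rest$u[i]; v <- rest$v[i]
        cu <- cluster_of[[u]]; cv <- cluster_of[[v]]
        if (is.na(cu) && is.na(cv)) {
          n_clusters <- n_clusters + 1L
          cluster_of[c(u, v)] <- n_clusters
        } else if (is.na(cu)) {
          cluster_of[[u]] <- cv
        } else if (is.na(cv)) {
          cluster_of[[v]] <- cu
        } # both already clustered: leave as-is
      }
    }
  }
  groups <- list()
  for (cid in unique(cluster_of[!is.na(cluster_of)])) {
    members <- unlist(units[names(cluster_of)[!is.na(cluster_of) &
                                              cluster_of == cid]],
                      use.names = FALSE)
    groups[[length(groups) + 1L]] <- sort(members)
  }
  unclustered <- unlist(units[is.na(cluster_of)], use.names = FALSE)
  ids <- assign_og_ids(level, groups)
  og_set(level, ids$groups, unclustered = unclustered)
}

#' Conserve and extend seed clusters
#'
#' Seed clusters (e.g. manually curated groups for a level) are conserved:
#' the co-membership of a seed is never broken. Every computed OG that
#' intersects a seed is unioned with all other OGs intersecting that seed and
#' with the seed itself; the seed of origin is recorded on the resulting OG.
#' Seed members unknown at the level are ignored with a warning, and two
#' seeds forced into one OG are merged with a warning, recording both
#' origins.
#'
#' @param ogset An `og_set`.
#' @param seeds Named list of seed clusters (character vectors of members).
#' @return The extended `og_set`.
#' @export
extend_seeds <- function(ogset, seeds) {
  if (!length(seeds)) return(ogset)
  if (is.null(names(seeds)) || any(!nzchar(names(seeds)))) {
    stop("seeds must be a named list")
  }
  level_proteins <- c(unlist(ogset$groups, use.names = FALSE), ogset$unclustered)
  seeds <- lapply(seeds, function(m) {
    unknown <- setdiff(m, level_proteins)
    if (length(unknown)) {
      warning("seed member(s) unknown at level '", ogset$level, "' ignored: ",
              paste(utils::head(unknown, 5L), collapse = ", "))
    }
    intersect(m, level_proteins)
  })
  seeds <- seeds[lengths(seeds) > 0L]
  if (!length(seeds)) return(ogset)
  # union-find over computed groups (+ pseudo-groups for unclustered members)
  pool <- c(ogset$groups, lapply(ogset$unclustered, identity))
  origin <- vector("list", length(pool))
  parent <- seq_along(pool)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (sid in sort(names(seeds))) {
    touching <- which(vapply(seq_along(pool), function(i) {
      length(intersect(pool[[i]], seeds[[sid]])) > 0L
    }, logical(1)))
    roots <- unique(vapply(touching, find, integer(1)))
    tgt <- roots[1L]
    parent[roots] <- tgt
    prior <- unique(unlist(origin[roots]))
    if (length(prior)) {
      warning("seed '", sid, "' forces a merge with seed(s) ",
              paste(prior, collapse = ", "), " at level '", ogset$level, "'")
    }
    origin[[tgt]] <- unique(c(prior, sid))
  }
  root_of <- vapply(seq_along(pool), find, integer(1))
  merged <- lapply(split(seq_along(pool), root_of),
                   function(ix) sort(unique(unlist(pool[ix]))))
  merged_origin <- lapply(split(seq_along(pool), root_of), function(ix) {
    unique(unlist(origin[ix]))
  })
  seeded <- vapply(merged_origin, function(o) length(o) > 0L, logical(1))
  # unclustered singletons not touched by any seed stay unclustered
  was_single <- vapply(split(seq_along(pool), root_of), function(ix) {
    length(ix) == 1L && ix > length(ogset$groups)
  }, logical(1))
  keep_group <- !was_single | seeded
  groups <- merged[keep_group]
  so_raw <- merged_origin[keep_group]
  names(groups) <- paste0("tmp", seq_along(groups))
  so <- stats::setNames(so_raw, names(groups))
  so <- so[vapply(so, length, integer(1)) > 0L]
  ids <- assign_og_ids(ogset$level, groups, so)
  og_set(ogset$level, ids$groups,
         unclustered = unlist(merged[!keep_group], use.names = FALSE),
         seed_origin = ids$seed_origin)
}

#' Build orthologous groups at one taxonomic level
#'
#' Orchestrates the per-level clustering: restrict the similarity graph to
#' the level's species, collapse in-paralogs into units, find bidirectional
#' best hits between units, merge best-hit triangles into OGs and finally
#' conserve/extend any seed clusters. Deterministic for fixed input.
#'
#' @param g A `hit_graph` (full graph; restricted internally).
#' @param level A level entry of a `level_hierarchy` (list with `id` and
#'   `species`).
#' @param seeds Optional named list of seed clusters.
#' @return An `og_set` for the level.
#' @examples
#' hits <- data.frame(query = c("S1.a", "S1.a", "S2.b"),
#'                    subject = c("S2.b", "S3.c", "S3.c"),
#'                    bitscore = c(200, 180, 190))
#' g <- symmetrize(filter_hits(hits))
#' build_ogs(g, list(id = "root", species = c("S1", "S2", "S3")))
#' @export
build_ogs <- function(g, level, seeds = NULL) {
  gl <- restrict_to_level(g, level)
  units <- detect_inparalogs(gl)
  bbh <- unit_best_hits(units, gl)
  ogs <- triangle_merge(bbh, units, level$id)
  if (length(seeds)) ogs <- extend_seeds(ogs, seeds)
  ogs
}
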