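# Independent brute-force oracles and tiny fixture builders shared by the
# unit and acceptance tests. Everything here is deliberately written with a
# different algorithmic route than the package implementation.

# --- graph fixtures ---------------------------------------------------------

# build a hit_graph directly from a weight table (a, b, w); undirected input
graph_from_edges <- function(a, b, w) {
  symmetrize(data.frame(query = a, subject = b, bitscore = w,
                        stringsAsFactors = FALSE))
}

random_hit_graph <- function(n_prot, n_species) {
  sp <- sample(paste0("S", seq_len(n_species)), n_prot, replace = TRUE)
  ids <- paste0(sp, ".p", seq_len(n_prot))
  pairs <- utils::combn(n_prot, 2L)
  keep <- stats::runif(ncol(pairs)) < 0.5
  pairs <- pairs[, keep, drop = FALSE]
  if (!ncol(pairs)) return(graph_from_edges(character(0), character(0), numeric(0)))
  graph_from_edges(ids[pairs[1L, ]], ids[pairs[2L, ]],
                   round(stats::runif(ncol(pairs), 51, 500), 1))
}

# brute-force in-paralog partition: evaluate the linking predicate on every
# same-species pair by direct scans, then merge sets naively
oracle_inparalogs <- function(g) {
  nodes <- g$nodes
  e <- g$edges
  sp <- g$species
  wt <- function(x, y) {
    hit <- (e$a == x & e$b == y) | (e$a == y & e$b == x)
    if (any(hit)) e$weight[hit][1L] else NA_real_
  }
  bestout <- function(x) {
    other <- nodes[sp[nodes] != sp[x]]
    ws <- vapply(other, function(y) wt(x, y), numeric(1))
    ws <- ws[!is.na(ws)]
    if (length(ws)) max(ws) else 0
  }
  sets <- as.list(nodes)
  find_set <- function(x) which(vapply(sets, function(s) x %in% s, logical(1)))
  for (x in nodes) {
    for (y in nodes) {
      if (x >= y || sp[x] != sp[y]) next
      w <- wt(x, y)
      if (is.na(w)) next
      if (w >= max(bestout(x), bestout(y))) {
        i <- find_set(x); j <- find_set(y)
        if (i != j) {
          sets[[i]] <- c(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
        }
      }
    }
  }
  unname(lapply(sets, sort))
}

same_partition <- function(p1, p2) {
  k1 <- sort(vapply(p1, function(m) paste(sort(m), collapse = ","), character(1)))
  k2 <- sort(vapply(p2, function(m) paste(sort(m), collapse = ","), character(1)))
  identical(k1, k2)
}

# --- gene-tree enumeration and the species-overlap oracle -------------------

# all rooted binary tree shapes with n leaves, as nested lists ("L" = leaf)
tree_shapes <- local({
  memo <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (n == 1L) list("L") else {
      acc <- list()
      for (k in seq_len(n %/% 2L)) {
        left <- tree_shapes(k); right <- tree_shapes(n - k)
        for (i in seq_along(left)) {
          jstart <- if (k == n - k) i else 1L
          for (j in jstart:length(right)) {
            acc[[length(acc) + 1L]] <- list(left[[i]], right[[j]])
          }
        }
      }
      acc
    }
    memo[[key]] <<- out
    out
  }
})

count_leaves <- function(shape) {
  if (identical(shape, "L")) 1L else
    count_leaves(shape[[1]]) + count_leaves(shape[[2]])
}

# attach species labels (an integer vector, one per leaf in left-to-right
# order) and unique protein names; returns newick plus the oracle labels
labeled_tree_newick <- function(shape, species_idx) {
  counter <- 0L
  build <- function(s) {
    if (identical(s, "L")) {
      counter <<- counter + 1L
      return(paste0("S", species_idx[counter], ".g", counter))
    }
    paste0("(", build(s[[1]]), ",", build(s[[2]]), ")")
  }
  paste0(build(shape), ";")
}

# naive recursive oracle: map clade (sorted leaf names) -> event
oracle_events <- function(shape, species_idx) {
  counter <- 0L
  out <- list()
  recurse <- function(s) {
    if (identical(s, "L")) {
      counter <<- counter + 1L
      return(list(leaves = paste0("S", species_idx[counter], ".g", counter),
                  species = paste0("S", species_idx[counter])))
    }
    l <- recurse(s[[1]]); r <- recurse(s[[2]])
    ev <- if (length(intersect(l$species, r$species))) "duplication" else "speciation"
    leaves <- sort(c(l$leaves, r$leaves))
    out[[paste(leaves, collapse = ",")]] <<- ev
    list(leaves = leaves, species = union(l$species, r$species))
  }
  recurse(shape)
  out
}

# clade -> event map from a labeled gene_tree (implementation side)
impl_event_map <- function(gt) {
  tr <- gt$tree
  ntip <- length(tr$tip.label)
  edge <- tr$edge[ape::postorder(tr), , drop = FALSE]
  sets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tr$tip.label[i]
  out <- list()
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1L]; c <- edge[r, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  for (node in (ntip + 1L):(ntip + tr$Nnode)) {
    out[[paste(sort(sets[[node]]), collapse = ",")]] <- gt$events[node - ntip]
  }
  out
}

# --- annotation propagation oracle ------------------------------------------

# brute-force nearest annotated ancestor search by member containment
oracle_inherited_count <- function(oh, annos) {
  ord <- leafward_order(oh$hierarchy)
  count <- 0L
  for (lv in ord) {
    os <- oh$ogsets[[lv]]
    if (is.null(os)) next
    for (og in names(os$groups)) {
      a <- annos[[og]]
      if (!is.null(a) && nzchar(a$description)) next
      members <- os$groups[[og]]
      cur <- lv
      found <- FALSE
      repeat {
        cur <- oh$hierarchy$levels[[cur]]$parent
        if (is.na(cur) || is.null(oh$ogsets[[cur]])) break
        anc_sets <- oh$ogsets[[cur]]$groups
        hit <- names(anc_sets)[vapply(anc_sets, function(m) {
          length(intersect(m, members)) > 0L
        }, logical(1))]
        if (length(hit) == 1L) {
          pa <- annos[[hit]]
          if (!is.null(pa) && nzchar(pa$description)) { found <- TRUE; break }
        } else if (length(hit) > 1L) break
      }
      if (found) count <- count + 1L
    }
  }
  count
}

# --- misc -------------------------------------------------------------------

build_all_levels <- function(ds) {
  g <- symmetrize(filter_hits(ds$hits))
  ogsets <- list()
  for (lv in leafward_order(ds$tax$hierarchy)) {
    ogsets[[lv]] <- build_ogs(g, ds$tax$hierarchy$levels[[lv]])
  }
  og_hierarchy(ds$tax$hierarchy, ogsets)
}

og_membership_key <- function(os) {
  sort(unname(vapply(os$groups, function(m) paste(sort(m), collapse = ","),
                     character(1))))
}
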