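#' Simulation configuration
#'
#' Conditions for the synthetic study system: a random species taxonomy,
#' gene families evolved by birth-death along the species tree, and noisy
#' bit-scores derived from gene-tree distances.
#'
#' @param n_species Number of species (>= 2).
#' @param n_levels Number of taxonomic levels (>= 1; root always included).
#' @param n_families Gene families per simulated dataset.
#' @param dup_rate Expected duplications per gene lineage per species-tree
#'   branch (Poisson rate; a lineage duplicates with probability
#'   `1 - exp(-dup_rate)` on each branch).
#' @param loss_rate Expected losses per lineage per branch (probability
#'   `1 - exp(-loss_rate)`).
#' @param score_base Bit-score of two identical sequences (zero divergence),
#'   in bits; must exceed the storage threshold.
#' @param decay Bits lost per unit of gene-tree distance.
#' @param noise_sd Standard deviation of the Gaussian score noise, in bits.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 10L, n_levels = 4L, n_families = 3L,
                       dup_rate = 0.1, loss_rate = 0.05,
                       score_base = 500, decay = 10, noise_sd = 5) {
  stopifnot(n_species >= 2L, n_levels >= 1L, n_families >= 1L,
            dup_rate >= 0, loss_rate >= 0, score_base > 50,
            decay >= 0, noise_sd >= 0)
  structure(list(n_species = as.integer(n_species),
                 n_levels = as.integer(n_levels),
                 n_families = as.integer(n_families),
                 dup_rate = dup_rate, loss_rate = loss_rate,
                 score_base = score_base, decay = decay,
                 noise_sd = noise_sd),
            class = "sim_config")
}

# tips below a species-tree node
sp_subtree_tips <- function(st, node) {
  if (node <= st$n_tips) return(node)
  unlist(lapply(st$children[[node]], sp_subtree_tips, st = st))
}

#' Simulate a species taxonomy with nested levels
#'
#' Generates a random rooted species tree by Kingman-coalescent topology
#' (two uniformly chosen lineages coalesce per step) with unit-spaced,
#' integer coalescence heights, so the tree is ultrametric and leaf-to-leaf
#' distances are exact integers. `n_levels` internal nodes are designated as
#' taxonomic levels (the root always among them); each level's species set
#' is its subtree's leaves, so the subset invariant holds by construction.
#'
#' @param cfg A `sim_config`.
#' @param seed Optional integer seed (local to this call).
#' @return A `sim_taxonomy`: list with `hierarchy` (a `level_hierarchy`),
#'   `sptree` and `level_nodes` (named map level id -> species-tree node).
#' @export
simulate_taxonomy <- function(cfg, seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, simulate_taxonomy(cfg)))
  n <- cfg$n_species
  if (cfg$n_levels > n - 1L) {
    stop("n_levels (", cfg$n_levels, ") exceeds internal node count (",
         n - 1L, ")")
  }
  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  children <- vector("list", n_nodes)
  height <- c(rep(0, n), seq_len(n - 1L))
  active <- seq_len(n)
  for (k in seq_len(n - 1L)) {
    pick <- sort(sample(seq_along(active), 2L))
    m <- n + k
    children[[m]] <- active[pick]
    parent[active[pick]] <- m
    active <- c(active[-pick], m)
  }
  st <- list(n_tips = n, parent = parent, children = children,
             height = height, tip_species = paste0("S", seq_len(n)))
  class(st) <- "species_tree"
  root <- n_nodes
  internals <- setdiff((n + 1L):n_nodes, root)
  extra <- if (cfg$n_levels > 1L) {
    sort(sample(internals, cfg$n_levels - 1L))
  } else integer(0)
  level_nodes <- c(root, extra)
  level_ids <- stats::setNames(paste0("lv", level_nodes), level_nodes)
  levels <- lapply(level_nodes, function(v) {
    # nearest designated ancestor
    p <- parent[v]
    while (!is.na(p) && !(p %in% level_nodes)) p <- parent[p]
    list(id = level_ids[[as.character(v)]],
         name = level_ids[[as.character(v)]],
         parent = if (is.na(p)) NA_character_ else level_ids[[as.character(p)]],
         species = st$tip_species[sort(sp_subtree_tips(st, v))])
  })
  structure(list(hierarchy = level_hierarchy(levels), sptree = st,
                 level_nodes = stats::setNames(level_nodes,
                                               paste0("lv", level_nodes))),
            class = "sim_taxonomy")
}

#' Simulate one gene family with known duplication/loss history
#'
#' A single ancestral gene starts at the species-tree root. Along each
#' species-tree branch, each gene lineage duplicates with probability
#' `1 - exp(-dup_rate)` (the duplication node is placed at the top of the
#' branch) and each resulting lineage is lost with probability
#' `1 - exp(-loss_rate)`. Surviving lineages speciate at internal nodes and
#' become extant genes at the tips. The true gene tree (with duplication/
#' speciation labels) and the ground-truth OG partition at every taxonomic
#' level (extant genes grouped by their ancestral gene copy at the level's
#' root node) are recorded. A family with fewer than two extant genes is
#' resampled, up to `max_retry` times.
#'
#' @param tax A `sim_taxonomy`.
#' @param cfg A `sim_config`.
#' @param family_id Token used in gene identifiers
#'   (`"<species>.<family_id>g<k>"`).
#' @param seed Optional integer seed (local to this call).
#' @param max_retry Resampling bound for (near-)extinct families.
#' @param root_dup Force one duplication of the ancestral gene at the root
#'   (before any speciation); useful for hand-traceable ground truth.
#' @return A `true_family`: `tree` (a labeled `gene_tree`), `leaves`,
#'   `truth` (named list: level id -> list of member vectors), plus the
#'   internal event table.
#' @export
simulate_family <- function(tax, cfg, family_id = "f1", seed = NULL,
                            max_retry = 100L, root_dup = FALSE) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_family(tax, cfg, family_id,
                                                  max_retry = max_retry,
                                                  root_dup = root_dup)))
  }
  st <- tax$sptree
  p_dup <- 1 - exp(-cfg$dup_rate)
  p_loss <- 1 - exp(-cfg$loss_rate)
  for (attempt in seq_len(max_retry)) {
    fam <- sim_family_once(st, p_dup, p_loss, family_id, root_dup)
    if (length(fam$leaf_nodes) >= 2L) {
      return(finish_family(fam, tax, family_id))
    }
  }
  stop("family extinct in ", max_retry, " attempts (loss rate too high?)")
}

# one birth-death realization along the species tree; returns the raw gene
# node table (type/height/parent/label) and per-species-node copy lists
sim_family_once <- function(st, p_dup, p_loss, family_id, root_dup = FALSE) {
  type <- character(0); height <- numeric(0)
  parent <- integer(0); label <- character(0)
  copy_at <- vector("list", length(st$height))
  new_node <- function(ty, h, pa, lb = NA_character_) {
    type <<- c(type, ty); height <<- c(height, h)
    parent <<- c(parent, pa); label <<- c(label, lb)
    length(type)
  }
  sp_counter <- stats::setNames(rep(0L, st$n_tips), st$tip_species)
  root <- length(st$height)
  if (root_dup) {
    g0 <- new_node("duplication", st$height[root], NA_integer_)
    c1 <- new_node("speciation", st$height[root], g0)
    c2 <- new_node("speciation", st$height[root], g0)
    copy_at[[root]] <- c(c1, c2)
  } else {
    g0 <- new_node("speciation", st$height[root], NA_integer_)
    copy_at[[root]] <- g0
  }
  walk <- function(v) {
    for (ch in st$children[[v]]) {
      for (x in copy_at[[v]]) {
        sources <- if (stats::runif(1) < p_dup) {
          d <- new_node("duplication", st$height[v], x)
          c(d, d)
        } else x
        for (src in sources) {
          if (stats::runif(1) < p_loss) next
          if (ch <= st$n_tips) {
            sp <- st$tip_species[ch]
            sp_counter[sp] <<- sp_counter[sp] + 1L
            lb <- paste0(sp, ".", family_id, "g", sp_counter[sp])
            arr <- new_node("leaf", 0, src, lb)
          } else {
            arr <- new_node("speciation", st$height[ch], src)
          }
          copy_at[[ch]] <<- c(copy_at[[ch]], arr)
        }
      }
      if (ch > st$n_tips) walk(ch)
    }
  }
  walk(root)
  list(type = type, height = height, parent = parent, label = label,
       copy_at = copy_at, leaf_nodes = which(type == "leaf"))
}

# assemble the pruned labeled gene tree and per-level ground truth
finish_family <- function(fam, tax, family_id) {
  n_nodes <- length(fam$type)
  kids <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    p <- fam$parent[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  # extant leaf count under each gene node
  n_desc <- integer(n_nodes)
  for (i in rev(seq_len(n_nodes))) { # children always have larger ids
    n_desc[i] <- if (fam$type[i] == "leaf") 1L else
      sum(n_desc[kids[[i]]])
  }
  to_newick <- function(i, top_height) {
    live <- kids[[i]][n_desc[kids[[i]]] > 0L]
    if (fam$type[i] == "leaf") {
      return(paste0(fam$label[i], ":", format(top_height - 0)))
    }
    if (length(live) == 1L) return(to_newick(live, top_height))
    subs <- vapply(live, to_newick, character(1), top_height = fam$height[i])
    lab <- if (fam$type[i] == "duplication") "D" else "S"
    paste0("(", paste(subs, collapse = ","), ")", lab, ":",
           format(top_height - fam$height[i]))
  }
  root_gene <- 1L
  nwk <- paste0(sub(":[^:]*$", "", to_newick(root_gene, fam$height[root_gene])),
                ";")
  tr <- ape::read.tree(text = nwk)
  events <- ifelse(tr$node.label == "D", "duplication", "speciation")
  gt <- as_gene_tree(tr, events = events)
  truth <- lapply(names(tax$level_nodes), function(lid) {
    v <- tax$level_nodes[[lid]]
    parts <- lapply(fam$copy_at[[v]], function(cp) {
      leaves_under(cp, kids, fam)
    })
    parts[lengths(parts) > 0L]
  })
  names(truth) <- names(tax$level_nodes)
  structure(list(tree = gt, leaves = sort(fam$label[fam$leaf_nodes]),
                 truth = truth, family_id = family_id, nodes = fam),
            class = "true_family")
}

leaves_under <- function(i, kids, fam) {
  if (fam$type[i] == "leaf") return(fam$label[i])
  sort(unlist(lapply(kids[[i]], leaves_under, kids = kids, fam = fam)))
}

#' @export
print.true_family <- function(x, ...) {
  cat(sprintf("Simulated family %s: %d extant genes, %d duplication(s)\n",
              x$family_id, length(x$leaves),
              sum(x$tree$events == "duplication")))
  invisible(x)
}

# true LCA event for every leaf pair, from the raw (unpruned) node table;
# independent of the phylo-based path used by pairwise_relations()
true_relations <- function(fam) {
  nodes <- fam$nodes
  leaf_ids <- nodes$leaf_nodes
  labels <- nodes$label[leaf_ids]
  ord <- order(labels)
  leaf_ids <- leaf_ids[ord]; labels <- labels[ord]
  anc_path <- lapply(leaf_ids, function(i) {
    path <- i
    while (!is.na(nodes$parent[path[length(path)]])) {
      path <- c(path, nodes$parent[path[length(path)]])
    }
    path
  })
  res <- list(orthologs = list(), inparalogs = list(), paralogs = list())
  n <- length(leaf_ids)
  if (n < 2L) return(lapply(res, function(z) data.frame(a = character(0),
                                                        b = character(0))))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      lca <- intersect(anc_path[[i]], anc_path[[j]])[1L]
      a <- labels[i]; b <- labels[j]
      if (species_of(a) == species_of(b)) {
        res$inparalogs[[length(res$inparalogs) + 1L]] <- c(a, b)
      } else if (nodes$type[lca] == "duplication") {
        res$paralogs[[length(res$paralogs) + 1L]] <- c(a, b)
      } else {
        res$orthologs[[length(res$orthologs) + 1L]] <- c(a, b)
      }
    }
  }
  lapply(res, function(z) {
    if (!length(z)) return(data.frame(a = character(0), b = character(0),
                                      stringsAsFactors = FALSE))
    m <- do.call(rbind, z)
    data.frame(a = pmin(m[, 1], m[, 2]), b = pmax(m[, 1], m[, 2]),
               stringsAsFactors = FALSE)
  })
}

#' Noisy all-vs-all bit-scores for a simulated family
#'
#' For every ordered pair of extant genes, the bit-score is
#' `score_base - decay * d + N(0, noise_sd)`, floored at zero, where `d` is
#' the gene-tree patristic distance (twice the height of the pair's last
#' common ancestor; the simulated trees are ultrametric with integer
#' heights). Both directions are emitted with independent noise, emulating
#' an asymmetric all-vs-all search.
#'
#' @param fam A `true_family`.
#' @param cfg A `sim_config`.
#' @param seed Optional integer seed (local to this call).
#' @return Data.frame `query`, `subject`, `bitscore`.
#' @export
scores_from_family <- function(fam, cfg, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, scores_from_family(fam, cfg)))
  }
  nodes <- fam$nodes
  leaf_ids <- nodes$leaf_nodes
  labels <- nodes$label[leaf_ids]
  ord <- order(labels)
  leaf_ids <- leaf_ids[ord]; labels <- labels[ord]
  n <- length(labels)
  if (n < 2L) {
    return(data.frame(query = character(0), subject = character(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  }
  anc <- lapply(leaf_ids, function(i) {
    path <- i
    while (!is.na(nodes$parent[path[length(path)]])) {
      path <- c(path, nodes$parent[path[length(path)]])
    }
    path
  })
  query <- character(0); subject <- character(0); bitscore <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      lca <- intersect(anc[[i]], anc[[j]])[1L]
      d <- 2 * nodes$height[lca]
      base <- cfg$score_base - cfg$decay * d
      noise <- if (cfg$noise_sd > 0) stats::rnorm(2L, 0, cfg$noise_sd) else c(0, 0)
      query <- c(query, labels[i], labels[j])
      subject <- c(subject, labels[j], labels[i])
      bitscore <- c(bitscore, pmax(0, base + noise))
    }
  }
  data.frame(query = query, subject = subject, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: one taxonomy plus `n_families` gene families and
#' their combined hit table, all under a single seed.
#'
#' @param cfg A `sim_config`.
#' @param seed Integer seed.
#' @return List with `tax`, `families`, `hits` and `truth` (per-level
#'   ground-truth partitions pooled over families).
#' @export
simulate_dataset <- function(cfg, seed) {
  withr::with_seed(seed, {
    tax <- simulate_taxonomy(cfg)
    families <- lapply(seq_len(cfg$n_families), function(k) {
      simulate_family(tax, cfg, family_id = paste0("f", k))
    })
    hits <- do.call(rbind, lapply(families, scores_from_family, cfg = cfg))
    truth <- stats::setNames(lapply(names(tax$level_nodes), function(lid) {
      do.call(c, lapply(families, function(f) f$truth[[lid]]))
    }), names(tax$level_nodes))
    list(tax = tax, families = families, hits = hits, truth = truth)
  })
}

# unordered co-membership or relation pairs as strings
pair_keys_partition <- function(parts) {
  unlist(lapply(parts, function(m) {
    m <- sort(m)
    if (length(m) < 2L) return(character(0))
    idx <- utils::combn(length(m), 2L)
    paste(m[idx[1L, ]], m[idx[2L, ]], sep = "\r")
  }))
}

pair_keys <- function(x) {
  if (is.data.frame(x)) {
    paste(pmin(x$a, x$b), pmax(x$a, x$b), sep = "\r")
  } else if (inherits(x, "og_set")) {
    pair_keys_partition(x$groups)
  } else {
    pair_keys_partition(x)
  }
}

genes_of <- function(x) {
  if (is.data.frame(x)) unique(c(x$a, x$b))
  else if (inherits(x, "og_set")) unique(c(unlist(x$groups), x$unclustered))
  else unique(unlist(x))
}

#' Pair-based precision, recall and F-measure
#'
#' Compares predictions against ground truth at the level of unordered
#' pairs: co-membership pairs for OG partitions, or relation pairs for
#' pairwise ortholog lists. An empty prediction has precision 1.0 by
#' convention (nothing asserted, nothing wrong) and recall 0 when true
#' pairs exist.
#'
#' @param predicted An `og_set`, a list of member vectors, or a data.frame
#'   with columns `a`, `b`.
#' @param truth Same forms as `predicted`.
#' @return List with `precision`, `recall` and `F`.
#' @export
evaluate_recovery <- function(predicted, truth) {
  gp <- genes_of(predicted); gt <- genes_of(truth)
  if (length(gp) && length(gt) && !length(intersect(gp, gt))) {
    stop("disjoint gene universes between prediction and truth")
  }
  pred <- unique(pair_keys(predicted))
  tru <- unique(pair_keys(truth))
  inter <- length(intersect(pred, tru))
  precision <- if (!length(pred)) 1.0 else inter / length(pred)
  recall <- if (!length(tru)) 1.0 else inter / length(tru)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, F = f)
}

#' Random nearest-neighbour-interchange perturbation of a gene tree
#'
#' Each eligible internal edge (both endpoints internal nodes) is perturbed
#' with probability `prop` by swapping a random child of the edge's lower
#' node with the node's sibling -- a topology-noise model for imperfect tree
#' inference.
#'
#' @param gt A `gene_tree`.
#' @param prop Per-edge perturbation probability.
#' @param seed Optional integer seed (local to this call).
#' @return The perturbed `gene_tree` (unlabeled).
#' @export
nni_perturb <- function(gt, prop = 0.1, seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, nni_perturb(gt, prop)))
  tr <- gt$tree
  ntip <- length(tr$tip.label)
  cand <- which(tr$edge[, 1L] > ntip & tr$edge[, 2L] > ntip)
  for (i in cand) {
    if (stats::runif(1) >= prop) next
    p <- tr$edge[i, 1L]; v <- tr$edge[i, 2L]
    sibs <- tr$edge[tr$edge[, 1L] == p & tr$edge[, 2L] != v, 2L]
    chs <- tr$edge[tr$edge[, 1L] == v, 2L]
    if (!length(sibs) || length(chs) < 2L) next
    s <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
    x <- sample(chs, 1L)
    row_ps <- which(tr$edge[, 1L] == p & tr$edge[, 2L] == s)[1L]
    row_vx <- which(tr$edge[, 1L] == v & tr$edge[, 2L] == x)[1L]
    tr$edge[row_ps, 2L] <- x
    tr$edge[row_vx, 2L] <- s
  }
  tr$node.label <- NULL
  tr <- ape::read.tree(text = ape::write.tree(tr))
  as_gene_tree(tr)
}

#' Write a simulated dataset as a fixture bundle
#'
#' Emits the exact input formats consumed by the other modules: the level
#' table, the hit TSV, one Newick gene tree per family (true event labels as
#' internal node labels `D`/`S`) and the ground-truth membership TSV.
#'
#' @param ds A dataset from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hierarchy(ds$tax$hierarchy, file.path(dir, "levels.tsv"))
  write_hits(ds$hits, file.path(dir, "hits.tsv"))
  tree_dir <- file.path(dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  for (f in ds$families) {
    tr <- f$tree$tree
    tr$node.label <- ifelse(f$tree$events == "duplication", "D", "S")
    ape::write.tree(tr, file.path(tree_dir, paste0(f$family_id, ".nwk")))
  }
  truth_sets <- lapply(names(ds$truth), function(lv) {
    groups <- ds$truth[[lv]]
    names(groups) <- paste0("tmp", seq_along(groups))
    ids <- assign_og_ids(lv, groups)
    og_set(lv, ids$groups)
  })
  names(truth_sets) <- names(ds$truth)
  write_members(truth_sets, file.path(dir, "truth_members.tsv"))
  invisible(dir)
}
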