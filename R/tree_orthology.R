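#' Gene trees with species-tagged leaves
#'
#' A `gene_tree` wraps a rooted `ape::phylo` tree whose leaf names follow
#' the `"speciesid.proteinid"` convention, together with the species of each
#' leaf and an event label (`"speciation"` / `"duplication"`) per internal
#' node once [label_events()] has been run.
#'
#' @param tree A rooted `phylo` object.
#' @param events Optional character vector of event labels, one per internal
#'   node (in `phylo` node order); `NA` for unlabeled.
#' @return A `gene_tree`.
#' @export
as_gene_tree <- function(tree, events = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("gene tree needs at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf name(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  species <- stats::setNames(species_of(tree$tip.label), tree$tip.label)
  if (is.null(events)) events <- rep(NA_character_, tree$Nnode)
  stopifnot(length(events) == tree$Nnode)
  structure(list(tree = tree, species = species, events = events),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("Gene tree: %d leaves, %d species, events %s\n",
              length(x$tree$tip.label), length(unique(x$species)),
              if (all(is.na(x$events))) "unlabeled" else
                paste0(sum(x$events == "duplication", na.rm = TRUE), " dup / ",
                       sum(x$events == "speciation", na.rm = TRUE), " spec")))
  invisible(x)
}

#' Parse a rooted gene tree from Newick
#'
#' Leaf names must carry the species prefix (`"speciesid.proteinid"`).
#' Unrooted trees (root with more than two children) are rejected unless
#' `force_root = TRUE`, in which case the tree is midpoint-rooted (requires
#' the phangorn package). Multifurcations below the root are allowed.
#'
#' @param text Newick string (exclusive with `file`).
#' @param file Path to a Newick file.
#' @param force_root Midpoint-root unrooted input instead of failing.
#' @return A `gene_tree`.
#' @examples
#' parse_gene_tree("((9606.A,10090.B),(9606.C,10090.D));")
#' @export
parse_gene_tree <- function(text = NULL, file = NULL, force_root = FALSE) {
  tr <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) stop("malformed Newick input")
  root <- length(tr$tip.label) + 1L
  root_children <- sum(tr$edge[, 1L] == root)
  if (root_children > 2L) {
    if (!force_root) {
      stop("unrooted tree (", root_children, " children at root); ",
           "set force_root = TRUE to midpoint-root")
    }
    if (!requireNamespace("phangorn", quietly = TRUE)) {
      stop("midpoint rooting requires the phangorn package")
    }
    if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
    tr <- phangorn::midpoint(tr)
  }
  as_gene_tree(tr)
}

#' Label gene-tree nodes as speciation or duplication by species overlap
#'
#' An internal node is labeled a duplication when the species sets of at
#' least two of its child subtrees intersect -- the same species on both
#' sides of a split can only arise by gene duplication (ignoring horizontal
#' transfer). All other internal nodes are speciations. Multifurcations are
#' treated as simultaneous splits: any overlapping pair of child subtrees
#' makes the node a duplication. Any species overlap counts (no fractional
#' threshold).
#'
#' @param gt A `gene_tree`.
#' @return The `gene_tree` with `events` filled in.
#' @examples
#' gt <- parse_gene_tree("((9606.A,10090.B),(9606.C,10090.D));")
#' label_events(gt)$events
#' @export
label_events <- function(gt) {
  stopifnot(inherits(gt, "gene_tree"))
  tr <- gt$tree
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  tip_sp <- unname(gt$species[tr$tip.label])
  edge <- tr$edge[ape::postorder(tr), , drop = FALSE]
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tip_sp[i]
  events <- rep(NA_character_, nnode)
  kids <- split(edge[, 2L], edge[, 1L])
  # postorder guarantees children are finished before their parent appears
  for (node in unique(edge[, 1L])) {
    ch <- kids[[as.character(node)]]
    child_sets <- sets[ch]
    u <- unique(unlist(child_sets))
    dup <- sum(lengths(lapply(child_sets, unique))) > length(u)
    events[node - ntip] <- if (dup) "duplication" else "speciation"
    sets[[node]] <- u
  }
  gt$events <- events
  gt
}

#' Typed pairwise orthology relations from a labeled gene tree
#'
#' Every leaf pair is classified by the event at its last common ancestor:
#' cross-species pairs with a speciation LCA are orthologs; same-species
#' pairs are in-paralogs; cross-species pairs with a duplication LCA are
#' paralogs (excluded from the ortholog list). Ortholog pairs are typed by
#' counting each leaf's co-orthologs in the partner's species: both counts 1
#' gives `one2one`, exactly one count 1 gives `one2many`, otherwise
#' `many2many`.
#'
#' @param gt A labeled `gene_tree` (see [label_events()]).
#' @return List with data.frames `orthologs` (`a`, `b`, `relation`),
#'   `inparalogs` (`a`, `b`) and `paralogs` (`a`, `b`); in each row `a < b`.
#' @examples
#' gt <- label_events(parse_gene_tree("(9606.A,(10090.B1,10090.B2));"))
#' pairwise_relations(gt)$orthologs
#' @export
pairwise_relations <- function(gt) {
  stopifnot(inherits(gt, "gene_tree"))
  if (anyNA(gt$events)) stop("tree is not fully labeled; run label_events()")
  tr <- gt$tree
  tips <- tr$tip.label
  ntip <- length(tips)
  sp <- unname(gt$species[tips])
  lca <- ape::mrca(tr)
  ij <- which(upper.tri(lca), arr.ind = TRUE)
  a <- tips[ij[, 1L]]; b <- tips[ij[, 2L]]
  ev <- gt$events[lca[ij] - ntip]
  sa <- sp[ij[, 1L]]; sb <- sp[ij[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  same_sp <- sa == sb
  is_orth <- !same_sp & ev == "speciation"
  is_para <- !same_sp & ev == "duplication"
  orth <- data.frame(a = a[is_orth], b = b[is_orth], stringsAsFactors = FALSE)
  if (nrow(orth)) {
    # co-ortholog counts: orthologs of x within a given species
    both <- data.frame(x = c(orth$a, orth$b), y = c(orth$b, orth$a),
                       stringsAsFactors = FALSE)
    key <- paste(both$x, species_of(both$y), sep = "\r")
    cnt <- table(key)
    n_a <- as.integer(cnt[paste(orth$a, species_of(orth$b), sep = "\r")])
    n_b <- as.integer(cnt[paste(orth$b, species_of(orth$a), sep = "\r")])
    orth$relation <- ifelse(n_a == 1L & n_b == 1L, "one2one",
                     ifelse(n_a == 1L | n_b == 1L, "one2many", "many2many"))
  } else {
    orth$relation <- character(0)
  }
  ord <- order(orth$a, orth$b)
  inpar <- data.frame(a = a[same_sp], b = b[same_sp], stringsAsFactors = FALSE)
  par <- data.frame(a = a[is_para], b = b[is_para], stringsAsFactors = FALSE)
  list(orthologs = orth[ord, , drop = FALSE],
       inparalogs = inpar[order(inpar$a, inpar$b), , drop = FALSE],
       paralogs = par[order(par$a, par$b), , drop = FALSE])
}
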