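DESCRIPTION_STOPWORDS <- c("protein", "putative", "hypothetical",
                           "uncharacterized", "predicted", "conserved")

# tokenize a free-text description: lowercase, strip punctuation (keeping
# intra-word hyphens), drop stop-words, pure numbers and accession-like
# tokens (short letter prefix followed by a run of >= 3 digits)
description_tokens <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9-]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- toks[nzchar(toks) & toks != "-"]
  drop <- toks %in% DESCRIPTION_STOPWORDS |
    grepl("^[0-9]+([.][0-9]+)?$", toks) |
    grepl("^[a-z]{0,5}[0-9]{3,}$", toks)
  toks[!drop]
}

#' Consensus description for a group of proteins
#'
#' Heuristic for the most descriptive shared description among annotated
#' members of a group: descriptions are tokenized to lowercase words
#' (punctuation stripped, stop-words like "protein"/"putative" and purely
#' numeric or accession-like tokens dropped) and the longest word n-gram
#' occurring in the greatest number of descriptions is returned, ranking by
#' coverage first, then n-gram length, then total character length, then
#' lexicographically. With several inputs, a candidate must occur in at
#' least two descriptions, otherwise the result is empty; a single
#' (non-empty) input is returned verbatim.
#'
#' @param descriptions Character vector of free-text descriptions; empties
#'   are ignored.
#' @return A single consensus string (possibly `""`).
#' @examples
#' consensus_description(c("ABC transporter ATP-binding protein",
#'                         "ABC transporter permease"))
#' @export
consensus_description <- function(descriptions) {
  descriptions <- descriptions[!is.na(descriptions) & nzchar(trimws(descriptions))]
  if (!length(descriptions)) return("")
  if (length(descriptions) == 1L) return(descriptions[[1L]])
  per_desc <- lapply(descriptions, function(d) {
    toks <- description_tokens(d)
    if (!length(toks)) return(character(0))
    grams <- character(0)
    for (n in seq_along(toks)) {
      for (i in seq_len(length(toks) - n + 1L)) {
        grams <- c(grams, paste(toks[i:(i + n - 1L)], collapse = " "))
      }
    }
    unique(grams)
  })
  cov <- table(unlist(per_desc))
  cov <- cov[cov >= 2L]
  if (!length(cov)) return("")
  cand <- names(cov)
  n_words <- lengths(strsplit(cand, " ", fixed = TRUE))
  ord <- order(-as.integer(cov), -n_words, -nchar(cand), cand)
  cand[ord[1L]]
}

#' Read per-protein functional annotations
#'
#' Tab-separated, seven columns: `protein_id`, `description`, `GO_csv`,
#' `KEGG_csv`, `SMART_csv`, `PFAM_csv`, `clan_architecture_csv` (ordered
#' Pfam clan ids). Empty fields are allowed.
#'
#' @param path Path to the annotation table.
#' @return Data.frame with those columns (csv fields kept as strings).
#' @export
read_annotations <- function(path) {
  tl <- read_tsv_lines(path)
  cols <- c("protein_id", "description", "GO", "KEGG", "SMART", "PFAM",
            "clan_architecture")
  if (!length(tl$lines)) {
    return(stats::setNames(
      data.frame(matrix(character(0), 0, 7), stringsAsFactors = FALSE), cols))
  }
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  m <- t(vapply(parts, function(p) c(p, rep("", 7L))[1:7], character(7)))
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  out
}

#' @rdname read_annotations
#' @param annos Annotation data.frame.
#' @export
write_annotations <- function(annos, path) {
  lines <- apply(annos, 1L, paste, collapse = "\t")
  write_tsv_lines(unname(lines), path)
}

split_csv <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else
    trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Functional term-frequency profile of an OG
#'
#' For each namespace (GO, KEGG, SMART, PFAM), the frequency of each term
#' among the group members that carry at least one term in that namespace
#' (the denominator is annotated members, not all members).
#'
#' @param members Character vector of member protein ids.
#' @param annos Annotation data.frame (see [read_annotations()]).
#' @return Data.frame `namespace`, `term`, `freq`, `n_annotated`.
#' @export
functional_profile <- function(members, annos) {
  out <- list()
  rows <- annos[annos$protein_id %in% members, , drop = FALSE]
  for (ns in c("GO", "KEGG", "SMART", "PFAM")) {
    terms <- lapply(rows[[ns]], split_csv)
    annotated <- lengths(terms) > 0L
    n_ann <- sum(annotated)
    if (!n_ann) next
    cnt <- table(unlist(lapply(terms[annotated], unique)))
    out[[ns]] <- data.frame(namespace = ns, term = names(cnt),
                            freq = as.numeric(cnt) / n_ann,
                            n_annotated = n_ann, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(namespace = character(0), term = character(0),
                      freq = numeric(0), n_annotated = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$namespace, res$term), , drop = FALSE]
}

#' Per-OG annotation records
#'
#' @param description Free-text description (may be `""`).
#' @param cog_category Character vector of single-letter COG functional
#'   categories (may be empty; categories are carried through, not
#'   classified here).
#' @param inherited Was the annotation inherited from an ancestor OG?
#' @return A list with those fields (class `og_annotation`).
#' @export
og_annotation <- function(description = "", cog_category = character(0),
                          inherited = FALSE) {
  structure(list(description = description, cog_category = cog_category,
                 inherited = inherited), class = "og_annotation")
}

#' Propagate annotations from parent to child OGs
#'
#' With a hierarchically consistent OG hierarchy, groups near the tips that
#' lack annotations inherit the description and COG categories of their
#' nearest annotated ancestor group (found by member containment). Inherited
#' annotations are flagged (`inherited = TRUE`) so downstream applications
#' can exclude them.
#'
#' @param oh A consistent `og_hierarchy`.
#' @param annos Named list of [og_annotation()] records keyed by OG id; OGs
#'   absent from the list are treated as unannotated.
#' @return The updated named list, covering every OG in the hierarchy.
#' @export
propagate_annotations <- function(oh, annos) {
  if (!is_consistent(oh)) {
    stop("OG hierarchy is not consistent; run enforce_consistency() first")
  }
  rootward <- rev(leafward_order(oh$hierarchy))
  for (lv in rootward) {
    os <- oh$ogsets[[lv]]
    if (is.null(os)) next
    parent_level <- oh$hierarchy$levels[[lv]]$parent
    parent_of <- NULL
    if (!is.na(parent_level) && !is.null(oh$ogsets[[parent_level]])) {
      pos <- oh$ogsets[[parent_level]]
      parent_of <- stats::setNames(
        rep(names(pos$groups), lengths(pos$groups)),
        unlist(pos$groups, use.names = FALSE))
    }
    for (og in names(os$groups)) {
      a <- annos[[og]] %||% og_annotation()
      if (!nzchar(a$description) && !is.null(parent_of)) {
        pid <- unique(stats::na.omit(parent_of[os$groups[[og]]]))
        if (length(pid) == 1L) {
          pa <- annos[[pid]]
          if (!is.null(pa) && nzchar(pa$description)) {
            a <- og_annotation(description = pa$description,
                               cog_category = pa$cog_category,
                               inherited = TRUE)
          }
        }
      }
      annos[[og]] <- a
    }
  }
  annos
}

#' Merge OGs sharing a majority Pfam clan-level domain architecture
#'
#' Applied to viral OGs: for each group, the majority architecture is the
#' ordered clan-id list held by a strict majority (>50%) of the members that
#' have a non-empty architecture; groups sharing an identical majority
#' architecture are merged. Groups without a strict majority are untouched.
#'
#' @param ogset An `og_set`.
#' @param annos Annotation data.frame with a `clan_architecture` csv column.
#' @return The merged `og_set`.
#' @export
merge_by_clan_architecture <- function(ogset, annos) {
  arch_of <- stats::setNames(
    vapply(annos$clan_architecture, function(x) {
      paste(split_csv(x), collapse = "|")
    }, character(1), USE.NAMES = FALSE),
    annos$protein_id)
  majority <- vapply(ogset$groups, function(m) {
    a <- arch_of[m]
    a <- a[!is.na(a) & nzchar(a)]
    if (!length(a)) return(NA_character_)
    cnt <- sort(table(a), decreasing = TRUE)
    if (cnt[1L] * 2L > length(a)) names(cnt)[1L] else NA_character_
  }, character(1))
  groups <- ogset$groups
  so <- ogset$seed_origin
  for (arch in unique(stats::na.omit(majority))) {
    ids <- names(majority)[!is.na(majority) & majority == arch]
    if (length(ids) < 2L) next
    merged <- sort(unique(unlist(groups[ids], use.names = FALSE)))
    org <- unique(unlist(so[ids]))
    groups[ids] <- NULL
    groups[[paste0("arch:", arch)]] <- merged
    so[ids] <- NULL
    if (length(org)) so[[paste0("arch:", arch)]] <- org
  }
  ids <- assign_og_ids(ogset$level, groups, so)
  og_set(ogset$level, ids$groups, unclustered = ogset$unclustered,
         seed_origin = ids$seed_origin)
}

#' Cleave a polyprotein into its mature peptide chains
#'
#' Viral polyproteins are cleaved in silico following chain annotations
#' (1-based inclusive coordinates). Only the smallest units are retained:
#' a chain whose interval strictly contains another chain is discarded.
#' Identical resulting subsequences are deduplicated so the output is
#' non-redundant.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param chains Data.frame with columns `start`, `end`.
#' @param id Identifier of the polyprotein; output ids are
#'   `"<id>_<start>-<end>"`.
#' @return Data.frame `id`, `start`, `end`, `seq`.
#' @examples
#' cleave_polyprotein(strrep("A", 10), data.frame(start = c(1, 6), end = c(5, 10)), "P1")
#' @export
cleave_polyprotein <- function(sequence, chains, id = "polyprotein") {
  n <- nchar(sequence)
  if (!nrow(chains)) {
    return(data.frame(id = character(0), start = integer(0), end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  if (any(chains$start < 1L | chains$end > n | chains$start > chains$end)) {
    stop("chain coordinates out of range for sequence of length ", n)
  }
  chains <- unique(chains[, c("start", "end")])
  contains_other <- vapply(seq_len(nrow(chains)), function(i) {
    any(chains$start >= chains$start[i] & chains$end <= chains$end[i] &
        (chains$start > chains$start[i] | chains$end < chains$end[i]))
  }, logical(1))
  kept <- chains[!contains_other, , drop = FALSE]
  kept <- kept[order(kept$start, kept$end), , drop = FALSE]
  out <- data.frame(id = paste0(id, "_", kept$start, "-", kept$end),
                    start = as.integer(kept$start), end = as.integer(kept$end),
                    seq = substring(sequence, kept$start, kept$end),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}
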