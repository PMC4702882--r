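#' Write and read hit tables
#'
#' Three-column tab-separated `(query, subject, bitscore)`; the writer/reader
#' pair round-trips byte-stably.
#'
#' @param hits Data.frame `query`, `subject`, `bitscore`.
#' @param path File path.
#' @return `path` (writer) / the data.frame (reader via [parse_hits()]).
#' @export
write_hits <- function(hits, path) {
  lines <- paste(hits$query, hits$subject, format_score(hits$bitscore),
                 sep = "\t")
  write_tsv_lines(lines, path)
}

#' Write OG membership tables
#'
#' One row per OG: `level_id`, `og_id`, `n_members`, `n_species`,
#' comma-separated member ids -- the bulk "members" file shape of orthology
#' databases. Unclustered singletons are not part of the member file.
#'
#' @param ogsets A named list of `og_set` (or a single `og_set`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_members <- function(ogsets, path) {
  if (inherits(ogsets, "og_set")) ogsets <- stats::setNames(list(ogsets),
                                                            ogsets$level)
  lines <- character(0)
  for (lv in names(ogsets)) {
    os <- ogsets[[lv]]
    for (og in names(os$groups)) {
      m <- os$groups[[og]]
      lines <- c(lines, paste(lv, og, length(m),
                              length(unique(species_of(m))),
                              paste(m, collapse = ","), sep = "\t"))
    }
  }
  write_tsv_lines(lines, path)
}

#' @rdname write_members
#' @return Named list of `og_set` per level (reader).
#' @export
read_members <- function(path) {
  tl <- read_tsv_lines(path)
  out <- list()
  if (!length(tl$lines)) return(out)
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 5L) stop("line ", tl$numbers[i],
                             ": expected 5 tab-separated fields")
    lv <- p[1]
    if (is.null(out[[lv]])) out[[lv]] <- list()
    out[[lv]][[p[2]]] <- strsplit(p[5], ",", fixed = TRUE)[[1]]
  }
  lapply(stats::setNames(names(out), names(out)), function(lv) {
    og_set(lv, out[[lv]])
  })
}

#' Write typed pairwise orthology predictions
#'
#' Tab-separated `(og_id, protein_a, protein_b, relation)`.
#'
#' @param pairs Data.frame with columns `og_id`, `a`, `b`, `relation`.
#' @param path File path.
#' @return `path`, invisibly / the data.frame (reader).
#' @export
write_pair_relations <- function(pairs, path) {
  lines <- paste(pairs$og_id, pairs$a, pairs$b, pairs$relation, sep = "\t")
  write_tsv_lines(lines, path)
}

#' @rdname write_pair_relations
#' @export
read_pair_relations <- function(path) {
  tl <- read_tsv_lines(path)
  if (!length(tl$lines)) {
    return(data.frame(og_id = character(0), a = character(0), b = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  m <- t(vapply(parts, function(p) p[1:4], character(4)))
  data.frame(og_id = m[, 1], a = m[, 2], b = m[, 3], relation = m[, 4],
             stringsAsFactors = FALSE)
}

#' Write the consistency reconciliation report
#'
#' Tab-separated audit trail of every split/merge resolution:
#' `(child_level, child_og, resolution, partition_sizes,
#' species_overlap_size)`.
#'
#' @param report Data.frame as attached by [enforce_consistency()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_split_report <- function(report, path) {
  lines <- paste(report$child_level, report$child_og, report$resolution,
                 report$partition_sizes, report$species_overlap_size,
                 sep = "\t")
  write_tsv_lines(lines, path)
}

# flat key = value configuration files with '#' comments
read_config <- function(path) {
  tl <- read_tsv_lines(path)
  out <- list()
  for (ln in tl$lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

write_manifest <- function(path, stage, inputs, params = list()) {
  manifest <- list(stage = stage,
                   inputs = inputs,
                   params = params,
                   package = as.character(utils::packageVersion("ognest")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the per-level OG building stage
#'
#' Reads the level table and hit table, filters and symmetrizes the hits,
#' builds OGs at every level (in leafward order) and writes one members file
#' per level plus a run manifest.
#'
#' @param cfg List with `hits`, `levels`, `out_dir`, optional `threshold`
#'   (default 50) and optional `seeds` (members TSV of seed clusters,
#'   conserved at their level).
#' @return The `og_hierarchy`, invisibly.
#' @export
run_build <- function(cfg) {
  stopifnot(file.exists(cfg$hits), file.exists(cfg$levels))
  h <- load_hierarchy(cfg$levels)
  threshold <- cfg$threshold %||% 50
  hits <- filter_hits(parse_hits(cfg$hits), threshold)
  if (!nrow(hits)) warning("no hits above threshold ", threshold)
  g <- symmetrize(hits)
  seed_sets <- if (!is.null(cfg$seeds)) read_members(cfg$seeds) else list()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ogsets <- list()
  for (lv in leafward_order(h)) {
    level <- h$levels[[lv]]
    seeds <- if (!is.null(seed_sets[[lv]])) seed_sets[[lv]]$groups else NULL
    ogsets[[lv]] <- build_ogs(g, level, seeds = seeds)
    write_members(ogsets[lv], file.path(cfg$out_dir,
                                        paste0("members.", lv, ".tsv")))
  }
  write_manifest(file.path(cfg$out_dir, "build.manifest.json"), "build",
                 inputs = list(hits = cfg$hits, levels = cfg$levels,
                               seeds = cfg$seeds %||% NA),
                 params = list(threshold = threshold))
  invisible(og_hierarchy(h, ogsets))
}

#' Run the hierarchical consistency stage
#'
#' Reads per-level members files, enforces hierarchical consistency and
#' writes the reconciled members plus the resolution report.
#'
#' @param cfg List with `levels`, `members` (single members TSV or directory
#'   of `members.<level>.tsv`) and `out_dir`.
#' @return The consistent `og_hierarchy`, invisibly.
#' @export
run_reconcile <- function(cfg) {
  h <- load_hierarchy(cfg$levels)
  ogsets <- if (dir.exists(cfg$members)) {
    files <- list.files(cfg$members, pattern = "^members\\..*\\.tsv$",
                        full.names = TRUE)
    do.call(c, lapply(sort(files), read_members))
  } else read_members(cfg$members)
  oh <- enforce_consistency(og_hierarchy(h, ogsets))
  if (!is_consistent(oh)) stop("nesting invariant still violated after enforcement")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_members(oh$ogsets, file.path(cfg$out_dir, "members.reconciled.tsv"))
  write_split_report(attr(oh, "report"),
                     file.path(cfg$out_dir, "reconciliation.report.tsv"))
  write_manifest(file.path(cfg$out_dir, "reconcile.manifest.json"), "reconcile",
                 inputs = list(levels = cfg$levels, members = cfg$members))
  invisible(oh)
}

#' Run the pairwise orthology stage
#'
#' Parses one Newick gene tree per OG (filename `<og_id>.nwk`), labels
#' speciation/duplication events by species overlap and writes the
#' concatenated typed ortholog pair list. Optionally restricts the output to
#' pairs touching a query protein and a set of target species (guided-query
#' semantics).
#'
#' @param cfg List with `trees` (directory), `out_dir`, optional `query`
#'   (protein id) and `target_species` (character vector).
#' @return The pair data.frame, invisibly.
#' @export
run_orthologs <- function(cfg) {
  files <- sort(list.files(cfg$trees, pattern = "\\.nwk$", full.names = TRUE))
  all_pairs <- list()
  for (f in files) {
    og <- sub("\\.nwk$", "", basename(f))
    gt <- tryCatch(parse_gene_tree(file = f), error = function(e) {
      warning("skipping tree ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(gt)) next
    rel <- pairwise_relations(label_events(gt))$orthologs
    if (nrow(rel)) rel$og_id <- og
    all_pairs[[og]] <- rel
  }
  pairs <- if (length(all_pairs)) do.call(rbind, all_pairs) else
    data.frame(a = character(0), b = character(0), relation = character(0),
               og_id = character(0), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  if (!is.null(cfg$query)) {
    touch <- pairs$a == cfg$query | pairs$b == cfg$query
    pairs <- pairs[touch, , drop = FALSE]
  }
  if (!is.null(cfg$target_species)) {
    keep_sp <- function(x) species_of(x) %in% cfg$target_species |
      (!is.null(cfg$query) & x == (cfg$query %||% ""))
    pairs <- pairs[keep_sp(pairs$a) & keep_sp(pairs$b), , drop = FALSE]
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pair_relations(pairs[, c("og_id", "a", "b", "relation")],
                       file.path(cfg$out_dir, "pairwise_orthologs.tsv"))
  write_manifest(file.path(cfg$out_dir, "orthologs.manifest.json"), "orthologs",
                 inputs = list(trees = cfg$trees),
                 params = list(query = cfg$query %||% NA,
                               target_species = cfg$target_species %||% NA))
  invisible(pairs)
}

#' Run the functional annotation stage
#'
#' Computes consensus descriptions and term-frequency profiles per OG from
#' member annotations, propagates annotations root-ward OGs lacking them
#' (flagging inherited ones) and writes the OG annotation tables. The count
#' of newly inherited OGs is reported via a message.
#'
#' @param cfg List with `levels`, `members` (reconciled members TSV),
#'   `annotations` (protein annotation TSV) and `out_dir`.
#' @return Named list of `og_annotation`, invisibly.
#' @export
run_annotate <- function(cfg) {
  h <- load_hierarchy(cfg$levels)
  ogsets <- read_members(cfg$members)
  oh <- og_hierarchy(h, ogsets)
  pann <- read_annotations(cfg$annotations)
  desc_of <- stats::setNames(pann$description, pann$protein_id)
  annos <- list()
  freq_lines <- character(0)
  for (lv in names(oh$ogsets)) {
    os <- oh$ogsets[[lv]]
    for (og in names(os$groups)) {
      members <- os$groups[[og]]
      d <- consensus_description(stats::na.omit(desc_of[members]))
      annos[[og]] <- og_annotation(description = d)
      prof <- functional_profile(members, pann)
      if (nrow(prof)) {
        freq_lines <- c(freq_lines,
                        paste(lv, og, prof$namespace, prof$term,
                              format_score(prof$freq), sep = "\t"))
      }
    }
  }
  before <- sum(vapply(annos, function(a) nzchar(a$description), logical(1)))
  annos <- propagate_annotations(oh, annos)
  inherited <- sum(vapply(annos, `[[`, logical(1), "inherited"))
  message("annotation propagation: ", inherited, " OG(s) newly inherited (",
          before, " directly annotated)")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ann_lines <- character(0)
  for (lv in names(oh$ogsets)) {
    for (og in names(oh$ogsets[[lv]]$groups)) {
      a <- annos[[og]]
      ann_lines <- c(ann_lines,
                     paste(lv, og, paste(a$cog_category, collapse = ""),
                           a$description, as.integer(a$inherited), sep = "\t"))
    }
  }
  write_tsv_lines(ann_lines, file.path(cfg$out_dir, "og_annotations.tsv"))
  write_tsv_lines(freq_lines, file.path(cfg$out_dir, "term_frequencies.tsv"))
  write_manifest(file.path(cfg$out_dir, "annotate.manifest.json"), "annotate",
                 inputs = list(levels = cfg$levels, members = cfg$members,
                               annotations = cfg$annotations),
                 params = list(inherited = inherited))
  invisible(annos)
}

#' Export per-OG member sequences as FASTA
#'
#' Hand-off point to downstream profile construction: given a FASTA of all
#' protein sequences, writes one FASTA per OG containing its members.
#' Requires the Biostrings package.
#'
#' @param ogset An `og_set`.
#' @param fasta Path to the FASTA of member sequences.
#' @param out_dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
export_og_fasta <- function(ogset, fasta, out_dir) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("export_og_fasta requires the Biostrings package")
  }
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (og in names(ogset$groups)) {
    m <- intersect(ogset$groups[[og]], names(seqs))
    if (!length(m)) next
    p <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9@._-]", "_", og), ".faa"))
    Biostrings::writeXStringSet(seqs[m], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
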