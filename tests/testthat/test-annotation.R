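textConnection_file <- function(lines) {
  tf <- tempfile()
  writeLines(lines, tf)
  tf
}

test_that("consensus description picks the widest-coverage longest shared n-gram", {
  expect_identical(
    consensus_description(c("ABC transporter ATP-binding protein",
                            "ABC transporter permease")),
    "abc transporter")
  # single description returned verbatim
  expect_identical(consensus_description("kinase"), "kinase")
  # fully stop-listed inputs yield an empty consensus
  expect_identical(
    consensus_description(c("hypothetical protein", "uncharacterized protein")),
    "")
  # nothing shared between two descriptions
  expect_identical(consensus_description(c("sulfatase", "dehydrogenase")), "")
  # empties ignored; remaining single input verbatim
  expect_identical(consensus_description(c("", "Sec24-related protein")),
                   "Sec24-related protein")
  # deterministic and idempotent
  d <- consensus_description(c("DNA polymerase III subunit alpha",
                               "DNA polymerase III subunit epsilon"))
  expect_identical(d, "dna polymerase iii subunit")
  expect_identical(consensus_description(d), d)
})

test_that("coverage outranks n-gram length", {
  # "histidine kinase" shared by 2, "kinase" shared by all 3
  out <- consensus_description(c("histidine kinase", "histidine kinase",
                                 "tyrosine kinase"))
  expect_identical(out, "kinase")
})

mk_oh <- function() {
  h <- level_hierarchy(list(
    list(id = "root", name = "root", parent = NA, species = paste0("S", 1:4)),
    list(id = "mid", name = "mid", parent = "root", species = paste0("S", 1:2)),
    list(id = "kid", name = "kid", parent = "mid", species = "S1")))
  root <- og_set("root", list("root@1" = c("S1.a", "S2.b", "S3.c"),
                              "root@2" = c("S1.x", "S4.y")))
  mid <- og_set("mid", list("mid@1" = c("S1.a", "S2.b"), "mid@2" = "S1.x"))
  kid <- og_set("kid", list("kid@1" = "S1.a"))
  og_hierarchy(h, list(root = root, mid = mid, kid = kid))
}

test_that("unannotated child OGs inherit from the nearest annotated ancestor, flagged", {
  oh <- mk_oh()
  annos <- list("root@1" = og_annotation("sec24-related protein", "U"))
  out <- propagate_annotations(oh, annos)
  expect_identical(out[["mid@1"]]$description, "sec24-related protein")
  expect_true(out[["mid@1"]]$inherited)
  expect_identical(out[["mid@1"]]$cog_category, "U")
  # two levels down: inherits through the (now annotated) mid level
  expect_identical(out[["kid@1"]]$description, "sec24-related protein")
  expect_true(out[["kid@1"]]$inherited)
  # annotated child is untouched and unflagged
  out2 <- propagate_annotations(oh, c(annos, list(
    "mid@1" = og_annotation("coatomer subunit"))))
  expect_identical(out2[["mid@1"]]$description, "coatomer subunit")
  expect_false(out2[["mid@1"]]$inherited)
  # an entirely unannotated lineage stays empty
  expect_identical(out[["mid@2"]]$description, "")
  expect_false(out[["mid@2"]]$inherited)
})

test_that("inherited counts match the brute-force ancestor-search oracle", {
  cfg <- sim_config()
  for (s in c(2, 9)) {
    ds <- simulate_dataset(cfg, seed = s)
    oh <- enforce_consistency(build_all_levels(ds))
    # annotate roughly half of the root-side OGs
    root_lv <- oh$hierarchy$root
    ogs <- names(oh$ogsets[[root_lv]]$groups)
    annos <- list()
    for (i in seq_along(ogs)) {
      if (i %% 2L == 1L) annos[[ogs[i]]] <- og_annotation(paste("desc", i))
    }
    out <- propagate_annotations(oh, annos)
    n_flagged <- sum(vapply(out, `[[`, logical(1), "inherited"))
    expect_identical(n_flagged, oracle_inherited_count(oh, annos))
  }
})

test_that("functional profiles use annotated members as the denominator", {
  annos <- read_annotations(textConnection_file(c(
    "S1.a\tdesc\tGO:0005524,GO:0016020\t\t\t\t",
    "S1.b\tdesc\tGO:0005524\t\t\t\t",
    "S2.c\tdesc\tGO:0016020\t\t\t\t",
    "S2.d\tdesc\tGO:0003677\t\t\t\t",
    "S3.e\tdesc\t\tko00010,ko00020\t\t\t")))
  prof <- functional_profile(c("S1.a", "S1.b", "S2.c", "S2.d"), annos)
  expect_equal(prof$freq[prof$term == "GO:0005524"], 0.5)
  expect_equal(prof$freq[prof$term == "GO:0016020"], 0.5)
  # one member with two KEGG pathways -> both at frequency 1.0
  prof2 <- functional_profile("S3.e", annos)
  expect_equal(prof2$freq[prof2$namespace == "KEGG"], c(1.0, 1.0))
  # no annotations -> empty profile
  expect_identical(nrow(functional_profile("S9.none", annos)), 0L)
  # frequency times denominator is an integer count
  with_num <- prof$freq * prof$n_annotated
  expect_equal(with_num, round(with_num))
  expect_true(all(prof$freq > 0 & prof$freq <= 1))
})

test_that("OGs sharing a majority clan architecture are merged", {
  annos <- read_annotations(textConnection_file(c(
    "S1.a\t\t\t\t\t\tCL0023,CL0123",
    "S2.b\t\t\t\t\t\tCL0023,CL0123",
    "S3.c\t\t\t\t\t\tCL0999",
    "S1.d\t\t\t\t\t\tCL0023,CL0123",
    "S2.e\t\t\t\t\t\tCL0023,CL0123",
    "S1.f\t\t\t\t\t\tCL0001",
    "S2.g\t\t\t\t\t\tCL0002")))
  os <- og_set("viral", list(v1 = c("S1.a", "S2.b", "S3.c"),
                             v2 = c("S1.d", "S2.e"),
                             v3 = c("S1.f", "S2.g")))
  merged <- merge_by_clan_architecture(os, annos)
  # v1 (majority 2/3) and v2 (2/2) share CL0023|CL0123 -> merged; v3 has a
  # 50/50 tie, untouched
  expect_length(merged$groups, 2L)
  sizes <- sort(lengths(merged$groups))
  expect_identical(unname(sizes), c(2L, 5L))
  # no architecture data at all -> unchanged
  empty_annos <- read_annotations(textConnection_file(character(0)))
  merged2 <- merge_by_clan_architecture(os, empty_annos)
  expect_true(same_partition(unname(merged2$groups), unname(os$groups)))
})

test_that("polyprotein cleavage retains the smallest units, non-redundantly", {
  seqchars <- paste(rep(c(LETTERS[1:25]), 10), collapse = "")
  sequence <- substr(seqchars, 1, 250)
  # two complementary chains
  out <- cleave_polyprotein(sequence, data.frame(start = c(1, 101),
                                                 end = c(100, 250)), "P1")
  expect_identical(nchar(out$seq), c(100L, 150L))
  expect_identical(out$id, c("P1_1-100", "P1_101-250"))
  # a containing chain is discarded
  out2 <- cleave_polyprotein(sequence,
                             data.frame(start = c(1, 1, 101),
                                        end = c(250, 100, 250)), "P1")
  expect_identical(nrow(out2), 2L)
  expect_false("P1_1-250" %in% out2$id)
  # single full-length chain is the identity
  out3 <- cleave_polyprotein(sequence, data.frame(start = 1, end = 250), "P1")
  expect_identical(out3$seq, sequence)
  # out-of-range coordinates rejected
  expect_error(cleave_polyprotein(sequence, data.frame(start = 0, end = 10)),
               "out of range")
  expect_error(cleave_polyprotein(sequence, data.frame(start = 5, end = 251)),
               "out of range")
  # every product is a contiguous substring; non-overlapping chains sum <= length
  expect_true(all(vapply(seq_len(nrow(out)), function(i) {
    grepl(out$seq[i], sequence, fixed = TRUE)
  }, logical(1))))
  expect_lte(sum(nchar(out$seq)), nchar(sequence))
  # duplicate subsequences are deduplicated
  rep_seq <- strrep("AB", 50)
  out4 <- cleave_polyprotein(rep_seq, data.frame(start = c(1, 11), end = c(10, 20)), "P2")
  expect_identical(nrow(out4), 1L)
})
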