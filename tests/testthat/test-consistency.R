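# small builders: an og_set from a plain list, and a two/three-level
# hierarchy used across these tests
mk_set <- function(level, ...) {
  groups <- list(...)
  names(groups) <- paste0(level, "@", seq_along(groups))
  og_set(level, groups)
}

two_level_h <- function(child_sp, root_sp) {
  level_hierarchy(list(
    list(id = "root", name = "root", parent = NA, species = root_sp),
    list(id = "kid", name = "kid", parent = "root", species = child_sp)))
}

test_that("species_overlap intersects the species sets of two groups", {
  expect_length(species_overlap(c("S1.x", "S2.y"), "S3.z"), 0L)
  expect_identical(species_overlap("S1.x", "S1.y"), "S1")
  expect_identical(species_overlap(c("S1.x", "S2.y"), c("S2.z", "S3.w")), "S2")
})

test_that("find_parental_splits reports child OGs divided at the parent", {
  parent <- mk_set("root", c("S1.a1", "S1.a2", "S3.e"), c("S2.b1", "S2.b2"))
  # child OG fully inside one parent OG -> no record
  child_ok <- mk_set("kid", c("S1.a1", "S1.a2"))
  expect_length(find_parental_splits(child_ok, parent), 0L)

  # child OG spanning both parent OGs -> one record, partitions largest first
  child_split <- mk_set("kid", c("S1.a1", "S1.a2", "S2.b1", "S2.b2", "S3.e"))
  recs <- find_parental_splits(child_split, parent)
  expect_length(recs, 1L)
  expect_identical(recs[[1]]$partitions[[1]], c("S1.a1", "S1.a2", "S3.e"))
  expect_identical(recs[[1]]$partitions[[2]], c("S2.b1", "S2.b2"))

  # members unclustered at the parent are excluded and reported
  child_extra <- mk_set("kid", c("S1.a1", "S4.orphan"))
  recs2 <- find_parental_splits(child_extra, parent)
  expect_length(recs2, 0L)
  expect_identical(attr(recs2, "skipped"), "S4.orphan")
})

test_that("a split with no species overlap merges the parent OGs", {
  h <- two_level_h(child_sp = paste0("S", 1:4), root_sp = paste0("S", 1:4))
  parent <- mk_set("root", c("S1.a", "S2.b"), c("S3.c", "S4.d"))
  child <- mk_set("kid", c("S1.a", "S2.b", "S3.c", "S4.d"))
  oh <- og_hierarchy(h, list(root = parent, kid = child))
  out <- enforce_consistency(oh)
  expect_true(is_consistent(out))
  # parents merged into one OG; the child OG untouched
  expect_length(out$ogsets$root$groups, 1L)
  expect_setequal(out$ogsets$root$groups[[1]], c("S1.a", "S2.b", "S3.c", "S4.d"))
  expect_true(same_partition(unname(out$ogsets$kid$groups),
                             list(c("S1.a", "S2.b", "S3.c", "S4.d"))))
  expect_identical(attr(out, "report")$resolution, "merged")
})

test_that("a split with species overlap separates the smaller partition downstream", {
  h <- level_hierarchy(list(
    list(id = "root", name = "root", parent = NA, species = paste0("S", 1:3)),
    list(id = "mid", name = "mid", parent = "root", species = paste0("S", 1:2)),
    list(id = "kid", name = "kid", parent = "mid", species = paste0("S", 1:2))))
  # parent distinguishes lineage a (3 members) from lineage c (2 members);
  # the mid and kid levels lump them -- species overlap {S1,S2} is real
  root <- mk_set("root", c("S1.a", "S2.b", "S3.x"), c("S1.c", "S2.d"))
  mid <- mk_set("mid", c("S1.a", "S2.b", "S1.c", "S2.d"))
  kid <- mk_set("kid", c("S1.a", "S2.b", "S1.c", "S2.d"))
  oh <- og_hierarchy(h, list(root = root, mid = mid, kid = kid))
  out <- enforce_consistency(oh)
  expect_true(is_consistent(out))
  expected <- list(c("S1.a", "S2.b"), c("S1.c", "S2.d"))
  expect_true(same_partition(unname(out$ogsets$mid$groups), expected))
  expect_true(same_partition(unname(out$ogsets$kid$groups), expected))
  expect_true("separated" %in% attr(out, "report")$resolution)
})

test_that("equal-size overlapping partitions use the documented tie-break", {
  h <- two_level_h(child_sp = paste0("S", 1:2), root_sp = paste0("S", 1:2))
  # equal sizes (2 vs 2) but partition {S1.a,S2.b} spans 2 species while
  # {S1.c,S1.d} spans 1 -> the single-species partition is "smaller"
  root <- mk_set("root", c("S1.a", "S2.b"), c("S1.c", "S1.d"))
  child <- mk_set("kid", c("S1.a", "S2.b", "S1.c", "S1.d"))
  oh <- og_hierarchy(h, list(root = root, kid = child))
  out <- enforce_consistency(oh)
  expect_true(is_consistent(out))
  expect_true(same_partition(unname(out$ogsets$kid$groups),
                             list(c("S1.a", "S2.b"), c("S1.c", "S1.d"))))
})

test_that("an already consistent hierarchy is returned unchanged", {
  h <- two_level_h(child_sp = paste0("S", 1:2), root_sp = paste0("S", 1:4))
  root <- mk_set("root", c("S1.a", "S2.b", "S3.c"), c("S1.x", "S4.y"))
  child <- mk_set("kid", c("S1.a", "S2.b"), c("S1.x"))
  oh <- og_hierarchy(h, list(root = root, kid = child))
  out <- enforce_consistency(oh)
  expect_identical(nrow(attr(out, "report")), 0L)
  expect_true(same_partition(unname(out$ogsets$root$groups),
                             unname(root$groups)))
  expect_true(same_partition(unname(out$ogsets$kid$groups),
                             unname(child$groups)))
})

test_that("enforcement is idempotent and conserves proteins", {
  for (s in c(3, 8, 21)) {
    ds <- simulate_dataset(sim_config(), seed = s)
    oh <- build_all_levels(ds)
    before <- lapply(oh$ogsets, function(x) sort(c(unlist(x$groups), x$unclustered)))
    once <- enforce_consistency(oh)
    twice <- enforce_consistency(once)
    expect_true(is_consistent(once))
    for (lv in names(once$ogsets)) {
      expect_identical(og_membership_key(once$ogsets[[lv]]),
                       og_membership_key(twice$ogsets[[lv]]))
      after <- sort(c(unlist(once$ogsets[[lv]]$groups),
                      once$ogsets[[lv]]$unclustered))
      expect_identical(after, before[[lv]])
    }
  }
})

test_that("ground-truth partitions pass enforcement unchanged", {
  ds <- simulate_dataset(sim_config(dup_rate = 0.3), seed = 5)
  truth_sets <- lapply(names(ds$truth), function(lv) {
    og_set(lv, setNames(ds$truth[[lv]], paste0(lv, "@", seq_along(ds$truth[[lv]]))))
  })
  names(truth_sets) <- names(ds$truth)
  oh <- og_hierarchy(ds$tax$hierarchy, truth_sets)
  expect_true(is_consistent(oh))
  out <- enforce_consistency(oh)
  expect_identical(nrow(attr(out, "report")), 0L)
  for (lv in names(truth_sets)) {
    expect_identical(og_membership_key(out$ogsets[[lv]]),
                     og_membership_key(truth_sets[[lv]]))
  }
})
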