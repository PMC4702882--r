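# hand-computed oracle values below follow the in-paralog linking rule
# score(a,b) >= max(bestout(a), bestout(b)) applied manually to each fixture

test_that("in-paralog collapse links same-species pairs closer than any cross-species hit", {
  # score(a,b)=200 beats both bestout values (150, 140) -> one unit
  g <- graph_from_edges(c("S1.a", "S1.a", "S1.b"),
                        c("S1.b", "S2.x", "S2.y"),
                        c(200, 150, 140))
  units <- detect_inparalogs(g)
  expect_true(same_partition(unname(units),
                             list(c("S1.a", "S1.b"), "S2.x", "S2.y")))

  # score(a,b)=100 < bestout(a)=150 -> separate units
  g2 <- graph_from_edges(c("S1.a", "S1.a", "S1.b"),
                         c("S1.b", "S2.x", "S2.y"),
                         c(100, 150, 90))
  units2 <- detect_inparalogs(g2)
  expect_true(same_partition(unname(units2),
                             list("S1.a", "S1.b", "S2.x", "S2.y")))

  # one protein per species -> all singletons
  g3 <- graph_from_edges(c("S1.a", "S2.b"), c("S2.b", "S3.c"), c(100, 100))
  expect_true(all(lengths(detect_inparalogs(g3)) == 1L))
})

test_that("in-paralog collapse matches the brute-force oracle on random graphs", {
  set.seed(42)
  for (rep in 1:40) {
    g <- random_hit_graph(sample(4:20, 1), sample(2:4, 1))
    if (!length(g$nodes)) next
    expect_true(same_partition(unname(detect_inparalogs(g)), oracle_inparalogs(g)),
                info = paste("rep", rep))
  }
})

test_that("unit best hits are reciprocal per species, with ties kept", {
  # two units, one cross edge -> bidirectional best hit
  g <- graph_from_edges("S1.a", "S2.b", 100)
  u <- detect_inparalogs(g)
  bbh <- unit_best_hits(u, g)
  expect_identical(nrow(bbh), 1L)

  # U's best in S2 is V, but V's best in S1 is W -> no U-V edge
  g2 <- graph_from_edges(c("S1.u", "S1.w", "S1.w"),
                         c("S2.v", "S2.v", "S2.z"),
                         c(100, 150, 80))
  u2 <- detect_inparalogs(g2)
  bbh2 <- unit_best_hits(u2, g2)
  unit_of <- setNames(rep(names(u2), lengths(u2)), unlist(u2))
  keys <- paste(pmin(bbh2$u, bbh2$v), pmax(bbh2$u, bbh2$v))
  uv_key <- paste(pmin(unit_of[["S1.u"]], unit_of[["S2.v"]]),
                  pmax(unit_of[["S1.u"]], unit_of[["S2.v"]]))
  wv_key <- paste(pmin(unit_of[["S1.w"]], unit_of[["S2.v"]]),
                  pmax(unit_of[["S1.w"]], unit_of[["S2.v"]]))
  expect_false(uv_key %in% keys)
  expect_true(wv_key %in% keys)

  # equal best scores to two reciprocating partners -> both edges kept
  g3 <- graph_from_edges(c("S1.u", "S1.u"), c("S2.v1", "S2.v2"), c(100, 100))
  u3 <- detect_inparalogs(g3)
  bbh3 <- unit_best_hits(u3, g3)
  expect_identical(nrow(bbh3), 2L)
})

test_that("triangle merging builds OGs from three-species triangles and shared edges", {
  # single triangle over 3 species -> one OG with all members
  tri <- graph_from_edges(c("S1.a", "S2.b", "S1.a"),
                          c("S2.b", "S3.c", "S3.c"),
                          c(100, 100, 100))
  og1 <- build_ogs(tri, list(id = "root", species = paste0("S", 1:3)))
  expect_length(og1$groups, 1L)
  expect_setequal(og1$groups[[1]], c("S1.a", "S2.b", "S3.c"))

  # two triangles sharing an edge -> one OG of 4 units
  edges <- rbind(c("S1.a", "S2.b"), c("S2.b", "S3.c"), c("S1.a", "S3.c"),
                 c("S1.a", "S4.d"), c("S2.b", "S4.d"))
  g2 <- graph_from_edges(edges[, 1], edges[, 2], rep(100, 5))
  og2 <- build_ogs(g2, list(id = "root", species = paste0("S", 1:4)))
  expect_length(og2$groups, 1L)
  expect_setequal(og2$groups[[1]], c("S1.a", "S2.b", "S3.c", "S4.d"))

  # a lone best-hit edge with no triangle still forms a two-unit OG
  g3 <- graph_from_edges("S1.a", "S2.b", 100)
  og3 <- build_ogs(g3, list(id = "root", species = paste0("S", 1:2)))
  expect_length(og3$groups, 1L)
  expect_setequal(og3$groups[[1]], c("S1.a", "S2.b"))
})

test_that("seed clusters are conserved, extended and merged when forced", {
  g <- graph_from_edges(c("S1.a", "S2.b", "S1.a", "S1.x", "S2.y", "S1.x"),
                        c("S2.b", "S3.c", "S3.c", "S2.y", "S3.z", "S3.z"),
                        rep(100, 6))
  level <- list(id = "root", species = paste0("S", 1:3))
  base <- build_ogs(g, level)
  expect_length(base$groups, 2L)

  # seed equal to a computed OG: membership unchanged, origin recorded
  seeded <- extend_seeds(base, list(COG0001 = c("S1.a", "S2.b", "S3.c")))
  expect_true(same_partition(unname(seeded$groups), unname(base$groups)))
  expect_true("COG0001" %in% unlist(seeded$seed_origin))

  # seed spanning the two computed OGs forces their union
  spanning <- extend_seeds(base, list(COG0002 = c("S1.a", "S1.x")))
  expect_length(spanning$groups, 1L)
  expect_setequal(spanning$groups[[1]],
                  c("S1.a", "S2.b", "S3.c", "S1.x", "S2.y", "S3.z"))

  # empty seed set is the identity
  expect_identical(extend_seeds(base, list()), base)

  # unknown seed members are ignored with a warning
  expect_warning(extend_seeds(base, list(X = c("S1.a", "S9.none"))), "unknown")
})

test_that("build_ogs is deterministic and produces disjoint groups", {
  # 3 species, 1 gene each, all pairwise best hits -> one OG
  g <- graph_from_edges(c("S1.a", "S1.a", "S2.b"),
                        c("S2.b", "S3.c", "S3.c"),
                        c(90, 80, 70))
  level <- list(id = "root", species = paste0("S", 1:3))
  og <- build_ogs(g, level)
  expect_length(og$groups, 1L)

  # empty graph -> empty OG set
  none <- build_ogs(symmetrize(data.frame(query = character(0),
                                          subject = character(0),
                                          bitscore = numeric(0))), level)
  expect_length(none$groups, 0L)

  # simulated family with a post-speciation duplication: both same-species
  # copies land in one OG via in-paralog collapsing (checked against truth)
  ds <- simulate_dataset(sim_config(n_families = 1, loss_rate = 0,
                                    noise_sd = 0, dup_rate = 0.3), seed = 7)
  oh <- build_all_levels(ds)
  for (lv in names(ds$truth)) {
    r <- evaluate_recovery(oh$ogsets[[lv]], ds$truth[[lv]])
    expect_equal(r$F, 1.0, info = lv)
  }

  # determinism and disjointness on a noisy dataset
  ds2 <- simulate_dataset(sim_config(), seed = 13)
  a <- build_all_levels(ds2); b <- build_all_levels(ds2)
  for (lv in names(a$ogsets)) {
    expect_identical(a$ogsets[[lv]]$groups, b$ogsets[[lv]]$groups)
    members <- unlist(a$ogsets[[lv]]$groups)
    expect_false(anyDuplicated(members) > 0)
  }
})
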