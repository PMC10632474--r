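# Paralog similarity rules, neighbourhoods and clustering.

# Small graph builder from an explicit edge list: every protein gets a
# self score of 100 and every listed edge a cross bit-score of 50, so both
# compatibility rules pass for listed edges and fail otherwise.
graph_from_edges <- function(proteins, edges) {
  self <- tibble::tibble(query_id = proteins, subject_id = proteins,
                         percent_identity = 100, bit_score = 100)
  cross <- if (length(edges)) {
    tibble::tibble(query_id = vapply(edges, `[`, "", 1),
                   subject_id = vapply(edges, `[`, "", 2),
                   percent_identity = 60, bit_score = 50)
  } else {
    tibble::tibble(query_id = character(), subject_id = character(),
                   percent_identity = numeric(), bit_score = numeric())
  }
  build_similarity_graph(
    dplyr::bind_rows(self, cross),
    tibble::tibble(protein_id = proteins, length = 300L),
    tibble::tibble(protein_id = proteins, cog = "C1"))
}

test_that("length compatibility is an inclusive 60% ratio rule", {
  expect_true(length_compatible(100, 60))
  expect_false(length_compatible(100, 59))
  expect_true(length_compatible(60, 100))
  set.seed(61)
  a <- sample(50:500, 200, replace = TRUE)
  b <- sample(50:500, 200, replace = TRUE)
  expect_equal(length_compatible(a, b),
               pmin(a, b) / pmax(a, b) >= 0.6)
})

test_that("the bit-score rule switches threshold with COG sharing", {
  hits <- tibble::tibble(
    query_id = c("A", "B", "A"), subject_id = c("A", "B", "B"),
    percent_identity = 100, bit_score = c(200, 180, 30))
  self <- self_scores(hits)
  same_cog <- tibble::tibble(protein_id = c("A", "B"), cog = "C9")
  diff_cog <- tibble::tibble(protein_id = c("A", "B"), cog = c("C1", "C2"))
  # Max_bit_score = 200; same COG: 30 >= 0.1*200; different: 30 < 0.2*200
  expect_true(bitscore_compatible("A", "B", hits, self, same_cog))
  expect_false(bitscore_compatible("A", "B", hits, self, diff_cog))
  # no cross hit at all -> incompatible
  no_cross <- hits[1:2, ]
  expect_false(bitscore_compatible("A", "B", no_cross, self, same_cog))
  expect_error(
    bitscore_compatible("A", "Z", hits, self, same_cog), "self hit")
})

test_that("neighbourhoods follow the graph: isolated, clique, path", {
  g3 <- graph_from_edges(c("a", "b", "c", "z"),
                         list(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(first_order_neighbors("z", g3), character(0))
  expect_equal(first_order_neighbors("a", g3), c("b", "c"))
  expect_equal(second_order_neighbors("z", g3), character(0))
  # path a-b-c: second order of a = b's neighbours minus a
  gp <- graph_from_edges(c("a", "b", "c"),
                         list(c("a", "b"), c("b", "c")))
  expect_equal(second_order_neighbors("a", gp), "c")
  # clique of 4: everyone's second-order set is the other three
  g4 <- graph_from_edges(
    c("p", "q", "r", "s"),
    list(c("p", "q"), c("p", "r"), c("p", "s"), c("q", "r"),
         c("q", "s"), c("r", "s")))
  for (x in c("p", "q", "r", "s")) {
    expect_equal(second_order_neighbors(x, g4),
                 sort(setdiff(c("p", "q", "r", "s"), x)))
  }
})

test_that("first-order neighbourhoods equal the adjacency oracle", {
  set.seed(67)
  proteins <- sprintf("n%02d", 1:12)
  all_pairs <- t(combn(proteins, 2))
  pick <- runif(nrow(all_pairs)) < 0.3
  edges <- lapply(which(pick), function(i) all_pairs[i, ])
  g <- graph_from_edges(proteins, edges)
  for (p in proteins) {
    oracle <- sort(unique(c(
      all_pairs[pick & all_pairs[, 1] == p, 2],
      all_pairs[pick & all_pairs[, 2] == p, 1])))
    expect_equal(first_order_neighbors(p, g), oracle)
  }
})

test_that("disjoint cliques cluster into exactly their components", {
  g <- graph_from_edges(
    c("a1", "a2", "a3", "b1", "b2", "b3"),
    list(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
         c("b1", "b2"), c("b1", "b3"), c("b2", "b3")))
  groups <- cluster_paralogs(g)
  split_groups <- split(groups$protein_id, groups$group_id)
  expect_equal(length(split_groups), 2)
  expect_equal(canon_sets(split_groups),
               canon_sets(list(c("a1", "a2", "a3"), c("b1", "b2", "b3"))))
  # uniform 2-cliques are likewise recovered whole
  g2 <- graph_from_edges(c("x1", "x2", "y1", "y2"),
                         list(c("x1", "x2"), c("y1", "y2")))
  groups2 <- cluster_paralogs(g2)
  expect_equal(canon_sets(split(groups2$protein_id, groups2$group_id)),
               canon_sets(list(c("x1", "x2"), c("y1", "y2"))))
})

test_that("an edgeless proteome reports no paralog groups", {
  g <- graph_from_edges(c("a", "b", "c"), list())
  groups <- cluster_paralogs(g)
  expect_equal(nrow(groups), 0)
  # but the internal partition still assigns every protein once
  part <- attr(groups, "partition")
  expect_setequal(part$protein_id, c("a", "b", "c"))
  expect_true(all(part$group_size == 1))
})

test_that("clustering is invariant to input row order", {
  set.seed(71)
  u <- simulate_blast_universe(n_families = 6,
                               family_sizes = c(4, 3, 2, 5, 1, 3),
                               seed = 7)
  g1 <- build_similarity_graph(u$hits, u$proteins, u$cog_map)
  shuffle <- sample.int(nrow(u$hits))
  g2 <- build_similarity_graph(u$hits[shuffle, ], u$proteins, u$cog_map)
  expect_identical(cluster_paralogs(g1), cluster_paralogs(g2))
})

test_that("the six-protein worked example clusters as hand-computed", {
  fx <- six_protein_universe()
  g <- build_similarity_graph(fx$hits, fx$proteins, fx$cog_map)
  # edges: P1-P2 (90 >= 0.1*800), P1-P3 (85 >= 80), P2-P3 (82 >= 76),
  # P2-P5 (80 >= 79); P1-P5 fails (70 < 80); P3-P4 fails only because the
  # COGs differ (100 < 0.2*720, though 100 >= 0.1*720); P6 is isolated
  expect_equal(nrow(g$edges), 4)
  expect_equal(first_order_neighbors("P1", g), c("P2", "P3"))
  expect_equal(first_order_neighbors("P4", g), character(0))
  # second-order counts: P1 -> {P2,P3,P5}, P3 -> {P1,P2,P5}, P2 -> {P1,P3},
  # P5 -> {P1,P3}; reference is P1 (ties with P3 break lexicographically)
  expect_equal(second_order_neighbors("P1", g), c("P2", "P3", "P5"))
  expect_equal(second_order_neighbors("P2", g), c("P1", "P3"))
  groups <- cluster_paralogs(g)
  expect_equal(unique(groups$reference_protein), "P1")
  expect_setequal(groups$protein_id, c("P1", "P2", "P3", "P5"))
  # flipping P4's COG to match P3 adds the P3-P4 edge (0.1 rule now applies)
  cog2 <- fx$cog_map
  cog2$cog[cog2$protein_id == "P4"] <- "C0001"
  g2 <- build_similarity_graph(fx$hits, fx$proteins, cog2)
  expect_equal(nrow(g2$edges), 5)
  expect_true("P4" %in% first_order_neighbors("P3", g2))
})

test_that("clustering recovers planted families from the toy universe", {
  u <- simulate_blast_universe(n_families = 12, seed = 29)
  g <- build_similarity_graph(u$hits, u$proteins, u$cog_map)
  groups <- cluster_paralogs(g)
  got <- canon_sets(split(groups$protein_id, groups$group_id))
  want <- canon_sets(split(u$truth_groups$protein_id,
                           u$truth_groups$family_id))
  expect_equal(got, want)
  # reported groups are pairwise disjoint
  expect_equal(anyDuplicated(groups$protein_id), 0L)
})

test_that("group summaries count compositions like a tally oracle", {
  groups <- tibble::tibble(
    group_id = c("G1", "G1", "G2", "G2"),
    reference_protein = c("a", "a", "c", "c"),
    protein_id = c("a", "b", "c", "d"),
    group_size = 2L)
  calls <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                          label = c("essential", "essential",
                                    "essential", "non_essential"))
  s <- summarize_paralog_groups(groups, calls)
  expect_equal(s$overview$pure_essential, 1L)
  expect_equal(s$overview$mixed, 1L)
  expect_equal(s$overview$n_genes, 4L)

  empty <- groups[0, ]
  s0 <- summarize_paralog_groups(empty, calls)
  expect_equal(s0$overview$n_groups, 0L)
  expect_equal(s0$overview$max_group_size, 0L)

  expect_error(summarize_paralog_groups(
    groups, calls[1:2, ]), "without essentiality call")

  # randomised tally oracle
  set.seed(73)
  n_g <- 40
  sizes <- sample(2:6, n_g, replace = TRUE)
  gid <- rep(sprintf("G%02d", 1:n_g), sizes)
  pid <- sprintf("p%03d", seq_along(gid))
  rg <- tibble::tibble(group_id = gid, reference_protein = gid,
                       protein_id = pid,
                       group_size = rep(sizes, sizes))
  rc <- tibble::tibble(
    feature_id = pid,
    label = sample(c("essential", "non_essential", "unclear",
                     "domain_essential"), length(pid), replace = TRUE))
  s <- summarize_paralog_groups(rg, rc)
  eff <- ifelse(rc$label == "domain_essential", "essential", rc$label)
  names(eff) <- rc$feature_id
  oracle_pure_e <- sum(vapply(split(pid, gid), function(ids)
    all(eff[ids] == "essential"), logical(1)))
  expect_equal(s$overview$pure_essential, oracle_pure_e)
  expect_equal(s$overview$n_groups, n_g)
})
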