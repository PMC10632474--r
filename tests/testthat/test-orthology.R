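# BLAST filtering, bidirectional best hits, comparative essentiality,
# conservation profiling.

make_hits <- function(q, s, bit, pid = 50, ev = 1e-30, qcov = 100,
                      scov = 100) {
  tibble::tibble(query_id = q, subject_id = s, percent_identity = pid,
                 evalue = ev, bit_score = bit, query_cov = qcov,
                 subject_cov = scov)
}

test_that("filter boundaries are inclusive, per 'at least' semantics", {
  hits <- make_hits(c("a", "b", "c", "d"), c("x", "x", "x", "x"),
                    bit = 100,
                    ev = c(1e-5, 1e-4, 1e-6, 1e-6),
                    qcov = c(70, 99, 69.9, 99),
                    scov = c(70, 99, 99, 69.9))
  kept <- filter_hits(hits)
  expect_equal(kept$query_id, "a")
})

test_that("filtering equals the predicate oracle and is monotone", {
  set.seed(41)
  n <- 500
  hits <- make_hits(sprintf("q%d", 1:n), "s",
                    bit = runif(n, 30, 300),
                    ev = 10^runif(n, -60, 0),
                    qcov = runif(n, 0, 100), scov = runif(n, 0, 100))
  kept <- filter_hits(hits)
  oracle <- hits[hits$evalue <= 1e-5 & hits$query_cov >= 70 &
                   hits$subject_cov >= 70, ]
  expect_equal(kept, oracle)
  tighter <- filter_hits(hits, max_evalue = 1e-10, min_qcov = 80,
                         min_scov = 90)
  expect_true(all(tighter$query_id %in% kept$query_id))
})

test_that("mutual best hits pair up; one-sided bests do not", {
  ab <- make_hits(c("a1", "a2"), c("b1", "b2"), bit = c(200, 150))
  ba <- make_hits(c("b1", "b2"), c("a1", "a2"), bit = c(190, 140))
  pairs <- bidirectional_best_hits(ab, ba)
  expect_equal(pairs$id_a, c("a1", "a2"))
  expect_equal(pairs$bit_score_ab, c(200, 150))
  # b1's best flips to a2 -> a1/b1 no longer mutual
  ba2 <- make_hits(c("b1", "b1", "b2"), c("a1", "a2", "a2"),
                   bit = c(190, 250, 140))
  pairs2 <- bidirectional_best_hits(ab, ba2)
  expect_false("a1" %in% pairs2$id_a)
})

test_that("close runner-up bit-scores mark a query as unresolvable paralogy", {
  ab <- make_hits(c("a1", "a1"), c("b1", "b2"), bit = c(200, 195))
  ba <- make_hits("b1", "a1", bit = 198)
  expect_equal(nrow(bidirectional_best_hits(ab, ba)), 0)  # 195 >= 180
  ab2 <- make_hits(c("a1", "a1"), c("b1", "b2"), bit = c(200, 150))
  expect_equal(nrow(bidirectional_best_hits(ab2, ba)), 1)  # 150 < 180
})

test_that("the BBH pair set is symmetric under swapping the two tables", {
  set.seed(43)
  for (rep in 1:5) {
    na <- 15; nb <- 12
    ab <- make_hits(sprintf("a%d", sample(1:na, 60, replace = TRUE)),
                    sprintf("b%d", sample(1:nb, 60, replace = TRUE)),
                    bit = round(runif(60, 50, 400), 1),
                    pid = round(runif(60, 30, 99), 1))
    ba <- make_hits(sprintf("b%d", sample(1:nb, 60, replace = TRUE)),
                    sprintf("a%d", sample(1:na, 60, replace = TRUE)),
                    bit = round(runif(60, 50, 400), 1),
                    pid = round(runif(60, 30, 99), 1))
    fwd <- bidirectional_best_hits(ab, ba)
    rev <- bidirectional_best_hits(ba, ab)
    expect_equal(
      dplyr::arrange(fwd[c("id_a", "id_b")], id_a),
      dplyr::arrange(tibble::tibble(id_a = rev$id_b, id_b = rev$id_a),
                     id_a))
  }
})

label_tbl <- function(ids, labels) {
  tibble::tibble(feature_id = ids, label = labels)
}

test_that("the agreement table reproduces a hand-labelled example", {
  pairs <- tibble::tibble(id_a = c("a1", "a2", "a3", "a4"),
                          id_b = c("b1", "b2", "b3", "b4"))
  ca <- label_tbl(paste0("a", 1:4),
                  c("essential", "non_essential", "essential",
                    "non_essential"))
  cb <- label_tbl(paste0("b", 1:4),
                  c("essential", "non_essential", "non_essential",
                    "unclear"))
  cmp <- compare_essentiality(pairs, ca, cb)
  g <- glance(cmp)
  expect_equal(g$n_agree, 2L)
  expect_equal(g$agreement_percent, 50)
  expect_equal(g$agree_essential, 1L)
  expect_equal(g$essential_a_only, 1L)
})

test_that("an empty pair set yields an empty, division-safe table", {
  pairs <- tibble::tibble(id_a = character(), id_b = character())
  cmp <- compare_essentiality(pairs, label_tbl("a", "essential"),
                              label_tbl("b", "unclear"))
  g <- glance(cmp)
  expect_equal(g$n_pairs, 0L)
  expect_true(is.na(g$agreement_percent))
  expect_equal(sum(tidy(cmp)$n), 0L)
})

test_that("the 3x3 contingency matches a counting oracle on random labels", {
  set.seed(47)
  labs <- c("essential", "non_essential", "unclear")
  n <- 1000
  ca <- label_tbl(sprintf("a%d", 1:n), sample(labs, n, replace = TRUE))
  cb <- label_tbl(sprintf("b%d", 1:n), sample(labs, n, replace = TRUE))
  pairs <- tibble::tibble(id_a = ca$feature_id, id_b = cb$feature_id)
  cmp <- compare_essentiality(pairs, ca, cb)
  oracle <- as.data.frame(table(a = ca$label, b = cb$label),
                          stringsAsFactors = FALSE)
  tidy_tab <- tidy(cmp)
  for (i in seq_len(nrow(oracle))) {
    got <- tidy_tab$n[tidy_tab$label_a == oracle$a[i] &
                        tidy_tab$label_b == oracle$b[i]]
    expect_equal(got, oracle$Freq[i])
  }
  expect_error(
    compare_essentiality(tibble::tibble(id_a = "zz", id_b = "b1"), ca, cb),
    "without calls")
})

# --- conservation ---

cons_fixture <- function() {
  # 6 species over 3 nested levels; two strains of sp1 collapse
  org2sp <- tibble::tibble(
    organism = c("o1a", "o1b", "o2", "o3", "o4", "o5", "o6"),
    species = c("sp1", "sp1", "sp2", "sp3", "sp4", "sp5", "sp6"))
  sp2tax <- tibble::tibble(
    species = paste0("sp", 1:6),
    taxon = c("Planctomycetes", "Planctomycetes", "PVC", "PVC",
              "Prokaryotes", "Prokaryotes"))
  list(org2sp = org2sp, sp2tax = sp2tax)
}

test_that("conservation levels nest and classify genes by species reach", {
  fx <- cons_fixture()
  hits <- tibble::tibble(
    query_id = c("g1", "g1", "g2", "g2", "g3"),
    organism = c("o1a", "o1b", "o3", "o1a", "o5"))
  calls <- label_tbl(c("g1", "g2", "g3", "g4"),
                     c("essential", "non_essential", "essential",
                       "unclear"))
  rec <- conservation_profile(hits, fx$org2sp, fx$sp2tax, calls)
  expect_equal(rec$specific_level[rec$feature_id == "g1"],
               "Planctomycetes")
  expect_equal(rec$specific_level[rec$feature_id == "g2"], "PVC")
  expect_equal(rec$specific_level[rec$feature_id == "g3"], "Prokaryotes")
  # strain collapse: g1 hits two strains of one species
  expect_equal(rec$n_species[rec$feature_id == "g1"], 1L)
  # no hits: innermost level by convention, flagged
  expect_true(rec$no_external_homologs[rec$feature_id == "g4"])
  expect_equal(rec$specific_level[rec$feature_id == "g4"],
               "Planctomycetes")
  s <- conservation_summary(rec)
  expect_true(all(diff(s$total) >= 0))  # nested counts never shrink
  expect_equal(s$total[s$level == "Prokaryotes"], 4L)
})

test_that("the level summary matches a set-cover oracle on a toy universe", {
  set.seed(53)
  fx <- cons_fixture()
  genes <- sprintf("g%02d", 1:30)
  hits <- tibble::tibble(
    query_id = sample(genes, 120, replace = TRUE),
    organism = sample(fx$org2sp$organism, 120, replace = TRUE))
  calls <- label_tbl(genes, sample(c("essential", "non_essential",
                                     "unclear"), 30, replace = TRUE))
  rec <- conservation_profile(hits, fx$org2sp, fx$sp2tax, calls)
  depth <- c(Planctomycetes = 1, PVC = 2, Prokaryotes = 3)
  tax_of_org <- depth[fx$sp2tax$taxon[
    match(fx$org2sp$species, fx$sp2tax$species)]]
  names(tax_of_org) <- fx$org2sp$organism
  oracle_level <- vapply(genes, function(g) {
    orgs <- hits$organism[hits$query_id == g]
    if (length(orgs) == 0) return("Planctomycetes")
    names(depth)[max(tax_of_org[orgs])]
  }, character(1))
  expect_equal(setNames(rec$specific_level, rec$feature_id),
               oracle_level)
})

test_that("unmapped organisms are reported as a hard error", {
  fx <- cons_fixture()
  hits <- tibble::tibble(query_id = "g1", organism = "mystery")
  calls <- label_tbl("g1", "essential")
  expect_error(conservation_profile(hits, fx$org2sp, fx$sp2tax, calls),
               "mystery")
})
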