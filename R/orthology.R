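#' Filter BLAST hits on E-value and alignment coverage
#'
#' Keeps a hit iff `evalue <= max_evalue` and both query and subject
#' coverage are `>= ` their minima; all three boundaries are inclusive.
#' Tightening any threshold can only remove hits.
#'
#' @param hits Hit tibble from [read_blast_tabular()] with coverage columns.
#' @param max_evalue Maximum E-value (default 1e-5).
#' @param min_qcov,min_scov Minimum query / subject coverage in percent
#'   (default 70).
#' @return The filtered hit tibble.
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, min_qcov = 70,
                        min_scov = 70) {
  check_columns(hits, c("evalue", "query_cov", "subject_cov"))
  if (anyNA(hits$query_cov) || anyNA(hits$subject_cov)) {
    abort("Coverage columns contain NA; read the BLAST table with qlen/slen.")
  }
  filter(hits,
         .data$evalue <= max_evalue,
         .data$query_cov >= min_qcov,
         .data$subject_cov >= min_scov)
}

# Best hit per query with deterministic tie-breaking: bit-score, then
# percent identity, then lexicographic subject id.  Also reports the
# runner-up bit-score (best hit to a *different* subject).
best_hits_per_query <- function(hits) {
  check_columns(hits, c("query_id", "subject_id", "bit_score",
                        "percent_identity"))
  per_pair <- hits |>
    group_by(.data$query_id, .data$subject_id) |>
    summarise(bit_score = max(.data$bit_score),
              percent_identity = max(.data$percent_identity),
              .groups = "drop")
  per_pair |>
    arrange(.data$query_id, desc(.data$bit_score),
            desc(.data$percent_identity), .data$subject_id) |>
    group_by(.data$query_id) |>
    summarise(
      best_subject = first(.data$subject_id),
      best_bit = first(.data$bit_score),
      runner_up_bit = if (n() > 1) .data$bit_score[2] else NA_real_,
      .groups = "drop"
    )
}

#' Bidirectional best-hit ortholog pairs
#'
#' Computes the best hit of every query in both directions (A vs B and
#' B vs A) and emits the pair (a, b) iff each is the other's best hit.
#' Proteins with paralogies that are hard to resolve are discarded: if
#' either side has a runner-up hit with bit-score at least
#' `paralogy_margin` times its best bit-score, the pair is dropped.  Ties
#' for best hit are broken by bit-score, then percent identity, then
#' lexicographic subject id, so the pair set is deterministic and symmetric
#' under swapping the two tables.
#'
#' @param hits_ab Filtered hits of proteome A queried against B.
#' @param hits_ba Filtered hits of proteome B queried against A.
#' @param paralogy_margin Runner-up bit-score fraction above which a query
#'   is considered ambiguous (default 0.9).
#' @return A tibble with `id_a`, `id_b`, `bit_score_ab`, `bit_score_ba`.
#'   Each id appears in at most one pair.
#' @export
bidirectional_best_hits <- function(hits_ab, hits_ba,
                                    paralogy_margin = 0.9) {
  stopifnot(paralogy_margin > 0, paralogy_margin <= 1)
  best_ab <- best_hits_per_query(hits_ab)
  best_ba <- best_hits_per_query(hits_ba)
  ambiguous <- function(b) {
    !is.na(b$runner_up_bit) & b$runner_up_bit >= paralogy_margin * b$best_bit
  }
  best_ab <- filter(best_ab, !ambiguous(best_ab))
  best_ba <- filter(best_ba, !ambiguous(best_ba))
  inner_join(
    select(best_ab, id_a = "query_id", id_b = "best_subject",
           bit_score_ab = "best_bit"),
    select(best_ba, id_b = "query_id", id_a = "best_subject",
           bit_score_ba = "best_bit"),
    by = c("id_a", "id_b")
  ) |>
    arrange(.data$id_a)
}

#' Cross-species essentiality agreement over an ortholog map
#'
#' Joins per-species call labels onto a BBH pair table and tabulates the
#' 3x3 label contingency (`essential` / `non_essential` / `unclear`), the
#' agreement fraction, and the discordant gene lists.
#'
#' @param pairs BBH tibble from [bidirectional_best_hits()].
#' @param calls_a,calls_b Call tibbles with `feature_id` and `label` for
#'   proteomes A and B.
#' @return An object of class `essentiality_comparison`: a list with
#'   `pairs` (the pair table with `label_a`, `label_b`, `agree`),
#'   `contingency` (3x3 count tibble) and `n_pairs`.  Use `tidy()` for the
#'   contingency in long form and `glance()` for the headline agreement
#'   statistics.
#' @export
compare_essentiality <- function(pairs, calls_a, calls_b) {
  check_columns(pairs, c("id_a", "id_b"))
  check_columns(calls_a, c("feature_id", "label"))
  check_columns(calls_b, c("feature_id", "label"))
  labs <- c("essential", "non_essential", "unclear")
  missing_a <- setdiff(pairs$id_a, calls_a$feature_id)
  missing_b <- setdiff(pairs$id_b, calls_b$feature_id)
  if (length(missing_a) || length(missing_b)) {
    abort(sprintf("Pairs reference genes without calls: %s",
                  paste(head(c(missing_a, missing_b), 5), collapse = ", ")))
  }
  tagged <- pairs |>
    left_join(select(calls_a, id_a = "feature_id", label_a = "label"),
              by = "id_a") |>
    left_join(select(calls_b, id_b = "feature_id", label_b = "label"),
              by = "id_b") |>
    mutate(agree = .data$label_a == .data$label_b)
  contingency <- tagged |>
    count(label_a = factor(.data$label_a, labs),
          label_b = factor(.data$label_b, labs), .drop = FALSE) |>
    mutate(label_a = as.character(.data$label_a),
           label_b = as.character(.data$label_b))
  structure(
    list(pairs = tagged, contingency = contingency, n_pairs = nrow(tagged)),
    class = "essentiality_comparison"
  )
}

#' @export
print.essentiality_comparison <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Essentiality comparison over %d ortholog pairs\n", x$n_pairs))
  cat(sprintf("  agree: %d (%.1f%%); of which essential %d, non-essential %d, unclear %d\n",
              g$n_agree, g$agreement_percent, g$agree_essential,
              g$agree_non_essential, g$agree_unclear))
  cat(sprintf("  essential only in A: %d; only in B: %d\n",
              g$essential_a_only, g$essential_b_only))
  invisible(x)
}

#' Tidy / summarise an essentiality comparison
#'
#' `tidy()` returns the 3x3 contingency in long form; `glance()` a one-row
#' summary: pair count, agreement count and percentage, agreeing counts per
#' label, and discordant counts.
#'
#' @param x An `essentiality_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.essentiality_comparison <- function(x, ...) {
  x$contingency
}

#' @rdname tidy.essentiality_comparison
#' @export
glance.essentiality_comparison <- function(x, ...) {
  p <- x$pairs
  n <- nrow(p)
  n_agree <- sum(p$agree)
  tibble(
    n_pairs = n,
    n_agree = n_agree,
    agreement_percent = if (n > 0) 100 * n_agree / n else NA_real_,
    agree_essential = sum(p$agree & p$label_a == "essential"),
    agree_non_essential = sum(p$agree & p$label_a == "non_essential"),
    agree_unclear = sum(p$agree & p$label_a == "unclear"),
    essential_a_only = sum(p$label_a == "essential" &
                             p$label_b != "essential"),
    essential_b_only = sum(p$label_b == "essential" &
                             p$label_a != "essential")
  )
}

#' Taxonomic conservation profile of query genes
#'
#' For each query gene, collects the set of species with at least one
#' surviving BLAST hit (hits are grouped by species to collapse strain-level
#' differences) and assigns the innermost taxonomic level that contains all
#' of them.  Levels are nested, innermost first (default
#' Planctomycetes within PVC within Prokaryotes): a gene is *specific to*
#' level L when every species it hits maps to a taxon at or inside L.
#' Genes with no surviving hits are specific to the innermost level by
#' convention and flagged `no_external_homologs`.
#'
#' @param hits Filtered hit tibble carrying an `organism` column (the
#'   subject's organism identifier) in addition to `query_id`.
#' @param organism_to_species Tibble (`organism`, `species`) collapsing
#'   strains into species.
#' @param species_to_taxon Tibble (`species`, `taxon`); every taxon must be
#'   one of `level_order`.
#' @param calls Call tibble for the query genes (`feature_id`, `label`).
#' @param level_order Character vector of nested levels, innermost first.
#' @return A tibble with one row per query gene: `feature_id`, `label`,
#'   `n_species`, `specific_level`, `no_external_homologs`.  Summarise with
#'   [conservation_summary()].
#' @export
conservation_profile <- function(hits, organism_to_species, species_to_taxon,
                                 calls,
                                 level_order = c("Planctomycetes", "PVC",
                                                 "Prokaryotes")) {
  check_columns(hits, c("query_id", "organism"))
  check_columns(organism_to_species, c("organism", "species"))
  check_columns(species_to_taxon, c("species", "taxon"))
  check_columns(calls, c("feature_id", "label"))
  unmapped <- setdiff(unique(hits$organism), organism_to_species$organism)
  if (length(unmapped) > 0) {
    abort(sprintf("Organism(s) without species mapping: %s",
                  paste(head(unmapped, 10), collapse = ", ")))
  }
  sp_tax <- species_to_taxon
  bad_tax <- setdiff(unique(sp_tax$taxon), level_order)
  if (length(bad_tax) > 0) {
    abort(sprintf("Taxon(s) outside level_order: %s",
                  paste(bad_tax, collapse = ", ")))
  }
  unmapped_sp <- setdiff(unique(organism_to_species$species), sp_tax$species)
  if (length(unmapped_sp) > 0) {
    abort(sprintf("Species without taxon mapping: %s",
                  paste(head(unmapped_sp, 10), collapse = ", ")))
  }
  depth <- setNames(seq_along(level_order), level_order)
  per_gene <- hits |>
    left_join(organism_to_species, by = "organism") |>
    left_join(sp_tax, by = "species") |>
    distinct(.data$query_id, .data$species, .data$taxon) |>
    group_by(.data$query_id) |>
    summarise(n_species = dplyr::n_distinct(.data$species),
              max_depth = max(depth[.data$taxon]),
              .groups = "drop")
  calls |>
    select("feature_id", "label") |>
    left_join(per_gene, by = c(feature_id = "query_id")) |>
    mutate(
      no_external_homologs = is.na(.data$n_species),
      n_species = dplyr::coalesce(.data$n_species, 0L),
      specific_level = level_order[dplyr::coalesce(.data$max_depth, 1L)]
    ) |>
    select(-"max_depth")
}

#' Nested conservation summary by essentiality label
#'
#' Counts genes specific to each nested taxonomic level, split by call
#' label.  Because the levels are nested, a gene specific to the innermost
#' level is also counted at every enclosing level, so counts are
#' monotonically non-decreasing from innermost to outermost.
#'
#' @param records Tibble from [conservation_profile()].
#' @param level_order The same nested level vector, innermost first.
#' @return A tibble with one row per level: `level`, `essential`,
#'   `non_essential`, `unclear`, `total`.
#' @export
conservation_summary <- function(records,
                                 level_order = c("Planctomycetes", "PVC",
                                                 "Prokaryotes")) {
  check_columns(records, c("feature_id", "label", "specific_level"))
  depth <- setNames(seq_along(level_order), level_order)
  gene_depth <- depth[records$specific_level]
  purrr::map_dfr(seq_along(level_order), function(i) {
    within <- gene_depth <= i
    tibble(
      level = level_order[i],
      essential = sum(within & records$label == "essential"),
      non_essential = sum(within & records$label == "non_essential"),
      unclear = sum(within & records$label == "unclear"),
      total = sum(within)
    )
  })
}
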