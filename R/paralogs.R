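#' Length compatibility rule for paralog candidates
#'
#' Two proteins are length-compatible when the shorter is at least
#' `min_len_frac` (default 60%) of the length of the longer; the boundary
#' is inclusive.
#'
#' @param len_a,len_b Positive protein lengths (vectorised).
#' @param min_len_frac Minimum shorter/longer length ratio.
#' @return Logical vector.
#' @export
length_compatible <- function(len_a, len_b, min_len_frac = 0.6) {
  stopifnot(all(len_a > 0), all(len_b > 0))
  pmin(len_a, len_b) / pmax(len_a, len_b) >= min_len_frac
}

#' Extract self bit-scores from an all-vs-all hit table
#'
#' @param hits BLAST-6-shaped tibble including self hits
#'   (`query_id == subject_id`).
#' @return Tibble (`protein_id`, `self_score`), taking the maximum when a
#'   self comparison appears more than once.
#' @export
self_scores <- function(hits) {
  check_columns(hits, c("query_id", "subject_id", "bit_score"))
  hits |>
    filter(.data$query_id == .data$subject_id) |>
    group_by(protein_id = .data$query_id) |>
    summarise(self_score = max(.data$bit_score), .groups = "drop")
}

#' Bit-score compatibility rule for paralog candidates
#'
#' For proteins a and b, `Max_bit_score` is the larger of their two self
#' bit-scores, and the cross score is the larger of the a-vs-b and b-vs-a
#' hit bit-scores (0 when no hit exists).  The pair is compatible when the
#' cross score reaches `same_cog_frac` (default 0.1) of `Max_bit_score` if
#' a and b share at least one COG label, or `diff_cog_frac` (default 0.2)
#' otherwise.
#'
#' @param a,b Protein ids (scalar).
#' @param hits All-vs-all hit tibble.
#' @param self Tibble from [self_scores()] (must cover a and b).
#' @param cog_map Tibble (`protein_id`, `cog`); a protein may have several
#'   rows (multi-label).  Proteins absent from the map share no COG.
#' @param same_cog_frac,diff_cog_frac Threshold fractions of
#'   `Max_bit_score`.
#' @return Logical scalar.
#' @export
bitscore_compatible <- function(a, b, hits, self, cog_map,
                                same_cog_frac = 0.1, diff_cog_frac = 0.2) {
  ss <- setNames(self$self_score, self$protein_id)
  if (!all(c(a, b) %in% names(ss))) {
    abort(sprintf("Missing self hit for: %s",
                  paste(setdiff(c(a, b), names(ss)), collapse = ", ")))
  }
  max_bit <- max(ss[[a]], ss[[b]])
  cross <- hits$bit_score[(hits$query_id == a & hits$subject_id == b) |
                            (hits$query_id == b & hits$subject_id == a)]
  cross <- if (length(cross) == 0) 0 else max(cross)
  cogs_a <- cog_map$cog[cog_map$protein_id == a]
  cogs_b <- cog_map$cog[cog_map$protein_id == b]
  frac <- if (length(intersect(cogs_a, cogs_b)) > 0) same_cog_frac else
    diff_cog_frac
  cross >= frac * max_bit
}

#' Build the paralog similarity graph
#'
#' Applies the length and bit-score compatibility rules to every pair of
#' proteins with a BLAST hit between them and returns the resulting
#' undirected similarity graph.  Every protein must have a self hit (the
#' bit-score normaliser).
#'
#' @param hits All-vs-all self-proteome hit tibble including self hits.
#' @param proteins Tibble (`protein_id`, `length`).
#' @param cog_map Tibble (`protein_id`, `cog`), multi-label allowed.
#' @param min_len_frac,same_cog_frac,diff_cog_frac Rule thresholds (see
#'   [length_compatible()] and [bitscore_compatible()]).
#' @return An object of class `similarity_graph`: list with `proteins`
#'   (character vector), `self_score` (named numeric), `edges` (tibble
#'   `a`, `b` with `a < b`), and `adjacency` (named list of neighbour
#'   vectors).
#' @export
build_similarity_graph <- function(hits, proteins, cog_map,
                                   min_len_frac = 0.6,
                                   same_cog_frac = 0.1,
                                   diff_cog_frac = 0.2) {
  check_columns(proteins, c("protein_id", "length"))
  check_columns(cog_map, c("protein_id", "cog"))
  self <- self_scores(hits)
  missing_self <- setdiff(proteins$protein_id, self$protein_id)
  if (length(missing_self) > 0) {
    abort(sprintf("Protein(s) without self hit: %s",
                  paste(head(missing_self, 10), collapse = ", ")))
  }
  len <- setNames(proteins$length, proteins$protein_id)
  ss <- setNames(self$self_score, self$protein_id)

  cross_raw <- filter(hits,
                      .data$query_id != .data$subject_id,
                      .data$query_id %in% proteins$protein_id,
                      .data$subject_id %in% proteins$protein_id)
  cross <- if (nrow(cross_raw) > 0) {
    cross_raw |>
      mutate(a = pmin(.data$query_id, .data$subject_id),
             b = pmax(.data$query_id, .data$subject_id)) |>
      group_by(.data$a, .data$b) |>
      summarise(cross_bit = max(.data$bit_score), .groups = "drop")
  } else {
    tibble(a = character(), b = character(), cross_bit = numeric())
  }

  if (nrow(cross) > 0) {
    cog_sets <- split(cog_map$cog, cog_map$protein_id)
    shares_cog <- purrr::map2_lgl(cross$a, cross$b, function(a, b) {
      length(intersect(cog_sets[[a]] %||% character(),
                       cog_sets[[b]] %||% character())) > 0
    })
    cross <- cross |>
      mutate(
        len_ok = length_compatible(len[.data$a], len[.data$b], min_len_frac),
        max_bit = pmax(ss[.data$a], ss[.data$b]),
        frac = ifelse(shares_cog, same_cog_frac, diff_cog_frac),
        bit_ok = .data$cross_bit >= .data$frac * .data$max_bit
      )
    edges <- cross |>
      filter(.data$len_ok, .data$bit_ok) |>
      select("a", "b") |>
      arrange(.data$a, .data$b)
  } else {
    edges <- tibble(a = character(), b = character())
  }

  adjacency <- setNames(
    vector("list", nrow(proteins)), sort(proteins$protein_id))
  for (p in names(adjacency)) adjacency[[p]] <- character()
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]
    adjacency[[a]] <- c(adjacency[[a]], b)
    adjacency[[b]] <- c(adjacency[[b]], a)
  }
  adjacency <- lapply(adjacency, function(v) sort(unique(v)))
  structure(
    list(proteins = sort(proteins$protein_id),
         self_score = ss, edges = edges, adjacency = adjacency),
    class = "similarity_graph"
  )
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("Similarity graph: %d proteins, %d edges\n",
              length(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' First- and second-order similarity neighbours
#'
#' `first_order_neighbors()` returns every protein q != p that satisfies
#' both compatibility rules against p (an edge in the similarity graph).
#' `second_order_neighbors()` returns the non-redundant union of the
#' first-order neighbours of p's first-order neighbours, excluding p
#' itself.
#'
#' @param p Protein id.
#' @param graph A `similarity_graph`.
#' @param within Optional character vector restricting the graph to a
#'   subset of proteins (used during clustering, where assigned proteins
#'   are no longer considered).
#' @return Sorted character vector of protein ids.
#' @export
first_order_neighbors <- function(p, graph, within = NULL) {
  stopifnot(inherits(graph, "similarity_graph"))
  nb <- graph$adjacency[[p]] %||% character()
  if (!is.null(within)) nb <- nb[nb %in% within]
  nb
}

#' @rdname first_order_neighbors
#' @export
second_order_neighbors <- function(p, graph, within = NULL) {
  fo <- first_order_neighbors(p, graph, within)
  so <- unique(unlist(lapply(fo, first_order_neighbors, graph = graph,
                             within = within)))
  sort(setdiff(so %||% character(), p))
}

#' Cluster a proteome into paralog groups
#'
#' Iteratively: (1) among unassigned proteins, pick the one with the most
#' second-order similarity neighbours (ties broken by lexicographic id) as
#' the reference; (2) every unassigned first- or second-order neighbour q
#' of the reference joins its group if q's own second-order neighbour count
#' is at least `member_frac` (default 20%) of the reference's; (3) the
#' group is removed and neighbour counts are recomputed on the remaining
#' subgraph; repeat until every protein is assigned.  Singleton groups are
#' recorded but only groups with at least `min_size` members (default 2)
#' are reported.
#'
#' Candidate members are drawn from the union of the reference's first- and
#' second-order neighbours: in a two-member family the partner is a
#' first-order neighbour whose neighbourhood contributes no *other*
#' protein, and restricting membership to strict second-order neighbours
#' would make such pairs unrecoverable (see the methods vignette).
#'
#' @param graph A `similarity_graph`.
#' @param member_frac Minimum fraction of the reference's second-order
#'   neighbour count a member must reach.
#' @param min_size Minimum reported group size.
#' @return A tibble with one row per reported group member: `group_id`,
#'   `reference_protein`, `protein_id`, `group_size`.  The full partition
#'   including singletons is attached as attribute `"partition"`.
#' @export
cluster_paralogs <- function(graph, member_frac = 0.2, min_size = 2L) {
  stopifnot(inherits(graph, "similarity_graph"),
            member_frac >= 0, member_frac <= 1)
  remaining <- graph$proteins
  groups <- list()
  while (length(remaining) > 0) {
    so <- lapply(setNames(remaining, remaining), second_order_neighbors,
                 graph = graph, within = remaining)
    counts <- vapply(so, length, integer(1))
    # highest second-order count, ties lexicographic (remaining is sorted)
    ref <- remaining[which.max(counts)]
    candidates <- sort(union(first_order_neighbors(ref, graph, remaining),
                             so[[ref]]))
    eligible <- candidates[vapply(
      candidates, function(q) counts[[q]] >= member_frac * counts[[ref]],
      logical(1))]
    members <- sort(c(ref, eligible))
    groups[[length(groups) + 1L]] <- list(reference = ref, members = members)
    remaining <- setdiff(remaining, members)
  }
  partition <- purrr::map_dfr(seq_along(groups), function(i) {
    tibble(group_id = sprintf("PG%04d", i),
           reference_protein = groups[[i]]$reference,
           protein_id = groups[[i]]$members,
           group_size = length(groups[[i]]$members))
  })
  out <- filter(partition, .data$group_size >= min_size)
  attr(out, "partition") <- partition
  out
}

#' Summarise paralog groups by essentiality
#'
#' Tabulates the label composition of each paralog group and counts groups
#' that are purely essential, purely non-essential, mixed
#' (essential + non-essential), or containing unclear members.
#'
#' @param groups Tibble from [cluster_paralogs()].
#' @param calls Call tibble covering every group member (`feature_id`,
#'   `label`); `domain_essential` members count as essential.
#' @return An object of class `paralog_summary`: list with `per_group`
#'   (tibble: group id, size, label counts, composition) and `overview`
#'   (one-row tibble with group counts and the size distribution extremes).
#' @export
summarize_paralog_groups <- function(groups, calls) {
  check_columns(groups, c("group_id", "protein_id", "group_size"))
  check_columns(calls, c("feature_id", "label"))
  missing <- setdiff(groups$protein_id, calls$feature_id)
  if (length(missing) > 0) {
    abort(sprintf("Group member(s) without essentiality call: %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  per_group <- groups |>
    left_join(select(calls, protein_id = "feature_id", "label"),
              by = "protein_id") |>
    mutate(label = ifelse(.data$label == "domain_essential", "essential",
                          .data$label)) |>
    group_by(.data$group_id, .data$group_size) |>
    summarise(
      n_essential = sum(.data$label == "essential"),
      n_non_essential = sum(.data$label == "non_essential"),
      n_unclear = sum(.data$label == "unclear"),
      .groups = "drop"
    ) |>
    mutate(composition = dplyr::case_when(
      .data$n_essential == .data$group_size ~ "pure_essential",
      .data$n_non_essential == .data$group_size ~ "pure_non_essential",
      .data$n_essential > 0 & .data$n_non_essential > 0 ~ "mixed",
      TRUE ~ "with_unclear"
    ))
  overview <- tibble(
    n_groups = nrow(per_group),
    n_genes = sum(per_group$group_size),
    pure_essential = sum(per_group$composition == "pure_essential"),
    pure_non_essential = sum(per_group$composition == "pure_non_essential"),
    mixed = sum(per_group$composition == "mixed"),
    with_unclear = sum(per_group$n_unclear > 0),
    max_group_size = if (nrow(per_group)) max(per_group$group_size) else 0L
  )
  structure(list(per_group = per_group, overview = overview),
            class = "paralog_summary")
}

#' @export
print.paralog_summary <- function(x, ...) {
  o <- x$overview
  cat(sprintf(
    "%d paralog groups (%d genes): %d pure essential, %d pure non-essential, %d mixed; largest group %d\n",
    o$n_groups, o$n_genes, o$pure_essential, o$pure_non_essential, o$mixed,
    o$max_group_size))
  invisible(x)
}
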