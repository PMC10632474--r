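#' Build a phyletic presence/absence frequency matrix
#'
#' For every ortholog group (OG) carried by a query gene, computes the
#' fraction of each taxonomic class's organisms that contain at least one
#' member of the group.  Duplicate `(organism, og)` records collapse to a
#' single presence, so frequencies are invariant to duplication.  Classes
#' with fewer than `min_class_size` organisms are dropped.  Query genes
#' without an OG assignment are listed in the `"unmapped_genes"` attribute.
#'
#' @param gene_to_og Tibble (`feature_id`, `og`); `og` may be `NA` for
#'   unassigned genes.
#' @param og_presence Tibble (`organism`, `og`) listing which organisms
#'   contain which OGs.
#' @param organism_to_class Tibble (`organism`, `class`); every organism in
#'   `og_presence` must be mapped.
#' @param min_class_size Minimum organisms per retained class (default 5).
#' @return A wide tibble with one row per OG (`og` column) and one numeric
#'   column per retained class holding frequencies in [0, 1].  Attributes:
#'   `"class_sizes"` (named integer) and `"unmapped_genes"` (character).
#' @export
build_phyletic_matrix <- function(gene_to_og, og_presence, organism_to_class,
                                  min_class_size = 5L) {
  check_columns(gene_to_og, c("feature_id", "og"))
  check_columns(og_presence, c("organism", "og"))
  check_columns(organism_to_class, c("organism", "class"))
  unmapped_org <- setdiff(unique(og_presence$organism),
                          organism_to_class$organism)
  if (length(unmapped_org) > 0) {
    abort(sprintf("Organism(s) without class: %s",
                  paste(head(unmapped_org, 10), collapse = ", ")))
  }
  class_sizes <- organism_to_class |>
    distinct(.data$organism, .data$class) |>
    count(.data$class, name = "n_organisms")
  kept_classes <- class_sizes$class[class_sizes$n_organisms >= min_class_size]
  if (length(kept_classes) == 0) {
    abort("No class reaches min_class_size organisms.")
  }
  ogs <- sort(unique(gene_to_og$og[!is.na(gene_to_og$og)]))
  unmapped_genes <- gene_to_og$feature_id[is.na(gene_to_og$og)]

  pres <- og_presence |>
    filter(.data$og %in% ogs) |>
    distinct(.data$organism, .data$og) |>
    left_join(distinct(organism_to_class, .data$organism, .data$class),
              by = "organism") |>
    filter(.data$class %in% kept_classes) |>
    count(.data$og, .data$class, name = "n_present")

  grid <- tidyr::expand_grid(og = ogs, class = kept_classes) |>
    left_join(pres, by = c("og", "class")) |>
    left_join(class_sizes, by = "class") |>
    mutate(frequency = dplyr::coalesce(.data$n_present, 0L) /
             .data$n_organisms)
  wide <- grid |>
    select("og", "class", "frequency") |>
    tidyr::pivot_wider(names_from = "class", values_from = "frequency") |>
    arrange(.data$og)
  attr(wide, "class_sizes") <- setNames(
    class_sizes$n_organisms[match(kept_classes, class_sizes$class)],
    kept_classes)
  attr(wide, "unmapped_genes") <- unmapped_genes
  wide
}

# Wide phyletic tibble -> numeric matrix with OG rownames.
phyletic_as_matrix <- function(mat_tbl) {
  check_columns(mat_tbl, "og")
  m <- as.matrix(mat_tbl[setdiff(names(mat_tbl), "og")])
  rownames(m) <- mat_tbl$og
  storage.mode(m) <- "double"
  m
}

#' Order a phyletic matrix by hierarchical clustering
#'
#' Complete-linkage agglomerative clustering on the Euclidean distances
#' between OG frequency rows.  Rows are pre-sorted by OG id so the result
#' is deterministic: equal distances are resolved by the fixed input
#' order.  A single-row matrix returns the identity ordering with no tree.
#'
#' @param mat_tbl Wide tibble from [build_phyletic_matrix()].
#' @return A list with `order` (OG ids in dendrogram leaf order), `hclust`
#'   (the `stats::hclust` tree, `NULL` for a single row), `merge_heights`
#'   (sorted merge distances) and `newick` (the tree in Newick format via
#'   \pkg{ape}, `NULL` for fewer than 2 rows).
#' @export
cluster_phyletic <- function(mat_tbl) {
  m <- phyletic_as_matrix(arrange(mat_tbl, .data$og))
  if (nrow(m) < 1) abort("Empty phyletic matrix.")
  if (nrow(m) == 1) {
    return(list(order = rownames(m), hclust = NULL,
                merge_heights = numeric(), newick = NULL))
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "complete")
  phy <- ape::as.phylo(hc)
  list(
    order = rownames(m)[hc$order],
    hclust = hc,
    merge_heights = sort(hc$height),
    newick = ape::write.tree(phy)
  )
}

#' Assign OGs to phyletic pattern groups
#'
#' Partitions the rows of a phyletic matrix by the first matching
#' presence/absence pattern.  A pattern is defined by the set of classes
#' where the OG must be common (frequency `>= tau_high`); outside that set
#' the OG must be rare (frequency `<= tau_low`) unless
#' `require_absent_elsewhere = FALSE` for that pattern.  Typical patterns:
#' universal (high everywhere), or restricted to one clade's classes.
#'
#' @param mat_tbl Wide tibble from [build_phyletic_matrix()].
#' @param class_subsets Named list; each element is a character vector of
#'   class columns in which the pattern requires high frequency.
#' @param tau_high Minimum frequency inside the subset (default 0.5).
#' @param tau_low Maximum frequency outside the subset (default 0.1).
#' @param require_absent_elsewhere Logical, recycled over patterns: enforce
#'   the `tau_low` bound outside the subset (default `TRUE`; set `FALSE`
#'   for patterns like "universal in bacteria, regardless of archaea").
#' @return A tibble (`og`, `pattern`), `pattern` being the first matching
#'   name or `"unassigned"`.
#' @export
extract_pattern_groups <- function(mat_tbl, class_subsets, tau_high = 0.5,
                                   tau_low = 0.1,
                                   require_absent_elsewhere = TRUE) {
  stopifnot(is.list(class_subsets), length(class_subsets) > 0,
            !is.null(names(class_subsets)))
  classes <- setdiff(names(mat_tbl), "og")
  bad <- setdiff(unique(unlist(class_subsets)), classes)
  if (length(bad) > 0) {
    abort(sprintf("Pattern subset names absent from matrix: %s",
                  paste(bad, collapse = ", ")))
  }
  req <- rep_len(require_absent_elsewhere, length(class_subsets))
  m <- phyletic_as_matrix(mat_tbl)
  pattern <- rep("unassigned", nrow(m))
  for (i in rev(seq_along(class_subsets))) {
    inside <- class_subsets[[i]]
    outside <- setdiff(classes, inside)
    ok_in <- rowSums(m[, inside, drop = FALSE] >= tau_high) == length(inside)
    ok_out <- if (req[i] && length(outside) > 0) {
      rowSums(m[, outside, drop = FALSE] <= tau_low) == length(outside)
    } else TRUE
    pattern[ok_in & ok_out] <- names(class_subsets)[i]
  }
  tibble(og = rownames(m), pattern = pattern)
}

#' Write an ordered phyletic matrix and its tree
#'
#' Convenience output: the frequency matrix with rows in dendrogram leaf
#' order as TSV, the leaf order as a one-column file, and the merge tree in
#' Newick format.
#'
#' @param mat_tbl Wide tibble from [build_phyletic_matrix()].
#' @param clustering Result of [cluster_phyletic()] on the same matrix.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the ordered matrix tibble.
#' @export
write_phyletic_outputs <- function(mat_tbl, clustering, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ordered <- mat_tbl[match(clustering$order, mat_tbl$og), ]
  readr::write_tsv(ordered, file.path(dir, "phyletic_matrix.tsv"),
                   progress = FALSE)
  readr::write_lines(clustering$order, file.path(dir, "leaf_order.txt"))
  if (!is.null(clustering$newick)) {
    readr::write_lines(clustering$newick, file.path(dir, "merge_tree.nwk"))
  }
  invisible(ordered)
}
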