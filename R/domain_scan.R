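#' Sliding-window insertion counts within genes
#'
#' Slides a fixed-length window (default 300 bp) along each gene from its
#' annotated start in steps of `step` bp (default 150), regardless of
#' strand, and counts the unique insertion sites inside each window.
#' Windows are placed at offsets 0, step, 2*step, ... while
#' `offset + window <= gene length`; trailing fragments shorter than the
#' window are discarded, so a gene shorter than `window` has no windows at
#' all.  A window with zero insertions marks a candidate essential domain.
#'
#' @param annotation Feature tibble.
#' @param insertions Insertion tibble.
#' @param window Window length in bp.
#' @param step Step between window starts in bp.
#' @return A tibble with one row per window: `feature_id`, `offset`
#'   (0-based, gene-relative), `win_start`, `win_end` (genomic, 1-based
#'   inclusive), `insertion_count`.  Genes with no windows contribute no
#'   rows.
#' @export
scan_windows <- function(annotation, insertions, window = 300L,
                         step = 150L) {
  validate_annotation(annotation)
  stopifnot(window >= 1, step >= 1)
  len <- annotation$end - annotation$start + 1L
  n_win <- pmax(0L, (len - as.integer(window)) %/% as.integer(step) + 1L)
  if (sum(n_win) == 0) {
    return(tibble(feature_id = character(), offset = integer(),
                  win_start = integer(), win_end = integer(),
                  insertion_count = integer()))
  }
  idx <- rep.int(seq_len(nrow(annotation)), n_win)
  offset <- unlist(lapply(n_win[n_win > 0],
                          function(k) as.integer(step) * (seq_len(k) - 1L)))
  win <- tibble(
    feature_id = annotation$feature_id[idx],
    replicon_id = annotation$replicon_id[idx],
    offset = offset,
    win_start = annotation$start[idx] + offset,
    win_end = annotation$start[idx] + offset + as.integer(window) - 1L
  )
  win$insertion_count <- count_sites_in_intervals(
    rename(win, start = "win_start", end = "win_end"), insertions)
  select(win, -"replicon_id")
}

#' Per-gene free-window summary
#'
#' Collapses [scan_windows()] output to one row per annotated gene:
#' `n_windows`, `n_free_windows` (windows with zero insertions) and
#' `has_free_window`.  Genes too short for a single window report zero
#' windows and `has_free_window = FALSE`.
#'
#' @inheritParams scan_windows
#' @return A tibble with one row per gene.
#' @export
free_window_summary <- function(annotation, insertions, window = 300L,
                                step = 150L) {
  win <- scan_windows(annotation, insertions, window, step)
  per_gene <- win |>
    group_by(.data$feature_id) |>
    summarise(n_windows = n(),
              n_free_windows = sum(.data$insertion_count == 0L),
              .groups = "drop")
  tibble(feature_id = annotation$feature_id) |>
    left_join(per_gene, by = "feature_id") |>
    mutate(
      n_windows = dplyr::coalesce(.data$n_windows, 0L),
      n_free_windows = dplyr::coalesce(.data$n_free_windows, 0L),
      has_free_window = .data$n_free_windows > 0L
    )
}

#' Upgrade calls with domain essentiality
#'
#' A statistically `unclear` or `non_essential` gene that contains at least
#' one insertion-free window is relabelled `domain_essential`: only part of
#' the encoded protein is intolerant of insertions.  Genes already called
#' `essential` are never relabelled.  The set of upgrades, broken down by
#' prior label, is attached as the `"upgrade_report"` attribute.
#'
#' @param calls Call tibble from [classify_genes()].
#' @param annotation Feature tibble.
#' @param insertions Insertion tibble.
#' @param window,step Sliding-window geometry (see [scan_windows()]).
#' @return The call tibble with upgraded labels and an added
#'   `has_free_window` column; `attr(, "upgrade_report")` is a tibble with
#'   one row per upgraded gene (`feature_id`, `prior_label`).
#' @export
apply_domain_essentiality <- function(calls, annotation, insertions,
                                      window = 300L, step = 150L) {
  check_columns(calls, c("feature_id", "label"))
  fw <- free_window_summary(annotation, insertions, window, step)
  out <- calls |>
    left_join(select(fw, "feature_id", "has_free_window"),
              by = "feature_id") |>
    mutate(has_free_window = dplyr::coalesce(.data$has_free_window, FALSE))
  upgrade <- out$label %in% c("unclear", "non_essential") & out$has_free_window
  report <- tibble(feature_id = out$feature_id[upgrade],
                   prior_label = out$label[upgrade])
  out$label[upgrade] <- "domain_essential"
  attr(out, "upgrade_report") <- report
  out
}
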