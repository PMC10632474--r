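#' Run the core essentiality pipeline
#'
#' Chains the four core stages -- insertion-index table, mixture fit,
#' likelihood-ratio classification, domain-essentiality upgrade -- and
#' optionally writes every stage output as TSV together with a JSON run
#' manifest (package version, parameters, parameter hash), so a run is
#' reproducible from its manifest alone.
#'
#' @param annotation Feature tibble from [read_annotation()] or
#'   [simulate_genome()].
#' @param insertions Insertion tibble from [read_insertions()] or
#'   [simulate_insertions()].
#' @param cutoffs Mixture section cutoffs (see [fit_mixture()]).
#' @param k_threshold Likelihood-ratio threshold (see [classify_genes()]).
#' @param window,step Domain-scan geometry (see [scan_windows()]);
#'   `window = NULL` skips the domain-essentiality stage.
#' @param replicon_lengths Optional replicon lengths for the saturation
#'   summary (see [library_summary()]); `NULL` skips it.
#' @param outdir Optional output directory; when given, writes
#'   `insertion_index.tsv`, `calls.tsv`, `fit.tsv` and `manifest.json`.
#' @return A list with `index` (index table), `fit` (`mixture_fit`),
#'   `calls` (final call tibble with the four-label vocabulary),
#'   `upgrade_report`, and `summary` (or `NULL`).
#' @export
run_essentiality_pipeline <- function(annotation, insertions,
                                      cutoffs = c(0.013, 0.022, 0.25),
                                      k_threshold = 12,
                                      window = 300L, step = 150L,
                                      replicon_lengths = NULL,
                                      outdir = NULL) {
  if (!is.null(window)) {
    stopifnot(window >= 1, step >= 1)
  }
  stopifnot(k_threshold > 1, length(cutoffs) == 3, all(diff(cutoffs) > 0),
            all(cutoffs > 0))
  idx <- insertion_index(annotation, insertions)
  fit <- fit_mixture(idx, cutoffs = cutoffs)
  calls <- classify_genes(idx, fit, k_threshold = k_threshold)
  upgrade_report <- NULL
  if (!is.null(window)) {
    calls <- apply_domain_essentiality(calls, annotation, insertions,
                                       window = window, step = step)
    upgrade_report <- attr(calls, "upgrade_report")
  }
  summary <- if (!is.null(replicon_lengths)) {
    library_summary(annotation, insertions, replicon_lengths)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(idx, file.path(outdir, "insertion_index.tsv"),
                     progress = FALSE)
    write_calls(calls, file.path(outdir, "calls.tsv"))
    readr::write_tsv(glance(fit), file.path(outdir, "fit.tsv"),
                     progress = FALSE)
    params <- list(cutoffs = cutoffs, k_threshold = k_threshold,
                   window = window, step = step)
    manifest <- list(
      package = "tradistat",
      version = as.character(utils::packageVersion("tradistat")),
      parameters = params,
      parameter_hash = rlang::hash(params),
      n_genes = nrow(idx),
      n_unique_sites = nrow(distinct(insertions, .data$replicon_id,
                                     .data$position))
    )
    writeLines(manifest_json(manifest), file.path(outdir, "manifest.json"))
  }
  list(index = idx, fit = fit, calls = calls,
       upgrade_report = upgrade_report, summary = summary)
}

# Minimal JSON serialiser for the flat manifest (avoids a hard jsonlite
# dependency in the core path).
manifest_json <- function(x, indent = "") {
  esc <- function(s) gsub('"', '\\\\"', s)
  render <- function(v) {
    if (is.list(v)) return(manifest_json(v, paste0(indent, "  ")))
    if (is.null(v)) return("null")
    if (is.character(v) && length(v) == 1) return(sprintf('"%s"', esc(v)))
    if (length(v) == 1) return(format(v, digits = 15))
    sprintf("[%s]", paste(vapply(v, render, character(1)), collapse = ", "))
  }
  body <- vapply(names(x), function(nm) {
    sprintf('%s  "%s": %s', indent, esc(nm), render(x[[nm]]))
  }, character(1))
  sprintf("%s{\n%s\n%s}", "", paste(body, collapse = ",\n"), indent)
}

#' Plot essentiality calls along the genome
#'
#' Gene-level overview: insertion index against genomic position, coloured
#' by call label.
#'
#' @param calls Call tibble (needs `insertion_index` and `label`).
#' @param annotation Feature tibble supplying gene midpoints.
#' @return A ggplot object.
#' @export
plot_calls <- function(calls, annotation) {
  check_columns(calls, c("feature_id", "insertion_index", "label"))
  validate_annotation(annotation)
  df <- calls |>
    left_join(select(annotation, "feature_id", "start", "end"),
              by = "feature_id") |>
    mutate(midpoint = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint,
                                   y = .data$insertion_index,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "genomic position (bp)", y = "insertion index",
                  colour = "call") +
    ggplot2::theme_minimal()
}
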