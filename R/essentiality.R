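# Count unique insertion positions inside arbitrary [start, end] intervals.
# Sites are reduced to sorted unique positions per replicon; per-interval
# counts come from two findInterval() lookups, which is exact and O(log m)
# per interval.
count_sites_in_intervals <- function(intervals, insertions) {
  counts <- integer(nrow(intervals))
  pos_by_rep <- split(insertions$position, insertions$replicon_id)
  pos_by_rep <- lapply(pos_by_rep, function(p) sort(unique(p)))
  for (rep_id in unique(intervals$replicon_id)) {
    rows <- which(intervals$replicon_id == rep_id)
    p <- pos_by_rep[[rep_id]]
    if (is.null(p) || length(p) == 0) next
    counts[rows] <- findInterval(intervals$end[rows], p) -
      findInterval(intervals$start[rows] - 1L, p)
  }
  counts
}

#' Per-gene insertion-index table
#'
#' For every annotated feature (CDS, tRNA, rRNA, ncRNA and pseudogenes
#' alike), counts the unique insertion sites falling within its coordinates
#' (a site at position p belongs to a gene g iff `g.start <= p <= g.end`;
#' sites inside overlapping genes are counted once per gene) and normalises
#' by gene length: the *insertion index*.
#'
#' @param annotation Feature tibble from [read_annotation()].
#' @param insertions Insertion tibble from [read_insertions()].
#' @return A tibble with `feature_id`, `replicon_id`, `length_bp`,
#'   `unique_insertions`, `insertion_index`.
#' @export
insertion_index <- function(annotation, insertions) {
  validate_annotation(annotation)
  check_columns(insertions, c("replicon_id", "position"))
  if (nrow(annotation) > 0 && any(annotation$end < annotation$start)) {
    abort("Zero- or negative-length gene in annotation.")
  }
  tibble(
    feature_id = annotation$feature_id,
    replicon_id = annotation$replicon_id,
    length_bp = annotation$end - annotation$start + 1L,
    unique_insertions = count_sites_in_intervals(annotation, insertions)
  ) |>
    mutate(insertion_index = .data$unique_insertions / .data$length_bp)
}

#' Library saturation summary
#'
#' Per-replicon unique-site totals, the genic/intergenic split, and the
#' headline saturation statistic bp-per-insertion
#' (`replicon_length / unique_sites`, rounded to integer): a saturated
#' library has on the order of one unique insertion per 10-15 bp.
#'
#' @param annotation Feature tibble.
#' @param insertions Insertion tibble.
#' @param replicon_lengths Named numeric vector or tibble
#'   (`replicon_id`, `length`) of replicon sizes in bp.
#' @return A tibble with one row per replicon: `replicon_id`, `length_bp`,
#'   `unique_sites`, `genic_sites`, `intergenic_sites`, `bp_per_insertion`.
#' @export
library_summary <- function(annotation, insertions, replicon_lengths) {
  validate_annotation(annotation)
  if (is.data.frame(replicon_lengths)) {
    check_columns(replicon_lengths, c("replicon_id", "length"))
    rl <- setNames(replicon_lengths$length, replicon_lengths$replicon_id)
  } else {
    rl <- replicon_lengths
  }
  sites <- distinct(insertions, .data$replicon_id, .data$position)
  reps <- unique(sites$replicon_id)
  if (!all(reps %in% names(rl))) {
    abort(sprintf("Missing replicon length(s) for: %s",
                  paste(setdiff(reps, names(rl)), collapse = ", ")))
  }
  purrr::map_dfr(reps, function(r) {
    s <- filter(sites, .data$replicon_id == r)
    ann <- filter(annotation, .data$replicon_id == r)
    genic <- if (nrow(ann) == 0) rep(FALSE, nrow(s)) else {
      purrr::map_lgl(s$position,
                     function(p) any(ann$start <= p & p <= ann$end))
    }
    tibble(
      replicon_id = r,
      length_bp = as.integer(rl[[r]]),
      unique_sites = nrow(s),
      genic_sites = sum(genic),
      intergenic_sites = sum(!genic),
      bp_per_insertion = as.integer(round(rl[[r]] / max(1L, nrow(s))))
    )
  })
}

#' Fit the exponential/gamma insertion-index mixture
#'
#' The bimodal insertion-index distribution is split into three sections at
#' manually chosen cutoffs (defaults 0.013, 0.022 and 0.25).  The essential
#' mode -- indices below `cutoffs[1]`, zeros included -- is fitted with an
#' exponential distribution by its closed-form maximum-likelihood estimate
#' `rate = n / sum(x)`.  The non-essential mode -- indices in
#' `[cutoffs[2], cutoffs[3]]` -- is fitted with a gamma distribution by
#' maximum likelihood (via \pkg{fitdistrplus}).  Indices in the transition
#' band and above the upper cutoff are excluded from fitting but are still
#' scored and classified later.
#'
#' When every index in the essential section is zero the exponential MLE is
#' unbounded and `exp_rate` is `+Inf`; [log_likelihood_score()] handles this
#' degenerate fit (zero-index genes score `+Inf`, all others `-Inf`).
#'
#' @param index_table Tibble from [insertion_index()], or any data frame
#'   with an `insertion_index` column.
#' @param cutoffs Numeric length-3, strictly increasing: the section
#'   boundaries on the insertion-index axis.
#' @param min_section Minimum observations required in each fitting section.
#' @return An object of class `mixture_fit` with elements `exp_rate`,
#'   `gamma_shape`, `gamma_scale`, `cutoffs` (named low/mid/high),
#'   `n_exp_fit`, `n_gamma_fit`, `n_transition`, `n_outlier`.
#' @export
fit_mixture <- function(index_table, cutoffs = c(0.013, 0.022, 0.25),
                        min_section = 10L) {
  check_columns(index_table, "insertion_index")
  x <- index_table$insertion_index
  stopifnot(length(cutoffs) == 3, all(diff(cutoffs) > 0), cutoffs[1] > 0)
  x1 <- x[x < cutoffs[1]]
  x2 <- x[x >= cutoffs[2] & x <= cutoffs[3]]
  if (length(x1) < min_section) {
    abort(sprintf(
      "Only %d indices below the low cutoff %.4g (need >= %d); adjust cutoffs.",
      length(x1), cutoffs[1], min_section))
  }
  if (length(x2) < min_section) {
    abort(sprintf(
      "Only %d indices in [%.4g, %.4g] (need >= %d); adjust cutoffs.",
      length(x2), cutoffs[2], cutoffs[3], min_section))
  }
  exp_rate <- length(x1) / sum(x1)  # closed-form MLE; +Inf when all zeros
  if (!is.finite(exp_rate)) {
    warn("All indices in the essential section are zero; exponential rate is +Inf (degenerate fit).")
  }
  # Gamma MLE on the data rescaled by its mean: numerically safer for
  # indices of magnitude 1e-2, and exactly equivariant (shape unchanged,
  # scale multiplies back).
  m <- mean(x2)
  gf <- tryCatch(
    fitdistrplus::fitdist(x2 / m, "gamma", method = "mle"),
    error = function(e) abort(sprintf(
      "Gamma MLE did not converge on %d observations in [%.4g, %.4g]: %s",
      length(x2), cutoffs[2], cutoffs[3], conditionMessage(e)))
  )
  gamma_shape <- unname(gf$estimate[["shape"]])
  gamma_scale <- m / unname(gf$estimate[["rate"]])
  stopifnot(gamma_shape > 0, gamma_scale > 0)
  structure(
    list(
      exp_rate = exp_rate,
      gamma_shape = gamma_shape,
      gamma_scale = gamma_scale,
      cutoffs = c(low = cutoffs[1], mid = cutoffs[2], high = cutoffs[3]),
      n_exp_fit = length(x1),
      n_gamma_fit = length(x2),
      n_transition = sum(x >= cutoffs[1] & x < cutoffs[2]),
      n_outlier = sum(x > cutoffs[3])
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Insertion-index mixture fit\n")
  cat(sprintf("  exponential rate: %g  (n = %d, index < %.4g)\n",
              x$exp_rate, x$n_exp_fit, x$cutoffs[["low"]]))
  cat(sprintf("  gamma shape %.4g, scale %.4g (mean %.4g)  (n = %d, [%.4g, %.4g])\n",
              x$gamma_shape, x$gamma_scale, x$gamma_shape * x$gamma_scale,
              x$n_gamma_fit, x$cutoffs[["mid"]], x$cutoffs[["high"]]))
  cat(sprintf("  excluded: %d transition, %d above high cutoff\n",
              x$n_transition, x$n_outlier))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy / summarise a mixture fit
#'
#' `tidy()` returns one row per fitted parameter; `glance()` returns a
#' one-row model summary including the gamma mean (the fitted non-essential
#' insertion-index mean).
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(
    term = c("exp_rate", "gamma_shape", "gamma_scale"),
    estimate = c(x$exp_rate, x$gamma_shape, x$gamma_scale),
    component = c("exponential", "gamma", "gamma")
  )
}

#' @rdname tidy.mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(
    exp_rate = x$exp_rate,
    gamma_shape = x$gamma_shape,
    gamma_scale = x$gamma_scale,
    gamma_mean = x$gamma_shape * x$gamma_scale,
    n_exp_fit = x$n_exp_fit,
    n_gamma_fit = x$n_gamma_fit,
    cutoff_low = x$cutoffs[["low"]],
    cutoff_mid = x$cutoffs[["mid"]],
    cutoff_high = x$cutoffs[["high"]]
  )
}

#' Log2 likelihood-ratio score of an insertion index
#'
#' `log2(f_exp(x; rate) / f_gamma(x; shape, scale))`: large positive scores
#' mean the index is far more likely under the essential (exponential) mode,
#' large negative scores far more likely under the non-essential (gamma)
#' mode.  An index of exactly zero has zero gamma density (for shape > 1)
#' and scores `+Inf`, a deliberate sentinel: a gene with no insertions can
#' never score below a gene with insertions.  A degenerate fit with infinite
#' exponential rate scores `+Inf` at zero and `-Inf` elsewhere.
#'
#' @param index Numeric vector of insertion indices.
#' @param fit A `mixture_fit`.
#' @return Numeric vector of scores (possibly `+/-Inf`).
#' @export
log_likelihood_score <- function(index, fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!is.finite(fit$exp_rate)) {
    return(ifelse(index == 0, Inf, -Inf))
  }
  out <- numeric(length(index))
  zero <- index == 0
  out[zero] <- Inf
  if (any(!zero)) {
    x <- index[!zero]
    out[!zero] <- (dexp(x, rate = fit$exp_rate, log = TRUE) -
                     dgamma(x, shape = fit$gamma_shape,
                            scale = fit$gamma_scale, log = TRUE)) / log(2)
  }
  out
}

# Pure score -> label rule, exposed for boundary tests and reuse.
#' Label from a log-likelihood score
#'
#' Applies the likelihood-ratio rule: `essential` iff
#' `score > log2(k_threshold)` (the gene is more than k times as likely
#' under the essential mode), `non_essential` iff
#' `score < -log2(k_threshold)`, `unclear` otherwise.  Both inequalities are
#' strict, so a score of exactly `log2(k_threshold)` is `unclear`.
#'
#' @param score Numeric vector of log2 likelihood-ratio scores.
#' @param k_threshold Likelihood-ratio threshold (default 12).
#' @return Character vector of labels.
#' @export
label_from_score <- function(score, k_threshold = 12) {
  thr <- log2(k_threshold)
  dplyr::case_when(
    score > thr ~ "essential",
    score < -thr ~ "non_essential",
    TRUE ~ "unclear"
  )
}

#' Classify genes by the likelihood-ratio rule
#'
#' Scores every gene in the index table against the fitted mixture and
#' labels it `essential`, `non_essential` or `unclear` (see
#' [label_from_score()]).  Every gene receives exactly one label.
#'
#' @param index_table Tibble from [insertion_index()].
#' @param fit A `mixture_fit`.
#' @param k_threshold Likelihood-ratio threshold (default 12: a gene must be
#'   more than 12 times as likely under one mode to be called).
#' @return The index table with added columns `log_likelihood_score`,
#'   `label` and `zero_index` (flag for the `+Inf` sentinel scores).
#' @export
classify_genes <- function(index_table, fit, k_threshold = 12) {
  check_columns(index_table, c("feature_id", "insertion_index"))
  stopifnot(k_threshold > 1)
  index_table |>
    mutate(
      log_likelihood_score = log_likelihood_score(.data$insertion_index, fit),
      label = label_from_score(.data$log_likelihood_score, k_threshold),
      zero_index = .data$insertion_index == 0
    )
}

#' Plot the insertion-index distribution with the fitted mixture
#'
#' Histogram of insertion indices overlaid with the fitted exponential and
#' gamma densities (each scaled by the fraction of genes in its fitting
#' section) and the three section cutoffs.
#'
#' @param object A `mixture_fit`.
#' @param index_table The index table the fit was computed from.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_fit <- function(object, index_table, bins = 80, ...) {
  check_columns(index_table, "insertion_index")
  x <- index_table$insertion_index
  n <- length(x)
  xmax <- max(object$cutoffs[["high"]] * 1.2, stats::quantile(x, 0.99))
  grid <- seq(1e-6, xmax, length.out = 400)
  dens <- bind_rows(
    tibble(x = grid, component = "exponential",
           density = if (is.finite(object$exp_rate))
             dexp(grid, object$exp_rate) * object$n_exp_fit / n else NA_real_),
    tibble(x = grid, component = "gamma",
           density = dgamma(grid, shape = object$gamma_shape,
                            scale = object$gamma_scale) *
             object$n_gamma_fit / n)
  )
  ggplot2::ggplot(tibble(index = x), ggplot2::aes(x = .data$index)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = dplyr::filter(dens, !is.na(.data$density)),
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_vline(xintercept = unname(object$cutoffs),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::coord_cartesian(xlim = c(0, xmax)) +
    ggplot2::labs(x = "insertion index", y = "density",
                  colour = "fitted mode") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
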