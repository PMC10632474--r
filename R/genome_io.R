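#' Read a genome annotation into a feature table
#'
#' Parses a GFF3 file (via \pkg{rtracklayer}) or a flat feature TSV into the
#' internal feature table used by every downstream stage.  Coordinates are
#' 1-based inclusive throughout the package (the GFF3 convention).
#'
#' For GFF3 input, features of type `CDS`, `tRNA`, `rRNA`, `ncRNA` and
#' `pseudogene` are retained (`tmRNA`, `SRP_RNA` and `RNase_P_RNA` are folded
#' into `ncRNA`); structural records such as `region`, `gene` or `exon` are
#' dropped so that each analysable feature is emitted exactly once.  The
#' feature identifier is taken from the `locus_tag` attribute when present,
#' otherwise from `ID`, otherwise from `Name`.
#'
#' A feature TSV must have the columns `feature_id`, `replicon_id`, `start`,
#' `end`, `strand` and `kind`; kinds outside the vocabulary are coerced to
#' `"other"`.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"feature_tsv"`.
#' @return A tibble with columns `feature_id`, `replicon_id`, `start`, `end`,
#'   `strand`, `kind`, sorted by `(replicon_id, start)`.  Pseudogenes, tRNA
#'   and rRNA features are retained and analysed like CDS.
#' @export
read_annotation <- function(path, format = c("gff3", "feature_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Annotation file not found: %s", path))
  }
  if (format == "gff3") {
    gr <- tryCatch(
      rtracklayer::import(path, format = "gff3"),
      error = function(e) {
        abort(sprintf("Failed to parse GFF3 '%s': %s", path, conditionMessage(e)))
      }
    )
    if (length(gr) == 0) {
      return(empty_annotation())
    }
    meta <- as.data.frame(gr)
    kind_raw <- as.character(meta$type)
    kind <- dplyr::case_when(
      kind_raw %in% c("CDS", "tRNA", "rRNA", "ncRNA", "pseudogene") ~ kind_raw,
      kind_raw %in% c("tmRNA", "SRP_RNA", "RNase_P_RNA") ~ "ncRNA",
      TRUE ~ NA_character_
    )
    keep <- !is.na(kind)
    if (!any(keep)) {
      return(empty_annotation())
    }
    meta <- meta[keep, , drop = FALSE]
    id <- rep(NA_character_, nrow(meta))
    for (col in c("locus_tag", "ID", "Name")) {
      if (col %in% names(meta)) {
        vals <- as.character(meta[[col]])
        id <- ifelse(is.na(id) & !is.na(vals), vals, id)
      }
    }
    if (anyNA(id)) {
      abort("GFF3 features without locus_tag/ID/Name attribute cannot be identified.")
    }
    ann <- tibble(
      feature_id = id,
      replicon_id = as.character(meta$seqnames),
      start = as.integer(meta$start),
      end = as.integer(meta$end),
      strand = ifelse(as.character(meta$strand) == "-", "-", "+"),
      kind = kind[keep]
    )
  } else {
    ann <- read_tsv_strict(path, c("feature_id", "replicon_id", "start",
                                   "end", "strand", "kind"))
    ann <- mutate(ann,
      feature_id = as.character(.data$feature_id),
      replicon_id = as.character(.data$replicon_id),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      strand = as.character(.data$strand),
      kind = ifelse(.data$kind %in% c("CDS", "tRNA", "rRNA", "ncRNA",
                                      "pseudogene"),
                    as.character(.data$kind), "other")
    )
  }
  validate_annotation(ann)
  arrange(ann, .data$replicon_id, .data$start)
}

empty_annotation <- function() {
  tibble(
    feature_id = character(), replicon_id = character(),
    start = integer(), end = integer(),
    strand = character(), kind = character()
  )
}

validate_annotation <- function(ann) {
  check_columns(ann, c("feature_id", "replicon_id", "start", "end",
                       "strand", "kind"), "annotation")
  if (nrow(ann) == 0) return(invisible(ann))
  if (anyDuplicated(ann$feature_id)) {
    dups <- unique(ann$feature_id[duplicated(ann$feature_id)])
    abort(sprintf("Duplicate feature_id(s): %s",
                  paste(head(dups, 5), collapse = ", ")))
  }
  if (any(ann$start < 1)) abort("Feature start coordinates must be >= 1.")
  if (any(ann$end < ann$start)) abort("Feature end must be >= start.")
  if (!all(ann$strand %in% c("+", "-"))) {
    abort("Feature strand must be '+' or '-'.")
  }
  invisible(ann)
}

# readr-based TSV reader that fails loudly, reporting the first bad line.
read_tsv_strict <- function(path, required_cols) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(tb)
  if (nrow(probs) > 0) {
    abort(sprintf("Parse error in '%s' at line %d: expected %s, got %s.",
                  path, probs$row[1] + 1L, probs$expected[1], probs$actual[1]))
  }
  missing <- setdiff(required_cols, names(tb))
  if (length(missing) > 0) {
    abort(sprintf("'%s' is missing required column(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
  tb
}

#' Read mapped transposon insertion sites
#'
#' Supports three dialects: `"plot"` (one line per genome position, two
#' whitespace-separated columns of forward/reverse junction-read counts,
#' summed; the line number is the position), `"bed"` (0-based half-open
#' intervals; the score column carries the read count, 1 when absent), and
#' `"tsv"` (columns `replicon_id`, `position`, `read_count`).
#'
#' Positions with zero reads are dropped; duplicate positions (e.g. the two
#' strands of a BED file) are merged by summing their read counts, so a site
#' is unique per `(replicon_id, position)`.
#'
#' @param path Input file.
#' @param format `"plot"`, `"bed"` or `"tsv"`.
#' @param replicon_id Replicon name to attach to `"plot"` input, which does
#'   not carry one.
#' @return A tibble with columns `replicon_id`, `position` (1-based),
#'   `read_count`, sorted by `(replicon_id, position)`.
#' @export
read_insertions <- function(path, format = c("plot", "bed", "tsv"),
                            replicon_id = "chr") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Insertion file not found: %s", path))
  if (format == "plot") {
    mat <- tryCatch(
      as.matrix(utils::read.table(path, header = FALSE)),
      error = function(e) abort(sprintf("Failed to parse plot file '%s': %s",
                                        path, conditionMessage(e)))
    )
    if (ncol(mat) == 1) mat <- cbind(mat, 0)
    counts <- mat[, 1] + mat[, 2]
    if (any(counts < 0)) abort("Negative read counts in plot file.")
    keep <- counts > 0
    ins <- tibble(
      replicon_id = replicon_id,
      position = which(keep),
      read_count = as.integer(counts[keep])
    )
  } else if (format == "bed") {
    raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE, comment = "#")
    if (ncol(raw) < 3) abort("BED input needs at least 3 columns.")
    count <- if (ncol(raw) >= 5) suppressWarnings(as.numeric(raw[[5]])) else 1
    count[is.na(count)] <- 1
    ins <- tibble(
      replicon_id = as.character(raw[[1]]),
      # BED is 0-based half-open: chromStart k covers 1-based position k + 1.
      position = as.integer(raw[[2]]) + 1L,
      read_count = as.integer(count)
    )
  } else {
    tb <- read_tsv_strict(path, c("replicon_id", "position", "read_count"))
    ins <- tibble(
      replicon_id = as.character(tb$replicon_id),
      position = as.integer(tb$position),
      read_count = as.integer(tb$read_count)
    )
  }
  normalize_insertions(ins)
}

# Merge duplicate positions, drop zero counts, validate, sort.
normalize_insertions <- function(ins) {
  check_columns(ins, c("replicon_id", "position", "read_count"), "insertions")
  if (any(ins$position < 1)) abort("Insertion positions must be >= 1.")
  if (any(ins$read_count < 0)) abort("Insertion read counts must be >= 0.")
  ins |>
    filter(.data$read_count > 0) |>
    group_by(.data$replicon_id, .data$position) |>
    summarise(read_count = as.integer(sum(.data$read_count)),
              .groups = "drop") |>
    arrange(.data$replicon_id, .data$position)
}

#' Write an insertion-site table as TSV
#'
#' @param insertions Tibble from [read_insertions()] or
#'   [simulate_insertions()].
#' @param path Output path.
#' @return `insertions`, invisibly (so the call can sit inside a pipe).
#' @export
write_insertions <- function(insertions, path) {
  check_columns(insertions, c("replicon_id", "position", "read_count"))
  readr::write_tsv(insertions, path, progress = FALSE)
  invisible(insertions)
}

# Standard BLAST outfmt-6 column names.
.blast6_cols <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatches", "gap_opens",
                  "q_start", "q_end", "s_start", "s_end",
                  "evalue", "bit_score")

#' Read BLAST tabular (outfmt 6) output
#'
#' Reads the 12 standard tab-separated columns, optionally extended with
#' `qlen` and `slen` (from `-outfmt "6 std qlen slen"`).  When lengths are
#' present, alignment coverage is derived as
#' `query_cov = 100 * alignment_length / query_length` and analogously for
#' the subject, which is what the downstream E-value/coverage filter
#' consumes.  Self hits (`query_id == subject_id`) are retained; the paralog
#' module uses them as the self bit-score reference.
#'
#' @param path Tab-separated BLAST output.
#' @param with_lengths Logical; `TRUE` when `qlen`/`slen` columns 13-14 are
#'   present.
#' @return A tibble of hits; with `with_lengths = TRUE` it additionally has
#'   `query_length`, `subject_length`, `query_cov`, `subject_cov`.
#' @export
read_blast_tabular <- function(path, with_lengths = TRUE) {
  if (!file.exists(path)) abort(sprintf("BLAST file not found: %s", path))
  expected <- if (with_lengths) 14L else 12L
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (nrow(raw) == 0) {
    cols <- c(.blast6_cols,
              if (with_lengths) c("query_length", "subject_length",
                                  "query_cov", "subject_cov"))
    out <- as_tibble(setNames(rep(list(logical()), length(cols)), cols))
    return(out)
  }
  if (ncol(raw) < expected) {
    abort(sprintf("'%s' has %d columns; %d expected for outfmt 6%s.",
                  path, ncol(raw), expected,
                  if (with_lengths) " + qlen/slen" else ""))
  }
  nm <- c(.blast6_cols,
          if (with_lengths) c("query_length", "subject_length"))
  hits <- setNames(raw[seq_along(nm)], nm)
  hits <- mutate(hits,
    query_id = as.character(.data$query_id),
    subject_id = as.character(.data$subject_id),
    across(c("percent_identity", "evalue", "bit_score"), as.numeric),
    across(c("alignment_length", "mismatches", "gap_opens",
             "q_start", "q_end", "s_start", "s_end"), as.integer)
  )
  if (with_lengths) {
    hits <- mutate(hits,
      query_length = as.integer(.data$query_length),
      subject_length = as.integer(.data$subject_length),
      query_cov = 100 * .data$alignment_length / .data$query_length,
      subject_cov = 100 * .data$alignment_length / .data$subject_length
    )
  }
  as_tibble(hits)
}

#' Write and re-read essentiality calls
#'
#' `write_calls()` writes the per-gene call table as a UTF-8 TSV with a
#' header row; `read_calls()` reads it back, so that
#' `read_calls(write_calls(x, path))` reproduces `x` exactly.  Labels are
#' restricted to the four-value vocabulary `essential`, `non_essential`,
#' `unclear`, `domain_essential`.
#'
#' @param calls Tibble from [classify_genes()] or
#'   [apply_domain_essentiality()].
#' @param path Output / input TSV path.
#' @return `write_calls()` returns `calls` invisibly; `read_calls()` returns
#'   the call tibble.
#' @export
write_calls <- function(calls, path) {
  cols <- c("feature_id", "replicon_id", "length_bp", "unique_insertions",
            "insertion_index", "log_likelihood_score", "label")
  check_columns(calls, cols)
  bad <- setdiff(unique(calls$label), .call_labels)
  if (length(bad) > 0) {
    abort(sprintf("Invalid label(s) in calls: %s", paste(bad, collapse = ", ")))
  }
  readr::write_tsv(calls[cols], path, progress = FALSE)
  invisible(calls)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  tb <- read_tsv_strict(path, c("feature_id", "replicon_id", "length_bp",
                                "unique_insertions", "insertion_index",
                                "log_likelihood_score", "label"))
  mutate(tb,
    feature_id = as.character(.data$feature_id),
    replicon_id = as.character(.data$replicon_id),
    length_bp = as.integer(.data$length_bp),
    unique_insertions = as.integer(.data$unique_insertions),
    insertion_index = as.numeric(.data$insertion_index),
    log_likelihood_score = as.numeric(.data$log_likelihood_score),
    label = as.character(.data$label)
  )
}
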