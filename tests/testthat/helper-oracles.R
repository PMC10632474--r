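# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (nested loops, direct formulas) so they cannot share a
# defect with the implementation they check.

# O(genes x sites) interval-membership count of unique insertion positions.
brute_count_sites <- function(annotation, insertions) {
  sites <- unique(insertions[c("replicon_id", "position")])
  vapply(seq_len(nrow(annotation)), function(i) {
    sum(sites$replicon_id == annotation$replicon_id[i] &
          sites$position >= annotation$start[i] &
          sites$position <= annotation$end[i])
  }, integer(1))
}

# Per-offset window counts for a single gene (positions are genomic).
brute_window_counts <- function(start, end, positions, window = 300,
                                step = 150) {
  len <- end - start + 1
  offs <- integer(0)
  o <- 0
  while (o + window <= len) {
    offs <- c(offs, o)
    o <- o + step
  }
  vapply(offs, function(o) {
    lo <- start + o
    hi <- lo + window - 1
    sum(positions >= lo & positions <= hi)
  }, numeric(1))
}

# Naive agglomerative complete-linkage: returns sorted merge heights.
brute_complete_linkage_heights <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- max(vapply(clusters[[i]], function(a) {
          max(vapply(clusters[[j]], function(b) {
            sqrt(sum((m[a, ] - m[b, ])^2))
          }, numeric(1)))
        }, numeric(1)))
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# Direct numerical gamma MLE via optim on the hand-written negative
# log-likelihood (independent of fitdistrplus).
oracle_gamma_mle <- function(x) {
  nll <- function(par) {
    shape <- exp(par[1])
    scale <- exp(par[2])
    -sum((shape - 1) * log(x) - x / scale - lgamma(shape) -
           shape * log(scale))
  }
  m <- mean(x)
  v <- stats::var(x)
  start <- log(c(m^2 / v, v / m))
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  c(shape = exp(fit$par[1]), scale = exp(fit$par[2]))
}

# Random small annotation on one replicon (possibly overlapping genes).
random_annotation <- function(n_genes, genome_length, seed = NULL,
                              replicon_id = "chr") {
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(genome_length - 50L, n_genes, replace = TRUE)
  len <- sample(30:400, n_genes, replace = TRUE)
  tibble::tibble(
    feature_id = sprintf("g%04d", seq_len(n_genes)),
    replicon_id = replicon_id,
    start = start,
    end = pmin(start + len - 1L, genome_length),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    kind = sample(c("CDS", "tRNA", "rRNA", "pseudogene"), n_genes,
                  replace = TRUE)
  )
}

random_insertions <- function(n_sites, genome_length, replicon_id = "chr") {
  tibble::tibble(
    replicon_id = replicon_id,
    position = sample.int(genome_length, n_sites, replace = TRUE),
    read_count = sample(1:20, n_sites, replace = TRUE)
  ) |> tradistat:::normalize_insertions()
}

# A mixture_fit object with chosen parameters, bypassing fitting (for score
# and classification tests).
manual_fit <- function(exp_rate = 100, gamma_shape = 3, gamma_scale = 0.03,
                       cutoffs = c(0.013, 0.022, 0.25)) {
  structure(
    list(exp_rate = exp_rate, gamma_shape = gamma_shape,
         gamma_scale = gamma_scale,
         cutoffs = c(low = cutoffs[1], mid = cutoffs[2], high = cutoffs[3]),
         n_exp_fit = 100L, n_gamma_fit = 100L, n_transition = 0L,
         n_outlier = 0L),
    class = "mixture_fit"
  )
}

# Canonical form of a list of id sets (sorted members, sorted sets) so two
# partitions can be compared with expect_equal.
canon_sets <- function(sets) {
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, paste, "", collapse = ","))])
}

# Hand-worked six-protein paralog fixture.  P1-P2-P3 form a same-COG
# triangle, P5 attaches to P2 only; P4 fails the bit-score rule against P3
# solely because their COGs differ; P6 is length-incompatible with
# everything.
six_protein_universe <- function() {
  proteins <- tibble::tibble(
    protein_id = c("P1", "P2", "P3", "P4", "P5", "P6"),
    length = c(400L, 380L, 360L, 250L, 395L, 100L)
  )
  cog_map <- tibble::tibble(
    protein_id = c("P1", "P2", "P3", "P4", "P5", "P6"),
    cog = c("C0001", "C0001", "C0001", "C0002", "C0001", "C0001")
  )
  self <- tibble::tibble(
    query_id = proteins$protein_id, subject_id = proteins$protein_id,
    percent_identity = 100, bit_score = 2 * proteins$length
  )
  cross <- tibble::tibble(
    query_id =   c("P1", "P1", "P2", "P2", "P1", "P3"),
    subject_id = c("P2", "P3", "P3", "P5", "P5", "P4"),
    percent_identity = 50,
    bit_score = c(90, 85, 82, 80, 70, 100)
  )
  list(proteins = proteins, cog_map = cog_map,
       hits = dplyr::bind_rows(self, cross))
}

# Shared phyletic-profile fixture: random presence table over
# equally sized classes.
phyletic_fixture <- function(n_classes = 3, orgs_per_class = 5,
                             n_ogs = 8, seed = 81, p = 0.4) {
  set.seed(seed)
  classes <- sprintf("class%d", seq_len(n_classes))
  org2cls <- tibble::tibble(
    organism = sprintf("org%02d", seq_len(n_classes * orgs_per_class)),
    class = rep(classes, each = orgs_per_class))
  ogs <- sprintf("OG%04d", seq_len(n_ogs))
  grid <- expand.grid(organism = org2cls$organism, og = ogs,
                      stringsAsFactors = FALSE)
  presence <- tibble::as_tibble(grid[runif(nrow(grid)) < p, ])
  gene2og <- tibble::tibble(feature_id = sprintf("g%02d", seq_len(n_ogs)),
                            og = ogs)
  list(gene2og = gene2og, presence = presence, org2cls = org2cls,
       classes = classes, ogs = ogs)
}
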