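#' Configuration for a synthetic TraDIS library
#'
#' Bundles every tunable of the simulator with validated defaults.  The
#' defaults describe a saturated library of the kind the classifier is
#' designed for: 2000 genes with gamma-distributed lengths (mean 900 bp),
#' 15% of genes essential with no residual (leak) insertions, a unique-site
#' density of one insertion per 11 bp in dispensable sequence, and a small
#' fraction of domain-essential genes carrying a 450 bp insertion-free block
#' (window + step of the domain scan, so a full sliding window always fits
#' inside the block).
#'
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @param n_genes Number of genes to simulate.
#' @param mean_gene_length Mean gene length in bp (gamma-distributed lengths).
#' @param gene_length_shape Shape of the gene-length gamma distribution.
#' @param intergenic_fraction Fraction of the genome that is intergenic.
#' @param essential_fraction Fraction of genes that are essential.
#' @param domain_essential_fraction Fraction of genes that are
#'   domain-essential.
#' @param nonessential_density Per-bp Bernoulli insertion probability in
#'   dispensable sequence (genes and intergenic); default 1/11.
#' @param essential_leak_density Per-bp insertion probability inside
#'   essential genes (default 0; set small and positive to stress the
#'   classifier).
#' @param domain_free_block Length in bp of the insertion-free block planted
#'   in domain-essential genes.
#' @param read_count_mean Mean junction-read count per unique site (counts
#'   are 1 + geometric; they do not affect the essentiality statistic).
#' @param replicon_id Replicon name used in the synthetic annotation.
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       mean_gene_length = 900,
                       gene_length_shape = 4,
                       intergenic_fraction = 0.15,
                       essential_fraction = 0.15,
                       domain_essential_fraction = 0.01,
                       nonessential_density = 1 / 11,
                       essential_leak_density = 0,
                       domain_free_block = 450L,
                       read_count_mean = 5,
                       replicon_id = "sim_chr") {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    mean_gene_length = mean_gene_length,
    gene_length_shape = gene_length_shape,
    intergenic_fraction = intergenic_fraction,
    essential_fraction = essential_fraction,
    domain_essential_fraction = domain_essential_fraction,
    nonessential_density = nonessential_density,
    essential_leak_density = essential_leak_density,
    domain_free_block = as.integer(domain_free_block),
    read_count_mean = read_count_mean,
    replicon_id = replicon_id
  )
  stopifnot(
    cfg$n_genes >= 1,
    cfg$mean_gene_length > 0, cfg$gene_length_shape > 0,
    cfg$intergenic_fraction >= 0, cfg$intergenic_fraction < 1,
    cfg$essential_fraction >= 0, cfg$essential_fraction <= 1,
    cfg$domain_essential_fraction >= 0,
    cfg$essential_fraction + cfg$domain_essential_fraction <= 1,
    cfg$nonessential_density >= 0, cfg$nonessential_density <= 1,
    cfg$essential_leak_density >= 0, cfg$essential_leak_density <= 1,
    cfg$domain_free_block >= 1,
    cfg$read_count_mean >= 1
  )
  structure(cfg, class = "sim_config")
}

#' Simulate a genome annotation
#'
#' Draws `n_genes` non-overlapping genes on a single replicon.  Gene lengths
#' are gamma-distributed with mean `mean_gene_length`; genes are separated
#' by exponential-length intergenic gaps sized so that the intergenic
#' fraction of the genome matches `intergenic_fraction` in expectation.
#' Identical configurations (including the seed) give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with `annotation` (feature tibble as from
#'   [read_annotation()]) and `genome_length` (bp).
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  shape <- config$gene_length_shape
  lengths <- pmax(90L, as.integer(round(
    rgamma(n, shape = shape, scale = config$mean_gene_length / shape)
  )))
  f <- config$intergenic_fraction
  mean_gap <- if (f > 0) f / (1 - f) * sum(lengths) / (n + 1) else 1
  gaps <- pmax(1L, as.integer(round(rexp(n + 1, rate = 1 / mean_gap))))
  starts <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lengths[i]
  }
  genome_length <- pos + gaps[n + 1] - 1L
  ann <- tibble(
    feature_id = sprintf("sim_%04d", seq_len(n)),
    replicon_id = config$replicon_id,
    start = starts,
    end = starts + lengths - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    kind = "CDS"
  )
  validate_annotation(ann)
  stopifnot(all(ann$start[-1] > ann$end[-n] | n == 1))
  list(annotation = ann, genome_length = genome_length)
}

# Bernoulli(p) insertion positions on 1..len, returned as sorted offsets.
draw_sites <- function(len, p) {
  if (len <= 0 || p <= 0) return(integer(0))
  k <- rbinom(1, len, p)
  if (k == 0) return(integer(0))
  sort(sample.int(len, k))
}

#' Simulate a transposon insertion library with known ground truth
#'
#' Labels genes essential / domain-essential / non-essential according to the
#' configured fractions, then draws unique insertion sites as a per-base
#' Bernoulli process: dispensable genes and intergenic sequence at
#' `nonessential_density`, essential genes at `essential_leak_density`, and
#' domain-essential genes at `nonessential_density` outside one contiguous
#' insertion-free block of `domain_free_block` bp placed uniformly within
#' the gene.  Genes shorter than the block are relabelled non-essential with
#' a message.  Read counts per site are 1 + geometric, for format realism
#' only.
#'
#' @param annotation Feature tibble (normally from [simulate_genome()]).
#' @param config A [sim_config()].
#' @param genome_length Replicon length in bp; intergenic insertions are
#'   drawn over the complement of the gene intervals.
#' @return A list with `insertions` (tibble: `replicon_id`, `position`,
#'   `read_count`), `truth` (tibble: `feature_id`, `truth_label` in
#'   `essential` / `non_essential` / `domain_essential`), and `free_blocks`
#'   (tibble of the planted insertion-free block per domain-essential gene).
#' @export
simulate_insertions <- function(annotation, config = sim_config(),
                                genome_length = max(annotation$end)) {
  stopifnot(inherits(config, "sim_config"))
  validate_annotation(annotation)
  set.seed(config$seed + 1L)
  n <- nrow(annotation)
  len <- annotation$end - annotation$start + 1L

  n_ess <- round(config$essential_fraction * n)
  n_dom <- round(config$domain_essential_fraction * n)
  truth <- rep("non_essential", n)
  idx <- sample.int(n)
  truth[idx[seq_len(n_ess)]] <- "essential"
  if (n_dom > 0) {
    dom_pool <- idx[-seq_len(n_ess)]
    # a domain-essential gene must be able to host the free block plus at
    # least one flanking bp on each side, otherwise it is indistinguishable
    # from a fully essential gene
    dom_ok <- dom_pool[len[dom_pool] >= config$domain_free_block + 2L]
    if (length(dom_ok) < n_dom) {
      inform(sprintf(
        "Only %d of %d requested domain-essential genes are long enough for a %d bp free block; the rest stay non-essential.",
        length(dom_ok), n_dom, config$domain_free_block))
      n_dom <- length(dom_ok)
    }
    truth[dom_ok[seq_len(n_dom)]] <- "domain_essential"
  }

  p_ne <- config$nonessential_density
  p_leak <- config$essential_leak_density
  positions <- vector("list", n + 1L)
  blocks <- list()
  for (i in seq_len(n)) {
    L <- len[i]
    if (truth[i] == "essential") {
      off <- draw_sites(L, p_leak)
    } else if (truth[i] == "domain_essential") {
      B <- config$domain_free_block
      b_start <- 1L + sample.int(L - B - 1L, 1)  # keep >=1 bp flank each side
      off <- draw_sites(L, p_ne)
      off <- off[off < b_start | off > b_start + B - 1L]
      blocks[[length(blocks) + 1L]] <- tibble(
        feature_id = annotation$feature_id[i],
        block_start = annotation$start[i] + b_start - 1L,
        block_end = annotation$start[i] + b_start + B - 2L
      )
    } else {
      off <- draw_sites(L, p_ne)
    }
    positions[[i]] <- annotation$start[i] + off - 1L
  }

  # intergenic complement of the gene intervals
  genic <- logical(genome_length)
  for (i in seq_len(n)) {
    genic[annotation$start[i]:min(annotation$end[i], genome_length)] <- TRUE
  }
  inter_pos <- which(!genic)
  if (length(inter_pos) > 0 && p_ne > 0) {
    k <- rbinom(1, length(inter_pos), p_ne)
    if (k > 0) positions[[n + 1L]] <- sort(sample(inter_pos, k))
  }

  pos <- sort(unique(unlist(positions)))
  rc_prob <- 1 / config$read_count_mean
  ins <- tibble(
    replicon_id = config$replicon_id,
    position = as.integer(pos),
    read_count = 1L + as.integer(rgeom(length(pos), rc_prob))
  )
  list(
    insertions = ins,
    truth = tibble(feature_id = annotation$feature_id, truth_label = truth),
    free_blocks = if (length(blocks)) bind_rows(blocks) else
      tibble(feature_id = character(), block_start = integer(),
             block_end = integer())
  )
}

#' Simulate an annotated genome plus insertion library in one call
#'
#' @param config A [sim_config()].
#' @return A list with `annotation`, `genome_length`, `insertions`, `truth`,
#'   `free_blocks` and the `config` used.
#' @export
simulate_library <- function(config = sim_config()) {
  g <- simulate_genome(config)
  ins <- simulate_insertions(g$annotation, config, g$genome_length)
  c(g, ins, list(config = config))
}

#' Simulate a toy all-vs-all BLAST universe with planted paralog families
#'
#' Builds a proteome of `n_families` families with the given sizes.  Members
#' of a family share a COG label, have mutually compatible lengths (within
#' 15% of the family base length) and within-family bit-scores far above the
#' paralog thresholds; self hits are present for every protein; sparse
#' between-family hits are far below threshold.  The planted families of
#' size >= 2 are the ground-truth paralog groups.
#'
#' @param n_families Number of families.
#' @param family_sizes Integer vector of family sizes (recycled / sampled
#'   from 1..10 when `NULL`).
#' @param seed Integer seed.
#' @return A list with `proteins` (tibble: `protein_id`, `length`, `cog`),
#'   `hits` (BLAST-6-shaped tibble including self hits), `cog_map` (tibble:
#'   `protein_id`, `cog`), and `truth_groups` (tibble: `family_id`,
#'   `protein_id` for families of size >= 2).
#' @export
simulate_blast_universe <- function(n_families = 20, family_sizes = NULL,
                                    seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(family_sizes)) {
    family_sizes <- sample(1:10, n_families, replace = TRUE)
  }
  stopifnot(length(family_sizes) == n_families, all(family_sizes >= 1))
  prot <- list()
  hits <- list()
  pid <- 0L
  for (f in seq_len(n_families)) {
    s <- family_sizes[f]
    base_len <- sample(200:600, 1)
    lens <- as.integer(round(base_len * runif(s, 0.85, 1.15)))
    ids <- sprintf("prot_%03d_%02d", f, seq_len(s))
    cog <- sprintf("COG%04d", f)
    prot[[f]] <- tibble(protein_id = ids, length = lens, cog = cog,
                        family_id = sprintf("fam_%03d", f))
    # self hits: bit-score ~ 2 bits per residue
    hits[[length(hits) + 1L]] <- tibble(
      query_id = ids, subject_id = ids, percent_identity = 100,
      alignment_length = lens, evalue = 0, bit_score = 2 * lens,
      query_length = lens, subject_length = lens,
      query_cov = 100, subject_cov = 100
    )
    if (s > 1) {
      pr <- expand.grid(i = seq_len(s), j = seq_len(s))
      pr <- pr[pr$i != pr$j, ]
      mn <- pmin(lens[pr$i], lens[pr$j])
      hits[[length(hits) + 1L]] <- tibble(
        query_id = ids[pr$i], subject_id = ids[pr$j],
        percent_identity = round(runif(nrow(pr), 40, 80), 1),
        alignment_length = mn,
        evalue = 1e-30, bit_score = round(1.2 * mn + runif(nrow(pr), 0, 5), 1),
        query_length = lens[pr$i], subject_length = lens[pr$j],
        query_cov = 100 * mn / lens[pr$i], subject_cov = 100 * mn / lens[pr$j]
      )
    }
  }
  proteins <- bind_rows(prot)
  # sparse spurious between-family hits, all far below the 0.1 * self-score
  # threshold
  n_noise <- max(1L, nrow(proteins))
  qi <- sample.int(nrow(proteins), n_noise, replace = TRUE)
  si <- sample.int(nrow(proteins), n_noise, replace = TRUE)
  diff_fam <- proteins$family_id[qi] != proteins$family_id[si]
  if (any(diff_fam)) {
    qi <- qi[diff_fam]; si <- si[diff_fam]
    mn <- pmin(proteins$length[qi], proteins$length[si])
    hits[[length(hits) + 1L]] <- tibble(
      query_id = proteins$protein_id[qi], subject_id = proteins$protein_id[si],
      percent_identity = round(runif(length(qi), 15, 25), 1),
      alignment_length = as.integer(round(0.3 * mn)),
      evalue = 1e-3,
      bit_score = round(0.05 * 2 * mn, 1),
      query_length = proteins$length[qi],
      subject_length = proteins$length[si],
      query_cov = 100 * 0.3, subject_cov = 100 * 0.3
    )
  }
  fam_sizes <- table(proteins$family_id)
  truth <- proteins |>
    filter(.data$family_id %in% names(fam_sizes)[fam_sizes >= 2]) |>
    select("family_id", "protein_id")
  list(
    proteins = select(proteins, "protein_id", "length", "cog"),
    hits = bind_rows(hits),
    cog_map = select(proteins, "protein_id", "cog"),
    truth_groups = truth
  )
}
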