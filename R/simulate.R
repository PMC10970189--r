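#' Configuration for the two-group expression simulator
#'
#' Collects every knob of the synthetic-data generator in one validated list.
#' The defaults emulate the study design the pipeline targets: two contrasted
#' groups of bulk expression samples (72 "sensitive" and 96 "tolerant", the
#' sizes that survive outlier removal in a typical multi-dataset merge), a
#' shared universe of genes organised into tightly co-expressed module blocks,
#' a small set of broadly connected hub genes, and a set of planted gene pairs
#' whose correlation differs between the groups by `planted_delta`.
#'
#' Within-module correlation defaults to 0.95: at the conventional signed soft
#' threshold (beta = 22) and TOM export cutoff (0.4) only blocks this tight
#' produce any network edges, which is the regime real co-expression networks
#' exported at those thresholds occupy.
#'
#' @param n_genes Total number of genes simulated.
#' @param n_samples_per_group Integer vector of length 2: samples in group A
#'   ("sensitive") and group B ("tolerant").
#' @param n_modules Number of co-expressed module blocks.
#' @param module_size Genes per module block.
#' @param within_module_cor Pairwise Pearson correlation between the core
#'   genes of a module block, in (0, 1). Block membership is graded: each
#'   block has a small perfectly loaded core at this correlation and a cubic
#'   decline of factor loadings toward a floor, the profile that gives
#'   simulated co-expression data the right-skewed connectivity
#'   distribution observed in real networks.
#' @param n_hub_genes Number of hub genes: an additional tightly
#'   co-expressed block with graded loadings whose top members carry the
#'   highest connectivity in the simulated data.
#' @param n_diff_pairs Number of planted differentially correlated gene pairs.
#'   Planted pairs are disjoint from module blocks and hubs.
#' @param planted_delta Target difference r_A - r_B for planted pairs, in
#'   (0, 2]. By default r_B = 0 and r_A = planted_delta; targets are clamped
#'   to [-0.99, 0.99] to keep Fisher's z finite.
#' @param noise_sd Standard deviation of the per-gene noise added to the
#'   latent factor signal (the factor itself has unit variance).
#' @param n_duplicate_probes Genes to split into duplicate probe rows in
#'   [corrupt_with_probes_and_outliers()].
#' @param n_outlier_samples Shifted outlier samples appended per group by
#'   [corrupt_with_probes_and_outliers()].
#' @param seed Integer seed; fully determines the simulated output.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_two_group_expression()]
#' @export
sim_config <- function(n_genes = 300L,
                       n_samples_per_group = c(72L, 96L),
                       n_modules = 6L,
                       module_size = 25L,
                       within_module_cor = 0.95,
                       n_hub_genes = 10L,
                       n_diff_pairs = 10L,
                       planted_delta = 0.9,
                       noise_sd = 1,
                       n_duplicate_probes = 0L,
                       n_outlier_samples = 0L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    within_module_cor = within_module_cor,
    n_hub_genes = as.integer(n_hub_genes),
    n_diff_pairs = as.integer(n_diff_pairs),
    planted_delta = planted_delta,
    noise_sd = noise_sd,
    n_duplicate_probes = as.integer(n_duplicate_probes),
    n_outlier_samples = as.integer(n_outlier_samples),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$n_samples_per_group) == 2L,
    all(cfg$n_samples_per_group >= 4L),
    cfg$n_genes >= 1L,
    cfg$n_modules >= 0L, cfg$module_size >= 2L,
    cfg$within_module_cor > 0, cfg$within_module_cor < 1,
    cfg$planted_delta > 0, cfg$planted_delta <= 2,
    cfg$noise_sd > 0,
    cfg$n_hub_genes >= 0L, cfg$n_diff_pairs >= 0L,
    cfg$n_duplicate_probes >= 0L, cfg$n_outlier_samples >= 0L
  )
  n_structured <- cfg$n_modules * cfg$module_size + cfg$n_hub_genes +
    2L * cfg$n_diff_pairs
  if (n_structured > cfg$n_genes) {
    stop("sim_config: modules, hubs and planted pairs need ", n_structured,
         " genes but n_genes = ", cfg$n_genes, call. = FALSE)
  }
  invisible(cfg)
}

gene_ids <- function(n) sprintf("G%04d", seq_len(n))

# Latent Gaussian -> nonnegative expression. An affine map preserves all
# pairwise correlations exactly; the floor at 0 is ~6 sd out so it never
# distorts them in practice.
latent_to_expression <- function(z) {
  x <- 50 + 10 * z
  x[x < 0] <- 0
  x
}

#' Simulate two-group expression data with planted structure
#'
#' Draws gene-by-sample expression for two groups from a latent factor model.
#' Genes in a module block share a unit-variance factor; the block's core
#' genes load at `sqrt(within_module_cor)` (pairwise correlation
#' `within_module_cor`) and the remaining members' loadings decline
#' cubically toward a floor, so membership is graded as in real
#' co-expression modules. Hub genes form one extra graded block drawn the
#' same way. Each planted differential pair is an
#' independent bivariate draw with target correlation `r_A` in group A and
#' `r_A - planted_delta` in group B (clamped to [-0.99, 0.99]); remaining
#' genes are independent noise. Latent values are mapped to nonnegative
#' expression by an affine shift, which preserves every planted correlation
#' exactly.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_output` with elements
#'   * `expression`: named list of two tibbles (`sensitive`, `tolerant`),
#'     each with a `gene_id` column followed by one numeric column per sample;
#'   * `modules`: tibble of `gene_id`, `module`;
#'   * `hubs`: character vector of hub gene IDs;
#'   * `planted_pairs`: tibble of `gene_i`, `gene_j`, `r_sensitive`,
#'     `r_tolerant`, `delta_r` (population targets);
#'   * `probe_map`, `outlier_samples`: filled by
#'     [corrupt_with_probes_and_outliers()], initially empty/NULL;
#'   * `config`: the configuration used.
#' @examples
#' sim <- simulate_two_group_expression(sim_config(n_genes = 60, n_modules = 2,
#'                                                 module_size = 10, seed = 7))
#' sim$expression$sensitive
#' @export
simulate_two_group_expression <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)

  ids <- gene_ids(config$n_genes)
  n_mod_genes <- config$n_modules * config$module_size
  mod_idx <- seq_len(n_mod_genes)
  hub_idx <- seq_len(config$n_hub_genes) + n_mod_genes
  pair_idx <- seq_len(2L * config$n_diff_pairs) + n_mod_genes + config$n_hub_genes

  module_of <- rep(seq_len(config$n_modules), each = config$module_size)

  # Planted pair targets: r_A - r_B = planted_delta, anchored so the pair is
  # strongly co-expressed in group A (inside the regime that survives TOM
  # export at a high soft threshold) and essentially uncorrelated in group B
  # — a correlation present in one condition and lost in the other.
  clamp <- function(r) pmin(0.99, pmax(-0.99, r))
  r_a <- clamp(0.05 + config$planted_delta)
  r_b <- clamp(r_a - config$planted_delta)
  planted <- if (config$n_diff_pairs > 0L) {
    tibble::tibble(
      gene_i = ids[pair_idx[seq(1L, length(pair_idx), by = 2L)]],
      gene_j = ids[pair_idx[seq(2L, length(pair_idx), by = 2L)]],
      r_sensitive = r_a,
      r_tolerant = r_b,
      delta_r = r_a - r_b
    )
  } else {
    tibble::tibble(gene_i = character(), gene_j = character(),
                   r_sensitive = double(), r_tolerant = double(),
                   delta_r = double())
  }

  w <- config$within_module_cor

  # Factor-correlation profile of a co-expression block: a small perfectly
  # loaded core (pairwise correlation = the block's tightness) and a cubic
  # decline toward a 0.30 floor, so block membership is graded. The graded
  # profile gives the connectivity distribution the heavy right-skewed shape
  # real co-expression data shows, which a flat profile cannot.
  block_profile <- function(size, tightness) {
    cmax <- sqrt(tightness)
    n_core <- min(2L, size)
    if (size == n_core) return(rep(cmax, size))
    periphery <- cmax * (0.30 + 0.70 * seq(1, 1 / (size - n_core),
                                           length.out = size - n_core)^3)
    c(rep(cmax, n_core), periphery)
  }

  draw_block <- function(loadings, n_samples) {
    f <- stats::rnorm(n_samples)
    eps <- matrix(stats::rnorm(length(loadings) * n_samples),
                  nrow = length(loadings))
    # unit-variance genes at noise_sd = 1; noise_sd scales the residual only
    loadings * matrix(rep(f, each = length(loadings)), nrow = length(loadings)) +
      config$noise_sd * sqrt(1 - loadings^2) * eps
  }

  draw_group <- function(n_samples, group, r_pair) {
    z <- matrix(0, nrow = config$n_genes, ncol = n_samples)
    for (m in seq_len(config$n_modules)) {
      # module tightness declines slightly across modules so block cores do
      # not pile up at one connectivity value
      w_m <- max(0.5, w - 0.012 * (m - 1))
      rows <- mod_idx[module_of == m]
      z[rows, ] <- draw_block(block_profile(length(rows), w_m), n_samples)
    }
    if (length(hub_idx)) {
      hub_load <- sqrt(w) * seq(1, 0.75, length.out = length(hub_idx))
      z[hub_idx, ] <- draw_block(hub_load, n_samples)
    }
    if (config$n_diff_pairs > 0L) {
      for (p in seq_len(config$n_diff_pairs)) {
        i <- pair_idx[2L * p - 1L]
        j <- pair_idx[2L * p]
        u <- stats::rnorm(n_samples)
        v <- r_pair * u + sqrt(1 - r_pair^2) * stats::rnorm(n_samples)
        z[i, ] <- u
        z[j, ] <- v
      }
    }
    free <- setdiff(seq_len(config$n_genes), c(mod_idx, hub_idx, pair_idx))
    if (length(free)) {
      z[free, ] <- matrix(stats::rnorm(length(free) * n_samples), nrow = length(free))
    }
    x <- latent_to_expression(z)
    dimnames(x) <- list(ids, sprintf("%s_s%03d", group, seq_len(n_samples)))
    expression_tibble(x)
  }

  expr <- list(
    sensitive = draw_group(config$n_samples_per_group[1], "sens", r_a),
    tolerant = draw_group(config$n_samples_per_group[2], "tol", r_b)
  )

  structure(list(
    expression = expr,
    modules = tibble::tibble(gene_id = ids[mod_idx],
                             module = module_of),
    hubs = ids[hub_idx],
    planted_pairs = planted,
    probe_map = tibble::tibble(probe = character(), gene = character()),
    outlier_samples = tibble::tibble(group = character(), sample_id = character()),
    config = config
  ), class = "sim_output")
}

#' Corrupt a simulated dataset with duplicate probes and outlier samples
#'
#' Exercises the preprocessing stages: splits the first `n_duplicate_probes`
#' genes into two probe rows (`<gene>_p1`, `<gene>_p2`) carrying independent
#' measurement noise, and appends `n_outlier_samples` samples per group drawn
#' from a distribution shifted by `outlier_shift` expression units. The truth
#' (probe map, outlier sample IDs) is recorded in the returned object.
#'
#' @param sim A `sim_output` from [simulate_two_group_expression()].
#' @param config The [sim_config()] used (defaults to `sim$config`).
#' @param probe_noise_sd SD of independent noise added to each probe row, on
#'   the expression scale.
#' @param outlier_shift Location shift of outlier samples, on the expression
#'   scale. The default (50, i.e. five times the expression-scale SD of 10)
#'   makes outliers unambiguous to average-linkage clustering.
#' @return A `sim_output` with modified expression tables and filled
#'   `probe_map` and `outlier_samples`.
#' @export
corrupt_with_probes_and_outliers <- function(sim, config = sim$config,
                                             probe_noise_sd = 2,
                                             outlier_shift = 50) {
  stopifnot(inherits(sim, "sim_output"))
  n_dup <- config$n_duplicate_probes
  n_out <- config$n_outlier_samples
  if (n_dup == 0L && n_out == 0L) return(sim)

  ids <- sim$expression$sensitive$gene_id
  stopifnot(n_dup <= length(ids))
  set.seed(config$seed + 1L)

  dup_genes <- ids[seq_len(n_dup)]
  probe_map <- tibble::tibble(
    probe = if (n_dup > 0L) {
      as.vector(rbind(paste0(dup_genes, "_p1"), paste0(dup_genes, "_p2")))
    } else {
      character()
    },
    gene = rep(dup_genes, each = 2L)
  )

  out_truth <- list()
  for (grp in names(sim$expression)) {
    x <- expression_matrix(sim$expression[[grp]])
    stopifnot(n_out <= ncol(x))
    if (n_dup > 0L) {
      dup_rows <- x[dup_genes, , drop = FALSE]
      p1 <- dup_rows + matrix(stats::rnorm(length(dup_rows), sd = probe_noise_sd),
                              nrow = n_dup)
      p2 <- dup_rows + matrix(stats::rnorm(length(dup_rows), sd = probe_noise_sd),
                              nrow = n_dup)
      rownames(p1) <- paste0(dup_genes, "_p1")
      rownames(p2) <- paste0(dup_genes, "_p2")
      x <- rbind(x[setdiff(rownames(x), dup_genes), , drop = FALSE], p1, p2)
    }
    if (n_out > 0L) {
      out_ids <- sprintf("%s_outlier%02d", grp, seq_len(n_out))
      shifted <- matrix(stats::rnorm(nrow(x) * n_out, mean = outlier_shift, sd = 10),
                        nrow = nrow(x)) +
        rowMeans(x)
      shifted[shifted < 0] <- 0
      colnames(shifted) <- out_ids
      x <- cbind(x, shifted)
      out_truth[[grp]] <- tibble::tibble(group = grp, sample_id = out_ids)
    }
    sim$expression[[grp]] <- expression_tibble(x)
  }
  sim$probe_map <- probe_map
  sim$outlier_samples <- dplyr::bind_rows(out_truth)
  sim
}

#' Generate GO-annotation, gene-position and marker-interval fixtures
#'
#' Builds the annotation side inputs the pipeline consumes, with known truth:
#' random GO terms over the simulated genes plus one term (`GO:TEST01`)
#' deliberately enriched in the hub genes; the four transcription-activity GO
#' terms (GO:0006350, GO:0030528, GO:0006351, GO:0006366) attached to a known
#' transcription-factor subset; a genome position for every gene; and marker
#' intervals covering a known subset of genes.
#'
#' @param sim A `sim_output`.
#' @param n_terms Number of random background GO terms (>= 1).
#' @param n_intervals Number of marker intervals (0 allowed).
#' @param seed Integer seed.
#' @return A list with tibbles `go_annotation` (gene, term), `gene_positions`
#'   (gene_id, chrom, position), `marker_intervals` (chrom, start, end, name),
#'   and truth vectors `enriched_term`, `tf_genes`, `genes_in_intervals`.
#' @export
generate_fixture_annotations <- function(sim, n_terms = 20L, n_intervals = 5L,
                                         seed = 1L) {
  stopifnot(inherits(sim, "sim_output"), n_terms >= 1L, n_intervals >= 0L)
  set.seed(seed)
  ids <- sim$expression$sensitive$gene_id
  n <- length(ids)

  # background terms: each gene gets 1-3 random terms
  terms <- sprintf("GO:RND%03d", seq_len(n_terms))
  ann <- purrr::map_dfr(ids, function(g) {
    tibble::tibble(gene = g,
                   term = sample(terms, sample(1:3, 1)))
  })

  # one term packed with the hubs plus a few random genes: enriched by design
  enriched_term <- "GO:TEST01"
  enriched_genes <- unique(c(sim$hubs, sample(ids, max(1L, n %/% 50))))
  ann <- dplyr::bind_rows(ann,
                          tibble::tibble(gene = enriched_genes, term = enriched_term))

  # transcription-activity terms on a known TF subset: half the hubs, a few
  # module genes, and one side of the first planted differential pairs (so
  # TF-centred differential modules exist downstream), one term each
  tf_terms <- c("GO:0006350", "GO:0030528", "GO:0006351", "GO:0006366")
  tf_genes <- unique(c(
    sim$hubs[seq_len(ceiling(length(sim$hubs) / 2))],
    utils::head(sim$modules$gene_id, 4L),
    utils::head(sim$planted_pairs$gene_i, 3L)
  ))
  if (length(tf_genes)) {
    ann <- dplyr::bind_rows(ann, tibble::tibble(
      gene = tf_genes,
      term = sample(tf_terms, length(tf_genes), replace = TRUE)
    ))
  }
  ann <- dplyr::distinct(dplyr::arrange(ann, .data$gene, .data$term))

  gene_positions <- tibble::tibble(
    gene_id = ids,
    chrom = sprintf("chr%d", sample(1:12, n, replace = TRUE)),
    position = sample(1:3e7, n)
  )

  if (n_intervals > 0L) {
    anchors <- dplyr::slice_sample(gene_positions, n = n_intervals)
    marker_intervals <- tibble::tibble(
      chrom = anchors$chrom,
      start = pmax(1L, anchors$position - 2e6L),
      end = anchors$position + 2e6L,
      name = sprintf("mqtl%02d", seq_len(n_intervals))
    )
  } else {
    marker_intervals <- tibble::tibble(chrom = character(), start = integer(),
                                       end = integer(), name = character())
  }
  hits <- dplyr::inner_join(gene_positions, marker_intervals,
                            by = dplyr::join_by("chrom",
                                                dplyr::between("position", "start", "end")))

  list(go_annotation = ann,
       gene_positions = gene_positions,
       marker_intervals = marker_intervals,
       enriched_term = enriched_term,
       tf_genes = tf_genes,
       genes_in_intervals = unique(hits$gene_id))
}
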