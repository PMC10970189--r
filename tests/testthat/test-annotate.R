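test_that("enrichment p-values equal the hypergeometric tail oracle", {
  set.seed(19)
  for (i in 1:50) {
    N <- sample(50:1000, 1)
    K <- sample(1:(N %/% 2), 1)
    n <- sample(1:(N %/% 2), 1)
    k <- sample(0:min(K, n), 1)
    if (k == 0) k <- 1
    p_pkg <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p_pkg, oracle_hyper_tail(k, K, N, n), tolerance = 1e-10)
    # and the one-sided Fisher exact test agrees
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2)
    expect_equal(p_pkg, stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("go_enrichment builds the right 2x2 counts and flags planted signal", {
  genes <- sprintf("G%03d", 1:100)
  ann <- tibble::tibble(
    gene = c(genes, genes[1:10], genes[11:60]),
    term = c(rep("GO:ALL", 100), rep("GO:HIT", 10), rep("GO:OTHER", 50))
  )
  study <- genes[1:20]
  res <- go_enrichment(study, ann, max_p = 1, max_fdr = 1)
  hit <- res[res$term == "GO:HIT", ]
  expect_equal(hit$k, 10)
  expect_equal(hit$n, 20)
  expect_equal(hit$K, 10)
  expect_equal(hit$N, 100)
  expect_equal(hit$p_value,
               stats::phyper(9, 10, 90, 20, lower.tail = FALSE))
  # a term covering the whole background can never be enriched
  expect_equal(res$p_value[res$term == "GO:ALL"], 1)
  strict <- go_enrichment(study, ann)
  expect_true("GO:HIT" %in% strict$term)
  expect_false("GO:ALL" %in% strict$term)
  expect_error(go_enrichment(character(), ann), "empty study set")
  expect_error(go_enrichment("NOT_THERE", ann), "outside the background")
})

test_that("enrichment is invariant to gene order and FDR is monotone in p", {
  sim <- small_sim()
  fx <- generate_fixture_annotations(sim, n_terms = 15, n_intervals = 0,
                                     seed = 4)
  study <- c(sim$hubs, sim$modules$gene_id[1:5])
  res1 <- go_enrichment(study, fx$go_annotation, max_p = 1, max_fdr = 1)
  res2 <- go_enrichment(rev(study),
                        fx$go_annotation[sample(nrow(fx$go_annotation)), ],
                        max_p = 1, max_fdr = 1)
  expect_equal(res1, res2)
  expect_false(is.unsorted(res1$p_value))
  expect_false(is.unsorted(res1$fdr[order(res1$p_value)]))
  # the hub-loaded term is recovered as significant
  expect_true(fx$enriched_term %in%
                go_enrichment(study, fx$go_annotation)$term)
})

test_that("interval mapping is inclusive at both boundaries", {
  pos <- tibble::tibble(gene_id = c("gStart", "gMid", "gEnd", "gOut", "gChr"),
                        chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                        position = c(100, 550, 1000, 1001, 550))
  iv <- tibble::tibble(chrom = "chr1", start = 100, end = 1000, name = "q1")
  hits <- map_genes_to_intervals(pos, iv)
  expect_setequal(hits$gene_id, c("gStart", "gMid", "gEnd"))
  expect_true(all(hits$position >= hits$start & hits$position <= hits$end))
})

test_that("interval mapping equals the nested-loop containment oracle", {
  set.seed(20)
  pos <- tibble::tibble(gene_id = sprintf("G%02d", 1:20),
                        chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
                        position = sample(1:5000, 20))
  iv <- tibble::tibble(chrom = c("chr1", "chr2", "chr1"),
                       start = c(1, 1000, 2500),
                       end = c(2000, 3000, 2600),
                       name = c("q1", "q2", "q3"))
  hits <- map_genes_to_intervals(pos, iv)
  manual <- 0
  for (g in seq_len(nrow(pos))) {
    for (q in seq_len(nrow(iv))) {
      if (pos$chrom[g] == iv$chrom[q] &&
          pos$position[g] >= iv$start[q] && pos$position[g] <= iv$end[q]) {
        manual <- manual + 1
        expect_true(any(hits$gene_id == pos$gene_id[g] &
                          hits$interval == iv$name[q]))
      }
    }
  }
  expect_equal(nrow(hits), manual)
  expect_error(map_genes_to_intervals(pos,
                                      tibble::tibble(chrom = "chr1", start = 10,
                                                     end = 5, name = "bad")),
               "start > end")
})

test_that("TF selection keeps exactly the transcription-annotated genes", {
  ann <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                        term = c("GO:0006350", "GO:9999999", "GO:0030528",
                                 "GO:0006366"))
  expect_equal(select_transcription_factors(c("g1", "g2", "g3"), ann),
               c("g1", "g3"))
  expect_equal(select_transcription_factors("g2", ann), character())
  sim <- small_sim()
  fx <- generate_fixture_annotations(sim, n_terms = 10, n_intervals = 0,
                                     seed = 6)
  picked <- select_transcription_factors(sim$expression$sensitive$gene_id,
                                         fx$go_annotation)
  expect_setequal(picked, fx$tf_genes)
})

test_that("TF modules collect exactly the selected pairs touching each TF", {
  pairs <- tibble::tibble(
    gene_i = c("tf1", "tf1", "g3", "g5"),
    gene_j = c("g1", "g2", "tf1", "g6"),
    r_sensitive = c(0.9, -0.2, 0.8, 0.9),
    r_tolerant = c(0.1, 0.6, -0.1, 0.05),
    delta_r = c(0.8, -0.8, 0.9, 0.85),
    fdr = c(0.01, 0.02, 0.03, 0.001)
  )
  mods <- build_tf_modules(c("tf1", "tf_lonely"), pairs)
  expect_equal(unique(mods$tf), "tf1")
  expect_setequal(mods$partner, c("g1", "g2", "g3"))
  expect_equal(mods$sign[mods$partner == "g2"], "negative")
  expect_equal(mods$sign[mods$partner == "g1"], "positive")
  # module edges are a subset of the selected pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_true(all(key(mods$tf, mods$partner) %in% key(pairs$gene_i, pairs$gene_j)))
  # a TF pair of two TFs appears in both modules
  mods2 <- build_tf_modules(c("tf1", "g3"), pairs)
  expect_equal(sum(mods2$tf == "g3" & mods2$partner == "tf1"), 1)
  expect_equal(sum(mods2$tf == "tf1" & mods2$partner == "g3"), 1)
})
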