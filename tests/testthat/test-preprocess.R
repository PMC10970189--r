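test_that("probe averaging takes per-sample means and passes unmapped rows through", {
  tbl <- tibble::tibble(gene_id = c("p1", "p2", "G9"),
                        s1 = c(2, 4, 7), s2 = c(4, 8, 9))
  pm <- tibble::tibble(probe = c("p1", "p2"), gene = "g")
  out <- average_probes(tbl, pm)
  expect_equal(out$s1[out$gene_id == "g"], 3)
  expect_equal(out$s2[out$gene_id == "g"], 6)
  expect_equal(out[out$gene_id == "G9", -1], tbl[tbl$gene_id == "G9", -1])
})

test_that("probe averaging matches a brute-force loop on random data", {
  set.seed(1)
  tbl <- expression_tibble(matrix(stats::runif(5 * 6), 5,
                                  dimnames = list(paste0("p", 1:5),
                                                  paste0("s", 1:6))))
  pm <- tibble::tibble(probe = paste0("p", 1:5),
                       gene = c("gA", "gA", "gB", "gB", "gB"))
  out <- average_probes(tbl, pm)
  x <- expression_matrix(tbl)
  for (g in c("gA", "gB")) {
    rows <- pm$probe[pm$gene == g]
    for (s in colnames(x)) {
      manual <- 0
      for (p in rows) manual <- manual + x[p, s]
      expect_equal(out[[s]][out$gene_id == g], manual / length(rows))
    }
  }
})

test_that("ambiguous probe maps are rejected", {
  tbl <- tibble::tibble(gene_id = "p1", s1 = 1, s2 = 2)
  pm <- tibble::tibble(probe = c("p1", "p1"), gene = c("gA", "gB"))
  expect_error(average_probes(tbl, pm), "multiple genes")
})

test_that("dataset merging intersects genes and keeps first-input order", {
  m1 <- tibble::tibble(gene_id = c("A", "B", "C"), s1 = 1:3)
  m2 <- tibble::tibble(gene_id = c("D", "C", "B"), t1 = 4:6, t2 = 7:9)
  out <- merge_datasets(list(x = m1, y = m2))
  expect_equal(out$gene_id, c("B", "C"))
  expect_equal(names(out), c("gene_id", "x.s1", "y.t1", "y.t2"))
  expect_equal(out$y.t1, c(6, 5))
  expect_identical(merge_datasets(list(m1)), m1)
  expect_error(merge_datasets(list(m1, tibble::tibble(gene_id = "Z", u = 1))),
               "no genes shared")
})

test_that("merging three overlapping fixtures keeps exactly the common genes", {
  set.seed(2)
  all_genes <- sprintf("G%03d", 1:240)
  common <- sample(all_genes, 120)
  # each dataset gets private extra genes so the three-way intersection is
  # exactly the common set
  private <- split(setdiff(all_genes, common), rep(1:3, each = 40))
  mk <- function(i, extra, prefix) {
    ids <- sample(c(common, sample(private[[i]], extra)))
    expression_tibble(matrix(stats::runif(length(ids) * 4),
                             ncol = 4,
                             dimnames = list(ids, paste0(prefix, 1:4))))
  }
  merged <- merge_datasets(list(mk(1, 30, "a"), mk(2, 40, "b"), mk(3, 10, "c")))
  expect_equal(nrow(merged), 120)
  expect_setequal(merged$gene_id, common)
})

test_that("rescaling maps each sample onto [0, 100] exactly and is idempotent", {
  tbl <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        s1 = c(1, 2, 3), s2 = c(0, 100, 50))
  out <- rescale_samples(tbl)
  expect_equal(out$s1, c(0, 50, 100))
  expect_equal(out$s2, c(0, 100, 50))
  expect_identical(rescale_samples(out), out)

  set.seed(3)
  rnd <- expression_tibble(matrix(stats::rnorm(40, 10, 4), 8,
                                  dimnames = list(paste0("g", 1:8),
                                                  paste0("s", 1:5))))
  scaled <- expression_matrix(rescale_samples(rnd))
  raw <- expression_matrix(rnd)
  for (s in colnames(raw)) {
    lo <- min(raw[, s]); hi <- max(raw[, s])
    for (g in rownames(raw)) {
      expect_equal(scaled[g, s], (raw[g, s] - lo) / (hi - lo) * 100)
    }
    expect_equal(min(scaled[, s]), 0)
    expect_equal(max(scaled[, s]), 100)
  }
})

test_that("constant sample columns abort rescaling with the sample named", {
  tbl <- tibble::tibble(gene_id = c("g1", "g2"), ok = c(1, 2), flat = c(5, 5))
  expect_error(rescale_samples(tbl), "flat")
})

test_that("the expression filter keeps the 50%-of-samples boundary and is idempotent", {
  tbl <- tibble::tibble(gene_id = c("boundary", "allzero", "high"),
                        s1 = c(0.5, 0, 50), s2 = c(2, 0, 60),
                        s3 = c(3, 0, 70), s4 = c(0, 0, 80))
  out <- filter_low_expression(tbl)
  expect_setequal(out$gene_id, c("boundary", "high"))
  expect_identical(filter_low_expression(out), out)
})

test_that("the expression filter agrees with a per-gene counting oracle", {
  set.seed(4)
  x <- matrix(stats::runif(100 * 10, 0, 3), 100,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:10)))
  tbl <- expression_tibble(x)
  out <- filter_low_expression(tbl, expression_floor = 1,
                               min_fraction_expressed = 0.5)
  keep <- character()
  for (g in rownames(x)) {
    cnt <- 0
    for (s in colnames(x)) if (x[g, s] > 1) cnt <- cnt + 1
    if (cnt / ncol(x) >= 0.5) keep <- c(keep, g)
  }
  expect_equal(out$gene_id, keep)
})

test_that("outlier detection leaves clean data intact under a generous cut", {
  tbl <- small_expression(n_genes = 20, n_samples = 10, seed = 5)
  out <- detect_outlier_samples(tbl, cut_height = 1e6)
  expect_equal(sum(out$is_outlier), 0)
  expect_setequal(attr(out, "kept"), names(tbl)[-1])
})

test_that("planted far-shifted outliers are exactly the removed samples", {
  cfg <- sim_config(n_genes = 60, n_modules = 2, module_size = 10,
                    n_hub_genes = 0, n_diff_pairs = 0,
                    n_samples_per_group = c(30, 30),
                    n_outlier_samples = 3, seed = 21)
  sim <- corrupt_with_probes_and_outliers(simulate_two_group_expression(cfg))
  for (grp in c("sensitive", "tolerant")) {
    out <- detect_outlier_samples(sim$expression[[grp]])
    truth <- sim$outlier_samples$sample_id[sim$outlier_samples$group == grp]
    expect_setequal(attr(out, "removed"), truth)
    cleaned <- drop_outlier_samples(sim$expression[[grp]], out)
    expect_equal(ncol(cleaned) - 1, 30)
  }
})

test_that("identical duplicate samples are never flagged as outliers", {
  base <- small_expression(n_genes = 15, n_samples = 4, seed = 6)
  tbl <- base
  tbl$dup1 <- tbl$s01
  tbl$dup2 <- tbl$s01
  out <- detect_outlier_samples(tbl, cut_height = 1e6)
  expect_false(any(out$is_outlier[out$sample_id %in% c("s01", "dup1", "dup2")]))
})
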