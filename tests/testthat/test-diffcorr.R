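test_that("Fisher z transform is odd, zero at zero, and matches the log form", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 0.5 * log(19), tolerance = 1e-10)
  set.seed(14)
  r <- stats::runif(50, -0.999, 0.999)
  expect_equal(fisher_z(-r), -fisher_z(r))
  # clamped at the boundary, stays finite
  expect_true(is.finite(fisher_z(1)))
  expect_true(is.finite(fisher_z(-1)))
})

test_that("the z-test is zero under equality and antisymmetric under group swap", {
  eq <- differential_correlation_test(0.42, 30, 0.42, 50)
  expect_equal(eq$z_stat, 0)
  expect_equal(eq$p_value, 1)
  fwd <- differential_correlation_test(0.8, 40, 0.1, 60)
  rev <- differential_correlation_test(0.1, 60, 0.8, 40)
  expect_equal(fwd$z_stat, -rev$z_stat)
  expect_equal(fwd$p_value, rev$p_value)
  expect_error(differential_correlation_test(0.5, 3, 0.2, 50), "3 samples")
})

test_that("the z-test matches an erfc-based evaluation of the textbook formula", {
  skip_if_not_installed("pracma")
  r1 <- 0.9; n1 <- 72; r2 <- 0.1; n2 <- 96
  out <- differential_correlation_test(r1, n1, r2, n2)
  z_oracle <- (0.5 * log((1 + r1) / (1 - r1)) - 0.5 * log((1 + r2) / (1 - r2))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p_oracle <- pracma::erfc(abs(z_oracle) / sqrt(2))
  expect_equal(out$z_stat, z_oracle, tolerance = 1e-12)
  expect_equal(out$p_value, p_oracle, tolerance = 1e-12)
})

test_that("screening emits one record per unordered pair with delta_r filled", {
  sim <- small_sim()
  genes <- sim$expression$sensitive$gene_id[1:12]
  rec <- screen_all_pairs(sim$expression$sensitive, sim$expression$tolerant,
                          gene_universe = genes)
  expect_equal(nrow(rec), choose(12, 2))
  expect_equal(rec$delta_r, rec$r_sensitive - rec$r_tolerant)
  expect_equal(unique(rec$n_sensitive), 40)
  expect_equal(unique(rec$n_tolerant), 50)
  expect_false(any(duplicated(paste(rec$gene_i, rec$gene_j))))
})

test_that("pairs with a constant gene are dropped with a warning", {
  xs <- matrix(stats::runif(12), 3,
               dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  xt <- xs + matrix(stats::runif(12), 3)
  xt["g2", ] <- 7
  w <- testthat::capture_warnings(
    rec <- screen_all_pairs(expression_tibble(xs), expression_tibble(xt))
  )
  expect_true(any(grepl("constant", w)))
  expect_equal(nrow(rec), 1)
  expect_setequal(c(rec$gene_i, rec$gene_j), c("g1", "g3"))
})

test_that("planted differential pairs carry large |delta_r| in the screen", {
  sim <- simulate_two_group_expression(sim_config(
    n_genes = 30, n_modules = 1, module_size = 10, n_hub_genes = 0,
    n_diff_pairs = 5, planted_delta = 0.9,
    n_samples_per_group = c(72, 96), seed = 15
  ))
  rec <- screen_all_pairs(sim$expression$sensitive, sim$expression$tolerant)
  planted <- dplyr::inner_join(rec, sim$planted_pairs,
                               by = c("gene_i", "gene_j"),
                               suffix = c("", "_true"))
  expect_equal(nrow(planted), 5)
  # individual estimates carry sampling noise of sd ~ 0.11 at these n
  expect_true(all(abs(abs(planted$delta_r) - 0.9) < 0.3))
  expect_lt(abs(mean(abs(planted$delta_r)) - 0.9), 0.15)
})

test_that("BH adjustment matches stats::p.adjust and handles edge cases", {
  rec <- tibble::tibble(p_value = c(1, 1, 1), z_stat = c(0, 0, 0))
  expect_equal(adjust_fdr(rec)$fdr, c(1, 1, 1))
  one <- tibble::tibble(p_value = 0.03, z_stat = 2)
  expect_equal(adjust_fdr(one)$fdr, 0.03)
  set.seed(16)
  many <- tibble::tibble(p_value = stats::runif(200), z_stat = stats::rnorm(200))
  expect_equal(adjust_fdr(many)$fdr,
               stats::p.adjust(many$p_value, method = "BH"))
})

test_that("local fdr is small in the tails and near one in the null bulk", {
  set.seed(17)
  z <- c(stats::rnorm(2000), stats::rnorm(40, mean = 6))
  rec <- tibble::tibble(z_stat = z, p_value = 2 * stats::pnorm(-abs(z)))
  out <- adjust_fdr(rec, method = "local")
  expect_true(all(out$fdr >= 0 & out$fdr <= 1))
  expect_lt(mean(out$fdr[z > 5]), 0.2)
  expect_gt(mean(out$fdr[abs(z) < 1]), 0.8)
})

test_that("selection excludes the low-versus-moderate correlation example", {
  rec <- tibble::tibble(
    gene_i = c("a", "c", "e"), gene_j = c("b", "d", "f"),
    r_sensitive = c(0, 0.85, 0.9), r_tolerant = c(0.6, 0.15, 0.9),
    delta_r = c(-0.6, 0.7, 0), fdr = c(1e-6, 0.01, 1)
  )
  sel <- select_significant_pairs(rec)
  # |delta| = 0.6 excluded no matter how significant; 0.7 boundary included
  expect_false("a" %in% sel$gene_i)
  expect_true("c" %in% sel$gene_i)
  expect_false("e" %in% sel$gene_i)
})

test_that("selection is invariant under group swap up to sign", {
  sim <- small_sim()
  genes <- sim$expression$sensitive$gene_id[1:10]
  fwd <- adjust_fdr(screen_all_pairs(sim$expression$sensitive,
                                     sim$expression$tolerant, genes))
  rev <- adjust_fdr(screen_all_pairs(sim$expression$tolerant,
                                     sim$expression$sensitive, genes))
  expect_equal(fwd$delta_r, -rev$delta_r)
  expect_equal(fwd$z_stat, -rev$z_stat)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(nrow(select_significant_pairs(fwd, 0.5, 0.1)),
               nrow(select_significant_pairs(rev, 0.5, 0.1)))
})

test_that("an all-null screen selects nothing at the default thresholds", {
  # 1000 independent null pairs at the study's group sizes
  set.seed(18)
  n1 <- 72; n2 <- 96
  r1 <- replicate(1000, oracle_cor(stats::rnorm(n1), stats::rnorm(n1)))
  r2 <- replicate(1000, oracle_cor(stats::rnorm(n2), stats::rnorm(n2)))
  test <- differential_correlation_test(r1, n1, r2, n2)
  rec <- tibble::tibble(gene_i = sprintf("a%04d", 1:1000),
                        gene_j = sprintf("b%04d", 1:1000),
                        r_sensitive = r1, r_tolerant = r2,
                        delta_r = r1 - r2,
                        z_stat = test$z_stat, p_value = test$p_value)
  sel <- select_significant_pairs(adjust_fdr(rec))
  expect_equal(nrow(sel), 0)
})
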