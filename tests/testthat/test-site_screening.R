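test_that("equal-width binning follows the boundary conventions", {
  expect_identical(bin_beta_values(c(0, 0.5, 1), 10), c(0L, 5L, 9L))
  expect_identical(bin_beta_values(0.999, 10), 9L)
  grid <- (seq_len(1000) - 1) / 1000
  expect_true(all(tabulate(bin_beta_values(grid, 10) + 1L) == 100))
  expect_error(bin_beta_values(c(0.2, 1.3), 10), "1\\.3")
  expect_error(bin_beta_values(0.5, 1), "n_bins")
  expect_identical(bin_beta_values(c(0.1, NA), 10), c(1L, NA))
})

test_that("the 2x2 textbook case gives statistic 20 with df 1", {
  # 10 samples of tissue a near 0, 10 of tissue b near 1: counts
  # [[10,0],[0,10]], expected 5 per cell, statistic 4 * 25/5 = 20
  v <- c(rep(0.1, 10), rep(0.9, 10))
  lab <- rep(c("a", "b"), each = 10)
  r <- chi_square_tissue_test(v, lab, n_bins = 2)
  expect_equal(r$statistic, 20)
  expect_identical(r$df, 1L)
  expect_equal(r$p_value, stats::pchisq(20, 1, lower.tail = FALSE))
})

test_that("identical distributions give statistic 0 and p-value 1", {
  v <- rep(c(0.1, 0.5, 0.9), times = 2)
  lab <- rep(c("a", "b"), each = 3)
  r <- chi_square_tissue_test(v, lab, n_bins = 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # all mass in one bin: not an error, df collapses to 0
  r2 <- chi_square_tissue_test(rep(0.55, 20), rep(c("a", "b"), 10),
                               n_bins = 10)
  expect_equal(r2$statistic, 0)
  expect_identical(r2$df, 0L)
  expect_equal(r2$p_value, 1)
})

test_that("chi-square matches the standard contingency test on 50 random draws", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(30:120, 1)
    nb <- sample(2:6, 1)
    nt <- sample(2:4, 1)
    v <- stats::runif(n)
    lab <- sample(letters[1:nt], n, replace = TRUE)
    r <- chi_square_tissue_test(v, lab, n_bins = nb)
    tab <- table(bin_beta_values(v, nb), lab)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_lt(abs(r$statistic - unname(ref$statistic)), 1e-9)
    expect_lt(abs(r$p_value - ref$p.value), 1e-9)
    expect_identical(r$df, as.integer(ref$parameter))
  }
})

test_that("missing values are dropped pairwise with their labels", {
  v <- c(0.1, 0.1, NA, 0.9, 0.9, 0.2)
  lab <- c("a", "a", "a", "b", "b", "b")
  r <- chi_square_tissue_test(v, lab, n_bins = 2)
  r2 <- chi_square_tissue_test(v[-3], lab[-3], n_bins = 2)
  expect_equal(r$statistic, r2$statistic)
})

test_that("the tissue screen restricts to healthy samples and applies tau_p", {
  cfg <- cohort_config(tissues = c("brain", "kidney", "lung"),
                       n_healthy_per_tissue = 30, n_disease_per_tissue = 10,
                       n_sites = 150, n_tissue_specific = 15,
                       n_disease_specific_per_tissue = 5,
                       tissue_shift = 0.3, seed = 11)
  co <- generate_cohort(cfg)
  scr <- screen_tissue_specific(co$betas, co$metadata, tau_p = 0.01)
  expect_identical(nrow(scr$results), 150L)
  # Eq-style selection consistency: exactly the sites with p < tau_p,
  # ordered by ascending p-value then site id
  expected <- scr$results[scr$results$p_value < 0.01, ]
  expected <- expected$site_id[order(expected$p_value, expected$site_id)]
  expect_identical(scr$selected_sites, expected)
  # planted sites dominate the selection
  expect_gt(mean(co$truth$tissue_specific_sites %in% scr$selected_sites),
            0.9)

  expect_identical(
    screen_tissue_specific(co$betas, co$metadata, tau_p = 0)$selected_sites,
    character(0))
  expect_error(screen_tissue_specific(co$betas, co$metadata, tau_p = 2),
               "tau_p")
  md_dis <- co$metadata; md_dis$status <- 1L
  expect_error(screen_tissue_specific(co$betas, md_dis), "no healthy")
})

test_that("screen statistics increase with the planted shift (mean trend)", {
  mean_stat <- function(shift, seed) {
    cfg <- cohort_config(tissues = c("a", "b"),
                         tissue_shift = shift, seed = seed,
                         n_healthy_per_tissue = 25, n_disease_per_tissue = 0,
                         n_sites = 40, n_tissue_specific = 8,
                         n_disease_specific_per_tissue = 0,
                         baseline_beta_low = 0.2, baseline_beta_high = 0.5)
    co <- generate_cohort(cfg)
    scr <- screen_tissue_specific(co$betas, co$metadata)
    mean(scr$results$statistic[scr$results$site_id %in%
                                 co$truth$tissue_specific_sites])
  }
  seeds <- 1:20
  lo <- mean(vapply(seeds, function(s) mean_stat(0.10, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) mean_stat(0.25, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("disease ranking is deterministic and finds a perfect separator", {
  set.seed(21)
  n <- 60
  x <- matrix(stats::runif(n * 51), n, 51,
              dimnames = list(sprintf("s%02d", 1:n),
                              sprintf("cg%03d", 1:51)))
  y <- rep(c(0L, 1L), each = n / 2)
  x[, 1] <- ifelse(y == 0, stats::runif(n, 0, 0.2), stats::runif(n, 0.8, 1))
  md <- data.frame(sample_id = rownames(x), tissue = "lung", status = y,
                   stringsAsFactors = FALSE)
  m <- methyl_matrix(x)
  rk <- rank_disease_sites(m, md, "lung", colnames(x), top_k = 10)
  # univariate oracle: site with the largest standardised mean separation
  sep <- apply(x, 2, function(v)
    abs(mean(v[y == 1]) - mean(v[y == 0])) / stats::sd(v))
  expect_identical(rk$ranking$site_id[1], names(which.max(sep)))
  expect_identical(rk$ranking$site_id[1], "cg001")
  rk2 <- rank_disease_sites(m, md, "lung", colnames(x), top_k = 10)
  expect_identical(rk$ranking, rk2$ranking)
})

test_that("top-k degenerate cases and errors behave", {
  co <- separable_cohort(n_per_class = 20, n_sites = 12, n_signal = 4,
                         seed = 31)
  sites <- colnames(co$betas)
  rk <- rank_disease_sites(co$betas, co$metadata, "brain", sites,
                           top_k = 100)
  expect_identical(sort(rk$selected_sites), sort(sites))
  expect_identical(sort(rk$ranking$site_id), sort(sites))
  expect_error(rank_disease_sites(co$betas, co$metadata, "brain",
                                  character(0)), "empty")
  expect_error(rank_disease_sites(co$betas, co$metadata, "brain",
                                  c(sites[1], "cg_nope")), "cg_nope")
  md_h <- co$metadata; md_h$status <- 0L
  expect_error(rank_disease_sites(co$betas, md_h, "brain", sites),
               "single health status")
})

test_that("signed ranking puts hypermethylated sites first", {
  set.seed(33)
  n <- 80
  x <- matrix(stats::runif(n * 3, 0.3, 0.7), n, 3,
              dimnames = list(sprintf("s%02d", 1:n), c("up", "down", "ns")))
  y <- rep(c(0L, 1L), each = n / 2)
  x[, "up"] <- pmin(x[, "up"] + 0.25 * y, 1)
  x[, "down"] <- pmax(x[, "down"] - 0.25 * y, 0)
  md <- data.frame(sample_id = rownames(x), tissue = "brain", status = y,
                   stringsAsFactors = FALSE)
  m <- methyl_matrix(x)
  rs <- rank_disease_sites(m, md, "brain", colnames(x), top_k = 1,
                           signed = TRUE)
  expect_identical(rs$selected_sites, "up")
  ra <- rank_disease_sites(m, md, "brain", colnames(x), top_k = 2,
                           signed = FALSE)
  expect_setequal(ra$selected_sites, c("up", "down"))
})

test_that("site summaries compute medians, fold change and SEs by hand", {
  fx <- summary_fixture(c(0.1, 0.3), c(0.2, 0.6))
  s <- site_summary(fx$m, fx$md, "brain", "cgX")
  expect_equal(s$H_M, 0.2)
  expect_equal(s$D_M, 0.4)
  expect_equal(s$magnification, 2.0)
  expect_equal(s$H_SE, stats::sd(c(0.1, 0.3)) / sqrt(2))

  fx2 <- summary_fixture(c(0.2, 0.5), c(0.2, 0.5))
  expect_equal(site_summary(fx2$m, fx2$md, "brain", "cgX")$magnification, 1)

  fx3 <- summary_fixture(c(0, 0, 0), c(0.2, 0.3, 0.4))
  expect_true(is.na(site_summary(fx3$m, fx3$md, "brain",
                                 "cgX")$magnification))

  expect_error(site_summary(fx$m, fx$md, "brain", "cgZ"), "unknown site")
})

test_that("summary table attaches the optional gene lookup", {
  fx <- summary_fixture(c(0.03, 0.04, 0.05), c(0.39, 0.399, 0.41),
                        site = "cg14038391")
  tab <- site_summary_table(fx$m, fx$md, "brain", "cg14038391",
                            gene_lookup = c(cg14038391 = "GENE1"))
  expect_identical(tab$gene, "GENE1")
  expect_equal(tab$magnification, 9.975)
})

test_that("bootstrap SE of the median is available and deterministic", {
  fx <- summary_fixture(stats::runif(20, 0.1, 0.3),
                        stats::runif(20, 0.5, 0.7))
  a <- site_summary(fx$m, fx$md, "brain", "cgX", se_method = "boot_median")
  b <- site_summary(fx$m, fx$md, "brain", "cgX", se_method = "boot_median")
  expect_equal(a$H_SE, b$H_SE)
  expect_gt(a$H_SE, 0)
})
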