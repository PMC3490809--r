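msa_toy <- function(n_windows = 10, n_a = 3, n_b = 3, seed = 6, shift = 0) {
  # windows x arrays log-mean matrix plus the long tibble the caller takes
  set.seed(seed)
  arrays <- c(sprintf("a%d", seq_len(n_a)), sprintf("b%d", seq_len(n_b)))
  m <- matrix(rnorm(n_windows * (n_a + n_b), 5, 0.3), n_windows,
              dimnames = list(NULL, arrays))
  m[, seq_len(n_a)] <- m[, seq_len(n_a)] + shift
  long <- tidyr::expand_grid(pos = seq(0L, by = 2L,
                                       length.out = n_windows),
                             array_id = arrays) %>%
    mutate(unigene_id = "u1", n_probes = 3L,
           log_mean = as.vector(t(m)))
  samples <- tibble(array_id = arrays,
                    genotype = rep(c("gA", "gB"), c(n_a, n_b)))
  list(m = m, long = long, samples = samples)
}

test_that("position log means follow the weighted definition", {
  gn <- tibble(probe_id = "g1", unigene_id = "u1", start = 0L, length = 25L,
               strand = "+", gc_count = 10L, quality = NA_real_)
  x <- wide_intensity(matrix(exp(1), 1, 1, dimnames = list("g1", "a1")))
  lm1 <- position_log_means(x, all_true_mask(x), gn)
  expect_true(all(abs(lm1$log_mean - 1) < 1e-12))

  gn2 <- tibble(probe_id = c("g1", "g2"), unigene_id = "u1",
                start = c(0L, 2L), length = 25L, strand = "+",
                gc_count = 10L, quality = NA_real_)
  x2 <- wide_intensity(matrix(c(2, 4), 2, 1,
                              dimnames = list(c("g1", "g2"), "a1")))
  flat <- weight_profile(-12:12, rep(1, 25))
  lm2 <- position_log_means(x2, all_true_mask(x2), gn2, flat)
  both <- lm2[lm2$pos >= 2 & lm2$pos <= 22, ]
  expect_true(all(abs(both$log_mean - log(3)) < 1e-12))
})

test_that("position log means match an independent recomputation", {
  study <- small_study()
  prof <- default_weight_profile()
  lm <- position_log_means(study$norm, study$mask, study$layout, prof)
  # brute force on one unigene via the window oracle applied to intensities
  vals <- as.matrix(study$norm[-1])
  rownames(vals) <- study$norm$probe_id
  maskm <- as.matrix(study$mask[-1])
  vals[!maskm] <- NA
  sub_layout <- study$layout[study$layout$unigene_id == "u01", ]
  oracle <- oracle_sppdev_windows(vals, sub_layout, prof) %>%
    mutate(log_mean = log(sppdev))
  got <- lm %>% filter(unigene_id == "u01") %>%
    arrange(pos, array_id)
  oracle <- arrange(oracle, pos, array_id)
  expect_equal(got$log_mean, oracle$log_mean, tolerance = 1e-10)
})

test_that("the moderation constant matches its closed form", {
  expect_equal(msa_a_constant(3, 3), 1 / 6)
  expect_equal(msa_a_constant(2, 2), 0.5)
  expect_equal(msa_a_constant(3, 2), 5 / 18)
  expect_error(msa_a_constant(1, 1), "n_a")
})

test_that("D-stats match the brute-force definitions on a toy", {
  toy <- msa_toy(10)
  stats <- msa_dstat(toy$long, toy$samples, "gA", "gB")
  oracle <- oracle_dstat(toy$m, 3)
  expect_equal(stats$s_i, oracle$s_i, tolerance = 1e-10)
  expect_equal(attr(stats, "s0"), oracle$s0, tolerance = 1e-10)
  expect_equal(stats$d_stat, oracle$d, tolerance = 1e-10)
  expect_equal(attr(stats, "a_constant"), 1 / 6)
  # literal printed spread form agrees with its own oracle too
  stats_ss <- msa_dstat(toy$long, toy$samples, "gA", "gB", spread = "ss")
  oracle_ss <- oracle_dstat(toy$m, 3, spread = "ss")
  expect_equal(stats_ss$d_stat, oracle_ss$d, tolerance = 1e-10)
})

test_that("identical genotypes give D = 0 and constant spreads pin S0", {
  arrays <- c("a1", "a2", "b1", "b2")
  long <- tidyr::expand_grid(pos = c(0L, 2L), array_id = arrays) %>%
    mutate(unigene_id = "u1", n_probes = 2L,
           log_mean = rep(c(5, 5.2, 5, 5.2), 2))
  samples <- tibble(array_id = arrays, genotype = c("gA", "gA", "gB", "gB"))
  stats <- msa_dstat(long, samples, "gA", "gB")
  expect_true(all(stats$d_stat == 0))
  expect_equal(attr(stats, "s0"), stats$s_i[1])  # median of equal spreads
})

test_that("D-stat is antisymmetric and scale invariant", {
  toy <- msa_toy(12, shift = 0.4)
  ab <- msa_dstat(toy$long, toy$samples, "gA", "gB")
  ba <- msa_dstat(toy$long, toy$samples, "gB", "gA")
  expect_equal(ab$d_stat, -ba$d_stat, tolerance = 1e-12)
  scaled <- mutate(toy$long, log_mean = log_mean + log(7))  # x7 intensities
  sc <- msa_dstat(scaled, toy$samples, "gA", "gB")
  expect_equal(ab$d_stat, sc$d_stat, tolerance = 1e-10)
})

test_that("delta above the maximum statistic calls nothing", {
  toy <- msa_toy(30, shift = 0.5)
  calls <- msa_call(toy$long, toy$samples, "gA", "gB", delta = 1e6,
                    permutations = 100, seed = 1, delta_rule = "dstat")
  expect_equal(nrow(calls), 0L)
})

test_that("exhaustive label permutations reproduce a full-enumeration FDR", {
  toy <- msa_toy(40, shift = 0)
  toy$m[1:4, 1:3] <- toy$m[1:4, 1:3] + 3  # strong signal in 4 windows
  long <- toy$long
  long$log_mean <- as.vector(t(toy$m))
  delta <- 0.5
  calls <- msa_call(long, toy$samples, "gA", "gB", delta = delta,
                    exhaustive = TRUE, delta_rule = "dstat", center = FALSE,
                    min_width = 2, min_probes = 1)
  # independent enumeration over all 20 assignments
  groups <- combn(6, 3, simplify = FALSE)
  d_obs <- oracle_dstat(toy$m, 3)$d
  counts <- vapply(groups, function(g) {
    perm <- cbind(toy$m[, g, drop = FALSE], toy$m[, -g, drop = FALSE])
    sum(abs(oracle_dstat(perm, 3)$d) >= delta)
  }, numeric(1))
  expected_fdr <- min(mean(counts) / sum(abs(d_obs) >= delta), 1)
  expect_equal(attr(calls, "fdr_estimate"), expected_fdr, tolerance = 1e-10)
})

test_that("strong planted signal is called with few label permutations", {
  toy <- msa_toy(60, seed = 2)
  toy$m[11:16, 1:3] <- toy$m[11:16, 1:3] + 3
  long <- toy$long
  long$log_mean <- as.vector(t(toy$m))
  calls <- msa_call(long, toy$samples, "gA", "gB", delta = 0.2,
                    permutations = 100, seed = 2, min_width = 4,
                    min_probes = 1)
  expect_gte(nrow(calls), 1L)
  expect_true(any(calls$start <= 20 & calls$end >= 26))
})
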