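test_that("SFPdev matches the defining formula on simple cases", {
  gn <- tibble(probe_id = c("g1", "g2", "g3"), unigene_id = "u1",
               start = c(0L, 2L, 4L), length = 25L, strand = "+",
               gc_count = 10L, quality = NA_real_)
  m <- matrix(c(100, 100, 200), ncol = 1, dimnames = list(gn$probe_id, "a1"))
  x <- wide_intensity(m)
  mask <- all_true_mask(x)
  dev <- compute_sfpdev(x, mask, gn)
  ref <- mean(c(100, 100, 200))
  expect_equal(dev$a1, (c(100, 100, 200) - ref) / c(100, 100, 200))
  # Y = 200 against a bin mean of 100 gives 0.5
  gn2 <- tibble(probe_id = c("g1", "g2", "g3"), unigene_id = "u1",
                start = c(0L, 2L, 4L), length = 25L, strand = "+",
                gc_count = 12L, quality = NA_real_)
  m2 <- matrix(c(0.5, 99.5, 200), ncol = 1, dimnames = list(gn2$probe_id, "a1"))
  dev2 <- compute_sfpdev(wide_intensity(m2), all_true_mask(wide_intensity(m2)),
                         gn2)
  expect_equal(dev2$a1[dev2$probe_id == "g3"], 0.5)
  # and Y equal to its bin mean gives exactly 0
  m3 <- matrix(c(100, 50, 150), ncol = 1, dimnames = list(gn2$probe_id, "a1"))
  dev3 <- compute_sfpdev(wide_intensity(m3), all_true_mask(wide_intensity(m3)),
                         gn2)
  expect_equal(dev3$a1[dev3$probe_id == "g1"], 0)
})

test_that("SFPdev equals a brute-force oracle on a random array", {
  set.seed(9)
  gn <- tibble(probe_id = sprintf("g%02d", 1:50), unigene_id = "u1",
               start = seq(0L, by = 2L, length.out = 50), length = 25L,
               strand = "+", gc_count = sample(9:13, 50, replace = TRUE),
               quality = NA_real_)
  m <- matrix(exp(rnorm(100, 5, 0.7)), 50, 2,
              dimnames = list(gn$probe_id, c("a1", "a2")))
  x <- wide_intensity(m)
  mask <- all_true_mask(x)
  mask$a1[c(3, 17, 30)] <- FALSE  # some non-informative probes
  dev <- compute_sfpdev(x, mask, gn)
  oracle <- oracle_sfpdev(m, as.matrix(mask[-1]), gn)
  expect_equal(as.matrix(dev[-1]), oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("bins with under two informative probes yield no deviations", {
  gn <- tibble(probe_id = c("g1", "g2"), unigene_id = "u1",
               start = c(0L, 2L), length = 25L, strand = "+",
               gc_count = c(10L, 11L), quality = NA_real_)
  m <- matrix(c(10, 20), ncol = 1, dimnames = list(gn$probe_id, "a1"))
  x <- wide_intensity(m)
  dev <- compute_sfpdev(x, all_true_mask(x), gn)
  expect_true(all(is.na(dev$a1)))
  expect_equal(nrow(attr(dev, "skipped_bins")), 2L)
})

test_that("window deviations are weight-renormalized means of probe deviations", {
  profile <- default_weight_profile()
  # single covering probe: window equals the probe's SFPdev, any weight
  gn <- tibble(probe_id = "g1", unigene_id = "u1", start = 0L, length = 25L,
               strand = "+", gc_count = 10L, quality = NA_real_)
  dev <- tibble(probe_id = "g1", a1 = 0.4)
  win <- sppdev_windows(dev, gn, profile)
  expect_equal(win$sppdev, rep(0.4, nrow(win)))
  expect_equal(win$pos, seq(0L, 22L, by = 2L))

  # two probes with equal weights average to 0.3
  gn2 <- tibble(probe_id = c("g1", "g2"), unigene_id = "u1",
                start = c(0L, 2L), length = 25L, strand = "+",
                gc_count = 10L, quality = NA_real_)
  dev2 <- tibble(probe_id = c("g1", "g2"), a1 = c(0.2, 0.4))
  flat <- weight_profile(-12:12, rep(1, 25))
  win2 <- sppdev_windows(dev2, gn2, flat)
  both <- win2[win2$pos >= 2 & win2$pos <= 22, ]
  expect_true(all(abs(both$sppdev - 0.3) < 1e-12))
  expect_true(all(both$n_probes == 2))
})

test_that("window deviations match the brute-force oracle on a toy chip", {
  study <- small_study()
  profile <- default_weight_profile()
  sub_layout <- study$layout[study$layout$unigene_id %in%
                               c("u01", "u02", "u03"), ]
  dev <- study$dev
  devm <- as.matrix(dev[-1]); rownames(devm) <- dev$probe_id
  oracle <- oracle_sppdev_windows(devm, sub_layout, profile)
  got <- study$windows %>%
    filter(unigene_id %in% c("u01", "u02", "u03")) %>%
    arrange(unigene_id, pos, array_id)
  oracle <- arrange(oracle, unigene_id, pos, array_id)
  expect_equal(got$sppdev, oracle$sppdev, tolerance = 1e-10)
  expect_equal(got$n_probes, oracle$n_probes)
})

test_that("the ratio statistic divides replicate means", {
  samples <- tibble(array_id = c("a1", "a2", "b1", "b2"),
                    genotype = c("gA", "gA", "gB", "gB"))
  win <- tidyr::expand_grid(unigene_id = "u1", pos = c(0L, 2L),
                            array_id = samples$array_id) %>%
    mutate(sppdev = c(0.4, 0.4, 0.2, 0.2,   # pos 0: means 0.4 / 0.2
                      0.3, 0.3, 0.3, 0.3),  # pos 2: identical means
           n_probes = 2L)
  rs <- ratio_statistic(win, samples, "gA", "gB")
  expect_equal(rs$r_s[rs$pos == 0], 2)
  expect_equal(rs$r_s[rs$pos == 2], 1)
  # zero denominator is reported absent
  win$sppdev[win$pos == 2 & win$array_id %in% c("b1", "b2")] <- c(0.1, -0.1)
  rs2 <- ratio_statistic(win, samples, "gA", "gB")
  expect_true(is.na(rs2$r_s[rs2$pos == 2]))
  expect_equal(nrow(attr(rs2, "zero_denominator")), 1L)
})

test_that("a five-window toy matches hand-computed ratios", {
  samples <- tibble(array_id = c("a1", "a2", "b1", "b2"),
                    genotype = rep(c("gA", "gB"), each = 2))
  set.seed(4)
  vals <- matrix(rnorm(20, -0.5, 0.2), 5, 4)
  win <- tidyr::expand_grid(pos = seq(0L, 8L, 2L),
                            array_id = samples$array_id) %>%
    mutate(unigene_id = "u1", n_probes = 3L,
           sppdev = as.vector(t(vals)))
  rs <- ratio_statistic(win, samples, "gA", "gB") %>% arrange(pos)
  byhand <- rowMeans(vals[, 1:2]) / rowMeans(vals[, 3:4])
  expect_equal(rs$r_s, byhand, tolerance = 1e-12)
  oracle <- oracle_ratio(win, samples, "gA", "gB") %>% arrange(pos)
  expect_equal(rs$r_s, oracle$r_s, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  p <- sort(runif(50))
  expect_true(all(diff(bh_adjust(p)) >= -1e-15))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ranges merge, honor minimum width/probes, and filter direction", {
  test_tbl <- tibble(
    unigene_id = "u1",
    pos = c(10L, 12L, 14L, 30L, 50L, 52L),
    mean_a = -0.5, mean_b = -1,
    r_s = c(0.5, 0.4, 0.5, 0.5, 1.3, 1.3),
    n_probes_min = c(3L, 3L, 3L, 3L, 3L, 3L),
    p = 0.001, fdr = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01))
  calls <- call_spps(test_tbl, fdr_cutoff = 0.1, min_width = 4,
                     min_probes = 2, direction = "lt1")
  # windows 10,12,14 merge into [10,16); lone window at 30 fails min_width;
  # ratio > 1 windows are discarded by the direction filter
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 10L)
  expect_equal(calls$end, 16L)
  expect_equal(calls$n_probes_min, 3L)
  # with direction "both" the 50-52 pair forms a width-4 range
  calls2 <- call_spps(test_tbl, 0.1, direction = "both")
  expect_equal(nrow(calls2), 2L)
  # min_probes: ranges whose best window has too few probes are dropped
  test_tbl$n_probes_min <- 1L
  expect_equal(nrow(call_spps(test_tbl, 0.1)), 0L)
})

test_that("calls are invariant to array order and unigene order", {
  study <- small_study()
  samples <- study$sim$samples
  t1 <- permutation_pvalues(study$windows, samples, "gA", "gB",
                            B = 150, seed = 3)
  shuffled <- study$windows[sample(nrow(study$windows)), ]
  t2 <- permutation_pvalues(shuffled, samples[rev(seq_len(nrow(samples))), ],
                            "gA", "gB", B = 150, seed = 3)
  c1 <- call_spps(t1, 0.2)
  c2 <- call_spps(t2, 0.2)
  expect_equal(arrange(as_tibble(c1), unigene_id, start),
               arrange(as_tibble(c2), unigene_id, start))
})

test_that("calls round-trip through the BED writer sidecar", {
  study <- small_study()
  test <- permutation_pvalues(study$windows, study$sim$samples, "gA", "gB",
                              B = 150, seed = 3)
  calls <- call_spps(test, 0.5, direction = "both")
  expect_gt(nrow(calls), 0)
  f <- withr::local_tempfile(fileext = ".bed")
  write_calls(calls, f)
  expect_equal(ncol(read.table(f, sep = "\t")), 6L)
  back <- read_calls(f)
  expect_equal(as.data.frame(back), as.data.frame(calls), ignore_attr = TRUE)
})

test_that("weight profile estimation recovers symmetry and central peak", {
  study <- small_study()
  prof <- estimate_weight_profile(study$dev, study$sim$samples,
                                  study$truth, study$layout, min_snps = 2)
  expect_s3_class(prof, "spp_weight_profile")
  expect_equal(max(prof$weight), 1)
  # the peak sits among the central offsets
  expect_lte(abs(prof$offset[which.max(prof$weight)]), 8)
  # central average clearly above edge average
  central <- mean(prof$weight[abs(prof$offset) <= 4])
  edge <- mean(prof$weight[abs(prof$offset) >= 11])
  expect_gt(central, 2 * edge)
  # symmetric by construction
  w <- setNames(prof$weight, prof$offset)
  expect_equal(unname(w[as.character(5:10)]), unname(w[as.character(-(5:10))]))
  # few training SNPs -> low-confidence warning
  expect_warning(
    estimate_weight_profile(study$dev, study$sim$samples, study$truth[1, ],
                            study$layout),
    "low-confidence")
})
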