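# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops over the definitions, independent of the package internals
# they check.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

random_seqs <- function(n, len, seed) {
  set.seed(seed)
  setNames(
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1)),
    sprintf("u%02d", seq_len(n)))
}

# wide intensity tibble from a plain matrix
wide_intensity <- function(m, state = "normalized") {
  out <- tibble(probe_id = rownames(m), !!!as.data.frame(m))
  attr(out, "state") <- state
  out
}

all_true_mask <- function(x) {
  m <- x
  for (a in setdiff(names(m), "probe_id")) m[[a]] <- TRUE
  m
}

# --- brute-force oracles -----------------------------------------------------

# SFPdev by direct per-probe evaluation of the formula
oracle_sfpdev <- function(values, mask, layout) {
  out <- values * NA_real_
  arrays <- colnames(values)
  for (a in arrays) {
    for (i in seq_len(nrow(values))) {
      pid <- rownames(values)[i]
      row <- layout[layout$probe_id == pid, ]
      if (row$unigene_id == "=AG=") next
      if (!mask[i, a]) next
      bin_ids <- layout$probe_id[layout$gc_count == row$gc_count &
                                   layout$unigene_id != "=AG="]
      inf <- bin_ids[mask[match(bin_ids, rownames(values)), a]]
      if (length(inf) < 2) next
      r <- mean(values[match(inf, rownames(values)), a])
      out[i, a] <- (values[i, a] - r) / values[i, a]
    }
  }
  out
}

# SPPdev per window by direct loops over covering probes
oracle_sppdev_windows <- function(dev, layout, profile) {
  g <- layout[layout$unigene_id != "=AG=", ]
  arrays <- colnames(dev)
  rows <- list()
  for (u in unique(g$unigene_id)) {
    gu <- g[g$unigene_id == u, ]
    span <- seq(0, max(gu$start + gu$length) - 2, by = 2)
    for (pos in span) {
      cover <- gu[gu$start <= pos & gu$start + gu$length >= pos + 2, ]
      if (!nrow(cover)) next
      for (a in arrays) {
        w <- c(); v <- c()
        for (k in seq_len(nrow(cover))) {
          dv <- dev[match(cover$probe_id[k], rownames(dev)), a]
          if (is.na(dv)) next
          off <- pos + 1 - (cover$start[k] + (cover$length[k] - 1) / 2)
          wk <- approx(profile$offset, profile$weight, xout = off,
                       rule = 2)$y
          w <- c(w, wk); v <- c(v, dv)
        }
        if (!length(w)) next
        rows[[length(rows) + 1]] <-
          tibble(unigene_id = u, pos = pos, array_id = a,
                 sppdev = sum(w * v) / sum(w), n_probes = length(w))
      }
    }
  }
  bind_rows(rows)
}

# ratio statistic by hand
oracle_ratio <- function(windows, samples, ga, gb) {
  keys <- unique(windows[c("unigene_id", "pos")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- windows[windows$unigene_id == keys$unigene_id[i] &
                     windows$pos == keys$pos[i], ]
    aa <- sub$sppdev[sub$array_id %in%
                       samples$array_id[samples$genotype == ga]]
    bb <- sub$sppdev[sub$array_id %in%
                       samples$array_id[samples$genotype == gb]]
    if (!length(aa) || !length(bb)) next
    rows[[i]] <- tibble(unigene_id = keys$unigene_id[i], pos = keys$pos[i],
                        r_s = if (mean(bb) == 0) NA_real_ else
                          mean(aa) / mean(bb))
  }
  bind_rows(rows)
}

# full enumeration of column permutations, pooled null, ecdf two-sided p
oracle_perm_exhaustive <- function(W, n_a) {
  # W: windows x arrays matrix, first n_a columns genotype A
  n <- ncol(W)
  perm_list <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      for (rest in perm_list(v[-k])) out[[length(out) + 1]] <- c(v[k], rest)
    }
    out
  }
  perms <- perm_list(seq_len(n))
  pool <- c()
  for (p in perms) {
    ra <- rowMeans(W[, p[1:n_a], drop = FALSE])
    rb <- rowMeans(W[, p[(n_a + 1):n], drop = FALSE])
    r <- ra / rb
    pool <- c(pool, r[is.finite(r)])
  }
  robs <- rowMeans(W[, 1:n_a, drop = FALSE]) /
    rowMeans(W[, (n_a + 1):n, drop = FALSE])
  p <- numeric(length(robs))
  for (i in seq_along(robs)) {
    p[i] <- min(1, 2 * min(mean(pool < robs[i]), mean(pool > robs[i])))
  }
  p
}

# D-stat by direct evaluation of the definitions
oracle_dstat <- function(lm_wide, n_a, spread = "sd", denominator = "plus") {
  # lm_wide: windows x arrays matrix of log-means, first n_a columns = A
  n <- ncol(lm_wide)
  m <- nrow(lm_wide)
  a_const <- (1 / n_a + 1 / (n - n_a)) / (n - 2)
  s_i <- numeric(m); num <- numeric(m)
  for (i in seq_len(m)) {
    xa <- lm_wide[i, 1:n_a]; xb <- lm_wide[i, (n_a + 1):n]
    ssa <- sum((xa - mean(xa))^2); ssb <- sum((xb - mean(xb))^2)
    s_raw <- a_const * (ssa + ssb)
    s_i[i] <- if (spread == "sd") sqrt(s_raw) else s_raw
    num[i] <- mean(xa) - mean(xb)
  }
  s0 <- median(s_i)
  d <- if (denominator == "plus") num / (s_i + s0) else
    num / pmax(s_i - s0, 1e-8)
  list(s_i = s_i, s0 = s0, d = d, a_const = a_const)
}

# marker-code truth table as an independent multiset map of the printed rules
oracle_marker_code <- function(triple) {
  key <- paste(sort(triple), collapse = "")
  switch(key,
         "AAA" = "A", "BBB" = "B",
         "-BB" = "C", "-AA" = "D",
         "---" = "-",
         "I")  # both alleles present, or two missing plus one call
}

# sliding-window duplicate-locus oracle: count loci matching the query
# full-length with <= max_mm mismatches, both strands
oracle_dup_hits <- function(query, refs, max_mm = 2) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  hits <- 0L
  for (q in c(query, revcomp(query))) {
    qv <- strsplit(q, "")[[1]]
    for (ref in refs) {
      rv <- strsplit(ref, "")[[1]]
      if (length(rv) < length(qv)) next
      for (s in 1:(length(rv) - length(qv) + 1)) {
        mm <- sum(qv != rv[s:(s + length(qv) - 1)])
        if (mm <= max_mm) hits <- hits + 1L
      }
    }
  }
  hits
}

# --- small simulated study, cached across tests ------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache)) {
    assign(name, force(expr), .fixture_cache)
  }
  get(name, .fixture_cache)
}

# a small two-genotype study used by several module tests
small_study <- function() {
  cached("small_study", {
    seqs <- random_seqs(4, 260, seed = 101)
    layout <- tile_unigenes(seqs, ag_per_bin = 30, seed = 101)
    variants <- plant_pairwise_variants(unigene_lengths(layout), 4,
                                        genotype = "gB", min_spacing = 100,
                                        seed = 101)
    panel <- tibble(genotype = c("gA", "gB"))
    sim <- simulate_panel(layout, panel, variants,
                          spp_sim_params(seed = 101))
    norm <- quantile_normalize(background_correct(sim$intensity, "rma"))
    thresholds <- ag_percentile(norm, layout, 90)
    mask <- informative_mask(norm, layout, thresholds)
    dev <- compute_sfpdev(norm, mask, layout)
    windows <- sppdev_windows(dev, layout)
    list(layout = layout, variants = variants, sim = sim, norm = norm,
         mask = mask, dev = dev, windows = windows,
         truth = variants[, c("unigene_id", "position")])
  })
}

# --- acceptance-scale studies (cached; sizes stated in the methods vignette) --

# two-genotype study: 200 planted SNPs on 200 unigenes of 200 bp (the chip's
# typical contiguous-stretch length), 3+3 replicate arrays
acceptance_study <- function() {
  cached("acceptance_study", {
    seed <- 11
    seqs <- random_seqs(200, 200, seed = seed)
    layout <- tile_unigenes(seqs, ag_per_bin = 50, seed = seed)
    variants <- plant_pairwise_variants(unigene_lengths(layout), 200,
                                        genotype = "gB", min_spacing = 80,
                                        seed = seed)
    panel <- tibble(genotype = c("gA", "gB"))
    sim <- simulate_panel(layout, panel, variants,
                          spp_sim_params(seed = seed))
    norm <- quantile_normalize(background_correct(sim$intensity, "rma"))
    thresholds <- ag_percentile(norm, layout, 90)
    mask <- informative_mask(norm, layout, thresholds)
    dev <- compute_sfpdev(norm, mask, layout)
    windows <- sppdev_windows(dev, layout)
    log_means <- position_log_means(norm, mask, layout)
    list(layout = layout, sim = sim, norm = norm, mask = mask, dev = dev,
         windows = windows, log_means = log_means,
         truth = variants[, c("unigene_id", "position")])
  })
}

# matched null study: no planted variants, ~2000 windows
null_study <- function() {
  cached("null_study", {
    seed <- 1
    seqs <- random_seqs(7, 600, seed = seed)
    layout <- tile_unigenes(seqs, ag_per_bin = 40, seed = seed)
    panel <- tibble(genotype = c("gA", "gB"))
    sim <- simulate_panel(layout, panel, NULL, spp_sim_params(seed = seed))
    norm <- quantile_normalize(background_correct(sim$intensity, "rma"))
    thresholds <- ag_percentile(norm, layout, 90)
    mask <- informative_mask(norm, layout, thresholds)
    windows <- sppdev_windows(compute_sfpdev(norm, mask, layout), layout)
    list(layout = layout, sim = sim, windows = windows)
  })
}

# 12-genotype, 3-species panel with planted private and intraspecific
# variants, simulated at a chosen replicate noise level
dp_study <- function(noise_sd) {
  cached(paste0("dp_study_", noise_sd), {
    seed <- 9
    panel <- tibble(genotype = sprintf("g%02d", 1:12),
                    species = rep(c("spA", "spB", "spC"), c(6, 4, 2)))
    seqs <- random_seqs(30, 300, seed = seed)
    layout <- tile_unigenes(seqs, ag_per_bin = 40, seed = seed)
    planted <- plant_species_panel(unigene_lengths(layout), panel,
                                   n_private = c(spA = 8, spB = 8, spC = 8),
                                   n_intraspecific = 6, min_spacing = 80,
                                   seed = seed)
    sim <- simulate_panel(layout, panel, planted$variants,
                          spp_sim_params(seed = seed, noise_sd = noise_sd))
    norm <- quantile_normalize(background_correct(sim$intensity, "rma"))
    thresholds <- ag_percentile(norm, layout, 90)
    mask <- informative_mask(norm, layout, thresholds)
    windows <- sppdev_windows(compute_sfpdev(norm, mask, layout), layout)
    filtered <- filter_panel_markers(dp_genotype(windows, sim$samples))
    # planted distinct carrier-set patterns per unigene
    planted_haps <- planted$variants %>%
      group_by(unigene_id, position) %>%
      summarise(pat = paste(sort(genotype), collapse = ","),
                .groups = "drop") %>%
      distinct(unigene_id, pat) %>%
      nrow()
    list(panel = panel, planted = planted, planted_haps = planted_haps,
         sim = sim, windows = windows, filtered = filtered)
  })
}

dp_marker_fixture <- function() {
  # hand-built marker windows for four genotypes: one clean range plus one
  # width-4 violator for each filter, and a lone narrow single-probe window
  m <- tibble(
    unigene_id = c("u1", "u1", "u1", "u1", "u2", "u2", "u2", "u2", "u3"),
    start = c(10L, 12L, 30L, 32L, 6L, 8L, 40L, 42L, 70L),
    end = c(12L, 14L, 32L, 34L, 8L, 10L, 42L, 44L, 72L),
    cluster_ratio = c(1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 1.1, 1.1, 2.0),
    n_probes_min = c(3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 1L),
    g1 = c("A", "A", "A", "A", "A", "A", "A", "A", "A"),
    g2 = c("A", "A", "A", "A", "I", "I", "A", "A", "A"),
    g3 = c("B", "B", "B", "B", "B", "B", "B", "B", "B"),
    g4 = c("B", "B", "-", "-", "B", "B", "B", "B", "B"))
  structure(m, genotypes = c("g1", "g2", "g3", "g4"),
            class = c("spp_markers", class(tibble())))
}
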