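#' Per-window log mean intensities
#'
#' For each 2 bp window and replicate array, the natural log of the
#' weight-renormalized mean intensity of the informative probes covering
#' the window (weights from the same position profile as the SPPdev
#' caller). Windows with no informative probe on an array are absent for
#' that array.
#'
#' @param x Normalized intensity tibble.
#' @param mask Informative mask on the same matrix.
#' @param layout Layout tibble.
#' @param profile A [weight_profile()].
#' @return Long tibble `unigene_id`, `pos`, `array_id`, `log_mean`,
#'   `n_probes`.
#' @export
position_log_means <- function(x, mask, layout,
                               profile = default_weight_profile()) {
  require_state(x, "normalized", "position_log_means()")
  pw <- probe_windows(layout) %>%
    mutate(w = profile_weight(profile, .data$offset))
  long <- x %>%
    tidyr::pivot_longer(-"probe_id", names_to = "array_id", values_to = "value") %>%
    inner_join(
      tidyr::pivot_longer(mask, -"probe_id", names_to = "array_id",
                          values_to = "informative"),
      by = c("probe_id", "array_id")) %>%
    filter(.data$informative)
  inner_join(pw, long, by = "probe_id", relationship = "many-to-many") %>%
    group_by(.data$unigene_id, .data$pos, .data$array_id) %>%
    summarise(log_mean = log(sum(.data$w * .data$value) / sum(.data$w)),
              n_probes = n(), .groups = "drop")
}

#' Moderation constant of the positional D-statistic
#'
#' \deqn{a = (1/n_A + 1/n_B) / (n_A + n_B - 2)}
#'
#' @param n_a,n_b Replicate counts per genotype (each >= 1, sum > 2).
#' @return The constant.
#' @export
msa_a_constant <- function(n_a, n_b) {
  if (n_a < 1 || n_b < 1 || n_a + n_b <= 2) {
    abort("need n_a, n_b >= 1 and n_a + n_b > 2")
  }
  (1 / n_a + 1 / n_b) / (n_a + n_b - 2)
}

#' Positional moderated D-statistic
#'
#' Per window, with replicate log-mean intensities per genotype:
#' \deqn{S_i = a \,(SS_A + SS_B)} (within-genotype sums of squared
#' deviations), and
#' \deqn{D = (\bar{x}_A - \bar{x}_B) / (s_i + S_0)}
#' where by default \eqn{s_i = \sqrt{S_i}} (the pooled standard error,
#' `spread = "sd"`; `spread = "ss"` uses \eqn{S_i} itself) and \eqn{S_0}
#' is the chip-wide median of the \eqn{s_i} (`denominator = "plus"`;
#' `"minus"` subtracts the median with a small positive floor). Windows
#' with fewer than 2 replicates in either genotype are skipped.
#'
#' @param log_means Output of [position_log_means()].
#' @param samples Sample sheet (`array_id`, `genotype`).
#' @param genotype_a,genotype_b The two genotypes compared.
#' @param denominator `"plus"` (default) or `"minus"`.
#' @param spread `"sd"` (default, pooled SE) or `"ss"` (raw moderated sum
#'   of squares).
#' @return Tibble of class `spp_msa`: `unigene_id`, `pos`, `mean_a`,
#'   `mean_b`, `s_i`, `d_stat`, `n_probes_min`; attributes `s0`,
#'   `a_constant` (at the modal replicate counts), `denominator`, `spread`.
#' @export
msa_dstat <- function(log_means, samples, genotype_a, genotype_b,
                      denominator = c("plus", "minus"),
                      spread = c("sd", "ss")) {
  denominator <- match.arg(denominator)
  spread <- match.arg(spread)
  labelled <- log_means %>%
    inner_join(samples[, c("array_id", "genotype")], by = "array_id") %>%
    filter(.data$genotype %in% c(genotype_a, genotype_b))
  stats <- labelled %>%
    group_by(.data$unigene_id, .data$pos) %>%
    summarise(
      n_a = sum(.data$genotype == genotype_a),
      n_b = sum(.data$genotype == genotype_b),
      mean_a = mean(.data$log_mean[.data$genotype == genotype_a]),
      mean_b = mean(.data$log_mean[.data$genotype == genotype_b]),
      ss_a = sum((.data$log_mean[.data$genotype == genotype_a] - .data$mean_a)^2),
      ss_b = sum((.data$log_mean[.data$genotype == genotype_b] - .data$mean_b)^2),
      n_probes_min = min(.data$n_probes), .groups = "drop") %>%
    filter(.data$n_a >= 2, .data$n_b >= 2) %>%
    mutate(a_const = (1 / .data$n_a + 1 / .data$n_b) / (.data$n_a + .data$n_b - 2),
           s_i_raw = .data$a_const * (.data$ss_a + .data$ss_b),
           s_i = if (spread == "sd") sqrt(.data$s_i_raw) else .data$s_i_raw)
  s0 <- median(stats$s_i)
  denom <- if (denominator == "plus") stats$s_i + s0 else
    pmax(stats$s_i - s0, 1e-8)
  out <- stats %>%
    mutate(d_stat = (.data$mean_a - .data$mean_b) / denom) %>%
    select("unigene_id", "pos", "mean_a", "mean_b", "s_i", "d_stat",
           "n_probes_min")
  attr(out, "s0") <- s0
  attr(out, "a_constant") <- msa_a_constant(
    as.integer(names(sort(-table(stats$n_a)))[1]),
    as.integer(names(sort(-table(stats$n_b)))[1]))
  attr(out, "denominator") <- denominator
  attr(out, "spread") <- spread
  class(out) <- c("spp_msa", class(tibble()))
  out
}

# Observed statistic plus a windows x permutations matrix of permuted
# D-stats, restricted to windows observed on every array (so the ranked
# null is comparable across permutations).
msa_perm_setup <- function(log_means, samples, genotype_a, genotype_b,
                           permutations, seed, exhaustive, denominator,
                           spread, center = TRUE, exclude_identity = TRUE) {
  sam <- filter(samples, .data$genotype %in% c(genotype_a, genotype_b)) %>%
    arrange(.data$genotype != genotype_a, .data$array_id)
  arr <- sam$array_id
  n_a <- sum(sam$genotype == genotype_a)
  n <- length(arr)
  complete <- log_means %>%
    filter(.data$array_id %in% arr) %>%
    group_by(.data$unigene_id, .data$pos) %>%
    filter(n() == length(arr)) %>%
    ungroup()
  obs <- msa_dstat(complete, sam, genotype_a, genotype_b,
                   denominator = denominator, spread = spread)
  W <- complete %>%
    select("unigene_id", "pos", "array_id", "log_mean") %>%
    tidyr::pivot_wider(names_from = "array_id", values_from = "log_mean") %>%
    arrange(.data$unigene_id, .data$pos)
  M <- as.matrix(W[arr])
  groupings <- if (exhaustive) {
    utils::combn(n, n_a, simplify = FALSE)
  } else NULL
  a_set <- seq_len(n_a)
  b_set <- seq(n_a + 1L, n)
  draw_grouping <- function() {
    for (try in 1:1000) {
      g <- sort(sample.int(n, n_a))
      if (!exclude_identity ||
          !(identical(g, a_set) ||
              (n_a == n - n_a && identical(g, b_set)))) return(g)
    }
    g
  }
  dstat_for <- function(a_idx) {
    A <- M[, a_idx, drop = FALSE]
    B <- M[, -a_idx, drop = FALSE]
    ma <- rowMeans(A); mb <- rowMeans(B)
    ssa <- rowSums((A - ma)^2); ssb <- rowSums((B - mb)^2)
    a_const <- msa_a_constant(ncol(A), ncol(B))
    s_raw <- a_const * (ssa + ssb)
    s <- if (spread == "sd") sqrt(s_raw) else s_raw
    s0 <- median(s)
    if (denominator == "plus") (ma - mb) / (s + s0)
    else (ma - mb) / pmax(s - s0, 1e-8)
  }
  nperm <- if (exhaustive) length(groupings) else permutations
  perm_d <- with_seed(seed, {
    vapply(seq_len(nperm), function(b) {
      a_idx <- if (exhaustive) groupings[[b]] else draw_grouping()
      dstat_for(a_idx)
    }, numeric(nrow(M)))
  })
  perm_d <- matrix(perm_d, nrow = nrow(M))
  d_obs <- obs$d_stat
  if (center && nrow(M) > 1) {
    # quantile normalization leaves a small global shift when one genotype
    # carries net signal loss; the delta rule is applied to median-centered
    # statistics (observed and permuted alike) so calling is robust to it
    d_obs <- d_obs - median(d_obs)
    perm_d <- sweep(perm_d, 2, apply(perm_d, 2, median))
  }
  list(obs = obs, d_obs = d_obs, perm_d = perm_d, n_perm = nperm)
}

sam_cutoffs <- function(d_obs, perm_d, delta) {
  m <- length(d_obs)
  ord <- order(d_obs)
  d_sorted <- d_obs[ord]
  expected <- rowMeans(matrix(apply(perm_d, 2, sort), nrow = m))
  diffs <- d_sorted - expected
  mid <- which.min(abs(expected))
  up_idx <- which(diffs >= delta & seq_len(m) >= mid)
  lo_idx <- which(diffs <= -delta & seq_len(m) <= mid)
  list(cut_up = if (length(up_idx)) d_sorted[min(up_idx)] else Inf,
       cut_lo = if (length(lo_idx)) d_sorted[max(lo_idx)] else -Inf)
}

#' Call SPPs with the positional D-statistic
#'
#' Significance at threshold `delta` is decided by the permutation-based
#' delta rule of the moderated-statistic literature (`delta_rule = "sam"`,
#' the default): observed D-stats are ranked against the permutation
#' average of the same order statistics, and the cutoffs are the outermost
#' observed values whose deviation from expectation reaches `delta`. The
#' estimated FDR at `delta` is the permutation-average count of windows
#' beyond the cutoffs divided by the observed count. `delta_rule =
#' "dstat"` instead thresholds `|D| >= delta` directly. Merging and range
#' filtering are identical to [call_spps()].
#'
#' @inheritParams msa_dstat
#' @param delta Delta threshold (> 0; the headline analysis uses 0.2).
#' @param permutations Genotype-label permutations for the null.
#' @param seed Seed for the permutation draws.
#' @param min_width,min_probes Range filters, as in [call_spps()].
#' @param delta_rule `"sam"` or `"dstat"`.
#' @param exhaustive Enumerate all label assignments instead of sampling.
#' @param center Apply the delta rule to median-centered statistics
#'   (observed and permuted alike); see [msa_perm_setup] notes in the
#'   source. Recommended with quantile-normalized input.
#' @param exclude_identity Reject sampled label assignments equal to the
#'   observed grouping (see [permutation_pvalues()]).
#' @return An `spp_calls` tibble (method `"msa"`, `fdr_or_p` = the
#'   delta-level FDR estimate) with attributes `fdr_estimate`, `delta`,
#'   `cutoffs`, `n_significant_windows`.
#' @export
msa_call <- function(log_means, samples, genotype_a, genotype_b, delta = 0.2,
                     permutations = 100, seed = NULL, min_width = 4,
                     min_probes = 2, delta_rule = c("sam", "dstat"),
                     denominator = c("plus", "minus"),
                     spread = c("sd", "ss"), exhaustive = FALSE,
                     center = TRUE, exclude_identity = TRUE) {
  delta_rule <- match.arg(delta_rule)
  denominator <- match.arg(denominator)
  spread <- match.arg(spread)
  if (delta <= 0) abort("`delta` must be > 0")
  setup <- msa_perm_setup(log_means, samples, genotype_a, genotype_b,
                          permutations, seed, exhaustive, denominator, spread,
                          center = center, exclude_identity = exclude_identity)
  obs <- setup$obs
  d <- setup$d_obs
  if (delta_rule == "sam") {
    cuts <- sam_cutoffs(d, setup$perm_d, delta)
  } else {
    cuts <- list(cut_up = delta, cut_lo = -delta)
  }
  sig_idx <- d >= cuts$cut_up | d <= cuts$cut_lo
  perm_counts <- colSums(setup$perm_d >= cuts$cut_up |
                           setup$perm_d <= cuts$cut_lo)
  n_sig <- sum(sig_idx)
  fdr_est <- if (n_sig > 0) min(mean(perm_counts) / n_sig, 1) else NA_real_
  sig <- obs[sig_idx, ] %>% mutate(fdr_or_p = fdr_est)
  calls <- merge_windows(sig, stat_col = "d_stat", sig_col = "fdr_or_p",
                         method = "msa", min_width = min_width,
                         min_probes = min_probes)
  # merge_windows derives direction from a ratio; for D-stats the sign of
  # the statistic itself is the direction of the deviation
  calls$direction <- as.integer(sign(calls$statistic))
  attr(calls, "fdr_estimate") <- fdr_est
  attr(calls, "delta") <- delta
  attr(calls, "cutoffs") <- cuts
  attr(calls, "n_significant_windows") <- n_sig
  calls
}

#' Permutation FDR of the D-statistic over a delta grid
#'
#' Shares one set of permutations across all deltas and reports, per delta,
#' the observed significant-window count, the permutation-average null
#' count and their ratio (the estimated FDR, capped at 1).
#'
#' @inheritParams msa_call
#' @param deltas Increasing grid of delta thresholds.
#' @return Tibble `delta`, `n_observed`, `n_permuted_mean`, `fdr`.
#' @export
msa_fdr_curve <- function(log_means, samples, genotype_a, genotype_b,
                          deltas = seq(0.2, 1.6, by = 0.2),
                          permutations = 100, seed = NULL,
                          delta_rule = c("sam", "dstat"),
                          denominator = c("plus", "minus"),
                          spread = c("sd", "ss"), exhaustive = FALSE,
                          center = TRUE, exclude_identity = TRUE) {
  delta_rule <- match.arg(delta_rule)
  denominator <- match.arg(denominator)
  spread <- match.arg(spread)
  setup <- msa_perm_setup(log_means, samples, genotype_a, genotype_b,
                          permutations, seed, exhaustive, denominator, spread,
                          center = center, exclude_identity = exclude_identity)
  rows <- purrr::map(deltas, function(delta) {
    if (delta_rule == "sam") {
      cuts <- sam_cutoffs(setup$d_obs, setup$perm_d, delta)
    } else {
      cuts <- list(cut_up = delta, cut_lo = -delta)
    }
    n_obs <- sum(setup$d_obs >= cuts$cut_up |
                   setup$d_obs <= cuts$cut_lo)
    n_perm <- mean(colSums(setup$perm_d >= cuts$cut_up |
                             setup$perm_d <= cuts$cut_lo))
    tibble(delta = delta, n_observed = n_obs, n_permuted_mean = n_perm,
           fdr = if (n_obs > 0) min(n_perm / n_obs, 1) else NA_real_)
  })
  bind_rows(rows)
}
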