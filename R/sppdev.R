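#' Per-probe deviation from the GC-matched reference (SFPdev)
#'
#' For each informative probe i on each array g,
#' \deqn{SFPdev_{ig} = (Y_i - R(Y_i)) / Y_i}
#' where \eqn{R(Y_i)} is the mean intensity of all informative genomic
#' probes with the same GC count on the same array (AG probes excluded from
#' both sides). Non-informative probes get `NA`. Bins with fewer than two
#' informative probes on an array yield no deviations there; these are
#' reported in attribute `skipped_bins`.
#'
#' @param x Normalized intensity tibble.
#' @param mask Informative mask from [informative_mask()] on the same matrix.
#' @param layout Layout tibble.
#' @return Wide tibble of SFPdev values (probe_id x arrays).
#' @export
compute_sfpdev <- function(x, mask, layout) {
  require_state(x, "normalized", "compute_sfpdev()")
  info <- layout[, c("probe_id", "unigene_id", "gc_count")]
  long <- x %>%
    tidyr::pivot_longer(-"probe_id", names_to = "array_id", values_to = "value") %>%
    inner_join(
      tidyr::pivot_longer(mask, -"probe_id", names_to = "array_id",
                          values_to = "informative"),
      by = c("probe_id", "array_id")) %>%
    inner_join(info, by = "probe_id") %>%
    filter(!is_ag(.data$unigene_id)) %>%
    group_by(.data$array_id, .data$gc_count) %>%
    mutate(n_inf = sum(.data$informative),
           ref = if_else(.data$n_inf >= 2,
                         mean(.data$value[.data$informative]), NA_real_)) %>%
    ungroup() %>%
    mutate(sfpdev = if_else(.data$informative & !is.na(.data$ref),
                            (.data$value - .data$ref) / .data$value, NA_real_))
  skipped <- long %>%
    filter(.data$informative, .data$n_inf < 2) %>%
    distinct(.data$array_id, .data$gc_count)
  dev <- long %>%
    select("probe_id", "array_id", "sfpdev") %>%
    tidyr::pivot_wider(names_from = "array_id", values_from = "sfpdev")
  dev <- dev[match(intersect(x$probe_id, dev$probe_id), dev$probe_id), ]
  attr(dev, "skipped_bins") <- skipped
  dev
}

#' Position weight profiles
#'
#' A weight profile maps the offset of a 2 bp window midpoint from a probe
#' center to a non-negative weight; weights over the probes covering one
#' window are renormalized to sum to 1 at use time, so only the shape
#' matters. The default mirrors the mismatch sensitivity of 25-mers: full
#' weight for the 16 most central bases, decaying toward the probe edges.
#'
#' @param offset Integer offsets (typically `-12:12`).
#' @param weight Non-negative weights, maximal near offset 0.
#' @return A tibble of class `spp_weight_profile`.
#' @export
weight_profile <- function(offset, weight) {
  if (any(weight < 0)) abort("weights must be non-negative")
  structure(tibble(offset = as.integer(offset), weight = as.numeric(weight)),
            class = c("spp_weight_profile", class(tibble())))
}

#' @rdname weight_profile
#' @export
default_weight_profile <- function() {
  curve <- default_sensitivity_curve()
  weight_profile(as.integer(names(curve)), unname(curve) / max(curve))
}

profile_weight <- function(profile, offset) {
  stats::approx(profile$offset, profile$weight, xout = offset, rule = 2)$y
}

#' Estimate the position weight profile from training SNPs
#'
#' Reproduces the empirical weighting-factor calibration: probes covering a
#' training SNP that differs between two genotypes respond according to the
#' SNP's offset from their center. With `scale = "loss"` (the default) each
#' covering probe's genotype difference in mean SFPdev is converted to an
#' implied fractional signal loss — the exact inverse of the SFPdev
#' response to an intensity loss: `d = (dev_hi - dev_lo) / (1 - dev_hi)`,
#' `loss = d / (1 + d)` — where the per-SNP orientation (which genotype
#' lost signal) is inferred from the central probes, and a residual
#' reference-ratio bias is removed using the same unigenes' non-covering
#' probes. `scale = "raw"` instead reports the raw mean |SFPdev
#' difference| per offset. Offset means are symmetrized (averaging +o and
#' -o) and normalized to a maximum of 1.
#'
#' @param dev SFPdev tibble from [compute_sfpdev()].
#' @param samples Sample sheet (`array_id`, `genotype`).
#' @param snps Training SNPs: tibble `unigene_id`, `position` (0-based).
#' @param layout Layout tibble.
#' @param genotypes Length-2 character: the two genotypes compared
#'   (default: the two present in `samples`).
#' @param scale `"loss"` or `"raw"` (see Details).
#' @param min_snps Below this many usable SNPs the profile is flagged
#'   low-confidence with a warning.
#' @return An [weight_profile()] with attributes `n_snps`, `low_confidence`.
#' @export
estimate_weight_profile <- function(dev, samples, snps, layout,
                                    genotypes = NULL,
                                    scale = c("loss", "raw"), min_snps = 50) {
  scale <- match.arg(scale)
  assert_columns(snps, c("unigene_id", "position"), "snps")
  if (is.null(genotypes)) genotypes <- unique(samples$genotype)
  if (length(genotypes) != 2) abort("exactly two genotypes are required")
  gmean <- dev %>%
    tidyr::pivot_longer(-"probe_id", names_to = "array_id", values_to = "sfpdev") %>%
    inner_join(samples[, c("array_id", "genotype")], by = "array_id") %>%
    filter(.data$genotype %in% genotypes) %>%
    group_by(.data$probe_id, .data$genotype) %>%
    summarise(m = mean(.data$sfpdev, na.rm = TRUE), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "genotype", values_from = "m") %>%
    rename(dev_a = all_of(genotypes[1]), dev_b = all_of(genotypes[2]))
  g <- layout[!is_ag(layout$unigene_id), ]
  all_probes <- semi_join(g, snps, by = "unigene_id") %>%
    inner_join(gmean, by = "probe_id") %>%
    filter(is.finite(.data$dev_a), is.finite(.data$dev_b)) %>%
    mutate(signed = (.data$dev_a - .data$dev_b) /
             pmax(1 - pmax(.data$dev_a, .data$dev_b), 1e-8))
  hits <- inner_join(snps, all_probes, by = "unigene_id",
                     relationship = "many-to-many") %>%
    filter(.data$start <= .data$position,
           .data$start + .data$length > .data$position) %>%
    mutate(offset = as.integer(round(.data$position -
                                       (.data$start + (.data$length - 1) / 2))))
  n_snps <- nrow(distinct(hits, .data$unigene_id, .data$position))
  if (n_snps < min_snps) {
    warn(sprintf("only %d usable training SNPs (< %d); weight profile is low-confidence",
                 n_snps, min_snps))
  }
  # per-SNP orientation from the central probes, so the response is the
  # signed deviation of the allele that lost signal
  hits <- hits %>%
    group_by(.data$unigene_id, .data$position) %>%
    mutate(dir = sign(sum(.data$signed[abs(.data$offset) <= 6]) + 1e-12)) %>%
    ungroup() %>%
    mutate(d_oriented = .data$signed * .data$dir)
  if (scale == "loss") {
    # residual reference-ratio bias, measured on probes not covering a SNP
    background <- anti_join(
      all_probes,
      distinct(hits, probe_id = .data$probe_id), by = "probe_id")
    bias <- if (nrow(background)) median(background$signed) else 0
    hits <- hits %>%
      mutate(d = pmax(.data$d_oriented - .data$dir * bias, 0),
             resp = .data$d / (1 + .data$d))
  } else {
    hits <- mutate(hits, resp = abs(.data$dev_a - .data$dev_b))
  }
  per_off <- hits %>%
    group_by(.data$offset) %>%
    summarise(resp = mean(.data$resp), .groups = "drop")
  offs <- seq(min(per_off$offset), max(per_off$offset))
  w <- stats::approx(per_off$offset, per_off$resp, xout = offs, rule = 2)$y
  # symmetric fit: average the response at +o and -o
  wsym <- (w + rev(w)) / 2
  prof <- weight_profile(offs, wsym / max(wsym))
  attr(prof, "n_snps") <- n_snps
  attr(prof, "low_confidence") <- n_snps < min_snps
  prof
}

# Expand a layout into (probe, window) coverage rows on the 2 bp grid:
# windows [pos, pos + 2) at even pos fully inside the probe, with the
# offset of the window midpoint from the probe center.
probe_windows <- function(layout) {
  g <- layout[!is_ag(layout$unigene_id),
              c("probe_id", "unigene_id", "start", "length")]
  if (!nrow(g)) {
    return(tibble(probe_id = character(), unigene_id = character(),
                  pos = integer(), offset = double()))
  }
  first_pos <- as.integer(ceiling(g$start / 2) * 2)
  last_pos <- as.integer(floor((g$start + g$length - 2) / 2) * 2)
  nwin <- pmax((last_pos - first_pos) %/% 2L + 1L, 0L)
  idx <- rep.int(seq_len(nrow(g)), nwin)
  pos <- unlist(purrr::map2(first_pos, last_pos, function(a, b)
    if (b >= a) seq(a, b, by = 2L) else integer(0)))
  tibble(probe_id = g$probe_id[idx], unigene_id = g$unigene_id[idx],
         pos = pos,
         offset = pos + 1 - (g$start[idx] + (g$length[idx] - 1) / 2))
}

#' Sliding-window position deviation (SPPdev)
#'
#' For every 2 bp window s covered by at least one informative probe,
#' \deqn{SPPdev_s = \sum_k w_k \, SFPdev_k}
#' over the informative probes k covering s, with weights taken from the
#' profile at the offset of the window midpoint from each probe's center
#' and renormalized to sum to 1 per window per array (a weighted mean, so
#' windows with different coverage are comparable; a single covering probe
#' reproduces its SFPdev exactly).
#'
#' @param dev SFPdev tibble from [compute_sfpdev()].
#' @param layout Layout tibble.
#' @param profile A [weight_profile()].
#' @return Long tibble `unigene_id`, `pos` (0-based window start on the
#'   2 bp grid), `array_id`, `sppdev`, `n_probes` (informative probes
#'   entering the window on that array).
#' @export
sppdev_windows <- function(dev, layout, profile = default_weight_profile()) {
  pw <- probe_windows(layout) %>%
    mutate(w = profile_weight(profile, .data$offset))
  long <- dev %>%
    tidyr::pivot_longer(-"probe_id", names_to = "array_id",
                        values_to = "sfpdev") %>%
    filter(!is.na(.data$sfpdev))
  inner_join(pw, long, by = "probe_id", relationship = "many-to-many") %>%
    group_by(.data$unigene_id, .data$pos, .data$array_id) %>%
    summarise(sppdev = sum(.data$w * .data$sfpdev) / sum(.data$w),
              n_probes = n(), .groups = "drop")
}

#' Ratio statistic for a two-genotype comparison
#'
#' Per window s, \eqn{R_s} is the ratio of the replicate-mean SPPdev of
#' genotype A to that of genotype B. Windows where the denominator mean is
#' exactly 0 get `NA` (reported in attribute `zero_denominator`).
#'
#' @param windows SPPdev windows from [sppdev_windows()].
#' @param samples Sample sheet (`array_id`, `genotype`).
#' @param genotype_a,genotype_b The numerator and denominator genotypes.
#' @return Tibble `unigene_id`, `pos`, `mean_a`, `mean_b`, `r_s`,
#'   `n_probes_min` (the window's minimum informative-probe count over the
#'   arrays entering the ratio).
#' @export
ratio_statistic <- function(windows, samples, genotype_a, genotype_b) {
  labelled <- windows %>%
    inner_join(samples[, c("array_id", "genotype")], by = "array_id") %>%
    filter(.data$genotype %in% c(genotype_a, genotype_b))
  out <- labelled %>%
    group_by(.data$unigene_id, .data$pos) %>%
    summarise(
      mean_a = mean(.data$sppdev[.data$genotype == genotype_a]),
      mean_b = mean(.data$sppdev[.data$genotype == genotype_b]),
      n_probes_min = min(.data$n_probes),
      n_arrays = n(), .groups = "drop") %>%
    filter(is.finite(.data$mean_a), is.finite(.data$mean_b)) %>%
    mutate(r_s = if_else(.data$mean_b == 0, NA_real_,
                         .data$mean_a / .data$mean_b)) %>%
    select("unigene_id", "pos", "mean_a", "mean_b", "r_s", "n_probes_min")
  attr(out, "zero_denominator") <- filter(out, is.na(.data$r_s))[
    c("unigene_id", "pos")]
  out
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation test for the SPPdev ratio statistic
#'
#' Within each unigene, the columns of the windows-by-arrays SPPdev matrix
#' (the replicate arrays of both genotypes) are permuted B times and the
#' ratio statistic recomputed. The null distribution of \eqn{R_s} is
#' assumed equal across positions of a unigene, so the permuted ratios are
#' pooled over all windows and permutations. The two-sided p-value of a
#' window measures extremity against the pooled null on either tail:
#' `tails = "ecdf"` (default) takes twice the smaller pooled tail
#' probability at \eqn{R_s} (well-defined for ratios of either sign);
#' `tails = "reflect"` counts pooled values beyond \eqn{R_s} or beyond its
#' reciprocal (for \eqn{R_s \ge 1}, values \eqn{> R_s} or \eqn{< 1/R_s};
#' mirrored below 1), the ratio-symmetric reading that presumes positive
#' ratios. P-values are then FDR-adjusted with [bh_adjust()].
#'
#' @inheritParams ratio_statistic
#' @param B Number of permutations (>= 100 unless `exhaustive`).
#' @param seed Seed for the permutation draws.
#' @param exhaustive Enumerate all column permutations instead of sampling
#'   (only for small arrays-per-unigene counts).
#' @param fdr_scope `"unigene"` (the six-step procedure runs per unigene,
#'   so the step-up adjustment is applied within each unigene) or
#'   `"global"` (across all windows of the chip).
#' @param tails Two-sided extremity convention, `"ecdf"` or `"reflect"`
#'   (see Details).
#' @param exclude_identity When sampling, reject permutations that
#'   reproduce the observed genotype grouping (or its mirror): with signal
#'   present, the identity arrangement re-injects the observed extreme
#'   ratios into the pooled null at every position, inflating the p-values
#'   of true polymorphisms. Exhaustive enumeration always keeps all
#'   permutations.
#' @return A tibble of class `spp_test`: `unigene_id`, `pos`, `mean_a`,
#'   `mean_b`, `r_s`, `n_probes_min`, `p`, `fdr`; attributes `B` and
#'   `n_pooled` record the realized null size per unigene.
#' @export
permutation_pvalues <- function(windows, samples, genotype_a, genotype_b,
                                B = 300, seed = NULL, exhaustive = FALSE,
                                fdr_scope = c("unigene", "global"),
                                tails = c("ecdf", "reflect"),
                                exclude_identity = TRUE) {
  fdr_scope <- match.arg(fdr_scope)
  tails <- match.arg(tails)
  sam <- filter(samples, .data$genotype %in% c(genotype_a, genotype_b))
  # canonical array order so results do not depend on sample-sheet order
  cols_a <- sort(sam$array_id[sam$genotype == genotype_a])
  cols_b <- sort(sam$array_id[sam$genotype == genotype_b])
  n_a <- length(cols_a); n_b <- length(cols_b); n <- n_a + n_b
  if (n < 4) abort("need at least 4 arrays across the two genotypes")
  if (!exhaustive && B < 100) abort("B must be >= 100")
  arr <- c(cols_a, cols_b)

  perms <- if (exhaustive) all_permutations(n) else NULL
  a_set <- seq_len(n_a)
  is_identity <- function(idx) {
    grp <- sort(idx[a_set])
    identical(grp, a_set) ||
      (n_a == n_b && identical(grp, seq(n_a + 1L, n)))
  }
  draw_perm <- function() {
    for (try in 1:1000) {
      idx <- sample.int(n)
      if (!exclude_identity || !is_identity(idx)) return(idx)
    }
    idx
  }
  observed <- ratio_statistic(windows, samples, genotype_a, genotype_b)

  wdat <- filter(windows, .data$array_id %in% arr)
  unis <- unique(observed$unigene_id)
  pooled_sizes <- integer(length(unis))
  res <- with_seed(seed, purrr::map(seq_along(unis), function(ui) {
    u <- unis[ui]
    wu <- filter(wdat, .data$unigene_id == u)
    W <- wu %>%
      select("pos", "array_id", "sppdev") %>%
      tidyr::pivot_wider(names_from = "array_id", values_from = "sppdev") %>%
      arrange(.data$pos)
    M <- as.matrix(W[arr[arr %in% names(W)]])
    if (!all(arr %in% colnames(M))) {
      miss <- setdiff(arr, colnames(M))
      M <- cbind(M, matrix(NA_real_, nrow(M), length(miss),
                           dimnames = list(NULL, miss)))
    }
    M <- M[, arr, drop = FALSE]
    nperm <- if (exhaustive) nrow(perms) else B
    pool <- vector("list", nperm)
    for (b in seq_len(nperm)) {
      idx <- if (exhaustive) perms[b, ] else draw_perm()
      ma <- rowMeans(M[, idx[seq_len(n_a)], drop = FALSE], na.rm = TRUE)
      mb <- rowMeans(M[, idx[n_a + seq_len(n_b)], drop = FALSE], na.rm = TRUE)
      r <- ma / mb
      pool[[b]] <- r[is.finite(r)]
    }
    pool <- unlist(pool)
    pooled_sizes[ui] <<- length(pool)
    obs_u <- filter(observed, .data$unigene_id == u)
    p <- vapply(obs_u$r_s, function(r) {
      if (!is.finite(r)) return(NA_real_)
      if (tails == "ecdf") {
        min(2 * min(mean(pool < r), mean(pool > r)), 1)
      } else if (r >= 1) {
        mean(pool > r | pool < 1 / r)
      } else {
        mean(pool < r | pool > 1 / r)
      }
    }, numeric(1))
    mutate(obs_u, p = p)
  }))
  out <- bind_rows(res)
  out <- if (fdr_scope == "unigene") {
    out %>%
      group_by(.data$unigene_id) %>%
      mutate(fdr = bh_adjust(.data$p)) %>%
      ungroup()
  } else {
    mutate(out, fdr = bh_adjust(.data$p))
  }
  attr(out, "B") <- if (exhaustive) nrow(perms) else B
  attr(out, "n_pooled") <- setNames(pooled_sizes, unis)
  class(out) <- c("spp_test", class(tibble()))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, capped at 1.
#' Values outside `[0, 1]` are an error; `NA`s are passed through.
#'
#' @param pvalues Numeric p-values.
#' @return Adjusted p-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call SPP ranges from a position test
#'
#' Windows passing the FDR cutoff (and the direction filter, applied per
#' window) are merged into maximal ranges of adjacent/overlapping 2 bp
#' windows. Ranges narrower than `min_width` bases, or whose every window
#' has fewer than `min_probes` informative probes, are discarded. The
#' pair-wise analysis default keeps only ratios below 1 (the A/B < 1
#' orientation; deviations above 1 showed a high empirical false positive
#' rate).
#'
#' @param test An `spp_test` from [permutation_pvalues()].
#' @param fdr_cutoff Keep windows with `fdr <=` this value (default 0.1).
#' @param min_width Minimum range width in bases (default 4).
#' @param min_probes Minimum informative probes supporting the range's
#'   best-covered window (default 2).
#' @param direction `"lt1"` (keep windows with ratio < 1), `"gt1"`, or
#'   `"both"`.
#' @param method Method tag recorded on the calls.
#' @return Tibble of class `spp_calls`: `unigene_id`, `start`, `end`
#'   (half-open), `method`, `statistic` (ratio at the range's most
#'   significant window), `fdr_or_p`, `n_probes_min`, `direction`.
#' @export
call_spps <- function(test, fdr_cutoff = 0.1, min_width = 4, min_probes = 2,
                      direction = c("lt1", "gt1", "both"), method = "sfpdev") {
  direction <- match.arg(direction)
  sig <- test %>%
    filter(!is.na(.data$fdr), .data$fdr <= fdr_cutoff) %>%
    filter(switch(direction,
                  lt1 = .data$r_s < 1,
                  gt1 = .data$r_s > 1,
                  both = TRUE))
  merge_windows(sig, stat_col = "r_s", sig_col = "fdr", method = method,
                min_width = min_width, min_probes = min_probes)
}

# Merge significant 2 bp windows into maximal ranges and apply the range
# filters shared by all callers.
merge_windows <- function(sig, stat_col, sig_col, method, min_width,
                          min_probes, width_of_window = 2L) {
  empty <- tibble(unigene_id = character(), start = integer(), end = integer(),
                  method = character(), statistic = double(),
                  fdr_or_p = double(), n_probes_min = integer(),
                  direction = integer())
  if (!nrow(sig)) {
    return(structure(empty, class = c("spp_calls", class(tibble()))))
  }
  calls <- sig %>%
    arrange(.data$unigene_id, .data$pos) %>%
    group_by(.data$unigene_id) %>%
    mutate(new_range = .data$pos - lag(.data$pos, default = -1e9) > width_of_window,
           range_id = cumsum(.data$new_range)) %>%
    group_by(.data$unigene_id, .data$range_id) %>%
    summarise(start = min(.data$pos),
              end = max(.data$pos) + width_of_window,
              best = which.min(.data[[sig_col]]),
              statistic = .data[[stat_col]][.data$best],
              fdr_or_p = min(.data[[sig_col]]),
              n_probes_min = max(.data$n_probes_min),
              .groups = "drop") %>%
    filter(.data$end - .data$start >= min_width,
           .data$n_probes_min >= min_probes) %>%
    mutate(method = method,
           direction = as.integer(sign(1 - .data$statistic))) %>%
    select("unigene_id", "start", "end", "method", "statistic",
           "fdr_or_p", "n_probes_min", "direction")
  structure(calls, class = c("spp_calls", class(tibble())))
}

#' Write SPP calls as BED plus a statistics sidecar
#'
#' BED columns: unigene, start, end, name = method, score = -10*log10 of
#' the call's FDR/p (capped at 1000), strand ".". The TSV sidecar carries
#' the full statistics and is read back by [read_calls()].
#'
#' @param calls An `spp_calls` tibble.
#' @param path Path of the BED file; the sidecar gets extension `.tsv`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  bed <- calls %>%
    mutate(score = pmin(round(-10 * log10(pmax(.data$fdr_or_p, 1e-100))), 1000),
           strand = ".") %>%
    select("unigene_id", "start", "end", "method", "score", "strand")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  readr::write_tsv(calls, paste0(sub("\\.bed$", "", path), ".tsv"),
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  tsv <- if (grepl("\\.tsv$", path)) path else paste0(sub("\\.bed$", "", path), ".tsv")
  out <- readr::read_tsv(tsv, col_types = readr::cols(
    unigene_id = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), method = readr::col_character(),
    statistic = readr::col_double(), fdr_or_p = readr::col_double(),
    n_probes_min = readr::col_integer(), direction = readr::col_integer()),
    progress = FALSE)
  structure(out, class = c("spp_calls", class(tibble())))
}
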