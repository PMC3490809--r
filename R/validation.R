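#' Read a SNP truth set from VCF
#'
#' CHROM is the unigene id; POS is converted from 1-based VCF convention
#' to the package's 0-based coordinates.
#'
#' @param path VCF file (plain text or gzipped).
#' @return Tibble `unigene_id`, `position` (0-based), `ref`, `alt`.
#' @export
read_truth_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(tibble(unigene_id = character(), position = integer(),
                  ref = character(), alt = character()))
  }
  tibble(unigene_id = fix$CHROM,
         position = as.integer(fix$POS) - 1L,
         ref = fix$REF, alt = fix$ALT)
}

#' Score SPP calls against a truth set
#'
#' A call is a true positive iff a truth variant lies within `margin`
#' bases of its range, i.e. in the half-open extension
#' `[start - margin, end + margin)`. Calls whose extended range has no
#' truth coverage are excluded from the FDR ("excluded_no_coverage"); by
#' default coverage is the full length of every unigene present in the
#' truth set, or explicit intervals via `coverage`. Calls overlapping an
#' optional set of mapped-marker intervals are rescued as true.
#'
#' @param calls An `spp_calls` tibble.
#' @param truth Truth tibble from [read_truth_vcf()] (or any tibble with
#'   `unigene_id`, `position`).
#' @param margin Bases added on each side (default 8).
#' @param coverage Optional tibble `unigene_id`, `start`, `end` of regions
#'   where truth is known.
#' @param mapped Optional tibble `unigene_id`, `start`, `end` of mapped
#'   markers; overlapping calls are considered real.
#' @return The calls with a `status` column
#'   (`true_positive` / `false_positive` / `excluded_no_coverage`), class
#'   `spp_validation`, with attribute `observed_fdr` = FP / (TP + FP).
#' @export
score_calls <- function(calls, truth, margin = 8, coverage = NULL,
                        mapped = NULL) {
  assert_columns(truth, c("unigene_id", "position"), "truth")
  if (is.null(coverage)) {
    coverage <- truth %>%
      distinct(.data$unigene_id) %>%
      mutate(start = -Inf, end = Inf)
  }
  status <- vapply(seq_len(nrow(calls)), function(i) {
    lo <- calls$start[i] - margin
    hi <- calls$end[i] + margin
    u <- calls$unigene_id[i]
    cov <- coverage[coverage$unigene_id == u, ]
    covered <- nrow(cov) > 0 && any(cov$start < hi & cov$end > lo)
    if (!covered) return("excluded_no_coverage")
    hits <- truth$unigene_id == u & truth$position >= lo & truth$position < hi
    if (any(hits)) return("true_positive")
    if (!is.null(mapped)) {
      mp <- mapped[mapped$unigene_id == u, ]
      if (nrow(mp) > 0 && any(mp$start < calls$end[i] & mp$end > calls$start[i])) {
        return("true_positive")
      }
    }
    "false_positive"
  }, character(1))
  out <- mutate(calls, status = status)
  tp <- sum(status == "true_positive"); fp <- sum(status == "false_positive")
  attr(out, "observed_fdr") <- if (tp + fp > 0) fp / (tp + fp) else NA_real_
  class(out) <- c("spp_validation", class(tibble()))
  out
}

#' Screen calls at duplicated loci
#'
#' Extracts each call's subsequence plus `margin` bases on either side and
#' scans a set of reference sequences (both strands) for near-exact copies:
#' full-length matches with at most `max_mismatch` mismatches (coverage
#' 100%, satisfying the >= 95% criterion). A call matching at least
#' `min_hits` distinct loci is flagged duplicated; when the call's own
#' unigene is among the references its self-match contributes one hit.
#' Queries shorter than 20 bases are screened with a warning.
#'
#' @param calls An `spp_calls` tibble.
#' @param unigenes Named character vector of the unigene sequences the
#'   calls live on.
#' @param references List of named character vectors (one per reference
#'   collection) to scan; defaults to the unigenes themselves.
#' @param margin Bases added on each side of the call range (default 8).
#' @param max_mismatch Maximum mismatches for a hit (default 2).
#' @param min_hits Distinct loci needed to flag duplication (default 2).
#' @return `calls` with columns `n_loci` and `duplicated`.
#' @export
duplicate_locus_screen <- function(calls, unigenes, references = NULL,
                                   margin = 8, max_mismatch = 2,
                                   min_hits = 2) {
  if (is.null(references)) references <- list(unigenes)
  subjects <- unlist(references)
  subj_sets <- lapply(subjects, Biostrings::DNAString)
  n_loci <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    u <- calls$unigene_id[i]
    seq_u <- unigenes[[u]]
    if (is.null(seq_u)) abort(sprintf("no sequence for unigene '%s'", u))
    lo <- max(calls$start[i] - margin, 0) + 1L
    hi <- min(calls$end[i] + margin, nchar(seq_u))
    query <- substr(seq_u, lo, hi)
    if (nchar(query) < 20) {
      warn(sprintf("duplicate screen query for %s:[%d,%d) is shorter than 20 bases",
                   u, calls$start[i], calls$end[i]))
    }
    q <- Biostrings::DNAString(query)
    qrc <- Biostrings::reverseComplement(q)
    hits <- 0L
    for (s in subj_sets) {
      if (length(s) < length(q)) next
      hits <- hits +
        length(Biostrings::matchPattern(q, s, max.mismatch = max_mismatch)) +
        length(Biostrings::matchPattern(qrc, s, max.mismatch = max_mismatch))
    }
    n_loci[i] <- hits
  }
  mutate(calls, n_loci = n_loci, duplicated = n_loci >= min_hits)
}

#' Observed FDR over a grid of call thresholds
#'
#' Re-scores the calls against the truth set at each threshold on the
#' calls' own statistic column (`fdr_or_p`): calls with `fdr_or_p <=`
#' threshold are retained and the observed FDR = FP / (TP + FP) recomputed
#' after exclusions. With zero surviving calls the FDR is reported absent.
#'
#' @inheritParams score_calls
#' @param thresholds Numeric thresholds to evaluate.
#' @return Tibble `threshold`, `n_calls`, `n_tp`, `n_fp`, `n_excluded`,
#'   `observed_fdr`.
#' @export
fdr_curve <- function(calls, truth, thresholds, margin = 8, coverage = NULL,
                      mapped = NULL) {
  scored <- score_calls(calls, truth, margin = margin, coverage = coverage,
                        mapped = mapped)
  rows <- purrr::map(thresholds, function(t) {
    keep <- filter(scored, .data$fdr_or_p <= t)
    tp <- sum(keep$status == "true_positive")
    fp <- sum(keep$status == "false_positive")
    tibble(threshold = t, n_calls = nrow(keep), n_tp = tp, n_fp = fp,
           n_excluded = sum(keep$status == "excluded_no_coverage"),
           observed_fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_)
  })
  bind_rows(rows)
}

#' Sensitivity of calls against planted variants
#'
#' Fraction of truth variants having a call range within `margin` bases
#' (the converse of [score_calls()]'s true-positive rule).
#'
#' @inheritParams score_calls
#' @return A single number in `[0, 1]`.
#' @export
call_sensitivity <- function(calls, truth, margin = 8) {
  if (!nrow(truth)) return(NA_real_)
  found <- vapply(seq_len(nrow(truth)), function(i) {
    any(calls$unigene_id == truth$unigene_id[i] &
          calls$start - margin <= truth$position[i] &
          calls$end + margin > truth$position[i])
  }, logical(1))
  mean(found)
}
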