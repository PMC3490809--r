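# Intensity matrices are wide tibbles (probe_id + one column per array)
# carrying their processing state in attribute "state":
# raw -> background_corrected -> normalized (transitions only forward).

intensity_state <- function(x) attr(x, "state") %||% NA_character_

set_state <- function(x, state) {
  attr(x, "state") <- state
  x
}

require_state <- function(x, state, op) {
  st <- intensity_state(x)
  if (!is.na(st) && st != state) {
    abort(sprintf("%s expects a matrix in state '%s', got '%s'", op, state, st))
  }
  invisible(x)
}

#' Read and write intensity matrices
#'
#' TSV with a `probe_id` column followed by one column per array.
#'
#' @param path File path.
#' @param state Processing state to record on the matrix read
#'   (`"raw"`, `"background_corrected"` or `"normalized"`).
#' @param x Intensity tibble to write.
#' @return `read_intensity()` returns a wide intensity tibble.
#' @export
read_intensity <- function(path, state = "raw") {
  x <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  set_state(x, state)
}

#' @rdname read_intensity
#' @export
write_intensity <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Background-correct an intensity matrix
#'
#' Per-array convolution-model correction (normal background plus
#' exponential signal, the standard RMA-style "normexp" estimator as
#' implemented in limma). Output is strictly positive and elementwise no
#' larger than the input. `method = "none"` passes values through (the
#' reproducible path for testing), only advancing the state.
#'
#' @param x Raw intensity tibble.
#' @param method `"rma"` (normexp convolution) or `"none"`.
#' @return Intensity tibble in state `"background_corrected"`.
#' @export
background_correct <- function(x, method = c("rma", "none")) {
  method <- match.arg(method)
  require_state(x, "raw", "background_correct()")
  m <- wide_to_matrix(x)
  bad <- rownames(m)[!stats::complete.cases(m) | apply(m <= 0, 1, any)]
  if (length(bad)) {
    abort(sprintf("non-positive or missing raw values for probe(s): %s%s",
                  paste(head(bad, 5), collapse = ", "),
                  if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else ""))
  }
  if (method == "rma") {
    corrected <- limma::backgroundCorrect.matrix(m, method = "normexp",
                                                 verbose = FALSE)
    m <- pmin(corrected, m)
  }
  set_state(matrix_to_wide(m), "background_corrected")
}

#' Quantile-normalize across arrays
#'
#' Forces every array to share the across-array mean of sorted values; tied
#' values receive the mean of the normalized values at their tied ranks.
#' Idempotent.
#'
#' @param x Background-corrected intensity tibble.
#' @return Intensity tibble in state `"normalized"`.
#' @export
quantile_normalize <- function(x) {
  require_state(x, "background_corrected", "quantile_normalize()")
  m <- wide_to_matrix(x)
  if (anyNA(m)) abort("arrays cover unequal probe sets (missing values)")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  set_state(matrix_to_wide(out), "normalized")
}

#' Per-bin anti-genomic background thresholds
#'
#' Empirical percentile (linear interpolation, type-7 quantile) of the AG
#' probe intensities within each GC bin on each array. Bins with fewer than
#' `min_ag` AG probes are flagged unreliable and yield no usable threshold;
#' their genomic probes are treated as non-informative downstream.
#'
#' @param x Intensity tibble (any state; thresholds and the mask must come
#'   from the same matrix).
#' @param layout Layout tibble locating the AG probes and GC bins.
#' @param percentile Percentile in `[0, 100]`; the analysis default is 90.
#' @param min_ag Minimum AG probes per bin for a reliable threshold.
#' @return Tibble `gc_bin`, `array_id`, `threshold`, `n_ag`, `reliable`.
#' @export
ag_percentile <- function(x, layout, percentile = 90, min_ag = 20) {
  assert_scalar_number(percentile, "percentile", min = 0, max = 100)
  ag <- layout[is_ag(layout$unigene_id), c("probe_id", "gc_count")]
  long <- x %>%
    semi_join(ag, by = "probe_id") %>%
    tidyr::pivot_longer(-"probe_id", names_to = "array_id", values_to = "value") %>%
    inner_join(ag, by = "probe_id")
  out <- long %>%
    group_by(gc_bin = .data$gc_count, .data$array_id) %>%
    summarise(threshold = quantile(.data$value, percentile / 100, type = 7,
                                   names = FALSE),
              n_ag = n(), .groups = "drop") %>%
    mutate(reliable = .data$n_ag >= min_ag)
  attr(out, "percentile") <- percentile
  out
}

#' Informative-probe mask
#'
#' Marks a genomic probe informative on an array iff its intensity strictly
#' exceeds the AG threshold of its GC bin on that array ("above the 90th
#' percentile"; equality excluded). AG probes are never informative. Probes
#' in bins without a reliable threshold are non-informative; their count is
#' reported in attribute `n_unthresholded`.
#'
#' @param x Intensity tibble the thresholds were computed on.
#' @param layout Layout tibble.
#' @param thresholds Output of [ag_percentile()] on the same matrix.
#' @return Wide logical tibble (probe_id x arrays) with attribute
#'   `percentile_used`.
#' @export
informative_mask <- function(x, layout, thresholds) {
  assert_columns(thresholds, c("gc_bin", "array_id", "threshold", "reliable"),
                 "thresholds")
  usable <- filter(thresholds, .data$reliable, !is.na(.data$threshold))
  info <- layout[, c("probe_id", "unigene_id", "gc_count")]
  long <- x %>%
    tidyr::pivot_longer(-"probe_id", names_to = "array_id", values_to = "value") %>%
    inner_join(info, by = "probe_id") %>%
    left_join(usable, by = c(gc_count = "gc_bin", "array_id")) %>%
    mutate(informative = !is_ag(.data$unigene_id) &
             !is.na(.data$threshold) & .data$value > .data$threshold)
  n_unthresholded <- long %>%
    filter(!is_ag(.data$unigene_id), is.na(.data$threshold)) %>%
    nrow()
  mask <- long %>%
    select("probe_id", "array_id", "informative") %>%
    tidyr::pivot_wider(names_from = "array_id", values_from = "informative")
  mask <- mask[match(x$probe_id, mask$probe_id), ]
  attr(mask, "percentile_used") <- attr(thresholds, "percentile")
  attr(mask, "n_unthresholded") <- n_unthresholded
  mask
}

#' @rdname read_intensity
#' @param mask Logical mask tibble (written as 0/1).
#' @export
write_mask <- function(mask, path) {
  out <- mask
  for (a in array_ids(out)) out[[a]] <- as.integer(out[[a]])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_intensity
#' @export
read_mask <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_integer()),
    progress = FALSE)
  for (a in array_ids(x)) x[[a]] <- as.logical(x[[a]])
  x
}
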