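# broom-style tidiers for the result containers.

#' @method tidy spp_test
#' @export
tidy.spp_test <- function(x, ...) as_tibble(x)

#' @method glance spp_test
#' @export
glance.spp_test <- function(x, fdr_cutoff = 0.1, ...) {
  tibble(n_windows = nrow(x),
         n_unigenes = dplyr::n_distinct(x$unigene_id),
         n_permutations = attr(x, "B") %||% NA_integer_,
         n_significant = sum(x$fdr <= fdr_cutoff, na.rm = TRUE),
         min_fdr = suppressWarnings(min(x$fdr, na.rm = TRUE)))
}

#' @method tidy spp_calls
#' @export
tidy.spp_calls <- function(x, ...) as_tibble(x)

#' @method glance spp_calls
#' @export
glance.spp_calls <- function(x, ...) {
  tibble(n_calls = nrow(x),
         n_unigenes = dplyr::n_distinct(x$unigene_id),
         mean_width = if (nrow(x)) mean(x$end - x$start) else NA_real_,
         fdr_estimate = attr(x, "fdr_estimate") %||% NA_real_)
}

#' @method tidy spp_msa
#' @export
tidy.spp_msa <- function(x, ...) as_tibble(x)

#' @method glance spp_msa
#' @export
glance.spp_msa <- function(x, ...) {
  tibble(n_windows = nrow(x),
         n_unigenes = dplyr::n_distinct(x$unigene_id),
         s0 = attr(x, "s0"),
         a_constant = attr(x, "a_constant"),
         denominator = attr(x, "denominator"),
         spread = attr(x, "spread"))
}

#' @method tidy spp_markers
#' @export
tidy.spp_markers <- function(x, ...) as_tibble(x)

#' @method glance spp_markers
#' @export
glance.spp_markers <- function(x, ...) {
  genotypes <- marker_genotypes(x)
  tibble(n_markers = nrow(x),
         n_unigenes = dplyr::n_distinct(x$unigene_id),
         n_genotypes = length(genotypes))
}

#' @method tidy spp_weight_profile
#' @export
tidy.spp_weight_profile <- function(x, ...) as_tibble(x)

#' @method glance spp_weight_profile
#' @export
glance.spp_weight_profile <- function(x, ...) {
  tibble(n_offsets = nrow(x),
         n_snps = attr(x, "n_snps") %||% NA_integer_,
         low_confidence = attr(x, "low_confidence") %||% FALSE,
         peak_offset = x$offset[which.max(x$weight)])
}

#' @method glance spp_validation
#' @export
glance.spp_validation <- function(x, ...) {
  tibble(n_calls = nrow(x),
         n_tp = sum(x$status == "true_positive"),
         n_fp = sum(x$status == "false_positive"),
         n_excluded = sum(x$status == "excluded_no_coverage"),
         observed_fdr = attr(x, "observed_fdr"))
}
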