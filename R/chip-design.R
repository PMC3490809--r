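#' Tile a unigene sequence with overlapping probes
#'
#' Generates a staggered tiling path of fixed-length probes along a single
#' unigene, the layout geometry used throughout the package: probes start at
#' offsets 0, `stagger`, `2 * stagger`, ... (0-based, half-open coordinates)
#' and may alternate between the sense and antisense strand at each step.
#' GC counts are computed from the probe subsequence; IUPAC ambiguity codes
#' count as non-GC, and probes containing more than `max_ambiguous`
#' ambiguous bases are dropped.
#'
#' @param sequence A single nucleotide string (or an object coercible to
#'   character, e.g. one element of a `Biostrings::DNAStringSet`).
#' @param unigene_id Identifier recorded for every probe.
#' @param probe_length Probe length in bases (default 25).
#' @param stagger Offset between consecutive probe starts in bases (default 2).
#' @param alternate_strands Alternate sense/antisense at each step?
#' @param max_ambiguous Drop probes with more than this many non-ACGT bases.
#' @return A tibble with columns `probe_id`, `unigene_id`, `start`, `length`,
#'   `strand` (`"+"`/`"-"`), `gc_count`, `quality` (NA; populated by chip
#'   vendors, see [drop_low_quality()]).
#' @examples
#' tile_unigene(strrep("ACGT", 20), "u1")
#' @export
tile_unigene <- function(sequence, unigene_id = "unigene1", probe_length = 25,
                         stagger = 2, alternate_strands = TRUE,
                         max_ambiguous = 2) {
  sequence <- toupper(as.character(sequence))
  assert_scalar_number(probe_length, "probe_length", min = 1)
  assert_scalar_number(stagger, "stagger", min = 1)
  len <- nchar(sequence)
  if (len < probe_length) {
    warn(sprintf("sequence '%s' (%d nt) is shorter than probe_length (%d); no probes tiled",
                 unigene_id, len, probe_length))
    return(empty_probe_table())
  }
  starts <- seq(0L, len - probe_length, by = stagger)
  dna <- Biostrings::DNAString(sequence)
  gc <- Biostrings::letterFrequencyInSlidingView(dna, probe_length,
                                                 "GC")[starts + 1L, 1]
  acgt <- Biostrings::letterFrequencyInSlidingView(dna, probe_length,
                                                   c("A", "C", "G", "T"))
  ambiguous <- probe_length - rowSums(acgt)[starts + 1L]
  strand <- if (alternate_strands) {
    ifelse(seq_along(starts) %% 2L == 1L, "+", "-")
  } else rep("+", length(starts))
  out <- tibble(
    probe_id = sprintf("%s:%d%s", unigene_id, starts, strand),
    unigene_id = unigene_id,
    start = as.integer(starts),
    length = as.integer(probe_length),
    strand = strand,
    gc_count = as.integer(gc),
    quality = NA_real_
  )
  out[ambiguous <= max_ambiguous, ]
}

empty_probe_table <- function() {
  tibble(probe_id = character(), unigene_id = character(),
         start = integer(), length = integer(), strand = character(),
         gc_count = integer(), quality = double())
}

#' Tile a set of unigene sequences into a chip layout
#'
#' Applies [tile_unigene()] to every sequence and appends anti-genomic (AG)
#' background probes covering the occupied GC bins. AG probes have no
#' unigene assignment (reserved unigene token `"=AG="`, start -1) and no
#' sequence; only their per-GC-bin intensity distribution is ever used.
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet` of
#'   unigene sequences.
#' @param ag_per_bin Number of AG probes per occupied GC bin (0 for none).
#' @param seed Seed for AG probe id generation (determinism of the layout).
#' @inheritParams tile_unigene
#' @return A layout tibble (see [tile_unigene()]) carrying the unigene
#'   lengths in attribute `unigene_lengths`.
#' @export
tile_unigenes <- function(sequences, probe_length = 25, stagger = 2,
                          alternate_strands = TRUE, ag_per_bin = 50,
                          seed = NULL, max_ambiguous = 2) {
  seqs <- setNames(as.character(sequences), names(sequences))
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    abort("`sequences` must be named by unigene id")
  }
  probes <- purrr::map2(seqs, ids, function(s, id) {
    tile_unigene(s, id, probe_length = probe_length, stagger = stagger,
                 alternate_strands = alternate_strands,
                 max_ambiguous = max_ambiguous)
  })
  layout <- bind_rows(probes)
  if (ag_per_bin > 0 && nrow(layout)) {
    ag <- make_ag_probes(ag_per_bin, sort(unique(layout$gc_count)), seed = seed)
    layout <- bind_rows(layout, ag)
  }
  attr(layout, "unigene_lengths") <- setNames(nchar(seqs), ids)
  layout
}

#' Anti-genomic background probes
#'
#' Creates `count_per_bin` AG probes for each requested GC bin. AG probes
#' carry only a GC label; their simulated/observed intensities estimate the
#' per-bin background distribution used by [ag_percentile()].
#'
#' @param count_per_bin Probes per bin (>= 1).
#' @param gc_bins Integer GC counts to cover.
#' @param seed Optional seed; the same seed yields identical probe ids.
#' @return A layout-shaped tibble with `unigene_id = "=AG="`, `start = -1`.
#' @export
make_ag_probes <- function(count_per_bin, gc_bins, seed = NULL) {
  assert_scalar_number(count_per_bin, "count_per_bin", min = 1)
  if (length(gc_bins) == 0) abort("`gc_bins` must be non-empty")
  gc_bins <- sort(unique(as.integer(gc_bins)))
  with_seed(seed, {
    grid <- tidyr::expand_grid(gc_count = gc_bins, idx = seq_len(count_per_bin))
    tibble(
      probe_id = sprintf("AG_gc%02d_%04d", grid$gc_count, grid$idx),
      unigene_id = AG_TOKEN,
      start = -1L,
      length = 25L,
      strand = "+",
      gc_count = grid$gc_count,
      quality = NA_real_
    )
  })
}

#' Drop probes below a quality threshold
#'
#' Retains probes whose vendor quality score is strictly greater than
#' `min_quality` (the chip-design screen uses quality > 0.25). Probes with
#' an absent quality score are kept. Per-unigene tiling may become
#' discontiguous; contiguous stretches are a downstream concept.
#'
#' @param probes A layout tibble.
#' @param min_quality Strict lower bound on `quality`.
#' @return The filtered layout tibble (attributes preserved).
#' @export
drop_low_quality <- function(probes, min_quality = 0.25) {
  assert_columns(probes, "quality", "probes")
  keep <- is.na(probes$quality) | probes$quality > min_quality
  out <- probes[keep, ]
  attr(out, "unigene_lengths") <- attr(probes, "unigene_lengths")
  out
}

#' Recorded or derived unigene lengths of a layout
#'
#' @param layout A layout tibble.
#' @return Named integer vector of unigene lengths; derived as
#'   `max(start + length)` per unigene when the layout does not carry
#'   recorded lengths (e.g. after [read_layout()]).
#' @export
unigene_lengths <- function(layout) {
  lens <- attr(layout, "unigene_lengths")
  if (!is.null(lens)) return(lens)
  g <- layout[!is_ag(layout$unigene_id), ]
  tapply(g$start + g$length, g$unigene_id, max)
}

#' Read and write chip layout files
#'
#' BED-like TSV with header columns `unigene_id`, `start`, `length`,
#' `strand`, `gc_count`, `quality`, `probe_id`. AG probes use the reserved
#' unigene token `"=AG="` with start -1. `write_layout()` then
#' `read_layout()` is the identity on all fields.
#'
#' @param path File path.
#' @param layout Layout tibble to write.
#' @return `read_layout()` returns a layout tibble; `write_layout()` its
#'   `path`, invisibly.
#' @export
read_layout <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    unigene_id = readr::col_character(), start = readr::col_integer(),
    length = readr::col_integer(), strand = readr::col_character(),
    gc_count = readr::col_integer(), quality = readr::col_double(),
    probe_id = readr::col_character()), progress = FALSE)
  if (nrow(raw) == 0) {
    warn(sprintf("layout file '%s' contains no probes", path))
    return(empty_probe_table())
  }
  line <- seq_len(nrow(raw)) + 1L  # data line numbers (header is line 1)
  bad_strand <- which(!raw$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    abort(sprintf("line %d: unknown strand token '%s'",
                  line[bad_strand[1]], raw$strand[bad_strand[1]]))
  }
  bad_start <- which(raw$start < 0 & !is_ag(raw$unigene_id))
  if (length(bad_start)) {
    abort(sprintf("line %d: negative start %d", line[bad_start[1]],
                  raw$start[bad_start[1]]))
  }
  dup <- which(duplicated(raw$probe_id))
  if (length(dup)) {
    abort(sprintf("line %d: duplicate probe_id '%s'", line[dup[1]],
                  raw$probe_id[dup[1]]))
  }
  raw[c("probe_id", "unigene_id", "start", "length", "strand",
        "gc_count", "quality")]
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  assert_columns(layout, c("probe_id", "unigene_id", "start", "length",
                           "strand", "gc_count", "quality"), "layout")
  readr::write_tsv(layout[c("unigene_id", "start", "length", "strand",
                            "gc_count", "quality", "probe_id")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read unigene sequences from FASTA
#'
#' @param path FASTA file of unigene sequences.
#' @return Named character vector of sequences.
#' @export
read_unigenes <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
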