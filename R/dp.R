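#' Bimodal split of per-array deviations at one window
#'
#' Splits the SPPdev values of all arrays at a window into two clusters at
#' the largest gap among cuts leaving at least `min_side` arrays per side
#' (maximizing the number of arrays assigned under each peak). Arrays
#' falling inside the central `ambiguity_band` fraction of the interval
#' between the two mode means are treated as missing. The higher-signal
#' mode is the A allele; since SPPdev = 1 - R/Y increases with
#' hybridization signal Y, that is the mode with the larger deviation mean.
#' The between-mode separation is summarized as `cluster_ratio`: by default
#' the ratio of the implied relative hybridization signals
#' 1/(1 - SPPdev) of the two mode means (`ratio_scale = "signal"`, the
#' exact inverse of the SFPdev definition); `"raw"` uses
#' `|m_high| / |m_low|`. Splits with `cluster_ratio < min_ratio` or an
#' invalid side are not markers.
#'
#' @param values Named numeric (names = array ids) of SPPdev at one window.
#' @param min_side Minimum arrays per cluster (default 2).
#' @param ambiguity_band Central fraction of the inter-mode interval
#'   treated as missing (default 0.2).
#' @param min_ratio Minimum between-mode ratio for a valid marker.
#' @param ratio_scale `"signal"` or `"raw"`.
#' @return `NULL` if no valid split, otherwise a list with `calls`
#'   (character per array: `"A"`, `"B"` or `"-"`) and `cluster_ratio`.
#' @export
bimodal_split <- function(values, min_side = 2, ambiguity_band = 0.2,
                          min_ratio = 1.2, ratio_scale = c("signal", "raw")) {
  ratio_scale <- match.arg(ratio_scale)
  present <- values[!is.na(values)]
  if (length(present) < 2 * min_side) return(NULL)
  ord <- order(present)
  v <- present[ord]
  n <- length(v)
  cut_idx <- seq(min_side, n - min_side)
  if (!length(cut_idx)) return(NULL)
  gaps <- v[cut_idx + 1] - v[cut_idx]
  if (max(gaps) <= 0) return(NULL)  # ties straddling every valid cut: unimodal
  best <- cut_idx[which.max(gaps)]
  m_low <- mean(v[seq_len(best)])
  m_high <- mean(v[seq(best + 1, n)])
  if (!(m_high > m_low)) return(NULL)
  center <- (m_low + m_high) / 2
  half_band <- ambiguity_band * (m_high - m_low) / 2
  calls_present <- dplyr::case_when(
    abs(present - center) < half_band ~ "-",
    present > center ~ "A",
    TRUE ~ "B")
  if (sum(calls_present == "A") < min_side ||
      sum(calls_present == "B") < min_side) return(NULL)
  cluster_ratio <- if (ratio_scale == "signal") {
    if (m_high >= 1) Inf else (1 - m_low) / (1 - m_high)
  } else {
    if (m_low == 0) Inf else abs(m_high) / abs(m_low)
  }
  if (is.finite(cluster_ratio) && cluster_ratio < min_ratio) return(NULL)
  calls <- setNames(rep("-", length(values)), names(values))
  calls[names(present)] <- calls_present
  list(calls = calls, cluster_ratio = cluster_ratio)
}

# Relative hybridization signal implied by a deviation value:
# SFPdev = 1 - R/Y  =>  Y = R / (1 - SFPdev), monotone increasing in the
# deviation and positive for dev < 1; deviations >= 1 map to +Inf.
implied_signal <- function(dev) if (dev >= 1) Inf else 1 / (1 - dev)

#' Summarize three replicate allele calls into a marker code
#'
#' Deterministic total mapping of replicate triples from
#' \{A, B, -\} to marker codes: A iff (A,A,A); B iff (B,B,B); C iff two B
#' and one missing; D iff two A and one missing; I for any combination
#' containing both A and B, or two missing plus a single call; "-" iff all
#' three are missing.
#'
#' @param calls Character vector of length 3 (order irrelevant), entries in
#'   `c("A", "B", "-")`.
#' @return A single marker code in `c("A","B","C","D","I","-")`.
#' @export
summarize_replicates <- function(calls) {
  if (length(calls) != 3) abort("exactly 3 replicate calls are required")
  if (!all(calls %in% c("A", "B", "-"))) {
    abort("replicate calls must be 'A', 'B' or '-'")
  }
  n_a <- sum(calls == "A"); n_b <- sum(calls == "B"); n_m <- sum(calls == "-")
  if (n_a == 3) return("A")
  if (n_b == 3) return("B")
  if (n_b == 2 && n_m == 1) return("C")
  if (n_a == 2 && n_m == 1) return("D")
  if (n_m == 3) return("-")
  "I"  # both alleles present, or two missing plus one call
}

#' Genotype a diversity panel window by window
#'
#' Runs [bimodal_split()] on every 2 bp window across all arrays of a
#' panel and summarizes the replicate calls per genotype with
#' [summarize_replicates()]. Windows with no valid bimodal split are not
#' markers and are omitted.
#'
#' @param windows SPPdev windows from [sppdev_windows()] over the panel.
#' @param samples Sample sheet (`array_id`, `genotype`, `replicate`).
#' @param min_side,ambiguity_band,min_ratio,ratio_scale See
#'   [bimodal_split()].
#' @return A marker tibble of class `spp_markers`: `unigene_id`, `start`,
#'   `end` (the 2 bp window), `cluster_ratio`, `n_probes_min`, then one
#'   column per genotype with codes A/B/C/D/I/-.
#' @export
dp_genotype <- function(windows, samples, min_side = 2, ambiguity_band = 0.2,
                        min_ratio = 1.2, ratio_scale = c("signal", "raw")) {
  ratio_scale <- match.arg(ratio_scale)
  assert_columns(samples, c("array_id", "genotype"), "samples")
  genotypes <- unique(samples$genotype)
  geno_of <- setNames(samples$genotype, samples$array_id)
  wide <- windows %>%
    select("unigene_id", "pos", "array_id", "sppdev", "n_probes") %>%
    tidyr::nest(.by = c("unigene_id", "pos"))
  rows <- purrr::pmap(wide, function(unigene_id, pos, data) {
    values <- setNames(rep(NA_real_, length(geno_of)), names(geno_of))
    values[data$array_id] <- data$sppdev
    split <- bimodal_split(values, min_side = min_side,
                           ambiguity_band = ambiguity_band,
                           min_ratio = min_ratio, ratio_scale = ratio_scale)
    if (is.null(split)) return(NULL)
    codes <- vapply(genotypes, function(g) {
      reps <- split$calls[names(geno_of)[geno_of == g]]
      if (length(reps) != 3) return(NA_character_)
      summarize_replicates(unname(reps))
    }, character(1))
    row <- tibble(unigene_id = unigene_id, start = pos, end = pos + 2L,
                  cluster_ratio = split$cluster_ratio,
                  n_probes_min = min(data$n_probes))
    row[genotypes] <- as.list(codes)
    row
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(unigene_id = character(), start = integer(), end = integer(),
                  cluster_ratio = double(), n_probes_min = integer())
    out[genotypes] <- replicate(length(genotypes), character(0),
                                simplify = FALSE)
  }
  structure(out, genotypes = genotypes,
            class = c("spp_markers", class(tibble())))
}

marker_genotypes <- function(markers) {
  attr(markers, "genotypes") %||%
    setdiff(names(markers), c("unigene_id", "start", "end", "cluster_ratio",
                              "n_probes_min", "pattern"))
}

#' Filter panel markers
#'
#' Merges adjacent/overlapping marker windows with identical genotype call
#' patterns into ranges, then removes ranges violating any bound: more
#' than `max_missing` "-" calls, more than `max_inconsistent` "I" calls,
#' best window covered by fewer than `min_probes` probes, width below
#' `min_width`, or between-mode ratio below `min_ratio` at every window.
#'
#' @param markers An `spp_markers` tibble from [dp_genotype()].
#' @param max_missing,max_inconsistent Maximum "-" and "I" genotypes.
#' @param min_probes,min_width Range support filters (defaults 2 and 4).
#' @param min_ratio Minimum between-mode ratio (default 1.2).
#' @param max_gap Identical-pattern windows separated by at most this many
#'   bases merge into one range (default 2: one intervening failed window
#'   is bridged, reflecting the heavy probe overlap of adjacent windows).
#' @return Filtered `spp_markers` with ranges instead of single windows,
#'   plus a `pattern` column (the concatenated genotype calls).
#' @export
filter_panel_markers <- function(markers, max_missing = 0,
                                 max_inconsistent = 0, min_probes = 2,
                                 min_width = 4, min_ratio = 1.2,
                                 max_gap = 2) {
  genotypes <- marker_genotypes(markers)
  with_pattern <- markers %>%
    mutate(pattern = purrr::pmap_chr(across(all_of(genotypes)),
                                     function(...) paste(..., sep = "")))
  merged <- with_pattern %>%
    arrange(.data$unigene_id, .data$start) %>%
    group_by(.data$unigene_id, .data$pattern) %>%
    mutate(new_range = .data$start - lag(.data$end, default = -1e9) > max_gap,
           range_id = cumsum(.data$new_range)) %>%
    group_by(.data$unigene_id, .data$pattern, .data$range_id) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              cluster_ratio = max(.data$cluster_ratio),
              n_probes_min = max(.data$n_probes_min),
              across(all_of(genotypes), first), .groups = "drop") %>%
    select(-"range_id")
  kept <- merged %>%
    mutate(n_missing = rowSums(across(all_of(genotypes), ~ .x == "-")),
           n_inconsistent = rowSums(across(all_of(genotypes), ~ .x == "I"))) %>%
    filter(.data$n_missing <= max_missing,
           .data$n_inconsistent <= max_inconsistent,
           .data$n_probes_min >= min_probes,
           .data$end - .data$start >= min_width,
           .data$cluster_ratio >= min_ratio) %>%
    select("unigene_id", "start", "end", "cluster_ratio", "n_probes_min",
           all_of(genotypes), "pattern") %>%
    arrange(.data$unigene_id, .data$start)
  structure(kept, genotypes = genotypes,
            class = c("spp_markers", class(tibble())))
}

#' Collapse duplicate marker patterns into haplotypes
#'
#' Within each unigene, markers sharing an identical genotype-call pattern
#' are collapsed to one representative (the first by position), yielding
#' the set of distinct haplotype-defining patterns. C/D codes participate
#' as their own symbols by default; `permissive = TRUE` first maps C to B
#' and D to A.
#'
#' @param markers A filtered `spp_markers`.
#' @param permissive Map C->B and D->A before comparing patterns?
#' @return Tibble `unigene_id`, `pattern`, `n_markers` (windows collapsed),
#'   `start`, `end` (of the representative marker) and the genotype calls.
#' @export
collapse_haplotypes <- function(markers, permissive = FALSE) {
  genotypes <- marker_genotypes(markers)
  m <- markers
  if (permissive) {
    for (g in genotypes) {
      m[[g]] <- dplyr::recode(m[[g]], C = "B", D = "A")
    }
  }
  m$pattern <- purrr::pmap_chr(m[genotypes], function(...) paste(..., sep = ""))
  out <- m %>%
    arrange(.data$unigene_id, .data$start) %>%
    group_by(.data$unigene_id, .data$pattern) %>%
    summarise(n_markers = n(), start = first(.data$start),
              end = first(.data$end), across(all_of(genotypes), first),
              .groups = "drop")
  structure(out, genotypes = genotypes,
            class = c("spp_markers", class(tibble())))
}

# Allele underlying a marker code: A/D carry the high-signal allele,
# B/C the low-signal allele, I and "-" are missing.
marker_allele <- function(code) {
  dplyr::case_when(code %in% c("A", "D") ~ "A",
                   code %in% c("B", "C") ~ "B",
                   TRUE ~ NA_character_)
}

#' Classify markers by the population level of their polymorphism
#'
#' A marker is `interspecific_only` when it is monomorphic within every
#' species but polymorphic across species; `private` to species X when all
#' of X carries one allele and all other genotypes the other;
#' `intraspecific` when some species is polymorphic within itself;
#' `monomorphic` otherwise. Species with a single member are treated as
#' monomorphic within. The categories partition the markers; `private`
#' takes precedence over the broader `interspecific_only`.
#'
#' @param markers An `spp_markers`.
#' @param panel Panel tibble (`genotype`, `species`).
#' @return `markers` with columns `level` and `level_species` (the private
#'   species, or comma-joined polymorphic species for intraspecific).
#' @export
classify_markers_by_level <- function(markers, panel) {
  assert_columns(panel, c("genotype", "species"), "panel")
  genotypes <- marker_genotypes(markers)
  panel <- filter(panel, .data$genotype %in% genotypes)
  res <- purrr::pmap(markers[genotypes], function(...) {
    alleles <- setNames(marker_allele(c(...)), genotypes)
    by_species <- split(alleles[panel$genotype], panel$species)
    poly_within <- vapply(by_species, function(a) {
      a <- a[!is.na(a)]
      length(unique(a)) > 1
    }, logical(1))
    consensus <- vapply(by_species, function(a) {
      a <- a[!is.na(a)]
      if (length(unique(a)) == 1) unique(a) else NA_character_
    }, character(1))
    if (any(poly_within)) {
      return(list(level = "intraspecific",
                  species = paste(names(poly_within)[poly_within],
                                  collapse = ",")))
    }
    known <- consensus[!is.na(consensus)]
    if (length(unique(known)) <= 1) {
      return(list(level = "monomorphic", species = NA_character_))
    }
    for (sp in names(known)) {
      others <- known[setdiff(names(known), sp)]
      if (length(unique(others)) == 1 && unique(others) != known[[sp]]) {
        return(list(level = "private", species = sp))
      }
    }
    list(level = "interspecific_only", species = NA_character_)
  })
  markers %>%
    mutate(level = purrr::map_chr(res, "level"),
           level_species = purrr::map_chr(res, "species"))
}

#' Per-unigene haplotype frequencies across the panel
#'
#' A genotype's haplotype at a unigene is its allele vector over the
#' unigene's markers; the frequency of a haplotype is the number of
#' genotypes carrying it divided by the panel size. Genotypes with any
#' missing allele in the unigene are excluded from the numerators, so
#' frequencies per unigene sum to at most 1.
#'
#' @param markers An `spp_markers` (typically after collapse).
#' @param panel Panel tibble (`genotype`).
#' @return Tibble `unigene_id`, `haplotype`, `n_genotypes`, `frequency`.
#' @export
haplotype_frequencies <- function(markers, panel) {
  genotypes <- intersect(marker_genotypes(markers), panel$genotype)
  n_panel <- nrow(panel)
  markers %>%
    tidyr::pivot_longer(all_of(genotypes), names_to = "genotype",
                        values_to = "code") %>%
    mutate(allele = marker_allele(.data$code)) %>%
    arrange(.data$unigene_id, .data$start) %>%
    group_by(.data$unigene_id, .data$genotype) %>%
    summarise(haplotype = if (anyNA(.data$allele)) NA_character_ else
      paste(.data$allele, collapse = ""), .groups = "drop") %>%
    filter(!is.na(.data$haplotype)) %>%
    count(.data$unigene_id, .data$haplotype, name = "n_genotypes") %>%
    mutate(frequency = .data$n_genotypes / n_panel)
}

#' Export markers as a binary 0/1 table
#'
#' Genotype-by-marker table scored like restriction-site markers: the
#' high-signal allele (A or D) as 1, the low-signal allele (B or C) as 0,
#' inconsistent or missing calls as the missing token `NA`.
#'
#' @param markers An `spp_markers` (filtered).
#' @param path Optional TSV output path.
#' @return The binary tibble (`genotype` x marker columns named
#'   `unigene:start-end`), invisibly if written.
#' @export
export_binary_markers <- function(markers, path = NULL) {
  genotypes <- marker_genotypes(markers)
  marker_id <- sprintf("%s:%d-%d", markers$unigene_id, markers$start,
                       markers$end)
  m <- t(vapply(seq_len(nrow(markers)), function(i) {
    allele <- marker_allele(unlist(markers[i, genotypes]))
    ifelse(is.na(allele), NA_integer_, as.integer(allele == "A"))
  }, integer(length(genotypes))))
  out <- tibble(genotype = genotypes,
                !!!setNames(as.data.frame(t(m)), marker_id))
  if (!is.null(path)) {
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}

#' @rdname export_binary_markers
#' @export
read_binary_markers <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    genotype = readr::col_character(), .default = readr::col_integer()),
    progress = FALSE)
}
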