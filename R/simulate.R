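#' Simulation parameters for synthetic hybridizations
#'
#' Bundles the signal model used by [simulate_panel()]. Intensities are
#' log-normal: for probe p on array a of genotype g,
#' \deqn{\ln Y_{pa} = \mu(gc_p) + \alpha_p + \sum_v \ln(1 - loss(o_{pv})) + \epsilon_{pa}}
#' where \eqn{\mu} is the GC-dependent baseline, \eqn{\alpha_p} a per-probe
#' affinity effect shared across arrays (real probes differ strongly in
#' hybridization efficiency), the sum runs over variants v carried by g and
#' covered by p with offset \eqn{o_{pv}} from the probe center, and
#' \eqn{\epsilon} is replicate noise. Anti-genomic probes draw from the same
#' model with baseline shifted by `log(dim_fraction)` and no variant term.
#'
#' @param baseline_by_gc Function gc_count -> mean log-intensity. Default
#'   `log(500) + 0.04 * (gc - 12.5)`: a mild GC slope around a median
#'   intensity of ~500 units.
#' @param sensitivity_curve Named numeric of fractional signal loss per
#'   offset from the probe center (see [default_sensitivity_curve()]).
#' @param noise_sd Additive replicate noise SD on the natural-log scale.
#' @param probe_effect_sd SD of the per-probe affinity effect (ln scale).
#' @param replicate_count Replicate arrays per genotype.
#' @param dim_fraction Background level of AG probes relative to genomic
#'   probes (< 1).
#' @param seed Integer seed; identical parameters give bit-identical output.
#' @return A list of class `spp_sim_params`.
#' @export
spp_sim_params <- function(baseline_by_gc = NULL,
                           sensitivity_curve = default_sensitivity_curve(),
                           noise_sd = 0.1, probe_effect_sd = 0.8,
                           replicate_count = 3, dim_fraction = 0.05,
                           seed = 1) {
  if (is.null(baseline_by_gc)) {
    baseline_by_gc <- function(gc) log(500) + 0.04 * (gc - 12.5)
  }
  if (any(sensitivity_curve < 0 | sensitivity_curve > 1)) {
    abort("`sensitivity_curve` values must lie in [0, 1]")
  }
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(dim_fraction, "dim_fraction", min = 0)
  structure(list(baseline_by_gc = baseline_by_gc,
                 sensitivity_curve = sensitivity_curve,
                 noise_sd = noise_sd, probe_effect_sd = probe_effect_sd,
                 replicate_count = as.integer(replicate_count),
                 dim_fraction = dim_fraction, seed = seed),
            class = "spp_sim_params")
}

#' Default mismatch sensitivity curve
#'
#' Fractional signal loss caused by a single mismatch as a function of its
#' offset from the probe center: a symmetric trapezoid losing 50% of signal
#' for the 16 most central bases (|offset| <= 8) and decaying linearly to 5%
#' at the probe edge (|offset| = 12). Fully overridable.
#'
#' @param max_offset Half-width of the probe (12 for 25-mers).
#' @param central_loss Loss inside the plateau.
#' @param edge_loss Loss at the outermost base.
#' @param plateau Plateau half-width in bases.
#' @return Named numeric vector over offsets `-max_offset:max_offset`.
#' @export
default_sensitivity_curve <- function(max_offset = 12, central_loss = 0.5,
                                      edge_loss = 0.05, plateau = 8) {
  offs <- -max_offset:max_offset
  loss <- ifelse(abs(offs) <= plateau, central_loss,
                 central_loss + (abs(offs) - plateau) / (max_offset - plateau) *
                   (edge_loss - central_loss))
  setNames(loss, offs)
}

sensitivity_loss <- function(curve, offset) {
  offs <- as.integer(names(curve))
  idx <- match(round(offset), offs)
  out <- ifelse(is.na(idx), 0, curve[pmax(idx, 1L)])
  unname(out)
}

#' Simulate a hybridization panel
#'
#' Generates a raw probe-by-array intensity matrix for a panel of genotypes
#' with planted variants, under the model described in [spp_sim_params()].
#' Every variant position must fall on a unigene known to the layout.
#'
#' @param layout Layout tibble (genomic + AG probes), see [tile_unigenes()].
#' @param panel Tibble with column `genotype` (optionally `species`,
#'   `class`); one row per genotype.
#' @param variants Tibble of planted variants with columns `genotype`,
#'   `unigene_id`, `position` (0-based) and optionally `allele`
#'   (`"variant"`/`"reference"`; missing rows mean reference). May be empty.
#' @param params An [spp_sim_params()] object.
#' @return List of class `spp_sim` with `intensity` (wide tibble `probe_id`
#'   x array columns, attribute `state = "raw"`), `samples` (array_id,
#'   genotype, species, class, replicate) and the `variants` used.
#' @export
simulate_panel <- function(layout, panel, variants = NULL, params = spp_sim_params()) {
  assert_columns(layout, c("probe_id", "unigene_id", "start", "length", "gc_count"),
                 "layout")
  assert_columns(panel, "genotype", "panel")
  if (is.null(variants) || nrow(variants) == 0) {
    variants <- tibble(genotype = character(), unigene_id = character(),
                       position = integer(), allele = character())
  }
  if (!"allele" %in% names(variants)) variants$allele <- "variant"
  variants <- filter(variants, .data$allele == "variant")
  known <- unique(layout$unigene_id)
  bad <- setdiff(unique(variants$unigene_id), known)
  if (length(bad)) {
    abort(sprintf("variants on unigene(s) unknown to the layout: %s",
                  paste(bad, collapse = ", ")))
  }

  samples <- tidyr::expand_grid(
    genotype = panel$genotype,
    replicate = seq_len(params$replicate_count)
  ) %>%
    left_join(panel, by = "genotype") %>%
    mutate(array_id = sprintf("%s_r%d", .data$genotype, .data$replicate),
           species = if ("species" %in% names(panel)) .data$species else NA_character_,
           class = if ("class" %in% names(panel)) .data$class else NA_character_) %>%
    select("array_id", "genotype", "species", "class", "replicate")

  ag <- is_ag(layout$unigene_id)
  base <- params$baseline_by_gc(layout$gc_count) +
    ifelse(ag, log(params$dim_fraction), 0)

  with_seed(params$seed, {
    affinity <- rnorm(nrow(layout), sd = params$probe_effect_sd)

    # per-genotype total log attenuation per probe from planted variants
    center <- layout$start + (layout$length - 1L) / 2
    atten <- matrix(0, nrow(layout), nrow(panel),
                    dimnames = list(layout$probe_id, panel$genotype))
    if (nrow(variants)) {
      for (k in seq_len(nrow(variants))) {
        v <- variants[k, ]
        hit <- which(!ag & layout$unigene_id == v$unigene_id &
                       layout$start <= v$position &
                       layout$start + layout$length > v$position)
        if (length(hit)) {
          loss <- sensitivity_loss(params$sensitivity_curve,
                                   v$position - center[hit])
          atten[hit, v$genotype] <- atten[hit, v$genotype] + log(1 - loss)
        }
      }
    }

    m <- matrix(NA_real_, nrow(layout), nrow(samples),
                dimnames = list(layout$probe_id, samples$array_id))
    for (j in seq_len(nrow(samples))) {
      mu <- base + affinity + atten[, samples$genotype[j]]
      m[, j] <- exp(mu + rnorm(nrow(layout), sd = params$noise_sd))
    }
  })

  intensity <- matrix_to_wide(m)
  attr(intensity, "state") <- "raw"
  structure(list(intensity = intensity, samples = samples, variants = variants),
            class = "spp_sim")
}

#' Plant variants for a two-genotype comparison
#'
#' Draws SNP positions uniformly along each unigene (within the
#' center-covered region, at least `min_spacing` bases apart) and assigns
#' them to `genotype`; all other genotypes carry the reference allele.
#' Variants are biallelic and homozygous, as in inbred lines.
#'
#' @param lengths Named vector of unigene lengths (see [unigene_lengths()]).
#' @param n_snps Total number of variants to plant.
#' @param genotype Carrier genotype label.
#' @param min_spacing Minimum distance between variants on a unigene.
#' @param seed Seed for position sampling.
#' @return Variants tibble (`genotype`, `unigene_id`, `position`, `allele`).
#' @export
plant_pairwise_variants <- function(lengths, n_snps, genotype = "gB",
                                    min_spacing = 50, seed = 1) {
  positions <- sample_positions(lengths, n_snps, min_spacing, seed)
  mutate(positions, genotype = genotype, allele = "variant") %>%
    select("genotype", "unigene_id", "position", "allele")
}

sample_positions <- function(lengths, n_snps, min_spacing, seed) {
  with_seed(seed, {
    ids <- rep(names(lengths), length.out = n_snps)
    out <- vector("list", length(lengths))
    for (i in seq_along(lengths)) {
      id <- names(lengths)[i]
      k <- sum(ids == id)
      if (k == 0) next
      lo <- 12L
      hi <- as.integer(lengths[[i]]) - 13L
      cand <- seq(lo, hi)
      pos <- integer(0)
      for (tries in seq_len(50 * k)) {
        if (length(pos) >= k || !length(cand)) break
        p <- sample(cand, 1)
        pos <- c(pos, p)
        cand <- cand[abs(cand - p) >= min_spacing]
      }
      out[[i]] <- tibble(unigene_id = id, position = sort(pos))
    }
    bind_rows(out)
  })
}

#' Plant species-structured variants for a diversity panel
#'
#' Creates markers with known population level: variants private to one
#' species (all of its genotypes carry the variant, no others do) and
#' intraspecific variants (a random strict subset of one species' genotypes
#' carries the variant). The returned object records the planted truth per
#' position so panel-level classification can be checked exactly.
#'
#' @param lengths Named unigene lengths.
#' @param panel Panel tibble with `genotype` and `species`.
#' @param n_private Named integer vector: private variants per species.
#' @param n_intraspecific Number of intraspecific variants (planted in the
#'   first species with > 1 genotype).
#' @param min_spacing Minimum distance between planted positions.
#' @param seed Seed.
#' @return List with `variants` (tibble, one row per carrier genotype per
#'   position) and `truth` (tibble `unigene_id`, `position`, `level`,
#'   `species`).
#' @export
plant_species_panel <- function(lengths, panel, n_private,
                                n_intraspecific = 0, min_spacing = 50,
                                seed = 1) {
  assert_columns(panel, c("genotype", "species"), "panel")
  n_total <- sum(n_private) + n_intraspecific
  positions <- sample_positions(lengths, n_total, min_spacing, seed)
  if (nrow(positions) < n_total) {
    abort("unigene set too small for the requested number of planted variants")
  }
  labels <- c(rep(names(n_private), n_private),
              rep("__intra__", n_intraspecific))
  with_seed(seed + 1L, {
    labels <- sample(labels)
    truth <- mutate(positions, label = labels)
    intra_species <- panel %>% count(.data$species) %>%
      filter(n > 1) %>% pull(.data$species) %>% first()
    rows <- purrr::pmap(truth, function(unigene_id, position, label) {
      if (label == "__intra__") {
        members <- panel$genotype[panel$species == intra_species]
        k <- sample(seq_len(length(members) - 1L), 1)
        carriers <- sample(members, k)
        level <- "intraspecific"
        sp <- intra_species
      } else {
        carriers <- panel$genotype[panel$species == label]
        level <- "private"
        sp <- label
      }
      list(variants = tibble(genotype = carriers, unigene_id = unigene_id,
                             position = position, allele = "variant"),
           truth = tibble(unigene_id = unigene_id, position = position,
                          level = level, species = sp))
    })
  })
  list(variants = bind_rows(purrr::map(rows, "variants")),
       truth = bind_rows(purrr::map(rows, "truth")))
}

#' Write planted variants as a minimal VCF truth file
#'
#' One record per (unigene, position) with a genotype column per panel
#' member (1/1 for variant carriers, 0/0 otherwise). Positions are written
#' 1-based per VCF convention; the file is readable by [read_truth_vcf()].
#'
#' @param variants Variants tibble (`genotype`, `unigene_id`, `position`).
#' @param panel Panel tibble naming all genotypes (columns for non-carriers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(variants, panel, path) {
  genotypes <- panel$genotype
  sites <- distinct(variants, .data$unigene_id, .data$position) %>%
    arrange(.data$unigene_id, .data$position)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=spptools_simulation",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes), collapse = "\t"))
  lines <- character(nrow(sites))
  if (nrow(sites)) {
    carrier_key <- paste(variants$unigene_id, variants$position, variants$genotype)
    for (i in seq_len(nrow(sites))) {
      gt <- ifelse(paste(sites$unigene_id[i], sites$position[i], genotypes) %in%
                     carrier_key, "1/1", "0/0")
      lines[i] <- paste(c(sites$unigene_id[i], sites$position[i] + 1L,
                          ".", "A", "C", ".", "PASS", ".", "GT", gt),
                        collapse = "\t")
    }
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
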