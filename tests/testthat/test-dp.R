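test_that("bimodal split separates clean clusters and maps alleles by signal", {
  v <- setNames(c(1, 1, 1, 5, 5, 5), sprintf("a%d", 1:6))
  s <- bimodal_split(v)
  # higher deviation = higher hybridization signal = A allele
  expect_equal(unname(s$calls), c("B", "B", "B", "A", "A", "A"))
  expect_gte(s$cluster_ratio, 1.2)

  # unimodal (all equal) values are not a marker
  expect_null(bimodal_split(setNames(rep(2, 6), sprintf("a%d", 1:6))))

  # a value at the midpoint of a clean split becomes missing
  v2 <- setNames(c(1, 1, 1, 3, 5, 5, 5), sprintf("a%d", 1:7))
  s2 <- bimodal_split(v2)
  expect_equal(unname(s2$calls[4]), "-")
  expect_equal(unname(s2$calls[c(1, 7)]), c("B", "A"))

  # sides below min_side are rejected
  expect_null(bimodal_split(setNames(c(1, 5, 5, 5, 5, 5), sprintf("a%d", 1:6)),
                            min_side = 2))
  # weak separation fails the ratio requirement
  v3 <- setNames(c(0.50, 0.50, 0.50, 0.53, 0.53, 0.53), sprintf("a%d", 1:6))
  expect_null(bimodal_split(v3, min_ratio = 1.2))
})

test_that("replicate summarization reproduces the printed code table exactly", {
  # every ordering of every multiset of {A, B, -}
  letters3 <- c("A", "B", "-")
  combos <- expand.grid(r1 = letters3, r2 = letters3, r3 = letters3,
                        stringsAsFactors = FALSE)
  expect_equal(nrow(combos), 27L)
  for (i in seq_len(nrow(combos))) {
    triple <- unlist(combos[i, ])
    expect_equal(summarize_replicates(triple), oracle_marker_code(triple),
                 label = paste(triple, collapse = "/"))
  }
  # the printed examples, verbatim
  expect_equal(summarize_replicates(c("A", "A", "A")), "A")
  expect_equal(summarize_replicates(c("B", "B", "-")), "C")
  expect_equal(summarize_replicates(c("A", "A", "-")), "D")
  expect_equal(summarize_replicates(c("A", "B", "A")), "I")
  expect_equal(summarize_replicates(c("-", "-", "B")), "I")
  expect_equal(summarize_replicates(c("-", "-", "-")), "-")
  expect_error(summarize_replicates(c("A", "A")), "exactly 3")
  expect_error(summarize_replicates(c("A", "A", "x")), "must be")
})


test_that("panel filters remove exactly the constructed violators", {
  m <- dp_marker_fixture()
  filt <- filter_panel_markers(m)
  # u1 10-14 merge (identical pattern) into a width-4 range and survive;
  # u1 [30,34): a "-" genotype under zero-missing -> removed;
  # u2 [6,10): an "I" under zero-inconsistent -> removed;
  # u2 [40,44): ratio 1.1 < 1.2 -> removed;
  # u3: single probe and width 2 -> removed
  expect_equal(nrow(filt), 1L)
  expect_equal(filt$start, 10L)
  expect_equal(filt$end, 14L)
  expect_equal(filt$pattern, "AABB")
  # relaxing each bound readmits exactly its violator
  expect_equal(nrow(filter_panel_markers(m, max_missing = 1)), 2L)
  expect_equal(nrow(filter_panel_markers(m, max_inconsistent = 1)), 2L)
  expect_equal(nrow(filter_panel_markers(m, min_ratio = 1.0)), 2L)
  expect_equal(nrow(filter_panel_markers(m, min_width = 2, min_probes = 1)), 2L)
})

test_that("haplotype collapse keeps one representative per pattern", {
  m <- tibble(
    unigene_id = c("u1", "u1", "u1", "u2"),
    start = c(0L, 10L, 20L, 0L), end = c(4L, 14L, 24L, 4L),
    cluster_ratio = 1.5, n_probes_min = 3L,
    g1 = c("A", "A", "B", "A"), g2 = c("B", "B", "A", "B"),
    g3 = c("B", "B", "A", "D"))
  m <- structure(m, genotypes = c("g1", "g2", "g3"),
                 class = c("spp_markers", class(tibble())))
  haps <- collapse_haplotypes(m)
  expect_equal(nrow(haps), 3L)  # u1: ABB + BAA, u2: ABD
  expect_equal(haps$n_markers[haps$unigene_id == "u1" & haps$pattern == "ABB"], 2L)
  # permissive mapping folds D into A
  m2 <- m
  m2$unigene_id <- c("u1", "u1", "u1", "u1")
  m2$g3 <- c("B", "C", "A", "B")  # patterns ABB, ABC, BAA, ABB
  haps2 <- collapse_haplotypes(m2)
  expect_equal(nrow(haps2), 3L)
  # permissive mapping folds C into B, so ABC joins the ABB pattern
  haps2p <- collapse_haplotypes(m2, permissive = TRUE)
  expect_equal(nrow(haps2p), 2L)
})

test_that("markers classify into disjoint population levels", {
  panel <- tibble(genotype = sprintf("g%d", 1:6),
                  species = c("s1", "s1", "s1", "s2", "s2", "s3"))
  m <- tibble(
    unigene_id = sprintf("u%d", 1:4), start = 0L, end = 4L,
    cluster_ratio = 1.5, n_probes_min = 3L,
    g1 = c("A", "A", "A", "A"),
    g2 = c("A", "A", "B", "A"),
    g3 = c("A", "A", "A", "A"),
    g4 = c("B", "B", "A", "A"),
    g5 = c("B", "B", "A", "A"),
    g6 = c("B", "A", "A", "A"))
  m <- structure(m, genotypes = sprintf("g%d", 1:6),
                 class = c("spp_markers", class(tibble())))
  cls <- classify_markers_by_level(m, panel)
  # u1: s1 all A, s2 all B, s3 B -> polymorphic across but s2+s3 share B,
  #     all of s1 carries A and all others B -> private to s1
  expect_equal(cls$level[1], "private")
  expect_equal(cls$level_species[1], "s1")
  # u2: every s2 member carries B and every other genotype A -> private s2
  expect_equal(cls$level[2], "private")
  expect_equal(cls$level_species[2], "s2")
  # u3: polymorphic inside s1 -> intraspecific, not interspecific
  expect_equal(cls$level[3], "intraspecific")
  expect_equal(cls$level_species[3], "s1")
  # u4: monomorphic everywhere
  expect_equal(cls$level[4], "monomorphic")
  # partition: each marker has exactly one level
  expect_true(all(table(seq_len(nrow(cls)), cls$level) <= 1))
})

test_that("haplotype frequencies divide by the panel size", {
  panel <- tibble(genotype = sprintf("g%02d", 1:52))
  m <- tibble(unigene_id = "u1", start = 0L, end = 4L,
              cluster_ratio = 1.5, n_probes_min = 3L)
  calls <- c(rep("A", 13), rep("B", 38), "-")
  m[panel$genotype] <- as.list(calls)
  m <- structure(m, genotypes = panel$genotype,
                 class = c("spp_markers", class(tibble())))
  freq <- haplotype_frequencies(m, panel)
  expect_equal(freq$frequency[freq$haplotype == "A"], 13 / 52)
  expect_equal(freq$frequency[freq$haplotype == "B"], 38 / 52)
  # missing genotypes excluded from numerators, so sums stay <= 1
  expect_lte(sum(freq$frequency), 1)
})

test_that("binary export scores alleles like restriction sites", {
  m <- dp_marker_fixture()[1:3, ]
  bin <- export_binary_markers(m)
  expect_equal(bin$genotype, c("g1", "g2", "g3", "g4"))
  first <- bin[[2]]
  expect_equal(first, c(1L, 1L, 0L, 0L))        # A -> 1, B -> 0
  expect_true(is.na(bin[[4]][4]))               # "-" -> missing token
  f <- withr::local_tempfile(fileext = ".tsv")
  export_binary_markers(m, f)
  expect_equal(as.data.frame(read_binary_markers(f)), as.data.frame(bin))
})

test_that("panel genotyping recovers a planted split end to end", {
  study <- small_study()
  # treat the six arrays as six genotypes with one replicate each is not
  # allowed (3 replicates required), so genotype on the 2x3 panel windows
  markers <- dp_genotype(study$windows, study$sim$samples)
  expect_s3_class(markers, "spp_markers")
  expect_true(all(c("gA", "gB") %in% names(markers)))
  filt <- filter_panel_markers(markers, min_ratio = 1.2)
  # every planted variant yields a polymorphic gA/gB marker range nearby
  hit <- vapply(seq_len(nrow(study$truth)), function(i) {
    any(filt$unigene_id == study$truth$unigene_id[i] &
          filt$start - 13 <= study$truth$position[i] &
          filt$end + 13 > study$truth$position[i] &
          filt$gA != filt$gB)
  }, logical(1))
  expect_gte(mean(hit), 0.75)
})
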