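test_that("tetramer_profile canonicalizes and skips invalid windows", {
  p <- tetramer_profile("AAAA")
  expect_equal(unname(p["AAAA"]), 1)
  expect_equal(sum(p), 1)
  expect_length(p, 136)

  # TTTT canonicalizes onto AAAA
  p2 <- tetramer_profile("AAAATTTT")
  expect_gt(p2[["AAAA"]], 0.3)

  # windows containing N are skipped: only the N-free windows count
  p3 <- tetramer_profile("ACGNACGT")
  expect_equal(unname(p3[["ACGT"]]), 1)   # sole valid window (palindromic 4-mer)
  expect_error(tetramer_profile("ACG"), "shorter than 4")
  expect_error(tetramer_profile("NNNNNN"), "no valid")

  # strand symmetry: a sequence and its reverse complement share a signature
  s <- random_dna(2000)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_equal(tetramer_profile(s), tetramer_profile(rc))
})

test_that("fragment_genome applies the 25% tail rule", {
  expect_length(fragment_genome(strrep("A", 100000), 20000), 5)
  f6 <- fragment_genome(strrep("A", 105000), 20000)
  expect_length(f6, 6)                       # 5 kb tail = 25% kept
  expect_identical(nchar(f6[6]), 5000L)
  expect_length(fragment_genome(strrep("A", 104000), 20000), 5)  # 4 kb dropped
  expect_error(fragment_genome("", 100), "nonempty")
  expect_error(fragment_genome("ACGT", 0), "fragment_length")
})

test_that("select_contaminants enforces the signature-similarity range", {
  tet <- small_world_tetramers()
  set.seed(9)
  elig <- select_contaminants("G001", tet)
  expect_false("G001" %in% elig)
  for (g in elig)
    expect_gte(bray_curtis_similarity(tet["G001", ], tet[g, ]), 0.80)

  # an identical-composition genome is always eligible
  tet2 <- rbind(tet, clone = tet["G001", ])
  expect_true("clone" %in% select_contaminants("G001", tet2))

  # compositionally alien pool -> error
  gc_lo <- paste(sample(c("A", "T"), 5000, TRUE, prob = c(0.5, 0.5)), collapse = "")
  gc_hi <- paste(sample(c("G", "C"), 5000, TRUE, prob = c(0.5, 0.5)), collapse = "")
  tet3 <- rbind(q = tetramer_profile(gc_lo), p = tetramer_profile(gc_hi))
  expect_error(select_contaminants("q", tet3), "unusable")

  # fixed seed gives identical ordering
  set.seed(77); a <- select_contaminants("G001", tet)
  set.seed(77); b <- select_contaminants("G001", tet)
  expect_identical(a, b)
})

test_that("simulate_bin records realized, manifest-consistent truth", {
  seqs <- small_world_sequences()
  tet <- small_world_tetramers()

  set.seed(201)
  b <- simulate_bin("G002", seqs, tet, fragment_length = 5000)
  src <- sub(".*\\|src=([^|]+)\\|.*", "\\1", names(b$contigs))
  qlen <- nchar(seqs[["G002"]])
  expect_equal(sum(nchar(b$contigs[src == "G002"])) / qlen, b$truth_completeness)
  expect_equal(sum(nchar(b$contigs[src != "G002"])) / qlen, b$truth_contamination)
  expect_identical(sort(unique(src[src != "G002"])), sort(b$contaminant_ids))

  # zero contamination: no contaminant fragments
  set.seed(202)
  b0 <- simulate_bin("G003", seqs, tet, fragment_length = 5000,
                     cont_range = c(0, 0))
  expect_identical(b0$contaminant_ids, character(0))
  expect_equal(b0$truth_contamination, 0)

  # full completeness, no contamination: the bin reassembles the genome and
  # annotation recovers the stored profile up to tokens cut at fragment
  # boundaries (each boundary can destroy at most one planted token)
  set.seed(203)
  b1 <- simulate_bin("G004", seqs, tet, fragment_length = 5000,
                     comp_range = c(1, 1), cont_range = c(0, 0))
  expect_equal(b1$truth_completeness, 1)
  w <- small_world()
  p <- toy_annotate(b1$contigs, w$catalog, "bin")
  stored <- w$genomes[["G004"]]$profile$counts
  got <- profile_counts(p, names(stored))
  expect_true(all(got <= stored))
  expect_lte(sum(stored) - sum(got), length(b1$contigs) - 1)
  # and with the genome as a single unfragmented contig the identity is exact
  set.seed(203)
  b1w <- simulate_bin("G004", lapply(seqs, identity), tet, fragment_length = 0,
                      comp_range = c(1, 1), cont_range = c(0, 0))
  expect_identical(toy_annotate(b1w$contigs, w$catalog, "bin")$counts, stored)

  # quantization arithmetic: 100 kb genome at 20 kb, comp target 0.8 -> 4/5
  solo <- list(g = strrep("ACGT", 25000), h = strrep("ACGT", 25000))
  set.seed(204)
  b2 <- simulate_bin("g", solo, fragment_length = 20000,
                     comp_range = c(0.8, 0.8), cont_range = c(0, 0))
  expect_equal(b2$truth_completeness, 0.8)
  expect_length(b2$contigs, 4)
})

test_that("native-contig mode passes contigs through unfragmented", {
  contigs <- c(random_dna(6000), random_dna(4000), random_dna(2000))
  seqs <- list(g = contigs, h = c(random_dna(5000), random_dna(5000)))
  set.seed(205)
  b <- simulate_bin("g", seqs, fragment_length = 0,
                    comp_range = c(1, 1), cont_range = c(0, 0))
  expect_identical(sort(unname(nchar(b$contigs))), sort(nchar(contigs)))
})

test_that("bins round-trip through FASTA + manifest", {
  seqs <- small_world_sequences()
  tet <- small_world_tetramers()
  set.seed(206)
  bins <- lapply(1:3, function(i)
    simulate_bin("G001", seqs, tet, fragment_length = 5000,
                 bin_id = sprintf("bin%02d", i)))
  dir <- withr::local_tempdir()
  write_bins(bins, dir, seed = 206)
  manifest <- read.delim(file.path(dir, "manifest.tsv"))
  expect_identical(nrow(manifest), 3L)
  for (i in 1:3) {
    back <- read_fasta(file.path(dir, sprintf("bin%02d.fasta", i)))
    expect_identical(unname(back), unname(bins[[i]]$contigs))
    src <- sub(".*\\|src=([^|]+)\\|.*", "\\1", names(back))
    expect_equal(sum(nchar(back[src == "G001"])) / manifest$query_length[i],
                 manifest$truth_completeness[i])
  }
})

test_that("generate_synthetic_world satisfies its construction invariants", {
  w <- small_world()
  expect_length(w$genomes, 12)

  # annotation round trip on every genome
  for (g in w$genomes)
    expect_identical(toy_annotate(g$sequence, w$catalog, g$genome_id)$counts,
                     g$profile$counts)

  # core families are single-copy in >= 95% of genomes
  core <- grep("^CORE", names(w$catalog), value = TRUE)
  single <- vapply(core, function(f)
    mean(vapply(w$genomes, function(g) profile_counts(g$profile, f) == 1,
                logical(1))), numeric(1))
  expect_gte(mean(single), 0.95)

  # same-clade profiles are more similar than cross-clade ones
  profiles <- lapply(w$genomes, `[[`, "profile")
  d <- profile_dissimilarity_matrix(profiles)
  cl <- vapply(w$genomes, `[[`, numeric(1), "clade")
  same <- outer(cl, cl, "=="); diag(same) <- NA
  expect_lt(mean(d[which(same)]), mean(d[which(!same)]))

  # byte-identical regeneration under the same seed
  w2 <- generate_synthetic_world(n_genomes = 12, n_core_families = 40,
                                 n_accessory_families = 80,
                                 genome_length = 60000, n_clades = 3, seed = 7)
  expect_identical(w2$genomes[["G005"]]$sequence, w$genomes[["G005"]]$sequence)
  expect_identical(lapply(w2$genomes, `[[`, "profile"),
                   lapply(w$genomes, `[[`, "profile"))

  # taxonomy is a rooted tree over all genome taxids
  for (g in w$genomes)
    expect_no_error(lca_taxonomy(c(g$taxid), w$taxonomy))
})

test_that("realized completeness tracks the sampled target distribution", {
  seqs <- small_world_sequences()
  tet <- small_world_tetramers()
  set.seed(207)
  ids <- rep(names(seqs), length.out = 120)
  comps <- vapply(seq_along(ids), function(i)
    simulate_bin(ids[i], seqs, tet, fragment_length = 5000)$truth_completeness,
    numeric(1))
  # mean close to the 0.8 midpoint; range within quantization of one fragment
  q <- 5000 / 60000
  expect_lt(abs(mean(comps) - 0.8), 0.02 + q / 2)
  expect_gte(min(comps), 0.60 - q)
  expect_lte(max(comps), 1.0)
})
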