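# Shared fixtures, generated in code and memoized across test files.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# a small synthetic world for fast unit tests
small_world <- function() {
  memo("small_world", generate_synthetic_world(
    n_genomes = 12, n_core_families = 40, n_accessory_families = 80,
    genome_length = 60000, n_clades = 3, seed = 7))
}

small_world_db <- function() {
  memo("small_world_db", {
    w <- small_world()
    build_reference_db(lapply(w$genomes, `[[`, "profile"), world_metadata(w))
  })
}

small_world_sequences <- function() {
  memo("small_world_seqs", lapply(small_world()$genomes, `[[`, "sequence"))
}

small_world_tetramers <- function() {
  memo("small_world_tet", {
    seqs <- small_world_sequences()
    tet <- t(vapply(seqs, tetramer_profile, numeric(136)))
    rownames(tet) <- names(seqs)
    tet
  })
}

# annotated bin sets from disjoint genome halves of the small world,
# for stage-II training/validation unit tests
small_bins <- function(which_half = c("train", "valid"), n_per_genome = 6) {
  which_half <- match.arg(which_half)
  memo(paste0("small_bins_", which_half), {
    w <- small_world()
    seqs <- small_world_sequences()
    tet <- small_world_tetramers()
    ids <- names(seqs)[if (which_half == "train") c(1:3, 5:7, 9:10)
                       else c(4, 8, 11, 12)]
    set.seed(if (which_half == "train") 301 else 302)
    bins <- unlist(lapply(ids, function(g) {
      lapply(seq_len(n_per_genome), function(i)
        simulate_bin(g, seqs, tet, fragment_length = 5000,
                     bin_id = sprintf("%s_%s_b%02d", which_half, g, i)))
    }), recursive = FALSE)
    annotate_bins(bins, w$catalog)
  })
}

# a quick configuration for unit tests (smaller network, lower K)
quick_config <- function(...) {
  stage2_config(K = 3, c_max_comp = 4, c_max_cont = 4, hidden_units = 15,
                maxit = 200, seed = 5, ...)
}

# random sparse profile over <= max_families families
random_profile <- function(id, n_fam = 50, max_count = 5, p_present = 0.4) {
  fams <- sprintf("F%02d", seq_len(n_fam))
  present <- runif(n_fam) < p_present
  if (!any(present)) present[sample(n_fam, 1)] <- TRUE
  domain_profile(id, setNames(sample(max_count, sum(present), replace = TRUE),
                              fams[present]))
}

# brute-force oracle for the count-coincidence similarity: plain loop over
# the union of family ids, no set operations shared with the implementation
oracle_similarity <- function(q, r) {
  fams <- union(names(q$counts), names(r$counts))
  hits <- 0
  nq <- 0
  nr <- 0
  for (f in fams) {
    cq <- if (f %in% names(q$counts)) q$counts[[f]] else 0
    cr <- if (f %in% names(r$counts)) r$counts[[f]] else 0
    if (cq > 0) nq <- nq + 1
    if (cr > 0) nr <- nr + 1
    if (cq > 0 && cq == cr) hits <- hits + 1
  }
  hits / sqrt(nq * nr)
}

# brute-force oracle for dynamic marker extraction
oracle_markers <- function(neighbors) {
  fams <- sort(unique(unlist(lapply(neighbors, function(p) names(p$counts)))))
  out <- setNames(numeric(0), character(0))
  for (f in fams) {
    vals <- vapply(neighbors, function(p)
      if (f %in% names(p$counts)) p$counts[[f]] else 0, numeric(1))
    if (all(vals > 0) && length(unique(vals)) == 1) out[f] <- vals[1]
  }
  out
}

# brute-force oracle for the marker-based estimates
oracle_estimate <- function(q, markers) {
  M <- length(markers)
  cont <- 0
  total <- 0
  for (m in names(markers)) {
    cq <- if (m %in% names(q$counts)) q$counts[[m]] else 0
    ratio <- cq / markers[[m]]
    total <- total + ratio
    if (ratio > 1) cont <- cont + (ratio - 1)
  }
  list(cont = cont / M, comp = total / M - cont / M)
}

# simple uniform random DNA
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
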