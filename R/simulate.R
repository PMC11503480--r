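#' Canonical tetranucleotide frequency profile
#'
#' Counts all 4-mer windows of a sequence, mapping each window to the
#' lexicographically smaller of itself and its reverse complement (136
#' canonical 4-mers). Windows containing characters outside ACGT are
#' skipped. Counts are normalized to frequencies. The tetramer profile is a
#' compositional genome signature: genomes that could plausibly end up in
#' the same metagenomic bin have similar signatures.
#'
#' @param sequence a nucleotide string of length >= 4 (case insensitive), or
#'   a character vector of contigs (windows never span contigs).
#' @return Named numeric vector of length 136 summing to 1.
#' @export
tetramer_profile <- function(sequence) {
  if (all(nchar(sequence) < 4)) stop("sequence shorter than 4 nt")
  seqs <- gsub("[^ACGT]", "N", toupper(sequence))
  seqs <- seqs[nchar(seqs) >= 4]
  counts <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = 4))
  canon <- canonical_4mers()
  folded <- stats::setNames(numeric(length(canon$levels)), canon$levels)
  agg <- tapply(counts, canon$map[names(counts)], sum)
  folded[names(agg)] <- agg
  total <- sum(folded)
  if (total == 0) stop("no valid ACGT 4-mer window in sequence")
  folded / total
}

canonical_4mers <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bases <- c("A", "C", "G", "T")
    kmers <- apply(expand.grid(bases, bases, bases, bases)[, 4:1], 1, paste,
                   collapse = "")
    rc <- revcomp(kmers)
    map <- stats::setNames(pmin(kmers, rc), kmers)
    cache <<- list(map = map, levels = sort(unique(map)))
    cache
  }
})

#' Cut a sequence into fixed-length fragments
#'
#' Consecutive non-overlapping windows from the start of the sequence. A
#' trailing remainder is kept as a shorter final fragment when it is at
#' least 25% of the fragment length (avoiding tiny contigs while limiting
#' the bias from discarded sequence), otherwise it is dropped.
#'
#' @param sequence a nonempty nucleotide string.
#' @param fragment_length window size in bp (>= 1).
#' @return Character vector of fragments.
#' @export
fragment_genome <- function(sequence, fragment_length) {
  L <- nchar(sequence)
  if (length(sequence) != 1 || L == 0) stop("need one nonempty sequence")
  if (fragment_length < 1) stop("fragment_length must be >= 1")
  n_full <- L %/% fragment_length
  tail_len <- L - n_full * fragment_length
  starts <- seq_len(n_full) * fragment_length - fragment_length + 1
  frags <- substring(sequence, starts, starts + fragment_length - 1)
  if (tail_len >= 0.25 * fragment_length)
    frags <- c(frags, substring(sequence, n_full * fragment_length + 1, L))
  frags
}

#' Order eligible contaminant genomes for a query
#'
#' A genome is an eligible contaminant if the Bray-Curtis similarity of its
#' tetramer profile to the query's is at least `min_similarity` (default
#' 0.80), i.e. it has a genomic signature a real binner could confuse with
#' the query. Eligible genomes are returned in uniformly random order (from
#' the current RNG state); the simulator consumes them in this order until
#' the contamination target is met.
#'
#' @param query_id genome id of the query (excluded from the pool).
#' @param tetramers matrix of tetramer profiles, rows named by genome id.
#' @param min_similarity eligibility threshold.
#' @return Character vector of genome ids (random order).
#' @export
select_contaminants <- function(query_id, tetramers, min_similarity = 0.80) {
  pool <- setdiff(rownames(tetramers), query_id)
  if (length(pool) == 0) stop("empty contaminant pool")
  sims <- vapply(pool, function(g)
    bray_curtis_similarity(tetramers[query_id, ], tetramers[g, ]), numeric(1))
  eligible <- pool[sims >= min_similarity]
  if (length(eligible) == 0)
    stop(sprintf(paste0("no genome within tetramer similarity %.2f of '%s'; ",
                        "query unusable for contaminated bins"),
                 min_similarity, query_id))
  sample(eligible)
}

#' Simulate one genome bin with known ground truth
#'
#' Emulates the outcome of metagenomic binning: completeness and
#' contamination targets are drawn uniformly from `comp_range` and
#' `cont_range`, the query genome is fragmented and a matching number of its
#' fragments is sampled without replacement, and contaminant fragments are
#' drawn from signature-similar genomes (consumed in the order produced by
#' [select_contaminants()], fragments shuffled without replacement within
#' each genome) until the contamination target — expressed relative to the
#' complete query genome length — is met. The recorded truth values are the
#' REALIZED (fragment-quantized) fractions, so downstream evaluation is
#' exact.
#'
#' With `fragment_length = 0` the native contigs of each genome are used
#' unfragmented (for multi-contig inputs), and the contamination target is
#' met by accumulating whole contigs.
#'
#' @param query_id genome id of the query.
#' @param sequences named list of genomes; each element is a character
#'   vector of one or more contigs.
#' @param tetramers precomputed tetramer profile matrix (see
#'   [select_contaminants()]); computed on the fly when `NULL`.
#' @param fragment_length fragment size in bp, or 0 for native contigs.
#' @param comp_range,cont_range sampling ranges for the target completeness
#'   and contamination.
#' @param min_similarity contaminant eligibility threshold.
#' @param bin_id identifier for the bin.
#' @return An object of class `simulated_bin`: `contigs` (named
#'   `binID|src=genome|frag=i`), `truth_completeness`,
#'   `truth_contamination`, `source_genome`, `contaminant_ids`,
#'   `fragment_length`, `query_length`.
#' @export
simulate_bin <- function(query_id, sequences, tetramers = NULL,
                         fragment_length = 20000,
                         comp_range = c(0.60, 1.00),
                         cont_range = c(0.0, 0.30),
                         min_similarity = 0.80,
                         bin_id = paste0(query_id, "_bin")) {
  if (!query_id %in% names(sequences)) stop("query genome not in sequence set")
  if (is.null(tetramers)) {
    tetramers <- t(vapply(sequences, tetramer_profile, numeric(136)))
    rownames(tetramers) <- names(sequences)
  }
  comp_target <- stats::runif(1, comp_range[1], comp_range[2])
  cont_target <- stats::runif(1, cont_range[1], cont_range[2])
  qlen <- sum(nchar(sequences[[query_id]]))

  frags_of <- function(id) {
    contigs <- sequences[[id]]
    if (fragment_length == 0) return(contigs)
    unlist(lapply(contigs, fragment_genome, fragment_length = fragment_length))
  }

  qfrags <- frags_of(query_id)
  n_q <- max(1L, round(comp_target * length(qfrags)))
  q_take <- sort(sample(length(qfrags), n_q))
  contigs <- stats::setNames(
    qfrags[q_take],
    sprintf("%s|src=%s|frag=%d", bin_id, query_id, q_take))

  contaminant_ids <- character(0)
  if (cont_target > 0) {
    if (fragment_length > 0) {
      n_c <- round(cont_target * qlen / fragment_length)
    } else {
      n_c <- NA_integer_  # native mode: accumulate contigs up to target bp
    }
    target_bp <- cont_target * qlen
    need <- function(got_n, got_bp) {
      if (fragment_length > 0) got_n < n_c else got_bp < target_bp
    }
    if ((fragment_length > 0 && n_c > 0) || fragment_length == 0) {
      order_ids <- select_contaminants(query_id, tetramers, min_similarity)
      got_n <- 0L; got_bp <- 0
      for (cid in order_ids) {
        if (!need(got_n, got_bp)) break
        cf <- sample(frags_of(cid))
        for (k in seq_along(cf)) {
          if (!need(got_n, got_bp)) break
          got_n <- got_n + 1L
          got_bp <- got_bp + nchar(cf[k])
          contigs <- c(contigs, stats::setNames(
            cf[k], sprintf("%s|src=%s|frag=%d", bin_id, cid, k)))
          if (!cid %in% contaminant_ids)
            contaminant_ids <- c(contaminant_ids, cid)
        }
      }
      if (need(got_n, got_bp))
        stop(sprintf("contamination %.3f unrealizable for '%s': eligible pool exhausted",
                     cont_target, query_id))
    }
  }

  src <- sub(".*\\|src=([^|]+)\\|.*", "\\1", names(contigs))
  query_bp <- sum(nchar(contigs[src == query_id]))
  cont_bp <- sum(nchar(contigs[src != query_id]))
  structure(list(bin_id = bin_id,
                 contigs = contigs,
                 truth_completeness = query_bp / qlen,
                 truth_contamination = cont_bp / qlen,
                 source_genome = query_id,
                 contaminant_ids = contaminant_ids,
                 fragment_length = fragment_length,
                 query_length = qlen),
            class = "simulated_bin")
}

#' @export
#' @method print simulated_bin
print.simulated_bin <- function(x, ...) {
  cat(sprintf("<simulated_bin> %s: %d contigs, comp %.3f, cont %.3f (%d contaminants)\n",
              x$bin_id, length(x$contigs), x$truth_completeness,
              x$truth_contamination, length(x$contaminant_ids)))
  invisible(x)
}

#' Write simulated bins as FASTA plus a manifest
#'
#' One FASTA per bin (headers `binID|src=genomeID|frag=i`) and a manifest
#' TSV with columns bin_id, truth_completeness, truth_contamination, source,
#' contaminants (comma separated), fragment_length, query_length, seed.
#'
#' @param bins list of `simulated_bin`.
#' @param dir output directory.
#' @param seed the seed the bins were generated under (bookkeeping only).
#' @return `dir`, invisibly.
#' @export
write_bins <- function(bins, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in bins) write_fasta(b$contigs, file.path(dir, paste0(b$bin_id, ".fasta")))
  manifest <- do.call(rbind, lapply(bins, function(b) data.frame(
    bin_id = b$bin_id,
    truth_completeness = b$truth_completeness,
    truth_contamination = b$truth_contamination,
    source = b$source_genome,
    contaminants = paste(b$contaminant_ids, collapse = ","),
    fragment_length = b$fragment_length,
    query_length = b$query_length,
    seed = seed, stringsAsFactors = FALSE)))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate a synthetic domain world
#'
#' Builds a self-contained stand-in for a real reference corpus: a catalog
#' of protein families represented by distinct nucleotide tokens, and a set
#' of genomes organized in clades. Each clade has its own base profile
#' (core families single-copy; a clade-specific subset of accessory
#' families at counts 1-3) and its own nucleotide composition (GC content),
#' so that profile similarity and tetramer-signature similarity are both
#' higher within clades than across them. Per-genome noise perturbs the
#' clade profile: a core family stays single-copy with probability 0.99
#' (otherwise lost or duplicated), and each accessory count moves by +/-1
#' with probability 0.2 (keeping dereplicated same-clade genomes roughly 10
#' to 20% apart in Bray-Curtis profile distance, as in a dereplicated
#' reference corpus). Token copies are planted at non-overlapping random
#' positions on random background, so [toy_annotate()] recovers each
#' genome's stored profile exactly. Release dates are assigned within each
#' clade across three windows (before 2021-01-01, 2021-01-01 to 2022-06-01,
#' after) so a date-based split keeps every clade represented in every
#' part.
#'
#' @param n_genomes number of genomes.
#' @param n_core_families families intended as near-universal single-copy.
#' @param n_accessory_families clade-variable families.
#' @param genome_length genome size in bp.
#' @param n_clades number of clades.
#' @param token_length token size in nt (>= 20).
#' @param seed RNG seed; a fixed seed yields a byte-identical world.
#' @return An object of class `synthetic_world`: `catalog`, `genomes`
#'   (list of `genome_id`, `sequence`, `profile`, `superkingdom`, `taxid`,
#'   `release_date`, `clade`), `taxonomy` (parent map), `params`.
#' @export
generate_synthetic_world <- function(n_genomes = 60,
                                     n_core_families = 150,
                                     n_accessory_families = 300,
                                     genome_length = 300000,
                                     n_clades = 6,
                                     token_length = 25,
                                     seed = 42) {
  if (token_length < 20) stop("tokens must be at least 20 nt")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_fam <- n_core_families + n_accessory_families
  fam_ids <- c(sprintf("CORE%04d", seq_len(n_core_families)),
               sprintf("ACC%04d", seq_len(n_accessory_families)))
  repeat {
    toks <- apply(matrix(sample(bases, n_fam * token_length, replace = TRUE),
                         nrow = n_fam), 1, paste, collapse = "")
    if (!anyDuplicated(c(toks, revcomp(toks)))) break
  }
  catalog <- stats::setNames(toks, fam_ids)
  core <- fam_ids[seq_len(n_core_families)]
  accessory <- setdiff(fam_ids, core)

  clade_of <- rep(seq_len(n_clades), length.out = n_genomes)
  clade_gc <- seq(0.35, 0.65, length.out = n_clades)
  clade_sk <- ifelse(seq_len(n_clades) %% 3 == 0, "archaea", "bacteria")
  clade_base <- lapply(seq_len(n_clades), function(k) {
    acc <- stats::setNames(integer(length(accessory)), accessory)
    present <- stats::runif(length(accessory)) < 0.5
    acc[present] <- sample(1:3, sum(present), replace = TRUE,
                           prob = c(0.6, 0.3, 0.1))
    c(stats::setNames(rep(1L, length(core)), core), acc)
  })

  date_windows <- list(c("2020-01-01", "2020-12-01"),
                       c("2021-03-01", "2022-05-01"),
                       c("2022-08-01", "2023-06-01"))
  # within each clade: positions 1-4 -> oldest window, 5-7 middle, 8+ newest
  window_of <- function(pos) if (pos <= 4) 1 else if (pos <= 7) 2 else 3

  genomes <- vector("list", n_genomes)
  clade_pos <- integer(n_clades)
  for (i in seq_len(n_genomes)) {
    k <- clade_of[i]
    clade_pos[k] <- clade_pos[k] + 1L
    counts <- clade_base[[k]]
    # per-genome noise
    u <- stats::runif(length(core))
    counts[core][u > 0.99 & u <= 0.995] <- 0L
    counts[core][u > 0.995] <- 2L
    flip <- stats::runif(length(accessory)) < 0.2
    delta <- sample(c(-1L, 1L), sum(flip), replace = TRUE)
    counts[accessory][flip] <- pmin(3L, pmax(0L, counts[accessory][flip] + delta))
    counts <- counts[counts > 0]

    gc <- clade_gc[k]
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    chars <- sample(bases, genome_length, replace = TRUE, prob = probs)
    n_copies <- sum(counts)
    if (n_copies * token_length > genome_length)
      stop("genome too short to host all planted tokens")
    # non-overlapping starts: nondecreasing offsets + forced spacing
    v <- sort(sample.int(genome_length - n_copies * token_length + 1,
                         n_copies, replace = TRUE))
    starts <- v + (seq_len(n_copies) - 1L) * token_length
    inst <- sample(rep(names(counts), counts))  # random token order along genome
    for (j in seq_len(n_copies)) {
      chars[starts[j]:(starts[j] + token_length - 1L)] <-
        strsplit(catalog[[inst[j]]], "")[[1]]
    }
    w <- window_of(clade_pos[k])
    lo <- as.Date(date_windows[[w]][1]); hi <- as.Date(date_windows[[w]][2])
    gid <- sprintf("G%03d", i)
    genomes[[i]] <- list(
      genome_id = gid,
      sequence = paste(chars, collapse = ""),
      profile = domain_profile(gid, counts),
      superkingdom = clade_sk[k],
      taxid = 100L + i,
      release_date = lo + sample.int(as.integer(hi - lo), 1),
      clade = k)
  }
  names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")

  taxonomy <- c("1" = 1L, "2" = 1L, "3" = 1L)
  for (k in seq_len(n_clades))
    taxonomy[as.character(10L + k)] <- if (clade_sk[k] == "archaea") 3L else 2L
  for (i in seq_len(n_genomes))
    taxonomy[as.character(100L + i)] <- 10L + clade_of[i]

  structure(list(catalog = catalog, genomes = genomes, taxonomy = taxonomy,
                 params = list(n_genomes = n_genomes,
                               n_core_families = n_core_families,
                               n_accessory_families = n_accessory_families,
                               genome_length = genome_length,
                               n_clades = n_clades,
                               token_length = token_length, seed = seed)),
            class = "synthetic_world")
}

#' @export
#' @method print synthetic_world
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d genomes, %d families, %d clades, seed %d\n",
              length(x$genomes), length(x$catalog), x$params$n_clades,
              x$params$seed))
  invisible(x)
}

#' Metadata table of a synthetic world
#' @param world a `synthetic_world`.
#' @return data.frame with genome_id, superkingdom, taxid, release_date, clade.
#' @export
world_metadata <- function(world) {
  do.call(rbind, lapply(world$genomes, function(g) data.frame(
    genome_id = g$genome_id, superkingdom = g$superkingdom,
    taxid = g$taxid, release_date = g$release_date, clade = g$clade,
    stringsAsFactors = FALSE)))
}
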