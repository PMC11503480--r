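#' Protein-domain count profiles
#'
#' A domain profile is a sparse map from protein-family identifier to a
#' positive integer copy number, together with the genome (or bin) identifier
#' it was computed from. Zero counts are never stored: the support of the
#' profile is exactly the set of stored family ids. Profiles are the input to
#' nearest-neighbor search, marker extraction and the count-ratio-histogram
#' transform.
#'
#' @param genome_id single genome/bin identifier.
#' @param counts named numeric vector of positive integer counts; names are
#'   family ids. May be empty (a profile with no detected families).
#' @return An object of class `domain_profile` with elements `genome_id` and
#'   `counts` (named, sorted by family id).
#' @examples
#' p <- domain_profile("g1", c(PF1 = 2, PF2 = 1))
#' profile_support(p)
#' @export
domain_profile <- function(genome_id, counts = numeric(0)) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, !is.na(genome_id))
  counts <- unlist(counts)
  if (length(counts) > 0) {
    if (is.null(names(counts)) || anyNA(names(counts)) || any(names(counts) == ""))
      stop("profile counts must be named by family id")
    if (anyDuplicated(names(counts)))
      stop("duplicate family ids in profile counts")
    if (anyNA(counts) || any(counts < 1) || any(counts != round(counts)))
      stop("profile counts must be positive integers (zero counts are absent, not stored)")
    ord <- order(names(counts))
    counts <- stats::setNames(as.numeric(counts)[ord], names(counts)[ord])
  } else {
    counts <- stats::setNames(numeric(0), character(0))
  }
  structure(list(genome_id = genome_id, counts = counts),
            class = "domain_profile")
}

#' @export
#' @method print domain_profile
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile> %s: %d families, total count %d\n",
              x$genome_id, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Support (nonzero families) of a profile
#' @param p a `domain_profile`.
#' @return Character vector of family ids with nonzero count.
#' @export
profile_support <- function(p) names(p$counts)

#' Look up counts for given families, zero when absent
#' @param p a `domain_profile`.
#' @param families character vector of family ids.
#' @return Numeric vector of counts aligned with `families` (0 where absent).
#' @export
profile_counts <- function(p, families) {
  out <- p$counts[families]
  out[is.na(out)] <- 0
  stats::setNames(as.numeric(out), families)
}

#' Read domain profiles from a tab-separated table
#'
#' The table has a header `genome_id\tfamily_id\tcount`, one observation per
#' row. Rows sharing a `genome_id` are collected into one profile.
#'
#' @param path path to the TSV file.
#' @return List of `domain_profile`, one per distinct `genome_id`, in first
#'   order of appearance.
#' @export
read_profile_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  required <- c("genome_id", "family_id", "count")
  if (!all(required %in% names(tab)))
    stop("profile table must have columns genome_id, family_id, count")
  if (nrow(tab) == 0) return(list())
  cnt <- suppressWarnings(as.numeric(tab$count))
  bad <- which(is.na(cnt) | cnt != round(cnt))
  if (length(bad) > 0)
    stop(sprintf("malformed count %s at line %d of %s",
                 tab$count[bad[1]], bad[1] + 1L, path))
  nonpos <- which(cnt <= 0)
  if (length(nonpos) > 0)
    stop(sprintf("count must be a positive integer at line %d of %s (got %s)",
                 nonpos[1] + 1L, path, tab$count[nonpos[1]]))
  ids <- unique(tab$genome_id)
  lapply(ids, function(g) {
    rows <- tab$genome_id == g
    domain_profile(g, stats::setNames(cnt[rows], tab$family_id[rows]))
  })
}

#' Write domain profiles to a tab-separated table
#' @param profiles list of `domain_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    if (length(p$counts) == 0) return(NULL)
    data.frame(genome_id = p$genome_id, family_id = names(p$counts),
               count = as.integer(p$counts), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(data.frame(genome_id = character(0),
                                                family_id = character(0),
                                                count = integer(0)))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate sequences by exact token matching
#'
#' A deliberately simple annotation backend used for testing the pipeline end
#' to end: every protein family is represented by a distinct nucleotide token
#' (>= 20 nt) and the count of a family is the number of (possibly
#' overlapping) occurrences of its token on either strand across all
#' sequences. This mirrors the contract of a real domain annotator (a profile
#' whose support is a subset of the catalog's families) without translated
#' ORF search.
#'
#' A token identical to its own reverse complement is counted once per
#' genomic occurrence, not once per strand.
#'
#' @param sequences character vector of nucleotide sequences (case
#'   insensitive; characters outside ACGT never match).
#' @param catalog named character vector mapping family id to token.
#' @param genome_id identifier for the resulting profile.
#' @return A `domain_profile`; families with zero matches are absent.
#' @export
toy_annotate <- function(sequences, catalog, genome_id = "query") {
  if (length(catalog) == 0) stop("empty annotation catalog")
  if (is.null(names(catalog)) || anyDuplicated(names(catalog)))
    stop("catalog must be uniquely named by family id")
  if (anyDuplicated(toupper(catalog)))
    stop("duplicate tokens in catalog")
  if (any(nchar(catalog) < 20))
    stop("catalog tokens must be at least 20 nt")
  seqs <- gsub("[^ACGT]", "N", toupper(sequences))
  subject <- Biostrings::DNAStringSet(seqs)
  toks <- toupper(unname(unlist(catalog)))
  rcs <- revcomp(toks)
  palindrome <- toks == rcs
  counts <- if (length(unique(nchar(toks))) == 1) {
    # constant-width catalog: one Aho-Corasick pass for all patterns
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(c(toks, rcs)))
    hits <- rowSums(Biostrings::vcountPDict(pd, subject))
    fwd <- hits[seq_along(toks)]
    rev <- hits[length(toks) + seq_along(toks)]
    ifelse(palindrome, fwd, fwd + rev)
  } else {
    vapply(seq_along(toks), function(i) {
      fwd <- sum(Biostrings::vcountPattern(toks[i], subject))
      if (palindrome[i]) return(fwd)
      fwd + sum(Biostrings::vcountPattern(rcs[i], subject))
    }, numeric(1))
  }
  names(counts) <- names(catalog)
  domain_profile(genome_id, counts[counts > 0])
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Bray-Curtis similarity between two nonnegative vectors
#'
#' `1 - sum(|x - y|) / sum(x + y)`. Symmetric, 1 iff `x == y`, 0 for vectors
#' with disjoint support. Used both for profile dereplication (as a
#' dissimilarity) and for the tetranucleotide-signature constraint on
#' simulated contaminants.
#'
#' @param x,y nonnegative numeric vectors of equal length, not both all-zero.
#' @return Similarity in `[0, 1]`.
#' @examples
#' bray_curtis_similarity(c(1, 0), c(0.5, 0.5))  # 0.5
#' @export
bray_curtis_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have the same dimension")
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0))
    stop("vectors must be nonnegative and free of NA")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  1 - sum(abs(x - y)) / tot
}

#' Bray-Curtis dissimilarity matrix between profiles
#'
#' Profiles are first converted to relative frequencies over the union of
#' their supports, so genomes of different sizes are comparable.
#'
#' @param profiles list of `domain_profile`.
#' @return A symmetric matrix of dissimilarities with genome ids as dimnames.
#' @export
profile_dissimilarity_matrix <- function(profiles) {
  if (length(profiles) == 0) stop("no profiles given")
  fams <- sort(unique(unlist(lapply(profiles, profile_support))))
  mat <- t(vapply(profiles, function(p) {
    v <- profile_counts(p, fams)
    s <- sum(v)
    if (s > 0) v / s else v
  }, numeric(length(fams))))
  rownames(mat) <- vapply(profiles, function(p) p$genome_id, character(1))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- 1 - bray_curtis_similarity(mat[i, ], mat[j, ])
      }
    }
  }
  d
}

#' Read sequences from a FASTA file
#' @param path FASTA file (single-line or wrapped).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}
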