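#' Dereplicate profiles by agglomerative clustering
#'
#' Profiles are converted to relative frequencies, compared with Bray-Curtis
#' dissimilarity, clustered with average linkage, and the tree is cut at the
#' given dissimilarity threshold, so two representatives are never closer
#' than the threshold. The representative of each cluster is its medoid (the
#' member with the smallest summed dissimilarity to the rest of the cluster);
#' ties go to the lexicographically smallest genome id, making the whole
#' operation deterministic.
#'
#' @param profiles list of `domain_profile` (at least one).
#' @param dissimilarity_threshold cut height in (0, 1); default 0.10.
#' @return A list of class `cluster_assignment` with `labels` (named integer
#'   vector genome_id -> cluster index) and `representatives` (named character
#'   vector cluster index -> genome_id).
#' @export
cluster_profiles <- function(profiles, dissimilarity_threshold = 0.10) {
  if (length(profiles) == 0) stop("cannot cluster an empty profile set")
  if (dissimilarity_threshold <= 0 || dissimilarity_threshold >= 1)
    stop("dissimilarity threshold must lie in (0, 1)")
  ids <- vapply(profiles, function(p) p$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids among profiles")
  if (length(profiles) == 1) {
    return(structure(list(labels = stats::setNames(1L, ids),
                          representatives = stats::setNames(ids, "1")),
                     class = "cluster_assignment"))
  }
  d <- profile_dissimilarity_matrix(profiles)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # heavy distance ties can leave float jitter in the merge heights
  hc$height <- round(hc$height, 10)
  labels <- stats::cutree(hc, h = dissimilarity_threshold)
  reps <- vapply(sort(unique(labels)), function(k) {
    members <- names(labels)[labels == k]
    if (length(members) == 1) return(members)
    sums <- rowSums(d[members, members, drop = FALSE])
    members[order(sums, members)][1]
  }, character(1))
  structure(list(labels = labels,
                 representatives = stats::setNames(reps, sort(unique(labels)))),
            class = "cluster_assignment")
}

#' Universal single-copy marker discovery
#'
#' A family is a universal marker for a superkingdom if it occurs exactly
#' once in at least `coverage` (default 95%) of that superkingdom's cluster
#' representatives.
#'
#' @param representatives list of `reference_entry` (see [reference_entry()]).
#' @param superkingdom `"bacteria"` or `"archaea"`.
#' @param coverage required fraction of representatives with count exactly 1.
#' @return Sorted character vector of marker family ids.
#' @export
find_universal_markers <- function(representatives, superkingdom,
                                   coverage = 0.95) {
  sk <- match.arg(superkingdom, c("bacteria", "archaea"))
  reps <- Filter(function(e) e$superkingdom == sk, representatives)
  if (length(reps) == 0)
    stop(sprintf("no representatives for superkingdom '%s'", sk))
  fams <- sort(unique(unlist(lapply(reps, function(e) profile_support(e$profile)))))
  n <- length(reps)
  single <- vapply(fams, function(f) {
    sum(vapply(reps, function(e) profile_counts(e$profile, f) == 1, logical(1)))
  }, numeric(1))
  sort(fams[single / n >= coverage])
}

#' Marker-presence completeness
#'
#' Fraction of a marker set detected (count >= 1) in a query profile. This is
#' the quick presence-based completeness used to prefilter queries and to
#' drop suspect reference genomes during database construction.
#'
#' @param q a `domain_profile`.
#' @param markers nonempty character vector of marker family ids.
#' @return Fraction in `[0, 1]`.
#' @export
marker_presence_completeness <- function(q, markers) {
  if (length(markers) == 0) stop("empty marker set")
  mean(profile_counts(q, markers) >= 1)
}

#' Reference entry: profile plus metadata
#' @param profile a `domain_profile`.
#' @param superkingdom `"bacteria"` or `"archaea"`.
#' @param taxid optional integer NCBI-style taxon id.
#' @param release_date optional `Date` (or string coercible to one).
#' @return An object of class `reference_entry`.
#' @export
reference_entry <- function(profile, superkingdom, taxid = NA_integer_,
                            release_date = NA) {
  sk <- match.arg(superkingdom, c("bacteria", "archaea"))
  structure(list(profile = profile, superkingdom = sk,
                 taxid = as.integer(taxid),
                 release_date = if (all(is.na(release_date))) as.Date(NA)
                                else as.Date(release_date)),
            class = "reference_entry")
}

#' Build the reference database
#'
#' Multistage filtering: (1) dereplicate all input profiles by agglomerative
#' clustering; (2) discover universal single-copy markers per superkingdom on
#' the representatives; (3) drop genomes whose marker-presence completeness
#' against their own superkingdom's markers falls below `min_completeness`
#' (guarding against mislabelled incomplete genomes); (4) re-cluster the
#' survivors with the same settings. The final representatives become the
#' database entries; the marker sets from step (2) are retained for
#' prefiltering queries.
#'
#' @param profiles list of `domain_profile`.
#' @param metadata data.frame with columns `genome_id`, `superkingdom`, and
#'   optionally `taxid` and `release_date` (ISO-8601).
#' @param dissimilarity_threshold clustering cut height (both rounds).
#' @param coverage marker coverage criterion.
#' @param min_completeness completeness cutoff for stage (3).
#' @return An object of class `reference_db`: `entries` (named list of
#'   `reference_entry`), `universal_markers` (list per superkingdom),
#'   `build_params`, and per-stage `diagnostics` counts.
#' @export
build_reference_db <- function(profiles, metadata,
                               dissimilarity_threshold = 0.10,
                               coverage = 0.95,
                               min_completeness = 0.95) {
  stopifnot(all(c("genome_id", "superkingdom") %in% names(metadata)))
  ids <- vapply(profiles, function(p) p$genome_id, character(1))
  if (!all(ids %in% metadata$genome_id))
    stop("metadata missing for some genome ids")
  meta <- metadata[match(ids, metadata$genome_id), , drop = FALSE]
  entry_of <- function(i) {
    reference_entry(profiles[[i]], meta$superkingdom[i],
                    if ("taxid" %in% names(meta)) meta$taxid[i] else NA,
                    if ("release_date" %in% names(meta)) meta$release_date[i] else NA)
  }
  entries_all <- stats::setNames(lapply(seq_along(profiles), entry_of), ids)

  # (1) first dereplication round
  cl1 <- cluster_profiles(profiles, dissimilarity_threshold)
  rep_ids <- unname(cl1$representatives)
  reps <- entries_all[rep_ids]

  # (2) universal markers per superkingdom present among representatives
  sks <- unique(vapply(reps, function(e) e$superkingdom, character(1)))
  markers <- lapply(stats::setNames(sks, sks), function(sk)
    find_universal_markers(reps, sk, coverage))

  # (3) completeness filter on ALL input genomes against their own kingdom
  keep <- vapply(seq_along(profiles), function(i) {
    sk <- meta$superkingdom[i]
    if (!sk %in% names(markers) || length(markers[[sk]]) == 0) return(FALSE)
    marker_presence_completeness(profiles[[i]], markers[[sk]]) >= min_completeness
  }, logical(1))
  survivors <- profiles[keep]
  if (length(survivors) == 0)
    stop(sprintf(paste0("all genomes filtered out (input %d, representatives %d, ",
                        "passing completeness filter 0)"),
                 length(profiles), length(rep_ids)))

  # (4) re-cluster survivors; final representatives are the database entries
  cl2 <- cluster_profiles(survivors, dissimilarity_threshold)
  final_ids <- unname(cl2$representatives)
  structure(list(
    entries = entries_all[final_ids],
    universal_markers = markers,
    build_params = list(dissimilarity_threshold = dissimilarity_threshold,
                        coverage = coverage,
                        min_completeness = min_completeness),
    diagnostics = list(n_input = length(profiles),
                       n_first_representatives = length(rep_ids),
                       n_completeness_pass = sum(keep),
                       n_entries = length(final_ids))),
    class = "reference_db")
}

#' @export
#' @method print reference_db
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d entries; markers: %s\n",
              length(x$entries),
              paste(sprintf("%s=%d", names(x$universal_markers),
                            lengths(x$universal_markers)), collapse = ", ")))
  invisible(x)
}

#' Serialize a reference database to a directory
#'
#' Writes `profiles.tsv`, `metadata.tsv` (genome_id, superkingdom, taxid,
#' release_date ISO-8601), `markers.tsv` (superkingdom, family_id) and
#' `params.json`.
#'
#' @param db a `reference_db`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_profile_table(lapply(db$entries, `[[`, "profile"),
                      file.path(dir, "profiles.tsv"))
  meta <- data.frame(
    genome_id = names(db$entries),
    superkingdom = vapply(db$entries, `[[`, character(1), "superkingdom"),
    taxid = vapply(db$entries, `[[`, integer(1), "taxid"),
    release_date = vapply(db$entries, function(e)
      if (is.na(e$release_date)) "" else format(e$release_date, "%Y-%m-%d"),
      character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mk <- do.call(rbind, lapply(names(db$universal_markers), function(sk)
    if (length(db$universal_markers[[sk]]) == 0) NULL else
      data.frame(superkingdom = sk, family_id = db$universal_markers[[sk]],
                 stringsAsFactors = FALSE)))
  if (is.null(mk))
    mk <- data.frame(superkingdom = character(0), family_id = character(0))
  utils::write.table(mk, file.path(dir, "markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(db$build_params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a reference database written by [write_reference_db()]
#' @param dir database directory.
#' @return A `reference_db`.
#' @export
read_reference_db <- function(dir) {
  profiles <- read_profile_table(file.path(dir, "profiles.tsv"))
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"), sep = "\t",
                            colClasses = "character", quote = "")
  ids <- vapply(profiles, function(p) p$genome_id, character(1))
  meta <- meta[match(ids, meta$genome_id), , drop = FALSE]
  entries <- stats::setNames(lapply(seq_along(profiles), function(i) {
    reference_entry(profiles[[i]], meta$superkingdom[i],
                    if (meta$taxid[i] %in% c("", "NA")) NA else as.integer(meta$taxid[i]),
                    if (meta$release_date[i] == "") NA else meta$release_date[i])
  }), ids)
  mk <- utils::read.delim(file.path(dir, "markers.tsv"), sep = "\t",
                          colClasses = "character", quote = "")
  markers <- lapply(split(mk$family_id, mk$superkingdom), sort)
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  structure(list(entries = entries, universal_markers = markers,
                 build_params = params, diagnostics = NULL),
            class = "reference_db")
}

#' Construct a reference database directly from entries (no filtering)
#'
#' Convenience constructor used when the entries and marker sets are already
#' known (for example, in tests and for the part-1 split of an evaluation
#' run, where the database build is carried out explicitly beforehand).
#'
#' @param entries named list of `reference_entry`.
#' @param universal_markers list mapping superkingdom to marker family ids.
#' @param build_params optional list of build parameters.
#' @return A `reference_db`.
#' @export
reference_db <- function(entries, universal_markers, build_params = list()) {
  ids <- vapply(entries, function(e) e$profile$genome_id, character(1))
  names(entries) <- ids
  structure(list(entries = entries, universal_markers = universal_markers,
                 build_params = build_params, diagnostics = NULL),
            class = "reference_db")
}
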