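#' Count-coincidence profile similarity
#'
#' The number of families with identical nonzero counts in the query and the
#' reference, normalized by the geometric mean of the two support sizes:
#' `|{i : C_q(i) = C_r(i) > 0}| / sqrt(|supp(r)| * |supp(q)|)`. Requiring
#' exact equality means mostly small counts contribute, which keeps the
#' measure robust against count inflation by contaminants.
#'
#' @param q,r `domain_profile`s with nonempty support.
#' @return Similarity in `[0, 1]`; 1 iff the profiles are identical.
#' @export
profile_similarity <- function(q, r) {
  if (length(q$counts) == 0 || length(r$counts) == 0)
    stop("profile similarity undefined for an empty profile")
  shared <- intersect(names(q$counts), names(r$counts))
  hits <- sum(q$counts[shared] == r$counts[shared])
  hits / sqrt(length(r$counts) * length(q$counts))
}

#' K-nearest reference profiles
#'
#' Ranks all database entries by [profile_similarity()] to the query and
#' returns the top `K`; ties are broken by genome id ascending so results are
#' deterministic. If the database holds fewer than `K` entries, all are
#' returned with a warning.
#'
#' @param q a `domain_profile`.
#' @param db a `reference_db`.
#' @param K neighborhood size (>= 1).
#' @return data.frame with columns `genome_id` and `similarity`, ordered by
#'   decreasing similarity.
#' @export
knn_search <- function(q, db, K = 9) {
  if (K < 1) stop("K must be at least 1")
  if (length(db$entries) == 0) stop("empty reference database")
  ids <- names(db$entries)
  sims <- vapply(db$entries, function(e) profile_similarity(q, e$profile),
                 numeric(1))
  ord <- order(-sims, ids)
  if (length(ids) < K) {
    warning(sprintf("database has only %d entries; K reduced from %d",
                    length(ids), K))
    K <- length(ids)
  }
  top <- ord[seq_len(K)]
  data.frame(genome_id = ids[top], similarity = unname(sims[top]),
             stringsAsFactors = FALSE)
}

#' Query-specific marker extraction
#'
#' The dynamic marker set of a query is the set of families with equal
#' nonzero counts across all K nearest reference profiles, together with that
#' agreed count. Markers are not restricted to single-copy families.
#'
#' @param neighbors list of `domain_profile` (the K nearest references).
#' @return Named numeric vector mapping marker family id to its agreed
#'   reference count; possibly empty.
#' @export
extract_markers <- function(neighbors) {
  if (length(neighbors) == 0) stop("need at least one neighbor profile")
  shared <- Reduce(intersect, lapply(neighbors, function(p) names(p$counts)))
  if (length(shared) == 0) return(stats::setNames(numeric(0), character(0)))
  counts <- vapply(neighbors, function(p) p$counts[shared],
                   numeric(length(shared)))
  counts <- matrix(counts, nrow = length(shared))
  agree <- apply(counts, 1, function(x) all(x == x[1]))
  out <- stats::setNames(counts[agree, 1], shared[agree])
  out[order(names(out))]
}

#' Marker-based completeness and contamination
#'
#' Given the query counts `C_q(m)` and agreed reference counts `C_r(m)` over
#' `M` markers: contamination is the mean positive excess
#' `mean(max(C_q/C_r - 1, 0))` and completeness is `mean(C_q/C_r)` minus the
#' contamination. Marker families absent from the query contribute a count
#' of zero. The raw completeness can exceed 1 when query counts exceed the
#' reference asymmetrically; the reported value is clamped at 1 while the
#' unclamped value is kept for downstream feature construction.
#'
#' @param q a `domain_profile`.
#' @param markers named numeric vector from [extract_markers()]; must be
#'   nonempty.
#' @return List with `completeness` (clamped to `[0, 1]`),
#'   `completeness_raw`, `contamination` and `n_markers`.
#' @export
stage1_estimate <- function(q, markers) {
  if (length(markers) == 0)
    stop("no markers: stage I cannot estimate quality for this query",
         call. = FALSE)
  if (any(markers < 1)) stop("marker reference counts must be >= 1")
  cq <- profile_counts(q, names(markers))
  ratio <- cq / markers
  cont <- mean(pmax(ratio - 1, 0))
  comp_raw <- mean(ratio) - cont
  list(completeness = min(comp_raw, 1),
       completeness_raw = comp_raw,
       contamination = cont,
       n_markers = length(markers))
}

#' Prefilter a query by universal marker presence
#'
#' Nearest-neighbor search is unreliable for nearly empty inputs, so queries
#' whose presence-based completeness is below `threshold` (default 10%) for
#' BOTH superkingdom marker sets are rejected before any search.
#'
#' @param q a `domain_profile`.
#' @param db a `reference_db` carrying `universal_markers`.
#' @param threshold minimum presence fraction; default 0.10.
#' @return List with `status` (`"pass"` or `"rejected"`) and the per-set
#'   presence fractions.
#' @export
prefilter <- function(q, db, threshold = 0.10) {
  mk <- db$universal_markers
  mk <- mk[lengths(mk) > 0]
  if (length(mk) == 0)
    stop("reference database has no universal marker sets")
  pres <- vapply(mk, function(m) marker_presence_completeness(q, m), numeric(1))
  list(status = if (all(pres < threshold)) "rejected" else "pass",
       presence = pres)
}

#' Stage routing rule
#'
#' Stage II is trained only on the quality range completeness 60-100% /
#' contamination 0-30%. If the stage-I completeness is below 0.60 or the
#' stage-I contamination is above 0.30 (strict inequalities), the stage-I
#' estimates are reported as final; otherwise the query is routed to the
#' stage-II refinement.
#'
#' @param comp,cont stage-I estimates (fractions, >= 0).
#' @return `"final"` or `"refine"`.
#' @export
route <- function(comp, cont) {
  stopifnot(is.finite(comp), is.finite(cont), comp >= 0, cont >= 0)
  if (comp < 0.60 || cont > 0.30) "final" else "refine"
}

#' Full stage-I analysis of a query profile
#'
#' Runs prefilter, K-nearest-neighbor search, marker extraction and the
#' marker-based estimate, then applies the routing rule. Queries rejected by
#' the prefilter, or for which no markers can be extracted, are reported
#' with `route = "rejected"` and a machine-readable `reason` instead of
#' fabricated estimates.
#'
#' @param q a `domain_profile`.
#' @param db a `reference_db`.
#' @param K neighborhood size.
#' @param prefilter_threshold see [prefilter()].
#' @return An object of class `stage1_result`: `completeness`,
#'   `completeness_raw`, `contamination`, `neighbors` (data.frame),
#'   `n_markers`, `route` and (when rejected) `reason`.
#' @export
stage1_analyze <- function(q, db, K = 9, prefilter_threshold = 0.10) {
  pf <- prefilter(q, db, prefilter_threshold)
  if (pf$status == "rejected") {
    return(structure(list(completeness = NA_real_, completeness_raw = NA_real_,
                          contamination = NA_real_, neighbors = NULL,
                          n_markers = 0L, route = "rejected",
                          reason = "completeness below prefilter threshold",
                          presence = pf$presence),
                     class = "stage1_result"))
  }
  nb <- knn_search(q, db, K)
  markers <- extract_markers(lapply(db$entries[nb$genome_id], `[[`, "profile"))
  if (length(markers) == 0) {
    return(structure(list(completeness = NA_real_, completeness_raw = NA_real_,
                          contamination = NA_real_, neighbors = nb,
                          n_markers = 0L, route = "rejected",
                          reason = "no markers shared by the nearest neighbors",
                          presence = pf$presence),
                     class = "stage1_result"))
  }
  est <- stage1_estimate(q, markers)
  structure(list(completeness = est$completeness,
                 completeness_raw = est$completeness_raw,
                 contamination = est$contamination,
                 neighbors = nb,
                 n_markers = est$n_markers,
                 markers = markers,
                 route = route(est$completeness, est$contamination),
                 reason = NA_character_,
                 presence = pf$presence),
            class = "stage1_result")
}

#' @export
#' @method print stage1_result
print.stage1_result <- function(x, ...) {
  if (x$route == "rejected") {
    cat(sprintf("<stage1_result> rejected: %s\n", x$reason))
  } else {
    cat(sprintf("<stage1_result> comp %.3f, cont %.3f (%d markers, route %s)\n",
                x$completeness, x$contamination, x$n_markers, x$route))
  }
  invisible(x)
}

#' Lowest common ancestor in a rooted taxonomy
#'
#' @param neighbor_taxids integer vector of taxon ids (nonempty).
#' @param parents named vector mapping each taxid to its parent taxid; the
#'   root maps to itself.
#' @return The taxid of the deepest node ancestral to (or equal to) all
#'   neighbors.
#' @export
lca_taxonomy <- function(neighbor_taxids, parents) {
  if (length(neighbor_taxids) == 0) stop("no neighbor taxids given")
  path_to_root <- function(t) {
    key <- as.character(t)
    path <- t
    while (TRUE) {
      if (!key %in% names(parents)) stop(sprintf("unknown taxid %s", key))
      up <- parents[[key]]
      if (identical(as.character(up), key)) break
      path <- c(path, up)
      key <- as.character(up)
    }
    path
  }
  paths <- lapply(unique(neighbor_taxids), path_to_root)
  common <- Reduce(intersect, paths)
  if (length(common) == 0) stop("taxids share no common ancestor (forest?)")
  common[1]  # paths are ordered leaf -> root, so first common = deepest
}
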