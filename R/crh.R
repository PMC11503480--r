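#' Count-ratio-histogram bin centers
#'
#' The centers are the set of possible ratios `a/b` with `a, b` integers in
#' `1..c_max`, deduplicated exactly (so 2/4 and 1/2 coincide) and sorted
#' ascending. The set always contains 1 and is closed under reciprocals. For
#' `c_max = 4` the centers are 1/4, 1/3, 1/2, 2/3, 3/4, 1, 4/3, 3/2, 2, 3, 4.
#'
#' Centers are kept as exact reduced fractions (numerator/denominator pairs)
#' so that deduplication and the nearest-center assignment never rely on
#' floating-point comparisons.
#'
#' @param c_max histogram resolution (integer >= 1).
#' @return An object of class `bin_centers` with fields `c_max`, `num`,
#'   `den`, `value` (numeric centers) and `label` (e.g. `"3/4"`).
#' @examples
#' bin_centers(4)$value
#' @export
bin_centers <- function(c_max) {
  if (length(c_max) != 1 || is.na(c_max) || c_max < 1 || c_max != round(c_max))
    stop("c_max must be a single integer >= 1")
  c_max <- as.integer(c_max)
  grid <- expand.grid(a = seq_len(c_max), b = seq_len(c_max))
  g <- mapply(gcd_int, grid$a, grid$b)
  num <- grid$a / g
  den <- grid$b / g
  key <- paste(num, den)
  keep <- !duplicated(key)
  num <- num[keep]; den <- den[keep]
  ord <- order(num / den)
  num <- num[ord]; den <- den[ord]
  structure(list(c_max = c_max, num = num, den = den,
                 value = num / den,
                 label = ifelse(den == 1, as.character(num),
                                paste0(num, "/", den))),
            class = "bin_centers")
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' @export
#' @method print bin_centers
print.bin_centers <- function(x, ...) {
  cat(sprintf("<bin_centers> c_max=%d: %s\n", x$c_max,
              paste(x$label, collapse = ", ")))
  invisible(x)
}

# Exact nearest-center assignment for a vector of count pairs (cq, cr),
# cr > 0, ratio within (0, c_max]. Distances |cq/cr - n_j/d_j| are compared
# after scaling by cr * lcm(denominators), i.e. in exact integer arithmetic;
# ties go to the center closer to 1 (and the centers adjacent to a midpoint
# never straddle 1 at equal distance, so this is unambiguous).
nearest_center_index <- function(cq, cr, centers) {
  D <- Reduce(function(a, b) a * b / gcd_int(a, b), unique(centers$den))
  wj <- D / centers$den                      # integer weights
  tie_dist <- abs(centers$num - centers$den) * wj  # |center - 1| scaled by D
  vapply(seq_along(cq), function(i) {
    d <- abs(cq[i] * centers$den - centers$num * cr[i]) * wj  # scaled by cr*D
    cand <- which(d == min(d))
    if (length(cand) > 1) cand <- cand[which.min(tie_dist[cand])]
    cand[1]
  }, integer(1))
}

#' Count ratio histogram of a query against one reference
#'
#' For every family in the union of the two supports, the ratio
#' `C_q / C_r` is assigned to the nearest bin center. The two extreme bins
#' are overloaded: the left-most bin additionally collects families present
#' only in the reference (ratio 0), and the right-most bin collects families
#' with a ratio above `c_max` as well as families present only in the query.
#' Frequencies are the bin counts divided by the number of families
#' considered, so they always sum to 1.
#'
#' A histogram concentrated at center 1 indicates a complete, uncontaminated
#' query; mass on the left flank indicates missing families (incompleteness)
#' and mass on the right flank indicates excess counts (contamination).
#'
#' @param q a `domain_profile` (may be empty).
#' @param r a `domain_profile` with nonempty support.
#' @param c_max histogram resolution, or a prebuilt [bin_centers()] object.
#' @return An object of class `crh`: `c_max`, `centers`, `frequencies`
#'   (aligned with the centers, summing to 1) and `n_families`.
#' @export
compute_crh <- function(q, r, c_max) {
  centers <- if (inherits(c_max, "bin_centers")) c_max else bin_centers(c_max)
  if (length(r$counts) == 0) stop("empty reference profile")
  fams <- union(names(q$counts), names(r$counts))
  cq <- profile_counts(q, fams)
  cr <- profile_counts(r, fams)
  B <- length(centers$value)
  bins <- integer(length(fams))
  left <- cr > 0 & cq == 0
  right <- cr == 0 | (cr > 0 & cq > centers$c_max * cr)
  bins[left] <- 1L
  bins[right] <- B
  mid <- !(left | right)
  if (any(mid))
    bins[mid] <- nearest_center_index(cq[mid], cr[mid], centers)
  freq <- tabulate(bins, nbins = B) / length(fams)
  structure(list(c_max = centers$c_max, centers = centers,
                 frequencies = freq, n_families = length(fams)),
            class = "crh")
}

#' Mean CRH over the K nearest references
#'
#' Each per-neighbor histogram is normalized on its own and the histograms
#' are then averaged element-wise, so the mean still sums to 1.
#'
#' @param q a `domain_profile`.
#' @param neighbors nonempty list of `domain_profile`.
#' @param c_max histogram resolution, or a prebuilt [bin_centers()] object.
#' @return A `crh` whose `n_families` is the mean family count per
#'   comparison.
#' @export
mean_crh <- function(q, neighbors, c_max) {
  if (length(neighbors) == 0) stop("need at least one neighbor")
  centers <- if (inherits(c_max, "bin_centers")) c_max else bin_centers(c_max)
  crhs <- lapply(neighbors, function(r) compute_crh(q, r, centers))
  freq <- Reduce(`+`, lapply(crhs, `[[`, "frequencies")) / length(crhs)
  structure(list(c_max = centers$c_max, centers = centers,
                 frequencies = freq,
                 n_families = mean(vapply(crhs, `[[`, numeric(1), "n_families"))),
            class = "crh")
}

#' Assemble the stage-II feature vector
#'
#' Concatenates the mean CRH frequencies with the stage-I completeness and
#' contamination estimates (the unclamped completeness, so the learner sees
#' the full signal). The ordering is fixed: CRH bins ascending by center,
#' then `comp1`, then `cont1`; names follow the pattern `crh_<center>`.
#'
#' @param mean_crh a `crh` from [mean_crh()].
#' @param stage1 a `stage1_result` (route must not be `"rejected"`), or a
#'   list with elements `completeness_raw` and `contamination`.
#' @return Named numeric vector of length `|centers| + 2`.
#' @export
build_features <- function(mean_crh, stage1) {
  comp1 <- if (!is.null(stage1$completeness_raw)) stage1$completeness_raw
           else stage1$completeness
  cont1 <- stage1$contamination
  stopifnot(is.finite(comp1), is.finite(cont1))
  stats::setNames(c(mean_crh$frequencies, comp1, cont1),
                  c(paste0("crh_", mean_crh$centers$label), "comp1", "cont1"))
}
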