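#' Date-based three-way split
#'
#' Divides reference entries into three parts by release date using
#' half-open intervals: part 1 is `release < d1`, part 2 is
#' `d1 <= release < d2`, part 3 is `release >= d2`. Entries released exactly
#' on a split date therefore go to the later part. Splitting by date rather
#' than at random emulates how genuinely novel genomes relate to an existing
#' reference corpus.
#'
#' @param entries data.frame with `genome_id` and `release_date` columns, or
#'   a list of `reference_entry`.
#' @param d1,d2 split dates (`d1 < d2`).
#' @return An object of class `date_split` with character vectors `part1`,
#'   `part2`, `part3`.
#' @export
date_split <- function(entries, d1, d2) {
  d1 <- as.Date(d1); d2 <- as.Date(d2)
  if (!d1 < d2) stop("d1 must be earlier than d2")
  if (is.data.frame(entries)) {
    ids <- entries$genome_id
    dates <- as.Date(entries$release_date)
  } else {
    ids <- vapply(entries, function(e) e$profile$genome_id, character(1))
    dates <- as.Date(vapply(entries, function(e) as.character(e$release_date),
                            character(1)))
  }
  if (anyNA(dates)) stop("undated entries cannot be split by release date")
  structure(list(part1 = ids[dates < d1],
                 part2 = ids[dates >= d1 & dates < d2],
                 part3 = ids[dates >= d2]),
            class = "date_split")
}

#' @export
#' @method print date_split
print.date_split <- function(x, ...) {
  cat(sprintf("<date_split> part1=%d part2=%d part3=%d\n",
              length(x$part1), length(x$part2), length(x$part3)))
  invisible(x)
}

#' Prediction error metrics in percentage points
#'
#' @param truth,predicted numeric vectors of equal length (fractions).
#' @return List with `mae` (mean absolute error), `median_ae`, `sd_ae`
#'   (standard deviation of the absolute errors) and `signed` (per-item
#'   `predicted - truth`), all in percentage points; positive signed error
#'   means overestimation.
#' @export
error_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (length(truth) == 0) stop("empty vectors")
  signed <- (predicted - truth) * 100
  ae <- abs(signed)
  list(mae = mean(ae), median_ae = stats::median(ae),
       sd_ae = stats::sd(ae), signed = signed)
}

#' Evaluate the pipeline on a set of bins
#'
#' Runs the full prediction (stage I, routing, optional stage-II
#' refinement) on every bin and compares against the recorded ground truth.
#' Bins rejected at stage I are excluded from the error aggregates and
#' counted separately.
#'
#' @param bins bin list (with `profile` and truth fields).
#' @param db a `reference_db`.
#' @param model a `quality_model`, or `NULL` for stage-I-only evaluation.
#' @param config defaults to `model$config`.
#' @return List of class `evaluation_report`: `records` (per-bin
#'   data.frame), `stage1_mae_comp/cont`, `final_mae_comp/cont`,
#'   `final_median_comp/cont`, `n_rejected`.
#' @export
evaluate_bins <- function(bins, db, model = NULL,
                          config = if (!is.null(model)) model$config
                                   else stage2_config()) {
  recs <- lapply(bins, function(b) {
    pr <- predict_quality(b$profile, db, model, config)
    data.frame(bin_id = b$bin_id, source_genome = b$source_genome,
               truth_completeness = b$truth_completeness,
               truth_contamination = b$truth_contamination,
               comp_stage1 = pr$stage1$completeness,
               cont_stage1 = pr$stage1$contamination,
               completeness = pr$completeness,
               contamination = pr$contamination,
               stage = pr$stage, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  ok <- records$stage != "rejected"
  r <- records[ok, ]
  m_comp1 <- error_metrics(r$truth_completeness, r$comp_stage1)
  m_cont1 <- error_metrics(r$truth_contamination, r$cont_stage1)
  m_comp <- error_metrics(r$truth_completeness, r$completeness)
  m_cont <- error_metrics(r$truth_contamination, r$contamination)
  structure(list(records = records,
                 stage1_mae_comp = m_comp1$mae, stage1_mae_cont = m_cont1$mae,
                 final_mae_comp = m_comp$mae, final_mae_cont = m_cont$mae,
                 final_median_comp = m_comp$median_ae,
                 final_median_cont = m_cont$median_ae,
                 n_rejected = sum(!ok)),
            class = "evaluation_report")
}

#' @export
#' @method print evaluation_report
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> %d bins (%d rejected)\n",
                     "  stage I MAE: comp %.2f %%pt, cont %.2f %%pt\n",
                     "  final   MAE: comp %.2f %%pt, cont %.2f %%pt\n"),
              nrow(x$records), x$n_rejected,
              x$stage1_mae_comp, x$stage1_mae_cont,
              x$final_mae_comp, x$final_mae_cont))
  invisible(x)
}

#' Two-fold cross-validation over the two recent parts
#'
#' Fold A trains on the part-2 bins and validates on the part-3 bins; fold B
#' reverses the roles. The oldest part serves exclusively as the reference
#' database for the nearest-neighbor search of both folds. Reported MAEs are
#' per fold and averaged over the two validation folds. Bins in the two
#' parts must derive from disjoint genome sets.
#'
#' @param part2_bins,part3_bins bin lists (with `profile` and truths).
#' @param db reference database built from part 1.
#' @param config a [stage2_config()].
#' @return List with `folds` (per-fold `evaluation_report`s) and `averaged`
#'   (mean validation MAE for both indices, stage I and final).
#' @export
cross_validate_2fold <- function(part2_bins, part3_bins, db,
                                 config = stage2_config()) {
  src2 <- unique(vapply(part2_bins, `[[`, character(1), "source_genome"))
  src3 <- unique(vapply(part3_bins, `[[`, character(1), "source_genome"))
  if (length(intersect(src2, src3)) > 0)
    stop("leakage: the two folds share source genomes")
  run_fold <- function(train, valid) {
    model <- train_quality_model(train, db, config)
    evaluate_bins(valid, db, model, config)
  }
  foldA <- run_fold(part2_bins, part3_bins)
  foldB <- run_fold(part3_bins, part2_bins)
  list(folds = list(A = foldA, B = foldB),
       averaged = list(
         mae_comp = (foldA$final_mae_comp + foldB$final_mae_comp) / 2,
         mae_cont = (foldA$final_mae_cont + foldB$final_mae_cont) / 2,
         stage1_mae_comp = (foldA$stage1_mae_comp + foldB$stage1_mae_comp) / 2,
         stage1_mae_cont = (foldA$stage1_mae_cont + foldB$stage1_mae_cont) / 2))
}

#' Write an evaluation report as TSV plus JSON summary
#' @param report an `evaluation_report`.
#' @param path output TSV path; a `.json` summary is written alongside.
#' @param group_by optional column of `report$records` for per-group MAEs.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path, group_by = NULL) {
  utils::write.table(report$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(stage1_mae_comp = report$stage1_mae_comp,
                  stage1_mae_cont = report$stage1_mae_cont,
                  final_mae_comp = report$final_mae_comp,
                  final_mae_cont = report$final_mae_cont,
                  final_median_comp = report$final_median_comp,
                  final_median_cont = report$final_median_cont,
                  n_rejected = report$n_rejected)
  if (!is.null(group_by)) {
    ok <- report$records$stage != "rejected"
    groups <- split(report$records[ok, ], report$records[[group_by]][ok])
    summary$groups <- lapply(groups, function(g) list(
      n = nrow(g),
      mae_comp = mean(abs(g$completeness - g$truth_completeness)) * 100,
      mae_cont = mean(abs(g$contamination - g$truth_contamination)) * 100))
  }
  jsonlite::write_json(summary, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
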