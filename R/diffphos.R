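# Quantile normalization and differential phosphorylation calls.

#' Quantile normalize a signal matrix
#'
#' Forces every column (sample) onto the identical empirical distribution:
#' the k-th smallest value of each column becomes the mean across columns of
#' the k-th smallest values. Tied values within a column receive the average
#' of the reference values over the ranks the tied block occupies (the
#' behaviour of the usual microarray implementations). Shape, dimnames and
#' the within-column rank order are preserved; the map is idempotent.
#'
#' @param m numeric matrix, spots x samples, with at least one row and one
#'   column.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0 || ncol(m) == 0) stop("cannot normalize an empty matrix")
  if (!is.numeric(m) || anyNA(m)) stop("matrix must be numeric without NA")
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(matrix(sorted, nrow = nrow(m)))
  csum <- c(0, cumsum(ref))
  out <- apply(m, 2, function(x) {
    ra <- rank(x, ties.method = "average")
    k <- stats::ave(x, x, FUN = length)      # size of each tied block
    lo <- ra - (k - 1) / 2                   # first and last rank of the block
    hi <- ra + (k - 1) / 2
    (csum[hi + 1] - csum[lo]) / k
  })
  out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  out
}

#' Two-sample differential phosphorylation test for one spot
#'
#' Two-sided Student's t-test (pooled variance by default; set
#' `var_equal = FALSE` for Welch) on normalized replicate signals, plus the
#' fold change `mean(test) / mean(control)`. Direction is `"up"` when
#' `p < alpha` and FC > 1, `"down"` when `p < alpha` and FC < 1, `"ns"`
#' otherwise. Degenerate cases: both sides constant and equal gives p = 1;
#' both sides constant but different gives p = 0; a zero control mean makes
#' the fold change undefined, flagging the record (`flagged = TRUE`).
#'
#' @param test,control numeric replicate vectors (length >= 2 each).
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance t-test if TRUE (default).
#' @return list with `p_value`, `fold_change`, `direction`, `flagged`.
#' @export
differential_test <- function(test, control, alpha = 0.05, var_equal = TRUE) {
  if (length(test) < 2 || length(control) < 2)
    stop("need at least 2 replicates per side")
  flagged <- FALSE
  fc <- NA_real_
  if (mean(control) == 0) {
    flagged <- TRUE
  } else {
    fc <- mean(test) / mean(control)
  }
  if (stats::sd(test) == 0 && stats::sd(control) == 0) {
    p <- if (mean(test) == mean(control)) 1 else 0
  } else {
    p <- stats::t.test(test, control, var.equal = var_equal)$p.value
  }
  direction <- "ns"
  if (!flagged && p < alpha) direction <- if (fc > 1) "up" else if (fc < 1) "down" else "ns"
  list(p_value = p, fold_change = fc, direction = direction, flagged = flagged)
}

#' Differential phosphorylation between a test and a control group
#'
#' Selects the spots with `SR == sr_level` in both groups, quantile
#' normalizes the two groups' replicate columns jointly (so that the groups
#' are directly comparable), and tests each spot with [differential_test].
#' Spots with an undefined fold change (zero control mean after
#' normalization) are dropped with a warning.
#'
#' @param dataset a floored [kinome_dataset].
#' @param test,control group labels.
#' @param sr_level reliability level used for spot selection (default 6).
#' @param alpha significance level (default 0.05).
#' @param scores optional named list of precomputed [score_dataset] tables.
#' @param normalize quantile normalize before testing (default TRUE).
#' @param var_equal pooled-variance t-test (default TRUE).
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()]; the default `"none"` keeps raw p-values.
#' @return A `differential_records` data frame: annotation columns plus
#'   `p_value`, `fold_change`, `direction`. Attribute `"common_spots"`
#'   carries the selected spot set.
#' @export
differential_analysis <- function(dataset, test, control, sr_level = 6,
                                  alpha = 0.05, scores = NULL,
                                  normalize = TRUE, var_equal = TRUE,
                                  p_adjust = "none") {
  if (is.null(scores))
    scores <- list(score_dataset(dataset, test), score_dataset(dataset, control))
  else
    scores <- list(scores[[test]], scores[[control]])
  common <- select_common_spots(scores[[1]], scores[[2]], sr_level)
  ann <- dataset$layout[match(common, dataset$layout$spot_id), , drop = FALSE]
  mt <- dataset$groups[[test]][common, , drop = FALSE]
  mc <- dataset$groups[[control]][common, , drop = FALSE]
  if (length(common) > 0 && normalize) {
    joint <- quantile_normalize(cbind(mt, mc))
    mt <- joint[, seq_len(ncol(mt)), drop = FALSE]
    mc <- joint[, ncol(mt) + seq_len(ncol(mc)), drop = FALSE]
  }
  res <- lapply(seq_along(common), function(i)
    differential_test(mt[i, ], mc[i, ], alpha = alpha, var_equal = var_equal))
  p <- vapply(res, `[[`, 0, "p_value")
  fc <- vapply(res, `[[`, 0, "fold_change")
  flagged <- vapply(res, `[[`, TRUE, "flagged")
  if (p_adjust != "none" && length(p)) {
    p <- stats::p.adjust(p, method = p_adjust)
  }
  direction <- ifelse(!flagged & p < alpha & fc > 1, "up",
                      ifelse(!flagged & p < alpha & fc < 1, "down", "ns"))
  out <- data.frame(spot_id = common,
                    protein_name = ann$protein_name,
                    symbol = ann$symbol,
                    uniprot_accession = ann$uniprot_accession,
                    sequence = ann$sequence,
                    p_value = p, fold_change = fc, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$phospho_positions <- ann$phospho_positions
  if (any(flagged)) {
    warning(sum(flagged), " spot(s) with zero control mean excluded: ",
            paste(common[flagged], collapse = ", "))
    out <- out[!flagged, , drop = FALSE]
  }
  class(out) <- c("differential_records", "data.frame")
  attr(out, "common_spots") <- common
  attr(out, "contrast") <- c(test = test, control = control)
  attr(out, "alpha") <- alpha
  out
}

#' Volcano-plot table and up/down counts
#'
#' @param records a `differential_records` table.
#' @param alpha significance level used for the counts (default 0.05).
#' @return list with `table` (`spot_id`, `log2_fc`, `neg_log10_p`,
#'   `direction`) and `counts` (named vector `up`, `down`).
#' @export
volcano_table <- function(records, alpha = 0.05) {
  direction <- ifelse(records$p_value < alpha & records$fold_change > 1, "up",
                      ifelse(records$p_value < alpha & records$fold_change < 1,
                             "down", "ns"))
  tab <- data.frame(spot_id = records$spot_id,
                    log2_fc = log2(records$fold_change),
                    neg_log10_p = -log10(records$p_value),
                    direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab,
       counts = c(up = sum(direction == "up"), down = sum(direction == "down")))
}
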