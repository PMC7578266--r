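# Spot-reliability (SR) scoring.
#
# Two per-spot parameters are computed across a group's technical
# replicates: P1 = sd/A (a coefficient of variation) and P2 = A/M (a
# mean/median skew ratio), with A the mean, M the median and sd the sample
# (n-1) standard deviation. Each parameter is banded High/Medium/Low and
# the pair is combined into an integer reliability score SR in 1..6.
#
# Band boundaries (the published ranges are open; boundary points are
# resolved deterministically, High band taking precedence):
#   P1: High  P1 < 0.20; Medium 0.20 <= P1 < 0.50; Low otherwise.
#   P2: High  0.80 < P2 < 1.20;
#       Medium (0.70 < P2 <= 0.80) or (1.20 <= P2 < 1.40); Low otherwise.
# Undefined ratios (A = 0 or M = 0 after flooring) are classified Low: an
# all-zero or zero-median spot is maximally unreliable.

SR_LEVELS <- c("High", "Medium", "Low")

# 9-entry combination table, symmetric in its two arguments
SR_TABLE <- matrix(c(6L, 5L, 4L,
                     5L, 3L, 2L,
                     4L, 2L, 1L),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(SR_LEVELS, SR_LEVELS))

#' Per-spot replicate statistics
#'
#' @param values numeric vector of replicate signals for one spot
#'   (length >= 2, flooring already applied).
#' @return Named vector `c(A, M, sd)`: mean, median, sample (n-1) sd.
#' @export
spot_statistics <- function(values) {
  if (!is.numeric(values) || length(values) < 2)
    stop("need at least 2 numeric replicate values")
  if (anyNA(values)) stop("missing replicate values are not allowed")
  c(A = mean(values), M = stats::median(values), sd = stats::sd(values))
}

#' Classify the P1 (sd/mean) parameter
#'
#' @param p1 numeric vector of P1 values; `NaN`/`NA` (mean zero) maps to
#'   `"Low"` with a warning.
#' @return Character vector of levels `"High"`, `"Medium"` or `"Low"`.
#' @export
classify_p1 <- function(p1) {
  out <- ifelse(p1 < 0.20, "High", ifelse(p1 < 0.50, "Medium", "Low"))
  und <- !is.finite(p1)
  if (any(und)) {
    warning(sum(und), " spot(s) with undefined P1 (zero mean) classified Low")
    out[und] <- "Low"
  }
  out
}

#' Classify the P2 (mean/median) parameter
#'
#' @param p2 numeric vector of P2 values; `NaN`/`NA`/`Inf` (median zero)
#'   maps to `"Low"` with a warning.
#' @return Character vector of levels `"High"`, `"Medium"` or `"Low"`.
#' @export
classify_p2 <- function(p2) {
  out <- ifelse(p2 > 0.80 & p2 < 1.20, "High",
                ifelse(p2 > 0.70 & p2 < 1.40, "Medium", "Low"))
  und <- !is.finite(p2)
  if (any(und)) {
    warning(sum(und), " spot(s) with undefined P2 (zero median) classified Low")
    out[und] <- "Low"
  }
  out
}

#' Combine P1 and P2 levels into the SR score
#'
#' Exact lookup of the published 9-entry combination: High/High gives 6,
#' Low/Low gives 1, and the table is symmetric in its arguments.
#'
#' @param level_p1,level_p2 character vectors of levels.
#' @return Integer vector of SR scores in 1..6.
#' @export
sr_score <- function(level_p1, level_p2) {
  if (!all(level_p1 %in% SR_LEVELS) || !all(level_p2 %in% SR_LEVELS))
    stop("levels must be High, Medium or Low")
  SR_TABLE[cbind(match(level_p1, SR_LEVELS), match(level_p2, SR_LEVELS))]
}

#' Score every spot of one group
#'
#' @param dataset a [kinome_dataset] (flooring should be applied first).
#' @param group group label.
#' @return A `spot_reliability` data frame with one row per spot:
#'   `spot_id`, `A`, `M`, `sd`, `P1`, `P2`, `level_P1`, `level_P2`, `SR`.
#' @export
score_dataset <- function(dataset, group) {
  if (!group %in% names(dataset$groups))
    stop("unknown group '", group, "'; available: ",
         paste(names(dataset$groups), collapse = ", "))
  m <- dataset$groups[[group]]
  if (nrow(m) == 0) {
    out <- data.frame(spot_id = character(0), A = numeric(0), M = numeric(0),
                      sd = numeric(0), P1 = numeric(0), P2 = numeric(0),
                      level_P1 = character(0), level_P2 = character(0),
                      SR = integer(0))
    class(out) <- c("spot_reliability", "data.frame")
    return(out)
  }
  A <- rowMeans(m)
  M <- apply(m, 1, stats::median)
  s <- apply(m, 1, stats::sd)
  P1 <- ifelse(A > 0, s / A, NaN)
  P2 <- ifelse(M > 0, A / M, NaN)
  l1 <- suppressWarnings(classify_p1(P1))
  l2 <- suppressWarnings(classify_p2(P2))
  out <- data.frame(spot_id = rownames(m), A = A, M = M, sd = s,
                    P1 = P1, P2 = P2, level_P1 = l1, level_P2 = l2,
                    SR = sr_score(l1, l2), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("spot_reliability", "data.frame")
  out
}

#' SR histogram for one group
#'
#' Counts of spots at each SR level 1..6 (the per-group summary bar chart
#' of a run report).
#' @param scores a `spot_reliability` table from [score_dataset].
#' @return Named integer vector of length 6.
#' @export
sr_histogram <- function(scores) {
  counts <- tabulate(scores$SR, nbins = 6)
  names(counts) <- as.character(1:6)
  counts
}

#' Spots sharing an SR level in two groups
#'
#' Pairwise comparisons only use spots whose reliability is identical in
#' both groups, avoiding unbalanced data.
#'
#' @param scores_a,scores_b `spot_reliability` tables for the two groups.
#' @param sr_level integer in 1..6.
#' @return Character vector of spot_ids with `SR == sr_level` in both
#'   groups, in the order of `scores_a` (layout order).
#' @export
select_common_spots <- function(scores_a, scores_b, sr_level) {
  if (!sr_level %in% 1:6) stop("sr_level must be in 1..6")
  in_a <- scores_a$spot_id[scores_a$SR == sr_level]
  in_b <- scores_b$spot_id[scores_b$SR == sr_level]
  in_a[in_a %in% in_b]
}
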