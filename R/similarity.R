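# The chi degree-of-similarity statistic between two surfaces.
#
# Over the N spots common to both groups at a given SR level,
#
#   chi^2 = (1/N) * sum_i ( (I0[i] - It[i]) / (1 - |s0[i] - st[i]|) )^2
#
# where I and s are the per-spot mean and sample sd of normalized replicate
# signals in the model (0) and test (t) group. chi = sqrt(chi^2) is
# reported: 0 for identical profiles, growing with mean-intensity
# differences, each term inflated when the two groups' spot noise levels
# diverge. The statistic is symmetric in its two arguments and carries no
# inferential calibration; it is a descriptive distance.
#
# The denominator is only guaranteed positive when |s0 - st| < 1; profiles
# are therefore built from quantile-normalized intensities rescaled to
# [0, 1] by the global maximum of the pair before chi is computed.

#' Per-group intensity profile over a fixed spot set
#'
#' @param m numeric matrix of normalized signals, spots x replicates, with
#'   spot_ids as rownames.
#' @return A `group_profile`: list with `spot_ids`, `I` (per-spot means)
#'   and `sigma` (per-spot sample sds).
#' @export
group_profile <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("profile matrix needs spot_id rownames")
  structure(list(spot_ids = rownames(m), I = rowMeans(m),
                 sigma = apply(m, 1, stats::sd)),
            class = "group_profile")
}

#' chi degree of similarity between two profiles
#'
#' @param model,test `group_profile`s sharing the same spot_ids in the same
#'   order (or plain lists with `I` and `sigma` components).
#' @param squared return chi^2 instead of chi (default FALSE).
#' @return Non-negative scalar; 0 iff the mean profiles are identical.
#' @export
compute_chi <- function(model, test, squared = FALSE) {
  if (!is.null(model$spot_ids) && !is.null(test$spot_ids) &&
      !identical(model$spot_ids, test$spot_ids))
    stop("profiles must share the same spot_ids in the same order")
  n <- length(model$I)
  if (n == 0) stop("no spots to compare")
  if (length(test$I) != n || length(model$sigma) != n ||
      length(test$sigma) != n)
    stop("profile component lengths disagree")
  denom <- 1 - abs(model$sigma - test$sigma)
  if (any(denom <= 0)) {
    bad <- if (!is.null(model$spot_ids)) model$spot_ids[denom <= 0] else
      which(denom <= 0)
    stop("sigma difference >= 1 makes chi undefined for spot(s): ",
         paste(bad, collapse = ", "),
         "; rescale intensities (see pairwise_similarity)")
  }
  chi2 <- mean(((model$I - test$I) / denom)^2)
  if (squared) chi2 else sqrt(chi2)
}

#' Pairwise chi similarity matrix across all groups
#'
#' For each unordered pair of groups: selects the spots with
#' `SR == sr_level` in both, quantile normalizes the pair's replicate
#' columns jointly, rescales by the pair's global maximum (keeping the
#' denominator of chi positive), and computes chi. Pairs with no common
#' spot get `NA` with a warning.
#'
#' @param dataset a floored [kinome_dataset] with >= 2 groups.
#' @param sr_level reliability level (default 6).
#' @param scores optional named list of precomputed [score_dataset] tables.
#' @param squared report chi^2 instead of chi.
#' @return A `chi_matrix`: list with `group_labels`, `sr_level`, `chi`
#'   (symmetric matrix, zero diagonal), `n_spots_used`, and `long`
#'   (heatmap-ready long-format data frame).
#' @export
pairwise_similarity <- function(dataset, sr_level = 6, scores = NULL,
                                squared = FALSE) {
  labels <- names(dataset$groups)
  if (length(labels) < 2) stop("need at least 2 groups")
  if (!sr_level %in% 1:6) stop("sr_level must be in 1..6")
  if (is.null(scores))
    scores <- lapply(stats::setNames(labels, labels),
                     function(g) score_dataset(dataset, g))
  k <- length(labels)
  chi <- matrix(0, k, k, dimnames = list(labels, labels))
  nus <- matrix(0L, k, k, dimnames = list(labels, labels))
  long <- NULL
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      a <- labels[i]; b <- labels[j]
      common <- select_common_spots(scores[[a]], scores[[b]], sr_level)
      nus[i, j] <- nus[j, i] <- length(common)
      if (length(common) == 0) {
        warning("no common SR-", sr_level, " spots for ", a, " vs ", b)
        val <- NA_real_
      } else {
        ma <- dataset$groups[[a]][common, , drop = FALSE]
        mb <- dataset$groups[[b]][common, , drop = FALSE]
        joint <- quantile_normalize(cbind(ma, mb))
        top <- max(joint)
        if (top > 0) joint <- joint / top
        pa <- group_profile(joint[, seq_len(ncol(ma)), drop = FALSE])
        pb <- group_profile(joint[, ncol(ma) + seq_len(ncol(mb)), drop = FALSE])
        val <- compute_chi(pa, pb, squared = squared)
      }
      chi[i, j] <- chi[j, i] <- val
      long <- rbind(long, data.frame(group_a = a, group_b = b,
                                     sr = sr_level, n_spots = length(common),
                                     chi = val, stringsAsFactors = FALSE))
    }
  }
  structure(list(group_labels = labels, sr_level = sr_level, chi = chi,
                 n_spots_used = nus, long = long),
            class = "chi_matrix")
}

#' @export
print.chi_matrix <- function(x, ...) {
  cat("chi similarity at SR =", x$sr_level, "\n")
  print(round(x$chi, 3))
  invisible(x)
}
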