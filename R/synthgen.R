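# Synthetic chip-data generator with known ground truth.
#
# Emulates the structure of a tyrosine-kinase peptide array experiment:
# 144 spots (one internal control peptide), 3 technical replicates per
# group, positive right-skewed fluorescence signals, occasional negative
# background-subtracted values. Replicates are drawn log-normally around a
# per-spot baseline; each spot belongs to a quality class whose coefficient
# of variation (CV) controls the reliability parameter P1 (for a log-normal
# at small CV, P1 is approximately the CV, and the mean/median ratio P2
# stays near 1), so SR class membership is controlled analytically.
# Group effects are multiplicative fold changes on chosen spots.

#' Configuration for the synthetic generator
#'
#' @param n_spots total spots including the internal control (default 144,
#'   the standard tyrosine-kinase chip size).
#' @param n_replicates technical replicates per group (default 3).
#' @param group_specs named list, one entry per group:
#'   `list(baseline = <log-mean signal>, effects = <named numeric vector,
#'   spot index -> fold effect>)`. Defaults to a two-group
#'   (`control`/`test`) null design at baseline `log(300)`.
#' @param quality_mix named proportions of spots per quality class
#'   (must sum to 1). Class names must appear in `class_cv`.
#' @param class_cv named CV per quality class. Defaults target SR 6
#'   (CV 0.08, P1 High), SR 5 (CV 0.32, P1 Medium) and SR 4 (CV 0.85,
#'   P1 Low) with P2 near 1 in each case.
#' @param neg_background_rate probability that a replicate value is negated
#'   (shrunk and sign-flipped) to emulate background over-subtraction.
#' @param seed integer RNG seed; generation is reproducible given the seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_spots = 144, n_replicates = 3,
                         group_specs = list(
                           control = list(baseline = log(300), effects = NULL),
                           test = list(baseline = log(300), effects = NULL)),
                         quality_mix = c(sr6 = 0.40, sr5 = 0.35, sr4 = 0.25),
                         class_cv = c(sr6 = 0.08, sr5 = 0.32, sr4 = 0.85),
                         neg_background_rate = 0.02, seed = 1) {
  if (n_spots < 1) stop("n_spots must be >= 1")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (abs(sum(quality_mix) - 1) > 1e-8) stop("quality_mix must sum to 1")
  if (any(quality_mix < 0)) stop("quality_mix proportions must be >= 0")
  if (!all(names(quality_mix) %in% names(class_cv)))
    stop("every quality class needs a CV in class_cv")
  if (any(class_cv < 0)) stop("CVs must be >= 0")
  if (neg_background_rate < 0 || neg_background_rate > 1)
    stop("neg_background_rate must be in [0, 1]")
  if (is.null(names(group_specs)) || any(!nzchar(names(group_specs))))
    stop("group_specs must be a named list")
  structure(list(n_spots = n_spots, n_replicates = n_replicates,
                 group_specs = group_specs, quality_mix = quality_mix,
                 class_cv = class_cv,
                 neg_background_rate = neg_background_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic chip layout
#'
#' Random 13-mer peptides, each containing at least one tyrosine, with
#' spot ids following the `SYMBOL_start_end` convention; the first spot is
#' the internal control peptide (`ART_003_...` naming).
#'
#' @param n_spots number of spots including the control.
#' @param seed RNG seed.
#' @return A [peptide_layout].
#' @export
make_layout <- function(n_spots, seed = 1) {
  if (n_spots < 1) stop("n_spots must be >= 1")
  set.seed(seed)
  aa <- setdiff(AA_CODES, "X")
  ids <- "ART_003_EAI(pY)AAPFAKKKXC"
  # the control id embeds its (pre-phosphorylated) sequence; store a plain
  # sequence string for it
  seqs <- "EAIYAAPFAKKKX"
  names_ <- "internal control peptide"
  syms <- "ART3"
  accs <- "SYN00000"
  pos <- list(integer(0))
  if (n_spots > 1) {
    for (i in seq_len(n_spots - 1)) {
      sym <- sprintf("SYN%03d", i)
      start <- sample.int(900, 1)
      chars <- sample(aa, 13, replace = TRUE)
      chars[sample.int(13, 1)] <- "Y"                 # guarantee a tyrosine
      offsets <- which(chars == "Y")
      p <- start - 1L + sort(sample(offsets, min(length(offsets),
                                                 sample.int(3, 1))))
      ids <- c(ids, sprintf("%s_%d_%d", sym, start, start + 12L))
      seqs <- c(seqs, paste(chars, collapse = ""))
      names_ <- c(names_, sprintf("synthetic protein %03d", i))
      syms <- c(syms, sym)
      accs <- c(accs, sprintf("SYN%05d", i))
      pos <- c(pos, list(as.integer(p)))
    }
  }
  peptide_layout(spot_id = ids, sequence = seqs, protein_name = names_,
                 symbol = syms, phospho_positions = pos,
                 uniprot_accession = accs)
}

#' Generate a synthetic intensity dataset with ground truth
#'
#' Each non-control spot draws a log-baseline shared across groups
#' (spot-to-spot heterogeneity, sd 1 on the log scale), gets a quality
#' class from `quality_mix`, and per group per replicate a log-normal
#' signal with the class CV (sdlog chosen so the true CV equals the class
#' CV) around `group baseline x spot baseline x fold effect`. A fraction
#' `neg_background_rate` of values is replaced by a small negative value to
#' exercise the flooring rule. The control spot is generated like an SR 6
#' spot; it is expected to be excluded downstream.
#'
#' @param config a [synth_config].
#' @return list with `dataset` (a [kinome_dataset], flooring NOT applied)
#'   and `truth` (data frame: `spot_id`, `quality_class`, `target_sr`,
#'   `cv`, plus one `fold_<group>` column per group).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  layout <- make_layout(config$n_spots, seed = config$seed)
  n <- config$n_spots
  classes <- names(config$quality_mix)
  cls <- if (n > 1)
    sample(classes, n - 1, replace = TRUE, prob = config$quality_mix)
  else character(0)
  # the control spot behaves like the best available class
  quality <- c(if ("sr6" %in% classes) "sr6" else classes[1], cls)
  cv <- config$class_cv[quality]
  sdlog <- sqrt(log(1 + cv^2))
  spot_base <- stats::rnorm(n, 0, 1)       # shared spot heterogeneity
  target_sr <- vapply(quality, function(q) {
    switch(q, sr6 = 6L, sr5 = 5L, sr4 = 4L, sr3 = 3L, sr2 = 2L, sr1 = 1L, NA_integer_)
  }, 0L)
  groups <- list()
  truth <- data.frame(spot_id = layout$spot_id, quality_class = quality,
                      target_sr = target_sr, cv = as.numeric(cv),
                      row.names = NULL, stringsAsFactors = FALSE)
  for (g in names(config$group_specs)) {
    spec <- config$group_specs[[g]]
    fold <- rep(1, n)
    if (!is.null(spec$effects) && length(spec$effects)) {
      idx <- as.integer(names(spec$effects))
      if (anyNA(idx) || any(idx < 1 | idx > n))
        stop("effect spot indices out of range for group ", g)
      fold[idx] <- as.numeric(spec$effects)
    }
    mu <- spec$baseline + spot_base + log(fold)   # log-scale location
    m <- matrix(0, n, config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      # median-parameterized log-normal; true CV equals the class CV
      m[, r] <- exp(mu + stats::rnorm(n, 0, 1) * sdlog)
    }
    if (config$neg_background_rate > 0) {
      flip <- matrix(stats::runif(length(m)) < config$neg_background_rate,
                     nrow = n)
      m[flip] <- -m[flip] * stats::runif(sum(flip), 0.01, 0.10)
    }
    groups[[g]] <- m
    truth[[paste0("fold_", g)]] <- fold
  }
  list(dataset = kinome_dataset(layout, groups), truth = truth)
}
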