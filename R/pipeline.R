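# End-to-end orchestration: ingest -> score -> select -> normalize ->
# differential -> chi -> report files.

#' Pipeline run configuration
#'
#' @param control_group label of the reference surface.
#' @param test_groups labels of the surfaces compared against the control.
#' @param sr_level reliability level for spot selection (default 6, the
#'   most stringent; lower levels admit noisier spots).
#' @param alpha t-test significance level (default 0.05; raw p-values, no
#'   multiple-testing correction, matching the conventional reporting of
#'   these arrays).
#' @param control_peptide_id spot_id of the internal control peptide to
#'   exclude (default the tyrosine-kinase chip's `ART_003` control).
#' @param output_dir directory for report files.
#' @param seed optional integer recorded in the manifest; the analysis path
#'   itself is deterministic.
#' @return A `run_config` list.
#' @export
run_config <- function(control_group, test_groups, sr_level = 6,
                       alpha = 0.05,
                       control_peptide_id = "ART_003_EAI(pY)AAPFAKKKXC",
                       output_dir = ".", seed = NULL) {
  if (!sr_level %in% 1:6) stop("sr_level must be in 1..6")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (control_group %in% test_groups)
    stop("control_group must not appear in test_groups")
  structure(list(control_group = control_group, test_groups = test_groups,
                 sr_level = sr_level, alpha = alpha,
                 control_peptide_id = control_peptide_id,
                 output_dir = output_dir, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: read (or accept) the dataset, exclude the internal control spot,
#' floor negative values, score spot reliability per group, and then per
#' test group select the common spots at the configured SR level, quantile
#' normalize, call differential phosphorylation, and write the volcano
#' table; finally compute the pairwise chi matrix over all configured
#' groups. Deterministic: identical inputs and config give byte-identical
#' outputs.
#'
#' Files written to `config$output_dir`: `<group>_sr_histogram.tsv` per
#' group, `<test>_common_spots.txt`, `<test>_differential.tsv` (annotation
#' plus p-value and fold change) and `<test>_volcano.tsv` per test group,
#' `chi_sr<k>.tsv` + `chi_sr<k>_matrix.csv`, and a JSON `manifest.json`
#' with config, stage spot counts and input hashes.
#'
#' @param config a [run_config].
#' @param dataset a [kinome_dataset]; alternatively give `layout_path` and
#'   `intensities_path`.
#' @param layout_path,intensities_path input files, used when `dataset` is
#'   NULL.
#' @return Invisibly, a list with `dataset`, `scores`, `differential`
#'   (per test group), `volcano`, `chi`, and `manifest`.
#' @export
run_pipeline <- function(config, dataset = NULL, layout_path = NULL,
                         intensities_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  hashes <- list()
  if (is.null(dataset)) {
    if (is.null(layout_path) || is.null(intensities_path))
      stop("give either a dataset or layout_path + intensities_path")
    layout <- read_layout(layout_path)
    dataset <- read_intensities(intensities_path, layout)
    hashes <- list(layout = unname(tools::md5sum(layout_path)),
                   intensities = unname(tools::md5sum(intensities_path)))
  }
  groups_used <- c(config$control_group, config$test_groups)
  missing_groups <- setdiff(groups_used, names(dataset$groups))
  if (length(missing_groups))
    stop("stage ingest: group(s) not in dataset: ",
         paste(missing_groups, collapse = ", "))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  n_raw <- nrow(dataset$layout)
  dataset <- withCallingHandlers(
    exclude_control(dataset, config$control_peptide_id),
    warning = function(w) invokeRestart("muffleWarning"))
  dataset <- floor_negatives(dataset)
  counts <- list(spots_raw = n_raw, spots_analyzed = nrow(dataset$layout))

  scores <- lapply(stats::setNames(groups_used, groups_used),
                   function(g) score_dataset(dataset, g))
  for (g in groups_used) {
    h <- sr_histogram(scores[[g]])
    utils::write.table(data.frame(SR = names(h), count = as.integer(h)),
                       file.path(config$output_dir,
                                 paste0(g, "_sr_histogram.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts[[paste0("sr", config$sr_level, "_", g)]] <-
      sum(scores[[g]]$SR == config$sr_level)
  }

  differential <- list(); volcano <- list()
  for (g in config$test_groups) {
    common <- select_common_spots(scores[[g]], scores[[config$control_group]],
                                  config$sr_level)
    writeLines(common, file.path(config$output_dir,
                                 paste0(g, "_common_spots.txt")))
    counts[[paste0("common_", g)]] <- length(common)
    rec <- differential_analysis(dataset, test = g,
                                 control = config$control_group,
                                 sr_level = config$sr_level,
                                 alpha = config$alpha, scores = scores)
    differential[[g]] <- rec
    tab <- data.frame(Spot = rec$spot_id, Protein = rec$protein_name,
                      Symbol = rec$symbol,
                      p = vapply(rec$phospho_positions, format_positions, ""),
                      `Uniprot accession` = rec$uniprot_accession,
                      Sequence = rec$sequence, `p-value` = rec$p_value,
                      FC = rec$fold_change, direction = rec$direction,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(config$output_dir,
                                      paste0(g, "_differential.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    v <- volcano_table(rec, alpha = config$alpha)
    volcano[[g]] <- v
    utils::write.table(v$table, file.path(config$output_dir,
                                          paste0(g, "_volcano.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts[[paste0("up_", g)]] <- unname(v$counts["up"])
    counts[[paste0("down_", g)]] <- unname(v$counts["down"])
  }

  sub <- dataset
  sub$groups <- dataset$groups[groups_used]
  warn <- character(0)
  chi <- withCallingHandlers(
    pairwise_similarity(sub, sr_level = config$sr_level,
                        scores = scores[groups_used]),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  utils::write.table(chi$long,
                     file.path(config$output_dir,
                               sprintf("chi_sr%d.tsv", config$sr_level)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(chi$chi,
                   file.path(config$output_dir,
                             sprintf("chi_sr%d_matrix.csv", config$sr_level)))

  manifest <- list(
    package = "kinomeSR",
    package_version = as.character(utils::packageVersion("kinomeSR")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config), input_hashes = hashes,
    stage_counts = counts, warnings = warn)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(dataset = dataset, scores = scores,
                 differential = differential, volcano = volcano, chi = chi,
                 manifest = manifest))
}
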