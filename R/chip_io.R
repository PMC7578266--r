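# Chip layout / intensity table I/O and basic dataset hygiene.
#
# A layout is one row per array spot: spot_id, protein_name, symbol,
# phospho_positions (list-column of 1-based integer protein coordinates),
# uniprot_accession, sequence (13-mer in the usual tyrosine-kinase chip).
# Intensities come as one matrix per experimental group, spots x technical
# replicates, background-subtracted so raw values may be negative.

AA_CODES <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
              "S","T","V","W","Y","X")

#' Construct a peptide layout table
#'
#' @param spot_id character vector of unique spot identifiers
#'   (conventionally `SYMBOL_start_end`).
#' @param sequence peptide sequences, one-letter amino-acid codes
#'   (the 20 standard codes plus X).
#' @param protein_name,symbol,uniprot_accession optional annotation columns.
#' @param phospho_positions list of integer vectors (1-based protein
#'   coordinates of the phospho-acceptor residues), or a character vector in
#'   bracketed form (`"[573, 579, 580]"`).
#' @return A `peptide_layout` data frame.
#' @export
peptide_layout <- function(spot_id, sequence,
                           protein_name = rep("", length(spot_id)),
                           symbol = rep("", length(spot_id)),
                           phospho_positions = vector("list", length(spot_id)),
                           uniprot_accession = rep("", length(spot_id))) {
  spot_id <- as.character(spot_id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(spot_id))
    stop("duplicate spot_id in layout: ",
         paste(unique(spot_id[duplicated(spot_id)]), collapse = ", "))
  if (is.character(phospho_positions))
    phospho_positions <- lapply(phospho_positions, parse_positions)
  phospho_positions <- lapply(phospho_positions, function(p) {
    p <- as.integer(p)
    if (length(p) && (anyNA(p) || any(p < 1)))
      stop("phospho positions must be positive integers")
    sort(p)
  })
  bad <- !grepl(sprintf("^[%s]+$", paste(AA_CODES, collapse = "")), sequence)
  if (any(bad))
    stop("invalid amino-acid sequence for spot(s): ",
         paste(spot_id[bad], collapse = ", "))
  out <- data.frame(spot_id = spot_id, protein_name = as.character(protein_name),
                    symbol = as.character(symbol),
                    uniprot_accession = as.character(uniprot_accession),
                    sequence = sequence, stringsAsFactors = FALSE)
  out$phospho_positions <- phospho_positions
  out <- out[, c("spot_id", "protein_name", "symbol", "phospho_positions",
                 "uniprot_accession", "sequence")]
  class(out) <- c("peptide_layout", "data.frame")
  out
}

#' Parse a bracketed phospho-position list
#'
#' `"[573, 579, 580]"` becomes `c(573L, 579L, 580L)`. Empty strings and
#' `"[]"` give `integer(0)`.
#' @param x a single character string.
#' @return integer vector, sorted ascending.
#' @export
parse_positions <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(integer(0))
  body <- gsub("^\\s*\\[|\\]\\s*$", "", x)
  if (!nzchar(trimws(body))) return(integer(0))
  parts <- trimws(strsplit(body, ",")[[1]])
  vals <- suppressWarnings(as.integer(parts))
  if (anyNA(vals)) stop("cannot parse phospho positions: ", x)
  sort(vals)
}

#' Render phospho positions in bracketed form
#' @param p integer vector.
#' @return A string like `"[573, 579, 580]"`.
#' @export
format_positions <- function(p) {
  paste0("[", paste(p, collapse = ", "), "]")
}

guess_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a chip layout table
#'
#' Accepts comma- or tab-separated files with a header row. Required
#' columns: `spot_id` and `sequence`; `protein_name`, `symbol`,
#' `phospho_positions` (bracketed lists) and `uniprot_accession` are read
#' when present. Column names can be remapped via `col_map`.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma.
#' @param col_map optional named character vector mapping standard names to
#'   the file's column names, e.g. `c(spot_id = "Spot", sequence = "Sequence")`.
#' @return A [peptide_layout] in file order.
#' @export
read_layout <- function(path, sep = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  if (is.null(sep)) sep <- guess_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(tab))
        names(tab)[names(tab) == col_map[[std]]] <- std
    }
  }
  for (req in c("spot_id", "sequence"))
    if (!req %in% names(tab))
      stop("layout is missing required column '", req, "'")
  grab <- function(col) if (col %in% names(tab)) tab[[col]] else rep("", nrow(tab))
  peptide_layout(spot_id = tab$spot_id,
                 sequence = tab$sequence,
                 protein_name = grab("protein_name"),
                 symbol = grab("symbol"),
                 phospho_positions = grab("phospho_positions"),
                 uniprot_accession = grab("uniprot_accession"))
}

#' Write a chip layout table
#'
#' Inverse of [read_layout]; `read_layout(write_layout(x, f))` round-trips.
#' @param layout a [peptide_layout].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path, sep = "\t") {
  out <- as.data.frame(layout)
  out$phospho_positions <- vapply(layout$phospho_positions, format_positions, "")
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle a layout and per-group replicate matrices into a dataset
#'
#' @param layout a [peptide_layout].
#' @param groups named list of numeric matrices, one per experimental group,
#'   each `n_spots x n_replicates` with rows in layout order. Missing values
#'   are not allowed: every per-spot statistic assumes a full replicate
#'   vector.
#' @param flooring_applied has negative flooring already been applied?
#' @return A `kinome_dataset` object.
#' @export
kinome_dataset <- function(layout, groups, flooring_applied = FALSE) {
  stopifnot(inherits(layout, "peptide_layout"), is.list(groups))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list of matrices")
  groups <- lapply(groups, function(m) {
    m <- as.matrix(m)
    if (!is.numeric(m)) stop("intensity values must be numeric")
    if (anyNA(m)) stop("missing replicate values are not allowed")
    if (nrow(m) != nrow(layout))
      stop("group matrix rows (", nrow(m), ") do not match layout spots (",
           nrow(layout), ")")
    if (ncol(m) < 2) stop("each group needs at least 2 replicates")
    rownames(m) <- layout$spot_id
    m
  })
  if (flooring_applied && any(vapply(groups, min, 0) < 0))
    stop("flooring_applied is TRUE but negative values are present")
  structure(list(layout = layout, groups = groups,
                 flooring_applied = flooring_applied),
            class = "kinome_dataset")
}

#' @export
print.kinome_dataset <- function(x, ...) {
  cat("kinome_dataset:", nrow(x$layout), "spots;",
      length(x$groups), "group(s):",
      paste(sprintf("%s (n=%d)", names(x$groups),
                    vapply(x$groups, ncol, 0L)), collapse = ", "),
      "\n  negative flooring applied:", x$flooring_applied, "\n")
  invisible(x)
}

#' Read per-spot replicate intensities
#'
#' Expects one row per spot with a `spot_id` column plus signal columns named
#' `<group>_rep<k>`. Spot order and identity must match `layout`.
#'
#' @param path file path (CSV or TSV with header).
#' @param layout the matching [peptide_layout].
#' @param sep separator; `NULL` auto-detects.
#' @return A [kinome_dataset] (flooring not yet applied).
#' @export
read_intensities <- function(path, layout, sep = NULL) {
  if (!file.exists(path)) stop("intensity file not found: ", path)
  if (is.null(sep)) sep <- guess_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, quote = "\"")
  if (!"spot_id" %in% names(tab)) stop("intensity table needs a spot_id column")
  if (!identical(as.character(tab$spot_id), layout$spot_id))
    stop("intensity spot_ids do not match the layout")
  sig <- setdiff(names(tab), "spot_id")
  m <- regmatches(sig, regexec("^(.*)_rep([0-9]+)$", sig))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    stop("signal columns must be named <group>_rep<k>; offending: ",
         paste(sig[bad], collapse = ", "))
  grp <- vapply(m, `[`, "", 2L)
  groups <- lapply(split(sig, grp), function(cols) {
    as.matrix(tab[, cols, drop = FALSE])
  })
  kinome_dataset(layout, groups)
}

#' Write per-spot replicate intensities
#' @param dataset a [kinome_dataset].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_intensities <- function(dataset, path, sep = "\t") {
  cols <- lapply(names(dataset$groups), function(g) {
    m <- dataset$groups[[g]]
    colnames(m) <- sprintf("%s_rep%d", g, seq_len(ncol(m)))
    m
  })
  out <- data.frame(spot_id = dataset$layout$spot_id, do.call(cbind, cols),
                    check.names = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove the internal control peptide from a dataset
#'
#' The chip carries one internal positive-control spot (on the tyrosine
#' kinase chip, the `ART_003` pre-phosphorylated peptide) that is excluded
#' before any analysis. Absent control ids are a warning, not an error.
#'
#' @param dataset a [kinome_dataset].
#' @param control_id spot_id of the control peptide.
#' @return The dataset without the control spot; other rows keep their order.
#' @export
exclude_control <- function(dataset, control_id) {
  keep <- dataset$layout$spot_id != control_id
  if (all(keep)) {
    warning("control spot '", control_id, "' not present; dataset unchanged")
    return(dataset)
  }
  layout <- dataset$layout[keep, , drop = FALSE]
  class(layout) <- c("peptide_layout", "data.frame")
  groups <- lapply(dataset$groups, function(m) m[keep, , drop = FALSE])
  structure(list(layout = layout, groups = groups,
                 flooring_applied = dataset$flooring_applied),
            class = "kinome_dataset")
}

#' Floor negative signals to zero
#'
#' Background subtraction can push weak spots below zero; such values are
#' set to 0 before reliability scoring. Idempotent.
#'
#' @param dataset a [kinome_dataset].
#' @return The dataset with all values `>= 0` and `flooring_applied = TRUE`.
#' @export
floor_negatives <- function(dataset) {
  groups <- lapply(dataset$groups, function(m) {
    if (!is.numeric(m)) stop("non-numeric intensity values")
    pmax(m, 0)
  })
  structure(list(layout = dataset$layout, groups = groups,
                 flooring_applied = TRUE),
            class = "kinome_dataset")
}
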