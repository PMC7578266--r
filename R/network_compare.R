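# Protein-protein interaction network (PPIN) utilities.
#
# Differentially phosphorylated proteins plus their predicted kinase
# interactors form an undirected simple graph; per-node degree, betweenness
# and closeness centralities rank the nodes, and top-decile sets are
# compared across surfaces. Centrality conventions follow the Cytoscape
# NetworkAnalyzer defaults for undirected graphs: betweenness is normalized
# by (n-1)(n-2)/2 with endpoints excluded; closeness is computed within
# each connected component as (reachable)/(sum of distances), so isolated
# nodes get 0.

#' Format kinase-substrate predictor input from differential records
#'
#' One row per (accession, phospho-site) pair of the significant records
#' (direction != "ns"), the substrate/position layout consumed by
#' sequence-based kinase-site predictors. Records without a UniProt
#' accession are skipped with a warning.
#'
#' @param records a `differential_records` table (with `phospho_positions`).
#' @return data frame with `substrate_accession`, `position`,
#'   `substrate_symbol`.
#' @export
export_networkin_input <- function(records) {
  sig <- records[records$direction != "ns", , drop = FALSE]
  empty <- data.frame(substrate_accession = character(0),
                      position = integer(0),
                      substrate_symbol = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(empty)
  missing_acc <- !nzchar(sig$uniprot_accession)
  if (any(missing_acc)) {
    warning("skipping record(s) without accession: ",
            paste(sig$spot_id[missing_acc], collapse = ", "))
    sig <- sig[!missing_acc, , drop = FALSE]
  }
  if (nrow(sig) == 0) return(empty)
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    pos <- sig$phospho_positions[[i]]
    if (length(pos) == 0) return(NULL)
    data.frame(substrate_accession = sig$uniprot_accession[i],
               position = pos,
               substrate_symbol = sig$symbol[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Read a kinase-site prediction table
#'
#' Parses a predictor-output-style TSV with substrate, position, predicted
#' interactor and score columns (extra columns ignored).
#'
#' @param path file path.
#' @param sep separator; `NULL` auto-detects.
#' @return data frame with `substrate_symbol`, `site_position`,
#'   `predicted_interactor`, `score`.
#' @export
read_predictions <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  if (is.null(sep)) sep <- guess_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("substrate_symbol", "site_position", "predicted_interactor")
  if (!all(need %in% names(tab)))
    stop("prediction table needs columns: ", paste(need, collapse = ", "))
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  tab$site_position <- as.integer(tab$site_position)
  if (any(tab$site_position < 1, na.rm = TRUE))
    stop("site positions must be >= 1")
  if (any(tab$score < 0, na.rm = TRUE)) stop("scores must be >= 0")
  tab[, c("substrate_symbol", "site_position", "predicted_interactor", "score")]
}

#' Build an undirected PPIN from an edge list
#'
#' Duplicate and reversed edges are collapsed, self-loops dropped, and the
#' graph optionally restricted to a node whitelist. Edge lists follow the
#' STRING-export convention: two protein-symbol columns, optional
#' combined-score column (any pre-filtering on score is the caller's
#' responsibility).
#'
#' @param edges data frame (or file path to a TSV/CSV) whose first two
#'   columns name the interacting protein symbols.
#' @param node_whitelist optional character vector; keep only edges with
#'   both endpoints (and nodes) in this set.
#' @return A `ppin` object wrapping an [igraph::graph] plus (later) metrics.
#' @export
build_ppin <- function(edges, node_whitelist = NULL) {
  if (is.character(edges) && length(edges) == 1) {
    path <- edges
    if (!file.exists(path)) stop("edge list file not found: ", path)
    edges <- utils::read.table(path, sep = guess_sep(path), header = TRUE,
                               stringsAsFactors = FALSE, check.names = FALSE)
  }
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0 && ncol(edges) < 2)
    stop("edge list needs two symbol columns")
  if (nrow(edges) == 0) {
    a <- b <- character(0)
  } else {
    a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
    bad <- which(!nzchar(a) | !nzchar(b) | is.na(a) | is.na(b))
    if (length(bad))
      stop("malformed edge list row(s): ", paste(bad, collapse = ", "))
    if (!is.null(node_whitelist)) {
      keep <- a %in% node_whitelist & b %in% node_whitelist
      a <- a[keep]; b <- b[keep]
    }
    keep <- a != b                         # drop self-loops
    a <- a[keep]; b <- b[keep]
    key <- paste(pmin(a, b), pmax(a, b))   # collapse reversed duplicates
    dup <- duplicated(key)
    a <- a[!dup]; b <- b[!dup]
  }
  nodes <- if (is.null(node_whitelist)) sort(unique(c(a, b)))
           else sort(unique(as.character(node_whitelist)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  structure(list(graph = g, metrics = NULL), class = "ppin")
}

#' @export
print.ppin <- function(x, ...) {
  cat("ppin:", igraph::vcount(x$graph), "proteins,",
      igraph::ecount(x$graph), "interactions;",
      if (is.null(x$metrics)) "metrics not computed" else "metrics computed",
      "\n")
  invisible(x)
}

#' Compute degree, betweenness and closeness centralities
#'
#' @param ppin a [build_ppin] object; the graph may be disconnected.
#' @return The `ppin` with a `metrics` data frame (`node`, `degree`,
#'   `betweenness`, `closeness`).
#' @export
centrality_metrics <- function(ppin) {
  g <- ppin$graph
  n <- igraph::vcount(g)
  if (n == 0) {
    ppin$metrics <- data.frame(node = character(0), degree = numeric(0),
                               betweenness = numeric(0), closeness = numeric(0),
                               stringsAsFactors = FALSE)
    return(ppin)
  }
  deg <- igraph::degree(g)
  btw <- if (n > 2) igraph::betweenness(g, directed = FALSE, normalized = TRUE)
         else rep(0, n)
  clo <- suppressWarnings(igraph::closeness(g, mode = "all", normalized = TRUE))
  clo[!is.finite(clo)] <- 0                # isolated nodes reach no one
  ppin$metrics <- data.frame(node = igraph::V(g)$name, degree = as.numeric(deg),
                             betweenness = as.numeric(btw),
                             closeness = as.numeric(clo),
                             row.names = NULL, stringsAsFactors = FALSE)
  ppin
}

#' Nodes in the upper 10th percentile of a centrality metric
#'
#' The threshold is the 90th percentile by linear interpolation
#' ([stats::quantile] type 7); nodes whose value ties the threshold are
#' included.
#'
#' @param ppin a `ppin` with metrics computed.
#' @param metric one of `"degree"`, `"betweenness"`, `"closeness"`.
#' @return Character vector of node symbols.
#' @export
top_decile <- function(ppin, metric) {
  if (is.null(ppin$metrics)) ppin <- centrality_metrics(ppin)
  if (!metric %in% c("degree", "betweenness", "closeness"))
    stop("unknown metric '", metric, "'")
  v <- ppin$metrics[[metric]]
  if (length(v) == 0) return(character(0))
  thr <- stats::quantile(v, 0.9, type = 7, names = FALSE)
  ppin$metrics$node[v >= thr]
}

#' Venn partition of two networks' node sets
#'
#' @param ppin_a,ppin_b `ppin` objects.
#' @param metric `"all_nodes"` to compare full node sets, or a centrality
#'   name to compare [top_decile] sets.
#' @return list of disjoint sets `only_a`, `shared`, `only_b` whose union
#'   is the union of the two input sets.
#' @export
compare_networks <- function(ppin_a, ppin_b, metric = "all_nodes") {
  pick <- function(p) {
    if (metric == "all_nodes") igraph::V(p$graph)$name %||% character(0)
    else top_decile(p, metric)
  }
  a <- pick(ppin_a); b <- pick(ppin_b)
  list(only_a = setdiff(a, b), shared = intersect(a, b),
       only_b = setdiff(b, a))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
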