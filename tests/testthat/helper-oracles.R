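# Independent oracles and tiny fixture builders shared across tests.

# Sort-average-reassign quantile normalization (distinct values only).
qn_oracle <- function(m) {
  mu <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) mu[rank(x)])
  matrix(out, nrow = nrow(m), dimnames = dimnames(m))
}

# Closed-form pooled two-sample two-sided t-test.
ttest_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), df = n1 + n2 - 2)
}

# Term-by-term chi evaluation.
chi_oracle <- function(I0, It, s0, st) {
  sqrt(mean(((I0 - It) / (1 - abs(s0 - st)))^2))
}

# Exhaustive shortest-path centralities on an adjacency matrix.
# Conventions: betweenness normalized by (n-1)(n-2)/2, endpoints excluded;
# closeness per component = (#reachable)/(sum of distances); isolated -> 0.
bf_centralities <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n); cnt <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; cnt[s, s] <- 1
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1; nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] == 1)) {
        if (is.infinite(dist[s, w])) {
          dist[s, w] <- d; nxt <- c(nxt, w); cnt[s, w] <- cnt[s, w] + cnt[s, v]
        } else if (dist[s, w] == d) {
          cnt[s, w] <- cnt[s, w] + cnt[s, v]
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n); clo <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n))
      if (s < t && s != v && t != v && is.finite(dist[s, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t])
        tot <- tot + cnt[s, v] * cnt[v, t] / cnt[s, t]
    btw[v] <- if (n > 2) tot / ((n - 1) * (n - 2) / 2) else 0
    reach <- which(is.finite(dist[v, ]) & seq_len(n) != v)
    clo[v] <- if (length(reach)) length(reach) / sum(dist[v, reach]) else 0
  }
  list(degree = rowSums(adj), betweenness = btw, closeness = clo)
}

# All undirected simple graphs on n labelled nodes, as adjacency matrices.
enumerate_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ne <- nrow(pairs)
  lapply(0:(2^ne - 1), function(mask) {
    adj <- matrix(0L, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
    if (ne > 0) {
      on <- which(bitwAnd(mask, 2^(seq_len(ne) - 1)) > 0)
      for (e in on) {
        adj[pairs[e, 1], pairs[e, 2]] <- 1L
        adj[pairs[e, 2], pairs[e, 1]] <- 1L
      }
    }
    adj
  })
}

# Run a ppin through centrality_metrics and compare with bf_centralities.
centralities_match <- function(adj, tol = 1e-10) {
  n <- nrow(adj)
  el <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  p <- build_ppin(data.frame(a = rownames(adj)[el[, 1]],
                             b = rownames(adj)[el[, 2]],
                             stringsAsFactors = FALSE),
                  node_whitelist = rownames(adj))
  m <- centrality_metrics(p)$metrics
  o <- bf_centralities(adj[m$node, m$node, drop = FALSE])
  max(abs(m$degree - o$degree), abs(m$betweenness - o$betweenness),
      abs(m$closeness - o$closeness)) <= tol
}

# Minimal layout + dataset builders.
tiny_layout <- function(ids) {
  peptide_layout(spot_id = ids,
                 sequence = rep("EEAPEDLYKDFLT", length(ids)),
                 symbol = sub("_.*", "", ids),
                 phospho_positions = rep(list(10L), length(ids)),
                 uniprot_accession = sprintf("P%05d", seq_along(ids)))
}

tiny_dataset <- function(mats, ids = NULL) {
  n <- nrow(mats[[1]])
  if (is.null(ids)) ids <- sprintf("SP%02d_1_13", seq_len(n))
  kinome_dataset(tiny_layout(ids), mats)
}
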