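# Protein-protein interaction network characterization: STRING-style TSV
# loading, density with a random-gene-set simulated null (Box-Cox
# normalized), Louvain module detection and per-module reports.

#' Load a STRING-style interaction TSV as an undirected simple graph
#'
#' Expects a tab-separated file with header columns `node1`, `node2`,
#' `combined_score` (STRING convention: integer confidence 0-1000).
#' Self-loops are dropped, duplicate edges (in either orientation) are
#' merged keeping the maximum score, and edges below `min_score` are
#' discarded.
#'
#' @param path TSV path.
#' @param min_score minimum combined score to retain an edge (default 400,
#'   STRING's "medium confidence").
#' @return an `igraph` undirected graph with edge attribute
#'   `combined_score`.
#' @export
load_interactions <- function(path, min_score = 400) {
  if (!file.exists(path)) stopf("interaction file not found: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("node1", "node2", "combined_score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("interaction TSV lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tab$combined_score <- suppressWarnings(as.numeric(tab$combined_score))
  bad <- which(is.na(tab$node1) | is.na(tab$node2) | is.na(tab$combined_score) |
                 tab$node1 == "" | tab$node2 == "")
  if (length(bad)) stopf("malformed interaction row %d (header is line 1)",
                         bad[1] + 1L)
  interaction_network(tab$node1, tab$node2, tab$combined_score, min_score)
}

#' Build an interaction network from edge vectors
#'
#' @param node1,node2,combined_score parallel edge vectors.
#' @param min_score score threshold applied after deduplication.
#' @return an `igraph` undirected simple graph.
#' @export
interaction_network <- function(node1, node2, combined_score,
                                min_score = 400) {
  a <- pmin(node1, node2)
  b <- pmax(node1, node2)
  keep <- a != b  # drop self-loops
  a <- a[keep]; b <- b[keep]; s <- combined_score[keep]
  key <- paste0(a, "\r", b)
  s <- tapply(s, key, max)
  pair <- do.call(rbind, strsplit(names(s), "\r", fixed = TRUE))
  keep <- s >= min_score
  if (!any(keep)) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  igraph::graph_from_data_frame(
    data.frame(from = pair[keep, 1], to = pair[keep, 2],
               combined_score = as.numeric(s[keep]),
               stringsAsFactors = FALSE),
    directed = FALSE)
}

#' Density of an undirected simple graph
#'
#' The ratio of observed to possible connections, `2E / (n (n - 1))`.
#' @param graph an `igraph` graph with at least 2 nodes.
#' @return density in `[0, 1]`.
#' @export
network_density <- function(graph) {
  if (igraph::vcount(graph) < 2L) stopf("density needs at least 2 nodes")
  igraph::edge_density(graph)
}

#' Simulate the null distribution of induced-subgraph density
#'
#' Repeatedly samples `m` genes uniformly without replacement from the
#' full gene universe, induces the subgraph on the sampled genes and
#' records its density. Universe genes absent from the interaction network
#' enter as isolated nodes (they contribute no edges but count toward the
#' possible-connection denominator). The replicate densities are Box-Cox
#' transformed to approximate normality, and the transformed mean and
#' standard deviation are stored for p-value computation.
#'
#' @param graph an `igraph` network.
#' @param universe character vector of all candidate genes.
#' @param m subgraph size to sample.
#' @param reps number of replicates (default 10000; raise to 100000 for
#'   publication-grade tails).
#' @param seed integer seed.
#' @return object of class `null_density_model`: list with `m`,
#'   `densities`, `shift`, `lambda`, `mean_t`, `sd_t`, `reps`, `seed`.
#' @export
simulate_null_density <- function(graph, universe, m, reps = 10000L,
                                  seed = 1L) {
  if (m < 2L) stopf("subgraph size must be >= 2")
  if (m > length(universe)) stopf("subgraph size exceeds universe")
  set.seed(seed)
  adj <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  idx_of <- match(universe, rownames(adj))  # NA for isolated universe genes
  dens <- vapply(seq_len(reps), function(r) {
    pick <- idx_of[sample.int(length(universe), m)]
    pick <- pick[!is.na(pick)]
    if (length(pick) < 2L) return(0)
    sum(adj[pick, pick]) / (m * (m - 1))
  }, numeric(1))
  bc <- if (length(unique(dens)) == 1L) {
    # degenerate null (e.g. empty or complete network): identity transform
    list(shift = 0, lambda = 1, transformed = dens)
  } else {
    boxcox_transform(dens)
  }
  structure(list(m = m, densities = dens, shift = bc$shift,
                 lambda = bc$lambda, mean_t = mean(bc$transformed),
                 sd_t = sd(bc$transformed), reps = reps, seed = seed),
            class = "null_density_model")
}

#' @export
print.null_density_model <- function(x, ...) {
  cat(sprintf("<null_density_model> m = %d, %d replicates; mean density %.4g; Box-Cox lambda = %.3g, shift = %.3g\n",
              x$m, x$reps, mean(x$densities), x$lambda, x$shift))
  invisible(x)
}

#' Box-Cox power transform with profile-likelihood lambda
#'
#' Shifts the data to positivity (shift 0 when `min > 0`; otherwise
#' `-min` plus half the smallest positive sample, or `1e-6` when all
#' samples are zero), selects lambda by profile maximum likelihood, and
#' applies `((x + shift)^lambda - 1) / lambda` (natural log at
#' `lambda = 0`).
#'
#' @param x numeric samples, length >= 10, not all equal.
#' @param lambda_grid candidate lambdas for the profile search.
#' @return list `shift`, `lambda`, `transformed`.
#' @export
boxcox_transform <- function(x, lambda_grid = seq(-2, 2, by = 0.01)) {
  if (length(x) < 10L) stopf("Box-Cox fit needs >= 10 samples")
  if (length(unique(x)) == 1L) stopf("Box-Cox transform undefined for constant samples")
  shift <- 0
  if (min(x) <= 0) {
    pos <- x[x > 0]
    shift <- -min(x) + if (length(pos)) min(pos) / 2 else 1e-6
  }
  bc <- MASS::boxcox(y ~ 1, data = data.frame(y = x + shift),
                     lambda = lambda_grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  y <- if (abs(lambda) < 1e-12) log(x + shift) else ((x + shift)^lambda - 1) / lambda
  list(shift = shift, lambda = lambda, transformed = y)
}

#' Normal-approximation p-value of an observed density under the null
#'
#' Applies the null model's Box-Cox transform to the observed density and
#' returns the upper-tail normal probability under the transformed null's
#' mean and standard deviation.
#'
#' @param observed observed density.
#' @param null a `null_density_model`.
#' @return upper-tail p-value.
#' @export
density_pvalue <- function(observed, null) {
  if (!is.finite(null$sd_t) || null$sd_t == 0) {
    stopf("degenerate null model (zero variance); p-value undefined")
  }
  z <- observed + null$shift
  if (z <= 0) stopf("observed density below the Box-Cox transform domain")
  t_obs <- if (abs(null$lambda) < 1e-12) log(z) else (z^null$lambda - 1) / null$lambda
  pnorm(t_obs, mean = null$mean_t, sd = null$sd_t, lower.tail = FALSE)
}

#' Louvain community detection
#'
#' Multi-level greedy modularity optimization at resolution 1 on the
#' unweighted graph (set `weighted = TRUE` to use `combined_score` edge
#' weights). The node sweep order is derived from `seed`, making the
#' partition reproducible. Singleton modules are permitted; downstream
#' reporting excludes them from density statistics.
#'
#' @param graph an `igraph` graph.
#' @param seed integer seed.
#' @param weighted use edge weights (default `FALSE`).
#' @return object of class `module_partition`: list with `membership`
#'   (named integer vector, module ids contiguous from 1), `sizes`,
#'   `modularity`, `seed`.
#' @export
louvain_modules <- function(graph, seed = 1L, weighted = FALSE) {
  if (igraph::vcount(graph) == 0L) stopf("empty graph")
  set.seed(seed)
  w <- if (weighted) igraph::E(graph)$combined_score else NA
  cl <- igraph::cluster_louvain(graph, weights = w)
  memb <- igraph::membership(cl)
  structure(list(membership = memb,
                 sizes = as.integer(table(memb)),
                 modularity = igraph::modularity(graph, memb,
                                                 weights = if (weighted) w else NULL),
                 seed = seed),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules over %d nodes (sizes %s), modularity %.3f\n",
              length(x$sizes), length(x$membership),
              paste(sort(x$sizes, decreasing = TRUE), collapse = ", "),
              x$modularity))
  invisible(x)
}

#' Per-module density report with simulated-null p-values
#'
#' For every module of size >= 2, the induced-subgraph density and its
#' p-value against a simulated random-gene-set null of matching size
#' (see [simulate_null_density()]). Modules of a single protein have no
#' defined density and are flagged excluded. Node degrees are computed in
#' the full analyzed network.
#'
#' @param graph the analyzed `igraph` network.
#' @param partition a `module_partition`.
#' @param universe gene universe for null sampling.
#' @param reps null replicates per module size (default 1000).
#' @param seed integer seed.
#' @return list with `modules` (data.frame `module`, `size`, `density`,
#'   `p_value`, `excluded`) and `degrees` (data.frame `gene`, `module`,
#'   `degree`).
#' @export
module_report <- function(graph, partition, universe, reps = 1000L,
                          seed = 1L) {
  memb <- partition$membership
  ids <- sort(unique(as.integer(memb)))
  rows <- lapply(ids, function(mod) {
    nodes <- names(memb)[memb == mod]
    if (length(nodes) < 2L) {
      return(data.frame(module = mod, size = length(nodes), density = NA_real_,
                        p_value = NA_real_, excluded = TRUE))
    }
    sub <- igraph::induced_subgraph(graph, nodes)
    d <- network_density(sub)
    null <- simulate_null_density(graph, universe, m = length(nodes),
                                  reps = reps, seed = seed + mod)
    data.frame(module = mod, size = length(nodes), density = d,
               p_value = density_pvalue(d, null), excluded = FALSE)
  })
  degrees <- data.frame(gene = names(memb), module = as.integer(memb),
                        degree = as.integer(igraph::degree(graph)[names(memb)]),
                        stringsAsFactors = FALSE)
  list(modules = do.call(rbind, rows),
       degrees = degrees[order(-degrees$degree), ])
}
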