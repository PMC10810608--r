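#' Levenshtein edit distance between two strings
#'
#' Standard unit-cost edit distance (substitutions, insertions, deletions)
#' by dynamic programming, with an optional early-exit bound: with a finite
#' `max_dist` the function may return any value greater than the bound when
#' the true distance exceeds it, but always agrees with the full DP when
#' the true distance is within the bound.
#'
#' @param a,b character strings (amino-acid alphabet expected, any
#'   characters accepted).
#' @param max_dist optional non-negative bound for early exit.
#' @return Integer distance.
#' @examples
#' levenshtein("CARGW", "CARGF")  # 1 substitution
#' levenshtein("CARW", "CARGW")   # 1 insertion
#' @export
levenshtein <- function(a, b, max_dist = Inf) {
  if (a == b) return(0L)
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (abs(n - m) > max_dist) return(abs(n - m))
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    sub_cost <- prev[1:m] + (x[i] != y)
    for (jj in seq_len(m)) {
      cur[jj + 1L] <- min(sub_cost[jj], prev[jj + 1L] + 1L, cur[jj] + 1L)
    }
    if (min(cur) > max_dist) return(min(cur))
    prev <- cur
  }
  prev[m + 1L]
}

# all single-deletion variants of a string
.deletion_variants <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i)
    paste0(substr(s, 1L, i - 1L), substr(s, i + 1L, n)), "")
}

#' Build a CDR3 similarity network (Levenshtein distance 1)
#'
#' Nodes are unique CDR3 amino-acid strings; an edge connects two nodes
#' exactly when their sequences lie at Levenshtein distance 1 (one
#' substitution, insertion or deletion). Construction uses
#' deletion-neighborhood hashing -- every string is keyed by itself and by
#' each of its single-deletion variants, candidate pairs share a key and
#' are verified by exact distance computation -- so runtime scales with the
#' total neighborhood size rather than the number of string pairs.
#' Connected components mark groups of similar CDR3s; components with at
#' least `min_cluster_size` nodes are flagged as expanded (clonal-expansion
#' candidates).
#'
#' @param cdr3 character vector of unique CDR3 amino-acid strings.
#' @param counts optional abundance per CDR3 (defaults to 1).
#' @param min_cluster_size component size from which a component is flagged
#'   expanded.
#' @param metric `"levenshtein"` (default; includes length +/- 1 indels) or
#'   `"hamming"` (substitutions only, equal lengths).
#' @return An object of class `cdr3_network`: list(nodes = tibble(cdr3_aa,
#'   count, component, expanded), edges = tibble(source, target),
#'   min_cluster_size, metric).
#' @examples
#' net <- build_cdr3_network(c("CARGW", "CARGF", "CTTTW"))
#' nrow(net$edges)  # 1: CARGW - CARGF
#' @export
build_cdr3_network <- function(cdr3, counts = NULL, min_cluster_size = 3,
                               metric = c("levenshtein", "hamming")) {
  metric <- match.arg(metric)
  if (anyDuplicated(cdr3)) stop("input CDR3 strings must be unique")
  n <- length(cdr3)
  if (is.null(counts)) counts <- rep(1L, n)
  stopifnot(length(counts) == n)

  pair_ok <- function(i, j) {
    if (metric == "hamming") {
      nchar(cdr3[i]) == nchar(cdr3[j]) &&
        sum(strsplit(cdr3[i], "")[[1]] != strsplit(cdr3[j], "")[[1]]) == 1L
    } else {
      levenshtein(cdr3[i], cdr3[j], max_dist = 1L) == 1L
    }
  }

  edges_i <- integer(0); edges_j <- integer(0)
  if (n >= 2) {
    key_list <- vector("list", n)
    for (i in seq_len(n)) key_list[[i]] <- c(cdr3[i], .deletion_variants(cdr3[i]))
    keys <- unlist(key_list, use.names = FALSE)
    owner <- rep(seq_len(n), lengths(key_list))
    grp <- split(seq_along(keys), keys)
    seen <- new.env(hash = TRUE)
    for (g in grp) {
      if (length(g) < 2) next
      members <- owner[g]
      for (ii in seq_len(length(g) - 1L)) {
        for (jj in seq(ii + 1L, length(g))) {
          u <- members[ii]; v <- members[jj]
          if (u == v) next
          a <- min(u, v); b <- max(u, v)
          key <- paste0(a, ":", b)
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          if (pair_ok(a, b)) {
            edges_i <- c(edges_i, a); edges_j <- c(edges_j, b)
          }
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges_i))
    g <- igraph::add_edges(g, rbind(edges_i, edges_j))
  comp <- igraph::components(g)
  expanded_ids <- which(comp$csize >= min_cluster_size)
  nodes <- tibble(cdr3_aa = cdr3, count = as.integer(counts),
                  component = as.integer(comp$membership),
                  expanded = comp$membership %in% expanded_ids)
  edges <- tibble(source = cdr3[edges_i], target = cdr3[edges_j])
  structure(list(nodes = nodes, edges = edges,
                 min_cluster_size = min_cluster_size, metric = metric),
            class = "cdr3_network")
}

#' @export
print.cdr3_network <- function(x, ...) {
  cat(sprintf("<cdr3_network> %d nodes, %d edges, %d components (%d expanded)\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$component)),
              length(unique(x$nodes$component[x$nodes$expanded]))))
  invisible(x)
}

#' Export / read back a similarity network
#'
#' Writes the edge list (source, target) and node attributes (cdr3_aa,
#' count, component, expanded) as TSV, optionally also GraphML for network
#' viewers. `read_cdr3_network` reconstructs the network losslessly from
#' the two TSVs.
#'
#' @param net a `cdr3_network`.
#' @param edge_path,node_path output TSV paths.
#' @param graphml_path optional GraphML output path.
#' @return Invisibly, the written paths.
#' @export
export_network <- function(net, edge_path, node_path, graphml_path = NULL) {
  readr::write_tsv(net$edges, edge_path, progress = FALSE)
  readr::write_tsv(net$nodes, node_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(c(edges = edge_path, nodes = node_path))
}

#' @rdname export_network
#' @param min_cluster_size,metric metadata restored onto the read network.
#' @export
read_cdr3_network <- function(edge_path, node_path, min_cluster_size = 3,
                              metric = "levenshtein") {
  edges <- readr::read_tsv(edge_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  nodes <- readr::read_tsv(node_path, show_col_types = FALSE,
                           col_types = readr::cols(cdr3_aa = "c", count = "i",
                                                   component = "i",
                                                   expanded = "l"))
  structure(list(nodes = as_tibble(nodes), edges = as_tibble(edges),
                 min_cluster_size = min_cluster_size, metric = metric),
            class = "cdr3_network")
}
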