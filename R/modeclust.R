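## Binding-mode comparison and clustering.
##
## Interaction graphs are compared with a subgraph matching kernel: the raw
## kernel sums, over all injective label-preserving mappings of up to
## `max_nodes` nodes (each counted once as a set of node pairs), the product
## of edge kernels k_e(d1, d2) = max(0, 1 - |d1 - d2| / dmax) over the mapped
## edge pairs. The value reported is the cosine normalization
## k(g1,g2) / sqrt(k(g1,g1) k(g2,g2)), in [0, 1]. Binding modes are clusters
## of graphs under DBSCAN on 1 - similarity (eps = 0.23, min_samples = 2),
## with isolated graphs counting as their own mode, followed by a correction
## that merges clusters whose graphs embed into the graphs of another
## cluster.

smk_edge_kernel <- function(d1, d2, dmax) pmax(0, 1 - abs(d1 - d2) / dmax)

## raw kernel by vectorized enumeration over compatible node pairs
smk_raw <- function(g1, g2, max_nodes = 3L, dmax = 1.0) {
  n1 <- graph_size(g1); n2 <- graph_size(g2)
  if (n1 == 0L || n2 == 0L) return(0)
  comp <- which(outer(g1$nodes$label, g2$nodes$label, "=="), arr.ind = TRUE)
  m <- nrow(comp)
  if (m == 0L) return(0)
  total <- m  # size-1 mappings, node kernel = 1
  if (max_nodes >= 2L && m >= 2L) {
    pairs <- utils::combn(m, 2)
    i1 <- comp[pairs[1, ], 1]; i2 <- comp[pairs[2, ], 1]
    j1 <- comp[pairs[1, ], 2]; j2 <- comp[pairs[2, ], 2]
    ok <- i1 != i2 & j1 != j2
    if (any(ok)) {
      w <- smk_edge_kernel(g1$D[cbind(i1[ok], i2[ok])],
                           g2$D[cbind(j1[ok], j2[ok])], dmax)
      total <- total + sum(w)
      if (max_nodes >= 3L && m >= 3L) {
        trip <- utils::combn(m, 3)
        a <- comp[trip[1, ], , drop = FALSE]
        b <- comp[trip[2, ], , drop = FALSE]
        c_ <- comp[trip[3, ], , drop = FALSE]
        ok3 <- a[, 1] != b[, 1] & a[, 1] != c_[, 1] & b[, 1] != c_[, 1] &
          a[, 2] != b[, 2] & a[, 2] != c_[, 2] & b[, 2] != c_[, 2]
        if (any(ok3)) {
          a <- a[ok3, , drop = FALSE]; b <- b[ok3, , drop = FALSE]
          c_ <- c_[ok3, , drop = FALSE]
          w3 <- smk_edge_kernel(g1$D[cbind(a[, 1], b[, 1])],
                                g2$D[cbind(a[, 2], b[, 2])], dmax) *
            smk_edge_kernel(g1$D[cbind(a[, 1], c_[, 1])],
                            g2$D[cbind(a[, 2], c_[, 2])], dmax) *
            smk_edge_kernel(g1$D[cbind(b[, 1], c_[, 1])],
                            g2$D[cbind(b[, 2], c_[, 2])], dmax)
          total <- total + sum(w3)
        }
      }
    }
  }
  total
}

#' Subgraph matching kernel similarity between interaction graphs
#'
#' Normalized similarity in [0, 1]; 1 for identical nonempty graphs, 0 when
#' the graphs share no node label (or either graph is empty).
#'
#' @param g1,g2 \code{interaction_graph} objects.
#' @param max_nodes maximum mapped subgraph size (default 3).
#' @param edge_dmax edge kernel tolerance in Angstrom (default 1).
#' @return A similarity score in [0, 1].
#' @examples
#' g <- build_interaction_graph(data.frame(
#'   itype = "HYDROPHOBIC", lig_atom = 1:2, prot_atom = 1:2,
#'   distance = 4, angle = NA, lx = c(0, 2), ly = 0, lz = 0,
#'   px = c(0, 2), py = 0, pz = 4))
#' smk_similarity(g, g)  # 1
#' @export
smk_similarity <- function(g1, g2, max_nodes = 3L, edge_dmax = 1.0) {
  if (graph_size(g1) == 0L || graph_size(g2) == 0L) return(0)
  k12 <- smk_raw(g1, g2, max_nodes, edge_dmax)
  if (k12 == 0) return(0)
  k11 <- smk_raw(g1, g1, max_nodes, edge_dmax)
  k22 <- smk_raw(g2, g2, max_nodes, edge_dmax)
  min(1, k12 / sqrt(k11 * k22))
}

## all-pairs similarity matrix for a list of graphs
smk_matrix <- function(graphs, max_nodes = 3L, edge_dmax = 1.0) {
  n <- length(graphs)
  S <- diag(1, n)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    S[i, j] <- S[j, i] <- smk_similarity(graphs[[i]], graphs[[j]],
                                         max_nodes, edge_dmax)
  }
  ## empty graphs have self-similarity 0 by the empty-vs-any convention,
  ## but keep the diagonal at 1 so each empty graph clusters with nothing
  S
}

#' DBSCAN on a precomputed distance matrix
#'
#' Standard density-based clustering. With \code{min_samples = 2} the
#' clusters are exactly the connected components of the eps-threshold graph
#' and noise points are the isolated items.
#'
#' @param distances symmetric nonnegative matrix with zero diagonal.
#' @param eps neighborhood radius (a point's eps-neighborhood includes
#'   itself).
#' @param min_samples minimum neighborhood size for a core point.
#' @return Integer cluster labels (1, 2, ...) with noise marked 0.
#' @examples
#' d <- matrix(c(0, .1, .1, 0), 2)
#' dbscan_precomputed(d, eps = 0.23, min_samples = 2)
#' @export
dbscan_precomputed <- function(distances, eps, min_samples = 2L) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n == 0L) return(integer())
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(d < -1e-12) || any(abs(diag(d)) > 1e-8))
    stop("distance matrix must be nonnegative with zero diagonal")
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cid <- cid + 1L
    labels[i] <- cid
    frontier <- setdiff(nb[[i]], i)
    while (length(frontier)) {
      q <- frontier[1]; frontier <- frontier[-1]
      if (labels[q] == 0L) {
        labels[q] <- cid
        if (core[q]) frontier <- union(frontier, setdiff(nb[[q]],
                                                         which(labels != 0L)))
      }
    }
  }
  labels
}

#' Count the binding modes of a fragment
#'
#' Clusters the interaction graphs of all observations of one fragment by
#' DBSCAN on 1 - kernel similarity (eps = \code{config$mode_eps},
#' min_samples = 2). Noise graphs each count as their own binding mode. The
#' inclusion-merge correction ([merge_included_clusters()]) is then applied.
#'
#' @param graphs list of \code{interaction_graph} objects (>= 1).
#' @param config a [pipeline_config()].
#' @return An object of class \code{"mode_clustering"}: \code{labels} (one
#'   per graph, after merging), \code{n_modes}, \code{merged_pairs}.
#' @export
count_binding_modes <- function(graphs, config = pipeline_config()) {
  stopifnot(length(graphs) >= 1L)
  S <- smk_matrix(graphs, config$smk_max_nodes, config$smk_edge_dmax)
  d <- 1 - S
  d[d < 0] <- 0
  diag(d) <- 0
  labels <- dbscan_precomputed(d, config$mode_eps, config$cluster_min_samples)
  ## noise graphs become singleton modes
  nz <- max(labels, 0L)
  for (i in which(labels == 0L)) {
    nz <- nz + 1L
    labels[i] <- nz
  }
  clust <- list(labels = labels, n_modes = length(unique(labels)),
                merged_pairs = list())
  class(clust) <- "mode_clustering"
  merge_included_clusters(clust, graphs, edge_tol = config$edge_tol)
}

#' @export
print.mode_clustering <- function(x, ...) {
  cat(sprintf("<mode_clustering: %d mode(s) over %d graph(s)%s>\n",
              x$n_modes, length(x$labels),
              if (length(x$merged_pairs))
                sprintf(", %d merge(s)", length(x$merged_pairs)) else ""))
  invisible(x)
}

#' Test whether one interaction graph embeds into another
#'
#' TRUE iff there is an injective label-preserving mapping of all nodes of
#' \code{g_small} into \code{g_big} such that every pair of mapped nodes has
#' an edge-length difference at most \code{edge_tol}.
#'
#' @param g_small,g_big \code{interaction_graph} objects.
#' @param edge_tol edge-length tolerance in Angstrom (default 0.5).
#' @return Logical flag.
#' @export
graph_included <- function(g_small, g_big, edge_tol = 0.5) {
  ns <- graph_size(g_small); nb <- graph_size(g_big)
  if (ns == 0L) return(TRUE)
  if (ns > nb) return(FALSE)
  cand <- lapply(seq_len(ns), function(i)
    which(g_big$nodes$label == g_small$nodes$label[i]))
  if (any(vapply(cand, length, integer(1)) == 0L)) return(FALSE)
  assign_next <- function(k, mapped) {
    if (k > ns) return(TRUE)
    for (j in setdiff(cand[[k]], mapped)) {
      ok <- TRUE
      if (k > 1L) for (p in seq_len(k - 1L)) {
        if (abs(g_small$D[p, k] - g_big$D[mapped[p], j]) > edge_tol) {
          ok <- FALSE; break
        }
      }
      if (ok && assign_next(k + 1L, c(mapped, j))) return(TRUE)
    }
    FALSE
  }
  assign_next(1L, integer())
}

#' Merge binding-mode clusters related by graph inclusion
#'
#' Clusters A and B are merged when every graph of A embeds
#' ([graph_included()]) into at least one graph of B; the merge relation is
#' closed transitively. This corrects the over-splitting that occurs when one
#' binding mode is a sub-pattern of another. Never increases the mode count;
#' idempotent.
#'
#' @param clustering a \code{mode_clustering}.
#' @param graphs the graphs that were clustered.
#' @param edge_tol embedding edge tolerance in Angstrom.
#' @return The corrected \code{mode_clustering}.
#' @export
merge_included_clusters <- function(clustering, graphs, edge_tol = 0.5) {
  labels <- clustering$labels
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k <= 1L) {
    clustering$n_modes <- k
    return(clustering)
  }
  members <- lapply(ids, function(cl) which(labels == cl))
  ## inclusion relation between clusters
  merge_edges <- list()
  for (ai in seq_len(k)) for (bi in seq_len(k)) {
    if (ai == bi) next
    all_in <- all(vapply(members[[ai]], function(gi) {
      any(vapply(members[[bi]], function(gj)
        graph_included(graphs[[gi]], graphs[[gj]], edge_tol), logical(1)))
    }, logical(1)))
    if (all_in) merge_edges[[length(merge_edges) + 1L]] <- c(ai, bi)
  }
  if (length(merge_edges)) {
    g <- igraph::make_empty_graph(n = k, directed = FALSE)
    g <- igraph::add_edges(g, unlist(merge_edges))
    comp <- igraph::components(g)$membership
    new_labels <- comp[match(labels, ids)]
    clustering$merged_pairs <- c(clustering$merged_pairs,
                                 lapply(merge_edges, function(e) ids[e]))
    labels <- as.integer(new_labels)
  } else {
    labels <- match(labels, ids)
  }
  clustering$labels <- labels
  clustering$n_modes <- length(unique(labels))
  clustering
}

#' Symmetry-aware conformer RMSD
#'
#' Minimum heavy-atom RMSD between two conformers of the same chemical
#' species after optimal rigid superposition, minimized over the automorphism
#' group of the molecular graph (so that, e.g., a benzene ring rotated by 60
#' degrees in its plane scores 0).
#'
#' @param conf1,conf2 \code{molecule} objects with identical molecular
#'   graphs.
#' @param max_maps cap on the number of automorphisms examined.
#' @return RMSD in Angstrom.
#' @export
symmetry_rmsd <- function(conf1, conf2, max_maps = 10000L) {
  g1 <- mol_graph(conf1); g2 <- mol_graph(conf2)
  if (igraph::vcount(g1) != igraph::vcount(g2) ||
      igraph::ecount(g1) != igraph::ecount(g2))
    stop("conformers are not the same chemical species")
  col1 <- as.integer(factor(igraph::V(g1)$element,
                            levels = sort(unique(c(igraph::V(g1)$element,
                                                   igraph::V(g2)$element)))))
  col2 <- as.integer(factor(igraph::V(g2)$element,
                            levels = sort(unique(c(igraph::V(g1)$element,
                                                   igraph::V(g2)$element)))))
  maps <- igraph::subgraph_isomorphisms(
    g1, g2, method = "vf2",
    vertex.color1 = col2, vertex.color2 = col1)
  if (length(maps) == 0L)
    stop("conformers are not the same chemical species")
  if (length(maps) > max_maps) maps <- maps[seq_len(max_maps)]
  xyz1 <- heavy_coords(conf1)
  xyz2 <- heavy_coords(conf2)
  best <- Inf
  for (m in maps) {
    perm <- as.integer(m)
    fit <- kabsch_superpose(xyz2[perm, , drop = FALSE], xyz1)
    if (fit$rmsd < best) best <- fit$rmsd
  }
  best
}
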