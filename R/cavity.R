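## Binding-cavity description and comparison.
##
## A cavity is described as a cloud of lattice points around the bound
## fragment (within 4 A of its heavy atoms, clash-free, buried), each labeled
## with the pharmacophoric property of the nearest protein heavy atom
## (charged > H-bonding > aromatic > hydrophobic precedence, DUMMY when no
## protein atom lies within 4 A). Clouds are compared by label-aware rigid
## registration: descriptor-matched candidate correspondences, RANSAC over
## 3-point samples, label-constrained ICP refinement, scored as the fraction
## of points of the smaller cloud with a same-label counterpart within the
## inlier distance after alignment. Comparison runs in both directions and
## keeps the best score.

CLOUD_LABELS <- c("HYDROPHOBIC", "AROMATIC", "HB_DONOR", "HB_ACCEPTOR",
                  "POSITIVE", "NEGATIVE", "DUMMY")

## the 14 lattice ray directions: 6 axes + 8 cube diagonals
RAY_DIRECTIONS <- {
  ax <- rbind(diag(3), -diag(3))
  dg <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  unname(rbind(ax, dg))
}

new_labeled_cloud <- function(points, labels, spacing) {
  stopifnot(nrow(points) == length(labels))
  cl <- list(points = as.matrix(points), labels = as.character(labels),
             spacing = spacing)
  class(cl) <- "labeled_cloud"
  cl
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat(sprintf("<labeled_cloud: %d point(s), spacing %g A>\n",
              nrow(x$points), x$spacing))
  if (nrow(x$points)) print(table(x$labels))
  invisible(x)
}

## pharmacophoric label of each protein heavy atom, with precedence
## charged > H-bonding > aromatic > hydrophobic > DUMMY
protein_atom_pharm_labels <- function(res) {
  roles <- protein_atom_roles(res)
  phobic <- protein_hydrophobic(res, roles)
  lab <- rep("DUMMY", nrow(res))
  lab[phobic] <- "HYDROPHOBIC"
  lab[roles$aromatic] <- "AROMATIC"
  lab[roles$acceptor] <- "HB_ACCEPTOR"
  lab[roles$donor] <- "HB_DONOR"
  lab[roles$pos] <- "POSITIVE"
  lab[roles$neg] <- "NEGATIVE"
  lab
}

#' Generate the pharmacophore-labeled cavity cloud around a bound fragment
#'
#' Lattice points (spacing \code{config$grid_spacing}) are kept iff they are
#' (a) at least \code{config$clash_dist} from every protein heavy atom,
#' (b) within \code{config$cavity_fragment_dist} (4 A) of a fragment heavy
#' atom, and (c) buried: at least \code{config$buriedness_min} of 14 lattice
#' ray directions hit a protein heavy atom within \code{config$ray_length}.
#' Each kept point is labeled by the pharmacophoric type of the nearest
#' protein heavy atom within 4 A, else DUMMY.
#'
#' @param site a \code{protein_site} (nonempty).
#' @param ligand the matching ligand instance.
#' @param config a [pipeline_config()].
#' @return A \code{labeled_cloud}; zero points flag an unusable entry.
#' @export
generate_cavity_cloud <- function(site, ligand, config = pipeline_config()) {
  res <- site$residues
  frag <- heavy_coords(ligand$molecule)
  spacing <- config$grid_spacing
  if (nrow(res) == 0L || nrow(frag) == 0L)
    return(new_labeled_cloud(matrix(numeric(0), 0, 3), character(), spacing))
  prot <- as.matrix(res[!res$is_h, c("x", "y", "z")])
  rng <- apply(frag, 2, range)
  lo <- floor((rng[1, ] - config$cavity_fragment_dist) / spacing) * spacing
  hi <- ceiling((rng[2, ] + config$cavity_fragment_dist) / spacing) * spacing
  grid <- as.matrix(expand.grid(seq(lo[1], hi[1], by = spacing),
                                seq(lo[2], hi[2], by = spacing),
                                seq(lo[3], hi[3], by = spacing)))
  colnames(grid) <- NULL
  ## (b) near the fragment
  dfrag <- cross_dist(grid, frag)
  keep <- apply(dfrag, 1, min) <= config$cavity_fragment_dist
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L)
    return(new_labeled_cloud(matrix(numeric(0), 0, 3), character(), spacing))
  ## (a) clash-free
  dprot <- cross_dist(grid, prot)
  mind <- apply(dprot, 1, min)
  keep <- mind >= config$clash_dist
  grid <- grid[keep, , drop = FALSE]
  dprot <- dprot[keep, , drop = FALSE]
  mind <- mind[keep]
  if (nrow(grid) == 0L)
    return(new_labeled_cloud(matrix(numeric(0), 0, 3), character(), spacing))
  ## (c) buriedness: ray k from point x is blocked if some protein atom
  ## projects onto it at 0 < t <= ray_length with perpendicular offset
  ## <= ray_width
  buried <- vapply(seq_len(nrow(grid)), function(i) {
    v <- sweep(prot, 2, grid[i, ])  # vectors to protein atoms
    t_ <- v %*% t(RAY_DIRECTIONS)   # projections, n_prot x 14
    vv <- rowSums(v^2)
    perp2 <- pmax(0, vv - t_^2)
    hits <- colSums(t_ > 0 & t_ <= config$ray_length &
                      perp2 <= config$ray_width^2) > 0
    sum(hits) >= config$buriedness_min
  }, logical(1))
  grid <- grid[buried, , drop = FALSE]
  dprot <- dprot[buried, , drop = FALSE]
  if (nrow(grid) == 0L)
    return(new_labeled_cloud(matrix(numeric(0), 0, 3), character(), spacing))
  atom_lab <- protein_atom_pharm_labels(res[!res$is_h, , drop = FALSE])
  nearest <- apply(dprot, 1, which.min)
  nearest_d <- dprot[cbind(seq_len(nrow(grid)), nearest)]
  labels <- ifelse(nearest_d <= 4.0, atom_lab[nearest], "DUMMY")
  new_labeled_cloud(grid, labels, spacing)
}

## per-point descriptor: neighbor label histogram in two distance shells
## (0-2 A, 2-4 A) x 7 labels
cloud_descriptors <- function(cloud) {
  n <- nrow(cloud$points)
  D <- cross_dist(cloud$points, cloud$points)
  lab_idx <- match(cloud$labels, CLOUD_LABELS)
  desc <- matrix(0, n, 14)
  for (i in seq_len(n)) {
    near <- which(D[i, ] > 0 & D[i, ] <= 2)
    far <- which(D[i, ] > 2 & D[i, ] <= 4)
    if (length(near)) desc[i, 1:7] <- tabulate(lab_idx[near], 7)
    if (length(far)) desc[i, 8:14] <- tabulate(lab_idx[far], 7)
  }
  desc
}

## same-label inlier fraction of the smaller cloud after alignment of
## `moving` (transformed coordinates) onto `fixed`
cloud_overlap_score <- function(moving_pts, moving_lab, fixed, inlier_dist) {
  small_is_moving <- nrow(moving_pts) <= nrow(fixed$points)
  D <- cross_dist(moving_pts, fixed$points)
  same <- outer(moving_lab, fixed$labels, "==")
  D[!same] <- Inf
  if (small_is_moving) {
    matched <- apply(D, 1, min) <= inlier_dist
  } else {
    matched <- apply(D, 2, min) <= inlier_dist
  }
  mean(matched)
}

## descriptor cache: clouds are immutable once built
cloud_descriptors_cached <- function(cloud) {
  d <- attr(cloud, "descriptors")
  if (is.null(d)) d <- cloud_descriptors(cloud)
  d
}

## one-directional registration: align cloud a onto cloud b
register_clouds <- function(a, b, config,
                            desc_a = cloud_descriptors_cached(a),
                            desc_b = cloud_descriptors_cached(b)) {
  na <- nrow(a$points); nb <- nrow(b$points)
  ## candidate correspondences: same label, top-3 descriptor matches
  cand <- list()
  for (i in seq_len(na)) {
    js <- which(b$labels == a$labels[i])
    if (!length(js)) next
    dd <- colSums((t(desc_b[js, , drop = FALSE]) - desc_a[i, ])^2)
    js <- js[order(dd)][seq_len(min(3L, length(js)))]
    for (j in js) cand[[length(cand) + 1L]] <- c(i, j)
  }
  if (length(cand) < 3L) return(NULL)
  cand <- do.call(rbind, cand)
  n_small <- min(na, nb)
  best <- list(score = -1, transform = NULL)
  n_iter <- config$ransac_iter
  for (it in seq_len(n_iter)) {
    rows <- sample.int(nrow(cand), 3L)
    ai <- cand[rows, 1]; bj <- cand[rows, 2]
    if (anyDuplicated(ai) || anyDuplicated(bj)) next
    pa <- a$points[ai, , drop = FALSE]
    pb <- b$points[bj, , drop = FALSE]
    ## reject degenerate (near-collinear) samples
    if (svd(sweep(pa, 2, colMeans(pa)))$d[2] < 0.4) next
    fit <- tryCatch(kabsch_superpose(pb, pa), error = function(e) NULL)
    if (is.null(fit)) next
    moved <- apply_transform(a$points, fit)
    sc <- cloud_overlap_score(moved, a$labels, b, config$inlier_dist)
    if (sc > best$score) {
      best$score <- sc
      best$transform <- fit
    }
    if (best$score >= 0.95) break
    ## plateau exit: with no usable correspondences the score cannot improve
    if (it >= 50L && best$score < 0.3) break
  }
  if (is.null(best$transform)) return(NULL)
  ## label-constrained ICP refinement
  transform <- best$transform
  for (iter in seq_len(8L)) {
    moved <- apply_transform(a$points, transform)
    D <- cross_dist(moved, b$points)
    same <- outer(a$labels, b$labels, "==")
    D[!same] <- Inf
    j <- apply(D, 1, which.min)
    dmin <- D[cbind(seq_len(na), j)]
    sel <- which(is.finite(dmin) & dmin <= 2.5)
    if (length(sel) < 3L) break
    fit <- tryCatch(kabsch_superpose(b$points[j[sel], , drop = FALSE],
                                     a$points[sel, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) break
    moved2 <- apply_transform(a$points, fit)
    sc <- cloud_overlap_score(moved2, a$labels, b, config$inlier_dist)
    if (sc >= best$score) {
      best$score <- sc
      transform <- fit
      best$transform <- fit
    } else break
  }
  best
}

#' Compare two binding-cavity clouds by rigid registration
#'
#' Aligns the clouds by label-aware descriptor matching, RANSAC over 3-point
#' correspondences and label-constrained ICP, then scores the alignment as
#' the fraction of points of the smaller cloud having a same-label
#' counterpart within \code{config$inlier_dist} (1.5 A). The comparison is
#' run in both directions and the best score is retained. Clouds with fewer
#' than 3 points are scored by direct label-bag overlap and flagged
#' low-confidence.
#'
#' @param c1,c2 \code{labeled_cloud} objects (nonempty).
#' @param config a [pipeline_config()].
#' @param seed RNG seed for the RANSAC sampling (default
#'   \code{config$random_seed}).
#' @return An object of class \code{"cavity_comparison"}: \code{score} in
#'   [0, 1], \code{transform} (rotation + translation), \code{direction}
#'   (1 if cloud 1 was moved onto cloud 2), \code{low_confidence}.
#' @export
cavity_similarity <- function(c1, c2, config = pipeline_config(),
                              seed = config$random_seed) {
  stopifnot(inherits(c1, "labeled_cloud"), inherits(c2, "labeled_cloud"))
  if (nrow(c1$points) == 0L || nrow(c2$points) == 0L)
    stop("cavity clouds must be nonempty")
  if (length(intersect(c1$labels, c2$labels)) == 0L) {
    cmp <- list(score = 0, transform = NULL, direction = NA_integer_,
                low_confidence = FALSE)
    class(cmp) <- "cavity_comparison"
    return(cmp)
  }
  if (nrow(c1$points) < 3L || nrow(c2$points) < 3L) {
    t1 <- table(factor(c1$labels, levels = CLOUD_LABELS))
    t2 <- table(factor(c2$labels, levels = CLOUD_LABELS))
    sc <- sum(pmin(t1, t2)) / min(nrow(c1$points), nrow(c2$points))
    cmp <- list(score = as.numeric(sc), transform = NULL,
                direction = NA_integer_, low_confidence = TRUE)
    class(cmp) <- "cavity_comparison"
    return(cmp)
  }
  d1 <- cloud_descriptors_cached(c1)
  d2 <- cloud_descriptors_cached(c2)
  res <- with_seed(seed, {
    r12 <- register_clouds(c1, c2, config, d1, d2)
    r21 <- if (!is.null(r12) && r12$score >= 0.95) NULL else
      register_clouds(c2, c1, config, d2, d1)
    list(r12 = r12, r21 = r21)
  })
  s12 <- if (is.null(res$r12)) -1 else res$r12$score
  s21 <- if (is.null(res$r21)) -1 else res$r21$score
  if (s12 < 0 && s21 < 0) {
    cmp <- list(score = 0, transform = NULL, direction = NA_integer_,
                low_confidence = TRUE)
    class(cmp) <- "cavity_comparison"
    return(cmp)
  }
  direction <- if (s12 >= s21) 1L else 2L
  best <- if (direction == 1L) res$r12 else res$r21
  cmp <- list(score = max(0, min(1, best$score)), transform = best$transform,
              direction = direction, low_confidence = FALSE)
  class(cmp) <- "cavity_comparison"
  cmp
}

#' @export
print.cavity_comparison <- function(x, ...) {
  cat(sprintf("<cavity_comparison: score %.3f%s>\n", x$score,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Count the distinct binding cavities of a fragment
#'
#' All-against-all cavity comparison followed by DBSCAN (min_samples = 2) on
#' 1 - score. By default two observations cluster together iff their score is
#' at least \code{config$cavity_score_threshold} (0.47), the recommended
#' decision value for similar sites; \code{literal_eps = TRUE} instead uses
#' eps = 0.47 on the distance itself (i.e. clusters at score > 0.53). Noise
#' observations each count as a distinct cavity.
#'
#' @param clouds list of nonempty \code{labeled_cloud} objects (>= 1).
#' @param config a [pipeline_config()].
#' @param literal_eps strict reading of eps = 0.47 on 1 - score.
#' @param seed RNG seed for the registration step.
#' @return Integer: the number of distinct cavities (>= 1).
#' @export
count_cavities <- function(clouds, config = pipeline_config(),
                           literal_eps = FALSE, seed = config$random_seed) {
  stopifnot(length(clouds) >= 1L)
  n <- length(clouds)
  if (n == 1L) return(1L)
  clouds <- lapply(clouds, function(cl) {
    attr(cl, "descriptors") <- cloud_descriptors_cached(cl)
    cl
  })
  S <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    S[i, j] <- S[j, i] <- cavity_similarity(clouds[[i]], clouds[[j]], config,
                                            seed = seed + 131L * i + j)$score
  }
  d <- 1 - S
  diag(d) <- 0
  eps <- if (literal_eps) 0.47 else 1 - config$cavity_score_threshold
  labels <- dbscan_precomputed(d, eps, config$cluster_min_samples)
  length(unique(labels[labels != 0L])) + sum(labels == 0L)
}

#' Write a labeled cloud as MOL2 or XYZ-with-label text
#'
#' @param cloud a \code{labeled_cloud}.
#' @param path output path.
#' @param format \code{"mol2"} (label-encoded atom names) or \code{"xyz"}
#'   (x, y, z, label columns).
#' @export
write_cloud <- function(cloud, path, format = c("mol2", "xyz")) {
  format <- match.arg(format)
  if (format == "xyz") {
    utils::write.table(
      data.frame(x = cloud$points[, 1], y = cloud$points[, 2],
                 z = cloud$points[, 3], label = cloud$labels),
      path, row.names = FALSE, quote = FALSE, sep = "\t")
    return(invisible(path))
  }
  lab <- substr(gsub("_", "", cloud$labels), 1, 6)
  mol <- molecule(data.frame(
    name = paste0(lab, seq_len(nrow(cloud$points))), element = "C",
    x = cloud$points[, 1], y = cloud$points[, 2], z = cloud$points[, 3]))
  write_mol2(mol, path, name = "binding_cavity")
}
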