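#' Pipeline configuration
#'
#' Collects every tunable threshold of the versatile-fragment pipeline in one
#' validated object. Defaults are the study conditions: fragment definition
#' (MW < 300 Da, 2-18 heavy atoms), binding-mode clustering at eps = 0.23 on
#' 1 - kernel similarity, cavity similarity decision value 0.47, subgraph
#' matching kernel with subgraphs of up to 3 nodes and an edge-kernel distance
#' tolerance of 1 Angstrom, cavity points within 4 Angstrom of the fragment,
#' sequence-identity clustering at eps 0.10 / 0.75 with Smith-Waterman gap
#' penalties 10 / 0.5 and a 100-column minimum alignment length. The binding
#' site radius (6.5 Angstrom) and the geometric cavity-reconstruction knobs
#' (grid spacing, clash distance, buriedness) are package defaults, stated in
#' the methods vignette.
#'
#' @param mw_max maximum fragment molecular weight, Da (exclusive bound).
#' @param heavy_min,heavy_max allowed heavy (non-hydrogen) atom count range.
#' @param ro3 named list of rule-of-three limits
#'   (\code{mw}, \code{hbd}, \code{hba}, \code{logp}, \code{rotb}).
#' @param mode_eps DBSCAN eps on 1 - kernel similarity for binding modes.
#' @param cavity_score_threshold cavity similarity decision value; two cavity
#'   observations cluster together iff their registration score is at least
#'   this value (see \code{literal_eps} in [count_cavities()]).
#' @param cluster_min_samples DBSCAN min_samples (2 throughout).
#' @param smk_max_nodes maximum common-subgraph size in the kernel.
#' @param smk_edge_dmax edge kernel tolerance, Angstrom; pairs of edges whose
#'   lengths differ by more than this contribute zero.
#' @param cavity_fragment_dist maximum cavity point to fragment heavy atom
#'   distance, Angstrom.
#' @param identity_eps_close,identity_eps_distant DBSCAN eps values for
#'   sequence-identity clustering (>= 90\% identity, >= 25\% identity).
#' @param sw_gap_open,sw_gap_extend Smith-Waterman affine gap penalties.
#' @param min_alignment_len minimum alignment length (columns) for a sequence
#'   identity to count.
#' @param site_radius binding-site residue inclusion radius, Angstrom.
#' @param grid_spacing cavity lattice spacing, Angstrom.
#' @param clash_dist minimum cavity point to protein heavy atom distance.
#' @param buriedness_min minimum number (out of 14 lattice ray directions)
#'   that must hit a protein heavy atom for a point to count as buried.
#' @param ray_length buriedness ray length, Angstrom.
#' @param ray_width maximal perpendicular distance at which a protein atom
#'   blocks a ray, Angstrom.
#' @param inlier_dist registration inlier distance, Angstrom.
#' @param ransac_iter RANSAC iteration budget for cavity registration.
#' @param edge_tol edge-length tolerance for the cluster inclusion-merge
#'   correction, Angstrom.
#' @param random_seed seed for the stochastic registration step.
#' @return A validated list of class \code{"pipeline_config"}.
#' @examples
#' cfg <- pipeline_config()
#' cfg$mode_eps
#' @export
pipeline_config <- function(mw_max = 300, heavy_min = 2, heavy_max = 18,
                            ro3 = list(mw = 300, hbd = 3, hba = 3,
                                       logp = 3, rotb = 3),
                            mode_eps = 0.23,
                            cavity_score_threshold = 0.47,
                            cluster_min_samples = 2L,
                            smk_max_nodes = 3L,
                            smk_edge_dmax = 1.0,
                            cavity_fragment_dist = 4.0,
                            identity_eps_close = 0.10,
                            identity_eps_distant = 0.75,
                            sw_gap_open = 10,
                            sw_gap_extend = 0.5,
                            min_alignment_len = 100L,
                            site_radius = 6.5,
                            grid_spacing = 1.5,
                            clash_dist = 2.0,
                            buriedness_min = 7L,
                            ray_length = 8.0,
                            ray_width = 1.5,
                            inlier_dist = 1.5,
                            ransac_iter = 300L,
                            edge_tol = 0.5,
                            random_seed = 42L) {
  cfg <- list(
    mw_max = mw_max, heavy_min = heavy_min, heavy_max = heavy_max, ro3 = ro3,
    mode_eps = mode_eps, cavity_score_threshold = cavity_score_threshold,
    cluster_min_samples = as.integer(cluster_min_samples),
    smk_max_nodes = as.integer(smk_max_nodes), smk_edge_dmax = smk_edge_dmax,
    cavity_fragment_dist = cavity_fragment_dist,
    identity_eps_close = identity_eps_close,
    identity_eps_distant = identity_eps_distant,
    sw_gap_open = sw_gap_open, sw_gap_extend = sw_gap_extend,
    min_alignment_len = as.integer(min_alignment_len),
    site_radius = site_radius, grid_spacing = grid_spacing,
    clash_dist = clash_dist, buriedness_min = as.integer(buriedness_min),
    ray_length = ray_length, ray_width = ray_width,
    inlier_dist = inlier_dist, ransac_iter = as.integer(ransac_iter),
    edge_tol = edge_tol, random_seed = as.integer(random_seed))
  num <- unlist(cfg[c("mw_max", "heavy_min", "heavy_max", "mode_eps",
                      "cavity_score_threshold", "smk_max_nodes",
                      "smk_edge_dmax", "cavity_fragment_dist",
                      "identity_eps_close", "identity_eps_distant",
                      "sw_gap_open", "sw_gap_extend", "min_alignment_len",
                      "site_radius", "grid_spacing", "clash_dist",
                      "buriedness_min", "ray_length", "ray_width",
                      "inlier_dist", "ransac_iter", "edge_tol")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all pipeline_config thresholds must be positive and finite")
  for (eps in c(cfg$mode_eps, cfg$identity_eps_close, cfg$identity_eps_distant,
                cfg$cavity_score_threshold))
    if (eps <= 0 || eps >= 1) stop("eps-type thresholds must lie in (0, 1)")
  if (cfg$heavy_min > cfg$heavy_max) stop("heavy_min must not exceed heavy_max")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  fragment: MW < %g Da, heavy atoms %d-%d\n",
              x$mw_max, x$heavy_min, x$heavy_max))
  cat(sprintf("  modes: SMK max nodes %d, edge dmax %g A, eps %g\n",
              x$smk_max_nodes, x$smk_edge_dmax, x$mode_eps))
  cat(sprintf("  cavities: point dist %g A, score threshold %g\n",
              x$cavity_fragment_dist, x$cavity_score_threshold))
  cat(sprintf("  sequences: SW gaps %g/%g, min alignment %d aa, eps %g/%g\n",
              x$sw_gap_open, x$sw_gap_extend, x$min_alignment_len,
              x$identity_eps_close, x$identity_eps_distant))
  cat(sprintf("  site radius %g A, seed %d\n", x$site_radius, x$random_seed))
  invisible(x)
}
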