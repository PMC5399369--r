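## Structural connectome: 8-node weighted undirected network over the
## cortico-basal ganglia-thalamocortical circuit, fiber-density edge
## weights, weighted degree centrality, and group comparisons.

## Identifier recorded in outputs so the exact edge-weight convention in use
## is always traceable.
FIBER_DENSITY_VARIANT <- "meanFA*2/(Si+Sj)*sum(1/l)"

#' The eight-region circuit atlas
#'
#' Region names and surface areas (mm^2) for the eight nodes of the
#' cortico-basal ganglia-thalamocortical circuit: caudate, putamen,
#' pallidum, thalamus, sensorimotor (motor) cortex, associative cortex,
#' limbic cortex and substantia nigra.  Surface areas are plausible
#' magnitudes (large for cortical composites, small for nuclei); they enter
#' the analysis only through the fiber-density normalisation.
#'
#' @param surface_areas optional named numeric vector overriding the default
#'   areas; names must be the eight region names.
#' @return data.frame with columns `region` and `surface_area_mm2`.
#' @export
roi_atlas <- function(surface_areas = NULL) {
  atlas <- data.frame(
    region = c("caudate", "putamen", "pallidum", "thalamus", "motor",
               "associative", "limbic", "substantia_nigra"),
    surface_area_mm2 = c(1200, 1600, 800, 1800, 18000, 25000, 12000, 300),
    stringsAsFactors = FALSE
  )
  if (!is.null(surface_areas)) {
    if (!setequal(names(surface_areas), atlas$region)) {
      stop("'surface_areas' must be named by the eight atlas regions")
    }
    atlas$surface_area_mm2 <- unname(surface_areas[atlas$region])
  }
  if (any(atlas$surface_area_mm2 <= 0)) stop("surface areas must be > 0")
  atlas
}

#' Fiber-density edge weight between two regions
#'
#' The edge weight is the connection efficiency between two regions: the
#' number of streamlines normalised by their lengths and by the surface
#' areas of the two regions, scaled by the mean fractional anisotropy along
#' the connection:
#' \deqn{w_{ij} = \overline{FA}(i,j) \cdot \frac{2}{S_i + S_j}
#'       \sum_f \frac{1}{l(f)}}
#' A pair with no fibers has weight 0.
#'
#' @param lengths streamline lengths in mm (strictly positive).
#' @param fa per-fiber fractional anisotropy summaries in (0, 1).
#' @param s_i,s_j region surface areas in mm^2 (strictly positive).
#' @return a single non-negative edge weight.
#' @export
fiber_density_edge <- function(lengths, fa, s_i, s_j) {
  if (s_i <= 0 || s_j <= 0) stop("surface areas must be > 0")
  if (length(lengths) == 0L) return(0)
  if (length(lengths) != length(fa)) {
    stop("'lengths' and 'fa' must have one entry per fiber")
  }
  if (any(lengths <= 0)) stop("fiber lengths must be > 0")
  if (any(fa <= 0 | fa >= 1)) stop("FA values must lie in (0, 1)")
  mean(fa) * (2 / (s_i + s_j)) * sum(1 / lengths)
}

#' Build a subject's connectivity matrix from streamline records
#'
#' @param streamlines data.frame with columns region_i, region_j, length_mm,
#'   mean_fa (one row per fiber) for a single subject.
#' @param atlas region atlas from [roi_atlas()].
#' @return symmetric 8 x 8 matrix of fiber-density edge weights with zero
#'   diagonal, dimnames = region names.
#' @export
build_connectivity <- function(streamlines, atlas = roi_atlas()) {
  nodes <- atlas$region
  C <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(streamlines) == 0L) return(C)
  unknown <- setdiff(unique(c(streamlines$region_i, streamlines$region_j)),
                     nodes)
  if (length(unknown)) {
    stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  }
  areas <- setNames(atlas$surface_area_mm2, nodes)
  key <- paste(pmin(streamlines$region_i, streamlines$region_j),
               pmax(streamlines$region_i, streamlines$region_j), sep = "|")
  for (pk in unique(key)) {
    rows <- key == pk
    ij <- strsplit(pk, "|", fixed = TRUE)[[1]]
    w <- fiber_density_edge(streamlines$length_mm[rows],
                            streamlines$mean_fa[rows],
                            areas[ij[1]], areas[ij[2]])
    C[ij[1], ij[2]] <- w
    C[ij[2], ij[1]] <- w
  }
  C
}

#' Weighted degree centrality
#'
#' The degree centrality of a node is the sum of all edge weights incident
#' to it, i.e. the node's row sum in the connectivity matrix.
#'
#' @param c_mat a symmetric connectivity matrix with zero diagonal and
#'   non-negative finite entries.
#' @return named numeric vector of node degree centralities.
#' @export
degree_centrality <- function(c_mat) {
  if (!is.matrix(c_mat) || nrow(c_mat) != ncol(c_mat)) {
    stop("'c_mat' must be a square matrix")
  }
  if (!isTRUE(all.equal(c_mat, t(c_mat), tolerance = 1e-10))) {
    stop("connectivity matrix must be symmetric")
  }
  if (any(!is.finite(c_mat)) || any(c_mat < 0) || any(diag(c_mat) != 0)) {
    stop("connectivity matrix must be finite, non-negative, zero-diagonal")
  }
  rowSums(c_mat)
}

#' Degree centralities for a whole cohort of streamline records
#'
#' Convenience wrapper building each subject's connectivity matrix and
#' degree-centrality vector.
#'
#' @param streamlines cohort-level streamline data.frame (column
#'   subject_id plus fiber records).
#' @param atlas region atlas.
#' @param subject_ids optional vector fixing subject order; defaults to
#'   order of first appearance.
#' @return data.frame: subject_id plus one degree-centrality column per node.
#' @export
cohort_degree_centrality <- function(streamlines, atlas = roi_atlas(),
                                     subject_ids = NULL) {
  ids <- subject_ids %||% unique(streamlines$subject_id)
  rows <- split(seq_len(nrow(streamlines)), streamlines$subject_id)
  dc <- t(vapply(ids, function(id) {
    idx <- rows[[id]]
    sl <- if (is.null(idx)) streamlines[0, ] else streamlines[idx, ]
    degree_centrality(build_connectivity(sl, atlas))
  }, numeric(nrow(atlas))))
  out <- data.frame(subject_id = ids, dc, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out) <- c("subject_id", atlas$region)
  out
}

#' Group comparison of node degree centralities
#'
#' Per-node two-sample Welch t-tests between healthy controls and patients,
#' Bonferroni-corrected over the tested nodes (corrected p = min(1, p * m)).
#' Nodes with corrected p below `alpha` are flagged significant and feed the
#' association stage as intermediate phenotypes.
#'
#' @param dc_hc,dc_pd numeric matrices/data.frames of degree centralities,
#'   subjects in rows and nodes in columns (same columns both groups).
#' @param alpha corrected significance level.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame per node: group means and sds, t, raw and corrected p,
#'   significance flag and the direction of any PD shift.
#' @export
group_dc_tests <- function(dc_hc, dc_pd, alpha = 0.05, var_equal = FALSE) {
  dc_hc <- as.matrix(dc_hc)
  dc_pd <- as.matrix(dc_pd)
  if (!identical(colnames(dc_hc), colnames(dc_pd))) {
    stop("both groups must have identical node columns")
  }
  if (nrow(dc_hc) < 2 || nrow(dc_pd) < 2) stop("need >= 2 subjects per group")
  m <- ncol(dc_hc)
  res <- lapply(seq_len(m), function(j) {
    x <- dc_hc[, j]; y <- dc_pd[, j]
    if (var(x) == 0 && var(y) == 0) {
      warning("node '", colnames(dc_hc)[j],
              "': zero variance in both groups, p set to 1")
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- t.test(x, y, var.equal = var_equal)
    }
    data.frame(node = colnames(dc_hc)[j],
               mean_hc = mean(x), sd_hc = sd(x),
               mean_pd = mean(y), sd_pd = sd(y),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(1, res$p * m)
  res$significant <- res$p_bonferroni < alpha
  res$direction <- ifelse(res$mean_pd > res$mean_hc, "PD>HC",
                          ifelse(res$mean_pd < res$mean_hc, "PD<HC", "="))
  rownames(res) <- NULL
  res
}
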