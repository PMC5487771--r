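#' DBSCAN clustering parameters
#'
#' @param epsilon neighbourhood radius in the distance-matrix metric
#'   (Angstrom for RMSD matrices).
#' @param minpoints minimum neighbourhood size for a core point. The
#'   neighbourhood includes the query point itself, so `minpoints = 2` means
#'   "at least one other point within epsilon" — conventions differ between
#'   implementations and published epsilon/minpoints values only make sense
#'   under a fixed one.
#' @return object of class `cluster_params`.
#' @export
cluster_params <- function(epsilon, minpoints = 2L) {
  stopifnot(epsilon > 0, minpoints >= 1L)
  structure(list(epsilon = epsilon, minpoints = as.integer(minpoints)),
            class = "cluster_params")
}

#' Density-based clustering of a distance matrix (DBSCAN)
#'
#' Standard DBSCAN semantics on a precomputed symmetric distance matrix: a
#' core point has at least `minpoints` neighbours within `epsilon` (itself
#' included); clusters are the density-connected sets of core points plus
#' their border points; unreachable non-core points are noise (label 0).
#' Border points reachable from several clusters are assigned to the first
#' core cluster that reaches them in a deterministic ascending-index scan.
#'
#' @param distance_matrix symmetric numeric matrix with zero diagonal.
#' @param params a [cluster_params()].
#' @return object of class `gag_clusters`: `labels` (0 = noise), `populations`
#'   (named per-cluster counts), `representatives` (per-cluster medoid index),
#'   `is_core` (logical).
#' @export
dbscan_cluster <- function(distance_matrix, params) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  eps <- params$epsilon
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- lengths(nbrs) >= params$minpoints
  labels <- integer(n)                # 0 = unassigned / noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbrs[[i]]
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (is_core[j]) queue <- c(queue, nbrs[[j]][labels[nbrs[[j]]] == 0L])
      }
    }
  }
  pops <- if (cl > 0L) table(factor(labels[labels > 0L], levels = seq_len(cl)))
          else table(integer())
  res <- structure(list(labels = labels,
                        populations = as.integer(pops),
                        representatives = integer(cl),
                        is_core = is_core,
                        params = params),
                   class = "gag_clusters")
  names(res$populations) <- as.character(seq_len(cl))
  res$representatives <- cluster_representatives(res, d)
  res
}

#' @export
print.gag_clusters <- function(x, ...) {
  k <- length(x$populations)
  cat("DBSCAN:", k, "cluster(s),", sum(x$labels == 0L), "noise point(s) of",
      length(x$labels), sprintf("(epsilon = %g, minpoints = %d)\n",
                                x$params$epsilon, x$params$minpoints))
  if (k) {
    ord <- order(-x$populations, as.integer(names(x$populations)))
    show <- utils::head(ord, 10L)
    cat("  populations:", paste0("#", names(x$populations)[show], "=",
                                 x$populations[show], collapse = " "), "\n")
  }
  invisible(x)
}

#' Medoid representative of each cluster
#'
#' The representative of a cluster is the member minimising the summed
#' in-cluster distance (ties broken by lowest index).
#'
#' @param result a `gag_clusters`.
#' @param distance_matrix the matrix the clustering was computed on.
#' @return integer vector of item indices, one per cluster id.
#' @export
cluster_representatives <- function(result, distance_matrix) {
  d <- as.matrix(distance_matrix)
  k <- length(result$populations)
  reps <- integer(k)
  for (c in seq_len(k)) {
    members <- which(result$labels == c)
    ss <- rowSums(d[members, members, drop = FALSE])
    reps[c] <- members[which.min(ss)]
  }
  reps
}

#' Cluster binding-loop conformations of an ensemble
#'
#' Extracts the heavy atoms of the given loop residues, computes the pairwise
#' least-squares-fitted RMSD matrix over frames (each frame pair superposed on
#' the loop atoms), clusters with DBSCAN, and returns the medoid frames of the
#' `top_n` most populated clusters (descending population, ties by lowest
#' cluster id). This is how representative receptor conformations for
#' ensemble docking are extracted from a trajectory.
#'
#' @param ensemble a `gag_ensemble`.
#' @param loop_residues integer vector of protein residue numbers (e.g.
#'   `c(17:19, 112:114, 118:122, 126:129)` for an FGF1-style heparin-binding
#'   loop set).
#' @param params a [cluster_params()] (e.g. epsilon 0.92 Angstrom,
#'   minpoints 2).
#' @param top_n number of clusters to report (all, if fewer exist).
#' @return list with `representatives` (frame indices, most populated first),
#'   `clusters` (the `gag_clusters`), `rmsd_matrix`.
#' @export
cluster_loop_conformations <- function(ensemble, loop_residues, params,
                                       top_n = 10L) {
  a <- ensemble$atoms
  sel <- which(a$role == "protein" & a$resnum %in% loop_residues &
                 a$element != "H")
  missing <- setdiff(loop_residues, a$resnum[a$role == "protein"])
  if (length(missing))
    stop("loop residue(s) not present in the topology: ",
         paste(missing, collapse = ", "))
  nf <- length(ensemble$frames)
  xyz <- do.call(rbind, lapply(ensemble$frames, function(f)
    as.vector(t(f[sel, , drop = FALSE]))))
  d <- matrix(0, nf, nf)
  natoms <- length(sel)
  for (i in seq_len(max(nf - 1L, 1L))) {
    if (i >= nf) break
    for (j in (i + 1L):nf) {
      fitted <- suppressWarnings(bio3d::fit.xyz(xyz[i, ], xyz[j, ]))
      r <- sqrt(sum((xyz[i, ] - as.numeric(fitted))^2) / natoms)
      d[i, j] <- r
      d[j, i] <- r
    }
  }
  cl <- dbscan_cluster(d, params)
  k <- length(cl$populations)
  ord <- order(-cl$populations, seq_len(k))
  keep <- utils::head(ord, top_n)
  list(representatives = cl$representatives[keep],
       clusters = cl, rmsd_matrix = d)
}

#' Write cluster assignments to TSV
#'
#' @param result a `gag_clusters`.
#' @param path TSV path.
#' @param items optional item labels.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(result, path, items = NULL) {
  n <- length(result$labels)
  df <- data.frame(
    item = items %||% seq_len(n),
    label = result$labels,
    is_core = result$is_core,
    is_representative = seq_len(n) %in% result$representatives
  )
  write_canonical_tsv(df, path,
                      meta = sprintf("epsilon = %g; minpoints = %d",
                                     result$params$epsilon,
                                     result$params$minpoints))
  invisible(path)
}
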