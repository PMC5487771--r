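#' Construct a ligand pose
#'
#' A pose holds the ligand (glycan) atoms of one docking solution or one
#' extracted frame: names, elements, residue numbers and coordinates, with an
#' optional score.
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param element character vector of chemical elements, length n.
#' @param name optional atom names.
#' @param resnum optional residue numbers (used for ring centroids).
#' @param score optional score/energy, kcal/mol.
#' @param source label for provenance.
#' @return object of class `gag_pose`.
#' @export
pose <- function(coords, element, name = NULL, resnum = NULL,
                 score = NA_real_, source = "") {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  n <- nrow(coords)
  stopifnot(n >= 1L, length(element) == n, all(nzchar(element)))
  structure(list(coords = coords, element = as.character(element),
                 name = name %||% paste0(element, seq_len(n)),
                 resnum = resnum %||% rep(1L, n),
                 score = score, source = source),
            class = "gag_pose")
}

#' Read poses from a multi-model PDB file
#'
#' Each model becomes one pose consisting of the atoms whose residue name is
#' in `glycan_resnames`.
#'
#' @param path multi-model PDB file.
#' @param glycan_resnames residue names forming the ligand.
#' @return list of `gag_pose`.
#' @export
read_poses <- function(path, glycan_resnames) {
  ens <- parse_structure_ensemble(path, glycan_resnames = glycan_resnames)
  gi <- which(ens$atoms$role == "glycan")
  lapply(seq_along(ens$frames), function(f)
    pose(ens$frames[[f]][gi, , drop = FALSE],
         element = ens$atoms$element[gi], name = ens$atoms$name[gi],
         resnum = ens$atoms$resnum[gi],
         source = paste0(basename(path), "#", f)))
}

#' Ordered-atom RMSD between two poses
#'
#' Root-mean-square deviation over index-matched atom pairs, by default
#' without superposition (pose placement matters for docking solutions); with
#' `superpose = TRUE` poses are least-squares fitted first.
#'
#' @param a,b `gag_pose`s with identical atom count and ordering.
#' @param superpose least-squares fit `b` onto `a` before measuring.
#' @return RMSD in Angstrom.
#' @export
pairwise_rmsd <- function(a, b, superpose = FALSE) {
  if (nrow(a$coords) != nrow(b$coords))
    stop("poses have different atom counts (", nrow(a$coords), " vs ",
         nrow(b$coords), ")")
  B <- b$coords
  if (superpose) {
    fitted <- suppressWarnings(
      bio3d::fit.xyz(as.vector(t(a$coords)), as.vector(t(B))))
    B <- matrix(as.numeric(fitted), ncol = 3L, byrow = TRUE)
  }
  sqrt(mean(rowSums((a$coords - B)^2)))
}

# ---- linear assignment (Hungarian algorithm, O(n^3) with potentials) --------
# cost: n x m matrix, n <= m; returns for each row the assigned column,
# minimising the total cost.
hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L)      # p[j+1]: row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0L:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Atom-type-matched RMSD (RMSatd) between two poses
#'
#' Like RMSD, but instead of relying on atom ordering it pairs up spatially
#' close atoms of the same chemical element: within each element type, atoms
#' of `a` are matched one-to-one to atoms of `b` by the assignment minimising
#' the total squared distance (optimal, not greedy), and the RMS is taken
#' over all matched pairs. Appropriate for near-symmetric ligands such as
#' GAG chains, whose docking solutions may be chemically equivalent yet
#' index-permuted. When one pose has more atoms of some element, the excess
#' atoms are excluded and reported in the `unmatched` attribute.
#'
#' @param a,b `gag_pose`s sharing at least one element type.
#' @return RMSatd in Angstrom, with attribute `unmatched` (named count of
#'   excluded atoms per element, if any).
#' @export
rmsatd <- function(a, b) {
  common <- intersect(unique(a$element), unique(b$element))
  if (!length(common))
    stop("poses share no element types")
  ss <- 0; np <- 0L
  unmatched <- c(table(a$element[!a$element %in% common]),
                 table(b$element[!b$element %in% common]))
  for (el in common) {
    ia <- which(a$element == el)
    ib <- which(b$element == el)
    swap <- length(ia) > length(ib)
    if (swap) { tmp <- ia; ia <- ib; ib <- tmp
                A <- b$coords; B <- a$coords } else { A <- a$coords; B <- b$coords }
    d2 <- cross_dist(A[ia, , drop = FALSE], B[ib, , drop = FALSE])^2
    asg <- hungarian_assign(d2)
    # recompute the matched distances directly: the outer-product form used
    # for the cost matrix loses precision near zero
    ss <- ss + sum((A[ia, , drop = FALSE] -
                      B[ib[asg], , drop = FALSE])^2)
    np <- np + length(ia)
    if (length(ib) > length(ia)) {
      extra <- stats::setNames(length(ib) - length(ia), el)
      unmatched <- c(unmatched, extra)
    }
  }
  out <- sqrt(ss / np)
  if (length(unmatched)) attr(out, "unmatched") <- unmatched
  out
}

#' Classify pose orientation relative to a reference axis
#'
#' The ligand axis runs from the centroid of the first (non-reducing) ring to
#' the centroid of the last (reducing) ring. The angle to the reference axis
#' classifies the pose: parallel when at most `thresholds[1]` degrees,
#' antiparallel when at least `thresholds[2]`, perpendicular otherwise.
#' The defaults split the angle range into symmetric tertiles about 90
#' degrees.
#'
#' @param p a `gag_pose` with ring residue numbers.
#' @param reference_axis length-3 vector (need not be normalised).
#' @param annotation a `gag_glycan` mapping residue numbers to ring indices.
#' @param thresholds c(parallel_max, antiparallel_min), degrees.
#' @return `"parallel"`, `"antiparallel"` or `"perpendicular"`, with the
#'   angle (degrees) as attribute `angle`.
#' @export
classify_orientation <- function(p, reference_axis, annotation,
                                 thresholds = c(45, 135)) {
  ring <- annotation$ring_index[match(p$resnum, annotation$resnum)]
  if (anyNA(ring)) stop("pose contains residues outside the annotation")
  if (length(unique(ring)) < 2L) stop("need at least 2 rings for an axis")
  cen <- function(k) colMeans(p$coords[ring == k, , drop = FALSE])
  axis_lig <- cen(max(ring)) - cen(min(ring))
  if (sqrt(sum(axis_lig^2)) < 1e-9)
    stop("terminal ring centroids coincide; ligand axis undefined")
  ref <- reference_axis / sqrt(sum(reference_axis^2))
  lig <- axis_lig / sqrt(sum(axis_lig^2))
  cosang <- min(1, max(-1, sum(ref * lig)))
  theta <- acos(cosang) * 180 / pi
  cls <- if (theta <= thresholds[1L]) "parallel"
         else if (theta >= thresholds[2L]) "antiparallel"
         else "perpendicular"
  attr(cls, "angle") <- theta
  cls
}

#' Discard unbound poses
#'
#' Keeps the poses having at least one sugar-residue atom within `cutoff`
#' Angstrom of the anchor point (typically the C-alpha of a binding-site
#' residue); input order is preserved.
#'
#' @param poses list of `gag_pose`.
#' @param anchor length-3 coordinate vector, Angstrom.
#' @param cutoff distance cutoff, Angstrom (default 10).
#' @return the bound subset of `poses`, with attribute `kept` (logical).
#' @export
filter_bound_poses <- function(poses, anchor, cutoff = 10) {
  stopifnot(cutoff > 0, length(anchor) == 3L)
  keep <- vapply(poses, function(p) {
    d2 <- rowSums(sweep(p$coords, 2L, anchor)^2)
    min(d2) <= cutoff^2
  }, TRUE)
  out <- poses[keep]
  attr(out, "kept") <- keep
  out
}

#' Pairwise distance matrix over a pose set
#'
#' @param poses list of `gag_pose`.
#' @param metric `"rmsd"` (ordered, see [pairwise_rmsd()]) or `"rmsatd"`.
#' @param superpose passed to [pairwise_rmsd()].
#' @return symmetric matrix of distances, Angstrom.
#' @export
pose_distance_matrix <- function(poses, metric = c("rmsd", "rmsatd"),
                                 superpose = FALSE) {
  metric <- match.arg(metric)
  n <- length(poses)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- if (metric == "rmsd")
      pairwise_rmsd(poses[[i]], poses[[j]], superpose = superpose)
    else as.numeric(rmsatd(poses[[i]], poses[[j]]))
  }
  d
}
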