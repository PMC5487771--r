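test_that("ordered RMSD has its closed forms and matches direct evaluation", {
  set.seed(41)
  a <- random_pose(rep(c("C", "O"), 5L))
  expect_equal(pairwise_rmsd(a, a), 0)
  b <- a
  b$coords <- b$coords + matrix(rep(c(3, 0, 0), each = 10L), ncol = 3L)
  expect_equal(pairwise_rmsd(a, b), 3, tolerance = 1e-9)
  expect_equal(pairwise_rmsd(a, b, superpose = TRUE), 0, tolerance = 1e-6)
  c_ <- random_pose(rep(c("C", "O"), 5L))
  direct <- sqrt(mean(rowSums((a$coords - c_$coords)^2)))
  expect_equal(pairwise_rmsd(a, c_), direct, tolerance = 1e-9)
  short <- random_pose(c("C", "O"))
  expect_error(pairwise_rmsd(a, short), "atom counts")
})

test_that("RMSatd equals the exhaustive same-type pairing minimum", {
  set.seed(42)
  # permuting atoms within types leaves RMSatd at zero
  a <- random_pose(c("C", "C", "C", "O", "O", "N"))
  perm <- c(3L, 1L, 2L, 5L, 4L, 6L)          # permutes within each element
  b <- a; b$coords <- a$coords[perm, ]
  expect_equal(as.numeric(rmsatd(a, b)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(rmsatd(a, a)), 0)
  # crossed two-atom case: the optimal pairing is the crossing one
  a2 <- pose(rbind(c(0, 0, 0), c(10, 0, 0)), c("C", "C"))
  b2 <- pose(rbind(c(10, 1, 0), c(0, 1, 0)), c("C", "C"))
  expect_equal(as.numeric(rmsatd(a2, b2)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(rmsatd(a2, b2)), brute_rmsatd(a2, b2),
               tolerance = 1e-12)
  # random fixtures: equality with brute force, symmetry, rmsatd <= rmsd
  for (rep in 1:25) {
    el <- sample(c("C", "O", "N", "S"), sample(4:8, 1L), replace = TRUE)
    x <- random_pose(el); y <- random_pose(el)
    v <- as.numeric(rmsatd(x, y))
    expect_equal(v, brute_rmsatd(x, y), tolerance = 1e-10)
    expect_equal(v, as.numeric(rmsatd(y, x)), tolerance = 1e-10)
    expect_lte(v, pairwise_rmsd(x, y) + 1e-12)
  }
  # unequal counts: excess atoms excluded and reported
  x <- pose(rbind(c(0, 0, 0), c(1, 0, 0), c(9, 9, 9)), c("C", "C", "C"))
  y <- pose(rbind(c(0, 0, 0), c(1, 0, 0)), c("C", "C"))
  v <- rmsatd(x, y)
  expect_equal(as.numeric(v), 0, tolerance = 1e-12)
  expect_equal(unname(attr(v, "unmatched")["C"]), 1L, ignore_attr = TRUE)
  expect_error(rmsatd(pose(diag(3), c("C", "C", "C")),
                      pose(diag(3), c("O", "O", "O"))), "no element")
})

test_that("orientation classes split the angle range and rotate together", {
  ann <- data.frame(ring_index = 1:2, chain = "B", resnum = 1:2,
                    resname = "SGN", ring_type = "GlcNS", sulfation = "",
                    token = "GlcNS")
  class(ann) <- c("gag_glycan", "data.frame")
  mk <- function(v) pose(rbind(c(0, 0, 0), v), c("C", "C"), resnum = 1:2)
  ref <- c(1, 0, 0)
  expect_equal(as.character(classify_orientation(mk(c(5, 0, 0)), ref, ann)),
               "parallel")
  expect_equal(as.character(classify_orientation(mk(c(-5, 0, 0)), ref, ann)),
               "antiparallel")
  expect_equal(as.character(classify_orientation(mk(c(0, 5, 0)), ref, ann)),
               "perpendicular")
  expect_error(classify_orientation(mk(c(0, 0, 0)), ref, ann), "coincide")
  # simultaneous rotation of pose and reference leaves the class unchanged
  set.seed(43)
  for (rep in 1:10) {
    v <- rnorm(3L); v <- 5 * v / sqrt(sum(v^2))
    tf <- random_rigid_transform()
    cls1 <- classify_orientation(mk(v), ref, ann)
    p2 <- mk(as.vector(tf$R %*% v))
    cls2 <- classify_orientation(p2, as.vector(tf$R %*% ref), ann)
    expect_equal(as.character(cls1), as.character(cls2))
    expect_equal(attr(cls1, "angle"), attr(cls2, "angle"), tolerance = 1e-6)
  }
})

test_that("bound-pose filtering matches a brute-force distance scan", {
  near <- pose(rbind(c(9, 0, 0), c(12, 0, 0)), c("C", "O"))
  far <- pose(rbind(c(11, 0, 0), c(14, 0, 0)), c("C", "O"))
  kept <- filter_bound_poses(list(near, far), c(0, 0, 0), 10)
  expect_length(kept, 1L)
  expect_equal(attr(kept, "kept"), c(TRUE, FALSE))
  set.seed(44)
  poses <- lapply(1:40, function(i) random_pose(rep("C", 4L), scale = 15))
  anchor <- c(2, -3, 1)
  got <- attr(filter_bound_poses(poses, anchor, 10), "kept")
  brute <- vapply(poses, function(p)
    min(sqrt(rowSums(sweep(p$coords, 2L, anchor)^2))) <= 10, TRUE)
  expect_equal(got, brute)
  # order is preserved: the kept list is a subsequence of the input
  expect_equal(which(got), sort(which(got)))
})

test_that("DBSCAN handles the degenerate and constructed cases", {
  expect_equal(dbscan_cluster(matrix(0, 1L, 1L),
                              cluster_params(1, 2L))$labels, 0L)
  # two tight blobs far apart: exactly two clusters, no noise
  set.seed(45)
  pts <- rbind(matrix(rnorm(20L, 0, 0.2), ncol = 2L),
               matrix(rnorm(20L, 50, 0.2), ncol = 2L))
  d <- as.matrix(dist(pts))
  cl <- dbscan_cluster(d, cluster_params(3, 4L))
  expect_equal(sort(unique(cl$labels)), 1:2)
  expect_equal(unname(cl$populations), c(10L, 10L))
  expect_error(dbscan_cluster(matrix(c(0, 1, 2, 0), 2L),
                              cluster_params(1, 2L)), "symmetric")
})

test_that("DBSCAN labelling agrees with the graph-components formulation", {
  set.seed(46)
  for (rep in 1:10) {
    pts <- matrix(runif(60L, 0, 10), ncol = 2L)
    d <- as.matrix(dist(pts))
    eps <- runif(1L, 0.5, 3)
    mp <- sample(2:5, 1L)
    expect_equal(dbscan_cluster(d, cluster_params(eps, mp))$labels,
                 ref_dbscan(d, eps, mp))
  }
  # permutation invariance (up to relabelling) away from border ambiguity
  pts <- rbind(matrix(rnorm(16L, 0, 0.3), ncol = 2L),
               matrix(rnorm(16L, 20, 0.3), ncol = 2L),
               matrix(runif(8L, 40, 80), ncol = 2L))
  d <- as.matrix(dist(pts))
  l1 <- dbscan_cluster(d, cluster_params(2, 3L))$labels
  perm <- sample(nrow(pts))
  l2 <- dbscan_cluster(d[perm, perm], cluster_params(2, 3L))$labels
  expect_equal(l2 == 0L, l1[perm] == 0L)
  expect_equal(length(unique(l2)), length(unique(l1)))
  # same partition: co-membership must agree
  expect_equal(outer(l2, l2, `==`) & l2 > 0,
               outer(l1[perm], l1[perm], `==`) & l1[perm] > 0)
})

test_that("medoid representatives minimise summed in-cluster distance", {
  # symmetric 3-point cluster on a line: the middle point is the medoid
  d <- as.matrix(dist(c(0, 1, 2)))
  cl <- dbscan_cluster(d, cluster_params(1.5, 2L))
  expect_equal(cl$representatives, 2L)
  # singleton cluster is its own representative
  d2 <- as.matrix(dist(c(0, 0.1, 50)))
  cl2 <- dbscan_cluster(d2, cluster_params(1, 1L))
  expect_equal(cl2$labels, c(1L, 1L, 2L))
  expect_equal(cl2$representatives[2L], 3L)
  # random clusters: exhaustive medoid search
  set.seed(47)
  pts <- c(rnorm(7L, 0, 1), rnorm(7L, 30, 1))
  d3 <- as.matrix(dist(pts))
  cl3 <- dbscan_cluster(d3, cluster_params(5, 2L))
  for (c_ in seq_along(cl3$populations)) {
    mem <- which(cl3$labels == c_)
    sums <- vapply(mem, function(i) sum(d3[i, mem]), 0)
    expect_equal(cl3$representatives[c_], mem[which.min(sums)])
  }
})

test_that("loop clustering recovers planted conformer populations", {
  # three internal loop conformations (bent angles), planted populations;
  # the base shape is non-collinear so superposition is well-posed
  mk_frame <- function(shape) {
    bend <- c(0, shape * 2.5, 0)
    rbind(c(0, 0, 0), c(3, 1, 0) + bend, c(6, 0, 1),
          c(9, 0.5, 0), c(50, 50, 50))
  }
  df <- data.frame(name = c("CA", "CA", "CA", "CA", "C1"),
                   element = c("C", "C", "C", "C", "C"),
                   resnum = c(17L, 18L, 19L, 20L, 101L),
                   role = c(rep("protein", 4L), "glycan"))
  shapes <- rep(c(0L, 1L, 2L), times = c(6L, 4L, 2L))
  set.seed(48)
  frames <- lapply(shapes, function(s) {
    f <- mk_frame(s)
    tf <- random_rigid_transform()   # rigid motion must not split clusters
    t(tf$R %*% t(f)) + matrix(tf$t, nrow(f), 3L, byrow = TRUE)
  })
  ens <- make_ensemble(df, frames)
  res <- cluster_loop_conformations(ens, 17:20, cluster_params(0.9, 2L))
  expect_equal(unname(res$clusters$populations), c(6L, 4L, 2L))
  expect_equal(res$clusters$labels, shapes + 1L)
  expect_equal(length(res$representatives), 3L)
  # identical frames collapse to one cluster represented by frame 1
  ens1 <- make_ensemble(df, rep(list(mk_frame(0L)), 5L))
  res1 <- cluster_loop_conformations(ens1, 17:20, cluster_params(0.9, 2L))
  expect_equal(res1$representatives, 1L)
  expect_equal(length(res1$clusters$populations), 1L)
  # top_n larger than the cluster count returns all clusters
  expect_length(cluster_loop_conformations(ens, 17:20,
                                           cluster_params(0.9, 2L),
                                           top_n = 50L)$representatives, 3L)
  expect_error(cluster_loop_conformations(ens, c(17L, 999L),
                                          cluster_params(0.9, 2L)), "999")
})
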