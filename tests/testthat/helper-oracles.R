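# Independent oracles and tiny fixture builders used across the suite.
# Every oracle is a brute-force or alternative-formulation implementation,
# kept deliberately separate from the package's own code paths.

# Build a minimal ensemble from a per-atom table and a list of frames.
make_ensemble <- function(df, frames, bonded_h = NULL) {
  atoms <- data.frame(
    serial = seq_len(nrow(df)), name = df$name, element = df$element,
    chain = df$chain %||% "A",
    resnum = df$resnum, resname = df$resname %||% "RES",
    role = df$role,
    charge = df$charge %||% NA_real_,
    rmin_half = df$rmin_half %||% NA_real_,
    epsilon = df$epsilon %||% NA_real_,
    born_radius = df$born_radius %||% NA_real_,
    stringsAsFactors = FALSE
  )
  structure_ensemble(atoms, frames, bonded_h = bonded_h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive O(N^2) hydrogen-bond search over every donor-acceptor pair.
brute_hbonds <- function(ensemble, frame, dcut = 3.0, acut = 135,
                         intermolecular = TRUE) {
  co <- if (is.matrix(frame)) frame else ensemble$frames[[frame]]
  a <- ensemble$atoms
  rlab <- paste(a$chain, a$resnum, a$resname)
  found <- character()
  for (d in seq_len(nrow(a))) {
    if (!a$element[d] %in% c("N", "O")) next
    hs <- match(ensemble$bonded_h[[d]], a$serial)
    if (!length(hs)) next
    for (acc in seq_len(nrow(a))) {
      if (!a$element[acc] %in% c("N", "O")) next
      if (rlab[d] == rlab[acc]) next
      if (intermolecular &&
          !((a$role[d] == "protein" && a$role[acc] == "glycan") ||
            (a$role[d] == "glycan" && a$role[acc] == "protein"))) next
      if (sqrt(sum((co[d, ] - co[acc, ])^2)) > dcut) next
      for (h in hs) {
        u <- co[d, ] - co[h, ]; v <- co[acc, ] - co[h, ]
        ang <- acos(min(1, max(-1, sum(u * v) /
                                 sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
        if (ang >= acut) {
          found <- c(found, paste(d, acc))
          break
        }
      }
    }
  }
  sort(found)
}

# DBSCAN by an independent formulation: clusters are connected components of
# the epsilon-graph restricted to core points (via igraph); a border point
# joins the lowest-id cluster among its core neighbours; everything else is
# noise. Matches the package's documented border policy exactly, including
# cluster numbering (ascending by smallest core index).
ref_dbscan <- function(d, eps, minpts) {
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- which(lengths(nb) >= minpts)
  lab <- integer(n)
  if (length(core)) {
    adj <- d[core, core, drop = FALSE] <= eps
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    first <- tapply(core, comp, min)
    relab <- as.integer(rank(first))
    lab[core] <- relab[comp]
    for (i in setdiff(seq_len(n), core)) {
      cn <- intersect(nb[[i]], core)
      if (length(cn)) lab[i] <- min(lab[cn])
    }
  }
  lab
}

# Exhaustive-minimum RMSatd over all same-element pairings (<= ~6 per type).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

brute_rmsatd <- function(a, b) {
  ss <- 0; np <- 0L
  for (el in intersect(unique(a$element), unique(b$element))) {
    ia <- which(a$element == el)
    ib <- which(b$element == el)
    if (length(ia) > length(ib)) { tmp <- ia; ia <- ib; ib <- tmp
                                   A <- b$coords; B <- a$coords }
    else { A <- a$coords; B <- b$coords }
    best <- Inf
    for (p in all_perms(ib)) {
      p <- p[seq_along(ia)]
      best <- min(best, sum((A[ia, , drop = FALSE] -
                               B[p, , drop = FALSE])^2))
    }
    ss <- ss + best; np <- np + length(ia)
  }
  sqrt(ss / np)
}

# Random pose with given element multiset.
random_pose <- function(elements, scale = 5) {
  pose(matrix(stats::runif(3 * length(elements), -scale, scale),
              ncol = 3L), elements)
}

# Random rigid-body transform applied to every frame of an ensemble.
random_rigid_transform <- function() {
  M <- matrix(stats::rnorm(9L), 3L)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  list(R = R, t = stats::rnorm(3L, 0, 10))
}

apply_rigid <- function(ensemble, tf) {
  ensemble$frames <- lapply(ensemble$frames, function(f)
    t(tf$R %*% t(f)) + matrix(tf$t, nrow(f), 3L, byrow = TRUE))
  ensemble
}

# Top-k cells "residue ring" of one site-map channel.
top_cells <- function(map, channel, k) {
  m <- map$channels[[channel]]
  idx <- order(-as.vector(m))[seq_len(k)]
  ij <- arrayInd(idx, dim(m))
  paste(rownames(m)[ij[, 1L]], colnames(m)[ij[, 2L]])
}

# Random H-bond test system: residues of one N/O heavy atom plus an attached
# hydrogen and an extra bare acceptor, at fresh random positions every frame
# (H kept ~0.97 A from its heavy atom).
random_hb_ensemble <- function(n_res = 10L, n_frames = 1L, box = 8) {
  rows <- list(); bh <- list()
  for (i in seq_len(n_res)) {
    role <- if (i %% 2L) "protein" else "glycan"
    el <- sample(c("N", "O"), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      name = "X", element = el, resnum = i, role = role)
    rows[[length(rows) + 1L]] <- data.frame(
      name = "HX", element = "H", resnum = i, role = role)
    rows[[length(rows) + 1L]] <- data.frame(
      name = "Y", element = "O", resnum = i, role = role)
  }
  df <- do.call(rbind, rows)
  n <- nrow(df)
  frames <- lapply(seq_len(n_frames), function(f) {
    co <- matrix(stats::runif(n * 3L, 0, box), ncol = 3L)
    for (k in seq(1L, n, by = 3L)) {      # H rides on its heavy atom
      u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
      co[k + 1L, ] <- co[k, ] + 0.97 * u
    }
    co
  })
  bonded <- rep(list(integer()), n)
  for (k in seq(1L, n, by = 3L)) bonded[[k]] <- k + 1L   # serial == row here
  make_ensemble(df, frames, bonded_h = bonded)
}

# Random charged toy complex for energy-conservation checks.
random_charged_ensemble <- function(np = 3L, ng = 2L, n_frames = 2L,
                                    atoms_per_res = 3L) {
  rows <- list()
  for (i in seq_len(np)) for (k in seq_len(atoms_per_res))
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("P", k), element = sample(c("C", "N", "O"), 1L),
      chain = "A", resnum = i, role = "protein")
  for (j in seq_len(ng)) for (k in seq_len(atoms_per_res))
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0("G", k), element = sample(c("C", "O", "S"), 1L),
      chain = "B", resnum = 100L + j, role = "glycan")
  df <- do.call(rbind, rows)
  n <- nrow(df)
  df$charge <- stats::runif(n, -0.8, 0.8)
  df$rmin_half <- stats::runif(n, 1.2, 2.0)
  df$epsilon <- stats::runif(n, 0.05, 0.3)
  df$born_radius <- stats::runif(n, 0.8, 2.0)
  frames <- lapply(seq_len(n_frames), function(f)
    matrix(stats::runif(n * 3L, 0, 12), ncol = 3L))
  ens <- make_ensemble(df, frames)
  ann <- annotate_glycan(ens, paste(rep("X", ng), collapse = "-"))
  list(ensemble = ens, annotation = ann)
}
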