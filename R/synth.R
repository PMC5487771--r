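#' Specification for the synthetic-data generators
#'
#' Central parameter object for all ground-truth generators. Defaults emulate
#' the statistical structure of ensemble-docking studies of heparin
#' oligosaccharides: a hexasaccharide ligand with planted hydrogen-bond
#' occupancies and hot residue-ring energy pairs, pose sets with planted
#' cluster structure and a bound/unbound mixture, and per-ligand binding
#' free-energy distributions with a planted affinity order (means 5 kcal/mol
#' apart, SD 10 kcal/mol, 100 values per ligand — the scale of ~100 docking
#' solutions per ligand).
#'
#' @param seed integer seed; every generator is fully deterministic given it.
#' @param n_protein_residues number of toy protein fragments.
#' @param glycan_pattern sulfation pattern string (see [annotate_glycan()]).
#' @param n_frames frames in the toy ensemble.
#' @param planted_hbond_pairs data.frame `residue`, `ring`, `occupancy`.
#' @param planted_hot_pairs data.frame `residue`, `ring`, `mean` (kcal/mol).
#' @param noise_sd background cell SD, kcal/mol, for the decomposition
#'   fixture.
#' @param split_ratio fraction of each fixture cell's energy put in the vdW
#'   component (remainder electrostatic).
#' @param occupancy_mode `"bernoulli"` (independent per frame, the default,
#'   matching a percentage-of-frames statistic), `"exact"` (deterministic
#'   toggling with exact counts) or `"markov"` (time-correlated switching).
#' @param markov_stay persistence parameter of the Markov mode.
#' @param coord_jitter_sd optional Gaussian jitter (Angstrom) on static atoms.
#' @param pose list: `n_clusters`, `spread` (minimum center separation, A),
#'   `within_sd` (within-cluster rigid translation SD, A),
#'   `unbound_fraction`, `n_poses`, `anchor`, `cutoff`.
#' @param deltag list: named `means` (kcal/mol), `sd`, `n`.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       n_protein_residues = 8L,
                       glycan_pattern =
                         "GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S-IdoA2S",
                       n_frames = 100L,
                       planted_hbond_pairs = data.frame(
                         residue = c(2L, 4L, 6L), ring = c(1L, 3L, 5L),
                         occupancy = c(0.9, 0.5, 0.1)),
                       planted_hot_pairs = data.frame(
                         residue = 1:5, ring = 1:5, mean = -8),
                       noise_sd = 1,
                       split_ratio = 0.5,
                       occupancy_mode = c("bernoulli", "exact", "markov"),
                       markov_stay = 0.8,
                       coord_jitter_sd = 0,
                       pose = list(),
                       deltag = list()) {
  occupancy_mode <- match.arg(occupancy_mode)
  pose_def <- list(n_clusters = 3L, spread = 20, within_sd = 0.5,
                   unbound_fraction = 0.3, n_poses = 100L,
                   anchor = c(0, 0, 0), cutoff = 10)
  pose_def[names(pose)] <- pose
  dg_def <- list(means = c(L1 = -60, L2 = -55, L3 = -50, L4 = -45, L5 = -40),
                 sd = 10, n = 100L)
  dg_def[names(deltag)] <- deltag
  stopifnot(all(planted_hbond_pairs$occupancy >= 0 &
                  planted_hbond_pairs$occupancy <= 1),
            noise_sd >= 0, pose_def$within_sd >= 0, dg_def$sd >= 0,
            split_ratio >= 0, split_ratio <= 1)
  structure(list(seed = as.integer(seed),
                 n_protein_residues = as.integer(n_protein_residues),
                 glycan_pattern = glycan_pattern,
                 n_frames = as.integer(n_frames),
                 planted_hbond_pairs = planted_hbond_pairs,
                 planted_hot_pairs = planted_hot_pairs,
                 noise_sd = noise_sd, split_ratio = split_ratio,
                 occupancy_mode = occupancy_mode,
                 markov_stay = markov_stay,
                 coord_jitter_sd = coord_jitter_sd,
                 pose = pose_def, deltag = dg_def),
            class = "synth_spec")
}

# element -> (rmin/2, epsilon, born radius), AMBER-like magnitudes
elem_nb <- function(el) {
  tab <- list(C = c(1.908, 0.1094, 1.70), N = c(1.824, 0.1700, 1.55),
              O = c(1.661, 0.2100, 1.50), S = c(2.000, 0.2500, 1.80),
              H = c(0.600, 0.0157, 0.80))
  t(vapply(el, function(e) tab[[e]] %||% c(1.7, 0.1, 1.5), numeric(3L)))
}

ring_resname <- function(type) {
  switch(type, GlcNS = "SGN", GlcN = "GCN", IdoA2S = "IDS", IdoA = "IDO",
         "UNK")
}

# Per-frame on/off state sequence for one planted occupancy.
plant_states <- function(n, occ, mode, stay) {
  switch(mode,
    bernoulli = stats::runif(n) < occ,
    exact = floor(seq_len(n) * occ) > floor((seq_len(n) - 1L) * occ),
    markov = {
      s <- logical(n)
      s[1L] <- stats::runif(1) < occ
      p_on <- stay + (1 - stay) * occ     # stay on
      p_off <- (1 - stay) * occ           # switch on
      for (f in seq_len(n)[-1L])
        s[f] <- stats::runif(1) < if (s[f - 1L]) p_on else p_off
      s
    })
}

#' Generate a toy protein-glycan ensemble with planted ground truth
#'
#' Builds a geometric toy complex: protein residues as small rigid fragments
#' (backbone-like N-H donor, carbonyl acceptor, charged carbon) lining a row,
#' and the glycan as a chain of ring fragments (anomeric carbon, ring oxygen,
#' hydroxyl, and a sulfate group on sulfated rings) running parallel to it,
#' from the non-reducing end. For each planted hydrogen-bond pair a dedicated
#' ring oxygen toggles, frame by frame, between a geometry inside the
#' 3.0-Angstrom / 135-degree window (2.85 A, near-linear) and one well
#' outside (6 A), with per-frame probability equal to the target occupancy.
#' For each planted hot pair a unit positive/negative charge pair (protein
#' carbon, ring carbon at ~3.6 A) makes that cell dominate the electrostatic
#' interaction energy; all other atoms carry small background charges. The
#' fragments only exercise the geometric and energetic definitions — they
#' are not meant to fold plausibly.
#'
#' @param spec a [synth_spec()].
#' @return list: `ensemble` (a `gag_ensemble` with nonbonded parameters),
#'   `annotation` (a `gag_glycan`), `truth` (planted H-bond pairs with donor
#'   and acceptor atoms and realised per-frame states; planted hot pairs with
#'   residue labels).
#' @export
gen_toy_complex_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    np <- spec$n_protein_residues
    tokens <- strsplit(spec$glycan_pattern, "-", fixed = TRUE)[[1L]]
    dp <- length(tokens)
    hb <- spec$planted_hbond_pairs
    hot <- spec$planted_hot_pairs
    stopifnot(all(hb$residue >= 1 & hb$residue <= np),
              all(hb$ring >= 1 & hb$ring <= dp),
              all(hot$residue >= 1 & hot$residue <= np),
              all(hot$ring >= 1 & hot$ring <= dp))
    rows <- list()
    add <- function(name, el, x, y, z, chain, resnum, resname, q) {
      rows[[length(rows) + 1L]] <<- data.frame(
        name = name, element = el, x = x, y = y, z = z, chain = chain,
        resnum = resnum, resname = resname, charge = q,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(np)) {
      qbase <- if (i %% 2L) 0.05 else -0.05
      qca <- qbase + if (i %in% hot$residue) 1 else 0
      add("CA", "C", 6 * i, 0.0, 0, "A", i, "TOY", qca)
      add("N", "N", 6 * i, 1.4, 0, "A", i, "TOY", 0.02)
      add("HN", "H", 6 * i, 2.4, 0, "A", i, "TOY", 0.01)
      add("O", "O", 6 * i + 1.3, -0.6, 0, "A", i, "TOY", -0.02)
    }
    for (j in seq_len(dp)) {
      info <- parse_pattern_token(tokens[j])
      rn <- ring_resname(info$type)
      resnum <- 100L + j
      add("C1", "C", 6 * j, 9.0, 0, "B", resnum, rn, -0.05)
      add("O5", "O", 6 * j + 1.3, 9.5, 0, "B", resnum, rn, -0.02)
      add("O3", "O", 6 * j - 1.3, 9.5, 0, "B", resnum, rn, -0.02)
      add("H3", "H", 6 * j - 1.3, 10.5, 0, "B", resnum, rn, 0.01)
      if (length(info$flags)) {
        add("S1", "S", 6 * j, 10.8, 0, "B", resnum, rn, 0.3)
        add("O1S", "O", 6 * j - 1.2, 11.5, 0, "B", resnum, rn, -0.2)
        add("O2S", "O", 6 * j + 1.2, 11.5, 0, "B", resnum, rn, -0.2)
        add("O3S", "O", 6 * j, 10.8, 1.3, "B", resnum, rn, -0.2)
      }
    }
    # planted H-bond acceptors (toggled per frame) and hot-pair charges
    hb_atoms <- integer(nrow(hb))
    ring_rn <- vapply(tokens, function(t)
      ring_resname(parse_pattern_token(t)$type), "")
    for (k in seq_len(nrow(hb))) {
      i <- hb$residue[k]; j <- hb$ring[k]
      delta <- min(0.15 * (j - 1L), 0.8)
      add(paste0("OP", k), "O", 6 * i + delta, 4.25, 0, "B", 100L + j,
          ring_rn[j], -0.05)
      hb_atoms[k] <- length(rows)
    }
    for (k in seq_len(nrow(hot))) {
      i <- hot$residue[k]; j <- hot$ring[k]
      add(paste0("QP", k), "C", 6 * i - 1.0 - 0.1 * (j - 1L), 3.5, 0, "B",
          100L + j, ring_rn[j], -1)
    }
    at <- do.call(rbind, rows)
    nb <- elem_nb(at$element)
    atoms <- data.frame(
      serial = seq_len(nrow(at)), name = at$name, element = at$element,
      chain = at$chain, resnum = at$resnum, resname = at$resname,
      role = ifelse(at$chain == "A", "protein", "glycan"),
      charge = at$charge, rmin_half = nb[, 1L], epsilon = nb[, 2L],
      born_radius = nb[, 3L], stringsAsFactors = FALSE)
    base <- as.matrix(at[, c("x", "y", "z")])
    dimnames(base) <- NULL
    for (attempt in seq_len(5L)) {
      coords <- base
      if (spec$coord_jitter_sd > 0)
        coords <- coords + matrix(stats::rnorm(length(coords), 0,
                                               spec$coord_jitter_sd),
                                  ncol = 3L)
      # clash check with planted acceptors in their "on" position
      dd <- cross_dist(coords, coords)
      diag(dd) <- Inf
      if (min(dd) >= 0.8) break
      if (attempt == 5L || spec$coord_jitter_sd == 0)
        stop("infeasible toy geometry: atoms closer than 0.8 Angstrom")
    }
    states <- lapply(hb$occupancy, plant_states, n = spec$n_frames,
                     mode = spec$occupancy_mode, stay = spec$markov_stay)
    frames <- lapply(seq_len(spec$n_frames), function(f) {
      co <- coords
      for (k in seq_len(nrow(hb)))
        if (!states[[k]][f]) co[hb_atoms[k], 2L] <- 7.4
      co
    })
    bh <- rep(list(integer()), nrow(atoms))
    for (i in seq_len(nrow(atoms)))
      if (atoms$name[i] == "N") bh[[i]] <- atoms$serial[i + 1L]   # HN follows
    o3 <- which(atoms$name == "O3")
    for (i in o3) bh[[i]] <- atoms$serial[i + 1L]                 # H3 follows
    ens <- structure_ensemble(atoms, frames, bonded_h = bh)
    ann <- annotate_glycan(ens, spec$glycan_pattern)
    plab <- function(i) residue_label("A", i, "TOY")
    truth <- list(
      hbond = if (nrow(hb)) data.frame(
        residue = hb$residue, ring = hb$ring, occupancy = hb$occupancy,
        realized = vapply(states, mean, 0),
        donor_res = plab(hb$residue), donor_atom = "N",
        acceptor_res = residue_label("B", 100L + hb$ring, ring_rn[hb$ring]),
        acceptor_atom = paste0("OP", seq_len(nrow(hb))),
        stringsAsFactors = FALSE) else NULL,
      hot = if (nrow(hot)) data.frame(
        residue = hot$residue, ring = hot$ring, mean = hot$mean,
        residue_label = plab(hot$residue), stringsAsFactors = FALSE)
      else NULL)
    list(ensemble = ens, annotation = ann, truth = truth)
  })
}

# rotation matrix sending unit e_x to unit vector v
rot_ex_to <- function(v) {
  v <- v / sqrt(sum(v^2))
  e <- c(1, 0, 0)
  c_ <- sum(e * v)
  if (c_ > 1 - 1e-12) return(diag(3L))
  if (c_ < -1 + 1e-12) return(diag(c(-1, -1, 1)))
  ax <- c(e[2] * v[3] - e[3] * v[2], e[3] * v[1] - e[1] * v[3],
          e[1] * v[2] - e[2] * v[1])
  s <- sqrt(sum(ax^2))
  ax <- ax / s
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3L,
              byrow = TRUE)
  diag(3L) + s * K + (1 - c_) * (K %*% K)
}

#' Generate a docking pose set with planted clusters and unbound poses
#'
#' Bound poses are sampled around planted cluster centers (rigid Gaussian
#' translations of a common ligand template, oriented toward the anchor);
#' cluster centers sit on coordinate axes at a radius guaranteeing the
#' requested minimum separation. The unbound fraction is scattered far
#' outside the binding cutoff at mutually distant positions with random
#' orientations. True cluster labels (0 = unbound) and bound flags are
#' returned alongside the poses — tests read the truth, never re-infer it.
#'
#' @param spec a [synth_spec()]; see its `pose` element.
#' @return list: `poses` (list of `gag_pose`), `labels` (true cluster ids,
#'   0 = unbound), `bound` (logical), `anchor`, `template_axis` (unit vector
#'   of the template's non-reducing-to-reducing axis before rotation).
#' @export
gen_pose_set <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed + 1L, {
    ps <- spec$pose
    tokens <- strsplit(spec$glycan_pattern, "-", fixed = TRUE)[[1L]]
    dp <- length(tokens)
    stopifnot(dp >= 2L, ps$n_clusters >= 1L, ps$n_clusters <= 6L)
    L <- 5 * (dp - 1L)
    tmpl <- do.call(rbind, lapply(seq_len(dp), function(j)
      rbind(c(5 * (j - 1L) - L / 2, 0, 0),
            c(5 * (j - 1L) - L / 2 + 0.7, 0.9, 0))))
    el <- rep(c("C", "O"), dp)
    resnum <- rep(seq_len(dp), each = 2L)
    dirs <- rbind(diag(3L), -diag(3L))
    rad <- max(ps$spread / sqrt(2) + 0.1, L / 2 + 5)
    n <- ps$n_poses
    n_unbound <- round(ps$unbound_fraction * n)
    n_bound <- n - n_unbound
    labels <- integer(n)
    poses <- vector("list", n)
    cl_of <- rep_len(seq_len(ps$n_clusters), n_bound)
    for (b in seq_len(n_bound)) {
      c_ <- cl_of[b]
      center <- ps$anchor + rad * dirs[c_, ]
      R <- rot_ex_to(ps$anchor - center)      # reducing end points inward
      shift <- stats::rnorm(3L, 0, ps$within_sd)
      co <- t(R %*% t(tmpl)) + matrix(center + shift, nrow(tmpl), 3L,
                                      byrow = TRUE)
      poses[[b]] <- pose(co, el, resnum = resnum,
                         source = sprintf("bound.c%d.%d", c_, b))
      labels[b] <- c_
    }
    for (u in seq_len(n_unbound)) {
      v <- stats::rnorm(3L)
      v <- v / sqrt(sum(v^2))
      center <- ps$anchor + (rad + L / 2 + ps$cutoff + 10 + 6 * u) * v
      R <- rot_ex_to(stats::rnorm(3L))
      co <- t(R %*% t(tmpl)) + matrix(center, nrow(tmpl), 3L, byrow = TRUE)
      poses[[n_bound + u]] <- pose(co, el, resnum = resnum,
                                   source = sprintf("unbound.%d", u))
    }
    list(poses = poses, labels = labels,
         bound = c(rep(TRUE, n_bound), rep(FALSE, n_unbound)),
         anchor = ps$anchor, template_axis = c(1, 0, 0))
  })
}

#' Generate a decomposition table with planted hot pairs
#'
#' Background cells draw favorable-only noise (negative half-normal with the
#' spec's `noise_sd`); planted hot cells sit at their planted means plus
#' noise. Each cell's total splits into vdW and electrostatic components by
#' `split_ratio`, with the electrostatic part decomposed into a vacuum term
#' (1.5x total) and an opposing reaction-field term (-0.5x), the usual
#' screening structure. Hot cells additionally carry a high residue-pair
#' hydrogen-bond fraction (~0.9) against a small background (~|N(0, 0.03)|),
#' so one fixture feeds all three site-map channels.
#'
#' @param spec a [synth_spec()].
#' @return list: `table` (a `gag_energy` with `hbond_fraction`), `hot_pairs`
#'   (data.frame `residue`, `ring_index`, `mean`, `residue_label`).
#' @export
gen_decomp_fixture <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed + 2L, {
    np <- spec$n_protein_residues
    dp <- length(strsplit(spec$glycan_pattern, "-", fixed = TRUE)[[1L]])
    hot <- spec$planted_hot_pairs
    grid <- expand.grid(residue = seq_len(np), ring_index = seq_len(dp),
                        KEEP.OUT.ATTRS = FALSE)
    total <- -abs(stats::rnorm(nrow(grid), 0, spec$noise_sd))
    hbf <- pmin(1, abs(stats::rnorm(nrow(grid), 0, 0.03)))
    ih <- match(paste(hot$residue, hot$ring),
                paste(grid$residue, grid$ring_index))
    stopifnot(!anyNA(ih))
    total[ih] <- hot$mean + stats::rnorm(nrow(hot), 0, spec$noise_sd)
    hbf[ih] <- pmin(1, pmax(0, 0.9 + stats::rnorm(nrow(hot), 0, 0.02)))
    vdw <- spec$split_ratio * total
    ele_total <- (1 - spec$split_ratio) * total
    labels <- residue_label("A", grid$residue, "TOY")
    tab <- pair_energy_table(
      residue = labels, ring_index = grid$ring_index, vdw = vdw,
      ele_vac = 1.5 * ele_total, ele_rf = -0.5 * ele_total,
      hbond_fraction = hbf, provenance = "ingested")
    list(table = tab,
         hot_pairs = data.frame(
           residue = hot$residue, ring_index = hot$ring, mean = hot$mean,
           residue_label = residue_label("A", hot$residue, "TOY"),
           stringsAsFactors = FALSE))
  })
}

#' Generate per-ligand binding free-energy samples with a planted order
#'
#' Normal draws at the planted means/SD/n of the spec's `deltag` element.
#'
#' @param spec a [synth_spec()].
#' @return list: `samples` (a `gag_deltag`), `true_order` (ligand labels,
#'   strongest planted binder first).
#' @export
gen_deltag_samples <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed + 3L, {
    dg <- spec$deltag
    stopifnot(!is.null(names(dg$means)))
    vals <- lapply(dg$means, function(m) stats::rnorm(dg$n, m, dg$sd))
    list(samples = deltag_samples(vals),
         true_order = names(sort(dg$means)))
  })
}
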