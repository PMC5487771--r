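#' Parameters of the internal pairwise energy engine
#'
#' The internal engine is a self-contained, conservation-checkable source of
#' physically shaped interaction tables: Lennard-Jones van der Waals, vacuum
#' Coulomb electrostatics, and a Generalized-Born-style screened reaction
#' field. Born radii are supplied per atom, not solved for; production
#' decompositions are expected to be ingested from an external solver via
#' [parse_decomp_table()].
#'
#' @param interior_dielectric solute dielectric (default 1).
#' @param solvent_dielectric solvent dielectric (default 78.5).
#' @param coulomb_constant electrostatic constant, kcal A / (mol e^2).
#' @return object of class `energy_params`.
#' @export
energy_params <- function(interior_dielectric = 1,
                          solvent_dielectric = 78.5,
                          coulomb_constant = 332.0636) {
  stopifnot(interior_dielectric > 0, solvent_dielectric > 0,
            coulomb_constant > 0)
  structure(list(interior_dielectric = interior_dielectric,
                 solvent_dielectric = solvent_dielectric,
                 coulomb_constant = coulomb_constant),
            class = "energy_params")
}

# Vectorised core: all inputs recycled to common length.
pair_energy_components <- function(q1, q2, rm1, rm2, eps1, eps2,
                                   R1, R2, r, params) {
  if (any(r <= 0)) stop("pair distance must be > 0")
  k <- params$coulomb_constant
  ei <- params$interior_dielectric
  es <- params$solvent_dielectric
  rmin <- rm1 + rm2                        # Lorentz combining on rmin/2
  eps <- sqrt(eps1 * eps2)                 # Berthelot combining
  sr6 <- (rmin / r)^6
  vdw <- eps * (sr6^2 - 2 * sr6)
  ele_vac <- k * q1 * q2 / (ei * r)
  fgb <- sqrt(r^2 + R1 * R2 * exp(-r^2 / (4 * R1 * R2)))
  ele_rf <- -k * (1 / ei - 1 / es) * q1 * q2 / fgb
  list(vdw = vdw, ele_vac = ele_vac, ele_rf = ele_rf)
}

#' Pairwise interaction energy between two atoms
#'
#' @param a1,a2 lists (or single data.frame rows) with `charge` (e),
#'   `rmin_half` (Angstrom), `epsilon` (kcal/mol) and `born_radius`
#'   (Angstrom).
#' @param r interatomic distance, Angstrom (> 0).
#' @param params an [energy_params()].
#' @return named numeric vector `vdw`, `ele_vac`, `ele_rf` (kcal/mol).
#' @export
atom_pair_energies <- function(a1, a2, r, params = energy_params()) {
  need <- c("charge", "rmin_half", "epsilon", "born_radius")
  for (a in list(a1, a2))
    if (any(vapply(need, function(f) is.null(a[[f]]) || is.na(a[[f]]), TRUE)))
      stop("atom is missing nonbonded parameter(s): ",
           paste(need[vapply(need, function(f)
             is.null(a[[f]]) || is.na(a[[f]]), TRUE)], collapse = ", "))
  e <- pair_energy_components(a1$charge, a2$charge, a1$rmin_half,
                              a2$rmin_half, a1$epsilon, a2$epsilon,
                              a1$born_radius, a2$born_radius, r, params)
  c(vdw = e$vdw, ele_vac = e$ele_vac, ele_rf = e$ele_rf)
}

# Residue labels and ring indices for glycan atoms given an annotation.
glycan_ring_of_atoms <- function(ensemble, annotation) {
  glab <- residue_label(annotation$chain, annotation$resnum,
                        annotation$resname)
  annotation$ring_index[match(atom_res_labels(ensemble), glab)]
}

#' Per-(protein residue, sugar ring) energy decomposition
#'
#' Sums [atom_pair_energies()] over every intermolecular atom pair of each
#' (protein residue, glycan ring) cell, with no distance cutoff, and averages
#' over frames. Serves as the internal stand-in for an external per-residue
#' pairwise decomposition and as the conservation oracle for the site-maps:
#' the component-wise sum over all cells equals the total protein-glycan
#' interaction energy by construction.
#'
#' @param ensemble a `gag_ensemble` whose atoms carry `charge`, `rmin_half`,
#'   `epsilon`, `born_radius` (see [attach_atom_params()]).
#' @param annotation a `gag_glycan`.
#' @param params an [energy_params()].
#' @return a `gag_energy` table; see [pair_energy_table()].
#' @export
residue_pair_decomposition <- function(ensemble, annotation,
                                       params = energy_params()) {
  a <- ensemble$atoms
  need <- c("charge", "rmin_half", "epsilon", "born_radius")
  bad <- which(Reduce(`|`, lapply(need, function(f) is.na(a[[f]]))))
  if (length(bad))
    stop("atoms without nonbonded parameters: ",
         paste(utils::head(a$name[bad], 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  pi_ <- which(a$role == "protein")
  gi <- which(a$role == "glycan")
  if (!length(pi_) || !length(gi))
    stop("ensemble must contain both protein and glycan atoms")
  plab <- atom_res_labels(ensemble)[pi_]
  ring <- glycan_ring_of_atoms(ensemble, annotation)[gi]
  if (anyNA(ring))
    stop("glycan atoms not covered by the annotation")
  cellkey <- function(p, r) paste(p, r, sep = "\r")
  keys <- cellkey(rep(plab, times = length(gi)),
                  rep(ring, each = length(pi_)))
  q1 <- rep(a$charge[pi_], times = length(gi))
  q2 <- rep(a$charge[gi], each = length(pi_))
  rm1 <- rep(a$rmin_half[pi_], times = length(gi))
  rm2 <- rep(a$rmin_half[gi], each = length(pi_))
  e1 <- rep(a$epsilon[pi_], times = length(gi))
  e2 <- rep(a$epsilon[gi], each = length(pi_))
  R1 <- rep(a$born_radius[pi_], times = length(gi))
  R2 <- rep(a$born_radius[gi], each = length(pi_))
  nf <- length(ensemble$frames)
  acc <- NULL
  for (f in seq_len(nf)) {
    co <- ensemble$frames[[f]]
    r <- as.vector(cross_dist(co[pi_, , drop = FALSE],
                              co[gi, , drop = FALSE]))
    e <- pair_energy_components(q1, q2, rm1, rm2, e1, e2, R1, R2, r, params)
    s <- rowsum(cbind(vdw = e$vdw, ele_vac = e$ele_vac, ele_rf = e$ele_rf),
                keys)
    acc <- if (is.null(acc)) s else acc + s
  }
  acc <- acc / nf
  parts <- strsplit(rownames(acc), "\r", fixed = TRUE)
  pair_energy_table(
    residue = vapply(parts, `[`, "", 1L),
    ring_index = as.integer(vapply(parts, `[`, "", 2L)),
    vdw = acc[, "vdw"], ele_vac = acc[, "ele_vac"], ele_rf = acc[, "ele_rf"],
    provenance = "internal_engine", n_frames_averaged = nf
  )
}

#' Total intermolecular interaction energy (direct sum)
#'
#' Direct double loop over all protein-glycan atom pairs, frame-averaged.
#' Independent of the residue bookkeeping in
#' [residue_pair_decomposition()]; used to verify that the decomposition
#' conserves each component.
#'
#' @inheritParams residue_pair_decomposition
#' @return named numeric vector `vdw`, `ele_vac`, `ele_rf` (kcal/mol).
#' @export
total_interaction_energy <- function(ensemble, params = energy_params()) {
  a <- ensemble$atoms
  pi_ <- which(a$role == "protein")
  gi <- which(a$role == "glycan")
  tot <- c(vdw = 0, ele_vac = 0, ele_rf = 0)
  for (f in seq_along(ensemble$frames)) {
    co <- ensemble$frames[[f]]
    for (i in pi_) for (j in gi) {
      r <- sqrt(sum((co[i, ] - co[j, ])^2))
      e <- pair_energy_components(a$charge[i], a$charge[j], a$rmin_half[i],
                                  a$rmin_half[j], a$epsilon[i], a$epsilon[j],
                                  a$born_radius[i], a$born_radius[j],
                                  r, params)
      tot <- tot + c(e$vdw, e$ele_vac, e$ele_rf)
    }
  }
  tot / length(ensemble$frames)
}

#' Average several decomposition tables cell-wise
#'
#' Arithmetic mean per cell and component over tables with identical key
#' sets (e.g. replicas or frame blocks); `n_frames_averaged` accumulates.
#'
#' @param tables list of `gag_energy` tables.
#' @return a `gag_energy` table.
#' @export
average_decomposition <- function(tables) {
  stopifnot(length(tables) >= 1L)
  key <- function(t) paste(t$residue, t$ring_index, sep = "\r")
  ref <- tables[[1L]]
  ord <- order(key(ref))
  ref <- ref[ord, , drop = FALSE]
  k0 <- key(ref)
  acc <- as.matrix(ref[, c("vdw", "ele_vac", "ele_rf")])
  nf <- attr(ref, "n_frames_averaged") %||% 1L
  for (t in tables[-1L]) {
    t <- t[order(key(t)), , drop = FALSE]
    if (!identical(key(t), k0))
      stop("decomposition tables have mismatched (residue, ring) key sets")
    acc <- acc + as.matrix(t[, c("vdw", "ele_vac", "ele_rf")])
    nf <- nf + (attr(t, "n_frames_averaged") %||% 1L)
  }
  acc <- acc / length(tables)
  pair_energy_table(
    residue = ref$residue, ring_index = ref$ring_index,
    vdw = acc[, "vdw"], ele_vac = acc[, "ele_vac"], ele_rf = acc[, "ele_rf"],
    hbond_fraction = ref$hbond_fraction,
    provenance = attr(ref, "provenance") %||% "ingested",
    n_frames_averaged = nf
  )
}
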