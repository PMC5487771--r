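#' Construct a structural ensemble
#'
#' A `gag_ensemble` bundles a fixed topology (one row per atom) with an ordered
#' list of coordinate frames, the shared data model for all ensemble-based
#' analyses. Coordinates are in Angstrom, charges in elementary charge units,
#' Lennard-Jones parameters in the rmin/2 (Angstrom) + epsilon (kcal/mol)
#' convention.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `chain`,
#'   `resnum`, `resname`, `role` (`"protein"`, `"glycan"` or `"other"`), and
#'   optionally `charge`, `rmin_half`, `epsilon`, `born_radius`.
#' @param frames list of numeric matrices (one per frame, `nrow(atoms)` x 3).
#' @param bonded_h list (same length as `nrow(atoms)`) of atom serial vectors:
#'   the hydrogens covalently bonded to each heavy atom (empty for most).
#' @param frame_times optional numeric vector of frame times (ps).
#' @return object of class `gag_ensemble`.
#' @export
structure_ensemble <- function(atoms, frames, bonded_h = NULL,
                               frame_times = NULL) {
  stopifnot(is.data.frame(atoms), is.list(frames), length(frames) >= 1L)
  req <- c("serial", "name", "element", "chain", "resnum", "resname", "role")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("atom serials must be unique within the topology")
  if (any(!nzchar(atoms$element)))
    stop("every atom must have a non-empty element")
  for (opt in c("charge", "rmin_half", "epsilon", "born_radius"))
    if (is.null(atoms[[opt]])) atoms[[opt]] <- NA_real_
  n <- nrow(atoms)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3L)
      stop("frame ", i, " does not match the topology (expected ", n,
           " x 3 coordinates)")
    if (any(!is.finite(f)))
      stop("frame ", i, " contains non-finite coordinates")
  }
  if (is.null(bonded_h)) bonded_h <- rep(list(integer()), n)
  stopifnot(length(bonded_h) == n)
  structure(
    list(atoms = atoms, frames = frames, bonded_h = bonded_h,
         frame_times = frame_times),
    class = "gag_ensemble"
  )
}

#' @export
print.gag_ensemble <- function(x, ...) {
  cat("Structural ensemble:", nrow(x$atoms), "atoms,",
      length(x$frames), "frame(s)\n")
  tab <- table(x$atoms$role[!duplicated(residue_label(
    x$atoms$chain, x$atoms$resnum, x$atoms$resname))])
  cat("  residues:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Residue label per atom.
atom_res_labels <- function(ensemble) {
  residue_label(ensemble$atoms$chain, ensemble$atoms$resnum,
                ensemble$atoms$resname)
}

# Row indices of the hydrogens bonded to atom row i.
bonded_h_rows <- function(ensemble, i) {
  match(ensemble$bonded_h[[i]], ensemble$atoms$serial)
}

# Infer covalently bonded hydrogens: H within `dmax` Angstrom of a heavy atom
# in the reference frame; each H is attached to its nearest heavy atom.
infer_bonded_hydrogens <- function(atoms, coords, dmax = 1.2) {
  n <- nrow(atoms)
  out <- rep(list(integer()), n)
  hrows <- which(atoms$element == "H")
  heavy <- which(atoms$element != "H")
  if (!length(hrows) || !length(heavy)) return(out)
  d <- cross_dist(coords[hrows, , drop = FALSE], coords[heavy, , drop = FALSE])
  for (k in seq_along(hrows)) {
    j <- which.min(d[k, ])
    if (d[k, j] <= dmax) {
      hv <- heavy[j]
      out[[hv]] <- c(out[[hv]], atoms$serial[hrows[k]])
    }
  }
  out
}

#' Parse a multi-model PDB file into a structural ensemble
#'
#' Each MODEL record becomes one frame; all models must share the same atom
#' ordering. Residues are partitioned into protein and glycan by residue name
#' (and optionally chain). Covalently bonded hydrogens are inferred from the
#' first frame (H within 1.2 Angstrom of its nearest heavy atom), as required
#' by the donor/H-bond machinery.
#'
#' @param path path to a (multi-model) PDB file.
#' @param glycan_resnames character vector of residue names treated as glycan
#'   rings. At least one matching residue must be present.
#' @param protein_chains optional character vector restricting which chains are
#'   treated as protein; residues outside it (and not glycan) get role
#'   `"other"`.
#' @return a [structure_ensemble()].
#' @export
parse_structure_ensemble <- function(path, glycan_resnames,
                                     protein_chains = NULL) {
  stopifnot(file.exists(path), length(glycan_resnames) >= 1L)
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1L) {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
    if (length(unique(counts)) != 1L)
      stop("inconsistent atom counts across models: model ",
           which(counts != counts[1])[1], " has ",
           counts[counts != counts[1]][1], " atoms, expected ", counts[1])
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || any(is.na(elem) | !nzchar(trimws(elem)))) {
    fixme <- is.na(elem) | !nzchar(trimws(elem))
    elem[fixme] <- bio3d::atom2ele(at$elety[fixme])
  }
  elem <- trimws(elem)
  chain <- ifelse(is.na(at$chain), " ", at$chain)
  role <- ifelse(at$resid %in% glycan_resnames, "glycan",
                 if (is.null(protein_chains)) "protein"
                 else ifelse(chain %in% protein_chains, "protein", "other"))
  if (!any(role == "glycan"))
    stop("no glycan residues found: none of ",
         paste(glycan_resnames, collapse = ", "), " occurs in ", path)
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = elem,
    chain = chain, resnum = at$resno, resname = trimws(at$resid),
    role = role, stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  bh <- infer_bonded_hydrogens(atoms, frames[[1L]])
  structure_ensemble(atoms, frames, bonded_h = bh)
}

#' Write a structural ensemble as a multi-model PDB file
#'
#' One MODEL record per frame. Round-trips through
#' [parse_structure_ensemble()] to PDB coordinate precision (1e-3 Angstrom).
#'
#' @param ensemble a `gag_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "gag_ensemble"))
  a <- ensemble$atoms
  xyz <- do.call(rbind, lapply(ensemble$frames, function(f) as.vector(t(f))))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
    eleno = a$serial, elety = a$name, resid = a$resname,
    chain = a$chain, resno = a$resnum,
    o = rep(1, nrow(a)), b = rep(0, nrow(a)), elesy = a$element
  )
  invisible(path)
}

# ---- glycan annotation -------------------------------------------------------

# Parse one sulfation-pattern token, e.g. "GlcNS6S", "IdoA2S", "IdoA", "GlcN".
parse_pattern_token <- function(token) {
  flags <- character()
  if (grepl("^GlcN", token)) {
    rest <- substring(token, 5L)
    if (startsWith(rest, "S")) {
      flags <- "NS"
      rest <- substring(rest, 2L)
    }
    codes <- regmatches(rest, gregexpr("[0-9]S", rest))[[1L]]
    flags <- c(flags, codes)
    type <- if ("NS" %in% flags) "GlcNS" else "GlcN"
  } else if (grepl("^IdoA", token)) {
    rest <- substring(token, 5L)
    flags <- regmatches(rest, gregexpr("[0-9]S", rest))[[1L]]
    type <- if ("2S" %in% flags) "IdoA2S" else "IdoA"
  } else {
    type <- "other"
  }
  list(type = type, flags = flags)
}

#' Annotate the glycan chain of an ensemble with a sulfation pattern
#'
#' The pattern string lists one ring per glycan residue, from the non-reducing
#' to the reducing end, separated by `-`. Recognised ring tokens are `GlcN`,
#' `GlcNS` (optionally with positional sulfation codes such as `6S` or `3S`,
#' e.g. `GlcNS6S`), `IdoA`, `IdoA2S`; anything else gets ring type `other`.
#' Glycan residues are taken in order of appearance in the topology, which
#' must run from the non-reducing end.
#'
#' @param ensemble a `gag_ensemble`.
#' @param pattern pattern string, e.g.
#'   `"GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S-IdoA2S"` for a fully sulfated
#'   heparin hexasaccharide.
#' @return a `gag_glycan` data.frame with one row per ring: `ring_index`
#'   (1-based from the non-reducing end), `chain`, `resnum`, `resname`,
#'   `ring_type`, `sulfation` (comma-joined flags) and `token`.
#' @export
annotate_glycan <- function(ensemble, pattern) {
  stopifnot(inherits(ensemble, "gag_ensemble"))
  g <- ensemble$atoms[ensemble$atoms$role == "glycan", , drop = FALSE]
  lab <- residue_label(g$chain, g$resnum, g$resname)
  keep <- !duplicated(lab)
  res <- g[keep, c("chain", "resnum", "resname")]
  tokens <- strsplit(pattern, "-", fixed = TRUE)[[1L]]
  if (length(tokens) != nrow(res))
    stop("pattern has ", length(tokens), " rings but the ensemble has ",
         nrow(res), " glycan residues")
  parsed <- lapply(tokens, parse_pattern_token)
  ann <- data.frame(
    ring_index = seq_len(nrow(res)),
    chain = res$chain, resnum = res$resnum, resname = res$resname,
    ring_type = vapply(parsed, `[[`, "", "type"),
    sulfation = vapply(parsed, function(p) paste(p$flags, collapse = ","), ""),
    token = tokens,
    stringsAsFactors = FALSE
  )
  class(ann) <- c("gag_glycan", "data.frame")
  ann
}

#' Format a glycan annotation back into its pattern string
#' @param annotation a `gag_glycan`.
#' @return the pattern string (non-reducing to reducing end).
#' @export
format_glycan_pattern <- function(annotation) {
  paste(annotation$token[order(annotation$ring_index)], collapse = "-")
}

#' Evenly subsample the tail of an ensemble
#'
#' Selects `count` frames at evenly spaced indices within the final
#' `tail_frames` window (endpoints of the window included whenever
#' `count >= 2`), the usual convention for energy post-processing of the
#' last stretch of a trajectory.
#'
#' @param ensemble a `gag_ensemble`.
#' @param tail_frames size of the trailing window.
#' @param count number of frames to keep (`<= tail_frames`).
#' @return a `gag_ensemble` with `count` frames.
#' @export
subsample_tail <- function(ensemble, tail_frames, count) {
  stopifnot(inherits(ensemble, "gag_ensemble"))
  n <- length(ensemble$frames)
  if (tail_frames > n)
    stop("tail_frames (", tail_frames, ") exceeds the ", n, " frames available")
  if (count > tail_frames)
    stop("count (", count, ") exceeds tail_frames (", tail_frames, ")")
  if (count < 1L) stop("count must be >= 1")
  start <- n - tail_frames + 1L
  idx <- if (count == 1L) n else
    start + as.integer(round(seq(0, tail_frames - 1L, length.out = count)))
  out <- ensemble
  out$frames <- ensemble$frames[idx]
  if (!is.null(ensemble$frame_times))
    out$frame_times <- ensemble$frame_times[idx]
  attr(out, "subsampled_indices") <- idx
  out
}

# ---- per-atom parameter tables ----------------------------------------------

#' Write / read per-atom nonbonded parameters
#'
#' PDB files carry no charges or Lennard-Jones parameters, so ensembles that
#' feed the internal energy engine exchange them through a sidecar TSV keyed
#' by atom serial (columns `serial`, `charge`, `rmin_half`, `epsilon`,
#' `born_radius`).
#'
#' @param ensemble a `gag_ensemble`.
#' @param path TSV path.
#' @return `write_atom_params()`: `path` invisibly; `attach_atom_params()`:
#'   the ensemble with parameters merged onto its atoms.
#' @export
write_atom_params <- function(ensemble, path) {
  a <- ensemble$atoms
  write_canonical_tsv(
    a[, c("serial", "charge", "rmin_half", "epsilon", "born_radius")], path,
    meta = "per-atom nonbonded parameters (e, Angstrom, kcal/mol, Angstrom)"
  )
  invisible(path)
}

#' @rdname write_atom_params
#' @export
attach_atom_params <- function(ensemble, path) {
  p <- read_canonical_tsv(path)
  i <- match(ensemble$atoms$serial, p$serial)
  if (anyNA(i))
    stop("parameter table is missing atom serial(s): ",
         paste(ensemble$atoms$serial[is.na(i)], collapse = ", "))
  for (col in c("charge", "rmin_half", "epsilon", "born_radius"))
    ensemble$atoms[[col]] <- p[[col]][i]
  ensemble
}
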