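#' Geometric hydrogen-bond criteria
#'
#' The default criteria are the common trajectory-analysis convention: heavy
#' donor-acceptor distance at most 3.0 Angstrom and donor-H-acceptor angle at
#' least 135 degrees.
#'
#' @param heavy_distance_cutoff heavy-atom D...A distance cutoff, Angstrom.
#' @param dha_angle_cutoff D-H...A angle cutoff, degrees (bond kept when the
#'   angle is `>=` the cutoff).
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(heavy_distance_cutoff = 3.0,
                           dha_angle_cutoff = 135) {
  stopifnot(heavy_distance_cutoff > 0,
            dha_angle_cutoff > 0, dha_angle_cutoff <= 180)
  structure(list(heavy_distance_cutoff = heavy_distance_cutoff,
                 dha_angle_cutoff = dha_angle_cutoff),
            class = "hbond_criteria")
}

#' Classify atoms as hydrogen-bond donors and acceptors
#'
#' Donors are N/O heavy atoms carrying at least one covalently bonded
#' hydrogen; acceptors are all N/O heavy atoms (including sulfate and
#' carboxylate oxygens). An atom may be both. With `distance_only = TRUE`
#' (the fallback for structures without hydrogens) every N/O atom is treated
#' as a potential donor.
#'
#' @param ensemble a `gag_ensemble`.
#' @param distance_only logical; see above.
#' @return list with integer atom-row vectors `donors` and `acceptors`.
#' @export
classify_donors_acceptors <- function(ensemble, distance_only = FALSE) {
  a <- ensemble$atoms
  no <- which(a$element %in% c("N", "O"))
  has_h <- lengths(ensemble$bonded_h[no]) > 0L
  donors <- if (distance_only) no else no[has_h]
  list(donors = donors, acceptors = no)
}

#' Detect hydrogen bonds in a single frame
#'
#' A donor-acceptor atom pair (in different residues) forms a hydrogen bond
#' when the heavy-atom distance is within the cutoff and at least one bonded
#' hydrogen satisfies the D-H...A angle cutoff; the qualifying hydrogen is
#' reported. With `distance_only = TRUE` the angle test is skipped (crystal
#' structures without hydrogens) and the reported hydrogen is `NA`.
#'
#' @param ensemble a `gag_ensemble`.
#' @param frame frame index, or an `natoms` x 3 coordinate matrix.
#' @param criteria an [hbond_criteria()].
#' @param intermolecular if `TRUE` (default) only protein-glycan pairs are
#'   considered; otherwise any pair of distinct residues.
#' @param distance_only skip the angle criterion (see Details). A donor
#'   without hydrogens is a hard error unless this is set.
#' @param donors,acceptors optional atom-row vectors; defaults to
#'   [classify_donors_acceptors()].
#' @return data.frame with atom-row columns `donor`, `h` (serial of the
#'   qualifying hydrogen, `NA` in distance-only mode), `acceptor`, plus
#'   distance and angle.
#' @export
detect_hbonds_frame <- function(ensemble, frame, criteria = hbond_criteria(),
                                intermolecular = TRUE, distance_only = FALSE,
                                donors = NULL, acceptors = NULL) {
  stopifnot(inherits(ensemble, "gag_ensemble"))
  coords <- if (is.matrix(frame)) frame else ensemble$frames[[frame]]
  da <- classify_donors_acceptors(ensemble, distance_only = distance_only)
  if (is.null(donors)) donors <- da$donors
  if (is.null(acceptors)) acceptors <- da$acceptors
  empty <- data.frame(donor = integer(), h = integer(), acceptor = integer(),
                      distance = numeric(), angle = numeric())
  if (!length(donors) || !length(acceptors)) return(empty)
  if (!distance_only) {
    noh <- donors[lengths(ensemble$bonded_h[donors]) == 0L]
    if (length(noh))
      stop("donor atom(s) without bonded hydrogens (set distance_only for ",
           "H-free structures): ",
           paste(ensemble$atoms$name[noh], residue_label(
             ensemble$atoms$chain[noh], ensemble$atoms$resnum[noh],
             ensemble$atoms$resname[noh]), collapse = ", "))
  }
  a <- ensemble$atoms
  rlab <- atom_res_labels(ensemble)
  d <- cross_dist(coords[donors, , drop = FALSE],
                  coords[acceptors, , drop = FALSE])
  cand <- which(d <= criteria$heavy_distance_cutoff, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  di <- donors[cand[, 1L]]
  ai <- acceptors[cand[, 2L]]
  keep <- rlab[di] != rlab[ai]
  if (intermolecular)
    keep <- keep & ((a$role[di] == "protein" & a$role[ai] == "glycan") |
                    (a$role[di] == "glycan" & a$role[ai] == "protein"))
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  di <- donors[cand[, 1L]]
  ai <- acceptors[cand[, 2L]]
  dist <- d[cand]
  if (distance_only) {
    # without hydrogens donor/acceptor direction is unknowable: report each
    # unordered pair once (both atoms are in the candidate N/O set)
    keep <- di < ai
    return(data.frame(donor = di[keep], h = NA_integer_,
                      acceptor = ai[keep], distance = dist[keep],
                      angle = NA_real_))
  }
  out <- vector("list", length(di))
  for (k in seq_along(di)) {
    hs <- bonded_h_rows(ensemble, di[k])
    for (h in hs) {
      ang <- angle_deg(coords[di[k], ], coords[h, ], coords[ai[k], ])
      if (ang >= criteria$dha_angle_cutoff) {
        out[[k]] <- data.frame(donor = di[k], h = a$serial[h],
                               acceptor = ai[k], distance = dist[k],
                               angle = ang)
        break
      }
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Hydrogen-bond occupancy across an ensemble
#'
#' For each donor-acceptor atom pair, the occupancy is the fraction of frames
#' in which the pair satisfies the geometric criteria (multiple hydrogens on
#' one donor count once per frame).
#'
#' @inheritParams detect_hbonds_frame
#' @return a `gag_occupancy` data.frame with columns `donor_res`,
#'   `donor_atom`, `acceptor_res`, `acceptor_atom`, `fraction`, sorted by
#'   decreasing fraction; attributes `n_frames`, `criteria`, `distance_only`.
#' @export
occupancy_table <- function(ensemble, criteria = hbond_criteria(),
                            intermolecular = TRUE, distance_only = FALSE) {
  stopifnot(length(ensemble$frames) >= 1L)
  da <- classify_donors_acceptors(ensemble, distance_only = distance_only)
  counts <- new.env(parent = emptyenv())
  for (f in seq_along(ensemble$frames)) {
    hb <- detect_hbonds_frame(ensemble, f, criteria,
                              intermolecular = intermolecular,
                              distance_only = distance_only,
                              donors = da$donors, acceptors = da$acceptors)
    if (!nrow(hb)) next
    keys <- paste(hb$donor, hb$acceptor, sep = "|")
    for (k in unique(keys))
      assign(k, (counts[[k]] %||% 0L) + 1L, envir = counts)
  }
  keys <- ls(counts)
  a <- ensemble$atoms
  rlab <- atom_res_labels(ensemble)
  if (length(keys)) {
    ij <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    di <- as.integer(ij[, 1L]); ai <- as.integer(ij[, 2L])
    tab <- data.frame(
      donor_res = rlab[di], donor_atom = a$name[di],
      acceptor_res = rlab[ai], acceptor_atom = a$name[ai],
      fraction = vapply(keys, function(k) counts[[k]], 0L) /
        length(ensemble$frames),
      stringsAsFactors = FALSE
    )
    tab <- tab[order(-tab$fraction, tab$donor_res, tab$acceptor_res,
                     tab$donor_atom, tab$acceptor_atom), ]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(donor_res = character(), donor_atom = character(),
                      acceptor_res = character(), acceptor_atom = character(),
                      fraction = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(tab$fraction >= 0 & tab$fraction <= 1))
  attr(tab, "n_frames") <- length(ensemble$frames)
  attr(tab, "criteria") <- criteria
  attr(tab, "distance_only") <- distance_only
  class(tab) <- c("gag_occupancy", "data.frame")
  tab
}

#' Keep the k most frequent hydrogen bonds
#'
#' Selection used when comparing structure-derived and docking-derived
#' hydrogen-bond sets of matched size (e.g. the 33 most frequent bonds).
#' Ties are broken deterministically by donor residue number, acceptor
#' residue number, then atom names.
#'
#' @param table a `gag_occupancy`.
#' @param k number of bonds to keep (`k = 0` empties the table; `k` larger
#'   than the table returns it whole).
#' @return a `gag_occupancy` with at most `k` rows.
#' @export
select_top_bonds <- function(table, k) {
  stopifnot(k >= 0)
  dres <- split_residue_label(table$donor_res)
  ares <- split_residue_label(table$acceptor_res)
  ord <- order(-table$fraction, dres$resnum, ares$resnum,
               table$donor_atom, table$acceptor_atom)
  out <- table[ord[seq_len(min(k, nrow(table)))], , drop = FALSE]
  rownames(out) <- NULL
  for (at in c("n_frames", "criteria", "distance_only"))
    attr(out, at) <- attr(table, at)
  class(out) <- class(table)
  out
}

#' Collapse atom-pair occupancies to (protein residue, sugar ring) pairs
#'
#' The residue-pair statistic is the maximum over that pair's atom-pair
#' occupancies, which avoids counting one physical contact several times
#' through alternative hydrogens. The glycan side of each bond is identified
#' through the annotation; pairs with no annotated ring on either side are
#' dropped.
#'
#' @param table a `gag_occupancy`.
#' @param annotation a `gag_glycan` from [annotate_glycan()].
#' @return data.frame `protein_res` (residue label), `ring_index`, `fraction`,
#'   one row per residue pair.
#' @export
residue_occupancy <- function(table, annotation) {
  glab <- residue_label(annotation$chain, annotation$resnum,
                        annotation$resname)
  empty <- data.frame(protein_res = character(), ring_index = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE)
  if (!nrow(table)) return(empty)
  d_ring <- match(table$donor_res, glab)
  a_ring <- match(table$acceptor_res, glab)
  has <- xor(is.na(d_ring), is.na(a_ring))
  if (!any(has)) return(empty)
  ring <- ifelse(is.na(d_ring), a_ring, d_ring)[has]
  prot <- ifelse(is.na(d_ring), table$donor_res, table$acceptor_res)[has]
  ring <- annotation$ring_index[ring]
  agg <- stats::aggregate(
    list(fraction = table$fraction[has]),
    by = list(protein_res = prot, ring_index = ring), FUN = max)
  agg[order(agg$protein_res, agg$ring_index), , drop = FALSE]
}

#' Write / read an occupancy table as canonical TSV
#' @param table a `gag_occupancy`.
#' @param path TSV path.
#' @return `write_occupancy()`: `path` invisibly; `read_occupancy()` the
#'   table with its `n_frames` attribute restored.
#' @export
write_occupancy <- function(table, path) {
  meta <- c(paste("n_frames =", attr(table, "n_frames")),
            paste("distance_only =", isTRUE(attr(table, "distance_only"))))
  if (isTRUE(attr(table, "distance_only")))
    meta <- c(meta, "warning = angle criterion skipped (no hydrogens)")
  write_canonical_tsv(as.data.frame(table), path, meta = meta)
  invisible(path)
}

#' @rdname write_occupancy
#' @export
read_occupancy <- function(path) {
  tab <- read_canonical_tsv(path)
  meta <- read_tsv_meta(path)
  attr(tab, "n_frames") <- as.integer(meta_get(meta, "n_frames", NA))
  attr(tab, "distance_only") <-
    identical(meta_get(meta, "distance_only", "FALSE"), "TRUE")
  class(tab) <- c("gag_occupancy", "data.frame")
  tab
}
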