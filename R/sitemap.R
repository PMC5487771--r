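#' Assemble a three-channel site-map
#'
#' A site-map is a protein-residue x sugar-ring matrix per interaction
#' channel: `hbond` (occupancy fraction), `ele` and `vdw` (favorable
#' interaction magnitude, `max(0, -E)` in kcal/mol before normalisation).
#' Unfavorable (positive) energies are clipped to zero and counted in the
#' `clipped` metadata; the signed values remain available in the upstream
#' energy table.
#'
#' @param energies a `gag_energy` table.
#' @param occupancy optional `gag_occupancy` (atom-pair level); collapsed to
#'   residue pairs via [residue_occupancy()]. If omitted, the energy table's
#'   `hbond_fraction` column feeds the `hbond` channel.
#' @param annotation a `gag_glycan`; defines the ring axis (1..dp from the
#'   non-reducing end). Required when `occupancy` is given; otherwise rings
#'   default to those present in `energies`.
#' @return object of class `gag_sitemap`: list with `channels` (named list of
#'   matrices sharing dimnames), `normalization` (`"none"`), `n_sources`,
#'   `clipped` counts.
#' @export
build_sitemap <- function(energies, occupancy = NULL, annotation = NULL) {
  stopifnot(inherits(energies, "gag_energy"))
  rings <- if (!is.null(annotation)) sort(unique(annotation$ring_index))
           else sort(unique(energies$ring_index))
  if (length(setdiff(energies$ring_index, rings)))
    stop("energy table contains ring indices outside the annotation: ",
         paste(setdiff(energies$ring_index, rings), collapse = ", "))
  hb <- if (!is.null(occupancy)) {
    if (is.null(annotation))
      stop("annotation is required to place occupancy entries on rings")
    residue_occupancy(occupancy, annotation)
  } else if (nrow(energies) && !all(is.na(energies$hbond_fraction))) {
    data.frame(protein_res = energies$residue,
               ring_index = energies$ring_index,
               fraction = ifelse(is.na(energies$hbond_fraction), 0,
                                 energies$hbond_fraction))
  } else {
    data.frame(protein_res = character(), ring_index = integer(),
               fraction = numeric())
  }
  residues <- sort(unique(c(energies$residue, hb$protein_res)))
  if (length(setdiff(hb$ring_index, rings)))
    stop("occupancy entries reference rings outside the annotation")
  dn <- list(residues, as.character(rings))
  blank <- matrix(0, length(residues), length(rings), dimnames = dn)
  ch <- list(hbond = blank, ele = blank, vdw = blank)
  if (nrow(energies)) {
    ij <- cbind(match(energies$residue, residues),
                match(energies$ring_index, rings))
    ch$ele[ij] <- pmax(0, -energies$ele_total)
    ch$vdw[ij] <- pmax(0, -energies$vdw)
  }
  if (nrow(hb)) {
    ij <- cbind(match(hb$protein_res, residues),
                match(hb$ring_index, rings))
    ch$hbond[ij] <- hb$fraction
  }
  clipped <- c(ele = sum(energies$ele_total > 0),
               vdw = sum(energies$vdw > 0))
  structure(list(channels = ch, normalization = "none",
                 n_sources = 1L, clipped = clipped),
            class = "gag_sitemap")
}

#' @export
print.gag_sitemap <- function(x, ...) {
  d <- dim(x$channels$hbond)
  cat("Site-map:", d[1L], "protein residues x", d[2L], "rings;",
      "normalization:", x$normalization, ";",
      x$n_sources, "source(s)\n")
  cat("  clipped unfavorable cells: ele =", x$clipped["ele"],
      ", vdw =", x$clipped["vdw"], "\n")
  invisible(x)
}

#' Normalise a site-map
#'
#' `per_ring` divides each ring column by its absolute sum, making maps of
#' glycans of different lengths comparable ring by ring (all-zero columns are
#' left unchanged and flagged); `global` divides each channel by its grand
#' absolute sum. Both are idempotent.
#'
#' @param map a `gag_sitemap`.
#' @param mode `"per_ring"` or `"global"`.
#' @return the normalised `gag_sitemap`.
#' @export
normalize_sitemap <- function(map, mode = c("per_ring", "global")) {
  mode <- match.arg(mode)
  zero_flag <- character()
  for (nm in names(map$channels)) {
    m <- map$channels[[nm]]
    if (mode == "per_ring") {
      s <- colSums(abs(m))
      nz <- s > 0
      m[, nz] <- sweep(m[, nz, drop = FALSE], 2L, s[nz], "/")
      if (any(!nz)) zero_flag <- c(zero_flag, paste0(nm, ":ring ",
        paste(colnames(m)[!nz], collapse = ",")))
    } else {
      s <- sum(abs(m))
      if (s > 0) m <- m / s else zero_flag <- c(zero_flag, nm)
    }
    map$channels[[nm]] <- m
  }
  map$normalization <- mode
  attr(map, "all_zero") <- zero_flag
  map
}

#' Aggregate site-maps over structures or poses
#'
#' Per-channel (optionally weighted) sum over maps with identical index sets,
#' followed by global normalisation, so each channel reads as the fraction of
#' that interaction type carried by each residue-ring cell across the whole
#' source set.
#'
#' @param maps list of `gag_sitemap`s with identical dimnames.
#' @param weights optional numeric weights, one per map.
#' @return a globally normalised `gag_sitemap`; `n_sources` accumulates.
#' @export
aggregate_sitemaps <- function(maps, weights = NULL) {
  stopifnot(length(maps) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(maps))
  stopifnot(length(weights) == length(maps))
  dn <- dimnames(maps[[1L]]$channels$hbond)
  out <- maps[[1L]]
  acc <- lapply(out$channels, function(m) m * weights[1L])
  clip <- out$clipped
  nsrc <- out$n_sources
  for (i in seq_along(maps)[-1L]) {
    m <- maps[[i]]
    if (!identical(dimnames(m$channels$hbond), dn))
      stop("site-maps have mismatched residue/ring index sets")
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + weights[i] * m$channels[[nm]]
    clip <- clip + m$clipped
    nsrc <- nsrc + m$n_sources
  }
  out$channels <- acc
  out$clipped <- clip
  out$n_sources <- nsrc
  out$normalization <- "none"
  normalize_sitemap(out, "global")
}

#' Correlate two site-maps on one channel
#'
#' Correlation over the flattened cell vectors of the chosen channel; the
#' headline coefficient is Pearson, with Spearman available for rank-based
#' comparison. Maps of different glycan lengths should be per-ring
#' normalised and aligned on ring index from the non-reducing end before
#' comparison.
#'
#' @param a,b `gag_sitemap`s with identical index sets.
#' @param channel `"hbond"`, `"ele"` or `"vdw"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return the correlation coefficient, or `NA` with attribute `reason` when
#'   a channel has zero variance.
#' @export
correlate_sitemaps <- function(a, b, channel = c("hbond", "ele", "vdw"),
                               method = c("pearson", "spearman")) {
  channel <- match.arg(channel)
  method <- match.arg(method)
  if (!identical(dimnames(a$channels[[channel]]),
                 dimnames(b$channels[[channel]])))
    stop("site-maps have mismatched residue/ring index sets")
  x <- as.vector(a$channels[[channel]])
  y <- as.vector(b$channels[[channel]])
  if (length(x) < 3L)
    stop("need at least 3 cells to correlate")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_
    attr(r, "reason") <- "zero variance in at least one map"
    return(r)
  }
  stats::cor(x, y, method = method)
}

#' Signed difference between two site-maps
#'
#' Cell-wise `a - b` per channel for maps normalised the same way; the
#' summary lists the cells whose absolute difference exceeds a quantile of
#' the nonzero differences, where losses/gains of individual contacts (e.g.
#' after removing one sulfate group) show up.
#'
#' @param a,b `gag_sitemap`s, same normalisation and index sets.
#' @param quantile top-difference threshold (default 0.95, i.e. top 5%).
#' @return list with `channels` (signed difference matrices) and `top`
#'   (data.frame of the cells above the threshold).
#' @export
difference_map <- function(a, b, quantile = 0.95) {
  if (!identical(a$normalization, b$normalization))
    stop("site-maps must share a normalization mode (got ",
         a$normalization, " vs ", b$normalization, ")")
  diffs <- Map(function(x, y) x - y, a$channels, b$channels)
  top <- do.call(rbind, lapply(names(diffs), function(nm) {
    d <- diffs[[nm]]
    v <- abs(as.vector(d))
    if (!any(v > 0)) return(NULL)
    thr <- stats::quantile(v[v > 0], quantile)
    idx <- which(abs(d) >= thr, arr.ind = TRUE)
    data.frame(channel = nm,
               residue = rownames(d)[idx[, 1L]],
               ring_index = as.integer(colnames(d)[idx[, 2L]]),
               delta = d[idx], stringsAsFactors = FALSE)
  }))
  list(channels = diffs, top = top)
}

#' Write / read a site-map as canonical TSV
#'
#' Long format: one row per (residue, ring, channel) cell; metadata comments
#' record the normalisation mode and source count. Round-trips to 1e-6.
#'
#' @param map a `gag_sitemap`.
#' @param path TSV path.
#' @return `write_sitemap()`: `path` invisibly; `read_sitemap()`: the map.
#' @export
write_sitemap <- function(map, path) {
  rows <- do.call(rbind, lapply(names(map$channels), function(nm) {
    m <- map$channels[[nm]]
    data.frame(residue = rep(rownames(m), ncol(m)),
               ring_index = rep(as.integer(colnames(m)), each = nrow(m)),
               channel = nm, value = as.vector(m), stringsAsFactors = FALSE)
  }))
  write_canonical_tsv(rows, path,
                      meta = c(paste("normalization =", map$normalization),
                               paste("n_sources =", map$n_sources)))
  invisible(path)
}

#' @rdname write_sitemap
#' @export
read_sitemap <- function(path) {
  tab <- read_canonical_tsv(path)
  meta <- read_tsv_meta(path)
  residues <- sort(unique(tab$residue))
  rings <- sort(unique(tab$ring_index))
  dn <- list(residues, as.character(rings))
  ch <- lapply(c(hbond = "hbond", ele = "ele", vdw = "vdw"), function(nm) {
    m <- matrix(0, length(residues), length(rings), dimnames = dn)
    sub <- tab[tab$channel == nm, , drop = FALSE]
    m[cbind(match(sub$residue, residues), match(sub$ring_index, rings))] <-
      sub$value
    m
  })
  structure(list(channels = ch,
                 normalization = meta_get(meta, "normalization", "none"),
                 n_sources = as.integer(meta_get(meta, "n_sources", "1")),
                 clipped = c(ele = NA_integer_, vdw = NA_integer_)),
            class = "gag_sitemap")
}

#' Heat-map display of one site-map channel
#'
#' @param x a `gag_sitemap`.
#' @param channel channel to draw.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot.gag_sitemap <- function(x, channel = c("hbond", "ele", "vdw"), ...) {
  channel <- match.arg(channel)
  m <- x$channels[[channel]]
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  xlab = "sugar ring (non-reducing to reducing)",
                  ylab = "", axes = FALSE,
                  main = paste("site-map:", channel), ...)
  graphics::axis(1L, at = seq_len(ncol(m)), labels = colnames(m))
  graphics::axis(2L, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  invisible(m)
}
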