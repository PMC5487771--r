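#' Construct a per-residue-pair energy table
#'
#' One row per (protein residue, glycan ring) cell holding van der Waals,
#' in-vacuo electrostatic and reaction-field components (kcal/mol). The total
#' electrostatic term is always recomputed as `ele_vac + ele_rf`. Optionally
#' carries a residue-pair hydrogen-bond fraction in `[0, 1]`, which lets a
#' single table feed all three site-map channels.
#'
#' @param residue protein residue labels (`chain:resnum:resname`, or any
#'   unique label).
#' @param ring_index 1-based glycan ring index from the non-reducing end.
#' @param vdw,ele_vac,ele_rf components, kcal/mol.
#' @param hbond_fraction optional H-bond occupancy per cell.
#' @param provenance `"ingested"` or `"internal_engine"`.
#' @param n_frames_averaged number of frames behind the averages.
#' @return a `gag_energy` data.frame with column `ele_total` added.
#' @export
pair_energy_table <- function(residue, ring_index, vdw, ele_vac, ele_rf,
                              hbond_fraction = NULL,
                              provenance = c("ingested", "internal_engine"),
                              n_frames_averaged = 1L) {
  provenance <- match.arg(provenance)
  tab <- data.frame(residue = as.character(residue),
                    ring_index = as.integer(ring_index),
                    vdw = as.numeric(vdw), ele_vac = as.numeric(ele_vac),
                    ele_rf = as.numeric(ele_rf),
                    stringsAsFactors = FALSE)
  tab$ele_total <- tab$ele_vac + tab$ele_rf
  tab$hbond_fraction <- if (is.null(hbond_fraction))
    rep(NA_real_, nrow(tab)) else as.numeric(hbond_fraction)
  if (anyDuplicated(paste(tab$residue, tab$ring_index)))
    stop("duplicate (residue, ring_index) cells in energy table")
  tab <- tab[order(tab$residue, tab$ring_index), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "provenance") <- provenance
  attr(tab, "n_frames_averaged") <- as.integer(n_frames_averaged)
  class(tab) <- c("gag_energy", "data.frame")
  tab
}

#' @export
print.gag_energy <- function(x, ...) {
  cat("Pair energy table:", nrow(x), "cells,",
      length(unique(x$residue)), "protein residues x",
      length(unique(x$ring_index)), "rings",
      sprintf("(%s, %d frame(s) averaged)\n",
              attr(x, "provenance") %||% "ingested",
              attr(x, "n_frames_averaged") %||% 1L))
  NextMethod()
}

#' Write a decomposition table as canonical TSV
#'
#' One row per (residue, ring) cell with columns `residue`, `ring_index`,
#' `vdw`, `ele_vac`, `ele_rf`, `ele_total`, `hbond_fraction`; UTF-8,
#' tab-separated, `#` metadata comments. Values re-read identically to
#' 1e-6 kcal/mol.
#'
#' @param table a `gag_energy`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_decomp_table <- function(table, path) {
  meta <- c(paste("provenance =", attr(table, "provenance") %||% "ingested"),
            paste("n_frames_averaged =",
                  attr(table, "n_frames_averaged") %||% 1L))
  write_canonical_tsv(as.data.frame(table), path, meta = meta)
  invisible(path)
}

# Column lookup by fuzzy name for the AMBER-style CSV dialect.
find_col <- function(nms, pattern, label) {
  hit <- grep(pattern, nms, ignore.case = TRUE, perl = TRUE)
  if (!length(hit))
    stop("decomposition table is missing required column: ", label)
  hit[1L]
}

#' Parse a per-residue pairwise energy-decomposition table
#'
#' Two dialects are supported. `canonical_tsv` is this package's own format
#' (see [write_decomp_table()]). `amber_csv` is the MMPBSA-style pairwise
#' decomposition CSV: a header line containing `Resid 1` / `Resid 2` columns
#' (residues as `NAME number`) and numeric columns whose names contain
#' `van der Waals`, `Electrostatic` and `Polar Solvation`; parsing is driven
#' by column names, never positions. If a `Location` column distinguishes
#' total/sidechain/backbone rows, the total (`TDC`) rows are used when
#' present, otherwise sidechain and backbone rows are summed per pair.
#' The total electrostatic component is recomputed as the sum of the vacuum
#' and reaction-field (polar solvation) parts.
#'
#' @param path input file.
#' @param dialect `"canonical_tsv"` or `"amber_csv"`.
#' @param annotation optional `gag_glycan`; when given, glycan residue numbers
#'   in an `amber_csv` table are mapped onto its ring indices, otherwise rings
#'   are numbered by order of appearance.
#' @return a `gag_energy` table.
#' @export
parse_decomp_table <- function(path,
                               dialect = c("canonical_tsv", "amber_csv"),
                               annotation = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "canonical_tsv") {
    tab <- read_canonical_tsv(path)
    for (col in c("residue", "ring_index", "vdw", "ele_vac", "ele_rf"))
      if (is.null(tab[[col]]))
        stop("decomposition table is missing required column: ", col)
    if (anyDuplicated(paste(tab$residue, tab$ring_index)))
      stop("duplicate (residue, ring_index) rows in ", path)
    meta <- read_tsv_meta(path)
    prov <- meta_get(meta, "provenance", "ingested")
    if (!prov %in% c("ingested", "internal_engine")) prov <- "ingested"
    if (nrow(tab) == 0L)
      return(pair_energy_table(character(), integer(), numeric(), numeric(),
                               numeric(), provenance = prov))
    return(pair_energy_table(
      tab$residue, tab$ring_index, tab$vdw, tab$ele_vac, tab$ele_rf,
      hbond_fraction = tab$hbond_fraction,
      provenance = prov,
      n_frames_averaged = as.integer(meta_get(meta, "n_frames_averaged", "1"))
    ))
  }
  lines <- readLines(path)
  hdr <- grep("Resid\\s*1", lines)[1L]
  if (is.na(hdr)) stop("decomposition table is missing required column: Resid 1")
  tab <- utils::read.csv(text = paste(lines[hdr:length(lines)],
                                      collapse = "\n"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  tab <- tab[rowSums(!is.na(tab) & tab != "") > 0, , drop = FALSE]
  nms <- names(tab)
  c1 <- find_col(nms, "Resid\\s*1", "Resid 1")
  c2 <- find_col(nms, "Resid\\s*2", "Resid 2")
  cv <- find_col(nms, "van der Waals", "van der Waals")
  ce <- find_col(nms, "^(?!.*polar).*electrostatic", "Electrostatic")
  cp <- find_col(nms, "polar solv", "Polar Solvation")
  loc <- grep("^location$", nms, ignore.case = TRUE)
  parse_res <- function(x) {
    x <- trimws(x)
    m <- regexec("^([A-Za-z0-9']+)\\s+(-?[0-9]+)$", x)
    parts <- regmatches(x, m)
    bad <- lengths(parts) != 3L
    if (any(bad)) stop("unparseable residue identifier(s): ",
                       paste(unique(x[bad]), collapse = ", "))
    data.frame(resname = vapply(parts, `[`, "", 2L),
               resnum = as.integer(vapply(parts, `[`, "", 3L)),
               stringsAsFactors = FALSE)
  }
  r1 <- parse_res(tab[[c1]])
  r2 <- parse_res(tab[[c2]])
  num <- function(col) as.numeric(tab[[col]])
  df <- data.frame(resname1 = r1$resname, resnum1 = r1$resnum,
                   resname2 = r2$resname, resnum2 = r2$resnum,
                   vdw = num(cv), ele_vac = num(ce), ele_rf = num(cp),
                   stringsAsFactors = FALSE)
  if (length(loc)) {
    lv <- toupper(trimws(tab[[loc[1L]]]))
    df <- if (any(lv == "TDC")) df[lv == "TDC", , drop = FALSE]
          else stats::aggregate(df[c("vdw", "ele_vac", "ele_rf")],
                                by = df[c("resname1", "resnum1",
                                          "resname2", "resnum2")], FUN = sum)
  }
  pairkey <- paste(df$resname1, df$resnum1, df$resname2, df$resnum2)
  if (anyDuplicated(pairkey))
    stop("duplicate residue-pair row(s) in ", path, ": ",
         pairkey[duplicated(pairkey)][1L])
  if (!is.null(annotation)) {
    ring <- annotation$ring_index[match(df$resnum2, annotation$resnum)]
    if (anyNA(ring))
      stop("glycan residue number(s) not in the annotation: ",
           paste(unique(df$resnum2[is.na(ring)]), collapse = ", "))
  } else {
    ring <- match(df$resnum2, unique(df$resnum2))
  }
  pair_energy_table(
    residue = residue_label(" ", df$resnum1, df$resname1),
    ring_index = ring, vdw = df$vdw, ele_vac = df$ele_vac,
    ele_rf = df$ele_rf, provenance = "ingested"
  )
}
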