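#' Construct per-ligand binding free-energy samples
#'
#' Holds lists of binding free-energy values (kcal/mol, more negative =
#' stronger binding) per ligand, optionally partitioned into groupings (e.g.
#' per receptor conformation).
#'
#' @param values named list of numeric vectors (one per ligand), or a
#'   data.frame with columns `ligand`, `value` and optionally `group`.
#' @param groups optional character/integer vector parallel to the unlisted
#'   values assigning each value to a grouping.
#' @return object of class `gag_deltag`: data.frame `ligand`, `value`
#'   (+ `group` when present).
#' @export
deltag_samples <- function(values, groups = NULL) {
  if (is.data.frame(values)) {
    df <- values
    stopifnot(all(c("ligand", "value") %in% names(df)))
  } else {
    stopifnot(is.list(values), !is.null(names(values)))
    df <- data.frame(
      ligand = rep(names(values), lengths(values)),
      value = unlist(values, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    if (!is.null(groups)) df$group <- groups
  }
  if (!all(is.finite(df$value))) stop("all free-energy values must be finite")
  if (any(table(df$ligand) == 0L)) stop("each ligand needs >= 1 value")
  class(df) <- c("gag_deltag", "data.frame")
  df
}

#' Rank ligands by their single best free-energy value
#'
#' Orders ligands by their most favourable (minimum) value ascending — the
#' classical "best scored pose" ranking. Ties break by ligand label.
#'
#' @param samples a `gag_deltag`.
#' @return character vector of ligand labels, strongest binder first, with
#'   the best values as attribute `best`.
#' @export
rank_by_best <- function(samples) {
  best <- tapply(samples$value, samples$ligand, min)
  ord <- order(best, names(best))
  out <- names(best)[ord]
  attr(out, "best") <- as.numeric(best)[ord]
  out
}

#' Rank-occurrence table across groupings
#'
#' Within each grouping, ligands are ranked by their best value; the table
#' counts how many times each ligand landed in each ranking position. With
#' the whole set of solutions split into groupings, this summarises the
#' ranking distribution instead of a single best-pose order.
#'
#' @param samples a `gag_deltag` with a `group` column; every grouping must
#'   contain every ligand.
#' @return object of class `gag_ranktable`: ligand x position count matrix
#'   with attribute `n_groups`.
#' @export
rank_occurrence <- function(samples) {
  if (is.null(samples$group))
    stop("rank_occurrence needs grouped samples (group column)")
  ligands <- sort(unique(samples$ligand))
  groups <- unique(samples$group)
  tab <- matrix(0L, length(ligands), length(ligands),
                dimnames = list(ligands, paste0("rank", seq_along(ligands))))
  for (g in groups) {
    sub <- samples[samples$group == g, , drop = FALSE]
    miss <- setdiff(ligands, sub$ligand)
    if (length(miss))
      stop("grouping ", g, " is missing ligand(s): ",
           paste(miss, collapse = ", "))
    r <- rank_by_best(deltag_samples(sub[c("ligand", "value")]))
    ij <- cbind(match(r, ligands), seq_along(r))
    tab[ij] <- tab[ij] + 1L
  }
  structure(tab, n_groups = length(groups), class = "gag_ranktable")
}

#' @export
print.gag_ranktable <- function(x, ...) {
  cat("Rank-occurrence table over", attr(x, "n_groups"), "grouping(s):\n")
  print(unclass(x))
  invisible(x)
}

#' Resample groupings from pooled samples
#'
#' Builds `n_groups` bootstrap groupings, each holding `per_group` value(s)
#' per ligand drawn with replacement from that ligand's pooled values. With
#' the default of one value per grouping, the consensus mean rank over many
#' groupings estimates the stochastic ordering of the whole per-ligand
#' distributions rather than the ordering of their extreme values. The
#' resampling indices depend only on the RNG state, never on the values, so
#' rankings derived from the result are invariant under shifting all values
#' by a constant.
#'
#' @param samples a `gag_deltag`.
#' @param n_groups number of groupings.
#' @param per_group values per ligand per grouping.
#' @return a `gag_deltag` with a `group` column.
#' @export
bootstrap_groupings <- function(samples, n_groups = 100L, per_group = 1L) {
  ligands <- sort(unique(samples$ligand))
  out <- lapply(ligands, function(l) {
    v <- samples$value[samples$ligand == l]
    idx <- sample.int(length(v), n_groups * per_group, replace = TRUE)
    data.frame(ligand = l, value = v[idx],
               group = rep(seq_len(n_groups), each = per_group),
               stringsAsFactors = FALSE)
  })
  deltag_samples(do.call(rbind, out))
}

#' Pairwise Welch t-tests between ligand free-energy distributions
#'
#' Two-sided unequal-variance t-test for every unordered ligand pair;
#' a pair is significant when `p < alpha`. A degenerate pair (zero variance
#' on both sides, equal means) gets `t = 0`, `p = 1` and is flagged. A Holm
#' correction is available but off by default (raw per-pair decisions).
#'
#' @param samples a `gag_deltag` with at least 2 values per ligand.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame `ligand1`, `ligand2`, `t`, `p`, `significant`,
#'   `degenerate`.
#' @export
welch_ttest_matrix <- function(samples, alpha = 0.05,
                               adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  ligands <- sort(unique(samples$ligand))
  vals <- split(samples$value, samples$ligand)[ligands]
  if (any(lengths(vals) < 2L))
    stop("each ligand needs >= 2 values for a t-test")
  pairs <- utils::combn(ligands, 2L)
  res <- apply(pairs, 2L, function(pr) {
    x <- vals[[pr[1L]]]; y <- vals[[pr[2L]]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) return(c(t = 0, p = 1, degen = 1))
      return(c(t = Inf * sign(mean(x) - mean(y)), p = 0, degen = 1))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    c(t = unname(tt$statistic), p = tt$p.value, degen = 0)
  })
  p <- res["p", ]
  if (adjust == "holm") p <- stats::p.adjust(p, "holm")
  data.frame(ligand1 = pairs[1L, ], ligand2 = pairs[2L, ],
             t = res["t", ], p = p, significant = p < alpha,
             degenerate = res["degen", ] == 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Consensus ranking from a rank-occurrence table
#'
#' Orders ligands by mean occupied rank position ascending; ties break by
#' number of rank-1 finishes (descending), then label.
#'
#' @param table a `gag_ranktable`.
#' @return character vector of ligand labels, strongest first, with mean
#'   ranks as attribute `mean_rank`.
#' @export
consensus_ranking <- function(table) {
  m <- unclass(table)
  pos <- seq_len(ncol(m))
  mean_rank <- as.vector(m %*% pos) / rowSums(m)
  ord <- order(mean_rank, -m[, 1L], rownames(m))
  out <- rownames(m)[ord]
  attr(out, "mean_rank") <- mean_rank[ord]
  out
}

#' Read / write free-energy samples as TSV
#'
#' Two-column TSV `ligand`, `value` with optional `group` column.
#'
#' @param samples a `gag_deltag`.
#' @param path TSV path.
#' @return `write_deltag()`: `path` invisibly; `read_deltag()`: the samples.
#' @export
write_deltag <- function(samples, path) {
  write_canonical_tsv(as.data.frame(samples), path,
                      meta = "binding free energies, kcal/mol")
  invisible(path)
}

#' @rdname write_deltag
#' @export
read_deltag <- function(path) {
  deltag_samples(read_canonical_tsv(path))
}
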