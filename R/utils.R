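# Internal helpers shared across modules.

# Canonical residue label "chain:resnum:resname", unique within a structure.
residue_label <- function(chain, resnum, resname) {
  paste(chain, resnum, resname, sep = ":")
}

# Split a residue label back into its parts.
split_residue_label <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)
  data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resnum = as.integer(vapply(parts, `[`, "", 2L)),
    resname = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

# Euclidean distance between rows of a and rows of b (n x 3 matrices).
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3L)
  b <- matrix(b, ncol = 3L)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Angle a-b-c at vertex b, degrees.
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# Run code with a temporarily fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Read a TSV written by the package: tab-separated, '#' comments, header row.
read_canonical_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "")
}

# Write a data.frame as canonical TSV with optional '#'-prefixed metadata.
write_canonical_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.9f", x))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

# Read '#'-comment metadata lines of the form "# key = value".
read_tsv_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#")]
  lines <- sub("^#+\\s*", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  eq <- regexpr("=", lines, fixed = TRUE)
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substr(lines, eq + 1L, nchar(lines)))
  keep <- nzchar(keys)
  stats::setNames(vals[keep], keys[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Metadata lookup with default for the named vectors read_tsv_meta returns.
meta_get <- function(meta, key, default) {
  if (key %in% names(meta)) meta[[key]] else default
}
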