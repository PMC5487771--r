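mk_map <- function(vals, nres = 4L, nring = 3L, seed = NULL) {
  # build a sitemap from an energy table whose cells are -vals (favorable)
  pair_energy_table(
    residue = rep(sprintf("A:%d:TOY", seq_len(nres)), each = nring),
    ring_index = rep(seq_len(nring), nres),
    vdw = -vals / 2, ele_vac = -1.5 * vals / 2, ele_rf = 0.5 * vals / 2,
    hbond_fraction = pmin(1, abs(vals) / max(abs(vals), 1))) |>
    build_sitemap()
}

test_that("channel construction follows the favorable-magnitude convention", {
  tab <- pair_energy_table(
    residue = c("A:1:TOY", "A:2:TOY"), ring_index = c(1L, 1L),
    vdw = c(-1, 0.5), ele_vac = c(-7, 3), ele_rf = c(2, -1),
    hbond_fraction = c(0.4, 0))
  sm <- build_sitemap(tab)
  expect_equal(sm$channels$ele["A:1:TOY", "1"], 5)   # -(-5)
  expect_equal(sm$channels$ele["A:2:TOY", "1"], 0)   # +2 clipped
  expect_equal(sm$channels$vdw["A:1:TOY", "1"], 1)
  expect_equal(unname(sm$clipped["ele"]), 1L)
  expect_equal(unname(sm$clipped["vdw"]), 1L)
  expect_equal(sm$channels$hbond["A:1:TOY", "1"], 0.4)
})

test_that("per-ring normalization divides columns by absolute sums", {
  tab <- pair_energy_table(
    residue = c("A:1:TOY", "A:2:TOY", "A:1:TOY", "A:2:TOY"),
    ring_index = c(1L, 1L, 2L, 2L),
    vdw = c(-3, -1, 0, 0), ele_vac = c(-3, -1, 0, 0), ele_rf = rep(0, 4L))
  sm <- normalize_sitemap(build_sitemap(tab), "per_ring")
  expect_equal(unname(sm$channels$vdw[, "1"]), c(0.75, 0.25))
  # all-zero ring column unchanged, and flagged
  expect_equal(unname(sm$channels$vdw[, "2"]), c(0, 0))
  expect_true(any(grepl("ring", attr(sm, "all_zero"))))
  # idempotent
  sm2 <- normalize_sitemap(sm, "per_ring")
  expect_equal(sm2$channels$vdw, sm$channels$vdw, tolerance = 1e-12)
  # columns sum to 1 in absolute value (or are all-zero)
  cs <- colSums(abs(sm$channels$vdw))
  expect_true(all(abs(cs - 1) < 1e-12 | cs == 0))
  # global mode: grand absolute sum is 1
  smg <- normalize_sitemap(build_sitemap(tab), "global")
  expect_equal(sum(abs(smg$channels$vdw)), 1, tolerance = 1e-12)
})

test_that("aggregation is scale-stable and permutation-invariant", {
  set.seed(21)
  maps <- lapply(1:6, function(i) mk_map(abs(rnorm(12L)) + 0.1))
  one <- aggregate_sitemaps(maps[1L])
  expect_equal(one$channels$ele,
               normalize_sitemap(maps[[1L]], "global")$channels$ele,
               tolerance = 1e-12)
  twice <- aggregate_sitemaps(list(maps[[1L]], maps[[1L]]))
  expect_equal(twice$channels$ele, one$channels$ele, tolerance = 1e-12)
  a <- aggregate_sitemaps(maps)
  b <- aggregate_sitemaps(rev(maps))
  for (ch in c("hbond", "ele", "vdw"))
    expect_equal(a$channels[[ch]], b$channels[[ch]], tolerance = 1e-12)
  expect_equal(a$n_sources, 6L)
  bad <- mk_map(abs(rnorm(8L)) + 0.1, nres = 4L, nring = 2L)
  expect_error(aggregate_sitemaps(list(maps[[1L]], bad)), "mismatched")
})

test_that("correlation matches the direct Pearson formula", {
  set.seed(22)
  a <- mk_map(abs(rnorm(60L)) + 0.1, nres = 10L, nring = 6L)
  b <- mk_map(abs(rnorm(60L)) + 0.1, nres = 10L, nring = 6L)
  expect_equal(correlate_sitemaps(a, a, "ele"), 1, tolerance = 1e-12)
  # direct formula evaluation as the oracle
  x <- as.vector(a$channels$ele); y <- as.vector(b$channels$ele)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_sitemaps(a, b, "ele"), r_direct, tolerance = 1e-12)
  # negation: r = -1 (negate a channel in place)
  neg <- a
  neg$channels$ele <- 2 * mean(x) - a$channels$ele   # reflected copy
  expect_equal(correlate_sitemaps(a, neg, "ele"), -1, tolerance = 1e-12)
  # zero variance is NA with a reason, not an error
  flat <- a
  flat$channels$ele[] <- 1
  r0 <- correlate_sitemaps(a, flat, "ele")
  expect_true(is.na(r0))
  expect_match(attr(r0, "reason"), "variance")
  # Spearman is available as the rank-based alternative
  expect_equal(correlate_sitemaps(a, b, "ele", method = "spearman"),
               cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("difference maps are antisymmetric and localise planted changes", {
  set.seed(23)
  base_vals <- abs(rnorm(60L)) + 0.1
  a <- normalize_sitemap(mk_map(base_vals, 10L, 6L), "per_ring")
  changed <- base_vals
  ring4 <- rep(seq_len(6L), 10L) == 4L
  changed[ring4] <- changed[ring4] + 5      # one ring's contacts strengthened
  b <- normalize_sitemap(mk_map(changed, 10L, 6L), "per_ring")
  d <- difference_map(a, b)
  expect_equal(d$channels$ele, -difference_map(b, a)$channels$ele,
               tolerance = 1e-12)
  self <- difference_map(a, a)
  expect_true(all(abs(self$channels$ele) < 1e-15))
  # top-|delta| electrostatic cells all sit in the altered ring's column
  top_e <- d$top[d$top$channel == "ele", ]
  expect_true(all(top_e$ring_index == 4L))
  unnorm <- mk_map(base_vals, 10L, 6L)
  expect_error(difference_map(a, unnorm), "normalization")
})

test_that("a planted salt bridge tops both the ele and hbond channels", {
  spec <- synth_spec(
    seed = 31,
    planted_hbond_pairs = data.frame(residue = 4L, ring = 2L,
                                     occupancy = 1),
    planted_hot_pairs = data.frame(residue = 4L, ring = 2L, mean = -8))
  g <- gen_toy_complex_ensemble(spec)
  occ <- occupancy_table(g$ensemble)
  dec <- residue_pair_decomposition(g$ensemble, g$annotation)
  sm <- build_sitemap(dec, occ, g$annotation)
  expect_equal(top_cells(sm, "ele", 1L), "A:4:TOY 2")
  expect_equal(top_cells(sm, "hbond", 1L), "A:4:TOY 2")
})

test_that("site-maps round-trip through the canonical TSV", {
  set.seed(24)
  sm <- normalize_sitemap(mk_map(abs(rnorm(12L)) + 0.1), "per_ring")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sitemap(sm, f)
  back <- read_sitemap(f)
  expect_equal(back$normalization, "per_ring")
  for (ch in c("hbond", "ele", "vdw"))
    expect_equal(back$channels[[ch]], sm$channels[[ch]], tolerance = 1e-6)
})
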