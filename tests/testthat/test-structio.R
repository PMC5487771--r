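toy_pdb_text <- function(n_models = 2L, shift = 0.1) {
  unlist(lapply(seq_len(n_models), function(m) {
    z <- sprintf("%8.3f", (m - 1L) * shift)
    c(sprintf("MODEL     %d", m),
      paste0("ATOM      1  N   ALA A   1       0.000   0.000", z,
             "  1.00  0.00           N"),
      paste0("ATOM      2  HN  ALA A   1       1.000   0.000", z,
             "  1.00  0.00           H"),
      paste0("ATOM      3  CA  ALA A   1       1.500   1.000", z,
             "  1.00  0.00           C"),
      paste0("ATOM      4  O5  SGN B  10       2.800   0.000", z,
             "  1.00  0.00           O"),
      paste0("ATOM      5  C1  SGN B  10       3.800   1.000", z,
             "  1.00  0.00           C"),
      paste0("ATOM      6  O2  IDS B  11       6.000   0.000", z,
             "  1.00  0.00           O"),
      "ENDMDL")
  }))
}

test_that("multi-model PDB parsing partitions residues and keeps topology", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_text(2L), f)
  ens <- parse_structure_ensemble(f, glycan_resnames = c("SGN", "IDS"))
  expect_length(ens$frames, 2L)
  expect_equal(nrow(ens$atoms), 6L)
  expect_equal(ens$atoms$role, c(rep("protein", 3L), rep("glycan", 3L)))
  # hydrogens inferred from covalent distance
  expect_equal(ens$bonded_h[[1L]], 2L)
  expect_equal(lengths(ens$bonded_h)[-1L], rep(0L, 5L),
               ignore_attr = TRUE)
  # frames share the topology, coordinates differ by the model shift
  expect_equal(ens$frames[[2L]][, 3L] - ens$frames[[1L]][, 3L],
               rep(0.1, 6L), tolerance = 1e-9)
})

test_that("degenerate PDB inputs are hard errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_text(2L), f)
  expect_error(parse_structure_ensemble(f, glycan_resnames = "ZZZ"),
               "no glycan residues")
  lines <- toy_pdb_text(2L)
  lines <- lines[-10L]            # drop one atom from model 2
  writeLines(lines, f)
  expect_error(parse_structure_ensemble(f, glycan_resnames = "SGN"),
               "inconsistent atom counts.*model 2")
})

test_that("ensembles round-trip through PDB to coordinate precision", {
  set.seed(42)
  g <- gen_toy_complex_ensemble(synth_spec(seed = 5, n_frames = 10L))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_ensemble(g$ensemble, f)
  back <- parse_structure_ensemble(
    f, glycan_resnames = unique(g$annotation$resname))
  expect_length(back$frames, 10L)
  expect_equal(back$atoms$name, g$ensemble$atoms$name)
  expect_equal(back$atoms$role, g$ensemble$atoms$role)
  for (i in seq_along(back$frames))
    expect_lt(max(abs(back$frames[[i]] - g$ensemble$frames[[i]])), 1e-3)
})

test_that("glycan annotation encodes sulfation patterns and round-trips", {
  g <- gen_toy_complex_ensemble(
    synth_spec(seed = 1, n_frames = 1L,
               glycan_pattern = "GlcNS6S-IdoA-GlcNS6S-IdoA-GlcNS6S-IdoA",
               planted_hbond_pairs = data.frame(residue = integer(),
                                                ring = integer(),
                                                occupancy = numeric()),
               planted_hot_pairs = data.frame(residue = integer(),
                                              ring = integer(),
                                              mean = numeric())))
  ann <- g$annotation
  # a derivative with no sulfates on its iduronic acids has no IdoA2S rings
  expect_equal(sum(ann$ring_type == "IdoA2S"), 0L)
  expect_equal(ann$ring_type[c(2L, 4L, 6L)], rep("IdoA", 3L))
  expect_equal(ann$ring_index, 1:6)

  g5 <- gen_toy_complex_ensemble(
    synth_spec(seed = 1, n_frames = 1L,
               glycan_pattern = "GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S",
               planted_hbond_pairs = data.frame(residue = integer(),
                                                ring = integer(),
                                                occupancy = numeric()),
               planted_hot_pairs = data.frame(residue = integer(),
                                              ring = integer(),
                                              mean = numeric())))
  expect_equal(g5$annotation$ring_type,
               c("GlcNS", "IdoA2S", "GlcNS", "IdoA2S", "GlcNS"))
  # ring_index is a bijection onto the glycan residues
  expect_equal(sort(g5$annotation$ring_index), 1:5)
  expect_false(anyDuplicated(g5$annotation$resnum) > 0L)
  # encode -> decode -> encode is the identity on the pattern string
  expect_equal(format_glycan_pattern(g5$annotation),
               "GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S")
  expect_error(annotate_glycan(g5$ensemble, "GlcNS-IdoA"), "5 glycan")
})

test_that("tail subsampling is even, endpoint-inclusive and idempotent", {
  df <- data.frame(name = "X", element = "C", resnum = 1L, role = "glycan")
  frames <- lapply(1:1000, function(i) matrix(c(i, 0, 0), 1L))
  ens <- make_ensemble(df, frames)
  sub <- subsample_tail(ens, 500L, 100L)
  idx <- vapply(sub$frames, function(f) f[1L, 1L], 0)
  expect_length(idx, 100L)
  expect_true(all(diff(idx) > 0))          # a subsequence of the input order
  expect_true(all(idx >= 501))             # inside the tail window
  expect_equal(idx[c(1L, 100L)], c(501, 1000))

  # count == window: the whole tail, unchanged
  sub2 <- subsample_tail(ens, 50L, 50L)
  expect_equal(vapply(sub2$frames, function(f) f[1L, 1L], 0),
               as.numeric(951:1000))
  # 3 of a 10-frame window: first, middle, last under even spacing
  sub3 <- subsample_tail(ens, 10L, 3L)
  expect_equal(vapply(sub3$frames, function(f) f[1L, 1L], 0) - 990,
               c(1, 5, 10))
  expect_error(subsample_tail(ens, 10L, 11L), "exceeds tail_frames")
})

test_that("canonical decomposition TSV round-trips bit-for-bit at 1e-6", {
  set.seed(7)
  tab <- pair_energy_table(
    residue = rep(sprintf("A:%d:TOY", 1:4), each = 3L),
    ring_index = rep(1:3, 4L),
    vdw = rnorm(12L), ele_vac = rnorm(12L), ele_rf = rnorm(12L),
    hbond_fraction = runif(12L), provenance = "internal_engine",
    n_frames_averaged = 17L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_decomp_table(tab, f)
  back <- parse_decomp_table(f, "canonical_tsv")
  for (col in c("vdw", "ele_vac", "ele_rf", "ele_total", "hbond_fraction"))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-6)
  expect_equal(back$residue, tab$residue)
  expect_equal(attr(back, "provenance"), "internal_engine")
  expect_equal(attr(back, "n_frames_averaged"), 17L)
  # empty table is valid
  empty <- pair_energy_table(character(), integer(), numeric(), numeric(),
                             numeric())
  write_decomp_table(empty, f)
  expect_equal(nrow(parse_decomp_table(f, "canonical_tsv")), 0L)
})

test_that("AMBER-style pairwise CSV is parsed by column names", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Per-residue pairwise decomposition",
    "Resid 1,Resid 2,Internal Avg.,van der Waals Avg.,Electrostatic Avg.,Polar Solvation Avg.,TOTAL Avg.",
    "LYS 118,LIG 201,0.0,-2.7,-15.0,5.0,-12.7",
    "LYS 113,LIG 201,0.0,-2.0,-10.5,3.5,-9.0",
    "LYS 128,LIG 202,0.0,-1.7,-9.0,3.0,-7.7",
    "GLN 127,LIG 202,0.0,-1.4,-7.0,2.0,-6.4"
  ), f)
  tab <- parse_decomp_table(f, "amber_csv")
  total <- tab$vdw + tab$ele_total
  expect_equal(tab$ele_total, tab$ele_vac + tab$ele_rf, tolerance = 1e-9)
  top <- tab$residue[which.min(total)]
  expect_match(top, "118:LYS")
  expect_equal(min(total), -12.7, tolerance = 1e-9)
  expect_equal(sort(unique(tab$ring_index)), 1:2)
  # missing required column and duplicate rows are hard errors
  writeLines(c("Resid 1,Resid 2,van der Waals Avg.,Electrostatic Avg.",
               "LYS 118,LIG 201,-2.7,-15.0"), f)
  expect_error(parse_decomp_table(f, "amber_csv"), "Polar Solvation")
  writeLines(c(
    "Resid 1,Resid 2,van der Waals Avg.,Electrostatic Avg.,Polar Solvation Avg.",
    "LYS 118,LIG 201,-2.7,-15.0,5.0",
    "LYS 118,LIG 201,-2.7,-15.0,5.0"), f)
  expect_error(parse_decomp_table(f, "amber_csv"), "duplicate")
})

test_that("atom parameter sidecars restore nonbonded parameters", {
  g <- gen_toy_complex_ensemble(synth_spec(seed = 2, n_frames = 2L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_atom_params(g$ensemble, f)
  stripped <- g$ensemble
  stripped$atoms$charge <- NA_real_
  back <- attach_atom_params(stripped, f)
  expect_equal(back$atoms$charge, g$ensemble$atoms$charge, tolerance = 1e-6)
  expect_equal(back$atoms$rmin_half, g$ensemble$atoms$rmin_half,
               tolerance = 1e-6)
})
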