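make_site_yaml <- function(path, n = 2, with_ref = FALSE,
                           ref_name = "ref.pdb", drop_atom = NULL) {
  lines <- c("protein_label: demo")
  if (with_ref) {
    ref_path <- file.path(dirname(path), ref_name)
    recs <- character(0)
    serial <- 0L
    for (r in seq_len(n)) {
      for (a in c("N", "CA", "C", "O")) {
        if (!is.null(drop_atom) && r == drop_atom[[1]] &&
            a == drop_atom[[2]])
          next
        serial <- serial + 1L
        recs <- c(recs, sprintf(
          "ATOM  %5d  %-3s GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial, a, r, r * 4, serial * 1.5, 0, substr(a, 1, 1)))
      }
    }
    writeLines(c(recs, "END"), ref_path)
    lines <- c(lines, paste0("reference_pdb: ", ref_name), "residues:")
    for (r in seq_len(n))
      lines <- c(lines, sprintf("  - {chain: A, resnum: %d, resname: GLY}",
                                r))
  } else {
    lines <- c(lines, "residues:")
    for (r in seq_len(n)) {
      lines <- c(lines,
                 sprintf("  - chain: A\n    resnum: %d\n    resname: GLY", r),
                 "    atoms:",
                 sprintf("      N: [%g, 0, 0]", r),
                 sprintf("      CA: [%g, 1, 0]", r),
                 sprintf("      C: [%g, 2, 0]", r),
                 sprintf("      O: [%g, 3, 0]", r))
    }
  }
  writeLines(lines, path)
  path
}

test_that("written synthetic trajectories round-trip through the reader", {
  spec <- synthetic_spec(n_frames = 3, planted_sites = c(0, 0, 0),
                         n_noise_waters = 5, noise_box = c(30, 30, 30),
                         seed = 12)
  pdb <- tempfile(fileext = ".pdb")
  tr <- generate_trajectory(spec, path = pdb)
  back <- read_water_frames(pdb)
  expect_length(back, length(tr))
  for (f in seq_along(tr)) {
    expect_identical(n_waters(back[[f]]), n_waters(tr[[f]]))
    expect_equal(back[[f]]$o, tr[[f]]$o, tolerance = 1e-3)
    expect_equal(back[[f]]$h1, tr[[f]]$h1, tolerance = 1e-3)
    expect_equal(back[[f]]$h2, tr[[f]]$h2, tolerance = 1e-3)
  }
})

test_that("reader preserves model count and water count per model", {
  pdb <- tempfile(fileext = ".pdb")
  tri <- planted_triangle(c(0, 0, 0))
  f1 <- water_frame(tri$o, tri$h1, tri$h2, frame_index = 1L)
  f2 <- water_frame(tri$o + 5, tri$h1 + 5, tri$h2 + 5, frame_index = 2L)
  write_water_frames(water_trajectory(list(f1, f2)), pdb)
  tr <- read_water_frames(pdb)
  expect_length(tr, 2L)
  expect_identical(vapply(tr, n_waters, integer(1)), c(3L, 3L))
  expect_identical(vapply(tr, function(f) f$frame_index, integer(1)),
                   1:2)
})

test_that("a water missing one hydrogen is rejected with its identity", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       0.957   0.000   0.000  1.00  0.00           H",
    "ENDMDL", "END"), pdb)
  expect_error(read_water_frames(pdb), "HOH A1.*exactly 2 hydrogens")
})

test_that("malformed coordinate records fail with a line number", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  O   HOH A   1       0.000   xx.000   0.000  1.00  0.00",
    "ENDMDL", "END"), pdb)
  expect_error(read_water_frames(pdb), "line 2")
  expect_error(read_water_frames(tempfile()), "not found")
})

test_that("non-water records are ignored and empty files rejected", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  O   HOH A   2       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      3  H1  HOH A   2       0.957   0.000   0.000  1.00  0.00           H",
    "ATOM      4  H2  HOH A   2      -0.240   0.927   0.000  1.00  0.00           H",
    "ENDMDL", "END"), pdb)
  tr <- read_water_frames(pdb)
  expect_identical(n_waters(tr[[1]]), 1L)
  # whitelist is configurable: excluding HOH leaves an empty frame
  tr2 <- read_water_frames(pdb, water_resnames = "SOL")
  expect_identical(n_waters(tr2[[1]]), 0L)
})

test_that("binding-site configs read from inline coordinates", {
  cfg <- make_site_yaml(tempfile(fileext = ".yaml"), n = 1)
  site <- read_binding_site(cfg)
  expect_s3_class(site, "binding_site")
  expect_identical(n_site_atoms(site), 4L)
  expect_equal(unname(site$coords[1, ]), c(1, 0, 0))
  expect_equal(unname(site$coords[4, ]), c(1, 3, 0))
})

test_that("binding-site configs read backbone atoms from a reference PDB", {
  dir <- tempfile(); dir.create(dir)
  cfg <- make_site_yaml(file.path(dir, "site.yaml"), n = 16,
                        with_ref = TRUE)
  site <- read_binding_site(cfg)
  expect_identical(nrow(site$residues), 16L)
  expect_identical(n_site_atoms(site), 64L)
  expect_error(read_binding_site(cfg, expected_residues = 12),
               "expected 12")
})

test_that("a reference PDB missing a backbone atom is rejected by residue", {
  dir <- tempfile(); dir.create(dir)
  cfg <- make_site_yaml(file.path(dir, "site.yaml"), n = 3,
                        with_ref = TRUE, drop_atom = list(2, "CA"))
  expect_error(read_binding_site(cfg), "residue A2.*CA")
})

test_that("site pairing requires equal residue counts", {
  s1 <- synthetic_binding_site(n_residues = 4)
  s2 <- synthetic_binding_site(n_residues = 5)
  expect_error(site_pairing(s1, s2), "4 vs 5")
  expect_identical(site_pairing(s1, s1)$pairing, 1:4)
})

test_that("ring tables round-trip through TSV", {
  spec <- synthetic_spec(n_frames = 4, planted_sites = rbind(
    c(0, 0, 0), c(12, 0, 0)), seed = 8)
  rings <- detect_twns_trajectory(generate_trajectory(spec))
  path <- tempfile(fileext = ".tsv")
  write_rings(rings, path)
  back <- read_rings(path)
  expect_identical(nrow(back), nrow(rings))
  expect_identical(back$water_i, rings$water_i)
  expect_equal(back$e_ij, rings$e_ij, tolerance = 1e-10)
  expect_equal(back$centroid_z, rings$centroid_z, tolerance = 1e-10)
  # empty ring set writes a header-only table
  empty_path <- tempfile(fileext = ".tsv")
  write_rings(rings[0, ], empty_path)
  expect_identical(nrow(read_rings(empty_path)), 0L)
  expect_length(readLines(empty_path), 1L)
})
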