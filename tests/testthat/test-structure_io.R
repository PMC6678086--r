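test_that("PDB coordinates are converted Angstrom -> nm exactly", {
  p <- write_test_pdb(data.frame(chain = "A", resnum = 1, resname = "ALA",
                                 atom = "CA", x = 10, y = 0, z = 0))
  s <- read_structure(p)
  expect_equal(nrow(s$topology$atoms), 1L)
  expect_equal(s$coords[1, ], c(1.0, 0, 0))
})

test_that("altLoc resolves to highest occupancy, ties keep the first", {
  df <- data.frame(chain = "A", resnum = c(1, 1), resname = "ALA",
                   atom = "CA", altloc = c("A", "B"),
                   occupancy = c(0.6, 0.4),
                   x = c(1, 2), y = 0, z = 0)
  s <- read_structure(write_test_pdb(df))
  expect_equal(nrow(s$topology$atoms), 1L)
  expect_equal(s$coords[1, 1], 0.1)        # location A retained

  df$occupancy <- c(0.5, 0.5)              # tie: first encountered wins
  s2 <- read_structure(write_test_pdb(df))
  expect_equal(s2$coords[1, 1], 0.1)
})

test_that("malformed and empty files raise parse errors naming the line", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      bad_coords_here_xx",
               "END"), p)
  expect_error(read_structure(p), "line 1")
  p2 <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", p2)
  expect_error(read_structure(p2), "no ATOM records")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("synthetic peptide stand-in parses to 9 residues EEYLQAFTY", {
  s <- read_structure(synthetic_peptide_pdb())
  expect_equal(nrow(s$topology$atoms), 9L)
  expect_equal(chain_sequence(s$topology, "C"), "EEYLQAFTY")
})

test_that("multi-model trajectories concatenate in file order", {
  df <- data.frame(chain = "A", resnum = 1:4, resname = "ALA",
                   atom = "CA", x = (1:4) * 5, y = 0, z = 0)
  topo <- read_structure(write_test_pdb(df))$topology
  p1 <- write_test_pdb(df, model_blocks = 3)
  traj <- read_trajectory(p1, topo)
  expect_equal(n_frames(traj), 3L)
  expect_equal(frame_coords(traj, 1), frame_coords(traj, 3))
  expect_equal(traj$times, c(0.04, 0.08, 0.12))

  p2 <- write_test_pdb(df, model_blocks = 5)
  p3 <- write_test_pdb(df, model_blocks = 5)
  expect_equal(n_frames(read_trajectory(c(p2, p3), topo)), 10L)
})

test_that("atom-count mismatch errors name the frame index", {
  df4 <- data.frame(chain = "A", resnum = 1:4, resname = "ALA",
                    atom = "CA", x = (1:4) * 5, y = 0, z = 0)
  topo5 <- make_ca_topology(5)
  p <- write_test_pdb(df4, model_blocks = 2)
  expect_error(read_trajectory(p, topo5), "frame 1")
})

test_that("write/read round trip preserves metadata and coordinates", {
  set.seed(7)
  topo <- make_ca_topology(100)
  frames <- lapply(1:10, function(i) anisotropic_cloud(100) + i * 0.01)
  traj <- make_test_trajectory(frames, topo)
  p <- tempfile(fileext = ".pdb")
  write_trajectory(traj, p)
  lines <- readLines(p)
  expect_equal(sum(startsWith(lines, "MODEL")), 10L)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 10L)
  back <- read_trajectory(p, topo)
  expect_equal(n_frames(back), 10L)
  # PDB stores Angstrom to 3 decimals: half-ulp is 5e-4 A = 5e-5 nm
  expect_lt(max(abs(back$coords - traj$coords)), 5e-5 + 1e-12)
  expect_identical(back$topology$atoms$chain_id, topo$atoms$chain_id)
  expect_identical(back$topology$atoms$resnum, topo$atoms$resnum)
})

test_that("single-frame write produces exactly one MODEL/ENDMDL pair", {
  traj <- make_test_trajectory(list(anisotropic_cloud(5)))
  p <- tempfile(fileext = ".pdb")
  write_trajectory(traj, p)
  lines <- readLines(p)
  expect_equal(sum(startsWith(lines, "MODEL")), 1L)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 1L)
})

test_that("select_domain resolves intervals, preserves order, errors on empty", {
  topo <- make_ca_topology(10)
  sp <- domain_spec("mid", "A", list(c(2, 4)))
  expect_identical(select_domain(topo, sp), 2:4)
  sp2 <- domain_spec("split", "A", list(c(1, 2), c(9, 10)))
  expect_identical(select_domain(topo, sp2), c(1:2, 9:10))
  # idempotent / order-stable; union of disjoint specs = concatenation
  expect_identical(select_domain(topo, sp2), select_domain(topo, sp2))
  expect_identical(c(select_domain(topo, domain_spec("a", "A", list(c(1, 2)))),
                     select_domain(topo, domain_spec("b", "A", list(c(9, 10))))),
                   select_domain(topo, sp2))
  expect_error(select_domain(topo, domain_spec("x", "B", list(c(1, 2)))),
               "chain 'B'")
  expect_error(select_domain(topo, domain_spec("x", "A", list(c(1, 2)),
                                               atom_filter = "CB")),
               "empty")
})

test_that("missing residues in an interval warn but do not error", {
  topo <- make_ca_topology(10)
  topo$atoms <- topo$atoms[-5, ]           # crystal gap at residue 5
  topo <- domainmotion:::new_topology(topo$atoms)
  expect_warning(idx <- select_domain(topo, domain_spec("g", "A",
                                                        list(c(3, 7)))),
                 "no matching atom")
  expect_length(idx, 4L)
})

test_that("domain_spec rejects invalid intervals and names", {
  expect_error(domain_spec("d", "A", list(c(5, 2))), "start <= end")
  expect_error(domain_spec("d", "A", list(c(1, 5), c(4, 8))), "overlap")
  expect_error(domain_spec("", "A", list(c(1, 2))), "non-empty")
})

test_that("thin_trajectory keeps every k-th frame with its time", {
  traj <- make_test_trajectory(lapply(1:10, function(i)
    matrix(i, 4, 3)), dt_ns = 0.04)
  th <- thin_trajectory(traj, 5)
  expect_equal(n_frames(th), 2L)
  expect_equal(th$times, c(0.2, 0.4))
  expect_equal(frame_coords(th, 1), matrix(5, 4, 3))
})
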