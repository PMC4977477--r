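test_that("angle normalization maps onto (-180, 180] and is idempotent", {
  set.seed(11)
  x <- runif(500, -1000, 1000)
  a <- normalize_angle(x)
  expect_true(all(a > -180 & a <= 180))
  expect_equal(normalize_angle(a), a)
  expect_equal(normalize_angle(c(190, -181, 360, 180)), c(-170, 179, 0, 180))
  # representatives of the same circle point agree
  expect_equal(normalize_angle(x + 360), a)
})

test_that("topology constructor enforces its invariants", {
  expect_error(protein_topology("ALA", c(180, 180)), "at least 2")
  expect_error(protein_topology(c("ALA", "SER"), c(1, 2, 3)), "expected 2n")
  expect_error(protein_topology(c("ALA", "SER"), rep(0, 4),
    segments = data.frame(label = "H1", kind = "helix", start = 0, end = 3)),
    "within")
  expect_error(protein_topology(rep("ALA", 6), rep(0, 12),
    segments = data.frame(label = c("A", "B"), kind = "helix",
                          start = c(0, 2), end = c(3, 5))),
    "overlap")
  topo <- protein_topology(c("VAL", "SER", "LEU"), rep(0, 6))
  expect_equal(topo$hydrophobic, c(TRUE, FALSE, TRUE))
})

test_that("forward kinematics is deterministic and torsion-faithful", {
  topo <- helix_topo(6)
  a <- forward_kinematics(topo, topo$native_torsions)
  b <- forward_kinematics(topo, topo$native_torsions)
  expect_identical(a, b)                      # bitwise determinism
  expect_equal(dim(a), c(36L, 3L))
  # full round trip: realized coordinates return the input dihedrals
  set.seed(7)
  for (rep in 1:5) {
    q <- random_conf(topo, sprintf("r%d", rep))
    xyz <- forward_kinematics(topo, q)
    at <- attr(xyz, "atom")
    got <- measure_torsions(xyz[at == "N", ], xyz[at == "CA", ],
                            xyz[at == "C", ])
    idx <- 2:(2 * topo$n - 1)                  # terminals are placeholders
    expect_lt(max(abs(normalize_angle(got[idx] - q$torsions[idx]))), 1e-6)
  }
})

test_that("a single phi change moves only downstream atoms", {
  topo <- helix_topo(6)
  base <- forward_kinematics(topo, topo$native_torsions)
  tors <- topo$native_torsions
  tors[2 * 3 - 1] <- tors[2 * 3 - 1] + 25     # phi of residue 3
  moved <- forward_kinematics(topo, tors)
  res <- attr(base, "residue"); at <- attr(base, "atom")
  upstream <- res < 3 | (res == 3 & at %in% c("N", "H", "CA"))
  expect_equal(moved[upstream, ], base[upstream, ])
  expect_gt(max(abs(moved[!upstream, ] - base[!upstream, ])), 0.1)
})

test_that("perturbation touches only the requested torsions", {
  topo <- helix_topo(5)
  q <- conformation(topo$native_torsions, id = "q")
  expect_error(perturb(q, integer(0), 10), "empty")
  expect_error(perturb(q, 3, -1), "magnitude")
  set.seed(3)
  p1 <- perturb(q, 3L, 20, id = "p1")
  expect_equal(p1$torsions[-3L], q$torsions[-3L])
  expect_true(is.na(p1$energy))
  # near-zero magnitude leaves angles essentially unchanged
  pz <- perturb(q, c(3L, 4L), 1e-12, id = "pz")
  expect_equal(pz$torsions, q$torsions, tolerance = 1e-9)
  # seeded reproducibility
  set.seed(99); a <- perturb(q, c(3L, 5L), 30, id = "a")
  set.seed(99); b <- perturb(q, c(3L, 5L), 30, id = "a")
  expect_identical(a$torsions, b$torsions)
})

test_that("PDB export round-trips through the reader", {
  topo <- make_toy_protein(10, plan = "helix", seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_native_pdb(topo, f)
  back <- read_native_pdb(f)
  expect_equal(back$n, 10L)
  idx <- 2:(2 * topo$n - 1)
  # ATOM records carry 0.001 A coordinates, which bounds recovered dihedrals
  # to ~0.1 degree; the tolerance reflects that quantization
  expect_lt(max(abs(normalize_angle(
    back$native_torsions[idx] - topo$native_torsions[idx]))), 0.2)
  # ideal helix dihedrals recovered
  expect_equal(unname(back$native_torsions[idx][seq(1, 17, 2)]),
               rep(-47, 9), tolerance = 1e-2)
  # segment annotation survives
  expect_equal(back$segments$kind, "helix")
  expect_equal(back$segments$start, 0L)
  expect_equal(back$segments$end, 10L)
})

test_that("minimal and defective PDB inputs behave as specified", {
  topo <- tiny_topo()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_native_pdb(topo, f)
  back <- read_native_pdb(f)
  expect_equal(back$n, 2L)
  expect_length(back$native_torsions, 4L)
  # undefined terminal dihedrals use the documented placeholder
  expect_equal(back$native_torsions[c(1, 4)], c(180, 180))

  # drop residue 1's CA: the error names the residue
  lines <- readLines(f)
  bad <- lines[!grepl("^ATOM.* CA  ALA A   1 ", lines)]
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f2)
  expect_error(read_native_pdb(f2), "residue 1.*CA")
})

test_that("conformation files round-trip", {
  topo <- helix_topo(4)
  set.seed(5)
  confs <- list(conformation(topo$native_torsions, "native", energy = 12.5),
                random_conf(topo, "s1"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_conformations(confs, f)
  back <- read_conformations(f)
  expect_equal(back[[1]]$torsions, confs[[1]]$torsions)
  expect_equal(back[[2]]$torsions, confs[[2]]$torsions)
  expect_equal(back[[1]]$energy, 12.5)
  expect_equal(back[[2]]$id, "s1")
})
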