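# independent transcription of the constraint-term potential, used as the
# oracle against total_energy
oracle_energy <- function(topo, tors, model) {
  xyz <- forward_kinematics(topo, tors)
  if (!clash_check(topo, xyz, model, "sampling")) return(Inf)
  cs <- constraint_set(topo, model)
  u <- 0
  for (r in seq_len(nrow(cs))) {
    d <- sqrt(sum((xyz[cs$i[r], ] - xyz[cs$j[r], ])^2))
    u <- u + model$K_d * (sqrt((d - model$d_0)^2 + model$d_c^2) - model$d_c)
  }
  u + hydrophobic_term(topo, xyz, model)
}

test_that("clash thresholds differ between sampling and connecting phases", {
  topo <- helix_topo(6)
  model <- energy_model()
  xyz <- forward_kinematics(topo, topo$native_torsions)
  expect_true(clash_check(topo, xyz, model, "sampling"))
  # drag residue 1's O next to residue 5's CB: 1.5 A apart, not bonded
  bad <- xyz
  bad[6, ] <- bad[4 * 6 + 4, ] + c(1.5, 0, 0)
  expect_false(clash_check(topo, bad, model, "sampling"))   # < 2.4 A
  expect_true(clash_check(topo, bad, model, "connecting"))  # >= 1.0 A
  bad[6, ] <- bad[4 * 6 + 4, ] + c(0.5, 0, 0)
  expect_false(clash_check(topo, bad, model, "connecting"))
})

test_that("total energy matches a direct transcription of the potential", {
  topo <- helix_topo(6)
  model <- energy_model()
  set.seed(21)
  for (k in 1:10) {
    q <- random_conf(topo, sprintf("e%d", k))
    expect_equal(total_energy(topo, q, model, "sampling"),
                 oracle_energy(topo, q$torsions, model), tolerance = 1e-12)
  }
  # constraint bracket vanishes at d = d_0 and is nonnegative, so the total
  # is bounded below by the hydrophobic term
  for (k in 1:10) {
    q <- random_conf(topo, sprintf("f%d", k))
    xyz <- forward_kinematics(topo, q)
    e <- total_energy(topo, q, model, "sampling", coords = xyz)
    if (is.finite(e)) expect_gte(e, hydrophobic_term(topo, xyz, model))
  }
})

test_that("the call counter counts every energy evaluation, clashes too", {
  topo <- helix_topo(6)
  model <- energy_model()
  reset_energy_calls(model)
  total_energy(topo, topo$native_torsions, model)
  expect_equal(energy_calls(model), 1L)
  # a clashing conformation still costs a call and returns the sentinel
  set.seed(22)
  found <- FALSE
  for (k in 1:100) {
    q <- random_conf(topo, sprintf("c%d", k))
    e <- total_energy(topo, q, model, "sampling")
    if (!is.finite(e)) { found <- TRUE; break }
  }
  expect_true(found)
  expect_equal(energy_calls(model), 1L + k)
  # connect_pair's reported cost equals the counter increment
  a <- conformation(topo$native_torsions, "a")
  set.seed(23)
  b <- perturb(a, 5:8, 15, id = "b")
  before <- energy_calls(model)
  res <- connect_pair(topo, a, b, model)
  expect_equal(res$energy_calls, energy_calls(model) - before)
})

test_that("hydrophobic term is a step contact potential", {
  # no hydrophobic residues at all
  topo0 <- protein_topology(rep("SER", 6), rep(c(-57, -47), 6))
  xyz0 <- forward_kinematics(topo0, topo0$native_torsions)
  expect_equal(hydrophobic_term(topo0, xyz0, energy_model()), 0)

  # exactly one eligible pair in contact contributes one unit
  topo1 <- protein_topology(c("VAL", "SER", "SER", "VAL", "SER", "SER"),
                            rep(c(-57, -47), 6))
  xyz1 <- forward_kinematics(topo1, topo1$native_torsions)
  m <- energy_model()
  cb <- xyz1[c(4, 3 * 6 + 4), ]
  d14 <- sqrt(sum((cb[1, ] - cb[2, ])^2))
  expect_lte(d14, m$hp_cutoff)   # helix places CB(i), CB(i+3) within 6 A
  expect_equal(hydrophobic_term(topo1, xyz1, m), -1)

  # brute-force all-pairs scan agrees on random conformations
  topo <- protein_topology(rep(c("VAL", "SER", "LEU"), 3), rep(0, 18))
  set.seed(24)
  for (k in 1:10) {
    q <- random_conf(topo, sprintf("h%d", k))
    xyz <- forward_kinematics(topo, q)
    cnt <- 0
    for (i in 1:8) for (j in (i + 1):9) {
      if (topo$hydrophobic[i] && topo$hydrophobic[j] && j - i >= 3) {
        d <- sqrt(sum((xyz[(i - 1) * 6 + 4, ] - xyz[(j - 1) * 6 + 4, ])^2))
        if (d <= m$hp_cutoff) cnt <- cnt + 1
      }
    }
    expect_equal(hydrophobic_term(topo, xyz, m), -cnt)
  }
})

test_that("open-chain energy is deterministic and definitional", {
  topo <- helix_topo(6)
  model <- energy_model()
  e1 <- open_chain_energy(topo, model)
  e2 <- open_chain_energy(topo, model)
  expect_identical(e1, e2)
  expect_identical(e1, total_energy(topo, rep(180, 12), model, "sampling"))
  expect_true(is.finite(e1) && e1 > 0)
})
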