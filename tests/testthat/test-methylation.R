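test_that("placed adducts satisfy bond length, bond angle and requested dihedral", {
  fix <- make_toy_rna(5, 0, seed = 13)
  spec <- adduct_spec()
  for (s in 1:5) for (tor in c(-120, 75.0, 10.5)) {
    placed <- place_adduct(fix$model, list(chain = "A", seq_id = s), spec, tor)
    o2 <- placed$parent_position
    cm <- placed$adduct_position
    expect_equal(sqrt(sum((cm - o2)^2)), spec$bond_length, tolerance = 1e-6)
    c2 <- ribomethscore:::.atom_position(fix$model, "A", s, "C2'")
    c1 <- ribomethscore:::.atom_position(fix$model, "A", s, "C1'")
    v1 <- c2 - o2; v2 <- cm - o2
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(ang, spec$bond_angle, tolerance = 1e-4)
    expect_equal(dihedral_angle(c1, c2, o2, cm), tor, tolerance = 1e-4)
  }
})

test_that("degenerate collinear reference geometry errors", {
  atoms <- data.frame(chain = "A", seq_id = 1L, resname = "A",
                      atom = c("C1'", "C2'", "O2'"), element = c("C", "C", "O"),
                      x = c(0, 1.5, 3.0), y = 0, z = 0, b = 10, occ = 1,
                      stringsAsFactors = FALSE)
  bad <- atomic_model(atoms)
  expect_error(place_adduct(bad, list(chain = "A", seq_id = 1L)), "collinear")
})

test_that("missing parent atoms error at placement", {
  fix <- make_toy_rna(2, 0, seed = 1)
  a <- fix$model$atoms
  m <- atomic_model(a[!(a$seq_id == 1 & a$atom == "O2'"), ])
  expect_error(place_adduct(m, list(chain = "A", seq_id = 1L)), "O2'")
})

test_that("torsion scan equals brute-force clearance maximization and is deterministic", {
  fix <- make_toy_rna(3, 0, seed = 17)
  spec <- adduct_spec()
  for (s in 1:3) {
    got <- choose_clash_free_torsion(fix$model, list(chain = "A", seq_id = s), spec)
    # independent brute force over the same grid
    tors <- seq(-175, 180, by = 5)
    a <- fix$model$atoms
    excl <- (a$seq_id == s & a$atom %in% c("C2'", "O2'", "CM'")) |
            toupper(a$element) == "H"
    env <- as.matrix(a[!excl, c("x", "y", "z")])
    radii <- vdw_radius(a$element[!excl]) + vdw_radius("C")
    c1 <- ribomethscore:::.atom_position(fix$model, "A", s, "C1'")
    c2 <- ribomethscore:::.atom_position(fix$model, "A", s, "C2'")
    o2 <- ribomethscore:::.atom_position(fix$model, "A", s, "O2'")
    clr <- vapply(tors, function(tt) {
      cm <- place_internal(c1, c2, o2, spec$bond_length, spec$bond_angle, tt)
      min(sqrt(rowSums(sweep(env, 2, cm)^2)) - radii)
    }, numeric(1))
    expect_equal(got$torsion, tors[which.max(clr)])
    expect_equal(got$min_clearance, max(clr), tolerance = 1e-9)
    # determinism
    again <- choose_clash_free_torsion(fix$model, list(chain = "A", seq_id = s), spec)
    expect_identical(got, again)
  }
})

test_that("a decoy atom at a scanned methyl position repels the chosen torsion", {
  fix <- make_toy_rna(1, 0, seed = 3)
  spec <- adduct_spec()
  p60 <- place_adduct(fix$model, list(chain = "A", seq_id = 1L), spec, 60)
  a <- fix$model$atoms
  decoy <- a[1, ]
  decoy$seq_id <- 99L; decoy$atom <- "XD"; decoy$element <- "C"
  decoy$x <- p60$adduct_position[1]
  decoy$y <- p60$adduct_position[2]
  decoy$z <- p60$adduct_position[3]
  m2 <- atomic_model(rbind(a, decoy))
  got <- choose_clash_free_torsion(m2, list(chain = "A", seq_id = 1L), spec)
  expect_false(isTRUE(all.equal(got$torsion, 60)))
  # clearance at 60 with the decoy present is the full vdW overlap
  scan60 <- ribomethscore:::.torsion_scan(m2, "A", 1L, spec, 5)
  clr60 <- scan60$clearance[scan60$torsions == 60]
  expect_gte(got$min_clearance, clr60)
  expect_lt(clr60, -2)   # decoy coincides with the methyl position
})

test_that("a fully caged site reports clash_free = FALSE but still the clearance argmax", {
  fix <- make_toy_rna(1, 0, seed = 5)
  spec <- adduct_spec()
  scan <- ribomethscore:::.torsion_scan(fix$model, "A", 1L, spec, 30)
  a <- fix$model$atoms
  cage <- do.call(rbind, lapply(seq_along(scan$torsions), function(i) {
    row <- a[1, ]
    row$seq_id <- 100L + i; row$atom <- "XC"; row$element <- "C"
    row$x <- scan$xyz[i, 1]; row$y <- scan$xyz[i, 2]; row$z <- scan$xyz[i, 3]
    row
  }))
  caged <- atomic_model(rbind(a, cage))
  got <- choose_clash_free_torsion(caged, list(chain = "A", seq_id = 1L),
                                   spec, step = 30)
  expect_false(got$clash_free)
  full <- ribomethscore:::.torsion_scan(caged, "A", 1L, spec, 30)
  expect_equal(got$min_clearance, max(full$clearance), tolerance = 1e-9)
})

test_that("density-guided refinement recovers a known torsion optimum", {
  fix <- make_toy_rna(1, 0, seed = 3)
  spec <- adduct_spec()
  target <- place_adduct(fix$model, list(chain = "A", seq_id = 1L), spec, 75)
  m <- gaussian_map(target$adduct_position, sigma = 1.0, voxel = 0.2)
  for (start in c(-150, -30, 160)) {
    p0 <- place_adduct(fix$model, list(chain = "A", seq_id = 1L), spec, start)
    ref <- refine_torsion_against_map(fix$model, p0, m, spec)
    expect_true(ref$refined)
    expect_equal(ref$torsion, 75, tolerance = 2)
  }
})

test_that("refinement is monotone in the objective and flat maps leave torsions unchanged", {
  fix <- make_toy_rna(1, 0, seed = 3)
  spec <- adduct_spec()
  target <- place_adduct(fix$model, list(chain = "A", seq_id = 1L), spec, 75)
  m <- gaussian_map(target$adduct_position, sigma = 1.0, voxel = 0.25, half = 7)
  for (start in seq(-160, 160, by = 40)) {
    p0 <- place_adduct(fix$model, list(chain = "A", seq_id = 1L), spec, start)
    ref <- refine_torsion_against_map(fix$model, p0, m, spec)
    j0 <- map_value_at(m, p0$adduct_position)$value
    j1 <- map_value_at(m, ref$adduct_position)$value
    expect_gte(j1, j0)
  }
  flat <- density_map(array(2.5, dim = c(40, 40, 40)), 1,
                      target$adduct_position - 20)
  p0 <- place_adduct(fix$model, list(chain = "A", seq_id = 1L), spec, -30)
  ref <- refine_torsion_against_map(fix$model, p0, flat, spec)
  expect_equal(ref$torsion, -30)
  expect_true(ref$refined)
})

test_that("refinement can be disabled in the screen config (pass-through)", {
  fix <- make_toy_rna(4, 0.25, seed = 19)
  map <- simulate_map(fix$model, sim_spec(noise_sd = 0))
  res_off <- run_screen(fix$model, map, config = screen_config(refine = FALSE))
  # without refinement, reported torsions are exactly the clash-scan output
  for (i in seq_len(nrow(res_off$records))) {
    r <- res_off$records[i, ]
    want <- choose_clash_free_torsion(fix$model,
                                      list(chain = r$chain, seq_id = r$seq_id))
    expect_equal(r$torsion, want$torsion)
  }
})

test_that("adduct construction respects a custom adduct specification", {
  fix <- make_toy_rna(1, 0, seed = 23)
  spec <- adduct_spec(bond_length = 1.36, bond_angle = 117,
                      probe_extension = 2.1)
  placed <- place_adduct(fix$model, list(chain = "A", seq_id = 1L), spec, 40)
  expect_equal(sqrt(sum((placed$adduct_position - placed$parent_position)^2)),
               1.36, tolerance = 1e-6)
  ext <- extended_position(placed, spec)
  expect_equal(sqrt(sum((ext - placed$parent_position)^2)), 2.1,
               tolerance = 1e-9)
  expect_error(adduct_spec(probe_extension = 1.43), "exceed")
  expect_error(adduct_spec(bond_length = -1), "> 0")
})
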