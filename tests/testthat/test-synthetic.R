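test_that("toy generator honours counts, spacing and reproducibility", {
  fix <- make_toy_rna(20, 0.25, seed = 1)
  expect_equal(nrow(fix$truth$methylated_sites), 5L)
  expect_equal(fix$truth$n_candidates, 20L)
  expect_equal(n_residues(fix$model), 20L)
  a <- fix$model$atoms
  o2 <- as.matrix(a[a$atom == "O2'", c("x", "y", "z")])
  d <- as.matrix(dist(o2))
  expect_gte(min(d[upper.tri(d)]), 8)
  again <- make_toy_rna(20, 0.25, seed = 1)
  expect_identical(fix$model$atoms, again$model$atoms)
  expect_identical(fix$truth$methylated_sites, again$truth$methylated_sites)
  other <- make_toy_rna(20, 0.25, seed = 2)
  expect_false(identical(fix$model$atoms, other$model$atoms))
})

test_that("boundary fractions and the empty model behave", {
  none <- make_toy_rna(0, 0.5, seed = 1)
  expect_equal(nrow(none$model$atoms), 0L)
  expect_equal(nrow(none$truth$methylated_sites), 0L)
  all_m <- make_toy_rna(6, 1.0, seed = 3)
  expect_equal(nrow(all_m$truth$methylated_sites), 6L)
  expect_equal(sum(all_m$model$atoms$atom == "CM'"), 6L)
  expect_error(make_toy_rna(50, 0.2, seed = 1, min_spacing = 30, box = 40),
               "min_spacing")
})

test_that("true methyls are built with the screen's own placement geometry", {
  fix <- make_toy_rna(10, 0.4, seed = 21)
  spec <- adduct_spec()
  for (i in seq_len(nrow(fix$truth$methylated_sites))) {
    s <- fix$truth$methylated_sites$seq_id[i]
    a <- fix$model$atoms
    cm <- as.numeric(a[a$seq_id == s & a$atom == "CM'", c("x", "y", "z")])
    o2 <- as.numeric(a[a$seq_id == s & a$atom == "O2'", c("x", "y", "z")])
    expect_equal(sqrt(sum((cm - o2)^2)), spec$bond_length, tolerance = 1e-6)
  }
  # unlabelled residues carry no methyl
  lab <- fix$truth$methylated_sites$seq_id
  a <- fix$model$atoms
  expect_equal(sort(unique(a$seq_id[a$atom == "CM'"])), sort(lab))
})

test_that("a single-atom map matches the closed-form Gaussian integral", {
  atoms <- data.frame(chain = "A", seq_id = 1L, resname = "A", atom = "C1'",
                      element = "C", x = 0, y = 0, z = 0, b = 20, occ = 1,
                      stringsAsFactors = FALSE)
  one <- atomic_model(atoms)
  spec <- sim_spec(resolution_proxy = 3.0, voxel_size = 0.5, noise_sd = 0,
                   padding = 6)
  m <- simulate_map(one, spec)
  # maximum at the voxel nearest the atom
  peak <- which(m$grid == max(m$grid), arr.ind = TRUE)[1, ]
  peak_pos <- m$origin + (peak - 1) * m$voxel
  expect_lte(max(abs(peak_pos - c(0, 0, 0))), max(m$voxel) / 2 + 1e-9)
  # discrete mass ~ analytic integral of the kernel
  sigma <- 0.425 * 3.0
  analytic <- (2 * pi * sigma^2)^(3 / 2)
  expect_equal(sum(m$grid) * prod(m$voxel), analytic, tolerance = 0.05)
})

test_that("methyl atoms change the simulated map only near the methyl positions", {
  fix <- make_toy_rna(8, 0.25, seed = 41)
  spec <- sim_spec(noise_sd = 0)
  a <- fix$model$atoms
  bounds <- list(lo = c(min(a$x), min(a$y), min(a$z)) - spec$padding,
                 hi = c(max(a$x), max(a$y), max(a$z)) + spec$padding)
  with_m <- simulate_map(fix$model, spec, bounds = bounds)
  bare <- atomic_model(a[a$atom != "CM'", ])
  without_m <- simulate_map(bare, spec, bounds = bounds)
  expect_identical(dim(with_m$grid), dim(without_m$grid))
  dv <- with_m$grid - without_m$grid
  # voxels far from every methyl are bit-identical; methyl voxels gain density
  cms <- as.matrix(a[a$atom == "CM'", c("x", "y", "z")])
  sigma <- spec$kernel_sigma
  ax <- lapply(1:3, function(k)
    with_m$origin[k] + (seq_len(dim(dv)[k]) - 1L) * with_m$voxel[k])
  changed <- which(abs(dv) > 0, arr.ind = TRUE)
  pos <- cbind(ax[[1]][changed[, 1]], ax[[2]][changed[, 2]], ax[[3]][changed[, 3]])
  # kernels are stamped on per-axis windows, so locality is per-coordinate
  cheb <- apply(pos, 1, function(p)
    min(apply(abs(sweep(cms, 2, p)), 1, max)))
  expect_lte(max(cheb), 4 * sigma + max(with_m$voxel))
  near <- map_value_at(with_m, cms)$value - map_value_at(without_m, cms)$value
  expect_true(all(near > 0.5))
})

test_that("simulated noise has the requested standard deviation and is seeded", {
  fix <- make_toy_rna(4, 0, seed = 51)
  clean <- simulate_map(fix$model, sim_spec(noise_sd = 0, seed = 9))
  noisy <- simulate_map(fix$model, sim_spec(noise_sd = 0.25, seed = 9))
  resid <- as.vector(noisy$grid - clean$grid)
  expect_equal(sd(resid), 0.25, tolerance = 0.05)
  noisy2 <- simulate_map(fix$model, sim_spec(noise_sd = 0.25, seed = 9))
  expect_identical(noisy$grid, noisy2$grid)
  noisy3 <- simulate_map(fix$model, sim_spec(noise_sd = 0.25, seed = 10))
  expect_false(identical(noisy$grid, noisy3$grid))
})

test_that("recovery statistics equal a brute-force count over the record list", {
  fix <- make_toy_rna(12, 0.25, seed = 61)
  map <- simulate_map(fix$model, sim_spec(noise_sd = 0))
  res <- run_screen(fix$model, map)
  tk <- truth_keys(fix$truth)
  for (top_n in c(0L, 3L, 12L)) {
    stats <- evaluate_recovery(res, fix$truth, top_n)
    brute <- sum(record_keys(res) %in% tk & res$records$rank <= top_n)
    expect_equal(stats$recovered, brute)
    expect_lte(stats$recovered, min(top_n, length(tk)))
  }
  expect_equal(evaluate_recovery(res, fix$truth, 0L)$recovered, 0L)
  # truth referencing an absent residue errors
  bad <- fix$truth
  bad$methylated_sites <- rbind(bad$methylated_sites,
                                data.frame(chain = "A", seq_id = 999L))
  expect_error(evaluate_recovery(res, bad, 5L), "absent")
})

test_that("forced rankings give recovered = k for any window at least k", {
  rec <- data.frame(chain = "A", seq_id = 1:10, torsion = 0,
                    sc_mapval = 10:1, sc_falloff = 2,
                    probe_x = 0, probe_y = 0, probe_z = 0,
                    ext_x = 0, ext_y = 0, ext_z = 0, notes = "",
                    stringsAsFactors = FALSE)
  res <- rank_sites(rec, screen_config())
  truth <- structure(list(methylated_sites = data.frame(
    chain = "A", seq_id = 1:3, stringsAsFactors = FALSE),
    n_candidates = 10L), class = "ground_truth")
  for (top_n in 3:10)
    expect_equal(evaluate_recovery(res, truth, top_n)$recovered, 3L)
})

test_that("truth tables round-trip through TSV", {
  fix <- make_toy_rna(10, 0.3, seed = 71)
  path <- tempfile(fileext = ".tsv")
  write_truth_tsv(fix$truth, path)
  back <- read_truth_tsv(path, n_candidates = 10L)
  expect_equal(back$methylated_sites$seq_id, fix$truth$methylated_sites$seq_id)
  expect_equal(back$methylated_sites$chain, fix$truth$methylated_sites$chain)
})
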