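# Synthetic fixtures: toy RNA models with known 2'-O-methylation ground
# truth and simulated density maps, so the whole screen and its recovery
# behaviour can be validated without any experimental data.
#
# Residues are built from an idealized internal-coordinate adenosine
# template (ribose + base heavy atoms, beta-D-ribo stereochemistry: the
# 2'-OH on the opposite sugar face from the base and C5') and placed at
# random positions and orientations with a minimum O2'-O2' spacing, with no
# chain connectivity -- the screen probes local density only, so isolated
# nucleotides exercise everything the scoring logic depends on.

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Idealized adenosine heavy-atom template, O2' at the origin.
# Built once from internal coordinates: a puckered five-membered furanose,
# exocyclic substituents on the stereochemically correct faces, and a planar
# purine in the anti orientation about the glycosidic bond.
.adenosine_template <- function() {
  r <- 1.46 / (2 * sin(pi / 5))
  ang <- (90 - 72 * (0:4)) * pi / 180   # O4', C1', C2', C3', C4'
  pucker <- c(0.00, 0.10, -0.25, 0.40, -0.10)
  ring <- cbind(r * cos(ang), r * sin(ang), pucker)
  rownames(ring) <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  centroid <- colMeans(ring)
  # exocyclic substituent: radially out from the ring, tilted to one face
  exo <- function(at, bond, face, tilt = 55) {
    radial <- ring[at, ] - centroid
    radial[3L] <- 0
    radial <- radial / sqrt(sum(radial^2))
    th <- tilt * pi / 180
    ring[at, ] + bond * (radial * cos(th) + c(0, 0, face * sin(th)))
  }
  o2p <- exo("C2'", 1.41, -1)
  o3p <- exo("C3'", 1.42, -1)
  c5p <- exo("C4'", 1.51, +1)
  n9  <- exo("C1'", 1.47, +1)
  o5p <- place_internal(ring["C3'", ], ring["C4'", ], c5p, 1.44, 109.5, 180)
  p   <- place_internal(ring["C4'", ], c5p, o5p, 1.59, 120.0, 180)
  op1 <- place_internal(c5p, o5p, p, 1.48, 109.5, 60)
  op2 <- place_internal(c5p, o5p, p, 1.48, 109.5, -60)
  # purine, planar by construction (ring torsions 0/180), anti glycosidic
  c4 <- place_internal(ring["O4'", ], ring["C1'", ], n9, 1.37, 126.0, -120)
  c5 <- place_internal(ring["C1'", ], n9, c4, 1.38, 106.0, 180)
  n7 <- place_internal(n9, c4, c5, 1.39, 110.0, 0)
  c8 <- place_internal(c4, c5, n7, 1.31, 104.0, 0)
  n3 <- place_internal(n7, c5, c4, 1.35, 127.0, 180)
  c2 <- place_internal(c5, c4, n3, 1.33, 111.0, 0)
  n1 <- place_internal(c4, n3, c2, 1.34, 129.0, 0)
  c6 <- place_internal(n3, c2, n1, 1.35, 118.0, 0)
  n6 <- place_internal(c2, n1, c6, 1.34, 119.0, 180)
  xyz <- rbind(P = p, OP1 = op1, OP2 = op2, "O5'" = o5p, "C5'" = c5p,
               "C4'" = ring["C4'", ], "O4'" = ring["O4'", ],
               "C3'" = ring["C3'", ], "O3'" = o3p,
               "C2'" = ring["C2'", ], "O2'" = o2p, "C1'" = ring["C1'", ],
               N9 = n9, C8 = c8, N7 = n7, C5 = c5, C6 = c6, N6 = n6,
               N1 = n1, C2 = c2, N3 = n3, C4 = c4)
  sweep(xyz, 2L, o2p)                  # O2' at the origin
}

.template_elements <- function(names) toupper(substr(gsub("[^A-Za-z]", "", names), 1L, 1L))

#' Simulation specification for synthetic maps
#'
#' The density surrogate places an isotropic Gaussian kernel on every heavy
#' atom with sd \code{0.425 * resolution_proxy} (so the kernel FWHM matches
#' the nominal resolution), plus optional i.i.d. Gaussian noise.
#'
#' @param resolution_proxy nominal resolution in Angstrom (> 0); controls
#'   kernel width.
#' @param voxel_size grid spacing, Angstrom.
#' @param amplitude_mode "uniform" (every atom peak height 1) or
#'   "atomic_number" (peak height = element Z).
#' @param noise_sd standard deviation of additive Gaussian noise, map units.
#' @param padding margin around the model bounding box, Angstrom; must be at
#'   least 3 kernel sd so the density of edge atoms is contained.
#' @param seed integer seed for the noise.
#' @return an object of class \code{sim_spec}.
#' @export
sim_spec <- function(resolution_proxy = 3.0, voxel_size = 0.5,
                     amplitude_mode = c("uniform", "atomic_number"),
                     noise_sd = 0, padding = 6, seed = 1L) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (resolution_proxy <= 0) stop("resolution_proxy must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  sigma <- 0.425 * resolution_proxy
  if (padding < 3 * sigma)
    stop("padding must be at least 3 kernel sd (", round(3 * sigma, 2), " A)")
  structure(list(resolution_proxy = resolution_proxy,
                 voxel_size = voxel_size, amplitude_mode = amplitude_mode,
                 kernel_sigma = sigma, noise_sd = noise_sd,
                 padding = padding, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate a toy RNA model with known methylation ground truth
#'
#' Builds \code{n_residues} adenosine nucleotides from an idealized
#' internal-coordinate template, placed at random positions and orientations
#' with pairwise O2'-O2' distance at least \code{min_spacing} (and no
#' inter-residue atom interpenetration). Exactly
#' \code{round(n_residues * frac_methylated)} residues, chosen at random,
#' are labelled methylated and receive a real methyl atom built by the
#' methylation module at a random clash-free torsion. Bit-for-bit
#' reproducible for a given seed.
#'
#' @param n_residues number of nucleotides (>= 0).
#' @param frac_methylated fraction of residues to methylate, in \[0, 1\].
#' @param seed integer seed.
#' @param min_spacing minimum pairwise O2'-O2' distance, Angstrom.
#' @param box edge length of the cubic placement region, Angstrom; sized
#'   automatically from \code{n_residues} and \code{min_spacing} when NULL.
#'   Placement errors when the spacing cannot be satisfied in the box after
#'   a bounded number of retries.
#' @param spec \code{\link{adduct_spec}} used to build the true methyls.
#' @return list with \code{model} (an \code{atomic_model}) and \code{truth}
#'   (class \code{ground_truth}: \code{methylated_sites} data.frame with
#'   chain and seq_id, and \code{n_candidates}).
#' @export
make_toy_rna <- function(n_residues, frac_methylated = 0.25, seed = 1L,
                         min_spacing = 8, box = NULL, spec = adduct_spec()) {
  stopifnot(n_residues >= 0, frac_methylated >= 0, frac_methylated <= 1)
  tmpl <- .adenosine_template()
  elements <- .template_elements(rownames(tmpl))
  empty_truth <- structure(list(
    methylated_sites = data.frame(chain = character(0L), seq_id = integer(0L),
                                  stringsAsFactors = FALSE),
    n_candidates = as.integer(n_residues)), class = "ground_truth")
  if (n_residues == 0L) {
    model <- atomic_model(data.frame(
      chain = character(0L), seq_id = integer(0L), resname = character(0L),
      atom = character(0L), element = character(0L), x = numeric(0L),
      y = numeric(0L), z = numeric(0L), b = numeric(0L), occ = numeric(0L),
      stringsAsFactors = FALSE))
    return(list(model = model, truth = empty_truth))
  }
  .with_seed(seed, {
    if (is.null(box))
      box <- max(20, min_spacing * ceiling(n_residues^(1 / 3)) * 1.4)
    placed_o2 <- matrix(numeric(0L), ncol = 3L)
    all_xyz <- matrix(numeric(0L), ncol = 3L)
    coords <- vector("list", n_residues)
    tries <- 0L
    max_tries <- 500L * n_residues
    i <- 1L
    while (i <= n_residues) {
      if (tries >= max_tries)
        stop("could not satisfy min_spacing = ", min_spacing,
             " A for ", n_residues, " residues after ", max_tries, " tries")
      tries <- tries + 1L
      pos <- stats::runif(3L, 0, box)
      if (nrow(placed_o2) &&
          min(sqrt(rowSums(sweep(placed_o2, 2L, pos)^2))) < min_spacing)
        next
      rot <- .random_rotation()
      xyz <- tmpl %*% t(rot)
      xyz <- sweep(xyz, 2L, pos, "+")
      if (nrow(all_xyz)) {
        mind <- min(apply(xyz, 1L, function(q)
          min(rowSums(sweep(all_xyz, 2L, q)^2))))
        if (mind < 3.2^2) next
      }
      coords[[i]] <- xyz
      placed_o2 <- rbind(placed_o2, pos)
      all_xyz <- rbind(all_xyz, xyz)
      i <- i + 1L
    }
    natom <- nrow(tmpl)
    atoms <- data.frame(
      chain = "A",
      seq_id = rep(seq_len(n_residues), each = natom),
      resname = "A",
      atom = rep(rownames(tmpl), n_residues),
      element = rep(elements, n_residues),
      x = unlist(lapply(coords, function(m) m[, 1L])),
      y = unlist(lapply(coords, function(m) m[, 2L])),
      z = unlist(lapply(coords, function(m) m[, 3L])),
      b = 30, occ = 1, stringsAsFactors = FALSE)
    model <- atomic_model(atoms)
    k <- round(n_residues * frac_methylated)
    meth <- sort(sample.int(n_residues, k))
    for (s in meth) {
      scan <- .torsion_scan(model, "A", s, spec, step = 5)
      ok <- which(scan$clearance >= -0.6)
      tor <- if (length(ok)) scan$torsions[ok[sample.int(length(ok), 1L)]]
             else scan$torsions[which.max(scan$clearance)]
      placed <- place_adduct(model, list(chain = "A", seq_id = s), spec, tor)
      model <- add_adduct_to_model(model, placed, spec)
    }
    truth <- structure(list(
      methylated_sites = data.frame(chain = rep("A", k), seq_id = meth,
                                    stringsAsFactors = FALSE),
      n_candidates = as.integer(n_residues)), class = "ground_truth")
    list(model = model, truth = truth)
  })
}

.atomic_numbers <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

#' Simulate a density map from an atomic model
#'
#' Sum of isotropic Gaussian kernels over the model's heavy atoms (sd from
#' the kernel rule of the \code{\link{sim_spec}}, truncated at 4 sd),
#' evaluated on a grid covering the model bounding box plus padding, with
#' optional seeded i.i.d. Gaussian noise.
#'
#' @param model a non-empty \code{atomic_model}.
#' @param spec a \code{\link{sim_spec}}.
#' @param bounds optional list with numeric 3-vectors \code{lo} and
#'   \code{hi} fixing the grid extent in Angstrom (padding is not added);
#'   by default the model bounding box plus padding is used. Useful for
#'   simulating model variants on one common grid.
#' @return a \code{density_map}.
#' @export
simulate_map <- function(model, spec = sim_spec(), bounds = NULL) {
  a <- model$atoms
  if (nrow(a) == 0L) stop("cannot simulate a map from an empty model")
  heavy <- toupper(a$element) != "H"
  a <- a[heavy, , drop = FALSE]
  sigma <- spec$kernel_sigma
  vox <- spec$voxel_size
  if (is.null(bounds)) {
    lo <- c(min(a$x), min(a$y), min(a$z)) - spec$padding
    hi <- c(max(a$x), max(a$y), max(a$z)) + spec$padding
  } else {
    lo <- as.numeric(bounds$lo)
    hi <- as.numeric(bounds$hi)
  }
  dims <- as.integer(ceiling((hi - lo) / vox)) + 1L
  grid <- array(0, dim = dims)
  axes <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 1L) * vox)
  amp <- if (spec$amplitude_mode == "uniform") rep(1, nrow(a)) else {
    z <- .atomic_numbers[toupper(a$element)]
    z[is.na(z)] <- 6
    unname(z)
  }
  cut <- 4 * sigma
  for (i in seq_len(nrow(a))) {
    p <- c(a$x[i], a$y[i], a$z[i])
    rng <- lapply(1:3, function(k) {
      j <- which(abs(axes[[k]] - p[k]) <= cut)
      if (!length(j)) integer(0L) else j
    })
    if (any(!lengths(rng))) next
    g1 <- exp(-(axes[[1L]][rng[[1L]]] - p[1L])^2 / (2 * sigma^2))
    g2 <- exp(-(axes[[2L]][rng[[2L]]] - p[2L])^2 / (2 * sigma^2))
    g3 <- exp(-(axes[[3L]][rng[[3L]]] - p[3L])^2 / (2 * sigma^2))
    grid[rng[[1L]], rng[[2L]], rng[[3L]]] <-
      grid[rng[[1L]], rng[[2L]], rng[[3L]]] + amp[i] * (g1 %o% g2 %o% g3)
  }
  if (spec$noise_sd > 0) {
    grid <- grid + .with_seed(spec$seed,
      array(stats::rnorm(length(grid), 0, spec$noise_sd), dim = dims))
  }
  density_map(grid, vox, lo)
}

#' Top-N recovery statistics against ground truth
#'
#' Counts how many truly methylated sites rank within the top \code{top_n}
#' by Sc_MapVal, and tallies the falloff criterion split by truth label.
#'
#' @param result a \code{methyl_screen}.
#' @param truth a \code{ground_truth} from \code{\link{make_toy_rna}} (or a
#'   compatible list with a \code{methylated_sites} data.frame).
#' @param top_n size of the rank window.
#' @return an object of class \code{recovery_stats}: top_n, recovered,
#'   n_true, falloff_pass_true, falloff_pass_false, mean_falloff_true,
#'   mean_falloff_false.
#' @export
evaluate_recovery <- function(result, truth, top_n) {
  r <- result$records
  key <- function(ch, id) paste(ch, id, sep = "\r")
  tkey <- key(truth$methylated_sites$chain, truth$methylated_sites$seq_id)
  rkey <- key(r$chain, r$seq_id)
  ekey <- if (NROW(result$excluded_sites))
    key(result$excluded_sites$chain, result$excluded_sites$seq_id) else character(0L)
  missing <- setdiff(tkey, c(rkey, ekey))
  if (length(missing))
    stop("ground truth references residues absent from the screen result: ",
         paste(gsub("\r", "", missing), collapse = ", "))
  is_true <- rkey %in% tkey
  recovered <- sum(is_true & r$rank <= top_n)
  structure(list(
    top_n = as.integer(top_n),
    recovered = as.integer(recovered),
    n_true = length(tkey),
    falloff_pass_true = sum(r$falloff_pass[is_true]),
    falloff_pass_false = sum(r$falloff_pass[!is_true]),
    mean_falloff_true = if (any(is_true))
      mean(r$sc_falloff[is_true], na.rm = TRUE) else NA_real_,
    mean_falloff_false = if (any(!is_true))
      mean(r$sc_falloff[!is_true], na.rm = TRUE) else NA_real_),
    class = "recovery_stats")
}

#' @export
print.recovery_stats <- function(x, ...) {
  cat(sprintf("Recovery: %d of %d known sites in the top %d\n",
              x$recovered, x$n_true, x$top_n))
  cat(sprintf("Falloff criterion passed: %d true, %d decoy\n",
              x$falloff_pass_true, x$falloff_pass_false))
  cat(sprintf("Mean Sc_FallOff: %.3f (true) vs %.3f (decoy)\n",
              x$mean_falloff_true, x$mean_falloff_false))
  invisible(x)
}

#' Write a ground-truth table as TSV
#'
#' Columns: chain, seq_id, label (1 = methylated). The same format is
#' accepted by \code{\link{read_truth_tsv}} and by the CLI's evaluate
#' subcommand for user-supplied known-site lists.
#'
#' @param truth a \code{ground_truth}.
#' @param path output path.
#' @param n_candidates candidate count recorded alongside (taken from the
#'   truth object when present).
#' @export
write_truth_tsv <- function(truth, path, n_candidates = truth$n_candidates) {
  out <- data.frame(chain = truth$methylated_sites$chain,
                    seq_id = truth$methylated_sites$seq_id,
                    label = 1L, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(NULL)
}

#' Read a known-sites / ground-truth TSV
#'
#' @param path TSV with columns chain, seq_id (and optionally label; rows
#'   with label 0 are dropped).
#' @param n_candidates optional candidate count to record.
#' @return a \code{ground_truth}.
#' @export
read_truth_tsv <- function(path, n_candidates = NA_integer_) {
  t <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c(chain = "character"),
                         stringsAsFactors = FALSE)
  if (!all(c("chain", "seq_id") %in% names(t)))
    stop("truth file must have columns chain and seq_id")
  if ("label" %in% names(t)) t <- t[t$label != 0, , drop = FALSE]
  structure(list(
    methylated_sites = data.frame(chain = as.character(t$chain),
                                  seq_id = as.integer(t$seq_id),
                                  stringsAsFactors = FALSE),
    n_candidates = as.integer(n_candidates)), class = "ground_truth")
}
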