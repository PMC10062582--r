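# Hypothetical 2'-O-methylation of candidate riboses.
#
# The adduct is built purely from internal coordinates (bond length, bond
# angle at the parent oxygen, dihedral about the C2'-O2' bond), so the only
# degree of freedom once the parent geometry is fixed is the O2'-CM' torsion.
# Torsion selection avoids steric clashes; an optional density-guided torsion
# refinement settles the methyl into local map density, standing in for the
# molecular-dynamics settling a full modelling pipeline would use.

#' Adduct specification
#'
#' Chemical definition of the hypothetical modification. The defaults
#' describe a 2'-O-methyl group on adenosine: parent atom O2', C-O bond
#' 1.43 Angstrom, C2'-O2'-CM' angle 113 degrees (standard 2'-O-methyl
#' nucleoside stereochemistry, as in the wwPDB chemical component A2M), and
#' a probe extension of 2.4 Angstrom along the O2'-methyl bond for the
#' falloff score. All fields are configurable so other residue modifications
#' can be screened with the same machinery.
#'
#' @param target_residue_codes component codes of candidate residues.
#' @param parent_atom atom the adduct bonds to.
#' @param bond_length parent-adduct bond length, Angstrom (> 0).
#' @param bond_angle bond angle at the parent atom, degrees.
#' @param torsion_reference four atom names defining the adduct dihedral;
#'   must end in the adduct atom name.
#' @param adduct_atom_name name given to the placed atom.
#' @param adduct_element element of the placed atom.
#' @param adduct_residue_code component code used when writing modified
#'   residues.
#' @param probe_extension distance from the parent atom to the extended
#'   falloff probe, Angstrom; must exceed \code{bond_length}.
#' @return an object of class \code{adduct_spec}.
#' @export
adduct_spec <- function(target_residue_codes = "A",
                        parent_atom = "O2'",
                        bond_length = 1.43,
                        bond_angle = 113.0,
                        torsion_reference = c("C1'", "C2'", "O2'", "CM'"),
                        adduct_atom_name = "CM'",
                        adduct_element = "C",
                        adduct_residue_code = "A2M",
                        probe_extension = 2.4) {
  if (bond_length <= 0) stop("bond_length must be > 0")
  if (probe_extension <= bond_length)
    stop("probe_extension must exceed bond_length")
  if (length(torsion_reference) != 4L)
    stop("torsion_reference must name four atoms")
  if (torsion_reference[4L] != adduct_atom_name)
    stop("torsion_reference must end in the adduct atom name")
  structure(list(target_residue_codes = target_residue_codes,
                 parent_atom = parent_atom,
                 bond_length = bond_length,
                 bond_angle = bond_angle,
                 torsion_reference = torsion_reference,
                 adduct_atom_name = adduct_atom_name,
                 adduct_element = adduct_element,
                 adduct_residue_code = adduct_residue_code,
                 probe_extension = probe_extension),
            class = "adduct_spec")
}

# Reference positions (rows a, b, c) for the adduct dihedral of one site;
# errors if any is missing.
.reference_positions <- function(model, chain, seq_id, spec) {
  ref <- spec$torsion_reference[1:3]
  pos <- lapply(ref, function(nm) .atom_position(model, chain, seq_id, nm))
  bad <- vapply(pos, is.null, logical(1L))
  if (any(bad))
    stop("residue ", chain, seq_id, " is missing parent atom(s): ",
         paste(ref[bad], collapse = ", "))
  pos
}

#' Place the hypothetical adduct at a given torsion
#'
#' Constructs the adduct position from internal coordinates (bond length,
#' bond angle, requested dihedral) using the three reference atoms of the
#' site. Recomputing the dihedral from the produced coordinates returns the
#' requested torsion.
#'
#' @param model an \code{atomic_model}.
#' @param site one row of \code{\link{select_candidates}} output, or any
#'   list with \code{chain} and \code{seq_id}.
#' @param spec an \code{\link{adduct_spec}}.
#' @param torsion requested dihedral, degrees.
#' @return an object of class \code{placed_adduct}: chain, seq_id,
#'   \code{adduct_position}, \code{parent_position}, \code{torsion},
#'   \code{clash_free}, \code{min_clearance}, \code{refined}.
#' @export
place_adduct <- function(model, site, spec = adduct_spec(), torsion = 180) {
  pos <- .reference_positions(model, site$chain, site$seq_id, spec)
  d <- place_internal(pos[[1L]], pos[[2L]], pos[[3L]],
                      spec$bond_length, spec$bond_angle, torsion)
  structure(list(chain = site$chain, seq_id = site$seq_id,
                 adduct_position = d, parent_position = pos[[3L]],
                 torsion = torsion, clash_free = NA, min_clearance = NA_real_,
                 refined = FALSE),
            class = "placed_adduct")
}

# Heavy atoms eligible for clearance checks against the adduct of one site:
# excludes atoms within two covalent bonds of the adduct (the parent atom and
# the atom it bonds to) and any atom in the same residue already carrying the
# adduct name (hypothetical methylation of an already-methylated residue is
# idempotent). Returns positions matrix and vdW radii.
.clearance_environment <- function(model, chain, seq_id, spec) {
  a <- model$atoms
  same_res <- a$chain == chain & a$seq_id == seq_id
  bonded <- same_res & a$atom %in% spec$torsion_reference[2:3]
  existing <- same_res & a$atom == spec$adduct_atom_name
  hydrogen <- toupper(a$element) == "H"
  keep <- !(bonded | existing | hydrogen)
  list(xyz = as.matrix(a[keep, c("x", "y", "z")]),
       radii = vdw_radius(a$element[keep]))
}

# Clearance (min over environment atoms of distance minus vdW-radius sum) of
# candidate adduct positions; pos is an n x 3 matrix, returns length n.
.clearances <- function(pos, env, adduct_radius) {
  if (nrow(env$xyz) == 0L) return(rep(Inf, nrow(pos)))
  out <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    d <- sqrt(rowSums(sweep(env$xyz, 2L, pos[i, ], "-")^2))
    out[i] <- min(d - (env$radii + adduct_radius))
  }
  out
}

# Adduct positions over a torsion grid for one site.
.torsion_positions <- function(model, chain, seq_id, spec, torsions) {
  pos <- .reference_positions(model, chain, seq_id, spec)
  t(vapply(torsions, function(tor)
    place_internal(pos[[1L]], pos[[2L]], pos[[3L]],
                   spec$bond_length, spec$bond_angle, tor),
    numeric(3L)))
}

# Full scan: torsion grid, positions, clearances. Shared by the public scan,
# the refinement penalty and the synthetic generator.
.torsion_scan <- function(model, chain, seq_id, spec, step) {
  torsions <- seq(-180 + step, 180, by = step)
  xyz <- .torsion_positions(model, chain, seq_id, spec, torsions)
  env <- .clearance_environment(model, chain, seq_id, spec)
  clr <- .clearances(xyz, env, vdw_radius(spec$adduct_element))
  list(torsions = torsions, xyz = xyz, clearance = clr, env = env)
}

#' Choose a clash-avoiding adduct torsion
#'
#' Scans the adduct dihedral over a full turn and returns the torsion that
#' maximizes steric clearance: the minimum, over all model heavy atoms
#' except those within two covalent bonds of the adduct, of the interatomic
#' distance minus the sum of van der Waals radii. A placement is deemed
#' clash-free when the clearance is at least \code{-overlap_cutoff} (default
#' 0.6 Angstrom of allowed vdW overlap, the conventional clash criterion).
#' Ties are broken towards the smallest torsion value, making the scan
#' deterministic.
#'
#' @inheritParams place_adduct
#' @param step torsion scan step, degrees.
#' @param overlap_cutoff allowed vdW overlap before a contact counts as a
#'   clash, Angstrom.
#' @return list with \code{torsion} (degrees), \code{clash_free} (logical)
#'   and \code{min_clearance} (Angstrom, the clearance at the chosen
#'   torsion).
#' @export
choose_clash_free_torsion <- function(model, site, spec = adduct_spec(),
                                      step = 5, overlap_cutoff = 0.6) {
  scan <- .torsion_scan(model, site$chain, site$seq_id, spec, step)
  best <- which.max(scan$clearance)   # first max = smallest torsion
  list(torsion = scan$torsions[best],
       clash_free = scan$clearance[best] >= -overlap_cutoff,
       min_clearance = scan$clearance[best])
}

# Objective for density-guided torsion refinement. The clash penalty is
# expressed in map-rms units per Angstrom of vdW overlap so the optimum is
# invariant under rescaling of the map.
.refine_objective <- function(map, pos, clearance, penalty_rms) {
  mv <- map_value_at(map, pos)
  val <- mv$value
  val[!mv$inside_grid] <- NA_real_
  val - penalty_rms * map$stats$rms * pmax(0, -clearance)
}

#' Density-guided torsion refinement
#'
#' Settles a placed adduct into local map density by maximizing
#' J(torsion) = map value at the adduct position minus a clash penalty
#' proportional to any vdW overlap. A coarse scan over the full turn is
#' followed by a local fine scan to 0.1 degree resolution. The returned
#' placement never has a lower objective than the input. This deterministic
#' one-dimensional optimization stands in for a map-weighted
#' molecular-dynamics settling step; the adduct torsion is the modification's
#' only internal degree of freedom when the rest of the model is held rigid.
#'
#' @param model an \code{atomic_model}.
#' @param placed a \code{placed_adduct} from \code{\link{place_adduct}}.
#' @param map a \code{density_map}; the adduct must lie inside it for at
#'   least one torsion.
#' @param spec an \code{\link{adduct_spec}}.
#' @param step coarse scan step, degrees.
#' @param penalty clash penalty in map-rms units per Angstrom of overlap.
#' @param overlap_cutoff allowed vdW overlap for the clash flag, Angstrom.
#' @return a \code{placed_adduct} with \code{refined = TRUE}.
#' @export
refine_torsion_against_map <- function(model, placed, map,
                                       spec = adduct_spec(), step = 5,
                                       penalty = 2, overlap_cutoff = 0.6) {
  stopifnot(inherits(placed, "placed_adduct"))
  scan <- .torsion_scan(model, placed$chain, placed$seq_id, spec, step)
  # include the input torsion among the candidates so J never decreases
  tor_in <- placed$torsion
  xyz_in <- .torsion_positions(model, placed$chain, placed$seq_id, spec, tor_in)
  clr_in <- .clearances(xyz_in, scan$env, vdw_radius(spec$adduct_element))
  tors <- c(scan$torsions, tor_in)
  objs <- c(.refine_objective(map, scan$xyz, scan$clearance, penalty),
            .refine_objective(map, xyz_in, clr_in, penalty))
  if (all(is.na(objs)))
    stop("adduct of residue ", placed$chain, placed$seq_id,
         " lies outside the map at every torsion")
  best <- which.max(ifelse(is.na(objs), -Inf, objs))
  centre <- tors[best]
  # fine scan to 0.1 degree around the coarse optimum
  fine <- seq(centre - step, centre + step, by = 0.1)
  fine <- ((fine + 180) %% 360) - 180
  fine[fine <= -180] <- fine[fine <= -180] + 360
  fxyz <- .torsion_positions(model, placed$chain, placed$seq_id, spec, fine)
  fclr <- .clearances(fxyz, scan$env, vdw_radius(spec$adduct_element))
  fobj <- .refine_objective(map, fxyz, fclr, penalty)
  cand_t <- c(fine, tor_in)
  cand_o <- ifelse(is.na(c(fobj, objs[length(objs)])), -Inf,
                   c(fobj, objs[length(objs)]))
  cand_c <- c(fclr, clr_in)
  # keep the input torsion unless a candidate improves the objective beyond
  # numerical noise (leaves flat objectives untouched)
  jmax <- max(cand_o)
  tol <- 1e-8 * (1 + abs(jmax))
  j_in <- cand_o[length(cand_o)]
  k <- if (is.finite(j_in) && j_in >= jmax - tol) length(cand_o)
       else which.max(cand_o)
  out <- place_adduct(model, placed, spec, cand_t[k])
  out$min_clearance <- cand_c[k]
  out$clash_free <- cand_c[k] >= -overlap_cutoff
  out$refined <- TRUE
  out
}

#' Add a placed adduct to a model
#'
#' Appends the adduct atom to its residue's atom records; optionally renames
#' the residue to the adduct component code.
#'
#' @param model an \code{atomic_model}.
#' @param placed a \code{placed_adduct}.
#' @param spec an \code{\link{adduct_spec}}.
#' @param rename_residue if TRUE the residue's component code is changed to
#'   \code{spec$adduct_residue_code}.
#' @return the modified \code{atomic_model}.
#' @export
add_adduct_to_model <- function(model, placed, spec = adduct_spec(),
                                rename_residue = FALSE) {
  a <- model$atoms
  rows <- .residue_rows(model, placed$chain, placed$seq_id)
  if (!length(rows)) stop("residue not found in model")
  new <- a[rows[1L], , drop = FALSE]
  new$atom <- spec$adduct_atom_name
  new$element <- spec$adduct_element
  new$x <- placed$adduct_position[1L]
  new$y <- placed$adduct_position[2L]
  new$z <- placed$adduct_position[3L]
  new$occ <- 1
  if (rename_residue) a$resname[rows] <- spec$adduct_residue_code
  last <- rows[length(rows)]
  a <- rbind(a[seq_len(last), , drop = FALSE], new,
             if (last < nrow(a)) a[(last + 1L):nrow(a), , drop = FALSE])
  atomic_model(a, model$source_format)
}
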