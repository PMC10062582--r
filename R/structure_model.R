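# Atomic model container and PDB/mmCIF input/output.
#
# The in-memory representation is deliberately flat, in the style of
# bio3d's pdb$atom table: one data.frame row per heavy atom with author
# chain/residue numbering, which is the numbering all reports use.

#' Construct an atomic model
#'
#' @param atoms data.frame with columns chain (character), seq_id (integer),
#'   resname (character, component code), atom (character, atom name),
#'   element (character, element symbol), x, y, z (Angstrom), b (B-factor),
#'   occ (occupancy in \[0,1\]).
#' @param source_format "pdb", "mmcif" or NA for models built in memory.
#' @return an object of class \code{atomic_model}.
#' @export
atomic_model <- function(atoms, source_format = NA_character_) {
  required <- c("chain", "seq_id", "resname", "atom", "element",
                "x", "y", "z", "b", "occ")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atoms table lacks columns: ", paste(missing, collapse = ", "))
  atoms <- as.data.frame(atoms)[required]
  atoms$chain <- as.character(atoms$chain)
  atoms$seq_id <- as.integer(atoms$seq_id)
  atoms$resname <- as.character(atoms$resname)
  atoms$atom <- as.character(atoms$atom)
  atoms$element <- as.character(atoms$element)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in model")
  if (any(!is.na(atoms$occ) & (atoms$occ < 0 | atoms$occ > 1)))
    stop("occupancies must lie in [0, 1]")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbols in model")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_format = source_format),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  a <- x$atoms
  keys <- unique(paste(a$chain, a$seq_id))
  cat(sprintf("<atomic_model> %d atoms, %d residues, %d chain(s)%s\n",
              nrow(a), length(keys), length(unique(a$chain)),
              if (is.na(x$source_format)) "" else paste0(" [", x$source_format, "]")))
  invisible(x)
}

#' Number of residues in a model
#' @param model an \code{atomic_model}.
#' @return integer count of distinct (chain, seq_id) pairs.
#' @export
n_residues <- function(model) {
  length(unique(paste(model$atoms$chain, model$atoms$seq_id, sep = "\r")))
}

# Rows of the atom table belonging to one residue.
.residue_rows <- function(model, chain, seq_id) {
  which(model$atoms$chain == chain & model$atoms$seq_id == seq_id)
}

# Position of a named atom in a residue, or NULL if absent.
.atom_position <- function(model, chain, seq_id, name) {
  i <- .residue_rows(model, chain, seq_id)
  i <- i[model$atoms$atom[i] == name]
  if (!length(i)) return(NULL)
  as.numeric(model$atoms[i[1L], c("x", "y", "z")])
}

.infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdb = , ent = "pdb",
         cif = , mmcif = "mmcif",
         stop("cannot infer model format from extension '.", ext,
              "'; pass format = \"pdb\" or \"mmcif\""))
}

# Derive an element symbol from a PDB atom name when the element column is
# absent; two-letter metals are right-justified in PDB names, so a name whose
# first character is alphabetic after stripping digits is taken as the symbol.
.element_from_name <- function(name) {
  s <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(s, 1L, 2L))
  ifelse(two %in% c("MG", "NA", "CL", "FE", "ZN", "MN", "BR"),
         two, toupper(substr(s, 1L, 1L)))
}

# Keep one alternate conformer per atom: highest occupancy, ties to the
# alphabetically first altloc. Operates on a bio3d-style atom table.
.resolve_altloc <- function(at) {
  alt <- at$alt
  if (is.null(alt)) return(at)
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  occ <- at$o
  occ[is.na(occ)] <- 1
  ord <- order(key, -occ, alt)
  keep <- ord[!duplicated(key[ord])]
  at[sort(keep), , drop = FALSE]
}

#' Read an atomic model from PDB or mmCIF
#'
#' Only the first model block of multi-model files is used; for atoms with
#' alternate locations the highest-occupancy conformer is kept. Hydrogens
#' are retained if present but the screen itself only uses heavy atoms.
#'
#' @param path file path.
#' @param format "pdb" or "mmcif"; inferred from the extension when NULL.
#' @return an \code{atomic_model}.
#' @export
read_model <- function(path, format = NULL) {
  if (!file.exists(path)) stop("model file does not exist: ", path)
  if (is.null(format)) format <- .infer_format(path)
  format <- match.arg(format, c("pdb", "mmcif"))
  pdb <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  }
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("zero atoms parsed from ", path)
  at <- .resolve_altloc(at)
  # bio3d::read.cif keeps mmCIF quoting around primed atom names
  elety <- gsub("^'(.*)'$", "\\1", gsub('^"(.*)"$', "\\1", at$elety))
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep("", nrow(at))
  elesy <- trimws(ifelse(is.na(elesy), "", elesy))
  elesy[!nzchar(elesy)] <- .element_from_name(elety[!nzchar(elesy)])
  occ <- at$o
  occ[is.na(occ)] <- 1
  bfac <- at$b
  bfac[is.na(bfac)] <- 0
  ch <- as.character(at$chain)
  ch[is.na(ch) | !nzchar(ch)] <- "A"
  atomic_model(data.frame(
    chain = ch, seq_id = as.integer(at$resno), resname = trimws(at$resid),
    atom = elety, element = toupper(elesy),
    x = at$x, y = at$y, z = at$z, b = bfac, occ = pmin(occ, 1),
    stringsAsFactors = FALSE), source_format = format)
}

.pdb_atom_name_field <- function(name, element) {
  ifelse(nchar(name) >= 4L, substr(name, 1L, 4L),
         ifelse(nchar(element) >= 2L,
                formatC(name, width = -4L),
                formatC(paste0(" ", name), width = -4L)))
}

.write_pdb <- function(model, path) {
  a <- model$atoms
  nm <- .pdb_atom_name_field(a$atom, a$element)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000L, nm, a$resname, substr(a$chain, 1L, 1L),
    a$seq_id, a$x, a$y, a$z, a$occ, a$b, toupper(a$element))
  writeLines(c(lines, "END"), path)
}

.cif_quote <- function(x) {
  ifelse(grepl("['\" ]", x) | !nzchar(x), paste0('"', x, '"'), x)
}

.write_mmcif <- function(model, path) {
  a <- model$atoms
  hdr <- c("data_model", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.4f %.4f %.4f %.2f %.2f %d %s %s %s 1",
    seq_len(nrow(a)), toupper(a$element), .cif_quote(a$atom), a$resname,
    a$chain, a$seq_id, a$x, a$y, a$z, a$occ, a$b, a$seq_id, a$resname,
    a$chain, .cif_quote(a$atom))
  writeLines(c(hdr, rows, "#"), path)
}

#' Write an atomic model to PDB or mmCIF
#'
#' The emitted file re-parses with \code{\link{read_model}} into an equal
#' model to format precision (1e-3 Angstrom for PDB, 1e-4 for mmCIF).
#' Adduct atoms placed by the methylation module are written with their
#' configured atom names.
#'
#' @param model an \code{atomic_model}; must be non-empty.
#' @param path output file path.
#' @param format "pdb" or "mmcif"; inferred from the extension when NULL.
#' @export
write_model <- function(model, path, format = NULL) {
  stopifnot(inherits(model, "atomic_model"))
  if (nrow(model$atoms) == 0L) stop("refusing to write an empty model")
  if (is.null(format)) format <- .infer_format(path)
  format <- match.arg(format, c("pdb", "mmcif"))
  if (format == "pdb") .write_pdb(model, path) else .write_mmcif(model, path)
  invisible(NULL)
}

#' Enumerate candidate modification sites
#'
#' Walks the model in order and returns one row per residue whose component
#' code matches the adduct specification's target codes. Residues missing a
#' required parent atom are flagged (\code{parent_atoms_present = FALSE})
#' with a reason, and are skipped by downstream placement.
#'
#' @param model an \code{atomic_model}.
#' @param spec an \code{\link{adduct_spec}}.
#' @return data.frame of class \code{candidate_sites} with columns chain,
#'   seq_id, resname, parent_atoms_present, reason_excluded.
#' @export
select_candidates <- function(model, spec = adduct_spec()) {
  a <- model$atoms
  key <- paste(a$chain, a$seq_id, sep = "\r")
  first <- !duplicated(key)
  sel <- first & (a$resname %in% spec$target_residue_codes)
  required <- unique(c(spec$parent_atom, spec$torsion_reference[1:3]))
  out <- data.frame(chain = a$chain[sel], seq_id = a$seq_id[sel],
                    resname = a$resname[sel],
                    parent_atoms_present = logical(sum(sel)),
                    reason_excluded = rep(NA_character_, sum(sel)),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    for (i in seq_len(nrow(out))) {
      have <- a$atom[key == paste(out$chain[i], out$seq_id[i], sep = "\r")]
      miss <- setdiff(required, have)
      out$parent_atoms_present[i] <- length(miss) == 0L
      if (length(miss))
        out$reason_excluded[i] <- paste("missing", paste(miss, collapse = ", "))
    }
  }
  class(out) <- c("candidate_sites", "data.frame")
  out
}
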