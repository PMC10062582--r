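# Sc_MapVal / Sc_FallOff scoring, ranking and the end-to-end screen.
#
# Sc_MapVal is the interpolated map value at the hypothetical methyl carbon.
# Sc_FallOff divides it by the map value at a probe displaced along the
# O2'->methyl bond extended to 2.4 A from the parent oxygen: genuine methyl
# density falls off along that direction (ratio > 1), while flat density or
# an adjacent unattributed blob (an ion, say) does not. Candidates are
# ranked by Sc_MapVal descending; the falloff flag uses a strict > threshold.

#' Screen configuration
#'
#' @param falloff_threshold Sc_FallOff must strictly exceed this for the
#'   falloff flag (default 1.5).
#' @param denominator_epsilon the falloff denominator is deemed unreliable
#'   (score undefined) when its magnitude is at most this fraction of the
#'   map rms; guards against near-zero map values outside the molecular
#'   envelope producing spurious huge ratios.
#' @param refine run density-guided torsion refinement before scoring.
#' @param torsion_step torsion scan step, degrees.
#' @param overlap_cutoff allowed vdW overlap before a clash is flagged,
#'   Angstrom.
#' @param refine_penalty clash penalty during refinement, map-rms units per
#'   Angstrom of overlap (keeps refinement scale-invariant).
#' @param report_top_n rows shown by print/summary; all candidates are
#'   always scored and stored.
#' @return an object of class \code{screen_config}.
#' @export
screen_config <- function(falloff_threshold = 1.5,
                          denominator_epsilon = 0.05,
                          refine = TRUE,
                          torsion_step = 5,
                          overlap_cutoff = 0.6,
                          refine_penalty = 2,
                          report_top_n = 15L) {
  if (falloff_threshold <= 0) stop("falloff_threshold must be > 0")
  if (denominator_epsilon < 0) stop("denominator_epsilon must be >= 0")
  structure(list(falloff_threshold = falloff_threshold,
                 denominator_epsilon = denominator_epsilon,
                 refine = isTRUE(refine),
                 torsion_step = torsion_step,
                 overlap_cutoff = overlap_cutoff,
                 refine_penalty = refine_penalty,
                 report_top_n = as.integer(report_top_n)),
            class = "screen_config")
}

#' Extended falloff probe position
#'
#' Prolongs the parent-to-adduct bond to the configured probe extension:
#' the probe lies on the bond line at exactly \code{spec$probe_extension}
#' Angstrom from the parent atom, beyond the adduct.
#'
#' @param placed a \code{placed_adduct}.
#' @param spec an \code{\link{adduct_spec}}.
#' @return numeric 3-vector, Angstrom.
#' @export
extended_position <- function(placed, spec = adduct_spec()) {
  v <- placed$adduct_position - placed$parent_position
  n <- .norm3(v)
  if (n < 1e-9) stop("zero-length parent-adduct bond vector")
  placed$parent_position + spec$probe_extension * (v / n)
}

#' Score one placed adduct
#'
#' Computes Sc_MapVal (map value at the adduct position) and Sc_FallOff
#' (Sc_MapVal divided by the map value at the extended probe). The falloff
#' is undefined (NA, with a note) when the denominator's magnitude is at
#' most \code{denominator_epsilon} times the map rms. Both probe positions
#' must lie inside the map.
#'
#' @param map a \code{density_map}.
#' @param placed a \code{placed_adduct}.
#' @param spec an \code{\link{adduct_spec}}.
#' @param config a \code{\link{screen_config}}.
#' @return one-row data.frame: chain, seq_id, torsion, sc_mapval,
#'   sc_falloff, probe and extended probe coordinates, notes.
#' @export
score_site <- function(map, placed, spec = adduct_spec(),
                       config = screen_config()) {
  p1 <- placed$adduct_position
  p2 <- extended_position(placed, spec)
  mv <- map_value_at(map, rbind(p1, p2))
  if (!all(mv$inside_grid))
    stop("probe position of residue ", placed$chain, placed$seq_id,
         " lies outside the map")
  v1 <- mv$value[1L]
  v2 <- mv$value[2L]
  eps <- config$denominator_epsilon * map$stats$rms
  notes <- character(0L)
  if (isFALSE(placed$clash_free)) notes <- c(notes, "clash")
  if (abs(v2) <= eps) {
    falloff <- NA_real_
    notes <- c(notes, "undefined-denominator")
  } else {
    falloff <- v1 / v2
  }
  data.frame(chain = placed$chain, seq_id = placed$seq_id,
             torsion = placed$torsion, sc_mapval = v1, sc_falloff = falloff,
             probe_x = p1[1L], probe_y = p1[2L], probe_z = p1[3L],
             ext_x = p2[1L], ext_y = p2[2L], ext_z = p2[3L],
             notes = paste(notes, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Rank scored candidates
#'
#' Sorts records by Sc_MapVal descending (ties broken by chain then seq_id
#' ascending, making the ranking total and order-independent), assigns
#' ranks 1..N, and applies the falloff criterion: \code{falloff_pass} is
#' TRUE when Sc_FallOff is defined and strictly exceeds the threshold.
#'
#' @param records data.frame of \code{\link{score_site}} rows.
#' @param config a \code{\link{screen_config}}.
#' @param excluded optional \code{candidate_sites} rows excluded upstream.
#' @param map_provenance optional provenance list echoed into the result.
#' @return an object of class \code{methyl_screen}.
#' @export
rank_sites <- function(records, config = screen_config(), excluded = NULL,
                       map_provenance = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(chain = character(0L), seq_id = integer(0L),
                          torsion = numeric(0L), sc_mapval = numeric(0L),
                          sc_falloff = numeric(0L), probe_x = numeric(0L),
                          probe_y = numeric(0L), probe_z = numeric(0L),
                          ext_x = numeric(0L), ext_y = numeric(0L),
                          ext_z = numeric(0L), notes = character(0L),
                          stringsAsFactors = FALSE)
  }
  ord <- order(-records$sc_mapval, records$chain, records$seq_id)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  records$rank <- seq_len(nrow(records))
  records$falloff_pass <- !is.na(records$sc_falloff) &
    records$sc_falloff > config$falloff_threshold
  structure(list(records = records,
                 excluded_sites = excluded,
                 config = config,
                 map_provenance = map_provenance),
            class = "methyl_screen")
}

#' Run the full modification screen
#'
#' Pipeline per candidate residue: clash-avoiding torsion selection,
#' internal-coordinate adduct placement, optional density-guided torsion
#' refinement, then Sc_MapVal / Sc_FallOff scoring; finally global ranking.
#' The model and map must already share one coordinate frame (no fitting is
#' performed). A per-site failure (missing atoms, degenerate geometry,
#' probes outside the map) excludes that site with a recorded reason rather
#' than aborting the screen. Deterministic given inputs and configuration.
#'
#' @param model an \code{atomic_model}.
#' @param map a \code{density_map}.
#' @param spec an \code{\link{adduct_spec}}.
#' @param config a \code{\link{screen_config}}.
#' @return an object of class \code{methyl_screen}: \code{records} (ranked
#'   score rows), \code{excluded_sites}, \code{config} and
#'   \code{map_provenance}.
#' @export
run_screen <- function(model, map, spec = adduct_spec(),
                       config = screen_config()) {
  stopifnot(inherits(model, "atomic_model"), inherits(map, "density_map"))
  cand <- select_candidates(model, spec)
  if (nrow(cand) == 0L)
    warning("no candidate residues with codes ",
            paste(spec$target_residue_codes, collapse = ","), " in model")
  excluded <- cand[0L, , drop = FALSE]
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    site <- cand[i, , drop = FALSE]
    if (!site$parent_atoms_present) {
      excluded <- rbind(excluded, site)
      next
    }
    res <- tryCatch({
      tor <- choose_clash_free_torsion(model, site, spec,
                                       step = config$torsion_step,
                                       overlap_cutoff = config$overlap_cutoff)
      placed <- place_adduct(model, site, spec, tor$torsion)
      placed$clash_free <- tor$clash_free
      placed$min_clearance <- tor$min_clearance
      if (config$refine)
        placed <- refine_torsion_against_map(
          model, placed, map, spec, step = config$torsion_step,
          penalty = config$refine_penalty,
          overlap_cutoff = config$overlap_cutoff)
      score_site(map, placed, spec, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      site$reason_excluded <- conditionMessage(res)
      site$parent_atoms_present <- FALSE
      excluded <- rbind(excluded, site)
    } else {
      rows[[i]] <- res
    }
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  prov <- attr(map, "source")
  prov <- c(prov, list(stats = map$stats, dim = dim(map$grid)))
  rank_sites(records, config, excluded = excluded, map_provenance = prov)
}

#' @export
print.methyl_screen <- function(x, n = NULL, ...) {
  r <- x$records
  n <- if (is.null(n)) min(nrow(r), x$config$report_top_n) else min(n, nrow(r))
  cat(sprintf("<methyl_screen> %d candidates scored, %d excluded\n",
              nrow(r), NROW(x$excluded_sites)))
  if (n > 0L) {
    show <- r[seq_len(n), c("rank", "chain", "seq_id", "torsion",
                            "sc_mapval", "sc_falloff", "falloff_pass")]
    show$torsion <- round(show$torsion, 1)
    show$sc_mapval <- signif(show$sc_mapval, 4)
    show$sc_falloff <- signif(show$sc_falloff, 4)
    print(show, row.names = FALSE)
    if (nrow(r) > n) cat(sprintf("  ... %d more rows\n", nrow(r) - n))
  }
  invisible(x)
}

#' @export
summary.methyl_screen <- function(object, ...) {
  r <- object$records
  cat(sprintf("Modification screen: %d candidates scored, %d excluded\n",
              nrow(r), NROW(object$excluded_sites)))
  if (nrow(r)) {
    cat(sprintf("Sc_MapVal range: %.4g .. %.4g\n",
                min(r$sc_mapval), max(r$sc_mapval)))
    def <- !is.na(r$sc_falloff)
    cat(sprintf("Sc_FallOff defined for %d/%d; %d pass the > %.2f criterion\n",
                sum(def), nrow(r), sum(r$falloff_pass),
                object$config$falloff_threshold))
  }
  invisible(object)
}

#' @export
as.data.frame.methyl_screen <- function(x, ...) x$records

#' @export
plot.methyl_screen <- function(x, ...) {
  r <- x$records
  if (!nrow(r)) { warning("empty screen result"); return(invisible(x)) }
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(r$rank, r$sc_mapval, xlab = "rank", ylab = "Sc_MapVal",
       main = "Map value by rank", pch = 16, cex = 0.7, ...)
  ok <- !is.na(r$sc_falloff)
  plot(r$rank[ok], r$sc_falloff[ok], xlab = "rank", ylab = "Sc_FallOff",
       main = "Falloff by rank", pch = 16, cex = 0.7,
       col = ifelse(r$falloff_pass[ok], "firebrick", "grey40"), ...)
  graphics::abline(h = x$config$falloff_threshold, lty = 2)
  invisible(x)
}

# Fixed TSV column order for screen reports.
.screen_tsv_cols <- c("chain", "seq_id", "torsion", "sc_mapval",
                      "sc_falloff", "rank", "falloff_pass", "notes")

#' Write a screen result as TSV
#'
#' One row per scored candidate, fixed column order (chain, seq_id, torsion,
#' sc_mapval, sc_falloff, rank, falloff_pass, notes). Numbers are written
#' with fixed formatting so identical screens produce byte-identical files.
#'
#' @param result a \code{methyl_screen}.
#' @param path output path.
#' @export
write_screen_tsv <- function(result, path) {
  r <- result$records
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  out <- data.frame(chain = r$chain, seq_id = r$seq_id,
                    torsion = fmt(r$torsion), sc_mapval = fmt(r$sc_mapval),
                    sc_falloff = fmt(r$sc_falloff), rank = r$rank,
                    falloff_pass = r$falloff_pass, notes = r$notes,
                    stringsAsFactors = FALSE)
  utils::write.table(out[.screen_tsv_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(NULL)
}

#' Write a screen result as JSON, including provenance
#'
#' @param result a \code{methyl_screen}.
#' @param path output path.
#' @export
write_screen_json <- function(result, path) {
  payload <- list(
    records = result$records,
    excluded_sites = if (NROW(result$excluded_sites))
      as.data.frame(result$excluded_sites) else list(),
    config = unclass(result$config),
    map_provenance = result$map_provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(NULL)
}
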