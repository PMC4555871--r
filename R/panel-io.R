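# Panel export/import: JSON sensor records and FASTA strands.

#' Export a sensor panel to JSON
#'
#' @param panel A `tgt_panel` or list of [tgt_sensor()] objects.
#' @param path File path; `.json` is conventional.
#' @export
export_panel_json <- function(panel, path) {
  recs <- lapply(panel, function(s) list(
    id = s$id,
    ligand_strand = s$ligand_strand$bases,
    ligand_modification = s$ligand_strand$modification,
    anchor_strand = s$anchor_strand$bases,
    biotin_position = s$biotin_position,
    mean_rupture_force = s$mean_rupture_force,
    rupture_mode = s$rupture_mode,
    fwhm = s$fwhm,
    np_conjugated = s$np_conjugated
  ))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Import a sensor panel from JSON
#'
#' @param path File written by [export_panel_json()].
#' @return A `tgt_panel`.
#' @export
import_panel_json <- function(path) {
  recs <- jsonlite::read_json(path)
  panel <- lapply(recs, function(r) {
    s <- tgt_sensor(r$biotin_position,
                    np_conjugated = isTRUE(r$np_conjugated),
                    rupture_mode = r$rupture_mode,
                    id = r$id)
    if (s$mean_rupture_force != r$mean_rupture_force)
      stop("JSON force does not match the position/force map", call. = FALSE)
    s
  })
  structure(panel, class = "tgt_panel")
}

#' Export panel strands to FASTA
#'
#' Two records per sensor (ligand and anchor strand); modifications are
#' encoded in the description line, never in the sequence.
#'
#' @param panel A `tgt_panel`.
#' @param path Output FASTA path.
#' @export
export_panel_fasta <- function(panel, path) {
  seqs <- character(0)
  for (s in panel) {
    nm_lig <- sprintf("%s_ligand mod=%s", s$id, s$ligand_strand$modification)
    nm_anc <- sprintf("%s_anchor mod=biotin_at_position(%d) force=%gpN",
                      s$id, s$biotin_position, s$mean_rupture_force)
    seqs[nm_lig] <- s$ligand_strand$bases
    seqs[nm_anc] <- s$anchor_strand$bases
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
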