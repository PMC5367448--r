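# PDB-format model I/O, via bio3d.  Bead models are written as CA-only
# records, one chain per component/strand; atomic PDB structures read
# with bio3d can be converted to the same particle representation, since
# at ~28 A resolution bead and atomic models render indistinguishably.

CHAIN_MAP <- data.frame(
  chain = c("A", "B", "C", "D", "E", "F"),
  component = c("actin", "actin", "tropomyosin", "tropomyosin",
                "troponin", "troponin"),
  strand = c(1L, 2L, 1L, 2L, 1L, 2L),
  stringsAsFactors = FALSE)

#' Write a filament model as a PDB file
#'
#' Particles are written as CA-only ATOM records, one chain per
#' component/strand (A/B actin, C/D tropomyosin, E/F troponin), with the
#' particle weight stored in the B-factor column and the subunit index
#' as the residue number.
#'
#' @param model A `filament_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  key <- paste(model$component, model$strand)
  mkey <- paste(CHAIN_MAP$component, CHAIN_MAP$strand)
  chain <- CHAIN_MAP$chain[match(key, mkey)]
  xyz <- as.numeric(t(model_coords(model)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = model$subunit_index,
                   resid = rep("ALA", nrow(model)),
                   chain = chain,
                   elety = rep("CA", nrow(model)),
                   b = model$weight,
                   o = rep(1, nrow(model)))
  invisible(path)
}

#' Read a PDB file as a filament model
#'
#' Chains are mapped back to components with the same convention used by
#' [write_model_pdb()]; unknown chains are imported as component
#' `"other"`.  For atomic structures (no weights in B), a unit weight
#' per atom is used.
#'
#' @param path Path to a PDB file.
#' @param params Optional [helical_params()] to attach.
#' @param use_b_weights Take particle weights from the B-factor column
#'   (the convention of [write_model_pdb()]).
#' @return A `filament_model`.
#' @export
read_model_pdb <- function(path, params = helical_params(),
                           use_b_weights = TRUE) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  m <- match(at$chain, CHAIN_MAP$chain)
  comp <- ifelse(is.na(m), "other", CHAIN_MAP$component[m])
  strand <- ifelse(is.na(m), 1L, CHAIN_MAP$strand[m])
  w <- if (use_b_weights && !all(is.na(at$b)) && any(at$b > 0)) at$b
       else rep(1, nrow(at))
  df <- data.frame(
    x = at$x, y = at$y, z = at$z, weight = w,
    component = comp, strand = as.integer(strand),
    subunit_index = as.integer(at$resno),
    subunit_label = NA_character_, residue_tag = NA_character_,
    in_unit = FALSE, stringsAsFactors = FALSE)
  new_filament_model(df, params)
}

#' Write per-subunit fit results as TSV
#'
#' @param fits Data frame from [fit_all_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits_tsv <- function(fits, path) {
  out <- data.frame(strand = fits$strand, subunit = fits$subunit_label,
                    azimuth_deg = fits$azimuth, axial_A = fits$axial_shift,
                    radial_A = fits$radial_shift, score = fits$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fits TSV written by [write_fits_tsv()]
#' @param path Path to the TSV.
#' @return Data frame in [fit_all_segments()] column layout.
#' @export
read_fits_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(subunit_label = x$subunit, strand = x$strand,
             azimuth = x$azimuth_deg, axial_shift = x$axial_A,
             radial_shift = x$radial_A, score = x$score,
             stringsAsFactors = FALSE)
}
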