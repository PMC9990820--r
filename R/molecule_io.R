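#' Read/write aligned molecules as a CSV atom table
#'
#' The native plain-text exchange format for field calculations: one row
#' per atom with columns `mol_id, element, x, y, z, charge, radius,
#' hydrophobicity, hbd, hba` (property columns optional on read).
#'
#' @param path file path.
#' @param molecules named list of [molecule3d()].
#' @return `read_molecules_csv()` returns a named list of `molecule3d`
#'   (in first-appearance order).
#' @export
read_molecules_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mol_id" %in% names(raw)) stop("missing `mol_id` column",
                                      call. = FALSE)
  ids <- unique(raw$mol_id)
  mols <- lapply(ids, function(id) {
    molecule3d(raw[raw$mol_id == id, setdiff(names(raw), "mol_id"),
                   drop = FALSE])
  })
  stats::setNames(mols, ids)
}

#' @rdname read_molecules_csv
#' @export
write_molecules_csv <- function(molecules, path) {
  if (is.null(names(molecules))) {
    names(molecules) <- paste0("mol", seq_along(molecules))
  }
  rows <- lapply(names(molecules), function(id) {
    df <- as.data.frame(molecules[[id]])
    cbind(mol_id = id, df)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read molecules from an SDF file
#'
#' Uses ChemmineR to parse the structure blocks; coordinates and
#' element symbols come from the atom block, formal charges from the
#' parsed molecule, and van der Waals radii from the element lookup.
#' Hydrophobicity and donor/acceptor flags are not encoded in plain SDF
#' and default to zero; supply them via the CSV atom-table format when
#' they matter.
#'
#' @param path SDF file path.
#' @return Named list of [molecule3d()].
#' @export
read_sdf_molecules <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading SDF requires the ChemmineR package", call. = FALSE)
  }
  sdfs <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdfs)
  mols <- lapply(seq_along(sdfs), function(i) {
    ab <- ChemmineR::atomblock(sdfs[[i]])
    element <- sub("_.*$", "", rownames(ab))
    molecule3d(data.frame(element = element,
                          x = ab[, 1], y = ab[, 2], z = ab[, 3]))
  })
  stats::setNames(mols, make.unique(ids))
}

#' Read molecules from a MOL2 file
#'
#' Uses bio3d to parse the Tripos MOL2 atom records; partial charges
#' come from the charge column and the element is derived from the
#' SYBYL atom type (the part before the dot).
#'
#' @param path MOL2 file path.
#' @return Named list of [molecule3d()].
#' @export
read_mol2_molecules <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading MOL2 requires the bio3d package", call. = FALSE)
  }
  m <- bio3d::read.mol2(path)
  if (!is.list(m) || !is.null(m$atom)) m <- list(m)
  mols <- lapply(m, function(one) {
    at <- one$atom
    molecule3d(data.frame(
      element = sub("\\..*$", "", at$elety),
      x = at$x, y = at$y, z = at$z,
      charge = if (!is.null(at$charge)) at$charge else 0))
  })
  ids <- vapply(m, function(one) {
    if (!is.null(one$name) && length(one$name)) one$name[1] else NA_character_
  }, character(1))
  ids[is.na(ids)] <- paste0("mol", which(is.na(ids)))
  stats::setNames(mols, make.unique(ids))
}
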