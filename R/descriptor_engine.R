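#' Descriptor matrices
#'
#' A descriptor matrix is a numeric matrix with compounds in rows
#' (rownames = compound ids) and named descriptor columns, as produced by
#' cheminformatics descriptor calculators.  Values must be finite after
#' cleaning; [clean_descriptors()] drops columns containing missing
#' values and near-constant columns, mirroring how descriptor-selection
#' software discards uninformative descriptors before screening.
#'
#' @param values numeric matrix or data.frame, compounds x descriptors.
#' @param names optional descriptor names (defaults to column names).
#' @param compound_ids optional compound ids (defaults to row names).
#' @return A numeric matrix with dimnames set.
#' @export
descriptor_matrix <- function(values, names = NULL, compound_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(names)) colnames(values) <- names
  if (!is.null(compound_ids)) rownames(values) <- compound_ids
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("D", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) {
    stop("descriptor names must be unique", call. = FALSE)
  }
  values
}

#' @param D descriptor matrix.
#' @param max_rel_sd columns whose standard deviation is below
#'   `max_rel_sd * (1 + |mean|)` are treated as constant and dropped.
#' @rdname descriptor_matrix
#' @export
clean_descriptors <- function(D, max_rel_sd = 1e-10) {
  has_na <- apply(D, 2, function(x) any(!is.finite(x)))
  if (any(has_na)) {
    message("dropping ", sum(has_na), " descriptor(s) with missing values: ",
            paste(utils::head(colnames(D)[has_na], 5), collapse = ", "))
    D <- D[, !has_na, drop = FALSE]
  }
  sds <- apply(D, 2, stats::sd)
  mus <- colMeans(D)
  const <- sds < max_rel_sd * (1 + abs(mus))
  if (any(const)) {
    message("dropping ", sum(const), " near-constant descriptor(s)")
    D <- D[, !const, drop = FALSE]
  }
  if (ncol(D) == 0) stop("no descriptors left after cleaning", call. = FALSE)
  D
}

#' Read/write descriptor matrices as CSV
#'
#' First column = compound id, remaining header = descriptor names.
#' @param path file path.
#' @param D descriptor matrix.
#' @export
read_descriptors <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  descriptor_matrix(raw[, -1, drop = FALSE], compound_ids = raw[[1]])
}

#' @rdname read_descriptors
#' @export
write_descriptors <- function(D, path) {
  df <- data.frame(id = rownames(D), D, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pearson correlation matrix of selected descriptors
#'
#' @param D descriptor matrix.
#' @param subset descriptor names to correlate (default: all).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(D, subset = colnames(D)) {
  missing_cols <- setdiff(subset, colnames(D))
  if (length(missing_cols)) {
    stop("unknown descriptors: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- D[, subset, drop = FALSE]
  if (nrow(X) < 2) stop("need at least 2 compounds", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant descriptor column(s): ",
         paste(subset[sds == 0], collapse = ", "),
         " (correlation undefined)", call. = FALSE)
  }
  R <- stats::cor(X)
  diag(R) <- 1
  R
}

#' Screen a descriptor subset for collinearity
#'
#' A subset passes when every off-diagonal pairwise |r| is strictly below
#' `threshold` (default 0.8, the conventional multicollinearity bound for
#' descriptor-selection models).
#'
#' @inheritParams correlation_matrix
#' @param threshold maximum tolerated absolute pairwise correlation.
#' @return A list with `pass` (logical), `max_abs_r`, and `offending`
#'   (data.frame of violating pairs: `name1`, `name2`, `r`).
#' @export
collinearity_screen <- function(D, subset = colnames(D), threshold = 0.8) {
  R <- correlation_matrix(D, subset)
  off <- which(upper.tri(R) & abs(R) >= threshold, arr.ind = TRUE)
  offending <- data.frame(
    name1 = rownames(R)[off[, 1]],
    name2 = colnames(R)[off[, 2]],
    r = R[off],
    stringsAsFactors = FALSE
  )
  max_abs <- if (length(R) > 1) max(abs(R[upper.tri(R)]), 0) else 0
  list(pass = nrow(offending) == 0, max_abs_r = max_abs, offending = offending)
}

#' Molecular-orbital coefficient sets
#'
#' Per-atom HOMO (highest occupied molecular orbital) coefficients used to
#' compute Fukui-type reactivity indices.  Stored as parallel vectors of
#' atom ids and element labels plus a list of numeric coefficient vectors
#' (one vector per atom; an atom may contribute several basis-function
#' coefficients).
#'
#' @param atom_id character vector of unique atom ids.
#' @param element character vector of element symbols, one per atom.
#' @param coefficients list of numeric vectors, one per atom.
#' @return An object of class `mo_set`.
#' @export
mo_set <- function(atom_id, element, coefficients) {
  atom_id <- as.character(atom_id)
  if (anyDuplicated(atom_id)) stop("atom ids must be unique", call. = FALSE)
  if (length(element) != length(atom_id) ||
      length(coefficients) != length(atom_id)) {
    stop("`element` and `coefficients` must align with `atom_id`",
         call. = FALSE)
  }
  coefficients <- lapply(coefficients, as.numeric)
  ok <- vapply(coefficients,
               function(x) length(x) >= 1 && all(is.finite(x)), logical(1))
  if (!all(ok)) {
    stop("every atom needs >= 1 finite HOMO coefficient", call. = FALSE)
  }
  structure(list(atom_id = atom_id, element = as.character(element),
                 coefficients = coefficients),
            class = "mo_set")
}

#' Fukui nucleophilic reactivity index
#'
#' The nucleophilic reactivity index of an atom set A is
#' `N_A = sum over atoms in A of sum(C_i^HOMO ^ 2)`: the summed squares of
#' the HOMO coefficients on those atoms.  Large values mark sites that are
#' susceptible to electrophilic attack.  Indices are dimensionless and
#' non-negative, invariant to coefficient sign, and additive over disjoint
#' atom subsets.
#'
#' @param mo an [mo_set()].
#' @param atom_subset atom ids to sum over (non-empty).
#' @return A single non-negative number.
#' @export
#' @examples
#' m <- mo_set(c("O1", "O2"), c("O", "O"), list(c(0.1, 0.2), 0.5))
#' nucleophilic_reactivity_index(m, c("O1", "O2"))  # 0.30
nucleophilic_reactivity_index <- function(mo, atom_subset) {
  stopifnot(inherits(mo, "mo_set"))
  atom_subset <- as.character(atom_subset)
  if (length(atom_subset) == 0) stop("`atom_subset` is empty", call. = FALSE)
  idx <- match(atom_subset, mo$atom_id)
  if (anyNA(idx)) {
    stop("unknown atom id(s): ",
         paste(atom_subset[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sum(vapply(mo$coefficients[idx], function(cc) sum(cc^2), numeric(1)))
}

#' Per-atom reactivity indices
#'
#' @inheritParams nucleophilic_reactivity_index
#' @return Named numeric vector, one index per atom.
#' @export
atom_reactivity_indices <- function(mo) {
  stopifnot(inherits(mo, "mo_set"))
  stats::setNames(
    vapply(mo$coefficients, function(cc) sum(cc^2), numeric(1)),
    mo$atom_id
  )
}

#' Minimum reactivity index over atoms of one element
#'
#' Descriptors such as "minimum nucleophilic reactivity index for an O
#' atom" take the smallest per-atom index among atoms of the given
#' element.
#'
#' @inheritParams nucleophilic_reactivity_index
#' @param element element symbol, e.g. `"O"`.
#' @export
min_index_over_element <- function(mo, element) {
  stopifnot(inherits(mo, "mo_set"))
  sel <- mo$element == element
  if (!any(sel)) stop("no atoms of element ", element, call. = FALSE)
  min(atom_reactivity_indices(mo)[sel])
}

#' Read/write MO coefficient sets as JSON
#'
#' JSON layout: an array of `{atom_id, element, coefficients: [...]}`.
#' @param path file path.
#' @param mo an `mo_set`.
#' @export
read_mo_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  mo_set(
    atom_id = vapply(raw, `[[`, character(1), "atom_id"),
    element = vapply(raw, `[[`, character(1), "element"),
    coefficients = lapply(raw, function(a) unlist(a$coefficients))
  )
}

#' @rdname read_mo_set
#' @export
write_mo_set <- function(mo, path) {
  out <- lapply(seq_along(mo$atom_id), function(i) {
    list(atom_id = mo$atom_id[i], element = mo$element[i],
         coefficients = mo$coefficients[[i]])
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
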