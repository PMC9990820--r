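#' Compound activity tables
#'
#' A compound table is a plain `data.frame` (class `"compound_table"`) with
#' one row per compound and columns `id`, `ic50_nM`, and optionally
#' `activity` (the log-transformed scale used for modelling) and `split`
#' (`"train"`, `"test"` or `"unassigned"`).
#'
#' @param id character vector of unique compound labels (e.g. `"19g"`).
#' @param ic50_nM positive numeric vector of IC50 values in nanomolar.
#' @param activity optional numeric vector of transformed activities.
#' @param split optional character vector of split labels.
#' @return A `compound_table` data.frame.
#' @seealso [transform_activity()], [split_table()], [quinazoline_ic50()]
#' @export
#' @examples
#' compound_table(c("a", "b"), c(10, 1000))
compound_table <- function(id, ic50_nM, activity = NULL, split = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("compound ids must be unique; duplicated: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(ic50_nM) || length(ic50_nM) != length(id)) {
    stop("`ic50_nM` must be numeric, one value per id", call. = FALSE)
  }
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("IC50 values must be finite and strictly positive (nM)", call. = FALSE)
  }
  if (is.null(split)) split <- rep("unassigned", length(id))
  split <- as.character(split)
  bad <- setdiff(unique(split), c("train", "test", "unassigned"))
  if (length(bad)) {
    stop("invalid split labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(split) != length(id)) {
    stop("`split` must have one label per compound", call. = FALSE)
  }
  tab <- data.frame(id = id, ic50_nM = as.numeric(ic50_nM),
                    activity = if (is.null(activity)) NA_real_ else activity,
                    split = split, stringsAsFactors = FALSE)
  class(tab) <- c("compound_table", "data.frame")
  tab
}

#' Transform IC50 (nM) to the modelling activity scale
#'
#' Computes `-log10(IC50) + 9` for IC50 given in nanomolar.  This is the
#' standard pIC50 transform: reading the concentration in molar,
#' `pIC50 = -log10(IC50[M]) = -log10(IC50[nM] * 1e-9) = -log10(IC50[nM]) + 9`,
#' so an IC50 of 1 nM maps to 9.  The log scale stabilises the spread of
#' potencies that range over several orders of magnitude.
#'
#' @param ic50_nM positive numeric vector, IC50 in nM.
#' @return Numeric vector of transformed activities (pIC50 units).
#' @export
#' @examples
#' transform_activity(c(1, 1000, 0.55))
transform_activity <- function(ic50_nM) {
  if (!is.numeric(ic50_nM) || length(ic50_nM) == 0) {
    stop("`ic50_nM` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("IC50 values must be finite and strictly positive", call. = FALSE)
  }
  -log10(ic50_nM) + 9
}

# run `expr` under a private RNG stream; global .Random.seed is restored
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Assign train/test split labels to a compound table
#'
#' Draws a seeded random split.  The training-set size is
#' `floor(ratio_train * n)`, clamped so that both splits contain at
#' least one compound.  A 4:1 split (`ratio_train = 0.8`) of 37
#' compounds therefore yields 29 train and 8 test.
#'
#' @param table a [compound_table()].
#' @param ratio_train training fraction, strictly between 0 and 1.
#' @param seed integer seed; the same seed always reproduces the same split.
#' @return The table with `split` filled in.
#' @export
split_table <- function(table, ratio_train = 0.8, seed) {
  n <- nrow(table)
  if (n < 2) stop("need at least 2 compounds to split", call. = FALSE)
  if (!is.numeric(ratio_train) || ratio_train <= 0 || ratio_train >= 1) {
    stop("`ratio_train` must be in (0, 1)", call. = FALSE)
  }
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  n_train <- floor(ratio_train * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_train))
  table$split <- "test"
  table$split[idx] <- "train"
  table
}

#' The 37-compound quinazoline FGFR4-inhibitor activity table
#'
#' IC50 values (nM) for a published series of 37 quinazoline derivatives
#' assayed against FGFR4-driven osteosarcoma cells.  Ships with the
#' package as a plain-text fixture.  The `test_set_3d` column records
#' which 8 compounds were held out as the external test set of the
#' original 3D-QSAR experiment; the original 2D split used an
#' unrecorded system-time seed and is not reproducible, so fresh splits
#' must be drawn with [split_table()].  Molecular structures are not
#' included (the source prints them only as drawings).
#'
#' @param transform if `TRUE` (default) the `activity` column is filled
#'   with [transform_activity()] values.
#' @return A `compound_table` with 37 rows and a logical
#'   `test_set_3d` column.
#' @export
#' @examples
#' tab <- quinazoline_ic50()
#' tab[tab$id == "19g", ]
quinazoline_ic50 <- function(transform = TRUE) {
  path <- system.file("extdata", "quinazoline_ic50.csv", package = "qsarpipe",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- compound_table(raw$id, raw$ic50_nM)
  if (transform) tab$activity <- transform_activity(tab$ic50_nM)
  tab$test_set_3d <- as.logical(raw$test_set_3d)
  tab
}

#' Read / write compound tables as CSV
#'
#' Column layout: `id, ic50_nM, activity, split` (extra columns are
#' preserved on read).
#'
#' @param path file path.
#' @param table a `compound_table`.
#' @return `read_compound_table()` returns a `compound_table`;
#'   `write_compound_table()` returns `path` invisibly.
#' @export
read_compound_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "ic50_nM")
  if (!all(need %in% names(raw))) {
    stop("compound CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- compound_table(raw$id, raw$ic50_nM,
                        activity = if ("activity" %in% names(raw)) raw$activity,
                        split = if ("split" %in% names(raw)) raw$split)
  extra <- setdiff(names(raw), names(tab))
  for (col in extra) tab[[col]] <- raw[[col]]
  tab
}

#' @rdname read_compound_table
#' @export
write_compound_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
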