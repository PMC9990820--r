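# van der Waals radii (Angstrom) used when a structure file carries none
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
               S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

COMSIA_PROPERTIES <- c("steric", "electrostatic", "hydrophobic", "hbd", "hba")

#' 3D molecules for field calculations
#'
#' A `molecule3d` is a data.frame of atoms with columns `element`,
#' `x`, `y`, `z` (Angstrom), `charge` (partial charge, e), `radius`
#' (van der Waals, Angstrom), `hydrophobicity` (dimensionless atomic
#' hydrophobicity), and 0/1 flags `hbd`, `hba` (hydrogen-bond
#' donor/acceptor).  Molecules entering field calculations must already
#' be aligned onto a common template ([align_to_template()] provides a
#' rigid-body least-squares fit).
#'
#' @param atoms data.frame with at least `element`, `x`, `y`, `z`;
#'   missing property columns get defaults (charge 0, element vdW
#'   radius, hydrophobicity 0, flags 0).
#' @return A `molecule3d` data.frame.
#' @export
molecule3d <- function(atoms) {
  atoms <- as.data.frame(atoms)
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$radius)) {
    atoms$radius <- unname(VDW_RADII[atoms$element])
    atoms$radius[is.na(atoms$radius)] <- 1.70
  }
  if (any(!is.finite(atoms$radius)) || any(atoms$radius <= 0)) {
    stop("atom radii must be positive", call. = FALSE)
  }
  if (is.null(atoms$hydrophobicity)) atoms$hydrophobicity <- 0
  if (is.null(atoms$hbd)) atoms$hbd <- 0
  if (is.null(atoms$hba)) atoms$hba <- 0
  class(atoms) <- c("molecule3d", "data.frame")
  atoms
}

atom_coords <- function(mol) as.matrix(mol[, c("x", "y", "z")])

#' Rectangular lattice enclosing a set of aligned molecules
#'
#' Builds an axis-aligned grid at the given spacing extending `margin`
#' Angstrom beyond the union of all atoms on every side (defaults: 2 A
#' spacing, 4 A margin, the conventional CoMSIA region settings).
#'
#' @param molecules non-empty list of [molecule3d()].
#' @param spacing lattice spacing, Angstrom.
#' @param margin padding beyond the atom bounding box, Angstrom.
#' @return A `grid_spec`: list with `origin`, `spacing`, `npts`
#'   (points per axis), `margin`.
#' @export
build_grid <- function(molecules, spacing = 2, margin = 4) {
  if (length(molecules) == 0) stop("empty molecule set", call. = FALSE)
  stopifnot(spacing > 0, margin >= 0)
  xyz <- do.call(rbind, lapply(molecules, atom_coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  npts <- pmax(1L, as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L)
  structure(list(origin = lo, spacing = spacing, npts = npts,
                 margin = margin),
            class = "grid_spec")
}

#' Grid point coordinates
#' @param grid a `grid_spec` (or a numeric matrix of points, returned
#'   unchanged).
#' @return Numeric matrix, n_points x 3, x varying fastest.
#' @export
grid_points <- function(grid) {
  if (is.matrix(grid)) return(grid)
  stopifnot(inherits(grid, "grid_spec"))
  ax <- lapply(1:3, function(d) {
    grid$origin[d] + grid$spacing * (seq_len(grid$npts[d]) - 1L)
  })
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

# per-atom weight for one CoMSIA property type
property_weights <- function(mol, property) {
  switch(property,
         steric = mol$radius^3,
         electrostatic = mol$charge,
         hydrophobic = mol$hydrophobicity,
         hbd = as.numeric(mol$hbd),
         hba = as.numeric(mol$hba),
         stop("unknown property: ", property, call. = FALSE))
}

#' CoMSIA similarity field of one molecule
#'
#' Distance-dependent Gaussian similarity index at grid point q:
#' `A(q) = -sum_atoms w_probe * w_atom * exp(-attenuation * r_aq^2)`,
#' with the property weight `w_atom` equal to radius^3 (steric), partial
#' charge (electrostatic), atomic hydrophobicity, or the donor/acceptor
#' flag, and a unit probe (`w_probe = 1` for every property).  The
#' Gaussian form needs no energy cut-off and behaves smoothly at lattice
#' points close to atoms.
#'
#' @param mol a [molecule3d()].
#' @param grid a `grid_spec` or a points matrix.
#' @param property one of `"steric"`, `"electrostatic"`,
#'   `"hydrophobic"`, `"hbd"`, `"hba"`.
#' @param attenuation Gaussian attenuation factor alpha, 1/Angstrom^2
#'   (0.3 is the conventional CoMSIA value).
#' @param probe probe weight (1 by default for all properties).
#' @return Numeric vector of field values, one per grid point.
#' @export
similarity_field <- function(mol, grid, property, attenuation = 0.3,
                             probe = 1) {
  stopifnot(attenuation > 0)
  property <- match.arg(property, COMSIA_PROPERTIES)
  P <- grid_points(grid)
  A <- atom_coords(mol)
  w <- property_weights(mol, property)
  d2 <- outer(rowSums(P^2), rowSums(A^2), "+") - 2 * (P %*% t(A))
  d2[d2 < 0] <- 0  # numerical guard
  -drop(exp(-attenuation * d2) %*% w) * probe
}

#' Assemble the molecule x field-column block
#'
#' Computes all five (by default) CoMSIA property fields for every
#' molecule on a shared grid and stacks them into one matrix of
#' n_molecules x (n_gridpoints * n_properties) with column metadata.
#'
#' @param molecules list of [molecule3d()].
#' @param grid a `grid_spec` (built with [build_grid()] if omitted).
#' @param properties property types to include.
#' @param attenuation Gaussian attenuation, see [similarity_field()].
#' @return A `field_block`: list with `values` (matrix), `meta`
#'   (data.frame: `column`, `property`, `point`, `x`, `y`, `z`),
#'   `grid`, `attenuation`, and `block_scales` (NULL until scaled).
#' @export
field_block <- function(molecules, grid = NULL,
                        properties = COMSIA_PROPERTIES,
                        attenuation = 0.3) {
  if (is.null(grid)) grid <- build_grid(molecules)
  properties <- match.arg(properties, COMSIA_PROPERTIES, several.ok = TRUE)
  P <- grid_points(grid)
  np <- nrow(P)
  blocks <- lapply(properties, function(pr) {
    t(vapply(molecules,
             function(m) similarity_field(m, P, pr, attenuation),
             numeric(np)))
  })
  values <- do.call(cbind, blocks)
  meta <- data.frame(
    column = seq_len(ncol(values)),
    property = rep(properties, each = np),
    point = rep(seq_len(np), length(properties)),
    x = rep(P[, 1], length(properties)),
    y = rep(P[, 2], length(properties)),
    z = rep(P[, 3], length(properties)),
    stringsAsFactors = FALSE)
  colnames(values) <- paste0(meta$property, "_", meta$point)
  structure(list(values = values, meta = meta, grid = grid,
                 attenuation = attenuation, block_scales = NULL),
            class = "field_block")
}

#' CoMFA-style block scaling
#'
#' Rescales each property block so every block carries the same total
#' column variance; without this, field-contribution fractions are
#' dominated by whichever property happens to have the largest raw
#' scale.  The applied scales are stored so new molecules can be
#' processed identically at prediction time.
#'
#' @param F a [field_block()].
#' @param scales optional named vector of precomputed per-property
#'   scales (used at prediction time).
#' @return The scaled `field_block`.
#' @export
block_scale <- function(F, scales = NULL) {
  props <- unique(F$meta$property)
  if (is.null(scales)) {
    scales <- vapply(props, function(pr) {
      cols <- F$meta$property == pr
      tv <- sum(apply(F$values[, cols, drop = FALSE], 2, stats::var))
      if (tv > 0) 1 / sqrt(tv) else 1
    }, numeric(1))
  }
  for (pr in props) {
    cols <- F$meta$property == pr
    F$values[, cols] <- F$values[, cols, drop = FALSE] * scales[[pr]]
  }
  F$block_scales <- scales
  F
}

#' Drop low-variance field columns
#'
#' Removes columns whose standard deviation across molecules is below
#' `min_sd` (lattice points far from any atom, or identical in every
#' molecule, carry no information and inflate the PLS problem).
#'
#' @param F a [field_block()].
#' @param min_sd minimum column standard deviation to keep.
#' @return The filtered `field_block`.
#' @export
column_filter <- function(F, min_sd = 0.05) {
  sds <- apply(F$values, 2, stats::sd)
  keep <- sds >= min_sd
  if (!any(keep)) stop("column filter removed every field column; ",
                       "lower `min_sd`", call. = FALSE)
  F$values <- F$values[, keep, drop = FALSE]
  F$meta <- F$meta[keep, , drop = FALSE]
  F
}

# select columns of F by meta$column ids (prediction-time alignment)
select_columns <- function(F, column_ids) {
  idx <- match(column_ids, F$meta$column)
  if (anyNA(idx)) stop("field block does not contain the model's columns",
                       call. = FALSE)
  F$values <- F$values[, idx, drop = FALSE]
  F$meta <- F$meta[idx, , drop = FALSE]
  F
}

# NIPALS PLS1: returns regression vectors for every component count
pls1_nipals <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  a <- 0
  for (c in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # residual X carries no covariance with y
    w <- w / nw
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pp <- drop(crossprod(Xc, tt)) / tt2
    qq <- sum(yc * tt) / tt2
    Xc <- Xc - tcrossprod(tt, pp)
    yc <- yc - qq * tt
    W[, c] <- w; P[, c] <- pp; q[c] <- qq
    a <- c
  }
  if (a == 0) stop("PLS failed: X has no covariance with y", call. = FALSE)
  # B_c = W_c (P_c' W_c)^-1 q_c for each component count c
  B <- matrix(0, p, a)
  for (c in seq_len(a)) {
    Wc <- W[, 1:c, drop = FALSE]; Pc <- P[, 1:c, drop = FALSE]
    B[, c] <- Wc %*% solve(crossprod(Pc, Wc), q[1:c])
  }
  list(B = B, x_means = xm, y_mean = ym, ncomp = a)
}

pls1_predict <- function(fit, X, comp) {
  drop(sweep(X, 2, fit$x_means) %*% fit$B[, comp]) + fit$y_mean
}

#' PLS regression on a field block with LOO component selection
#'
#' Fits NIPALS partial least squares of the activity on the field
#' columns.  For every component count up to `max_components` the
#' leave-one-out cross-validated `q2(c) = 1 - PRESS(c)/TSS` is computed
#' from n full refits; the optimum number of components (ONC) maximises
#' q2.  The final, non-validated model at the ONC reports `r2`,
#' `SEE = sqrt(RSS/(n - ONC - 1))`, the F statistic, and per-property
#' field contributions (normalised sums of |coefficient x column SD|
#' within each property block).
#'
#' @param F a [field_block()] (typically block-scaled and
#'   column-filtered; see [prepare_fields()]).
#' @param y numeric activity vector.
#' @param max_components largest component count to try.
#' @return An object of class `pls_model`: `n_components`, `q2`,
#'   `q2_by_component`, `r2`, `see`, `f_stat`, `coefficients`,
#'   `intercept` terms (`x_means`, `y_mean`), `contributions`,
#'   `fitted`, `meta`.
#' @export
fit_pls <- function(F, y, max_components = 10) {
  X <- F$values
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal the number of molecules",
                           call. = FALSE)
  if (stats::sd(y) == 0) stop("degenerate activity: y is constant",
                              call. = FALSE)
  if (n < max_components + 2) {
    stop("need n >= max_components + 2 molecules", call. = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  full <- pls1_nipals(X, y, max_components)
  ncomp <- full$ncomp
  press <- numeric(ncomp)
  for (i in seq_len(n)) {
    fi <- pls1_nipals(X[-i, , drop = FALSE], y[-i], ncomp)
    for (c in seq_len(ncomp)) {
      cc <- min(c, fi$ncomp)
      pred <- pls1_predict(fi, X[i, , drop = FALSE], cc)
      press[c] <- press[c] + (y[i] - pred)^2
    }
  }
  q2 <- 1 - press / tss
  onc <- which.max(q2)
  B <- full$B[, onc]
  fitted <- pls1_predict(full, X, onc)
  rss <- sum((y - fitted)^2)
  r2 <- 1 - rss / tss
  see <- sqrt(rss / (n - onc - 1))
  f_stat <- (r2 / max(1 - r2, .Machine$double.eps)) * (n - onc - 1) / onc
  sds <- apply(X, 2, stats::sd)
  contrib_raw <- tapply(abs(B * sds), F$meta$property, sum)
  contributions <- contrib_raw / sum(contrib_raw)
  structure(list(
    n_components = onc, q2 = q2[onc], q2_by_component = q2,
    r2 = r2, see = see, f_stat = f_stat,
    coefficients = stats::setNames(B, colnames(X)),
    x_means = full$x_means, y_mean = full$y_mean,
    contributions = contributions,
    fitted = fitted, n = n,
    meta = F$meta
  ), class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  F <- if (inherits(newdata, "field_block")) {
    select_columns(newdata, object$meta$column)
  } else {
    stop("`newdata` must be a field_block", call. = FALSE)
  }
  drop(sweep(F$values, 2, object$x_means) %*% object$coefficients) +
    object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS field model: ONC = %d  q2 = %.3f  r2 = %.3f  SEE = %.4g  F = %.2f\n",
              x$n_components, x$q2, x$r2, x$see, x$f_stat))
  cat("field contributions:\n")
  print(round(x$contributions, 3))
  invisible(x)
}

#' Block-scale and variance-filter a field block
#'
#' Convenience preprocessing applied before [fit_pls()]: CoMFA-style
#' block scaling followed by the low-variance column filter.
#'
#' @inheritParams column_filter
#' @export
prepare_fields <- function(F, min_sd = 0.05) {
  column_filter(block_scale(F), min_sd = min_sd)
}

#' Fit a CoMSIA model directly from aligned molecules
#'
#' Wraps grid construction, field calculation, preprocessing and PLS
#' into one call, and remembers everything needed to score new
#' molecules on the same footing (grid, attenuation, block scales,
#' retained columns).
#'
#' @param molecules list of aligned [molecule3d()].
#' @param y activity vector (transformed scale).
#' @param spacing,margin grid geometry, Angstrom.
#' @param attenuation Gaussian attenuation factor.
#' @param properties CoMSIA property types to include.
#' @param min_sd column filter threshold (after block scaling).
#' @param max_components largest PLS component count to try.
#' @return A `comsia_model` wrapping the `pls_model` (also inherits its
#'   fields) plus the preprocessing state.
#' @export
fit_comsia <- function(molecules, y, spacing = 2, margin = 4,
                       attenuation = 0.3, properties = COMSIA_PROPERTIES,
                       min_sd = 0.05, max_components = 10) {
  grid <- build_grid(molecules, spacing = spacing, margin = margin)
  F_raw <- field_block(molecules, grid, properties = properties,
                       attenuation = attenuation)
  F <- prepare_fields(F_raw, min_sd = min_sd)
  pls <- fit_pls(F, y, max_components = max_components)
  structure(c(pls, list(grid = grid, attenuation = attenuation,
                        properties = properties,
                        block_scales = F$block_scales,
                        fields = F)),
            class = c("comsia_model", "pls_model"))
}

#' @export
predict.comsia_model <- function(object, newdata, ...) {
  if (inherits(newdata, "field_block")) {
    return(NextMethod())
  }
  F_new <- field_block(newdata, object$grid,
                       properties = object$properties,
                       attenuation = object$attenuation)
  F_new <- block_scale(F_new, scales = object$block_scales)
  F_new <- select_columns(F_new, object$meta$column)
  drop(sweep(F_new$values, 2, object$x_means) %*% object$coefficients) +
    object$y_mean
}

#' STDEV*COEFF contour maps
#'
#' For each property type, the contour value of a retained lattice
#' point is `sd(column) * coefficient` from the fitted PLS model.
#' Points above the `upper_pct` percentile of that property's values
#' are favorable (activity rises with the field there), points below
#' the `lower_pct` percentile are unfavorable; the two sets are
#' disjoint.
#'
#' @param model a fitted `pls_model` / `comsia_model`.
#' @param F the prepared [field_block()] the model was fitted on (for a
#'   `comsia_model` it defaults to the stored block).
#' @param upper_pct,lower_pct percentile thresholds (defaults 80/20).
#' @return A `contour_map`: named list per property, each a list with
#'   `favorable` and `unfavorable` data.frames (`point`, `x`, `y`,
#'   `z`, `value`) and the two `thresholds`.
#' @export
contour_map <- function(model, F = NULL, upper_pct = 80, lower_pct = 20) {
  if (is.null(F)) {
    if (is.null(model$fields)) stop("supply the fitted field block `F`",
                                    call. = FALSE)
    F <- model$fields
  }
  stopifnot(upper_pct > lower_pct)
  sds <- apply(F$values, 2, stats::sd)
  v <- unname(model$coefficients) * sds
  out <- list()
  for (pr in unique(F$meta$property)) {
    sel <- F$meta$property == pr
    if (!any(sel)) {
      warning("no retained columns for property ", pr)
      next
    }
    vp <- v[sel]
    thr <- stats::quantile(vp, c(lower_pct, upper_pct) / 100,
                           names = FALSE)
    fav <- sel & v > thr[2]
    unf <- sel & v < thr[1]
    mk <- function(mask) {
      data.frame(point = F$meta$point[mask], x = F$meta$x[mask],
                 y = F$meta$y[mask], z = F$meta$z[mask],
                 value = v[mask], stringsAsFactors = FALSE)
    }
    out[[pr]] <- list(favorable = mk(fav), unfavorable = mk(unf),
                      thresholds = c(lower = thr[1], upper = thr[2]))
  }
  structure(out, class = "contour_map")
}

#' Export contour points as a PDB-style pseudo-atom file
#'
#' Favorable points are written as pseudo-atoms named `FAV`,
#' unfavorable as `UNF`, one chain per property, so the maps can be
#' opened in any molecular viewer.
#'
#' @param map a [contour_map()].
#' @param path output file.
#' @export
write_contour_pdb <- function(map, path) {
  lines <- character()
  serial <- 0L
  for (pr in names(map)) {
    for (cls in c("favorable", "unfavorable")) {
      df <- map[[pr]][[cls]]
      if (nrow(df) == 0) next
      for (i in seq_len(nrow(df))) {
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, if (cls == "favorable") "FAV" else "UNF",
          toupper(substr(pr, 1, 3)), serial,
          df$x[i], df$y[i], df$z[i], 1.0, abs(df$value[i]), "X"))
      }
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Rigid-body least-squares alignment onto a template
#'
#' Kabsch superposition: finds the rotation + translation minimising the
#' RMSD between mapped atom pairs and applies it to the whole molecule.
#'
#' @param mol molecule to move.
#' @param template reference [molecule3d()].
#' @param atom_map two-column integer matrix of (mol atom, template
#'   atom) index pairs; defaults to matching atoms 1..min(n) in order.
#' @return The transformed `molecule3d`.
#' @export
align_to_template <- function(mol, template, atom_map = NULL) {
  if (is.null(atom_map)) {
    k <- min(nrow(mol), nrow(template))
    atom_map <- cbind(seq_len(k), seq_len(k))
  }
  P <- atom_coords(mol)[atom_map[, 1], , drop = FALSE]
  Q <- atom_coords(template)[atom_map[, 2], , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  S <- svd(crossprod(sweep(P, 2, pc), sweep(Q, 2, qc)))
  d <- sign(det(S$v %*% t(S$u)))
  R <- S$v %*% diag(c(1, 1, d)) %*% t(S$u)
  XYZ <- sweep(atom_coords(mol), 2, pc) %*% t(R)
  XYZ <- sweep(XYZ, 2, qc, "+")
  mol$x <- XYZ[, 1]; mol$y <- XYZ[, 2]; mol$z <- XYZ[, 3]
  mol
}
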