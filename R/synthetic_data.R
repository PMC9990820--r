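#' Synthetic descriptor set with a planted linear signal
#'
#' Generates a compounds x descriptors matrix plus an activity vector
#' obeying a known linear model, for exercising descriptor selection
#' end to end.  Descriptor columns are independent draws (standard
#' normal by default; `"lognormal"` mimics strictly positive
#' reactivity-index-like descriptors).  The activity is
#' `X[, names(coefficients)] %*% coefficients + N(0, noise_sd^2)`.
#' With the default coefficients (3, -2, 1) the default `noise_sd` of
#' 1.25 places the planted signal at R2 ~ 0.9, the quality regime of
#' realistic well-fitting QSAR models.
#'
#' @param n_compounds,n_descriptors design size.
#' @param coefficients named numeric vector of planted coefficients;
#'   names must be among the generated column names `D1..Dk`.
#' @param noise_sd Gaussian noise standard deviation on the activity.
#' @param seed integer seed; output is a pure function of the arguments.
#' @param dist `"normal"` or `"lognormal"` column distribution.
#' @return List with `descriptors` (matrix), `activity` (vector), and
#'   `truth` (planted coefficients, informative column names,
#'   `noise_sd`).
#' @export
gen_descriptor_set <- function(n_compounds = 40, n_descriptors = 103,
                               coefficients = c(D1 = 3, D2 = -2, D3 = 1),
                               noise_sd = 1.25, seed = 1,
                               dist = c("normal", "lognormal")) {
  dist <- match.arg(dist)
  stopifnot(noise_sd >= 0, n_compounds >= 2, n_descriptors >= 1)
  cols <- paste0("D", seq_len(n_descriptors))
  if (!all(names(coefficients) %in% cols)) {
    stop("planted model references missing column(s): ",
         paste(setdiff(names(coefficients), cols), collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_compounds * n_descriptors),
                n_compounds, n_descriptors, dimnames = list(
                  paste0("cmpd", seq_len(n_compounds)), cols))
    if (dist == "lognormal") X <- exp(X)
    y <- drop(X[, names(coefficients), drop = FALSE] %*% coefficients) +
      stats::rnorm(n_compounds, sd = noise_sd)
    list(descriptors = X, activity = y,
         truth = list(coefficients = coefficients,
                      informative = names(coefficients),
                      noise_sd = noise_sd))
  })
}

#' Synthetic data from a planted symbolic expression
#'
#' Draws uniform inputs and evaluates a planted expression over the
#' `+ - * / cos` alphabet, for exercising symbolic-regression recovery.
#'
#' @param expression expression string, e.g. `"2*x + cos(z)"`.
#' @param n number of rows.
#' @param variables variable names (= columns of the output matrix).
#' @param noise_sd Gaussian noise standard deviation.
#' @param range length-2 numeric: uniform sampling range of every
#'   variable.
#' @param seed integer seed.
#' @return List with `X` (matrix), `y`, and `truth` (the canonical
#'   expression string).  A constant expression yields zero-variance
#'   `y` and a warning.
#' @export
gen_symbolic_set <- function(expression, n = 200, variables = c("x", "z"),
                             noise_sd = 0, range = c(-3, 3), seed = 1) {
  stopifnot(noise_sd >= 0, n >= 1, length(variables) >= 1)
  expr <- tryCatch(parse(text = expression)[[1]],
                   error = function(e) stop("cannot parse expression: ",
                                            expression, call. = FALSE))
  used_funs <- setdiff(all.names(expr), all.vars(expr))
  allowed <- c("+", "-", "*", "/", "cos", "(")
  if (!all(used_funs %in% allowed)) {
    stop("expression uses unsupported function(s): ",
         paste(setdiff(used_funs, allowed), collapse = ", "), call. = FALSE)
  }
  if (!all(all.vars(expr) %in% variables)) {
    stop("expression references unknown variable(s): ",
         paste(setdiff(all.vars(expr), variables), collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    X <- matrix(stats::runif(n * length(variables), range[1], range[2]),
                n, length(variables), dimnames = list(NULL, variables))
    y <- eval(expr, as.data.frame(X)) + stats::rnorm(n, sd = noise_sd)
    y <- rep_len(y, n)
    if (stats::sd(y) == 0) warning("planted expression yields constant y")
    list(X = X, y = y, truth = list(expression = expression))
  })
}

#' Synthetic aligned molecule series with a planted pharmacophore site
#'
#' Emulates a pre-aligned congeneric series: every molecule shares a
#' rigid scaffold (identical atom positions up to a small jitter) plus
#' one variable substituent site.  The site's partial charge varies
#' across molecules and drives the activity linearly
#' (`activity = effect * charge + N(0, noise_sd^2)`); site
#' hydrophobicity and donor/acceptor flags vary too but carry no
#' signal.  The default noise of 0.05 activity units against a uniform
#' (-0.5, 0.5) e charge spread keeps the planted field signal in the
#' clearly detectable regime that a well-behaved CoMSIA study assumes.
#'
#' @param n_molecules number of molecules.
#' @param n_scaffold scaffold atoms per molecule (besides the site).
#' @param effect linear effect of site charge on activity.
#' @param noise_sd activity noise standard deviation.
#' @param jitter_sd coordinate jitter (Angstrom), default 0.02,
#'   bounded well under alignment accuracy.
#' @param seed integer seed.
#' @return List with `molecules` (named list of [molecule3d()]),
#'   `activity`, and `truth` (`site_position`, `effect`,
#'   `site_charges`, `noise_sd`).
#' @export
gen_aligned_molecules <- function(n_molecules = 20, n_scaffold = 8,
                                  effect = 1, noise_sd = 0.05,
                                  jitter_sd = 0.02, seed = 1) {
  stopifnot(n_molecules >= 2, n_scaffold >= 2, noise_sd >= 0,
            jitter_sd >= 0, jitter_sd <= 0.1)
  with_seed(seed, {
    scaffold <- cbind(x = stats::runif(n_scaffold, -3, 3),
                      y = stats::runif(n_scaffold, -3, 3),
                      z = stats::runif(n_scaffold, -3, 3))
    scaffold_charge <- stats::runif(n_scaffold, -0.2, 0.2)
    site <- c(x = 4, y = 0, z = 0)  # substituent position off the scaffold
    q <- stats::runif(n_molecules, -0.5, 0.5)
    mols <- lapply(seq_len(n_molecules), function(i) {
      xyz <- rbind(scaffold, site) +
        matrix(stats::rnorm(3 * (n_scaffold + 1), sd = jitter_sd),
               ncol = 3)
      molecule3d(data.frame(
        element = c(rep("C", n_scaffold), "O"),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        charge = c(scaffold_charge, q[i]),
        hydrophobicity = c(rep(0.5, n_scaffold), stats::runif(1, -1, 1)),
        hbd = c(rep(0, n_scaffold), stats::rbinom(1, 1, 0.5)),
        hba = c(rep(0, n_scaffold), 1)))
    })
    names(mols) <- paste0("mol", seq_len(n_molecules))
    activity <- effect * q + stats::rnorm(n_molecules, sd = noise_sd)
    list(molecules = mols, activity = activity,
         truth = list(site_position = site, effect = effect,
                      site_charges = q, noise_sd = noise_sd))
  })
}

#' Synthetic MO coefficient sets with known reactivity indices
#'
#' Builds per-atom HOMO coefficient vectors whose sums of squares equal
#' prescribed target indices, so the minimum-over-element index is
#' known by construction.
#'
#' @param indices named numeric vector of target per-atom indices
#'   (names become atom ids).
#' @param elements element symbol per atom.
#' @param n_coeff coefficients per atom.
#' @param seed integer seed.
#' @return An [mo_set()] whose [atom_reactivity_indices()] equal
#'   `indices` exactly (up to floating point).
#' @export
gen_mo_coefficients <- function(indices, elements, n_coeff = 3, seed = 1) {
  stopifnot(length(indices) == length(elements), all(indices >= 0),
            n_coeff >= 1)
  if (is.null(names(indices))) {
    names(indices) <- paste0(elements, seq_along(indices))
  }
  with_seed(seed, {
    coefs <- lapply(indices, function(s) {
      v <- stats::rnorm(n_coeff)
      if (s == 0) return(rep(0, n_coeff))
      v * sqrt(s / sum(v^2))
    })
    mo_set(names(indices), elements, coefs)
  })
}
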