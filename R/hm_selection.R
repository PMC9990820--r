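#' Ordinary least squares with QSAR model statistics
#'
#' Fits `y ~ X` with an intercept and reports the statistics used by
#' CODESSA-style heuristic descriptor selection: R2, the F statistic
#' `F = [R2/(1-R2)] * [(n-k-1)/k]`, the squared standard error
#' `s2 = RSS/(n-k-1)`, and per-coefficient t values
#' (coefficient / standard error, with standard errors from
#' `(X'X)^-1 s2`).
#'
#' @param X numeric matrix of descriptors (n x k, named columns).
#' @param y numeric response of length n.
#' @return An object of class `hm_linear_model`: list with
#'   `descriptor_names`, `coefficients` (named, excluding intercept),
#'   `intercept`, `r2`, `f_stat`, `s2`, `t_values`, `r2_cv` (`NA` until
#'   filled by [loo_r2cv()] callers), `n`, `k`, `fitted`, `residuals`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n <= k + 1) stop("need n > k + 1 observations", call. = FALSE)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("degenerate response: y is constant (TSS = 0)",
                     call. = FALSE)
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    dep <- colnames(Xi)[qr_x$pivot[(qr_x$rank + 1):ncol(Xi)]]
    stop("rank-deficient design; linearly dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  coef_all <- qr.coef(qr_x, y)
  fitted <- drop(Xi %*% coef_all)
  resid <- y - fitted
  rss <- sum(resid^2)
  r2 <- 1 - rss / tss
  s2 <- rss / (n - k - 1)
  f_stat <- (r2 / max(1 - r2, .Machine$double.eps)) * (n - k - 1) / k
  xtx_inv <- chol2inv(qr.R(qr_x))
  se_all <- sqrt(pmax(diag(xtx_inv), 0) * s2)
  t_all <- ifelse(se_all > 0, coef_all / se_all, sign(coef_all) * Inf)
  structure(list(
    descriptor_names = colnames(X),
    coefficients = coef_all[-1],
    intercept = unname(coef_all[1]),
    r2 = r2, f_stat = f_stat, s2 = s2,
    t_values = t_all[-1],
    r2_cv = NA_real_,
    n = n, k = k,
    fitted = fitted, residuals = resid,
    tss = tss, rss = rss
  ), class = "hm_linear_model")
}

#' @export
predict.hm_linear_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$descriptor_names, drop = FALSE]
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
print.hm_linear_model <- function(x, ...) {
  cat("Linear QSAR model:", length(x$descriptor_names), "descriptor(s)\n")
  cat("  ", paste(x$descriptor_names, collapse = " + "), "\n")
  cat(sprintf("  R2 = %.4f  F = %.3f  s2 = %.4g  R2cv = %s\n",
              x$r2, x$f_stat, x$s2,
              if (is.na(x$r2_cv)) "NA" else sprintf("%.4f", x$r2_cv)))
  invisible(x)
}

#' Heuristic-method fitness function
#'
#' Composite score used to rank candidate regressions while growing the
#' descriptor set: `w = R2 * F * n / (N * s2)`, with `n` the number of
#' training samples and `N` the number of candidate descriptors.  Larger
#' is better; an exact fit (`s2 = 0`) returns `Inf` with a warning.
#'
#' @param model an `hm_linear_model`.
#' @param n number of samples (defaults to the model's).
#' @param N number of descriptors in the candidate pool.
#' @export
fitness_w <- function(model, n = model$n, N) {
  if (model$s2 == 0) {
    warning("perfect fit (s2 = 0): fitness is infinite")
    return(Inf)
  }
  model$r2 * model$f_stat * n / (N * model$s2)
}

#' Leave-one-out cross-validated R2
#'
#' `R2cv = 1 - PRESS/TSS`, with PRESS the sum of squared leave-one-out
#' prediction errors.  Computed via the hat-matrix identity
#' `e_(i) = e_i / (1 - h_ii)`, which is algebraically identical to n
#' separate refits.
#'
#' @inheritParams fit_ols
#' @return A single number (at most 1; can be negative).
#' @export
loo_r2cv <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 2) stop("need n > k + 2 for leave-one-out", call. = FALSE)
  fit <- fit_ols(X, y)
  Xi <- cbind(1, X)
  h <- diag(Xi %*% chol2inv(qr.R(qr(Xi))) %*% t(Xi))
  press <- sum((fit$residuals / (1 - h))^2)
  1 - press / fit$tss
}

#' Configuration for the heuristic descriptor search
#'
#' @param max_descriptors largest model size to grow to.
#' @param beam_width number of models retained per size ("the optimal 10
#'   correlation results" convention).
#' @param one_param_r2_floor minimum single-descriptor R2 to survive the
#'   pre-screen.
#' @param t_floor minimum single-descriptor |t| to survive the pre-screen.
#'   Set to 0 to disable (recommended when weak-but-real descriptors are
#'   expected; see the methods vignette).
#' @param collinearity_threshold maximum |r| allowed between any two
#'   descriptors in one model.
#' @export
hm_config <- function(max_descriptors = 8, beam_width = 10,
                      one_param_r2_floor = 0.01, t_floor = 1.5,
                      collinearity_threshold = 0.8) {
  stopifnot(max_descriptors >= 1, beam_width >= 1,
            one_param_r2_floor >= 0, t_floor >= 0,
            collinearity_threshold > 0)
  structure(list(max_descriptors = max_descriptors, beam_width = beam_width,
                 one_param_r2_floor = one_param_r2_floor, t_floor = t_floor,
                 collinearity_threshold = collinearity_threshold),
            class = "hm_config")
}

#' Heuristic-method descriptor selection (stepwise beam search)
#'
#' CODESSA-style heuristic multiple linear regression: (a) screen
#' descriptors one at a time, dropping those below the R2 / |t| floors;
#' (b) fit all surviving pairs and rank them by R2; (c) grow the best
#' models one descriptor at a time, scoring candidates by the composite
#' fitness [fitness_w()] and skipping additions whose pairwise |r| with
#' an included descriptor reaches the collinearity threshold, until
#' `max_descriptors`.  The top `beam_width` models of every size are
#' retained and annotated with leave-one-out R2cv.
#'
#' @param D descriptor matrix (should be pre-cleaned; see
#'   [clean_descriptors()]).
#' @param y numeric activity vector.
#' @param config an [hm_config()].
#' @return An object of class `hm_result`: list with `by_size` (list of
#'   model lists, ranked within each size), `survivors` (names passing
#'   the pre-screen), and `config`.
#' @export
hm_search <- function(D, y, config = hm_config()) {
  D <- clean_descriptors(descriptor_matrix(D))
  n <- nrow(D)
  if (length(y) != n) stop("length(y) must equal nrow(D)", call. = FALSE)

  # (a) one-parameter screen
  singles <- lapply(colnames(D), function(nm) fit_ols(D[, nm, drop = FALSE], y))
  names(singles) <- colnames(D)
  keep <- vapply(singles, function(m) {
    m$r2 >= config$one_param_r2_floor && abs(m$t_values[1]) >= config$t_floor
  }, logical(1))
  survivors <- colnames(D)[keep]
  if (length(survivors) == 0) {
    stop("no descriptor passed the one-parameter screen; ",
         "lower `one_param_r2_floor` / `t_floor`", call. = FALSE)
  }
  R <- suppressWarnings(stats::cor(D[, survivors, drop = FALSE]))

  rank_top <- function(models, score, width) {
    models[order(-score)][seq_len(min(width, length(models)))]
  }
  by_size <- list()
  s1 <- singles[survivors]
  by_size[["1"]] <- rank_top(s1, vapply(s1, `[[`, numeric(1), "r2"),
                             config$beam_width)

  if (config$max_descriptors >= 2 && length(survivors) >= 2) {
    # (b) all admissible pairs, ranked by R2
    pairs <- utils::combn(survivors, 2, simplify = FALSE)
    pairs <- Filter(function(p) abs(R[p[1], p[2]]) < config$collinearity_threshold,
                    pairs)
    if (length(pairs)) {
      pm <- lapply(pairs, function(p) fit_ols(D[, p, drop = FALSE], y))
      by_size[["2"]] <- rank_top(pm, vapply(pm, `[[`, numeric(1), "r2"),
                                 config$beam_width)
    }
  }

  # (c) beam extension scored by the fitness function
  N_pool <- length(survivors)
  size <- 3
  while (size <= config$max_descriptors &&
         !is.null(by_size[[as.character(size - 1)]])) {
    beam <- by_size[[as.character(size - 1)]]
    cand <- list(); cand_w <- numeric(); seen <- character()
    for (m in beam) {
      for (nm in setdiff(survivors, m$descriptor_names)) {
        if (max(abs(R[nm, m$descriptor_names])) >= config$collinearity_threshold)
          next
        key <- paste(sort(c(m$descriptor_names, nm)), collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        fit <- tryCatch(
          fit_ols(D[, c(m$descriptor_names, nm), drop = FALSE], y),
          error = function(e) NULL)
        if (is.null(fit)) next
        cand[[length(cand) + 1L]] <- fit
        cand_w[length(cand)] <- suppressWarnings(fitness_w(fit, N = N_pool))
      }
    }
    if (length(cand) == 0) break
    by_size[[as.character(size)]] <- rank_top(cand, cand_w, config$beam_width)
    size <- size + 1
  }

  for (s in names(by_size)) {
    by_size[[s]] <- lapply(by_size[[s]], function(m) {
      m$r2_cv <- tryCatch(
        loo_r2cv(D[, m$descriptor_names, drop = FALSE], y),
        error = function(e) NA_real_)
      m
    })
  }
  structure(list(by_size = by_size, survivors = survivors, config = config),
            class = "hm_result")
}

#' Best model of a given size from a heuristic search
#'
#' @param result an `hm_result`.
#' @param size model size (number of descriptors); default: the largest
#'   size reached.
#' @export
best_model <- function(result, size = NULL) {
  stopifnot(inherits(result, "hm_result"))
  sizes <- as.integer(names(result$by_size))
  if (is.null(size)) size <- max(sizes)
  m <- result$by_size[[as.character(size)]]
  if (is.null(m)) stop("no models of size ", size, call. = FALSE)
  m[[1]]
}

#' @export
print.hm_result <- function(x, ...) {
  for (s in names(x$by_size)) {
    top <- x$by_size[[s]][[1]]
    cat(sprintf("size %s: best R2 = %.4f (%s)\n", s, top$r2,
                paste(top$descriptor_names, collapse = ", ")))
  }
  invisible(x)
}

#' Reference linear 2D-QSAR model for the quinazoline series
#'
#' The published heuristic-method linear model relating three
#' quantum-chemical descriptors to log IC50 for the 37-compound
#' quinazoline FGFR4-inhibitor series:
#'
#' `logIC50 = 1.5952e3 * x - 1.1630e2 * y + 2.5642e4 * z - 0.75167`
#'
#' where `x` is the average electrophilic reactivity index for a C atom
#' (Avg-ERC), `y` the HA-dependent HDSA-2/TMSA quantum-chemical surface
#' descriptor, and `z` the minimum nucleophilic reactivity index for an
#' O atom (Min-NRO).  The positive Min-NRO coefficient is the design
#' rule exploited for new compounds: lowering the most nucleophilic
#' oxygen's index lowers predicted IC50 (raises potency).
#'
#' @param avg_erc,hdsa2_tmsa,min_nro descriptor values (vectorised).
#' @return Predicted log IC50.
#' @export
#' @examples
#' ref_linear_model(0, 0, 0)  # intercept: -0.75167
ref_linear_model <- function(avg_erc, hdsa2_tmsa, min_nro) {
  stopifnot(is.numeric(avg_erc), is.numeric(hdsa2_tmsa), is.numeric(min_nro))
  1.5952e3 * avg_erc - 1.1630e2 * hdsa2_tmsa + 2.5642e4 * min_nro - 7.5167e-1
}
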