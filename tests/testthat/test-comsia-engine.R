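test_that("grid construction honours spacing/margin and translation covariance", {
  mol <- tiny_molecule()
  g <- build_grid(list(mol), spacing = 2, margin = 4)
  expect_equal(g$npts, c(5L, 5L, 5L))
  P <- grid_points(g)
  expect_equal(range(P[, 1]), c(-4, 4))
  expect_equal(nrow(P), 125)

  # translating the molecules translates the grid by the same vector
  t_vec <- c(1.3, -2.1, 0.7)
  mol2 <- mol
  mol2$x <- mol2$x + t_vec[1]; mol2$y <- mol2$y + t_vec[2]
  mol2$z <- mol2$z + t_vec[3]
  g2 <- build_grid(list(mol2), spacing = 2, margin = 4)
  expect_equal(grid_points(g2), sweep(P, 2, t_vec, "+"),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(build_grid(list()), "empty")
})

test_that("similarity field matches the closed form -w * exp(-alpha r^2)", {
  mol <- tiny_molecule(radius = 1)
  # grid point at the atom: steric weight r^3 = 1, exp(0) = 1
  expect_equal(similarity_field(mol, matrix(0, 1, 3), "steric",
                                attenuation = 0.3), -1, tolerance = 1e-12)
  # distance 1, alpha = 0.3
  expect_equal(similarity_field(mol, matrix(c(1, 0, 0), 1, 3), "steric",
                                attenuation = 0.3),
               -exp(-0.3), tolerance = 1e-10)
  # electrostatic uses the partial charge as weight
  molq <- tiny_molecule(charge = -0.4)
  expect_equal(similarity_field(molq, matrix(c(0, 2, 0), 1, 3),
                                "electrostatic", attenuation = 0.3),
               0.4 * exp(-0.3 * 4), tolerance = 1e-10)
  expect_error(similarity_field(mol, matrix(0, 1, 3), "magnetic"),
               "should be one of")
})

test_that("fields are additive over atoms", {
  a1 <- tiny_molecule(matrix(c(0, 0, 0), 1), charge = 0.3, radius = 1.2,
                      hydro = 0.5, hbd = 1)
  a2 <- tiny_molecule(matrix(c(1.5, -1, 2), 1), charge = -0.2, radius = 1.7,
                      hydro = -0.3, hba = 1)
  both <- molecule3d(rbind(as.data.frame(a1), as.data.frame(a2)))
  P <- matrix(runif(30, -3, 3), 10, 3)
  for (pr in c("steric", "electrostatic", "hydrophobic", "hbd", "hba")) {
    expect_equal(similarity_field(both, P, pr),
                 similarity_field(a1, P, pr) + similarity_field(a2, P, pr),
                 tolerance = 1e-12)
  }
})

test_that("column filter drops exactly the flat columns", {
  am <- gen_aligned_molecules(n_molecules = 8, seed = 4)
  F <- field_block(am$molecules, build_grid(am$molecules, 2, 2))
  sds <- apply(F$values, 2, sd)
  Ff <- column_filter(F, min_sd = 0)
  expect_equal(ncol(Ff$values), ncol(F$values))  # min_sd = 0 is identity
  Ff2 <- column_filter(F, min_sd = 0.01)
  expect_equal(ncol(Ff2$values), sum(sds >= 0.01))
  expect_error(column_filter(F, min_sd = 1e9), "every field column")

  # planted construction: 10 informative columns among zero-variance decoys
  Fc <- F
  keep10 <- order(-sds)[1:10]
  Fc$values[, -keep10] <- 0
  Fc2 <- column_filter(Fc, min_sd = 1e-9)
  expect_equal(ncol(Fc2$values), 10)
})

test_that("PLS recovers an exact rank-two linear response", {
  set.seed(31)
  n <- 15; p <- 40
  # X of exact rank 2: two latent score vectors times loadings
  t1 <- rnorm(n); t2 <- rnorm(n)
  X <- tcrossprod(t1, rnorm(p)) + tcrossprod(t2, rnorm(p))
  F <- fake_field_block(X)
  y <- 2 + t1 - 0.5 * t2
  model <- fit_pls(F, y, max_components = 5)
  expect_gte(model$r2, 1 - 1e-8)
  expect_lte(model$n_components, 2)
  # fitted values equal predictions on the training block
  expect_equal(predict(model, F), model$fitted, tolerance = 1e-10)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(1)
  n <- 15; p <- 30
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  y <- drop(X %*% rnorm(p) * 0.2) + rnorm(n, sd = 0.3)
  fit <- qsarpipe:::pls1_nipals(X, y, 3)
  for (c in 1:3) {
    mo <- mixOmics::pls(X, y, ncomp = c, mode = "regression", scale = FALSE)
    ref <- predict(mo, X)$predict[, 1, c]
    expect_equal(unname(qsarpipe:::pls1_predict(fit, X, c)), unname(ref),
                 tolerance = 1e-10)
  }
})

test_that("LOO q2 equals an explicit n-loop refit oracle", {
  am <- gen_aligned_molecules(n_molecules = 12, seed = 9)
  F <- prepare_fields(field_block(am$molecules), min_sd = 0.01)
  y <- am$activity
  max_c <- 4
  model <- fit_pls(F, y, max_components = max_c)
  X <- F$values
  tss <- sum((y - mean(y))^2)
  press <- numeric(max_c)
  for (i in seq_len(nrow(X))) {
    fi <- qsarpipe:::pls1_nipals(X[-i, , drop = FALSE], y[-i], max_c)
    for (c in seq_len(max_c)) {
      pred <- qsarpipe:::pls1_predict(fi, X[i, , drop = FALSE],
                                      min(c, fi$ncomp))
      press[c] <- press[c] + (y[i] - pred)^2
    }
  }
  expect_equal(model$q2_by_component, 1 - press / tss, tolerance = 1e-8)
  # ONC maximises q2 by construction
  expect_equal(model$q2, max(model$q2_by_component))
})

test_that("field contributions are a simplex and electrostatics dominates the planted fixture", {
  am <- gen_aligned_molecules(seed = 13)
  model <- fit_comsia(am$molecules, am$activity, max_components = 5)
  expect_equal(sum(model$contributions), 1, tolerance = 1e-9)
  expect_true(all(model$contributions >= 0))
  # activity was planted in the site charge: electrostatic field leads
  expect_equal(names(which.max(model$contributions)), "electrostatic")
  expect_gt(model$q2, 0.5)
})

test_that("predictions are consistent and duplicate molecules score identically", {
  am <- gen_aligned_molecules(n_molecules = 14, seed = 23)
  model <- fit_comsia(am$molecules, am$activity, max_components = 5)
  pred_train <- predict(model, am$molecules)
  expect_equal(pred_train, model$fitted, tolerance = 1e-10)
  dup <- am$molecules[c(3, 3)]
  pd <- predict(model, dup)
  expect_equal(pd[1], pd[2], tolerance = 1e-12)
})

test_that("model statistics are invariant under a common rigid rotation", {
  am <- gen_aligned_molecules(n_molecules = 12, seed = 37)
  grid <- build_grid(am$molecules)
  P <- grid_points(grid)
  y <- am$activity

  fit_on <- function(mols, points) {
    F <- prepare_fields(field_block(mols, points), min_sd = 0.01)
    fit_pls(F, y, max_components = 4)
  }
  base <- fit_on(am$molecules, P)

  theta <- 0.83
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  rot_mols <- lapply(am$molecules, function(m) {
    XYZ <- as.matrix(m[, c("x", "y", "z")]) %*% t(R)
    m$x <- XYZ[, 1]; m$y <- XYZ[, 2]; m$z <- XYZ[, 3]
    m
  })
  rot <- fit_on(rot_mols, P %*% t(R))
  expect_equal(rot$q2, base$q2, tolerance = 1e-8)
  expect_equal(rot$r2, base$r2, tolerance = 1e-8)
  expect_equal(rot$see, base$see, tolerance = 1e-8)
})

test_that("contour maps localise the planted charge hotspot", {
  # similarity indices are negative-sensed (-sum w exp(-ar^2)), so a site
  # whose charge RAISES activity carries a negative field coefficient and
  # lands in the lower STDEV*COEFF tail; planting a negative effect puts
  # the hotspot in the favorable (upper-tail) contour.
  am <- gen_aligned_molecules(n_molecules = 16, effect = -1, noise_sd = 0,
                              seed = 3)
  model <- fit_comsia(am$molecules, am$activity, max_components = 4)
  map <- contour_map(model)
  fav <- map$electrostatic$favorable
  unf <- map$electrostatic$unfavorable
  expect_gt(nrow(fav), 0)
  # favorable and unfavorable sets are disjoint
  expect_length(intersect(fav$point, unf$point), 0)
  # the site sits at (4, 0, 0): some favorable electrostatic point lies
  # within one lattice spacing of it
  d <- sqrt((fav$x - 4)^2 + fav$y^2 + fav$z^2)
  expect_lte(min(d), 2)

  # and with a positive effect the same site shows in the opposite tail
  am2 <- gen_aligned_molecules(n_molecules = 16, effect = 1, noise_sd = 0,
                               seed = 3)
  model2 <- fit_comsia(am2$molecules, am2$activity, max_components = 4)
  unf2 <- contour_map(model2)$electrostatic$unfavorable
  d2 <- sqrt((unf2$x - 4)^2 + unf2$y^2 + unf2$z^2)
  expect_lte(min(d2), 2)

  # degenerate model: all-zero coefficients give empty contours
  zero <- model
  zero$coefficients[] <- 0
  mz <- contour_map(zero, model$fields)
  expect_equal(nrow(mz$electrostatic$favorable), 0)
  expect_equal(nrow(mz$electrostatic$unfavorable), 0)
})

test_that("Kabsch alignment undoes a rigid motion", {
  am <- gen_aligned_molecules(n_molecules = 2, seed = 8)
  mol <- am$molecules[[1]]
  theta <- 0.6
  R <- matrix(c(cos(theta), 0, sin(theta), 0, 1, 0,
                -sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
  moved <- mol
  XYZ <- as.matrix(mol[, c("x", "y", "z")]) %*% t(R)
  moved$x <- XYZ[, 1] + 3; moved$y <- XYZ[, 2] - 1; moved$z <- XYZ[, 3] + 2
  back <- align_to_template(moved, mol)
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
               as.matrix(mol[, c("x", "y", "z")]), tolerance = 1e-8)
})

test_that("contour PDB export writes one pseudo-atom per contour point", {
  am <- gen_aligned_molecules(n_molecules = 10, seed = 44)
  model <- fit_comsia(am$molecules, am$activity, max_components = 3)
  map <- contour_map(model)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_contour_pdb(map, path)
  lines <- readLines(path)
  n_pts <- sum(vapply(map, function(p) {
    nrow(p$favorable) + nrow(p$unfavorable)
  }, numeric(1)))
  expect_equal(sum(startsWith(lines, "HETATM")), n_pts)
  expect_equal(tail(lines, 1), "END")
})
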