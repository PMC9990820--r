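# Shared test fixtures, all generated in code.

# tiny aligned-molecule pair for field tests
tiny_molecule <- function(xyz = matrix(0, 1, 3), charge = 0, radius = 1,
                          hydro = 0, hbd = 0, hba = 0, element = "C") {
  molecule3d(data.frame(element = element,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        charge = charge, radius = radius,
                        hydrophobicity = hydro, hbd = hbd, hba = hba))
}

# brute-force leave-one-out R2cv: n independent refits (the oracle)
brute_force_r2cv <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    fit <- fit_ols(X[-i, , drop = FALSE], y[-i])
    pred <- predict(fit, X[i, , drop = FALSE])
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# default GEP config for small, fast test runs
small_gep_config <- function(max_generations = 20, ...) {
  gep_config(terminals = c("x", "z"), head_length = 6, n_genes = 2,
             population_size = 30, max_generations = max_generations,
             seed = 1, ...)
}

# field-block-shaped object with prescribed values, for PLS unit tests
fake_field_block <- function(values, properties = "electrostatic") {
  p <- ncol(values)
  meta <- data.frame(column = seq_len(p),
                     property = rep_len(properties, p),
                     point = seq_len(p), x = 0, y = 0, z = 0,
                     stringsAsFactors = FALSE)
  colnames(values) <- paste0(meta$property, "_", meta$point)
  structure(list(values = values, meta = meta, grid = NULL,
                 attenuation = 0.3, block_scales = NULL),
            class = "field_block")
}

# random valid chromosome plus its infix-evaluation oracle value:
# evaluate the exported infix string with R's own parser/evaluator
infix_oracle <- function(chrom, config, bindings) {
  expr <- parse(text = chromosome_to_infix(chrom, config))[[1]]
  eval(expr, bindings)
}
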