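test_that("Karva decoding is breadth-first with ignored non-coding tail", {
  # canonical example: "+ x y" decodes to x + y
  tree <- karva_decode(c("+", "x", "y", "x", "x"))
  expect_equal(tree_to_infix(tree), "(x + y)")

  # a terminal at position 0 makes a single-leaf tree
  tree1 <- karva_decode(c("x", "+", "y", "z"))
  expect_equal(length(tree1$symbols), 1)
  expect_equal(tree_to_infix(tree1), "x")

  # hand-drawn breadth-first decode of "* + x cos y z":
  # level 0: *;  level 1: + x;  level 2 (children of +): cos y;
  # child of cos: z   =>   ((cos(z) + y) * x)
  tree2 <- karva_decode(c("*", "+", "x", "cos", "y", "z", "x", "y", "z"))
  expect_equal(tree_to_infix(tree2), "((cos(z) + y) * x)")
  b <- list(x = 2, y = 3, z = 0)
  expect_equal(evaluate_tree(tree2, b), (cos(0) + 3) * 2)

  # function in the tail region is a validation error
  expect_error(karva_decode(c("x", "y", "+"), tail_start = 2), "tail")
})

test_that("tree evaluation matches R's own evaluation of the infix export", {
  cfg <- small_gep_config()
  set.seed(14)
  for (i in 1:25) {
    chrom <- random_chromosome(cfg)
    b <- list(x = runif(4, -2, 2), z = runif(4, 0.5, 2))
    trees <- decode_chromosome(chrom, cfg)
    mine <- Reduce(`+`, lapply(trees, evaluate_tree, bindings = b))
    oracle <- infix_oracle(chrom, cfg, b)
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
  expect_error(evaluate_tree(karva_decode("q"), list(x = 1)), "unbound")
})

test_that("fitness is 1000/(1+RMSE), monotone, lethal on bad predictions", {
  y <- c(1, 2, 3)
  expect_equal(gep_fitness(y, y), 1000)
  expect_equal(gep_fitness(y + 999, y), 1)
  rmses <- c(0.1, 0.5, 2, 10)
  fits <- vapply(rmses, function(r) gep_fitness(y + r, y), numeric(1))
  expect_true(all(diff(fits) < 0))
  expect_equal(gep_fitness(NULL, y), 0)
  expect_equal(gep_fitness(c(1, Inf, 3), y), 0)
})

test_that("genetic operators preserve the Karva head/tail alphabet", {
  cfg <- gep_config(terminals = c("x", "z", "1"), head_length = 5,
                    n_genes = 3, population_size = 10, seed = 2,
                    rates = list(mutation = 0.3, is_transposition = 1,
                                 ris_transposition = 1,
                                 gene_transposition = 1,
                                 one_point = 1, two_point = 1,
                                 gene_recombination = 1))
  set.seed(99)
  chrom <- random_chromosome(cfg)
  other <- random_chromosome(cfg)
  for (i in 1:2000) {
    op <- i %% 5
    if (op == 0) chrom <- qsarpipe:::op_mutate(chrom, cfg)
    if (op == 1) chrom <- qsarpipe:::op_is_transpose(chrom, cfg)
    if (op == 2) chrom <- qsarpipe:::op_ris_transpose(chrom, cfg)
    if (op == 3) chrom <- qsarpipe:::op_gene_transpose(chrom, cfg)
    if (op == 4) {
      pair <- qsarpipe:::recombine_pair(chrom, other, cfg)
      chrom <- pair[[1]]; other <- pair[[2]]
    }
    expect_true(valid_chromosome(chrom, cfg))
    expect_true(valid_chromosome(other, cfg))
  }
})

test_that("evolution contract: determinism, elitism, zero-generation runs", {
  sym <- gen_symbolic_set("x + cos(z)", n = 50, seed = 6)
  cfg <- small_gep_config(max_generations = 10)
  m1 <- gep_evolve(sym$X, sym$y, cfg)
  m2 <- gep_evolve(sym$X, sym$y, cfg)
  expect_identical(m1$expression, m2$expression)
  expect_identical(m1$log, m2$log)
  # elitism = 1 makes best fitness monotone non-decreasing
  expect_true(all(diff(m1$log$best_fitness) >= -1e-12))

  m0 <- gep_evolve(sym$X, sym$y, small_gep_config(max_generations = 0))
  expect_equal(nrow(m0$log), 1)
  expect_equal(m0$log$generation, 0)
})

test_that("with all rates zero and full elitism the population is a fixed point", {
  sym <- gen_symbolic_set("x", n = 20, seed = 1)
  cfg <- gep_config(terminals = c("x", "z"), head_length = 4, n_genes = 2,
                    population_size = 6, elitism = 6, max_generations = 5,
                    seed = 3,
                    rates = list(mutation = 0, is_transposition = 0,
                                 ris_transposition = 0,
                                 gene_transposition = 0, one_point = 0,
                                 two_point = 0, gene_recombination = 0))
  m <- gep_evolve(sym$X, sym$y, cfg)
  expect_true(all(m$log$best_fitness == m$log$best_fitness[1]))
  expect_true(all(m$log$mean_fitness == m$log$mean_fitness[1]))
  expect_identical(m$log$best_expression,
                   rep(m$log$best_expression[1], nrow(m$log)))
})

test_that("evolution recovers a planted expression on clean data", {
  sym <- gen_symbolic_set("2*x + cos(z)", n = 100, seed = 8)
  cfg <- gep_config(terminals = c("x", "z"), population_size = 100,
                    max_generations = 300, target_r2 = 0.99, seed = 20)
  m <- gep_evolve(sym$X, sym$y, cfg)
  expect_gte(m$r2, 0.99)
})

test_that("reference GEP equation matches its pre-computed value and tree form", {
  # value at (1,1,1) computed with an independent evaluator beforehand
  expect_equal(ref_gep_model(1, 1, 1), 17.85847325533361, tolerance = 1e-12)
  expect_error(ref_gep_model(0, 1, 1), "zero denominator")
  expect_error(ref_gep_model(1, 1, 0), "zero denominator")

  # dual implementation: the same formula hand-built as an expression
  # tree (prefix form) and evaluated by the tree walker
  mk <- function(s, ...) {
    kids <- list(...)
    syms <- s; children <- list(NULL)
    offs <- integer(0)
    for (k in kids) {
      offs <- c(offs, length(syms) + 1L)
      children <- c(children, lapply(k$children, function(ch) {
        if (is.null(ch)) NULL else ch + length(syms)
      }))
      syms <- c(syms, k$symbols)
    }
    children[[1]] <- if (length(offs)) offs else NULL
    structure(list(symbols = syms, children = children),
              class = "expr_tree")
  }
  leaf <- function(s) structure(list(symbols = s, children = list(NULL)),
                                class = "expr_tree")
  X <- leaf("x"); Y <- leaf("y"); Z <- leaf("z")
  y3x <- mk("/", Y, mk("*", leaf("3"), X))
  inner <- mk("+",
              mk("*",
                 mk("/", mk("/", mk("*", mk("cos", X), X), Y), Z),
                 mk("cos", mk("*", leaf("2"), Y))),
              y3x)
  full <- mk("+",
    mk("-",
       mk("+",
          mk("-",
             mk("+",
                mk("+", mk("*", leaf("14"), Y), mk("*", leaf("2"), X)),
                mk("+", leaf("1"), mk("cos", y3x))),
             mk("cos", X)),
          mk("cos", inner)),
       mk("cos", leaf("1"))),
    leaf("0"))
  set.seed(55)
  for (i in 1:100) {
    b <- list(x = runif(1, 0.2, 3), y = runif(1, 0.2, 3),
              z = runif(1, 0.2, 3))
    expect_equal(evaluate_tree(full, b),
                 ref_gep_model(b$x, b$y, b$z), tolerance = 1e-12)
  }

  # the linear 14y term dominates at large y (bounded cosine remainder)
  diffs <- ref_gep_model(1.3, 1e6 + 1, 0.7) - ref_gep_model(1.3, 1e6, 0.7)
  expect_lt(abs(diffs - 14), 4)

  # the strict left-to-right variant differs only through y/3x
  v1 <- ref_gep_model(2, 1, 1)
  v2 <- ref_gep_model(2, 1, 1, variant = "strict_ltr")
  expect_false(isTRUE(all.equal(v1, v2)))
})

test_that("protected division is lethal during evolution scoring", {
  cfg <- gep_config(terminals = c("x"), head_length = 2, n_genes = 1,
                    population_size = 2, seed = 1)
  # gene "/ x x" with x containing a zero
  chrom <- structure(c("/", "x", "x", "x", "x"), class = "gep_chromosome")
  expect_null(qsarpipe:::evaluate_chromosome(chrom, cfg, list(x = c(1, 0))))
  expect_equal(gep_fitness(
    qsarpipe:::evaluate_chromosome(chrom, cfg, list(x = c(1, 0))),
    c(1, 1)), 0)
  # unprotected evaluation divides through
  expect_equal(qsarpipe:::evaluate_chromosome(chrom, cfg, list(x = 2),
                                              protected = FALSE), 1)
})
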