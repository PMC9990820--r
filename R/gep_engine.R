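# Function alphabet shared by the GEP machinery: four arithmetic
# operators plus cosine, the operator set of the reference 2D-QSAR model.
GEP_ARITIES <- c("+" = 2L, "-" = 2L, "*" = 2L, "/" = 2L, "cos" = 1L)

#' Configuration for gene expression programming
#'
#' A GEP chromosome is a fixed-length string of `n_genes` genes, each
#' with a head of `head_length` symbols (functions or terminals) and a
#' tail of `head_length * (max_arity - 1) + 1` symbols (terminals only),
#' which guarantees that every genome decodes to a syntactically valid
#' expression tree.  Gene values are combined with the `linking`
#' function.  Defaults follow the canonical GEP settings (head 8,
#' 3 genes linked by `+`, population 50, mutation 0.044, transposition
#' 0.1 each, one-/two-point/gene recombination 0.3/0.3/0.1, elitism 1).
#'
#' @param terminals character vector of terminal symbols; variable names
#'   must cover the columns of the training matrix.  Numeric literals
#'   (e.g. `"1"`) are allowed as constant terminals.
#' @param function_set subset of `+ - * / cos`.
#' @param head_length,n_genes genome structure.
#' @param linking linking function between genes: `"+"` or `"*"`.
#' @param population_size,max_generations,elitism evolution controls.
#' @param rates named list of operator probabilities: `mutation`
#'   (per-symbol), `is_transposition`, `ris_transposition`,
#'   `gene_transposition` (per-chromosome), `one_point`, `two_point`,
#'   `gene_recombination` (per-pair).
#' @param target_r2 optional early-stop threshold on the best training R2.
#' @param seed integer seed; runs are bit-reproducible for a fixed seed.
#' @export
gep_config <- function(terminals,
                       function_set = c("+", "-", "*", "/", "cos"),
                       head_length = 8, n_genes = 3, linking = "+",
                       population_size = 50,
                       rates = list(),
                       max_generations = 100, elitism = 1,
                       target_r2 = NULL, seed = 1) {
  function_set <- match.arg(function_set, names(GEP_ARITIES),
                            several.ok = TRUE)
  stopifnot(length(terminals) >= 1, head_length >= 1, n_genes >= 1,
            population_size >= 2, elitism >= 0,
            elitism <= population_size, max_generations >= 0)
  linking <- match.arg(linking, c("+", "*"))
  default_rates <- list(mutation = 0.044, is_transposition = 0.1,
                        ris_transposition = 0.1, gene_transposition = 0.1,
                        one_point = 0.3, two_point = 0.3,
                        gene_recombination = 0.1)
  rates <- utils::modifyList(default_rates, rates)
  bad <- vapply(rates, function(r) !is.numeric(r) || r < 0 || r > 1,
                logical(1))
  if (any(bad)) {
    stop("operator rates must lie in [0, 1]: ",
         paste(names(rates)[bad], collapse = ", "), call. = FALSE)
  }
  max_arity <- max(GEP_ARITIES[function_set])
  tail_length <- head_length * (max_arity - 1L) + 1L
  structure(list(
    terminals = as.character(terminals), function_set = function_set,
    head_length = as.integer(head_length), tail_length = tail_length,
    gene_length = as.integer(head_length + tail_length),
    n_genes = as.integer(n_genes), linking = linking,
    population_size = as.integer(population_size), rates = rates,
    max_generations = as.integer(max_generations),
    elitism = as.integer(elitism),
    target_r2 = target_r2, seed = seed
  ), class = "gep_config")
}

# logical mask of head positions over the whole chromosome
head_mask <- function(config) {
  rep(rep(c(TRUE, FALSE), config$n_genes),
      rep(c(config$head_length, config$tail_length), config$n_genes))
}

#' Random chromosome respecting the Karva head/tail alphabet
#' @param config a [gep_config()].
#' @return Character vector of symbols (class `gep_chromosome`).
#' @export
random_chromosome <- function(config) {
  head_pool <- c(config$function_set, config$terminals)
  genes <- replicate(config$n_genes, c(
    sample(head_pool, config$head_length, replace = TRUE),
    sample(config$terminals, config$tail_length, replace = TRUE)
  ), simplify = FALSE)
  structure(unlist(genes), class = "gep_chromosome")
}

#' Check the head/tail alphabet constraints of a chromosome
#' @param chrom chromosome (character vector).
#' @param config a [gep_config()].
#' @return `TRUE` or `FALSE`.
#' @export
valid_chromosome <- function(chrom, config) {
  if (length(chrom) != config$gene_length * config$n_genes) return(FALSE)
  hm <- head_mask(config)
  all(chrom[hm] %in% c(config$function_set, config$terminals)) &&
    all(chrom[!hm] %in% config$terminals)
}

#' Decode one Karva gene into an expression tree
#'
#' Karva decoding is breadth-first: the first symbol is the root; each
#' function node consumes the next `arity` unread symbols as its
#' children, level by level.  Symbols beyond the last needed one are
#' ignored (they are the genome's non-coding region).
#'
#' @param gene character vector of symbols (head then tail).
#' @param function_set functions appearing in heads; anything else is a
#'   terminal.
#' @param tail_start position of the first tail symbol; when given, a
#'   function symbol at or after it raises a validation error.
#' @return An object of class `expr_tree`: list with `symbols` (used
#'   symbols, breadth-first) and `children` (list of child indices,
#'   `NULL` for leaves).
#' @export
karva_decode <- function(gene, function_set = names(GEP_ARITIES),
                         tail_start = NULL) {
  arities <- GEP_ARITIES[function_set]
  if (!is.null(tail_start)) {
    in_tail <- seq_along(gene) >= tail_start
    if (any(gene[in_tail] %in% function_set)) {
      stop("malformed gene: function symbol in the tail", call. = FALSE)
    }
  }
  total <- 1L
  j <- 1L
  children <- vector("list", length(gene))
  while (j <= total) {
    a <- arities[gene[j]]
    if (!is.na(a) && a > 0L) {
      if (total + a > length(gene)) {
        stop("malformed gene: runs out of symbols while decoding",
             call. = FALSE)
      }
      children[[j]] <- (total + 1L):(total + a)
      total <- total + a
    }
    j <- j + 1L
  }
  structure(list(symbols = gene[seq_len(total)],
                 children = children[seq_len(total)]),
            class = "expr_tree")
}

#' Evaluate an expression tree
#'
#' Nodes are evaluated bottom-up with vectorised arithmetic, so bindings
#' may be numeric vectors (columns of a data set) and the result has the
#' common length.  Terminals resolve first against `bindings`, then as
#' numeric literals.
#'
#' @param tree an `expr_tree` from [karva_decode()].
#' @param bindings named list (or environment) of numeric vectors.
#' @param protected if `TRUE`, any division whose denominator comes
#'   within 1e-12 of zero makes the whole evaluation return `NULL`
#'   (the "lethal" convention used during evolution, so singular
#'   expressions are never rewarded); if `FALSE`, plain IEEE division.
#' @return Numeric vector, or `NULL` under the protected convention.
#' @export
evaluate_tree <- function(tree, bindings, protected = FALSE) {
  syms <- tree$symbols
  kids <- tree$children
  n <- length(syms)
  vals <- vector("list", n)
  for (i in n:1) {
    ch <- kids[[i]]
    s <- syms[i]
    if (is.null(ch)) {
      v <- bindings[[s]]
      if (is.null(v)) {
        v <- suppressWarnings(as.numeric(s))
        if (is.na(v)) stop("unbound variable: ", s, call. = FALSE)
      }
      vals[[i]] <- v
    } else if (s == "cos") {
      vals[[i]] <- cos(vals[[ch[1L]]])
    } else {
      a <- vals[[ch[1L]]]
      b <- vals[[ch[2L]]]
      vals[[i]] <- switch(s,
        "+" = a + b,
        "-" = a - b,
        "*" = a * b,
        "/" = {
          if (protected && any(abs(b) < 1e-12)) return(NULL)
          a / b
        },
        stop("unknown function: ", s, call. = FALSE))
    }
  }
  vals[[1L]]
}

#' Render an expression tree as an infix string
#' @param tree an `expr_tree`.
#' @return A parseable infix string, fully parenthesised.
#' @export
tree_to_infix <- function(tree) {
  rec <- function(i) {
    ch <- tree$children[[i]]
    s <- tree$symbols[i]
    if (is.null(ch)) return(s)
    if (s == "cos") return(paste0("cos(", rec(ch[1L]), ")"))
    paste0("(", rec(ch[1L]), " ", s, " ", rec(ch[2L]), ")")
  }
  rec(1L)
}

#' Decode a whole chromosome into its gene trees
#' @inheritParams valid_chromosome
#' @return List of `expr_tree`, one per gene.
#' @export
decode_chromosome <- function(chrom, config) {
  lapply(seq_len(config$n_genes), function(g) {
    lo <- (g - 1L) * config$gene_length + 1L
    karva_decode(chrom[lo:(lo + config$gene_length - 1L)],
                 config$function_set,
                 tail_start = config$head_length + 1L)
  })
}

#' @rdname decode_chromosome
#' @export
chromosome_to_infix <- function(chrom, config) {
  paste(vapply(decode_chromosome(chrom, config), tree_to_infix,
               character(1)),
        collapse = paste0(" ", config$linking, " "))
}

# evaluate a chromosome on a data list; NULL under lethal division
evaluate_chromosome <- function(chrom, config, data, protected = TRUE) {
  acc <- NULL
  for (tree in decode_chromosome(chrom, config)) {
    v <- evaluate_tree(tree, data, protected = protected)
    if (is.null(v)) return(NULL)
    acc <- if (is.null(acc)) v else switch(config$linking,
                                           "+" = acc + v, "*" = acc * v)
  }
  acc
}

#' GEP fitness from root-mean-square error
#'
#' `fitness = 1000 / (1 + RMSE)`: strictly decreasing in RMSE, 1000 for a
#' perfect fit, and 0 ("lethal") when predictions are undefined or
#' non-finite.
#'
#' @param predictions numeric vector or `NULL` (lethal).
#' @param y observed response.
#' @export
gep_fitness <- function(predictions, y) {
  if (is.null(predictions) || any(!is.finite(predictions))) return(0)
  rmse <- sqrt(mean((y - predictions)^2))
  1000 / (1 + rmse)
}

# ---- genetic operators -----------------------------------------------------
# All operators preserve the head/tail alphabet by construction.

# draw one element of x (safe for length-1 x, unlike sample())
pick1 <- function(x) x[sample.int(length(x), 1L)]

op_mutate <- function(chrom, config) {
  L <- length(chrom)
  hit <- which(stats::runif(L) < config$rates$mutation)
  if (length(hit) == 0) return(chrom)
  hm <- head_mask(config)
  head_pool <- c(config$function_set, config$terminals)
  for (i in hit) {
    chrom[i] <- if (hm[i]) sample(head_pool, 1L) else
      sample(config$terminals, 1L)
  }
  chrom
}

# insert a copied transposon at a non-root position of one gene's head
op_is_transpose <- function(chrom, config) {
  h <- config$head_length
  if (h < 2L || stats::runif(1) >= config$rates$is_transposition) return(chrom)
  len <- pick1(1:3)
  len <- min(len, h - 1L)
  start <- sample.int(length(chrom) - len + 1L, 1L)
  transposon <- chrom[start:(start + len - 1L)]
  g <- sample.int(config$n_genes, 1L)
  lo <- (g - 1L) * config$gene_length
  head <- chrom[(lo + 1L):(lo + h)]
  ins <- pick1(2:h)
  new_head <- append(head, transposon, after = ins - 1L)[1:h]
  chrom[(lo + 1L):(lo + h)] <- new_head
  chrom
}

# root transposition: a function-headed transposon becomes the gene root
op_ris_transpose <- function(chrom, config) {
  if (stats::runif(1) >= config$rates$ris_transposition) return(chrom)
  h <- config$head_length
  g <- sample.int(config$n_genes, 1L)
  lo <- (g - 1L) * config$gene_length
  head <- chrom[(lo + 1L):(lo + h)]
  from <- sample.int(h, 1L)
  fpos <- which(head[from:h] %in% config$function_set)
  if (length(fpos) == 0) return(chrom)  # no function downstream: no-op
  p <- from + fpos[1L] - 1L
  len <- min(pick1(1:3), h - p + 1L)
  transposon <- head[p:(p + len - 1L)]
  chrom[(lo + 1L):(lo + h)] <- c(transposon, head)[1:h]
  chrom
}

op_gene_transpose <- function(chrom, config) {
  if (config$n_genes < 2L ||
      stats::runif(1) >= config$rates$gene_transposition) return(chrom)
  g <- pick1(2:config$n_genes)
  gl <- config$gene_length
  idx <- matrix(seq_along(chrom), nrow = gl)
  order_genes <- c(g, setdiff(seq_len(config$n_genes), g))
  chrom[] <- chrom[as.vector(idx[, order_genes])]
  chrom
}

recombine_pair <- function(c1, c2, config) {
  L <- length(c1)
  if (stats::runif(1) < config$rates$one_point) {
    p <- sample.int(L - 1L, 1L)
    tmp <- c1[(p + 1L):L]
    c1[(p + 1L):L] <- c2[(p + 1L):L]
    c2[(p + 1L):L] <- tmp
  }
  if (stats::runif(1) < config$rates$two_point) {
    ps <- sort(sample.int(L, 2L))
    seg <- ps[1L]:ps[2L]
    tmp <- c1[seg]
    c1[seg] <- c2[seg]
    c2[seg] <- tmp
  }
  if (config$n_genes >= 2L &&
      stats::runif(1) < config$rates$gene_recombination) {
    g <- sample.int(config$n_genes, 1L)
    seg <- ((g - 1L) * config$gene_length + 1L):(g * config$gene_length)
    tmp <- c1[seg]
    c1[seg] <- c2[seg]
    c2[seg] <- tmp
  }
  list(c1, c2)
}

# fitness-proportional sampling; uniform fallback when all fitness is 0
roulette_select <- function(fitness, m) {
  if (sum(fitness) <= 0) return(sample.int(length(fitness), m, replace = TRUE))
  sample.int(length(fitness), m, replace = TRUE, prob = fitness)
}

#' Evolve a GEP population against a training set
#'
#' Runs the canonical GEP loop: random initial population, Karva
#' decoding, fitness evaluation, termination check, elitist roulette
#' selection, then mutation, IS/RIS/gene transposition and
#' one-point/two-point/gene recombination to form the next generation.
#' The best `elitism` chromosomes are copied unchanged each generation,
#' so the best fitness is monotone non-decreasing.
#'
#' @param X numeric matrix or data.frame of inputs; column names must be
#'   covered by `config$terminals`.
#' @param y numeric response.
#' @param config a [gep_config()].
#' @return An object of class `gep_model`: list with `chromosome`,
#'   `expression` (infix string), `fitness`, `rmse`, `r2`, `log`
#'   (per-generation data.frame: `generation`, `best_fitness`,
#'   `mean_fitness`, `best_expression`), and `config`.
#' @export
gep_evolve <- function(X, y, config) {
  X <- as.data.frame(X)
  if (!all(colnames(X) %in% config$terminals)) {
    stop("`config$terminals` must cover the columns of X", call. = FALSE)
  }
  if (nrow(X) == 0) stop("empty training set", call. = FALSE)
  data <- as.list(X)
  tss <- sum((y - mean(y))^2)

  with_seed(config$seed, {
    pop <- replicate(config$population_size, random_chromosome(config),
                     simplify = FALSE)
    score <- function(pop) {
      vapply(pop, function(ch) {
        gep_fitness(evaluate_chromosome(ch, config, data), y)
      }, numeric(1))
    }
    fits <- score(pop)
    log_rows <- list()
    gen <- 0L
    repeat {
      best_i <- which.max(fits)
      best_expr <- chromosome_to_infix(pop[[best_i]], config)
      log_rows[[gen + 1L]] <- data.frame(
        generation = gen, best_fitness = fits[best_i],
        mean_fitness = mean(fits), best_expression = best_expr,
        stringsAsFactors = FALSE)
      best_rmse <- 1000 / max(fits[best_i], .Machine$double.xmin) - 1
      best_r2 <- 1 - length(y) * best_rmse^2 / tss
      if (gen >= config$max_generations) break
      if (!is.null(config$target_r2) && fits[best_i] > 0 &&
          best_r2 >= config$target_r2) break

      elite_idx <- order(-fits)[seq_len(config$elitism)]
      elite <- pop[elite_idx]
      n_rest <- config$population_size - config$elitism
      sel <- pop[roulette_select(fits, n_rest)]
      sel <- lapply(sel, function(ch) {
        ch <- op_mutate(ch, config)
        ch <- op_is_transpose(ch, config)
        ch <- op_ris_transpose(ch, config)
        op_gene_transpose(ch, config)
      })
      if (length(sel) >= 2L) {
        ord <- sample.int(length(sel))
        for (j in seq(1L, length(ord) - 1L, by = 2L)) {
          pair <- recombine_pair(sel[[ord[j]]], sel[[ord[j + 1L]]], config)
          sel[[ord[j]]] <- pair[[1L]]
          sel[[ord[j + 1L]]] <- pair[[2L]]
        }
      }
      pop <- c(elite, sel)
      fits <- score(pop)
      gen <- gen + 1L
    }
    best_i <- which.max(fits)
    best <- pop[[best_i]]
    pred <- evaluate_chromosome(best, config, data)
    rmse <- if (is.null(pred)) Inf else sqrt(mean((y - pred)^2))
    structure(list(
      chromosome = best,
      expression = chromosome_to_infix(best, config),
      fitness = fits[best_i],
      rmse = rmse,
      r2 = if (is.finite(rmse)) 1 - sum((y - pred)^2) / tss else -Inf,
      log = do.call(rbind, log_rows),
      config = config
    ), class = "gep_model")
  })
}

#' @export
predict.gep_model <- function(object, newdata, ...) {
  v <- evaluate_chromosome(object$chromosome, object$config,
                           as.list(as.data.frame(newdata)),
                           protected = FALSE)
  n <- nrow(as.data.frame(newdata))
  rep_len(v, n)
}

#' @export
print.gep_model <- function(x, ...) {
  cat("GEP model:", x$expression, "\n")
  cat(sprintf("  fitness = %.3f  RMSE = %.4g  R2 = %.4f  (%d generations)\n",
              x$fitness, x$rmse, x$r2, max(x$log$generation)))
  invisible(x)
}

#' Reference non-linear (GEP) 2D-QSAR model for the quinazoline series
#'
#' The published symbolic-regression equation relating the same three
#' descriptors as [ref_linear_model()] to log IC50:
#'
#' `logIC50 = 14y + 2x + 1 + cos(y/(3x)) - cos(x)
#'            + cos(((cos(x) * x) / y) / z * cos(2y) + y/(3x)) - cos(1)`
#'
#' with `x` = Avg-ERC, `y` = HDSA-2/TMSA(QC), `z` = Min-NRO.  The
#' equation was machine-generated as C code, so division chains
#' associate left to right (`a/y/z` means `(a/y)/z`).  The one genuinely
#' ambiguous token is the compact quotient `y/3x`: by default it is read
#' as `y/(3x)` (implicit multiplication binds first); `variant =
#' "strict_ltr"` reads it as `(y/3)*x` instead.
#'
#' @param x,y,z descriptor values (vectorised); all must be non-zero
#'   (they appear in denominators).
#' @param variant `"implicit"` (default) or `"strict_ltr"`, see above.
#' @return Predicted log IC50.
#' @export
ref_gep_model <- function(x, y, z, variant = c("implicit", "strict_ltr")) {
  variant <- match.arg(variant)
  if (any(x == 0) || any(y == 0) || any(z == 0)) {
    stop("zero denominator: x, y and z must all be non-zero", call. = FALSE)
  }
  y3x <- if (variant == "implicit") y / (3 * x) else y / 3 * x
  14 * y + 2 * x + 1 + cos(y3x) - cos(x) +
    cos(((cos(x) * x) / y) / z * cos(2 * y) + y3x) - cos(1)
}
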