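# Compact real-coded genetic algorithm with box constraints: tournament
# selection, blend crossover, Gaussian mutation, elitism. Deterministic under
# a fixed seed.

#' Genetic-algorithm settings
#'
#' @param pop_size population size.
#' @param generations maximum generations.
#' @param elite number of elite individuals copied unchanged.
#' @param tournament tournament size for selection.
#' @param p_crossover blend-crossover probability.
#' @param p_mutation per-gene Gaussian mutation probability.
#' @param mutation_sd mutation standard deviation as a fraction of the box
#'   width.
#' @param seed RNG seed.
#' @export
ga_config <- function(pop_size = 24, generations = 20, elite = 2,
                      tournament = 3, p_crossover = 0.9, p_mutation = 0.25,
                      mutation_sd = 0.12, seed = 1L) {
  structure(list(pop_size = pop_size, generations = generations,
                 elite = elite, tournament = tournament,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 mutation_sd = mutation_sd, seed = seed),
            class = "pf_ga_config")
}

#' Minimize a function over a box by a real-coded genetic algorithm
#'
#' @param fn objective, `function(par) -> scalar` (non-finite treated as
#'   failure and assigned the worst fitness).
#' @param lower,upper box bounds (numeric vectors).
#' @param config [ga_config()].
#' @return list: `par`, `value`, `trace` (best objective per generation),
#'   `evals` (matrix of all evaluated parameters with objective values),
#'   `n_failed`.
#' @export
ga_optimize <- function(fn, lower, upper, config = ga_config()) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  set.seed(config$seed)
  width <- upper - lower
  clamp <- function(x) pmin(pmax(x, lower), upper)
  pop <- t(replicate(config$pop_size, lower + stats::runif(d) * width))
  evals <- list()
  n_failed <- 0L
  score <- function(x) {
    v <- tryCatch(fn(x), error = function(e) NA_real_)
    if (!is.finite(v)) {
      n_failed <<- n_failed + 1L
      v <- NA_real_
    }
    evals[[length(evals) + 1L]] <<- c(x, v)
    v
  }
  fit <- apply(pop, 1, score)
  if (all(is.na(fit)))
    stop("all genetic-algorithm evaluations failed; see the evaluation log")
  worst <- max(fit, na.rm = TRUE) * 10 + 1
  fit[is.na(fit)] <- worst
  trace <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(config$elite)], , drop = FALSE]
    while (nrow(newpop) < config$pop_size) {
      pick <- function() {
        cand <- sample.int(config$pop_size, config$tournament)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (stats::runif(1) < config$p_crossover) {
        a <- stats::runif(d, -0.25, 1.25)  # BLX-alpha style blend
        child <- a * p1 + (1 - a) * p2
      } else child <- p1
      mut <- stats::runif(d) < config$p_mutation
      child[mut] <- child[mut] +
        stats::rnorm(sum(mut), 0, config$mutation_sd * width[mut])
      newpop <- rbind(newpop, clamp(child))
    }
    keep_fit <- fit[ord[seq_len(config$elite)]]
    new_fit <- apply(newpop[-seq_len(config$elite), , drop = FALSE], 1, score)
    new_fit[is.na(new_fit)] <- worst
    pop <- newpop
    fit <- c(keep_fit, new_fit)
    trace[gen] <- min(fit)
  }
  best <- which.min(fit)
  ev <- do.call(rbind, evals)
  colnames(ev) <- c(paste0("par", seq_len(d)), "objective")
  list(par = pop[best, ], value = fit[best], trace = trace, evals = ev,
       n_failed = n_failed)
}
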