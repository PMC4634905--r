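#' Genetic algorithm configuration
#'
#' Settings for the seeded GA used both for wrapper feature selection
#' (binary chromosomes = dimension subsets) and for ensemble weight tuning
#' (simplex chromosomes = non-negative weights summing to 1).
#'
#' @param population_size chromosomes per generation (default 100).
#' @param max_generations hard cap on generations (default 60).
#' @param fitness_tolerance stop when the improvement of the best fitness
#'   over the last `stall_generations` generations falls below this value
#'   (default 1e-6).
#' @param stall_generations window for the tolerance check (default 50, the
#'   stall-generation limit conventional in GA toolboxes; set to 1 to stop
#'   after a single generation without improvement).
#' @param elitism_count chromosomes copied unchanged to the next generation.
#' @param crossover_fraction fraction of non-elite offspring produced by
#'   crossover (the rest by mutation).
#' @param mutation_rate per-gene flip probability for binary chromosomes.
#' @param mutation_sd standard deviation of the Gaussian perturbation for
#'   simplex chromosomes (applied before simplex repair).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, max_generations = 60L,
                      fitness_tolerance = 1e-6, stall_generations = 50L,
                      elitism_count = 2L, crossover_fraction = 0.8,
                      mutation_rate = 0.01, mutation_sd = 0.1) {
  population_size <- as.integer(population_size)
  max_generations <- as.integer(max_generations)
  if (population_size < 2L) stop("population_size must be >= 2", call. = FALSE)
  if (max_generations < 1L) stop("max_generations must be >= 1", call. = FALSE)
  if (fitness_tolerance < 0) stop("fitness_tolerance must be >= 0",
                                  call. = FALSE)
  if (elitism_count < 0L || elitism_count >= population_size)
    stop("elitism_count must be in [0, population_size)", call. = FALSE)
  if (crossover_fraction < 0 || crossover_fraction > 1)
    stop("crossover_fraction must be in [0,1]", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0,1]", call. = FALSE)
  structure(list(population_size = population_size,
                 max_generations = max_generations,
                 fitness_tolerance = fitness_tolerance,
                 stall_generations = as.integer(stall_generations),
                 elitism_count = as.integer(elitism_count),
                 crossover_fraction = crossover_fraction,
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd),
            class = "ga_config")
}

simplex_repair <- function(w) {
  w[w < 0] <- 0
  tot <- sum(w)
  if (tot == 0) rep(1 / length(w), length(w)) else w / tot
}

#' Maximise a fitness function with a seeded genetic algorithm
#'
#' Generational GA with rank-based fitness scaling, stochastic universal
#' sampling, elitism, uniform (scattered) crossover and per-gene mutation.
#' Two encodings are supported: `"binary"` chromosomes in \{0,1\}^length, and
#' `"simplex"` chromosomes (non-negative reals summing to 1, repaired after
#' every genetic operation by clipping negatives to 0 and renormalising;
#' an all-zero vector is repaired to uniform).  Simplex crossover is a
#' per-gene uniform blend of the two parents; simplex mutation adds Gaussian
#' noise (`mutation_sd`) before repair.  The initial simplex population
#' contains the simplex corners (one-hot weight vectors) and centre as
#' deterministic anchors, the rest drawn uniformly.
#'
#' The search stops when the best fitness has improved by less than
#' `fitness_tolerance` over the last `stall_generations` generations, or at
#' `max_generations`.  Fitness must be deterministic in the chromosome
#' (callers fix any internal cross-validation folds per run); each unique
#' chromosome is evaluated once per run (cached).  A non-finite fitness
#' value is replaced by `-Inf` with a warning.
#'
#' @param fitness function taking one chromosome (numeric vector) and
#'   returning a scalar.
#' @param length chromosome length.
#' @param encoding `"binary"` or `"simplex"`.
#' @param config a [ga_config()].
#' @param seed optional integer seed; when given, the run is bit-for-bit
#'   reproducible.
#' @return An object of class `ga_result`: `best_chromosome`,
#'   `best_fitness`, `trace` (best-so-far fitness per generation, length
#'   `generations_run`), `generations_run`, `n_evaluated`.
#' @export
ga_maximize <- function(fitness, length, encoding = c("binary", "simplex"),
                        config = ga_config(), seed = NULL) {
  encoding <- match.arg(encoding)
  L <- as.integer(length)
  if (L < 1L) stop("chromosome length must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  np <- config$population_size
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  warned_nonfinite <- FALSE
  eval1 <- function(ch) {
    key <- paste(ch, collapse = ",")
    if (!is.null(v <- cache[[key]])) return(v)
    v <- fitness(ch)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      if (!warned_nonfinite) {
        warning("non-finite fitness; chromosome(s) assigned -Inf",
                call. = FALSE)
        warned_nonfinite <<- TRUE
      }
      v <- -Inf
    }
    n_eval <<- n_eval + 1L
    cache[[key]] <- v
    v
  }
  new_chrom <- function() {
    if (encoding == "binary") as.numeric(stats::runif(L) < 0.5)
    else simplex_repair(stats::runif(L))
  }
  pop <- do.call(rbind, lapply(seq_len(np), function(i) new_chrom()))
  if (encoding == "simplex") {
    # deterministic anchors: the simplex corners (single-predictor weights)
    # and its centre, so degenerate optima are always reachable
    anchors <- utils::head(rbind(diag(L), rep(1 / L, L)), np)
    pop[seq_len(nrow(anchors)), ] <- anchors
  }
  fit <- apply(pop, 1L, eval1)
  trace <- max(fit)
  gen <- 1L
  repeat {
    if (gen >= config$max_generations) break
    if (gen > config$stall_generations) {
      w <- config$stall_generations
      if (isTRUE(trace[gen] - trace[gen - w] < config$fitness_tolerance)) break
    }
    ord <- order(-fit, seq_len(np))
    n_elite <- config$elitism_count
    n_xover <- round(config$crossover_fraction * (np - n_elite))
    n_mut <- np - n_elite - n_xover
    # rank-based scaling (expectation ~ 1/sqrt(rank)), SUS parent sampling
    expect <- 1 / sqrt(seq_len(np))
    n_parents <- 2L * n_xover + n_mut
    expect <- expect / sum(expect) * n_parents
    cum <- cumsum(expect)
    pointers <- stats::runif(1L) + seq_len(n_parents) - 1L
    parents <- ord[pmin(findInterval(pointers, cum) + 1L, np)]
    parents <- parents[sample.int(n_parents)]
    next_pop <- matrix(0, np, L)
    if (n_elite > 0L)
      next_pop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    row <- n_elite
    pi <- 1L
    for (i in seq_len(n_xover)) {
      p1 <- pop[parents[pi], ]; p2 <- pop[parents[pi + 1L], ]
      pi <- pi + 2L
      child <- if (encoding == "binary") {
        mask <- stats::runif(L) < 0.5
        ifelse(mask, p1, p2)
      } else {
        simplex_repair(p1 + stats::runif(L) * (p2 - p1))
      }
      row <- row + 1L
      next_pop[row, ] <- child
    }
    for (i in seq_len(n_mut)) {
      p <- pop[parents[pi], ]; pi <- pi + 1L
      child <- if (encoding == "binary") {
        flip <- stats::runif(L) < config$mutation_rate
        ifelse(flip, 1 - p, p)
      } else {
        simplex_repair(p + stats::rnorm(L, 0, config$mutation_sd))
      }
      row <- row + 1L
      next_pop[row, ] <- child
    }
    pop <- next_pop
    fit <- apply(pop, 1L, eval1)
    gen <- gen + 1L
    trace <- c(trace, max(trace[gen - 1L], max(fit)))
  }
  # best over all generations: elites guarantee it survives in final pop,
  # except when elitism_count = 0; track via trace + final scan
  best_i <- order(-fit, seq_len(np))[1L]
  best <- pop[best_i, ]
  best_f <- fit[best_i]
  if (best_f < trace[gen]) best_f <- trace[gen]  # defensive; equal with elitism
  structure(list(best_chromosome = best, best_fitness = best_f,
                 trace = trace, generations_run = gen, n_evaluated = n_eval),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("ga_result: best fitness %.6g after %d generation(s), %d evaluations\n",
              x$best_fitness, x$generations_run, x$n_evaluated))
  invisible(x)
}
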