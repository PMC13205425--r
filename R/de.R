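# Differential evolution (DE/best/1/bin) over flat decision vectors encoding
# a whole filter bank: 6 coordinates per filter in the order
# (m, sigma, theta, lambda, gamma, psi). DE works in continuous space; the
# window size m is only rounded to an integer when a vector is decoded into a
# bank, so mutation/crossover/repair operate exactly on real vectors.

#' DE configuration
#'
#' Defaults follow the study protocol: population 30, scale factor `F = 0.8`,
#' crossover rate `CR = 0.9`, at most 30 generations, stopping early when the
#' best cross-validated error reaches `1e-6`, and 4 filters (a 24-dimensional
#' decision vector).
#'
#' @param pop_size population size `N` (at least 4).
#' @param scale_factor mutation scale factor `F`.
#' @param crossover_rate binomial crossover probability `CR`.
#' @param max_iter maximum number of generations.
#' @param error_threshold stop once the best fitness is at or below this.
#' @param n_filters number of Gabor filters encoded per vector.
#' @param seed RNG seed for the run.
#' @return object of class `de_config`.
#' @export
de_config <- function(pop_size = 30L, scale_factor = 0.8,
                      crossover_rate = 0.9, max_iter = 30L,
                      error_threshold = 1e-6, n_filters = 4L, seed = 1L) {
  stopifnot(pop_size >= 4L, scale_factor >= 0, crossover_rate >= 0,
            crossover_rate <= 1, max_iter >= 1L, n_filters >= 1L)
  structure(list(pop_size = as.integer(pop_size),
                 scale_factor = scale_factor,
                 crossover_rate = crossover_rate,
                 max_iter = as.integer(max_iter),
                 error_threshold = error_threshold,
                 n_filters = as.integer(n_filters),
                 seed = as.integer(seed)),
            class = "de_config")
}

#' Per-coordinate search bounds for a filter bank
#'
#' Repeats the six per-parameter domains (window 1-20, envelope scale 1-5,
#' orientation 0-pi, wavelength 1-10, aspect 0-1, phase 0-2pi) once per
#' filter.
#'
#' @param n_filters number of filters.
#' @return list with numeric vectors `lower` and `upper` of length
#'   `6 * n_filters`.
#' @export
default_bounds <- function(n_filters = 4L) {
  list(lower = rep(unname(gabor_domain$lower), n_filters),
       upper = rep(unname(gabor_domain$upper), n_filters))
}

check_bounds <- function(bounds) {
  stopifnot(is.numeric(bounds$lower), is.numeric(bounds$upper),
            length(bounds$lower) == length(bounds$upper),
            all(bounds$lower < bounds$upper))
  invisible(bounds)
}

#' Initialize a DE population
#'
#' Draws `pop_size` vectors with each coordinate uniform on its
#' `[lower, upper]` interval. Seeds the RNG from `config$seed` unless
#' `seed = NULL` (used internally when the caller manages the stream).
#'
#' @param config a `de_config`.
#' @param bounds bounds list as from [default_bounds()].
#' @param seed RNG seed; `NULL` to use the current RNG state.
#' @return numeric matrix, one row per population member.
#' @export
init_population <- function(config, bounds = default_bounds(config$n_filters),
                            seed = config$seed) {
  check_bounds(bounds)
  if (config$pop_size < 4L) {
    stop("DE/best/1 needs a population of at least 4")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- length(bounds$lower)
  pop <- matrix(runif(config$pop_size * d), config$pop_size, d)
  sweep(sweep(pop, 2L, bounds$upper - bounds$lower, "*"),
        2L, bounds$lower, "+")
}

#' DE/best/1 mutation
#'
#' Donor vector `V = best + F * (a - b)`; no bound repair is applied here.
#'
#' @param best,a,b numeric vectors of equal length (`a`, `b` drawn from
#'   distinct population members).
#' @param scale_factor mutation scale factor `F`.
#' @return numeric donor vector.
#' @export
mutate_best1 <- function(best, a, b, scale_factor) {
  stopifnot(length(best) == length(a), length(a) == length(b))
  best + scale_factor * (a - b)
}

#' Binomial crossover
#'
#' Coordinate `j` of the trial takes the donor value iff `u_j <= CR` or
#' `j == j_rand`; the forced index guarantees at least one donor coordinate.
#' Consumes `1 + length(target)` RNG draws when `j_rand` is not supplied.
#'
#' @param target,donor numeric vectors of equal length.
#' @param crossover_rate crossover probability `CR`.
#' @param j_rand forced donor index; drawn uniformly when `NULL`.
#' @return numeric trial vector.
#' @export
crossover_bin <- function(target, donor, crossover_rate, j_rand = NULL) {
  d <- length(target)
  stopifnot(length(donor) == d, d >= 1L)
  if (is.null(j_rand)) j_rand <- sample.int(d, 1L)
  take <- runif(d) <= crossover_rate
  take[j_rand] <- TRUE
  ifelse(take, donor, target)
}

# truncated (toward-zero) remainder; R's %% is the floored variant
trunc_mod <- function(x, m) x - trunc(x / m) * m

#' Modulus-reflection bound repair
#'
#' Folds out-of-bound coordinates back into `[L, U]` without truncation:
#' values below `L` map to `U - |x mod (U - L)|`, values above `U` to
#' `L + |x mod (U - L)|`, where `mod` is the truncated (toward-zero)
#' remainder and in-range values pass through. Idempotent.
#'
#' @param v numeric vector.
#' @param bounds bounds list (`lower`, `upper`).
#' @return repaired numeric vector, always within bounds.
#' @export
repair_bounds <- function(v, bounds) {
  check_bounds(bounds)
  lo <- bounds$lower; hi <- bounds$upper
  stopifnot(length(v) == length(lo))
  r <- abs(trunc_mod(v, hi - lo))
  out <- v
  below <- v < lo; above <- v > hi
  out[below] <- hi[below] - r[below]
  out[above] <- lo[above] + r[above]
  out
}

#' Greedy one-to-one selection
#'
#' Keeps the trial only on strict improvement (`E(trial) < E(target)`); ties
#' retain the target.
#'
#' @param target,trial candidates: lists with `vector` and evaluated
#'   `fitness`.
#' @return the surviving candidate.
#' @export
select_greedy <- function(target, trial) {
  if (is.null(target$fitness) || is.null(trial$fitness) ||
      is.na(target$fitness) || is.na(trial$fitness)) {
    stop("both candidates must have evaluated fitness")
  }
  if (trial$fitness < target$fitness) trial else target
}

#' Decode a decision vector into a filter bank
#'
#' Groups coordinates in blocks of six, order (m, sigma, theta, lambda,
#' gamma, psi). The window size is rounded half-away-from-zero to an integer
#' and clamped to `[1, 20]`; all other parameters pass through unchanged.
#'
#' @param v numeric vector of length divisible by 6 (already within bounds).
#' @return a `gabor_bank`.
#' @export
decode_vector <- function(v) {
  if (length(v) %% 6L != 0L) {
    stop("decision vector length ", length(v), " is not divisible by 6")
  }
  blocks <- matrix(v, nrow = 6L)
  gabor_bank(lapply(seq_len(ncol(blocks)), function(j) {
    b <- blocks[, j]
    m <- min(max(floor(b[1] + 0.5), 1), 20)  # half-away-from-zero for m > 0
    gabor_params(m, b[2], b[3], b[4], b[5], b[6])
  }))
}

#' Encode a filter bank as a decision vector
#'
#' Inverse of [decode_vector()] (exact for integer window sizes).
#'
#' @param bank a `gabor_bank`.
#' @return numeric vector of length `6 * Nf`.
#' @export
encode_bank <- function(bank) {
  stopifnot(inherits(bank, "gabor_bank"))
  unlist(lapply(bank$filters, function(p) {
    c(p$m, p$sigma, p$theta, p$lambda, p$gamma, p$psi)
  }), use.names = FALSE)
}

#' Run a DE/best/1/bin optimization
#'
#' Evolves a population of decision vectors against `fitness_fn`. Per
#' generation and target (in index order): draw two distinct partners `a`,
#' `b` (excluding the target and the current best), mutate, binomial
#' crossover with a forced donor index, modulus-reflection repair, evaluate,
#' and select greedily. Stops when the best fitness reaches
#' `error_threshold` or after `max_iter` generations. Fully reproducible
#' under `config$seed`; the stream order per target is fixed as partner
#' draws, then the forced index, then the crossover uniforms.
#'
#' @param fitness_fn function mapping a (repaired) decision vector to an
#'   error in `[0, 1]`.
#' @param config a `de_config`.
#' @param bounds bounds list; defaults to [default_bounds()] for
#'   `config$n_filters`.
#' @return object of class `de_result`: `best` (list with `vector`,
#'   `fitness`), `best_bank` (decoded), `history` (per-generation best/mean/sd
#'   data frame, generation 0 = initial population), `seed`, `config`,
#'   `termination_reason`.
#' @export
run_de <- function(fitness_fn, config = de_config(),
                   bounds = default_bounds(config$n_filters)) {
  check_bounds(bounds)
  n <- config$pop_size
  d <- length(bounds$lower)
  set.seed(config$seed)
  pop <- init_population(config, bounds, seed = NULL)
  fit <- numeric(n)
  for (i in seq_len(n)) {
    fit[i] <- eval_fitness(fitness_fn, pop[i, ], 0L, i)
  }
  best_idx <- which.min(fit)
  hist_rows <- list(data.frame(generation = 0L, best = min(fit),
                               mean = mean(fit), sd = sd(fit)))
  reason <- "max_iterations"
  last_gen <- 0L
  for (gen in seq_len(config$max_iter)) {
    for (i in seq_len(n)) {
      pool <- setdiff(seq_len(n), c(i, best_idx))
      ab <- pool[sample.int(length(pool), 2L)]
      donor <- mutate_best1(pop[best_idx, ], pop[ab[1L], ], pop[ab[2L], ],
                            config$scale_factor)
      trial <- crossover_bin(pop[i, ], donor, config$crossover_rate)
      trial <- repair_bounds(trial, bounds)
      ft <- eval_fitness(fitness_fn, trial, gen, i)
      if (ft < fit[i]) {
        pop[i, ] <- trial
        fit[i] <- ft
        if (ft < fit[best_idx]) best_idx <- i
      }
    }
    hist_rows[[gen + 1L]] <- data.frame(generation = gen, best = min(fit),
                                        mean = mean(fit), sd = sd(fit))
    last_gen <- gen
    if (fit[best_idx] <= config$error_threshold) {
      reason <- "threshold"
      break
    }
  }
  structure(list(
    best = list(vector = pop[best_idx, ], fitness = fit[best_idx]),
    best_bank = decode_vector(pop[best_idx, ]),
    history = do.call(rbind, hist_rows),
    seed = config$seed,
    config = config,
    termination_reason = reason,
    generations = last_gen
  ), class = "de_result")
}

eval_fitness <- function(fitness_fn, v, gen, i) {
  ft <- tryCatch(fitness_fn(v), error = function(e) {
    stop("fitness evaluation failed at generation ", gen, ", candidate ", i,
         ": ", conditionMessage(e), call. = FALSE)
  })
  if (!is.finite(ft) || ft < 0 || ft > 1) {
    stop("fitness must be a number in [0, 1]; got ", ft,
         " (generation ", gen, ", candidate ", i, ")")
  }
  ft
}

#' @export
print.de_result <- function(x, ...) {
  cat("DE run (seed ", x$seed, "): best fitness ",
      format(x$best$fitness, digits = 6), " after ", x$generations,
      " generation(s), stopped on ", x$termination_reason, "\n", sep = "")
  invisible(x)
}
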