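# The grammatical-evolution loop: tournament selection on niching-adjusted
# fitness, effective single-point crossover, integer-flipping mutation,
# elitism on nominal fitness, a deduplicated hall of fame, and stall-based
# stopping.

#' Evolution configuration
#'
#' Defaults are the standard protocol values: population 50, at most 100
#' generations with a 30-generation stall stop, tournament size 3,
#' crossover rate 0.7, mutation rate 0.015, one elite, codon size 256,
#' chromosome capacity 100, hall of fame of 20.
#'
#' @param population_size number of individuals (>= 2).
#' @param max_generations generation cap `G`.
#' @param stall_generations stop after this many generations without
#'   improvement of the best nominal fitness.
#' @param tournament_size tournament size `tau`.
#' @param crossover_rate probability `beta` that a selected pair is crossed.
#' @param mutation_rate per-codon replacement probability `alpha`.
#' @param elite_size individuals copied unmodified each generation (chosen
#'   by nominal fitness).
#' @param codon_size exclusive upper bound on codon values.
#' @param chromosome_capacity codons per chromosome.
#' @param hall_of_fame_size archive size.
#' @param memoize cache fitness by phenotype text across the run (proxy
#'   fitness is stochastic, so caching freezes the first draw; set FALSE
#'   to re-evaluate duplicates).
#' @param seed integer seed for the whole run.
#' @return a list of class `ge_config`.
#' @export
ge_config <- function(population_size = 50L, max_generations = 100L,
                      stall_generations = 30L, tournament_size = 3L,
                      crossover_rate = 0.7, mutation_rate = 0.015,
                      elite_size = 1L, codon_size = 256L,
                      chromosome_capacity = 100L, hall_of_fame_size = 20L,
                      memoize = TRUE, seed = 1L) {
  gn_assert(population_size >= 2, "population_size must be >= 2")
  gn_assert(tournament_size >= 1 && tournament_size <= population_size,
            "tournament_size must be in [1, population_size]")
  gn_assert(crossover_rate >= 0 && crossover_rate <= 1, "invalid crossover_rate")
  gn_assert(mutation_rate >= 0 && mutation_rate <= 1, "invalid mutation_rate")
  gn_assert(elite_size >= 0 && elite_size < population_size,
            "elite_size must be in [0, population_size)")
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 tournament_size = as.integer(tournament_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elite_size = as.integer(elite_size),
                 codon_size = as.integer(codon_size),
                 chromosome_capacity = as.integer(chromosome_capacity),
                 hall_of_fame_size = as.integer(hall_of_fame_size),
                 memoize = isTRUE(memoize), seed = as.integer(seed)),
            class = "ge_config")
}

#' Similarity between two phenotypes (niching kernel)
#'
#' 0 when the individuals differ in the number of convolutional or dense
#' layers; otherwise the fraction of positionally-aligned hyperparameter
#' slots (input setup, conv-layer fields in order, dense-layer fields in
#' order, learning setup) holding identical values.
#'
#' @param a,b `topology_spec`s, or individuals carrying complete
#'   derivations (`$derivation$phenotype`).
#' @return a number in `[0, 1]`.
#' @export
similarity <- function(a, b) {
  sa <- as_phenotype(a); sb <- as_phenotype(b)
  if (n_conv(sa) != n_conv(sb) || n_dense(sa) != n_dense(sb)) return(0)
  va <- phenotype_slots(sa); vb <- phenotype_slots(sb)
  sum(va == vb) / length(va)
}

as_phenotype <- function(x) {
  if (inherits(x, "topology_spec")) return(x)
  if (!is.null(x$derivation)) {
    if (is.null(x$derivation$phenotype))
      gn_stop("similarity undefined for incomplete derivations",
              "gennas_contract_error")
    return(x$derivation$phenotype)
  }
  gn_stop("cannot extract a phenotype", "gennas_argument_error")
}

#' Niching adjustment of a population's fitness
#'
#' Sets each individual's adjusted fitness to
#' `fa(i) = fn(i) * (1 - sum_{j != i} sim(i, j) / (|P| - 1))`. Nominal
#' fitness is unchanged. A population of one keeps `fa = fn`; pairs where
#' either derivation is incomplete contribute similarity 0.
#'
#' @param population list of individuals with `fn` set.
#' @return the population with `fa` set.
#' @export
adjust_fitness <- function(population) {
  P <- length(population)
  gn_assert(all(vapply(population, function(i) !is.null(i$fn), logical(1))),
            "all individuals must have nominal fitness set")
  if (P == 1) {
    population[[1]]$fa <- population[[1]]$fn
    return(population)
  }
  specs <- lapply(population, function(i) i$derivation$phenotype)
  sims <- matrix(0, P, P)
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    s <- if (is.null(specs[[i]]) || is.null(specs[[j]])) 0
         else similarity(specs[[i]], specs[[j]])
    sims[i, j] <- s; sims[j, i] <- s
  }
  for (i in seq_len(P))
    population[[i]]$fa <- population[[i]]$fn *
      (1 - sum(sims[i, -i]) / (P - 1))
  population
}

#' Tournament selection
#'
#' Draws `tau` members uniformly with replacement and returns the index of
#' the one with the highest fitness; ties are broken uniformly at random.
#'
#' @param population list of evaluated individuals.
#' @param tau tournament size.
#' @param key `"adjusted"` (default, selection fitness) or `"nominal"`.
#' @return the index of the winner in `population`.
#' @export
tournament_select <- function(population, tau, key = c("adjusted", "nominal")) {
  key <- match.arg(key)
  gn_assert(length(population) >= 1, "population must be non-empty")
  cand <- sample.int(length(population), tau, replace = TRUE)
  fit <- vapply(cand, function(i)
    if (key == "adjusted") population[[i]]$fa else population[[i]]$fn,
    numeric(1))
  best <- cand[fit == max(fit)]
  if (length(best) > 1) best <- best[sample.int(length(best), 1)]
  best[[1]]
}

#' Effective single-point crossover
#'
#' With probability `beta`, one cut point is drawn uniformly inside the
#' effective region -- `[1, min(used(p1), used(p2)) - 1]`, where `used` is
#' the number of codons each parent's derivation consumed -- and the
#' chromosome tails are exchanged, guaranteeing the crossover affects the
#' phenotype. Otherwise (or when no valid cut point exists) copies of the
#' parents are returned.
#'
#' @param p1,p2 individuals with derivations (codons_used known).
#' @param beta crossover probability.
#' @return list of two chromosomes, with attribute `crossed` (logical) and
#'   `cut` (the cut point or NA).
#' @export
crossover <- function(p1, p2, beta) {
  c1 <- p1$chromosome; c2 <- p2$chromosome
  used <- min(p1$derivation$codons_used, p2$derivation$codons_used)
  crossed <- FALSE; cut <- NA_integer_
  if (stats::runif(1) < beta && used >= 2) {
    cut <- sample.int(used - 1L, 1)
    k1 <- c(c1[seq_len(cut)], c2[(cut + 1L):length(c2)])
    k2 <- c(c2[seq_len(cut)], c1[(cut + 1L):length(c1)])
    c1 <- chromosome(k1, attr(p1$chromosome, "codon_size"),
                     attr(p1$chromosome, "capacity"))
    c2 <- chromosome(k2, attr(p2$chromosome, "codon_size"),
                     attr(p2$chromosome, "capacity"))
    crossed <- TRUE
  }
  structure(list(c1, c2), crossed = crossed, cut = cut)
}

#' Integer-flipping mutation
#'
#' Each codon is independently replaced, with probability `alpha`, by a new
#' uniform draw from `[0, codon_size)` (which may repeat the old value).
#' None, one, or several positions can mutate.
#'
#' @param chrom a `ge_chromosome`.
#' @param alpha per-codon mutation rate.
#' @return the mutated chromosome, with attribute `n_mutated` (number of
#'   positions redrawn).
#' @export
mutate <- function(chrom, alpha) {
  codon_size <- attr(chrom, "codon_size")
  hit <- stats::runif(length(chrom)) < alpha
  out <- unclass(chrom)
  attributes(out) <- NULL
  if (any(hit))
    out[hit] <- sample.int(codon_size, sum(hit), replace = TRUE) - 1L
  res <- chromosome(out, codon_size, attr(chrom, "capacity"))
  attr(res, "n_mutated") <- sum(hit)
  res
}

## ---- hall of fame ----------------------------------------------------------

#' Create an empty hall of fame
#' @param max_size archive capacity (default 20).
#' @return an object of class `hall_of_fame`.
#' @export
hall_of_fame <- function(max_size = 20L) {
  structure(list(entries = list(), max_size = as.integer(max_size)),
            class = "hall_of_fame")
}

#' Insert an individual into the hall of fame
#'
#' Entries are kept sorted by nominal fitness (descending) with at most one
#' entry per distinct phenotype: re-inserting an existing phenotype only
#' raises its recorded fitness (proxy fitness is stochastic). The archive
#' is truncated to its capacity.
#'
#' @param hof a [hall_of_fame()].
#' @param ind an evaluated individual with a complete derivation.
#' @return the updated hall of fame.
#' @export
update_hall_of_fame <- function(hof, ind) {
  stopifnot(inherits(hof, "hall_of_fame"))
  if (is.null(ind$derivation$phenotype) || is.null(ind$fn)) return(hof)
  txt <- phenotype_to_text(ind$derivation$phenotype)
  existing <- vapply(hof$entries, function(e) e$text, character(1))
  hit <- which(existing == txt)
  if (length(hit) == 1) {
    if (ind$fn > hof$entries[[hit]]$fn) hof$entries[[hit]]$fn <- ind$fn
  } else {
    hof$entries[[length(hof$entries) + 1]] <-
      list(phenotype = ind$derivation$phenotype, text = txt,
           chromosome = ind$chromosome, fn = ind$fn)
  }
  ord <- order(vapply(hof$entries, function(e) e$fn, numeric(1)),
               decreasing = TRUE)
  hof$entries <- hof$entries[ord]
  if (length(hof$entries) > hof$max_size)
    hof$entries <- hof$entries[seq_len(hof$max_size)]
  hof
}

#' @export
print.hall_of_fame <- function(x, ...) {
  cat("<hall_of_fame> ", length(x$entries), "/", x$max_size, " entries\n",
      sep = "")
  for (e in utils::head(x$entries, 5))
    cat(sprintf("  fn=%.4f  %s\n", e$fn, e$text))
  if (length(x$entries) > 5) cat("  ...\n")
  invisible(x)
}

## ---- the loop --------------------------------------------------------------

#' Run grammatical evolution
#'
#' Generational loop: random initial chromosomes; each generation decodes
#' and evaluates nominal fitness (incomplete derivations and failing
#' evaluations score 0), applies the niching adjustment, copies the top
#' `elite_size` individuals by nominal fitness unmodified, and fills the
#' rest by tournament selection on adjusted fitness, effective crossover
#' and mutation (elites are the only individuals never mutated). The hall
#' of fame archives the best distinct phenotypes seen. The run stops after
#' `max_generations`, or once the best nominal fitness has not improved for
#' `stall_generations` generations.
#'
#' @param config a [ge_config()].
#' @param fitness_fn function mapping a [topology_spec()] to a fitness in
#'   `[0, 1]`; errors inside it score 0 for that individual.
#' @param grammar a `ge_grammar` (default: the shipped topology grammar).
#' @param verbose print per-generation progress.
#' @return an object of class `ge_run`: list with `hall_of_fame`,
#'   `history` (data frame: `generation`, `best_fn`, `mean_fn`,
#'   `best_phenotype`), `population` (final, evaluated), `config`.
#' @export
evolve <- function(config, fitness_fn,
                   grammar = read_grammar(default_grammar_path()),
                   verbose = FALSE) {
  stopifnot(inherits(config, "ge_config"), is.function(fitness_fn))
  with_seed(config$seed, {
    cache <- new.env(parent = emptyenv())
    eval_ind <- function(chrom) {
      d <- decode_topology(chrom, grammar)
      fn <- if (!d$complete) 0 else {
        txt <- phenotype_to_text(d$phenotype)
        if (config$memoize && exists(txt, cache, inherits = FALSE)) {
          get(txt, cache, inherits = FALSE)
        } else {
          v <- tryCatch(fitness_fn(d$phenotype), error = function(e) {
            warning("fitness_fn failed (scored 0): ", conditionMessage(e))
            0
          })
          if (!is.finite(v)) v <- 0
          if (config$memoize) assign(txt, v, cache)
          v
        }
      }
      list(chromosome = chrom, derivation = d, fn = fn, fa = NULL)
    }
    pop <- lapply(seq_len(config$population_size), function(i)
      eval_ind(random_chromosome(config$codon_size,
                                 config$chromosome_capacity)))
    hof <- hall_of_fame(config$hall_of_fame_size)
    history <- NULL
    best_so_far <- -Inf; stall <- 0L
    for (gen in seq_len(config$max_generations)) {
      pop <- adjust_fitness(pop)
      for (ind in pop) hof <- update_hall_of_fame(hof, ind)
      fns <- vapply(pop, function(i) i$fn, numeric(1))
      # rank by nominal fitness, ties broken uniformly at random
      ord <- order(fns, stats::runif(length(fns)), decreasing = TRUE)
      best <- pop[[ord[[1]]]]
      best_txt <- if (!is.null(best$derivation$phenotype))
        phenotype_to_text(best$derivation$phenotype) else NA_character_
      history <- rbind(history, data.frame(
        generation = gen, best_fn = max(fns), mean_fn = mean(fns),
        best_phenotype = best_txt, stringsAsFactors = FALSE))
      if (verbose)
        message(sprintf("gen %3d  best %.4f  mean %.4f", gen, max(fns),
                        mean(fns)))
      if (max(fns) > best_so_far + 1e-12) {
        best_so_far <- max(fns); stall <- 0L
      } else stall <- stall + 1L
      if (gen == config$max_generations || stall >= config$stall_generations)
        break
      elites <- pop[ord[seq_len(config$elite_size)]]
      nxt <- elites
      while (length(nxt) < config$population_size) {
        i1 <- tournament_select(pop, config$tournament_size)
        i2 <- tournament_select(pop, config$tournament_size)
        kids <- crossover(pop[[i1]], pop[[i2]], config$crossover_rate)
        for (k in kids) {
          if (length(nxt) >= config$population_size) break
          nxt[[length(nxt) + 1]] <- eval_ind(mutate(k, config$mutation_rate))
        }
      }
      pop <- nxt
    }
    structure(list(hall_of_fame = hof, history = history, population = pop,
                   config = config), class = "ge_run")
  })
}

#' @export
print.ge_run <- function(x, ...) {
  cat("<ge_run> ", nrow(x$history), " generations, best fn = ",
      format(max(x$history$best_fn), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write run artifacts as delimited text
#'
#' @param run a `ge_run`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(run$history, file.path(dir, "history.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hof <- data.frame(
    rank = seq_along(run$hall_of_fame$entries),
    fn = vapply(run$hall_of_fame$entries, function(e) e$fn, numeric(1)),
    phenotype = vapply(run$hall_of_fame$entries, function(e) e$text,
                       character(1)),
    chromosome = vapply(run$hall_of_fame$entries, function(e)
      paste(as.integer(e$chromosome), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(hof, file.path(dir, "hall_of_fame.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
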