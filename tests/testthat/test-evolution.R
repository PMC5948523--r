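# Evolutionary operators, niching and the loop

test_that("similarity: self is 1, layer-count mismatch is 0, symmetric and bounded", {
  a <- tiny_spec()
  expect_identical(similarity(a, a), 1)
  b2 <- topology_spec(32, 24, 2,
                      list(conv_layer_spec(8, 3), conv_layer_spec(8, 3),
                           conv_layer_spec(8, 3)),
                      list(dense_layer_spec("GRU", 8)))
  b3 <- topology_spec(32, 24, 2, list(conv_layer_spec(8, 3)),
                      list(dense_layer_spec("GRU", 8),
                           dense_layer_spec("GRU", 8)))
  expect_identical(similarity(a, b2), 0)  # 1 vs 3 conv layers
  expect_identical(similarity(a, b3), 0)  # 1 vs 2 dense layers

  g <- read_grammar(default_grammar_path())
  set.seed(21)
  inds <- random_individuals(12, g)
  for (i in 1:11) for (j in (i + 1):12) {
    sij <- similarity(inds[[i]]$derivation$phenotype,
                      inds[[j]]$derivation$phenotype)
    expect_identical(sij, similarity(inds[[j]]$derivation$phenotype,
                                     inds[[i]]$derivation$phenotype))
    expect_gte(sij, 0); expect_lte(sij, 1)
    expect_equal(sij, oracle_similarity(inds[[i]]$derivation$phenotype,
                                        inds[[j]]$derivation$phenotype))
  }
})

test_that("two 1-conv/1-dense specs differing in exactly half their slots score 0.5", {
  # 14 slots: B,w,wstep + 4 conv + 5 dense + f,eta; change 7 of them
  a <- topology_spec(25, 8, 1, list(conv_layer_spec(8, 2, 1, "linear")),
                     list(dense_layer_spec("LSTM", 512, 0, "linear", "none")),
                     "Adam", 1e-3)
  b <- topology_spec(50, 16, 2, list(conv_layer_spec(16, 3, 2, "ReLU")),
                     list(dense_layer_spec("LSTM", 512, 0, "linear", "none")),
                     "Adam", 1e-3)
  expect_identical(similarity(a, b), 0.5)
})

test_that("adjust_fitness implements the niching formula", {
  g <- read_grammar(default_grammar_path())
  set.seed(31)
  for (rep in 1:30) {
    P <- sample(2:10, 1)
    pop <- random_individuals(P, g)
    adj <- adjust_fitness(pop)
    sims <- matrix(0, P, P); diag(sims) <- 1
    for (i in seq_len(P)) for (j in seq_len(P)) if (i != j)
      sims[i, j] <- oracle_similarity(pop[[i]]$derivation$phenotype,
                                      pop[[j]]$derivation$phenotype)
    want <- oracle_adjust(vapply(pop, `[[`, numeric(1), "fn"), sims)
    got <- vapply(adj, `[[`, numeric(1), "fa")
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got <= vapply(adj, `[[`, numeric(1), "fn") + 1e-12))
  }
})

test_that("adjust_fitness: identical population collapses to 0, dissimilar keeps fn", {
  base <- list(chromosome = NULL,
               derivation = list(complete = TRUE, phenotype = tiny_spec()),
               fn = 0.8, fa = NULL)
  same <- adjust_fitness(list(base, base, base))
  expect_equal(vapply(same, `[[`, numeric(1), "fa"), c(0, 0, 0))

  specs <- list(tiny_spec(),
                topology_spec(32, 24, 2,
                              list(conv_layer_spec(8, 3), conv_layer_spec(8, 3)),
                              list(dense_layer_spec("GRU", 8))),
                topology_spec(32, 24, 2,
                              list(conv_layer_spec(8, 3), conv_layer_spec(8, 3),
                                   conv_layer_spec(8, 3)),
                              list(dense_layer_spec("GRU", 8))))
  pop <- lapply(seq_along(specs), function(i)
    list(chromosome = NULL,
         derivation = list(complete = TRUE, phenotype = specs[[i]]),
         fn = c(0.8, 0.6, 0.4)[[i]], fa = NULL))
  adj <- adjust_fitness(pop)
  expect_equal(vapply(adj, `[[`, numeric(1), "fa"), c(0.8, 0.6, 0.4))

  single <- adjust_fitness(list(base))
  expect_identical(single[[1]]$fa, 0.8)
})

test_that("tournament selection: dominance, tau=1 uniformity, tie-breaks", {
  pop <- lapply(1:10, function(i)
    list(chromosome = NULL, derivation = NULL, fn = i / 10, fa = i / 10))
  set.seed(41)
  # selection pressure: tournament winners outscore the population mean
  winners <- replicate(2000, tournament_select(pop, tau = 3))
  expect_gt(mean(vapply(winners, function(i) pop[[i]]$fa, numeric(1))),
            mean(vapply(pop, `[[`, numeric(1), "fa")))
  # a strictly dominant individual wins every tournament it is drawn into:
  # with tau = |P| and a unique maximum, it wins with probability
  # 1 - ((P-1)/P)^P; when it loses it is because it was never drawn
  dom <- pop; dom[[10]]$fa <- 10
  w10 <- replicate(2000, tournament_select(dom, tau = 10))
  p_hit <- 1 - (9 / 10)^10
  expect_lt(abs(mean(w10 == 10) - p_hit),
            3 * sqrt(p_hit * (1 - p_hit) / 2000))
  # tau = 1 is uniform selection
  picks <- replicate(5000, tournament_select(pop, tau = 1))
  expect_gt(min(table(factor(picks, levels = 1:10))), 5000 / 10 * 0.7)
  # ties broken randomly, not by list order
  tied <- lapply(1:4, function(i)
    list(chromosome = NULL, derivation = NULL, fn = 0.5, fa = 0.5))
  picks <- replicate(2000, tournament_select(tied, tau = 4))
  expect_true(all(table(factor(picks, levels = 1:4)) > 0))
})

test_that("crossover: beta=0 copies, mechanics at a forced cut, effective region", {
  g <- read_grammar(default_grammar_path())
  set.seed(51)
  inds <- random_individuals(2, g)
  p1 <- inds[[1]]; p2 <- inds[[2]]
  kids <- crossover(p1, p2, beta = 0)
  expect_identical(as.integer(kids[[1]]), as.integer(p1$chromosome))
  expect_identical(as.integer(kids[[2]]), as.integer(p2$chromosome))
  expect_false(attr(kids, "crossed"))

  kids <- crossover(p1, p2, beta = 1)
  cut <- attr(kids, "cut")
  expect_true(attr(kids, "crossed"))
  expect_identical(as.integer(kids[[1]]),
                   c(as.integer(p1$chromosome)[1:cut],
                     as.integer(p2$chromosome)[(cut + 1):100]))
  expect_identical(as.integer(kids[[2]]),
                   c(as.integer(p2$chromosome)[1:cut],
                     as.integer(p1$chromosome)[(cut + 1):100]))

  for (r in 1:300) {
    pr <- random_individuals(2, g)
    kids <- crossover(pr[[1]], pr[[2]], beta = 1)
    m <- min(pr[[1]]$derivation$codons_used, pr[[2]]$derivation$codons_used)
    if (attr(kids, "crossed")) expect_lt(attr(kids, "cut"), m)
  }
})

test_that("mutation: zero rate is identity, rate 1 on binary codons flips about half", {
  ch <- chromosome(rep(0L, 100), codon_size = 2, capacity = 100)
  set.seed(61)
  expect_identical(as.integer(mutate(ch, 0)), rep(0L, 100))
  flips <- replicate(200, sum(as.integer(mutate(ch, 1))))
  # each position redrawn uniformly from {0,1}: Binomial(100, 0.5)
  expect_lt(abs(mean(flips) - 50), 3 * sd(flips) / sqrt(length(flips)) + 1)
})

test_that("hall of fame inserts, deduplicates and truncates", {
  hof <- hall_of_fame(20)
  g <- read_grammar(default_grammar_path())
  set.seed(71)
  ind <- random_individuals(1, g)[[1]]
  hof <- update_hall_of_fame(hof, ind)
  expect_length(hof$entries, 1)
  # duplicate phenotype with equal fitness: unchanged
  hof2 <- update_hall_of_fame(hof, ind)
  expect_identical(hof, hof2)
  # duplicate with higher fitness only raises the recorded value
  better <- ind; better$fn <- ind$fn + 0.1
  hof3 <- update_hall_of_fame(hof, better)
  expect_length(hof3$entries, 1)
  expect_equal(hof3$entries[[1]]$fn, ind$fn + 0.1)

  # 30 distinct phenotypes with fn = k/30: archive keeps the top 20 sorted
  inds <- random_individuals(60, g)
  texts <- vapply(inds, function(i) phenotype_to_text(i$derivation$phenotype),
                  character(1))
  inds <- inds[!duplicated(texts)][1:30]
  for (k in 1:30) inds[[k]]$fn <- k / 30
  hof <- hall_of_fame(20)
  for (ind in inds) hof <- update_hall_of_fame(hof, ind)
  fns <- vapply(hof$entries, `[[`, numeric(1), "fn")
  expect_length(fns, 20)
  expect_equal(fns, sort((11:30) / 30, decreasing = TRUE))
})

test_that("evolve: stall stop, optimizable landscape, determinism, monotone best", {
  g <- read_grammar(default_grammar_path())
  cfg <- ge_config(population_size = 10, max_generations = 50,
                   stall_generations = 5, seed = 81)
  run <- evolve(cfg, function(spec) 0.5, grammar = g)
  expect_identical(nrow(run$history), cfg$stall_generations + 1L)
  expect_equal(max(run$history$best_fn), 0.5)

  # fitness depending only on one decoded field is quickly optimized
  fit <- function(spec) spec$conv_layers[[1]]$kernels / 256
  cfg2 <- ge_config(population_size = 20, max_generations = 40,
                    stall_generations = 40, seed = 82)
  run2 <- evolve(cfg2, fit, grammar = g)
  expect_equal(max(run2$history$best_fn), 1)
  expect_true(all(diff(run2$history$best_fn) >= 0))

  run3 <- evolve(cfg2, fit, grammar = g)
  expect_identical(run2$history, run3$history)
})

test_that("evolve maps fitness errors to 0 and keeps going", {
  g <- read_grammar(default_grammar_path())
  cfg <- ge_config(population_size = 6, max_generations = 3,
                   stall_generations = 3, seed = 91)
  boom <- function(spec) if (n_conv(spec) >= 2) stop("boom") else 0.4
  expect_warning(run <- evolve(cfg, boom, grammar = g), "scored 0")
  expect_true(all(run$history$best_fn <= 0.4))
})
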