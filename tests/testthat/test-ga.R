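test_that("the pair contribution follows the award/penalty rule", {
  ctl <- ga_control()
  expect_equal(pair_term(0.3, 0.1, 0.2, 0.9, ctl), -5)   # |dp| = 0.2
  expect_equal(pair_term(0.05, 0.0, 0.4, 0.4, ctl), 5)   # equal descriptors
  expect_equal(pair_term(0.05, 0.0, 0.3, 0.8, ctl), 4.5)
  # branch switch is exactly at epsilon
  expect_equal(pair_term(0.1, 0.0, 0, 0, ctl), -5)
  expect_equal(pair_term(0.0999999, 0.0, 0, 0, ctl), 5)
  # vectorized and pure
  expect_equal(pair_term(c(0.3, 0.05), c(0.1, 0.0), c(0.2, 0.3), c(0.9, 0.8), ctl),
               c(-5, 4.5))
})

test_that("chromosome fitness reproduces hand-computed worked examples", {
  d <- worked_example_dataset()
  expect_equal(chromosome_fitness(c(1, 1), d), (4.9 + 5) + (-5 - 5) + (-5 - 5))
  expect_equal(chromosome_fitness(c(1, 0), d), 4.9 - 5 - 5)
  expect_identical(chromosome_fitness(c(0, 0), d), 0)
  expect_error(chromosome_fitness(c(1, 1, 1), d), "length")
  expect_error(chromosome_fitness(c(1, 2), d), "0 or 1")
})

test_that("vectorized fitness equals the brute-force triple-loop oracle exactly", {
  for (seed in 1:30) {
    inst <- random_instance(seed)
    expect_identical(chromosome_fitness(inst$genes, inst$data),
                     naive_fitness(inst$genes, inst$data))
  }
})

test_that("the once-per-pair penalty variant matches its own oracle", {
  ctl <- ga_control(penalty_per_pair = TRUE)
  for (seed in 31:40) {
    inst <- random_instance(seed)
    expect_equal(chromosome_fitness(inst$genes, inst$data, ctl),
                 naive_fitness_per_pair(inst$genes, inst$data, ctl))
  }
})

test_that("fitness is additive over disjoint descriptor sets", {
  for (seed in 41:50) {
    inst <- random_instance(seed)
    D <- length(inst$genes)
    a <- b <- numeric(D)
    on <- which(inst$genes == 1)
    if (length(on) < 2) next
    half <- seq_len(length(on) %/% 2)
    a[on[half]] <- 1
    b[on[-half]] <- 1
    expect_equal(chromosome_fitness(inst$genes, inst$data),
                 chromosome_fitness(a, inst$data) +
                   chromosome_fitness(b, inst$data))
  }
})

test_that("initial populations are fair coin flips, reproducible by seed", {
  ctl <- ga_control(population_size = 100, seed = 7)
  pop <- init_population(200, ctl)
  expect_s3_class(pop, "qspkr_population")
  expect_identical(dim(pop$chromosomes), c(100L, 200L))
  expect_true(all(pop$chromosomes %in% c(0, 1)))
  expect_identical(pop$generation, 0L)
  pop2 <- init_population(200, ctl)
  expect_identical(pop$chromosomes, pop2$chromosomes)
  expect_lt(abs(mean(pop$chromosomes) - 0.5), 0.01)
  expect_error(init_population(0, ctl), "at least 1")
})

test_that("single-point crossover swaps tails at the break point and conserves bits", {
  ctl <- ga_control()
  a <- c(0, 0, 0, 0, 0, 0); b <- c(1, 1, 1, 1, 1, 1)
  for (seed in 1:10) {
    set.seed(seed)
    kids <- crossover(a, b, ctl)
    bp <- kids$break_point
    expect_true(bp >= 1 && bp <= 5)
    expect_identical(kids$child1, c(a[seq_len(bp)], b[(bp + 1):6]))
    expect_identical(kids$child2, c(b[seq_len(bp)], a[(bp + 1):6]))
    expect_equal(sum(kids$child1) + sum(kids$child2), sum(a) + sum(b))
  }
  # identical parents are unchanged for any break point
  set.seed(1)
  same <- crossover(b, b, ctl)
  expect_identical(same$child1, b)
  expect_identical(same$child2, b)
  # crossover probability zero copies the parents
  set.seed(2)
  none <- crossover(a, b, ga_control(crossover_probability = 0))
  expect_identical(none$child1, a)
  expect_true(is.na(none$break_point))
  expect_error(crossover(a, c(1, 0), ctl), "equal length")
})

test_that("mutation touches at most one bit, at the configured rate", {
  g <- rbinom(50, 1, 0.5)
  set.seed(3)
  for (i in 1:50)
    expect_identical(mutate(g, ga_control(mutation_probability = 0)), g)
  set.seed(4)
  for (i in 1:50)
    expect_equal(sum(mutate(g, ga_control(mutation_probability = 1)) != g), 1)
  set.seed(5)
  changed <- sum(vapply(1:20000, function(i) any(mutate(g, ga_control()) != g),
                        logical(1)))
  # 99% binomial interval around 0.1 for 20000 draws is +/- 0.0055
  expect_lt(abs(changed / 20000 - 0.1), 0.0075)
})

test_that("one generation step preserves population size under both schemes", {
  d <- small_synth(1, n = 20, D = 40, n_inf = 3)$data
  for (scheme in c("penalized", "fitness")) {
    ctl <- ga_control(population_size = 30, selection = scheme, seed = 9)
    pop <- init_population(ncol(d$X), ctl)
    pop$fitness <- vapply(seq_len(30),
                          function(i) chromosome_fitness(pop$chromosomes[i, ], d, ctl),
                          numeric(1))
    set.seed(10)
    nxt <- select_next_generation(pop, d, ctl)
    expect_identical(dim(nxt$chromosomes), dim(pop$chromosomes))
    expect_identical(nxt$generation, 1L)
  }
  expect_error(select_next_generation(init_population(40, ga_control(seed = 1)), d),
               "evaluated")
})

test_that("elitist raw-fitness evolution never loses the best fitness", {
  d <- small_synth(2, n = 20, D = 40, n_inf = 3)$data
  ctl <- ga_control(population_size = 40, selection = "fitness",
                    elitism_count = 1, seed = 11)
  pop <- init_population(ncol(d$X), ctl)
  best <- -Inf
  for (gen in 1:8) {
    pop$fitness <- vapply(seq_len(40),
                          function(i) chromosome_fitness(pop$chromosomes[i, ], d, ctl),
                          numeric(1))
    expect_gte(max(pop$fitness), best)
    best <- max(max(pop$fitness), best)
    pop <- select_next_generation(pop, d, ctl)
  }
})

test_that("a full GA run is reproducible and respects the gene limit", {
  synth <- small_synth(3, n = 30, D = 60, n_inf = 4)
  a <- run_ga(synth$data, ga_control(seed = 5))
  b <- run_ga(synth$data, ga_control(seed = 5))
  expect_identical(a$selected, b$selected)
  expect_identical(a$fitness_trajectory, b$fitness_trajectory)
  expect_identical(a$termination, "gene_limit")
  expect_lte(length(a$selected), 15)
  expect_identical(a$selected, sort(a$selected))
  expect_identical(a$selected_names, synth$data$descriptor_names[a$selected])
  expect_error(run_ga(synth$data, ga_control(gene_limit = 100)),
               "fewer descriptors")
})

test_that("a dataset with no similar-PK pair triggers a warning but still runs", {
  # five compounds, one per cluster: every normalized PK difference >= epsilon
  d <- tiny_dataset(dp = c(0, 0.25, 0.5, 0.75, 1),
                    X = matrix(runif(5 * 20, min = 0, max = 1), 5, 20))
  expect_warning(res <- run_ga(d, ga_control(population_size = 50,
                                             max_generations = 100, seed = 2)),
                 "award branch")
  expect_lte(length(res$selected), 15)
})

test_that("constant descriptors are never selected", {
  synth <- small_synth(4, n = 25, D = 50, n_inf = 3)
  d <- synth$data
  d$X[, 7] <- 0
  d$constant[7] <- TRUE
  res <- run_ga(d, ga_control(seed = 3))
  expect_false(7 %in% res$selected)
})
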