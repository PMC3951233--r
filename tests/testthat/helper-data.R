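# Shared fixtures and independent oracles, built in code.

# A qspkr_dataset assembled by hand from already-normalized values.
tiny_dataset <- function(dp, X, constant = rep(FALSE, ncol(X))) {
  X <- as.matrix(X)
  structure(list(
    compound_ids = sprintf("c%02d", seq_along(dp)),
    descriptor_names = sprintf("d%03d", seq_len(ncol(X))),
    X = X, dp = as.numeric(dp),
    scale_x = data.frame(column = sprintf("d%03d", seq_len(ncol(X))),
                         min = 0, max = 1),
    scale_pk = data.frame(column = "pk", min = 0, max = 1),
    constant = constant, pk_name = "pk", pk_unit = NA_character_),
    class = "qspkr_dataset")
}

# The three-compound, two-descriptor worked example.
worked_example_dataset <- function() {
  tiny_dataset(dp = c(0, 0.05, 0.5),
               X = cbind(c(0.1, 0.2, 0.9), c(0.5, 0.5, 0.5)))
}

# Independent brute-force oracle for the triple-sum fitness: loops over
# included descriptors and all unordered compound pairs, accumulating
# term by term.
naive_fitness <- function(genes, data, control = ga_control()) {
  n <- nrow(data$X)
  acc <- 0
  for (k in which(genes == 1)) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        acc <- acc + if (abs(data$dp[i] - data$dp[j]) >= control$epsilon)
          -control$penalty
        else control$award - abs(data$X[i, k] - data$X[j, k])
      }
    }
  }
  acc
}

# Oracle for the once-per-pair penalty reading.
naive_fitness_per_pair <- function(genes, data, control) {
  n <- nrow(data$X)
  acc <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (abs(data$dp[i] - data$dp[j]) >= control$epsilon) {
        if (sum(genes) > 0) acc <- acc - control$penalty
      } else {
        for (k in which(genes == 1))
          acc <- acc + control$award - abs(data$X[i, k] - data$X[j, k])
      }
    }
  }
  acc
}

random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:10, 1)
  D <- sample(2:10, 1)
  list(data = tiny_dataset(runif(n), matrix(runif(n * D), n, D)),
       genes = rbinom(D, 1, 0.5))
}

# A small planted benchmark used by recovery-style tests.
small_synth <- function(seed, n = 40L, D = 200L, n_inf = 5L,
                        noise_sd = 0.05) {
  generate_dataset(synthetic_spec(n_compounds = n, n_descriptors = D,
                                  n_informative = n_inf,
                                  noise_sd = noise_sd, seed = seed))
}
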