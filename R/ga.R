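# Genetic-algorithm descriptor selection with the award/penalty
# pairwise fitness function.
#
# A chromosome is a binary inclusion mask over descriptor columns.  For
# every unordered compound pair (i, j) and every included descriptor k
# the pair contributes
#
#     F(i, j, k) = -penalty                      if |dp_i - dp_j| >= epsilon
#                = award - |dd_ik - dd_jk|       if |dp_i - dp_j| <  epsilon
#
# and the chromosome fitness is the triple sum of F over pairs and
# included descriptors.  Because F never depends on the other included
# descriptors, fitness is additive over descriptors: each descriptor
# has a fixed marginal contribution, precomputed once per dataset so a
# population is scored with a single matrix-vector product.

#' Genetic-algorithm control parameters
#'
#' @param population_size Number of chromosomes per generation (default 500).
#' @param crossover_probability Probability that a selected parent pair
#'   is recombined rather than copied (default 1: always).
#' @param mutation_probability Probability that the single randomly
#'   chosen gene of a chromosome is flipped (default 0.1).
#' @param award Score added per included descriptor for a compound pair
#'   whose normalized PK values differ by less than `epsilon`
#'   (default 5); the pair's descriptor difference is subtracted from it.
#' @param penalty Score subtracted for a pair whose normalized PK
#'   values differ by at least `epsilon` (default 5).
#' @param epsilon Normalized-PK-difference threshold separating the
#'   award and penalty branches (default 0.1).
#' @param gene_limit Termination threshold: the run stops once the best
#'   chromosome includes at most this many descriptors (default 15).
#' @param max_generations Safety cap on generations (default 500).
#' @param elitism_count Number of best chromosomes copied unchanged
#'   into the next generation (default 1).
#' @param penalty_per_pair If `TRUE`, a dissimilar-PK pair is penalized
#'   once regardless of how many descriptors are included (an
#'   alternative reading of the fitness description); default `FALSE`
#'   applies the penalty per included descriptor, as the summation
#'   formula indexes the contribution by descriptor.
#' @param fitness_rows Optional row indices restricting the compound
#'   pairs used in fitness evaluation (e.g. a training fold); default
#'   uses all compounds.
#' @param selection Chromosome ranking used by survivor and parent
#'   selection.  `"penalized"` (default) ranks by the per-descriptor
#'   average score with a logarithmic subset-size penalty (see
#'   Details); `"fitness"` ranks by raw fitness with a
#'   binary-tournament generational scheme.
#' @param size_penalty Multiplier on the standard deviation of the
#'   per-descriptor marginal scores that sets the size-penalty weight
#'   `lambda` for `selection = "penalized"` (default 1.5).
#' @param breeding_fraction Fraction of the population (best-ranked
#'   first) used as the breeding pool under `selection = "penalized"`
#'   (default 0.1).
#' @param seed Optional integer seed making the run reproducible.
#'
#' @details
#' Because every descriptor's contribution to the fitness enters as a
#' fixed (almost always negative) marginal, raw-fitness selection
#' pressure is dominated by how many descriptors a chromosome carries,
#' not which ones: subsets shrink while their composition drifts at
#' random.  The default `"penalized"` ranking therefore compares
#' chromosomes on their average per-descriptor score plus
#' `lambda * log(size)`, with `lambda = size_penalty * sd(marginals)`.
#' Removing a typical descriptor always improves this score, so subsets
#' keep shrinking toward the gene limit, while a descriptor whose
#' marginal score is an outlier (better than the bulk by more than a
#' few standard deviations) is never profitably removed and is
#' re-admitted if lost.  The raw-fitness scheme is retained for
#' comparison; its degeneration is demonstrated in the package
#' vignette.
#' @return A validated list of class `qspkr_ga_control`.
#' @export
ga_control <- function(population_size = 500L,
                       crossover_probability = 1,
                       mutation_probability = 0.1,
                       award = 5,
                       penalty = 5,
                       epsilon = 0.1,
                       gene_limit = 15L,
                       max_generations = 500L,
                       elitism_count = 1L,
                       penalty_per_pair = FALSE,
                       fitness_rows = NULL,
                       selection = c("penalized", "fitness"),
                       size_penalty = 1.5,
                       breeding_fraction = 0.1,
                       seed = NULL) {
  ctl <- list(population_size = as.integer(population_size),
              crossover_probability = crossover_probability,
              mutation_probability = mutation_probability,
              award = award, penalty = penalty, epsilon = epsilon,
              gene_limit = as.integer(gene_limit),
              max_generations = as.integer(max_generations),
              elitism_count = as.integer(elitism_count),
              penalty_per_pair = isTRUE(penalty_per_pair),
              fitness_rows = fitness_rows,
              selection = match.arg(selection),
              size_penalty = size_penalty,
              breeding_fraction = breeding_fraction,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(ctl$population_size >= 2L,
            ctl$crossover_probability >= 0, ctl$crossover_probability <= 1,
            ctl$mutation_probability >= 0, ctl$mutation_probability <= 1,
            ctl$award >= 0, ctl$penalty >= 0,
            ctl$epsilon > 0, ctl$epsilon < 1,
            ctl$gene_limit >= 1L, ctl$max_generations >= 1L,
            ctl$elitism_count >= 0L,
            ctl$elitism_count < ctl$population_size,
            ctl$size_penalty > 0,
            ctl$breeding_fraction > 0, ctl$breeding_fraction <= 1)
  class(ctl) <- "qspkr_ga_control"
  ctl
}

#' Per-pair fitness contribution of one descriptor
#'
#' Pure, vectorized evaluation of the award/penalty rule for a single
#' descriptor and one (or several) compound pairs.
#'
#' @param dp_i,dp_j Normalized pharmacokinetic values of the two
#'   compounds, in `[0, 1]`.
#' @param dd_ik,dd_jk Normalized values of descriptor `k` for the two
#'   compounds, in `[0, 1]`.
#' @param control A [ga_control()] object supplying `award`, `penalty`
#'   and `epsilon`.
#' @return Numeric score(s): `-penalty` where `|dp_i - dp_j| >= epsilon`,
#'   `award - |dd_ik - dd_jk|` otherwise.
#' @export
pair_term <- function(dp_i, dp_j, dd_ik, dd_jk, control = ga_control()) {
  ifelse(abs(dp_i - dp_j) >= control$epsilon,
         -control$penalty,
         control$award - abs(dd_ik - dd_jk))
}

# All unordered pairs i < j of rows, in the canonical loop order
# (i ascending, then j ascending), plus the award-branch mask.
pair_index <- function(dp, epsilon, rows = NULL) {
  if (is.null(rows)) rows <- seq_along(dp)
  n <- length(rows)
  if (n < 2L) stop("need at least two compounds to form pairs")
  i <- rep.int(rows[seq_len(n - 1L)], times = (n - 1L):1L)
  j <- rows[unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n),
                   use.names = FALSE)]
  list(i = i, j = j, award = abs(dp[i] - dp[j]) < epsilon)
}

# Per-descriptor marginal fitness contributions, plus the weight of
# the logarithmic size penalty used by "penalized" selection.
fitness_context <- function(data, control) {
  pr <- pair_index(data$dp, control$epsilon, control$fitness_rows)
  n_award <- sum(pr$award)
  n_pen <- length(pr$i) - n_award
  Xa_i <- data$X[pr$i[pr$award], , drop = FALSE]
  Xa_j <- data$X[pr$j[pr$award], , drop = FALSE]
  award_part <- control$award * n_award - colSums(abs(Xa_i - Xa_j))
  marg <- if (control$penalty_per_pair) award_part
          else award_part - control$penalty * n_pen
  live <- if (any(data$constant)) marg[!data$constant] else marg
  s <- if (length(live) > 1L) stats::sd(live) else 0
  lambda <- max(control$size_penalty * s,
                1e-8 * (1 + abs(mean(live))))  # floor keeps size pressure alive
  list(marginal = marg, lambda = lambda,
       n_award_pairs = n_award, n_penalty_pairs = n_pen,
       n_pairs = length(pr$i))
}

# Size-penalized selection score (lower is better): average
# per-descriptor cost plus lambda * log(size).  An empty chromosome is
# not a candidate model and scores worst.
selection_score <- function(fitness, gene_counts, ctx) {
  ifelse(gene_counts > 0,
         -fitness / gene_counts + ctx$lambda * log(gene_counts),
         Inf)
}

population_fitness <- function(pop, ctx, control) {
  f <- as.numeric(pop %*% ctx$marginal)
  if (control$penalty_per_pair)
    f <- f - control$penalty * ctx$n_penalty_pairs * (rowSums(pop) > 0)
  f
}

#' Fitness of a single chromosome
#'
#' Sums the award/penalty contribution of every unordered compound pair
#' for every descriptor included in the chromosome.  An all-zero
#' chromosome has fitness 0.  Identical (to the last bit) to a naive
#' triple loop over descriptors and pairs.
#'
#' @param genes Binary vector, one gene per descriptor column of `data`
#'   (1 = descriptor included).
#' @param data A `qspkr_dataset`.
#' @param control A [ga_control()] object.
#' @return The scalar fitness score.
#' @export
chromosome_fitness <- function(genes, data, control = ga_control()) {
  genes <- check_genes(genes, ncol(data$X))
  ctx <- fitness_context(data, control)
  as.numeric(population_fitness(matrix(genes, nrow = 1L), ctx, control))
}

check_genes <- function(genes, n_descriptors) {
  genes <- as.numeric(genes)
  if (length(genes) != n_descriptors)
    stop(sprintf("chromosome length %d does not match descriptor count %d",
                 length(genes), n_descriptors))
  if (!all(genes %in% c(0, 1))) stop("genes must be 0 or 1")
  genes
}

#' Random initial population
#'
#' Every gene of every chromosome is an independent fair coin flip, so
#' initial chromosomes include about half of all descriptors.
#'
#' @param n_descriptors Number of descriptor columns (chromosome length).
#' @param control A [ga_control()] object; `population_size` sets the
#'   number of chromosomes and `seed` (if non-NULL) makes the draw
#'   reproducible.
#' @return An object of class `qspkr_population`: list with
#'   `chromosomes` (a `population_size` x `n_descriptors` 0/1 matrix),
#'   `generation = 0` and an empty `fitness` ledger.
#' @export
init_population <- function(n_descriptors, control = ga_control()) {
  n_descriptors <- as.integer(n_descriptors)
  if (n_descriptors < 1L) stop("n_descriptors must be at least 1")
  if (!is.null(control$seed)) set.seed(control$seed)
  chrom <- matrix(sample(c(0, 1), control$population_size * n_descriptors,
                         replace = TRUE),
                  nrow = control$population_size)
  structure(list(chromosomes = chrom, generation = 0L, fitness = NULL),
            class = "qspkr_population")
}

#' @export
print.qspkr_population <- function(x, ...) {
  cat(sprintf("<qspkr_population> %d chromosomes x %d genes, generation %d%s\n",
              nrow(x$chromosomes), ncol(x$chromosomes), x$generation,
              if (is.null(x$fitness)) " (unevaluated)" else
                sprintf(", best fitness %g", max(x$fitness))))
  invisible(x)
}

#' Single-point crossover
#'
#' With probability `crossover_probability` a break point is drawn
#' uniformly from the interior positions `1..L-1` (both segments
#' non-empty) and the two parents exchange tails: the first child takes
#' positions `1..b` from `parent_a` and `b+1..L` from `parent_b`, the
#' second child the reverse.  Otherwise the parents are returned
#' unchanged.  Uses the current RNG state.
#'
#' @param parent_a,parent_b Binary gene vectors of equal length.
#' @param control A [ga_control()] object.
#' @return A list with elements `child1`, `child2` and `break_point`
#'   (`NA` if no crossover happened).
#' @export
crossover <- function(parent_a, parent_b, control = ga_control()) {
  L <- length(parent_a)
  if (length(parent_b) != L) stop("parent chromosomes must have equal length")
  if (L < 2L) stop("chromosomes must have at least two genes to recombine")
  if (stats::runif(1) <= control$crossover_probability) {
    b <- sample.int(L - 1L, 1L)
    list(child1 = c(parent_a[seq_len(b)], parent_b[(b + 1L):L]),
         child2 = c(parent_b[seq_len(b)], parent_a[(b + 1L):L]),
         break_point = b)
  } else {
    list(child1 = parent_a, child2 = parent_b, break_point = NA_integer_)
  }
}

#' Point mutation
#'
#' One gene position is chosen uniformly at random; with probability
#' `mutation_probability` that single bit is flipped, otherwise the
#' chromosome is returned unchanged.  The output therefore differs from
#' the input in at most one position.  Uses the current RNG state.
#'
#' @param genes Binary gene vector.
#' @param control A [ga_control()] object.
#' @return The (possibly) mutated gene vector.
#' @export
mutate <- function(genes, control = ga_control()) {
  if (length(genes) < 1L) stop("chromosome must be non-empty")
  pos <- sample.int(length(genes), 1L)
  if (stats::runif(1) < control$mutation_probability)
    genes[pos] <- 1 - genes[pos]
  genes
}

# Rank chromosomes: higher fitness first; ties broken by fewer genes,
# then by lexicographically smaller bit string (parsimony pressure).
rank_population <- function(chrom, fitness) {
  gene_counts <- rowSums(chrom)
  ord <- order(-fitness, gene_counts)
  # lexicographic tie-break only among rows still tied after the first
  # two keys (rare; usually identical clones)
  key <- paste(-fitness, gene_counts)[ord]
  ties <- split(seq_along(ord), factor(key, levels = unique(key)))
  for (grp in ties) {
    if (length(grp) > 1L) {
      lex <- do.call(order, as.data.frame(chrom[ord[grp], , drop = FALSE]))
      ord[grp] <- ord[grp][lex]
    }
  }
  ord
}

# Binary tournament: higher fitness wins, fewer genes breaks ties,
# lower index breaks exact ties.
tournament_pick <- function(fitness, gene_counts, n, N) {
  a <- sample.int(N, n, replace = TRUE)
  b <- sample.int(N, n, replace = TRUE)
  a_wins <- fitness[a] > fitness[b] |
    (fitness[a] == fitness[b] & gene_counts[a] <= gene_counts[b])
  ifelse(a_wins, a, b)
}

breed_children <- function(chrom, parent_idx, control) {
  n_pairs <- length(parent_idx) %/% 2L
  kids <- matrix(0, 2L * n_pairs, ncol(chrom))
  row <- 0L
  for (p in seq_len(n_pairs)) {
    cr <- crossover(chrom[parent_idx[2L * p - 1L], ],
                    chrom[parent_idx[2L * p], ], control)
    kids[row + 1L, ] <- mutate(cr$child1, control)
    kids[row + 2L, ] <- mutate(cr$child2, control)
    row <- row + 2L
  }
  kids
}

# One generation under "penalized" selection: breed from the top
# breeding_fraction of the current population, then keep the best
# population_size chromosomes among parents and children, preferring
# distinct genotypes (identical fitness is used as a cheap genotype
# fingerprint) so the survivor set does not fill up with copies.
next_generation_penalized <- function(chrom, fitness, ctx, control) {
  N <- control$population_size
  g <- rowSums(chrom)
  ord <- order(selection_score(fitness, g, ctx), g)
  pool <- ord[seq_len(max(2L, ceiling(control$breeding_fraction * N)))]
  parents <- pool[sample.int(length(pool), 2L * ceiling(N / 2), replace = TRUE)]
  kids <- breed_children(chrom, parents, control)
  all_chrom <- rbind(chrom, kids)
  fa <- as.numeric(all_chrom %*% ctx$marginal)
  if (control$penalty_per_pair)
    fa <- fa - control$penalty * ctx$n_penalty_pairs * (rowSums(all_chrom) > 0)
  ga <- rowSums(all_chrom)
  ordk <- order(selection_score(fa, ga, ctx), ga)
  dup <- duplicated(fa[ordk])
  keep <- c(ordk[!dup], ordk[dup])[seq_len(N)]
  list(chromosomes = all_chrom[keep, , drop = FALSE], fitness = fa[keep])
}

# One generation under classic raw-fitness selection: elitism plus
# binary-tournament parents, generational replacement.
next_generation_fitness <- function(chrom, fitness, ctx, control) {
  N <- control$population_size
  gene_counts <- rowSums(chrom)
  nxt <- matrix(0, N, ncol(chrom))
  n_elite <- min(control$elitism_count, N)
  if (n_elite > 0L) {
    ord <- rank_population(chrom, fitness)
    nxt[seq_len(n_elite), ] <- chrom[ord[seq_len(n_elite)], , drop = FALSE]
  }
  need <- N - n_elite
  parents <- tournament_pick(fitness, gene_counts, 2L * ceiling(need / 2), N)
  kids <- breed_children(chrom, parents, control)
  nxt[(n_elite + 1L):N, ] <- kids[seq_len(need), , drop = FALSE]
  list(chromosomes = nxt, fitness = NULL)
}

#' Produce the next generation
#'
#' Advances an evaluated population by one generation of parent
#' selection, single-point crossover and point mutation, under the
#' scheme named in `control$selection` (see [ga_control()]).  Under the
#' default `"penalized"` scheme the next population is the best
#' `population_size` chromosomes among parents and children ranked by
#' the size-penalized score, so the best-ranked chromosome is always
#' retained; under `"fitness"` the top `elitism_count` chromosomes are
#' copied and the rest replaced by tournament offspring.  Population
#' size is preserved.  Uses the current RNG state.
#'
#' @param pop An evaluated `qspkr_population` (fitness ledger present).
#' @param data The `qspkr_dataset` the population is evolving on.
#' @param control A [ga_control()] object.
#' @return A `qspkr_population` with `generation` incremented (fitness
#'   ledger present for `"penalized"`, empty for `"fitness"`).
#' @export
select_next_generation <- function(pop, data, control = ga_control()) {
  stopifnot(inherits(pop, "qspkr_population"))
  if (is.null(pop$fitness)) stop("population must be evaluated first")
  ctx <- fitness_context(data, control)
  stepf <- if (control$selection == "penalized") next_generation_penalized
           else next_generation_fitness
  nxt <- stepf(pop$chromosomes, pop$fitness, ctx, control)
  structure(list(chromosomes = nxt$chromosomes,
                 generation = pop$generation + 1L,
                 fitness = nxt$fitness),
            class = "qspkr_population")
}

#' Run the genetic algorithm
#'
#' Evolves a population of descriptor-inclusion chromosomes under the
#' award/penalty fitness until the best chromosome includes at most
#' `gene_limit` descriptors (the intended stopping rule: fitness
#' decreases with every extra descriptor, so gene counts shrink over
#' generations and the limit prevents complete loss of descriptors) or
#' until `max_generations` is reached.
#'
#' Constant descriptor columns carry no pairwise information and are
#' excluded from selection.  If no compound pair falls within `epsilon`
#' the award branch can never fire; a warning is issued and the run
#' proceeds (every descriptor is then purely penalized).
#'
#' @param data A `qspkr_dataset` with at least 3 compounds and at least
#'   `gene_limit` descriptors.
#' @param control A [ga_control()] object; set `seed` for a
#'   reproducible run.
#' @return An object of class `qspkr_ga`: list with `selected`
#'   (sorted indices of descriptors in the best chromosome),
#'   `selected_names`, `best_genes`, `best_fitness`,
#'   `fitness_trajectory` (best fitness per generation),
#'   `gene_count_trajectory`, `generations`, `termination`
#'   (`"gene_limit"` or `"max_generations"`), `seed` and `control`.
#' @export
run_ga <- function(data, control = ga_control()) {
  stopifnot(inherits(data, "qspkr_dataset"))
  n_desc <- ncol(data$X)
  if (nrow(data$X) < 3L) stop("need at least 3 compounds")
  if (n_desc < control$gene_limit)
    stop("fewer descriptors than gene_limit; selection is trivial")
  ctx <- fitness_context(data, control)
  if (ctx$n_award_pairs == 0L)
    warning("no compound pair has normalized PK difference below epsilon; ",
            "the award branch never fires and all descriptors are penalized")

  pop <- init_population(n_desc, control)  # seeds the RNG if control$seed set
  # constant descriptors carry no pairwise signal: keep them out of play
  if (any(data$constant)) pop$chromosomes[, data$constant] <- 0
  chrom <- pop$chromosomes
  fitness <- population_fitness(chrom, ctx, control)
  stepf <- if (control$selection == "penalized") next_generation_penalized
           else next_generation_fitness
  traj <- numeric(0)
  genes_traj <- integer(0)
  termination <- "max_generations"
  best <- NULL
  for (gen in 0:control$max_generations) {
    g <- rowSums(chrom)
    best_i <- if (control$selection == "penalized")
      order(selection_score(fitness, g, ctx), g)[1L]
    else rank_population(chrom, fitness)[1L]
    best <- list(genes = chrom[best_i, ], fitness = fitness[best_i])
    traj <- c(traj, best$fitness)
    genes_traj <- c(genes_traj, sum(best$genes))
    if (sum(best$genes) <= control$gene_limit) {
      termination <- "gene_limit"
      break
    }
    if (gen == control$max_generations) break
    nxt <- stepf(chrom, fitness, ctx, control)
    chrom <- nxt$chromosomes
    if (any(data$constant)) {
      chrom[, data$constant] <- 0  # masking invalidates cached fitness
      nxt$fitness <- NULL
    }
    fitness <- if (is.null(nxt$fitness))
      population_fitness(chrom, ctx, control) else nxt$fitness
  }
  sel <- which(best$genes == 1)
  structure(list(selected = sel,
                 selected_names = data$descriptor_names[sel],
                 best_genes = best$genes,
                 best_fitness = best$fitness,
                 fitness_trajectory = traj,
                 gene_count_trajectory = genes_traj,
                 generations = length(traj) - 1L,
                 termination = termination,
                 n_award_pairs = ctx$n_award_pairs,
                 n_pairs = ctx$n_pairs,
                 seed = control$seed,
                 control = control),
            class = "qspkr_ga")
}

#' @export
print.qspkr_ga <- function(x, ...) {
  cat(sprintf(
    "<qspkr_ga> %d descriptors selected after %d generations (%s)\n",
    length(x$selected), x$generations, x$termination))
  cat(sprintf("  best fitness %.4f; %d of %d compound pairs in award branch\n",
              x$best_fitness, x$n_award_pairs, x$n_pairs))
  if (length(x$selected))
    cat("  selected:", paste(utils::head(x$selected_names, 15L),
                             collapse = ", "), "\n")
  invisible(x)
}
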