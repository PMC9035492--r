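## NSGA-II: elitist non-dominated sorting genetic algorithm.
##
## Implemented from scratch (non-dominated sorting, crowding distance,
## binary tournament on (rank, crowding), simulated binary crossover,
## polynomial mutation, (mu + lambda) environmental selection). The test
## suite verifies the sorting core against a brute-force dominance
## oracle.

#' Pareto dominance
#'
#' `a` dominates `b` iff `a <= b` in every objective and `a < b` in at
#' least one (all objectives are minimized).
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) {
    stop("objective vectors must have equal length", call. = FALSE)
  }
  all(a <= b) && any(a < b)
}

#' Fast non-dominated sorting
#'
#' Partitions a population into Pareto fronts: front 0 is the
#' non-dominated set, front k is non-dominated once fronts `< k` are
#' removed.
#'
#' @param objectives Numeric matrix, one row per individual, one column
#'   per objective.
#' @return Integer vector of front indices (0-based), one per row.
#' @export
fast_nondominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) stop("empty population", call. = FALSE)
  rank <- integer(n)
  dominated_by <- vector("list", n)  # indices each i dominates
  n_dom <- integer(n)                # how many dominate i
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(objectives[i, ], objectives[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(objectives[j, ], objectives[i, ])) {
        n_dom[i] <- n_dom[i] + 1L
      }
    }
  }
  front <- which(n_dom == 0L)
  k <- 0L
  while (length(front)) {
    rank[front] <- k
    nxt <- integer(0)
    for (i in front) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- nxt
    k <- k + 1L
  }
  rank
}

#' Crowding distance within a front
#'
#' For each objective the front is sorted and each interior individual
#' accumulates the gap between its neighbors, normalized by the
#' objective's range; the extreme individuals of every objective receive
#' `Inf`. Larger is less crowded.
#'
#' @param objectives Numeric matrix of one front (rows = individuals).
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) stop("empty front", call. = FALSE)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(objectives))) {
    o <- objectives[, m]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1]]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        d[ord[i]] <- d[ord[i]] + (o[ord[i + 1]] - o[ord[i - 1]]) / rng
      }
    }
  }
  d
}

#' GA configuration
#'
#' Settings of the evolutionary loop. Defaults follow the canonical
#' NSGA-II description: simulated binary crossover (SBX) with
#' distribution index 15, polynomial mutation with index 20 and rate
#' `1/n_genes`.
#'
#' @param pop_size Even population size `>= 4`.
#' @param generations Number of generations.
#' @param p_crossover,eta_crossover SBX probability and distribution
#'   index.
#' @param p_mutation Per-gene mutation probability; `NULL` means
#'   `1/n_genes`.
#' @param eta_mutation Polynomial-mutation distribution index.
#' @param seed Integer random seed (reproducibility of the whole run).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50, generations = 100,
                      p_crossover = 0.9, eta_crossover = 15,
                      p_mutation = NULL, eta_mutation = 20, seed = 1) {
  if (pop_size < 4 || pop_size %% 2 != 0) {
    stop("pop_size must be even and >= 4", call. = FALSE)
  }
  if (generations < 1) stop("generations must be >= 1", call. = FALSE)
  for (pr in c(p_crossover, p_mutation)) {
    if (!is.null(pr) && (pr < 0 || pr > 1)) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, eta_crossover = eta_crossover,
                 p_mutation = p_mutation, eta_mutation = eta_mutation,
                 seed = as.integer(seed)),
            class = "ga_config")
}

## --- variation operators (canonical real-coded NSGA-II) ---------------

.sbx_crossover <- function(x1, x2, lower, upper, eta, p_cross) {
  c1 <- x1; c2 <- x2
  if (stats::runif(1) < p_cross) {
    for (g in seq_along(x1)) {
      if (stats::runif(1) > 0.5 || abs(x1[g] - x2[g]) < 1e-14) next
      lo <- min(x1[g], x2[g]); hi <- max(x1[g], x2[g])
      u <- stats::runif(1)
      beta_q <- if (u <= 0.5) (2 * u)^(1 / (eta + 1)) else
        (1 / (2 * (1 - u)))^(1 / (eta + 1))
      v1 <- 0.5 * ((1 + beta_q) * lo + (1 - beta_q) * hi)
      v2 <- 0.5 * ((1 - beta_q) * lo + (1 + beta_q) * hi)
      c1[g] <- min(max(v1, lower[g]), upper[g])
      c2[g] <- min(max(v2, lower[g]), upper[g])
    }
  }
  list(c1, c2)
}

.poly_mutation <- function(x, lower, upper, eta, p_mut) {
  for (g in seq_along(x)) {
    if (stats::runif(1) >= p_mut) next
    rng <- upper[g] - lower[g]
    if (rng <= 0) next
    u <- stats::runif(1)
    delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1 else
      1 - (2 * (1 - u))^(1 / (eta + 1))
    x[g] <- min(max(x[g] + delta * rng, lower[g]), upper[g])
  }
  x
}

.tournament_pick <- function(rank, crowd) {
  n <- length(rank)
  i <- sample.int(n, 1); j <- sample.int(n, 1)
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowd[i] > crowd[j]) i else j
}

.eval_population <- function(genomes, objective_fn, n_obj = NULL) {
  objs <- lapply(seq_len(nrow(genomes)), function(i) {
    o <- tryCatch(objective_fn(genomes[i, ]), error = function(e) NULL)
    if (is.null(o) || any(!is.finite(o))) NULL else as.numeric(o)
  })
  if (is.null(n_obj)) {
    ok <- which(!vapply(objs, is.null, logical(1)))
    if (!length(ok)) {
      stop("objective function failed on every genome in the population",
           call. = FALSE)
    }
    n_obj <- length(objs[[ok[1]]])
  }
  ## failures become the +Inf-like sentinel: dominated by everything finite
  big <- 1e300
  rows <- lapply(objs, function(o) if (is.null(o)) rep(big, n_obj) else o)
  do.call(rbind, rows)
}

#' Run the NSGA-II evolutionary loop
#'
#' Elitist (mu + lambda) evolution: binary tournament selection on
#' (front rank, crowding distance), SBX crossover, polynomial mutation,
#' then environmental selection of the best `pop_size` individuals from
#' the union of parents and offspring by (rank, crowding). A genome on
#' which `objective_fn` errors or returns non-finite values is assigned
#' a huge sentinel objective vector (it is dominated and washed out);
#' a generation in which every evaluation fails aborts the run.
#'
#' @param objective_fn Function mapping a genome (numeric vector within
#'   `bounds`) to a numeric objective vector (minimized).
#' @param bounds Two-column matrix (lower, upper), one row per gene.
#' @param cfg A [ga_config()].
#' @return List with `genomes` (matrix of the final population),
#'   `objectives`, `rank`, `crowding`, and `pareto` — a list with the
#'   rank-0 `genomes` and `objectives`.
#' @export
nsga2_evolve <- function(objective_fn, bounds, cfg = ga_config()) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2 || any(bounds[, 1] > bounds[, 2])) {
    stop("bounds must be a (lower, upper) matrix with lower <= upper",
         call. = FALSE)
  }
  lower <- bounds[, 1]; upper <- bounds[, 2]
  ng <- nrow(bounds)
  p_mut <- if (is.null(cfg$p_mutation)) 1 / ng else cfg$p_mutation
  set.seed(cfg$seed)

  genomes <- matrix(0, cfg$pop_size, ng)
  for (i in seq_len(cfg$pop_size)) {
    genomes[i, ] <- stats::runif(ng, lower, upper)
  }
  objs <- .eval_population(genomes, objective_fn)
  rank <- fast_nondominated_sort(objs)
  crowd <- .crowding_by_front(objs, rank)

  for (gen in seq_len(cfg$generations)) {
    kids <- matrix(NA_real_, nrow = cfg$pop_size, ncol = ng)
    for (k in seq(1, cfg$pop_size, by = 2)) {
      i <- .tournament_pick(rank, crowd)
      j <- .tournament_pick(rank, crowd)
      cc <- .sbx_crossover(genomes[i, ], genomes[j, ], lower, upper,
                           cfg$eta_crossover, cfg$p_crossover)
      kids[k, ] <- .poly_mutation(cc[[1]], lower, upper,
                                  cfg$eta_mutation, p_mut)
      kids[k + 1, ] <- .poly_mutation(cc[[2]], lower, upper,
                                      cfg$eta_mutation, p_mut)
    }
    kid_objs <- .eval_population(kids, objective_fn, ncol(objs))
    if (all(kid_objs >= 1e300)) {
      stop("all objective evaluations failed in generation ", gen,
           call. = FALSE)
    }
    all_genomes <- rbind(genomes, kids)
    all_objs <- rbind(objs, kid_objs)
    all_rank <- fast_nondominated_sort(all_objs)
    all_crowd <- .crowding_by_front(all_objs, all_rank)
    keep <- order(all_rank, -all_crowd)[seq_len(cfg$pop_size)]
    genomes <- all_genomes[keep, , drop = FALSE]
    objs <- all_objs[keep, , drop = FALSE]
    rank <- all_rank[keep]
    crowd <- all_crowd[keep]
  }
  pareto <- rank == 0
  list(genomes = genomes, objectives = objs, rank = rank, crowding = crowd,
       pareto = list(genomes = genomes[pareto, , drop = FALSE],
                     objectives = objs[pareto, , drop = FALSE]))
}

.crowding_by_front <- function(objs, rank) {
  crowd <- numeric(length(rank))
  for (k in unique(rank)) {
    idx <- which(rank == k)
    crowd[idx] <- crowding_distance(objs[idx, , drop = FALSE])
  }
  crowd
}
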