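#' Weighted Erdos-Renyi null edge probability
#'
#' The null model for the spin-glass Hamiltonian: a random graph in which
#' every node pair carries the same expected weight
#' `p = sum of observed weights / number of pairs`, i.e. the ER graph "with
#' the same number of edges" extended to weighted networks by conserving
#' total weight. This conservation is what makes the all-in-one partition
#' have exactly zero energy at resolution 1.
#'
#' @param net a [corr_network()] with >= 2 nodes.
#' @return scalar `p >= 0`.
#' @export
null_edge_probability <- function(net) {
  stopifnot(inherits(net, "corr_network"))
  k <- length(net$labels)
  if (k < 2L) stop("size error: need >= 2 nodes", call. = FALSE)
  sum(net$weights[upper.tri(net$weights)]) / (k * (k - 1) / 2)
}

#' Canonicalize a module assignment
#'
#' Converts an integer module assignment into the canonical partition form:
#' a list of node-label sets, modules ordered by the position (in the node
#' order) of their smallest member, members listed in node order. Two
#' assignments that differ only by a permutation of module indices produce
#' identical canonical forms, and re-canonicalizing is idempotent.
#'
#' @param assignment integer vector of module indices, one per node, named
#'   by node label (or unnamed, in which case `labels` gives the node
#'   order).
#' @param labels node labels in network order.
#' @return object of class `partition`: list of character vectors.
#' @export
canonical_partition <- function(assignment, labels = names(assignment)) {
  if (is.list(assignment) && inherits(assignment, "partition")) {
    # re-canonicalize a partition object
    labs <- unlist(assignment, use.names = FALSE)
    if (is.null(labels) || !length(labels)) labels <- sort(labs)
    a <- integer(length(labels)); names(a) <- labels
    for (m in seq_along(assignment)) a[assignment[[m]]] <- m
    assignment <- a
  }
  if (is.null(labels))
    stop("node labels required to canonicalize", call. = FALSE)
  if (anyNA(assignment))
    stop("coverage error: unassigned node", call. = FALSE)
  mods <- split(seq_along(labels), assignment[labels])
  first <- vapply(mods, min, 0L)
  mods <- mods[order(first)]
  out <- lapply(mods, function(ix) labels[sort(ix)])
  names(out) <- NULL
  structure(out, class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition with", length(x), "modules:\n")
  for (i in seq_along(x))
    cat("  module ", i, ": {", paste(x[[i]], collapse = ", "), "}\n",
        sep = "")
  invisible(x)
}

# internal: string key identifying a canonical partition
.partition_key <- function(part) {
  paste(vapply(part, paste, "", collapse = ","), collapse = "|")
}

# internal: partition -> integer assignment named by labels
.partition_assignment <- function(part, labels) {
  a <- rep(NA_integer_, length(labels)); names(a) <- labels
  for (m in seq_along(part)) {
    unknown <- setdiff(part[[m]], labels)
    if (length(unknown))
      stop("coverage error: unknown node ", unknown[1], call. = FALSE)
    a[part[[m]]] <- m
  }
  if (anyNA(a))
    stop("coverage error: node ", names(a)[which(is.na(a))[1]],
         " missing from partition", call. = FALSE)
  a
}

#' Spin-glass energy of a partition
#'
#' The Reichardt-Bornholdt Hamiltonian restricted to a given module
#' assignment: minus the sum, over unordered pairs of nodes placed in the
#' same module, of the observed weight minus `gamma` times the null
#' expectation,
#' \deqn{H(\sigma) = -\sum_{i<j} (W_{ij} - \gamma p)\, \delta_{\sigma_i \sigma_j}.}
#' (The sum over unordered pairs is half the ordered-pair sum; the argmin is
#' unaffected.) At `gamma = 1` the all-singleton partition and the
#' all-in-one partition both have energy 0, the latter because the null
#' conserves total weight.
#'
#' @param part a [canonical_partition()] (or any list of node-label sets
#'   covering the network).
#' @param net a [corr_network()].
#' @param p null edge probability, from [null_edge_probability()].
#' @param gamma resolution parameter (default 1, the standard choice).
#' @return scalar energy.
#' @export
rb_energy <- function(part, net, p = null_edge_probability(net), gamma = 1) {
  stopifnot(inherits(net, "corr_network"))
  a <- .partition_assignment(part, net$labels)
  same <- outer(a, a, "==")
  contrib <- (net$weights - gamma * p) * same
  -sum(contrib[upper.tri(contrib)])
}

# internal: enumerate set partitions of n items via restricted growth
# strings, calling fn(assignment) for each
.for_each_partition <- function(n, fn) {
  a <- integer(n)
  recurse <- function(i, maxg) {
    if (i > n) { fn(a); return(invisible(NULL)) }
    for (g in seq_len(maxg + 1L)) {
      a[i] <<- g
      recurse(i + 1L, max(maxg, g))
    }
  }
  recurse(1L, 0L)
}

#' Exhaustive minimum-energy partition (test oracle)
#'
#' Enumerates every set partition of the node set (restricted growth
#' strings) and returns the global minimum of [rb_energy()] together with
#' all partitions attaining it (ties within `1e-12`). Exponential in the
#' node count; refused above 12 nodes.
#'
#' @param net a [corr_network()] with <= 12 nodes.
#' @param p null edge probability.
#' @param gamma resolution parameter.
#' @param tol tie tolerance on energies.
#' @return list with `energy` (scalar) and `partitions` (list of canonical
#'   partitions attaining it).
#' @export
brute_force_min <- function(net, p = null_edge_probability(net), gamma = 1,
                            tol = 1e-12) {
  stopifnot(inherits(net, "corr_network"))
  k <- length(net$labels)
  if (k > 12L)
    stop("size error: exhaustive enumeration limited to 12 nodes",
         call. = FALSE)
  labels <- net$labels
  wmp <- net$weights - gamma * p
  diag(wmp) <- 0
  best <- Inf
  best_parts <- list()
  .for_each_partition(k, function(a) {
    same <- outer(a, a, "==")
    e <- -sum((wmp * same)[upper.tri(same)])
    if (e < best - tol) {
      best <<- e
      names(a) <- labels
      best_parts <<- list(canonical_partition(a, labels))
    } else if (e <= best + tol) {
      names(a) <- labels
      best_parts <<- c(best_parts, list(canonical_partition(a, labels)))
    }
  })
  # drop duplicate canonical forms among ties
  keys <- vapply(best_parts, .partition_key, "")
  list(energy = best, partitions = best_parts[!duplicated(keys)])
}

#' Simulated-annealing configuration
#'
#' Schedule and trial parameters for the spin-glass minimization. The
#' annealer starts each trial from a uniform random assignment over
#' `q = k` spin states, performs single-spin Metropolis updates under
#' geometric cooling, and returns the best-energy state visited.
#'
#' @param trials number of independent annealing trials for
#'   [frequency_solutions()].
#' @param initial_temperature starting temperature; `NA` (default)
#'   auto-calibrates so that roughly 90% of uphill moves from the initial
#'   random state would be accepted.
#' @param cooling_factor geometric cooling multiplier in (0, 1).
#' @param sweeps_per_temperature Metropolis sweeps (each sweep = one
#'   attempted update per node) at each temperature.
#' @param min_temperature temperature at which cooling stops.
#' @param max_stale stop early after this many consecutive temperature
#'   steps without improvement of the best energy.
#' @param gamma resolution parameter of the Hamiltonian.
#' @param master_seed integer seed from which per-trial seeds are spawned.
#' @return object of class `anneal_config`.
#' @export
anneal_config <- function(trials = 100L, initial_temperature = NA_real_,
                          cooling_factor = 0.99,
                          sweeps_per_temperature = 50L,
                          min_temperature = 1e-3, max_stale = 100L,
                          gamma = 1, master_seed = 1L) {
  if (trials < 1L) stop("config error: trials must be >= 1", call. = FALSE)
  if (!is.na(initial_temperature) && initial_temperature <= 0)
    stop("config error: initial_temperature must be positive", call. = FALSE)
  if (cooling_factor <= 0 || cooling_factor >= 1)
    stop("config error: cooling_factor must lie in (0, 1)", call. = FALSE)
  if (sweeps_per_temperature < 1L || min_temperature <= 0 || max_stale < 1L)
    stop("config error: invalid schedule parameter", call. = FALSE)
  if (gamma <= 0) stop("config error: gamma must be positive", call. = FALSE)
  structure(
    list(trials = as.integer(trials),
         initial_temperature = initial_temperature,
         cooling_factor = cooling_factor,
         sweeps_per_temperature = as.integer(sweeps_per_temperature),
         min_temperature = min_temperature,
         max_stale = as.integer(max_stale),
         gamma = gamma, master_seed = as.integer(master_seed)),
    class = "anneal_config")
}

#' One simulated-annealing trial
#'
#' Minimizes the spin-glass Hamiltonian by single-spin Metropolis updates
#' under geometric cooling, starting from a random assignment drawn from
#' the trial seed. Deterministic given `(config, trial_seed)`. Empty spin
#' states are dropped and the result canonicalized.
#'
#' @param net a [corr_network()] with >= 2 nodes.
#' @param p null edge probability.
#' @param config an [anneal_config()].
#' @param trial_seed integer seed for this trial.
#' @return list with `partition` (canonical), `energy`, and
#'   `initial_energy` of the random starting state.
#' @export
anneal <- function(net, p = null_edge_probability(net),
                   config = anneal_config(), trial_seed = 1L) {
  stopifnot(inherits(net, "corr_network"),
            inherits(config, "anneal_config"))
  k <- length(net$labels)
  if (k < 2L) stop("size error: need >= 2 nodes", call. = FALSE)
  res <- anneal_cpp(net$weights, p, config$gamma,
                    if (is.na(config$initial_temperature)) -1
                    else config$initial_temperature,
                    config$cooling_factor, config$sweeps_per_temperature,
                    config$min_temperature, config$max_stale,
                    as.integer(trial_seed))
  a <- res$assignment
  names(a) <- net$labels
  list(partition = canonical_partition(a, net$labels),
       energy = res$energy, initial_energy = res$initial_energy)
}

#' Occurrence frequencies of partitions over repeated annealing trials
#'
#' Runs `config$trials` independent annealing trials (per-trial seeds
#' spawned deterministically from `config$master_seed`, only the random
#' initial spin states and update order differing between trials) and
#' tallies the distinct canonical partitions found. Because the energy
#' landscape of the spin glass typically has several near-minimal states,
#' repeated trials reveal multiple solutions; their occurrence frequencies
#' measure the ambiguity of the modular architecture.
#'
#' @param net a [corr_network()].
#' @param p null edge probability.
#' @param config an [anneal_config()].
#' @return object of class `solution_frequency_table`: a data frame with
#'   one row per distinct partition (count, frequency, mean energy),
#'   sorted by descending frequency, with the partitions themselves in
#'   `attr(, "partitions")` and the trial count in `attr(, "trials")`.
#' @export
frequency_solutions <- function(net, p = null_edge_probability(net),
                                config = anneal_config()) {
  stopifnot(inherits(config, "anneal_config"))
  seeds <- spawn_seeds(config$master_seed, config$trials)
  keys <- character(config$trials)
  energies <- numeric(config$trials)
  parts <- new.env(parent = emptyenv())
  for (t in seq_len(config$trials)) {
    res <- anneal(net, p, config, trial_seed = seeds[t])
    key <- .partition_key(res$partition)
    keys[t] <- key
    energies[t] <- res$energy
    if (is.null(parts[[key]])) parts[[key]] <- res$partition
  }
  tab <- table(keys)
  ord_keys <- names(sort(tab, decreasing = TRUE))
  df <- data.frame(
    solution = seq_along(ord_keys),
    modules = vapply(ord_keys, function(k) length(parts[[k]]), 0L),
    count = as.integer(tab[ord_keys]),
    frequency = as.integer(tab[ord_keys]) / config$trials,
    mean_energy = vapply(ord_keys,
                         function(k) mean(energies[keys == k]), 0),
    row.names = NULL)
  structure(df, class = c("solution_frequency_table", "data.frame"),
            partitions = lapply(ord_keys, function(k) parts[[k]]),
            trials = config$trials)
}

#' @export
print.solution_frequency_table <- function(x, n = 5L, ...) {
  cat("Solution frequencies over", attr(x, "trials"), "annealing trials (",
      nrow(x), "distinct partitions)\n")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  top <- attr(x, "partitions")[[1]]
  cat("top solution:\n")
  print(top)
  invisible(x)
}

#' Most frequent partition of a frequency table
#' @param table a [frequency_solutions()] result.
#' @return the top-ranked canonical `partition`.
#' @export
top_partition <- function(table) {
  stopifnot(inherits(table, "solution_frequency_table"))
  attr(table, "partitions")[[1]]
}

#' Reproducibility of a module across annealing trials
#'
#' The fraction of trials whose resulting partition contains the given node
#' set exactly as one of its modules (set equality, not containment). This
#' is the per-module reproducibility reported alongside the most frequent
#' solution.
#'
#' @param table a [frequency_solutions()] result.
#' @param nodeset character vector of node labels.
#' @return frequency in \[0, 1\].
#' @export
module_reproducibility <- function(table, nodeset) {
  stopifnot(inherits(table, "solution_frequency_table"))
  if (!length(nodeset)) stop("nodeset must be non-empty", call. = FALSE)
  known <- unique(unlist(attr(table, "partitions")[[1]]))
  all_known <- unique(unlist(attr(table, "partitions")))
  unknown <- setdiff(nodeset, all_known)
  if (length(unknown))
    stop("label error: unknown node ", unknown[1], call. = FALSE)
  target <- sort(nodeset)
  parts <- attr(table, "partitions")
  hit <- vapply(parts, function(p)
    any(vapply(p, function(mod) identical(sort(mod), target), TRUE)), TRUE)
  sum(table$frequency[hit])
}

#' Spawn per-trial seeds from a master seed
#'
#' Deterministic, collision-unlikely seed stream used by every repeated
#' analysis in the package (annealing trials, leave-one-out subsets).
#'
#' @param master_seed integer.
#' @param n number of seeds.
#' @return integer vector of `n` seeds in \[1, 2^31 - 2\].
#' @export
spawn_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(master_seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}
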