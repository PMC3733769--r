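#' Fit a morphological correlation network and extract its modules
#'
#' The main entry point. From raw landmark data the pipeline is: (1)
#' generalized Procrustes superimposition on the reference landmarks and
#' transfer of the fitted transforms to the measurement points ([gpa()],
#' [transfer()]); (2) all-pairs Escoufier Rv coefficients between
#' measurement-point coordinate blocks ([rv_matrix()]); (3) thresholding
#' into a weighted correlation network ([threshold_network()]); (4)
#' repeated spin-glass annealing under a weighted Erdos-Renyi null to
#' extract modules with occurrence frequencies ([frequency_solutions()]).
#' A precomputed `rv_matrix` may be supplied instead of landmark data, in
#' which case stages 1-2 are skipped.
#'
#' @param x a [landmark_dataset()] or an `rv_matrix`.
#' @param tau Rv threshold for the network (default 0.2; `NULL` = none).
#' @param trials number of annealing trials.
#' @param gamma resolution parameter of the spin-glass Hamiltonian.
#' @param use replicate handling for the Rv stage.
#' @param seed master seed for the annealing trials.
#' @param anneal_control an [anneal_config()]; its `trials`, `gamma` and
#'   `master_seed` fields are overridden by the arguments above.
#' @return an object of class `mcn` with components `fit` (the Procrustes
#'   fit, when starting from landmarks), `aligned`, `anova` (Procrustes
#'   ANOVA, when replicates exist), `rv`, `network`, `p` (null edge
#'   probability), `solutions` (the frequency table), and `modules` (the
#'   most frequent partition).
#' @examples
#' sim <- generate_landmarks(paper_shaped_spec("tjuno_like", seed = 7))
#' m <- mcn(sim$dataset, tau = 0.2, trials = 20, seed = 7)
#' print(m)
#' @export
mcn <- function(x, tau = 0.2, trials = 100L, gamma = 1,
                use = c("specimen_means", "all_replicates"), seed = 1L,
                anneal_control = anneal_config()) {
  use <- match.arg(use)
  cl <- match.call()
  fit <- NULL; aligned <- NULL; anova <- NULL
  if (inherits(x, "landmark_dataset")) {
    fit <- gpa(x)
    aligned <- transfer(fit, x)
    if (all(table(aligned$specimen) >= 2) &&
        length(unique(table(aligned$specimen))) == 1L &&
        max(aligned$replicate) >= 2L)
      anova <- procrustes_anova(aligned)
    rv <- rv_matrix(aligned, use)
  } else if (inherits(x, "rv_matrix")) {
    rv <- x
  } else {
    stop("`x` must be a landmark_dataset or an rv_matrix", call. = FALSE)
  }
  net <- threshold_network(rv, tau)
  p <- null_edge_probability(net)
  config <- anneal_control
  config$trials <- as.integer(trials)
  config$gamma <- gamma
  config$master_seed <- as.integer(seed)
  solutions <- frequency_solutions(net, p, config)
  structure(
    list(call = cl, fit = fit, aligned = aligned, anova = anova, rv = rv,
         network = net, p = p, tau = tau, gamma = gamma,
         config = config, solutions = solutions,
         modules = top_partition(solutions)),
    class = "mcn")
}

#' @export
print.mcn <- function(x, ...) {
  cat("Morphological correlation network fit\n")
  cat("  nodes:", length(x$network$labels),
      " edges:", n_edges(x$network),
      " tau:", if (is.null(x$tau)) "none" else x$tau, "\n")
  cat("  annealing trials:", attr(x$solutions, "trials"),
      " distinct solutions:", nrow(x$solutions), "\n")
  cat("  most frequent solution (frequency ",
      signif(x$solutions$frequency[1], 3), "):\n", sep = "")
  print(x$modules)
  invisible(x)
}

#' @export
summary.mcn <- function(object, ...) {
  x <- object
  reps <- vapply(x$modules, function(mod)
    module_reproducibility(x$solutions, mod), 0)
  out <- list(
    n_nodes = length(x$network$labels),
    n_edges = n_edges(x$network),
    tau = x$tau, gamma = x$gamma, p = x$p,
    trials = attr(x$solutions, "trials"),
    n_solutions = nrow(x$solutions),
    top_frequency = x$solutions$frequency[1],
    top_energy = x$solutions$mean_energy[1],
    modules = x$modules,
    module_reproducibility = reps,
    anova = x$anova)
  class(out) <- "summary.mcn"
  out
}

#' @export
print.summary.mcn <- function(x, ...) {
  cat("Morphological correlation network: ", x$n_nodes, " nodes, ",
      x$n_edges, " edges (tau = ",
      if (is.null(x$tau)) "none" else x$tau,
      ", gamma = ", x$gamma, ", p = ", signif(x$p, 4), ")\n", sep = "")
  cat("Most frequent solution: frequency ", signif(x$top_frequency, 4),
      " of ", x$trials, " trials, energy ", signif(x$top_energy, 6),
      "\n", sep = "")
  for (i in seq_along(x$modules))
    cat("  module ", i, " {", paste(x$modules[[i]], collapse = ", "),
        "}: reproducibility ", signif(x$module_reproducibility[i], 4),
        "\n", sep = "")
  if (!is.null(x$anova)) {
    cat("\nDigitization error (Procrustes ANOVA):\n")
    print(x$anova)
  }
  invisible(x)
}

#' Coefficients of an mcn fit: the retained Rv weights
#' @param object an `mcn` fit.
#' @param ... unused.
#' @return named numeric vector of retained edge weights ("MPi--MPj").
#' @export
coef.mcn <- function(object, ...) {
  w <- object$network$weights
  labs <- object$network$labels
  k <- length(labs)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  out <- w[cbind(ut[, 1], ut[, 2])]
  names(out) <- paste0(labs[ut[, 1]], "--", labs[ut[, 2]])
  out
}

#' Plot an mcn fit as a module-colored network
#'
#' Draws the thresholded correlation network with nodes colored by the
#' most frequent module assignment; edge width and darkness scale with the
#' Rv weight, mirroring the usual presentation of these networks.
#'
#' @param x an `mcn` fit.
#' @param seed layout seed.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.mcn <- function(x, seed = 1L, ...) {
  g <- as_igraph_network(x$network)
  a <- .partition_assignment(x$modules, x$network$labels)
  pal <- grDevices::hcl.colors(max(a), "Dynamic")
  w <- igraph::E(g)$weight
  grey <- grDevices::gray(1 - 0.8 * (if (length(w)) w / max(w) else 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  igraph::plot.igraph(
    g, vertex.color = pal[a[igraph::V(g)$name]],
    edge.width = if (length(w)) 1 + 4 * w / max(w) else 1,
    edge.color = grey, ...)
  invisible(x)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' One-command orchestration: starting from a landmark file (CSV/TPS), a
#' precomputed Rv matrix file, or an in-memory dataset, runs alignment,
#' Rv computation, thresholding, module extraction, and (optionally) the
#' threshold sweep and leave-one-out analyses, writing all artifacts and a
#' reproduction manifest into `output_dir`.
#'
#' @param input a [landmark_dataset()], an `rv_matrix`, or a file path.
#' @param output_dir directory for the report bundle (created if needed).
#' @param input_format when `input` is a path: `"csv"`, `"tps"`, or
#'   `"rv"` (precomputed Rv matrix; skips the alignment stages).
#' @param roles,labels passed to [read_landmarks()] for TPS input.
#' @param tau primary threshold.
#' @param sweep_taus thresholds for the sensitivity sweep, or `NULL` to
#'   skip it.
#' @param loo run the leave-one-out analysis?
#' @param trials annealing trials for the primary detection.
#' @param robustness_trials annealing trials per sweep level / subset.
#' @param gamma resolution parameter.
#' @param use replicate handling.
#' @param seed master seed.
#' @return (invisibly) a list with the `mcn` fit and any robustness
#'   reports; files are written under `output_dir`.
#' @export
run_pipeline <- function(input, output_dir,
                         input_format = c("csv", "tps", "rv"),
                         roles = NULL, labels = NULL, tau = 0.2,
                         sweep_taus = list(NULL, 0.2, 0.4), loo = FALSE,
                         trials = 1000L, robustness_trials = 200L,
                         gamma = 1,
                         use = c("specimen_means", "all_replicates"),
                         seed = 1L) {
  use <- match.arg(use)
  input_format <- match.arg(input_format)
  if (is.character(input)) {
    input <- if (input_format == "rv") read_rv_matrix(input)
    else read_landmarks(input, input_format, roles, labels)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(output_dir, ...)

  m <- mcn(input, tau = tau, trials = trials, gamma = gamma, use = use,
           seed = seed)
  if (!is.null(m$aligned))
    utils::write.csv(as.data.frame(m$aligned), fp("aligned.csv"),
                     row.names = FALSE)
  if (!is.null(m$anova))
    utils::write.csv(as.data.frame(m$anova), fp("procrustes_anova.csv"),
                     row.names = FALSE)
  write_rv_matrix(m$rv, fp("rv_matrix.csv"))
  write_network(m$network, fp("network.edgelist"), "edgelist")
  write_network(m$network, fp("network.graphml"), "graphml")
  .write_solutions_json(m$solutions, m$modules, fp("solutions.json"))

  rcfg <- m$config
  rcfg$trials <- as.integer(robustness_trials)
  sweep <- NULL
  if (!is.null(sweep_taus) && length(sweep_taus)) {
    sweep <- threshold_sweep(m$rv, sweep_taus, rcfg)
    jsonlite::write_json(
      list(taus = vapply(sweep$taus, function(t)
             if (is.null(t)) "none" else format(t), ""),
           agreement = sweep$agreement, rand = sweep$rand,
           top_partitions = lapply(sweep$top_partitions, unclass)),
      fp("sweep.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  loo_rep <- NULL
  if (loo && inherits(input, "landmark_dataset")) {
    loo_rep <- leave_one_out(input, tau = tau, use = use, config = rcfg)
    jsonlite::write_json(
      list(agreement_fraction = loo_rep$agreement_fraction,
           stable = loo_rep$stable, entries = loo_rep$entries),
      fp("leave_one_out.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  manifest <- list(
    package = "mcnet",
    version = as.character(utils::packageVersion("mcnet")),
    seed = seed, tau = if (is.null(tau)) "none" else tau,
    gamma = gamma, trials = trials,
    robustness_trials = robustness_trials, use = use,
    n_nodes = length(m$network$labels), n_edges = n_edges(m$network),
    null_p = m$p)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(mcn = m, sweep = sweep, loo = loo_rep))
}

# internal: frequency table + top partition as JSON
.write_solutions_json <- function(tab, modules, path) {
  parts <- attr(tab, "partitions")
  entries <- lapply(seq_len(nrow(tab)), function(i)
    list(modules = lapply(parts[[i]], identity),
         count = tab$count[i], frequency = tab$frequency[i],
         mean_energy = tab$mean_energy[i]))
  jsonlite::write_json(
    list(trials = attr(tab, "trials"), top = unclass(modules),
         solutions = entries),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
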