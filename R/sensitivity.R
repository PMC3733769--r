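#' Rand index between two partitions
#'
#' Fraction of node pairs on which two partitions agree (same module in
#' both, or different in both). Reported as a similarity diagnostic
#' alongside the exact-equality architecture comparisons; never used as a
#' pass criterion.
#'
#' @param p1,p2 partitions (lists of node-label sets) over the same nodes.
#' @return scalar in \[0, 1\].
#' @export
rand_index <- function(p1, p2) {
  labels <- sort(unique(unlist(p1)))
  if (!setequal(labels, unlist(p2)))
    stop("partitions cover different node sets", call. = FALSE)
  a1 <- .partition_assignment(p1, labels)
  a2 <- .partition_assignment(p2, labels)
  k <- length(labels)
  if (k < 2L) return(1)
  s1 <- outer(a1, a1, "==")
  s2 <- outer(a2, a2, "==")
  ut <- upper.tri(s1)
  mean(s1[ut] == s2[ut])
}

#' Threshold sensitivity sweep
#'
#' Rebuilds the correlation network at each threshold level, extracts the
#' solution-frequency table at each, and compares the most frequent
#' architectures across levels by exact canonical-partition equality (with
#' the Rand index as an additional diagnostic). Each level is run with the
#' same master seed, so a single-level sweep reproduces a direct
#' [frequency_solutions()] run exactly.
#'
#' @param rv an `rv_matrix`.
#' @param taus list of threshold levels; use `NULL` elements for "no
#'   threshold". E.g. `list(NULL, 0.2, 0.4)`.
#' @param config an [anneal_config()].
#' @return object of class `sweep_report`: per-level frequency tables, the
#'   top partitions, a logical agreement matrix, and a Rand-index matrix.
#' @export
threshold_sweep <- function(rv, taus = list(NULL, 0.2, 0.4),
                            config = anneal_config()) {
  stopifnot(inherits(rv, "rv_matrix"))
  if (!is.list(taus)) taus <- as.list(taus)
  if (!length(taus)) stop("argument error: empty tau list", call. = FALSE)
  nlev <- length(taus)
  tables <- vector("list", nlev)
  tops <- vector("list", nlev)
  for (l in seq_len(nlev)) {
    net <- threshold_network(rv, taus[[l]])
    tables[[l]] <- frequency_solutions(net, null_edge_probability(net),
                                       config)
    tops[[l]] <- top_partition(tables[[l]])
  }
  lev_names <- vapply(taus, function(t)
    if (is.null(t)) "none" else format(t), "")
  agree <- matrix(NA, nlev, nlev, dimnames = list(lev_names, lev_names))
  rand <- matrix(NA_real_, nlev, nlev,
                 dimnames = list(lev_names, lev_names))
  for (a in seq_len(nlev)) for (b in seq_len(nlev)) {
    agree[a, b] <- identical(.partition_key(tops[[a]]),
                             .partition_key(tops[[b]]))
    rand[a, b] <- rand_index(tops[[a]], tops[[b]])
  }
  structure(list(taus = taus, tables = tables, top_partitions = tops,
                 agreement = agree, rand = rand),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("Threshold sweep over", length(x$taus), "levels\n")
  for (l in seq_along(x$taus)) {
    tau <- x$taus[[l]]
    cat("  tau =", if (is.null(tau)) "none" else tau,
        ": top frequency", signif(x$tables[[l]]$frequency[1], 3),
        "with", length(x$top_partitions[[l]]), "modules\n")
  }
  cat("top-architecture agreement:\n")
  print(x$agreement)
  invisible(x)
}

#' Leave-one-out sample-size sufficiency analysis
#'
#' Checks whether the detected modular architecture is stable under removal
#' of single specimens: for each specimen, the full pipeline (GPA on
#' reference landmarks, transfer, Rv matrix, thresholding, repeated
#' annealing) is rerun on the remaining n - 1 specimens and the most
#' frequent architecture is compared — by exact canonical equality — to the
#' full-sample one. An unstable architecture at n - 1 signals an
#' insufficient sample for covariance estimation.
#'
#' @param dataset a [landmark_dataset()] with >= 4 specimens.
#' @param tau threshold for the correlation network (`NULL` = none).
#' @param use replicate handling for [rv_matrix()].
#' @param config an [anneal_config()]; the same master seed is reused for
#'   every subset, so runs are reproducible.
#' @return object of class `loo_report`: the full-sample top partition, a
#'   per-omitted-specimen data frame (top frequency, agreement flag, Rand
#'   index), and the overall agreement fraction.
#' @export
leave_one_out <- function(dataset, tau = 0.2,
                          use = c("specimen_means", "all_replicates"),
                          config = anneal_config()) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  use <- match.arg(use)
  ids <- unique(dataset$specimen)
  n <- length(ids)
  if (n < 4L) stop("insufficient sample: need >= 4 specimens", call. = FALSE)

  run_once <- function(ds) {
    fit <- gpa(ds)
    aligned <- transfer(fit, ds)
    rv <- rv_matrix(aligned, use)
    net <- threshold_network(rv, tau)
    frequency_solutions(net, null_edge_probability(net), config)
  }
  full_tab <- run_once(dataset)
  full_top <- top_partition(full_tab)
  full_key <- .partition_key(full_top)

  tops <- vector("list", n)
  freq <- numeric(n)
  agree <- logical(n)
  rand <- numeric(n)
  for (i in seq_len(n)) {
    sub <- subset_specimens(dataset, setdiff(ids, ids[i]))
    tab <- run_once(sub)
    tops[[i]] <- top_partition(tab)
    freq[i] <- tab$frequency[1]
    agree[i] <- identical(.partition_key(tops[[i]]), full_key)
    rand[i] <- rand_index(tops[[i]], full_top)
  }
  entries <- data.frame(omitted = ids, top_frequency = freq,
                        agrees = agree, rand = rand)
  structure(list(full_top = full_top, full_table = full_tab,
                 entries = entries, top_partitions = tops,
                 agreement_fraction = mean(agree),
                 stable = mean(agree) == 1),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  n <- nrow(x$entries)
  cat("Leave-one-out stability over", n, "specimens\n")
  cat("  full-sample top architecture:", length(x$full_top), "modules\n")
  cat("  agreement fraction:", signif(x$agreement_fraction, 4), "\n")
  if (!x$stable)
    cat("  note: architecture unstable under single-specimen removal;\n",
        "  sample size may be insufficient for covariance estimation\n")
  invisible(x)
}
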