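# Permutation significance of the biclustering and Rand-index replication.

# Rewire a graph preserving both degree sequences via double-edge swaps
# (default null), or reshuffle each patient's comorbidities preserving only
# patient degrees (the cruder row-wise shuffle, kept as a documented switch).
permute_graph <- function(graph, method = c("swap", "shuffle"),
                          swap_factor = 10) {
  method <- match.arg(method)
  A <- graph$incidence
  n <- nrow(A)
  d <- ncol(A)
  if (method == "swap") {
    e <- which(A == 1L, arr.ind = TRUE)
    sw <- bipartite_edge_swap_cpp(e[, 1] - 1L, e[, 2] - 1L, d,
                                  as.integer(swap_factor * graph$m),
                                  as.integer(100 * swap_factor * graph$m))
    B <- matrix(0L, n, d, dimnames = dimnames(A))
    B[cbind(sw[, 1] + 1L, sw[, 2] + 1L)] <- 1L
  } else {
    B <- t(apply(A, 1, sample))
    dimnames(B) <- dimnames(A)
    storage.mode(B) <- "integer"
  }
  structure(list(incidence = B, patients = graph$patients,
                 comorbidities = graph$comorbidities,
                 k = rowSums(B), d = colSums(B), m = sum(B)),
            class = "bipartite_graph")
}

#' Permutation test of bicluster modularity
#'
#' No closed-form estimator of modularity variance exists, so significance
#' is assessed by permutation: each permutation rewires the graph (by
#' default with degree-preserving double-edge swaps, at least `10 * m`
#' swaps), the optimizer is re-run on the rewired graph with a reduced
#' restart budget, and the optimized null modularity is recorded. The
#' observed Q is compared with the null distribution via a z score, a
#' normal-approximation one-sided P, and the empirical estimator
#' `P = (1 + #\{null >= obs\}) / (n_perm + 1)` which never returns zero.
#'
#' @param graph A [build_graph()] result.
#' @param partition Observed [bicluster_partition()]; computed with
#'   `obs_restarts` restarts when `NULL`.
#' @param n_perm Number of permutations (>= 20; the sd is unstable below).
#' @param seed Integer RNG seed.
#' @param restarts Restart budget for re-optimizing each permuted graph.
#' @param obs_restarts Restart budget for the observed partition when it is
#'   not supplied.
#' @param null `"swap"` (degree-preserving, default) or `"shuffle"`
#'   (row-wise reshuffle preserving only patient degrees).
#' @param swap_factor Swaps per edge for the swap null.
#' @return Object of class `modularity_significance` with fields `q_obs`,
#'   `null_qs`, `null_mean`, `null_sd`, `z`, `p_normal`, `p_empirical`,
#'   `n_perm`, `null_model`, `seed`.
#' @export
modularity_significance <- function(graph, partition = NULL, n_perm = 1000,
                                    seed = 1L, restarts = 5,
                                    obs_restarts = 20,
                                    null = c("swap", "shuffle"),
                                    swap_factor = 10) {
  null <- match.arg(null)
  if (n_perm < 20) stop("n_perm < 20 gives an unstable null sd; refused")
  if (is.null(partition))
    partition <- maximize_modularity(graph, restarts = obs_restarts,
                                     seed = stage_seed(seed, "observed"))
  q_obs <- partition$Q
  null_qs <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      gp <- permute_graph(graph, null, swap_factor)
      maximize_modularity(gp, restarts = restarts,
                          seed = sample.int(2147483646L, 1))$Q
    }, 0)
  })
  null_mean <- mean(null_qs)
  null_sd <- sd(null_qs)
  z <- if (null_sd > 0) (q_obs - null_mean) / null_sd else
    ifelse(q_obs > null_mean, Inf, 0)
  structure(list(q_obs = q_obs, null_qs = null_qs,
                 null_mean = null_mean, null_sd = null_sd, z = z,
                 p_normal = pnorm(z, lower.tail = FALSE),
                 p_empirical = (1 + sum(null_qs >= q_obs)) / (n_perm + 1),
                 n_perm = n_perm, null_model = null, seed = seed),
            class = "modularity_significance")
}

#' @export
print.modularity_significance <- function(x, ...) {
  cat(sprintf("Q = %.3f; z = %.2f; empirical P = %.4g (n_perm = %d, %s null)\n",
              x$q_obs, x$z, x$p_empirical, x$n_perm, x$null_model))
  invisible(x)
}

#' Rand index between two partitions of the same items
#'
#' `RI = (a + b) / choose(n, 2)` where `a` counts item pairs co-clustered in
#' both partitions and `b` pairs separated in both. If both label vectors
#' are named over the same item set they are aligned by name, otherwise by
#' position.
#'
#' @param a,b Cluster label vectors over the same items (length >= 2).
#' @return The Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions cover different item sets")
  n <- length(a)
  if (n < 2) stop("need at least 2 items")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions cover different item sets")
    b <- b[names(a)]
  }
  ct <- table(a, b)
  sum_ij <- sum(choose(ct, 2))
  sum_i <- sum(choose(rowSums(ct), 2))
  sum_j <- sum(choose(colSums(ct), 2))
  (choose(n, 2) + 2 * sum_ij - sum_i - sum_j) / choose(n, 2)
}

#' Adjusted Rand index
#'
#' Rand index corrected for chance agreement under the permutation model;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @inheritParams rand_index
#' @return The adjusted Rand index (<= 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions cover different item sets")
  n <- length(a)
  if (n < 2) stop("need at least 2 items")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions cover different item sets")
    b <- b[names(a)]
  }
  ct <- table(a, b)
  sum_ij <- sum(choose(ct, 2))
  sum_i <- sum(choose(rowSums(ct), 2))
  sum_j <- sum(choose(colSums(ct), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Replication test of comorbidity co-clustering across split halves
#'
#' The two halves share comorbidity nodes but not patients, so replication
#' is measured on the comorbidity-node labelings only: the observed Rand
#' index between the training and replication partitions is compared with a
#' null built by randomly permuting the replication half's comorbidity
#' labels.
#'
#' @param part_train,part_repl [bicluster_partition()]s over the same
#'   comorbidity node set (callers must intersect and refit first if the
#'   sets differ).
#' @param n_perm Number of label permutations.
#' @param seed Integer RNG seed.
#' @return Object of class `replication_result` with `ri`, `z`, `p`
#'   (empirical), `null_mean`, `null_sd`, `n_perm`, `seed`.
#' @export
replication_test <- function(part_train, part_repl, n_perm = 1000,
                             seed = 1L) {
  lt <- part_train$comorbidity_labels
  lr <- part_repl$comorbidity_labels
  if (!setequal(names(lt), names(lr)))
    stop("comorbidity node sets differ between halves; intersect and refit first")
  lr <- lr[names(lt)]
  ri <- rand_index(unname(lt), unname(lr))
  null_ris <- withr::with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) rand_index(unname(lt), sample(unname(lr))), 0)
  })
  null_sd <- sd(null_ris)
  z <- if (null_sd > 0) (ri - mean(null_ris)) / null_sd else
    ifelse(ri > mean(null_ris), Inf, 0)
  structure(list(ri = ri, z = z,
                 p = (1 + sum(null_ris >= ri)) / (n_perm + 1),
                 null_mean = mean(null_ris), null_sd = null_sd,
                 null_ris = null_ris, n_perm = n_perm, seed = seed),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("RI = %.3f; z = %.2f; empirical P = %.4g (n_perm = %d)\n",
              x$ri, x$z, x$p, x$n_perm))
  invisible(x)
}
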