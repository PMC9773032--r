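# Bipartite patient-comorbidity graph, Barber bipartite modularity, and
# BRIM-style modularity maximization.
#
# Barber modularity of a partition that assigns every patient node i and
# comorbidity node j a shared cluster label g:
#
#   Q = (1/m) * sum_ij (A_ij - k_i * d_j / m) * delta(g_i, g_j)
#
# where A is the n x d binary incidence, k_i and d_j the degrees and m the
# edge count. Q is the observed fraction of within-cluster edges minus its
# expectation under the degree-preserving random bipartite null.

#' Build the case-only bipartite patient-comorbidity graph
#'
#' @param cohort Cohort `data.frame`, already filtered to the patients to
#'   analyze (readmitted cases with at least one selected comorbidity; see
#'   [drop_empty_patients()]).
#' @param selected Character vector of comorbidity columns to use as the
#'   comorbidity node set.
#' @return An object of class `bipartite_graph`: list with `incidence`
#'   (n x d binary matrix, dimnames = patient ids x comorbidity names),
#'   degree vectors `k` (patients) and `d` (comorbidities), and edge count
#'   `m`.
#' @export
build_graph <- function(cohort, selected = comorbidity_cols(cohort)) {
  if (nrow(cohort) == 0) stop("empty graph: no patients")
  A <- as.matrix(cohort[selected])
  storage.mode(A) <- "integer"
  if (!all(A %in% c(0L, 1L))) stop("comorbidity matrix must be binary 0/1")
  rownames(A) <- cohort$patient_id
  k <- rowSums(A)
  if (any(k == 0))
    stop("patients with zero selected comorbidities present; ",
         "run drop_empty_patients() first")
  structure(list(incidence = A,
                 patients = rownames(A),
                 comorbidities = colnames(A),
                 k = k, d = colSums(A), m = sum(A)),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("bipartite_graph: %d patients, %d comorbidities, %d edges\n",
              length(x$patients), length(x$comorbidities), x$m))
  invisible(x)
}

#' Construct a bicluster partition and compute its modularity
#'
#' Patient and comorbidity nodes share one label space; a bicluster is the
#' patient subgroup plus the comorbidities carrying its label. Labels are
#' canonicalized to consecutive integers in order of first appearance
#' (comorbidity nodes first), and Barber modularity is computed.
#'
#' @param graph A [build_graph()] result.
#' @param patient_labels,comorbidity_labels Integer cluster labels, aligned
#'   with `graph$patients` / `graph$comorbidities`.
#' @return An object of class `bicluster_partition`: named label vectors,
#'   `K` (number of distinct labels) and `Q`.
#' @export
bicluster_partition <- function(graph, patient_labels, comorbidity_labels) {
  stopifnot(length(patient_labels) == length(graph$patients),
            length(comorbidity_labels) == length(graph$comorbidities))
  all_lab <- c(comorbidity_labels, patient_labels)
  map <- setNames(seq_along(unique(all_lab)), unique(all_lab))
  pl <- unname(map[as.character(patient_labels)])
  cl <- unname(map[as.character(comorbidity_labels)])
  names(pl) <- graph$patients
  names(cl) <- graph$comorbidities
  q <- barber_q(graph, pl, cl)
  structure(list(patient_labels = pl, comorbidity_labels = cl,
                 K = length(map), Q = q),
            class = "bicluster_partition")
}

#' @export
print.bicluster_partition <- function(x, ...) {
  cat(sprintf("bicluster_partition: K = %d clusters, Q = %.4f\n", x$K, x$Q))
  invisible(x)
}

# Core modularity evaluation on raw label vectors.
barber_q <- function(graph, patient_labels, comorbidity_labels) {
  A <- graph$incidence
  k <- graph$k
  dg <- graph$d
  m <- graph$m
  if (m == 0) return(0)
  q <- 0
  for (L in intersect(unique(patient_labels), unique(comorbidity_labels))) {
    ip <- patient_labels == L
    jc <- comorbidity_labels == L
    q <- q + sum(A[ip, jc, drop = FALSE]) - sum(k[ip]) * sum(dg[jc]) / m
  }
  q / m
}

#' Barber bipartite modularity of a partition
#'
#' Evaluates Q exactly per the formula above; `Q` lies in `[-1, 1]`, the
#' single-cluster partition always gives 0, and K equal-sized perfect
#' biclusters give `1 - 1/K`.
#'
#' @param graph A [build_graph()] result.
#' @param partition A [bicluster_partition()], or `NULL` if raw label
#'   vectors are supplied.
#' @param patient_labels,comorbidity_labels Raw label vectors (used when
#'   `partition` is `NULL`).
#' @return Modularity Q (scalar).
#' @export
barber_modularity <- function(graph, partition = NULL,
                              patient_labels = NULL,
                              comorbidity_labels = NULL) {
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "bicluster_partition"))
    patient_labels <- partition$patient_labels
    comorbidity_labels <- partition$comorbidity_labels
  }
  stopifnot(length(patient_labels) == length(graph$patients),
            length(comorbidity_labels) == length(graph$comorbidities))
  barber_q(graph, patient_labels, comorbidity_labels)
}

# --- BRIM optimizer ---------------------------------------------------------

# One side of the alternating update: given comorbidity labels, assign each
# patient to the label maximizing its modularity contribution
#   S_ic = sum_{j in cluster c} (A_ij - k_i d_j / m).
# Exact ties go to the lowest label; a patient whose best contribution is
# negative is parked in a fresh singleton label (contribution 0).
assign_patients <- function(A, k, dg, m, cl) {
  labs <- sort(unique(cl))
  Tc <- outer(cl, labs, "==") + 0
  S <- A %*% Tc - (k %o% as.vector(crossprod(dg, Tc))) / m
  best <- max.col(S, ties.method = "first")
  smax <- S[cbind(seq_len(nrow(S)), best)]
  pl <- labs[best]
  iso <- smax < 0
  if (any(iso)) pl[iso] <- max(labs) + seq_len(sum(iso))
  pl
}

assign_comorbidities <- function(A, k, dg, m, pl) {
  labs <- sort(unique(pl))
  Tp <- outer(pl, labs, "==") + 0
  S <- crossprod(A, Tp) - (dg %o% as.vector(crossprod(k, Tp))) / m
  best <- max.col(S, ties.method = "first")
  smax <- S[cbind(seq_len(nrow(S)), best)]
  cl <- labs[best]
  iso <- smax < 0
  if (any(iso)) cl[iso] <- max(labs) + seq_len(sum(iso))
  cl
}

# Run BRIM from an initial comorbidity labeling to a fixed point of the
# alternating argmax updates. Q is non-decreasing across sweeps.
brim_run <- function(graph, cl0, max_sweeps = 200) {
  A <- graph$incidence
  k <- graph$k
  dg <- graph$d
  m <- graph$m
  cl <- as.integer(factor(cl0))
  pl <- rep.int(1L, nrow(A))
  q_prev <- -Inf
  converged <- FALSE
  sweeps <- 0L
  for (s in seq_len(max_sweeps)) {
    sweeps <- s
    pl <- assign_patients(A, k, dg, m, cl)
    cl <- assign_comorbidities(A, k, dg, m, pl)
    q <- barber_q(graph, pl, cl)
    if (q <= q_prev + 1e-12) { converged <- TRUE; break }
    q_prev <- q
  }
  list(pl = pl, cl = cl, q = barber_q(graph, pl, cl),
       sweeps = sweeps, converged = converged)
}

# Warm starts: agglomerative co-clustering of comorbidity columns by Jaccard
# distance, cut at several depths, plus the all-singleton labeling.
warm_starts <- function(A) {
  d <- ncol(A)
  starts <- list(seq_len(d))
  if (d >= 3) {
    X <- crossprod(A)                      # co-occurrence counts
    sz <- diag(X)
    un <- outer(sz, sz, "+") - X
    jac <- 1 - X / pmax(un, 1)
    hc <- hclust(as.dist(jac), method = "average")
    for (kk in 2:min(8L, d - 1L)) starts[[length(starts) + 1L]] <- cutree(hc, kk)
  }
  starts
}

brim_component <- function(graph, restarts, max_sweeps, k_max) {
  d <- length(graph$comorbidities)
  n <- length(graph$patients)
  if (graph$m == 0 || d == 0 || n == 0)
    return(list(pl = rep.int(1L, n), cl = rep.int(1L, d), q = 0,
                sweeps = 0L, converged = TRUE))
  k_max <- max(2L, min(k_max %||% 15L, d))
  starts <- warm_starts(graph$incidence)
  for (r in seq_len(restarts)) {
    K0 <- 2L + (r - 1L) %% (k_max - 1L)
    starts[[length(starts) + 1L]] <- sample.int(K0, d, replace = TRUE)
  }
  best <- NULL
  for (st in starts) {
    res <- brim_run(graph, st, max_sweeps)
    if (is.null(best) || res$q > best$q + 1e-15) best <- res
  }
  best
}

# Connected components of the bipartite graph (patient indices, comorbidity
# indices per component). Zero-degree comorbidities form singleton
# components.
bipartite_components <- function(graph) {
  g <- igraph::graph_from_biadjacency_matrix(graph$incidence != 0)
  memb <- igraph::components(g)$membership
  n <- length(graph$patients)
  d <- length(graph$comorbidities)
  lapply(seq_len(max(memb)), function(cc) {
    list(patients = which(memb[seq_len(n)] == cc),
         comorbidities = which(memb[n + seq_len(d)] == cc))
  })
}

subgraph_bipartite <- function(graph, pi, ci) {
  A <- graph$incidence[pi, ci, drop = FALSE]
  structure(list(incidence = A,
                 patients = graph$patients[pi],
                 comorbidities = graph$comorbidities[ci],
                 k = rowSums(A), d = colSums(A), m = sum(A)),
            class = "bipartite_graph")
}

#' Maximize Barber modularity by alternating (BRIM-style) optimization
#'
#' Alternates between assigning each patient to the comorbidity-cluster
#' label that maximizes its modularity contribution and vice versa, until a
#' fixed point. The search is initialized from an agglomerative co-clustering
#' warm start (Jaccard distance between comorbidity columns cut at several
#' depths), an all-singleton comorbidity labeling, and `restarts` seeded
#' random labelings whose initial cluster count cycles over 2..`k_max`. The
#' number of clusters K is emergent, never user-fixed. Connected components
#' are optimized independently and their labels unioned. The best-Q
#' partition across all starts is returned; the procedure is deterministic
#' given `seed` and `restarts`.
#'
#' @param graph A [build_graph()] result.
#' @param restarts Number of random restarts per component.
#' @param seed Integer RNG seed.
#' @param max_sweeps Cap on alternating sweeps per start; hitting the cap is
#'   reported with a warning and the best-so-far partition is returned.
#' @param k_max Largest initial label count for random restarts (default
#'   `min(15, d)`).
#' @return A [bicluster_partition()] with attributes `converged` and
#'   `restarts`.
#' @export
maximize_modularity <- function(graph, restarts = 20, seed = 1L,
                                max_sweeps = 200, k_max = NULL) {
  withr::with_seed(seed, {
    comps <- bipartite_components(graph)
    n <- length(graph$patients)
    d <- length(graph$comorbidities)
    pl <- integer(n)
    cl <- integer(d)
    offset <- 0L
    converged <- TRUE
    for (cmp in comps) {
      sub <- subgraph_bipartite(graph, cmp$patients, cmp$comorbidities)
      res <- brim_component(sub, restarts, max_sweeps, k_max)
      if (!res$converged) converged <- FALSE
      pl[cmp$patients] <- res$pl + offset
      cl[cmp$comorbidities] <- if (length(res$cl)) res$cl + offset else integer(0)
      offset <- offset + max(c(res$pl, res$cl, 0L))
    }
    if (!converged)
      warning("BRIM hit the sweep cap before convergence; returning best-so-far")
    part <- bicluster_partition(graph, pl, cl)
    attr(part, "converged") <- converged
    attr(part, "restarts") <- restarts
    attr(part, "seed") <- seed
    part
  })
}
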