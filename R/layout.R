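# Network layout (force-directed + exploded cluster separation), annotation
# and export.

#' Force-directed layout with exploded cluster separation
#'
#' Runs a seeded Fruchterman-Reingold layout on the full bipartite graph,
#' then translates each cluster's nodes radially outward from the global
#' centroid along the cluster-centroid direction by `explode_radius`, so
#' dense biclusters become visually separable. All nodes of a cluster share
#' one displacement vector; `explode_radius = 0` leaves the force-directed
#' coordinates untouched.
#'
#' @param graph A [build_graph()] result.
#' @param partition A [bicluster_partition()].
#' @param explode_radius Scalar radial displacement per cluster (layout
#'   units).
#' @param seed Integer RNG seed for the force-directed stage.
#' @return Object of class `network_layout`: `coordinates` data.frame
#'   (`node`, `type`, `cluster`, `x`, `y`), per-cluster `centroids`, and
#'   `explode_radius`.
#' @export
layout_network <- function(graph, partition, explode_radius = 0.5,
                           seed = 1L) {
  g <- igraph::graph_from_biadjacency_matrix(graph$incidence != 0)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  labels <- c(partition$patient_labels, partition$comorbidity_labels)
  center <- colMeans(xy)
  for (L in unique(labels)) {
    idx <- which(labels == L)
    cent <- colMeans(xy[idx, , drop = FALSE])
    dir <- cent - center
    len <- sqrt(sum(dir^2))
    dir <- if (len > 0) dir / len else c(1, 0)
    xy[idx, 1] <- xy[idx, 1] + explode_radius * dir[1]
    xy[idx, 2] <- xy[idx, 2] + explode_radius * dir[2]
  }
  coords <- data.frame(
    node = c(graph$patients, graph$comorbidities),
    type = rep(c("patient", "comorbidity"),
               c(length(graph$patients), length(graph$comorbidities))),
    cluster = unname(labels),
    x = xy[, 1], y = xy[, 2],
    stringsAsFactors = FALSE)
  cents <- do.call(rbind, lapply(sort(unique(labels)), function(L) {
    data.frame(cluster = L,
               x = mean(coords$x[coords$cluster == L]),
               y = mean(coords$y[coords$cluster == L]))
  }))
  structure(list(coordinates = coords, centroids = cents,
                 explode_radius = explode_radius, seed = seed),
            class = "network_layout")
}

#' Annotate and render the bicluster network
#'
#' Builds the per-bicluster annotation the clinician-facing figures carry:
#' comorbidity labels ranked by descending univariable odds ratio with the
#' OR in parentheses, juxtaposed with the subgroup's readmission risk
#' rendered as a percentage (0.196 -> "19.6%"). Optionally renders the
#' exploded network with these annotations to an SVG/PNG/PDF file (chosen by
#' extension) or the current device.
#'
#' @param layout A [layout_network()] result.
#' @param features A [select_features()] report carrying `or_train` per
#'   comorbidity; an OR missing for a displayed comorbidity is an error.
#' @param risks A [subgroup_risk()] table (`subgroup`, `risk`).
#' @param file Output figure path (`NULL` renders to the active device;
#'   `NA` skips rendering).
#' @param max_edges Edges are drawn only when the graph has at most this
#'   many (density guard for large cohorts).
#' @param graph Optional [build_graph()] result used to draw edges.
#' @return The annotation table (one row per displayed bicluster:
#'   `cluster`, `risk_label`, `comorbidity_labels`), invisibly when
#'   rendering.
#' @export
annotate_network <- function(layout, features, risks, file = NULL,
                             max_edges = 5000, graph = NULL) {
  co <- layout$coordinates
  clusters <- sort(unique(co$cluster))
  ors <- setNames(features$or_train, features$comorbidity)
  risk_by_sub <- setNames(risks$risk, risks$subgroup)
  ann <- list()
  for (L in clusters) {
    cnodes <- co$node[co$cluster == L & co$type == "comorbidity"]
    if (length(cnodes) == 0) {
      warning(sprintf("bicluster %d has no comorbidity nodes; omitted", L))
      next
    }
    if (anyNA(ors[cnodes]))
      stop("missing odds ratio for displayed comorbidity: ",
           paste(cnodes[is.na(ors[cnodes])], collapse = ", "))
    ord <- cnodes[order(-ors[cnodes])]
    lab <- paste(sprintf("%s (%.2g)", ord, ors[ord]), collapse = ", ")
    risk <- unname(risk_by_sub[as.character(L)])
    ann[[length(ann) + 1L]] <- data.frame(
      cluster = L,
      risk_label = if (length(risk) == 1 && !is.na(risk))
        sprintf("%.1f%%", 100 * risk) else NA_character_,
      comorbidity_labels = lab,
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, ann)
  if (!is.null(file) && length(file) == 1 && is.na(file)) return(ann)

  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           svg = svg(file, width = 8, height = 8),
           png = png(file, width = 1600, height = 1600, res = 200),
           pdf = pdf(file, width = 8, height = 8),
           stop("unsupported figure format: ", ext))
    on.exit(dev.off(), add = TRUE)
  }
  pal <- hcl.colors(max(length(clusters), 2), "Dark 3")
  colmap <- setNames(pal[seq_along(clusters)], clusters)
  op <- par(mar = c(1, 1, 2, 1))
  on.exit(par(op), add = TRUE)
  plot(co$x, co$y, type = "n", axes = FALSE, xlab = "", ylab = "",
       main = "Patient subgroups and co-occurring comorbidities")
  if (!is.null(graph) && graph$m <= max_edges) {
    e <- which(graph$incidence == 1L, arr.ind = TRUE)
    pco <- co[co$type == "patient", ]
    cco <- co[co$type == "comorbidity", ]
    segments(pco$x[e[, 1]], pco$y[e[, 1]], cco$x[e[, 2]], cco$y[e[, 2]],
             col = "#00000022")
  }
  pts <- co$type == "patient"
  points(co$x[pts], co$y[pts], pch = 16, cex = 0.4,
         col = colmap[as.character(co$cluster[pts])])
  points(co$x[!pts], co$y[!pts], pch = 15, cex = 1.1,
         col = colmap[as.character(co$cluster[!pts])])
  text(co$x[!pts], co$y[!pts], co$node[!pts], pos = 3, cex = 0.6)
  if (!is.null(ann)) {
    cen <- layout$centroids
    for (r in seq_len(nrow(ann))) {
      L <- ann$cluster[r]
      cxy <- cen[cen$cluster == L, ]
      text(cxy$x, cxy$y,
           sprintf("S%d%s", L,
                   if (!is.na(ann$risk_label[r]))
                     paste0(": ", ann$risk_label[r]) else ""),
           font = 2, cex = 0.9, col = "blue")
    }
  }
  invisible(ann)
}

#' Export the bicluster network as GraphML
#'
#' Node attributes: `type` (patient/comorbidity), `cluster`, `degree`.
#' Graph attributes: modularity `Q`, and `z` / `p` when a
#' [modularity_significance()] result is supplied.
#'
#' @param graph A [build_graph()] result.
#' @param partition A [bicluster_partition()].
#' @param file Output `.graphml` path.
#' @param significance Optional [modularity_significance()] result.
#' @return `file`, invisibly.
#' @export
export_graphml <- function(graph, partition, file, significance = NULL) {
  g <- igraph::graph_from_biadjacency_matrix(graph$incidence != 0)
  igraph::V(g)$type_label <- rep(c("patient", "comorbidity"),
                                 c(length(graph$patients),
                                   length(graph$comorbidities)))
  igraph::V(g)$cluster <- unname(c(partition$patient_labels,
                                   partition$comorbidity_labels))
  igraph::V(g)$degree <- unname(c(graph$k, graph$d))
  g <- igraph::set_graph_attr(g, "Q", partition$Q)
  if (!is.null(significance)) {
    g <- igraph::set_graph_attr(g, "z", significance$z)
    g <- igraph::set_graph_attr(g, "p_empirical", significance$p_empirical)
  }
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Partition table for CSV export
#'
#' @param partition A [bicluster_partition()].
#' @return data.frame with `node_id`, `type`, `cluster`.
#' @export
partition_table <- function(partition) {
  data.frame(
    node_id = c(names(partition$patient_labels),
                names(partition$comorbidity_labels)),
    type = rep(c("patient", "comorbidity"),
               c(length(partition$patient_labels),
                 length(partition$comorbidity_labels))),
    cluster = unname(c(partition$patient_labels,
                       partition$comorbidity_labels)),
    stringsAsFactors = FALSE)
}
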