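#' Build a co-occurrence network from SparCC results
#'
#' Keeps edges with |rho| strictly greater than `r_min` (0.4 by convention)
#' and BH-adjusted q strictly below `q_max` (0.05); records edge sign and
#' drops isolated nodes. An empty result is returned with a warning, not an
#' error — sparse groups legitimately yield empty networks.
#'
#' @param fit a `sparcc_fit` augmented by [edge_significance()].
#' @param r_min minimum |correlation| (strict inequality).
#' @param q_max maximum FDR-adjusted p (strict inequality).
#' @return object of class `cooccurrence_network`: list with `nodes`
#'   (`data.frame` taxon_id, degree, role, cluster) and `edges`
#'   (`data.frame` from, to, rho, q, sign, backbone).
#' @export
build_network <- function(fit, r_min = 0.4, q_max = 0.05) {
  if (is.null(fit$q)) stopf("run edge_significance() before build_network()")
  D <- nrow(fit$rho)
  ids <- rownames(fit$rho)
  ut <- which(upper.tri(fit$rho), arr.ind = TRUE)
  keep <- abs(fit$rho[ut]) > r_min & fit$q[ut] < q_max
  e <- ut[keep, , drop = FALSE]
  edges <- data.frame(from = ids[e[, 1]], to = ids[e[, 2]],
                      rho = fit$rho[e], q = fit$q[e],
                      sign = ifelse(fit$rho[e] >= 0, "positive", "negative"),
                      backbone = logical(nrow(e)), stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    warnf("no edges pass |rho| > %g and q < %g; empty network", r_min, q_max)
    nodes <- data.frame(taxon_id = character(), degree = integer(),
                        role = character(), cluster = integer(),
                        stringsAsFactors = FALSE)
    return(structure(list(nodes = nodes, edges = edges), class = "cooccurrence_network"))
  }
  present <- sort(unique(c(edges$from, edges$to)))
  deg <- table(factor(c(edges$from, edges$to), levels = present))
  nodes <- data.frame(taxon_id = present, degree = as.integer(deg),
                      role = NA_character_, cluster = NA_integer_,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network> %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  invisible(x)
}

net_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes$taxon_id)
}

#' MCODE-style dense-core detection
#'
#' Vertex weighting and greedy seed expansion in the style of the MCODE
#' plug-in: each vertex is weighted by the highest k-core number of its
#' closed neighbourhood times that core's edge density; unvisited vertices
#' are taken as seeds in decreasing weight order (ties by identifier) and
#' expanded through neighbours whose weight is at least
#' `(1 - node_score_cutoff)` of the seed weight. Clusters not containing a
#' `k_core`-core are discarded. Cluster members are labelled `core`;
#' non-members adjacent to a core node are `peripheral`. Defaults are the
#' plug-in's (degree cutoff 2, node score cutoff 0.2, k-core 2, no
#' haircut/fluff).
#'
#' @param net a `cooccurrence_network`.
#' @param node_score_cutoff expansion tolerance in \[0, 1\].
#' @param k_core minimum core the cluster must contain.
#' @param degree_cutoff minimum degree for a vertex to be scored.
#' @return the network with `nodes$role` and `nodes$cluster` filled in;
#'   attribute `"clusters"` lists member ids per cluster, ordered by cluster
#'   score (density x size) then lexically.
#' @export
mcode_cores <- function(net, node_score_cutoff = 0.2, k_core = 2,
                        degree_cutoff = 2) {
  if (nrow(net$edges) == 0) {
    attr(net, "clusters") <- list()
    return(net)
  }
  g <- net_igraph(net)
  ids <- igraph::V(g)$name
  w <- vapply(seq_along(ids), function(v) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    if (length(nb) - 1 < degree_cutoff) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    kc <- igraph::coreness(sub)
    kmax <- max(kc)
    core_sub <- igraph::induced_subgraph(sub, which(kc == kmax))
    dens <- igraph::edge_density(core_sub)
    if (is.nan(dens)) dens <- 0
    kmax * dens
  }, numeric(1))
  names(w) <- ids
  visited <- rep(FALSE, length(ids))
  clusters <- list()
  ord <- order(-w, ids)
  for (seed_i in ord) {
    if (visited[seed_i] || w[seed_i] <= 0) next
    thr <- w[seed_i] * (1 - node_score_cutoff)
    members <- seed_i
    visited[seed_i] <- TRUE
    frontier <- seed_i
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(igraph::neighbors(g, v))) {
          if (!visited[u] && w[u] >= thr) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    sub <- igraph::induced_subgraph(g, members)
    if (max(igraph::coreness(sub)) >= k_core)
      clusters[[length(clusters) + 1]] <- sort(ids[members])
  }
  score <- vapply(clusters, function(m) {
    sub <- igraph::induced_subgraph(g, match(m, ids))
    d <- igraph::edge_density(sub); if (is.nan(d)) d <- 0
    d * length(m)
  }, numeric(1))
  first <- vapply(clusters, function(m) m[1], character(1))
  clusters <- clusters[order(-score, first)]
  core_ids <- unique(unlist(clusters))
  net$nodes$role <- NA_character_
  net$nodes$cluster <- NA_integer_
  for (ci in seq_along(clusters)) {
    sel <- net$nodes$taxon_id %in% clusters[[ci]]
    net$nodes$role[sel] <- "core"
    net$nodes$cluster[sel] <- ci
  }
  periph <- vapply(net$nodes$taxon_id, function(v) {
    if (v %in% core_ids) return(FALSE)
    nb <- ids[as.integer(igraph::neighbors(g, match(v, ids)))]
    any(nb %in% core_ids)
  }, logical(1))
  net$nodes$role[periph] <- "peripheral"
  attr(net, "clusters") <- clusters
  net
}

#' Correlation-weighted network backbone
#'
#' Maximum spanning forest on |rho| per connected component: the skeleton of
#' strongest associations, flagged on the edge table (rendered bold in the
#' study's figures). Flags satisfy the forest identity
#' (#flagged = #nodes - #components).
#'
#' @param net a `cooccurrence_network`.
#' @return the network with `edges$backbone` filled in.
#' @export
backbone <- function(net) {
  if (nrow(net$edges) == 0) return(net)
  g <- net_igraph(net)
  igraph::E(g)$eid <- seq_len(nrow(net$edges))
  mst <- igraph::mst(g, weights = -abs(net$edges$rho))
  net$edges$backbone <- seq_len(nrow(net$edges)) %in% igraph::E(mst)$eid
  net
}

#' Cross-network functional group
#'
#' Three-step rule for a disease-related functional group: (1) find edges
#' whose unordered endpoint pair occurs in both the healthy-control and the
#' early-lesion network (edge sign ignored by default — a pair that flips
#' sign between stages still interacts; `sign_strict = TRUE` requires equal
#' sign); (2) collect the endpoint species; (3) retain those present as
#' nodes of the carcinoma network.
#'
#' @param net_hc,net_esin,net_escc three `cooccurrence_network` objects over
#'   a shared taxon namespace (healthy, early lesion, carcinoma).
#' @param sign_strict require matching edge sign in step 1.
#' @return list with `species` (retained ids), `common_edges`
#'   (`data.frame` of the step-1 pairs), `candidates` (step-2 species).
#' @export
functional_group <- function(net_hc, net_esin, net_escc, sign_strict = FALSE) {
  key <- function(net, with_sign) {
    if (nrow(net$edges) == 0) return(character(0))
    a <- pmin(net$edges$from, net$edges$to)
    b <- pmax(net$edges$from, net$edges$to)
    if (with_sign) paste(a, b, net$edges$sign, sep = "\r") else paste(a, b, sep = "\r")
  }
  common <- intersect(key(net_hc, sign_strict), key(net_esin, sign_strict))
  if (!length(common)) {
    warnf("no common interactions between the two reference networks")
    return(list(species = character(0),
                common_edges = data.frame(from = character(0), to = character(0)),
                candidates = character(0)))
  }
  parts <- do.call(rbind, strsplit(common, "\r", fixed = TRUE))
  common_edges <- data.frame(from = parts[, 1], to = parts[, 2],
                             stringsAsFactors = FALSE)
  candidates <- sort(unique(c(common_edges$from, common_edges$to)))
  species <- candidates[candidates %in% net_escc$nodes$taxon_id]
  list(species = species, common_edges = common_edges, candidates = candidates)
}

#' Export a network as an edge-list TSV
#'
#' Columns: source, target, rho, q, sign, backbone — importable into
#' Cytoscape and friends.
#'
#' @param net a `cooccurrence_network`.
#' @param path output TSV path.
#' @export
write_network <- function(net, path) {
  e <- net$edges
  names(e)[1:2] <- c("source", "target")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
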