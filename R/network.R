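# A pmd_network wraps an undirected igraph multigraph plus tidy node and
# edge tables. Parallel edges with distinct PMD labels are allowed; the PMD
# label is stored on the graph as a character attribute (GraphML-safe).

new_pmd_network <- function(nodes, edges, digits, cor_cutoff = NA_real_) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (nrow(nodes) > 0L) {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(edges) > 0L)
        data.frame(from = edges$from, to = edges$to,
                   pmd = formatC(edges$pmd, format = "f",
                                 digits = max(digits, 0)))
      else data.frame(from = character(0), to = character(0),
                      pmd = character(0)),
      directed = FALSE,
      vertices = data.frame(name = nodes$node_id)
    )
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  }
  structure(
    list(nodes = nodes, edges = edges, graph = g, digits = digits,
         cor_cutoff = cor_cutoff),
    class = "pmd_network"
  )
}

#' @export
print.pmd_network <- function(x, ...) {
  cat("<PMD network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (digits = ", x$digits, ")\n", sep = "")
  if (nrow(x$edges) > 0L) {
    tab <- sort(table(x$edges$pmd), decreasing = TRUE)
    show <- utils::head(tab, 5)
    cat("  edge PMDs: ",
        paste0(names(show), " (", as.integer(show), ")", collapse = ", "),
        if (length(tab) > 5) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Build a PMD network over experimental peaks
#'
#' Nodes are features, edges connect feature pairs whose m/z difference
#' matches a PMD in `pmd_set` and whose intensity correlation exceeds
#' `cor_cutoff`. By default only features participating in at least one
#' retained edge become nodes.
#'
#' @param t A peak table.
#' @param pmd_set Numeric PMD values defining candidate edges.
#' @param digits Decimals for PMD matching (default 2).
#' @param cor_cutoff Minimum Pearson correlation for an edge (default 0.6,
#'   strict inequality).
#' @param include_isolated Keep all features as nodes even without edges
#'   (default FALSE).
#' @return A `pmd_network`.
#' @export
build_peak_network <- function(t, pmd_set, digits = 2, cor_cutoff = 0.6,
                               include_isolated = FALSE) {
  t <- validate_peak_table(t)
  pairs <- find_pairs(t, pmd_set, digits = digits)
  pairs <- pair_statistics(t, pairs)
  keep <- !is.na(pairs$pearson_r) & pairs$pearson_r > cor_cutoff
  edges <- pairs[keep, c("from", "to", "pmd", "pearson_r")]
  ids <- if (include_isolated) t$feature_id else
    unique(c(edges$from, edges$to))
  nodes <- tibble::tibble(
    node_id = t$feature_id, mass = t$mz, label = t$feature_id,
    kind = "peak"
  )
  nodes <- nodes[nodes$node_id %in% ids, ]
  new_pmd_network(nodes, edges, digits, cor_cutoff)
}

#' Targeted recursive PMD network search around a seed m/z
#'
#' Local breadth-first expansion: starting from the feature(s) matching
#' `seed_mz`, each frontier feature admits features lying at its m/z plus or
#' minus any PMD in `pmd_set` (rounded match) whose intensity correlation
#' with the frontier feature exceeds `cor_cutoff`. Expansion repeats until
#' no new feature is admitted or `max_depth` generations have run. Each
#' feature is admitted once, so termination is guaranteed and the result
#' does not depend on feature order. With unlimited depth the node set
#' equals the seed's connected component of [build_peak_network()].
#'
#' @param t A peak table.
#' @param seed_mz The m/z of the feature of interest (matched after rounding
#'   to `digits`).
#' @param pmd_set Numeric PMD values to follow.
#' @param digits Decimals for matching (default 2).
#' @param cor_cutoff Minimum Pearson correlation for admission (default
#'   0.6).
#' @param max_depth Maximum number of expansion generations (default `Inf`).
#' @return A `pmd_network` whose nodes carry a `generation` column (0 for
#'   the seed).
#' @export
recursive_target_network <- function(t, seed_mz, pmd_set, digits = 2,
                                     cor_cutoff = 0.6, max_depth = Inf) {
  t <- validate_peak_table(t)
  if (!is.numeric(pmd_set) || length(pmd_set) == 0L) {
    stop("`pmd_set` must be a non-empty numeric vector", call. = FALSE)
  }
  t <- t[order(t$feature_id), ]
  m <- intensity_matrix(t)
  mz <- t$mz
  ids <- t$feature_id
  seeds <- which(round_pmd(mz, digits) == round_pmd(seed_mz, digits))
  if (length(seeds) == 0L) {
    stop("no feature matches seed m/z ", seed_mz, " at ", digits,
         " decimals", call. = FALSE)
  }
  pmd_r <- round_pmd(pmd_set, digits)
  visited <- logical(length(ids))
  generation <- rep(NA_integer_, length(ids))
  visited[seeds] <- TRUE
  generation[seeds] <- 0L
  frontier <- sort(seeds)
  depth <- 0L
  edges <- list()
  while (length(frontier) > 0L && depth < max_depth) {
    depth <- depth + 1L
    new_frontier <- integer(0)
    for (f in frontier) {
      cand <- which(round_pmd(abs(mz - mz[f]), digits) %in% pmd_r)
      cand <- setdiff(cand, f)
      for (cc in cand) {
        st <- pair_stat_one(m[f, ], m[cc, ])
        if (!is.na(st[["pearson_r"]]) && st[["pearson_r"]] > cor_cutoff) {
          a <- min(f, cc); b <- max(f, cc)
          edges[[length(edges) + 1L]] <- c(a, b)
          if (!visited[cc]) {
            visited[cc] <- TRUE
            generation[cc] <- depth
            new_frontier <- c(new_frontier, cc)
          }
        }
      }
    }
    frontier <- sort(unique(new_frontier))
  }
  keep <- which(visited)
  nodes <- tibble::tibble(node_id = ids[keep], mass = mz[keep],
                          label = ids[keep], kind = "peak",
                          generation = generation[keep])
  if (length(edges) > 0L) {
    e <- unique(do.call(rbind, edges))
    edges_tbl <- tibble::tibble(
      from = ids[pmin(e[, 1], e[, 2])], to = ids[pmax(e[, 1], e[, 2])],
      pmd = round_pmd(abs(mz[e[, 1]] - mz[e[, 2]]), digits),
      pearson_r = purrr::map2_dbl(e[, 1], e[, 2], function(a, b)
        pair_stat_one(m[a, ], m[b, ])[["pearson_r"]])
    )
  } else {
    edges_tbl <- tibble::tibble(from = character(0), to = character(0),
                                pmd = numeric(0), pearson_r = numeric(0))
  }
  new_pmd_network(nodes, edges_tbl, digits, cor_cutoff)
}

#' Build a PMD network over compounds
#'
#' Edges connect compound pairs whose mass difference rounds into
#' `pmd_set`; there is no correlation filter (compound databases carry no
#' intensities). PMD 0 edges between distinct compounds mark isomer pairs.
#' Compounds should be deduplicated upstream (see [dedupe_compounds()]).
#'
#' @param compounds A compound table with at least 2 rows.
#' @param pmd_set Numeric PMD values defining edges.
#' @param digits Decimals for matching (default 3).
#' @param drop_isolated Remove nodes without any edge (default FALSE).
#' @return A `pmd_network` with node `kind = "compound"`.
#' @export
build_compound_network <- function(compounds, pmd_set, digits = 3,
                                   drop_isolated = FALSE) {
  x <- as_compound_tbl(compounds)
  if (nrow(x) < 2L) stop("need at least 2 compounds", call. = FALSE)
  if (!is.numeric(pmd_set) || length(pmd_set) == 0L) {
    stop("`pmd_set` must be a non-empty numeric vector", call. = FALSE)
  }
  n <- nrow(x)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d <- pmd(x$mass[i], x$mass[j], digits)
  keep <- d %in% round_pmd(pmd_set, digits)
  edges <- tibble::tibble(from = x$compound_id[i][keep],
                          to = x$compound_id[j][keep],
                          pmd = d[keep], pearson_r = NA_real_)
  nodes <- tibble::tibble(node_id = x$compound_id, mass = x$mass,
                          label = x$name, kind = "compound")
  if (drop_isolated) {
    nodes <- nodes[nodes$node_id %in% unique(c(edges$from, edges$to)), ]
  }
  new_pmd_network(nodes, edges, digits)
}

#' Topology summary of a PMD network
#'
#' Average degree is 2E/N (self-loops count 2, parallel edges each count);
#' average path length is the mean unweighted shortest-path edge count over
#' pairs of distinct nodes within the same component ("edges end-to-end").
#'
#' @param net A `pmd_network`.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `average_degree`,
#'   `average_path_length` (NA when no two nodes are connected),
#'   `n_components`.
#' @export
topology <- function(net) {
  stopifnot(inherits(net, "pmd_network"))
  n <- nrow(net$nodes); e <- nrow(net$edges)
  if (n == 0L) {
    warning("empty network", call. = FALSE)
    return(tibble::tibble(n_nodes = 0L, n_edges = 0L, average_degree = 0,
                          average_path_length = NA_real_, n_components = 0L))
  }
  apl <- suppressWarnings(igraph::mean_distance(net$graph, directed = FALSE,
                                                unconnected = TRUE))
  if (is.nan(apl)) apl <- NA_real_
  tibble::tibble(
    n_nodes = n, n_edges = e,
    average_degree = 2 * e / n,
    average_path_length = apl,
    n_components = igraph::count_components(net$graph)
  )
}

#' Per-node degrees of a PMD network
#'
#' @param net A `pmd_network`.
#' @return A tibble `node_id`, `degree` (self-loops counting 2).
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "pmd_network"))
  if (nrow(net$nodes) == 0L) {
    return(tibble::tibble(node_id = character(0), degree = integer(0)))
  }
  d <- igraph::degree(net$graph, loops = TRUE)
  tibble::tibble(node_id = names(d), degree = as.integer(d))
}

#' Source appointment of nodes: endogenous versus exogenous
#'
#' Classifies nodes by the connectivity of their network neighbourhood:
#' a node whose connected component has average degree above
#' `degree_threshold` (default 3) is called endogenous; below, exogenous
#' (isolated nodes have component average degree 0). The component's average
#' shortest-path length is reported as supporting evidence -- longer paths
#' also suggest endogenous origin -- but does not veto the degree call.
#'
#' @param net A `pmd_network`.
#' @param node_ids Nodes to classify (default: all nodes).
#' @param degree_threshold Component average-degree threshold (default 3).
#' @param path_threshold Optional average-path-length threshold used only
#'   for the `path_support` column.
#' @return A tibble: `node_id`, `degree`, `component`, `component_size`,
#'   `component_avg_degree`, `component_avg_path_length`, `classification`
#'   (`"endogenous"`, `"exogenous"`, or `"indeterminate"` exactly at the
#'   threshold), `path_support` (NA when no `path_threshold` given).
#' @export
source_classify <- function(net, node_ids = NULL, degree_threshold = 3,
                            path_threshold = NULL) {
  stopifnot(inherits(net, "pmd_network"))
  if (is.null(node_ids)) node_ids <- net$nodes$node_id
  miss <- setdiff(node_ids, net$nodes$node_id)
  if (length(miss) > 0L) {
    stop("node(s) absent from network: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  comp <- igraph::components(net$graph)
  memb <- comp$membership
  degs <- igraph::degree(net$graph, loops = TRUE)
  comp_stats <- purrr::map(seq_len(comp$no), function(ci) {
    vs <- names(memb)[memb == ci]
    sub <- igraph::induced_subgraph(net$graph, vs)
    apl <- suppressWarnings(igraph::mean_distance(sub, directed = FALSE,
                                                  unconnected = TRUE))
    tibble::tibble(component = ci, component_size = length(vs),
                   component_avg_degree = mean(degs[vs]),
                   component_avg_path_length =
                     if (is.nan(apl)) NA_real_ else apl)
  }) |> purrr::list_rbind()
  out <- tibble::tibble(
    node_id = node_ids,
    degree = as.integer(degs[node_ids]),
    component = as.integer(memb[node_ids])
  ) |>
    dplyr::left_join(comp_stats, by = "component") |>
    dplyr::mutate(
      classification = dplyr::case_when(
        abs(.data$component_avg_degree - degree_threshold) < 1e-9 ~
          "indeterminate",
        .data$component_avg_degree > degree_threshold ~ "endogenous",
        TRUE ~ "exogenous"
      ),
      path_support = if (is.null(path_threshold)) NA else
        .data$component_avg_path_length > path_threshold
    )
  out
}

#' Resampled degree contrast between endogenous and exogenous pools
#'
#' Per replicate: draw `n_draw` exogenous compounds, pool them with all
#' endogenous compounds, mine the pooled set's top-`k_top` pairwise PMDs,
#' build the compound network on those PMDs, and record each group's mean
#' node degree. Reports per-group means with 2.5/97.5 percentile intervals
#' over replicates. Seeded and bit-reproducible.
#'
#' @param endogenous,exogenous Compound tables (or numeric mass vectors).
#' @param k_top Number of top-frequency PMDs for the network (default 10).
#' @param n_draw Exogenous compounds drawn per replicate (default: the
#'   endogenous pool size, capped at the exogenous pool size).
#' @param n_rep Number of replicates (default 1000).
#' @param digits Decimals for PMD rounding (default 3).
#' @param seed Optional integer seed.
#' @return A `pmd_resample` object: list with `summary` (group, mean_degree,
#'   ci_lo, ci_hi), `replicates` (rep, group, mean_degree) and the call
#'   parameters.
#' @export
resample_degree_contrast <- function(endogenous, exogenous, k_top = 10,
                                     n_draw = NULL, n_rep = 1000,
                                     digits = 3, seed = NULL) {
  mass_of <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    as_compound_tbl(x)$mass
  }
  me <- mass_of(endogenous)
  mx <- mass_of(exogenous)
  if (length(me) == 0L || length(mx) == 0L) {
    stop("both pools must be non-empty", call. = FALSE)
  }
  if (is.null(n_draw)) n_draw <- min(length(me), length(mx))
  if (n_draw > length(mx)) {
    stop("`n_draw` exceeds the exogenous pool size", call. = FALSE)
  }
  run <- function() {
    reps <- purrr::map(seq_len(n_rep), function(rep_i) {
      drawn <- sort(sample.int(length(mx), n_draw))
      mass <- c(me, mx[drawn])
      grp <- c(rep("endogenous", length(me)), rep("exogenous", n_draw))
      n <- length(mass)
      dm <- round_pmd(abs(outer(mass, mass, "-")), digits)
      ut <- upper.tri(dm)
      vals <- dm[ut]
      tab <- table(vals[vals != 0])
      tab <- tab[order(-as.integer(tab), as.numeric(names(tab)))]
      top <- as.numeric(names(utils::head(tab, k_top)))
      adj <- ut & matrix(dm %in% top, n, n)
      deg <- rowSums(adj) + colSums(adj)
      tibble::tibble(rep = rep_i, group = c("endogenous", "exogenous"),
                     mean_degree = c(mean(deg[grp == "endogenous"]),
                                     mean(deg[grp == "exogenous"])))
    }) |> purrr::list_rbind()
    reps
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  summ <- reps |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      ci_lo = stats::quantile(.data$mean_degree, 0.025, names = FALSE),
      ci_hi = stats::quantile(.data$mean_degree, 0.975, names = FALSE),
      mean_degree = mean(.data$mean_degree),
      .groups = "drop"
    ) |>
    dplyr::select("group", "mean_degree", "ci_lo", "ci_hi")
  structure(list(summary = summ, replicates = reps, k_top = k_top,
                 n_draw = n_draw, n_rep = n_rep, digits = digits,
                 seed = seed),
            class = "pmd_resample")
}

#' @export
print.pmd_resample <- function(x, ...) {
  cat("<PMD degree resampling> ", x$n_rep, " replicates, n_draw = ",
      x$n_draw, ", top-", x$k_top, " PMDs\n", sep = "")
  print(x$summary)
  invisible(x)
}
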