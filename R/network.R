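#' Build the bipartite lncRNA–CEG co-expression network
#'
#' Assembles the CEG provenance rows of one or more results into a strictly
#' bipartite graph: lncRNA nodes on one side, protein-coding (CEG) nodes on
#' the other, one edge per association that passed the thresholds. Graphs
#' spanning several datasets keep one edge per dataset (the edge key is
#' (lnc_id, pcg_id, dataset_id)) so cross-dataset support stays visible; use
#' [collapse_edges()] to merge parallel edges.
#'
#' @param cegs A `coex_result`, a CEG tibble with provenance columns, or a
#'   list of either (combined across datasets).
#' @param lnc_ids Optional lncRNA ids to force as nodes even when their CEG
#'   set is empty.
#' @return A `coex_graph`: list of `nodes` (tibble `id`, `node_class`) and
#'   `edges` (tibble `lnc_id`, `pcg_id`, `coefficient`, `p_value`,
#'   `dataset_id`).
#' @export
build_network <- function(cegs, lnc_ids = NULL) {
  as_ceg_tbl <- function(x) if (inherits(x, "coex_result")) x$cegs else as_tibble(x)
  edges <- if (is.data.frame(cegs) || inherits(cegs, "coex_result")) {
    as_ceg_tbl(cegs)
  } else {
    bind_rows(map(cegs, as_ceg_tbl))
  }
  if (nrow(edges) > 0L) {
    edges <- edges |>
      transmute(
        lnc_id = .data$lnc_id, pcg_id = .data$pcg_id,
        coefficient = .data$coefficient, p_value = .data$p_value,
        dataset_id = .data$dataset_id
      )
    dup <- duplicated(edges[, c("lnc_id", "pcg_id", "dataset_id")])
    if (any(dup)) {
      abort(sprintf(
        "duplicate edge (%s, %s, %s) in CEG input",
        edges$lnc_id[dup][1], edges$pcg_id[dup][1], edges$dataset_id[dup][1]
      ))
    }
  } else {
    edges <- tibble(
      lnc_id = character(), pcg_id = character(), coefficient = double(),
      p_value = double(), dataset_id = character()
    )
  }
  lnc_nodes <- sort(unique(c(edges$lnc_id, lnc_ids)))
  pcg_nodes <- sort(unique(edges$pcg_id))
  overlap <- intersect(lnc_nodes, pcg_nodes)
  if (length(overlap) > 0L) {
    abort(sprintf(
      "graph is not bipartite: '%s' appears as both lncRNA and protein-coding node",
      overlap[1]
    ))
  }
  new_coex_graph(
    nodes = tibble(
      id = c(lnc_nodes, pcg_nodes),
      node_class = rep(c("LNCRNA", "PCG"), c(length(lnc_nodes), length(pcg_nodes)))
    ),
    edges = edges
  )
}

new_coex_graph <- function(nodes, edges) {
  check_bipartite(nodes, edges)
  structure(list(nodes = nodes, edges = edges), class = "coex_graph")
}

check_bipartite <- function(nodes, edges) {
  if (anyDuplicated(nodes$id)) {
    abort("duplicate node id in graph")
  }
  cls <- setNames(nodes$node_class, nodes$id)
  missing <- setdiff(c(edges$lnc_id, edges$pcg_id), nodes$id)
  if (length(missing) > 0L) {
    abort(sprintf("edge endpoint '%s' missing from nodes", missing[1]))
  }
  if (nrow(edges) > 0L &&
    (any(cls[edges$lnc_id] != "LNCRNA") || any(cls[edges$pcg_id] != "PCG"))) {
    abort("graph is not bipartite: an edge joins nodes of the same class")
  }
  invisible(NULL)
}

#' @export
print.coex_graph <- function(x, ...) {
  cat(sprintf(
    "<coex_graph> %d nodes (%d lncRNA, %d PCG), %d edges across %d dataset(s)\n",
    nrow(x$nodes), sum(x$nodes$node_class == "LNCRNA"),
    sum(x$nodes$node_class == "PCG"), nrow(x$edges),
    length(unique(x$edges$dataset_id))
  ))
  invisible(x)
}

#' Collapse parallel multi-dataset edges
#'
#' Merges edges sharing (lnc_id, pcg_id) across datasets, keeping the
#' attributes of the smallest p-value and recording the supporting datasets.
#'
#' @param graph A `coex_graph`.
#' @return A `coex_graph` with one edge per (lnc_id, pcg_id); `dataset_id`
#'   becomes the comma-joined support list and an `n_datasets` column is
#'   added.
#' @export
collapse_edges <- function(graph) {
  stopifnot(inherits(graph, "coex_graph"))
  edges <- graph$edges |>
    group_by(.data$lnc_id, .data$pcg_id) |>
    arrange(.data$p_value, .by_group = TRUE) |>
    summarise(
      coefficient = first(.data$coefficient),
      p_value = first(.data$p_value),
      n_datasets = n(),
      dataset_id = paste(sort(unique(.data$dataset_id)), collapse = ","),
      .groups = "drop"
    )
  new_coex_graph(graph$nodes, edges)
}

as_igraph <- function(graph) {
  ig <- igraph::graph_from_data_frame(
    d = graph$edges |> rename(from = "lnc_id", to = "pcg_id"),
    directed = FALSE,
    vertices = graph$nodes |> rename(name = "id")
  )
  ig
}

#' Write a co-expression network to disk
#'
#' Three formats are supported, all re-readable by [read_network()]:
#' * `"graphml"` — single file with typed node (`node_class`) and edge
#'   attributes, via igraph.
#' * `"sif"` — Cytoscape simple-interaction lines `lnc coexp pcg` (isolated
#'   nodes as lone-id lines) plus a companion `<path>.edges.tsv` carrying edge
#'   attributes.
#' * `"tsv"` — two files, `<path>.nodes.tsv` and `<path>.edges.tsv`,
#'   importable into desktop Cytoscape.
#'
#' @param graph A `coex_graph`.
#' @param path Output path (base path for multi-file formats).
#' @param format `"graphml"`, `"sif"`, or `"tsv"`.
#' @return Character vector of the file(s) written, invisibly.
#' @export
write_network <- function(graph, path, format = c("graphml", "sif", "tsv")) {
  stopifnot(inherits(graph, "coex_graph"))
  format <- match.arg(format)
  files <- switch(format,
    graphml = {
      igraph::write_graph(as_igraph(graph), path, format = "graphml")
      path
    },
    sif = {
      sif_lines <- c(
        sprintf("%s\tcoexp\t%s", graph$edges$lnc_id, graph$edges$pcg_id),
        setdiff(graph$nodes$id, c(graph$edges$lnc_id, graph$edges$pcg_id))
      )
      writeLines(sif_lines, path)
      edge_path <- paste0(path, ".edges.tsv")
      readr::write_tsv(graph$edges, edge_path)
      c(path, edge_path)
    },
    tsv = {
      node_path <- paste0(path, ".nodes.tsv")
      edge_path <- paste0(path, ".edges.tsv")
      readr::write_tsv(graph$nodes, node_path)
      readr::write_tsv(graph$edges, edge_path)
      c(node_path, edge_path)
    }
  )
  invisible(files)
}

#' Read a co-expression network written by [write_network()]
#'
#' Bipartiteness is re-checked on read. For SIF input, lone-id lines are taken
#' as lncRNAs with empty CEG sets (the only isolated nodes the builder
#' produces).
#'
#' @param path Path given to [write_network()].
#' @param format `"graphml"`, `"sif"`, or `"tsv"`.
#' @return A `coex_graph`.
#' @export
read_network <- function(path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    check_file_exists(path, "GraphML file")
    ig <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble(
      id = igraph::vertex_attr(ig, "name"),
      node_class = igraph::vertex_attr(ig, "node_class")
    )
    el <- igraph::as_edgelist(ig)
    cls <- setNames(nodes$node_class, nodes$id)
    edges <- tibble(
      lnc_id = ifelse(cls[el[, 1]] == "LNCRNA", el[, 1], el[, 2]),
      pcg_id = ifelse(cls[el[, 1]] == "LNCRNA", el[, 2], el[, 1]),
      coefficient = igraph::edge_attr(ig, "coefficient") %||% double(),
      p_value = igraph::edge_attr(ig, "p_value") %||% double(),
      dataset_id = igraph::edge_attr(ig, "dataset_id") %||% character()
    )
  } else if (format == "sif") {
    check_file_exists(path, "SIF file")
    edges <- readr::read_tsv(paste0(path, ".edges.tsv"),
      show_col_types = FALSE, progress = FALSE
    )
    lines <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
    lone <- map_chr(lines[lengths(lines) == 1L], 1L)
    nodes <- tibble(
      id = c(sort(unique(c(edges$lnc_id, lone))), sort(unique(edges$pcg_id))),
      node_class = rep(
        c("LNCRNA", "PCG"),
        c(length(unique(c(edges$lnc_id, lone))), length(unique(edges$pcg_id)))
      )
    )
  } else {
    nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"),
      show_col_types = FALSE, progress = FALSE
    )
    edges <- readr::read_tsv(paste0(path, ".edges.tsv"),
      show_col_types = FALSE, progress = FALSE
    )
  }
  edges <- as_tibble(edges) |>
    mutate(dataset_id = as.character(.data$dataset_id)) |>
    arrange(.data$lnc_id, .data$pcg_id, .data$dataset_id)
  new_coex_graph(as_tibble(nodes) |> arrange(desc(.data$node_class == "LNCRNA"), .data$id), edges)
}

#' @rdname build_network
#' @param x A `coex_graph`.
#' @param ... Unused.
#' @method tidy coex_graph
#' @export
tidy.coex_graph <- function(x, ...) {
  as_tibble(x$edges)
}

#' @rdname build_network
#' @method glance coex_graph
#' @export
glance.coex_graph <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_lncrnas = sum(x$nodes$node_class == "LNCRNA"),
    n_pcgs = sum(x$nodes$node_class == "PCG"),
    n_edges = nrow(x$edges),
    n_datasets = length(unique(x$edges$dataset_id))
  )
}

#' Plot a co-expression network
#'
#' Simple bipartite layout: lncRNA hubs surrounded by their CEGs
#' (Fruchterman–Reingold via igraph), edge darkness by significance.
#'
#' @param object A `coex_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coex_graph
#' @export
autoplot.coex_graph <- function(object, ...) {
  ig <- as_igraph(object)
  set.seed(1L)
  xy <- igraph::layout_with_fr(ig)
  nodes <- object$nodes |> mutate(x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(select(nodes, "id", x0 = "x", y0 = "y"), by = c(lnc_id = "id")) |>
    left_join(select(nodes, "id", x1 = "x", y1 = "y"), by = c(pcg_id = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$node_class,
                   size = .data$node_class == "LNCRNA")
    ) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 3, `FALSE` = 1), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, title = "lncRNA-CEG co-expression network")
}
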