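#' Merge per-bait HCIP lists into one interaction network
#'
#' Builds an undirected network from high-confidence interacting proteins
#' (HCIPs) collected over several baits and possibly several cell lines.
#' Bait-to-prey observations in both directions (A pulls down B and B pulls
#' down A) collapse into one edge flagged `reciprocal`; observations of the
#' same pair in different cell lines merge into one edge carrying all the
#' evidence (set `merge_cell_lines = FALSE` to keep one edge per cell line
#' instead). Baits are nodes even when they returned no HCIPs; self-pulls
#' (bait listed as its own prey) are dropped.
#'
#' @param hcips Either a single tibble of HCIPs with columns `bait`, `prey`
#'   and optionally `cell_line` and `NWD` (as produced by [filter_hcips()]),
#'   or a list of such tibbles (one per bait; a named empty element keeps
#'   that bait as an isolated node).
#' @param baits Optional character vector of bait identifiers to force into
#'   the node set even without HCIPs.
#' @param merge_cell_lines Merge evidence for the same pair across cell
#'   lines into one edge (default `TRUE`).
#'
#' @return An `interaction_network` object: a list with tibbles `nodes`
#'   (`id`, `role` in bait/prey/both), `edges` (`from`, `to`, `reciprocal`,
#'   `n_evidence`, `max_nwd`, `cell_lines`) and `evidence` (the deduplicated
#'   input observations).
#' @examples
#' hcips <- tibble::tibble(
#'   bait = c("A", "A", "B", "B"),
#'   prey = c("B", "C", "A", "C"),
#'   NWD = c(2, 3, 2.5, 1.6)
#' )
#' net <- build_network(hcips)
#' network_stats(net)[c("n_nodes", "n_edges", "n_reciprocal")]
#' @export
build_network <- function(hcips, baits = NULL, merge_cell_lines = TRUE) {
  if (is.data.frame(hcips)) hcips <- list(hcips)
  forced_baits <- as.character(baits)
  for (i in seq_along(hcips)) {
    el <- tibble::as_tibble(hcips[[i]])
    nm <- names(hcips)[i]
    if (!is.null(nm) && nzchar(nm %||% "")) forced_baits <- c(forced_baits, nm)
    if (nrow(el) > 0 && !all(c("bait", "prey") %in% names(el))) {
      stop("each HCIP table needs columns bait and prey", call. = FALSE)
    }
    hcips[[i]] <- el
  }
  ev <- dplyr::bind_rows(hcips)
  if (nrow(ev) == 0) {
    ev <- tibble::tibble(bait = character(), prey = character(),
                         cell_line = character(), NWD = numeric())
  }
  if (!"cell_line" %in% names(ev)) ev$cell_line <- "unknown"
  if (!"NWD" %in% names(ev)) ev$NWD <- NA_real_
  ev <- ev[, c("bait", "prey", "cell_line", "NWD")]

  dup <- duplicated(ev[c("bait", "prey", "cell_line")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (bait, prey, cell line) entries de-duplicated")
    ev <- ev[!dup, , drop = FALSE]
  }
  self <- ev$bait == ev$prey
  if (any(self)) ev <- ev[!self, , drop = FALSE]

  all_baits <- unique(c(forced_baits, ev$bait))
  node_ids <- sort(unique(c(all_baits, ev$prey)))
  is_bait <- node_ids %in% all_baits
  is_prey <- node_ids %in% ev$prey
  nodes <- tibble::tibble(
    id = node_ids,
    role = dplyr::case_when(is_bait & is_prey ~ "both",
                            is_bait ~ "bait",
                            TRUE ~ "prey")
  )

  if (nrow(ev) > 0) {
    ev$from <- pmin(ev$bait, ev$prey)
    ev$to <- pmax(ev$bait, ev$prey)
    keys <- if (merge_cell_lines) c("from", "to") else c("from", "to", "cell_line")
    edges <- ev |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        reciprocal = dplyr::n_distinct(.data$bait) > 1,
        n_evidence = dplyr::n(),
        max_nwd = if (all(is.na(.data$NWD))) NA_real_ else max(.data$NWD, na.rm = TRUE),
        cell_lines = paste(sort(unique(.data$cell_line)), collapse = ";"),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$from, .data$to)
  } else {
    edges <- tibble::tibble(from = character(), to = character(),
                            reciprocal = logical(), n_evidence = integer(),
                            max_nwd = numeric(), cell_lines = character())
  }

  structure(list(nodes = nodes, edges = edges,
                 evidence = ev[, c("bait", "prey", "cell_line", "NWD")]),
            class = "interaction_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary statistics of an interaction network
#'
#' @param net An [build_network()] `interaction_network`.
#' @return A list with `n_nodes`, `n_edges`, `n_reciprocal` and `degree`
#'   (named integer vector over all nodes; the degree sum equals twice the
#'   edge count).
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  deg <- setNames(integer(nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges) > 0) {
    tab <- table(c(net$edges$from, net$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  list(
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    n_reciprocal = sum(net$edges$reciprocal),
    degree = deg
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf("<interaction_network> %d nodes, %d edges (%d reciprocal)\n",
              s$n_nodes, s$n_edges, s$n_reciprocal))
  invisible(x)
}

#' Convert an interaction network to an igraph graph
#'
#' @param net An `interaction_network`.
#' @return An undirected [igraph::graph] with node attribute `role` and edge
#'   attributes `reciprocal`, `n_evidence`, `max_nwd`, `cell_lines`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  edges <- net$edges
  edges$max_nwd[is.na(edges$max_nwd)] <- -1  # GraphML has no NA; -1 = unknown
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export / import an interaction network
#'
#' Supported formats: `"tsv"` (edge list with columns `source`, `target`,
#' `reciprocal`, `n_evidence`, `max_NWD`, `cell_lines`) and `"graphml"`
#' (written via igraph, readable by standard graph tools; node roles and all
#' edge attributes preserved, so re-import reproduces the network; isolated
#' nodes survive only in GraphML).
#'
#' @param net An `interaction_network`.
#' @param path Output file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `export_network()` returns `path` invisibly; `import_network()`
#'   returns an `interaction_network` (with empty per-observation evidence).
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "interaction_network"))
  if (format == "tsv") {
    df <- net$edges
    names(df) <- c("source", "target", "reciprocal", "n_evidence", "max_NWD",
                   "cell_lines")
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readr::read_tsv(path, col_types = readr::cols(
      source = readr::col_character(), target = readr::col_character(),
      reciprocal = readr::col_logical(), n_evidence = readr::col_integer(),
      max_NWD = readr::col_double(), cell_lines = readr::col_character()
    ), progress = FALSE)
    edges <- tibble::tibble(from = df$source, to = df$target,
                            reciprocal = df$reciprocal,
                            n_evidence = df$n_evidence,
                            max_nwd = df$max_NWD, cell_lines = df$cell_lines)
    ids <- sort(unique(c(edges$from, edges$to)))
    nodes <- tibble::tibble(id = ids, role = NA_character_)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble::tibble(id = igraph::V(g)$name,
                            role = igraph::V(g)$role)
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble::tibble(
      from = pmin(el$from, el$to), to = pmax(el$from, el$to),
      reciprocal = as.logical(el$reciprocal),
      n_evidence = as.integer(el$n_evidence),
      max_nwd = ifelse(el$max_nwd < 0, NA_real_, el$max_nwd),
      cell_lines = el$cell_lines
    )
    ord <- order(nodes$id)
    nodes <- nodes[ord, , drop = FALSE]
  }
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(list(nodes = nodes, edges = edges,
                 evidence = tibble::tibble(bait = character(), prey = character(),
                                           cell_line = character(), NWD = numeric())),
            class = "interaction_network")
}
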