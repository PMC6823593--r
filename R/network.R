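#' Directed signed interaction network
#'
#' Container for the output of [infer_network()]: a directed graph whose edges
#' carry a sign (`cooperative` or `competitive`), a weight in `[-1, 1]` (the
#' best conformity score among the triplets supporting the edge) and the number
#' of merged triplets.  Nodes carry a site-presence `category` and their
#' maximum relative abundance.
#'
#' @param nodes Data frame with columns `taxon`, `category`, `max_abundance`.
#' @param edges Data frame with columns `source`, `target`, `sign`, `weight`,
#'   `n_triplets`.  Self-edges and duplicate `(source, target, sign)` rows are
#'   rejected.
#' @return An object of class `rmn_network`.
#' @export
rmn_network <- function(nodes = NULL, edges = NULL) {
  if (is.null(edges)) edges <- empty_edge_frame()
  edges <- as.data.frame(edges)
  need <- c("source", "target", "sign", "weight", "n_triplets")
  if (!all(need %in% names(edges)))
    stop("edges must have columns: ", paste(need, collapse = ", "))
  edges <- edges[, need, drop = FALSE]
  if (nrow(edges)) {
    if (!all(edges$sign %in% c("cooperative", "competitive")))
      stop("edge sign must be 'cooperative' or 'competitive'")
    if (any(edges$source == edges$target)) stop("self-edges are not allowed")
    if (anyDuplicated(edges[, c("source", "target", "sign")]))
      stop("duplicate (source, target, sign) edge")
    if (any(edges$weight < -1 | edges$weight > 1))
      stop("edge weights must lie in [-1, 1]")
  }
  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$source, edges$target)))
    nodes <- data.frame(taxon = ids,
                        category = rep(NA_character_, length(ids)),
                        max_abundance = rep(NA_real_, length(ids)))
  }
  nodes <- as.data.frame(nodes)
  if (!all(c("taxon", "category", "max_abundance") %in% names(nodes)))
    stop("nodes must have columns taxon, category, max_abundance")
  if (anyDuplicated(nodes$taxon)) stop("duplicate node")
  dangling <- setdiff(c(edges$source, edges$target), nodes$taxon)
  if (length(dangling)) stop("edge endpoint missing from nodes: ", dangling[1])
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "rmn_network")
}

empty_edge_frame <- function() {
  data.frame(source = character(0), target = character(0),
             sign = character(0), weight = numeric(0),
             n_triplets = integer(0))
}

#' @export
print.rmn_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(paste0("rmn_network: %d nodes, %d cooperative + %d competitive",
                     " edges, %d mutual-negative pair(s)\n"),
              s$n_nodes, s$n_coop_edges, s$n_comp_edges, s$n_mutual_negative))
  invisible(x)
}

#' Mutually negative taxon pairs
#'
#' Finds unordered pairs `{a, b}` connected by competitive edges in both
#' directions -- the signature of reciprocal competition.
#'
#' @param network An [rmn_network()].
#' @return Data frame with columns `a`, `b` (lexicographically ordered within
#'   and across rows); zero rows when there is no reciprocal competition.
#' @export
mutual_negative_pairs <- function(network) {
  stopifnot(inherits(network, "rmn_network"))
  comp <- network$edges[network$edges$sign == "competitive", , drop = FALSE]
  if (!nrow(comp)) return(data.frame(a = character(0), b = character(0)))
  fwd <- paste(comp$source, comp$target, sep = "\r")
  rev <- paste(comp$target, comp$source, sep = "\r")
  mutual <- comp[fwd %in% rev & comp$source < comp$target, , drop = FALSE]
  out <- data.frame(a = mutual$source, b = mutual$target)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unreciprocated cooperative edges
#'
#' Cooperative edges `a -> b` for which no cooperative edge `b -> a` exists
#' (unilateral positive interactions).
#'
#' @param network An [rmn_network()].
#' @return Data frame of qualifying edges (same columns as `network$edges`).
#' @export
unilateral_positive_edges <- function(network) {
  stopifnot(inherits(network, "rmn_network"))
  coop <- network$edges[network$edges$sign == "cooperative", , drop = FALSE]
  if (!nrow(coop)) return(coop)
  fwd <- paste(coop$source, coop$target, sep = "\r")
  rev <- paste(coop$target, coop$source, sep = "\r")
  out <- coop[!(fwd %in% rev), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Network summary counts
#'
#' @param network An [rmn_network()].
#' @return List with `n_nodes`, `n_coop_edges`, `n_comp_edges`,
#'   `n_mutual_negative`.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "rmn_network"))
  list(n_nodes = nrow(network$nodes),
       n_coop_edges = sum(network$edges$sign == "cooperative"),
       n_comp_edges = sum(network$edges$sign == "competitive"),
       n_mutual_negative = nrow(mutual_negative_pairs(network)))
}

#' Convert to an igraph object
#'
#' @param network An [rmn_network()].
#' @return An [igraph::igraph] directed graph with node attributes `category`,
#'   `max_abundance` and edge attributes `sign`, `weight`, `n_triplets`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "rmn_network"))
  nodes <- network$nodes
  names(nodes)[1] <- "name"
  nodes$category <- ifelse(is.na(nodes$category), "", nodes$category)
  nodes$max_abundance <- ifelse(is.na(nodes$max_abundance), -1,
                                nodes$max_abundance)
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = nodes)
}

#' Build an rmn_network from an igraph object
#'
#' Inverse of [as_igraph()]; used when re-importing GraphML exports.
#'
#' @param g A directed igraph graph with edge attribute `sign`.
#' @return An [rmn_network()].
#' @export
from_igraph <- function(g) {
  ed <- igraph::as_data_frame(g, what = "edges")
  vt <- igraph::as_data_frame(g, what = "vertices")
  if (is.null(ed$weight)) ed$weight <- rep(1, nrow(ed))
  if (is.null(ed$n_triplets)) ed$n_triplets <- rep(1L, nrow(ed))
  edges <- data.frame(source = ed$from, target = ed$to, sign = ed$sign,
                      weight = as.numeric(ed$weight),
                      n_triplets = as.integer(ed$n_triplets))
  category <- if (!is.null(vt$category)) {
    ifelse(nzchar(vt$category), vt$category, NA_character_)
  } else rep(NA_character_, nrow(vt))
  max_ab <- if (!is.null(vt$max_abundance)) {
    ifelse(vt$max_abundance < 0, NA_real_, vt$max_abundance)
  } else rep(NA_real_, nrow(vt))
  nodes <- data.frame(taxon = vt$name, category = category,
                      max_abundance = max_ab)
  rmn_network(nodes, edges)
}

#' Export a network to disk
#'
#' Writes the network as a tab-delimited edge list (`source target sign weight
#' n_triplets`, rows sorted by source, target, sign), GraphML or Graphviz DOT.
#' Node attributes `category` and `max_abundance` and edge attributes `sign`,
#' `weight`, `n_triplets` are carried by the graph formats.  Output is
#' deterministic: two writes of the same network are byte-identical.
#'
#' @param network An [rmn_network()].
#' @param path Output file path.
#' @param format One of `"edgelist"`, `"graphml"`, `"dot"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("edgelist", "graphml", "dot")) {
  stopifnot(inherits(network, "rmn_network"))
  if (!format[1] %in% c("edgelist", "graphml", "dot"))
    stop("unknown format '", format[1],
         "'; valid formats: edgelist, graphml, dot")
  format <- match.arg(format)
  if (format == "edgelist") {
    e <- network$edges
    e <- e[order(e$source, e$target, e$sign), , drop = FALSE]
    lines <- c("source\ttarget\tsign\tweight\tn_triplets",
               if (nrow(e)) sprintf("%s\t%s\t%s\t%s\t%d", e$source, e$target,
                                    e$sign, num_token(e$weight), e$n_triplets))
    writeLines(lines, path)
  } else {
    igraph::write_graph(as_igraph(network), path, format = format)
  }
  invisible(path)
}

num_token <- function(x) {
  # locale-independent, full-precision numeric formatting
  vapply(x, function(v) sprintf("%.12g", v), "")
}

#' Read a network edge list written by [write_network()]
#'
#' @param path Path to a tab-delimited edge list.
#' @return An [rmn_network()] (node attributes are unknown and left `NA`).
#' @export
read_network_edgelist <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  rmn_network(edges = data.frame(source = as.character(d$source),
                                 target = as.character(d$target),
                                 sign = d$sign, weight = d$weight,
                                 n_triplets = as.integer(d$n_triplets)))
}

#' Render a network figure
#'
#' Draws the network with a seeded (hence reproducible) Fruchterman-Reingold
#' layout.  Nodes are coloured by site-presence category (present at both
#' sites, at one site only, or below threshold) and edges by sign: competitive
#' red, cooperative blue.
#'
#' @param network An [rmn_network()].
#' @param path Output image path; the extension picks the device (`.png` or
#'   `.svg` via [grDevices::svg()] when available, otherwise png).
#' @param seed Integer seed fixing the layout.
#' @param node_colors Named vector mapping categories to colours; names are
#'   matched against node categories, with `both`, `*_only` (two regions, in
#'   sorted label order) and `below_threshold` filled from the defaults
#'   purple/pink/green/grey.
#' @param edge_colors Named vector with entries `cooperative` and
#'   `competitive`.
#' @param width,height Device size in pixels.
#' @return Invisibly, the layout coordinate matrix (one row per node).
#' @export
render_network <- function(network, path, seed = 0,
                           node_colors = NULL,
                           edge_colors = c(cooperative = "blue",
                                           competitive = "red"),
                           width = 800, height = 800) {
  stopifnot(inherits(network, "rmn_network"))
  g <- as_igraph(network)
  coords <- if (igraph::vcount(g) > 0) {
    with_seed(seed, igraph::layout_with_fr(g))
  } else matrix(numeric(0), ncol = 2)

  cats <- network$nodes$category
  palette <- node_color_map(cats, node_colors)
  vcol <- unname(palette[ifelse(is.na(cats), "below_threshold", cats)])
  ecol <- unname(edge_colors[network$edges$sign])

  ext <- tolower(tools::file_ext(path))
  if (ext == "svg" && capabilities("cairo")) {
    grDevices::svg(path, width = width / 100, height = height / 100)
  } else {
    grDevices::png(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  if (igraph::vcount(g) == 0) {
    graphics::plot.new()
    graphics::title(main = "empty network")
  } else {
    igraph::plot.igraph(g, layout = coords, vertex.color = vcol,
                        edge.color = ecol, vertex.label.color = "black",
                        edge.arrow.size = 0.5)
  }
  invisible(coords)
}

node_color_map <- function(categories, node_colors = NULL) {
  cats <- unique(categories[!is.na(categories)])
  only <- sort(grep("_only$", cats, value = TRUE))
  defaults <- c(both = "#9467bd", below_threshold = "grey70")
  only_defaults <- c("#e377c2", "#2ca02c")  # first region pink, second green
  for (i in seq_along(only)) {
    defaults[only[i]] <- only_defaults[((i - 1) %% 2) + 1]
  }
  if (!is.null(node_colors)) defaults[names(node_colors)] <- node_colors
  defaults
}
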