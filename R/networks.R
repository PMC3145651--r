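#' Signed gene-gene interaction network
#'
#' Edges carry an effect annotation (`positive`, `negative`, `unspecified`)
#' as drawn in curated interaction maps; all degree computations treat the
#' network as undirected and simple, so effects and edge direction are
#' annotation only. Self-loops are removed and duplicate source-target pairs
#' collapsed at construction.
#'
#' @param edges data frame with columns `source`, `target` and optionally
#'   `effect`.
#' @param nodes optional node inventory; defaults to the union of edge
#'   endpoints. Extra isolated nodes may be listed.
#' @return an object of class `InteractionNetwork` with elements `nodes` and
#'   `edges`.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  allowed <- c("positive", "negative", "unspecified")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        effect = character(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = as.character(edges$source),
                        target = as.character(edges$target),
                        effect = if ("effect" %in% names(edges))
                          as.character(edges$effect) else "unspecified",
                        stringsAsFactors = FALSE)
    edges$effect[is.na(edges$effect) | edges$effect == ""] <- "unspecified"
    bad <- setdiff(unique(edges$effect), allowed)
    if (length(bad) > 0L) {
      stop("unknown effect token(s): ", paste(bad, collapse = ", "),
           "; allowed: ", paste(allowed, collapse = ", "))
    }
    loops <- edges$source == edges$target
    if (any(loops)) {
      message("dropping ", sum(loops), " self-loop edge(s)")
      edges <- edges[!loops, , drop = FALSE]
    }
    edges <- edges[!duplicated(edges[c("source", "target")]), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- unique(c(as.character(nodes), edges$source, edges$target))
  structure(list(nodes = nodes, edges = edges), class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat("InteractionNetwork:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Read a tab-delimited edge list
#'
#' Lines are `source TAB target [TAB effect]` with effect in
#' positive/negative/unspecified (default unspecified). Self-loops are
#' dropped with a message; duplicate pairs collapse to one edge.
#'
#' @param path edge-list path.
#' @return an `InteractionNetwork`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(interaction_network(NULL))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths < 2L)) {
    stop("edge line ", which(widths < 2L)[1L], " has fewer than 2 fields")
  }
  interaction_network(data.frame(
    source = vapply(fields, `[[`, character(1L), 1L),
    target = vapply(fields, `[[`, character(1L), 2L),
    effect = vapply(fields, function(f)
      if (length(f) >= 3L) f[[3L]] else "unspecified", character(1L)),
    stringsAsFactors = FALSE))
}

#' Write an edge list to TSV
#' @param net an `InteractionNetwork`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# igraph view: undirected, simple
.as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[c("source", "target")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::simplify(g)
}

#' Named gene set
#'
#' @param genes character vector of gene identifiers; duplicates are removed
#'   preserving first-appearance order.
#' @param name label for the set.
#' @return an object of class `GeneSet`.
#' @export
gene_set <- function(genes, name = "gene_set") {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  structure(list(name = name, genes = genes), class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$genes)

#' Coerce a GeneSet or character vector to a plain identifier vector
#' @param x a `GeneSet` or character vector.
#' @return character vector of gene identifiers.
#' @export
as_gene_vector <- function(x) {
  if (inherits(x, "GeneSet")) x$genes else as.character(x)
}

#' Read a gene list (one identifier per line, '#' comments ignored)
#' @param path file path.
#' @param name label for the resulting set (defaults to the file name).
#' @return a `GeneSet`; an error is raised if no identifiers remain.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("gene list '", path, "' is empty")
  gene_set(lines, name = name)
}

#' Write a gene list, one identifier per line
#' @param gs a `GeneSet` or character vector.
#' @param path output path.
#' @export
write_gene_list <- function(gs, path) {
  writeLines(as_gene_vector(gs), path)
  invisible(path)
}
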