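#' Node connectivity of an interaction network
#'
#' Degree = number of distinct interaction partners: edge direction is
#' ignored, antiparallel edges collapse, self-loops are excluded (already
#' removed at construction). Isolated nodes listed in the node inventory get
#' degree 0.
#'
#' @param net an `InteractionNetwork`.
#' @return data frame with columns `node`, `degree_sub`.
#' @export
node_degrees <- function(net) {
  g <- .as_igraph(net)
  deg <- igraph::degree(g)
  data.frame(node = names(deg), degree_sub = as.integer(deg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hidden-edge fractions relative to a reference network
#'
#' For each node of the candidate subnetwork, the hidden fraction is the
#' proportion of its reference-network (global knowledge base) partners that
#' are absent from the subnetwork: `1 - degree_sub / degree_ref`, with 0 by
#' convention for nodes isolated in the reference. Subnetwork edges absent
#' from the reference are kept but flagged with a warning.
#'
#' @param sub candidate `InteractionNetwork`; its nodes must all appear in
#'   `ref`.
#' @param ref reference `InteractionNetwork`.
#' @return data frame with columns `node`, `degree_sub`, `degree_ref`,
#'   `hidden_fraction`.
#' @export
hidden_fractions <- function(sub, ref) {
  missing <- setdiff(sub$nodes, ref$nodes)
  if (length(missing) > 0L) {
    stop("subnetwork node(s) absent from reference: ",
         paste(missing, collapse = ", "))
  }
  key <- function(net) {
    if (nrow(net$edges) == 0L) return(character())
    unique(paste(pmin(net$edges$source, net$edges$target),
                 pmax(net$edges$source, net$edges$target), sep = "\r"))
  }
  extra <- setdiff(key(sub), key(ref))
  if (length(extra) > 0L) {
    warning(length(extra), " subnetwork edge(s) not present in the reference",
            " network (kept)")
  }
  ds <- node_degrees(sub)
  dr <- node_degrees(ref)
  degree_ref <- dr$degree_sub[match(ds$node, dr$node)]
  hidden <- ifelse(degree_ref > 0L, 1 - ds$degree_sub / degree_ref, 0)
  data.frame(node = ds$node, degree_sub = ds$degree_sub,
             degree_ref = as.integer(degree_ref),
             hidden_fraction = pmax(hidden, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select hub genes by connectivity and hidden-edge criteria
#'
#' A node is a hub when its subnetwork degree reaches `min_connections`
#' (default 31: "more than thirty" partners) and, if a reference network is
#' supplied, its hidden-edge fraction is strictly below
#' `max_hidden_fraction` (default 0.5). Without a reference the hidden-edge
#' criterion is skipped.
#'
#' @param sub candidate `InteractionNetwork`.
#' @param ref optional reference `InteractionNetwork`.
#' @param min_connections minimum degree (inclusive).
#' @param max_hidden_fraction exclusive upper bound on the hidden fraction.
#' @return a sorted `GeneSet` of hub genes.
#' @export
select_hubs <- function(sub, ref = NULL, min_connections = 31,
                        max_hidden_fraction = 0.5) {
  stopifnot(min_connections >= 1, max_hidden_fraction >= 0,
            max_hidden_fraction <= 1)
  if (is.null(ref)) {
    tab <- node_degrees(sub)
    keep <- tab$degree_sub >= min_connections
  } else {
    tab <- hidden_fractions(sub, ref)
    keep <- tab$degree_sub >= min_connections &
      tab$hidden_fraction < max_hidden_fraction
  }
  gene_set(sort(tab$node[keep]), "hubs")
}
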