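#' Build a kin network from relatedness estimates
#'
#' Edges are the estimates that pass the estimator-appropriate significance
#' filter — bootstrap CI lower bound above 0 when intervals are present
#' (likelihood estimator), strictly positive point estimates otherwise
#' (counting estimator; negative estimates are retained in tables but never
#' drawn) — classed `close` when relatedness is at least `close_threshold`
#' and `distant` otherwise, weighted by relatedness.
#'
#' @param est a `kin_estimates` table from [kinship()].
#' @param close_threshold relatedness separating close from distant
#'   relationships (default 0.2; `class = close` iff `r >= 0.2`).
#' @param samples optional [sample_table()] supplying node localities.
#' @return An object of class `kin_network`: list with `nodes` (data.frame
#'   `sample_id`, `locality`) and `edges` (data.frame `sample_i`,
#'   `sample_j`, `relatedness`, `class`).
#' @export
build_network <- function(est, close_threshold = 0.2, samples = NULL) {
  keep <- if (!is.null(est$ci_low))
    !is.na(est$ci_low) & est$ci_low > 0
  else
    !is.na(est$relatedness) & est$relatedness > 0
  edges <- as.data.frame(est)[keep, c("sample_i", "sample_j", "relatedness")]
  edges$class <- ifelse(edges$relatedness >= close_threshold,
                        "close", "distant")
  rownames(edges) <- NULL
  ids <- attr(est, "samples")
  nodes <- data.frame(sample_id = ids,
                      locality = if (!is.null(samples))
                        samples$locality[match(ids, samples$sample_id)]
                      else NA_character_,
                      stringsAsFactors = FALSE)
  out <- list(nodes = nodes, edges = edges,
              close_threshold = close_threshold)
  class(out) <- "kin_network"
  out
}

#' @export
print.kin_network <- function(x, ...) {
  cat(sprintf("kin network: %d samples, %d edges (%d close, %d distant at r >= %.2f)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$class == "close"), sum(x$edges$class == "distant"),
              x$close_threshold))
  invisible(x)
}

#' Convert a kin network to an igraph object
#'
#' @param x a `kin_network`.
#' @return An undirected `igraph` graph with edge attributes `weight`
#'   (relatedness) and `class`, and vertex attribute `locality`.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "kin_network"))
  igraph::graph_from_data_frame(
    transform(x$edges, weight = relatedness),
    directed = FALSE,
    vertices = data.frame(name = x$nodes$sample_id,
                          locality = x$nodes$locality))
}

#' @export
plot.kin_network <- function(x, ...) {
  g <- as_igraph(x)
  lty <- ifelse(igraph::E(g)$class == "close", 1, 2)
  igraph::plot.igraph(g,
                      edge.width = 1 + 4 * igraph::E(g)$weight,
                      edge.lty = lty,
                      vertex.size = 8, vertex.label.cex = 0.7, ...)
  invisible(x)
}
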