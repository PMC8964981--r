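# broom-style accessors for the fitted objects.

#' Tidy a node model
#'
#' @param x A `node_model`.
#' @param ... Unused.
#' @return Tibble: one row per node with `node_id`, `n_cells`, and the
#'   centroid coordinates (one column per marker).
#' @export
tidy.node_model <- function(x, ...) {
  bind_cols(
    tibble(node_id = x$node_ids,
           n_cells = as.integer(table(factor(x$assignments$node_id,
                                             levels = x$node_ids)))),
    as_tibble(x$centroids)
  )
}

#' One-row summary of a node model
#'
#' @param x A `node_model`.
#' @param ... Unused.
#' @return Tibble: `k`, `panel`, `n_cells`, `n_markers`, `tot_withinss`.
#' @export
glance.node_model <- function(x, ...) {
  tibble(k = x$k, panel = x$panel, n_cells = nrow(x$assignments),
         n_markers = length(x$markers), tot_withinss = x$tot_withinss)
}

#' Tidy a signed network
#'
#' @param x A `signed_network`.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `r`, `sign`) with endpoint
#'   lineages joined.
#' @export
tidy.signed_network <- function(x, ...) {
  lin <- setNames(x$nodes$lineage, x$nodes$node_id)
  mutate(x$edges,
         lineage_from = unname(lin[.data$from]),
         lineage_to = unname(lin[.data$to]))
}

#' One-row summary of a signed network
#'
#' @param x A `signed_network`.
#' @param ... Unused.
#' @return The [network_properties()] row.
#' @export
glance.signed_network <- function(x, ...) {
  network_properties(x)
}
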