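#' Group scheme: taxon-to-trophic-group mapping
#'
#' A group scheme maps reported taxon names to trophic groups and tags each
#' group with a broad class (zooplankton, cephalopod, mesopelagic fish,
#' seabird, seal, ...) and a mid-trophic flag (groups from zooplankton to
#' demersal fish, the energy conduit from producers to top predators).
#' The fine resolution of the circumpolar analysis uses ~50 groups; the
#' coarse functional view uses 15. Memberships are data, not code: they are
#' supplied as a table, never hard-coded.
#'
#' @param mapping data.frame with columns `taxon`, `group`, and optionally
#'   `class` and `mid_trophic` (logical).
#' @return a `group_scheme` data.frame.
#' @export
group_scheme <- function(mapping) {
  stopifnot(is.data.frame(mapping),
            all(c("taxon", "group") %in% names(mapping)))
  mapping$taxon <- as.character(mapping$taxon)
  mapping$group <- as.character(mapping$group)
  if (anyDuplicated(mapping$taxon)) {
    dup <- mapping$taxon[duplicated(mapping$taxon)][1]
    stop("taxon mapped to more than one group: ", dup)
  }
  if (is.null(mapping$class)) mapping$class <- NA_character_
  if (is.null(mapping$mid_trophic)) mapping$mid_trophic <- FALSE
  mapping$mid_trophic <- as.logical(mapping$mid_trophic)
  mapping <- mapping[c("taxon", "group", "class", "mid_trophic")]
  class(mapping) <- c("group_scheme", "data.frame")
  mapping
}

#' Read a group scheme from CSV
#'
#' Expected columns: `taxon`, `group`, `class`, `mid_trophic`.
#'
#' @param path CSV path.
#' @return a [group_scheme()].
#' @export
read_group_scheme <- function(path) {
  group_scheme(utils::read.csv(path, stringsAsFactors = FALSE,
                               fileEncoding = "UTF-8"))
}

#' Replace taxon names by trophic group names
#'
#' Records whose predator or prey taxon is absent from the scheme are
#' dropped and reported (an unmapped taxon is a reporting gap, not a
#' failure).
#'
#' @param records refined records data.frame.
#' @param scheme a [group_scheme()].
#' @return list with `records` (predator_name/prey_name replaced by group
#'   names) and `unmapped`, a data.frame of dropped record_ids with the
#'   offending taxon.
#' @export
map_taxa <- function(records, scheme) {
  lookup <- stats::setNames(scheme$group, scheme$taxon)
  pred <- unname(lookup[records$predator_name])
  prey <- unname(lookup[records$prey_name])
  bad <- is.na(pred) | is.na(prey)
  unmapped <- data.frame(
    record_id = records$record_id[bad],
    taxon = ifelse(is.na(pred[bad]), records$predator_name[bad],
                   records$prey_name[bad]),
    stringsAsFactors = FALSE
  )
  out <- records[!bad, , drop = FALSE]
  out$predator_name <- pred[!bad]
  out$prey_name <- prey[!bad]
  rownames(out) <- NULL
  list(records = out, unmapped = unmapped)
}

.mean_or_na <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_real_ else mean(v)
}

#' Build a weighted directed food web from grouped records
#'
#' One edge per distinct (prey group, predator group) pair with at least one
#' contributing record; edges point prey -> predator. Each edge carries the
#' arithmetic mean of each diet metric over the contributing records that
#' report it, and the count of contributing records. With
#' `require_metric = TRUE`, pairs with no non-missing value of the chosen
#' metric are omitted entirely (the treatment the sector webs apply to the
#' fraction-of-occurrence metric). Self-loops (a group preying on itself)
#' are ordinary edges.
#'
#' @param records grouped records (see [map_taxa()]).
#' @param metric which metric governs `require_metric` and downstream
#'   defaults: `"occurrence"` or `"diet_weight"`.
#' @param require_metric logical; drop pairs lacking any value of `metric`?
#' @return a `food_web` object: list with `edges` (data.frame `prey`,
#'   `predator`, `weight_occurrence`, `weight_diet`, `n_records`, sorted by
#'   prey then predator), `nodes` (groups on >= 1 retained edge), `metric`.
#' @export
build_web <- function(records, metric = c("occurrence", "diet_weight"),
                      require_metric = FALSE) {
  metric <- match.arg(metric)
  if (nrow(records) == 0) {
    edges <- data.frame(prey = character(), predator = character(),
                        weight_occurrence = numeric(),
                        weight_diet = numeric(), n_records = integer(),
                        stringsAsFactors = FALSE)
    return(structure(list(edges = edges, nodes = character(),
                          metric = metric), class = "food_web"))
  }
  key <- paste(records$prey_name, records$predator_name, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  edges <- do.call(rbind, lapply(idx, function(i) {
    data.frame(
      prey = records$prey_name[i[1]],
      predator = records$predator_name[i[1]],
      weight_occurrence = .mean_or_na(records$fraction_occurrence[i]),
      weight_diet = .mean_or_na(records$fraction_diet_weight[i]),
      n_records = length(i),
      stringsAsFactors = FALSE
    )
  }))
  if (require_metric) {
    wcol <- if (metric == "occurrence") "weight_occurrence" else "weight_diet"
    edges <- edges[!is.na(edges[[wcol]]), , drop = FALSE]
  }
  edges <- edges[order(edges$prey, edges$predator), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         nodes = sort(unique(c(edges$prey, edges$predator))),
         metric = metric),
    class = "food_web"
  )
}

#' @export
print.food_web <- function(x, ...) {
  cat("food_web:", length(x$nodes), "groups,", nrow(x$edges),
      "directed prey->predator links (metric:", x$metric, ")\n")
  invisible(x)
}

#' Coarsen a fine-group web into functional groups
#'
#' Re-labels records from fine trophic groups to coarse functional groups
#' and rebuilds the web from the pooled records, weighting edges by the mean
#' fraction of diet by weight over the pooled data (averaging data, not
#' averages). Edges with no diet-weight value anywhere are kept but flagged
#' `weight_missing` -- the interaction is known to occur even though its
#' gravimetric contribution is unreported (rendered as dashed edges
#' downstream). Set `pool_records = FALSE` to instead average the fine-edge
#' means within each coarse pair.
#'
#' @param records records grouped under the fine scheme.
#' @param coarse_map data.frame with columns `group` (fine) and
#'   `coarse_group`; every fine group present in `records` must be mapped.
#' @param pool_records logical; pool records before averaging (default) or
#'   average the fine-edge means.
#' @return a `food_web` (metric `"diet_weight"`) whose edge table gains a
#'   logical `weight_missing` column.
#' @export
coarsen <- function(records, coarse_map, pool_records = TRUE) {
  stopifnot(all(c("group", "coarse_group") %in% names(coarse_map)))
  lookup <- stats::setNames(as.character(coarse_map$coarse_group),
                            as.character(coarse_map$group))
  fine_groups <- unique(c(records$predator_name, records$prey_name))
  absent <- setdiff(fine_groups, names(lookup))
  if (length(absent)) {
    stop("fine groups absent from the coarse mapping: ",
         paste(absent, collapse = ", "))
  }
  if (pool_records) {
    records$predator_name <- unname(lookup[records$predator_name])
    records$prey_name <- unname(lookup[records$prey_name])
    web <- build_web(records, metric = "diet_weight", require_metric = FALSE)
  } else {
    fine <- build_web(records, metric = "diet_weight", require_metric = FALSE)
    e <- fine$edges
    e$prey <- unname(lookup[e$prey])
    e$predator <- unname(lookup[e$predator])
    key <- paste(e$prey, e$predator, sep = "\r")
    idx <- split(seq_len(nrow(e)), key)
    edges <- do.call(rbind, lapply(idx, function(i) {
      data.frame(prey = e$prey[i[1]], predator = e$predator[i[1]],
                 weight_occurrence = .mean_or_na(e$weight_occurrence[i]),
                 weight_diet = .mean_or_na(e$weight_diet[i]),
                 n_records = sum(e$n_records[i]), stringsAsFactors = FALSE)
    }))
    edges <- edges[order(edges$prey, edges$predator), , drop = FALSE]
    rownames(edges) <- NULL
    web <- structure(
      list(edges = edges,
           nodes = sort(unique(c(edges$prey, edges$predator))),
           metric = "diet_weight"),
      class = "food_web")
  }
  web$edges$weight_missing <- is.na(web$edges$weight_diet)
  web
}

#' Export a food web as an edge-list CSV
#'
#' Columns: prey, predator, weight_occurrence, weight_diet, n_records (plus
#' weight_missing for coarse webs). Missing weights are empty fields.
#'
#' @param web a `food_web`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(web, path) {
  utils::write.csv(web$edges, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a food web to an igraph graph
#'
#' Directed prey -> predator, edge attributes `weight_occurrence`,
#' `weight_diet`, `n_records`, and `weight` set to the web's governing
#' metric (for igraph's weighted-graph conventions).
#'
#' @param web a `food_web`.
#' @return an [igraph::igraph] object.
#' @export
as_igraph <- function(web) {
  e <- web$edges
  wcol <- if (web$metric == "occurrence") "weight_occurrence" else "weight_diet"
  e$weight <- e[[wcol]]
  igraph::graph_from_data_frame(e, directed = TRUE,
                                vertices = data.frame(name = web$nodes))
}

#' Export a food web as GraphML
#'
#' @param web a `food_web`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(web, path) {
  igraph::write_graph(as_igraph(web), path, format = "graphml")
  invisible(path)
}
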