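#' Network structure summary
#'
#' S = number of trophic groups on at least one retained link, L = number of
#' directed prey->predator links, connectance C = L/S^2 (the fraction of all
#' possible directed links, self-links included in the denominator, that are
#' realized), and link density LD = L/S (links per group).
#'
#' @param web a `food_web` with at least one node.
#' @return a `network_summary`: list with `S`, `L`, `C`, `LD`.
#' @export
network_summary <- function(web) {
  S <- length(web$nodes)
  if (S == 0) stop("summary undefined for an empty web")
  L <- nrow(web$edges)
  structure(list(S = S, L = L, C = L / S^2, LD = L / S),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("S = %d groups, L = %d links, C = %.4f, LD = %.4f\n",
              x$S, x$L, x$C, x$LD))
  invisible(x)
}

#' @export
as.data.frame.network_summary <- function(x, ...) {
  data.frame(S = x$S, L = x$L, C = x$C, LD = x$LD)
}

.metric_col <- function(metric) {
  switch(match.arg(metric, c("occurrence", "diet_weight")),
         occurrence = "weight_occurrence",
         diet_weight = "weight_diet")
}

#' Weighted out-degree strength of a group
#'
#' Sum of the chosen metric's weights over the edges leaving the group,
#' i.e. the weighted total of predation pressure on it across predator
#' groups. Edges whose weight is missing under that metric contribute zero;
#' their count is attached as attribute `n_missing` (a coverage note).
#'
#' @param web a `food_web`.
#' @param group a node name in the web.
#' @param metric `"occurrence"` or `"diet_weight"`.
#' @return numeric strength with attribute `n_missing`.
#' @export
out_strength <- function(web, group, metric = c("occurrence", "diet_weight")) {
  wcol <- .metric_col(metric)
  if (!(group %in% web$nodes)) stop("unknown group: ", group)
  w <- web$edges[[wcol]][web$edges$prey == group]
  structure(sum(w, na.rm = TRUE), n_missing = sum(is.na(w)))
}

#' Weighted in-degree strength of a group
#'
#' Sum of the chosen metric's weights over edges arriving at the group (the
#' weighted count of groups it feeds on).
#'
#' @inheritParams out_strength
#' @return numeric strength with attribute `n_missing`.
#' @export
in_strength <- function(web, group, metric = c("occurrence", "diet_weight")) {
  wcol <- .metric_col(metric)
  if (!(group %in% web$nodes)) stop("unknown group: ", group)
  w <- web$edges[[wcol]][web$edges$predator == group]
  structure(sum(w, na.rm = TRUE), n_missing = sum(is.na(w)))
}

#' Out-degree of a group
#'
#' Number of predator groups consuming the group (count of edges leaving it).
#'
#' @inheritParams out_strength
#' @return integer count.
#' @export
out_degree <- function(web, group) {
  if (!(group %in% web$nodes)) stop("unknown group: ", group)
  sum(web$edges$prey == group)
}

#' Mid-trophic out-degree strength table
#'
#' One row per mid-trophic group present in the web (mid-trophic flags come
#' from the group scheme), with the out-degree and the out-degree strength
#' under both diet metrics, both as proportions and percentages. Rows are
#' sorted by descending strength under `sort_by`, ties broken
#' alphabetically.
#'
#' @param web a `food_web`.
#' @param scheme a [group_scheme()] supplying `mid_trophic` flags per group.
#' @param sort_by which metric orders the table.
#' @return data.frame with columns `group`, `out_degree`,
#'   `out_strength_occurrence`, `out_strength_diet`,
#'   `out_strength_occurrence_pct`, `out_strength_diet_pct`,
#'   `n_missing_occurrence`, `n_missing_diet`.
#' @export
strength_table <- function(web, scheme,
                           sort_by = c("occurrence", "diet_weight")) {
  sort_by <- match.arg(sort_by)
  mid_groups <- sort(unique(scheme$group[scheme$mid_trophic]))
  mid_groups <- intersect(mid_groups, web$nodes)
  rows <- lapply(mid_groups, function(g) {
    so <- out_strength(web, g, "occurrence")
    sd <- out_strength(web, g, "diet_weight")
    data.frame(
      group = g,
      out_degree = out_degree(web, g),
      out_strength_occurrence = as.numeric(so),
      out_strength_diet = as.numeric(sd),
      out_strength_occurrence_pct = 100 * as.numeric(so),
      out_strength_diet_pct = 100 * as.numeric(sd),
      n_missing_occurrence = attr(so, "n_missing"),
      n_missing_diet = attr(sd, "n_missing"),
      stringsAsFactors = FALSE
    )
  })
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame(
    group = character(), out_degree = integer(),
    out_strength_occurrence = numeric(), out_strength_diet = numeric(),
    out_strength_occurrence_pct = numeric(), out_strength_diet_pct = numeric(),
    n_missing_occurrence = integer(), n_missing_diet = integer(),
    stringsAsFactors = FALSE
  )
  key <- if (sort_by == "occurrence") tab$out_strength_occurrence else tab$out_strength_diet
  tab <- tab[order(-key, tab$group), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
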