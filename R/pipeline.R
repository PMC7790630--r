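#' Pipeline configuration
#'
#' Everything one end-to-end run needs: the records (a data.frame or a CSV
#' path), the grouping tables, the sector scheme, refinement settings,
#' accumulation settings, and the output directory. Referenced files must
#' exist.
#'
#' @param records records data.frame, or `NULL` to read `records_path`.
#' @param records_path path to a canonical record CSV (used when `records`
#'   is NULL).
#' @param group_scheme a [group_scheme()] or path to its CSV.
#' @param coarse_map fine-to-coarse data.frame (`group`, `coarse_group`) or
#'   path to its CSV; default `NULL` collapses groups onto their class tags
#'   via [coarse_map_from_scheme()].
#' @param scheme a [sector_scheme()].
#' @param refinement a [refinement_config()].
#' @param out_dir output directory (created if absent).
#' @param n_perm permutations for the accumulation curves.
#' @param seed seed for the accumulation curves.
#' @param require_metric drop links lacking a fraction-of-occurrence value
#'   from the fine webs (default TRUE, the sector-web treatment).
#' @param percent_mode are diet metrics in the input CSV percentages?
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(records = NULL, records_path = NULL,
                            group_scheme, coarse_map = NULL,
                            scheme = sector_scheme(),
                            refinement = refinement_config(),
                            out_dir = "dietweb-output",
                            n_perm = 200, seed = 1,
                            require_metric = TRUE, percent_mode = FALSE) {
  if (is.null(records) && is.null(records_path)) {
    stop("one of records or records_path is required")
  }
  if (!is.null(records_path) && !file.exists(records_path)) {
    stop("records_path does not exist: ", records_path)
  }
  if (is.character(group_scheme)) {
    if (!file.exists(group_scheme)) stop("group scheme file not found")
    group_scheme <- read_group_scheme(group_scheme)
  }
  if (is.character(coarse_map)) {
    if (!file.exists(coarse_map)) stop("coarse map file not found")
    coarse_map <- utils::read.csv(coarse_map, stringsAsFactors = FALSE)
  }
  structure(
    list(records = records, records_path = records_path,
         group_scheme = group_scheme, coarse_map = coarse_map,
         scheme = scheme, refinement = refinement, out_dir = out_dir,
         n_perm = n_perm, seed = seed, require_metric = require_metric,
         percent_mode = percent_mode),
    class = "pipeline_config"
  )
}

.slug <- function(x) gsub("[^A-Za-z0-9]+", "_", tolower(x))

.config_hash <- function(config) {
  # hash the scientific settings only: input data and output locations vary
  # between otherwise-identical runs
  keep <- setdiff(names(config), c("records", "records_path", "out_dir"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[keep]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full food-web pipeline
#'
#' Reads and validates records, applies the refinement rules, aggregates
#' taxa into trophic groups, partitions by sector, and -- per sector and
#' for the pooled dataset -- builds the fine-group web (weighted by mean
#' fraction of occurrence, links without occurrence data excluded when
#' `require_metric`), the coarse functional-group web (weighted by mean
#' fraction of diet by weight), the network summary, the mid-trophic
#' strength table, and the source-randomized accumulation curve with its
#' negative-exponential fit. All tables are written sorted so identical
#' configuration and inputs give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a `pipeline_result`: list with `units` (per-sector
#'   results), `summary` (the combined summary table), `counts`
#'   (per-stage record counts) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  records <- stage("read", {
    if (is.null(config$records)) {
      read_diet_records(config$records_path,
                        percent_mode = config$percent_mode)
    } else {
      res <- validate_diet_records(config$records,
                                   percent_mode = config$percent_mode)
      attr(res$records, "rejections") <- res$rejections
      res$records
    }
  })
  utils::write.csv(rejection_report(records), out("rejections.csv"),
                   row.names = FALSE)

  refined <- stage("refine", apply_refinement(records, config$refinement))
  write_refinement_report(refined$report, out("refinement_report.csv"))

  grouped <- stage("group", map_taxa(refined$records, config$group_scheme))
  utils::write.csv(grouped$unmapped, out("unmapped_taxa.csv"),
                   row.names = FALSE)

  coarse_map <- config$coarse_map
  if (is.null(coarse_map)) {
    coarse_map <- coarse_map_from_scheme(config$group_scheme)
  }

  by_sector <- stage("sectors", split_by_sector(grouped$records,
                                                config$scheme))
  units <- c(by_sector, list("Southern Ocean" = grouped$records))

  summary_rows <- list()
  unit_results <- list()
  for (unit in names(units)) {
    recs <- units[[unit]]
    slug <- .slug(unit)
    if (nrow(recs) == 0) {
      summary_rows[[unit]] <- data.frame(
        sector = unit, n_sources = 0L, n_observations = 0L,
        S = NA_integer_, L = NA_integer_, C = NA_real_, LD = NA_real_,
        status = "no data", stringsAsFactors = FALSE)
      unit_results[[unit]] <- list(status = "no data")
      next
    }
    res <- stage(paste0("webs:", unit), {
      write_diet_records(recs, out(paste0(slug, "_records.csv")))
      fine <- build_web(recs, metric = "occurrence",
                        require_metric = config$require_metric)
      coarse <- coarsen(recs, coarse_map)
      write_edge_list(fine, out(paste0(slug, "_fine_edges.csv")))
      write_graphml(fine, out(paste0(slug, "_fine.graphml")))
      write_edge_list(coarse, out(paste0(slug, "_coarse_edges.csv")))
      summ <- if (length(fine$nodes)) network_summary(fine) else NULL
      strengths <- strength_table(fine, config$group_scheme)
      utils::write.csv(strengths, out(paste0(slug, "_strengths.csv")),
                       row.names = FALSE, na = "")
      acc <- accumulation_curve(recs, n_perm = config$n_perm,
                                seed = config$seed)
      fit <- if (acc$n_sources >= 3) fit_negative_exponential(acc) else NULL
      write_accumulation(acc, out(paste0(slug, "_accumulation.csv")),
                         fit = fit)
      list(fine = fine, coarse = coarse, summary = summ,
           strengths = strengths, accumulation = acc, fit = fit,
           status = "ok")
    })
    unit_results[[unit]] <- res
    summary_rows[[unit]] <- data.frame(
      sector = unit,
      n_sources = length(unique(recs$source_id)),
      n_observations = nrow(recs),
      S = if (is.null(res$summary)) NA_integer_ else res$summary$S,
      L = if (is.null(res$summary)) NA_integer_ else res$summary$L,
      C = if (is.null(res$summary)) NA_real_ else res$summary$C,
      LD = if (is.null(res$summary)) NA_real_ else res$summary$LD,
      status = if (is.null(res$summary)) "no links" else "ok",
      stringsAsFactors = FALSE)
  }
  summary_tab <- do.call(rbind, summary_rows[names(units)])
  rownames(summary_tab) <- NULL
  utils::write.csv(summary_tab, out("network_summary.csv"),
                   row.names = FALSE, na = "")

  counts <- c(read = nrow(records),
              rejected = nrow(rejection_report(records)),
              refined = nrow(refined$records),
              refinement_drops = nrow(refined$report),
              grouped = nrow(grouped$records),
              unmapped = nrow(grouped$unmapped))
  log_lines <- c(
    sprintf("config_hash: %s", .config_hash(config)),
    sprintf("seed: %d  n_perm: %d", config$seed, config$n_perm),
    sprintf("%s: %d", names(counts), counts)
  )
  writeLines(log_lines, out("run_log.txt"))

  invisible(structure(
    list(units = unit_results, summary = summary_tab, counts = counts,
         out_dir = config$out_dir),
    class = "pipeline_result"
  ))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("dietweb pipeline run ->", x$out_dir, "\n")
  print(x$summary)
  invisible(x)
}
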