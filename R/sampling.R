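## Species-accumulation diagnostics: do the regional webs just reflect how
## hard each region was sampled? The sampling unit is the source study, not
## the record; accumulation is classical without-replacement sampling of
## sources, so the Monte-Carlo curve has an exact hypergeometric expectation.

.source_group_sets <- function(records) {
  stopifnot(all(c("source_id", "prey_name") %in% names(records)))
  sources <- sort(unique(records$source_id))
  if (length(sources) == 0) stop("no sources in records")
  lapply(stats::setNames(sources, sources), function(s) {
    unique(records$prey_name[records$source_id == s])
  })
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Source-randomized species accumulation curve
#'
#' Mean cumulative number of distinct prey groups observed after sampling
#' x = 1..n distinct source studies, averaged over `n_perm` random orderings
#' of the sources (sampling without replacement). Deterministic given the
#' seed; the caller's RNG state is left untouched.
#'
#' @param records grouped records carrying `source_id` and prey group names.
#' @param n_perm number of random source orderings.
#' @param seed integer seed.
#' @return an `accumulation_result`: list with `curve` (data.frame `x`,
#'   `mean_count`, `sd_count` -- the across-permutation standard deviation),
#'   `n_sources`, `total_groups`, `n_perm`, `seed`.
#' @export
accumulation_curve <- function(records, n_perm = 1000, seed = 1) {
  sets <- .source_group_sets(records)
  n <- length(sets)
  all_groups <- sort(unique(unlist(sets)))
  set_idx <- lapply(sets, function(g) match(g, all_groups))
  counts <- matrix(0L, nrow = n_perm, ncol = n)
  .with_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm <- sample.int(n)
      seen <- logical(length(all_groups))
      acc <- 0L
      for (j in seq_len(n)) {
        idx <- set_idx[[perm[j]]]
        new <- idx[!seen[idx]]
        seen[new] <- TRUE
        acc <- acc + length(new)
        counts[p, j] <- acc
      }
    }
  })
  structure(
    list(curve = data.frame(x = seq_len(n),
                            mean_count = colMeans(counts),
                            sd_count = apply(counts, 2, stats::sd)),
         n_sources = n, total_groups = length(all_groups),
         n_perm = n_perm, seed = seed),
    class = "accumulation_result"
  )
}

#' Exact expected accumulation curve
#'
#' Closed-form expectation of the without-replacement accumulation curve:
#' a group seen in n_g of the n sources is absent from a random sample of x
#' sources with hypergeometric probability C(n - n_g, x)/C(n, x), so
#' E[count at x] = sum over groups of 1 - C(n - n_g, x)/C(n, x). Serves as
#' the analytical oracle for [accumulation_curve()].
#'
#' @param records grouped records carrying `source_id` and prey group names.
#' @return data.frame with columns `x`, `expected_count`.
#' @export
accumulation_expectation <- function(records) {
  sets <- .source_group_sets(records)
  n <- length(sets)
  all_groups <- unique(unlist(sets))
  n_g <- vapply(all_groups, function(g) {
    sum(vapply(sets, function(s) g %in% s, logical(1)))
  }, numeric(1))
  expected <- vapply(seq_len(n), function(x) {
    # lchoose returns -Inf when x > n - n_g: absence impossible, term = 1
    p_absent <- exp(lchoose(n - n_g, x) - lchoose(n, x))
    sum(1 - p_absent)
  }, numeric(1))
  data.frame(x = seq_len(n), expected_count = expected)
}

#' Fit a negative exponential to an accumulation curve
#'
#' Least-squares fit of S(x) = S_max (1 - exp(-k x)) to the mean curve,
#' with the documented initialization S_max0 = max(count), k0 = 1. Uses
#' [stats::nls()]; on failure (e.g. a flat curve makes the gradient
#' singular) falls back to Nelder-Mead on the log-parameter scale. A fit is
#' flagged (`flagged = TRUE`) rather than silently trusted when the
#' optimizer did not converge or the rate has run to the boundary
#' (exp(-k) < 1e-8: the curve is flat within the model class and S_max is
#' just the plateau value).
#'
#' @param curve an `accumulation_result`, or a data.frame whose first two
#'   columns are x and the (mean or expected) count; >= 3 points required.
#' @return a `neg_exp_fit`: list with `S_max`, `k`, `rss`, `converged`,
#'   `flagged`, `message`.
#' @export
fit_negative_exponential <- function(curve) {
  if (inherits(curve, "accumulation_result")) curve <- curve$curve
  x <- curve[[1]]
  y <- curve[[2]]
  if (length(x) < 3) stop("at least 3 curve points required")
  smax0 <- max(y)
  k0 <- 1
  fit <- tryCatch(
    stats::nls(y ~ smax * (1 - exp(-k * x)),
               start = list(smax = smax0, k = k0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e
  )
  if (inherits(fit, "nls")) {
    par <- stats::coef(fit)
    res <- list(S_max = unname(par["smax"]), k = unname(par["k"]),
                rss = sum(stats::resid(fit)^2), converged = TRUE,
                message = "nls converged")
  } else {
    rss_fn <- function(lp) {
      smax <- exp(lp[1]); k <- exp(lp[2])
      sum((y - smax * (1 - exp(-k * x)))^2)
    }
    opt <- stats::optim(c(log(max(smax0, 1e-8)), log(k0)), rss_fn,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    res <- list(S_max = exp(opt$par[1]), k = exp(opt$par[2]),
                rss = opt$value, converged = opt$convergence == 0,
                message = paste("nls failed (", conditionMessage(fit),
                                "); Nelder-Mead fallback", sep = ""))
  }
  res$flagged <- !res$converged || exp(-res$k) < 1e-8
  if (res$flagged && exp(-res$k) < 1e-8) {
    res$message <- paste(res$message, "- boundary fit: rate at upper limit,",
                         "curve flat within the model class")
  }
  structure(res, class = "neg_exp_fit")
}

#' @export
print.neg_exp_fit <- function(x, ...) {
  cat(sprintf("S(x) = S_max (1 - exp(-k x)): S_max = %.4f, k = %.4f, rss = %.3g%s\n",
              x$S_max, x$k, x$rss,
              if (x$flagged) "  [FLAGGED]" else ""))
  invisible(x)
}

#' @export
print.accumulation_result <- function(x, ...) {
  cat(sprintf("accumulation over %d sources (%d prey groups, %d permutations, seed %d)\n",
              x$n_sources, x$total_groups, x$n_perm, x$seed))
  invisible(x)
}

#' Write an accumulation curve (and optional fit) to CSV
#'
#' The permutation count and seed are recorded as comment metadata in the
#' first lines of the file.
#'
#' @param result an `accumulation_result`.
#' @param path output path.
#' @param fit optional `neg_exp_fit` to record in the metadata.
#' @return `path`, invisibly.
#' @export
write_accumulation <- function(result, path, fit = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# n_perm=%d seed=%d n_sources=%d total_groups=%d",
                     result$n_perm, result$seed, result$n_sources,
                     result$total_groups), con)
  if (!is.null(fit)) {
    writeLines(sprintf("# fit S_max=%.10g k=%.10g rss=%.10g flagged=%s",
                       fit$S_max, fit$k, fit$rss, fit$flagged), con)
  }
  utils::write.csv(result$curve, con, row.names = FALSE)
  invisible(path)
}
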