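# Fixture builders and independent brute-force oracles. Oracles use plain
# loops and enumeration only -- they never call the code paths they check.

make_records <- function(n = 1, record_id = sprintf("r%03d", seq_len(n)),
                         source_id = "study1", predator_name = "pred",
                         prey_name = "prey", latitude = -60, longitude = 0,
                         month = 12L, fraction_occurrence = 0.5,
                         fraction_diet_weight = NA_real_,
                         method = "stomach") {
  r <- function(v) rep_len(v, n)
  data.frame(record_id = r(record_id), source_id = r(source_id),
             predator_name = r(predator_name), prey_name = r(prey_name),
             latitude = r(latitude), longitude = r(longitude),
             month = r(as.integer(month)),
             fraction_occurrence = r(fraction_occurrence),
             fraction_diet_weight = r(fraction_diet_weight),
             method = r(method), stringsAsFactors = FALSE)
}

# Random grouped-record fixture over small node sets; weights may be missing.
random_grouped_records <- function(n, n_groups = 6, p_missing = 0.3) {
  groups <- paste0("g", seq_len(n_groups))
  fo <- round(runif(n), 3)
  fw <- round(runif(n), 3)
  fo[runif(n) < p_missing] <- NA_real_
  fw[runif(n) < p_missing] <- NA_real_
  make_records(n,
               source_id = sample(paste0("s", 1:4), n, replace = TRUE),
               predator_name = sample(groups, n, replace = TRUE),
               prey_name = sample(groups, n, replace = TRUE),
               fraction_occurrence = fo, fraction_diet_weight = fw)
}

# Brute-force network statistics from an edge table: explicit loops over
# every (prey, predator) node pair and every edge.
oracle_stats <- function(edges) {
  nodes <- sort(unique(c(edges$prey, edges$predator)))
  S <- length(nodes)
  L <- 0L
  for (a in nodes) for (b in nodes) {
    if (any(edges$prey == a & edges$predator == b)) L <- L + 1L
  }
  out_deg <- in_deg <- setNames(integer(S), nodes)
  out_occ <- in_occ <- out_diet <- in_diet <- setNames(numeric(S), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$prey[i]; b <- edges$predator[i]
    out_deg[a] <- out_deg[a] + 1L
    in_deg[b] <- in_deg[b] + 1L
    if (!is.na(edges$weight_occurrence[i])) {
      out_occ[a] <- out_occ[a] + edges$weight_occurrence[i]
      in_occ[b] <- in_occ[b] + edges$weight_occurrence[i]
    }
    if (!is.na(edges$weight_diet[i])) {
      out_diet[a] <- out_diet[a] + edges$weight_diet[i]
      in_diet[b] <- in_diet[b] + edges$weight_diet[i]
    }
  }
  list(S = S, L = L, C = L / S^2, LD = L / S,
       out_deg = out_deg, in_deg = in_deg,
       out_occ = out_occ, in_occ = in_occ,
       out_diet = out_diet, in_diet = in_diet)
}

# All permutations of 1..n (n small), for exhaustive accumulation oracles.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Exact expected accumulation curve by enumerating every source ordering.
enum_accumulation <- function(sets) {
  n <- length(sets)
  perms <- all_permutations(n)
  totals <- numeric(n)
  for (perm in perms) {
    seen <- character(0)
    for (j in seq_len(n)) {
      seen <- union(seen, sets[[perm[j]]])
      totals[j] <- totals[j] + length(seen)
    }
  }
  totals / length(perms)
}

# Exact variance of the cumulative distinct-group count at each x, by
# hypergeometric inclusion-exclusion over group pairs: the count is a sum of
# presence indicators, absence probabilities are C(n - n_g, x)/C(n, x), and
# joint absence of g and h is C(n_00, x)/C(n, x) with n_00 the number of
# sources containing neither. Gives the true standard error of a Monte-Carlo
# mean even where a finite sample sits exactly on the plateau (estimated
# sd = 0).
exact_accum_var <- function(sets) {
  n <- length(sets)
  groups <- unique(unlist(sets))
  has <- vapply(sets, function(s) groups %in% s,
                logical(length(groups)))  # groups x sources
  if (length(groups) == 1) has <- matrix(has, nrow = 1)
  absent_prob <- function(m, x) {
    if (x > n - m) 0 else exp(lchoose(n - m, x) - lchoose(n, x))
  }
  vapply(seq_len(n), function(x) {
    a <- vapply(rowSums(has), absent_prob, numeric(1), x = x)
    v <- sum((1 - a) * a)
    if (length(groups) >= 2) {
      for (g in seq_len(length(groups) - 1)) {
        for (h in seq((g + 1), length(groups))) {
          n00 <- sum(!has[g, ] & !has[h, ])
          both_absent <- absent_prob(n - n00, x)
          cov_gh <- both_absent - a[g] * a[h]
          v <- v + 2 * cov_gh
        }
      }
    }
    v
  }, numeric(1))
}

write_records_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(c(paste(dietweb::diet_record_columns, collapse = ","), lines),
             path)
  path
}
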