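test_that("map_taxa relabels to groups and reports unmapped taxa", {
  scheme <- group_scheme(data.frame(
    taxon = c("Euphausia superba", "Pygoscelis antarcticus", "Electrona"),
    group = c("Antarctic krill", "chinstrap penguin", "myctophids"),
    mid_trophic = c(TRUE, FALSE, TRUE)
  ))
  recs <- make_records(3, predator_name = c("Pygoscelis antarcticus",
                                            "Pygoscelis antarcticus",
                                            "Xenobalanus"),
                       prey_name = c("Euphausia superba", "Electrona",
                                     "Euphausia superba"))
  res <- map_taxa(recs, scheme)
  expect_equal(res$records$prey_name, c("Antarctic krill", "myctophids"))
  expect_equal(res$records$predator_name, rep("chinstrap penguin", 2))
  expect_equal(res$unmapped$taxon, "Xenobalanus")
  expect_equal(nrow(res$records), nrow(recs) - nrow(res$unmapped))
})

test_that("edge weights are record-level means; missing metrics excluded from them", {
  recs <- make_records(2, predator_name = "chinstrap penguin",
                       prey_name = "Antarctic krill",
                       fraction_occurrence = c(0.4, 0.6),
                       fraction_diet_weight = c(0.3, NA))
  web <- build_web(recs)
  expect_equal(nrow(web$edges), 1)
  expect_equal(web$edges$weight_occurrence, 0.5)
  expect_equal(web$edges$weight_diet, 0.3)  # mean over the one reported value
  expect_equal(web$edges$n_records, 2)
})

test_that("require_metric omits pairs with no value for the chosen metric", {
  recs <- make_records(2, prey_name = c("krill", "squid"),
                       fraction_occurrence = c(NA, 0.2))
  web <- build_web(recs, metric = "occurrence", require_metric = TRUE)
  expect_equal(web$edges$prey, "squid")
  expect_false("krill" %in% web$nodes)
  # without the flag the pair stays, weight missing
  web2 <- build_web(recs, require_metric = FALSE)
  expect_equal(nrow(web2$edges), 2)
  expect_true(is.na(web2$edges$weight_occurrence[web2$edges$prey == "krill"]))
})

test_that("an empty input gives an empty web, not an error", {
  web <- build_web(make_records(0))
  expect_s3_class(web, "food_web")
  expect_equal(length(web$nodes), 0)
  expect_error(network_summary(web), "empty")
})

test_that("on random fixtures every edge weight equals the brute-force mean", {
  set.seed(21)
  for (rep in 1:5) {
    recs <- random_grouped_records(50)
    web <- build_web(recs, require_metric = FALSE)
    # conservation of records into edges
    expect_equal(sum(web$edges$n_records), nrow(recs))
    # nodes are exactly the groups on >= 1 edge
    expect_setequal(web$nodes, c(web$edges$prey, web$edges$predator))
    for (i in seq_len(nrow(web$edges))) {
      sel <- recs$prey_name == web$edges$prey[i] &
        recs$predator_name == web$edges$predator[i]
      for (pair in list(c("weight_occurrence", "fraction_occurrence"),
                        c("weight_diet", "fraction_diet_weight"))) {
        v <- recs[[pair[2]]][sel]
        v <- v[!is.na(v)]
        expected <- if (length(v)) mean(v) else NA_real_
        expect_equal(web$edges[[pair[1]]][i], expected)
      }
      expect_equal(web$edges$n_records[i], sum(sel))
    }
  }
})

test_that("coarsening pools records across fine groups before averaging", {
  coarse_map <- data.frame(group = c("myctophids", "bathylagids", "penguin"),
                           coarse_group = c("mesopelagic fish",
                                            "mesopelagic fish", "penguins"))
  recs <- make_records(3, predator_name = "penguin",
                       prey_name = c("myctophids", "bathylagids", "myctophids"),
                       fraction_diet_weight = c(0.3, 0.6, 0.9))
  web <- coarsen(recs, coarse_map)
  expect_equal(nrow(web$edges), 1)
  expect_equal(web$edges$prey, "mesopelagic fish")
  expect_equal(web$edges$weight_diet, 0.6)
  expect_false(web$edges$weight_missing)
})

test_that("links without any diet-weight data are kept but flagged", {
  coarse_map <- data.frame(group = c("krill", "seal"),
                           coarse_group = c("zooplankton", "seals"))
  recs <- make_records(1, predator_name = "seal", prey_name = "krill",
                       fraction_diet_weight = NA_real_)
  web <- coarsen(recs, coarse_map)
  expect_equal(nrow(web$edges), 1)
  expect_true(web$edges$weight_missing)
})

test_that("a fine group missing from the coarse map is a configuration error", {
  coarse_map <- data.frame(group = "krill", coarse_group = "zooplankton")
  recs <- make_records(1, predator_name = "seal", prey_name = "krill")
  expect_error(coarsen(recs, coarse_map), "absent from the coarse mapping")
})

test_that("coarsening never increases the edge count", {
  set.seed(31)
  for (rep in 1:5) {
    recs <- random_grouped_records(40)
    groups <- unique(c(recs$predator_name, recs$prey_name))
    coarse_map <- data.frame(
      group = groups,
      coarse_group = sample(c("A", "B", "C"), length(groups), replace = TRUE)
    )
    fine <- build_web(recs, require_metric = FALSE)
    coarse <- coarsen(recs, coarse_map)
    expect_lte(nrow(coarse$edges), nrow(fine$edges))
    # distinct coarse pairs by direct enumeration
    expected_pairs <- unique(paste(
      coarse_map$coarse_group[match(recs$prey_name, coarse_map$group)],
      coarse_map$coarse_group[match(recs$predator_name, coarse_map$group)]
    ))
    expect_equal(nrow(coarse$edges), length(expected_pairs))
  }
})

test_that("averaging fine-edge means is available as the alternative rule", {
  coarse_map <- data.frame(group = c("a", "b", "pred"),
                           coarse_group = c("AB", "AB", "P"))
  # pair (a,pred): weights 0.2, 0.4 -> fine mean 0.3; pair (b,pred): 0.8
  recs <- make_records(3, predator_name = "pred",
                       prey_name = c("a", "a", "b"),
                       fraction_diet_weight = c(0.2, 0.4, 0.8))
  pooled <- coarsen(recs, coarse_map, pool_records = TRUE)
  averaged <- coarsen(recs, coarse_map, pool_records = FALSE)
  expect_equal(pooled$edges$weight_diet, mean(c(0.2, 0.4, 0.8)))
  expect_equal(averaged$edges$weight_diet, mean(c(0.3, 0.8)))
})

test_that("edge-list and GraphML exports round-trip the web structure", {
  recs <- random_grouped_records(30)
  web <- build_web(recs, require_metric = FALSE)
  csv <- tempfile(fileext = ".csv")
  write_edge_list(web, csv)
  back <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(back$prey, web$edges$prey)
  expect_equal(back$n_records, web$edges$n_records)
  gml <- tempfile(fileext = ".graphml")
  write_graphml(web, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), length(web$nodes))
  expect_equal(igraph::gsize(g), nrow(web$edges))
})
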