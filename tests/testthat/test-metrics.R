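abcd <- c("a", "b", "c", "d")

test_that("contingency table counts shared proteins exactly", {
  t1 <- contingency_table(list(c("a", "b", "c")), list(c("a", "b", "c")))
  expect_equal(unclass(t1)[1, 1], 3L, ignore_attr = TRUE)

  t2 <- contingency_table(list(abcd), list(c("a", "b"), c("c", "d")))
  expect_equal(as.integer(t2), c(2L, 2L))
  expect_equal(attr(t2, "row_sizes"), 4L)
  expect_equal(attr(t2, "col_sizes"), c(2L, 2L))

  t3 <- contingency_table(list(c("a", "b")), list(c("x", "y")))
  expect_true(all(t3 == 0))

  expect_error(contingency_table(list(character(0)), list("a")), "non-empty")
})

test_that("SN, PPV and ACC follow the contingency formulas", {
  perfect <- contingency_table(list(c("a", "b"), c("c", "d")),
                               list(c("a", "b"), c("c", "d")))
  expect_equal(as.list(sn_ppv_acc(perfect)), list(sn = 1, ppv = 1, acc = 1))

  split2 <- sn_ppv_acc(contingency_table(list(abcd), list(c("a", "b"), c("c", "d"))))
  expect_equal(split2$sn, 0.5)
  expect_equal(split2$ppv, 1)
  expect_equal(split2$acc, sqrt(0.5))

  zero <- sn_ppv_acc(contingency_table(list(c("a", "b")), list(c("x", "y"))))
  expect_equal(as.numeric(zero), c(0, 0, 0))
})

test_that("separation is the geometric mean of both averages", {
  perfect <- contingency_table(list(c("a", "b"), c("c", "d")),
                               list(c("a", "b"), c("c", "d")))
  expect_equal(separation(perfect), 1)

  expect_equal(separation(contingency_table(list(c("a", "b")), list(c("x", "y")))), 0)

  sp <- separation(contingency_table(list(abcd), list(c("a", "b"), c("c", "d"))))
  expect_equal(sp, sqrt(0.5), tolerance = 1e-12)
})

test_that("overlap score is squared intersection over size product", {
  expect_equal(overlap_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap_score(c("a", "b"), c("x", "y")), 0)
  expect_equal(overlap_score(c("a", "b", "c"), abcd), 9 / 12)
  expect_error(overlap_score(character(0), "a"), "non-empty")
})

test_that("fraction match uses a strict threshold in the stated direction", {
  expect_equal(fraction_match(list(c("a", "b")), list(c("a", "b"))), 1)
  expect_equal(fraction_match(list(c("a", "b")), list(c("x", "y"))), 0)
  # overlap 4/8 = 0.5 > 0.25
  expect_equal(fraction_match(list(abcd), list(c("a", "b"))), 1)
  # overlap exactly at the threshold does not count
  expect_equal(fraction_match(list(abcd), list("a")), 0)

  # direction flag: two clusters, only one matched
  gold <- list(abcd)
  pred <- list(c("a", "b"), c("x", "y"))
  expect_equal(fraction_match(gold, pred, count = "gold"), 1)
  expect_equal(fraction_match(gold, pred, count = "pred"), 0.5)
})

test_that("maximum matching ratio matches hand cases and brute force", {
  expect_equal(max_matching_ratio(list(c("a", "b"), c("c", "d")),
                                  list(c("a", "b"), c("c", "d"))), 1)
  expect_equal(max_matching_ratio(list(abcd), list(c("a", "b", "c"))), 0.75)

  # one cluster overlapping each of two complexes at 0.75: only one edge
  # can enter the matching
  gold <- list(c("a", "b", "c"), c("d", "e", "f"))
  pred <- list(c("a", "b", "c", "d", "e", "f")[c(1, 2, 3, 4)])  # hits both
  w1 <- overlap_score(gold[[1]], pred[[1]])
  w2 <- overlap_score(gold[[2]], pred[[1]])
  expect_equal(max_matching_ratio(gold, pred), max(w1, w2) / 2)

  set.seed(61)
  for (i in 1:20) {
    universe <- paste0("p", 1:12)
    gold <- rand_complex_set(sample(2:6, 1), universe)
    pred <- rand_complex_set(sample(2:6, 1), universe)
    w <- outer(seq_along(gold), seq_along(pred),
               Vectorize(function(i, j) overlap_score(gold[[i]], pred[[j]])))
    expect_equal(max_matching_ratio(gold, pred),
                 brute_matching_weight(w) / length(gold),
                 tolerance = 1e-9)
  }
})

test_that("Jaccard precision/recall require similarity strictly above 0.5", {
  expect_equal(as.numeric(jaccard_prf(list(abcd), list(abcd))), c(1, 1, 1))
  expect_equal(as.numeric(jaccard_prf(list(abcd), list(c("a", "b", "c")))), c(1, 1, 1))
  # Jaccard exactly 0.5 is not a match
  expect_equal(as.numeric(jaccard_prf(list(abcd), list(c("a", "b")))), c(0, 0, 0))
})

test_that("affinity-matched precision+/recall+ respect theta and the matching", {
  expect_equal(as.numeric(na_prf(list(abcd), list(abcd), theta = 0.5)), c(1, 1, 1))
  expect_equal(as.numeric(na_prf(list(abcd), list(c("a", "b", "c")), theta = 0.8)),
               c(0, 0, 0))

  # 2 complexes, 3 clusters, one eligible pair: (1/3, 1/2, 0.4)
  gold <- list(c("a", "b"), c("c", "d"))
  pred <- list(c("a", "b"), c("x", "y"), c("z", "w"))
  expect_equal(as.numeric(na_prf(gold, pred, theta = 0.5)), c(1 / 3, 1 / 2, 0.4))

  expect_error(na_prf(gold, pred, theta = 1.5), "\\[0, 1\\]")
})

test_that("precision+/recall+ are monotone non-increasing in theta", {
  set.seed(67)
  thetas <- seq(0, 1, by = 0.05)
  for (i in 1:10) {
    universe <- paste0("p", 1:15)
    gold <- rand_complex_set(sample(2:5, 1), universe)
    pred <- rand_complex_set(sample(2:5, 1), universe)
    f <- vapply(thetas, function(th) na_prf(gold, pred, th)$f_measure_plus, 0)
    expect_true(all(diff(f) <= 1e-12))
  }
})

test_that("modularity matches hand evaluation and rejects overlaps", {
  tri2 <- ppi_graph(rbind(t(combn(c("a", "b", "c"), 2)), t(combn(c("d", "e", "f"), 2))))
  expect_equal(cluster_modularity(tri2, list(c("a", "b", "c"), c("d", "e", "f"))), 0.5)

  tri <- complete_graph(c("a", "b", "c"))
  expect_equal(cluster_modularity(tri, list(letters[1:3])), 0)
  expect_equal(cluster_modularity(tri, list("a", "b", "c")), -1 / 3)

  expect_error(cluster_modularity(tri, list(c("a", "b"), c("b", "c"))), "overlapping")
  expect_error(cluster_modularity(tri, list(c("a", "b"))), "partition")

  # random partition of an ER graph: modularity concentrates near zero
  set.seed(71)
  g <- rand_gnp(60, 0.2)
  memb <- split(igraph::V(g)$name, rep(1:6, each = 10))
  q <- cluster_modularity(g, unname(memb))
  expect_lt(abs(q), 0.1)
  expect_lte(q, 1)
})

test_that("composite score sums its five components", {
  expect_equal(
    composite_score(list(mmr = 0.75, frm = 1, sep = sqrt(0.5),
                         acc = sqrt(0.5), f_measure = 1)),
    0.75 + 1 + sqrt(0.5) + sqrt(0.5) + 1
  )
  expect_equal(
    composite_score(list(mmr = 0, frm = 0, sep = 0, acc = 0, f_measure = 0)), 0
  )
  expect_error(composite_score(list(mmr = 1)), "must provide")
})

test_that("MMR + F+ curve behaves across the theta grid", {
  gold <- list(c("a", "b"), c("c", "d"))
  ident <- mmr_fplus_curve(gold, gold, thetas = c(0, 0.5, 1))
  expect_equal(ident$mmr_f_plus, c(2, 2, 2))

  none <- mmr_fplus_curve(gold, list(c("x", "y")), thetas = c(0, 0.5))
  expect_equal(none$mmr_f_plus, c(0, 0))

  one <- mmr_fplus_curve(list(abcd), list(c("a", "b", "c")), thetas = c(0.5, 0.8))
  expect_equal(one$mmr_f_plus, c(0.75 + 1, 0.75 + 0))

  expect_error(mmr_fplus_curve(gold, gold, thetas = c(-0.1)), "\\[0, 1\\]")
})

test_that("a perfect disjoint prediction scores 1 everywhere", {
  net <- plant_network(fixture_plant_specs()$mixed_small, noise_edges = 0, seed = 9)
  rep <- score_clusters(net$complexes, net$complexes, graph = net$graph)
  vals <- tidy(rep)
  bounded <- vals$value[vals$measure %in% c(
    "sn", "ppv", "acc", "sep", "frm", "mmr", "precision", "recall",
    "f_measure", "precision_plus", "recall_plus", "f_measure_plus"
  )]
  expect_equal(bounded, rep(1, 12))
  expect_equal(rep$composite, 5)
  expect_s3_class(glance(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_output(print(rep), "metrics")
})

test_that("restricting the gold standard to network proteins drops outsiders", {
  g <- complete_graph(c("a", "b", "c"))
  gold <- list(c("a", "b", "c", "zz"), c("q1", "q2"))
  rep <- score_clusters(gold, list(c("a", "b", "c")), graph = g,
                        restrict_gold = TRUE)
  expect_equal(rep$n_gold, 1L)
  expect_equal(rep$recall, 1)
})
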