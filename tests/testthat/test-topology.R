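test_that("node summaries count degrees, weights and range proportions", {
  parc <- toy_path_parcellation()
  tab <- toy_table(parc, data.frame(
    source = c("B", "C", "A", "A", "A", "F"),
    target = c("A", "A", "B", "C", "D", "A"),
    status = c("sparse", "dense", "intermediate", "dense", "absent", "sparse")
  ))
  summ <- suppressMessages(node_summaries(tab, parc,
                                          unknown_areas = parc$areas$name))
  a <- summ[summ$area == "A", ]
  expect_equal(a$in_degree, 3)
  expect_equal(a$out_degree, 2)
  expect_equal(a$degree, 5)
  # 2 sparse + 1 intermediate + 2 dense -> 2 + 10 + 200
  expect_equal(a$weighted_degree, 212)
  expect_equal(a$n_examined, 6)
  # distances from A: B=1, C=2, D=3, F=5 -> present at 1,1,2,5 and B->A,C->A
  expect_equal(a$prop_short, 4 / 5)
  expect_equal(a$prop_long, 1 / 5)
  # 6 areas: 10 ordered pairs involve A; 6 examined
  expect_equal(a$n_unknown, 4)
  e <- summ[summ$area == "E", ]
  expect_true(is.na(e$prop_short))
  expect_equal(e$degree, 0)
})

test_that("degree identities hold on generated data", {
  x <- synthetic_connectome(generator_config(n_areas = 25, seed = 52))
  summ <- suppressMessages(node_summaries(x$table, x$parcellation))
  n_present <- sum(binarize(x$table)$status == "present")
  expect_equal(sum(summ$in_degree), n_present)
  expect_equal(sum(summ$out_degree), n_present)
  expect_equal(summ$degree, summ$in_degree + summ$out_degree)
  expect_equal(summ$degree, summ$n_sparse + summ$n_intermediate + summ$n_dense)
  expect_equal(summ$weighted_degree,
               summ$n_sparse + 10 * summ$n_intermediate + 100 * summ$n_dense)
  expect_true(all(summ$prop_short + summ$prop_long <= 1, na.rm = TRUE))
})

test_that("degree-type correlations are computed over typed areas only", {
  x <- synthetic_connectome(generator_config(n_areas = 36, seed = 53))
  x$parcellation$areas$structural_type[1:4] <- NA
  summ <- suppressMessages(node_summaries(x$table, x$parcellation))
  res <- suppressMessages(degree_type_correlations(summ, x$parcellation))
  expect_named(res, c("degree", "weighted_degree", "n_sparse",
                      "n_intermediate", "n_dense", "n_examined"))
  expect_equal(res$degree$n, 32)
  expect_true(abs(res$degree$statistic) <= 1)
  res2 <- suppressMessages(degree_type_correlations(
    summ, x$parcellation, exclude = x$parcellation$areas$name[5:6]))
  expect_equal(res2$degree$n, 30)
})

test_that("module comparisons handle the degenerate all-equal case", {
  nm <- paste0("m", 1:12)
  adj <- matrix(FALSE, 12, 12, dimnames = list(nm, nm))
  for (i in 1:11) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  parc <- parcellation(data.frame(
    name = nm, structural_type = rep(3, 12),
    module = rep(MODULE_LEVELS, each = 3),
    hub = rep(c(TRUE, FALSE, FALSE), 4)), adj)
  mc <- suppressWarnings(module_comparisons(parc))
  expect_equal(mc$kruskal$statistic, 0)
  expect_equal(mc$jt_trend$statistic, 0)
  expect_equal(unname(mc$medians_module), rep(3, 4))
  expect_equal(nrow(mc$posthoc), 6)
})

test_that("module statistics on the stand-in fixture have the built-in gradient", {
  f <- load_fixture()
  mc <- suppressMessages(module_comparisons(f$parcellation))
  expect_equal(mc$n_areas, 48)
  # types decrease along visual -> auditory -> somatosensory -> fronto-limbic
  expect_lt(mc$jt_trend$statistic, 0)
  expect_lt(mc$jt_trend$p_value, 0.05)
  expect_true(all(diff(mc$medians_module) <= 0))
  # hub areas sit at the low-type end
  expect_lt(mc$medians_hub["hub"], mc$medians_hub["nonhub"])
})

test_that("robustness scan reduces to the plain correlation at q = 0", {
  x <- synthetic_connectome(generator_config(n_areas = 36, seed = 54))
  summ <- suppressMessages(node_summaries(x$table, x$parcellation))
  rob <- suppressMessages(robustness_scan(summ, x$parcellation,
                                          q_grid = c(0, 0.5, 1)))
  base <- suppressMessages(degree_type_correlations(summ, x$parcellation))
  expect_equal(rob$rho[rob$q == 0], base$degree$statistic)
  expect_equal(rob$p_value[rob$q == 0], base$degree$p_value)
  expect_error(robustness_scan(summ, x$parcellation, q_grid = numeric(0)),
               "empty")
})

test_that("robustness scan matches a direct recomputation oracle at q = 1", {
  x <- synthetic_connectome(generator_config(n_areas = 36, seed = 55))
  summ <- suppressMessages(node_summaries(x$table, x$parcellation))
  rob <- suppressMessages(robustness_scan(summ, x$parcellation, q_grid = 1))
  ty <- setNames(x$parcellation$areas$structural_type,
                 x$parcellation$areas$name)
  df <- summ[!is.na(summ$n_unknown), ]
  expect_equal(rob$rho,
               oracle_spearman_rho(df$degree + df$n_unknown,
                                   unname(ty[df$area])))
  # with uniform unknown counts the correlation is unchanged by q
  summ2 <- summ
  summ2$n_unknown[!is.na(summ2$n_unknown)] <- 10L
  rob2 <- suppressMessages(robustness_scan(summ2, x$parcellation,
                                           q_grid = c(0, 1)))
  expect_equal(rob2$rho[1], rob2$rho[2])
})

test_that("connection-range trends aggregate per structural type", {
  f <- load_fixture()
  summ <- suppressMessages(node_summaries(f$table, f$parcellation))
  rt <- connection_range_trends(summ, f$parcellation)
  expect_equal(rt$by_type$structural_type, 1:5)
  expect_equal(sum(rt$by_type$n), 49)
  expect_true(all(rt$by_type$mean_prop_short >= 0 &
                    rt$by_type$mean_prop_short <= 1))
})
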