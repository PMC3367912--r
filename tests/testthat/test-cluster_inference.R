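test_that("paired t maps match hand computation, antisymmetry, and flagging", {
  d <- matrix(c(1, 2, 3), 3, 1)   # differences {1,2,3}: t = 2 / (1/sqrt(3))
  expect_equal(as.vector(paired_t_map(d)), 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(as.vector(paired_t_map(d)), 3.4641, tolerance = 1e-4)
  a <- matrix(rnorm(5 * 4), 5, 4); b <- matrix(rnorm(5 * 4), 5, 4)
  expect_equal(paired_t_map(a, b), -paired_t_map(b, a), ignore_attr = TRUE)
  const <- matrix(2, 4, 2)        # zero-variance differences are flagged
  tmap <- paired_t_map(const)
  expect_true(all(is.na(tmap)))
  expect_identical(attr(tmap, "flagged"), 1:2)
  expect_error(paired_t_map(matrix(1, 1, 3)), class = "oscmeg_config_error")
})

test_that("cluster formation enumerates a path-graph fixture and handles the empty case", {
  path_adj <- oscmeg:::adjacency_from_edges(5, cbind(1:4, 2:5))
  tmap <- c(5, 5, 0, -5, -5)
  cl <- form_clusters(tmap, path_adj, t_crit = 2)
  expect_length(cl, 2L)
  pos <- cl[[which(sapply(cl, `[[`, "sign") == 1)]]
  neg <- cl[[which(sapply(cl, `[[`, "sign") == -1)]]
  expect_identical(pos$members, 1:2); expect_equal(pos$sum_t, 10)
  expect_identical(neg$members, 4:5); expect_equal(neg$sum_t, -10)
  expect_length(form_clusters(c(0.5, -1, 0.2, 1, -0.3), path_adj, t_crit = 2), 0L)
})

test_that("cluster formation on a toy cortex matches the flood-fill oracle", {
  mesh <- fixture_mesh(50, 1)   # 100-vertex mesh
  adj <- vertex_adjacency(mesh)
  A <- adjacency_matrix_of(adj)
  set.seed(13)
  for (rep_ in 1:5) {
    tmap <- rnorm(mesh$n_vertices, sd = 2)
    cl <- form_clusters(tmap, adj, t_crit = 2)
    oracle <- c(flood_fill_clusters(which(tmap > 2), A),
                flood_fill_clusters(which(-tmap > 2), A))
    sig <- function(l) sort(vapply(l, function(m)
      paste(sort(as.integer(m)), collapse = "-"), ""))
    expect_identical(sig(lapply(cl, `[[`, "members")), sig(oracle))
    for (c_ in cl) expect_equal(c_$sum_t, sum(tmap[c_$members]))
  }
})

test_that("time-frequency lattice adjacency has the closed-form edge count", {
  expect_equal(nrow(tf_adjacency(c(1, 2), c(0, 1))$edges), 4L)
  n <- 7
  expect_equal(nrow(tf_adjacency(5, seq_len(n))$edges), n - 1L)
  expect_equal(nrow(tf_adjacency(c(4, 8, 16), 1:4)$edges), 3 * 3 + 2 * 4)
  # no diagonal adjacency: every edge differs in exactly one axis by one step
  adj <- tf_adjacency(c(4, 8, 16), 1:4)
  fi <- (adj$edges - 1) %% 3 + 1
  ti <- (adj$edges - 1) %/% 3 + 1
  expect_true(all((abs(fi[, 1] - fi[, 2]) + abs(ti[, 1] - ti[, 2])) == 1))
  expect_error(tf_adjacency(c(2, 1), 1:3), class = "oscmeg_config_error")
})

test_that("identical conditions produce no clusters", {
  x <- matrix(rnorm(5 * 6), 5, 6)
  adj <- oscmeg:::adjacency_from_edges(6, cbind(1:5, 2:6))
  res <- suppressWarnings(permutation_cluster_test(x, x, adj,
                                                   n_randomizations = 200, seed = 1))
  expect_length(res$clusters, 0L)
})

test_that("permutation p values match exhaustive sign-flip enumeration (5 subjects)", {
  set.seed(17)
  adj <- oscmeg:::adjacency_from_edges(3, cbind(1:2, 2:3))
  A <- adjacency_matrix_of(adj)
  t_crit <- stats::qt(1 - 0.025, 4)
  found <- 0
  for (rep_ in 1:8) {
    d <- matrix(rnorm(5 * 3, mean = rep_ * 0.3), 5, 3)
    res <- permutation_cluster_test(d, NULL, adj, n_randomizations = 1500, seed = 2)
    expect_true(res$exact)
    if (!length(res$clusters)) next
    found <- found + length(res$clusters)
    oracle_p <- enumerate_cluster_p(d, A, t_crit)
    expect_equal(sapply(res$clusters, `[[`, "p"), oracle_p, tolerance = 1e-12)
  }
  expect_gt(found, 0)
})

test_that("cluster statistics are invariant under element relabeling", {
  set.seed(19)
  mesh <- fixture_mesh(32, 1)
  adj <- vertex_adjacency(mesh)
  d <- matrix(rnorm(6 * mesh$n_vertices, 0.4, 1), 6)
  res1 <- permutation_cluster_test(d, NULL, adj, n_randomizations = 300, seed = 3)
  perm <- sample(mesh$n_vertices)
  inv_perm <- order(perm)
  adj2 <- oscmeg:::adjacency_from_edges(mesh$n_vertices,
                                        cbind(perm[adj$edges[, 1]], perm[adj$edges[, 2]]))
  res2 <- permutation_cluster_test(d[, inv_perm], NULL, adj2,
                                   n_randomizations = 300, seed = 3)
  stat1 <- sort(sapply(res1$clusters, `[[`, "sum_t"))
  stat2 <- sort(sapply(res2$clusters, `[[`, "sum_t"))
  expect_equal(stat1, stat2, tolerance = 1e-10)
  expect_equal(sort(sapply(res1$clusters, `[[`, "p")),
               sort(sapply(res2$clusters, `[[`, "p")), tolerance = 1e-12)
})

test_that("stronger planted effects never weaken the minimum cluster p", {
  set.seed(23)
  mesh <- fixture_mesh(32, 1)
  adj <- vertex_adjacency(mesh)
  noise <- matrix(rnorm(9 * mesh$n_vertices), 9)   # common random numbers
  effect <- matrix(0, 9, mesh$n_vertices)
  effect[, which(mesh$roi == "pericalcarine")] <- 1
  minp <- sapply(c(0.5, 1.5, 3), function(es) {
    res <- permutation_cluster_test(noise + es * effect, NULL, adj,
                                    n_randomizations = 600, seed = 4)
    if (length(res$clusters)) min(sapply(res$clusters, `[[`, "p")) else 1
  })
  expect_true(all(diff(minp) <= 0))
})

test_that("a-priori ROI t tests match hand computations and flag degeneracy", {
  mk <- function(vals_ph, vals_loc) {
    rbind(data.frame(subject = seq_along(vals_ph), roi = "cuneus",
                     hemisphere = "left", band = "alpha",
                     condition = "attend_phoneme", value_db = vals_ph),
          data.frame(subject = seq_along(vals_loc), roi = "cuneus",
                     hemisphere = "left", band = "alpha",
                     condition = "attend_location", value_db = vals_loc))
  }
  same <- roi_band_tests(mk(c(1, 2, 3, 4), c(1, 2, 3, 4) - 1e-30), "phoneme_vs_location")
  # identical condition values: t = 0 is degenerate (zero-variance difference)
  expect_true(same$flagged | (abs(same$t) < 1e-6 && same$p > 0.99))
  onep <- roi_band_tests(mk(c(1, 2, 3, 4, 5), c(0, 0, 0, 0, 0)), "active_vs_zero")
  ph <- onep[onep$condition == "attend_phoneme", ]
  expect_equal(ph$t, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-4)
  expect_equal(ph$t, 4.2426, tolerance = 1e-4)
  flagged <- roi_band_tests(mk(c(3, 3, 3, 3), c(0, 0, 0, 0)), "active_vs_zero")
  expect_true(flagged$flagged[flagged$condition == "attend_phoneme"])
  expect_error(roi_band_tests(mk(1:4, 1:4)[1:4, ], "phoneme_vs_location"),
               class = "oscmeg_data_error")
})
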