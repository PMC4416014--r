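test_that("LFR subnetwork hits its degree and mixing targets", {
  degs <- numeric(); mixes <- numeric()
  for (s in 1:10) {
    g <- generate_lfr_subnetwork(400, 4, 16, 0.2, seed = 300 + s)
    d <- tabulate(c(g$edges$u, g$edges$v), 400)
    degs <- c(degs, mean(d))
    mixes <- c(mixes, realized_mixing(g$edges, g$labels))
    expect_lte(max(d), 16)
    expect_gte(min(table(g$labels)), 10)
  }
  expect_lt(abs(mean(degs) - 4) / 4, 0.1)
  expect_lt(abs(mean(mixes) - 0.2), 0.05)
})

test_that("zero mixing gives a disjoint union over communities", {
  g <- generate_lfr_subnetwork(200, 4, 12, 0, seed = 2)
  expect_true(all(g$labels[g$edges$u] == g$labels[g$edges$v]))
})

test_that("mixed-module assignment covers both classes in every module", {
  withr::with_seed(71, {
    mix <- assign_mixed_modules(rep(1:3, times = c(5, 5, 5)),
                                rep(1:5, times = c(4, 4, 4, 4, 4)))
    expect_equal(mix$nc, 3)
    expect_setequal(mix$A, 1:3)          # bijection for the smaller side
    expect_setequal(unique(mix$B), 1:3)  # every module gets >= 1 B community

    mix2 <- assign_mixed_modules(rep(1:4, each = 3), rep(1:4, each = 3))
    expect_equal(mix2$nc, 4)
    expect_setequal(mix2$A, 1:4)
    expect_setequal(mix2$B, 1:4)
  })
})

test_that("B communities spread uniformly over modules under the constraint", {
  withr::with_seed(81, {
    counts <- matrix(0, 4, 2)
    for (i in 1:600) {
      mix <- assign_mixed_modules(rep(1:2, each = 3), rep(1:4, each = 3))
      for (b in 1:4) counts[b, mix$B[b]] <- counts[b, mix$B[b]] + 1
    }
    # each B community is symmetric between the two modules
    expect_true(all(abs(counts[, 1] / 600 - 0.5) < 0.08))
  })
})

test_that("bipartite link placement respects p and the edge budget", {
  modA <- rep(1:3, each = 10)
  modB <- rep(1:3, each = 20)
  bip1 <- generate_bipartite_links(30, 60, modA, modB, p = 1, kPi = 3,
                                   seed = 5)
  expect_equal(nrow(bip1), 90)
  expect_true(all(modA[bip1$a] == modB[bip1$b]))
  expect_false(any(duplicated(paste(bip1$a, bip1$b))))

  # p = 0: within-module fraction matches the size-based expectation
  withr::with_seed(91, {
    fr <- replicate(20, {
      bip0 <- generate_bipartite_links(30, 60, modA, modB, p = 0, kPi = 3)
      mean(modA[bip0$a] == modB[bip0$b])
    })
    baseline <- sum(10 * 20 * 3) / (30 * 60)
    expect_lt(abs(mean(fr) - baseline), 0.05)
  })
})

test_that("the default benchmark is a valid labeled 2-HN", {
  b <- generate_benchmark(benchmark_spec(seed = 33L))
  expect_s3_class(b$net, "hetnet")
  expect_equal(nrow(b$net$nodes), 1000)
  st <- subnetwork_stats(b$net)
  expect_true(st$mA > 0 && st$mPi > 0 && st$mB > 0)
  expect_equal(st$mPi, round(4 * 400))   # kPi * NA bipartite edges
  expect_length(b$labels, 1000)
  # every planted module is mixed
  types <- classify_modules(b$net, as_partition(b$labels, b$net))
  expect_true(all(types == "mixed"))
  # labels ride along in the node table
  expect_equal(unname(b$labels[b$net$nodes$node_id]), b$net$nodes$module)
})

test_that("generation is deterministic for a fixed spec and seed", {
  b1 <- generate_benchmark(benchmark_spec(seed = 44L))
  b2 <- generate_benchmark(benchmark_spec(seed = 44L))
  expect_identical(b1$net, b2$net)
  expect_identical(b1$labels, b2$labels)
  b3 <- generate_benchmark(benchmark_spec(seed = 45L))
  expect_false(identical(b1$net$edges, b3$net$edges))
})

test_that("realized mixing parameters track the requested values", {
  muAs <- numeric(); muBs <- numeric()
  for (s in 1:10) {
    b <- generate_benchmark(benchmark_spec(muA = 0.3, muB = 0.5,
                                           seed = 500 + s))
    idx <- stats::setNames(seq_len(nrow(b$net$nodes)), b$net$nodes$node_id)
    for (side in c("A", "B")) {
      ids <- b$net$nodes$node_id[b$net$nodes$class == side]
      ch <- if (side == "A") "AA" else "BB"
      sub <- b$net$edges[b$net$edges$channel == ch, ]
      loc <- stats::setNames(seq_along(ids), ids)
      comm <- b$communities[[side]]
      ed <- data.frame(u = loc[sub$u], v = loc[sub$v])
      m <- realized_mixing(ed, comm)
      if (side == "A") muAs <- c(muAs, m) else muBs <- c(muBs, m)
    }
  }
  expect_lt(abs(mean(muAs) - 0.3), 0.05)
  expect_lt(abs(mean(muBs) - 0.5), 0.05)
})

test_that("weighted benchmarks realize strength ~ degree^beta and weight mixing", {
  sm <- numeric(); bet <- numeric()
  for (s in 1:5) {
    b <- generate_benchmark(benchmark_spec(muA = 0.3, weighting = "GA",
                                           beta = 2, seed = 700 + s))
    aa <- b$net$edges[b$net$edges$channel == "AA", ]
    aid <- paste0("a", 1:400)
    loc <- stats::setNames(1:400, aid)
    ed <- data.frame(u = loc[aa$u], v = loc[aa$v], weight = aa$weight)
    deg <- tabulate(c(ed$u, ed$v), 400)
    str <- numeric(400)
    sums <- rowsum(c(ed$weight, ed$weight), c(ed$u, ed$v))
    str[as.integer(rownames(sums))] <- sums[, 1]
    # strength ~ degree^2 (log-log slope near 2)
    keep <- deg > 0
    bet <- c(bet, stats::coef(stats::lm(log(str[keep]) ~ log(deg[keep])))[2])
    sm <- c(sm, realized_mixing(ed, b$communities$A))
  }
  expect_lt(abs(mean(bet) - 2), 0.2)
  expect_lt(abs(mean(sm) - 0.3), 0.05)
})

test_that("infeasible parameter combinations raise generation errors", {
  expect_error(benchmark_spec(kA = 20, maxkA = 16), "kA")
  expect_error(generate_bipartite_links(3, 3, rep(1, 3), rep(1, 3),
                                        p = 1, kPi = 10),
               "capacity")
})
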