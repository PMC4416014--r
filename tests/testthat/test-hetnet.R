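test_that("channels are inferred from endpoint classes and counted per channel", {
  net <- hetnet(
    data.frame(node_id = c("c1", "g1", "g2"), class = c("A", "B", "B")),
    data.frame(u = c("c1", "g1"), v = c("g1", "g2")))
  st <- subnetwork_stats(net)
  expect_equal(st$mA, 0)
  expect_equal(st$mPi, 1)
  expect_equal(st$mB, 1)
  expect_equal(sort(unique(net$edges$channel)), c("AB", "BB"))
  # AB edges are stored A-endpoint first
  ab <- net$edges[net$edges$channel == "AB", ]
  expect_equal(ab$u, "c1")
})

test_that("invalid inputs are rejected with informative errors", {
  nodes <- data.frame(node_id = c("a1", "b1"), class = c("A", "B"))
  expect_error(hetnet(nodes, data.frame(u = "a1", v = "gX")), "unknown node")
  expect_error(hetnet(data.frame(node_id = "x", class = "C"),
                      data.frame(u = character(), v = character())),
               "class")
  expect_error(hetnet(nodes, data.frame(u = "a1", v = "b1", weight = 0)),
               "positive")
  expect_error(hetnet(nodes, data.frame(u = "a1", v = "b1", weight = -2)),
               "positive")
  expect_error(hetnet(nodes, data.frame(u = "a1", v = "a1")), "self-loop")
  expect_error(hetnet(nodes, data.frame(u = c("a1", "b1"), v = c("b1", "a1"))),
               "duplicate")
})

test_that("read/write round-trips networks exactly, including weights", {
  withr::with_seed(11, {
    for (i in 1:5) {
      net <- random_hetnet(n = 15, p_edge = 0.3)
      np <- withr::local_tempfile(fileext = ".tsv")
      ep <- withr::local_tempfile(fileext = ".tsv")
      write_hetnet(net, np, ep)
      back <- read_hetnet(np, ep)
      expect_equal(back$nodes, net$nodes)
      expect_equal(back$edges[order(back$edges$u, back$edges$v), ],
                   net$edges[order(net$edges$u, net$edges$v), ],
                   ignore_attr = TRUE)
    }
  })
  # full-precision weights and ground-truth label column survive
  net <- hetnet(data.frame(node_id = c("a1", "b1"), class = c("A", "B"),
                           module = c(3L, 3L)),
                data.frame(u = "a1", v = "b1", weight = 2.5))
  np <- withr::local_tempfile(); ep <- withr::local_tempfile()
  write_hetnet(net, np, ep)
  back <- read_hetnet(np, ep)
  expect_identical(back$edges$weight, 2.5)
  expect_identical(back$nodes$module, c(3L, 3L))
})

test_that("empty networks round-trip as header-only files", {
  net <- hetnet(data.frame(node_id = character(), class = character()),
                data.frame(u = character(), v = character()))
  np <- withr::local_tempfile(); ep <- withr::local_tempfile()
  write_hetnet(net, np, ep)
  expect_length(readLines(np), 1)
  expect_length(readLines(ep), 1)
  back <- read_hetnet(np, ep)
  expect_equal(nrow(back$nodes), 0)
  expect_equal(nrow(back$edges), 0)
})

test_that("subnetwork stats count strictly per channel and scale linearly", {
  net <- hetnet(
    data.frame(node_id = c("a1", "a2", "b1", "b2"),
               class = c("A", "A", "B", "B")),
    data.frame(u = c("a1", "a1", "b1"), v = c("a2", "b1", "b2")))
  st <- subnetwork_stats(net)
  expect_equal(st$mA, 1); expect_equal(st$mPi, 1); expect_equal(st$mB, 1)
  expect_equal(st$dA[["a1"]], 1)
  expect_equal(st$kPi[["a1"]], 1)
  expect_equal(st$dPi[["b1"]], 1)
  expect_equal(st$dB[["b1"]], 1)
  # degrees in channels a node cannot touch are zero
  expect_equal(st$dB[["a1"]], 0)
  expect_equal(st$dA[["b1"]], 0)
  expect_equal(st$kPi[["b1"]], 0)

  net2 <- net
  aa <- net2$edges$channel == "AA"
  net2$edges$weight[aa] <- net2$edges$weight[aa] * 2
  st2 <- subnetwork_stats(net2)
  expect_equal(st2$mA, 2 * st$mA)
  expect_equal(st2$dA, 2 * st$dA)
  expect_equal(st2$mPi, st$mPi)
  expect_equal(st2$mB, st$mB)
})

test_that("degree-sum identities hold on random networks", {
  withr::with_seed(7, {
    for (i in 1:10) {
      net <- random_hetnet(n = 50, p_edge = 0.08)
      st <- subnetwork_stats(net)
      expect_equal(sum(st$dA), 2 * st$mA)
      expect_equal(sum(st$kPi), st$mPi)
      expect_equal(sum(st$dPi), st$mPi)
      expect_equal(sum(st$dB), 2 * st$mB)
    }
  })
})

test_that("module-network export aggregates submodules with conservation", {
  net <- hetnet(
    data.frame(node_id = c("a1", "a2", "b1"), class = c("A", "A", "B")),
    data.frame(u = c("a1", "a1"), v = c("a2", "b1")))
  part <- as_partition(c(a1 = 1, a2 = 1, b1 = 1), net)
  prefix <- file.path(withr::local_tempdir(), "mod")
  out <- export_module_network(net, part, prefix)
  expect_equal(nrow(out$supernodes), 2)
  asn <- out$supernodes[out$supernodes$class == "A", ]
  expect_equal(asn$self_loop_weight, 1)
  expect_equal(asn$size, 2L)
  expect_equal(out$edges$weight, 1)   # single A-B supernode edge
  expect_equal(out$edges$intra, 1L)
  expect_true(file.exists(paste0(prefix, "_supernodes.tsv")))
  expect_true(file.exists(paste0(prefix, "_edges.tsv")))

  # single-class module emits exactly one supernode
  part2 <- as_partition(c(a1 = 1, a2 = 1, b1 = 2), net)
  out2 <- export_module_network(net, part2, prefix)
  expect_equal(sum(out2$supernodes$module_id == 2), 1)
  expect_equal(out2$edges$intra, 0L)

  # conservation: self-loops plus coarse edges account for all weight
  withr::with_seed(13, {
    for (i in 1:5) {
      rnet <- random_hetnet(n = 20, p_edge = 0.25)
      rpart <- random_partition(rnet, k = 3)
      o <- export_module_network(rnet, rpart, prefix)
      expect_equal(sum(o$supernodes$self_loop_weight) + sum(o$edges$weight),
                   sum(rnet$edges$weight))
    }
  })
})
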