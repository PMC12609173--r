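test_that("degree metrics and hub roles follow the chain example", {
  adj <- matrix(NA_real_, 4, 4, dimnames = rep(list(c("S", "A", "B", "C")), 2))
  adj["S", "A"] <- 0.8; adj["A", "B"] <- 0.7; adj["B", "C"] <- -0.5
  g <- causal_graph(adj)
  expect_equal(nrow(g$edges), 3)
  d <- classify_hubs(degree_metrics(g))
  rownames(d) <- d$node
  expect_equal(d["S", "outin_degree"], 1)
  expect_equal(d["A", "outin_degree"], 0)
  expect_equal(d["C", "outin_degree"], -1)
  expect_equal(d$role, c("source", "balanced", "balanced", "target"))
  expect_equal(d["A", "in_strength"], 0.8)
  expect_equal(d["A", "out_strength"], 0.7)
  # sub-threshold entries are dropped
  adj["C", "S"] <- 0.1
  expect_equal(nrow(causal_graph(adj, 0.2)$edges), 3)
})

test_that("degree metrics match an edge-enumeration oracle on random graphs", {
  for (s in 1:10) {
    set.seed(s)
    g <- causal_graph(random_adjacency(8))
    d <- degree_metrics(g)
    for (i in seq_len(8)) {
      out_e <- g$edges[g$edges$source == g$nodes[i], ]
      in_e <- g$edges[g$edges$target == g$nodes[i], ]
      expect_equal(d$out_degree[i], nrow(out_e))
      expect_equal(d$in_degree[i], nrow(in_e))
      expect_equal(d$out_strength[i], sum(abs(out_e$gc)), tolerance = 1e-12)
      expect_equal(d$in_strength[i], sum(abs(in_e$gc)), tolerance = 1e-12)
    }
  }
})

test_that("modularity matches igraph and closed forms", {
  set.seed(7)
  for (s in 1:10) {
    n <- sample(5:9, 1)
    g <- causal_graph(random_adjacency(n))
    if (nrow(g$edges) == 0) next
    memb <- sample(1:3, n, replace = TRUE)
    expect_equal(modularity_q(g, memb), igraph_q(g, memb), tolerance = 1e-12)
    # the all-in-one partition always has Q = 0 exactly
    expect_equal(modularity_q(g, rep(1, n)), 0, tolerance = 1e-12)
  }
  g0 <- causal_graph(matrix(NA_real_, 3, 3))
  expect_error(modularity_q(g0, 1:3), "no edges")
})

test_that("exhaustive modularity search finds the planted two-module split", {
  # two directed triangles joined by one weak edge
  adj <- matrix(NA_real_, 6, 6,
                dimnames = rep(list(c("a1", "a2", "a3", "b1", "b2", "b3")), 2))
  adj["a1", "a2"] <- adj["a2", "a3"] <- adj["a3", "a1"] <- 1
  adj["b1", "b2"] <- adj["b2", "b3"] <- adj["b3", "b1"] <- 1
  adj["a1", "b1"] <- 0.25
  g <- causal_graph(adj)
  part <- newman_modularity(g)
  expect_equal(part$method, "exhaustive")
  expect_length(unique(part$membership), 2)
  expect_equal(unname(part$membership[1:3]), rep(part$membership[["a1"]], 3))
  expect_equal(unname(part$membership[4:6]), rep(part$membership[["b1"]], 3))
  # the reported Q is the true maximum over every partition (test-local
  # enumeration, igraph evaluation)
  qs <- vapply(enum_partitions(6), function(p) igraph_q(g, p), 0)
  expect_equal(part$Q, max(qs), tolerance = 1e-12)
})

test_that("greedy search recovers clear module structure beyond the exhaustive limit", {
  # twelve nodes: two directed 6-cycles with a single weak bridge
  nm <- c(paste0("a", 1:6), paste0("b", 1:6))
  adj <- matrix(NA_real_, 12, 12, dimnames = list(nm, nm))
  for (i in 1:6) {
    adj[paste0("a", i), paste0("a", i %% 6 + 1)] <- 1
    adj[paste0("b", i), paste0("b", i %% 6 + 1)] <- 1
  }
  adj["a1", "b1"] <- 0.25
  g <- causal_graph(adj)
  part <- newman_modularity(g)
  expect_equal(part$method, "greedy")
  expect_length(unique(part$membership), 2)
  expect_length(unique(part$membership[1:6]), 1)
  expect_length(unique(part$membership[7:12]), 1)
  expect_gt(part$Q, 0.3)
})

test_that("ROI GC network recovers a planted chain and rejects degenerate input", {
  set.seed(9)
  T <- 2000
  x <- rnorm(T)
  y <- c(0, 0.8 * x[-T]) + rnorm(T, 0, 0.6)
  z <- c(0, 0.8 * y[-T]) + rnorm(T, 0, 0.6)
  g <- roi_gc_matrix(cbind(x = x, y = y, z = z), analysis_config())
  expect_setequal(paste(g$edges$source, g$edges$target),
                  c("x y", "y z"))
  expect_true(all(g$edges$sign == 1))
  # independent series stay unconnected
  g0 <- roi_gc_matrix(matrix(rnorm(T * 3), T), analysis_config())
  expect_equal(nrow(g0$edges), 0)
  expect_error(roi_gc_matrix(matrix(rnorm(20), 20, 1)), "at least 2")
  expect_error(roi_gc_matrix(matrix(rnorm(8 * 3), 8)), "at least 10")
})

test_that("binomial forward inference matches closed-form tails", {
  tab <- data.frame(domain = c("memory", "language", "motor"),
                    k = c(9, 0, 5), n = c(10, 8, 10), p = c(0.5, 0.3, 0.5))
  res <- forward_inference_decoding(tab, alpha = 0.05)
  expect_equal(res$p_value[1], 11 / 1024, tolerance = 1e-12)  # P(X >= 9), n=10, p=.5
  expect_equal(res$p_value[2], 1)                             # k = 0 is never enriched
  expect_equal(res$q, p.adjust(res$p_value, "BH"), tolerance = 1e-12)
  expect_true(res$enriched[1])
  expect_false(res$enriched[2])
  expect_error(forward_inference_decoding(data.frame(domain = "x", k = 5, n = 4, p = 0.5)),
               "0 <= k <= n")
  expect_error(forward_inference_decoding(data.frame(domain = "x", k = 1, n = 4, p = 1.2)),
               "base rates")
  expect_error(forward_inference_decoding(data.frame(domain = "x", k = 1)), "missing")
})
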