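block_matrix <- function(sizes, cor_within, n = 40, noise = NULL, seed = 1) {
  # planted blocks via a shared factor: within-block correlation cor_within
  set.seed(seed)
  if (is.null(noise)) noise <- 1
  loading <- sqrt(cor_within / (1 - cor_within)) * noise
  ng <- sum(sizes)
  x <- matrix(rnorm(ng * n, 0, noise), ng, n,
              dimnames = list(sprintf("g%03d", seq_len(ng)),
                              sprintf("s%03d", seq_len(n))))
  start <- cumsum(c(1, sizes))
  for (b in seq_along(sizes)) {
    f <- rnorm(n)
    idx <- start[b]:(start[b] + sizes[b] - 1)
    x[idx, ] <- x[idx, ] + loading * matrix(f, sizes[b], n, byrow = TRUE)
  }
  x
}

test_that("adjacency and TOM reproduce hand computations", {
  # two perfectly correlated genes: a = 1 for any beta
  x <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8, 4, 3, 2, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  net <- build_network(x, beta = 6)
  expect_equal(net$adjacency["a", "b"], 1, tolerance = 1e-12)

  # brute-force TOM from the returned adjacency, elementwise loops
  net2 <- build_network(block_matrix(c(6), 0.5, n = 15, seed = 2), beta = 2)
  A <- net2$adjacency
  for (i in 1:3) for (j in 4:6) {
    l <- sum(A[i, -c(i, j)] * A[-c(i, j), j])
    w <- (l + A[i, j]) /
      (min(sum(A[i, -i]), sum(A[j, -j])) + 1 - A[i, j])
    expect_equal(net2$tom[i, j], w, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # hand value: three genes, all pairwise a = 0.5 -> w12 = (0.25+0.5)/(2-0.5)
  expect_equal((0.5 * 0.5 + 0.5) / (1 + 1 - 0.5), 0.5)

  # orthogonal genes: zero adjacency and zero off-diagonal TOM
  y <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1)) * 1.0
  dimnames(y) <- list(c("a", "b", "c"), paste0("s", 1:4))
  net3 <- build_network(y, beta = 2)
  expect_equal(max(abs(net3$adjacency)), 0, tolerance = 1e-12)
  expect_equal(max(abs(net3$tom - diag(3))), 0, tolerance = 1e-12)
})

test_that("TOM is symmetric with unit diagonal and entries in [0, 1]", {
  x <- block_matrix(c(20, 15), 0.6, seed = 3)
  net <- build_network(x, beta = 6)
  expect_equal(net$tom, t(net$tom))
  expect_equal(unname(diag(net$tom)), rep(1, nrow(x)))
  expect_true(all(net$tom >= 0 & net$tom <= 1 + 1e-12))
  expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
  expect_error(build_network(rbind(x, const = 1)), "zero-variance")
})

test_that("two planted blocks are recovered exactly at default settings", {
  for (seed in 1:5) {
    x <- block_matrix(c(50, 50), 0.8, seed = seed)
    net <- build_network(x, beta = 6)
    assignment <- detect_modules(net)
    truth <- rep(c("A", "B"), each = 50)
    expect_equal(length(setdiff(unique(assignment), "unassigned")), 2)
    expect_equal(adjusted_rand_index(assignment, truth), 1.0)
  }
})

test_that("module detection degenerates sensibly", {
  # all genes identical: one module containing everything
  x <- matrix(rep(rnorm(30), each = 25), 25, 30,
              dimnames = list(sprintf("g%02d", 1:25), sprintf("s%02d", 1:30)))
  x <- x + matrix(rnorm(25 * 30, 0, 1e-6), 25, 30)  # break exact constancy
  net <- build_network(x, beta = 6)
  a <- detect_modules(net, min_size = 20)
  expect_equal(unname(a), rep("M1", 25))
  # min size above the gene count: everything unassigned
  expect_true(all(detect_modules(net, min_size = 26) == "unassigned"))
})

test_that("module detection is invariant to gene order", {
  x <- block_matrix(c(40, 30), 0.7, seed = 6)
  net <- build_network(x, beta = 6)
  a1 <- detect_modules(net)
  set.seed(7)
  perm <- sample(nrow(x))
  a2 <- detect_modules(build_network(x[perm, ], beta = 6))
  expect_equal(adjusted_rand_index(a1[rownames(x)], a2[rownames(x)]), 1.0)
})

test_that("eigengenes follow the closed forms and the sign convention", {
  set.seed(8)
  n <- 50
  # singleton module: kME of its gene is 1
  x <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("a", "b"), sprintf("s%02d", seq_len(n))))
  ms <- eigengenes_kme(x, c(a = "M1", b = "unassigned"), top_k = 5)
  expect_equal(unname(ms$kme["a", "M1"]), 1, tolerance = 1e-12)
  expect_equal(sd(ms$eigengenes[, "M1"]), 1, tolerance = 1e-12)

  # two-gene module with correlation r: kME = sqrt((1 + r)/2)
  f <- rnorm(n)
  y <- rbind(g1 = f + rnorm(n, 0, 0.6), g2 = f + rnorm(n, 0, 0.6))
  colnames(y) <- sprintf("s%02d", seq_len(n))
  r <- cor(y[1, ], y[2, ])
  ms2 <- eigengenes_kme(y, c(g1 = "M1", g2 = "M1"), top_k = 2)
  expect_equal(unname(abs(ms2$kme[, "M1"])), rep(sqrt((1 + r) / 2), 2),
               tolerance = 1e-10)

  # r = 1 gives kME = 1
  z <- rbind(g1 = f, g2 = 2 * f + 1)
  colnames(z) <- sprintf("s%02d", seq_len(n))
  ms3 <- eigengenes_kme(z, c(g1 = "M1", g2 = "M1"), top_k = 2)
  expect_equal(unname(ms3$kme[, "M1"]), c(1, 1), tolerance = 1e-10)

  # negating the data flips the eigengene so mean kME stays >= 0
  ms4 <- eigengenes_kme(-y, c(g1 = "M1", g2 = "M1"), top_k = 2)
  expect_gte(mean(ms4$kme[, "M1"]), 0)
  expect_equal(abs(ms4$eigengenes[, 1]), abs(ms2$eigengenes[, 1]),
               tolerance = 1e-10)
})

test_that("the eigengene is the variance-maximising unit combination", {
  set.seed(9)
  x <- block_matrix(c(12), 0.5, n = 30, seed = 9)
  ms <- eigengenes_kme(x, setNames(rep("M1", 12), rownames(x)), top_k = 3)
  z <- t(scale(t(x)))
  pc <- prcomp(t(z))
  # explained variance of the eigengene equals PC1's
  expect_equal(abs(cor(ms$eigengenes[, 1], pc$x[, 1])), 1, tolerance = 1e-8)
})

test_that("module overlap reproduces the enumeration and calibration oracles", {
  # identical 5/5 partitions of 10 genes: diagonal pair p = 1/C(10,5)
  g <- sprintf("g%02d", 1:10)
  a <- setNames(rep(c("M1", "M2"), each = 5), g)
  out <- module_overlap(a, a, universe = 10)
  expect_equal(out$p[out$od_module == "M1" & out$ppp_module == "M1"],
               1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(out$k[out$od_module == "M1" & out$ppp_module == "M2"], 0)
  expect_equal(out$p[out$od_module == "M1" & out$ppp_module == "M2"], 1)

  # independent random partitions: p < 0.05 in about 5% of pairs
  set.seed(10)
  g <- sprintf("g%03d", 1:200)
  hits <- replicate(40, {
    a <- setNames(sample(paste0("M", 1:4), 200, replace = TRUE), g)
    b <- setNames(sample(paste0("M", 1:4), 200, replace = TRUE), g)
    mean(module_overlap(a, b, universe = 200)$p < 0.05)
  })
  expect_lt(abs(mean(hits) - 0.05), 0.03)
  expect_error(module_overlap(a, setNames(rep("M1", 3), c("x", "y", "z"))),
               "universe")
})

test_that("trait correlation matches the analytic t formula and flags degeneracies", {
  set.seed(11)
  x <- block_matrix(c(10), 0.6, n = 5, seed = 11)
  ms <- eigengenes_kme(x, setNames(rep("M1", 10), rownames(x)), top_k = 2)
  e <- ms$eigengenes[, 1]
  tr <- data.frame(t1 = e, t2 = -e, t3 = c(2, 1, 4, 3, 5),
                   t4 = rep(1, 5))
  rownames(tr) <- rownames(ms$eigengenes)
  out <- trait_correlation(ms, tr)
  expect_equal(out$r[out$trait == "t1"], 1)
  expect_equal(out$p[out$trait == "t1"], 0)
  expect_equal(out$flag[out$trait == "t1"], "perfect_correlation")
  expect_equal(out$r[out$trait == "t2"], -1)
  r <- cor(e, tr$t3)
  tstat <- r * sqrt(3 / (1 - r^2))
  expect_equal(out$r[out$trait == "t3"], r, tolerance = 1e-12)
  expect_equal(out$p[out$trait == "t3"], 2 * pt(-abs(tstat), df = 3),
               tolerance = 1e-12)
  expect_equal(out$flag[out$trait == "t4"], "constant_trait")
})

test_that("signature-module enrichment agrees with enumeration across k", {
  g <- sprintf("g%04d", 1:2000)
  assign <- setNames(rep("unassigned", 2000), g)
  assign[1:500] <- "M1"
  sig <- c(g[1:14], g[501:505])  # 14 of 19 inside the module set
  ot <- signature_module_enrichment(sig, assign, modules = "M1",
                                    universe = 2000)
  expect_equal(ot$k, 14)
  expect_equal(ot$p, hyper_tail_enum(14, 500, 19, 2000), tolerance = 1e-10)
  # disjoint signature: k = 0, p = 1
  ot0 <- signature_module_enrichment(g[1900:1910], assign, modules = "M1",
                                     universe = 2000)
  expect_equal(ot0$p, 1)
  # signature filling the whole selection: minimal attainable p
  assign2 <- setNames(rep("unassigned", 100), sprintf("h%03d", 1:100))
  assign2[1:5] <- "M1"
  sig2 <- names(assign2)[1:5]
  ot2 <- signature_module_enrichment(sig2, assign2, modules = "M1",
                                     universe = 100)
  expect_equal(ot2$p, hyper_tail_enum(5, 5, 5, 100), tolerance = 1e-12)
  expect_error(signature_module_enrichment(sig2, assign2, modules = character(0),
                                           universe = 100), "empty module")
})

test_that("planted-block module recovery holds across seeds at defaults", {
  ari <- sapply(1:5, function(seed) {
    x <- block_matrix(c(50, 50), 0.8, seed = 100 + seed)
    assignment <- detect_modules(build_network(x, beta = 6))
    adjusted_rand_index(assignment, rep(c("A", "B"), each = 50))
  })
  expect_true(all(ari >= 0.9))
})
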