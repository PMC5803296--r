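test_that("expression filter: degenerate equality retains nothing", {
  m <- matrix(5, 4, 8, dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  b <- toy_bundle(m, rep(c("ND", "T2D"), each = 4))
  expect_length(filter_expressed(b), 0)
})

test_that("expression filter matches an exhaustive brute-force check", {
  # hand-placed toy: tau is the pooled 75th percentile; gene passes iff it
  # strictly exceeds tau in >= 25% of some group's samples
  set.seed(31)
  m <- matrix(rnorm(4 * 8, 5, 2), 4, 8,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  groups <- rep(c("ND", "T2D"), each = 4)
  m[1, 1:3] <- 100   # gene exceeding tau in 3/4 of group ND -> retained
  m[2, ] <- -100     # never exceeds tau -> dropped
  b <- toy_bundle(m, groups)
  got <- filter_expressed(b, 0.75, 0.25)
  tau <- quantile(m, 0.75, names = FALSE)
  want <- rownames(m)[vapply(rownames(m), function(g) {
    any(vapply(unique(groups), function(gr)
      mean(m[g, groups == gr] > tau) >= 0.25, logical(1)))
  }, logical(1))]
  expect_setequal(got, want)
  expect_true("g1" %in% got)
  expect_false("g2" %in% got)

  # brute-force agreement on random matrices and random thresholds
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(30 * 12, 6, 1.5), 30, 12,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12)))
    groups <- sample(c("ND", "T2D", "IGT"), 12, replace = TRUE)
    q <- runif(1, 0.5, 0.9); f <- runif(1, 0.1, 0.9)
    b <- toy_bundle(m, groups)
    tau <- quantile(m, q, names = FALSE)
    want <- rownames(m)[vapply(rownames(m), function(g)
      any(vapply(unique(groups), function(gr)
        mean(m[g, groups == gr] > tau) >= f, logical(1))), logical(1))]
    expect_setequal(filter_expressed(b, q, f), want)
  }
})

test_that("expression filter keeps a uniformly maximal gene at sample_fraction 1", {
  set.seed(7)
  m <- matrix(rnorm(5 * 6, 5, 1), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  m[3, ] <- 50
  b <- toy_bundle(m, rep(c("ND", "T2D"), each = 3))
  expect_true("g3" %in% filter_expressed(b, 0.75, 1))
})

test_that("expression filter is monotone in sample_fraction", {
  set.seed(13)
  m <- matrix(rnorm(40 * 10, 6, 2), 40, 10,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:10)))
  b <- toy_bundle(m, rep(c("ND", "T2D"), each = 5))
  fracs <- c(0.1, 0.25, 0.5, 0.75, 1)
  sets <- lapply(fracs, function(f) filter_expressed(b, 0.75, f))
  for (i in seq_along(fracs)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("exclusion rules reproduce the published thresholds on constructed cases", {
  md <- data.frame(sample = c("a", "b", "c", "d"),
                   cohort = "OD",
                   group = c("ND", "ND", "T2D", "ND"),
                   fructosamine = c(290, 200, 400, 200),
                   glucose = c(5, 12, 20, 6),
                   insulin = c(1, 1, 1, 1))
  excl <- exclude_samples(md)
  # ND donor with fructosamine 290 umol/l is excluded for that reason
  expect_true(any(excl$sample == "a" & excl$reason == "fructosamine"))
  # ND donor with glucose 12 mmol/l is excluded
  expect_true(any(excl$sample == "b" & excl$reason == "glucose"))
  # diabetic donors are exempt from the no-history rules
  expect_false("c" %in% excl$sample)
  expect_false("d" %in% excl$sample)
})

test_that("insulin rule flags low secretors below mean - 1 SD, by hand", {
  md <- data.frame(sample = paste0("s", 1:6), cohort = "OD", group = "ND",
                   fructosamine = 200, glucose = 5,
                   insulin = c(1, 5, 5, 5, 5, 5))
  excl <- exclude_samples(md)
  ins <- excl[excl$reason == "insulin", ]
  expect_equal(ins$sample, "s1")          # mean - SD = 2.70; only the 1 falls below
  expect_equal(mean(md$insulin) - sd(md$insulin), 2.70, tolerance = 1e-3)
})

test_that("exclusion is idempotent, order-independent, and empty on empty input", {
  expect_equal(nrow(exclude_samples(data.frame(sample = character(0),
                                               group = character(0)))), 0)
  set.seed(5)
  md <- data.frame(sample = paste0("s", 1:20), cohort = "OD",
                   group = rep(c("ND", "T2D"), 10),
                   fructosamine = rnorm(20, 250, 40),
                   glucose = rnorm(20, 8, 3), insulin = rnorm(20, 1, 0.3))
  a <- exclude_samples(md)
  perm <- sample(nrow(md))
  b <- exclude_samples(md[perm, ])
  key <- function(x) sort(paste(x$sample, x$reason))
  expect_identical(key(a), key(b))
  # removing the flagged samples and re-running the history rules flags nothing new
  md2 <- md[!md$sample %in% a$sample, ]
  a2 <- exclude_samples(md2)
  expect_true(all(a2$reason == "insulin"))  # only the empirical rule can re-trigger
})

test_that("missing fields skip a rule with a warning instead of excluding", {
  md <- data.frame(sample = c("a", "b"), group = c("ND", "ND"),
                   glucose = c(5, 6), insulin = c(1, 1.2))
  expect_warning(excl <- exclude_samples(md), "fructosamine")
  expect_equal(nrow(excl), 0)
})

test_that("contamination scores reduce to the marker mean and detect a planted shift", {
  set.seed(17)
  n <- 20
  m <- matrix(rnorm(10 * 2 * n, 6, 0.5), 10, 2 * n,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:(2 * n))))
  cohort <- rep(c("OD", "PPP"), each = n)
  m[1:3, cohort == "PPP"] <- m[1:3, cohort == "PPP"] + 2
  md <- data.frame(sample = colnames(m), cohort = cohort, group = "ND")
  b <- expression_bundle(m, md)

  res1 <- contamination_check(b, list(single = "g5"))
  expect_equal(unname(res1$scores[, "single"]), unname(m["g5", ]))

  res <- contamination_check(b, list(exo = c("g1", "g2", "g3")))
  se <- 0.5 / sqrt(3) * sqrt(2 / n)
  expect_lt(abs(abs(res$comparison$difference[1]) - 2), 3 * se)
  expect_error(contamination_check(b, list(bad = "nope")), "disjoint")
})

test_that("identical cohorts give a near-zero contamination difference", {
  set.seed(19)
  m0 <- matrix(rnorm(10 * 12, 6, 0.5), 10, 12)
  m <- cbind(m0, m0)
  dimnames(m) <- list(paste0("g", 1:10), paste0("s", 1:24))
  md <- data.frame(sample = colnames(m), cohort = rep(c("OD", "PPP"), each = 12),
                   group = "ND")
  res <- contamination_check(expression_bundle(m, md), list(mk = c("g1", "g2")))
  expect_equal(res$comparison$difference[1], 0, tolerance = 1e-12)
})

test_that("PCA matches a direct eigendecomposition and conserves variance", {
  m <- matrix(c(1, 2, 3, 2, 4, 1, 0, 1, 5), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  emb <- pca_embed(m)
  ev <- eigen(cov(t(m)))
  expect_equal(sort(emb$sdev^2, decreasing = TRUE),
               sort(ev$values, decreasing = TRUE)[seq_along(emb$sdev)],
               tolerance = 1e-10)
  expect_equal(sum(emb$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(emb$variance_fraction) <= 1e-12))
  # coordinates match the projection on the leading eigenvector up to sign
  ctr <- scale(t(m), scale = FALSE)
  expect_equal(abs(emb$coordinates[, 1]), abs(drop(ctr %*% ev$vectors[, 1])),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(pca_embed(m[, 1, drop = FALSE]), "2 samples")
})

test_that("PCA: duplicated samples coincide and variance fractions ignore sample order", {
  set.seed(29)
  m <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  m[, 2] <- m[, 1]
  emb <- pca_embed(m)
  expect_equal(emb$coordinates[1, ], emb$coordinates[2, ], tolerance = 1e-10)
  perm <- c(3, 1, 6, 2, 4, 5)
  emb2 <- pca_embed(m[, perm])
  expect_equal(emb$variance_fraction, emb2$variance_fraction, tolerance = 1e-10)
})
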