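test_that("voxelwise t matches hand-computed statistics", {
  d <- c(4, 3, 2)
  # one-sample: maps constant c with injected variance at one voxel pattern
  set.seed(7)
  base <- array(0.3, d)
  maps <- lapply(1:5, function(i) base + array(rnorm(prod(d), sd = 0.05), d))
  sm <- voxelwise_t(maps, list(type = "one_sample"), "greater")
  X <- sapply(maps, as.vector)
  t_hand <- apply(X, 1, function(x) mean(x) / (sd(x) / sqrt(5)))
  expect_equal(as.vector(sm$t), t_hand, tolerance = 1e-12)
  expect_equal(sm$df, 4)
  # two-sample pooled t at a single differing voxel
  g1 <- lapply(1:3, function(i) array(rnorm(prod(d), sd = 0.1), d))
  g2 <- lapply(1:4, function(i) array(rnorm(prod(d), sd = 0.1), d))
  sm2 <- voxelwise_t(c(g1, g2),
                     list(type = "two_sample",
                          groups = c(rep("EtOH", 3), rep("Con", 4))), "greater")
  X2 <- sapply(c(g1, g2), as.vector)
  t_hand2 <- apply(X2, 1, function(x) {
    a <- x[1:3]; b <- x[4:7]
    sp <- sqrt((2 * var(a) + 3 * var(b)) / 5)
    (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 4))
  })
  expect_equal(as.vector(sm2$t), t_hand2, tolerance = 1e-12)
  # identical groups give t = 0; zero-variance difference flags infinite t
  same <- lapply(1:4, function(i) base)
  sm3 <- voxelwise_t(c(same, same),
                     list(type = "two_sample",
                          groups = rep(c("EtOH", "Con"), each = 4)), "greater")
  expect_true(all(sm3$t == 0))
  shifted <- lapply(1:4, function(i) base + 1)
  sm4 <- voxelwise_t(c(shifted, same),
                     list(type = "two_sample",
                          groups = rep(c("EtOH", "Con"), each = 4)), "greater")
  expect_true(all(sm4$t == Inf))
  expect_error(voxelwise_t(maps[1:1], list(type = "one_sample")), "at least 2")
})

test_that("exhaustive permutation p equals brute-force enumeration", {
  d <- c(5, 4, 3)
  set.seed(2)
  maps <- lapply(1:6, function(i) array(rnorm(prod(d)), d))
  groups <- c(rep("EtOH", 3), rep("Con", 3))
  for (tail in c("greater", "less")) {
    pm <- permutation_p(maps, list(type = "two_sample", groups = groups),
                        tail, n_perm = 5000, seed = 9)
    X <- sapply(maps, as.vector)
    tstat <- function(i1) {
      i2 <- setdiff(1:6, i1)
      m1 <- rowMeans(X[, i1]); m2 <- rowMeans(X[, i2])
      sp <- (apply(X[, i1], 1, var) * 2 + apply(X[, i2], 1, var) * 2) / 4
      (m1 - m2) / sqrt(sp * (2 / 3))
    }
    obs <- tstat(1:3)
    perms <- combn(6, 3, simplify = FALSE)
    hits <- rowSums(sapply(perms, function(s) {
      tp <- tstat(s)
      if (tail == "greater") tp >= obs - 1e-12 else tp <= obs + 1e-12
    }))
    expect_equal(as.vector(pm$p), hits / 20, tolerance = 1e-12)
  }
})

test_that("one-sample sign-flip permutation hits the combinatorial floor", {
  d <- c(3, 3, 2)
  maps <- lapply(1:4, function(i) array(abs(rnorm(prod(d))) + 0.5, d))
  pm <- permutation_p(maps, list(type = "one_sample"), "greater",
                      n_perm = 100, seed = 2)
  # every voxel strictly positive in all maps: p = 1/16 everywhere
  expect_true(all(pm$p == 1 / 16))
  expect_error(permutation_p(maps, list(type = "one_sample"), "greater",
                             n_perm = 10), "meaningless")
  expect_warning(permutation_p(maps, list(type = "one_sample"), "greater",
                               n_perm = 50, seed = 2), "coarse")
})

test_that("permutation p-values are uniform under an exchangeable null", {
  d <- c(22, 22, 20)  # ~10k voxels
  set.seed(31)
  maps <- lapply(1:8, function(i) array(rnorm(prod(d)), d))
  pm <- permutation_p(maps,
                      list(type = "two_sample",
                           groups = rep(c("EtOH", "Con"), each = 4)),
                      "greater", n_perm = 5000, seed = 5)
  ks <- suppressWarnings(ks.test(as.vector(pm$p), "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("FWHM estimation recovers known smoothness and is scale invariant", {
  d <- c(48L, 48L, 48L)
  mask <- array(TRUE, d)
  set.seed(12)
  sm <- lapply(1:4, function(i)
    jacmorph:::cpp_gauss_smooth(array(rnorm(prod(d)), d), rep(3 / 2.3548, 3)))
  fw <- estimate_fwhm(sm, mask, c(1, 1, 1))
  expect_true(all(abs(fw$fwhm_vox - 3) < 0.45))
  raw <- lapply(1:4, function(i) array(rnorm(prod(d)), d))
  fw0 <- estimate_fwhm(raw, mask, c(1, 1, 1))
  expect_true(all(fw0$fwhm_vox <= 1.2))
  # scaling residuals does not change the estimate
  fw2 <- estimate_fwhm(lapply(sm, function(x) 10 * x), mask, c(1, 1, 1))
  expect_equal(fw2$fwhm_vox, fw$fwhm_vox, tolerance = 1e-12)
  expect_error(estimate_fwhm(sm, array(FALSE, d), c(1, 1, 1)), "mask")
  expect_error(estimate_fwhm(sm[1], mask, c(1, 1, 1)), ">= 2")
})

test_that("Monte-Carlo cluster threshold behaves across regimes", {
  geom <- list(dim = c(48L, 48L, 48L), spacing = c(1, 1, 1))
  mask <- array(TRUE, geom$dim)
  # alpha = 1: no correction
  thr1 <- mc_cluster_threshold(geom, mask, c(2, 2, 2), 0.01, alpha = 1,
                               n_sim = 200, seed = 3)
  expect_equal(thr1$min_cluster_size, 1L)
  # near-independent voxels: small threshold
  thr0 <- suppressWarnings(mc_cluster_threshold(geom, mask, c(0.1, 0.1, 0.1),
                                                0.01, 0.05, n_sim = 300, seed = 4))
  expect_lte(thr0$min_cluster_size, 5L)
  # monotone in smoothness
  thr2 <- mc_cluster_threshold(geom, mask, c(1, 1, 1), 0.01, 0.05,
                               n_sim = 300, seed = 5)
  thr4 <- mc_cluster_threshold(geom, mask, c(4, 4, 4), 0.01, 0.05,
                               n_sim = 300, seed = 5)
  expect_gte(thr4$min_cluster_size, thr2$min_cluster_size)
  expect_error(mc_cluster_threshold(geom, mask, c(2, 2, 2), 0.01, 0.05,
                                    n_sim = 50), "n_sim")
})

test_that("cluster extraction thresholds sizes and respects connectivity", {
  d <- c(20L, 20L, 10L)
  mk_pmap <- function(p) structure(list(t = array(1, d), p = p, tail = "greater",
                                        design = list(type = "one_sample"),
                                        df = 4, mask = array(TRUE, d)),
                                   class = "stat_map")
  # all p = 1 -> empty set is valid
  cs0 <- extract_clusters(mk_pmap(array(1, d)), 0.01, 10, 6)
  expect_length(cs0$clusters, 0)
  # one large and one small blob with a size threshold in between
  p <- array(1, d)
  p[2:11, 2:11, 2:8] <- 0.001    # 700 voxels
  p[14:18, 14:18, 2:8] <- 0.001  # 175 voxels
  cs <- extract_clusters(mk_pmap(p), 0.01, 607, 6)
  expect_length(cs$clusters, 1)
  expect_equal(cs$sizes, 700L)
  expect_equal(cs$direction, "expand")
  # two diagonally touching blobs: 2 components at 6-connectivity, 1 at 26
  p2 <- array(1, d)
  p2[3:5, 3:5, 3:5] <- 0.001
  p2[6:8, 6:8, 6:8] <- 0.001
  cs6 <- extract_clusters(mk_pmap(p2), 0.01, 1, 6)
  cs26 <- extract_clusters(mk_pmap(p2), 0.01, 1, 26)
  expect_length(cs6$clusters, 2)
  expect_length(cs26$clusters, 1)
  # a voxel cannot be both expansion and shrinkage within a comparison
  pm_l <- mk_pmap(p2); pm_l$tail <- "less"
  cs_l <- extract_clusters(pm_l, 0.01, 1, 6)
  expect_equal(cs_l$direction, "shrink")
  expect_equal(intersect(unlist(cs6$clusters), integer(0)), integer(0))
})
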