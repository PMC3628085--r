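# UniFrac, Faith's PD, filtering, rarefaction, and PCoA.

test_that("depth filter keeps exactly the samples at or above threshold", {
  depths <- c(1, 4999, 5000, 6000, 300473)
  tb <- makeOtu(depths, paste0("S", 1:5), "OTU_1")
  expect_equal(ncol(otuCounts(filterByDepth(tb, 5000))), 3)
  expect_equal(ncol(otuCounts(filterByDepth(tb, 1))), 5)
  expect_equal(ncol(otuCounts(filterByDepth(tb, 1e7))), 0)
})

test_that("rarefaction subsamples exactly and deterministically", {
  tb <- makeOtu(c(3000, 2000, 500, 4500), c("S1", "S2"))
  rar <- rarefyCounts(tb, 5000, seed = 1)
  expect_equal(unname(colSums(otuCounts(rar))), c(5000, 5000))
  expect_identical(otuCounts(rar)[, "S1"], otuCounts(tb)[, "S1"]) # exact depth
  expect_identical(otuCounts(rarefyCounts(tb, 5000, seed = 1)),
                   otuCounts(rar))
  # forced outcome: only one OTU has reads
  big <- makeOtu(c(1e6, 0), "S1", c("A", "B"))
  expect_equal(unname(otuCounts(rarefyCounts(big, 5000, seed = 2))[, 1]),
               c(5000, 0))
  # shallow sample is an error naming the sample
  expect_error(rarefyCounts(makeOtu(10, "shallow"), 100, seed = 1),
               "shallow")
})

test_that("rarefaction draws are hypergeometric (moment check)", {
  tb <- makeOtu(c(500, 500), "S1", c("A", "B"))
  draws <- vapply(1:4000, function(r)
    otuCounts(rarefyCounts(tb, 100, seed = r))["A", 1], numeric(1))
  expect_equal(mean(draws), 50, tolerance = 0.01)   # +/- ~0.5 absolute
  # sd = sqrt(100 * .25 * 900/999) ~ 4.74
  expect_equal(sd(draws), 4.74, tolerance = 0.05)
})

test_that("UniFrac reproduces hand-computed quartet cases", {
  tr <- quartetTree()
  tb <- makeOtu(c(1, 1, 0, 0,   0, 0, 1, 1,   1, 0, 1, 0,   1, 0, 0, 1),
                c("ab", "cd", "ac", "ad"), c("A", "B", "C", "D"))
  expect_equal(unweightedUnifrac(tb, tr, "ab", "cd"), 1)
  expect_equal(unweightedUnifrac(tb, tr, "ac", "ad"), 0.4)
  expect_equal(unweightedUnifrac(tb, tr, "ab", "ab"), 0)
  # weighted two-tip instance
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  tb2 <- makeOtu(c(10, 0, 0, 5), c("i", "j"), c("A", "B"))
  expect_equal(weightedUnifrac(tb2, tr2, "i", "j"), 2)
  expect_equal(weightedUnifrac(tb2, tr2, "i", "j", normalized = TRUE), 1)
  expect_equal(weightedUnifrac(tb2, tr2, "i", "i"), 0)
})

test_that("both UniFrac variants match the brute-force oracle", {
  withr::with_seed(101, {
    for (case in 1:250) {
      inst <- randomUnifracCase()
      tb <- otuTable(inst$counts)
      expect_equal(unweightedUnifrac(tb, inst$tree, "s1", "s2"),
                   bruteUnifrac(inst$counts, inst$tree, "s1", "s2",
                                "unweighted"),
                   tolerance = 1e-12)
      expect_equal(weightedUnifrac(tb, inst$tree, "s1", "s2"),
                   bruteUnifrac(inst$counts, inst$tree, "s1", "s2",
                                "weighted"),
                   tolerance = 1e-12)
      expect_equal(weightedUnifrac(tb, inst$tree, "s1", "s2",
                                   normalized = TRUE),
                   bruteUnifrac(inst$counts, inst$tree, "s1", "s2",
                                "weighted", normalized = TRUE),
                   tolerance = 1e-12)
    }
  })
})

test_that("UniFrac matrices are symmetric, zero-diagonal and bounded", {
  cfg <- nullSimulationConfig(n_families = 4, n_taxa = 40, seed = 8)
  ds <- simulateDataset(cfg)
  for (metric in c("unweighted", "weighted")) {
    D <- as.matrix(unifracDistance(ds$table, ds$tree, metric = metric))
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0))
    if (metric == "unweighted") expect_true(all(D <= 1 + 1e-12))
  }
})

test_that("Faith's PD spans observed tips through the root", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  tb <- makeOtu(c(1, 1, 0, 0), "s", c("A", "B", "C", "D"))
  expect_equal(unname(faithPD(tb, star)), 2)
  all4 <- makeOtu(c(1, 1, 1, 1), "s", c("A", "B", "C", "D"))
  expect_equal(unname(faithPD(all4, star)), 4)
  # root inclusion: single tip A on ((A:1,B:2):3,C:4)
  tr <- ape::read.tree(text = "((A:1,B:2):3,C:4);")
  one <- makeOtu(c(1, 0, 0), "s", c("A", "B", "C"))
  expect_equal(unname(faithPD(one, tr)), 4)
  # empty sample: 0 with a warning
  none <- makeOtu(c(0, 0, 0), "s", c("A", "B", "C"))
  expect_warning(pd0 <- faithPD(none, tr), "empty")
  expect_equal(unname(pd0), 0)
})

test_that("Faith's PD is monotone under taxon addition", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      tr <- ape::rtree(10)
      pres <- rbinom(10, 1, 0.4)
      if (sum(pres) == 0) pres[1] <- 1
      more <- pres
      off <- which(more == 0)
      if (length(off)) more[sample(off, 1)] <- 1
      tb <- makeOtu(c(pres, more), c("less", "more"), tr$tip.label)
      pd <- faithPD(tb, tr)
      expect_gte(pd["more"], pd["less"])
    }
  })
})

test_that("PD matches picante on a random instance", {
  withr::with_seed(77, {
    tr <- ape::rtree(15)
    cnt <- matrix(rpois(15 * 4, 1), 15, 4,
                  dimnames = list(tr$tip.label, paste0("s", 1:4)))
    cnt[, 1] <- pmax(cnt[, 1], 1)
    pd_pkg <- faithPD(otuTable(cnt), tr)
    pd_ref <- picante::pd(t(cnt), tr, include.root = TRUE)$PD
    ok <- colSums(cnt) > 0
    expect_equal(unname(pd_pkg[ok]), pd_ref[ok], tolerance = 1e-10)
  })
})

test_that("rarefaction curves are reproducible and anchored at full depth", {
  cfg <- nullSimulationConfig(n_families = 2, n_taxa = 30,
                              depth_meanlog = log(300), seed = 12)
  ds <- simulateDataset(cfg)
  tb <- ds$table[, 1:2]
  tots <- colSums(otuCounts(tb))
  anchor <- names(which.min(tots))   # sample whose total is a curve depth
  cur <- rarefactionCurve(tb, ds$tree, depths = c(50, 150, min(tots)),
                          n_iter = 5, seed = 9)
  full <- cur[cur$depth == min(tots) & cur$sample == anchor, ]
  expect_equal(full$sd_pd, 0)
  expect_equal(full$mean_pd, unname(faithPD(tb, ds$tree, anchor)))
  # mean PD non-decreasing with depth per sample
  for (s in unique(cur$sample)) {
    m <- cur$mean_pd[cur$sample == s]
    expect_true(all(diff(m) >= -1e-9))
  }
  # first iterate independent of n_iter
  cur1 <- rarefactionCurve(tb, ds$tree, depths = 50, n_iter = 1, seed = 9)
  expect_equal(cur1$mean_pd[1],
               rarefactionCurve(tb[, 1], ds$tree, depths = 50,
                                n_iter = 1, seed = 9)$mean_pd[1])
})

test_that("PCoA reproduces forced geometries", {
  two <- matrix(c(0, .8, .8, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  res <- pcoa(distanceMatrix(two))
  expect_equal(ncol(res$points), 1)
  expect_equal(sort(unname(res$points[, 1])), c(-.4, .4))

  three <- matrix(1, 3, 3); diag(three) <- 0
  dimnames(three) <- list(letters[1:3], letters[1:3])
  res3 <- pcoa(distanceMatrix(three))
  pos <- res3$eigenvalues[res3$eigenvalues > 1e-9]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  zeros <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(abs(pcoa(distanceMatrix(zeros))$eigenvalues) < 1e-12))
})

test_that("PCoA embeds Euclidean matrices exactly and matches cmdscale", {
  withr::with_seed(33, {
    X <- matrix(rnorm(7 * 3), 7, 3)
    D <- as.matrix(dist(X))
    dimnames(D) <- list(paste0("s", 1:7), paste0("s", 1:7))
    res <- pcoa(distanceMatrix(D))
    Dhat <- as.matrix(dist(res$points))
    expect_equal(unname(Dhat), unname(D), tolerance = 1e-8)
    ref <- cmdscale(D, k = 3, eig = TRUE)
    expect_equal(sort(res$eigenvalues, decreasing = TRUE)[1:3],
                 sort(ref$eig, decreasing = TRUE)[1:3], tolerance = 1e-8)
  })
  expect_warning(pcoa(distanceMatrix(matrix(c(0, 1, 1, 0), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b")))),
                      n_axes = 5), "truncating")
})
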