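# Dyad construction, the rank statistic, the permutation test, PERMANOVA,
# the age-trajectory regression and the power computation.

test_that("anosimR reproduces hand-ranked cases and is antisymmetric", {
  expect_equal(anosimR(c(0.1, 0.2), c(0.3, 0.4)), 1)
  expect_equal(anosimR(c(0.1, 0.3), c(0.2, 0.4)), 0.5)
  expect_equal(anosimR(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_error(anosimR(numeric(0), 1), "non-empty")
  withr::with_seed(19, {
    for (rep in 1:30) {
      w <- runif(sample(2:10, 1)); b <- runif(sample(2:10, 1))
      r <- anosimR(w, b)
      expect_true(abs(r) <= 1)
      expect_equal(anosimR(b, w), -r)
    }
  })
})

test_that("dyad construction follows the within/between pairing rules", {
  md <- coupleMetadata(2)
  dy <- buildDyads(md, "spouses", "forehead")
  expect_equal(sum(dy$pairs$within), 2)
  expect_equal(sum(!dy$pairs$within), 4)  # 2 cross M-F + 2 cross same-sex

  # families: household of 3 + household of 2 -> C(3,2) + C(2,2) = 4 within
  d <- metadataTable(coupleMetadata(2))
  extra <- d[1, ]
  extra$host_id <- "F01_C1"; extra$sample_id <- "F01_C1.forehead"
  extra$role <- "child"; extra$age <- 5
  md3 <- sampleMetadata(rbind(d, extra))
  fam <- buildDyads(md3, "families", "forehead")
  expect_equal(sum(fam$pairs$within), 4)
  expect_equal(nrow(fam$pairs), choose(5, 2))

  expect_error(buildDyads(md, "father_infant", "forehead"), "no within")
  expect_error(buildDyads(sampleMetadata(d[d$family_id == "F01", ]),
                          "spouses", "forehead"), ">= 2 eligible")
})

test_that("a perfectly separated dataset yields R = 1 with the smallest p", {
  md <- coupleMetadata(4)
  ids <- sampleIDs(md)
  n <- length(ids)
  D <- matrix(1, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  d <- metadataTable(md)
  for (f in unique(d$family_id)) {
    s <- d$sample_id[d$family_id == f]
    D[s[1], s[2]] <- D[s[2], s[1]] <- 0.1
  }
  res <- dyadPermutationTest(distanceMatrix(D), md, "spouses", "forehead",
                             n_perm = 500, seed = 4)
  expect_equal(res@R, 1)
  expect_lte(res@p_value, 0.06)
  expect_gte(res@p_value, 1 / 501)
  expect_equal(res@n_within, 4L)
  expect_lt(res@mean_within, res@mean_between)
  # 4!^2 = 576 distinct permutations > 100: no warning recorded
  expect_false(any(grepl("distinct", res@warnings)))
  res3 <- dyadPermutationTest(distanceMatrix(D[1:6, 1:6]),
                              sampleMetadata(d[d$family_id %in%
                                               c("F01", "F02", "F03"), ]),
                              "spouses", "forehead", n_perm = 200, seed = 4)
  expect_true(any(grepl("distinct", res3@warnings)))  # 3!^2 = 36 < 100
})

test_that("the permutation test is deterministic given a seed", {
  cfg <- simulationConfig(n_families_by_type = c(children = 0, dogs = 0,
                                                 both = 0, neither = 5),
                          n_taxa = 40, depth_meanlog = log(400), seed = 6)
  ds <- simulateDataset(cfg)
  md <- metadataTable(ds$metadata)
  ids <- md$sample_id[md$body_site == "oral"]
  dm <- unifracDistance(ds$table[, ids], ds$tree)
  r1 <- dyadPermutationTest(dm, ds$metadata, "spouses", "oral",
                            n_perm = 200, seed = 42)
  r2 <- dyadPermutationTest(dm, ds$metadata, "spouses", "oral",
                            n_perm = 200, seed = 42)
  expect_identical(r1@p_value, r2@p_value)
  expect_identical(r1@R, r2@R)
})

test_that("owner-dog dyads pair adult skin with cohabiting vs other dogs", {
  cfg <- simulationConfig(n_families_by_type = c(children = 0, dogs = 4,
                                                 both = 0, neither = 2),
                          n_taxa = 40, depth_meanlog = log(400), seed = 13)
  ds <- simulateDataset(cfg)
  dy <- buildDyads(ds$metadata, "owner_own_dog",
                   c("forehead", "paw_BL"))
  md <- metadataTable(ds$metadata)
  expect_true(all(dy$pairs$within == (dy$pairs$fam1 == dy$pairs$fam2)))
  expect_true(all(md$species[match(dy$pairs$host2, md$host_id)] == "dog"))
  expect_true(all(md$has_dog[match(dy$pairs$host1, md$host_id)]))
  expect_error(dyadPermutationTest(
    unifracDistance(ds$table, ds$tree), ds$metadata, "nonowner_dog",
    c("forehead", "paw_BL")), "groupSharingComparison")
})

test_that("PERMANOVA matches the worked example and a naive oracle", {
  m <- matrix(1, 4, 4); diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 0.1; m[3, 4] <- m[4, 3] <- 0.1
  dimnames(m) <- list(letters[1:4], letters[1:4])
  res <- permanovaOneway(distanceMatrix(m), c("g", "g", "h", "h"),
                         n_perm = 99, seed = 1)
  expect_equal(res@pseudo_F, 199)
  expect_equal(res@df_between, 1L)
  expect_equal(res@df_residual, 2L)

  withr::with_seed(59, {
    for (rep in 1:15) {
      n <- sample(6:12, 1)
      X <- matrix(rnorm(n * 3), n, 3)
      D <- as.matrix(dist(X))
      dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
      g <- sample(rep(c("a", "b", "c"), length.out = n))
      res <- permanovaOneway(distanceMatrix(D), g, n_perm = 9, seed = 1)
      expect_equal(res@pseudo_F, naivePseudoF(D, g), tolerance = 1e-9)
    }
  })
})

test_that("PERMANOVA pseudo-F agrees with vegan::adonis2", {
  withr::with_seed(91, {
    n <- 12
    X <- matrix(rnorm(n * 4), n, 4)
    D <- as.matrix(dist(X))
    dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
    g <- rep(c("a", "b", "c"), each = 4)
    ours <- permanovaOneway(distanceMatrix(D), g, n_perm = 9, seed = 1)
    ref <- vegan::adonis2(as.dist(D) ~ g,
                          data = data.frame(g = g), permutations = 9)
    expect_equal(ours@pseudo_F, ref$F[1], tolerance = 1e-8)
  })
})

test_that("equidistant samples give pseudo-F exactly 1 (no group signal)", {
  # with all pairwise distances equal, MS_between = MS_within = d^2/2
  m <- matrix(1, 4, 4); diag(m) <- 0
  dimnames(m) <- list(letters[1:4], letters[1:4])
  res <- permanovaOneway(distanceMatrix(m), c("g", "g", "h", "h"),
                         n_perm = 19, seed = 1)
  expect_equal(res@pseudo_F, 1)
  expect_equal(res@pseudo_F, naivePseudoF(m, c("g", "g", "h", "h")))
})

test_that("age trajectory handles flat distances and recovers the age gradient", {
  md <- coupleMetadata(4, sites = "fecal")
  ids <- sampleIDs(md)
  D <- matrix(0.5, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(D) <- 0
  flat <- ageTrajectory(distanceMatrix(D), md, "fecal")
  expect_true(flat$degenerate)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  # age effect isolated (no household sharing): infants sit far from the
  # adult baseline and mean distance declines with age over childhood.
  # The decay is exponential in age, so a straight-line fit explains only
  # part of the variance; the r-squared floor reflects what the
  # generator's default effect sizes actually produce.
  cfg <- simulationConfig(n_families_by_type = c(children = 10, dogs = 0,
                                                 both = 0, neither = 4),
                          n_taxa = 80, depth_meanlog = log(1500),
                          kappa_family = Inf, w_sp = 0, w_pc = 0,
                          seed = 19)
  ds <- simulateDataset(cfg)
  mdt <- metadataTable(ds$metadata)
  ids <- mdt$sample_id[mdt$body_site == "oral"]
  dm <- unifracDistance(ds$table[, ids], ds$tree, metric = "weighted")
  traj <- ageTrajectory(dm, ds$metadata, "oral", max_age = 18)
  expect_lt(traj$slope, 0)            # infants far from the adult baseline
  expect_gt(traj$r_squared, 0.3)
  # infants average farther from the baseline than older children
  pts <- traj$points
  expect_gt(mean(pts$mean_dist[pts$age < 1]),
            mean(pts$mean_dist[pts$age >= 3]))
})

test_that("minimum detectable effect follows the closed form", {
  expect_equal(round(minDetectableEffect(2757, 3071, 0.05, 0.90), 3), 0.085)
  expect_equal(minDetectableEffect(100, 100, 0.05, 0.80), 0.396,
               tolerance = 1e-3)
  expect_equal(minDetectableEffect(20, 50), minDetectableEffect(50, 20))
  expect_error(minDetectableEffect(1, 50))
})
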