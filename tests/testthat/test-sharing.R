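# Shared-phylotype accounting, taxon-family collapse, and the age-group
# ANOVA on family-level abundances.

test_that("shared phylotype counts are presence-set intersections", {
  tb <- makeOtu(c(1, 1, 1, 0,  0, 1, 1, 1), c("i", "j"), paste0("O", 1:4))
  expect_equal(sharedPhylotypes(tb, "i", "j"), 2)
  dis <- makeOtu(c(1, 1, 0, 0,  0, 0, 1, 1), c("i", "j"), paste0("O", 1:4))
  expect_equal(sharedPhylotypes(dis, "i", "j"), 0)
  expect_equal(sharedPhylotypes(tb, "i", "i"), 3)  # richness of the sample
  expect_error(sharedPhylotypes(tb, "i", "nope"), "unknown sample")
  uneq <- makeOtu(c(5, 0, 1, 1), c("i", "j"), c("O1", "O2"))
  expect_warning(sharedPhylotypes(uneq, "i", "j"), "unequal depths")
})

test_that("per-family shared counts conserve the total per pair", {
  cfg <- simulationConfig(n_families_by_type = c(children = 0, dogs = 0,
                                                 both = 0, neither = 5),
                          n_taxa = 60, depth_meanlog = log(500),
                          depth_sdlog = 0, seed = 23)
  ds <- simulateDataset(cfg)
  dy <- buildDyads(ds$metadata, "spouses", "forehead")
  sh <- sharedByTaxonFamily(ds$table, dy)
  p <- dy$pairs
  totals <- vapply(seq_len(nrow(p)), function(k)
    sharedPhylotypes(ds$table, p$s1[k], p$s2[k]), numeric(1))
  expect_equal(unname(colSums(sh$per_pair)), totals)
  expect_true(all(c("mean_within", "p_bonferroni") %in%
                  names(sh$by_family)))
  expect_true(all(sh$by_family$p_bonferroni >=
                  sh$by_family$p_value - 1e-15))
})

test_that("a planted family-specific sharing excess is detected", {
  # within pairs share extra OTUs all belonging to one taxonomy family
  withr::with_seed(41, {
    n_pairs <- 30
    n_otu <- 40
    tax <- sprintf("k__Bacteria; p__X; c__; o__; f__%s; g__; s__",
                   rep(c("Streptococcaceae", "Moraxellaceae"),
                       each = n_otu / 2))
    samples <- paste0("s", seq_len(4 * n_pairs))
    cnt <- matrix(rbinom(n_otu * 4 * n_pairs, 1, 0.3), n_otu,
                  dimnames = list(paste0("O", 1:n_otu), samples))
    pairs <- data.frame(
      s1 = samples[seq(1, 4 * n_pairs, by = 2)],
      s2 = samples[seq(2, 4 * n_pairs, by = 2)],
      within = rep(c(TRUE, FALSE), n_pairs))
    strep <- which(seq_len(n_otu) <= n_otu / 2)
    for (k in which(pairs$within)) {
      boost <- sample(strep, 8)
      cnt[boost, pairs$s1[k]] <- 1
      cnt[boost, pairs$s2[k]] <- 1
    }
    sh <- sharedByTaxonFamily(otuTable(cnt, tax), pairs)
    row <- sh$by_family[sh$by_family$family == "Streptococcaceae", ]
    expect_true(row$significant)
    expect_gt(row$mean_within, row$mean_between)
  })
})

test_that("identical within/between sharing yields no flagged family", {
  withr::with_seed(47, {
    flags <- vapply(1:10, function(rep) {
      n_otu <- 30
      tax <- sprintf("f__%s", rep(c("A", "B", "C"), each = 10))
      samples <- paste0("s", 1:40)
      cnt <- matrix(rbinom(n_otu * 40, 1, 0.4), n_otu,
                    dimnames = list(paste0("O", 1:n_otu), samples))
      pairs <- data.frame(s1 = samples[seq(1, 39, 2)],
                          s2 = samples[seq(2, 40, 2)],
                          within = rep(c(TRUE, FALSE), 10))
      any(sharedByTaxonFamily(otuTable(cnt, tax), pairs)$by_family$significant)
    }, logical(1))
    expect_lte(mean(flags), 0.2)   # type-I control after Bonferroni
  })
})

test_that("sharing strata compare cohabitation against dog ownership", {
  cfg <- simulationConfig(n_families_by_type = c(children = 0, dogs = 6,
                                                 both = 0, neither = 6),
                          n_taxa = 80, depth_meanlog = log(800),
                          depth_sdlog = 0, seed = 29)
  ds <- simulateDataset(cfg)
  res <- groupSharingComparison(ds$table, ds$metadata, "forehead")
  expect_setequal(res$strata$stratum,
                  c("cohabiting_dog", "cohabiting_nodog",
                    "separate_dog", "separate_nodog"))
  expect_true(all(res$strata$n_pairs >= 2))
  expect_equal(nrow(res$contrasts), choose(4, 2))
  # dog-owning separate pairs share more than non-dog separate pairs
  # (dog-contact effect adds shared rare taxa on owners' skin)
  s <- res$strata
  expect_gt(s$mean[s$stratum == "separate_dog"],
            s$mean[s$stratum == "separate_nodog"])
})

test_that("family collapse yields percentages that sum to 100", {
  tax <- c("f__Streptococcaceae", "f__Streptococcaceae", "f__Moraxellaceae")
  tb <- makeOtu(c(30, 20, 50), "S1", paste0("O", 1:3), tax)
  pct <- collapseToFamily(tb)
  expect_equal(pct["Streptococcaceae", "S1"], 50)
  expect_equal(unname(colSums(pct)), 100)
  # unannotated OTUs pool into "unclassified"
  tb2 <- makeOtu(c(10, 90), "S1", c("O1", "O2"),
                 c("f__Prevotellaceae", "k__Bacteria"))
  expect_equal(collapseToFamily(tb2)["unclassified", "S1"], 90)
})

test_that("age-group ANOVA matches the F-distribution oracle and filters", {
  # toy: group means 1.5 vs 3.5, F = 8 on df (1, 2), p = P(F_{1,2} > 8)
  ft <- matrix(c(1, 2, 3, 4), 1, 4,
               dimnames = list("Streptococcaceae", paste0("s", 1:4)))
  d <- data.frame(sample_id = paste0("s", 1:4),
                  host_id = paste0("h", 1:4), family_id = "F01",
                  body_site = "fecal", species = "human",
                  role = c("child", "child", "adult_M", "adult_F"),
                  age = c(5, 6, 30, 31), has_dog = FALSE, has_cat = FALSE,
                  family_size = 4L)
  md <- sampleMetadata(d)
  res <- taxonAgeAnova(ft, md, groups = c("child", "adult"))
  expect_equal(res$F_value, 8, tolerance = 1e-12)
  expect_equal(res$p_value, pf(8, 1, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$mean_child, 1.5)
  expect_equal(res$mean_adult, 3.5)

  # families under the 1% abundance floor are not tested
  ft2 <- rbind(ft, Rare = c(0.5, 0.5, 0.5, 0.5))
  res2 <- taxonAgeAnova(ft2, md, groups = c("child", "adult"))
  expect_false("Rare" %in% res2$family)
})

test_that("the infant taxon signature is recovered from generator output", {
  cfg <- simulationConfig(n_families_by_type = c(children = 12, dogs = 0,
                                                 both = 0, neither = 6),
                          n_taxa = 80, depth_meanlog = log(1000), seed = 37)
  ds <- simulateDataset(cfg)
  md <- metadataTable(ds$metadata)
  oral <- md$sample_id[md$body_site == "oral"]
  pct <- collapseToFamily(ds$table[, oral])
  res <- taxonAgeAnova(pct, ds$metadata,
                       groups = c("infant", "child", "adult"))
  strep <- res[res$family == "Streptococcaceae", ]
  expect_true(nrow(strep) == 1 && strep$significant)
  expect_gt(strep$mean_infant, strep$mean_adult)
})
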