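# Shared-phylotype accounting and taxon-family summaries: per-pair shared
# OTU counts, breakdowns by taxonomy family with rank-sum tests, sharing
# comparisons across cohabitation x dog-ownership strata, collapse to
# family-level relative abundances, and the age-group ANOVA.

#' Age-group classification
#'
#' Bins ages (years) into the study's groups: infant (under 1), child
#' (1 to under 18), adult (18 to under 60), senior (60 and over).
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels infant, child, adult, senior.
#' @export
ageGroup <- function(age) {
  cut(age, breaks = c(-Inf, 1, 18, 60, Inf), right = FALSE,
      labels = c("infant", "child", "adult", "senior"))
}

#' Number of phylotypes shared by two samples
#'
#' Presence-based (count >= 1 in both). Tables should be rarefied to a
#' common depth first so richness differences do not masquerade as
#' sharing differences; unequal depths trigger a warning.
#'
#' @param table an [OtuTable-class].
#' @param sample_i,sample_j sample ids.
#' @return integer shared-phylotype count.
#' @export
sharedPhylotypes <- function(table, sample_i, sample_j) {
  cnt <- otuCounts(table)
  missing <- setdiff(c(sample_i, sample_j), colnames(cnt))
  if (length(missing)) stop("unknown sample id: ", missing[1])
  if (sum(cnt[, sample_i]) != sum(cnt[, sample_j]))
    warning("samples have unequal depths; rarefy to a common depth first")
  sum(cnt[, sample_i] >= 1 & cnt[, sample_j] >= 1)
}

.pairFrame <- function(pairs) {
  if (inherits(pairs, "DyadPairs")) pairs <- pairs$pairs
  stopifnot(is.data.frame(pairs), all(c("s1", "s2") %in% names(pairs)))
  pairs
}

# shared counts per taxonomy family (rows) per pair (columns)
.sharedByFamilyMatrix <- function(table, pairs, rank = "family") {
  cnt <- otuCounts(table)
  tax <- otuTaxonomy(table)
  if (!length(tax))
    stop("table has no taxonomy; use sharedPhylotypes() for rank-free counts")
  fam <- taxonomyRank(tax[rownames(cnt)], rank)
  P <- (cnt >= 1) * 1
  shared <- P[, pairs$s1, drop = FALSE] * P[, pairs$s2, drop = FALSE]
  rowsum(shared, fam)
}

#' Shared phylotypes broken down by taxonomy family
#'
#' For each taxonomy family, counts the phylotypes of that family shared
#' by each within pair and each between pair, and compares the two
#' distributions with a two-sided Wilcoxon rank-sum test, Bonferroni
#' corrected across families. The per-family counts of any pair sum to its
#' total shared-phylotype count.
#'
#' @param table an [OtuTable-class] with taxonomy (rarefied upstream).
#' @param pairs a \code{DyadPairs} object from [buildDyads()] or a
#'   data.frame with columns \code{s1, s2, within}.
#' @param rank taxonomy rank to break down by (default family).
#' @return list with \code{by_family} (data.frame: family, n_within,
#'   n_between, mean_within, ci_lo/hi_within, mean_between,
#'   ci_lo/hi_between, p_value, p_bonferroni, significant) and
#'   \code{per_pair} (family x pair matrix of shared counts).
#' @export
sharedByTaxonFamily <- function(table, pairs, rank = "family") {
  p <- .pairFrame(pairs)
  stopifnot("within" %in% names(p))
  M <- .sharedByFamilyMatrix(table, p, rank)
  w <- p$within
  ci_half <- function(x) if (length(x) > 1) 1.96 * sd(x) / sqrt(length(x)) else 0
  res <- do.call(rbind, lapply(rownames(M), function(f) {
    xw <- M[f, w]; xb <- M[f, !w]
    pv <- if (length(unique(c(xw, xb))) == 1) 1 else
      suppressWarnings(wilcox.test(xw, xb)$p.value)
    data.frame(family = f, n_within = length(xw), n_between = length(xb),
               mean_within = mean(xw),
               ci_lo_within = mean(xw) - ci_half(xw),
               ci_hi_within = mean(xw) + ci_half(xw),
               mean_between = mean(xb),
               ci_lo_between = mean(xb) - ci_half(xb),
               ci_hi_between = mean(xb) + ci_half(xb),
               p_value = pv, stringsAsFactors = FALSE)
  }))
  res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
  res$significant <- res$p_bonferroni < 0.05
  rownames(res) <- NULL
  list(by_family = res, per_pair = M)
}

#' Shared phylotypes across cohabitation and dog-ownership strata
#'
#' Forms all adult-adult pairs at a body site and stratifies them by
#' whether the two adults cohabit and whether both households own dogs:
#' \code{cohabiting_dog}, \code{cohabiting_nodog}, \code{separate_dog},
#' \code{separate_nodog} (pairs of mixed ownership are dropped). Reports
#' shared-phylotype means with 95% CIs per stratum and Wilcoxon rank-sum
#' tests for every stratum contrast, Bonferroni corrected.
#'
#' @param table an [OtuTable-class] (rarefied upstream).
#' @param metadata a [SampleMetadata-class].
#' @param site body site to compare at.
#' @return list with \code{strata} (data.frame: stratum, n_pairs, mean,
#'   ci_lo, ci_hi) and \code{contrasts} (data.frame: stratum_1, stratum_2,
#'   p_value, p_bonferroni).
#' @export
groupSharingComparison <- function(table, metadata, site) {
  md <- metadataTable(metadata)
  cnt <- otuCounts(table)
  h <- md[md$body_site == site & md$species == "human" &
          md$role %in% c("adult_M", "adult_F", "senior") &
          md$sample_id %in% colnames(cnt), , drop = FALSE]
  if (nrow(h) < 2) stop("fewer than two eligible adults at site '", site, "'")
  idx <- t(utils::combn(nrow(h), 2))
  cohab <- h$family_id[idx[, 1]] == h$family_id[idx[, 2]]
  both_dog <- h$has_dog[idx[, 1]] & h$has_dog[idx[, 2]]
  neither_dog <- !h$has_dog[idx[, 1]] & !h$has_dog[idx[, 2]]
  stratum <- rep(NA_character_, nrow(idx))
  stratum[cohab & both_dog] <- "cohabiting_dog"
  stratum[cohab & neither_dog] <- "cohabiting_nodog"
  stratum[!cohab & both_dog] <- "separate_dog"
  stratum[!cohab & neither_dog] <- "separate_nodog"
  keep <- !is.na(stratum)
  idx <- idx[keep, , drop = FALSE]
  stratum <- stratum[keep]
  P <- (cnt >= 1) * 1
  shared <- colSums(P[, h$sample_id[idx[, 1]], drop = FALSE] *
                    P[, h$sample_id[idx[, 2]], drop = FALSE])
  levels_all <- c("cohabiting_dog", "cohabiting_nodog",
                  "separate_dog", "separate_nodog")
  present <- levels_all[levels_all %in% stratum]
  skipped <- setdiff(levels_all, present)
  if (length(skipped))
    warning("empty stratum(s) skipped: ", paste(skipped, collapse = ", "))
  strata <- do.call(rbind, lapply(present, function(s) {
    x <- shared[stratum == s]
    half <- if (length(x) > 1) 1.96 * sd(x) / sqrt(length(x)) else 0
    data.frame(stratum = s, n_pairs = length(x), mean = mean(x),
               ci_lo = mean(x) - half, ci_hi = mean(x) + half,
               stringsAsFactors = FALSE)
  }))
  contrasts <- NULL
  if (length(present) >= 2) {
    cmb <- t(utils::combn(present, 2))
    contrasts <- do.call(rbind, lapply(seq_len(nrow(cmb)), function(k) {
      x1 <- shared[stratum == cmb[k, 1]]
      x2 <- shared[stratum == cmb[k, 2]]
      pv <- if (length(unique(c(x1, x2))) == 1) 1 else
        suppressWarnings(wilcox.test(x1, x2)$p.value)
      data.frame(stratum_1 = cmb[k, 1], stratum_2 = cmb[k, 2],
                 p_value = pv, stringsAsFactors = FALSE)
    }))
    contrasts$p_bonferroni <- pmin(1, contrasts$p_value * nrow(contrasts))
  }
  list(strata = strata, contrasts = contrasts)
}

#' Collapse an OTU table to family-level relative abundances
#'
#' Counts are summed over OTUs sharing a taxonomy-family label and
#' converted to percent of each sample's total; OTUs without a family
#' assignment pool into \code{"unclassified"}.
#'
#' @param table an [OtuTable-class] with taxonomy.
#' @param rank taxonomy rank (default family).
#' @return numeric matrix, taxon families x samples, in percent (columns
#'   of non-empty samples sum to 100).
#' @export
collapseToFamily <- function(table, rank = "family") {
  cnt <- otuCounts(table)
  tax <- otuTaxonomy(table)
  if (!length(tax)) stop("table has no taxonomy")
  fam <- taxonomyRank(tax[rownames(cnt)], rank)
  agg <- rowsum(cnt, fam)
  tot <- colSums(agg)
  pct <- sweep(agg, 2, ifelse(tot > 0, tot, 1), "/") * 100
  pct
}

#' ANOVA of family-level abundances across age groups
#'
#' Restricts to taxon families whose abundance exceeds
#' \code{min_abundance} percent (by default the grand mean across all
#' tested samples; \code{filter_scope = "per_group"} retains a family if
#' any group mean exceeds the threshold), runs a one-way ANOVA of percent
#' abundance against age group per family, and Bonferroni-corrects across
#' the retained families.
#'
#' @param family_table percent-abundance matrix from [collapseToFamily()].
#' @param metadata a [SampleMetadata-class] covering the columns.
#' @param groups age-group levels to include.
#' @param min_abundance retention threshold in percent (default 1).
#' @param filter_scope \code{"overall"} or \code{"per_group"}.
#' @return data.frame: family, group means (%), F_value, df_between,
#'   df_within, p_value, p_bonferroni, significant, degenerate.
#' @export
taxonAgeAnova <- function(family_table, metadata,
                          groups = c("infant", "child", "adult", "senior"),
                          min_abundance = 1,
                          filter_scope = c("overall", "per_group")) {
  filter_scope <- match.arg(filter_scope)
  md <- metadataTable(metadata)
  md <- md[md$species == "human", , drop = FALSE]
  md$age_group <- as.character(ageGroup(md$age))
  md <- md[md$age_group %in% groups &
           md$sample_id %in% colnames(family_table), , drop = FALSE]
  grp <- factor(md$age_group, levels = groups)
  used <- droplevels(grp)
  if (nlevels(used) < 2 || any(table(used) < 2))
    stop("need >= 2 age groups with >= 2 samples each")
  X <- family_table[, md$sample_id, drop = FALSE]
  grand <- rowMeans(X)
  group_means <- t(apply(X, 1, function(x) tapply(x, grp, mean)))
  retained <- if (filter_scope == "overall") grand > min_abundance else
    apply(group_means, 1, function(m) any(m > min_abundance, na.rm = TRUE))
  X <- X[retained, , drop = FALSE]
  if (!nrow(X)) return(data.frame())
  res <- do.call(rbind, lapply(rownames(X), function(f) {
    x <- X[f, ]
    degenerate <- all(tapply(x, used, var) == 0, na.rm = TRUE)
    if (degenerate) {
      Fv <- NA_real_; pv <- NA_real_
      dfb <- nlevels(used) - 1L; dfw <- length(x) - nlevels(used)
    } else {
      fit <- aov(x ~ used)
      s <- summary(fit)[[1]]
      Fv <- s[["F value"]][1]; pv <- s[["Pr(>F)"]][1]
      dfb <- s[["Df"]][1]; dfw <- s[["Df"]][2]
    }
    out <- data.frame(family = f, stringsAsFactors = FALSE)
    for (g in groups)
      out[[paste0("mean_", g)]] <-
        if (g %in% levels(used)) mean(x[used == g]) else NA_real_
    out$F_value <- Fv; out$df_between <- dfb; out$df_within <- dfw
    out$p_value <- pv; out$degenerate <- degenerate
    out
  }))
  res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
  res$significant <- !is.na(res$p_bonferroni) & res$p_bonferroni < 0.05
  rownames(res) <- NULL
  res
}
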