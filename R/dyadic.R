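# Dyadic within- vs between-household inference: pair construction per
# comparison category, the ANOSIM-like rank statistic R, its permutation
# null (family labels shuffled within role strata), one-way PERMANOVA,
# the age-trajectory regression against an adult baseline, and the
# minimal-detectable-effect computation.

DYAD_CATEGORIES <- c("families", "spouses", "father_child", "mother_child",
                     "father_infant", "mother_infant", "dogs",
                     "owner_own_dog", "owner_other_dog", "nonowner_dog")

.hostsAtSite <- function(md, site, species = NULL, roles = NULL,
                         age_range = NULL, has_dog = NULL) {
  d <- md[md$body_site == site, , drop = FALSE]
  if (!is.null(species)) d <- d[d$species %in% species, , drop = FALSE]
  if (!is.null(roles)) d <- d[d$role %in% roles, , drop = FALSE]
  if (!is.null(age_range))
    d <- d[d$age >= age_range[1] & d$age <= age_range[2], , drop = FALSE]
  if (!is.null(has_dog)) d <- d[d$has_dog == has_dog, , drop = FALSE]
  if (anyDuplicated(d$host_id))
    stop("multiple samples per host at site '", site, "'")
  d[, c("sample_id", "host_id", "family_id", "role", "age", "has_dog")]
}

.crossPairs <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(NULL)
  idx <- expand.grid(i = seq_len(nrow(A)), j = seq_len(nrow(B)))
  idx <- idx[A$host_id[idx$i] != B$host_id[idx$j], , drop = FALSE]
  data.frame(s1 = A$sample_id[idx$i], s2 = B$sample_id[idx$j],
             host1 = A$host_id[idx$i], host2 = B$host_id[idx$j],
             fam1 = A$family_id[idx$i], fam2 = B$family_id[idx$j],
             stringsAsFactors = FALSE)
}

.selfPairs <- function(A) {
  if (nrow(A) < 2) return(NULL)
  idx <- t(utils::combn(nrow(A), 2))
  data.frame(s1 = A$sample_id[idx[, 1]], s2 = A$sample_id[idx[, 2]],
             host1 = A$host_id[idx[, 1]], host2 = A$host_id[idx[, 2]],
             fam1 = A$family_id[idx[, 1]], fam2 = A$family_id[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Build within- and between-household dyads for one comparison category
#'
#' Pair predicates follow the study's comparison table: for partners the
#' within group is male x female adults of the same household and the
#' between group all male x female combinations across households;
#' parent-child categories pair a parent with children aged
#' \code{child_age} (default 3-18 y) or infants (under 1 y); \code{dogs}
#' pairs cohabiting dogs vs dogs of different households;
#' \code{owner_own_dog} pairs a dog-owning adult's skin sample with their
#' own vs other families' dogs. \code{owner_other_dog} contrasts
#' dog-owning adults paired with other families' dogs (within) against
#' non-owning adults paired with dogs (between); \code{nonowner_dog}
#' returns only the non-owner x dog pairs (a stratum for sharing
#' comparisons, not a testable dyad).
#'
#' @param metadata a [SampleMetadata-class].
#' @param category one of \code{families, spouses, father_child,
#'   mother_child, father_infant, mother_infant, dogs, owner_own_dog,
#'   owner_other_dog, nonowner_dog}.
#' @param site body site; for the owner/dog categories a length-2 vector
#'   \code{c(human_site, dog_site)} (a single site is recycled).
#' @param child_age numeric length-2 age window for "child" dyads.
#' @param infant_age_max upper age bound (years) for "infant" dyads.
#' @return An object of class \code{DyadPairs}: list with \code{pairs}
#'   (data.frame \code{s1, s2, host1, host2, fam1, fam2, within}),
#'   \code{hosts} (per eligible host: id, family, role stratum),
#'   \code{category}, \code{site}, \code{perm_unit}.
#' @export
buildDyads <- function(metadata, category, site, child_age = c(3, 18),
                       infant_age_max = 1) {
  stopifnot(is(metadata, "SampleMetadata"))
  category <- match.arg(category, DYAD_CATEGORIES)
  md <- metadataTable(metadata)
  adult_roles <- c("adult_M", "adult_F", "senior")
  perm_unit <- "family"
  if (category %in% c("owner_own_dog", "owner_other_dog", "nonowner_dog")) {
    if (length(site) == 1) site <- c(site, site)
    hA <- .hostsAtSite(md, site[1], species = "human", roles = adult_roles)
    hB <- .hostsAtSite(md, site[2], species = "dog")
    if (category == "owner_own_dog") {
      hA <- hA[hA$has_dog, , drop = FALSE]
      pairs <- .crossPairs(hA, hB)
      if (!is.null(pairs)) pairs$within <- pairs$fam1 == pairs$fam2
    } else if (category == "owner_other_dog") {
      perm_unit <- "ownership"
      pairs <- .crossPairs(hA, hB)
      if (!is.null(pairs)) {
        own <- hA$has_dog[match(pairs$host1, hA$host_id)]
        keep <- !(own & pairs$fam1 == pairs$fam2)  # drop owner-own-dog pairs
        pairs <- pairs[keep, , drop = FALSE]
        pairs$within <- own[keep]
      }
    } else {
      perm_unit <- "none"
      hA <- hA[!hA$has_dog, , drop = FALSE]
      pairs <- .crossPairs(hA, hB)
      if (!is.null(pairs)) pairs$within <- FALSE
    }
    hosts <- rbind(hA, hB)
  } else {
    if (category == "spouses") {
      # within: male x female adults of the same household; between: all
      # combinations of those same males and females across households
      # (including same-sex cross-family pairs, per the stated rule)
      hM <- .hostsAtSite(md, site, roles = "adult_M")
      hF <- .hostsAtSite(md, site, roles = "adult_F")
      mf <- .crossPairs(hM, hF)
      if (!is.null(mf)) {
        mf$within <- mf$fam1 == mf$fam2
        mf$type <- "mf"
      }
      ss <- rbind(.selfPairs(hM), .selfPairs(hF))
      if (!is.null(ss)) {
        ss <- ss[ss$fam1 != ss$fam2, , drop = FALSE]
        if (nrow(ss)) { ss$within <- FALSE; ss$type <- "ss" } else ss <- NULL
      }
      pairs <- rbind(mf, ss)
      hosts <- rbind(hM, hF)
      if (is.null(pairs) || !nrow(pairs) || !any(pairs$within))
        stop("category 'spouses' has no within pairs at site '", site, "'")
      if (length(unique(hosts$family_id)) < 2)
        stop("category 'spouses' needs >= 2 eligible families")
      hosts <- hosts[!duplicated(hosts$host_id), , drop = FALSE]
      return(structure(list(pairs = pairs, hosts = hosts,
                            category = category, site = site,
                            perm_unit = "family"),
                       class = "DyadPairs"))
    }
    groups <- switch(category,
      families      = list(.hostsAtSite(md, site, species = "human")),
      father_child  = list(.hostsAtSite(md, site, roles = "adult_M"),
                           .hostsAtSite(md, site, roles = c("child", "infant"),
                                        age_range = child_age)),
      mother_child  = list(.hostsAtSite(md, site, roles = "adult_F"),
                           .hostsAtSite(md, site, roles = c("child", "infant"),
                                        age_range = child_age)),
      father_infant = list(.hostsAtSite(md, site, roles = "adult_M"),
                           .hostsAtSite(md, site, roles = "infant",
                                        age_range = c(0, infant_age_max))),
      mother_infant = list(.hostsAtSite(md, site, roles = "adult_F"),
                           .hostsAtSite(md, site, roles = "infant",
                                        age_range = c(0, infant_age_max))),
      dogs          = list(.hostsAtSite(md, site, species = "dog")))
    if (length(groups) == 1) {
      pairs <- .selfPairs(groups[[1]])
      hosts <- groups[[1]]
    } else {
      pairs <- .crossPairs(groups[[1]], groups[[2]])
      hosts <- rbind(groups[[1]], groups[[2]])
    }
    if (!is.null(pairs)) pairs$within <- pairs$fam1 == pairs$fam2
  }
  if (is.null(pairs) || !nrow(pairs) || !any(pairs$within) &&
      perm_unit != "none")
    stop("category '", category, "' has no within pairs at site '",
         paste(site, collapse = "/"), "'")
  if (length(unique(hosts$family_id)) < 2)
    stop("category '", category, "' needs >= 2 eligible families")
  hosts <- hosts[!duplicated(hosts$host_id), , drop = FALSE]
  structure(list(pairs = pairs, hosts = hosts, category = category,
                 site = site, perm_unit = perm_unit),
            class = "DyadPairs")
}

#' ANOSIM-like rank statistic on two sets of distances
#'
#' All distances are ranked jointly (ties midranked);
#' \eqn{R = (\bar r_{between} - \bar r_{within}) / (N/2)}, bounded in
#' [-1, 1]. Positive R means within-pair distances are smaller than
#' between-pair distances.
#'
#' @param within,between numeric distance vectors (both non-empty).
#' @return The R statistic.
#' @examples
#' anosimR(c(0.1, 0.2), c(0.3, 0.4))  # 1
#' @export
anosimR <- function(within, between) {
  if (!length(within) || !length(between))
    stop("both distance sets must be non-empty")
  rk <- rank(c(within, between))
  n_w <- length(within)
  (mean(rk[-seq_len(n_w)]) - mean(rk[seq_len(n_w)])) / (length(rk) / 2)
}

# log number of distinct family-label rearrangements within role strata
.logDistinctPerms <- function(hosts) {
  total <- 0
  for (r in unique(hosts$role)) {
    fams <- hosts$family_id[hosts$role == r]
    total <- total + lgamma(length(fams) + 1) -
      sum(lgamma(table(fams) + 1))
  }
  total
}

#' Dyadic within- vs between-household permutation test
#'
#' Computes the observed [anosimR()] over the dyads of
#' [buildDyads()], then builds the null by permuting family labels among
#' the eligible individuals within each role stratum (mothers' households
#' shuffled among mothers, fathers' among fathers, ...), re-forming the
#' dyads and recomputing R each time. One-sided (within more similar than
#' between); p uses the add-one estimator
#' \eqn{(1 + \#\{R_{perm} \ge R_{obs}\}) / (1 + n_{perm})}.
#'
#' @param dm a [DistanceMatrix-class] (samples must cover the dyads; pairs
#'   whose samples were filtered out are dropped with a warning).
#' @param metadata a [SampleMetadata-class].
#' @param category,site,child_age,infant_age_max passed to [buildDyads()].
#' @param n_perm number of permutations (study default 10,000).
#' @param seed integer seed.
#' @return A [DyadTestResult-class].
#' @export
dyadPermutationTest <- function(dm, metadata, category, site,
                                n_perm = 10000, seed = 1L,
                                child_age = c(3, 18), infant_age_max = 1) {
  dy <- buildDyads(metadata, category, site, child_age, infant_age_max)
  if (dy$perm_unit == "none")
    stop("category '", category, "' defines no within/between contrast; ",
         "use groupSharingComparison() for ownership strata")
  D <- as.matrix(dm)
  p <- dy$pairs
  have <- p$s1 %in% rownames(D) & p$s2 %in% rownames(D)
  if (!all(have)) {
    warning(sum(!have), " pair(s) dropped: sample(s) absent from the ",
            "distance matrix")
    p <- p[have, , drop = FALSE]
  }
  if (!any(p$within) || !any(!p$within))
    stop("need both within and between pairs after filtering")
  d <- D[cbind(match(p$s1, rownames(D)), match(p$s2, rownames(D)))]
  rk <- rank(d)
  N <- length(d)
  half_N <- N / 2
  R_of <- function(w) (mean(rk[!w]) - mean(rk[w])) / half_N
  R_obs <- R_of(p$within)

  hosts <- dy$hosts
  hosts <- hosts[hosts$sample_id %in% rownames(D) |
                 hosts$host_id %in% c(p$host1, p$host2), , drop = FALSE]
  i1 <- match(p$host1, hosts$host_id)
  i2 <- match(p$host2, hosts$host_id)
  warnings <- character()
  if (dy$perm_unit == "family" &&
      .logDistinctPerms(hosts) < log(100))
    warnings <- c(warnings, "fewer than 100 distinct permutations")

  pair_type <- if (!is.null(p$type)) p$type else rep("std", nrow(p))
  R_perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(b) {
      if (dy$perm_unit == "family") {
        fam <- hosts$family_id
        for (r in unique(hosts$role)) {
          s <- which(hosts$role == r)
          fam[s] <- fam[s][sample.int(length(s))]
        }
        samefam <- fam[i1] == fam[i2]
        if (dy$category == "spouses") {
          # same-sex pairs landing in one household leave the universe
          keep <- !(pair_type == "ss" & samefam)
          w <- pair_type == "mf" & samefam
          if (!all(keep)) {
            if (!any(w[keep]) || all(w[keep])) return(NA_real_)
            rks <- rank(d[keep])
            return((mean(rks[!w[keep]]) - mean(rks[w[keep]])) /
                   (sum(keep) / 2))
          }
        } else w <- samefam
      } else {
        # ownership mode: permute which families own dogs
        fams <- unique(hosts$family_id)
        own_by_fam <- vapply(fams, function(f)
          any(hosts$has_dog[hosts$family_id == f]), logical(1))
        own_perm <- own_by_fam[sample.int(length(fams))]
        names(own_perm) <- fams
        own1 <- own_perm[hosts$family_id[i1]]
        w <- own1 & p$fam1 != p$fam2
      }
      if (!any(w) || all(w)) return(NA_real_)
      R_of(w)
    }, numeric(1))
  })
  valid <- !is.na(R_perm)
  if (any(!valid))
    warnings <- c(warnings, sprintf("%d degenerate permutation(s) skipped",
                                    sum(!valid)))
  p_value <- (1 + sum(R_perm[valid] >= R_obs)) / (1 + sum(valid))

  ci <- function(x) {
    m <- mean(x)
    half <- if (length(x) > 1) 1.96 * sd(x) / sqrt(length(x)) else 0
    c(m - half, m + half)
  }
  new("DyadTestResult", category = dy$category,
      site = as.character(dy$site),
      R = R_obs, p_value = p_value,
      n_within = sum(p$within), n_between = sum(!p$within),
      mean_within = mean(d[p$within]), mean_between = mean(d[!p$within]),
      ci_within = ci(d[p$within]), ci_between = ci(d[!p$within]),
      n_permutations = as.integer(sum(valid)), warnings = warnings)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Partitions squared distances among vs within groups:
#' \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / N},
#' \eqn{SS_{within} = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g},
#' pseudo-F \eqn{= (SS_{between}/(a-1)) / (SS_{within}/(N-a))}, tested by
#' permuting group labels. Also returns the square root of the among-group
#' variance-component estimate
#' \eqn{(MS_{between} - MS_{within}) / \bar n}.
#'
#' @param dm a [DistanceMatrix-class].
#' @param grouping factor/character of group labels, either named by
#'   sample id or aligned with the matrix order; >= 2 groups, N > a.
#' @param n_perm number of label permutations (study default 999).
#' @param seed integer seed.
#' @return A [PermanovaResult-class].
#' @export
permanovaOneway <- function(dm, grouping, n_perm = 999, seed = 1L) {
  D <- as.matrix(dm)
  N <- nrow(D)
  if (!is.null(names(grouping))) {
    stopifnot(all(rownames(D) %in% names(grouping)))
    grouping <- grouping[rownames(D)]
  }
  stopifnot(length(grouping) == N)
  g <- factor(grouping)
  a <- nlevels(g)
  stopifnot(a >= 2, N > a)
  D2 <- D * D
  ss_total <- sum(D2[upper.tri(D2)]) / N
  ss_within_of <- function(g) {
    Z <- model.matrix(~ g - 1)
    grp <- diag(crossprod(Z, D2 %*% Z)) / 2
    sum(grp / colSums(Z))
  }
  ssw <- ss_within_of(g)
  ssb <- ss_total - ssw
  df_b <- a - 1L
  df_w <- N - a
  F_of <- function(ssw) if (ssw <= 0) Inf else (ss_total - ssw) / df_b /
                                               (ssw / df_w)
  F_obs <- F_of(ssw)
  F_perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(b)
      F_of(ss_within_of(g[sample.int(N)])), numeric(1))
  })
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  n_g <- tabulate(g)
  nbar <- (N - sum(n_g^2) / N) / df_b
  ms_b <- ssb / df_b
  ms_w <- ssw / df_w
  v_between <- sqrt(max(0, (ms_b - ms_w) / nbar))
  new("PermanovaResult", pseudo_F = F_obs, df_between = df_b,
      df_residual = as.integer(df_w), p_value = p,
      component_of_variation = v_between,
      n_permutations = as.integer(n_perm))
}

#' Distance to the adult baseline as a function of age
#'
#' For each participant with a sample at the site, averages their distance
#' to all baseline adults' same-site samples (baseline ages default 30-45
#' years; the focal participant and, by default, their own household are
#' excluded), then fits an ordinary least-squares line of mean distance
#' against age.
#'
#' @param dm a [DistanceMatrix-class].
#' @param metadata a [SampleMetadata-class].
#' @param site body site.
#' @param baseline length-2 age window defining baseline adults.
#' @param include_own_family logical; include same-household baseline
#'   adults (default FALSE, so household sharing does not masquerade as an
#'   age effect).
#' @param max_age restrict focal participants to ages <= max_age
#'   (default Inf: everyone).
#' @return list with \code{points} (host, age, mean_dist, n_baseline),
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{p_value},
#'   \code{degenerate} flag.
#' @export
ageTrajectory <- function(dm, metadata, site, baseline = c(30, 45),
                          include_own_family = FALSE, max_age = Inf) {
  md <- metadataTable(metadata)
  D <- as.matrix(dm)
  at_site <- md[md$body_site == site & md$species == "human" &
                md$sample_id %in% rownames(D), , drop = FALSE]
  base <- at_site[at_site$age >= baseline[1] & at_site$age <= baseline[2], ,
                  drop = FALSE]
  if (nrow(base) < 2) stop("need >= 2 baseline adults at site '", site, "'")
  focal <- at_site[at_site$age <= max_age, , drop = FALSE]
  rows <- lapply(seq_len(nrow(focal)), function(k) {
    b <- base[base$host_id != focal$host_id[k], , drop = FALSE]
    if (!include_own_family)
      b <- b[b$family_id != focal$family_id[k], , drop = FALSE]
    if (!nrow(b)) return(NULL)
    data.frame(host = focal$host_id[k], age = focal$age[k],
               mean_dist = mean(D[focal$sample_id[k], b$sample_id]),
               n_baseline = nrow(b), stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, rows)
  degenerate <- var(pts$mean_dist) == 0 || length(unique(pts$age)) < 2
  if (degenerate) {
    slope <- 0; intercept <- mean(pts$mean_dist); r2 <- 0; pv <- NA_real_
  } else {
    fit <- lm(mean_dist ~ age, data = pts)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    s <- summary(fit)
    r2 <- s$r.squared
    pv <- s$coefficients[2, 4]
  }
  list(points = pts, slope = slope, intercept = intercept,
       r_squared = r2, p_value = pv, degenerate = degenerate)
}

#' Minimal detectable effect size (two-sample power analysis)
#'
#' Normal-approximation Cohen's d detectable with the given sample sizes:
#' \eqn{d = (z_{1-\alpha/2} + z_{power})\sqrt{1/n_1 + 1/n_2}}.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return Cohen's d.
#' @examples
#' minDetectableEffect(2757, 3071, 0.05, 0.90)  # ~0.085
#' @export
minDetectableEffect <- function(n1, n2, alpha = 0.05, power = 0.90) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  (qnorm(1 - alpha / 2) + qnorm(power)) * sqrt(1 / n1 + 1 / n2)
}
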