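# Shared fixtures and independent oracles used across the suite.

quartetTree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")

makeOtu <- function(counts, samples, otus = NULL, taxonomy = NULL) {
  m <- matrix(counts, ncol = length(samples))
  if (is.null(otus)) otus <- paste0("OTU_", seq_len(nrow(m)))
  dimnames(m) <- list(otus, samples)
  otuTable(m, taxonomy)
}

# minimal metadata: couples-only households, one site
coupleMetadata <- function(n_families, sites = "forehead") {
  rows <- list()
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%02d", f)
    for (who in c("M", "F")) {
      host <- paste0(fam, "_", who)
      rows[[host]] <- data.frame(
        sample_id = paste(host, sites, sep = "."), host_id = host,
        family_id = fam, body_site = sites, species = "human",
        role = paste0("adult_", who), age = 35, has_dog = FALSE,
        has_cat = FALSE, family_size = 2L, stringsAsFactors = FALSE)
    }
  }
  sampleMetadata(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

# independent brute-force UniFrac: enumerates every edge's descendant tip
# set by recursive descent over the edge list (a different traversal than
# the package's postorder accumulation)
edgeTipSets <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(kids[[as.character(node)]], desc))
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc(tree$edge[e, 2]))
}

bruteUnifrac <- function(counts, tree, i, j,
                         metric = c("unweighted", "weighted"),
                         normalized = FALSE) {
  metric <- match.arg(metric)
  sets <- edgeTipSets(tree)
  len <- tree$edge.length
  ci <- counts[tree$tip.label, i]
  cj <- counts[tree$tip.label, j]
  if (metric == "unweighted") {
    uniq <- obs <- 0
    for (e in seq_along(sets)) {
      pi <- any(ci[sets[[e]]] > 0)
      pj <- any(cj[sets[[e]]] > 0)
      if (pi || pj) obs <- obs + len[e]
      if (xor(pi, pj)) uniq <- uniq + len[e]
    }
    uniq / obs
  } else {
    d <- 0
    for (e in seq_along(sets))
      d <- d + len[e] * abs(sum(ci[sets[[e]]]) / sum(ci) -
                            sum(cj[sets[[e]]]) / sum(cj))
    if (normalized) {
      tip_depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
      d <- d / sum(tip_depth * (ci / sum(ci) + cj / sum(cj)))
    }
    d
  }
}

# naive double-loop one-way PERMANOVA pseudo-F
naivePseudoF <- function(D, g) {
  g <- as.factor(g)
  N <- nrow(D)
  a <- nlevels(g)
  ss_t <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) ss_t <- ss_t + D[i, j]^2
  ss_t <- ss_t / N
  ss_w <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    s <- 0
    if (length(idx) > 1)
      for (i in idx) for (j in idx) if (i < j) s <- s + D[i, j]^2
    ss_w <- ss_w + s / length(idx)
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (N - a))
}

# random presence/abundance instance on a random tree (<= max_tips tips)
randomUnifracCase <- function(max_tips = 16) {
  n <- sample(3:max_tips, 1)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 2))
  cnt <- matrix(rpois(2 * n, 2), n, 2,
                dimnames = list(tr$tip.label, c("s1", "s2")))
  # ensure both samples non-empty
  if (sum(cnt[, 1]) == 0) cnt[sample.int(n, 1), 1] <- 1
  if (sum(cnt[, 2]) == 0) cnt[sample.int(n, 1), 2] <- 1
  list(tree = tr, counts = cnt)
}
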