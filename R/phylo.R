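# Phylogenetic community metrics: UniFrac (unweighted / weighted raw /
# weighted normalized), Faith's PD, depth filtering, rarefaction, and
# classical PCoA. All metrics are computed from a per-edge summary of the
# tree (which samples have reads below each edge), built once per table.

# Per-edge descendant read counts for every sample.
# Returns edge lengths, an edges x samples count matrix, per-sample totals,
# and root-to-tip depths (for the normalized weighted variant).
.branchPartition <- function(counts, tree) {
  tips <- tree$tip.label
  nonzero <- rownames(counts)[rowSums(counts) > 0]
  missing <- setdiff(nonzero, tips)
  if (length(missing))
    stop("OTU(s) with nonzero counts absent from tree: ",
         paste(head(missing, 3), collapse = ", "))
  n_node <- max(tree$edge)
  S <- ncol(counts)
  node_cnt <- matrix(0, n_node, S)
  idx <- match(rownames(counts), tips)
  keep <- !is.na(idx)
  node_cnt[idx[keep], ] <- counts[keep, , drop = FALSE]
  po <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(po$edge)))
    node_cnt[po$edge[e, 1], ] <- node_cnt[po$edge[e, 1], ] +
                                 node_cnt[po$edge[e, 2], ]
  # root-to-node depths (preorder = reverse postorder)
  depth <- numeric(n_node)
  for (e in rev(seq_len(nrow(po$edge))))
    depth[po$edge[e, 2]] <- depth[po$edge[e, 1]] + po$edge.length[e]
  list(lengths = po$edge.length,
       edge_counts = node_cnt[po$edge[, 2], , drop = FALSE],
       totals = colSums(counts),
       tip_depth = setNames(depth[seq_along(tips)], tips),
       sample_ids = colnames(counts))
}

.partitionFor <- function(table, tree) {
  stopifnot(is(table, "OtuTable"))
  .branchPartition(otuCounts(table), tree)
}

#' Keep samples with at least a minimum sequencing depth
#'
#' Samples whose total count falls below \code{min_depth} are dropped
#' (the standard pre-rarefaction filter; the study removed samples with
#' fewer than 5000 sequences). OTUs left with all-zero rows are retained.
#'
#' @param table an [OtuTable-class].
#' @param min_depth integer >= 1.
#' @return The filtered [OtuTable-class]; may have zero samples.
#' @export
filterByDepth <- function(table, min_depth) {
  stopifnot(is(table, "OtuTable"), min_depth >= 1)
  keep <- colSums(otuCounts(table)) >= min_depth
  table[, keep]
}

# Deterministic per-key substream seed: results do not depend on the order
# in which samples are processed.
.substreamSeed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

.rarefyVector <- function(x, depth) {
  tot <- sum(x)
  picked <- sample.int(tot, depth)
  tabulate(findInterval(picked, c(0, cumsum(x)), left.open = TRUE),
           nbins = length(x))
}

#' Rarefy every sample to a fixed depth
#'
#' Subsamples exactly \code{depth} reads per sample without replacement
#' (multivariate hypergeometric). Each sample uses its own RNG substream
#' derived from \code{seed} and the sample id, so results are independent
#' of sample order.
#'
#' @param table an [OtuTable-class]; every sample must have at least
#'   \code{depth} reads (see [filterByDepth()]).
#' @param depth target depth (the study used 5000).
#' @param seed integer seed.
#' @return An [OtuTable-class] whose column sums all equal \code{depth}.
#' @export
rarefyCounts <- function(table, depth, seed) {
  stopifnot(is(table, "OtuTable"), depth >= 1)
  cnt <- otuCounts(table)
  tot <- colSums(cnt)
  if (any(tot < depth))
    stop("sample(s) shallower than rarefaction depth ", depth, ": ",
         paste(head(colnames(cnt)[tot < depth], 3), collapse = ", "))
  out <- cnt
  for (j in seq_len(ncol(cnt))) {
    if (tot[j] == depth) next
    sub <- .substreamSeed(seed, colnames(cnt)[j])
    out[, j] <- withr::with_seed(sub, .rarefyVector(cnt[, j], depth))
  }
  otuTable(out, if (length(otuTaxonomy(table))) otuTaxonomy(table) else NULL)
}

#' Pairwise UniFrac distance between two samples
#'
#' \code{unweightedUnifrac} is the fraction of observed branch length
#' leading only to taxa present (count >= 1) in exactly one of the two
#' samples. \code{weightedUnifrac} is
#' \eqn{\sum_e \ell_e |p_{ie} - p_{je}|} over edges, where \eqn{p} is the
#' proportion of a sample's reads descending from the edge; the normalized
#' variant divides by \eqn{\sum_k d_k (p_{ik} + p_{jk})} over tips
#' (\eqn{d_k} = root-to-tip distance), bounding it in [0, 1].
#'
#' @param table an [OtuTable-class] (typically rarefied).
#' @param tree rooted \code{phylo} with branch lengths covering the
#'   observed OTUs.
#' @param sample_i,sample_j sample ids.
#' @param normalized logical; weighted variant only (default raw).
#' @return A single distance.
#' @export
unweightedUnifrac <- function(table, tree, sample_i, sample_j) {
  if (identical(sample_i, sample_j)) {
    if (sum(otuCounts(table)[, sample_i]) == 0)
      stop("unweighted UniFrac undefined: both samples empty")
    return(0)
  }
  dm <- unifracDistance(table[, c(sample_i, sample_j)], tree,
                        metric = "unweighted")
  as.matrix(dm)[1, 2]
}

#' @rdname unweightedUnifrac
#' @export
weightedUnifrac <- function(table, tree, sample_i, sample_j,
                            normalized = FALSE) {
  if (identical(sample_i, sample_j)) {
    if (sum(otuCounts(table)[, sample_i]) == 0)
      stop("weighted UniFrac undefined for empty sample(s)")
    return(0)
  }
  dm <- unifracDistance(table[, c(sample_i, sample_j)], tree,
                        metric = "weighted", normalized = normalized)
  as.matrix(dm)[1, 2]
}

#' All pairwise UniFrac distances
#'
#' @inheritParams unweightedUnifrac
#' @param metric \code{"unweighted"} or \code{"weighted"}.
#' @return A [DistanceMatrix-class] over the table's samples.
#' @export
unifracDistance <- function(table, tree,
                            metric = c("unweighted", "weighted"),
                            normalized = FALSE) {
  metric <- match.arg(metric)
  bp <- .partitionFor(table, tree)
  S <- length(bp$sample_ids)
  if (metric == "unweighted") {
    P <- (bp$edge_counts > 0) * 1
    PL <- P * bp$lengths
    both <- crossprod(P, PL)                    # sum of L where both present
    tot <- colSums(PL)
    tots <- outer(tot, tot, "+")
    union <- tots - both
    if (any(union == 0 & upper.tri(union)))
      stop("unweighted UniFrac undefined: a sample pair observes no branch")
    D <- (tots - 2 * both) / union
    D[union == 0] <- 0
  } else {
    if (any(bp$totals == 0))
      stop("weighted UniFrac undefined for empty sample(s): ",
           paste(head(bp$sample_ids[bp$totals == 0], 3), collapse = ", "))
    prop <- sweep(bp$edge_counts, 2, bp$totals, "/")
    D <- matrix(0, S, S)
    for (i in seq_len(S - 1)) {
      js <- (i + 1):S
      D[i, js] <- colSums(bp$lengths *
                          abs(prop[, js, drop = FALSE] - prop[, i]))
      D[js, i] <- D[i, js]
    }
    if (normalized) {
      cnt <- otuCounts(table)
      tip_p <- sweep(cnt, 2, bp$totals, "/")
      dvec <- bp$tip_depth[rownames(cnt)]
      dvec[is.na(dvec)] <- 0
      Dn <- colSums(tip_p * dvec)
      denom <- outer(Dn, Dn, "+")
      D <- ifelse(denom > 0, D / denom, 0)
    }
  }
  D <- pmax(D, 0)           # guard against -1e-17-scale rounding
  diag(D) <- 0
  dimnames(D) <- list(bp$sample_ids, bp$sample_ids)
  distanceMatrix(D)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree spanning a sample's observed
#' taxa and the tree root (root-inclusive convention). Empty samples score
#' 0 with a warning, so rarefaction curves stay total.
#'
#' @param table an [OtuTable-class].
#' @param tree rooted \code{phylo} with branch lengths.
#' @param samples sample ids (default: all).
#' @return Named numeric vector of PD values.
#' @export
faithPD <- function(table, tree, samples = NULL) {
  if (!is.null(samples)) table <- table[, samples]
  bp <- .partitionFor(table, tree)
  if (any(bp$totals == 0))
    warning("empty sample(s) assigned PD = 0: ",
            paste(head(bp$sample_ids[bp$totals == 0], 3), collapse = ", "))
  setNames(colSums((bp$edge_counts > 0) * bp$lengths), bp$sample_ids)
}

#' Rarefaction curves of phylogenetic diversity
#'
#' For each sample and each requested depth not exceeding the sample's
#' total, averages [faithPD()] over \code{n_iter} independent rarefactions.
#' The RNG substream is keyed by (sample, depth, iteration), so the first
#' iterate is identical whatever \code{n_iter} is.
#'
#' @param table an [OtuTable-class].
#' @param tree rooted \code{phylo}.
#' @param depths ascending integer depths.
#' @param n_iter rarefactions per point (default 10).
#' @param seed integer seed.
#' @return data.frame with columns \code{sample}, \code{depth},
#'   \code{mean_pd}, \code{sd_pd}, \code{ci_lo}, \code{ci_hi},
#'   \code{n_iter}; CI is mean +/- 1.96 sd / sqrt(n_iter).
#' @export
rarefactionCurve <- function(table, tree, depths, n_iter = 10, seed) {
  stopifnot(!is.unsorted(depths), n_iter >= 1)
  cnt <- otuCounts(table)
  tax <- if (length(otuTaxonomy(table))) otuTaxonomy(table) else NULL
  rows <- list()
  for (j in seq_len(ncol(cnt))) {
    id <- colnames(cnt)[j]
    tot <- sum(cnt[, j])
    for (d in depths[depths <= tot]) {
      pd <- vapply(seq_len(n_iter), function(it) {
        sub <- .substreamSeed(seed, paste(id, d, it, sep = "\r"))
        x <- if (tot == d) cnt[, j] else
          withr::with_seed(sub, .rarefyVector(cnt[, j], d))
        one <- otuTable(matrix(x, ncol = 1,
                               dimnames = list(rownames(cnt), id)), tax)
        unname(faithPD(one, tree))
      }, numeric(1))
      m <- mean(pd); s <- if (n_iter > 1) sd(pd) else 0
      half <- 1.96 * s / sqrt(n_iter)
      rows[[length(rows) + 1]] <-
        data.frame(sample = id, depth = d, mean_pd = m, sd_pd = s,
                   ci_lo = m - half, ci_hi = m + half, n_iter = n_iter)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Classical principal coordinates analysis
#'
#' Double-centers \eqn{-D^2/2}, eigendecomposes, and returns coordinates
#' \eqn{v_k \sqrt{\lambda_k}} for the positive eigenvalues in descending
#' order. Negative eigenvalues (non-Euclidean structure) are reported but
#' contribute no axes.
#'
#' @param dm a [DistanceMatrix-class].
#' @param n_axes number of axes to return (default: all positive).
#' @return list with \code{points} (samples x axes), \code{eigenvalues}
#'   (all, descending), and \code{prop_explained} (over positive
#'   eigenvalues).
#' @export
pcoa <- function(dm, n_axes = NULL) {
  stopifnot(is(dm, "DistanceMatrix"))
  D <- as.matrix(dm)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals)) * 1e-12 + 1e-300
  pos <- which(vals > tol)
  if (is.null(n_axes)) n_axes <- length(pos)
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive eigenvalue(s); truncating axes")
    n_axes <- length(pos)
  }
  pts <- matrix(0, n, n_axes,
                dimnames = list(rownames(D),
                                if (n_axes) paste0("PC", seq_len(n_axes))))
  for (k in seq_len(n_axes))
    pts[, k] <- eig$vectors[, pos[k]] * sqrt(vals[pos[k]])
  list(points = pts, eigenvalues = vals,
       prop_explained = if (length(pos)) vals[pos] / sum(vals[pos])
                        else numeric(0))
}
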