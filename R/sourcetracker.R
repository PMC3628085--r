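# Source attribution: estimate what fraction of a sink community's reads
# derive from designated source environments (oral, fecal, ...) plus an
# implicit "unknown" source, via a collapsed Gibbs sampler over per-read
# source assignments (the SourceTracker model family).

#' Train source profiles for source attribution
#'
#' Pools the counts of all training samples assigned to each declared
#' source environment. By default the sink samples' own households are
#' excluded from the training pool (leave-one-out), so a sink cannot
#' explain itself through its household's contribution to the sources.
#'
#' @param table an [OtuTable-class].
#' @param metadata a [SampleMetadata-class].
#' @param source_definition named list or character vector mapping source
#'   label to body site(s), e.g. \code{list(oral = "oral", fecal =
#'   "fecal")}.
#' @param exclude_families family ids to leave out of the training pool
#'   (typically the sink samples' households); NULL for none.
#' @param species restrict training samples to a host species
#'   (default "human").
#' @param alpha_source per-taxon smoothing pseudocount for known sources.
#' @param alpha_unknown per-taxon pseudocount for the unknown source.
#' @param beta prior pseudocount on mixing proportions.
#' @return A [SourceModel-class].
#' @export
fitSources <- function(table, metadata, source_definition,
                       exclude_families = NULL, species = "human",
                       alpha_source = 0.001, alpha_unknown = 0.1,
                       beta = 10) {
  cnt <- otuCounts(table)
  md <- metadataTable(metadata)
  if (is.character(source_definition))
    source_definition <- as.list(source_definition)
  stopifnot(length(source_definition) >= 1,
            !is.null(names(source_definition)))
  profiles <- t(vapply(names(source_definition), function(lab) {
    sites <- source_definition[[lab]]
    sel <- md$body_site %in% sites & md$sample_id %in% colnames(cnt)
    if (!is.null(species)) sel <- sel & md$species %in% species
    if (!is.null(exclude_families))
      sel <- sel & !(md$family_id %in% exclude_families)
    if (!any(sel))
      stop("source '", lab, "' has no training samples")
    rowSums(cnt[, md$sample_id[sel], drop = FALSE])
  }, numeric(nrow(cnt))))
  colnames(profiles) <- rownames(cnt)
  new("SourceModel", profiles = profiles, alpha_source = alpha_source,
      alpha_unknown = alpha_unknown, beta = beta)
}

#' Estimate source mixing proportions for sink samples
#'
#' Collapsed Gibbs sampler over per-read source labels
#' \eqn{z_i \in} sources \eqn{\cup} \{unknown\}. The conditional for a
#' read of taxon \eqn{t} is proportional to
#' \deqn{\frac{m_{s,t} + n^{-i}_{s,t} + \alpha_s}
#'            {m_{s,\cdot} + n^{-i}_{s,\cdot} + T\alpha_s}
#'       \,(n^{-i}_s + \beta)}
#' with training counts \eqn{m} zero (and \eqn{\alpha} =
#' \code{alpha_unknown}) for the unknown source. Reported proportions are
#' posterior means of \eqn{n_s / N} after burn-in; a fixed seed makes the
#' chain deterministic.
#'
#' @param model a [SourceModel-class] from [fitSources()].
#' @param sink named count vector, or an [OtuTable-class] whose columns
#'   are the sink samples.
#' @param n_draws posterior draws kept per sink (default 1000).
#' @param burn_in discarded initial sweeps (default 100).
#' @param seed integer seed.
#' @return A [SourceEstimate-class].
#' @export
estimateMixture <- function(model, sink, n_draws = 1000, burn_in = 100,
                            seed = 1L) {
  stopifnot(is(model, "SourceModel"))
  if (is(sink, "OtuTable")) sink_m <- otuCounts(sink)
  else {
    stopifnot(is.numeric(sink), !is.null(names(sink)))
    sink_m <- matrix(sink, ncol = 1, dimnames = list(names(sink), "sink"))
  }
  taxa <- union(colnames(model@profiles), rownames(sink_m))
  prof <- matrix(0, nrow(model@profiles), length(taxa),
                 dimnames = list(rownames(model@profiles), taxa))
  prof[, colnames(model@profiles)] <- model@profiles
  labels <- c(rownames(prof), "Unknown")
  alpha <- c(rep(model@alpha_source, nrow(prof)), model@alpha_unknown)
  props <- sds <- matrix(0, ncol(sink_m), length(labels),
                         dimnames = list(colnames(sink_m), labels))
  for (j in seq_len(ncol(sink_m))) {
    x <- integer(length(taxa))
    names(x) <- taxa
    x[rownames(sink_m)] <- as.integer(sink_m[, j])
    if (sum(x) == 0) stop("sink sample '", colnames(sink_m)[j],
                          "' is empty")
    sub <- .substreamSeed(seed, colnames(sink_m)[j])
    res <- withr::with_seed(sub,
      gibbs_sources_cpp(x, prof, alpha, model@beta,
                        as.integer(n_draws), as.integer(burn_in)))
    props[j, ] <- res$mean
    sds[j, ] <- res$sd
  }
  new("SourceEstimate", proportions = props, sds = sds,
      n_draws = as.integer(n_draws), burn_in = as.integer(burn_in),
      seed = as.integer(seed))
}
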