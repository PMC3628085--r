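#' @name accessors
#' @title Accessors for microShare data objects
#' @description Extract the pieces of the core containers without touching
#' slots directly.
#' @param object an [OtuTable-class], [DistanceMatrix-class] or
#'   [SampleMetadata-class] object.
#' @return \code{otuCounts}: the OTU x sample count matrix.
#'   \code{sampleIDs}/\code{otuIDs}: character vectors of ids.
#'   \code{otuTaxonomy}: named taxonomy strings (length 0 if absent).
#'   \code{metadataTable}: the metadata data.frame.
NULL

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(object) standardGeneric("otuCounts"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("otuIDs", function(object) standardGeneric("otuIDs"))
#' @rdname accessors
#' @export
setGeneric("otuTaxonomy", function(object) standardGeneric("otuTaxonomy"))
#' @rdname accessors
#' @export
setGeneric("metadataTable", function(object) standardGeneric("metadataTable"))

#' @rdname accessors
setMethod("otuCounts", "OtuTable", function(object) object@counts)
#' @rdname accessors
setMethod("sampleIDs", "OtuTable", function(object) colnames(object@counts))
#' @rdname accessors
setMethod("sampleIDs", "DistanceMatrix",
          function(object) rownames(object@values))
#' @rdname accessors
setMethod("sampleIDs", "SampleMetadata",
          function(object) object@data$sample_id)
#' @rdname accessors
setMethod("otuIDs", "OtuTable", function(object) rownames(object@counts))
#' @rdname accessors
setMethod("otuTaxonomy", "OtuTable", function(object) object@taxonomy)
#' @rdname accessors
setMethod("metadataTable", "SampleMetadata", function(object) object@data)

#' @export
setMethod("dim", "OtuTable", function(x) dim(x@counts))

#' Coerce a DistanceMatrix to a base matrix
#' @param x a [DistanceMatrix-class].
#' @param ... ignored.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

#' Subset an OtuTable by OTUs (i) and/or samples (j)
#' @param x an [OtuTable-class].
#' @param i,j OTU and sample indices (any form \code{[} accepts).
#' @param ... ignored.
#' @param drop ignored; dimensions are always kept.
#' @export
setMethod("[", "OtuTable", function(x, i, j, ..., drop = FALSE) {
  cnt <- x@counts[i, j, drop = FALSE]
  tax <- x@taxonomy
  if (length(tax)) tax <- tax[rownames(cnt)]
  new("OtuTable", counts = cnt, taxonomy = tax)
})

#' Subset a DistanceMatrix to a set of samples
#' @param x a [DistanceMatrix-class].
#' @param i sample indices.
#' @param j ignored (subsetting is symmetric).
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "DistanceMatrix", function(x, i, j, ..., drop = FALSE) {
  new("DistanceMatrix", values = x@values[i, i, drop = FALSE])
})

setMethod("show", "OtuTable", function(object) {
  cat("OtuTable:", nrow(object@counts), "phylotypes x",
      ncol(object@counts), "samples\n")
  cat("  total counts:", sum(object@counts),
      if (length(object@taxonomy)) "| taxonomy: present"
      else "| taxonomy: absent", "\n")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix:", nrow(object@values), "samples\n")
  if (nrow(object@values) > 1) {
    off <- object@values[upper.tri(object@values)]
    cat(sprintf("  distances: min %.4g / mean %.4g / max %.4g\n",
                min(off), mean(off), max(off)))
  }
})

setMethod("show", "SampleMetadata", function(object) {
  d <- object@data
  cat("SampleMetadata:", nrow(d), "samples,",
      length(unique(d$host_id)), "hosts,",
      length(unique(d$family_id)), "families\n")
  cat("  species:", paste(sprintf("%s=%d", names(table(d$species)),
                                  table(d$species)), collapse = ", "), "\n")
})

setMethod("show", "DyadTestResult", function(object) {
  cat(sprintf("Dyadic permutation test [%s | %s]\n",
              object@category, paste(object@site, collapse = "+")))
  cat(sprintf("  R = %.3f, p = %.4g (%d permutations)\n",
              object@R, object@p_value, object@n_permutations))
  cat(sprintf("  within:  n = %d, mean = %.4f [%.4f, %.4f]\n",
              object@n_within, object@mean_within,
              object@ci_within[1], object@ci_within[2]))
  cat(sprintf("  between: n = %d, mean = %.4f [%.4f, %.4f]\n",
              object@n_between, object@mean_between,
              object@ci_between[1], object@ci_between[2]))
  if (length(object@warnings))
    cat("  warning:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "PermanovaResult", function(object) {
  cat("One-way PERMANOVA\n")
  cat(sprintf("  pseudo-F = %.4f on df (%d, %d), p = %.4g (%d permutations)\n",
              object@pseudo_F, object@df_between, object@df_residual,
              object@p_value, object@n_permutations))
  cat(sprintf("  sqrt among-group variance component = %.4f\n",
              object@component_of_variation))
})

setMethod("show", "SourceModel", function(object) {
  cat("SourceModel:", nrow(object@profiles), "sources x",
      ncol(object@profiles), "taxa\n")
  cat("  sources:", paste(rownames(object@profiles), collapse = ", "), "\n")
})

setMethod("show", "SourceEstimate", function(object) {
  cat("SourceEstimate:", nrow(object@proportions), "sink sample(s)\n")
  print(round(object@proportions, 3))
})
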