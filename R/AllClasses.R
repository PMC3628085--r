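#' @import methods
#' @importFrom stats aov cmdscale coef lm na.omit p.adjust pf pnorm qnorm
#'   quantile rbinom rexp rgamma rlnorm rmultinom runif sd setNames var
#'   wilcox.test qt median model.matrix
#' @importFrom utils read.delim write.table head modifyList
#' @importFrom withr with_seed
#' @useDynLib microShare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_BODY_SITES <- c("fecal", "oral", "forehead", "palm_L", "palm_R",
                      "paw_BL", "paw_BR", "paw_FL", "paw_FR")
DOG_ONLY_SITES   <- c("paw_BL", "paw_BR", "paw_FL", "paw_FR")
HUMAN_ONLY_SITES <- c("palm_L", "palm_R")
VALID_ROLES      <- c("adult_M", "adult_F", "child", "infant", "senior", "dog")
VALID_SPECIES    <- c("human", "dog")

#' OtuTable: a phylotype-by-sample count matrix
#'
#' Container for a 16S phylotype (OTU) count table: a non-negative integer
#' matrix with OTUs as rows and samples as columns, plus an optional
#' seven-rank greengenes-style taxonomy string per OTU
#' (\code{"k__...; p__...; ...; s__..."}).
#'
#' @slot counts numeric matrix (integral values, \eqn{\ge 0}), OTUs x samples,
#'   with unique dimnames.
#' @slot taxonomy named character vector of taxonomy strings keyed by OTU id;
#'   length zero when no taxonomy is attached.
#' @export
setClass("OtuTable",
         representation(counts = "matrix", taxonomy = "character"))

setValidity("OtuTable", function(object) {
  cnt <- object@counts
  msgs <- character()
  if ((nrow(cnt) > 0 && is.null(rownames(cnt))) ||
      (ncol(cnt) > 0 && is.null(colnames(cnt))))
    msgs <- c(msgs, "counts must have OTU rownames and sample colnames")
  else {
    if (anyDuplicated(rownames(cnt))) msgs <- c(msgs, "duplicate OTU ids")
    if (anyDuplicated(colnames(cnt))) msgs <- c(msgs, "duplicate sample ids")
  }
  if (length(cnt) && (any(!is.finite(cnt)) || any(cnt < 0)))
    msgs <- c(msgs, "counts must be finite and >= 0")
  if (length(cnt) && any(cnt != round(cnt)))
    msgs <- c(msgs, "counts must be whole numbers")
  if (length(object@taxonomy)) {
    if (is.null(names(object@taxonomy)) ||
        !all(names(object@taxonomy) %in% rownames(cnt)) ||
        length(object@taxonomy) != nrow(cnt))
      msgs <- c(msgs, "taxonomy must be named by, and cover, the OTU ids")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OtuTable
#'
#' @param counts OTU x sample matrix of non-negative integer counts with
#'   dimnames.
#' @param taxonomy optional character vector of taxonomy strings, one per
#'   OTU (recycled names from \code{rownames(counts)} if unnamed).
#' @return An [OtuTable-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 0L, 7L), 2, 2,
#'             dimnames = list(c("OTU_1", "OTU_2"), c("S1", "S2")))
#' otuTable(m)
#' @export
otuTable <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(taxonomy)) taxonomy <- character()
  else {
    taxonomy <- as.character(taxonomy)
    names(taxonomy) <- rownames(counts)
  }
  new("OtuTable", counts = counts, taxonomy = taxonomy)
}

#' DistanceMatrix: labeled pairwise community dissimilarities
#'
#' A symmetric, zero-diagonal, non-negative square matrix of pairwise
#' sample dissimilarities, carrying explicit sample ids.
#'
#' @slot values numeric square matrix with identical row/col names.
#' @export
setClass("DistanceMatrix", representation(values = "matrix"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msgs <- c(msgs, "row and column sample ids must be present and identical")
  else if (anyDuplicated(rownames(v)))
    msgs <- c(msgs, "duplicate sample ids")
  if (length(v)) {
    if (any(!is.finite(v)) || any(v < 0))
      msgs <- c(msgs, "distances must be finite and >= 0")
    if (max(abs(v - t(v))) > 1e-8)
      msgs <- c(msgs, "matrix asymmetric beyond 1e-8")
    if (any(abs(diag(v)) > 1e-12))
      msgs <- c(msgs, "diagonal must be zero")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DistanceMatrix
#'
#' Small asymmetries (below 1e-8) are symmetrized by averaging.
#'
#' @param values square numeric matrix with matching dimnames.
#' @return A [DistanceMatrix-class] object.
#' @export
distanceMatrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) == ncol(values) && length(values) &&
      max(abs(values - t(values))) <= 1e-8) {
    values <- (values + t(values)) / 2
    diag(values) <- 0
  }
  new("DistanceMatrix", values = values)
}

#' SampleMetadata: per-sample host and household attributes
#'
#' Wraps the mapping-file data.frame (one row per sample) that drives every
#' grouping in the analysis: host and family ids, body site, host species,
#' household role, age in years, pet-ownership flags, and family size.
#'
#' @slot data data.frame with columns \code{sample_id}, \code{host_id},
#'   \code{family_id}, \code{body_site}, \code{species}, \code{role},
#'   \code{age}, \code{has_dog}, \code{has_cat}, \code{family_size}.
#' @export
setClass("SampleMetadata", representation(data = "data.frame"))

METADATA_COLUMNS <- c("sample_id", "host_id", "family_id", "body_site",
                      "species", "role", "age", "has_dog", "has_cat",
                      "family_size")

setValidity("SampleMetadata", function(object) {
  d <- object@data
  msgs <- character()
  missing_cols <- setdiff(METADATA_COLUMNS, names(d))
  if (length(missing_cols))
    return(paste("missing metadata columns:",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(d$sample_id)) msgs <- c(msgs, "duplicate sample ids")
  bad_site <- setdiff(unique(d$body_site), VALID_BODY_SITES)
  if (length(bad_site))
    msgs <- c(msgs, paste("unknown body_site:", paste(bad_site, collapse = ", ")))
  bad_role <- setdiff(unique(d$role), VALID_ROLES)
  if (length(bad_role))
    msgs <- c(msgs, paste("unknown role:", paste(bad_role, collapse = ", ")))
  bad_sp <- setdiff(unique(d$species), VALID_SPECIES)
  if (length(bad_sp))
    msgs <- c(msgs, paste("unknown species:", paste(bad_sp, collapse = ", ")))
  if (!length(msgs)) {
    if (any(d$species != "dog" & d$body_site %in% DOG_ONLY_SITES))
      msgs <- c(msgs, "paw sites are valid only for dogs")
    if (any(d$species != "human" & d$body_site %in% HUMAN_ONLY_SITES))
      msgs <- c(msgs, "palm sites are valid only for humans")
    if (any(!is.finite(d$age) | d$age < 0))
      msgs <- c(msgs, "age must be a non-negative number of years")
    # role/age-bin consistency: infant 0-1, child 1-17, adult 18-59, senior >=60
    hum <- d$species == "human"
    ok <- rep(TRUE, nrow(d))
    ok[hum & d$role == "infant"]  <- d$age[hum & d$role == "infant"] < 1
    ok[hum & d$role == "child"]   <- d$age[hum & d$role == "child"] >= 1 &
                                     d$age[hum & d$role == "child"] < 18
    adl <- hum & d$role %in% c("adult_M", "adult_F")
    ok[adl] <- d$age[adl] >= 18 & d$age[adl] < 60
    ok[hum & d$role == "senior"] <- d$age[hum & d$role == "senior"] >= 60
    if (any(hum & d$role == "dog") || any(!hum & d$role != "dog"))
      msgs <- c(msgs, "role 'dog' must match species 'dog'")
    if (!all(ok))
      msgs <- c(msgs, paste("role inconsistent with age for sample(s):",
                            paste(head(d$sample_id[!ok], 3), collapse = ", ")))
    if (any(d$family_size < 1))
      msgs <- c(msgs, "family_size must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct SampleMetadata from a data.frame
#'
#' @param data data.frame with the columns listed under
#'   [SampleMetadata-class].
#' @return A validated [SampleMetadata-class] object.
#' @export
sampleMetadata <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  rownames(data) <- NULL
  new("SampleMetadata", data = data)
}

#' DyadTestResult: one dyad category's permutation test
#'
#' @slot category dyad category name (e.g. "spouses").
#' @slot site body site(s) the distances came from.
#' @slot R observed rank statistic in [-1, 1].
#' @slot p_value one-sided permutation p (add-one estimator).
#' @slot n_within,n_between pair counts.
#' @slot mean_within,mean_between mean distances.
#' @slot ci_within,ci_between 95% confidence intervals (length-2 numeric).
#' @slot n_permutations number of label permutations drawn.
#' @slot warnings character vector of diagnostics (e.g. few distinct
#'   permutations).
#' @export
setClass("DyadTestResult",
         representation(category = "character", site = "character",
                        R = "numeric", p_value = "numeric",
                        n_within = "integer", n_between = "integer",
                        mean_within = "numeric", mean_between = "numeric",
                        ci_within = "numeric", ci_between = "numeric",
                        n_permutations = "integer", warnings = "character"))

setValidity("DyadTestResult", function(object) {
  msgs <- character()
  if (abs(object@R) > 1 + 1e-12) msgs <- c(msgs, "R must lie in [-1, 1]")
  if (object@p_value < 1 / (object@n_permutations + 1) - 1e-12 ||
      object@p_value > 1)
    msgs <- c(msgs, "p must lie in [1/(n_perm+1), 1]")
  if (length(msgs)) msgs else TRUE
})

#' PermanovaResult: one-way PERMANOVA on a distance matrix
#'
#' @slot pseudo_F F-like ratio of among- to within-group mean squared
#'   distances (Inf flagged when within-group SS is zero).
#' @slot df_between,df_residual degrees of freedom (a-1, N-a).
#' @slot p_value permutation p-value.
#' @slot component_of_variation estimate of the among-group variance
#'   component (sqrt scale as reported in PERMANOVA tables).
#' @slot n_permutations number of permutations.
#' @export
setClass("PermanovaResult",
         representation(pseudo_F = "numeric", df_between = "integer",
                        df_residual = "integer", p_value = "numeric",
                        component_of_variation = "numeric",
                        n_permutations = "integer"))

#' SourceModel: trained source profiles for source attribution
#'
#' @slot profiles source x taxon matrix of pooled training counts.
#' @slot alpha_source per-taxon smoothing pseudocount for known sources.
#' @slot alpha_unknown per-taxon pseudocount for the implicit unknown source.
#' @slot beta prior pseudocount on source assignment proportions.
#' @export
setClass("SourceModel",
         representation(profiles = "matrix", alpha_source = "numeric",
                        alpha_unknown = "numeric", beta = "numeric"))

setValidity("SourceModel", function(object) {
  msgs <- character()
  if (nrow(object@profiles) < 1) msgs <- c(msgs, "need at least one source")
  if (any(object@profiles < 0)) msgs <- c(msgs, "profiles must be >= 0")
  if (object@alpha_source <= 0 || object@alpha_unknown <= 0 ||
      object@beta <= 0)
    msgs <- c(msgs, "alpha_source, alpha_unknown and beta must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' SourceEstimate: posterior mixing proportions for sink samples
#'
#' @slot proportions sink x (sources + "Unknown") matrix of posterior mean
#'   mixing proportions; rows sum to 1.
#' @slot sds matching matrix of posterior standard deviations.
#' @slot n_draws,burn_in Gibbs sampler settings.
#' @slot seed RNG seed used.
#' @export
setClass("SourceEstimate",
         representation(proportions = "matrix", sds = "matrix",
                        n_draws = "integer", burn_in = "integer",
                        seed = "integer"))

setValidity("SourceEstimate", function(object) {
  p <- object@proportions
  if (length(p) && (any(p < -1e-9) ||
                    any(abs(rowSums(p) - 1) > 1e-9)))
    "proportions must be a simplex per sink" else TRUE
})
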