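# Readers/writers for the classic tab-separated OTU table, BIOM-JSON,
# newick trees, QIIME-style mapping files, and labeled square distance
# matrices. All readers validate against the container invariants.

#' Read an OTU table
#'
#' Reads a phylotype count table in either the classic tab-separated
#' dialect (optional leading comment line; header line beginning
#' \code{"#OTU ID"}; optional trailing \code{"taxonomy"} or
#' \code{"Consensus Lineage"} column) or BIOM-JSON (format 1.0, via the
#' \pkg{biomformat} package). Orientation is normalized to OTUs x samples.
#'
#' @param path path to the file.
#' @param format \code{"classic_tsv"} or \code{"biom_json"}.
#' @return An [OtuTable-class].
#' @export
readOtuTable <- function(path, format = c("classic_tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "classic_tsv") .readClassicOtu(path) else .readBiomJson(path)
}

.readClassicOtu <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty OTU table file: ", path)
  hdr_idx <- which(startsWith(lines, "#OTU ID"))[1]
  if (is.na(hdr_idx)) {
    # tolerate a file whose first non-comment line is the header sans '#'
    stop("malformed OTU table: no '#OTU ID' header line in ", path)
  }
  header <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  if (length(header) < 1) stop("malformed header line ", hdr_idx)
  tax_col <- length(header) > 1 &&
    tolower(header[length(header)]) %in% c("taxonomy", "consensus lineage")
  sample_ids <- header[-1]
  if (tax_col) sample_ids <- sample_ids[-length(sample_ids)]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in header: ",
         sample_ids[duplicated(sample_ids)][1])
  body <- lines[-seq_len(hdr_idx)]
  n_otu <- length(body)
  counts <- matrix(0, n_otu, length(sample_ids))
  otu_ids <- character(n_otu)
  taxonomy <- if (tax_col) character(n_otu) else NULL
  for (k in seq_along(body)) {
    fields <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    expected <- 1 + length(sample_ids) + as.integer(tax_col)
    if (length(fields) != expected)
      stop(sprintf("line %d: expected %d fields, found %d",
                   hdr_idx + k, expected, length(fields)))
    otu_ids[k] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[2:(1 + length(sample_ids))]))
    bad <- which(!is.finite(vals) | vals < 0 | vals != round(vals))
    if (length(bad))
      stop(sprintf("line %d, field %d ('%s'): counts must be non-negative integers",
                   hdr_idx + k, 1 + bad[1], fields[1 + bad[1]]))
    counts[k, ] <- vals
    if (tax_col) taxonomy[k] <- fields[length(fields)]
  }
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id: ", otu_ids[duplicated(otu_ids)][1])
  dimnames(counts) <- list(otu_ids, sample_ids)
  otuTable(counts, taxonomy)
}

.readBiomJson <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the 'biomformat' package is required for BIOM-JSON input")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")   # observations x samples
  if (any(m < 0) || any(m != round(m)))
    stop("BIOM table contains non-integer or negative counts")
  om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  taxonomy <- NULL
  if (!is.null(om)) {
    if (is.data.frame(om) && nrow(om) == nrow(m)) {
      taxonomy <- apply(om, 1, function(r)
        paste(r[!is.na(r) & nzchar(r)], collapse = "; "))
    } else if (is.list(om) && length(om) == nrow(m)) {
      taxonomy <- vapply(om, function(r)
        paste(unlist(r), collapse = "; "), character(1))
    }
    if (!is.null(taxonomy) && !any(nzchar(taxonomy))) taxonomy <- NULL
  }
  otuTable(m, taxonomy)
}

#' Write an OTU table
#'
#' Inverse of [readOtuTable()]: \code{readOtuTable(writeOtuTable(t))}
#' reproduces counts, ids and taxonomy exactly. Classic output is
#' deterministic (byte-identical across writes).
#'
#' @param table an [OtuTable-class].
#' @param path output path.
#' @param format \code{"classic_tsv"} or \code{"biom_json"}.
#' @return \code{path}, invisibly.
#' @export
writeOtuTable <- function(table, path,
                          format = c("classic_tsv", "biom_json")) {
  format <- match.arg(format)
  stopifnot(is(table, "OtuTable"))
  validObject(table)
  if (format == "classic_tsv") {
    cnt <- otuCounts(table)
    tax <- otuTaxonomy(table)
    has_tax <- length(tax) > 0
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("# Constructed from biom file", con)
    writeLines(paste(c("#OTU ID", colnames(cnt),
                       if (has_tax) "taxonomy"), collapse = "\t"), con)
    if (nrow(cnt)) {
      body <- vapply(seq_len(nrow(cnt)), function(i) {
        paste(c(rownames(cnt)[i], format(cnt[i, ], scientific = FALSE,
                                         trim = TRUE),
                if (has_tax) tax[rownames(cnt)[i]]), collapse = "\t")
      }, character(1))
      writeLines(body, con)
    }
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the 'biomformat' package is required for BIOM-JSON output")
    tax <- otuTaxonomy(table)
    om <- NULL
    if (length(tax)) {
      om <- data.frame(taxonomy = unname(tax[otuIDs(table)]),
                       row.names = otuIDs(table),
                       stringsAsFactors = FALSE)
    }
    b <- biomformat::make_biom(otuCounts(table), observation_metadata = om)
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read a rooted newick tree
#'
#' Uses \pkg{ape}. Missing branch lengths default to 0 with a warning;
#' duplicate tip labels and unparseable strings are errors.
#'
#' @param path newick file.
#' @return An \pkg{ape} \code{phylo} object.
#' @export
readTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop("newick parse error in ", path, ": ", conditionMessage(e)),
    warning = function(w)
      stop("newick parse error in ", path, ": ", conditionMessage(w)))
  if (is.null(tr)) stop("newick parse error in ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip name: ", tr$tip.label[duplicated(tr$tip.label)][1])
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (any(is.na(tr$edge.length))) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  tr
}

#' Write a tree in newick format
#' @param tree an \pkg{ape} \code{phylo}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

.parseFlag <- function(x, column) {
  x_low <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x_low %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x_low %in% c("false", "f", "no", "n", "0")] <- FALSE
  if (any(is.na(out)))
    stop("column '", column, "': unrecognized boolean value '",
         x[is.na(out)][1], "'")
  out
}

#' Read a per-sample mapping file
#'
#' Tab-separated metadata whose first header field is \code{"#SampleID"}.
#' Ages are years (fractions allowed, e.g. 0.5 for a six-month-old).
#'
#' @param path mapping file.
#' @return A [SampleMetadata-class].
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#SampleID"))
    stop("mapping file must start with a '#SampleID' header: ", path)
  d <- read.delim(path, header = TRUE, sep = "\t", comment.char = "",
                  check.names = FALSE, stringsAsFactors = FALSE)
  names(d)[1] <- "sample_id"
  missing_cols <- setdiff(setdiff(METADATA_COLUMNS, "sample_id"), names(d))
  if (length(missing_cols))
    stop("mapping file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  d$age <- suppressWarnings(as.numeric(d$age))
  if (any(is.na(d$age))) stop("column 'age': non-numeric value")
  d$has_dog <- .parseFlag(d$has_dog, "has_dog")
  d$has_cat <- .parseFlag(d$has_cat, "has_cat")
  d$family_size <- as.integer(d$family_size)
  sampleMetadata(d[, c(METADATA_COLUMNS,
                       setdiff(names(d), METADATA_COLUMNS))])
}

#' Write a mapping file
#' @param metadata a [SampleMetadata-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMetadata <- function(metadata, path) {
  stopifnot(is(metadata, "SampleMetadata"))
  d <- metadataTable(metadata)
  names(d)[1] <- "#SampleID"
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(d), collapse = "\t"), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a labeled square distance matrix
#'
#' Tab-separated, sample ids in the first row and first column. Asymmetry
#' beyond 1e-8 is an error; smaller asymmetry is averaged away.
#'
#' @param path file path.
#' @return A [DistanceMatrix-class].
#' @export
readDistanceMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                  check.names = FALSE, comment.char = "")
  m <- as.matrix(d)
  if (nrow(m) != ncol(m))
    stop("distance matrix is not square: ", nrow(m), " x ", ncol(m))
  if (!identical(rownames(m), colnames(m)))
    stop("row and column sample ids disagree")
  if (length(m) && max(abs(m - t(m))) > 1e-8)
    stop("distance matrix asymmetric beyond 1e-8")
  distanceMatrix(m)
}

#' Write a labeled square distance matrix
#'
#' Full double precision is kept so read/write round-trips are exact to
#' better than 1e-12.
#'
#' @param dm a [DistanceMatrix-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMatrix <- function(dm, path) {
  stopifnot(is(dm, "DistanceMatrix"))
  m <- as.matrix(dm)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

GG_RANKS <- c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
              family = "f__", genus = "g__", species = "s__")

#' Extract one rank from greengenes-style taxonomy strings
#'
#' @param taxonomy character vector of semicolon-delimited strings with
#'   \code{k__}/\code{p__}/... prefixes.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return character vector; \code{"unclassified"} where the rank is missing
#'   or empty.
#' @examples
#' tax <- "k__Bacteria; p__Firmicutes; c__Bacilli; f__Streptococcaceae; g__; s__"
#' taxonomyRank(tax, "family")
#' @export
taxonomyRank <- function(taxonomy, rank = "family") {
  rank <- match.arg(rank, names(GG_RANKS))
  prefix <- GG_RANKS[[rank]]
  out <- vapply(strsplit(taxonomy, ";", fixed = TRUE), function(tokens) {
    tokens <- trimws(tokens)
    hit <- tokens[startsWith(tokens, prefix)]
    if (!length(hit)) return("unclassified")
    val <- sub(prefix, "", hit[1], fixed = TRUE)
    if (!nzchar(val)) "unclassified" else val
  }, character(1))
  unname(out)
}
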