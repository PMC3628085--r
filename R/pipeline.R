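# End-to-end orchestration: simulate (or load) -> depth filter -> rarefy ->
# per-site distance matrices -> dyadic tests / PERMANOVA / sharing /
# source attribution / age trajectory -> tab-separated report tables plus
# a run log. Every stage's artifact is materialized so any stage can be
# re-run or inspected on its own.

.pipelineDefaults <- function() {
  list(seed = NULL,
       simulate = TRUE,
       simulate_only = FALSE,
       otu_table = NULL, tree = NULL, map = NULL,   # inputs when simulate=FALSE
       n_families_children = 17, n_families_dogs = 17,
       n_families_both = 8, n_families_neither = 18,
       n_taxa = 500,
       depth_meanlog = log(20000), depth_sdlog = 0.6,
       w_sp = 0.35, w_pc = 0.2, w_dog = 0.15,
       min_depth = 5000, rarefy_depth = 5000,
       metric = "unweighted", normalized = FALSE,
       sites = c("forehead", "fecal"),
       categories = c("spouses", "families"),
       n_perm = 10000, permanova_perm = 999,
       source_sink_site = "palm_R",
       source_sites = c(oral = "oral", fecal = "fecal"),
       source_draws = 1000, source_burn_in = 100,
       age_site = "fecal")
}

.readKeyValueConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    if (!any(is.na(num))) vals <- num
    else if (all(tolower(vals) %in% c("true", "false")))
      vals <- tolower(vals) == "true"
    out[[key]] <- vals
  }
  out
}

.writeTable <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.outPath <- function(out_dir, name, force) {
  p <- file.path(out_dir, name)
  if (file.exists(p) && !force)
    stop("output exists (use force = TRUE to overwrite): ", p)
  p
}

#' Run the full household-sharing pipeline
#'
#' Simulates a dataset (or loads one), filters and rarefies, computes
#' per-site UniFrac distance matrices, runs the dyadic permutation tests
#' and a per-site one-way PERMANOVA on family membership, the
#' shared-phylotype breakdown for couples, source attribution of a skin
#' sink from oral/fecal sources, and the age-trajectory regression. All
#' results are written to \code{out_dir} as tab-separated tables; a run
#' log records parameters and seeds. Deterministic given the seed.
#'
#' @param out_dir output directory (created if needed).
#' @param config named list of overrides, or the path of a flat
#'   \code{key=value} config file. \code{seed} is mandatory. See the
#'   package vignette for the full key list.
#' @param force overwrite existing outputs.
#' @return Invisibly, a list with the in-memory results.
#' @export
runPipeline <- function(out_dir, config = list(), force = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- .readKeyValueConfig(config)
  cfg <- modifyList(.pipelineDefaults(), config)
  if (is.null(cfg$seed))
    stop("config must set 'seed': stochastic stages refuse to run unseeded")
  seed <- as.integer(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("microShare %s",
                         as.character(utils::packageVersion("microShare"))),
                 sprintf("started %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 vapply(names(cfg), function(k)
                   sprintf("%s = %s", k, paste(cfg[[k]], collapse = ",")),
                   character(1)))

  if (isTRUE(cfg$simulate)) {
    sim_cfg <- simulationConfig(
      n_families_by_type = c(children = cfg$n_families_children,
                             dogs = cfg$n_families_dogs,
                             both = cfg$n_families_both,
                             neither = cfg$n_families_neither),
      n_taxa = cfg$n_taxa, depth_meanlog = cfg$depth_meanlog,
      depth_sdlog = cfg$depth_sdlog, w_sp = cfg$w_sp, w_pc = cfg$w_pc,
      w_dog = cfg$w_dog, seed = seed)
    ds <- simulateDataset(sim_cfg)
    writeOtuTable(ds$table, .outPath(out_dir, "otu_table.tsv", force))
    writeTree(ds$tree, .outPath(out_dir, "tree.nwk", force))
    writeMetadata(ds$metadata, .outPath(out_dir, "map.tsv", force))
    if (isTRUE(cfg$simulate_only)) {
      writeLines(log_lines, .outPath(out_dir, "run_log.txt", force))
      return(invisible(ds))
    }
  } else {
    if (is.null(cfg$otu_table) || is.null(cfg$tree) || is.null(cfg$map))
      stop("simulate = FALSE requires otu_table, tree and map paths")
    ds <- list(table = readOtuTable(cfg$otu_table),
               tree = readTree(cfg$tree),
               metadata = readMetadata(cfg$map))
  }

  filtered <- filterByDepth(ds$table, cfg$min_depth)
  rarefied <- rarefyCounts(filtered, cfg$rarefy_depth, seed)
  writeOtuTable(rarefied, .outPath(out_dir, "rarefied.tsv", force))

  md <- metadataTable(ds$metadata)
  dms <- list()
  for (site in cfg$sites) {
    ids <- md$sample_id[md$body_site == site]
    ids <- intersect(ids, sampleIDs(rarefied))
    dm <- unifracDistance(rarefied[, ids], ds$tree, metric = cfg$metric,
                          normalized = isTRUE(cfg$normalized))
    dms[[site]] <- dm
    writeDistanceMatrix(dm, .outPath(out_dir,
                                     paste0("dist_", site, ".tsv"), force))
  }

  dyad_rows <- list()
  for (cat in cfg$categories) for (site in cfg$sites) {
    res <- tryCatch(
      dyadPermutationTest(dms[[site]], ds$metadata, cat, site,
                          n_perm = cfg$n_perm, seed = seed),
      error = function(e) {
        stop("stage dyad-test failed for ", cat, " / ", site, ": ",
             conditionMessage(e))
      })
    dyad_rows[[paste(cat, site)]] <- data.frame(
      category = cat, site = site, R = res@R, p_value = res@p_value,
      n_within = res@n_within, n_between = res@n_between,
      mean_within = res@mean_within, mean_between = res@mean_between,
      n_permutations = res@n_permutations)
  }
  dyads <- do.call(rbind, dyad_rows)
  .writeTable(dyads, .outPath(out_dir, "dyad_tests.tsv", force))

  perm_rows <- lapply(cfg$sites, function(site) {
    ids <- sampleIDs(dms[[site]])
    fam <- setNames(md$family_id[match(ids, md$sample_id)], ids)
    res <- permanovaOneway(dms[[site]], fam, n_perm = cfg$permanova_perm,
                           seed = seed)
    data.frame(site = site, pseudo_F = res@pseudo_F,
               df_between = res@df_between, df_residual = res@df_residual,
               p_value = res@p_value,
               component_of_variation = res@component_of_variation)
  })
  permanova <- do.call(rbind, perm_rows)
  .writeTable(permanova, .outPath(out_dir, "permanova.tsv", force))

  sharing <- tryCatch({
    dy <- buildDyads(ds$metadata, "spouses", cfg$sites[1])
    keep <- dy$pairs$s1 %in% sampleIDs(rarefied) &
            dy$pairs$s2 %in% sampleIDs(rarefied)
    sh <- sharedByTaxonFamily(rarefied, dy$pairs[keep, , drop = FALSE])
    .writeTable(sh$by_family,
                .outPath(out_dir, paste0("shared_", cfg$sites[1], ".tsv"),
                         force))
    sh
  }, error = function(e) {
    warning("stage shared skipped: ", conditionMessage(e)); NULL
  })

  sinks_md <- md[md$body_site == cfg$source_sink_site &
                 md$species == "human" &
                 md$sample_id %in% sampleIDs(rarefied), , drop = FALSE]
  source_est <- NULL
  if (nrow(sinks_md)) {
    est_rows <- lapply(seq_len(nrow(sinks_md)), function(k) {
      model <- fitSources(rarefied, ds$metadata, as.list(cfg$source_sites),
                          exclude_families = sinks_md$family_id[k])
      est <- estimateMixture(model,
                             rarefied[, sinks_md$sample_id[k]],
                             n_draws = cfg$source_draws,
                             burn_in = cfg$source_burn_in, seed = seed)
      cbind(data.frame(sample_id = sinks_md$sample_id[k]),
            as.data.frame(est@proportions))
    })
    source_est <- do.call(rbind, est_rows)
    .writeTable(source_est, .outPath(out_dir, "source_estimates.tsv", force))
  }

  age <- tryCatch(
    ageTrajectory(dms[[cfg$age_site]], ds$metadata, cfg$age_site),
    error = function(e) {
      warning("stage age-traj skipped: ", conditionMessage(e)); NULL
    })
  if (!is.null(age)) {
    .writeTable(age$points, .outPath(out_dir, "age_trajectory.tsv", force))
    log_lines <- c(log_lines,
                   sprintf("age_trajectory: slope=%.6g r2=%.4f",
                           age$slope, age$r_squared))
  }

  writeLines(log_lines, .outPath(out_dir, "run_log.txt", force))
  invisible(list(table = rarefied, metadata = ds$metadata, tree = ds$tree,
                 distances = dms, dyad_tests = dyads, permanova = permanova,
                 sharing = sharing, source_estimates = source_est,
                 age_trajectory = age))
}
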