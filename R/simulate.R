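# Hierarchical Dirichlet-multinomial simulator of household-structured
# microbiota: per-site baselines, per-family profiles, couple sharing,
# age-dependent infant signatures, and a dog-contact effect on the skin
# of dog-owning humans. The generator exists so every downstream stage
# (distances, dyadic tests, sharing, attribution) can be validated against
# known ground truth.

# 25 taxon families used for simulated taxonomy (greengenes-style lineages)
SIM_TAXON_FAMILIES <- data.frame(
  family = c("Propionibacteriaceae", "Corynebacteriaceae", "Micrococcaceae",
             "Streptococcaceae", "Staphylococcaceae", "Carnobacteriaceae",
             "Lactobacillaceae", "Lachnospiraceae", "Ruminococcaceae",
             "Veillonellaceae", "Clostridiaceae", "Prevotellaceae",
             "Porphyromonadaceae", "Bacteroidaceae", "Flavobacteriaceae",
             "Neisseriaceae", "Comamonadaceae", "Methylophilaceae",
             "Pasteurellaceae", "Moraxellaceae", "Enterobacteriaceae",
             "Pseudomonadaceae", "Sphingomonadaceae", "Hyphomicrobiaceae",
             "Fusobacteriaceae"),
  phylum = c(rep("Actinobacteria", 3), rep("Firmicutes", 8),
             rep("Bacteroidetes", 4), rep("Proteobacteria", 9),
             "Fusobacteria"),
  stringsAsFactors = FALSE)

SKIN_FAMILIES <- c("Propionibacteriaceae", "Streptococcaceae",
                   "Staphylococcaceae")
ORAL_FAMILIES <- c("Streptococcaceae", "Veillonellaceae", "Neisseriaceae",
                   "Pasteurellaceae", "Prevotellaceae")
GUT_FAMILIES  <- c("Bacteroidaceae", "Lachnospiraceae", "Ruminococcaceae",
                   "Prevotellaceae", "Porphyromonadaceae")
HUMAN_SITES <- c("fecal", "oral", "forehead", "palm_L", "palm_R")
DOG_SITES   <- c("fecal", "oral", "forehead", "paw_BL", "paw_BR",
                 "paw_FL", "paw_FR")
HUMAN_SKIN_SITES <- c("forehead", "palm_L", "palm_R")

#' Simulation configuration
#'
#' Parameters of the household-microbiota generator. Defaults mirror the
#' surveyed cohort design: 17 families with children, 17 with dogs, 8 with
#' both, 18 with neither (60 households), five body sites per human and
#' seven per dog.
#'
#' @param n_families_by_type named integer vector
#'   \code{c(children=, dogs=, both=, neither=)}.
#' @param n_taxa number of phylotypes on the simulated tree.
#' @param n_taxon_families number of taxonomy family labels (max 25).
#' @param depth_meanlog,depth_sdlog lognormal read-depth distribution
#'   (truncated to >= 1); defaults give a mean depth near 20,000 reads.
#' @param kappa_site Dirichlet concentration of per-site baselines.
#' @param kappa_family concentration of family profiles around the site
#'   baseline; \code{Inf} disables the family effect.
#' @param kappa_individual concentration of individual profiles around
#'   their mixture target; \code{Inf} disables individual noise.
#' @param w_sp spouse-sharing mixture weight in [0, 1].
#' @param w_pc parent-child (contact) mixture weight in [0, 1].
#' @param w_dog dog-to-human-skin mixture weight in [0, 1]; applied only to
#'   skin sites of humans in dog-owning households and only through taxa
#'   rare on human skin.
#' @param age_tau e-folding age (years) of the infant community signature.
#' @param seed integer RNG seed.
#' @return A list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(n_families_by_type = c(children = 17, dogs = 17,
                                                    both = 8, neither = 18),
                             n_taxa = 500, n_taxon_families = 25,
                             depth_meanlog = log(20000), depth_sdlog = 0.6,
                             kappa_site = 50, kappa_family = 30,
                             kappa_individual = 200,
                             w_sp = 0.35, w_pc = 0.2, w_dog = 0.15,
                             age_tau = 1.5, seed = 1L) {
  cfg <- list(n_families_by_type = n_families_by_type, n_taxa = n_taxa,
              n_taxon_families = n_taxon_families,
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              kappa_site = kappa_site, kappa_family = kappa_family,
              kappa_individual = kappa_individual,
              w_sp = w_sp, w_pc = w_pc, w_dog = w_dog,
              age_tau = age_tau, seed = as.integer(seed))
  stopifnot(all(c("children", "dogs", "both", "neither") %in%
                names(cfg$n_families_by_type)),
            all(cfg$n_families_by_type >= 0),
            cfg$n_taxa >= 2,
            cfg$n_taxon_families >= 1,
            cfg$n_taxon_families <= nrow(SIM_TAXON_FAMILIES),
            cfg$kappa_site > 0, cfg$kappa_family > 0,
            cfg$kappa_individual > 0,
            cfg$w_sp >= 0, cfg$w_sp <= 1, cfg$w_pc >= 0, cfg$w_pc <= 1,
            cfg$w_dog >= 0, cfg$w_dog <= 1, cfg$age_tau > 0)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' A no-structure configuration for calibration studies
#'
#' Couples-only households with every sharing effect switched off
#' (\code{w_sp = w_pc = w_dog = 0}, \code{kappa_family = Inf}), so all
#' same-site samples are exchangeable and any dyadic test should reject at
#' its nominal rate. Sized small (few families, few taxa, shallow depth)
#' because calibration repeats the full pipeline many times.
#'
#' @param n_families number of (childless, dogless) households.
#' @param n_taxa,depth_meanlog,seed passed to [simulationConfig()].
#' @param ... further overrides.
#' @return A \code{SimulationConfig}.
#' @export
nullSimulationConfig <- function(n_families = 8, n_taxa = 40,
                                 depth_meanlog = log(400), seed = 1L, ...) {
  simulationConfig(n_families_by_type = c(children = 0, dogs = 0, both = 0,
                                          neither = n_families),
                   n_taxa = n_taxa, depth_meanlog = depth_meanlog,
                   depth_sdlog = 0.3, kappa_family = Inf,
                   w_sp = 0, w_pc = 0, w_dog = 0, seed = seed, ...)
}

#' Simulate a rooted phylotype tree
#'
#' Builds a rooted bifurcating tree over \code{OTU_1..OTU_n} by iterative
#' random pair-joining with i.i.d. Exponential(mean 0.1) branch lengths,
#' and assigns tips round-robin to \code{n_taxon_families} greengenes-style
#' taxonomy strings (stored in \code{$tip.taxonomy}).
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @param n_taxon_families number of family labels.
#' @return An \pkg{ape} \code{phylo} with a \code{tip.taxonomy} element.
#' @export
simulateTree <- function(n_taxa, seed, n_taxon_families = 25) {
  stopifnot(n_taxa >= 2)
  withr::with_seed(as.integer(seed), {
    labels <- paste0("OTU_", seq_len(n_taxa))
    nodes <- labels
    while (length(nodes) > 1) {
      pick <- sample.int(length(nodes), 2)
      len <- rexp(2, rate = 10)   # mean 0.1
      joined <- sprintf("(%s:%.10f,%s:%.10f)",
                        nodes[pick[1]], len[1], nodes[pick[2]], len[2])
      nodes <- c(nodes[-pick], joined)
    }
    tr <- ape::read.tree(text = paste0(nodes, ";"))
    fams <- SIM_TAXON_FAMILIES[seq_len(n_taxon_families), , drop = FALSE]
    k <- rep(seq_len(n_taxon_families), length.out = n_taxa)
    tr$tip.taxonomy <- setNames(
      sprintf("k__Bacteria; p__%s; c__; o__; f__%s; g__; s__",
              fams$phylum[k], fams$family[k]), labels)[tr$tip.label]
    tr
  })
}

#' Simulate household rosters and sample metadata
#'
#' Every household has two cohabiting adults (one \code{adult_M}, one
#' \code{adult_F}); child-type households add 1-3 children with ages
#' Uniform(0.5, 18) years (role \code{infant} below age 1); dog-type
#' households add 1-2 dogs. Offspring ages follow the surveyed cohort's
#' skew: about a third are infants (0.5-1 y), most of the rest are 1-6 y,
#' with a small 12-18 y tail. Humans contribute five samples (fecal, oral,
#' forehead, both palms), dogs seven (fecal, oral, forehead, four paws).
#'
#' @param config a [simulationConfig()].
#' @return A [SampleMetadata-class].
#' @export
simulateHouseholds <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(config$seed + 1L, {
    nft <- config$n_families_by_type
    types <- rep(c("children", "dogs", "both", "neither"),
                 times = nft[c("children", "dogs", "both", "neither")])
    rows <- list()
    for (f in seq_along(types)) {
      fam <- sprintf("F%03d", f)
      type <- types[f]
      hosts <- data.frame(
        host_id = paste0(fam, c("_M", "_F")),
        species = "human",
        role = c("adult_M", "adult_F"),
        age = round(runif(2, 26, 59), 1),
        stringsAsFactors = FALSE)
      if (type %in% c("children", "both")) {
        nc <- sample.int(3, 1)
        # offspring age mixture follows the surveyed cohort: roughly a
        # third infants (6-12 mo), most children aged 1-6, a small tail of
        # adolescents, and none in between
        bin <- sample.int(3, nc, replace = TRUE,
                          prob = c(12, 21, 5) / 38)
        ages <- round(ifelse(bin == 1, runif(nc, 0.5, 1),
                      ifelse(bin == 2, runif(nc, 1, 6),
                             runif(nc, 12, 18))), 1)
        ages <- pmin(ages, 17.9)   # keep rounded ages inside the child bin
        hosts <- rbind(hosts, data.frame(
          host_id = sprintf("%s_C%d", fam, seq_len(nc)),
          species = "human",
          role = ifelse(ages < 1, "infant", "child"),
          age = ages, stringsAsFactors = FALSE))
      }
      if (type %in% c("dogs", "both")) {
        nd <- sample.int(2, 1)
        hosts <- rbind(hosts, data.frame(
          host_id = sprintf("%s_D%d", fam, seq_len(nd)),
          species = "dog", role = "dog",
          age = round(runif(nd, 1, 12), 1), stringsAsFactors = FALSE))
      }
      has_dog <- type %in% c("dogs", "both")
      has_cat <- runif(1) < 0.3
      fam_size <- sum(hosts$species == "human")
      for (h in seq_len(nrow(hosts))) {
        sites <- if (hosts$species[h] == "human") HUMAN_SITES else DOG_SITES
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = paste(hosts$host_id[h], sites, sep = "."),
          host_id = hosts$host_id[h], family_id = fam,
          body_site = sites, species = hosts$species[h],
          role = hosts$role[h], age = hosts$age[h],
          has_dog = has_dog, has_cat = has_cat,
          family_size = fam_size, stringsAsFactors = FALSE)
      }
    }
    sampleMetadata(do.call(rbind, rows))
  })
}

.rdirichlet <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  g <- rgamma(sum(pos), shape = alpha[pos])
  if (all(g == 0)) g[which.max(alpha[pos])] <- 1   # degenerate guard
  x[pos] <- g / sum(g)
  x
}

# Dirichlet(kappa * mean) with kappa = Inf collapsing to the mean itself
.drawProfile <- function(kappa, mean_vec) {
  if (is.infinite(kappa)) mean_vec else .rdirichlet(kappa * mean_vec)
}

#' Simulate phylotype counts for a household roster
#'
#' Hierarchical generative model, fully determined by \code{config$seed}:
#' \enumerate{
#'   \item per (species, body site) baseline
#'     \eqn{\beta_s \sim} Dirichlet(\code{kappa_site} x sparse mask), with
#'     human skin weighted toward Propionibacteriaceae / Streptococcaceae /
#'     Staphylococcaceae, oral and gut toward their signature families, and
#'     dog sites given a flat, even profile;
#'   \item per family-by-site profile
#'     \eqn{\phi_{f,s} \sim} Dirichlet(\code{kappa_family} \eqn{\beta_s});
#'   \item per-individual target: adults mix \eqn{(1-w_{sp})\phi + w_{sp}\psi}
#'     where \eqn{\psi} is a couple-shared draw; children mix toward an
#'     infant signature (elevated Streptococcaceae) with weight
#'     \eqn{e^{-age/\tau}}; skin sites of humans in dog-owning households
#'     mix in \code{w_dog} of a family dog-source profile restricted to
#'     taxa rare on human skin;
#'   \item individual profile \eqn{\sim} Dirichlet(\code{kappa_individual}
#'     x target); counts \eqn{\sim} Multinomial(depth, profile) with
#'     lognormal depths.
#' }
#'
#' @param metadata a [SampleMetadata-class] from [simulateHouseholds()].
#' @param tree a \code{phylo} from [simulateTree()] (its
#'   \code{tip.taxonomy} drives the site weightings).
#' @param config the same [simulationConfig()].
#' @param return_profiles logical; attach the latent per-sample expected
#'   profiles as attribute \code{"profiles"} (for validation).
#' @return An [OtuTable-class] with taxonomy.
#' @export
simulateCounts <- function(metadata, tree, config, return_profiles = FALSE) {
  stopifnot(inherits(config, "SimulationConfig"), is(metadata, "SampleMetadata"))
  md <- metadataTable(metadata)
  taxa <- tree$tip.label
  n_taxa <- length(taxa)
  fam_label <- taxonomyRank(tree$tip.taxonomy[taxa], "family")
  withr::with_seed(config$seed + 2L, {
    site_keys <- c(paste0("human.", HUMAN_SITES), paste0("dog.", DOG_SITES))
    beta <- list()
    for (key in site_keys) {
      sp <- sub("\\..*", "", key)
      site <- sub(".*\\.", "", key)
      active <- runif(n_taxa) < 0.6
      w <- as.numeric(active)
      if (sp == "human") {
        if (site %in% HUMAN_SKIN_SITES) {
          boost <- fam_label %in% SKIN_FAMILIES
        } else if (site == "oral") {
          boost <- fam_label %in% ORAL_FAMILIES
        } else boost <- fam_label %in% GUT_FAMILIES
        w[boost] <- pmax(w[boost], 1) * 20
      }                                     # dog sites stay flat and even
      w <- w / sum(w)
      beta[[key]] <- .rdirichlet(config$kappa_site * w)
    }
    # infant signature: site baseline tilted strongly toward Streptococcaceae
    iota <- lapply(beta[paste0("human.", HUMAN_SITES)], function(b) {
      w <- b * ifelse(fam_label == "Streptococcaceae", 40, 1)
      w / sum(w)
    })
    names(iota) <- paste0("human.", HUMAN_SITES)
    skin_ref <- beta[["human.forehead"]]
    rare_mask <- skin_ref <= stats::median(skin_ref[skin_ref > 0])

    families <- unique(md$family_id)
    phi <- psi <- vector("list", length(families))
    names(phi) <- names(psi) <- families
    delta <- list()
    for (fam in families) {
      phi[[fam]] <- lapply(beta, function(b)
        .drawProfile(config$kappa_family, b))
      # couple-shared component: a family-specific draw at individual-scale
      # dispersion around the family profile, so the spouse effect exists
      # (and is tunable via w_sp) even when the family effect is disabled
      psi[[fam]] <- lapply(phi[[fam]], function(p)
        .drawProfile(config$kappa_individual, p))
      if (any(md$has_dog[md$family_id == fam])) {
        d <- .drawProfile(config$kappa_individual, beta[["dog.paw_FL"]])
        d <- d * rare_mask
        if (sum(d) == 0) d <- rare_mask / sum(rare_mask)
        delta[[fam]] <- d / sum(d)
      }
    }

    counts <- matrix(0, n_taxa, nrow(md),
                     dimnames = list(taxa, md$sample_id))
    profiles <- if (return_profiles) counts else NULL
    for (r in seq_len(nrow(md))) {
      key <- paste(md$species[r], md$body_site[r], sep = ".")
      fam <- md$family_id[r]
      target <- phi[[fam]][[key]]
      if (md$species[r] == "human") {
        shared <- psi[[fam]][[key]]
        if (md$role[r] %in% c("adult_M", "adult_F", "senior")) {
          target <- (1 - config$w_sp) * target + config$w_sp * shared
        } else {
          base <- (1 - config$w_pc) * target + config$w_pc * shared
          a <- exp(-md$age[r] / config$age_tau)
          target <- (1 - a) * base + a * iota[[key]]
        }
        if (md$has_dog[r] && md$body_site[r] %in% HUMAN_SKIN_SITES)
          target <- (1 - config$w_dog) * target + config$w_dog * delta[[fam]]
      }
      prof <- .drawProfile(config$kappa_individual, target)
      depth <- max(1, round(rlnorm(1, config$depth_meanlog,
                                   config$depth_sdlog)))
      counts[, r] <- rmultinom(1, depth, prof)
      if (return_profiles) profiles[, r] <- prof
    }
    out <- otuTable(counts, tree$tip.taxonomy[taxa])
    if (return_profiles) attr(out, "profiles") <- profiles
    out
  })
}

#' Simulate a complete dataset (tree, metadata, counts)
#'
#' @param config a [simulationConfig()].
#' @return list with \code{tree}, \code{metadata}, \code{table}.
#' @export
simulateDataset <- function(config = simulationConfig()) {
  tree <- simulateTree(config$n_taxa, config$seed, config$n_taxon_families)
  metadata <- simulateHouseholds(config)
  table <- simulateCounts(metadata, tree, config)
  list(tree = tree, metadata = metadata, table = table)
}
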