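#' Default species-level motif prevalences
#'
#' Plausible marginal frequencies for the 11 motif classes used by the
#' annotation generator; the labyrinthine motif sits at 5% of species,
#' matching its rough share in large fish pattern surveys, and the other
#' classes span the few-percent to tens-of-percent range such surveys
#' report.
#' @return Named numeric vector over [motif_classes()].
#' @export
default_prevalences <- function() {
  c("St-H" = 0.08, "St-D" = 0.05, "St-V" = 0.12, "Maze" = 0.05,
    "Sp-D" = 0.08, "Sp-L" = 0.07, "Eyes" = 0.06, "Area" = 0.15,
    "Sddl" = 0.04, "Bltc" = 0.10, "Mono" = 0.20)
}

#' Generate a synthetic species-level annotation table
#'
#' Species counts per genus are `1 + Geometric` with the requested mean
#' (or constant, see `species_per_genus`); every motif flag is drawn
#' independently at its species-level prevalence — except Maze, whose
#' per-species probability is multiplied by `blending_effect` (capped at
#' 1) in genera that already contain both a Sp-D and a Sp-L carrier.
#' `blending_effect = 1` is the independence null; larger values inject
#' the genus-level excess of labyrinthine species among spot-bearing
#' genera that the pattern blending hypothesis predicts, directly at the
#' level the collocation screen measures.
#'
#' Note a confounder that matters for calibration: with heterogeneous
#' genus sizes, larger genera carry more of *every* motif, so genus-level
#' flags co-occur positively even when species-level draws are fully
#' independent — the z score of the screen then runs systematically
#' positive. Type-I calibration of the association measures therefore
#' uses `species_per_genus = "fixed"`, which removes the size channel;
#' the same caveat applies to collocation screens on real taxonomies.
#'
#' @param n_genera Number of genera (0 gives an empty table).
#' @param mean_species Mean species per genus.
#' @param species_per_genus `"geometric"` (default, realistic
#'   heterogeneity) or `"fixed"` (every genus has
#'   `round(mean_species)` species; the null-calibration condition).
#' @param prevalence Named prevalence vector (see [default_prevalences()]).
#' @param blending_effect Maze hazard multiplier in genera carrying both
#'   spot motifs (>= 0; 1 = null).
#' @param genera_per_family,families_per_order Taxonomy shape.
#' @param seed Seed.
#' @return An `annotation_table`.
#' @export
gen_annotation_table <- function(n_genera = 2000, mean_species = 4.5,
                                 species_per_genus = c("geometric",
                                                       "fixed"),
                                 prevalence = default_prevalences(),
                                 blending_effect = 1,
                                 genera_per_family = 7,
                                 families_per_order = 10, seed = NULL) {
  species_per_genus <- match.arg(species_per_genus)
  stopifnot(blending_effect >= 0, all(prevalence > 0 & prevalence < 1),
            setequal(names(prevalence), motif_classes()))
  if (!is.null(seed)) set.seed(seed)
  if (n_genera == 0) {
    empty <- as.data.frame(stats::setNames(
      rep(list(integer(0)), 4 + 11), c(taxonomy_cols(), motif_classes())))
    for (cc in taxonomy_cols()) empty[[cc]] <- character(0)
    class(empty) <- c("annotation_table", "data.frame")
    return(empty)
  }
  n_sp <- if (species_per_genus == "geometric")
    1L + stats::rgeom(n_genera, prob = 1 / mean_species)
  else rep(max(1L, as.integer(round(mean_species))), n_genera)
  genus <- sprintf("G%04d", seq_len(n_genera))
  fam <- sprintf("F%04d", (seq_len(n_genera) - 1) %/% genera_per_family + 1)
  ord <- sprintf("O%03d",
                 (match(fam, unique(fam)) - 1) %/% families_per_order + 1)
  rows <- vector("list", n_genera)
  others <- setdiff(motif_classes(), "Maze")
  for (gi in seq_len(n_genera)) {
    k <- n_sp[gi]
    flags <- vapply(others, function(m)
      stats::rbinom(k, 1, prevalence[[m]]), integer(k) * 0L)
    flags <- matrix(flags, nrow = k, dimnames = list(NULL, others))
    both_spots <- any(flags[, "Sp-D"] == 1) && any(flags[, "Sp-L"] == 1)
    p_maze <- min(1, prevalence[["Maze"]] *
                    if (both_spots) blending_effect else 1)
    maze <- stats::rbinom(k, 1, p_maze)
    df <- as.data.frame(flags)
    df$Maze <- maze
    df <- df[motif_classes()]
    df <- cbind(data.frame(species = paste0(genus[gi], "_sp", seq_len(k)),
                           genus = genus[gi], family = fam[gi],
                           order = ord[gi],
                           stringsAsFactors = FALSE), df)
    rows[[gi]] <- df
  }
  out <- do.call(rbind, rows)
  names(out) <- c(taxonomy_cols(), motif_classes())
  as_annotation_table(out)
}

#' Write / read round-trip helper for annotation tables
#'
#' @param t An `annotation_table`.
#' @param path Output TSV path.
#' @export
write_annotations <- function(t, path) {
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dependent rate model with a pattern-blending signature
#'
#' The canonical generator used in the package's parameter-recovery
#' studies: Maze gain is concentrated in the both-spots context
#' (`d = 4` vs `a = b = c = 0.05`) and Maze loss is suppressed there
#' (`h = 0.1` vs `e = f = g = 3`), while the two spot motifs turn over at a
#' moderate context-free rate (0.4). Rates are on the unit-tree-height
#' clock used by [fit_model()].
#'
#' @param spot_rate Gain/loss rate of the non-Maze transitions.
#' @param maze_gain Maze gain rates in contexts (neither, Sp-D only,
#'   Sp-L only, both).
#' @param maze_loss Maze loss rates in the same contexts.
#' @return A dependent [rate_model()].
#' @export
blending_rate_model <- function(spot_rate = 0.4,
                                maze_gain = c(0.05, 0.05, 0.05, 4),
                                maze_loss = c(3, 3, 3, 0.1)) {
  nm <- rate_model("dependent")$param_names
  r <- stats::setNames(rep(spot_rate, length(nm)), nm)
  r[grep("^gain_Maze", nm)] <- maze_gain
  r[grep("^loss_Maze", nm)] <- maze_loss
  rate_model("dependent", r)
}

#' Generate a birth-death genus tree with evolved motif states
#'
#' Simulates a birth-death tree conditioned on `n_tips` surviving tips and
#' evolves the 8-state motif chain along it with [simulate_ctmc()].
#'
#' @param n_tips Number of tips.
#' @param birth_rate,death_rate Speciation/extinction rates
#'   (`birth_rate > death_rate >= 0`).
#' @param q A [rate_model()] or generator matrix.
#' @param root_state Root state index.
#' @param seed Seed.
#' @return A list: `tree` (tips renamed `G1..Gn`), `tip_states`.
#' @export
gen_trait_tree <- function(n_tips, birth_rate = 1, death_rate = 0,
                           q = rate_model("independent"), root_state = 1,
                           seed = NULL) {
  stopifnot(birth_rate > death_rate, death_rate >= 0, n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = death_rate)
  tree$tip.label <- paste0("G", seq_len(n_tips))
  states <- simulate_ctmc(tree, q, root_state = root_state)
  list(tree = tree, tip_states = states)
}

#' Generate allele-frequency data with known introgression
#'
#' Ancestral frequencies are uniform on (0.05, 0.95); populations P1-P3
#' drift from them independently under a Balding-Nichols model with
#' divergence `F_st`-like parameter `divergence`; the outgroup stays at the
#' ancestral state frequency 0 for the derived allele (it polarizes the
#' sites). Introgression is injected as a frequency mixture
#' `p2' = (1 - f) p2 + f p3`.
#'
#' @param n_sites,n_blocks Sites and jackknife blocks.
#' @param divergence Balding-Nichols drift parameter in (0, 1).
#' @param admixture_f Introgressed fraction from P3 into P2 (in `[0, 1)`).
#' @param seed Seed.
#' @return A [freq_matrix()].
#' @export
gen_genotypes <- function(n_sites = 10000, n_blocks = 50,
                          divergence = 0.1, admixture_f = 0, seed = NULL) {
  stopifnot(n_blocks >= 2, admixture_f >= 0, admixture_f < 1,
            divergence > 0, divergence < 1)
  if (!is.null(seed)) set.seed(seed)
  p_anc <- stats::runif(n_sites, 0.05, 0.95)
  bn <- function(p) {
    a <- p * (1 - divergence) / divergence
    b <- (1 - p) * (1 - divergence) / divergence
    stats::rbeta(length(p), a, b)
  }
  p1 <- bn(p_anc); p2 <- bn(p_anc); p3 <- bn(p_anc)
  p2 <- (1 - admixture_f) * p2 + admixture_f * p3
  block <- sort(rep_len(seq_len(n_blocks), n_sites))
  freq_matrix(p1, p2, p3, rep(0, n_sites), block)
}

#' Generate diagnostic-site genotypes for hybrid classes
#'
#' Sites are fixed differences between two parental panels (derived-allele
#' frequency 0 in panel A, 1 in panel B). `"F1"` individuals carry one
#' haplotype from each panel (dosage 1 everywhere); `"F2"` individuals draw
#' each gamete's ancestry independently per site (free recombination, no
#' selection: dosage `Binomial(2, 1/2)`); parentals are homozygous.
#'
#' @param n_sites Number of diagnostic sites.
#' @param class One of `"F1"`, `"F2"`, `"parental_a"`, `"parental_b"`.
#' @param n_individuals Columns to generate.
#' @param missing_rate Fraction of sites set to `NA` (uncallable).
#' @param seed Seed.
#' @return A [diagnostic_genotypes()] object.
#' @export
gen_diagnostic_genotypes <- function(n_sites = 10000,
                                     class = c("F1", "F2", "parental_a",
                                               "parental_b"),
                                     n_individuals = 1, missing_rate = 0,
                                     seed = NULL) {
  class <- match.arg(class)
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(switch(class,
    F1 = rep(1L, n_sites * n_individuals),
    F2 = stats::rbinom(n_sites * n_individuals, 2, 0.5),
    parental_a = rep(0L, n_sites * n_individuals),
    parental_b = rep(2L, n_sites * n_individuals)),
    nrow = n_sites,
    dimnames = list(NULL, paste0(class, "_", seq_len(n_individuals))))
  if (missing_rate > 0)
    g[stats::runif(length(g)) < missing_rate] <- NA
  diagnostic_genotypes(g, panel_a_freq = rep(0, n_sites),
                       panel_b_freq = rep(1, n_sites))
}

#' Generate a synthetic pattern image from the RD model
#'
#' Runs the simulator on a periodic grid at the calibrated kinetic offset
#' for the requested regime and binarizes the stationary field.
#'
#' @param kind `"spots_dark"`, `"spots_light"` or `"labyrinth"` (the
#'   mid-gradient regime).
#' @param size Grid edge length in cells.
#' @param seed Seed.
#' @param n_steps Integration steps.
#' @return A [binary_pattern()] with the raw `u` field as attribute
#'   `field`.
#' @export
gen_pattern_images <- function(kind = c("spots_dark", "spots_light",
                                        "labyrinth"),
                               size = 64, seed = 1, n_steps = 2000) {
  kind <- match.arg(kind)
  C <- switch(kind,
              spots_dark = c_dark_spots(),
              spots_light = c_light_spots(),
              labyrinth = (c_dark_spots() + c_light_spots()) / 2)
  mesh <- make_grid_mesh(size, size, periodic = TRUE)
  st <- simulate(mesh, kinetic_params(C = C), n_steps = n_steps,
                 seed = seed)
  pig <- field_to_matrix(mesh, binarize_field(st))
  bp <- binary_pattern(pig)
  attr(bp, "field") <- field_to_matrix(mesh, st$u)
  attr(bp, "kind") <- kind
  bp
}
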