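#' The 11 pattern motif classes
#'
#' Column order used throughout: four stripe classes (St-H horizontal,
#' St-D diagonal, St-V vertical, Maze labyrinthine), three spot classes
#' (Sp-D dark spots, Sp-L light spots, Eyes eyespots), and four others
#' (Area, Sddl saddle, Bltc blotch, Mono monotone).
#' @return Character vector of the 11 motif names.
#' @export
motif_classes <- function() {
  c("St-H", "St-D", "St-V", "Maze", "Sp-D", "Sp-L",
    "Eyes", "Area", "Sddl", "Bltc", "Mono")
}

taxonomy_cols <- function() c("species", "genus", "family", "order")

#' Read and validate a species-level motif annotation table
#'
#' Expects one row per species (or per image) with taxonomy columns
#' `species`, `genus`, `family`, `order` and one binary column per motif
#' class. Rows sharing a species (multiple annotated images) are collapsed
#' by logical OR over the motif flags.
#'
#' @param path TSV or CSV file (delimiter inferred from the extension, or
#'   pass `sep`).
#' @param sep Optional field separator override.
#' @return A validated `annotation_table` data.frame.
#' @export
read_annotations <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_annotation_table(df)
}

#' @rdname read_annotations
#' @param df A data.frame in the annotation schema.
#' @export
as_annotation_table <- function(df) {
  need <- c(taxonomy_cols(), motif_classes())
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing annotation columns: ", paste(missing, collapse = ", "))
  for (m in motif_classes()) {
    v <- df[[m]]
    if (!all(v %in% c(0, 1)))
      stop(sprintf("motif column '%s' must be binary 0/1", m))
    df[[m]] <- as.integer(v)
  }
  if (anyNA(df$genus) || any(df$genus == ""))
    stop("every species needs a genus")
  if (anyDuplicated(df$species)) {
    agg <- stats::aggregate(df[motif_classes()],
                            by = df[c("species", "genus", "family", "order")],
                            FUN = max)
    df <- agg
  }
  df <- df[c(taxonomy_cols(), motif_classes())]
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Aggregate species annotations to genus level
#'
#' A genus carries a motif iff any of its member species does (logical OR);
#' the species count per genus is recorded for the genus-size filters of
#' the collocation screens. Aggregating an already genus-level table (one
#' species per genus) is a no-op on the flags.
#'
#' @param t An `annotation_table` (see [read_annotations()]).
#' @return A `genus_motif_table` data.frame: `genus`, `n_species`, 11 motif
#'   flags.
#' @export
aggregate_to_genus <- function(t) {
  stopifnot(inherits(t, "data.frame"))
  if (inherits(t, "genus_motif_table")) return(t)
  flags <- stats::aggregate(t[motif_classes()], by = t["genus"], FUN = max)
  nsp <- stats::aggregate(list(n_species = t$species), by = t["genus"],
                          FUN = function(x) length(unique(x)))
  g <- merge(nsp, flags, by = "genus")
  class(g) <- c("genus_motif_table", "data.frame")
  g
}

check_motif <- function(g, m) {
  if (!m %in% motif_classes())
    stop("unknown motif name: ", m)
  if (!m %in% names(g))
    stop("motif column absent from table: ", m)
}

contingency_from_flags <- function(a, b) {
  O11 <- sum(a == 1 & b == 1)
  O10 <- sum(a == 1 & b == 0)
  O01 <- sum(a == 0 & b == 1)
  O00 <- sum(a == 0 & b == 0)
  N <- O11 + O10 + O01 + O00
  A1 <- O11 + O10; A0 <- O01 + O00
  B1 <- O11 + O01; B0 <- O10 + O00
  structure(list(O11 = O11, O10 = O10, O01 = O01, O00 = O00,
                 A1 = A1, A0 = A0, B1 = B1, B0 = B0, N = N,
                 E11 = A1 * B1 / N, E10 = A1 * B0 / N,
                 E01 = A0 * B1 / N, E00 = A0 * B0 / N),
            class = "contingency_counts")
}

#' Genus-level pairwise contingency counts
#'
#' Counts, over all genera with at least `min_species` species, the
#' co-occurrence of two motifs: `O11` genera carrying both, `O10` only
#' motif A, `O01` only motif B, `O00` neither, plus marginals and expected
#' counts `Eij = Ai Bj / N`.
#'
#' @param g A `genus_motif_table` ([aggregate_to_genus()]).
#' @param motif_a,motif_b Motif names (distinct).
#' @param min_species Genus-size filter (default 2, the pairwise screen's
#'   convention).
#' @return A `contingency_counts` object.
#' @export
pair_contingency <- function(g, motif_a, motif_b, min_species = 2) {
  check_motif(g, motif_a); check_motif(g, motif_b)
  if (motif_a == motif_b) stop("motifs must be distinct")
  stopifnot(min_species >= 1)
  keep <- g$n_species >= min_species
  contingency_from_flags(g[[motif_a]][keep], g[[motif_b]][keep])
}

#' Triple (anchor-pair) contingency counts
#'
#' The anchor pair plays the role of motif A: "A occurs" in a genus iff
#' both anchor motifs occur there. Otherwise identical to
#' [pair_contingency()]; the genus-size filter defaults to 3, the triple
#' screen's convention.
#'
#' @param g A `genus_motif_table`.
#' @param pair Character vector of the two anchor motifs.
#' @param motif_b The candidate partner motif.
#' @param min_species Genus-size filter (default 3).
#' @return A `contingency_counts` object.
#' @export
triple_contingency <- function(g, pair, motif_b, min_species = 3) {
  stopifnot(length(pair) == 2)
  if (pair[1] == pair[2]) stop("anchor motifs must be distinct")
  if (motif_b %in% pair) stop("partner motif must differ from the anchors")
  for (m in c(pair, motif_b)) check_motif(g, m)
  keep <- g$n_species >= min_species
  a <- as.integer(g[[pair[1]]][keep] == 1 & g[[pair[2]]][keep] == 1)
  contingency_from_flags(a, g[[motif_b]][keep])
}

#' The six collocation association measures
#'
#' From a 2x2 genus contingency table computes Jaccard index
#' `JI = O11 / (O10 + O01 + O11)`, Sorensen-Dice coefficient
#' `SDC = 2 O11 / (A1 + B1)`, Simpson similarity `SSI = O11 / min(A1, B1)`,
#' the log-likelihood statistic `LL = 2 sum_ij Oij ln(Oij / Eij)` (terms
#' with `Oij = 0` contribute 0), and the corpus-linguistics
#' `T = (O11 - E11) / sqrt(O11)` and `Z = (O11 - E11) / sqrt(E11)` scores.
#'
#' The typeset source of the T and Z formulas omits radicals; the standard
#' definitions with square-root denominators are used by default, and
#' `radicals = FALSE` switches to the literal no-radical variant for
#' sensitivity analysis. `T` is reported as 0 (with attribute
#' `t_undefined`) when `O11 = 0`.
#'
#' @param cc A `contingency_counts` object.
#' @param radicals Use square-root denominators in T and Z (default TRUE).
#' @param log_base Base of the logarithm in LL (default natural log).
#' @return A one-row data.frame with columns `JI`, `SDC`, `SSI`, `LL`, `T`,
#'   `Z` plus the counts.
#' @export
association_measures <- function(cc, radicals = TRUE, log_base = exp(1)) {
  stopifnot(inherits(cc, "contingency_counts"))
  if (cc$N <= 0) stop("empty contingency table (N = 0)")
  O <- c(cc$O11, cc$O10, cc$O01, cc$O00)
  E <- c(cc$E11, cc$E10, cc$E01, cc$E00)
  ll_terms <- ifelse(O == 0, 0, O * log(O / E, base = log_base))
  JI <- if (cc$O10 + cc$O01 + cc$O11 > 0)
    cc$O11 / (cc$O10 + cc$O01 + cc$O11) else NA_real_
  SDC <- if (cc$A1 + cc$B1 > 0) 2 * cc$O11 / (cc$A1 + cc$B1) else NA_real_
  SSI <- if (min(cc$A1, cc$B1) > 0) cc$O11 / min(cc$A1, cc$B1) else NA_real_
  dT <- if (radicals) sqrt(cc$O11) else cc$O11
  dZ <- if (radicals) sqrt(cc$E11) else cc$E11
  T <- if (cc$O11 > 0) (cc$O11 - cc$E11) / dT else 0
  Z <- if (cc$E11 > 0) (cc$O11 - cc$E11) / dZ else NA_real_
  out <- data.frame(JI = JI, SDC = SDC, SSI = SSI, LL = 2 * sum(ll_terms),
                    T = T, Z = Z,
                    O11 = cc$O11, O10 = cc$O10, O01 = cc$O01, O00 = cc$O00,
                    N = cc$N, E11 = cc$E11)
  attr(out, "t_undefined") <- cc$O11 == 0
  out
}

#' Collocation screen over all motif combinations
#'
#' `mode = "pairwise"`: all unordered pairs of the 11 motifs, genera with
#' at least 2 species. `mode = "triple"`: every remaining motif against the
#' `anchor` pair, genera with at least 3 species. Returns a tidy table of
#' the six measures, ranked by each measure on request.
#'
#' @param g A `genus_motif_table`.
#' @param mode `"pairwise"` or `"triple"`.
#' @param anchor Anchor motif pair for triple mode (default the two simple
#'   spot motifs, the pattern-blending hypothesis' parent phenotypes).
#' @param min_species Genus-size filter; defaults to 2 (pairwise) or 3
#'   (triple).
#' @param radicals Passed to [association_measures()].
#' @return A data.frame with one row per combination and the six measures.
#' @export
association_screen <- function(g, mode = c("pairwise", "triple"),
                               anchor = c("Sp-D", "Sp-L"),
                               min_species = NULL, radicals = TRUE) {
  mode <- match.arg(mode)
  if (mode == "pairwise") {
    if (is.null(min_species)) min_species <- 2
    combos <- utils::combn(motif_classes(), 2)
    rows <- lapply(seq_len(ncol(combos)), function(i) {
      cc <- pair_contingency(g, combos[1, i], combos[2, i], min_species)
      cbind(data.frame(motif_a = combos[1, i], motif_b = combos[2, i]),
            association_measures(cc, radicals = radicals))
    })
  } else {
    if (is.null(min_species)) min_species <- 3
    partners <- setdiff(motif_classes(), anchor)
    rows <- lapply(partners, function(m) {
      cc <- triple_contingency(g, anchor, m, min_species)
      cbind(data.frame(motif_a = paste(anchor, collapse = "&"),
                       motif_b = m),
            association_measures(cc, radicals = radicals))
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Square score matrix of a pairwise screen
#'
#' @param screen Output of [association_screen()] in pairwise mode.
#' @param measure One of `"JI"`, `"SDC"`, `"SSI"`, `"LL"`, `"T"`, `"Z"`.
#' @return A symmetric 11x11 matrix (diagonal `NA`).
#' @export
screen_matrix <- function(screen, measure = "Z") {
  mm <- motif_classes()
  M <- matrix(NA_real_, length(mm), length(mm), dimnames = list(mm, mm))
  for (i in seq_len(nrow(screen))) {
    M[screen$motif_a[i], screen$motif_b[i]] <- screen[[measure]][i]
    M[screen$motif_b[i], screen$motif_a[i]] <- screen[[measure]][i]
  }
  M
}
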