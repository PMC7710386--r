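#' Build a frequency matrix for four-taxon tests
#'
#' @param p1,p2,p3,p4 Derived-allele frequencies per biallelic site in the
#'   populations (P1, P2; P3 the candidate donor; P4 the outgroup, which
#'   polarizes the alleles and is typically 0).
#' @param block Genomic block id per site (emulating e.g. 5-Mb jackknife
#'   blocks). Use [assign_blocks()] when only coordinates are available.
#' @return A `freq_matrix` data.frame with columns `block`, `p1`..`p4`.
#' @export
freq_matrix <- function(p1, p2, p3, p4, block) {
  df <- data.frame(block = block, p1 = p1, p2 = p2, p3 = p3, p4 = p4)
  pp <- as.matrix(df[, c("p1", "p2", "p3", "p4")])
  if (any(pp < 0 | pp > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  class(df) <- c("freq_matrix", "data.frame")
  df
}

#' Assign jackknife blocks from genomic coordinates
#'
#' @param chrom,pos Chromosome and position per site.
#' @param block_size Block length in the units of `pos` (default 5e6, i.e.
#'   5-Mb blocks).
#' @return Character vector of block ids.
#' @export
assign_blocks <- function(chrom, pos, block_size = 5e6) {
  paste0(chrom, ":", floor(pos / block_size))
}

#' Read a frequency matrix from TSV
#'
#' Expects columns `block`, `p1`, `p2`, `p3`, `p4` (extra columns kept).
#' @param path TSV file.
#' @return A `freq_matrix`.
#' @export
read_freq_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("block", "p1", "p2", "p3", "p4")
  if (length(setdiff(need, names(df))))
    stop("freq matrix needs columns: ", paste(need, collapse = ", "))
  freq_matrix(df$p1, df$p2, df$p3, df$p4, df$block)
}

#' Patterson's D with block-jackknife significance
#'
#' Frequency-based ABBA-BABA: per site,
#' `pABBA = (1 - p1) p2 p3 (1 - p4)` and `pBABA = p1 (1 - p2) p3 (1 - p4)`;
#' `D = (sum pABBA - sum pBABA) / (sum pABBA + sum pBABA)`. The standard
#' error comes from the delete-one-block jackknife over the `block` column
#' and `z = D / SE`. Sites with any missing frequency are dropped (and
#' counted in `n_dropped`).
#'
#' @param fm A [freq_matrix()].
#' @return A `dstat_result` list: `D`, `z`, `se`, `n_blocks`, `abba_sum`,
#'   `baba_sum`, `n_sites`, `n_dropped`.
#' @export
patterson_d <- function(fm) {
  ok <- stats::complete.cases(fm[, c("p1", "p2", "p3", "p4")])
  n_dropped <- sum(!ok)
  fm <- fm[ok, ]
  abba <- (1 - fm$p1) * fm$p2 * fm$p3 * (1 - fm$p4)
  baba <- fm$p1 * (1 - fm$p2) * fm$p3 * (1 - fm$p4)
  tot_a <- sum(abba); tot_b <- sum(baba)
  if (tot_a + tot_b <= 0)
    stop("no informative sites: ABBA + BABA is zero")
  D <- (tot_a - tot_b) / (tot_a + tot_b)
  blocks <- unique(fm$block)
  gB <- length(blocks)
  if (gB < 2) stop("block jackknife needs at least 2 blocks")
  a_blk <- tapply(abba, fm$block, sum)[as.character(blocks)]
  b_blk <- tapply(baba, fm$block, sum)[as.character(blocks)]
  D_del <- ((tot_a - a_blk) - (tot_b - b_blk)) /
    ((tot_a - a_blk) + (tot_b - b_blk))
  ok_blk <- is.finite(D_del)   # a block may hold all informative sites
  se <- if (sum(ok_blk) >= 2) {
    dv <- D_del[ok_blk]
    g2 <- length(dv)
    sqrt((g2 - 1) / g2 * sum((dv - mean(dv))^2))
  } else NA_real_
  structure(list(D = D,
                 z = if (is.finite(se) && se > 0) D / se else NA_real_,
                 se = se,
                 n_blocks = gB, abba_sum = tot_a, baba_sum = tot_b,
                 n_sites = nrow(fm), n_dropped = n_dropped),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("Patterson's D = %.4f (z = %.2f, %d blocks, %d sites)\n",
              x$D, x$z, x$n_blocks, x$n_sites))
  invisible(x)
}

#' Trio-level D_min statistic
#'
#' Evaluates Patterson's D under the three possible topologies of a species
#' trio `(A, B, C)` with a fixed outgroup — `D(A,B;C,O)`, `D(A,C;B,O)`,
#' `D(C,B;A,O)` — by permuting the frequency columns, and returns the
#' minimum absolute value, a conservative signal of introgression that
#' cannot be explained by a wrong assumed topology.
#'
#' The reported p-value is the two-sided normal p of the jackknife z score
#' of the topology attaining the minimum |D| (the attribution rule is a
#' package decision, flagged in the output).
#'
#' @param fm A [freq_matrix()] whose `p1`, `p2`, `p3` columns hold taxa
#'   `A`, `B`, `C` and `p4` the outgroup.
#' @param labels Optional names of `(A, B, C)` for reporting.
#' @return A `dmin_result` list with the three `dstat_result`s, `D_min`,
#'   `z_min`, `p_value`, `topology`.
#' @export
d_min <- function(fm, labels = c("A", "B", "C")) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(3, 2, 1))
  topo <- vapply(perms, function(pm) {
    sprintf("(%s,%s;%s,O)", labels[pm[1]], labels[pm[2]], labels[pm[3]])
  }, character(1))
  fits <- lapply(perms, function(pm) {
    cols <- c("p1", "p2", "p3")[pm]
    patterson_d(freq_matrix(fm[[cols[1]]], fm[[cols[2]]], fm[[cols[3]]],
                            fm$p4, fm$block))
  })
  absD <- vapply(fits, function(f) abs(f$D), numeric(1))
  i <- which.min(absD)
  z <- fits[[i]]$z
  structure(list(fits = stats::setNames(fits, topo),
                 D_min = absD[i], z_min = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 topology = topo[i], labels = labels,
                 p_value_rule = "z of the minimum-|D| topology"),
            class = "dmin_result")
}

#' @export
print.dmin_result <- function(x, ...) {
  cat(sprintf("D_min = %.4f at %s (z = %.2f, p = %.3g)\n",
              x$D_min, x$topology, x$z_min, x$p_value))
  invisible(x)
}

#' Holm-Bonferroni step-down decisions
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param alpha Familywise error rate.
#' @return A data.frame: `p`, `p_adjusted` (via `p.adjust(..., "holm")`),
#'   `reject`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.01) {
  if (length(pvals) == 0) stop("no p-values supplied")
  stopifnot(all(pvals >= 0 & pvals <= 1))
  adj <- stats::p.adjust(pvals, method = "holm")
  data.frame(p = pvals, p_adjusted = adj, reject = adj < alpha)
}

#' Diagnostic genotypes container
#'
#' Sites diagnostic between two reference panels: derived-allele frequency
#' 0 in one panel and 1 in the other. Genotypes are derived-allele dosages
#' 0/1/2, `NA` = not callable.
#'
#' @param genotypes Site x individual integer matrix of dosages.
#' @param panel_a_freq,panel_b_freq Per-site frequencies in the two panels
#'   (used to verify fixation).
#' @param tol Fixation tolerance.
#' @return A `diagnostic_genotypes` object.
#' @export
diagnostic_genotypes <- function(genotypes, panel_a_freq = NULL,
                                 panel_b_freq = NULL, tol = 0) {
  g <- as.matrix(genotypes)
  if (!all(g %in% c(0L, 1L, 2L, NA)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  if (!is.null(panel_a_freq) && !is.null(panel_b_freq)) {
    fixed <- (panel_a_freq <= tol & panel_b_freq >= 1 - tol) |
      (panel_b_freq <= tol & panel_a_freq >= 1 - tol)
    if (!all(fixed))
      stop(sprintf("%d sites are not fixed differences between the panels",
                   sum(!fixed)))
  }
  structure(list(genotypes = g), class = "diagnostic_genotypes")
}

#' Interclass heterozygosity
#'
#' Fraction of callable ancestry-diagnostic sites at which an individual is
#' heterozygous (dosage exactly 1), i.e. carries one allele from each
#' parental panel. Near 1 for F1 hybrids, near 0.5 for F2s, near 0 for
#' pure parentals. An optional site-block split yields a delete-one-block
#' jackknife standard error.
#'
#' @param dg A [diagnostic_genotypes()] object (or dosage matrix).
#' @param individual Column name or index.
#' @param n_blocks Number of contiguous site blocks for the jackknife SE
#'   (default 25; set to 0 to skip).
#' @return A list: `heterozygosity`, `n_callable`, `se` (NA when skipped).
#' @export
interclass_heterozygosity <- function(dg, individual, n_blocks = 25) {
  g <- if (inherits(dg, "diagnostic_genotypes")) dg$genotypes else
    as.matrix(dg)
  x <- g[, individual]
  ok <- !is.na(x)
  if (!any(ok)) stop("no callable diagnostic sites for this individual")
  het <- x[ok] == 1L
  h <- mean(het)
  se <- NA_real_
  if (n_blocks >= 2 && sum(ok) >= n_blocks) {
    blk <- cut(seq_along(het), breaks = n_blocks, labels = FALSE)
    h_del <- vapply(seq_len(n_blocks), function(b) mean(het[blk != b]),
                    numeric(1))
    se <- sqrt((n_blocks - 1) / n_blocks * sum((h_del - mean(h_del))^2))
  }
  list(heterozygosity = h, n_callable = sum(ok), se = se)
}
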