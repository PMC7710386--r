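# shared small fixtures, built in code

# rasterized disk of radius r, centered
disk_image <- function(r, margin = 14) {
  n <- 2 * r + 2 * margin
  xx <- outer(seq_len(n) - (n + 1) / 2, rep(1, n))
  yy <- t(xx)
  (xx^2 + yy^2) <= r^2
}

# annotation table with hand-countable genus structure (6 genera)
toy_annotations <- function() {
  motifs <- motif_classes()
  zero <- stats::setNames(as.list(rep(0L, length(motifs))), motifs)
  row <- function(species, genus, ...) {
    f <- zero
    set <- list(...)
    f[names(set)] <- set
    cbind(data.frame(species = species, genus = genus,
                     family = "Fam1", order = "Ord1",
                     stringsAsFactors = FALSE),
          as.data.frame(f, check.names = FALSE))
  }
  df <- rbind(
    row("g1_s1", "g1", `Sp-D` = 1L, `Sp-L` = 1L),
    row("g1_s2", "g1", Maze = 1L),
    row("g2_s1", "g2", `Sp-D` = 1L),
    row("g2_s2", "g2", Maze = 1L),
    row("g3_s1", "g3", `Sp-D` = 1L, Maze = 1L),
    row("g3_s2", "g3"),
    row("g4_s1", "g4", `Sp-L` = 1L),
    row("g4_s2", "g4", `Sp-L` = 1L),
    row("g5_s1", "g5", Maze = 1L, `Sp-D` = 1L, `Sp-L` = 1L),
    row("g5_s2", "g5"),
    row("g5_s3", "g5"),
    row("g6_s1", "g6")
  )
  as_annotation_table(df)
}

# random small annotation tables for oracle property tests
random_genus_table <- function(n_genera, seed) {
  set.seed(seed)
  g <- data.frame(genus = paste0("g", seq_len(n_genera)),
                  n_species = sample(1:6, n_genera, replace = TRUE))
  for (m in motif_classes())
    g[[m]] <- sample(0:1, n_genera, replace = TRUE)
  class(g) <- c("genus_motif_table", "data.frame")
  g
}

# independent re-derivation of the six association measures from a genus
# table, via explicit genus enumeration (the brute-force oracle)
brute_force_measures <- function(g, motif_a, motif_b, min_species = 2) {
  O <- c(O11 = 0, O10 = 0, O01 = 0, O00 = 0)
  for (i in seq_len(nrow(g))) {
    if (g$n_species[i] < min_species) next
    a <- g[[motif_a]][i] == 1
    b <- g[[motif_b]][i] == 1
    key <- paste0("O", as.integer(a), as.integer(b))
    O[key] <- O[key] + 1
  }
  N <- sum(O)
  A1 <- O[["O11"]] + O[["O10"]]; B1 <- O[["O11"]] + O[["O01"]]
  A0 <- N - A1; B0 <- N - B1
  E <- c(A1 * B1, A1 * B0, A0 * B1, A0 * B0) / N
  Ov <- unname(O)
  ll <- sum(ifelse(Ov == 0, 0, Ov * log(Ov / E)))
  list(JI = O[["O11"]] / (O[["O10"]] + O[["O01"]] + O[["O11"]]),
       SDC = 2 * O[["O11"]] / (A1 + B1),
       SSI = O[["O11"]] / min(A1, B1),
       LL = 2 * ll,
       T = if (O[["O11"]] > 0) (O[["O11"]] - E[1]) / sqrt(O[["O11"]]) else 0,
       Z = (O[["O11"]] - E[1]) / sqrt(E[1]),
       O = O, N = N)
}

# tiny deterministic genus tree
cherry_tree <- function(t1 = 1, t2 = 1) {
  ape::read.tree(text = sprintf("(A:%f,B:%f);", t1, t2))
}
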