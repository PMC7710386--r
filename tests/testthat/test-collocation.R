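test_that("annotation tables are validated and species collapsed by OR", {
  t <- toy_annotations()
  expect_s3_class(t, "annotation_table")
  expect_equal(nrow(t), 12)
  # duplicate species collapse
  d <- as.data.frame(t)
  d2 <- rbind(d, within(d[1, ], Maze <- 1L))
  tt <- as_annotation_table(d2)
  expect_equal(nrow(tt), 12)
  expect_equal(tt$Maze[tt$species == "g1_s1"], 1L)
  # non-binary flag and missing column
  bad <- d; bad$Maze[1] <- 2L
  expect_error(as_annotation_table(bad), "binary")
  expect_error(as_annotation_table(d[, -5]), "missing annotation columns")
})

test_that("round-trip through TSV preserves the table", {
  t <- toy_annotations()
  f <- tempfile(fileext = ".tsv")
  write_annotations(t, f)
  t2 <- read_annotations(f)
  expect_equal(as.data.frame(t)[order(t$species), ],
               as.data.frame(t2)[order(t2$species), ],
               ignore_attr = TRUE)
})

test_that("genus aggregation ORs species flags and counts species", {
  g <- aggregate_to_genus(toy_annotations())
  expect_equal(nrow(g), 6)
  gg <- g[order(g$genus), ]
  expect_equal(gg$n_species, c(2L, 2L, 2L, 2L, 3L, 1L))
  expect_equal(gg$Maze, c(1L, 1L, 1L, 0L, 1L, 0L))
  expect_equal(gg$`Sp-D`, c(1L, 1L, 1L, 0L, 1L, 0L))
  # a one-species-per-genus table aggregates to its own flags
  t1 <- toy_annotations()
  t1 <- t1[!duplicated(t1$genus), ]
  g1 <- aggregate_to_genus(as_annotation_table(as.data.frame(t1)))
  expect_true(all(g1$n_species == 1L))
  expect_equal(g1$Maze[order(g1$genus)],
               t1$Maze[order(t1$genus)])
})

test_that("pairwise contingency counts match hand enumeration", {
  g <- aggregate_to_genus(toy_annotations())
  # genera with >= 2 species: g1..g5; Sp-D flags 1,1,1,0,1; Maze 1,1,1,0,1
  cc <- pair_contingency(g, "Sp-D", "Maze", min_species = 2)
  expect_equal(cc$O11, 4); expect_equal(cc$O00, 1)
  expect_equal(cc$O10, 0); expect_equal(cc$O01, 0)
  expect_equal(cc$N, 5)
  # swapping motifs transposes the off-diagonal
  c1 <- pair_contingency(g, "Sp-D", "Sp-L")
  c2 <- pair_contingency(g, "Sp-L", "Sp-D")
  expect_equal(c1$O10, c2$O01)
  expect_equal(c1$O11, c2$O11); expect_equal(c1$O00, c2$O00)
  expect_error(pair_contingency(g, "Maze", "Maze"), "distinct")
  expect_error(pair_contingency(g, "Nope", "Maze"), "unknown motif")
  # filter larger than every genus leaves nothing for the measures
  c0 <- pair_contingency(g, "Sp-D", "Maze", min_species = 99)
  expect_error(association_measures(c0), "N = 0")
})

test_that("association measures reproduce direct arithmetic", {
  cc <- structure(list(O11 = 3, O10 = 1, O01 = 2, O00 = 10,
                       A1 = 4, A0 = 12, B1 = 5, B0 = 11, N = 16,
                       E11 = 4 * 5 / 16, E10 = 4 * 11 / 16,
                       E01 = 12 * 5 / 16, E00 = 12 * 11 / 16),
                  class = "contingency_counts")
  m <- association_measures(cc)
  expect_equal(m$JI, 0.5)
  expect_equal(m$SDC, 6 / 9)
  expect_equal(m$SSI, 3 / 4)
  expect_equal(m$T, (3 - 1.25) / sqrt(3))
  expect_equal(m$Z, (3 - 1.25) / sqrt(1.25))
  # literal no-radical variant
  m2 <- association_measures(cc, radicals = FALSE)
  expect_equal(m2$Z, (3 - 1.25) / 1.25)
  # exact independence: all observed equal expected
  ci <- patternblend:::contingency_from_flags(
    rep(c(1, 1, 0, 0), 2), rep(c(1, 0, 1, 0), 2))
  mi <- association_measures(ci)
  expect_equal(mi$LL, 0, tolerance = 1e-12)
  expect_equal(mi$T, 0); expect_equal(mi$Z, 0)
})

test_that("Z and T share the sign of O11 - E11 and JI <= SSI", {
  for (s in 1:50) {
    g <- random_genus_table(30, seed = s)
    m <- association_measures(pair_contingency(g, "Maze", "Sp-D",
                                               min_species = 1))
    expect_equal(sign(m$T), sign(m$Z))
    if (!is.na(m$JI) && !is.na(m$SSI)) expect_lte(m$JI, m$SSI + 1e-12)
  }
})

test_that("triple contingency treats the anchor pair as one motif", {
  g <- aggregate_to_genus(toy_annotations())
  # genera with >= 3 species: only g5 (both spots + Maze)
  cc <- triple_contingency(g, c("Sp-D", "Sp-L"), "Maze", min_species = 3)
  expect_equal(cc$O11, 1); expect_equal(cc$N, 1)
  # constructed table: Maze occurs iff both spots do
  g2 <- random_genus_table(40, seed = 9)
  g2$Maze <- as.integer(g2$`Sp-D` == 1 & g2$`Sp-L` == 1)
  c2 <- triple_contingency(g2, c("Sp-D", "Sp-L"), "Maze", min_species = 1)
  expect_equal(c2$O10, 0)
  expect_equal(c2$O01, 0)
  expect_error(triple_contingency(g, c("Sp-D", "Sp-D"), "Maze"),
               "distinct")
  expect_error(triple_contingency(g, c("Sp-D", "Sp-L"), "Sp-D"),
               "differ")
  # the min_species = 3 default excludes two-species genera
  c3 <- triple_contingency(g, c("Sp-D", "Sp-L"), "Maze")
  expect_equal(c3$N, 1)
})

test_that("screens cover all combinations and pairwise scores are symmetric", {
  g <- aggregate_to_genus(gen_annotation_table(300, seed = 4))
  sp <- association_screen(g, mode = "pairwise")
  expect_equal(nrow(sp), choose(11, 2))
  M <- screen_matrix(sp, "Z")
  expect_equal(M, t(M))
  tr <- association_screen(g, mode = "triple")
  expect_equal(nrow(tr), 9)
  expect_true(all(tr$motif_a == "Sp-D&Sp-L"))
})

test_that("measures agree with brute-force genus enumeration", {
  for (s in 1:60) {
    g <- random_genus_table(sample(5:25, 1), seed = 1000 + s)
    a <- sample(motif_classes(), 2)
    cc <- try(pair_contingency(g, a[1], a[2]), silent = TRUE)
    if (inherits(cc, "try-error")) next
    bf <- brute_force_measures(g, a[1], a[2])
    if (bf$N == 0) next
    m <- association_measures(cc)
    expect_equal(m$O11, unname(bf$O["O11"]))
    for (k in c("JI", "SDC", "SSI", "LL", "T", "Z"))
      if (is.finite(bf[[k]]))
        expect_equal(m[[k]], bf[[k]], tolerance = 1e-12)
  }
})
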