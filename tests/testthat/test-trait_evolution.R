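test_that("generators are valid CTMC rate matrices", {
  for (mdl in c("independent", "dependent")) {
    rm <- rate_model(mdl)
    Q <- build_generator(rm)
    expect_equal(rowSums(Q), rep(0, 8), ignore_attr = TRUE,
                 tolerance = 1e-12)
    off <- Q; diag(off) <- 0
    expect_true(all(off >= 0))
    # non-zero rates only between single-motif changes
    bits <- patternblend:::state_bits()
    for (s in 1:8) for (t in 1:8) {
      if (s == t) next
      if (sum(bits[s, ] != bits[t, ]) > 1) expect_equal(Q[s, t], 0)
    }
    # transition probabilities are stochastic for a range of times
    for (tt in c(0.01, 0.5, 3, 20)) {
      P <- as.matrix(Matrix::expm(Q * tt))
      expect_equal(rowSums(P), rep(1, 8), ignore_attr = TRUE,
                   tolerance = 1e-9)
      expect_true(all(P > -1e-12))
    }
  }
  expect_equal(length(rate_model("independent")$rates), 6)
  expect_equal(length(rate_model("dependent")$rates), 24)
  expect_equal(length(rate_model("partial", independent_motif = 3)$rates),
               10)
})

test_that("maze rate summary round-trips and collapses when independent", {
  rm <- blending_rate_model()
  expect_equal(maze_rate_summary(rm),
               c(a = 0.05, b = 0.05, c = 0.05, d = 4,
                 e = 3, f = 3, g = 3, h = 0.1))
  nm <- rate_model("independent")$param_names
  ri <- rate_model("independent",
                   stats::setNames(seq(0.1, 0.6, by = 0.1), nm))
  mr <- maze_rate_summary(ri)
  expect_true(all(mr[c("a", "b", "c")] == mr["d"]))
  expect_true(all(mr[c("e", "f", "g")] == mr["h"]))
})

test_that("pruning likelihood matches the 2-state closed form", {
  lambda <- 0.7; t1 <- 1.5
  tr <- cherry_tree(t1, 1e-9)
  Q <- matrix(c(-lambda, lambda, 0, 0), 2, 2, byrow = TRUE)
  # gain-only chain from a root fixed at state 1:
  # P(tip in state 2) = 1 - exp(-lambda t)
  ll <- ctmc_loglik(tr, c(A = 2L, B = 1L), Q, root = "fixed",
                    root_state = 1)
  expect_equal(exp(ll), 1 - exp(-lambda * t1), tolerance = 1e-6)
  # zero-length branch pins the tip to its parent's state
  tr0 <- cherry_tree(0, 2)
  ll_match <- ctmc_loglik(tr0, c(A = 1L, B = 1L), Q, root = "fixed",
                          root_state = 1)
  ll_mismatch <- ctmc_loglik(tr0, c(A = 2L, B = 1L), Q, root = "fixed",
                             root_state = 1)
  expect_true(is.finite(ll_match))
  expect_equal(ll_mismatch, -Inf)
})

test_that("pruning equals brute-force summation over internal states", {
  skip_if_not_installed("Matrix")
  brute_force_ll <- function(tree, tip_states, Q, prior) {
    tr <- ape::reorder.phylo(tree, "postorder")
    n_tip <- length(tr$tip.label)
    n_node <- max(tr$edge)
    internals <- (n_tip + 1):n_node
    k <- nrow(Q)
    P <- lapply(seq_len(nrow(tr$edge)), function(e)
      as.matrix(Matrix::expm(Q * tr$edge.length[e])))
    ts <- tip_states[tr$tip.label]
    grid <- expand.grid(rep(list(seq_len(k)), length(internals)))
    root <- setdiff(tr$edge[, 1], tr$edge[, 2])
    tot <- 0
    for (r in seq_len(nrow(grid))) {
      st <- integer(n_node)
      st[seq_len(n_tip)] <- ts
      st[internals] <- unlist(grid[r, ])
      pr <- prior[st[root]]
      for (e in seq_len(nrow(tr$edge)))
        pr <- pr * P[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
      tot <- tot + pr
    }
    log(tot)
  }
  # 8 states, 4 tips, dependent generator
  set.seed(42)
  nm <- rate_model("dependent")$param_names
  rm <- rate_model("dependent",
                   stats::setNames(stats::runif(24, 0.05, 2), nm))
  Q <- build_generator(rm)
  g <- gen_trait_tree(4, q = rm, seed = 8)
  ll <- ctmc_loglik(g$tree, g$tip_states, Q)
  bf <- brute_force_ll(g$tree, g$tip_states, Q, rep(1 / 8, 8))
  expect_equal(ll, bf, tolerance = 1e-10)
  # 2 states, 3 tips, fixed root
  tr <- ape::read.tree(text = "((A:0.4,B:0.9):0.6,C:1.3);")
  Q2 <- matrix(c(-0.5, 0.5, 0.8, -0.8), 2, 2, byrow = TRUE)
  ts2 <- c(A = 1L, B = 2L, C = 2L)
  ll2 <- ctmc_loglik(tr, ts2, Q2, root = "uniform")
  bf2 <- brute_force_ll(tr, ts2, Q2, c(0.5, 0.5))
  expect_equal(ll2, bf2, tolerance = 1e-10)
})

test_that("likelihood is invariant to swapping symmetric tips", {
  tr <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  Q <- build_generator(rate_model("independent"))
  l1 <- ctmc_loglik(tr, c(A = 3L, B = 5L, C = 1L), Q)
  l2 <- ctmc_loglik(tr, c(A = 5L, B = 3L, C = 1L), Q)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("stationary root prior solves pi Q = 0", {
  rm <- blending_rate_model()
  Q <- build_generator(rm)
  pi0 <- patternblend:::stationary_dist(Q)
  expect_equal(sum(pi0), 1)
  expect_lt(max(abs(pi0 %*% Q)), 1e-10)
  expect_true(is.finite(ctmc_loglik(
    gen_trait_tree(6, q = rm, seed = 2)$tree,
    gen_trait_tree(6, q = rm, seed = 2)$tip_states, Q,
    root = "stationary")))
})

test_that("the forward simulator obeys degenerate and Poisson limits", {
  zero <- rate_model("independent",
                     stats::setNames(rep(0, 6),
                                     rate_model("independent")$param_names))
  g <- gen_trait_tree(12, q = zero, root_state = 5, seed = 3)
  expect_true(all(g$tip_states == 5))
  # transition count on a long two-branch tree is Poisson(rate * length)
  tr <- cherry_tree(40, 40)
  Q2 <- matrix(c(-0.25, 0.25, 0.25, -0.25), 2, 2, byrow = TRUE)
  set.seed(9)
  counts <- vapply(1:300, function(i)
    attr(simulate_ctmc(tr, Q2, root_state = 1), "n_transitions"),
    numeric(1))
  lam <- 0.25 * 80
  expect_equal(mean(counts), lam, tolerance = 3 * sqrt(lam / 300) / lam)
  # symmetric chain on long branches reaches the 50:50 stationary state
  star <- ape::stree(300, "star")
  star$edge.length <- rep(60, 300)
  tips <- simulate_ctmc(star, Q2, root_state = 1, seed = 11)
  expect_equal(mean(tips == 2), 0.5, tolerance = 0.12)
  expect_identical(simulate_ctmc(tr, Q2, 1, seed = 4),
                   simulate_ctmc(tr, Q2, 1, seed = 4))
})

test_that("genus pruning keeps one representative species per genus", {
  txt <- "(((Ga_s1:1,Ga_s2:1):1,(Gb_s1:1,Gb_s2:1):1):1,Gc_s1:3);"
  tr <- ape::read.tree(text = txt)
  reps <- prune_to_genus(tr, n_replicates = 5, seed = 2)
  expect_length(reps, 5)
  for (r in reps) {
    expect_setequal(r$tip.label, c("Ga", "Gb", "Gc"))
    expect_equal(ape::Ntip(r), 3)
  }
  r1 <- prune_to_genus(tr, n_replicates = 3, seed = 7)
  r2 <- prune_to_genus(tr, n_replicates = 3, seed = 7)
  expect_identical(lapply(r1, `[[`, "tip.label"),
                   lapply(r2, `[[`, "tip.label"))
  expect_error(prune_to_genus(tr, genera = c("Gx", "Gy")), "no overlap")
})

test_that("model fitting is sane on nested models and degenerate data", {
  g <- gen_trait_tree(60, q = blending_rate_model(), seed = 21)
  fi <- fit_model(g$tree, g$tip_states, model = "independent",
                  n_starts = 1)
  fd <- fit_model(g$tree, g$tip_states, model = "dependent", n_starts = 1)
  expect_gte(fd$loglik, fi$loglik - 1e-6)   # nested models
  expect_equal(fi$n_params, 6); expect_equal(fd$n_params, 24)
  cmp0 <- compare_models(fi, fi)
  expect_equal(cmp0$score, 0)
  # zero trait variation drives all rates to the lower bound
  mono <- stats::setNames(rep(1L, 60), g$tree$tip.label)
  fm <- fit_model(g$tree, mono, model = "independent", n_starts = 1)
  expect_true(all(fm$rate_model$rates <= 1.1e-4))
  # partial model fits too
  fp <- fit_model(g$tree, g$tip_states, model = "partial",
                  independent_motif = 3, n_starts = 1)
  expect_equal(fp$n_params, 10)
  expect_gte(fd$loglik, fp$loglik - 1e-6)
})

test_that("stepping-stone evidence runs and orders models sensibly", {
  g <- gen_trait_tree(40, q = blending_rate_model(), seed = 31)
  cmp <- stepping_stone_evidence(g$tree, g$tip_states, n_stones = 4,
                                 iter_per_stone = 80, warmup = 40,
                                 seed = 2)
  expect_true(is.finite(cmp$logml_ind))
  expect_true(is.finite(cmp$logml_dep))
  expect_identical(cmp$method, "mcmc_ss")
})
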