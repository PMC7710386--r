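#' Motif state coding
#'
#' The presence/absence of the three focal motifs is coded as a 3-bit
#' string in the fixed order (Sp-D, Sp-L, Maze); e.g. `"110"` = both spot
#' motifs present, Maze absent. State indices run 1..8 with
#' `index = 1 + SpD + 2 SpL + 4 Maze`.
#'
#' @return Character vector of the 8 state labels in index order.
#' @export
motif_states <- function() {
  bits <- expand.grid(SpD = 0:1, SpL = 0:1, Maze = 0:1)
  apply(bits, 1, paste, collapse = "")
}

state_bits <- function() {
  as.matrix(expand.grid(SpD = 0:1, SpL = 0:1, Maze = 0:1))
}

#' Encode a trait table into state indices
#'
#' @param traits Data.frame with columns `genus` (or `species`), `Sp-D`,
#'   `Sp-L`, `Maze` in 0/1 coding.
#' @param motifs The three motif columns, in bit order.
#' @return Named integer vector of state indices (1..8).
#' @export
states_from_traits <- function(traits, motifs = c("Sp-D", "Sp-L", "Maze")) {
  stopifnot(all(motifs %in% names(traits)))
  lab <- if ("genus" %in% names(traits)) traits$genus else traits$species
  idx <- 1L + traits[[motifs[1]]] + 2L * traits[[motifs[2]]] +
    4L * traits[[motifs[3]]]
  stats::setNames(as.integer(idx), lab)
}

# dependency sets per model class: deps[[i]] = indices of the motifs whose
# state conditions motif i's gain/loss rates
model_deps <- function(model = c("independent", "dependent", "partial"),
                       independent_motif = 3) {
  model <- match.arg(model)
  switch(model,
    independent = list(integer(0), integer(0), integer(0)),
    dependent = list(c(2L, 3L), c(1L, 3L), c(1L, 2L)),
    partial = {
      im <- as.integer(independent_motif)
      stopifnot(im %in% 1:3)
      others <- setdiff(1:3, im)
      d <- vector("list", 3)
      d[[im]] <- integer(0)
      d[[others[1]]] <- others[2]
      d[[others[2]]] <- others[1]
      d
    })
}

#' Rate model for the 8-state motif chain
#'
#' Defines the parameterization of the 8x8 generator over the joint state
#' of (Sp-D, Sp-L, Maze). Only single-motif changes have non-zero rates.
#' Under the independent model each motif has a context-free gain and loss
#' rate (6 parameters); under the dependent model each motif's gain and
#' loss rate depends on the joint state of the other two motifs (24
#' parameters); under a partial model (`"partial"`, with
#' `independent_motif` naming the uncoupled one) the remaining two motifs
#' depend only on each other (10 parameters).
#'
#' @param model `"independent"`, `"dependent"` or `"partial"`.
#' @param rates Named numeric vector of non-negative rates; defaults to all
#'   0.5. Names follow `gain|loss_<motif>[.<context>]`, e.g.
#'   `gain_Maze.11` = Maze gain when both spot motifs are present.
#' @param independent_motif For partial models: which motif (1 = Sp-D,
#'   2 = Sp-L, 3 = Maze) evolves independently.
#' @param motifs Motif labels in bit order.
#' @return A `rate_model` object.
#' @export
rate_model <- function(model = c("independent", "dependent", "partial"),
                       rates = NULL, independent_motif = 3,
                       motifs = c("Sp-D", "Sp-L", "Maze")) {
  model <- match.arg(model)
  deps <- model_deps(model, independent_motif)
  nm <- unlist(lapply(1:3, function(i) {
    ctx <- if (length(deps[[i]]) == 0) "" else
      paste0(".", apply(as.matrix(expand.grid(
        rep(list(0:1), length(deps[[i]])))), 1, paste, collapse = ""))
    as.vector(outer(c("gain", "loss"), paste0("_", motifs[i], ctx),
                    paste0))
  }))
  if (is.null(rates)) rates <- stats::setNames(rep(0.5, length(nm)), nm)
  if (!setequal(names(rates), nm))
    stop("rate names must be exactly: ", paste(nm, collapse = ", "))
  rates <- rates[nm]
  if (any(rates < 0)) stop("rates must be non-negative")
  # precomputed cell -> parameter map so the generator can be rebuilt
  # cheaply inside optimizer loops
  bits <- state_bits()
  from <- integer(0); to <- integer(0); pidx <- integer(0)
  for (s in 1:8) {
    for (i in 1:3) {
      t_bits <- bits[s, ]
      t_bits[i] <- 1 - t_bits[i]
      tt <- 1 + sum(t_bits * c(1, 2, 4))
      kind <- if (bits[s, i] == 0) "gain" else "loss"
      ctx <- if (length(deps[[i]]) == 0) "" else
        paste0(".", paste(bits[s, deps[[i]]], collapse = ""))
      from <- c(from, s); to <- c(to, tt)
      pidx <- c(pidx, match(paste0(kind, "_", motifs[i], ctx), nm))
    }
  }
  structure(list(model = model, deps = deps, rates = rates,
                 param_names = nm, motifs = motifs,
                 map = list(from = from, to = to, pidx = pidx),
                 independent_motif = if (model == "partial")
                   independent_motif else NA),
            class = "rate_model")
}

# fast generator rebuild from a bare rate vector (same order as
# param_names), using the precomputed map
generator_from_rates <- function(rm, rates) {
  Q <- matrix(0, 8, 8, dimnames = list(motif_states(), motif_states()))
  Q[cbind(rm$map$from, rm$map$to)] <- rates[rm$map$pidx]
  diag(Q) <- -rowSums(Q)
  Q
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model: %s, %d parameters>\n", x$model, length(x$rates)))
  print(round(x$rates, 4))
  invisible(x)
}

#' Build the 8x8 generator matrix of a rate model
#'
#' Off-diagonal entries are non-zero only between states differing in a
#' single motif; rows sum to zero.
#'
#' @param rm A [rate_model()].
#' @return An 8x8 generator matrix with state labels as dimnames.
#' @export
build_generator <- function(rm) {
  stopifnot(inherits(rm, "rate_model"))
  generator_from_rates(rm, unname(rm$rates))
}

postorder_edges <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  list(edge = tree$edge, edge_length = tree$edge.length, tree = tree)
}

root_prior_vec <- function(root, k, Q = NULL, root_state = NULL) {
  if (is.numeric(root) && length(root) == k) return(root / sum(root))
  switch(root,
    uniform = rep(1 / k, k),
    fixed = {
      stopifnot(!is.null(root_state))
      v <- rep(0, k); v[root_state] <- 1; v
    },
    stop("unknown root prior"))
}

stationary_dist <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' CTMC log-likelihood on a tree (Felsenstein pruning)
#'
#' Post-order pruning with a matrix exponential per branch (compiled).
#' Works for any number of states; tip states outside `1..k` (or `NA`)
#' are treated as ambiguous.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip_states Integer state indices, named by tip label or given in
#'   tip order.
#' @param Q Generator matrix (rows sum to zero), or a [rate_model()].
#' @param root Root state distribution: `"uniform"` (default),
#'   `"stationary"`, `"fixed"` (with `root_state`), or a probability
#'   vector.
#' @param root_state State index for `root = "fixed"`.
#' @return Log-likelihood (scalar).
#' @export
ctmc_loglik <- function(tree, tip_states, Q, root = "uniform",
                        root_state = NULL) {
  if (inherits(Q, "rate_model")) Q <- build_generator(Q)
  k <- nrow(Q)
  if (!is.null(names(tip_states)))
    tip_states <- tip_states[tree$tip.label]
  ts <- as.integer(tip_states)
  ts[is.na(ts)] <- 0L
  po <- postorder_edges(tree)
  prior <- if (identical(root, "stationary")) stationary_dist(Q) else
    root_prior_vec(root, k, Q, root_state)
  .ctmc_loglik_cpp(po$edge, po$edge_length, length(tree$tip.label),
                   ts, Q, prior)
}

#' Simulate a CTMC along a tree
#'
#' Exact stochastic simulation: exponential waiting times and embedded
#' jump chain along every branch, from a fixed root state.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param Q Generator matrix or [rate_model()].
#' @param root_state Integer state index at the root.
#' @param seed Optional seed.
#' @return Integer tip states named by tip label, with the full node state
#'   vector as attribute `node_states` and total transition count as
#'   attribute `n_transitions`.
#' @export
simulate_ctmc <- function(tree, Q, root_state = 1, seed = NULL) {
  if (inherits(Q, "rate_model")) Q <- build_generator(Q)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(Q)
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_node <- max(tree_cw$edge)
  states <- integer(n_node)
  root <- setdiff(tree_cw$edge[, 1], tree_cw$edge[, 2])[1]
  states[root] <- root_state
  n_trans <- 0L
  for (e in seq_len(nrow(tree_cw$edge))) {
    s <- states[tree_cw$edge[e, 1]]
    t_rem <- tree_cw$edge.length[e]
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      w <- stats::rexp(1, rate)
      if (w > t_rem) break
      t_rem <- t_rem - w
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(k, 1, prob = probs)
      n_trans <- n_trans + 1L
    }
    states[tree_cw$edge[e, 2]] <- s
  }
  out <- stats::setNames(states[seq_len(n_tip)], tree_cw$tip.label)
  attr(out, "node_states") <- states
  attr(out, "n_transitions") <- n_trans
  out
}

#' Prune a species tree to genus-level replicates
#'
#' Each replicate keeps one randomly chosen species per genus (tips are
#' renamed to the genus); repeating the draw yields a set of genus trees
#' that propagates the within-genus sampling uncertainty. Genus labels are
#' taken from the tip labels (`Genus_species`, split at the first `_`) or
#' supplied explicitly.
#'
#' @param species_tree A `phylo`.
#' @param genera Optional character vector restricting to these genera
#'   (e.g. the genera with trait data).
#' @param n_replicates Number of replicate genus trees.
#' @param seed Seed making the selection sequence reproducible.
#' @param genus_of Optional function mapping tip labels to genus names.
#' @return A list of `phylo` genus trees (class `multiPhylo`).
#' @export
prune_to_genus <- function(species_tree, genera = NULL, n_replicates = 1,
                           seed = NULL, genus_of = NULL) {
  if (is.null(genus_of)) genus_of <- function(x) sub("_.*$", "", x)
  gl <- genus_of(species_tree$tip.label)
  if (!is.null(genera)) {
    keep <- gl %in% genera
    if (!any(keep)) stop("no overlap between tree genera and trait data")
  } else keep <- rep(TRUE, length(gl))
  if (!is.null(seed)) set.seed(seed)
  tips_by_genus <- split(species_tree$tip.label[keep], gl[keep])
  if (length(tips_by_genus) < 2)
    stop("need at least 2 genera with tree coverage")
  reps <- lapply(seq_len(n_replicates), function(r) {
    chosen <- vapply(tips_by_genus, function(tt)
      if (length(tt) == 1L) tt else sample(tt, 1L), character(1))
    tr <- ape::keep.tip(species_tree, unname(chosen))
    tr$tip.label <- names(chosen)[match(tr$tip.label, unname(chosen))]
    tr
  })
  class(reps) <- "multiPhylo"
  reps
}

rescale_unit_height <- function(tree) {
  h <- max(ape::node.depth.edgelength(tree))
  if (h <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Penalized maximum-likelihood fit of a motif rate model
#'
#' Maximizes the pruning log-likelihood over the non-negative rates of the
#' chosen model class, optimizing on the log scale with bounded L-BFGS-B
#' and multiple starts. By default the fit is a MAP estimate under iid
#' exponential rate priors with mean `prior_mean` (the prior family of the
#' Bayesian treatment of this model class): the penalty removes the flat
#' likelihood ridges that otherwise let a rate explode to the bound on the
#' strength of a single tip in a rare context. Set `prior_mean = Inf` for
#' plain maximum likelihood. Reported log-likelihoods and AIC are always
#' the unpenalized values at the optimum.
#'
#' With several replicate genus trees the objective is the mean
#' log-likelihood across replicates (the alternative, one fit per
#' replicate, is available via `per_tree = TRUE`). Trees are rescaled to
#' unit height first, so rates are expected changes per total tree depth.
#'
#' @param trees A `phylo`, `multiPhylo` or list of trees.
#' @param tip_states Named integer state vector (see
#'   [states_from_traits()]); shared across replicate trees.
#' @param model,independent_motif Model class, see [rate_model()].
#' @param root Root prior, see [ctmc_loglik()].
#' @param n_starts Number of optimizer starts.
#' @param seed Seed for start jitter.
#' @param rate_bounds Lower/upper rate bounds (on the unit-height clock).
#' @param prior_mean Mean of the exponential rate prior of the MAP
#'   penalty; `Inf` disables it (plain ML).
#' @param rescale Rescale trees to unit height (default TRUE).
#' @param per_tree Fit each replicate tree separately and return the list
#'   of fits.
#' @return A `rate_fit`: the fitted `rate_model`, `loglik`, `n_params`,
#'   `aic`, optimizer diagnostics. For `per_tree = TRUE`, a list of fits.
#' @export
fit_model <- function(trees, tip_states,
                      model = c("independent", "dependent", "partial"),
                      independent_motif = 3, root = "uniform",
                      n_starts = 2, seed = 1,
                      rate_bounds = c(1e-4, 50), prior_mean = 1,
                      rescale = TRUE, per_tree = FALSE) {
  model <- match.arg(model)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(tr) {
    if (is.null(tr$edge.length)) stop("trees need branch lengths")
    if (rescale) rescale_unit_height(tr) else tr
  })
  if (per_tree)
    return(lapply(seq_along(trees), function(i)
      fit_model(trees[[i]], tip_states, model = model,
                independent_motif = independent_motif, root = root,
                n_starts = n_starts, seed = seed + i,
                rate_bounds = rate_bounds, prior_mean = prior_mean,
                rescale = FALSE)))
  template <- rate_model(model, independent_motif = independent_motif)
  nm <- template$param_names
  # precompute traversal order and aligned tip states per tree
  pre <- lapply(trees, function(tr) {
    po <- postorder_edges(tr)
    ts <- if (!is.null(names(tip_states)))
      tip_states[tr$tip.label] else tip_states
    ts <- as.integer(ts)
    ts[is.na(ts)] <- 0L
    list(edge = po$edge, len = po$edge_length,
         n_tip = length(tr$tip.label), ts = ts)
  })
  obj <- function(logr) {
    Q <- generator_from_rates(template, exp(logr))
    prior <- if (identical(root, "stationary")) stationary_dist(Q) else
      root_prior_vec(root, 8, Q)
    ll <- vapply(pre, function(p)
      .ctmc_loglik_cpp(p$edge, p$len, p$n_tip, p$ts, Q, prior),
      numeric(1))
    nll <- -mean(ll)
    if (is.finite(prior_mean)) nll <- nll + sum(exp(logr)) / prior_mean
    # keep L-BFGS-B on finite ground when the likelihood underflows
    if (!is.finite(nll)) 1e10 else nll
  }
  set.seed(seed)
  lb <- log(rate_bounds[1]); ub <- log(rate_bounds[2])
  starts <- lapply(seq_len(n_starts), function(s)
    pmin(pmax(log(0.5) + stats::rnorm(length(nm), 0, if (s == 1) 0 else 1),
              lb), ub))
  fits <- lapply(starts, function(st)
    tryCatch(stats::optim(st, obj, method = "L-BFGS-B",
                          lower = lb, upper = ub,
                          control = list(maxit = 500)),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("optimizer failed on every start")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  rm <- rate_model(model, stats::setNames(exp(best$par), nm),
                   independent_motif)
  # report the unpenalized log-likelihood at the optimum
  Q_best <- generator_from_rates(template, exp(best$par))
  prior_best <- if (identical(root, "stationary")) stationary_dist(Q_best)
    else root_prior_vec(root, 8, Q_best)
  ll <- mean(vapply(pre, function(p)
    .ctmc_loglik_cpp(p$edge, p$len, p$n_tip, p$ts, Q_best, prior_best),
    numeric(1)))
  structure(list(rate_model = rm, loglik = ll, n_params = length(nm),
                 aic = 2 * length(nm) - 2 * ll,
                 convergence = best$convergence,
                 n_trees = length(trees), root = root),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit: %s, logLik = %.3f over %d tree(s), AIC = %.2f>\n",
              x$rate_model$model, x$loglik, x$n_trees, x$aic))
  invisible(x)
}

evidence_label <- function(score) {
  if (score > 10) "very strong" else if (score > 5) "strong" else
    if (score > 2) "positive" else "none"
}

#' Compare independent and dependent fits
#'
#' Default comparisons use maximized likelihoods: `"aic"` picks the model
#' with the lower AIC; `"lrt"` performs the likelihood-ratio test of the
#' nested pair. `"mcmc_ss"` runs the Bayesian route
#' ([stepping_stone_evidence()]) and compares log marginal likelihoods. In
#' every case the reported `score` is twice the (marginal or maximized)
#' log-likelihood difference dependent minus independent, with evidence
#' labels "positive" (> 2), "strong" (> 5) and "very strong" (> 10).
#'
#' @param fit_ind,fit_dep `rate_fit`s of the independent and dependent
#'   model on the same data.
#' @param method `"aic"` (default), `"lrt"` or `"mcmc_ss"`.
#' @param trees,tip_states Required for `"mcmc_ss"` (the fits do not carry
#'   the data); passed to [stepping_stone_evidence()].
#' @param ... For `"mcmc_ss"`: further arguments to
#'   [stepping_stone_evidence()].
#' @return A `model_comparison` list: `score`, `winner`, `evidence`,
#'   per-method details.
#' @export
compare_models <- function(fit_ind, fit_dep, method = c("aic", "lrt",
                                                        "mcmc_ss"),
                           trees = NULL, tip_states = NULL, ...) {
  method <- match.arg(method)
  if (method == "mcmc_ss") {
    if (is.null(trees) || is.null(tip_states))
      stop("mcmc_ss comparison needs trees and tip_states")
    return(stepping_stone_evidence(trees, tip_states, ...))
  }
  stopifnot(inherits(fit_ind, "rate_fit"), inherits(fit_dep, "rate_fit"))
  if (fit_ind$n_trees != fit_dep$n_trees)
    stop("fits are not on the same data")
  score <- 2 * (fit_dep$loglik - fit_ind$loglik)
  df <- fit_dep$n_params - fit_ind$n_params
  if (method == "aic") {
    winner <- if (fit_dep$aic < fit_ind$aic) "dependent" else "independent"
    detail <- list(aic_ind = fit_ind$aic, aic_dep = fit_dep$aic)
  } else {
    p <- stats::pchisq(max(score, 0), df = df, lower.tail = FALSE)
    winner <- if (p < 0.05) "dependent" else "independent"
    detail <- list(lrt_stat = score, df = df, p_value = p)
  }
  structure(c(list(score = score, winner = winner,
                   evidence = evidence_label(score), method = method),
              detail),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison [%s]: score = %.2f, winner = %s (%s)>\n",
              x$method, x$score, x$winner, x$evidence))
  invisible(x)
}

#' Maze gain and loss rates by spot-motif context
#'
#' Extracts the eight transition rates between "without Maze" and "with
#' Maze" from a fitted generator: gains `a` (neither spot motif), `b`
#' (Sp-D only), `c` (Sp-L only), `d` (both), and the corresponding losses
#' `e`-`h`. For an independent-model fit `a = b = c = d` and
#' `e = f = g = h` by construction.
#'
#' @param fit A `rate_fit` or `rate_model`.
#' @return Named numeric vector `a`-`h`.
#' @export
maze_rate_summary <- function(fit) {
  rm <- if (inherits(fit, "rate_fit")) fit$rate_model else fit
  stopifnot(inherits(rm, "rate_model"))
  Q <- build_generator(rm)
  bits <- state_bits()
  ctxs <- list(a = c(0, 0), b = c(1, 0), c = c(0, 1), d = c(1, 1))
  out <- numeric(0)
  for (nm in names(ctxs)) {
    ctx <- ctxs[[nm]]
    from <- 1 + ctx[1] + 2 * ctx[2]          # Maze = 0
    to <- from + 4                            # Maze = 1
    out[nm] <- Q[from, to]
  }
  for (i in seq_along(ctxs)) {
    ctx <- ctxs[[i]]
    from <- 1 + ctx[1] + 2 * ctx[2] + 4
    to <- from - 4
    out[c("e", "f", "g", "h")[i]] <- Q[from, to]
  }
  out
}
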