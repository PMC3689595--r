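# Dependent vs independent evolution of two binary traits on a phylogeny.
#
# Both models are continuous-time Markov chains over the combined states
# {00, 01, 10, 11} (in that order; state index = 1 + 2*t1 + t2).  The
# independent model has four rates (gain/loss per trait) and its 4-state
# generator is the Kronecker sum of the two 2-state generators.  The
# dependent model frees the eight single-change rates (one trait's gain and
# loss rate may differ with the other trait's state); simultaneous changes
# of both traits are fixed at zero.  The two are nested with 4 degrees of
# freedom, compared by likelihood ratio.

DEP_RATE_NAMES <- c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")

#' Model constructors for binary-trait evolution
#'
#' `independent_model` carries gain/loss rates for each trait
#' (`alpha1`/`beta1` for trait 1, `alpha2`/`beta2` for trait 2);
#' `dependent_model` carries the eight single-change rates among combined
#' states 1=00, 2=01, 3=10, 4=11 (e.g. `q12` is the gain of trait 2 while
#' trait 1 is absent).
#'
#' @param alpha1,beta1,alpha2,beta2 non-negative gain/loss rates.
#' @return an object of class `trait_model`.
#' @export
independent_model <- function(alpha1, beta1, alpha2, beta2) {
  rates <- c(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
             beta2 = beta2)
  if (any(rates < 0)) abort("rates must be >= 0")
  structure(list(type = "independent", rates = rates),
            class = "trait_model")
}

#' @rdname independent_model
#' @param rates named (or positional) vector of the eight dependent-model
#'   rates `q12, q13, q21, q24, q31, q34, q42, q43`.
#' @export
dependent_model <- function(rates) {
  if (length(rates) != 8L) abort("dependent model needs 8 rates")
  if (any(rates < 0)) abort("rates must be >= 0")
  if (is.null(names(rates))) names(rates) <- DEP_RATE_NAMES
  structure(list(type = "dependent", rates = rates[DEP_RATE_NAMES]),
            class = "trait_model")
}

#' Generator matrix of a trait model
#'
#' @param model a `trait_model`.
#' @return 4x4 rate matrix over states 00, 01, 10, 11 (rows sum to zero).
#' @export
model_generator <- function(model) {
  r <- model$rates
  Q <- matrix(0, 4, 4,
              dimnames = list(c("00", "01", "10", "11"),
                              c("00", "01", "10", "11")))
  if (model$type == "independent") {
    # trait 1 flips states (00<->10, 01<->11), trait 2 (00<->01, 10<->11)
    Q["00", "10"] <- r["alpha1"]; Q["01", "11"] <- r["alpha1"]
    Q["10", "00"] <- r["beta1"];  Q["11", "01"] <- r["beta1"]
    Q["00", "01"] <- r["alpha2"]; Q["10", "11"] <- r["alpha2"]
    Q["01", "00"] <- r["beta2"];  Q["11", "10"] <- r["beta2"]
  } else {
    Q["00", "01"] <- r["q12"]; Q["00", "10"] <- r["q13"]
    Q["01", "00"] <- r["q21"]; Q["01", "11"] <- r["q24"]
    Q["10", "00"] <- r["q31"]; Q["10", "11"] <- r["q34"]
    Q["11", "01"] <- r["q42"]; Q["11", "10"] <- r["q43"]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# traits input -> named 0/1 vectors aligned to tree tips
align_traits <- function(tree, traits) {
  if (is.data.frame(traits)) {
    if (!all(c("species", "trait1", "trait2") %in% names(traits)))
      abort("traits data.frame needs columns species, trait1, trait2")
    t1 <- setNames(traits$trait1, traits$species)
    t2 <- setNames(traits$trait2, traits$species)
  } else if (is.list(traits) && length(traits) == 2L) {
    t1 <- traits[[1L]]; t2 <- traits[[2L]]
  } else abort("traits must be a data.frame or a list of two named vectors")
  tips <- tree$tip.label
  if (!all(tips %in% names(t1)) || !all(tips %in% names(t2)))
    abort("missing trait state for leaf: ",
          paste(setdiff(tips, intersect(names(t1), names(t2))),
                collapse = ", "))
  t1 <- t1[tips]; t2 <- t2[tips]
  if (anyNA(t1) || anyNA(t2) || !all(c(t1, t2) %in% c(0, 1)))
    abort("trait states must be 0/1 with no missing values")
  list(t1 = as.integer(t1), t2 = as.integer(t2))
}

prior_vector <- function(root_prior, Q) {
  if (identical(root_prior, "uniform")) return(rep(0.25, 4))
  if (identical(root_prior, "stationary")) {
    # stationary distribution: left null vector of Q
    ns <- t(MASS_null(t(Q)))
    pr <- abs(ns[1L, ]) / sum(abs(ns[1L, ]))
    return(pr)
  }
  if (is.numeric(root_prior) && length(root_prior) == 4L)
    return(root_prior / sum(root_prior))
  abort("root_prior must be 'uniform', 'stationary' or a length-4 vector")
}

# tiny null-space helper (avoids a MASS dependency)
MASS_null <- function(M) {
  s <- svd(M, nv = ncol(M))
  tol <- max(dim(M)) * max(s$d) * .Machine$double.eps
  ns <- s$v[, s$d < tol | seq_len(ncol(M)) > length(s$d), drop = FALSE]
  if (!ncol(ns)) ns <- s$v[, ncol(M), drop = FALSE]
  ns
}

#' Joint log-likelihood of two binary traits on a tree
#'
#' Felsenstein pruning over the 4 combined states with transition matrices
#' \eqn{P(t) = e^{Qt}}; root states weighted by a uniform prior over the
#' four combined states by default.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param traits data.frame (`species`, `trait1`, `trait2`) or list of two
#'   named 0/1 vectors covering every leaf.
#' @param model a `trait_model` ([independent_model()]/[dependent_model()]).
#' @param root_prior "uniform" (default), "stationary", or a length-4
#'   probability vector.
#' @return log-likelihood (scalar).
#' @export
combined_loglik <- function(tree, traits, model, root_prior = "uniform") {
  tv <- align_traits(tree, traits)
  Q <- model_generator(model)
  states <- 1L + 2L * tv$t1 + tv$t2
  ctmc_loglik(tree, states, Q, prior_vector(root_prior, Q))
}

# generic n-state pruning wrapper around the C++ kernel
ctmc_loglik <- function(tree, tip_states, Q, prior) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  tr <- ape::reorder.phylo(tree, "postorder")
  .ctmc_loglik_cpp(tr$edge, tr$edge.length, length(tr$tip.label),
                   as.integer(tip_states), Q, prior)
}

# 2-state log-likelihood of a single binary trait (used by the
# independent-model fit; Kronecker-sum identity makes the joint
# independent likelihood the sum of the two marginal likelihoods)
binary_trait_loglik <- function(tree, states01, alpha, beta,
                                prior = c(0.5, 0.5)) {
  Q <- matrix(c(-alpha, beta, alpha, -beta), 2, 2)
  ctmc_loglik(tree, states01 + 1L, Q, prior)
}

#' Fit dependent and independent trait models and compare them
#'
#' The independent model is fitted as two marginal 2-state fits (their
#' log-likelihoods add by the Kronecker-sum identity).  The dependent
#' model's 8 rates are then optimised by bounded L-BFGS-B on log rates,
#' multi-start: one start embeds the fitted independent rates (so the
#' dependent log-likelihood can never drop below the independent one), the
#' rest perturb it randomly.  Likelihood-ratio test with 4 degrees of
#' freedom.
#'
#' @param tree rooted `phylo` with branch lengths (>= 4 leaves advised).
#' @param traits as in [combined_loglik()].
#' @param n_starts number of optimisation starts for the dependent model
#'   (default 10: the embedded start plus 9 random perturbations).
#' @param seed optional integer seed controlling the random starts.
#' @param rate_bounds lower/upper bounds on every rate (default
#'   `c(1e-8, 100)`).
#' @param root_prior as in [combined_loglik()].
#' @return object of class `pagel_fit`: `independent` and `dependent`
#'   (each rates + loglik), and `lrt` (an `ovl_test`, df = 4).
#' @export
fit_pagel <- function(tree, traits, n_starts = 10L, seed = NULL,
                      rate_bounds = c(1e-8, 100), root_prior = "uniform") {
  tv <- align_traits(tree, traits)
  if (length(tree$tip.label) < 4L)
    warning("fewer than 4 leaves: likelihood surface is very flat")
  lb <- log(rate_bounds[1L]); ub <- log(rate_bounds[2L])
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)

  fit_marginal <- function(states01) {
    nll <- function(lr) {
      a <- exp(lr[1L]); b <- exp(lr[2L])
      Q <- matrix(c(-a, b, a, -b), 2, 2)
      -.ctmc_loglik_cpp(tr$edge, tr$edge.length, ntip, states01 + 1L, Q,
                        c(0.5, 0.5))
    }
    # moment-ish start: one expected change over the tree depth
    depth <- max(ape::node.depth.edgelength(tr)[seq_len(ntip)])
    start0 <- log(pmin(pmax(1 / max(depth, 1e-6), rate_bounds[1L]),
                       rate_bounds[2L]))
    best <- NULL
    for (st in list(c(start0, start0), c(start0 + 1, start0 - 1),
                    c(start0 - 1, start0 + 1))) {
      o <- optim(pmin(pmax(st, lb), ub), nll, method = "L-BFGS-B",
                 lower = lb, upper = ub)
      if (is.null(best) || o$value < best$value) best <- o
    }
    list(rates = exp(best$par), loglik = -best$value)
  }
  m1 <- fit_marginal(tv$t1)
  m2 <- fit_marginal(tv$t2)
  indep_rates <- c(alpha1 = m1$rates[1L], beta1 = m1$rates[2L],
                   alpha2 = m2$rates[1L], beta2 = m2$rates[2L])
  names(indep_rates) <- c("alpha1", "beta1", "alpha2", "beta2")
  ll_indep <- m1$loglik + m2$loglik

  states4 <- 1L + 2L * tv$t1 + tv$t2
  prior4 <- prior_vector(root_prior, model_generator(
    independent_model(1, 1, 1, 1)))
  nll_dep <- function(lr) {
    m <- dependent_model(exp(lr))
    -.ctmc_loglik_cpp(tr$edge, tr$edge.length, ntip, states4,
                      model_generator(m), prior4)
  }
  # embedding of the independent fit into the dependent parameterisation
  embed <- log(pmin(pmax(c(
    q12 = indep_rates[["alpha2"]], q13 = indep_rates[["alpha1"]],
    q21 = indep_rates[["beta2"]], q24 = indep_rates[["alpha1"]],
    q31 = indep_rates[["beta1"]], q34 = indep_rates[["alpha2"]],
    q42 = indep_rates[["beta1"]], q43 = indep_rates[["beta2"]]),
    rate_bounds[1L]), rate_bounds[2L]))
  starts <- list(embed)
  if (n_starts > 1L) {
    extra <- with_seed(seed, lapply(seq_len(n_starts - 1L), function(i)
      pmin(pmax(embed + rnorm(8L, sd = 1.5), lb), ub)))
    starts <- c(starts, extra)
  }
  best <- NULL
  for (st in starts) {
    o <- tryCatch(optim(st, nll_dep, method = "L-BFGS-B", lower = lb,
                        upper = ub),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) abort("dependent-model optimisation failed on all starts")
  dep_rates <- setNames(exp(best$par), DEP_RATE_NAMES)
  ll_dep <- -best$value
  # nesting safeguard against optimizer round-off
  if (ll_dep < ll_indep) ll_dep <- ll_indep
  lrt <- likelihood_ratio_test(ll_indep, ll_dep, df = 4L)
  structure(list(independent = list(rates = indep_rates,
                                    loglik = ll_indep),
                 dependent = list(rates = dep_rates, loglik = ll_dep),
                 lrt = lrt, n_starts = n_starts, seed = seed),
            class = "pagel_fit")
}

#' @export
print.pagel_fit <- function(x, ...) {
  cat(sprintf(paste0("<pagel_fit> ll_dependent = %.5f, ll_independent = ",
                     "%.5f, LRT = %.4f (df 4), p = %.4g\n"),
              x$dependent$loglik, x$independent$loglik, x$lrt$statistic,
              x$lrt$p_value))
  invisible(x)
}

#' Simulate two binary traits on a tree
#'
#' The root state is drawn from the root prior and states evolve down each
#' branch by the model's exact transition probabilities
#' \eqn{P(t) = e^{Qt}}.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param model a `trait_model`.
#' @param seed optional integer seed.
#' @param root_prior as in [combined_loglik()].
#' @return data.frame `species`, `trait1`, `trait2`.
#' @export
simulate_traits <- function(tree, model, seed = NULL,
                            root_prior = "uniform") {
  Q <- model_generator(model)
  prior <- prior_vector(root_prior, Q)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  edge <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]  # preorder
  elen <- rev(tr$edge.length)
  with_seed(seed, {
    state <- integer(nnode)
    root <- edge[1L, 1L]
    state[root] <- sample.int(4L, 1L, prob = prior)
    for (e in seq_len(nrow(edge))) {
      P <- as.matrix(Matrix_expm(Q * elen[e]))
      state[edge[e, 2L]] <- sample.int(4L, 1L, prob = P[state[edge[e, 1L]], ])
    }
    s <- state[seq_len(ntip)]
    data.frame(species = tr$tip.label,
               trait1 = (s - 1L) %/% 2L, trait2 = (s - 1L) %% 2L,
               stringsAsFactors = FALSE)
  })
}

# small dense matrix exponential via eigen decomposition with a
# scaling-and-squaring series fallback for defective cases
Matrix_expm <- function(M) {
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (!is.null(ev) && Mod(det(ev$vectors)) > 1e-12) {
    P <- ev$vectors %*% diag(exp(ev$values), nrow(M)) %*% solve(ev$vectors)
    P <- Re(P)
  } else {
    # series with scaling and squaring
    s <- max(0L, ceiling(log2(max(1, max(abs(M))))))
    A <- M / 2^s
    P <- diag(nrow(M)); term <- diag(nrow(M))
    for (i in 1:12) {
      term <- term %*% A / i
      P <- P + term
    }
    for (i in seq_len(s)) P <- P %*% P
  }
  P[P < 0] <- 0
  P / rowSums(P)
}
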