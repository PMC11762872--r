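# 12-state substitution models and maximum likelihood on encoded
# alignments: Felsenstein pruning, per-edge Brent branch-length
# optimization, NNI (exhaustive enumeration for small taxon sets),
# and direct GTR12 estimation from the data.

#' Equal-rates 12-state substitution model (JC12)
#'
#' All exchangeabilities equal, uniform stationary distribution; rate
#' normalized to one expected substitution per site per unit time.
#' @param table translation table fixing the state order.
#' @return list with `name`, `Q`, `pi`, `states`; class `ss_subst_model`.
#' @export
model_jc12 <- function(table = translation_table()) {
  states <- table$symbol
  Q <- matrix(1 / 11, 12, 12, dimnames = list(states, states))
  diag(Q) <- -1
  obj <- list(name = "JC12", Q = Q, pi = stats::setNames(rep(1 / 12, 12), states),
              states = states)
  class(obj) <- "ss_subst_model"
  obj
}

#' General time-reversible 12-state model (GTR12)
#'
#' Built from 66 exchangeabilities (upper triangle, row-major) and a
#' stationary distribution; normalized to one expected substitution per
#' site per unit time.
#' @param rates numeric vector of 66 positive exchangeabilities.
#' @param pi stationary distribution (length 12, sums to 1).
#' @param table translation table fixing the state order.
#' @return an `ss_subst_model`.
#' @export
model_gtr12 <- function(rates, pi = rep(1 / 12, 12),
                        table = translation_table()) {
  states <- table$symbol
  stopifnot(length(rates) == 66, all(rates > 0),
            length(pi) == 12, abs(sum(pi) - 1) < 1e-8, all(pi > 0))
  R <- matrix(0, 12, 12)
  R[upper.tri(R)] <- rates
  R <- R + t(R)
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(states, states)
  # eigen-decomposition of the pi-symmetrized generator, cached for P(t)
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
  obj <- list(name = "GTR12", Q = Q, pi = stats::setNames(pi, states),
              states = states, rates = rates,
              eig = list(values = ev$values,
                         right = diag(1 / sp) %*% ev$vectors,
                         left = t(ev$vectors) %*% diag(sp)))
  class(obj) <- "ss_subst_model"
  obj
}

#' Transition probability matrix P(t) = exp(Qt)
#' @param model an `ss_subst_model`.
#' @param t branch length (>= 0).
#' @return row-stochastic 12x12 matrix.
#' @export
prob_matrix <- function(model, t) {
  if (t < 0) stopf("prob_matrix: negative branch length")
  if (model$name == "JC12") {
    e <- exp(-12 * t / 11)
    ps <- 1 / 12 + 11 / 12 * e
    pd <- 1 / 12 - 1 / 12 * e
    P <- matrix(pd, 12, 12, dimnames = list(model$states, model$states))
    diag(P) <- ps
    return(P)
  }
  P <- model$eig$right %*% diag(exp(model$eig$values * t)) %*% model$eig$left
  P[P < 0] <- 0
  dimnames(P) <- list(model$states, model$states)
  P
}

msa_patterns <- function(msa, states) {
  m <- msa_matrix(msa)
  key <- apply(m, 2, paste, collapse = "\r")
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = m[, first, drop = FALSE], weights = as.numeric(tab))
}

# conditional likelihood vectors at a tip: unit vector, or ones for
# gap/wildcard (missing data)
tip_partials <- function(sym, states) {
  npat <- length(sym)
  Lmat <- matrix(0, length(states), npat)
  idx <- match(sym, states)
  miss <- is.na(idx)
  Lmat[, miss] <- 1
  Lmat[cbind(idx[!miss], which(!miss))] <- 1
  Lmat
}

#' Log-likelihood of an encoded alignment on a tree
#'
#' Felsenstein pruning over site patterns, summed in log space with
#' per-node scaling. Gaps and wildcards are missing data (summed over
#' states). For a reversible model the virtual root placement does not
#' change the value.
#'
#' @param msa data.frame with columns `id`, `symbols`.
#' @param tree `ape::phylo` with branch lengths; tip labels must match the
#'   alignment ids.
#' @param model an `ss_subst_model`.
#' @return total log-likelihood.
#' @export
log_likelihood <- function(msa, tree, model = model_jc12()) {
  if (!setequal(tree$tip.label, msa$id))
    stopf("log_likelihood: tree labels do not match alignment ids")
  loglik_engine(ll_data(msa, model), tree, model)
}

# precomputed site patterns + per-taxon tip partials, reusable across
# many likelihood evaluations of the same alignment
ll_data <- function(msa, model) {
  pat <- msa_patterns(msa, model$states)
  tips <- lapply(seq_len(nrow(msa)), function(i)
    tip_partials(pat$patterns[i, ], model$states))
  names(tips) <- msa$id
  list(weights = pat$weights, tips = tips, npat = ncol(pat$patterns))
}

loglik_engine <- function(data, tree, model) {
  if (is.null(tree$edge.length)) stopf("log_likelihood: tree has no branch lengths")
  if (any(tree$edge.length < 0)) stopf("log_likelihood: negative branch length")
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  partial <- vector("list", ntip + tr$Nnode)
  scalelog <- rep(0, data$npat)
  for (i in seq_len(ntip)) {
    p <- data$tips[[tr$tip.label[i]]]
    if (is.null(p)) stopf("log_likelihood: tree labels do not match alignment ids")
    partial[[i]] <- p
  }
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    P <- prob_matrix(model, tr$edge.length[e])
    contrib <- P %*% partial[[child]]
    if (is.null(partial[[parent]])) partial[[parent]] <- contrib
    else {
      partial[[parent]] <- partial[[parent]] * contrib
      mx <- apply(partial[[parent]], 2, max)
      mx[mx == 0] <- 1
      partial[[parent]] <- sweep(partial[[parent]], 2, mx, `/`)
      scalelog <- scalelog + log(mx)
    }
  }
  root <- tr$edge[nrow(tr$edge), 1]
  sitelik <- as.numeric(model$pi %*% partial[[root]])
  sum(data$weights * (log(sitelik) + scalelog))
}

optimize_branch_lengths <- function(msa, tree, model, tol = 1e-6,
                                    max_sweeps = 3, upper = 10,
                                    data = NULL) {
  if (is.null(data)) data <- ll_data(msa, model)
  tree <- stats::reorder(tree, "postorder")
  ll <- loglik_engine(data, tree, model)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tr <- tree
        tr$edge.length[e] <- x
        loglik_engine(data, tr, model)
      }
      opt <- stats::optimize(f, interval = c(0, upper), maximum = TRUE,
                             tol = tol)
      if (opt$objective > ll + tol) {
        tree$edge.length[e] <- opt$maximum
        ll <- opt$objective
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(tree = tree, loglik = ll)
}

#' Maximum-likelihood tree search for the 12-state model
#'
#' Starts from the NJ tree on JC12 distances, optimizes branch lengths by
#' per-edge Brent search (tolerance 1e-6), and searches topologies either
#' exhaustively (small taxon sets) or by first-improvement NNI.
#'
#' @param msa data.frame with columns `id`, `symbols`.
#' @param model an `ss_subst_model`.
#' @param exhaustive_max exhaustive enumeration is used up to this many
#'   taxa; NNI beyond.
#' @param tol branch-length optimization tolerance.
#' @return list with `tree` (branch-length-optimized `phylo`) and `loglik`.
#' @export
ml_search <- function(msa, model = model_jc12(), exhaustive_max = 6,
                      tol = 1e-6) {
  n <- nrow(msa)
  if (n < 3) stopf("ml_search requires >= 3 taxa")
  data <- ll_data(msa, model)
  if (n <= exhaustive_max) {
    trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = msa$id)
    best <- NULL
    for (k in seq_along(trees)) {
      tr <- trees[[k]]  # [[ expands the compressed tip labels
      tr$edge.length <- rep(0.1, nrow(tr$edge))
      fit <- optimize_branch_lengths(msa, tr, model, tol = tol, data = data)
      if (is.null(best) || fit$loglik > best$loglik + 1e-9) best <- fit
    }
    return(best)
  }
  start <- neighbor_joining(dist_matrix(msa, "jc12"))
  start$edge.length[start$edge.length <= 0] <- 1e-6
  best <- optimize_branch_lengths(msa, start, model, tol = tol, data = data)
  repeat {
    improved <- FALSE
    nbrs <- phangorn::nni(best$tree)
    for (k in seq_along(nbrs)) {
      nb <- nbrs[[k]]
      nb$edge.length <- rep(0.1, nrow(nb$edge))
      fit <- optimize_branch_lengths(msa, nb, model, tol = tol,
                                     max_sweeps = 2, data = data)
      if (fit$loglik > best$loglik + 1e-6) {
        best <- fit
        improved <- TRUE
        break  # first improvement
      }
    }
    if (!improved) break
  }
  best
}

#' Estimate a GTR12 model from the data
#'
#' Stationary frequencies are taken from the alignment (with a small
#' pseudocount); exchangeabilities are found by direct likelihood
#' maximization (L-BFGS-B on log-rates) on a fixed tree.
#'
#' @param msa data.frame with columns `id`, `symbols`.
#' @param tree tree with branch lengths (default: NJ on JC12 distances).
#' @param maxit optimizer iteration budget.
#' @param table translation table fixing the state order.
#' @return an `ss_subst_model` of name `GTR12`.
#' @export
estimate_gtr12 <- function(msa, tree = NULL, maxit = 50,
                           table = translation_table()) {
  if (is.null(tree)) {
    tree <- neighbor_joining(dist_matrix(msa, "jc12"))
    tree$edge.length[tree$edge.length <= 0] <- 1e-6
  }
  states <- table$symbol
  syms <- unlist(lapply(msa$symbols, chars))
  counts <- tabulate(match(syms, states), nbins = 12) + 1
  pi <- counts / sum(counts)
  obj <- function(logr) {
    m <- model_gtr12(exp(logr), pi = pi, table = table)
    -log_likelihood(msa, tree, m)
  }
  fit <- stats::optim(rep(0, 66), obj, method = "L-BFGS-B",
                      lower = -8, upper = 8,
                      control = list(maxit = maxit))
  model_gtr12(exp(fit$par), pi = pi, table = table)
}
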