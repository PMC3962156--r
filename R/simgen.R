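# Simulated data generation: Kingman coalescent genealogies under constant
# size or exponential growth, GTR+Gamma sequence evolution along trees,
# infinite-sites mutation dropping, and the Robinson-Foulds tree distance.
#
# Time convention: coalescent branch lengths are in units of 4Ne
# generations (the convention of Hudson's ms), so E[TMRCA] = 1 - 1/n and
# the expected number of infinite-sites segregating sites is theta * a_n
# with a_n the (n-1)-th harmonic number. theta = 4*Ne*mu is expressed per
# locus (per kilobase for 1 kb loci).

# Demography ------------------------------------------------------------------

#' Demographic model for the coalescent sampler
#'
#' Constant population size, or exponential growth at rate `growth_rate`
#' (ms's -G convention: looking backward in time the relative population
#' size is `exp(-growth_rate * t)` until `onset_time`, the time at which
#' the expansion started, and constant earlier than that).
#'
#' @param model `"constant"` or `"growth"`.
#' @param growth_rate exponential growth rate (per 4Ne generations;
#'   positive = expansion toward the present).
#' @param onset_time time of expansion onset, backward from the present,
#'   in units of 4Ne generations.
#' @return an object of class `demography`.
#' @export
demography <- function(model = c("constant", "growth"), growth_rate = 0,
                       onset_time = Inf) {
  model <- match.arg(model)
  if (model == "growth") {
    if (!is.finite(growth_rate)) stop("growth_rate must be finite")
    if (onset_time < 0) stop("onset_time must be >= 0")
  } else {
    growth_rate <- 0
    onset_time <- Inf
  }
  structure(list(model = model, growth_rate = growth_rate,
                 onset_time = onset_time), class = "demography")
}

# cumulative coalescent intensity multiplier G(t) = int_0^t 1/nu(s) ds for
# nu(s) = exp(-alpha*s) (s <= tau), exp(-alpha*tau) (s > tau), and its
# inverse; alpha = 0 collapses to the identity.
.demog_G <- function(t, alpha, tau) {
  if (alpha == 0) return(t)
  g_tau <- if (is.finite(tau)) (exp(alpha * tau) - 1) / alpha else Inf
  ifelse(t <= tau, (exp(alpha * t) - 1) / alpha,
         g_tau + (t - tau) * exp(alpha * tau))
}

.demog_G_inv <- function(c_, alpha, tau) {
  if (alpha == 0) return(c_)
  g_tau <- if (is.finite(tau)) (exp(alpha * tau) - 1) / alpha else Inf
  if (c_ <= g_tau) {
    log1p(alpha * c_) / alpha
  } else {
    tau + (c_ - g_tau) * exp(-alpha * tau)
  }
}

#' Sample a coalescent genealogy
#'
#' Standard Kingman coalescent: with `k` active lineages the waiting time
#' to the next coalescence is exponential with rate `k(k-1)` (in 4Ne
#' units). Under growth the waiting times are rescaled through the inverse
#' cumulative intensity of the exponential population-size trajectory.
#'
#' @param n number of sampled lineages (>= 2).
#' @param demog a [demography()].
#' @param seed optional integer seed.
#' @return an ultrametric [ape::phylo] tree with branch lengths in 4Ne
#'   units and tips `t1..tn`.
#' @export
sample_coalescent_tree <- function(n, demog = demography(), seed = NULL) {
  if (n < 2L) stop("n must be >= 2")
  stopifnot(inherits(demog, "demography"))
  if (!is.null(seed)) set.seed(seed)
  alpha <- demog$growth_rate
  tau <- demog$onset_time
  n <- as.integer(n)
  n_nodes <- 2L * n - 1L
  node_time <- numeric(n_nodes)
  edge <- matrix(0L, 2L * n - 2L, 2L)
  edge_len <- numeric(2L * n - 2L)
  active <- seq_len(n)
  t_now <- 0
  e <- 0L
  for (k in n:2L) {
    w <- rexp(1L, rate = k * (k - 1L))
    if (alpha == 0) {
      t_now <- t_now + w
    } else {
      t_now <- .demog_G_inv(.demog_G(t_now, alpha, tau) + w, alpha, tau)
    }
    pair <- sample(length(active), 2L)
    parent <- 2L * n - (n - k + 1L)   # root ends up as node n+1
    node_time[parent] <- t_now
    for (ch in active[pair]) {
      e <- e + 1L
      edge[e, ] <- c(parent, ch)
      edge_len[e] <- t_now - node_time[ch]
    }
    active <- c(active[-pair], parent)
  }
  tr <- structure(list(edge = edge, edge.length = edge_len,
                       tip.label = paste0("t", seq_len(n)),
                       Nnode = n - 1L), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Scale all branch lengths of a tree
#'
#' Multiplying coalescent branch lengths (4Ne units) by 0.01 converts them
#' to expected substitutions per site for a setup where theta = 10
#' mutations per kilobase per 4Ne generations.
#'
#' @param tree an [ape::phylo] tree.
#' @param factor positive scale factor.
#' @return the rescaled tree.
#' @export
scale_branches <- function(tree, factor) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(factor) || factor <= 0) stop("factor must be > 0")
  tree$edge.length <- tree$edge.length * factor
  tree
}

# Infinite-sites mutations -----------------------------------------------------

#' Drop infinite-sites mutations on a coalescent genealogy
#'
#' Poisson mutations at rate `theta` per unit branch length (4Ne units),
#' each creating a new segregating column whose derived state 1 marks the
#' leaves under the mutated branch. This is the mutation model of the
#' classical summary-statistic estimators: E[S] = theta * a_n.
#'
#' @param tree a coalescent tree in 4Ne units (see
#'   [sample_coalescent_tree()]).
#' @param theta population mutation rate 4*Ne*mu per locus.
#' @param seed optional integer seed.
#' @return a [binary_matrix()] with known ancestral states (0 = ancestral);
#'   rows follow the tree's tip order.
#' @export
simulate_infinite_sites <- function(tree, theta, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (theta < 0) stop("theta must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  lens <- tree$edge.length
  m <- rpois(1L, theta * sum(lens))
  if (m == 0L) {
    bm <- matrix(integer(), nrow = n, ncol = 0L,
                 dimnames = list(tree$tip.label, NULL))
    return(binary_matrix(bm, ancestral = "known"))
  }
  hit <- sample.int(length(lens), m, replace = TRUE, prob = lens)
  desc <- phangorn::Descendants(tree, tree$edge[, 2L], type = "tips")
  mat <- matrix(0L, nrow = n, ncol = m,
                dimnames = list(tree$tip.label, NULL))
  for (j in seq_len(m)) {
    mat[desc[[hit[[j]]]], j] <- 1L
  }
  binary_matrix(mat, ancestral = "known")
}

# GTR + Gamma -------------------------------------------------------------------

#' GTR+Gamma substitution model
#'
#' General time-reversible model with discrete-Gamma rate heterogeneity.
#' The rate matrix is normalised to one expected substitution per unit
#' branch length. The packaged defaults are typical empirical estimates
#' for a large multi-species nucleotide alignment; all values are
#' configurable.
#'
#' @param rates six symmetric exchangeabilities, order AC, AG, AT, CG, CT,
#'   GT (GT is conventionally 1).
#' @param base_freq four stationary base frequencies (A, C, G, T; sum 1).
#' @param alpha Gamma shape parameter (`Inf` = no rate heterogeneity).
#' @param ncat number of discrete mean-rate categories (default 4).
#' @return an object of class `gtr_model`.
#' @export
gtr_model <- function(rates = c(AC = 1.6, AG = 4.3, AT = 1.2,
                                CG = 1.1, CT = 5.9, GT = 1.0),
                      base_freq = c(A = 0.27, C = 0.22, G = 0.26,
                                    T = 0.25),
                      alpha = 0.5, ncat = 4L) {
  rates <- unname(rates)
  base_freq <- unname(base_freq)
  if (length(rates) != 6L || any(rates <= 0)) {
    stop("rates must be six positive exchangeabilities")
  }
  if (length(base_freq) != 4L || any(base_freq <= 0)) {
    stop("base_freq must be four positive frequencies")
  }
  if (abs(sum(base_freq) - 1) > 1e-8) stop("base frequencies must sum to 1")
  if (!(is.infinite(alpha) || alpha > 0)) stop("alpha must be > 0")
  Q <- matrix(0, 4L, 4L, dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- rates[k] * base_freq[j]
    Q[j, i] <- rates[k] * base_freq[i]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * base_freq)   # one expected substitution per unit
  structure(list(Q = Q, base_freq = base_freq, rates = rates,
                 alpha = alpha, ncat = as.integer(ncat)),
            class = "gtr_model")
}

# mean-rate discretisation of the Gamma(alpha, alpha) distribution
.discrete_gamma_rates <- function(alpha, k) {
  if (is.infinite(alpha)) return(rep(1, k))
  b <- c(0, qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha), Inf)
  # E[X; X < b] for X ~ Gamma(alpha, alpha) is pgamma(b, alpha + 1, alpha)
  k * diff(pgamma(b, shape = alpha + 1, rate = alpha))
}

.gtr_eigen <- function(model) {
  ps <- sqrt(model$base_freq)
  B <- diag(ps) %*% model$Q %*% diag(1 / ps)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       U1 = diag(1 / ps) %*% e$vectors,
       U2 = t(e$vectors) %*% diag(ps))
}

.gtr_pmat <- function(eig, t) {
  P <- eig$U1 %*% (exp(eig$values * t) * eig$U2)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate sequences under GTR+Gamma along a tree
#'
#' The root state is drawn from the stationary frequencies; each site is
#' assigned one of the discrete Gamma rate categories; along every branch
#' states evolve by the transition matrix `expm(Q * rate * length)`
#' computed from the eigendecomposition of the reversible rate matrix.
#' No indels are simulated.
#'
#' @param tree an [ape::phylo] tree with branch lengths in expected
#'   substitutions per site.
#' @param model a [gtr_model()].
#' @param length number of sites.
#' @param seed optional integer seed.
#' @return character matrix (tips x sites) over A/C/G/T with the tree's
#'   tip labels as row names.
#' @export
simulate_sequences_gtr_gamma <- function(tree, model = gtr_model(),
                                         length = 1000L, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "gtr_model"))
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  n <- base::length(tree$tip.label)
  cat_rates <- .discrete_gamma_rates(model$alpha, model$ncat)
  site_cat <- sample.int(model$ncat, length, replace = TRUE)
  eig <- .gtr_eigen(model)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_nodes <- n + tree$Nnode
  states <- matrix(0L, n_nodes, length)
  root <- tree$edge[nrow(tree$edge), 1L]
  states[root, ] <- sample.int(4L, length, replace = TRUE,
                               prob = model$base_freq)
  # parents before children: walk the postorder edge list backwards
  for (e in rev(seq_len(nrow(tree$edge)))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    len <- tree$edge.length[[e]]
    ps <- states[parent, ]
    cs <- integer(length)
    for (g in seq_len(model$ncat)) {
      P <- .gtr_pmat(eig, len * cat_rates[[g]])
      cum <- t(apply(P, 1L, cumsum))
      for (s in 1:4) {
        idx <- which(site_cat == g & ps == s)
        if (base::length(idx)) {
          cs[idx] <- findInterval(runif(base::length(idx)),
                                  cum[s, ], left.open = TRUE) + 1L
        }
      }
    }
    states[child, ] <- cs
  }
  out <- matrix(c("A", "C", "G", "T")[states[seq_len(n), ]], n, length)
  rownames(out) <- tree$tip.label
  out
}

# Robinson-Foulds ---------------------------------------------------------------

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartitions, plus the
#' normalised distance (absolute / 2(n-3), the maximum for binary unrooted
#' trees).
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return named numeric vector `c(absolute, normalized)`.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  n <- length(t1$tip.label)
  abs_rf <- phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
  c(absolute = abs_rf,
    normalized = if (n > 3L) abs_rf / (2 * (n - 3L)) else 0)
}
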