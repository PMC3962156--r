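# Rejection approximate Bayesian computation for the population mutation
# rate and an exponential-growth demography, using multi-locus averages of
# theta_pi, theta_w, ZnS and Fay & Wu's H as summary statistics.

#' Configuration for rejection ABC
#'
#' Priors are uniform on finite ranges. Candidate datasets are simulated
#' with the coalescent + infinite-sites machinery of this package; the
#' distance is Euclidean on summaries standardised by their
#' across-simulation standard deviation; the retained sample is summarised
#' by the marginal MAP (Gaussian kernel density mode, Silverman bandwidth)
#' and the median.
#'
#' @param priors named list of `c(min, max)` ranges for `theta` (per
#'   locus), and, for the growth model, `growth_rate` and `onset_time`.
#' @param model `"constant"` (only theta estimated) or `"growth"`.
#' @param n_sims number of candidate parameter vectors.
#' @param n_keep number of retained simulations (<= `n_sims`).
#' @param n_loci,n_samples,locus_theta_scale simulated study design:
#'   independent loci per dataset, sequences per locus, and a multiplier
#'   mapping the theta prior to per-locus theta (1 for 1 kb loci with a
#'   per-kb prior).
#' @return an object of class `abc_config`.
#' @export
abc_config <- function(priors = list(theta = c(0.1, 200),
                                     growth_rate = c(-10, 10),
                                     onset_time = c(0, 4)),
                       model = c("growth", "constant"),
                       n_sims = 10000L, n_keep = 100L,
                       n_loci = 20L, n_samples = 100L,
                       locus_theta_scale = 1) {
  model <- match.arg(model)
  if (n_keep > n_sims) stop("n_keep must be <= n_sims")
  for (p in priors) {
    if (length(p) != 2L || !all(is.finite(p)) || p[2L] <= p[1L]) {
      stop("each prior must be a finite c(min, max) range")
    }
  }
  if (is.null(priors$theta)) stop("a theta prior is required")
  structure(list(priors = priors, model = model,
                 n_sims = as.integer(n_sims), n_keep = as.integer(n_keep),
                 n_loci = as.integer(n_loci),
                 n_samples = as.integer(n_samples),
                 locus_theta_scale = locus_theta_scale),
            class = "abc_config")
}

.simulate_summaries <- function(theta, demog, config) {
  loci <- lapply(seq_len(config$n_loci), function(i) {
    tr <- sample_coalescent_tree(config$n_samples, demog)
    simulate_infinite_sites(tr, theta * config$locus_theta_scale)
  })
  s <- multilocus_summaries(loci)
  c(theta_pi = s$theta_pi, theta_w = s$theta_w, zns = s$zns, h = s$h)
}

.kde_map <- function(x) {
  if (length(unique(x)) == 1L) return(x[[1L]])
  d <- density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Rejection ABC for population mutation rate and growth
#'
#' Draws `n_sims` parameter vectors from the priors, simulates a
#' multi-locus dataset for each, standardises every summary statistic by
#' its standard deviation across simulations, and retains the `n_keep`
#' parameter vectors whose summaries are closest (Euclidean distance) to
#' the standardised observation. No regression adjustment is applied.
#'
#' @param observed named numeric vector of observed averaged summaries
#'   (any subset of `theta_pi`, `theta_w`, `zns`, `h`).
#' @param config an [abc_config()].
#' @param seed optional integer seed.
#' @return an object of class `posterior_sample`: list with `samples`
#'   (retained parameter data frame, with distances), `map` and `median`
#'   (named per-parameter point estimates), `sims` (all simulated
#'   parameters and summaries), and `used_stats`.
#' @export
abc_reject <- function(observed, config = abc_config(), seed = NULL) {
  stopifnot(inherits(config, "abc_config"))
  if (!is.null(seed)) set.seed(seed)
  stats_all <- c("theta_pi", "theta_w", "zns", "h")
  use <- intersect(stats_all, names(observed))
  if (length(use) == 0L) stop("observed must name at least one summary")
  runi <- function(rng, n) runif(n, rng[1L], rng[2L])
  n <- config$n_sims
  params <- data.frame(theta = runi(config$priors$theta, n))
  if (config$model == "growth") {
    params$growth_rate <- runi(config$priors$growth_rate, n)
    params$onset_time <- runi(config$priors$onset_time, n)
  }
  summaries <- matrix(NA_real_, n, length(stats_all),
                      dimnames = list(NULL, stats_all))
  for (i in seq_len(n)) {
    demog <- if (config$model == "growth") {
      demography("growth", params$growth_rate[[i]],
                 params$onset_time[[i]])
    } else demography()
    summaries[i, ] <- .simulate_summaries(params$theta[[i]], demog, config)
  }
  sds <- apply(summaries[, use, drop = FALSE], 2L, sd, na.rm = TRUE)
  degenerate <- !is.finite(sds) | sds == 0
  if (any(degenerate)) {
    warning("dropping degenerate summary statistic(s): ",
            paste(use[degenerate], collapse = ", "))
    use <- use[!degenerate]
    sds <- sds[!degenerate]
  }
  if (length(use) == 0L) stop("no usable summary statistics")
  z_sim <- sweep(summaries[, use, drop = FALSE], 2L, sds, "/")
  z_obs <- observed[use] / sds
  dist <- sqrt(rowSums(sweep(z_sim, 2L, z_obs, "-")^2))
  dist[!is.finite(dist)] <- Inf
  keep <- order(dist)[seq_len(config$n_keep)]
  samples <- params[keep, , drop = FALSE]
  samples$distance <- dist[keep]
  rownames(samples) <- NULL
  pars <- setdiff(names(params), "distance")
  structure(list(
    samples = samples,
    map = vapply(pars, function(p) .kde_map(samples[[p]]), numeric(1L)),
    median = vapply(pars, function(p) median(samples[[p]]), numeric(1L)),
    sims = cbind(params, summaries),
    used_stats = use, config = config), class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("<posterior_sample> ", nrow(x$samples), " retained of ",
      x$config$n_sims, " simulations\n", sep = "")
  for (p in names(x$map)) {
    cat(sprintf("  %-12s MAP %.4g  median %.4g\n", p, x$map[[p]],
                x$median[[p]]))
  }
  invisible(x)
}
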