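# ABC correction of RAD-based diversity estimates: reference-table
# simulation under the neutral panmictic model, rejection sampling with a
# tolerance rate, and local linear regression adjustment of the accepted
# draws (classical regression-ABC: MAD standardisation, Euclidean distance,
# Epanechnikov kernel weights). Inference is on log10(theta).

#' Uniform prior on log10(theta)
#'
#' @param lower,upper bounds on the log10 scale; defaults cover theta from
#'   1e-5 to 1e-1, the range over which the drop-out bias goes from
#'   negligible to severe.
#' @return object of class \code{rad_prior}.
#' @export
abc_prior <- function(lower = -5, upper = -1) {
  stopifnot(lower < upper)
  structure(list(lower = lower, upper = upper), class = "rad_prior")
}

stat_columns <- function(table) {
  setdiff(names(table), c("log10_theta", "valid"))
}

#' Simulate an ABC reference table
#'
#' Draws \code{n_sims} values of log10(theta) from the prior and runs the
#' full simulation pipeline (neutral panmictic model, random motifs, random
#' diploid pairing, digestion, estimators) for each, recording the summary
#' statistics an observed RAD experiment provides: the observed RAD
#' diversity \eqn{\pi_{RADobs}} and the locus-sharing proportion(s).
#' Rows where the statistics are undefined (no shared locus, possible near
#' theta = 0.1) are kept with \code{valid = FALSE} and excluded from
#' inference.
#'
#' @param n_sims number of simulations (rows).
#' @param prior an \code{\link{abc_prior}}.
#' @param n_loci,locus_len per-simulation locus layout. The default desk
#'   scale (200 loci of 2 kb) preserves the estimator geometry of the full
#'   1000 x 10 kb design at a fraction of the cost.
#' @param n_motifs,motif_len,tag_len digestion parameters.
#' @param stat_mode \code{"mean_share"} (default: two statistics,
#'   \eqn{\pi_{RADobs}} and the mean of the two per-individual sharing
#'   proportions) or \code{"per_individual"} (three statistics, one sharing
#'   proportion per individual).
#' @param mode estimator normalisation, see \code{\link{pi_locus}}.
#' @param seed master seed; row i uses substream i.
#' @return object of class \code{rad_reference_table}: a data frame with
#'   \code{log10_theta}, the statistic columns and \code{valid}, plus
#'   attributes recording the simulation settings.
#' @export
build_reference_table <- function(n_sims, prior = abc_prior(),
                                  n_loci = 200L, locus_len = 2000L,
                                  n_motifs = 10L, motif_len = 8L,
                                  tag_len = 100L,
                                  stat_mode = c("mean_share", "per_individual"),
                                  mode = "pair_mean", seed = 1L) {
  stat_mode <- match.arg(stat_mode)
  stopifnot(n_sims >= 1L)
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    row_seed <- mix_seed(seed, i)
    lt <- with_seed(mix_seed(row_seed, 1L),
                    runif(1L, prior$lower, prior$upper))
    cfg <- model_config("panmictic", theta_site = 10^lt, n_loci = n_loci,
                        locus_len = locus_len, seed = mix_seed(row_seed, 2L))
    res <- tryCatch(rad_replicate(cfg, n_motifs, motif_len, tag_len, mode),
                    error = function(e) NULL)
    if (is.null(res)) {
      stats <- c(pi_rad_obs = NA_real_, share_1 = NA_real_, share_2 = NA_real_)
    } else {
      stats <- c(pi_rad_obs = res$pi_rad, share_1 = res$share_1,
                 share_2 = res$share_2)
    }
    if (stat_mode == "mean_share")
      stats <- c(pi_rad_obs = unname(stats["pi_rad_obs"]),
                 share_mean = mean(stats[c("share_1", "share_2")]))
    rows[[i]] <- c(log10_theta = lt, stats)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab$valid <- rowSums(!is.finite(as.matrix(tab[stat_columns(tab)]))) == 0L
  if (!any(tab$valid)) stop("all reference-table rows have undefined statistics")
  structure(tab, class = c("rad_reference_table", "data.frame"),
            prior = prior, stat_mode = stat_mode, mode = mode, seed = seed,
            sim = list(n_loci = n_loci, locus_len = locus_len,
                       n_motifs = n_motifs, motif_len = motif_len,
                       tag_len = tag_len))
}

#' Observed summary statistics from a catalog
#'
#' Convenience extractor producing the statistics vector
#' \code{\link{abc_estimate}} expects, in the same order as a reference
#' table built with the given \code{stat_mode}.
#'
#' @inheritParams build_reference_table
#' @param catalog a \code{rad_catalog} (e.g. from
#'   \code{\link{digest_and_estimate}} runs or simulations).
#' @return named numeric vector of summary statistics.
#' @export
observed_stats <- function(catalog, stat_mode = c("mean_share", "per_individual"),
                           mode = "pair_mean") {
  stat_mode <- match.arg(stat_mode)
  pr <- pi_rad(catalog, mode)
  sh <- sharing_proportions(catalog)
  if (stat_mode == "mean_share")
    c(pi_rad_obs = pr, share_mean = mean(sh))
  else c(pi_rad_obs = pr, share_1 = unname(sh[1L]), share_2 = unname(sh[2L]))
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1L]], 0)
}

#' ABC posterior for theta from observed RAD statistics
#'
#' Rejection ABC with optional local linear regression adjustment. The
#' table's statistics (and the observation) are standardised by their median
#' absolute deviation, the closest fraction \code{tolerance} of rows by
#' Euclidean distance is accepted, and under \code{method = "loclinear"} an
#' Epanechnikov-weighted linear regression of log10(theta) on the
#' standardised statistics corrects each accepted draw to the observed
#' statistics: \eqn{\theta_i^* = \theta_i - b'(s_i - s_{obs})}. The point
#' estimate is the weighted posterior median of the adjusted draws.
#'
#' @param obs_stats numeric vector of observed statistics, same order as the
#'   table's statistic columns (see \code{\link{observed_stats}}).
#' @param table a \code{\link{build_reference_table}} result.
#' @param tolerance accepted fraction of the (valid) table rows; the study
#'   uses 0.05.
#' @param method \code{"loclinear"} (default) or \code{"rejection"}. A
#'   degenerate accepted set (singular regression) falls back to rejection
#'   with a warning.
#' @return object of class \code{rad_posterior}: accepted and adjusted
#'   log10(theta) draws, kernel weights, point estimates (weighted median
#'   and mean) and 95\% credible interval on both scales.
#' @export
abc_estimate <- function(obs_stats, table, tolerance = 0.05,
                         method = c("loclinear", "rejection")) {
  method <- match.arg(method)
  stopifnot(tolerance > 0, tolerance <= 1)
  cols <- stat_columns(table)
  stopifnot(length(obs_stats) == length(cols))
  tab <- table[table$valid, , drop = FALSE]
  S <- as.matrix(tab[cols])
  obs <- as.numeric(obs_stats)
  scale <- apply(S, 2L, mad)
  scale[scale == 0] <- 1 # constant statistic carries no distance information
  Sz <- sweep(S, 2L, scale, "/")
  oz <- obs / scale
  d <- sqrt(rowSums(sweep(Sz, 2L, oz, "-")^2))
  n_acc <- as.integer(max(1, ceiling(tolerance * nrow(tab))))
  acc <- order(d)[seq_len(n_acc)]
  theta_acc <- tab$log10_theta[acc]
  d_acc <- d[acc]
  d_max <- max(d_acc)
  w <- if (d_max > 0) 1 - (d_acc / d_max)^2 else rep(1, n_acc)
  if (all(w == 0)) w <- rep(1, n_acc)
  adjusted <- theta_acc
  used <- "rejection"
  if (method == "loclinear" && n_acc > length(cols) + 1L) {
    X <- Sz[acc, , drop = FALSE]
    # statistics constant within the accepted set carry no local
    # information; regress on the informative ones only
    keep <- apply(X, 2L, function(v) diff(range(v)) > 0)
    X <- X[, keep, drop = FALSE]
    fit <- if (ncol(X) > 0L) lm(theta_acc ~ X, weights = w) else NULL
    b <- if (is.null(fit)) NA_real_ else coef(fit)[-1L]
    if (any(is.na(b))) {
      warning("singular local regression; falling back to rejection")
    } else {
      adjusted <- theta_acc - as.numeric(sweep(X, 2L, oz[keep], "-") %*% b)
      # keep the adjustment inside the prior support: for observations far
      # outside the table's statistic range the linear extrapolation is
      # meaningless, so adjusted draws are truncated to the sampled support
      adjusted <- pmin(pmax(adjusted, min(tab$log10_theta)),
                       max(tab$log10_theta))
      used <- "loclinear"
    }
  } else if (method == "loclinear") {
    warning("too few accepted draws for local regression; using rejection")
  }
  pt <- weighted_quantile(adjusted, w, 0.5)
  ci <- weighted_quantile(adjusted, w, c(0.025, 0.975))
  structure(list(accepted = theta_acc, adjusted = adjusted, weights = w,
                 point_log10_theta = pt, point_theta = 10^pt,
                 mean_log10_theta = sum(w * adjusted) / sum(w),
                 ci_log10_theta = ci, ci_theta = 10^ci,
                 tolerance = tolerance, method = used,
                 n_accepted = n_acc),
            class = "rad_posterior")
}

#' @export
print.rad_posterior <- function(x, ...) {
  cat("ABC posterior (", x$method, ", tolerance ", x$tolerance, ", ",
      x$n_accepted, " accepted)\n", sep = "")
  cat(sprintf("  theta = %.4g  [95%% CI %.4g - %.4g]\n",
              x$point_theta, x$ci_theta[1L], x$ci_theta[2L]))
  cat(sprintf("  log10 theta = %.3f  [%.3f - %.3f]\n",
              x$point_log10_theta, x$ci_log10_theta[1L], x$ci_log10_theta[2L]))
  invisible(x)
}

#' Leave-one-out ABC cross-validation
#'
#' Treats randomly chosen reference-table rows as pseudo-observed data: each
#' is removed from the table and its theta re-estimated from its own
#' statistics. Recovery accuracy (correlation and median absolute error on
#' the log10 scale) measures how well the ABC correction retrieves the true
#' polymorphism from RAD-biased observations.
#'
#' @param table a \code{\link{build_reference_table}} result.
#' @param n_pseudo number of pseudo-observed rows.
#' @param tolerance,method passed to \code{\link{abc_estimate}}.
#' @param seed seed for the choice of pseudo-observed rows.
#' @return object of class \code{rad_abc_cv}: data frame with
#'   \code{true_log10_theta}, \code{estimated_log10_theta}, \code{error};
#'   attribute \code{summary} holds the correlation, median absolute error
#'   and residual sign counts.
#' @export
cross_validate <- function(table, n_pseudo = 100L, tolerance = 0.05,
                           method = "loclinear", seed = 1L) {
  valid_idx <- which(table$valid)
  stopifnot(n_pseudo >= 1L, n_pseudo < length(valid_idx))
  cols <- stat_columns(table)
  pick <- with_seed(seed, sample(valid_idx, n_pseudo))
  res <- lapply(pick, function(i) {
    obs <- as.numeric(table[i, cols])
    post <- abc_estimate(obs, table[-i, , drop = FALSE], tolerance, method)
    c(true = table$log10_theta[i], est = post$point_log10_theta)
  })
  res <- as.data.frame(do.call(rbind, res))
  out <- data.frame(true_log10_theta = res$true,
                    estimated_log10_theta = res$est,
                    error = res$est - res$true)
  summary <- list(
    correlation = cor(out$true_log10_theta, out$estimated_log10_theta),
    median_abs_error = median(abs(out$error)),
    n_positive = sum(out$error > 0), n_negative = sum(out$error < 0))
  structure(out, class = c("rad_abc_cv", "data.frame"), summary = summary)
}

#' @export
print.rad_abc_cv <- function(x, ...) {
  s <- attr(x, "summary")
  cat("ABC cross-validation over", nrow(x), "pseudo-observations\n")
  cat(sprintf("  correlation (log10 scale): %.3f\n", s$correlation))
  cat(sprintf("  median |error| (log10):    %.3f\n", s$median_abs_error))
  cat(sprintf("  residual signs: %d positive / %d negative\n",
              s$n_positive, s$n_negative))
  invisible(x)
}

#' Write / read a reference table as TSV
#'
#' @param table a \code{rad_reference_table}.
#' @param path TSV path.
#' @return invisibly, \code{path} (writer) or the re-read table (reader;
#'   simulation-settings attributes are not round-tripped).
#' @export
write_reference_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  tab <- read.delim(path)
  stopifnot("log10_theta" %in% names(tab), "valid" %in% names(tab))
  tab$valid <- as.logical(tab$valid)
  structure(tab, class = c("rad_reference_table", "data.frame"))
}
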