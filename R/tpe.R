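# Tree-structured Parzen estimator (multivariate) over discrete numeric
# search grids.
#
# After a random start-up phase, observed trials are split at the
# gamma-quantile of the loss into "good" and "rest" sets, modelled by
# multivariate Gaussian Parzen mixtures l(x) and g(x) with product kernels
# centered on the observed configurations (so correlations between
# dimensions survive in the proposals).  Candidates are drawn from l —
# jitter one good configuration in every dimension and snap to the grids —
# and ranked by log l(x) - log g(x); the floor mixture keeps unvisited
# regions reachable.

parzen_bandwidth <- function(obs, grid) {
  step <- if (length(grid) > 1) min(diff(sort(unique(grid)))) else 1
  s <- stats::sd(obs)
  if (!is.finite(s) || s < step) s <- step
  max(0.5 * s * (4 / (3 * max(length(obs), 2)))^0.2, step)
}

# log of the product-kernel mixture density at configuration x
# (obs: matrix n x D, bw: length-D bandwidths, spans: length-D grid spans)
parzen_log_mixture <- function(x, obs, bw, spans) {
  lk <- sweep(obs, 2, x)                      # obs - x
  lk <- sweep(lk, 2, bw, "/")
  logk <- -0.5 * rowSums(lk^2) - sum(log(bw)) -
    0.5 * ncol(obs) * log(2 * pi)
  m <- max(logk)
  dens <- exp(m) * mean(exp(logk - m))
  floor_d <- exp(-sum(log(spans)))
  log(0.9 * dens + 0.1 * floor_d)
}

#' Minimize an objective over discrete grids with a TPE sampler
#'
#' @param space named list; each element is the numeric grid of admissible
#'   values for one parameter.
#' @param objective function taking a named list of parameter values and
#'   returning a scalar loss.
#' @param n_iter total number of trials.
#' @param seed RNG seed (all sampling flows from it).
#' @param n_startup number of initial uniform-random trials.
#' @param gamma quantile separating "good" from "rest" trials.
#' @param n_candidates candidates scored per TPE iteration.
#' @return list with `best_params`, `best_value`, `trace` (best-so-far loss
#'   per iteration), `history` (data.frame of all trials), `seed`.
#' @export
tpe_optimize <- function(space, objective, n_iter, seed = 1L,
                         n_startup = 20L, gamma = 0.25, n_candidates = 24L) {
  stopifnot(n_iter >= 1, length(space) >= 1)
  set.seed(seed)
  dims <- names(space)
  hist_par <- matrix(NA_real_, n_iter, length(dims),
                     dimnames = list(NULL, dims))
  losses <- rep(NA_real_, n_iter)
  trace <- rep(NA_real_, n_iter)
  best_v <- Inf; best_p <- NULL
  snap <- function(x, grid) grid[which.min(abs(grid - x))]
  for (it in seq_len(n_iter)) {
    if (it <= max(n_startup, 2L)) {
      cand <- lapply(space, function(g) g[sample.int(length(g), 1)])
    } else {
      done <- seq_len(it - 1L)
      # good set capped at 25 so the l-model keeps concentrating on the very
      # best configurations as the history grows
      n_good <- min(max(2L, ceiling(gamma * length(done))), 25L)
      ord <- order(losses[done])
      good <- done[ord[seq_len(n_good)]]
      rest <- done[ord[(n_good + 1L):length(ord)]]
      if (length(rest) == 0L) rest <- done
      gm <- hist_par[good, , drop = FALSE]
      rm_ <- hist_par[rest, , drop = FALSE]
      bw_l <- vapply(dims, function(d) parzen_bandwidth(gm[, d], space[[d]]), 0)
      bw_g <- vapply(dims, function(d) parzen_bandwidth(rm_[, d], space[[d]]), 0)
      spans <- vapply(dims, function(d)
        diff(range(space[[d]])) + bw_l[[d]], 0)
      # draw candidates around good configurations; keep the best-scoring one
      best_score <- -Inf; cand <- NULL
      for (k in seq_len(n_candidates)) {
        if (k == 1L && runif(1) < 0.25) {
          x <- vapply(dims, function(d)
            space[[d]][sample.int(length(space[[d]]), 1)], 0)
        } else {
          ctr <- gm[sample.int(nrow(gm), 1), ]
          x <- vapply(seq_along(dims), function(j)
            snap(ctr[j] + rnorm(1, 0, bw_l[j]), space[[dims[j]]]), 0)
          names(x) <- dims
        }
        score <- parzen_log_mixture(x, gm, bw_l, spans) -
          parzen_log_mixture(x, rm_, bw_g, spans)
        if (score > best_score) { best_score <- score; cand <- as.list(x) }
      }
    }
    loss <- objective(cand)
    if (!is.finite(loss)) loss <- .Machine$double.xmax
    hist_par[it, ] <- unlist(cand)
    losses[it] <- loss
    if (loss < best_v) { best_v <- loss; best_p <- cand }
    trace[it] <- best_v
  }
  list(best_params = best_p, best_value = best_v, trace = trace,
       history = data.frame(hist_par, loss = losses), seed = seed)
}
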