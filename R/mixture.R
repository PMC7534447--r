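#' Fit a univariate Gaussian mixture by EM
#'
#' Maximum-likelihood fit of a k-component univariate Gaussian mixture by
#' expectation-maximization, restarted `n_restarts` times from jittered
#' quantile-spread initial means; the best restart by log-likelihood is
#' returned. Two model families are supported: `"free_variance"` (each
#' component has its own standard deviation) and `"equal_variance"` (one
#' shared standard deviation). The parameter count is
#' `(k - 1) + k + k` for free variance and `(k - 1) + k + 1` for equal
#' variance (weights, means, variance terms), and the reported BIC follows
#' the model-based-clustering convention `2 * logLik - p * ln(n)`, so the
#' best model is the one with MAXIMUM BIC.
#'
#' A variance floor of 1e-8 on the component standard deviations guards
#' against singular components; a restart whose component collapses to
#' the floor is discarded and retried.
#'
#' @param values Finite numeric vector, length >= 2k.
#' @param k Number of components, >= 1.
#' @param family `"free_variance"` or `"equal_variance"`.
#' @param n_restarts EM restarts (default 10).
#' @param seed RNG seed controlling restart jitter (default 1).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @return A `mixture_fit` object: `k`, `weights`, `means`, `sds`,
#'   `family`, `log_likelihood`, `bic`, `n`, `converged`, `seed`, and the
#'   per-iteration `loglik_trace` of the winning restart.
#' @export
fit_mixture <- function(values, k,
                        family = c("free_variance", "equal_variance"),
                        n_restarts = 10L, seed = 1L,
                        max_iter = 500L, tol = 1e-6) {
  family <- match.arg(family)
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  if (!is_scalar_number(k) || k < 1) stop("k must be >= 1")
  k <- as.integer(k)
  if (n < 2L * k) stop("need at least 2k observations (n = ", n, ", k = ", k, ")")
  if (stats::sd(x) == 0) stop("zero-variance data")

  base_means <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  sx <- stats::sd(x)
  sd_floor <- 1e-8

  # Short-run/long-run restart scheme: every restart gets a cheap
  # burn-in, and only the best burn-in is run to full convergence.
  best <- NULL
  local_seed(seed, {
    attempt <- 0L
    done <- 0L
    while (done < n_restarts && attempt < 4L * n_restarts) {
      attempt <- attempt + 1L
      mu <- if (attempt == 1L) base_means
            else base_means + stats::rnorm(k, 0, sx / 2)
      fit <- em_once(x, k, family, mu, sx,
                     max_iter = min(50L, max_iter),
                     tol = max(tol, 1e-4), sd_floor = sd_floor)
      if (fit$degenerate) next
      done <- done + 1L
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (is.null(best))
    stop("all EM restarts collapsed to singular components")
  polished <- em_once(x, k, family, best$means, sx, max_iter, tol, sd_floor,
                      w = best$weights, sds = best$sds)
  if (!polished$degenerate) {
    polished$trace <- c(best$trace, polished$trace)
    best <- polished
  }

  p <- if (family == "free_variance") (k - 1L) + k + k else (k - 1L) + k + 1L
  ord <- order(best$means)
  structure(list(k = k,
                 weights = best$weights[ord],
                 means = best$means[ord],
                 sds = best$sds[ord],
                 family = family,
                 log_likelihood = best$loglik,
                 bic = 2 * best$loglik - p * log(n),
                 n = n,
                 converged = best$converged,
                 seed = seed,
                 loglik_trace = best$trace),
            class = "mixture_fit")
}

# One EM run. Returns loglik trace so monotonicity can be asserted.
# Inner loop is fully vectorized (explicit Gaussian log-density, row
# max via max.col, moment-form variance update) so thousands of
# iterations stay cheap.
em_once <- function(x, k, family, mu, sx, max_iter, tol, sd_floor,
                    w = rep(1 / k, k), sds = rep(sx, k)) {
  n <- length(x)
  x2 <- x * x
  lp <- matrix(0, n, k)
  trace <- numeric(max_iter)
  ll_old <- -Inf
  converged <- FALSE
  degenerate <- FALSE
  const <- -0.5 * log(2 * pi)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (j in seq_len(k))
      lp[, j] <- log(w[j]) + const - log(sds[j]) -
        0.5 * ((x - mu[j]) / sds[j])^2
    if (k == 1L) {
      lse <- lp[, 1L]
      resp <- matrix(1, n, 1L)
    } else {
      m <- lp[cbind(seq_len(n), max.col(lp, ties.method = "first"))]
      lse <- m + log(rowSums(exp(lp - m)))
      resp <- exp(lp - lse)
    }
    ll <- sum(lse)
    trace[iter] <- ll
    nj <- colSums(resp)
    if (any(nj < 1e-12)) { degenerate <- TRUE; break }
    w <- nj / n
    mu <- colSums(resp * x) / nj
    ex2 <- colSums(resp * x2) / nj
    vj <- pmax(ex2 - mu^2, 0)
    if (family == "free_variance") {
      sds <- sqrt(vj)
    } else {
      sds <- rep(sqrt(sum(nj * vj) / n), k)
    }
    if (any(sds <= sd_floor)) { degenerate <- TRUE; break }
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = sds,
       loglik = trace[iter], trace = trace[seq_len(iter)],
       converged = converged, degenerate = degenerate)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: k = %d (%s), n = %d\n",
              x$k, x$family, x$n))
  cat(sprintf("  logLik %.3f, BIC %.3f, converged: %s\n",
              x$log_likelihood, x$bic, x$converged))
  tab <- rbind(weight = x$weights, mean = x$means, sd = x$sds)
  colnames(tab) <- paste0("comp", seq_len(x$k))
  print(round(tab, 4))
  invisible(x)
}

#' Mixture-component selection by BIC
#'
#' Fits Gaussian mixtures over a (k, family) grid and selects the fit
#' with maximum BIC (`2 * logLik - p * ln n`), the convention under which
#' larger is better. Ties go to the smaller k, then to the equal-variance
#' family. Applied to a per-gene CpG o/e distribution this estimates the
#' number of methylation-signature modes.
#'
#' @param values Finite numeric vector (undefined CpG o/e values must be
#'   excluded upstream, e.g. `table$cpg_oe[table$defined]`).
#' @param k_max Largest component count tried (default 5).
#' @param families Model families to try (default both).
#' @param n_restarts,seed,max_iter,tol Passed to [fit_mixture()].
#' @return A `mixture_selection`: list of all `fits`, the `selected`
#'   fit, and a `bic_table` data frame (k, family, bic, converged).
#' @export
select_components <- function(values, k_max = 5L,
                              families = c("equal_variance", "free_variance"),
                              n_restarts = 10L, seed = 1L,
                              max_iter = 500L, tol = 1e-6) {
  if (!is_scalar_number(k_max) || k_max < 1) stop("k_max must be >= 1")
  families <- match.arg(families, c("equal_variance", "free_variance"),
                        several.ok = TRUE)
  grid <- expand.grid(k = seq_len(k_max), family = families,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- fit_mixture(values, k = grid$k[i], family = grid$family[i],
                             n_restarts = n_restarts,
                             seed = derive_seed(seed, paste0(grid$family[i], grid$k[i])),
                             max_iter = max_iter, tol = tol)
  }
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  # max BIC; ties -> smaller k, then equal_variance
  pref <- order(-bic, grid$k, grid$family != "equal_variance")
  sel <- pref[1L]
  structure(list(fits = fits,
                 selected = fits[[sel]],
                 bic_table = data.frame(k = grid$k, family = grid$family,
                                        bic = bic,
                                        converged = vapply(fits, `[[`,
                                                           logical(1), "converged"))),
            class = "mixture_selection")
}

#' @export
print.mixture_selection <- function(x, ...) {
  cat("Mixture component selection over",
      nrow(x$bic_table), "candidate models\n")
  cat(sprintf("  selected: k = %d (%s), BIC %.3f\n",
              x$selected$k, x$selected$family, x$selected$bic))
  print(x$bic_table)
  invisible(x)
}

#' @export
summary.mixture_selection <- function(object, ...) {
  print(object$selected)
  invisible(object)
}

#' Plot a mixture selection over a CpG o/e histogram
#'
#' @param x A `mixture_selection`.
#' @param values The data vector the selection was fitted to.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.mixture_selection <- function(x, values, ...) {
  graphics::hist(values, freq = FALSE, breaks = 50,
                 main = sprintf("Selected k = %d (%s)",
                                x$selected$k, x$selected$family),
                 xlab = "CpG o/e", ...)
  fit <- x$selected
  xs <- seq(min(values), max(values), length.out = 400)
  dens <- rowSums(vapply(seq_len(fit$k), function(j)
    fit$weights[j] * stats::dnorm(xs, fit$means[j], fit$sds[j]),
    numeric(length(xs))))
  graphics::lines(xs, dens, lwd = 2, col = "firebrick")
  invisible(x)
}
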