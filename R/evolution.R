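# Finite Gaussian mixture clustering of clonality trajectories.
#
# Mutations are points in R^T (one coordinate per timepoint, the CCF at
# that timepoint). A mixture with k components is fitted by EM; the number
# of components and the covariance family are selected by BIC
# (minimizing n_params * ln(n) - 2 * loglik). Three covariance families
# span the volume/shape spectrum: spherical (sigma_k^2 I), diagonal
# (per-component axis-aligned) and full (per-component unconstrained).

MIX_FAMILIES <- c("spherical", "diagonal", "full")
COV_FLOOR <- 1e-6

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1, prob = p)
      nd <- rowSums((x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, nd)
    }
  }
  x[idx, , drop = FALSE]
}

# per-component log density matrix (n x k)
log_dens <- function(x, means, covs, family) {
  n <- nrow(x); d <- ncol(x); k <- nrow(means)
  ld <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    xc <- x - matrix(means[j, ], n, d, byrow = TRUE)
    if (family == "spherical") {
      s2 <- covs[[j]]
      ld[, j] <- -0.5 * (d * log(2 * pi * s2) + rowSums(xc^2) / s2)
    } else if (family == "diagonal") {
      v <- covs[[j]]
      ld[, j] <- -0.5 * (d * log(2 * pi) + sum(log(v)) +
                           rowSums(sweep(xc^2, 2, v, "/")))
    } else {
      ch <- chol(covs[[j]])
      z <- xc %*% chol2inv(ch) * xc
      ld[, j] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + rowSums(z))
    }
  }
  ld
}

mstep_cov <- function(x, r, means, family) {
  n <- nrow(x); d <- ncol(x); k <- ncol(r)
  Nk <- colSums(r)
  lapply(seq_len(k), function(j) {
    xc <- x - matrix(means[j, ], n, d, byrow = TRUE)
    if (family == "spherical") {
      max(sum(r[, j] * rowSums(xc^2)) / (d * Nk[j]), COV_FLOOR)
    } else if (family == "diagonal") {
      pmax(colSums(r[, j] * xc^2) / Nk[j], COV_FLOOR)
    } else {
      S <- crossprod(xc * sqrt(r[, j])) / Nk[j]
      diag(S) <- pmax(diag(S), COV_FLOOR)
      # ridge until positive definite (degenerate directions)
      ridge <- 0
      while (inherits(try(chol(S + diag(ridge, d)), silent = TRUE), "try-error")) {
        ridge <- if (ridge == 0) COV_FLOOR else ridge * 10
        if (ridge > 1) stop("covariance not repairable", call. = FALSE)
      }
      S + diag(ridge, d)
    }
  })
}

mixture_n_params <- function(k, d, family) {
  cov_p <- switch(family, spherical = k, diagonal = k * d,
                  full = k * d * (d + 1) / 2)
  as.integer((k - 1) + k * d + cov_p)
}

em_once <- function(x, k, family, max_iter = 500, tol = 1e-6) {
  n <- nrow(x); d <- ncol(x)
  centers <- kmeanspp_centers(x, k)
  # hard initial responsibilities from nearest seeded center
  dmat <- vapply(seq_len(k), function(j)
    rowSums((x - matrix(centers[j, ], n, d, byrow = TRUE))^2), numeric(n))
  assign0 <- max.col(-dmat, ties.method = "first")
  r <- matrix(0, n, k); r[cbind(seq_len(n), assign0)] <- 1
  r <- r + 1e-10; r <- r / rowSums(r)

  # with k > 1, components need at least d + 1 effective members: smaller
  # ones collapse onto single points and the likelihood spikes unboundedly
  min_members <- if (k > 1) d + 1 else 1e-8
  ll_prev <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    Nk <- colSums(r)
    if (any(Nk < min_members)) return(NULL)   # degenerate start
    w <- Nk / n
    means <- (t(r) %*% x) / Nk
    covs <- tryCatch(mstep_cov(x, r, means, family), error = function(e) NULL)
    if (is.null(covs)) return(NULL)
    ld <- log_dens(x, means, covs, family)
    num <- sweep(ld, 2, log(w), "+")
    ll <- sum(logsumexp_rows(num))
    if (!is.finite(ll)) return(NULL)
    trace <- c(trace, ll)
    r <- exp(num - logsumexp_rows(num))
    if (is.finite(ll_prev) && abs(ll - ll_prev) / (abs(ll_prev) + 1e-12) < tol) break
    ll_prev <- ll
  }
  list(weights = w, means = means, covariances = covs, loglik = ll,
       responsibilities = r, loglik_trace = trace,
       converged = iter < max_iter)
}

#' Fit a Gaussian mixture to clonality trajectories
#'
#' EM with k-means++ seeding and multiple restarts; the best restart by
#' log-likelihood is returned. Covariance diagonals are floored at 1e-6 so
#' coordinates that are exactly constant within a component (for instance
#' confidently absent timepoints) do not make the fit singular.
#' Deterministic for a given `seed`.
#'
#' @param x numeric matrix (rows = mutations, columns = timepoints), or a
#'   `longevol_ccf` object (rows with low-depth cells are dropped, see
#'   [clustering_rows()]).
#' @param k number of components (`k <= nrow(x)`).
#' @param family covariance family: `"spherical"`, `"diagonal"` or
#'   `"full"`.
#' @param seed integer seed; restart seeds are derived from it.
#' @param n_restarts number of k-means++ restarts (default 10).
#' @param max_iter,tol EM stopping rule: relative log-likelihood change
#'   below `tol` (default 1e-6) or `max_iter` (default 500) iterations.
#' @return an object of class `mixture_fit` with elements `k`, `family`,
#'   `weights`, `means`, `covariances`, `loglik`, `bic`, `n_params`,
#'   `assignments` (max-posterior, ties to the lowest component id),
#'   `responsibilities`, `loglik_trace`, `converged`.
#' @export
fit_mixture <- function(x, k, family = c("spherical", "diagonal", "full"),
                        seed = 1, n_restarts = 10, max_iter = 500, tol = 1e-6) {
  family <- match.arg(family)
  if (inherits(x, "longevol_ccf")) x <- x$values[clustering_rows(x), , drop = FALSE]
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < k) stopf("n = %d rows < k = %d components", n, k)
  if (k > 1 && nrow(unique(x)) == 1)
    stopf("degenerate fit: all %d rows identical with k = %d", n, k)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- withr::with_seed((seed + 1000003 * r) %% .Machine$integer.max,
                            em_once(x, k, family, max_iter, tol))
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stopf("degenerate fit: all %d restarts failed (k = %d, %s)",
                           n_restarts, k, family)
  np <- mixture_n_params(k, d, family)
  structure(c(best, list(
    k = k, family = family, n = n, d = d, seed = seed,
    n_params = np, bic = np * log(n) - 2 * best$loglik,
    assignments = max.col(best$responsibilities, ties.method = "first"))),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture: k = %d (%s), n = %d, loglik = %.2f, BIC = %.2f\n",
              x$k, x$family, x$n, x$loglik, x$bic))
  invisible(x)
}

#' Select the number of clusters and covariance family by BIC
#'
#' Fits every combination of `k = 1..k_max` and the requested covariance
#' families, and returns the fit minimizing
#' `BIC = n_params * ln(n) - 2 * loglik`. Ties break to smaller `k`, then
#' family order spherical < diagonal < full. Combinations whose EM
#' degenerates are skipped; an error is raised only if all fail.
#'
#' @inheritParams fit_mixture
#' @param k_max largest number of components tried.
#' @param families subset of `c("spherical", "diagonal", "full")`.
#' @return the winning `mixture_fit`, with a `bic_table` data.frame
#'   attribute recording every scored combination.
#' @export
select_model <- function(x, k_max = 6, families = MIX_FAMILIES, seed = 1,
                         n_restarts = 10) {
  if (k_max < 1) stopf("k_max must be >= 1")
  families <- match.arg(families, MIX_FAMILIES, several.ok = TRUE)
  families <- MIX_FAMILIES[MIX_FAMILIES %in% families]   # canonical order
  if (inherits(x, "longevol_ccf")) x <- x$values[clustering_rows(x), , drop = FALSE]
  x <- as.matrix(x)
  fits <- list()
  tab <- data.frame(k = integer(), family = character(), bic = numeric(),
                    loglik = numeric())
  for (k in seq_len(min(k_max, nrow(x)))) {
    for (fam in families) {
      # only score identifiable models: fewer parameters than observations
      if (mixture_n_params(k, ncol(x), fam) >= nrow(x)) next
      fit <- tryCatch(fit_mixture(x, k, fam, seed = seed, n_restarts = n_restarts),
                      error = function(e) NULL)
      if (is.null(fit)) next
      fits[[length(fits) + 1L]] <- fit
      tab <- rbind(tab, data.frame(k = k, family = fam, bic = fit$bic,
                                   loglik = fit$loglik))
    }
  }
  if (!length(fits)) stopf("all (k, family) combinations failed")
  fam_rank <- match(tab$family, MIX_FAMILIES)
  best <- order(tab$bic, tab$k, fam_rank)[1]
  out <- fits[[best]]
  attr(out, "bic_table") <- tab
  out
}

#' Classify a clonality trajectory
#'
#' Presence at a timepoint means mean CCF at or above
#' `presence_threshold`. A trajectory is `preserved` when present at every
#' timepoint; `lost` when present at the first and absent at the final
#' timepoint; `emerged@t` when absent at all timepoints before `t` (t > 1)
#' and present from `t` onward; anything else is `transient`.
#'
#' @param traj numeric vector of mean CCF per timepoint.
#' @param presence_threshold presence cutoff in (0, 1), default 0.10.
#' @return a single string: `"preserved"`, `"lost"`, `"emerged@t"` or
#'   `"transient"`.
#' @examples
#' trajectory_class(c(0.92, 0.88, 0.85))  # preserved
#' trajectory_class(c(0.60, 0.03, 0.01))  # lost
#' trajectory_class(c(0.02, 0.04, 0.45))  # emerged@3
#' @export
trajectory_class <- function(traj, presence_threshold = 0.10) {
  stopifnot(presence_threshold > 0, presence_threshold < 1)
  present <- traj >= presence_threshold
  tn <- length(present)
  if (all(present)) return("preserved")
  if (present[1] && !present[tn]) return("lost")
  if (any(present)) {
    t0 <- which(present)[1]
    if (t0 > 1 && all(present[t0:tn])) return(paste0("emerged@", t0))
  }
  "transient"
}

#' Classify fitted mixture components as clone-evolution classes
#'
#' Applies [trajectory_class()] to each component's mean CCF trajectory.
#' Components that attracted no mutations under the hard max-posterior
#' assignment are dropped.
#'
#' @param fit a `mixture_fit` from [fit_mixture()] or [select_model()].
#' @param presence_threshold presence cutoff, default 0.10.
#' @return data.frame with `cluster_id`, `size`, `evo_class` and one
#'   `mean_t<j>` column per timepoint.
#' @export
classify_clusters <- function(fit, presence_threshold = 0.10) {
  stopifnot(inherits(fit, "mixture_fit"))
  sizes <- tabulate(fit$assignments, nbins = fit$k)
  keep <- which(sizes > 0)
  out <- data.frame(cluster_id = keep, size = sizes[keep],
                    evo_class = vapply(keep, function(j)
                      trajectory_class(fit$means[j, ], presence_threshold),
                      character(1)))
  for (j in seq_len(fit$d))
    out[[paste0("mean_t", j)]] <- fit$means[keep, j]
  rownames(out) <- NULL
  out
}
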