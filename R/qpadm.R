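#' f4 profiles of left populations against a right set
#'
#' For every left population `l`, computes the vector of
#' `f4(l, r0; rj, r0)` over the non-base right populations `rj`, together
#' with delete-one-block values.  Under an admixture model the target's
#' profile is the weight-combination of its sources' profiles, which is the
#' linear system the weight fit solves.
#'
#' @param fmat frequency matrix (sites x populations).
#' @param left left population columns (target first, then sources).
#' @param rights right (reference) population columns; the first is the
#'   base `r0`.
#' @param blocks integer block index per site.
#' @param allsnps per-statistic site overlap (TRUE, the "allsnps"
#'   behaviour) or the global intersection over all left and right
#'   populations (FALSE).
#' @return list with `est` (L x (R-1) matrix), `loo` (L x (R-1) x B array
#'   of delete-one-block estimates), `n_blocks`, `n_snps`.
#' @export
f4_profile <- function(fmat, left, rights, blocks, allsnps = TRUE) {
  if (length(rights) < 2L) stop("f4_profile: need >= 2 right populations")
  cols <- c(left, rights)
  miss <- setdiff(cols, colnames(fmat))
  if (length(miss)) stop("f4_profile: missing populations: ",
                         paste(miss, collapse = ", "))
  empty <- cols[vapply(cols, function(p) all(is.na(fmat[, p])), TRUE)]
  if (length(empty)) stop("f4_profile: population(s) empty after filters: ",
                          paste(empty, collapse = ", "))
  r0 <- rights[1]; rj <- rights[-1]
  B <- max(blocks)
  L <- length(left); J <- length(rj)
  est <- matrix(NA_real_, L, J, dimnames = list(left, rj))
  loo <- array(NA_real_, dim = c(L, J, B))
  nsnp <- matrix(0L, L, J)
  base_ok <- if (allsnps) rep(TRUE, nrow(fmat)) else
    stats::complete.cases(fmat[, cols, drop = FALSE])
  for (li in seq_len(L)) {
    dl <- fmat[, left[li]] - fmat[, r0]
    for (ji in seq_len(J)) {
      t <- dl * (fmat[, rj[ji]] - fmat[, r0])
      ok <- base_ok & !is.na(t)
      if (!any(ok)) stop("f4_profile: no overlap for (", left[li], ", ",
                         rj[ji], ")")
      tb <- rep(0, B); nb <- rep(0L, B)
      agg <- rowsum(t[ok], blocks[ok])
      cnt <- rowsum(rep(1L, sum(ok)), blocks[ok])
      bi <- as.integer(rownames(agg))
      tb[bi] <- agg; nb[bi] <- cnt
      tot <- sum(tb); n <- sum(nb)
      est[li, ji] <- tot / n
      l <- (tot - tb) / pmax(n - nb, 1L)
      l[nb == n] <- NA  # a block holding all sites cannot be deleted
      loo[li, ji, ] <- l
      nsnp[li, ji] <- n
    }
  }
  list(est = est, loo = loo, n_blocks = B, n_snps = nsnp)
}

# Solve the constrained GLS for admixture weights given profile estimates.
# Returns weights (length k, summing to 1), the residual vector and the
# chi-square against covariance Q.
solve_weights <- function(est, Q, target, sources) {
  k <- length(sources)
  y <- est[target, ]
  if (k == 1L) {
    e <- y - est[sources, ]
    return(list(alpha = stats::setNames(1, sources), resid = e))
  }
  base <- sources[k]
  b <- y - est[base, ]
  M <- t(est[sources[-k], , drop = FALSE]) -
    matrix(est[base, ], ncol = k - 1L, nrow = length(b))
  Qi <- solve_ridge(Q)
  A <- t(M) %*% Qi %*% M
  rhs <- t(M) %*% Qi %*% b
  a_head <- as.numeric(solve_ridge_sys(A, rhs))
  alpha <- c(a_head, 1 - sum(a_head))
  names(alpha) <- c(sources[-k], base)
  e <- as.numeric(b - M %*% a_head)
  list(alpha = alpha[sources], resid = e)
}

solve_ridge <- function(Q) {
  eps <- max(1e-8 * sum(diag(Q)) / nrow(Q), 1e-14)
  out <- tryCatch(solve(Q), error = function(e) NULL)
  if (is.null(out)) {
    message("qpadm fit: singular covariance; ridge ", signif(eps, 3), " applied")
    out <- tryCatch(solve(Q + diag(eps, nrow(Q))), error = function(e) NULL)
    if (is.null(out)) stop("qpadm fit: covariance singular even after ridge")
  }
  out
}

solve_ridge_sys <- function(A, rhs) {
  out <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(out)) {
    eps <- 1e-8 * sum(diag(A)) / nrow(A)
    out <- solve(A + diag(eps, nrow(A)), rhs)
  }
  out
}

#' Fit admixture weights for a target from source populations (qpAdm style)
#'
#' Expresses the target's f4 profile against the right populations as a
#' weight combination of the source profiles (weights summing to one),
#' estimated by feasible generalized least squares under the
#' block-jackknife covariance of the residual profile.  The full-model
#' p-value is the chi-square tail of the weighted residual with
#' `(n_rights - 1) - (n_sources - 1)` degrees of freedom; weight standard
#' errors come from re-fitting on every block deletion.
#'
#' @inheritParams f4_profile
#' @param target target population column.
#' @param sources source population columns (1-3).
#' @return An object of class `qpadm_fit`: list with `weights`, `se`,
#'   `p_value`, `chi2`, `df`, `feasible` (all weights in `[0,1]`),
#'   `target`, `sources`, `rights`, `n_blocks`.
#' @export
fit_weights <- function(fmat, target, sources, rights, blocks,
                        allsnps = TRUE) {
  if (length(sources) < 1L || length(sources) > 3L) {
    stop("fit_weights: 1-3 sources supported")
  }
  if (length(rights) < length(sources) + 1L) {
    stop("fit_weights: need at least sources + 1 right populations")
  }
  prof <- f4_profile(fmat, c(target, sources), rights, blocks, allsnps)
  B <- prof$n_blocks
  J <- ncol(prof$est)
  # residual covariance via delete-one-block jackknife at the current fit
  fit0 <- solve_weights(prof$est, diag(J), target, sources)
  loo_mat <- function(b) {
    eb <- prof$loo[, , b, drop = FALSE]
    dim(eb) <- dim(prof$est)
    dimnames(eb) <- dimnames(prof$est)
    eb[is.na(eb)] <- prof$est[is.na(eb)]
    eb
  }
  resid_loo <- function(alpha) {
    E <- matrix(NA_real_, B, J)
    for (b in seq_len(B)) {
      if (all(is.na(prof$loo[, , b]))) next
      eb <- loo_mat(b)
      E[b, ] <- eb[target, ] - as.numeric(alpha %*% eb[sources, , drop = FALSE])
    }
    E[stats::complete.cases(E), , drop = FALSE]
  }
  jack_cov <- function(alpha) {
    E <- resid_loo(alpha)
    nb <- nrow(E)
    ctr <- sweep(E, 2L, colMeans(E))
    (nb - 1) / nb * crossprod(ctr)  # delete-one jackknife covariance
  }
  Q <- jack_cov(fit0$alpha)
  fit <- solve_weights(prof$est, Q, target, sources)
  Q <- jack_cov(fit$alpha)
  fit <- solve_weights(prof$est, Q, target, sources)
  Qi <- solve_ridge(Q)
  chi2 <- as.numeric(t(fit$resid) %*% Qi %*% fit$resid)
  df <- J - (length(sources) - 1L)
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  # block jackknife of the whole fit for weight SEs
  se <- rep(NA_real_, length(sources))
  if (length(sources) > 1L) {
    W <- matrix(NA_real_, B, length(sources))
    for (b in seq_len(B)) {
      if (all(is.na(prof$loo[, , b]))) next
      W[b, ] <- solve_weights(loo_mat(b), Q, target, sources)$alpha
    }
    W <- W[stats::complete.cases(W), , drop = FALSE]
    nb <- nrow(W)
    se <- sqrt((nb - 1) / nb * colSums(sweep(W, 2L, colMeans(W))^2))
  }
  structure(list(target = target, sources = sources, rights = rights,
                 weights = fit$alpha, se = stats::setNames(se, sources),
                 chi2 = chi2, df = df, p_value = p,
                 feasible = all(fit$alpha >= 0 & fit$alpha <= 1),
                 n_blocks = B),
            class = "qpadm_fit")
}

#' @export
print.qpadm_fit <- function(x, ...) {
  cat("qpadm fit:", x$target, "=",
      paste(sprintf("%.3f*%s", x$weights, x$sources), collapse = " + "), "\n")
  cat("  full-model p =", signif(x$p_value, 3), " (chi2 =", signif(x$chi2, 4),
      ", df =", x$df, "); feasible:", x$feasible, "\n")
  invisible(x)
}

#' Nested-model plausibility rule
#'
#' Fits, for each source dropped, the reduced model, and declares the full
#' model plausible only when every nested model is rejected (nested p <
#' 0.05), the full model itself fits (p >= 0.05), and the weights are
#' feasible.  The three conditions are reported separately.
#'
#' @inheritParams fit_weights
#' @param alpha_nested rejection level for nested models (default 0.05).
#' @return list with `full` (the `qpadm_fit`), `nested` (data.frame
#'   dropped-source p-values), `conditions` and `plausible`.
#' @export
nested_rule <- function(fmat, target, sources, rights, blocks,
                        allsnps = TRUE, alpha_nested = 0.05) {
  full <- fit_weights(fmat, target, sources, rights, blocks, allsnps)
  nested <- data.frame(dropped = character(0), p_value = numeric(0),
                       stringsAsFactors = FALSE)
  undecidable <- FALSE
  for (s in sources) {
    reduced <- setdiff(sources, s)
    if (!length(reduced)) next
    fit_r <- tryCatch(
      fit_weights(fmat, target, reduced, rights, blocks, allsnps),
      error = function(e) NULL)
    if (is.null(fit_r)) {
      undecidable <- TRUE
      nested <- rbind(nested, data.frame(dropped = s, p_value = NA_real_))
      next
    }
    nested <- rbind(nested, data.frame(dropped = s, p_value = fit_r$p_value))
  }
  conditions <- list(
    nested_all_rejected = nrow(nested) > 0 && !any(is.na(nested$p_value)) &&
      all(nested$p_value < alpha_nested),
    full_fits = full$p_value >= alpha_nested,
    feasible = full$feasible)
  plausible <- !undecidable && all(unlist(conditions))
  list(full = full, nested = nested, conditions = conditions,
       plausible = plausible, undecidable = undecidable)
}

#' Rotating-outgroup model screen
#'
#' Fits every `k`-subset of a candidate pool as sources with the pool
#' complement (plus any fixed rights) as the right set, passes each model
#' through the nested rule, and ranks results by plausibility then
#' full-model p-value.  Models whose sources include single-individual
#' populations are flagged.
#'
#' @inheritParams fit_weights
#' @param pool candidate population columns to rotate.
#' @param k_sources number of sources per model.
#' @param fixed_rights populations always kept in the right set.
#' @param single_individuals pool members that are single individuals
#'   (flagged, per standard caution).
#' @param max_models refuse to enumerate above this many subsets.
#' @return data.frame, one row per model: sources, p_value, weights,
#'   plausible, flags.
#' @export
rotate_outgroups <- function(fmat, target, pool, k_sources, blocks,
                             fixed_rights = character(0),
                             single_individuals = character(0),
                             allsnps = TRUE, max_models = 200L) {
  combos <- utils::combn(pool, k_sources, simplify = FALSE)
  if (length(combos) > max_models) {
    stop("rotate_outgroups: ", length(combos), " models exceed the guard of ",
         max_models, "; reduce the pool or raise max_models explicitly")
  }
  rows <- list()
  for (src in combos) {
    rights <- c(fixed_rights, setdiff(pool, src))
    if (length(rights) < k_sources + 1L) next
    nr <- tryCatch(
      nested_rule(fmat, target, src, rights, blocks, allsnps),
      error = function(e) NULL)
    if (is.null(nr)) next
    rows[[length(rows) + 1L]] <- data.frame(
      sources = paste(src, collapse = "+"),
      p_value = nr$full$p_value,
      weights = paste(sprintf("%.3f", nr$full$weights), collapse = ","),
      feasible = nr$full$feasible,
      plausible = nr$plausible,
      single_individual_source = any(src %in% single_individuals),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(-out$plausible, -out$p_value), , drop = FALSE]
}

#' Per-individual ancestry decomposition with two-way fallback
#'
#' Fits a fixed three-source model for one individual (its pseudo-haploid
#' codes acting as the target frequency column).  When a nested model is
#' not rejected (nested p > 0.05), the analysis falls back to the
#' corresponding two-way model: if that surviving model lacks the focal
#' source, the focal ancestry is set to 0.  The provenance of the fallback
#' path is recorded.
#'
#' @inheritParams fit_weights
#' @param individual target column (an individual's codes).
#' @param sources exactly three source columns; `focal` defaults to the
#'   first.
#' @param focal the source whose ancestry fraction is reported.
#' @return list with `weights` (length 3, in source order; NA when a model
#'   failed entirely), `focal_ancestry`, `provenance` ("three_way",
#'   "fallback_two_way", "fallback_zero" or "failed"), `p_value`.
#' @export
per_individual_ancestry <- function(fmat, individual, sources, rights,
                                    blocks, focal = sources[1],
                                    allsnps = TRUE) {
  stopifnot(length(sources) == 3L, focal %in% sources)
  nr <- tryCatch(nested_rule(fmat, individual, sources, rights, blocks,
                             allsnps),
                 error = function(e) NULL)
  if (is.null(nr)) {
    return(list(weights = stats::setNames(rep(NA_real_, 3), sources),
                focal_ancestry = NA_real_, provenance = "failed",
                p_value = NA_real_))
  }
  weak <- nr$nested[!is.na(nr$nested$p_value) & nr$nested$p_value > 0.05, ]
  if (nrow(weak) == 0L) {
    return(list(weights = nr$full$weights,
                focal_ancestry = unname(nr$full$weights[focal]),
                provenance = "three_way", p_value = nr$full$p_value))
  }
  # drop the least-needed source (highest nested p) and refit two-way
  dropped <- weak$dropped[which.max(weak$p_value)]
  surviving <- setdiff(sources, dropped)
  if (!(focal %in% surviving)) {
    return(list(weights = stats::setNames(rep(NA_real_, 3), sources),
                focal_ancestry = 0, provenance = "fallback_zero",
                p_value = nr$full$p_value))
  }
  two <- tryCatch(fit_weights(fmat, individual, surviving, rights, blocks,
                              allsnps),
                  error = function(e) NULL)
  if (is.null(two)) {
    return(list(weights = stats::setNames(rep(NA_real_, 3), sources),
                focal_ancestry = NA_real_, provenance = "failed",
                p_value = NA_real_))
  }
  w <- stats::setNames(rep(0, 3), sources)
  w[surviving] <- two$weights
  list(weights = w, focal_ancestry = unname(w[focal]),
       provenance = "fallback_two_way", p_value = two$p_value)
}
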