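#' Pairwise pseudo-haploid mismatch rate (READ-style P0)
#'
#' Computes, over sites passing a minor-allele-frequency filter in a
#' designated reference population, the fraction of overlapping sites where
#' two pseudo-haploid genotype vectors disagree, in non-overlapping genomic
#' windows and overall.
#'
#' @param hap_i,hap_j integer vectors of pseudo-haploid calls (0/1/NA) over
#'   the panel's sites.
#' @param panel a `snp_panel` with a frequency column `freq_pop`.
#' @param freq_pop population used for the MAF filter.
#' @param min_maf minimum minor-allele frequency (default 0.1).
#' @param window window span in bp (default 1 Mb); per-window values support
#'   a spread estimate.
#' @return list with `p0` (overall mismatch fraction), `n_overlap`,
#'   `windows` (data.frame chrom, window, n, p0).  `p0` is NA at zero
#'   overlap.
#' @export
read_p0 <- function(hap_i, hap_j, panel, freq_pop, min_maf = 0.1,
                    window = 1e6) {
  if (is.null(panel$freq) || !(freq_pop %in% colnames(panel$freq))) {
    stop("read_p0: no frequencies for population '", freq_pop, "'")
  }
  f <- panel$freq[, freq_pop]
  keep <- !is.na(f) & pmin(f, 1 - f) >= min_maf
  ok <- keep & !is.na(hap_i) & !is.na(hap_j)
  n <- sum(ok)
  if (n == 0L) {
    return(list(p0 = NA_real_, n_overlap = 0L,
                windows = data.frame(chrom = character(0), window = integer(0),
                                     n = integer(0), p0 = numeric(0))))
  }
  mm <- hap_i[ok] != hap_j[ok]
  # integer window key: chromosome index * offset + window ordinal
  chrom_i <- match(panel$sites$chrom[ok], unique(panel$sites$chrom))
  win <- chrom_i * 2^20 + panel$sites$pos[ok] %/% window
  agg_m <- rowsum(as.numeric(mm), win)
  agg_n <- rowsum(rep(1L, n), win)
  windows <- data.frame(window = as.numeric(rownames(agg_m)),
                        n = as.integer(agg_n),
                        p0 = as.numeric(agg_m / agg_n))
  list(p0 = mean(mm), n_overlap = n, windows = windows)
}

#' Classify READ mismatch rates into degrees of relatedness
#'
#' Normalizes raw P0 values by the cohort median (assuming a mostly
#' unrelated cohort) and classifies pairs by midpoint cutoffs between the
#' expected normalized mismatch `1 - phi` for kinship `phi` = 0.5 (identical
#' / same individual), 0.25 (first degree), 0.125 (second degree) and 0
#' (unrelated): below 0.625 identical, `[0.625, 0.8125)` first degree,
#' `[0.8125, 0.90625)` second degree, at or above 0.90625 unrelated.
#'
#' @param p0 numeric vector of raw P0 values, one per pair.
#' @param norm explicit normalization value; when NULL the cohort median is
#'   used, requiring at least 10 pairs.
#' @return data.frame with `p0_raw`, `p0_normalized`, `degree` (factor
#'   identical/first/second/unrelated).
#' @export
classify_read <- function(p0, norm = NULL) {
  if (is.null(norm)) {
    usable <- sum(!is.na(p0))
    if (usable < 10L) {
      stop("classify_read: only ", usable, " pairs; cohort-median ",
           "normalization needs >= 10. Supply an explicit `norm` value ",
           "(the expected unrelated-pair P0).")
    }
    norm <- stats::median(p0, na.rm = TRUE)
  }
  pn <- p0 / norm
  degree <- cut(pn, breaks = c(-Inf, 0.625, 0.8125, 0.90625, Inf),
                labels = c("identical", "first", "second", "unrelated"),
                right = FALSE)
  data.frame(p0_raw = p0, p0_normalized = pn, degree = degree)
}

#' IBS counts, R0, R1 and KING-robust theta from diploid calls
#'
#' Operative definitions (frozen here): with counts over overlapping sites,
#' IBS0 = opposite homozygotes, IBS2 = identical genotypes, IBS1 = the rest;
#' `king_theta = (N_both_het - 2 * IBS0) / (N_het_i + N_het_j)` (the
#' KING-robust within-family estimator); `R0 = IBS0 / N_both_het`;
#' `R1 = N_both_het / (IBS0 + IBS1)`.
#'
#' @param g_i,g_j integer vectors of diploid allele-2 doses (0/1/2/NA).
#' @return list of counts and statistics; `r0` is NA when there are no
#'   double-heterozygous sites.
#' @export
ibs_stats <- function(g_i, g_j) {
  ok <- !is.na(g_i) & !is.na(g_j)
  a <- g_i[ok]; b <- g_j[ok]
  ibs0 <- sum(abs(a - b) == 2L)
  ibs2 <- sum(a == b)
  ibs1 <- sum(ok) - ibs0 - ibs2
  nhh <- sum(a == 1L & b == 1L)
  het_i <- sum(a == 1L); het_j <- sum(b == 1L)
  king <- if (het_i + het_j > 0L) (nhh - 2 * ibs0) / (het_i + het_j) else NA_real_
  r0 <- if (nhh > 0L) ibs0 / nhh else NA_real_
  r1 <- if (ibs0 + ibs1 > 0L) nhh / (ibs0 + ibs1) else NA_real_
  list(n_overlap = sum(ok), ibs0 = ibs0, ibs1 = ibs1, ibs2 = ibs2,
       n_both_het = nhh, king_theta = king, r0 = r0, r1 = r1)
}

# Per-site mixture-component likelihoods for the non-inbred 9-cell joint
# genotype table: c0 (IBD 0), c1 (IBD 1), c2 (IBD 2), given GL matrices and
# allele-2 frequency p.
k_component_liks <- function(l1, l2, p) {
  q <- 1 - p
  w0 <- q^2; w1 <- 2 * p * q; w2 <- p^2
  s1 <- l1[, 1] * w0 + l1[, 2] * w1 + l1[, 3] * w2
  s2 <- l2[, 1] * w0 + l2[, 2] * w1 + l2[, 3] * w2
  c0 <- s1 * s2
  c2 <- l1[, 1] * l2[, 1] * w0 + l1[, 2] * l2[, 2] * w1 + l1[, 3] * l2[, 3] * w2
  c1 <- q^3 * l1[, 1] * l2[, 1] +
    q^2 * p * (l1[, 1] * l2[, 2] + l1[, 2] * l2[, 1]) +
    p * q * l1[, 2] * l2[, 2] +
    p^2 * q * (l1[, 2] * l2[, 3] + l1[, 3] * l2[, 2]) +
    p^3 * l1[, 3] * l2[, 3]
  cbind(c0, c1, c2)
}

#' Maximum-likelihood IBD-sharing coefficients from genotype likelihoods
#'
#' EM estimation of the non-inbred sharing coefficients (k0, k1, k2) for a
#' pair of individuals from their genotype-likelihood triples and reference
#' allele frequencies, maximizing
#' `sum_sites log sum_{g1,g2} L1(g1) L2(g2) P(g1, g2 | f, k)` over the
#' k-simplex.  The kinship coefficient is `theta = k1/4 + k2/2`.
#'
#' @param gl_i,gl_j numeric matrices sites x 3 of linear genotype
#'   likelihoods (rows with NA are dropped).
#' @param freq allele-2 frequency vector over the same sites.
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter maximum EM iterations (default 200).
#' @return list with `k` (named length-3 simplex vector), `theta`,
#'   `loglik`, `n_sites`, `converged`, `iterations`.
#' @export
ml_k_coefficients <- function(gl_i, gl_j, freq, tol = 1e-6, max_iter = 200L) {
  ok <- !is.na(gl_i[, 1]) & !is.na(gl_j[, 1]) & !is.na(freq)
  l1 <- gl_i[ok, , drop = FALSE]
  l2 <- gl_j[ok, , drop = FALSE]
  p <- freq[ok]
  n <- sum(ok)
  if (n == 0L) {
    return(list(k = c(k0 = NA_real_, k1 = NA_real_, k2 = NA_real_),
                theta = NA_real_, loglik = NA_real_, n_sites = 0L,
                converged = FALSE, iterations = 0L))
  }
  comp <- k_component_liks(l1, l2, p)
  k <- c(1, 1, 1) / 3
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    mix <- comp %*% k
    ll <- sum(log(pmax(mix, 1e-300)))
    w <- comp * rep(k, each = nrow(comp)) / as.numeric(pmax(mix, 1e-300))
    k <- colMeans(w)
    k <- k / sum(k)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    ll_old <- ll
  }
  k <- stats::setNames(as.numeric(k), c("k0", "k1", "k2"))
  list(k = k, theta = k[["k1"]] / 4 + k[["k2"]] / 2, loglik = ll,
       n_sites = n, converged = converged, iterations = it)
}

# EM for a two-component sharing mixture: per-site IBD component likelihood
# c_ibd vs independent component c_ind; returns the sharing proportion.
share_em <- function(c_ibd, c_ind, tol = 1e-6, max_iter = 200L) {
  s <- 0.25
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    mix <- s * c_ibd + (1 - s) * c_ind
    ll <- sum(log(pmax(mix, 1e-300)))
    w <- s * c_ibd / pmax(mix, 1e-300)
    s <- mean(w)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  s
}

#' X-chromosome kinship coefficient
#'
#' Estimates the X kinship coefficient: the probability that a randomly
#' drawn X allele from each individual is identical by descent.  On this
#' scale mother-son and father-daughter transmissions score about 0.5,
#' brothers about 0.5, father-son 0, and an identical male sampled twice 1.
#' Male X data are treated as haploid (2-column likelihoods), female data
#' as diploid; each pair type uses a matched joint model (male-male and
#' male-female via a two-component sharing mixture, female-female via the
#' diploid k-model whose theta is the X kinship directly).
#'
#' @param l_i,l_j likelihood matrices over X sites: 2 columns for males,
#'   3 for females.
#' @param freq allele-2 frequency vector over the same sites.
#' @param sex_i,sex_j "M" or "F".
#' @param min_overlap overlap gate; below it the estimate is withheld
#'   (default 1000 sites).
#' @return list with `theta_x` (NA when gated), `n_overlap`, `gated`.
#' @export
theta_x <- function(l_i, l_j, freq, sex_i, sex_j, min_overlap = 1000L) {
  ok <- !is.na(l_i[, 1]) & !is.na(l_j[, 1]) & !is.na(freq)
  n <- sum(ok)
  if (n < min_overlap) {
    return(list(theta_x = NA_real_, n_overlap = n, gated = TRUE))
  }
  l1 <- l_i[ok, , drop = FALSE]; l2 <- l_j[ok, , drop = FALSE]
  p <- freq[ok]; q <- 1 - p
  type <- paste0(sex_i, sex_j)
  if (type == "MM") {
    c_ibd <- l1[, 1] * l2[, 1] * q + l1[, 2] * l2[, 2] * p
    c_ind <- (l1[, 1] * q + l1[, 2] * p) * (l2[, 1] * q + l2[, 2] * p)
    s <- share_em(c_ibd, c_ind)
  } else if (type %in% c("MF", "FM")) {
    if (type == "FM") { tmp <- l1; l1 <- l2; l2 <- tmp }
    # l1 male haploid (2 col), l2 female diploid (3 col); mixture component:
    # one female allele IBD with the male allele, the other drawn from the
    # frequency.  The mixture weight counts "IBD with one named allele", so
    # the random-allele kinship is half of it.
    c_ibd <- q * l1[, 1] * (q * l2[, 1] + p * l2[, 2]) +
      p * l1[, 2] * (q * l2[, 2] + p * l2[, 3])
    c_ind <- (q * l1[, 1] + p * l1[, 2]) *
      (q^2 * l2[, 1] + 2 * p * q * l2[, 2] + p^2 * l2[, 3])
    s <- share_em(c_ibd, c_ind) / 2
  } else {
    fit <- ml_k_coefficients(l1, l2, p)
    s <- fit$theta
  }
  list(theta_x = s, n_overlap = n, gated = FALSE)
}

#' Consolidate READ and likelihood-based degree calls
#'
#' When both methods call a degree and they agree, that degree is returned;
#' on conflict the likelihood-based (NgsRelate-equivalent) call takes
#' priority and the conflict is flagged; when only one method produced a
#' gated call its result is used with provenance recorded.
#'
#' @param degree_read,degree_ml character degree calls
#'   ("identical"/"first"/"second"/"unrelated") or NA.
#' @return list with `degree`, `source` ("both", "ml", "read" or "none") and
#'   `conflict` flag.
#' @export
consolidate_degree <- function(degree_read, degree_ml) {
  has_r <- !is.na(degree_read); has_m <- !is.na(degree_ml)
  if (has_r && has_m) {
    if (degree_read == degree_ml) {
      list(degree = degree_ml, source = "both", conflict = FALSE)
    } else {
      list(degree = degree_ml, source = "ml", conflict = TRUE)
    }
  } else if (has_m) {
    list(degree = degree_ml, source = "ml", conflict = FALSE)
  } else if (has_r) {
    list(degree = degree_read, source = "read", conflict = FALSE)
  } else {
    list(degree = NA_character_, source = "none", conflict = FALSE)
  }
}

#' Degree classification from estimated kinship theta
#'
#' Midpoint cutoffs on the kinship coefficient: theta above 0.354 identical,
#' `(0.177, 0.354]` first degree, `(0.088, 0.177]` second degree, otherwise
#' unrelated (the KING convention of powers-of-two boundaries
#' `1/2^(5/2), 1/2^(7/2)` ...).
#'
#' @param theta kinship coefficient estimate(s).
#' @return character vector of degrees.
#' @export
degree_from_theta <- function(theta) {
  cut(theta, breaks = c(-Inf, 2^-3.5, 2^-2.5, 2^-1.5, Inf),
      labels = c("unrelated", "second", "first", "identical"),
      right = TRUE)
}

#' Pairwise kinship table for a cohort
#'
#' Builds the full dyad table: READ-style P0 with cohort-median
#' normalization, IBS/KING statistics from diploid calls when present,
#' maximum-likelihood k-coefficients on a per-pair distance-thinned site
#' set, X-chromosome theta when X likelihoods are supplied, overlap gates,
#' and the consolidated degree.
#'
#' @param store a `geno_store` with `haploid` (for P0) and/or `gl`
#'   components on an autosomal panel carrying `freq_pop` frequencies.
#' @param freq_pop reference population for MAF filtering and k-model
#'   frequencies.
#' @param store_x optional `geno_store` on an X panel (gl component used).
#' @param sexes named character vector of "M"/"F" per individual (needed for
#'   `store_x`).
#' @param min_maf MAF filter for P0 (default 0.1).
#' @param thin_gap per-pair thinning distance in bp for the likelihood
#'   model (default 2500).
#' @param gate_auto,gate_x overlap gates (defaults 10000 and 1000 SNPs).
#' @param norm explicit P0 normalization value (default cohort median).
#' @return data.frame, one row per unordered pair, with all pair-kinship
#'   fields and gate flags.
#' @export
kinship_table <- function(store, freq_pop, store_x = NULL, sexes = NULL,
                          min_maf = 0.1, thin_gap = 2500,
                          gate_auto = 10000L, gate_x = 1000L, norm = NULL) {
  ids <- store$ind$id
  pairs <- utils::combn(ids, 2L)
  np <- ncol(pairs)
  res <- data.frame(id1 = pairs[1, ], id2 = pairs[2, ],
                    n_overlap_auto = NA_integer_, p0_raw = NA_real_,
                    p0_normalized = NA_real_, degree_read = NA_character_,
                    ibs0 = NA_integer_, ibs1 = NA_integer_, ibs2 = NA_integer_,
                    r0 = NA_real_, r1 = NA_real_, king_theta = NA_real_,
                    k0 = NA_real_, k1 = NA_real_, k2 = NA_real_,
                    theta_auto = NA_real_, n_overlap_ml = NA_integer_,
                    degree_ml = NA_character_, theta_x = NA_real_,
                    n_overlap_x = NA_integer_, gate_auto = FALSE,
                    gate_x = FALSE, degree_final = NA_character_,
                    degree_source = NA_character_, conflict = FALSE,
                    stringsAsFactors = FALSE)
  freq <- store$panel$freq[, freq_pop]
  for (k in seq_len(np)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ii <- match(i, ids); jj <- match(j, ids)
    if (!is.null(store$haploid)) {
      r <- read_p0(store$haploid[, ii], store$haploid[, jj], store$panel,
                   freq_pop, min_maf = min_maf)
      res$n_overlap_auto[k] <- r$n_overlap
      res$p0_raw[k] <- r$p0
    }
    if (!is.null(store$diploid)) {
      ib <- ibs_stats(store$diploid[, ii], store$diploid[, jj])
      res$ibs0[k] <- ib$ibs0; res$ibs1[k] <- ib$ibs1; res$ibs2[k] <- ib$ibs2
      res$r0[k] <- ib$r0; res$r1[k] <- ib$r1; res$king_theta[k] <- ib$king_theta
    }
    if (!is.null(store$gl)) {
      both <- which(!is.na(store$gl[, ii, 1]) & !is.na(store$gl[, jj, 1]) &
                      !is.na(freq))
      if (length(both)) {
        sub <- panel_subset(store$panel, both)
        kept <- thin_by_distance(sub, thin_gap)
        use <- both[match(kept$sites$id, sub$sites$id)]
        fit <- ml_k_coefficients(store$gl[use, ii, , drop = TRUE],
                                 store$gl[use, jj, , drop = TRUE], freq[use])
        res$k0[k] <- fit$k[["k0"]]; res$k1[k] <- fit$k[["k1"]]
        res$k2[k] <- fit$k[["k2"]]; res$theta_auto[k] <- fit$theta
        res$n_overlap_ml[k] <- fit$n_sites
      }
    }
    if (!is.null(store_x) && !is.null(sexes)) {
      fx <- store_x$panel$freq[, freq_pop]
      li <- x_likelihoods(store_x, ii, sexes[[i]])
      lj <- x_likelihoods(store_x, jj, sexes[[j]])
      tx <- theta_x(li, lj, fx, sexes[[i]], sexes[[j]], min_overlap = gate_x)
      res$theta_x[k] <- tx$theta_x
      res$n_overlap_x[k] <- tx$n_overlap
      res$gate_x[k] <- !tx$gated
    }
  }
  res$gate_auto <- !is.na(res$n_overlap_auto) & res$n_overlap_auto >= gate_auto
  cls <- classify_read(res$p0_raw, norm = norm)
  res$p0_normalized <- cls$p0_normalized
  res$degree_read <- as.character(cls$degree)
  res$degree_read[!res$gate_auto] <- NA_character_
  res$degree_ml <- as.character(degree_from_theta(res$theta_auto))
  ml_gate <- !is.na(res$n_overlap_ml) & res$n_overlap_ml >= gate_auto
  res$degree_ml[!ml_gate] <- NA_character_
  for (k in seq_len(np)) {
    con <- consolidate_degree(res$degree_read[k], res$degree_ml[k])
    res$degree_final[k] <- con$degree
    res$degree_source[k] <- con$source
    res$conflict[k] <- con$conflict
  }
  res
}

# Extract per-individual X likelihood matrix: haploid 2-col for males (from
# the gl array's hom columns renormalized), diploid 3-col for females.
x_likelihoods <- function(store_x, idx, sex) {
  gl <- store_x$gl[, idx, , drop = TRUE]
  if (sex == "M") {
    h <- gl[, c(1, 3)]
    tot <- rowSums(h)
    h / ifelse(tot > 0, tot, NA_real_)
  } else {
    gl
  }
}
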