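#' Post-mortem damage profiles
#'
#' Probability of deamination miscalls by distance from the read end:
#' C-to-T assessed with the 5' profile, G-to-A with the 3' profile (here both
#' indexed by the read's distance to its nearer end, the resolution the
#' pileups carry).  Reads without a usable distance fall back to a flat rate.
#'
#' @param ct numeric vector, C-to-T probability at distance 1, 2, ...;
#'   distances beyond the vector use the flat rate.
#' @param ga numeric vector, G-to-A probability by distance.
#' @param flat fallback rate for distances outside the profiles or missing.
#' @return An object of class `damage_profile`.
#' @export
damage_profile <- function(ct = numeric(0), ga = numeric(0), flat = 0) {
  stopifnot(all(ct >= 0 & ct <= 1), all(ga >= 0 & ga <= 1),
            flat >= 0, flat <= 1)
  structure(list(ct = ct, ga = ga, flat = flat), class = "damage_profile")
}

#' Constant-rate damage profile helper
#' @param rate deamination probability applied at distances 1..`span`.
#' @param span number of terminal positions affected.
#' @param flat rate beyond `span`.
#' @return a [damage_profile()].
#' @export
flat_damage <- function(rate, span = 2L, flat = 0) {
  damage_profile(ct = rep(rate, span), ga = rep(rate, span), flat = flat)
}

# Damage probability for a vector of distances (NA -> flat rate).
damage_rate <- function(damage, which = c("CT", "GA"), dist) {
  which <- match.arg(which)
  prof <- if (which == "CT") damage$ct else damage$ga
  out <- rep(damage$flat, length(dist))
  if (length(prof) > 0L) {
    ok <- !is.na(dist) & dist >= 1L & dist <= length(prof)
    out[ok] <- prof[dist[ok]]
  }
  out
}

#' Read damage profile from TSV
#' @param path TSV with columns `dist`, `ct`, `ga` (rates by terminal
#'   distance), optionally a `flat` column (first value used).
#' @return a [damage_profile()].
#' @export
read_damage_profile <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  d <- d[order(d$dist), ]
  flat <- if ("flat" %in% names(d)) d$flat[1] else 0
  damage_profile(ct = d$ct, ga = d$ga, flat = flat)
}

# P(observed base | true allele base) for each read, under:
#   true base --deamination (C->T / G->A, prob d)--> template
#   template --sequencing error (prob e, uniform other base)--> observed
# Vectorized over reads. obs, truth: base letters; e: error prob; dct/dga:
# per-read damage probabilities.
p_obs_given_true <- function(obs, truth, e, dct, dga) {
  d <- numeric(length(truth))
  is_c <- truth == "C"; is_g <- truth == "G"
  d[is_c] <- dct[is_c]; d[is_g] <- dga[is_g]
  dam <- truth
  dam[is_c] <- "T"; dam[is_g] <- "A"
  # P(obs | template): (1 - e) if equal else e/3
  p_if <- function(template) {
    out <- e / 3
    eq <- obs == template
    out[eq] <- 1 - e[eq]
    out
  }
  (1 - d) * p_if(truth) + d * p_if(dam)
}

#' Damage-aware genotype-likelihood calling
#'
#' For each covered site, computes genotype likelihoods as the product over
#' reads of the read likelihood under each genotype, where the per-read error
#' model combines the base-quality error probability with the deamination
#' probability whenever the true/observed pair is a deamination pair (C-to-T
#' via the 5'-distance profile, G-to-A via the 3'-distance profile; reads
#' without distance use the flat fallback).  The genotype quality GQ is the
#' phred-scaled difference between the best and second-best genotype
#' posterior under a flat prior.
#'
#' @param pileup data.frame with columns `site`, `base`, `qual`, `dist` for
#'   one individual (as produced by [simulate_reads()]).
#' @param panel a `snp_panel`; `sites` indexes rows of `panel$sites` that the
#'   pileup's `site` column refers to (default all rows).
#' @param damage a [damage_profile()].
#' @param ploidy 2 for diploid calls (genotypes a1/a1, a1/a2, a2/a2) or 1 for
#'   haploid calls (a1, a2) as used on the male X and Y.
#' @return list with `lik` (sites x genotypes matrix of normalized linear
#'   likelihoods, NA rows where no reads), `best` (allele-2 dose of the
#'   maximum-likelihood genotype), `gq` (phred difference best vs second) and
#'   `depth`.
#' @export
call_genotype_likelihoods <- function(pileup, panel, damage = damage_profile(),
                                      ploidy = 2L,
                                      sites = seq_len(nrow(panel$sites))) {
  s <- length(sites)
  a1 <- panel$sites$a1[sites]
  a2 <- panel$sites$a2[sites]
  ngen <- if (ploidy == 2L) 3L else 2L
  lik <- matrix(NA_real_, nrow = s, ncol = ngen)
  depth <- integer(s)
  gq <- rep(NA_real_, s)
  best <- rep(NA_integer_, s)
  if (nrow(pileup) == 0L) {
    return(list(lik = lik, best = best, gq = gq, depth = depth))
  }
  e <- 10^(-pileup$qual / 10)
  dct <- damage_rate(damage, "CT", pileup$dist)
  dga <- damage_rate(damage, "GA", pileup$dist)
  p1 <- p_obs_given_true(pileup$base, a1[pileup$site], e, dct, dga)
  p2 <- p_obs_given_true(pileup$base, a2[pileup$site], e, dct, dga)
  # per-read log-likelihood under each genotype
  if (ploidy == 2L) {
    ll <- cbind(log(p1), log(0.5 * p1 + 0.5 * p2), log(p2))
  } else {
    ll <- cbind(log(p1), log(p2))
  }
  agg <- rowsum(ll, group = pileup$site)
  idx <- as.integer(rownames(agg))
  depth[idx] <- tabulate(pileup$site, nbins = s)[idx]
  # normalize in linear scale per covered site (vectorized row max/min)
  cols <- lapply(seq_len(ncol(agg)), function(k) agg[, k])
  mx <- do.call(pmax, cols)
  lin <- exp(agg - mx)
  lin <- lin / rowSums(lin)
  lik[idx, ] <- lin
  second <- if (ncol(agg) == 2L) do.call(pmin, cols) else
    rowSums(agg) - mx - do.call(pmin, cols)
  gq[idx] <- 10 * (mx - second) / log(10)
  best[idx] <- max.col(agg, ties.method = "first") - 1L
  list(lik = lik, best = best, gq = gq, depth = depth)
}

#' Pseudo-haploid calling
#'
#' Draws one read uniformly at random per covered site (seeded per
#' individual) and reports its allele: 0 if it matches allele 1, 1 if allele
#' 2, missing otherwise or when the site has no reads.  This is the
#' haploidization step feeding mismatch-rate kinship estimation.
#'
#' @inheritParams call_genotype_likelihoods
#' @param seed global seed; the draw stream is keyed by `(seed, id)` so
#'   results do not depend on the order individuals are processed.
#' @param id individual identifier used for the RNG stream.
#' @return integer vector over sites: 0, 1 or NA.
#' @export
call_pseudohaploid <- function(pileup, panel, seed = 1L, id = "ind",
                               sites = seq_len(nrow(panel$sites))) {
  s <- length(sites)
  out <- rep(NA_integer_, s)
  if (nrow(pileup) == 0L) return(out)
  set.seed(seed_for(seed, paste0(id, "/ph")))
  # one uniform draw per read; keep the max per site
  u <- stats::runif(nrow(pileup))
  o <- order(pileup$site, u, decreasing = c(FALSE, TRUE), method = "radix")
  first <- o[!duplicated(pileup$site[o])]
  chosen_site <- pileup$site[first]
  chosen_base <- pileup$base[first]
  a1 <- panel$sites$a1[sites][chosen_site]
  a2 <- panel$sites$a2[sites][chosen_site]
  val <- ifelse(chosen_base == a1, 0L, ifelse(chosen_base == a2, 1L, NA_integer_))
  out[chosen_site] <- val
  out
}

#' Genetic-sex assignment from sex-chromosome read ratios
#'
#' Computes `Ry = nY / (nX + nY)` with an exact binomial 95% confidence
#' interval and assigns XY when the interval lies entirely above the male
#' threshold, XX when entirely below the female threshold, and unknown
#' otherwise (or when no sex-chromosome reads are present).
#'
#' @param reads_x,reads_y read counts mapping to X and Y.
#' @param reads_autosomal optional autosomal read count (reported only).
#' @param female_max,male_min thresholds on Ry (defaults 0.016 and 0.075,
#'   the conventional shotgun-ratio cutpoints).
#' @return list with `sex` ("XX", "XY" or "unknown"), `ry`, `ci` and counts.
#' @export
assign_genetic_sex <- function(reads_x, reads_y, reads_autosomal = NA_integer_,
                               female_max = 0.016, male_min = 0.075) {
  stopifnot(reads_x >= 0, reads_y >= 0)
  n <- reads_x + reads_y
  if (n == 0) {
    return(list(sex = "unknown", ry = NA_real_, ci = c(NA_real_, NA_real_),
                reads_x = reads_x, reads_y = reads_y,
                reads_autosomal = reads_autosomal))
  }
  bt <- stats::binom.test(reads_y, n)
  ci <- as.numeric(bt$conf.int)
  sex <- if (ci[2] < female_max) "XX" else if (ci[1] > male_min) "XY" else "unknown"
  list(sex = sex, ry = reads_y / n, ci = ci,
       reads_x = reads_x, reads_y = reads_y, reads_autosomal = reads_autosomal)
}

#' Authenticity quality-control gate
#'
#' Fails an individual when the contamination estimate exceeds
#' `max_contamination` or the terminal damage frequency falls below
#' `min_damage` (the classic aDNA authenticity screen).  Missing fields are
#' reported but never fail the gate.
#'
#' @param record list or one-row data.frame with optional fields
#'   `contamination` and `damage` (terminal damage frequency).
#' @param max_contamination contamination threshold (default 0.2).
#' @param min_damage minimum terminal damage frequency (default 0.25).
#' @return list with `pass` (logical), `reasons` (character, failing checks)
#'   and `missing` (character, fields absent).
#' @export
qc_gate <- function(record, max_contamination = 0.2, min_damage = 0.25) {
  reasons <- character(0)
  missing_fields <- character(0)
  cont <- record[["contamination"]]
  dam <- record[["damage"]]
  if (is.null(cont) || is.na(cont)) {
    missing_fields <- c(missing_fields, "contamination")
  } else if (cont > max_contamination) {
    reasons <- c(reasons, "contamination")
  }
  if (is.null(dam) || is.na(dam)) {
    missing_fields <- c(missing_fields, "damage")
  } else if (dam < min_damage) {
    reasons <- c(reasons, "damage")
  }
  list(pass = length(reasons) == 0L, reasons = reasons, missing = missing_fields)
}
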