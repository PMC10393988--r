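#' Genomic block schemes for jackknife resampling
#'
#' Assigns every panel site to a contiguous genomic block (default 5 Mb
#' span per chromosome).  Blocks are the resampling unit of all f-statistic
#' standard errors, making them robust to linkage.
#'
#' @param panel a `snp_panel`.
#' @param block_bp block span in bp (default 5e6).
#' @return integer vector of block indices (1..n_blocks), one per site.
#' @export
block_scheme <- function(panel, block_bp = 5e6) {
  key <- paste0(panel$sites$chrom, ":", panel$sites$pos %/% block_bp)
  as.integer(factor(key, levels = unique(key)))
}

#' Weighted delete-one-block jackknife for ratio statistics
#'
#' Computes `theta = sum(num) / sum(den)` and its standard error by the
#' weighted (Busing-style) delete-one-block jackknife with block weights
#' proportional to their site counts.  Mean-type statistics are the special
#' case `den = 1` per site.
#'
#' @param num per-site numerator terms (NAs dropped pairwise).
#' @param blocks integer block index per site.
#' @param den per-site denominator terms (default 1).
#' @return list with `est`, `se`, `z`, `n_snps`, `n_blocks`.
#' @export
block_jackknife <- function(num, blocks, den = NULL) {
  if (is.null(den)) den <- rep(1, length(num))
  ok <- !is.na(num) & !is.na(den)
  num <- num[ok]; den <- den[ok]; blocks <- blocks[ok]
  n_snps <- length(num)
  if (n_snps == 0L) stop("block_jackknife: no usable sites")
  tot_num <- sum(num); tot_den <- sum(den)
  if (tot_den == 0) stop("block_jackknife: zero denominator")
  est <- tot_num / tot_den
  bn <- rowsum(num, blocks); bd <- rowsum(den, blocks)
  m <- as.numeric(rowsum(rep(1, n_snps), blocks))
  B <- length(m)
  if (B < 2L) {
    return(list(est = est, se = NA_real_, z = NA_real_,
                n_snps = n_snps, n_blocks = B))
  }
  loo <- (tot_num - bn) / (tot_den - bd)
  n <- sum(m)
  h <- n / m
  theta_j <- B * est - sum((1 - m / n) * loo)
  tau <- h * est - (h - 1) * loo
  var <- sum((tau - theta_j)^2 / (h - 1)) / B
  se <- sqrt(var)
  list(est = est, se = se, z = est / se, n_snps = n_snps, n_blocks = B)
}

fstat_result <- function(kind, pops, jk) {
  data.frame(kind = kind, pops = paste(pops, collapse = ","),
             est = jk$est, se = jk$se, z = jk$z,
             n_snps = jk$n_snps, n_blocks = jk$n_blocks,
             stringsAsFactors = FALSE)
}

get_cols <- function(fmat, pops) {
  missing_p <- setdiff(pops, colnames(fmat))
  if (length(missing_p)) {
    stop("population(s) not in frequency matrix: ",
         paste(missing_p, collapse = ", "))
  }
  fmat[, pops, drop = FALSE]
}

#' f3 statistic with block-jackknife standard error
#'
#' `f3(O; A, B) = mean over sites of (pO - pA)(pO - pB)`, the shared-drift
#' statistic: large positive values mean A and B share drift relative to the
#' apex O (outgroup-f3 when O is an outgroup).  Sites missing in any of the
#' three columns are dropped (per-statistic overlap).
#'
#' @param fmat numeric matrix sites x populations/individuals of allele-2
#'   frequencies (individual columns may hold pseudo-haploid 0/1 codes).
#' @param o,a,b column names: apex, and the two test populations.
#' @param blocks integer block index per site (see [block_scheme()]).
#' @return one-row data.frame (kind, pops, est, se, z, n_snps, n_blocks).
#' @export
fstat_f3 <- function(fmat, o, a, b, blocks) {
  f <- get_cols(fmat, c(o, a, b))
  t <- (f[, 1] - f[, 2]) * (f[, 1] - f[, 3])
  if (all(is.na(t))) stop("fstat_f3: no overlapping sites for (",
                          paste(c(o, a, b), collapse = ", "), ")")
  fstat_result("f3", c(o, a, b), block_jackknife(t, blocks))
}

#' f4 statistic with block-jackknife standard error
#'
#' `f4(A, B; C, D) = mean over sites of (pA - pB)(pC - pD)`.
#'
#' @inheritParams fstat_f3
#' @param a,b,c,d column names for the two population pairs.
#' @return one-row data.frame as in [fstat_f3()].
#' @export
fstat_f4 <- function(fmat, a, b, c, d, blocks) {
  f <- get_cols(fmat, c(a, b, c, d))
  t <- (f[, 1] - f[, 2]) * (f[, 3] - f[, 4])
  if (all(is.na(t))) stop("fstat_f4: no overlapping sites")
  fstat_result("f4", c(a, b, c, d), block_jackknife(t, blocks))
}

#' D statistic (normalized ABBA-BABA) with block-jackknife Z
#'
#' `D(W, X; Y, Z) = sum (pW - pX)(pY - pZ) / sum (pW + pX - 2 pW pX)(pY + pZ
#' - 2 pY pZ)`; nonzero D indicates asymmetric affinity (gene flow) breaking
#' the tree ((W,X),(Y,Z)).
#'
#' @inheritParams fstat_f3
#' @param w,x,y,z column names.
#' @return one-row data.frame as in [fstat_f3()].
#' @export
fstat_d <- function(fmat, w, x, y, z, blocks) {
  f <- get_cols(fmat, c(w, x, y, z))
  num <- (f[, 1] - f[, 2]) * (f[, 3] - f[, 4])
  den <- (f[, 1] + f[, 2] - 2 * f[, 1] * f[, 2]) *
    (f[, 3] + f[, 4] - 2 * f[, 3] * f[, 4])
  ok <- !is.na(num) & !is.na(den)
  if (!any(ok)) stop("fstat_d: no overlapping sites")
  if (sum(den[ok]) == 0) {
    stop("fstat_d: zero denominator (no polymorphism in the W/X or Y/Z pair)")
  }
  fstat_result("D", c(w, x, y, z), block_jackknife(num, blocks, den))
}

#' Population allele frequencies from a genotype store
#'
#' Plain allele-count means per population: pseudo-haploid codes contribute
#' one allele each, diploid doses two.  No heterozygosity correction is
#' applied (appropriate for pseudo-haploid data; see the methods vignette).
#'
#' @param store a `geno_store`.
#' @param groups named list: population name -> individual ids.
#' @param use "haploid" or "diploid" component.
#' @return matrix sites x populations of allele-2 frequencies (NA where no
#'   individual has data).
#' @export
pop_freqs <- function(store, groups, use = c("haploid", "diploid")) {
  use <- match.arg(use)
  g <- store[[use]]
  if (is.null(g)) stop("pop_freqs: store lacks a ", use, " component")
  denom_per <- if (use == "haploid") 1 else 2
  out <- sapply(groups, function(ids) {
    m <- g[, match(ids, store$ind$id), drop = FALSE]
    cnt <- rowSums(!is.na(m)) * denom_per
    tot <- rowSums(m, na.rm = TRUE)
    ifelse(cnt > 0, tot / cnt, NA_real_)
  })
  colnames(out) <- names(groups)
  out
}

#' Cohort filters for population-level f statistics
#'
#' Applies the standard cohort hygiene before population-level statistics:
#' drops variants whose allele 2 is observed in exactly one ancient
#' individual (singletons), drops individuals genotyped at fewer than
#' `min_genotyped` of the remaining sites, and keeps only the
#' highest-coverage member of each kin group.
#'
#' @param geno matrix sites x individuals of genotype codes (pseudo-haploid
#'   0/1 or diploid doses; NA missing).
#' @param coverage named numeric vector of genome coverage per individual.
#' @param kin_groups list of character vectors, each a group of individuals
#'   sharing direct genetic kinship.
#' @param min_genotyped minimum genotyped fraction (default 0.85).
#' @return list with `geno` (filtered matrix), `individuals`, `sites`
#'   (logical keep mask over input rows) and `dropped` (named list of
#'   removals with reasons).
#' @export
filter_cohort <- function(geno, coverage = NULL, kin_groups = list(),
                          min_genotyped = 0.85) {
  dropped <- list()
  kin_drop <- character(0)
  for (grp in kin_groups) {
    grp <- intersect(grp, colnames(geno))
    if (length(grp) < 2L) next
    cov <- coverage[grp]
    keep_one <- grp[which.max(cov)]
    kin_drop <- c(kin_drop, setdiff(grp, keep_one))
  }
  dropped$kin <- kin_drop
  keep_ind <- setdiff(colnames(geno), kin_drop)
  g <- geno[, keep_ind, drop = FALSE]
  carriers <- rowSums(g > 0, na.rm = TRUE)
  keep_sites <- carriers != 1L
  dropped$singleton_sites <- sum(!keep_sites)
  g <- g[keep_sites, , drop = FALSE]
  frac <- colMeans(!is.na(g))
  low <- colnames(g)[frac < min_genotyped]
  dropped$low_genotyping <- low
  g <- g[, setdiff(colnames(g), low), drop = FALSE]
  if (ncol(g) == 0L) stop("filter_cohort: all individuals filtered out")
  list(geno = g, individuals = colnames(g), sites = keep_sites,
       dropped = dropped)
}

#' Within-group diversity as 1 - f3 over non-relative pairs
#'
#' For every pair of group members not related at degree two or closer,
#' computes the pairwise outgroup f3 and reports `1 - f3` (larger = more
#' diverse).  Duplicate or related dyads are excluded via the kinship table.
#'
#' @param fmat frequency matrix with one column per individual plus the
#'   outgroup.
#' @param members individual column names forming the group.
#' @param outgroup outgroup column name.
#' @param blocks block index per site.
#' @param kin optional data.frame with `id1`, `id2`, `degree_final`; dyads
#'   with degree identical/first/second are excluded.
#' @param labels optional named vector of site labels per individual for a
#'   by-site split.
#' @return list with `pairs` (data.frame id1, id2, f3, one_minus_f3) and
#'   `summary` (median and IQR of 1 - f3, overall and per label).
#' @export
within_group_diversity <- function(fmat, members, outgroup, blocks,
                                   kin = NULL, labels = NULL) {
  if (length(members) < 2L) stop("within_group_diversity: need >= 2 individuals")
  excluded <- character(0)
  if (!is.null(kin)) {
    rel <- kin$degree_final %in% c("identical", "first", "second")
    excluded <- paste(pmin(kin$id1[rel], kin$id2[rel]),
                      pmax(kin$id1[rel], kin$id2[rel]))
  }
  cmb <- utils::combn(members, 2L)
  rows <- list()
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    if (paste(min(i, j), max(i, j)) %in% excluded) next
    r <- fstat_f3(fmat, outgroup, i, j, blocks)
    rows[[length(rows) + 1L]] <- data.frame(id1 = i, id2 = j, f3 = r$est,
                                            se = r$se,
                                            one_minus_f3 = 1 - r$est,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("within_group_diversity: < 2 eligible individuals")
  pairs <- do.call(rbind, rows)
  summarize <- function(v) c(median = stats::median(v),
                             q25 = unname(stats::quantile(v, 0.25)),
                             q75 = unname(stats::quantile(v, 0.75)))
  summary <- list(overall = summarize(pairs$one_minus_f3))
  if (!is.null(labels)) {
    key <- paste(labels[pairs$id1], labels[pairs$id2], sep = "|")
    same <- labels[pairs$id1] == labels[pairs$id2]
    for (lab in unique(labels[pairs$id1][same])) {
      sel <- same & labels[pairs$id1] == lab
      if (any(sel)) summary[[lab]] <- summarize(pairs$one_minus_f3[sel])
    }
  }
  list(pairs = pairs, summary = summary)
}

#' Autosome versus X-chromosome f3 contrast
#'
#' For each partner population, computes outgroup f3 of the target on the
#' autosomal and X panels, fits a least-squares line of the autosomal values
#' on the X values across partners, and reports each partner's standardized
#' residual.  Sex-biased admixture from a partner-like source shows up as a
#' positive residual (autosomal affinity elevated relative to X for
#' male-driven gene flow).
#'
#' @param fmat_auto,fmat_x frequency matrices for the autosomal and X
#'   panels.
#' @param target target population/individual column.
#' @param partners partner population columns.
#' @param outgroup outgroup column.
#' @param blocks_auto,blocks_x block indices for each panel.
#' @return data.frame per partner: f3_auto, se_auto, f3_x, se_x, residual
#'   (standardized).  Partners missing X data are skipped with a message.
#' @export
x_autosome_contrast <- function(fmat_auto, fmat_x, target, partners,
                                outgroup, blocks_auto, blocks_x) {
  rows <- list()
  for (p in partners) {
    fx_ok <- p %in% colnames(fmat_x) && any(!is.na(fmat_x[, p]))
    if (!fx_ok) {
      message("x_autosome_contrast: no X data for ", p, "; skipped")
      next
    }
    ra <- fstat_f3(fmat_auto, outgroup, target, p, blocks_auto)
    rx <- fstat_f3(fmat_x, outgroup, target, p, blocks_x)
    rows[[p]] <- data.frame(partner = p, f3_auto = ra$est, se_auto = ra$se,
                            f3_x = rx$est, se_x = rx$se,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 3L) {
    stop("x_autosome_contrast: need >= 3 partners with X data to fit a trend")
  }
  fit <- stats::lm(f3_auto ~ f3_x, data = out)
  res <- stats::residuals(fit)
  out$residual <- res / stats::sd(res)
  rownames(out) <- NULL
  out
}

#' Per-individual site-affinity D test (patrilocality screen)
#'
#' For every individual of a site, computes `D(outgroup, individual; site
#' population, culture cohort)` where the site population excludes the
#' focal individual and (by default) its first/second-degree relatives, and
#' summarizes the D distributions by sex with a rank-based two-sided
#' comparison.  Positive D means the individual is closer to its own site
#' than to the wider cohort; under patrilocality resident males show a
#' male-shifted distribution.
#'
#' @param fmat frequency matrix with one column per individual plus the
#'   outgroup.
#' @param site_ids individual columns belonging to the site.
#' @param cohort_ids individual columns of the wider culture cohort (focal
#'   and site individuals are removed automatically).
#' @param outgroup outgroup column.
#' @param blocks block index per site.
#' @param sexes named "M"/"F" vector.
#' @param kin optional kinship table (`id1`, `id2`, `degree_final`) used to
#'   exclude the focal individual's close relatives from the site term.
#' @param exclude_relatives drop degree <= 2 relatives of the focal from the
#'   site population (default TRUE).
#' @return list with `per_individual` (id, sex, d, z), `by_sex` medians and
#'   `rank_test` (wilcoxon p, NA when a sex class is empty).
#' @export
patrilocality_dtest <- function(fmat, site_ids, cohort_ids, outgroup, blocks,
                                sexes, kin = NULL, exclude_relatives = TRUE) {
  rows <- list()
  for (focal in site_ids) {
    others <- setdiff(site_ids, focal)
    if (exclude_relatives && !is.null(kin)) {
      rel <- kin$degree_final %in% c("identical", "first", "second") &
        (kin$id1 == focal | kin$id2 == focal)
      rel_ids <- unique(c(kin$id1[rel], kin$id2[rel]))
      others <- setdiff(others, rel_ids)
    }
    if (!length(others)) next
    if (focal %in% others) stop("patrilocality_dtest: focal in site population")
    coh <- setdiff(cohort_ids, c(focal, site_ids))
    site_f <- rowMeans(fmat[, others, drop = FALSE], na.rm = TRUE)
    coh_f <- rowMeans(fmat[, coh, drop = FALSE], na.rm = TRUE)
    fm <- cbind(fmat[, c(outgroup, focal)], site = site_f, cohort = coh_f)
    colnames(fm) <- c(outgroup, focal, ".site", ".cohort")
    r <- fstat_d(fm, outgroup, focal, ".cohort", ".site", blocks)
    # sign: positive = closer to own site than cohort
    rows[[focal]] <- data.frame(id = focal, sex = unname(sexes[focal]),
                                d = r$est, z = r$z, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  by_sex <- tapply(per$d, per$sex, stats::median)
  p <- NA_real_
  if (all(c("M", "F") %in% per$sex)) {
    p <- stats::wilcox.test(per$d[per$sex == "M"], per$d[per$sex == "F"],
                            exact = FALSE)$p.value
  }
  list(per_individual = per, by_sex = by_sex, rank_test_p = p)
}
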