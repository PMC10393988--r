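#' SNP panel objects
#'
#' A `snp_panel` is the site map shared by all stages of the pipeline: one row
#' per biallelic site with chromosome label, chromosome class (autosome, X or
#' Y), 1-based position, the two alleles, and the derived mutation class
#' (transition or transversion).  Per-population frequencies of `a2` may be
#' attached as a sites-by-populations matrix.
#'
#' @param sites data.frame with columns `id`, `chrom`, `class`, `pos`, `a1`,
#'   `a2`.  Positions must be strictly increasing within each chromosome.
#' @param freq optional numeric matrix (rows = sites, columns = populations)
#'   of allele-2 frequencies in `[0, 1]`.
#' @return An object of class `snp_panel`: a list with elements `sites`
#'   (data.frame, with a derived `mut` column) and `freq` (matrix or NULL).
#' @export
snp_panel <- function(sites, freq = NULL) {
  required <- c("id", "chrom", "class", "pos", "a1", "a2")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0L) {
    stop("snp_panel: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (anyDuplicated(sites$id)) {
    stop("snp_panel: duplicate site ids (first: ",
         sites$id[anyDuplicated(sites$id)], ")")
  }
  if (!all(sites$class %in% c("autosome", "X", "Y"))) {
    stop("snp_panel: chromosome class must be autosome, X or Y")
  }
  bases <- c("A", "C", "G", "T")
  if (!all(sites$a1 %in% bases) || !all(sites$a2 %in% bases)) {
    stop("snp_panel: alleles must be A/C/G/T")
  }
  if (any(sites$a1 == sites$a2)) {
    stop("snp_panel: alleles must differ (site ",
         sites$id[which(sites$a1 == sites$a2)[1]], ")")
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) {
      bad <- which(sites$chrom == ch)[which(diff(p) <= 0)[1] + 1L]
      stop("snp_panel: positions not strictly increasing on ", ch,
           " at line ", bad, " (site ", sites$id[bad], ")")
    }
  }
  sites$mut <- mutation_class(sites$a1, sites$a2)
  if (!is.null(freq)) {
    freq <- as.matrix(freq)
    if (nrow(freq) != nrow(sites)) {
      stop("snp_panel: freq has ", nrow(freq), " rows for ", nrow(sites), " sites")
    }
    if (any(freq < 0 | freq > 1, na.rm = TRUE)) stop("snp_panel: frequencies outside [0,1]")
    rownames(freq) <- sites$id
  }
  structure(list(sites = sites, freq = freq), class = "snp_panel")
}

#' Classify allele pairs as transitions or transversions
#'
#' @param a1,a2 character vectors of alleles.
#' @return character vector, "transition" or "transversion".
#' @export
mutation_class <- function(a1, a2) {
  purine <- c("A", "G")
  ifelse((a1 %in% purine) == (a2 %in% purine), "transition", "transversion")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel:", nrow(x$sites), "sites (",
      sum(x$sites$class == "autosome"), "autosomal,",
      sum(x$sites$class == "X"), "X,",
      sum(x$sites$class == "Y"), "Y )\n")
  if (!is.null(x$freq)) {
    cat("  population frequencies:", paste(colnames(x$freq), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of sites in a panel
#' @param panel a `snp_panel`.
#' @return integer count.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Subset a panel by site index
#'
#' @param panel a `snp_panel`.
#' @param idx integer or logical index over sites.
#' @return A `snp_panel` restricted to the selected sites.
#' @export
panel_subset <- function(panel, idx) {
  sites <- panel$sites[idx, , drop = FALSE]
  freq <- if (is.null(panel$freq)) NULL else panel$freq[idx, , drop = FALSE]
  out <- list(sites = sites, freq = freq)
  class(out) <- "snp_panel"
  out
}

#' Generate synthetic panel site maps
#'
#' Lays out `n` sites uniformly at random over a set of synthetic chromosomes
#' and assigns random biallelic allele pairs.  Used by the simulator to give
#' sites realistic coordinates so that distance thinning and genomic-block
#' jackknifing operate as they would on real data.
#'
#' @param n number of sites.
#' @param n_chrom number of chromosomes (ignored when `class != "autosome"`,
#'   where a single chromosome is used).
#' @param chrom_length chromosome length in bp.
#' @param class chromosome class for all sites.
#' @param transversions_only if TRUE, only transversion allele pairs are drawn
#'   (emulating a transversions-only capture panel).
#' @param prefix prefix for chromosome and site names.
#' @return data.frame suitable as the `sites` argument of [snp_panel()].
#' @export
synth_panel_sites <- function(n, n_chrom = 22L, chrom_length = 1.3e8,
                              class = "autosome", transversions_only = FALSE,
                              prefix = NULL) {
  if (class != "autosome") n_chrom <- 1L
  if (is.null(prefix)) {
    prefix <- switch(class, autosome = "chr", X = "chrX", Y = "chrY")
  }
  chrom <- sort(sample.int(n_chrom, n, replace = TRUE))
  pos <- integer(n)
  for (c_i in unique(chrom)) {
    k <- sum(chrom == c_i)
    pos[chrom == c_i] <- sort(sample.int(as.integer(chrom_length), k))
  }
  chrom_lab <- if (class == "autosome") paste0(prefix, chrom) else rep(prefix, n)
  pairs <- list(c("A", "C"), c("A", "T"), c("C", "G"), c("G", "T"),  # transversions
                c("A", "G"), c("C", "T"))                            # transitions
  if (transversions_only) pairs <- pairs[1:4]
  pick <- sample.int(length(pairs), n, replace = TRUE)
  a1 <- vapply(pairs, `[`, "", 1L)[pick]
  a2 <- vapply(pairs, `[`, "", 2L)[pick]
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  data.frame(id = paste0(class, "_", seq_len(n)), chrom = chrom_lab,
             class = class, pos = pos, a1 = a1, a2 = a2,
             stringsAsFactors = FALSE)
}

#' Filter a panel to transversions with a minimum outgroup MAF
#'
#' Mirrors the construction of transversions-only reference panels ascertained
#' on minor-allele frequency in an outgroup population (the classic design
#' that removes deamination-driven transition artefacts): keeps transversion
#' sites whose minor-allele frequency in `outgroup` is at least `min_maf`.
#'
#' @param panel a `snp_panel` carrying frequencies for `outgroup`.
#' @param outgroup population (frequency column) used for ascertainment.
#' @param min_maf minimum minor-allele frequency (default 0.1).
#' @return the filtered `snp_panel`.
#' @export
transversion_panel <- function(panel, outgroup, min_maf = 0.1) {
  if (is.null(panel$freq) || !(outgroup %in% colnames(panel$freq))) {
    stop("transversion_panel: no frequencies for population '", outgroup, "'")
  }
  f <- panel$freq[, outgroup]
  maf <- pmin(f, 1 - f)
  keep <- panel$sites$mut == "transversion" & !is.na(maf) & maf >= min_maf
  panel_subset(panel, keep)
}

#' Thin a panel by physical distance
#'
#' Greedy left-to-right scan per chromosome: a site is kept only if it lies at
#' least `min_gap` bp from the previously kept site.  Deterministic; the first
#' site of every chromosome is always kept.  This is the LD-pruning step
#' applied to each merged pair of individuals before likelihood-based
#' relatedness estimation.
#'
#' @param panel a `snp_panel`.
#' @param min_gap minimum gap in bp (>= 0).
#' @return the thinned `snp_panel`.
#' @export
thin_by_distance <- function(panel, min_gap) {
  if (min_gap < 0) stop("thin_by_distance: min_gap must be >= 0")
  if (min_gap == 0) return(panel)
  keep <- logical(nrow(panel$sites))
  for (ch in unique(panel$sites$chrom)) {
    idx <- which(panel$sites$chrom == ch)
    pos <- panel$sites$pos[idx]
    last <- -Inf
    for (i in seq_along(idx)) {
      if (pos[i] - last >= min_gap) {
        keep[idx[i]] <- TRUE
        last <- pos[i]
      }
    }
  }
  panel_subset(panel, keep)
}
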