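#' Sequencing specifications
#'
#' Parameters of the read simulator emulating damaged, contaminated,
#' low-coverage ancient-DNA data: Poisson site depth, per-base sequencing
#' error, terminal deamination (through a [damage_profile()]), and a
#' contamination fraction drawing reads from another population's allele
#' frequencies.
#'
#' @param mean_depth expected reads per site (Poisson lambda, > 0 allowed to
#'   be arbitrarily small).
#' @param base_error probability that a read base is miscalled (substituted
#'   by one of the other three bases uniformly).
#' @param damage a [damage_profile()] (C-to-T by 5' distance, G-to-A by 3'
#'   distance); defaults to no damage.
#' @param contamination fraction of reads drawn from the contaminant
#'   population instead of the individual, in `[0, 1]`.
#' @param contaminant_population frequency column used for contaminant reads.
#' @param max_dist largest distance-to-read-end simulated; each read's
#'   distance to its nearer end is uniform on `1:max_dist`.
#' @param seed integer RNG seed (per-individual streams are derived from it).
#' @return An object of class `sequencing_spec`.
#' @export
sequencing_spec <- function(mean_depth, base_error = 0.001,
                            damage = damage_profile(),
                            contamination = 0, contaminant_population = NULL,
                            max_dist = 15L, seed = 1L) {
  stopifnot(mean_depth > 0, base_error >= 0, base_error <= 1,
            contamination >= 0, contamination <= 1)
  if (contamination > 0 && is.null(contaminant_population)) {
    stop("sequencing_spec: contamination > 0 needs a contaminant_population")
  }
  structure(list(mean_depth = mean_depth, base_error = base_error,
                 damage = damage, contamination = contamination,
                 contaminant_population = contaminant_population,
                 max_dist = as.integer(max_dist), seed = as.integer(seed)),
            class = "sequencing_spec")
}

base_qual_from_error <- function(e) {
  if (e <= 0) return(93L)
  as.integer(min(93L, round(-10 * log10(e))))
}

OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Simulate read pileups for a set of individuals
#'
#' For every individual and site, draws `Poisson(mean_depth)` reads.  Each
#' read samples one of the individual's true alleles (or, with probability
#' `contamination`, an allele from the contaminant population's frequency),
#' is deaminated (C-to-T with the 5' profile probability at its distance,
#' G-to-A with the 3' profile), and finally miscalled with the base-error
#' probability.  The distance to the nearer read end is stored so the caller
#' can apply position-dependent damage rates.
#'
#' @param drop a [gene_drop()] providing true haplotypes (or a list with the
#'   same structure).
#' @param spec a [sequencing_spec()].
#' @param class chromosome class to sequence ("autosome", "X" or "Y").
#' @param individuals ids to sequence (default all in the drop).
#' @return An object of class `pileup_set`: a named list of per-individual
#'   data.frames with columns `site` (index into the class's site subset),
#'   `base`, `qual`, `dist`, plus the panel and class as attributes.
#' @export
simulate_reads <- function(drop, spec, class = "autosome",
                           individuals = colnames(drop$auto$h1)) {
  stopifnot(inherits(spec, "sequencing_spec"))
  comp <- switch(class, autosome = drop$auto, X = drop$x, Y = drop$y,
                 stop("simulate_reads: unknown class ", class))
  sites <- comp$sites
  s <- length(sites)
  a1 <- drop$panel$sites$a1[sites]
  a2 <- drop$panel$sites$a2[sites]
  fc <- NULL
  if (spec$contamination > 0) {
    if (!(spec$contaminant_population %in% colnames(drop$panel$freq))) {
      stop("simulate_reads: contaminant population not in frequency table")
    }
    fc <- drop$panel$freq[sites, spec$contaminant_population]
  }
  qual <- base_qual_from_error(spec$base_error)
  out <- vector("list", length(individuals))
  names(out) <- individuals
  empty <- data.frame(site = integer(0), base = character(0),
                      qual = integer(0), dist = integer(0),
                      stringsAsFactors = FALSE)
  if (s == 0L) {
    for (id in individuals) out[[id]] <- empty
    return(structure(out, class = "pileup_set", panel = drop$panel,
                     sites = sites, chrom_class = class))
  }
  for (id in individuals) {
    set.seed(seed_for(spec$seed, paste0(id, "/", class)))
    depth <- stats::rpois(s, spec$mean_depth)
    site_idx <- rep.int(seq_len(s), depth)
    nr <- length(site_idx)
    if (nr == 0L) {
      out[[id]] <- data.frame(site = integer(0), base = character(0),
                              qual = integer(0), dist = integer(0),
                              stringsAsFactors = FALSE)
      next
    }
    h1 <- comp$h1[, id]
    haploid <- class == "Y" ||
      (class == "X" && is.na(comp$h2[1L, id]))
    if (haploid) {
      allele <- h1[site_idx]
    } else {
      pick <- stats::runif(nr) < 0.5
      allele <- comp$h2[, id][site_idx]
      allele[pick] <- h1[site_idx][pick]
    }
    if (!is.null(fc) && spec$contamination > 0) {
      is_cont <- stats::runif(nr) < spec$contamination
      if (any(is_cont)) {
        allele[is_cont] <- stats::rbinom(sum(is_cont), 1L, fc[site_idx[is_cont]])
      }
    }
    base <- a1[site_idx]
    alt <- allele == 1L
    base[alt] <- a2[site_idx][alt]
    dist <- sample.int(spec$max_dist, nr, replace = TRUE)
    # post-mortem deamination, position-dependent
    d_ct <- damage_rate(spec$damage, "CT", dist)
    d_ga <- damage_rate(spec$damage, "GA", dist)
    u <- stats::runif(nr)
    base[base == "C" & u < d_ct] <- "T"
    base[base == "G" & u < d_ga] <- "A"
    # sequencing error to a uniform other base
    err <- stats::runif(nr) < spec$base_error
    if (any(err)) {
      k <- which(err)
      base[k] <- vapply(base[k], function(b) sample(OTHER_BASES[[b]], 1L), "")
    }
    out[[id]] <- data.frame(site = site_idx, base = base,
                            qual = rep.int(qual, nr), dist = dist,
                            stringsAsFactors = FALSE)
  }
  structure(out, class = "pileup_set", panel = drop$panel,
            sites = sites, chrom_class = class)
}
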