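# Small shared fixtures built in code.

toy_panel <- function(n = 100, seed = 42, pops = "POP") {
  set.seed(seed)
  panel <- snp_panel(synth_panel_sites(n))
  panel$freq <- matrix(stats::runif(n * length(pops), 0.05, 0.95),
                       ncol = length(pops), dimnames = list(NULL, pops))
  panel
}

# A tiny nuclear family: parents + son + daughter.
toy_family <- function() {
  pedigree_spec(data.frame(
    id = c("mo", "fa", "son", "dau"),
    sex = c("F", "M", "M", "F"),
    generation = c(1, 1, 2, 2),
    age_class = c("adult", "adult", "juvenile", "juvenile"),
    mother = c(NA, NA, "mo", "mo"),
    father = c(NA, NA, "fa", "fa"),
    stringsAsFactors = FALSE))
}

# Pileup data.frame from explicit reads.
mk_pileup <- function(site, base, qual = 40L, dist = 10L) {
  data.frame(site = site, base = base,
             qual = rep_len(qual, length(site)),
             dist = rep_len(dist, length(site)),
             stringsAsFactors = FALSE)
}

# One-site biallelic panel with chosen alleles.
one_site_panel <- function(a1, a2) {
  snp_panel(data.frame(id = "s1", chrom = "chr1", class = "autosome",
                       pos = 100L, a1 = a1, a2 = a2,
                       stringsAsFactors = FALSE))
}
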