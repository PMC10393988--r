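#' Pedigree specifications
#'
#' Truth object for the kinship and pedigree-reconstruction stages: a set of
#' individuals with sex, generation and age class, parent links (founders have
#' none), and uniparental lineage labels for founders (mitochondrial for all,
#' Y for males).
#'
#' @param members data.frame with columns `id`, `sex` ("M"/"F"),
#'   `generation` (integer, founders lowest), `age_class` ("adult",
#'   "juvenile" or "unknown"); optional `mother`, `father` (NA for founders);
#'   optional `mito`, `y` founder lineage labels (non-founders inherit).
#' @return An object of class `pedigree_spec`, members ordered so that
#'   parents precede children.
#' @export
pedigree_spec <- function(members) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sex", "generation", "age_class") %in% names(members)))
  if (anyDuplicated(members$id)) stop("pedigree_spec: duplicate ids")
  if (!all(members$sex %in% c("M", "F"))) stop("pedigree_spec: sex must be M or F")
  if (is.null(members$mother)) members$mother <- NA_character_
  if (is.null(members$father)) members$father <- NA_character_
  founder <- is.na(members$mother) & is.na(members$father)
  half <- xor(is.na(members$mother), is.na(members$father))
  if (any(half)) {
    stop("pedigree_spec: individual ", members$id[half][1],
         " has exactly one parent recorded; non-founders need both")
  }
  for (col in c("mother", "father")) {
    ref <- members[[col]][!is.na(members[[col]])]
    missing_ref <- setdiff(ref, members$id)
    if (length(missing_ref)) {
      stop("pedigree_spec: missing parent record for ", missing_ref[1])
    }
  }
  sex_of <- stats::setNames(members$sex, members$id)
  if (any(sex_of[stats::na.omit(members$mother)] != "F")) {
    stop("pedigree_spec: a recorded mother is not female")
  }
  if (any(sex_of[stats::na.omit(members$father)] != "M")) {
    stop("pedigree_spec: a recorded father is not male")
  }
  # Topological order over parent links; failure = someone is their own ancestor.
  ord <- character(0)
  placed <- character(0)
  pending <- members$id
  repeat {
    ready <- pending[vapply(pending, function(i) {
      r <- members[members$id == i, ]
      (is.na(r$mother) || r$mother %in% placed) &&
        (is.na(r$father) || r$father %in% placed)
    }, TRUE)]
    if (!length(ready)) break
    ord <- c(ord, ready); placed <- c(placed, ready)
    pending <- setdiff(pending, ready)
  }
  if (length(pending)) {
    stop("pedigree_spec: ancestry cycle involving ", paste(pending, collapse = ", "))
  }
  members <- members[match(ord, members$id), ]
  rownames(members) <- NULL
  if (is.null(members$mito)) members$mito <- NA_character_
  if (is.null(members$y)) members$y <- NA_character_
  needs_mito <- founder_of(members) & is.na(members$mito)
  members$mito[needs_mito] <- paste0("mt_", members$id[needs_mito])
  needs_y <- founder_of(members) & members$sex == "M" & is.na(members$y)
  members$y[needs_y] <- paste0("Y_", members$id[needs_y])
  structure(list(members = members), class = "pedigree_spec")
}

founder_of <- function(members) is.na(members$mother) & is.na(members$father)

#' @export
print.pedigree_spec <- function(x, ...) {
  m <- x$members
  cat("pedigree_spec:", nrow(m), "members (", sum(founder_of(m)), "founders ),",
      length(unique(m$generation)), "generations\n")
  invisible(x)
}

# Deterministic small hash so per-individual RNG streams are reproducible and
# independent of processing order.
seed_for <- function(seed, id) {
  h <- 0
  for (k in utf8ToInt(id)) h <- (h * 131 + k) %% 1987654321
  as.integer((seed + h) %% 2147483629L + 1L)
}

#' Drop genes through a pedigree
#'
#' Draws founder genotypes in Hardy-Weinberg proportions from a named
#' population's allele frequencies, then transmits alleles Mendelianly:
#' autosomes receive one random allele from each parent per site (sites
#' independent; no linkage), the X is hemizygous in males and transmitted
#' mother-to-son / both-parents-to-daughter, Y-class sites and the Y lineage
#' label pass father to son, and the mitochondrial label passes mother to all
#' offspring.  Every founder allele carries a unique identity-by-descent tag
#' that is copied on transmission, so realized k-coefficients are available
#' as ground truth via [realized_k()].
#'
#' @param ped a [pedigree_spec()].
#' @param panel a `snp_panel` with a frequency column for `founder_pop`
#'   (autosomal, X and Y class sites all handled).
#' @param founder_pop population whose frequencies founders are drawn from.
#' @param seed integer RNG seed.
#' @return An object of class `gene_drop`: haplotype and IBD-tag matrices per
#'   chromosome class, inherited uniparental labels, and the input panel.
#' @export
gene_drop <- function(ped, panel, founder_pop, seed) {
  stopifnot(inherits(ped, "pedigree_spec"), inherits(panel, "snp_panel"))
  if (is.null(panel$freq) || !(founder_pop %in% colnames(panel$freq))) {
    stop("gene_drop: founder population '", founder_pop, "' not in frequency table")
  }
  m <- ped$members
  n <- nrow(m)
  ids <- m$id
  sex <- stats::setNames(m$sex, ids)
  auto <- which(panel$sites$class == "autosome")
  xs <- which(panel$sites$class == "X")
  ys <- which(panel$sites$class == "Y")
  fa <- panel$freq[auto, founder_pop]
  fx <- panel$freq[xs, founder_pop]
  fy <- panel$freq[ys, founder_pop]

  mk <- function(s) matrix(NA_integer_, nrow = s, ncol = n, dimnames = list(NULL, ids))
  A1 <- mk(length(auto)); A2 <- mk(length(auto))   # allele dose of a2: 0/1
  La1 <- mk(length(auto)); La2 <- mk(length(auto)) # founder-allele IBD tags
  X1 <- mk(length(xs)); X2 <- mk(length(xs))       # males: X2 stays NA
  Lx1 <- mk(length(xs)); Lx2 <- mk(length(xs))
  Yh <- mk(length(ys))
  mito <- stats::setNames(m$mito, ids)
  ylab <- stats::setNames(m$y, ids)

  tag <- 0L
  for (i in seq_len(n)) {
    id <- ids[i]
    set.seed(seed_for(seed, id))
    if (founder_of(m)[i]) {
      A1[, i] <- stats::rbinom(length(auto), 1L, fa)
      A2[, i] <- stats::rbinom(length(auto), 1L, fa)
      La1[, i] <- tag + 1L; La2[, i] <- tag + 2L
      X1[, i] <- stats::rbinom(length(xs), 1L, fx)
      Lx1[, i] <- tag + 3L
      if (sex[id] == "F") {
        X2[, i] <- stats::rbinom(length(xs), 1L, fx)
        Lx2[, i] <- tag + 4L
      }
      if (sex[id] == "M") Yh[, i] <- stats::rbinom(length(ys), 1L, fy)
      tag <- tag + 4L
    } else {
      mo <- which(ids == m$mother[i]); fth <- which(ids == m$father[i])
      pick_m <- stats::rbinom(length(auto), 1L, 0.5) == 1L
      A1[, i] <- ifelse(pick_m, A1[, mo], A2[, mo])
      La1[, i] <- ifelse(pick_m, La1[, mo], La2[, mo])
      pick_f <- stats::rbinom(length(auto), 1L, 0.5) == 1L
      A2[, i] <- ifelse(pick_f, A1[, fth], A2[, fth])
      La2[, i] <- ifelse(pick_f, La1[, fth], La2[, fth])
      # X: maternal X always; paternal X only for daughters
      pick_x <- stats::rbinom(length(xs), 1L, 0.5) == 1L
      mat_x <- ifelse(pick_x & !is.na(X2[, mo]), X2[, mo], X1[, mo])
      mat_lx <- ifelse(pick_x & !is.na(X2[, mo]), Lx2[, mo], Lx1[, mo])
      X1[, i] <- mat_x; Lx1[, i] <- mat_lx
      if (sex[id] == "F") {
        X2[, i] <- X1[, fth]; Lx2[, i] <- Lx1[, fth]
      } else {
        Yh[, i] <- Yh[, fth]
        ylab[id] <- ylab[ids[fth]]
      }
      mito[id] <- mito[ids[mo]]
    }
  }
  labels <- data.frame(id = ids, sex = m$sex, generation = m$generation,
                       age_class = m$age_class, mito = unname(mito),
                       y = unname(ylab), stringsAsFactors = FALSE)
  structure(list(panel = panel, members = m, labels = labels,
                 auto = list(h1 = A1, h2 = A2, l1 = La1, l2 = La2, sites = auto),
                 x = list(h1 = X1, h2 = X2, l1 = Lx1, l2 = Lx2, sites = xs),
                 y = list(h1 = Yh, sites = ys),
                 founder_pop = founder_pop),
            class = "gene_drop")
}

#' @export
print.gene_drop <- function(x, ...) {
  cat("gene_drop:", ncol(x$auto$h1), "individuals;",
      nrow(x$auto$h1), "autosomal /", nrow(x$x$h1), "X /", nrow(x$y$h1),
      "Y sites; founders from", x$founder_pop, "\n")
  invisible(x)
}

#' True diploid genotype matrix from a gene drop
#'
#' @param drop a [gene_drop()].
#' @param class chromosome class; male X genotypes are reported on the
#'   hemizygous 0/1 scale.
#' @return integer matrix sites x individuals of allele-2 dose.
#' @export
true_genotypes <- function(drop, class = "autosome") {
  if (class == "autosome") return(drop$auto$h1 + drop$auto$h2)
  if (class == "X") {
    g <- drop$x$h1 + ifelse(is.na(drop$x$h2), 0L, drop$x$h2)
    # males carry a single allele: report 0/1
    return(g)
  }
  if (class == "Y") return(drop$y$h1)
  stop("true_genotypes: unknown class ", class)
}

#' Pedigree-expected kinship coefficients (autosomal and X)
#'
#' Computes the autosomal kinship coefficient phi and the X-chromosome
#' kinship coefficient (males haploid: sons take the maternal value,
#' daughters average both parents) for every pair, by the standard
#' recursive algorithm over the pedigree.  Founders are assumed mutually
#' unrelated and non-inbred.
#'
#' @param ped a [pedigree_spec()].
#' @return list with matrices `phi` and `phi_x` (individuals x
#'   individuals).
#' @export
kinship_coefficients <- function(ped) {
  m <- ped$members
  ids <- m$id
  n <- length(ids)
  ord <- stats::setNames(seq_len(n), ids)  # members are topologically sorted
  mo <- stats::setNames(m$mother, ids)
  fa <- stats::setNames(m$father, ids)
  sex <- stats::setNames(m$sex, ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  phix <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    id_i <- ids[i]
    # self terms
    if (is.na(mo[id_i])) {
      phi[i, i] <- 0.5
      phix[i, i] <- if (sex[id_i] == "M") 1 else 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[mo[id_i], fa[id_i]])
      phix[i, i] <- if (sex[id_i] == "M") 1 else
        0.5 * (1 + phix[mo[id_i], fa[id_i]])
    }
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      id_j <- ids[j]
      if (is.na(mo[id_i])) {
        # i is a founder appearing later; expand j if j is a non-founder,
        # else unrelated
        if (is.na(mo[id_j])) next
        phi[i, j] <- 0.5 * (phi[id_i, mo[id_j]] + phi[id_i, fa[id_j]])
        phix[i, j] <- if (sex[id_j] == "M") phix[id_i, mo[id_j]] else
          0.5 * (phix[id_i, mo[id_j]] + phix[id_i, fa[id_j]])
      } else {
        phi[i, j] <- 0.5 * (phi[mo[id_i], id_j] + phi[fa[id_i], id_j])
        phix[i, j] <- if (sex[id_i] == "M") phix[mo[id_i], id_j] else
          0.5 * (phix[mo[id_i], id_j] + phix[fa[id_i], id_j])
      }
      phi[j, i] <- phi[i, j]
      phix[j, i] <- phix[i, j]
    }
  }
  list(phi = phi, phi_x = phix)
}

#' Realized IBD-sharing coefficients for a pair
#'
#' Counts, per autosomal site, how many alleles the two individuals share
#' identical by descent according to the simulator's transmission record, and
#' returns the realized proportions of sites with 0, 1 and 2 shared alleles.
#' This is the genome-realized analogue of the pedigree-expected k vector and
#' serves as ground truth for the likelihood-based estimators.
#'
#' @param drop a [gene_drop()].
#' @param i,j individual ids.
#' @return named numeric vector `c(k0, k1, k2)`.
#' @export
realized_k <- function(drop, i, j) {
  a <- drop$auto
  m1 <- (a$l1[, i] == a$l1[, j]) + (a$l2[, i] == a$l2[, j])
  m2 <- (a$l1[, i] == a$l2[, j]) + (a$l2[, i] == a$l1[, j])
  shared <- pmax(m1, m2)
  c(k0 = mean(shared == 0), k1 = mean(shared == 1), k2 = mean(shared == 2))
}
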