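#' Genotype stores
#'
#' Container for individuals-by-sites genotype data: diploid calls (allele-2
#' dose 0/1/2, NA missing), pseudo-haploid calls (0/1, NA), normalized linear
#' genotype-likelihood triples, and phred-like genotype qualities.  All
#' components are optional except the panel and individual table; matrices
#' are sites x individuals.
#'
#' @param panel a `snp_panel`.
#' @param ind data.frame of individual metadata with at least an `id` column
#'   (sex, age class, group, culture, haplogroup and QC fields as available).
#' @param diploid,haploid integer matrices (sites x individuals) or NULL.
#' @param gl 3-d array sites x individuals x 3 of linear-scale genotype
#'   likelihoods normalizing to 1 (within 1e-6) at non-missing entries, or
#'   NULL.
#' @param gq numeric matrix of genotype qualities, or NULL.
#' @return An object of class `geno_store`.
#' @export
geno_store <- function(panel, ind, diploid = NULL, haploid = NULL,
                       gl = NULL, gq = NULL) {
  stopifnot(inherits(panel, "snp_panel"), "id" %in% names(ind))
  s <- nrow(panel$sites); n <- nrow(ind)
  chk <- function(m, what) {
    if (!is.null(m) && (nrow(m) != s || ncol(m) != n)) {
      stop("geno_store: ", what, " is ", nrow(m), "x", ncol(m),
           ", expected ", s, "x", n)
    }
  }
  chk(diploid, "diploid"); chk(haploid, "haploid"); chk(gq, "gq")
  if (!is.null(gl)) {
    if (!identical(dim(gl)[1:2], as.integer(c(s, n))) || dim(gl)[3] != 3L) {
      stop("geno_store: gl must be sites x individuals x 3")
    }
    tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
    bad <- !is.na(tot) & abs(tot - 1) > 1e-6
    if (any(bad)) stop("geno_store: ", sum(bad), " likelihood triples do not normalize")
  }
  if (!is.null(diploid)) colnames(diploid) <- ind$id
  if (!is.null(haploid)) colnames(haploid) <- ind$id
  structure(list(panel = panel, ind = as.data.frame(ind), diploid = diploid,
                 haploid = haploid, gl = gl, gq = gq),
            class = "geno_store")
}

#' @export
print.geno_store <- function(x, ...) {
  cat("geno_store:", nrow(x$ind), "individuals x", nrow(x$panel$sites), "sites;",
      "components:", paste(c("diploid", "haploid", "gl", "gq")[
        !vapply(x[c("diploid", "haploid", "gl", "gq")], is.null, TRUE)],
        collapse = ", "), "\n")
  invisible(x)
}

# ---- EIGENSTRAT ------------------------------------------------------------

#' Read an EIGENSTRAT geno/snp/ind triplet
#'
#' The `.snp` file supplies the site map (id, chromosome, genetic position,
#' physical position, allele1, allele2); the `.geno` file holds one line per
#' site of digits counting copies of allele1 (9 = missing), following the
#' EIGENSTRAT convention; the `.ind` file holds id, sex code and group.
#' Chromosome class is inferred: labels containing "X"/"23" are X,
#' "Y"/"24" are Y, all else autosomal.
#'
#' @param prefix path prefix; `<prefix>.geno`, `.snp`, `.ind` must exist.
#' @return a `geno_store` with the diploid component filled in.
#' @export
read_eigenstrat <- function(prefix) {
  snp <- utils::read.table(paste0(prefix, ".snp"), header = FALSE,
                           stringsAsFactors = FALSE)
  names(snp)[1:6] <- c("id", "chrom", "gpos", "pos", "a1", "a2")
  ind <- utils::read.table(paste0(prefix, ".ind"), header = FALSE,
                           stringsAsFactors = FALSE)
  names(ind)[1:3] <- c("id", "sex", "group")
  lines <- readLines(paste0(prefix, ".geno"))
  if (length(lines) != nrow(snp)) {
    stop("read_eigenstrat: geno has ", length(lines), " lines for ",
         nrow(snp), " snp records")
  }
  widths <- nchar(lines)
  if (any(widths != nrow(ind))) {
    stop("read_eigenstrat: ragged geno line ", which(widths != nrow(ind))[1],
         " (width ", widths[which(widths != nrow(ind))[1]],
         ", expected ", nrow(ind), ")")
  }
  mat <- t(matrix(unlist(lapply(lines, function(l) utf8ToInt(l) - 48L)),
                  nrow = nrow(ind)))
  if (any(!(mat %in% c(0L, 1L, 2L, 9L)))) {
    bad <- which(apply(mat, 1L, function(r) any(!(r %in% c(0L, 1L, 2L, 9L)))))[1]
    stop("read_eigenstrat: unknown genotype character at geno line ", bad)
  }
  mat[mat == 9L] <- NA_integer_
  cls <- ifelse(grepl("X|^23$", snp$chrom), "X",
                ifelse(grepl("Y|^24$", snp$chrom), "Y", "autosome"))
  panel <- snp_panel(data.frame(id = snp$id, chrom = as.character(snp$chrom),
                                class = cls, pos = snp$pos,
                                a1 = snp$a1, a2 = snp$a2,
                                stringsAsFactors = FALSE))
  # geno digit counts allele1; internal diploid code counts allele2
  diploid <- 2L - mat
  geno_store(panel, ind, diploid = diploid)
}

#' Write an EIGENSTRAT geno/snp/ind triplet
#'
#' Inverse of [read_eigenstrat()]: internal allele-2 dose `g` is written as
#' the digit `2 - g`, NA as 9.
#'
#' @param store a `geno_store` with a diploid component.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(store, prefix) {
  stopifnot(inherits(store, "geno_store"), !is.null(store$diploid))
  s <- store$panel$sites
  utils::write.table(
    data.frame(s$id, s$chrom, 0, s$pos, s$a1, s$a2),
    paste0(prefix, ".snp"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  ind <- store$ind
  sex <- if ("sex" %in% names(ind)) ind$sex else rep("U", nrow(ind))
  grp <- if ("group" %in% names(ind)) ind$group else rep("pop", nrow(ind))
  utils::write.table(data.frame(ind$id, sex, grp), paste0(prefix, ".ind"),
                     quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  dig <- 2L - store$diploid
  dig[is.na(dig)] <- 9L
  writeLines(apply(dig, 1L, paste, collapse = ""), paste0(prefix, ".geno"))
  invisible(prefix)
}

# ---- VCF with genotype likelihoods ----------------------------------------

#' Write a VCF with GT, PL and GQ plus per-population INFO allele frequencies
#'
#' Emits a minimal VCF 4.2 dialect: biallelic records with `GT:PL:GQ` per
#' sample and `AF_<POP>` INFO tags for every population frequency column on
#' the store's panel.  PL values are phred-scaled likelihood ratios against
#' the best genotype; sites with no likelihood are written as missing.
#'
#' @param store a `geno_store` with a `gl` component.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_gl <- function(store, path) {
  stopifnot(inherits(store, "geno_store"), !is.null(store$gl))
  s <- store$panel$sites
  n <- nrow(store$ind)
  pops <- colnames(store$panel$freq)
  info <- rep(".", nrow(s))
  if (!is.null(pops)) {
    parts <- lapply(pops, function(p) {
      sprintf("AF_%s=%.6g", p, store$panel$freq[, p])
    })
    info <- do.call(paste, c(parts, sep = ";"))
  }
  gt_codes <- c("0/0", "0/1", "1/1")
  fmt <- matrix("./.:.:.", nrow = nrow(s), ncol = n)
  for (j in seq_len(n)) {
    lik <- store$gl[, j, ]
    cov <- !is.na(lik[, 1])
    if (!any(cov)) next
    lg <- -10 * log10(pmax(lik[cov, , drop = FALSE], 1e-30))
    lg <- lg - apply(lg, 1L, min)
    pl <- apply(round(lg), 1L, paste, collapse = ",")
    best <- max.col(lik[cov, , drop = FALSE], ties.method = "first")
    if (!is.null(store$diploid)) {
      d <- store$diploid[cov, j] + 1L
      best[!is.na(d)] <- d[!is.na(d)]
    }
    gq <- if (!is.null(store$gq)) {
      ifelse(is.na(store$gq[cov, j]), ".",
             as.character(as.integer(round(store$gq[cov, j]))))
    } else "."
    fmt[cov, j] <- paste0(gt_codes[best], ":", pl, ":", gq)
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=paleokin",
           if (!is.null(pops)) {
             sprintf("##INFO=<ID=AF_%s,Number=1,Type=Float,Description=\"Allele 2 frequency in %s\">",
                     pops, pops)
           },
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", store$ind$id), collapse = "\t"))
  body <- paste(s$chrom, s$pos, s$id, s$a1, s$a2, ".", "PASS", info,
                "GT:PL:GQ",
                apply(fmt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF with genotype likelihoods
#'
#' Parses biallelic records with PL (or GL) fields into a `geno_store`:
#' PL values become normalized linear likelihood triples, GT becomes the
#' diploid call, GQ is carried through, and `AF_<POP>` INFO tags become panel
#' frequency columns.  Multiallelic records are skipped and their count
#' reported via a message and the `n_multiallelic` attribute.
#'
#' @param path VCF path (plain text or gzipped).
#' @return a `geno_store`; attribute `n_multiallelic` counts skipped records.
#' @export
read_vcf_gl <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)  # single-record files drop to a vector
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  multi <- grepl(",", fx$ALT)
  n_multi <- sum(multi)
  if (n_multi > 0L) {
    message("read_vcf_gl: skipped ", n_multi, " multiallelic records")
    v <- v[!multi, ]
    fx <- fx[!multi, , drop = FALSE]
  }
  pl <- tryCatch(vcfR::extract.gt(v, element = "PL"), error = function(e) NULL)
  gl_field <- FALSE
  if (is.null(pl) || all(is.na(pl))) {
    pl <- tryCatch(vcfR::extract.gt(v, element = "GL"), error = function(e) NULL)
    gl_field <- TRUE
  }
  if (is.null(pl) || all(is.na(pl))) {
    stop("read_vcf_gl: no PL or GL field on any record")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  samples <- colnames(v@gt)[-1]
  s <- nrow(fx); n <- length(samples)
  as_mat <- function(x) {
    if (is.null(x) || is.matrix(x)) x else matrix(x, nrow = s, ncol = n)
  }
  pl <- as_mat(pl); gt <- as_mat(gt); gq <- as_mat(gq)
  ids <- ifelse(fx$ID == "." | is.na(fx$ID),
                paste0(fx$CHROM, "_", fx$POS), fx$ID)
  # INFO AF_<POP> tags -> frequency columns
  info <- v@fix[, "INFO"]
  tags <- unique(unlist(regmatches(info, gregexpr("AF_[A-Za-z0-9_.]+(?==)",
                                                  info, perl = TRUE))))
  freq <- NULL
  if (length(tags)) {
    freq <- sapply(tags, function(tg) {
      mm <- regmatches(info, regexpr(paste0(tg, "=[-0-9.eE]+"), info))
      out <- rep(NA_real_, s)
      hit <- grepl(paste0(tg, "="), info)
      out[hit] <- as.numeric(sub(paste0(tg, "="), "", mm))
      out
    })
    colnames(freq) <- sub("^AF_", "", tags)
  }
  cls <- ifelse(grepl("X|^23$", fx$CHROM), "X",
                ifelse(grepl("Y|^24$", fx$CHROM), "Y", "autosome"))
  panel <- snp_panel(data.frame(id = ids, chrom = fx$CHROM, class = cls,
                                pos = as.integer(fx$POS), a1 = fx$REF,
                                a2 = fx$ALT, stringsAsFactors = FALSE),
                     freq = freq)
  gl <- array(NA_real_, dim = c(s, n, 3L))
  diploid <- matrix(NA_integer_, s, n)
  for (j in seq_len(n)) {
    pj <- pl[, j]
    cov <- !is.na(pj) & pj != "."
    if (any(cov)) {
      vals <- do.call(rbind, lapply(strsplit(pj[cov], ","), as.numeric))
      lin <- if (gl_field) 10^(vals) else 10^(-vals / 10)
      lin <- lin / rowSums(lin)
      gl[cov, j, ] <- lin
    }
    gj <- gt[, j]
    g_ok <- !is.na(gj) & gj %in% c("0/0", "0/1", "1/0", "1/1", "0|0", "0|1", "1|0", "1|1")
    dose <- rep(NA_integer_, s)
    dose[g_ok] <- vapply(strsplit(gsub("\\|", "/", gj[g_ok]), "/"),
                         function(a) sum(as.integer(a)), 0L)
    diploid[, j] <- dose
  }
  ind <- data.frame(id = samples, stringsAsFactors = FALSE)
  out <- geno_store(panel, ind, diploid = diploid, gl = gl,
                    gq = if (all(is.na(gq))) NULL else unname(gq))
  attr(out, "n_multiallelic") <- n_multi
  out
}
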