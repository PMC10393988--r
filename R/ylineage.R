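#' Y-haplogroup trees with branch-defining SNPs
#'
#' A rooted tree of haplogroup labels plus a table of branch-defining SNPs
#' (each marker sits on exactly one branch, identified by the child node it
#' leads to), in the ISOGG style: marker name, haplogroup, position,
#' ancestral allele, derived allele.  Indel markers are rejected.
#'
#' @param nodes data.frame with columns `haplogroup`, `parent` (NA for the
#'   single root).
#' @param snps data.frame with columns `name`, `haplogroup`, `position`,
#'   `ancestral`, `derived`.
#' @return An object of class `haplogroup_tree`.
#' @export
haplogroup_tree <- function(nodes, snps) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(all(c("haplogroup", "parent") %in% names(nodes)),
            all(c("name", "haplogroup", "position", "ancestral", "derived")
                %in% names(snps)))
  if (anyDuplicated(nodes$haplogroup)) stop("haplogroup_tree: duplicate labels")
  roots <- nodes$haplogroup[is.na(nodes$parent)]
  if (length(roots) != 1L) {
    stop("haplogroup_tree: expected a single root, found ", length(roots))
  }
  if (!all(stats::na.omit(nodes$parent) %in% nodes$haplogroup)) {
    stop("haplogroup_tree: parent labels missing from node list")
  }
  bases <- c("A", "C", "G", "T")
  if (!all(snps$ancestral %in% bases) || !all(snps$derived %in% bases)) {
    stop("haplogroup_tree: markers must be single-base substitutions (no indels)")
  }
  if (!all(snps$haplogroup %in% nodes$haplogroup)) {
    stop("haplogroup_tree: marker attached to unknown haplogroup")
  }
  if (anyDuplicated(snps$position)) {
    # multi-position markers must already be split; same position on two
    # branches is not representable
    stop("haplogroup_tree: duplicate marker positions")
  }
  # depth-check acyclicity by walking to root from every node
  parent_of <- stats::setNames(nodes$parent, nodes$haplogroup)
  for (h in nodes$haplogroup) {
    seen <- character(0); cur <- h
    while (!is.na(parent_of[[cur]])) {
      if (cur %in% seen) stop("haplogroup_tree: cycle at ", cur)
      seen <- c(seen, cur); cur <- parent_of[[cur]]
    }
  }
  structure(list(nodes = nodes, snps = snps, root = roots,
                 parent_of = parent_of),
            class = "haplogroup_tree")
}

#' Read an ISOGG-style haplogroup tree from TSV files
#' @param nodes_path TSV with columns haplogroup, parent (empty = root).
#' @param snps_path TSV with columns name, haplogroup, position, ancestral,
#'   derived.
#' @return a [haplogroup_tree()].
#' @export
read_haplogroup_tree <- function(nodes_path, snps_path) {
  nodes <- utils::read.table(nodes_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, na.strings = c("NA", ""))
  snps <- utils::read.table(snps_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  haplogroup_tree(nodes, snps)
}

# Root-to-node path (vector of node labels, root first).
hg_path <- function(tree, node) {
  path <- node
  while (!is.na(tree$parent_of[[node]])) {
    node <- tree$parent_of[[node]]
    path <- c(node, path)
  }
  path
}

#' Recode damage-suspect Y-chromosome calls
#'
#' Applies the ancient-DNA hygiene rules before haplogroup assignment:
#' calls at transition sites with genotype quality below `min_gq` are kept
#' only when the called allele is C or G (T and A calls there are
#' indistinguishable from deamination); at transversion sites whose two
#' alleles do not include T, an observed T is relabelled C (and an observed
#' A is relabelled G where A is not an allele), treating them as post-mortem
#' deamination products.  All recodings and drops are reported.
#'
#' @param calls data.frame with columns `position`, `allele` (called base)
#'   and `gq`.
#' @param tree a [haplogroup_tree()] supplying the per-position
#'   ancestral/derived context.
#' @param min_gq quality threshold for the transition rule (default 50).
#' @return list with `calls` (usable calls joined to marker context, with a
#'   `recoded` flag), `n_dropped_lowq_transition`, `n_recoded`.
#' @export
recode_y_calls <- function(calls, tree, min_gq = 50) {
  m <- merge(calls, tree$snps, by = "position")
  if (nrow(m) == 0L) {
    return(list(calls = m, n_dropped_lowq_transition = 0L, n_recoded = 0L))
  }
  is_transition <- mutation_class(m$ancestral, m$derived) == "transition"
  m$recoded <- FALSE
  # deamination relabelling at transversion sites lacking the damaged base
  no_t <- !is_transition & m$ancestral != "T" & m$derived != "T"
  t_obs <- no_t & m$allele == "T"
  m$allele[t_obs] <- "C"; m$recoded[t_obs] <- TRUE
  no_a <- !is_transition & m$ancestral != "A" & m$derived != "A"
  a_obs <- no_a & m$allele == "A"
  m$allele[a_obs] <- "G"; m$recoded[a_obs] <- TRUE
  # low-quality transition calls usable only when C or G was observed
  drop <- is_transition & !is.na(m$gq) & m$gq < min_gq &
    !(m$allele %in% c("C", "G"))
  out <- m[!drop, , drop = FALSE]
  list(calls = out, n_dropped_lowq_transition = sum(drop),
       n_recoded = sum(out$recoded))
}

#' Assign the Y-chromosome haplogroup from usable calls
#'
#' Scores every root-to-node lineage by its cumulative count of derived
#' calls on the lineage's branches, picks the lineage with maximal support,
#' and assigns the deepest node on that lineage whose own branch carries at
#' least one derived call.  Derived calls off the chosen lineage are counted
#' but ignored.  Ties between lineages are broken in favour of the lineage
#' with fewer conflicting ancestral calls on its branches; a remaining tie
#' stops the assignment at the deepest common ancestor with a conflict
#' flag.
#'
#' @param calls recoded call table from [recode_y_calls()] (`$calls`), or
#'   any data.frame with `haplogroup`, `allele`, `ancestral`, `derived`.
#' @param tree a [haplogroup_tree()].
#' @return list with `haplogroup`, `n_derived_support` (derived calls on
#'   the assigned lineage), `n_off_path_derived`, `conflict` flag and
#'   `lineage` (root-to-assignment path).
#' @export
assign_haplogroup <- function(calls, tree) {
  nodes <- tree$nodes$haplogroup
  der_count <- stats::setNames(rep(0L, length(nodes)), nodes)
  anc_count <- der_count
  if (nrow(calls) > 0L) {
    is_der <- calls$allele == calls$derived
    is_anc <- calls$allele == calls$ancestral
    d <- table(calls$haplogroup[is_der])
    a <- table(calls$haplogroup[is_anc])
    der_count[names(d)] <- as.integer(d)
    anc_count[names(a)] <- as.integer(a)
  }
  if (sum(der_count) == 0L) {
    return(list(haplogroup = tree$root, n_derived_support = 0L,
                n_off_path_derived = 0L, conflict = FALSE,
                lineage = tree$root))
  }
  paths <- lapply(nodes, function(n) hg_path(tree, n))
  names(paths) <- nodes
  score <- vapply(paths, function(p) sum(der_count[p]), 0L)
  anc_conf <- vapply(paths, function(p) sum(anc_count[p]), 0L)
  # candidate lineage tips: nodes whose own branch carries derived support
  # (an unsupported descendant is the same lineage as its parent)
  cand <- nodes[der_count > 0L]
  best <- cand[score[cand] == max(score[cand])]
  conflict <- FALSE
  if (length(best) > 1L) {
    # prefer the deepest when all best nodes lie on one lineage
    depths <- vapply(paths[best], length, 0L)
    deepest <- best[which.max(depths)]
    if (all(vapply(best, function(b) b %in% paths[[deepest]], TRUE))) {
      best <- deepest
    } else {
      least_conf <- best[anc_conf[best] == min(anc_conf[best])]
      if (length(least_conf) == 1L) {
        best <- least_conf
      } else {
        # deepest common ancestor of the tied lineages
        common <- Reduce(intersect, paths[least_conf])
        best <- common[length(common)]
        conflict <- TRUE
      }
    }
  }
  lineage <- paths[[best]]
  supported <- lineage[der_count[lineage] > 0L]
  assigned <- if (length(supported)) supported[length(supported)] else tree$root
  lin_out <- hg_path(tree, assigned)
  list(haplogroup = assigned,
       n_derived_support = sum(der_count[lin_out]),
       n_off_path_derived = sum(der_count) - sum(der_count[lineage]),
       conflict = conflict,
       lineage = lin_out)
}

#' Random haplogroup tree generator
#'
#' Builds a random rooted tree with `n_nodes` labels and a fixed number of
#' branch-defining markers per branch, mixing transition and transversion
#' substitutions, for simulation studies of the assignment procedure.
#'
#' @param n_nodes number of haplogroup nodes.
#' @param markers_per_branch markers on every non-root branch.
#' @param seed RNG seed.
#' @return a [haplogroup_tree()].
#' @export
random_haplogroup_tree <- function(n_nodes = 50L, markers_per_branch = 3L,
                                   seed = 1L) {
  set.seed(seed)
  labels <- paste0("H", seq_len(n_nodes))
  parent <- c(NA_character_,
              vapply(2:n_nodes, function(i) labels[sample.int(i - 1L, 1L)], ""))
  n_mark <- (n_nodes - 1L) * markers_per_branch
  pairs <- list(c("C", "T"), c("G", "A"), c("A", "C"), c("G", "C"),
                c("A", "T"), c("G", "T"))
  pick <- sample.int(6L, n_mark, replace = TRUE)
  snps <- data.frame(
    name = paste0("M", seq_len(n_mark)),
    haplogroup = rep(labels[-1], each = markers_per_branch),
    position = sample.int(2.6e7, n_mark),
    ancestral = vapply(pairs, `[`, "", 1L)[pick],
    derived = vapply(pairs, `[`, "", 2L)[pick],
    stringsAsFactors = FALSE)
  haplogroup_tree(data.frame(haplogroup = labels, parent = parent,
                             stringsAsFactors = FALSE), snps)
}

#' Simulate Y-marker calls for a known lineage
#'
#' Generates per-marker calls for a male whose true haplogroup is
#' `true_node`: derived on the root-to-node lineage, ancestral elsewhere,
#' with random missingness, deamination miscalls (true C observed as T,
#' true G as A, at `damage_rate`), and genotype qualities drawn low with
#' probability `lowq_rate`.
#'
#' Deamination miscalls arise from single damaged reads at shallow sites, so
#' they are confined to calls whose genotype quality is low; well-supported
#' (high-GQ) calls are taken as damage-free, which is the premise of the
#' GQ-based transition rule.
#'
#' @param tree a [haplogroup_tree()].
#' @param true_node generating haplogroup label.
#' @param missing_rate fraction of markers with no call.
#' @param damage_rate probability that a low-quality call of a C/G allele
#'   reads as its deamination product (C as T, G as A).
#' @param lowq_rate probability a call's GQ falls below 50.
#' @param seed RNG seed.
#' @return data.frame with `position`, `allele`, `gq`.
#' @export
simulate_y_calls <- function(tree, true_node, missing_rate = 0.2,
                             damage_rate = 0.3, lowq_rate = 0.3, seed = 1L) {
  set.seed(seed)
  on_path <- tree$snps$haplogroup %in% hg_path(tree, true_node)
  truth <- ifelse(on_path, tree$snps$derived, tree$snps$ancestral)
  keep <- stats::runif(length(truth)) >= missing_rate
  lowq <- stats::runif(length(truth)) < lowq_rate
  gq <- ifelse(lowq, sample(20:49, length(truth), replace = TRUE),
               sample(50:99, length(truth), replace = TRUE))
  allele <- truth
  dam <- lowq & stats::runif(length(truth)) < damage_rate
  allele[dam & truth == "C"] <- "T"
  allele[dam & truth == "G"] <- "A"
  data.frame(position = tree$snps$position[keep], allele = allele[keep],
             gq = gq[keep], stringsAsFactors = FALSE)
}
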