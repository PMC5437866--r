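#' Prune a phylogeny to a set of tips
#'
#' Induced subtree on the kept tips, with unbranched internal nodes
#' collapsed and their branch lengths summed, so pairwise patristic
#' distances among kept tips are preserved. Names in \code{keep} that are
#' absent from the tree are not silently dropped: they are returned as an
#' explicit \code{unmatched} vector.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param keep character vector of tip labels to retain (>= 3 matched).
#' @return list with elements \code{tree} (the pruned \code{phylo}) and
#'   \code{unmatched} (character vector of names not found).
#' @export
prune_tree <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unmatched <- setdiff(keep, tree$tip.label)
  matched <- intersect(keep, tree$tip.label)
  if (length(matched) < 3)
    stop("fewer than 3 of the requested tips are in the tree")
  list(tree = ape::keep.tip(tree, matched), unmatched = unmatched)
}

# Children of every node, from a postorder edge matrix.
children_of <- function(tree) {
  split(tree$edge[, 2], factor(tree$edge[, 1],
                               levels = seq_len(ape::Ntip(tree) + tree$Nnode)))
}

# Floor for zero-length branches: a small fraction of tree height, so the
# inverse-branch-length weights stay finite.
edge_lengths_floored <- function(tree) {
  h <- max(ape::node.depth.edgelength(tree))
  if (h <= 0) h <- 1
  pmax(tree$edge.length, 1e-8 * h)
}

#' Sum of sister-clade differences for a binary trait
#'
#' The raw d value underlying the D statistic: ancestral nodal values are
#' estimated from the tip states by branch-length-weighted averaging of
#' daughter values (each daughter weighted by the inverse of its — possibly
#' extended — branch length, the node's own branch being extended by the
#' harmonic term, as in contrast calculations), and d is the sum over
#' internal nodes of the absolute differences between daughter values. At a
#' polytomy the node contributes the mean absolute pairwise daughter
#' difference.
#'
#' @param tree rooted \code{phylo} with branch lengths, >= 3 tips.
#' @param trait named 0/1 vector covering every tip; both states must be
#'   present.
#' @return the scalar d value.
#' @export
sister_diff_sum <- function(tree, trait) {
  trait <- check_trait(tree, trait)
  tree <- stats::reorder(tree, "postorder")
  n <- ape::Ntip(tree)
  len <- edge_lengths_floored(tree)
  nnode <- tree$Nnode
  val <- c(trait[tree$tip.label], rep(NA_real_, nnode))
  # working branch length of the edge above each node
  blen <- rep(NA_real_, n + nnode)
  blen[tree$edge[, 2]] <- len
  kids <- children_of(tree)
  d <- 0
  for (v in unique(tree$edge[, 1])) {   # postorder: children first
    ch <- kids[[v]]
    w <- 1 / blen[ch]
    val[v] <- sum(w * val[ch]) / sum(w)
    if (!is.na(blen[v])) blen[v] <- blen[v] + 1 / sum(w)
    dif <- outer(val[ch], val[ch], "-")
    m <- length(ch)
    d <- d + sum(abs(dif[lower.tri(dif)])) / (m * (m - 1) / 2)
  }
  d
}

check_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait must be named by tip label")
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss)) stop("trait missing for tip(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  trait <- trait[tree$tip.label]
  if (!all(trait %in% c(0, 1))) stop("trait states must be 0/1")
  if (length(unique(trait)) < 2)
    stop("both trait states must be present on the tree")
  trait
}

# Linear representation of the sister-difference sum: because the nodal
# averaging is linear in the tip states, d(x) = sum(wt * |M %*% x|) for a
# matrix M (one row per daughter pair) that depends only on the tree.
# Built once, it evaluates d for thousands of traits by one matrix product.
d_operator <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  n <- ape::Ntip(tree)
  len <- edge_lengths_floored(tree)
  nnode <- tree$Nnode
  coef <- matrix(0, n + nnode, n)
  coef[cbind(seq_len(n), seq_len(n))] <- 1   # tip i carries tip state i
  blen <- rep(NA_real_, n + nnode)
  blen[tree$edge[, 2]] <- len
  kids <- children_of(tree)
  rows <- list(); wts <- numeric(0)
  for (v in unique(tree$edge[, 1])) {
    ch <- kids[[v]]
    w <- 1 / blen[ch]
    coef[v, ] <- colSums(coef[ch, , drop = FALSE] * (w / sum(w)))
    if (!is.na(blen[v])) blen[v] <- blen[v] + 1 / sum(w)
    m <- length(ch)
    npair <- m * (m - 1) / 2
    for (i in seq_len(m - 1)) for (j in seq((i + 1), m)) {
      rows[[length(rows) + 1]] <- coef[ch[i], ] - coef[ch[j], ]
      wts <- c(wts, 1 / npair)
    }
  }
  list(M = do.call(rbind, rows), wt = wts, tip_order = tree$tip.label)
}

# Evaluate d for a matrix of trait columns (tips ordered as op$tip_order).
d_apply <- function(op, X) as.numeric(op$wt %*% abs(op$M %*% X))

# Brownian-motion tip values on a tree: each edge contributes an
# independent normal increment with variance equal to its length; root 0.
# Returns an Ntip x n_sim matrix.
bm_tips <- function(tree, n_sim) {
  tree <- stats::reorder(tree, "postorder")
  n <- ape::Ntip(tree)
  edge <- tree$edge[rev(seq_len(nrow(tree$edge))), , drop = FALSE]  # preorder
  len <- edge_lengths_floored(tree)[rev(seq_len(nrow(tree$edge)))]
  V <- matrix(0, n + tree$Nnode, n_sim)
  Z <- matrix(stats::rnorm(length(len) * n_sim, sd = rep(sqrt(len), n_sim)),
              nrow = length(len))
  for (e in seq_len(nrow(edge)))
    V[edge[e, 2], ] <- V[edge[e, 1], ] + Z[e, ]
  rownames(V) <- c(tree$tip.label, rep(NA, tree$Nnode))
  V[seq_len(n), , drop = FALSE]
}

# Dichotomise continuous tip values at the rank matching the requested
# number of ones; ties broken by draw order.
threshold_at_prevalence <- function(X, n_ones) {
  apply(X, 2, function(x) {
    s <- integer(length(x))
    s[order(x, decreasing = TRUE)[seq_len(n_ones)]] <- 1L
    s
  })
}

#' D statistic for phylogenetic signal in a binary trait
#'
#' The observed sister-clade difference sum \code{d_obs} is scaled between
#' two calibrations obtained by simulation: random permutation of the tip
#' states (phylogenetically random expectation) and Brownian motion on the
#' tree thresholded to the observed prevalence (clumped expectation):
#' \deqn{D = (d_{obs} - mean(d_{Brownian})) / (mean(d_{random}) - mean(d_{Brownian}))}
#' D is close to 1 when states are distributed randomly with respect to
#' phylogeny and close to 0 when they are as clumped as a Brownian-threshold
#' trait; values outside [0, 1] are legitimate (overdispersion gives D > 1)
#' and are never clamped. Every permutation and every thresholded simulation
#' conserves the observed number of 1-state tips.
#'
#' Two p-values are reported: \code{p_random}, the fraction of permutation d
#' values \eqn{\le d_{obs}} (small when the trait is more clumped than
#' random), and \code{p_brownian}, the fraction of Brownian d values
#' \eqn{\ge d_{obs}} (small when the trait is more overdispersed than
#' Brownian). A random-like trait therefore has large \code{p_random} and
#' small \code{p_brownian}.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param trait named 0/1 vector over tips (1 = false-positive species).
#' @param n_perm number of permutations and of Brownian simulations.
#' @param seed integer seed; results are reproducible given it.
#' @return list of class \code{d_result}: \code{d_obs, mean_d_random,
#'   mean_d_brownian, D, p_random, p_brownian, n_perm, seed, n_tips,
#'   n_ones}.
#' @export
d_statistic <- function(tree, trait, n_perm = 1000, seed = 1) {
  trait <- check_trait(tree, trait)
  if (n_perm < 100)
    warning("n_perm < 100 gives an unstable calibration of D")
  op <- d_operator(tree)
  x <- trait[op$tip_order]
  d_obs <- d_apply(op, matrix(x, ncol = 1))
  n <- length(x)
  n_ones <- sum(x)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) x[sample.int(n)],
                   numeric(n))
    d_perm <- d_apply(op, perm)
    bm <- threshold_at_prevalence(bm_tips(tree, n_perm)[op$tip_order, ,
                                                        drop = FALSE], n_ones)
    d_bm <- d_apply(op, bm)
  })
  mr <- mean(d_perm); mb <- mean(d_bm)
  structure(list(
    d_obs = d_obs, mean_d_random = mr, mean_d_brownian = mb,
    D = (d_obs - mb) / (mr - mb),
    p_random = mean(d_perm <= d_obs),
    p_brownian = mean(d_bm >= d_obs),
    n_perm = n_perm, seed = seed, n_tips = n, n_ones = n_ones
  ), class = "d_result")
}

#' @export
print.d_result <- function(x, ...) {
  cat(sprintf("D = %.3f (d_obs %.3f; random mean %.3f, Brownian mean %.3f)\n",
              x$D, x$d_obs, x$mean_d_random, x$mean_d_brownian))
  cat(sprintf("p (random model) = %.3f, p (Brownian model) = %.3f; %d tips, %d in state 1\n",
              x$p_random, x$p_brownian, x$n_tips, x$n_ones))
  invisible(x)
}

#' Binary false-positive trait for a site, matched to a tree
#'
#' Builds the 0/1 trait (1 = species recorded as a false positive at the
#' site, 0 = true-positive species) over the tips of a phylogeny. Survey
#' names are matched to tip labels with spaces replaced by underscores.
#' Unmatched species are reported, not dropped silently.
#'
#' @param tree a \code{phylo} object.
#' @param fp_species character vector of false-positive species names.
#' @param tp_species character vector of true-positive (accepted and
#'   observed) species names.
#' @return list with \code{trait} (named 0/1 vector over the matched tips),
#'   \code{tree} (pruned to those tips) and \code{unmatched}.
#' @export
fp_trait_on_tree <- function(tree, fp_species, tp_species) {
  lab <- function(x) gsub(" ", "_", x)
  fp <- unique(lab(fp_species)); tp <- setdiff(unique(lab(tp_species)), fp)
  pruned <- prune_tree(tree, c(fp, tp))
  trait <- setNames(as.integer(pruned$tree$tip.label %in% fp),
                    pruned$tree$tip.label)
  list(trait = trait, tree = pruned$tree, unmatched = pruned$unmatched)
}

#' Genus-level cautious-recording trait on a tree
#'
#' For the genus-level signal test: every tip whose genus (the portion of
#' the tip label before the first underscore) received at least one
#' cautious record gets state 1.
#'
#' @param tree a \code{phylo} object.
#' @param cautious_genera character vector of genus names.
#' @return named 0/1 vector over all tips.
#' @export
genus_trait_on_tree <- function(tree, cautious_genera) {
  g <- sub("_.*$", "", tree$tip.label)
  setNames(as.integer(g %in% cautious_genera), tree$tip.label)
}
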