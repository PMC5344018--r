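#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Reconstructs ancestral values of a continuous trait on a fixed,
#' time-calibrated binary tree under a Brownian-motion (BM) null model:
#' variation accumulates proportionally with time, with zero-mean increments
#' of constant variance \eqn{\sigma^2} per My. Point estimates are the
#' GLS/ML values obtained by two-pass belief propagation: a tip-to-root pass
#' of precision-weighted averaging (Felsenstein pruning), then a root-to-tip
#' finishing pass combining each node's subtree message with the message
#' from the rest of the tree. The root estimate equals the phylogenetic
#' (GLS) mean \eqn{(1'V^{-1}x)/(1'V^{-1}1)}.
#'
#' BM reconstructions are intrinsically shrunk towards intermediate values;
#' rates of change read off them are conservative. This is a property of the
#' null model, not corrected here.
#'
#' @param tree A binary `phylo` with branch lengths in My.
#' @param tip_values Named numeric vector, names = tip labels (trait units,
#'   e.g. mm).
#' @param trait Optional trait name carried into the result.
#' @param conf Coverage of the reported interval (default 0.95).
#' @return An object of class `asr_bm`: list with `estimate`, `ci_low`,
#'   `ci_high` (length n.tips + n.nodes, ape node order), `sigma2` (ML
#'   estimate, trait-units^2/My), `n_tips`, `trait`, `tree`.
#' @seealso [node_table()] for a flat per-node data frame.
#' @export
asr_bm <- function(tree, tip_values, trait = "trait", conf = 0.95) {
  validate_tree(tree, require_binary = TRUE)
  n <- length(tree$tip.label)
  if (n < 2L) stop("need at least 2 tips")
  x <- match_tip_values(tree, tip_values)
  depths <- node_depths(tree)
  if (all(depths[seq_len(n)] == 0))
    stop("all root-to-tip path lengths are zero: covariance is singular")

  m <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  L <- po$edge.length
  root <- E[nrow(E), 1L]

  # tip-to-root pass: below-message (mu_b, v_b) at each node, where v_b is
  # the conditional variance (in sigma^2 units) of the node state given its
  # subtree, under a flat prior.
  mu_b <- numeric(m); v_b <- numeric(m)
  mu_b[seq_len(n)] <- x
  acc_w <- numeric(m)   # running precision at internal nodes
  acc_wm <- numeric(m)  # running precision-weighted mean
  kids <- vector("list", m)
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    kids[[p]] <- c(kids[[p]], i)
    if (length(kids[[p]]) == 2L) {
      e1 <- kids[[p]][1L]; e2 <- kids[[p]][2L]
      c1 <- E[e1, 2L]; c2 <- E[e2, 2L]
      vh1 <- L[e1] + v_b[c1]; vh2 <- L[e2] + v_b[c2]
      cm <- combine_messages(c(mu_b[c1], mu_b[c2]), c(vh1, vh2))
      mu_b[p] <- cm$mu; v_b[p] <- cm$v
    }
  }

  # ML sigma^2 from the standardized-contrast quadratic form:
  # (x - mu)' V^-1 (x - mu) = sum of squared contrasts; divide by n for ML.
  contr2 <- 0
  for (p in (n + 1L):m) {
    e1 <- kids[[p]][1L]; e2 <- kids[[p]][2L]
    c1 <- E[e1, 2L]; c2 <- E[e2, 2L]
    vs <- (L[e1] + v_b[c1]) + (L[e2] + v_b[c2])
    if (vs > 0) contr2 <- contr2 + (mu_b[c1] - mu_b[c2])^2 / vs
  }
  sigma2 <- contr2 / n

  # root-to-tip finishing pass: above-message (mu_a, v_a) per non-root node,
  # then the posterior combination below x above.
  mu_a <- rep(NA_real_, m); v_a <- rep(Inf, m)
  est <- numeric(m); vcond <- numeric(m)
  est[seq_len(n)] <- x                      # tips: observed exactly
  est[root] <- mu_b[root]; vcond[root] <- v_b[root]
  pre <- rev(seq_len(nrow(E)))              # preorder: parent before child
  for (i in pre) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    sib_edge <- setdiff(kids[[p]], i)
    sc <- E[sib_edge, 2L]
    mus <- mu_b[sc]; vs <- L[sib_edge] + v_b[sc]
    if (p != root && is.finite(v_a[p])) {
      mus <- c(mus, mu_a[p]); vs <- c(vs, v_a[p])
    }
    cm <- combine_messages(mus, vs)
    mu_a[ch] <- cm$mu
    v_a[ch] <- cm$v + L[i]
    if (ch > n) {
      cc <- combine_messages(c(mu_b[ch], mu_a[ch]), c(v_b[ch], v_a[ch]))
      est[ch] <- cc$mu
      vcond[ch] <- cc$v
    }
  }

  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(pmax(sigma2 * vcond, 0))
  structure(list(
    estimate = stats::setNames(est, c(tree$tip.label,
                                      rep(NA_character_, tree$Nnode))),
    ci_low = est - half,
    ci_high = est + half,
    sigma2 = sigma2,
    n_tips = n,
    trait = trait,
    conf = conf,
    tree = tree
  ), class = "asr_bm")
}

# Precision-weighted combination of normal messages (mu_i, v_i).
# A zero-variance message is exact and dominates (zero-length branches:
# the node inherits that value).
combine_messages <- function(mu, v) {
  stopifnot(length(mu) == length(v), length(mu) >= 1L)
  zero <- v <= 0
  if (any(zero)) return(list(mu = mu[which(zero)[1L]], v = 0))
  w <- 1 / v
  list(mu = sum(w * mu) / sum(w), v = 1 / sum(w))
}

#' @export
print.asr_bm <- function(x, ...) {
  cat("Brownian-motion ancestral reconstruction of '", x$trait, "'\n",
      sep = "")
  cat("  tips:", x$n_tips, " internal nodes:",
      length(x$estimate) - x$n_tips, "\n")
  cat(sprintf("  ML rate sigma^2 = %.6g (trait-units^2/My)\n", x$sigma2))
  root <- x$n_tips + 1L
  cat(sprintf("  root estimate = %.6g [%.6g, %.6g] (%d%% interval)\n",
              x$estimate[root], x$ci_low[root], x$ci_high[root],
              round(100 * x$conf)))
  invisible(x)
}

#' Flat per-node table of an ancestral reconstruction
#'
#' @param asr An `asr_bm` object.
#' @return data frame: `node` (ape id), `is_tip`, `label`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @export
node_table <- function(asr) {
  stopifnot(inherits(asr, "asr_bm"))
  n <- asr$n_tips
  m <- length(asr$estimate)
  data.frame(
    node = seq_len(m),
    is_tip = seq_len(m) <= n,
    label = c(asr$tree$tip.label, rep(NA_character_, m - n)),
    estimate = unname(asr$estimate),
    ci_low = asr$ci_low,
    ci_high = asr$ci_high,
    stringsAsFactors = FALSE
  )
}

#' Parsimony reconstruction of a binary character
#'
#' Fitch/Sankoff reconstruction of a binary (0/1) character, typically a
#' male secondary sexual character (SSC). Reports the minimum number of
#' state changes, the full most-parsimonious-reconstruction (MPR) state set
#' per node (ambiguity is reported, not hidden), and per-branch gains
#' (0 to 1) and losses (1 to 0) under a DELTRAN-style resolution that delays
#' changes towards the tips; the gain/loss counts of the opposite
#' (ACCTRAN-style, changes pulled rootward) resolution are reported as the
#' alternative.
#'
#' When the root MPR set is ambiguous the DELTRAN pass takes state 0
#' (character absent) as ancestral, the usual prior for derived secondary
#' sexual characters; the ambiguity is still flagged.
#'
#' @param tree A binary `phylo`.
#' @param tip_states Named vector of 0/1 states, names = tip labels.
#' @param character_name Optional character name carried into the result.
#' @return An object of class `asr_parsimony`: `length` (minimum changes),
#'   `mpr` (m x 2 logical matrix, column j = state j-1 attainable),
#'   `resolved` (DELTRAN state per node), `gains`/`losses` (data frames of
#'   branches), `alt_n_gains`/`alt_n_losses` (ACCTRAN counts),
#'   `ambiguous_nodes`, `tree`.
#' @export
asr_parsimony <- function(tree, tip_states, character_name = "character") {
  validate_tree(tree, require_binary = TRUE)
  n <- length(tree$tip.label)
  s <- match_tip_values(tree, tip_states, what = "tip state")
  if (!all(s %in% c(0, 1)))
    stop("states must be binary 0/1; offending species: ",
         paste(names(s)[!s %in% c(0, 1)], collapse = ", "))
  m <- n + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  root <- E[nrow(E), 1L]

  # Sankoff down-pass: cost of the subtree below node v given v has state j.
  down <- matrix(0, m, 2L)
  down[seq_len(n), ] <- Inf
  down[cbind(seq_len(n), s + 1L)] <- 0
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1L]; ch <- E[i, 2L]
    down[p, 1L] <- down[p, 1L] + min(down[ch, 1L], down[ch, 2L] + 1)
    down[p, 2L] <- down[p, 2L] + min(down[ch, 2L], down[ch, 1L] + 1)
  }
  plen <- min(down[root, ])

  # up-pass: cost of the rest of the tree given v has state j.
  up <- matrix(0, m, 2L)
  for (i in rev(seq_len(nrow(E)))) {       # preorder
    p <- E[i, 1L]; ch <- E[i, 2L]
    # parent's total cost excluding this child's subtree, per parent state
    rest <- c(up[p, 1L] + down[p, 1L] -
                min(down[ch, 1L], down[ch, 2L] + 1),
              up[p, 2L] + down[p, 2L] -
                min(down[ch, 2L], down[ch, 1L] + 1))
    up[ch, 1L] <- min(rest[1L], rest[2L] + 1)
    up[ch, 2L] <- min(rest[2L], rest[1L] + 1)
  }
  total <- down + up
  mpr <- total == plen                      # m x 2 logical
  ambiguous <- which(mpr[, 1L] & mpr[, 2L])

  resolve <- function(deltran) {
    res <- integer(m)
    res[root] <- if (xor(mpr[root, 1L], mpr[root, 2L])) {
      which(mpr[root, ]) - 1L
    } else 0L                               # ambiguous root: absent ancestral
    for (i in rev(seq_len(nrow(E)))) {
      p <- E[i, 1L]; ch <- E[i, 2L]
      ps <- res[p]
      keep <- down[ch, ps + 1L]             # cost if child keeps parent state
      flip <- down[ch, 2L - ps] + 1         # cost if child changes
      res[ch] <- if (deltran) {
        if (keep <= flip) ps else 1L - ps   # ties: delay the change
      } else {
        if (flip <= keep) 1L - ps else ps   # ties: change early
      }
    }
    res
  }
  res_del <- resolve(deltran = TRUE)
  res_acc <- resolve(deltran = FALSE)

  br <- branches(tree)
  ev <- function(res) {
    d <- res[br$child] - res[br$parent]
    list(gains = br[d == 1L, , drop = FALSE],
         losses = br[d == -1L, , drop = FALSE])
  }
  del <- ev(res_del); acc <- ev(res_acc)

  structure(list(
    character_name = character_name,
    length = as.integer(plen),
    mpr = mpr,
    resolved = res_del,
    gains = del$gains,
    losses = del$losses,
    alt_n_gains = nrow(acc$gains),
    alt_n_losses = nrow(acc$losses),
    ambiguous_nodes = ambiguous,
    tree = tree
  ), class = "asr_parsimony")
}

#' @export
print.asr_parsimony <- function(x, ...) {
  cat("Parsimony reconstruction of '", x$character_name, "'\n", sep = "")
  cat("  minimum changes:", x$length, "\n")
  cat("  gains:", nrow(x$gains), " losses:", nrow(x$losses),
      " (DELTRAN; ACCTRAN alternative:", x$alt_n_gains, "gains,",
      x$alt_n_losses, "losses)\n")
  if (length(x$ambiguous_nodes))
    cat("  ambiguous MPR at", length(x$ambiguous_nodes), "node(s):",
        paste(utils::head(x$ambiguous_nodes, 10L), collapse = ", "), "\n")
  invisible(x)
}
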