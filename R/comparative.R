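#' Phylogenetic independent contrasts
#'
#' Felsenstein's pruning algorithm: a post-order traversal computing, at
#' each internal node with daughters i and j, the standardized contrast
#' \eqn{(x_i - x_j)/\sqrt{v_i + v_j}} and the corrected branch length
#' \eqn{v_k' = v_k + v_i v_j/(v_i + v_j)} passed up to the parent. Under
#' Brownian motion the n-1 contrasts are i.i.d. N(0, sigma^2), which is
#' what licenses ordinary regression on them.
#'
#' Zero-length branches (typically inserted by [resolve_polytomies()])
#' receive a small additive constant, `1e-8 *` tree depth, inside the
#' variance terms only; a message reports how many branches were adjusted.
#' Patristic structure is otherwise untouched.
#'
#' @param tree A binary `phylo` (resolve polytomies first).
#' @param tip_values Named numeric vector of trait values.
#' @param trait Optional trait name.
#' @return An object of class `pic_set`: data frame `contrasts` with one
#'   row per internal node (`node`, `contrast`, `variance` = v_i + v_j,
#'   `corrected_length`), plus `trait` and `n_tips` attributes.
#' @export
pic_contrasts <- function(tree, tip_values, trait = "trait") {
  if (!(ape::is.rooted(tree) && ape::is.binary(tree)))
    stop("tree contains polytomies; call resolve_polytomies() first")
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (n < 2L) stop("need at least 2 tips")
  x <- match_tip_values(tree, tip_values)

  eps <- 1e-8 * max(node_depths(tree))
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  L <- po$edge.length
  n_zero <- sum(L == 0)
  if (n_zero > 0) {
    L[L == 0] <- eps
    message("pic_contrasts: added ", format(eps), " to ", n_zero,
            " zero-length branch(es) in variance terms")
  }
  m <- n + tree$Nnode
  val <- numeric(m); val[seq_len(n)] <- x
  extra <- numeric(m)
  kids <- vector("list", m)
  out_node <- integer(tree$Nnode)
  out_con <- numeric(tree$Nnode)
  out_var <- numeric(tree$Nnode)
  out_cl <- numeric(tree$Nnode)
  k <- 0L
  for (i in seq_len(nrow(E))) {
    p <- E[i, 1L]
    kids[[p]] <- c(kids[[p]], i)
    if (length(kids[[p]]) == 2L) {
      e1 <- kids[[p]][1L]; e2 <- kids[[p]][2L]
      c1 <- E[e1, 2L]; c2 <- E[e2, 2L]
      v1 <- L[e1] + extra[c1]; v2 <- L[e2] + extra[c2]
      vs <- v1 + v2
      if (vs <= 0)
        stop("zero contrast variance at node ", p)
      k <- k + 1L
      out_node[k] <- p
      out_con[k] <- (val[c1] - val[c2]) / sqrt(vs)
      out_var[k] <- vs
      out_cl[k] <- v1 * v2 / vs
      val[p] <- (val[c1] / v1 + val[c2] / v2) / (1 / v1 + 1 / v2)
      extra[p] <- out_cl[k]
    }
  }
  structure(list(
    contrasts = data.frame(node = out_node, contrast = out_con,
                           variance = out_var, corrected_length = out_cl),
    trait = trait,
    n_tips = n
  ), class = "pic_set")
}

#' @export
print.pic_set <- function(x, ...) {
  cat("Phylogenetic independent contrasts of '", x$trait, "': ",
      nrow(x$contrasts), " contrasts from ", x$n_tips, " tips\n", sep = "")
  invisible(x)
}

# PDAP sign convention: flip each contrast pair so the x member is >= 0.
positivize_contrasts <- function(cx, cy) {
  s <- ifelse(cx < 0, -1, 1)
  list(x = cx * s, y = cy * s)
}

#' Reduced major axis (type II) regression
#'
#' Symmetric line-fitting for allometry, where both variables carry error:
#' slope = sign(cov) * SD(y)/SD(x), or through the origin
#' sign(sum xy) * sqrt(sum y^2 / sum x^2) (the form used on positivized
#' independent contrasts). The isometry test reports whether slope 1 lies
#' outside the confidence interval: for log-log size data a slope above 1
#' is positive allometry (Rensch's rule when y = male, x = female).
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param through_origin Fit through the origin (use for contrasts, after
#'   sign-positivization).
#' @param ci_method `"bootstrap"` (percentile over resampled pairs, seeded)
#'   or `"analytic"` (Jolicoeur's RMA interval from the F distribution).
#' @param n_boot Bootstrap replicates (default 1999).
#' @param seed Seed for the bootstrap stream.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `rma_fit`: `slope`, `intercept` (0 if through
#'   origin), `ci_low`, `ci_high`, `r2`, `p` (correlation test; df = n-1
#'   through the origin, n-2 otherwise), `n`, `isometry_rejected`.
#' @export
rma <- function(x, y, through_origin = FALSE,
                ci_method = c("bootstrap", "analytic"),
                n_boot = 1999L, seed = 1L, conf = 0.95) {
  ci_method <- match.arg(ci_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations, got ", n)

  est <- function(x, y) {
    if (through_origin) {
      sx2 <- sum(x^2); sy2 <- sum(y^2)
      if (sx2 == 0 || sy2 == 0) stop("zero variation in x or y")
      sxy <- sum(x * y)
      list(slope = (if (sxy < 0) -1 else 1) * sqrt(sy2 / sx2),
           r = sxy / sqrt(sx2 * sy2), intercept = 0)
    } else {
      sdx <- stats::sd(x); sdy <- stats::sd(y)
      if (sdx == 0 || sdy == 0) stop("zero variation in x or y")
      r <- stats::cor(x, y)
      b <- (if (r < 0) -1 else 1) * sdy / sdx
      list(slope = b, r = r, intercept = mean(y) - b * mean(x))
    }
  }
  fit <- est(x, y)
  r <- fit$r
  df <- if (through_origin) n - 1L else n - 2L
  p <- if (abs(r) >= 1) 0 else {
    tt <- abs(r) * sqrt(df / (1 - r^2))
    2 * stats::pt(tt, df, lower.tail = FALSE)
  }

  alpha <- 1 - conf
  if (ci_method == "analytic") {
    B <- stats::qf(conf, 1, df) * (1 - r^2) / df
    ci <- sort(abs(fit$slope) * c(sqrt(B + 1) - sqrt(B),
                                  sqrt(B + 1) + sqrt(B)))
    if (fit$slope < 0) ci <- sort(-ci)
  } else {
    bs <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(est(x[idx], y[idx])$slope, error = function(e) NA_real_)
      }, numeric(1))
    })
    ci <- unname(stats::quantile(bs, c(alpha / 2, 1 - alpha / 2),
                                 na.rm = TRUE, names = FALSE))
  }

  structure(list(
    slope = fit$slope, intercept = fit$intercept,
    ci_low = ci[1L], ci_high = ci[2L],
    r2 = r^2, p = p, n = n,
    through_origin = through_origin, ci_method = ci_method,
    conf = conf, seed = if (ci_method == "bootstrap") seed else NA_integer_,
    isometry_rejected = !(ci[1L] <= 1 && 1 <= ci[2L])
  ), class = "rma_fit")
}

#' @export
print.rma_fit <- function(x, ...) {
  cat(sprintf(
    "RMA regression%s: slope %.4g [%.4g, %.4g], R^2 %.3f, p %.3g, n %d\n",
    if (x$through_origin) " (through origin)" else "",
    x$slope, x$ci_low, x$ci_high, x$r2, x$p, x$n))
  cat("  isometry (slope = 1)",
      if (x$isometry_rejected) "rejected" else "not rejected",
      "at the", paste0(round(100 * x$conf), "%"), "level\n")
  invisible(x)
}

#' Contrast correlation between two traits
#'
#' Computes independent contrasts of both traits on the same tree,
#' positivizes on the x-trait (flipping the paired y-contrast with it), and
#' fits a through-origin regression. Used for e.g. the correlation of rSSD
#' contrasts with male/female body size or genital metrics.
#'
#' @param tree A binary `phylo`.
#' @param trait_x,trait_y Named numeric vectors over the same tip set.
#' @param ... Passed to [rma()] (`ci_method`, `seed`, ...).
#' @return An `rma_fit` (through the origin) on the contrast pairs.
#' @export
contrast_correlation <- function(tree, trait_x, trait_y, ...) {
  nx <- names(trait_x); ny <- names(trait_y)
  if (!setequal(nx, ny))
    stop("tip sets differ: only in x: ",
         paste(setdiff(nx, ny), collapse = ", "),
         "; only in y: ", paste(setdiff(ny, nx), collapse = ", "))
  px <- pic_contrasts(tree, trait_x, trait = "x")
  py <- pic_contrasts(tree, trait_y, trait = "y")
  pp <- positivize_contrasts(px$contrasts$contrast, py$contrasts$contrast)
  rma(pp$x, pp$y, through_origin = TRUE, ...)
}

#' Blomberg's K phylogenetic signal
#'
#' K compares the fit of the tip data to the tree against the fit expected
#' under Brownian motion: K = (MSE0/MSE)_observed divided by
#' (MSE0/MSE)_expected, where MSE0 is the mean squared deviation of tips
#' from the phylogenetic (GLS) mean, MSE the GLS mean squared error under
#' the tree covariance V, and the BM expectation is
#' (tr(V) - n/sum(V^-1)) / (n - 1). K = 1 matches BM; K < 1 indicates less
#' phylogenetic signal than BM (labile or convergent evolution), K > 1
#' more. Significance is a one-sided permutation test: tip values are
#' shuffled across the tree and signal is measured by the variance of the
#' independent contrasts (smaller = more signal), as in the original
#' method.
#'
#' @param tree A binary `phylo` with positive root-to-tip depths.
#' @param tip_values Named numeric vector, n >= 4.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation stream.
#' @return Object of class `k_result`: `K`, `p`, `n_perm`, `seed`, `n`,
#'   `pic_variance_observed`.
#' @export
blomberg_k <- function(tree, tip_values, n_perm = 999L, seed = 1L) {
  validate_tree(tree, require_binary = TRUE)
  n <- length(tree$tip.label)
  if (n < 4L) stop("need at least 4 tips")
  x <- match_tip_values(tree, tip_values)
  if (stats::sd(x) == 0) stop("constant tip data: K is undefined")

  V <- ape::vcv(tree)
  x <- x[rownames(V)]
  Vi <- solve(V)
  one <- rep(1, n)
  a0 <- sum(Vi %*% x) / sum(Vi)
  dev <- x - a0
  mse0 <- sum(dev^2) / (n - 1)
  mse <- drop(t(dev) %*% Vi %*% dev) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  K <- (mse0 / mse) / expected

  pic_var <- function(v) {
    names(v) <- names(x)
    stats::var(suppressMessages(pic_contrasts(tree, v))$contrasts$contrast)
  }
  obs <- pic_var(x)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pic_var(sample(unname(x))) <= obs
    }, logical(1)))
  })
  p <- (hits + 1) / (n_perm + 1)

  structure(list(K = K, p = p, n_perm = as.integer(n_perm),
                 seed = seed, n = n, pic_variance_observed = obs),
            class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4g (n = %d), permutation p = %.4g (%d perms)\n",
              x$K, x$n, x$p, x$n_perm))
  invisible(x)
}
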