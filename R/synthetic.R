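#' Simulate a Yule (pure-birth) tree
#'
#' Binary ultrametric phylogeny with a fixed number of tips under a
#' pure-birth process, branch lengths in My. Delegates to [ape::rphylo()]
#' (death rate 0) under a locally scoped seed, so results are reproducible
#' and the caller's RNG stream is untouched.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate, events/My (> 0).
#' @param seed Integer seed.
#' @return A binary ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 0.11, seed = 1L) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate,
                                      death = 0))
  validate_tree(tree)
  tree
}

#' Simulate correlated bivariate Brownian evolution of male and female size
#'
#' Evolves (male, female) body length jointly along the tree: on a branch
#' of duration t the increment is bivariate normal with covariance
#' \deqn{[[\sigma_m^2 t, \rho \sigma_m \sigma_f t],
#'        [\rho \sigma_m \sigma_f t, \sigma_f^2 t]].}
#' Unequal sex-specific rates with high cross-sex correlation are the
#' generating regime of Rensch's rule: a male/female rate ratio of ~1.4
#' with rho = 0.9 reproduces an allometric contrast slope of ~1.4. All node
#' values (ancestors included) are returned as ground truth for testing
#' reconstruction and branch-change metrics.
#'
#' Defaults emulate a *Limnebius*-like regime: rates in mm/sqrt(My) giving
#' a rate ratio 1.44, strong genetic correlation between the sexes, and
#' root sizes of 1.50/1.45 mm. On the linear mm scale a BM walk can in
#' principle wander non-positive when rate^2 x depth is large relative to
#' the root value; the returned table is not positivity-checked, and
#' log- or ratio-based downstream analyses flag such values instead.
#'
#' @param tree A `phylo` with branch lengths in My.
#' @param sigma_male,sigma_female BM rates, trait units per sqrt(My).
#' @param rho Cross-sex correlation in [-1, 1].
#' @param root_male,root_female Root values (mm).
#' @param seed Integer seed.
#' @return list of class `bm_bivariate_sim`: `tips` (a [trait_table()] of
#'   species, male_length, female_length with derived SSD/rSSD),
#'   `node_values` (matrix (n+Nnode) x 2, ape node order, ground truth),
#'   `tree`, `config`.
#' @export
simulate_bm_bivariate <- function(tree,
                                  sigma_male = 0.0504,
                                  sigma_female = 0.035,
                                  rho = 0.9,
                                  root_male = 1.50,
                                  root_female = 1.45,
                                  seed = 1L) {
  validate_tree(tree)
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (sigma_male < 0 || sigma_female < 0) stop("rates must be >= 0")
  n <- length(tree$tip.label)
  m <- n + tree$Nnode
  S <- matrix(c(sigma_male^2, rho * sigma_male * sigma_female,
                rho * sigma_male * sigma_female, sigma_female^2), 2L, 2L)
  # chol of a possibly singular 2x2 (|rho| = 1 or a zero rate)
  C <- tryCatch(chol(S), error = function(e) {
    ev <- eigen(S, symmetric = TRUE)
    t(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2L))
  })
  root <- n + 1L
  vals <- matrix(NA_real_, m, 2L,
                 dimnames = list(NULL, c("male", "female")))
  vals[root, ] <- c(root_male, root_female)
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge; L <- po$edge.length
  vals <- with_seed(seed, {
    for (i in rev(seq_len(nrow(E)))) {   # preorder
      z <- stats::rnorm(2L)
      vals[E[i, 2L], ] <- vals[E[i, 1L], ] + sqrt(L[i]) * drop(t(C) %*% z)
    }
    vals
  })
  tips <- data.frame(species = tree$tip.label,
                     male_length = vals[seq_len(n), 1L],
                     female_length = vals[seq_len(n), 2L],
                     stringsAsFactors = FALSE)
  tips$ssd <- tips$male_length - tips$female_length
  tips$rssd <- tips$male_length / tips$female_length
  class(tips) <- c("trait_table", "data.frame")
  structure(list(
    tips = tips,
    node_values = vals,
    tree = tree,
    config = list(sigma_male = sigma_male, sigma_female = sigma_female,
                  rho = rho, root_male = root_male,
                  root_female = root_female, seed = seed)
  ), class = "bm_bivariate_sim")
}

#' Simulate a binary character history on a tree
#'
#' Two-state Markov evolution of a presence/absence character (e.g. a male
#' secondary sexual character): on each branch, waiting times to the next
#' event are exponential with the gain rate (state 0) or loss rate
#' (state 1). The true per-branch event list is retained as ground truth
#' for parsimony reconstruction. The root starts in state 0 (character
#' absent), the natural prior for a derived SSC.
#'
#' @param tree A `phylo`.
#' @param gain_rate,loss_rate Events/My (>= 0).
#' @param seed Integer seed.
#' @param root_state Root state (default 0).
#' @return list of class `binary_char_sim`: `tip_states` (named 0/1),
#'   `node_states` (per ape node id), `events` (data frame `parent`,
#'   `child`, `type` in gain/loss), `n_events`, `tree`, `config`.
#' @export
simulate_binary_character <- function(tree, gain_rate = 0.02,
                                      loss_rate = 0.01, seed = 1L,
                                      root_state = 0L) {
  validate_tree(tree)
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (!root_state %in% c(0L, 1L)) stop("root_state must be 0 or 1")
  n <- length(tree$tip.label)
  m <- n + tree$Nnode
  root <- n + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge; L <- po$edge.length
  states <- integer(m); states[root] <- root_state
  ev_parent <- integer(0); ev_child <- integer(0); ev_type <- character(0)
  res <- with_seed(seed, {
    for (i in rev(seq_len(nrow(E)))) {  # preorder
      s <- states[E[i, 1L]]
      t_left <- L[i]
      repeat {
        rate <- if (s == 0L) gain_rate else loss_rate
        if (rate <= 0) break
        w <- stats::rexp(1L, rate)
        if (w >= t_left) break
        t_left <- t_left - w
        ev_parent <- c(ev_parent, E[i, 1L])
        ev_child <- c(ev_child, E[i, 2L])
        ev_type <- c(ev_type, if (s == 0L) "gain" else "loss")
        s <- 1L - s
      }
      states[E[i, 2L]] <- s
    }
    list(states = states,
         events = data.frame(parent = ev_parent, child = ev_child,
                             type = ev_type, stringsAsFactors = FALSE))
  })
  structure(list(
    tip_states = stats::setNames(res$states[seq_len(n)], tree$tip.label),
    node_states = res$states,
    events = res$events,
    n_events = nrow(res$events),
    tree = tree,
    config = list(gain_rate = gain_rate, loss_rate = loss_rate,
                  seed = seed, root_state = root_state)
  ), class = "binary_char_sim")
}

#' Generate a raster phantom of known fractal dimension
#'
#' Calibration shapes for the box-counting estimator: a 1-px straight line
#' (dimension 1), a filled square (2), a circle outline (1), and the Koch
#' curve (log 4 / log 3 ~ 1.2619).
#'
#' @param shape One of `"line"`, `"filled_square"`, `"koch"`,
#'   `"circle_outline"`.
#' @param canvas Canvas side in pixels (>= 256).
#' @param iterations Koch iterations (default 6).
#' @return An `outline_image` (logical matrix `canvas` x `canvas`).
#' @export
generate_phantom <- function(shape = c("line", "filled_square", "koch",
                                       "circle_outline"),
                             canvas = 1024L, iterations = 6L) {
  shape <- match.arg(shape)
  canvas <- as.integer(canvas)
  if (canvas < 256L) stop("canvas must be >= 256 px")
  img <- matrix(FALSE, canvas, canvas)
  pad <- max(2L, canvas %/% 32L)
  lo <- pad; hi <- canvas - pad
  if (shape == "line") {
    img[canvas %/% 2L, lo:hi] <- TRUE
  } else if (shape == "filled_square") {
    img[lo:hi, lo:hi] <- TRUE
  } else if (shape == "circle_outline") {
    r <- (hi - lo) / 2
    cx <- canvas / 2
    th <- seq(0, 2 * pi, length.out = ceiling(8 * pi * r))
    px <- pmin(canvas, pmax(1, round(cx + r * cos(th))))
    py <- pmin(canvas, pmax(1, round(cx + r * sin(th))))
    img[cbind(px, py)] <- TRUE
  } else { # koch curve from (0,0) to (1,0), apex height sqrt(3)/6
    pts <- koch_points(iterations)
    w <- hi - lo
    px <- lo + pts[, 1L] * w
    py <- canvas %/% 2L + (pts[, 2L] - sqrt(3) / 12) * w
    img <- rasterize_polyline(img, px, py)
  }
  as_outline_image(img)
}

# Koch curve vertex list after k iterations; 4^k segments.
koch_points <- function(k) {
  pts <- matrix(c(0, 0, 1, 0), ncol = 2L, byrow = TRUE)
  rot60 <- matrix(c(cos(pi / 3), sin(pi / 3),
                    -sin(pi / 3), cos(pi / 3)), 2L, 2L)
  for (i in seq_len(k)) {
    a <- pts[-nrow(pts), , drop = FALSE]
    b <- pts[-1L, , drop = FALSE]
    d <- (b - a) / 3
    p1 <- a + d
    p3 <- a + 2 * d
    p2 <- p1 + t(rot60 %*% t(d))
    new <- matrix(NA_real_, 4L * nrow(a) + 1L, 2L)
    new[seq(1L, by = 4L, length.out = nrow(a)), ] <- a
    new[seq(2L, by = 4L, length.out = nrow(a)), ] <- p1
    new[seq(3L, by = 4L, length.out = nrow(a)), ] <- p2
    new[seq(4L, by = 4L, length.out = nrow(a)), ] <- p3
    new[nrow(new), ] <- pts[nrow(pts), ]
    pts <- new
  }
  pts
}

# Set pixels along each polyline segment, sampling ~2 points per pixel.
rasterize_polyline <- function(img, px, py) {
  nseg <- length(px) - 1L
  for (i in seq_len(nseg)) {
    len <- sqrt((px[i + 1L] - px[i])^2 + (py[i + 1L] - py[i])^2)
    k <- max(2L, ceiling(2 * len))
    t <- seq(0, 1, length.out = k)
    xs <- pmin(ncol(img), pmax(1, round(px[i] + t * (px[i + 1L] - px[i]))))
    ys <- pmin(nrow(img), pmax(1, round(py[i] + t * (py[i + 1L] - py[i]))))
    img[cbind(ys, xs)] <- TRUE
  }
  img
}

#' A packaged Limnebius-like synthetic dataset
#'
#' One-call generator for the study-scale fixture: a 71-tip Yule tree,
#' correlated bivariate BM body sizes (rate ratio 1.44, rho 0.9, roots
#' 1.50/1.45 mm), one binary SSC history, and per-species genital metrics
#' (aedeagus length from univariate BM; perimeter and fractal dimension
#' with rSSD-linked variation). All ground truth is retained.
#'
#' @param seed Master seed; sub-seeds for each generator are derived from
#'   it.
#' @param n_tips Number of species (default 71).
#' @return list: `tree`, `traits` (trait table incl. genital columns),
#'   `bm` (the [simulate_bm_bivariate()] object), `ssc` (the
#'   [simulate_binary_character()] object).
#' @export
limnebius_like_dataset <- function(seed = 42L, n_tips = 71L) {
  seeds <- derive_seeds(seed, c("tree", "bm", "ssc", "genital"))
  tree <- simulate_yule_tree(n_tips, birth_rate = 0.11,
                             seed = seeds[["tree"]])
  bm <- simulate_bm_bivariate(tree, seed = seeds[["bm"]])
  ssc <- simulate_binary_character(tree, seed = seeds[["ssc"]])
  traits <- bm$tips
  gen <- with_seed(seeds[["genital"]], {
    # aedeagus length: univariate BM, root 0.45 mm, floored at 0.05 mm
    g <- simulate_bm_bivariate(tree, sigma_male = 0.02,
                               sigma_female = 0.02, rho = 1,
                               root_male = 0.45, root_female = 0.45,
                               seed = sample.int(2^30, 1L))
    len <- pmax(0.05, g$tips$male_length)
    complexity <- pmax(2.2, stats::rnorm(nrow(traits), 3, 0.35) +
                         1.5 * (traits$rssd - 1))
    fd <- pmin(1.95, pmax(1.02, 1.15 + 0.6 * (traits$rssd - 1) +
                            stats::rnorm(nrow(traits), 0, 0.05)))
    list(len = len, per = len * complexity, fd = fd)
  })
  traits$aedeagus_length <- gen$len
  traits$aedeagus_perimeter <- gen$per
  traits$perimeter_complexity <- perimeter_complexity(gen$per, gen$len)
  traits$fractal_dimension <- gen$fd
  list(tree = tree, traits = traits, bm = bm, ssc = ssc)
}

# Named, independent sub-seeds derived from one master seed (kept < 2^31).
derive_seeds <- function(seed, names) {
  with_seed(seed, stats::setNames(sample.int(2^30, length(names)), names))
}
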