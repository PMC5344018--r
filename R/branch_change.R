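#' Ancestor-descendant change per branch
#'
#' For every branch of the tree (terminals included) computes, from
#' reconstructed node values: the arithmetic change (final - initial), its
#' absolute value, and the rate in darwins,
#' \eqn{|\ln(\mathrm{final}/\mathrm{initial})| / t} with t the branch
#' duration in My. The natural-log ratio makes the rate proportional and
#' comparable across species of different sizes; 1 darwin is a change by a
#' factor e over one million years.
#'
#' darwins are defined only for strictly positive initial and final values
#' and positive durations; other branches get `NA` with
#' `darwins_defined = FALSE` (they are flagged, never silently zeroed).
#'
#' @param tree A `phylo`.
#' @param node_values Either an `asr_bm` object on the same tree or a
#'   numeric vector of values indexed by ape node id (length
#'   n.tips + n.nodes).
#' @param trait Optional trait name.
#' @return data frame of class `branch_changes`: `parent`, `child`,
#'   `child_label`, `duration`, `initial`, `final`, `change`, `abs_change`,
#'   `darwins`, `darwins_defined`, `trait`.
#' @export
branch_changes <- function(tree, node_values, trait = NULL) {
  validate_tree(tree)
  m <- length(tree$tip.label) + tree$Nnode
  if (inherits(node_values, "asr_bm")) {
    if (is.null(trait)) trait <- node_values$trait
    node_values <- node_values$estimate
  }
  if (is.null(trait)) trait <- "trait"
  vals <- unname(as.numeric(node_values))
  if (length(vals) != m)
    stop("node_values must cover all ", m, " nodes, got ", length(vals))
  if (anyNA(vals))
    stop("missing node value at node(s): ",
         paste(which(is.na(vals)), collapse = ", "))
  br <- branches(tree)
  ini <- vals[br$parent]
  fin <- vals[br$child]
  ok <- ini > 0 & fin > 0 & br$duration > 0
  dar <- rep(NA_real_, nrow(br))
  dar[ok] <- abs(log(fin[ok] / ini[ok])) / br$duration[ok]
  out <- data.frame(
    br,
    initial = ini,
    final = fin,
    change = fin - ini,
    abs_change = abs(fin - ini),
    darwins = dar,
    darwins_defined = ok,
    trait = trait,
    stringsAsFactors = FALSE
  )
  class(out) <- c("branch_changes", "data.frame")
  out
}

#' Qualitative coding of per-branch change
#'
#' Codes each branch `+`, `-` or `=` for male size, female size and SSD
#' (SSD = male - female, in mm). Male/female changes smaller than
#' `size_threshold` (default 5%) of the branch's initial value are treated
#' as within experimental error and coded `=`; SSD changes smaller than
#' `ssd_threshold_fraction` (default 5%) of the total range of observed SSD
#' values are coded `=`. In `mode = "all_changes"` every branch is coded
#' `+`/`-` by the raw sign, with zero change coded `=` (it carries no
#' sign).
#'
#' @param records_male,records_female [branch_changes()] frames on the same
#'   branches (male and female body length).
#' @param ssd_range Total range (max - min, mm) of observed SSD used for
#'   the SSD threshold; by default computed from the records' node values
#'   over all nodes (tips + ancestors). Pass a tips-only range to restrict.
#' @param size_threshold Fraction of initial size below which sex-specific
#'   change is `=` (default 0.05).
#' @param ssd_threshold_fraction Fraction of `ssd_range` below which SSD
#'   change is `=` (default 0.05).
#' @param mode `"over_5pct"` applies the thresholds; `"all_changes"` codes
#'   every branch by raw sign.
#' @return data frame of class `branch_codes`: `parent`, `child`,
#'   `duration`, `code_male`, `code_female`, `code_ssd`, plus threshold
#'   attributes `size_threshold`, `ssd_threshold`, `ssd_range`, `mode`.
#' @export
code_branches <- function(records_male, records_female,
                          ssd_range = NULL,
                          size_threshold = 0.05,
                          ssd_threshold_fraction = 0.05,
                          mode = c("over_5pct", "all_changes")) {
  mode <- match.arg(mode)
  align_branch_records(records_male, records_female)
  if (!(size_threshold > 0 && size_threshold < 1) ||
      !(ssd_threshold_fraction > 0 && ssd_threshold_fraction < 1))
    stop("thresholds must lie in (0, 1)")

  ssd_ini <- records_male$initial - records_female$initial
  ssd_fin <- records_male$final - records_female$final
  d_ssd <- ssd_fin - ssd_ini
  if (is.null(ssd_range)) {
    all_ssd <- c(ssd_ini, ssd_fin)
    ssd_range <- max(all_ssd) - min(all_ssd)
  }
  if (ssd_range <= 0) stop("ssd_range must be > 0")

  code_sex <- function(rec) {
    raw <- ifelse(rec$change > 0, "+", ifelse(rec$change < 0, "-", "="))
    if (mode == "all_changes") return(raw)
    rel <- abs(rec$change) / abs(rec$initial)
    ifelse(rel < size_threshold, "=", raw)
  }
  raw_ssd <- ifelse(d_ssd > 0, "+", ifelse(d_ssd < 0, "-", "="))
  code_ssd <- if (mode == "all_changes") raw_ssd else
    ifelse(abs(d_ssd) < ssd_threshold_fraction * ssd_range, "=", raw_ssd)

  out <- data.frame(
    parent = records_male$parent,
    child = records_male$child,
    duration = records_male$duration,
    code_male = code_sex(records_male),
    code_female = code_sex(records_female),
    code_ssd = code_ssd,
    stringsAsFactors = FALSE
  )
  attr(out, "size_threshold") <- size_threshold
  attr(out, "ssd_threshold") <- ssd_threshold_fraction * ssd_range
  attr(out, "ssd_range") <- ssd_range
  attr(out, "mode") <- mode
  class(out) <- c("branch_codes", "data.frame")
  out
}

align_branch_records <- function(a, b) {
  if (!inherits(a, "data.frame") || !inherits(b, "data.frame"))
    stop("records must be branch_changes data frames")
  if (nrow(a) != nrow(b) ||
      any(a$parent != b$parent) || any(a$child != b$child))
    stop("male and female records are not aligned on the same branches")
  invisible(TRUE)
}

#' Cross-tabulation of branch codes
#'
#' Counts branches per (female code, male code, SSD code) combination,
#' the per-branch summary of which sexes drive SSD change across the
#' phylogeny.
#'
#' @param codes A [code_branches()] frame.
#' @return data frame of class `change_summary` with columns `code_female`
#'   (`lf`), `code_male` (`lm`), `code_ssd`, `count`; attribute `total` =
#'   number of branches. Only observed combinations are listed.
#' @export
crosstab <- function(codes) {
  stopifnot(inherits(codes, "branch_codes"))
  tab <- as.data.frame(
    table(code_female = codes$code_female,
          code_male = codes$code_male,
          code_ssd = codes$code_ssd),
    stringsAsFactors = FALSE
  )
  names(tab)[4L] <- "count"
  tab <- tab[tab$count > 0, , drop = FALSE]
  tab <- tab[order(tab$code_ssd, tab$code_female, tab$code_male), ]
  rownames(tab) <- NULL
  attr(tab, "total") <- nrow(codes)
  attr(tab, "mode") <- attr(codes, "mode")
  class(tab) <- c("change_summary", "data.frame")
  tab
}

#' Count branches where SSD change is driven by one sex only
#'
#' From a `>5%` coded table: branches where SSD changed (`+` or `-`) while
#' exactly one sex changed (the other coded `=`).
#'
#' @param codes A [code_branches()] frame in `over_5pct` mode.
#' @return list with `n_male_only` and `n_female_only`.
#' @export
single_sex_ssd_changes <- function(codes) {
  stopifnot(inherits(codes, "branch_codes"))
  ssd_moved <- codes$code_ssd != "="
  list(
    n_male_only = sum(ssd_moved & codes$code_male != "=" &
                        codes$code_female == "="),
    n_female_only = sum(ssd_moved & codes$code_female != "=" &
                          codes$code_male == "=")
  )
}

#' Exact binomial sign test for single-sex SSD changes
#'
#' Tests whether SSD changes driven by one sex only are equally likely to
#' be male- or female-driven: exact two-sided binomial p-value for H0:
#' p = 0.5 on (`n_male_only`, `n_female_only`).
#'
#' @param n_male_only,n_female_only Non-negative counts, sum >= 1.
#' @return The exact two-sided p-value.
#' @export
sign_binomial_test <- function(n_male_only, n_female_only) {
  if (n_male_only < 0 || n_female_only < 0 ||
      n_male_only != round(n_male_only) ||
      n_female_only != round(n_female_only))
    stop("counts must be non-negative integers")
  tot <- n_male_only + n_female_only
  if (tot < 1) stop("both counts are zero")
  stats::binom.test(n_male_only, tot, p = 0.5)$p.value
}

#' Regress male-female rate differences on each sex's change
#'
#' OLS fits of (male metric - female metric) on the male metric and,
#' separately, on the female metric, over all aligned branches. Used with
#' the darwins rate or the absolute phenotypic change. Under Rensch's rule
#' (males more labile) the male fit has the larger slope and R^2. Branches
#' with undefined darwins are dropped with a reported count.
#'
#' @param records_male,records_female Aligned [branch_changes()] frames.
#' @param metric `"darwins"` or `"absolute"` (absolute phenotypic change).
#' @return list of class `rate_diff_fit`: elements `male` and `female`,
#'   each with `slope`, `intercept`, `r2`, `p`, `n`; plus `metric`,
#'   `n_dropped`.
#' @export
rate_difference_regression <- function(records_male, records_female,
                                       metric = c("darwins", "absolute")) {
  metric <- match.arg(metric)
  align_branch_records(records_male, records_female)
  if (metric == "darwins") {
    ok <- records_male$darwins_defined & records_female$darwins_defined
    mm <- records_male$darwins[ok]
    ff <- records_female$darwins[ok]
  } else {
    ok <- rep(TRUE, nrow(records_male))
    mm <- records_male$abs_change
    ff <- records_female$abs_change
  }
  n_drop <- sum(!ok)
  if (length(mm) < 3L)
    stop("fewer than 3 usable branches (", n_drop, " dropped)")
  d <- mm - ff
  fit1 <- function(y, x) {
    if (stats::sd(x) == 0)
      return(list(slope = NA_real_, intercept = mean(y), r2 = NA_real_,
                  p = NA_real_, n = length(y)))
    f <- stats::lm(y ~ x)
    s <- summary(f)
    list(slope = unname(stats::coef(f)[2L]),
         intercept = unname(stats::coef(f)[1L]),
         r2 = s$r.squared,
         p = unname(s$coefficients[2L, 4L]),
         n = length(y))
  }
  structure(list(male = fit1(d, mm), female = fit1(d, ff),
                 metric = metric, n_dropped = n_drop),
            class = "rate_diff_fit")
}

#' @export
print.rate_diff_fit <- function(x, ...) {
  cat("Regression of (male - female) ", x$metric,
      " on each sex's change (", x$male$n, " branches",
      if (x$n_dropped) paste0(", ", x$n_dropped, " dropped"), ")\n",
      sep = "")
  for (sex in c("male", "female"))
    cat(sprintf("  vs %-6s slope %+.4g, R^2 %.3f, p %.3g\n",
                sex, x[[sex]]$slope, x[[sex]]$r2, x[[sex]]$p))
  invisible(x)
}
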