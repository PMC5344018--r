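#' Run the full SSD / Rensch's rule analysis
#'
#' End-to-end orchestration over a time-calibrated tree and a species trait
#' table, producing the standard result surface:
#' \itemize{
#'   \item `allometry` — RMA regressions of male on female log10 body size,
#'     per taxon group, both on positivized independent contrasts (through
#'     the origin) and on raw species data; isometry test per row.
#'   \item `rssd_size_correlation` — through-origin contrast correlations
#'     (R^2, p) of rSSD with male and female length per group.
#'   \item `rssd_genital_correlation` — the same against aedeagus length,
#'     perimeter complexity and fractal dimension, when present.
#'   \item `phylogenetic_signal` — Blomberg's K with permutation p for
#'     rSSD, male and female length.
#'   \item `branch_changes_male` / `_female`, `branch_codes`,
#'     `change_crosstab` (both "all changes" and ">5%" modes),
#'     `single_sex` counts with the exact binomial sign test.
#'   \item `rate_difference` — OLS fits of (male - female) rate difference
#'     on each sex, in darwins and absolute change.
#'   \item `ssc_parsimony` — Fitch reconstruction per binary SSC, when
#'     supplied.
#' }
#'
#' Polytomies are resolved reproducibly; species missing from tree or
#' table are pruned with a warning. All randomized steps (polytomy
#' resolution, bootstrap, permutations) draw independent named sub-seeds
#' from `seed`, recorded in the result, so a rerun with the same inputs is
#' identical.
#'
#' @param tree A `phylo` (branch lengths in My).
#' @param traits A [trait_table()].
#' @param ssc_states Optional: named 0/1 vector, or data frame with a
#'   `species` column and one 0/1 column per character.
#' @param groups Optional named list of species subsets (e.g. subgenera);
#'   the whole tree is always analysed as group `"all"`.
#' @param size_threshold,ssd_threshold_fraction Coding thresholds
#'   (defaults 0.05, see [code_branches()]).
#' @param n_boot Bootstrap replicates for RMA intervals (default 1999).
#' @param n_perm Permutations for K (default 999).
#' @param seed Master seed.
#' @return list of class `renschkit_report`; see Details.
#' @export
run_full_analysis <- function(tree, traits, ssc_states = NULL,
                              groups = NULL,
                              size_threshold = 0.05,
                              ssd_threshold_fraction = 0.05,
                              n_boot = 1999L, n_perm = 999L,
                              seed = 1L) {
  validate_tree(tree)
  if (!inherits(traits, "data.frame") ||
      !all(c("species", "male_length", "female_length") %in% names(traits)))
    stop("traits must be a trait_table (species, male_length, female_length)")
  seeds <- derive_seeds(seed, c("polytomy", "boot", "perm"))

  common <- intersect(tree$tip.label, traits$species)
  if (length(common) == 0L) stop("no species shared by tree and trait table")
  drop_tree <- setdiff(tree$tip.label, common)
  drop_tab <- setdiff(traits$species, common)
  if (length(drop_tree))
    warning("pruning ", length(drop_tree), " tip(s) absent from trait table")
  if (length(drop_tab))
    warning("dropping ", length(drop_tab),
            " trait row(s) absent from tree")
  if (length(drop_tree)) tree <- ape::keep.tip(tree, common)
  traits <- traits[match(tree$tip.label, traits$species), , drop = FALSE]
  tree <- resolve_polytomies(tree, seed = seeds[["polytomy"]])

  groups <- c(list(all = tree$tip.label), groups)
  tv <- function(col, sp = tree$tip.label) {
    stats::setNames(traits[[col]][match(sp, traits$species)], sp)
  }

  # --- allometry (Table-1 style): per group, contrasts + raw -------------
  allom <- list()
  rssd_size <- list()
  for (g in names(groups)) {
    sp <- intersect(groups[[g]], tree$tip.label)
    row <- allometry_rows(tree, sp, tv, g, n_boot, seeds[["boot"]])
    allom[[g]] <- row$allom
    rssd_size[[g]] <- row$rssd_size
  }
  allometry <- do.call(rbind, allom)
  rssd_size_correlation <- do.call(rbind, rssd_size)
  rownames(allometry) <- rownames(rssd_size_correlation) <- NULL

  # --- rSSD vs genital metrics (Table-3 style) ---------------------------
  gen_cols <- intersect(c("aedeagus_length", "perimeter_complexity",
                          "fractal_dimension"), names(traits))
  rssd_genital <- NULL
  if (length(gen_cols)) {
    rssd_genital <- do.call(rbind, lapply(gen_cols, function(col) {
      fit <- tryCatch(
        suppressMessages(contrast_correlation(
          tree, tv(col), tv("rssd"),
          n_boot = n_boot, seed = seeds[["boot"]])),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      data.frame(metric = col, n = fit$n, r2 = fit$r2, p = fit$p,
                 stringsAsFactors = FALSE)
    }))
  }

  # --- phylogenetic signal ----------------------------------------------
  signal <- do.call(rbind, lapply(
    c(rssd = "rssd", male = "male_length", female = "female_length"),
    function(col) {
      k <- blomberg_k(tree, tv(col), n_perm = n_perm,
                      seed = seeds[["perm"]])
      data.frame(trait = col, K = k$K, p = k$p, n = k$n,
                 stringsAsFactors = FALSE)
    }))
  rownames(signal) <- NULL

  # --- ancestral reconstruction + branch changes -------------------------
  asr_male <- asr_bm(tree, tv("male_length"), trait = "male_length")
  asr_female <- asr_bm(tree, tv("female_length"), trait = "female_length")
  rec_m <- branch_changes(tree, asr_male)
  rec_f <- branch_changes(tree, asr_female)
  codes_5 <- code_branches(rec_m, rec_f,
                           size_threshold = size_threshold,
                           ssd_threshold_fraction = ssd_threshold_fraction,
                           mode = "over_5pct")
  codes_all <- code_branches(rec_m, rec_f, mode = "all_changes")
  singles <- single_sex_ssd_changes(codes_5)
  sign_p <- if (singles$n_male_only + singles$n_female_only >= 1)
    sign_binomial_test(singles$n_male_only, singles$n_female_only)
  else NA_real_

  rate_diff <- list(
    darwins = rate_difference_regression(rec_m, rec_f, "darwins"),
    absolute = rate_difference_regression(rec_m, rec_f, "absolute"))

  # --- SSC parsimony -----------------------------------------------------
  ssc <- NULL
  if (!is.null(ssc_states)) {
    chars <- if (is.data.frame(ssc_states)) {
      cols <- setdiff(names(ssc_states), "species")
      stats::setNames(lapply(cols, function(cl) {
        stats::setNames(ssc_states[[cl]], ssc_states$species)
      }), cols)
    } else list(ssc = ssc_states)
    ssc <- lapply(names(chars), function(nm) {
      asr_parsimony(tree, chars[[nm]][tree$tip.label], character_name = nm)
    })
    names(ssc) <- names(chars)
  }

  structure(list(
    tree = tree,
    traits = traits,
    allometry = allometry,
    rssd_size_correlation = rssd_size_correlation,
    rssd_genital_correlation = rssd_genital,
    phylogenetic_signal = signal,
    asr_male = asr_male,
    asr_female = asr_female,
    branch_changes_male = rec_m,
    branch_changes_female = rec_f,
    branch_codes = list(over_5pct = codes_5, all_changes = codes_all),
    change_crosstab = list(over_5pct = crosstab(codes_5),
                           all_changes = crosstab(codes_all)),
    single_sex = c(singles, list(sign_test_p = sign_p)),
    rate_difference = rate_diff,
    ssc_parsimony = ssc,
    seeds = seeds,
    config = list(size_threshold = size_threshold,
                  ssd_threshold_fraction = ssd_threshold_fraction,
                  n_boot = n_boot, n_perm = n_perm, seed = seed)
  ), class = "renschkit_report")
}

# One group's allometry (contrasts + raw) and rSSD-size correlation rows.
allometry_rows <- function(tree, sp, tv, g, n_boot, boot_seed) {
  sub <- if (length(sp) < length(tree$tip.label))
    ape::keep.tip(tree, sp) else tree
  lm10 <- log10(tv("male_length", sp))
  lf10 <- log10(tv("female_length", sp))
  arow <- function(data_type, fit) {
    if (is.null(fit))
      return(data.frame(group = g, data = data_type, n = length(sp),
                        slope = NA, ci_low = NA, ci_high = NA, r2 = NA,
                        p = NA, isometry_rejected = NA))
    data.frame(group = g, data = data_type, n = fit$n, slope = fit$slope,
               ci_low = fit$ci_low, ci_high = fit$ci_high, r2 = fit$r2,
               p = fit$p, isometry_rejected = fit$isometry_rejected,
               stringsAsFactors = FALSE)
  }
  safe <- function(expr) tryCatch(suppressMessages(expr),
                                  error = function(e) NULL)
  fit_c <- safe({
    cf <- pic_contrasts(sub, lf10)$contrasts$contrast
    cm <- pic_contrasts(sub, lm10)$contrasts$contrast
    pp <- positivize_contrasts(cf, cm)
    rma(pp$x, pp$y, through_origin = TRUE, n_boot = n_boot,
        seed = boot_seed)
  })
  fit_r <- safe(rma(lf10, lm10, n_boot = n_boot, seed = boot_seed))
  allom <- rbind(arow("contrasts", fit_c), arow("raw", fit_r))

  crow <- function(sex, col) {
    fit <- safe(contrast_correlation(sub, tv(col, sp), tv("rssd", sp),
                                     n_boot = n_boot, seed = boot_seed))
    if (is.null(fit))
      return(data.frame(group = g, sex = sex, n = length(sp), r2 = NA,
                        p = NA))
    data.frame(group = g, sex = sex, n = fit$n, r2 = fit$r2, p = fit$p,
               stringsAsFactors = FALSE)
  }
  list(allom = allom,
       rssd_size = rbind(crow("male", "male_length"),
                         crow("female", "female_length")))
}

#' @export
print.renschkit_report <- function(x, ...) {
  cat("renschkit analysis report:", length(x$tree$tip.label),
      "species,", nrow(x$branch_changes_male), "branches\n\n")
  cat("Allometry (RMA, male ~ female log10 size):\n")
  print(x$allometry, digits = 3)
  cat("\nPhylogenetic signal (Blomberg's K):\n")
  print(x$phylogenetic_signal, digits = 3)
  cat("\nSingle-sex SSD changes: male-only =", x$single_sex$n_male_only,
      ", female-only =", x$single_sex$n_female_only,
      sprintf(", exact binomial p = %.4g\n", x$single_sex$sign_test_p))
  invisible(x)
}

#' Write a report bundle as delimited tables
#'
#' Flat CSV export of every tabular component plus the resolved tree
#' (Newick) and BM node estimates per sex.
#'
#' @param report A [run_full_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "renschkit_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(obj, name) {
    if (!is.null(obj))
      utils::write.csv(as.data.frame(obj),
                       file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  w(report$allometry, "allometry")
  w(report$rssd_size_correlation, "rssd_size_correlation")
  w(report$rssd_genital_correlation, "rssd_genital_correlation")
  w(report$phylogenetic_signal, "phylogenetic_signal")
  w(report$branch_changes_male, "branch_changes_male")
  w(report$branch_changes_female, "branch_changes_female")
  w(report$branch_codes$over_5pct, "branch_codes_over5pct")
  w(report$branch_codes$all_changes, "branch_codes_all")
  w(report$change_crosstab$over_5pct, "crosstab_over5pct")
  w(report$change_crosstab$all_changes, "crosstab_all")
  w(node_table(report$asr_male), "asr_male_nodes")
  w(node_table(report$asr_female), "asr_female_nodes")
  write_tree(report$tree, file.path(dir, "tree_resolved.nwk"))
  invisible(dir)
}
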