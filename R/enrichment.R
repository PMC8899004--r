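#' Carrier 2x2 table
#'
#' @param a case carriers, `b` case non-carriers, `c` control carriers,
#'   `d` control non-carriers (non-negative integers).
#' @param b,c,d see `a`.
#' @return object of class `two_by_two` (named integer vector a/b/c/d).
#' @export
two_by_two <- function(a, b, c, d) {
  x <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (any(x < 0) || any(x != round(x))) {
    stop("cell counts must be non-negative integers")
  }
  structure(as.integer(round(x)), names = names(x), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("carrier", "non-carrier")))
  print(m)
  invisible(x)
}

#' Person-level carrier status
#'
#' A participant carries a variant set when they carry at least one
#' qualifying variant under the gene's inheritance rule: genotype >= 1 for
#' autosomal-dominant (or mixed) genes, genotype == 2 (homozygous alternate)
#' for strictly autosomal-recessive genes.
#'
#' @param genotypes `genotype_matrix`.
#' @param qualifying_ids variant_ids of the qualifying set.
#' @param annotations annotation data.frame (supplies gene per variant).
#' @param panel `panel_config` (supplies inheritance per gene).
#' @return named logical vector over participants (missing genotypes count
#'   as non-carrier).
#' @export
carrier_status <- function(genotypes, qualifying_ids, annotations, panel) {
  carrier <- stats::setNames(rep(FALSE, ncol(genotypes)), colnames(genotypes))
  miss <- setdiff(qualifying_ids, rownames(genotypes))
  if (length(miss) > 0L) {
    stop("qualifying variant(s) absent from genotype matrix: ",
         paste(miss, collapse = ", "))
  }
  for (vid in qualifying_ids) {
    gene <- annotations$gene_symbol[match(vid, annotations$variant_id)]
    inh <- panel$genes$inheritance[match(gene, panel$genes$symbol)]
    if (is.na(inh)) inh <- "AD"
    g <- genotypes[vid, ]
    hit <- if (inh == "AR") !is.na(g) & g == 2L else !is.na(g) & g >= 1L
    carrier <- carrier | hit
  }
  carrier
}

#' Carrier counts by case/control group
#'
#' Builds the carrier 2x2 table for one tier set (e.g. P/LP, or P/LP plus
#' VUS+). Each participant is counted once regardless of how many qualifying
#' variants they carry.
#'
#' @param genotypes `genotype_matrix`.
#' @param classifications data.frame from [classify_callset()].
#' @param case_map named character vector id -> "case"/"control".
#' @param annotations annotation data.frame.
#' @param panel `panel_config`.
#' @param tiers labels counted as qualifying, in report vocabulary
#'   (default `c("Pathogenic", "Likely pathogenic")`; add `"VUS+"` for the
#'   extended set).
#' @return a [two_by_two()]; attribute `carriers` lists carrier ids by group.
#' @export
carrier_counts <- function(genotypes, classifications, case_map, annotations,
                           panel,
                           tiers = c("Pathogenic", "Likely pathogenic")) {
  miss <- setdiff(names(case_map), colnames(genotypes))
  if (length(miss) > 0L) {
    stop("case_map id(s) not in genotype matrix: ",
         paste(miss, collapse = ", "))
  }
  qualifying <- classifications$variant_id[classifications$label %in% tiers]
  carrier <- carrier_status(genotypes, qualifying, annotations, panel)
  carrier <- carrier[names(case_map)]
  is_case <- case_map == "case"
  tab <- two_by_two(
    a = sum(carrier & is_case), b = sum(!carrier & is_case),
    c = sum(carrier & !is_case), d = sum(!carrier & !is_case)
  )
  attr(tab, "carriers") <- list(
    case = names(case_map)[carrier & is_case],
    control = names(case_map)[carrier & !is_case]
  )
  tab
}

.log_hyper <- function(x, n1, n2, k) {
  lchoose(n1, x) + lchoose(n2, k - x) - lchoose(n1 + n2, k)
}

#' Two-sided exact test on a 2x2 table
#'
#' Conditional on the margins, the carrier count among cases follows a
#' hypergeometric distribution. The two-sided p-value sums the probabilities
#' of all tables with the same margins whose point probability does not
#' exceed that of the observed table (minimum-likelihood convention, with a
#' 1e-7 relative tolerance on the comparison); probabilities are computed via
#' log-factorials for numerical stability. `method = "doubled"` instead
#' doubles the smaller one-sided tail (capped at 1).
#'
#' @param t a [two_by_two()].
#' @param method `"minlik"` (default) or `"doubled"`.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(t, method = c("minlik", "doubled")) {
  method <- match.arg(method)
  a <- t[["a"]]; b <- t[["b"]]; c <- t[["c"]]; d <- t[["d"]]
  n1 <- a + b; n2 <- c + d; k <- a + c
  if (n1 == 0L || n2 == 0L || k == 0L || b + d == 0L) {
    warning("degenerate margins; p = 1")
    return(1)
  }
  support <- max(0L, k - n2):min(k, n1)
  logp <- .log_hyper(support, n1, n2, k)
  log_obs <- .log_hyper(a, n1, n2, k)
  if (method == "minlik") {
    p <- sum(exp(logp[logp <= log_obs + log1p(1e-7)]))
  } else {
    lower <- sum(exp(logp[support <= a]))
    upper <- sum(exp(logp[support >= a]))
    p <- 2 * min(lower, upper)
  }
  min(p, 1)
}

#' Odds ratio of a 2x2 table
#'
#' @param t a [two_by_two()].
#' @param correction apply the Haldane–Anscombe 0.5 continuity correction to
#'   every cell (default FALSE).
#' @return (a d)/(b c); `Inf` when a zero in the denominator meets a positive
#'   numerator; `NaN` for 0/0.
#' @export
odds_ratio <- function(t, correction = FALSE) {
  x <- as.numeric(unclass(t))
  if (correction) x <- x + 0.5
  (x[1] * x[4]) / (x[2] * x[3])
}

#' Carrier-enrichment summary
#'
#' @param t a [two_by_two()].
#' @param method exact-test convention, see [fisher_exact_two_sided()].
#' @return list of class `enrichment_result`: prevalences (percent),
#'   odds ratio, two-sided p and method tag.
#' @export
enrichment_result <- function(t, method = "minlik") {
  prev_case <- 100 * t[["a"]] / (t[["a"]] + t[["b"]])
  prev_control <- 100 * t[["c"]] / (t[["c"]] + t[["d"]])
  structure(list(
    table = t,
    prevalence_case = prev_case,
    prevalence_control = prev_control,
    odds_ratio = odds_ratio(t),
    p_two_sided = fisher_exact_two_sided(t, method = method),
    method = paste0("exact_", method)
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "carriers %d/%d cases (%.1f%%) vs %d/%d controls (%.1f%%); OR %.3g; p = %.3g\n",
    x$table[["a"]], x$table[["a"]] + x$table[["b"]], x$prevalence_case,
    x$table[["c"]], x$table[["c"]] + x$table[["d"]], x$prevalence_control,
    x$odds_ratio, x$p_two_sided
  ))
  invisible(x)
}

#' Compare a variable between cases and controls
#'
#' Continuous variables: Welch two-sample t test with group mean (SD)
#' summaries. Categorical variables: chi-square test on the contingency
#' table with count (percent) summaries.
#'
#' @param participants phenotype data.frame.
#' @param case_map named vector id -> "case"/"control".
#' @param variable column name in `participants`.
#' @return list with `variable`, `type`, `statistic`, `p`, and `summary`
#'   (per-group formatted strings).
#' @export
compare_groups <- function(participants, case_map, variable) {
  if (!variable %in% names(participants)) {
    stop("unknown variable: ", variable)
  }
  grp <- unname(case_map[participants$id])
  x <- participants[[variable]]
  keep <- !is.na(x) & !is.na(grp)
  x <- x[keep]; grp <- grp[keep]
  if (min(table(grp)) < 2L) stop("fewer than 2 non-missing values per group")
  if (is.numeric(x)) {
    x1 <- x[grp == "case"]; x2 <- x[grp == "control"]
    if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
      # degenerate: no within-group variability; identical means are a
      # perfect null, different means a certain difference
      ht <- list(statistic = c(t = if (mean(x1) == mean(x2)) 0 else Inf),
                 p.value = if (mean(x1) == mean(x2)) 1 else 0)
    } else {
      ht <- stats::t.test(x1, x2, var.equal = FALSE)
    }
    summ <- vapply(c("case", "control"), function(g) {
      sprintf("%.1f (%.1f)", mean(x[grp == g]), stats::sd(x[grp == g]))
    }, character(1))
    list(variable = variable, type = "continuous",
         statistic = unname(ht$statistic), p = ht$p.value, summary = summ)
  } else {
    tab <- table(grp, x)
    ht <- stats::chisq.test(tab)
    summ <- vapply(c("case", "control"), function(g) {
      n <- tab[g, ]
      paste(sprintf("%s %d (%.1f%%)", colnames(tab), n, 100 * n / sum(n)),
            collapse = ", ")
    }, character(1))
    list(variable = variable, type = "categorical",
         statistic = unname(ht$statistic), p = ht$p.value, summary = summ)
  }
}

#' Welch t test from summary statistics
#'
#' Two-sided unequal-variance t test computed from group means, SDs and
#' sizes (Welch–Satterthwaite degrees of freedom); useful for checking
#' published group comparisons without raw data.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  tstat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Monte-Carlo power of the carrier-enrichment design
#'
#' Simulates case and control carrier counts as independent binomials,
#' applies the two-sided exact test to each simulated 2x2 table and reports
#' the rejection fraction at level `alpha` with its binomial Monte-Carlo
#' standard error. The exact test is memoized over the distinct simulated
#' tables, so large replicate counts are cheap.
#'
#' @param n_cases,n_controls group sizes.
#' @param p_case,p_control carrier probabilities (0 <= p_control <= p_case
#'   <= 1 for a power run; equality gives a null-calibration run).
#' @param alpha significance level (default 0.05).
#' @param n_reps number of simulated cohorts (>= 1000 for reported
#'   estimates; default 10000).
#' @param seed RNG seed.
#' @return list of class `power_estimate`: `power`, `se`, `n_reps`, spec.
#' @export
power_simulation <- function(n_cases, n_controls, p_case, p_control,
                             alpha = 0.05, n_reps = 10000, seed = 1) {
  stopifnot(p_case >= 0, p_case <= 1, p_control >= 0, p_control <= 1,
            n_reps >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  a <- stats::rbinom(n_reps, n_cases, p_case)
  c <- stats::rbinom(n_reps, n_controls, p_control)
  key <- paste(a, c)
  uniq <- !duplicated(key)
  pv <- vapply(which(uniq), function(i) {
    suppressWarnings(fisher_exact_two_sided(
      two_by_two(a[i], n_cases - a[i], c[i], n_controls - c[i])
    ))
  }, numeric(1))
  p_all <- pv[match(key, key[uniq])]
  power <- mean(p_all < alpha)
  structure(list(
    power = power,
    se = sqrt(power * (1 - power) / n_reps),
    n_reps = n_reps,
    spec = list(n_cases = n_cases, n_controls = n_controls, p_case = p_case,
                p_control = p_control, alpha = alpha, seed = seed)
  ), class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("power = %.3f (MC SE %.4f, %d reps)\n",
              x$power, x$se, x$n_reps))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
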