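#' D'Agostino-Pearson omnibus normality test
#'
#' Combines a skewness z-test (D'Agostino's transformation) and a kurtosis
#' z-test (Anscombe-Glynn transformation) into the omnibus statistic
#' `K2 = Z_skew^2 + Z_kurt^2`, referred to a chi-square distribution with 2
#' degrees of freedom.
#'
#' @param x Numeric sample, `n >= 8`.
#' @param alpha Significance level used for the `normal` verdict.
#' @return A list with `statistic` (K2), `p`, `normal` (`p > alpha`),
#'   `z_skew`, `z_kurt` and `n`.
#' @export
dagostino_pearson <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("insufficient n for omnibus test (need >= 8, got ", n, ")")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 <= 0) stop("zero variance sample")
  # skewness z (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  a <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1
  z_skew <- delta * log(y / a + sqrt((y / a)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term2 <- sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)
  z_kurt <- (term1 - term2) / sqrt(2 / (9 * A))
  K2 <- z_skew^2 + z_kurt^2
  p <- stats::pchisq(K2, df = 2, lower.tail = FALSE)
  list(statistic = K2, p = p, normal = p > alpha,
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Omnibus Kruskal-Wallis H (with tie correction, via
#' [stats::kruskal.test()]) followed by Dunn's rank-based z tests of each
#' non-reference group against the reference, with tie-corrected variance
#' and Bonferroni adjustment.  By default multiplicity is counted over the
#' many-to-one comparisons actually made (mutants vs control); set
#' `scope = "all"` to adjust over all pairwise comparisons instead.
#'
#' @param groups Named list of numeric vectors, one per genotype.
#' @param reference Name of the reference (control) group.
#' @param scope Multiplicity scope for the Bonferroni adjustment.
#' @return A `dc_stat` object: list with `test`, `statistic` (H), `df`, `p`,
#'   `comparisons` (data.frame: `group`, `n`, `z`, `p_unadj`, `p_adj`,
#'   `stars`), `n_ref` and `flag` (`"degenerate"` when all values are
#'   identical, in which case H = 0 and p = 1).
#' @export
kw_dunn <- function(groups, reference = names(groups)[1L],
                    scope = c("reference", "all")) {
  scope <- match.arg(scope)
  .check_groups(groups, reference, min_n = 1L)
  if (sum(lengths(groups)) < 3L) stop("need at least 3 observations in total")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  flag <- NULL
  if (length(unique(values)) == 1L) {
    H <- 0; p <- 1; df <- length(groups) - 1L
    flag <- "degenerate"
  } else {
    kt <- stats::kruskal.test(values, g)
    H <- unname(kt$statistic); p <- kt$p.value; df <- unname(kt$parameter)
  }
  # Dunn's z statistics vs the reference, tie-corrected
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n_i <- lengths(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  others <- setdiff(names(groups), reference)
  m <- if (scope == "reference") length(others) else
    length(groups) * (length(groups) - 1L) / 2L
  comp <- do.call(rbind, lapply(others, function(gname) {
    if (s2 <= 0) {
      z <- 0; pu <- 1
    } else {
      z <- (rbar[[gname]] - rbar[[reference]]) /
        sqrt(s2 * (1 / n_i[[gname]] + 1 / n_i[[reference]]))
      pu <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(group = gname, n = n_i[[gname]], z = z, p_unadj = pu,
               p_adj = min(1, pu * m))
  }))
  comp$stars <- star_map(comp$p_adj)
  rownames(comp) <- NULL
  structure(list(test = "Kruskal-Wallis + Dunn", statistic = H, df = df,
                 p = p, comparisons = comp, reference = reference,
                 n_ref = n_i[[reference]], flag = flag),
            class = "dc_stat")
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Ordinary one-way ANOVA (via [stats::aov()]) followed by Dunnett's
#' single-step comparisons of every group against the reference, computed
#' with \pkg{multcomp}.  The multivariate-t adjustment involves randomized
#' quadrature; the RNG state is set and restored internally so results are
#' reproducible.
#'
#' @inheritParams kw_dunn
#' @return A `dc_stat` object with `statistic` (F), `df` (numerator,
#'   denominator), `p` and per-comparison adjusted p-values.
#' @export
anova_dunnett <- function(groups, reference = names(groups)[1L]) {
  .check_groups(groups, reference, min_n = 2L)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)),
              levels = c(reference, setdiff(names(groups), reference)))
  if (all(vapply(groups, stats::var, numeric(1L)) == 0))
    stop("zero within-group variance in every group")
  dat <- data.frame(value = values, g = g)
  fit <- stats::aov(value ~ g, data = dat)
  an <- summary(fit)[[1L]]
  Fstat <- an[["F value"]][1L]
  p <- an[["Pr(>F)"]][1L]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(20220915L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  gh <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gh, test = multcomp::adjusted("single-step"))
  others <- setdiff(names(groups), reference)
  comp <- data.frame(group = others, n = lengths(groups)[others],
                     t = unname(sm$test$tstat),
                     p_adj = unname(sm$test$pvalues))
  comp$stars <- star_map(comp$p_adj)
  rownames(comp) <- NULL
  structure(list(test = "one-way ANOVA + Dunnett", statistic = Fstat,
                 df = c(an$Df[1L], an$Df[2L]), p = p, comparisons = comp,
                 reference = reference, n_ref = length(groups[[reference]]),
                 flag = NULL),
            class = "dc_stat")
}

.check_groups <- function(groups, reference, min_n) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  if (!reference %in% names(groups))
    stop("reference group '", reference, "' not among groups")
  if (any(lengths(groups) < min_n))
    stop("every group needs at least ", min_n, " observation(s)")
  if (any(!vapply(groups, function(v) all(is.finite(v)), logical(1L))))
    stop("group values must be finite")
}

#' Pearson chi-square test on a phenotype count table
#'
#' Pearson's chi-square (no continuity correction) on a genotype-by-category
#' count table, e.g. a mutant-vs-control 2 x k table of dorsal-closure
#' phenotype classes.
#'
#' @param counts Matrix of non-negative integer counts, at least 2 x 2.
#' @return A `dc_stat` object with `statistic` (chi-square), `df`, `p` and
#'   `stars`.
#' @export
phenotype_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("count table must be at least 2 x 2")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the count table")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(test = "Pearson chi-square", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 comparisons = NULL, stars = star_map(ct$p.value),
                 n_ref = sum(counts), flag = NULL),
            class = "dc_stat")
}

#' Map p-values to significance stars
#'
#' `ns` for p > 0.05, `*` for p <= 0.05, `**` for p <= 0.01, `***` for
#' p <= 0.001 and `****` for p <= 0.0001 (each boundary closed).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Character vector of star labels.
#' @export
star_map <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  cut(p, breaks = c(-Inf, 0.0001, 0.001, 0.01, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = TRUE) |>
    as.character()
}

#' @export
print.dc_stat <- function(x, ...) {
  cat(x$test, ": statistic = ", signif(x$statistic, 5),
      ", p = ", format.pval(x$p, digits = 4), "\n", sep = "")
  if (!is.null(x$flag)) cat("  [", x$flag, "]\n", sep = "")
  if (!is.null(x$comparisons)) {
    cat("  comparisons vs '", x$reference, "':\n", sep = "")
    print(x$comparisons, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Summary report of genotype comparisons
#'
#' Assembles the per-measurement statistics into a summary grid: one row
#' per measurement, one column per genotype, cells holding the sample size
#' and the adjusted p-value vs the control (or `ns`).
#'
#' @param results Named list of `dc_stat` objects; names are the measurement
#'   labels (e.g. "DC duration", "zipping speed").
#' @return A data.frame with a `measurement` column, a reference column
#'   (sample size only) and one column per comparison group.
#' @export
summary_table <- function(results) {
  if (!length(results)) {
    return(data.frame(measurement = character(0)))
  }
  stopifnot(!is.null(names(results)))
  groups <- unique(unlist(lapply(results, function(r)
    if (is.null(r$comparisons)) character(0) else r$comparisons$group)))
  refs <- unique(unlist(lapply(results, function(r) r$reference)))
  ref <- if (length(refs)) refs[1L] else "reference"
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    row <- stats::setNames(as.list(rep("", length(groups) + 2L)),
                           c("measurement", ref, groups))
    row$measurement <- nm
    row[[ref]] <- paste0("n = ", r$n_ref)
    if (!is.null(r$comparisons)) {
      for (i in seq_len(nrow(r$comparisons))) {
        cm <- r$comparisons[i, ]
        lab <- if (cm$p_adj > 0.05) "ns" else
          paste0("p = ", signif(cm$p_adj, 3))
        row[[cm$group]] <- paste0(lab, ", n = ", cm$n)
      }
    }
    as.data.frame(row, check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a summary report as Markdown
#'
#' @param tab A [summary_table()] data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_md <- function(tab, path) {
  hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
  body <- apply(tab, 1L, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  writeLines(c(hdr, sep, body), path)
  invisible(path)
}
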