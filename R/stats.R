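#' Mann-Whitney U test
#'
#' `U = sum_ij [x_i > y_j] + 0.5 * [x_i = y_j]`. For `n + m <= 12` the
#' two-sided p-value is exact, by full enumeration of all `choose(n+m, n)`
#' group assignments of the pooled sample (ties handled by the half-count
#' convention); otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @return list: `U`, `p`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0)
    stop("mann_whitney_u: both samples must be non-empty")
  n <- length(x); m <- length(y)
  ustat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u <- ustat(x, y)
  nm <- n * m
  if (n + m <= 12) {
    pooled <- c(x, y)
    idx <- utils::combn(n + m, n)
    us <- apply(idx, 2, function(ii) ustat(pooled[ii], pooled[-ii]))
    # two-sided: arrangements at least as extreme on either side of nm/2
    dev <- abs(u - nm / 2)
    p <- mean(abs(us - nm / 2) >= dev - 1e-12)
    return(list(U = u, p = p, method = "exact"))
  }
  pooled <- c(x, y)
  ties <- table(pooled)
  ntot <- n + m
  mu <- nm / 2
  sigma2 <- nm / 12 * ((ntot + 1) - sum(ties^3 - ties) / (ntot * (ntot - 1)))
  if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = u, p = p, method = "normal")
}

#' Bonferroni correction
#'
#' `corrected_p = min(1, k * p)`, exactly.
#'
#' @param p numeric vector of p-values.
#' @param k number of comparisons; defaults to `length(p)`.
#' @return corrected p-values.
#' @export
bonferroni <- function(p, k = length(p)) {
  pmin(1, k * p)
}

#' Group-level comparison of a per-unit metric
#'
#' Two-way ANOVA (group x behavior) on a long-format metric table, with
#' Bonferroni-corrected pairwise Mann-Whitney contrasts; or a
#' repeated-measures ANOVA (within-subject band factor) when
#' `design = "repeated"` and the table carries a `subject` column.
#'
#' @param metric_table data.frame with columns `value`, `group`, and
#'   (for the two-way design) `behavior`, or (for the repeated design)
#'   `band` and `subject`.
#' @param design `"twoway"` or `"repeated"`.
#' @param alpha significance level.
#' @return object of class `group_comparison`: `anova` (data.frame of
#'   effects: effect, F, df1, df2, p), `pairwise` (data.frame: contrast,
#'   group summaries, U, p, corrected_p, significant).
#' @export
group_compare <- function(metric_table, design = c("twoway", "repeated"),
                          alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(all(c("value", "group") %in% names(metric_table)))
  metric_table$group <- factor(metric_table$group)
  if (design == "twoway") {
    stopifnot("behavior" %in% names(metric_table))
    metric_table$behavior <- factor(metric_table$behavior)
    cells <- table(metric_table$group, metric_table$behavior)
    if (any(cells < 2))
      stop("group_compare: every group x behavior cell needs >= 2 values")
    fit <- stats::aov(value ~ group * behavior, data = metric_table)
    s <- summary(fit)[[1]]
    eff <- trimws(rownames(s))
    keep <- eff != "Residuals"
    an <- data.frame(effect = eff[keep], F = s$`F value`[keep],
                     df1 = s$Df[keep], df2 = s$Df[!keep][1],
                     p = s$`Pr(>F)`[keep], stringsAsFactors = FALSE)
    # pairwise group contrasts within each behavior level
    rows <- list()
    for (b in levels(metric_table$behavior)) {
      sub <- metric_table[metric_table$behavior == b, ]
      gl <- levels(metric_table$group)
      xs <- sub$value[sub$group == gl[1]]
      ys <- sub$value[sub$group == gl[2]]
      mw <- mann_whitney_u(xs, ys)
      rows[[b]] <- data.frame(
        contrast = paste0(gl[1], " vs ", gl[2], " @ ", b),
        mean_1 = mean(xs), sem_1 = stats::sd(xs) / sqrt(length(xs)),
        n_1 = length(xs),
        mean_2 = mean(ys), sem_2 = stats::sd(ys) / sqrt(length(ys)),
        n_2 = length(ys),
        U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    }
    pw <- do.call(rbind, rows)
  } else {
    stopifnot(all(c("band", "subject") %in% names(metric_table)))
    metric_table$band <- factor(metric_table$band)
    metric_table$subject <- factor(metric_table$subject)
    fit <- stats::aov(value ~ group * band + Error(subject / band),
                      data = metric_table)
    s <- summary(fit)
    an <- do.call(rbind, lapply(s, function(stratum) {
      tab <- stratum[[1]]
      eff <- trimws(rownames(tab))
      keep <- eff != "Residuals" & !is.na(tab$`F value`)
      if (!any(keep)) return(NULL)
      data.frame(effect = eff[keep], F = tab$`F value`[keep],
                 df1 = tab$Df[keep], df2 = tab$Df[eff == "Residuals"][1],
                 p = tab$`Pr(>F)`[keep], stringsAsFactors = FALSE)
    }))
    rownames(an) <- NULL
    # per-band group contrasts
    rows <- list()
    for (b in levels(metric_table$band)) {
      sub <- metric_table[metric_table$band == b, ]
      gl <- levels(metric_table$group)
      xs <- sub$value[sub$group == gl[1]]
      ys <- sub$value[sub$group == gl[2]]
      mw <- mann_whitney_u(xs, ys)
      rows[[b]] <- data.frame(
        contrast = paste0(gl[1], " vs ", gl[2], " @ ", b),
        mean_1 = mean(xs), sem_1 = stats::sd(xs) / sqrt(length(xs)),
        n_1 = length(xs),
        mean_2 = mean(ys), sem_2 = stats::sd(ys) / sqrt(length(ys)),
        n_2 = length(ys),
        U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    }
    pw <- do.call(rbind, rows)
  }
  # degenerate inputs: with (numerically) constant values the SS are pure
  # rounding noise -> report F = 0, p = 1
  if (stats::var(metric_table$value) <
      1e-20 * (1 + mean(metric_table$value)^2)) {
    an$F[] <- 0
    an$p[] <- 1
  }
  an$p[!is.finite(an$F)] <- 1
  an$F[!is.finite(an$F)] <- 0
  pw$corrected_p <- bonferroni(pw$p, nrow(pw))
  pw$significant <- pw$corrected_p < alpha
  rownames(pw) <- NULL
  structure(list(anova = an, pairwise = pw, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\nANOVA:\n")
  print(x$anova, digits = 4)
  cat("Pairwise (Bonferroni-corrected):\n")
  print(x$pairwise[, c("contrast", "mean_1", "mean_2", "p", "corrected_p",
                       "significant")], digits = 4)
  invisible(x)
}
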