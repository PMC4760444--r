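#' Paired and one-sample t tests, tidy output
#'
#' Thin wrappers around [stats::t.test()] returning one-row tibbles, with the
#' degenerate zero-variance case handled explicitly: identical differences
#' with zero mean give `t = 0, p = 1`; identical nonzero differences give an
#' infinite statistic, flagged, with the p value reported at the machine
#' floor.
#'
#' @param pre,post Matched numeric vectors.
#' @return One-row tibble: `estimate` (mean difference post - pre),
#'   `statistic`, `df`, `p.value`, `flag` (NA or `"zero variance"`).
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2,
            !anyNA(pre), !anyNA(post))
  one_sample_t(post - pre, reference = 0)
}

#' @rdname paired_t
#' @param values Numeric sample.
#' @param reference Null value the mean is tested against.
#' @export
one_sample_t <- function(values, reference = 0) {
  stopifnot(length(values) >= 2, !anyNA(values))
  n <- length(values)
  stderr <- stats::sd(values) / sqrt(n)
  # same degeneracy criterion t.test applies before it refuses to run
  if (stderr < 10 * .Machine$double.eps * max(1, abs(mean(values)))) {
    m <- mean(values) - reference
    degenerate <- abs(m) > 10 * .Machine$double.eps * max(1, abs(reference))
    return(tibble::tibble(
      estimate = m,
      statistic = if (degenerate) sign(m) * Inf else 0,
      df = n - 1,
      p.value = if (degenerate) .Machine$double.xmin else 1,
      flag = if (degenerate) "zero variance" else NA_character_
    ))
  }
  ht <- stats::t.test(values, mu = reference)
  tibble::tibble(
    estimate = unname(ht$estimate) - reference,
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value,
    flag = NA_character_
  )
}

#' Two-by-two repeated-measures ANOVA with Tukey HSD
#'
#' Fully within-subject 2x2 design (e.g. session x hemisphere, or session x
#' CVR-compartment sign): every subject contributes one value per cell.
#' Classical sums-of-squares decomposition with each effect tested against
#' its own effect-by-subject interaction, giving F statistics on (1, n - 1)
#' degrees of freedom for both main effects and the interaction. Tukey HSD
#' compares the four cell means using the A-by-B-by-subject (interaction
#' error) mean square and the studentized range with n - 1 error degrees of
#' freedom. Subjects with incomplete cells are excluded listwise and
#' recorded.
#'
#' @param data Tibble with columns `subject`, `a`, `b` (two-level factors)
#'   and `value` — or other names given via the `cols` argument.
#' @param cols Named character vector mapping `subject`, `a`, `b`, `value`
#'   to the columns of `data`.
#' @return An object of class `rm_anova` with `tidy()` (effect table) and
#'   `glance()` methods and a `tukey` tibble of pairwise cell comparisons.
#' @export
rm_anova_2x2 <- function(data,
                         cols = c(subject = "subject", a = "a", b = "b",
                                  value = "value")) {
  d <- tibble::tibble(
    subject = as.character(data[[cols[["subject"]]]]),
    a = as.character(data[[cols[["a"]]]]),
    b = as.character(data[[cols[["b"]]]]),
    value = as.numeric(data[[cols[["value"]]]])
  )
  la <- sort(unique(d$a))
  lb <- sort(unique(d$b))
  if (length(la) != 2 || length(lb) != 2) stop("both factors must have two levels")
  complete <- dplyr::summarize(
    dplyr::group_by(d, .data$subject),
    ok = dplyr::n() == 4 && !anyNA(.data$value) &&
      nrow(unique(cbind(.data$a, .data$b))) == 4
  )
  excluded <- complete$subject[!complete$ok]
  d <- dplyr::filter(d, !(.data$subject %in% excluded))
  subj <- sort(unique(d$subject))
  n <- length(subj)
  if (n < 2) stop("need at least two subjects with complete cells")

  y <- array(NA_real_, c(n, 2, 2),
             dimnames = list(subj, la, lb))
  for (r in seq_len(nrow(d))) {
    y[d$subject[r], d$a[r], d$b[r]] <- d$value[r]
  }

  gm <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_ab <- apply(y, c(2, 3), mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)

  ss_a <- 2 * n * sum((m_a - gm)^2)
  ss_b <- 2 * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
  ss_sa <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_a) + gm)^2)
  ss_sb <- 2 * sum((m_sb - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_b) + gm)^2)
  # A x B x subject residual: what the full additive decomposition leaves over
  fit <- array(0, dim(y))
  for (i in seq_len(n)) for (j in 1:2) for (k in 1:2) {
    fit[i, j, k] <- m_ab[j, k] + m_sa[i, j] + m_sb[i, k] -
      m_s[i] - m_a[j] - m_b[k] + gm
  }
  ss_sab <- sum((y - fit)^2)

  dfe <- n - 1
  f_of <- function(ss, ss_err) {
    if (ss <= .Machine$double.eps * max(1, abs(gm))^2) return(0)
    if (ss_err == 0) return(Inf)
    ss / (ss_err / dfe)
  }
  eff <- tibble::tibble(
    term = c("a", "b", "a:b"),
    sumsq = c(ss_a, ss_b, ss_ab),
    error_sumsq = c(ss_sa, ss_sb, ss_sab),
    df = 1,
    error_df = dfe,
    statistic = c(f_of(ss_a, ss_sa), f_of(ss_b, ss_sb), f_of(ss_ab, ss_sab))
  )
  eff$p.value <- stats::pf(eff$statistic, 1, dfe, lower.tail = FALSE)

  # Tukey HSD over the four cell means, interaction error term
  mse <- ss_sab / dfe
  cells <- tibble::tibble(
    a = rep(la, each = 2), b = rep(lb, 2),
    cell = paste(rep(la, each = 2), rep(lb, 2), sep = ":"),
    mean = as.vector(t(m_ab))
  )
  pairs <- utils::combn(seq_len(4), 2)
  tukey <- tibble::tibble(
    contrast = apply(pairs, 2, function(p) {
      paste(cells$cell[p[1]], "-", cells$cell[p[2]])
    }),
    estimate = apply(pairs, 2, function(p) cells$mean[p[1]] - cells$mean[p[2]]),
    q = apply(pairs, 2, function(p) {
      diff <- abs(cells$mean[p[1]] - cells$mean[p[2]])
      if (diff == 0) 0 else diff / sqrt(mse / n)
    })
  )
  tukey$p.value <- ifelse(
    is.finite(tukey$q),
    stats::ptukey(tukey$q, nmeans = 4, df = dfe, lower.tail = FALSE),
    0
  )

  structure(
    list(
      effects = eff, tukey = tukey, cells = cells,
      n_subjects = n, excluded = excluded,
      factor_levels = list(a = la, b = lb),
      error_ms = c(a = ss_sa / dfe, b = ss_sb / dfe, `a:b` = mse)
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> 2x2 within-subject, n = %d\n", x$n_subjects))
  print(x$effects)
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) x$effects

#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_excluded = length(x$excluded),
    p_a = x$effects$p.value[1],
    p_b = x$effects$p.value[2],
    p_interaction = x$effects$p.value[3]
  )
}

#' Median and interquartile range with Tukey-hinge quartiles
#'
#' The inclusive-hinge convention ([stats::fivenum()]): each half of the
#' sorted sample includes the overall median when n is odd. Suits small
#' skewed counts such as per-subject lesion tallies.
#'
#' @param values Numeric sample, `n >= 1`.
#' @return One-row tibble: `median`, `iqr`, `q1`, `q3`.
#' @examples
#' median_iqr(c(0, 1, 3, 3, 38))  # median 3, IQR 2
#' @export
median_iqr <- function(values) {
  stopifnot(length(values) >= 1, !anyNA(values))
  fn <- stats::fivenum(values)
  tibble::tibble(median = fn[3], iqr = fn[4] - fn[2], q1 = fn[2], q3 = fn[4])
}
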