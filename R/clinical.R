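#' Diagnostic cutoff configuration
#'
#' Predefined diagnostic cutoffs for CSF neurofilament light chain (NfL,
#' 1227 pg/mL) and phosphorylated neurofilament heavy chain (pNfH, 750 pg/mL),
#' and the normative percentile below which a cognitive subdomain score is
#' abnormal (5th percentile).
#'
#' @param nfl_cutoff,pnfh_cutoff Positive concentrations, pg/mL.
#' @param ecas_percentile Abnormality percentile, in (0, 50).
#' @return A `cutoff_config` list.
#' @export
cutoff_config <- function(nfl_cutoff = 1227, pnfh_cutoff = 750,
                          ecas_percentile = 5) {
  stopifnot(nfl_cutoff > 0, pnfh_cutoff > 0,
            ecas_percentile > 0, ecas_percentile < 50)
  structure(list(nfl_cutoff = nfl_cutoff, pnfh_cutoff = pnfh_cutoff,
                 ecas_percentile = ecas_percentile),
            class = "cutoff_config")
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction (this convention reproduces published cohort
#' tables exactly); equivalent to the closed form
#' `N (ad - bc)^2 / (r1 r2 c1 c2)` with 1 degree of freedom.
#'
#' @param table 2x2 matrix of non-negative integer counts with all margins
#'   positive.
#' @return Tibble `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("a 2x2 table is required", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins of the 2x2 table must be positive", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

# exact one-sided tail of the Mann-Whitney U distribution by enumeration of
# all assignments of the pooled (mid-)ranks to the first sample
mw_exact_p <- function(r, n1, u_obs, side) {
  n <- length(r)
  combs <- utils::combn(n, n1)
  base <- n1 * (n1 + 1) / 2
  u_all <- colSums(matrix(r[combs], nrow = n1)) - base
  eps <- 1e-9
  switch(side,
         less = mean(u_all <= u_obs + eps),
         greater = mean(u_all >= u_obs - eps),
         two.sided = min(1, 2 * min(mean(u_all <= u_obs + eps),
                                    mean(u_all >= u_obs - eps))))
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with mid-ranks for ties. Both samples of size
#' 8 or less use exact enumeration of the permutation distribution of U
#' (valid under ties); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param side `"less"` (x tends smaller), `"greater"`, or `"two.sided"`.
#' @return Tibble `u` (U statistic of `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, side = c("less", "greater", "two.sided")) {
  side <- match.arg(side)
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 8L && n2 <= 8L) {
    p <- mw_exact_p(r, n1, u, side)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      # all observations tied: U is at its null mean with certainty
      p <- if (side == "two.sided") 1 else 1
    } else {
      mu <- n1 * n2 / 2
      p <- switch(side,
                  less = stats::pnorm((u - mu + 0.5) / sqrt(v)),
                  greater = stats::pnorm((u - mu - 0.5) / sqrt(v),
                                         lower.tail = FALSE),
                  two.sided = min(1, 2 * min(
                    stats::pnorm((u - mu + 0.5) / sqrt(v)),
                    stats::pnorm((u - mu - 0.5) / sqrt(v),
                                 lower.tail = FALSE))))
    }
    method <- "normal approximation"
  }
  tibble::tibble(u = u, p_value = p, method = method)
}

#' Flag elevated neurofilament concentrations
#'
#' Elevated means strictly above the diagnostic cutoff (a value exactly at
#' the cutoff does not surpass it).
#'
#' @param nfl,pnfh Positive concentrations, pg/mL (vectorized; `NA` allowed
#'   for missing assays).
#' @param cfg A [cutoff_config()].
#' @return Tibble `nfl`, `pnfh`, `nfl_elevated`, `pnfh_elevated`,
#'   `any_elevated`.
#' @export
flag_nf <- function(nfl, pnfh, cfg = cutoff_config()) {
  stopifnot(inherits(cfg, "cutoff_config"))
  if (any(nfl <= 0, na.rm = TRUE) || any(pnfh <= 0, na.rm = TRUE)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  nfl_e <- nfl > cfg$nfl_cutoff
  pnfh_e <- pnfh > cfg$pnfh_cutoff
  tibble::tibble(nfl = nfl, pnfh = pnfh,
                 nfl_elevated = nfl_e, pnfh_elevated = pnfh_e,
                 any_elevated = nfl_e | pnfh_e)
}

#' Classify cognitive subdomain scores against normative data
#'
#' A score is abnormal when it lies strictly below the normative percentile
#' threshold `mean + qnorm(percentile / 100) * sd` (5th percentile by
#' default, i.e. mean minus 1.6449 SD).
#'
#' @param scores Named numeric vector of subdomain scores.
#' @param norms Tibble with `subdomain`, `mean`, `sd` normative rows covering
#'   every scored subdomain.
#' @param cfg A [cutoff_config()].
#' @return Tibble `subdomain`, `score`, `threshold`, `abnormal`, with
#'   attribute `n_abnormal`.
#' @export
classify_ecas <- function(scores, norms, cfg = cutoff_config()) {
  stopifnot(inherits(cfg, "cutoff_config"))
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("`scores` must be a named vector", call. = FALSE)
  }
  missing <- setdiff(names(scores), norms$subdomain)
  if (length(missing)) {
    stop("no normative data for subdomain(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  z <- stats::qnorm(cfg$ecas_percentile / 100)
  out <- purrr::map_dfr(names(scores), function(s) {
    nr <- norms[norms$subdomain == s, ]
    thr <- nr$mean + z * nr$sd
    tibble::tibble(subdomain = s, score = unname(scores[[s]]),
                   threshold = thr, abnormal = scores[[s]] < thr)
  })
  attr(out, "n_abnormal") <- sum(out$abnormal)
  out
}

fmt_median_range <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_character_)
  sprintf("%.3g (%.3g-%.3g)", stats::median(x), min(x), max(x))
}

fmt_count_pct <- function(k, n) sprintf("%d (%.0f)", k, 100 * k / n)

#' Cohort demographics and biomarker summary
#'
#' Builds a demographics-table style summary: medians (ranges) with
#' Mann-Whitney comparisons for numeric variables, counts (percent) with
#' chi-square comparisons for dichotomous ones, and the neurofilament
#' cutoff classification. Tests whose 2x2 margins vanish (e.g. a sign absent
#' in one whole group) report `NA`.
#'
#' @param participants Tibble with `subject_id`, `group`, `age`, and
#'   optionally `sex`, `tiv`, `nfl`, `pnfh`, `umn_sign`.
#' @param cfg A [cutoff_config()].
#' @return Tibble `characteristic`, `carrier`, `control`, `test`,
#'   `statistic`, `p_value`.
#' @export
cohort_summary <- function(participants, cfg = cutoff_config()) {
  req <- c("subject_id", "group", "age")
  if (!all(req %in% names(participants))) {
    stop("participants must contain ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  g <- factor(as.character(participants$group),
              levels = c("control", "carrier"))
  if (any(table(g) == 0L)) {
    stop("both groups must contain at least one participant", call. = FALSE)
  }
  carrier <- participants[g == "carrier", ]
  control <- participants[g == "control", ]
  rows <- list()

  num_row <- function(name, col) {
    if (!col %in% names(participants)) return(NULL)
    xc <- carrier[[col]]
    xk <- control[[col]]
    mw <- mann_whitney(xc[is.finite(xc)], xk[is.finite(xk)],
                       side = "two.sided")
    tibble::tibble(characteristic = name,
                   carrier = fmt_median_range(xc),
                   control = fmt_median_range(xk),
                   test = "Mann-Whitney U",
                   statistic = mw$u, p_value = mw$p_value)
  }
  bin_row <- function(name, flag_carrier, flag_control) {
    tab <- rbind(c(sum(flag_carrier), sum(!flag_carrier)),
                 c(sum(flag_control), sum(!flag_control)))
    ok <- all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    cs <- if (ok) chi_square_2x2(tab) else NULL
    tibble::tibble(characteristic = name,
                   carrier = fmt_count_pct(sum(flag_carrier), nrow(carrier)),
                   control = fmt_count_pct(sum(flag_control), nrow(control)),
                   test = if (ok) "chi-square" else NA_character_,
                   statistic = if (ok) cs$statistic else NA_real_,
                   p_value = if (ok) cs$p_value else NA_real_)
  }

  rows$age <- num_row("Age, y", "age")
  if ("sex" %in% names(participants)) {
    rows$sex <- bin_row("Women, No. (%)", carrier$sex == "F",
                        control$sex == "F")
  }
  rows$tiv <- num_row("Total intracranial volume, mm3", "tiv")
  rows$nfl <- num_row("NfL, pg/mL", "nfl")
  rows$pnfh <- num_row("pNfH, pg/mL", "pnfh")
  if ("nfl" %in% names(participants)) {
    fc <- flag_nf(carrier$nfl, carrier$pnfh, cfg)
    fk <- flag_nf(control$nfl, control$pnfh, cfg)
    rows$nfl_cut <- bin_row(
      sprintf("NfL > %g pg/mL, No. (%%)", cfg$nfl_cutoff),
      fc$nfl_elevated %in% TRUE, fk$nfl_elevated %in% TRUE)
  }
  if ("umn_sign" %in% names(participants)) {
    rows$umn <- bin_row("UMN signs, No. (%)", carrier$umn_sign %in% TRUE,
                        control$umn_sign %in% TRUE)
  }
  dplyr::bind_rows(rows)
}
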