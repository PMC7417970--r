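#' Regional mean uptake for one image
#'
#' Mean over the voxels of each atlas label inside the analysis mask. Regions
#' with no in-mask voxel (or no defined value there) are dropped with a
#' warning.
#'
#' @param image Volume.
#' @param template A `template_set`.
#' @param mask Optional analysis mask.
#' @return Tibble `region`, `label`, `n_voxels`, `mean`.
#' @export
voi_means <- function(image, template, mask = NULL) {
  stopifnot(is_volume(image), inherits(template, "template_set"))
  lab <- unclass(template$atlas)
  keep <- if (is.null(mask)) TRUE else as_mask_array(mask)
  x <- unclass(image)
  rows <- purrr::map_dfr(seq_len(nrow(template$labels)), function(i) {
    sel <- lab == template$labels$label[i] & keep
    v <- x[sel]
    v <- v[is.finite(v)]
    tibble::tibble(region = template$labels$name[i],
                   label = template$labels$label[i],
                   n_voxels = length(v),
                   mean = if (length(v)) mean(v) else NA_real_)
  })
  dropped <- rows$region[rows$n_voxels == 0L]
  if (length(dropped)) {
    warning("dropping region(s) with no defined in-mask voxel: ",
            paste(dropped, collapse = ", "))
    rows <- rows[rows$n_voxels > 0L, ]
  }
  rows
}

#' Regional means for a whole cohort
#'
#' @param images Named list of volumes (names are subject ids).
#' @param template A `template_set`.
#' @param mask Optional analysis mask.
#' @return Long tibble: `subject_id` plus the [voi_means()] columns.
#' @export
region_table <- function(images, template, mask = NULL) {
  purrr::map_dfr(names(images), function(id) {
    dplyr::mutate(suppressWarnings(voi_means(images[[id]], template, mask)),
                  subject_id = id, .before = 1)
  })
}

#' Per-region group comparison adjusted for age
#'
#' For each region, fits `mean ~ group + age` and tests the carrier effect
#' one-sidedly (default: carriers lower, matching a hypometabolism
#' hypothesis).
#'
#' @param table A [region_table()] tibble (columns `subject_id`, `region`,
#'   `mean`).
#' @param participants Tibble with `subject_id`, `group`, `age`.
#' @param side `"less"` (carrier < control) or `"greater"`.
#' @return Tibble `region`, `estimate` (carrier minus control), `t`, `df`,
#'   `p_value` (one-sided), `p_two_sided`.
#' @export
group_compare_regions <- function(table, participants,
                                  side = c("less", "greater")) {
  side <- match.arg(side)
  df <- dplyr::inner_join(table,
                          dplyr::select(participants, "subject_id", "group",
                                        "age"),
                          by = "subject_id")
  df$group <- factor(as.character(df$group), levels = c("control", "carrier"))
  counts <- table(unique(df[c("subject_id", "group")])$group)
  if (any(counts < 3L)) {
    stop("each group needs at least 3 subjects", call. = FALSE)
  }
  purrr::map_dfr(split(df, df$region), function(d) {
    if (stats::var(d$mean) == 0) {
      stop(sprintf("degenerate (constant) regional means in '%s'",
                   d$region[1]), call. = FALSE)
    }
    fit <- stats::lm(mean ~ group + age, data = d)
    co <- summary(fit)$coefficients
    tval <- co["groupcarrier", "t value"]
    dfree <- fit$df.residual
    p1 <- if (side == "less") stats::pt(tval, dfree) else
      stats::pt(tval, dfree, lower.tail = FALSE)
    tibble::tibble(region = d$region[1],
                   estimate = co["groupcarrier", "Estimate"],
                   t = tval, df = dfree,
                   p_value = p1,
                   p_two_sided = co["groupcarrier", "Pr(>|t|)"])
  })
}

#' Benjamini-Hochberg step-up multiple-testing correction
#'
#' Rejects all hypotheses with `p <= p_(k)` where
#' `k = max{ i : p_(i) <= i q / m }`.
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @param q Target false-discovery rate (default 0.05).
#' @return Tibble `index`, `p_value`, `p_adjusted`, `rejected`, with
#'   attributes `k` (number rejected) and `threshold` (largest rejected p, 0
#'   if none).
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  if (!length(pvals)) {
    out <- tibble::tibble(index = integer(0), p_value = numeric(0),
                          p_adjusted = numeric(0), rejected = logical(0))
    attr(out, "k") <- 0L
    attr(out, "threshold") <- 0
    return(out)
  }
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  rejected <- adj <= q
  out <- tibble::tibble(index = seq_along(pvals), p_value = pvals,
                        p_adjusted = adj, rejected = rejected)
  attr(out, "k") <- sum(rejected)
  attr(out, "threshold") <- if (any(rejected)) max(pvals[rejected]) else 0
  out
}
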