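#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic uses
#' midranks for ties. The two-sided p-value is exact (full enumeration) when
#' `n1 + n2 <= 12` and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples (each >= 1 observation).
#' @return One-row tibble: `n_x`, `n_y`, `U` (statistic for `x`), `p_value`,
#'   `method`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) abort("Both samples need >= 1 observation.")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- (n1 + n2 <= 12) && !ties
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  tibble(n_x = n1, n_y = n2, U = U, p_value = min(p, 1),
         method = if (exact) "exact" else "normal approximation")
}

#' Percent difference relative to a reference mean
#'
#' `100 * (other - reference) / reference`.
#'
#' @param reference_mean reference (e.g. healthy-group) mean; nonzero.
#' @param other_mean comparison (e.g. obese-group) mean.
#' @return Percent difference (positive = increase over the reference).
#' @export
percent_difference <- function(reference_mean, other_mean) {
  if (any(reference_mean == 0)) abort("Reference mean must be nonzero.")
  100 * (other_mean - reference_mean) / reference_mean
}

#' Group summary: mean, SEM and Mann-Whitney comparison per feature
#'
#' Summarizes each morphological feature per group as mean ± SEM with
#' `SEM = sd / sqrt(n)` and `n` the pooled per-adipocyte count in the group
#' (not the per-animal count), and tests the two groups with a two-sided
#' Mann-Whitney test on the pooled per-adipocyte values. The first group (in
#' `reference` or alphabetical order) serves as the reference for percent
#' differences.
#'
#' @param features an `adipo_features` tibble carrying a `group` column.
#' @param feature_cols features to summarize.
#' @param reference reference group label; default the first sorted level.
#' @param alpha significance threshold for the `significant` flag.
#' @return An `adipo_group_summary` tibble: one row per feature with per-group
#'   mean/SEM/n, U, p-value, percent difference and significance flag.
#' @export
group_summary <- function(features,
                          feature_cols = c("volume", "nod", "equiv_diameter", "sphericity"),
                          reference = NULL, alpha = 0.05) {
  if (!"group" %in% names(features) || any(is.na(features$group))) {
    abort("Every row must carry a `group` label.")
  }
  groups <- sort(unique(features$group))
  if (!is.null(reference)) {
    groups <- c(reference, setdiff(groups, reference))
  }
  counts <- table(features$group)
  if (any(counts < 2)) abort("Every group needs >= 2 observations.")
  long <- tidyr::pivot_longer(features, dplyr::all_of(feature_cols),
                              names_to = "feature", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  per_group <- long |>
    dplyr::group_by(.data$feature, .data$group) |>
    dplyr::summarise(mean = mean(.data$value), sem = sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  wide <- tidyr::pivot_wider(per_group, names_from = "group",
                             values_from = c("mean", "sem", "n"))
  if (length(groups) == 2) {
    tests <- long |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(
        mw = list(mann_whitney(.data$value[.data$group == groups[1]],
                               .data$value[.data$group == groups[2]])),
        .groups = "drop") |>
      tidyr::unnest("mw") |>
      dplyr::select("feature", "U", "p_value")
    wide <- dplyr::left_join(wide, tests, by = "feature")
    wide$percent_difference <- percent_difference(
      wide[[paste0("mean_", groups[1])]], wide[[paste0("mean_", groups[2])]])
    wide$significant <- wide$p_value < alpha
  }
  wide <- wide[match(feature_cols, wide$feature), , drop = FALSE]
  attr(wide, "groups") <- groups
  attr(wide, "reference") <- groups[1]
  attr(wide, "alpha") <- alpha
  class(wide) <- c("adipo_group_summary", class(wide))
  wide
}

# step-up FDR machinery ------------------------------------------------------

#' False-discovery-rate step-up procedures
#'
#' Standard linear step-up (`"bh"`) and the two-stage adaptive step-up
#' (`"two_stage"`, the default of common biostatistics software for
#' "FDR at Q"): stage one runs the linear step-up at `Q / (1 + Q)` to estimate
#' the number of true nulls `m0 = m - r1`, stage two reruns it at level
#' `Q * m / ((1 + Q) * m0)`.
#'
#' @param p vector of p-values.
#' @param Q target FDR (fraction), default 0.05.
#' @param method `"two_stage"` or `"bh"`.
#' @return List with `q` (adjusted values comparable to `Q`) and `reject`
#'   (logical discovery flags).
#' @export
fdr_step_up <- function(p, Q = 0.05, method = c("two_stage", "bh")) {
  method <- match.arg(method)
  m <- length(p)
  if (m == 0) return(list(q = numeric(0), reject = logical(0)))
  bh_reject <- function(p, level) {
    o <- order(p)
    thr <- level * seq_len(m) / m
    k <- which(p[o] <= thr)
    rej <- logical(m)
    if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  bh_adjust <- function(p) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(m / rev(seq_len(m)) * p[o]))[ro]
  }
  if (method == "bh") {
    return(list(q = bh_adjust(p), reject = bh_reject(p, Q)))
  }
  q1 <- Q / (1 + Q)
  r1 <- sum(bh_reject(p, q1))
  if (r1 == 0) {
    return(list(q = pmin(1, bh_adjust(p) * (1 + Q)), reject = logical(m)))
  }
  if (r1 == m) {
    return(list(q = pmin(1, bh_adjust(p) * (1 + Q) / m), reject = rep(TRUE, m)))
  }
  m0 <- m - r1
  q <- pmin(1, bh_adjust(p) * m0 / m * (1 + Q))
  list(q = q, reject = bh_reject(p, q1 * m / m0))
}

#' Bin specification for distribution analyses
#'
#' Uniform-width, left-closed/right-open bins (the last bin is closed) per
#' feature. The defaults follow the class widths conventional for adipocyte
#' morphometry panels: 50,000 µm³ for volume, 5 µm for NOD, 10 µm for
#' equivalent diameter and 0.04 for sphericity.
#'
#' @param feature feature name.
#' @param width bin width.
#' @param lo,hi range covered (extended with an overflow bin if data exceed
#'   it).
#' @return A one-row `bin_spec` tibble.
#' @export
bin_spec <- function(feature, width, lo = 0, hi) {
  if (width <= 0 || hi <= lo) abort("Bin edges must be strictly increasing.")
  tibble(feature = feature, width = width, lo = lo, hi = hi)
}

#' @rdname bin_spec
#' @export
default_bin_specs <- function() {
  dplyr::bind_rows(
    bin_spec("volume", 50000, 0, 1e6),
    bin_spec("nod", 5, 0, 150),
    bin_spec("equiv_diameter", 10, 0, 200),
    bin_spec("sphericity", 0.04, 0, 1)
  )
}

#' Binned per-sample distributions of adipocyte features
#'
#' Histograms every feature per sample on the bin grid of `specs`
#' (left-closed, right-open; last bin closed; an overflow bin is appended
#' when observations exceed the specified range), then averages counts per
#' group. Per-sample counts always sum to the number of cells retained for
#' that sample.
#'
#' @param features an `adipo_features` tibble with `group` and `sample_id`.
#' @param specs a `bin_spec` tibble, by default [default_bin_specs()].
#' @return An `adipo_distribution` tibble: `feature`, `bin_lo`, `bin_hi`,
#'   `group`, `sample_id`, `count`.
#' @export
binned_distribution <- function(features, specs = default_bin_specs()) {
  specs <- dplyr::filter(specs, .data$feature %in% names(features))
  out <- purrr::pmap_dfr(specs, function(feature, width, lo, hi) {
    vals <- features[[feature]]
    keep <- !is.na(vals)
    vmax <- if (any(keep)) max(vals[keep]) else hi
    hi2 <- if (vmax >= hi) lo + width * ceiling((vmax - lo) / width + 1e-9) else hi
    if (hi2 == hi && vmax == hi) hi2 <- hi + width
    edges <- seq(lo, hi2, by = width)
    if (edges[length(edges)] < hi2) edges <- c(edges, edges[length(edges)] + width)
    df <- features[keep, c("group", "sample_id")]
    df$value <- vals[keep]
    df$bin <- pmin(findInterval(df$value, edges, rightmost.closed = TRUE),
                   length(edges) - 1L)
    grid <- tidyr::expand_grid(
      dplyr::distinct(features[, c("group", "sample_id")]),
      bin = seq_len(length(edges) - 1L)
    )
    counted <- df |>
      dplyr::count(.data$group, .data$sample_id, .data$bin, name = "count")
    grid |>
      dplyr::left_join(counted, by = c("group", "sample_id", "bin")) |>
      dplyr::mutate(
        feature = feature,
        count = dplyr::coalesce(.data$count, 0L),
        bin_lo = edges[.data$bin],
        bin_hi = edges[.data$bin + 1L]
      ) |>
      dplyr::select("feature", "bin_lo", "bin_hi", "group", "sample_id", "count")
  })
  class(out) <- c("adipo_distribution", class(out))
  out
}

#' Per-group mean bin counts
#'
#' @param dist an `adipo_distribution` from [binned_distribution()].
#' @return Tibble of per-group mean (and SEM) counts per bin.
#' @export
distribution_summary <- function(dist) {
  dist |>
    dplyr::group_by(.data$feature, .data$bin_lo, .data$bin_hi, .data$group) |>
    dplyr::summarise(mean_count = mean(.data$count),
                     sem_count = sd(.data$count) / sqrt(dplyr::n()),
                     n_samples = dplyr::n(), .groups = "drop")
}

#' Multiple Mann-Whitney comparisons across bins with FDR control
#'
#' For every bin (within each feature), compares the two groups' per-sample
#' counts with a Mann-Whitney test, then applies the step-up FDR procedure at
#' `Q` across the bins of that feature. Bins with no cells in either group
#' are skipped (flagged `tested = FALSE`).
#'
#' @param dist an `adipo_distribution` from [binned_distribution()].
#' @param Q target FDR, default 0.05 (i.e. Q = 5%).
#' @param method FDR method, see [fdr_step_up()].
#' @return Tibble: `feature`, `bin_lo`, `bin_hi`, `p_value`, `q_value`,
#'   `discovery`, `tested`.
#' @export
multiple_mw_fdr <- function(dist, Q = 0.05, method = c("two_stage", "bh")) {
  method <- match.arg(method)
  groups <- sort(unique(dist$group))
  if (length(groups) != 2) abort("Exactly two groups are required.")
  per_bin <- dist |>
    dplyr::group_by(.data$feature, .data$bin_lo, .data$bin_hi) |>
    dplyr::summarise(
      total = sum(.data$count),
      p_value = {
        a <- .data$count[.data$group == groups[1]]
        b <- .data$count[.data$group == groups[2]]
        if (sum(.data$count) == 0) NA_real_ else mann_whitney(a, b)$p_value
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(tested = !is.na(.data$p_value))
  per_bin <- per_bin |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(d, key) {
      d$q_value <- NA_real_
      d$discovery <- FALSE
      idx <- which(d$tested)
      if (length(idx) > 0) {
        res <- fdr_step_up(d$p_value[idx], Q = Q, method = method)
        d$q_value[idx] <- res$q
        d$discovery[idx] <- res$reject
      }
      d
    }) |>
    dplyr::ungroup()
  n_skip <- sum(!per_bin$tested)
  if (n_skip > 0) {
    inform(sprintf("%d empty bin(s) skipped (no cells in either group).", n_skip))
  }
  dplyr::select(per_bin, "feature", "bin_lo", "bin_hi", "p_value",
                "q_value", "discovery", "tested")
}
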