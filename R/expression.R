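check_ct_table <- function(ct_data) {
  needed <- c("sample_id", "group", "gene_role", "ct")
  missing_cols <- setdiff(needed, names(ct_data))
  if (length(missing_cols)) {
    stop("Ct table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(ct_data$gene_role), c("target", "reference"))
  if (length(bad)) {
    stop("gene_role must be 'target' or 'reference', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(ct_data$ct) || any(ct_data$ct <= 0)) {
    stop("Ct values must be positive and non-missing", call. = FALSE)
  }
  invisible(ct_data)
}

#' Per-sample delta-Ct
#'
#' Averages technical replicates on the Ct scale, then computes
#' `dCt = Ct(target) - Ct(reference)` for each sample. Every sample must
#' carry both a target and a reference measurement.
#'
#' @param ct_data Data frame with columns `sample_id`, `group`,
#'   `gene_role` (`"target"`/`"reference"`), `ct`, and optionally
#'   `replicate` (technical replicates share `sample_id` and `gene_role`).
#' @return A tibble with one row per sample: `sample_id`, `group`,
#'   `ct_target`, `ct_reference`, `delta_ct`.
#' @examples
#' ct <- tibble::tibble(sample_id = "s1", group = "W1",
#'                      gene_role = c("target", "reference"),
#'                      ct = c(25, 20))
#' delta_ct(ct)
#' @export
delta_ct <- function(ct_data) {
  check_ct_table(ct_data)
  wide <- ct_data |>
    dplyr::group_by(.data$sample_id, .data$group, .data$gene_role) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene_role", values_from = "ct",
                       names_prefix = "ct_")
  for (col in c("ct_target", "ct_reference")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  unpaired <- is.na(wide$ct_target) | is.na(wide$ct_reference)
  if (any(unpaired)) {
    stop("sample(s) missing a target or reference Ct: ",
         paste(wide$sample_id[unpaired], collapse = ", "), call. = FALSE)
  }
  wide |>
    dplyr::mutate(delta_ct = .data$ct_target - .data$ct_reference) |>
    dplyr::select("sample_id", "group", "ct_target", "ct_reference",
                  "delta_ct")
}

#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Per-sample `ddCt = dCt - mean(dCt over the calibrator group)` and fold
#' change `2^-ddCt`, i.e. expression relative to the average of the control
#' (calibrator) group. By construction the calibrator group's mean `ddCt`
#' is 0, so its geometric-mean fold change is 1.
#'
#' @inheritParams delta_ct
#' @param calibrator The `group` label used as calibrator; must be present.
#' @return A tibble with one row per sample: `sample_id`, `group`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @examples
#' ct <- simulate_ct(c(W1 = 1, W16 = 4), n_per_group = 4,
#'                   sigma_ct = 0.2, seed = 1)
#' relative_expression(ct, calibrator = "W1")
#' @export
relative_expression <- function(ct_data, calibrator) {
  dct <- delta_ct(ct_data)
  if (!calibrator %in% dct$group) {
    stop("calibrator group '", calibrator, "' has no samples",
         call. = FALSE)
  }
  cal_mean <- mean(dct$delta_ct[dct$group == calibrator])
  dct |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct - cal_mean,
      fold_change = 2^(-.data$delta_delta_ct)
    ) |>
    dplyr::select("sample_id", "group", "delta_ct", "delta_delta_ct",
                  "fold_change")
}

significance_mark <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "ns")
}

#' Group comparisons of relative expression by Student's t-test
#'
#' Two-sided t-tests between expression groups, by default on the `dCt`
#' scale (statistically better behaved; p-values on that scale do not
#' depend on the calibrator choice) with the pooled-variance (Student)
#' test, `df = n_a + n_b - 2`. Significance marks follow the usual figure
#' convention: `*` for p < 0.05, `**` for p < 0.01, `ns` otherwise.
#'
#' @param rel A tibble from [relative_expression()] (or [delta_ct()] when
#'   `scale = "dct"`).
#' @param pairs Optional two-column data frame / matrix of group pairs to
#'   compare; default all unordered pairs of groups present.
#' @param scale `"dct"` (default) to compare `delta_ct`, `"fold"` to
#'   compare fold changes.
#' @param var_equal Pooled-variance Student test (`TRUE`, default) or
#'   Welch (`FALSE`).
#' @return A tibble with `group_a`, `group_b`, `n_a`, `n_b`, `t`, `df`,
#'   `p`, `mark`.
#' @examples
#' ct <- simulate_ct(c(W1 = 1, W16 = 4), n_per_group = 6,
#'                   sigma_ct = 0.3, seed = 1)
#' rel <- relative_expression(ct, calibrator = "W1")
#' compare_expression(rel)
#' @export
compare_expression <- function(rel, pairs = NULL,
                               scale = c("dct", "fold"),
                               var_equal = TRUE) {
  scale <- match.arg(scale)
  value_col <- if (scale == "dct") "delta_ct" else "fold_change"
  if (!value_col %in% names(rel)) {
    stop("`rel` lacks column ", value_col,
         if (scale == "fold") " (run relative_expression() first)",
         call. = FALSE)
  }
  groups <- unique(rel$group)
  if (is.null(pairs)) {
    if (length(groups) < 2) {
      stop("need at least two groups to compare", call. = FALSE)
    }
    pairs <- t(utils::combn(groups, 2))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- as.character(pairs[i, 1]); b <- as.character(pairs[i, 2])
    xa <- rel[[value_col]][rel$group == a]
    xb <- rel[[value_col]][rel$group == b]
    if (length(xa) < 2 || length(xb) < 2) {
      stop("group '", if (length(xa) < 2) a else b,
           "' has fewer than 2 samples", call. = FALSE)
    }
    # degenerate zero-variance groups: t.test() refuses; define t = 0 /
    # p = 1 for identical constants, p = 0 for separated constants
    tt <- tryCatch(stats::t.test(xa, xb, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {
      d <- mean(xa) - mean(xb)
      tt <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
                 parameter = length(xa) + length(xb) - 2,
                 p.value = if (d == 0) 1 else 0)
    }
    tibble::tibble(
      group_a = a, group_b = b,
      n_a = length(xa), n_b = length(xb),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, mark = significance_mark(tt$p.value)
    )
  })
}
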