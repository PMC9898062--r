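#' @title Percentile-based exclusion of non-myofiber ROIs
#' @description Automated segmentation inevitably produces some non-fiber
#'   regions. Three successive percentile filters remove them: segmentation
#'   certainty (classification-channel `Mean` and `Mean_boundary`, default
#'   5th-95th percentile), cross-sectional area (default 10th-99th,
#'   optionally per sample group), and circularity (default above the 1st
#'   percentile). Every filter computes its cuts on the full pooled ROI set,
#'   so the flags are independent of evaluation order. An aggregate code in
#'   {0, 0.4, 0.7, 1} encodes which filter (if any) excluded each ROI, for
#'   overlay visualisation. Finally one section per sample is retained,
#'   requiring at least 100 surviving fibers.
#' @name qc_filter
NULL

#' Filter configuration with the protocol defaults
#'
#' @param certainty_pct two-sided percentile band (low, high) for the
#'   certainty metrics.
#' @param certainty_metrics which classification-channel metrics are active;
#'   `StdDev_boundary` is inactive by default because filtering on the other
#'   two already cleans it up.
#' @param csa_pct percentile band for cross-sectional area.
#' @param csa_group_by optional name of a grouping to apply the CSA cuts
#'   within (passed per call as `group_of`).
#' @param circ_pct lower percentile for circularity.
#' @param min_fibers_per_sample minimum surviving fibers for a sample to be
#'   retained.
#' @export
filter_config <- function(certainty_pct = c(5, 95),
                          certainty_metrics = c("Mean", "Mean_boundary"),
                          csa_pct = c(10, 99),
                          csa_group_by = NULL,
                          circ_pct = 1,
                          min_fibers_per_sample = 100) {
  chk <- function(p) {
    if (length(p) == 2 && (p[1] < 0 || p[2] > 100 || p[1] >= p[2])) {
      stop("percentile band must satisfy 0 <= low < high <= 100")
    }
  }
  chk(certainty_pct); chk(csa_pct)
  ok <- c("Mean", "Mean_boundary", "StdDev_boundary")
  if (length(setdiff(certainty_metrics, ok))) stop("unknown certainty metric")
  list(certainty_pct = certainty_pct, certainty_metrics = certainty_metrics,
       csa_pct = csa_pct, csa_group_by = csa_group_by,
       circ_pct = circ_pct, min_fibers_per_sample = min_fibers_per_sample)
}

#' Linear-interpolation percentile cuts
#'
#' Rank-based type-7 percentiles (the interpolation convention of the
#' statistical environment the analysis was designed in).
#'
#' @param values numeric vector (>= 2 values).
#' @param low,high percentages in `[0, 100]`.
#' @return named vector `c(low_cut, high_cut)`.
#' @export
percentile_bounds <- function(values, low, high) {
  if (length(values) < 2) stop("need at least 2 values")
  q <- stats::quantile(values, c(low, high) / 100, type = 7, names = FALSE)
  c(low_cut = q[1], high_cut = q[2])
}

# strict two-sided pass with the all-ties degeneracy rule
pass_band <- function(v, cuts) {
  if (length(unique(v)) == 1) return(rep(TRUE, length(v)))
  v > cuts[1] & v < cuts[2]
}

# one ROI-level row per fiber, taken from the classification channel rows
roi_level <- function(table) {
  stopifnot(inherits(table, "mfi_table"))
  nch <- attr(table, "n_channels")
  df <- as.data.frame(table)
  ch5 <- df[df$channel == nch, , drop = FALSE]
  ch5[order(ch5$roi_id), , drop = FALSE]
}

#' Segmentation-certainty filter
#'
#' For each active metric of the classification channel (interior `Mean` —
#' boundary probability leaking inside, the smaller the better;
#' `Mean_boundary` — boundary probability on the strip, the larger the
#' better; optionally `StdDev_boundary`), percentile cuts are computed over
#' all pooled ROIs and an ROI passes iff it lies strictly inside the band
#' for every active metric.
#'
#' @param table an [mfi_table()] including the classification channel.
#' @param cfg a [filter_config()].
#' @return data frame `roi_id`, `pass_certainty`.
#' @export
filter_certainty <- function(table, cfg = filter_config()) {
  nch <- attr(table, "n_channels")
  if (!any(table$channel == nch)) stop("classification channel records missing")
  r <- roi_level(table)
  pass <- rep(TRUE, nrow(r))
  for (m in cfg$certainty_metrics) {
    v <- r[[m]]
    cuts <- percentile_bounds(v, cfg$certainty_pct[1], cfg$certainty_pct[2])
    pass <- pass & pass_band(v, cuts)
  }
  data.frame(roi_id = r$roi_id, pass_certainty = pass)
}

#' Cross-sectional-area filter
#'
#' Cuts are computed within each sample group (or pooled when `group_of` is
#' `NULL`) over ALL ROIs — including those already failed by the certainty
#' filter, so the cuts do not depend on filter order. A group with fewer
#' than 2 ROIs passes trivially with a warning.
#'
#' @param table an [mfi_table()].
#' @param cfg a [filter_config()].
#' @param group_of optional vector of group keys, one per ROI (in
#'   `roi_id`-sorted order) or named by `roi_id`.
#' @return data frame `roi_id`, `pass_csa`.
#' @export
filter_csa <- function(table, cfg = filter_config(), group_of = NULL) {
  r <- roi_level(table)
  csa <- r$Area
  if (is.null(group_of)) group_of <- rep("all", nrow(r))
  if (!is.null(names(group_of))) group_of <- group_of[as.character(r$roi_id)]
  if (length(group_of) != nrow(r) || anyNA(group_of)) {
    stop("group key must be defined for every ROI")
  }
  pass <- rep(TRUE, nrow(r))
  for (g in unique(group_of)) {
    sel <- group_of == g
    if (sum(sel) < 2) {
      warning("group '", g, "' has fewer than 2 ROIs; it passes trivially")
      next
    }
    cuts <- percentile_bounds(csa[sel], cfg$csa_pct[1], cfg$csa_pct[2])
    pass[sel] <- pass_band(csa[sel], cuts)
  }
  data.frame(roi_id = r$roi_id, pass_csa = pass)
}

#' Circularity filter
#'
#' Pass iff circularity strictly exceeds the pooled low-percentile cut
#' (default 1st percentile), rejecting longitudinally sectioned and
#' mis-merged elongated ROIs.
#'
#' @inheritParams filter_csa
#' @return data frame `roi_id`, `pass_circ`.
#' @export
filter_circularity <- function(table, cfg = filter_config()) {
  r <- roi_level(table)
  v <- r[["Circ."]]
  if (length(unique(v)) == 1) {
    pass <- rep(TRUE, nrow(r))
  } else {
    cut <- stats::quantile(v, cfg$circ_pct / 100, type = 7, names = FALSE)
    pass <- v > cut
  }
  data.frame(roi_id = r$roi_id, pass_circ = pass)
}

#' Aggregate filtering codes
#'
#' Combines the three per-ROI flags into the visualisation code:
#' 0 = failed certainty; 0.4 = passed certainty only; 0.7 = passed
#' certainty and CSA only; 1 = passed all three.
#'
#' @param flags data frame with `pass_certainty`, `pass_csa`, `pass_circ`.
#' @return `flags` with an added `aggregate_code` column.
#' @export
aggregate_codes <- function(flags) {
  need <- c("pass_certainty", "pass_csa", "pass_circ")
  if (length(setdiff(need, names(flags)))) stop("flags must contain all three filters")
  code <- ifelse(!flags$pass_certainty, 0,
          ifelse(!flags$pass_csa, 0.4,
          ifelse(!flags$pass_circ, 0.7, 1)))
  flags$aggregate_code <- code
  flags
}

#' Run all three filters and aggregate
#'
#' @inheritParams filter_csa
#' @return data frame `roi_id`, three pass flags, `aggregate_code`.
#' @export
qc_filter <- function(table, cfg = filter_config(), group_of = NULL) {
  f1 <- filter_certainty(table, cfg)
  f2 <- filter_csa(table, cfg, group_of)
  f3 <- filter_circularity(table, cfg)
  flags <- Reduce(function(a, b) merge(a, b, by = "roi_id"), list(f1, f2, f3))
  aggregate_codes(flags)
}

#' Select the replicate section for a sample
#'
#' Returns the section with the highest surviving-fiber count (ties broken
#' by the lowest section index); the sample is excluded when even the best
#' section falls below `min_fibers`.
#'
#' @param counts named integer vector: section id -> surviving fiber count.
#' @param min_fibers minimum fiber count for retention (default 100).
#' @return list with `section` (name of the selected section), `count`, and
#'   `retained` (logical).
#' @export
select_replicate <- function(counts, min_fibers = 100) {
  if (length(counts) == 0) stop("no sections supplied")
  nm <- names(counts)
  tie <- if (is.null(nm)) seq_along(counts) else {
    num <- suppressWarnings(as.numeric(nm))
    if (anyNA(num)) xtfrm(nm) else num
  }
  ord <- order(-as.numeric(counts), tie)
  best <- ord[1]
  list(section = if (is.null(nm)) best else nm[best],
       count = as.numeric(counts[best]),
       retained = as.numeric(counts[best]) >= min_fibers)
}

#' Write the `_Filt` table: measurements plus filter columns
#'
#' Appends one 0/1 column per filter and the aggregate code to every
#' channel row of each ROI, tab-delimited, for the overlay renderer.
#'
#' @param table an [mfi_table()].
#' @param flags output of [qc_filter()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filt_table <- function(table, flags, path) {
  df <- as.data.frame(table)
  cols <- intersect(MFI_COLUMNS, names(df))
  out <- df[, cols, drop = FALSE]
  m <- match(df$roi_id, flags$roi_id)
  if (anyNA(m)) stop("flags missing for some ROIs")
  out$pass_certainty <- as.integer(flags$pass_certainty[m])
  out$pass_csa <- as.integer(flags$pass_csa[m])
  out$pass_circ <- as.integer(flags$pass_circ[m])
  out$aggregate_code <- flags$aggregate_code[m]
  for (nm in setdiff(cols, "Label")) out[[nm]] <- formatC(out[[nm]], format = "f", digits = 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
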