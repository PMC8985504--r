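#' Two-dimensional (x, h) histograms with exact bin volumes
#'
#' Bins the folded `(x, |h|)` positions of pair records on a square grid
#' clipped to the search sphere.  Each bin is a small cylindrical shell; its
#' volume is `2 * pi * (x2^2 - x1^2) * dh`, doubled because the folded |h|
#' axis aggregates both faces of the ring plane, and computed exactly
#' (spherical-cap correction) for bins straddling the sphere boundary.
#' Densities are counts divided by bin volume, which makes bins of different
#' `x` comparable; bins with `x` below one bin width have near-zero volume
#' and are flagged `low_volume`.
#'
#' @param pairs a `pair_set`, or a data.frame with columns `x` and `h`.
#' @param bin bin width in Angstrom (`dx = dh`); the canonical choices are
#'   0.01 for count maps and 0.05 for density maps.
#' @param radius sphere radius in Angstrom.
#' @return object of class `histogram2d`: `x_edges`, `h_edges`, `counts`,
#'   `volumes`, `densities` (matrices, x by h), `low_volume` (logical vector
#'   over x bins), `bin`, `radius`, and `folded = TRUE` (|h| aggregates the
#'   two half-spaces; volumes are doubled accordingly).
#' @export
build_histograms <- function(pairs, bin = 0.05, radius = 5.0) {
  if (bin <= 0) stop("bin width must be > 0")
  df <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  edges <- seq(0, radius, by = bin)
  if (abs(edges[length(edges)] - radius) > 1e-12) edges <- c(edges, radius)
  nb <- length(edges) - 1L
  counts <- matrix(0L, nb, nb)
  if (nrow(df)) {
    ix <- findInterval(df$x, edges, rightmost.closed = TRUE)
    ih <- findInterval(df$h, edges, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nb & ih >= 1 & ih <= nb
    for (k in which(ok)) counts[ix[k], ih[k]] <- counts[ix[k], ih[k]] + 1L
  }
  vol <- matrix(0, nb, nb)
  for (i in seq_len(nb)) {
    x1 <- edges[i]; x2 <- edges[i + 1]
    if (x1 >= radius) next
    for (j in seq_len(nb)) {
      vol[i, j] <- .clipped_rect_volume(x1, min(x2, radius),
                                        edges[j], edges[j + 1], radius)
    }
  }
  dens <- ifelse(vol > 0, counts / vol, NA_real_)
  out <- list(x_edges = edges, h_edges = edges, counts = counts,
              volumes = vol, densities = dens,
              low_volume = edges[-length(edges)] < bin,
              bin = bin, radius = radius, folded = TRUE)
  class(out) <- "histogram2d"
  out
}

#' @export
print.histogram2d <- function(x, ...) {
  cat(sprintf("histogram2d: %d x %d bins of %.3g A, %d records, radius %g A\n",
              nrow(x$counts), ncol(x$counts), x$bin, sum(x$counts), x$radius))
  invisible(x)
}

#' Write a histogram as CSV with explicit bin-edge columns
#'
#' @param hist a `histogram2d`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  nb <- length(hist$x_edges) - 1L
  grid <- expand.grid(i = seq_len(nb), j = seq_len(nb))
  df <- data.frame(
    x_lo = hist$x_edges[grid$i], x_hi = hist$x_edges[grid$i + 1],
    h_lo = hist$h_edges[grid$j], h_hi = hist$h_edges[grid$j + 1],
    count = hist$counts[cbind(grid$i, grid$j)],
    volume = hist$volumes[cbind(grid$i, grid$j)],
    density = hist$densities[cbind(grid$i, grid$j)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Region occupancy tables
#'
#' Counts and percentages of each group's pairs falling in regions A, B and
#' C; the percentage is the ratio of the region count to the group's count
#' in the entire sphere.
#'
#' @param pairs a `pair_set` or pairs data.frame.
#' @param group_by grouping column: `"ring_code"`, `"anion_code"` or
#'   `"ring_class"`.
#' @return data.frame with one row per group: counts `A`, `B`, `C`,
#'   `sphere`, and percentages `A_pct`, `B_pct`, `C_pct`.
#' @export
region_occupancy <- function(pairs,
                             group_by = c("ring_code", "anion_code",
                                          "ring_class")) {
  group_by <- match.arg(group_by)
  df <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  if (!nrow(df)) {
    return(data.frame(group = character(), A = integer(), B = integer(),
                      C = integer(), sphere = integer(), A_pct = numeric(),
                      B_pct = numeric(), C_pct = numeric()))
  }
  g <- df[[group_by]]
  out <- do.call(rbind, lapply(sort(unique(g)), function(gr) {
    sub <- df[g == gr, ]
    n <- nrow(sub)
    cnt <- vapply(c("A", "B", "C"), function(rg) sum(sub$region == rg), 0L)
    data.frame(group = gr, A = cnt[["A"]], B = cnt[["B"]], C = cnt[["C"]],
               sphere = n,
               A_pct = 100 * cnt[["A"]] / n, B_pct = 100 * cnt[["B"]] / n,
               C_pct = 100 * cnt[["C"]] / n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Orientation histogram of planar anions per region
#'
#' Angle between the anion plane and the ring plane, binned in `[0, 90]`
#' degrees and reported per region.  Only planar anions enter; metal-bound
#' anions (ion pairs) and linear/monoatomic anions are excluded.
#'
#' @param pairs a `pair_set` or pairs data.frame (needs columns
#'   `orientation_angle`, `metal_bound`, `region`).
#' @param breaks angle bin edges in degrees.
#' @return data.frame: `region`, `angle_lo`, `angle_hi`, `count`.
#' @export
orientation_histogram <- function(pairs, breaks = seq(0, 90, by = 10)) {
  df <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  df <- df[!is.na(df$orientation_angle) & !df$metal_bound, , drop = FALSE]
  out <- expand.grid(region = c("A", "B", "C", "outside"),
                     bin = seq_len(length(breaks) - 1L),
                     stringsAsFactors = FALSE)
  out$angle_lo <- breaks[out$bin]
  out$angle_hi <- breaks[out$bin + 1L]
  out$count <- 0L
  for (k in seq_len(nrow(df))) {
    b <- findInterval(df$orientation_angle[k], breaks, rightmost.closed = TRUE)
    hit <- out$region == df$region[k] & out$bin == b
    out$count[hit] <- out$count[hit] + 1L
  }
  out$bin <- NULL
  out
}

#' Histogram of sequence separations per region
#'
#' @param pairs a `pair_set` or pairs data.frame.
#' @param region restrict to one region label, or `NULL` for all (reported
#'   per region).
#' @return data.frame: `region`, `delta`, `count` (same-chain pairs with a
#'   defined separation only).
#' @export
delta_histogram <- function(pairs, region = NULL) {
  df <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  df <- df[df$same_chain & !is.na(df$delta), , drop = FALSE]
  if (!is.null(region)) df <- df[df$region %in% region, , drop = FALSE]
  if (!nrow(df)) {
    return(data.frame(region = character(), delta = integer(),
                      count = integer()))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = list(region = df$region, delta = df$delta),
                          FUN = sum)
  agg[order(agg$region, agg$delta), , drop = FALSE]
}

#' Synthon group counts and percentages per region
#'
#' One row per motif group (i-vii), plus "rest" and "total", per region.
#' Groups overlap, so percentages need not sum to 100.
#'
#' @param pairs a classified `pair_set` (see [classify_pairs()]) or a pairs
#'   data.frame with a `synthons` column.
#' @param regions region labels to report.
#' @return data.frame: `region`, `group`, `count`, `pct` (of the region's
#'   total pair count).
#' @export
synthon_fractions <- function(pairs, regions = c("A", "B", "C")) {
  df <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  groups <- c("i", "ii", "iii", "iv", "v", "vi", "vii")
  out <- list()
  for (rg in regions) {
    sub <- df[df$region == rg, , drop = FALSE]
    total <- nrow(sub)
    flags <- strsplit(sub$synthons, ",", fixed = TRUE)
    for (g in groups) {
      n <- sum(vapply(flags, function(f) g %in% f, logical(1)))
      out[[length(out) + 1L]] <- data.frame(
        region = rg, group = g, count = n,
        pct = if (total) 100 * n / total else NA_real_)
    }
    nrest <- sum(!nzchar(sub$synthons))
    out[[length(out) + 1L]] <- data.frame(
      region = rg, group = "rest", count = nrest,
      pct = if (total) 100 * nrest / total else NA_real_)
    out[[length(out) + 1L]] <- data.frame(
      region = rg, group = "total", count = total, pct = if (total) 100 else NA_real_)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
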