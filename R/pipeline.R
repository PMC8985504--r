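#' Mine ring-anion pairs from a set of structure files
#'
#' End-to-end orchestration: read each structure, apply the resolution
#' filter, place amino-acid polar hydrogens, perceive rings/anions/cations/
#' donors, search the sphere, classify the ternary synthons, annotate
#' sequence separations and tetraloops, and deduplicate across sequence
#' clusters.  Deterministic for identical inputs and configuration.
#'
#' @param paths character vector of mmCIF/PDB files, or a list of
#'   `structure_model` objects.
#' @param resolution_cutoff resolution filter in Angstrom (default 2.5).
#' @param keep_unresolved keep entries with no resolution record?
#' @param radius search sphere radius in Angstrom.
#' @param spec a [region_spec()].
#' @param thresholds a [default_synthon_thresholds()].
#' @param dict a [default_chem_dictionary()].
#' @param clusters cluster map from [read_cluster_map()], or `NULL`.
#' @param dssp named character vector of DSSP file paths keyed by pdb id
#'   (lower case), or `NULL`.
#' @param add_hydrogens place amino-acid polar hydrogens before donor
#'   perception?
#' @return list of class `mine_result`: `pairs` (combined data.frame),
#'   `sets` (per-structure classified `pair_set`s) and `manifest`
#'   (per-stage counts, filtered files, configuration echo).
#' @export
run_mine <- function(paths, resolution_cutoff = 2.5, keep_unresolved = FALSE,
                     radius = 5.0, spec = default_region_spec(),
                     thresholds = default_synthon_thresholds(),
                     dict = default_chem_dictionary(), clusters = NULL,
                     dssp = NULL, add_hydrogens = TRUE) {
  models <- list()
  filtered <- character()
  failed <- character()
  if (is.character(paths)) {
    for (p in paths) {
      m <- tryCatch(read_structure(p), error = function(e) {
        warning("skipping unreadable file ", p, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(m)) { failed <- c(failed, p); next }
      if (!filter_by_resolution(m, resolution_cutoff, keep_unresolved)) {
        filtered <- c(filtered, p)
        next
      }
      models[[length(models) + 1L]] <- m
    }
    if (!length(models) && !length(filtered)) {
      stop("no parseable input structures")
    }
  } else {
    models <- Filter(function(m) filter_by_resolution(m, resolution_cutoff,
                                                      keep_unresolved), paths)
    filtered <- setdiff(vapply(paths, function(m) m$pdb_id, ""),
                        vapply(models, function(m) m$pdb_id, ""))
  }
  sets <- list()
  counts <- list()
  for (m in models) {
    if (add_hydrogens) m <- add_amino_acid_hydrogens(m)
    rings <- detect_aromatic_rings(m)
    anions <- detect_anion_sites(m, dict)
    cations <- detect_cation_sites(m, dict)
    donors <- detect_h_donors(m)
    ps <- find_pairs(m, rings, anions, radius = radius, spec = spec)
    ps <- classify_pairs(ps, cations, donors, thresholds)
    ps <- flag_gnra(ps, m)
    if (!is.null(dssp)) {
      dp <- dssp[tolower(m$pdb_id)]
      if (!is.na(dp)) ps <- attach_secondary_structure(ps, unname(dp))
    }
    sets[[m$pdb_id]] <- ps
    counts[[m$pdb_id]] <- c(rings = length(rings), anions = length(anions),
                            cations = length(cations),
                            donors = length(donors), pairs = nrow(ps$pairs))
  }
  pairs <- do.call(rbind, c(lapply(sets, function(s) s$pairs),
                            list(make.row.names = FALSE)))
  if (is.null(pairs)) pairs <- .empty_pairs_df()
  pairs <- deduplicate_pairs(pairs, clusters)
  out <- list(pairs = pairs, sets = sets,
              manifest = list(
                n_input = if (is.character(paths)) length(paths) else
                  length(paths),
                n_mined = length(models), filtered = filtered,
                failed = failed, counts = counts,
                config = list(resolution_cutoff = resolution_cutoff,
                              radius = radius, spec = unclass(spec),
                              thresholds = unclass(thresholds))))
  class(out) <- "mine_result"
  out
}

#' Build the report tables from mined pairs
#'
#' @param pairs a `mine_result`, `pair_set`, or pairs data.frame.
#' @param bin histogram bin width in Angstrom.
#' @param exclude_hbond_pairs drop pairs flagged with motif (v) before
#'   histogramming (the "after exclusion of anion-ring hydrogen bonds"
#'   view).
#' @param out_dir optional directory; when given, every table is also
#'   written as CSV.
#' @return list of tables: `histogram` (a `histogram2d`),
#'   `region_by_ring`, `region_by_anion`, `orientation`, `delta`,
#'   `synthons`.
#' @export
run_report <- function(pairs, bin = 0.05, exclude_hbond_pairs = FALSE,
                       out_dir = NULL) {
  df <- if (inherits(pairs, "mine_result")) pairs$pairs
    else if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  need <- c("x", "h", "region", "ring_code", "anion_code", "synthons")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pair table lacks column(s): ",
                         paste(miss, collapse = ", "))
  hdf <- df
  if (exclude_hbond_pairs) {
    hdf <- hdf[!vapply(strsplit(hdf$synthons, ","), function(f) "v" %in% f,
                       logical(1)), , drop = FALSE]
  }
  rep <- list(
    histogram = build_histograms(hdf, bin = bin),
    region_by_ring = region_occupancy(df, "ring_code"),
    region_by_anion = region_occupancy(df, "anion_code"),
    orientation = orientation_histogram(df),
    delta = delta_histogram(df),
    synthons = synthon_fractions(df)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_histogram_csv(rep$histogram, file.path(out_dir, "histogram.csv"))
    for (nm in c("region_by_ring", "region_by_anion", "orientation",
                 "delta", "synthons")) {
      utils::write.csv(rep[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(df, file.path(out_dir, "pairs.csv"), row.names = FALSE)
  }
  rep
}
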