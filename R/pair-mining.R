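#' @name pair_mining
#' @title Mining ring-anion pairs within the search sphere
#' @description
#' For every detected aromatic ring, anion sites with an atom inside the
#' search sphere (default radius 5 Angstrom around the ring centroid) yield
#' one pair record; the site atom nearest to the centroid is the pair's
#' representative.  Records carry the `(x, h, side)` cylindrical position,
#' the region label, the signed sequence separation of same-chain pairs, and
#' optional secondary-structure and tetraloop annotations.
NULL

.empty_pairs_df <- function() {
  data.frame(
    pdb_id = character(), ring_idx = integer(), anion_idx = integer(),
    ring_code = character(), ring_class = character(),
    ring_chain = character(), ring_resno = integer(),
    ring_res_key = character(), anion_code = character(),
    anion_chain = character(), anion_resno = integer(),
    anion_res_key = character(), anion_atom = character(),
    rep_i = integer(), x = numeric(), h = numeric(), side = integer(),
    r = numeric(), region = character(), same_chain = logical(),
    delta = integer(), orientation_angle = numeric(),
    metal_bound = logical(), ss_ring = character(), ss_anion = character(),
    gnra = character(), synthons = character(), stringsAsFactors = FALSE)
}

# hash-grid neighbour search: indices of `pts` within `radius` of `q`
.make_grid <- function(pts, cell) {
  keys <- paste(floor(pts[, 1] / cell), floor(pts[, 2] / cell),
                floor(pts[, 3] / cell), sep = "_")
  split(seq_len(nrow(pts)), keys)
}

.grid_query <- function(grid, pts, q, cell, radius) {
  cx <- floor(q[1] / cell); cy <- floor(q[2] / cell); cz <- floor(q[3] / cell)
  cand <- integer()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- paste(cx + dx, cy + dy, cz + dz, sep = "_")
    hit <- grid[[k]]
    if (!is.null(hit)) cand <- c(cand, hit)
  }
  if (!length(cand)) return(integer())
  d <- sqrt(colSums((t(pts[cand, , drop = FALSE]) - q)^2))
  cand[d <= radius]
}

#' Find ring-anion pairs within the search sphere
#'
#' One record per (ring, anion site) whose nearest site atom lies within
#' `radius` of the ring centroid; that atom becomes the representative.
#' Anion sites belonging to the ring's own residue are excluded.  A hash-grid
#' spatial index keeps the search near-linear in atom count; results are
#' identical to the all-pairs scan.
#'
#' @param m a `structure_model`.
#' @param rings list from [detect_aromatic_rings()].
#' @param anions list from [detect_anion_sites()].
#' @param radius search radius in Angstrom (default 5).
#' @param spec a [region_spec()] for region labelling.
#' @return object of class `pair_set`: list with `pairs` (data.frame),
#'   `rings`, `frames`, `anions`, `pdb_id`.
#' @export
find_pairs <- function(m, rings, anions, radius = 5.0,
                       spec = default_region_spec()) {
  frames <- lapply(rings, ring_frame)
  out <- list(pairs = .empty_pairs_df(), rings = rings, frames = frames,
              anions = anions,
              pdb_id = m$pdb_id)
  class(out) <- "pair_set"
  if (!length(rings) || !length(anions)) return(out)

  site_of <- rep(seq_along(anions), vapply(anions, function(a) nrow(a$coords), 1L))
  apts <- do.call(rbind, lapply(anions, function(a) a$coords))
  atom_i <- unlist(lapply(anions, function(a) seq_len(nrow(a$coords))))
  grid <- .make_grid(apts, radius)
  rt <- residue_table(m)
  res_class <- stats::setNames(rt$class, rt$key)

  rows <- list()
  for (ri in seq_along(rings)) {
    rg <- rings[[ri]]
    fr <- frames[[ri]]
    hit <- .grid_query(grid, apts, fr$centroid, radius, radius)
    if (!length(hit)) next
    d <- sqrt(colSums((t(apts[hit, , drop = FALSE]) - fr$centroid)^2))
    for (si in unique(site_of[hit])) {
      a <- anions[[si]]
      if (a$res_key == rg$res_key) next
      sel <- which(site_of[hit] == si)
      best <- sel[which.min(d[sel])]
      pos <- project_to_ring_frame(fr, apts[hit[best], ])
      same <- a$chain == rg$chain
      ring_poly <- rg$ring_class != "ligand"
      anion_poly <- res_class[[a$res_key]] %in%
        c("amino-acid", "ribonucleotide", "deoxyribonucleotide")
      delta <- sequence_delta(rg$resno, rg$insert, a$resno, a$insert,
                              same_chain = same,
                              both_polymeric = ring_poly && anion_poly)
      ang <- if (a$planarity == "planar" && !is.null(a$plane)) {
        plane_angle(fr$normal, a$plane$normal)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        pdb_id = m$pdb_id, ring_idx = ri, anion_idx = si,
        ring_code = rg$ring_code, ring_class = rg$ring_class,
        ring_chain = rg$chain, ring_resno = rg$resno,
        ring_res_key = rg$res_key, anion_code = a$resid,
        anion_chain = a$chain, anion_resno = a$resno,
        anion_res_key = a$res_key,
        anion_atom = a$site_names[atom_i[hit[best]]],
        rep_i = atom_i[hit[best]],
        x = pos$x, h = pos$h, side = pos$side, r = pos$r,
        region = assign_region(pos$x, pos$h, spec),
        same_chain = same, delta = delta,
        orientation_angle = ang, metal_bound = a$metal_bound,
        ss_ring = NA_character_, ss_anion = NA_character_,
        gnra = NA_character_, synthons = "",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) out$pairs <- do.call(rbind, rows)
  rownames(out$pairs) <- NULL
  out
}

#' Signed sequence separation of a same-chain pair
#'
#' `rID - aID` with author numbering; `NA` when the residues sit on different
#' chains, either is non-polymeric, or an insertion code makes the numbering
#' ambiguous.
#'
#' @param ring_resno,anion_resno author sequence numbers.
#' @param ring_insert,anion_insert insertion codes (`NA`/`""` for none).
#' @param same_chain,both_polymeric logical preconditions.
#' @return integer or `NA`.
#' @export
sequence_delta <- function(ring_resno, ring_insert, anion_resno, anion_insert,
                           same_chain = TRUE, both_polymeric = TRUE) {
  has_ins <- function(i) !is.na(i) & i != ""
  if (!same_chain || !both_polymeric ||
      has_ins(ring_insert) || has_ins(anion_insert)) {
    return(NA_integer_)
  }
  as.integer(ring_resno - anion_resno)
}

# ---- non-redundant pair sets ------------------------------------------------

#' Read a chain-to-sequence-cluster mapping table
#'
#' Three columns (tab- or comma-separated, optional header line
#' `pdb_id...`): `pdb_id`, `chain_id`, `cluster_id`.
#'
#' @param path file path.
#' @return named character vector, names `"<pdb_id>|<chain_id>"`.
#' @export
read_cluster_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*(#|pdb_id)", lines)]
  parts <- strsplit(lines, "[\t,]\\s*")
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed cluster map line: ", lines[which(bad)[1]])
  stats::setNames(vapply(parts, `[`, "", 3),
                  paste(tolower(vapply(parts, `[`, "", 1)),
                        vapply(parts, `[`, "", 2), sep = "|"))
}

.cluster_of <- function(clusters, pdb_id, chain) {
  key <- paste(tolower(pdb_id), chain, sep = "|")
  hit <- clusters[key]
  miss <- is.na(hit)
  if (any(miss)) {
    warning("no sequence cluster for ", paste(unique(key[miss]), collapse = ", "),
            "; using fallback ids", call. = FALSE)
    hit[miss] <- paste0("unclustered:", key[miss])
  }
  unname(hit)
}

#' Deduplicate pairs across redundant depositions
#'
#' Each motif is kept once per pair of sequence clusters: the uniqueness key
#' combines the ring- and anion-chain clusters, the ring code, the anion
#' residue code and site-atom name, the sequence separation (or an
#' inter-chain marker) and the region.  The first occurrence in `(pdb_id,
#' ring)` order is retained, so the result is deterministic and idempotent.
#'
#' @param pairs a `pair_set` or a pairs data.frame (possibly concatenated
#'   over structures).
#' @param clusters named vector from [read_cluster_map()], or `NULL` to treat
#'   every chain as its own cluster (no cross-entry deduplication; a warning
#'   is issued).
#' @return pairs of the same shape, reduced to unique records.
#' @export
deduplicate_pairs <- function(pairs, clusters = NULL) {
  df <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  if (!nrow(df)) return(pairs)
  if (is.null(clusters)) {
    warning("no cluster map supplied: every chain is its own cluster, ",
            "so no deduplication happens across entries", call. = FALSE)
    rc <- paste(tolower(df$pdb_id), df$ring_chain, sep = "|")
    ac <- paste(tolower(df$pdb_id), df$anion_chain, sep = "|")
  } else {
    rc <- .cluster_of(clusters, df$pdb_id, df$ring_chain)
    ac <- .cluster_of(clusters, df$pdb_id, df$anion_chain)
  }
  key <- paste(rc, ac, df$ring_code,
               df$anion_code, df$anion_atom,
               ifelse(is.na(df$delta), "interchain", df$delta),
               df$region, sep = "//")
  ord <- order(df$pdb_id, df$ring_idx, df$anion_idx)
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)
  if (inherits(pairs, "pair_set")) {
    pairs$pairs <- df[keep, , drop = FALSE]
    rownames(pairs$pairs) <- NULL
    return(pairs)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- secondary structure ----------------------------------------------------

#' Parse a classic-format DSSP output file
#'
#' Reads the per-residue block of a DSSP text file (the assignment algorithm
#' itself is external; its output is consumed here).
#'
#' @param path DSSP file path.
#' @return data.frame with `chain`, `resno`, `insert`, `ss` (one of
#'   `H,G,I,E,B,T,S,-`).
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (!length(start)) stop("not a classic DSSP file: ", path)
  body <- lines[(start[1] + 1L):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "-"
  data.frame(
    chain = trimws(substr(body, 12, 12)),
    resno = as.integer(trimws(substr(body, 6, 10))),
    insert = trimws(substr(body, 11, 11)),
    ss = ss, stringsAsFactors = FALSE)
}

#' Attach DSSP secondary-structure codes to pair records
#'
#' Amino-acid residues of each pair gain their DSSP code; nucleotides and
#' residues absent from the DSSP output stay `NA`.
#'
#' @param pairs a `pair_set`.
#' @param dssp a file path or a data.frame from [read_dssp()].
#' @return the `pair_set` with `ss_ring`/`ss_anion` filled in.
#' @export
attach_secondary_structure <- function(pairs, dssp) {
  stopifnot(inherits(pairs, "pair_set"))
  if (is.character(dssp)) dssp <- read_dssp(dssp)
  df <- pairs$pairs
  if (!nrow(df)) return(pairs)
  dkey <- paste(dssp$chain, dssp$resno, sep = "|")
  look <- function(chain, resno, is_aa) {
    out <- rep(NA_character_, length(chain))
    i <- match(paste(chain, resno, sep = "|"), dkey)
    out[is_aa & !is.na(i)] <- dssp$ss[i[is_aa & !is.na(i)]]
    if (any(is_aa & is.na(i))) {
      warning("residues missing from DSSP output left unannotated",
              call. = FALSE)
    }
    out
  }
  ring_aa <- df$ring_class == "amino-acid"
  anion_aa <- df$anion_code %in% .AA3
  df$ss_ring <- look(df$ring_chain, df$ring_resno, ring_aa)
  df$ss_anion <- look(df$anion_chain, df$anion_resno, anion_aa)
  pairs$pairs <- df
  pairs
}

# ---- GNRA tetraloop flags ---------------------------------------------------

#' Flag GNRA tetraloop ring-anion pairs in RNA chains
#'
#' A pair is flagged `gnra_GR` when the ring residue is the G and the anion
#' residue the R of a contiguous G-N-R-A subsequence (R is G or A) with
#' sequence separation `rID - aID = -2`, and `gnra_GA` analogously for the
#' G...A pair at separation -3.
#'
#' @param pairs a `pair_set`.
#' @param m the `structure_model` the pairs came from (provides the chain
#'   sequences).
#' @return the `pair_set` with the `gnra` column filled in.
#' @export
flag_gnra <- function(pairs, m) {
  stopifnot(inherits(pairs, "pair_set"))
  df <- pairs$pairs
  if (!nrow(df)) return(pairs)
  rt <- residue_table(m)
  rna <- rt[rt$class == "ribonucleotide" & (is.na(rt$insert) | rt$insert == ""), ]
  base_at <- stats::setNames(rna$resid, paste(rna$chain, rna$resno, sep = "|"))
  gnra_window <- function(chain, i) {
    b <- base_at[paste(chain, i + 0:3, sep = "|")]
    if (anyNA(b)) return(FALSE)
    b[1] == "G" && b[3] %in% c("G", "A") && b[4] == "A"
  }
  for (k in seq_len(nrow(df))) {
    if (df$ring_class[k] != "ribonucleotide") next
    if (!df$same_chain[k] || is.na(df$delta[k])) next
    if (sub("\\..*$", "", df$ring_code[k]) != "G") next
    i <- df$ring_resno[k]
    if (df$delta[k] == -2L && gnra_window(df$ring_chain[k], i)) {
      df$gnra[k] <- "gnra_GR"
    } else if (df$delta[k] == -3L && gnra_window(df$ring_chain[k], i)) {
      df$gnra[k] <- "gnra_GA"
    }
  }
  pairs$pairs <- df
  pairs
}
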